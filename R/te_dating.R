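# Kimura two-parameter divergence, LTR-pair and consensus-based
# insertion ages, and the correlation / expression-category analyses
# built on them.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Columns with gaps, `N` or any non-ACGT character are excluded from
#' the comparable sites. With transition proportion `P` (A<->G, C<->T)
#' and transversion proportion `Q` over the comparable sites,
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. Saturated pairs
#' (either log argument <= 0) raise an explicit error rather than
#' returning `NaN`.
#'
#' @param seq_a,seq_b Equal-length (gapped) nucleotide strings.
#' @return List with `d`, `P`, `Q`, `comparable_sites`, `transitions`,
#'   `transversions`.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length")
  }
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n < 1L) stop("no comparable sites")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ti <- diff & ((a %in% PURINES & b %in% PURINES) |
                  (a %in% PYRIMIDINES & b %in% PYRIMIDINES))
  P <- sum(ti) / n
  Q <- sum(diff & !ti) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    stop("K2P saturation: substitution proportions too high (P = ",
         signif(P, 4), ", Q = ", signif(Q, 4), ")")
  }
  d <- -0.5 * log(arg1) - 0.25 * log(arg2)
  list(d = d, P = P, Q = Q, comparable_sites = n,
       transitions = sum(ti), transversions = sum(diff & !ti))
}

#' LTR-pair insertion age
#'
#' `T = d / (2r)`: the two LTRs of one element are identical at
#' insertion and each accumulates substitutions at rate `r`
#' thereafter, so their pairwise divergence grows at `2r` per year.
#'
#' @param d K2P divergence between the 5' and 3' LTRs (subs/site).
#' @param rate Substitution rate `r` in subs/site/yr (default `2e-8`).
#' @return Age in years.
#' @export
ltr_insertion_age <- function(d, rate = 2e-8) {
  if (any(d < 0)) stop("divergence must be >= 0")
  if (rate <= 0) stop("rate must be positive")
  d / (2 * rate)
}

#' Consensus-based family age
#'
#' Computes the K2P distance of each member to the family consensus
#' (a proxy for the ancestral element), averages them into `k`, and
#' converts to years as `T = k / r`: each copy is a single lineage
#' diverging from the ancestor at rate `r`. Members whose distance is
#' saturated are excluded with a warning; if all members saturate, an
#' error is raised.
#'
#' @param members Named character vector of member sequences, each the
#'   same length as `consensus` (or already aligned to it).
#' @param consensus Consensus/ancestral sequence string.
#' @param rate Substitution rate in subs/site/yr.
#' @param family_id Id recorded in the result.
#' @return List with `family_id`, `k` (mean corrected divergence),
#'   `age_years`, `n_members`, `member_d` (per-member distances).
#' @export
family_consensus_age <- function(members, consensus, rate = 2e-8,
                                 family_id = "family") {
  stopifnot(length(members) >= 2L)
  if (rate <= 0) stop("rate must be positive")
  d <- vapply(members, function(m) {
    tryCatch(k2p_distance(m, consensus)$d, error = function(e) NA_real_)
  }, 0)
  if (anyNA(d)) {
    warning(sum(is.na(d)), " member(s) excluded for K2P saturation")
    d <- d[!is.na(d)]
  }
  if (length(d) == 0L) stop("all members saturated against the consensus")
  k <- mean(d)
  structure(list(family_id = family_id, k = k, age_years = k / rate,
                 n_members = length(d), member_d = d),
            class = "family_age",
            age_formula = "T = k/r (printed form 'T = kr' inverted)")
}

#' Correlation between family divergence and estimated age
#'
#' Pearson correlation between the mean corrected divergences `k` and
#' the estimated ages across families. Because age is linear in `k`,
#' the correlation is exactly 1 whenever the `k` values vary.
#'
#' @param family_ages List of [family_consensus_age()] results (or a
#'   data.frame with columns `k` and `age_years`).
#' @return Pearson correlation coefficient (with attribute `low_n`
#'   flagged when fewer than 3 families are supplied).
#' @export
age_divergence_correlation <- function(family_ages) {
  if (is.data.frame(family_ages)) {
    k <- family_ages$k
    age <- family_ages$age_years
  } else {
    k <- vapply(family_ages, `[[`, 0, "k")
    age <- vapply(family_ages, `[[`, 0, "age_years")
  }
  if (length(k) < 2L) stop("need at least 2 families")
  if (stats::sd(k) == 0) {
    stop("zero variance in k: correlation undefined")
  }
  r <- cor(k, age)
  if (length(k) < 3L) attr(r, "low_n") <- TRUE
  r
}

#' Correlation between element age and genome amplification
#'
#' Standard Pearson correlation between per-element insertion ages and
#' per-element genome coverage (a copy-number proxy), over matched
#' element ids.
#'
#' @param ages Named numeric vector of ages (names = element ids).
#' @param coverages Named numeric vector of coverages over the same
#'   ids.
#' @return Pearson correlation coefficient.
#' @export
age_amplification_correlation <- function(ages, coverages) {
  if (is.null(names(ages)) || is.null(names(coverages))) {
    stop("ages and coverages must be named by element id")
  }
  if (length(ages) < 3L) stop("need at least 3 elements")
  only_a <- setdiff(names(ages), names(coverages))
  only_c <- setdiff(names(coverages), names(ages))
  if (length(only_a) > 0L || length(only_c) > 0L) {
    stop("element ids do not match; only in ages: ",
         paste(head(only_a, 5L), collapse = ", "),
         "; only in coverages: ", paste(head(only_c, 5L), collapse = ", "))
  }
  cor(ages, coverages[names(ages)])
}

#' Classify TE expression from coverage tables
#'
#' Each element is categorised from its transcriptome coverages:
#' `silent` when both flower and root_stem are below the presence
#' threshold, `flower_only` / `rootstem_only` when exactly one reaches
#' it, `both` otherwise. Also reports Pearson correlations between the
#' genome column and each transcriptome column.
#'
#' @param table Coverage `data.frame` with columns `element_id`,
#'   `genome`, `flower`, `root_stem` (see [read_coverage_table()]).
#' @param presence_threshold Minimum coverage counting as expressed;
#'   the default 5e-4 means any value that would still be positive
#'   after rounding to 3 decimals.
#' @return List with `profiles` (`element_id`, coverages, `category`),
#'   `category_counts`, and `correlations` (genome vs flower, genome
#'   vs root_stem, genome vs mean transcriptome).
#' @export
classify_expression <- function(table, presence_threshold = 5e-4) {
  need <- c("element_id", "genome", "flower", "root_stem")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0L) {
    stop("coverage table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  fl <- table$flower >= presence_threshold
  rs <- table$root_stem >= presence_threshold
  category <- ifelse(!fl & !rs, "silent",
                     ifelse(fl & !rs, "flower_only",
                            ifelse(!fl & rs, "rootstem_only", "both")))
  profiles <- data.frame(element_id = table$element_id,
                         genome = table$genome, flower = table$flower,
                         root_stem = table$root_stem, category = category,
                         stringsAsFactors = FALSE)
  counts <- table(factor(category, levels = c("silent", "flower_only",
                                              "rootstem_only", "both")))
  list(profiles = profiles,
       category_counts = as.data.frame(counts,
                                       responseName = "n",
                                       stringsAsFactors = FALSE),
       correlations = c(
         genome_vs_flower = cor(table$genome, table$flower),
         genome_vs_rootstem = cor(table$genome, table$root_stem),
         genome_vs_transcriptome = cor(table$genome,
                                       (table$flower + table$root_stem) / 2)))
}
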