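# De novo repeat family detection: k-mer-support interval calling,
# single-linkage clustering under blastclust-style identity/coverage
# thresholds, star-alignment consensus building, and family abundance
# summaries.

#' Call repetitive intervals from k-mer support
#'
#' Maximal runs of positions covered by k-mers occurring
#' `>= freq_threshold` times are merged across gaps of up to
#' `merge_gap` bp (tolerating isolated low-frequency k-mers inside
#' diverged copies) and emitted when at least `min_len` bp long.
#'
#' @param seqs Named character vector of scaffolds/clones.
#' @param index [build_kmer_index()] built over the same sequence set.
#' @param freq_threshold Repetitive-count threshold (default 4).
#' @param min_len Minimum emitted interval length (default 50 bp).
#' @param merge_gap Maximum uncovered gap to bridge (default 50 bp).
#' @return `data.frame` of repeat copies: `copy_id`, `scaffold`,
#'   `start`, `end` (0-based half-open) and `seq`.
#' @export
find_repeat_intervals <- function(seqs, index, freq_threshold = 4L,
                                  min_len = 50L, merge_gap = 50L) {
  prof <- repetitive_profile(seqs, index, freq_threshold)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    cov <- prof$coverage[[i]]
    if (length(cov) == 0L || !any(cov)) next
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    iv <- cbind(starts[r$values], ends[r$values])  # 1-based closed
    if (nrow(iv) > 1L) {
      gaps <- iv[-1L, 1L] - iv[-nrow(iv), 2L] - 1L
      grp <- cumsum(c(0L, gaps > merge_gap))
      iv <- cbind(tapply(iv[, 1L], grp, min), tapply(iv[, 2L], grp, max))
    }
    len <- iv[, 2L] - iv[, 1L] + 1L
    iv <- iv[len >= min_len, , drop = FALSE]
    if (nrow(iv) == 0L) next
    out[[i]] <- data.frame(
      scaffold = names(seqs)[i],
      start = as.integer(iv[, 1L] - 1L), end = as.integer(iv[, 2L]),
      seq = substring(seqs[[i]], iv[, 1L], iv[, 2L]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(copy_id = character(0), scaffold = character(0),
                      start = integer(0), end = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  res <- res[order(res$scaffold, res$start), , drop = FALSE]
  res <- cbind(copy_id = sprintf("rep%05d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# Unique words of a sequence plus its reverse complement; used as a
# cheap relatedness prefilter before any alignment is attempted.
word_set <- function(seq, w = 12L) {
  n <- nchar(seq)
  if (n < w) return(character(0))
  fwd <- unique(substring(seq, seq_len(n - w + 1L), seq.int(w, n)))
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  unique(c(fwd, substring(rc, seq_len(n - w + 1L), seq.int(w, n))))
}

# Best local alignment identity and coverage of the shorter sequence,
# blastclust-style (-S identity over -L of the shorter length).
pair_link <- function(a, b, identity_threshold, coverage_threshold,
                      match = 1, mismatch = -1, gap = -2) {
  shorter <- min(nchar(a), nchar(b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = TRUE),
    gapOpening = 0, gapExtension = abs(gap))
  w <- Biostrings::nchar(aln)
  if (w == 0L) return(FALSE)
  ident <- Biostrings::nmatch(aln) / w
  cov_len <- min(Biostrings::width(Biostrings::pattern(aln)),
                 Biostrings::width(Biostrings::subject(aln)))
  (ident >= identity_threshold) && (cov_len / shorter >= coverage_threshold)
}

#' Cluster repeat copies into families
#'
#' Two copies link when their best local alignment has identity
#' `>= identity_threshold` over at least `coverage_threshold` of the
#' shorter sequence's length; families are the single-linkage connected
#' components. Components with fewer than `min_copies` members stay
#' visible in the cluster report but are not emitted as families.
#'
#' @param copies Output of [find_repeat_intervals()] (needs `copy_id`,
#'   `seq`).
#' @param identity_threshold Minimum alignment identity (default 0.80).
#' @param coverage_threshold Minimum aligned share of the shorter
#'   sequence (default 0.51).
#' @param min_copies Minimum family size (default 5).
#' @return List with `families` (list of `repeat_family` objects:
#'   `family_id`, `members`, `member_ids`, `consensus`, `copy_number`,
#'   `total_bp`) and `report` (a `cluster_report`, see
#'   [cluster_report()]).
#' @export
cluster_copies <- function(copies, identity_threshold = 0.80,
                           coverage_threshold = 0.51, min_copies = 5L) {
  stopifnot(nrow(copies) >= 1L)
  n <- nrow(copies)
  edges <- integer(0)
  if (n > 1L) {
    # prefilter: sequences sharing no 12-mer word (either strand)
    # cannot reach 80% identity over half the shorter sequence
    words <- lapply(copies$seq, word_set)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (!any(words[[i]] %in% words[[j]])) next
        if (pair_link(copies$seq[i], copies$seq[j],
                      identity_threshold, coverage_threshold)) {
          edges <- c(edges, i, j)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  fam_comp <- which(sizes >= min_copies)
  families <- lapply(seq_along(fam_comp), function(q) {
    idx <- which(comp == fam_comp[q])
    members <- setNames(copies$seq[idx], copies$copy_id[idx])
    fam <- list(family_id = sprintf("FAM%04d", q),
                members = members,
                member_ids = copies$copy_id[idx],
                consensus = NA_character_,
                copy_number = length(idx),
                total_bp = sum(nchar(members)))
    class(fam) <- "repeat_family"
    fam$consensus <- build_consensus(fam)
    fam
  })
  report <- cluster_report(n_sequences = n,
                           cluster_sizes = sizes[sizes > 1L],
                           n_unclustered = sum(sizes == 1L))
  membership <- data.frame(copy_id = copies$copy_id,
                           component = comp,
                           family_id = NA_character_,
                           stringsAsFactors = FALSE)
  for (q in seq_along(fam_comp)) {
    membership$family_id[comp == fam_comp[q]] <- sprintf("FAM%04d", q)
  }
  list(families = families, report = report, membership = membership)
}

#' Cluster report
#'
#' Summary of a clustering run in the layout of a blastclust report:
#' sequence and cluster totals, a size histogram at the >5/>20/>50/>100
#' thresholds, and the largest cluster size. Conservation invariant:
#' `n_unclustered + sum(cluster sizes) = n_sequences`.
#'
#' @param n_sequences Total sequences clustered.
#' @param cluster_sizes Integer vector of sizes of clusters with >= 2
#'   members.
#' @param n_unclustered Number of singleton sequences.
#' @return A `cluster_report` list.
#' @export
cluster_report <- function(n_sequences, cluster_sizes, n_unclustered) {
  stopifnot(n_unclustered + sum(cluster_sizes) == n_sequences)
  structure(list(
    n_sequences = n_sequences,
    n_unclustered = n_unclustered,
    n_clusters = length(cluster_sizes),
    clusters_gt5 = sum(cluster_sizes > 5L),
    clusters_gt20 = sum(cluster_sizes > 20L),
    clusters_gt50 = sum(cluster_sizes > 50L),
    clusters_gt100 = sum(cluster_sizes > 100L),
    largest_cluster_size = if (length(cluster_sizes) > 0L)
      max(cluster_sizes) else 0L,
    cluster_sizes = sort(cluster_sizes, decreasing = TRUE)
  ), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("Total number of sequences\t", x$n_sequences, "\n",
      "Number of sequences not clustered\t", x$n_unclustered, "\n",
      "Number of clusters\t", x$n_clusters, "\n",
      "Clusters with >5 sequences\t", x$clusters_gt5, "\n",
      "Clusters with >20 sequences\t", x$clusters_gt20, "\n",
      "Clusters with >50 sequences\t", x$clusters_gt50, "\n",
      "Clusters with >100 sequences\t", x$clusters_gt100, "\n",
      "Number of sequences in the largest cluster\t",
      x$largest_cluster_size, "\n", sep = "")
  invisible(x)
}

#' Build a family consensus by star alignment
#'
#' Members are globally aligned to the longest member; each column of
#' the longest member takes the majority base (ties broken
#' alphabetically). The consensus length equals the longest member's
#' length. With a single member, that member is returned with a
#' warning.
#'
#' @param family A `repeat_family` (or any list with a `members` named
#'   character vector).
#' @return Consensus nucleotide string.
#' @export
build_consensus <- function(family) {
  members <- family$members
  stopifnot(length(members) >= 1L)
  if (length(members) == 1L) {
    warning("single-member family: returning the member as consensus")
    return(unname(members[1L]))
  }
  ref_i <- which.max(nchar(members))
  ref <- members[[ref_i]]
  ref_len <- nchar(ref)
  # votes[base, column of ref]
  votes <- matrix(0L, nrow = 4L, ncol = ref_len,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  add_votes <- function(chars, cols) {
    keep <- chars %in% rownames(votes)
    idx <- cbind(match(chars[keep], rownames(votes)), cols[keep])
    for (q in seq_len(nrow(idx))) {
      votes[idx[q, 1L], idx[q, 2L]] <<- votes[idx[q, 1L], idx[q, 2L]] + 1L
    }
  }
  add_votes(strsplit(ref, "")[[1L]], seq_len(ref_len))
  for (i in seq_along(members)[-ref_i]) {
    m <- members[[i]]
    if (nchar(m) == ref_len && ref_len == nchar(ref)) {
      # equal length: with a substitution-only mutation process the
      # trivial column-to-column alignment is exact
      add_votes(strsplit(m, "")[[1L]], seq_len(ref_len))
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(m), Biostrings::DNAString(ref),
      type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE),
      gapOpening = 2, gapExtension = 2)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    ref_col <- cumsum(sub != "-") +
      (Biostrings::start(Biostrings::subject(aln)) - 1L)
    keep <- sub != "-" & pat != "-"
    add_votes(pat[keep], ref_col[keep])
  }
  top <- apply(votes, 2L, function(v) rownames(votes)[which.max(v)])
  paste(top, collapse = "")
}

#' Family abundance curve
#'
#' Sorts families by total bp (and, separately, by copy number) and
#' reports how many of the top families account for half of the
#' repetitive content on each measure, plus the full cumulative table.
#'
#' @param families List of `repeat_family` objects (needs `total_bp`,
#'   `copy_number`, `family_id`).
#' @return List with `families_for_50pct_bp`, `families_for_50pct_copies`
#'   and `cumulative` (a data.frame sorted by bp).
#' @export
family_abundance_curve <- function(families) {
  stopifnot(length(families) >= 1L)
  bp <- vapply(families, `[[`, 0, "total_bp")
  cn <- vapply(families, `[[`, 0, "copy_number")
  ids <- vapply(families, `[[`, "", "family_id")
  prefix_for_half <- function(x) {
    o <- order(x, decreasing = TRUE)
    cum <- cumsum(x[o]) / sum(x)
    which(cum >= 0.5)[1L]
  }
  o <- order(bp, decreasing = TRUE)
  list(families_for_50pct_bp = prefix_for_half(bp),
       families_for_50pct_copies = prefix_for_half(cn),
       cumulative = data.frame(
         family_id = ids[o], total_bp = bp[o], copy_number = cn[o],
         cum_bp_share = cumsum(bp[o]) / sum(bp),
         cum_copy_share = cumsum(cn[o]) / sum(cn),
         stringsAsFactors = FALSE))
}
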