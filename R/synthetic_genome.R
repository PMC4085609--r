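# Forward simulator: clone-scale sequences with planted repeat structure
# and full ground truth. The substitution process is Kimura's two-parameter
# model simulated exactly: in K2P every base has the same total exit rate
# (alpha + 2*beta), so drawing a Poisson(d) number of substitution events
# per site and resolving each event by the jump probabilities
# (transition kappa/(kappa + 2), each transversion 1/(kappa + 2))
# reproduces the continuous-time chain exactly, multiple hits included.

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

#' Generate random background sequence
#'
#' I.i.d. bases at a specified GC content (default 39%, a typical plant
#' nuclear value). Background sequence is the non-repetitive matrix into
#' which the simulator plants elements.
#'
#' @param n Length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @return A single sequence string.
#' @export
random_background <- function(n, gc = 0.39) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

mutate_chars <- function(chars, d, ti_tv_ratio) {
  n_events <- rpois(length(chars), d)
  p_ti <- ti_tv_ratio / (ti_tv_ratio + 2)
  while (any(n_events > 0L)) {
    i <- which(n_events > 0L)
    is_ti <- runif(length(i)) < p_ti
    if (any(is_ti)) {
      chars[i[is_ti]] <- TRANSITION_OF[chars[i[is_ti]]]
    }
    if (any(!is_ti)) {
      j <- i[!is_ti]
      pick <- runif(length(j)) < 0.5
      chars[j] <- vapply(seq_along(j), function(q) {
        TRANSVERSIONS_OF[[chars[j[q]]]][if (pick[q]) 1L else 2L]
      }, "")
    }
    n_events[i] <- n_events[i] - 1L
  }
  chars
}

#' Mutate a sequence under the K2P substitution process
#'
#' Applies `Poisson(rate * age)` substitution events per site, each a
#' transition or transversion in the ratio `ti_tv_ratio` (kappa =
#' alpha/beta), allowing multiple hits per site. This is the forward
#' model that the K2P divergence estimator ([k2p_distance()]) inverts.
#'
#' @param seq Nucleotide string over `{A,C,G,T}`.
#' @param age_years Elapsed time in years (>= 0).
#' @param rate Substitution rate in subs/site/yr (default `2e-8`).
#' @param ti_tv_ratio Transition/transversion rate ratio kappa (default 2).
#' @param seed Optional integer seed for reproducibility.
#' @return The mutated sequence string.
#' @export
mutate_sequence <- function(seq, age_years, rate = 2e-8, ti_tv_ratio = 2,
                            seed = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L,
            age_years >= 0, rate >= 0, ti_tv_ratio > 0)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (any(!chars %in% c("A", "C", "G", "T"))) {
    stop("mutate_sequence: sequence must be over {A,C,G,T}")
  }
  if (!is.null(seed)) set.seed(seed)
  d <- rate * age_years
  if (d == 0) return(seq)
  paste(mutate_chars(chars, d, ti_tv_ratio), collapse = "")
}

#' Specify a repeat family for simulation
#'
#' @param family_id Family identifier.
#' @param ancestor_length Ancestral element length in bp (non-LTR
#'   families).
#' @param n_copies Copy number (used as sampling weight by
#'   [build_synthetic_clones()] and as the count by [simulate_family()]).
#' @param age_years Family amplification age in years: every copy
#'   diverges from the ancestor for this long (expected divergence
#'   `rate * age_years`).
#' @param is_ltr If `TRUE` the element is an LTR retrotransposon with
#'   paired terminal repeats (`ltr_length` each) flanking
#'   `internal_length` bp; total length is `2*ltr_length +
#'   internal_length`.
#' @param ltr_length,internal_length LTR geometry (required when
#'   `is_ltr`); `ltr_length` must be >= 20 bp to be datable.
#' @param repeat_class Truth class label (see [repeat_classes()]).
#' @return A `family_spec` list.
#' @export
family_spec <- function(family_id, ancestor_length = NULL, n_copies = 10L,
                        age_years = 0, is_ltr = FALSE, ltr_length = NULL,
                        internal_length = NULL, repeat_class = "novel") {
  stopifnot(n_copies >= 1L, age_years >= 0)
  if (!repeat_class %in% REPEAT_CLASSES) {
    stop("unknown repeat_class '", repeat_class, "'")
  }
  if (is_ltr) {
    if (is.null(ltr_length) || is.null(internal_length)) {
      stop("is_ltr families need ltr_length and internal_length")
    }
    if (ltr_length < 20L) stop("ltr_length < 20 bp: too short to date")
    ancestor_length <- 2L * ltr_length + internal_length
  } else {
    if (is.null(ancestor_length) || ancestor_length < 1L) {
      stop("ancestor_length required for non-LTR families")
    }
  }
  structure(list(family_id = family_id,
                 ancestor_length = as.integer(ancestor_length),
                 n_copies = as.integer(n_copies),
                 age_years = age_years, is_ltr = isTRUE(is_ltr),
                 ltr_length = if (is_ltr) as.integer(ltr_length) else NA_integer_,
                 internal_length = if (is_ltr) as.integer(internal_length) else NA_integer_,
                 repeat_class = repeat_class),
            class = "family_spec")
}

#' Simulate one LTR retrotransposon insertion
#'
#' Both terminal repeats derive from a single ancestral LTR and are then
#' mutated independently for `age_years`, so the expected pairwise LTR
#' divergence is `2 * rate * age_years` — the quantity the
#' `T = d/(2r)` dating formula inverts.
#'
#' @param spec A [family_spec()] with `is_ltr = TRUE`.
#' @param rate Substitution rate (subs/site/yr).
#' @param ti_tv_ratio Transition/transversion rate ratio kappa.
#' @param seed Optional seed.
#' @param ancestor_ltr,ancestor_internal Optional fixed ancestral
#'   sequences (generated randomly when `NULL`).
#' @return List with `element` (full sequence), `ltr5`, `ltr3`,
#'   `internal`, and `truth` (true age and expected LTR-pair divergence).
#' @export
simulate_ltr_element <- function(spec, rate = 2e-8, ti_tv_ratio = 2,
                                 seed = NULL, ancestor_ltr = NULL,
                                 ancestor_internal = NULL) {
  if (!isTRUE(spec$is_ltr)) stop("spec is not an LTR family")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ancestor_ltr)) ancestor_ltr <- random_background(spec$ltr_length)
  if (is.null(ancestor_internal)) {
    ancestor_internal <- random_background(spec$internal_length)
  }
  age <- spec$age_years
  ltr5 <- mutate_sequence(ancestor_ltr, age, rate, ti_tv_ratio)
  ltr3 <- mutate_sequence(ancestor_ltr, age, rate, ti_tv_ratio)
  internal <- if (age > 0) {
    mutate_sequence(ancestor_internal, age, rate, ti_tv_ratio)
  } else ancestor_internal
  list(element = paste0(ltr5, internal, ltr3),
       ltr5 = ltr5, ltr3 = ltr3, internal = internal,
       truth = list(family_id = spec$family_id, age_years = age,
                    expected_ltr_divergence = 2 * rate * age,
                    length = 2L * spec$ltr_length + spec$internal_length))
}

#' Simulate a repeat family amplified from one ancestor
#'
#' Each copy is mutated independently from the ancestral consensus for
#' `age_years`, giving an expected per-copy divergence of
#' `rate * age_years` — the quantity consensus-based family dating
#' ([family_consensus_age()]) inverts.
#'
#' @param spec A [family_spec()].
#' @param rate Substitution rate (subs/site/yr).
#' @param ti_tv_ratio Kappa.
#' @param seed Optional seed.
#' @return List with `ancestor`, `copies` (named character vector) and
#'   `truth` (per-copy true divergence and age).
#' @export
simulate_family <- function(spec, rate = 2e-8, ti_tv_ratio = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ancestor <- random_background(spec$ancestor_length)
  ids <- sprintf("%s_copy%03d", spec$family_id, seq_len(spec$n_copies))
  copies <- vapply(ids, function(id) {
    if (spec$age_years > 0) {
      mutate_sequence(ancestor, spec$age_years, rate, ti_tv_ratio)
    } else ancestor
  }, "")
  list(ancestor = ancestor, copies = copies,
       truth = data.frame(copy_id = ids, family_id = spec$family_id,
                          true_divergence = rate * spec$age_years,
                          true_age = spec$age_years,
                          stringsAsFactors = FALSE))
}

default_families <- function() {
  list(
    family_spec("F01", n_copies = 30L, age_years = 0.5e6, is_ltr = TRUE,
                ltr_length = 1500L, internal_length = 4000L,
                repeat_class = "Ty1-Copia"),
    family_spec("F02", n_copies = 25L, age_years = 1.0e6, is_ltr = TRUE,
                ltr_length = 1000L, internal_length = 3000L,
                repeat_class = "Ty3-Gypsy"),
    family_spec("F03", ancestor_length = 3000L, n_copies = 15L,
                age_years = 0.25e6, repeat_class = "novel"),
    family_spec("F04", ancestor_length = 2000L, n_copies = 10L,
                age_years = 1.0e6, repeat_class = "unclassified"),
    family_spec("F05", ancestor_length = 500L, n_copies = 10L,
                age_years = 0.1e6, repeat_class = "centromeric"),
    family_spec("F06", ancestor_length = 1500L, n_copies = 5L,
                age_years = 2.7e6, repeat_class = "novel")
  )
}

default_class_targets <- function() {
  data.frame(class = c("high", "mid", "low"),
             n = c(80L, 14L, 2L),
             min = c(0.75, 0.50, 0.10),
             max = c(0.95, 0.65, 0.30),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults emulate a 96-clone BAC survey of a repeat-rich plant genome:
#' 80 clones with planted repetitive fractions in `[0.75, 0.95]`, 14 in
#' `[0.50, 0.65]` and 2 in `[0.10, 0.30]`; an element pool dominated by
#' recently amplified LTR retrotransposon families with a minor older
#' component; substitution rate `2e-8` subs/site/yr; 39% GC background.
#'
#' @param n_clones Number of clones (default 96).
#' @param clone_length_range `(min, max)` clone length in bp.
#' @param rate Substitution rate in subs/site/yr.
#' @param ti_tv_ratio Kappa (default 2).
#' @param gc Background GC fraction.
#' @param class_targets Data frame with columns `class`, `n`, `min`,
#'   `max`: how many clones target each repetitive-fraction band.
#' @param families List of [family_spec()]s; `n_copies` acts as the
#'   sampling weight when drawing copies.
#' @param ssr_per_clone,lc_per_clone How many SSR loci / AT-rich
#'   low-complexity tracts to plant per clone.
#' @param ssr_motifs Named numeric vector: canonical motif -> sampling
#'   weight for planted SSRs.
#' @param nesting_probability Probability that an element is inserted
#'   inside a previously placed element rather than in background.
#' @param seed Integer seed; fixes the whole run.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_clones = 96L,
                              clone_length_range = c(50000L, 200000L),
                              rate = 2e-8, ti_tv_ratio = 2, gc = 0.39,
                              class_targets = default_class_targets(),
                              families = default_families(),
                              ssr_per_clone = 3L, lc_per_clone = 2L,
                              ssr_motifs = c(ACC = 0.30, AT = 0.20,
                                             AAG = 0.15, ATC = 0.15,
                                             AAAT = 0.10, AC = 0.10),
                              nesting_probability = 0.05,
                              seed = 1L) {
  stopifnot(n_clones >= 1L, length(clone_length_range) == 2L,
            clone_length_range[1L] >= 1000L,
            clone_length_range[2L] >= clone_length_range[1L],
            rate > 0, ti_tv_ratio > 0, gc >= 0, gc <= 1,
            nesting_probability >= 0, nesting_probability <= 1)
  if (sum(class_targets$n) != n_clones) {
    stop("class_targets$n must sum to n_clones")
  }
  if (any(class_targets$min < 0) || any(class_targets$max > 1) ||
      any(class_targets$min > class_targets$max)) {
    stop("class target fraction bands must satisfy 0 <= min <= max <= 1")
  }
  structure(list(n_clones = as.integer(n_clones),
                 clone_length_range = as.integer(clone_length_range),
                 rate = rate, ti_tv_ratio = ti_tv_ratio, gc = gc,
                 class_targets = class_targets, families = families,
                 ssr_per_clone = as.integer(ssr_per_clone),
                 lc_per_clone = as.integer(lc_per_clone),
                 ssr_motifs = ssr_motifs,
                 nesting_probability = nesting_probability,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# A piece is a planted fragment: its sequence plus truth rows in
# piece-relative 0-based half-open coordinates.
new_piece <- function(seq, truth) list(seq = seq, truth = truth)

piece_truth_row <- function(copy_id, family_id, repeat_class, start, end,
                            divergence, age) {
  data.frame(copy_id = copy_id, family_id = family_id,
             repeat_class = repeat_class, start = as.integer(start),
             end = as.integer(end), true_divergence = divergence,
             true_age = age, stringsAsFactors = FALSE)
}

# Insert guest piece into host piece at a uniform interior point,
# splitting any truth row that spans the insertion point (nested TEs).
nest_piece <- function(host, guest) {
  hlen <- nchar(host$seq)
  glen <- nchar(guest$seq)
  if (hlen < 120L) return(NULL)
  p <- sample(seq.int(50L, hlen - 50L), 1L)
  seq <- paste0(substr(host$seq, 1L, p), guest$seq,
                substr(host$seq, p + 1L, hlen))
  rows <- host$truth
  keep <- rows[rows$end <= p, , drop = FALSE]
  after <- rows[rows$start >= p, , drop = FALSE]
  span <- rows[rows$start < p & rows$end > p, , drop = FALSE]
  if (nrow(after) > 0L) {
    after$start <- after$start + glen
    after$end <- after$end + glen
  }
  frags <- NULL
  if (nrow(span) > 0L) {
    left <- span; left$end <- p
    right <- span
    right$start <- p + glen
    right$end <- span$end + glen
    frags <- rbind(left, right)
  }
  gt <- guest$truth
  gt$start <- gt$start + p
  gt$end <- gt$end + p
  new_piece(seq, rbind(keep, frags, after, gt))
}

simulate_copy <- function(spec, rate, ti_tv_ratio, copy_id,
                          ancestors) {
  anc <- ancestors[[spec$family_id]]
  if (spec$is_ltr) {
    el <- simulate_ltr_element(spec, rate, ti_tv_ratio,
                               ancestor_ltr = anc$ltr,
                               ancestor_internal = anc$internal)
    seq <- el$element
  } else {
    seq <- if (spec$age_years > 0) {
      mutate_sequence(anc$seq, spec$age_years, rate, ti_tv_ratio)
    } else anc$seq
  }
  new_piece(seq, piece_truth_row(copy_id, spec$family_id, spec$repeat_class,
                                 0L, nchar(seq), rate * spec$age_years,
                                 spec$age_years))
}

plant_ssr_piece <- function(motif, n_units, copy_id) {
  seq <- strrep(motif, n_units)
  new_piece(seq, piece_truth_row(copy_id, paste0("SSR_", motif), "SSR",
                                 0L, nchar(seq), 0, 0))
}

plant_lc_piece <- function(len, copy_id) {
  # AT-rich tract: ~95% A/T with occasional G/C
  b <- sample(c("A", "T", "G", "C"), len, replace = TRUE,
              prob = c(0.475, 0.475, 0.025, 0.025))
  new_piece(paste(b, collapse = ""),
            piece_truth_row(copy_id, "LC", "low_complexity", 0L, len, 0, 0))
}

#' Build synthetic clones with planted repeats and ground truth
#'
#' Assembles each clone from i.i.d. background sequence plus repeat
#' copies drawn (with family weights) from the configured element pool
#' until the planted TE fraction reaches the clone's target band; the
#' last copy is truncated so the realized fraction lands within 0.03 of
#' its target. Elements are placed uniformly at random; with probability
#' `nesting_probability` an element is inserted inside a previously
#' placed element, splitting the host's truth interval into two
#' fragments that share one `family_id`. Perfect SSR arrays and AT-rich
#' low-complexity tracts are planted in the background (their few bp are
#' tracked in the truth but not counted toward the TE fraction), and the
#' flanking base on either side of every SSR is chosen so it cannot
#' extend the planted tandem array.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, writes `clones.fasta`,
#'   `truth.gff3`, `truth_copies.tsv` and `clone_classes.tsv`.
#' @return List with `clones` (named character vector), `truth` (list:
#'   `annotations`, `copies`, `clones`) and `config`.
#' @export
build_synthetic_clones <- function(config = simulation_config(),
                                   out_dir = NULL) {
  set.seed(config$seed)
  ct <- config$class_targets
  clone_class <- rep(ct$class, ct$n)
  target <- unlist(Map(function(n, lo, hi) runif(n, lo, hi),
                       ct$n, ct$min, ct$max))
  fam_w <- vapply(config$families, `[[`, 1L, "n_copies")
  fam_ids <- vapply(config$families, `[[`, "", "family_id")

  # one fixed ancestor per family for the whole run
  ancestors <- lapply(config$families, function(fs) {
    if (fs$is_ltr) {
      list(ltr = random_background(fs$ltr_length, config$gc),
           internal = random_background(fs$internal_length, config$gc))
    } else {
      list(seq = random_background(fs$ancestor_length, config$gc))
    }
  })
  names(ancestors) <- fam_ids

  clones <- character(config$n_clones)
  clone_ids <- sprintf("clone%03d", seq_len(config$n_clones))
  names(clones) <- clone_ids
  ann_list <- vector("list", config$n_clones)
  clone_rows <- vector("list", config$n_clones)
  copy_counter <- 0L

  for (ci in seq_len(config$n_clones)) {
    L <- sample(seq.int(config$clone_length_range[1L],
                        config$clone_length_range[2L]), 1L)
    tgt <- target[ci]
    if (tgt > 0.97) {
      stop("target repetitive fraction ", round(tgt, 3),
           " infeasible for clone ", clone_ids[ci])
    }
    target_bp <- round(tgt * L)
    pieces <- list()
    planted <- 0L
    while (planted < target_bp) {
      fi <- sample(length(config$families), 1L, prob = fam_w)
      spec <- config$families[[fi]]
      copy_counter <- copy_counter + 1L
      cp <- simulate_copy(spec, config$rate, config$ti_tv_ratio,
                          sprintf("copy%05d", copy_counter), ancestors)
      clen <- nchar(cp$seq)
      remaining <- target_bp - planted
      if (clen > remaining) {
        if (remaining < 60L) break
        cp$seq <- substr(cp$seq, 1L, remaining)  # truncated terminal copy
        cp$truth$end <- as.integer(remaining)
        clen <- remaining
      }
      nested <- FALSE
      if (length(pieces) > 0L && runif(1) < config$nesting_probability) {
        hi <- sample(length(pieces), 1L)
        np <- nest_piece(pieces[[hi]], cp)
        if (!is.null(np)) {
          pieces[[hi]] <- np
          nested <- TRUE
        }
      }
      if (!nested) pieces[[length(pieces) + 1L]] <- cp
      planted <- planted + clen
    }
    te_bp <- planted

    ssr_info <- list()
    for (s in seq_len(config$ssr_per_clone)) {
      motif <- sample(names(config$ssr_motifs), 1L, prob = config$ssr_motifs)
      min_u <- if (nchar(motif) == 2L) 8L else 6L
      n_units <- sample(seq.int(min_u, 25L), 1L)
      copy_counter <- copy_counter + 1L
      pieces[[length(pieces) + 1L]] <-
        plant_ssr_piece(motif, n_units, sprintf("copy%05d", copy_counter))
      ssr_info[[length(ssr_info) + 1L]] <-
        list(idx = length(pieces), motif = motif)
    }
    for (s in seq_len(config$lc_per_clone)) {
      copy_counter <- copy_counter + 1L
      pieces[[length(pieces) + 1L]] <-
        plant_lc_piece(sample(40:150, 1L), sprintf("copy%05d", copy_counter))
    }

    piece_bp <- sum(vapply(pieces, function(p) nchar(p$seq), 0L))
    bg_bp <- L - piece_bp
    np <- length(pieces)
    if (bg_bp < 2L * (np + 1L)) {
      stop("target repetitive fraction ", round(tgt, 3),
           " infeasible for clone ", clone_ids[ci],
           " (insufficient background)")
    }
    # distribute background into np+1 gaps, each >= 2 bp
    extra <- bg_bp - 2L * (np + 1L)
    cuts <- sort(sample.int(extra + 1L, np, replace = TRUE) - 1L)
    gaps <- diff(c(0L, cuts, extra)) + 2L
    order_idx <- sample.int(np)
    seq_parts <- character(2L * np + 1L)
    seq_parts[1L] <- random_background(gaps[1L], config$gc)
    truth_rows <- vector("list", np)
    pos <- gaps[1L]
    ssr_idx_map <- vapply(ssr_info, `[[`, 0L, "idx")
    ssr_fix <- list()
    for (q in seq_len(np)) {
      p <- pieces[[order_idx[q]]]
      tr <- p$truth
      tr$start <- tr$start + pos
      tr$end <- tr$end + pos
      tr$clone_id <- clone_ids[ci]
      truth_rows[[q]] <- tr
      seq_parts[2L * q] <- p$seq
      if (order_idx[q] %in% ssr_idx_map) {
        motif <- ssr_info[[match(order_idx[q], ssr_idx_map)]]$motif
        ssr_fix[[length(ssr_fix) + 1L]] <-
          list(start = pos, end = pos + nchar(p$seq), motif = motif)
      }
      pos <- pos + nchar(p$seq)
      seq_parts[2L * q + 1L] <- random_background(gaps[q + 1L], config$gc)
      pos <- pos + gaps[q + 1L]
    }
    clone_seq <- paste(seq_parts, collapse = "")
    # ensure planted SSR arrays are maximal exactly at their truth bounds
    for (fx in ssr_fix) {
      m <- nchar(fx$motif)
      ch <- substr(clone_seq, fx$start, fx$start)        # base before locus
      period_ch <- substr(clone_seq, fx$start + m, fx$start + m)
      if (fx$start >= 1L && ch == period_ch) {
        repl <- setdiff(c("A", "C", "G", "T"), period_ch)[1L]
        substr(clone_seq, fx$start, fx$start) <- repl
      }
      e <- fx$end
      if (e < nchar(clone_seq)) {
        ch <- substr(clone_seq, e + 1L, e + 1L)           # base after locus
        period_ch <- substr(clone_seq, e + 1L - m, e + 1L - m)
        if (ch == period_ch) {
          repl <- setdiff(c("A", "C", "G", "T"), period_ch)[1L]
          substr(clone_seq, e + 1L, e + 1L) <- repl
        }
      }
    }
    clones[ci] <- clone_seq
    ann_list[[ci]] <- do.call(rbind, truth_rows)
    clone_rows[[ci]] <- data.frame(
      clone_id = clone_ids[ci], length = nchar(clone_seq),
      target_fraction = tgt, realized_fraction = te_bp / L,
      clone_class = clone_class[ci], stringsAsFactors = FALSE)
  }

  copies <- do.call(rbind, ann_list)
  ann <- repeat_annotation(scaffold = copies$clone_id, start = copies$start,
                           end = copies$end,
                           repeat_class = copies$repeat_class,
                           family_id = copies$family_id, score = 1)
  clones_df <- do.call(rbind, clone_rows)
  out <- list(clones = clones,
              truth = list(annotations = ann,
                           copies = copies[, c("copy_id", "family_id",
                                               "repeat_class", "clone_id",
                                               "start", "end",
                                               "true_divergence", "true_age")],
                           clones = clones_df),
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(clones, file.path(out_dir, "clones.fasta"))
    write_annotations(ann, file.path(out_dir, "truth.gff3"), "GFF3")
    write.table(out$truth$copies, file.path(out_dir, "truth_copies.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(clones_df, file.path(out_dir, "clone_classes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
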