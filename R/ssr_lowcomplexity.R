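# Perfect SSR (di/tri/tetra) detection, strand/rotation canonical
# motifs, and AT-rich low-complexity regions.

rev_comp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, ""))
}

rotations <- function(m) {
  n <- nchar(m)
  vapply(seq_len(n), function(i) {
    paste0(substr(m, i, n), substr(m, 1L, i - 1L))
  }, "")
}

is_primitive <- function(m) {
  n <- nchar(m)
  for (p in seq_len(n - 1L)) {
    if (n %% p == 0L && strrep(substr(m, 1L, p), n %/% p) == m) return(FALSE)
  }
  TRUE
}

#' Canonical SSR motif
#'
#' The lexicographically smallest string among all rotations of the
#' motif and all rotations of its reverse complement, so that e.g.
#' `TGG`, `GGT`, `GTG`, `CCA`, `CAC` and `ACC` all map to `ACC`
#' (the `TGG/CCA` equivalence class). The motif must be primitive
#' (not a repetition of a shorter motif).
#'
#' @param motif Motif string of length 2-4 over `{A,C,G,T}`.
#' @return The canonical representative.
#' @export
canonical_motif <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1L)
  n <- nchar(motif)
  if (n < 2L || n > 4L) stop("motif length must be 2-4")
  if (grepl("[^ACGT]", motif)) stop("motif must be over {A,C,G,T}")
  if (!is_primitive(motif)) {
    stop("motif '", motif, "' is not primitive")
  }
  min(c(rotations(motif), rotations(unname(rev_comp(motif)))))
}

#' Find perfect SSR loci
#'
#' Detects maximal perfect tandem arrays of primitive 2-4 bp motifs
#' with at least `min_units` repetitions (per motif length class).
#' Runs whose length is not a multiple of the period are trimmed to
#' whole units. Overlapping calls of different motif length are
#' resolved to the longest locus (ties to the shorter motif).
#'
#' @param seq A sequence string.
#' @param min_units Named integer vector of minimum unit counts per
#'   motif length (`"2"`, `"3"`, `"4"`); defaults di >= 6, tri >= 5,
#'   tetra >= 5.
#' @param scaffold_id Scaffold id recorded in the output.
#' @return `data.frame` of loci: `scaffold`, `start`, `end` (0-based
#'   half-open), `motif`, `canonical_motif`, `n_units`.
#' @export
find_ssrs <- function(seq, min_units = c(`2` = 6L, `3` = 5L, `4` = 5L),
                      scaffold_id = "seq") {
  stopifnot(all(min_units >= 2L))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  loci <- list()
  for (m in 2:4) {
    if (n < (min_units[[as.character(m)]] * m)) next
    eq <- chars[seq_len(n - m)] == chars[seq.int(m + 1L, n)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in which(r$values)) {
      run_len <- r$lengths[q] + m          # total length of periodic run
      if (run_len < min_units[[as.character(m)]] * m) next
      s <- starts[q]                        # 1-based run start
      motif <- paste(chars[seq.int(s, s + m - 1L)], collapse = "")
      if (!is_primitive(motif)) next        # captured at a shorter period
      units <- run_len %/% m
      loci[[length(loci) + 1L]] <- data.frame(
        start = s - 1L, end = s - 1L + units * m, motif = motif,
        n_units = units, stringsAsFactors = FALSE)
    }
  }
  if (length(loci) == 0L) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      canonical_motif = character(0), n_units = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, loci)
  # longest locus wins overlaps; ties to the shorter motif
  df <- df[order(-(df$end - df$start), nchar(df$motif), df$start), ,
           drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1L]) {
    prior <- which(keep[seq_len(i - 1L)])
    if (any(df$start[prior] < df$end[i] & df$end[prior] > df$start[i])) {
      keep[i] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  data.frame(scaffold = scaffold_id, start = df$start, end = df$end,
             motif = df$motif,
             canonical_motif = vapply(df$motif, canonical_motif, ""),
             n_units = df$n_units, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Find AT-rich low-complexity regions
#'
#' Maximal unions of `min_len`-bp windows whose A+T fraction is at
#' least `at_threshold`. Merged regions whose overall fraction dips
#' below the threshold are trimmed from the ends until they comply.
#'
#' @param seq A sequence string.
#' @param at_threshold Minimum A+T fraction (default 0.90).
#' @param min_len Window / minimum region length (default 30 bp).
#' @param scaffold_id Scaffold id recorded in the output.
#' @return `data.frame`: `scaffold`, `start`, `end`, `at_fraction`.
#' @export
find_low_complexity <- function(seq, at_threshold = 0.90, min_len = 30L,
                                scaffold_id = "seq") {
  stopifnot(at_threshold > 0, at_threshold <= 1, min_len >= 2L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  empty <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), at_fraction = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < min_len) return(empty)
  at <- as.integer(chars %in% c("A", "T"))
  cs <- c(0L, cumsum(at))
  win_at <- (cs[seq.int(min_len + 1L, n + 1L)] - cs[seq_len(n - min_len + 1L)])
  ok <- win_at >= at_threshold * min_len      # qualifying window starts
  if (!any(ok)) return(empty)
  covered <- logical(n)
  for (off in 0:(min_len - 1L)) {
    covered[which(ok) + off] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (q in which(r$values)) {
    s <- starts[q]; e <- ends[q]
    frac <- (cs[e + 1L] - cs[s]) / (e - s + 1L)
    # trim non-AT edges until the merged region meets the threshold
    while (frac < at_threshold && (e - s + 1L) > min_len) {
      if (at[s] == 0L) s <- s + 1L
      else if (at[e] == 0L) e <- e - 1L
      else break
      frac <- (cs[e + 1L] - cs[s]) / (e - s + 1L)
    }
    if (frac >= at_threshold && (e - s + 1L) >= min_len) {
      out[[length(out) + 1L]] <- data.frame(
        scaffold = scaffold_id, start = s - 1L, end = e,
        at_fraction = frac, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Summarise SSR motif frequencies
#'
#' Counts loci and total repeat units per canonical motif, and totals
#' per motif-length class, both sorted by abundance.
#'
#' @param loci Output of [find_ssrs()] (rows from several scaffolds may
#'   be concatenated).
#' @return List with `per_motif` (canonical motif, n_loci, total_units,
#'   motif_length) and `per_class` (motif_length, n_loci, total_units).
#' @export
ssr_summary <- function(loci) {
  if (nrow(loci) == 0L) {
    return(list(per_motif = data.frame(canonical_motif = character(0),
                                       motif_length = integer(0),
                                       n_loci = integer(0),
                                       total_units = integer(0)),
                per_class = data.frame(motif_length = integer(0),
                                       n_loci = integer(0),
                                       total_units = integer(0))))
  }
  agg <- aggregate(cbind(n_loci = 1L, total_units = loci$n_units),
                   by = list(canonical_motif = loci$canonical_motif),
                   FUN = sum)
  agg$motif_length <- nchar(agg$canonical_motif)
  agg <- agg[order(-agg$n_loci, -agg$total_units, agg$canonical_motif), ,
             drop = FALSE]
  cls <- aggregate(cbind(n_loci = 1L, total_units = loci$n_units),
                   by = list(motif_length = nchar(loci$motif)), FUN = sum)
  cls <- cls[order(-cls$n_loci), , drop = FALSE]
  rownames(agg) <- rownames(cls) <- NULL
  list(per_motif = agg[, c("canonical_motif", "motif_length", "n_loci",
                           "total_units")],
       per_class = cls)
}
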