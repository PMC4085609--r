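# Canonical k-mer occurrence index and the low/mid/high repetitiveness
# classification of clones. Counting is strand-collapsed: a k-mer and its
# reverse complement share one canonical key, because repeats insert in
# both orientations. k-mers containing N are excluded.

#' Build a canonical k-mer occurrence index
#'
#' Counts every k-mer position across the input set under canonical
#' (strand-collapsed) keys. Sequences shorter than `k` contribute
#' nothing (with a warning); windows containing `N` are skipped.
#'
#' @param seqs Named character vector of sequences (see [read_fasta()]).
#' @param k k-mer size (default 20; 2 <= k <= 26 so keys are exact).
#' @return A `kmer_index` object (fields `k`, `key`, `count`).
#' @export
build_kmer_index <- function(seqs, k = 20L) {
  k <- as.integer(k)
  stopifnot(k >= 2L, k <= 26L)
  seqs <- as.character(seqs)
  if (all(nchar(seqs) < k)) stop("no sequence is at least k bp long")
  if (any(nchar(seqs) < k)) {
    warning(sum(nchar(seqs) < k), " sequence(s) shorter than k contribute nothing")
  }
  idx <- cpp_kmer_index(seqs, k)
  structure(list(k = k, key = idx$key, count = idx$count),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index: k =", x$k, "|", length(x$key), "distinct canonical k-mers |",
      sum(as.numeric(x$count)), "positions\n")
  invisible(x)
}

#' Per-position repeat coverage and repetitive fraction
#'
#' A position is repeat-covered when it lies within the k-span of at
#' least one k-mer whose index count is `>= freq_threshold`. The
#' repetitive fraction of a sequence is the covered share of its length.
#'
#' `repetitive_profile()` computes coverage for many sequences in one
#' pass (one index lookup structure); `repetitive_fraction()` is the
#' single-sequence convenience wrapper.
#'
#' @param seqs Named character vector of sequences.
#' @param seq A single sequence string.
#' @param index A [build_kmer_index()] result.
#' @param freq_threshold Minimum occurrence count for a k-mer to be
#'   considered repetitive (default 4: a two-copy duplication is not yet
#'   repetitive, family-scale amplification is).
#' @return `repetitive_profile()`: list with `coverage` (list of logical
#'   vectors) and `fraction` (named numeric). `repetitive_fraction()`:
#'   a single numeric in `[0, 1]`.
#' @export
repetitive_profile <- function(seqs, index, freq_threshold = 4L) {
  stopifnot(inherits(index, "kmer_index"), freq_threshold >= 1L)
  seqs <- as.character(seqs)
  cov <- cpp_kmer_coverage(seqs, index$k, index$key, index$count,
                           as.integer(freq_threshold))
  names(cov) <- names(seqs)
  frac <- vapply(cov, function(v) if (length(v) == 0L) 0 else mean(v), 0)
  short <- nchar(seqs) < index$k
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than k: fraction 0")
    frac[short] <- 0
  }
  list(coverage = cov, fraction = frac)
}

#' @rdname repetitive_profile
#' @export
repetitive_fraction <- function(seq, index, freq_threshold = 4L) {
  unname(repetitive_profile(setNames(seq, "x"), index, freq_threshold)$fraction)
}

#' Classify a clone by repetitive fraction
#'
#' `low = [0, 0.40)`, `mid = [0.40, 0.70)`, `high = [0.70, 1]`. The
#' upper class is closed on the left: a fraction of exactly 0.40 is mid
#' and 0.70 is high.
#'
#' @param fraction Numeric vector of fractions in `[0, 1]`.
#' @return Character vector over `{"low", "mid", "high"}`.
#' @export
classify_clone <- function(fraction) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1)) {
    stop("fraction must be in [0, 1]")
  }
  ifelse(fraction >= 0.70, "high", ifelse(fraction >= 0.40, "mid", "low"))
}

#' Per-clone landscape classification table
#'
#' Convenience wrapper: index the clones, compute per-clone repetitive
#' fractions and classify them.
#'
#' @param seqs Named character vector of clones.
#' @param k k-mer size.
#' @param freq_threshold Repetitive-count threshold.
#' @param index Optional prebuilt index over a superset of `seqs`.
#' @return `data.frame` with `clone_id`, `fraction`, `clone_class`.
#' @export
classify_clones <- function(seqs, k = 20L, freq_threshold = 4L, index = NULL) {
  if (is.null(index)) index <- build_kmer_index(seqs, k)
  prof <- repetitive_profile(seqs, index, freq_threshold)
  data.frame(clone_id = names(seqs), fraction = unname(prof$fraction),
             clone_class = classify_clone(unname(prof$fraction)),
             stringsAsFactors = FALSE)
}
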