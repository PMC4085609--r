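# Spatial randomness of repeats along scaffolds: 5-kb binning,
# binarization by masked fraction, and the one-sample runs
# (Wald-Wolfowitz) test under its normal approximation.

#' Select scaffolds long enough for spatial analysis
#'
#' Keeps scaffolds whose longest N-free (contiguous) stretch is at
#' least `min_contiguous` bp (boundary closed: exactly 50 kb
#' qualifies).
#'
#' @param seqs Named character vector of scaffolds.
#' @param min_contiguous Minimum contiguous length (default 50000).
#' @return Character vector of qualifying scaffold ids.
#' @export
select_scaffolds <- function(seqs, min_contiguous = 50000L) {
  if (length(seqs) == 0L) return(character(0))
  contig <- vapply(seq_along(seqs), function(i) {
    parts <- strsplit(seqs[[i]], "N+")[[1L]]
    if (length(parts) == 0L) 0L else max(nchar(parts))
  }, 0L)
  names(seqs)[contig >= min_contiguous]
}

#' Binarize repeat occupancy along a scaffold
#'
#' Divides the scaffold into `bin_size` bins, computes the repeat-
#' covered fraction of each bin from overlap-resolved annotations, and
#' binarizes: 1 (repetitive) when occupancy `>= binarize_threshold`,
#' else 0 (putatively euchromatic). A trailing partial bin is kept
#' when at least half of `bin_size`, otherwise dropped.
#'
#' @param scaffold_id Scaffold id.
#' @param scaffold_length Its length in bp.
#' @param ann Overlap-resolved annotation `data.frame`.
#' @param bin_size Bin width in bp (default 5000).
#' @param binarize_threshold Occupancy needed to call a bin repetitive
#'   (default 0.5).
#' @return A `bin_series` list: `scaffold_id`, `bin_size`, `values`
#'   (0/1 vector), `occupancy` (per-bin fractions), `bin_bp` (per-bin
#'   widths).
#' @export
binarize <- function(scaffold_id, scaffold_length, ann, bin_size = 5000L,
                     binarize_threshold = 0.5) {
  if (bin_size <= 0L) stop("bin_size must be positive")
  validate_annotations(ann)
  ann <- ann[ann$scaffold == scaffold_id, , drop = FALSE]
  n_full <- scaffold_length %/% bin_size
  tail_bp <- scaffold_length - n_full * bin_size
  keep_tail <- tail_bp >= bin_size / 2
  n_bins <- n_full + as.integer(keep_tail)
  if (n_bins == 0L) stop("scaffold shorter than half a bin")
  widths <- rep(bin_size, n_bins)
  if (keep_tail) widths[n_bins] <- tail_bp
  covered <- numeric(n_bins)
  if (nrow(ann) > 0L) {
    for (i in seq_len(nrow(ann))) {
      b_first <- ann$start[i] %/% bin_size + 1L
      b_last <- (ann$end[i] - 1L) %/% bin_size + 1L
      for (b in seq.int(b_first, min(b_last, n_bins))) {
        lo <- (b - 1L) * bin_size
        hi <- lo + widths[b]
        covered[b] <- covered[b] +
          max(0L, min(ann$end[i], hi) - max(ann$start[i], lo))
      }
    }
  }
  occupancy <- covered / widths
  structure(list(scaffold_id = scaffold_id, bin_size = bin_size,
                 values = as.integer(occupancy >= binarize_threshold),
                 occupancy = occupancy, bin_bp = widths),
            class = "bin_series")
}

#' One-sample runs test of a binary series
#'
#' Wald-Wolfowitz runs test under the normal approximation: with `n1`
#' ones and `n0` zeros and `R` observed runs,
#' `mu = 2 n1 n0 / (n1 + n0) + 1` and
#' `sigma^2 = 2 n1 n0 (2 n1 n0 - n1 - n0) / ((n1+n0)^2 (n1+n0-1))`;
#' `p = 2 (1 - Phi(|z|))` with `z = (R - mu) / sigma` and no
#' continuity correction. Series with fewer than 20 bins are flagged
#' approximate. A series of all 1s or all 0s is degenerate and raises
#' an error.
#'
#' @param series A `bin_series` from [binarize()], or a plain 0/1
#'   vector.
#' @return A `runs_test_result` list: `n1`, `n0`, `R`, `mu`, `sigma`,
#'   `z`, `p_two_sided`, `approximate`.
#' @export
runs_test <- function(series) {
  v <- if (inherits(series, "bin_series")) series$values else
    as.integer(series)
  if (any(!v %in% c(0L, 1L))) stop("series must be binary (0/1)")
  n1 <- sum(v == 1L)
  n0 <- sum(v == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("degenerate series (all ", if (n1 == 0L) "0" else "1",
         "s): runs test undefined")
  }
  R <- 1L + sum(v[-1L] != v[-length(v)])
  n <- n1 + n0
  mu <- 2 * n1 * n0 / n + 1
  sigma2 <- 2 * n1 * n0 * (2 * n1 * n0 - n) / (n^2 * (n - 1))
  sigma <- sqrt(sigma2)
  z <- (R - mu) / sigma
  structure(list(n1 = n1, n0 = n0, R = R, mu = mu, sigma = sigma, z = z,
                 p_two_sided = 2 * pnorm(-abs(z)),
                 approximate = n < 20L,
                 scaffold_id = if (inherits(series, "bin_series"))
                   series$scaffold_id else NA_character_),
            class = "runs_test_result")
}

#' @export
print.runs_test_result <- function(x, ...) {
  cat("runs test: n1 =", x$n1, "n0 =", x$n0, "R =", x$R,
      sprintf("mu = %.3f z = %.3f p = %.4f%s\n", x$mu, x$z, x$p_two_sided,
              if (x$approximate) " (small-n approximation)" else ""))
  invisible(x)
}

#' Per-scaffold spatial randomness report
#'
#' Runs [runs_test()] on each binarized scaffold, flags those with
#' `p < alpha` as nonrandom, and sorts by p-value. Degenerate series
#' (all 0 or all 1) are reported with `NA` statistics and never
#' flagged. A Bonferroni-adjusted column is included for transparency,
#' but flagging follows the per-scaffold alpha.
#'
#' @param series_list List of `bin_series` (or plain 0/1 vectors,
#'   named).
#' @param alpha Per-scaffold significance level (default 0.05).
#' @return `data.frame`: `scaffold_id`, `n_bins`, `n1`, `n0`, `R`,
#'   `z`, `p`, `p_bonferroni`, `nonrandom`; attribute `n_nonrandom`.
#' @export
randomness_report <- function(series_list, alpha = 0.05) {
  if (length(series_list) == 0L) {
    out <- data.frame(scaffold_id = character(0), n_bins = integer(0),
                      n1 = integer(0), n0 = integer(0), R = integer(0),
                      z = numeric(0), p = numeric(0),
                      p_bonferroni = numeric(0), nonrandom = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_nonrandom") <- 0L
    return(out)
  }
  rows <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    id <- if (inherits(s, "bin_series")) s$scaffold_id else
      (names(series_list)[i] %||% as.character(i))
    v <- if (inherits(s, "bin_series")) s$values else as.integer(s)
    res <- tryCatch(runs_test(v), error = function(e) NULL)
    if (is.null(res)) {
      data.frame(scaffold_id = id, n_bins = length(v), n1 = sum(v == 1L),
                 n0 = sum(v == 0L), R = NA_integer_, z = NA_real_,
                 p = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(scaffold_id = id, n_bins = length(v), n1 = res$n1,
                 n0 = res$n0, R = res$R, z = res$z, p = res$p_two_sided,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  m <- sum(!is.na(out$p))
  out$p_bonferroni <- pmin(1, out$p * m)
  out$nonrandom <- !is.na(out$p) & out$p < alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_nonrandom") <- sum(out$nonrandom)
  out
}
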