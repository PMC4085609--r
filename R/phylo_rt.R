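# Poisson-corrected amino-acid distances and neighbor-joining with
# bootstrap support, for reverse-transcriptase domain phylogenies.

AA_OK <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Poisson-corrected amino-acid distance
#'
#' `d = -log(1 - p)` with `p` the mismatch proportion over
#' pairwise-complete positions (columns where both sequences carry an
#' unambiguous residue; gaps, `X`, `*` etc. are deleted pairwise).
#'
#' @param seq_a,seq_b Equal-length aligned amino-acid strings.
#' @return Distance in substitutions per site.
#' @export
poisson_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length")
  }
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  ok <- a %in% AA_OK & b %in% AA_OK
  n <- sum(ok)
  if (n < 1L) stop("no pairwise-complete positions")
  p <- sum(a[ok] != b[ok]) / n
  if (p >= 1) stop("Poisson saturation: p >= 1")
  -log(1 - p)
}

#' Poisson distance matrix from an alignment
#'
#' @param aln Named character vector of equal-length aligned amino-acid
#'   sequences.
#' @param deletion `"pairwise"` (default; ambiguous positions removed
#'   per sequence pair) or `"complete"` (columns with any ambiguous
#'   character removed once for all taxa).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
poisson_dist_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(length(aln) >= 2L, !is.null(names(aln)))
  if (length(unique(nchar(aln))) != 1L) {
    stop("alignment rows must all have equal length")
  }
  if (deletion == "complete") {
    mat <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
    keep <- apply(mat, 2L, function(col) all(col %in% AA_OK))
    if (!any(keep)) stop("no complete columns")
    aln <- setNames(apply(mat[, keep, drop = FALSE], 1L, paste,
                          collapse = ""), names(aln))
  }
  n <- length(aln)
  dm <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dm[i, j] <- dm[j, i] <- poisson_distance(aln[[i]], aln[[j]])
    }
  }
  dm
}

#' Neighbor-joining tree
#'
#' Classic NJ on a symmetric distance matrix: Q-criterion joins with
#' the standard branch-length formulas, a deterministic tie-break by
#' the lexicographically smallest joined label pair, and negative
#' branch-length estimates clamped to zero with the deficit moved to
#' the sister edge (so the joined path length is preserved).
#'
#' @param dm Symmetric numeric distance matrix with taxon dimnames.
#' @return An [ape::read.tree()]-style `phylo` object (unrooted).
#' @export
neighbor_joining <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-12 || any(diag(dm) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  newick <- labels            # growing subtree strings per active node
  key <- labels               # lexicographic tie-break key per node
  D <- dm
  active <- seq_len(n)
  fmt <- function(x) sprintf("%.15g", x)
  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    ck <- apply(cand, 1L, function(ij) {
      p <- sort(c(key[active[ij[1L]]], key[active[ij[2L]]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(ck)[1L], ]
    i <- active[pick[1L]]; j <- active[pick[2L]]
    dij <- D[i, j]
    bi <- dij / 2 + (r[pick[1L]] - r[pick[2L]]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    # new node replaces i; distances by the standard reduction
    newD <- (D[i, active] + D[j, active] - dij) / 2
    D[i, active] <- newD
    D[active, i] <- newD
    D[i, i] <- 0
    newick[i] <- paste0("(", newick[i], ":", fmt(bi), ",",
                        newick[j], ":", fmt(bj), ")")
    key[i] <- min(key[i], key[j])
    active <- setdiff(active, j)
  }
  a <- active
  d12 <- D[a[1L], a[2L]]; d13 <- D[a[1L], a[3L]]; d23 <- D[a[2L], a[3L]]
  b1 <- (d12 + d13 - d23) / 2
  b2 <- (d12 + d23 - d13) / 2
  b3 <- (d13 + d23 - d12) / 2
  b <- c(b1, b2, b3)
  for (q in 1:3) {                      # clamp with deficit to sisters
    if (b[q] < 0) {
      b[-q] <- b[-q] + b[q] / 2
      b[q] <- 0
    }
  }
  nwk <- paste0("(", newick[a[1L]], ":", fmt(b[1L]), ",",
                newick[a[2L]], ":", fmt(b[2L]), ",",
                newick[a[3L]], ":", fmt(b[3L]), ");")
  ape::read.tree(text = nwk)
}

#' Neighbor-joining with bootstrap support
#'
#' Builds the full-data NJ tree from Poisson distances, then resamples
#' alignment columns with replacement `n_replicates` times, rebuilds
#' the tree on each pseudo-alignment, and reports for every internal
#' edge of the full-data tree the fraction of replicate trees that
#' contain the same bipartition. Replicates in which any pairwise
#' distance saturates are skipped (counted out of the denominator).
#'
#' @param aln Named character vector of equal-length aligned amino-acid
#'   sequences.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @param deletion Column-deletion mode, see [poisson_dist_matrix()].
#' @return The full-data `phylo` tree with `node.label` set to the
#'   support fractions (root label empty) and attribute
#'   `n_effective_replicates`.
#' @export
bootstrap_support <- function(aln, n_replicates = 1000L, seed = NULL,
                              deletion = "pairwise") {
  stopifnot(n_replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  full <- neighbor_joining(poisson_dist_matrix(aln, deletion))
  L <- nchar(aln[[1L]])
  reps <- vector("list", n_replicates)
  ok <- 0L
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    res <- vapply(aln, function(s) {
      paste(strsplit(s, "", fixed = TRUE)[[1L]][cols], collapse = "")
    }, "")
    tr <- tryCatch(neighbor_joining(poisson_dist_matrix(res, deletion)),
                   error = function(e) NULL)
    if (!is.null(tr)) {
      ok <- ok + 1L
      reps[[ok]] <- tr
    }
  }
  if (ok == 0L) stop("all bootstrap replicates failed")
  reps <- reps[seq_len(ok)]
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- counts / ok
  full$node.label <- c("", sprintf("%.3f", support[-1L]))
  if (length(support) >= 1L) full$node.label <- sprintf("%.3f", support)
  full$node.label[1L] <- ""
  attr(full, "support") <- support
  attr(full, "n_effective_replicates") <- ok
  full
}
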