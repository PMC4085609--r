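# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: naive dictionary k-mer counting, a
# closed-form runs distribution, per-base overlap assignment, and
# random additive trees.

rc_string <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Naive canonical k-mer counting on small inputs.
naive_kmer_counts <- function(seqs, k) {
  tab <- list()
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    kmers <- substring(s, seq_len(n - k + 1L), seq.int(k, n))
    kmers <- kmers[!grepl("[^ACGT]", kmers)]
    canon <- pmin(kmers, rc_string(kmers))
    for (km in canon) tab[[km]] <- (tab[[km]] %||% 0L) + 1L
  }
  unlist(tab) %||% setNames(integer(0), character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Decode the package's numeric canonical keys back to strings so the
# index can be compared against the naive counts.
decode_key <- function(key, k) {
  bases <- c("A", "C", "G", "T")
  vapply(key, function(x) {
    out <- character(k)
    for (i in k:1) {
      out[i] <- bases[(x %% 4) + 1]
      x <- x %/% 4
    }
    paste(out, collapse = "")
  }, "")
}

# Exact runs-count pmf for n1 ones and n0 zeros (standard
# combinatorial form), and the exact two-sided p-value defined as the
# total probability of run counts at least as far from the mean.
runs_pmf <- function(n1, n0) {
  Rs <- 2:(2 * min(n1, n0) + as.integer(n1 != n0))
  p <- vapply(Rs, function(R) {
    if (R %% 2 == 0) {
      k <- R / 2
      2 * choose(n1 - 1, k - 1) * choose(n0 - 1, k - 1)
    } else {
      k <- (R - 1) / 2
      choose(n1 - 1, k - 1) * choose(n0 - 1, k) +
        choose(n1 - 1, k) * choose(n0 - 1, k - 1)
    }
  }, 0)
  setNames(p / choose(n1 + n0, n1), Rs)
}

exact_runs_p <- function(n1, n0, R) {
  pmf <- runs_pmf(n1, n0)
  mu <- 2 * n1 * n0 / (n1 + n0) + 1
  sum(pmf[abs(as.numeric(names(pmf)) - mu) >= abs(R - mu) - 1e-9])
}

# Per-base winner assignment for overlap resolution: each base goes to
# the annotation ranked first by (score desc, length desc, family id,
# start). Returns a list of per-scaffold integer vectors of annotation
# row indices (0 = unannotated).
per_base_assignment <- function(ann) {
  fam <- ifelse(is.na(ann$family_id), "~", ann$family_id)
  rank <- order(order(-ann$score, -(ann$end - ann$start), fam, ann$start))
  out <- list()
  for (sc in unique(ann$scaffold)) {
    idx <- which(ann$scaffold == sc)
    L <- max(ann$end[idx])
    v <- integer(L)
    best <- rep(Inf, L)
    for (i in idx) {
      pos <- (ann$start[i] + 1L):ann$end[i]
      better <- rank[i] < best[pos]
      v[pos[better]] <- i
      best[pos[better]] <- rank[i]
    }
    out[[sc]] <- v
  }
  out
}

# Random unrooted binary tree with positive branch lengths and its
# additive (cophenetic) distance matrix.
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) runif(n, 0.1, 2))
  tr$tip.label <- sort(tr$tip.label)  # deterministic label set
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

# All primitive motifs of lengths 2..4.
all_primitive_motifs <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (m in 2:4) {
    grids <- do.call(expand.grid, rep(list(bases), m))
    motifs <- apply(grids, 1L, paste, collapse = "")
    prim <- vapply(motifs, function(x) {
      for (p in seq_len(m - 1L)) {
        if (m %% p == 0L && strrep(substr(x, 1L, p), m / p) == x) {
          return(FALSE)
        }
      }
      TRUE
    }, TRUE)
    out <- c(out, motifs[prim])
  }
  out
}

# Small deterministic simulator configs for the suite.
small_sim_config <- function(seed = 9, n_clones = 6L) {
  simulation_config(
    n_clones = n_clones, clone_length_range = c(12000L, 18000L),
    class_targets = data.frame(
      class = c("high", "mid", "low"),
      n = c(n_clones - 4L, 2L, 2L),
      min = c(0.75, 0.50, 0.10), max = c(0.90, 0.65, 0.30)),
    families = list(
      family_spec("FA", ancestor_length = 1500L, n_copies = 20L,
                  age_years = 2e5, repeat_class = "novel"),
      family_spec("FB", is_ltr = TRUE, ltr_length = 300L,
                  internal_length = 900L, n_copies = 20L,
                  age_years = 5e5, repeat_class = "Ty1-Copia")),
    nesting_probability = 0.05, seed = seed)
}

# An SSR fixture built by direct construction: a background scanned
# clean of chance arrays, then perfect arrays planted with flanks that
# cannot extend them.
plant_ssr_fixture <- function(n_loci = 100L, seed = 31L) {
  set.seed(seed)
  motifs <- c("AT", "AC", "ACC", "AAG", "ATC", "AAAT", "ACGT")
  gap_clean <- function(len) {
    repeat {
      g <- random_background(len)
      if (nrow(find_ssrs(g)) == 0L) return(g)
    }
  }
  parts <- character(2L * n_loci + 1L)
  truth <- vector("list", n_loci)
  parts[1L] <- gap_clean(200L)
  pos <- nchar(parts[1L])
  for (i in seq_len(n_loci)) {
    motif <- sample(motifs, 1L)
    units <- sample(6:20, 1L)
    arr <- strrep(motif, units)
    m <- nchar(motif)
    # flanks that break the period on both sides
    left <- substr(arr, m, m)
    lfix <- setdiff(c("A", "C", "G", "T"), left)[1L]
    right <- substr(arr, nchar(arr) - m + 1L, nchar(arr) - m + 1L)
    rfix <- setdiff(c("A", "C", "G", "T"), right)[1L]
    gap <- gap_clean(150L)
    substr(parts[2L * i - 1L],
           nchar(parts[2L * i - 1L]), nchar(parts[2L * i - 1L])) <- lfix
    parts[2L * i] <- arr
    truth[[i]] <- data.frame(start = pos, end = pos + nchar(arr),
                             motif = motif, n_units = units,
                             stringsAsFactors = FALSE)
    pos <- pos + nchar(arr)
    substr(gap, 1L, 1L) <- rfix
    parts[2L * i + 1L] <- gap
    pos <- pos + nchar(gap)
  }
  list(seq = paste(parts, collapse = ""), truth = do.call(rbind, truth))
}
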