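# Homology masking against a labelled repeat library, score-based
# overlap resolution, and composition/extrapolation summaries in the
# layout of a genome-survey repeat table.

#' Mask sequences with a labelled repeat library
#'
#' Seed-and-extend local alignment: exact seed words from each library
#' sequence are located on both strands of each scaffold, seed hits are
#' grouped into candidate windows, and each candidate is verified by a
#' local alignment. Hits with identity `>= min_identity` over
#' `>= min_len` bp are reported; each reported interval inherits class
#' and family from its best-scoring library sequence.
#'
#' Library headers must carry the class label: either a `class=<class>`
#' token or `<family>#<class>` in the id, with `<class>` drawn from
#' [repeat_classes()].
#'
#' @param seqs Named character vector of scaffolds.
#' @param library Named character vector of labelled library sequences
#'   (e.g. family consensi), or a path to a FASTA file.
#' @param min_identity Minimum alignment identity (default 0.80).
#' @param min_len Minimum hit length (default 50 bp).
#' @param seed_len Exact seed word length (default 12).
#' @return Annotation `data.frame` (see [repeat_annotation()]); `score`
#'   is the alignment identity fraction.
#' @export
mask_with_library <- function(seqs, library, min_identity = 0.80,
                              min_len = 50L, seed_len = 12L) {
  if (is.character(library) && length(library) == 1L && file.exists(library)) {
    library <- read_fasta(library)
  }
  lab <- parse_library_labels(library)
  hits <- list()
  for (li in seq_along(library)) {
    lseq <- library[[li]]
    for (si in seq_along(seqs)) {
      h <- seed_extend_hits(seqs[[si]], lseq, min_identity, min_len, seed_len)
      if (!is.null(h)) {
        h$scaffold <- names(seqs)[si]
        h$repeat_class <- lab$class[li]
        h$family_id <- lab$family[li]
        hits[[length(hits) + 1L]] <- h
      }
    }
  }
  if (length(hits) == 0L) {
    return(repeat_annotation(character(0), integer(0), integer(0),
                             character(0))[0, ])
  }
  h <- do.call(rbind, hits)
  # among overlapping hits from different library sequences keep all;
  # resolve_overlaps() arbitrates later. But collapse near-duplicate
  # hits of the same library sequence on the same scaffold.
  ann <- repeat_annotation(h$scaffold, h$start, h$end, h$repeat_class,
                           h$family_id, h$score, h$strand)
  sort_annotations(ann)
}

parse_library_labels <- function(library) {
  ids <- names(library)
  if (is.null(ids)) stop("library sequences must be named")
  desc <- attr(library, "description")
  cls <- rep(NA_character_, length(ids))
  fam <- ids
  hash <- grepl("#", ids, fixed = TRUE)
  cls[hash] <- sub("^[^#]*#", "", ids[hash])
  fam[hash] <- sub("#.*$", "", ids[hash])
  if (!is.null(desc)) {
    d <- desc[ids]
    has <- !is.na(d) & grepl("class=", d)
    cls[has] <- sub("^.*class=([^ ;]+).*$", "\\1", d[has])
  }
  bad <- is.na(cls) | !cls %in% REPEAT_CLASSES
  if (any(bad)) {
    stop("unlabelled or unknown-class library record '", ids[which(bad)[1L]],
         "' (use 'family#class' ids or a 'class=' header token)")
  }
  list(family = fam, class = cls)
}

# Seed-and-extend one library sequence against one scaffold (both
# strands). Returns data.frame(start, end, strand, score) in 0-based
# half-open scaffold coordinates, or NULL.
seed_extend_hits <- function(scaffold, lseq, min_identity, min_len,
                             seed_len) {
  subj <- Biostrings::DNAString(scaffold)
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") lseq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(lseq)))
    qlen <- nchar(q)
    if (qlen < seed_len) next
    starts <- seq.int(1L, qlen - seed_len + 1L, by = seed_len)
    seed_pos <- integer(0)
    for (s in starts) {
      word <- substr(q, s, s + seed_len - 1L)
      if (grepl("N", word, fixed = TRUE)) next
      m <- Biostrings::matchPattern(word, subj)
      if (length(m) > 0L) {
        # project seed hit to implied query start on the scaffold
        seed_pos <- c(seed_pos, Biostrings::start(m) - (s - 1L))
      }
    }
    if (length(seed_pos) == 0L) next
    # group implied starts within half a query length into candidates
    seed_pos <- sort(seed_pos)
    grp <- cumsum(c(0L, diff(seed_pos) > max(qlen %/% 2L, seed_len)))
    cand <- tapply(seed_pos, grp, function(p) round(mean(p)))
    for (cs in cand) {
      w_start <- max(1L, cs - qlen %/% 2L)
      w_end <- min(nchar(scaffold), cs + qlen + qlen %/% 2L)
      window <- Biostrings::subseq(subj, w_start, w_end)
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(q), window, type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = TRUE),
        gapOpening = 0, gapExtension = 2)
      w <- Biostrings::nchar(aln)
      if (w == 0L) next
      ident <- Biostrings::nmatch(aln) / w
      hit_s <- w_start + Biostrings::start(Biostrings::subject(aln)) - 2L
      hit_e <- w_start + Biostrings::end(Biostrings::subject(aln)) - 1L
      if (ident >= min_identity && (hit_e - hit_s) >= min_len) {
        out[[length(out) + 1L]] <- data.frame(
          start = hit_s, end = hit_e, strand = strand, score = ident,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  h <- do.call(rbind, out)
  # drop hits nested inside a longer hit of this same library sequence
  h <- h[order(-(h$end - h$start), -h$score, h$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))[-1L]) {
    prior <- which(keep[seq_len(i - 1L)])
    if (any(h$start[prior] <= h$start[i] & h$end[prior] >= h$end[i])) {
      keep[i] <- FALSE
    }
  }
  h[keep, , drop = FALSE]
}

#' Resolve overlapping annotations
#'
#' Contested bases go to the higher score; ties by longer interval,
#' then lexicographic family id. Losers are truncated (possibly split
#' into fragments). The output is pairwise-disjoint and covers exactly
#' the union of the input intervals.
#'
#' @param ann Annotation `data.frame`.
#' @param min_fragment Fragments shorter than this are dropped
#'   (default 1, i.e. keep everything).
#' @return Non-overlapping annotation `data.frame`.
#' @export
resolve_overlaps <- function(ann, min_fragment = 1L) {
  validate_annotations(ann)
  if (nrow(ann) <= 1L) return(ann)
  fam <- ifelse(is.na(ann$family_id), "~", ann$family_id)  # NA sorts last
  o <- order(ann$scaffold, -ann$score, -(ann$end - ann$start), fam,
             ann$start)
  ann <- ann[o, , drop = FALSE]
  out <- list()
  for (sc in unique(ann$scaffold)) {
    rows <- ann[ann$scaffold == sc, , drop = FALSE]
    occupied <- IRanges::IRanges()
    for (i in seq_len(nrow(rows))) {
      iv <- IRanges::IRanges(start = rows$start[i] + 1L, end = rows$end[i])
      free <- IRanges::setdiff(iv, occupied)
      if (length(free) == 0L) next
      w <- IRanges::width(free)
      keep <- w >= min_fragment
      if (!any(keep)) next
      free <- free[keep]
      frag <- rows[rep(i, length(free)), , drop = FALSE]
      frag$start <- IRanges::start(free) - 1L
      frag$end <- IRanges::end(free)
      out[[length(out) + 1L]] <- frag
      occupied <- IRanges::union(occupied, iv)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  sort_annotations(res)
}

#' Summarise repeat composition and extrapolate to the genome
#'
#' Per-class totals over overlap-resolved annotations, with
#' `pct_of_genome = 100 * class_bp / dataset_bp`,
#' `genome_bp = (class_bp / dataset_bp) * genome_size` and
#' `pct_of_repetitive = 100 * class_bp / total_repetitive_bp`,
#' plus a totals row. Classes absent from the annotations appear with
#' zeros so the table always has the full class vocabulary.
#'
#' @param ann Overlap-resolved annotation `data.frame`.
#' @param dataset_bp Total analysed sequence length in bp.
#' @param genome_size Genome size in bp for extrapolation (default
#'   3.6e9).
#' @return `data.frame` with one row per repeat class plus a `TOTAL`
#'   row: `repeat_class`, `bac_bp`, `genome_bp`, `pct_of_genome`,
#'   `pct_of_repetitive`.
#' @export
summarize_composition <- function(ann, dataset_bp, genome_size = 3.6e9) {
  if (dataset_bp <= 0) stop("dataset_bp must be positive")
  validate_annotations(ann)
  bp <- setNames(rep(0, length(REPEAT_CLASSES)), REPEAT_CLASSES)
  if (nrow(ann) > 0L) {
    got <- tapply(ann$end - ann$start, ann$repeat_class, sum)
    bp[names(got)] <- got
  }
  total <- sum(bp)
  pct_rep <- if (total > 0) 100 * bp / total else bp * 0
  res <- data.frame(
    repeat_class = c(names(bp), "TOTAL"),
    bac_bp = c(unname(bp), total),
    genome_bp = c(unname(bp), total) / dataset_bp * genome_size,
    pct_of_genome = 100 * c(unname(bp), total) / dataset_bp,
    pct_of_repetitive = c(unname(pct_rep), if (total > 0) 100 else 0),
    stringsAsFactors = FALSE)
  attr(res, "dataset_bp") <- dataset_bp
  attr(res, "genome_size") <- genome_size
  res
}

#' Repeat density by region class
#'
#' bp per repeat copy, split by repeat-dense (putatively
#' heterochromatic) vs repeat-poor (putatively euchromatic) regions.
#' A copy is assigned to the region containing its interval midpoint,
#' avoiding double-counting of copies that straddle region boundaries.
#'
#' @param ann Annotation `data.frame` of repeat copies.
#' @param regions `data.frame` with `scaffold`, `start`, `end` (0-based
#'   half-open) and `region_class` in `{"dense", "poor"}`; regions must
#'   partition the analysed scaffolds.
#' @return List with `bp_per_repeat_dense`, `bp_per_repeat_poor`,
#'   `bp_per_repeat_avg` (each `NA` when its region set holds no
#'   repeats) and the underlying `counts` table.
#' @export
repeat_density <- function(ann, regions) {
  stopifnot(all(c("scaffold", "start", "end", "region_class") %in%
                  names(regions)))
  validate_annotations(ann)
  mid <- (ann$start + ann$end) / 2
  region_of <- rep(NA_character_, nrow(ann))
  for (i in seq_len(nrow(regions))) {
    sel <- ann$scaffold == regions$scaffold[i] &
      mid >= regions$start[i] & mid < regions$end[i]
    region_of[sel] <- regions$region_class[i]
  }
  region_bp <- tapply(regions$end - regions$start, regions$region_class, sum)
  dens <- function(cls) {
    n <- sum(region_of == cls, na.rm = TRUE)
    if (is.na(region_bp[cls]) || n == 0L) NA_real_
    else unname(region_bp[cls]) / n
  }
  n_all <- sum(!is.na(region_of))
  list(bp_per_repeat_dense = dens("dense"),
       bp_per_repeat_poor = dens("poor"),
       bp_per_repeat_avg = if (n_all > 0L) sum(region_bp) / n_all else NA_real_,
       counts = data.frame(
         region_class = names(region_bp),
         region_bp = as.numeric(region_bp),
         n_repeats = vapply(names(region_bp), function(cl)
           sum(region_of == cl, na.rm = TRUE), 0L),
         stringsAsFactors = FALSE))
}
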