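# End-to-end orchestration: simulate (optional) -> k-mer index ->
# landscape classification -> de novo discovery -> clustering/consensus
# library -> homology masking -> overlap resolution -> composition and
# density -> SSR / low-complexity -> family dating -> spatial runs
# tests -> report bundle; plus truth-recovery metrics for simulated
# inputs.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis stages with its default.
#'
#' @param k k-mer size (default 20).
#' @param freq_threshold Repetitive k-mer count threshold (default 4).
#' @param min_len Minimum repeat length in bp (default 50).
#' @param merge_gap Interval merge gap in bp (default 50).
#' @param min_copies Minimum family size (default 5).
#' @param identity_threshold,coverage_threshold Clustering thresholds
#'   (defaults 0.80 / 0.51).
#' @param min_identity Masking identity threshold (default 0.80).
#' @param bin_size Spatial bin width in bp (default 5000).
#' @param binarize_threshold Bin repetitive-occupancy cut (default 0.5).
#' @param min_contiguous Minimum scaffold length for spatial analysis
#'   (default 50000).
#' @param rate Substitution rate in subs/site/yr (default 2e-8).
#' @param genome_size Genome size for extrapolation (default 3.6e9).
#' @param alpha Runs-test significance level (default 0.05).
#' @param seed Top-level seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k = 20L, freq_threshold = 4L, min_len = 50L,
                            merge_gap = 50L, min_copies = 5L,
                            identity_threshold = 0.80,
                            coverage_threshold = 0.51,
                            min_identity = 0.80, bin_size = 5000L,
                            binarize_threshold = 0.5,
                            min_contiguous = 50000L, rate = 2e-8,
                            genome_size = 3.6e9, alpha = 0.05, seed = 1L) {
  cfg <- list(k = as.integer(k), freq_threshold = as.integer(freq_threshold),
              min_len = as.integer(min_len), merge_gap = as.integer(merge_gap),
              min_copies = as.integer(min_copies),
              identity_threshold = identity_threshold,
              coverage_threshold = coverage_threshold,
              min_identity = min_identity, bin_size = as.integer(bin_size),
              binarize_threshold = binarize_threshold,
              min_contiguous = as.integer(min_contiguous), rate = rate,
              genome_size = genome_size, alpha = alpha,
              seed = as.integer(seed))
  stopifnot(cfg$k >= 2L, cfg$freq_threshold >= 1L, cfg$min_len >= 1L,
            cfg$min_copies >= 1L, cfg$identity_threshold > 0,
            cfg$identity_threshold <= 1, cfg$coverage_threshold > 0,
            cfg$coverage_threshold <= 1, cfg$bin_size > 0L,
            cfg$rate > 0, cfg$genome_size > 0, cfg$alpha > 0, cfg$alpha < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full repeat-landscape analysis
#'
#' Executes the stage order: (optional) simulation, k-mer indexing,
#' clone classification, de novo repeat interval calling, family
#' clustering and consensus-library construction, homology masking of
#' the input against that library, overlap resolution, composition and
#' density summaries, SSR/low-complexity detection, consensus-based
#' family dating, and per-scaffold runs tests. All tabular outputs are
#' written to `out_dir` when given, together with a log that echoes
#' the configuration and seeds.
#'
#' @param clones Named character vector of input sequences, a FASTA
#'   path, or `NULL` to simulate from `sim_config`.
#' @param config A [pipeline_config()].
#' @param sim_config A [simulation_config()] used when `clones` is
#'   `NULL`; its truth enables [recovery_report()].
#' @param out_dir Optional output directory.
#' @return List with elements `clones`, `landscape`, `copies`,
#'   `clustering`, `library`, `annotations`, `resolved`, `composition`,
#'   `density`, `ssr`, `ssr_summary`, `low_complexity`, `family_ages`,
#'   `spatial`, `truth` (when simulated), `recovery` (when simulated),
#'   `config`.
#' @export
run_full <- function(clones = NULL, config = pipeline_config(),
                     sim_config = NULL, out_dir = NULL) {
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  truth <- NULL
  if (is.null(clones)) {
    if (is.null(sim_config)) stop("either clones or sim_config is required")
    say("stage simulate: ", sim_config$n_clones, " clones, seed ",
        sim_config$seed)
    sim <- build_synthetic_clones(sim_config)
    clones <- sim$clones
    truth <- sim$truth
  } else if (is.character(clones) && length(clones) == 1L &&
             file.exists(clones)) {
    say("stage load: ", clones)
    clones <- read_fasta(clones)
  } else if (is.character(clones) && length(clones) == 1L &&
             !grepl("^[ACGTN]+$", clones)) {
    stop("input FASTA not found: ", clones)
  }
  dataset_bp <- sum(nchar(clones))
  say("dataset: ", length(clones), " sequences, ", dataset_bp, " bp")

  say("stage index: k = ", config$k)
  index <- build_kmer_index(clones, config$k)
  prof <- repetitive_profile(clones, index, config$freq_threshold)
  landscape <- data.frame(clone_id = names(clones),
                          fraction = unname(prof$fraction),
                          clone_class = classify_clone(unname(prof$fraction)),
                          stringsAsFactors = FALSE)

  say("stage discovery")
  copies <- find_repeat_intervals(clones, index, config$freq_threshold,
                                  config$min_len, config$merge_gap)
  say("  ", nrow(copies), " repeat intervals")
  clustering <- NULL
  lib <- character(0)
  if (nrow(copies) > 0L) {
    set.seed(derive_seed(config$seed, "discovery"))
    clustering <- cluster_copies(copies, config$identity_threshold,
                                 config$coverage_threshold,
                                 config$min_copies)
    say("  ", length(clustering$families), " families (",
        clustering$report$n_unclustered, " unclustered)")
    lib <- vapply(clustering$families, `[[`, "", "consensus")
    names(lib) <- paste0(vapply(clustering$families, `[[`, "", "family_id"),
                         "#novel")
  }

  ann <- NULL
  if (length(lib) > 0L) {
    say("stage mask: library of ", length(lib), " consensi")
    ann <- mask_with_library(clones, lib, config$min_identity,
                             config$min_len)
    say("  ", nrow(ann), " hits")
  }

  say("stage ssr")
  ssr <- do.call(rbind, lapply(names(clones), function(id) {
    find_ssrs(clones[[id]], scaffold_id = id)
  }))
  lc <- do.call(rbind, lapply(names(clones), function(id) {
    find_low_complexity(clones[[id]], scaffold_id = id)
  }))
  ssr_ann <- if (nrow(ssr) > 0L) {
    repeat_annotation(ssr$scaffold, ssr$start, ssr$end, "SSR",
                      paste0("SSR_", ssr$canonical_motif), score = 1.0)
  } else NULL
  lc_ann <- if (!is.null(lc) && nrow(lc) > 0L) {
    repeat_annotation(lc$scaffold, lc$start, lc$end, "low_complexity",
                      NA_character_, score = 0.5)
  } else NULL

  all_ann <- do.call(rbind, Filter(Negate(is.null),
                                   list(ann, ssr_ann, lc_ann)))
  if (is.null(all_ann)) {
    all_ann <- repeat_annotation(character(0), integer(0), integer(0),
                                 character(0))[0, ]
  }
  say("stage resolve: ", nrow(all_ann), " raw annotations")
  resolved <- if (nrow(all_ann) > 0L) resolve_overlaps(all_ann) else all_ann
  pre_bp <- sum(all_ann$end - all_ann$start)
  post_bp <- sum(resolved$end - resolved$start)
  say("  pre-resolution ", pre_bp, " bp; post-resolution ", post_bp, " bp")

  composition <- summarize_composition(resolved, dataset_bp,
                                       config$genome_size)

  # density regions from the k-mer landscape: one region per bin,
  # dense when at least half its positions are repeat-covered
  regions <- do.call(rbind, lapply(names(clones), function(id) {
    cov <- prof$coverage[[id]]
    L <- length(cov)
    if (L < config$bin_size / 2) return(NULL)
    starts <- seq.int(0L, L - 1L, by = config$bin_size)
    ends <- pmin(starts + config$bin_size, L)
    keep <- (ends - starts) >= config$bin_size / 2
    starts <- starts[keep]; ends <- ends[keep]
    occ <- vapply(seq_along(starts), function(b) {
      mean(cov[(starts[b] + 1L):ends[b]])
    }, 0)
    data.frame(scaffold = id, start = starts, end = ends,
               region_class = ifelse(occ >= 0.5, "dense", "poor"),
               stringsAsFactors = FALSE)
  }))
  density <- if (!is.null(regions) && nrow(resolved) > 0L) {
    repeat_density(resolved, regions)
  } else NULL

  say("stage dating")
  family_ages <- list()
  if (!is.null(clustering)) {
    for (fam in clustering$families) {
      fa <- tryCatch(
        family_consensus_age(fam$members, fam$consensus, config$rate,
                             fam$family_id),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fa)) family_ages[[length(family_ages) + 1L]] <- fa
    }
  }

  say("stage spatial")
  keep_ids <- select_scaffolds(clones, config$min_contiguous)
  series <- lapply(keep_ids, function(id) {
    binarize(id, nchar(clones[[id]]), resolved, config$bin_size,
             config$binarize_threshold)
  })
  spatial <- randomness_report(series, config$alpha)

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- recovery_report(
      truth, list(copies = copies, clustering = clustering,
                  landscape = landscape, ssr = ssr,
                  family_ages = family_ages),
      k = config$k, rate = config$rate)
  }

  out <- list(clones = clones, landscape = landscape, copies = copies,
              clustering = clustering, library = lib,
              annotations = all_ann, resolved = resolved,
              composition = composition, density = density, ssr = ssr,
              ssr_summary = ssr_summary(ssr), low_complexity = lc,
              family_ages = family_ages, spatial = spatial, truth = truth,
              recovery = recovery, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) {
      if (!is.null(x) && is.data.frame(x)) {
        write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }
    }
    write_fasta(clones, file.path(out_dir, "input.fasta"))
    wt(landscape, "landscape.tsv")
    wt(copies[, setdiff(names(copies), "seq")], "repeat_copies.tsv")
    if (!is.null(clustering)) {
      rep_df <- with(clustering$report, data.frame(
        statistic = c("Total number of sequences",
                      "Number of sequences not clustered",
                      "Number of clusters", "Clusters with >5 sequences",
                      "Clusters with >20 sequences",
                      "Clusters with >50 sequences",
                      "Clusters with >100 sequences",
                      "Number of sequences in the largest cluster"),
        value = c(n_sequences, n_unclustered, n_clusters, clusters_gt5,
                  clusters_gt20, clusters_gt50, clusters_gt100,
                  largest_cluster_size)))
      wt(rep_df, "cluster_report.tsv")
      wt(clustering$membership, "family_membership.tsv")
      if (length(lib) > 0L) {
        write_fasta(lib, file.path(out_dir, "family_consensi.fasta"))
      }
    }
    if (nrow(resolved) > 0L) {
      write_annotations(resolved, file.path(out_dir, "annotations.gff3"),
                        "GFF3")
    }
    wt(composition, "composition.tsv")
    wt(ssr, "ssr_loci.tsv")
    wt(out$ssr_summary$per_motif, "ssr_motifs.tsv")
    wt(lc, "low_complexity.tsv")
    if (length(family_ages) > 0L) {
      wt(data.frame(family_id = vapply(family_ages, `[[`, "", "family_id"),
                    k = vapply(family_ages, `[[`, 0, "k"),
                    age_years = vapply(family_ages, `[[`, 0, "age_years")),
         "family_ages.tsv")
    }
    wt(spatial, "runs_tests.tsv")
    if (!is.null(recovery)) wt(recovery$summary, "recovery.tsv")
    say("outputs written to ", out_dir)
    writeLines(c(paste0("# config: ",
                        paste(names(unclass(config)),
                              unlist(config), sep = "=", collapse = " ")),
                 log_lines), file.path(out_dir, "pipeline.log"))
  }
  out
}

#' Recovery metrics against simulator ground truth
#'
#' Compares pipeline results with the planted truth: clone-class
#' confusion matrix, family count, copy-boundary precision/recall at a
#' +/- `k` bp tolerance, per-family age bias/RMSE (discovered families
#' matched to planted ones by member-interval overlap), and SSR
#' recall/precision (exact-interval matching).
#'
#' @param truth Truth list from [build_synthetic_clones()].
#' @param results List with any of `copies`, `clustering`, `landscape`,
#'   `ssr`, `family_ages` (as produced by [run_full()]).
#' @param k Boundary tolerance in bp (the k-mer size).
#' @param rate Substitution rate used for the age comparison.
#' @return List of metric tables plus a flat `summary` data.frame.
#' @export
recovery_report <- function(truth, results, k = 20L, rate = 2e-8) {
  out <- list()
  te_truth <- truth$annotations[
    !truth$annotations$repeat_class %in% c("SSR", "low_complexity"), ,
    drop = FALSE]

  if (!is.null(results$landscape)) {
    tc <- truth$clones
    lc <- results$landscape
    m <- merge(tc[, c("clone_id", "clone_class")],
               lc[, c("clone_id", "clone_class")], by = "clone_id",
               suffixes = c("_truth", "_called"))
    out$clone_confusion <- table(truth = m$clone_class_truth,
                                 called = m$clone_class_called)
    out$clone_class_accuracy <-
      mean(m$clone_class_truth == m$clone_class_called)
  }

  if (!is.null(results$copies) && nrow(results$copies) > 0L) {
    cp <- results$copies
    tp_bounds <- 0L
    for (i in seq_len(nrow(te_truth))) {
      same <- cp[cp$scaffold == te_truth$scaffold[i], , drop = FALSE]
      if (nrow(same) == 0L) next
      hit <- any(abs(same$start - te_truth$start[i]) <= k &
                   abs(same$end - te_truth$end[i]) <= k)
      # merged calls: count boundary recovery separately
      if (hit) tp_bounds <- tp_bounds + 1L
    }
    out$copy_boundary_recall <- tp_bounds / max(1L, nrow(te_truth))
    # bp-level recall: planted TE bases covered by discovered intervals
    cov_bp <- 0L; truth_bp <- 0L
    for (sc in unique(te_truth$scaffold)) {
      ti <- te_truth[te_truth$scaffold == sc, , drop = FALSE]
      ci <- cp[cp$scaffold == sc, , drop = FALSE]
      t_ir <- IRanges::reduce(IRanges::IRanges(ti$start + 1L, ti$end))
      truth_bp <- truth_bp + sum(IRanges::width(t_ir))
      if (nrow(ci) > 0L) {
        c_ir <- IRanges::reduce(IRanges::IRanges(ci$start + 1L, ci$end))
        cov_bp <- cov_bp +
          sum(IRanges::width(IRanges::intersect(t_ir, c_ir)))
      }
    }
    out$copy_bp_recall <- cov_bp / max(1L, truth_bp)
  }

  if (!is.null(results$clustering)) {
    out$n_families_planted <- length(unique(te_truth$family_id))
    out$n_families_recovered <- length(results$clustering$families)
  }

  if (!is.null(results$ssr)) {
    st <- truth$annotations[truth$annotations$repeat_class == "SSR", ,
                            drop = FALSE]
    ds <- results$ssr
    if (nrow(st) > 0L) {
      key_t <- paste(st$scaffold, st$start, st$end)
      key_d <- paste(ds$scaffold, ds$start, ds$end)
      out$ssr_recall <- mean(key_t %in% key_d)
      planted_like <- key_d %in% key_t
      out$ssr_precision <- if (nrow(ds) > 0L) mean(planted_like) else NA_real_
    }
  }

  if (!is.null(results$family_ages) && length(results$family_ages) > 0L &&
      !is.null(results$clustering)) {
    true_age_of_family <- tapply(truth$copies$true_age,
                                 truth$copies$family_id, mean)
    mem <- results$clustering$membership
    cp <- results$copies
    rows <- list()
    for (fa in results$family_ages) {
      ids <- mem$copy_id[!is.na(mem$family_id) &
                           mem$family_id == fa$family_id]
      sel <- cp[cp$copy_id %in% ids, , drop = FALSE]
      votes <- character(0)
      for (i in seq_len(nrow(sel))) {
        ov <- te_truth$scaffold == sel$scaffold[i] &
          te_truth$start < sel$end[i] & te_truth$end > sel$start[i]
        votes <- c(votes, te_truth$family_id[ov])
      }
      if (length(votes) == 0L) next
      planted <- names(sort(table(votes), decreasing = TRUE))[1L]
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = fa$family_id, planted_family = planted,
        est_age = fa$age_years,
        true_age = unname(true_age_of_family[planted]),
        stringsAsFactors = FALSE)
    }
    if (length(rows) > 0L) {
      am <- do.call(rbind, rows)
      am$bias <- am$est_age - am$true_age
      out$age_match <- am
      out$age_rmse <- sqrt(mean(am$bias^2))
    }
  }

  num <- Filter(function(x) is.numeric(x) && length(x) == 1L, out)
  out$summary <- data.frame(metric = names(num),
                            value = unlist(num, use.names = FALSE),
                            stringsAsFactors = FALSE)
  out
}
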