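test_that("library masking recovers planted copies and honours thresholds", {
  set.seed(17)
  anc <- random_background(1200)
  copy <- mutate_sequence(anc, 2.5e6, 2e-8)        # ~5% diverged
  copy_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(copy)))
  scaf <- paste0(random_background(2000), copy, random_background(2000),
                 copy_rc, random_background(1000))
  ann <- mask_with_library(c(s1 = scaf), c("FAM1#Ty1-Copia" = anc))
  expect_gte(nrow(ann), 2L)
  expect_true(all(ann$repeat_class == "Ty1-Copia"))
  expect_true(all(ann$family_id == "FAM1"))
  # forward copy covered >= 90%
  fwd <- ann[ann$strand == "+", ]
  cov_fwd <- sum(pmin(fwd$end, 3200) - pmax(fwd$start, 2000))
  expect_gte(cov_fwd / 1200, 0.90)
  # reverse copy found on the minus strand
  rev <- ann[ann$strand == "-", ]
  expect_gte(nrow(rev), 1L)

  # unrelated library: no hits
  none <- mask_with_library(c(s1 = random_background(3000)),
                            c("FAMX#novel" = random_background(800)))
  expect_equal(nrow(none), 0L)

  # ~30% diverged copy fails the 0.80 identity threshold
  far <- mutate_sequence(anc, 25e6, 2e-8)
  scaf_far <- paste0(random_background(1000), far, random_background(1000))
  ann_far <- mask_with_library(c(s1 = scaf_far), c("FAM1#Ty1-Copia" = anc),
                               min_identity = 0.80)
  hit_bp <- if (nrow(ann_far) > 0)
    sum(pmin(ann_far$end, 2200) - pmax(ann_far$start, 1000)) else 0
  expect_lt(hit_bp / 1200, 0.5)

  # unlabeled library record rejected by name
  expect_error(mask_with_library(c(s1 = scaf), c(plain = anc)), "plain")
})

test_that("overlap resolution applies the score/length/family rules", {
  ann <- repeat_annotation(
    scaffold = c("s", "s"), start = c(0L, 50L), end = c(100L, 150L),
    repeat_class = c("Ty1-Copia", "Ty3-Gypsy"),
    family_id = c("A", "B"), score = c(0.9, 0.8))
  res <- resolve_overlaps(ann)
  res <- res[order(res$start), ]
  expect_equal(res$start, c(0L, 100L))
  expect_equal(res$end, c(100L, 150L))
  expect_equal(res$family_id, c("A", "B"))

  # identical intervals, equal scores: lexicographic family wins
  tie <- repeat_annotation(
    scaffold = c("s", "s"), start = c(0L, 0L), end = c(100L, 100L),
    repeat_class = c("novel", "novel"), family_id = c("B", "A"),
    score = c(0.5, 0.5))
  res_tie <- resolve_overlaps(tie)
  expect_equal(nrow(res_tie), 1L)
  expect_equal(res_tie$family_id, "A")

  # a loser can be split into two fragments
  split <- repeat_annotation(
    scaffold = c("s", "s"), start = c(100L, 0L), end = c(200L, 300L),
    repeat_class = c("SSR", "novel"), family_id = c("S", "N"),
    score = c(1, 0.5))
  res_split <- resolve_overlaps(split)
  n_frag <- res_split[res_split$family_id == "N", ]
  expect_equal(nrow(n_frag), 2L)
  expect_equal(sort(n_frag$start), c(0L, 200L))
})

test_that("random overlap fuzz is disjoint and matches per-base assignment", {
  set.seed(18)
  n <- 200
  ann <- repeat_annotation(
    scaffold = sample(c("s1", "s2"), n, replace = TRUE),
    start = st <- sample(0:4000, n, replace = TRUE),
    end = st + sample(20:400, n, replace = TRUE),
    repeat_class = sample(c("novel", "SSR", "Ty1-Copia"), n, replace = TRUE),
    family_id = sample(sprintf("F%02d", 1:12), n, replace = TRUE),
    score = runif(n))
  res <- resolve_overlaps(ann)

  # pairwise disjoint per scaffold
  for (sc in unique(res$scaffold)) {
    rows <- res[res$scaffold == sc, ]
    rows <- rows[order(rows$start), ]
    if (nrow(rows) > 1) {
      expect_true(all(rows$start[-1] >= rows$end[-nrow(rows)]))
    }
  }

  # union-preserving and per-base winner identical to the oracle
  oracle <- per_base_assignment(ann)
  for (sc in unique(ann$scaffold)) {
    v <- oracle[[sc]]
    rows <- res[res$scaffold == sc, ]
    got <- integer(length(v))
    for (i in seq_len(nrow(rows))) {
      key <- which(ann$scaffold == sc & ann$family_id == rows$family_id[i] &
                     ann$score == rows$score[i] &
                     ann$repeat_class == rows$repeat_class[i] &
                     ann$start <= rows$start[i] & ann$end >= rows$end[i])
      got[(rows$start[i] + 1):rows$end[i]] <- key[1]
    }
    expect_equal(sum(got > 0), sum(v > 0))  # union preserved
    expect_equal(got, v)                    # same winner everywhere
  }
})

test_that("composition summary reproduces survey-table arithmetic", {
  # one annotation per class with the exact printed class totals
  bp <- c(`Ty1-Copia` = 2014560, `Ty3-Gypsy` = 2633637,
          LINE_SINE = 14316, `ClassI-unclassified` = 2307645,
          `ClassI-novel` = 2463529, `DNA-nonMITE` = 19451, MITE = 3442,
          `DNA-unclassified` = 32398, rDNA = 34127, centromeric = 32353,
          telomeric = 1281, SSR = 160912, unclassified = 1194287,
          novel = 1462325)
  ann <- repeat_annotation(scaffold = names(bp), start = 0L,
                           end = as.integer(bp),
                           repeat_class = names(bp), score = 1)
  comp <- summarize_composition(ann, dataset_bp = 14058762,
                                genome_size = 3.6e9)
  row <- comp[comp$repeat_class == "Ty1-Copia", ]
  expect_equal(round(row$pct_of_genome, 2), 14.33)
  expect_equal(round(row$pct_of_repetitive, 2), 16.28)
  tot <- comp[comp$repeat_class == "TOTAL", ]
  expect_equal(tot$bac_bp, 12374263)
  expect_equal(round(tot$pct_of_genome, 2), 88.02)
  # extrapolation identity: genome_bp / genome_size = pct / 100
  expect_equal(comp$genome_bp / 3.6e9, comp$pct_of_genome / 100)

  # invariance to annotation order
  comp2 <- summarize_composition(ann[rev(seq_len(nrow(ann))), ],
                                 14058762, 3.6e9)
  expect_equal(comp, comp2, ignore_attr = TRUE)

  empty <- summarize_composition(ann[0, ], 1000)
  expect_true(all(empty$bac_bp == 0))
  expect_error(summarize_composition(ann, 0), "positive")
})

test_that("repeat density divides region bp by midpoint-assigned copies", {
  regions <- data.frame(scaffold = "s", start = c(0L, 10000L),
                        end = c(10000L, 20000L),
                        region_class = c("dense", "poor"))
  ann <- repeat_annotation(
    scaffold = "s", start = seq(0L, 9500L, by = 500L)[1:20],
    end = seq(0L, 9500L, by = 500L)[1:20] + 400L,
    repeat_class = "novel", score = 1)
  dens <- repeat_density(ann, regions)
  expect_equal(dens$bp_per_repeat_dense, 500)   # 10,000 bp / 20 copies
  expect_true(is.na(dens$bp_per_repeat_poor))   # absent, not zero
  expect_equal(dens$bp_per_repeat_avg, 1000)    # 20,000 bp / 20 copies
})
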