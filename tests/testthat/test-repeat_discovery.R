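test_that("interval calling finds planted copies and applies the filters", {
  set.seed(13)
  # unique sequence: nothing called
  uniq <- c(u = random_background(5000))
  idx_u <- build_kmer_index(uniq, 20)
  expect_equal(nrow(find_repeat_intervals(uniq, idx_u, 4)), 0L)

  # five copies of a 300-bp element planted with wide spacing
  anc <- random_background(300)
  gaps <- replicate(6, random_background(700))
  scaf <- paste0(gaps[1], anc, gaps[2], anc, gaps[3], anc, gaps[4], anc,
                 gaps[5], anc, gaps[6])
  seqs <- c(s = scaf)
  idx <- build_kmer_index(seqs, 20)
  copies <- find_repeat_intervals(seqs, idx, freq_threshold = 4,
                                  min_len = 50, merge_gap = 50)
  expect_gte(nrow(copies), 5L)
  starts_truth <- 700 + (0:4) * 1000
  for (st in starts_truth) {
    expect_true(any(abs(copies$start - st) <= 20 &
                      abs(copies$end - (st + 300)) <= 20))
  }
  # emitted sequences match the clone slices
  expect_equal(copies$seq[1],
               substr(scaf, copies$start[1] + 1, copies$end[1]))

  # a 49-bp repeated block is excluded by min_len = 50
  blk <- random_background(49)
  scaf2 <- paste0(random_background(600), blk, random_background(600), blk,
                  random_background(600), blk, random_background(600), blk,
                  random_background(600))
  seqs2 <- c(s = scaf2)
  idx2 <- build_kmer_index(seqs2, 20)
  called2 <- find_repeat_intervals(seqs2, idx2, freq_threshold = 4,
                                   min_len = 50)
  expect_equal(nrow(called2), 0L)
})

test_that("clustering links copies blastclust-style and reports conservation", {
  set.seed(14)
  # 10 copies of one ancestor at ~5% divergence form one family
  anc <- random_background(800)
  cps <- vapply(1:10, function(i) mutate_sequence(anc, 2.5e6, 2e-8), "")
  copies <- data.frame(copy_id = sprintf("c%02d", 1:10), scaffold = "s",
                       start = 0L, end = 800L, seq = cps,
                       stringsAsFactors = FALSE)
  res <- cluster_copies(copies)
  expect_equal(length(res$families), 1L)
  expect_equal(res$families[[1]]$copy_number, 10L)
  expect_equal(res$families[[1]]$total_bp, 8000L)
  rep <- res$report
  expect_equal(rep$n_unclustered + sum(rep$cluster_sizes), rep$n_sequences)

  # two unrelated families, plus a lone copy that stays unclustered
  anc2 <- random_background(800)
  cps2 <- vapply(1:6, function(i) mutate_sequence(anc2, 2.5e6, 2e-8), "")
  lone <- random_background(700)
  copies2 <- data.frame(
    copy_id = sprintf("c%02d", 1:17), scaffold = "s", start = 0L,
    end = 800L, seq = c(cps, cps2, lone), stringsAsFactors = FALSE)
  res2 <- cluster_copies(copies2)
  expect_equal(length(res2$families), 2L)
  expect_equal(sort(vapply(res2$families, `[[`, 0L, "copy_number")),
               c(6L, 10L))
  expect_equal(res2$report$n_unclustered, 1L)

  # permuting input order changes no family composition
  perm <- sample(nrow(copies2))
  res3 <- cluster_copies(copies2[perm, ])
  members3 <- lapply(res3$families, function(f) sort(f$member_ids))
  members2 <- lapply(res2$families, function(f) sort(f$member_ids))
  expect_setequal(vapply(members3, paste, "", collapse = ","),
                  vapply(members2, paste, "", collapse = ","))
})

test_that("consensus building recovers the ancestor by majority vote", {
  # identical members reproduce themselves
  fam_id <- list(members = setNames(rep("ACGTACGT", 3), paste0("m", 1:3)))
  expect_equal(build_consensus(fam_id), "ACGTACGT")

  # tie columns resolve alphabetically
  fam_tie <- list(members = setNames(c("AAAA", "AAAA", "CAAA", "CAAA"),
                                     paste0("m", 1:4)))
  expect_equal(substr(build_consensus(fam_tie), 1, 1), "A")

  # 20 copies at 10% divergence: consensus >= 99% identical to ancestor
  set.seed(15)
  anc <- random_background(1000)
  cps <- vapply(1:20, function(i) mutate_sequence(anc, 5e6, 2e-8), "")
  fam <- list(members = setNames(cps, sprintf("m%02d", 1:20)))
  cons <- build_consensus(fam)
  expect_equal(nchar(cons), 1000L)
  ident <- mean(strsplit(cons, "")[[1]] == strsplit(anc, "")[[1]])
  expect_gte(ident, 0.99)

  expect_warning(one <- build_consensus(list(members = c(m = "ACGT"))),
                 "single-member")
  expect_equal(one, "ACGT")
})

test_that("abundance curve finds the smallest prefix reaching half", {
  mk <- function(id, bp, cn) list(family_id = id, total_bp = bp,
                                  copy_number = cn)
  fams <- list(mk("a", 500, 2), mk("b", 300, 3), mk("c", 200, 5))
  curve <- family_abundance_curve(fams)
  expect_equal(curve$families_for_50pct_bp, 1L)       # 500/1000
  expect_equal(curve$families_for_50pct_copies, 1L)   # top family: 5/10

  eq <- lapply(1:10, function(i) mk(paste0("f", i), 100, 1))
  expect_equal(family_abundance_curve(eq)$families_for_50pct_bp, 5L)

  # Zipf-like sizes match a brute-force prefix scan
  set.seed(16)
  sizes <- round(1000 / seq_len(30)^1.1)
  fams_z <- lapply(seq_along(sizes), function(i)
    mk(paste0("z", i), sizes[i], sizes[i] %/% 10 + 1L))
  curve_z <- family_abundance_curve(fams_z)
  brute <- which(cumsum(sort(sizes, decreasing = TRUE)) >=
                   0.5 * sum(sizes))[1]
  expect_equal(curve_z$families_for_50pct_bp, brute)
})
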