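test_that("K2P forward simulation matches the closed-form P and Q", {
  set.seed(21)
  s <- random_background(10000)
  expect_identical(mutate_sequence(s, 0, 2e-8), s)  # zero divergence
  expect_identical(mutate_sequence(s, 1e6, 2e-8, seed = 5),
                   mutate_sequence(s, 1e6, 2e-8, seed = 5))  # determinism
  expect_error(mutate_sequence("ACGN", 1e6, 2e-8), "\\{A,C,G,T\\}")

  # d = rate * age = 0.1 with kappa = 2: alpha*t = d*kappa/(kappa+2),
  # beta*t = d/(kappa+2); expected transition/transversion proportions
  d <- 0.1; kappa <- 2
  at <- d * kappa / (kappa + 2); bt <- d / (kappa + 2)
  P_exp <- 1 / 4 + exp(-4 * bt) / 4 - exp(-2 * (at + bt)) / 2
  Q_exp <- 1 / 2 - exp(-4 * bt) / 2
  p_exp <- P_exp + Q_exp
  m <- mutate_sequence(s, 5e6, 2e-8, kappa, seed = 17)
  a <- strsplit(s, "")[[1]]; b <- strsplit(m, "")[[1]]
  p_obs <- mean(a != b)
  n <- nchar(s)
  expect_lt(abs(p_obs - p_exp), 5 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("LTR elements calibrate to 2rT pairwise divergence", {
  spec <- family_spec("L", is_ltr = TRUE, ltr_length = 1500L,
                      internal_length = 200L, age_years = 2.7e6)
  el0 <- simulate_ltr_element(
    family_spec("L0", is_ltr = TRUE, ltr_length = 100L,
                internal_length = 50L, age_years = 0), seed = 1)
  expect_identical(el0$ltr5, el0$ltr3)  # identical at insertion
  expect_equal(nchar(el0$element), 2 * 100 + 50)
  expect_error(family_spec("x", is_ltr = TRUE, ltr_length = 10L,
                           internal_length = 100L), "too short to date")

  set.seed(77)
  n_rep <- 150
  dvg <- replicate(n_rep, {
    el <- simulate_ltr_element(spec)
    k2p_distance(el$ltr5, el$ltr3)$d
  })
  target <- 2 * 2e-8 * 2.7e6  # 0.108
  expect_lt(abs(mean(dvg) - target), 3 * sd(dvg) / sqrt(n_rep))
})

test_that("family copies calibrate to rT divergence from the ancestor", {
  fs0 <- family_spec("F0", ancestor_length = 300L, n_copies = 1L,
                     age_years = 0)
  fam0 <- simulate_family(fs0, seed = 2)
  expect_identical(unname(fam0$copies[1]), fam0$ancestor)
  expect_false(anyDuplicated(names(fam0$copies)) > 0)

  fs <- family_spec("F", ancestor_length = 2000L, n_copies = 50L,
                    age_years = 14.4e6)
  fam <- simulate_family(fs, seed = 3)
  d <- vapply(fam$copies, function(cp) k2p_distance(cp, fam$ancestor)$d, 0)
  target <- 2e-8 * 14.4e6  # 0.288
  expect_lt(abs(mean(d) - target), 3 * sd(d) / sqrt(length(d)))
})

test_that("synthetic clones respect class targets, truth and determinism", {
  cfg <- small_sim_config(seed = 41)
  sim <- build_synthetic_clones(cfg)
  tc <- sim$truth$clones
  expect_equal(nrow(tc), 6L)
  expect_true(all(abs(tc$realized_fraction - tc$target_fraction) <= 0.03))
  expect_equal(unname(nchar(sim$clones)), tc$length)

  # truth intervals lie within their clones
  ann <- sim$truth$annotations
  lens <- setNames(nchar(sim$clones), names(sim$clones))
  expect_true(all(ann$start >= 0 & ann$end <= lens[ann$scaffold]))

  # determinism: same seed, byte-identical clones and truth
  sim2 <- build_synthetic_clones(cfg)
  expect_identical(sim$clones, sim2$clones)
  expect_identical(sim$truth, sim2$truth)

  # nesting_probability 0: no TE truth interval strictly inside another
  cfg0 <- small_sim_config(seed = 42)
  cfg0$nesting_probability <- 0
  s0 <- build_synthetic_clones(cfg0)
  a0 <- s0$truth$annotations
  nested <- FALSE
  for (sc in unique(a0$scaffold)) {
    rows <- a0[a0$scaffold == sc, ]
    if (nrow(rows) < 2) next
    for (i in seq_len(nrow(rows))) {
      inside <- rows$start <= rows$start[i] & rows$end >= rows$end[i]
      if (sum(inside) > 1L) nested <- TRUE
    }
  }
  expect_false(nested)

  # ground-truth repetitive bp matches the reported realized fraction
  te <- ann[!ann$repeat_class %in% c("SSR", "low_complexity"), ]
  bp <- tapply(te$end - te$start, te$scaffold, sum)
  expect_equal(as.numeric(bp[tc$clone_id]) / tc$length,
               tc$realized_fraction, tolerance = 1e-9)
})

test_that("class-target bookkeeping mirrors an 80/14/2 survey design", {
  cfg <- simulation_config(seed = 1)
  ct <- cfg$class_targets
  expect_equal(ct$n, c(80L, 14L, 2L))
  expect_equal(sum(ct$n), cfg$n_clones)
  expect_error(simulation_config(n_clones = 10), "sum to n_clones")
})
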