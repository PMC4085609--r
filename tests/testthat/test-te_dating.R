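test_that("K2P distance matches direct evaluation and an ape oracle", {
  expect_equal(k2p_distance("ACGT", "ACGT")$d, 0)

  # 100 comparable sites, 10 transitions, 5 transversions: d = 0.1702
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  res <- k2p_distance(a, b)
  expect_equal(res$P, 0.10)
  expect_equal(res$Q, 0.05)
  expect_equal(res$d, -0.5 * log(1 - 0.25) - 0.25 * log(0.9))
  expect_equal(round(res$d, 4), 0.1702)

  # saturation is an explicit error, not NaN
  sat <- paste0(strrep("G", 50), strrep("A", 50))
  expect_error(k2p_distance(strrep("A", 100), sat), "saturation")

  # gap and N columns excluded from comparable sites
  resg <- k2p_distance("AC-GTN", "ACCGTA")
  expect_equal(resg$comparable_sites, 4L)

  # oracle: agrees with ape::dist.dna(model = "K80") on random pairs
  set.seed(22)
  for (i in 1:20) {
    s <- random_background(sample(200:1000, 1))
    m <- mutate_sequence(s, sample(1:12, 1) * 1e6, 2e-8)
    mine <- k2p_distance(s, m)$d
    bin <- ape::as.DNAbin(strsplit(tolower(c(x = s, y = m)), ""))
    ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
    expect_equal(mine, ref, tolerance = 1e-12)
    # correction only inflates the raw mismatch proportion
    p_raw <- mean(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
    expect_gte(mine, p_raw)
  }
})

test_that("LTR insertion ages follow T = d/(2r)", {
  expect_equal(ltr_insertion_age(0), 0)
  expect_equal(ltr_insertion_age(0.1702, 2e-8), 4.255e6)
  expect_equal(ltr_insertion_age(0.108, 2e-8), 2.7e6)
  expect_error(ltr_insertion_age(0.1, 0), "positive")
  expect_error(ltr_insertion_age(-0.1), ">= 0")
})

test_that("consensus-based family ages invert rT", {
  set.seed(23)
  anc <- random_background(1500)
  same <- setNames(rep(anc, 3), paste0("m", 1:3))
  fa0 <- family_consensus_age(same, anc)
  expect_equal(fa0$age_years, 0)

  fs <- family_spec("F", ancestor_length = 2000L, n_copies = 50L,
                    age_years = 14.4e6)
  fam <- simulate_family(fs, seed = 24)
  fa <- family_consensus_age(fam$copies, fam$ancestor, rate = 2e-8)
  expect_lt(abs(fa$age_years - 14.4e6) / 14.4e6, 0.05)

  # monotone in k
  fs2 <- family_spec("G", ancestor_length = 2000L, n_copies = 20L,
                     age_years = 2e6)
  fam2 <- simulate_family(fs2, seed = 25)
  fa2 <- family_consensus_age(fam2$copies, fam2$ancestor)
  expect_lt(fa2$k, fa$k)
  expect_lt(fa2$age_years, fa$age_years)
})

test_that("age-divergence correlation is exactly 1 by linearity", {
  set.seed(26)
  fas <- lapply(1:20, function(i) {
    k <- runif(1, 0.01, 0.3)
    list(family_id = paste0("F", i), k = k, age_years = k / 2e-8)
  })
  expect_equal(age_divergence_correlation(fas), 1.0)
  expect_error(age_divergence_correlation(list(
    list(family_id = "a", k = 0.1, age_years = 5e6),
    list(family_id = "b", k = 0.1, age_years = 5e6))), "zero variance")
  two <- age_divergence_correlation(list(
    list(family_id = "a", k = 0.1, age_years = 5e6),
    list(family_id = "b", k = 0.2, age_years = 1e7)))
  expect_true(isTRUE(attr(two, "low_n")))
})

test_that("age-amplification correlation behaves at the extremes and null", {
  ages <- setNames(runif(50, 0, 14e6), paste0("e", 1:50))
  expect_equal(age_amplification_correlation(ages, 2 * ages), 1.0)
  expect_equal(age_amplification_correlation(ages, -3 * ages), -1.0)
  set.seed(27)
  cov256 <- setNames(exp(runif(256, 0, log(1000))), paste0("e", 1:256))
  ages256 <- setNames(runif(256, 0, 14.4e6), paste0("e", 1:256))
  expect_lt(abs(age_amplification_correlation(ages256, cov256)), 0.15)
  expect_error(
    age_amplification_correlation(ages, setNames(runif(3), c("x", "y", "z"))),
    "ids do not match")
})

test_that("expression classification recovers planted categories", {
  tab <- data.frame(element_id = "e1", genome = 10, flower = 5,
                    root_stem = 0)
  expect_equal(classify_expression(tab)$profiles$category, "flower_only")
  tab0 <- data.frame(element_id = "e1", genome = 10, flower = 0,
                     root_stem = 0)
  expect_equal(classify_expression(tab0)$profiles$category, "silent")

  # planted 9 silent / 7 rootstem-only / 21 flower-only among 256
  set.seed(28)
  n <- 256
  cat_truth <- c(rep("silent", 9), rep("rootstem_only", 7),
                 rep("flower_only", 21), rep("both", n - 37))
  fl <- ifelse(cat_truth %in% c("flower_only", "both"), runif(n, 1, 50), 0)
  rs <- ifelse(cat_truth %in% c("rootstem_only", "both"), runif(n, 1, 50), 0)
  tabn <- data.frame(element_id = paste0("e", 1:n),
                     genome = runif(n, 1, 100), flower = fl, root_stem = rs)
  got <- classify_expression(tabn)
  expect_equal(got$profiles$category, cat_truth)
  cc <- setNames(got$category_counts$n, got$category_counts$Var1)
  expect_equal(unname(cc[c("silent", "rootstem_only", "flower_only")]),
               c(9L, 7L, 21L))
  expect_error(classify_expression(tabn[, -3]), "lacks columns")
})
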