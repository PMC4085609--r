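test_that("canonical motifs collapse rotation/reverse-complement classes", {
  expect_equal(canonical_motif("TGG"), "ACC")
  expect_equal(canonical_motif("CCA"), "ACC")  # TGG/CCA equivalence
  expect_equal(canonical_motif("AT"), "AT")
  expect_error(canonical_motif("AA"), "primitive")
  expect_error(canonical_motif("ATAT"), "primitive")
  expect_error(canonical_motif("A"), "length")

  # exhaustive: idempotent and constant on each equivalence class
  for (m in all_primitive_motifs()) {
    cm <- canonical_motif(m)
    expect_equal(canonical_motif(cm), cm)
    rc <- rc_string(m)
    n <- nchar(m)
    rots <- vapply(seq_len(n), function(i)
      paste0(substr(m, i, n), substr(m, 1, i - 1)), "")
    rc_rots <- vapply(seq_len(n), function(i)
      paste0(substr(rc, i, n), substr(rc, 1, i - 1)), "")
    expect_true(all(vapply(c(rots, rc_rots), canonical_motif, "") == cm))
    expect_equal(cm, min(c(rots, rc_rots)))  # enumeration oracle
  }
})

test_that("SSR detection reports maximal perfect arrays with whole units", {
  loci <- find_ssrs("ATATATATATAT")
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$motif, "AT")
  expect_equal(loci$n_units, 6L)
  expect_equal(loci$end - loci$start, 12L)

  loci3 <- find_ssrs("ACGACGACGACGACG")
  expect_equal(nrow(loci3), 1L)
  expect_equal(loci3$canonical_motif, canonical_motif("ACG"))
  expect_equal(loci3$n_units, 5L)

  # partial trailing unit trimmed to whole units
  part <- find_ssrs(paste0(strrep("AT", 7), "A"))
  expect_equal(part$n_units, 7L)
  expect_equal(part$end - part$start, 14L)

  # below min_units: nothing
  expect_equal(nrow(find_ssrs(strrep("AT", 5))), 0L)

  # loci never overlap and re-validate as perfect tandems
  fix <- plant_ssr_fixture(n_loci = 30, seed = 7)
  got <- find_ssrs(fix$seq)
  got <- got[order(got$start), ]
  if (nrow(got) > 1) {
    expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
  }
  for (i in seq_len(nrow(got))) {
    sub <- substr(fix$seq, got$start[i] + 1, got$end[i])
    expect_equal(sub, strrep(got$motif[i], got$n_units[i]))
  }
})

test_that("planted perfect arrays are recovered with full recall/precision", {
  fix <- plant_ssr_fixture(n_loci = 100, seed = 31)
  got <- find_ssrs(fix$seq)
  key_truth <- paste(fix$truth$start, fix$truth$end)
  key_got <- paste(got$start, got$end)
  expect_equal(mean(key_truth %in% key_got), 1.0)  # recall
  expect_equal(mean(key_got %in% key_truth), 1.0)  # precision
  m <- merge(fix$truth, got, by = "start")
  expect_equal(unname(vapply(m$motif.x, canonical_motif, "")),
               unname(m$canonical_motif))
})

test_that("low-complexity detection finds AT-rich tracts only", {
  # a pure AT dinucleotide run is both an SSR and low-complexity
  run <- strrep("AT", 25)
  lc <- find_low_complexity(run)
  expect_equal(nrow(lc), 1L)
  expect_equal(lc$at_fraction, 1.0)
  expect_gte(nrow(find_ssrs(run)), 1L)

  # short runs fail min_len
  expect_equal(nrow(find_low_complexity(strrep("A", 29))), 0L)

  # uniform-GC random sequence has no regions at threshold 0.9
  set.seed(19)
  rnd <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
               collapse = "")
  expect_equal(nrow(find_low_complexity(rnd, 0.9, 30)), 0L)

  # every reported region satisfies its own invariant
  set.seed(20)
  mix <- paste0(random_background(500, gc = 0.4),
                paste(sample(c("A", "T", "G"), 120, replace = TRUE,
                             prob = c(0.48, 0.48, 0.04)), collapse = ""),
                random_background(500, gc = 0.4))
  regs <- find_low_complexity(mix)
  if (nrow(regs) > 0) {
    expect_true(all(regs$at_fraction >= 0.9))
    expect_true(all(regs$end - regs$start >= 30))
  }
})

test_that("SSR summaries tally canonical motifs and length classes", {
  loci <- rbind(
    find_ssrs(strrep("AT", 6)),
    find_ssrs(strrep("AT", 8)),
    find_ssrs(strrep("ACC", 5)))
  s <- ssr_summary(loci)
  at_row <- s$per_motif[s$per_motif$canonical_motif == "AT", ]
  expect_equal(at_row$n_loci, 2L)
  expect_equal(at_row$total_units, 14L)
  acc_row <- s$per_motif[s$per_motif$canonical_motif == "ACC", ]
  expect_equal(acc_row$n_loci, 1L)

  empty <- ssr_summary(find_ssrs("ACGT"))
  expect_equal(nrow(empty$per_motif), 0L)

  # planted motif spectrum recovered exactly
  fix <- plant_ssr_fixture(n_loci = 60, seed = 8)
  got <- ssr_summary(find_ssrs(fix$seq))
  want <- table(vapply(fix$truth$motif, canonical_motif, ""))
  for (cm in names(want)) {
    expect_equal(got$per_motif$n_loci[got$per_motif$canonical_motif == cm],
                 unname(as.integer(want[cm])))
  }
})
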