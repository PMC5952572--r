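test_that("reference generation is deterministic and includes the panel", {
  cfg <- small_ref_config()
  r1 <- make_references(cfg, seed = 5)
  r2 <- make_references(cfg, seed = 5)
  expect_identical(r1$host, r2$host)
  expect_identical(r1$exogenous, r2$exogenous)
  expect_identical(r1$nonhost, r2$nonhost)

  # requested panel sequences present verbatim (RNA stored as DNA)
  expect_true("ACGGACAAGAATAGGCTTCGGCT" %in% r1$panel$srna_sequence)
  expect_equal(nrow(r1$panel), 6L)

  # changing the seed changes the host genome
  r3 <- make_references(cfg, seed = 6)
  expect_false(identical(r1$host, r3$host))

  # planted sequences stay within sRNA length bounds and off the host
  planted <- c(r1$panel$srna_sequence, r1$exogenous, r1$kit_sequence)
  expect_true(all(nchar(planted) >= 15 & nchar(planted) <= 45))
  expect_false(any(vapply(c(r1$exogenous, r1$kit_sequence),
                          function(s) grepl(s, r1$host, fixed = TRUE),
                          logical(1))))
})

test_that("mock libraries contain only contaminants and spike-in", {
  refs <- make_references(small_ref_config(), seed = 9)
  meta <- library_meta("m1", "mock", volume_uL = 0,
                      spikein_name = refs$spike$name,
                      spikein_copies_per_uL = 40000)
  d <- library_design(meta, total_reads = 2000, error_rate = 0, seed = 2)
  lib <- simulate_library(d, refs)
  expect_equal(nrow(lib), 2000L)
  inserts <- sub(paste0(ADAPTER, ".*$"), "", lib$seq)
  pool <- c(refs$panel$srna_sequence, refs$spike$sequence)
  expect_true(all(inserts %in% pool))
})

test_that("contaminant relative abundance is inversely proportional to volume", {
  refs <- make_references(small_ref_config(), seed = 9)
  mk <- function(V, seed) {
    meta <- library_meta(paste0("p", V), "plasma", volume_uL = V,
                        spikein_name = refs$spike$name,
                        spikein_copies_per_uL = 40000)
    d <- library_design(meta, total_reads = 2e5, error_rate = 0, seed = seed)
    comp <- attr(simulate_library(d, refs), "composition")
    sum(comp$reads[comp$category == "contaminant"]) / sum(comp$reads)
  }
  f100 <- mk(100, 11)
  f1000 <- mk(1000, 12)
  ratio <- f100 / f1000
  # binomial sampling errors on each fraction, propagated to the ratio
  se100 <- sqrt(f100 * (1 - f100) / 2e5) / f100
  se1000 <- sqrt(f1000 * (1 - f1000) / 2e5) / f1000
  se_ratio <- ratio * sqrt(se100^2 + se1000^2)
  expect_lt(abs(ratio - 10), 3 * se_ratio + 0.15)
})

test_that("read construction appends the adapter after the insert", {
  refs <- make_references(small_ref_config(), seed = 9)
  meta <- library_meta("p1", "plasma", volume_uL = 100,
                      spikein_name = refs$spike$name,
                      spikein_copies_per_uL = 40000)
  d <- library_design(meta, total_reads = 500, error_rate = 0, seed = 3)
  lib <- simulate_library(d, refs)
  expect_true(all(nchar(lib$seq) == 75L))
  comp <- attr(lib, "composition")
  pool <- comp$seq[comp$reads > 0]
  ok <- vapply(lib$seq, function(r) {
    ins <- pool[startsWith(r, pool)][1]
    !is.na(ins) &&
      startsWith(paste0(ADAPTER, strrep("A", 75)),
                 substr(r, nchar(ins) + 1L, 75L))
  }, logical(1))
  expect_true(all(ok))
})

test_that("empty pools and determinism behave as contracted", {
  refs <- make_references(small_ref_config(), seed = 9)
  water <- library_meta("w1", "water", volume_uL = 0)
  d <- library_design(water, total_reads = 100, seed = 4)
  expect_error(simulate_library(d, refs), "empty fragment pool")
  d0 <- library_design(water, total_reads = 0, seed = 4)
  expect_equal(nrow(simulate_library(d0, refs)), 0L)

  plasma <- library_meta("p1", "plasma", volume_uL = 45,
                        spikein_name = refs$spike$name,
                        spikein_copies_per_uL = 40000)
  d1 <- library_design(plasma, total_reads = 1000, seed = 8)
  expect_identical(simulate_library(d1, refs), simulate_library(d1, refs))
})

test_that("titration designs enumerate libraries with distinct metadata", {
  refs <- make_references(small_ref_config(), seed = 9)
  base <- library_design(
    library_meta("t", "plasma", volume_uL = 100,
                 spikein_name = refs$spike$name,
                 spikein_copies_per_uL = 40000),
    total_reads = 200, seed = 1
  )
  tit <- simulate_titration(volumes = c(45, 100, 225, 500, 1115),
                            column_types = c("regular", "ultraclean"),
                            refs = refs, base_design = base, seed = 77,
                            replicates = 2L)
  expect_equal(length(tit$reads), 20L)
  expect_equal(anyDuplicated(tit$meta$library_id), 0L)
  expect_setequal(unique(tit$meta$volume_uL), c(45, 100, 225, 500, 1115))

  one <- simulate_titration(volumes = 100, column_types = "regular",
                            refs = refs, base_design = base, seed = 77,
                            replicates = 3L)
  expect_true(all(one$meta$volume_uL == 100))
})

test_that("ultra-clean columns deplete contaminants by the clean-up factor", {
  refs <- make_references(small_ref_config(), seed = 9)
  frac <- function(col, seed) {
    meta <- library_meta("m", "mock", column = col, volume_uL = 0,
                        spikein_name = refs$spike$name,
                        spikein_copies_per_uL = 40000)
    d <- library_design(meta, total_reads = 3e5, error_rate = 0, seed = seed)
    comp <- attr(simulate_library(d, refs), "composition")
    sum(comp$reads[comp$category == "contaminant"]) / sum(comp$reads)
  }
  f_reg <- frac("regular", 21)
  f_uc <- frac("ultraclean", 22)
  # the planted factor is 60; compare odds ratios because the contaminant
  # share of the regular-column pool is far from small
  odds <- (f_reg / (1 - f_reg)) / (f_uc / (1 - f_uc))
  expect_gt(odds, 60 * 0.8)
  expect_lt(odds, 60 * 1.2)
})

test_that("simulated qPCR curves space quantification cycles by log2(10)", {
  q <- simulate_qpcr(10^(1:7))
  cps <- call_cp_set(q)
  expect_true(all(cps$flag == "ok"))
  spacing <- -diff(cps$cp)
  expect_true(all(abs(spacing - log2(10)) <= 0.01))

  q0 <- simulate_qpcr(c(0, 100))
  expect_equal(q0$no_amplification, c(TRUE, FALSE))
  expect_equal(call_cp_set(q0)$flag[1], "no_amplification")

  qn1 <- simulate_qpcr(1e4, noise_sd = 0.02, seed = 5)
  qn2 <- simulate_qpcr(1e4, noise_sd = 0.02, seed = 5)
  expect_identical(qn1$fluorescence, qn2$fluorescence)
})

test_that("generated category fractions match the multinomial design", {
  refs <- make_references(small_ref_config(), seed = 13)
  meta <- library_meta("p1", "plasma", volume_uL = 100,
                      spikein_name = refs$spike$name,
                      spikein_copies_per_uL = 40000)
  for (seed in 1:5) {
    d <- library_design(meta, total_reads = 1000, error_rate = 0, seed = seed)
    comp <- attr(simulate_library(d, refs), "composition")
    p <- comp$copies / sum(comp$copies)
    by_cat <- tapply(comp$reads, comp$category, sum)
    p_cat <- tapply(comp$copies, comp$category, sum) / sum(comp$copies)
    for (cat in names(by_cat)) {
      expected <- 1000 * p_cat[cat]
      sd4 <- 4 * sqrt(1000 * p_cat[cat] * (1 - p_cat[cat]))
      expect_lt(abs(by_cat[cat] - expected), sd4 + 1)
    }
  }
})
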