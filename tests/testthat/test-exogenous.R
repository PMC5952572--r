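test_that("low-complexity flags entropy-poor and homopolymer sequences", {
  expect_true(low_complexity(strrep("A", 15)))          # entropy 0
  expect_false(low_complexity(strrep("ACGT", 4)))       # entropy 2.0 bits
  expect_true(low_complexity(paste0(strrep("A", 15), "C")))  # 15/16 homopolymer
  expect_equal(shannon_entropy(strrep("ACGT", 4)), 2.0)
  expect_equal(shannon_entropy(strrep("A", 10)), 0)
})

# a small hand-built study: 28 plasma libraries and 10 controls
cascade_fixture <- function(counts_fun) {
  n_p <- 28L; n_c <- 10L
  ids <- c(sprintf("p%02d", 1:n_p), sprintf("c%02d", 1:n_c))
  meta <- library_meta(ids,
                       c(rep("plasma", n_p), rep("mock", n_c)),
                       volume_uL = c(rep(100, n_p), rep(0, n_c)))
  counts <- counts_fun(n_p, n_c)
  ct_from_matrix(counts, meta, min_total = 1L)
}

test_that("the cascade applies its filters in order with strict thresholds", {
  seqs <- c(
    contam   = "ACGGACAAGAATAGGCTTCGGCT",  # assigned to a confirmed contaminant
    in_ctrl  = "ACACACGTGTGTACACACGTGT",   # detected in 2 of 10 controls
    cap_hit  = "TGCATGCATAGCTAGCTAGGCA",   # reaches 10 copies in one control
    weak     = "GATTACAGATTACAGATTACA",    # 3 reads in 8 libraries (not >3)
    edge     = "TTGACCGTAAGGCTAACGTGA",    # 4 reads in 8 libraries (passes)
    lowc     = "AAAAAAAAAAAAAAAAAAAAC",    # homopolymer
    hostseq  = "CCGGAACCGGTTCCAAGGTTC",    # hit on the host genome
    good     = "TCTAGGCAATGGACTACGCAT"     # survives everything
  )
  ct <- cascade_fixture(function(n_p, n_c) {
    m <- matrix(0L, nrow = length(seqs), ncol = n_p + n_c,
                dimnames = list(unname(seqs),
                                c(sprintf("p%02d", 1:n_p), sprintf("c%02d", 1:n_c))))
    m[1, 1:n_p] <- 50L                       # contaminant abundant in plasma
    m[2, 1:n_p] <- 10L; m[2, 29:30] <- 1L    # present in 2/10 controls (20%)
    m[3, 1:n_p] <- 10L; m[3, 29] <- 10L      # 10 copies in one control
    m[4, 1:8] <- 3L                          # not more than 3 reads
    m[5, 1:8] <- 4L                          # more than 3 reads in 8 > 7 libs
    m[6, 1:n_p] <- 10L
    m[7, 1:n_p] <- 10L
    m[8, 1:n_p] <- 10L
    m
  })
  host_hits <- data.frame(sequence = seqs[["hostseq"]], reference_id = "host",
                          position = 0L, strand = "+", mismatches = 0L,
                          stringsAsFactors = FALSE)
  rep <- run_cascade(ct, contaminant_set = seqs[["contam"]],
                     host_hits = host_hits)
  st <- setNames(rep$table$status, rep$table$sequence)
  expect_equal(st[[seqs[["contam"]]]], "confirmed_contaminant")
  expect_equal(st[[seqs[["in_ctrl"]]]], "control_presence")
  expect_equal(st[[seqs[["cap_hit"]]]], "control_copy_cap")
  expect_equal(st[[seqs[["weak"]]]], "low_abundance")
  expect_equal(st[[seqs[["lowc"]]]], "low_complexity")
  expect_equal(st[[seqs[["hostseq"]]]], "host_like")
  expect_equal(st[[seqs[["edge"]]]], "candidate")
  expect_equal(st[[seqs[["good"]]]], "candidate")

  # survivor sets are nested: stage counts never increase
  expect_true(all(diff(unname(rep$stage_counts)) <= 0))
})

test_that("the library threshold rescales as a fraction of the design", {
  # 14 plasma libraries: the 7-of-28 rule becomes >3.5 libraries
  ids <- c(sprintf("p%02d", 1:14), "c01", "c02")
  meta <- library_meta(ids, c(rep("plasma", 14), "mock", "mock"),
                       volume_uL = c(rep(100, 14), 0, 0))
  counts <- matrix(0L, 2, 16,
                   dimnames = list(c("TTGACCGTAAGGCTAACGTGA",
                                     "TCTAGGCAATGGACTACGCAT"), ids))
  counts[1, 1:4] <- 5L   # 4 > 3.5 libraries: passes
  counts[2, 1:3] <- 5L   # 3 < 3.5: fails
  ct <- ct_from_matrix(counts, meta, min_total = 1L)
  rep <- run_cascade(ct, contaminant_set = character(0))
  st <- setNames(rep$table$status, rep$table$sequence)
  expect_equal(st[["TTGACCGTAAGGCTAACGTGA"]], "candidate")
  expect_equal(st[["TCTAGGCAATGGACTACGCAT"]], "low_abundance")
})

test_that("candidate classification prioritizes host and excludes kit genera", {
  hits <- data.frame(
    sequence = c("s1", "s1", "s2", "s3x"),
    reference_id = c("host_chr", "plant_g", "kit_g", "plant_g"),
    position = 0L, strand = "+",
    mismatches = c(0L, 0L, 0L, 1L),
    taxon_group = c("host", "plant", "bacteria", "plant"),
    genus = c("Homo", "Arabidopsis", "Bradyrhizobium", "Arabidopsis"),
    stringsAsFactors = FALSE
  )
  out <- classify_candidates(c("s1", "s2", "s3x", "s4"), hits,
                             kit_genera = "Bradyrhizobium")
  expect_true(out$removed[out$sequence == "s1"])      # host beats plant at 0 mm
  expect_equal(out$reason[out$sequence == "s1"], "host_like")
  expect_true(out$removed[out$sequence == "s2"])      # kit genus only
  expect_equal(out$reason[out$sequence == "s2"], "kit_genus")
  expect_false(out$removed[out$sequence == "s3x"])
  expect_equal(out$best_taxon[out$sequence == "s3x"], "plant")
  expect_equal(out$best_taxon[out$sequence == "s4"], "unknown")
  expect_error(classify_candidates("s1", hits[, 1:5], "X"), "taxon_group")
})

test_that("the cascade refuses degenerate designs", {
  meta <- library_meta(c("c1", "c2"), c("mock", "mock"), volume_uL = 0)
  counts <- matrix(1L, 1, 2, dimnames = list("ACGTACGTACGTACG", c("c1", "c2")))
  ct <- ct_from_matrix(counts, meta, min_total = 1L)
  expect_error(run_cascade(ct, character(0)), "plasma")

  meta2 <- library_meta(c("p1", "p2"), c("plasma", "plasma"), volume_uL = 100)
  ct2 <- ct_from_matrix(matrix(1L, 1, 2, dimnames = list("ACGTACGTACGTACG",
                                                         c("p1", "p2"))),
                        meta2, min_total = 1L)
  expect_error(run_cascade(ct2, character(0)), "control")
})
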