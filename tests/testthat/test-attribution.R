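test_that("mapping reports exact and mismatched hits, bounded by max_mm", {
  set.seed(41)
  ref <- c(g1 = paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = ""))
  read <- substr(ref, 1001, 1022)
  h <- map_reads(read, ref)
  expect_true(any(h$position == 1000L & h$mismatches == 0L & h$strand == "+"))

  # three substitutions exceed max_mm = 2
  flip <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  r3 <- read
  substr(r3, 2, 2) <- flip(substr(r3, 2, 2))
  substr(r3, 8, 8) <- flip(substr(r3, 8, 8))
  substr(r3, 15, 15) <- flip(substr(r3, 15, 15))
  h3 <- map_reads(r3, ref)
  expect_false(any(h3$position == 1000L))

  expect_error(map_reads(read, character(0)), "empty reference")
})

test_that("mapping equals a brute-force window scan", {
  set.seed(42)
  refs <- c(gA = paste(sample(c("A", "C", "G", "T"), 8000, TRUE), collapse = ""),
            gB = paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = ""))
  reads <- c(
    substr(refs[1], 501, 525),
    revcomp(substr(refs[2], 301, 322)),
    paste(sample(c("A", "C", "G", "T"), 18, TRUE), collapse = "")
  )
  # add a planted read with one substitution
  mut <- substr(refs[1], 2001, 2024)
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(mut, 5, 5))[1]
  reads <- c(reads, mut)

  got <- map_reads(reads, refs, max_mm = 2L)
  want <- do.call(rbind, lapply(reads, bf_map, reference = refs, max_mm = 2L))
  key <- function(d) sort(with(d, paste(sequence, reference_id, position,
                                        strand, mismatches)))
  expect_equal(key(got), key(want))
})

test_that("host attribution takes priority and partitions exhaustively", {
  hits <- data.frame(sequence = c("s1", "s1"), reference_id = c("host", "bact"),
                     position = c(0L, 5L), strand = "+", mismatches = 0L,
                     stringsAsFactors = FALSE)
  part <- attribute_host(c("s1", "s2"), hits)
  expect_equal(part$host, "s1")   # maps to host AND a bacterial genome
  expect_equal(part$nonhost, "s2")
  empty <- attribute_host(character(0), hits)
  expect_equal(length(empty$host) + length(empty$nonhost), 0L)
})

test_that("decoy filter applies the length and decoy-excess criteria", {
  set.seed(43)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  long_read <- paste(sample(c("A", "C", "G", "T"), 28, TRUE), collapse = "")
  short_read <- paste(sample(c("A", "C", "G", "T"), 18, TRUE), collapse = "")
  genomes <- c(
    with_long = paste0(bg(2000), long_read, bg(2000)),
    with_short_only = paste0(bg(2000), short_read, bg(2000)),
    empty_genome = bg(4000)
  )
  kept <- decoy_filter(c(long_read, short_read), genomes, seed = 99)
  expect_true("with_long" %in% kept)
  # recruits only an 18-nt read: fails the 25-nt criterion
  expect_false("with_short_only" %in% kept)
  expect_false("empty_genome" %in% kept)

  # same genome set but with the length criterion disabled
  kept2 <- decoy_filter(c(long_read, short_read), genomes, seed = 99,
                        require_long_read = FALSE)
  expect_true("with_short_only" %in% kept2)

  # a genome built from decoy sequences recruits more decoys than reads
  seqs <- replicate(4, paste(sample(c("A", "C", "G", "T"), 26, TRUE), collapse = ""))
  decs <- shuffle_decoys(seqs, seed = 7)
  trap <- c(decoy_trap = paste0(bg(500), paste(decs, collapse = bg(50)), bg(500)),
            real_home = paste0(bg(500), seqs[1], bg(500)))
  kept3 <- decoy_filter(seqs, trap, seed = 7)
  expect_false("decoy_trap" %in% kept3)
  expect_true("real_home" %in% kept3)
})

test_that("decoy reads themselves recruit essentially no genomes", {
  set.seed(44)
  genomes <- setNames(
    replicate(4, paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")),
    paste0("g", 1:4)
  )
  reads <- replicate(10, paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = ""))
  decs <- shuffle_decoys(reads, seed = 123)
  kept <- decoy_filter(decs, genomes, seed = 124)
  expect_length(kept, 0L)
})

test_that("loci merge overlapping same-strand hits only", {
  hits <- data.frame(
    sequence = c("r1", "r2", "r3"),
    reference_id = "g1",
    position = c(100L, 110L, 105L),
    strand = c("+", "+", "-"),
    mismatches = 0L, stringsAsFactors = FALSE
  )
  # give the reads lengths via their sequences
  hits$sequence <- c(strrep("A", 20), strrep("C", 20), strrep("G", 20))
  res <- build_loci(hits, counts = setNames(c(3, 2, 5), hits$sequence))
  expect_equal(nrow(res$loci), 2L)
  plus <- res$loci[res$loci$strand == "+", ]
  expect_equal(plus$start, 100L)
  expect_equal(plus$end, 130L)   # union of [100,120) and [110,130)
  expect_equal(plus$raw_count, 5)
  minus <- res$loci[res$loci$strand == "-", ]
  expect_equal(minus$raw_count, 5)
  expect_equal(nrow(build_loci(hits[0, ])$loci), 0L)
})

test_that("cross-mapping correction reproduces hand-computed allocations", {
  # read unique to one locus keeps its count
  inc <- data.frame(sequence = "u", locus_id = "L1", stringsAsFactors = FALSE)
  expect_equal(unname(crossmap_correct(inc, c(u = 7))$corrected), 7)

  # two loci with unique counts 10 and 2 sharing a read of count 6:
  # proportional allocation gives 5 and 1, totals 15 and 3
  inc <- data.frame(
    sequence = c("u1", "u2", "s", "s"),
    locus_id = c("A", "B", "A", "B"), stringsAsFactors = FALSE
  )
  res <- crossmap_correct(inc, c(u1 = 10, u2 = 2, s = 6))
  expect_equal(res$corrected[["A"]], 15)
  expect_equal(res$corrected[["B"]], 3)
  expect_equal(sum(res$corrected), 18)

  # no unique reads anywhere: symmetric 50/50 split
  inc <- data.frame(sequence = c("s1", "s1", "s2", "s2"),
                    locus_id = c("A", "B", "A", "B"), stringsAsFactors = FALSE)
  res <- crossmap_correct(inc, c(s1 = 4, s2 = 2))
  expect_equal(unname(res$corrected), c(3, 3))
})

test_that("cross-mapping correction matches brute-force EM and conserves counts", {
  set.seed(45)
  for (rep in 1:5) {
    n_loci <- sample(3:10, 1)
    n_reads <- sample(5:15, 1)
    loci <- paste0("L", seq_len(n_loci))
    inc <- do.call(rbind, lapply(seq_len(n_reads), function(i) {
      k <- sample(1:min(3, n_loci), 1)
      data.frame(sequence = paste0("r", i),
                 locus_id = sample(loci, k), stringsAsFactors = FALSE)
    }))
    counts <- setNames(sample(1:20, n_reads, replace = TRUE),
                       paste0("r", seq_len(n_reads)))
    res <- crossmap_correct(inc, counts, tol = 1e-10, max_iter = 1000)
    want <- bf_em(inc, counts, iters = 2000)
    expect_equal(res$corrected[sort(names(res$corrected))],
                 want[sort(names(want))], tolerance = 1e-6)
    expect_equal(sum(res$corrected), sum(counts[unique(inc$sequence)]),
                 tolerance = 1e-9)
  }
})

test_that("SAM and BED exports are well-formed", {
  set.seed(46)
  ref <- c(g1 = paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""))
  read <- substr(ref, 501, 522)
  hits <- map_reads(read, ref)
  sam <- tempfile(fileext = ".sam")
  write_sam(hits, ref, sam)
  lines <- readLines(sam)
  expect_true(any(startsWith(lines, "@SQ")))
  body <- lines[!startsWith(lines, "@")]
  expect_equal(length(body), nrow(hits))
  expect_true(all(grepl("NM:i:\\d+$", body)))

  loc <- build_loci(hits)
  bed <- tempfile(fileext = ".bed")
  write_loci_bed(loc$loci, bed)
  expect_equal(length(readLines(bed)), nrow(loc$loci))
})
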