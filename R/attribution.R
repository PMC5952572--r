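## Attribution: assign collapsed reads to host vs non-host references,
## control mapping specificity with shuffled decoy reads, build loci and
## redistribute multi-mapped counts.

#' Map sequences against a reference collection
#'
#' Reports every substitution-only alignment with at most `max_mm`
#' mismatches (no indels), on both strands of every reference sequence.
#' Ordering is deterministic: by query, then reference, strand (`+`
#' before `-`) and position.
#'
#' @param sequences character vector of query sequences (collapsed reads).
#' @param reference named character vector or `DNAStringSet` of reference
#'   sequences.
#' @param max_mm maximum substitutions per hit.
#' @return data.frame with columns `sequence`, `reference_id`, `position`
#'   (0-based start on the plus strand), `strand`, `mismatches`.
#' @export
map_reads <- function(sequences, reference, max_mm = 2L) {
  if (inherits(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  if (length(reference) == 0L || all(!nzchar(reference))) {
    stop("empty reference collection")
  }
  if (is.null(names(reference))) {
    names(reference) <- sprintf("ref%d", seq_along(reference))
  }
  sequences <- unique(sequences)
  subjects <- lapply(reference, Biostrings::DNAString)
  out <- vector("list", length(sequences) * length(reference) * 2L)
  k <- 0L
  for (s in sequences) {
    pats <- list("+" = Biostrings::DNAString(s),
                 "-" = Biostrings::reverseComplement(Biostrings::DNAString(s)))
    for (ri in seq_along(subjects)) {
      if (nchar(s) > nchar(reference[ri])) next
      for (strand in c("+", "-")) {
        m <- Biostrings::matchPattern(pats[[strand]], subjects[[ri]],
                                      max.mismatch = max_mm,
                                      with.indels = FALSE, fixed = TRUE)
        if (length(m) == 0L) next
        starts <- BiocGenerics::start(m)
        mm <- Biostrings::neditAt(pats[[strand]], subjects[[ri]], at = starts,
                                  with.indels = FALSE, fixed = TRUE)
        keep <- mm <= max_mm
        if (!any(keep)) next
        k <- k + 1L
        out[[k]] <- data.frame(
          sequence = s, reference_id = names(reference)[ri],
          position = starts[keep] - 1L, strand = strand,
          mismatches = as.integer(mm[keep]), stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0L) {
    return(data.frame(sequence = character(0), reference_id = character(0),
                      position = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(match(res$sequence, sequences),
                   match(res$reference_id, names(reference)),
                   match(res$strand, c("+", "-")), res$position), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Partition sequences into host and non-host
#'
#' Host attribution takes priority: any sequence with at least one hit to
#' the host genome is attributed to the host, regardless of non-host
#' hits. The partition is exhaustive and disjoint.
#'
#' @param sequences character vector (or an `srna_count_table`, whose row
#'   names are used).
#' @param host_hits a [map_reads()] result against the host genome.
#' @return list with `host` and `nonhost` character vectors.
#' @export
attribute_host <- function(sequences, host_hits) {
  if (inherits(sequences, "srna_count_table")) {
    sequences <- rownames(sequences$counts)
  }
  is_host <- sequences %in% unique(host_hits$sequence)
  list(host = sequences[is_host], nonhost = sequences[!is_host])
}

#' Shuffle sequences into a decoy read set
#'
#' Per-read uniform permutation of nucleotides: length and mononucleotide
#' composition are preserved.
#'
#' @param sequences character vector.
#' @param seed integer seed.
#' @return character vector of shuffled sequences.
#' @export
shuffle_decoys <- function(sequences, seed) {
  set.seed(seed)
  vapply(strsplit(sequences, "", fixed = TRUE), function(ch) {
    paste(sample(ch), collapse = "")
  }, character(1L))
}

#' Decoy-based reference genome filter
#'
#' A non-host genome is retained only when (a) it recruits at least one
#' real read of at least `min_len` nt and (b) it recruits strictly more
#' real reads than shuffled decoy reads. Both criteria can be switched
#' off independently.
#'
#' @param sequences non-host sequences (collapsed reads).
#' @param genomes named character vector of candidate reference genomes.
#' @param seed seed for the decoy shuffle.
#' @param max_mm maximum mismatches for mapping.
#' @param min_len minimum real-read length for criterion (a).
#' @param require_long_read,require_decoy_excess enable criteria (a)/(b).
#' @return character vector of retained genome names, with attribute
#'   `summary`: per-genome real/decoy recruitment counts.
#' @export
decoy_filter <- function(sequences, genomes, seed, max_mm = 2L, min_len = 25L,
                         require_long_read = TRUE, require_decoy_excess = TRUE) {
  real <- map_reads(sequences, genomes, max_mm)
  decoys <- shuffle_decoys(sequences, seed)
  dec <- map_reads(decoys, genomes, max_mm)
  gnames <- names(genomes)
  n_real <- vapply(gnames, function(g) {
    length(unique(real$sequence[real$reference_id == g]))
  }, integer(1L))
  n_long <- vapply(gnames, function(g) {
    hits <- unique(real$sequence[real$reference_id == g])
    sum(nchar(hits) >= min_len)
  }, integer(1L))
  n_dec <- vapply(gnames, function(g) {
    length(unique(dec$sequence[dec$reference_id == g]))
  }, integer(1L))
  keep <- rep(TRUE, length(gnames))
  if (require_long_read) keep <- keep & n_long >= 1L
  if (require_decoy_excess) keep <- keep & n_real > n_dec
  res <- gnames[keep]
  attr(res, "summary") <- data.frame(
    genome = gnames, real_reads = n_real, long_reads = n_long,
    decoy_reads = n_dec, retained = keep, stringsAsFactors = FALSE
  )
  res
}

#' Build loci from mapping hits
#'
#' Overlapping same-strand hits on the same reference are merged into
#' maximal intervals. Raw counts sum the collapse counts of the distinct
#' reads touching each locus.
#'
#' @param hits a [map_reads()] result.
#' @param counts named numeric vector of collapse counts per sequence
#'   (default 1 per sequence).
#' @return list with `loci` (data.frame `locus_id`, `reference_id`,
#'   `start`, `end` 0-based half-open, `strand`, `raw_count`) and
#'   `incidence` (data.frame `sequence`, `locus_id`).
#' @export
build_loci <- function(hits, counts = NULL) {
  if (nrow(hits) == 0L) {
    return(list(
      loci = data.frame(locus_id = character(0), reference_id = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), raw_count = numeric(0),
                        stringsAsFactors = FALSE),
      incidence = data.frame(sequence = character(0), locus_id = character(0),
                             stringsAsFactors = FALSE)
    ))
  }
  if (is.null(counts)) {
    counts <- setNames(rep(1, length(unique(hits$sequence))),
                       unique(hits$sequence))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = hits$reference_id,
    ranges = IRanges::IRanges(start = hits$position + 1L,
                              width = nchar(hits$sequence)),
    strand = hits$strand
  )
  red <- GenomicRanges::reduce(gr, ignore.strand = FALSE)
  ov <- GenomicRanges::findOverlaps(gr, red)
  locus_of_hit <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  # substitution-only hits lie fully inside one merged interval
  inc <- unique(data.frame(
    sequence = hits$sequence,
    locus = locus_of_hit,
    stringsAsFactors = FALSE
  ))
  locus_id <- sprintf("%s:%d-%d(%s)",
                      as.character(GenomicRanges::seqnames(red)),
                      BiocGenerics::start(red) - 1L, BiocGenerics::end(red),
                      as.character(BiocGenerics::strand(red)))
  inc$locus_id <- locus_id[inc$locus]
  raw <- vapply(seq_along(red), function(i) {
    sum(counts[inc$sequence[inc$locus == i]])
  }, numeric(1L))
  loci <- data.frame(
    locus_id = locus_id,
    reference_id = as.character(GenomicRanges::seqnames(red)),
    start = BiocGenerics::start(red) - 1L,
    end = BiocGenerics::end(red),
    strand = as.character(BiocGenerics::strand(red)),
    raw_count = raw, stringsAsFactors = FALSE
  )
  list(loci = loci, incidence = inc[, c("sequence", "locus_id")])
}

#' Cross-mapping correction of multi-mapped counts
#'
#' Iterative proportional allocation: locus weights are initialized from
#' uniquely mapping reads; each multi-mapped read's collapse count is
#' then repeatedly re-allocated across its loci in proportion to the
#' current locus weights until the largest locus change falls below
#' `tol`. When none of a read's loci carry weight, its count is split
#' uniformly. Each read's allocation sums exactly to its count, so the
#' total is conserved.
#'
#' @param incidence data.frame with columns `sequence`, `locus_id`
#'   listing every (read, locus) mapping pair.
#' @param counts named numeric vector of collapse counts per sequence.
#' @param tol convergence tolerance on the largest locus-count change.
#' @param max_iter iteration cap; non-convergence returns the last
#'   iterate with `converged = FALSE`.
#' @return list with `corrected` (named numeric per locus), `converged`,
#'   `iterations`.
#' @export
crossmap_correct <- function(incidence, counts, tol = 1e-6, max_iter = 100L) {
  loci <- unique(incidence$locus_id)
  if (length(loci) == 0L) {
    return(list(corrected = setNames(numeric(0), character(0)),
                converged = TRUE, iterations = 0L))
  }
  seqs <- unique(incidence$sequence)
  missing <- setdiff(seqs, names(counts))
  if (length(missing)) stop("counts missing for sequence(s): ",
                            paste(utils::head(missing, 3L), collapse = ", "))
  loci_of <- split(incidence$locus_id, incidence$sequence)
  nl <- lengths(loci_of)
  uniq_seqs <- names(loci_of)[nl == 1L]
  multi_seqs <- names(loci_of)[nl > 1L]
  unique_counts <- setNames(rep(0, length(loci)), loci)
  if (length(uniq_seqs)) {
    u <- tapply(counts[uniq_seqs], unlist(loci_of[uniq_seqs]), sum)
    unique_counts[names(u)] <- u
  }
  total <- unique_counts
  if (length(multi_seqs) == 0L) {
    return(list(corrected = total, converged = TRUE, iterations = 0L))
  }
  weights <- unique_counts
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    alloc <- setNames(rep(0, length(loci)), loci)
    for (s in multi_seqs) {
      ls <- loci_of[[s]]
      w <- weights[ls]
      sw <- sum(w)
      share <- if (sw > 0) counts[s] * w / sw else rep(counts[s] / length(ls), length(ls))
      alloc[ls] <- alloc[ls] + share
    }
    new_total <- unique_counts + alloc
    delta <- max(abs(new_total - total))
    total <- new_total
    weights <- new_total
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("cross-mapping correction did not converge in ",
                          max_iter, " iterations")
  list(corrected = total, converged = converged, iterations = it)
}

#' Export mapping hits as minimal SAM
#'
#' @param hits a [map_reads()] result.
#' @param reference the reference collection used (for header lengths).
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(hits, reference, path) {
  if (inherits(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_along(reference)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(reference)[i],
                       nchar(reference[i])), con)
  }
  if (nrow(hits)) {
    flag <- ifelse(hits$strand == "-", 16L, 0L)
    seqout <- ifelse(hits$strand == "-", revcomp(hits$sequence), hits$sequence)
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                       hits$sequence, flag, hits$reference_id,
                       hits$position + 1L, nchar(hits$sequence), seqout,
                       hits$mismatches), con)
  }
  invisible(path)
}

#' Export loci as BED6 with corrected counts
#'
#' BED coordinates stay 0-based half-open; the score column carries the
#' raw count and a seventh column the cross-mapping-corrected count.
#'
#' @param loci `loci` data.frame from [build_loci()].
#' @param corrected optional named corrected counts from
#'   [crossmap_correct()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path, corrected = NULL) {
  cc <- if (is.null(corrected)) rep(NA_real_, nrow(loci)) else corrected[loci$locus_id]
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s\t%s",
                   loci$reference_id, loci$start, loci$end, loci$locus_id,
                   loci$raw_count, loci$strand,
                   ifelse(is.na(cc), ".", format(cc, digits = 10)))
  writeLines(lines, path)
  invisible(path)
}
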