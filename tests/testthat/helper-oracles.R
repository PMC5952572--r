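# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive and share no code with the package internals.

# all substitution-only alignments of `read` against every window of every
# reference sequence, both strands, by explicit per-position comparison
bf_map <- function(read, reference, max_mm = 2L) {
  rc1 <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  out <- list()
  for (ri in seq_along(reference)) {
    ref <- reference[[ri]]
    refc <- strsplit(ref, "")[[1]]
    L <- nchar(read)
    if (L > length(refc)) next
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else rc1(read)
      qc <- strsplit(q, "")[[1]]
      for (s in 1:(length(refc) - L + 1L)) {
        mm <- sum(refc[s:(s + L - 1L)] != qc)
        if (mm <= max_mm) {
          out[[length(out) + 1L]] <- data.frame(
            sequence = read, reference_id = names(reference)[ri],
            position = s - 1L, strand = strand, mismatches = mm,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sequence = character(0), reference_id = character(0),
                      position = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# longest common substring by dynamic programming
bf_lcs <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  best <- 0L
  prev <- integer(length(bc))
  for (i in seq_along(ac)) {
    cur <- integer(length(bc))
    for (j in seq_along(bc)) {
      if (ac[i] == bc[j]) {
        cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

# plain-loop proportional-allocation EM over explicit read records
bf_em <- function(incidence, counts, iters = 500L) {
  loci <- unique(incidence$locus_id)
  reads <- unique(incidence$sequence)
  loci_of <- lapply(reads, function(s) incidence$locus_id[incidence$sequence == s])
  names(loci_of) <- reads
  uniq <- setNames(rep(0, length(loci)), loci)
  for (s in reads) {
    if (length(loci_of[[s]]) == 1L) uniq[loci_of[[s]]] <- uniq[loci_of[[s]]] + counts[s]
  }
  total <- uniq
  for (k in seq_len(iters)) {
    alloc <- setNames(rep(0, length(loci)), loci)
    for (s in reads) {
      ls <- loci_of[[s]]
      if (length(ls) == 1L) next
      w <- total[ls]
      share <- if (sum(w) > 0) counts[s] * w / sum(w)
               else rep(counts[s] / length(ls), length(ls))
      for (j in seq_along(ls)) alloc[ls[j]] <- alloc[ls[j]] + share[j]
    }
    total <- uniq + alloc
  }
  total
}

# hand count of assay-assigned reads in a collapsed library: a read counts
# toward an assay when it shares an exact block of >= 14 nt with the primer
bf_assay_rpm <- function(collapsed, panel, drop_singletons = TRUE) {
  total <- sum(collapsed$count)
  kept <- if (drop_singletons) collapsed[collapsed$count > 1L, , drop = FALSE] else collapsed
  rpm <- numeric(nrow(panel))
  assigned <- rep(NA_integer_, nrow(kept))
  bestov <- rep(0L, nrow(kept))
  for (i in seq_len(nrow(kept))) {
    for (ai in seq_len(nrow(panel))) {
      ov <- bf_lcs(kept$seq[i], panel$primer_sequence[ai])
      if (ov >= 14L && ov > bestov[i]) { assigned[i] <- ai; bestov[i] <- ov }
    }
  }
  for (ai in seq_len(nrow(panel))) {
    rpm[ai] <- sum(kept$count[!is.na(assigned) & assigned == ai]) / total * 1e6
  }
  rpm
}
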