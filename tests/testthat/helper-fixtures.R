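# Shared fixtures built in code. Sizes are deliberately small so the
# default test run stays fast; the acceptance tests use larger instances.

ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

small_ref_config <- function(...) {
  ref_config(host_length = 20000L, n_endogenous = 40L,
             nonhost_length = 6000L, ...)
}

# deterministic read table from plain sequences (constant high quality)
reads_from_seqs <- function(seqs, qual_char = "E") {
  data.frame(id = sprintf("r%d", seq_along(seqs)), seq = seqs,
             qual = strrep(qual_char, nchar(seqs)), stringsAsFactors = FALSE)
}

# count table built directly from a counts matrix (bypasses preprocessing)
ct_from_matrix <- function(counts, meta, mode = "study", min_total = 1L) {
  if (is.null(colnames(counts))) colnames(counts) <- meta$library_id
  collapsed <- lapply(seq_len(ncol(counts)), function(j) {
    keep <- counts[, j] > 0
    data.frame(seq = rownames(counts)[keep], count = counts[keep, j],
               stringsAsFactors = FALSE)
  })
  names(collapsed) <- colnames(counts)
  build_count_table(collapsed, meta, mode = mode, min_total = min_total)
}
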