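## Contaminant identification and quantification: primer-rule matching,
## control-library flagging, spike-in normalization, external-dataset
## screening and depletion reporting.

#' Assign sequences to contaminant assays by the primer rule
#'
#' A sequence is assigned to an assay if and only if it shares an exact
#' (100% identity) alignment of at least `min_overlap` nucleotides with
#' the assay's primer; the read may extend beyond the primer. Ties are
#' broken by longest overlap, then assay order in the panel.
#'
#' @param sequences character vector (DNA or RNA alphabet).
#' @param assays a [contaminant_panel()].
#' @param min_overlap minimum exact-match block length (nt).
#' @return data.frame with columns `sequence`, `assay` (`NA` when
#'   unassigned) and `overlap` (longest exact block with that primer).
#' @export
match_contaminants <- function(sequences, assays, min_overlap = 14L) {
  stopifnot(inherits(assays, "data.frame"), nrow(assays) >= 1L)
  seqs <- rna_to_dna(sequences)
  n <- length(seqs)
  best_assay <- rep(NA_character_, n)
  best_ov <- rep(0L, n)
  for (ai in seq_len(nrow(assays))) {
    primer <- rna_to_dna(assays$primer_sequence[ai])
    lp <- nchar(primer)
    ov <- rep(0L, n)
    # the longest exact common block with a primer is a primer substring;
    # scan primer substrings longest-first and record the first hit length
    for (len in seq.int(lp, min_overlap)) {
      open <- ov == 0L
      if (!any(open)) break
      starts <- seq_len(lp - len + 1L)
      for (s in unique(substring(primer, starts, starts + len - 1L))) {
        idx <- which(open & grepl(s, seqs, fixed = TRUE))
        if (length(idx)) { ov[idx] <- len; open[idx] <- FALSE }
      }
    }
    better <- ov >= min_overlap & ov > best_ov
    best_assay[better] <- assays$name[ai]
    best_ov[better] <- ov[better]
  }
  data.frame(sequence = sequences, assay = best_assay, overlap = best_ov,
             stringsAsFactors = FALSE)
}

#' Flag contaminant sequences from extraction-control libraries
#'
#' Sequences found in the extraction controls (mock extractions, column
#' eluates, water and no-template libraries) are treated as artefacts: a
#' sequence is flagged when it is detected at `min_copies` or more in
#' more than `presence_frac` of the control libraries. The spike-in is
#' excluded from flagging. The pipeline requires at least one control
#' library; running without extraction controls is an error.
#'
#' @param ct an `srna_count_table`.
#' @param presence_frac control-library presence fraction above which a
#'   sequence is flagged.
#' @param min_copies detection threshold per control library.
#' @param spike spike-in specification to exclude (or `NULL`).
#' @return character vector of flagged contaminant sequences.
#' @export
flag_control_sequences <- function(ct, presence_frac = 0.5, min_copies = 1,
                                   spike = spikein_spec()) {
  stopifnot(inherits(ct, "srna_count_table"))
  is_ctrl <- is_control_type(ct$meta$type)
  if (!any(is_ctrl)) {
    stop("no control libraries in the count table; extraction controls ",
         "must be sequenced alongside the study samples")
  }
  ctrl <- ct$counts[, is_ctrl, drop = FALSE]
  frac <- rowSums(ctrl >= min_copies) / ncol(ctrl)
  flagged <- rownames(ctrl)[frac > presence_frac]
  if (!is.null(spike)) flagged <- setdiff(flagged, spike$sequence)
  flagged
}

#' Spike-in normalization to absolute copy numbers
#'
#' Converts counts to absolute copies per microlitre of eluate by
#' normalizing to the spike-in: `copies(seq) = count(seq) / count(spike)
#' * copies_per_uL_eluate`. Libraries in which the spike-in is not
#' detected cannot be normalized and are flagged rather than silently
#' zeroed.
#'
#' @param ct an `srna_count_table`.
#' @param spike a [spikein_spec()].
#' @return list with `copies` (matrix, sequences x normalizable
#'   libraries; copies per uL eluate) and `flagged` (library ids lacking
#'   the spike-in).
#' @export
spikein_normalize <- function(ct, spike = spikein_spec()) {
  stopifnot(inherits(ct, "srna_count_table"))
  if (!spike$sequence %in% rownames(ct$counts)) {
    stop("spike-in sequence not present in the count table")
  }
  spike_counts <- ct$counts[spike$sequence, ]
  ok <- spike_counts > 0
  copies <- sweep(ct$counts[, ok, drop = FALSE], 2L, spike_counts[ok], "/") *
    spike$copies_per_uL_eluate
  list(copies = copies, flagged = colnames(ct$counts)[!ok])
}

#' Screen a sequencing dataset for known contaminant assays
#'
#' Applies public-mode preprocessing (adapter trimming, 5' N clipping,
#' quality filtering, collapsing, singleton removal) and reports reads
#' per million retained reads for each assay, using the primer-based
#' assignment rule.
#'
#' @param fastq FASTQ path, read table, or an already-collapsed
#'   data.frame with columns `seq`, `count`.
#' @param assays a [contaminant_panel()].
#' @param adapters 3' adapter sequences for trimming.
#' @param min_overlap primer-rule overlap (nt).
#' @param drop_singletons remove singleton sequences (public-data mode).
#' @return data.frame with columns `assay`, `reads`, `rpm`; attribute
#'   `retained_reads` carries the library size used.
#' @export
screen_dataset <- function(fastq, assays = contaminant_panel(),
                           adapters = "TGGAATTCTCGGGTGCCAAGG",
                           min_overlap = 14L, drop_singletons = TRUE) {
  if (is.character(fastq) && length(fastq) == 1L) {
    if (!file.exists(fastq)) stop("unreadable FASTQ: ", fastq)
    fastq <- read_fastq(fastq)
  }
  collapsed <- if (is.data.frame(fastq) && all(c("seq", "count") %in% names(fastq))) {
    fastq
  } else {
    preprocess_library(fastq, adapters)
  }
  total <- sum(collapsed$count)
  if (drop_singletons) collapsed <- collapsed[collapsed$count > 1L, , drop = FALSE]
  asg <- match_contaminants(collapsed$seq, assays, min_overlap)
  reads <- vapply(assays$name, function(a) {
    sum(collapsed$count[!is.na(asg$assay) & asg$assay == a])
  }, numeric(1L))
  rpm <- if (total > 0) reads / total * 1e6 else rep(NA_real_, length(reads))
  out <- data.frame(assay = assays$name, reads = reads, rpm = rpm,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "retained_reads") <- total
  out
}

#' Depletion report for a contaminant-removal treatment
#'
#' Compares paired absolute copy estimates with and without a column
#' treatment (e.g. bleach, water washes, NaOH) and aggregates fold change
#' and percent reduction as mean +/- SD across assays/replicates.
#'
#' @param copies_treated,copies_untreated numeric vectors of paired
#'   absolute copy estimates.
#' @return list with per-pair `fold_change` and `percent_reduction`, and
#'   aggregate `mean_fold`, `mean_reduction`, `sd_reduction`. Pairs with
#'   `treated = 0` yield infinite fold change (flagged); pairs with
#'   `untreated = 0` are undefined and flagged.
#' @export
depletion_report <- function(copies_treated, copies_untreated) {
  stopifnot(length(copies_treated) == length(copies_untreated))
  undefined <- copies_untreated == 0
  fold <- ifelse(undefined, NA_real_, copies_untreated / copies_treated)
  red <- ifelse(undefined, NA_real_, (1 - copies_treated / copies_untreated) * 100)
  list(
    fold_change = fold,
    percent_reduction = red,
    infinite_fold = !undefined & copies_treated == 0,
    undefined = undefined,
    mean_fold = mean(fold[is.finite(fold)]),
    mean_reduction = mean(red, na.rm = TRUE),
    sd_reduction = stats::sd(red, na.rm = TRUE)
  )
}
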