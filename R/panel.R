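#' Load a contaminant assay panel
#'
#' An assay panel describes named contaminant small RNAs together with the
#' qPCR forward primer used to detect them and the assay annealing
#' temperature. The package ships the six confirmed extraction-column
#' contaminants (`contaminant_panel()` with no arguments); user panels are
#' read from a TSV with columns `name`, `srna_sequence`, `primer_sequence`
#' and `annealing_temp_C`.
#'
#' All sequences are canonicalized to the DNA alphabet at load, and the
#' panel is checked for self-consistency: every primer must match its own
#' sRNA sequence under the assignment rule (an exact shared block of at
#' least `min_overlap` nucleotides; see [match_contaminants()]).
#'
#' @param path TSV file; default is the packaged six-assay panel.
#' @param min_overlap minimum exact overlap (nt) for the self-consistency
#'   check; the default mirrors the matching rule's 14-nt alignment length.
#' @return a `contaminant_panel` data frame.
#' @export
contaminant_panel <- function(path = NULL, min_overlap = 14L) {
  if (is.null(path)) {
    path <- system.file("extdata", "contaminant_panel.tsv",
                        package = "srnaclean", mustWork = TRUE)
  }
  panel <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("name", "srna_sequence", "primer_sequence", "annealing_temp_C")
  missing <- setdiff(required, names(panel))
  if (length(missing)) {
    stop("assay panel lacks column(s): ", paste(missing, collapse = ", "))
  }
  panel$srna_sequence <- rna_to_dna(panel$srna_sequence)
  panel$primer_sequence <- rna_to_dna(panel$primer_sequence)
  ok <- mapply(function(s, p) {
    longest_common_substring(s, p) >= min_overlap
  }, panel$srna_sequence, panel$primer_sequence)
  if (!all(ok)) {
    stop("assay(s) fail primer/sRNA self-consistency: ",
         paste(panel$name[!ok], collapse = ", "))
  }
  class(panel) <- c("contaminant_panel", "data.frame")
  panel
}

#' Spike-in specification
#'
#' Describes the synthetic RNA added during library preparation to enable
#' absolute quantification. The default is the hsa-miR-486-5p spike-in at
#' 40,000 copies per microlitre of column eluate.
#'
#' @param name spike-in name.
#' @param sequence spike-in sequence (RNA or DNA alphabet).
#' @param copies_per_uL_eluate known concentration in the eluate.
#' @return a `spikein_spec` list.
#' @export
spikein_spec <- function(name = "hsa-miR-486-5p",
                         sequence = "UCCUGUACUGAGCUGCCCCGAG",
                         copies_per_uL_eluate = 40000) {
  stopifnot(copies_per_uL_eluate > 0)
  structure(
    list(name = name,
         sequence = rna_to_dna(sequence),
         copies_per_uL_eluate = copies_per_uL_eluate),
    class = "spikein_spec"
  )
}

#' @export
print.spikein_spec <- function(x, ...) {
  cat("Spike-in:", x$name, "(", x$sequence, ")",
      "at", x$copies_per_uL_eluate, "copies/uL eluate\n")
  invisible(x)
}
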