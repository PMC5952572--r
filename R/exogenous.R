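## Exogenous-candidate cascade: ordered multi-criteria filtering of
## non-host sequences from plasma libraries, designed for low-biomass
## data where reagent contamination dominates the non-host fraction.

#' Cascade parameters
#'
#' Defaults reproduce the printed filtering rule for a 28-library plasma
#' titration: a candidate must be non-identical to any sequence assigned
#' to the confirmed contaminants, absent from at least 90% of the
#' controls, never reach 10 copies in any control, and be detected by
#' more than 3 reads in more than 7 of the 28 plasma libraries. The
#' 7-of-28 library rule rescales as a fraction (0.25) when the plasma
#' library count differs from `library_total`.
#'
#' @param control_absence_frac minimum fraction of controls from which a
#'   candidate must be absent.
#' @param control_copy_cap copy number in any single control at or above
#'   which a sequence is dropped.
#' @param min_reads per-library read threshold (strictly greater-than).
#' @param min_libraries plasma-library threshold (strictly greater-than).
#' @param library_total plasma library count the `min_libraries`
#'   threshold refers to.
#' @param complexity_threshold minimum Shannon entropy (bits/symbol).
#' @param kit_genera genera treated as known sequencing-kit contaminants.
#' @return a `cascade_params` list.
#' @export
cascade_params <- function(control_absence_frac = 0.90,
                           control_copy_cap = 10,
                           min_reads = 3L,
                           min_libraries = 7L,
                           library_total = 28L,
                           complexity_threshold = 1.5,
                           kit_genera = c("Bradyrhizobium", "Ralstonia",
                                          "Burkholderia", "Propionibacterium",
                                          "Methylobacterium", "Acinetobacter",
                                          "Pseudomonas", "Stenotrophomonas",
                                          "Herbaspirillum")) {
  stopifnot(control_absence_frac > 0, control_absence_frac <= 1,
            control_copy_cap > 0, min_reads > 0, min_libraries > 0,
            library_total > 0)
  structure(as.list(environment()), class = "cascade_params")
}

#' Low-complexity flag
#'
#' A sequence is low-complexity when its mononucleotide Shannon entropy
#' falls below `threshold` bits or its longest homopolymer spans at
#' least two thirds of its length.
#'
#' @param sequence character vector of sequences.
#' @param threshold entropy threshold (bits per symbol).
#' @return logical vector.
#' @export
low_complexity <- function(sequence, threshold = 1.5) {
  vapply(sequence, function(s) {
    shannon_entropy(s) < threshold ||
      longest_homopolymer(s) * 3L >= 2L * nchar(s)
  }, logical(1L), USE.NAMES = FALSE)
}

#' Classify candidate sequences by best reference hit
#'
#' The best hit has the fewest mismatches, ties broken by longest
#' overlap, then reference order; ties toward removal are conservative.
#' Candidates whose best hit is host or vertebrate are removed as
#' potentially host-derived; candidates whose best hit belongs to a
#' known kit-contaminant genus are removed as reagent artefacts. The
#' remainder are labelled with the best-hit taxon, or `"unknown"` when
#' nothing matches.
#'
#' @param candidates character vector of candidate sequences.
#' @param reference_hits [map_reads()]-style hits against a taxon-labelled
#'   reference collection, with additional columns `taxon_group` (one of
#'   `host`, `vertebrate`, `bacteria`, `fungi`, `plant`, ...) and `genus`.
#' @param kit_genera genera treated as kit contaminants.
#' @return data.frame with columns `sequence`, `best_taxon`, `best_genus`,
#'   `removed`, `reason` (`host_like`, `kit_genus` or `NA`).
#' @export
classify_candidates <- function(candidates, reference_hits, kit_genera) {
  if (!all(c("taxon_group", "genus") %in% names(reference_hits))) {
    stop("reference hits must carry 'taxon_group' and 'genus' labels")
  }
  out <- data.frame(sequence = candidates, best_taxon = "unknown",
                    best_genus = NA_character_, removed = FALSE,
                    reason = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(candidates)) {
    h <- reference_hits[reference_hits$sequence == candidates[i], , drop = FALSE]
    if (nrow(h) == 0L) next
    ov <- nchar(h$sequence)
    # host/vertebrate outrank other taxa on equal alignment quality
    prio <- ifelse(h$taxon_group %in% c("host", "vertebrate"), 0L,
                   ifelse(h$genus %in% kit_genera, 1L, 2L))
    o <- order(h$mismatches, -ov, prio)
    best <- h[o[1L], ]
    out$best_taxon[i] <- best$taxon_group
    out$best_genus[i] <- best$genus
    if (best$taxon_group %in% c("host", "vertebrate")) {
      out$removed[i] <- TRUE; out$reason[i] <- "host_like"
    } else if (best$genus %in% kit_genera) {
      out$removed[i] <- TRUE; out$reason[i] <- "kit_genus"
    }
  }
  out
}

#' Run the exogenous-candidate cascade
#'
#' Applies the ordered filters to every sequence of a study count table:
#' (1) drop sequences assigned to the confirmed contaminants; (2) drop
#' sequences detected in more than `1 - control_absence_frac` of the
#' control libraries; (3) drop sequences reaching `control_copy_cap`
#' copies in any control; (4) keep only sequences with more than
#' `min_reads` reads in more than `min_libraries` (rescaled) of the
#' plasma libraries; (5) drop low-complexity sequences; (6) drop
#' sequences with any host hit; (7) drop sequences whose best reference
#' hit is host/vertebrate or a kit-contaminant genus. Survivors are the
#' exogenous candidates; survivor sets are nested by construction.
#'
#' @param ct an `srna_count_table` containing plasma and control
#'   libraries.
#' @param contaminant_set sequences assigned to confirmed contaminants
#'   (e.g. union of [match_contaminants()] assignments and
#'   [flag_control_sequences()] flags).
#' @param params a [cascade_params()].
#' @param host_hits [map_reads()] result against the host genome (or
#'   `NULL` to skip stage 6).
#' @param reference_hits taxon-labelled hits for stage 7 (or `NULL` to
#'   skip; surviving candidates are then labelled `unclassified`).
#' @param spike spike-in spec; the spike-in sequence is not a candidate.
#' @return a `cascade_report`: list with `table` (per-sequence stage
#'   outcome), `stage_counts` (survivors after each stage), `candidates`
#'   (surviving sequences with taxon labels).
#' @export
run_cascade <- function(ct, contaminant_set, params = cascade_params(),
                        host_hits = NULL, reference_hits = NULL,
                        spike = spikein_spec()) {
  stopifnot(inherits(ct, "srna_count_table"), inherits(params, "cascade_params"))
  is_ctrl <- is_control_type(ct$meta$type)
  is_plasma <- ct$meta$type == "plasma"
  if (!any(is_plasma)) stop("cascade requires at least one plasma library")
  if (!any(is_ctrl)) {
    stop("cascade requires control libraries; extraction controls must be ",
         "sequenced alongside the study samples")
  }
  seqs <- rownames(ct$counts)
  ctrl <- ct$counts[, is_ctrl, drop = FALSE]
  plasma <- ct$counts[, is_plasma, drop = FALSE]
  n_plasma <- ncol(plasma)
  lib_threshold <- params$min_libraries / params$library_total * n_plasma

  status <- rep("candidate", length(seqs))
  alive <- rep(TRUE, length(seqs))
  if (!is.null(spike)) {
    drop <- alive & seqs == spike$sequence
    status[drop] <- "spike_in"; alive[drop] <- FALSE
  }
  stage_counts <- c(input = sum(alive))

  drop <- alive & seqs %in% contaminant_set
  status[drop] <- "confirmed_contaminant"; alive[drop] <- FALSE
  stage_counts["confirmed_contaminant"] <- sum(alive)

  # small epsilon guards the strict comparisons against floating-point
  # representation of the fraction thresholds (e.g. 1 - 0.9)
  eps <- 1e-9
  ctrl_frac <- rowSums(ctrl >= 1) / ncol(ctrl)
  drop <- alive & ctrl_frac > (1 - params$control_absence_frac) + eps
  status[drop] <- "control_presence"; alive[drop] <- FALSE
  stage_counts["control_presence"] <- sum(alive)

  drop <- alive & apply(ctrl, 1L, max) >= params$control_copy_cap
  status[drop] <- "control_copy_cap"; alive[drop] <- FALSE
  stage_counts["control_copy_cap"] <- sum(alive)

  n_detect <- rowSums(plasma > params$min_reads)
  drop <- alive & !(n_detect > lib_threshold + eps)
  status[drop] <- "low_abundance"; alive[drop] <- FALSE
  stage_counts["low_abundance"] <- sum(alive)

  if (any(alive)) {
    lc <- rep(FALSE, length(seqs))
    lc[alive] <- low_complexity(seqs[alive], params$complexity_threshold)
    drop <- alive & lc
    status[drop] <- "low_complexity"; alive[drop] <- FALSE
  }
  stage_counts["low_complexity"] <- sum(alive)

  if (!is.null(host_hits)) {
    drop <- alive & seqs %in% unique(host_hits$sequence)
    status[drop] <- "host_like"; alive[drop] <- FALSE
  }
  stage_counts["host_like"] <- sum(alive)

  taxon <- rep(NA_character_, length(seqs))
  if (!is.null(reference_hits) && any(alive)) {
    cls <- classify_candidates(seqs[alive], reference_hits, params$kit_genera)
    taxon[alive] <- cls$best_taxon
    idx <- which(alive)
    rm_host <- idx[cls$removed & cls$reason == "host_like"]
    status[rm_host] <- "host_like"; alive[rm_host] <- FALSE
    rm_kit <- idx[cls$removed & cls$reason == "kit_genus"]
    status[rm_kit] <- "kit_genus"; alive[rm_kit] <- FALSE
  } else if (any(alive)) {
    taxon[alive] <- "unclassified"
  }
  stage_counts["kit_genus"] <- sum(alive)
  stage_counts["candidate"] <- sum(alive)

  tab <- data.frame(sequence = seqs, status = status,
                    best_hit_taxon = taxon, stringsAsFactors = FALSE)
  structure(
    list(table = tab, stage_counts = stage_counts,
         candidates = tab[tab$status == "candidate", , drop = FALSE],
         params = params, n_plasma = n_plasma, n_controls = ncol(ctrl)),
    class = "cascade_report"
  )
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Exogenous-candidate cascade:", x$n_plasma, "plasma /",
      x$n_controls, "control libraries\n")
  cat("Survivors per stage:\n")
  print(x$stage_counts)
  invisible(x)
}

#' Write a cascade report to TSV/JSON
#'
#' @param report a `cascade_report`.
#' @param tsv_path per-sequence outcome TSV path (or `NULL`).
#' @param json_path stage-survivor-count JSON path (or `NULL`).
#' @return the report, invisibly.
#' @export
write_cascade_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    write.table(report$table, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(report$stage_counts), json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
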