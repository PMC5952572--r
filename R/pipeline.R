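## End-to-end orchestration. A single configuration (list or YAML file)
## drives all modules; every run writes its resolved configuration next
## to the outputs for reproducibility. Outputs are deterministic given
## the master seed.

default_config <- function() {
  list(
    mode = "analyze",
    seed = 1L,
    out_dir = "srnaclean_out",
    # inputs (analyze/screen/titrate)
    fastq_dir = NULL,
    metadata = NULL,
    host_fasta = NULL,
    nonhost_fasta = NULL,
    nonhost_taxa = NULL,
    assay_panel = NULL,          # NULL = packaged six-assay panel
    # preprocessing
    adapters = "TGGAATTCTCGGGTGCCAAGG",
    min_overlap = 10L, max_mismatch = 1L, min_len = 15L,
    q_min = 30L, p_min = 90,
    table_mode = "study",
    # contaminants / cascade
    primer_overlap = 14L,
    presence_frac = 0.5,
    spikein_name = "hsa-miR-486-5p",
    spikein_sequence = "UCCUGUACUGAGCUGCCCCGAG",
    spikein_copies_per_uL = 40000,
    control_absence_frac = 0.90,
    control_copy_cap = 10,
    min_reads = 3L, min_libraries = 7L, library_total = 28L,
    # mapping
    max_mm = 2L,
    # titration
    threshold_cpm = 100,
    # simulate
    reads_per_library = 1e6,
    sim = list()                 # extra library_design()/simulate_dataset() args
  )
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(default_config(), config)
  cfg$mode <- match.arg(cfg$mode,
                        c("simulate", "analyze", "screen", "qpcr", "titrate"))
  cfg
}

.log_line <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  message(msg)
}

.spike_from_config <- function(cfg) {
  spikein_spec(cfg$spikein_name, cfg$spikein_sequence, cfg$spikein_copies_per_uL)
}

.read_libraries <- function(cfg) {
  meta <- read.delim(cfg$metadata, stringsAsFactors = FALSE)
  class(meta) <- c("library_meta", "data.frame")
  collapsed <- list()
  for (id in meta$library_id) {
    fq <- file.path(cfg$fastq_dir, paste0(id, ".fastq"))
    if (!file.exists(fq)) fq <- paste0(fq, ".gz")
    if (!file.exists(fq)) {
      # empty control libraries (e.g. water) may legitimately have no reads
      collapsed[[id]] <- data.frame(seq = character(0), count = integer(0),
                                    stringsAsFactors = FALSE)
      next
    }
    collapsed[[id]] <- preprocess_library(fq, cfg$adapters, cfg$min_overlap,
                                          cfg$max_mismatch, cfg$min_len,
                                          cfg$q_min, cfg$p_min)
  }
  list(meta = meta, collapsed = collapsed)
}

#' Run the pipeline
#'
#' Modes: `simulate` writes a synthetic dataset (FASTQ, references,
#' metadata); `analyze` runs preprocessing, contaminant flagging,
#' spike-in normalization and the exogenous-candidate cascade on a
#' directory of FASTQ libraries with metadata; `screen` reports per-assay
#' rpm for arbitrary FASTQ files (public-data mode); `qpcr` calls Cq
#' values and fits/applies a standard curve; `titrate` determines the
#' minimal safe input volume from an analyzed titration series.
#' `analyze` refuses to run without extraction-control libraries:
#' extraction controls should always be sequenced with the study samples.
#'
#' @param config configuration list or YAML path; see the package
#'   vignette for the full set of keys. Defaults equal the study values
#'   (q30/p90 quality rule, 30-count retention, 14-nt primer overlap,
#'   90% control absence / 10-copy cap / 3-read / 7-of-28 cascade,
#'   100-cpm titration threshold, 40,000 copies/uL spike-in).
#' @return an invisible list of the run's main results (mode-dependent);
#'   outputs and a run log are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "resolved_config.yaml"))
  logcon <- file(file.path(cfg$out_dir, "run_log.txt"), "w")
  on.exit(close(logcon))
  .log_line(logcon, "srnaclean run: mode=", cfg$mode, " seed=", cfg$seed)

  res <- switch(
    cfg$mode,
    simulate = {
      refs <- make_references(ref_config(spike = .spike_from_config(cfg)),
                              seed = cfg$seed)
      sim <- do.call(simulate_dataset,
                     c(list(refs = refs, seed = cfg$seed,
                            reads_per_library = cfg$reads_per_library),
                       cfg$sim))
      write_dataset(sim, refs, cfg$out_dir)
      .log_line(logcon, "wrote ", length(sim$reads), " libraries to ", cfg$out_dir)
      list(refs = refs, meta = sim$meta)
    },
    analyze = {
      if (is.null(cfg$fastq_dir) || is.null(cfg$metadata)) {
        stop("analyze mode requires 'fastq_dir' and 'metadata'")
      }
      libs <- .read_libraries(cfg)
      if (!any(is_control_type(libs$meta$type))) {
        stop("no extraction-control libraries in metadata; extraction ",
             "controls should always be sequenced with the study samples")
      }
      ct <- build_count_table(libs$collapsed, libs$meta, mode = cfg$table_mode)
      .log_line(logcon, "count table: ", nrow(ct$counts), " sequences x ",
                ncol(ct$counts), " libraries")
      .log_line(logcon, "library sizes: ",
                paste(ct$library_sizes, collapse = ","))
      panel <- contaminant_panel(cfg$assay_panel)
      spike <- .spike_from_config(cfg)
      flagged <- flag_control_sequences(ct, cfg$presence_frac, spike = spike)
      asg <- match_contaminants(rownames(ct$counts), panel, cfg$primer_overlap)
      assigned <- asg$sequence[!is.na(asg$assay)]
      contaminant_set <- union(flagged, assigned)
      host_hits <- NULL
      if (!is.null(cfg$host_fasta)) {
        host <- Biostrings::readDNAStringSet(cfg$host_fasta)
        host_hits <- map_reads(rownames(ct$counts), host, cfg$max_mm)
      }
      ref_hits <- NULL
      if (!is.null(cfg$nonhost_fasta) && !is.null(cfg$nonhost_taxa)) {
        nh <- Biostrings::readDNAStringSet(cfg$nonhost_fasta)
        taxa <- read.delim(cfg$nonhost_taxa, stringsAsFactors = FALSE)
        ref_hits <- map_reads(rownames(ct$counts), nh, cfg$max_mm)
        ref_hits$taxon_group <- taxa$taxon_group[match(ref_hits$reference_id, taxa$name)]
        ref_hits$genus <- taxa$genus[match(ref_hits$reference_id, taxa$name)]
      }
      params <- cascade_params(cfg$control_absence_frac, cfg$control_copy_cap,
                               cfg$min_reads, cfg$min_libraries,
                               cfg$library_total)
      report <- run_cascade(ct, contaminant_set, params, host_hits, ref_hits,
                            spike = spike)
      norm <- if (spike$sequence %in% rownames(ct$counts)) {
        spikein_normalize(ct, spike)
      } else NULL
      write_count_table(ct, file.path(cfg$out_dir, "count_table.tsv"))
      writeLines(sort(contaminant_set),
                 file.path(cfg$out_dir, "contaminant_sequences.txt"))
      write_cascade_report(report,
                           file.path(cfg$out_dir, "cascade_report.tsv"),
                           file.path(cfg$out_dir, "cascade_summary.json"))
      if (!is.null(norm)) {
        df <- data.frame(sequence = rownames(norm$copies), norm$copies,
                         check.names = FALSE)
        write.table(df, file.path(cfg$out_dir, "copies_per_uL.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      .log_line(logcon, "flagged ", length(flagged),
                " control-derived sequences; ", nrow(report$candidates),
                " exogenous candidates")
      .log_line(logcon, "cascade survivors: ",
                paste(names(report$stage_counts), report$stage_counts,
                      sep = "=", collapse = " "))
      list(count_table = ct, contaminant_set = contaminant_set,
           cascade = report, normalized = norm)
    },
    screen = {
      if (is.null(cfg$fastq_dir)) stop("screen mode requires 'fastq_dir'")
      files <- list.files(cfg$fastq_dir, pattern = "\\.fastq(\\.gz)?$",
                          full.names = TRUE)
      if (!length(files)) stop("no FASTQ files under ", cfg$fastq_dir)
      panel <- contaminant_panel(cfg$assay_panel)
      tabs <- lapply(files, function(f) {
        r <- screen_dataset(f, panel, cfg$adapters, cfg$primer_overlap)
        data.frame(library = sub("\\.fastq(\\.gz)?$", "", basename(f)),
                   r, stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, tabs)
      write.table(tab, file.path(cfg$out_dir, "screen_rpm.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      .log_line(logcon, "screened ", length(files), " libraries")
      tab
    },
    qpcr = {
      if (is.null(cfg$curves_csv)) stop("qpcr mode requires 'curves_csv'")
      curves <- utils::read.csv(cfg$curves_csv, check.names = FALSE)
      cyc <- curves[[1L]]
      fl <- as.matrix(curves[, -1L, drop = FALSE])
      cps <- call_cp_set(fl)
      cps$true_copies <- NULL
      if (!is.null(cfg$standards)) {
        std <- cfg$standards  # named list: reaction -> known copies
        idx <- match(names(std), cps$reaction)
        curve <- fit_standard_curve(unlist(std), cps$cp[idx])
        cps$copies <- quantify_copies(cps$cp, curve)
        .log_line(logcon, sprintf("standard curve: m=%.4f b=%.4f E=%.1f%%",
                                  curve$m, curve$b, curve$efficiency * 100))
      } else curve <- NULL
      write.table(cps, file.path(cfg$out_dir, "cq_calls.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(cq = cps, curve = curve)
    },
    titrate = {
      if (is.null(cfg$fastq_dir) || is.null(cfg$metadata)) {
        stop("titrate mode requires 'fastq_dir' and 'metadata'")
      }
      libs <- .read_libraries(cfg)
      plasma <- libs$meta$library_id[libs$meta$type == "plasma"]
      collapsed <- libs$collapsed[plasma]
      panel <- contaminant_panel(cfg$assay_panel)
      rpm <- vapply(collapsed, function(x) {
        screen_dataset(x, panel, drop_singletons = FALSE)$rpm
      }, numeric(nrow(panel)))
      rownames(rpm) <- panel$name
      sizes <- vapply(collapsed, function(x) sum(x$count), numeric(1L))
      vols <- libs$meta$volume_uL[match(plasma, libs$meta$library_id)]
      fit <- safe_input_volume(rpm, vols, sizes, cfg$threshold_cpm)
      jsonlite::write_json(
        list(per_assay = fit$per_assay,
             overall_safe_volume = fit$overall_safe_volume,
             overall_safe_volume_tested = fit$overall_safe_volume_tested,
             threshold_cpm = fit$threshold_cpm),
        file.path(cfg$out_dir, "titration_fit.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows"
      )
      .log_line(logcon, "overall safe volume (fit): ",
                round(fit$overall_safe_volume, 1), " uL")
      fit
    }
  )
  invisible(res)
}
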