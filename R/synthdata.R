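## Synthetic data: reference sets, sequencing libraries and qPCR curves
## with the statistical structure the downstream analysis assumes.
##
## The composition model is copy-number based: sample-borne RNA scales
## with the plasma input volume V (copies per uL), while column-borne
## contaminants contribute a fixed number of copies per extraction
## column. Relative contaminant abundance in a library is therefore
## inversely proportional to V whenever the sample-borne pool dominates —
## the inverse-volume law is emergent, not hard-coded.

#' Reference-set configuration
#'
#' @param host_length host genome length (bp).
#' @param n_endogenous number of host sRNA loci planted in the host genome.
#' @param endogenous_lengths candidate host sRNA lengths (nt).
#' @param include_panel include the packaged six-assay contaminant panel.
#' @param n_exogenous number of planted non-host (exogenous) sRNAs.
#' @param exogenous_lengths candidate exogenous sRNA lengths (nt).
#' @param include_kit_sequence plant one sRNA carried only by a genome of
#'   a known sequencing-kit contaminant genus (exercises the kit-genus
#'   exclusion).
#' @param nonhost_length length of each synthetic non-host genome (bp).
#' @param spike spike-in specification, see [spikein_spec()].
#' @return a `ref_config` list.
#' @export
ref_config <- function(host_length = 50000L, n_endogenous = 60L,
                       endogenous_lengths = 18:24, include_panel = TRUE,
                       n_exogenous = 5L, exogenous_lengths = 20:22,
                       include_kit_sequence = TRUE, nonhost_length = 10000L,
                       spike = spikein_spec()) {
  structure(as.list(environment()), class = "ref_config")
}

# planted sequences must be 15-45 nt and reasonably complex
.draw_panel_seq <- function(lengths, host, avoid, primers, n_try = 200L) {
  for (i in seq_len(n_try)) {
    s <- random_dna(1L, sample(lengths, 1L))
    if (shannon_entropy(s) < 1.6) next
    if (s %in% avoid) next
    if (any(grepl(s, host, fixed = TRUE)) ||
        any(grepl(revcomp(s), host, fixed = TRUE))) next
    if (length(primers) &&
        any(vapply(primers, function(p) longest_common_substring(s, p) >= 14L,
                   logical(1L)))) next
    return(s)
  }
  stop("could not draw a planted sequence distinct from the host genome")
}

.embed <- function(genome, seqs) {
  for (s in seqs) {
    pos <- sample.int(nchar(genome) - nchar(s), 1L)
    substr(genome, pos, pos + nchar(s) - 1L) <- s
  }
  genome
}

#' Generate a synthetic reference set
#'
#' Builds a host genome with planted host sRNA loci, a contaminant panel
#' (the packaged six confirmed column contaminants by default), a planted
#' exogenous panel, a spike-in, and a collection of taxon-labelled
#' non-host genomes embedding the contaminant and exogenous sequences.
#' Generation is deterministic for a fixed `(config, seed)`; a planted
#' panel sequence colliding with the host genome at exact-match level
#' triggers regeneration of the host and finally a hard error.
#'
#' @param config a [ref_config()].
#' @param seed integer seed (mandatory).
#' @return a `reference_set` list: `host` (named character), `host_loci`
#'   (data.frame `seq`, `weight`), `panel` (contaminant panel),
#'   `exogenous` (named character), `kit_sequence`, `spike`, `nonhost`
#'   (named character), `nonhost_info` (data.frame `name`, `taxon_group`,
#'   `genus`, `kit_genus`).
#' @export
make_references <- function(config = ref_config(), seed) {
  stopifnot(inherits(config, "ref_config"), !missing(seed))
  set.seed(seed)
  panel <- if (config$include_panel) contaminant_panel() else NULL
  panel_seqs <- if (is.null(panel)) character(0) else panel$srna_sequence
  primers <- if (is.null(panel)) character(0) else panel$primer_sequence

  host <- NULL
  for (attempt in 1:5) {
    cand <- random_dna(1L, config$host_length)
    collide <- vapply(c(panel_seqs, if (!is.null(config$spike)) config$spike$sequence),
                      function(s) grepl(s, cand, fixed = TRUE) ||
                        grepl(revcomp(s), cand, fixed = TRUE), logical(1L))
    if (!any(collide)) { host <- cand; break }
  }
  if (is.null(host)) stop("panel sequences collide with every generated host genome")
  names(host) <- "host_chr1"

  # host sRNA loci are genuine substrings of the host genome
  n_endo <- config$n_endogenous
  lens <- sample(config$endogenous_lengths, n_endo, replace = TRUE)
  starts <- sample.int(config$host_length - max(lens), n_endo)
  endo <- substring(host, starts, starts + lens - 1L)
  dup <- duplicated(endo)
  endo <- endo[!dup]
  weights <- exp(rnorm(length(endo), 0, 1))
  host_loci <- data.frame(seq = endo, weight = weights / sum(weights),
                          stringsAsFactors = FALSE)

  avoid <- c(panel_seqs, endo)
  exo <- character(0)
  if (config$n_exogenous > 0L) {
    for (i in seq_len(config$n_exogenous)) {
      s <- .draw_panel_seq(config$exogenous_lengths, host, avoid, primers)
      exo <- c(exo, s); avoid <- c(avoid, s)
    }
    names(exo) <- sprintf("exo%d", seq_along(exo))
  }
  kit_seq <- NULL
  if (config$include_kit_sequence) {
    kit_seq <- .draw_panel_seq(config$exogenous_lengths, host, avoid, primers)
    names(kit_seq) <- "kit1"
  }

  # synthetic non-host genomes; groups/genera follow the panel's putative
  # origins, plus one vertebrate genome and one kit-contaminant genus
  info <- data.frame(
    name = c("Lactobacillus_syn", "Bacillus_syn", "Aspergillus_syn",
             "Arabidopsis_syn", "Chlorella_syn", "Mus_syn",
             "Bradyrhizobium_syn"),
    taxon_group = c("bacteria", "bacteria", "fungi", "plant", "plant",
                    "vertebrate", "bacteria"),
    genus = c("Lactobacillus", "Bacillus", "Aspergillus", "Arabidopsis",
              "Chlorella", "Mus", "Bradyrhizobium"),
    kit_genus = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  genomes <- setNames(random_dna(nrow(info), config$nonhost_length), info$name)
  plant_in <- function(gname, seqs) genomes[gname] <<- .embed(genomes[gname], seqs)
  if (!is.null(panel)) {
    plant_in("Chlorella_syn", panel_seqs[1])       # algae-origin contaminant
    plant_in("Aspergillus_syn", panel_seqs[2])
    plant_in("Arabidopsis_syn", panel_seqs[3])
    plant_in("Lactobacillus_syn", panel_seqs[4:5])
    plant_in("Bacillus_syn", panel_seqs[6])
  }
  if (length(exo)) {
    # exo sequences rotate over the non-kit, non-vertebrate genomes; the
    # last one stays unplanted (origin unknown)
    hosts_for_exo <- c("Lactobacillus_syn", "Bacillus_syn", "Aspergillus_syn",
                       "Arabidopsis_syn")
    n_planted <- max(length(exo) - 1L, 0L)
    for (i in seq_len(n_planted)) {
      plant_in(hosts_for_exo[(i - 1L) %% length(hosts_for_exo) + 1L], exo[i])
    }
  }
  if (!is.null(kit_seq)) plant_in("Bradyrhizobium_syn", kit_seq)

  structure(
    list(host = host, host_loci = host_loci, panel = panel,
         exogenous = exo, kit_sequence = kit_seq, spike = config$spike,
         nonhost = genomes, nonhost_info = info, config = config, seed = seed),
    class = "reference_set"
  )
}

#' Library design
#'
#' Copy-number composition of one simulated sequencing library. Defaults
#' encode the study conditions: 75-nt single-end reads with the standard
#' small-RNA 3' adapter, spike-in at 40,000 copies/uL of a 14-uL eluate,
#' column contaminants at fixed copies per column scaled so the most
#' abundant contaminant reaches roughly 5000 cpm at 100 uL plasma input on
#' a regular column, sample-borne RNA at 2e5 copies/uL, exogenous sRNAs at
#' 4 copies/uL (about 20 cpm), and ultra-clean columns depleting
#' contaminants 60-fold.
#'
#' @param meta one-row [library_meta()].
#' @param total_reads reads to draw (multinomially) for the library.
#' @param endogenous_copies_per_uL host sRNA copies per uL plasma.
#' @param contaminant_copies_per_column named copies per column for each
#'   panel contaminant (`NULL` = default profile matching the panel).
#' @param exogenous_copies_per_uL copies per uL plasma for each planted
#'   exogenous sRNA.
#' @param kit_copies_per_uL copies per uL for the planted kit-genus sRNA.
#' @param carryover_copies copies of each contaminant carried over into
#'   water/no-template controls (default 0).
#' @param error_rate per-base substitution probability.
#' @param adapter 3' adapter sequence.
#' @param read_length read length (nt).
#' @param eluate_volume_uL eluate volume; spike-in total copies are
#'   `spikein_copies_per_uL * eluate_volume_uL`.
#' @param ultraclean_factor fold-depletion of column contaminants on
#'   ultra-clean columns.
#' @param low_quality_frac fraction of reads emitted with low-quality
#'   bases (exercises the quality filter; default 0).
#' @param seed integer seed (mandatory).
#' @return a `library_design` list.
#' @export
library_design <- function(meta, total_reads = 1e6,
                           endogenous_copies_per_uL = 2e5,
                           contaminant_copies_per_column = NULL,
                           exogenous_copies_per_uL = 4,
                           kit_copies_per_uL = 4,
                           carryover_copies = 0,
                           error_rate = 0.001,
                           adapter = "TGGAATTCTCGGGTGCCAAGG",
                           read_length = 75L,
                           eluate_volume_uL = 14,
                           ultraclean_factor = 60,
                           low_quality_frac = 0,
                           seed) {
  stopifnot(inherits(meta, "library_meta"), nrow(meta) == 1L,
            total_reads >= 0, error_rate >= 0, !missing(seed),
            nzchar(adapter))
  if (endogenous_copies_per_uL < 0 || exogenous_copies_per_uL < 0 ||
      kit_copies_per_uL < 0 || carryover_copies < 0) {
    stop("copy-number rates must be non-negative")
  }
  structure(as.list(environment()), class = "library_design")
}

# default contaminant copies per column: the panel's relative plasma cpm
# profile scaled so the top contaminant sits near 5000 cpm at V = 100 uL
# on a regular column under the default sample-borne pool
default_contaminant_copies <- function(panel) {
  prof <- c(104000, 24800, 25400, 21000, 12100, 10500)
  if (nrow(panel) == length(prof)) return(setNames(prof, panel$name))
  # other panels: equal mid-range levels
  setNames(rep(20000, nrow(panel)), panel$name)
}

# fragment pool (sequence, copies, category) for one library design
.library_pool <- function(design, refs) {
  meta <- design$meta
  V <- meta$volume_uL
  pool <- data.frame(seq = character(0), copies = numeric(0),
                     category = character(0), name = character(0),
                     stringsAsFactors = FALSE)
  add <- function(seqs, copies, category, names) {
    rbind(pool, data.frame(seq = unname(seqs), copies = unname(copies),
                           category = category, name = names,
                           stringsAsFactors = FALSE))
  }
  contam <- design$contaminant_copies_per_column
  if (is.null(contam) && !is.null(refs$panel)) {
    contam <- default_contaminant_copies(refs$panel)
  }
  if (identical(meta$column, "ultraclean")) contam <- contam / design$ultraclean_factor

  type <- meta$type
  if (type == "plasma") {
    pool <- add(refs$host_loci$seq,
                refs$host_loci$weight * design$endogenous_copies_per_uL * V,
                "endogenous", sprintf("endo%d", seq_len(nrow(refs$host_loci))))
    if (length(refs$exogenous)) {
      pool <- add(refs$exogenous, rep(design$exogenous_copies_per_uL * V,
                                      length(refs$exogenous)),
                  "exogenous", names(refs$exogenous))
    }
    if (!is.null(refs$kit_sequence)) {
      pool <- add(refs$kit_sequence, design$kit_copies_per_uL * V,
                  "kit", names(refs$kit_sequence))
    }
  }
  if (type %in% c("plasma", "mock", "eluate") && !is.null(refs$panel)) {
    pool <- add(refs$panel$srna_sequence, contam[refs$panel$name],
                "contaminant", refs$panel$name)
  }
  if (type %in% c("water", "no_template") && design$carryover_copies > 0 &&
      !is.null(refs$panel)) {
    pool <- add(refs$panel$srna_sequence,
                rep(design$carryover_copies, nrow(refs$panel)),
                "carryover", refs$panel$name)
  }
  if (meta$spikein_copies_per_uL > 0) {
    pool <- add(refs$spike$sequence,
                meta$spikein_copies_per_uL * design$eluate_volume_uL,
                "spike", refs$spike$name)
  }
  pool[pool$copies > 0, , drop = FALSE]
}

# inject substitution errors, one read at a time for reads drawn with >0
# errors (a small minority at realistic error rates)
.inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, error_rate)
  idx <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    p <- sample.int(lens[i], nerr[i])
    for (j in p) {
      cur <- substr(seqs[i], j, j)
      substr(seqs[i], j, j) <- sample(setdiff(bases, cur), 1L)
    }
  }
  seqs
}

#' Simulate one sequencing library
#'
#' Draws `total_reads` reads multinomially from the design's copy-number
#' pool, injects substitution errors into the sRNA insert, appends the 3'
#' adapter and pads/truncates to the read length. Mock libraries contain
#' only contaminants plus spike-in; water and no-template controls contain
#' only carry-over noise (default none; an empty pool with
#' `total_reads > 0` is an error).
#'
#' @param design a [library_design()].
#' @param refs a [make_references()] reference set.
#' @return read table (`id`, `seq`, `qual`) with attribute `composition`:
#'   a data.frame of pool sequences with planted copies and drawn reads.
#' @export
simulate_library <- function(design, refs) {
  stopifnot(inherits(design, "library_design"), inherits(refs, "reference_set"))
  set.seed(design$seed)
  pool <- .library_pool(design, refs)
  n <- round(design$total_reads)
  empty <- data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(empty, "composition") <- cbind(pool, reads = integer(nrow(pool)))
    return(empty)
  }
  if (nrow(pool) == 0L) {
    stop("library ", design$meta$library_id,
         ": empty fragment pool with total_reads > 0")
  }
  draw <- as.integer(rmultinom(1L, n, pool$copies))
  inserts <- rep.int(pool$seq, draw)
  inserts <- .inject_errors(inserts, design$error_rate)
  rl <- design$read_length
  full <- substr(paste0(inserts, design$adapter, strrep("A", rl)), 1L, rl)
  qual <- strrep(phred_char(36L), rl)
  quals <- rep.int(qual, length(full))
  if (design$low_quality_frac > 0) {
    nlow <- round(design$low_quality_frac * length(full))
    if (nlow > 0L) {
      k <- ceiling(0.2 * rl)
      lowq <- paste0(strrep("#", k), strrep(phred_char(36L), rl - k))
      pick <- sample.int(length(full), nlow)
      quals[pick] <- lowq
    }
  }
  out <- data.frame(
    id = sprintf("%s_read%d", design$meta$library_id, seq_along(full)),
    seq = full, qual = quals, stringsAsFactors = FALSE
  )
  attr(out, "composition") <- cbind(pool, reads = draw)
  out
}

#' Simulate a plasma titration series
#'
#' One or more replicate libraries per (volume, column type), with
#' per-library seeds derived deterministically from the master seed.
#' Ultra-clean columns deplete column contaminants by the design's
#' `ultraclean_factor`.
#'
#' @param volumes plasma input volumes (uL); the study design is
#'   `c(45, 100, 225, 500, 1115)`.
#' @param column_types subset of `c("regular", "ultraclean")`.
#' @param refs reference set.
#' @param base_design a [library_design()] used as template (its `meta`
#'   and `seed` are overridden per library).
#' @param seed master seed.
#' @param replicates replicates per (volume, column); either a single
#'   count or a vector along `volumes`.
#' @return list with `reads` (named list of read tables) and `meta`
#'   ([library_meta()] for all libraries).
#' @export
simulate_titration <- function(volumes = c(45, 100, 225, 500, 1115),
                               column_types = c("regular", "ultraclean"),
                               refs, base_design, seed,
                               replicates = 1L) {
  stopifnot(length(volumes) >= 1L, all(volumes > 0))
  if (length(replicates) == 1L) replicates <- rep.int(replicates, length(volumes))
  stopifnot(length(replicates) == length(volumes))
  ids <- character(0); metas <- list(); reads <- list()
  k <- 0L
  for (col in column_types) {
    for (vi in seq_along(volumes)) {
      for (r in seq_len(replicates[vi])) {
        k <- k + 1L
        id <- sprintf("plasma_V%g_%s_r%d", volumes[vi], col, r)
        if (id %in% ids) stop("duplicate (volume, column, replicate): ", id)
        ids <- c(ids, id)
        m <- library_meta(id, "plasma", column = col, batch = col,
                          volume_uL = volumes[vi],
                          spikein_name = refs$spike$name,
                          spikein_copies_per_uL = refs$spike$copies_per_uL_eluate,
                          seed = derive_seed(seed, k))
        d <- base_design
        d$meta <- m
        d$seed <- m$seed
        reads[[id]] <- simulate_library(d, refs)
        metas[[id]] <- m
      }
    }
  }
  meta <- do.call(rbind, metas)
  class(meta) <- c("library_meta", "data.frame")
  rownames(meta) <- NULL
  list(reads = reads, meta = meta)
}

#' Simulate a complete study dataset
#'
#' A plasma titration series (default: 5 volumes x 2 column types with
#' replicates 3/3/3/3/2 per column, i.e. 28 plasma libraries) plus
#' negative controls: mock extractions and column eluates with spike-in,
#' and empty water controls.
#'
#' @param refs reference set.
#' @param seed master seed.
#' @param reads_per_library sequencing depth per non-empty library.
#' @param volumes,replicates titration design (see [simulate_titration()]).
#' @param n_mock,n_eluate,n_water numbers of control libraries (mocks are
#'   split between column types; water controls are empty).
#' @param ... further arguments to [library_design()] (e.g.
#'   `exogenous_copies_per_uL`, `error_rate`).
#' @return list with `reads` (named list of read tables) and `meta`.
#' @export
simulate_dataset <- function(refs, seed, reads_per_library = 1e6,
                             volumes = c(45, 100, 225, 500, 1115),
                             replicates = c(3L, 3L, 3L, 3L, 2L),
                             n_mock = 6L, n_eluate = 4L, n_water = 2L, ...) {
  template <- library_design(
    meta = library_meta("template", "plasma", volume_uL = 100,
                        spikein_name = refs$spike$name,
                        spikein_copies_per_uL = refs$spike$copies_per_uL_eluate),
    total_reads = reads_per_library, seed = seed, ...
  )
  tit <- simulate_titration(volumes, c("regular", "ultraclean"), refs,
                            template, seed = seed, replicates = replicates)
  reads <- tit$reads
  metas <- list(tit$meta)
  k <- 10000L
  add_lib <- function(id, type, column, n, spike) {
    k <<- k + 1L
    m <- library_meta(id, type, column = column, batch = column, volume_uL = 0,
                      spikein_name = if (spike) refs$spike$name else NA_character_,
                      spikein_copies_per_uL = if (spike) refs$spike$copies_per_uL_eluate else 0,
                      seed = derive_seed(seed, k))
    d <- template
    d$meta <- m
    d$seed <- m$seed
    d$total_reads <- if (type %in% c("water", "no_template")) 0 else reads_per_library
    reads[[id]] <<- simulate_library(d, refs)
    metas[[length(metas) + 1L]] <<- m
  }
  for (i in seq_len(n_mock)) {
    add_lib(sprintf("mock_%d", i), "mock",
            if (i %% 2L == 0L) "ultraclean" else "regular", reads_per_library, TRUE)
  }
  for (i in seq_len(n_eluate)) {
    add_lib(sprintf("eluate_%d", i), "eluate",
            if (i %% 2L == 0L) "ultraclean" else "regular", reads_per_library, TRUE)
  }
  for (i in seq_len(n_water)) {
    add_lib(sprintf("water_%d", i), "water", "regular", 0, FALSE)
  }
  meta <- do.call(rbind, metas)
  class(meta) <- c("library_meta", "data.frame")
  rownames(meta) <- NULL
  list(reads = reads, meta = meta)
}

#' Simulate qPCR amplification curves
#'
#' Four-parameter sigmoid in cycle number; the curve midpoint shifts by
#' `-log10(copies) * log(10)/log(1 + efficiency)` cycles, so with perfect
#' per-cycle doubling (`efficiency = 1`) quantification cycles are spaced
#' `log2(10) = 3.3219` cycles per decade. `noise_sd = 0` gives analytic
#' curves. Non-positive copy numbers yield a flat baseline flagged as
#' no-amplification.
#'
#' @param true_copies vector of input copy numbers, one reaction each.
#' @param curve_params list overriding any of `cycles`, `baseline`,
#'   `scale`, `steepness`, `efficiency`, `mid1` (midpoint at 1 copy).
#' @param noise_sd fluorescence noise standard deviation.
#' @param seed integer seed (mandatory when `noise_sd > 0`).
#' @return a `qpcr_curves` list: `cycles`, `fluorescence` (cycles x
#'   reactions matrix), `true_copies`, `no_amplification` (logical).
#' @export
simulate_qpcr <- function(true_copies, curve_params = list(), noise_sd = 0,
                          seed = 1L) {
  p <- utils::modifyList(
    list(cycles = 1:40, baseline = 0.05, scale = 1.0, steepness = 1.25,
         efficiency = 1.0, mid1 = 36),
    curve_params
  )
  stopifnot(p$efficiency > 0, length(true_copies) >= 1L)
  set.seed(seed)
  cyc <- p$cycles
  shift <- log(10) / log(1 + p$efficiency)
  fl <- vapply(true_copies, function(cp) {
    if (cp <= 0) return(rep(p$baseline, length(cyc)))
    mid <- p$mid1 - log10(cp) * shift
    p$baseline + p$scale / (1 + exp(-(cyc - mid) / p$steepness))
  }, numeric(length(cyc)))
  fl <- matrix(fl, nrow = length(cyc))
  if (noise_sd > 0) fl <- fl + matrix(rnorm(length(fl), 0, noise_sd), nrow = length(cyc))
  colnames(fl) <- sprintf("rxn%d", seq_along(true_copies))
  structure(
    list(cycles = cyc, fluorescence = fl, true_copies = true_copies,
         no_amplification = true_copies <= 0, noise_sd = noise_sd),
    class = "qpcr_curves"
  )
}

#' Write simulated references, libraries and metadata to disk
#'
#' References as FASTA, libraries as FASTQ (optionally gzipped), metadata
#' as TSV with the standard columns.
#'
#' @param sim a [simulate_dataset()]/[simulate_titration()] result.
#' @param refs the reference set used.
#' @param dir output directory (created if needed).
#' @param gzip gzip FASTQ output.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, refs, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  host <- Biostrings::DNAStringSet(refs$host)
  Biostrings::writeXStringSet(host, file.path(dir, "host.fa"))
  nh <- Biostrings::DNAStringSet(refs$nonhost)
  Biostrings::writeXStringSet(nh, file.path(dir, "nonhost.fa"))
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  for (id in names(sim$reads)) {
    r <- sim$reads[[id]]
    if (nrow(r)) write_fastq(r, file.path(dir, paste0(id, ext)))
  }
  write.table(sim$meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(refs$nonhost_info, file.path(dir, "nonhost_taxa.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
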