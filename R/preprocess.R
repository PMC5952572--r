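## Preprocessing: raw FASTQ -> collapsed, quality-filtered unique-read
## count tables. Reads are carried as a data.frame with columns `seq` and
## `qual` (Phred+33); the pipeline order is fixed:
## trim_adapters -> clip_5prime_ns -> quality_filter -> collapse_reads.

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (optionally gzip-compressed).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTQ file: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE
  )
}

#' Write a read table to FASTQ
#'
#' @param reads data.frame with columns `seq`, `qual` (and optionally `id`).
#' @param path output file; a `.gz` suffix enables compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- if (!is.null(reads$id)) reads$id else sprintf("read%d", seq_len(nrow(reads)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# Leftmost 1-based start of a 3' adapter occurrence in each sequence, or NA.
# An occurrence is the adapter (or an end-truncated prefix of it) aligned
# with >= min_overlap nt and <= max_mismatch substitutions. Exact internal
# and exact end-anchored matches are found first (fast path); a
# mismatch-tolerant scan covers the rest.
adapter_match_pos <- function(seqs, adapter, min_overlap = 10L, max_mismatch = 1L) {
  n <- length(seqs)
  pos <- rep.int(NA_integer_, n)
  if (n == 0L) return(pos)
  la <- nchar(adapter)
  w <- nchar(seqs)

  hit <- regexpr(adapter, seqs, fixed = TRUE, useBytes = TRUE)
  pos[hit > 0L] <- hit[hit > 0L]

  # exact adapter prefix running into the read end
  todo <- which(is.na(pos) & w >= min_overlap)
  if (length(todo) && la > min_overlap) {
    for (j in seq.int(min(la - 1L, max(w[todo])), min_overlap)) {
      if (!length(todo)) break
      pre <- substr(adapter, 1L, j)
      idx <- todo[endsWith(seqs[todo], pre)]
      if (length(idx)) {
        pos[idx] <- w[idx] - j + 1L
        todo <- setdiff(todo, idx)
      }
    }
  }

  if (max_mismatch > 0L) {
    todo <- which(is.na(pos) & w >= min_overlap)
    if (length(todo)) {
      # prefilter: one of the two halves of the adapter's first min_overlap
      # bases must be present exactly when at most one mismatch is allowed
      half <- min_overlap %/% 2L
      h1 <- substr(adapter, 1L, half)
      h2 <- substr(adapter, half + 1L, min_overlap)
      cand <- todo[grepl(h1, seqs[todo], fixed = TRUE) |
                   grepl(h2, seqs[todo], fixed = TRUE)]
      if (length(cand)) {
        sub <- seqs[cand]
        wc <- w[cand]
        found <- rep.int(NA_integer_, length(cand))
        a_chars <- strsplit(adapter, "", fixed = TRUE)[[1L]]
        for (s in seq_len(max(wc) - min_overlap + 1L)) {
          open <- which(is.na(found) & wc - s + 1L >= min_overlap)
          if (!length(open)) break
          ov <- pmin(la, wc[open] - s + 1L)
          mm <- integer(length(open))
          for (k in seq_len(max(ov))) {
            act <- ov >= k
            mm[act] <- mm[act] +
              (substr(sub[open[act]], s + k - 1L, s + k - 1L) != a_chars[k])
          }
          ok <- open[mm <= max_mismatch]
          if (length(ok)) found[ok] <- s
        }
        pos[cand] <- found
      }
    }
  }
  pos
}

#' Trim 3' adapter sequences from reads
#'
#' Removes the leftmost occurrence of each adapter (full, end-truncated to
#' at least `min_overlap` nt, or carrying up to `max_mismatch`
#' substitutions) together with everything 3' of it, and repeats the pass
#' recursively until no further occurrence is removed. Reads shorter than
#' `min_len` after trimming are discarded.
#'
#' @param reads read table (`seq`, `qual`).
#' @param adapters character vector of 3' adapter sequences.
#' @param min_overlap minimum adapter overlap at the read end (nt).
#' @param max_mismatch substitutions tolerated in an occurrence.
#' @param min_len minimum retained read length after trimming.
#' @return trimmed read table.
#' @export
trim_adapters <- function(reads, adapters, min_overlap = 10L,
                          max_mismatch = 1L, min_len = 15L) {
  stopifnot(length(adapters) >= 1L, all(nzchar(adapters)))
  adapters <- rna_to_dna(adapters)
  if (nrow(reads) == 0L) return(reads)
  seqs <- reads$seq
  quals <- reads$qual
  repeat {
    changed <- FALSE
    for (ad in adapters) {
      pos <- adapter_match_pos(seqs, ad, min_overlap, max_mismatch)
      hit <- which(!is.na(pos))
      if (length(hit)) {
        changed <- TRUE
        seqs[hit] <- substr(seqs[hit], 1L, pos[hit] - 1L)
        quals[hit] <- substr(quals[hit], 1L, pos[hit] - 1L)
      }
    }
    if (!changed) break
  }
  keep <- nchar(seqs) >= min_len
  out <- reads[keep, , drop = FALSE]
  out$seq <- seqs[keep]
  out$qual <- quals[keep]
  rownames(out) <- NULL
  out
}

#' Clip leading N bases
#'
#' Removes runs of `N` at the 5' end only; internal and 3' `N`s are left
#' untouched. Reads falling below `min_len` are discarded.
#'
#' @param reads read table.
#' @param min_len minimum retained read length.
#' @return clipped read table.
#' @export
clip_5prime_ns <- function(reads, min_len = 15L) {
  if (nrow(reads) == 0L) return(reads)
  nlead <- attr(regexpr("^N+", reads$seq, useBytes = TRUE), "match.length")
  nlead[nlead < 0L] <- 0L
  seqs <- substr(reads$seq, nlead + 1L, nchar(reads$seq))
  quals <- substr(reads$qual, nlead + 1L, nchar(reads$qual))
  keep <- nchar(seqs) >= min_len
  out <- reads[keep, , drop = FALSE]
  out$seq <- seqs[keep]
  out$qual <- quals[keep]
  rownames(out) <- NULL
  out
}

# character-class pattern matching Phred+33 scores >= q (codes 33+q .. 126)
.good_qual_class <- function(q) {
  lo <- 33L + as.integer(q)
  if (lo > 126L) return(NULL)
  esc <- function(code) {
    ch <- intToUtf8(code)
    if (ch %in% c("]", "\\", "^", "-")) paste0("\\", ch) else ch
  }
  paste0("[", esc(lo), "-", esc(126L), "]")
}

#' Quality-filter reads
#'
#' A read is retained if and only if at least `p_min` percent of its bases
#' have Phred quality of at least `q_min` (Phred+33 encoding).
#'
#' @param reads read table.
#' @param q_min per-base quality threshold.
#' @param p_min minimum percentage of bases meeting `q_min`.
#' @return filtered read table.
#' @export
quality_filter <- function(reads, q_min = 30L, p_min = 90) {
  if (nrow(reads) == 0L) return(reads)
  nseq <- nchar(reads$seq)
  nq <- nchar(reads$qual)
  bad <- which(nseq != nq)
  if (length(bad)) {
    stop("quality string length mismatch for record(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  cls <- .good_qual_class(q_min)
  ngood <- if (is.null(cls)) 0L else nchar(gsub(cls, "", reads$qual, useBytes = TRUE))
  ngood <- nq - ngood
  keep <- ngood * 100 >= p_min * nq
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse identical reads
#'
#' Replaces identical read sequences by one record carrying the read
#' abundance. Output is ordered by descending count, ties broken
#' lexicographically; the counts sum to the number of input reads.
#'
#' @param reads read table (or a character vector of sequences).
#' @return data.frame with columns `seq`, `count`.
#' @export
collapse_reads <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (length(seqs) == 0L) {
    return(data.frame(seq = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  srt <- sort(seqs, method = "radix")
  r <- rle(srt)
  o <- order(-r$lengths, r$values, method = "radix")
  data.frame(seq = r$values[o], count = r$lengths[o], stringsAsFactors = FALSE)
}

#' Library metadata table
#'
#' @param library_id unique library identifiers.
#' @param type sample type: `plasma`, `mock`, `eluate`, `water` or
#'   `no_template`.
#' @param column extraction column type: `regular` or `ultraclean`.
#' @param batch column batch label.
#' @param volume_uL plasma input volume (0 for controls).
#' @param spikein_name,spikein_copies_per_uL spike-in identity and level
#'   (`NA`/0 when no spike-in was added).
#' @param seed per-library simulation seed (NA for real data).
#' @return data.frame of class `library_meta`.
#' @export
library_meta <- function(library_id, type, column = "regular", batch = "b1",
                         volume_uL = 0, spikein_name = NA_character_,
                         spikein_copies_per_uL = 0, seed = NA_integer_) {
  type <- match.arg(type, c("plasma", "mock", "eluate", "water", "no_template"),
                    several.ok = TRUE)
  m <- data.frame(library_id = library_id, type = type, column = column,
                  batch = batch, volume_uL = volume_uL,
                  spikein_name = spikein_name,
                  spikein_copies_per_uL = spikein_copies_per_uL,
                  seed = seed, stringsAsFactors = FALSE)
  if (anyDuplicated(m$library_id)) stop("duplicate library ids")
  class(m) <- c("library_meta", "data.frame")
  m
}

#' Is a sample type an extraction/sequencing control?
#'
#' @param type character vector of sample types.
#' @return logical: `TRUE` for `mock`, `eluate`, `water`, `no_template`.
#' @export
is_control_type <- function(type) {
  type %in% c("mock", "eluate", "water", "no_template")
}

#' Build a sequences-by-libraries count table
#'
#' Combines per-library collapsed reads into a count matrix and applies
#' the abundance retention rule: in `study` mode, only sequences found at
#' least 30 times in all analysed libraries together are retained; in
#' `public` mode (for external datasets of heterogeneous design) only
#' singleton sequences are removed. Library sizes are recorded before row
#' filtering so relative abundances stay anchored to the retained-read
#' totals.
#'
#' @param collapsed named list of collapsed-read data.frames
#'   (one per library, names = library ids).
#' @param meta [library_meta()] table covering the same library ids.
#' @param mode `"study"` or `"public"`.
#' @param min_total optional override of the minimum summed count for a
#'   sequence to be retained (defaults: 30 in study mode, 2 in public).
#' @return an object of class `srna_count_table`: list with elements
#'   `counts` (integer matrix, sequences x libraries), `meta`,
#'   `library_sizes`, `mode`.
#' @export
build_count_table <- function(collapsed, meta, mode = c("study", "public"),
                              min_total = NULL) {
  mode <- match.arg(mode)
  ids <- names(collapsed)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("collapsed must be a named list with unique library ids")
  }
  if (!all(ids %in% meta$library_id)) {
    stop("metadata missing for library id(s): ",
         paste(setdiff(ids, meta$library_id), collapse = ", "))
  }
  meta <- meta[match(ids, meta$library_id), , drop = FALSE]
  library_sizes <- vapply(collapsed, function(x) sum(x$count), numeric(1))
  all_seqs <- sort(unique(unlist(lapply(collapsed, `[[`, "seq"), use.names = FALSE)))
  counts <- matrix(0L, nrow = length(all_seqs), ncol = length(ids),
                   dimnames = list(all_seqs, ids))
  for (j in seq_along(ids)) {
    x <- collapsed[[j]]
    if (nrow(x)) counts[match(x$seq, all_seqs), j] <- as.integer(x$count)
  }
  if (is.null(min_total)) min_total <- if (mode == "study") 30L else 2L
  keep <- rowSums(counts) >= min_total
  counts <- counts[keep, , drop = FALSE]
  structure(
    list(counts = counts, meta = meta,
         library_sizes = setNames(library_sizes, ids), mode = mode),
    class = "srna_count_table"
  )
}

#' Counts per million retained reads
#'
#' @param ct an `srna_count_table`.
#' @return numeric matrix of cpm; columns for empty libraries are `NaN`.
#' @export
cpm <- function(ct) {
  stopifnot(inherits(ct, "srna_count_table"))
  sweep(ct$counts, 2L, ct$library_sizes, "/") * 1e6
}

#' @export
print.srna_count_table <- function(x, ...) {
  cat("srna_count_table:", nrow(x$counts), "sequences x",
      ncol(x$counts), "libraries (mode:", x$mode, ")\n")
  cat("library sizes:", paste(x$library_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Run the fixed preprocessing chain on one library
#'
#' Convenience wrapper applying, in order, adapter trimming, 5' N
#' clipping, quality filtering and read collapsing.
#'
#' @param reads read table (or FASTQ path).
#' @param adapters 3' adapter sequences.
#' @param min_overlap,max_mismatch,min_len see [trim_adapters()].
#' @param q_min,p_min see [quality_filter()].
#' @return collapsed-read data.frame (`seq`, `count`).
#' @export
preprocess_library <- function(reads, adapters, min_overlap = 10L,
                               max_mismatch = 1L, min_len = 15L,
                               q_min = 30L, p_min = 90) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  reads <- trim_adapters(reads, adapters, min_overlap, max_mismatch, min_len)
  reads <- clip_5prime_ns(reads, min_len)
  reads <- quality_filter(reads, q_min, p_min)
  collapse_reads(reads)
}

#' Write collapsed reads as FASTA
#'
#' Headers follow the `>seqN_count` convention.
#'
#' @param collapsed collapsed-read data.frame.
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  x <- Biostrings::DNAStringSet(collapsed$seq)
  names(x) <- sprintf("seq%d_%d", seq_len(nrow(collapsed)), collapsed$count)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a count table as TSV
#'
#' @param ct an `srna_count_table`.
#' @param path output TSV (rows = sequences, columns = library ids).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(ct, path) {
  df <- data.frame(sequence = rownames(ct$counts), ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
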