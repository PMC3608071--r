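#' Read a small RNA library from FASTQ or FASTA
#'
#' FASTQ is expected in plain 4-line records with Phred+33 qualities;
#' both formats may be gzip-compressed. Qualities are carried along but
#' not used by any downstream step (mapping is perfect-match, so erroneous
#' reads simply fail to map).
#'
#' @param path Input file.
#' @param format `"auto"` (by extension, then by first character),
#'   `"fastq"` or `"fasta"`.
#' @return `data.frame` with columns `id`, `sequence` and, for FASTQ,
#'   `quality`.
#' @export
read_small_rna <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") format <- sniff_format(path)
  if (format == "fastq") validate_fastq_shape(path)
  res <- tryCatch({
    if (format == "fastq") {
      # suppress Biostrings' harmless mcols-dropped warning
      x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
      data.frame(id = names(x),
                 sequence = as.character(x),
                 quality = as.character(Biostrings::quality(x)),
                 stringsAsFactors = FALSE)
    } else {
      x <- Biostrings::readDNAStringSet(path)
      data.frame(id = names(x),
                 sequence = as.character(x),
                 stringsAsFactors = FALSE)
    }
  }, error = function(e) {
    stop(sprintf("failed to parse %s file '%s': %s",
                 format, path, conditionMessage(e)), call. = FALSE)
  })
  rownames(res) <- NULL
  res$sequence <- toupper(res$sequence)
  res
}

# 4-line-record integrity check; Biostrings tolerates some truncations
validate_fastq_shape <- function(path) {
  lines <- readLines(gzfile(path))
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("truncated FASTQ record %d in '%s'",
                 length(lines) %/% 4L + 1L, path), call. = FALSE)
  }
  invisible(TRUE)
}

sniff_format <- function(path) {
  if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) return("fastq")
  if (grepl("\\.(fa|fasta|fas|fna)(\\.gz)?$", path, ignore.case = TRUE)) return("fasta")
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!length(first)) return("fasta")
  if (startsWith(first, "@")) "fastq" else "fasta"
}

#' Trim the 3' adapter and apply the insert length window
#'
#' The insert is the read prefix before the leftmost exact occurrence of
#' the full adapter; if the full adapter does not occur, an exact adapter
#' prefix of at least `min_overlap` bases anchored at the read's 3' end is
#' accepted instead (the longest such prefix is used). Reads with no
#' detectable adapter are rejected (`"no_adapter"`); inserts outside
#' `[min_len, max_len]` are rejected (`"length"`).
#'
#' @param reads Character vector of read sequences, or the `data.frame`
#'   returned by [read_small_rna()].
#' @param adapter 3' adapter sequence (must be supplied; it is not encoded
#'   in the data).
#' @param min_len,max_len Retained insert length window in nt.
#' @param min_overlap Minimum adapter prefix length for the 3'-anchored
#'   fallback match.
#' @return `data.frame` with columns `read`, `insert` (`NA` when
#'   rejected), `status` (`"accepted"`, `"length"`, `"no_adapter"`).
#' @export
trim_adapter <- function(reads, adapter, min_len = 15L, max_len = 45L,
                         min_overlap = 7L) {
  if (is.data.frame(reads)) reads <- reads$sequence
  stopifnot(is.character(adapter), length(adapter) == 1L, nchar(adapter) > 0L)
  adapter <- toupper(adapter)
  reads <- toupper(reads)
  n <- length(reads)
  insert_len <- rep(NA_integer_, n)
  if (n) {
    pos <- regexpr(adapter, reads, fixed = TRUE)
    full <- pos > 0L
    insert_len[full] <- as.integer(pos[full]) - 1L
    # 3'-anchored partial adapter: longest adapter prefix ending the read
    open <- which(!full)
    kmax <- min(nchar(adapter) - 1L, max(nchar(reads)))
    if (kmax >= min_overlap) {
      for (k in kmax:min_overlap) {
        if (!length(open)) break
        hit <- endsWith(reads[open], substr(adapter, 1L, k))
        insert_len[open[hit]] <- nchar(reads[open[hit]]) - k
        open <- open[!hit]
      }
    }
  }
  status <- ifelse(is.na(insert_len), "no_adapter",
                   ifelse(insert_len < min_len | insert_len > max_len,
                          "length", "accepted"))
  insert <- ifelse(status == "accepted", substr(reads, 1L, insert_len), NA)
  data.frame(read = reads, insert = insert, status = status,
             stringsAsFactors = FALSE)
}

#' Apply only the insert length window (pre-trimmed input)
#'
#' For libraries that were already adapter-trimmed upstream: keeps reads
#' whose length lies in `[min_len, max_len]`.
#'
#' @inheritParams trim_adapter
#' @return Same shape as [trim_adapter()]'s result (`insert` equals the
#'   read when accepted; rejections have status `"length"`).
#' @export
length_filter <- function(reads, min_len = 15L, max_len = 45L) {
  if (is.data.frame(reads)) reads <- reads$sequence
  reads <- toupper(reads)
  len <- nchar(reads)
  ok <- len >= min_len & len <= max_len
  data.frame(read = reads,
             insert = ifelse(ok, reads, NA),
             status = ifelse(ok, "accepted", "length"),
             stringsAsFactors = FALSE)
}

#' Construct a species table
#'
#' @param sample_id Sample identifier.
#' @param species `data.frame` with columns `sequence`, `count`
#'   (one row per unique sequence, `count >= 1`).
#' @return Object of class `species_table` with elements `sample_id`,
#'   `species` (ordered by count descending, then sequence) and
#'   `total_reads`.
#' @export
species_table <- function(sample_id, species) {
  stopifnot(is.data.frame(species),
            all(c("sequence", "count") %in% names(species)))
  species <- data.frame(sequence = as.character(species$sequence),
                        count = as.numeric(species$count),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(species$sequence)) stop("duplicate sequences in species table")
  if (nrow(species) && any(species$count < 1)) stop("species counts must be >= 1")
  species <- species[order(-species$count, species$sequence), , drop = FALSE]
  rownames(species) <- NULL
  structure(list(sample_id = sample_id, species = species,
                 total_reads = sum(species$count)),
            class = "species_table")
}

#' @export
print.species_table <- function(x, ...) {
  cat(sprintf("<species_table> %s: %d species, %s reads\n",
              x$sample_id, nrow(x$species),
              format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' Collapse trimmed reads into unique siRNA species
#'
#' One entry per distinct sequence; counts sum to the number of input
#' reads. The result is independent of input order (deterministic
#' ordering: count descending, then lexicographic).
#'
#' @param reads Character vector of accepted insert sequences, or a
#'   [trim_adapter()] / [length_filter()] result (only accepted rows are
#'   used).
#' @param sample_id Sample identifier.
#' @return A [species_table()].
#' @export
collapse_species <- function(reads, sample_id) {
  if (is.data.frame(reads)) reads <- reads$insert[reads$status == "accepted"]
  reads <- reads[!is.na(reads)]
  if (!length(reads)) {
    return(species_table(sample_id, data.frame(sequence = character(),
                                               count = numeric())))
  }
  tab <- table(reads)
  species_table(sample_id,
                data.frame(sequence = names(tab),
                           count = as.numeric(tab),
                           stringsAsFactors = FALSE))
}
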