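#' Construct a reference locus
#'
#' A reference locus is a single nucleotide sequence (the coordinate frame
#' for every downstream analysis) together with an ordered, non-overlapping
#' set of named features (e.g. `five_prime_upstream`, `exon1`, `intron`,
#' `exon2`, `three_prime_downstream`). All coordinates in this package are
#' 1-based and inclusive, matching the convention used for positions on a
#' GenBank/EMBL record.
#'
#' @param id Accession or identifier string.
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T` (uppercased on
#'   input). Ambiguity codes are rejected because downstream mapping allows
#'   only perfect matches and wildcards would silently change counts.
#' @param features `data.frame` with columns `name`, `start`, `end`
#'   (1-based inclusive). May have zero rows.
#' @return An object of class `reference_locus`: a list with elements `id`,
#'   `sequence`, `length` and `features` (sorted by `start`).
#' @export
reference_locus <- function(id, sequence, features = empty_features()) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L == 0L) stop("reference sequence is empty")
  bad <- gregexpr("[^ACGT]", sequence)[[1L]]
  if (bad[1L] != -1L) {
    stop(sprintf("non-ACGT character '%s' in reference '%s' at position %d",
                 substr(sequence, bad[1L], bad[1L]), id, bad[1L]))
  }
  features <- validate_features(features, L)
  structure(list(id = id, sequence = sequence, length = L,
                 features = features),
            class = "reference_locus")
}

empty_features <- function() {
  data.frame(name = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

validate_features <- function(features, L) {
  stopifnot(is.data.frame(features))
  need <- c("name", "start", "end")
  if (!all(need %in% names(features))) {
    stop("feature table must have columns name, start, end")
  }
  features <- features[, need, drop = FALSE]
  features$name <- as.character(features$name)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features) == 0L) return(features)
  if (anyNA(features)) stop("feature table contains missing values")
  if (any(features$start < 1L) || any(features$end > L)) {
    bad <- features[features$start < 1L | features$end > L, , drop = FALSE]
    stop(sprintf("feature '%s' [%d, %d] out of range for a %d-nt reference",
                 bad$name[1L], bad$start[1L], bad$end[1L], L))
  }
  if (any(features$start > features$end)) stop("feature with start > end")
  if (anyDuplicated(features$name)) stop("duplicate feature names")
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  n <- nrow(features)
  if (n > 1L && any(features$start[-1L] <= features$end[-n])) {
    i <- which(features$start[-1L] <= features$end[-n])[1L]
    stop(sprintf("features '%s' and '%s' overlap",
                 features$name[i], features$name[i + 1L]))
  }
  features
}

#' @export
print.reference_locus <- function(x, ...) {
  cat(sprintf("<reference_locus> %s (%d nt, %d features)\n",
              x$id, x$length, nrow(x$features)))
  if (nrow(x$features)) print(x$features)
  invisible(x)
}

#' Load a reference locus from FASTA plus a feature annotation
#'
#' The FASTA file must contain exactly one record. The annotation is either
#' a minimal 3-column TSV (`name`, `start`, `end`; a header line is
#' detected and skipped automatically) or a GFF3 file whose `seqid` must
#' match the FASTA record id; in the GFF3 dialect the feature name is taken
#' from the `type` column after applying `type_map`.
#'
#' @param fasta_path Path to a single-record FASTA file.
#' @param annotation_path Path to the feature annotation, or `NULL` for a
#'   locus without features (only sequence-level operations possible).
#' @param dialect `"tsv"` or `"gff3"`.
#' @param type_map Named character vector mapping GFF3 `type` values to
#'   feature names (GFF3 dialect only); unmapped types keep their own name.
#' @return A [reference_locus()].
#' @export
load_reference <- function(fasta_path, annotation_path = NULL,
                           dialect = c("tsv", "gff3"), type_map = NULL) {
  dialect <- match.arg(dialect)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    stop(sprintf("expected exactly one FASTA record in '%s', found %d",
                 fasta_path, length(seqs)))
  }
  id <- sub("\\s.*$", "", names(seqs)[1L])
  sequence <- as.character(seqs[[1L]])
  features <- if (is.null(annotation_path)) {
    empty_features()
  } else if (dialect == "tsv") {
    read_feature_tsv(annotation_path)
  } else {
    read_feature_gff3(annotation_path, id, type_map)
  }
  reference_locus(id, sequence, features)
}

read_feature_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_features())
  first <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  skip_header <- length(first) >= 3L && is.na(suppressWarnings(as.integer(first[2L])))
  tab <- read.table(text = lines, sep = "\t", header = skip_header,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("feature TSV needs 3 columns: name, start, end")
  names(tab)[1:3] <- c("name", "start", "end")
  tab[, 1:3]
}

read_feature_gff3 <- function(path, locus_id, type_map) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!length(gr)) return(empty_features())
  seqids <- as.character(GenomicRanges::seqnames(gr))
  if (!all(seqids == locus_id)) {
    stop(sprintf("GFF3 seqid(s) %s do not match FASTA id '%s'",
                 paste(unique(setdiff(seqids, locus_id)), collapse = ", "),
                 locus_id))
  }
  type <- as.character(gr$type)
  name <- if (is.null(type_map)) type else {
    ifelse(type %in% names(type_map), unname(type_map[type]), type)
  }
  data.frame(name = name,
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write a reference locus back to FASTA + TSV
#'
#' Inverse of [load_reference()] (TSV dialect); loading the written files
#' reproduces an identical locus.
#'
#' @param locus A [reference_locus()].
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the locus.
#' @export
write_reference <- function(locus, fasta_path, annotation_path) {
  stopifnot(inherits(locus, "reference_locus"))
  seqs <- Biostrings::DNAStringSet(setNames(locus$sequence, locus$id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  write.table(locus$features, annotation_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(locus)
}

#' Feature containing a reference position
#'
#' @param locus A [reference_locus()].
#' @param position Vector of 1-based coordinates in `[1, L]`.
#' @return Character vector: the containing feature name, or
#'   `"unannotated"` for positions in gaps between features.
#' @export
feature_of <- function(locus, position) {
  stopifnot(inherits(locus, "reference_locus"))
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L) || any(position > locus$length)) {
    stop(sprintf("position out of range [1, %d]", locus$length))
  }
  f <- locus$features
  if (!nrow(f)) return(rep("unannotated", length(position)))
  idx <- findInterval(position, f$start)
  hit <- idx >= 1L & position <= ifelse(idx >= 1L, f$end[pmax(idx, 1L)], 0L)
  out <- rep("unannotated", length(position))
  out[hit] <- f$name[idx[hit]]
  out
}

#' First coordinate of the downstream feature at an adjacency boundary
#'
#' For two features that abut (upstream `end` + 1 == downstream `start`),
#' returns the downstream feature's first base, e.g. the first nucleotide
#' of exon 2 at an intron--exon 2 boundary.
#'
#' @param locus A [reference_locus()].
#' @param upstream_feature,downstream_feature Feature names.
#' @return Integer 1-based coordinate.
#' @export
boundary_coordinate <- function(locus, upstream_feature, downstream_feature) {
  f <- locus$features
  up <- f[f$name == upstream_feature, , drop = FALSE]
  dn <- f[f$name == downstream_feature, , drop = FALSE]
  if (nrow(up) != 1L || nrow(dn) != 1L) {
    stop("both boundary features must exist in the annotation")
  }
  if (up$end + 1L != dn$start) {
    stop(sprintf("features '%s' [%d, %d] and '%s' [%d, %d] are not adjacent",
                 upstream_feature, up$start, up$end,
                 downstream_feature, dn$start, dn$end))
  }
  as.integer(dn$start)
}

#' Pair of allele references for discriminating classification
#'
#' Holds two versions of the locus (e.g. the endogenous gene and a
#' transgene that diverge in the 3' UTR) so siRNA species can be classed
#' as common to both, specific to one, or matching neither.
#'
#' @param reference_a,reference_b [reference_locus()] objects.
#' @param label_a,label_b Labels used in reports.
#' @return An object of class `allele_pair`.
#' @export
allele_pair <- function(reference_a, reference_b,
                        label_a = "allele_a", label_b = "allele_b") {
  stopifnot(inherits(reference_a, "reference_locus"),
            inherits(reference_b, "reference_locus"))
  if (identical(reference_a$sequence, reference_b$sequence)) {
    stop("allele references are identical; nothing to discriminate")
  }
  structure(list(reference_a = reference_a, reference_b = reference_b,
                 label_a = label_a, label_b = label_b),
            class = "allele_pair")
}
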