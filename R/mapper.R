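#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of ACGT(N) sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Place one siRNA species on the reference by perfect matching
#'
#' Finds every occurrence of the species on both strands of the locus,
#' allowing only perfect matches. A sense alignment satisfies
#' `reference[start..end] == species`; an antisense alignment satisfies
#' `revcomp(reference[start..end]) == species`. For antisense alignments
#' the species' 5' end sits at reference coordinate `end` (the rightmost
#' matched base) -- all downstream position, boundary and phase logic uses
#' this convention.
#'
#' @param sequence Species sequence (5'->3' as sequenced).
#' @param locus A [reference_locus()].
#' @return `data.frame` with columns `strand` (`"sense"`/`"antisense"`),
#'   `start`, `end` (1-based inclusive), sorted by (strand, start);
#'   zero rows when the species does not match anywhere.
#' @export
map_species <- function(sequence, locus) {
  stopifnot(inherits(locus, "reference_locus"))
  subject <- locus_subject(locus)
  hits_for <- function(pat) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject)
    data.frame(start = Biostrings::start(m), end = Biostrings::end(m))
  }
  s <- hits_for(sequence)
  a <- hits_for(revcomp(sequence))
  out <- rbind(
    if (nrow(s)) cbind(strand = "sense", s) else NULL,
    if (nrow(a)) cbind(strand = "antisense", a) else NULL
  )
  if (is.null(out)) {
    out <- data.frame(strand = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  out[order(match(out$strand, c("sense", "antisense")), out$start), ,
      drop = FALSE]
}

# cache the DNAString subject on the locus environment-free list is not
# possible; rebuild cheaply (loci are a few kb)
locus_subject <- function(locus) Biostrings::DNAString(locus$sequence)

#' Construct a mapped set
#'
#' Usually produced by [map_table()]; the constructor is exported so
#' mapped sets can also be assembled programmatically (e.g. from published
#' per-species read totals).
#'
#' @param sample_id Sample identifier.
#' @param alignments `data.frame` with columns `sequence`, `strand`,
#'   `start`, `end`, `length`, `count`, `n_placements`.
#' @param unmapped `data.frame` with columns `sequence`, `count` for
#'   species with no perfect match.
#' @param locus_id,locus_length Identity and length of the reference the
#'   alignments refer to.
#' @param multimap_policy `"all"`, `"fractional"` or `"unique"`; see
#'   [map_table()].
#' @return Object of class `mapped_set`.
#' @export
mapped_set <- function(sample_id, alignments, unmapped, locus_id,
                       locus_length,
                       multimap_policy = c("all", "fractional", "unique")) {
  multimap_policy <- match.arg(multimap_policy)
  need <- c("sequence", "strand", "start", "end", "length", "count",
            "n_placements")
  stopifnot(is.data.frame(alignments), all(need %in% names(alignments)))
  alignments <- alignments[, need, drop = FALSE]
  if (nrow(alignments)) {
    stopifnot(all(alignments$strand %in% c("sense", "antisense")),
              all(alignments$end - alignments$start + 1L == alignments$length),
              all(nchar(alignments$sequence) == alignments$length),
              all(alignments$start >= 1L),
              all(alignments$end <= locus_length),
              all(alignments$count >= 1),
              all(alignments$n_placements >= 1L))
  }
  if (missing(unmapped) || is.null(unmapped)) {
    unmapped <- data.frame(sequence = character(), count = numeric())
  }
  rownames(alignments) <- NULL
  structure(list(sample_id = sample_id,
                 alignments = alignments,
                 unmapped = unmapped,
                 locus_id = locus_id,
                 locus_length = as.integer(locus_length),
                 multimap_policy = multimap_policy),
            class = "mapped_set")
}

#' @export
print.mapped_set <- function(x, ...) {
  cat(sprintf(
    "<mapped_set> %s on %s (%d nt): %d placements of %d species; %d species unmapped; policy '%s'\n",
    x$sample_id, x$locus_id, x$locus_length, nrow(x$alignments),
    length(unique(x$alignments$sequence)), nrow(x$unmapped),
    x$multimap_policy))
  invisible(x)
}

#' Map a whole species table onto the reference locus
#'
#' Runs [map_species()] for every species and aggregates the placements
#' into a `mapped_set`, tallying unmapped species. The multimap policy
#' governs how a species with `m > 1` placements contributes:
#' \describe{
#'   \item{all}{full `count` at every placement in position tracks and
#'     size distributions; read totals still count every read exactly once
#'     (each placement weighted `count/m`).}
#'   \item{fractional}{`count/m` at every placement everywhere.}
#'   \item{unique}{multi-placement species are excluded from all
#'     attribution (their placements remain listed).}
#' }
#' On an effectively single-copy locus the policies coincide.
#'
#' @param table A [species_table()].
#' @param locus A [reference_locus()].
#' @param multimap_policy See above.
#' @return A [mapped_set()].
#' @export
map_table <- function(table, locus,
                      multimap_policy = c("all", "fractional", "unique")) {
  stopifnot(inherits(table, "species_table"))
  multimap_policy <- match.arg(multimap_policy)
  sp <- table$species
  rows <- vector("list", nrow(sp))
  unmapped_idx <- logical(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    hits <- map_species(sp$sequence[i], locus)
    if (!nrow(hits)) {
      unmapped_idx[i] <- TRUE
      next
    }
    rows[[i]] <- data.frame(sequence = sp$sequence[i],
                            strand = hits$strand,
                            start = hits$start,
                            end = hits$end,
                            length = nchar(sp$sequence[i]),
                            count = sp$count[i],
                            n_placements = nrow(hits),
                            stringsAsFactors = FALSE)
  }
  alignments <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(alignments)) {
    alignments <- data.frame(sequence = character(), strand = character(),
                             start = integer(), end = integer(),
                             length = integer(), count = numeric(),
                             n_placements = integer(),
                             stringsAsFactors = FALSE)
  }
  mapped_set(sample_id = table$sample_id,
             alignments = alignments,
             unmapped = sp[unmapped_idx, c("sequence", "count"), drop = FALSE],
             locus_id = locus$id,
             locus_length = locus$length,
             multimap_policy = multimap_policy)
}

# Per-placement attribution weights.
# accounting = "track": weights used by position tracks / size histograms.
# accounting = "total": weights used by read-total accounting (each read
# counted once across its placements).
alignment_weights <- function(mapped, accounting = c("track", "total")) {
  accounting <- match.arg(accounting)
  al <- mapped$alignments
  if (!nrow(al)) return(numeric())
  switch(mapped$multimap_policy,
         all = if (accounting == "track") al$count else al$count / al$n_placements,
         fractional = al$count / al$n_placements,
         unique = ifelse(al$n_placements == 1L, al$count, 0))
}

#' Strand-resolved mapped read totals
#'
#' Read accounting in the style of a mapped-read summary table: how many
#' reads mapped on the sense strand, the antisense strand, and in total,
#' under the mapped set's multimap policy (each read counted at most
#' once).
#'
#' @param mapped A [mapped_set()].
#' @return Named numeric vector `c(sense, antisense, total)`.
#' @export
strand_read_totals <- function(mapped) {
  stopifnot(inherits(mapped, "mapped_set"))
  w <- alignment_weights(mapped, "total")
  sense <- sum(w[mapped$alignments$strand == "sense"])
  anti <- sum(w[mapped$alignments$strand == "antisense"])
  c(sense = sense, antisense = anti, total = sense + anti)
}

#' 5' end coordinate of each alignment
#'
#' Sense alignments have their 5' end at `start`; antisense alignments at
#' `end` (rightmost matched base).
#'
#' @param alignments The `alignments` data frame of a [mapped_set()].
#' @return Integer vector of 5'-end reference coordinates.
#' @export
five_prime_end <- function(alignments) {
  ifelse(alignments$strand == "sense", alignments$start, alignments$end)
}

#' Write a mapped set as TSV
#'
#' Columns: sequence, strand, start, end, length, count, n_placements.
#'
#' @param mapped A [mapped_set()].
#' @param path Output path.
#' @return Invisibly, the mapped set.
#' @export
write_mapped <- function(mapped, path) {
  write.table(mapped$alignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(mapped)
}
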