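#' Strand-resolved size distribution of mapped siRNAs
#'
#' Histogram of mapped read counts by insert length and strand over a
#' tabulated range (default 18--25 nt), with an `"other"` bin so that the
#' grand total reconciles with the mapped read total.
#'
#' @param mapped A [mapped_set()].
#' @param range Length-2 integer vector, inclusive tabulated range in nt.
#' @return `data.frame` with columns `length` (character; the range plus
#'   `"other"`), `sense`, `antisense`.
#' @export
size_distribution <- function(mapped, range = c(18L, 25L)) {
  stopifnot(inherits(mapped, "mapped_set"), length(range) == 2L,
            range[1L] <= range[2L])
  lens <- seq(range[1L], range[2L])
  bins <- c(as.character(lens), "other")
  out <- data.frame(length = bins,
                    sense = 0, antisense = 0,
                    stringsAsFactors = FALSE)
  al <- mapped$alignments
  if (nrow(al)) {
    w <- alignment_weights(mapped, "track")
    bin <- ifelse(al$length %in% lens, as.character(al$length), "other")
    for (str in c("sense", "antisense")) {
      agg <- tapply(w[al$strand == str], bin[al$strand == str], sum)
      out[[str]][match(names(agg), out$length)] <- as.numeric(agg)
    }
  }
  out
}

#' Per-position abundance track for one length class and strand
#'
#' Read counts indexed by the 5'-end reference coordinate of each
#' alignment of the requested length class and strand (sense: `start`;
#' antisense: `end`).
#'
#' @param mapped A [mapped_set()].
#' @param length Length class in nt (e.g. 21).
#' @param strand `"sense"` or `"antisense"`.
#' @return Numeric vector of length `L` (the locus length); position `i`
#'   holds the reads whose 5' end maps at coordinate `i`. Attributes
#'   `sample_id`, `length` and `strand` identify the track.
#' @export
position_track <- function(mapped, length, strand = c("sense", "antisense")) {
  stopifnot(inherits(mapped, "mapped_set"))
  strand <- match.arg(strand)
  track <- numeric(mapped$locus_length)
  al <- mapped$alignments
  keep <- al$length == length & al$strand == strand
  if (any(keep)) {
    w <- alignment_weights(mapped, "track")[keep]
    coord <- five_prime_end(al[keep, , drop = FALSE])
    agg <- tapply(w, coord, sum)
    track[as.integer(names(agg))] <- as.numeric(agg)
  }
  structure(track, sample_id = mapped$sample_id, length = length,
            strand = strand)
}

#' Attribution of mapped reads to locus features
#'
#' Each alignment is attributed to the feature containing its 5'-end
#' coordinate (one convention everywhere; the same 5'-end rule drives
#' position tracks, boundary distances and phase assignment).
#'
#' @param mapped A [mapped_set()].
#' @param locus The [reference_locus()] the set was mapped to.
#' @return `data.frame` with columns `feature`, `reads`, `fraction`
#'   (fractions sum to 1 over features plus `"unannotated"` when any
#'   reads mapped).
#' @export
feature_confinement <- function(mapped, locus) {
  stopifnot(inherits(mapped, "mapped_set"), inherits(locus, "reference_locus"))
  feats <- c(locus$features$name, "unannotated")
  out <- data.frame(feature = feats, reads = 0, fraction = 0,
                    stringsAsFactors = FALSE)
  al <- mapped$alignments
  if (nrow(al)) {
    w <- alignment_weights(mapped, "track")
    f <- feature_of(locus, five_prime_end(al))
    agg <- tapply(w, f, sum)
    out$reads[match(names(agg), out$feature)] <- as.numeric(agg)
    if (sum(out$reads) > 0) out$fraction <- out$reads / sum(out$reads)
  }
  out
}

#' Distance from a feature boundary to the nearest siRNA
#'
#' For each (strand, length class): the distance in nt from the first base
#' of the downstream feature (e.g. exon 2 at an intron--exon 2 boundary)
#' to the nearest qualifying alignment's boundary-proximal matched base,
#' where qualifying alignments lie fully within the downstream feature.
#' A distance of 0 means the alignment is flush with the boundary. For
#' antisense alignments the boundary-proximal base is the alignment's 3'
#' end, matching how antisense siRNA ends are annotated next to an
#' upstream boundary. Classes with no qualifying alignment are reported
#' as `NA`.
#'
#' @param mapped A [mapped_set()].
#' @param locus The [reference_locus()].
#' @param boundary Character vector `c(upstream, downstream)` of adjacent
#'   feature names.
#' @param lengths Length classes to report.
#' @return `data.frame` with columns `strand`, `length`, `distance`,
#'   `n_alignments` (number of qualifying alignments).
#' @export
boundary_distances <- function(mapped, locus,
                               boundary = c("intron", "exon2"),
                               lengths = c(21L, 22L)) {
  stopifnot(inherits(mapped, "mapped_set"), length(boundary) == 2L)
  bcoord <- boundary_coordinate(locus, boundary[1L], boundary[2L])
  dn <- locus$features[locus$features$name == boundary[2L], ]
  al <- mapped$alignments
  grid <- expand.grid(strand = c("sense", "antisense"), length = lengths,
                      stringsAsFactors = FALSE)
  grid$distance <- NA_integer_
  grid$n_alignments <- 0L
  for (i in seq_len(nrow(grid))) {
    keep <- al$strand == grid$strand[i] & al$length == grid$length[i] &
      al$start >= dn$start & al$end <= dn$end
    grid$n_alignments[i] <- sum(keep)
    if (any(keep)) grid$distance[i] <- min(al$start[keep]) - bcoord
  }
  grid
}

#' Classify siRNA species against two allele references
#'
#' Each species is perfect-match tested (both strands, full sequence)
#' against both references of an [allele_pair()]: species matching both
#' are `common`, those matching exactly one are `specific_a` /
#' `specific_b`, and those matching neither are `unplaced`. Testing the
#' whole species against each whole reference handles indels between
#' alleles without any coordinate lifting.
#'
#' @param table A [species_table()].
#' @param pair An [allele_pair()].
#' @return List of class `allele_classification` with elements `species`
#'   (`data.frame`: sequence, count, class) and `counts` (named species
#'   tally per class).
#' @export
classify_alleles <- function(table, pair) {
  stopifnot(inherits(table, "species_table"), inherits(pair, "allele_pair"))
  sp <- table$species
  cls <- character(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    in_a <- nrow(map_species(sp$sequence[i], pair$reference_a)) > 0L
    in_b <- nrow(map_species(sp$sequence[i], pair$reference_b)) > 0L
    cls[i] <- if (in_a && in_b) "common"
      else if (in_a) "specific_a"
      else if (in_b) "specific_b"
      else "unplaced"
  }
  species <- data.frame(sequence = sp$sequence, count = sp$count,
                        class = cls, stringsAsFactors = FALSE)
  lvls <- c("common", "specific_a", "specific_b", "unplaced")
  counts <- setNames(vapply(lvls, function(x) sum(cls == x), numeric(1)), lvls)
  structure(list(species = species, counts = counts,
                 label_a = pair$label_a, label_b = pair$label_b),
            class = "allele_classification")
}

#' @export
print.allele_classification <- function(x, ...) {
  cat(sprintf("<allele_classification> a = %s, b = %s\n", x$label_a, x$label_b))
  print(x$counts)
  invisible(x)
}
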