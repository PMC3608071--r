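#' Phase register of a 5'-end coordinate
#'
#' With a 21-nt phasing unit each strand has 21 possible registers
#' ("phases"). Phase 1 is anchored at the first nucleotide of the
#' reference for the sense strand and at the last nucleotide for the
#' antisense strand:
#' sense `p = ((coord - 1) mod u) + 1`,
#' antisense `p = ((L - coord) mod u) + 1`.
#'
#' @param coord Vector of 1-based 5'-end coordinates.
#' @param strand `"sense"` or `"antisense"`.
#' @param L Locus length in nt.
#' @param unit Phasing unit length in nt (default 21).
#' @return Integer vector of phases in `[1, unit]`.
#' @export
phase_of <- function(coord, strand = c("sense", "antisense"), L,
                     unit = 21L) {
  strand <- match.arg(strand)
  coord <- as.integer(coord)
  if (any(is.na(coord)) || any(coord < 1L) || any(coord > L)) {
    stop(sprintf("coordinate out of range [1, %d]", L))
  }
  if (strand == "sense") ((coord - 1L) %% unit) + 1L
  else ((L - coord) %% unit) + 1L
}

#' Cycle positions of one (strand, phase)
#'
#' The arithmetic progression of 5'-end coordinates, step `unit`,
#' belonging to a phase, ordered 5'->3' along the strand (ascending for
#' sense, descending for antisense).
#'
#' @inheritParams phase_of
#' @param phase Phase in `[1, unit]`.
#' @return Integer vector of coordinates.
#' @export
cycle_positions <- function(strand = c("sense", "antisense"), phase, L,
                            unit = 21L) {
  strand <- match.arg(strand)
  stopifnot(phase >= 1L, phase <= unit)
  if (strand == "sense") seq.int(phase, L, by = unit)
  else seq.int(L - (phase - 1L), 1L, by = -unit)
}

# read depth of `length`-nt 5' ends per coordinate for one strand
five_prime_depth <- function(mapped, strand, length = 21L) {
  al <- mapped$alignments
  keep <- al$strand == strand & al$length == length
  depth <- numeric(mapped$locus_length)
  if (any(keep)) {
    w <- alignment_weights(mapped, "track")[keep]
    coord <- five_prime_end(al[keep, , drop = FALSE])
    agg <- tapply(w, coord, sum)
    depth[as.integer(names(agg))] <- as.numeric(agg)
  }
  depth
}

#' Occupied cycle positions of one phase
#'
#' A cycle position is occupied when at least `min_depth` reads of a
#' `length`-nt siRNA have their 5' end exactly there (presence/absence
#' analysis; depth 1 suffices by default).
#'
#' @param mapped A [mapped_set()].
#' @inheritParams cycle_positions
#' @param length siRNA length class gating occupancy (21-nt only by
#'   default; other lengths do not count).
#' @param min_depth Minimum read depth for a cycle position to count.
#' @return `data.frame` with columns `coord`, `reads`, ordered 5'->3'
#'   along the strand.
#' @export
occupancy <- function(mapped, strand = c("sense", "antisense"), phase,
                      length = 21L, unit = 21L, min_depth = 1) {
  stopifnot(inherits(mapped, "mapped_set"))
  strand <- match.arg(strand)
  depth <- five_prime_depth(mapped, strand, length)
  cyc <- cycle_positions(strand, phase, mapped$locus_length, unit)
  occ <- depth[cyc] >= min_depth
  data.frame(coord = cyc[occ], reads = depth[cyc][occ])
}

#' Call phased siRNA producing regions
#'
#' A phased region is a maximal run of at least `min_units` consecutive
#' occupied cycle positions within one (strand, phase); its span is
#' `unit * n_units` nt. Coordinates are reported both strand-relative
#' (`first_unit_coord` / `last_unit_coord` are the 5'-end coordinates of
#' the first and last unit along the strand; `five_prime_coord` repeats
#' the first, `three_prime_coord` is the last unit's terminal base) and
#' absolute (`left` / `right` on the reference).
#'
#' @param mapped A [mapped_set()].
#' @param strand `"sense"` or `"antisense"`.
#' @param min_units Minimum run length in units (default 3).
#' @param length,unit,min_depth See [occupancy()].
#' @return `data.frame` with one row per region, sorted by
#'   (phase, first_unit_coord): columns `strand`, `phase`,
#'   `first_unit_coord`, `last_unit_coord`, `n_units`, `span`, `left`,
#'   `right`, `five_prime_coord`, `three_prime_coord`.
#' @export
call_phased_regions <- function(mapped, strand = c("sense", "antisense"),
                                min_units = 3L, length = 21L, unit = 21L,
                                min_depth = 1) {
  stopifnot(inherits(mapped, "mapped_set"))
  strand <- match.arg(strand)
  rows <- list()
  for (phase in seq_len(unit)) {
    occ <- occupancy(mapped, strand, phase, length, unit, min_depth)
    if (!nrow(occ)) next
    # cycle index along the strand (consecutive units differ by 1)
    idx <- if (strand == "sense") (occ$coord - phase) %/% unit
           else (mapped$locus_length - (phase - 1L) - occ$coord) %/% unit
    o <- order(idx)
    idx <- idx[o]
    coord <- occ$coord[o]
    run <- cumsum(c(1L, diff(idx) != 1L))
    for (r in split(seq_along(idx), run)) {
      n_units <- base::length(r)
      if (n_units < min_units) next
      first <- coord[r[1L]]
      last <- coord[r[n_units]]
      if (strand == "sense") {
        left <- first; right <- last + unit - 1L; three <- last + unit - 1L
      } else {
        left <- last - unit + 1L; right <- first; three <- last - unit + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        strand = strand, phase = phase,
        first_unit_coord = first, last_unit_coord = last,
        n_units = n_units, span = unit * n_units,
        left = left, right = right,
        five_prime_coord = first, three_prime_coord = three,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(strand = character(), phase = integer(),
                      first_unit_coord = integer(), last_unit_coord = integer(),
                      n_units = integer(), span = integer(),
                      left = integer(), right = integer(),
                      five_prime_coord = integer(),
                      three_prime_coord = integer(),
                      stringsAsFactors = FALSE)
  } else {
    out <- out[order(out$phase, out$first_unit_coord), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Phasing score track (Howell-style)
#'
#' Within a sliding window of `window_cycles` consecutive cycle positions
#' of one phase, let `P` be the total reads at in-phase positions, `U`
#' the total reads at out-of-phase positions inside the window footprint,
#' and `k` the number of occupied in-phase cycle positions. The window
#' score is `(k - 2) * ln(1 + factor * P / (1 + U))` when
#' `k >= min_occupied` (default 3), else 0. Each cycle position is
#' assigned the maximum score over all full windows containing it, so a
#' clean run of three or more occupied units scores positive throughout.
#' The window is clamped to the number of available cycles on short loci.
#'
#' @param mapped A [mapped_set()].
#' @param strand `"sense"` or `"antisense"`.
#' @param window_cycles Window length in cycles (default 9).
#' @param length,unit See [occupancy()].
#' @param factor Multiplier on the in-phase/out-of-phase ratio
#'   (default 10).
#' @param min_occupied Minimum occupied in-phase cycles for a nonzero
#'   window score (default 3).
#' @return `data.frame` with columns `strand`, `phase`, `cycle`
#'   (1-based index along the strand), `coord`, `reads` (in-phase reads
#'   at the cycle position) and `score`.
#' @export
phasing_score <- function(mapped, strand = c("sense", "antisense"),
                          window_cycles = 9L, length = 21L, unit = 21L,
                          factor = 10, min_occupied = 3L) {
  stopifnot(inherits(mapped, "mapped_set"))
  strand <- match.arg(strand)
  L <- mapped$locus_length
  depth <- five_prime_depth(mapped, strand, length)
  out <- list()
  for (phase in seq_len(unit)) {
    cyc <- cycle_positions(strand, phase, L, unit)
    n <- base::length(cyc)
    if (!n) next
    w <- min(window_cycles, n)
    in_reads <- depth[cyc]
    score <- numeric(n)
    for (s in seq_len(n - w + 1L)) {
      idx <- s:(s + w - 1L)
      P <- sum(in_reads[idx])
      k <- sum(in_reads[idx] > 0)
      if (k >= min_occupied) {
        foot <- if (strand == "sense") {
          cyc[s]:min(L, cyc[s + w - 1L] + unit - 1L)
        } else {
          max(1L, cyc[s + w - 1L] - unit + 1L):cyc[s]
        }
        U <- sum(depth[foot]) - P
        ws <- (k - 2) * log(1 + factor * P / (1 + U))
      } else ws <- 0
      score[idx] <- pmax(score[idx], ws)
    }
    out[[phase]] <- data.frame(strand = strand, phase = phase,
                               cycle = seq_len(n), coord = cyc,
                               reads = in_reads, score = score,
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Conservation of phased-region ends across samples
#'
#' A region end in sample B is conserved when some region in sample A on
#' the same strand has the identical coordinate (5' ends compared with 5'
#' ends, 3' with 3'; exact identity by default -- neighboring phases
#' offset by a single nucleotide count as distinct). A tolerance in nt is
#' available for exploration.
#'
#' @param regions_a,regions_b [call_phased_regions()] results from the
#'   same locus (A is the sample conserved ends are looked up in; counts
#'   are reported for B's regions).
#' @param tolerance Maximum coordinate difference still counted as
#'   conserved (default 0).
#' @return List with `regions` (B's regions plus logical columns
#'   `five_conserved`, `three_conserved`) and `summary` (`data.frame`
#'   per strand: `n_regions`, `n_five_conserved`, `n_three_conserved`).
#' @export
end_conservation <- function(regions_a, regions_b, tolerance = 0L) {
  conserved <- function(x, pool) {
    if (!length(pool)) return(rep(FALSE, length(x)))
    vapply(x, function(v) any(abs(pool - v) <= tolerance), logical(1))
  }
  regions_b$five_conserved <- FALSE
  regions_b$three_conserved <- FALSE
  for (str in unique(regions_b$strand)) {
    bi <- regions_b$strand == str
    ai <- regions_a$strand == str
    regions_b$five_conserved[bi] <-
      conserved(regions_b$five_prime_coord[bi], regions_a$five_prime_coord[ai])
    regions_b$three_conserved[bi] <-
      conserved(regions_b$three_prime_coord[bi], regions_a$three_prime_coord[ai])
  }
  strands <- unique(regions_b$strand)
  summary <- data.frame(
    strand = strands,
    n_regions = vapply(strands, function(s) sum(regions_b$strand == s), numeric(1)),
    n_five_conserved = vapply(strands, function(s)
      sum(regions_b$five_conserved[regions_b$strand == s]), numeric(1)),
    n_three_conserved = vapply(strands, function(s)
      sum(regions_b$three_conserved[regions_b$strand == s]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(regions = regions_b, summary = summary)
}

#' Per-phase summary of called regions
#'
#' One row per (strand, phase) -- including phases with zero regions --
#' with the number of regions, total and maximum contiguous units, and
#' the extreme 5' / 3' coordinates along the strand (most-upstream 5'
#' end, most-downstream 3' end; `NA` when the phase has no region).
#'
#' @param regions A [call_phased_regions()] result (may mix strands).
#' @param unit Phasing unit (number of phases per strand).
#' @param strands Strands to tabulate.
#' @return `data.frame` with columns `strand`, `phase`, `n_regions`,
#'   `total_units`, `max_units`, `five_prime_extreme`,
#'   `three_prime_extreme`.
#' @export
phase_summary <- function(regions, unit = 21L,
                          strands = c("sense", "antisense")) {
  grid <- expand.grid(phase = seq_len(unit), strand = strands,
                      stringsAsFactors = FALSE)[, c("strand", "phase")]
  grid$n_regions <- 0L
  grid$total_units <- 0L
  grid$max_units <- 0L
  grid$five_prime_extreme <- NA_integer_
  grid$three_prime_extreme <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    r <- regions[regions$strand == grid$strand[i] &
                   regions$phase == grid$phase[i], , drop = FALSE]
    if (!nrow(r)) next
    grid$n_regions[i] <- nrow(r)
    grid$total_units[i] <- sum(r$n_units)
    grid$max_units[i] <- max(r$n_units)
    if (grid$strand[i] == "sense") {
      grid$five_prime_extreme[i] <- min(r$five_prime_coord)
      grid$three_prime_extreme[i] <- max(r$three_prime_coord)
    } else {
      grid$five_prime_extreme[i] <- max(r$five_prime_coord)
      grid$three_prime_extreme[i] <- min(r$three_prime_coord)
    }
  }
  grid
}
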