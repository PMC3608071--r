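#' Species of one length class and strand, ranked by abundance
#'
#' Extracts the siRNA species of a given length class and strand from a
#' mapped set, applies the abundance filter (strictly more than
#' `min_reads_exclusive` reads, i.e. the ">5 reads" rule with the
#' default), and ranks by count descending with average ranks for ties.
#' Rows are ordered by count descending then sequence (lexicographic
#' tie-break for deterministic top-N membership); the `position` column
#' gives that deterministic 1..n ordering while `rank` carries
#' tie-averaged ranks.
#'
#' @param mapped A [mapped_set()].
#' @param length Length class in nt (default 21).
#' @param strand `"sense"` or `"antisense"`.
#' @param min_reads_exclusive Retain species with `count >` this value;
#'   use 0 to keep all species.
#' @return `data.frame` with columns `sequence`, `strand`, `count`,
#'   `rank`, `position`.
#' @export
rank_species <- function(mapped, length = 21L,
                         strand = c("sense", "antisense"),
                         min_reads_exclusive = 5) {
  stopifnot(inherits(mapped, "mapped_set"))
  strand <- match.arg(strand)
  al <- mapped$alignments
  keep <- al$length == length & al$strand == strand
  sp <- unique(al[keep, c("sequence", "count"), drop = FALSE])
  sp <- sp[sp$count > min_reads_exclusive, , drop = FALSE]
  sp <- sp[order(-sp$count, sp$sequence), , drop = FALSE]
  rownames(sp) <- NULL
  data.frame(sequence = sp$sequence,
             strand = if (nrow(sp)) strand else character(),
             count = sp$count,
             rank = if (nrow(sp)) rank(-sp$count, ties.method = "average") else numeric(),
             position = seq_len(nrow(sp)),
             stringsAsFactors = FALSE)
}

#' Read coverage of the abundance filter (value B / value A)
#'
#' `value_a` is the total number of reads of the length class on the
#' strand; `value_b` is the total restricted to species passing the
#' abundance filter. Their ratio says what fraction of the signal the
#' filtered species carry (conventionally reported to 3 decimals).
#'
#' @inheritParams rank_species
#' @return List with `value_a`, `value_b`, `ratio` (`NA` when
#'   `value_a == 0`).
#' @export
coverage_fraction <- function(mapped, length = 21L,
                              strand = c("sense", "antisense"),
                              min_reads_exclusive = 5) {
  strand <- match.arg(strand)
  all_sp <- rank_species(mapped, length, strand, min_reads_exclusive = 0)
  value_a <- sum(all_sp$count)
  value_b <- sum(all_sp$count[all_sp$count > min_reads_exclusive])
  list(value_a = value_a, value_b = value_b,
       ratio = if (value_a > 0) value_b / value_a else NA_real_)
}

#' Where do one sample's most abundant species rank in another sample?
#'
#' For each of ranking `a`'s top `n` species (deterministic `position`
#' ordering), reports its position in ranking `b` (`NA` when absent), and
#' summarises: `n_found` of `n` were found in `b`, all within `b`'s top
#' `k_within` (the maximum position in `b` among the found species).
#'
#' @param ranked_a,ranked_b Results of [rank_species()].
#' @param n Number of top species of `a` to look up (clamped with a
#'   warning when `a` has fewer).
#' @return List with `table` (`sequence`, `count_a`, `position_a`,
#'   `position_b`), `n`, `n_found`, `k_within`.
#' @export
top_n_overlap <- function(ranked_a, ranked_b, n = 20L) {
  stopifnot(nrow(ranked_a) > 0L, nrow(ranked_b) > 0L)
  if (n > nrow(ranked_a)) {
    warning(sprintf("n = %d exceeds the %d ranked species; clamping",
                    n, nrow(ranked_a)))
    n <- nrow(ranked_a)
  }
  top <- ranked_a[seq_len(n), , drop = FALSE]
  pos_b <- ranked_b$position[match(top$sequence, ranked_b$sequence)]
  list(table = data.frame(sequence = top$sequence,
                          count_a = top$count,
                          position_a = top$position,
                          position_b = pos_b,
                          stringsAsFactors = FALSE),
       n = n,
       n_found = sum(!is.na(pos_b)),
       k_within = if (any(!is.na(pos_b))) max(pos_b, na.rm = TRUE) else NA_integer_)
}

#' Spearman rank correlation of species abundances across two samples
#'
#' Computed on the species present in BOTH rankings (which are normally
#' already abundance-filtered by [rank_species()]). In the default
#' `"rerank"` mode the common species are re-ranked within the common set
#' (average ranks for ties) before correlating -- equivalent to a Spearman
#' correlation of the two count vectors. In `"global"` mode each sample's
#' original tie-averaged ranks are carried into the common set and
#' Pearson-correlated. The p-value comes from [stats::cor.test()] (exact
#' for small tie-free samples, t-approximation otherwise) in rerank mode,
#' and from the t-approximation in global mode.
#'
#' @param ranked_a,ranked_b Results of [rank_species()].
#' @param mode `"rerank"` (default) or `"global"`.
#' @param min_common Minimum number of common species required (an error
#'   is raised below it).
#' @return List with `rs`, `n_common`, `p_value`, `mode`.
#' @export
spearman_rank_correlation <- function(ranked_a, ranked_b,
                                      mode = c("rerank", "global"),
                                      min_common = 3L) {
  mode <- match.arg(mode)
  common <- intersect(ranked_a$sequence, ranked_b$sequence)
  n <- length(common)
  if (n < min_common) {
    stop(sprintf("insufficient common species (%d < %d)", n, min_common))
  }
  ia <- match(common, ranked_a$sequence)
  ib <- match(common, ranked_b$sequence)
  if (mode == "rerank") {
    ct <- suppressWarnings(
      cor.test(ranked_a$count[ia], ranked_b$count[ib], method = "spearman"))
    rs <- unname(ct$estimate)
    p <- ct$p.value
  } else {
    ra <- ranked_a$rank[ia]
    rb <- ranked_b$rank[ib]
    rs <- cor(ra, rb)
    tstat <- rs * sqrt((n - 2) / max(1 - rs^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rs = rs, n_common = n, p_value = p, mode = mode)
}

#' Full commonality report for one length class and strand
#'
#' Bundles the per-sample read accounting (value A / value B / coverage),
#' species tallies, top-N overlap and Spearman rank correlation for a
#' pair of samples.
#'
#' @param mapped_a,mapped_b [mapped_set()] objects for the two samples.
#' @param length Length class in nt.
#' @param strand `"sense"` or `"antisense"`.
#' @param min_reads_exclusive Abundance filter (strictly greater than).
#' @param top_n Top-N overlap size.
#' @param mode Spearman mode, see [spearman_rank_correlation()].
#' @return List of class `commonality_report`.
#' @export
commonality_report <- function(mapped_a, mapped_b, length = 21L,
                               strand = c("sense", "antisense"),
                               min_reads_exclusive = 5, top_n = 20L,
                               mode = c("rerank", "global")) {
  strand <- match.arg(strand)
  mode <- match.arg(mode)
  ranked <- list(a = rank_species(mapped_a, length, strand, min_reads_exclusive),
                 b = rank_species(mapped_b, length, strand, min_reads_exclusive))
  cov <- list(a = coverage_fraction(mapped_a, length, strand, min_reads_exclusive),
              b = coverage_fraction(mapped_b, length, strand, min_reads_exclusive))
  n_all <- c(a = nrow(rank_species(mapped_a, length, strand, 0)),
             b = nrow(rank_species(mapped_b, length, strand, 0)))
  overlap <- if (nrow(ranked$a) && nrow(ranked$b)) {
    top_n_overlap(ranked$a, ranked$b, top_n)
  }
  rs <- tryCatch(
    spearman_rank_correlation(ranked$a, ranked$b, mode = mode),
    error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      list(rs = NA_real_, n_common = length(intersect(ranked$a$sequence,
                                                      ranked$b$sequence)),
           p_value = NA_real_, mode = mode)
    })
  structure(list(length = length, strand = strand,
                 min_reads_exclusive = min_reads_exclusive,
                 samples = c(a = mapped_a$sample_id, b = mapped_b$sample_id),
                 coverage = cov,
                 n_species = n_all,
                 n_species_above_threshold = c(a = nrow(ranked$a),
                                               b = nrow(ranked$b)),
                 ranked = ranked,
                 top_n_overlap = overlap,
                 spearman = rs),
            class = "commonality_report")
}

#' @export
print.commonality_report <- function(x, ...) {
  cat(sprintf("<commonality_report> %d-nt %s strand: %s vs %s\n",
              x$length, x$strand, x$samples[["a"]], x$samples[["b"]]))
  cat(sprintf("  coverage (B/A): %s = %.3f, %s = %.3f\n",
              x$samples[["a"]], x$coverage$a$ratio,
              x$samples[["b"]], x$coverage$b$ratio))
  cat(sprintf("  species > %g reads: %d and %d (%d common); rs = %.3f (p = %.3g)\n",
              x$min_reads_exclusive,
              x$n_species_above_threshold[["a"]],
              x$n_species_above_threshold[["b"]],
              x$spearman$n_common, x$spearman$rs, x$spearman$p_value))
  invisible(x)
}
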