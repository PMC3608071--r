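#' Default phased trains planted by the simulator
#'
#' Three trains echoing the structure seen in silenced petal libraries: a
#' long 19-unit antisense train, a 12-unit sense train and a shorter
#' 8-unit antisense train, all confined to exon 2. `first_unit_coord`
#' `NA` means the train is auto-placed on a free cycle position of its
#' (strand, phase).
#'
#' @return `data.frame` with columns `strand`, `phase`, `n_units`,
#'   `depth`, `first_unit_coord`.
#' @export
default_phased_trains <- function() {
  data.frame(strand = c("antisense", "sense", "antisense"),
             phase = c(10L, 12L, 11L),
             n_units = c(19L, 12L, 8L),
             depth = c(25, 20, 15),
             first_unit_coord = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Design of a synthetic small RNA library
#'
#' Encodes the statistical structure the analysis assumes: a size-class
#' mixture dominated by 21-nt then 22-nt species, an antisense excess,
#' uneven hot spots confined to exon 2 with heavy-tailed (log-normal)
#' species abundances, phased 21-nt unit trains, a thin uniform
#' background, and reads emitted as insert + 3' adapter.
#'
#' @param n_reads Total reads in the library.
#' @param size_mixture Named proportions over insert lengths (must sum
#'   to 1).
#' @param antisense_fraction Probability a species is antisense.
#' @param n_species Number of hot-spot species drawn (0 disables the
#'   hot-spot layer).
#' @param n_hotspots Number of hot-spot centers.
#' @param hotspot_sdlog Log-normal sd of hot-spot weights.
#' @param abundance_sdlog Log-normal sd of per-species abundance around
#'   its hot-spot weight.
#' @param position_jitter_sd Gaussian sd (nt) of species 5' ends around
#'   their hot-spot center.
#' @param phased_trains `data.frame` as in [default_phased_trains()];
#'   use a zero-row frame for no trains.
#' @param background_fraction Fraction of reads from a uniform
#'   background over the whole locus (depth 1 species; the "leaky"
#'   negative-control layer).
#' @param confine Feature name hot spots and trains are confined to
#'   (`NULL` for the whole locus).
#' @param adapter 3' adapter appended to every insert.
#' @param read_length Sequencer read length in nt; inserts are padded
#'   with adapter (then `A`) and truncated to this length.
#' @param error_rate Per-base substitution rate applied to emitted reads
#'   (0 by default: perfect-match mapping would silently drop erroneous
#'   reads, so errors are only useful to exercise unmapped accounting).
#' @param format `"fastq"` or `"fasta"` output.
#' @return Object of class `sirna_design`.
#' @export
sirna_design <- function(n_reads = 20000L,
                         size_mixture = c(`18` = 0.01, `19` = 0.015,
                                          `20` = 0.025, `21` = 0.62,
                                          `22` = 0.17, `23` = 0.04,
                                          `24` = 0.08, `25` = 0.04),
                         antisense_fraction = 0.7,
                         n_species = 400L,
                         n_hotspots = 10L,
                         hotspot_sdlog = 1,
                         abundance_sdlog = 1.5,
                         position_jitter_sd = 4,
                         phased_trains = default_phased_trains(),
                         background_fraction = 0.002,
                         confine = "exon2",
                         adapter = "TCGTATGCCGTCTTCTGCTTG",
                         read_length = 52L,
                         error_rate = 0,
                         format = c("fastq", "fasta")) {
  format <- match.arg(format)
  stopifnot(n_reads >= 0, abs(sum(size_mixture) - 1) < 1e-8,
            antisense_fraction >= 0, antisense_fraction <= 1,
            background_fraction >= 0, background_fraction < 1,
            nchar(adapter) > 0, read_length >= 15L,
            error_rate >= 0, error_rate < 1,
            is.data.frame(phased_trains))
  structure(list(n_reads = as.integer(n_reads), size_mixture = size_mixture,
                 antisense_fraction = antisense_fraction,
                 n_species = as.integer(n_species),
                 n_hotspots = as.integer(n_hotspots),
                 hotspot_sdlog = hotspot_sdlog,
                 abundance_sdlog = abundance_sdlog,
                 position_jitter_sd = position_jitter_sd,
                 phased_trains = phased_trains,
                 background_fraction = background_fraction,
                 confine = confine, adapter = toupper(adapter),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, format = format),
            class = "sirna_design")
}

#' Generate a random annotated locus
#'
#' Random ACGT sequence carrying the canonical five-feature annotation
#' (5' upstream, exon 1, intron, exon 2, 3' downstream) or any custom
#' named feature lengths; the features tile the sequence end to end.
#' Deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param feature_lengths Integer vector of feature lengths in nt
#'   (all `>= 1`); default 200/180/300/1200/200 giving a 2080-nt locus.
#' @param id Locus identifier.
#' @return A [reference_locus()].
#' @export
generate_locus <- function(seed,
                           feature_lengths = c(five_prime_upstream = 200L,
                                               exon1 = 180L, intron = 300L,
                                               exon2 = 1200L,
                                               three_prime_downstream = 200L),
                           id = "synthetic_locus") {
  if (any(feature_lengths < 1L)) stop("feature lengths must be >= 1")
  if (is.null(names(feature_lengths))) {
    names(feature_lengths) <- if (length(feature_lengths) == 5L) {
      c("five_prime_upstream", "exon1", "intron", "exon2",
        "three_prime_downstream")
    } else paste0("feature", seq_along(feature_lengths))
  }
  L <- sum(feature_lengths)
  sequence <- withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
  ends <- cumsum(feature_lengths)
  starts <- ends - feature_lengths + 1L
  reference_locus(id, sequence,
                  data.frame(name = names(feature_lengths),
                             start = as.integer(starts),
                             end = as.integer(ends),
                             stringsAsFactors = FALSE))
}

# region (start, end) the design confines planted signal to
confine_region <- function(design, locus) {
  if (is.null(design$confine)) return(c(1L, locus$length))
  f <- locus$features[locus$features$name == design$confine, ]
  if (nrow(f) != 1L) {
    stop(sprintf("confinement feature '%s' not in the locus annotation",
                 design$confine))
  }
  c(f$start, f$end)
}

# resolve train placements onto concrete cycle positions inside `region`
place_trains <- function(trains, locus, region, unit = 21L) {
  if (!nrow(trains)) {
    trains$last_unit_coord <- integer()
    return(trains)
  }
  L <- locus$length
  if (!"first_unit_coord" %in% names(trains)) {
    trains$first_unit_coord <- NA_integer_
  }
  trains$first_unit_coord <- as.integer(trains$first_unit_coord)
  trains$last_unit_coord <- NA_integer_
  placed_units <- list()  # per (strand:phase) unit coords already used
  for (i in seq_len(nrow(trains))) {
    str <- trains$strand[i]; phase <- trains$phase[i]
    n <- trains$n_units[i]
    cyc <- cycle_positions(str, phase, L, unit)
    fits <- if (str == "sense") {
      cyc >= region[1L] & cyc + unit * (n - 1L) + unit - 1L <= region[2L]
    } else {
      cyc <= region[2L] & cyc - unit * (n - 1L) - unit + 1L >= region[1L]
    }
    cand <- cyc[fits]
    key <- paste(str, phase)
    used <- placed_units[[key]]
    if (!is.null(used)) {
      clear <- vapply(cand, function(c0) {
        units <- if (str == "sense") c0 + unit * (0:(n - 1L))
                 else c0 - unit * (0:(n - 1L))
        all(abs(outer(units, used, "-")) >= 2L * unit)
      }, logical(1))
      cand <- cand[clear]
    }
    c0 <- trains$first_unit_coord[i]
    if (is.na(c0)) {
      if (!length(cand)) {
        stop(sprintf("no room for a %d-unit train (strand %s, phase %d) in [%d, %d]",
                     n, str, phase, region[1L], region[2L]))
      }
      c0 <- if (length(cand) == 1L) cand else sample(cand, 1L)
    } else if (!(c0 %in% cyc[fits])) {
      stop(sprintf("first_unit_coord %d invalid for strand %s phase %d train of %d units",
                   c0, str, phase, n))
    }
    units <- if (str == "sense") c0 + unit * (0:(n - 1L))
             else c0 - unit * (0:(n - 1L))
    placed_units[[key]] <- c(used, units)
    trains$first_unit_coord[i] <- c0
    trains$last_unit_coord[i] <- units[n]
  }
  trains
}

# sequence of a species from its 5' coordinate, length and strand
species_sequence <- function(locus, five, len, strand) {
  start <- ifelse(strand == "sense", five, five - len + 1L)
  end <- ifelse(strand == "sense", five + len - 1L, five)
  seqs <- substring(locus$sequence, start, end)
  anti <- strand == "antisense"
  if (any(anti)) seqs[anti] <- revcomp(seqs[anti])
  seqs
}

train_species <- function(trains, locus, unit = 21L) {
  rows <- lapply(seq_len(nrow(trains)), function(i) {
    n <- trains$n_units[i]
    dir <- if (trains$strand[i] == "sense") 1L else -1L
    five <- trains$first_unit_coord[i] + dir * unit * (0:(n - 1L))
    data.frame(five_prime = five, length = unit,
               strand = trains$strand[i], count = trains$depth[i],
               origin = "train", stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(five_prime = integer(), length = integer(),
                     strand = character(), count = numeric(),
                     origin = character(), stringsAsFactors = FALSE)
  }
  df
}

sample_lengths <- function(n, size_mixture) {
  as.integer(sample(names(size_mixture), n, replace = TRUE,
                    prob = size_mixture))
}

# species universe for the hot-spot layer: positions, lengths, strands and
# a shared log-abundance (hot-spot weight x species log-normal draw)
hotspot_universe <- function(design, locus, region, sdlog) {
  n <- design$n_species
  if (n <= 0L) {
    return(data.frame(five_prime = integer(), length = integer(),
                      strand = character(), logmu = numeric(),
                      stringsAsFactors = FALSE))
  }
  centers <- sample(seq.int(region[1L], region[2L]), design$n_hotspots)
  hw <- rlnorm(design$n_hotspots, 0, design$hotspot_sdlog)
  h <- sample.int(design$n_hotspots, n, replace = TRUE, prob = hw)
  len <- sample_lengths(n, design$size_mixture)
  strand <- ifelse(stats::runif(n) < design$antisense_fraction,
                   "antisense", "sense")
  five <- centers[h] + as.integer(round(rnorm(n, 0, design$position_jitter_sd)))
  lo <- ifelse(strand == "sense", region[1L], region[1L] + len - 1L)
  hi <- ifelse(strand == "sense", region[2L] - len + 1L, region[2L])
  five <- pmin(pmax(five, lo), hi)
  df <- data.frame(five_prime = five, length = len, strand = strand,
                   logmu = log(hw[h]) + rnorm(n, 0, sdlog),
                   stringsAsFactors = FALSE)
  # merge duplicated placements (same species drawn twice)
  key <- paste(df$five_prime, df$length, df$strand)
  if (anyDuplicated(key)) {
    agg <- tapply(exp(df$logmu), key, sum)
    df <- df[!duplicated(key), , drop = FALSE]
    df$logmu <- log(as.numeric(agg[paste(df$five_prime, df$length,
                                         df$strand)]))
  }
  rownames(df) <- NULL
  df
}

background_species <- function(n_bg, design, locus) {
  if (n_bg <= 0L) {
    return(data.frame(five_prime = integer(), length = integer(),
                      strand = character(), count = numeric(),
                      origin = character(), stringsAsFactors = FALSE))
  }
  len <- sample_lengths(n_bg, design$size_mixture)
  strand <- ifelse(stats::runif(n_bg) < design$antisense_fraction,
                   "antisense", "sense")
  lo <- ifelse(strand == "sense", 1L, len)
  hi <- ifelse(strand == "sense", locus$length - len + 1L, locus$length)
  five <- lo + as.integer(floor(stats::runif(n_bg) * (hi - lo + 1L)))
  df <- data.frame(five_prime = five, length = len, strand = strand,
                   count = 1, origin = "background",
                   stringsAsFactors = FALSE)
  aggregate_species_rows(df)
}

# rescale expected species abundances so the expected read mass of each
# (length, strand) cell matches the design mixture (renormalized over the
# cells that received at least one species); within a cell the heavy-tailed
# relative abundances are untouched
balance_classes <- function(lam, len, strand, design) {
  cell <- paste(len, strand)
  target <- unname(design$size_mixture[as.character(len)]) *
    ifelse(strand == "antisense", design$antisense_fraction,
           1 - design$antisense_fraction)
  tot_target <- sum(target[!duplicated(cell)])
  cell_sum <- tapply(lam, cell, sum)
  lam * (target / tot_target) / as.numeric(cell_sum[cell])
}

aggregate_species_rows <- function(df) {
  if (!nrow(df)) return(df)
  key <- paste(df$five_prime, df$length, df$strand)
  if (anyDuplicated(key)) {
    cnt <- tapply(df$count, key, sum)
    org <- tapply(df$origin, key, function(x)
      paste(sort(unique(x)), collapse = "+"))
    df <- df[!duplicated(key), , drop = FALSE]
    k <- paste(df$five_prime, df$length, df$strand)
    df$count <- as.numeric(cnt[k])
    df$origin <- as.character(org[k])
  }
  rownames(df) <- NULL
  df
}

# turn planted rows into the ground-truth species table (adds sequences,
# merges rows that collapse to the same sequence)
finalize_species <- function(rows, locus) {
  rows <- rows[rows$count > 0, , drop = FALSE]
  if (!nrow(rows)) {
    return(data.frame(sequence = character(), strand = character(),
                      five_prime = integer(), length = integer(),
                      count = numeric(), origin = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- aggregate_species_rows(rows)
  rows$sequence <- species_sequence(locus, rows$five_prime, rows$length,
                                    rows$strand)
  if (anyDuplicated(rows$sequence)) {
    cnt <- tapply(rows$count, rows$sequence, sum)
    rows <- rows[!duplicated(rows$sequence), , drop = FALSE]
    rows$count <- as.numeric(cnt[rows$sequence])
  }
  rows <- rows[order(-rows$count, rows$sequence),
               c("sequence", "strand", "five_prime", "length", "count",
                 "origin"), drop = FALSE]
  rownames(rows) <- NULL
  rows
}

truth_totals <- function(species, locus) {
  by_ls <- if (nrow(species)) {
    stats::aggregate(count ~ length + strand, species, sum)
  } else data.frame(length = integer(), strand = character(),
                    count = numeric())
  by_feature <- if (nrow(species)) {
    f <- feature_of(locus, species$five_prime)
    agg <- tapply(species$count, f, sum)
    data.frame(feature = names(agg), reads = as.numeric(agg),
               stringsAsFactors = FALSE)
  } else data.frame(feature = character(), reads = numeric())
  list(total_reads = sum(species$count),
       strand_reads = c(
         sense = sum(species$count[species$strand == "sense"]),
         antisense = sum(species$count[species$strand == "antisense"])),
       by_length_strand = by_ls,
       by_feature = by_feature)
}

apply_sequencing_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  vapply(reads, function(r) {
    bases <- strsplit(r, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(bases)) < error_rate)
    if (length(hit)) {
      for (j in hit) bases[j] <- sample(setdiff(c("A", "C", "G", "T"),
                                                bases[j]), 1L)
    }
    paste(bases, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

emit_reads <- function(species, design) {
  inserts <- rep(species$sequence, times = round(species$count))
  if (!length(inserts)) return(character())
  raw <- substr(paste0(inserts, design$adapter,
                       strrep("A", design$read_length)),
                1L, design$read_length)
  raw <- apply_sequencing_errors(raw, design$error_rate)
  raw[sample.int(length(raw))]
}

write_reads <- function(reads, path, format, prefix = "sr") {
  n <- length(reads)
  ids <- sprintf("%s%06d", prefix, seq_len(n))
  if (format == "fastq") {
    lines <- character(4L * n)
    lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", ids)
    lines[seq(2L, by = 4L, length.out = n)] <- reads
    lines[seq(3L, by = 4L, length.out = n)] <- "+"
    lines[seq(4L, by = 4L, length.out = n)] <- strrep("I", nchar(reads))
  } else {
    lines <- character(2L * n)
    lines[seq(1L, by = 2L, length.out = n)] <- paste0(">", ids)
    lines[seq(2L, by = 2L, length.out = n)] <- reads
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate one small RNA library with ground truth
#'
#' Draws species from planted phased trains (exact per-unit depth),
#' log-normal hot spots and a uniform background, emits adapter-carrying
#' reads in shuffled order, and returns full bookkeeping that reconciles
#' exactly with the emitted reads. Byte-identical output for identical
#' (design, seed).
#'
#' @param design A [sirna_design()].
#' @param locus A [reference_locus()] (e.g. from [generate_locus()]).
#' @param seed Integer seed; fully determines the library.
#' @param path Optional output path; when given, reads are written in
#'   the design's format.
#' @param sample_id Sample identifier carried into the truth tables.
#' @return List with elements `sample_id`, `reads` (character vector of
#'   raw reads), `path`, `species` (ground-truth `data.frame`: sequence,
#'   strand, five_prime, length, count, origin), `trains` (placed
#'   trains), `totals` (read accounting), `design`, `seed`.
#' @export
simulate_library <- function(design, locus, seed, path = NULL,
                             sample_id = "sim") {
  stopifnot(inherits(design, "sirna_design"),
            inherits(locus, "reference_locus"))
  withr::with_seed(seed, {
    region <- confine_region(design, locus)
    trains <- place_trains(design$phased_trains, locus, region)
    tr_sp <- train_species(trains, locus)
    n_train <- sum(tr_sp$count)
    n_bg <- round(design$background_fraction * design$n_reads)
    n_hot <- max(design$n_reads - n_train - n_bg, 0)
    hot_rows <- NULL
    if (design$n_species > 0L && n_hot > 0) {
      uni <- hotspot_universe(design, locus, region, design$abundance_sdlog)
      lam <- balance_classes(exp(uni$logmu), uni$length, uni$strand, design)
      cnt <- as.numeric(rmultinom(1L, n_hot, lam))
      hot_rows <- data.frame(five_prime = uni$five_prime,
                             length = uni$length, strand = uni$strand,
                             count = cnt, origin = "hotspot",
                             stringsAsFactors = FALSE)
    }
    bg_rows <- background_species(n_bg, design, locus)
    species <- finalize_species(
      rbind(tr_sp[, c("five_prime", "length", "strand", "count", "origin")],
            hot_rows, bg_rows), locus)
    reads <- emit_reads(species, design)
    if (!is.null(path)) write_reads(reads, path, design$format)
    list(sample_id = sample_id, reads = reads, path = path,
         species = species, trains = trains,
         totals = truth_totals(species, locus),
         design = design, seed = seed)
  })
}

#' Simulate a coupled pair of libraries
#'
#' Both samples share the species universe, the planted trains and a
#' shared Gaussian log-abundance term; each adds independent Gaussian
#' noise before Poisson-multinomial count realization. The achieved (not
#' just targeted) Spearman rank correlation of the realized counts is
#' recorded in the ground truth, both over all species present in both
#' samples and over the abundance-filtered set.
#'
#' @param design A [sirna_design()] (read depth of sample A; also used
#'   for sample B unless `n_reads_b` is given).
#' @param locus A [reference_locus()].
#' @param seed Integer seed.
#' @param coupling List with `shared_sdlog` (sd of the shared
#'   log-abundance; 0 decouples the samples), `noise_sdlog` (per-sample
#'   sd) and optionally `realization` (`"sampled"`, the default
#'   multinomial realization, or `"expected"` for deterministic rounded
#'   expectations -- useful as a noiseless diagnostic where zero
#'   per-sample noise gives a rank correlation of exactly 1). Defaults
#'   target a rank correlation around 0.85.
#' @param n_reads_b Read depth of sample B (default: same as A).
#' @param paths Optional length-2 character vector of output paths.
#' @param sample_ids Identifiers for the two samples.
#' @param min_reads_exclusive Abundance filter used for the filtered
#'   achieved correlation.
#' @return List with per-sample entries `a` and `b` (same shape as
#'   [simulate_library()] minus `design`), plus `trains`,
#'   `achieved_rs` (filtered common set), `achieved_rs_all`,
#'   `achieved_rs_21` (per strand, 21-nt species only -- the like-for-like
#'   reference for the pipeline's stratified estimate), `n_common`,
#'   `coupling`, `seed`.
#' @export
simulate_paired <- function(design, locus, seed,
                            coupling = list(shared_sdlog = 1.5,
                                            noise_sdlog = 0.5),
                            n_reads_b = NULL, paths = NULL,
                            sample_ids = c("sim_a", "sim_b"),
                            min_reads_exclusive = 5) {
  stopifnot(inherits(design, "sirna_design"),
            inherits(locus, "reference_locus"))
  n_reads <- c(design$n_reads,
               if (is.null(n_reads_b)) design$n_reads else as.integer(n_reads_b))
  withr::with_seed(seed, {
    region <- confine_region(design, locus)
    trains <- place_trains(design$phased_trains, locus, region)
    tr_sp <- train_species(trains, locus)
    n_train <- sum(tr_sp$count)
    uni <- hotspot_universe(design, locus, region, coupling$shared_sdlog)
    samples <- vector("list", 2L)
    for (s in 1:2) {
      n_bg <- round(design$background_fraction * n_reads[s])
      n_hot <- max(n_reads[s] - n_train - n_bg, 0)
      hot_rows <- NULL
      if (nrow(uni) && n_hot > 0) {
        lam <- exp(uni$logmu + rnorm(nrow(uni), 0, coupling$noise_sdlog))
        lam <- balance_classes(lam, uni$length, uni$strand, design)
        cnt <- if (identical(coupling$realization, "expected")) {
          round(lam / sum(lam) * n_hot)
        } else {
          as.numeric(rmultinom(1L, n_hot, lam))
        }
        hot_rows <- data.frame(five_prime = uni$five_prime,
                               length = uni$length, strand = uni$strand,
                               count = cnt, origin = "hotspot",
                               stringsAsFactors = FALSE)
      }
      bg_rows <- background_species(n_bg, design, locus)
      species <- finalize_species(
        rbind(tr_sp[, c("five_prime", "length", "strand", "count", "origin")],
              hot_rows, bg_rows), locus)
      reads <- emit_reads(species, design)
      path <- if (!is.null(paths)) paths[s] else NULL
      if (!is.null(path)) write_reads(reads, path, design$format)
      samples[[s]] <- list(sample_id = sample_ids[s], reads = reads,
                           path = path, species = species,
                           totals = truth_totals(species, locus))
    }
    merged <- merge(samples[[1L]]$species[, c("sequence", "strand",
                                              "length", "count")],
                    samples[[2L]]$species[, c("sequence", "count")],
                    by = "sequence", suffixes = c("_a", "_b"))
    names(merged)[names(merged) == "count"] <- "count_a"
    filt <- merged[merged$count_a > min_reads_exclusive &
                     merged$count_b > min_reads_exclusive, , drop = FALSE]
    rs_of <- function(df) {
      if (nrow(df) >= 3L) {
        suppressWarnings(cor(df$count_a, df$count_b, method = "spearman"))
      } else NA_real_
    }
    rs_class <- vapply(c(sense = "sense", antisense = "antisense"),
                       function(str) rs_of(filt[filt$strand == str &
                                                  filt$length == 21L, ]),
                       numeric(1))
    list(a = samples[[1L]], b = samples[[2L]], trains = trains,
         achieved_rs = rs_of(filt), achieved_rs_all = rs_of(merged),
         achieved_rs_21 = rs_class,
         n_common = nrow(filt), coupling = coupling, seed = seed)
  })
}
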