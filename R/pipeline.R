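pipeline_defaults <- function() {
  list(adapter = NULL, min_len = 15L, max_len = 45L, min_overlap = 7L,
       pre_trimmed = FALSE, min_reads_exclusive = 5, min_units = 3L,
       size_range = c(18L, 25L), phases = 21L, window_cycles = 9L,
       multimap_policy = "all", top_n = 20L, spearman_mode = "rerank",
       boundary = c("intron", "exon2"), track_lengths = c(21L, 22L, 23L, 24L),
       output_dir = NULL, seed = NULL, log_level = "info")
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or an R list. Unknown keys are rejected and
#' all problems are collected before reporting. Required: `samples`
#' (list of `id` + `path`, optionally `format`, `pre_trimmed`),
#' `reference` (`fasta` + `annotation`, optional `dialect`), and
#' `adapter` unless every sample is pre-trimmed. Optional: `pairs`
#' (list of `[sample_a, sample_b]`), `allele_reference` (`fasta`,
#' optional `annotation`, `label_a`, `label_b`), and the threshold knobs
#' echoed by the defaults (`min_reads_exclusive = 5`, `min_units = 3`,
#' `size_range = [18, 25]`, `phases = 21`, `window_cycles = 9`, ...).
#'
#' @param config Path to a YAML file, or a named list.
#' @param stop_on_error When `TRUE` (default) an error listing every
#'   problem is raised; when `FALSE` the character vector of problems is
#'   returned (empty when valid).
#' @return Normalized config of class `run_config` (defaults resolved),
#'   or the problem vector when `stop_on_error = FALSE`.
#' @export
validate_config <- function(config, stop_on_error = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  errors <- character()
  defaults <- pipeline_defaults()
  known <- c(names(defaults), "samples", "reference", "allele_reference",
             "pairs")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    errors <- c(errors, sprintf("unknown config key(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[intersect(names(config), known)])
  if (is.null(cfg$samples) || !length(cfg$samples)) {
    errors <- c(errors, "no samples defined")
  } else {
    for (i in seq_along(cfg$samples)) {
      s <- cfg$samples[[i]]
      bad <- setdiff(names(s), c("id", "path", "format", "pre_trimmed"))
      if (length(bad)) {
        errors <- c(errors, sprintf("sample %d: unknown key(s) %s", i,
                                    paste(bad, collapse = ", ")))
      }
      if (is.null(s$id) || is.null(s$path)) {
        errors <- c(errors, sprintf("sample %d needs 'id' and 'path'", i))
      }
    }
  }
  if (is.null(cfg$reference) || is.null(cfg$reference$fasta)) {
    errors <- c(errors, "reference.fasta is required")
  }
  if (!is.null(cfg$reference)) {
    bad <- setdiff(names(cfg$reference), c("fasta", "annotation", "dialect"))
    if (length(bad)) {
      errors <- c(errors, sprintf("reference: unknown key(s) %s",
                                  paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(cfg$allele_reference)) {
    bad <- setdiff(names(cfg$allele_reference),
                   c("fasta", "annotation", "label_a", "label_b"))
    if (length(bad)) {
      errors <- c(errors, sprintf("allele_reference: unknown key(s) %s",
                                  paste(bad, collapse = ", ")))
    }
  }
  all_pre <- length(cfg$samples) &&
    all(vapply(cfg$samples, function(s) isTRUE(s$pre_trimmed) ||
                 isTRUE(cfg$pre_trimmed), logical(1)))
  if (is.null(cfg$adapter) && !all_pre) {
    errors <- c(errors, "adapter is required unless all samples are pre_trimmed")
  }
  for (key in c("min_len", "max_len", "min_overlap", "min_reads_exclusive",
                "min_units", "phases", "window_cycles", "top_n")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      errors <- c(errors, sprintf("%s must be a non-negative number", key))
    }
  }
  if (!is.numeric(cfg$size_range) || length(cfg$size_range) != 2L ||
      cfg$size_range[1L] > cfg$size_range[2L]) {
    errors <- c(errors, "size_range must be an ascending pair of lengths")
  }
  if (!cfg$multimap_policy %in% c("all", "fractional", "unique")) {
    errors <- c(errors, "multimap_policy must be all, fractional or unique")
  }
  if (!is.null(cfg$pairs)) {
    ids <- vapply(cfg$samples, function(s) s$id %||% "", character(1))
    for (p in cfg$pairs) {
      if (length(p) != 2L || !all(unlist(p) %in% ids)) {
        errors <- c(errors, sprintf("pair [%s] does not name two known samples",
                                    paste(unlist(p), collapse = ", ")))
      }
    }
  }
  if (length(errors)) {
    if (stop_on_error) {
      stop(paste(c("invalid configuration:", paste0("  - ", errors)),
                 collapse = "\n"), call. = FALSE)
    }
    return(errors)
  }
  if (!stop_on_error) return(character())
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipe_log <- function(cfg, fmt, ...) {
  if (!identical(cfg$log_level, "quiet")) message(sprintf(fmt, ...))
}

#' Run the full analysis pipeline
#'
#' Orchestrates trim -> collapse -> map -> profile for every sample and
#' the commonality / phasing / end-conservation comparisons for every
#' configured pair, with per-stage read-accounting log lines. Optional
#' stages degrade gracefully: allele classification is skipped (with a
#' warning) when no allele reference is configured, boundary statistics
#' when the boundary features are absent, and pair comparisons fall back
#' to `NA` correlations when too few common species pass the filter.
#'
#' @param config A `run_config` from [validate_config()], a raw list, or
#'   a YAML path.
#' @return A report bundle (list of class `report_bundle`): per-sample
#'   entries (`species`, `mapped`, `read_accounting`, `strand_totals`,
#'   `size_distribution`, `position_tracks`, `feature_confinement`,
#'   `boundary`, `alleles`, `regions`, `phase_summary`), per-pair
#'   entries (`commonality` per strand, `end_conservation`,
#'   `phase_summary` per sample), and a `provenance` block (config,
#'   config hash, package version, timestamp; the hash covers the config
#'   only, so re-runs of the same config reproduce identical tables).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  locus <- load_reference(config$reference$fasta,
                          config$reference$annotation,
                          dialect = config$reference$dialect %||% "tsv")
  pair_ref <- NULL
  if (!is.null(config$allele_reference)) {
    ref_b <- load_reference(config$allele_reference$fasta,
                            config$allele_reference$annotation)
    pair_ref <- allele_pair(locus, ref_b,
                            label_a = config$allele_reference$label_a %||% "reference",
                            label_b = config$allele_reference$label_b %||% "alternate")
  } else {
    warning("no allele_reference configured; allele classification skipped",
            call. = FALSE)
  }
  has_boundary <- all(config$boundary %in% locus$features$name)
  if (!has_boundary) {
    warning("boundary features absent from annotation; boundary statistics skipped",
            call. = FALSE)
  }
  samples <- list()
  for (s in config$samples) {
    raw <- read_small_rna(s$path, format = s$format %||% "auto")
    pre <- isTRUE(s$pre_trimmed) || isTRUE(config$pre_trimmed)
    trimmed <- if (pre) {
      length_filter(raw, config$min_len, config$max_len)
    } else {
      trim_adapter(raw, config$adapter, config$min_len, config$max_len,
                   config$min_overlap)
    }
    tab <- collapse_species(trimmed, s$id)
    mapped <- map_table(tab, locus, config$multimap_policy)
    totals <- strand_read_totals(mapped)
    accounting <- c(input = nrow(raw),
                    accepted = sum(trimmed$status == "accepted"),
                    rejected_length = sum(trimmed$status == "length"),
                    rejected_no_adapter = sum(trimmed$status == "no_adapter"),
                    mapped = unname(totals["total"]),
                    unmapped = sum(mapped$unmapped$count))
    pipe_log(config,
             "[%s] reads in=%d accepted=%d rejected=%d; mapped=%g (sense=%g antisense=%g) unmapped=%g",
             s$id, accounting["input"], accounting["accepted"],
             accounting["rejected_length"] + accounting["rejected_no_adapter"],
             totals["total"], totals["sense"], totals["antisense"],
             accounting["unmapped"])
    tracks <- list()
    for (len in config$track_lengths) {
      for (str in c("sense", "antisense")) {
        tracks[[sprintf("%d_%s", len, str)]] <- position_track(mapped, len, str)
      }
    }
    regions <- rbind(
      call_phased_regions(mapped, "sense", config$min_units,
                          unit = config$phases),
      call_phased_regions(mapped, "antisense", config$min_units,
                          unit = config$phases))
    samples[[s$id]] <- list(
      species = tab, mapped = mapped,
      read_accounting = accounting, strand_totals = totals,
      size_distribution = size_distribution(mapped, config$size_range),
      position_tracks = tracks,
      feature_confinement = feature_confinement(mapped, locus),
      boundary = if (has_boundary) {
        boundary_distances(mapped, locus, config$boundary)
      },
      alleles = if (!is.null(pair_ref)) classify_alleles(tab, pair_ref),
      regions = regions,
      phase_summary = phase_summary(regions, unit = config$phases))
  }
  pairs <- list()
  for (p in config$pairs %||% list()) {
    a <- samples[[p[[1L]]]]; b <- samples[[p[[2L]]]]
    key <- paste(p[[1L]], p[[2L]], sep = "_vs_")
    comm <- list()
    for (str in c("sense", "antisense")) {
      comm[[str]] <- commonality_report(
        a$mapped, b$mapped, length = 21L, strand = str,
        min_reads_exclusive = config$min_reads_exclusive,
        top_n = config$top_n, mode = config$spearman_mode)
      pipe_log(config, "[%s] %s strand: rs=%.3f over %d common species",
               key, str, comm[[str]]$spearman$rs, comm[[str]]$spearman$n_common)
    }
    pairs[[key]] <- list(
      commonality = comm,
      end_conservation = end_conservation(a$regions, b$regions))
  }
  bundle <- structure(
    list(samples = samples, pairs = pairs,
         provenance = list(config = unclass(config),
                           config_hash = rlang::hash(unclass(config)),
                           package_version = as.character(utils::packageVersion("phasir")),
                           created = format(Sys.time(), tz = "UTC"))),
    class = "report_bundle")
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d sample(s), %d pair(s); config %s\n",
              length(x$samples), length(x$pairs),
              x$provenance$config_hash))
  invisible(x)
}

#' Write the tables of a report bundle as TSV files
#'
#' One subdirectory per sample (species table, alignments, size
#' distribution, feature confinement, boundary report, phased regions,
#' per-phase summary, bedGraph-like position tracks) and per pair
#' (commonality summary, end-conservation summary). Every file carries
#' the config hash in a header comment.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  hash_line <- sprintf("# config_hash: %s", bundle$provenance$config_hash)
  emit <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hash_line, con)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
  }
  for (id in names(bundle$samples)) {
    s <- bundle$samples[[id]]
    d <- file.path(dir, id)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    emit(s$species$species, file.path(d, "species.tsv"))
    emit(s$mapped$alignments, file.path(d, "alignments.tsv"))
    emit(s$size_distribution, file.path(d, "size_distribution.tsv"))
    emit(s$feature_confinement, file.path(d, "feature_confinement.tsv"))
    if (!is.null(s$boundary)) emit(s$boundary, file.path(d, "boundary.tsv"))
    if (!is.null(s$alleles)) emit(s$alleles$species, file.path(d, "alleles.tsv"))
    emit(s$regions, file.path(d, "phased_regions.tsv"))
    emit(s$phase_summary, file.path(d, "phase_summary.tsv"))
    for (nm in names(s$position_tracks)) {
      tr <- s$position_tracks[[nm]]
      nz <- which(tr > 0)
      emit(data.frame(locus = rep(s$mapped$locus_id, length(nz)),
                      start = nz - 1L, end = nz, reads = unname(tr[nz])),
           file.path(d, sprintf("track_%s.tsv", nm)))
    }
  }
  for (key in names(bundle$pairs)) {
    p <- bundle$pairs[[key]]
    d <- file.path(dir, key)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    rows <- lapply(p$commonality, function(cm) data.frame(
      length = cm$length, strand = cm$strand,
      value_a = cm$coverage$a$value_a, value_b_a = cm$coverage$a$value_b,
      coverage_a = cm$coverage$a$ratio,
      value_a_b = cm$coverage$b$value_a, value_b_b = cm$coverage$b$value_b,
      coverage_b = cm$coverage$b$ratio,
      n_species_a = cm$n_species[["a"]], n_species_b = cm$n_species[["b"]],
      n_above_a = cm$n_species_above_threshold[["a"]],
      n_above_b = cm$n_species_above_threshold[["b"]],
      n_common = cm$spearman$n_common, rs = cm$spearman$rs,
      p_value = cm$spearman$p_value))
    emit(do.call(rbind, rows), file.path(d, "commonality.tsv"))
    emit(p$end_conservation$summary, file.path(d, "end_conservation.tsv"))
  }
  invisible(dir)
}
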