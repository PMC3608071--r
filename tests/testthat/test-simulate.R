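test_that("locus generation is deterministic with exact feature arithmetic", {
  loc <- generate_locus(1L, c(200L, 180L, 300L, 1200L, 200L))
  expect_equal(loc$length, 2080L)
  e2 <- loc$features[loc$features$name == "exon2", ]
  expect_equal(c(e2$start, e2$end), c(681L, 1880L))
  expect_identical(generate_locus(1L, c(200L, 180L, 300L, 1200L, 200L)),
                   loc)
  expect_false(identical(generate_locus(2L)$sequence, loc$sequence))
  expect_error(generate_locus(1L, c(100L, 0L)), ">= 1")
})

test_that("identical (design, seed) give byte-identical libraries", {
  d <- withr::local_tempdir()
  locus <- demo_locus()
  design <- sirna_design(n_reads = 2000L)
  p1 <- file.path(d, "a.fastq"); p2 <- file.path(d, "b.fastq")
  lib1 <- simulate_library(design, locus, seed = 5L, path = p1)
  lib2 <- simulate_library(design, locus, seed = 5L, path = p2)
  expect_identical(lib1$reads, lib2$reads)
  expect_identical(lib1$species, lib2$species)
  expect_identical(readLines(p1), readLines(p2))
  expect_false(identical(simulate_library(design, locus, seed = 6L)$reads,
                         lib1$reads))
})

test_that("an empty design yields an empty library", {
  locus <- demo_locus()
  lib <- simulate_library(trains_only_design(default_phased_trains()[0, ],
                                             n_reads = 0L),
                          locus, seed = 1L)
  expect_equal(length(lib$reads), 0L)
  expect_equal(lib$totals$total_reads, 0)
})

test_that("ground truth reconciles exactly with the emitted reads", {
  locus <- demo_locus()
  lib <- simulate_library(sirna_design(n_reads = 5000L), locus, seed = 12L)
  expect_equal(length(lib$reads), 5000L)
  expect_equal(lib$totals$total_reads, 5000)
  # pipeline round trip recovers the truth exactly (error-free reads)
  mapped <- map_table(collapse_species(
    trim_adapter(lib$reads, lib$design$adapter), "s"), locus)
  totals <- strand_read_totals(mapped)
  expect_equal(unname(totals[c("sense", "antisense")]),
               unname(lib$totals$strand_reads))
  expect_equal(unname(totals["total"]), 5000)
  sd <- size_distribution(mapped)
  for (i in seq_len(nrow(lib$totals$by_length_strand))) {
    row <- lib$totals$by_length_strand[i, ]
    expect_equal(sd[[row$strand]][sd$length == as.character(row$length)],
                 row$count)
  }
})

test_that("realized size-class read proportions follow the design mixture", {
  locus <- demo_locus()
  design <- sirna_design(n_reads = 10000L, background_fraction = 0,
                         phased_trains = default_phased_trains()[0, ])
  lib <- simulate_library(design, locus, seed = 13L)
  bl <- lib$totals$by_length_strand
  n <- lib$totals$total_reads
  for (len in as.integer(names(design$size_mixture))) {
    p <- unname(design$size_mixture[as.character(len)])
    got <- sum(bl$count[bl$length == len])
    expect_lt(abs(got - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  }
  # strand mixture obeys the antisense fraction at read level too
  p_anti <- design$antisense_fraction
  got_anti <- unname(lib$totals$strand_reads["antisense"])
  expect_lt(abs(got_anti - n * p_anti), 3 * sqrt(n * p_anti * (1 - p_anti)))
})

test_that("planted phased trains are recovered exactly on clean data", {
  locus <- demo_locus()
  trains <- data.frame(strand = c("sense", "antisense", "antisense"),
                       phase = c(3L, 10L, 10L),
                       n_units = c(6L, 19L, 4L),
                       depth = c(10, 10, 5),
                       first_unit_coord = NA_integer_)
  for (seed in 1:3) {
    lib <- simulate_library(trains_only_design(trains), locus, seed = seed)
    mapped <- map_table(collapse_species(
      trim_adapter(lib$reads, lib$design$adapter), "s"), locus)
    called <- rbind(call_phased_regions(mapped, "sense"),
                    call_phased_regions(mapped, "antisense"))
    planted <- lib$trains[order(lib$trains$phase,
                                lib$trains$first_unit_coord), ]
    called <- called[order(called$phase, called$first_unit_coord), ]
    expect_equal(nrow(called), nrow(planted))
    expect_equal(called$strand, planted$strand)
    expect_equal(called$phase, planted$phase)
    expect_equal(called$first_unit_coord, planted$first_unit_coord)
    expect_equal(called$last_unit_coord, planted$last_unit_coord)
    expect_equal(called$n_units, planted$n_units)
  }
})

test_that("decoupled sample pairs show near-zero rank correlation", {
  # a true null needs no shared structure at all: flat hot-spot weights
  # (hotspot_sdlog = 0), no shared log-abundance, and a within-class
  # comparison (21-nt antisense) so the shared size/strand mixture masses
  # cannot induce rank agreement
  locus <- demo_locus()
  design <- sirna_design(n_reads = 8000L, n_species = 200L,
                         hotspot_sdlog = 0, background_fraction = 0,
                         phased_trains = default_phased_trains()[0, ])
  rs <- vapply(1:20, function(seed) {
    sim <- simulate_paired(design, locus, seed = seed,
                           coupling = list(shared_sdlog = 0,
                                           noise_sdlog = 1))
    sim$achieved_rs_21[["antisense"]]
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.25)
})

test_that("zero per-sample noise with expected counts gives rs = 1", {
  locus <- demo_locus()
  design <- sirna_design(n_reads = 6000L, n_species = 150L,
                         background_fraction = 0,
                         phased_trains = default_phased_trains()[0, ])
  sim <- simulate_paired(design, locus, seed = 3L,
                         coupling = list(shared_sdlog = 1.5,
                                         noise_sdlog = 0,
                                         realization = "expected"))
  expect_equal(sim$achieved_rs, 1)
})

test_that("pipeline-estimated rs tracks the generator's achieved rs", {
  locus <- demo_locus()
  design <- sirna_design(n_reads = 8000L, n_species = 200L,
                         background_fraction = 0)
  for (seed in c(101L, 102L, 103L)) {
    sim <- simulate_paired(design, locus, seed = seed)
    est <- spearman_rank_correlation(
      rank_species(map_table(collapse_species(
        trim_adapter(sim$a$reads, design$adapter), "a"), locus),
        21L, "antisense"),
      rank_species(map_table(collapse_species(
        trim_adapter(sim$b$reads, design$adapter), "b"), locus),
        21L, "antisense"))
    expect_lt(abs(est$rs - sim$achieved_rs_21[["antisense"]]), 0.1)
  }
})
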