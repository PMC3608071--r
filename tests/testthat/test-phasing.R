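test_that("phase assignment anchors at the reference ends and cycles by 21", {
  L <- 1000L
  expect_equal(phase_of(1L, "sense", L), 1L)
  expect_equal(phase_of(22L, "sense", L), 1L)
  expect_equal(phase_of(2L, "sense", L), 2L)
  expect_equal(phase_of(L, "antisense", L), 1L)
  expect_equal(phase_of(L - 21L, "antisense", L), 1L)
  expect_error(phase_of(0L, "sense", L), "out of range")
  expect_error(phase_of(L + 1L, "antisense", L), "out of range")
})

test_that("the 21 phases partition every coordinate on each strand", {
  L <- 301L  # deliberately not a multiple of 21
  for (str in c("sense", "antisense")) {
    sets <- lapply(1:21, function(p) cycle_positions(str, p, L))
    expect_equal(sort(unlist(sets)), 1:L)
    expect_equal(length(unique(phase_of(1:L, str, L))), 21L)
    # coordinates listed for phase p are exactly those phase_of maps to p
    for (p in c(1L, 7L, 21L)) {
      expect_true(all(phase_of(sets[[p]], str, L) == p))
    }
  }
})

test_that("occupancy requires exact 21-nt 5' ends at cycle positions", {
  # 21-nt sense alignment at coordinate 43: phase ((43-1) mod 21) + 1 = 1
  m <- mk_mapped(list(strand = "sense", start = 43L, end = 63L, count = 2),
                 list(strand = "sense", start = 80L, end = 101L, count = 9),
                 locus_length = 500L)
  occ <- occupancy(m, "sense", phase = 1L)
  expect_equal(occ$coord, 43L)
  expect_equal(occ$reads, 2)
  # the 22-nt alignment at coordinate 80 (phase 17) never counts
  expect_equal(nrow(occupancy(m, "sense", phase = 17L)), 0L)
})

test_that("region calling finds maximal runs of three or more units", {
  L <- 2100L
  mk_train <- function(strand, coords, counts = 1) {
    specs <- lapply(seq_along(coords), function(i) {
      if (strand == "sense") list(strand = strand, start = coords[i],
                                  end = coords[i] + 20L, count = counts)
      else list(strand = strand, start = coords[i] - 20L,
                end = coords[i], count = counts)
    })
    do.call(mk_mapped, c(specs, locus_length = L))
  }
  # 19 consecutive units in one phase: a single 399-nt region
  coords <- 100L + 21L * (0:18)
  m19 <- mk_train("sense", coords)
  got <- call_phased_regions(m19, "sense")
  expect_equal(nrow(got), 1L)
  expect_equal(got$n_units, 19L)
  expect_equal(got$span, 399L)
  expect_equal(got$first_unit_coord, 100L)
  expect_equal(got$last_unit_coord, 100L + 21L * 18L)
  # two consecutive units only: no region
  expect_equal(nrow(call_phased_regions(mk_train("sense", 100L + 21L * (0:1)),
                                        "sense")), 0L)
  # units at cycles 1-4 and 6-9 (cycle 5 empty): two maximal 4-unit regions
  split_coords <- 100L + 21L * c(0:3, 5:8)
  got2 <- call_phased_regions(mk_train("sense", split_coords), "sense")
  expect_equal(got2$n_units, c(4L, 4L))
  expect_equal(got2$first_unit_coord, c(100L, 100L + 21L * 5L))
  # antisense trains run right-to-left; 5' end is the rightmost coordinate
  anti_coords <- 2000L - 21L * (0:4)
  got3 <- call_phased_regions(mk_train("antisense", anti_coords), "antisense")
  expect_equal(got3$n_units, 5L)
  expect_equal(got3$five_prime_coord, 2000L)
  expect_equal(got3$three_prime_coord, 2000L - 21L * 4L - 20L)
  expect_equal(got3$left, 2000L - 21L * 4L - 20L)
  expect_equal(got3$right, 2000L)
})

test_that("phasing scores follow the Howell formula with a k >= 3 gate", {
  L <- 9L * 21L + 30L
  # cycles of sense phase 1 at 1, 22, 43, ...; occupy the first five with
  # reads 10 + 4 x 5 (P = 30) and plant 2 out-of-phase reads at 30
  specs <- lapply(1:5, function(i) list(strand = "sense",
                                        start = 1L + 21L * (i - 1L),
                                        end = 21L + 21L * (i - 1L),
                                        count = c(10, 5, 5, 5, 5)[i]))
  specs <- c(specs, list(list(strand = "sense", start = 30L, end = 50L,
                              count = 2)))
  m <- do.call(mk_mapped, c(specs, locus_length = L))
  tr <- phasing_score(m, "sense")
  p1 <- tr[tr$phase == 1L, ]
  # window over cycles 1-9: P = 30, U = 2, k = 5 -> (5-2) ln(1 + 300/3)
  expect_equal(p1$score[p1$cycle == 1L], 3 * log(101))
  # k = 2 occupied cycles -> gated to zero
  m2 <- do.call(mk_mapped, c(specs[1:2], locus_length = L))
  expect_true(all(phasing_score(m2, "sense")$score == 0))
  # empty mapped set -> all-zero track
  expect_true(all(phasing_score(mk_mapped(locus_length = L),
                                "sense")$score == 0))
})

test_that("clean called regions have positive scores throughout", {
  locus <- demo_locus()
  trains <- data.frame(strand = c("sense", "antisense"),
                       phase = c(4L, 16L), n_units = c(3L, 7L),
                       depth = c(5, 8), first_unit_coord = NA_integer_)
  lib <- simulate_library(trains_only_design(trains), locus, seed = 81L)
  mapped <- map_table(collapse_species(
    trim_adapter(lib$reads, lib$design$adapter), "s"), locus)
  for (str in c("sense", "antisense")) {
    regions <- call_phased_regions(mapped, str)
    scores <- phasing_score(mapped, str)
    for (i in seq_len(nrow(regions))) {
      r <- regions[i, ]
      sel <- scores$phase == r$phase &
        scores$coord >= min(r$first_unit_coord, r$last_unit_coord) &
        scores$coord <= max(r$first_unit_coord, r$last_unit_coord)
      expect_true(all(scores$score[sel] > 0))
    }
  }
})

test_that("end conservation demands exact coordinate identity", {
  regions <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
      data.frame(strand = r[[1L]], phase = as.integer(r[[2L]]),
                 first_unit_coord = as.integer(r[[3L]]),
                 last_unit_coord = as.integer(r[[4L]]),
                 n_units = 3L, span = 63L,
                 left = min(as.integer(r[[3L]]), as.integer(r[[4L]])),
                 right = max(as.integer(r[[3L]]), as.integer(r[[4L]])),
                 five_prime_coord = as.integer(r[[3L]]),
                 three_prime_coord = as.integer(r[[5L]]),
                 stringsAsFactors = FALSE)))
  }
  a <- regions(list("sense", 1, 100, 142, 162),
               list("sense", 3, 300, 342, 362))
  ec_same <- end_conservation(a, a)
  expect_equal(ec_same$summary$n_five_conserved, 2)
  expect_equal(ec_same$summary$n_three_conserved, 2)
  b_disjoint <- regions(list("sense", 2, 500, 542, 562))
  ec0 <- end_conservation(a, b_disjoint)
  expect_equal(ec0$summary$n_five_conserved, 0)
  expect_equal(ec0$summary$n_three_conserved, 0)
  # neighboring phase offset by one nucleotide: distinct, not conserved
  b_offset <- regions(list("sense", 2, 101, 143, 163))
  ec1 <- end_conservation(a, b_offset)
  expect_equal(ec1$summary$n_five_conserved, 0)
  # ... unless a tolerance is explicitly allowed
  ec_tol <- end_conservation(a, b_offset, tolerance = 1L)
  expect_equal(ec_tol$summary$n_five_conserved, 1)
  # strands never cross-match
  b_anti <- regions(list("antisense", 1, 142, 100, 80))
  expect_equal(end_conservation(a, b_anti)$summary$n_five_conserved, 0)
})

test_that("phase summaries recount regions per phase, zeros included", {
  empty <- call_phased_regions(mk_mapped(locus_length = 2100L), "sense")
  ps0 <- phase_summary(empty)
  expect_equal(nrow(ps0), 42L)  # 21 phases x 2 strands
  expect_true(all(ps0$n_regions == 0))
  L <- 2100L
  coords <- 110L + 21L * (0:18)  # phase of 110 is ((110-1) mod 21)+1 = 5
  specs <- lapply(coords, function(cc) list(strand = "sense", start = cc,
                                            end = cc + 20L, count = 1))
  m <- do.call(mk_mapped, c(specs, locus_length = L))
  reg <- call_phased_regions(m, "sense")
  ps <- phase_summary(reg)
  row <- ps[ps$strand == "sense" & ps$phase == phase_of(110L, "sense", L), ]
  expect_equal(row$max_units, 19L)
  expect_equal(row$n_regions, 1L)
  # brute-force recount oracle over a multi-region fixture
  multi <- rbind(reg, reg[1, ])
  multi$first_unit_coord[2] <- multi$first_unit_coord[2] + 630L
  multi$n_units[2] <- 4L
  ps2 <- phase_summary(multi)
  sel <- ps2$strand == "sense" & ps2$phase == reg$phase[1]
  expect_equal(ps2$n_regions[sel], 2L)
  expect_equal(ps2$total_units[sel], 23L)
  expect_equal(ps2$max_units[sel], 19L)
})
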