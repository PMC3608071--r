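test_that("size distribution tabulates stranded counts with an other bin", {
  empty <- mk_mapped(locus_length = 500L)
  sd0 <- size_distribution(empty)
  expect_true(all(sd0$sense == 0) && all(sd0$antisense == 0))
  m <- mk_mapped(list(strand = "sense", start = 1L, end = 21L, count = 3),
                 list(strand = "sense", start = 51L, end = 71L, count = 2),
                 list(strand = "sense", start = 101L, end = 122L, count = 1),
                 list(strand = "sense", start = 151L, end = 181L, count = 4),
                 locus_length = 500L)
  sd1 <- size_distribution(m)
  expect_equal(sd1$sense[sd1$length == "21"], 5)
  expect_equal(sd1$sense[sd1$length == "22"], 1)
  expect_equal(sd1$sense[sd1$length == "other"], 4)  # a 31-nt alignment
  expect_true(all(sd1$antisense == 0))
  expect_equal(sum(sd1$sense), sum(m$alignments$count))
})

test_that("position tracks attribute counts at the 5' end per strand", {
  m <- mk_mapped(list(strand = "sense", start = 100L, end = 120L, count = 7),
                 locus_length = 300L)
  tr <- position_track(m, 21L, "sense")
  expect_equal(unname(tr[100L]), 7)
  expect_equal(sum(tr), 7)
  m2 <- mk_mapped(list(strand = "antisense", start = 100L, end = 120L,
                       count = 4),
                  locus_length = 300L)
  tr2 <- position_track(m2, 21L, "antisense")
  expect_equal(unname(tr2[120L]), 4)  # antisense 5' end = rightmost base
  expect_equal(unname(tr2[100L]), 0)
})

test_that("track sums equal the matching size-distribution cells", {
  locus <- demo_locus()
  lib <- simulate_library(sirna_design(n_reads = 6000L), locus, seed = 9L)
  mapped <- map_table(collapse_species(
    trim_adapter(lib$reads, lib$design$adapter), "s"), locus)
  sd <- size_distribution(mapped)
  for (len in 21:24) {
    for (str in c("sense", "antisense")) {
      expect_equal(sum(position_track(mapped, len, str)),
                   sd[[str]][sd$length == as.character(len)])
    }
  }
})

test_that("feature confinement uses the 5'-end rule and sums to one", {
  locus <- demo_locus()
  e2 <- locus$features[locus$features$name == "exon2", ]
  inside <- mk_mapped(list(strand = "sense", start = e2$start + 10L,
                           end = e2$start + 30L, count = 6),
                      locus_length = locus$length)
  fc <- feature_confinement(inside, locus)
  expect_equal(fc$fraction[fc$feature == "exon2"], 1)
  # 5' end in the intron, 3' end in exon 2 -> attributed to the intron
  straddle <- mk_mapped(list(strand = "sense", start = e2$start - 5L,
                             end = e2$start + 15L, count = 2),
                        locus_length = locus$length)
  fc2 <- feature_confinement(straddle, locus)
  expect_equal(fc2$reads[fc2$feature == "intron"], 2)
  expect_equal(sum(fc2$fraction), 1)
})

test_that("planted feature proportions are recovered", {
  locus <- demo_locus()
  lib <- simulate_library(sirna_design(n_reads = 8000L,
                                       background_fraction = 0.01),
                          locus, seed = 10L)
  mapped <- map_table(collapse_species(
    trim_adapter(lib$reads, lib$design$adapter), "s"), locus)
  fc <- feature_confinement(mapped, locus)
  truth <- lib$totals$by_feature
  for (i in seq_len(nrow(truth))) {
    expect_equal(fc$reads[fc$feature == truth$feature[i]], truth$reads[i])
  }
})

test_that("boundary distances follow the flush-is-zero rule", {
  locus <- demo_locus()
  b <- boundary_coordinate(locus, "intron", "exon2")
  flush <- mk_mapped(list(strand = "sense", start = b, end = b + 20L,
                          count = 1),
                     locus_length = locus$length)
  bd <- boundary_distances(flush, locus)
  expect_equal(bd$distance[bd$strand == "sense" & bd$length == 21L], 0L)
  # nearest sense 21-mer starting 13 nt into exon 2
  m13 <- mk_mapped(list(strand = "sense", start = b + 13L, end = b + 33L,
                        count = 5),
                   list(strand = "sense", start = b + 200L, end = b + 220L,
                        count = 50),
                   locus_length = locus$length)
  bd13 <- boundary_distances(m13, locus)
  expect_equal(bd13$distance[bd13$strand == "sense" & bd13$length == 21L],
               13L)
  # no antisense 22-nt alignment in exon 2 -> undefined
  expect_true(is.na(bd13$distance[bd13$strand == "antisense" &
                                    bd13$length == 22L]))
  # an alignment overlapping the boundary from the intron side is not
  # a qualifying exon 2 alignment
  cross <- mk_mapped(list(strand = "sense", start = b - 3L, end = b + 17L,
                          count = 2),
                     locus_length = locus$length)
  expect_true(is.na(boundary_distances(cross, locus)$distance[1L]))
})

test_that("adding an alignment can only shrink or keep boundary distances", {
  locus <- demo_locus()
  b <- boundary_coordinate(locus, "intron", "exon2")
  base_specs <- list(list(strand = "sense", start = b + 40L, end = b + 60L,
                          count = 2),
                     list(strand = "antisense", start = b + 70L,
                          end = b + 90L, count = 1))
  before <- boundary_distances(do.call(mk_mapped, c(base_specs,
                                                    locus_length = locus$length)),
                               locus)
  for (extra_start in c(b + 5L, b + 55L, b + 300L)) {
    specs <- c(base_specs, list(list(strand = "sense",
                                     start = extra_start,
                                     end = extra_start + 20L, count = 1)))
    after <- boundary_distances(do.call(mk_mapped, c(specs,
                                                     locus_length = locus$length)),
                                locus)
    sel <- after$strand == "sense" & after$length == 21L
    expect_lte(after$distance[sel], before$distance[sel])
  }
})

test_that("allele classification partitions species into four classes", {
  a <- rand_locus(61L, 60L, id = "endogene")
  pos <- 30L
  alt <- setdiff(c("A", "C", "G", "T"), substr(a$sequence, pos, pos))[1L]
  b <- reference_locus("transgene", paste0(substr(a$sequence, 1, pos - 1L),
                                           alt,
                                           substr(a$sequence, pos + 1L, 60L)))
  pair <- allele_pair(a, b, "endogene", "transgene")
  sp_a <- substr(a$sequence, 20, 40)          # covers the diagnostic base
  sp_b <- substr(b$sequence, 20, 40)
  sp_common <- substr(a$sequence, 1, 21)      # upstream of the divergence
  sp_none <- strrep("ACGTT", 5L)
  tab <- species_table("s", data.frame(
    sequence = c(sp_a, sp_b, sp_common, sp_none),
    count = c(4, 3, 2, 1)))
  got <- classify_alleles(tab, pair)
  cls <- setNames(got$species$class, got$species$sequence)
  expect_identical(unname(cls[sp_a]), "specific_a")
  expect_identical(unname(cls[sp_b]), "specific_b")
  expect_identical(unname(cls[sp_common]), "common")
  expect_identical(unname(cls[sp_none]), "unplaced")
  expect_equal(sum(got$counts), nrow(tab$species))
})
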