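# shared fixture builders and independent oracles

# deterministic distinct ACGT string: base-4 digits of i padded to `len`
int2seq <- function(i, len = 21L) {
  vapply(i, function(k) {
    digits <- integer(len)
    for (j in seq_len(len)) {
      digits[j] <- k %% 4L
      k <- k %/% 4L
    }
    paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
  }, character(1))
}

rand_seq <- function(n, len = 21L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

rand_locus <- function(seed, L = 2000L, id = "rand_locus",
                       features = NULL) {
  seq <- withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
  if (is.null(features)) reference_locus(id, seq)
  else reference_locus(id, seq, features)
}

# brute-force exact-match oracle: compare the species against every
# substring and every reverse-complemented substring of the locus
brute_force_map <- function(sequence, locus) {
  L <- locus$length
  w <- nchar(sequence)
  rows <- list()
  if (w <= L) {
    starts <- seq_len(L - w + 1L)
    subs <- substring(locus$sequence, starts, starts + w - 1L)
    s_hit <- starts[subs == sequence]
    a_hit <- starts[revcomp(subs) == sequence]
    if (length(s_hit)) {
      rows$s <- data.frame(strand = "sense", start = s_hit,
                           end = s_hit + w - 1L, stringsAsFactors = FALSE)
    }
    if (length(a_hit)) {
      rows$a <- data.frame(strand = "antisense", start = a_hit,
                           end = a_hit + w - 1L, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, unname(rows))
  if (is.null(out)) {
    out <- data.frame(strand = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  out[order(match(out$strand, c("sense", "antisense")), out$start), ,
      drop = FALSE]
}

# assemble a mapped_set directly from alignment specs (sequences are
# fabricated as distinct strings of the right length)
mk_mapped <- function(..., locus_length = 1000L, sample_id = "fx",
                      policy = "all") {
  specs <- list(...)
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    len <- sp$end - sp$start + 1L
    data.frame(sequence = sp$sequence %||% int2seq(i, len),
               strand = sp$strand, start = sp$start, end = sp$end,
               length = len, count = sp$count,
               n_placements = sp$n_placements %||% 1L,
               stringsAsFactors = FALSE)
  })
  alignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(), strand = character(),
               start = integer(), end = integer(), length = integer(),
               count = numeric(), n_placements = integer())
  mapped_set(sample_id, alignments, NULL, "fx_locus", locus_length, policy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mapped_set whose 21-nt species on `strand` have exactly the given counts
mapped_from_counts <- function(counts, strand = "sense",
                               locus_length = 100000L, sample_id = "tab") {
  n <- length(counts)
  starts <- seq(1L, by = 25L, length.out = n)
  alignments <- data.frame(sequence = int2seq(seq_len(n), 21L),
                           strand = strand, start = starts,
                           end = starts + 20L, length = 21L,
                           count = counts, n_placements = 1L,
                           stringsAsFactors = FALSE)
  mapped_set(sample_id, alignments, NULL, "tab_locus", locus_length, "all")
}

# ranked frame straight from a named count vector (names = sequences)
ranked_from_counts <- function(counts, strand = "sense") {
  df <- data.frame(sequence = names(counts), count = as.numeric(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  data.frame(sequence = df$sequence, strand = strand, count = df$count,
             rank = rank(-df$count, ties.method = "average"),
             position = seq_len(nrow(df)), stringsAsFactors = FALSE)
}

# five-feature locus with convenient exon2 bounds
demo_locus <- function(seed = 42L) {
  generate_locus(seed, c(five_prime_upstream = 100L, exon1 = 150L,
                         intron = 250L, exon2 = 1400L,
                         three_prime_downstream = 100L))
}

trains_only_design <- function(trains, n_reads = NULL, ...) {
  n <- if (is.null(n_reads)) sum(trains$n_units * trains$depth) else n_reads
  sirna_design(n_reads = n, n_species = 0L, background_fraction = 0,
               phased_trains = trains, ...)
}
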