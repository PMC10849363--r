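toy_paf <- function(qname, qstart, qend, tname, tstart, tend, strand = "+",
                    matches = NULL, qlen = 1e6L, tlen = 1e6L) {
  len <- qend - qstart
  tibble::tibble(qname = qname, qlen = qlen, qstart = qstart, qend = qend,
                 strand = strand, tname = tname, tlen = tlen,
                 tstart = tstart, tend = tend,
                 matches = matches %||% len, alnlen = len)
}

test_that("alignment filter drops low identity, short, and multi-mapped blocks", {
  p <- dplyr::bind_rows(
    toy_paf("q1", 0L, 50000L, "t1", 0L, 50000L, matches = 40000L),   # id 0.8
    toy_paf("q1", 60000L, 75000L, "t1", 60000L, 75000L),
    toy_paf("q1", 100000L, 105000L, "t1", 100000L, 105000L))         # short
  f <- filter_alignments(p, min_identity = 0.9, min_len = 10000)
  expect_equal(nrow(f), 1L)
  expect_equal(f$qstart, 60000L)
  # two retained blocks overlapping on the query axis are both removed
  p2 <- dplyr::bind_rows(
    toy_paf("q1", 0L, 50000L, "t1", 0L, 50000L),
    toy_paf("q1", 40000L, 90000L, "t2", 0L, 50000L),
    toy_paf("q1", 200000L, 260000L, "t1", 200000L, 260000L))
  f2 <- filter_alignments(p2)
  expect_equal(nrow(f2), 1L)
  expect_equal(f2$qstart, 200000L)
})

test_that("multi-overlap removal equals a brute-force pairwise oracle", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 60
    qs <- sample.int(500000, n)
    len <- sample(10000:40000, n, replace = TRUE)
    p <- toy_paf(sample(c("qA", "qB"), n, TRUE), as.integer(qs),
                 as.integer(qs + len), "t1", 0L, len)
    p$tstart <- as.integer(sample.int(900000, n))
    p$tend <- p$tstart + len
    f <- filter_alignments(p, min_identity = 0, min_len = 0)
    keep_oracle <- vapply(seq_len(n), function(i) {
      !any(p$qname == p$qname[i] & seq_len(n) != i &
             p$qstart < p$qend[i] & p$qend > p$qstart[i])
    }, logical(1))
    expect_equal(sort(f$qstart), sort(p$qstart[keep_oracle]))
  }
})

test_that("one-to-one fraction counts depth-exactly-one bases", {
  p <- toy_paf("q1", 0L, 1000000L, "t1", 0L, 1000000L)
  expect_equal(one_to_one_fraction(p, c(q1 = 1e6), axis = "query"), 100)
  # two blocks overlapping by half: overlap excluded from the 1:1 count
  p2 <- dplyr::bind_rows(
    toy_paf("q1", 0L, 400000L, "t1", 0L, 400000L),
    toy_paf("q1", 200000L, 600000L, "t2", 0L, 400000L))
  expect_equal(one_to_one_fraction(p2, c(q1 = 1e6), axis = "query"), 40)
  # depth bitmap oracle on a fuzzed set
  set.seed(73)
  qs <- as.integer(sample.int(90000, 40))
  p3 <- toy_paf("q1", qs, qs + 5000L, "t1", 0L, 5000L, qlen = 100000L)
  got <- one_to_one_fraction(p3, c(q1 = 1e5), axis = "query")
  depth <- integer(1e5)
  for (i in seq_len(40)) {
    idx <- (qs[i] + 1):(qs[i] + 5000)
    depth[idx] <- depth[idx] + 1L
  }
  expect_equal(got, 100 * sum(depth == 1) / 1e5)
})

test_that("duplication screen keeps maximal runs only", {
  # uniform depth 1 -> empty
  p <- toy_paf("q1", 0L, 500000L, "t1", 0L, 500000L)
  expect_equal(nrow(duplication_screen(p, c(t1 = 1e6), axis = "target")), 0L)
  # 150-kb depth-2 run split by a 1-bp depth-1 gap -> two sub-100kb runs
  p2 <- dplyr::bind_rows(
    toy_paf("q1", 0L, 150000L, "t1", 100000L, 250000L),
    toy_paf("q2", 0L, 74999L, "t1", 100000L, 174999L),
    toy_paf("q3", 0L, 75000L, "t1", 175000L, 250000L))
  out <- duplication_screen(p2, c(t1 = 1e6), min_span = 100000,
                            axis = "target")
  expect_equal(nrow(out), 0L)
  # without the gap the run is called
  p3 <- dplyr::bind_rows(
    toy_paf("q1", 0L, 150000L, "t1", 100000L, 250000L),
    toy_paf("q2", 0L, 150000L, "t1", 100000L, 250000L))
  out3 <- duplication_screen(p3, c(t1 = 1e6), min_span = 100000,
                             axis = "target")
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$start, 100000L)
  expect_equal(out3$end, 250000L)
})

test_that("a planted tandem duplication is recovered from coverage", {
  cfg <- sim_config(seed = 19, chromosome_lengths = c(8e5),
                    snp_rate = 0, indel_rate = 0, n_inversions = 0,
                    duplication_length = 150000, satellite_copies = 60,
                    genes_per_chromosome = 5, long_tracts_per_chromosome = 2,
                    short_tracts_per_chromosome = 6,
                    markers_per_chromosome = 10,
                    marker_false_hit_rate = 0, map_noise_sd = 0)
  st <- suppressWarnings(simulate_study(cfg))
  prefilter <- dplyr::filter(st$paf, matches / alnlen >= 0.9,
                             alnlen >= 10000)
  dup <- duplication_screen(prefilter, seq_lengths(st$contigs_a),
                            min_span = 100000, axis = "target")
  expect_gte(nrow(dup), 1L)
  truth_dup <- st$truth$duplications
  piece <- anchorpair:::chrom_interval_to_contigs(
    truth_dup$chrom[1], truth_dup$start[1], truth_dup$end[1],
    st$contig_truth_a)
  hit <- any(dup$contig == piece$contig[1] &
               pmin(dup$end, piece$end[1]) - pmax(dup$start, piece$start[1]) >
                 0.5 * (piece$end[1] - piece$start[1]))
  expect_true(hit)
})

test_that("nonaligning regions are classified by repeat content", {
  # fully aligned genome -> none
  p <- toy_paf("q1", 0L, 1000000L, "t1", 0L, 1000000L)
  empty_tracts <- tibble::tibble(contig = character(), start = integer(),
                                 end = integer(), classes = list())
  expect_equal(nrow(nonaligning_regions(p, c(q1 = 1e6), empty_tracts,
                                        axis = "query")), 0L)
  # planted unique insertion -> a `unique` region on the B axis
  cfg <- sim_config(seed = 29, chromosome_lengths = c(8e5),
                    snp_rate = 0, indel_rate = 0, n_inversions = 0,
                    unique_insertion_length = 150000, satellite_copies = 60,
                    genes_per_chromosome = 5, long_tracts_per_chromosome = 2,
                    short_tracts_per_chromosome = 6,
                    markers_per_chromosome = 10,
                    marker_false_hit_rate = 0, map_noise_sd = 0)
  st <- simulate_study(cfg)
  f <- filter_alignments(st$paf)
  tracts_b <- collapse_repeats(st$repeat_gff_b)
  na_b <- nonaligning_regions(f, seq_lengths(st$contigs_b), tracts_b,
                              min_span = 100000, axis = "query")
  expect_gte(nrow(na_b), 1L)
  expect_true(any(na_b$classification == "unique" & na_b$length >= 140000))
  # satellite expansion appears as a repeat-associated nonaligned region
  st0 <- small_zero_study()
  f0 <- filter_alignments(st0$paf)
  tr0 <- collapse_repeats(st0$repeat_gff_b)
  na0 <- nonaligning_regions(f0, seq_lengths(st0$contigs_b), tr0,
                             min_span = 2000, axis = "query")
  expect_true(any(na0$classification == "repeat_associated"))
})

test_that("inversions are called from strand runs with flanks", {
  q <- c(0L, 100000L, 200000L, 280000L, 330000L)
  s <- c("+", "+", "-", "-", "+")
  p <- toy_paf("q1", q, q + c(90000L, 90000L, 70000L, 40000L, 60000L),
               "t1", q, q + c(90000L, 90000L, 70000L, 40000L, 60000L),
               strand = s)
  calls <- detect_inversions(p, min_span = 100000)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$qstart, 200000L)
  expect_equal(calls$qend, 320000L)
  expect_equal(calls$inverted_strand, "-")
  expect_false(calls$low_confidence)
  # a fully minus alignment has no strand change
  p2 <- toy_paf("q1", c(0L, 200000L), c(100000L, 300000L), "t1",
                c(0L, 200000L), c(100000L, 300000L), strand = "-")
  expect_equal(nrow(detect_inversions(p2, min_span = 10000)), 0L)
})

test_that("spanning relationships need two partners above the span floor", {
  p <- dplyr::bind_rows(
    toy_paf("q1", 0L, 500000L, "t1", 0L, 500000L),
    toy_paf("q1", 500000L, 800000L, "t2", 0L, 300000L))
  s <- spanning_relationships(p, min_pair_span = 100000)
  q_events <- dplyr::filter(s, axis == "query")
  expect_equal(nrow(q_events), 1L)
  expect_equal(q_events$n_spanned, 2L)
  # a 50-kb second partner is below the default floor
  p2 <- dplyr::bind_rows(
    toy_paf("q1", 0L, 500000L, "t1", 0L, 500000L),
    toy_paf("q1", 500000L, 550000L, "t2", 0L, 50000L))
  s2 <- spanning_relationships(p2, min_pair_span = 100000)
  expect_equal(nrow(dplyr::filter(s2, axis == "query")), 0L)
})

test_that("coverage conserves aligned bp per axis", {
  st <- small_zero_study()
  runs <- anchorpair:::coverage_runs(st$paf, seq_lengths(st$contigs_a),
                                     "target")
  lhs <- sum((runs$end - runs$start) * runs$depth)
  expect_equal(lhs, sum(st$paf$tend - st$paf$tstart))
})
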