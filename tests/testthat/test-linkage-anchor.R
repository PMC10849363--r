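toy_hit <- function(query, subject, sstart, send, evalue, bitscore = 100) {
  tibble::tibble(query = query, subject = subject, pct_identity = 99,
                 aln_len = 90L, mismatches = 0L, gaps = 0L, qstart = 1L,
                 qend = 90L, sstart = as.integer(sstart),
                 send = as.integer(send), evalue = evalue,
                 bitscore = bitscore)
}

test_that("hit filtering is strict at the E-value threshold", {
  h <- dplyr::bind_rows(
    toy_hit("m1", "c1", 100, 189, 4e-24),    # exactly at threshold: removed
    toy_hit("m2", "c1", 200, 289, 1e-30),
    toy_hit("m3", "c1", 300, 389, 1e-3))
  f <- filter_hits(h)
  expect_equal(f$marker, "m2")
  # midpoint bp, strand-agnostic
  expect_equal(f$bp, as.integer(floor((199 + 289) / 2)))
  f2 <- filter_hits(toy_hit("m4", "c1", 500, 411, 1e-40))
  expect_equal(f2$bp, as.integer(floor((410 + 500) / 2)))
})

test_that("per-marker best-hit selection matches a brute-force scan", {
  set.seed(83)
  for (rep in 1:4) {
    n <- 80
    h <- toy_hit(sample(sprintf("m%02d", 1:20), n, TRUE),
                 sample(c("c1", "c2", "c3"), n, TRUE),
                 sample.int(10000, n), sample.int(10000, n) + 90L,
                 10^runif(n, -40, 0), bitscore = runif(n, 50, 200))
    f <- filter_hits(h, e_max = 4e-24)
    ok <- h[h$evalue < 4e-24, ]
    for (m in unique(f$marker)) {
      hm <- ok[ok$query == m, ]
      best <- hm[hm$evalue == min(hm$evalue), ]
      best <- best[best$bitscore == max(best$bitscore), ]
      expect_equal(nrow(best), 1L)
      expect_equal(f$contig[f$marker == m], best$subject)
    }
    # markers with no passing hit are absent
    expect_setequal(f$marker,
                    unique(ok$query)[vapply(unique(ok$query), function(m) {
                      hm <- ok[ok$query == m, ]
                      b <- hm[hm$evalue == min(hm$evalue), ]
                      nrow(b[b$bitscore == max(b$bitscore), ]) == 1
                    }, logical(1))])
  }
})

test_that("tied best hits drop the marker with a warning", {
  h <- dplyr::bind_rows(toy_hit("m1", "c1", 100, 189, 1e-30, 100),
                        toy_hit("m1", "c2", 100, 189, 1e-30, 100))
  expect_warning(f <- filter_hits(h), "tied")
  expect_equal(nrow(f), 0L)
})

toy_map <- function(markers, lgs, cm, cross = "cx") {
  tibble::tibble(marker = markers, cross = cross, linkage_group = lgs,
                 cM = cm)
}

test_that("contig assignment follows the strict-majority rule", {
  ret <- tibble::tibble(marker = sprintf("m%d", 1:6),
                        contig = "c1", bp = 1:6 * 1000L,
                        evalue = 1e-30, bitscore = 100)
  map5 <- toy_map(sprintf("m%d", 1:6), rep("LG3", 6), 1:6)
  a <- assign_contigs(ret, map5)
  expect_equal(a$assignments$linkage_group, "LG3")
  # 3 vs 3 tie: unassigned, flagged multi_LG
  map_tie <- toy_map(sprintf("m%d", 1:6), rep(c("LG1", "LG2"), each = 3), 1:6)
  a2 <- assign_contigs(ret, map_tie)
  expect_equal(nrow(a2$assignments), 0L)
  expect_equal(a2$conflicts$kind, "multi_LG")
  # 4 vs 2 is below the 2/3 margin? 4/6 = 0.667 exactly -> assigned
  map_23 <- toy_map(sprintf("m%d", 1:6), c(rep("LG1", 4), rep("LG2", 2)), 1:6)
  a3 <- assign_contigs(ret, map_23)
  expect_equal(a3$assignments$linkage_group, "LG1")
  # 3 vs 2 (0.6) is below 2/3 -> flagged
  ret5 <- ret[1:5, ]
  map_35 <- toy_map(sprintf("m%d", 1:5), c(rep("LG1", 3), rep("LG2", 2)), 1:5)
  a4 <- assign_contigs(ret5, map_35)
  expect_equal(nrow(a4$assignments), 0L)
})

test_that("orientation needs the marker count and span and follows the trend", {
  ret <- tibble::tibble(marker = c("m1", "m2", "m3"), contig = "c1",
                        bp = c(100000L, 200000L, 300000L),
                        evalue = 1e-30, bitscore = 100)
  map <- toy_map(c("m1", "m2", "m3"), "LG1", c(0, 1, 2))
  asg <- assign_contigs(ret, map)$assignments
  pl <- order_and_orient(asg, ret, map)
  expect_equal(pl$orientation, "+")
  # reversed physical order
  ret_rev <- dplyr::mutate(ret, bp = rev(bp))
  pl2 <- order_and_orient(asg, ret_rev, map)
  expect_equal(pl2$orientation, "-")
  # 20-kb span: below the 30-kb rule despite a monotone signal
  ret_short <- dplyr::mutate(ret, bp = c(10000L, 20000L, 30000L))
  pl3 <- order_and_orient(asg, ret_short, map)
  expect_equal(pl3$orientation, "?")
})

test_that("secondary maps insert between adjacent primary neighbours only", {
  placements <- tibble::tibble(
    contig = c("A", "B"), linkage_group = "LG1", rank = 1:2,
    orientation = "+", evidence = "primary_map", n_markers = 5L,
    span_bp = 50000L, anchor_cM = c(1, 5),
    orientation_evidence = "linkage_map")
  ret <- tibble::tibble(
    marker = c("a1", "a2", "x1", "x2", "b1", "b2"),
    contig = c("A", "A", "X", "X", "B", "B"),
    bp = c(1e5, 2e5, 1e5, 2e5, 1e5, 2e5),
    evalue = 1e-30, bitscore = 100)
  map2 <- toy_map(c("a1", "a2", "x1", "x2", "b1", "b2"), "LG1",
                  c(1, 1.5, 2, 2.5, 5, 5.5), cross = "cross2")
  out <- integrate_secondary_maps(placements, ret, map2, "cross1")
  expect_true("X" %in% out$placements$contig)
  expect_equal(out$placements$rank[out$placements$contig == "X"], 2L)
  expect_equal(out$placements$rank[out$placements$contig == "B"], 3L)
  expect_equal(out$placements$evidence[out$placements$contig == "X"],
               "secondary_map")
  # neighbours on different primary linkage groups: flagged, unplaced
  placements2 <- dplyr::mutate(placements,
                               linkage_group = c("LG1", "LG2"), rank = 1L)
  out2 <- integrate_secondary_maps(placements2, ret, map2, "cross1")
  expect_false("X" %in% out2$placements$contig)
  expect_equal(out2$conflicts$kind, "unresolved_insertion")
})

test_that("reference-guided reconciliation orients, flags, and appends", {
  placements <- tibble::tibble(
    contig = c("A", "B"), linkage_group = "LG1", rank = 1:2,
    orientation = c("?", "+"), evidence = "primary_map", n_markers = 2L,
    span_bp = 10000L, anchor_cM = c(1, 5),
    orientation_evidence = c("none", "linkage_map"))
  ord <- tibble::tibble(scaffold = "LG1", rank = 1:3,
                        contig = c("A", "B", "C"),
                        orientation = c("-", "-", "+"))
  out <- reconcile_reference_guided(placements, ord)
  pa <- out$placements
  expect_equal(pa$orientation[pa$contig == "A"], "-")
  expect_equal(pa$orientation_evidence[pa$contig == "A"], "reference_guided")
  # linkage orientation kept, disagreement flagged
  expect_equal(pa$orientation[pa$contig == "B"], "+")
  expect_equal(out$conflicts$kind, "orientation_disagreement")
  # unplaced contig appended to the LG tail
  expect_equal(pa$rank[pa$contig == "C"], 3L)
  expect_equal(pa$evidence[pa$contig == "C"], "reference_guided")
  # empty order table changes nothing
  out2 <- reconcile_reference_guided(placements, ord[0, ])
  expect_identical(out2$placements, placements)
})

test_that("scaffold length always equals components plus fixed gaps", {
  st <- small_zero_study()
  anchor <- suppressWarnings(
    anchor_contigs(st$marker_hits, st$maps, primary_cross = "cross1",
                   ref_order = st$ref_order, contigs = st$contigs_a))
  sc <- build_scaffolds(anchor$placements, st$contigs_a)
  lens <- seq_lengths(st$contigs_a)
  for (lg in sc$scaffolds$id) {
    comp <- anchor$placements[anchor$placements$linkage_group == lg, ]
    expected <- sum(lens[comp$contig]) + 100 * (nrow(comp) - 1)
    expect_equal(nchar(sc$scaffolds$seq[sc$scaffolds$id == lg]),
                 as.integer(expected))
  }
  # at zero noise the scaffold equals the chromosome up to gap runs
  lg_of_chrom <- setNames(paste0("LG", 1:2), paste0("chr", 1:2))
  for (ch in st$genome_a$id) {
    lg <- lg_of_chrom[[ch]]
    got <- gsub("N+", "", sc$scaffolds$seq[sc$scaffolds$id == lg])
    expect_identical(got, st$genome_a$seq[st$genome_a$id == ch])
  }
})
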