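prot_hit <- function(q, s, bits, ev = 1e-50) {
  tibble::tibble(query = q, subject = s, pct_identity = 95, aln_len = 100L,
                 mismatches = 2L, gaps = 0L, qstart = 1L, qend = 100L,
                 sstart = 1L, send = 100L, evalue = ev, bitscore = bits)
}

test_that("reciprocal best hits pair mutual bests only", {
  ab <- dplyr::bind_rows(prot_hit("a1", "b1", 500),
                         prot_hit("a2", "b1", 450),
                         prot_hit("a2", "b2", 100))
  ba <- dplyr::bind_rows(prot_hit("b1", "a1", 480),
                         prot_hit("b2", "a2", 90))
  r <- reciprocal_best_hits(ab, ba)
  # a1<->b1 is mutual; a2 prefers b1 (taken), so (a2, b2) is not reciprocal
  expect_equal(r$pairs$gene_a, "a1")
  expect_equal(r$pairs$gene_b, "b1")
  expect_true("a2" %in% r$unmatched_a)
  expect_true("b2" %in% r$unmatched_b)
  # a2's best is b1, but b1's best is a1
  ba2 <- prot_hit("b1", "a1", 480)
  r2 <- reciprocal_best_hits(ab, ba2)
  expect_equal(r2$pairs$gene_a, "a1")
  expect_true("a2" %in% r2$unmatched_a)
  # symmetry under swapping inputs
  r3 <- reciprocal_best_hits(ba, ab)
  expect_setequal(paste(r3$pairs$gene_a, r3$pairs$gene_b),
                  paste(r$pairs$gene_b, r$pairs$gene_a))
})

test_that("RBH equals a brute-force double loop on fuzzed score matrices", {
  set.seed(91)
  for (rep in 1:4) {
    na <- 12; nb <- 10
    sc <- matrix(runif(na * nb, 50, 500), na, nb,
                 dimnames = list(sprintf("a%02d", 1:na),
                                 sprintf("b%02d", 1:nb)))
    ab <- dplyr::bind_rows(lapply(rownames(sc), function(a) {
      dplyr::bind_rows(lapply(colnames(sc), function(b) {
        prot_hit(a, b, sc[a, b])
      }))
    }))
    ba <- dplyr::mutate(ab, tmp = query, query = subject, subject = tmp,
                        tmp = NULL)
    got <- reciprocal_best_hits(ab, ba)$pairs
    want <- list()
    for (a in rownames(sc)) {
      b <- colnames(sc)[which.max(sc[a, ])]
      if (rownames(sc)[which.max(sc[, b])] == a) {
        want[[length(want) + 1L]] <- paste(a, b)
      }
    }
    expect_setequal(paste(got$gene_a, got$gene_b), unlist(want))
  }
})

test_that("AED follows the nucleotide sensitivity/specificity formula", {
  ex <- tibble::tibble(start = 0L, end = 100L)
  expect_equal(compute_aed(ex, ex)$aed, 0)
  half <- tibble::tibble(start = 0L, end = 50L)
  res <- compute_aed(half, ex)
  expect_equal(res$sn, 0.5)
  expect_equal(res$sp, 1)
  expect_equal(res$aed, 0.25)
  disj <- tibble::tibble(start = 200L, end = 300L)
  expect_equal(compute_aed(disj, ex)$aed, 1)
  expect_error(compute_aed(ex[0, ], ex), "zero-length")
})

test_that("lift-over maps exons through plus and minus blocks", {
  blocks <- tibble::tibble(
    qname = "b1", qlen = 1000L, qstart = 100L, qend = 200L, strand = "+",
    tname = "a1", tlen = 1000L, tstart = 500L, tend = 600L,
    matches = 100L, alnlen = 100L)
  exon <- tibble::tibble(gene = "g1", exon = "g1.e1", contig = "a1",
                         start = 510L, end = 530L, strand = "+")
  lifted <- lift_annotations(exon, blocks, "a_to_b")$lifted
  expect_equal(lifted$contig, "b1")
  expect_equal(lifted$start, 110L)
  expect_equal(lifted$end, 130L)
  expect_equal(lifted$strand, "+")
  # minus block on a 10-bp toy: coordinates reflect, strand flips
  mblocks <- dplyr::mutate(blocks, strand = "-", qstart = 0L, qend = 100L,
                           tstart = 0L, tend = 100L)
  ex2 <- tibble::tibble(gene = "g2", exon = "g2.e1", contig = "a1",
                        start = 0L, end = 10L, strand = "+")
  l2 <- lift_annotations(ex2, mblocks, "a_to_b")$lifted
  expect_equal(l2$start, 90L)
  expect_equal(l2$end, 100L)
  expect_equal(l2$strand, "-")
  # round trip through the minus block restores the original
  back <- lift_annotations(
    dplyr::mutate(l2, exon = "g2.e1"), mblocks, "b_to_a")$lifted
  expect_equal(back$start, 0L)
  expect_equal(back$end, 10L)
  expect_equal(back$strand, "+")
})

test_that("zero-divergence lift round trip is the identity", {
  st <- small_zero_study()
  f <- filter_alignments(st$paf)
  exons_a <- gene_exon_table(st$gene_gff_a)
  lift <- lift_annotations(exons_a, f, "a_to_b")
  back <- lift_annotations(lift$lifted, f, "b_to_a")$lifted |>
    dplyr::arrange(.data$exon)
  orig <- exons_a |> dplyr::semi_join(back, by = "exon") |>
    dplyr::arrange(.data$exon)
  expect_gt(nrow(back), 0.8 * nrow(exons_a))
  expect_equal(back$contig, orig$contig)
  expect_equal(back$start, orig$start)
  expect_equal(back$end, orig$end)
  expect_equal(back$strand, orig$strand)
  # lifted exon lengths equal originals when fully covered by one block
  lifted <- lift$lifted |> dplyr::arrange(.data$exon)
  orig2 <- exons_a |> dplyr::semi_join(lifted, by = "exon") |>
    dplyr::arrange(.data$exon)
  expect_equal(lifted$end - lifted$start, orig2$end - orig2$start)
})

test_that("exon overlap matching pairs lifted genes and flags splits", {
  lift <- list(lifted = tibble::tibble(
    gene = c("g1", "g2"), exon = c("g1.e1", "g2.e1"), contig = "b_ctg",
    start = c(100L, 500L), end = c(200L, 700L), strand = "+"),
    unmapped = "g3")
  other <- tibble::tibble(gene = c("h1", "h2", "h3"),
                          exon = c("h1.e1", "h2.e1", "h3.e1"),
                          contig = "b_ctg",
                          start = c(199L, 500L, 600L),
                          end = c(250L, 590L, 700L), strand = "+")
  m <- exon_overlap_matching(lift, other)
  expect_equal(m$matches$n_partners[m$matches$gene == "g1"], 1L)  # 1 bp
  expect_true(m$matches$split[m$matches$gene == "g2"])
  expect_equal(m$pct_lifted, 100 * 2 / 3)
  # opposite strand does not match
  other_rev <- dplyr::mutate(other, strand = "-")
  m2 <- exon_overlap_matching(lift, other_rev)
  expect_equal(nrow(m2$matches), 0L)
})

test_that("ORF validity checks frame, start, stop, and internal stops", {
  v <- orf_validity(c("ATGAAATGA", "ATGTAAAAATGA", "ATGAA", "ATGAANTGA",
                      "TTGAAATGA", "ATGAAAAAA"))
  expect_equal(v$valid, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(v$reason, c(NA, "internal_stop", "too_short", "ambiguous",
                           "no_start", "no_stop"))
})

test_that("planted broken copies fail the ORF check in species B", {
  st <- small_zero_study()
  cds <- extract_cds(st$gene_gff_b, st$contigs_b)
  v <- orf_validity(cds$cds)
  truth_b <- st$truth$genes_b
  broken <- truth_b$gene[truth_b$broken]
  intact <- truth_b$gene[!truth_b$broken]
  expect_true(all(!v$valid[cds$gene %in% broken]))
  expect_true(all(v$valid[cds$gene %in% intact]))
})

test_that("correspondence matrix assigns and flags split chromosomes", {
  pairs <- tibble::tibble(gene_a = sprintf("a%d", 1:10),
                          gene_b = sprintf("b%d", 1:10))
  lg <- setNames(rep(c("LG1", "LG2"), c(4, 6)), pairs$gene_a)
  chrom <- setNames(rep(c("chr2", "chr2", "chr9"), c(4, 3, 3)), pairs$gene_b)
  cm <- chromosome_correspondence(pairs, lg, chrom)
  expect_equal(cm$assignment$chromosome[cm$assignment$linkage_group == "LG1"],
               "chr2")
  m <- cm$matrix
  expect_equal(m$proportion[m$linkage_group == "LG1" & m$chromosome == "chr2"],
               1)
  # chr2 is 4/7 in LG1 and 3/7 in LG2: split at the 20% threshold
  expect_true("chr2" %in% cm$split_chromosomes)
  expect_false("chr9" %in% cm$split_chromosomes)
  # row proportions sum to one
  sums <- m |> dplyr::group_by(linkage_group) |>
    dplyr::summarise(s = sum(proportion))
  expect_true(all(abs(sums$s - 1) < 1e-12))
})
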