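test_that("canonical k-mer counting matches the naive oracle", {
  kt <- count_kmers("ACGT", k = 4)
  expect_equal(kt$counts$kmer, "ACGT")
  expect_equal(kt$counts$count, 1)
  # N-containing windows are skipped
  kt2 <- count_kmers("ANCGT", k = 2)
  expect_setequal(kt2$counts$kmer, c("CG", "AC"))
  expect_equal(kt2$total_kmers, 2)
  # fuzz against the naive dictionary counter
  set.seed(17)
  for (k in c(3, 11, 28)) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 10000, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    got <- count_kmers(s, k)$counts
    want <- naive_kmer_counts(s, k)
    got <- got[order(got$kmer), ]
    want <- want[order(want$kmer), ]
    expect_equal(got$kmer, want$kmer)
    expect_equal(got$count, want$count)
  }
})

test_that("rotation classes are invariant under rotation and strand", {
  expect_equal(canonical_rotation("CGA"), "ACG")
  set.seed(23)
  for (i in 1:40) {
    m <- paste(sample(c("A", "C", "G", "T"), sample(4:30, 1),
                      replace = TRUE), collapse = "")
    cls <- canonical_rotation(m)
    expect_equal(canonical_rotation(cls), cls)        # idempotent
    expect_equal(canonical_rotation(revcomp(m)), cls) # strand invariant
    rot <- paste0(substr(m, 3, nchar(m)), substr(m, 1, 2))
    if (nchar(m) > 2) expect_equal(canonical_rotation(rot), cls)
  }
  motif <- "TGTCACAAACCCCATTGGACAGCGTGTG"
  d <- paste0(motif, motif)
  k <- nchar(motif)
  rots <- vapply(seq_len(k), function(i) substr(d, i, i + k - 1), character(1))
  expect_length(unique(canonical_rotation(rots)), 1L)
})

test_that("tandem k-mer arrays are chained, gapped, and grouped by class", {
  motif <- "TGTCACAAACCCCATTGGACAGCGTGTG"
  k <- nchar(motif)
  pad <- function(n) strrep("ACGTG", ceiling(n / 5))
  s1 <- paste0(substr(pad(3000), 1, 3000), strrep(motif, 10),
               substr(pad(3000), 1, 3000))
  a1 <- detect_kmer_arrays(tibble::tibble(id = "c1", seq = s1), k = k)
  expect_equal(nrow(a1), 1L)
  expect_equal(a1$n_arrays, 1L)
  expect_equal(a1$total_copies, 10L)
  expect_equal(a1$class, canonical_rotation(motif))
  # two arrays far apart: one class, two arrays
  s2 <- paste0(strrep(motif, 8), substr(pad(10000), 1, 10000),
               strrep(motif, 6))
  a2 <- detect_kmer_arrays(tibble::tibble(id = "c1", seq = s2), k = k)
  expect_equal(a2$n_arrays, 2L)
  expect_equal(a2$total_copies, 14L)
  # a 40-bp spacer (under the 2k default) does not split the array
  s3 <- paste0(strrep(motif, 5), substr(pad(40), 1, 40), strrep(motif, 5))
  a3 <- detect_kmer_arrays(tibble::tibble(id = "c1", seq = s3), k = k)
  expect_equal(a3$n_arrays, 1L)
  expect_equal(a3$total_copies, 10L)
})

test_that("tandem tract finder recovers toy and mutated satellites", {
  tr <- find_tandem_repeats("ACGACGACG", max_period = 10)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$period, 3L)
  expect_equal(tr$copy_number, 3)
  expect_equal(tr$consensus, "ACG")
  expect_equal(tr$start, 0L)
  expect_equal(tr$end, 9L)
  expect_equal(nrow(find_tandem_repeats("ACGTACGA", max_period = 10)), 0L)
  # planted 28-mer x 50 with 2% mutations
  motif <- "TGTCACAAACCCCATTGGACAGCGTGTG"
  set.seed(41)
  planted <- anchorpair:::mutate_bases(strrep(motif, 50), 0.02)
  tr2 <- find_tandem_repeats(planted, max_period = 40, min_match = 0.8)
  big <- tr2[which.max(tr2$end - tr2$start), ]
  expect_equal(big$period, 28L)
  expect_equal(canonical_rotation(big$consensus), canonical_rotation(motif))
})

test_that("exact-mode tandem candidates equal the quadratic brute force", {
  set.seed(53)
  for (rep in 1:4) {
    s <- paste0(
      paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = ""),
      strrep("ACG", 12),
      paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""),
      strrep("TTAGGC", 7),
      paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""))
    got <- anchorpair:::tandem_candidates(s, max_period = 20, min_copies = 3,
                                          min_match = 1)
    want <- brute_tandem_exact(s, max_period = 20, min_copies = 3)
    got <- got[order(got$period, got$start), c("start", "end", "period")]
    want <- want[order(want$period, want$start), ]
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("presence screen normalises per Mb and calls truth samples", {
  motif <- "TGTCACAAACCCCATTGGACAGCGTGTG"
  cls <- canonical_rotation(motif)
  set.seed(61)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  # 100 isolated copies scattered in ~1 Mb, flanked by A-runs so junction
  # windows cannot coincide with other rotations of the unit
  pieces <- character(200)
  pieces[seq(1, 200, 2)] <- replicate(100, bg(9960))
  pieces[seq(2, 200, 2)] <- paste0("AAAAAA", motif, "AAAAAA")
  with_sat <- tibble::tibble(id = "s", seq = paste(pieces, collapse = ""))
  without <- tibble::tibble(id = "s", seq = bg(500000))
  res <- screen_presence(cls, list(ingroup = with_sat, outgroup = without),
                         k = 28)
  expect_equal(res$copies[res$sample == "ingroup"], 100)
  expect_true(res$present[res$sample == "ingroup"])
  expect_false(res$present[res$sample == "outgroup"])
  empty <- screen_presence(cls, list(e = tibble::tibble(id = character(),
                                                        seq = character())))
  expect_equal(empty$copies, 0)
  expect_false(empty$present)
})
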