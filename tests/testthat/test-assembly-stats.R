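test_that("N50/L50 follow the cumulative definition", {
  s <- contig_stats(c(5, 4, 3))
  expect_equal(s$total_bp, 12)
  expect_equal(s$n50, 4)
  expect_equal(s$l50, 2)
  s1 <- contig_stats(10)
  expect_equal(s1$n50, 10)
  expect_equal(s1$l50, 1)
  expect_error(contig_stats(numeric(0)), "no contig")
})

test_that("overlapping and abutting repeat intervals collapse into tracts", {
  f <- tibble::tibble(contig = "c1", start = c(10L, 15L), end = c(20L, 30L),
                      ftype = c("LINE", "SINE"))
  tr <- collapse_repeats(f)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$start, 10L)
  expect_equal(tr$end, 30L)
  expect_equal(sum(tr$end - tr$start), 20L)
  expect_setequal(tr$classes[[1]], c("LINE", "SINE"))
  # abutting intervals merge
  f2 <- tibble::tibble(contig = "c1", start = c(0L, 10L), end = c(10L, 20L),
                       ftype = "X")
  expect_equal(nrow(collapse_repeats(f2)), 1L)
})

test_that("collapse total equals the per-base bitmap oracle on fuzzed inputs", {
  contigs <- c(c1 = 5000L, c2 = 3000L)
  for (seed in 1:5) {
    f <- random_features(1000, contigs, seed = seed)
    tr <- collapse_repeats(f)
    expect_equal(sum(tr$end - tr$start), bitmap_collapse_bp(f, contigs))
    # tracts are disjoint and sorted per contig
    by_ctg <- split(tr, tr$contig)
    for (g in by_ctg) {
      expect_true(all(diff(g$start) > 0))
      expect_true(all(g$start[-1] > g$end[-nrow(g)]))
    }
  }
})

test_that("terminal intervals take both 5-kb ends of long contigs only", {
  iv <- terminal_intervals(c(long = 12000L), L = 5000)
  expect_equal(iv$start, c(0L, 7000L))
  expect_equal(iv$end, c(5000L, 12000L))
  expect_message(iv2 <- terminal_intervals(c(short = 8000L, ok = 10000L),
                                           L = 5000),
                 "skipped")
  expect_equal(unique(iv2$contig), "ok")
  expect_error(suppressMessages(terminal_intervals(c(s = 3000L), L = 5000)),
               "no contig")
})

test_that("random windows are seed-reproducible and length-proportional", {
  lens <- c(a = 100000L, b = 50000L, c = 3000L)
  w1 <- random_windows(lens, n = 10000, L = 5000, seed = 99)
  w2 <- random_windows(lens, n = 10000, L = 5000, seed = 99)
  expect_identical(w1, w2)
  expect_false("c" %in% w1$contig)   # shorter than L
  expect_true(all(w1$end - w1$start == 5000L))
  # eligible-start proportionality: chi-square sanity
  tab <- table(w1$contig)
  p <- c(100000 - 5000 + 1, 50000 - 5000 + 1)
  p <- p / sum(p)
  chi <- sum((as.numeric(tab[c("a", "b")]) - 10000 * p)^2 / (10000 * p))
  expect_lt(chi, qchisq(0.999, df = 1))
})

test_that("interval coverage sums overlaps against disjoint tracts", {
  tracts <- tibble::tibble(contig = "c1", start = c(10L, 50L),
                           end = c(20L, 70L), classes = list("X", "Y"))
  iv <- tibble::tibble(contig = "c1", start = c(0L, 15L), end = c(60L, 18L))
  cov <- interval_repeat_coverage(iv, tracts)
  expect_equal(cov$covered_bp, c(10L + 10L, 3L))
})

test_that("Welch enrichment test matches the closed form and handles ties", {
  ident <- enrichment_test(rep(5, 10), rep(5, 12))
  expect_equal(ident$t, 0)
  expect_equal(ident$p_value, 1)
  set.seed(31)
  rand <- rnorm(100, 3000, 10)
  term <- rnorm(100, 4000, 10)
  res <- enrichment_test(term, rand)
  expect_lt(res$p_value, 1e-15)
  # independent Welch formula oracle
  tstat <- (mean(term) - mean(rand)) /
    sqrt(var(term) / 100 + var(rand) / 100)
  expect_equal(res$t, tstat, tolerance = 1e-12)
  g <- glance(res)
  expect_equal(g$statistic, res$t)
})

test_that("repeat-biased contig breaks enrich terminal repeat coverage", {
  st <- small_zero_study()
  res <- suppressMessages(
    terminal_enrichment(st$contigs_a, st$repeat_gff_a, n_random = 2000,
                        seed = 5))
  expect_gt(res$mean_terminal, res$mean_random)
  expect_lt(res$p_value, 0.05)
  comp <- res$composition
  expect_true(all(c("terminal", "random") %in% comp$group))
})

test_that("long-tract statistics count terminus overlap and >99% coverage", {
  # a 12-kb tract spanning a contig end
  tracts <- tibble::tibble(contig = "c1", start = 88000L, end = 100000L,
                           classes = list("LINE"))
  out <- long_tract_stats(tracts, c(c1 = 100000L))
  expect_equal(out$pct_tracts_long, 100)
  expect_equal(out$pct_long_overlapping_termini, 100)
  expect_equal(out$pct_termini_over99_covered, 50)  # end terminus only
  # no long tract
  small <- tibble::tibble(contig = "c1", start = 10L, end = 400L,
                          classes = list("X"))
  expect_warning(z <- long_tract_stats(small, c(c1 = 100000L)), "no tract")
  expect_equal(z$pct_tracts_long, 0)
  expect_equal(z$pct_long_overlapping_termini, 0)
})

test_that("per-class summaries and the cumulative distribution behave", {
  tracts <- tibble::tibble(contig = "c1", start = c(0L, 100L),
                           end = c(10L, 130L),
                           classes = list("A", c("A", "B")))
  rs <- repeat_summaries(tracts)
  expect_equal(rs$cdf$cum_frac, c(0.25, 1))
  expect_true(all(diff(rs$cdf$cum_frac) >= 0))
  a_bp <- rs$by_class$bp[rs$by_class$class == "A"]
  expect_equal(a_bp, 40)   # counted once per tract, may exceed merged total
  one <- repeat_summaries(tibble::tibble(contig = "c1", start = 0L,
                                         end = 50L, classes = list("Z")))
  expect_equal(one$by_class$bp / one$total_bp, 1)
})
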