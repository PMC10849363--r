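#' Assembly contiguity statistics
#'
#' N50 is the length at which the cumulative sum of descending contig
#' lengths first reaches half the assembly; L50 is the number of contigs up
#' to and including that point. Ties are handled by the cumulative
#' definition, with no interpolation.
#'
#' @param lengths Integer vector of contig lengths (or a sequence tibble).
#' @return A one-row tibble: `n_contigs`, `total_bp`, `n50`, `l50`.
#' @examples
#' contig_stats(c(5, 4, 3))
#' @export
contig_stats <- function(lengths) {
  if (is.data.frame(lengths)) lengths <- unname(seq_lengths(lengths))
  if (length(lengths) == 0) abort("no contig lengths supplied")
  stopifnot(all(lengths >= 1))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(s)
  i <- which(cs >= sum(s) / 2)[1]
  tibble(n_contigs = length(s), total_bp = sum(s), n50 = s[i], l50 = i)
}

as_contig_lengths <- function(contigs) {
  if (is.data.frame(contigs)) return(seq_lengths(contigs))
  stopifnot(!is.null(names(contigs)))
  contigs
}

#' Collapse repeat annotations into nonredundant tracts
#'
#' Takes possibly overlapping repeat features and merges them, per contig,
#' into disjoint tracts (abutting intervals are merged too, so tracts are
#' the units of the tract-count statistics). Each tract records the set of
#' repeat classes that contributed to it.
#'
#' @param features A feature tibble (see [read_gff3()]); `ftype` carries the
#'   repeat class label.
#' @return A tibble `contig`, `start`, `end`, `classes` (list of character),
#'   sorted by contig and start. Total repeat bp is `sum(end - start)`.
#' @export
collapse_repeats <- function(features) {
  if (nrow(features) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  classes = list()))
  }
  features |>
    group_by(.data$contig) |>
    group_split() |>
    purrr::map_dfr(function(f) {
      ir <- IRanges::IRanges(start = f$start + 1L, end = f$end)
      red <- IRanges::reduce(ir)
      ov <- IRanges::findOverlaps(ir, red, maxgap = 0L)
      cls <- split(f$ftype[S4Vectors::queryHits(ov)], S4Vectors::subjectHits(ov))
      tibble(contig = f$contig[1],
             start = IRanges::start(red) - 1L,
             end = IRanges::end(red),
             classes = lapply(seq_along(red),
                              function(i) sort(unique(cls[[as.character(i)]]))))
    }) |>
    arrange(.data$contig, .data$start)
}

#' Terminal and random genome windows
#'
#' `terminal_intervals()` returns the first and last `L` bp of every contig
#' at least `2 * L` long (shorter contigs are skipped, with a message, so no
#' contig is counted as both of its own termini). `random_windows()` draws
#' windows with the contig chosen proportional to its number of eligible
#' start positions and the start uniform; overlapping windows are permitted.
#'
#' @param contigs A sequence tibble or named vector of contig lengths.
#' @param L Window length in bp.
#' @return A tibble `contig`, `start`, `end` (0-based half-open); terminal
#'   intervals also carry `terminus` (`"start"`/`"end"`).
#' @export
terminal_intervals <- function(contigs, L = 5000) {
  stopifnot(L >= 1)
  len <- as_contig_lengths(contigs)
  short <- len < 2 * L
  if (any(short)) {
    inform(paste0(sum(short), " contig(s) shorter than ", 2 * L,
                  " bp skipped from terminal intervals"))
  }
  len <- len[!short]
  if (length(len) == 0) abort("no contig long enough for terminal intervals")
  bind_rows(
    tibble(contig = names(len), start = 0L, end = as.integer(L),
           terminus = "start"),
    tibble(contig = names(len), start = as.integer(len - L),
           end = as.integer(len), terminus = "end")
  ) |> arrange(.data$contig, .data$start)
}

#' @param n Number of random windows.
#' @param seed Optional integer seed for reproducible windows.
#' @rdname terminal_intervals
#' @export
random_windows <- function(contigs, n = 10000, L = 5000, seed = NULL) {
  stopifnot(L >= 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  len <- as_contig_lengths(contigs)
  len <- len[len >= L]
  if (length(len) == 0) abort(paste0("no contig of length >= ", L))
  w <- len - L + 1
  idx <- sample.int(length(len), n, replace = TRUE, prob = w)
  start <- floor(runif(n) * w[idx])
  tibble(contig = names(len)[idx], start = as.integer(start),
         end = as.integer(start + L))
}

#' Repeat coverage of intervals
#'
#' Adds, to each interval, the number of bp covered by the (disjoint)
#' repeat tracts, and optionally per-class covered bp.
#'
#' @param intervals A tibble `contig`, `start`, `end`.
#' @param tracts Collapsed tracts from [collapse_repeats()].
#' @return `intervals` with a `covered_bp` column.
#' @export
interval_repeat_coverage <- function(intervals, tracts) {
  intervals$covered_bp <- 0L
  if (nrow(intervals) == 0 || nrow(tracts) == 0) return(intervals)
  intervals$.row <- seq_len(nrow(intervals))
  for (ctg in intersect(unique(intervals$contig), unique(tracts$contig))) {
    iv <- intervals[intervals$contig == ctg, ]
    tr <- tracts[tracts$contig == ctg, ]
    qi <- IRanges::IRanges(iv$start + 1L, iv$end)
    ti <- IRanges::IRanges(tr$start + 1L, tr$end)
    ov <- IRanges::findOverlaps(qi, ti)
    if (length(ov) > 0) {
      w <- IRanges::width(IRanges::pintersect(
        qi[S4Vectors::queryHits(ov)], ti[S4Vectors::subjectHits(ov)]))
      cov <- tapply(w, S4Vectors::queryHits(ov), sum)
      rows <- iv$.row[as.integer(names(cov))]
      intervals$covered_bp[rows] <- as.integer(cov)
    }
  }
  intervals$.row <- NULL
  intervals
}

#' Welch test for terminal repeat enrichment
#'
#' Two-sample, two-tailed Welch (unequal variance) t-test of per-interval
#' repeat coverage, terminal windows versus random windows. When both groups
#' have zero variance and equal means the result is `t = 0, p = 1`.
#'
#' @param terminal_cov,random_cov Numeric vectors of covered bp per interval.
#' @param composition Optional tibble of per-class bp per group (carried
#'   through to the result).
#' @return An object of class `enrichment_result`.
#' @export
enrichment_test <- function(terminal_cov, random_cov, composition = NULL) {
  stopifnot(length(terminal_cov) > 0, length(random_cov) > 0)
  m1 <- mean(terminal_cov); m2 <- mean(random_cov)
  v1 <- stats::var(terminal_cov); v2 <- stats::var(random_cov)
  n1 <- length(terminal_cov); n2 <- length(random_cov)
  if ((is.na(v1) || v1 == 0) && (is.na(v2) || v2 == 0)) {
    if (isTRUE(all.equal(m1, m2))) {
      t_stat <- 0; p <- 1; df <- NA_real_
    } else {
      t_stat <- sign(m1 - m2) * Inf; p <- 0; df <- NA_real_
    }
  } else {
    tt <- t.test(terminal_cov, random_cov, var.equal = FALSE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
    df <- unname(tt$parameter)
  }
  structure(list(mean_terminal = m1, mean_random = m2, t = t_stat,
                 p_value = p, df = df, n_terminal = n1, n_random = n2,
                 composition = composition),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> mean terminal", round(x$mean_terminal, 1),
      "bp vs random", round(x$mean_random, 1), "bp; Welch t =",
      signif(x$t, 4), ", p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(group = c("terminal", "random"),
         mean_covered_bp = c(x$mean_terminal, x$mean_random),
         n = c(x$n_terminal, x$n_random))
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(statistic = x$t, p_value = x$p_value, df = x$df,
         mean_terminal = x$mean_terminal, mean_random = x$mean_random,
         n_terminal = x$n_terminal, n_random = x$n_random)
}

#' Terminal-versus-random repeat enrichment, end to end
#'
#' Convenience wrapper: collapses the annotation, builds terminal and random
#' windows, computes per-interval coverage and per-class composition of each
#' group, and runs the Welch test.
#'
#' @param contigs A sequence tibble or named vector of contig lengths.
#' @param features Repeat feature tibble.
#' @param L Window length (bp).
#' @param n_random Number of random windows.
#' @param seed Seed for the random windows.
#' @return An `enrichment_result`; `$composition` holds per-class bp by group.
#' @export
terminal_enrichment <- function(contigs, features, L = 5000, n_random = 10000,
                                seed = NULL) {
  tracts <- collapse_repeats(features)
  term <- terminal_intervals(contigs, L)
  rand <- random_windows(contigs, n_random, L, seed)
  tc <- interval_repeat_coverage(term, tracts)
  rc <- interval_repeat_coverage(rand, tracts)
  comp <- bind_rows(
    mutate(class_composition(term, features), group = "terminal"),
    mutate(class_composition(rand, features), group = "random"))
  enrichment_test(tc$covered_bp, rc$covered_bp, composition = comp)
}

# per-class covered bp within a set of intervals, from raw (uncollapsed)
# per-class features collapsed class by class
class_composition <- function(intervals, features) {
  purrr::map_dfr(split(features, features$ftype), function(f) {
    tr <- collapse_repeats(f)
    cov <- interval_repeat_coverage(intervals, tr)
    tibble(class = f$ftype[1], bp = sum(cov$covered_bp))
  }) |> arrange(desc(.data$bp))
}

#' Long-tract and terminus overlap statistics
#'
#' Computes the percentage of repeat tracts longer than `min_len`; of those
#' long tracts, the percentage overlapping (by at least 1 bp) any terminal
#' interval; and the percentage of terminal intervals more than 99% covered
#' by a single tract longer than `min_len`.
#'
#' @param tracts Collapsed tracts.
#' @param contigs A sequence tibble or named vector of contig lengths.
#' @param min_len Long-tract threshold (bp, strict).
#' @param L Terminal window length (bp).
#' @return One-row tibble: `n_tracts`, `n_long`, `pct_tracts_long`,
#'   `pct_long_overlapping_termini`, `pct_termini_over99_covered`.
#' @export
long_tract_stats <- function(tracts, contigs, min_len = 5000, L = 5000) {
  term <- terminal_intervals(contigs, L)
  tlen <- tracts$end - tracts$start
  long <- tracts[tlen > min_len, ]
  pct_long <- if (nrow(tracts) > 0) 100 * nrow(long) / nrow(tracts) else 0
  if (nrow(long) == 0) {
    warn("no tract exceeds min_len; overlap percentages reported as 0")
    return(tibble(n_tracts = nrow(tracts), n_long = 0L, pct_tracts_long = 0,
                  pct_long_overlapping_termini = 0,
                  pct_termini_over99_covered = 0))
  }
  ov_long <- interval_overlap_any(long, term)
  pct_ov <- 100 * sum(ov_long) / nrow(long)
  # >99% of a terminal window covered by one long tract
  covered99 <- vapply(seq_len(nrow(term)), function(i) {
    tr <- long[long$contig == term$contig[i], ]
    if (nrow(tr) == 0) return(FALSE)
    inter <- pmin(tr$end, term$end[i]) - pmax(tr$start, term$start[i])
    any(inter > 0.99 * (term$end[i] - term$start[i]))
  }, logical(1))
  tibble(n_tracts = nrow(tracts), n_long = nrow(long),
         pct_tracts_long = pct_long,
         pct_long_overlapping_termini = pct_ov,
         pct_termini_over99_covered = 100 * mean(covered99))
}

# does each interval in a overlap any interval in b (same contig, >=1 bp)?
interval_overlap_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    bb <- b[b$contig == a$contig[i], ]
    any(bb$start < a$end[i] & bb$end > a$start[i])
  }, logical(1))
}

#' Per-class totals and cumulative tract-length distribution
#'
#' Multi-class merged tracts contribute once to every class in their class
#' set, so the by-class total can exceed the merged total (flagged in the
#' `multi_class` column). The cumulative distribution gives the fraction of
#' total repeat bp held in tracts of length `<= x`.
#'
#' @param tracts Collapsed tracts.
#' @return An object of class `repeat_summary`: list with `by_class` and
#'   `cdf` tibbles and `total_bp`.
#' @export
repeat_summaries <- function(tracts) {
  len <- tracts$end - tracts$start
  by_class <- tibble(class = unlist(tracts$classes),
                     bp = rep(len, lengths(tracts$classes)),
                     multi_class = rep(lengths(tracts$classes) > 1,
                                       lengths(tracts$classes))) |>
    group_by(.data$class) |>
    summarise(bp = sum(.data$bp), n_tracts = n(),
              multi_class = any(.data$multi_class), .groups = "drop") |>
    arrange(desc(.data$bp))
  ord <- order(len)
  cdf <- tibble(length = len[ord], cum_bp = cumsum(as.numeric(len[ord]))) |>
    mutate(cum_frac = .data$cum_bp / sum(as.numeric(len)))
  structure(list(by_class = by_class, cdf = cdf, total_bp = sum(as.numeric(len))),
            class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat("<repeat_summary>", format(x$total_bp, big.mark = ","),
      "bp in", nrow(x$cdf), "tracts across", nrow(x$by_class), "classes\n")
  print(head(x$by_class, 8))
  invisible(x)
}

#' @export
tidy.repeat_summary <- function(x, ...) x$by_class

#' @export
glance.repeat_summary <- function(x, ...) {
  tibble(total_bp = x$total_bp, n_tracts = nrow(x$cdf),
         n_classes = nrow(x$by_class))
}

#' @export
autoplot.repeat_summary <- function(object, ...) {
  ggplot2::ggplot(object$cdf,
                  ggplot2::aes(x = .data$length, y = .data$cum_frac)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "tract length (bp)",
                  y = "cumulative fraction of repeat bp",
                  title = "Cumulative repeat tract length distribution") +
    ggplot2::theme_minimal()
}
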