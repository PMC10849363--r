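#' Count canonical k-mers
#'
#' Counts every k-long window of the supplied sequences under canonical form
#' (the lexicographically smaller of the k-mer and its reverse complement).
#' Windows containing `N` are skipped, so the total equals the number of
#' fully determined windows.
#'
#' @param seqs A sequence tibble (`id`, `seq`) or a character vector of
#'   sequences.
#' @param k Word size (1--32); 28 matches the satellite unit length this
#'   package's screens were designed around.
#' @return An object of class `kmer_table`: list with `k`, `counts` (tibble
#'   `kmer`, `count`, sorted by descending count), and `total_kmers`.
#' @export
count_kmers <- function(seqs, k = 28) {
  x <- if (is.data.frame(seqs)) seqs$seq else seqs
  stopifnot(k >= 1, k <= 32)
  df <- kmer_count_cpp(as.character(x), as.integer(k))
  counts <- as_tibble(df) |>
    mutate(count = as.numeric(.data$count)) |>
    arrange(desc(.data$count), .data$kmer)
  structure(list(k = as.integer(k), counts = counts,
                 total_kmers = sum(counts$count)),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("<kmer_table> k =", x$k, "|", nrow(x$counts), "distinct canonical k-mers |",
      format(x$total_kmers, big.mark = ","), "windows\n")
  print(head(x$counts, 5))
  invisible(x)
}

#' @export
tidy.kmer_table <- function(x, ...) x$counts

#' @export
glance.kmer_table <- function(x, ...) {
  tibble(k = x$k, distinct_kmers = nrow(x$counts), total_kmers = x$total_kmers)
}

#' Canonical rotation class of a tandem motif
#'
#' A tandem motif has arbitrary phase and strand; its class representative is
#' the lexicographic minimum over all rotations of the motif and of its
#' reverse complement. The result is invariant under rotation and reverse
#' complement, and idempotent.
#'
#' @param motif Character vector of DNA motifs (no `N`).
#' @return Character vector of class representatives.
#' @export
canonical_rotation <- function(motif) {
  vapply(motif, function(m) {
    stopifnot(nzchar(m), !grepl("N", m, fixed = TRUE))
    n <- nchar(m)
    rots <- function(s) {
      d <- paste0(s, s)
      vapply(seq_len(n), function(i) substr(d, i, i + n - 1L), character(1))
    }
    min(c(rots(m), rots(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

#' Detect tandem k-mer arrays
#'
#' Finds positions where the k-mer at `i` exactly equals the k-mer at
#' `i + k`, chains them into arrays (tolerating spacers up to `max_gap`
#' between consecutive tandem pairs, so interspersed elements do not split an
#' array), and groups arrays by the canonical rotation class of their unit.
#'
#' @param seqs A sequence tibble (`id`, `seq`).
#' @param k Tandem unit length.
#' @param min_copies Minimum copies for an array to be reported.
#' @param max_gap Maximum spacer (bp) bridged within one array.
#' @return A tibble with one row per rotation class: `class`,
#'   `total_copies`, `n_arrays`, and `arrays` (list-column of tibbles with
#'   `contig`, `start`, `end`, `copies`, `motif`).
#' @export
detect_kmer_arrays <- function(seqs, k = 28, min_copies = 5, max_gap = 2 * k) {
  stopifnot(k >= 2)
  arrays <- purrr::map2_dfr(seqs$id, seqs$seq, function(id, s) {
    pos <- tandem_positions_cpp(s, as.integer(k))
    if (length(pos) == 0) return(NULL)
    pos <- sort(pos)
    # gap between the end of the second copy of one pair and the next pair
    gap <- diff(pos) - 2L * k
    chain <- cumsum(c(0L, as.integer(gap > max_gap)))
    purrr::map_dfr(split(pos, chain), function(p) {
      # tandem-covered bp: union of the [p, p + 2k) windows in this chain
      cov <- sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(p + 1L, p + 2L * k))))
      tibble(contig = id,
             start = p[1],
             end = p[length(p)] + 2L * k,
             copies = as.integer(round(cov / k)),
             motif = substr(s, p[1] + 1L, p[1] + k))
    })
  })
  if (nrow(arrays) == 0 || is.null(arrays)) {
    return(tibble(class = character(), total_copies = integer(),
                  n_arrays = integer(), arrays = list()))
  }
  arrays <- arrays |>
    filter(.data$copies >= min_copies) |>
    mutate(class = canonical_rotation(.data$motif))
  arrays |>
    group_by(.data$class) |>
    summarise(total_copies = sum(.data$copies), n_arrays = n(),
              arrays = list(dplyr::pick("contig", "start", "end", "copies",
                                        "motif")),
              .groups = "drop") |>
    arrange(desc(.data$total_copies))
}

#' Screen samples for a satellite rotation class
#'
#' Counts, in every sample, canonical k-mers belonging to the given rotation
#' class, and normalises to copies per megabase so assemblies and read sets
#' of different sizes are comparable. A sample is called present when
#' `copies_per_mb >= threshold`.
#'
#' @param class Rotation class representative (see [canonical_rotation()]).
#' @param samples Named list of sequence tibbles (`id`, `seq`).
#' @param k Word size (defaults to the motif length).
#' @param threshold Presence threshold in copies per Mb.
#' @return A tibble `sample`, `copies`, `mb`, `copies_per_mb`, `present`.
#' @export
screen_presence <- function(class, samples, k = nchar(class), threshold = 1.0) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  member <- class_kmers(class, k)
  purrr::imap_dfr(samples, function(seqs, nm) {
    bp <- if (nrow(seqs) > 0) sum(nchar(seqs$seq)) else 0
    copies <- 0
    if (bp >= k && nrow(seqs) > 0) {
      tab <- count_kmers(seqs, k)
      copies <- sum(tab$counts$count[tab$counts$kmer %in% member])
    }
    mb <- bp / 1e6
    cpm <- if (mb > 0) copies / mb else 0
    tibble(sample = nm, copies = copies, mb = mb, copies_per_mb = cpm,
           present = cpm >= threshold)
  })
}

# the canonical k-mers generated by one rotation class
class_kmers <- function(class, k = nchar(class)) {
  stopifnot(nchar(class) == k)
  d <- paste0(class, class)
  rots <- vapply(seq_len(k), function(i) substr(d, i, i + k - 1L), character(1))
  unique(pmin(rots, revcomp(rots)))
}

#' Find tandem repeat tracts
#'
#' A desk-scale tandem-tract finder based on self-match fractions: for each
#' period `p <= max_period` it locates maximal runs where the base at `i`
#' equals the base at `i - p` for at least `min_match` of positions, grown
#' greedily from exact-match segments. Overlapping calls across periods are
#' resolved by keeping the highest `copy_number * match_fraction` (ties to
#' the smaller period). The consensus is the per-column majority over the
#' aligned copies.
#'
#' This is a simplified match-fraction model, not a reimplementation of
#' alignment-based tandem repeat finders; at `min_match = 1` it returns
#' exactly the maximal exact tandem runs.
#'
#' @param seqs A sequence tibble (`id`, `seq`) or a single DNA string.
#' @param max_period Largest period searched.
#' @param min_copies Minimum copy number of a reported tract.
#' @param min_match Minimum fraction of positions matching at lag `p`.
#' @return A tibble `contig`, `start`, `end` (0-based half-open), `period`,
#'   `copy_number`, `consensus`, `mean_match_fraction`.
#' @export
find_tandem_repeats <- function(seqs, max_period = 100, min_copies = 3,
                                min_match = 0.8) {
  if (!is.data.frame(seqs)) seqs <- tibble(id = "seq", seq = seqs)
  purrr::map2_dfr(seqs$id, seqs$seq, function(id, s) {
    cand <- tandem_candidates(s, max_period, min_copies, min_match)
    if (nrow(cand) == 0) return(NULL)
    cand <- cand |>
      mutate(score = .data$copy_number * .data$mean_match_fraction) |>
      arrange(desc(.data$score), .data$period, .data$start)
    kept <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (length(kept) == 0 ||
          !any(cand$start[i] < cand$end[kept] & cand$end[i] > cand$start[kept])) {
        kept <- c(kept, i)
      }
    }
    cand <- cand[sort(kept), ]
    cand$consensus <- vapply(seq_len(nrow(cand)), function(i) {
      tract_consensus(substr(s, cand$start[i] + 1L, cand$end[i]),
                      cand$period[i])
    }, character(1))
    tibble(contig = id, cand[, c("start", "end", "period", "copy_number",
                                 "consensus", "mean_match_fraction")])
  })
}

tandem_candidates <- function(s, max_period, min_copies, min_match) {
  n <- nchar(s)
  x <- charToRaw(s)
  out <- list()
  for (p in seq_len(min(max_period, n %/% 2))) {
    b <- x[(p + 1):n] == x[1:(n - p)]
    r <- rle(b)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ti <- which(r$values)
    if (length(ti) == 0) next
    used_until <- 0L
    for (j in ti) {
      if (starts[j] <= used_until) next
      run_s <- starts[j]
      run_e <- ends[j]
      matches <- r$lengths[j]
      jj <- j
      # greedily bridge mismatch gaps while the match fraction holds
      while (jj + 2 <= length(r$lengths)) {
        gap <- r$lengths[jj + 1]
        nxt <- r$lengths[jj + 2]
        if ((matches + nxt) / (run_e - run_s + 1 + gap + nxt) >= min_match) {
          matches <- matches + nxt
          run_e <- ends[jj + 2]
          jj <- jj + 2
        } else break
      }
      used_until <- run_e
      tract_len <- run_e - run_s + 1L + p
      if (tract_len >= min_copies * p) {
        out[[length(out) + 1L]] <- tibble(
          start = run_s - 1L, end = run_e + p, period = p,
          copy_number = tract_len / p,
          mean_match_fraction = matches / (run_e - run_s + 1L))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(start = integer(), end = integer(), period = integer(),
                  copy_number = numeric(), mean_match_fraction = numeric()))
  }
  bind_rows(out)
}

# per-column majority over copies aligned at the tract period
tract_consensus <- function(tract, p) {
  chars <- strsplit(tract, "")[[1]]
  col <- ((seq_along(chars) - 1L) %% p) + 1L
  vapply(seq_len(p), function(i) {
    tab <- sort(table(chars[col == i]), decreasing = TRUE)
    best <- tab[tab == tab[1]]
    sort(names(best))[1]
  }, character(1)) |> paste(collapse = "")
}
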