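#' Filter whole-genome alignments
#'
#' Drops blocks below the identity (`matches / alnlen`) or length threshold,
#' then removes every block whose query interval overlaps another retained
#' block by at least 1 bp, so that only uniquely aligning regions remain.
#' The multiplicity axis can be switched to the target.
#'
#' @param paf Alignment tibble from [read_paf()].
#' @param min_identity Minimum identity.
#' @param min_len Minimum block length (bp).
#' @param multiplicity_axis `"query"` (default) or `"target"`: axis on which
#'   multiply-aligned intervals are removed.
#' @return The filtered alignment tibble.
#' @export
filter_alignments <- function(paf, min_identity = 0.9, min_len = 10000,
                              multiplicity_axis = c("query", "target")) {
  multiplicity_axis <- match.arg(multiplicity_axis)
  keep <- paf |>
    filter(.data$matches / .data$alnlen >= min_identity,
           .data$alnlen >= min_len)
  if (nrow(keep) <= 1) return(keep)
  if (multiplicity_axis == "query") {
    nm <- keep$qname; s <- keep$qstart; e <- keep$qend
  } else {
    nm <- keep$tname; s <- keep$tstart; e <- keep$tend
  }
  drop <- logical(nrow(keep))
  for (ctg in unique(nm)) {
    i <- which(nm == ctg)
    if (length(i) < 2) next
    ir <- IRanges::IRanges(s[i] + 1L, e[i])
    drop[i] <- IRanges::countOverlaps(ir, ir) > 1
  }
  keep[!drop, ]
}

# run-length coverage profile of one axis as a tibble of depth runs
coverage_runs <- function(paf, genome_lengths, axis = c("query", "target")) {
  axis <- match.arg(axis)
  if (axis == "query") {
    nm <- paf$qname; s <- paf$qstart; e <- paf$qend
  } else {
    nm <- paf$tname; s <- paf$tstart; e <- paf$tend
  }
  purrr::imap_dfr(as.list(genome_lengths), function(len, ctg) {
    i <- which(nm == ctg)
    cov <- IRanges::coverage(IRanges::IRanges(s[i] + 1L, e[i]), width = len)
    r <- S4Vectors::runLength(cov)
    ends <- cumsum(r)
    tibble(contig = ctg, start = ends - r, end = ends,
           depth = S4Vectors::runValue(cov))
  })
}

#' One-to-one aligned fraction of a genome
#'
#' Percentage of the genome covered by exactly one filtered alignment
#' block, computed per axis.
#'
#' @param paf Filtered alignment tibble.
#' @param genome_lengths Named vector of contig lengths for the chosen axis.
#' @param axis `"query"` or `"target"`.
#' @return A single percentage.
#' @export
one_to_one_fraction <- function(paf, genome_lengths,
                                axis = c("query", "target")) {
  axis <- match.arg(axis)
  runs <- coverage_runs(paf, genome_lengths, axis)
  one <- runs |> filter(.data$depth == 1)
  100 * sum(one$end - one$start) / sum(as.numeric(genome_lengths))
}

#' Screen for large duplications by alignment depth
#'
#' Maximal runs of alignment depth at least `min_depth` spanning at least
#' `min_span` bp. Run on alignments *before* multiplicity filtering, since
#' multiple alignment is exactly the duplication signal.
#'
#' @param paf Alignment tibble (identity/length filtered only).
#' @param genome_lengths Named vector of contig lengths for the axis.
#' @param min_span Minimum run length (bp).
#' @param min_depth Minimum depth.
#' @param axis `"query"` or `"target"`.
#' @return A tibble `contig`, `start`, `end`, `min_depth_observed`.
#' @export
duplication_screen <- function(paf, genome_lengths, min_span = 100000,
                               min_depth = 2, axis = c("query", "target")) {
  axis <- match.arg(axis)
  runs <- coverage_runs(paf, genome_lengths, axis)
  high <- runs |>
    filter(.data$depth >= min_depth) |>
    arrange(.data$contig, .data$start)
  if (nrow(high) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  min_depth_observed = integer()))
  }
  high |>
    group_by(.data$contig) |>
    mutate(block = cumsum(c(TRUE, .data$start[-1] != .data$end[-n()]))) |>
    group_by(.data$contig, .data$block) |>
    summarise(start = min(.data$start), end = max(.data$end),
              min_depth_observed = min(.data$depth), .groups = "drop") |>
    filter(.data$end - .data$start >= min_span) |>
    select("contig", "start", "end", "min_depth_observed") |>
    arrange(.data$contig, .data$start)
}

#' Identify and classify large nonaligning regions
#'
#' Complements the filtered alignment footprint per contig, keeps regions of
#' at least `min_span` bp, computes their repeat fraction against the merged
#' repeat set (annotation tracts plus tandem-finder tracts), and classifies
#' each region as `repeat_associated` (fraction at least 0.5) or `unique`.
#'
#' @param paf Filtered alignment tibble.
#' @param genome_lengths Named contig lengths for the chosen axis.
#' @param repeat_tracts Collapsed repeat tracts (may be merged with tandem
#'   tracts beforehand via [collapse_repeats()] on their union).
#' @param min_span Minimum region length (bp).
#' @param axis `"query"` or `"target"`.
#' @return A tibble `contig`, `start`, `end`, `length`, `repeat_bp`,
#'   `repeat_fraction`, `classification`.
#' @export
nonaligning_regions <- function(paf, genome_lengths, repeat_tracts,
                                min_span = 100000,
                                axis = c("query", "target")) {
  axis <- match.arg(axis)
  runs <- coverage_runs(paf, genome_lengths, axis)
  regions <- runs |>
    filter(.data$depth == 0, .data$end - .data$start >= min_span) |>
    select("contig", "start", "end")
  if (nrow(regions) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  length = integer(), repeat_bp = integer(),
                  repeat_fraction = numeric(), classification = character()))
  }
  regions <- interval_repeat_coverage(regions, repeat_tracts)
  regions |>
    mutate(length = .data$end - .data$start,
           repeat_bp = .data$covered_bp,
           repeat_fraction = .data$repeat_bp / .data$length,
           classification = if_else(.data$repeat_fraction >= 0.5,
                                    "repeat_associated", "unique")) |>
    select("contig", "start", "end", "length", "repeat_bp",
           "repeat_fraction", "classification")
}

#' Detect inversions from strand changes within contig pairs
#'
#' Within each aligned (query contig, target contig) pair, blocks are sorted
#' along the query; the pair's majority strand (by aligned bp) is the
#' flanking strand, and each maximal run of opposite-strand blocks whose
#' query span reaches `min_span` yields one call. Runs touching either end
#' of the pair's block list have no flank on one side and are flagged low
#' confidence, since the orientation of a whole contig is arbitrary.
#'
#' @param paf Filtered alignment tibble.
#' @param min_span Minimum query span of the inverted run (bp).
#' @return A tibble `qname`, `tname`, `qstart`, `qend`, `tstart`, `tend`,
#'   `n_blocks`, `flanking_strand`, `inverted_strand`, `low_confidence`.
#' @export
detect_inversions <- function(paf, min_span = 100000) {
  empty <- tibble(qname = character(), tname = character(),
                  qstart = integer(), qend = integer(), tstart = integer(),
                  tend = integer(), n_blocks = integer(),
                  flanking_strand = character(), inverted_strand = character(),
                  low_confidence = logical())
  if (nrow(paf) == 0) return(empty)
  paf |>
    group_by(.data$qname, .data$tname) |>
    group_split() |>
    purrr::map_dfr(function(g) {
      g <- g |> arrange(.data$qstart)
      bp_by_strand <- tapply(g$alnlen, g$strand, sum)
      flank <- names(bp_by_strand)[which.max(bp_by_strand)]
      inv <- g$strand != flank
      if (!any(inv)) return(NULL)
      r <- rle(inv)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      purrr::map_dfr(runs, function(j) {
        blk <- g[starts[j]:ends[j], ]
        qspan <- max(blk$qend) - min(blk$qstart)
        if (qspan < min_span) return(NULL)
        tibble(qname = g$qname[1], tname = g$tname[1],
               qstart = min(blk$qstart), qend = max(blk$qend),
               tstart = min(blk$tstart), tend = max(blk$tend),
               n_blocks = nrow(blk),
               flanking_strand = flank,
               inverted_strand = blk$strand[1],
               low_confidence = starts[j] == 1 | ends[j] == nrow(g))
      })
    }) |>
    (\(x) if (nrow(x) == 0) empty else x)() |>
    arrange(.data$qname, .data$qstart)
}

#' Contigs spanning multiple contigs of the other assembly
#'
#' Reports contigs aligned to two or more distinct contigs of the other
#' species, each pair contributing at least `min_pair_span` aligned bp —
#' the signature of an assembly break present in one species but spanned in
#' the other. Computed symmetrically for both axes.
#'
#' @param paf Filtered alignment tibble.
#' @param min_pair_span Minimum aligned bp per (contig, partner) pair.
#' @return A tibble `axis`, `contig`, `n_spanned`, `spanned` (list of
#'   per-partner tibbles `partner`, `aligned_bp`).
#' @export
spanning_relationships <- function(paf, min_pair_span = 100000) {
  one_axis <- function(nm, partner, label) {
    tibble(contig = nm, partner = partner, bp = paf$alnlen) |>
      group_by(.data$contig, .data$partner) |>
      summarise(aligned_bp = sum(.data$bp), .groups = "drop") |>
      filter(.data$aligned_bp >= min_pair_span) |>
      group_by(.data$contig) |>
      filter(n() >= 2) |>
      summarise(n_spanned = n(),
                spanned = list(dplyr::pick("partner", "aligned_bp")),
                .groups = "drop") |>
      mutate(axis = label, .before = 1)
  }
  bind_rows(one_axis(paf$qname, paf$tname, "query"),
            one_axis(paf$tname, paf$qname, "target"))
}

#' Whole-genome comparison, end to end
#'
#' Applies the identity/length filter, removes multiply-aligned query
#' intervals, and computes the one-to-one fractions, duplication screen
#' (from pre-multiplicity-filter alignments), nonaligning regions for both
#' axes, inversions, and spanning relationships.
#'
#' @param paf Raw alignment tibble (query = assembly B, target = assembly A).
#' @param lengths_a,lengths_b Named contig lengths of target (A) and query
#'   (B) assemblies.
#' @param tracts_a,tracts_b Collapsed repeat tracts per assembly (annotation
#'   merged with tandem tracts as desired).
#' @param min_identity,min_len,min_span See the individual steps.
#' @return An object of class `wga_result`.
#' @export
compare_wga <- function(paf, lengths_a, lengths_b, tracts_a = NULL,
                        tracts_b = NULL, min_identity = 0.9, min_len = 10000,
                        min_span = 100000) {
  prefilter <- paf |>
    filter(.data$matches / .data$alnlen >= min_identity,
           .data$alnlen >= min_len)
  filtered <- filter_alignments(paf, min_identity, min_len)
  empty_tracts <- tibble(contig = character(), start = integer(),
                         end = integer(), classes = list())
  res <- list(
    filtered = filtered,
    one_to_one = tibble(
      assembly = c("A", "B"),
      pct = c(one_to_one_fraction(filtered, lengths_a, "target"),
              one_to_one_fraction(filtered, lengths_b, "query"))),
    duplications = bind_rows(
      mutate(duplication_screen(prefilter, lengths_a, min_span,
                                axis = "target"), assembly = "A"),
      mutate(duplication_screen(prefilter, lengths_b, min_span,
                                axis = "query"), assembly = "B")),
    nonaligned = bind_rows(
      mutate(nonaligning_regions(filtered, lengths_a,
                                 tracts_a %||% empty_tracts, min_span,
                                 "target"), assembly = "A"),
      mutate(nonaligning_regions(filtered, lengths_b,
                                 tracts_b %||% empty_tracts, min_span,
                                 "query"), assembly = "B")),
    inversions = detect_inversions(filtered, min_span),
    spanning = spanning_relationships(filtered, min_span),
    params = list(min_identity = min_identity, min_len = min_len,
                  min_span = min_span))
  structure(res, class = "wga_result")
}

#' @export
print.wga_result <- function(x, ...) {
  cat("<wga_result> 1:1 aligned:",
      paste0(round(x$one_to_one$pct, 1), "%", collapse = " / "),
      "(A/B);", nrow(x$inversions), "inversion call(s);",
      nrow(x$duplications), "duplication candidate(s);",
      nrow(x$nonaligned), "nonaligned region(s)\n")
  invisible(x)
}

#' @export
glance.wga_result <- function(x, ...) {
  na_rep <- sum(x$nonaligned$classification == "repeat_associated")
  tibble(pct_one_to_one_a = x$one_to_one$pct[1],
         pct_one_to_one_b = x$one_to_one$pct[2],
         n_inversions = nrow(x$inversions),
         n_duplications = nrow(x$duplications),
         n_nonaligned = nrow(x$nonaligned),
         n_nonaligned_repeat = na_rep,
         n_blocks_retained = nrow(x$filtered))
}

#' @export
tidy.wga_result <- function(x, ...) x$inversions

#' @export
autoplot.wga_result <- function(object, ...) {
  f <- object$filtered
  ggplot2::ggplot(f, ggplot2::aes(x = .data$tstart, xend = .data$tend,
                                  y = .data$qstart, yend = .data$qend,
                                  colour = .data$strand)) +
    ggplot2::geom_segment() +
    ggplot2::facet_grid(.data$qname ~ .data$tname, scales = "free") +
    ggplot2::labs(x = "target position (bp)", y = "query position (bp)",
                  title = "Filtered whole-genome alignment blocks") +
    ggplot2::theme_minimal()
}
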