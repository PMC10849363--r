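#' Filter marker hits by E-value
#'
#' Retains tabular hits with E-value strictly below `e_max` (the default
#' threshold admits multiple SNPs within a short GBS locus while rejecting
#' spurious placements). When several hits of one marker survive, the lowest
#' E-value wins, ties broken by highest bit score; a marker whose best hits
#' remain tied is dropped with a warning, since it cannot be placed uniquely.
#'
#' The marker position on the contig is taken as the midpoint of the subject
#' interval, converted to the internal 0-based convention.
#'
#' @param hits A hit tibble (see [read_hits()]); `query` is the marker id.
#' @param e_max E-value threshold (strict `<`).
#' @return A tibble `marker`, `contig`, `bp`, `evalue`, `bitscore`.
#' @export
filter_hits <- function(hits, e_max = 4e-24) {
  kept <- hits |>
    filter(.data$evalue < e_max) |>
    mutate(bp = as.integer(floor((pmin(.data$sstart, .data$send) - 1 +
                                    pmax(.data$sstart, .data$send)) / 2)))
  if (nrow(kept) == 0) {
    return(tibble(marker = character(), contig = character(), bp = integer(),
                  evalue = numeric(), bitscore = numeric()))
  }
  best <- kept |>
    group_by(.data$query) |>
    filter(.data$evalue == min(.data$evalue)) |>
    filter(.data$bitscore == max(.data$bitscore)) |>
    ungroup()
  ambiguous <- best |> count(.data$query) |> filter(.data$n > 1) |> pull(.data$query)
  if (length(ambiguous) > 0) {
    warn(paste0("dropping ", length(ambiguous),
                " marker(s) with tied best hits: ",
                paste(head(ambiguous, 5), collapse = ", ")))
    best <- best |> filter(!.data$query %in% ambiguous)
  }
  best |>
    select(marker = "query", contig = "subject", "bp", "evalue", "bitscore") |>
    arrange(.data$marker)
}

#' Assign contigs to linkage groups by marker content
#'
#' A contig is assigned to the linkage group holding a strict majority of
#' its mapped markers; with two or more groups represented, the winning
#' group must hold at least two-thirds of the markers and not be tied,
#' otherwise the contig is left unassigned and flagged as a chimera
#' candidate (`multi_LG`).
#'
#' @param retained Filtered marker hits from [filter_hits()].
#' @param map A genetic-map tibble (`marker`, `cross`, `linkage_group`, `cM`).
#' @return List with `assignments` (tibble `contig`, `linkage_group`,
#'   `n_markers`) and `conflicts` (tibble `contig`, `kind`, `details`).
#' @export
assign_contigs <- function(retained, map) {
  lg_of <- map |> distinct(.data$marker, .data$linkage_group)
  dat <- retained |> inner_join(lg_of, by = "marker")
  tallies <- dat |>
    count(.data$contig, .data$linkage_group, name = "n_markers") |>
    group_by(.data$contig) |>
    arrange(desc(.data$n_markers), .by_group = TRUE) |>
    mutate(total = sum(.data$n_markers), n_lg = n()) |>
    ungroup()
  top <- tallies |>
    group_by(.data$contig) |>
    slice(1:2) |>
    summarise(second = ifelse(n() > 1, .data$n_markers[2], 0L),
              linkage_group = first(.data$linkage_group),
              n_markers = first(.data$n_markers),
              total = first(.data$total), n_lg = first(.data$n_lg),
              .groups = "drop")
  ok <- top$n_lg == 1 |
    (top$n_markers > top$second & top$n_markers / top$total >= 2 / 3)
  assignments <- top[ok, c("contig", "linkage_group", "n_markers")]
  conflicts <- tibble(
    contig = top$contig[!ok], kind = "multi_LG",
    details = paste0("markers split across ", top$n_lg[!ok],
                     " linkage groups (top ", top$n_markers[!ok], "/",
                     top$total[!ok], ")"))
  list(assignments = arrange(assignments, .data$contig), conflicts = conflicts)
}

# orientation from the sign of the rank correlation between genetic and
# physical position; eligibility requires both marker count and bp span
decide_orientation <- function(cM, bp, min_markers, min_span) {
  span <- diff(range(bp))
  if (length(bp) < min_markers || span < min_span) return("?")
  if (length(unique(cM)) < 2 || length(unique(bp)) < 2) return("?")
  rho <- suppressWarnings(cor(cM, bp, method = "spearman"))
  if (is.na(rho) || rho == 0) "?" else if (rho > 0) "+" else "-"
}

#' Order and orient contigs within linkage groups
#'
#' Contigs are ordered within each linkage group by the median genetic
#' position (cM) of their markers; ties are broken by marker count, contig
#' length, then contig id, for a fully deterministic order. A contig is
#' oriented only when it carries at least `min_markers` markers spanning at
#' least `min_span` bp: the orientation is the sign of the Spearman rank
#' correlation between cM and bp (equivalent, for monotone signals, to
#' testing which physical direction recombination distance increases in).
#'
#' @param assignments Output of [assign_contigs()] (`$assignments`).
#' @param retained Filtered marker hits.
#' @param map Genetic-map tibble.
#' @param min_markers Minimum markers to attempt orientation.
#' @param min_span Minimum marker bp span to attempt orientation.
#' @param contig_lengths Optional named lengths used in tie-breaks.
#' @return A placement tibble: `contig`, `linkage_group`, `rank`,
#'   `orientation`, `evidence`, `n_markers`, `span_bp`, `anchor_cM`,
#'   `orientation_evidence`.
#' @export
order_and_orient <- function(assignments, retained, map, min_markers = 3,
                             min_span = 30000, contig_lengths = NULL) {
  lg_of <- map |> distinct(.data$marker, .data$linkage_group)
  cm_of <- map |>
    group_by(.data$marker) |>
    summarise(cM = median(.data$cM), .groups = "drop")
  dat <- retained |>
    inner_join(lg_of, by = "marker") |>
    inner_join(cm_of, by = "marker") |>
    inner_join(assignments, by = c("contig", "linkage_group"),
               suffix = c("", ".a"))
  per_contig <- dat |>
    group_by(.data$contig, .data$linkage_group) |>
    summarise(n_markers = n(),
              span_bp = diff(range(.data$bp)),
              anchor_cM = median(.data$cM),
              orientation = decide_orientation(.data$cM, .data$bp,
                                               min_markers, min_span),
              .groups = "drop")
  len <- if (is.null(contig_lengths)) {
    setNames(rep(0, nrow(per_contig)), per_contig$contig)
  } else contig_lengths
  per_contig |>
    mutate(length = as.numeric(len[.data$contig]),
           evidence = "primary_map",
           orientation_evidence = if_else(.data$orientation == "?",
                                          "none", "linkage_map")) |>
    group_by(.data$linkage_group) |>
    arrange(.data$anchor_cM, desc(.data$n_markers), desc(.data$length),
            .data$contig, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    select("contig", "linkage_group", "rank", "orientation", "evidence",
           "n_markers", "span_bp", "anchor_cM", "orientation_evidence") |>
    arrange(.data$linkage_group, .data$rank)
}

#' Place additional contigs using secondary-cross maps
#'
#' Contigs without primary-map markers can still be placed when a secondary
#' cross maps them: the contig's neighbours in the secondary map order (among
#' contigs shared with the primary placement) determine the insertion point.
#' Insertion happens only when both neighbours exist, sit on one primary
#' linkage group, and are adjacent there; anything else is flagged
#' `unresolved_insertion` and the contig stays unplaced.
#'
#' @param placements Primary placement tibble from [order_and_orient()].
#' @param retained Filtered marker hits (all crosses).
#' @param map Genetic-map tibble covering all crosses.
#' @param primary_cross Cross id used for the primary placements.
#' @param min_markers,min_span Orientation eligibility (as in
#'   [order_and_orient()]).
#' @return List with updated `placements` and `conflicts`.
#' @export
integrate_secondary_maps <- function(placements, retained, map, primary_cross,
                                     min_markers = 3, min_span = 30000) {
  conflicts <- tibble(contig = character(), kind = character(),
                      details = character())
  secondary <- setdiff(unique(map$cross), primary_cross)
  for (cr in secondary) {
    map_c <- map |> filter(.data$cross == cr)
    asg <- assign_contigs(retained, map_c)$assignments
    cm_of <- map_c |> select("marker", sec_lg = "linkage_group", "cM")
    anchors <- retained |>
      inner_join(cm_of, by = "marker") |>
      inner_join(asg, by = "contig") |>
      filter(.data$sec_lg == .data$linkage_group) |>
      group_by(.data$contig, .data$sec_lg) |>
      summarise(sec_cM = median(.data$cM), n_markers = n(),
                span_bp = diff(range(.data$bp)),
                orientation = decide_orientation(.data$cM, .data$bp,
                                                 min_markers, min_span),
                .groups = "drop")
    new_contigs <- setdiff(anchors$contig, placements$contig)
    for (ctg in new_contigs) {
      a <- anchors[anchors$contig == ctg, ]
      shared <- anchors |>
        filter(.data$sec_lg == a$sec_lg, .data$contig %in% placements$contig) |>
        arrange(.data$sec_cM)
      prev <- shared |> filter(.data$sec_cM <= a$sec_cM) |> tail(1)
      nxt <- shared |> filter(.data$sec_cM > a$sec_cM) |> head(1)
      if (nrow(prev) == 0 || nrow(nxt) == 0) {
        conflicts <- bind_rows(conflicts, tibble(
          contig = ctg, kind = "unresolved_insertion",
          details = paste0("cross ", cr, ": fewer than two placed neighbours")))
        next
      }
      p1 <- placements[placements$contig == prev$contig, ]
      p2 <- placements[placements$contig == nxt$contig, ]
      if (p1$linkage_group != p2$linkage_group) {
        conflicts <- bind_rows(conflicts, tibble(
          contig = ctg, kind = "unresolved_insertion",
          details = paste0("cross ", cr, ": neighbours on different primary ",
                           "linkage groups (", p1$linkage_group, ", ",
                           p2$linkage_group, ")")))
        next
      }
      if (abs(p1$rank - p2$rank) != 1) {
        conflicts <- bind_rows(conflicts, tibble(
          contig = ctg, kind = "unresolved_insertion",
          details = paste0("cross ", cr, ": neighbours not adjacent in ",
                           "primary order")))
        next
      }
      lo <- min(p1$rank, p2$rank)
      in_lg <- placements$linkage_group == p1$linkage_group
      placements$rank[in_lg & placements$rank > lo] <-
        placements$rank[in_lg & placements$rank > lo] + 1L
      placements <- bind_rows(placements, tibble(
        contig = ctg, linkage_group = p1$linkage_group, rank = lo + 1L,
        orientation = a$orientation, evidence = "secondary_map",
        n_markers = a$n_markers, span_bp = a$span_bp, anchor_cM = NA_real_,
        orientation_evidence = if_else(a$orientation == "?", "none",
                                       "linkage_map")))
    }
  }
  list(placements = arrange(placements, .data$linkage_group, .data$rank),
       conflicts = conflicts)
}

#' Reconcile placements with a reference-guided order
#'
#' Contigs the linkage data could not orient adopt the reference-guided
#' orientation (recorded as such in `orientation_evidence`); contigs the
#' linkage data did orient keep their orientation, and any disagreement with
#' the reference is flagged `orientation_disagreement`. Unplaced contigs
#' present in the order table are appended to the tail of the matching
#' linkage group with `reference_guided` evidence.
#'
#' @param placements Placement tibble.
#' @param order_table Reference-guided order (see [read_order()]); the
#'   `scaffold` column is matched against linkage-group names for appending.
#' @param contig_lengths Optional named lengths; order-table rows for
#'   unknown contigs are skipped with a warning.
#' @return List with `placements` and `conflicts`.
#' @export
reconcile_reference_guided <- function(placements, order_table,
                                       contig_lengths = NULL) {
  conflicts <- tibble(contig = character(), kind = character(),
                      details = character())
  if (nrow(order_table) == 0) {
    return(list(placements = placements, conflicts = conflicts))
  }
  if (!is.null(contig_lengths)) {
    unknown <- setdiff(order_table$contig, names(contig_lengths))
    if (length(unknown) > 0) {
      warn(paste0("order table references ", length(unknown),
                  " unknown contig(s); rows skipped"))
      order_table <- order_table |> filter(!.data$contig %in% unknown)
    }
  }
  ref <- order_table |> distinct(.data$contig, .keep_all = TRUE)
  idx <- match(placements$contig, ref$contig)
  for (i in which(!is.na(idx))) {
    ref_or <- ref$orientation[idx[i]]
    if (ref_or == "?") next
    if (placements$orientation[i] == "?") {
      placements$orientation[i] <- ref_or
      placements$orientation_evidence[i] <- "reference_guided"
    } else if (placements$orientation[i] != ref_or) {
      conflicts <- bind_rows(conflicts, tibble(
        contig = placements$contig[i], kind = "orientation_disagreement",
        details = paste0("linkage ", placements$orientation[i],
                         " vs reference ", ref_or,
                         "; linkage orientation kept")))
    }
  }
  extra <- ref |>
    filter(!.data$contig %in% placements$contig,
           .data$scaffold %in% placements$linkage_group) |>
    arrange(.data$scaffold, .data$rank)
  for (i in seq_len(nrow(extra))) {
    lg <- extra$scaffold[i]
    placements <- bind_rows(placements, tibble(
      contig = extra$contig[i], linkage_group = lg,
      rank = max(placements$rank[placements$linkage_group == lg]) + 1L,
      orientation = extra$orientation[i], evidence = "reference_guided",
      n_markers = 0L, span_bp = 0L, anchor_cM = NA_real_,
      orientation_evidence = if_else(extra$orientation[i] == "?", "none",
                                     "reference_guided")))
  }
  list(placements = arrange(placements, .data$linkage_group, .data$rank),
       conflicts = conflicts)
}

#' Build scaffolds from placements
#'
#' Emits one scaffold per linkage group: contigs in rank order, minus-strand
#' contigs reverse-complemented, unoriented contigs used in their forward
#' sense but written to AGP with orientation `?`, and a fixed-length `U` gap
#' (`scaffold` type, linked, `map` evidence) between consecutive components.
#' The AGP invariants are validated before anything is returned.
#'
#' @param placements Placement tibble.
#' @param contigs Sequence tibble of the assembly being scaffolded.
#' @param gap Gap length in bp between components.
#' @return An object of class `scaffold_set`: list with `agp`, `scaffolds`
#'   (sequence tibble), and `summary` (one-row tibble).
#' @export
build_scaffolds <- function(placements, contigs, gap = 100) {
  validate_seqs(contigs)
  lens <- seq_lengths(contigs)
  missing <- setdiff(placements$contig, names(lens))
  if (length(missing) > 0) {
    abort(paste0("placements reference unknown contig(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  seq_of <- setNames(contigs$seq, contigs$id)
  agp <- list()
  scafs <- list()
  for (lg in unique(placements$linkage_group)) {
    pl <- placements |> filter(.data$linkage_group == lg) |> arrange(.data$rank)
    pos <- 1L
    part <- 1L
    pieces <- character(0)
    for (i in seq_len(nrow(pl))) {
      ctg <- pl$contig[i]
      clen <- as.integer(lens[ctg])
      if (i > 1) {
        agp[[length(agp) + 1L]] <- tibble(
          scaffold = lg, scaffold_start = pos,
          scaffold_end = pos + as.integer(gap) - 1L, part_number = part,
          component_type = "U", component_id = NA_character_,
          component_beg = NA_integer_, component_end = NA_integer_,
          orientation = NA_character_, gap_length = as.integer(gap),
          gap_type = "scaffold", linkage = "yes", evidence = "map")
        pieces <- c(pieces, strrep("N", gap))
        pos <- pos + as.integer(gap)
        part <- part + 1L
      }
      agp[[length(agp) + 1L]] <- tibble(
        scaffold = lg, scaffold_start = pos, scaffold_end = pos + clen - 1L,
        part_number = part, component_type = "W", component_id = ctg,
        component_beg = 1L, component_end = clen,
        orientation = pl$orientation[i], gap_length = NA_integer_,
        gap_type = NA_character_, linkage = NA_character_,
        evidence = NA_character_)
      s <- seq_of[[ctg]]
      pieces <- c(pieces, if (pl$orientation[i] == "-") revcomp(s) else s)
      pos <- pos + clen
      part <- part + 1L
    }
    scafs[[length(scafs) + 1L]] <- tibble(id = lg,
                                          seq = paste(pieces, collapse = ""))
  }
  agp <- bind_rows(agp)
  validate_agp(agp, lens)
  scaffolds <- bind_rows(scafs)
  placed_bp <- sum(lens[unique(placements$contig)])
  summary <- tibble(
    n_scaffolds = nrow(scaffolds),
    contigs_placed = length(unique(placements$contig)),
    bp_placed = placed_bp,
    pct_assembly = 100 * placed_bp / sum(lens),
    n_oriented = sum(placements$orientation != "?"))
  structure(list(agp = agp, scaffolds = scaffolds, summary = summary),
            class = "scaffold_set")
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat("<scaffold_set>", x$summary$n_scaffolds, "scaffolds,",
      x$summary$contigs_placed, "contigs,",
      format(x$summary$bp_placed, big.mark = ","), "bp (",
      round(x$summary$pct_assembly, 1), "% of assembly )\n")
  invisible(x)
}

#' Anchor an assembly to linkage maps, end to end
#'
#' Runs the full anchoring chain: E-value filtering, linkage-group
#' assignment, ordering and orientation from the primary cross, insertion of
#' secondary-cross contigs, and optional reconciliation with a
#' reference-guided order.
#'
#' @param hits Hit tibble (markers vs contigs).
#' @param map Genetic-map tibble covering all crosses.
#' @param primary_cross Cross id used for ordering; defaults to the cross
#'   with the most markers.
#' @param ref_order Optional reference-guided order table.
#' @param contigs Optional sequence tibble (enables length tie-breaks and
#'   scaffold building via [build_scaffolds()]).
#' @param e_max,min_markers,min_span See the individual steps.
#' @return An object of class `anchor_result`: list with `placements`,
#'   `conflicts`, `unplaced`, and `params`.
#' @export
anchor_contigs <- function(hits, map, primary_cross = NULL, ref_order = NULL,
                           contigs = NULL, e_max = 4e-24, min_markers = 3,
                           min_span = 30000) {
  if (is.null(primary_cross)) {
    primary_cross <- map |> count(.data$cross) |> slice_max(.data$n, n = 1) |>
      slice(1) |> pull(.data$cross)
  }
  lens <- if (is.null(contigs)) NULL else seq_lengths(contigs)
  retained <- filter_hits(hits, e_max)
  map_primary <- map |> filter(.data$cross == primary_cross)
  asg <- assign_contigs(retained, map_primary)
  placements <- order_and_orient(asg$assignments, retained, map_primary,
                                 min_markers, min_span, lens)
  sec <- integrate_secondary_maps(placements, retained, map, primary_cross,
                                  min_markers, min_span)
  conflicts <- bind_rows(asg$conflicts, sec$conflicts)
  placements <- sec$placements
  if (!is.null(ref_order)) {
    rec <- reconcile_reference_guided(placements, ref_order, lens)
    placements <- rec$placements
    conflicts <- bind_rows(conflicts, rec$conflicts)
  }
  unplaced <- if (is.null(lens)) {
    setdiff(unique(hits$subject), placements$contig)
  } else setdiff(names(lens), placements$contig)
  structure(list(placements = placements, conflicts = conflicts,
                 unplaced = unplaced,
                 params = list(primary_cross = primary_cross, e_max = e_max,
                               min_markers = min_markers,
                               min_span = min_span)),
            class = "anchor_result")
}

#' @export
print.anchor_result <- function(x, ...) {
  cat("<anchor_result>", nrow(x$placements), "contigs placed on",
      n_distinct(x$placements$linkage_group), "linkage groups;",
      sum(x$placements$orientation != "?"), "oriented;",
      nrow(x$conflicts), "conflicts;", length(x$unplaced), "unplaced\n")
  invisible(x)
}

#' @export
tidy.anchor_result <- function(x, ...) x$placements

#' @export
glance.anchor_result <- function(x, ...) {
  tibble(n_placed = nrow(x$placements),
         n_linkage_groups = n_distinct(x$placements$linkage_group),
         n_oriented = sum(x$placements$orientation != "?"),
         n_conflicts = nrow(x$conflicts),
         n_unplaced = length(x$unplaced))
}

#' @param object An `anchor_result`.
#' @param retained Filtered marker hits used for the placements (adds marker
#'   points to the plot when supplied).
#' @param ... Unused.
#' @rdname anchor_contigs
#' @export
autoplot.anchor_result <- function(object, retained = NULL, ...) {
  pl <- object$placements
  ggplot2::ggplot(pl, ggplot2::aes(x = .data$rank, y = .data$anchor_cM,
                                   shape = .data$orientation)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::facet_wrap(~linkage_group, scales = "free") +
    ggplot2::labs(x = "contig rank", y = "anchor position (cM)",
                  title = "Contig placements along linkage groups") +
    ggplot2::theme_minimal()
}
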