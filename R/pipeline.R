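#' Run the full comparative pipeline on a synthetic study
#'
#' Executes every stage in dependency order on the study's evidence files:
#' linkage anchoring (with secondary-map integration and reference-guided
#' reconciliation) and scaffolding; whole-genome alignment comparison;
#' repeat-interval statistics and terminal enrichment for both assemblies;
#' tandem k-mer array detection and cross-sample presence screening; and
#' the gene-model comparison (reciprocal best hits, lift-over, exon-overlap
#' matching, ORF validity, linkage-group/chromosome correspondence).
#' Finally the outputs are scored against the simulation truth.
#'
#' @param study A [simulate_study()] result.
#' @param min_identity,min_len,min_span Whole-genome alignment thresholds.
#' @param e_max,min_markers,min_span_anchor Anchoring thresholds.
#' @param n_random Random windows per assembly for the enrichment test.
#' @param outdir Optional directory: evidence and result tables are written
#'   there.
#' @return An object of class `pipeline_result`: per-stage results plus a
#'   `scorecard` tibble.
#' @export
run_pipeline <- function(study, min_identity = 0.9, min_len = 10000,
                         min_span = 100000, e_max = 4e-24, min_markers = 3,
                         min_span_anchor = 30000, n_random = 10000,
                         outdir = NULL) {
  stopifnot(inherits(study, "sim_study"))
  cfg <- study$config

  # --- anchoring --------------------------------------------------------
  anchor <- anchor_contigs(study$marker_hits, study$maps,
                           primary_cross = "cross1",
                           ref_order = study$ref_order,
                           contigs = study$contigs_a, e_max = e_max,
                           min_markers = min_markers,
                           min_span = min_span_anchor)
  scaffolds <- build_scaffolds(anchor$placements, study$contigs_a)

  # --- whole-genome comparison ------------------------------------------
  tracts_a <- collapse_repeats(study$repeat_gff_a)
  tracts_b <- collapse_repeats(study$repeat_gff_b)
  wga <- compare_wga(study$paf, seq_lengths(study$contigs_a),
                     seq_lengths(study$contigs_b), tracts_a, tracts_b,
                     min_identity, min_len, min_span)

  # --- repeat statistics -------------------------------------------------
  stats_a <- contig_stats(study$contigs_a)
  stats_b <- contig_stats(study$contigs_b)
  enrich_a <- terminal_enrichment(study$contigs_a, study$repeat_gff_a,
                                  n_random = n_random)
  enrich_b <- terminal_enrichment(study$contigs_b, study$repeat_gff_b,
                                  n_random = n_random)
  long_a <- long_tract_stats(tracts_a, study$contigs_a)
  long_b <- long_tract_stats(tracts_b, study$contigs_b)
  summary_a <- repeat_summaries(tracts_a)
  summary_b <- repeat_summaries(tracts_b)

  # --- tandem k-mer satellite -------------------------------------------
  k <- nchar(cfg$satellite_motif)
  arrays_a <- detect_kmer_arrays(study$contigs_a, k = k)
  arrays_b <- detect_kmer_arrays(study$contigs_b, k = k)
  top_class <- if (nrow(arrays_b) > 0) arrays_b$class[1] else NA_character_
  outgroup <- tibble(id = "outgroup", seq = random_dna(500000))
  presence <- if (!is.na(top_class)) {
    screen_presence(top_class, list(species_A = study$contigs_a,
                                    species_B = study$contigs_b,
                                    outgroup = outgroup), k = k)
  } else tibble()

  # --- gene comparison ---------------------------------------------------
  rbh <- reciprocal_best_hits(study$protein_hits_ab, study$protein_hits_ba)
  exons_a <- gene_exon_table(study$gene_gff_a)
  exons_b <- gene_exon_table(study$gene_gff_b)
  lift <- lift_annotations(exons_a, wga$filtered, direction = "a_to_b")
  match <- exon_overlap_matching(lift, exons_b)
  cds_b <- extract_cds(study$gene_gff_b, study$contigs_b)
  orf <- bind_rows(lapply(seq_len(nrow(cds_b)), function(i) {
    cbind(tibble(gene = cds_b$gene[i]), orf_validity(cds_b$cds[i]))
  }))
  lg_of_a_gene <- anchor$placements |>
    select("contig", "linkage_group") |>
    inner_join(exons_a |> distinct(.data$gene, .data$contig), by = "contig")
  chrom_of_b_gene <- setNames(study$truth$genes_b$chrom,
                              study$truth$genes_b$gene)
  corr <- chromosome_correspondence(
    rbh$pairs,
    setNames(lg_of_a_gene$linkage_group, lg_of_a_gene$gene),
    chrom_of_b_gene)

  result <- structure(list(
    anchor = anchor, scaffolds = scaffolds, wga = wga,
    assembly_stats = bind_rows(mutate(stats_a, assembly = "A"),
                               mutate(stats_b, assembly = "B")),
    enrichment = list(A = enrich_a, B = enrich_b),
    long_tracts = bind_rows(mutate(long_a, assembly = "A"),
                            mutate(long_b, assembly = "B")),
    repeat_summary = list(A = summary_a, B = summary_b),
    arrays = list(A = arrays_a, B = arrays_b),
    presence = presence, rbh = rbh, lift = lift, match = match, orf = orf,
    correspondence = corr, study = study), class = "pipeline_result")
  result$scorecard <- evaluate_against_truth(study, result)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$anchor)
  print(x$wga)
  cat("scorecard:\n")
  print(x$scorecard, n = 30)
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  tidyr::pivot_wider(x$scorecard, names_from = "metric",
                     values_from = "value")
}

#' Score pipeline outputs against the simulation truth
#'
#' Computes the structural-recovery scorecard: linkage-group assignment
#' accuracy, per-linkage-group Kendall tau between recovered and true
#' contig order (over linkage-evidenced placements), orientation accuracy
#' of linkage-oriented contigs, inversion precision and recall (matched at
#' 50% overlap on the target assembly), satellite rotation-class and
#' consensus recovery, the satellite expansion ratio between the species,
#' reciprocal-best-hit precision/recall against the true ortholog pairs,
#' and the count of B-specific array copies left without reciprocal
#' partners.
#'
#' @param study A [simulate_study()] result.
#' @param result A [run_pipeline()] result (or a compatible list).
#' @return A tibble `metric`, `value`.
#' @export
evaluate_against_truth <- function(study, result) {
  cfg <- study$config
  truth <- study$truth
  lg_of_chrom <- setNames(paste0("LG", seq_len(cfg$n_chromosomes)),
                          paste0("chr", seq_len(cfg$n_chromosomes)))
  pl <- result$anchor$placements |>
    inner_join(study$contig_truth_a, by = "contig",
               suffix = c("", ".truth"))
  linkage_pl <- pl |> filter(.data$evidence != "reference_guided")
  assignment_acc <- mean(linkage_pl$linkage_group ==
                           unname(lg_of_chrom[linkage_pl$chrom]))
  taus <- linkage_pl |>
    filter(.data$linkage_group == unname(lg_of_chrom[.data$chrom])) |>
    group_by(.data$linkage_group) |>
    summarise(tau = if (n() >= 2) {
      cor(.data$rank, .data$rank.truth, method = "kendall")
    } else 1, .groups = "drop")
  oriented <- pl |> filter(.data$orientation_evidence == "linkage_map")
  orient_acc <- if (nrow(oriented) > 0) {
    mean(oriented$orientation == oriented$orientation.truth)
  } else NA_real_

  # inversions: truth intervals on the A-contig axis
  inv_truth <- if (nrow(truth$inversions) > 0) {
    purrr::pmap_dfr(truth$inversions, function(chrom, start, end) {
      chrom_interval_to_contigs(chrom, start, end, study$contig_truth_a)
    })
  } else tibble(contig = character(), start = integer(), end = integer())
  calls <- result$wga$inversions
  matched_truth <- vapply(seq_len(nrow(inv_truth)), function(i) {
    tr <- inv_truth[i, ]
    any(calls$tname == tr$contig &
          pmin(calls$tend, tr$end) - pmax(calls$tstart, tr$start) >=
            0.5 * (tr$end - tr$start))
  }, logical(1))
  matched_call <- vapply(seq_len(nrow(calls)), function(i) {
    cl <- calls[i, ]
    any(inv_truth$contig == cl$tname &
          pmin(inv_truth$end, cl$tend) - pmax(inv_truth$start, cl$tstart) >=
            0.5 * (inv_truth$end - inv_truth$start))
  }, logical(1))
  inv_recall <- if (nrow(inv_truth) > 0) mean(matched_truth) else NA_real_
  inv_precision <- if (nrow(calls) > 0) mean(matched_call) else
    if (nrow(inv_truth) == 0) NA_real_ else 1

  # satellite recovery
  true_class <- canonical_rotation(cfg$satellite_motif)
  arrays_b <- result$arrays$B
  class_match <- as.numeric(nrow(arrays_b) > 0 &&
                              arrays_b$class[1] == true_class)
  sat_bp <- function(arr) {
    if (nrow(arr) == 0) return(0)
    hit <- arr |> filter(.data$class == true_class)
    if (nrow(hit) == 0) return(0)
    sum(purrr::map_dbl(hit$arrays, ~ sum(.x$end - .x$start)))
  }
  expansion_ratio <- sat_bp(arrays_b) / max(sat_bp(result$arrays$A), 1)
  # consensus from the largest detected B array
  consensus_match <- 0
  if (nrow(arrays_b) > 0) {
    loc <- arrays_b$arrays[[1]] |> slice_max(.data$copies, n = 1,
                                             with_ties = FALSE)
    s <- study$contigs_b$seq[study$contigs_b$id == loc$contig]
    tr <- find_tandem_repeats(substr(s, loc$start + 1, loc$end),
                              max_period = nchar(cfg$satellite_motif))
    if (nrow(tr) > 0) {
      tr1 <- tr |> slice_max(.data$end - .data$start, n = 1,
                             with_ties = FALSE)
      consensus_match <- as.numeric(
        tr1$period == nchar(cfg$satellite_motif) &&
          canonical_rotation(tr1$consensus) == true_class)
    }
  }

  # gene accounting
  pairs <- result$rbh$pairs
  true_pairs <- truth$ortholog_pairs
  key <- function(a, b) paste(a, b)
  rbh_recall <- mean(key(true_pairs$gene_a, true_pairs$gene_b) %in%
                       key(pairs$gene_a, pairs$gene_b))
  rbh_precision <- if (nrow(pairs) > 0) {
    mean(key(pairs$gene_a, pairs$gene_b) %in%
           key(true_pairs$gene_a, true_pairs$gene_b))
  } else NA_real_
  extra_b <- truth$genes_b |> filter(is.na(.data$ortholog))
  n_extra_unmatched <- sum(extra_b$gene %in% result$rbh$unmatched_b)

  tibble(metric = c("assignment_accuracy", "order_tau_min", "order_tau_mean",
                    "orientation_accuracy", "inversion_recall",
                    "inversion_precision", "satellite_class_match",
                    "satellite_consensus_match", "expansion_ratio",
                    "rbh_recall", "rbh_precision",
                    "n_extra_copies_unmatched", "n_extra_copies_true"),
         value = c(assignment_acc, min(taus$tau), mean(taus$tau),
                   orient_acc, inv_recall, inv_precision, class_match,
                   consensus_match, expansion_ratio, rbh_recall,
                   rbh_precision, n_extra_unmatched, nrow(extra_b)))
}

# write the main result tables of a pipeline run
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  readr::write_tsv(result$anchor$placements, p("placements.tsv"))
  readr::write_tsv(result$anchor$conflicts, p("conflicts.tsv"))
  write_agp(result$scaffolds$agp, p("scaffolds.agp"))
  write_fasta(result$scaffolds$scaffolds, p("scaffolds.fa"))
  readr::write_tsv(result$wga$one_to_one, p("one_to_one.tsv"))
  readr::write_tsv(result$wga$inversions, p("inversions.tsv"))
  readr::write_tsv(result$wga$duplications, p("duplications.tsv"))
  readr::write_tsv(result$wga$nonaligned, p("nonaligned.tsv"))
  readr::write_tsv(result$assembly_stats, p("assembly_stats.tsv"))
  readr::write_tsv(result$long_tracts, p("long_tracts.tsv"))
  readr::write_tsv(result$rbh$pairs, p("rbh_pairs.tsv"))
  readr::write_tsv(result$scorecard, p("scorecard.tsv"))
  jsonlite::write_json(
    list(scorecard = result$scorecard,
         glance_wga = glance(result$wga),
         glance_anchor = glance(result$anchor)),
    p("summary.json"), digits = NA)
  invisible(outdir)
}
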