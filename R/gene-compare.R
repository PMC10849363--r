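#' Reciprocal best hits between two annotation sets
#'
#' The best hit of each query is its maximum-bitscore subject (ties broken
#' by minimum E-value, then lexicographic subject id, for determinism); a
#' pair is kept when the two directions agree. Each gene appears in at most
#' one pair, and the result is symmetric in the two inputs.
#'
#' @param hits_ab Hit tibble, genes of A queried against B.
#' @param hits_ba Hit tibble, genes of B queried against A.
#' @return List with `pairs` (tibble `gene_a`, `gene_b`, `bitscore_ab`,
#'   `bitscore_ba`), `unmatched_a`, `unmatched_b` (character vectors of
#'   queries with hits but no reciprocal partner).
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  best <- function(h) {
    h |>
      group_by(.data$query) |>
      arrange(desc(.data$bitscore), .data$evalue, .data$subject,
              .by_group = TRUE) |>
      slice(1) |>
      ungroup() |>
      select("query", "subject", "bitscore")
  }
  ba <- best(hits_ab)
  bb <- best(hits_ba)
  pairs <- ba |>
    inner_join(bb, by = c("query" = "subject", "subject" = "query"),
               suffix = c("_ab", "_ba")) |>
    select(gene_a = "query", gene_b = "subject",
           bitscore_ab = "bitscore_ab", bitscore_ba = "bitscore_ba") |>
    arrange(.data$gene_a)
  list(pairs = pairs,
       unmatched_a = sort(setdiff(unique(hits_ab$query), pairs$gene_a)),
       unmatched_b = sort(setdiff(unique(hits_ba$query), pairs$gene_b)))
}

#' Annotation edit distance of a gene model against evidence
#'
#' Nucleotide-level concordance: with `TP` the bp shared between the model's
#' exon set and the union of the evidence intervals, sensitivity is
#' `TP / evidence bp`, specificity `TP / model bp`, and
#' `AED = 1 - (SN + SP) / 2`. Zero means the two nucleotide sets are
#' identical; one means they are disjoint.
#'
#' @param model_exons Tibble of model exon intervals (`start`, `end`,
#'   0-based half-open; one contig/strand assumed).
#' @param evidence_exons Tibble of evidence intervals, same convention.
#' @return A one-row tibble `sn`, `sp`, `aed`.
#' @export
compute_aed <- function(model_exons, evidence_exons) {
  mbp <- interval_union_bp(model_exons)
  ebp <- interval_union_bp(evidence_exons)
  if (mbp == 0 || ebp == 0) abort("zero-length model or evidence")
  m <- IRanges::reduce(IRanges::IRanges(model_exons$start + 1L,
                                        model_exons$end))
  e <- IRanges::reduce(IRanges::IRanges(evidence_exons$start + 1L,
                                        evidence_exons$end))
  tp <- sum(IRanges::width(IRanges::intersect(m, e)))
  sn <- tp / ebp
  sp <- tp / mbp
  tibble(sn = sn, sp = sp, aed = 1 - (sn + sp) / 2)
}

interval_union_bp <- function(x) {
  if (nrow(x) == 0) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(x$start + 1L, x$end))))
}

#' Lift gene models through filtered alignment blocks
#'
#' A desk-scale block-transform lift-over: each exon is assigned to the
#' alignment blocks covering it on the source axis; an exon lifts when at
#' least `cov_frac` of its bp lie in blocks of one consistent strand, its
#' endpoints then mapped by block offset (strand-aware, coordinates clipped
#' to block bounds); a gene lifts when at least one exon lifts. Exons split
#' across blocks of conflicting strands are left unmapped.
#'
#' @param genes Feature tibble of exon records with an `ID`-style attribute
#'   column `gene` (see [gene_exon_table()]), on the source assembly.
#' @param paf Filtered single-coverage alignment tibble; the source assembly
#'   must be the *target* axis when `direction = "a_to_b"`, the query axis
#'   when `direction = "b_to_a"`.
#' @param direction `"a_to_b"` (target axis to query axis) or `"b_to_a"`.
#' @param cov_frac Minimum covered fraction of an exon.
#' @return List with `lifted` (tibble `gene`, `exon`, `contig`, `start`,
#'   `end`, `strand`) and `unmapped` (character vector of gene ids with no
#'   liftable exon).
#' @export
lift_annotations <- function(genes, paf, direction = c("a_to_b", "b_to_a"),
                             cov_frac = 0.5) {
  direction <- match.arg(direction)
  blocks <- if (direction == "a_to_b") {
    paf |> select(src = "tname", src_start = "tstart", src_end = "tend",
                  dst = "qname", dst_start = "qstart", dst_end = "qend",
                  "strand")
  } else {
    paf |> select(src = "qname", src_start = "qstart", src_end = "qend",
                  dst = "tname", dst_start = "tstart", dst_end = "tend",
                  "strand")
  }
  lifted <- list()
  unmapped_exons <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    bl <- blocks |>
      filter(.data$src == g$contig, .data$src_start < g$end,
             .data$src_end > g$start)
    if (nrow(bl) == 0) next
    ov_bp <- pmin(bl$src_end, g$end) - pmax(bl$src_start, g$start)
    by_strand <- tapply(ov_bp, bl$strand, sum)
    best_strand <- names(by_strand)[which.max(by_strand)]
    if (by_strand[best_strand] / (g$end - g$start) < cov_frac) {
      unmapped_exons <- unmapped_exons + 1L
      next
    }
    bl <- bl[bl$strand == best_strand, ]
    pieces <- purrr::map_dfr(seq_len(nrow(bl)), function(j) {
      b <- bl[j, ]
      s <- max(g$start, b$src_start)
      e <- min(g$end, b$src_end)
      if (b$strand == "+") {
        tibble(dst = b$dst, start = b$dst_start + (s - b$src_start),
               end = b$dst_start + (e - b$src_start))
      } else {
        tibble(dst = b$dst, start = b$dst_end - (e - b$src_start),
               end = b$dst_end - (s - b$src_start))
      }
    })
    if (n_distinct(pieces$dst) > 1) {
      pieces <- pieces |> filter(.data$dst == pieces$dst[1])
    }
    out_strand <- if (best_strand == "+") g$strand else flip_strand(g$strand)
    lifted[[length(lifted) + 1L]] <- tibble(
      gene = g$gene, exon = g$exon, contig = pieces$dst[1],
      start = min(pieces$start), end = max(pieces$end), strand = out_strand)
  }
  lifted <- bind_rows(lifted)
  if (nrow(lifted) == 0) {
    lifted <- tibble(gene = character(), exon = character(),
                     contig = character(), start = integer(),
                     end = integer(), strand = character())
  }
  list(lifted = lifted,
       unmapped = sort(setdiff(unique(genes$gene), lifted$gene)))
}

flip_strand <- function(s) chartr("+-", "-+", s)

#' Exon table of a gene annotation
#'
#' Flattens a GFF3-style feature tibble to one row per exon with its parent
#' gene id (from the `Parent`/`ID` attribute chain or, failing that, the
#' `gene_id` attribute).
#'
#' @param features Feature tibble from [read_gff3()].
#' @return Tibble `gene`, `exon`, `contig`, `start`, `end`, `strand`.
#' @export
gene_exon_table <- function(features) {
  ex <- features |> filter(.data$ftype == "exon")
  gene <- gff_attr(ex, "gene_id")
  if (all(is.na(gene))) gene <- gff_attr(ex, "Parent")
  id <- gff_attr(ex, "ID")
  id[is.na(id)] <- paste0(gene[is.na(id)], ".e", seq_len(sum(is.na(id))))
  tibble(gene = gene, exon = id, contig = ex$contig, start = ex$start,
         end = ex$end, strand = ex$strand)
}

#' Match lifted genes to the other annotation by exon overlap
#'
#' A lifted gene matches any gene of the other annotation sharing at least
#' 1 bp of same-strand exon overlap; genes overlapping two or more genes are
#' flagged `split` (fragmentation of one model into several). The report
#' includes the percentage of the supplied genes that lifted at all.
#'
#' @param lift Output of [lift_annotations()].
#' @param other_exons Exon table ([gene_exon_table()]) of the other
#'   annotation.
#' @param all_genes Character vector of the gene ids that were lifted
#'   (defaults to those present in `lift`).
#' @return List with `matches` (tibble `gene`, `n_partners`, `partners`,
#'   `split`), `unmatched` (lifted but no exon overlap), `pct_lifted`.
#' @export
exon_overlap_matching <- function(lift, other_exons, all_genes = NULL) {
  lifted <- lift$lifted
  all_genes <- all_genes %||% sort(unique(c(lifted$gene, lift$unmapped)))
  if (nrow(lifted) == 0) {
    return(list(matches = tibble(gene = character(), n_partners = integer(),
                                 partners = list(), split = logical()),
                unmatched = character(), pct_lifted = 0))
  }
  hits <- lifted |>
    inner_join(other_exons, by = "contig", suffix = c("", ".o"),
               relationship = "many-to-many") |>
    filter(.data$strand == .data$strand.o, .data$start < .data$end.o,
           .data$end > .data$start.o) |>
    distinct(.data$gene, partner = .data$gene.o)
  matches <- hits |>
    group_by(.data$gene) |>
    summarise(n_partners = n(), partners = list(sort(.data$partner)),
              .groups = "drop") |>
    mutate(split = .data$n_partners >= 2)
  lifted_genes <- unique(lifted$gene)
  list(matches = matches,
       unmatched = sort(setdiff(lifted_genes, matches$gene)),
       pct_lifted = 100 * length(lifted_genes) / length(all_genes))
}

#' Open-reading-frame validity of a CDS
#'
#' A concatenated CDS (transcript orientation) is valid when it is at least
#' 6 bp, a multiple of 3, starts with `ATG`, ends with a stop codon, and
#' contains no internal stop under the standard code.
#'
#' @param cds Character vector of CDS sequences.
#' @return Tibble `valid` (logical), `reason` (`NA` when valid).
#' @export
orf_validity <- function(cds) {
  purrr::map_dfr(cds, function(s) {
    s <- toupper(s)
    if (grepl("[^ACGT]", s)) {
      return(tibble(valid = FALSE, reason = "ambiguous"))
    }
    n <- nchar(s)
    if (n < 6) return(tibble(valid = FALSE, reason = "too_short"))
    if (n %% 3 != 0) return(tibble(valid = FALSE, reason = "frame"))
    codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
    stops <- c("TAA", "TAG", "TGA")
    if (codons[1] != "ATG") return(tibble(valid = FALSE, reason = "no_start"))
    if (!codons[length(codons)] %in% stops) {
      return(tibble(valid = FALSE, reason = "no_stop"))
    }
    if (any(codons[-length(codons)] %in% stops)) {
      return(tibble(valid = FALSE, reason = "internal_stop"))
    }
    tibble(valid = TRUE, reason = NA_character_)
  })
}

#' Linkage-group to chromosome correspondence from shared orthologs
#'
#' For every linkage group of assembly A, the proportion of its reciprocal
#' best hit pairs whose partner lies on each reference chromosome (gene
#' order is not considered). Each linkage group is assigned its argmax
#' chromosome, and a chromosome is flagged split when two or more linkage
#' groups each hold at least `split_frac` of its pairs.
#'
#' @param pairs RBH pair tibble (`gene_a`, `gene_b`).
#' @param lg_of_a Named vector: linkage group of each A gene.
#' @param chrom_of_b Named vector: chromosome of each B gene.
#' @param split_frac Split-flag threshold.
#' @return An object of class `correspondence_matrix`: list with `matrix`
#'   (tibble `linkage_group`, `chromosome`, `n_pairs`, `proportion`),
#'   `assignment` (per-LG argmax), `split_chromosomes`, `n_dropped`.
#' @export
chromosome_correspondence <- function(pairs, lg_of_a, chrom_of_b,
                                      split_frac = 0.2) {
  lab <- pairs |>
    mutate(linkage_group = unname(lg_of_a[.data$gene_a]),
           chromosome = unname(chrom_of_b[.data$gene_b]))
  dropped <- sum(is.na(lab$linkage_group) | is.na(lab$chromosome))
  if (dropped > 0) {
    inform(paste0(dropped, " pair(s) without labels dropped"))
  }
  lab <- lab |> filter(!is.na(.data$linkage_group), !is.na(.data$chromosome))
  mat <- lab |>
    count(.data$linkage_group, .data$chromosome, name = "n_pairs") |>
    group_by(.data$linkage_group) |>
    mutate(proportion = .data$n_pairs / sum(.data$n_pairs)) |>
    ungroup()
  assignment <- mat |>
    group_by(.data$linkage_group) |>
    slice_max(.data$proportion, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("linkage_group", "chromosome", "proportion")
  split <- lab |>
    count(.data$chromosome, .data$linkage_group, name = "n_pairs") |>
    group_by(.data$chromosome) |>
    mutate(frac = .data$n_pairs / sum(.data$n_pairs)) |>
    summarise(n_major = sum(.data$frac >= split_frac), .groups = "drop") |>
    filter(.data$n_major >= 2) |>
    pull(.data$chromosome)
  structure(list(matrix = mat, assignment = assignment,
                 split_chromosomes = split, n_dropped = dropped),
            class = "correspondence_matrix")
}

#' @export
print.correspondence_matrix <- function(x, ...) {
  cat("<correspondence_matrix>", n_distinct(x$matrix$linkage_group),
      "linkage groups x", n_distinct(x$matrix$chromosome), "chromosomes;",
      length(x$split_chromosomes), "split chromosome(s)\n")
  invisible(x)
}

#' @export
tidy.correspondence_matrix <- function(x, ...) x$matrix

#' @export
glance.correspondence_matrix <- function(x, ...) {
  tibble(n_linkage_groups = n_distinct(x$matrix$linkage_group),
         n_chromosomes = n_distinct(x$matrix$chromosome),
         n_split_chromosomes = length(x$split_chromosomes),
         n_dropped = x$n_dropped)
}

#' @export
autoplot.correspondence_matrix <- function(object, ...) {
  ggplot2::ggplot(object$matrix,
                  ggplot2::aes(x = .data$chromosome, y = .data$linkage_group,
                               fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "reference chromosome", y = "linkage group",
                  fill = "proportion\nof RBH pairs",
                  title = "Linkage group / chromosome correspondence") +
    ggplot2::theme_minimal()
}
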