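#' Fragment simulated chromosomes into contigs
#'
#' Breakpoints are placed inside long (>= 5 kb) repeat tracts with
#' probability `contig_break_policy`, and uniformly otherwise, reproducing
#' the empirical enrichment of repeats at contig termini. Breaks never fall
#' inside the intervals listed in `avoid` (genes, satellite arrays,
#' inversions), so every planted element stays within one contig. Contig
#' ids are assigned in shuffled order and each contig receives a random
#' orientation (chromosomes left unbroken stay `+`), so the true order and
#' orientation are genuinely hidden from downstream stages.
#'
#' Concatenating the contigs in true rank order, reverse-complementing the
#' minus ones, reconstructs each chromosome exactly.
#'
#' @param genome Sequence tibble of chromosomes.
#' @param config A [sim_config()].
#' @param tracts Optional tibble `chrom`, `start`, `end` of repeat tracts
#'   (break targets are those >= 5 kb).
#' @param avoid Optional tibble `chrom`, `start`, `end` of no-break zones.
#' @param prefix Contig id prefix.
#' @return List with `contigs` (sequence tibble), `truth` (tibble `contig`,
#'   `chrom`, `rank`, `orientation`, `c_start`, `c_end`), and `breakpoints`
#'   (tibble `chrom`, `pos`, `in_long_tract`).
#' @export
fragment_into_contigs <- function(genome, config, tracts = NULL,
                                  avoid = NULL, prefix = "ctg") {
  avoid <- avoid %||% tibble(chrom = character(), start = integer(),
                             end = integer())
  long_tracts <- if (is.null(tracts)) {
    tibble(chrom = character(), start = integer(), end = integer())
  } else {
    tracts |> filter(.data$end - .data$start >= 5000)
  }
  truth <- list()
  bps <- list()
  for (i in seq_len(nrow(genome))) {
    ch <- genome$id[i]
    L <- nchar(genome$seq[i])
    n_breaks <- config$breaks_per_chromosome
    breaks <- integer(0)
    in_long <- logical(0)
    if (n_breaks > 0) {
      n_rep <- rbinom(1, n_breaks, config$contig_break_policy)
      lt <- long_tracts |> filter(.data$chrom == ch)
      if (n_rep > nrow(lt)) {
        warn(paste0(ch, ": only ", nrow(lt), " long tract(s) available for ",
                    n_rep, " repeat-targeted break(s); remainder uniform"))
        n_rep <- nrow(lt)
      }
      if (n_rep > 0) {
        pick <- lt[sample.int(nrow(lt), n_rep), ]
        pos <- as.integer(floor(runif(n_rep, pick$start + 200,
                                      pick$end - 200)))
        breaks <- c(breaks, pos)
        in_long <- c(in_long, rep(TRUE, n_rep))
      }
      n_unif <- n_breaks - n_rep
      av <- avoid |> filter(.data$chrom == ch)
      while (n_unif > 0) {
        pos <- as.integer(floor(runif(1, 20000, L - 20000)))
        if (!overlaps_any(pos, pos + 1L, av, margin = 500) &&
            (length(breaks) == 0 || min(abs(breaks - pos)) > 20000)) {
          breaks <- c(breaks, pos)
          in_long <- c(in_long, FALSE)
          n_unif <- n_unif - 1L
        }
      }
    }
    o <- order(breaks)
    breaks <- breaks[o]; in_long <- in_long[o]
    bps[[ch]] <- tibble(chrom = ch, pos = breaks, in_long_tract = in_long)
    bounds <- c(0L, breaks, L)
    k <- length(bounds) - 1L
    truth[[ch]] <- tibble(
      chrom = ch, rank = seq_len(k),
      orientation = if (k == 1) "+" else sample(c("+", "-"), k,
                                                replace = TRUE),
      c_start = bounds[-length(bounds)], c_end = bounds[-1])
  }
  truth <- bind_rows(truth)
  truth$contig <- sprintf("%s%03d", prefix,
                          sample.int(nrow(truth)))[seq_len(nrow(truth))]
  truth <- truth |> select("contig", "chrom", "rank", "orientation",
                           "c_start", "c_end")
  seqs <- purrr::pmap_dfr(truth, function(contig, chrom, rank, orientation,
                                          c_start, c_end) {
    s <- substr(genome$seq[genome$id == chrom], c_start + 1L, c_end)
    tibble(id = contig, seq = if (orientation == "-") revcomp(s) else s)
  }) |> arrange(.data$id)
  list(contigs = seqs, truth = truth, breakpoints = bind_rows(bps))
}

# map a chromosome interval [s, e) into contig coordinates, splitting at
# contig boundaries; `truth` is a fragmentation truth table for one genome
chrom_interval_to_contigs <- function(chrom, s, e, truth) {
  rows <- truth |>
    filter(.data$chrom == !!chrom, .data$c_start < e, .data$c_end > s)
  purrr::pmap_dfr(rows, function(contig, chrom, rank, orientation, c_start,
                                 c_end) {
    ps <- max(s, c_start); pe <- min(e, c_end)
    if (orientation == "+") {
      tibble(contig = contig, start = ps - c_start, end = pe - c_start,
             flipped = FALSE, chrom_start = ps, chrom_end = pe)
    } else {
      tibble(contig = contig, start = c_end - pe, end = c_end - ps,
             flipped = TRUE, chrom_start = ps, chrom_end = pe)
    }
  })
}

# count matching characters between two equal-length strings
string_matches <- function(a, b) {
  sum(charToRaw(a) == charToRaw(b))
}

#' Emit synthetic evidence files from the simulation truth
#'
#' Generates everything the downstream pipeline consumes: marker hits (true
#' placements passing the E-value filter, a configurable false-hit rate,
#' and decoy hits that fail it), a whole-genome PAF of B against A that
#' follows the truth blocks (split at inversions with flipped strand and at
#' contig boundaries, with match counts computed from the actual
#' sequences), repeat GFF3 annotations per species in contig coordinates,
#' gene GFF3 annotations per species, protein hit tables in both
#' directions (orthologs score above paralogs above decoys), and a
#' truth-derived reference-guided order table.
#'
#' @param gp Output of [simulate_genome_pair()].
#' @param frag_a,frag_b Outputs of [fragment_into_contigs()] for the two
#'   genomes.
#' @param markers Marker tibble from [sim_markers()].
#' @param config A [sim_config()].
#' @return List: `marker_hits`, `paf`, `repeat_gff_a`, `repeat_gff_b`,
#'   `gene_gff_a`, `gene_gff_b`, `protein_hits_ab`, `protein_hits_ba`,
#'   `ref_order`.
#' @export
emit_evidence <- function(gp, frag_a, frag_b, markers, config) {
  truth <- gp$truth
  seq_a <- setNames(frag_a$contigs$seq, frag_a$contigs$id)
  seq_b <- setNames(frag_b$contigs$seq, frag_b$contigs$id)

  # --- marker hits ------------------------------------------------------
  all_contigs <- frag_a$truth$contig
  clen_a <- setNames(frag_a$truth$c_end - frag_a$truth$c_start,
                     frag_a$truth$contig)
  marker_hits <- purrr::pmap_dfr(markers, function(marker, chrom, linkage_group,
                                                   bp, cM_true, ...) {
    rows <- list()
    if (runif(1) < config$marker_false_hit_rate) {
      ctg <- sample(all_contigs, 1)
      pos <- sample.int(max(1L, clen_a[ctg] - 90L), 1)
      rows[[1]] <- tibble(query = marker, subject = ctg, sstart = pos,
                          send = pos + 89L, ev = 10^runif(1, -60, -30),
                          bits = 160 + runif(1, 0, 20))
    } else {
      m <- chrom_interval_to_contigs(chrom, max(0L, bp - 45L), bp + 45L,
                                     frag_a$truth)
      m <- m |> slice_max(.data$end - .data$start, n = 1, with_ties = FALSE)
      if (m$flipped) {
        rows[[1]] <- tibble(query = marker, subject = m$contig,
                            sstart = m$end, send = m$start + 1L,
                            ev = 10^runif(1, -60, -30),
                            bits = 160 + runif(1, 0, 20))
      } else {
        rows[[1]] <- tibble(query = marker, subject = m$contig,
                            sstart = m$start + 1L, send = m$end,
                            ev = 10^runif(1, -60, -30),
                            bits = 160 + runif(1, 0, 20))
      }
    }
    if (runif(1) < 0.3) {
      ctg <- sample(all_contigs, 1)
      pos <- sample.int(max(1L, clen_a[ctg] - 90L), 1)
      rows[[2]] <- tibble(query = marker, subject = ctg, sstart = pos,
                          send = pos + 89L, ev = 10^runif(1, -20, 0),
                          bits = 40 + runif(1, 0, 20))
    }
    bind_rows(rows)
  })
  marker_hits <- marker_hits |>
    mutate(pct_identity = round(runif(n(), 97, 100), 2),
           aln_len = abs(.data$send - .data$sstart) + 1L,
           mismatches = 0L, gaps = 0L, qstart = 1L, qend = .data$aln_len) |>
    select("query", subject = "subject", "pct_identity", "aln_len",
           "mismatches", "gaps", "qstart", "qend", "sstart", "send",
           evalue = "ev", bitscore = "bits")

  # --- PAF of B (query) against A (target) ------------------------------
  paf_rows <- list()
  for (bi in seq_len(nrow(truth$blocks))) {
    blk <- truth$blocks[bi, ]
    pieces_a <- chrom_interval_to_contigs(blk$chrom, blk$a_start, blk$a_end,
                                          frag_a$truth)
    for (pi in seq_len(nrow(pieces_a))) {
      pa <- pieces_a[pi, ]
      # b interval of this a-piece under the block transform
      if (blk$strand == "+") {
        bs <- blk$b_start + (pa$chrom_start - blk$a_start)
        be <- blk$b_start + (pa$chrom_end - blk$a_start)
      } else {
        bs <- blk$b_start + (blk$a_end - pa$chrom_end)
        be <- blk$b_start + (blk$a_end - pa$chrom_start)
      }
      pieces_b <- chrom_interval_to_contigs(blk$chrom, bs, be, frag_b$truth)
      for (qi in seq_len(nrow(pieces_b))) {
        pb <- pieces_b[qi, ]
        # back-map the b-subinterval to the a axis
        if (blk$strand == "+") {
          as2 <- pa$chrom_start + (pb$chrom_start - bs)
          ae2 <- pa$chrom_start + (pb$chrom_end - bs)
        } else {
          as2 <- pa$chrom_start + (be - pb$chrom_end)
          ae2 <- pa$chrom_start + (be - pb$chrom_start)
        }
        len <- ae2 - as2
        if (len < 30) next
        # a-subinterval in A-contig coordinates
        ca <- frag_a$truth[frag_a$truth$contig == pa$contig, ]
        if (!pa$flipped) {
          ts <- as2 - ca$c_start; te <- ae2 - ca$c_start
        } else {
          ts <- ca$c_end - ae2; te <- ca$c_end - as2
        }
        fs <- xor(blk$strand == "-", xor(pa$flipped, pb$flipped))
        qsub <- substr(seq_b[[pb$contig]], pb$start + 1L, pb$end)
        tsub <- substr(seq_a[[pa$contig]], ts + 1L, te)
        mm <- string_matches(if (fs) revcomp(qsub) else qsub, tsub)
        paf_rows[[length(paf_rows) + 1L]] <- tibble(
          qname = pb$contig, qlen = nchar(seq_b[[pb$contig]]),
          qstart = pb$start, qend = pb$end,
          strand = if (fs) "-" else "+",
          tname = pa$contig, tlen = nchar(seq_a[[pa$contig]]),
          tstart = ts, tend = te, matches = mm, alnlen = len)
      }
    }
  }
  paf <- bind_rows(paf_rows) |> arrange(.data$tname, .data$tstart)

  # --- repeat annotations (contig coordinates, GFF3 tibbles) ------------
  make_repeat_gff <- function(rep_truth, sat_truth, frag) {
    reps <- bind_rows(
      rep_truth |> select("chrom", "start", "end", "class"),
      sat_truth |> mutate(class = "DNA/MuDR2-TC") |>
        select("chrom", "start", "end", "class"))
    purrr::pmap_dfr(reps, function(chrom, start, end, class) {
      chrom_interval_to_contigs(chrom, start, end, frag$truth) |>
        mutate(ftype = class)
    }) |>
      (\(d) tibble(contig = d$contig, source = "simrep", ftype = d$ftype,
                   start = as.integer(d$start), end = as.integer(d$end),
                   score = NA_real_,
                   strand = if_else(d$flipped, "-", "+"), frame = ".",
                   attributes = lapply(seq_len(nrow(d)),
                                       function(i) c(class = d$ftype[i]))))() |>
      arrange(.data$contig, .data$start)
  }
  repeat_gff_a <- make_repeat_gff(truth$repeats_a, truth$satellites_a, frag_a)
  repeat_gff_b <- make_repeat_gff(truth$repeats_b, truth$satellites_b, frag_b)

  # --- gene annotations --------------------------------------------------
  make_gene_gff <- function(genes, frag) {
    rows <- list()
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      ex <- g$exons[[1]]
      m <- chrom_interval_to_contigs(g$chrom, g$gstart, g$gend, frag$truth)
      if (nrow(m) != 1) next   # genes are never split by construction
      strand <- if (m$flipped) "-" else "+"
      exm <- purrr::map2_dfr(ex$start, ex$end, function(s, e) {
        chrom_interval_to_contigs(g$chrom, s, e, frag$truth)
      }) |> arrange(.data$start)
      gid <- g$gene
      rows[[length(rows) + 1L]] <- bind_rows(
        tibble(contig = m$contig, ftype = "gene", start = m$start,
               end = m$end, strand = strand,
               attributes = list(c(ID = gid))),
        tibble(contig = m$contig, ftype = "mRNA", start = m$start,
               end = m$end, strand = strand,
               attributes = list(c(ID = paste0(gid, ".t1"), Parent = gid))),
        purrr::map_dfr(seq_len(nrow(exm)), function(k) {
          bind_rows(
            tibble(contig = exm$contig[k], ftype = "exon",
                   start = exm$start[k], end = exm$end[k], strand = strand,
                   attributes = list(c(ID = paste0(gid, ".e", k),
                                       Parent = paste0(gid, ".t1"),
                                       gene_id = gid))),
            tibble(contig = exm$contig[k], ftype = "CDS",
                   start = exm$start[k], end = exm$end[k], strand = strand,
                   attributes = list(c(ID = paste0(gid, ".c", k),
                                       Parent = paste0(gid, ".t1"),
                                       gene_id = gid))))
        }))
    }
    bind_rows(rows) |>
      mutate(source = "simgene", score = NA_real_, frame = ".",
             start = as.integer(.data$start), end = as.integer(.data$end)) |>
      select("contig", "source", "ftype", "start", "end", "score", "strand",
             "frame", "attributes")
  }
  gene_gff_a <- make_gene_gff(truth$genes_a, frag_a)
  gene_gff_b <- make_gene_gff(truth$genes_b, frag_b)

  # --- protein hits (both directions) -----------------------------------
  ga <- truth$genes_a
  gb <- truth$genes_b
  fam_a <- setNames(ga$array, ga$gene)
  fam_b <- setNames(gb$array, gb$gene)
  mk_hit <- function(q, s, lo, hi) {
    tibble(query = q, subject = s, pct_identity = round(runif(1, 85, 100), 2),
           aln_len = 200L, mismatches = 5L, gaps = 0L, qstart = 1L,
           qend = 200L, sstart = 1L, send = 200L,
           evalue = 10^runif(1, -120, -80), bitscore = runif(1, lo, hi))
  }
  hits_ab <- list(); hits_ba <- list()
  for (i in seq_len(nrow(truth$ortholog_pairs))) {
    a <- truth$ortholog_pairs$gene_a[i]; b <- truth$ortholog_pairs$gene_b[i]
    hits_ab[[length(hits_ab) + 1L]] <- mk_hit(a, b, 500, 550)
    hits_ba[[length(hits_ba) + 1L]] <- mk_hit(b, a, 500, 550)
  }
  for (aid in unique(stats::na.omit(ga$array))) {
    mem_a <- ga$gene[!is.na(ga$array) & ga$array == aid]
    mem_b <- gb$gene[!is.na(gb$array) & gb$array == aid]
    orth_b <- setNames(truth$ortholog_pairs$gene_b,
                       truth$ortholog_pairs$gene_a)
    for (a in mem_a) for (b in mem_b) {
      if (!is.na(orth_b[a]) && orth_b[a] == b) next
      hits_ab[[length(hits_ab) + 1L]] <- mk_hit(a, b, 380, 420)
      hits_ba[[length(hits_ba) + 1L]] <- mk_hit(b, a, 380, 420)
    }
  }
  for (a in sample(ga$gene, min(20, nrow(ga)))) {
    hits_ab[[length(hits_ab) + 1L]] <- mk_hit(a, sample(gb$gene, 1), 60, 90)
  }
  protein_hits_ab <- bind_rows(hits_ab)
  protein_hits_ba <- bind_rows(hits_ba)

  # --- reference-guided order (truth-derived) ---------------------------
  lg_of_chrom <- setNames(paste0("LG", seq_len(config$n_chromosomes)),
                          paste0("chr", seq_len(config$n_chromosomes)))
  ref_order <- frag_a$truth |>
    mutate(scaffold = unname(lg_of_chrom[.data$chrom])) |>
    select("scaffold", "rank", "contig", "orientation") |>
    arrange(.data$scaffold, .data$rank)

  list(marker_hits = marker_hits, paf = paf,
       repeat_gff_a = repeat_gff_a, repeat_gff_b = repeat_gff_b,
       gene_gff_a = gene_gff_a, gene_gff_b = gene_gff_b,
       protein_hits_ab = protein_hits_ab, protein_hits_ba = protein_hits_ba,
       ref_order = ref_order)
}

#' Simulate a complete synthetic study
#'
#' Runs the whole generator: genome pair, fragmentation of both genomes
#' (with avoid zones so genes, satellite arrays and inversions stay within
#' single contigs), markers, F2 crosses (the primary cross omits the
#' markers of one mid-chromosome contig per chromosome, so secondary-map
#' insertion is exercised; the second cross carries every marker), and all
#' evidence files.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_study`: the configuration, genomes,
#'   contig sets, truth tables, maps, crosses, and evidence tibbles.
#' @export
simulate_study <- function(config = sim_config()) {
  gp <- simulate_genome_pair(config)
  truth <- gp$truth

  gene_iv_a <- truth$genes_a |> select(chrom = "chrom", start = "gstart",
                                       end = "gend")
  avoid_a <- bind_rows(
    gene_iv_a,
    truth$satellites_a |> select("chrom", "start", "end"),
    if (nrow(truth$inversions) > 0) {
      truth$inversions |> select("chrom", "start", "end")
    },
    if (nrow(truth$duplications) > 0) {
      truth$duplications |> select("chrom", "start", "end")
    })
  frag_a <- fragment_into_contigs(gp$genome_a, config,
                                  tracts = truth$repeats_a,
                                  avoid = avoid_a, prefix = "A_ctg")
  inv_b <- if (nrow(truth$inversions) > 0) {
    purrr::pmap_dfr(truth$inversions, function(chrom, start, end) {
      bl <- truth$blocks |> filter(.data$chrom == !!chrom)
      hit <- bl |> filter(.data$a_start == start, .data$a_end == end)
      tibble(chrom = chrom, start = hit$b_start[1], end = hit$b_end[1])
    })
  }
  avoid_b <- bind_rows(
    truth$genes_b |> select(chrom = "chrom", start = "gstart", end = "gend"),
    truth$satellites_b |> select("chrom", "start", "end"),
    inv_b)
  frag_b <- fragment_into_contigs(gp$genome_b, config,
                                  tracts = truth$repeats_b,
                                  avoid = avoid_b, prefix = "B_ctg")

  markers <- sim_markers(config)
  # hide one middle contig per chromosome from the primary cross
  hidden <- frag_a$truth |>
    group_by(.data$chrom) |>
    filter(n() >= 3, .data$rank > 1, .data$rank < max(.data$rank)) |>
    slice_max(.data$c_end - .data$c_start, n = 1, with_ties = FALSE) |>
    ungroup() |>
    pull(.data$contig)
  marker_contig <- purrr::pmap_chr(markers, function(marker, chrom,
                                                     linkage_group, bp, ...) {
    hit <- frag_a$truth |>
      filter(.data$chrom == !!chrom, .data$c_start <= bp, .data$c_end > bp)
    hit$contig[1]
  })
  markers$contig_a <- marker_contig

  crosses <- list()
  maps <- list()
  for (i in seq_len(config$n_crosses)) {
    cross_id <- paste0("cross", i)
    mk <- if (i == 1) {
      markers |> filter(!.data$contig_a %in% hidden)
    } else if (i == 2) {
      markers
    } else {
      markers |> filter(runif(n()) < config$marker_retention)
    }
    cr <- simulate_f2_cross(mk, config, cross = cross_id)
    crosses[[cross_id]] <- cr
    maps[[cross_id]] <- cr$map
  }
  maps <- bind_rows(maps)

  ev <- emit_evidence(gp, frag_a, frag_b, markers, config)
  structure(c(list(config = config,
                   genome_a = gp$genome_a, genome_b = gp$genome_b,
                   contigs_a = frag_a$contigs, contigs_b = frag_b$contigs,
                   contig_truth_a = frag_a$truth,
                   contig_truth_b = frag_b$truth,
                   breakpoints_a = frag_a$breakpoints,
                   breakpoints_b = frag_b$breakpoints,
                   truth = truth, markers = markers, hidden_contigs = hidden,
                   maps = maps, crosses = crosses),
              ev),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study>", nrow(x$genome_a), "chromosomes;",
      nrow(x$contigs_a), "A contigs /", nrow(x$contigs_b), "B contigs;",
      nrow(x$markers), "markers in", length(x$crosses), "crosses; seed",
      x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Serialises every evidence file in its standard format (FASTA, GFF3, PAF,
#' 12-column hits, map/order TSVs) plus the ground truth as JSON, so the
#' full pipeline can be exercised from files alone.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_fasta(study$contigs_a, p("contigs_A.fa"))
  write_fasta(study$contigs_b, p("contigs_B.fa"))
  write_gff3(study$repeat_gff_a, p("repeats_A.gff3"))
  write_gff3(study$repeat_gff_b, p("repeats_B.gff3"))
  write_gff3(study$gene_gff_a, p("genes_A.gff3"))
  write_gff3(study$gene_gff_b, p("genes_B.gff3"))
  write_paf(study$paf, p("B_vs_A.paf"))
  write_hits(study$marker_hits, p("marker_hits.tsv"))
  write_hits(study$protein_hits_ab, p("protein_A_vs_B.tsv"))
  write_hits(study$protein_hits_ba, p("protein_B_vs_A.tsv"))
  write_map(study$maps, p("genetic_map.tsv"))
  write_order(study$ref_order, p("ref_order.tsv"))
  truth <- study$truth
  truth$genes_a$exons <- lapply(truth$genes_a$exons, as.data.frame)
  truth$genes_b$exons <- lapply(truth$genes_b$exons, as.data.frame)
  jsonlite::write_json(
    c(truth, list(contig_truth_a = study$contig_truth_a,
                  contig_truth_b = study$contig_truth_b,
                  markers = study$markers)),
    p("truth.json"), digits = NA)
  invisible(dir)
}

#' Extract the CDS of annotated genes from contig sequences
#'
#' Concatenates CDS features per gene in transcript orientation
#' (reverse-complementing minus-strand genes), for open-reading-frame
#' checks.
#'
#' @param features Gene feature tibble (with `CDS` rows carrying a
#'   `gene_id` attribute).
#' @param seqs Sequence tibble of the contigs.
#' @return A tibble `gene`, `cds`.
#' @export
extract_cds <- function(features, seqs) {
  cds <- features |> filter(.data$ftype == "CDS")
  cds$gene <- gff_attr(cds, "gene_id")
  seq_of <- setNames(seqs$seq, seqs$id)
  cds |>
    group_by(.data$gene) |>
    group_split() |>
    purrr::map_dfr(function(g) {
      g <- g |> arrange(.data$start)
      pieces <- substring(seq_of[g$contig], g$start + 1L, g$end)
      s <- paste(pieces, collapse = "")
      if (g$strand[1] == "-") s <- revcomp(s)
      tibble(gene = g$gene[1], cds = s)
    })
}
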