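#' Simulation configuration
#'
#' Parameters of the synthetic study: a pair of genomes diverged from a
#' common ancestor, fragmented into contigs, genotyped in F2 intercrosses,
#' and compared through every downstream stage. The defaults define the
#' standard study conditions used by the package's own validation: five F2
#' crosses, divergence at the sub-percent level expected between congeneric
#' species, a 28-bp satellite expanded two-fold in species B, tandem gene
#' arrays with copy-number gain in B, and contig breaks placed
#' preferentially inside long repeat tracts.
#'
#' @param seed Integer seed; fully determines every output.
#' @param chromosome_lengths Chromosome lengths in bp (>= 10 kb each).
#' @param snp_rate,indel_rate Per-bp substitution / small-indel rates
#'   between the species.
#' @param n_inversions Number of planted inversions (species B).
#' @param inversion_length Length range (bp) of planted inversions.
#' @param repeat_library Tibble `motif`, `class` of interspersed/simple
#'   repeat units used for planted tracts.
#' @param satellite_motif Satellite unit sequence (one tandem array per
#'   chromosome).
#' @param satellite_copies Tandem copies per array in species A.
#' @param repeat_expansion_bias Species-B satellite copy multiplier.
#' @param n_gene_arrays Number of tandem gene arrays (at most one per
#'   chromosome).
#' @param array_copies Gene copies per array in species A.
#' @param array_copy_delta Extra copies gained by species B per array.
#' @param broken_orf_frac Fraction of B-specific gene copies planted with a
#'   premature stop codon.
#' @param genes_per_chromosome Singleton genes per chromosome.
#' @param long_tracts_per_chromosome,long_tract_length Long repeat tracts
#'   (break targets), count and bp range.
#' @param short_tracts_per_chromosome,short_tract_length Background repeat
#'   tracts, count and bp range.
#' @param duplication_length If positive, plant one tandem duplication of
#'   this many bp in species B.
#' @param unique_insertion_length If positive, plant one unique (novel
#'   sequence) insertion of this many bp in species B.
#' @param contig_break_policy Fraction of contig breaks placed inside long
#'   (>= 5 kb) repeat tracts.
#' @param breaks_per_chromosome Contig breaks per chromosome.
#' @param markers_per_chromosome GBS-style markers per chromosome.
#' @param n_crosses Number of F2 intercrosses (first cross is primary).
#' @param n_f2_per_cross F2 individuals per cross.
#' @param marker_retention Probability a marker is informative in a given
#'   cross.
#' @param marker_false_hit_rate Probability a marker's passing hit lands on
#'   the wrong contig.
#' @param map_noise_sd Gaussian noise (cM) on emitted map positions.
#' @param bp_per_cM Physical-to-genetic scale.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1,
                       chromosome_lengths = c(2e6, 1.5e6, 1.2e6),
                       snp_rate = 0.005,
                       indel_rate = 1e-5,
                       n_inversions = 3,
                       inversion_length = c(120000, 200000),
                       repeat_library = default_repeat_library(),
                       satellite_motif = "TGTCACAAACCCCATTGGACAGCGTGTG",
                       satellite_copies = 250,
                       repeat_expansion_bias = 2,
                       n_gene_arrays = 3,
                       array_copies = 4,
                       array_copy_delta = 2,
                       broken_orf_frac = 0.4,
                       genes_per_chromosome = 25,
                       long_tracts_per_chromosome = 4,
                       long_tract_length = c(6000, 12000),
                       short_tracts_per_chromosome = 30,
                       short_tract_length = c(200, 2000),
                       duplication_length = 0,
                       unique_insertion_length = 0,
                       contig_break_policy = 0.8,
                       breaks_per_chromosome = 3,
                       markers_per_chromosome = 30,
                       n_crosses = 5,
                       n_f2_per_cross = 100,
                       marker_retention = 0.85,
                       marker_false_hit_rate = 0.02,
                       map_noise_sd = 0.5,
                       bp_per_cM = 30000) {
  cfg <- as.list(environment())
  cfg$n_chromosomes <- length(chromosome_lengths)
  rates <- c(snp_rate, indel_rate, contig_break_policy, marker_retention,
             marker_false_hit_rate, broken_orf_frac)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (any(chromosome_lengths < 1e4)) {
    abort("chromosome lengths must be >= 10 kb")
  }
  if (n_inversions > 0 && max(inversion_length) >= min(chromosome_lengths)) {
    abort("requested inversion longer than the shortest chromosome")
  }
  if (repeat_expansion_bias < 0) abort("repeat_expansion_bias must be >= 0")
  stopifnot(bp_per_cM > 0, n_crosses >= 1, n_f2_per_cross >= 1)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_chromosomes, "chromosomes (",
      format(sum(x$chromosome_lengths), big.mark = ","), "bp ), snp rate",
      x$snp_rate, ", ", x$n_inversions, "inversions,", x$n_crosses,
      "crosses, seed", x$seed, "\n")
  invisible(x)
}

#' @rdname sim_config
#' @export
default_repeat_library <- function() {
  tibble(
    motif = c(
      "TTCAGGTCCTAACGGTTCAAGCGATTCTCCTGCCTCAGCCTCCCGAGTAGCTGGGATTAC",
      "GGCCGGGCGCGGTGGCTCACGCCTGTAATCCCAGCACTTTGGGAGGC",
      "CATTCATTCATTCATTGATTCATT",
      "TAGAGATGGAGTCTCGCTCTGTCGCCC",
      "TATATT"),
    class = c("LINE/CR1", "LTR/ERVL", "Satellite/simple", "DNA/hAT",
              "Simple_repeat"))
}

# ---------------------------------------------------------------------------
# interval placement helpers (all 0-based half-open, chromosome coordinates)

overlaps_any <- function(s, e, iv, margin = 0) {
  if (nrow(iv) == 0) return(FALSE)
  any(iv$start - margin < e & iv$end + margin > s)
}

place_intervals <- function(n, len_lo, len_hi, L, occupied, margin = 500,
                            edge = 2000, max_tries = 2000) {
  out <- occupied
  placed <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      len <- as.integer(round(runif(1, len_lo, len_hi)))
      if (len + 2 * edge >= L) {
        abort("interval too long for chromosome given edge margins")
      }
      s <- as.integer(floor(runif(1, edge, L - edge - len)))
      if (!overlaps_any(s, s + len, out, margin)) {
        row <- tibble(start = s, end = s + len)
        placed[[i]] <- row
        out <- bind_rows(out, row)
        break
      }
    }
    if (is.null(placed[[i]])) {
      abort("could not place interval; genome too full")
    }
  }
  bind_rows(placed)
}

# tandem-repeat filler: motif repeated to len bp with per-base mutations
tandem_fill <- function(motif, len, mut = 0.02) {
  reps <- ceiling(len / nchar(motif))
  s <- substr(strrep(motif, reps), 1, len)
  mutate_bases(s, mut)
}

mutate_bases <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  idx <- which(runif(n) < rate)
  if (length(idx) == 0) return(s)
  chars <- strsplit(s, "")[[1]]
  bases <- c("A", "C", "G", "T")
  cur <- match(chars[idx], bases)
  chars[idx] <- bases[((cur - 1L + sample.int(3, length(idx),
                                              replace = TRUE)) %% 4L) + 1L]
  paste(chars, collapse = "")
}

# ORF of len codons (including start and stop), standard code, no internal
# stop
make_orf <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(all_codons, stops)
  paste0("ATG",
         paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(stops, 1))
}

# plant `content` into a char vector at 0-based half-open [s, s+len)
plant <- function(chars, s, content) {
  cc <- strsplit(content, "")[[1]]
  chars[(s + 1L):(s + length(cc))] <- cc
  chars
}

#' Simulate a diverged genome pair with full ground truth
#'
#' Builds one ancestral genome per the configuration, plants repeat tracts,
#' one satellite array per chromosome, tandem gene arrays and singleton
#' genes, then derives species A (substitutions only; the ancestor is A's
#' coordinate backbone) and species B (satellite expansion, gene-array copy
#' gain, optional duplication/unique insertion, small indels, inversions,
#' then substitutions). Every planted element is recorded with exact
#' coordinates in both species' frames, together with the collinear
#' alignment blocks relating the two genomes.
#'
#' @param config A [sim_config()].
#' @return A list with `genome_a`, `genome_b` (sequence tibbles, one row per
#'   chromosome) and `truth` (list of tibbles: `inversions`, `repeats_a`,
#'   `repeats_b`, `satellites_a`, `satellites_b`, `genes_a`, `genes_b`,
#'   `ortholog_pairs`, `duplications`, `unique_insertions`, `blocks`).
#' @export
simulate_genome_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))

  truth <- list(inversions = list(), repeats = list(), satellites = list(),
                genes = list(), blocks = list(), dups = list(), uniq = list())
  genome_a <- list()
  genome_b <- list()
  genes_b_extra <- list()
  sat_b <- list()
  gene_counter <- 0L

  # distribute inversions, arrays, structural extras across chromosomes
  inv_chrom <- if (config$n_inversions > 0) {
    sort(sample(seq_len(config$n_chromosomes), config$n_inversions,
                replace = TRUE, prob = config$chromosome_lengths))
  } else integer(0)
  array_chrom <- if (config$n_gene_arrays > 0) {
    rep_len(seq_len(config$n_chromosomes), config$n_gene_arrays)
  } else integer(0)

  for (ci in seq_len(config$n_chromosomes)) {
    L <- as.integer(config$chromosome_lengths[ci])
    cname <- chrom_names[ci]
    chars <- strsplit(random_dna(L), "")[[1]]
    occupied <- tibble(start = integer(), end = integer())

    # --- inversions placed first (they are large); every other planted
    # element is kept outside them so truth coordinates stay one-block ----
    n_inv_here <- sum(inv_chrom == ci)
    inv_iv <- place_intervals(n_inv_here, config$inversion_length[1],
                              config$inversion_length[2], L, occupied,
                              margin = 2000)
    occupied <- bind_rows(occupied, inv_iv)
    if (nrow(inv_iv) > 0) {
      truth$inversions[[ci]] <- mutate(inv_iv, chrom = cname)
    }

    # --- long and short repeat tracts -----------------------------------
    lib <- config$repeat_library
    long_iv <- place_intervals(config$long_tracts_per_chromosome,
                               config$long_tract_length[1],
                               config$long_tract_length[2], L, occupied)
    occupied <- bind_rows(occupied, long_iv)
    short_iv <- place_intervals(config$short_tracts_per_chromosome,
                                config$short_tract_length[1],
                                config$short_tract_length[2], L, occupied)
    occupied <- bind_rows(occupied, short_iv)
    rep_iv <- bind_rows(mutate(long_iv, kind = "long"),
                        mutate(short_iv, kind = "short"))
    if (nrow(rep_iv) > 0) {
      rep_iv$class <- lib$class[sample.int(nrow(lib), nrow(rep_iv),
                                           replace = TRUE)]
      for (i in seq_len(nrow(rep_iv))) {
        motif <- lib$motif[lib$class == rep_iv$class[i]][1]
        chars <- plant(chars, rep_iv$start[i],
                       tandem_fill(motif, rep_iv$end[i] - rep_iv$start[i]))
      }
      truth$repeats[[ci]] <- mutate(rep_iv, chrom = cname)
    }

    # --- satellite array (one per chromosome) ---------------------------
    sat_len <- config$satellite_copies * nchar(config$satellite_motif)
    sat_iv <- place_intervals(1, sat_len, sat_len, L, occupied)
    occupied <- bind_rows(occupied, sat_iv)
    chars <- plant(chars, sat_iv$start,
                   substr(strrep(config$satellite_motif,
                                 config$satellite_copies + 1),
                          1, sat_len))
    truth$satellites[[ci]] <- tibble(
      chrom = cname, start = sat_iv$start, end = sat_iv$end,
      motif = config$satellite_motif, copies = config$satellite_copies)

    # --- genes: one tandem array (if assigned) + singletons -------------
    chrom_genes <- list()
    array_here <- which(array_chrom == ci)
    for (ai in array_here) {
      orf <- make_orf(sample(100:200, 1))
      unit <- paste0(orf, random_dna(200))
      arr_len <- nchar(unit) * config$array_copies
      iv <- place_intervals(1, arr_len, arr_len, L, occupied)
      occupied <- bind_rows(occupied, iv)
      chars <- plant(chars, iv$start, strrep(unit, config$array_copies))
      for (k in seq_len(config$array_copies)) {
        gene_counter <- gene_counter + 1L
        gs <- iv$start + (k - 1L) * nchar(unit)
        chrom_genes[[length(chrom_genes) + 1L]] <- tibble(
          idx = gene_counter, chrom = cname, gstart = gs,
          gend = gs + nchar(orf), strand = "+",
          exons = list(tibble(start = gs, end = gs + nchar(orf))),
          cds = orf, array = paste0("arr", ai))
      }
    }
    n_single <- config$genes_per_chromosome
    for (k in seq_len(n_single)) {
      orf <- make_orf(sample(100:300, 1))
      two_exon <- runif(1) < 0.2
      if (two_exon) {
        e1 <- 3L * sample(30:60, 1)
        intron <- random_dna(120)
        gene_seq <- paste0(substr(orf, 1, e1), intron,
                           substr(orf, e1 + 1, nchar(orf)))
      } else {
        gene_seq <- orf
      }
      iv <- place_intervals(1, nchar(gene_seq), nchar(gene_seq), L, occupied)
      occupied <- bind_rows(occupied, iv)
      chars <- plant(chars, iv$start, gene_seq)
      gene_counter <- gene_counter + 1L
      exons <- if (two_exon) {
        tibble(start = c(iv$start, iv$start + e1 + 120L),
               end = c(iv$start + e1, iv$start + nchar(gene_seq)))
      } else {
        tibble(start = iv$start, end = iv$end)
      }
      chrom_genes[[length(chrom_genes) + 1L]] <- tibble(
        idx = gene_counter, chrom = cname, gstart = iv$start, gend = iv$end,
        strand = "+", exons = list(exons), cds = orf, array = NA_character_)
    }
    genes_df <- bind_rows(chrom_genes)
    truth$genes[[ci]] <- genes_df

    # --- species-B edit events ------------------------------------------
    # insertions: satellite expansion, gene-array copy gain, optional
    # duplication / unique insertion; point events in free sequence
    edits <- tibble(pos = integer(), kind = character(), ins = character(),
                    del_len = integer(), dup_src_start = integer(),
                    dup_src_end = integer())
    extra_copies <- round(config$repeat_expansion_bias *
                            config$satellite_copies) - config$satellite_copies
    if (extra_copies > 0) {
      ins_seq <- substr(strrep(config$satellite_motif, extra_copies + 1), 1,
                        extra_copies * nchar(config$satellite_motif))
      edits <- bind_rows(edits, tibble(
        pos = sat_iv$end, kind = "satellite_expansion", ins = ins_seq,
        del_len = 0L, dup_src_start = NA_integer_, dup_src_end = NA_integer_))
    }
    arr_units <- genes_df |> filter(!is.na(.data$array))
    array_meta <- list()
    for (aid in unique(arr_units$array)) {
      if (config$array_copy_delta <= 0) next
      members <- arr_units |> filter(.data$array == aid)
      orf <- members$cds[1]
      unit <- paste0(orf, random_dna(200))
      ins_pieces <- character(config$array_copy_delta)
      broken <- runif(config$array_copy_delta) < config$broken_orf_frac
      for (k in seq_len(config$array_copy_delta)) {
        u <- unit
        if (broken[k]) {
          # in-frame premature stop one third of the way into the ORF;
          # replaces one codon, so the length is unchanged
          stop_at <- 3L * max(2L, (nchar(orf) %/% 9L))
          u <- paste0(substr(u, 1, stop_at), "TAA",
                      substr(u, stop_at + 4L, nchar(u)))
        }
        ins_pieces[k] <- u
      }
      ins_at <- max(members$gend) + 200L
      edits <- bind_rows(edits, tibble(
        pos = ins_at, kind = "gene_copies",
        ins = paste(ins_pieces, collapse = ""), del_len = 0L,
        dup_src_start = NA_integer_, dup_src_end = NA_integer_))
      array_meta[[length(array_meta) + 1L]] <- list(
        array = aid, n = config$array_copy_delta, orf_len = nchar(orf),
        unit_len = nchar(unit), broken = broken, chrom = cname,
        a_pos = ins_at)
    }
    if (config$duplication_length > 0 && ci == 1) {
      iv <- place_intervals(1, config$duplication_length,
                            config$duplication_length, L, occupied)
      occupied <- bind_rows(occupied, iv)
      edits <- bind_rows(edits, tibble(
        pos = iv$end, kind = "duplication",
        ins = paste(chars[(iv$start + 1L):iv$end], collapse = ""),
        del_len = 0L, dup_src_start = iv$start, dup_src_end = iv$end))
      truth$dups[[length(truth$dups) + 1L]] <-
        tibble(chrom = cname, start = iv$start, end = iv$end)
    }
    if (config$unique_insertion_length > 0 && ci == 1) {
      iv <- place_intervals(1, 1000, 1000, L, occupied)
      occupied <- bind_rows(occupied, iv)
      edits <- bind_rows(edits, tibble(
        pos = iv$start, kind = "unique_insertion",
        ins = random_dna(config$unique_insertion_length), del_len = 0L,
        dup_src_start = NA_integer_, dup_src_end = NA_integer_))
      truth$uniq[[length(truth$uniq) + 1L]] <-
        tibble(chrom = cname, a_pos = iv$start,
               length = config$unique_insertion_length)
    }
    # small indels in free sequence
    n_indels <- rbinom(1, L, config$indel_rate)
    if (n_indels > 0) {
      placed <- place_intervals(n_indels, 1, 5, L, occupied, margin = 200)
      occupied <- bind_rows(occupied, placed)
      for (i in seq_len(nrow(placed))) {
        if (runif(1) < 0.5) {
          edits <- bind_rows(edits, tibble(
            pos = placed$start[i], kind = "small_ins",
            ins = random_dna(placed$end[i] - placed$start[i]), del_len = 0L,
            dup_src_start = NA_integer_, dup_src_end = NA_integer_))
        } else {
          edits <- bind_rows(edits, tibble(
            pos = placed$start[i], kind = "small_del", ins = NA_character_,
            del_len = placed$end[i] - placed$start[i],
            dup_src_start = NA_integer_, dup_src_end = NA_integer_))
        }
      }
    }

    # --- build species B and the truth alignment blocks -----------------
    built <- build_species_b(chars, edits,
                             if (nrow(inv_iv) > 0) inv_iv else NULL, cname)
    seq_a <- mutate_bases(paste(chars, collapse = ""), config$snp_rate / 2)
    seq_b <- mutate_bases(built$seq, config$snp_rate / 2)
    genome_a[[ci]] <- tibble(id = cname, seq = seq_a)
    genome_b[[ci]] <- tibble(id = cname, seq = seq_b)
    truth$blocks[[ci]] <- built$blocks

    # B-side gene bookkeeping for planted extra copies
    for (meta in array_meta) {
      ins_row <- built$insertions |>
        filter(.data$kind == "gene_copies", .data$a_pos == meta$a_pos)
      b0 <- ins_row$b_start[1]
      for (k in seq_len(meta$n)) {
        gs <- b0 + (k - 1L) * meta$unit_len
        genes_b_extra[[length(genes_b_extra) + 1L]] <- tibble(
          chrom = meta$chrom, gstart = gs, gend = gs + meta$orf_len,
          strand = "+",
          exons = list(tibble(start = gs, end = gs + meta$orf_len)),
          array = meta$array, broken = meta$broken[k])
      }
    }
    sat_ins <- built$insertions |> filter(.data$kind == "satellite_expansion")
    sat_extra <- if (nrow(sat_ins) > 0) sat_ins$b_end[1] - sat_ins$b_start[1] else 0L
    sat_b[[ci]] <- tibble(
      chrom = cname,
      start = map_a_interval_to_b(sat_iv$start, sat_iv$end,
                                  truth$blocks[[ci]])$start,
      motif = config$satellite_motif,
      copies = config$satellite_copies + sat_extra %/%
        nchar(config$satellite_motif)) |>
      mutate(end = .data$start +
               (sat_iv$end - sat_iv$start) + sat_extra, .after = "start")
  }

  genes_a <- bind_rows(truth$genes) |>
    mutate(gene = sprintf("gA_%04d", .data$idx))
  genes_b_shared <- genes_a
  for (i in seq_len(nrow(genes_b_shared))) {
    bl <- truth$blocks[[match(genes_b_shared$chrom[i], chrom_names)]]
    m <- map_a_interval_to_b(genes_b_shared$gstart[i],
                             genes_b_shared$gend[i], bl)
    ex <- genes_b_shared$exons[[i]]
    ex2 <- purrr::map2_dfr(ex$start, ex$end, function(s, e) {
      as_tibble(map_a_interval_to_b(s, e, bl))
    })
    genes_b_shared$gstart[i] <- m$start
    genes_b_shared$gend[i] <- m$end
    genes_b_shared$exons[[i]] <- ex2
  }
  genes_b_shared <- genes_b_shared |>
    mutate(gene_b = sprintf("gB_%04d", .data$idx))
  extra <- bind_rows(genes_b_extra)
  if (nrow(extra) > 0) {
    extra <- extra |>
      mutate(gene_b = sprintf("gB_x%03d", row_number()), cds = NA_character_)
  }
  truth_out <- list(
    inversions = bind_rows(truth$inversions),
    repeats_a = bind_rows(truth$repeats) |>
      select("chrom", "start", "end", "class", "kind"),
    satellites_a = bind_rows(truth$satellites),
    satellites_b = bind_rows(sat_b) |>
      select("chrom", "start", "end", "motif", "copies"),
    genes_a = genes_a |> select("gene", "chrom", "gstart", "gend", "strand",
                                "exons", "cds", "array"),
    genes_b = bind_rows(
      genes_b_shared |> mutate(broken = FALSE) |>
        select(gene = "gene_b", "chrom", "gstart", "gend", "strand", "exons",
               "cds", "array", "broken", ortholog = "gene"),
      if (nrow(extra) > 0) {
        extra |> select(gene = "gene_b", "chrom", "gstart", "gend", "strand",
                        "exons", "cds", "array", "broken") |>
          mutate(ortholog = NA_character_)
      }),
    ortholog_pairs = tibble(gene_a = genes_a$gene,
                            gene_b = genes_b_shared$gene_b),
    duplications = bind_rows(truth$dups),
    unique_insertions = bind_rows(truth$uniq),
    blocks = bind_rows(truth$blocks))
  # repeats in B coordinates (every tract sits inside one collinear block)
  rb <- truth_out$repeats_a
  if (nrow(rb) > 0) {
    mapped <- purrr::pmap_dfr(rb, function(chrom, start, end, class, kind) {
      bl <- truth$blocks[[match(chrom, chrom_names)]]
      m <- map_a_interval_to_b(start, end, bl)
      tibble(chrom = chrom, start = m$start, end = m$end, class = class,
             kind = kind)
    })
    truth_out$repeats_b <- mapped
  } else {
    truth_out$repeats_b <- rb
  }
  list(genome_a = bind_rows(genome_a), genome_b = bind_rows(genome_b),
       truth = truth_out, config = config)
}

# assemble species B from ancestor chars, point edits and inversions;
# returns the sequence, collinear truth blocks, and insertion records
build_species_b <- function(chars, edits, inversions, cname) {
  L <- length(chars)
  ev <- list()
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    ev[[length(ev) + 1L]] <- tibble(
      start = e$pos,
      end = e$pos + (if (e$kind == "small_del") e$del_len else 0L),
      kind = e$kind, ins = e$ins,
      dup_src_start = e$dup_src_start, dup_src_end = e$dup_src_end)
  }
  if (!is.null(inversions)) {
    for (i in seq_len(nrow(inversions))) {
      ev[[length(ev) + 1L]] <- tibble(
        start = inversions$start[i], end = inversions$end[i],
        kind = "inversion", ins = NA_character_,
        dup_src_start = NA_integer_, dup_src_end = NA_integer_)
    }
  }
  ev <- if (length(ev) > 0) bind_rows(ev) |> arrange(.data$start) else
    tibble(start = integer(), end = integer(), kind = character(),
           ins = character(), dup_src_start = integer(),
           dup_src_end = integer())
  pieces <- character(0)
  blocks <- list()
  insertions <- list()
  cur <- 0L
  b_pos <- 0L
  emit_collinear <- function(s, e) {
    if (e <= s) return(invisible())
    pieces[[length(pieces) + 1L]] <<- paste(chars[(s + 1L):e], collapse = "")
    blocks[[length(blocks) + 1L]] <<- tibble(
      chrom = cname, a_start = s, a_end = e, b_start = b_pos,
      b_end = b_pos + (e - s), strand = "+", dup = FALSE)
    b_pos <<- b_pos + (e - s)
  }
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    emit_collinear(cur, e$start)
    if (e$kind == "inversion") {
      len <- e$end - e$start
      pieces[[length(pieces) + 1L]] <-
        revcomp(paste(chars[(e$start + 1L):e$end], collapse = ""))
      blocks[[length(blocks) + 1L]] <- tibble(
        chrom = cname, a_start = e$start, a_end = e$end, b_start = b_pos,
        b_end = b_pos + len, strand = "-", dup = FALSE)
      b_pos <- b_pos + len
      cur <- e$end
    } else if (e$kind == "small_del") {
      cur <- e$end
    } else {
      ins_len <- nchar(e$ins)
      pieces[[length(pieces) + 1L]] <- e$ins
      insertions[[length(insertions) + 1L]] <- tibble(
        chrom = cname, kind = e$kind, a_pos = e$start, b_start = b_pos,
        b_end = b_pos + ins_len)
      if (e$kind == "duplication") {
        blocks[[length(blocks) + 1L]] <- tibble(
          chrom = cname, a_start = e$dup_src_start, a_end = e$dup_src_end,
          b_start = b_pos, b_end = b_pos + ins_len, strand = "+",
          dup = TRUE)
      }
      b_pos <- b_pos + ins_len
      cur <- e$start
    }
  }
  emit_collinear(cur, L)
  list(seq = paste(pieces, collapse = ""),
       blocks = bind_rows(blocks),
       insertions = if (length(insertions) > 0) bind_rows(insertions) else
         tibble(chrom = character(), kind = character(), a_pos = integer(),
                b_start = integer(), b_end = integer()))
}

# map an interval through the collinear truth blocks of one chromosome;
# the interval must sit inside a single block
map_a_interval_to_b <- function(s, e, blocks) {
  hit <- blocks |>
    filter(!.data$dup, .data$a_start <= s, .data$a_end >= e) |>
    slice(1)
  if (nrow(hit) == 0) abort("interval not contained in one truth block")
  if (hit$strand == "+") {
    list(start = hit$b_start + (s - hit$a_start),
         end = hit$b_start + (e - hit$a_start), strand = "+")
  } else {
    list(start = hit$b_start + (hit$a_end - e),
         end = hit$b_start + (hit$a_end - s), strand = "-")
  }
}
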