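# shared fixtures: small study configurations and cached simulations so the
# generator runs once per scenario rather than once per test

.fixture_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 7, ...) {
  sim_config(seed = seed,
             chromosome_lengths = c(5e5, 4e5),
             n_inversions = 2,
             inversion_length = c(45000, 60000),
             satellite_copies = 80,
             n_gene_arrays = 2,
             genes_per_chromosome = 8,
             long_tracts_per_chromosome = 3,
             short_tracts_per_chromosome = 8,
             markers_per_chromosome = 20,
             n_crosses = 3,
             n_f2_per_cross = 60,
             breaks_per_chromosome = 2,
             ...)
}

zero_noise_args <- function() {
  list(snp_rate = 0, indel_rate = 0, marker_false_hit_rate = 0,
       map_noise_sd = 0)
}

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_zero_study <- function() {
  cached("small_zero_study", {
    cfg <- do.call(small_config, c(list(seed = 7), zero_noise_args()))
    simulate_study(cfg)
  })
}

small_noisy_study <- function() {
  cached("small_noisy_study", {
    cfg <- small_config(seed = 11)
    simulate_study(cfg)
  })
}

# naive canonical k-mer counter: independent oracle for count_kmers
naive_kmer_counts <- function(seqs, k) {
  wins <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }))
  wins <- wins[!grepl("N", wins, fixed = TRUE)]
  canon <- pmin(wins, revcomp(wins))
  tab <- table(canon)
  tibble::tibble(kmer = names(tab), count = as.numeric(tab))
}

# brute-force maximal exact tandem runs (quadratic oracle)
brute_tandem_exact <- function(s, max_period, min_copies) {
  n <- nchar(s)
  x <- strsplit(s, "")[[1]]
  out <- list()
  for (p in seq_len(min(max_period, n %/% 2))) {
    b <- x[(p + 1):n] == x[1:(n - p)]
    r <- rle(b)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      len <- ends[j] - starts[j] + 1L + p
      if (len >= min_copies * p) {
        out[[length(out) + 1L]] <- tibble::tibble(
          start = starts[j] - 1L, end = ends[j] + p, period = p)
      }
    }
  }
  dplyr::bind_rows(out)
}

# per-base bitmap oracle for interval collapse
bitmap_collapse_bp <- function(features, len_by_contig) {
  total <- 0L
  for (ctg in names(len_by_contig)) {
    f <- features[features$contig == ctg, ]
    if (nrow(f) == 0) next
    bits <- logical(len_by_contig[[ctg]])
    for (i in seq_len(nrow(f))) bits[(f$start[i] + 1):f$end[i]] <- TRUE
    total <- total + sum(bits)
  }
  total
}

random_features <- function(n, contigs, max_len = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctg <- sample(names(contigs), n, replace = TRUE)
  start <- vapply(ctg, function(cn) sample.int(contigs[[cn]] - max_len, 1),
                  integer(1))
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(contig = ctg, start = as.integer(start),
                 end = as.integer(start + len),
                 ftype = sample(c("LINE", "SINE", "DNA"), n, replace = TRUE))
}
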