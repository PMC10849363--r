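#' Haldane map function and its inverse
#'
#' Converts a recombination fraction to centimorgans under the Haldane
#' model (independent crossovers, no interference): `cM = -50 log(1 - 2r)`.
#' The inverse is exact, so the round trip is the identity.
#'
#' @param r Recombination fraction(s), `0 <= r < 0.5`.
#' @param cM Genetic distance(s) in centimorgans, `>= 0`.
#' @return Numeric vector.
#' @examples
#' haldane_cm(0.2)            # 25.541...
#' inverse_haldane(haldane_cm(0.3))
#' @export
haldane_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) abort("recombination fraction must be in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_cm
#' @export
inverse_haldane <- function(cM) {
  if (any(cM < 0)) abort("cM must be >= 0")
  (1 - exp(-cM / 50)) / 2
}

#' Lay out markers along simulated chromosomes
#'
#' Markers are spread near-evenly with uniform jitter, away from the
#' chromosome ends. Linkage groups are named `LG1`, `LG2`, ... in
#' chromosome order; the true genetic position is `bp / bp_per_cM`.
#'
#' @param config A [sim_config()].
#' @return A tibble `marker`, `chrom`, `linkage_group`, `bp`, `cM_true`.
#' @export
sim_markers <- function(config) {
  purrr::map_dfr(seq_len(config$n_chromosomes), function(ci) {
    L <- config$chromosome_lengths[ci]
    m <- config$markers_per_chromosome
    base <- seq(10000, L - 10000, length.out = m)
    jit <- runif(m, -0.3, 0.3) * (base[2] - base[1])
    bp <- sort(as.integer(round(pmin(pmax(base + jit, 1000), L - 1000))))
    bp <- bp + cumsum(c(0L, as.integer(diff(bp) == 0)))  # break exact ties
    tibble(marker = sprintf("chr%d_m%03d", ci, seq_len(m)),
           chrom = paste0("chr", ci),
           linkage_group = paste0("LG", ci),
           bp = bp,
           cM_true = bp / config$bp_per_cM)
  })
}

#' Simulate one F2 intercross and its genetic map
#'
#' Gametes recombine between adjacent markers with probability
#' `inverse_haldane(delta_bp / bp_per_cM)`; genotypes are the sum of two
#' independent gametes, coded `AA`/`AB`/`BB`. The emitted map position is
#' the true cumulative cM plus Gaussian noise, with monotonicity restored by
#' isotonic regression and the origin shifted to zero.
#'
#' @param markers Marker tibble for the markers segregating in this cross
#'   (subset of [sim_markers()] output), sorted by `chrom` then `bp`.
#' @param config A [sim_config()].
#' @param cross Cross id string.
#' @param seed Optional seed (otherwise continues the current RNG stream).
#' @return An object of class `sim_cross`: list with `cross`, `genotypes`
#'   (markers x individuals character matrix), `gametes` (markers x 2n 0/1
#'   matrix), `rf_true` (tibble of adjacent-marker recombination fractions),
#'   and `map` (tibble `marker`, `cross`, `linkage_group`, `cM`).
#' @export
simulate_f2_cross <- function(markers, config, cross = "cross1",
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_ind <- config$n_f2_per_cross
  n_gam <- 2L * n_ind
  geno <- list()
  gam_all <- list()
  rf_all <- list()
  map <- list()
  for (ch in unique(markers$chrom)) {
    mk <- markers |> filter(.data$chrom == ch) |> arrange(.data$bp)
    if (nrow(mk) < 2) {
      warn(paste0("chromosome ", ch, " has <2 markers; skipped"))
      next
    }
    d_cm <- diff(mk$bp) / config$bp_per_cM
    r <- inverse_haldane(d_cm)
    m <- nrow(mk)
    # gametes: first allele fair coin, then switch with probability r
    g <- matrix(0L, nrow = m, ncol = n_gam)
    g[1, ] <- rbinom(n_gam, 1, 0.5)
    for (i in 2:m) {
      sw <- rbinom(n_gam, 1, r[i - 1])
      g[i, ] <- (g[i - 1, ] + sw) %% 2L
    }
    rownames(g) <- mk$marker
    g1 <- g[, seq_len(n_ind), drop = FALSE]
    g2 <- g[, n_ind + seq_len(n_ind), drop = FALSE]
    gt <- matrix(c("AA", "AB", "BB")[g1 + g2 + 1L], nrow = m,
                 dimnames = list(mk$marker, sprintf("%s_f2_%03d", cross,
                                                    seq_len(n_ind))))
    geno[[ch]] <- gt
    gam_all[[ch]] <- g
    rf_all[[ch]] <- tibble(chrom = ch, marker_a = head(mk$marker, -1),
                           marker_b = tail(mk$marker, -1), rf = r)
    cm_true <- cumsum(c(0, d_cm))
    cm_noisy <- cm_true + rnorm(m, 0, config$map_noise_sd)
    cm_iso <- isoreg(seq_len(m), cm_noisy)$yf
    cm_iso <- cm_iso - min(cm_iso)
    map[[ch]] <- tibble(marker = mk$marker, cross = cross,
                        linkage_group = mk$linkage_group[1], cM = cm_iso)
  }
  structure(list(cross = cross,
                 genotypes = do.call(rbind, geno),
                 gametes = do.call(rbind, gam_all),
                 rf_true = bind_rows(rf_all),
                 map = bind_rows(map)),
            class = "sim_cross")
}

#' @export
print.sim_cross <- function(x, ...) {
  cat("<sim_cross>", x$cross, ":", nrow(x$genotypes), "markers x",
      ncol(x$genotypes), "F2 individuals\n")
  invisible(x)
}
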