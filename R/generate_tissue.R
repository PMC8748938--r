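#' Generate a synthetic marked-point-pattern tissue
#'
#' Simulates the cell populations of a multiplexed-IF tissue section with
#' the spatial structure the downstream statistics assume:
#' \itemize{
#'   \item tumor cells from a Thomas cluster process (Poisson nest parents
#'     at `nest_parent_intensity`, Poisson(`nest_mean_cells`) offspring,
#'     isotropic Gaussian `nest_sigma_um` spread), all PanCK+;
#'   \item nest-coherent PGRN status: each nest is PGRN-high with
#'     probability `p_nest_pgrn`, and cells of high nests are PGRN+ with
#'     probability `p_pgrn_within` (cells of low nests are PGRN-);
#'   \item MHCI positivity drawn per tumor cell conditionally on PGRN;
#'   \item stromal cells from a homogeneous Poisson process (all markers
#'     negative);
#'   \item CD8 cells from a homogeneous Poisson process thinned near PGRN+
#'     tumor cells: a candidate at distance `d` from the nearest PGRN+
#'     tumor cell is retained with probability
#'     `excl_floor + (1 - excl_floor) * min(1, d / excl_radius_um)`
#'     (retention is 1 everywhere when `excl_radius_um = 0` or no PGRN+
#'     tumor cell exists); retained CD8 cells are GzmB+ with probability
#'     `p_gzmb_given_cd8`.
#' }
#' Each cell class draws from an independent RNG substream of `config$seed`,
#' so the tissue is fully deterministic and, e.g., the tumor layout does not
#' change when CD8 simulation is added or removed. Points falling outside
#' the window are discarded. Nest parents are simulated on the window padded
#' by four nest sigmas so border nests are not under-represented.
#'
#' @param config A [sim_config()].
#' @return A [cell_table()] with columns `id`, `x_um`, `y_um`, logical
#'   marker columns (`PanCK`, `PGRN`, `MHCI`, `CD8`, `GzmB`), `compartment`
#'   (`tumor` / `stroma` / `immune`) and, for tumor cells, `nest` (parent
#'   index; `NA` otherwise).
#' @examples
#' cells <- generate_tissue(sim_config(window_um = c(400, 400), seed = 3))
#' mean(cells$PGRN[cells$compartment == "tumor"])
#' @export
generate_tissue <- function(config) {
  cfg <- validate_sim_config(config)
  W <- cfg$window_um[1]
  H <- cfg$window_um[2]
  area <- W * H

  streams <- rng_substreams(cfg$seed, 7L)
  names(streams) <- c("tumor", "pgrn", "mhc", "stroma", "cd8", "thin", "gzmb")

  # --- tumor nests (Thomas process) -----------------------------------
  pad <- 4 * cfg$nest_sigma_um
  tumor <- with_stream(streams$tumor, {
    n_par <- rpois(1, cfg$nest_parent_intensity * (W + 2 * pad) * (H + 2 * pad))
    if (n_par == 0) {
      list(x = numeric(0), y = numeric(0), nest = integer(0), n_par = 0L)
    } else {
      px <- runif(n_par, -pad, W + pad)
      py <- runif(n_par, -pad, H + pad)
      n_off <- rpois(n_par, cfg$nest_mean_cells)
      nest <- rep.int(seq_len(n_par), n_off)
      x <- px[nest] + rnorm(length(nest), 0, cfg$nest_sigma_um)
      y <- py[nest] + rnorm(length(nest), 0, cfg$nest_sigma_um)
      keep <- x >= 0 & x <= W & y >= 0 & y <= H
      list(x = x[keep], y = y[keep], nest = nest[keep], n_par = n_par)
    }
  })
  n_tum <- length(tumor$x)

  pgrn <- with_stream(streams$pgrn, {
    nest_high <- rbinom(tumor$n_par, 1, cfg$p_nest_pgrn) == 1
    in_high <- if (n_tum > 0) nest_high[tumor$nest] else logical(0)
    in_high & rbinom(n_tum, 1, cfg$p_pgrn_within) == 1
  })

  mhc <- with_stream(streams$mhc, {
    p <- ifelse(pgrn, cfg$p_mhc_given_pgrn_pos, cfg$p_mhc_given_pgrn_neg)
    rbinom(n_tum, 1, p) == 1
  })

  # --- stroma ---------------------------------------------------------
  stroma <- with_stream(streams$stroma, {
    n <- rpois(1, cfg$lambda_stroma * area)
    list(x = runif(n, 0, W), y = runif(n, 0, H))
  })

  # --- CD8 with exclusion thinning ------------------------------------
  cd8 <- with_stream(streams$cd8, {
    n <- rpois(1, cfg$lambda_cd8 * area)
    list(x = runif(n, 0, W), y = runif(n, 0, H))
  })
  n_cd8 <- length(cd8$x)

  keep_cd8 <- with_stream(streams$thin, {
    u <- runif(n_cd8)
    pgrn_idx <- which(pgrn)
    if (cfg$excl_radius_um == 0 || length(pgrn_idx) == 0 || n_cd8 == 0) {
      u <= 1  # retention 1 everywhere
    } else {
      d <- nearest_dist(cd8$x, cd8$y,
                        tumor$x[pgrn_idx], tumor$y[pgrn_idx])
      rho <- cfg$excl_floor +
        (1 - cfg$excl_floor) * pmin(1, d / cfg$excl_radius_um)
      u <= rho
    }
  })
  cd8x <- cd8$x[keep_cd8]
  cd8y <- cd8$y[keep_cd8]
  n_cd8k <- length(cd8x)

  gzmb <- with_stream(streams$gzmb, rbinom(n_cd8k, 1, cfg$p_gzmb_given_cd8) == 1)

  # --- assemble -------------------------------------------------------
  n_str <- length(stroma$x)
  n_all <- n_tum + n_str + n_cd8k
  df <- data.frame(
    id = seq_len(n_all),
    x_um = c(tumor$x, stroma$x, cd8x),
    y_um = c(tumor$y, stroma$y, cd8y),
    PanCK = c(rep(TRUE, n_tum), rep(FALSE, n_str + n_cd8k)),
    PGRN = c(pgrn, rep(FALSE, n_str + n_cd8k)),
    MHCI = c(mhc, rep(FALSE, n_str + n_cd8k)),
    CD8 = c(rep(FALSE, n_tum + n_str), rep(TRUE, n_cd8k)),
    GzmB = c(rep(FALSE, n_tum + n_str), gzmb),
    compartment = c(rep("tumor", n_tum), rep("stroma", n_str),
                    rep("immune", n_cd8k)),
    nest = c(tumor$nest, rep(NA_integer_, n_str + n_cd8k))
  )
  cell_table(df, window_um = cfg$window_um)
}

# For each query point, Euclidean distance to the nearest reference point.
# Chunked to bound the temporary distance matrix.
nearest_dist <- function(qx, qy, rx, ry, chunk = 2000L) {
  n <- length(qx)
  if (n == 0) return(numeric(0))
  if (length(rx) == 0) return(rep(Inf, n))
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(qx[idx], rx, "-")^2 + outer(qy[idx], ry, "-")^2
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}
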