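#' Simulation configuration for synthetic tissue
#'
#' Parameterizes the marked point-process tissue generator. Tumor cells are
#' placed by a Thomas cluster process (Poisson parents, Poisson offspring
#' counts, isotropic Gaussian spread) to emulate tumor nests; progranulin
#' (PGRN) status is assigned first per nest and then per cell, MHC class I
#' positivity is drawn conditionally on PGRN status, and CD8 cells are a
#' homogeneous Poisson process thinned near PGRN+ tumor cells with a linear
#' distance ramp.
#'
#' @param window_um Numeric length-2 vector, tissue window (width, height)
#'   in micrometers.
#' @param lambda_stroma Background (stromal) cell intensity, cells/um^2.
#' @param nest_parent_intensity Tumor nest (parent) intensity, nests/um^2.
#' @param nest_mean_cells Expected tumor cells per nest (Poisson mean).
#' @param nest_sigma_um Isotropic Gaussian offspring spread, um.
#' @param p_nest_pgrn Probability that a whole nest is PGRN-high.
#' @param p_pgrn_within Per-cell PGRN+ probability inside a PGRN-high nest
#'   (cells in PGRN-low nests are PGRN-negative). Setting
#'   `p_nest_pgrn = 1` degenerates to purely per-cell assignment.
#' @param p_mhc_given_pgrn_pos,p_mhc_given_pgrn_neg Conditional MHCI+
#'   probability for PGRN+ / PGRN- tumor cells.
#' @param lambda_cd8 Base CD8 cell intensity, cells/um^2 (before thinning).
#' @param excl_radius_um CD8 exclusion radius around PGRN+ tumor cells, um.
#'   Zero disables thinning.
#' @param excl_floor Retention probability at distance 0 (in \[0, 1\]); the
#'   retention ramp is `excl_floor + (1 - excl_floor) * min(1, d / excl_radius_um)`
#'   where `d` is the distance to the nearest PGRN+ tumor cell.
#' @param p_gzmb_given_cd8 Granzyme-B+ probability among retained CD8 cells.
#' @param seed Integer RNG seed; identical configs give identical tissues.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [generate_tissue()], [render_masks()]
#' @examples
#' cfg <- sim_config(window_um = c(500, 500), seed = 7)
#' cells <- generate_tissue(cfg)
#' table(cells$compartment)
#' @export
sim_config <- function(window_um = c(1000, 1000),
                       lambda_stroma = 5e-4,
                       nest_parent_intensity = 2e-5,
                       nest_mean_cells = 50,
                       nest_sigma_um = 30,
                       p_nest_pgrn = 0.5,
                       p_pgrn_within = 0.9,
                       p_mhc_given_pgrn_pos = 0.2,
                       p_mhc_given_pgrn_neg = 0.8,
                       lambda_cd8 = 5e-4,
                       excl_radius_um = 50,
                       excl_floor = 0.1,
                       p_gzmb_given_cd8 = 0.5,
                       seed = 1L) {
  cfg <- list(
    window_um = as.numeric(window_um),
    lambda_stroma = lambda_stroma,
    nest_parent_intensity = nest_parent_intensity,
    nest_mean_cells = nest_mean_cells,
    nest_sigma_um = nest_sigma_um,
    p_nest_pgrn = p_nest_pgrn,
    p_pgrn_within = p_pgrn_within,
    p_mhc_given_pgrn_pos = p_mhc_given_pgrn_pos,
    p_mhc_given_pgrn_neg = p_mhc_given_pgrn_neg,
    lambda_cd8 = lambda_cd8,
    excl_radius_um = excl_radius_um,
    excl_floor = excl_floor,
    p_gzmb_given_cd8 = p_gzmb_given_cd8,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_scalar <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  if (length(cfg$window_um) != 2L || any(!is.finite(cfg$window_um)) ||
      any(cfg$window_um <= 0)) {
    stop("`window_um` must be two positive finite dimensions", call. = FALSE)
  }
  rates <- c("lambda_stroma", "nest_parent_intensity", "nest_mean_cells",
             "nest_sigma_um", "lambda_cd8", "excl_radius_um")
  for (nm in rates) {
    chk_scalar(cfg[[nm]], nm)
    if (cfg[[nm]] < 0) {
      stop(sprintf("`%s` must be non-negative", nm), call. = FALSE)
    }
  }
  probs <- c("p_nest_pgrn", "p_pgrn_within", "p_mhc_given_pgrn_pos",
             "p_mhc_given_pgrn_neg", "excl_floor", "p_gzmb_given_cd8")
  for (nm in probs) {
    chk_scalar(cfg[[nm]], nm)
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop(sprintf("`%s` must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  if (is.na(cfg$seed)) stop("`seed` must be an integer", call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  window: %g x %g um, seed %d\n",
              x$window_um[1], x$window_um[2], x$seed))
  cat(sprintf("  intensities (per um^2): stroma %g, nest parents %g, CD8 %g\n",
              x$lambda_stroma, x$nest_parent_intensity, x$lambda_cd8))
  cat(sprintf("  nests: mean %g cells, sigma %g um, P(PGRN-high nest) %g\n",
              x$nest_mean_cells, x$nest_sigma_um, x$p_nest_pgrn))
  cat(sprintf("  P(MHCI+ | PGRN+/-) = %g / %g; CD8 exclusion R %g um, floor %g\n",
              x$p_mhc_given_pgrn_pos, x$p_mhc_given_pgrn_neg,
              x$excl_radius_um, x$excl_floor))
  invisible(x)
}

#' Rendering configuration for synthetic mask images
#'
#' Describes how a point-referenced cell table is rasterized into binary
#' channel masks: the pixel size, image shape, and the disk radii stamped
#' for the nuclear (DAPI) and marker channels.
#'
#' @param pixel_size_um Micrometers per pixel (> 0).
#' @param image_shape_px Integer (rows, cols); if `NULL`, derived from the
#'   cell table's window at render time (`ceiling(window / pixel_size)`).
#' @param r_nucleus_um DAPI (nucleus) disk radius, um.
#' @param r_marker_um Marker disk radius, um; either a single value for all
#'   marker channels or a named vector per channel.
#' @return An object of class `render_config`.
#' @export
render_config <- function(pixel_size_um = 1,
                          image_shape_px = NULL,
                          r_nucleus_um = 2,
                          r_marker_um = 3) {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0 ||
      !is.finite(pixel_size_um)) {
    stop("`pixel_size_um` must be positive", call. = FALSE)
  }
  if (!is.null(image_shape_px)) {
    if (length(image_shape_px) != 2L || any(image_shape_px < 1)) {
      stop("`image_shape_px` must be two positive integers", call. = FALSE)
    }
    image_shape_px <- as.integer(image_shape_px)
  }
  if (any(r_nucleus_um <= 0) || any(r_marker_um <= 0)) {
    stop("disk radii must be positive", call. = FALSE)
  }
  structure(list(pixel_size_um = pixel_size_um,
                 image_shape_px = image_shape_px,
                 r_nucleus_um = r_nucleus_um,
                 r_marker_um = r_marker_um),
            class = "render_config")
}

#' Read a simulation or render configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [sim_config()] (or [render_config()] for `read_render_config()`).
#' @return A validated `sim_config` / `render_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$window_um)) vals$window_um <- unlist(vals$window_um)
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @export
read_render_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$image_shape_px)) {
    vals$image_shape_px <- unlist(vals$image_shape_px)
  }
  do.call(render_config, vals)
}
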