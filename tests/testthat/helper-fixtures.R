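# Small fixtures built in code.

# A hand-placed cell table with known marker flags.
toy_cells <- function() {
  cell_table(data.frame(
    id = 1:6,
    x_um = c(10, 20, 30, 100, 110, 200),
    y_um = c(10, 20, 30, 100, 110, 200),
    PanCK = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    PGRN  = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    MHCI  = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    CD8   = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    GzmB  = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    compartment = c("tumor", "tumor", "tumor", "immune", "immune", "stroma")
  ), window_um = c(250, 250))
}

# Random cell table of n points on a window, ids shuffled, no markers.
random_points <- function(n, window = c(500, 500), id_offset = 0L) {
  cell_table(data.frame(
    id = sample(seq_len(n)) + id_offset,
    x_um = runif(n, 0, window[1]),
    y_um = runif(n, 0, window[2])
  ), window_um = window, channels = character(0))
}

# Config for a small image used in MHC-fraction cohort simulations:
# CD8/stroma off so only tumor cells are generated.
mhc_cohort_config <- function(p_pos, p_neg, seed) {
  sim_config(window_um = c(400, 400),
             lambda_stroma = 0,
             nest_parent_intensity = 5e-5,
             nest_mean_cells = 40,
             nest_sigma_um = 25,
             p_nest_pgrn = 0.5,
             p_pgrn_within = 0.9,
             p_mhc_given_pgrn_pos = p_pos,
             p_mhc_given_pgrn_neg = p_neg,
             lambda_cd8 = 0,
             excl_radius_um = 0,
             seed = seed)
}

# Simulate one cohort of `n_images` tissues and compare per-image MHCI+
# fractions between PGRN+PanCK+ and PGRN-PanCK+ tumor cells.
simulate_mhc_cohort_p <- function(p_pos, p_neg, n_images, seed) {
  images <- lapply(seq_len(n_images), function(i) {
    classify_cells(generate_tissue(mhc_cohort_config(p_pos, p_neg,
                                                     seed * 1000L + i)))
  })
  res <- conditional_marker_fraction(images, "tumor_pgrn_pos",
                                     "tumor_pgrn_neg", "MHCI")
  res$comparison$p_two_tailed
}

# Mean unique CD8 neighbors within `radius` of PGRN+ vs PGRN- tumor
# anchors for one simulated tissue; returns the difference (pos - neg).
cd8_neighbor_diff <- function(cfg, radius = 50) {
  cells <- classify_cells(generate_tissue(cfg))
  s_pos <- proximity_summary(cells, "tumor_pgrn_pos", "cd8", radius)
  s_neg <- proximity_summary(cells, "tumor_pgrn_neg", "cd8", radius)
  mean(s_pos$per_anchor$n_unique_partners) -
    mean(s_neg$per_anchor$n_unique_partners)
}
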