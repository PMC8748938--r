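# Round-trip validation: match simulated ground-truth cells to detected
# cells by nearest centroid and score marker-flag agreement.

#' Match ground-truth cells to detected cells by nearest centroid
#'
#' Each truth cell is matched to the nearest detected centroid within
#' `max_dist_um` (one-to-one, greedy by distance). Used to validate the
#' simulate - render - detect - assign round trip.
#'
#' @param truth,detected [cell_table()]s in the same frame.
#' @param max_dist_um Maximum matching distance, um.
#' @return Data frame with one row per truth cell: `truth_id`,
#'   `detected_id` (`NA` when unmatched), `dist_um`.
#' @export
match_cells <- function(truth, detected, max_dist_um) {
  n_t <- nrow(truth)
  out <- data.frame(truth_id = truth$id,
                    detected_id = rep(NA_integer_, n_t),
                    dist_um = rep(NA_real_, n_t))
  if (n_t == 0 || nrow(detected) == 0) return(out)
  d <- sqrt(outer(truth$x_um, detected$x_um, "-")^2 +
            outer(truth$y_um, detected$y_um, "-")^2)
  d[d > max_dist_um] <- Inf
  repeat {
    best <- which.min(d)
    if (length(best) == 0 || !is.finite(d[best])) break
    ti <- (best - 1L) %% n_t + 1L
    di <- (best - 1L) %/% n_t + 1L
    out$detected_id[ti] <- detected$id[di]
    out$dist_um[ti] <- d[best]
    d[ti, ] <- Inf
    d[, di] <- Inf
  }
  out
}

#' Score recovery of simulated cells through the imaging round trip
#'
#' Fraction of (optionally well-separated) ground-truth cells that are
#' recovered by detection with every marker flag correct. Overlapping
#' nuclei merge into one component by design (no instance segmentation),
#' so with `min_spacing_um` set, scoring is restricted to truth cells whose
#' nearest truth neighbor exceeds that spacing.
#'
#' @param truth Simulated [cell_table()] with marker flags.
#' @param detected Detected cell table after [assign_markers()].
#' @param channels Marker columns to compare (default the truth table's
#'   channels).
#' @param max_dist_um Matching radius, um.
#' @param min_spacing_um If non-`NULL`, only truth cells whose nearest
#'   truth neighbor is farther than this are scored.
#' @return A list with `n_scored`, `n_recovered` (matched with all flags
#'   correct), and `recovery` (their ratio).
#' @export
recovery_stats <- function(truth, detected,
                           channels = attr(truth, "channels"),
                           max_dist_um = 2, min_spacing_um = NULL) {
  scored <- truth
  if (!is.null(min_spacing_um) && nrow(truth) > 1) {
    d <- sqrt(outer(truth$x_um, truth$x_um, "-")^2 +
              outer(truth$y_um, truth$y_um, "-")^2)
    diag(d) <- Inf
    scored <- keep_cell_attrs(truth[apply(d, 1, min) > min_spacing_um, ,
                                    drop = FALSE], truth)
  }
  if (nrow(scored) == 0) {
    return(list(n_scored = 0L, n_recovered = 0L, recovery = NA_real_))
  }
  m <- match_cells(scored, detected, max_dist_um)
  ok <- logical(nrow(scored))
  for (i in seq_len(nrow(scored))) {
    if (is.na(m$detected_id[i])) next
    det_row <- detected[detected$id == m$detected_id[i], , drop = FALSE]
    ok[i] <- all(vapply(channels, function(ch) {
      isTRUE(as.logical(det_row[[ch]]) == as.logical(scored[[ch]][i]))
    }, TRUE))
  }
  list(n_scored = nrow(scored), n_recovered = sum(ok),
       recovery = mean(ok))
}
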