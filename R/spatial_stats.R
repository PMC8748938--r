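# Fixed-radius Euclidean proximity statistics between phenotype groups:
# the pipeline's core computation. The pairing threshold is closed
# (distance <= radius); ties at exactly the radius are measure-zero for
# continuous coordinates, so the convention is documented, not
# consequential. Throughout, "uM"/"um" denote micrometers.

#' All anchor-partner pairs within a radius
#'
#' Returns exactly the cross-group pairs whose centroid-to-centroid
#' Euclidean distance is at most `radius_um` (closed threshold). A cell
#' occurring in both groups (same id) never pairs with itself. Implemented
#' with a grid-bucket spatial index of cell size `radius_um`, so only the
#' 3x3 bucket neighborhood of each anchor is scanned.
#'
#' @param anchors,partners [cell_table()] subsets (e.g. from
#'   [cells_where()]) in the same coordinate frame.
#' @param radius_um Pairing radius in micrometers (> 0).
#' @return An object of class `pair_set`: a data frame with columns
#'   `anchor_id`, `partner_id`, `distance_um`, sorted by anchor then
#'   partner, with attribute `radius_um`.
#' @export
pairs_within_radius <- function(anchors, partners, radius_um) {
  if (!is.numeric(radius_um) || radius_um <= 0 || !is.finite(radius_um)) {
    stop("`radius_um` must be positive and finite", call. = FALSE)
  }
  ax <- anchors$x_um; ay <- anchors$y_um; aid <- anchors$id
  px <- partners$x_um; py <- partners$y_um; pid <- partners$id

  empty <- data.frame(anchor_id = integer(0), partner_id = integer(0),
                      distance_um = numeric(0))
  if (length(ax) == 0 || length(px) == 0) {
    return(structure(empty, radius_um = radius_um,
                     class = c("pair_set", "data.frame")))
  }

  ox <- min(ax, px); oy <- min(ay, py)
  bx_a <- floor((ax - ox) / radius_um); by_a <- floor((ay - oy) / radius_um)
  bx_p <- floor((px - ox) / radius_um); by_p <- floor((py - oy) / radius_um)
  nbx <- as.integer(max(bx_a, bx_p)) + 2L
  key_p <- as.integer(bx_p + nbx * by_p)
  part_by_bucket <- split(seq_along(px), key_p)

  out <- vector("list", 0)
  anch_by_bucket <- split(seq_along(ax), as.integer(bx_a + nbx * by_a))
  for (bk in names(anch_by_bucket)) {
    ai <- anch_by_bucket[[bk]]
    b <- as.integer(bk)
    bx <- b %% nbx; by <- b %/% nbx
    cand_keys <- as.integer(outer(bx + (-1:1), nbx * (by + (-1:1)), "+"))
    cand <- unlist(part_by_bucket[as.character(cand_keys)], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0) next
    d2 <- outer(ax[ai], px[cand], "-")^2 + outer(ay[ai], py[cand], "-")^2
    hit <- which(d2 <= radius_um^2, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    a_idx <- ai[hit[, 1]]
    p_idx <- cand[hit[, 2]]
    keep <- aid[a_idx] != pid[p_idx]  # no self-pairs
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      anchor_id = aid[a_idx[keep]],
      partner_id = pid[p_idx[keep]],
      distance_um = sqrt(d2[hit][keep]))
  }
  pairs <- if (length(out) == 0) empty else do.call(rbind, out)
  pairs <- pairs[order(pairs$anchor_id, pairs$partner_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs, radius_um = radius_um,
            class = c("pair_set", "data.frame"))
}

#' Per-anchor unique-neighbor counts and mean pair distance
#'
#' Summarizes a [pairs_within_radius()] result: for every anchor (including
#' anchors with no partner in range, which report 0) the number of distinct
#' partner cells within the radius, plus the mean distance over all pairs.
#'
#' @param pairs A `pair_set`.
#' @param anchor_ids Ids of the full anchor universe; must contain every
#'   anchor occurring in `pairs`.
#' @param partner_ids Optional ids of the partner universe (used only for
#'   the reported group size).
#' @return An object of class `neighbor_summary`: a list with `per_anchor`
#'   (data frame `id`, `n_unique_partners`), `mean_pair_distance_um`
#'   (`NA` when there are no pairs), `n_pairs`, `n_anchors`, `n_partners`.
#' @export
neighbor_summary <- function(pairs, anchor_ids, partner_ids = NULL) {
  stray <- setdiff(unique(pairs$anchor_id), anchor_ids)
  if (length(stray) > 0) {
    stop("pair anchors missing from the anchor universe: ",
         paste(utils::head(stray, 10), collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(pairs$anchor_id, levels = anchor_ids))
  per_anchor <- data.frame(id = anchor_ids,
                           n_unique_partners = as.integer(counts))
  structure(list(
    per_anchor = per_anchor,
    mean_pair_distance_um = if (nrow(pairs) == 0) NA_real_
                            else mean(pairs$distance_um),
    n_pairs = nrow(pairs),
    n_anchors = length(anchor_ids),
    n_partners = if (is.null(partner_ids)) length(unique(pairs$partner_id))
                 else length(partner_ids),
    radius_um = attr(pairs, "radius_um")
  ), class = "neighbor_summary")
}

#' @export
print.neighbor_summary <- function(x, ...) {
  cat(sprintf(
    "<neighbor_summary> %d anchors, %d partners, %d pairs within %g um\n",
    x$n_anchors, x$n_partners, x$n_pairs, x$radius_um))
  cat(sprintf("  mean unique partners/anchor: %.3f; mean pair distance: %s um\n",
              mean(x$per_anchor$n_unique_partners),
              format(x$mean_pair_distance_um, digits = 4)))
  invisible(x)
}

#' Proximity analysis between two phenotype groups
#'
#' Convenience wrapper: subsets a classified cell table to anchor and
#' partner phenotypes, pairs them within `radius_um` and summarizes.
#'
#' @param cells A classified [cell_table()].
#' @param anchor_phenotype,partner_phenotype Phenotype (or marker) column
#'   names.
#' @param radius_um Pairing radius, default 50 um.
#' @return A `neighbor_summary`.
#' @export
proximity_summary <- function(cells, anchor_phenotype, partner_phenotype,
                              radius_um = 50) {
  anchors <- cells_where(cells, anchor_phenotype)
  partners <- cells_where(cells, partner_phenotype)
  pairs <- pairs_within_radius(anchors, partners, radius_um)
  neighbor_summary(pairs, anchors$id, partners$id)
}

#' Phenotype-conditional marker fractions across images
#'
#' For each image, computes the fraction of `marker`-positive cells inside
#' two phenotype groups (e.g. the percentage of MHCI+ cells among
#' PGRN+PanCK+ vs PGRN-PanCK+ tumor cells), then compares the per-image
#' fractions between the groups with a two-tailed Mann-Whitney test.
#' Images where a group is empty contribute `NA` for that group's fraction
#' and are excluded from that group's test sample.
#'
#' @param images A list of classified [cell_table()]s, one per image, or a
#'   single cell table (treated as one image; no across-image test then
#'   unless `length(images) > 1`).
#' @param group_a,group_b Phenotype column names.
#' @param marker Marker column whose positive fraction is computed.
#' @return A list with `per_image` (data frame `image`, `frac_a`,
#'   `frac_b`, `n_a`, `n_b`) and `comparison` (a `group_comparison` from
#'   [mann_whitney_two_tailed()], or `NULL` with fewer than one image per
#'   group).
#' @export
conditional_marker_fraction <- function(images, group_a, group_b, marker) {
  if (inherits(images, "cell_table")) images <- list(images)
  frac_in <- function(cells, group) {
    g <- cells[as.logical(cells[[group]]), , drop = FALSE]
    c(n = nrow(g),
      frac = if (nrow(g) == 0) NA_real_ else mean(as.logical(g[[marker]])))
  }
  per_image <- do.call(rbind, lapply(seq_along(images), function(i) {
    cells <- images[[i]]
    for (col in c(group_a, group_b, marker)) {
      if (!col %in% names(cells)) {
        stop("image ", i, " lacks column: ", col, call. = FALSE)
      }
    }
    a <- frac_in(cells, group_a)
    b <- frac_in(cells, group_b)
    data.frame(image = i, frac_a = a["frac"], frac_b = b["frac"],
               n_a = a["n"], n_b = b["n"], row.names = NULL)
  }))
  fa <- per_image$frac_a[!is.na(per_image$frac_a)]
  fb <- per_image$frac_b[!is.na(per_image$frac_b)]
  if (length(fa) == 0) stop("group '", group_a, "' empty in every image",
                            call. = FALSE)
  if (length(fb) == 0) stop("group '", group_b, "' empty in every image",
                            call. = FALSE)
  cmp <- mann_whitney_two_tailed(fa, fb)
  list(per_image = per_image, comparison = cmp)
}
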