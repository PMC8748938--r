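# Image-to-cell-table stage: intensity thresholding, nucleus (DAPI)
# connected-component detection, and per-cell marker positivity from
# overlapping mask regions.

#' Threshold an intensity image into a binary mask
#'
#' A pixel is positive when its intensity is greater than or equal to the
#' threshold. `threshold = "otsu"` selects the threshold maximizing the
#' between-class variance over the exact histogram of observed values.
#'
#' @param image Numeric matrix of finite, non-negative intensities.
#' @param threshold A numeric cutoff, or `"otsu"`.
#' @param pixel_size_um Micrometers per pixel of the resulting mask.
#' @return A [binary_mask()].
#' @export
threshold_channel <- function(image, threshold = "otsu", pixel_size_um = 1) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(image)) || any(image < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (identical(threshold, "otsu")) {
    threshold <- otsu_threshold(image)
  } else if (!is.numeric(threshold) || length(threshold) != 1L) {
    stop("`threshold` must be a single number or \"otsu\"", call. = FALSE)
  }
  binary_mask(image >= threshold, pixel_size_um)
}

# Between-class variance maximization over the exact value histogram.
# Candidate thresholds are the observed levels; the mask splits into
# {< t} vs {>= t} consistent with threshold_channel's convention.
otsu_threshold <- function(image) {
  v <- sort(unique(as.vector(image)))
  if (length(v) < 2) {
    stop("constant image: Otsu threshold undefined (no separable classes)",
         call. = FALSE)
  }
  counts <- tabulate(match(as.vector(image), v), nbins = length(v))
  n <- sum(counts)
  cum_n <- cumsum(counts)
  cum_s <- cumsum(counts * v)
  total <- cum_s[length(v)]
  # split after level k: class0 = levels 1..k, class1 = rest
  k <- seq_len(length(v) - 1L)
  w0 <- cum_n[k] / n
  w1 <- 1 - w0
  mu0 <- cum_s[k] / cum_n[k]
  mu1 <- (total - cum_s[k]) / (n - cum_n[k])
  between <- w0 * w1 * (mu0 - mu1)^2
  best <- which.max(between)
  v[best + 1L]  # threshold value: smallest level of the upper class
}

#' Detect cells as connected components of a nuclear mask
#'
#' Each connected component of the (DAPI) mask becomes one cell, marked at
#' the component centroid; components below `min_area_px` pixels are
#' discarded. Centroids are reported in micrometers with the pixel-center
#' convention `(mean 0-based index + 0.5) * pixel_size_um` per axis. Ids
#' follow the raster-scan (row-major) order in which components are first
#' encountered. Touching nuclei are not split (no instance segmentation).
#'
#' @param dapi A [binary_mask()] of the nuclear channel.
#' @param min_area_px Minimum component area in pixels (default 4).
#' @param connectivity Pixel adjacency: 8 (default, includes diagonals)
#'   or 4.
#' @return A [cell_table()] with no marker columns; the nucleus pixel
#'   footprints are kept in the `footprints` attribute (a list of
#'   matrix-index vectors) for later marker assignment, along with the
#'   mask `shape` and `pixel_size_um`.
#' @export
detect_cells <- function(dapi, min_area_px = 4, connectivity = 8) {
  if (!inherits(dapi, "binary_mask")) {
    stop("`dapi` must be a binary_mask", call. = FALSE)
  }
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  grid <- dapi$grid
  ps <- dapi$pixel_size_um
  lab <- label_components(grid, connectivity)
  n_comp <- lab$n
  empty <- cell_table(
    data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0)),
    channels = character(0))
  if (n_comp == 0) {
    attr(empty, "footprints") <- list()
    attr(empty, "mask_shape") <- dim(grid)
    attr(empty, "pixel_size_um") <- ps
    return(empty)
  }

  idx <- lab$pixel_index           # column-major indices of TRUE pixels
  memb <- lab$membership           # component id per TRUE pixel
  nr <- nrow(grid)
  row1 <- ((idx - 1L) %% nr) + 1L  # 1-based
  col1 <- ((idx - 1L) %/% nr) + 1L

  # order components by first raster-scan (row-major) encounter
  rm_lin <- (row1 - 1L) * ncol(grid) + (col1 - 1L)
  first_seen <- tapply(rm_lin, memb, min)
  ord <- order(first_seen)
  new_id <- integer(n_comp)
  new_id[as.integer(names(first_seen))[ord]] <- seq_len(n_comp)
  memb <- new_id[memb]

  memb_f <- factor(memb, levels = seq_len(n_comp))
  area <- tabulate(memb, nbins = n_comp)
  cx <- tapply(col1 - 1L, memb_f, mean)   # mean 0-based col index
  cy <- tapply(row1 - 1L, memb_f, mean)
  keep <- which(area >= min_area_px)
  if (length(keep) == 0) {
    attr(empty, "footprints") <- list()
    attr(empty, "mask_shape") <- dim(grid)
    attr(empty, "pixel_size_um") <- ps
    return(empty)
  }

  df <- data.frame(
    id = seq_along(keep),
    x_um = (as.numeric(cx[keep]) + 0.5) * ps,
    y_um = (as.numeric(cy[keep]) + 0.5) * ps,
    area_px = area[keep]
  )
  footprints <- split(idx, memb_f)[keep]
  names(footprints) <- NULL
  cells <- cell_table(df, channels = character(0))
  attr(cells, "footprints") <- footprints
  attr(cells, "mask_shape") <- dim(grid)
  attr(cells, "pixel_size_um") <- ps
  cells
}

# Connected-component labelling via the pixel-adjacency graph
# (igraph::components). Returns TRUE-pixel column-major indices and their
# component membership.
label_components <- function(grid, connectivity = 8) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  idx <- which(grid)
  if (length(idx) == 0) {
    return(list(n = 0L, pixel_index = integer(0), membership = integer(0)))
  }
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) {
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  }
  row1 <- ((idx - 1L) %% nr) + 1L
  col1 <- ((idx - 1L) %/% nr) + 1L
  edges <- vector("list", length(shifts))
  for (s in seq_along(shifts)) {
    dr <- shifts[[s]][1]
    dc <- shifts[[s]][2]
    r2 <- row1 + dr
    c2 <- col1 + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    src <- idx[ok]
    both <- grid[nb]
    edges[[s]] <- cbind(vid[src[both]], vid[nb[both]])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)
  list(n = comp$no, pixel_index = idx,
       membership = as.integer(comp$membership))
}

#' Rule for converting mask overlap into marker positivity
#'
#' The region captured for a cell is its nucleus footprint dilated by
#' `dilation_um` (cytoplasmic/membranous markers such as PanCK, CD8 or
#' PGRN extend beyond the nucleus). A marker is called positive when the
#' marker-positive fraction of the captured region reaches
#' `min_overlap_fraction`; with the default `NULL`, any overlap of at
#' least one pixel counts.
#'
#' @param dilation_um Capture distance around the nucleus, um (>= 0).
#' @param min_overlap_fraction Minimum positive fraction in (0, 1], or
#'   `NULL` for the one-pixel rule.
#' @return An object of class `overlap_rule`.
#' @export
overlap_rule <- function(dilation_um = 3, min_overlap_fraction = NULL) {
  if (dilation_um < 0) stop("`dilation_um` must be >= 0", call. = FALSE)
  if (!is.null(min_overlap_fraction) &&
      (min_overlap_fraction <= 0 || min_overlap_fraction > 1)) {
    stop("`min_overlap_fraction` must be in (0, 1]", call. = FALSE)
  }
  structure(list(dilation_um = dilation_um,
                 min_overlap_fraction = min_overlap_fraction),
            class = "overlap_rule")
}

#' Assign per-cell marker positivity from overlapping mask regions
#'
#' For every marker channel of the stack (DAPI is never a marker), a cell
#' is scored by the overlap between the channel mask and the cell's
#' captured region under `rule`. Cells detected by [detect_cells()] use
#' their nucleus pixel footprint; cells without footprints (e.g. read from
#' CSV) fall back to a disk of radius `rule$dilation_um` around the
#' centroid.
#'
#' @param cells A [cell_table()].
#' @param stack A [mask_stack()] co-registered with the cells.
#' @param rule An [overlap_rule()].
#' @param channels Channels to assign; defaults to all stack channels
#'   except `DAPI`.
#' @return The cell table with one logical column per channel.
#' @export
assign_markers <- function(cells, stack, rule = overlap_rule(),
                           channels = setdiff(names(stack$channels), "DAPI")) {
  missing_ch <- setdiff(channels, names(stack$channels))
  if (length(missing_ch) > 0) {
    stop("channel(s) missing from stack: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  ps <- stack$pixel_size_um
  shape <- dim(stack$channels[[1]])
  nr <- shape[1]
  footprints <- attr(cells, "footprints")
  n <- nrow(cells)

  # disc of pixel offsets within dilation_um (pixel-center distance)
  r_px <- rule$dilation_um / ps
  span <- floor(r_px)
  offs <- expand.grid(dr = -span:span, dc = -span:span)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r_px^2, , drop = FALSE]

  captured <- vector("list", n)
  for (k in seq_len(n)) {
    if (!is.null(footprints) && length(footprints) >= k &&
        length(footprints[[k]]) > 0) {
      fp <- footprints[[k]]
      r1 <- ((fp - 1L) %% nr) + 1L
      c1 <- ((fp - 1L) %/% nr) + 1L
    } else {
      # centroid fallback: nucleus unknown, capture a disk around the point
      jc <- round(cells$x_um[k] / ps - 0.5)
      ic <- round(cells$y_um[k] / ps - 0.5)
      r1 <- ic + 1L
      c1 <- jc + 1L
    }
    rr <- as.vector(outer(r1, offs$dr, "+"))
    cc <- as.vector(outer(c1, offs$dc, "+"))
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= shape[2]
    captured[[k]] <- unique((cc[ok] - 1L) * nr + rr[ok])
  }

  for (ch in channels) {
    mask <- stack$channels[[ch]]
    flag <- logical(n)
    for (k in seq_len(n)) {
      cap <- captured[[k]]
      if (length(cap) == 0) next
      ov <- sum(mask[cap])
      flag[k] <- if (is.null(rule$min_overlap_fraction)) ov >= 1
                 else (ov / length(cap)) >= rule$min_overlap_fraction
    }
    cells[[ch]] <- flag
  }
  attr(cells, "channels") <- union(attr(cells, "channels"), channels)
  keep <- keep_cell_attrs(cells, cells)
  attr(keep, "footprints") <- footprints
  attr(keep, "mask_shape") <- attr(cells, "mask_shape")
  attr(keep, "pixel_size_um") <- attr(cells, "pixel_size_um")
  keep
}

#' Fraction of cells positive for a marker
#'
#' The whole-section positivity contract: positive cells over all detected
#' cells (cell denominator anchored on nuclear staining).
#'
#' @param cells A non-empty [cell_table()] with the marker flag present.
#' @param marker Marker (or phenotype) column name.
#' @return A fraction in \[0, 1\].
#' @export
positive_fraction <- function(cells, marker) {
  if (nrow(cells) == 0) {
    stop("cannot compute a positive fraction of zero cells", call. = FALSE)
  }
  if (!marker %in% names(cells)) {
    stop("marker flag not present: ", marker, call. = FALSE)
  }
  flags <- as.logical(cells[[marker]])
  if (anyNA(flags)) stop("marker flag contains NA", call. = FALSE)
  mean(flags)
}
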