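# Binary raster containers. Convention used throughout: x runs along
# columns, y along rows (y grows downward), pixel indices are 0-based in
# formulas, and a pixel's center sits at (index + 0.5) * pixel_size_um.

#' Construct a binary mask
#'
#' @param grid Logical matrix (rows = y, cols = x).
#' @param pixel_size_um Micrometers per pixel (> 0).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, pixel_size_um) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix", call. = FALSE)
  if (!is.logical(grid)) {
    storage.mode(grid) <- "logical"
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be positive", call. = FALSE)
  }
  structure(list(grid = grid, pixel_size_um = pixel_size_um),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px @ %g um/px, %d positive\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size_um, sum(x$grid)))
  invisible(x)
}

#' Construct a stack of co-registered channel masks
#'
#' All channels must share shape and pixel size (the channels are
#' co-registered rasters of one tissue field).
#'
#' @param channels Named list of logical matrices (or `binary_mask`
#'   objects), one per channel; must include any channel later used for
#'   cell detection (typically `DAPI`).
#' @param pixel_size_um Shared micrometers per pixel.
#' @return An object of class `mask_stack`.
#' @export
mask_stack <- function(channels, pixel_size_um) {
  if (is.null(names(channels)) || any(names(channels) == "")) {
    stop("channels must be named", call. = FALSE)
  }
  channels <- lapply(channels, function(ch) {
    if (inherits(ch, "binary_mask")) ch <- ch$grid
    if (!is.matrix(ch)) stop("each channel must be a matrix", call. = FALSE)
    storage.mode(ch) <- "logical"
    ch
  })
  shapes <- vapply(channels, dim, integer(2))
  if (ncol(shapes) > 1 && any(shapes != shapes[, 1])) {
    stop("all channels must share the same shape", call. = FALSE)
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<mask_stack> %d channels (%s), %d x %d px @ %g um/px\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], x$pixel_size_um))
  invisible(x)
}

#' Extract one channel of a mask stack as a binary mask
#'
#' @param stack A `mask_stack`.
#' @param name Channel name.
#' @return A `binary_mask`.
#' @export
get_channel <- function(stack, name) {
  if (!name %in% names(stack$channels)) {
    stop("channel not in stack: ", name, call. = FALSE)
  }
  binary_mask(stack$channels[[name]], stack$pixel_size_um)
}

#' Rasterize a cell table into binary channel masks
#'
#' Renders the DAPI channel as the union of disks of radius
#' `render$r_nucleus_um` at every cell, and one channel per marker as the
#' union of disks of radius `render$r_marker_um` at the cells positive for
#' that marker. A pixel is set when its center lies within the disk radius
#' of a cell position.
#'
#' @param cells A [cell_table()].
#' @param render A [render_config()]; when `image_shape_px` is `NULL` the
#'   shape is `ceiling(window_um / pixel_size_um)`.
#' @param window_um Coordinate window; defaults to the table's attribute.
#' @return A [mask_stack()] with a `DAPI` channel plus one channel per
#'   marker in `attr(cells, "channels")`.
#' @export
render_masks <- function(cells, render = render_config(),
                         window_um = attr(cells, "window_um")) {
  ps <- render$pixel_size_um
  shape <- render$image_shape_px
  if (is.null(shape)) {
    if (is.null(window_um)) {
      stop("no image shape and no window to derive it from", call. = FALSE)
    }
    shape <- c(ceiling(window_um[2] / ps), ceiling(window_um[1] / ps))
  }
  xmax <- shape[2] * ps
  ymax <- shape[1] * ps
  bad <- cells$x_um < 0 | cells$x_um > xmax | cells$y_um < 0 | cells$y_um > ymax
  if (any(bad)) {
    stop("cells outside the rendered field: ids ",
         paste(utils::head(cells$id[bad], 10), collapse = ", "),
         call. = FALSE)
  }

  channels <- attr(cells, "channels")
  out <- vector("list", length(channels) + 1L)
  names(out) <- c("DAPI", channels)
  out[["DAPI"]] <- stamp_disks(cells$x_um, cells$y_um,
                               render$r_nucleus_um, ps, shape)
  for (ch in channels) {
    r <- if (length(render$r_marker_um) > 1) render$r_marker_um[[ch]]
         else render$r_marker_um
    pos <- as.logical(cells[[ch]])
    out[[ch]] <- stamp_disks(cells$x_um[pos], cells$y_um[pos], r, ps, shape)
  }
  mask_stack(out, ps)
}

# Union of disks: pixel (i, j) (0-based) is set when its center
# ((j + 0.5) ps, (i + 0.5) ps) lies within r of some (x, y).
stamp_disks <- function(x, y, r, ps, shape) {
  grid <- matrix(FALSE, nrow = shape[1], ncol = shape[2])
  if (length(x) == 0) return(grid)
  for (k in seq_along(x)) {
    j0 <- max(0L, floor((x[k] - r) / ps - 0.5))
    j1 <- min(shape[2] - 1L, ceiling((x[k] + r) / ps - 0.5))
    i0 <- max(0L, floor((y[k] - r) / ps - 0.5))
    i1 <- min(shape[1] - 1L, ceiling((y[k] + r) / ps - 0.5))
    if (j1 < j0 || i1 < i0) next
    jj <- j0:j1
    ii <- i0:i1
    cx <- (jj + 0.5) * ps
    cy <- (ii + 0.5) * ps
    inside <- outer((cy - y[k])^2, (cx - x[k])^2, "+") <= r^2
    block <- grid[ii + 1L, jj + 1L, drop = FALSE]
    grid[ii + 1L, jj + 1L] <- block | inside
  }
  grid
}

#' Write / read a mask stack as per-channel PNGs with a JSON sidecar
#'
#' Each channel is stored as a 1-bit-equivalent grayscale PNG named
#' `<channel>.png`; `stack.json` records the pixel size and channel order.
#'
#' @param stack A `mask_stack`.
#' @param dir Directory to write into (created if needed) / read from.
#' @return `read_mask_stack()` returns a `mask_stack`; `write_mask_stack()`
#'   returns `dir` invisibly.
#' @export
write_mask_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(stack$channels)) {
    png::writePNG(stack$channels[[ch]] * 1,
                  file.path(dir, paste0(ch, ".png")))
  }
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um,
         channels = names(stack$channels)),
    file.path(dir, "stack.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_mask_stack
#' @export
read_mask_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  channels <- lapply(meta$channels, function(ch) {
    img <- png::readPNG(file.path(dir, paste0(ch, ".png")))
    if (length(dim(img)) == 3) img <- img[, , 1]
    img > 0.5
  })
  names(channels) <- meta$channels
  mask_stack(channels, meta$pixel_size_um)
}
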