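# Central exchange object: point-referenced cells in um with logical marker
# flags, optional phenotype columns, and (for simulated tissue) the
# ground-truth compartment.

#' Default marker channel names
#'
#' The fluorescent marker channels of the default panel, excluding the
#' nuclear counterstain (DAPI), which anchors cells but is never a marker
#' flag. The same table serves other panels (e.g. mouse H-2Db for MHCI) by
#' renaming channels.
#' @return Character vector of channel names.
#' @export
default_channels <- function() c("PanCK", "PGRN", "MHCI", "CD8", "GzmB")

#' Construct a cell table
#'
#' @param df Data frame with columns `id`, `x_um`, `y_um`, one logical (or
#'   0/1) column per marker channel, and optionally `compartment`.
#' @param window_um Optional (width, height) of the coordinate window, um.
#'   When given, coordinates are checked to lie inside it.
#' @param channels Character vector of marker channel names present.
#' @return A data frame of class `cell_table` carrying `window_um`,
#'   `channels` and `phenotypes` attributes.
#' @export
cell_table <- function(df, window_um = NULL, channels = default_channels()) {
  df <- as.data.frame(df)
  needed <- c("id", "x_um", "y_um")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("cell table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$id)) stop("cell ids must be unique", call. = FALSE)
  channels <- intersect(channels, names(df))
  for (ch in channels) df[[ch]] <- as.logical(df[[ch]])
  if (!is.null(window_um)) {
    bad <- df$x_um < 0 | df$x_um > window_um[1] |
           df$y_um < 0 | df$y_um > window_um[2]
    if (any(bad)) {
      stop("cells outside the declared window: ids ",
           paste(utils::head(df$id[bad], 10), collapse = ", "), call. = FALSE)
    }
  }
  structure(df,
            window_um = window_um,
            channels = channels,
            phenotypes = character(0),
            class = c("cell_table", "data.frame"))
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells, channels: %s\n",
              nrow(x), paste(attr(x, "channels"), collapse = ", ")))
  phen <- attr(x, "phenotypes")
  if (length(phen) > 0) {
    cat("  phenotypes: ", paste(phen, collapse = ", "), "\n", sep = "")
  }
  NextMethod()
}

#' Write / read a cell table as CSV
#'
#' Marker and phenotype flags are written as 0/1 columns. The window is not
#' stored in the CSV; supply it on read if downstream code needs it.
#'
#' @param cells A `cell_table`.
#' @param path Output / input CSV path.
#' @param window_um Optional window to attach on read.
#' @param channels Marker channel names to interpret as logical on read;
#'   defaults to the intersection of [default_channels()] with the header.
#' @return `read_cells()` returns a `cell_table`; `write_cells()` returns
#'   `path` invisibly.
#' @export
write_cells <- function(cells, path) {
  out <- as.data.frame(cells)
  flags <- c(attr(cells, "channels"), attr(cells, "phenotypes"))
  for (ch in flags) out[[ch]] <- as.integer(out[[ch]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path, window_um = NULL, channels = default_channels()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cell_table(df, window_um = window_um,
             channels = intersect(channels, names(df)))
}

#' Subset a cell table to a phenotype or marker flag
#'
#' @param cells A `cell_table` with the flag column present.
#' @param flag Name of a logical phenotype or marker column.
#' @return The `cell_table` rows where the flag is `TRUE`.
#' @export
cells_where <- function(cells, flag) {
  if (!flag %in% names(cells)) {
    stop("no such flag column: ", flag, call. = FALSE)
  }
  keep_cell_attrs(cells[as.logical(cells[[flag]]), , drop = FALSE], cells)
}

# data.frame subsetting drops custom attributes; restore them
keep_cell_attrs <- function(df, template) {
  structure(as.data.frame(df),
            window_um = attr(template, "window_um"),
            channels = attr(template, "channels"),
            phenotypes = attr(template, "phenotypes"),
            class = c("cell_table", "data.frame"))
}
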