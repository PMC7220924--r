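#' Construct a regular raster grid
#'
#' Minimal in-memory raster: a numeric matrix plus origin, pixel size and a
#' CRS label. Row 1 sits at the `ymin` edge; cell centres are at
#' `xmin + (j - 0.5) * dx`, `ymin + (i - 0.5) * dy`.
#'
#' @param values numeric matrix of cell values.
#' @param xmin,ymin coordinates of the grid's lower-left corner.
#' @param dx,dy pixel size along x (columns) and y (rows); must be positive.
#' @param crs free-text CRS label; grids only interoperate when labels match.
#' @return an object of class `rwlr_grid`.
#' @export
new_grid <- function(values, xmin = 0, ymin = 0, dx = 1, dy = 1, crs = "local") {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (dx <= 0 || dy <= 0) stop_rwlr("parameter", "pixel sizes dx, dy must be positive")
  structure(list(values = values, xmin = xmin, ymin = ymin, dx = dx, dy = dy,
                 crs = crs),
            class = "rwlr_grid")
}

grid_centres <- function(g) {
  list(x = g$xmin + (seq_len(ncol(g$values)) - 0.5) * g$dx,
       y = g$ymin + (seq_len(nrow(g$values)) - 0.5) * g$dy)
}

#' Nearest-neighbour resampling between aligned grids
#'
#' Each target cell takes the value of the source cell whose centre is
#' nearest to the target cell centre. No interpolation: the output value set
#' is a subset of the input value set, which is the property that makes
#' nearest-neighbour the standard choice for co-registering categorical or
#' index rasters (e.g. 500 m NDVI onto a 1 km temperature grid).
#'
#' @param src source `rwlr_grid`.
#' @param target an `rwlr_grid` (its values are ignored) or a list with
#'   fields `nrow`, `ncol`, `xmin`, `ymin`, `dx`, `dy` and optionally `crs`.
#' @return an `rwlr_grid` with the target geometry and resampled values.
#' @export
resample_nearest <- function(src, target) {
  if (!inherits(src, "rwlr_grid")) stop_rwlr("interface", "src must be an rwlr_grid")
  if (inherits(target, "rwlr_grid")) {
    tg <- target
    tnr <- nrow(tg$values); tnc <- ncol(tg$values)
  } else {
    tg <- target
    tg$crs <- tg$crs %||% src$crs
    tnr <- tg$nrow; tnc <- tg$ncol
  }
  if (!identical(src$crs, tg$crs))
    stop_rwlr("interface", sprintf("CRS mismatch: '%s' vs '%s'", src$crs, tg$crs))

  tx <- tg$xmin + (seq_len(tnc) - 0.5) * tg$dx
  ty <- tg$ymin + (seq_len(tnr) - 0.5) * tg$dy
  jj <- pmin(pmax(round((tx - src$xmin) / src$dx + 0.5), 1L), ncol(src$values))
  ii <- pmin(pmax(round((ty - src$ymin) / src$dy + 0.5), 1L), nrow(src$values))
  new_grid(src$values[ii, jj, drop = FALSE], xmin = tg$xmin, ymin = tg$ymin,
           dx = tg$dx, dy = tg$dy, crs = tg$crs)
}

#' Write / read a grid as plain text
#'
#' Serialization is CSV (cell values, no header) plus a JSON sidecar with the
#' geometry, keeping every artifact human-readable and diff-able.
#'
#' @param g an `rwlr_grid`.
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly (`write_grid_csv`); an `rwlr_grid`
#'   (`read_grid_csv`).
#' @export
write_grid_csv <- function(g, path) {
  stopifnot(inherits(g, "rwlr_grid"))
  utils::write.table(g$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- g[c("xmin", "ymin", "dx", "dy", "crs")]
  meta$nrow <- nrow(g$values); meta$ncol <- ncol(g$values)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_grid(vals, xmin = meta$xmin, ymin = meta$ymin, dx = meta$dx,
           dy = meta$dy, crs = meta$crs)
}
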