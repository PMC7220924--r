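#' Fit dry and wet edges of the NDVI / surface-temperature triangle
#'
#' The triangle (trapezoid) method bins pixels by NDVI, takes per-bin
#' temperature extremes, and regresses them on the bin centres: the upper
#' envelope `T_d = a + b * NDVI` is the dry edge (maximal water stress), the
#' lower envelope `T_w = c + d * NDVI` the wet edge. Edges are fitted per
#' scene over the whole scatter (the standard formulation; per-pixel edge
#' estimation is not well defined).
#'
#' Extremes are order statistics (inverse-ECDF quantiles), so
#' `edge_percentile = 1` is exactly the bin maximum and trimmed percentiles
#' discard whole points rather than interpolating.
#'
#' @param ndvi,lst co-registered numeric matrices/vectors (same length).
#' @param n_bins number of equal-width NDVI bins over the observed range
#'   (>= 5).
#' @param edge_percentile order-statistic level for the dry edge, in
#'   `(0.5, 1]`; the wet edge uses `1 - edge_percentile`. Default 1 = max/min.
#' @param min_pixels_per_bin bins with fewer valid pixels are skipped.
#' @param ndvi_min validity floor: pixels with NDVI below this (bare
#'   soil/water/cloud guard) are excluded from fitting.
#' @return a `triangle_edges` object: `a`, `b`, `c`, `d`, `ndvi_range`,
#'   `fit_r2_dry`, `fit_r2_wet`, `n_bins_used`.
#' @export
fit_triangle_edges <- function(ndvi, lst, n_bins = 20, edge_percentile = 1,
                               min_pixels_per_bin = 5, ndvi_min = 0.05) {
  x <- as.vector(ndvi); y <- as.vector(lst)
  if (length(x) != length(y))
    stop_rwlr("interface", "ndvi and lst must be co-registered (same length)")
  if (n_bins < 5) stop_rwlr("parameter", "n_bins must be >= 5")
  if (edge_percentile <= 0.5 || edge_percentile > 1)
    stop_rwlr("parameter", "edge_percentile must lie in (0.5, 1]")
  ok <- is.finite(x) & is.finite(y) & x >= ndvi_min
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 * min_pixels_per_bin)
    stop_rwlr("fit", "too few valid pixels for edge fitting")

  rng <- range(x)
  if (diff(rng) <= 0) stop_rwlr("fit", "NDVI has zero spread; no triangle")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), n_bins)
  centres <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2

  dry <- wet <- rep(NA_real_, n_bins)
  for (j in seq_len(n_bins)) {
    yj <- y[bin == j]
    if (length(yj) < min_pixels_per_bin) next
    dry[j] <- quantile(yj, edge_percentile, type = 1, names = FALSE)
    wet[j] <- quantile(yj, 1 - edge_percentile, type = 1, names = FALSE)
  }
  use <- is.finite(dry)
  if (sum(use) < 2) stop_rwlr("fit", "fewer than 2 usable NDVI bins")

  line_fit <- function(cx, cy) {
    X <- cbind(1, cx)
    beta <- solve(crossprod(X), crossprod(X, cy))
    res <- cy - X %*% beta
    tss <- sum((cy - mean(cy))^2)
    r2 <- if (tss < .Machine$double.eps) 1 else 1 - sum(res^2) / tss
    list(icpt = beta[1], slope = beta[2], r2 = max(min(r2, 1), 0))
  }
  fd <- line_fit(centres[use], dry[use])
  fw <- line_fit(centres[use], wet[use])

  edges <- structure(list(a = fd$icpt, b = fd$slope, c = fw$icpt,
                          d = fw$slope, ndvi_range = rng,
                          fit_r2_dry = fd$r2, fit_r2_wet = fw$r2,
                          n_bins_used = sum(use)),
                     class = "triangle_edges")
  sep <- edge_separation(edges, rng)
  if (any(sep <= 0))
    stop_rwlr("degenerate",
              "degenerate triangle: fitted dry edge does not exceed wet edge")
  edges
}

edge_separation <- function(edges, at) {
  (edges$a + edges$b * at) - (edges$c + edges$d * at)
}

#' Compute the Temperature Vegetation Dryness Index
#'
#' `TVDI = (T_obs - T_w) / (T_d - T_w)` evaluated per pixel with the edge
#' lines at that pixel's NDVI. Values are clipped into `[0, 1]` (the index
#' is defined as bounded); the clipped fraction is reported so an
#' over-trimmed triangle is visible. Pixels with missing inputs are NA and
#' flagged invalid; pixels whose NDVI falls outside the edges' fitted range
#' are computed by extrapolation but flagged in `qc_mask`.
#'
#' @param ndvi,lst numeric matrices (or vectors) on a common grid.
#' @param edges a `triangle_edges` object.
#' @param time optional composite timestamp carried through.
#' @param grid optional grid metadata list carried through.
#' @return a `tvdi_scene`: list with `tvdi`, `qc_mask`, `time`,
#'   `clip_fraction`, `grid`.
#' @export
compute_tvdi <- function(ndvi, lst, edges, time = NA, grid = NULL) {
  stopifnot(inherits(edges, "triangle_edges"))
  tdv <- edges$a + edges$b * ndvi
  twv <- edges$c + edges$d * ndvi
  raw <- (lst - twv) / (tdv - twv)
  valid <- is.finite(ndvi) & is.finite(lst)
  in_range <- valid & ndvi >= edges$ndvi_range[1] & ndvi <= edges$ndvi_range[2]
  tvdi <- clip01(raw)
  tvdi[!valid] <- NA_real_
  clip_fraction <- if (any(valid)) mean(raw[valid] < 0 | raw[valid] > 1) else NA_real_
  structure(list(tvdi = tvdi, qc_mask = in_range, time = time,
                 clip_fraction = clip_fraction, grid = grid),
            class = "tvdi_scene")
}

#' TVDI scenes for every composite of a synthetic stack
#'
#' @param stack a `scene_stack`.
#' @param edges `"truth"` (use the generator's planted edges), `"pooled"`
#'   (fit one triangle to the scatter pooled over all composites), or a
#'   `triangle_edges` object.
#' @param ... passed to [fit_triangle_edges()] when `edges = "pooled"`.
#' @return list of `tvdi_scene` objects, one per composite, with the edges
#'   used attached as attribute `edges`.
#' @export
stack_tvdi <- function(stack, edges = "pooled", ...) {
  stopifnot(inherits(stack, "scene_stack"))
  if (identical(edges, "truth")) {
    edges <- scene_true_edges(stack)
  } else if (identical(edges, "pooled")) {
    edges <- fit_triangle_edges(as.vector(stack$ndvi), as.vector(stack$lst), ...)
  }
  scenes <- lapply(seq_along(stack$times), function(k)
    compute_tvdi(stack$ndvi[, , k], stack$lst[, , k], edges,
                 time = stack$times[k], grid = stack$grid))
  attr(scenes, "edges") <- edges
  scenes
}
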