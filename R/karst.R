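#' Annual growing-season means from a sub-annual raster series
#'
#' Per pixel and calendar year, the arithmetic mean over observations whose
#' month falls in the growing season (default April-September). Pixel-years
#' with more than `max_missing` of their in-season observations missing are
#' dropped (NA) for that pixel.
#'
#' @param values `nrow x ncol x n_times` array.
#' @param dates Date vector of length `n_times`.
#' @param months integer months defining the season (default `4:9`).
#' @param max_missing maximum tolerated missing fraction per pixel-year
#'   (default 0.5).
#' @return list with `means` (`nrow x ncol x n_years` array) and `years`.
#' @export
growing_season_means <- function(values, dates, months = 4:9,
                                 max_missing = 0.5) {
  stopifnot(length(dates) == dim(values)[3])
  mth <- as.integer(format(dates, "%m"))
  yr <- as.integer(format(dates, "%Y"))
  in_season <- mth %in% months
  years <- sort(unique(yr[in_season]))
  nr <- dim(values)[1]; nc <- dim(values)[2]
  out <- array(NA_real_, c(nr, nc, length(years)))
  for (k in seq_along(years)) {
    idx <- which(in_season & yr == years[k])
    slab <- values[, , idx, drop = FALSE]
    n_obs <- apply(!is.na(slab), c(1, 2), sum)
    m <- apply(slab, c(1, 2), mean, na.rm = TRUE)
    m[n_obs < length(idx) * (1 - max_missing)] <- NA_real_
    m[n_obs == 0] <- NA_real_
    out[, , k] <- m
  }
  if (!any(is.finite(out)))
    stop_rwlr("input", "no complete growing-season year anywhere in the grid")
  list(means = out, years = years)
}

#' Per-pixel Pearson correlation between two annual series
#'
#' Correlates NDVI and temperature across years for every pixel,
#' pixels with fewer than `min_years` complete year-pairs, or zero variance
#' in either series, are masked invalid (with the zero-variance case noted
#' as a mask reason, not an error).
#'
#' @param ndvi,temp `nrow x ncol x years` arrays on a common grid.
#' @param min_years minimum complete year-pairs per pixel (default 3).
#' @return a `correlation_field`: `r` (matrix), `n_years` (matrix),
#'   `valid_mask` (logical matrix).
#' @export
pixel_correlation <- function(ndvi, temp, min_years = 3) {
  stopifnot(all(dim(ndvi) == dim(temp)))
  nr <- dim(ndvi)[1]; nc <- dim(ndvi)[2]; ny <- dim(ndvi)[3]
  X <- matrix(ndvi, nr * nc, ny)
  Y <- matrix(temp, nr * nc, ny)
  ok <- is.finite(X) & is.finite(Y)
  X[!ok] <- 0; Y[!ok] <- 0
  n <- rowSums(ok)
  sx <- rowSums(X); sy <- rowSums(Y)
  sxx <- rowSums(X^2); syy <- rowSums(Y^2); sxy <- rowSums(X * Y)
  vx <- n * sxx - sx^2
  vy <- n * syy - sy^2
  r <- (n * sxy - sx * sy) / sqrt(pmax(vx, 0) * pmax(vy, 0))
  zero_var <- vx <= .Machine$double.eps * pmax(sxx, 1) * n |
              vy <= .Machine$double.eps * pmax(syy, 1) * n
  r[zero_var] <- NA_real_
  valid <- n >= min_years & is.finite(r)
  structure(list(r = matrix(r, nr, nc), n_years = matrix(n, nr, nc),
                 valid_mask = matrix(valid, nr, nc)),
            class = "correlation_field")
}

shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  ri <- seq_len(nr) - di; ci <- seq_len(nc) - dj
  keep_r <- ri >= 1 & ri <= nr; keep_c <- ci >= 1 & ci <= nc
  out[keep_r, keep_c] <- m[ri[keep_r], ci[keep_c]]
  out
}

dilate_binary <- function(m, width, connectivity = 8) {
  offs <- if (connectivity == 8)
    expand.grid(di = -1:1, dj = -1:1) else
    data.frame(di = c(-1, 1, 0, 0, 0), dj = c(0, 0, -1, 1, 0))
  for (w in seq_len(width)) {
    acc <- matrix(FALSE, nrow(m), ncol(m))
    for (i in seq_len(nrow(offs)))
      acc <- acc | shift_mat(m, offs$di[i], offs$dj[i])
    m <- acc
  }
  m
}

erode_binary <- function(m, width, connectivity = 8)
  !dilate_binary(!m, width, connectivity)

#' Inner / outer buffer rings around a binary mask
#'
#' The outer zone is the morphological dilation of the mask minus the mask
#' (pixels within `width_pixels` outside the boundary); the inner zone is
#' the mask minus its erosion (the boundary-symmetric ring inside). The
#' structuring element is 8-connected (queen) by default.
#'
#' @param mask binary matrix (1/TRUE = carbonate).
#' @param width_pixels ring width; 0 returns empty zones.
#' @param connectivity 8 (default) or 4.
#' @param inner_mode `"ring"` (default, boundary-symmetric) or `"full"`
#'   (the whole mask body as the inner zone).
#' @return list with logical matrices `inner` and `outer`, plus the
#'   parameters used.
#' @export
buffer_zones <- function(mask, width_pixels = 1, connectivity = 8,
                         inner_mode = c("ring", "full")) {
  inner_mode <- match.arg(inner_mode)
  m <- mask > 0
  if (!any(m)) stop_rwlr("geometry", "mask is empty")
  if (all(m)) stop_rwlr("geometry", "mask covers the whole grid; no outside")
  if (width_pixels == 0)
    return(list(inner = m & FALSE, outer = m & FALSE,
                width_pixels = 0, connectivity = connectivity))
  outer <- dilate_binary(m, width_pixels, connectivity) & !m
  inner <- if (inner_mode == "full") m
           else m & !erode_binary(m, width_pixels, connectivity)
  list(inner = inner, outer = outer, width_pixels = width_pixels,
       connectivity = connectivity, inner_mode = inner_mode)
}

#' Rank-sum contrast of a correlation field between buffer zones
#'
#' Mann-Whitney-Wilcoxon test of the per-pixel correlations inside vs
#' outside the mask boundary, with zone means and normal-approximation 95%
#' confidence intervals. The test is exact (full rank enumeration) when
#' both zones hold at most 20 valid pixels and there are no ties; larger
#' samples use the normal approximation with tie correction.
#'
#' @param field a `correlation_field`.
#' @param zones output of [buffer_zones()].
#' @param alternative passed to [stats::wilcox.test()] (default two-sided).
#' @param alpha significance level (default 0.05).
#' @param min_n minimum valid pixels per zone (default 5; lower it only for
#'   toy examples).
#' @return a `buffer_contrast`: `inner_mean`, `outer_mean`, `ci95_inner`,
#'   `ci95_outer`, `n_inner`, `n_outer`, `u_stat`, `p_value`, `significant`.
#' @export
compare_zones <- function(field, zones, alternative = "two.sided",
                          alpha = 0.05, min_n = 5) {
  vi <- field$r[zones$inner & field$valid_mask]
  vo <- field$r[zones$outer & field$valid_mask]
  if (length(vi) < min_n || length(vo) < min_n)
    stop_rwlr("sample_size",
              sprintf("each zone needs >= %d valid pixels", min_n))
  use_exact <- max(length(vi), length(vo)) <= 20 &&
    !any(duplicated(c(vi, vo)))
  wt <- suppressWarnings(
    wilcox.test(vi, vo, alternative = alternative, exact = use_exact,
                correct = TRUE))
  ci <- function(v) mean(v) + c(-1, 1) * qnorm(0.975) * sd(v) / sqrt(length(v))
  structure(list(inner_mean = mean(vi), outer_mean = mean(vo),
                 ci95_inner = ci(vi), ci95_outer = ci(vo),
                 n_inner = length(vi), n_outer = length(vo),
                 u_stat = unname(wt$statistic), p_value = wt$p.value,
                 significant = wt$p.value < alpha, alpha = alpha),
            class = "buffer_contrast")
}

#' Karst buffer-zone NDVI-temperature signal test
#'
#' End-to-end wrapper: per-pixel growing-season NDVI-temperature
#' correlation, a desert screen (pixels whose mean NDVI falls below
#' `ndvi_floor` are dropped before zoning), buffer-ring construction around
#' the carbonate mask, and the rank-sum contrast.
#'
#' @param ndvi,temp annual `nrow x ncol x years` arrays (growing-season
#'   means).
#' @param mask binary carbonate mask matrix.
#' @param width_pixels buffer ring width (default 1; one 50-km pixel in the
#'   emulated archive).
#' @param ndvi_floor desert screen on the pixel mean NDVI (default 0.1).
#' @param inner_mode,connectivity see [buffer_zones()].
#' @param alpha significance level.
#' @return list with `contrast` (`buffer_contrast`), `field`
#'   (`correlation_field`) and `zones`.
#' @export
karst_signal <- function(ndvi, temp, mask, width_pixels = 1,
                         ndvi_floor = 0.1, inner_mode = "ring",
                         connectivity = 8, alpha = 0.05) {
  field <- pixel_correlation(ndvi, temp)
  mean_ndvi <- apply(ndvi, c(1, 2), mean, na.rm = TRUE)
  field$valid_mask <- field$valid_mask & mean_ndvi >= ndvi_floor
  zones <- buffer_zones(mask, width_pixels, connectivity, inner_mode)
  contrast <- compare_zones(field, zones, alpha = alpha)
  list(contrast = contrast, field = field, zones = zones)
}
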