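#' Simulate a global grid with a planted karst correlation contrast
#'
#' Builds annual growing-season mean temperature and NDVI series for every
#' pixel of a grid, with the NDVI-temperature correlation set by mask
#' membership: per pixel, `z_ndvi = r * z_temp + sqrt(1 - r^2) * noise`
#' where `r` is `r_inside` on carbonate (mask = 1) pixels and `r_outside`
#' elsewhere. Pixels are independent; both series are affinely rescaled to
#' plausible units (correlation is unchanged by that).
#'
#' @param nrow,ncol grid shape.
#' @param mask optional binary matrix (1 = carbonate); default is a centred
#'   square occupying the middle half of each dimension.
#' @param r_inside,r_outside target correlations, strictly inside (-1, 1).
#' @param years number of annual observations (>= 10); the default 30
#'   matches a 1982-2011 biweekly-archive span.
#' @param seed integer RNG seed.
#' @param temp_mean,temp_sd,ndvi_mean,ndvi_sd affine output scales.
#' @return a `global_grid`: list with `karst_mask` (matrix),
#'   `ndvi_series` and `temp_series` (`nrow x ncol x years` arrays), `years`
#'   and `params`.
#' @export
gen_global_grid <- function(nrow = 40, ncol = 40, mask = NULL,
                            r_inside = -0.2, r_outside = 0.3, years = 30,
                            seed = 1, temp_mean = 15, temp_sd = 2,
                            ndvi_mean = 0.5, ndvi_sd = 0.1) {
  if (abs(r_inside) >= 1 || abs(r_outside) >= 1)
    stop_rwlr("parameter", "target correlations must satisfy |r| < 1")
  if (years < 10) stop_rwlr("parameter", "years must be >= 10")
  if (is.null(mask)) {
    mask <- matrix(0L, nrow, ncol)
    mask[seq(floor(nrow / 4) + 1, floor(3 * nrow / 4)),
         seq(floor(ncol / 4) + 1, floor(3 * ncol / 4))] <- 1L
  }
  stopifnot(all(dim(mask) == c(nrow, ncol)), all(mask %in% c(0, 1)))

  set.seed(seed)
  npx <- nrow * ncol
  r <- ifelse(mask == 1, r_inside, r_outside)
  z_t <- array(rnorm(npx * years), c(nrow, ncol, years))
  eps <- array(rnorm(npx * years), c(nrow, ncol, years))
  rr <- array(rep(r, years), c(nrow, ncol, years))
  z_n <- rr * z_t + sqrt(1 - rr^2) * eps

  structure(list(
    karst_mask = mask,
    ndvi_series = pmin(pmax(ndvi_mean + ndvi_sd * z_n, -1), 1),
    temp_series = temp_mean + temp_sd * z_t,
    years = years,
    params = list(r_inside = r_inside, r_outside = r_outside, seed = seed)
  ), class = "global_grid")
}
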