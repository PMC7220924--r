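#' Simulate co-registered NDVI / surface-temperature composite stacks
#'
#' Forward model for the triangle method. Each pixel carries a soil-moisture
#' bucket driven by the daily precipitation series:
#' \deqn{S_{t+1} = \mathrm{clip}_{[0,1]}\big(S_t + \min(I_t, 1 - S_t) - \lambda_{px} S_t\big)}
#' where \eqn{I_t} is the day's infiltration (precipitation depth scaled by
#' `infil_per_mm`) and \eqn{\lambda_{px}} the pixel's total loss rate
#' (evapotranspiration plus leakage; leakage varies across pixels to mimic
#' the spatial heterogeneity of karst crevice density). During rain-free
#' periods moisture decays geometrically at rate \eqn{\lambda_{px}}, so a
#' larger leakage parameter means strictly faster within-dry-spell drying.
#'
#' The optical coupling places each pixel's temperature between the dry and
#' wet edges of a fixed triangle,
#' `lst = T_d(ndvi) - moisture * (T_d(ndvi) - T_w(ndvi)) + noise`, so the
#' latent ground-truth dryness index is exactly `1 - moisture`.
#'
#' @param precip a `precip_series` from [gen_precip()] (or equivalent).
#' @param leakage baseline leakage loss rate, per day (>= 0).
#' @param et_rate evapotranspiration loss rate, per day (>= 0).
#' @param edges_truth list with dry-edge intercept/slope `a`, `b` and
#'   wet-edge `c`, `d` (temperature in K, slope per NDVI unit); the dry edge
#'   must sit above the wet edge over `ndvi_range`.
#' @param noise_sd sd (K) of additive temperature noise; 0 gives an exact,
#'   invertible scene.
#' @param seed integer RNG seed.
#' @param nrow,ncol grid shape in pixels.
#' @param composite_interval days between composites (nominal 5).
#' @param infil_per_mm bucket fill per mm of rain. The default (0.1, i.e. a
#'   10 mm day refills an empty bucket) keeps buckets near saturation after
#'   wet runs so dry spells start from comparable moisture across leakage
#'   scenarios, isolating the decay-rate signal.
#' @param ndvi_range range of static per-pixel NDVI values.
#' @param ndvi_jitter_sd sd of per-composite NDVI jitter (0 = static NDVI).
#' @param leakage_heterogeneity half-width of the uniform per-pixel leakage
#'   multiplier (multiplier in `1 +/- leakage_heterogeneity`).
#' @param init_moisture optional scalar initial moisture; default draws each
#'   pixel uniformly in `[0.3, 1]`.
#' @return a `scene_stack`: list with `times` (day indices), `dates`, arrays
#'   `ndvi`, `lst`, `moisture_truth` (`nrow x ncol x n_times`),
#'   `moisture_daily` (`nrow x ncol x n_days`), per-pixel `loss_rate`,
#'   daily `infiltration`, `grid` metadata and `params`.
#' @export
gen_scene_stack <- function(precip, leakage = 0.05, et_rate = 0.03,
                            edges_truth = list(a = 320, b = -15, c = 290, d = 0),
                            noise_sd = 0, seed = 1, nrow = 20, ncol = 20,
                            composite_interval = 5, infil_per_mm = 0.1,
                            ndvi_range = c(0.1, 0.9), ndvi_jitter_sd = 0,
                            leakage_heterogeneity = 0.4, init_moisture = NULL) {
  if (leakage < 0 || et_rate < 0)
    stop_rwlr("parameter", "leakage and et_rate must be non-negative")
  e <- edges_truth
  td <- function(x) e$a + e$b * x
  tw <- function(x) e$c + e$d * x
  if (any(td(ndvi_range) <= tw(ndvi_range)))
    stop_rwlr("parameter", "degenerate triangle: T_d <= T_w inside ndvi_range")
  max_loss <- (et_rate + leakage * (1 + leakage_heterogeneity))
  if (max_loss >= 1)
    stop_rwlr("parameter", "total daily loss rate must be < 1")

  n_days <- nrow(precip)
  npx <- nrow * ncol
  set.seed(seed)
  ndvi_base <- matrix(runif(npx, ndvi_range[1], ndvi_range[2]), nrow, ncol)
  mult <- matrix(runif(npx, 1 - leakage_heterogeneity,
                       1 + leakage_heterogeneity), nrow, ncol)
  loss <- et_rate + leakage * mult
  s0 <- if (is.null(init_moisture)) matrix(runif(npx, 0.3, 1), nrow, ncol)
        else matrix(init_moisture, nrow, ncol)

  infil <- precip$precip_mm * infil_per_mm
  S <- array(NA_real_, c(nrow, ncol, n_days))
  cur <- clip01(s0)
  for (t in seq_len(n_days)) {
    cur <- clip01(cur + pmin(infil[t], 1 - cur) - loss * cur)
    S[, , t] <- cur
  }

  times <- seq(1L, n_days, by = composite_interval)
  nt <- length(times)
  moisture <- S[, , times, drop = FALSE]

  ndvi <- array(rep(ndvi_base, nt), c(nrow, ncol, nt))
  if (ndvi_jitter_sd > 0)
    ndvi <- ndvi + array(rnorm(npx * nt, 0, ndvi_jitter_sd), c(nrow, ncol, nt))
  tdv <- td(ndvi); twv <- tw(ndvi)
  lst <- tdv - moisture * (tdv - twv)
  if (noise_sd > 0)
    lst <- lst + array(rnorm(npx * nt, 0, noise_sd), c(nrow, ncol, nt))

  structure(list(
    times = times, dates = precip$date[times],
    ndvi = ndvi, lst = lst, moisture_truth = moisture,
    moisture_daily = S, loss_rate = loss, infiltration = infil,
    grid = list(nrow = nrow, ncol = ncol, xmin = 0, ymin = 0, dx = 1, dy = 1,
                crs = "local"),
    params = list(leakage = leakage, et_rate = et_rate,
                  edges_truth = e, noise_sd = noise_sd, seed = seed,
                  composite_interval = composite_interval,
                  infil_per_mm = infil_per_mm,
                  leakage_heterogeneity = leakage_heterogeneity)
  ), class = "scene_stack")
}

#' True triangle edges of a synthetic scene stack
#'
#' Convenience accessor returning the generator's planted edges as a
#' `triangle_edges` object usable by [compute_tvdi()].
#'
#' @param stack a `scene_stack`.
#' @return a `triangle_edges` object.
#' @export
scene_true_edges <- function(stack) {
  e <- stack$params$edges_truth
  structure(list(a = e$a, b = e$b, c = e$c, d = e$d,
                 ndvi_range = range(stack$ndvi, na.rm = TRUE),
                 fit_r2_dry = 1, fit_r2_wet = 1, n_bins_used = NA_integer_),
            class = "triangle_edges")
}
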