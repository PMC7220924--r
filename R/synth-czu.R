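#' Default path coefficients of the synthetic critical-zone-unit world
#'
#' Coefficients live on the standardized (unit-variance) scale of the
#' structural system, so at `noise_sd = 1` they are exactly the population
#' standardized path coefficients. Magnitudes echo the study system they
#' emulate: a strong positive bedrock-Ca effect on the water loss rate, a
#' dominant negative water-loss effect on productivity with a weaker
#' positive temperature effect (together explaining ~55% of NPP variance),
#' and a strong negative Si-Ca bedrock correlation.
#'
#' @return named list: `rwlr_brca`, `npp_rwlr`, `npp_mat`, `si_ca`.
#' @export
default_czu_betas <- function() {
  list(rwlr_brca = 0.85, npp_rwlr = -0.67, npp_mat = 0.32, si_ca = -0.90)
}

#' Simulate a critical-zone-unit covariate table with known path structure
#'
#' Generates `n` units from the recursive system (on z-scores):
#' \deqn{z_{Si} = si\_ca \cdot z_{Ca} + \epsilon, \quad
#'       z_{RWLR} = rwlr\_brca \cdot z_{Ca} + \epsilon, \quad
#'       z_{NPP} = npp\_rwlr \cdot z_{RWLR} + npp\_mat \cdot z_{MAT} + \epsilon}
#' with residual variances chosen so every endogenous z-score has unit
#' population variance at `noise_sd = 1`. Bedrock Ca is uniform over the
#' observed field range (4.8-74.2 oxide %); MAT is standard normal rescaled
#' to 11-20 degC; AP, solar duration, PDSI, soil N and the Mg/Fe/Al oxides
#' are independent noise (they carry no signal, mirroring their
#' non-significance in the system emulated). z-scores are then affinely
#' mapped to field units.
#'
#' @param n number of units (>= 10); 23 matches the emulated survey.
#' @param betas named list of path coefficients, see [default_czu_betas()].
#' @param noise_sd multiplier on the structural residual sd's; 1 keeps unit
#'   variances (betas = population standardized coefficients), 0 makes the
#'   endogenous variables exact functions of their parents.
#' @param seed integer RNG seed.
#' @return a `data.frame` (class `czu_table`) with columns
#'   `czu_id, rwlr, npp, mat, ap, sd, pdsi, soil_n, br_si, br_ca, br_mg,
#'   br_fe, br_al`, and attribute `truth` recording the betas, the implied
#'   population standardized coefficients at this `noise_sd`, and the
#'   realized-sample standardized coefficients (what equation-wise OLS
#'   recovers exactly as `noise_sd -> 0`).
#' @export
gen_czu_table <- function(n = 23, betas = default_czu_betas(), noise_sd = 1,
                          seed = 1) {
  if (n < 10) stop_rwlr("parameter", "n must be >= 10")
  b <- utils::modifyList(default_czu_betas(), as.list(betas))
  if (!all(vapply(b, is.finite, logical(1))))
    stop_rwlr("parameter", "all betas must be finite")
  resid_npp <- 1 - b$npp_rwlr^2 - b$npp_mat^2
  if (resid_npp < 0 || abs(b$rwlr_brca) > 1 || abs(b$si_ca) > 1)
    stop_rwlr("parameter",
              "betas imply negative residual variance on the unit scale")

  set.seed(seed)
  br_ca <- runif(n, 4.8, 74.2)
  z_ca <- (br_ca - mean(c(4.8, 74.2))) / ((74.2 - 4.8) / sqrt(12))
  z_si <- b$si_ca * z_ca + noise_sd * sqrt(1 - b$si_ca^2) * rnorm(n)
  z_rwlr <- b$rwlr_brca * z_ca +
    noise_sd * sqrt(1 - b$rwlr_brca^2) * rnorm(n)
  z_mat <- rnorm(n)
  z_npp <- b$npp_rwlr * z_rwlr + b$npp_mat * z_mat +
    noise_sd * sqrt(resid_npp) * rnorm(n)

  tab <- data.frame(
    czu_id = sprintf("CZU%02d", seq_len(n)),
    rwlr = 3 + 1.5 * z_rwlr,
    npp = 640 + 260 * z_npp,
    mat = 15.5 + 2.5 * z_mat,
    ap = 1500 + 390 * rnorm(n),
    sd = 1200 + 200 * rnorm(n),
    pdsi = 0.8 * rnorm(n),
    soil_n = pmax(0.25 + 0.08 * rnorm(n), 0.01),
    br_si = pmin(pmax(25.9 + 13.5 * z_si, 0), 100),
    br_ca = br_ca,
    br_mg = pmin(pmax(5 + 3 * rnorm(n), 0), 100),
    br_fe = pmin(pmax(4 + 2 * rnorm(n), 0), 100),
    br_al = pmin(pmax(8 + 4 * rnorm(n), 0), 100)
  )

  # population standardized coefficients implied by this noise_sd
  sd_rwlr <- sqrt(b$rwlr_brca^2 + noise_sd^2 * (1 - b$rwlr_brca^2))
  sd_npp <- sqrt((b$npp_rwlr * sd_rwlr)^2 + b$npp_mat^2 +
                   noise_sd^2 * resid_npp)
  std_pop <- list(rwlr_brca = b$rwlr_brca / sd_rwlr,
                  npp_rwlr = b$npp_rwlr * sd_rwlr / sd_npp,
                  npp_mat = b$npp_mat / sd_npp)
  # realized-sample standardization (exact OLS target when noise_sd = 0)
  std_sample <- list(
    rwlr_brca = b$rwlr_brca * sd(z_ca) / sd(z_rwlr),
    npp_rwlr = b$npp_rwlr * sd(z_rwlr) / sd(z_npp),
    npp_mat = b$npp_mat * sd(z_mat) / sd(z_npp))

  class(tab) <- c("czu_table", "data.frame")
  attr(tab, "truth") <- list(betas = b, noise_sd = noise_sd, seed = seed,
                             std_pop = std_pop, std_sample = std_sample,
                             scales = list(rwlr = c(3, 1.5),
                                           npp = c(640, 260),
                                           mat = c(15.5, 2.5)))
  tab
}

#' Write / read the CZU table (CSV with the canonical header)
#'
#' The column order `czu_id,rwlr,npp,mat,ap,sd,pdsi,soil_n,br_si,br_ca,
#' br_mg,br_fe,br_al` is part of the interface contract; the ground-truth
#' parameters travel in a JSON sidecar.
#'
#' @param tab a `czu_table`.
#' @param path CSV path; sidecar at `paste0(path, ".json")` if truth known.
#' @return `path` invisibly; `read_czu_csv` returns a `czu_table`.
#' @export
write_czu_csv <- function(tab, path) {
  cols <- c("czu_id", "rwlr", "npp", "mat", "ap", "sd", "pdsi", "soil_n",
            "br_si", "br_ca", "br_mg", "br_fe", "br_al")
  utils::write.csv(tab[, cols], path, row.names = FALSE)
  truth <- attr(tab, "truth")
  if (!is.null(truth))
    jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_czu_csv
#' @export
read_czu_csv <- function(path) {
  tab <- utils::read.csv(path)
  class(tab) <- c("czu_table", "data.frame")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(tab, "truth") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tab
}
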