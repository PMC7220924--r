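# least-squares AIC convention used throughout the ranking:
#   AIC = n * log(RSS / n) + 2 * (k + 2)
# (k predictors + intercept + error variance). Additive constants of the
# Gaussian likelihood are dropped; they cancel in every AIC comparison.
aic_ls <- function(rss, n, k) n * log(rss / n) + 2 * (k + 2)

ols_core <- function(y, X = NULL) {
  n <- length(y)
  Xd <- cbind(`(Intercept)` = rep(1, n), X)
  qrd <- qr(Xd)
  if (qrd$rank < ncol(Xd))
    stop_rwlr("fit", "rank-deficient design matrix")
  coefs <- qr.coef(qrd, y)
  fitted <- qr.fitted(qrd, y)
  list(coef = coefs, fitted = fitted, rss = sum((y - fitted)^2),
       n = n, k = ncol(Xd) - 1L, qr = qrd)
}

#' Ordinary least squares with the ranking AIC convention
#'
#' Small self-contained OLS summary used by the importance machinery:
#' coefficients with t-tests, R-squared, and `AIC = n log(RSS/n) + 2(k+2)`.
#' The convention (constants dropped) is recorded in the result and held
#' fixed across all model comparisons, which is all AIC differences need.
#'
#' @param y numeric response vector (no missing values).
#' @param x predictor matrix/data.frame, or `NULL` for the intercept-only
#'   model.
#' @return an `lm_fit`: `coefficients` (estimate, se, t, p), `r2`, `aic`,
#'   `rss`, `n`, `k`, `aic_convention`.
#' @examples
#' f <- fit_lm(c(2, 4, 6, 8), matrix(1:4, ncol = 1))
#' f$coefficients["x1", "estimate"]  # 2
#' @export
fit_lm <- function(y, x = NULL) {
  if (anyNA(y) || (!is.null(x) && anyNA(x)))
    stop_rwlr("input", "missing values are not allowed")
  if (!is.null(x)) {
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  core <- ols_core(y, x)
  n <- core$n; k <- core$k
  if (n <= k + 2)
    stop_rwlr("input", "need n > k + 2 observations")
  sigma2 <- core$rss / (n - k - 1)
  XtXinv <- chol2inv(qr.R(core$qr))
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  tval <- core$coef / se
  pval <- 2 * pt(abs(tval), df = n - k - 1, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss < .Machine$double.eps) 1 else 1 - core$rss / tss
  coefs <- cbind(estimate = core$coef, se = se, t = tval, p = pval)
  structure(list(coefficients = coefs, r2 = r2,
                 aic = aic_ls(core$rss, n, k), rss = core$rss, n = n, k = k,
                 aic_convention = "n*log(RSS/n) + 2*(k+2)"),
            class = "lm_fit")
}

#' Akaike weights from a vector of AIC values
#'
#' `delta = AIC - min(AIC)`; `w = exp(-delta/2) / sum(exp(-delta/2))`.
#' Invariant to adding a constant to every AIC.
#'
#' @param aic numeric vector.
#' @return list with `delta` and `weight` (weights sum to 1).
#' @export
akaike_weights <- function(aic) {
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  list(delta = delta, weight = w / sum(w))
}

#' All-subsets model ranking with Akaike weights and variable importance
#'
#' Fits every subset of the candidate predictors (optionally including the
#' intercept-only null model) by OLS, ranks by AIC, converts AIC
#' differences to Akaike weights, takes the best model subset as the
#' top-ranked models whose cumulative weight first exceeds `cum_weight`
#' (first crossing, inclusive), and scores each variable's relative
#' importance (RVI) as the summed weights of best-subset models containing
#' it. AIC ties are broken by fewer parameters, then lexicographic variable
#' names, so the ranking is deterministic.
#'
#' @param y numeric response.
#' @param candidates named numeric matrix/data.frame of candidate
#'   predictors; at most 12 (2^k enumeration).
#' @param include_null include the intercept-only model (default TRUE; its
#'   presence affects the weights, so it is an explicit, recorded choice).
#' @param cum_weight cumulative-weight threshold for the best subset
#'   (default 0.95).
#' @return a `model_ranking`: `models` data.frame (ordered by rank, with
#'   `model_id`, `variables`, `k`, `aic`, `delta`, `weight`, `cum_weight`,
#'   `in_best_subset`), `best_subset` (row indices), `rvi` (named vector),
#'   `aic_convention`.
#' @export
all_subsets_rank <- function(y, candidates, include_null = TRUE,
                             cum_weight = 0.95) {
  candidates <- as.matrix(candidates)
  k <- ncol(candidates)
  if (is.null(colnames(candidates)))
    stop_rwlr("interface", "candidates must be named")
  if (k > 12)
    stop_rwlr("size", "more than 12 candidates: 2^k enumeration refused")
  nm <- colnames(candidates)
  masks <- seq.int(if (include_null) 0L else 1L, 2L^k - 1L)

  rows <- lapply(masks, function(m) {
    inc <- which(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    X <- if (length(inc)) candidates[, inc, drop = FALSE] else NULL
    core <- ols_core(y, X)
    vars <- if (length(inc)) paste(sort(nm[inc]), collapse = "+") else "(null)"
    data.frame(model_id = m, variables = vars, k = length(inc),
               aic = aic_ls(core$rss, core$n, core$k))
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$aic, tab$k, tab$variables)
  tab <- tab[ord, , drop = FALSE]
  aw <- akaike_weights(tab$aic)
  tab$delta <- aw$delta
  tab$weight <- aw$weight
  tab$cum_weight <- cumsum(tab$weight)
  n_best <- which(tab$cum_weight > cum_weight)[1]
  tab$in_best_subset <- seq_len(nrow(tab)) <= n_best
  rownames(tab) <- NULL

  rvi <- vapply(nm, function(v) {
    has <- tab$in_best_subset &
      vapply(strsplit(tab$variables, "+", fixed = TRUE),
             function(s) v %in% s, logical(1))
    sum(tab$weight[has])
  }, numeric(1))

  structure(list(models = tab, best_subset = seq_len(n_best),
                 rvi = rvi, cum_weight_rule = cum_weight,
                 aic_convention = "n*log(RSS/n) + 2*(k+2)"),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, n = 6, ...) {
  cat("All-subsets AIC ranking (", nrow(x$models), " models, best subset ",
      length(x$best_subset), " models)\n", sep = "")
  print(utils::head(x$models, n))
  cat("RVI:\n"); print(round(sort(x$rvi, decreasing = TRUE), 3))
  invisible(x)
}

#' Pairwise-collinearity screen with AIC-based exclusion
#'
#' For every candidate pair with `|Pearson r| > threshold`, the member with
#' the weaker single-variable relationship to the response (greater AIC) is
#' excluded, except for the designated `keep_both` pair: there the
#' candidates are split into two subsets, one retaining each member (the
#' device used when two collinear drivers may act through different
#' mechanisms).
#'
#' @param candidates named numeric matrix/data.frame (complete cases).
#' @param response numeric response vector.
#' @param threshold absolute-correlation cut-off (default 0.70).
#' @param keep_both optional character vector of length 2 naming the pair to
#'   split rather than prune.
#' @return a `collinearity_report`: `pairwise_r` matrix, `excluded`
#'   data.frame (`variable`, `partner`, `reason`), `subsets` (list of
#'   retained candidate-name vectors; length 2 iff the `keep_both` pair was
#'   collinear).
#' @export
collinearity_screen <- function(candidates, response, threshold = 0.70,
                                keep_both = NULL) {
  candidates <- as.matrix(candidates)
  nm <- colnames(candidates)
  R <- cor(candidates)
  pairs <- which(abs(R) > threshold & upper.tri(R), arr.ind = TRUE)
  # most collinear pairs first
  if (nrow(pairs))
    pairs <- pairs[order(-abs(R[pairs]))[seq_len(nrow(pairs))], , drop = FALSE]

  dropped <- character(0); partner <- character(0)
  split_pair <- NULL
  for (i in seq_len(nrow(pairs))) {
    v1 <- nm[pairs[i, 1]]; v2 <- nm[pairs[i, 2]]
    if (v1 %in% dropped || v2 %in% dropped) next
    if (!is.null(keep_both) && setequal(c(v1, v2), keep_both)) {
      split_pair <- c(v1, v2)
      next
    }
    a1 <- fit_lm(response, candidates[, v1, drop = FALSE])$aic
    a2 <- fit_lm(response, candidates[, v2, drop = FALSE])$aic
    loser <- if (a1 > a2) v1 else v2
    dropped <- c(dropped, loser)
    partner <- c(partner, if (a1 > a2) v2 else v1)
  }
  retained <- setdiff(nm, dropped)
  subsets <- if (!is.null(split_pair) && all(split_pair %in% retained)) {
    list(setdiff(retained, split_pair[1]), setdiff(retained, split_pair[2]))
  } else list(retained)

  structure(list(pairwise_r = R,
                 excluded = data.frame(variable = dropped, partner = partner,
                                       reason = rep("collinear; greater single-variable AIC",
                                                    length(dropped))),
                 subsets = subsets, threshold = threshold),
            class = "collinearity_report")
}

#' Write a model ranking and its RVI table as CSV
#'
#' @param ranking a `model_ranking`.
#' @param models_path,rvi_path output CSV paths (either may be `NULL`).
#' @param response_name label stored in the RVI table.
#' @param single_aic optional named vector of single-variable AICs to carry
#'   into the RVI table (significance stars are derived from single-variable
#'   p-values when `y`/`candidates` are supplied instead).
#' @return invisibly, the RVI data.frame.
#' @export
write_ranking_csv <- function(ranking, models_path = NULL, rvi_path = NULL,
                              response_name = "", single_aic = NULL) {
  stopifnot(inherits(ranking, "model_ranking"))
  if (!is.null(models_path))
    utils::write.csv(ranking$models, models_path, row.names = FALSE)
  rvi <- data.frame(response = response_name, variable = names(ranking$rvi),
                    rvi = unname(ranking$rvi))
  if (!is.null(single_aic))
    rvi$best_single_aic <- unname(single_aic[rvi$variable])
  if (!is.null(rvi_path)) utils::write.csv(rvi, rvi_path, row.names = FALSE)
  invisible(rvi)
}
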