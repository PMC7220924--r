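#' Parse a recursive path-model specification
#'
#' One equation per line, lavaan-like syntax restricted to manifest
#' recursive paths: `"npp ~ rwlr + mat"`, `"rwlr ~ br_ca"`. The implied
#' directed graph must be acyclic.
#'
#' @param lines character vector of equations (or one string with
#'   newlines/semicolons).
#' @return a `path_spec`: list with `equations` (named list: endogenous ->
#'   predictors), `endogenous`, `exogenous`, `vars` (topological order).
#' @export
parse_path_spec <- function(lines) {
  lines <- unlist(strsplit(lines, "[\n;]"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  eqs <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "~", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop_rwlr("parse", sprintf("cannot parse equation '%s'", ln))
    lhs <- trimws(parts[1])
    rhs <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
    if (lhs %in% names(eqs))
      stop_rwlr("parse", sprintf("duplicate equation for '%s'", lhs))
    eqs[[lhs]] <- rhs
  }
  endo <- names(eqs)
  vars <- unique(c(unlist(eqs), endo))
  exo <- setdiff(vars, endo)

  # Kahn topological sort; failure means a cycle
  edges <- do.call(rbind, lapply(endo, function(y)
    data.frame(from = eqs[[y]], to = y)))
  order_out <- character(0)
  remaining <- vars
  repeat {
    free <- remaining[vapply(remaining, function(v)
      !any(edges$to == v & edges$from %in% remaining), logical(1))]
    if (!length(free)) {
      if (length(remaining)) stop_rwlr("graph", "path specification is cyclic")
      break
    }
    order_out <- c(order_out, free)
    remaining <- setdiff(remaining, free)
    if (!length(remaining)) break
  }
  structure(list(equations = eqs, endogenous = endo, exogenous = exo,
                 vars = order_out, edges = edges),
            class = "path_spec")
}

#' Fit a recursive path model by maximum likelihood
#'
#' Manifest-variable path analysis: each structural equation is estimated by
#' OLS (the ML solution for a recursive system with free exogenous
#' covariances), residual variances use the ML divisor `n`, and the
#' model-implied covariance matrix
#' \eqn{\Sigma = (I - B)^{-1} \Psi (I - B)^{-T}} is compared with the ML
#' sample covariance via the discrepancy
#' \eqn{F = \log|\Sigma| + tr(S\Sigma^{-1}) - \log|S| - p}, giving the
#' chi-square \eqn{(n-1) F}. CFI uses the independence baseline; the RMSEA
#' 90% interval inverts the noncentral chi-square distribution. The
#' standardized solution rescales each coefficient by the sample sd ratio.
#'
#' Bedrock Si and Ca are refused in one model: they are near-collinear by
#' construction and belong in separate model variants.
#'
#' @param data data.frame containing every variable of `spec` (complete
#'   cases required).
#' @param spec a `path_spec` or character vector of equations.
#' @param target variable for the total-effect decomposition (default
#'   `"npp"` when present, else the last endogenous variable).
#' @return a `path_fit`: `paths` (from, to, est, est_std, se, p), `r2`
#'   (per endogenous variable), `total_effects`, `chisq`, `df`, `chisq_p`,
#'   `cfi`, `rmsea` (point, lower90, upper90), `n`, `accepted`, `reasons`,
#'   `notes`.
#' @export
fit_path_model <- function(data, spec, target = NULL) {
  if (!inherits(spec, "path_spec")) spec <- parse_path_spec(spec)
  vars <- spec$vars
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop_rwlr("interface", paste("variables not in data:",
                                 paste(missing_vars, collapse = ", ")))
  lowered <- tolower(vars)
  if (all(c("br_si", "br_ca") %in% lowered))
    stop_rwlr("parameter",
              "br_si and br_ca are collinear by design; fit two model variants instead")
  d <- data[, vars, drop = FALSE]
  if (!all(complete.cases(d))) stop_rwlr("input", "complete data required")
  n <- nrow(d); p <- length(vars)

  S <- cov(d) * (n - 1) / n          # ML covariance
  sds <- sqrt(diag(S))
  endo <- spec$endogenous; exo <- spec$exogenous

  B <- matrix(0, p, p, dimnames = list(vars, vars))   # B[y, x]: x -> y
  Psi <- matrix(0, p, p, dimnames = list(vars, vars))
  Psi[exo, exo] <- S[exo, exo, drop = FALSE]
  paths <- NULL
  r2 <- setNames(numeric(length(endo)), endo)
  for (y in endo) {
    xs <- spec$equations[[y]]
    Xm <- as.matrix(d[, xs, drop = FALSE])
    core <- ols_core(d[[y]], Xm)
    est <- core$coef[-1]
    sigma2_ml <- core$rss / n
    dfree <- n - length(xs) - 1
    se <- if (dfree > 0) {
      XtXinv <- chol2inv(qr.R(core$qr))
      sqrt(pmax(diag(XtXinv)[-1], 0) * core$rss / dfree)
    } else rep(NA_real_, length(xs))
    pv <- 2 * pt(abs(est / se), df = max(dfree, 1), lower.tail = FALSE)
    B[y, xs] <- est
    Psi[y, y] <- sigma2_ml
    r2[y] <- 1 - sigma2_ml / S[y, y]
    paths <- rbind(paths, data.frame(
      from = xs, to = y, est = unname(est),
      est_std = unname(est) * sds[xs] / sds[y],
      se = unname(se), p = unname(pv)))
  }
  rownames(paths) <- NULL

  q <- nrow(paths) + length(endo) + length(exo) * (length(exo) + 1) / 2
  df <- p * (p + 1) / 2 - q
  notes <- character(0)
  if (df < 0) stop_rwlr("identification", "model has negative degrees of freedom")
  detS <- determinant(S, logarithm = TRUE)
  singular <- detS$sign <= 0 || !is.finite(detS$modulus) ||
    rcond(S) < 1e-12 || any(Psi[cbind(endo, endo)] < 1e-12 * diag(S)[endo])
  if (singular) {
    # exactly collinear (e.g. noise-free) data: coefficients are still
    # defined equation-wise, but the ML discrepancy is not
    notes <- c(notes, "singular sample covariance: fit indices unavailable")
    chisq <- chisq_p <- cfi <- NA_real_
    rmsea <- c(point = NA_real_, lower90 = NA_real_, upper90 = NA_real_)
  } else {
    A <- solve(diag(p) - B)
    Sigma <- A %*% Psi %*% t(A)
    ldS <- detS$modulus
    ldSig <- determinant(Sigma, logarithm = TRUE)$modulus
    Fml <- as.numeric(ldSig - ldS + sum(diag(S %*% solve(Sigma))) - p)
    chisq <- max((n - 1) * Fml, 0)
    chisq_p <- if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else 1
    if (df == 0) notes <- c(notes, "zero df: fit indices uninformative")

    # independence baseline
    Fb <- as.numeric(sum(log(diag(S))) - ldS)
    chisq_b <- max((n - 1) * Fb, 0)
    df_b <- p * (p - 1) / 2
    num <- max(chisq - df, 0)
    den <- max(chisq_b - df_b, chisq - df, 0)
    cfi <- if (den == 0) 1 else 1 - num / den
    rmsea <- rmsea_ci(chisq, df, n)
  }

  fit <- structure(list(paths = paths, r2 = r2, chisq = chisq, df = df,
                        chisq_p = chisq_p, cfi = cfi, rmsea = rmsea,
                        n = n, vars = vars, spec = spec, notes = notes),
                   class = "path_fit")
  if (is.null(target)) {
    # default outcome: the sink (an endogenous variable that predicts nothing)
    sinks <- endo[!endo %in% unlist(spec$equations)]
    target <- if ("npp" %in% tolower(vars)) vars[tolower(vars) == "npp"][1]
              else if (length(sinks)) sinks[1] else endo[length(endo)]
  }
  fit$total_effects <- total_effects(fit, target = target)
  verdict <- accept_model(fit)
  fit$accepted <- verdict$accepted
  fit$reasons <- verdict$reasons
  fit$notes <- unique(c(fit$notes, verdict$notes))
  fit
}

# 90% RMSEA interval by inverting the noncentral chi-square cdf
rmsea_ci <- function(chisq, df, n) {
  if (df <= 0) return(c(point = 0, lower90 = 0, upper90 = 0))
  point <- sqrt(max((chisq - df) / (df * (n - 1)), 0))
  solve_ncp <- function(target_p) {
    f <- function(l) pchisq(chisq, df, ncp = l) - target_p
    if (f(0) < 0) return(NA_real_)   # cdf already below target at ncp 0
    upper <- max(chisq * 2, df * 2, 10)
    while (f(upper) > 0 && upper < 1e8) upper <- upper * 2
    uniroot(f, c(0, upper), tol = 1e-9)$root
  }
  lo_ncp <- if (pchisq(chisq, df) < 0.95) 0 else solve_ncp(0.95)
  hi_ncp <- if (pchisq(chisq, df) < 0.05) 0 else solve_ncp(0.05)
  to_rmsea <- function(l) if (is.na(l)) 0 else sqrt(l / (df * (n - 1)))
  c(point = point, lower90 = to_rmsea(lo_ncp), upper90 = to_rmsea(hi_ncp))
}

#' Decompose standardized effects on a target variable
#'
#' Direct effect: the standardized coefficient of the edge into `target`
#' (0 when absent). Indirect effect: the sum over all directed chains of the
#' products of standardized coefficients along each chain. Total = direct +
#' indirect (the path-analysis decomposition rule).
#'
#' @param fit a `path_fit`, or any list with a `paths` data.frame carrying
#'   `from`, `to`, `est_std`.
#' @param target name of the outcome variable.
#' @return data.frame with `variable`, `direct`, `indirect`, `total`.
#' @export
total_effects <- function(fit, target) {
  paths <- fit$paths
  stopifnot(all(c("from", "to", "est_std") %in% names(paths)))
  vars <- setdiff(unique(c(paths$from, paths$to)), target)

  # guard: effect graph must be acyclic
  sum_paths <- function(v, visiting = character(0)) {
    if (v %in% visiting) stop_rwlr("graph", "cyclic path specification")
    out_edges <- paths[paths$from == v, , drop = FALSE]
    tot <- 0
    for (i in seq_len(nrow(out_edges))) {
      w <- out_edges$est_std[i]
      tot <- tot + if (out_edges$to[i] == target) w
                   else w * sum_paths(out_edges$to[i], c(visiting, v))
    }
    tot
  }
  rows <- lapply(vars, function(v) {
    direct <- sum(paths$est_std[paths$from == v & paths$to == target])
    total <- sum_paths(v)
    data.frame(variable = v, direct = direct, indirect = total - direct,
               total = total)
  })
  do.call(rbind, rows)
}

#' Model-acceptance verdict for a fitted path model
#'
#' A fit is accepted when all of: chi-square p > 0.05, CFI > 0.9, and the
#' lower bound of the 90% RMSEA interval < 0.05. Saturated (zero-df) models
#' pass with a warning note, since their fit indices carry no information.
#'
#' @param fit a `path_fit` (or list with `chisq_p`, `cfi`, `rmsea`, `df`).
#' @return list with `accepted` (logical), `reasons` (failed criteria),
#'   `notes`.
#' @export
accept_model <- function(fit) {
  if (anyNA(c(fit$chisq_p, fit$cfi, fit$rmsea[["lower90"]])))
    return(list(accepted = NA,
                reasons = "fit indices unavailable (singular covariance)",
                notes = character(0)))
  reasons <- character(0)
  if (!(fit$chisq_p > 0.05)) reasons <- c(reasons, "chisq_p")
  if (!(fit$cfi > 0.9)) reasons <- c(reasons, "CFI")
  if (!(fit$rmsea[["lower90"]] < 0.05)) reasons <- c(reasons, "RMSEA_lower90")
  notes <- if (!is.null(fit$df) && fit$df == 0)
    "zero df: fit indices uninformative" else character(0)
  list(accepted = length(reasons) == 0, reasons = reasons, notes = notes)
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("Recursive path model (n = %d): chisq = %.3f on %g df (p = %.3f), CFI = %.3f, RMSEA = %.3f [%.3f, %.3f]\n",
              x$n, x$chisq, x$df, x$chisq_p, x$cfi,
              x$rmsea[["point"]], x$rmsea[["lower90"]], x$rmsea[["upper90"]]))
  cat(if (isTRUE(x$accepted)) "ACCEPTED"
      else paste("REJECTED:", paste(x$reasons, collapse = ", ")), "\n")
  df <- x$paths
  df$est <- round(df$est, 3); df$est_std <- round(df$est_std, 3)
  df$p <- signif(df$p, 2)
  print(df[, c("from", "to", "est", "est_std", "p")])
  cat("R2:", paste(sprintf("%s = %.3f", names(x$r2), x$r2), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a path fit to JSON
#'
#' @param fit a `path_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_path_fit_json <- function(fit, path) {
  out <- list(paths = fit$paths, r2 = as.list(fit$r2),
              total_effects = fit$total_effects,
              fit_indices = list(chisq = fit$chisq, df = fit$df,
                                 chisq_p = fit$chisq_p, cfi = fit$cfi,
                                 rmsea = as.list(fit$rmsea)),
              accepted = fit$accepted, reasons = fit$reasons,
              notes = fit$notes, n = fit$n)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
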