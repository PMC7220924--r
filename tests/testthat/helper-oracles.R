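# Independent oracles and fixture builders. Everything here deliberately
# avoids the package's own code paths (rle, bitmask enumeration, the
# morphology kernels) so agreement is evidence, not tautology.

# exhaustive window scan for dry spells: every (start, end) window is
# tested for full dryness and maximality via a cumulative-sum trick
oracle_spells <- function(precip, min_length = 5, wet_threshold = 0) {
  dry <- precip$precip_mm <= wet_threshold
  n <- length(dry)
  cs <- c(0, cumsum(dry))
  grid <- expand.grid(s = seq_len(n), e = seq_len(n))
  grid <- grid[grid$e - grid$s + 1 >= min_length, ]
  len <- grid$e - grid$s + 1
  all_dry <- (cs[grid$e + 1] - cs[grid$s]) == len
  left_ok <- grid$s == 1 | !dry[pmax(grid$s - 1, 1)]
  right_ok <- grid$e == n | !dry[pmin(grid$e + 1, n)]
  sel <- grid[all_dry & left_ok & right_ok, , drop = FALSE]
  sel <- sel[order(sel$s), , drop = FALSE]
  data.frame(start_date = precip$date[sel$s], end_date = precip$date[sel$e],
             duration = sel$e - sel$s + 1)
}

# second, stats::lm-based implementation of the all-subsets ranking
oracle_rank <- function(y, X, include_null = TRUE, cum_weight = 0.95) {
  nm <- colnames(X)
  k <- ncol(X)
  n <- length(y)
  combos <- if (include_null) list(character(0)) else list()
  for (m in seq_len(k))
    combos <- c(combos, utils::combn(nm, m, simplify = FALSE))
  rows <- lapply(combos, function(v) {
    fit <- if (length(v))
      stats::lm(y ~ ., data = data.frame(y = y, X[, v, drop = FALSE]))
    else stats::lm(y ~ 1)
    rss <- sum(stats::residuals(fit)^2)
    data.frame(variables = if (length(v)) paste(sort(v), collapse = "+") else "(null)",
               k = length(v), aic = n * log(rss / n) + 2 * (length(v) + 2))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aic, tab$k, tab$variables), ]
  d <- tab$aic - min(tab$aic)
  tab$weight <- exp(-d / 2) / sum(exp(-d / 2))
  cw <- cumsum(tab$weight)
  n_best <- which(cw > cum_weight)[1]
  best <- tab[seq_len(n_best), ]
  rvi <- sapply(nm, function(v)
    sum(best$weight[sapply(strsplit(best$variables, "+", fixed = TRUE),
                           function(s) v %in% s)]))
  list(models = tab, rvi = rvi)
}

# exact two-sided Mann-Whitney p by full enumeration of rank assignments
oracle_wilcox_p <- function(x, y) {
  all_v <- c(x, y)
  stopifnot(!any(duplicated(all_v)))
  m <- length(x)
  u_of <- function(xi) {
    r <- rank(all_v)[xi]
    sum(r) - m * (m + 1) / 2
  }
  u_obs <- u_of(seq_len(m))
  sets <- utils::combn(length(all_v), m, simplify = FALSE)
  us <- vapply(sets, u_of, numeric(1))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# scene whose per-bin temperature extremes sit exactly on planted lines
# T_d = 320 - 15 * NDVI, T_w = 290 (the recoverability fixture)
scene_on_lines <- function(n_bins = 10, rng = c(0.1, 0.9),
                           a = 320, b = -15, cc = 290, d = 0) {
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  centres <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  td <- a + b * centres
  tw <- cc + d * centres
  ndvi <- c(rep(centres, each = 3), rng)       # endpoints pin the range
  lst <- c(rbind(td, tw, (td + tw) / 2), 300, 300)
  list(ndvi = ndvi, lst = lst, a = a, b = b, c = cc, d = d)
}

# direct-enumeration ring counts around a solid rectangle (8-connected)
oracle_ring_counts <- function(nr, nc, rows, cols, width = 1) {
  mask <- matrix(FALSE, nr, nc)
  mask[rows, cols] <- TRUE
  cheb <- function(i, j) {
    # Chebyshev distance from pixel (i, j) to the nearest mask / non-mask
    idx <- which(mask, arr.ind = TRUE)
    out <- which(!mask, arr.ind = TRUE)
    if (mask[i, j]) min(pmax(abs(out[, 1] - i), abs(out[, 2] - j)))
    else min(pmax(abs(idx[, 1] - i), abs(idx[, 2] - j)))
  }
  inner <- outer_ <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    dch <- cheb(i, j)
    if (mask[i, j] && dch <= width) inner <- inner + 1
    if (!mask[i, j] && dch <= width) outer_ <- outer_ + 1
  }
  c(inner = inner, outer = outer_)
}

# tiny deterministic precip data.frame from a depth vector
precip_from <- function(x, start = as.Date("2001-01-01")) {
  data.frame(date = start + seq_along(x) - 1, precip_mm = x)
}
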