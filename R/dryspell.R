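#' Detect dry spells in a daily precipitation series
#'
#' A dry spell is a maximal run of at least `min_length` consecutive days
#' whose precipitation does not exceed `wet_threshold` (default 0 mm: "no
#' precipitation" read literally; set 0.1 to ignore trace rain).
#'
#' @param precip a `precip_series` or data.frame with `date` (Date, gap-free
#'   daily) and `precip_mm`.
#' @param min_length minimum spell duration in days (default 5).
#' @param wet_threshold precipitation (mm) at or below which a day counts as
#'   dry.
#' @return a `data.frame` (class `dry_spells`) with `start_date`,
#'   `end_date`, `duration`, in chronological order; zero rows if none.
#' @export
detect_dry_spells <- function(precip, min_length = 5, wet_threshold = 0) {
  if (min_length < 2) stop_rwlr("parameter", "min_length must be >= 2")
  dates <- precip$date
  if (inherits(dates, "Date") && length(dates) > 1 &&
      any(as.integer(diff(dates)) != 1L))
    stop_rwlr("input", "precipitation record has date gaps")
  dry <- precip$precip_mm <= wet_threshold
  r <- rle(dry)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  out <- data.frame(start_date = dates[starts[keep]],
                    end_date = dates[ends[keep]],
                    duration = r$lengths[keep])
  class(out) <- c("dry_spells", "data.frame")
  out
}

#' Spatial-mean dryness index over a critical-zone-unit disc
#'
#' Averages valid TVDI pixels whose centres fall inside a disc (the CZU: a
#' fixed radius around a meteorological station) for every composite.
#' Composites where too few disc pixels are valid are dropped and recorded.
#'
#' @param scenes list of `tvdi_scene` objects sharing a grid (e.g. from
#'   [stack_tvdi()]).
#' @param disc list with `x`, `y` (disc centre, grid coordinates) and
#'   `radius` (same units as the pixel size, e.g. km).
#' @param min_valid_frac composites with a lower fraction of valid disc
#'   pixels are dropped (quality screen; default 0.5).
#' @return data.frame with `time`, `tvdi`, `n_valid`, `frac_valid`;
#'   attribute `dropped_times` lists screened-out composites.
#' @export
czu_mean_tvdi <- function(scenes, disc, min_valid_frac = 0.5) {
  stopifnot(length(scenes) > 0)
  g <- scenes[[1]]$grid %||% list(nrow = nrow(scenes[[1]]$tvdi),
                                  ncol = ncol(scenes[[1]]$tvdi),
                                  xmin = 0, ymin = 0, dx = 1, dy = 1)
  cx <- g$xmin + (seq_len(g$ncol) - 0.5) * g$dx
  cy <- g$ymin + (seq_len(g$nrow) - 0.5) * g$dy
  inside <- outer(cy, cx, function(yy, xx)
    (xx - disc$x)^2 + (yy - disc$y)^2 <= disc$radius^2)
  n_inside <- sum(inside)
  if (n_inside == 0)
    stop_rwlr("geometry", "disc does not intersect the grid")

  rows <- lapply(scenes, function(sc) {
    v <- sc$tvdi[inside]
    v <- v[is.finite(v)]
    data.frame(time = sc$time, tvdi = mean(v), n_valid = length(v),
               frac_valid = length(v) / n_inside)
  })
  out <- do.call(rbind, rows)
  dropped <- out$time[out$frac_valid < min_valid_frac]
  out <- out[out$frac_valid >= min_valid_frac, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_times") <- dropped
  attr(out, "n_inside") <- n_inside
  out
}

#' Regolith water loss rate from a dryness-index time series
#'
#' For each dry spell, the composites falling inside the spell define
#' consecutive-pair slopes `(TVDI_b - TVDI_a) / dT_ab`; their mean is the
#' spell's drying rate. Per-spell means are combined across spells by
#' `aggregate` and scaled by 100. The default combines by mean (the "average
#' variation during dry spells"); `"sum"` reproduces the literal summation
#' form, which confounds the index with spell count and is provided for
#' comparison.
#'
#' @param series data.frame with `time` (Date or numeric days) and `tvdi`
#'   (unit-mean dryness index), e.g. from [czu_mean_tvdi()].
#' @param spells a `dry_spells` data.frame; `start_date`/`end_date` must be
#'   comparable with `series$time` (both Date or both numeric).
#' @param aggregate `"mean"` (default) or `"sum"` over per-spell means.
#' @param min_composites spells with fewer valid composites are excluded
#'   (default 2, the minimum defining a slope).
#' @param slopes `"consecutive"` (default: all consecutive valid pairs) or
#'   `"endpoints"` (first vs last composite only).
#' @param czu_id identifier carried into the result.
#' @return an `rwlr_result`: list with `czu_id`, `rwlr` (x100 scale; `NA`
#'   when no spell is usable - distinct from a genuine 0), `n_spells_used`,
#'   `per_spell_means`, `aggregate`.
#' @export
compute_rwlr <- function(series, spells, aggregate = c("mean", "sum"),
                         min_composites = 2,
                         slopes = c("consecutive", "endpoints"),
                         czu_id = NA_character_) {
  aggregate <- match.arg(aggregate)
  slopes <- match.arg(slopes)
  tt <- series$time
  if (inherits(tt, "Date") != inherits(spells$start_date, "Date"))
    stop_rwlr("interface",
              "series time and spell dates must share a class (Date or numeric)")
  t_num <- as.numeric(tt)
  ord <- order(t_num)
  t_num <- t_num[ord]; v <- series$tvdi[ord]

  per_spell <- numeric(0)
  for (i in seq_len(nrow(spells))) {
    lo <- as.numeric(spells$start_date[i]); hi <- as.numeric(spells$end_date[i])
    sel <- which(t_num >= lo & t_num <= hi & is.finite(v))
    if (length(sel) < min_composites) next
    ts <- t_num[sel]; vs <- v[sel]
    sl <- if (slopes == "consecutive") diff(vs) / diff(ts)
          else (vs[length(vs)] - vs[1]) / (ts[length(ts)] - ts[1])
    per_spell <- c(per_spell, mean(sl))
  }
  rwlr <- if (length(per_spell) == 0) NA_real_
          else switch(aggregate, mean = mean(per_spell), sum = sum(per_spell)) * 100
  structure(list(czu_id = czu_id, rwlr = rwlr,
                 n_spells_used = length(per_spell),
                 per_spell_means = per_spell, aggregate = aggregate),
            class = "rwlr_result")
}

#' @export
print.rwlr_result <- function(x, ...) {
  cat(sprintf("RWLR result%s: rwlr = %s (aggregate = %s, %d spells used)\n",
              if (is.na(x$czu_id)) "" else paste0(" [", x$czu_id, "]"),
              format(x$rwlr), x$aggregate, x$n_spells_used))
  invisible(x)
}

#' Screen candidate critical-zone units for inclusion
#'
#' Retains sites with a full record span, no station relocation, and at
#' least `min_spells` identifiable dry spells; every exclusion is labelled
#' with the first failing rule (`"record_span"`, `"relocated"`,
#' `"min_spells"`).
#'
#' @param sites data.frame with `czu_id`, `n_years` (record span, years),
#'   `relocated` (logical), `n_spells`.
#' @param min_years required record span (default 10).
#' @param min_spells required number of identifiable dry spells (default 10).
#' @return list with `retained` (subset of `sites`) and `excluded`
#'   (`czu_id`, `reason`).
#' @export
filter_sites <- function(sites, min_years = 10, min_spells = 10) {
  reason <- rep(NA_character_, nrow(sites))
  reason[is.na(reason) & sites$n_years < min_years] <- "record_span"
  reason[is.na(reason) & sites$relocated] <- "relocated"
  reason[is.na(reason) & sites$n_spells < min_spells] <- "min_spells"
  keep <- is.na(reason)
  list(retained = sites[keep, , drop = FALSE],
       excluded = data.frame(czu_id = sites$czu_id[!keep],
                             reason = reason[!keep]))
}
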