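# Resilience indicators from longitudinal egg production: weekly
# aggregation of collection records, deviations from the batch mean
# curve, and the three per-period summaries LNvar, Skew and Rauto.

#' Weekly egg production for one hen
#'
#' Sums collection records into age-week counts.  Age-weeks are anchored
#' at hatch: week w covers days of age 7(w-1) to 7w-1.  Each record's
#' eggs are assigned wholly to the week containing its collection day (no
#' proration across the few days an interval may span).  A week is kept
#' only when collections cover all 7 of its days: coverage runs from
#' `coverage_start` (default: the first day of the week of the first
#' record) to the last collection day, so leading and trailing partial
#' weeks are dropped.
#'
#' @param day integer vector of collection days of age, strictly
#'   increasing.
#' @param eggs integer vector of eggs collected on each day.
#' @param coverage_start day of age from which recording is complete.
#' @return data.frame `week`, `eggs` over the covered weeks (possibly
#'   zero rows).
#' @export
weekly_counts <- function(day, eggs, coverage_start = NULL) {
  if (length(day) != length(eggs))
    stop("day and eggs must have equal length", call. = FALSE)
  if (length(day) == 0L)
    return(data.frame(week = integer(0), eggs = integer(0)))
  if (any(diff(day) <= 0))
    stop("collection days must be strictly increasing", call. = FALSE)
  if (any(eggs < 0)) stop("egg counts must be non-negative", call. = FALSE)
  if (is.null(coverage_start)) coverage_start <- 7L * (day[1L] %/% 7L)
  wk <- day %/% 7L + 1L
  sums <- tapply(eggs, wk, sum)
  w_all <- as.integer(names(sums))
  first_full <- ceiling(coverage_start / 7) + 1L  # first week starting at/after coverage_start
  if (coverage_start %% 7L == 0L) first_full <- coverage_start %/% 7L + 1L
  last_full <- (max(day) + 1L) %/% 7L             # last week fully covered
  keep_weeks <- w_all[w_all >= first_full & w_all <= last_full]
  if (!length(keep_weeks))
    return(data.frame(week = integer(0), eggs = integer(0)))
  full <- seq(min(keep_weeks), max(keep_weeks))
  out <- integer(length(full))
  out[match(keep_weeks, full)] <- as.integer(sums[as.character(keep_weeks)])
  data.frame(week = full, eggs = out)
}

#' Weekly egg production for a whole batch
#'
#' Vectorised application of the [weekly_counts()] aggregation rule to a
#' long egg-collection log.
#'
#' @param egg_log data.frame `hen`, `day`, `eggs` (one row per collection).
#' @return data.frame `hen`, `week`, `eggs`.
#' @export
weekly_production <- function(egg_log) {
  stopifnot(all(c("hen", "day", "eggs") %in% names(egg_log)))
  if (nrow(egg_log) == 0L)
    return(data.frame(hen = character(0), week = integer(0),
                      eggs = integer(0)))
  ord <- order(egg_log$hen, egg_log$day)
  hen <- egg_log$hen[ord]
  day <- as.integer(egg_log$day[ord])
  eggs <- as.integer(egg_log$eggs[ord])
  first <- c(TRUE, hen[-1L] != hen[-length(hen)])
  if (any(diff(day)[!first[-1L]] <= 0))
    stop("collection days must be strictly increasing within hen",
         call. = FALSE)
  wk <- day %/% 7L + 1L
  grp <- paste(hen, wk, sep = "\r")
  sums <- rowsum(eggs, grp, reorder = FALSE)
  gh <- sub("\r.*$", "", rownames(sums))
  gw <- as.integer(sub("^.*\r", "", rownames(sums)))
  # per-hen coverage window
  hens_u <- hen[first]
  cov_start <- 7L * (day[first] %/% 7L)
  last_day <- tapply(day, hen, max)[hens_u]
  first_full <- cov_start %/% 7L + 1L + as.integer(cov_start %% 7L != 0L)
  last_full <- (as.integer(last_day) + 1L) %/% 7L
  j <- match(gh, hens_u)
  keep <- gw >= first_full[j] & gw <= last_full[j]
  out <- data.frame(hen = gh[keep], week = gw[keep],
                    eggs = as.integer(sums[keep, 1L]),
                    stringsAsFactors = FALSE)
  out[order(out$hen, out$week), , drop = FALSE]
}

#' Batch mean lay curve
#'
#' Per age-week arithmetic mean of weekly egg counts over the hens
#' observed in that week; the expected production every hen is compared
#' against.
#'
#' @param weekly data.frame `hen`, `week`, `eggs` from
#'   [weekly_production()].
#' @return data.frame `week`, `mean_eggs`, `n_hens`, restricted to weeks
#'   with at least one observed hen.
#' @export
batch_mean <- function(weekly) {
  stopifnot(all(c("week", "eggs") %in% names(weekly)))
  if (nrow(weekly) == 0L)
    return(data.frame(week = integer(0), mean_eggs = numeric(0),
                      n_hens = integer(0)))
  m <- tapply(weekly$eggs, weekly$week, mean)
  n <- tapply(weekly$eggs, weekly$week, length)
  data.frame(week = as.integer(names(m)), mean_eggs = as.numeric(m),
             n_hens = as.integer(n))
}

#' Deviations of observed from expected weekly production
#'
#' Subtracts the batch mean curve from each hen's weekly counts,
#' preserving week order; only observed weeks appear.
#'
#' @param weekly data.frame `hen`, `week`, `eggs`.
#' @param curve data.frame `week`, `mean_eggs` (see [batch_mean()]).
#' @return data.frame `hen`, `week`, `deviation`.
#' @export
deviations <- function(weekly, curve) {
  j <- match(weekly$week, curve$week)
  if (anyNA(j))
    stop("week(s) absent from the batch curve: ",
         paste(unique(weekly$week[is.na(j)]), collapse = ", "),
         call. = FALSE)
  data.frame(hen = weekly$hen, week = weekly$week,
             deviation = weekly$eggs - curve$mean_eggs[j],
             stringsAsFactors = FALSE)
}

#' Log-variance of deviations (LNvar)
#'
#' Natural log of the sample variance (denominator n-1).  `NA` when fewer
#' than 2 values or when the variance is zero.
#'
#' @param x numeric deviation series.
#' @return scalar, or `NA_real_` when undefined.
#' @export
ln_variance <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  v <- sum((x - mean(x))^2) / (length(x) - 1L)
  if (v <= 0) return(NA_real_)
  log(v)
}

#' Skewness of deviations (Skew)
#'
#' Moment coefficient of skewness m3 / m2^(3/2) with central moments on
#' denominator n (unadjusted Fisher--Pearson g1).  `NA` when fewer than 3
#' values or zero variance.
#'
#' @param x numeric deviation series.
#' @return scalar, or `NA_real_` when undefined.
#' @export
skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 <= 0) return(NA_real_)
  mean(xc^3) / m2^1.5
}

#' Lag-one autocorrelation of deviations (Rauto)
#'
#' Serial estimator r1 = sum_t (d_t - dbar)(d_{t+1} - dbar) /
#' sum_t (d_t - dbar)^2 with a single mean and the full-series sum in the
#' denominator, so r1 is always in [-1, 1].  When `weeks` is supplied,
#' pairs spanning a gap (week difference != 1) are dropped from the
#' numerator; the denominator uses all values.  The Pearson correlation
#' of lagged pairs is available as `method = "pearson"`.
#'
#' @param x numeric deviation series, in time order.
#' @param weeks optional integer weeks matching `x`, for gap handling.
#' @param method `"serial"` (default) or `"pearson"`.
#' @return scalar, or `NA_real_` when undefined (fewer than 3 values,
#'   zero variance, or no valid lag pair).
#' @export
lag1_autocorrelation <- function(x, weeks = NULL,
                                 method = c("serial", "pearson")) {
  method <- match.arg(method)
  ok <- !is.na(x)
  x <- x[ok]
  if (!is.null(weeks)) weeks <- weeks[ok]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  adj <- if (is.null(weeks)) rep(TRUE, n - 1L) else diff(weeks) == 1L
  if (!any(adj)) return(NA_real_)
  if (method == "serial") {
    xc <- x - mean(x)
    den <- sum(xc^2)
    if (den <= 0) return(NA_real_)
    sum(xc[-n][adj] * xc[-1L][adj]) / den
  } else {
    a <- x[-n][adj]
    b <- x[-1L][adj]
    if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0)
      return(NA_real_)
    stats::cor(a, b)
  }
}

#' Resilience indicators per hen and period
#'
#' Computes LNvar, Skew and Rauto of the deviation series within each
#' period.  Periods are half-open week windows `[from, to)`; an infinite
#' upper bound means "to the hen's last observed week".  All three
#' indicators are set missing when the hen laid fewer than `min_eggs`
#' eggs in the period.  Counts of filtered hens per period are attached
#' as attribute `"filter_counts"`.
#'
#' @param weekly data.frame `hen`, `week`, `eggs`.
#' @param curve batch mean curve from [batch_mean()]; recomputed from
#'   `weekly` when `NULL`.
#' @param periods named list of `c(from, to)` week windows.
#' @param min_eggs minimum period egg total for the record to be kept.
#' @param rauto_method passed to [lag1_autocorrelation()].
#' @return data.frame `hen`, `period`, `ln_var`, `skew`, `r_auto`,
#'   `n_weeks`, `total_eggs`.
#' @export
resilience_indicators <- function(weekly, curve = NULL,
                                  periods = list("25-83" = c(25, 83),
                                                 "83-end" = c(83, Inf)),
                                  min_eggs = 20,
                                  rauto_method = "serial") {
  if (is.null(curve)) curve <- batch_mean(weekly)
  dev <- deviations(weekly, curve)
  dev <- dev[order(dev$hen, dev$week), , drop = FALSE]
  hens <- unique(dev$hen)
  if (is.null(names(periods)))
    names(periods) <- vapply(periods, function(p)
      paste0(p[1], "-", if (is.finite(p[2])) p[2] else "end"), character(1))
  dev_by_hen <- split(dev[c("week", "deviation")], dev$hen)
  eggs_by_hen <- split(weekly$eggs[order(weekly$hen, weekly$week)],
                       weekly$hen[order(weekly$hen, weekly$week)])
  res <- vector("list", length(periods))
  filter_counts <- integer(length(periods))
  names(filter_counts) <- names(periods)
  for (k in seq_along(periods)) {
    p <- periods[[k]]
    rows <- lapply(seq_along(hens), function(i) {
      d <- dev_by_hen[[hens[i]]]
      inw <- d$week >= p[1] & d$week < p[2]
      nw <- sum(inw)
      tot <- sum(eggs_by_hen[[hens[i]]][inw])
      if (nw == 0L || tot < min_eggs)
        return(data.frame(hen = hens[i], period = names(periods)[k],
                          ln_var = NA_real_, skew = NA_real_,
                          r_auto = NA_real_, n_weeks = nw,
                          total_eggs = tot, stringsAsFactors = FALSE))
      x <- d$deviation[inw]
      w <- d$week[inw]
      data.frame(hen = hens[i], period = names(periods)[k],
                 ln_var = ln_variance(x), skew = skewness(x),
                 r_auto = lag1_autocorrelation(x, w, method = rauto_method),
                 n_weeks = nw, total_eggs = tot, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    filter_counts[k] <- sum(out$n_weeks > 0L & out$total_eggs < min_eggs)
    res[[k]] <- out
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "filter_counts") <- filter_counts
  out
}
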