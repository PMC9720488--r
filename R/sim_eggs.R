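# Daily egg-laying simulator: individual lay probabilities follow a
# calibrated batch potential curve plus genetic level/persistency and barn
# row effects, damped multiplicatively by disturbance episodes with
# exponential recovery; daily Bernoulli lays are summed into 1-4 day
# collection records and truncated at death.

# target batch mean curve (eggs/week) at week of age w
egg_target_curve <- function(w, egg) {
  slope <- (egg$end_mean - egg$peak_mean) / (egg$end_week - egg$peak_week)
  ifelse(w <= egg$peak_week,
         pmax(0, egg$peak_mean * (w - egg$rise_start_week) /
                (egg$peak_week - egg$rise_start_week)),
         egg$peak_mean + slope * (w - egg$peak_week))
}

# E[min(X, cap)] for X ~ Normal(mu, sd)
trunc_mean_upper <- function(mu, sd, cap = 7) {
  if (sd <= 0) return(pmin(mu, cap))
  z <- (cap - mu) / sd
  mu - sd * stats::dnorm(z) - (mu - cap) * (1 - stats::pnorm(z))
}

# Solve the potential curve so that the realized batch mean (after the
# 7-egg cap over the individual-effect distribution and the steady-state
# disturbance burden) equals the target curve.
calibrate_potential_curve <- function(weeks, egg) {
  target <- egg_target_curve(weeks, egg)
  d <- egg$disturbance
  loss <- d$rate * (d$depth_min + d$depth_max) / 2 * d$tau_weeks
  decline <- pmin(0, target - egg$peak_mean)
  sdw <- sqrt(egg$sigma2_level + egg$sigma2_row +
                egg$sigma2_pers * decline^2)
  vapply(seq_along(weeks), function(i) {
    tg <- target[i]
    if (tg <= 0) return(0)
    f <- function(mu) trunc_mean_upper(mu, sdw[i]) * (1 - loss) - tg
    stats::uniroot(f, lower = tg - 1, upper = 7 + 4 * sdw[i] + 1,
                   tol = 1e-10)$root
  }, numeric(1))
}

# compositions of 7 into ordered parts of size 1..4 (collection intervals
# partitioning one week); enumerated once
week_compositions <- local({
  comps <- NULL
  function() {
    if (!is.null(comps)) return(comps)
    grow <- function(prefix, rem) {
      if (rem == 0) return(list(prefix))
      out <- list()
      for (p in seq_len(min(4, rem)))
        out <- c(out, grow(c(prefix, p), rem - p))
      out
    }
    comps <<- grow(integer(0), 7L)
    comps
  }
})

#' Simulate daily egg laying and collection records
#'
#' Each hen lays daily with probability equal to her individual potential
#' curve divided by 7: the calibrated batch potential plus her genetic
#' production level, barn-row effect, and (after the peak) a persistency
#' multiplier on the decline.  Disturbance episodes start as a Poisson
#' process per hen, reduce the lay probability multiplicatively by a
#' depth drawn uniform on the configured range, and decay exponentially.
#' Hens are culled by a constant weekly hazard; records stop at death.
#' Daily lays are summed into egg-collection records at 1-4 day
#' intervals.  By default the collection schedule is aligned so that each
#' age-week closes with a collection, keeping weekly sums in [0, 7]; with
#' `config$egg$allow_over7` the intervals free-run across week boundaries
#' so a week can occasionally register more than 7 eggs by misattribution.
#'
#' @param ped pedigree; hens = animals with a hatch week.
#' @param bv_level named breeding values for production level (eggs/week);
#'   `NULL` for none.
#' @param bv_pers named breeding values for persistency (multiplier on the
#'   post-peak decline); `NULL` for none.
#' @param config a [sim_config()].
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return list with `log` (data.frame `hen`, `day`, `eggs`; day is day of
#'   age of the collection), `life` (data.frame `hen`, `last_day`), and
#'   `rows` (data.frame `hen`, `row` barn-row assignment).
#' @export
simulate_egg_production <- function(ped, bv_level = NULL, bv_pers = NULL,
                                    config = sim_config(), seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  egg <- config$egg
  hens <- ped$animal[!is.na(ped$hatch_week)]
  n <- length(hens)
  weeks <- egg$start_week:egg$last_week
  nw <- length(weeks)
  day0 <- 7L * (egg$start_week - 1L)           # first simulated day of age
  day_end <- 7L * egg$last_week - 1L
  nd <- day_end - day0 + 1L

  g_lev <- if (is.null(bv_level)) numeric(n) else unname(bv_level[hens])
  g_per <- if (is.null(bv_pers)) numeric(n) else unname(bv_pers[hens])
  if (anyNA(g_lev) || anyNA(g_per))
    stop("breeding values missing for some hens", call. = FALSE)

  row_assign <- rep_len(seq_len(config$n_rows), n)[sample.int(n)]
  row_eff <- stats::rnorm(config$n_rows, 0, sqrt(egg$sigma2_row))

  mu_w <- calibrate_potential_curve(weeks, egg)
  mu_peak <- mu_w[match(egg$peak_week, weeks)]
  if (is.na(mu_peak)) mu_peak <- max(mu_w)
  decline_w <- pmin(0, mu_w - mu_peak)

  # individual weekly potential (n x nw)
  C <- outer(g_lev + row_eff[row_assign], rep(1, nw)) +
    matrix(mu_w, n, nw, byrow = TRUE) + outer(g_per, decline_w)
  P_week <- pmin(pmax(C, 0), 7)      # expected eggs/week, capped

  # disturbance severity factor per hen-day
  Fmat <- matrix(1, n, nd)
  d <- egg$disturbance
  if (d$rate > 0) {
    n_ev <- stats::rpois(n, d$rate * nw)
    tot <- sum(n_ev)
    if (tot > 0) {
      ev_hen <- rep.int(seq_len(n), n_ev)
      ev_t0 <- sample.int(nd, tot, replace = TRUE)
      ev_depth <- stats::runif(tot, d$depth_min, d$depth_max)
      tau_d <- d$tau_weeks * 7
      horizon <- ceiling(-tau_d * log(0.001))     # truncate negligible tails
      for (e in seq_len(tot)) {
        t0 <- ev_t0[e]
        tt <- t0:min(nd, t0 + horizon)
        Fmat[ev_hen[e], tt] <- Fmat[ev_hen[e], tt] *
          (1 - ev_depth[e] * exp(-(tt - t0) / tau_d))
      }
    }
  }

  # death: constant weekly hazard, uniform day within the death week
  last_day <- rep.int(day_end, n)
  if (egg$hazard > 0) {
    dw <- stats::rgeom(n, egg$hazard)            # weeks survived from start
    died <- dw < nw
    if (any(died))
      last_day[died] <- day0 + 7L * dw[died] + sample.int(7L, sum(died),
                                                          replace = TRUE) - 1L
  }

  # daily Bernoulli lays
  week_of_day <- rep(seq_len(nw), each = 7L)
  Pday <- P_week[, week_of_day] / 7 * Fmat
  lay <- matrix(stats::rbinom(n * nd, 1L, Pday), n, nd)
  alive <- outer(last_day, day0:day_end, ">=")
  lay[!alive] <- 0L
  CS <- lay %*% upper.tri(diag(nd), diag = TRUE)  # running totals per hen

  # collection days
  if (!egg$allow_over7) {
    comps <- week_compositions()
    slots <- n * nw
    ci <- sample.int(length(comps), slots, replace = TRUE)
    lens <- lengths(comps)[ci]
    offs <- unlist(comps[ci], use.names = FALSE)
    rec_hen <- rep.int(rep.int(seq_len(n), rep.int(nw, n)), lens)
    wk_start <- rep.int(rep(7L * (weeks - 1L), times = n), lens)
    rec_day <- wk_start + unlist(lapply(comps[ci], cumsum),
                                 use.names = FALSE) - 1L
  } else {
    # free-running 1-4 day intervals from the start of recording
    per_hen <- lapply(seq_len(n), function(i) {
      dsum <- day0 - 1L
      days <- integer(0)
      while (dsum < day_end) {
        dsum <- min(dsum + sample.int(4L, 1L), day_end)
        days <- c(days, dsum)
      }
      days
    })
    rec_hen <- rep.int(seq_len(n), lengths(per_hen))
    rec_day <- unlist(per_hen, use.names = FALSE)
  }

  keep <- rec_day <= last_day[rec_hen]
  rec_hen <- rec_hen[keep]
  rec_day <- rec_day[keep]
  # terminal collection on the day of death if it is not already scheduled
  died_early <- which(last_day < day_end)
  if (length(died_early)) {
    has_final <- rec_hen %in% died_early &
      rec_day == last_day[rec_hen]
    covered <- unique(rec_hen[has_final])
    add <- setdiff(died_early, covered)
    if (length(add)) {
      rec_hen <- c(rec_hen, add)
      rec_day <- c(rec_day, last_day[add])
    }
  }
  ord <- order(rec_hen, rec_day)
  rec_hen <- rec_hen[ord]
  rec_day <- rec_day[ord]

  col_idx <- rec_day - day0 + 1L
  cs_val <- CS[cbind(rec_hen, col_idx)]
  first <- c(TRUE, rec_hen[-1L] != rec_hen[-length(rec_hen)])
  eggs <- cs_val - c(0, cs_val[-length(cs_val)])
  eggs[first] <- cs_val[first]

  list(
    log = data.frame(hen = hens[rec_hen], day = rec_day, eggs = as.integer(eggs),
                     stringsAsFactors = FALSE),
    life = data.frame(hen = hens, last_day = last_day,
                      stringsAsFactors = FALSE),
    rows = data.frame(hen = hens, row = row_assign, stringsAsFactors = FALSE)
  )
}
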