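#' Longitudinal tumor-burden series
#'
#' One animal's time-ordered burden measurements (bioluminescent units or
#' mm3) in one anatomical compartment, with the day treatment started and
#' an optional detection threshold for incidence calls.
#'
#' @param animal_id identifier
#' @param time numeric days, strictly increasing, >= 0
#' @param burden positive burden values, one per timepoint
#' @param treatment_start day treatment began; must not exceed the last
#'   observation
#' @param compartment `"cranial"`, `"extracranial"` or `"flank"`
#' @param detection_threshold burden units; needed by [incidence_call()]
#' @return a `BurdenSeries` list.
#' @export
BurdenSeries <- function(animal_id, time, burden, treatment_start,
                         compartment = c("cranial", "extracranial", "flank"),
                         detection_threshold = NA_real_) {
  compartment <- match.arg(compartment)
  if (length(time) != length(burden)) stop("time and burden lengths differ")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(time < 0)) stop("times must be >= 0")
  if (any(burden <= 0)) stop("burdens must be positive")
  if (treatment_start > max(time))
    stop("treatment_start lies beyond the observed range")
  structure(
    list(animal_id = animal_id, compartment = compartment,
         time = as.numeric(time), burden = as.numeric(burden),
         treatment_start = treatment_start,
         detection_threshold = detection_threshold),
    class = "BurdenSeries"
  )
}

#' @export
print.BurdenSeries <- function(x, ...) {
  cat(sprintf("BurdenSeries %s (%s): %d timepoints, days %g-%g, treatment day %g\n",
              x$animal_id, x$compartment, length(x$time),
              min(x$time), max(x$time), x$treatment_start))
  invisible(x)
}

burden_at <- function(series, day) {
  i <- match(day, series$time)
  if (is.na(i)) stop("day ", day, " not an observed timepoint")
  series$burden[i]
}

#' Percent burden change between two observed days
#'
#' `100 * (burden(t1) - burden(t0)) / burden(t0)`, the waterfall-plot
#' quantity.
#'
#' @param series a [BurdenSeries()]
#' @param t0,t1 observed timepoints (days)
#' @return percent change (negative = regression).
#' @export
percent_change <- function(series, t0, t1) {
  b0 <- burden_at(series, t0)
  100 * (burden_at(series, t1) - b0) / b0
}

#' Rescale a burden series to treatment Day 0
#'
#' Divides every burden by the burden at `treatment_start`, so the series
#' reads as fold change relative to the start of treatment. Idempotent.
#'
#' @param series a [BurdenSeries()] whose `treatment_start` is observed
#' @return the rescaled `BurdenSeries`.
#' @export
normalize_burden <- function(series) {
  ref <- burden_at(series, series$treatment_start)
  series$burden <- series$burden / ref
  if (!is.na(series$detection_threshold))
    series$detection_threshold <- series$detection_threshold / ref
  series
}

#' Trapezoidal area under the burden curve
#'
#' @param series a [BurdenSeries()]
#' @param from_day,to_day window bounds (defaults: full observed range);
#'   only observed timepoints inside the window are used, no
#'   interpolation at the bounds
#' @return the trapezoidal integral of burden over time.
#' @export
auc_trapezoid <- function(series, from_day = min(series$time),
                          to_day = max(series$time)) {
  keep <- series$time >= from_day & series$time <= to_day
  t <- series$time[keep]; b <- series$burden[keep]
  if (length(t) < 2L) stop("need at least 2 observations in the window")
  sum(diff(t) * (utils::head(b, -1) + utils::tail(b, -1)) / 2)
}

#' Mann-Whitney U test (two-sided)
#'
#' U is the number of (a, b) pairs with a > b, counting ties as 1/2.
#' The two-sided p-value is exact where feasible: computed from the exact
#' U distribution when the data are tie-free and `n_A * n_B <= 400`, or
#' by complete enumeration of group assignments when ties are present and
#' `choose(n_A + n_B, n_A) <= 2e5`; otherwise the normal approximation
#' with tie correction and continuity correction is used. Exactness is
#' reported in the result.
#'
#' @param group_a,group_b numeric vectors (nonempty)
#' @return list with `U` (for group A), `p`, `method`.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be nonempty")
  na <- length(group_a); nb <- length(group_b)
  u <- mw_u(group_a, group_b)
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0L

  if (!has_ties && na * nb <= 400) {
    # exact distribution of U under the null, tie-free
    p_lo <- stats::pwilcox(u, na, nb)
    p_hi <- stats::pwilcox(na * nb - u, na, nb)  # P(U >= u) by symmetry
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(U = u, p = p, method = "exact"))
  }
  if (has_ties && choose(na + nb, na) <= 2e5) {
    pooled <- c(group_a, group_b)
    dev_obs <- abs(u - na * nb / 2)
    combos <- utils::combn(na + nb, na)
    devs <- apply(combos, 2, function(ia) {
      abs(mw_u(pooled[ia], pooled[-ia]) - na * nb / 2)
    })
    p <- mean(devs >= dev_obs - 1e-9)
    return(list(U = u, p = p, method = "enumeration"))
  }
  pooled <- c(group_a, group_b)
  n <- na + nb
  ties <- table(pooled)
  sigma2 <- na * nb / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (abs(u - na * nb / 2) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(U = u, p = min(1, 2 * stats::pnorm(z, lower.tail = FALSE)),
       method = "normal_approx")
}

mw_u <- function(a, b) {
  cmp <- outer(a, b, function(x, y) (x > y) + 0.5 * (x == y))
  sum(cmp)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time event/censoring times (> 0)
#' @param event 1 = event, 0 = censored
#' @return data.frame `time, n_risk, n_event, survival` with one row per
#'   distinct event time; survival starts at 1 and is non-increasing.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("need at least one record")
  if (any(time <= 0)) stop("times must be positive")
  event <- as.integer(event)
  ev_times <- sort(unique(time[event == 1]))
  if (length(ev_times) == 0L)
    return(data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), surv = numeric(0)))
  n_risk <- vapply(ev_times, function(t) sum(time >= t), integer(1))
  n_event <- vapply(ev_times, function(t) sum(time == t & event == 1L),
                    integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
             surv = surv)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank statistic over pooled event
#' times, 1 degree of freedom.
#'
#' @param time event/censoring times
#' @param event 1 = event, 0 = censored
#' @param group two-level group labels
#' @return list with `chisq`, `p`, `observed` and `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required")
  if (any(table(group) == 0L)) stop("both groups must be nonempty")
  event <- as.integer(event)
  ev_times <- sort(unique(time[event == 1L]))
  if (length(ev_times) == 0L) {
    warning("no events in either group; log-rank p set to 1")
    return(list(chisq = 0, p = 1,
                observed = c(0, 0), expected = c(0, 0)))
  }
  g1 <- group == levels(group)[1]
  o1 <- e1 <- v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1L)
    d1 <- sum(time == t & event == 1L & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) (o1 - e1)^2 / v else 0
  total_d <- sum(event == 1L)
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = c(o1, total_d - o1),
       expected = c(e1, total_d - e1))
}

#' Progression-free survival call
#'
#' PFS event at the first observed post-treatment timepoint whose burden
#' reaches `ratio` (default 2.0, i.e. ~200%) times the last recorded
#' pre-treatment burden, inclusive; otherwise censored at the last
#' observation. The "~200%" convention is interpreted as exactly 2.0x.
#'
#' @param series a [BurdenSeries()] with at least one observation at or
#'   before `treatment_start`
#' @param ratio progression threshold as a multiple of the last
#'   pre-treatment burden
#' @return list with `time` (days), `event` (1 = progressed,
#'   0 = censored).
#' @export
pfs_time <- function(series, ratio = 2.0) {
  pre <- series$time <= series$treatment_start
  if (!any(pre)) stop("no pre-treatment observation")
  baseline <- series$burden[max(which(pre))]
  post <- which(series$time > series$treatment_start)
  hit <- post[series$burden[post] >= ratio * baseline]
  if (length(hit))
    list(time = series$time[hit[1]], event = 1L)
  else
    list(time = max(series$time), event = 0L)
}

#' Resistance-onset call
#'
#' The post-treatment nadir tracks the maximal drug response; an animal
#' is called resistant at the first observed timepoint whose burden is at
#' least `fold` (default 10) times the running nadir of post-treatment
#' burdens observed so far, inclusive.
#'
#' @param series a [BurdenSeries()] with at least one post-treatment
#'   observation
#' @param fold resistance threshold as a multiple of the running nadir
#' @return list with `time` (day of the call or NA), `resistant` flag and
#'   `nadir` (the running nadir at the call, or overall).
#' @export
resistance_time <- function(series, fold = 10) {
  post <- which(series$time >= series$treatment_start)
  if (length(post) == 0L) stop("no post-treatment observation")
  nadir <- Inf
  for (i in post) {
    nadir <- min(nadir, series$burden[i])
    if (series$burden[i] >= fold * nadir)
      return(list(time = series$time[i], resistant = TRUE, nadir = nadir))
  }
  list(time = NA_real_, resistant = FALSE, nadir = nadir)
}

#' Metastasis incidence call
#'
#' A site is scored incident at the first timepoint whose burden exceeds
#' the detection threshold and stays above it at the next two observed
#' timepoints (signal must persist through at least two subsequent
#' imaging sessions).
#'
#' @param series a [BurdenSeries()] with `detection_threshold` set
#' @return list with `incident` flag and `onset` day (NA if not
#'   incident).
#' @export
incidence_call <- function(series) {
  thr <- series$detection_threshold
  if (is.na(thr)) stop("detection_threshold not set")
  n <- length(series$time)
  if (n < 3L) {
    warning("fewer than 3 timepoints; incidence cannot persist")
    return(list(incident = FALSE, onset = NA_real_))
  }
  above <- series$burden > thr
  for (i in seq_len(n - 2L)) {
    if (above[i] && above[i + 1L] && above[i + 2L])
      return(list(incident = TRUE, onset = series$time[i]))
  }
  list(incident = FALSE, onset = NA_real_)
}

#' Caliper tumor volume
#'
#' `volume = major * minor^2 * 0.52` (mm3), the standard ellipsoid
#' approximation for flank tumors.
#'
#' @param major_mm,minor_mm caliper axes in mm (> 0); a minor axis larger
#'   than the major axis triggers a warning
#' @return volume in mm3 (vectorized).
#' @export
tumor_volume <- function(major_mm, minor_mm) {
  if (any(major_mm <= 0) || any(minor_mm <= 0))
    stop("axes must be positive")
  if (any(minor_mm > major_mm))
    warning("minor axis exceeds major axis; check caliper order")
  major_mm * minor_mm^2 * 0.52
}
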