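# Lognormal length-of-stay model and Little's-law arrival rate.

#' Lognormal length-of-stay distribution
#'
#' Constructs the lognormal law used to sample intensive-care lengths of stay
#' (LOS). `meanlog` and `sdlog` are the mean and standard deviation of
#' log-days (the "location" and "scale" of the lognormal). Continuous draws
#' are rounded up to whole days, so every sampled stay occupies at least one
#' daily census count.
#'
#' The defaults describe the study cohort of a high-volume paediatric cardiac
#' ICU: median raw stay `exp(1.114)` of about 3 days with a heavy right tail.
#'
#' @param meanlog Mean of log-days (location parameter).
#' @param sdlog Standard deviation of log-days (scale parameter), `>= 0`.
#' @return An object of class `"los_lognormal"`.
#' @seealso [fit_los()], [sample_stays()], [classify_stay()]
#' @examples
#' los <- los_lognormal()
#' los
#' median(exp(stats::rnorm(1e4, coef(los)[1], coef(los)[2])))  # ~ exp(1.114)
#' @export
los_lognormal <- function(meanlog = 1.114, sdlog = 1.085) {
  if (!is.numeric(meanlog) || length(meanlog) != 1L || !is.finite(meanlog))
    stop("`meanlog` must be a single finite number", call. = FALSE)
  if (!is.numeric(sdlog) || length(sdlog) != 1L || !is.finite(sdlog) || sdlog < 0)
    stop("`sdlog` must be a single finite number >= 0", call. = FALSE)
  structure(
    list(meanlog = as.numeric(meanlog), sdlog = as.numeric(sdlog),
         rounding = "ceiling"),
    class = "los_lognormal"
  )
}

#' @export
print.los_lognormal <- function(x, ...) {
  cat("Lognormal length-of-stay model\n")
  cat(sprintf("  location (meanlog): %.4f\n", x$meanlog))
  cat(sprintf("  scale    (sdlog)  : %.4f\n", x$sdlog))
  cat(sprintf("  raw median %.3f d, raw mean %.3f d; draws rounded up to whole days\n",
              exp(x$meanlog), exp(x$meanlog + x$sdlog^2 / 2)))
  invisible(x)
}

#' @export
coef.los_lognormal <- function(object, ...) {
  c(meanlog = object$meanlog, sdlog = object$sdlog)
}

#' Fit the lognormal stay-length law
#'
#' Maximum-likelihood fit of a lognormal distribution to observed lengths of
#' stay: the fitted location and scale are the mean and (population, i.e.
#' `n`-denominator) standard deviation of the log-transformed stays, the
#' closed-form MLE. No censoring correction is applied.
#'
#' @param stays Numeric vector of strictly positive stay lengths in days
#'   (need not be integer).
#' @return A [los_lognormal()] object with the fitted parameters.
#' @examples
#' set.seed(1)
#' fit_los(stats::rlnorm(5000, 1.114, 1.085))
#' @export
fit_los <- function(stays) {
  if (!is.numeric(stays) || length(stays) < 2L)
    stop("`stays` must be a numeric vector with at least 2 values", call. = FALSE)
  if (anyNA(stays) || any(stays <= 0))
    stop("all stay lengths must be strictly positive and non-missing", call. = FALSE)
  lx <- log(stays)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  if (sigma == 0)
    stop("degenerate fit: all stay lengths are identical", call. = FALSE)
  los_lognormal(mu, sigma)
}

#' Sample whole-day lengths of stay
#'
#' Draws `n` stays from the lognormal law and rounds each up to a whole
#' number of days (so every stay is an integer `>= 1`). Uses the current
#' R random-number state; seed externally for reproducibility.
#'
#' @param dist A [los_lognormal()] object.
#' @param n Number of stays to draw (`>= 0`).
#' @param raw If `TRUE`, return the continuous pre-rounding draws instead.
#' @return Integer vector of stays in days (or numeric if `raw = TRUE`).
#' @export
sample_stays <- function(dist, n, raw = FALSE) {
  stopifnot(inherits(dist, "los_lognormal"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    stop("`n` must be a single non-negative count", call. = FALSE)
  x <- stats::rlnorm(n, meanlog = dist$meanlog, sdlog = dist$sdlog)
  if (raw) return(x)
  # the epsilon keeps exact integers (e.g. a degenerate sdlog = 0 law) from
  # being pushed up a day by floating-point noise in exp()
  as.integer(pmax(1, ceiling(x - 1e-9)))
}

#' @rdname sample_stays
#' @param object A [los_lognormal()] object (for the [stats::simulate()]
#'   generic).
#' @param nsim Number of stays to draw.
#' @param seed Optional integer seed applied before drawing.
#' @param ... Unused.
#' @export
simulate.los_lognormal <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sample_stays(object, nsim)
}

#' Classify a stay as short or long
#'
#' Short stays (1-2 days) are the cases the anticipatory policy schedules
#' early in the week; everything of 3 or more days is long.
#'
#' @param days Integer vector of whole-day stays, each `>= 1`.
#' @return Character vector, `"short"` or `"long"`.
#' @export
classify_stay <- function(days) {
  if (length(days) == 0L) return(character(0))
  if (!is.numeric(days) || anyNA(days) || any(days < 1))
    stop("`days` must be whole-day stays >= 1", call. = FALSE)
  ifelse(days <= 2, "short", "long")
}

#' Little's-law arrival rate
#'
#' From the steady-state identity `L = lambda * W` (average occupancy equals
#' arrival rate times mean stay), the daily arrival rate supported by
#' `capacity` beds is `capacity / mean_stay`; the weekly rate multiplies by
#' the 5 operating days.
#'
#' @param capacity Average number of beds available to the arrival stream
#'   (`>= 0`).
#' @param mean_stay Mean length of stay in days (`> 0`).
#' @return Named numeric vector `c(daily, weekly)`.
#' @examples
#' littles_law_rate(25, 6.56)  # ~3.81 patients/day, ~19.1/week
#' @export
littles_law_rate <- function(capacity, mean_stay) {
  if (!is.numeric(capacity) || length(capacity) != 1L || is.na(capacity) || capacity < 0)
    stop("`capacity` must be a single number >= 0", call. = FALSE)
  if (!is.numeric(mean_stay) || length(mean_stay) != 1L || is.na(mean_stay) || mean_stay <= 0)
    stop("`mean_stay` must be a single number > 0", call. = FALSE)
  daily <- capacity / mean_stay
  c(daily = daily, weekly = 5 * daily)
}

#' Intensive-care unit configuration
#'
#' Physical beds minus the share historically occupied by non-surgical
#' (medical) patients gives the effective capacity available to the elective
#' surgical stream. Defaults describe a 31-bed unit with a 20% medical load
#' (25 effective beds) and a historical mean stay of 6.56 days.
#'
#' @param total_beds Physical bed count.
#' @param medical_fraction Proportion of capacity held by medical patients,
#'   in `[0, 1)`.
#' @param mean_historical_los Historical mean length of stay in days, used by
#'   [littles_law_rate()].
#' @return An object of class `"unit_config"` with an `effective_capacity`
#'   field (`round(total_beds * (1 - medical_fraction))`).
#' @export
unit_config <- function(total_beds = 31L, medical_fraction = 0.20,
                        mean_historical_los = 6.56) {
  if (!is.numeric(total_beds) || length(total_beds) != 1L || total_beds < 1)
    stop("`total_beds` must be a positive count", call. = FALSE)
  if (!is.numeric(medical_fraction) || length(medical_fraction) != 1L ||
      medical_fraction < 0 || medical_fraction >= 1)
    stop("`medical_fraction` must be in [0, 1)", call. = FALSE)
  if (!is.numeric(mean_historical_los) || length(mean_historical_los) != 1L ||
      mean_historical_los <= 0)
    stop("`mean_historical_los` must be > 0", call. = FALSE)
  eff <- as.integer(round(total_beds * (1 - medical_fraction)))
  if (eff < 1)
    stop("effective capacity must be at least 1 bed", call. = FALSE)
  structure(
    list(total_beds = as.integer(total_beds),
         medical_fraction = medical_fraction,
         effective_capacity = eff,
         mean_historical_los = mean_historical_los),
    class = "unit_config"
  )
}

#' @export
print.unit_config <- function(x, ...) {
  cat(sprintf("ICU unit: %d beds, %.0f%% medical load -> %d effective surgical beds; historical mean LOS %.2f d\n",
              x$total_beds, 100 * x$medical_fraction, x$effective_capacity,
              x$mean_historical_los))
  invisible(x)
}
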