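# Discrete-day admit/discharge ledger engine and cross-replication aggregation.

ALL_DAYS <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

#' Scenario specification
#'
#' One complete simulation experiment: a scheduling policy, an OR slot
#' template, a demand level, the unit configuration and the stay-length law,
#' plus replication settings. The simulated calendar starts the 365-day
#' horizon on a Monday; the warm-up days immediately precede it, letting the
#' unit fill to a natural occupancy before statistics are collected
#' (warm-up occupants persist into the measured year, warm-up days do not).
#'
#' @param policy `"random"` (uniform weekday choice, a proxy for current
#'   practice) or `"anticipatory"` (short stays early in the week).
#' @param template A [slot_template()], or a two-day vector passed to it.
#' @param occupancy_level Demand level as a proportion of weekly slot
#'   capacity (study levels: 0.76, 0.86, 0.90).
#' @param unit A [unit_config()].
#' @param los A [los_lognormal()] stay-length law.
#' @param replications Number of simulated years per scenario.
#' @param horizon_days Days in the measured year.
#' @param warmup_days Warm-up days preceding the measured year.
#' @param weekly_min Minimum weekly surgical demand (`a` of the discrete
#'   uniform).
#' @param annual_guard Total annual surgical availability; cumulative demand
#'   over the 52 full weeks of the year never exceeds it. Defaults to
#'   `52 * sum(template)`.
#' @param weighted_random Random-policy toggle: draw weekdays with
#'   probability proportional to free slots.
#' @param round_robin_long Anticipatory-policy toggle: rotate long stays over
#'   Wed/Thu/Fri instead of filling each day first.
#' @return An object of class `"scenario_spec"`.
#' @seealso [run_scenario()], [run_replication()]
#' @export
scenario_spec <- function(policy = c("random", "anticipatory"),
                          template = slot_template(),
                          occupancy_level = 0.76,
                          unit = unit_config(),
                          los = los_lognormal(),
                          replications = 500L,
                          horizon_days = 365L,
                          warmup_days = 30L,
                          weekly_min = 8L,
                          annual_guard = NULL,
                          weighted_random = FALSE,
                          round_robin_long = FALSE) {
  policy <- match.arg(policy)
  if (!inherits(template, "slot_template")) template <- slot_template(template)
  stopifnot(inherits(unit, "unit_config"), inherits(los, "los_lognormal"))
  if (replications < 1L || horizon_days < 1L || warmup_days < 0L)
    stop("need replications >= 1, horizon_days >= 1, warmup_days >= 0",
         call. = FALSE)
  if (is.null(annual_guard)) annual_guard <- 52L * sum(template)
  demand <- demand_model(occupancy_level, template, weekly_min, annual_guard)
  structure(
    list(policy = policy, template = template,
         occupancy_level = occupancy_level, unit = unit, los = los,
         demand = demand,
         replications = as.integer(replications),
         horizon_days = as.integer(horizon_days),
         warmup_days = as.integer(warmup_days),
         weighted_random = isTRUE(weighted_random),
         round_robin_long = isTRUE(round_robin_long)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario: %s policy, extra slots %s, occupancy %.0f%%\n",
              x$policy, paste(attr(x$template, "extra_pair"), collapse = "+"),
              100 * x$occupancy_level))
  print(x$unit)
  print(x$demand)
  cat(sprintf("  LOS lognormal(%.3f, %.3f); %d replications of %d d + %d d warm-up\n",
              x$los$meanlog, x$los$sdlog, x$replications, x$horizon_days,
              x$warmup_days))
  invisible(x)
}

#' Advance the census by one day
#'
#' Discharges leave first; arrivals are then admitted while the census stays
#' within capacity, and any arrival that would push it over is canceled
#' (counted once, not rescheduled).
#'
#' @param census_before Occupied beds at the end of the previous day.
#' @param discharges_due Patients whose stay ends today (`<= census_before`).
#' @param arrivals Surgical patients scheduled to arrive today.
#' @param capacity Effective bed capacity.
#' @return List with `census_after`, `admitted`, `canceled`.
#' @examples
#' step_day(24, 2, 3, 25)  # all three admitted, unit full
#' step_day(25, 0, 2, 25)  # both canceled
#' @export
step_day <- function(census_before, discharges_due, arrivals, capacity) {
  v <- c(census_before, discharges_due, arrivals, capacity)
  if (anyNA(v) || any(v < 0))
    stop("all step_day inputs must be non-negative", call. = FALSE)
  if (discharges_due > census_before)
    stop("internal consistency error: more discharges due than occupants",
         call. = FALSE)
  canceled <- max(0, census_before - discharges_due + arrivals - capacity)
  admitted <- arrivals - canceled
  census_after <- census_before - discharges_due + admitted
  list(census_after = census_after, admitted = admitted, canceled = canceled)
}

# One simulated year (plus warm-up), using the current RNG state.
#
# Weekly sampling order is fixed (demand -> stays -> assignment) so runs are
# replayable. Scheduling is independent of the census: canceled patients are
# dropped, never rescheduled, so the weekly pool evolves only through slot
# availability. The ledger pass then admits each day's arrivals in assignment
# order until capacity is reached.
.simulate_replication <- function(spec, collect_patients = FALSE) {
  warmup <- spec$warmup_days
  horizon <- spec$horizon_days
  first_day <- 1L - warmup
  ndays <- warmup + horizon
  capacity <- spec$unit$effective_capacity
  dm <- spec$demand
  template <- spec$template
  n_weeks <- as.integer(ceiling(horizon / 7))     # demand generated for these
  n_full <- as.integer(horizon %/% 7)             # guard applies to these
  # first week whose Monday falls inside the simulated window
  w_first <- as.integer(ceiling((first_day - 1) / 7) + 1)

  assign_fun <-
    if (spec$policy == "random") {
      function(pool) assign_random(pool, template, spec$weighted_random)
    } else {
      function(pool) assign_anticipatory(pool, template, spec$round_robin_long)
    }

  maxpat <- (n_weeks - w_first + 1L) * (dm$b + 1L) + 64L
  p_day <- integer(maxpat)
  p_stay <- integer(maxpat)
  p_week <- integer(maxpat)
  np <- 0L
  pool <- integer(0)
  pool_week <- integer(0)
  guard_remaining <- dm$annual_guard
  demand_year <- 0L
  demand_full_weeks <- 0L
  pool_carry_in <- 0L

  dm_a <- dm$a
  dm_span <- dm$b - dm$a + 1L
  meanlog <- spec$los$meanlog
  sdlog <- spec$los$sdlog
  for (w in w_first:n_weeks) {
    if (w == 1L) pool_carry_in <- length(pool)
    guarded <- w >= 1L && w <= n_full
    # same draws as sample_weekly_demand() / sample_stays(), inlined
    d <- dm_a + sample.int(dm_span, 1L) - 1L
    if (guarded) {
      d <- as.integer(min(d, guard_remaining))
      guard_remaining <- guard_remaining - d
      demand_full_weeks <- demand_full_weeks + d
    }
    if (w >= 1L) demand_year <- demand_year + d
    stays_new <- as.integer(pmax(1, ceiling(stats::rlnorm(d, meanlog, sdlog) - 1e-9)))
    pool <- c(pool, stays_new)
    pool_week <- c(pool_week, rep.int(w, d))
    asn <- assign_fun(pool)
    assigned <- !is.na(asn$day)
    k <- sum(assigned)
    if (k > 0L) {
      idx <- np + seq_len(k)
      p_day[idx] <- (w - 1L) * 7L + asn$day[assigned]
      p_stay[idx] <- pool[assigned]
      p_week[idx] <- w
      np <- np + k
    }
    pool <- pool[!assigned]
    pool_week <- pool_week[!assigned]
  }

  pd <- p_day[seq_len(np)]
  ps <- p_stay[seq_len(np)]
  pw <- p_week[seq_len(np)]
  post_horizon <- sum(pd > horizon)

  # ledger pass over the in-window arrivals, in day-then-assignment order
  inh <- pd <= horizon
  di <- pd[inh] - first_day + 1L
  ord <- order(di)                       # stable: within-day order preserved
  di_s <- di[ord]
  stay_s <- ps[inh][ord]
  counts <- tabulate(di_s, nbins = ndays)
  pstart <- c(0L, cumsum(counts))
  maxstay <- if (length(stay_s) > 0L) max(stay_s) else 1L
  dep <- integer(ndays + maxstay + 1L)
  cen <- integer(ndays)
  adm <- integer(ndays)
  canc <- integer(ndays)
  disc <- integer(ndays)
  admitted_flag <- logical(length(di_s))
  census <- 0L

  for (i in seq_len(ndays)) {
    census <- census - dep[i]
    disc[i] <- dep[i]
    ai <- counts[i]
    if (ai > 0L) {
      freeb <- capacity - census
      admitted <- if (ai <= freeb) ai else freeb
      if (admitted > 0L) {
        js <- pstart[i] + seq_len(admitted)
        dd <- i + stay_s[js]
        for (d1 in dd) dep[d1] <- dep[d1] + 1L
        census <- census + admitted
        admitted_flag[js] <- TRUE
      }
      adm[i] <- admitted
      canc[i] <- ai - admitted
    }
    cen[i] <- census
  }

  yr <- (warmup + 1L):ndays
  out <- list(
    day = first_day:horizon,
    weekday = ALL_DAYS[((first_day:horizon) - 1L) %% 7L + 1L],
    arrivals = counts, admitted = adm, discharged = disc,
    census = cen, canceled = canc,
    census_year = cen[yr],
    counters = list(
      demand_year = demand_year,
      demand_full_weeks = demand_full_weeks,
      pool_carry_in = pool_carry_in,
      pool_end = length(pool),
      post_horizon = post_horizon,
      admitted_year = sum(adm[yr]),
      canceled_year = sum(canc[yr])
    )
  )

  if (collect_patients) {
    status <- character(np)
    status[pd > horizon] <- "waiting"
    stat_in <- ifelse(admitted_flag, "admitted", "canceled")
    # map sorted in-window order back to assignment order
    tmp <- character(sum(inh))
    tmp[ord] <- stat_in
    status[inh] <- tmp
    pat <- data.frame(
      id = seq_len(np + length(pool)),
      arrival_week = c(pw, pool_week),
      stay_days = c(ps, pool),
      stay_class = classify_stay(c(ps, pool)),
      assigned_day = c(ALL_DAYS[(pd - 1L) %% 7L + 1L], rep(NA_character_, length(pool))),
      arrival_day = c(pd, rep(NA_integer_, length(pool))),
      status = c(status, rep("waiting", length(pool))),
      stringsAsFactors = FALSE
    )
    out$patients <- pat
  }
  out
}

#' Run one replication and return its daily ledger
#'
#' Simulates the warm-up followed by the measured year under a fixed seed and
#' returns the day-by-day ledger. Day 1 is the Monday that opens the measured
#' year; warm-up days carry negative/zero day indices. Per-patient outcomes
#' and annual accounting counters are attached as attributes.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed for this replication.
#' @return A `data.frame` (one row per simulated day, warm-up included) with
#'   columns `day`, `weekday`, `arrivals`, `admitted`, `discharged`,
#'   `census`, `canceled`, and attributes `patients` (per-patient outcome
#'   table) and `counters` (annual accounting: demand, admitted, canceled,
#'   carried pool sizes).
#' @examples
#' led <- run_replication(scenario_spec(), seed = 42)
#' head(led[led$day >= 1, ])
#' attr(led, "counters")$canceled_year
#' @export
run_replication <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(seed)
  sim <- .simulate_replication(spec, collect_patients = TRUE)
  led <- data.frame(
    day = sim$day, weekday = sim$weekday, arrivals = sim$arrivals,
    admitted = sim$admitted, discharged = sim$discharged,
    census = sim$census, canceled = sim$canceled,
    stringsAsFactors = FALSE
  )
  attr(led, "patients") <- sim$patients
  attr(led, "counters") <- sim$counters
  attr(led, "seed") <- seed
  led
}

#' Run a scenario and aggregate its replications
#'
#' Repeats the one-year simulation over independent replications (each with
#' its own seed derived from the master seed) and aggregates: per-weekday
#' mean and SD of the end-of-day census (pooled over all occurrences of that
#' weekday in the measured year and over replications), mean annual
#' cancellations and the cancellation percentage (relative to mean annual
#' demand), and mean annual admissions.
#'
#' @param spec A [scenario_spec()].
#' @param seed Master seed from which per-replication seeds are derived.
#' @param rep_seeds Optional explicit vector of per-replication seeds
#'   (length `spec$replications`); used for common-random-number comparisons
#'   across scenarios.
#' @return An object of class `"scenario_summary"`.
#' @examples
#' s <- run_scenario(scenario_spec(replications = 20), seed = 1)
#' s
#' @export
run_scenario <- function(spec, seed = 1L, rep_seeds = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  R <- spec$replications
  if (is.null(rep_seeds)) {
    set.seed(seed)
    rep_seeds <- sample.int(2147483646L, R)
  }
  if (length(rep_seeds) != R)
    stop("`rep_seeds` must have one seed per replication", call. = FALSE)

  wd_idx <- ((seq_len(spec$horizon_days) - 1L) %% 7L) + 1L
  wd_at <- split(seq_len(spec$horizon_days), wd_idx)
  wsum <- numeric(7)
  wsumsq <- numeric(7)
  wn <- integer(7)
  canc <- numeric(R)
  admv <- numeric(R)
  demv <- numeric(R)
  for (r in seq_len(R)) {
    set.seed(rep_seeds[r])
    sim <- .simulate_replication(spec)
    cs <- sim$census_year
    for (k in 1:7) {
      v <- cs[wd_at[[k]]]
      wsum[k] <- wsum[k] + sum(v)
      wsumsq[k] <- wsumsq[k] + sum(v * v)
      wn[k] <- wn[k] + length(v)
    }
    canc[r] <- sim$counters$canceled_year
    admv[r] <- sim$counters$admitted_year
    demv[r] <- sim$counters$demand_year
  }
  wmean <- wsum / wn
  wsd <- sqrt(pmax(0, (wsumsq - wn * wmean^2) / (wn - 1)))
  names(wmean) <- names(wsd) <- ALL_DAYS

  structure(
    list(
      weekday_mean = wmean,
      weekday_sd = wsd,
      annual_cancellations = mean(canc),
      cancellation_pct = 100 * mean(canc) / mean(demv),
      annual_admissions = mean(admv),
      annual_demand = mean(demv),
      replications = R,
      reps = data.frame(cancellations = canc, admissions = admv,
                        demand = demv),
      spec = spec, seed = seed
    ),
    class = "scenario_summary"
  )
}

#' @export
print.scenario_summary <- function(x, digits = 2, ...) {
  sp <- x$spec
  cat(sprintf("Scenario summary: %s policy, extra %s, occupancy %.0f%% (%d replications)\n",
              sp$policy, paste(attr(sp$template, "extra_pair"), collapse = "+"),
              100 * sp$occupancy_level, x$replications))
  m <- rbind(mean = x$weekday_mean, sd = x$weekday_sd)
  print(round(m, digits))
  cat(sprintf("Annual: %.1f admissions, %.1f cancellations (%.1f%% of %.0f demanded)\n",
              x$annual_admissions, x$annual_cancellations,
              x$cancellation_pct, x$annual_demand))
  invisible(x)
}

#' @export
summary.scenario_summary <- function(object, ...) {
  sp <- weekday_spread(object$weekday_mean[1:5])
  c(
    weekday_mean_mon_fri = unname(sp["mean"]),
    weekday_sd_mon_fri = unname(sp["sd"]),
    annual_admissions = object$annual_admissions,
    annual_cancellations = object$annual_cancellations,
    cancellation_pct = object$cancellation_pct
  )
}

#' @export
plot.scenario_summary <- function(x, ...) {
  m <- x$weekday_mean[1:5]
  s <- x$weekday_sd[1:5]
  graphics::plot(1:5, m, type = "b", pch = 16, xaxt = "n",
                 xlab = "Weekday", ylab = "Mean end-of-day census",
                 ylim = range(c(m - s, m + s)), ...)
  graphics::axis(1, at = 1:5, labels = WEEKDAYS)
  graphics::arrows(1:5, m - s, 1:5, m + s, angle = 90, code = 3,
                   length = 0.04, col = "grey40")
  invisible(x)
}

#' Mean and spread of the five weekday census means
#'
#' Summarises a Mon-Fri census profile by its arithmetic mean and sample
#' standard deviation (n - 1 denominator); the SD measures weekday census
#' variation, the quantity schedule smoothing aims to reduce.
#'
#' @param weekday_means Exactly five values (Monday..Friday).
#' @return Named numeric vector `c(mean, sd)`.
#' @examples
#' weekday_spread(c(14.31, 16.94, 19.24, 19.43, 19.45))
#' @export
weekday_spread <- function(weekday_means) {
  if (!is.numeric(weekday_means) || length(weekday_means) != 5L)
    stop("`weekday_means` must contain exactly five values (Mon-Fri)",
         call. = FALSE)
  c(mean = mean(weekday_means), sd = stats::sd(weekday_means))
}
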