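# Weekly surgical demand, the waiting pool, and slot assignment policies.

WEEKDAYS <- c("Mon", "Tue", "Wed", "Thu", "Fri")

.match_weekday <- function(day) {
  i <- match(tolower(substr(day, 1, 3)), tolower(WEEKDAYS))
  if (anyNA(i))
    stop("weekday must be one of ", paste(WEEKDAYS, collapse = ", "),
         " (no weekend elective surgery)", call. = FALSE)
  i
}

#' Operating-room slot template
#'
#' Weekday elective-surgery capacity: 5 procedures every weekday, with 2
#' additional procedures on a chosen pair of days (7 there), for a weekly
#' total of 29. Weekends carry no elective slots.
#'
#' @param extra_days Two distinct weekdays (`"Mon"`..`"Fri"`, full names
#'   accepted) that receive the two extra daily procedures. The default
#'   `c("Tue", "Wed")` is the current allocation of the modelled centre.
#' @return An object of class `"slot_template"`: a named integer vector
#'   (Mon..Fri) with attribute `extra_pair`.
#' @examples
#' slot_template()                  # [5,7,7,5,5]
#' slot_template(c("Mon", "Fri"))   # [7,5,5,5,7]
#' @export
slot_template <- function(extra_days = c("Tue", "Wed")) {
  if (length(extra_days) != 2L)
    stop("`extra_days` must name exactly two weekdays", call. = FALSE)
  idx <- .match_weekday(extra_days)
  if (idx[1] == idx[2])
    stop("the two extra days must be distinct", call. = FALSE)
  slots <- rep(5L, 5L)
  slots[idx] <- 7L
  names(slots) <- WEEKDAYS
  structure(slots, extra_pair = WEEKDAYS[sort(idx)], class = "slot_template")
}

#' @export
print.slot_template <- function(x, ...) {
  cat("OR slot template (procedures/day):\n")
  print(stats::setNames(as.integer(x), names(x)))
  cat(sprintf("  extra pair: %s; weekly total %d\n",
              paste(attr(x, "extra_pair"), collapse = "+"), sum(x)))
  invisible(x)
}

#' Calibrate the weekly demand upper bound
#'
#' Weekly surgical demand is drawn from a discrete uniform on `[a, b]`. The
#' upper bound is chosen so the expected weekly demand `(a + b) / 2` equals
#' the target occupancy level times the weekly slot capacity:
#' `b = round(2 * occupancy_level * sum(template) - a)`, clamped to `b >= a`.
#'
#' @param occupancy_level Demand level as a proportion of weekly slot
#'   capacity, in `(0, 1]` (the study uses 0.76, 0.86, 0.90).
#' @param template A [slot_template()] (only its weekly total matters).
#' @param a Minimum weekly demand (default 8).
#' @return Integer upper bound `b`.
#' @examples
#' calibrate_weekly_bound(0.76, slot_template())  # 36
#' calibrate_weekly_bound(0.90, slot_template())  # 44
#' @export
calibrate_weekly_bound <- function(occupancy_level, template = slot_template(),
                                   a = 8L) {
  if (!is.numeric(occupancy_level) || length(occupancy_level) != 1L ||
      occupancy_level <= 0 || occupancy_level > 1)
    stop("`occupancy_level` must be in (0, 1]", call. = FALSE)
  if (!is.numeric(a) || length(a) != 1L || a < 0)
    stop("`a` must be a non-negative count", call. = FALSE)
  b <- as.integer(round(2 * occupancy_level * sum(template) - a))
  if (b < a) {
    warning("occupancy level too low for minimum weekly demand; clamping b = a",
            call. = FALSE)
    b <- as.integer(a)
  }
  b
}

#' Weekly demand model
#'
#' Bundles the discrete-uniform demand bounds with the annual availability
#' guard: cumulative sampled demand over the 52 full weeks of a simulated
#' year may never exceed `annual_guard` (the total annual surgical
#' availability, 52 weeks x 29 slots = 1508 by default).
#'
#' @inheritParams calibrate_weekly_bound
#' @param annual_guard Total annual surgical availability.
#' @return An object of class `"demand_model"` with fields `a`, `b`,
#'   `occupancy_level`, `annual_guard`.
#' @export
demand_model <- function(occupancy_level = 0.76, template = slot_template(),
                         a = 8L, annual_guard = 52L * sum(template)) {
  b <- calibrate_weekly_bound(occupancy_level, template, a)
  structure(
    list(a = as.integer(a), b = b, occupancy_level = occupancy_level,
         annual_guard = as.integer(annual_guard)),
    class = "demand_model"
  )
}

#' @export
print.demand_model <- function(x, ...) {
  cat(sprintf(
    "Weekly demand ~ DiscreteUniform[%d, %d] (mean %.2f, occupancy %.0f%%), annual guard %d\n",
    x$a, x$b, (x$a + x$b) / 2, 100 * x$occupancy_level, x$annual_guard))
  invisible(x)
}

#' Sample one week of surgical demand
#'
#' Draws from the discrete uniform on `[a, b]` and truncates to the remaining
#' annual availability, so the guard is never violated.
#'
#' @param model A [demand_model()].
#' @param guard_remaining Annual availability still unclaimed (`Inf` for an
#'   unguarded week).
#' @return Integer demand for the week.
#' @export
sample_weekly_demand <- function(model, guard_remaining = Inf) {
  stopifnot(inherits(model, "demand_model"))
  if (is.na(guard_remaining) || guard_remaining < 0)
    stop("`guard_remaining` must be >= 0", call. = FALSE)
  if (model$a > model$b)
    stop("demand model has a > b", call. = FALSE)
  d <- model$a + sample.int(model$b - model$a + 1L, 1L) - 1L
  as.integer(min(d, guard_remaining))
}

#' Assign waiting patients to weekday slots at random
#'
#' The random policy, a proxy for preference-driven scheduling: patients are
#' taken in waiting-pool (FIFO) order and each is placed on a weekday drawn
#' uniformly among the days that still have a free slot. Patients left over
#' when all 29 slots are taken stay in the pool for the next week.
#'
#' @param stays Integer vector of the waiting pool's stay lengths, in pool
#'   order.
#' @param template A [slot_template()].
#' @param weighted If `TRUE`, weekdays are drawn with probability
#'   proportional to their remaining free slots instead of uniformly.
#' @return List with `day` (integer weekday index 1..5 per patient, `NA` if
#'   the patient stays waiting) and `free` (remaining slots per weekday).
#' @export
assign_random <- function(stays, template = slot_template(), weighted = FALSE) {
  n <- length(stays)
  free <- as.integer(template)
  day <- rep(NA_integer_, n)
  n_place <- min(n, sum(free))
  if (n_place == 0L) return(list(day = day, free = free))
  if (weighted) {
    for (i in seq_len(n_place)) {
      avail <- which(free > 0L)
      d <- if (length(avail) == 1L) avail
           else avail[sample.int(length(avail), 1L, prob = free[avail])]
      day[i] <- d
      free[d] <- free[d] - 1L
    }
    return(list(day = day, free = free))
  }
  avail <- which(free > 0L)
  k <- length(avail)
  u <- stats::runif(n_place)  # one draw per placed patient
  for (i in seq_len(n_place)) {
    j <- floor(u[i] * k) + 1L  # uniform over the currently available days
    d <- avail[j]
    day[i] <- d
    free[d] <- free[d] - 1L
    if (free[d] == 0L) {
      avail <- avail[avail != d]
      k <- k - 1L
    }
  }
  list(day = day, free = free)
}

#' Assign waiting patients anticipatorily by expected stay
#'
#' The anticipatory policy: short-stay cases (1-2 days) are scheduled early
#' in the week — Monday first, then Tuesday — so they can be discharged
#' before the weekend; long-stay cases are clustered late — Wednesday, then
#' Thursday, then Friday — and are expected to stay over the weekend. Each
#' class spills into the other's days only when its own are full (shorts
#' spill Wed->Fri; longs spill Tue then Mon). The pool is processed in FIFO
#' order, so within each class pool order is preserved.
#'
#' @inheritParams assign_random
#' @param round_robin_long If `TRUE`, long-stay cases rotate over
#'   Wed/Thu/Fri instead of filling each day before moving to the next.
#' @return As [assign_random()].
#' @export
assign_anticipatory <- function(stays, template = slot_template(),
                                round_robin_long = FALSE) {
  n <- length(stays)
  free <- as.integer(template)
  day <- rep(NA_integer_, n)
  short_pref <- c(1L, 2L, 3L, 4L, 5L)
  long_pref <- c(3L, 4L, 5L, 2L, 1L)
  rr <- 0L  # rotating offset over Wed/Thu/Fri for round-robin long fill
  total_free <- sum(free)
  for (i in seq_len(n)) {
    if (total_free == 0L) break
    if (stays[i] <= 2L) {
      pref <- short_pref
    } else if (round_robin_long) {
      late <- c(3L, 4L, 5L)[(rr + 0:2) %% 3L + 1L]
      pref <- c(late, 2L, 1L)
    } else {
      pref <- long_pref
    }
    d <- pref[free[pref] > 0L][1]
    day[i] <- d
    free[d] <- free[d] - 1L
    total_free <- total_free - 1L
    if (stays[i] > 2L && round_robin_long && d >= 3L) rr <- rr + 1L
  }
  list(day = day, free = free)
}
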