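# Naive patient-state re-simulation used as an independent oracle for the
# ledger engine: every day it scans the full patient list, discharges whoever
# is due, then admits that day's arrivals one by one while a bed is free.
# Deliberately shares no code or data structures with the engine's
# tabulate/cumsum ledger pass.
naive_ledger <- function(arrival_day, stay, capacity, first_day, last_day) {
  n <- length(arrival_day)
  in_unit <- rep(FALSE, n)
  leave_on <- rep(NA_integer_, n)
  census <- 0L
  out <- data.frame(day = first_day:last_day, arrivals = 0L, admitted = 0L,
                    discharged = 0L, census = 0L, canceled = 0L)
  for (r in seq_len(nrow(out))) {
    t <- out$day[r]
    leaving <- which(in_unit & leave_on == t)
    in_unit[leaving] <- FALSE
    census <- census - length(leaving)
    out$discharged[r] <- length(leaving)
    todays <- which(arrival_day == t)
    out$arrivals[r] <- length(todays)
    for (p in todays) {
      if (census < capacity) {
        census <- census + 1L
        in_unit[p] <- TRUE
        leave_on[p] <- t + stay[p]
        out$admitted[r] <- out$admitted[r] + 1L
      } else {
        out$canceled[r] <- out$canceled[r] + 1L
      }
    }
    out$census[r] <- census
  }
  out
}

# A small scenario that forces congestion: few beds, short horizon.
tiny_congested_spec <- function(...) {
  suppressWarnings(scenario_spec(
    unit = unit_config(total_beds = 5, medical_fraction = 0.2),
    replications = 1L, horizon_days = 14L, warmup_days = 0L,
    weekly_min = 5L, occupancy_level = 0.15, ...
  ))
}
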