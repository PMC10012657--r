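# Day-pair search for the two extra OR slots and the 4-model comparison grid.

#' Enumerate candidate day pairs for the extra slots
#'
#' All `choose(5, 2) = 10` unordered pairs of weekdays Monday-Friday, in
#' lexicographic weekday order.
#'
#' @return A 10 x 2 character matrix of weekday pairs.
#' @export
enumerate_pairs <- function() {
  t(utils::combn(WEEKDAYS, 2L))
}

#' Pick the optimal day pair by the min-max range criterion
#'
#' For each candidate pair, the scenario's five weekday census means and five
#' weekday census SDs are reduced to their ranges (max minus min); the
#' optimal pair has the smallest mean-range, with ties broken by the smallest
#' SD-range and then by lexicographic pair order. A small range means the
#' census is level across the week - the smoothing objective.
#'
#' @param summaries List of ten [run_scenario()] summaries, one per pair in
#'   `pairs` order, all at the same policy and occupancy.
#' @param pairs 10 x 2 weekday matrix as from [enumerate_pairs()].
#' @return An object of class `"pair_search"`: a results table plus
#'   `optimal_pair`.
#' @export
range_criterion <- function(summaries, pairs = enumerate_pairs()) {
  if (length(summaries) != nrow(pairs))
    stop("need exactly one summary per candidate pair", call. = FALSE)
  mean_range <- vapply(summaries, function(s) {
    m <- s$weekday_mean[1:5]; max(m) - min(m)
  }, numeric(1))
  sd_range <- vapply(summaries, function(s) {
    m <- s$weekday_sd[1:5]; max(m) - min(m)
  }, numeric(1))
  best <- order(mean_range, sd_range, seq_along(mean_range))[1]
  tab <- data.frame(
    day1 = pairs[, 1], day2 = pairs[, 2],
    mean_range = mean_range, sd_range = sd_range,
    optimal = seq_along(mean_range) == best,
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, optimal_pair = unname(pairs[best, ]),
         summaries = summaries),
    class = "pair_search"
  )
}

#' Search all ten extra-slot day pairs
#'
#' Runs the scenario once per candidate pair of extra-slot days and applies
#' [range_criterion()]. By default all pairs share the same per-replication
#' seeds (common random numbers), so ranking differences reflect the slot
#' allocation rather than sampling noise.
#'
#' @param policy `"random"` or `"anticipatory"`.
#' @param occupancy_level Demand level; the search is defined at 0.76.
#' @param replications Simulated years per pair.
#' @param seed Master seed.
#' @param common_random_numbers Share replication seeds across pairs.
#' @param ... Further arguments to [scenario_spec()].
#' @return A `"pair_search"` object (see [range_criterion()]).
#' @examples
#' \donttest{
#' pair_search("anticipatory", replications = 100, seed = 1)$optimal_pair
#' }
#' @export
pair_search <- function(policy = c("random", "anticipatory"),
                        occupancy_level = 0.76, replications = 500L,
                        seed = 1L, common_random_numbers = TRUE, ...) {
  policy <- match.arg(policy)
  pairs <- enumerate_pairs()
  set.seed(seed)
  seed_mat <- matrix(sample.int(2147483646L, replications * nrow(pairs)),
                     ncol = nrow(pairs))
  summaries <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    spec <- scenario_spec(policy = policy,
                          template = slot_template(pairs[i, ]),
                          occupancy_level = occupancy_level,
                          replications = replications, ...)
    rs <- if (common_random_numbers) seed_mat[, 1] else seed_mat[, i]
    summaries[[i]] <- run_scenario(spec, rep_seeds = rs)
  }
  out <- range_criterion(summaries, pairs)
  out$policy <- policy
  out$occupancy_level <- occupancy_level
  out
}

#' @export
print.pair_search <- function(x, digits = 3, ...) {
  if (!is.null(x$policy))
    cat(sprintf("Extra-slot day-pair search (%s policy, occupancy %.0f%%)\n",
                x$policy, 100 * x$occupancy_level))
  tab <- x$table
  tab$mean_range <- round(tab$mean_range, digits)
  tab$sd_range <- round(tab$sd_range, digits)
  print(tab, row.names = FALSE)
  cat("Optimal pair:", paste(x$optimal_pair, collapse = " + "), "\n")
  invisible(x)
}

#' Percentage reduction in cancellations between two scenarios
#'
#' @param from,to Mean annual cancellation counts of the baseline and the
#'   alternative.
#' @return Percentage reduction `100 * (from - to) / from`.
#' @examples
#' cancellation_reduction(8.4, 3.6)  # 57.1
#' @export
cancellation_reduction <- function(from, to) {
  if (any(from <= 0)) stop("baseline cancellations must be > 0", call. = FALSE)
  100 * (from - to) / from
}

#' Compare the four scheduling models across occupancy levels
#'
#' The comparison grid of the study: Model 1A (random policy, extra slots on
#' the current Tue+Wed), 1B (random, extra on Mon+Fri - its optimal pair),
#' 2A (anticipatory, Tue+Wed) and 2B (anticipatory, Wed+Thu - its optimal
#' pair), each at the requested occupancy levels, plus the percentage
#' cancellation reductions of 2A, 1B and 2B relative to baseline 1A.
#'
#' @param occupancy_levels Demand levels to evaluate.
#' @param replications Simulated years per cell.
#' @param seed Master seed.
#' @param common_random_numbers Share replication seeds across cells.
#' @param ... Further arguments to [scenario_spec()].
#' @return An object of class `"model_comparison"` with a `grid` data frame
#'   (one row per model x occupancy), a `reductions` data frame, and the
#'   underlying summaries.
#' @examples
#' \donttest{
#' cmp <- compare_models(0.76, replications = 100, seed = 1)
#' cmp$grid
#' }
#' @export
compare_models <- function(occupancy_levels = c(0.76, 0.86, 0.90),
                           replications = 500L, seed = 1L,
                           common_random_numbers = TRUE, ...) {
  models <- list(
    `1A` = list(policy = "random", extra = c("Tue", "Wed")),
    `1B` = list(policy = "random", extra = c("Mon", "Fri")),
    `2A` = list(policy = "anticipatory", extra = c("Tue", "Wed")),
    `2B` = list(policy = "anticipatory", extra = c("Wed", "Thu"))
  )
  set.seed(seed)
  n_cells <- length(models) * length(occupancy_levels)
  seed_mat <- matrix(sample.int(2147483646L, replications * n_cells),
                     ncol = n_cells)
  grid <- expand.grid(model = names(models), occupancy = occupancy_levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  summaries <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    mod <- models[[grid$model[i]]]
    spec <- scenario_spec(policy = mod$policy,
                          template = slot_template(mod$extra),
                          occupancy_level = grid$occupancy[i],
                          replications = replications, ...)
    rs <- if (common_random_numbers) seed_mat[, 1] else seed_mat[, i]
    s <- run_scenario(spec, rep_seeds = rs)
    summaries[[i]] <- s
    rows[[i]] <- data.frame(
      model = grid$model[i], occupancy = grid$occupancy[i],
      policy = mod$policy, extra_pair = paste(mod$extra, collapse = "+"),
      cancellations = s$annual_cancellations,
      cancellation_pct = s$cancellation_pct,
      admissions = s$annual_admissions,
      census_weekday_sd = unname(weekday_spread(s$weekday_mean[1:5])["sd"]),
      stringsAsFactors = FALSE
    )
  }
  gridtab <- do.call(rbind, rows)
  red <- do.call(rbind, lapply(occupancy_levels, function(occ) {
    g <- gridtab[gridtab$occupancy == occ, ]
    base <- g$cancellations[g$model == "1A"]
    data.frame(
      occupancy = occ,
      comparison = c("1A->2A", "1A->1B", "1A->2B"),
      reduction_pct = cancellation_reduction(
        base, g$cancellations[match(c("2A", "1B", "2B"), g$model)]),
      stringsAsFactors = FALSE
    )
  }))
  structure(
    list(grid = gridtab, reductions = red, summaries = summaries,
         occupancy_levels = occupancy_levels, replications = replications,
         seed = seed),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, digits = 1, ...) {
  cat(sprintf("Model comparison (%d replications per cell)\n", x$replications))
  g <- x$grid
  g$cancellations <- round(g$cancellations, digits)
  g$cancellation_pct <- round(g$cancellation_pct, digits)
  g$admissions <- round(g$admissions)
  g$census_weekday_sd <- round(g$census_weekday_sd, 2)
  print(g, row.names = FALSE)
  cat("\nCancellation reductions vs Model 1A:\n")
  r <- x$reductions
  r$reduction_pct <- round(r$reduction_pct, digits)
  print(r, row.names = FALSE)
  invisible(x)
}

#' @export
plot.model_comparison <- function(x, occupancy = x$occupancy_levels[1], ...) {
  sel <- which(x$grid$occupancy == occupancy)
  if (length(sel) == 0L) stop("occupancy level not in the comparison", call. = FALSE)
  profs <- vapply(x$summaries[sel], function(s) s$weekday_mean[1:5], numeric(5))
  graphics::matplot(1:5, profs, type = "b", pch = 16, lty = 1:4, xaxt = "n",
                    xlab = "Weekday", ylab = "Mean end-of-day census",
                    main = sprintf("Weekday census profile at %.0f%% occupancy",
                                   100 * occupancy), ...)
  graphics::axis(1, at = 1:5, labels = WEEKDAYS)
  graphics::legend("topleft", legend = x$grid$model[sel], lty = 1:4,
                   col = seq_along(sel), pch = 16, bty = "n")
  invisible(x)
}
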