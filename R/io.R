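# Stay-record IO, report writers, synthetic cohort generator, CLI dispatcher.

#' Generate a synthetic historical cohort of ICU stays
#'
#' Emulates an admission/discharge extract: `n` stays with admission dates
#' uniform over the date range and whole-day lengths of stay sampled from the
#' given lognormal law. The default size matches the roughly decade-long
#' cohort of the modelled unit (14,526 stays). Refitting the generated stays
#' recovers the generating parameters, so the full pipeline is testable
#' without any real records.
#'
#' @param dist A [los_lognormal()].
#' @param n Number of stays (`>= 1`).
#' @param start,end Admission date range (ISO dates).
#' @param seed Optional integer seed.
#' @return A `data.frame` of stay records: `id`, `admit_date`,
#'   `discharge_date`, `los_days`.
#' @examples
#' head(generate_synthetic_cohort(n = 5, seed = 1))
#' @export
generate_synthetic_cohort <- function(dist = los_lognormal(), n = 14526L,
                                      start = "2009-09-01", end = "2019-11-30",
                                      seed = NULL) {
  stopifnot(inherits(dist, "los_lognormal"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive count", call. = FALSE)
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || end < start)
    stop("invalid or empty admission date range", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  admit <- sort(start + sample.int(as.integer(end - start) + 1L, n,
                                   replace = TRUE) - 1L)
  los <- sample_stays(dist, n)
  data.frame(
    id = seq_len(n),
    admit_date = admit,
    discharge_date = admit + los,
    los_days = los
  )
}

#' Read and write stay records
#'
#' Stay records are delimited text with a header; either both `admit_date`
#' and `discharge_date` columns (ISO dates, stay = discharge minus admission
#' in days, floored at 1) or an explicit `los_days` column must be present.
#' Malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return `read_stay_records()`: a `data.frame` of validated records;
#'   `write_stay_records()`: `path`, invisibly.
#' @export
read_stay_records <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  has_dates <- all(c("admit_date", "discharge_date") %in% names(df))
  has_los <- "los_days" %in% names(df)
  if (!has_dates && !has_los)
    stop("need either admit_date+discharge_date columns or a los_days column",
         call. = FALSE)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- character(0)
  if (has_dates) {
    adm <- as.Date(as.character(df$admit_date), optional = TRUE)
    dis <- as.Date(as.character(df$discharge_date), optional = TRUE)
    bad_date <- is.na(adm) | is.na(dis)
    if (any(bad_date))
      bad <- c(bad, sprintf("line %d: unparseable date", line[bad_date]))
    rev_order <- !bad_date & dis < adm
    if (any(rev_order))
      bad <- c(bad, sprintf("line %d: discharge before admission",
                            line[rev_order]))
    df$admit_date <- adm
    df$discharge_date <- dis
    if (!has_los)
      df$los_days <- pmax(1L, as.integer(dis - adm))
  }
  if (has_los) {
    los <- suppressWarnings(as.numeric(df$los_days))
    bad_los <- is.na(los) | los < 1
    if (any(bad_los))
      bad <- c(bad, sprintf("line %d: invalid stay length", line[bad_los]))
    df$los_days <- as.integer(los)
  }
  if (length(bad))
    stop("malformed stay records:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  if (!"id" %in% names(df)) df$id <- seq_len(nrow(df))
  df
}

#' @rdname read_stay_records
#' @param records Stay-record `data.frame` as from
#'   [generate_synthetic_cohort()].
#' @export
write_stay_records <- function(records, path, sep = ",") {
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write scenario and comparison results as delimited text
#'
#' `write_scenario_summary()` writes one scenario's weekday census profile
#' and annual figures as a key-value table. `write_comparison()` writes the
#' model-comparison grid, the reductions, and the weekday census profiles
#' (the tabular analogues of the study's report tables).
#' `write_pair_search()` writes the ten-pair range table.
#'
#' @param x The object to write.
#' @param path Output file (for `write_comparison()`, a directory).
#' @param sep Field separator.
#' @return The path(s) written, invisibly.
#' @export
write_scenario_summary <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "scenario_summary"))
  kv <- data.frame(
    key = c(paste0("census_mean_", names(x$weekday_mean)),
            paste0("census_sd_", names(x$weekday_sd)),
            "annual_admissions", "annual_cancellations", "cancellation_pct",
            "annual_demand", "replications", "policy", "occupancy_level"),
    value = c(x$weekday_mean, x$weekday_sd, x$annual_admissions,
              x$annual_cancellations, x$cancellation_pct, x$annual_demand,
              x$replications, x$spec$policy, x$spec$occupancy_level),
    stringsAsFactors = FALSE
  )
  utils::write.table(kv, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scenario_summary
#' @export
write_pair_search <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "pair_search"))
  utils::write.table(x$table, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_scenario_summary
#' @export
write_comparison <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "model_comparison"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  f1 <- file.path(path, "cancellations.tsv")
  f2 <- file.path(path, "reductions.tsv")
  f3 <- file.path(path, "census_profiles.tsv")
  utils::write.table(x$grid, f1, sep = sep, row.names = FALSE, quote = FALSE)
  utils::write.table(x$reductions, f2, sep = sep, row.names = FALSE,
                     quote = FALSE)
  profs <- do.call(rbind, lapply(seq_along(x$summaries), function(i) {
    s <- x$summaries[[i]]
    data.frame(model = x$grid$model[i], occupancy = x$grid$occupancy[i],
               weekday = names(s$weekday_mean),
               census_mean = unname(s$weekday_mean),
               census_sd = unname(s$weekday_sd),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(profs, f3, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(c(f1, f2, f3))
}

#' Write a daily ledger as delimited text
#'
#' @param ledger A [run_replication()] ledger.
#' @param path Output file.
#' @param sep Field separator.
#' @param replication Replication index recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path, sep = "\t", replication = 1L) {
  out <- cbind(replication = replication, ledger)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- command-line interface ------------------------------------------------

.cli_usage <- function() {
  cat(
"usage: cicusim <command> [--flag value ...]

commands:
  fit         --input FILE [--sep ,]
  run         [--policy random|anticipatory] [--extra Tue,Wed]
              [--occupancy 0.76] [--reps 500] [--seed 1] [--out FILE]
  pair-search [--policy random|anticipatory] [--occupancy 0.76]
              [--reps 500] [--seed 1] [--out FILE]
  compare     [--occupancy 0.76,0.86,0.90] [--reps 500] [--seed 1]
              [--out DIR]
  fixtures    [--n 14526] [--seed 1] --out FILE
")
}

.cli_parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("flag ", a, " needs a value", call. = FALSE)
    flags[[substring(a, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

.cli_flag <- function(flags, name, default = NULL) {
  if (!is.null(flags[[name]])) flags[[name]] else default
}

#' Command-line dispatcher
#'
#' Implements the `cicusim` command-line tool (see
#' `system.file("cli", "cicusim.R", package = "cicusim")`): `fit` fits the
#' stay-length law to a records file, `run` executes one scenario,
#' `pair-search` and `compare` produce the search table and the model
#' comparison, and `fixtures` writes a synthetic cohort. Every run logs its
#' configuration, seed and package version.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @examples
#' cicusim_cli(c("run", "--reps", "5", "--seed", "1"))
#' @export
cicusim_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1] %in% c("-h", "--help", "help")) {
    .cli_usage()
    return(invisible(0L))
  }
  cmd <- args[1]
  status <- tryCatch({
    flags <- .cli_parse_flags(args[-1])
    seed <- as.integer(.cli_flag(flags, "seed", "1"))
    message(sprintf("cicusim %s | command: %s | seed: %d",
                    as.character(utils::packageVersion("cicusim")), cmd, seed))
    switch(cmd,
      fit = {
        input <- .cli_flag(flags, "input")
        if (is.null(input)) stop("fit requires --input", call. = FALSE)
        rec <- read_stay_records(input, sep = .cli_flag(flags, "sep", ","))
        fit <- fit_los(rec$los_days)
        message(sprintf("fitted %d stays", nrow(rec)))
        cat(sprintf("meanlog %.6f\nsdlog %.6f\n", fit$meanlog, fit$sdlog))
      },
      run = {
        spec <- scenario_spec(
          policy = .cli_flag(flags, "policy", "random"),
          template = slot_template(strsplit(
            .cli_flag(flags, "extra", "Tue,Wed"), ",")[[1]]),
          occupancy_level = as.numeric(.cli_flag(flags, "occupancy", "0.76")),
          replications = as.integer(.cli_flag(flags, "reps", "500"))
        )
        message(paste(utils::capture.output(print(spec)), collapse = "\n"))
        s <- run_scenario(spec, seed = seed)
        print(s)
        out <- .cli_flag(flags, "out")
        if (!is.null(out)) write_scenario_summary(s, out)
      },
      `pair-search` = {
        ps <- pair_search(
          policy = .cli_flag(flags, "policy", "random"),
          occupancy_level = as.numeric(.cli_flag(flags, "occupancy", "0.76")),
          replications = as.integer(.cli_flag(flags, "reps", "500")),
          seed = seed)
        print(ps)
        out <- .cli_flag(flags, "out")
        if (!is.null(out)) write_pair_search(ps, out)
      },
      compare = {
        occ <- as.numeric(strsplit(
          .cli_flag(flags, "occupancy", "0.76,0.86,0.90"), ",")[[1]])
        cmp <- compare_models(
          occupancy_levels = occ,
          replications = as.integer(.cli_flag(flags, "reps", "500")),
          seed = seed)
        print(cmp)
        out <- .cli_flag(flags, "out")
        if (!is.null(out)) write_comparison(cmp, out)
      },
      fixtures = {
        out <- .cli_flag(flags, "out")
        if (is.null(out)) stop("fixtures requires --out", call. = FALSE)
        rec <- generate_synthetic_cohort(
          n = as.integer(.cli_flag(flags, "n", "14526")), seed = seed)
        write_stay_records(rec, out)
        message(sprintf("wrote %d synthetic stay records to %s",
                        nrow(rec), out))
      },
      stop("unknown command: ", cmd, call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
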