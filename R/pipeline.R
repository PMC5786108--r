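# End-to-end orchestration: synth -> metrics -> matrices -> profiles ->
# models, with a single JSON config, one master seed and a manifest of
# checksummed artifacts.

#' Build a run configuration
#'
#' Either point at existing CPI/roster/gap files or supply a
#' [synth_config()] to generate them. All randomness flows from `seed`
#' through per-stage derived substreams.
#'
#' @param out_dir Output directory (created if needed).
#' @param cpi_path,roster_path,gap_path Input files; leave `NULL` to
#'   synthesize.
#' @param synth A [synth_config()] used when no input paths are given.
#' @param origin Calendar date of day 0 of the timestamp scale.
#' @param gap_tolerance_s Episode gap tolerance, seconds.
#' @param exclude_weeks ISO week labels to drop from temporal profiles.
#' @param averaging Person-day pooling convention for category means.
#' @param k_list Dichotomization thresholds for the model stage.
#' @param seed Master seed.
#' @return A `run_config` list, validated.
#' @export
run_config <- function(out_dir,
                       cpi_path = NULL, roster_path = NULL, gap_path = NULL,
                       synth = synth_config(),
                       origin = if (!is.null(synth)) synth$origin
                                else as.Date("2009-07-01"),
                       gap_tolerance_s = 60,
                       exclude_weeks = character(),
                       averaging = "person_day",
                       k_list = 0:3,
                       seed = 1L) {
  paths <- c(cpi_path, roster_path, gap_path)
  if (length(paths)) {
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("input file(s) not found: ",
                              paste(missing, collapse = ", "))
  }
  if (is.null(cpi_path) && is.null(synth))
    stop("either input paths or a synth config are required")
  structure(list(out_dir = out_dir, cpi_path = cpi_path,
                 roster_path = roster_path, gap_path = gap_path,
                 synth = synth, origin = as.Date(origin),
                 gap_tolerance_s = gap_tolerance_s,
                 exclude_weeks = exclude_weeks, averaging = averaging,
                 k_list = k_list, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' The JSON mirrors the [run_config()] arguments; a `synth` object, when
#' present, mirrors the [synth_config()] arguments (matrix-valued fields
#' accept named nested lists of category pairs).
#'
#' @param path Path to the JSON file.
#' @param out_dir Override for the output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  synth <- NULL
  if (!is.null(cfg$synth)) {
    sc <- cfg$synth
    args <- list()
    for (nm in c("n_days", "origin", "dow_multipliers", "circadian_weights",
                 "same_ward_boost", "cross_ward_mult",
                 "weekend_duration_mult", "stay_mean_days", "seed")) {
      if (!is.null(sc[[nm]])) args[[nm]] <- sc[[nm]]
    }
    if (!is.null(sc$ward_census)) args$ward_census <- sc$ward_census
    if (!is.null(sc$pair_rate))
      args$pair_rate <- pairlist_to_matrix(sc$pair_rate, default_pair_rates())
    if (!is.null(sc$duration_mean_packets))
      args$duration_mean_packets <-
        pairlist_to_matrix(sc$duration_mean_packets,
                           default_duration_packets())
    if (!is.null(sc$gap_schedule))
      args$gap_schedule <- gap_schedule(sc$gap_schedule$start_date,
                                        sc$gap_schedule$end_date)
    synth <- do.call(synth_config, args)
  }
  run_config(out_dir = out_dir %||% cfg$out_dir %||% ".",
             cpi_path = cfg$cpi_path, roster_path = cfg$roster_path,
             gap_path = cfg$gap_path, synth = synth,
             origin = cfg$origin %||% (if (!is.null(synth)) synth$origin
                                       else "2009-07-01"),
             gap_tolerance_s = cfg$gap_tolerance_s %||% 60,
             exclude_weeks = cfg$exclude_weeks %||% character(),
             averaging = cfg$averaging %||% "person_day",
             k_list = cfg$k_list %||% 0:3,
             seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# overlay entries of a nested list cat -> cat -> value onto a default
# symmetric category matrix
pairlist_to_matrix <- function(lst, base) {
  for (a in names(lst)) for (b in names(lst[[a]])) {
    base[a, b] <- base[b, a] <- lst[[a]][[b]]
  }
  base
}

#' Run the full pipeline
#'
#' Executes every stage in order, writes tidy CSV artifacts under
#' `config$out_dir` and returns a manifest of paths with MD5 checksums.
#' Stage failures are recorded in the manifest; artifacts of earlier
#' stages are preserved.
#'
#' Artifacts: `cpi.csv`, `roster.csv`, `gaps.csv` (synth or copies),
#' `person_days.csv`, `pair_days.csv`, `episodes.csv`,
#' `category_distinct.csv`, `category_pair_duration.csv`,
#' `matrices.csv`, `hourly_counts.csv`, `hourly_distribution.csv`,
#' `median_by_pairtype.csv`, and `model_<population>_<outcome>.csv`.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return `data.table(stage, artifact, path, md5, status)`.
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list()
  note <- function(stage, artifact, path, status = "ok") {
    manifest[[length(manifest) + 1L]] <<- data.table(
      stage = stage, artifact = artifact, path = path,
      md5 = if (file.exists(path)) unname(tools::md5sum(path)) else NA_character_,
      status = status)
  }
  fail <- function(stage, e) {
    manifest[[length(manifest) + 1L]] <<- data.table(
      stage = stage, artifact = NA_character_, path = NA_character_,
      md5 = NA_character_, status = paste("failed:", conditionMessage(e)))
  }
  p <- function(f) file.path(config$out_dir, f)

  # -- stage: inputs ---------------------------------------------------
  if (is.null(config$cpi_path)) {
    ds <- generate_dataset(config$synth, seed = config$seed)
    records <- ds$records; roster <- ds$roster
    gaps <- config$synth$gap_schedule
    say(sprintf("synth: %d records, %d individuals", nrow(records),
                nrow(roster)))
    write_cpi_records(records, p("cpi.csv")); note("synth", "cpi", p("cpi.csv"))
    write_roster(roster, p("roster.csv")); note("synth", "roster", p("roster.csv"))
    write_gaps(gaps, p("gaps.csv")); note("synth", "gaps", p("gaps.csv"))
  } else {
    records <- read_cpi_records(config$cpi_path)
    roster <- read_roster(config$roster_path)
    gaps <- if (!is.null(config$gap_path)) read_gaps(config$gap_path)
            else gap_schedule()
    say(sprintf("inputs: %d records, %d individuals", nrow(records),
                nrow(roster)))
  }
  origin <- config$origin

  # -- stage: metrics --------------------------------------------------
  pdy <- ppd <- NULL
  tryCatch({
    pdy <- person_days(records, roster, gaps, origin)
    ppd <- pair_days(records, gaps, origin, config$gap_tolerance_s)
    eps <- build_episodes(records, config$gap_tolerance_s)
    stopifnot(sum(ppd$cum_duration_s) ==
                PACKET_S * sum(!in_gap(cpi_date(records$t, origin), gaps)))
    say(sprintf("metrics: %d person-days, %d pair-days, %d episodes",
                nrow(pdy), nrow(ppd), nrow(eps)))
    fwrite(pdy, p("person_days.csv")); note("metrics", "person_days", p("person_days.csv"))
    fwrite(ppd, p("pair_days.csv")); note("metrics", "pair_days", p("pair_days.csv"))
    fwrite(eps, p("episodes.csv")); note("metrics", "episodes", p("episodes.csv"))
    fwrite(category_mean_distinct(pdy, roster, config$averaging),
           p("category_distinct.csv"))
    note("metrics", "category_distinct", p("category_distinct.csv"))
    fwrite(category_pair_mean_duration(ppd, roster),
           p("category_pair_duration.csv"))
    note("metrics", "category_pair_duration", p("category_pair_duration.csv"))
  }, error = function(e) fail("metrics", e))

  # -- stage: matrices -------------------------------------------------
  tryCatch({
    wards <- intersect(CPI_WARDS, unique(roster$ward))
    longs <- lapply(wards, function(w) {
      rbindlist(list(
        as_long(contact_matrix(records, roster, w, gaps, origin,
                               config$averaging)),
        as_long(duration_matrix(ppd, roster, w))))
    })
    fwrite(rbindlist(longs), p("matrices.csv"))
    note("matrices", "matrices", p("matrices.csv"))
  }, error = function(e) fail("matrices", e))

  # -- stage: profiles -------------------------------------------------
  tryCatch({
    hc <- hourly_counts(records, roster, gaps, origin, config$exclude_weeks)
    fwrite(hc, p("hourly_counts.csv"))
    note("profiles", "hourly_counts", p("hourly_counts.csv"))
    hd <- rbindlist(lapply(c("weekday", "weekend"), function(d) {
      out <- hourly_distribution(hc, d)
      if (nrow(out)) out[, day_type := d]
      out
    }), fill = TRUE)
    fwrite(hd, p("hourly_distribution.csv"))
    note("profiles", "hourly_distribution", p("hourly_distribution.csv"))
    fwrite(median_hourly_by_pairtype(hc), p("median_by_pairtype.csv"))
    note("profiles", "median_by_pairtype", p("median_by_pairtype.csv"))
  }, error = function(e) fail("profiles", e))

  # -- stage: models ---------------------------------------------------
  for (pop in c("staff", "patients")) {
    tryCatch({
      tab <- build_outcome_table(pdy, roster, pop)
      for (oc in c("high_freq", "high_dur")) {
        sens <- sensitivity_analysis(tab, oc, k_list = config$k_list)
        f <- p(sprintf("model_%s_%s.csv", pop, sub("high_", "", oc)))
        fwrite(sens, f)
        note("models", sprintf("model_%s_%s", pop, oc), f)
      }
    }, error = function(e) fail(paste0("models_", pop), e))
  }

  m <- rbindlist(manifest)
  fwrite(m, p("manifest.csv"))
  m[]
}

#' Command-line entry point
#'
#' Subcommands: `synth`, `run-all` (both driven by a JSON config via
#' `--config`), plus `--seed` and `--out` overrides. Installed as
#' `inst/cli/cpinet.R`; invoke as
#' `Rscript -e 'cpinet::cpinet_main()' <subcommand> --config cfg.json`.
#'
#' @param args Character vector of CLI arguments (defaults to the
#'   command line).
#' @return Exit status, invisibly.
#' @export
cpinet_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: cpinet <synth|run-all> --config cfg.json",
        "[--seed N] [--out dir]\n")
    return(invisible(1L))
  }
  sub <- args[1L]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  out_dir <- opt("--out", ".")
  seed <- as.integer(opt("--seed", "1"))
  cfg_path <- opt("--config")
  cfg <- if (!is.null(cfg_path)) read_run_config(cfg_path, out_dir = out_dir)
         else run_config(out_dir = out_dir, seed = seed)
  cfg$seed <- seed
  if (sub == "synth") {
    ds <- generate_dataset(cfg$synth %||% synth_config(), seed = seed)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cpi_records(ds$records, file.path(out_dir, "cpi.csv"))
    write_roster(ds$roster, file.path(out_dir, "roster.csv"))
    write_gaps(ds$config$gap_schedule, file.path(out_dir, "gaps.csv"))
    message("wrote cpi.csv, roster.csv, gaps.csv to ", out_dir)
  } else if (sub == "run-all") {
    run_all(cfg)
  } else {
    stop("unknown subcommand: ", sub)
  }
  invisible(0L)
}
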