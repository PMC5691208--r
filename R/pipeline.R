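#' Pipeline configuration
#'
#' Collects every stage parameter of an end-to-end run — simulation preset,
#' detection settings, network-burst settings, distribution fitting,
#' homeostasis tolerance, bootstrap size — together with the global seed
#' and the input/output locations. All defaults are the package defaults
#' of the individual stages.
#'
#' @param preset A [network_preset()] or the name of a packaged preset
#'   (see [network_preset_fixture()]).
#' @param duration_s Simulated recording duration (seconds).
#' @param seed Global seed; expanded deterministically per stage.
#' @param stages Character vector of stages to run, any of `"simulate"`,
#'   `"activity"`, `"bursts"`, `"ratedist"`, `"homeostasis"`, `"switch"`.
#' @param nb_bin_ms,nb_window_ms,nb_threshold_frac Network-burst settings.
#' @param tolerance_pct Homeostasis restoration tolerance (percent).
#' @param n_boot Bootstrap replicates for the switch CI.
#' @param expression_csv Expression table path (defaults to the packaged
#'   published values).
#' @param timeline_csv Treatment-timeline table path (defaults to the
#'   packaged published values).
#' @param out_dir Output directory for stage outputs and the JSON summary,
#'   or `NULL` to keep results in memory only.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "WT-16div", duration_s = 600,
                            seed = 1L,
                            stages = c("simulate", "activity", "bursts",
                                       "ratedist", "homeostasis", "switch"),
                            nb_bin_ms = 15, nb_window_ms = 150,
                            nb_threshold_frac = 0.15, tolerance_pct = 12,
                            n_boot = 2000L,
                            expression_csv = NULL, timeline_csv = NULL,
                            out_dir = NULL) {
  known <- c("simulate", "activity", "bursts", "ratedist", "homeostasis",
             "switch")
  stages <- match.arg(stages, known, several.ok = TRUE)
  downstream <- c("activity", "bursts", "ratedist")
  if (any(downstream %in% stages) && !"simulate" %in% stages) {
    stop("stages ", paste(intersect(downstream, stages), collapse = ", "),
         " depend on 'simulate'")
  }
  if (is.character(preset)) preset <- network_preset_fixture(preset, seed)
  stopifnot(inherits(preset, "network_preset"))
  structure(list(preset = preset, duration_s = duration_s,
                 seed = as.integer(seed), stages = stages,
                 nb_bin_ms = nb_bin_ms, nb_window_ms = nb_window_ms,
                 nb_threshold_frac = nb_threshold_frac,
                 tolerance_pct = tolerance_pct, n_boot = as.integer(n_boot),
                 expression_csv = expression_csv,
                 timeline_csv = timeline_csv, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order on a simulated
#' recording: network simulation, activity metrics, burst and
#' network-burst analysis, rate-distribution fitting, homeostasis
#' classification of the configured timeline table, and the GABA-polarity
#' switch estimate from the configured expression table. Every parameter
#' and the seed are logged at start; identical configurations produce
#' identical results.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress the parameter log (default `FALSE`).
#' @return A named list summarising each executed stage (also written as
#'   `summary.json` under `out_dir` when one is configured), invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- function(...) if (!quiet) message(sprintf(...))
  for (p in c("duration_s", "seed", "nb_bin_ms", "nb_window_ms",
              "nb_threshold_frac", "tolerance_pct", "n_boot")) {
    log("param %s = %s", p, format(config[[p]]))
  }
  for (p in names(config$preset)) {
    log("preset %s = %s", p, format(config$preset[[p]]))
  }
  summary <- list(seed = config$seed)
  spikes <- NULL

  if ("simulate" %in% config$stages) {
    sim <- simulate_network(config$preset, config$duration_s)
    spikes <- sim$spikes
    summary$simulate <- list(n_spikes = nrow(spikes$spikes),
                             n_planted_nb = length(sim$ground_truth$nb_times))
    log("simulate: %d spikes, %d planted NB events",
        nrow(spikes$spikes), length(sim$ground_truth$nb_times))
  }
  if ("activity" %in% config$stages) {
    act <- compute_activity(spikes)
    summary$activity <- list(n_active = act$n_active, mfr_hz = act$mfr_hz)
    log("activity: %d active electrodes, MFR %.4g Hz", act$n_active,
        act$mfr_hz)
  }
  if ("bursts" %in% config$stages) {
    b <- detect_bursts(spikes)
    nb <- detect_network_bursts(spikes, bin_ms = config$nb_bin_ms,
                                window_ms = config$nb_window_ms,
                                threshold_frac = config$nb_threshold_frac)
    summary$bursts <- list(n_bursts = nrow(b$bursts),
                           mbr_per_min = b$mbr_per_min,
                           n_network_bursts = nrow(nb))
    if (nrow(nb) >= 2L) {
      ibi <- ibi_distribution(nb$start_s)
      summary$bursts$median_nb_ibi_s <- stats::median(ibi$ibis_s)
    }
    log("bursts: %d bursts (MBR %.4g/min), %d network bursts",
        nrow(b$bursts), b$mbr_per_min, nrow(nb))
  }
  if ("ratedist" %in% config$stages) {
    d <- build_rate_distribution(compute_activity(spikes))
    summary$ratedist <- list(fit_available = d$fit_available,
                             fit_mu = d$fit_mu, fit_sigma = d$fit_sigma,
                             n_active = d$n_active)
    log("ratedist: fit mu %.4g, sigma %.4g over %d active electrodes",
        d$fit_mu, d$fit_sigma, d$n_active)
  }
  if ("homeostasis" %in% config$stages) {
    path <- config$timeline_csv
    if (is.null(path)) {
      path <- system.file("extdata", "mfr_timeline_printed.csv",
                          package = "hdmea", mustWork = TRUE)
    }
    tab <- read_timeline_csv(path)
    key <- interaction(tab$genotype, tab$condition, drop = TRUE)
    verdicts <- list()
    for (d in split(tab, key)) {
      if (!all(c("2h", "48h") %in% d$timepoint)) next
      v <- classify_homeostasis(d, tolerance_pct = config$tolerance_pct)
      nm <- paste(d$genotype[1], d$condition[1], sep = ".")
      verdicts[[nm]] <- list(direction = v$response_direction,
                             restored = v$restored)
      log("homeostasis %s: %s, %s", nm, v$response_direction,
          if (v$restored) "restored" else "not restored")
    }
    summary$homeostasis <- verdicts
  }
  if ("switch" %in% config$stages) {
    path <- config$expression_csv
    if (is.null(path)) path <- expression_fixture_path()
    series <- read_expression_csv(path)
    genotypes <- unique(vapply(series, function(x) x$genotype, character(1)))
    est <- list()
    for (g in genotypes) {
      e <- bootstrap_switch(series[[paste0(g, ".NKCC1")]],
                            series[[paste0(g, ".KCC2")]],
                            n_boot = config$n_boot, seed = config$seed)
      est[[g]] <- list(crossing_div = e$crossing_div, ci_low = e$ci_low,
                       ci_high = e$ci_high)
      log("switch %s: %.4g DIV (CI %.4g-%.4g)", g, e$crossing_div,
          e$ci_low, e$ci_high)
    }
    summary$switch <- est
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(spikes)) {
      write_spike_table(spikes, file.path(config$out_dir, "spikes.csv"))
    }
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(summary)
}
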