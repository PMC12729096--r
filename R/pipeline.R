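#' Pipeline configuration
#'
#' Bundles every tunable of the analysis: screen geometry, event-detection
#' thresholds, dynamic-AOI size, separation minima, cohort generator
#' parameters, the stepwise-selection thresholds, the seed and the output
#' directory. The configuration is validated before any stage runs.
#'
#' @param seed Integer seed driving all randomness.
#' @param out_dir Optional output directory; created if missing.
#' @param geometry A [screen_geometry()].
#' @param detection A [detection_params()].
#' @param dynamic_aoi A [dynamic_aoi_spec()].
#' @param standard A [separation_standard()].
#' @param cohort A [cohort_params()].
#' @param grid_s Separation-check grid step (s).
#' @param entry_p,removal_p Stepwise logistic thresholds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = NULL,
                            geometry = screen_geometry(),
                            detection = detection_params(),
                            dynamic_aoi = dynamic_aoi_spec(),
                            standard = separation_standard(),
                            cohort = cohort_params(),
                            grid_s = 1, entry_p = 0.05, removal_p = 0.10) {
  cfg <- list(seed = seed, out_dir = out_dir, geometry = geometry,
              detection = detection, dynamic_aoi = dynamic_aoi,
              standard = standard, cohort = cohort, grid_s = grid_s,
              entry_p = entry_p, removal_p = removal_p)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg A [pipeline_config()] (or plain list with the same fields).
#' @return The config, invisibly; errors describe the offending field.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  if (!inherits(cfg$geometry, "screen_geometry"))
    stop("config: geometry must be a screen_geometry", call. = FALSE)
  if (!inherits(cfg$detection, "detection_params"))
    stop("config: detection must be detection_params", call. = FALSE)
  if (cfg$detection$blink_min_ms >= cfg$detection$blink_max_ms)
    stop("config: blink_min_ms must be below blink_max_ms", call. = FALSE)
  if (!inherits(cfg$standard, "separation_standard"))
    stop("config: standard must be a separation_standard", call. = FALSE)
  if (!inherits(cfg$cohort, "cohort_params"))
    stop("config: cohort must be cohort_params", call. = FALSE)
  if (cfg$grid_s <= 0) stop("config: grid_s must be positive", call. = FALSE)
  if (!(cfg$entry_p > 0 && cfg$entry_p < 1 &&
          cfg$removal_p > 0 && cfg$removal_p <= 1))
    stop("config: stepwise thresholds must lie in (0, 1)", call. = FALSE)
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Any field omitted from the file keeps its default; nested sections
#' (`geometry`, `detection`, `dynamic_aoi`, `standard`, `cohort`) are passed
#' to the corresponding constructors, so invalid settings are rejected
#' before any stage runs.
#'
#' @param path Path to a YAML config file.
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fn, section) do.call(fn, as.list(y[[section]] %||% list()))
  pipeline_config(
    seed = y$seed %||% 1,
    out_dir = y$out_dir,
    geometry = build(screen_geometry, "geometry"),
    detection = build(detection_params, "detection"),
    dynamic_aoi = build(dynamic_aoi_spec, "dynamic_aoi"),
    standard = build(separation_standard, "standard"),
    cohort = build(cohort_params, "cohort"),
    grid_s = y$grid_s %||% 1,
    entry_p = y$entry_p %||% 0.05,
    removal_p = y$removal_p %||% 0.10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyse one recorded session
#'
#' Runs event detection, static-AOI accounting and (for scenarios with
#' scripted conflicts, when the recording covers the analysis windows) the
#' dynamic-AOI conflict variables.
#'
#' @param stream A [gaze_stream()].
#' @param scenario The scenario the session was recorded under.
#' @param interventions Intervention log of the session.
#' @param scores Subjective scores (`isa_ratings`, `nasa_components`).
#' @param config A [pipeline_config()].
#' @return List with `metrics` (one-row data.frame), `conflicts` (list of
#'   `conflict_record`), `fixations`, `blinks`.
#' @export
analyze_session <- function(stream, scenario, interventions, scores,
                            config = pipeline_config()) {
  blinks <- detect_blinks(stream, config$detection)
  fixations <- detect_fixations(stream, config$detection)
  aois <- build_static_aois(stream$geometry)
  metrics <- session_metrics(stream, blinks, fixations, aois, scores)
  records <- list()
  stream_end_s <- (nrow(stream$samples)) * sample_period_ms(stream$geometry) /
    1000
  if (length(scenario$conflicts) > 0) {
    max_win <- max(vapply(scenario$conflicts, function(cf) cf$window_s[2],
                          numeric(1)))
    if (stream_end_s >= max_win && nrow(fixations) > 0) {
      conflict_ac <- unique(unlist(lapply(scenario$conflicts,
                                          `[[`, "aircraft")))
      in_win <- fixations$start_ms / 1000 < max_win
      fixations$aircraft <- NA_character_
      fixations$aircraft[in_win] <- assign_fixation_dynamic(
        fixations[in_win, , drop = FALSE],
        scenario$aircraft[conflict_ac], config$dynamic_aoi, scenario,
        interventions)
      records <- lapply(scenario$conflicts, function(cf)
        conflict_variables(fixations, scenario, cf, interventions,
                           config$standard))
    }
  }
  list(metrics = metrics, conflicts = records, fixations = fixations,
       blinks = blinks)
}

conflict_record_row <- function(rec, participant_id) {
  row <- data.frame(participant_id = participant_id, conflict = rec$conflict,
                    solved = rec$solved,
                    total_time_s = rec$total_fixation_time_s,
                    total_interventions = rec$total_interventions,
                    time_to_accept_s = rec$time_to_accept_s)
  for (a in names(rec$fixation_time_s))
    row[[paste0("time_", a, "_s")]] <- rec$fixation_time_s[[a]]
  for (a in names(rec$altitude_n))
    row[[paste0("alt_", a)]] <- rec$altitude_n[[a]]
  for (a in names(rec$speed_n))
    row[[paste0("speed_", a)]] <- rec$speed_n[[a]]
  row
}

#' Simulate and analyse a full cohort, session by session
#'
#' Generates each session with the same per-session substreams as
#' [simulate_cohort()] and analyses it immediately, so raw streams never
#' accumulate in memory. This is the main entry point for cohort-level
#' simulation studies.
#'
#' @param params A [cohort_params()].
#' @param seed Integer seed.
#' @param config A [pipeline_config()].
#' @return List of class `cohort_analysis`: `metrics` (one row per
#'   participant x condition with `traffic`/`complexity` columns),
#'   `conflicts` (one row per participant x scripted conflict),
#'   `participants` (ground-truth effects), `scenarios`.
#' @export
analyze_cohort <- function(params = cohort_params(), seed = 1,
                           config = pipeline_config(cohort = params,
                                                    seed = seed)) {
  participants <- draw_participants(params, seed)
  grid <- condition_grid()
  scenarios <- lapply(seq_len(nrow(grid)), function(i)
    generate_scenario(condition(grid$traffic[i], grid$complexity[i]),
                      geometry = config$geometry))
  names(scenarios) <- grid$id
  metrics_rows <- list()
  conflict_rows <- list()
  for (p in seq_len(nrow(participants))) {
    pr <- as.list(participants[p, ])
    solver <- list(easy = pr$solver_easy, difficult = pr$solver_difficult)
    for (ci in seq_len(nrow(grid))) {
      sc <- scenarios[[ci]]
      s_seed <- session_seed(seed, p, ci)
      iv <- if (length(sc$conflicts) > 0)
        simulate_interventions(sc, solver, params, s_seed) else
          data.frame(t_s = numeric(0), flight = character(0),
                     kind = character(0), value = numeric(0))
      stream <- simulate_gaze(sc, params, participant = pr, solver = solver,
                              interventions = iv, seed = s_seed + 1L,
                              participant_id = pr$participant_id,
                              condition_id = grid$id[ci])
      scores <- simulate_scores(condition(grid$traffic[ci],
                                          grid$complexity[ci]),
                                params, participant = pr, seed = s_seed + 2L)
      res <- analyze_session(stream, sc, iv, scores, config)
      m <- res$metrics
      m$traffic <- grid$traffic[ci]
      m$complexity <- grid$complexity[ci]
      metrics_rows[[length(metrics_rows) + 1L]] <- m
      for (rec in res$conflicts)
        conflict_rows[[length(conflict_rows) + 1L]] <-
          conflict_record_row(rec, pr$participant_id)
    }
  }
  metrics <- do.call(rbind, metrics_rows)
  conflicts <- if (length(conflict_rows) > 0)
    as.data.frame(data.table::rbindlist(conflict_rows, fill = TRUE)) else
      NULL
  structure(list(metrics = metrics, conflicts = conflicts,
                 participants = participants, scenarios = scenarios),
            class = "cohort_analysis")
}

#' Condition-level workload statistics
#'
#' Runs the 2 x 3 repeated-measures ANOVA on every session metric,
#' Bonferroni pairwise comparisons over complexity for metrics with a
#' significant complexity effect, and the Spearman matrix between
#' subjective workload and the ocular indices over the six condition means.
#' Sessions with undefined blink mean duration (zero blinks) exclude that
#' participant listwise from the blink-duration ANOVA.
#'
#' @param metrics The `metrics` table from [analyze_cohort()].
#' @return List with `anova` (per-metric [rm_anova_2x3()] tables),
#'   `pairwise` (per-metric complexity comparisons), `condition_means`,
#'   `spearman`.
#' @export
workload_statistics <- function(metrics) {
  metric_cols <- c("pupil_mean_mm", "blink_count", "blink_mean_ms",
                   "fix_time_sector_s", "fix_time_out_s", "fix_time_sheet_s",
                   "fix_count_sector", "fix_count_out", "fix_count_sheet",
                   "isa_mean", "nasa_sum", "head_distance_mean_cm")
  metric_cols <- intersect(metric_cols, names(metrics))
  anovas <- list()
  pairwise <- list()
  for (mc in metric_cols) {
    d <- metrics[, c("participant_id", "traffic", "complexity", mc)]
    if (anyNA(d[[mc]])) {     # listwise exclusion (e.g. zero-blink sessions)
      bad <- unique(d$participant_id[is.na(d[[mc]])])
      d <- d[!d$participant_id %in% bad, , drop = FALSE]
    }
    if (length(unique(d$participant_id)) < 3) next
    an <- rm_anova_2x3(d, value = mc)
    anovas[[mc]] <- an
    cpx <- an[an$effect == "complexity", ]
    if (!is.na(cpx$p) && cpx$p < 0.05)
      pairwise[[mc]] <- bonferroni_pairwise(d, "complexity", value = mc)
  }
  agg_cols <- intersect(c("isa_mean", "nasa_sum", "pupil_mean_mm",
                          "blink_count", "blink_mean_ms",
                          "fix_time_sector_s", "fix_time_sheet_s"),
                        names(metrics))
  cm <- stats::aggregate(metrics[agg_cols],
                         list(condition_id = metrics$condition_id), mean,
                         na.rm = TRUE)
  sp <- spearman_condition_matrix(cm[agg_cols])
  list(anova = anovas, pairwise = pairwise, condition_means = cm,
       spearman = sp)
}

#' Solver / non-solver conflict statistics
#'
#' For each scripted conflict: group descriptives, Mann-Whitney U tests of
#' every gaze/intervention variable between solvers and non-solvers, and
#' the forward-stepwise logistic regression of conflict outcome on those
#' variables.
#'
#' @param conflicts The `conflicts` table from [analyze_cohort()].
#' @param entry_p,removal_p Stepwise thresholds.
#' @return Named list per conflict: `n_solved`, `n_unsolved`,
#'   `descriptives`, `mann_whitney`, `stepwise` (NULL when a group is
#'   empty).
#' @export
cdr_statistics <- function(conflicts, entry_p = 0.05, removal_p = 0.10) {
  out <- list()
  for (cf in unique(conflicts$conflict)) {
    d <- conflicts[conflicts$conflict == cf, , drop = FALSE]
    # keep numeric variables fully observed for this conflict (columns from
    # the other conflict's aircraft are NA here)
    vars <- names(d)[vapply(d, function(col)
      is.numeric(col) && !anyNA(col), logical(1))]
    solved <- d[d$solved, , drop = FALSE]
    unsolved <- d[!d$solved, , drop = FALSE]
    res <- list(n_solved = nrow(solved), n_unsolved = nrow(unsolved))
    res$descriptives <- do.call(rbind, lapply(vars, function(v)
      data.frame(variable = v,
                 m_solved = mean(solved[[v]]), sd_solved = stats::sd(solved[[v]]),
                 m_unsolved = mean(unsolved[[v]]),
                 sd_unsolved = stats::sd(unsolved[[v]]))))
    if (nrow(solved) > 0 && nrow(unsolved) > 0) {
      res$mann_whitney <- do.call(rbind, lapply(vars, function(v) {
        mw <- mann_whitney(solved[[v]], unsolved[[v]])
        data.frame(variable = v, U = mw$U, p = mw$p)
      }))
      sw <- forward_stepwise_logistic(d[vars], d$solved,
                                      entry_p = entry_p,
                                      removal_p = removal_p)
      res$stepwise <- sw
    } else {
      res$mann_whitney <- NULL
      res$stepwise <- NULL
    }
    out[[cf]] <- res
  }
  out
}

strip_models <- function(cdr) {
  lapply(cdr, function(res) {
    if (!is.null(res$stepwise)) {
      res$stepwise <- res$stepwise[c("selected", "coefficients", "steps",
                                     "mcfadden_r2", "vif",
                                     "separation_flag")]
    }
    res
  })
}

#' Run the full pipeline
#'
#' Simulates the cohort defined by the configuration, analyses every
#' session, computes the workload and conflict statistics, and (when an
#' output directory is configured) writes the metrics and conflict tables
#' (CSV), the statistics (JSON), a sliding-window attention series for the
#' Easy conflict, and a run log echoing the configuration and its hash.
#' Given the same configuration and seed the outputs are identical.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_report`: `config_hash`, `analysis`
#'   ([analyze_cohort()] result), `workload`, `cdr`, `attention`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  analysis <- analyze_cohort(config$cohort, config$seed, config)
  workload <- workload_statistics(analysis$metrics)
  cdr <- if (!is.null(analysis$conflicts))
    cdr_statistics(analysis$conflicts, config$entry_p, config$removal_p) else
      NULL
  # attention series over the Easy-conflict window, first participant
  attention <- NULL
  sc <- analysis$scenarios[["t12_high"]]
  if (!is.null(sc) && length(sc$conflicts) > 0 &&
      config$cohort$session_seconds >= sc$conflicts$easy$window_s[2]) {
    pr <- as.list(analysis$participants[1, ])
    solver <- list(easy = pr$solver_easy, difficult = pr$solver_difficult)
    ci <- match("t12_high", condition_grid()$id)
    s_seed <- session_seed(config$seed, 1, ci)
    iv <- simulate_interventions(sc, solver, config$cohort, s_seed)
    stream <- simulate_gaze(sc, config$cohort, participant = pr,
                            solver = solver, interventions = iv,
                            seed = s_seed + 1L,
                            participant_id = pr$participant_id)
    fx <- detect_fixations(stream, config$detection)
    ac <- sc$conflicts$easy$aircraft
    fx$aircraft <- assign_fixation_dynamic(fx, sc$aircraft[ac],
                                           config$dynamic_aoi, sc, iv)
    attention <- sliding_window_attention(
      fx, ac, t_end_ms = sc$conflicts$easy$window_s[2] * 1000)
  }
  report <- structure(list(config_hash = cfg_hash, analysis = analysis,
                           workload = workload, cdr = cdr,
                           attention = attention),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(...) file.path(config$out_dir, ...)
    data.table::fwrite(analysis$metrics, w("metrics.csv"))
    if (!is.null(analysis$conflicts))
      data.table::fwrite(analysis$conflicts, w("conflicts.csv"))
    jsonlite::write_json(c(list(config_hash = cfg_hash), workload),
                         w("workload_statistics.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    if (!is.null(cdr))
      jsonlite::write_json(c(list(config_hash = cfg_hash),
                             strip_models(cdr)),
                           w("cdr_statistics.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, force = TRUE)
    if (!is.null(attention))
      data.table::fwrite(attention, w("attention_easy.csv"))
    writeLines(c(sprintf("atcgaze %s",
                         as.character(utils::packageVersion("atcgaze"))),
                 sprintf("config_hash: %s", cfg_hash),
                 sprintf("seed: %s", config$seed),
                 sprintf("participants: %d", config$cohort$n_participants),
                 sprintf("session_seconds: %g",
                         config$cohort$session_seconds)),
               w("run_log.txt"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d sessions analysed (config %s)\n",
              nrow(x$analysis$metrics), substr(x$config_hash, 1, 8)))
  invisible(x)
}
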