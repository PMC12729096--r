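#' En route separation minima
#'
#' Safe separation requires at least 5 NM laterally or at least 1,000 ft
#' vertically; a loss of separation occurs when both are simultaneously
#' below their minima (strict inequalities).
#'
#' @param lateral_min_nm Lateral minimum in NM (default 5).
#' @param vertical_min_ft Vertical minimum in ft (default 1000).
#' @return An object of class `separation_standard`.
#' @export
separation_standard <- function(lateral_min_nm = 5, vertical_min_ft = 1000) {
  if (lateral_min_nm <= 0 || vertical_min_ft <= 0)
    stop("separation minima must be positive", call. = FALSE)
  structure(list(lateral_min_nm = lateral_min_nm,
                 vertical_min_ft = vertical_min_ft),
            class = "separation_standard")
}

#' Lateral and vertical separation between two aircraft states
#'
#' @param a_state,b_state Lists or one-row data.frames with `x_nm`, `y_nm`,
#'   `alt_ft` at a common time.
#' @return Named numeric: `lateral_nm` (horizontal Euclidean distance) and
#'   `vertical_ft` (absolute altitude difference).
#' @export
separation <- function(a_state, b_state) {
  c(lateral_nm = sqrt((a_state$x_nm - b_state$x_nm)^2 +
                        (a_state$y_nm - b_state$y_nm)^2),
    vertical_ft = abs(a_state$alt_ft - b_state$alt_ft))
}

#' First loss of separation in a scenario
#'
#' Propagates all (or a subset of) trajectories on a regular time grid with
#' the intervention log applied, and scans every aircraft pair for the
#' earliest grid time at which lateral and vertical separation are
#' simultaneously below the minima (strict inequalities).
#'
#' @param scenario A scenario (from [generate_scenario()] or built by hand:
#'   a list with `aircraft`, `duration_s`).
#' @param interventions Optional intervention log data.frame (`t_s`,
#'   `flight`, `kind`, `value`). Flights must exist in the scenario.
#' @param standard A [separation_standard()].
#' @param grid_s Scan step in seconds (default 1).
#' @param flights Optional character vector restricting the check to a
#'   subset of aircraft (e.g. one conflict's pair).
#' @return A list with `time_s` (earliest violation time, `NA` if none) and
#'   `pair` (the two flight labels, `NA` if none).
#' @export
check_separation <- function(scenario, interventions = NULL,
                             standard = separation_standard(), grid_s = 1,
                             flights = NULL) {
  trajs <- scenario$aircraft
  if (!is.null(flights)) {
    missing_fl <- setdiff(flights, names(trajs))
    if (length(missing_fl) > 0)
      stop("unknown flight(s): ", paste(missing_fl, collapse = ", "),
           call. = FALSE)
    trajs <- trajs[flights]
  }
  if (!is.null(interventions) && nrow(interventions) > 0) {
    unknown <- setdiff(unique(interventions$flight), names(scenario$aircraft))
    if (length(unknown) > 0)
      stop("intervention log names unknown flight(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  times <- seq(0, scenario$duration_s, by = grid_s)
  states <- lapply(trajs, traj_states, times_s = times,
                   interventions = interventions)
  labels <- names(trajs)
  best_t <- NA_real_
  best_pair <- c(NA_character_, NA_character_)
  for (i in seq_along(states)) {
    for (j in seq_len(i - 1L)) {
      lat <- sqrt((states[[i]]$x_nm - states[[j]]$x_nm)^2 +
                    (states[[i]]$y_nm - states[[j]]$y_nm)^2)
      vert <- abs(states[[i]]$alt_ft - states[[j]]$alt_ft)
      hit <- lat < standard$lateral_min_nm & vert < standard$vertical_min_ft
      if (any(hit)) {
        t_hit <- times[which(hit)[1]]
        if (is.na(best_t) || t_hit < best_t) {
          best_t <- t_hit
          best_pair <- c(labels[j], labels[i])
        }
      }
    }
  }
  list(time_s = best_t, pair = best_pair)
}

#' Classify a conflict outcome as solved or unsolved
#'
#' A conflict is solved if, with the given interventions applied, the
#' separation minima are never simultaneously violated at any point during
#' the scenario.
#'
#' @inheritParams check_separation
#' @return `TRUE` (solved) or `FALSE` (unsolved).
#' @export
classify_solver <- function(scenario, interventions = NULL,
                            standard = separation_standard(), grid_s = 1,
                            flights = NULL) {
  is.na(check_separation(scenario, interventions, standard, grid_s,
                         flights)$time_s)
}

#' Per-conflict gaze and intervention variables
#'
#' Tabulates, for one scripted conflict, the outcome flag, the cumulative
#' fixation time on each involved aircraft over the conflict's analysis
#' window (clipped at sector entry for aircraft entering after the window
#' start), the altitude/speed intervention counts per flight, and the time
#' from sector entry to the controller's acceptance action when an `accept`
#' event is logged.
#'
#' @param fixations Data.frame with `start_ms`, `end_ms` and an `aircraft`
#'   column ([assign_fixation_dynamic()]).
#' @param scenario The scenario containing the conflict.
#' @param conflict A [conflict_spec()].
#' @param interventions Intervention log data.frame (may be empty/NULL).
#' @param standard A [separation_standard()].
#' @return A list of class `conflict_record`: `conflict`, `solved`,
#'   `fixation_time_s` (named per aircraft), `total_fixation_time_s`,
#'   `altitude_n` / `speed_n` (named per aircraft), `total_interventions`,
#'   `time_to_accept_s` (NA when no accept was logged).
#' @export
conflict_variables <- function(fixations, scenario, conflict,
                               interventions = NULL,
                               standard = separation_standard()) {
  ac <- conflict$aircraft
  missing_ac <- setdiff(ac, names(scenario$aircraft))
  if (length(missing_ac) > 0)
    stop("conflict names unknown aircraft: ",
         paste(missing_ac, collapse = ", "), call. = FALSE)
  if (!is.null(interventions) && nrow(interventions) > 0) {
    unknown <- setdiff(unique(interventions$flight), names(scenario$aircraft))
    if (length(unknown) > 0)
      stop("intervention log names unknown flight(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  fix_time <- vapply(ac, function(a) {
    entry <- sector_entry_s(scenario$aircraft[[a]], scenario)
    cumulative_fixation_time(fixations, a, conflict$window_s,
                             sector_entry_s = entry)
  }, numeric(1))
  count_kind <- function(kind) {
    vapply(ac, function(a) {
      if (is.null(interventions) || nrow(interventions) == 0) return(0L)
      sum(interventions$flight == a & interventions$kind == kind)
    }, integer(1))
  }
  alt_n <- count_kind("altitude")
  spd_n <- count_kind("speed")
  time_to_accept <- NA_real_
  if (!is.null(interventions) && nrow(interventions) > 0) {
    acc <- interventions[interventions$kind == "accept" &
                           interventions$flight %in% ac, , drop = FALSE]
    if (nrow(acc) > 0) {
      a <- acc$flight[which.min(acc$t_s)]
      entry <- sector_entry_s(scenario$aircraft[[a]], scenario)
      time_to_accept <- min(acc$t_s) - if (is.na(entry)) 0 else entry
    }
  }
  structure(
    list(conflict = conflict$name,
         solved = classify_solver(scenario, interventions, standard,
                                  flights = ac),
         fixation_time_s = fix_time,
         total_fixation_time_s = sum(fix_time),
         altitude_n = alt_n,
         speed_n = spd_n,
         total_interventions = sum(alt_n) + sum(spd_n),
         time_to_accept_s = time_to_accept),
    class = "conflict_record")
}

#' @export
print.conflict_record <- function(x, ...) {
  cat(sprintf("<conflict_record> %s: %s, %.1f s on conflict aircraft, %d intervention(s)\n",
              x$conflict, if (x$solved) "solved" else "unsolved",
              x$total_fixation_time_s, x$total_interventions))
  invisible(x)
}

#' Mann-Whitney U test between solver and non-solver groups
#'
#' Rank-sum U with two-sided p: exact when both groups are small and
#' untied, normal approximation with tie correction otherwise (the
#' behaviour of [stats::wilcox.test()]).
#'
#' @param group_a,group_b Numeric vectors (both non-empty).
#' @return A list with `U` (for `group_a`) and `p`.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Variance inflation factors
#'
#' `1 / (1 - R^2_j)` from regressing each predictor on all the others;
#' exactly 1 for a single predictor or mutually orthogonal predictors.
#' Perfect collinearity is reported as `Inf` with a warning.
#'
#' @param predictors Data.frame or matrix of numeric predictors (>= 2 rows).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(predictors) {
  X <- as.data.frame(predictors)
  if (nrow(X) < 2) stop("need at least 2 observations", call. = FALSE)
  p <- ncol(X)
  if (p == 1) return(stats::setNames(1, names(X)))
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm(X[[j]] ~ ., data = X[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared)  # collinear fits warn
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(is.infinite(out)))
    warning("perfectly collinear predictors: infinite VIF", call. = FALSE)
  stats::setNames(out, names(X))
}

#' Forward-stepwise (Wald) binomial logistic regression
#'
#' Mirrors the classic forward-stepwise procedure for binary outcomes: at
#' each step the candidate predictor with the smallest score-test p-value is
#' entered if it passes the entry threshold; after each entry, any predictor
#' whose Wald p-value exceeds the removal threshold is dropped; selection
#' stops when no candidate qualifies (or at the iteration cap). Reports the
#' likelihood-ratio chi-square of each entry step, McFadden's
#' R-squared (1 - lnL / lnL0) for the final model, and VIFs over the
#' selected predictors.
#'
#' @param predictors Data.frame of numeric predictors.
#' @param outcome Logical or 0/1 vector with both classes present.
#' @param entry_p Score-test entry threshold (default 0.05).
#' @param removal_p Wald removal threshold (default 0.10).
#' @param max_steps Iteration cap (default 25).
#' @return A list of class `stepwise_logistic`: `selected`, `coefficients`,
#'   `steps` (data.frame: step, variable, action, chisq, df, p_score,
#'   p_lr), `mcfadden_r2`, `vif`, `separation_flag`, `model` (the final
#'   [stats::glm()] fit).
#' @export
forward_stepwise_logistic <- function(predictors, outcome, entry_p = 0.05,
                                      removal_p = 0.10, max_steps = 25) {
  X <- as.data.frame(predictors)
  y <- as.integer(outcome)
  if (length(unique(y)) < 2)
    stop("outcome must contain both classes", call. = FALSE)
  if (ncol(X) < 1) stop("need at least one predictor", call. = FALSE)
  dat <- cbind(.y = y, X)
  selected <- character(0)
  steps <- data.frame(step = integer(0), variable = character(0),
                      action = character(0), chisq = numeric(0),
                      df = integer(0), p_score = numeric(0),
                      p_lr = numeric(0))
  sep_flag <- FALSE
  fit_formula <- function(vars) {
    rhs <- if (length(vars) == 0) "1" else
      paste(sprintf("`%s`", vars), collapse = " + ")
    stats::as.formula(paste("`.y` ~", rhs))
  }
  fit <- function(vars) {
    withCallingHandlers(
      stats::glm(fit_formula(vars), family = stats::binomial(), data = dat),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep_flag <<- TRUE
        invokeRestart("muffleWarning")
      })
  }
  current <- fit(selected)
  step_i <- 0L
  repeat {
    step_i <- step_i + 1L
    if (step_i > max_steps) break
    candidates <- setdiff(names(X), selected)
    if (length(candidates) == 0) break
    # score (Rao) test of adding each candidate to the current model
    score_p <- vapply(candidates, function(v) {
      bigger <- fit(c(selected, v))
      an <- stats::anova(current, bigger, test = "Rao")
      an$`Pr(>Chi)`[2]
    }, numeric(1))
    best <- which.min(score_p)
    if (!is.finite(score_p[best]) || score_p[best] > entry_p) break
    entered <- candidates[best]
    bigger <- fit(c(selected, entered))
    lr <- as.numeric(2 * (stats::logLik(bigger) - stats::logLik(current)))
    steps <- rbind(steps, data.frame(
      step = step_i, variable = entered, action = "enter",
      chisq = lr, df = 1L, p_score = score_p[best],
      p_lr = stats::pchisq(lr, 1, lower.tail = FALSE)))
    selected <- c(selected, entered)
    current <- bigger
    # backward sweep: Wald removal
    repeat {
      if (length(selected) == 0) break
      co <- summary(current)$coefficients
      rn <- gsub("`", "", rownames(co))
      wald_p <- co[match(selected, rn), 4]
      wald_p[is.na(wald_p)] <- 1
      worst <- which.max(wald_p)
      if (wald_p[worst] < removal_p) break
      removed <- selected[worst]
      selected <- setdiff(selected, removed)
      smaller <- fit(selected)
      lr <- as.numeric(2 * (stats::logLik(current) - stats::logLik(smaller)))
      steps <- rbind(steps, data.frame(
        step = step_i, variable = removed, action = "remove",
        chisq = lr, df = 1L, p_score = NA_real_,
        p_lr = stats::pchisq(lr, 1, lower.tail = FALSE)))
      current <- smaller
    }
  }
  null_ll <- as.numeric(stats::logLik(fit(character(0))))
  final_ll <- as.numeric(stats::logLik(current))
  r2 <- if (null_ll == 0) 0 else 1 - final_ll / null_ll
  out <- list(selected = selected,
              coefficients = stats::coef(current),
              steps = steps,
              mcfadden_r2 = r2,
              vif = if (length(selected) > 0)
                vif(X[, selected, drop = FALSE]) else numeric(0),
              separation_flag = sep_flag,
              model = current)
  if (sep_flag)
    warning("quasi-complete separation detected; coefficients unreliable",
            call. = FALSE)
  class(out) <- "stepwise_logistic"
  out
}

#' @export
print.stepwise_logistic <- function(x, ...) {
  cat("<stepwise_logistic>\n")
  if (length(x$selected) == 0) {
    cat("  no predictor entered (intercept-only model)\n")
  } else {
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  }
  cat(sprintf("  McFadden R2 = %.3f%s\n", x$mcfadden_r2,
              if (x$separation_flag) " (separation flagged)" else ""))
  invisible(x)
}
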