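#' Mean Instantaneous Self-Assessment (ISA) rating
#'
#' ISA is sampled every 2 min during a 16-min scenario, giving exactly eight
#' 1--7 ratings whose arithmetic mean is analysed.
#'
#' @param ratings Integer vector of exactly 8 ratings in 1..7.
#' @return The mean rating.
#' @export
isa_mean <- function(ratings) {
  if (length(ratings) != 8)
    stop("ISA requires exactly 8 ratings (one every 2 min)", call. = FALSE)
  if (any(is.na(ratings)) || any(ratings < 1 | ratings > 7))
    stop("ISA ratings must lie in 1..7", call. = FALSE)
  mean(ratings)
}

#' NASA-TLX raw sum
#'
#' Six component scores in 1..20 are summed to a raw 6--120 workload score
#' (unweighted scoring).
#'
#' @param components Integer vector of exactly 6 component scores in 1..20.
#' @return The raw sum.
#' @export
nasa_tlx_sum <- function(components) {
  if (length(components) != 6)
    stop("NASA-TLX requires exactly 6 component scores", call. = FALSE)
  if (any(is.na(components)) || any(components < 1 | components > 20))
    stop("NASA-TLX components must lie in 1..20", call. = FALSE)
  sum(components)
}

#' Session-level workload metrics
#'
#' Assembles the per-session mental-workload indices analysed across the
#' experiment: mean pupil diameter, blink count and mean blink duration,
#' fixation time (s) and count per static AOI, ISA mean, NASA-TLX sum, and
#' mean head (eye-tracker) distance. Blink mean duration is `NA` for
#' zero-blink sessions and propagates as missing.
#'
#' @param stream A [gaze_stream()].
#' @param blinks A `blink_detection` result for the stream.
#' @param fixations Fixations from [detect_fixations()].
#' @param aois Static AOIs from [build_static_aois()].
#' @param scores List with `isa_ratings` (8 values, 1..7) and
#'   `nasa_components` (6 values, 1..20).
#' @return A one-row data.frame of class `session_metrics`.
#' @export
session_metrics <- function(stream, blinks, fixations, aois, scores) {
  if (is.null(stream) || is.null(blinks) || is.null(fixations) ||
      is.null(aois) || is.null(scores))
    stop("all of stream, blinks, fixations, aois, scores are required",
         call. = FALSE)
  bs <- blink_stats(blinks)
  lab <- assign_fixation_static(fixations, aois)
  time_for <- function(l) sum(fixations$duration_ms[lab == l]) / 1000
  count_for <- function(l) sum(lab == l)
  dist_mean <- if ("eye_distance_cm" %in% names(stream$samples))
    mean(stream$samples$eye_distance_cm, na.rm = TRUE) else NA_real_
  out <- data.frame(
    participant_id = stream$participant_id,
    condition_id = stream$condition_id,
    pupil_mean_mm = pupil_mean(stream),
    blink_count = bs$count,
    blink_mean_ms = bs$mean_duration_ms,
    fix_time_sector_s = time_for("sector"),
    fix_time_out_s = time_for("out_of_sector"),
    fix_time_sheet_s = time_for("sheet"),
    fix_count_sector = count_for("sector"),
    fix_count_out = count_for("out_of_sector"),
    fix_count_sheet = count_for("sheet"),
    isa_mean = isa_mean(scores$isa_ratings),
    nasa_sum = nasa_tlx_sum(scores$nasa_components),
    head_distance_mean_cm = dist_mean)
  class(out) <- c("session_metrics", "data.frame")
  out
}

#' Two-by-three repeated-measures ANOVA
#'
#' Within-subject ANOVA for the 2 (traffic) x 3 (complexity) design. Returns
#' the traffic, complexity and interaction effects with F, degrees of
#' freedom, p, and partial eta squared. For effects with more than two
#' levels, sphericity is assessed with Mauchly's test and the Huynh-Feldt
#' correction is applied to the degrees of freedom and p-value whenever
#' Mauchly's p < 0.05.
#'
#' @param metrics Data.frame with columns `participant_id`, `traffic`,
#'   `complexity` and the metric named by `value`; one row per participant
#'   per condition, complete and balanced (no imputation is performed).
#' @param value Name of the metric column (default `"value"`).
#' @return A data.frame of class `anova_result` with one row per effect:
#'   `effect`, `F`, `df1`, `df2`, `p`, `eta_p_sq`, `hf_epsilon` (`NA` when
#'   no correction applies), `mauchly_p`, `corrected`.
#' @export
rm_anova_2x3 <- function(metrics, value = "value") {
  d <- metrics
  stopifnot(all(c("participant_id", "traffic", "complexity", value) %in%
                  names(d)))
  d$traffic <- factor(d$traffic)
  cpx_levels <- unique(as.character(d$complexity))
  named <- c("low", "medium", "high")
  d$complexity <- factor(d$complexity,
                         levels = if (all(cpx_levels %in% named))
                           intersect(named, cpx_levels) else sort(cpx_levels))
  if (nlevels(d$traffic) != 2 || nlevels(d$complexity) != 3)
    stop("design must have 2 traffic and 3 complexity levels", call. = FALSE)
  if (anyNA(d[[value]]))
    stop("missing cells: complete cases required (no imputation)",
         call. = FALSE)
  tab <- table(d$participant_id, d$traffic, d$complexity)
  if (any(tab != 1))
    stop("unbalanced design: need exactly one observation per participant ",
         "per condition", call. = FALSE)
  participants <- unique(d$participant_id)
  if (length(participants) < 3)
    stop("need at least 3 participants", call. = FALSE)
  # wide response matrix, conditions ordered traffic (slow) x complexity
  idata <- expand.grid(complexity = levels(d$complexity),
                       traffic = levels(d$traffic))[, c("traffic",
                                                        "complexity")]
  Y <- matrix(NA_real_, length(participants), 6)
  for (k in seq_len(6)) {
    sel <- d$traffic == idata$traffic[k] & d$complexity == idata$complexity[k]
    Y[, k] <- d[[value]][sel][match(participants, d$participant_id[sel])]
  }
  effects <- c("traffic", "complexity", "traffic:complexity")
  res <- data.frame(effect = effects, F = NA_real_, df1 = NA_real_,
                    df2 = NA_real_, p = NA_real_, eta_p_sq = NA_real_,
                    hf_epsilon = NA_real_, mauchly_p = NA_real_,
                    corrected = FALSE)
  # degenerate input (e.g. all cells equal within participant) yields zero
  # within-subject variance; report F = 0 rather than 0/0
  within_var <- apply(Y, 1, stats::var)
  if (all(within_var < 1e-24)) {
    res$F <- 0; res$p <- 1; res$eta_p_sq <- 0
    class(res) <- c("anova_result", "data.frame")
    return(res)
  }
  mod <- stats::lm(Y ~ 1)
  av <- car::Anova(mod, idata = idata, idesign = ~ traffic * complexity,
                   type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  for (i in seq_along(effects)) {
    row <- ut[effects[i], ]
    ss <- row[["Sum Sq"]]
    err <- row[["Error SS"]]
    res$F[i] <- if (ss < 1e-24) 0 else row[["F value"]]
    res$df1[i] <- row[["num Df"]]
    res$df2[i] <- row[["den Df"]]
    res$p[i] <- if (ss < 1e-24) 1 else row[["Pr(>F)"]]
    res$eta_p_sq[i] <- if (ss + err < 1e-24) 0 else ss / (ss + err)
  }
  # Huynh-Feldt correction for >2-level effects when Mauchly rejects
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments
  for (eff in c("complexity", "traffic:complexity")) {
    i <- match(eff, effects)
    m_p <- tryCatch(sph[eff, "p-value"], error = function(e) NA_real_)
    res$mauchly_p[i] <- m_p
    if (!is.na(m_p) && m_p < 0.05) {
      eps <- min(1, adj[eff, "HF eps"])
      res$hf_epsilon[i] <- eps
      res$df1[i] <- res$df1[i] * eps
      res$df2[i] <- res$df2[i] * eps
      res$p[i] <- adj[eff, "Pr(>F[HF])"]
      res$corrected[i] <- TRUE
    }
  }
  class(res) <- c("anova_result", "data.frame")
  res
}

#' Bonferroni-adjusted pairwise comparisons for one within-subject factor
#'
#' Paired t-tests between every pair of factor levels (each participant's
#' values averaged over the other factor), with p-values multiplied by the
#' number of comparisons and capped at 1.
#'
#' @param metrics Data.frame with `participant_id`, the factor column, and
#'   the metric column.
#' @param factor_name `"traffic"` or `"complexity"` (any column name).
#' @param value Name of the metric column.
#' @return Data.frame: `level_a`, `level_b`, `t`, `df`, `p_raw`, `p_adj`.
#' @export
bonferroni_pairwise <- function(metrics, factor_name, value = "value") {
  d <- metrics
  f <- factor(d[[factor_name]])
  if (nlevels(f) < 2) stop("factor needs at least 2 levels", call. = FALSE)
  agg <- stats::aggregate(d[[value]],
                          list(participant_id = d$participant_id, level = f),
                          mean)
  levs <- levels(f)
  pairs <- utils::combn(levs, 2)
  k <- ncol(pairs)
  out <- data.frame(level_a = pairs[1, ], level_b = pairs[2, ],
                    t = NA_real_, df = NA_real_, p_raw = NA_real_,
                    p_adj = NA_real_)
  for (i in seq_len(k)) {
    a <- agg$x[agg$level == pairs[1, i]][order(agg$participant_id[agg$level == pairs[1, i]])]
    b <- agg$x[agg$level == pairs[2, i]][order(agg$participant_id[agg$level == pairs[2, i]])]
    if (isTRUE(all.equal(a, b))) {
      out$t[i] <- 0; out$df[i] <- length(a) - 1
      out$p_raw[i] <- 1; out$p_adj[i] <- 1
      next
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    out$t[i] <- unname(tt$statistic)
    out$df[i] <- unname(tt$parameter)
    out$p_raw[i] <- tt$p.value
    out$p_adj[i] <- min(1, tt$p.value * k)
  }
  out
}

#' Spearman correlation matrix over condition means
#'
#' Rank correlations between pairs of variables computed over the six
#' traffic x complexity condition means, with exact p-values and Fisher-z
#' confidence intervals.
#'
#' @param condition_means Data.frame with one row per condition and one
#'   numeric column per variable.
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return Data.frame: `var_a`, `var_b`, `rho`, `p`, `ci_lower`, `ci_upper`.
#'   A constant variable yields `NA` rho flagged by a warning.
#' @export
spearman_condition_matrix <- function(condition_means, conf_level = 0.95) {
  vars <- names(condition_means)[vapply(condition_means, is.numeric,
                                        logical(1))]
  if (length(vars) < 2) stop("need at least 2 numeric variables",
                             call. = FALSE)
  n <- nrow(condition_means)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  pairs <- utils::combn(vars, 2)
  out <- data.frame(var_a = pairs[1, ], var_b = pairs[2, ],
                    rho = NA_real_, p = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  for (i in seq_len(ncol(pairs))) {
    a <- condition_means[[pairs[1, i]]]
    b <- condition_means[[pairs[2, i]]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("constant variable in pair ", pairs[1, i], " / ", pairs[2, i],
              ": rho undefined", call. = FALSE)
      next
    }
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
    rho <- unname(ct$estimate)
    out$rho[i] <- rho
    out$p[i] <- ct$p.value
    if (abs(rho) < 1 && n > 3) {
      se <- 1 / sqrt(n - 3)
      out$ci_lower[i] <- tanh(atanh(rho) - z * se)
      out$ci_upper[i] <- tanh(atanh(rho) + z * se)
    } else {
      out$ci_lower[i] <- out$ci_upper[i] <- rho
    }
  }
  out
}
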