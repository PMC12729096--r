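# Independent oracles and fixture builders used across the test files.

PERIOD_MS <- 1000 / 30

# Build a gaze stream from coordinate vectors on a uniform 30 Hz grid.
make_stream <- function(x, y, left_valid = rep(TRUE, length(x)),
                        right_valid = left_valid,
                        pupil = rep(3.5, length(x)),
                        geometry = screen_geometry()) {
  n <- length(x)
  gaze_stream(data.frame(
    t_ms = (seq_len(n) - 1) * PERIOD_MS,
    left_valid = left_valid, right_valid = right_valid,
    x_cm = x, y_cm = y,
    pupil_left_mm = pupil, pupil_right_mm = pupil,
    eye_distance_cm = rep(60, n)), geometry)
}

# Brute-force I-DT reference: scan each valid segment left to right; from
# start i take the longest window whose full pairwise dispersion (computed
# from scratch with dist()) stays within the bound; accept it if the
# duration reaches the minimum, else advance the start by one sample.
brute_force_idt <- function(stream, params = detection_params(),
                            geometry = stream$geometry) {
  s <- stream$samples
  period <- 1000 / geometry$sampling_rate_hz
  disp <- visual_angle_to_cm(params$fixation_dispersion_deg,
                             geometry$viewing_distance_cm)
  valid <- !is.na(s$x_cm) & !is.na(s$y_cm)
  n <- nrow(s)
  res <- list()
  seg_start <- NULL
  bounds <- rle(valid)
  ends <- cumsum(bounds$lengths)
  starts <- ends - bounds$lengths + 1
  for (seg in which(bounds$values)) {
    a <- starts[seg]; b <- ends[seg]
    i <- a
    while (i <= b) {
      j_max <- i
      for (j in i:b) {
        pts <- cbind(s$x_cm[i:j], s$y_cm[i:j])
        if (j > i && max(dist(pts)) > disp) break
        j_max <- j
      }
      dur <- s$t_ms[j_max] - s$t_ms[i] + period
      if (dur >= params$fixation_min_ms - 1e-9) {
        res[[length(res) + 1]] <- c(i, j_max)
        i <- j_max + 1
      } else {
        i <- i + 1
      }
    }
  }
  if (length(res) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  out <- do.call(rbind, res)
  data.frame(start = out[, 1], end = out[, 2])
}

# jittered random-walk stream whose windows exercise the dispersion bound
random_walk_stream <- function(n, seed, step_sd = 0.35) {
  set.seed(seed)
  x <- cumsum(rnorm(n, 0, step_sd)) + 30
  y <- cumsum(rnorm(n, 0, step_sd)) + 17
  valid <- runif(n) > 0.05
  make_stream(x, y, left_valid = valid, right_valid = valid)
}

# Balanced within-subject 2x3 ANOVA from first principles (textbook sums of
# squares); Y is participants x 6 columns ordered traffic (slow) x
# complexity (fast).
rm_anova_oracle <- function(Y) {
  n <- nrow(Y)
  A <- 2; B <- 3                    # traffic, complexity
  arr <- array(Y, dim = c(n, B, A)) # [subject, complexity, traffic]
  arr <- aperm(arr, c(1, 3, 2))     # [subject, traffic, complexity]
  G <- mean(arr)
  m_s <- apply(arr, 1, mean)
  m_a <- apply(arr, 2, mean)
  m_b <- apply(arr, 3, mean)
  m_sa <- apply(arr, c(1, 2), mean)
  m_sb <- apply(arr, c(1, 3), mean)
  m_ab <- apply(arr, c(2, 3), mean)
  ss_a <- n * B * sum((m_a - G)^2)
  ss_b <- n * A * sum((m_b - G)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, m_b, "+") + G)^2)
  ss_as <- B * sum((m_sa - outer(m_s, m_a, "+") + G)^2)
  ss_bs <- A * sum((m_sb - outer(m_s, m_b, "+") + G)^2)
  resid <- arr
  for (i in seq_len(n)) for (a in seq_len(A)) for (b in seq_len(B))
    resid[i, a, b] <- arr[i, a, b] - m_sa[i, a] - m_sb[i, b] - m_ab[a, b] +
      m_s[i] + m_a[a] + m_b[b] - G
  ss_abs <- sum(resid^2)
  f <- c(traffic = (ss_a / (A - 1)) / (ss_as / ((A - 1) * (n - 1))),
         complexity = (ss_b / (B - 1)) / (ss_bs / ((B - 1) * (n - 1))),
         interaction = (ss_ab / ((A - 1) * (B - 1))) /
           (ss_abs / ((A - 1) * (B - 1) * (n - 1))))
  eta <- c(ss_a / (ss_a + ss_as), ss_b / (ss_b + ss_bs),
           ss_ab / (ss_ab + ss_abs))
  p <- c(pf(f[1], A - 1, (A - 1) * (n - 1), lower.tail = FALSE),
         pf(f[2], B - 1, (B - 1) * (n - 1), lower.tail = FALSE),
         pf(f[3], (A - 1) * (B - 1), (A - 1) * (B - 1) * (n - 1),
            lower.tail = FALSE))
  list(F = f, p = p, eta_p_sq = eta)
}

# long-format metrics table from a participants x 6 matrix (columns ordered
# traffic slow, complexity fast: t6 low/med/high then t12 low/med/high)
long_from_wide <- function(Y) {
  n <- nrow(Y)
  grid <- expand.grid(complexity = c("low", "medium", "high"),
                      traffic = c(6L, 12L))
  do.call(rbind, lapply(seq_len(6), function(k)
    data.frame(participant_id = sprintf("P%02d", seq_len(n)),
               traffic = grid$traffic[k], complexity = grid$complexity[k],
               value = Y[, k])))
}

# exhaustive Mann-Whitney permutation reference (no ties)
mw_exact_perm <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- combn(m + n, m)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# two-trajectory hover scenario: aircraft fixed at a given lateral/vertical
# offset throughout (for separation-threshold scans)
hover_scenario <- function(lateral_nm, vertical_ft, duration_s = 10) {
  t1 <- trajectory("AAA111", data.frame(
    t_s = c(0, duration_s), x_nm = c(0, 0.001), y_nm = c(0, 0),
    alt_ft = c(30000, 30000), gs_kn = 1))
  t2 <- trajectory("BBB222", data.frame(
    t_s = c(0, duration_s), x_nm = c(lateral_nm, lateral_nm + 0.001),
    y_nm = c(0, 0), alt_ft = rep(30000 + vertical_ft, 2), gs_kn = 1))
  list(aircraft = list(AAA111 = t1, BBB222 = t2), duration_s = duration_s)
}

# inject both-eye-invalid gaps into a stream at known sample positions
inject_gaps <- function(stream, starts_idx, lengths) {
  s <- stream$samples
  for (k in seq_along(starts_idx)) {
    ii <- starts_idx[k]:(starts_idx[k] + lengths[k] - 1)
    s$left_valid[ii] <- FALSE
    s$right_valid[ii] <- FALSE
  }
  gaze_stream(s, stream$geometry)
}
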