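test_that("pairwise separation is Euclidean lateral plus absolute vertical", {
  a <- list(x_nm = 0, y_nm = 0, alt_ft = 30000)
  expect_equal(separation(a, a), c(lateral_nm = 0, vertical_ft = 0))
  b <- list(x_nm = 3, y_nm = 4, alt_ft = 30000)
  expect_equal(separation(a, b)[["lateral_nm"]], 5)
  c_ <- list(x_nm = 0, y_nm = 0, alt_ft = 31500)
  expect_equal(separation(a, c_),
               c(lateral_nm = 0, vertical_ft = 1500))
})

test_that("violation requires both minima to be strictly infringed", {
  expect_equal(check_separation(hover_scenario(4.9, 900))$time_s, 0)
  expect_true(is.na(check_separation(hover_scenario(5, 900))$time_s))
  expect_true(is.na(check_separation(hover_scenario(4.9, 1000))$time_s))
  expect_true(is.na(check_separation(hover_scenario(6, 1200))$time_s))
})

test_that("the packaged 12-high conflicts violate at their scripted times", {
  sc <- generate_scenario(condition(12, "high"))
  easy <- check_separation(sc, flights = c("POB456", "HYG532"))
  expect_equal(easy$time_s, 140)
  difficult <- check_separation(sc, flights = c("KET456", "REV756",
                                                "GPL751"))
  expect_equal(difficult$time_s, 240)
  expect_setequal(difficult$pair, c("KET456", "REV756"))
  # scenario-wide, the Easy conflict comes first
  expect_equal(check_separation(sc)$time_s, 140)
})

test_that("separation checking is monotone in the thresholds", {
  sc <- generate_scenario(condition(12, "high"))
  base <- check_separation(sc, flights = c("POB456", "HYG532"))$time_s
  wider <- check_separation(sc, flights = c("POB456", "HYG532"),
                            standard = separation_standard(8, 2000))$time_s
  expect_lte(wider, base)
  narrower <- check_separation(sc, flights = c("POB456", "HYG532"),
                               standard = separation_standard(2, 400))$time_s
  expect_gte(narrower, base)
})

test_that("a timely altitude clearance resolves the Easy conflict", {
  sc <- generate_scenario(condition(12, "high"))
  iv <- data.frame(t_s = 80, flight = "HYG532", kind = "altitude",
                   value = 32000)
  expect_true(is.na(check_separation(sc, iv,
                                     flights = c("POB456", "HYG532"))$time_s))
  expect_true(classify_solver(sc, iv, flights = c("POB456", "HYG532")))
  expect_false(classify_solver(sc, NULL, flights = c("POB456", "HYG532")))
  # a conflict-free pair is trivially solved
  expect_true(classify_solver(sc, NULL, flights = c("POB456", "SRT346")))
  expect_error(check_separation(sc, flights = "NOPE99"), "unknown flight")
})

test_that("post-violation clearances cannot change the outcome", {
  sc <- generate_scenario(condition(12, "high"))
  iv <- data.frame(t_s = 200, flight = "HYG532", kind = "altitude",
                   value = 32000)
  expect_false(classify_solver(sc, iv, flights = c("POB456", "HYG532")))
})

test_that("conflict variables tally fixation time and interventions", {
  sc <- generate_scenario(condition(12, "high"))
  cf <- sc$conflicts$easy
  fx <- data.frame(start_ms = c(70000, 90000), end_ms = c(75000, 95000),
                   duration_ms = c(5000, 5000), centroid_x_cm = 1,
                   centroid_y_cm = 1, n_samples = 150,
                   aircraft = c("HYG532", "POB456"))
  rec0 <- conflict_variables(fx[0, ], sc, cf, NULL)
  expect_equal(unname(rec0$fixation_time_s), c(0, 0))
  expect_equal(rec0$total_interventions, 0)
  expect_false(rec0$solved)

  iv <- data.frame(t_s = c(65, 80), flight = c("HYG532", "HYG532"),
                   kind = c("accept", "altitude"), value = c(NA, 32000))
  rec <- conflict_variables(fx, sc, cf, iv)
  expect_true(rec$solved)
  expect_equal(rec$altitude_n[["HYG532"]], 1)
  expect_equal(rec$total_interventions, 1)
  expect_equal(rec$fixation_time_s[["HYG532"]], 5)
  expect_equal(rec$total_fixation_time_s, 10)
  expect_equal(rec$time_to_accept_s, 65 - sector_entry_s(
    sc$aircraft$HYG532, sc))
  bad <- data.frame(t_s = 10, flight = "ZZZ999", kind = "altitude",
                    value = 30000)
  expect_error(conflict_variables(fx, sc, cf, bad), "unknown flight")
})

test_that("Mann-Whitney handles extremes and matches wilcox orientation", {
  a <- 1:8
  b <- 9:24
  mw <- mann_whitney(a, b)
  expect_true(mw$U %in% c(0, length(a) * length(b)))
  ident <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ident$p, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney equals exhaustive permutation for small groups", {
  set.seed(9)
  for (sizes in list(c(3, 4), c(4, 4), c(2, 7), c(5, 6), c(8, 8))) {
    a <- rnorm(sizes[1])
    b <- rnorm(sizes[2], 0.5)
    mw <- mann_whitney(a, b)
    ex <- mw_exact_perm(a, b)
    expect_equal(mw$U, ex$U)
    expect_equal(mw$p, ex$p, tolerance = 1e-12)
  }
})

test_that("VIF follows its closed form", {
  expect_equal(unname(vif(data.frame(x = rnorm(20)))), 1)
  # exactly orthogonal pair
  x1 <- scale(rnorm(40))[, 1]
  x2 <- scale(residuals(lm(rnorm(40) ~ x1)))[, 1]
  expect_equal(unname(vif(data.frame(x1, x2))), c(1, 1), tolerance = 1e-9)
  # empirical correlation exactly 0.9 -> VIF = 1/(1 - 0.81)
  z <- scale(residuals(lm(rnorm(40) ~ x1)))[, 1]
  x3 <- 0.9 * x1 + sqrt(1 - 0.81) * z
  v <- vif(data.frame(x1, x3))
  expect_equal(unname(v), rep(1 / (1 - 0.81), 2), tolerance = 1e-9)
  expect_warning(v2 <- vif(data.frame(a = x1, b = 2 * x1)), "collinear")
  expect_true(all(is.infinite(v2)))
})

test_that("VIF agrees with the standard regression-based diagnostic", {
  set.seed(10)
  X <- as.data.frame(matrix(rnorm(300), 100, 3))
  X$V3 <- X$V1 * 0.7 + X$V3
  y <- rnorm(100)
  fit <- lm(y ~ ., data = X)
  expect_equal(unname(vif(X)), unname(car::vif(fit)), tolerance = 1e-9)
})

test_that("stepwise selection finds a strong predictor and ignores noise", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 200
    X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    names(X) <- paste0("x", 1:6)
    eta <- 2 * X$x3
    y <- runif(n) < plogis(eta)
    sw <- suppressWarnings(forward_stepwise_logistic(X, y))
    if ("x3" %in% sw$selected) hits <- hits + 1
    expect_true(all(sw$vif >= 1))
    expect_true(sw$mcfadden_r2 >= 0 && sw$mcfadden_r2 < 1)
  }
  expect_gte(hits, 19)
})

test_that("an empty stepwise model has zero McFadden R-squared", {
  set.seed(17)                                  # seed where nothing enters
  X <- data.frame(x1 = rnorm(150), x2 = rnorm(150))
  y <- runif(150) < 0.5
  sw <- forward_stepwise_logistic(X, y)
  if (length(sw$selected) == 0) {
    expect_equal(sw$mcfadden_r2, 0)
    expect_equal(nrow(sw$steps), 0)
  } else {
    expect_lt(sw$mcfadden_r2, 0.05)
  }
  expect_error(forward_stepwise_logistic(X, rep(TRUE, 150)), "both classes")
})

test_that("quasi-complete separation is flagged", {
  X <- data.frame(x = c(rnorm(20, -3), rnorm(20, 3)))
  y <- rep(c(FALSE, TRUE), each = 20)
  expect_warning(sw <- forward_stepwise_logistic(X, y), "separation")
  expect_true(sw$separation_flag)
})
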