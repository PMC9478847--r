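# NIPALS PLSR against ordinary-least-squares oracles, component selection,
# and the error metrics.

test_that("with orthonormal predictors the regression vector is read off exactly", {
  set.seed(1)
  # centered orthonormal columns: the Gram matrix is the identity, so the
  # planted coefficients are the unique least-squares solution
  q <- qr.Q(qr(scale(matrix(rnorm(20 * 5), 20, 5), center = TRUE, scale = FALSE)))
  y <- 2 * q[, 1] - 1 * q[, 2]
  m <- fit_plsr(q, y, n_lv = 2L, strict = FALSE)
  expect_equal(m$coefficients, c(2, -1, 0, 0, 0), tolerance = 1e-8)
})

test_that("full-rank NIPALS equals ordinary least squares", {
  for (s in 1:3) {
    set.seed(s)
    x <- matrix(rnorm(50 * 10), 50, 10)
    y <- rnorm(50)
    m <- fit_plsr(x, y, n_lv = 10L)
    ols <- stats::lsfit(x, y)
    expect_equal(m$coefficients, unname(ols$coefficients[-1]), tolerance = 1e-8)
    expect_equal(predict(m, x), unname(y - ols$residuals), tolerance = 1e-8)
  }
})

test_that("degenerate targets and over-requested ranks are refused", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(fit_plsr(x, rep(1, 10), n_lv = 2L),
               class = "phenomap_error_degenerate_target")
  expect_error(fit_plsr(x, rnorm(10), n_lv = 5L),
               class = "phenomap_error_rank")
  # strictly rank-deficient X with more components requested than the rank
  x2 <- cbind(x[, 1], x[, 1], x[, 2], x[, 2], x[, 3], x[, 3])
  expect_error(fit_plsr(x2, x2[, 1] + rnorm(10, 0, 1e-3), n_lv = 5L),
               class = "phenomap_error_rank")
})

test_that("scores are orthogonal and calibration RSS never increases with components", {
  set.seed(2)
  x <- matrix(rnorm(60 * 12), 60, 12)
  y <- x %*% rnorm(12) + rnorm(60, 0, 0.5)
  m <- fit_plsr(x, y, n_lv = 8L)
  gram <- crossprod(m$x_scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  # Eq. 2-style reconstruction: X_centered = scores %*% t(loadings) + residual
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(m$x_scores %*% t(m$x_loadings) + m$x_residual, xc,
               tolerance = 1e-10, ignore_attr = TRUE)
  rss <- vapply(1:8, function(a) {
    fa <- fit_plsr(x, y, n_lv = a)
    sum((predict(fa, x) - y)^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("prediction behaves as the stated affine map", {
  set.seed(3)
  x <- matrix(rnorm(30 * 6), 30, 6)
  y <- x %*% rnorm(6) + rnorm(30, 0, 0.1)
  m <- fit_plsr(x, y, n_lv = 4L)
  # a spectrum equal to the centering means predicts the response mean
  expect_equal(predict(m, m$x_center), m$y_center, tolerance = 1e-10)
  # doubling a spectrum doubles y_hat minus the intercept
  s <- x[5, ]
  expect_equal(predict(m, 2 * s) - m$intercept,
               2 * (predict(m, s) - m$intercept), tolerance = 1e-10)
  expect_error(predict(m, rnorm(5)), class = "phenomap_error_grid")
})

test_that("one-SE component selection finds planted rank and resists pure noise", {
  set.seed(11)
  scores <- matrix(rnorm(80 * 2), 80, 2)
  load <- matrix(rnorm(2 * 12), 2, 12)
  x <- scores %*% load
  y <- scores %*% c(1.5, -2)
  expect_identical(as.integer(select_n_components(x, y, max_lv = 6L, seed = 2L)),
                   2L)
  picks <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    xn <- matrix(rnorm(40 * 10), 40, 10)
    yn <- rnorm(40)
    as.integer(select_n_components(xn, yn, max_lv = 5L, seed = s))
  }, integer(1))
  expect_gte(mean(picks == 1L), 0.9)
  # deterministic given seed
  set.seed(5); x5 <- matrix(rnorm(200), 20, 10); y5 <- rnorm(20)
  expect_identical(select_n_components(x5, y5, seed = 9L)[1],
                   select_n_components(x5, y5, seed = 9L)[1])
})

test_that("error metrics match their formulas", {
  y <- c(1, 2, 3, 4)
  perfect <- evaluate_predictions(y, y, 2L, "cal")
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$std_err, 0)
  expect_equal(perfect$rmse, 0)

  m <- evaluate_predictions(y, y + c(1, -1, 1, -1), 1L, "val")
  expect_equal(m$bias, 0)
  expect_equal(m$std_err, sqrt(4 / 3))

  base <- evaluate_predictions(y, rep(mean(y), 4), 1L, "val")
  expect_equal(base$r2, 0)

  shifted <- evaluate_predictions(y + 5, y + c(1, -1, 1, -1) + 5, 1L, "val")
  expect_equal(shifted$std_err, m$std_err)
  expect_equal(shifted$r2, m$r2)
  expect_error(evaluate_predictions(rep(1, 4), rep(1, 4), 1L, "val"),
               class = "phenomap_error_degenerate_target")
})

test_that("table-level fits expose broom-style summaries", {
  fx <- small_fixture()
  m <- fit_phenolics_model(fx$table, preprocess_spec("sg2"), n_lv = "cv",
                           seed = 1L)
  g <- glance(m)
  expect_named(g, c("preprocess", "n_bands", "n_lv", "r2_cal", "sec",
                    "r2_val", "sep", "rmse_val", "bias_val"))
  expect_identical(g$preprocess, "sg2")
  expect_true(g$r2_val > 0.5)  # a desk-scale fit must at least be informative
  td <- tidy(m)
  expect_identical(nrow(td), 106L)
  aug <- augment(m, fx$table)
  expect_true(all(c(".pred", ".resid") %in% names(aug)))
  expect_equal(aug$.resid, aug$.pred - aug$y)
})

test_that("comparator learners run behind one interface", {
  fx <- small_fixture()
  out <- dplyr::bind_rows(
    fit_comparator(fx$table, "pcr", preprocess_spec("sg2")),
    fit_comparator(fx$table, "regression_tree", preprocess_spec("sg2"))
  )
  expect_named(out, c("model", "r2_cal", "sec", "r2_val", "sep"))
  expect_true(all(is.finite(out$r2_val)))
})
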