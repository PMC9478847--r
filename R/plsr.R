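#' Partial least squares regression by NIPALS
#'
#' Fits a univariate-response PLSR model in score/loading form. With the
#' predictors X (n x B, centered internally) and response y (centered),
#' the decomposition is `X = A B' + C` and `y = D E' + F`, where A holds
#' the X scores, B the X loadings, D the y scores and E the y loadings;
#' the inner relation regresses the y scores on the X scores,
#' `D = A G + H` with `G = (A'A)^-1 A'D`. Each NIPALS iteration extracts
#' one latent variable from the deflated matrices. The regression vector
#' `K` (beta) and intercept are assembled so that
#' `y_hat = (x - x_center) . K + intercept`.
#'
#' @param x Predictor matrix, one row per (pretreated) spectrum.
#' @param y Numeric response vector (total phenolics, mg/g DW).
#' @param n_lv Number of latent variables, `<= min(n - 1, B)`.
#' @param tol Deflation tolerance; requesting more components than the
#'   effective rank raises a rank error.
#' @param strict If `FALSE`, a rank-deficient X truncates the component
#'   count to what the data support instead of erroring.
#' @return An object of class `plsr_model` with elements `x_scores`,
#'   `x_loadings`, `y_scores`, `y_loadings`, `weights`, `inner_coeffs`,
#'   `coefficients` (beta), `intercept`, `x_center`, `y_center`,
#'   `x_residual`, `y_residual`.
#' @export
fit_plsr <- function(x, y, n_lv, tol = 1e-12, strict = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); b <- ncol(x)
  if (n < 2L || length(y) != n) {
    abort_phenomap("need >= 2 rows and matching y length", "phenomap_error_parameter")
  }
  if (stats::sd(y) < 1e-12) {
    abort_phenomap("response has zero variance", "phenomap_error_degenerate_target")
  }
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > min(n - 1L, b)) {
    abort_phenomap("`n_lv` must be in [1, min(n - 1, B)]", "phenomap_error_rank")
  }
  x_center <- colMeans(x)
  y_center <- mean(y)
  xc <- sweep(x, 2L, x_center)
  yc <- y - y_center

  W <- matrix(0, b, n_lv)   # weights
  P <- matrix(0, b, n_lv)   # X loadings
  Tm <- matrix(0, n, n_lv)  # X scores
  U <- matrix(0, n, n_lv)   # y scores
  qv <- numeric(n_lv)       # y loadings
  g <- numeric(n_lv)        # inner coefficients

  xd <- xc; yd <- yc
  achieved <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(xd, yd)
    wn <- sqrt(sum(w^2))
    if (wn < tol) {
      if (strict) {
        abort_phenomap(
          sprintf("X is rank-deficient: only %d latent variable(s) available", a - 1L),
          "phenomap_error_rank"
        )
      }
      break
    }
    w <- w / wn
    t_a <- xd %*% w
    tt <- sum(t_a^2)
    if (tt < tol) {
      if (strict) {
        abort_phenomap("degenerate score vector during NIPALS",
                       "phenomap_error_rank")
      }
      break
    }
    p_a <- crossprod(xd, t_a) / tt
    q_a <- sum(yd * t_a) / tt
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    U[, a] <- yd
    qv[a] <- q_a
    g[a] <- sum(t_a * yd) / tt
    xd <- xd - t_a %*% t(p_a)
    yd <- yd - q_a * t_a
    achieved <- a
  }
  if (achieved < n_lv) {
    n_lv <- achieved
    W <- W[, seq_len(n_lv), drop = FALSE]
    P <- P[, seq_len(n_lv), drop = FALSE]
    Tm <- Tm[, seq_len(n_lv), drop = FALSE]
    U <- U[, seq_len(n_lv), drop = FALSE]
    qv <- qv[seq_len(n_lv)]
    g <- g[seq_len(n_lv)]
  }
  beta <- W %*% solve(crossprod(P, W), qv)
  model <- structure(
    list(n_lv = n_lv, weights = W, x_scores = Tm, x_loadings = P,
         y_scores = U, y_loadings = qv, inner_coeffs = g,
         x_residual = xd, y_residual = yd,
         coefficients = as.numeric(beta),
         intercept = y_center - sum(x_center * beta),
         x_center = x_center, y_center = y_center),
    class = "plsr_model"
  )
  model
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d latent variable(s), %d band(s)\n",
              x$n_lv, length(x$coefficients)))
  invisible(x)
}

#' Predict from a fitted PLSR model
#'
#' Row-wise linear prediction, `y_hat = (x - x_center) . K + intercept`.
#'
#' @param object A `plsr_model`.
#' @param x Spectra matrix (or single spectrum) on the model's band grid.
#' @param ... Unused.
#' @return Numeric vector of predictions (mg/g DW).
#' @export
predict.plsr_model <- function(object, x, ...) {
  x <- rbind_matrix(x)
  if (ncol(x) != length(object$coefficients)) {
    abort_phenomap("spectrum length does not match the model grid",
                   "phenomap_error_grid")
  }
  as.numeric(x %*% object$coefficients + object$intercept)
}

#' Cross-validated choice of the latent-variable count
#'
#' k-fold cross-validation over 1..`max_lv` components with the one-SE
#' rule: the selected count is the smallest whose CV RMSE lies within one
#' standard error of the global minimum. Fold assignment is seeded, so the
#' selection is deterministic.
#'
#' @param x,y Predictors and response, as in [fit_plsr()].
#' @param k_folds Number of folds (>= 2).
#' @param max_lv Largest component count to try.
#' @param seed Integer seed.
#' @return The selected count (integer) with the CV table attached as
#'   attribute `cv` (tibble: n_lv, rmse, se).
#' @export
select_n_components <- function(x, y, k_folds = 5L, max_lv = 10L, seed = 1L) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  if (max_lv < 1L) abort_phenomap("`max_lv` must be >= 1", "phenomap_error_parameter")
  if (k_folds < 2L) abort_phenomap("`k_folds` must be >= 2", "phenomap_error_parameter")
  max_lv <- min(max_lv, ncol(x), n - ceiling(n / k_folds) - 1L)
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  err <- matrix(NA_real_, k_folds, max_lv)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    fit_max <- fit_plsr(x[tr, , drop = FALSE], y[tr], n_lv = max_lv,
                        strict = FALSE)
    for (a in seq_len(min(max_lv, fit_max$n_lv))) {
      # reuse the NIPALS path: beta for a components from the stored matrices
      beta_a <- fit_max$weights[, 1:a, drop = FALSE] %*%
        solve(crossprod(fit_max$x_loadings[, 1:a, drop = FALSE],
                        fit_max$weights[, 1:a, drop = FALSE]),
              fit_max$y_loadings[1:a])
      pred <- sweep(x[!tr, , drop = FALSE], 2L, fit_max$x_center) %*% beta_a +
        fit_max$y_center
      err[f, a] <- sqrt(mean((y[!tr] - pred)^2))
    }
  }
  rmse <- colMeans(err)
  se <- apply(err, 2L, stats::sd) / sqrt(k_folds)
  best <- which.min(rmse)
  chosen <- which(rmse <= rmse[best] + se[best])[1L]
  structure(as.integer(chosen),
            cv = tibble::tibble(n_lv = seq_len(max_lv), rmse = rmse, se = se))
}

#' Regression error metrics for calibration/validation partitions
#'
#' Computes the standard chemometric summary of a prediction set:
#' `r2 = 1 - RSS/TSS`; on calibration rows the dispersion is the standard
#' error of calibration `SEC = sqrt(RSS / (n - n_lv - 1))`, on validation
#' rows the bias-corrected standard error of prediction
#' `SEP = sqrt(sum((e - mean(e))^2) / (n - 1))`; `rmse = sqrt(RSS / n)`
#' and `bias = mean(e)` with `e = y_hat - y`.
#'
#' @param y Reference values (mg/g DW).
#' @param y_hat Predictions.
#' @param n_lv Latent-variable count (for the SEC degrees of freedom).
#' @param partition `"cal"` or `"val"`.
#' @return One-row tibble: `partition`, `n`, `n_lv`, `r2`, `std_err`
#'   (SEC or SEP by partition), `rmse`, `bias`.
#' @export
evaluate_predictions <- function(y, y_hat, n_lv = 1L,
                                 partition = c("cal", "val")) {
  partition <- match.arg(partition)
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  n <- length(y)
  if (n < 2L || length(y_hat) != n) {
    abort_phenomap("need matching y / y_hat of length >= 2",
                   "phenomap_error_parameter")
  }
  tss <- sum((y - mean(y))^2)
  if (tss < 1e-20) {
    abort_phenomap("reference values are constant", "phenomap_error_degenerate_target")
  }
  e <- y_hat - y
  rss <- sum(e^2)
  std_err <- if (partition == "cal") {
    sqrt(rss / max(n - n_lv - 1L, 1L))
  } else {
    sqrt(sum((e - mean(e))^2) / (n - 1L))
  }
  tibble::tibble(
    partition = partition, n = n, n_lv = as.integer(n_lv),
    r2 = 1 - rss / tss, std_err = std_err,
    rmse = sqrt(rss / n), bias = mean(e)
  )
}

#' Fit the phenolics model from a split spectra table
#'
#' Table-level wrapper around the chemometrics core: freezes the
#' pretreatment on calibration rows, optionally restricts to a waveband
#' selection, chooses the latent-variable count by cross-validation (or
#' takes a fixed count), fits NIPALS PLSR and evaluates both partitions.
#'
#' @param table A spectra table with `split` assigned and `y` set.
#' @param preprocess A [preprocess_spec()] (applied on the full grid before
#'   any band selection).
#' @param selection Optional `band_selection` restricting the model to the
#'   selected wavebands.
#' @param n_lv `"cv"` for one-SE cross-validation or a fixed integer.
#' @param max_lv,k_folds,seed Cross-validation controls.
#' @return An object of class `phenomap_model`: the `plsr_model` core plus
#'   the frozen pretreatment, band grid, optional selection and a metrics
#'   tibble.
#' @export
fit_phenolics_model <- function(table, preprocess = preprocess_spec("raw"),
                                selection = NULL, n_lv = "cv",
                                max_lv = 15L, k_folds = 5L, seed = 1L) {
  stopifnot(inherits(preprocess, "preprocess_spec"))
  if (!all(c("cal", "val") %in% table$split)) {
    abort_phenomap("table must contain both 'cal' and 'val' rows",
                   "phenomap_error_split")
  }
  wl <- spectra_wavelengths(table)
  x <- spectra_matrix(table)
  cal <- table$split == "cal"
  preprocess <- preprocess_fit(preprocess, x[cal, , drop = FALSE])
  xp <- preprocess_apply(preprocess, x)
  sel_idx <- NULL
  if (!is.null(selection)) {
    sel_idx <- selection$selected_indices
    if (length(sel_idx) == 0L) {
      abort_phenomap("band selection is empty", "phenomap_error_selection")
    }
    xp <- xp[, sel_idx, drop = FALSE]
  }
  y <- table$y
  if (identical(n_lv, "cv")) {
    n_lv <- select_n_components(xp[cal, , drop = FALSE], y[cal],
                                k_folds = k_folds, max_lv = max_lv, seed = seed)
    cv_tbl <- attr(n_lv, "cv")
  } else {
    cv_tbl <- NULL
  }
  core <- fit_plsr(xp[cal, , drop = FALSE], y[cal], n_lv = as.integer(n_lv))
  pred <- predict(core, xp)
  metrics <- dplyr::bind_rows(
    evaluate_predictions(y[cal], pred[cal], core$n_lv, "cal"),
    evaluate_predictions(y[!cal], pred[!cal], core$n_lv, "val")
  )
  structure(
    list(core = core, preprocess = preprocess,
         wavelengths_full = wl,
         wavelengths = if (is.null(sel_idx)) wl else wl[sel_idx],
         selection = selection, metrics = metrics,
         cv = cv_tbl),
    class = "phenomap_model"
  )
}

#' @export
print.phenomap_model <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<phenomap_model> %s, %d band(s), %d LV; R2c %.3f SEC %.3f | R2v %.3f SEP %.3f mg/g\n",
    x$preprocess$method, length(x$wavelengths), x$core$n_lv,
    g$r2_cal, g$sec, g$r2_val, g$sep
  ))
  invisible(x)
}

#' Predict total phenolics for the rows of a spectra table
#'
#' @param object A `phenomap_model`.
#' @param table A spectra table on the model's full band grid.
#' @param ... Unused.
#' @return Numeric vector of predictions (mg/g DW).
#' @export
predict.phenomap_model <- function(object, table, ...) {
  wl <- spectra_wavelengths(table)
  if (length(wl) != length(object$wavelengths_full) ||
      max(abs(wl - object$wavelengths_full)) > 1e-6) {
    abort_phenomap("table grid does not match the model's band grid",
                   "phenomap_error_grid")
  }
  xp <- preprocess_apply(object$preprocess, spectra_matrix(table))
  if (!is.null(object$selection)) {
    xp <- xp[, object$selection$selected_indices, drop = FALSE]
  }
  predict(object$core, xp)
}

#' Broom-style tidiers for phenolics models
#'
#' `tidy()` returns the per-wavelength regression vector (beta
#' coefficients); `glance()` returns the one-row model summary with the
#' calibration/validation metrics; `augment()` appends predictions and
#' residuals to a spectra table as `.pred` / `.resid`.
#'
#' @param x,object A `phenomap_model`.
#' @param table Spectra table for `augment()`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy phenomap_model
#' @export
tidy.phenomap_model <- function(x, ...) {
  tibble::tibble(
    wavelength_nm = x$wavelengths,
    estimate = x$core$coefficients
  )
}

#' @rdname tidy.phenomap_model
#' @method glance phenomap_model
#' @export
glance.phenomap_model <- function(x, ...) {
  m <- x$metrics
  cal <- m[m$partition == "cal", ]
  val <- m[m$partition == "val", ]
  tibble::tibble(
    preprocess = x$preprocess$method,
    n_bands = length(x$wavelengths),
    n_lv = x$core$n_lv,
    r2_cal = cal$r2, sec = cal$std_err,
    r2_val = val$r2, sep = val$std_err,
    rmse_val = val$rmse, bias_val = val$bias
  )
}

#' @rdname tidy.phenomap_model
#' @method augment phenomap_model
#' @export
augment.phenomap_model <- function(x, table, ...) {
  table$.pred <- predict(x, table)
  table$.resid <- table$.pred - table$y
  table
}

#' Serialize a fitted model to JSON
#'
#' Writes the band grid, beta coefficients, intercept, centering means,
#' pretreatment spec, optional band selection and metrics — everything
#' needed to re-apply the model to new cubes.
#'
#' @param model A `phenomap_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(
    wavelengths_full = model$wavelengths_full,
    wavelengths = model$wavelengths,
    n_lv = model$core$n_lv,
    beta = model$core$coefficients,
    intercept = model$core$intercept,
    x_center = model$core$x_center,
    y_center = model$core$y_center,
    preprocess = model$preprocess[c("method", "sg_window", "sg_polyorder")],
    msc_reference = model$preprocess$msc_reference,
    selected_indices = model$selection$selected_indices,
    metrics = model$metrics
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Baseline comparator models
#'
#' Fits one of the reference learners used to benchmark PLSR — support
#' vector regression (`e1071`), a regression tree (`rpart`), or principal
#' component regression (PCA scores fed to ordinary least squares, composed
#' in-package) — on the same pretreated, optionally band-reduced table, and
#' evaluates it with the same metrics.
#'
#' @param table A split spectra table.
#' @param method `"svm"`, `"regression_tree"` or `"pcr"`.
#' @param preprocess A [preprocess_spec()].
#' @param selection Optional `band_selection`.
#' @param n_comp PCR component count.
#' @return One-row tibble: `model`, `r2_cal`, `sec`, `r2_val`, `sep`.
#' @export
fit_comparator <- function(table, method = c("svm", "regression_tree", "pcr"),
                           preprocess = preprocess_spec("raw"),
                           selection = NULL, n_comp = 10L) {
  method <- match.arg(method)
  cal <- table$split == "cal"
  x <- spectra_matrix(table)
  preprocess <- preprocess_fit(preprocess, x[cal, , drop = FALSE])
  xp <- preprocess_apply(preprocess, x)
  if (!is.null(selection)) xp <- xp[, selection$selected_indices, drop = FALSE]
  y <- table$y
  pred <- switch(method,
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        abort_phenomap("the 'e1071' package is required for SVM comparators",
                       "phenomap_error_dependency")
      }
      fit <- e1071::svm(xp[cal, , drop = FALSE], y[cal])
      as.numeric(predict(fit, xp))
    },
    regression_tree = {
      if (!requireNamespace("rpart", quietly = TRUE)) {
        abort_phenomap("the 'rpart' package is required for tree comparators",
                       "phenomap_error_dependency")
      }
      df <- as.data.frame(xp)
      df$.y <- y
      fit <- rpart::rpart(.y ~ ., data = df[cal, ])
      as.numeric(predict(fit, df))
    },
    pcr = {
      n_comp <- min(n_comp, ncol(xp), sum(cal) - 2L)
      pca <- stats::prcomp(xp[cal, , drop = FALSE], center = TRUE, scale. = FALSE)
      sc_cal <- pca$x[, seq_len(n_comp), drop = FALSE]
      fit <- stats::lm.fit(cbind(1, sc_cal), y[cal])
      sc_all <- sweep(xp, 2L, pca$center) %*% pca$rotation[, seq_len(n_comp), drop = FALSE]
      as.numeric(cbind(1, sc_all) %*% fit$coefficients)
    }
  )
  mc <- evaluate_predictions(y[cal], pred[cal], 1L, "cal")
  mv <- evaluate_predictions(y[!cal], pred[!cal], 1L, "val")
  tibble::tibble(model = method, r2_cal = mc$r2, sec = mc$std_err,
                 r2_val = mv$r2, sep = mv$std_err)
}
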