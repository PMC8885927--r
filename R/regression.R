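#' Percent sample deviation (SDEV)
#'
#' The model-error statistic used throughout pahcast:
#' \deqn{SDEV = 100 \sqrt{\frac{\sum ((cal - obs)/obs)^2}{N - k}}}
#' a root-mean-square *relative* error with a degrees-of-freedom correction.
#' Unlike R2, it weights small and large observations equally, so it exposes
#' models that fit the bulk of a right-skewed concentration distribution but
#' badly mispredict the low end.
#'
#' @param calculated Model predictions.
#' @param observed Observed values, all nonzero.
#' @param k Degrees-of-freedom correction; by convention in this package the
#'   number of fitted parameters including the intercept (0 gives the plain
#'   RMS relative error).
#' @return SDEV in percent (scalar).
#' @examples
#' sdev(c(2, 1), c(1, 1), k = 1)  # 100
#' @export
sdev <- function(calculated, observed, k = 0) {
  if (length(calculated) != length(observed)) {
    abort("`calculated` and `observed` must have the same length")
  }
  n <- length(observed)
  if (any(observed == 0)) abort("SDEV is undefined when any observed value is 0")
  if (n <= k) abort(sprintf("SDEV needs N > k (N = %d, k = %g)", n, k))
  100 * sqrt(sum(((calculated - observed) / observed)^2) / (n - k))
}

#' Fit a simple or multilinear surrogate model by OLS
#'
#' Ordinary least squares of one response column on one or more predictor
#' columns, with the full reporting surface used for surrogate PAH models:
#' coefficients with classical standard errors and two-sided t p-values,
#' R2, the overall F statistic with its p-value, N, the parameter count k,
#' and the SDEV of fitted versus observed response. The solve goes through
#' an orthogonal (QR) decomposition.
#'
#' @param data Tibble holding the response and predictors.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names.
#' @param intercept Fit an intercept (default `TRUE`).
#' @param sdev_k Value of k for the reported SDEV; defaults to the number of
#'   fitted parameters including the intercept. Pass another value to use the
#'   "number of predictors" reading instead.
#' @return A `pah_fit` object supporting [tidy()], [glance()], [predict()],
#'   [residual_diagnostics()] and [autoplot()].
#' @examples
#' d <- tibble::tibble(x = 1:10, y = 1 + 2 * (1:10))
#' fit <- fit_pah_ols(d, "y", "x")
#' glance(fit)$r_squared  # 1
#' @export
fit_pah_ols <- function(data, response, predictors, intercept = TRUE,
                        sdev_k = NULL) {
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("columns not in data: %s", paste(missing_cols, collapse = ", ")))
  }
  y <- data[[response]]
  n <- length(y)
  k <- length(predictors) + as.integer(intercept)
  if (n <= k) abort(sprintf("need N > k (N = %d, k = %d)", n, k))
  rhs <- paste(sprintf("`%s`", predictors), collapse = " + ")
  fml <- stats::as.formula(sprintf("`%s` ~ %s%s", response, rhs,
                                   if (intercept) "" else " - 1"))
  model <- lm(fml, data = data)
  if (anyNA(coef(model))) {
    dropped <- names(coef(model))[is.na(coef(model))]
    abort(sprintf("rank-deficient design; collinear term%s: %s",
                  if (length(dropped) > 1) "s" else "",
                  paste(gsub("`", "", dropped), collapse = ", ")))
  }
  sm <- withCallingHandlers(
    summary(model),
    warning = function(w) {
      # exact fits (noise-free oracles) trip summary.lm's perfect-fit warning
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  fstat <- sm$fstatistic
  overall_p <- if (!is.null(fstat)) {
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  } else {
    NA_real_
  }
  ct <- sm$coefficients
  coefs <- tibble(
    term = gsub("`", "", rownames(ct)),
    estimate = unname(ct[, 1]),
    std_error = unname(ct[, 2]),
    statistic = unname(ct[, 3]),
    p_value = unname(ct[, 4])
  )
  k_for_sdev <- sdev_k %||% k
  structure(
    list(
      model = model,
      response = response,
      predictors = predictors,
      intercept = intercept,
      coefficients = coefs,
      n = n,
      k = k,
      r_squared = sm$r.squared,
      f_statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
      p_value = overall_p,
      sdev_k = k_for_sdev,
      sdev_pct = sdev(stats::fitted(model), y, k = k_for_sdev)
    ),
    class = "pah_fit"
  )
}

#' @export
print.pah_fit <- function(x, ...) {
  cat(sprintf("<pah_fit> %s ~ %s%s\n", x$response,
              paste(x$predictors, collapse = " + "),
              if (x$intercept) "" else " (no intercept)"))
  cat(sprintf("  N = %d, k = %d, R2 = %.3f, F = %.4g, p = %.3g, SDEV = %.1f%%\n",
              x$n, x$k, x$r_squared, x$f_statistic, x$p_value, x$sdev_pct))
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_pah_ols
#' @param x,object A `pah_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pah_fit <- function(x, ...) x$coefficients

#' @rdname fit_pah_ols
#' @exportS3Method generics::glance
glance.pah_fit <- function(x, ...) {
  tibble(
    r_squared = x$r_squared,
    f_statistic = x$f_statistic,
    p_value = x$p_value,
    n = x$n,
    k = x$k,
    sdev_pct = x$sdev_pct,
    df_residual = x$n - x$k
  )
}

#' @rdname fit_pah_ols
#' @param new_data Tibble with the fit's predictor columns.
#' @export
predict.pah_fit <- function(object, new_data, ...) {
  missing_cols <- setdiff(object$predictors, names(new_data))
  if (length(missing_cols) > 0) {
    abort(sprintf("new_data is missing predictor%s: %s",
                  if (length(missing_cols) > 1) "s" else "",
                  paste(missing_cols, collapse = ", ")))
  }
  unname(predict(object$model, newdata = as.data.frame(new_data)))
}

# coerce a pah_fit or a term/estimate tibble (e.g. published_model()) to a
# plain coefficient table
coef_table <- function(fit) {
  if (inherits(fit, "pah_fit")) return(fit$coefficients[c("term", "estimate")])
  if (is.data.frame(fit) && all(c("term", "estimate") %in% names(fit))) {
    return(as_tibble(fit)[c("term", "estimate")])
  }
  abort("`fit` must be a pah_fit or a tibble with columns term and estimate")
}

# evaluate intercept + sum(coef * column) on `data`
linear_predict <- function(coefs, data) {
  icpt <- coefs$estimate[coefs$term == "(Intercept)"]
  icpt <- if (length(icpt) == 0) 0 else icpt
  terms <- coefs[coefs$term != "(Intercept)", ]
  missing_cols <- setdiff(terms$term, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("data is missing predictor%s: %s",
                  if (length(missing_cols) > 1) "s" else "",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- rep(icpt, nrow(data))
  for (i in seq_len(nrow(terms))) {
    out <- out + terms$estimate[i] * data[[terms$term[i]]]
  }
  out
}

#' Residual diagnostics for a surrogate fit
#'
#' Returns the unstandardized residuals together with, for each predictor,
#' the OLS slope of the residuals on that predictor and its p-value. For
#' predictors already in the model that slope is zero by the normal
#' equations, so the check is informative for *candidate* predictors or for
#' curvature (supply transformed columns via `extra`). The fit is flagged
#' `stable` when no trend is significant at 0.05.
#'
#' @param fit A `pah_fit`.
#' @param extra Optional tibble of additional columns (aligned with the
#'   training rows) to test residual trends against.
#' @return A `pah_diagnostics` list: `residuals` tibble (fitted, residual,
#'   predictor columns), `trends` tibble (term, slope, p_value), and
#'   `stable`.
#' @export
residual_diagnostics <- function(fit, extra = NULL) {
  stopifnot(inherits(fit, "pah_fit"))
  mf <- fit$model$model
  res <- stats::residuals(fit$model)
  resid_tbl <- tibble(
    fitted = unname(stats::fitted(fit$model)),
    residual = unname(res)
  )
  pred_data <- as_tibble(mf)[, -1, drop = FALSE]
  names(pred_data) <- gsub("`", "", names(pred_data))
  resid_tbl <- dplyr::bind_cols(resid_tbl, pred_data)
  if (!is.null(extra)) {
    extra <- as_tibble(extra)
    if (nrow(extra) != nrow(resid_tbl)) abort("`extra` must align with the training rows")
    pred_data <- dplyr::bind_cols(pred_data, extra)
  }
  trends <- purrr::map_dfr(names(pred_data), function(nm) {
    tfit <- lm(res ~ x, data = data.frame(res = res, x = pred_data[[nm]]))
    ct <- summary(tfit)$coefficients
    tibble(term = nm, slope = ct["x", 1], p_value = ct["x", 4])
  })
  structure(
    list(residuals = resid_tbl, trends = trends,
         stable = all(trends$p_value > 0.05)),
    class = "pah_diagnostics"
  )
}

#' @export
print.pah_diagnostics <- function(x, ...) {
  cat(sprintf("<pah_diagnostics> %s (all trend p > 0.05: %s)\n",
              if (x$stable) "stable" else "trend detected", x$stable))
  print(x$trends)
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pah_diagnostics <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$residuals, -c("fitted", "residual"),
    names_to = "predictor", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$residual)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~predictor, scales = "free_x") +
    ggplot2::labs(x = "predictor value", y = "unstandardized residual") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pah_fit <- function(object, ...) {
  d <- tibble(
    observed = object$model$model[[1]],
    calculated = unname(stats::fitted(object$model))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$calculated)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::labs(
      x = sprintf("%s (observed)", object$response),
      y = sprintf("%s (calculated)", object$response),
      title = sprintf("R2 = %.2f, SDEV = %.0f%%", object$r_squared, object$sdev_pct)
    ) +
    ggplot2::theme_minimal()
}
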