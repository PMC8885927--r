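#' Emission-to-sediment transfer parameters
#'
#' The transfer model maps a congener's annual regional emission E (tonnes
#' per year) to its expected sediment concentration (micrograms per kilogram
#' dry weight) through the hydrophobicity-dependent linear form
#' \deqn{C = K(\log K_{ow}) \, E + L(\log K_{ow})}
#' with the published closed forms
#' \deqn{K = k_{scale} \cdot \log K_{ow}^{\,k_{exponent}}, \qquad
#'       L = l_{slope} \cdot \log K_{ow} + l_{intercept}.}
#' K rises steeply with logKow (hydrophobic congeners partition into the
#' sediment organic phase), while L falls with logKow and turns negative
#' above logKow about 3.5 (soluble light congeners keep a positive
#' water-borne background). Defaults are the published constants; override
#' any of them, e.g. after [refit_transfer()].
#'
#' @param k_scale,k_exponent Power-law parameters of K (defaults 3e-6, 8.24).
#' @param l_slope,l_intercept Linear parameters of L (defaults -117.41,
#'   416.16).
#' @return A `pah_transfer_params` list.
#' @export
transfer_params <- function(k_scale = 3e-6, k_exponent = 8.24,
                            l_slope = -117.41, l_intercept = 416.16) {
  if (k_scale <= 0) abort("k_scale must be positive")
  structure(
    list(k_scale = k_scale, k_exponent = k_exponent,
         l_slope = l_slope, l_intercept = l_intercept),
    class = "pah_transfer_params"
  )
}

#' @export
print.pah_transfer_params <- function(x, ...) {
  cat(sprintf("<pah_transfer_params> K = %g * logKow^%g; L = %g * logKow + %g\n",
              x$k_scale, x$k_exponent, x$l_slope, x$l_intercept))
  invisible(x)
}

#' Transfer coefficients K and L
#'
#' Closed-form slope `K` and intercept `L` of the emission-to-sediment
#' transfer line as functions of a congener's logKow. Vectorised.
#'
#' @param logkow log10 octanol-water partition coefficient(s), positive.
#' @param params A [transfer_params()] object.
#' @return Numeric vector.
#' @examples
#' k_coefficient(1)  # 3e-6
#' l_coefficient(0)  # 416.16
#' @export
k_coefficient <- function(logkow, params = transfer_params()) {
  if (any(logkow <= 0)) abort("logkow must be positive")
  params$k_scale * logkow^params$k_exponent
}

#' @rdname k_coefficient
#' @export
l_coefficient <- function(logkow, params = transfer_params()) {
  if (any(!is.finite(logkow))) abort("logkow must be finite")
  params$l_slope * logkow + params$l_intercept
}

#' Predict one congener's sediment concentration from its emission
#'
#' `max(0, K * E + L)`: the linear transfer prediction, floored at zero
#' because a concentration cannot be negative (high-logKow congeners have
#' L < 0, so tiny emissions would otherwise predict below zero). Flooring
#' events are reported via the `"floored"` attribute.
#'
#' @param e Annual emission(s), tonnes per year, nonnegative.
#' @inheritParams k_coefficient
#' @return Predicted concentration(s), micrograms per kilogram dry weight,
#'   with attribute `floored` (logical vector).
#' @export
predict_congener <- function(e, logkow, params = transfer_params()) {
  if (any(e < 0)) abort("emissions must be nonnegative")
  raw <- k_coefficient(logkow, params) * e + l_coefficient(logkow, params)
  out <- pmax(0, raw)
  attr(out, "floored") <- raw < 0
  out
}

#' Predict total sediment PAH concentration from congener emissions
#'
#' Composes the transfer model with a four-congener surrogate model: each
#' characteristic congener's sediment concentration is predicted from its
#' regional emission and logKow via [predict_congener()], and the predicted
#' concentrations are combined through the surrogate model's intercept and
#' coefficients into the total concentration
#' \eqn{C_{total}(cal)}. When observed region-year totals are supplied they
#' are joined on (region, year) and the SDEV of the predictions is reported.
#'
#' @param emissions Tibble with `region`, `year` and one emission column
#'   (tonnes per year) per predictor congener of `sediment_fit`.
#' @param physchem Physicochemical table (`congener`, `logkow`); defaults to
#'   the packaged literature values.
#' @param sediment_fit A `pah_fit` or a term/estimate coefficient tibble;
#'   defaults to the published four-congener sediment model
#'   ([published_model()]).
#' @param observed Optional tibble `region`, `year`, `total` of observed
#'   (typically geometric-mean) totals.
#' @param params [transfer_params()].
#' @param sdev_k k convention for the reported SDEV (default 0: the
#'   prediction uses no parameter fitted to the observed totals). SDEV under
#'   k in \{0, 1, number of model parameters\} brackets the plausible
#'   readings; all appear in the `sdev_bracket` attribute when `observed` is
#'   given.
#' @return A `pah_prediction` tibble: one row per region-year with predicted
#'   per-congener concentrations (`C_<congener>`), `total_cal`, the number of
#'   floored congeners (`n_floored`) and, when available, `total_obs` and
#'   `rel_error`. Attributes: `sdev_pct`, `sdev_bracket`, `n`.
#' @examples
#' em <- tibble::tibble(region = "r", year = 2000L,
#'                      Nap = 2000, Acy = 500, Phe = 600, BaA = 60)
#' predict_total(em)
#' @export
predict_total <- function(emissions, physchem = pah_physchem(),
                          sediment_fit = published_model("sediment"),
                          observed = NULL, params = transfer_params(),
                          sdev_k = 0) {
  coefs <- coef_table(sediment_fit)
  congeners <- setdiff(coefs$term, "(Intercept)")
  missing_cols <- setdiff(congeners, names(emissions))
  if (length(missing_cols) > 0) {
    abort(sprintf("emissions table is missing congener%s: %s",
                  if (length(missing_cols) > 1) "s" else "",
                  paste(missing_cols, collapse = ", ")))
  }
  physchem <- as_tibble(physchem)
  kow <- setNames(physchem$logkow, physchem$congener)
  if (anyNA(kow[congeners])) {
    abort(sprintf("physchem table lacks logKow for: %s",
                  paste(congeners[is.na(kow[congeners])], collapse = ", ")))
  }
  out <- as_tibble(emissions)[c("region", "year")]
  floored <- matrix(FALSE, nrow(out), length(congeners))
  conc <- out
  for (i in seq_along(congeners)) {
    cg <- congeners[i]
    p <- predict_congener(emissions[[cg]], kow[[cg]], params)
    floored[, i] <- attr(p, "floored")
    conc[[paste0("C_", cg)]] <- as.numeric(p)
  }
  pred_data <- setNames(conc[paste0("C_", congeners)], congeners)
  conc$total_cal <- linear_predict(coefs, pred_data)
  conc$n_floored <- rowSums(floored)
  sdev_pct <- NA_real_
  sdev_bracket <- NULL
  if (!is.null(observed)) {
    observed <- as_tibble(observed)
    need <- c("region", "year", "total")
    missing_obs <- setdiff(need, names(observed))
    if (length(missing_obs) > 0) {
      abort(sprintf("observed table is missing: %s", paste(missing_obs, collapse = ", ")))
    }
    conc <- dplyr::left_join(conc, observed |>
                               dplyr::select("region", "year", total_obs = "total"),
                             by = c("region", "year"))
    have <- !is.na(conc$total_obs)
    conc$rel_error <- (conc$total_cal - conc$total_obs) / conc$total_obs
    if (sum(have) > 0) {
      ks <- unique(c(sdev_k, 0, 1, nrow(coefs)))
      ks <- ks[sum(have) > ks]
      sdev_bracket <- setNames(
        vapply(ks, function(k) sdev(conc$total_cal[have], conc$total_obs[have], k),
               numeric(1)),
        paste0("k", ks)
      )
      sdev_pct <- sdev_bracket[[paste0("k", sdev_k)]]
    }
  }
  structure(conc, class = c("pah_prediction", class(conc)),
            sdev_pct = sdev_pct, sdev_bracket = sdev_bracket,
            n = nrow(conc))
}

#' @exportS3Method ggplot2::autoplot
autoplot.pah_prediction <- function(object, ...) {
  if (!"total_obs" %in% names(object)) {
    abort("autoplot needs predictions joined with observed totals")
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$total_obs, y = .data$total_cal)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "observed total (ug/kg)", y = "calculated total (ug/kg)",
      title = sprintf("SDEV = %.0f%% (N = %d)",
                      attr(object, "sdev_pct"), attr(object, "n"))
    ) +
    ggplot2::theme_minimal()
}

#' Ratio of sediment to emission-source model coefficients versus logKow
#'
#' Divides, congener by congener, the coefficients of the sediment surrogate
#' model by those of the emission-factor surrogate model, and regresses the
#' ratio on logKow. A positive slope indicates that hydrophobic congeners
#' are enriched in sediments relative to their emission share — the
#' partitioning signal that motivates the logKow-dependent transfer model.
#'
#' @param sediment_fit,ef_fit `pah_fit` objects or term/estimate tibbles
#'   sharing the same predictor congeners (defaults: the published models).
#' @param physchem Physicochemical table (`congener`, `logkow`).
#' @return A list with `ratios` (tibble congener, sediment, ef, ratio,
#'   logkow) and `fit` (`pah_fit` of ratio ~ logkow).
#' @examples
#' coefficient_ratio_analysis()$ratios$ratio
#' @export
coefficient_ratio_analysis <- function(sediment_fit = published_model("sediment"),
                                       ef_fit = published_model("ef"),
                                       physchem = pah_physchem()) {
  sc <- coef_table(sediment_fit)
  ec <- coef_table(ef_fit)
  congeners <- setdiff(sc$term, "(Intercept)")
  if (!setequal(congeners, setdiff(ec$term, "(Intercept)"))) {
    abort("the two fits must share the same predictor congeners")
  }
  kow <- setNames(as_tibble(physchem)$logkow, as_tibble(physchem)$congener)
  ratios <- tibble(
    congener = intersect(PAH_NAMES, congeners),
  ) |>
    dplyr::mutate(
      sediment = sc$estimate[match(.data$congener, sc$term)],
      ef = ec$estimate[match(.data$congener, ec$term)],
      ratio = .data$sediment / .data$ef,
      logkow = unname(kow[.data$congener])
    )
  if (any(ratios$ef == 0)) {
    abort(sprintf("zero EF-model coefficient for: %s",
                  paste(ratios$congener[ratios$ef == 0], collapse = ", ")))
  }
  fit <- fit_pah_ols(ratios, "ratio", "logkow")
  list(ratios = ratios, fit = fit)
}

#' Refit the transfer closed forms from per-congener K and L values
#'
#' Optional recalibration: given user-supplied per-congener K and L (e.g.
#' from regional paired emission-concentration data), refits the power law
#' `K = a * logKow^b` by log-log OLS and the line `L = m * logKow + c` by
#' plain OLS, returning a new [transfer_params()].
#'
#' @param data Tibble with columns `logkow`, `k`, `l` (K > 0).
#' @return A `pah_transfer_params` with refit constants; the two underlying
#'   `pah_fit`s are attached as attribute `fits`.
#' @export
refit_transfer <- function(data) {
  data <- as_tibble(data)
  need <- c("logkow", "k", "l")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("refit table is missing: %s", paste(missing_cols, collapse = ", ")))
  }
  if (any(data$k <= 0)) abort("K values must be positive for the power-law refit")
  loglog <- tibble(log_k = log10(data$k), log_kow = log10(data$logkow))
  kfit <- fit_pah_ols(loglog, "log_k", "log_kow")
  lfit <- fit_pah_ols(data, "l", "logkow")
  kc <- kfit$coefficients
  lc <- lfit$coefficients
  out <- transfer_params(
    k_scale = 10^kc$estimate[kc$term == "(Intercept)"],
    k_exponent = kc$estimate[kc$term == "log_kow"],
    l_slope = lc$estimate[lc$term == "logkow"],
    l_intercept = lc$estimate[lc$term == "(Intercept)"]
  )
  attr(out, "fits") <- list(k = kfit, l = lfit)
  out
}
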