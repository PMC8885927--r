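# The 16 USEPA priority PAHs, in the fixed panel order used everywhere for
# column matching and tie-breaking.
PAH_NAMES <- c(
  "Nap", "Acy", "Ace", "Flo", "Phe", "Ant", "Flu", "Pyr",
  "BaA", "Chr", "BbF", "BkF", "BaP", "IcdP", "BghiP", "DahA"
)

PAH_RINGS <- c(
  Nap = 2L, Acy = 3L, Ace = 3L, Flo = 3L, Phe = 3L, Ant = 3L,
  Flu = 4L, Pyr = 4L, BaA = 4L, Chr = 4L, BbF = 5L, BkF = 5L,
  BaP = 5L, IcdP = 6L, BghiP = 6L, DahA = 5L
)

# Literature-default log10 octanol-water partition coefficients (unitless).
# These are synthetic stand-ins assembled from standard property compilations,
# not a copy of any single published table; override via the `physchem`
# argument wherever logKow enters a computation.
PAH_LOGKOW <- c(
  Nap = 3.37, Acy = 4.00, Ace = 3.92, Flo = 4.18, Phe = 4.57, Ant = 4.54,
  Flu = 5.22, Pyr = 5.18, BaA = 5.91, Chr = 5.86, BbF = 5.80, BkF = 6.00,
  BaP = 6.04, IcdP = 6.70, BghiP = 6.63, DahA = 6.75
)

#' The 16-congener priority PAH panel
#'
#' The panel fixes the identity and order of the sixteen priority polycyclic
#' aromatic hydrocarbons (Nap through DahA). All table readers, clustering and
#' model-fitting functions in pahcast match congener columns against this
#' panel, and panel order is the tie-break rule wherever one is needed.
#'
#' @return A tibble with one row per congener and columns `congener`,
#'   `ring_count`, and `logkow` (literature-default log10 Kow, overridable in
#'   downstream functions).
#' @examples
#' pah_panel()
#' @export
pah_panel <- function() {
  tibble(
    congener = PAH_NAMES,
    ring_count = unname(PAH_RINGS[PAH_NAMES]),
    logkow = unname(PAH_LOGKOW[PAH_NAMES])
  )
}

#' @rdname pah_panel
#' @return `pah_congeners()` returns the ordered character vector of the 16
#'   congener abbreviations.
#' @export
pah_congeners <- function() PAH_NAMES

#' Default physicochemical reference table
#'
#' Per-congener log10 octanol-water partition coefficients used by the
#' transfer model when no user table is supplied. Values are literature
#' defaults (see [pah_panel()]); supply your own table to override.
#'
#' @return A tibble with columns `congener` and `logkow`.
#' @export
pah_physchem <- function() {
  tibble(congener = PAH_NAMES, logkow = unname(PAH_LOGKOW[PAH_NAMES]))
}

#' Published surrogate-model coefficient sets
#'
#' Reference coefficient tables for the published four-congener multilinear
#' surrogate models: the sediment-concentration model
#' (response total concentration, micrograms per kilogram dry weight,
#' N = 754 China samples) and the emission-factor model (response total EF,
#' grams per tonne, N = 15 source divisions). The four predictors are the
#' characteristic congeners Nap, Acy, Phe and BaA. These ship so that
#' predictions and the coefficient-ratio analysis can be run without refitting
#' when the underlying sample-level tables are not at hand.
#'
#' @param model `"sediment"` for the concentration model or `"ef"` for the
#'   emission-factor model.
#' @return A tibble with columns `term` (`"(Intercept)"` and the four congener
#'   names), `estimate`, and `std_error`, carrying attributes `response`,
#'   `n`, `r_squared`, `f_statistic` and `sdev_pct` as published.
#' @examples
#' published_model("sediment")
#' @export
published_model <- function(model = c("sediment", "ef")) {
  model <- match.arg(model)
  out <- switch(model,
    sediment = structure(
      tibble(
        term = c("(Intercept)", "Nap", "Acy", "Phe", "BaA"),
        estimate = c(22.62, 0.84, 1.23, 3.78, 5.97),
        std_error = c(11.78, 0.07, 0.13, 0.15, 0.22)
      ),
      response = "C_totalPAHs", n = 754L, r_squared = 0.95,
      f_statistic = 2740, sdev_pct = 35
    ),
    ef = structure(
      tibble(
        term = c("(Intercept)", "Nap", "Acy", "Phe", "BaA"),
        estimate = c(-0.45, 0.98, 1.12, 2.82, 4.04),
        std_error = c(0.46, 0.12, 0.11, 0.23, 0.47)
      ),
      response = "EF_totalPAHs", n = 15L, r_squared = 0.99,
      f_statistic = 5257, sdev_pct = 24
    )
  )
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

# Return the congener columns present in `data`, erroring (with names) when
# panel coverage is incomplete.
congener_cols <- function(data, where = "table") {
  present <- intersect(PAH_NAMES, names(data))
  missing <- setdiff(PAH_NAMES, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing congener column%s: %s",
      where, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  present
}
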