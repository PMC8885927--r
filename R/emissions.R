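#' Time-dependent technology fraction (S-curve)
#'
#' Fraction of a source's activity handled by a given technology division as
#' it is phased in or out, following the symmetric-Gaussian S-curve
#' \deqn{X(t) = (X_0 - X_f) e^{-(t - t_0)^2 / (2 s^2)} + X_f, \quad t \ge t_0}
#' with `X(t) = X0` held constant before the transition start `t0` (evaluated
#' unclamped the curve would relax back toward `Xf` for `t < t0`, which
#' contradicts a monotone technology adoption, so the pre-transition branch
#' is clamped). X is bounded between `x0` and `xf` and monotone in t.
#'
#' @param transitions Tibble with columns `source`, `technology`, `x0`, `xf`,
#'   `t0`, `s` (fractions in \eqn{[0,1]}, years; `s > 0`).
#' @param years Integer vector of years to evaluate.
#' @return A tibble `source`, `technology`, `year`, `fraction` for every
#'   transition-year combination. Fractions are *not* renormalised here; see
#'   [effective_ef()].
#' @examples
#' tr <- tibble::tibble(source = "coke", technology = "old",
#'                      x0 = 1, xf = 0, t0 = 1990, s = 10)
#' technology_fraction(tr, c(1980, 1990, 2000))
#' @export
technology_fraction <- function(transitions, years) {
  transitions <- as_tibble(transitions)
  need <- c("source", "technology", "x0", "xf", "t0", "s")
  missing_cols <- setdiff(need, names(transitions))
  if (length(missing_cols) > 0) {
    abort(sprintf("transitions table is missing: %s", paste(missing_cols, collapse = ", ")))
  }
  if (any(transitions$s <= 0)) abort("rate parameter s must be positive")
  if (any(transitions$x0 < 0 | transitions$x0 > 1 |
            transitions$xf < 0 | transitions$xf > 1)) {
    abort("fractions x0 and xf must lie in [0, 1]")
  }
  tidyr::crossing(transitions, year = as.integer(years)) |>
    dplyr::mutate(
      fraction = s_curve(.data$year, .data$x0, .data$xf, .data$t0, .data$s)
    ) |>
    dplyr::select("source", "technology", "year", "fraction")
}

# vectorised S-curve core with the pre-t0 clamp
s_curve <- function(t, x0, xf, t0, s) {
  ifelse(t < t0, x0, (x0 - xf) * exp(-(t - t0)^2 / (2 * s^2)) + xf)
}

# fractions for every division of every source at `year`, renormalised to sum
# to 1 within each source; divisions absent from `transitions` get a constant
# fraction of 1 (single-division sources with fixed EFs)
division_fractions <- function(ef_table, transitions, year) {
  divs <- ef_table[intersect(c("division_id", "source", "technology"), names(ef_table))]
  if (!"source" %in% names(divs)) {
    divs$source <- divs$division_id
  }
  if (!"technology" %in% names(divs)) divs$technology <- NA_character_
  if (is.null(transitions) || nrow(transitions) == 0) {
    divs$fraction <- 1
  } else {
    fr <- technology_fraction(transitions, year)
    divs <- dplyr::left_join(divs, fr[c("source", "technology", "fraction")],
                             by = c("source", "technology"))
    divs$fraction[is.na(divs$fraction)] <- 1
  }
  divs |>
    dplyr::group_by(.data$source) |>
    dplyr::mutate(fraction = {
      tot <- sum(.data$fraction)
      if (tot <= 0) abort(sprintf(
        "technology fractions for source '%s' sum to 0 in %d",
        .data$source[1], year
      ))
      .data$fraction / tot
    }) |>
    dplyr::ungroup()
}

#' Technology-blended emission factors of a source
#'
#' Blends the per-division emission factors of one source into a single
#' per-congener EF vector for a given year, weighting each division by its
#' technology fraction (renormalised within the source to sum to 1). Sources
#' with a single division and no configured transition return their EF row
#' unchanged at any year.
#'
#' @param ef_table EF tibble (see [read_pah_table()] schema `"ef"`) with a
#'   `source` column distinguishing divisions of the same source.
#' @param transitions Transition-parameter tibble (see
#'   [technology_fraction()]), or `NULL` for fixed divisions.
#' @param source Source label.
#' @param year Year at which to evaluate the technology split.
#' @return One-row tibble: `source`, `year`, and the 16 blended congener EFs
#'   (grams per tonne).
#' @export
effective_ef <- function(ef_table, transitions, source, year) {
  cols <- congener_cols(ef_table)
  if (!"source" %in% names(ef_table)) ef_table$source <- ef_table$division_id
  rows <- ef_table[ef_table$source == source, , drop = FALSE]
  if (nrow(rows) == 0) abort(sprintf("unknown source '%s'", source))
  fr <- division_fractions(rows, transitions, year)
  w <- fr$fraction
  blended <- colSums(as.matrix(rows[cols]) * w)
  dplyr::bind_cols(tibble(source = source, year = as.integer(year)),
                   as_tibble(as.list(blended)))
}

#' Per-congener emission inventory
#'
#' Combines emission factors, technology-split fractions and activity data
#' into annual per-congener emissions for every region-year:
#' \deqn{E_i = \sum_{j,k} EF_{i,j,k} \, X_{j,k}(t) \, A_j \times 10^{-2}}
#' with EF in grams per tonne and activity A in units of 1e4 tonnes per
#' year, so E comes out in tonnes per year (1 g/t x 1e4 t = 1e4 g = 1e-2 t).
#'
#' @inheritParams effective_ef
#' @param activities Activity tibble with columns `region`, `year`, `source`,
#'   `activity` (1e4 t per year).
#' @return A tibble with `region`, `year`, the 16 congener emission columns
#'   (tonnes per year) and `total`. The per-source breakdown is attached as
#'   attribute `"by_source"` (long tibble region, year, source, congener,
#'   emission_t).
#' @examples
#' ef <- tibble::as_tibble(c(list(source = "s"),
#'   setNames(as.list(rep(2, 16)), pah_congeners())))
#' act <- tibble::tibble(region = "r", year = 2000L, source = "s", activity = 1)
#' total_emission(ef, NULL, act)$Nap  # 0.02 t/a
#' @export
total_emission <- function(ef_table, transitions, activities) {
  cols <- congener_cols(ef_table)
  activities <- as_tibble(activities)
  need <- c("region", "year", "source", "activity")
  missing_cols <- setdiff(need, names(activities))
  if (length(missing_cols) > 0) {
    abort(sprintf("activities table is missing: %s", paste(missing_cols, collapse = ", ")))
  }
  unknown <- setdiff(
    unique(activities$source),
    unique(if ("source" %in% names(ef_table)) ef_table$source else ef_table$division_id)
  )
  if (length(unknown) > 0) {
    abort(sprintf("activities reference unknown source%s: %s",
                  if (length(unknown) > 1) "s" else "", paste(unknown, collapse = ", ")))
  }
  if (!"source" %in% names(ef_table)) ef_table$source <- ef_table$division_id
  acts <- activities |>
    dplyr::group_by(.data$region, .data$year, .data$source) |>
    dplyr::summarise(activity = sum(.data$activity), .groups = "drop")
  # division weights per (source, year): renormalised technology fractions
  weights <- acts |>
    dplyr::distinct(.data$source, .data$year) |>
    purrr::pmap_dfr(function(source, year) {
      rows <- ef_table[ef_table$source == source, , drop = FALSE]
      fr <- division_fractions(rows, transitions, year)
      tibble(source = source, year = year,
             row = which(ef_table$source == source), fraction = fr$fraction)
    })
  efm <- as.matrix(ef_table[cols])
  by_source <- dplyr::inner_join(acts, weights, by = c("source", "year"),
                                 relationship = "many-to-many")
  contrib <- efm[by_source$row, , drop = FALSE] *
    (by_source$activity * by_source$fraction * 1e-2)
  by_source <- dplyr::bind_cols(
    by_source[c("region", "year", "source")],
    as_tibble(as.data.frame(contrib))
  ) |>
    dplyr::group_by(.data$region, .data$year, .data$source) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), sum), .groups = "drop")
  wide <- by_source |>
    dplyr::group_by(.data$region, .data$year) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), sum), .groups = "drop") |>
    pah_total()
  long <- tidyr::pivot_longer(by_source, dplyr::all_of(cols),
                              names_to = "congener", values_to = "emission_t")
  attr(wide, "by_source") <- long
  wide
}
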