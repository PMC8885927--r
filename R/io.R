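#' Read a congener data table
#'
#' Reads a delimited text file (CSV or TSV, sniffed from the extension) into a
#' validated tibble of one of four schemas:
#'
#' * `"concentration"`: one sediment sample per row; the 16 congener columns
#'   hold concentrations in micrograms per kilogram dry weight; optional
#'   metadata columns `sample_id`, `region`, `year`, `foc`.
#' * `"ef"`: one emission source division per row; congener columns hold
#'   emission factors in grams per tonne; label columns `source` and
#'   optionally `technology` (a `division_id` is derived as
#'   `source:technology`).
#' * `"activity"`: columns `region`, `year`, `source`, `activity`
#'   (units of 1e4 tonnes per year).
#' * `"physchem"`: columns `congener`, `logkow` (optionally `sw`,
#'   `half_life`); must cover the full panel with finite positive logKow.
#'
#' Left-censored concentration cells are substituted with half the limit of
#' detection (LOD), the standard convention for values reported below the
#' method LOD. Two encodings are accepted and may be mixed: a sentinel string
#' in the congener cell — `"<LOD"` (requiring a companion `<congener>_lod`
#' column) or an inline `"<0.2"` — or a logical flag column
#' `<congener>_cens` paired with `<congener>_lod`. Censored cells are flagged
#' in the `censored` attribute (a logical tibble aligned with the rows).
#' Exact zeros without an LOD are rejected: downstream geometric means and
#' relative errors are undefined at zero, so an LOD must be supplied.
#'
#' @param path Path to a delimited text file with a header row naming the
#'   congeners exactly as in [pah_congeners()].
#' @param schema One of `"concentration"`, `"ef"`, `"activity"`,
#'   `"physchem"`.
#' @return A tibble validated for the schema. Concentration and EF tables
#'   carry a `pah_schema` attribute and, for concentrations, a `censored`
#'   attribute. `foc` is normalised to percent (values supplied as fractions
#'   in (0, 1] are multiplied by 100).
#' @seealso [pah_total()], [aggregate_geomean()]
#' @export
read_pah_table <- function(path,
                           schema = c("concentration", "ef", "activity", "physchem")) {
  schema <- match.arg(schema)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  as_pah_table(raw, schema, where = path)
}

#' Validate an in-memory table against a congener schema
#'
#' The data-frame equivalent of [read_pah_table()]: applies the same schema
#' validation, censor substitution and unit normalisation to a table already
#' in memory.
#'
#' @param data A data frame.
#' @inheritParams read_pah_table
#' @param where Label used in error messages (defaults to `"table"`).
#' @return A validated tibble; see [read_pah_table()].
#' @export
as_pah_table <- function(data,
                         schema = c("concentration", "ef", "activity", "physchem"),
                         where = "table") {
  schema <- match.arg(schema)
  data <- as_tibble(data)
  switch(schema,
    concentration = validate_concentration(data, where),
    ef = validate_ef(data, where),
    activity = validate_activity(data, where),
    physchem = validate_physchem(data, where)
  )
}

parse_congener_cell <- function(x, lod, row, col) {
  # returns list(value, censored); x is a single character cell
  if (is.na(x) || !nzchar(trimws(x))) {
    abort(sprintf("missing value for %s in row %d", col, row))
  }
  x <- trimws(x)
  if (grepl("^<", x)) {
    inline <- sub("^<\\s*", "", x)
    if (toupper(inline) %in% c("LOD", "DL", "MDL", "")) {
      if (is.na(lod)) {
        abort(sprintf(
          "row %d, column %s: cell '%s' needs a %s_lod column with its LOD",
          row, col, x, col
        ))
      }
      return(list(value = lod / 2, censored = TRUE))
    }
    val <- suppressWarnings(as.numeric(inline))
    if (is.na(val)) {
      abort(sprintf("row %d, column %s: unparseable cell '%s'", row, col, x))
    }
    return(list(value = val / 2, censored = TRUE))
  }
  val <- suppressWarnings(as.numeric(x))
  if (is.na(val)) {
    abort(sprintf("row %d, column %s: unparseable cell '%s'", row, col, x))
  }
  list(value = val, censored = FALSE)
}

substitute_censored <- function(data, where) {
  cols <- congener_cols(data, where)
  n <- nrow(data)
  values <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  cens <- matrix(FALSE, n, length(cols), dimnames = list(NULL, cols))
  for (col in cols) {
    cells <- as.character(data[[col]])
    lod_col <- paste0(col, "_lod")
    lods <- if (lod_col %in% names(data)) {
      suppressWarnings(as.numeric(data[[lod_col]]))
    } else {
      rep(NA_real_, n)
    }
    cens_col <- paste0(col, "_cens")
    flags <- if (cens_col %in% names(data)) {
      parse_logical(data[[cens_col]])
    } else {
      rep(FALSE, n)
    }
    for (i in seq_len(n)) {
      if (isTRUE(flags[i])) {
        if (is.na(lods[i])) {
          abort(sprintf(
            "row %d, column %s: censor flag set but no LOD in %s", i, col, lod_col
          ))
        }
        values[i, col] <- lods[i] / 2
        cens[i, col] <- TRUE
      } else {
        parsed <- parse_congener_cell(cells[i], lods[i], i, col)
        values[i, col] <- parsed$value
        cens[i, col] <- parsed$censored
      }
      v <- values[i, col]
      if (v < 0) {
        abort(sprintf("row %d, column %s: negative concentration %g", i, col, v))
      }
      if (v == 0) {
        abort(sprintf(
          "row %d, column %s: exact zero without an LOD; supply the LOD so the half-LOD substitution applies",
          i, col
        ))
      }
    }
  }
  list(values = as_tibble(as.data.frame(values)), censored = as_tibble(as.data.frame(cens)))
}

parse_logical <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("true", "t", "1", "yes", "y")
  out
}

validate_concentration <- function(data, where) {
  sub <- substitute_censored(data, where)
  meta_names <- intersect(c("sample_id", "region", "year", "foc"), names(data))
  meta <- data[meta_names]
  if ("year" %in% names(meta)) meta$year <- as.integer(meta$year)
  if ("foc" %in% names(meta)) {
    foc <- suppressWarnings(as.numeric(meta$foc))
    if (anyNA(foc)) abort(sprintf("%s: unparseable foc values", where))
    # percent internally; values supplied on the 0-1 fraction scale are scaled up
    if (all(foc <= 1, na.rm = TRUE)) foc <- foc * 100
    meta$foc <- foc
  }
  out <- dplyr::bind_cols(meta, sub$values)
  attr(out, "pah_schema") <- "concentration"
  attr(out, "censored") <- sub$censored
  out
}

validate_ef <- function(data, where) {
  cols <- congener_cols(data, where)
  vals <- data[cols]
  vals[] <- lapply(vals, function(x) suppressWarnings(as.numeric(as.character(x))))
  bad <- which(is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "%s: unparseable EF cell in row %d, column %s",
      where, bad[1, 1], cols[bad[1, 2]]
    ))
  }
  neg <- which(as.matrix(vals) < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf(
      "%s: negative EF in row %d, column %s",
      where, neg[1, 1], cols[neg[1, 2]]
    ))
  }
  if (nrow(vals) < 2) abort(sprintf("%s: an EF table needs at least 2 divisions", where))
  meta_names <- intersect(c("division_id", "source", "technology"), names(data))
  meta <- data[meta_names]
  if (!"division_id" %in% names(meta)) {
    meta$division_id <- if (all(c("source", "technology") %in% names(meta))) {
      paste(meta$source, meta$technology, sep = ":")
    } else if ("source" %in% names(meta)) {
      meta$source
    } else {
      paste0("division_", seq_len(nrow(vals)))
    }
  }
  out <- dplyr::bind_cols(meta[union("division_id", meta_names)], vals)
  attr(out, "pah_schema") <- "ef"
  out
}

validate_activity <- function(data, where) {
  need <- c("region", "year", "source", "activity")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column%s: %s", where,
                  if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")))
  }
  out <- tibble(
    region = as.character(data$region),
    year = as.integer(data$year),
    source = as.character(data$source),
    activity = suppressWarnings(as.numeric(data$activity))
  )
  if (anyNA(out$activity)) abort(sprintf("%s: unparseable activity values", where))
  if (any(out$activity < 0)) abort(sprintf("%s: negative activity", where))
  attr(out, "pah_schema") <- "activity"
  out
}

validate_physchem <- function(data, where) {
  need <- c("congener", "logkow")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column%s: %s", where,
                  if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")))
  }
  out <- tibble(
    congener = as.character(data$congener),
    logkow = suppressWarnings(as.numeric(data$logkow))
  )
  for (opt in c("sw", "half_life")) {
    if (opt %in% names(data)) out[[opt]] <- suppressWarnings(as.numeric(data[[opt]]))
  }
  missing_cong <- setdiff(PAH_NAMES, out$congener)
  if (length(missing_cong) > 0) {
    abort(sprintf("%s is missing congener row%s: %s", where,
                  if (length(missing_cong) > 1) "s" else "",
                  paste(missing_cong, collapse = ", ")))
  }
  if (any(!is.finite(out$logkow)) || any(out$logkow <= 0)) {
    abort(sprintf("%s: logkow must be finite and positive", where))
  }
  out <- out[match(PAH_NAMES, out$congener), , drop = FALSE]
  attr(out, "pah_schema") <- "physchem"
  out
}

#' Per-row total over the 16 congeners
#'
#' Appends a `total` column holding the row sum over the full congener panel:
#' the total PAH concentration of a sediment sample (micrograms per kilogram)
#' or the total emission factor of a source division (grams per tonne).
#'
#' @param data A concentration or EF tibble covering the full panel.
#' @param name Name of the appended column (default `"total"`).
#' @return `data` with the total column appended (recomputed if it already
#'   exists).
#' @examples
#' tbl <- tibble::as_tibble(setNames(as.list(rep(1, 16)), pah_congeners()))
#' pah_total(tbl)$total  # 16
#' @export
pah_total <- function(data, name = "total") {
  cols <- congener_cols(data)
  data[[name]] <- rowSums(as.matrix(data[cols]))
  data
}

#' Geometric-mean aggregation of congener tables
#'
#' Collapses sample-level rows to one row per group (by default per
#' region-year), replacing each congener column by the geometric mean
#' `exp(mean(log(x)))` of its within-group values. This is the conventional
#' summary for environmental concentration data, whose within-region spread
#' is closer to lognormal than normal. All aggregated values must be strictly
#' positive, which the half-LOD censor substitution guarantees.
#'
#' @param data A concentration tibble.
#' @param ... Grouping columns (tidyselect), default `region, year`.
#' @return One row per group; congener columns hold geometric means. A
#'   `total` column, if present, is recomputed as the sum of the aggregated
#'   congeners.
#' @export
aggregate_geomean <- function(data, ...) {
  keys <- rlang::enquos(...)
  if (length(keys) == 0) keys <- rlang::quos(.data$region, .data$year)
  cols <- congener_cols(data)
  num_cols <- c(cols, intersect("foc", names(data)))
  vals <- as.matrix(data[cols])
  if (any(vals <= 0)) {
    abort("geometric-mean aggregation needs strictly positive values; apply the half-LOD substitution first")
  }
  had_total <- "total" %in% names(data)
  out <- data |>
    dplyr::group_by(!!!keys) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      dplyr::across(dplyr::all_of(num_cols), ~ exp(mean(log(.x)))),
      .groups = "drop"
    )
  if (had_total) out <- pah_total(out)
  out
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample K-S test of a variable against a normal distribution with the
#' sample mean and standard deviation plugged in (the classic SPSS-style
#' screen). The variable is judged normal when p > 0.05. Optionally applied
#' on the log scale, which is usually the better question to ask of
#' concentration data.
#'
#' @param values Numeric vector, at least 3 finite values with nonzero spread.
#' @param log Test `log(values)` instead of the raw values (default `FALSE`).
#' @return A one-row tibble with `statistic`, `p_value`, and `normal`
#'   (`TRUE` iff p > 0.05).
#' @export
normality_check <- function(values, log = FALSE) {
  x <- values[is.finite(values)]
  if (log) {
    if (any(x <= 0)) abort("log-scale normality check needs positive values")
    x <- base::log(x)
  }
  if (length(x) < 3) abort("normality check needs at least 3 finite values")
  if (sd(x) == 0) abort("normality check is undefined for a constant vector")
  ks <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  tibble(
    statistic = unname(ks$statistic),
    p_value = ks$p.value,
    normal = ks$p.value > 0.05
  )
}

#' Write a congener table to CSV
#'
#' Plain `readr::write_csv()` with full precision, provided so pipeline
#' outputs round-trip exactly through [read_pah_table()].
#'
#' @param data Tibble to write.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_pah_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}
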