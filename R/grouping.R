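#' Correlation-based distance between congener profiles
#'
#' Computes the congener-by-congener dissimilarity matrix
#' `d(i, j) = 1 - r(i, j)`, where r is the Pearson correlation of the two
#' congeners' values across the rows of the table (sediment samples or
#' emission-source divisions). Correlation distance is the standard
#' interval-similarity choice for clustering variables by profile shape; it
#' is invariant to rescaling any congener column, so results do not depend on
#' per-congener units or magnitudes.
#'
#' @param data A concentration or EF tibble covering the full panel, at least
#'   3 rows.
#' @param log Correlate log-transformed values instead of raw values
#'   (default `FALSE`).
#' @return A symmetric 16 x 16 matrix with zero diagonal, entries in
#'   \eqn{[0, 2]}.
#' @export
profile_distance <- function(data, log = FALSE) {
  cols <- congener_cols(data)
  if (nrow(data) < 3) abort("profile distance needs at least 3 rows")
  m <- as.matrix(data[cols])
  if (log) {
    if (any(m <= 0)) abort("log-scale distances need positive values")
    m <- base::log(m)
  }
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf(
      "constant congener column%s: %s (correlation undefined)",
      if (sum(sds == 0) > 1) "s" else "", paste(cols[sds == 0], collapse = ", ")
    ))
  }
  d <- 1 - cor(m)
  # clip tiny numerical overshoot outside [0, 2]
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  d
}

#' Hierarchical clustering of congeners
#'
#' Agglomerative clustering of the 16 congeners with average linkage (UPGMA)
#' on a profile-distance matrix, cut into `g` subgroups. Subgroup indices are
#' relabelled to be contiguous from 1 in panel order of first appearance, and
#' cuts of the same tree at successive `g` are nested partitions.
#'
#' @param distance A distance matrix from [profile_distance()] (or any
#'   symmetric dissimilarity over the panel). A concentration/EF tibble is
#'   also accepted and converted via [profile_distance()].
#' @param g Number of subgroups, between 2 and 16.
#' @return A `pah_grouping` object: list with `assignments` (tibble
#'   `congener`, `subgroup`), `g`, and `hclust` (the merge tree).
#'   Supports [tidy()] and [autoplot()].
#' @examples
#' sim <- simulate_study(sim_config(seed = 1))
#' grp <- cluster_congeners(profile_distance(sim$sediments), g = 4)
#' tidy(grp)
#' @export
cluster_congeners <- function(distance, g) {
  if (is.data.frame(distance)) distance <- profile_distance(distance)
  if (!is.matrix(distance) || nrow(distance) != ncol(distance)) {
    abort("`distance` must be a square matrix or a congener table")
  }
  if (!is.numeric(g) || length(g) != 1 || g < 2 || g > nrow(distance)) {
    abort(sprintf("`g` must be between 2 and %d", nrow(distance)))
  }
  g <- as.integer(g)
  hc <- hclust(as.dist(distance), method = "average")
  raw <- cutree(hc, k = g)
  # relabel so subgroup 1 is the one containing the first panel congener, etc.
  ord <- unique(raw[hc$labels][match(intersect(PAH_NAMES, hc$labels), hc$labels)])
  relabel <- setNames(seq_along(ord), ord)
  assignments <- tibble(
    congener = hc$labels,
    subgroup = as.integer(relabel[as.character(raw)])
  )
  assignments <- assignments[match(intersect(PAH_NAMES, assignments$congener),
                                   assignments$congener), ]
  structure(
    list(assignments = assignments, g = g, hclust = hc),
    class = "pah_grouping"
  )
}

#' @export
print.pah_grouping <- function(x, ...) {
  cat(sprintf("<pah_grouping> %d congeners in %d subgroups (average linkage)\n",
              nrow(x$assignments), x$g))
  groups <- split(x$assignments$congener, x$assignments$subgroup)
  for (i in names(groups)) {
    cat(sprintf("  %s: %s\n", i, paste(groups[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' @rdname cluster_congeners
#' @param x A `pah_grouping`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pah_grouping <- function(x, ...) x$assignments

#' Select the representative congener of each subgroup
#'
#' Within each subgroup, every member is regressed (simple OLS) on the
#' subgroup total concentration (or total EF); the subgroup total includes
#' the member itself, so a singleton subgroup has R2 = 1 by construction.
#' The member with the maximum R2 is the subgroup's representative
#' ("characteristic") congener — the single analyte that best tracks the
#' subgroup's collective burden. Ties are broken by panel order.
#'
#' @param data The concentration or EF tibble the grouping was built from.
#' @param grouping A `pah_grouping` from [cluster_congeners()].
#' @return A `pah_selection` object: tibble with one row per congener and
#'   columns `congener`, `subgroup`, `subgroup_size`, `r_squared`,
#'   `representative` (logical).
#' @export
select_representatives <- function(data, grouping) {
  stopifnot(inherits(grouping, "pah_grouping"))
  cols <- congener_cols(data)
  if (!setequal(grouping$assignments$congener, cols)) {
    abort("grouping and table cover different congener panels")
  }
  m <- as.matrix(data[cols])
  out <- grouping$assignments |>
    dplyr::group_by(.data$subgroup) |>
    dplyr::group_modify(function(df, key) {
      members <- df$congener
      total <- rowSums(m[, members, drop = FALSE])
      r2 <- vapply(members, function(cg) {
        if (length(members) == 1) return(1)
        suppressWarnings(cor(m[, cg], total))^2
      }, numeric(1))
      df$subgroup_size <- length(members)
      df$r_squared <- unname(r2)
      df$representative <- seq_along(members) == which.max(r2)
      df
    }) |>
    dplyr::ungroup()
  out <- out[match(intersect(PAH_NAMES, out$congener), out$congener),
             c("congener", "subgroup", "subgroup_size", "r_squared", "representative")]
  class(out) <- c("pah_selection", class(out))
  out
}

#' Characteristic congener set
#'
#' Composition of [cluster_congeners()] and [select_representatives()]:
#' clusters the congener profiles into `g` subgroups and returns the
#' max-R2 representative of each, in panel order. On emission-factor and
#' sediment tables with the structure of real source profiles, `g = 4`
#' yields the canonical set Nap, Acy, Phe, BaA.
#'
#' @inheritParams profile_distance
#' @param g Number of subgroups.
#' @return Character vector of `g` representative congeners, panel-ordered.
#' @examples
#' sim <- simulate_study(sim_config(seed = 1))
#' characteristic_set(sim$sediments, g = 4)
#' @export
characteristic_set <- function(data, g, log = FALSE) {
  grouping <- cluster_congeners(profile_distance(data, log = log), g)
  sel <- select_representatives(data, grouping)
  reps <- sel$congener[sel$representative]
  intersect(PAH_NAMES, reps)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pah_grouping <- function(object, ...) {
  hc <- object$hclust
  dend <- tibble(
    congener = hc$labels[hc$order],
    position = seq_along(hc$order)
  ) |>
    dplyr::left_join(object$assignments, by = "congener")
  ggplot2::ggplot(dend, ggplot2::aes(x = .data$position, y = 0,
                                     label = .data$congener,
                                     colour = factor(.data$subgroup))) +
    ggplot2::geom_text(angle = 90, hjust = 0) +
    ggplot2::scale_colour_discrete(name = "subgroup") +
    ggplot2::labs(
      title = sprintf("Average-linkage congener grouping (g = %d)", object$g),
      x = "dendrogram order", y = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
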