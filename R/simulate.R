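# Per-congener proportionality constants used by the generator: each congener
# tracks its subgroup representative (proportion 1) with a fixed share chosen
# to echo typical source-profile and sediment-profile shapes (mid-ring
# congeners Flu/Pyr/Chr abundant, DahA a trace constituent).
SAT_PROPS <- c(
  Nap = 1, Acy = 1, Ace = 0.25, Flo = 0.45, Phe = 1, Ant = 0.20,
  Flu = 0.75, Pyr = 0.65, BaA = 1, Chr = 0.85, BbF = 0.70, BkF = 0.45,
  BaP = 0.60, IcdP = 0.35, BghiP = 0.40, DahA = 0.12
)

# Default four-subgroup structure: Nap alone (dominant volatile), Acy alone,
# a Phe-led mid-ring group, and a BaA-led heavy group.
DEFAULT_BLOCKS <- c(
  Nap = 1L, Acy = 2L, Ace = 3L, Flo = 3L, Phe = 3L, Ant = 3L,
  Flu = 3L, Pyr = 3L, BaA = 4L, Chr = 4L, BbF = 4L, BkF = 4L,
  BaP = 4L, IcdP = 4L, BghiP = 4L, DahA = 4L
)

CONC_FLOOR <- 1e-3 # ug/kg floor keeping geometric means defined

#' Configuration of the synthetic study generator
#'
#' Bundles every knob of the synthetic-data module. The defaults define the
#' study conditions used throughout the package's tests: 754 sediment
#' samples over 30 regions, 15 emission-source divisions (six sources split
#' into conventional/improved technology divisions plus three fixed
#' single-division sources), the four-subgroup congener structure with
#' representatives Nap, Acy, Phe and BaA, published transfer constants, and
#' per-cell lognormal noise with sigma 0.7 — the level at which the
#' four-congener surrogate fit on a generated table of 754 samples realises
#' an SDEV in the 30-40 percent range, the regime of real compiled sediment
#' data. All randomness flows from `seed` (R's default Mersenne-Twister).
#'
#' @param seed Integer seed; identical configs give bit-identical outputs.
#' @param n_samples Total sediment samples, spread evenly over the grid.
#' @param n_divisions Number of EF divisions (>= 3).
#' @param regions Character vector of region labels.
#' @param years Integer vector of years.
#' @param blocks Named integer vector mapping each of the 16 congeners to a
#'   latent subgroup.
#' @param ef_meanlog Per-subgroup log-scale EF magnitude (g/t) locations;
#'   subgroup 1 (Nap) largest, subgroup 2 (Acy) second.
#' @param ef_sdlog Log-sd of the per-division subgroup latent factor.
#' @param ef_noise Log-sd of per-congener EF scatter around its loading.
#' @param transfer [transfer_params()] used by the forward model.
#' @param sigma Per-cell multiplicative lognormal noise (log-sd) on sediment
#'   concentrations.
#' @param profile_sdlog Log-sd of the per-region lognormal wobble on each
#'   satellite congener's proportionality: regional source mixes differ, so
#'   the congener profile around the representatives varies from region to
#'   region.
#' @param lod Limit of detection, ug/kg; generated cells below it are
#'   censored to lod/2 (0 disables censoring).
#' @param background Regional background concentration floor, ug/kg, applied
#'   to each representative's transfer-line expectation: the linear transfer
#'   form with its negative intercept for hydrophobic congeners cannot hold
#'   at very low emissions, where ubiquitous background deposition keeps
#'   sediment concentrations positive.
#' @param region_sdlog Log-sd of the shared regional activity scale.
#' @param source_sdlog Log-sd of per-source activity scatter within a region.
#' @param activity_base Median source activity, units of 1e4 t per year.
#' @return A `pah_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 754L,
                       n_divisions = 15L,
                       regions = sprintf("R%02d", 1:30),
                       years = c(2005L, 2010L, 2015L),
                       blocks = DEFAULT_BLOCKS,
                       ef_meanlog = log(c(3, 0.8, 0.5, 0.12)),
                       ef_sdlog = 1.0,
                       ef_noise = 0.2,
                       transfer = transfer_params(),
                       sigma = 0.7,
                       profile_sdlog = 0.1,
                       lod = 0.5,
                       background = 2,
                       region_sdlog = 0.3,
                       source_sdlog = 1.0,
                       activity_base = 5000) {
  if (n_divisions < 3) abort("n_divisions must be at least 3")
  if (sigma < 0) abort("noise sigma must be nonnegative")
  if (!setequal(names(blocks), PAH_NAMES)) {
    abort("blocks must name all 16 panel congeners")
  }
  blocks <- blocks[PAH_NAMES]
  n_groups <- max(blocks)
  if (length(ef_meanlog) != n_groups) {
    abort(sprintf("ef_meanlog must have one entry per subgroup (%d)", n_groups))
  }
  structure(
    list(
      seed = as.integer(seed), n_samples = as.integer(n_samples),
      n_divisions = as.integer(n_divisions), regions = regions,
      years = as.integer(years), blocks = blocks, ef_meanlog = ef_meanlog,
      ef_sdlog = ef_sdlog, ef_noise = ef_noise, transfer = transfer,
      sigma = sigma, profile_sdlog = profile_sdlog,
      lod = lod, background = background,
      region_sdlog = region_sdlog,
      source_sdlog = source_sdlog, activity_base = activity_base
    ),
    class = "pah_sim_config"
  )
}

# run `expr` under a derived seed without disturbing the caller's RNG state
with_sim_seed <- function(config, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((config$seed + offset) %% .Machine$integer.max)
  force(expr)
}

# source/technology layout: up to six paired sources, remainder single
division_layout <- function(n_divisions) {
  n_two <- min(6L, n_divisions %/% 2L)
  n_single <- n_divisions - 2L * n_two
  layout <- dplyr::bind_rows(
    tidyr::crossing(idx = seq_len(n_two),
                    technology = c("conventional", "improved")) |>
      dplyr::mutate(source = sprintf("split_source_%d", .data$idx)) |>
      dplyr::select("source", "technology"),
    tibble(source = sprintf("fixed_source_%d", seq_len(n_single)),
           technology = "fixed")
  )
  layout$division_id <- paste(layout$source, layout$technology, sep = ":")
  layout
}

# representative of each subgroup = member with the largest proportionality,
# panel order breaking ties
block_representatives <- function(blocks) {
  vapply(split(names(blocks), blocks), function(members) {
    members <- intersect(PAH_NAMES, members)
    members[which.max(SAT_PROPS[members])]
  }, character(1))
}

#' Simulate an emission-factor table
#'
#' Draws a divisions-by-congeners EF table (g/t) with the latent subgroup
#' structure the grouping stage assumes: each division gets one lognormal
#' latent factor per subgroup, and each congener's EF is its fixed
#' proportionality times the subgroup factor times lognormal scatter, so
#' within-subgroup correlations exceed between-subgroup correlations.
#' Improved-technology divisions carry a 0.4 abatement multiplier. Subgroup
#' magnitudes make Nap the dominant congener and Acy the runner-up.
#'
#' @param config A [sim_config()].
#' @return An EF tibble (`division_id`, `source`, `technology`, 16 congener
#'   columns) with the generating subgroup labels attached as attribute
#'   `"truth"` (see [ground_truth()]).
#' @export
simulate_ef_table <- function(config) {
  stopifnot(inherits(config, "pah_sim_config"))
  layout <- division_layout(config$n_divisions)
  blocks <- config$blocks
  n_groups <- max(blocks)
  with_sim_seed(config, 0L, {
    factors <- matrix(
      rlnorm(nrow(layout) * n_groups,
             meanlog = rep(config$ef_meanlog, each = nrow(layout)),
             sdlog = config$ef_sdlog),
      nrow = nrow(layout), ncol = n_groups
    )
    abate <- ifelse(layout$technology == "improved", 0.4, 1)
    reps <- block_representatives(blocks)
    ef <- sapply(PAH_NAMES, function(cg) {
      g <- blocks[[cg]]
      if (cg == reps[[as.character(g)]]) {
        factors[, g] * abate
      } else {
        SAT_PROPS[[cg]] * factors[, g] * abate *
          rlnorm(nrow(layout), 0, config$ef_noise)
      }
    })
    out <- dplyr::bind_cols(
      layout[c("division_id", "source", "technology")],
      as_tibble(as.data.frame(ef))
    )
    attr(out, "pah_schema") <- "ef"
    attr(out, "truth") <- ground_truth(config)
    out
  })
}

#' Default technology-transition parameters of the simulated sources
#'
#' Conventional divisions phase out (X0 = 0.9 toward Xf = 0.2) and improved
#' divisions phase in (0.1 toward 0.8) from 1995 with a 8-year rate; fixed
#' single-division sources carry no transition row (their fraction is 1).
#'
#' @param config A [sim_config()].
#' @return A transitions tibble for [technology_fraction()].
#' @export
simulate_transitions <- function(config) {
  layout <- division_layout(config$n_divisions)
  split_sources <- unique(layout$source[layout$technology != "fixed"])
  dplyr::bind_rows(
    tibble(source = split_sources, technology = "conventional",
           x0 = 0.9, xf = 0.2, t0 = 1995, s = 8),
    tibble(source = split_sources, technology = "improved",
           x0 = 0.1, xf = 0.8, t0 = 1995, s = 8)
  )
}

#' Simulate regional activity data
#'
#' Per region-year-source activity (1e4 t per year): a shared lognormal
#' regional scale (industrialisation level, log-sd `region_sdlog`) times
#' per-source lognormal scatter around the source's base activity.
#'
#' @param config A [sim_config()].
#' @return An activity tibble (`region`, `year`, `source`, `activity`).
#' @export
simulate_activities <- function(config) {
  stopifnot(inherits(config, "pah_sim_config"))
  layout <- division_layout(config$n_divisions)
  sources <- unique(layout$source)
  with_sim_seed(config, 1L, {
    base <- config$activity_base * rlnorm(length(sources), 0, 0.5)
    grid <- tidyr::crossing(region = config$regions, year = config$years)
    region_scale <- setNames(rlnorm(length(config$regions), 0, config$region_sdlog),
                             config$regions)
    out <- tidyr::crossing(grid, source = sources) |>
      dplyr::arrange(.data$region, .data$year, .data$source)
    out$activity <- base[match(out$source, sources)] *
      region_scale[out$region] *
      rlnorm(nrow(out), 0, config$source_sdlog)
    attr(out, "pah_schema") <- "activity"
    out
  })
}

#' Simulate a sediment concentration table from emissions
#'
#' The generator's forward model, the same one the analysis assumes: for each
#' region-year, each subgroup representative's expected concentration is the
#' transfer line `max(floor, K(logKow) * E + L(logKow))` evaluated at the
#' representative's regional emission; each sample draws the representative
#' with multiplicative lognormal noise (log-sd `sigma`), and every other
#' congener is its fixed proportion of the sampled representative times its
#' own lognormal noise. Cells below the LOD are substituted by LOD/2 and
#' flagged in the `censored` attribute. A weakly informative organic-carbon
#' column `foc` (percent) is included so baseline f_oc regressions can be
#' run.
#'
#' @param config A [sim_config()].
#' @param emissions Wide emission tibble (`region`, `year`, congener columns
#'   in t/a), e.g. from [total_emission()]; must cover the config grid.
#' @return A concentration tibble (`sample_id`, `region`, `year`, `foc`, 16
#'   congener columns, ug/kg) with attributes `censored` (logical tibble) and
#'   `truth`.
#' @export
simulate_sediments <- function(config, emissions) {
  stopifnot(inherits(config, "pah_sim_config"))
  grid <- tidyr::crossing(region = config$regions, year = config$years)
  em <- dplyr::inner_join(grid, as_tibble(emissions), by = c("region", "year"))
  if (nrow(em) < nrow(grid)) abort("emissions do not cover the region-year grid")
  blocks <- config$blocks
  reps <- block_representatives(blocks)
  kow <- PAH_LOGKOW
  # expected regional concentration of each representative via the transfer line
  base <- sapply(reps, function(cg) {
    pmax(config$background,
         k_coefficient(kow[[cg]], config$transfer) * em[[cg]] +
           l_coefficient(kow[[cg]], config$transfer))
  })
  base <- matrix(base, nrow = nrow(em), dimnames = list(NULL, reps))
  # spread n_samples over the grid as evenly as possible
  counts <- diff(floor(seq(0, config$n_samples, length.out = nrow(em) + 1)))
  with_sim_seed(config, 2L, {
    rows <- purrr::map_dfr(seq_len(nrow(em)), function(r) {
      n <- counts[r]
      if (n == 0) return(NULL)
      # regional congener profile: satellite proportions wobble by region
      region_prop <- SAT_PROPS * rlnorm(length(SAT_PROPS), 0, config$profile_sdlog)
      names(region_prop) <- names(SAT_PROPS)
      rep_draw <- sapply(reps, function(cg) {
        pmax(CONC_FLOOR, base[r, cg] * rlnorm(n, 0, config$sigma))
      })
      rep_draw <- matrix(rep_draw, nrow = n, dimnames = list(NULL, reps))
      vals <- sapply(PAH_NAMES, function(cg) {
        g <- as.character(blocks[[cg]])
        rep_cg <- reps[[g]]
        if (cg == rep_cg) return(rep_draw[, rep_cg])
        pmax(CONC_FLOOR,
             region_prop[[cg]] * rep_draw[, rep_cg] * rlnorm(n, 0, config$sigma))
      })
      vals <- matrix(vals, nrow = n, dimnames = list(NULL, PAH_NAMES))
      regional_total <- sum(base[r, ] * (1 + config$sigma))
      foc <- 2 * (regional_total / 500)^0.15 * rlnorm(n, 0, 0.6)
      dplyr::bind_cols(
        tibble(region = em$region[r], year = em$year[r], foc = foc),
        as_tibble(as.data.frame(vals))
      )
    })
    rows$sample_id <- sprintf("S%04d", seq_len(nrow(rows)))
    rows <- rows[c("sample_id", "region", "year", "foc", PAH_NAMES)]
    cens <- as_tibble(as.data.frame(
      sapply(PAH_NAMES, function(cg) config$lod > 0 & rows[[cg]] < config$lod)
    ))
    if (config$lod > 0) {
      for (cg in PAH_NAMES) rows[[cg]][cens[[cg]]] <- config$lod / 2
    }
    attr(rows, "pah_schema") <- "concentration"
    attr(rows, "censored") <- cens
    attr(rows, "truth") <- ground_truth(config)
    rows
  })
}

#' Generating latent state of a configuration
#'
#' Pure readback of what the generator plants: the congener-to-subgroup
#' labels with their fixed proportionalities, the subgroup representatives,
#' the noise-free combination coefficients relating the total concentration
#' to the representatives (intercept 0; coefficient of each representative =
#' 1 + sum of its satellites' proportions), and the transfer parameters.
#'
#' @param config A [sim_config()].
#' @return A list: `blocks` (tibble congener, subgroup, proportion,
#'   representative), `representatives` (character), `coefficients`
#'   (term/estimate tibble usable as `sediment_fit` in [predict_total()]),
#'   `transfer`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "pah_sim_config"))
  blocks <- config$blocks
  reps <- block_representatives(blocks)
  blk <- tibble(
    congener = PAH_NAMES,
    subgroup = unname(blocks[PAH_NAMES]),
    proportion = unname(SAT_PROPS[PAH_NAMES]),
    representative = PAH_NAMES %in% reps
  )
  coefs <- vapply(seq_along(reps), function(g) {
    members <- names(blocks)[blocks == as.integer(names(reps)[g])]
    sum(SAT_PROPS[members]) / SAT_PROPS[[reps[[g]]]]
  }, numeric(1))
  list(
    blocks = blk,
    representatives = unname(reps[order(match(reps, PAH_NAMES))]),
    coefficients = tibble(
      term = c("(Intercept)", unname(reps)),
      estimate = c(0, coefs)
    ),
    transfer = config$transfer
  )
}

#' Simulate a full synthetic study
#'
#' One call producing every table of the end-to-end pipeline under a single
#' seed: EF table, technology transitions, activities, the emission
#' inventory derived from them, the sediment concentration table generated
#' by the transfer forward model, and the observed region-year geometric-mean
#' totals.
#'
#' @param config A [sim_config()].
#' @return A list `ef`, `transitions`, `activities`, `emissions`,
#'   `sediments`, `observed`, `truth`, `config`.
#' @examples
#' study <- simulate_study(sim_config(seed = 7, n_samples = 60))
#' names(study)
#' @export
simulate_study <- function(config = sim_config()) {
  ef <- simulate_ef_table(config)
  transitions <- simulate_transitions(config)
  activities <- simulate_activities(config)
  emissions <- total_emission(ef, transitions, activities)
  sediments <- simulate_sediments(config, emissions)
  observed <- sediments |>
    pah_total() |>
    aggregate_geomean(.data$region, .data$year) |>
    dplyr::select("region", "year", "n_samples", "total")
  list(
    ef = ef, transitions = transitions, activities = activities,
    emissions = emissions, sediments = sediments, observed = observed,
    truth = attr(sediments, "truth"), config = config
  )
}

#' Simulate responses from a known linear model
#'
#' Draws lognormal predictors and a response equal to the linear predictor
#' times mean-one multiplicative lognormal noise — the structure the
#' surrogate concentration models assume. Used for parameter-recovery
#' checks.
#'
#' @param coefs Term/estimate tibble (as from [published_model()]).
#' @param n Number of rows.
#' @param sigma Log-sd of the multiplicative noise (mean-one lognormal);
#'   0.30 lands the fitted SDEV near 35 percent.
#' @param meanlog,sdlog Parameters of the lognormal predictors. The default
#'   spread (`sdlog = 0.3`) keeps leverage moderate, so classical OLS
#'   standard errors remain approximately valid despite the multiplicative
#'   (heteroscedastic) noise.
#' @param seed Optional seed (applied via the non-disturbing local RNG).
#' @return A tibble with one column per predictor plus `response`.
#' @export
simulate_linear_response <- function(coefs, n, sigma = 0.30,
                                     meanlog = log(50), sdlog = 0.3,
                                     seed = NULL) {
  coefs <- coef_table(coefs)
  terms <- setdiff(coefs$term, "(Intercept)")
  draw <- function() {
    x <- as_tibble(as.data.frame(
      matrix(rlnorm(n * length(terms), meanlog, sdlog), nrow = n,
             dimnames = list(NULL, terms))
    ))
    mu <- linear_predict(coefs, x)
    x$response <- mu * exp(rnorm(n, 0, sigma) - sigma^2 / 2)
    x
  }
  if (is.null(seed)) draw() else {
    with_sim_seed(list(seed = as.integer(seed)), 0L, draw())
  }
}
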