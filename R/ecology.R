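#' Larval density per area and per host plant
#'
#' Converts an abundance estimate into densities: individuals of the
#' focal species per 100 m2 of patch area and, when the host-plant count
#' is known, per 100 host plants. `species_fraction` apportions the
#' estimate to the focal species when shelters of a congener are mixed
#' in.
#'
#' @param n_hat Abundance estimate(s).
#' @param area Plot area in square metres, > 0.
#' @param species_fraction Proportion attributed to the focal species,
#'   in \code{[0, 1]} (default 1).
#' @param host_plants Optional host-plant count, > 0.
#' @return A tibble: `larvae_per_100m2` and (if `host_plants` given)
#'   `larvae_per_100_hostplants`.
#' @export
larval_density <- function(n_hat, area, species_fraction = 1,
                           host_plants = NULL) {
  if (any(area <= 0)) stop("area must be strictly positive", call. = FALSE)
  stopifnot(all(species_fraction >= 0 & species_fraction <= 1))
  out <- tibble::tibble(
    larvae_per_100m2 = n_hat * species_fraction / area * 100
  )
  if (!is.null(host_plants)) {
    if (any(host_plants <= 0)) {
      stop("host_plants must be positive", call. = FALSE)
    }
    out$larvae_per_100_hostplants <-
      n_hat * species_fraction / host_plants * 100
  }
  out
}

# focal-species share among identified individuals of one plot; empty
# shelters (species unknown) are apportioned by the same share
species_fraction_of <- function(ds, plot) {
  ind <- dplyr::filter(ds$individuals, .data$plot_id == plot)
  n_red <- sum(ind$species == "reducta")
  n_cam <- sum(ind$species == "camilla")
  if (n_red + n_cam == 0) return(1)
  n_red / (n_red + n_cam)
}

#' Per-plot density summary
#'
#' Applies [larval_density()] to each plot of a dataset using the plot
#' areas and host-plant counts on record and the plot's focal-species
#' fraction (share of the focal species among individuals identified to
#' species; unidentified — typically empty — shelters are apportioned by
#' that same share).
#'
#' @param ds A `detection_data` object with plot areas.
#' @param abundances Tibble `plot_id, n_hat`, e.g. from [abundance()].
#' @return A tibble: `plot_id`, `n_hat`, `species_fraction`,
#'   `larvae_per_100m2`, `larvae_per_100_hostplants`.
#' @export
density_summary <- function(ds, abundances) {
  abundances <- tibble::as_tibble(abundances)
  out <- abundances |>
    dplyr::select("plot_id", "n_hat") |>
    dplyr::left_join(ds$plots, by = "plot_id") |>
    dplyr::mutate(
      species_fraction = purrr::map_dbl(
        .data$plot_id, \(p) species_fraction_of(ds, p)
      )
    )
  dens <- larval_density(
    out$n_hat, out$area, out$species_fraction,
    host_plants = if (all(is.na(out$host_plants))) NULL else
      out$host_plants
  )
  dplyr::bind_cols(
    dplyr::select(out, "plot_id", "n_hat", "species_fraction"), dens
  )
}

#' Expected adult recruitment from larval abundance
#'
#' Multiplies overwintering-larva abundance by survival to adulthood.
#' High overwinter and post-winter mortality mean a plot of a few dozen
#' larvae typically yields only a handful of adults.
#'
#' @param n_hat Larval abundance estimate(s).
#' @param survival Survival proportion to the adult stage, in \code{[0, 1]}.
#' @return Expected number of adults.
#' @export
recruitment <- function(n_hat, survival) {
  stopifnot(all(survival >= 0 & survival <= 1))
  n_hat * survival
}
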