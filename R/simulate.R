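#' Default surveyor roster for the simulated study design
#'
#' Six experts and seven novices with fixed per-surveyor detection
#' probabilities (best expert 0.51; occasion-weighted group means
#' exactly 0.35 for experts and 0.16 for novices, the rates a pooled
#' experience-covariate fit estimates) and a plot coverage in which
#' seven surveyors search all three plots,
#' two search two, and four search one, giving 10/9/10 occasions on plots
#' A/B/C. Five experts cover every plot and the sixth skips plot B, so
#' the 2..6-expert subset scan has C(6,k) subsets on A and C and C(5,k)
#' on B.
#'
#' @return A tibble with `surveyor_id`, `experience`, `p_detect`, and a
#'   list-column `plots` of plot ids searched.
#' @export
default_roster <- function() {
  tibble::tibble(
    surveyor_id = c(paste0("E", 1:6), paste0("V", 1:7)),
    experience = rep(c("expert", "novice"), c(6, 7)),
    p_detect = c(
      0.51, 0.40, 0.35, 0.32, 0.25, 0.23,
      0.22, 0.18, 0.15, 0.13, 0.12, 0.10, 0.07
    ),
    plots = list(
      c("A", "B", "C"), c("A", "B", "C"), c("A", "B", "C"),
      c("A", "B", "C"), c("A", "B", "C"), c("A", "C"),
      c("A", "B", "C"), c("A", "B", "C"), c("A", "B"),
      c("A"), c("B"), c("C"), c("C")
    )
  )
}

default_sim_plots <- function() {
  tibble::tibble(
    plot_id = c("A", "B", "C"),
    true_n = c(32L, 18L, 28L),
    area = c(916, 807, 2952),
    host_plants = c(137L, 121L, 118L)
  )
}

# interleaved expert/novice search order within one plot
default_order <- function(roster, plot) {
  here <- roster[purrr::map_lgl(roster$plots, \(p) plot %in% p), ]
  ex <- here$surveyor_id[here$experience == "expert"]
  nv <- here$surveyor_id[here$experience == "novice"]
  n <- nrow(here)
  out <- character(n)
  ia <- ib <- 1L
  for (k in seq_len(n)) {
    take_ex <- (k %% 2L == 1L && ia <= length(ex)) || ib > length(nv)
    if (take_ex) {
      out[k] <- ex[ia]
      ia <- ia + 1L
    } else {
      out[k] <- nv[ib]
      ib <- ib + 1L
    }
  }
  out
}

#' Simulation configuration
#'
#' Defines the study conditions for [simulate_population()]. Defaults
#' reproduce the field design the package targets: three plots of a
#' honeysuckle clear-cut with true abundances 32/18/28, searched once
#' each by the [default_roster()] surveyors, detections independent
#' Bernoulli with surveyor-specific probabilities, roughly 45% of
#' shelters empty by the end of winter, a 95% share of the focal species
#' among occupied ones, and a 4% chance a shelter disappears mid-study.
#'
#' @param plots Tibble with `plot_id`, `true_n`, and optionally `area`,
#'   `host_plants`.
#' @param roster Tibble like [default_roster()]: `surveyor_id`,
#'   `experience`, `p_detect`, list-column `plots`.
#' @param orders Named list of surveyor-id vectors giving each plot's
#'   search order; default interleaves experts and novices.
#' @param heterogeneity Dispersion of an individual detectability
#'   multiplier; 0 (default) means equal detectability. For s > 0 each
#'   individual gets h_i = 2*Beta(1/s, 1/s), mean 1, and detection
#'   probabilities p_j*h_i are clipped to \code{[0, 1]}.
#' @param empty_fraction Probability an observed shelter is empty.
#' @param species_fraction Probability an occupied shelter holds the
#'   focal species (`reducta`) rather than `camilla`.
#' @param loss_probability Probability an observed shelter disappears
#'   during the study (violating closure; see [filter_closure()]).
#' @param seed Integer root seed; per-plot substreams are derived from it
#'   so one plot's draws do not shift another's.
#' @return A `sim_config` list.
#' @export
sim_config <- function(plots = default_sim_plots(),
                       roster = default_roster(),
                       orders = NULL,
                       heterogeneity = 0,
                       empty_fraction = 34 / 75,
                       species_fraction = 39 / 41,
                       loss_probability = 3 / 78,
                       seed = NULL) {
  plots <- tibble::as_tibble(plots)
  roster <- tibble::as_tibble(roster)
  stopifnot(
    all(plots$true_n > 0),
    all(roster$p_detect >= 0 & roster$p_detect <= 1),
    heterogeneity >= 0,
    empty_fraction >= 0, empty_fraction <= 1,
    species_fraction >= 0, species_fraction <= 1,
    loss_probability >= 0, loss_probability <= 1
  )
  if (is.null(orders)) {
    orders <- stats::setNames(
      purrr::map(plots$plot_id, \(p) default_order(roster, p)),
      plots$plot_id
    )
  }
  structure(
    list(
      plots = plots, roster = roster, orders = orders,
      heterogeneity = heterogeneity, empty_fraction = empty_fraction,
      species_fraction = species_fraction,
      loss_probability = loss_probability, seed = seed
    ),
    class = "sim_config"
  )
}

# deterministic 32-bit substream seed from root seed + stream label
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 2654435.0)
  as.integer((abs(seed) * 69069 + h) %% 2147483647)
}

#' Simulate a multi-surveyor detection dataset
#'
#' Draws D[i, t] ~ Bernoulli(p_t * h_i) independently over individuals
#' and occasions, with h_i == 1 unless heterogeneity is enabled. The
#' returned dataset contains only individuals detected at least once
#' (what a field study observes); the complete truth — per-plot true N
#' and every individual's detectability — is attached as the
#' `ground_truth` attribute (see [ground_truth()]).
#'
#' @param cfg A [sim_config()].
#' @return A [detection_data()] object with ground truth attached.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seed <- if (is.null(cfg$seed)) {
    as.integer(stats::runif(1, 1, 2^31 - 1))
  } else {
    as.integer(cfg$seed)
  }

  p_of <- stats::setNames(cfg$roster$p_detect, cfg$roster$surveyor_id)
  truth_all <- list()
  det_all <- list()
  occ_all <- list()
  ind_all <- list()

  for (pi in seq_len(nrow(cfg$plots))) {
    pid <- cfg$plots$plot_id[pi]
    n_true <- cfg$plots$true_n[pi]
    ord <- cfg$orders[[pid]]
    set.seed(substream_seed(seed, paste0("plot:", pid)))

    h <- rep(1, n_true)
    if (cfg$heterogeneity > 0) {
      a <- 1 / cfg$heterogeneity
      h <- 2 * stats::rbeta(n_true, a, a)
    }
    p_mat <- pmin(pmax(outer(h, p_of[ord]), 0), 1)
    d <- matrix(
      as.integer(stats::runif(length(p_mat)) < p_mat),
      n_true, length(ord)
    )
    ids <- sprintf("%s%03d", pid, seq_len(n_true))
    seen <- rowSums(d) > 0

    n_obs <- sum(seen)
    occup <- species <- lost <- rep(NA, n_true)
    if (n_obs) {
      emp <- stats::runif(n_true) < cfg$empty_fraction
      red <- stats::runif(n_true) < cfg$species_fraction
      lst <- stats::runif(n_true) < cfg$loss_probability
      occup <- ifelse(emp, "empty", "full")
      species <- ifelse(emp, "unknown", ifelse(red, "reducta", "camilla"))
      lost <- lst
    }

    truth_all[[pid]] <- tibble::tibble(
      plot_id = pid, hibernaculum_id = ids, detectability = h,
      detected_ever = seen
    )
    ind_all[[pid]] <- tibble::tibble(
      hibernaculum_id = ids[seen], plot_id = pid,
      species = species[seen], occupancy = occup[seen], lost = lost[seen]
    )
    occ_all[[pid]] <- tibble::tibble(
      plot_id = pid, occasion = seq_along(ord), surveyor_id = ord
    )
    if (n_obs) {
      det_all[[pid]] <- tibble::tibble(
        plot_id = pid,
        hibernaculum_id = rep(ids[seen], times = length(ord)),
        surveyor_id = rep(ord, each = n_obs),
        detected = as.integer(d[seen, , drop = FALSE])
      )
    }
  }

  detections <- dplyr::bind_rows(det_all)
  if (!nrow(detections)) {
    detections <- tibble::tibble(
      plot_id = character(), hibernaculum_id = character(),
      surveyor_id = character(), detected = integer()
    )
  }

  plots_tbl <- cfg$plots
  if (!"area" %in% names(plots_tbl)) plots_tbl$area <- NA_real_
  if (!"host_plants" %in% names(plots_tbl)) {
    plots_tbl$host_plants <- NA_integer_
  }

  ds <- detection_data(
    dplyr::bind_rows(ind_all),
    dplyr::select(cfg$roster, "surveyor_id", "experience"),
    dplyr::bind_rows(occ_all),
    detections,
    dplyr::select(plots_tbl, "plot_id", "area", "host_plants")
  )
  attr(ds, "ground_truth") <- list(
    true_n = dplyr::select(cfg$plots, "plot_id", "true_n"),
    individuals = dplyr::bind_rows(truth_all),
    surveyor_p = tibble::tibble(
      surveyor_id = cfg$roster$surveyor_id,
      experience = cfg$roster$experience,
      p_detect = cfg$roster$p_detect
    ),
    seed = seed
  )
  ds
}

#' Ground truth of a simulated dataset
#'
#' @param ds A dataset produced by [simulate_population()].
#' @return A list: `true_n` (per plot), `individuals` (all simulated
#'   individuals, including never-detected ones, with their detectability
#'   multipliers), `surveyor_p`, and the `seed` used.
#' @export
ground_truth <- function(ds) {
  gt <- attr(ds, "ground_truth")
  if (is.null(gt)) stop("dataset carries no ground truth", call. = FALSE)
  gt
}
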