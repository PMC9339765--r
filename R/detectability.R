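#' Simulate detection-count frequencies under equal detectability
#'
#' Closed-population estimators assume every individual is equally
#' detectable. Holding each surveyor's total catch fixed at its observed
#' value, this simulates detection histories in which each surveyor's
#' n_j finds are a uniform simple random sample (without replacement)
#' from the N individuals, and tallies how many individuals end up
#' detected k = 0..T times. The per-k median and 2.5/97.5 percentile
#' envelope across replicates form the reference bands an observed
#' frequency distribution is compared against.
#'
#' @param n_assumed Assumed true population size (integer; typically the
#'   rounded full-effort CMR estimate).
#' @param occasion_counts Vector of per-surveyor detection totals; each
#'   must not exceed `n_assumed`.
#' @param n_sim Number of simulated detection histories (default 10000).
#' @param seed Integer seed.
#' @return A tibble of class `frequency_bands` with columns `k`,
#'   `sim_median`, `sim_lcl`, `sim_ucl`; attributes `n_assumed`,
#'   `n_sim`, `seed`, `occasion_counts`.
#' @export
simulate_equal_detection <- function(n_assumed, occasion_counts,
                                     n_sim = 10000, seed = NULL) {
  n_assumed <- as.integer(round(n_assumed))
  stopifnot(n_assumed >= 1, all(occasion_counts >= 0))
  if (any(occasion_counts > n_assumed)) {
    stop("a surveyor cannot detect more individuals (",
         max(occasion_counts), ") than the assumed population size (",
         n_assumed, ")", call. = FALSE)
  }
  if (is.null(seed)) seed <- as.integer(stats::runif(1, 1, 2^31 - 1))
  set.seed(seed)
  t_n <- length(occasion_counts)
  tab <- matrix(0L, n_sim, t_n + 1)
  for (b in seq_len(n_sim)) {
    hits <- integer(n_assumed)
    for (nj in occasion_counts) {
      if (nj > 0) {
        idx <- sample.int(n_assumed, nj)
        hits[idx] <- hits[idx] + 1L
      }
    }
    tab[b, ] <- tabulate(hits + 1L, nbins = t_n + 1)
  }
  q <- apply(tab, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
             names = FALSE, type = 7)
  out <- tibble::tibble(
    k = 0:t_n, sim_median = q[1, ], sim_lcl = q[2, ], sim_ucl = q[3, ]
  )
  attr(out, "n_assumed") <- n_assumed
  attr(out, "n_sim") <- n_sim
  attr(out, "seed") <- seed
  attr(out, "occasion_counts") <- occasion_counts
  class(out) <- c("frequency_bands", class(out))
  out
}

#' Compare observed detection frequencies with equal-detection bands
#'
#' The observed frequency at k >= 1 is the number of individuals
#' detected exactly k times; at k = 0 it is the assumed population size
#' minus the number ever observed. Each frequency is flagged as inside
#' or outside the simulated 95% envelope; observed frequencies mostly
#' inside the bands are consistent with equal detectability.
#'
#' @param ds A `detection_data` object.
#' @param plot Plot id.
#' @param bands A `frequency_bands` object for that plot.
#' @return A tibble: `k`, `observed`, `sim_median`, `sim_lcl`,
#'   `sim_ucl`, `inside`.
#' @export
compare_observed <- function(ds, plot, bands) {
  d <- plot_matrix(ds, plot)
  n_assumed <- attr(bands, "n_assumed")
  m <- nrow(d)
  if (n_assumed < m) {
    stop("assumed population size (", n_assumed,
         ") is below the number observed (", m, ")", call. = FALSE)
  }
  t_n <- ncol(d)
  stopifnot(max(bands$k) == t_n)
  counts <- tabulate(rowSums(d) + 1L, nbins = t_n + 1)
  counts[1] <- n_assumed - m
  out <- dplyr::mutate(
    tibble::as_tibble(bands), observed = counts,
    inside = .data$observed >= .data$sim_lcl &
      .data$observed <= .data$sim_ucl
  ) |>
    dplyr::select("k", "observed", dplyr::everything())
  class(out) <- c("detectability_check", class(out))
  attributes(out)[c("n_assumed", "n_sim", "seed")] <-
    attributes(bands)[c("n_assumed", "n_sim", "seed")]
  out
}

#' Equal-detectability check for one plot
#'
#' Convenience wrapper: takes the per-surveyor totals from the data,
#' simulates equal-detection bands for the assumed population size, and
#' compares the observed frequencies against them.
#'
#' @param ds A `detection_data` object.
#' @param plot Plot id.
#' @param n_assumed Assumed true population size; default is the rounded
#'   full-effort Mt abundance estimate for the plot.
#' @param n_sim,seed Passed to [simulate_equal_detection()].
#' @return A `detectability_check` tibble (see [compare_observed()]).
#' @export
detectability_check <- function(ds, plot, n_assumed = NULL,
                                n_sim = 10000, seed = NULL) {
  if (is.null(n_assumed)) {
    ab <- abundance(fit_huggins(ds, "mt"), plot)
    n_assumed <- round(ab$n_hat)
  }
  d <- plot_matrix(ds, plot)
  bands <- simulate_equal_detection(
    n_assumed, colSums(d), n_sim = n_sim, seed = seed
  )
  compare_observed(ds, plot, bands)
}
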