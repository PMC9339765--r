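#' Accuracy and precision statistics for reduced-effort estimates
#'
#' `relative_error()` compares an estimate against the full-effort
#' benchmark: |N_i - N_f| / N_f. `relative_ci_width()` measures
#' precision: (upper - lower) / N_i. Both are dimensionless and
#' vectorised.
#'
#' @param n_i Estimate(s) under evaluation.
#' @param n_f Full-effort benchmark estimate(s), > 0.
#' @param lcl,ucl 95% interval bounds, `ucl >= lcl`.
#' @return Numeric vector.
#' @export
relative_error <- function(n_i, n_f) {
  if (any(n_f <= 0, na.rm = TRUE)) {
    stop("benchmark estimate must be positive", call. = FALSE)
  }
  sqrt((n_i - n_f)^2) / n_f
}

#' @rdname relative_error
#' @export
relative_ci_width <- function(lcl, ucl, n_i) {
  if (any(ucl < lcl, na.rm = TRUE)) {
    stop("upper CI limit below lower limit", call. = FALSE)
  }
  if (any(n_i <= 0, na.rm = TRUE)) {
    stop("estimate must be positive", call. = FALSE)
  }
  (ucl - lcl) / n_i
}

# one plot restricted to a surveyor subset (original order), dropping
# individuals never detected by the subset
subset_dataset <- function(ds, plot, surveyor_subset) {
  occ <- occasions_of(ds, plot) |>
    dplyr::filter(.data$surveyor_id %in% surveyor_subset) |>
    dplyr::mutate(occasion = seq_len(dplyr::n()))
  det <- ds$detections |>
    dplyr::filter(
      .data$plot_id == plot, .data$surveyor_id %in% surveyor_subset
    )
  seen <- det |>
    dplyr::summarise(n = sum(.data$detected), .by = "hibernaculum_id") |>
    dplyr::filter(.data$n > 0)
  ind <- ds$individuals |>
    dplyr::filter(
      .data$plot_id == plot,
      .data$hibernaculum_id %in% seen$hibernaculum_id
    )
  detection_data(
    ind, ds$surveyors, occ,
    dplyr::semi_join(det, seen, by = "hibernaculum_id"),
    dplyr::filter(ds$plots, .data$plot_id == plot)
  )
}

#' Reduced-effort CMR scan over expert subsets
#'
#' Refits the Huggins model for every k-surveyor subset of each plot's
#' experts (k in `k_range`), emulating a survey that deployed fewer
#' people. Detection is modelled as constant (M0) for two-surveyor
#' subsets — two occasions carry little information about time
#' dependence — and time-dependent (Mt) otherwise. Each refit is
#' compared with the full-effort (all-surveyor) estimate of the same
#' plot via [relative_error()] and [relative_ci_width()].
#'
#' A refit is "reliable" when the optimiser converged away from the
#' parameter boundary, the abundance variance is finite, and the upper
#' confidence limit is below 50 times the estimate; inestimable subsets
#' (e.g. two surveyors sharing no recaptures, which push the detection
#' probability to the boundary) are flagged, never dropped silently.
#'
#' @param ds A `detection_data` object (closure-filtered).
#' @param k_range Subset sizes to scan (default 2:6).
#' @param experts Surveyor ids to combine; default all with
#'   `experience == "expert"`. Only experts who searched a plot are
#'   combined for that plot.
#' @param n_full Optional tibble `plot_id, n_hat` of full-effort
#'   benchmarks; computed from an all-surveyor Mt fit when omitted.
#' @return A tibble of class `effort_scan`, one row per plot x subset:
#'   `plot_id`, `k`, `subset`, `m_obs`, `n_hat`, `lcl`, `ucl`,
#'   `converged`, `reliable`, `rel_error`, `rel_ci_width`.
#' @seealso [effort_summary()]
#' @export
reduced_effort_scan <- function(ds, k_range = 2:6, experts = NULL,
                                n_full = NULL) {
  if (is.null(experts)) {
    experts <- ds$surveyors$surveyor_id[
      ds$surveyors$experience == "expert"
    ]
  }
  if (!all(experts %in% ds$surveyors$surveyor_id)) {
    stop("unknown expert surveyor id", call. = FALSE)
  }
  if (is.null(n_full)) {
    full <- fit_huggins(ds, "mt")
    n_full <- dplyr::select(abundance(full), "plot_id",
                            n_full = "n_hat")
  } else {
    n_full <- dplyr::rename(tibble::as_tibble(n_full),
                            n_full = "n_hat")
  }

  rows <- list()
  for (pid in ds$plots$plot_id) {
    occ <- occasions_of(ds, pid)
    plot_experts <- occ$surveyor_id[occ$surveyor_id %in% experts]
    nf <- n_full$n_full[n_full$plot_id == pid]
    for (k in k_range[k_range <= length(plot_experts)]) {
      combos <- utils::combn(plot_experts, k, simplify = FALSE)
      for (sub in combos) {
        res <- tryCatch({
          sds <- subset_dataset(ds, pid, sub)
          f <- fit_huggins(sds, if (k == 2) "m0" else "mt")
          ab <- suppressWarnings(abundance(f, pid))
          ok <- f$converged && !f$boundary && is.finite(ab$se) &&
            is.finite(ab$ucl) && ab$ucl < 50 * ab$n_hat
          tibble::tibble(
            m_obs = ab$m_obs, n_hat = ab$n_hat, lcl = ab$lcl,
            ucl = ab$ucl, converged = f$converged, reliable = ok
          )
        }, error = function(e) tibble::tibble(
          m_obs = NA_integer_, n_hat = NA_real_, lcl = NA_real_,
          ucl = NA_real_, converged = FALSE, reliable = FALSE
        ))
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(
            plot_id = pid, k = k, subset = paste(sub, collapse = "+")
          ),
          res
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      rel_error = ifelse(
        is.finite(.data$n_hat),
        relative_error(.data$n_hat, n_full$n_full[
          match(.data$plot_id, n_full$plot_id)
        ]),
        NA_real_
      ),
      rel_ci_width = ifelse(
        .data$reliable,
        (.data$ucl - .data$lcl) / .data$n_hat,
        NA_real_
      )
    )
  class(out) <- c("effort_scan", class(out))
  out
}

#' Summarise a reduced-effort scan by surveyor number
#'
#' Arithmetic means of relative error and relative CI width over
#' reliable refits, with model counts, per subset size k.
#'
#' @param scan An `effort_scan` tibble.
#' @return A tibble with one row per k.
#' @export
effort_summary <- function(scan) {
  scan |>
    dplyr::summarise(
      n_models = dplyr::n(),
      n_reliable = sum(.data$reliable),
      mean_rel_error = mean(.data$rel_error[.data$reliable]),
      mean_rel_ci_width = mean(.data$rel_ci_width[.data$reliable]),
      .by = "k"
    ) |>
    dplyr::arrange(.data$k)
}

#' Scale a single surveyor's count to an abundance estimate
#'
#' When a surveyor's detection probability is known (from a previous
#' multi-surveyor study), one search suffices for a rough estimate:
#' count / p.
#'
#' @param count Number of individuals the surveyor detected.
#' @param p_scale Detection probability used as scaling factor, in
#'   (0, 1].
#' @return Abundance estimate(s).
#' @export
single_surveyor_estimate <- function(count, p_scale) {
  if (any(p_scale <= 0 | p_scale > 1)) {
    stop("scaling probability must be in (0, 1]", call. = FALSE)
  }
  count / p_scale
}

#' Single-expert scaling estimates across a dataset
#'
#' For every expert x plot searched, scales the expert's raw count by
#' (a) the expert-group mean detection probability from an
#' experience-covariate fit and (b) the surveyor's own probability from
#' a time-dependent fit, and compares both with the full-effort
#' benchmark.
#'
#' @param ds A `detection_data` object.
#' @param fit_mt Optional all-surveyor Mt `huggins_fit`.
#' @param fit_exp Optional experience-covariate `huggins_fit`.
#' @return A tibble: `plot_id`, `surveyor_id`, `count`,
#'   `estimate_group`, `estimate_surveyor`, `rel_error_group`,
#'   `rel_error_surveyor`.
#' @export
single_surveyor_scan <- function(ds, fit_mt = NULL, fit_exp = NULL) {
  if (is.null(fit_mt)) fit_mt <- fit_huggins(ds, "mt")
  if (is.null(fit_exp)) fit_exp <- fit_huggins(ds, "experience")
  n_full <- abundance(fit_mt)
  p_sv <- detection_probs(fit_mt)
  p_grp <- experience_probs(fit_exp)
  p_expert <- p_grp$estimate[p_grp$experience == "expert"]
  experts <- ds$surveyors$surveyor_id[ds$surveyors$experience == "expert"]

  ds$detections |>
    dplyr::filter(.data$surveyor_id %in% experts) |>
    dplyr::summarise(
      count = sum(.data$detected),
      .by = c("plot_id", "surveyor_id")
    ) |>
    dplyr::mutate(
      estimate_group = single_surveyor_estimate(.data$count, p_expert),
      estimate_surveyor = single_surveyor_estimate(
        .data$count,
        p_sv$estimate[match(.data$surveyor_id, p_sv$surveyor_id)]
      ),
      n_full = n_full$n_hat[match(.data$plot_id, n_full$plot_id)],
      rel_error_group = relative_error(.data$estimate_group,
                                       .data$n_full),
      rel_error_surveyor = relative_error(.data$estimate_surveyor,
                                          .data$n_full)
    ) |>
    dplyr::select(-"n_full")
}
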