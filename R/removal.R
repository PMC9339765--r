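#' Pseudo-removal depletion pairs for one surveyor order
#'
#' In a multi-surveyor search, individuals already found by an earlier
#' surveyor play the role of "removed" animals: under constant detection
#' probability the number of new detections declines linearly in the
#' number previously detected. For each occasion t (in the given order)
#' this returns x_t, the count of distinct individuals detected at any
#' earlier occasion, and y_t, the count first detected at t.
#'
#' @param d Binary detection matrix (individuals x occasions), e.g. from
#'   [plot_matrix()].
#' @param order Permutation of occasion indices (default: original
#'   search order).
#' @return A tibble with `position`, `occasion` (original index),
#'   `prev_detected` (x) and `new_detections` (y).
#' @export
depletion_pairs <- function(d, order = seq_len(ncol(d))) {
  stopifnot(setequal(order, seq_len(ncol(d))))
  y <- new_detection_counts(d, order)
  tibble::tibble(
    position = seq_along(order),
    occasion = as.integer(order),
    prev_detected = c(0, cumsum(y)[-length(y)]),
    new_detections = y
  )
}

# y_t per occasion of `order`; rows with no detections contribute nothing
new_detection_counts <- function(d, order) {
  t_n <- length(order)
  seen <- rowSums(d) > 0
  if (!any(seen)) return(rep(0L, t_n))
  first <- max.col(d[seen, order, drop = FALSE], ties.method = "first")
  tabulate(first, nbins = t_n)
}

#' Leslie-Davis depletion regression
#'
#' Ordinary least-squares fit of new detections on the number previously
#' detected; the x-axis intercept estimates population size. The fit is
#' degenerate (no estimate) when the slope is not strictly negative or
#' when all x values coincide so no slope exists.
#'
#' @param pairs Tibble from [depletion_pairs()] (columns `prev_detected`,
#'   `new_detections`), or any data frame with those columns.
#' @return A list: `slope`, `intercept`, `x_intercept` (NA when
#'   degenerate), `degenerate` flag.
#' @export
leslie_fit <- function(pairs) {
  x <- pairs$prev_detected
  y <- pairs$new_detections
  stopifnot(length(x) >= 2)
  if (stats::var(x) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_,
                x_intercept = NA_real_, degenerate = TRUE))
  }
  co <- stats::lm.fit(cbind(1, x), y)$coefficients
  slope <- co[[2]]
  intercept <- co[[1]]
  if (!is.finite(slope) || slope >= 0) {
    return(list(slope = slope, intercept = intercept,
                x_intercept = NA_real_, degenerate = TRUE))
  }
  list(slope = slope, intercept = intercept,
       x_intercept = -intercept / slope, degenerate = FALSE)
}

#' Permutation removal estimate of abundance
#'
#' Surveyors worked independently and without prior knowledge, so their
#' order is exchangeable: the depletion regression is recomputed under
#' `n_perm` uniformly random surveyor orders and summarised by the median
#' x-intercept and the 2.5/97.5 percentile interval. Orders whose
#' regression is degenerate (non-negative slope, or no slope) yield no
#' finite estimate; they are excluded from the summaries and counted in
#' `n_degenerate`.
#'
#' @param ds A `detection_data` object.
#' @param plot Optional plot id; default all plots.
#' @param n_perm Number of random surveyor orders (default 10000).
#' @param seed Integer seed; recorded in the result. Each plot draws from
#'   its own substream.
#' @return A tibble of class `removal_estimate` with one row per plot:
#'   `plot_id`, `mln`, `estimate` (median), `lcl`, `ucl`, `n_perm`,
#'   `n_degenerate`, `below_mln` (estimate undershoots the direct count —
#'   possible, flagged, not an error), `seed`. The per-plot vectors of
#'   finite x-intercepts are attached as attribute `draws`.
#' @export
permutation_removal <- function(ds, plot = NULL, n_perm = 10000,
                                seed = NULL) {
  plot_ids <- if (is.null(plot)) ds$plots$plot_id else plot
  if (is.null(seed)) seed <- as.integer(stats::runif(1, 1, 2^31 - 1))
  mln_tbl <- mln(ds)
  draws <- list()

  rows <- purrr::map(plot_ids, function(pid) {
    d <- plot_matrix(ds, pid)
    t_n <- ncol(d)
    if (t_n < 2) stop("plot '", pid, "' has fewer than 2 occasions",
                      call. = FALSE)
    set.seed(substream_seed(seed, paste0("removal:", pid)))
    xi <- numeric(n_perm)
    seen <- rowSums(d) > 0
    dv <- d[seen, , drop = FALSE]
    for (b in seq_len(n_perm)) {
      ord <- sample.int(t_n)
      y <- tabulate(
        max.col(dv[, ord, drop = FALSE], ties.method = "first"),
        nbins = t_n
      )
      x <- c(0, cumsum(y)[-t_n])
      f <- leslie_fit(
        list(prev_detected = x, new_detections = as.numeric(y))
      )
      xi[b] <- if (f$degenerate) NA_real_ else f$x_intercept
    }
    ok <- xi[is.finite(xi)]
    draws[[pid]] <<- ok
    m <- mln_tbl$mln[mln_tbl$plot_id == pid]
    if (!length(ok)) {
      return(tibble::tibble(
        plot_id = pid, mln = m, estimate = NA_real_, lcl = NA_real_,
        ucl = NA_real_, n_perm = n_perm, n_degenerate = n_perm,
        below_mln = NA, seed = seed
      ))
    }
    q <- stats::quantile(ok, c(0.5, 0.025, 0.975), names = FALSE,
                         type = 7)
    tibble::tibble(
      plot_id = pid, mln = m, estimate = q[1], lcl = q[2], ucl = q[3],
      n_perm = n_perm, n_degenerate = n_perm - length(ok),
      below_mln = q[1] < m, seed = seed
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "draws") <- draws
  class(out) <- c("removal_estimate", class(out))
  out
}

#' @export
print.removal_estimate <- function(x, ...) {
  cat("Permutation removal estimates (median and 95% percentile CI of ",
      "the depletion-regression x-intercept)\n", sep = "")
  NextMethod()
}
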