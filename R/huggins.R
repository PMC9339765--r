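#' Probability of at least one detection
#'
#' `p* = 1 - prod(1 - p_t)` over a vector of per-occasion detection
#' probabilities: the probability an individual enters the observed
#' dataset at all. The Huggins conditional likelihood divides by it, and
#' Horvitz-Thompson abundance sums its reciprocal.
#'
#' @param p Vector of per-occasion detection probabilities in \code{[0, 1]}.
#' @return A single probability.
#' @export
p_star <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  1 - prod(1 - p)
}

CLIP <- 1e-12

# model structure: per-plot sufficient statistics + occasion->eta design
huggins_structure <- function(ds, model) {
  plot_ids <- ds$plots$plot_id
  plot_ids <- plot_ids[plot_ids %in% ds$individuals$plot_id]
  sv_exp <- stats::setNames(ds$surveyors$experience,
                            ds$surveyors$surveyor_id)
  terms <- switch(model,
    m0 = "logit_p",
    mt = NULL,  # filled below, one per surveyor
    experience = c("(Intercept)", "expert")
  )
  plots <- purrr::map(plot_ids, function(pid) {
    d <- plot_matrix(ds, pid)
    if (ncol(d) < 2) {
      stop("plot '", pid, "' has fewer than 2 occasions", call. = FALSE)
    }
    list(plot_id = pid, surveyors = colnames(d), m_obs = nrow(d),
         n_t = colSums(d))
  })
  all_sv <- unique(unlist(purrr::map(plots, "surveyors")))
  if (model == "mt") terms <- paste0("p[", all_sv, "]")
  # design matrix rows per occasion of each plot
  plots <- purrr::map(plots, function(pl) {
    pl$X <- switch(model,
      m0 = matrix(1, length(pl$surveyors), 1),
      mt = {
        x <- matrix(0, length(pl$surveyors), length(all_sv))
        x[cbind(seq_along(pl$surveyors),
                match(pl$surveyors, all_sv))] <- 1
        x
      },
      experience = cbind(
        1, as.numeric(sv_exp[pl$surveyors] == "expert")
      )
    )
    pl
  })
  list(model = model, terms = terms, plots = plots, all_sv = all_sv,
       sv_exp = sv_exp)
}

huggins_loglik <- function(beta, str) {
  ll <- 0
  for (pl in str$plots) {
    p <- pmin(pmax(stats::plogis(drop(pl$X %*% beta)), CLIP), 1 - CLIP)
    ps <- 1 - prod(1 - p)
    ll <- ll + sum(pl$n_t * log(p) + (pl$m_obs - pl$n_t) * log(1 - p)) -
      pl$m_obs * log(ps)
  }
  ll
}

huggins_grad <- function(beta, str) {
  g <- numeric(length(beta))
  for (pl in str$plots) {
    p <- pmin(pmax(stats::plogis(drop(pl$X %*% beta)), CLIP), 1 - CLIP)
    ps <- 1 - prod(1 - p)
    # d ll / d eta_t
    ge <- pl$n_t * (1 - p) - (pl$m_obs - pl$n_t) * p -
      pl$m_obs * (1 - ps) * p / ps
    g <- g + drop(crossprod(pl$X, ge))
  }
  g
}

num_hessian <- function(fn, x, step = 1e-5) {
  k <- length(x)
  h <- pmax(step, step * abs(x))
  out <- matrix(0, k, k)
  for (j in seq_len(k)) {
    xp <- xm <- x
    xp[j] <- x[j] + h[j]
    xm[j] <- x[j] - h[j]
    out[, j] <- (fn(xp) - fn(xm)) / (2 * h[j])
  }
  (out + t(out)) / 2
}

#' Fit a Huggins closed-population model
#'
#' Maximises the conditional likelihood of the observed detection
#' histories (conditioning on each individual being detected at least
#' once) over logit-scale detection parameters, with capture and
#' recapture probabilities shared (p = c; the organisms cannot respond
#' behaviourally to being "caught"). Plots act as groups: detection
#' parameters are shared across plots, abundance is estimated per plot
#' by [abundance()].
#'
#' Detection structures:
#' \describe{
#'   \item{`"m0"`}{one constant probability;}
#'   \item{`"mt"`}{one probability per surveyor (time dependence), shared
#'     across the plots that surveyor searched;}
#'   \item{`"experience"`}{logit p = b0 + b1 * expert, a two-level
#'     occasion covariate.}
#' }
#'
#' @param ds A `detection_data` object (run [filter_closure()] first on
#'   field data).
#' @param model `"mt"` (default), `"m0"`, or `"experience"`.
#' @return A `huggins_fit` object; see [tidy.huggins_fit()],
#'   [detection_probs()], [abundance()].
#' @export
fit_huggins <- function(ds, model = c("mt", "m0", "experience")) {
  model <- match.arg(model)
  str <- huggins_structure(ds, model)
  k <- length(str$terms)
  nll <- function(b) -huggins_loglik(b, str)
  ngr <- function(b) -huggins_grad(b, str)

  p_naive <- {
    tot <- sum(purrr::map_dbl(str$plots, \(pl) sum(pl$n_t)))
    cells <- sum(purrr::map_dbl(
      str$plots, \(pl) pl$m_obs * length(pl$surveyors)
    ))
    min(max(tot / cells, 0.02), 0.98)
  }
  # Newton polish: BFGS stops on relative likelihood change; finish with
  # Newton steps so the gradient-norm convergence contract is met
  polish <- function(par) {
    for (it in 1:25) {
      g <- huggins_grad(par, str)
      if (!all(is.finite(g)) || max(abs(g)) < 1e-9 ||
          any(abs(par) > 12)) {
        break
      }
      hess <- num_hessian(function(b) huggins_grad(b, str), par)
      step <- tryCatch(solve(hess, g), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      cand <- par - step
      if (huggins_loglik(cand, str) >=
            huggins_loglik(par, str) - 1e-9) {
        par <- cand
      } else {
        break
      }
    }
    par
  }

  starts <- c(stats::qlogis(p_naive), -2, -1, 0)
  best <- NULL
  for (s0 in starts) {
    opt <- stats::optim(
      rep(s0, k), nll, ngr, method = "BFGS",
      control = list(maxit = 500, reltol = 1e-14)
    )
    opt$par <- polish(opt$par)
    opt$value <- -huggins_loglik(opt$par, str)
    gnorm <- max(abs(huggins_grad(opt$par, str)))
    boundary <- any(abs(opt$par) > 10)
    if (is.null(best) || opt$value < best$value - 1e-8) {
      best <- opt
      best$gnorm <- gnorm
      best$boundary <- boundary
    }
    if (gnorm < 1e-6 || boundary) break
  }
  converged <- best$gnorm < 1e-6 || best$boundary

  hess <- num_hessian(function(b) huggins_grad(b, str), best$par)
  vcov <- tryCatch(solve(-hess), error = function(e) {
    matrix(NA_real_, k, k)
  })
  se <- suppressWarnings(sqrt(diag(vcov)))

  structure(
    list(
      model = model, structure = str,
      beta = tibble::tibble(
        term = str$terms, estimate = best$par, std_error = se
      ),
      vcov = vcov, loglik = -best$value, converged = converged,
      boundary = best$boundary, grad_norm = best$gnorm, n_params = k
    ),
    class = "huggins_fit"
  )
}

#' @export
print.huggins_fit <- function(x, ...) {
  cat("Huggins closed-population fit (", x$model, "), ",
      length(x$structure$plots), " group(s), logLik ",
      format(x$loglik, digits = 6),
      if (!x$converged) " [NOT CONVERGED]" else "",
      if (x$boundary) " [boundary estimate]" else "", "\n", sep = "")
  print(detection_probs(x), n = Inf)
  invisible(x)
}

#' Per-occasion detection probabilities of a fit
#'
#' Back-transformed estimates with Wald 95% intervals computed on the
#' logit scale.
#'
#' @param fit A `huggins_fit`.
#' @return A tibble with `surveyor_id` (or group label), `experience`
#'   where known, `estimate`, `lcl`, `ucl`.
#' @export
detection_probs <- function(fit) {
  str <- fit$structure
  if (fit$model == "mt") {
    lab <- str$all_sv
    X <- diag(length(lab))
    exper <- unname(str$sv_exp[lab])
  } else if (fit$model == "m0") {
    lab <- "constant"
    X <- matrix(1, 1, 1)
    exper <- NA_character_
  } else {
    lab <- c("expert", "novice")
    X <- rbind(c(1, 1), c(1, 0))
    exper <- lab
  }
  eta <- drop(X %*% fit$beta$estimate)
  se <- sqrt(pmax(diag(X %*% fit$vcov %*% t(X)), 0))
  tibble::tibble(
    surveyor_id = lab, experience = exper,
    estimate = stats::plogis(eta),
    lcl = stats::plogis(eta - 1.96 * se),
    ucl = stats::plogis(eta + 1.96 * se)
  )
}

#' Experience-group detection probabilities
#'
#' @param fit A `huggins_fit` with `model = "experience"`.
#' @return A tibble with one row per experience level: `estimate`,
#'   `lcl`, `ucl`.
#' @export
experience_probs <- function(fit) {
  stopifnot(fit$model == "experience")
  dplyr::select(detection_probs(fit), -"surveyor_id")
}

# fitted p vector for one plot
plot_p <- function(fit, pl) {
  pmin(pmax(stats::plogis(drop(pl$X %*% fit$beta$estimate)), CLIP),
       1 - CLIP)
}

#' Horvitz-Thompson abundance per plot
#'
#' For each plot (group), abundance is the sum over observed individuals
#' of 1/p*_i — here M/p* since all individuals of a plot share the same
#' occasion probabilities. The variance combines the Huggins
#' binomial-type term `M (1 - p*) / p*^2` with a delta-method term for
#' detection-parameter uncertainty; the 95% interval is the MARK-style
#' log-normal interval on f0 = N - M, whose lower bound cannot fall
#' below the number of individuals actually observed.
#'
#' @param fit A converged `huggins_fit`.
#' @param plot Optional plot id; default all groups.
#' @return A tibble: `plot_id`, `m_obs`, `p_star` (probability of being
#'   detected at least once), `n_hat`, `f0`, `se`, `lcl`, `ucl`.
#' @export
abundance <- function(fit, plot = NULL) {
  if (!fit$converged) {
    warning("fit did not converge; abundance CIs not computed")
  }
  str <- fit$structure
  ids <- purrr::map_chr(str$plots, "plot_id")
  if (!is.null(plot)) {
    if (!plot %in% ids) stop("unknown plot id: ", plot, call. = FALSE)
    ids <- plot
  }
  beta <- fit$beta$estimate
  rows <- purrr::map(str$plots[match(ids, purrr::map_chr(
    str$plots, "plot_id"
  ))], function(pl) {
    p <- plot_p(fit, pl)
    ps <- 1 - prod(1 - p)
    n_hat <- pl$m_obs / ps
    var_ht <- pl$m_obs * (1 - ps) / ps^2
    # delta-method term, numeric Jacobian of N(beta), relative step 1e-5
    grad_n <- purrr::map_dbl(seq_along(beta), function(j) {
      h <- 1e-5 * max(1, abs(beta[j]))
      bp <- bm <- beta
      bp[j] <- beta[j] + h
      bm[j] <- beta[j] - h
      np <- pl$m_obs / (1 - prod(1 - stats::plogis(drop(pl$X %*% bp))))
      nm <- pl$m_obs / (1 - prod(1 - stats::plogis(drop(pl$X %*% bm))))
      (np - nm) / (2 * h)
    })
    var_delta <- drop(t(grad_n) %*% fit$vcov %*% grad_n)
    v <- var_ht + if (is.finite(var_delta)) max(var_delta, 0) else NA_real_
    f0 <- n_hat - pl$m_obs
    if (!fit$converged || !is.finite(v)) {
      lcl <- ucl <- NA_real_
    } else if (f0 <= 1e-8) {
      lcl <- ucl <- pl$m_obs
      f0 <- max(f0, 0)
    } else {
      cc <- exp(1.96 * sqrt(log(1 + v / f0^2)))
      lcl <- pl$m_obs + f0 / cc
      ucl <- pl$m_obs + f0 * cc
    }
    tibble::tibble(
      plot_id = pl$plot_id, m_obs = pl$m_obs, p_star = ps,
      n_hat = n_hat, f0 = f0, se = sqrt(v), lcl = lcl, ucl = ucl
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname tidy.huggins_fit
#' @export
glance.huggins_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, df = x$n_params,
    AIC = 2 * x$n_params - 2 * x$loglik,
    converged = x$converged, boundary = x$boundary
  )
}

#' Tidy a Huggins fit
#'
#' `tidy()` returns the logit-scale parameter table (add
#' `type = "probability"` for the back-transformed per-occasion table);
#' `glance()` returns a one-row model summary.
#'
#' @param x A `huggins_fit`.
#' @param type `"link"` (default) or `"probability"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.huggins_fit <- function(x, type = c("link", "probability"), ...) {
  type <- match.arg(type)
  if (type == "probability") return(detection_probs(x))
  dplyr::mutate(
    x$beta, statistic = .data$estimate / .data$std_error
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
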