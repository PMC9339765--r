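test_that("p_star composes per-occasion probabilities", {
  expect_equal(p_star(c(0.5, 0.5)), 0.75)
  expect_equal(p_star(c(0.2, 1, 0.3)), 1)
  expect_equal(p_star(rep(0.35, 10)), 1 - 0.65^10)
})

test_that("conditional log-likelihood matches hand computations", {
  # one individual, one occasion, detected: conditioning cancels
  str1 <- list(model = "m0", plots = list(list(
    plot_id = "P", surveyors = "S1", m_obs = 1, n_t = 1,
    X = matrix(1, 1, 1)
  )))
  expect_equal(sessilecmr:::huggins_loglik(qlogis(0.5), str1), 0)

  # history (1, 0) at p = 0.5 each
  str2 <- list(model = "m0", plots = list(list(
    plot_id = "P", surveyors = c("S1", "S2"), m_obs = 1, n_t = c(1, 0),
    X = matrix(1, 2, 1)
  )))
  expect_equal(sessilecmr:::huggins_loglik(qlogis(0.5), str2),
               log(0.5) + log(0.5) - log(0.75))
})

test_that("conditional log-likelihood matches full-history enumeration", {
  set.seed(41)
  for (i in 1:20) {
    m <- rand_capture_matrix(15, 3, runif(3, 0.2, 0.8))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (!nrow(m)) next
    ds <- ds_from_matrix(m)
    str <- sessilecmr:::huggins_structure(ds, "mt")
    beta <- rnorm(3)
    expect_equal(
      sessilecmr:::huggins_loglik(beta, str),
      enum_loglik(m, plogis(beta)),
      tolerance = 1e-10
    )
  }
})

test_that("analytic gradient matches numeric differentiation", {
  set.seed(43)
  m <- rand_capture_matrix(25, 4, c(0.5, 0.3, 0.4, 0.2))
  m <- m[rowSums(m) > 0, , drop = FALSE]
  ds <- ds_from_matrix(m)
  for (model in c("m0", "mt", "experience")) {
    str <- sessilecmr:::huggins_structure(ds, model)
    k <- length(str$terms)
    beta <- rnorm(k, 0, 0.5)
    g_num <- vapply(seq_len(k), function(j) {
      h <- 1e-6
      bp <- bm <- beta
      bp[j] <- beta[j] + h
      bm[j] <- beta[j] - h
      (sessilecmr:::huggins_loglik(bp, str) -
         sessilecmr:::huggins_loglik(bm, str)) / (2 * h)
    }, numeric(1))
    expect_equal(sessilecmr:::huggins_grad(beta, str), g_num,
                 tolerance = 1e-5)
  }
})

test_that("two-occasion time-dependent abundance equals Lincoln-Petersen", {
  set.seed(47)
  done <- 0
  while (done < 25) {
    m <- rand_capture_matrix(40, 2, runif(2, 0.35, 0.7))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    lp <- lp_parts(m)
    if (lp$m2 < 3 || lp$m2 >= min(lp$n1, lp$n2)) next
    fit <- fit_huggins(ds_from_matrix(m), "mt")
    ab <- abundance(fit)
    expect_equal(ab$n_hat, lp$n1 * lp$n2 / lp$m2, tolerance = 1e-6)
    # fitted occasion probabilities at their closed forms
    pr <- detection_probs(fit)
    expect_equal(pr$estimate, c(lp$m2 / lp$n2, lp$m2 / lp$n1),
                 tolerance = 1e-6)
    done <- done + 1
  }
})

test_that("symmetric two-occasion constant-p abundance equals Lincoln-Petersen", {
  # n1 = n2 = 20, m2 = 10 -> 40
  m <- rbind(
    matrix(rep(c(1, 1), 10), ncol = 2, byrow = TRUE),
    matrix(rep(c(1, 0), 10), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 1), 10), ncol = 2, byrow = TRUE)
  )
  fit <- fit_huggins(ds_from_matrix(m), "m0")
  expect_true(fit$converged)
  expect_equal(abundance(fit)$n_hat, 40, tolerance = 1e-6)
})

test_that("constraining all occasion probabilities equal reproduces the constant fit", {
  set.seed(53)
  m <- rand_capture_matrix(30, 5, 0.4)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  ds <- ds_from_matrix(m)
  f0 <- fit_huggins(ds, "m0")
  str_t <- sessilecmr:::huggins_structure(ds, "mt")
  ll_t <- sessilecmr:::huggins_loglik(rep(f0$beta$estimate, 5), str_t)
  expect_equal(ll_t, f0$loglik, tolerance = 1e-8)
})

test_that("complete detection drives estimates to the boundary with N = M", {
  m <- matrix(1L, 10, 3)
  fit <- fit_huggins(ds_from_matrix(m), "mt")
  expect_true(fit$boundary)
  ab <- abundance(fit)
  expect_equal(ab$n_hat, 10, tolerance = 1e-4)
  expect_equal(ab$lcl, 10)
  expect_equal(ab$ucl, 10)
})

test_that("likelihood is invariant to permuting individuals", {
  set.seed(59)
  m <- rand_capture_matrix(20, 4, 0.4)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  f1 <- fit_huggins(ds_from_matrix(m), "mt")
  f2 <- fit_huggins(ds_from_matrix(m[sample(nrow(m)), ]), "mt")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
  expect_equal(abundance(f1)$n_hat, abundance(f2)$n_hat,
               tolerance = 1e-8)
})

test_that("experience covariate collapses to equal probabilities when the effect is zero", {
  m <- rbind(c(1, 0, 1, 0), c(0, 1, 1, 1), c(1, 1, 0, 0))
  ds <- ds_from_matrix(m, experience = c("expert", "novice",
                                         "expert", "novice"))
  fit <- fit_huggins(ds, "experience")
  fit$beta$estimate <- c(qlogis(0.3), 0)
  pr <- detection_probs(fit)
  expect_equal(pr$estimate[1], pr$estimate[2])
  expect_equal(pr$estimate[1], 0.3)
})

test_that("experience-structured simulation recovers both group rates within the CI", {
  hits <- matrix(NA, 60, 2)
  truth <- c(expert = 0.35, novice = 0.16)
  for (r in seq_len(nrow(hits))) {
    ds <- filter_closure(
      simulate_population(sim_config(seed = 7000 + r))
    )
    pr <- experience_probs(fit_huggins(ds, "experience"))
    hits[r, 1] <- pr$lcl[1] <= truth[1] && truth[1] <= pr$ucl[1]
    hits[r, 2] <- pr$lcl[2] <= truth[2] && truth[2] <= pr$ucl[2]
  }
  expect_gte(mean(hits[, 1]), 0.9)
  expect_gte(mean(hits[, 2]), 0.9)
})

test_that("tidy and glance expose the fit in broom style", {
  set.seed(61)
  m <- rand_capture_matrix(25, 4, 0.4)
  ds <- ds_from_matrix(m)
  fit <- fit_huggins(ds, "mt")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error") %in% names(td)))
  expect_equal(nrow(td), 4)
  tp <- tidy(fit, type = "probability")
  expect_true(all(tp$estimate > 0 & tp$estimate < 1))
  expect_true(all(tp$lcl <= tp$estimate & tp$estimate <= tp$ucl))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
})
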