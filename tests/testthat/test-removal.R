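test_that("depletion pairs enumerate new and previously detected individuals", {
  # occasion 1 detects {a,b}, occasion 2 detects {b,c}
  m <- rbind(a = c(1, 0), b = c(1, 1), c = c(0, 1))
  pr <- depletion_pairs(m)
  expect_equal(pr$prev_detected, c(0, 2))
  expect_equal(pr$new_detections, c(2, 1))

  # identical occasions detecting the same set
  m2 <- matrix(1L, 4, 3)
  pr2 <- depletion_pairs(m2)
  expect_equal(pr2$prev_detected, c(0, 4, 4))
  expect_equal(pr2$new_detections, c(4, 0, 0))

  # reversing the order swaps roles
  pr3 <- depletion_pairs(m, order = c(2, 1))
  expect_equal(pr3$new_detections, c(2, 1))
})

test_that("new detections decline geometrically under constant detection", {
  # N=100, p=0.5: E[y_t] = 100 * 0.5^t, E[x_t] = 100 * (1 - 0.5^(t-1))
  set.seed(31)
  t_n <- 4
  acc_y <- acc_x <- numeric(t_n)
  n_rep <- 500
  for (r in seq_len(n_rep)) {
    m <- rand_capture_matrix(100, t_n, 0.5)
    pr <- depletion_pairs(m)
    acc_y <- acc_y + pr$new_detections
    acc_x <- acc_x + pr$prev_detected
  }
  ey <- 100 * 0.5 * 0.5^(0:(t_n - 1))
  ex <- 100 * (1 - 0.5^(0:(t_n - 1)))
  expect_true(all(abs(acc_y / n_rep - ey) < 1))
  expect_true(all(abs(acc_x / n_rep - ex) < 1.5))
})

test_that("the depletion regression recovers exactly collinear data and flags degeneracy", {
  pairs <- list(prev_detected = c(0, 50, 75, 87.5),
                new_detections = c(50, 25, 12.5, 6.25))
  f <- leslie_fit(pairs)
  expect_false(f$degenerate)
  expect_equal(f$slope, -0.5, tolerance = 1e-12)
  expect_equal(f$x_intercept, 100, tolerance = 1e-9)

  # non-negative slope: no estimate
  up <- leslie_fit(list(prev_detected = c(0, 5, 10),
                        new_detections = c(1, 3, 5)))
  expect_true(up$degenerate)
  expect_true(is.na(up$x_intercept))

  # all x identical: no slope
  flat <- leslie_fit(list(prev_detected = c(3, 3, 3),
                          new_detections = c(1, 2, 5)))
  expect_true(flat$degenerate)
})

test_that("least-squares fit agrees with the normal-equation oracle", {
  set.seed(7)
  for (i in 1:100) {
    x <- c(0, cumsum(abs(rnorm(5, 5))))
    y <- rnorm(6, 20 - 0.4 * x, 2)
    f <- leslie_fit(list(prev_detected = x, new_detections = y))
    o <- ols_oracle(x, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    if (o$slope < 0) {
      expect_equal(f$x_intercept, -o$intercept / o$slope,
                   tolerance = 1e-10)
    }
  }
})

test_that("a single permutation of two occasions matches the two-point closed form", {
  set.seed(13)
  checked_lp <- 0
  for (i in 1:50) {
    m <- rand_capture_matrix(40, 2, runif(1, 0.3, 0.7))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    lp <- lp_parts(m)
    pr <- depletion_pairs(m)
    f <- leslie_fit(pr)
    if (!f$degenerate) {
      expect_equal(f$x_intercept,
                   lp$n1^2 / (lp$n1 + lp$m2 - lp$n2),
                   tolerance = 1e-9)
    }
    # symmetric catches: the two-point line lands on Lincoln-Petersen
    if (!f$degenerate && lp$n1 == lp$n2 && lp$m2 > 0) {
      expect_equal(f$x_intercept, lp$n1 * lp$n2 / lp$m2,
                   tolerance = 1e-9)
      checked_lp <- checked_lp + 1
    }
  }
  expect_gt(checked_lp, 0)
})

test_that("perfect detection in one occasion pins every permutation at MLN", {
  m <- cbind(rep(1L, 12), matrix(0L, 12, 3))
  ds <- ds_from_matrix(m)
  est <- permutation_removal(ds, n_perm = 500, seed = 8)
  expect_equal(est$estimate, 12)
  expect_equal(est$lcl, 12)
  expect_equal(est$ucl, 12)
  # orders placing the perfect occasion last have identical x (all 0)
  expect_gt(est$n_degenerate, 0)
})

test_that("the permutation estimate is invariant to individual row order", {
  set.seed(17)
  m <- rand_capture_matrix(30, 6, 0.4)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  ds1 <- ds_from_matrix(m)
  ds2 <- ds_from_matrix(m[sample(nrow(m)), ])
  e1 <- permutation_removal(ds1, n_perm = 300, seed = 5)
  e2 <- permutation_removal(ds2, n_perm = 300, seed = 5)
  expect_equal(e1$estimate, e2$estimate)
  expect_equal(e1$lcl, e2$lcl)
  expect_equal(e1$ucl, e2$ucl)
})

test_that("an occasion detecting nothing new does not inflate the estimate", {
  set.seed(23)
  m <- rand_capture_matrix(30, 6, 0.4)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  base <- permutation_removal(ds_from_matrix(m), n_perm = 2000,
                              seed = 9)$estimate
  ext <- permutation_removal(ds_from_matrix(cbind(m, 0L)),
                             n_perm = 2000, seed = 9)$estimate
  expect_lte(ext, base * 1.05)
})

test_that("an all-degenerate plot yields an explicit failure row", {
  # two disjoint, equal-sized catches: slope 0 in either order
  m <- rbind(
    matrix(rep(c(1L, 0L), 3), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 1L), 3), ncol = 2, byrow = TRUE)
  )
  est <- permutation_removal(ds_from_matrix(m), n_perm = 100, seed = 2)
  expect_true(is.na(est$estimate))
  expect_equal(est$n_degenerate, 100)
})
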