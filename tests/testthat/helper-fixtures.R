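# Build a single-plot detection_data from a binary matrix.
# Rows with no detections are dropped (that is what a field study sees);
# `experience` recycles over the columns.
ds_from_matrix <- function(m, experience = "expert", plot_id = "P",
                           area = NA_real_) {
  n_occ <- ncol(m)
  sv <- paste0("S", seq_len(n_occ))
  experience <- rep_len(experience, n_occ)
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  ids <- sprintf("h%03d", which(keep))
  individuals <- tibble::tibble(hibernaculum_id = ids, plot_id = plot_id)
  detections <- tibble::tibble(
    plot_id = plot_id,
    hibernaculum_id = rep(ids, times = n_occ),
    surveyor_id = rep(sv, each = length(ids)),
    detected = as.integer(m)
  )
  detection_data(
    individuals,
    tibble::tibble(surveyor_id = sv, experience = experience),
    tibble::tibble(plot_id = plot_id, occasion = seq_len(n_occ),
                   surveyor_id = sv),
    detections,
    tibble::tibble(plot_id = plot_id, area = area)
  )
}

rand_capture_matrix <- function(n, n_occ, p) {
  matrix(rbinom(n * n_occ, 1, rep_len(p, n_occ)[rep(
    seq_len(n_occ), each = n
  )]), n, n_occ)
}

# conditional log-likelihood by explicit enumeration of all 2^T
# histories: log P(history_i) - log P(detected at least once)
enum_loglik <- function(m, p) {
  n_occ <- ncol(m)
  hists <- as.matrix(expand.grid(rep(list(0:1), n_occ)))
  prob <- apply(hists, 1, function(h) {
    prod(ifelse(h == 1, p, 1 - p))
  })
  p_detected <- sum(prob[rowSums(hists) > 0])
  sum(apply(m, 1, function(h) {
    log(prod(ifelse(h == 1, p, 1 - p))) - log(p_detected)
  }))
}

# OLS by the normal equations, no lm machinery
ols_oracle <- function(x, y) {
  xtx <- rbind(c(length(x), sum(x)), c(sum(x), sum(x^2)))
  beta <- solve(xtx, c(sum(y), sum(x * y)))
  list(intercept = beta[1], slope = beta[2])
}

# Lincoln-Petersen ingredients of a 2-occasion matrix
lp_parts <- function(m) {
  list(n1 = sum(m[, 1]), n2 = sum(m[, 2]), m2 = sum(m[, 1] & m[, 2]))
}
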