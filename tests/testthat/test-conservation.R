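# Draw per-gene divergence Q from the hierarchical model:
# W ~ Gamma(alpha, rate beta); Q | W ~ Gamma(nu/2, rate W).
draw_q <- function(n, alpha, beta, nu, seed) {
  set.seed(seed)
  W <- rgamma(n, shape = alpha, rate = beta)
  list(W = W, Q = rgamma(n, shape = nu / 2, rate = W))
}

test_that("correlation matrix inversion is exact and ridge-guarded", {
  set.seed(61)
  lg <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("A", "B", "C")))
  cm <- corr_mat_inv(lg)
  expect_equal(cm$R %*% cm$Rinv, diag(3), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_false(cm$ridged)

  # closed-form 2x2 check of the inversion path on a constructed R:
  # rho = 0.5 gives Rinv = (1/0.75) * [[1, -0.5], [-0.5, 1]]
  p <- correlated_pair(0.5, 100)
  lg2 <- cbind(A = p$x, B = p$y, C = rnorm(100))
  cm2 <- corr_mat_inv(lg2)
  sub <- solve(cm2$R[c("A", "B"), c("A", "B")])
  expect_equal(sub, matrix(c(1, -0.5, -0.5, 1) / 0.75, 2, 2,
                           dimnames = dimnames(sub)), tolerance = 1e-9)

  # duplicated organism column triggers the ridge with a warning
  lg3 <- cbind(A = p$x, B = p$x, C = rnorm(100))
  expect_warning(cm3 <- corr_mat_inv(lg3), "ridge")
  expect_true(cm3$ridged)
  expect_true(all(is.finite(cm3$Rinv)))

  expect_error(corr_mat_inv(lg[1:10, ]), "50 genes")
})

test_that("the quadratic form Q centers genes and uses the inverse matrix", {
  Rinv <- diag(3)
  dimnames(Rinv) <- list(c("A", "B", "C"), c("A", "B", "C"))
  lg <- rbind(g1 = c(A = 2, B = 2, C = 2),     # constant -> Q = 0
              g2 = c(A = 1, B = -1, C = 0),    # already centered -> 2
              g3 = c(A = 11, B = 9, C = 10))   # shift-invariant -> 2
  Q <- est_q(lg, Rinv)
  expect_equal(Q, c(0, 2, 2), ignore_attr = TRUE)
  expect_equal(attr(Q, "nu"), 2)

  # invariance under adding a gene-wise constant
  set.seed(62)
  lg2 <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(est_q(lg2 + 100, Rinv), est_q(lg2, Rinv))
})

test_that("gamma prior recovery, equivariance and failure modes", {
  d <- draw_q(4000, alpha = 2, beta = 4, nu = 10, seed = 63)
  fit <- fit_gamma_prior(d$Q, nu = 10)
  expect_gt(fit$alpha, 1.6); expect_lt(fit$alpha, 2.4)
  expect_gt(fit$beta, 3.2); expect_lt(fit$beta, 4.8)

  # doubling Q doubles beta and leaves alpha unchanged
  fit2 <- fit_gamma_prior(2 * d$Q, nu = 10)
  expect_equal(fit2$alpha, fit$alpha, tolerance = 1e-3)
  expect_equal(fit2$beta, 2 * fit$beta, tolerance = 1e-3)

  expect_error(fit_gamma_prior(rep(1.7, 500), nu = 10), "degenerate")
  expect_error(fit_gamma_prior(d$Q[1:50], nu = 10), "200 genes")
})

test_that("posterior conservation is conjugate and monotone", {
  expect_equal(posterior_w(6, alpha = 2, beta = 4, nu = 10), 0.7)
  expect_equal(posterior_w(0, alpha = 2, beta = 4, nu = 10), 7 / 4)
  q <- seq(0, 50, by = 0.5)
  w <- posterior_w(q, 2, 4, 10)
  expect_true(all(diff(w) < 0))

  # a point-mass-like prior (alpha -> Inf, alpha/beta fixed) pins the
  # posterior to the prior mean regardless of the data
  for (s in 10^(2:6)) {
    w <- posterior_w(c(0.1, 5, 50), alpha = 2 * s, beta = 4 * s, nu = 10)
    expect_equal(w, rep(0.5, 3), tolerance = 10 / s)
  }
})

test_that("HSG/LSG calling takes the empirical 5% tails", {
  W <- setNames(seq(0.01, 1, length.out = 100), paste0("g", 1:100))
  calls <- call_hsg_lsg(W, q = 0.05)
  expect_length(calls$hsg, 5)
  expect_length(calls$lsg, 5)
  expect_true(all(W[calls$hsg] > calls$thresholds["upper"]))
  expect_true(all(W[calls$lsg] < calls$thresholds["lower"]))

  expect_warning(c2 <- call_hsg_lsg(setNames(rep(1, 30), 1:30)), "equal")
  expect_length(c2$hsg, 0)

  # a bimodal mixture: the extreme components are recovered
  set.seed(64)
  lo <- abs(rnorm(50, 0.05, 0.01)); hi <- rnorm(50, 2, 0.05)
  W2 <- setNames(c(lo, runif(900, 0.3, 0.8), hi), paste0("g", 1:1000))
  c3 <- call_hsg_lsg(W2)
  expect_gte(mean(as.integer(sub("g", "", c3$lsg)) %in% 1:50), 0.95)
  expect_gte(mean(as.integer(sub("g", "", c3$hsg)) %in% 951:1000), 0.95)
})

test_that("end-to-end conservation recovery orders genes correctly", {
  # generate tip deviations from exactly the model the estimator inverts
  cfg <- sim_config(n_genes = 3000)
  sim <- simulate_expression(cfg, seed = 65)
  lg <- sim$dev  # noiseless log2 deviations
  cf <- estimate_conservation(lg)
  expect_equal(cf$nu, 10)
  expect_gte(cor(sim$W, cf$W, method = "spearman"), 0.5)
  expect_length(cf$calls$hsg, 150)
})

test_that("pathway summaries partition and rank conservation", {
  W <- setNames(c(rep(0.9, 15), rep(0.2, 15), rep(0.5, 5)),
                paste0("g", 1:35))
  pw <- list(high = paste0("g", 1:15), low = paste0("g", 16:30),
             tiny = paste0("g", 31:35))
  s <- pathway_w_distributions(W, pw, min_size = 11)
  expect_equal(s$pathway, c("high", "low"))
  expect_equal(s$rank, c(1, 2))
  expect_equal(attr(s, "skipped"), "tiny")
  # one pathway holding all genes reproduces the overall mean
  s2 <- pathway_w_distributions(W, list(all = names(W)), min_size = 11)
  expect_equal(s2$mean_w, mean(W))
})

test_that("relative-rate test: null behavior, direction and skipping", {
  set.seed(66)
  n <- 200
  zO <- rnorm(n); z1 <- zO + rnorm(n); z2 <- zO + rnorm(n)
  lg <- cbind(org1 = z1, org2 = z2, out = zO)
  rownames(lg) <- paste0("g", 1:n)
  # identical lineages: delta exactly 0, p = 1
  lg_eq <- cbind(org1 = z1, org2 = z1, out = zO)
  rownames(lg_eq) <- rownames(lg)
  rt0 <- relative_rate_test(lg_eq, rownames(lg), "org1", "org2", "out",
                            B = 500, seed = 1)
  expect_equal(rt0$delta, 0)
  expect_equal(rt0$p.value, 1)

  # a strong contrast is detected with the right direction
  z1f <- zO + rnorm(n, 0, 2)  # 4x the variance of org2
  lgf <- cbind(org1 = z1f, org2 = z2, out = zO)
  rownames(lgf) <- rownames(lg)
  rtf <- relative_rate_test(lgf, rownames(lg), "org1", "org2", "out",
                            B = 2000, seed = 2)
  expect_lt(rtf$p.value, 0.05)
  expect_equal(rtf$direction, "org1 faster")

  # determinism under the seed
  rtf2 <- relative_rate_test(lgf, rownames(lg), "org1", "org2", "out",
                             B = 2000, seed = 2)
  expect_equal(rtf, rtf2)

  # pathway wrapper skips undersized sets with a reason
  pw <- list(big = paste0("g", 1:60), small = paste0("g", 1:5))
  res <- pathway_rate_tests(lgf, pw, "org1", "org2", "out",
                            rate_test_config(B = 500), seed = 3)
  expect_equal(res$pathway, "big")
  expect_equal(attr(res, "skipped")$pathway, "small")
  expect_match(attr(res, "skipped")$reason, "< 11")
})
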