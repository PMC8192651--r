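# direct evaluation of the admixture log-likelihood, independent of the
# EM implementation
admix_loglik <- function(G, Q, P) {
  f <- Q %*% P
  f <- pmin(pmax(f, 1e-9), 1 - 1e-9)
  d <- G$dosage
  sum((d * log(f) + (2 - d) * log(1 - f))[!is.na(d)])
}

test_that("K = 1 reduces to the closed-form binomial fit", {
  pop <- small_pop()
  fit <- admixture_em(pop$G, K = 1, seed = 3, max_iter = 50, tol = 1e-8)
  expect_true(all(fit$Q == 1))
  d <- pop$G$dosage
  phat <- colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
  phat <- pmin(pmax(phat, 1e-6), 1 - 1e-6)
  expect_equal(unname(drop(fit$P)), unname(phat), tolerance = 1e-8)
  ll_closed <- sum((d * log(rep(phat, each = nrow(d))) +
                      (2 - d) * log(rep(1 - phat, each = nrow(d))))[!is.na(d)])
  expect_equal(fit$loglik, ll_closed, tolerance = 1e-6 * abs(ll_closed))
})

test_that("two fixed, disjoint populations are recovered to 0/1 membership", {
  d <- rbind(matrix(0L, 20, 200), matrix(2L, 20, 200))
  G <- toy_gm(d)
  fit <- admixture_em(G, K = 2, seed = 5, max_iter = 300, tol = 1e-8)
  truth <- rbind(matrix(c(1, 0), 20, 2, byrow = TRUE),
                 matrix(c(0, 1), 20, 2, byrow = TRUE))
  al <- align_runs(list(truth, fit$Q), reference_index = 1)
  expect_lt(max(abs(al$aligned[[2]] - truth)), 0.01)
})

test_that("the EM trace never decreases and the likelihood is label-invariant", {
  pop <- small_pop()
  for (K in c(2, 3)) {
    fit <- admixture_em(pop$G, K = K, seed = 11 + K, max_iter = 80, tol = 0)
    expect_true(all(diff(fit$loglik_trace) > -1e-6))
    perm <- sample(K)
    expect_equal(admix_loglik(pop$G, fit$Q[, perm], fit$P[perm, , drop = FALSE]),
                 admix_loglik(pop$G, fit$Q, fit$P), tolerance = 1e-10)
  }
})

test_that("alignment undoes column swaps and matches brute force at K = 2", {
  set.seed(61)
  Q <- matrix(rgamma(30 * 4, 0.5), 30, 4)
  Q <- Q / rowSums(Q)
  swapped <- Q[, c(3, 1, 4, 2)]
  al <- align_runs(list(Q, swapped))
  expect_equal(al$aligned[[2]], Q, ignore_attr = TRUE)
  expect_equal(sum((al$aligned[[2]] - Q)^2), 0)

  Q2 <- matrix(rgamma(25 * 2, 0.5), 25, 2)
  Q2 <- Q2 / rowSums(Q2)
  for (rep in 1:5) {
    R <- matrix(rgamma(25 * 2, 0.5), 25, 2)
    R <- R / rowSums(R)
    got <- align_runs(list(Q2, R))$permutations[[2]]
    briefs <- c(sum((R - Q2)^2), sum((R[, 2:1] - Q2)^2))
    expect_equal(got, list(1:2, 2:1)[[which.min(briefs)]])
  }
})

test_that("noisy replicate runs align to within the noise scale and average cleanly", {
  set.seed(67)
  Q <- matrix(rgamma(40 * 3, 0.4), 40, 3)
  Q <- Q / rowSums(Q)
  runs <- lapply(1:5, function(r) {
    R <- pmax(Q[, sample(3)] + matrix(rnorm(120, sd = 0.01), 40, 3), 1e-6)
    R / rowSums(R)
  })
  al <- align_runs(c(list(Q), runs))$aligned
  devs <- vapply(al[-1], function(A) mean(abs(A - Q)), numeric(1))
  expect_lt(mean(devs), 0.02)

  avg <- average_q(al)
  expect_true(all(abs(rowSums(avg) - 1) < 1e-9))
  expect_equal(average_q(list(Q, Q)), Q)
  expect_equal(average_q(list(matrix(c(1, 0), 1), matrix(c(0.8, 0.2), 1))),
               matrix(c(0.9, 0.1), 1))
})

test_that("Evanno table matches the hand-computed delta K", {
  ll <- list(`2` = c(-100, -102), `3` = c(-90, -92), `4` = c(-88, -90))
  ev <- evanno(ll)
  expect_equal(ev$Lp[ev$K == 3], 10)
  expect_equal(ev$Lpp_abs[ev$K == 3], 8)
  expect_equal(ev$deltaK[ev$K == 3], 8 / sqrt(2))
  expect_true(is.na(ev$deltaK[ev$K == 2]))  # boundary
  expect_true(is.na(ev$deltaK[ev$K == 4]))  # boundary
  expect_equal(best_k(ev), 3L)

  # exactly linear mean likelihood: zero curvature
  lin <- list(`2` = c(-10, -12), `3` = c(-8, -10), `4` = c(-6, -8))
  expect_equal(evanno(lin)$deltaK[2], 0)

  # zero replicate spread: flagged undefined, not infinite
  degen <- list(`2` = c(-10, -10), `3` = c(-5, -5), `4` = c(-4, -4))
  expect_true(all(is.na(evanno(degen)$deltaK)))

  expect_error(evanno(list(`2` = c(-1, -2), `4` = c(-1, -2))), "consecutive")
})

test_that("subpopulation assignment follows the threshold and group rules", {
  Q <- rbind(c(0.62, 0.28, 0.10),
             c(0.50, 0.20, 0.30),
             c(1.00, 0.00, 0.00),
             c(0.40, 0.35, 0.25))
  a1 <- assign_subpops(Q, threshold = 0.6)
  expect_equal(a1$label[1], "pop1")
  expect_equal(a1$label[2], "admix")
  expect_equal(a1$label[3], "pop1")

  groups <- c(`1` = "Ind", `2` = "Ind", `3` = "Jap")
  a2 <- assign_subpops(Q, threshold = 0.65, groups = groups,
                       group_threshold = 0.65)
  # row 2: max 0.5 < 0.65 but Ind sum 0.7 >= 0.65
  expect_equal(a2$label[2], "Ind-adm")
  expect_equal(a2$label[4], "Ind-adm")  # sum 0.75
  expect_equal(a2$label[3], "pop1")

  # total and deterministic: one label each, ties to the lowest column
  tie <- matrix(0.5, 2, 2)
  at <- assign_subpops(tie, threshold = 0.5)
  expect_equal(at$label, c("pop1", "pop1"))
  expect_error(assign_subpops(Q, threshold = 0.6, groups = c(`9` = "X")),
               "unknown")
})

test_that("PCA matches the dense covariance eigendecomposition and duplicates coincide", {
  set.seed(71)
  d <- matrix(sample(0:2, 20 * 100, replace = TRUE), 20, 100)
  d[1, ] <- d[2, ]                   # exact duplicate individuals
  G <- toy_gm(d)
  emb <- snp_pca(G, n_comp = 5)
  expect_equal(emb$scores[1, ], emb$scores[2, ], tolerance = 1e-10)

  # oracle: eigendecomposition of the explicit n x n covariance
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  X <- sweep(d[, poly], 2, 2 * p[poly])
  X <- sweep(X, 2, sqrt(2 * p[poly] * (1 - p[poly])), "/")
  C <- tcrossprod(X) / (nrow(X) - 1)
  eg <- eigen(C, symmetric = TRUE)
  oracle <- eg$vectors[, 1:5] %*% diag(sqrt(eg$values[1:5] * (nrow(X) - 1)))
  expect_equal(abs(unname(emb$scores)), abs(oracle), tolerance = 1e-8)
  expect_equal(emb$eigenvalues, eg$values[1:5], tolerance = 1e-8)
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))
})

test_that("top PCA scores separate simulated populations", {
  spec <- population_spec(K = 3, n = 90, L = 1000, fst = 0.2, alpha = 0.05,
                          F = 0.88, missing_rate = 0.02, seed = 73)
  pop <- sim_population(spec)
  lab <- apply(pop$Q, 1, which.max)
  pure <- apply(pop$Q, 1, max) > 0.9
  emb <- snp_pca(pop$G, n_comp = 2)
  expect_gt(mean_silhouette(emb$scores[pure, ], lab[pure]), 0.5)
})

test_that("classical scaling recovers planted configurations and the PCA dual", {
  set.seed(79)
  pts <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(dist(pts))
  emb <- pco(D, n_comp = 2)
  expect_equal(as.matrix(dist(emb$scores)), D, tolerance = 1e-8,
               ignore_attr = TRUE)

  zero <- matrix(0, 4, 4)
  expect_true(all(pco(zero, n_comp = 2)$scores == 0))
  expect_error(pco(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")

  # duality with unscaled PCA on complete data
  d <- matrix(sample(0:2, 30 * 80, replace = TRUE), 30, 80)
  G <- toy_gm(d)
  pc <- snp_pca(G, n_comp = 3, scale = FALSE)
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  Dg <- as.matrix(dist(sweep(d[, poly], 2, 2 * p[poly])))
  pcod <- pco(Dg, n_comp = 3)
  expect_equal(as.matrix(dist(pcod$scores)), as.matrix(dist(pc$scores)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("consensus averaging picks the dominant replicate cluster", {
  pop <- small_pop()
  runs <- admixture_runs(pop$G, K = 3, replicates = 4, seed = 81,
                         max_iter = 120, tol = 1e-4)
  cons <- consensus_q(runs)
  expect_true(all(abs(rowSums(cons$Q) - 1) < 1e-9))
  expect_gte(length(cons$members), 1)
  al <- align_runs(list(pop$Q, cons$Q))
  expect_lt(mean(abs(al$aligned[[2]] - pop$Q)), 0.1)
})
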