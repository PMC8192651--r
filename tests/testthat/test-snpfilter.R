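test_that("site statistics match hand counts", {
  G <- toy_gm(cbind(c(0, 1, 1, 2),      # 4/8 ALT alleles, 2/4 hets
                    c(0, 0, 0, NA),     # monomorphic, one missing
                    c(NA, NA, NA, NA))) # all missing
  st <- site_stats(G)
  expect_equal(st$p_alt[1], 0.5)
  expect_equal(st$hobs[1], 0.5)
  expect_equal(st$hexp[1], 0.5)
  expect_equal(st$ratio[1], 1.0)
  expect_equal(st$maf[1], 0.5)

  expect_equal(st$hexp[2], 0)
  expect_true(is.na(st$ratio[2]))
  expect_equal(st$missingness[2], 0.25)

  expect_true(is.na(st$p_alt[3]))
  expect_equal(st$missingness[3], 1)
})

test_that("F is the median heterozygosity deficit over qualifying sites", {
  st <- data.frame(
    n_called = 100, p_alt = c(0.5, 0.3, 0.4),
    maf = c(0.5, 0.3, 0.4),
    hobs = c(0.1, 0.05, 0.2), hexp = c(0.5, 0.42, 0.48),
    ratio = c(0.1, 0.05, 0.2) / c(0.5, 0.42, 0.48),
    missingness = 0
  )
  est <- estimate_inbreeding(st, maf_min = 0.05, factor = 5)
  expect_equal(est$F, 0.8)           # median of {0.800, 0.881, 0.583}
  expect_equal(est$cutoff, 1.0)
  expect_equal(est$n_sites_used, 3L)
})

test_that("a fully homozygous panel estimates F = 1 with cutoff 0, and het sites are then removed", {
  G <- toy_gm(cbind(c(0, 0, 2, 2), c(2, 2, 0, 0), c(0, 2, 0, 2)))
  est <- estimate_inbreeding(site_stats(G))
  expect_equal(est$F, 1)
  expect_equal(est$cutoff, 0)

  G2 <- toy_gm(cbind(c(0, 0, 2, 2), c(0, 1, 0, 2)))
  out <- het_excess_filter(G2, est)
  expect_equal(n_sites(out$G), 1)    # any heterozygote exceeds cutoff 0

  mono <- toy_gm(cbind(c(0, 0, 0, 0), c(0, 1, 1, 2)))
  out2 <- het_excess_filter(mono, inbreeding_estimate(0.9))
  # monomorphic site (undefined ratio) is retained by this filter
  expect_equal(n_sites(out2$G), 1)
  expect_equal(out2$G$sites$pos, mono$sites$pos[1])
})

test_that("no qualifying site is an estimation error", {
  G <- toy_gm(cbind(c(0, 1, 1, 2)))  # ratio exactly 1, not < 1
  expect_error(estimate_inbreeding(site_stats(G)), "no qualifying site")
})

test_that("the cutoff removes planted all-heterozygous sites and spares honest ones", {
  spec <- population_spec(K = 1, n = 200, L = 2000, F = 0.88,
                          missing_rate = 0.02, seed = 31)
  pop <- sim_population(spec)
  d <- pop$G$dosage
  set.seed(32)
  planted <- sort(sample.int(ncol(d), 50))
  d[, planted] <- 1L                 # paralog-like artefacts: all het
  G <- toy_gm(d, pos = pop$G$sites$pos, chrom = pop$G$sites$chrom)
  st <- site_stats(G)
  est <- estimate_inbreeding(st)
  out <- het_excess_filter(G, est, stats = st)
  kept_idx <- which(!(!is.na(st$ratio) & st$ratio > est$cutoff))
  expect_gte(sum(!(planted %in% kept_idx)), 48)
  honest <- setdiff(seq_len(ncol(d)), planted)
  expect_lt(mean(!(honest %in% kept_idx)), 0.01)
})

test_that("hard filters apply MAF, missingness, MAC and QUAL in one pass", {
  G <- toy_gm(cbind(c(rep(0L, 9), 1L),          # mac 1 < 3
                    c(rep(0L, 7), rep(NA, 3)),  # 30% missing, monomorphic
                    c(rep(0L, 5), rep(2L, 5)),  # clean, maf 0.5
                    c(rep(1L, 2), rep(0L, 8))), # mac 2 < 3, low qual
              qual = c(60, 60, 60, 10))
  out <- hard_filters(G, min_maf = 0.01, max_missing = 0.2, min_mac = 3,
                      min_qual = 30)
  expect_equal(n_sites(out$G), 1)               # only the clean site survives
  expect_equal(out$G$sites$pos, G$sites$pos[3])
  rep_ <- out$report
  expect_equal(rep_$removed[rep_$filter == "mac"], 3L)   # sites 1, 2, 4
  expect_equal(rep_$removed[rep_$filter == "maf"], 1L)   # site 2 (maf 0)
  expect_equal(rep_$removed[rep_$filter == "missingness"], 1L)
  expect_equal(rep_$removed[rep_$filter == "qual"], 1L)

  # neutral thresholds are the identity
  id <- hard_filters(G, min_maf = 0, max_missing = 1, min_mac = 0,
                     min_qual = 0)
  expect_equal(n_sites(id$G), 4)
  expect_equal(sum(id$report$removed[1:4]), 0L)
})

test_that("LD pruning drops one of two identical sites and keeps independent ones", {
  set.seed(41)
  x <- sample(0:2, 40, replace = TRUE)
  G <- toy_gm(cbind(x, x, sample(0:2, 40, replace = TRUE)))
  kept <- ld_prune(G, window_snps = 3, step_snps = 1, r2_max = 0.8)
  expect_equal(length(kept), 2)
  expect_true(3 %in% kept)
  expect_equal(sum(c(1, 2) %in% kept), 1)

  spec <- population_spec(K = 1, n = 150, L = 60, F = 0.8,
                          missing_rate = 0, seed = 43)
  pop <- sim_population(spec)  # unlinked sites: pairwise r2 tiny
  kept2 <- ld_prune(pop$G, window_snps = 10, step_snps = 1, r2_max = 0.8)
  expect_equal(length(kept2), 60)
})

test_that("after pruning no within-window pair exceeds r2_max (brute force)", {
  set.seed(47)
  spec <- population_spec(K = 2, n = 80, L = 120, fst = 0.3,
                          missing_rate = 0.05, seed = 47)
  pop <- sim_population(spec)
  d <- pop$G$dosage
  # plant correlated blocks: copies of a site with sprinkled noise
  for (anchor in c(10, 50, 90)) {
    for (off in 1:3) {
      cp <- d[, anchor]
      flip <- sample.int(length(cp), 4)
      cp[flip] <- sample(0:2, 4, replace = TRUE)
      d[, anchor + off] <- cp
    }
  }
  G <- toy_gm(d, pos = pop$G$sites$pos, chrom = pop$G$sites$chrom)
  window <- 10; r2max <- 0.5
  kept <- ld_prune(G, window_snps = window, step_snps = 3, r2_max = r2max)

  X <- G$dosage
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  chroms <- G$sites$chrom
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    for (s in seq_len(max(1, length(idx) - window + 1))) {
      w <- idx[s:min(s + window - 1, length(idx))]
      act <- intersect(w, kept)
      if (length(act) < 2) next
      r2 <- suppressWarnings(stats::cor(X[, act]))^2
      diag(r2) <- 0
      r2[is.na(r2)] <- 0
      expect_lte(max(r2), r2max)
    }
  }
})

test_that("thinning keeps the greedy left-to-right spacing", {
  G <- toy_gm(matrix(rep(c(0L, 2L), 3), 2), pos = c(100L, 150L, 300L))
  thinned <- thin(G, 100)
  expect_equal(thinned$sites$pos, c(100L, 300L))
  expect_equal(n_sites(thin(G, 0)), 3)
  single <- toy_gm(matrix(c(0L, 2L), 2, 1), pos = 5000L)
  expect_equal(n_sites(thin(single, 1e6)), 1)
})

test_that("the estimator recovers the simulated F in a homogeneous panel", {
  spec <- population_spec(K = 1, n = 300, L = 5000, F = 0.7,
                          missing_rate = 0.02, seed = 51)
  pop <- sim_population(spec)
  est <- estimate_inbreeding(site_stats(pop$G))
  expect_equal(est$F, 0.7, tolerance = 0.03)
})

test_that("the filter cascade logs counts that add up", {
  pop <- small_pop()
  out <- filter_cascade(pop$G, min_qual = 30, min_mac = 3, max_missing = 0.5,
                        min_maf = 0.05, prune = list(c(20, 5, 0.8)),
                        thin_bp = 5000)
  rep_ <- out$report
  remaining <- rep_$remaining[!is.na(rep_$remaining)]
  expect_true(all(diff(remaining) <= 0))
  expect_equal(remaining[length(remaining)], n_sites(out$G))
  expect_s3_class(out$inbreeding, "inbreeding_estimate")
  # independent recount of the final thinning invariant
  pos_by_chrom <- split(out$G$sites$pos, out$G$sites$chrom)
  expect_true(all(unlist(lapply(pos_by_chrom, function(p)
    length(p) < 2 || all(diff(p) >= 5000)))))
})
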