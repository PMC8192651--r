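#' Trait eligibility screen for GWAS
#'
#' Computes per-trait sample size, mean, sd and coefficient of variation
#' (CV = 100 sd / mean on non-missing values) and flags a trait eligible
#' when 0 < CV < `cv_max` and at least `n_min` samples are scored.
#' Zero-variance or non-positive-mean traits are ineligible with a reason.
#'
#' @param traits a `trait_table` (sample_id column plus numeric traits)
#' @param cv_max CV ceiling in percent (default 56)
#' @param n_min minimum number of non-missing values (default 30)
#' @return data.frame: `trait`, `n`, `mean`, `sd`, `cv`, `eligible`,
#'   `reason`
#' @export
trait_qc <- function(traits, cv_max = 56, n_min = 30) {
  stopifnot(ncol(traits) >= 2)
  nm <- names(traits)[-1]
  rows <- lapply(nm, function(tr) {
    x <- traits[[tr]]
    x <- x[!is.na(x)]
    n <- length(x)
    mu <- if (n > 0) mean(x) else NA_real_
    sdv <- if (n > 1) stats::sd(x) else NA_real_
    cv <- if (!is.na(mu) && mu > 0 && !is.na(sdv)) 100 * sdv / mu else NA_real_
    reason <- ""
    eligible <- TRUE
    if (n < n_min) {
      eligible <- FALSE; reason <- "too few observations"
    } else if (is.na(sdv) || sdv == 0) {
      eligible <- FALSE; reason <- "zero variance"
    } else if (is.na(mu) || mu <= 0) {
      eligible <- FALSE; reason <- "non-positive mean"
    } else if (cv >= cv_max) {
      eligible <- FALSE; reason <- sprintf("CV %.1f >= %s", cv, format(cv_max))
    }
    data.frame(trait = tr, n = n, mean = mu, sd = sdv, cv = cv,
               eligible = eligible, reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' VanRaden genomic relationship (kinship) matrix
#'
#' Z is the dosage matrix centred per site by 2p (missing entries 0 after
#' centring); the kinship is Z Z' / (2 sum p(1-p)), symmetric by
#' construction with diagonal near 1 + F for a panel inbred at level F.
#'
#' @param G a `genotype_matrix`
#' @return n x n kinship matrix
#' @export
vanraden_kinship <- function(G) {
  X <- G$dosage
  storage.mode(X) <- "double"
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2) stop("need at least 2 polymorphic sites")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(X, 2, 2 * p)
  Z[is.na(Z)] <- 0
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(G$sample_ids, G$sample_ids)
  K
}

# REML for y = W a + g + e, g ~ N(0, sg2 K), e ~ N(0, se2 I), via the
# spectral decomposition K = U S U'. Returns variance components and the
# rotated quantities needed for per-SNP GLS.
reml_null <- function(y, W, K) {
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  s <- pmax(eg$values, 0)
  if (min(eg$values) < -1e-6) {
    s <- eg$values - min(eg$values) + 1e-6  # ridge for an indefinite K
  }
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  Ws <- crossprod(U, W)
  p <- ncol(W)
  # profile REML over delta = se2 / sg2 (weights 1 / (s + delta))
  neg_reml <- function(log_delta) {
    delta <- exp(log_delta)
    wts <- 1 / (s + delta)
    WtW <- crossprod(Ws, Ws * wts)
    a <- solve(WtW, crossprod(Ws, ys * wts))
    r <- ys - drop(Ws %*% a)
    rss <- sum(wts * r^2)
    sg2 <- rss / (n - p)
    0.5 * ((n - p) * log(sg2) + sum(log(s + delta)) +
             determinant(WtW, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- stats::optimize(neg_reml, lower = log(1e-6), upper = log(1e6))
  delta <- exp(opt$minimum)
  wts <- 1 / (s + delta)
  WtW <- crossprod(Ws, Ws * wts)
  a <- solve(WtW, crossprod(Ws, ys * wts))
  r <- ys - drop(Ws %*% a)
  sg2 <- sum(wts * r^2) / (n - p)
  list(U = U, s = s, delta = delta, sigma_g2 = sg2, sigma_e2 = sg2 * delta,
       loglik = -opt$objective, weights = wts, ys = ys, Ws = Ws)
}

#' Mixed-linear-model association scan
#'
#' Tests each SNP in the model y = W a + x b + g + e with a polygenic
#' random effect g ~ N(0, sigma_g^2 K) and residual e ~ N(0, sigma_e^2 I).
#' Variance components are estimated once on the null model (no SNP) by
#' REML via the eigendecomposition of K; each SNP is then tested by
#' generalized least squares on the rotated data with a two-sided Wald
#' t-test. Samples missing the trait are excluded listwise; per-SNP
#' missing dosages are mean-imputed. With `K = NULL` (identity kinship and
#' no random effect) the scan reduces exactly to ordinary least squares.
#'
#' @param G a `genotype_matrix`
#' @param trait named numeric vector (names = sample ids), or a
#'   `trait_table` together with `trait_name`
#' @param covariates optional n x K ancestry matrix; because its rows sum
#'   to 1 the first column is dropped to keep the design full rank next to
#'   the intercept
#' @param K kinship matrix (e.g. [vanraden_kinship()]); `NULL` for plain
#'   linear regression
#' @param trait_name column to use when `trait` is a `trait_table`
#' @return data.frame: `chrom`, `pos`, `effect`, `se`, `p`,
#'   `minus_log10_p`; variance components in attribute `vc`
#' @export
mlm_assoc <- function(G, trait, covariates = NULL, K = NULL,
                      trait_name = NULL) {
  if (inherits(trait, "trait_table") || is.data.frame(trait)) {
    if (is.null(trait_name)) {
      if (ncol(trait) != 2) stop("trait_name needed for multi-trait tables")
      trait_name <- names(trait)[2]
    }
    y <- trait[[trait_name]]
    names(y) <- trait$sample_id
    trait <- y
  }
  if (is.null(names(trait))) {
    if (length(trait) != n_samples(G)) stop("unnamed trait of wrong length")
    names(trait) <- G$sample_ids
  }
  idx <- which(G$sample_ids %in% names(trait)[!is.na(trait)])
  if (length(idx) < 30) stop("trait observed for fewer than 30 samples")
  y <- as.numeric(trait[G$sample_ids[idx]])
  X <- G$dosage[idx, , drop = FALSE]
  storage.mode(X) <- "double"
  all_missing <- colSums(!is.na(X)) == 0
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  nas <- which(is.na(X))
  if (length(nas) > 0) {
    X[nas] <- mu[((nas - 1) %/% nrow(X)) + 1]
  }
  n <- length(y)

  W <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    Qc <- as_q(covariates)
    if (nrow(Qc) == n_samples(G)) Qc <- Qc[idx, , drop = FALSE]
    if (nrow(Qc) != n) stop("covariate rows do not match samples")
    if (ncol(Qc) > 1) W <- cbind(W, Qc[, -1, drop = FALSE])
    qrW <- qr(W)
    if (qrW$rank < ncol(W)) stop("singular covariate matrix")
  }
  p <- ncol(W)

  if (is.null(K)) {
    vc <- NULL
    wts <- rep(1, n)
    ys <- y
    Ws <- W
    Xs <- X
  } else {
    Ksub <- K[G$sample_ids[idx], G$sample_ids[idx]]
    if (max(abs(Ksub - t(Ksub))) > 1e-10) stop("kinship matrix not symmetric")
    vc <- reml_null(y, W, Ksub)
    wts <- vc$weights
    ys <- vc$ys
    Ws <- vc$Ws
    Xs <- crossprod(vc$U, X)
  }
  sw <- sqrt(wts)
  yt <- ys * sw
  Wt <- Ws * sw
  Xt <- Xs * sw
  # project covariates out, then per-SNP simple regression on the residuals
  WtWi <- solve(crossprod(Wt))
  Py <- yt - Wt %*% (WtWi %*% crossprod(Wt, yt))
  PX <- Xt - Wt %*% (WtWi %*% crossprod(Wt, Xt))
  xx <- colSums(PX^2)
  xy <- drop(crossprod(PX, Py))
  df <- n - p - 1
  beta <- ifelse(xx > 1e-12, xy / xx, NA_real_)
  yy <- sum(Py^2)
  rss <- pmax(yy - ifelse(xx > 1e-12, xy^2 / xx, 0), 0)
  se <- ifelse(xx > 1e-12, sqrt(rss / df / xx), NA_real_)
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  pval[all_missing] <- NA_real_
  beta[all_missing] <- NA_real_
  res <- data.frame(
    chrom = G$sites$chrom, pos = G$sites$pos,
    effect = beta, se = se, p = pval,
    minus_log10_p = -log10(pval),
    stringsAsFactors = FALSE
  )
  attr(res, "vc") <- if (is.null(vc)) NULL else
    list(sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2, delta = vc$delta,
         loglik = vc$loglik)
  attr(res, "n") <- n
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Genomic-control inflation factor
#'
#' lambda = median chi-squared of the p-values over the null median; 1 for
#' a well-calibrated scan, > 1 under residual confounding.
#'
#' @param p vector of p-values
#' @return lambda
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Welch's two-sample t-test
#'
#' Two-sided Welch t-test (unequal variances, Satterthwaite degrees of
#' freedom) on non-missing values; thin wrapper over [stats::t.test()].
#'
#' @param x,y numeric vectors
#' @return list with `t`, `df`, `p`
#' @export
welch_ttest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    stop("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Pearson correlation on pairwise-complete observations
#'
#' @param x,y numeric vectors of equal length
#' @return correlation coefficient
#' @export
pearson <- function(x, y) {
  stats::cor(x, y, use = "pairwise.complete.obs", method = "pearson")
}
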