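#' Maximum-likelihood admixture inference by EM
#'
#' Fits the admixture model for unphased biallelic genotypes: each
#' individual i carries ancestry proportions q_ik (rows of Q summing to 1)
#' and each ancestral population k an ALT-allele frequency p_kl per site, so
#' the per-gamete ALT probability is f_il = sum_k q_ik p_kl and the
#' log-likelihood over called genotypes g_il is
#' sum \[ g log f + (2 - g) log(1 - f) \]. Q and P are updated by the
#' classical alternating EM (expected allele-origin counts), which never
#' decreases the likelihood. P is clamped to \[1e-6, 1 - 1e-6\]; missing
#' genotypes are skipped in every sum.
#'
#' @param G a `genotype_matrix`
#' @param K number of ancestral populations (>= 1, <= n samples)
#' @param seed integer seed for the random initialisation
#' @param max_iter iteration cap (default 2000)
#' @param tol stop when the log-likelihood gain drops below this
#' @return object of class `admixture_fit`: list with `Q` (n x K), `P`
#'   (K x L), `loglik_trace`, `loglik`, `converged`, `n_iter`, `K`, `seed`
#' @export
admixture_em <- function(G, K, seed = 1, max_iter = 2000, tol = 1e-6) {
  n <- n_samples(G); L <- n_sites(G)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of samples")
  d <- G$dosage
  storage.mode(d) <- "double"
  C <- !is.na(d)                      # called mask
  if (any(rowSums(C) == 0)) stop("sample with all genotypes missing")
  G0 <- d; G0[!C] <- 0
  G2 <- (2 - G0) * C                  # REF-allele counts, zeroed at missing
  ncall2 <- 2 * rowSums(C)

  set.seed(seed)
  Q <- matrix(stats::rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  # frequency init: perturbed overall allele frequency
  phat <- colSums(G0) / pmax(2 * colSums(C), 1)
  P <- matrix(rep(phat, each = K), K, L) +
    matrix(stats::runif(K * L, -0.1, 0.1), K, L)
  P <- pmin(pmax(P, 1e-6), 1 - 1e-6)

  fit <- .admixture_em_cpp(G0, G2, ncall2, Q, P, as.integer(max_iter), tol)
  Q <- fit$Q
  rownames(Q) <- G$sample_ids
  structure(list(Q = Q, P = fit$P, loglik_trace = as.numeric(fit$trace),
                 loglik = fit$trace[fit$n_iter + 1],
                 converged = fit$converged,
                 n_iter = fit$n_iter, K = K, seed = seed),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K = %d, logLik = %.2f after %d iterations (%s)\n",
              x$K, x$loglik, x$n_iter,
              if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}

#' Run replicate admixture fits from different starts
#'
#' @param G a `genotype_matrix`
#' @param K number of populations
#' @param replicates number of restarts
#' @param seed base seed; replicate r uses `seed + r - 1`
#' @param ... passed to [admixture_em()]
#' @return list of `admixture_fit`s
#' @export
admixture_runs <- function(G, K, replicates = 5, seed = 1, ...) {
  lapply(seq_len(replicates), function(r) {
    admixture_em(G, K, seed = seed + r - 1L, ...)
  })
}

# extract a Q matrix from a fit or pass a matrix through
as_q <- function(x) {
  if (inherits(x, "admixture_fit")) x$Q else as.matrix(x)
}

# all permutations of 1..k (k small)
permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1)))
  }
  dimnames(out) <- NULL
  out
}

#' Align replicate Q matrices to a reference (label switching)
#'
#' Admixture labels are arbitrary per run; this finds, for each run, the
#' column permutation minimising the Frobenius distance to the reference
#' run. Exhaustive search over all K! permutations for K <= 8; greedy
#' best-match on column correlations above that.
#'
#' @param runs list of Q matrices (or `admixture_fit`s), equal dimensions
#' @param reference_index which run is the reference (default 1)
#' @return list with `aligned` (list of Q matrices, reference unchanged)
#'   and `permutations` (list of integer vectors; `aligned = Q[, perm]`)
#' @export
align_runs <- function(runs, reference_index = 1) {
  qs <- lapply(runs, as_q)
  dims <- vapply(qs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all runs must share the same n and K")
  }
  K <- ncol(qs[[1]])
  ref <- qs[[reference_index]]
  perms <- vector("list", length(qs))
  aligned <- vector("list", length(qs))
  for (r in seq_along(qs)) {
    Q <- qs[[r]]
    if (r == reference_index) {
      perm <- seq_len(K)
    } else if (K <= 8) {
      all_p <- permutations_of(K)
      cost <- apply(all_p, 1, function(p) sum((Q[, p] - ref)^2))
      perm <- all_p[which.min(cost), ]
    } else {
      cors <- suppressWarnings(stats::cor(Q, ref))
      cors[is.na(cors)] <- -Inf
      perm <- integer(K)
      taken_src <- rep(FALSE, K)
      for (step in seq_len(K)) {
        cand <- cors
        cand[taken_src, ] <- -Inf
        cand[, perm[perm > 0]] <- -Inf
        best <- which(cand == max(cand), arr.ind = TRUE)[1, ]
        perm[best[2]] <- best[1]
        taken_src[best[1]] <- TRUE
      }
    }
    perms[[r]] <- perm
    aligned[[r]] <- Q[, perm, drop = FALSE]
  }
  list(aligned = aligned, permutations = perms)
}

#' Average aligned Q matrices
#'
#' Entrywise mean of label-aligned replicate runs; rows are renormalised to
#' sum exactly to 1.
#'
#' @param aligned list of aligned Q matrices
#' @return a Q matrix
#' @export
average_q <- function(aligned) {
  if (length(aligned) == 0) stop("no runs to average")
  qs <- lapply(aligned, as_q)
  dims <- vapply(qs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("aligned runs must share dimensions")
  }
  M <- Reduce(`+`, qs) / length(qs)
  M / rowSums(M)
}

#' Consensus Q matrix from replicate runs
#'
#' Operationalises "average the runs belonging to the largest cluster":
#' runs are aligned to the best-likelihood run, clustered by mean per-entry
#' distance (single linkage at `dist_max`), and up to `max_averaged`
#' members of the largest cluster are averaged.
#'
#' @param runs list of `admixture_fit`s
#' @param dist_max cluster threshold on mean per-entry |difference|
#' @param max_averaged cap on the number of runs averaged
#' @return list with `Q` (consensus matrix), `members` (indices averaged)
#' @export
consensus_q <- function(runs, dist_max = 0.1, max_averaged = 10) {
  ll <- vapply(runs, function(f) f$loglik, numeric(1))
  ref <- which.max(ll)
  al <- align_runs(runs, reference_index = ref)$aligned
  R <- length(al)
  n <- nrow(al[[1]]) * ncol(al[[1]])
  D <- matrix(0, R, R)
  for (i in seq_len(R)) for (j in seq_len(R)) {
    D[i, j] <- sum(abs(al[[i]] - al[[j]])) / n
  }
  # connected components under dist <= dist_max
  comp <- seq_len(R)
  repeat {
    changed <- FALSE
    for (i in seq_len(R)) for (j in seq_len(R)) {
      if (D[i, j] <= dist_max && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sizes <- table(comp)
  big <- as.integer(names(sizes)[which.max(sizes)])
  members <- which(comp == big)
  members <- members[order(-ll[members])]
  members <- members[seq_len(min(length(members), max_averaged))]
  list(Q = average_q(al[members]), members = sort(members))
}

#' Evanno delta-K table from replicate log-likelihoods
#'
#' For each K with replicate final log-likelihoods, computes the replicate
#' mean and sd, the successive differences L'(K) = mean(K) - mean(K-1),
#' the curvature |L''(K)| = |L'(K+1) - L'(K)|, and
#' delta K = |L''(K)| / sd(K). Delta K is `NA` at the boundary K values and
#' wherever the replicate sd is 0 or fewer than 2 replicates exist.
#'
#' @param loglik_by_K named list: names are consecutive integer K values,
#'   elements are numeric vectors of replicate final log-likelihoods
#' @return data.frame with columns `K`, `n_rep`, `mean_L`, `sd_L`, `Lp`,
#'   `Lpp_abs`, `deltaK`
#' @export
evanno <- function(loglik_by_K) {
  Ks <- as.integer(names(loglik_by_K))
  if (anyNA(Ks)) stop("loglik_by_K must be named by integer K")
  o <- order(Ks)
  Ks <- Ks[o]; loglik_by_K <- loglik_by_K[o]
  if (length(Ks) > 1 && any(diff(Ks) != 1)) {
    stop("K values must be consecutive")
  }
  mean_L <- vapply(loglik_by_K, mean, numeric(1))
  sd_L <- vapply(loglik_by_K, stats::sd, numeric(1))
  n_rep <- vapply(loglik_by_K, length, integer(1))
  m <- length(Ks)
  Lp <- c(NA, diff(mean_L))
  Lpp_abs <- rep(NA_real_, m)
  if (m >= 3) Lpp_abs[2:(m - 1)] <- abs(Lp[3:m] - Lp[2:(m - 1)])
  deltaK <- ifelse(!is.na(Lpp_abs) & !is.na(sd_L) & sd_L > 0 & n_rep >= 2,
                   Lpp_abs / sd_L, NA_real_)
  data.frame(K = Ks, n_rep = n_rep, mean_L = mean_L, sd_L = sd_L,
             Lp = Lp, Lpp_abs = Lpp_abs, deltaK = deltaK)
}

#' Pick the K with the largest defined delta K
#'
#' @param ev an [evanno()] table
#' @return integer K, or `NA` if no delta K is defined
#' @export
best_k <- function(ev) {
  ok <- !is.na(ev$deltaK)
  if (!any(ok)) return(NA_integer_)
  ev$K[ok][which.max(ev$deltaK[ok])]
}

#' Assign samples to subpopulations from a Q matrix
#'
#' A sample is assigned to its largest ancestry component when that
#' component reaches `threshold` (ties broken toward the lowest column
#' index). Otherwise, when `groups` maps Q columns to major groups
#' (e.g. Indica / Japonica) and some group's summed components reach
#' `group_threshold`, the sample becomes `<group>-adm`; remaining samples
#' are `admix`.
#'
#' @param Q n x K matrix of ancestry proportions
#' @param threshold assignment threshold on the max component (0 < t <= 1)
#' @param groups optional named character vector mapping column index (as
#'   character) or column name to a group label
#' @param group_threshold threshold on the within-group sum (defaults to
#'   `threshold`)
#' @param labels optional subpopulation names per column (default
#'   `pop1..popK`)
#' @return data.frame: `sample`, `label`, `max_component`, `assigned_pop`,
#'   plus one `sum_<group>` column per group
#' @export
assign_subpops <- function(Q, threshold = 0.6, groups = NULL,
                           group_threshold = threshold, labels = NULL) {
  Q <- as_q(Q)
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  K <- ncol(Q)
  if (is.null(labels)) labels <- paste0("pop", seq_len(K))
  amax <- apply(Q, 1, which.max)     # ties -> lowest index
  mx <- Q[cbind(seq_len(nrow(Q)), amax)]
  label <- ifelse(mx >= threshold, labels[amax], "admix")
  out <- data.frame(
    sample = if (!is.null(rownames(Q))) rownames(Q) else seq_len(nrow(Q)),
    label = label, max_component = mx,
    assigned_pop = ifelse(mx >= threshold, labels[amax], NA_character_),
    stringsAsFactors = FALSE
  )
  if (!is.null(groups)) {
    keys <- names(groups)
    cols <- suppressWarnings(as.integer(keys))
    if (anyNA(cols)) {
      if (is.null(colnames(Q))) stop("groups name columns Q does not have")
      cols <- match(keys, colnames(Q))
    }
    if (anyNA(cols) || any(cols < 1 | cols > K)) {
      stop("groups reference unknown Q columns")
    }
    for (g in unique(groups)) {
      s <- rowSums(Q[, cols[groups == g], drop = FALSE])
      out[[paste0("sum_", g)]] <- s
      promote <- out$label == "admix" & s >= group_threshold
      out$label[promote] <- paste0(g, "-adm")
    }
  }
  out
}
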