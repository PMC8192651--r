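#' Specification of a synthetic structured, inbred population
#'
#' Defines the generative model the simulator draws from: `K` ancestral
#' populations diverged from a common pool under a Balding-Nichols model with
#' per-population divergence `fst`, individuals admixed with a symmetric
#' Dirichlet(`alpha`) prior, genotypes drawn with Wright's inbreeding
#' coefficient `F` (probability that the two gametes at a locus are identical
#' by descent), and calls masked missing at `missing_rate`. Site positions
#' are scattered uniformly along `chrom_lengths`.
#'
#' The defaults describe the small standing fixture used throughout the
#' package: a 3-way structured panel of 120 highly inbred lines (F = 0.88,
#' the level typical of predominantly selfing rice landraces) at 5,000 SNPs
#' on three chromosomes, 2% missing calls.
#'
#' @param K number of ancestral populations
#' @param L number of SNP sites
#' @param n number of individuals
#' @param fst per-population divergence in (0,1); recycled to length `K`
#' @param alpha symmetric Dirichlet concentration for admixture proportions
#' @param F inbreeding coefficient in \[0,1\]
#' @param missing_rate per-call missing probability in \[0,1)
#' @param chrom_lengths named vector of chromosome lengths (bp)
#' @param seed integer seed; every draw made from a spec is reproducible
#' @return an object of class `population_spec`
#' @export
population_spec <- function(K = 3, L = 5000, n = 120, fst = 0.15,
                            alpha = 0.2, F = 0.88, missing_rate = 0.02,
                            chrom_lengths = c(chr01 = 15e6, chr02 = 15e6,
                                              chr03 = 15e6),
                            seed = 1) {
  fst <- rep_len(fst, K)
  if (K < 1) stop("K must be >= 1")
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie in (0, 1)")
  if (alpha <= 0) stop("alpha must be positive")
  if (F < 0 || F > 1) stop("F must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- sprintf("chr%02d", seq_along(chrom_lengths))
  }
  if (L > sum(chrom_lengths)) stop("L exceeds total chromosome length")
  structure(list(K = K, L = L, n = n, fst = fst, alpha = alpha, F = F,
                 missing_rate = missing_rate, chrom_lengths = chrom_lengths,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Draw per-population ancestral allele frequencies
#'
#' Balding-Nichols divergence: for each site an ancestral frequency
#' p0 ~ Uniform(0.05, 0.95) is drawn, then population k's frequency from a
#' Beta with mean p0 and variance fst_k p0 (1 - p0), i.e. shape parameters
#' p0 (1 - fst_k)/fst_k and (1 - p0)(1 - fst_k)/fst_k. Entries are clamped
#' to \[1e-4, 1 - 1e-4\] so no population is fixed.
#'
#' @param spec a `population_spec`
#' @return K x L matrix of ALT-allele frequencies
#' @export
sim_frequencies <- function(spec) {
  set.seed(spec$seed)
  p0 <- stats::runif(spec$L, 0.05, 0.95)
  P <- matrix(NA_real_, nrow = spec$K, ncol = spec$L)
  for (k in seq_len(spec$K)) {
    lambda <- (1 - spec$fst[k]) / spec$fst[k]
    P[k, ] <- stats::rbeta(spec$L, p0 * lambda, (1 - p0) * lambda)
  }
  P <- pmin(pmax(P, 1e-4), 1 - 1e-4)
  attr(P, "p0") <- p0
  P
}

#' Draw admixture proportions
#'
#' Each individual's ancestry vector is an independent draw from a symmetric
#' Dirichlet(alpha, ..., alpha) over the K populations; rows sum to one.
#'
#' @param spec a `population_spec`
#' @return n x K Q matrix
#' @export
sim_admixture <- function(spec) {
  set.seed(spec$seed + 1L)
  if (spec$K == 1) {
    return(matrix(1, nrow = spec$n, ncol = 1))
  }
  g <- matrix(stats::rgamma(spec$n * spec$K, shape = spec$alpha),
              nrow = spec$n)
  # guard against all-zero rows at tiny alpha (numerically possible)
  zero <- rowSums(g) == 0
  if (any(zero)) {
    g[zero, ] <- 0
    g[cbind(which(zero), sample.int(spec$K, sum(zero), replace = TRUE))] <- 1
  }
  g / rowSums(g)
}

#' Draw diploid genotypes under admixture and inbreeding
#'
#' Individual i's per-gamete ALT probability at site l is
#' f_il = sum_k q_ik p_kl. With probability `F` the two gametes are
#' identical by descent: the genotype is 2 with probability f_il and 0
#' otherwise. With probability 1 - F the genotype is Binomial(2, f_il).
#' Calls are then masked missing independently at `missing_rate`. Site
#' positions are drawn uniformly along the spec's chromosomes and sorted.
#'
#' @param freqs K x L ancestral frequency matrix
#' @param Q n x K admixture matrix
#' @param F inbreeding coefficient in \[0,1\]
#' @param missing_rate per-call missing probability
#' @param spec the `population_spec` (for chromosome layout and sample names)
#' @param seed integer seed
#' @return a `genotype_matrix`
#' @export
sim_genotypes <- function(freqs, Q, F = 0, missing_rate = 0, spec = NULL,
                          seed = 1) {
  if (ncol(Q) != nrow(freqs)) stop("Q and freqs disagree on K")
  if (F < 0 || F > 1) stop("F must lie in [0, 1]")
  set.seed(seed)
  n <- nrow(Q); L <- ncol(freqs)
  f <- Q %*% freqs  # n x L individual ALT probabilities
  ibd <- stats::runif(n * L) < F
  g <- integer(n * L)
  g[ibd] <- 2L * (stats::runif(sum(ibd)) < f[ibd])
  g[!ibd] <- stats::rbinom(sum(!ibd), 2L, f[!ibd])
  if (missing_rate > 0) {
    g[stats::runif(n * L) < missing_rate] <- NA_integer_
  }
  dos <- matrix(g, nrow = n, ncol = L)

  chrom_lengths <- if (!is.null(spec)) spec$chrom_lengths else
    c(chr01 = max(1e6, L * 200))
  sites <- sim_sites(L, chrom_lengths)
  rownames(dos) <- sprintf("S%04d", seq_len(n))
  genotype_matrix(dos, sites, chrom_lengths = chrom_lengths)
}

# uniformly scattered, sorted, unique site positions along chromosomes
sim_sites <- function(L, chrom_lengths) {
  cum <- cumsum(as.numeric(chrom_lengths))
  u <- sort(sample.int(sum(chrom_lengths), L))
  chrom_idx <- findInterval(u - 1, c(0, cum))  # 1-based chromosome index
  pos <- u - c(0, cum)[chrom_idx]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  data.frame(chrom = names(chrom_lengths)[chrom_idx], pos = as.integer(pos),
             ref = ref, alt = unname(alt), qual = 60,
             stringsAsFactors = FALSE)
}

#' Additive quantitative trait specification
#'
#' @param causal_sites integer site indices carrying effects
#' @param effects additive effect sizes, one per causal site
#' @param h2 narrow-sense heritability in \[0,1\]
#' @param name trait name
#' @param baseline constant added to every phenotype (puts the trait on a
#'   realistic positive measurement scale; default 0)
#' @return object of class `trait_spec`
#' @export
trait_spec <- function(causal_sites, effects, h2 = 0.5, name = "trait",
                       baseline = 0) {
  if (length(causal_sites) != length(effects)) {
    stop("causal_sites and effects must have equal length")
  }
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  structure(list(causal_sites = as.integer(causal_sites),
                 effects = as.numeric(effects), h2 = h2, name = name,
                 baseline = baseline),
            class = "trait_spec")
}

#' Simulate an additive quantitative trait
#'
#' Genetic values are the dosage-weighted sum of effects (missing dosages
#' replaced by the per-site mean); independent Gaussian noise is scaled so
#' that Var(genetic) / Var(total) equals `h2`. With `h2 = 0` the trait is
#' pure standard-normal noise, independent of genotype.
#'
#' @param G a `genotype_matrix`
#' @param ts a `trait_spec`
#' @param seed integer seed
#' @return a `trait_table` data.frame (`sample_id` plus one trait column)
#' @export
sim_trait <- function(G, ts, seed = 1) {
  if (length(ts$causal_sites) > 0 &&
      (min(ts$causal_sites) < 1 || max(ts$causal_sites) > n_sites(G))) {
    stop("causal site index out of range")
  }
  set.seed(seed)
  n <- n_samples(G)
  if (length(ts$causal_sites) == 0) {
    gv <- numeric(n)
  } else {
    X <- G$dosage[, ts$causal_sites, drop = FALSE]
    X <- apply(X, 2, function(x) {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      x
    })
    gv <- drop(as.matrix(X) %*% ts$effects)
  }
  vg <- stats::var(gv)
  if (ts$h2 == 0 || vg == 0) {
    if (ts$h2 > 0 && vg == 0) {
      if (ts$h2 == 1) stop("h2 = 1 with zero genetic variance")
      y <- stats::rnorm(n)  # no genetic signal to scale against
    } else {
      y <- stats::rnorm(n)
    }
  } else if (ts$h2 == 1) {
    y <- gv
  } else {
    ve <- vg * (1 - ts$h2) / ts$h2
    y <- gv + stats::rnorm(n, sd = sqrt(ve))
  }
  y <- y + ts$baseline
  out <- data.frame(sample_id = G$sample_ids, y, stringsAsFactors = FALSE)
  names(out)[2] <- ts$name
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Simulate a complete structured panel
#'
#' Convenience wrapper chaining [sim_frequencies()], [sim_admixture()] and
#' [sim_genotypes()] (and optionally [sim_trait()]), returning the genotypes
#' together with the simulation truth needed by recovery tests.
#'
#' @param spec a `population_spec`
#' @param traits optional list of `trait_spec`s
#' @return list with `G` (genotype_matrix), `Q` (true admixture), `P` (true
#'   ancestral frequencies), `spec`, and `phenotypes` when traits are given
#' @export
sim_population <- function(spec, traits = NULL) {
  P <- sim_frequencies(spec)
  Q <- sim_admixture(spec)
  G <- sim_genotypes(P, Q, F = spec$F, missing_rate = spec$missing_rate,
                     spec = spec, seed = spec$seed + 2L)
  out <- list(G = G, Q = Q, P = P, spec = spec)
  if (!is.null(traits)) {
    ph <- NULL
    for (i in seq_along(traits)) {
      tt <- sim_trait(G, traits[[i]], seed = spec$seed + 10L + i)
      ph <- if (is.null(ph)) tt else merge(ph, tt, by = "sample_id", sort = FALSE)
    }
    class(ph) <- c("trait_table", "data.frame")
    out$phenotypes <- ph
  }
  out
}
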