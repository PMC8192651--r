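#' Per-site genotype statistics
#'
#' Computes, from called genotypes only: the number of called samples, the
#' ALT allele frequency, minor allele frequency, observed heterozygosity
#' (fraction of called samples that are heterozygous), Hardy-Weinberg
#' expected heterozygosity 2p(1-p) without finite-sample correction, their
#' ratio Hobs/Hexp (NA where Hexp = 0), and the per-site missingness.
#'
#' @param G a `genotype_matrix`
#' @return data.frame with one row per site: `n_called`, `p_alt`, `maf`,
#'   `hobs`, `hexp`, `ratio`, `missingness`
#' @export
site_stats <- function(G) {
  d <- G$dosage
  called <- !is.na(d)
  n_called <- colSums(called)
  alt <- colSums(d, na.rm = TRUE)
  p_alt <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  hobs <- ifelse(n_called > 0, colSums(d == 1L, na.rm = TRUE) / n_called,
                 NA_real_)
  hexp <- 2 * p_alt * (1 - p_alt)
  ratio <- ifelse(!is.na(hexp) & hexp > 0, hobs / hexp, NA_real_)
  data.frame(
    n_called = n_called,
    p_alt = p_alt,
    maf = pmin(p_alt, 1 - p_alt),
    hobs = hobs,
    hexp = hexp,
    ratio = ratio,
    missingness = 1 - n_called / nrow(d)
  )
}

#' Estimate the panel inbreeding coefficient from heterozygosity
#'
#' F is the median of 1 - Hobs/Hexp over sites with defined ratio < 1 and
#' minor allele frequency above `maf_min` — the heterozygosity deficit of a
#' partially selfing panel relative to Hardy-Weinberg. The associated
#' heterozygosity-excess cutoff is `factor * (1 - F)`: under inbreeding F
#' the most likely Hobs/Hexp is (1 - F), and a site exceeding `factor`
#' times that value has an excessive number of heterozygotes (typically a
#' paralogous alignment artefact rather than a real polymorphism).
#'
#' `inbreeding_estimate()` builds the same object directly from a known F,
#' e.g. to reuse a published panel estimate.
#'
#' @param stats a [site_stats()] table
#' @param maf_min qualifying sites must have maf strictly above this
#'   (default 0.05)
#' @param factor cutoff multiplier (default 5)
#' @return object of class `inbreeding_estimate`: list with `F`,
#'   `n_sites_used`, `factor`, `cutoff`
#' @export
estimate_inbreeding <- function(stats, maf_min = 0.05, factor = 5) {
  ok <- !is.na(stats$ratio) & stats$ratio < 1 &
    !is.na(stats$maf) & stats$maf > maf_min
  if (!any(ok)) {
    stop("no qualifying site (defined Hobs/Hexp < 1 and maf > ", maf_min,
         "); panel may be outbred or degenerate")
  }
  F <- stats::median(1 - stats$ratio[ok])
  inbreeding_estimate(F, factor = factor, n_sites_used = sum(ok))
}

#' @rdname estimate_inbreeding
#' @param F inbreeding coefficient (<= 1)
#' @param n_sites_used number of sites behind the estimate (informational)
#' @export
inbreeding_estimate <- function(F, factor = 5, n_sites_used = NA_integer_) {
  if (F > 1) stop("F cannot exceed 1")
  structure(list(F = F, n_sites_used = n_sites_used, factor = factor,
                 cutoff = factor * (1 - F)),
            class = "inbreeding_estimate")
}

#' @export
print.inbreeding_estimate <- function(x, ...) {
  cat(sprintf("inbreeding_estimate: F = %.4f (n sites = %s), cutoff %s*(1-F) = %.4f\n",
              x$F, format(x$n_sites_used), format(x$factor), x$cutoff))
  invisible(x)
}

filter_report <- function(filter, removed, remaining) {
  data.frame(filter = filter, removed = as.integer(removed),
             remaining = as.integer(remaining), stringsAsFactors = FALSE)
}

#' Remove sites with excess heterozygosity under inbreeding
#'
#' Drops every site whose Hobs/Hexp ratio is defined and exceeds the
#' cutoff of an [inbreeding_estimate()]. Monomorphic sites (undefined
#' ratio) are retained by this filter.
#'
#' @param G a `genotype_matrix`
#' @param est an `inbreeding_estimate`
#' @param stats optional precomputed [site_stats()] table
#' @return list with `G` (filtered matrix) and `report` (data.frame:
#'   filter, removed, remaining)
#' @export
het_excess_filter <- function(G, est, stats = NULL) {
  if (is.null(stats)) stats <- site_stats(G)
  drop <- !is.na(stats$ratio) & stats$ratio > est$cutoff
  list(
    G = subset_sites(G, !drop),
    report = filter_report("het_excess", sum(drop), sum(!drop))
  )
}

#' Hard site filters: MAF, missingness, minor allele count, quality
#'
#' A site survives iff `maf >= min_maf`, `missingness <= max_missing`,
#' minor-allele count `>= min_mac` and `qual >= min_qual`. All criteria are
#' evaluated in one pass; the report counts, per criterion, the sites
#' failing it (a site can fail several).
#'
#' @param G a `genotype_matrix`
#' @param min_maf minimum minor allele frequency (default 0)
#' @param max_missing maximum fraction missing (default 1)
#' @param min_mac minimum minor allele count (default 0)
#' @param min_qual minimum site QUAL (default 0)
#' @param stats optional precomputed [site_stats()] table
#' @return list with `G` and `report`
#' @export
hard_filters <- function(G, min_maf = 0, max_missing = 1, min_mac = 0,
                         min_qual = 0, stats = NULL) {
  if (is.null(stats)) stats <- site_stats(G)
  mac <- pmin(stats$p_alt, 1 - stats$p_alt) * 2 * stats$n_called
  fail_maf <- is.na(stats$maf) | stats$maf < min_maf
  fail_miss <- stats$missingness > max_missing
  fail_mac <- is.na(mac) | mac < min_mac
  fail_qual <- !is.na(G$sites$qual) & G$sites$qual < min_qual
  if (min_qual > 0) fail_qual <- fail_qual | is.na(G$sites$qual)
  drop <- fail_maf | fail_miss | fail_mac | fail_qual
  report <- filter_report(
    c("maf", "missingness", "mac", "qual", "hard_combined"),
    c(sum(fail_maf), sum(fail_miss), sum(fail_mac), sum(fail_qual), sum(drop)),
    c(rep(NA_integer_, 4), sum(!drop))
  )
  list(G = subset_sites(G, !drop), report = report)
}

#' LD pruning by pairwise r-squared within sliding windows
#'
#' Slides a window of `window_snps` sites (within each chromosome),
#' advancing by `step_snps`. Within each window, while any retained pair of
#' sites has squared Pearson correlation of dosages above `r2_max`
#' (missing dosages mean-imputed for the correlation only), the member of
#' the currently worst pair with the lower MAF is removed (tie broken by
#' removing the site at the larger coordinate). On completion no retained
#' pair within any window exceeds `r2_max`. Zero-variance sites correlate
#' 0 with everything.
#'
#' @param G a `genotype_matrix`
#' @param window_snps window size in SNPs (>= 2)
#' @param step_snps window step in SNPs
#' @param r2_max maximum allowed pairwise r-squared
#' @return sorted integer vector of retained site indices
#' @export
ld_prune <- function(G, window_snps = 50, step_snps = 10, r2_max = 0.8) {
  if (window_snps < 2) stop("window_snps must be >= 2")
  L <- n_sites(G)
  if (L == 0) return(integer(0))
  X <- G$dosage
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mu[j]
  }
  storage.mode(X) <- "double"
  maf <- site_stats(G)$maf
  maf[is.na(maf)] <- 0
  keep <- rep(TRUE, L)
  chrom_f <- factor(G$sites$chrom, levels = unique(G$sites$chrom))
  for (idx in split(seq_len(L), chrom_f)) {
    nc <- length(idx)
    starts <- unique(c(seq(1, max(1, nc - window_snps + 1), by = step_snps),
                       max(1, nc - window_snps + 1)))
    for (s in starts) {
      w <- idx[s:min(s + window_snps - 1, nc)]
      repeat {
        act <- w[keep[w]]
        if (length(act) < 2) break
        r <- suppressWarnings(stats::cor(X[, act, drop = FALSE]))
        r[is.na(r)] <- 0
        r2 <- r^2
        diag(r2) <- 0
        m <- max(r2)
        if (m <= r2_max) break
        pair <- which(r2 == m, arr.ind = TRUE)[1, ]
        i1 <- act[pair[1]]; i2 <- act[pair[2]]
        victim <- if (maf[i1] < maf[i2]) i1
          else if (maf[i2] < maf[i1]) i2
          else max(i1, i2)  # tie: larger coordinate goes
        keep[victim] <- FALSE
      }
    }
  }
  which(keep)
}

#' Thin sites to a minimum base-pair spacing
#'
#' Greedy left-to-right scan per chromosome: a site is kept only if it lies
#' at least `min_bp` beyond the last kept site.
#'
#' @param G a `genotype_matrix`
#' @param min_bp minimum spacing in bp (0 = identity)
#' @return a `genotype_matrix` of the retained sites
#' @export
thin <- function(G, min_bp = 0) {
  if (min_bp < 0) stop("min_bp must be >= 0")
  if (min_bp == 0 || n_sites(G) == 0) return(G)
  keep <- logical(n_sites(G))
  chrom_f <- factor(G$sites$chrom, levels = unique(G$sites$chrom))
  for (idx in split(seq_len(n_sites(G)), chrom_f)) {
    last <- -Inf
    for (i in idx) {
      if (G$sites$pos[i] - last >= min_bp) {
        keep[i] <- TRUE
        last <- G$sites$pos[i]
      }
    }
  }
  subset_sites(G, keep)
}

#' Run the full SNP filtering cascade
#'
#' Applies, in order: hard filters (quality, minor-allele count,
#' missingness), the inbreeding-aware heterozygosity-excess filter
#' (estimating F from the data unless an estimate is supplied), the MAF
#' filter, one or more LD-pruning rounds, and optional thinning. Returns
#' the filtered matrix, the stacked per-filter report and the inbreeding
#' estimate used.
#'
#' @param G a `genotype_matrix`
#' @param min_qual,min_mac,max_missing hard-filter thresholds
#' @param het_factor,het_maf heterozygosity-excess cutoff multiplier and
#'   the MAF floor for sites entering the F estimate
#' @param min_maf MAF filter applied after the heterozygosity filter
#' @param prune list of LD-pruning rounds, each `c(window, step, r2)`;
#'   `NULL` to skip
#' @param thin_bp minimum spacing for final thinning; 0 to skip
#' @param est optional externally supplied `inbreeding_estimate`
#' @return list with `G`, `report`, `inbreeding`
#' @export
filter_cascade <- function(G, min_qual = 30, min_mac = 3, max_missing = 0.5,
                           het_factor = 5, het_maf = 0.05, min_maf = 0.05,
                           prune = list(c(50, 10, 0.8)), thin_bp = 0,
                           est = NULL) {
  hf <- hard_filters(G, min_maf = 0, max_missing = max_missing,
                     min_mac = min_mac, min_qual = min_qual)
  G <- hf$G
  report <- hf$report
  stats <- site_stats(G)
  if (is.null(est)) {
    est <- estimate_inbreeding(stats, maf_min = het_maf, factor = het_factor)
  }
  he <- het_excess_filter(G, est, stats = stats)
  G <- he$G
  report <- rbind(report, he$report)
  mf <- hard_filters(G, min_maf = min_maf)
  report <- rbind(report, filter_report("maf_final",
                                        n_sites(G) - n_sites(mf$G),
                                        n_sites(mf$G)))
  G <- mf$G
  for (i in seq_along(prune)) {
    p <- prune[[i]]
    kept <- ld_prune(G, window_snps = p[1], step_snps = p[2], r2_max = p[3])
    removed <- n_sites(G) - length(kept)
    G <- subset_sites(G, kept)
    report <- rbind(report,
                    filter_report(paste0("ld_prune_", i), removed, n_sites(G)))
  }
  if (thin_bp > 0) {
    before <- n_sites(G)
    G <- thin(G, thin_bp)
    report <- rbind(report,
                    filter_report("thin", before - n_sites(G), n_sites(G)))
  }
  list(G = G, report = report, inbreeding = est)
}
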