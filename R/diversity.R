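#' Sliding-window nucleotide diversity (pi)
#'
#' Per-bp nucleotide diversity in sliding windows along each chromosome.
#' At a site with c0 called REF allele copies and c1 called ALT copies in
#' the chosen samples (m = c0 + c1 >= 2), the site diversity is
#' c0 c1 / C(m, 2) — the probability that two allele copies drawn without
#' replacement differ, i.e. the mean pairwise difference. A window's pi is
#' the sum of site diversities inside it divided by the window span in bp
#' (monomorphic and uncalled positions contribute zero, so the denominator
#' is the full window length). Windows start at position 1 and advance by
#' `step_bp`; terminal windows truncated by the chromosome end keep their
#' true span and are flagged partial.
#'
#' @param G a `genotype_matrix`
#' @param samples optional sample ids or indices restricting the panel
#' @param window_bp window length in bp (default 100 kb)
#' @param step_bp step between window starts (default 10 kb)
#' @param subpop label written into the output (default `"all"`)
#' @param chrom_lengths named chromosome lengths; defaults to the lengths
#'   carried by `G`, else the last site position per chromosome
#' @param drop_partial drop terminal partial windows instead of flagging
#' @return data.frame: `subpop`, `chrom`, `start`, `end`, `n_sites`, `pi`,
#'   `partial`
#' @export
window_pi <- function(G, samples = NULL, window_bp = 100000,
                      step_bp = 10000, subpop = "all",
                      chrom_lengths = NULL, drop_partial = FALSE) {
  if (window_bp < step_bp || step_bp < 1) {
    stop("need window_bp >= step_bp >= 1")
  }
  if (!is.null(samples)) G <- subset_samples(G, samples)
  if (n_samples(G) == 0) stop("empty sample subset")
  d <- G$dosage
  n_called <- colSums(!is.na(d))
  c1 <- colSums(d, na.rm = TRUE)
  m <- 2 * n_called
  c0 <- m - c1
  div <- ifelse(m >= 2, c0 * c1 / (m * (m - 1) / 2), 0)

  if (is.null(chrom_lengths)) chrom_lengths <- attr(G, "chrom_lengths")
  chroms <- unique(G$sites$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch)
      max(G$sites$pos[G$sites$chrom == ch]), numeric(1))
  }
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    len <- chrom_lengths[[ch]]
    if (is.null(len) || is.na(len)) {
      len <- max(G$sites$pos[G$sites$chrom == ch])
    }
    idx <- which(G$sites$chrom == ch)
    pos <- G$sites$pos[idx]
    starts <- seq(1, max(1, len), by = step_bp)
    starts <- starts[starts <= len]
    ends <- pmin(starts + window_bp - 1, len)
    # sum site diversities per window via cumulative sums over sorted pos
    cs <- c(0, cumsum(div[idx]))
    lo <- findInterval(starts - 1, pos)      # sites strictly before start
    hi <- findInterval(ends, pos)            # sites at or before end
    wsum <- cs[hi + 1] - cs[lo + 1]
    nsit <- hi - lo
    span <- ends - starts + 1
    out[[ci]] <- data.frame(
      subpop = subpop, chrom = ch, start = starts, end = ends,
      n_sites = nsit, pi = wsum / span, partial = span < window_bp,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (drop_partial) res <- res[!res$partial, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Windowed pi for each subpopulation of an assignment table
#'
#' @param G a `genotype_matrix`
#' @param assignments an [assign_subpops()] table (or data.frame with
#'   `sample` and `label`); the `admix` label is skipped
#' @param ... passed to [window_pi()]
#' @return row-bound [window_pi()] tables, one block per subpopulation
#' @export
window_pi_by_group <- function(G, assignments, ...) {
  labs <- setdiff(unique(assignments$label), "admix")
  do.call(rbind, lapply(labs, function(lb) {
    ids <- assignments$sample[assignments$label == lb]
    window_pi(G, samples = as.character(ids), subpop = lb, ...)
  }))
}

#' Genome-wide pi summary per subpopulation
#'
#' Arithmetic mean of window pi per subpopulation, plus per-chromosome
#' means for profiling.
#'
#' @param windows a [window_pi()] table (possibly several subpopulations)
#' @return list with `overall` (subpop, n_windows, mean_pi) and
#'   `by_chrom` (subpop, chrom, mean_pi)
#' @export
pi_summary <- function(windows) {
  if (nrow(windows) == 0) stop("no windows to summarise")
  overall <- aggregate(pi ~ subpop, data = windows, FUN = mean)
  names(overall)[2] <- "mean_pi"
  overall$n_windows <- aggregate(pi ~ subpop, data = windows, FUN = length)$pi
  by_chrom <- aggregate(pi ~ subpop + chrom, data = windows, FUN = mean)
  names(by_chrom)[3] <- "mean_pi"
  list(overall = overall[c("subpop", "n_windows", "mean_pi")],
       by_chrom = by_chrom)
}
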