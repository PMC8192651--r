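# Shared fixtures, built in code. Heavier simulated panels are cached per
# session so several test files can reuse them.

.fix <- new.env(parent = emptyenv())

# genotype matrix from a bare dosage matrix, evenly spaced sites on one
# chromosome unless positions are given
toy_gm <- function(dosage, pos = NULL, chrom = NULL, qual = 60) {
  dosage <- as.matrix(dosage)
  L <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  if (is.null(chrom)) chrom <- rep("chr01", L)
  ref <- rep_len(c("A", "C", "G", "T"), L)
  alt <- rep_len(c("C", "G", "T", "A"), L)
  genotype_matrix(dosage, data.frame(chrom = chrom, pos = pos, ref = ref,
                                     alt = alt, qual = qual))
}

# small structured panel reused across structure / assoc tests
small_pop <- function() {
  if (is.null(.fix$small_pop)) {
    spec <- population_spec(K = 3, n = 90, L = 1200, fst = 0.2, alpha = 0.2,
                            F = 0.88, missing_rate = 0.02, seed = 42)
    .fix$small_pop <- sim_population(spec)
  }
  .fix$small_pop
}

qtl_table_path <- function() {
  system.file("extdata", "rice_qtl_table.tsv", package = "ricepop")
}

# mean silhouette of a 2-D embedding against known labels
mean_silhouette <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
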