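#' Genotype matrix container
#'
#' Holds a panel of diploid samples genotyped at biallelic SNPs as an
#' alt-allele dosage matrix (0, 1, 2 or `NA` for missing) together with the
#' per-site records (chromosome, 1-based position, REF/ALT alleles, QUAL).
#' Every stage of the pipeline consumes and produces this container.
#'
#' @param dosage integer matrix, samples x sites; entries 0/1/2 or `NA`.
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`, `qual`;
#'   one row per dosage column, positions 1-based and strictly increasing
#'   within each chromosome.
#' @param sample_ids character vector of unique sample names; defaults to
#'   `rownames(dosage)`.
#' @param chrom_lengths optional named numeric vector of chromosome lengths
#'   in bp, carried along for windowed analyses.
#'
#' @return an object of class `genotype_matrix`: a list with elements
#'   `sample_ids`, `sites`, `dosage` (and attribute `chrom_lengths`).
#' @export
genotype_matrix <- function(dosage, sites, sample_ids = rownames(dosage),
                            chrom_lengths = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(nrow(dosage)))
  }
  sample_ids <- as.character(sample_ids)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt", "qual")
  miss <- setdiff(req, names(sites))
  if (length(miss) > 0) {
    stop("sites is missing column(s): ", paste(miss, collapse = ", "))
  }
  sites <- sites[req]
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  sites$qual <- as.numeric(sites$qual)

  if (length(sample_ids) != nrow(dosage)) {
    stop("length(sample_ids) must equal nrow(dosage)")
  }
  if (anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique")
  }
  if (nrow(sites) != ncol(dosage)) {
    stop("nrow(sites) must equal ncol(dosage)")
  }
  bad <- !(dosage %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) {
    stop("dosage values must be 0, 1, 2 or NA")
  }
  if (nrow(sites) > 0) {
    if (any(sites$pos < 1L)) stop("positions must be >= 1")
    if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
    if (any(sites$qual < 0, na.rm = TRUE)) stop("qual must be non-negative")
    by_chrom <- split(sites$pos, factor(sites$chrom, levels = unique(sites$chrom)))
    mono <- vapply(by_chrom, function(p) all(diff(p) > 0), logical(1))
    if (!all(mono)) {
      stop("positions must be strictly increasing within each chromosome")
    }
  }
  rownames(dosage) <- sample_ids
  colnames(dosage) <- NULL
  obj <- structure(
    list(sample_ids = sample_ids, sites = sites, dosage = dosage),
    class = "genotype_matrix"
  )
  attr(obj, "chrom_lengths") <- chrom_lengths
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d sites on %d chromosome(s); %.2f%% missing\n",
    n_samples(x), n_sites(x), length(unique(x$sites$chrom)),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' Number of samples / sites in a genotype matrix
#' @param G a `genotype_matrix`
#' @return integer count
#' @export
n_samples <- function(G) length(G$sample_ids)

#' @rdname n_samples
#' @export
n_sites <- function(G) nrow(G$sites)

#' Subset a genotype matrix by site or sample
#'
#' @param G a `genotype_matrix`
#' @param idx integer or logical index over sites (`subset_sites`) or samples
#'   (`subset_samples`). Site subsets must preserve the original order so the
#'   position-sorted invariant survives.
#' @return a `genotype_matrix`
#' @export
subset_sites <- function(G, idx) {
  if (is.logical(idx)) idx <- which(idx)
  idx <- as.integer(idx)
  if (is.unsorted(idx, strictly = TRUE)) {
    stop("site subset indices must be strictly increasing")
  }
  genotype_matrix(G$dosage[, idx, drop = FALSE], G$sites[idx, , drop = FALSE],
                  G$sample_ids, attr(G, "chrom_lengths"))
}

#' @rdname subset_sites
#' @export
subset_samples <- function(G, idx) {
  if (is.character(idx)) {
    pos <- match(idx, G$sample_ids)
    if (anyNA(pos)) {
      stop("unknown sample id(s): ", paste(idx[is.na(pos)], collapse = ", "))
    }
    idx <- pos
  }
  genotype_matrix(G$dosage[idx, , drop = FALSE], G$sites, G$sample_ids[idx],
                  attr(G, "chrom_lengths"))
}
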