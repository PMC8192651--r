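#' Read biallelic SNP genotypes from a VCF file
#'
#' Loads GT calls from a VCF 4.x file into a [genotype_matrix()], applying the
#' quality and biallelic filters used when the raw variant calls are first
#' reduced to an analysis-ready SNP set. Sites failing the QUAL threshold or
#' (when `require_biallelic`) carrying zero or more than one ALT allele are
#' dropped and tallied in the `skipped` attribute. Both `/` and `|` genotype
#' separators are accepted; `./.` (or any half-missing call) becomes `NA`.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param min_qual minimum QUAL to keep a site; records with missing QUAL are
#'   dropped whenever `min_qual > 0`.
#' @param require_biallelic drop records that are not strictly biallelic
#'   (default `TRUE`).
#' @return a `genotype_matrix`; attribute `skipped` holds per-reason counts
#'   of dropped records.
#' @export
read_vcf <- function(path, min_qual = 0, require_biallelic = TRUE) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  n_meta <- length(vcf@meta)  # '##' lines; +1 column header line below
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) {
    samples <- colnames(vcf@gt)
    samples <- samples[samples != "FORMAT"]
    empty <- matrix(NA_integer_, nrow = length(samples), ncol = 0)
    rownames(empty) <- samples
    return(genotype_matrix(empty, data.frame(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), qual = numeric()
    ), samples))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)

  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  not_biallelic <- is.na(alt) | alt == "." | grepl(",", alt, fixed = TRUE) |
    alt == ref
  low_qual <- if (min_qual > 0) is.na(qual) | qual < min_qual else rep(FALSE, nrow(fix))

  drop <- low_qual
  if (require_biallelic) drop <- drop | not_biallelic
  skipped <- c(
    low_qual = sum(low_qual),
    not_biallelic = if (require_biallelic) sum(not_biallelic & !low_qual) else 0L
  )
  keep <- which(!drop)

  gtk <- gt[keep, , drop = FALSE]
  # validate ploidy before recoding; report the offending file line
  ok <- is.na(gtk) | grepl("^[0-9]+([/|][0-9]+)?$|^\\.([/|]\\.)?$|^[0-9]+[/|]\\.$|^\\.[/|][0-9]+$", gtk)
  diploid <- is.na(gtk) | grepl("[/|]", gtk) | gtk == "."
  if (any(!ok | !diploid)) {
    bad <- which(!ok | !diploid, arr.ind = TRUE)[1, ]
    line <- n_meta + 1L + keep[bad[1]]
    stop("non-diploid or malformed GT '", gtk[bad[1], bad[2]],
         "' at VCF line ", line, " (sample ", samples[bad[2]], ")")
  }

  dos <- matrix(NA_integer_, nrow = nrow(gtk), ncol = ncol(gtk))
  a1 <- sub("[/|].*$", "", gtk)
  a2 <- sub("^.*[/|]", "", gtk)
  called <- !is.na(gtk) & a1 != "." & a2 != "."
  dos[called] <- (a1[called] != "0") + (a2[called] != "0")
  dos <- t(dos)  # samples x sites
  rownames(dos) <- samples

  sites <- data.frame(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep],
    alt = alt[keep],
    qual = qual[keep],
    stringsAsFactors = FALSE
  )
  # restore chromosome-wise position order if the file was unsorted
  ord <- order(factor(sites$chrom, levels = unique(sites$chrom)), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  dos <- dos[, ord, drop = FALSE]

  G <- genotype_matrix(dos, sites, samples)
  attr(G, "skipped") <- skipped
  G
}

#' Write a genotype matrix to a minimal VCF 4.2 file
#'
#' Emits CHROM/POS/REF/ALT/QUAL plus unphased GT calls (0/0, 0/1, 1/1, ./.)
#' so that `read_vcf(write_vcf(G))` reproduces sample ids, site records and
#' dosages exactly.
#'
#' @param G a `genotype_matrix`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_vcf <- function(G, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write VCF to '", path, "': ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ricepop",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$sample_ids), collapse = "\t")
  ), con)
  if (n_sites(G) == 0) return(invisible(path))
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_sites(G), ncol = n_samples(G))
  d <- t(G$dosage)
  gt[!is.na(d)] <- code[d[!is.na(d)] + 1L]
  qual <- ifelse(is.na(G$sites$qual), ".",
                 format(G$sites$qual, trim = TRUE, scientific = FALSE))
  rows <- paste(G$sites$chrom, G$sites$pos, ".", G$sites$ref, G$sites$alt,
                qual, ".", ".", "GT", sep = "\t")
  rows <- paste(rows, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(rows, con)
  invisible(path)
}
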