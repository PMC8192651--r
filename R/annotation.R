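#' Read gene records from a GFF3 annotation
#'
#' Keeps only features of type `gene` and returns their coordinates 1-based
#' inclusive, as annotated. Records without an `ID` attribute are skipped
#' with a warning; duplicated gene ids are an error.
#'
#' @param path GFF3 file
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- as.character(genes$ID)
  no_id <- is.na(ids) | ids == ""
  if (any(no_id)) {
    warning(sum(no_id), " gene record(s) without an ID attribute skipped")
    genes <- genes[!no_id]
    ids <- ids[!no_id]
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicated gene ID(s): ", paste(dup, collapse = ", "))
  }
  ann <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    stringsAsFactors = FALSE
  )
  if (nrow(ann) > 0 && any(ann$start > ann$end)) {
    stop("gene with start > end in annotation")
  }
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Read a phenotype or QTL-report table
#'
#' Typed readers for the two delimited tables the pipeline consumes:
#' `schema = "phenotype"` expects a sample-id column followed by numeric
#' trait columns (blank cells become `NA`); `schema = "qtl_report"` expects
#' one row per QTL with columns `qtl_name`, `trait`, `chrom`, `panels`
#' (flags separated by `;` or `&`, e.g. `FP;Jap`), `start`, `end`, `n_snps`,
#' `min_p`, `n_genes`, and validates the structural invariants of a QTL
#' table: `start < end` and at least 2 significant SNPs per QTL.
#'
#' @param path delimited text file with a header row
#' @param schema `"phenotype"` or `"qtl_report"`
#' @param sep field separator (default tab)
#' @param sig_threshold optional -log10(p) threshold; when supplied, each
#'   QTL's `min_p` must satisfy `-log10(min_p) >= sig_threshold`
#' @return data.frame; class `trait_table` or `qtl_report_table`
#' @export
read_table <- function(path, schema = c("phenotype", "qtl_report"),
                       sep = "\t", sig_threshold = NULL) {
  schema <- match.arg(schema)
  x <- utils::read.delim(path, sep = sep, header = TRUE,
                         na.strings = c("NA", ""), check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (schema == "phenotype") {
    if (ncol(x) < 2) stop("phenotype table needs a sample column plus traits")
    names(x)[1] <- "sample_id"
    x$sample_id <- as.character(x$sample_id)
    if (anyDuplicated(x$sample_id)) stop("duplicated sample ids in phenotype table")
    for (j in seq(2, ncol(x))) {
      v <- suppressWarnings(as.numeric(x[[j]]))
      if (any(is.na(v) & !is.na(x[[j]]))) {
        stop("trait column '", names(x)[j], "' is not numeric")
      }
      x[[j]] <- v
    }
    class(x) <- c("trait_table", "data.frame")
    return(x)
  }
  req <- c("qtl_name", "trait", "chrom", "panels", "start", "end",
           "n_snps", "min_p", "n_genes")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    stop("QTL table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  x <- x[req]
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  x$n_snps <- as.integer(x$n_snps)
  x$min_p <- as.numeric(x$min_p)
  x$n_genes <- as.integer(x$n_genes)
  if (any(x$start >= x$end)) {
    stop("QTL rows with start >= end: ",
         paste(x$qtl_name[x$start >= x$end], collapse = ", "))
  }
  if (any(x$n_snps < 2)) {
    stop("QTL must contain at least 2 significant SNPs; offending row(s): ",
         paste(x$qtl_name[x$n_snps < 2], collapse = ", "))
  }
  if (!is.null(sig_threshold)) {
    low <- -log10(x$min_p) < sig_threshold
    if (any(low)) {
      stop("QTL min p above significance threshold: ",
           paste(x$qtl_name[low], collapse = ", "))
    }
  }
  class(x) <- c("qtl_report_table", "data.frame")
  x
}

#' Split the panel-flag column of a QTL report into logical flags
#'
#' @param panels character vector like `"FP;Ind"` (separators `;` or `&`,
#'   surrounding whitespace ignored)
#' @return data.frame with logical columns `FP`, `Ind`, `Jap`
#' @export
panel_flags <- function(panels) {
  parts <- strsplit(as.character(panels), "[;&]")
  parts <- lapply(parts, function(p) trimws(p))
  data.frame(
    FP = vapply(parts, function(p) "FP" %in% p, logical(1)),
    Ind = vapply(parts, function(p) "Ind" %in% p, logical(1)),
    Jap = vapply(parts, function(p) "Jap" %in% p, logical(1))
  )
}
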