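#' Call significant associations
#'
#' @param results an [mlm_assoc()] table
#' @param threshold_log10p significance threshold on -log10(p); sites at
#'   exactly the threshold are included (default 8)
#' @return the significant rows, sorted by chromosome and position
#' @export
call_significant <- function(results, threshold_log10p = 8.0) {
  sig <- results[!is.na(results$minus_log10_p) &
                   results$minus_log10_p >= threshold_log10p, , drop = FALSE]
  sig[order(factor(sig$chrom, levels = unique(sig$chrom)), sig$pos), ,
      drop = FALSE]
}

#' Chain significant SNPs into candidate segments
#'
#' Consecutive significant SNPs on one chromosome are chained while the
#' inter-SNP gap is at most `gap_bp`; chains with fewer than `min_snps`
#' SNPs are discarded. A segment spans first to last SNP and records the
#' SNP count, the minimum p and the position of its most significant SNP.
#'
#' @param sig significant rows (as from [call_significant()]), sorted by
#'   chromosome and position
#' @param gap_bp maximum gap joining two SNPs into one chain (default
#'   250 kb)
#' @param min_snps minimum SNPs per retained segment (default 2)
#' @param panel,trait tags stamped on each segment
#' @return data.frame: `chrom`, `start`, `end`, `n_snps`, `min_p`,
#'   `peak_pos`, `panel`, `trait`
#' @export
build_segments <- function(sig, gap_bp = 250000, min_snps = 2,
                           panel = "FP", trait = NA_character_) {
  empty <- data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    n_snps = integer(), min_p = numeric(), peak_pos = numeric(),
    panel = character(), trait = character(), stringsAsFactors = FALSE
  )
  if (nrow(sig) == 0) return(empty)
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    breaks <- c(0, which(diff(s$pos) > gap_bp), nrow(s))
    for (b in seq_len(length(breaks) - 1)) {
      chain <- s[(breaks[b] + 1):breaks[b + 1], , drop = FALSE]
      if (nrow(chain) < min_snps) next
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(chain$pos), end = max(chain$pos),
        n_snps = nrow(chain), min_p = min(chain$p),
        peak_pos = chain$pos[which.min(chain$p)],
        panel = panel, trait = trait, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' Extend sub-threshold segments around their peak SNP
#'
#' A segment narrower than `min_width` bp is replaced by
#' `[peak - flank, peak + flank]` around its most significant SNP (start
#' floored at 1); wider segments pass through unchanged.
#'
#' @param segments a [build_segments()] table
#' @param min_width segments below this width are extended (default 100 kb)
#' @param flank extension either side of the peak (default 50 kb)
#' @return the table with adjusted `start`/`end`
#' @export
extend_small <- function(segments, min_width = 100000, flank = 50000) {
  if (nrow(segments) == 0) return(segments)
  width <- segments$end - segments$start + 1
  small <- width < min_width
  segments$start[small] <- pmax(1, segments$peak_pos[small] - flank)
  segments$end[small] <- segments$peak_pos[small] + flank
  segments
}

#' Merge per-panel, per-trait segments into final QTL regions
#'
#' Segments are first mapped through `trait_class_map` (by default grain
#' length, width and length/width ratio collapse into a single grain-size
#' class; other traits map to themselves). Segments of the same trait
#' class on the same chromosome whose intervals overlap by at least 1 bp
#' are unioned into one region carrying every contributing panel and
#' trait; non-overlapping segments pass through. Output is sorted by
#' chromosome and start.
#'
#' @param segments row-bound [extend_small()] tables across panels/traits
#' @param trait_class_map named character vector trait -> class; `NULL`
#'   uses the default grain-size map
#' @return data.frame: `chrom`, `start`, `end`, `trait_class`, `panels`,
#'   `traits`, `n_snps` (summed), `min_p`, `n_segments`
#' @export
merge_panels <- function(segments, trait_class_map = NULL) {
  if (is.null(trait_class_map)) {
    trait_class_map <- c(
      Grain_Length = "Grain_Size", Grain_Width = "Grain_Size",
      Grain_Length_Width_Ratio = "Grain_Size"
    )
  }
  if (nrow(segments) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), trait_class = character(),
                      panels = character(), traits = character(),
                      n_snps = integer(), min_p = numeric(),
                      n_segments = integer(), stringsAsFactors = FALSE))
  }
  tr <- as.character(segments$trait)
  cls <- ifelse(tr %in% names(trait_class_map), trait_class_map[tr], tr)
  if (anyNA(cls)) stop("trait missing from trait_class_map")
  segments$trait_class <- cls
  out <- list()
  for (key in unique(paste(segments$trait_class, segments$chrom, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    s <- segments[segments$trait_class == parts[1] &
                    segments$chrom == parts[2], , drop = FALSE]
    s <- s[order(s$start, s$end), , drop = FALSE]
    grp <- integer(nrow(s))
    g <- 1L
    grp[1] <- g
    hi <- s$end[1]
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start[i] <= hi) {         # >= 1 bp overlap, inclusive ends
        grp[i] <- g
        hi <- max(hi, s$end[i])
      } else {
        g <- g + 1L
        grp[i] <- g
        hi <- s$end[i]
      }
    }
    for (gg in unique(grp)) {
      m <- s[grp == gg, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chrom = parts[2], start = min(m$start), end = max(m$end),
        trait_class = parts[1],
        panels = paste(sort(unique(m$panel)), collapse = ";"),
        traits = paste(sort(unique(m$trait)), collapse = ";"),
        n_snps = sum(m$n_snps), min_p = min(m$min_p),
        n_segments = nrow(m), stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(factor(res$chrom, levels = sort(unique(res$chrom))),
                   res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count annotated genes overlapping QTL regions
#'
#' A gene counts when its 1-based inclusive interval overlaps the region's
#' interval by at least 1 bp on the same chromosome (a gene starting
#' exactly at the region end counts).
#'
#' @param regions a [merge_panels()] table (or any data.frame with
#'   `chrom`, `start`, `end`)
#' @param ann a [read_gff_genes()] annotation
#' @return the regions with `n_genes` and `gene_ids` (`;`-separated,
#'   sorted by gene start) appended
#' @export
count_genes <- function(regions, ann) {
  n_genes <- integer(nrow(regions))
  gene_ids <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    hit <- ann$chrom == regions$chrom[i] &
      ann$start <= regions$end[i] & ann$end >= regions$start[i]
    hits <- ann[hit, , drop = FALSE]
    hits <- hits[order(hits$start), , drop = FALSE]
    n_genes[i] <- nrow(hits)
    gene_ids[i] <- paste(hits$gene_id, collapse = ";")
  }
  regions$n_genes <- n_genes
  regions$gene_ids <- gene_ids
  regions
}

#' Aggregate a QTL table into headline summary counts
#'
#' Totals over a [read_table()] `qtl_report` table (or a merged-regions
#' table carrying `panels`, `n_snps`, `n_genes`): the number of QTLs, the
#' summed significant associations and genes, the per-panel counts (any
#' membership, plus panel-exclusive counts), the number of distinct
#' chromosomes and the total span in bp.
#'
#' @param qtl a `qtl_report_table` or compatible data.frame
#' @return list of summary scalars
#' @export
qtl_report <- function(qtl) {
  if (nrow(qtl) == 0) {
    return(list(n_qtl = 0L, total_associations = 0L, total_genes = 0L,
                n_full_panel = 0L, n_indica = 0L, n_japonica = 0L,
                n_japonica_only = 0L, n_indica_only = 0L,
                n_chromosomes = 0L, total_span_bp = 0))
  }
  fl <- panel_flags(qtl$panels)
  list(
    n_qtl = nrow(qtl),
    total_associations = sum(qtl$n_snps),
    total_genes = sum(qtl$n_genes),
    n_full_panel = sum(fl$FP),
    n_indica = sum(fl$Ind),
    n_japonica = sum(fl$Jap),
    n_japonica_only = sum(fl$Jap & !fl$FP & !fl$Ind),
    n_indica_only = sum(fl$Ind & !fl$FP & !fl$Jap),
    n_chromosomes = length(unique(qtl$chrom)),
    total_span_bp = sum(qtl$end - qtl$start + 1)
  )
}
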