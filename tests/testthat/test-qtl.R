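mk_assoc <- function(chrom, pos, p) {
  data.frame(chrom = chrom, pos = pos, effect = 1, se = 1, p = p,
             minus_log10_p = -log10(p), stringsAsFactors = FALSE)
}

test_that("significance calling is inclusive at the threshold", {
  res <- mk_assoc("chr01", c(100, 200, 300), c(1e-8, 0.5, 1e-9))
  sig <- call_significant(res, threshold_log10p = 8)
  expect_equal(sig$pos, c(100, 300))           # exactly 8.0 is included

  none <- call_significant(mk_assoc("chr01", 1:5, rep(0.5, 5)))
  expect_equal(nrow(none), 0)

  set.seed(113)
  rnd <- mk_assoc("chr01", sort(sample.int(1e6, 500)), 10^-runif(500, 0, 12))
  got <- call_significant(rnd, 8)
  expect_equal(nrow(got), sum(rnd$minus_log10_p >= 8))
})

test_that("segment chaining follows the gap rule and the 2-SNP minimum", {
  sig <- mk_assoc("chr01", c(1.0e6, 1.1e6, 1.5e6), rep(1e-10, 3))
  segs <- build_segments(sig, gap_bp = 250000, min_snps = 2)
  # 1.1 -> 1.5 Mb gap is 400 kb: chain breaks, singleton discarded
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, 1.0e6)
  expect_equal(segs$end, 1.1e6)
  expect_equal(segs$n_snps, 2L)

  single <- build_segments(mk_assoc("chr01", 5e6, 1e-12))
  expect_equal(nrow(single), 0)
})

test_that("chaining equals brute-force single-linkage clustering at the gap", {
  set.seed(127)
  for (rep in 1:5) {
    pos <- sort(sample.int(5e6, 60))
    sig <- mk_assoc("chr01", pos, 10^-runif(60, 8, 15))
    gap <- 100000
    segs <- build_segments(sig, gap_bp = gap, min_snps = 1)
    # oracle: transitive closure of |pos_i - pos_j| <= gap on sorted sites
    cl <- cumsum(c(1, diff(pos) > gap))
    expect_equal(nrow(segs), length(unique(cl)))
    expect_equal(segs$start, as.numeric(tapply(pos, cl, min)),
                 ignore_attr = TRUE)
    expect_equal(segs$end, as.numeric(tapply(pos, cl, max)),
                 ignore_attr = TRUE)
  }
})

test_that("narrow segments are extended symmetrically around their peak SNP", {
  sig <- mk_assoc("chr06", c(7483914, 7503914), c(6.5e-08, 5.90e-08))
  segs <- build_segments(sig, gap_bp = 250000, min_snps = 2, trait = "Grain_Length")
  ext <- extend_small(segs, min_width = 100000, flank = 50000)
  expect_equal(ext$start, 7453914)
  expect_equal(ext$end, 7553914)
  expect_equal(ext$end - ext$start + 1, 100001)

  wide <- data.frame(chrom = "chr02", start = 1e6, end = 2.3e6, n_snps = 5L,
                     min_p = 1e-10, peak_pos = 1.5e6, panel = "FP",
                     trait = "x")
  expect_equal(extend_small(wide), wide)

  near0 <- data.frame(chrom = "chr01", start = 15000, end = 25000,
                      n_snps = 2L, min_p = 1e-10, peak_pos = 20000,
                      panel = "FP", trait = "x")
  ext0 <- extend_small(near0, min_width = 100000, flank = 50000)
  expect_equal(ext0$start, 1)
  expect_equal(ext0$end, 70000)
})

test_that("panel merging unions overlapping intervals within a trait class", {
  segs <- rbind(
    data.frame(chrom = "chr03", start = 100e3, end = 300e3, n_snps = 3L,
               min_p = 1e-9, peak_pos = 200e3, panel = "FP",
               trait = "Grain_Length"),
    data.frame(chrom = "chr03", start = 250e3, end = 400e3, n_snps = 2L,
               min_p = 1e-10, peak_pos = 300e3, panel = "Jap",
               trait = "Grain_Length"),
    data.frame(chrom = "chr03", start = 380e3, end = 500e3, n_snps = 2L,
               min_p = 1e-8, peak_pos = 400e3, panel = "FP",
               trait = "Grain_Width"),
    data.frame(chrom = "chr03", start = 900e3, end = 950e3, n_snps = 2L,
               min_p = 1e-8, peak_pos = 920e3, panel = "FP",
               trait = "Heading_Date")
  )
  merged <- merge_panels(segs)
  gs <- merged[merged$trait_class == "Grain_Size", ]
  # grain length + grain width chains overlap into one grain-size region
  expect_equal(nrow(gs), 1)
  expect_equal(gs$start, 100e3)
  expect_equal(gs$end, 500e3)
  expect_equal(gs$panels, "FP;Jap")
  expect_equal(gs$n_snps, 7L)
  expect_equal(nrow(merged), 2)

  # non-overlap passes through distinct
  segs2 <- segs[c(1, 4), ]
  segs2$start[2] <- 600e3; segs2$end[2] <- 700e3
  expect_equal(nrow(merge_panels(segs2)), 2)
})

test_that("merged counts equal a brute-force union-find over random intervals", {
  set.seed(131)
  for (rep in 1:5) {
    n <- 25
    start <- sample.int(2e6, n)
    segs <- data.frame(chrom = "chr01", start = start,
                       end = start + sample.int(3e5, n), n_snps = 2L,
                       min_p = 1e-9, peak_pos = start, panel = "FP",
                       trait = "T1")
    merged <- merge_panels(segs, trait_class_map = c(T1 = "T1"))
    # oracle: union-find on pairwise interval overlap
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (segs$start[i] <= segs$end[j] && segs$start[j] <= segs$end[i]) {
        parent[find(i)] <- find(j)
      }
    }
    comps <- length(unique(vapply(seq_len(n), find, integer(1))))
    expect_equal(nrow(merged), comps)
    expect_true(all(merged$end - merged$start >= 0))
  }
})

test_that("gene counting uses 1 bp inclusive overlap", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr01",
                    start = c(10, 30, 100), end = c(20, 40, 200),
                    strand = "+")
  region <- data.frame(chrom = "chr01", start = 15, end = 35)
  got <- count_genes(region, ann)
  expect_equal(got$n_genes, 2)
  expect_equal(got$gene_ids, "g1;g2")

  # gene starting exactly at the region end still counts
  abut <- count_genes(data.frame(chrom = "chr01", start = 1, end = 100), ann)
  expect_equal(abut$n_genes, 3)

  none <- count_genes(region, ann[0, ])
  expect_equal(none$n_genes, 0)
})

test_that("the packaged QTL report aggregates to the published totals", {
  qtl <- read_table(qtl_table_path(), schema = "qtl_report")
  rpt <- qtl_report(qtl)
  expect_equal(rpt$n_qtl, 21L)
  expect_equal(rpt$total_associations, 643L)
  expect_equal(rpt$total_genes, 1730L)
  expect_equal(rpt$n_full_panel, 17L)
  expect_equal(rpt$n_japonica_only, 4L)
  expect_equal(rpt$n_chromosomes, 10L)

  empty <- qtl[0, ]
  rpt0 <- qtl_report(empty)
  expect_equal(rpt0$n_qtl, 0L)
  expect_equal(rpt0$total_associations, 0L)
})
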