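#!/usr/bin/env Rscript
# Stage 1 — simulate the standing diversity panel.
#
# Generates the synthetic structured, highly inbred rice-like panel every
# later stage consumes: K = 3 ancestral populations (Fst 0.15), 120 lines
# admixed under Dirichlet(0.2), inbreeding F = 0.88, 5,000 SNPs on three
# 15 Mb chromosomes, 2% missing calls, plus one additive trait with two
# large-effect loci (each duplicated into a perfectly linked tag SNP so a
# QTL can show >= 2 significant SNPs). Writes VCF + phenotypes + truth
# tables under results/panel/.

suppressMessages(library(ricepop))
out <- "results/panel"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- population_spec(K = 3, n = 120, L = 5000, fst = 0.15, alpha = 0.2,
                        F = 0.88, missing_rate = 0.02, seed = 1)
pop <- sim_population(spec)
G <- pop$G

chr <- G$sites$chrom
causal <- c(which(chr == "chr01")[150], which(chr == "chr02")[150])
d <- G$dosage
d[, causal + 1] <- d[, causal]           # perfect local LD at the QTLs
G <- genotype_matrix(d, G$sites, G$sample_ids, attr(G, "chrom_lengths"))
pheno <- sim_trait(G, trait_spec(causal, c(1, 1), h2 = 0.6,
                                 name = "Grain_Length", baseline = 8),
                   seed = 11)

write_vcf(G, file.path(out, "panel.vcf"))
write.table(pheno, file.path(out, "phenotypes.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(data.frame(sample = G$sample_ids, round(pop$Q, 6)),
            file.path(out, "truth_Q.tsv"), sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(data.frame(site_index = causal, chrom = chr[causal],
                       pos = G$sites$pos[causal]),
            file.path(out, "truth_causal.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("panel: %d samples x %d sites, true F = %.2f, 2 planted loci\n",
            n_samples(G), n_sites(G), spec$F))
cat("wrote", out, "\n")
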