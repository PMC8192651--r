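#!/usr/bin/env Rscript
# Stage 5 — mixed-model GWAS.
#
# Screens the phenotypes by coefficient of variation, builds the VanRaden
# kinship from the full SNP panel, and scans each eligible trait with the
# single-variance-component MLM using the consensus ancestry proportions
# as fixed covariates. Writes per-SNP association tables.

suppressMessages(library(ricepop))
G <- read_vcf("results/panel/panel.vcf")
pheno <- read_table("results/panel/phenotypes.tsv", schema = "phenotype")
Qtab <- read.delim("results/structure/Q_consensus.tsv")
Q <- as.matrix(Qtab[, -1])
dir.create("results/gwas", showWarnings = FALSE, recursive = TRUE)

qc <- trait_qc(pheno, cv_max = 56, n_min = 30)
write.table(qc, "results/gwas/trait_qc.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(qc, row.names = FALSE)

K <- vanraden_kinship(G)
for (tr in qc$trait[qc$eligible]) {
  res <- mlm_assoc(G, pheno, covariates = Q, K = K, trait_name = tr)
  vc <- attr(res, "vc")
  cat(sprintf("%s: sigma_g2 = %.3f, sigma_e2 = %.3f, lambda_GC = %.3f\n",
              tr, vc$sigma_g2, vc$sigma_e2, genomic_inflation(res$p)))
  write.table(cbind(trait = tr, res),
              file.path("results/gwas", paste0("assoc_", tr, ".tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
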