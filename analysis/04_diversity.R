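#!/usr/bin/env Rscript
# Stage 4 — nucleotide diversity.
#
# Sliding-window pi (100 kb windows, 10 kb step) along each chromosome for
# every assigned subpopulation and for the whole panel, with genome-wide
# means per subpopulation. Uses the unfiltered panel so monomorphic and
# low-MAF sites contribute their (zero or small) diversity.

suppressMessages(library(ricepop))
G <- read_vcf("results/panel/panel.vcf")
asn <- read.delim("results/structure/assignments.tsv")
dir.create("results/diversity", showWarnings = FALSE, recursive = TRUE)

wins <- rbind(
  window_pi(G, window_bp = 1e5, step_bp = 1e4, subpop = "all"),
  window_pi_by_group(G, asn, window_bp = 1e5, step_bp = 1e4)
)
write.table(wins, "results/diversity/pi_windows.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

sm <- pi_summary(wins)
write.table(sm$overall, "results/diversity/pi_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("genome-wide mean pi per subpopulation:\n")
print(sm$overall, row.names = FALSE)
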