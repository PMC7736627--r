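#!/usr/bin/env Rscript
# Codon-position-partitioned p-distances and NG86 Ka/Ks for every gene
# and congener pair (run 02_simulate.R first).

suppressPackageStartupMessages(library(mitocomp))

taxa <- c("tertius", "albofasciatus", "marmoratus")
genomes <- setNames(lapply(taxa, function(nm)
  read_genbank(file.path("results/synthetic", paste0(nm, ".gb")))), taxa)

cds <- lapply(genomes, pcg_coding_sequences)
pd_rows <- list()
for (i in 1:2) for (j in (i + 1):3) {
  pd <- codon_partition_distances(cds[[i]], cds[[j]])
  pd$pair <- paste(taxa[i], taxa[j], sep = "-")
  pd_rows[[length(pd_rows) + 1]] <- pd
}
pd <- do.call(rbind, pd_rows)
write.table(pd, "results/p_distances.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("third positions diverge faster than first+second:",
    mean(pd$p3 > pd$p12) * 100, "% of gene-pair comparisons\n")

kk <- kaks_table(genomes)
write.table(kk$pairs, "results/kaks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
means <- sort(kk$gene_means, decreasing = TRUE)
cat("\nper-gene mean Ka/Ks across the three pairs (descending):\n")
print(round(means, 3))
cat("\nall genes under purifying selection:",
    all(means < 1, na.rm = TRUE), "\n")
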