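#!/usr/bin/env Rscript
# Composition, skew, codon usage and RSCU over the simulated congeners
# (run 02_simulate.R first).

suppressPackageStartupMessages(library(mitocomp))

taxa <- c("tertius", "albofasciatus", "marmoratus")
genomes <- lapply(taxa, function(nm) {
  g <- read_genbank(file.path("results/synthetic", paste0(nm, ".gb")))
  g
})
names(genomes) <- taxa

comp_rows <- do.call(rbind, lapply(taxa, function(nm) {
  d <- rbind(partition_composition(genomes[[nm]], "whole"),
             partition_composition(genomes[[nm]], "category"),
             partition_composition(genomes[[nm]], "codon-position"))
  cbind(taxon = nm, d)
}))
write.table(comp_rows, "results/composition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("whole-genome A+T% and skews:\n")
print(comp_rows[comp_rows$label == "whole",
                c("taxon", "at_content", "at_skew", "gc_skew")],
      row.names = FALSE)

aud <- do.call(rbind, lapply(taxa, function(nm)
  cbind(taxon = nm, start_stop_audit(genomes[[nm]]))))
write.table(aud, "results/start_stop_audit.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nsense codons per genome:",
    paste(tapply(aud$aa_length, aud$taxon, sum), collapse = ", "), "\n")

rs <- do.call(rbind, lapply(taxa, function(nm)
  cbind(taxon = nm, rscu(codon_usage(genomes[[nm]])))))
write.table(rs, "results/rscu.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
u <- aa_usage(codon_usage(genomes[[1]]))
top <- sort(u$by_residue, decreasing = TRUE)
cat("\nmost-used residues (", names(top)[1], names(top)[2], names(top)[3],
    "), least-used:", names(top)[length(top)], "\n")

ol <- extract_region(genomes[[1]], "OL", orient = "h-strand")
cat("GCCGG motif hits in the replication origin:",
    length(motif_scan(ol, "GCCGG")), "\n")
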