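#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study system with known ground truth.
#
# Produces a CC/CXC chemokine-like master alignment with planted
# conserved, subfamily-discriminative and neutral columns; ortholog
# N-terminal regions with motifs planted at fixed presence rates; five
# Calpha-only ligand-receptor complexes with planted contacts; and
# variant / mutational-scan / interaction-network tables. Everything is
# derived from one seed, so later stages can regenerate identical
# inputs instead of deserializing them.

suppressPackageStartupMessages(library(chemodissect))

seed <- 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

spec <- generator_spec(seed = seed)
fam <- make_family_alignment(spec)
write_alignment(fam$aln, "results/data/family_alignment.fasta",
                "results/data/family_alignment_meta.tsv")
write.table(fam$truth, "results/data/family_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

mr <- make_motif_regions(spec)
write.table(mr$truth, "results/data/motif_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

subfams <- c(rep("CC", 3), rep("CXC", 2))
for (i in seq_along(subfams)) {
  tc <- make_toy_complex(spec, complex_id = paste0("cx", i),
                         subfamily = c(ligand = subfams[i],
                                       receptor = subfams[i]),
                         seed_offset = 10L + i)
  write_complex_pdb(tc$cx, sprintf("results/data/cx%d.pdb", i))
}

tabs <- make_tables(spec)
write.table(tabs$variants$data, "results/data/variants.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tabs$mutscan$data, "results/data/mutscan.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tabs$network$data, "results/data/network_edges.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "generated: %d aligned sequences x %d columns (%d labeled),\n",
  length(fam$aln$seqs), aln_width(fam$aln), sum(!is.na(fam$aln$labels))))
cat(sprintf(
  "  %d motif regions, %d toy complexes, %d variant rows, %d edges\n",
  length(mr$regions), length(subfams), nrow(tabs$variants$data),
  nrow(tabs$network$data)))
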