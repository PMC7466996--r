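#!/usr/bin/env Rscript
# Stage 1: build the synthetic study inputs — gene catalog, burden
# expression library (0-20 reporter copies in six strains), and the
# deletion-mutant signature compendium — and write them as TSV/BED.

library(burdenlab)

dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 20240901L)
catalog <- gen_gene_catalog(cfg)
lib <- gen_burden_library(catalog, cfg)
comp <- gen_mutant_compendium(catalog, cfg)

write_tsv(lib$expression, "results/expression_burden.tsv")
write_tsv(lib$strains, "results/strain_table.tsv")
write_tsv(comp$signatures, "results/mutant_signatures.tsv")
write_tsv(comp$mutants, "results/mutant_metadata.tsv")
write_bed(catalog, "results/gene_catalog.bed")

top <- lib$strains[lib$strains$copy_number == max(lib$strains$copy_number), ]
message(sprintf(
  "library: %d genes (%d TATA), %d strains; at %d copies growth -%.0f%%, size +%.0f%%",
  nrow(catalog), sum(catalog$is_tata), nrow(lib$strains), top$copy_number,
  100 * (1 - top$relative_growth_rate), 100 * (top$relative_size - 1)))
message(sprintf("compendium: %d mutants (%s)", cfg$n_mutants,
                paste(table(comp$mutants$class), collapse = "/")))
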