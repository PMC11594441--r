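#!/usr/bin/env Rscript

# Generate the synthetic study: a multiscale interactome (scale-free PPI
# layer, function hierarchy, sparse annotations), a connected disease
# module, and a herb catalog in which 20% of herbs are planted to target the
# module's direct neighborhood. Writes the study in the pipeline's on-disk
# formats plus the ground truth, so downstream steps can be re-run from
# files alone.

suppressPackageStartupMessages(library(herbwalk))

cfg <- synthetic_config(rng_seed = 1L)
study <- generate_study(cfg)

dir.create("results", showWarnings = FALSE)
paths <- write_study(study, "results/study")
writeLines(study$truth$planted, "results/study/planted_herbs.txt")

s <- summarize_network(study$network)
cat(sprintf("network: %d proteins, %d functions; %d ppi / %d annotation / %d hierarchy edges\n",
            s$proteins, s$functions, s$ppi, s$annotation, s$hierarchy))
cat(sprintf("catalog: %d herbs, %d ingredients, %d ingredient-target pairs\n",
            length(study$catalog$herbs), length(study$catalog$ingredients),
            nrow(study$catalog$ingredient_target)))
cat(sprintf("disease module: %d proteins; planted herbs: %s\n",
            length(study$disease$proteins),
            paste(study$truth$planted, collapse = ", ")))
cat("study written under results/study/\n")
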