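#!/usr/bin/env Rscript

# Ingredient-level ranking for the top planted herb: each ingredient is
# seeded with its full target set and scored against the disease profile,
# with the overlap denominator equal to that set's size.

suppressPackageStartupMessages(library(herbwalk))

study_dir <- "results/study"
cfg <- pipeline_config(
  network = c(ppi = file.path(study_dir, "ppi.tsv"),
              annotation = file.path(study_dir, "annotation.tsv"),
              hierarchy = file.path(study_dir, "hierarchy.tsv")),
  catalog = c(herb_ingredient = file.path(study_dir, "herb_ingredient.tsv"),
              ingredient_target = file.path(study_dir, "ingredient_target.tsv")),
  disease = file.path(study_dir, "disease_proteins.txt"),
  out_dir = "results"
)

ranking <- read.csv("results/herb_ranking.csv")
herb <- ranking$entity[1]
cat(sprintf("ranking ingredients of the top herb, %s\n\n", herb))

rk <- run_rank_ingredients(cfg, herb)
print(rk[, c("rank", "entity", "correlation_score", "overlap_k", "n_targets",
             "hypergeom_p", "enrichment", "prioritized")], row.names = FALSE)
cat(sprintf("\ntable: results/ingredient_ranking_%s.csv\n", herb))
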