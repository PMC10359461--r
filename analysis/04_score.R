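#!/usr/bin/env Rscript
# Stage 4: score per-component target avoidance across the taxonomic
# hierarchy for every species, subsampling each pangenome component to a
# fixed 10 kb before scoring so components are compared at equal power.

library(rmavoid)

seed <- 42L
out_dir <- "results"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

world <- generate_world(world_config(seed = seed))
prot <- plant_world_proteomes(world, seed = seed)
calls <- call_rm_systems(find_enzyme_hits(prot$proteome, prot$db, "all"))
genome_targets <- lapply(setNames(nm = unique(prot$proteome$genome_id)),
                         function(g) unique_genome_targets(calls, g))
mat <- build_presence_matrix(genome_targets, world$genome_species, k = 6,
                             species = world$taxonomy$species)
dict <- build_dictionary(mat, world$taxonomy)

scores <- do.call(rbind, lapply(world$taxonomy$species, function(sp) {
  prof <- component_avoidance_profile(world$genomes[[sp]], sp, dict, k = 6,
                                      subsample_length = 10000, seed = seed)
  cbind(species = sp, prof)
}))
write.table(scores, file.path(out_dir, "scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ok <- scores[scores$flag == "ok", ]
summ <- aggregate(median_z ~ component + level, data = ok, FUN = mean)
summ <- summ[order(match(summ$component, c("core", "non-core", "plasmid")),
                   match(summ$level, c("species", "genus", "family", "order",
                                       "class", "phylum", "kingdom"))), ]
cat("mean (over species) of median exceptionality by component and level:\n")
print(summ, row.names = FALSE, digits = 3)

sp_level <- ok[ok$level == "species", ]
by_comp <- tapply(sp_level$median_z, sp_level$component, mean)
cat(sprintf("\nat the species level: core %.2f, non-core %.2f, plasmid %.2f\n",
            by_comp[["core"]], by_comp[["non-core"]], by_comp[["plasmid"]]))
cat("plasmid genes avoid within-species targets more than chromosomal genes:",
    by_comp[["plasmid"]] < min(by_comp[["core"]], by_comp[["non-core"]]), "\n")
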