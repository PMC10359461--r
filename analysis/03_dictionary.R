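#!/usr/bin/env Rscript
# Stage 3: build the species x target presence matrix and the taxonomic
# target dictionary from the stage-2 detections.

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
write_presence_matrix(mat, file.path(out_dir, "presence_matrix.tsv"))

dict_long <- do.call(rbind, lapply(names(dict), function(sp)
  do.call(rbind, lapply(names(dict[[sp]]), function(lv) data.frame(
    species = sp, level = lv, n_targets = length(dict[[sp]][[lv]]),
    targets = paste(dict[[sp]][[lv]], collapse = ","))))))
write.table(dict_long, file.path(out_dir, "dictionary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("presence matrix: %d species x %d 6-mer targets\n",
            nrow(mat), ncol(mat)))
cat("target-set sizes up the hierarchy (first species):\n")
sp1 <- names(dict)[1]
print(vapply(dict[[sp1]], length, integer(1)))
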