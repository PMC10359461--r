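#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study world.
#
# Builds a seeded world of 8 species in a balanced taxonomy, each carrying 3
# palindromic 6-bp R-M targets, with per-species genomes split into core,
# non-core and plasmid gene components. Plasmid genes are depleted of the
# species' own targets (f = 0.8), emulating selection by within-species
# restriction. Also plants each species' systems as proteins so stage 2 can
# re-detect them from sequence alone.

library(rmavoid)

seed <- 42L
out_dir <- "results/world"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- world_config(seed = seed)
world <- generate_world(cfg)
prot <- plant_world_proteomes(world, seed = seed)

write.table(world$taxonomy, file.path(out_dir, "taxonomy.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (sp in world$taxonomy$species) {
  g <- world$genomes[[sp]]
  write_fasta(setNames(g$sequence, g$gene_id),
              file.path(out_dir, paste0(sp, "_genes.fasta")), type = "dna")
}
write_fasta(setNames(prot$db$sequence, prot$db$id),
            file.path(out_dir, "enzyme_db.fasta"), type = "protein")
write.table(prot$db[, c("id", "class", "motif", "tier")],
            file.path(out_dir, "enzyme_db.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(prot$proteome[, c("genome_id", "replicon_id", "ordinal",
                              "protein_id")],
            file.path(out_dir, "gene_order.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("world: %d species, %d distinct planted targets, %d proteome genes\n",
            nrow(world$taxonomy),
            length(unique(unlist(world$species_targets))),
            nrow(prot$proteome)))
cat("planted targets per species:\n")
for (sp in world$taxonomy$species)
  cat(" ", sp, ":", paste(world$species_targets[[sp]], collapse = " "), "\n")
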