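#!/usr/bin/env Rscript
# Build the synthetic study repertoire: a CIS-BP-dialect extract shaped
# like the human TF repertoire (theta = 0.74 background over 424 families,
# three over-expanded families of sizes 41/34/25, 50 excess singletons,
# eight DBD classes), with full ground truth. Downstream steps treat the
# emitted files exactly as they would treat a real database extract.

suppressPackageStartupMessages(library(bdifam))

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
# defaults encode the human-shaped regime; one class is generated at a
# much lower theta to emulate a fast-diversifying (zinc-finger-like) DBD
spec <- synthetic_spec(class_theta = c(DBD_08 = 0.45), seed = 11)
ds <- generate_dataset(spec)
print(ds)

paths <- write_synthetic(ds, "scratch/fixtures/human_like")
cat("wrote", length(paths), "files under scratch/fixtures/human_like\n")

# a ladder of smaller synthetic "species" for the cross-species comparison:
# increasing repertoire size with increasing redundancy
ladder <- data.frame(
  species = c("microsporidia_like", "yeast_like", "worm_like", "fly_like",
              "mouse_like"),
  theta = c(0.30, 0.40, 0.52, 0.62, 0.72),
  n_families = c(50, 90, 160, 260, 400))
for (i in seq_len(nrow(ladder))) {
  sp <- synthetic_spec(theta = ladder$theta[i],
                       n_families = ladder$n_families[i],
                       spikes = integer(0), extra_singletons = 0,
                       n_dbd_classes = 4, seed = 20 + i)
  write_synthetic(generate_dataset(sp),
                  file.path("scratch/fixtures", ladder$species[i]))
}
cat("wrote", nrow(ladder), "species-ladder fixtures\n")
write.table(ladder, "scratch/fixtures/species_ladder.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
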