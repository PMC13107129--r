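#!/usr/bin/env Rscript
# Generate the synthetic study data: five protein families (one rigid
# scaffold each, members = rigid motion + coordinate noise + sequence
# divergence) and a batch of replicons carrying a rep ORF followed by a
# noncoding region with a planted inverted repeat (156-166) and hairpin
# (from 176) at betapleolipovirus-like offsets.

library(repscan)

seed <- 11L
out <- "results/simulated"
dir.create(file.path(out, "pdb"), recursive = TRUE, showWarnings = FALSE)

cfg <- family_config(seed = stage_seed(seed, "simulate_families"))
ds <- make_family_dataset(cfg)
message(length(ds$structures), " structures in ", cfg$n_families,
        " families (chain length ", cfg$chain_length, ", sigma ",
        cfg$coord_noise_sigma, " A, substitution rate ",
        cfg$substitution_rate, ")")

write_fasta(ds$sequences, file.path(out, "members.fasta"))
utils::write.table(ds$labels, file.path(out, "families.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (s in ds$structures) {
  write_structure_pdb(s, file.path(out, "pdb", paste0(s$id, ".pdb")))
}

reps <- lapply(1:5, function(k)
  make_replicon(replicon_config(seed = stage_seed(seed,
                                                  paste0("replicon_", k)))))
write_fasta(do.call(rbind, lapply(reps, `[[`, "record")),
            file.path(out, "replicons.fasta"))
write_annotations(do.call(rbind, lapply(reps, `[[`, "annotations")),
                  file.path(out, "replicons.gff3"))
message(length(reps), " replicons written with planted ori annotations")
message("outputs under ", out)
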