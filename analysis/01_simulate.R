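#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
# A 24-residue ideal helix and its bulky planar mutant (PDB), five WT and
# five mutant replicate per-residue score tables with planted site/sphere
# energy shifts, and a 51-sample two-protein phenotype table with a known
# sparse feature signal.

suppressPackageStartupMessages(library(acdtol))
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260926
cfg <- synth_config(seed = seed)

helix <- make_helix_structure(cfg)
site <- paste0("A:", cfg$site)
mut <- make_bulky_mutant(helix, site, cfg$sidechain_size)
write_pdb(helix, file.path(out, "wt_helix.pdb"))
write_pdb(mut, file.path(out, "mut_helix.pdb"))
message("wrote WT (", nrow(helix$atoms), " atoms) and mutant (",
        nrow(mut$atoms), " atoms) structures; site ", site)

st <- make_score_tables(cfg)
for (i in seq_along(st$wt)) {
  write_score_table(st$wt[[i]], file.path(out, sprintf("scores_wt_rep%d.tsv", i)))
  write_score_table(st$mut[[i]], file.path(out, sprintf("scores_mut_rep%d.tsv", i)))
}
message("wrote ", 2 * cfg$replicates, " replicate score tables (",
        length(cfg$terms), " terms, planted site/sphere shifts ",
        cfg$site_shift, " / ", cfg$sphere_shift, " REU, noise sd ",
        cfg$score_noise_sd, ")")

ds <- make_labeled_dataset(cfg)
write.csv(ds$records, file.path(out, "phenotypes.csv"), row.names = FALSE)
write.csv(cbind(ds$records[, c("protein", "site")], as.data.frame(ds$X)),
          file.path(out, "features.csv"), row.names = FALSE)
message("wrote phenotype table: ", nrow(ds$records), " mutants (",
        paste(names(table(ds$records$protein)), table(ds$records$protein),
              sep = "=", collapse = ", "),
        "), labels balanced ", sum(ds$labels == "active"), " active / ",
        sum(ds$labels == "inactive"), " inactive")
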