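#!/usr/bin/env Rscript
# Stage 6 -- protein-lipid contact persistence and the disease-variant
# intersection. A full-length (2261-residue) dummy transporter is embedded
# in the bilayer and a contact schedule scripts persistent lipid partners at
# a designed residue set that includes the eleven disease-variant positions
# shipped in inst/extdata/abca1_variants.csv; the pipeline must recover the
# stable residues (total contact time strictly over the threshold) and the
# annotation intersection.
#
# Writes: results/contact_table.csv, results/stable_residues.csv,
#         results/lipid_type_frequency.csv, results/variant_intersection.csv

suppressMessages(library(memscape))
seed <- 1
n_frames <- 120          # 24 ns at 200 ps; persistence threshold scaled to 10 ns
min_time <- 10

base <- build_bilayer(bilayer_spec(), seed = seed)
system <- embed_protein(base, n_residues = 2261, radius = 14)
lips <- system$residues$resid[startsWith(system$residues$class, "lipid:")]

ann <- read_annotation(system.file("extdata", "abca1_variants.csv",
                                   package = "memscape"))
design <- sort(unique(c(ann$residue_id, c(120, 450, 900, 1500, 2000))))
# stable partners: in contact for 60 of 120 frames (12 ns > 10 ns threshold);
# one sub-threshold pair at exactly 50 frames (10.0 ns, excluded by strict >)
sch <- do.call(rbind, lapply(seq_along(design), function(i)
  contact_schedule(design[i], lips[i], 0, 60)))
sch <- rbind(sch, contact_schedule(300, lips[length(design) + 1], 0, 50))

stream <- simulate_frames(system, n_frames,
                          motion_model(jitter = 0, schedule = sch),
                          seed = seed, dt = 200)
tab <- persistence(stream, system, cutoff = 5)
write.csv(tab, "results/contact_table.csv", row.names = FALSE)

stable <- stable_residues(tab, min_time_ns = min_time)
write.csv(stable, "results/stable_residues.csv", row.names = FALSE)
cat(sprintf("%d residues with > %g ns of lipid contact\n", nrow(stable), min_time))
cat(sprintf("(a scheduled lipid sits in the crowded first shell of the coarse C-alpha cylinder, so spatial neighbours of the %d designed anchors accumulate time too; all anchors recovered: %s; residue 300 at exactly %g ns is excluded by the strict rule: %s)\n",
            length(design),
            ifelse(all(design %in% stable$protein_resid), "yes", "NO"),
            min_time, ifelse(300 %in% stable$protein_resid, "NO", "yes")))

freq <- lipid_type_frequency(tab, min_time_ns = min_time)
write.csv(freq, "results/lipid_type_frequency.csv", row.names = FALSE)
cat("Stable-shell lipid types (partnerships):\n")
print(freq, row.names = FALSE)

hit <- annotate_variants(stable, ann)
write.csv(hit, "results/variant_intersection.csv", row.names = FALSE)
cat(sprintf("%d of the %d stable residues are disease-variant positions: %s\n",
            nrow(hit), nrow(stable), paste(hit$variant_label, collapse = ", ")))
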