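#!/usr/bin/env Rscript
# Stage 5 -- lipid clustering on the census grid: the last trajectory frame
# is split into monolayers by mean centroid z, each monolayer is tiled with
# 6 A square cells, and per-type lipid counts are tallied with
# protein-occupied cells flagged.
#
# Reads:  results/system.pdb, results/trajectory.pdb (stage 1)
# Writes: results/census_<type>_<monolayer>.{csv,json} and _protein.csv

suppressMessages(library(memscape))
system <- read_structure("results/system.pdb")
stream <- read_frames("results/trajectory.pdb", system, dt = 200)
last <- frame_coords(stream, stream$n_frames)

for (type in c("POPC", "PSM")) {
  for (mono in c("top", "bottom")) {
    cg <- monolayer_census(system, type, mono, edge = 6, xyz = last)
    write_census_grid(cg, sprintf("results/census_%s_%s", tolower(type), mono))
    cat(sprintf("%s/%s: %d lipids over %dx%d cells; %d protein-flagged cells; max count %d\n",
                type, mono, cg$n_lipids, nrow(cg$counts), ncol(cg$counts),
                sum(cg$protein), max(cg$counts)))
  }
}
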