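#!/usr/bin/env Rscript
# Step 1: generate the synthetic AFM dataset.
#
# Renders the default 3 x 3 condition grid (DHA 0/30/100 uM x 1/6/24 h,
# 8 images per condition, 5 x 5 um scenes at 512 px) with known per-object
# ground truth, writes the images as 32-bit float TIFFs plus a manifest
# and ground-truth CSV. Images are bulky and reproducible from the seed,
# so they go under scratch/; the small tables that later steps need are
# copied to results/.

suppressMessages(library(fibriltrace))

seed <- 20260926L
scene_dir <- "scratch/scenes"
dir.create("results", showWarnings = FALSE)
dir.create(scene_dir, recursive = TRUE, showWarnings = FALSE)

message("rendering 9 conditions x 8 images (seed ", seed, ") ...")
entries <- generate_condition_grid(grid_config(), seed = seed,
                                   out_dir = scene_dir)

manifest <- attr(entries, "manifest")
truth <- attr(entries, "truth_table")
# the generator also writes manifest.csv and ground_truth.csv next to the
# images in scratch/scenes; later steps read them from there

n_fib <- sum(truth$kind == "fibril")
message(sprintf("wrote %d images to %s (%d fibrils, %d oligomers in truth)",
                nrow(manifest), scene_dir, n_fib, sum(truth$kind == "oligomer")))
message("per-condition true mean fibril lengths (nm):")
fib <- truth[truth$kind == "fibril", ]
key <- sub("_r[0-9]+$", "", fib$source_id)
print(round(tapply(fib$true_length_nm, key, mean), 1))
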