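#!/usr/bin/env Rscript
# Stage 1: build the binding-site cluster design library and simulate the
# raw datasets every later stage consumes — an iMITOMI-style saturation
# binding table (per-chamber bound/DNA fluorescence across 8 log-spaced
# free-TF concentration sections) and a plate-reader induction experiment
# (OD600/GFP/mScarlet every 10 min for 20 h, induced and uninduced).

suppressPackageStartupMessages(library(bindclust))

seed <- 20260930L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lib <- fixture_library(consensus_kd = 10, motif_length = 9L)
cat(sprintf("design library: %d targets (%d with overlapping sites)\n",
    length(lib),
    sum(vapply(lib, function(d) any(bindclust:::clash_matrix(d)), logical(1)))))

write_designs(lib, file.path(out, "designs.csv"))
emit_fasta(lib, file.path(out, "targets.fasta"))

imitomi <- simulate_imitomi(lib, seed = seed)
utils::write.csv(imitomi$measurements, file.path(out, "imitomi_measurements.csv"),
                 row.names = FALSE)
utils::write.csv(imitomi$truth, file.path(out, "imitomi_truth.csv"),
                 row.names = FALSE)
cat(sprintf("iMITOMI simulation: %d chamber measurements across %d targets\n",
            nrow(imitomi$measurements), length(lib)))

# plate-reader library: the minimal-promoter strains (site-count, affinity
# and mixed-affinity families) plus the NS reference strain
strains <- lib[c("NS", "S1", "S3", "S6", paste0("W", 1:6),
                 "Vm3", "Vm6", "Wm6", "W3Vm3", "W3Vm3r")]
plate <- simulate_platereader(strains, induced_conc = 500, seed = seed + 1L)
utils::write.csv(plate$series, file.path(out, "platereader_series.csv"),
                 row.names = FALSE)
utils::write.csv(plate$truth, file.path(out, "platereader_truth.csv"),
                 row.names = FALSE)
jsonlite::write_json(plate$blanks, file.path(out, "platereader_blanks.json"),
                     auto_unbox = TRUE)
cat(sprintf("plate-reader simulation: %d strains, %d readings\n",
            length(strains), nrow(plate$series)))

# provenance record so every stage can be re-run bit-identically
jsonlite::write_json(
  list(seed = seed, consensus_kd_nM = 10, motif_length_bp = 9,
       package_version = as.character(utils::packageVersion("bindclust"))),
  file.path(out, "provenance.json"), auto_unbox = TRUE)
cat("wrote", out, "\n")
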