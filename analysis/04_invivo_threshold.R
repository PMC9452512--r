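#!/usr/bin/env Rscript
# Stage 4: in-vivo analysis of the simulated plate-reader library. Each
# strain's GFP is blank-subtracted, normalized by OD600 and averaged over
# the 8.5-9.5 h post-induction window; TF-specific responses are
# induced-minus-uninduced differences and non-specific responses are
# uninduced differences against the NS reference strain. Mean occupancies
# predicted from the in-vitro parameters (over a sweep of plausible nuclear
# TF concentrations) are then related to the specific response through the
# thresholded activation model.

suppressPackageStartupMessages(library(bindclust))

dat <- "results/data"
series <- utils::read.csv(file.path(dat, "platereader_series.csv"))
blanks <- jsonlite::fromJSON(file.path(dat, "platereader_blanks.json"))
designs <- read_designs(file.path(dat, "designs.csv"))
names(designs) <- vapply(designs, `[[`, character(1), "target_id")

win_means <- function(strain, cond) {
  d <- series[series$strain_id == strain & series$condition == cond, ]
  vapply(split(d, d$replicate), function(r) {
    window_average(normalize_series(r, blank_gfp = blanks$gfp,
                                    blank_od = blanks$od))$mean
  }, numeric(1))
}

strains <- unique(series$strain_id)
resp <- do.call(rbind, lapply(strains, function(s) {
  sp <- specific_response(win_means(s, "induced"), win_means(s, "uninduced"))
  ns <- nonspecific_response(win_means(s, "uninduced"),
                             win_means("NS", "uninduced"))
  data.frame(strain_id = s, n_sites = designs[[s]]$n_sites,
             induced = sp$induced_mean, uninduced = sp$uninduced_mean,
             specific_response = sp$response,
             nonspecific_response = ns$response)
}))
utils::write.csv(resp, "results/invivo_responses.csv", row.names = FALSE)
cat("promoter responses (GFP/OD, 8.5-9.5 h window):\n")
print(resp, row.names = FALSE, digits = 3)

# predicted occupancies across the plausible nuclear concentration range
# (zinc-finger copy-number estimates translate to roughly 213-1322 nM;
# the central value is used for the threshold fit, the sweep for sensitivity)
conc_sweep <- c(213, 500, 1322)
occ <- do.call(rbind, lapply(conc_sweep, function(cc) {
  p <- predict_occupancy(designs[strains], cc)
  p$nuclear_conc_nM <- cc
  p
}))
utils::write.csv(occ, "results/predicted_occupancies.csv", row.names = FALSE)

fit_at <- function(cc, n_boot = 0L) {
  p <- predict_occupancy(designs[strains], cc)
  fit_threshold_model(p$n_mean[match(resp$strain_id, p$target_id)],
                      resp$specific_response, n_boot = n_boot, seed = 7)
}
tm <- fit_at(500, n_boot = 200L)
cat(sprintf("threshold fit at 500 nM: theta = %.2f, slope = %.0f, baseline = %.1f\n",
            tm$theta, tm$slope, tm$baseline))
sens <- vapply(conc_sweep, function(cc) fit_at(cc)$theta, numeric(1))
cat(sprintf(paste0("a thresholded relationship is identifiable across the ",
                   "%d-%d nM sweep;\nfitted theta rescales with the assumed ",
                   "concentration (%s) because the\npredicted occupancies do\n"),
            min(conc_sweep), max(conc_sweep),
            paste(sprintf("%.2f", sens), collapse = ", ")))
jsonlite::write_json(
  list(theta = tm$theta, slope = tm$slope, baseline = tm$baseline,
       rss = tm$rss, theta_ci = tm$theta_ci,
       theta_by_conc = as.list(stats::setNames(sens, paste0("nM", conc_sweep)))),
  "results/threshold_fit.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/threshold_fit.json\n")
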