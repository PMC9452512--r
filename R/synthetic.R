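#' Fixture library of binding-site cluster designs
#'
#' Builds the design families the analyses exercise: single and multi-site
#' strong clusters (S1/S3/S6), weak clusters W1-W6, very-weak clusters
#' (V-3/V-6) and W-6, mixed-affinity W3V-3 with a reordered variant, a
#' two-site spacing series (gap 0-20 bp), overlap series in which
#' neighboring sites share exactly 1 or 3 bp (strong and weak, 2-4 sites),
#' a no-site NS target, and PHO5-style two-region promoters in which each
#' region carries a native site (N), is ablated (A), or is replaced by a
#' cluster of 5 weak sites (C). K_ds derive from the affinity-class table.
#'
#' @param consensus_kd consensus-site K_d, nM.
#' @param motif_length motif length for the synthetic-library families
#'   (default 9, Zif268-like).
#' @return named list of [cluster_design()] objects.
#' @export
fixture_library <- function(consensus_kd = 10, motif_length = 9L) {
  L <- motif_length
  mk_sites <- function(starts, classes, len = L, prefix = "s") {
    lapply(seq_along(starts), function(i) {
      binding_site(paste0(prefix, i), starts[i], len, classes[i],
                   consensus_kd = consensus_kd)
    })
  }
  evenly <- function(n, gap = 4L, first = 2L) first + (seq_len(n) - 1) * (L + gap)
  designs <- list()
  for (cl in list(c("S", 1), c("S", 3), c("S", 6),
                  c("W", 1), c("W", 2), c("W", 3), c("W", 4), c("W", 5), c("W", 6),
                  c("V-", 3), c("V-", 6), c("W-", 6))) {
    n <- as.integer(cl[2])
    id <- paste0(sub("-", "m", cl[1]), n)  # V- -> Vm in ids
    designs[[id]] <- cluster_design(id, mk_sites(evenly(n), rep(cl[1], n)))
  }
  # mixed-affinity cluster and a reordered variant
  designs[["W3Vm3"]] <- cluster_design(
    "W3Vm3", mk_sites(evenly(6), c(rep("W", 3), rep("V-", 3))))
  designs[["W3Vm3r"]] <- cluster_design(
    "W3Vm3r", mk_sites(evenly(6), c("W", "V-", "W", "V-", "W", "V-")))
  # spacing series: two weak sites, gap 0..20 bp
  for (gap in 0:20) {
    id <- sprintf("spacing_W_d%02d", gap)
    designs[[id]] <- cluster_design(
      id, mk_sites(c(10L, 10L + L + gap), c("W", "W")))
  }
  # overlap series: neighboring sites share 1 or 3 bp
  for (shared in c(1L, 3L)) {
    for (cl in c("S", "W")) {
      for (n in 2:4) {
        id <- sprintf("ovl%d_%s%d", shared, cl, n)
        starts <- 10L + (seq_len(n) - 1) * (L - shared)
        designs[[id]] <- cluster_design(id, mk_sites(starts, rep(cl, n)))
      }
    }
  }
  designs[["NS"]] <- cluster_design("NS", list())
  # PHO5-style two-region promoters (6-bp E-box motif): N native strong site,
  # A ablated, C cluster of five weak sites
  region <- function(kind, offset, prefix) {
    if (kind == "A") return(list())
    if (kind == "N") return(mk_sites(offset + 20L, "S", len = 6L,
                                     prefix = prefix))
    mk_sites(offset + (seq_len(5) - 1) * 10L, rep("W", 5), len = 6L,
             prefix = prefix)
  }
  for (nfr in c("N", "A", "C")) for (nor in c("N", "A", "C")) {
    id <- sprintf("pho5_%s-%s", nfr, nor)
    sites <- c(region(nfr, 20L, "nfr"), region(nor, 120L, "nor"))
    designs[[id]] <- cluster_design(id, sites, target_length = 200L)
  }
  designs
}

# Default model used to generate true occupancies: independent unless the
# design has overlapping sites, then permissive with the given clash energy.
model_for_design <- function(design, clash_energy = 2) {
  if (any(clash_matrix(design))) {
    statmech_model("permissive", clash_energy = clash_energy)
  } else {
    statmech_model("independent")
  }
}

#' Simulate an iMITOMI-style saturation binding dataset
#'
#' Emulates a multiplexed microfluidic binding assay: each target is measured
#' in replicate chambers across log-spaced free-TF concentration sections
#' (the chip geometry motivating the default of 8 sections and 20-84
#' chambers). Per chamber the DNA signal has small lognormal variability and
#' the bound signal is
#' `step_rfu * <N>_true(c) * (dna / dna_ref) + Gaussian noise`, with the
#' noise SD a fraction of the single-site saturation signal. The free
#' concentration is treated as known (the assay measures it directly).
#'
#' @param designs list of [cluster_design()] objects.
#' @param concentrations free-TF concentration sections, nM (default 8
#'   log-spaced values spanning 1-30000 nM).
#' @param chambers_per_section replicate chambers per concentration.
#' @param noise_sd Gaussian noise SD as a fraction of `step_rfu`.
#' @param step_rfu fluorescence per bound TF (RFU).
#' @param dna_ref reference DNA signal (RFU).
#' @param dna_cv lognormal sdlog of the per-chamber DNA signal.
#' @param clash_energy true clash energy for overlapping designs (k_BT).
#' @param mode generating model: `"auto"` (independent unless the design has
#'   overlapping sites, then permissive) or an explicit [statmech_model()]
#'   mode applied to every design.
#' @param seed integer seed; fixed seed gives identical tables.
#' @return list with `measurements` (chamber_id, target_id, free_conc_nM,
#'   bound_rfu, dna_rfu, experiment_id) and `truth` (per-design K_ds, clash
#'   energy, step, and the generating model mode).
#' @export
simulate_imitomi <- function(designs,
                             concentrations = 10^seq(0, log10(30000),
                                                     length.out = 8),
                             chambers_per_section = 30L,
                             noise_sd = 0.05,
                             step_rfu = 500,
                             dna_ref = 1000,
                             dna_cv = 0.1,
                             clash_energy = 2,
                             mode = c("auto", "independent", "permissive",
                                      "exclusive"),
                             seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(chambers_per_section >= 1, noise_sd >= 0, step_rfu > 0)
  set.seed(seed)
  meas <- list(); truth <- list()
  for (d in designs) {
    model <- if (mode == "auto") {
      model_for_design(d, clash_energy)
    } else if (mode == "permissive") {
      statmech_model("permissive", clash_energy = clash_energy)
    } else {
      statmech_model(mode)
    }
    n_true <- mean_occupancy(d, concentrations, model)
    rows <- do.call(rbind, lapply(seq_along(concentrations), function(j) {
      nc <- chambers_per_section
      dna <- dna_ref * stats::rlnorm(nc, 0, dna_cv)
      bound <- step_rfu * n_true[j] * (dna / dna_ref) +
        stats::rnorm(nc, 0, noise_sd * step_rfu)
      data.frame(
        chamber_id = sprintf("%s_c%d_r%02d", d$target_id, j, seq_len(nc)),
        target_id = d$target_id,
        free_conc_nM = concentrations[j],
        bound_rfu = bound,
        dna_rfu = dna,
        experiment_id = sprintf("exp%d", j %% 3 + 1)
      )
    }))
    meas[[d$target_id]] <- rows
    truth[[d$target_id]] <- data.frame(
      target_id = d$target_id, n_sites = d$n_sites,
      kds_nM = paste(site_kds(d), collapse = ";"),
      model = model$mode,
      clash_energy = if (model$mode == "permissive") clash_energy else NA_real_,
      step_rfu = step_rfu, schema_version = 1L
    )
  }
  list(measurements = do.call(rbind, c(meas, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Simulate a plate-reader induction experiment
#'
#' One strain per design plus conditions induced/uninduced, with logistic
#' OD600 growth and GFP proportional to OD at a per-strain production level:
#' `baseline + leak_per_site * n_sites` in both conditions, plus the hinge
#' `slope * max(0, <N> - theta)` when induced, where `<N>` is the design's
#' true mean occupancy at the induced nuclear TF concentration. mScarlet is
#' a constant control channel. Readings every 10 min over `duration_h` hours
#' carry Gaussian measurement noise and additive channel blanks.
#'
#' @param designs list of [cluster_design()] objects.
#' @param induced_conc nuclear TF concentration when induced, nM.
#' @param theta,slope,baseline hinge parameters of the occupancy-expression
#'   relationship (expression units are GFP/OD).
#' @param leak_per_site non-specific leak per binding site (GFP/OD units).
#' @param clash_energy clash energy for overlapping designs.
#' @param replicates replicates per strain and condition.
#' @param duration_h experiment length, hours (10-min cadence).
#' @param od0,od_k,od_r logistic growth: initial OD, carrying capacity, rate.
#' @param blank_od,blank_gfp additive channel blanks.
#' @param od_noise_sd,gfp_noise_sd Gaussian reading noise SDs.
#' @param seed integer seed.
#' @return list with `series` (strain_id, condition, replicate, time_h,
#'   od600, gfp, mscarlet), `blanks`, and `truth` (per-strain occupancy and
#'   generating parameters).
#' @export
simulate_platereader <- function(designs,
                                 induced_conc = 500,
                                 theta = 1, slope = 500, baseline = 20,
                                 leak_per_site = 10,
                                 clash_energy = 2,
                                 replicates = 3L,
                                 duration_h = 20,
                                 od0 = 0.1, od_k = 1.5, od_r = 0.4,
                                 blank_od = 0.04, blank_gfp = 5,
                                 od_noise_sd = 0.002, gfp_noise_sd = 1,
                                 seed = 1L) {
  set.seed(seed)
  time_h <- seq(0, duration_h, by = 1 / 6)
  od_true <- od_k / (1 + (od_k / od0 - 1) * exp(-od_r * time_h))
  series <- list(); truth <- list()
  for (d in designs) {
    n_occ <- if (d$n_sites > 0) {
      mean_occupancy(d, induced_conc, model_for_design(d, clash_energy))
    } else 0
    for (cond in c("induced", "uninduced")) {
      p <- baseline + leak_per_site * d$n_sites +
        if (cond == "induced") slope * max(0, n_occ - theta) else 0
      for (r in seq_len(replicates)) {
        od <- od_true + blank_od + stats::rnorm(length(time_h), 0, od_noise_sd)
        gfp <- p * od_true + blank_gfp +
          stats::rnorm(length(time_h), 0, gfp_noise_sd)
        ms <- 100 * od_true + blank_gfp +
          stats::rnorm(length(time_h), 0, gfp_noise_sd)
        series[[length(series) + 1]] <- data.frame(
          strain_id = d$target_id, condition = cond, replicate = r,
          time_h = time_h, od600 = od, gfp = gfp, mscarlet = ms
        )
      }
    }
    truth[[d$target_id]] <- data.frame(
      target_id = d$target_id, n_sites = d$n_sites, n_mean_induced = n_occ,
      theta = theta, slope = slope, baseline = baseline,
      leak_per_site = leak_per_site, schema_version = 1L
    )
  }
  list(series = do.call(rbind, c(series, list(make.row.names = FALSE))),
       blanks = list(od = blank_od, gfp = blank_gfp),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}
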