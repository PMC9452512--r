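#' Normalize a plate-reader time series
#'
#' Per time point: `(GFP - blank_gfp) / (OD - blank_od)`, the media
#' background subtracted from each channel and the expression signal divided
#' by the cell density. Points whose blank-subtracted OD falls below
#' `od_floor` are masked (`NA`) to avoid division blow-ups early in growth.
#'
#' @param series data.frame with columns `time_h`, `od600`, and a signal
#'   column (`gfp` by default).
#' @param blank_gfp,blank_od per-channel media blanks.
#' @param signal name of the signal column.
#' @param od_floor minimum blank-subtracted OD for a usable point.
#' @return the series with an added `norm_expr` column (signal per OD).
#' @export
normalize_series <- function(series, blank_gfp = 0, blank_od = 0,
                             signal = "gfp", od_floor = 0.01) {
  stopifnot(all(diff(series$time_h) > 0))
  od <- series$od600 - blank_od
  g <- series[[signal]] - blank_gfp
  ok <- od >= od_floor
  if (!any(ok)) stop("all points below OD floor")
  out <- series
  out$norm_expr <- ifelse(ok, g / od, NA_real_)
  out
}

#' Average a normalized series over a time window
#'
#' Arithmetic mean of `norm_expr` over readings inside the closed window
#' (default 8.5-9.5 h after induction; at a 10-minute cadence aligned to
#' induction that is 7 readings).
#'
#' @param series output of [normalize_series()].
#' @param window closed time window in hours.
#' @return list with `mean` and `n_readings`.
#' @export
window_average <- function(series, window = c(8.5, 9.5)) {
  inw <- series$time_h >= window[1] & series$time_h <= window[2] &
    !is.na(series$norm_expr)
  if (!any(inw)) stop("empty window")
  list(mean = mean(series$norm_expr[inw]), n_readings = sum(inw))
}

#' TF-specific promoter response
#'
#' Difference in windowed expression between induced and uninduced
#' conditions. Replicate policy: when both conditions have the same number of
#' replicates they are treated as unpaired; the response is the difference of
#' condition means, with the per-replicate values retained for spread.
#'
#' @param induced,uninduced numeric vectors of window means (replicates).
#' @return list with `response` (mean difference), `induced_mean`,
#'   `uninduced_mean`, and the replicate vectors.
#' @export
specific_response <- function(induced, uninduced) {
  if (length(induced) == 0 || length(uninduced) == 0) {
    stop("missing condition")
  }
  list(response = mean(induced) - mean(uninduced),
       induced_mean = mean(induced), uninduced_mean = mean(uninduced),
       induced = induced, uninduced = uninduced)
}

#' Non-specific promoter response
#'
#' Difference in uninduced windowed expression between a promoter strain and
#' the designated reference strain (the no-site NS promoter for the synthetic
#' library; the ablated-ablated AA promoter for PHO5-style libraries). May be
#' negative.
#'
#' @param strain_uninduced,reference_uninduced numeric vectors of uninduced
#'   window means.
#' @return list with `response` and the two condition means.
#' @export
nonspecific_response <- function(strain_uninduced, reference_uninduced) {
  if (length(reference_uninduced) == 0) stop("reference missing")
  if (length(strain_uninduced) == 0) stop("missing condition")
  list(response = mean(strain_uninduced) - mean(reference_uninduced),
       strain_mean = mean(strain_uninduced),
       reference_mean = mean(reference_uninduced))
}

#' Convert molecules per cell to a nuclear concentration
#'
#' `c = copies / (N_A * V)`, reported in nM. The nuclear volume is an
#' explicit parameter: ~4.2 fL reproduces the published yeast estimates
#' (538 copies -> ~213 nM; 3334 copies -> ~1318 nM).
#'
#' @param copies molecules per cell (>= 0).
#' @param volume_fl nuclear volume in femtoliters (> 0).
#' @return concentration in nM.
#' @export
copies_to_concentration <- function(copies, volume_fl) {
  stopifnot(all(copies >= 0))
  if (any(volume_fl <= 0)) stop("nuclear volume must be > 0")
  avogadro <- 6.02214076e23
  copies / (avogadro * volume_fl * 1e-15) * 1e9
}

#' Predict in-vivo mean occupancy of promoter designs
#'
#' Delegates to the statistical-mechanical occupancy model at the supplied
#' nuclear TF concentration: independent binding by default, permissive
#' (with the given clash energy) for designs containing overlapping sites.
#'
#' @param designs list of [cluster_design()] objects.
#' @param nuclear_conc nuclear TF concentration, nM.
#' @param clash_energy clash energy (k_BT) used for overlapping designs.
#' @return data.frame with `target_id`, `n_sites`, `n_mean`.
#' @export
predict_occupancy <- function(designs, nuclear_conc, clash_energy = 2) {
  rows <- lapply(designs, function(d) {
    model <- if (any(clash_matrix(d))) {
      statmech_model("permissive", clash_energy = clash_energy)
    } else {
      statmech_model("independent")
    }
    data.frame(target_id = d$target_id, n_sites = d$n_sites,
               n_mean = mean_occupancy(d, nuclear_conc, model))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit a thresholded occupancy-to-expression model
#'
#' Least-squares fit of the hinge
#' `expression = baseline + slope * max(0, <N> - theta)`: expression is
#' silent up to an occupancy threshold theta (empirically around one bound
#' TF), then increases with mean occupancy. Theta is profiled over a grid of
#' candidate values (baseline and slope are linear given theta), then
#' refined by golden-section search; the CI is a promoter-resampling
#' bootstrap. The threshold is declared unidentifiable when the occupancies
#' do not straddle the fitted threshold or when the hinge explains less than
#' half of the expression variance (as when every promoter sits below the
#' true threshold and expression is flat).
#'
#' @param occupancies predicted mean occupancies, one per promoter.
#' @param expressions measured expression (e.g. GFP/OD window means).
#' @param n_boot bootstrap replicates for the theta CI (0 to skip).
#' @param seed seed for the bootstrap.
#' @param n_grid number of candidate thresholds profiled.
#' @return An object of class `threshold_model`: list with `theta`, `slope`,
#'   `baseline`, `rss`, `theta_ci` (5-95% bootstrap), `predict` (function of
#'   occupancy).
#' @export
fit_threshold_model <- function(occupancies, expressions, n_boot = 200L,
                                seed = 1L, n_grid = 200L) {
  stopifnot(length(occupancies) == length(expressions))
  if (length(occupancies) < 4) stop("need >= 4 promoters")
  fit_once <- function(occ, y) {
    lo <- min(occ); hi <- max(occ)
    if (hi - lo < 1e-12) return(NULL)
    rss_at <- function(th) {
      x <- pmax(0, occ - th)
      if (stats::sd(x) < 1e-12) return(Inf)
      m <- stats::lm(y ~ x)
      sum(stats::resid(m)^2)
    }
    grid <- seq(lo, hi - (hi - lo) / n_grid, length.out = n_grid)
    rssv <- vapply(grid, rss_at, numeric(1))
    if (!any(is.finite(rssv))) return(NULL)
    i <- which.min(rssv)
    lo_b <- grid[max(1, i - 1)]; hi_b <- grid[min(n_grid, i + 1)]
    th <- stats::optimize(rss_at, c(lo_b, hi_b), tol = 1e-9)$minimum
    if (rss_at(th) > rssv[i]) th <- grid[i]
    x <- pmax(0, occ - th)
    m <- stats::lm(y ~ x)
    list(theta = th, baseline = unname(stats::coef(m)[1]),
         slope = unname(stats::coef(m)[2]), rss = sum(stats::resid(m)^2))
  }
  # identifiability: occupancies must straddle the fitted threshold and the
  # hinge must actually explain the expression variation (if every promoter
  # sits below the true threshold the expression is flat and carries no
  # information on theta)
  main <- fit_once(occupancies, expressions)
  tss <- sum((expressions - mean(expressions))^2)
  if (is.null(main) ||
      sum(occupancies > main$theta) < 2 ||
      sum(occupancies <= main$theta) < 1 ||
      (tss > 0 && 1 - main$rss / tss < 0.5)) {
    stop("threshold unidentifiable: occupancies do not straddle a feasible threshold or expression does not depend on occupancy")
  }
  theta_ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    nb <- length(occupancies)
    th_b <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nb, nb, replace = TRUE)
      f <- tryCatch(fit_once(occupancies[idx], expressions[idx]),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$theta
    }, numeric(1))
    th_b <- th_b[is.finite(th_b)]
    if (length(th_b) > 10) {
      theta_ci <- unname(stats::quantile(th_b, c(0.05, 0.95)))
    }
  }
  structure(
    c(main, list(theta_ci = theta_ci,
                 predict = function(occ) {
                   main$baseline + main$slope * pmax(0, occ - main$theta)
                 })),
    class = "threshold_model"
  )
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> theta = %.3f, slope = %.4g, baseline = %.4g (RSS %.4g)\n",
              x$theta, x$slope, x$baseline, x$rss))
  if (!is.null(x$theta_ci)) {
    cat(sprintf("  theta 5-95%% bootstrap CI: [%.3f, %.3f]\n",
                x$theta_ci[1], x$theta_ci[2]))
  }
  invisible(x)
}
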