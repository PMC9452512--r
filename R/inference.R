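# Bound signal normalized by the per-chamber DNA signal (relative to the
# mean) when a dna_rfu column is available; otherwise used as-is.
dna_normalized_signal <- function(measurements) {
  y <- measurements$bound_rfu
  if ("dna_rfu" %in% names(measurements) &&
      all(is.finite(measurements$dna_rfu)) && all(measurements$dna_rfu > 0)) {
    y <- y / (measurements$dna_rfu / mean(measurements$dna_rfu))
  }
  y
}

#' Akaike / Bayesian information criterion for Gaussian least squares
#'
#' Gaussian-likelihood forms on the residual sum of squares:
#' `AIC = n ln(RSS/n) + 2k`, `BIC = n ln(RSS/n) + k ln(n)`. `k` should count
#' every estimated parameter including the noise variance, so that criterion
#' differences between nested models isolate the structural parameters.
#'
#' @param rss residual sum of squares (> 0).
#' @param n_obs number of observations (> k).
#' @param k number of estimated parameters (>= 1).
#' @return numeric criterion value.
#' @export
aic_gaussian <- function(rss, n_obs, k) {
  stopifnot(rss > 0, k >= 1, n_obs > k)
  n_obs * log(rss / n_obs) + 2 * k
}

#' @rdname aic_gaussian
#' @export
bic_gaussian <- function(rss, n_obs, k) {
  stopifnot(rss > 0, k >= 1, n_obs > k)
  n_obs * log(rss / n_obs) + k * log(n_obs)
}

#' Select the model with the lowest information criterion
#'
#' @param fits named list, each element a list carrying `aic` and `bic`.
#' @param criterion `"aic"` or `"bic"`.
#' @return name of the selected (lowest-criterion) model.
#' @export
select_model <- function(fits, criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  vals <- vapply(fits, function(f) f[[criterion]], numeric(1))
  names(fits)[which.min(vals)]
}

#' Fit a two-parameter saturation binding curve
#'
#' Least-squares fit of `B(c) = B_max * c / (K_d + c)` to one target's
#' chamber measurements. Initialization is deterministic: `K_d` starts at the
#' concentration whose mean signal is nearest half-maximal, `B_max` at the
#' maximum mean signal.
#'
#' @param measurements data.frame with columns `free_conc_nM` and `bound_rfu`
#'   (one row per chamber); a `target_id` column may be present and is
#'   carried through. When a `dna_rfu` column is present the bound signal is
#'   first normalized by the per-chamber DNA signal (relative to the mean DNA
#'   signal), the assay's convention for removing chamber-to-chamber DNA
#'   loading variability.
#' @return An object of class `sbc_fit`: list with `kd`, `bmax`, `rss`,
#'   `sigma` (residual SD, ML), `n_obs`, `aic`, `bic` (k = 3: K_d, B_max,
#'   sigma), `fitted_fn`, and NULL interval slots filled by
#'   [mcmc_credible_intervals()].
#' @export
fit_sbc <- function(measurements) {
  c_nM <- measurements$free_conc_nM
  y <- dna_normalized_signal(measurements)
  if (any(!is.finite(c_nM)) || any(!is.finite(y))) {
    stop("non-finite values in measurements")
  }
  if (length(unique(c_nM)) < 3) stop("fewer than 3 distinct concentrations")
  if (all(y == 0)) stop("all-zero signals")
  mu <- tapply(y, c_nM, mean)
  cs <- as.numeric(names(mu))
  if (stats::sd(mu) < 1e-12 * max(abs(mu), 1)) {
    stop("no concentration dependence")
  }
  bmax0 <- max(mu)
  kd0 <- cs[which.min(abs(mu - bmax0 / 2))]
  if (kd0 <= 0) kd0 <- min(cs[cs > 0])
  fit <- minpack.lm::nlsLM(
    y ~ bmax * c_nM / (kd + c_nM),
    start = list(bmax = bmax0, kd = kd0),
    lower = c(bmax = 1e-12, kd = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  n <- length(y)
  structure(
    list(kd = unname(est["kd"]), bmax = unname(est["bmax"]),
         kd_ci = NULL, bmax_ci = NULL, posterior = NULL, envelope = NULL,
         rss = rss, sigma = sqrt(rss / n), n_obs = n,
         aic = if (rss > 0) aic_gaussian(rss, n, 3) else -Inf,
         bic = if (rss > 0) bic_gaussian(rss, n, 3) else -Inf,
         target_id = if ("target_id" %in% names(measurements))
           measurements$target_id[1] else NA_character_,
         data = data.frame(free_conc_nM = c_nM, bound_rfu = y)),
    class = "sbc_fit"
  )
}

#' @export
print.sbc_fit <- function(x, ...) {
  cat(sprintf("<sbc_fit%s> K_d = %.4g nM, B_max = %.4g RFU, RSS = %.4g (n = %d)\n",
              if (!is.na(x$target_id)) paste0(" ", x$target_id) else "",
              x$kd, x$bmax, x$rss, x$n_obs))
  if (!is.null(x$kd_ci)) {
    cat(sprintf("  5-95%% CI: K_d [%.4g, %.4g], B_max [%.4g, %.4g]\n",
                x$kd_ci[1], x$kd_ci[2], x$bmax_ci[1], x$bmax_ci[2]))
  }
  invisible(x)
}

#' MCMC settings for credible-interval estimation
#'
#' Random-walk Metropolis on `(log K_d, log B_max, log sigma)` with flat
#' priors inside broad declared bounds, multiple chains, proposal-covariance
#' adaptation during burn-in, and a split-R-hat convergence gate.
#'
#' @param n_chains number of chains.
#' @param n_iter post-burn-in iterations per chain.
#' @param n_burnin burn-in (and adaptation) iterations per chain.
#' @param seed integer seed; the run is fully reproducible given the seed.
#' @param rhat_max convergence threshold on split-R-hat.
#' @param log_bounds 2x3 matrix of lower/upper bounds on the log-parameters
#'   relative to the point fit (rows lower/upper, columns logKd, logBmax,
#'   logSigma); defaults span +/- ~9 natural-log units.
#' @return list of settings.
#' @export
mcmc_settings <- function(n_chains = 4L, n_iter = 2000L, n_burnin = 1000L,
                          seed = 1L, rhat_max = 1.01, log_bounds = NULL) {
  list(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
       seed = seed, rhat_max = rhat_max, log_bounds = log_bounds)
}

# Split-R-hat (Gelman-Rubin on split chains) for a iterations x chains matrix.
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  mu <- colMeans(sp)
  B <- nn * stats::var(mu)
  W <- mean(apply(sp, 2, stats::var))
  if (W < .Machine$double.eps) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' MCMC credible intervals for a saturation-binding-curve fit
#'
#' Samples the posterior of `(log K_d, log B_max, log sigma)` under a
#' Gaussian likelihood and flat priors on the log-parameters within broad
#' bounds, using seeded multi-chain adaptive random-walk Metropolis. The
#' 5-95% credible intervals are the 5th/95th percentiles of the marginal
#' posteriors; the curve envelope is the pointwise 5th/95th percentile of
#' `B(c)` over posterior draws.
#'
#' @param fit an [fit_sbc()] result.
#' @param measurements the measurements the fit was computed from (defaults
#'   to those stored in the fit).
#' @param settings an [mcmc_settings()] list.
#' @param envelope_conc optional concentration grid for the curve envelope
#'   (default: 50 log-spaced points spanning the data).
#' @return the fit with `kd_ci`, `bmax_ci` (5-95%), `posterior` (data.frame
#'   of draws with columns `kd`, `bmax`, `sigma`), `envelope` (data.frame
#'   `conc_nM`, `lo`, `hi`), and `rhat` filled in.
#' @export
mcmc_credible_intervals <- function(fit, measurements = fit$data,
                                    settings = mcmc_settings(),
                                    envelope_conc = NULL) {
  c_nM <- measurements$free_conc_nM
  y <- measurements$bound_rfu
  n <- length(y)
  loglik <- function(th) {
    kd <- exp(th[1]); bmax <- exp(th[2]); sig <- exp(th[3])
    mu <- bmax * c_nM / (kd + c_nM)
    -n * log(sig) - sum((y - mu)^2) / (2 * sig^2)
  }
  th0 <- c(log(fit$kd), log(fit$bmax), log(max(fit$sigma, 1e-8)))
  lb <- settings$log_bounds
  if (is.null(lb)) lb <- rbind(th0 - 9, th0 + 9)
  # proposal covariance from the curvature of the log-likelihood at the mode
  # (numeric Hessian, including the strong logKd-logBmax correlation);
  # scalar scale adaptation during burn-in refines the acceptance rate
  prop_chol <- tryCatch({
    h <- 1e-4
    H <- matrix(0, 3, 3)
    for (i in 1:3) for (j in i:3) {
      ei <- replace(numeric(3), i, h); ej <- replace(numeric(3), j, h)
      H[i, j] <- H[j, i] <-
        (loglik(th0 + ei + ej) - loglik(th0 + ei - ej) -
           loglik(th0 - ei + ej) + loglik(th0 - ei - ej)) / (4 * h^2)
    }
    t(chol(solve(-H)))
  }, error = function(e) diag(c(0.05, 0.02, 0.1)))
  n_tot <- settings$n_burnin + settings$n_iter
  set.seed(settings$seed)
  chains <- vector("list", settings$n_chains)
  # independence-kernel proposal: Laplace approximation with inflated
  # covariance (heavier than the target so rejections are not sticky)
  ind_chol <- 1.5 * prop_chol
  log_q_ind <- function(v) {
    z <- forwardsolve(ind_chol, v - th0)
    -0.5 * sum(z^2)
  }
  for (ch in seq_len(settings$n_chains)) {
    th <- pmin(pmax(th0 + as.numeric(prop_chol %*% stats::rnorm(3)),
                    lb[1, ]), lb[2, ])
    ll <- loglik(th)
    scale <- 2.4 / sqrt(3)
    draws <- matrix(NA_real_, n_tot, 3)
    acc <- 0L; win <- 0L
    for (it in seq_len(n_tot)) {
      if (it %% 2L == 0L) {
        # independence Metropolis-Hastings step
        prop <- th0 + as.numeric(ind_chol %*% stats::rnorm(3))
        if (all(prop >= lb[1, ]) && all(prop <= lb[2, ])) {
          llp <- loglik(prop)
          if (log(stats::runif(1)) <
                (llp - log_q_ind(prop)) - (ll - log_q_ind(th))) {
            th <- prop; ll <- llp
          }
        }
      } else {
        # symmetric random-walk step
        prop <- th + scale * as.numeric(prop_chol %*% stats::rnorm(3))
        if (all(prop >= lb[1, ]) && all(prop <= lb[2, ])) {
          llp <- loglik(prop)
          if (log(stats::runif(1)) < llp - ll) {
            th <- prop; ll <- llp; acc <- acc + 1L
          }
        }
        win <- win + 1L
        # Robbins-Monro style scale adaptation during burn-in only
        if (it <= settings$n_burnin && win == 50L) {
          scale <- scale * exp(0.5 * (acc / 50 - 0.3))
          acc <- 0L; win <- 0L
        }
      }
      draws[it, ] <- th
    }
    chains[[ch]] <- draws[(settings$n_burnin + 1):n_tot, , drop = FALSE]
  }
  rhat <- vapply(1:3, function(p) {
    split_rhat(sapply(chains, function(d) d[, p]))
  }, numeric(1))
  if (max(rhat) > settings$rhat_max) {
    warning(sprintf("MCMC not converged (max split-R-hat %.4f > %.3f); intervals withheld",
                    max(rhat), settings$rhat_max))
    fit$rhat <- rhat
    return(fit)
  }
  post <- do.call(rbind, chains)
  kd_s <- exp(post[, 1]); bmax_s <- exp(post[, 2]); sig_s <- exp(post[, 3])
  fit$posterior <- data.frame(kd = kd_s, bmax = bmax_s, sigma = sig_s)
  fit$kd_ci <- unname(stats::quantile(kd_s, c(0.05, 0.95)))
  fit$bmax_ci <- unname(stats::quantile(bmax_s, c(0.05, 0.95)))
  if (is.null(envelope_conc)) {
    pos <- c_nM[c_nM > 0]
    envelope_conc <- exp(seq(log(min(pos)), log(max(pos)), length.out = 50))
  }
  env <- t(vapply(envelope_conc, function(cc) {
    b <- bmax_s * cc / (kd_s + cc)
    stats::quantile(b, c(0.05, 0.95))
  }, numeric(2)))
  fit$envelope <- data.frame(conc_nM = envelope_conc,
                             lo = env[, 1], hi = env[, 2])
  fit$rhat <- rhat
  fit
}

#' Calibrate the fluorescence-per-occupancy step
#'
#' Ordinary least-squares line `B_max(n) = step * n + intercept` over targets
#' whose site counts lie in `fit_range`. The slope is the fluorescence signal
#' corresponding to an occupancy of one TF bound per DNA molecule; dividing
#' bound signal by it converts RFU to mean occupancy.
#'
#' @param bmax_table data.frame with columns `n_sites` and `bmax`.
#' @param fit_range optional integer range of site counts to use (e.g. `1:3`
#'   when the largest targets do not saturate).
#' @param through_origin force the regression through the origin.
#' @return An object of class `occupancy_calibration`: list with `step`,
#'   `intercept`, `r_squared`, `fit_range`.
#' @export
calibrate_occupancy <- function(bmax_table, fit_range = NULL,
                                through_origin = FALSE) {
  d <- bmax_table
  if (!is.null(fit_range)) d <- d[d$n_sites %in% fit_range, , drop = FALSE]
  if (length(unique(d$n_sites)) < 2) stop("fewer than 2 distinct site counts")
  fm <- if (through_origin) bmax ~ n_sites + 0 else bmax ~ n_sites
  m <- stats::lm(fm, data = d)
  step <- unname(stats::coef(m)[["n_sites"]])
  if (step <= 0) stop("calibration step is not positive")
  rss <- sum(stats::resid(m)^2)
  tss <- if (through_origin) sum(d$bmax^2)
         else sum((d$bmax - mean(d$bmax))^2)
  structure(
    list(step = step,
         intercept = if (through_origin) 0
                     else unname(stats::coef(m)[["(Intercept)"]]),
         r_squared = 1 - rss / tss,
         fit_range = sort(unique(d$n_sites))),
    class = "occupancy_calibration"
  )
}

#' Convert a bound-TF signal to mean occupancy
#'
#' `<N> = bound_signal / step`. The calibration intercept is diagnostic only
#' and not subtracted (policy: the step is defined by the per-site increment,
#' and a zero signal maps to zero occupancy).
#'
#' @param bound_signal RFU (scalar or vector).
#' @param calibration an [calibrate_occupancy()] result.
#' @return mean occupancy (dimensionless).
#' @export
to_occupancy <- function(bound_signal, calibration) {
  if (calibration$step <= 0) stop("calibration step must be > 0")
  bound_signal / calibration$step
}

#' Concentration at which two occupancy curves cross
#'
#' Finds the free TF concentration where a cluster's mean-occupancy curve
#' reaches the occupancy of a reference (consensus/strong-site) curve, by
#' bisection on log-concentration. For `n` identical independent weak sites
#' (K_w) against one strong site (K_s) the root has the closed form
#' `c* = (K_w - n K_s) / (n - 1)`.
#'
#' @param cluster_fn,reference_fn functions mapping concentration (nM) to
#'   mean occupancy (e.g. closures over [mean_occupancy()]).
#' @param bracket search interval in nM (log-scanned).
#' @param n_grid number of log-grid points scanned for sign changes.
#' @param tol absolute root tolerance passed to [stats::uniroot()].
#' @return An object of class `cross_point`: list with `conc` (nM),
#'   `occupancy_at_cross`, `bracket`, and `all_roots` (warning issued when
#'   more than one crossing is found; the first is reported).
#' @export
cross_point <- function(cluster_fn, reference_fn,
                        bracket = c(1e-3, 1e6), n_grid = 400L, tol = 1e-12) {
  grid <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = n_grid))
  diff_fn <- function(cc) cluster_fn(cc) - reference_fn(cc)
  d <- vapply(grid, diff_fn, numeric(1))
  if (all(abs(d) < 1e-12)) {
    stop(structure(class = c("bindclust_degenerate", "error", "condition"),
                   list(message = "degenerate: curves coincide", call = NULL)))
  }
  sgn <- sign(d)
  flips <- which(sgn[-1] * sgn[-n_grid] < 0)
  exact <- which(abs(d) < 1e-15 & abs(d) < max(abs(d)) * 1e-12)
  if (length(flips) == 0 && length(exact) == 0) {
    stop(structure(class = c("bindclust_nocrossing", "error", "condition"),
                   list(message = "no crossing in bracket", call = NULL)))
  }
  roots <- vapply(flips, function(i) {
    r <- stats::uniroot(function(lc) diff_fn(exp(lc)),
                        lower = log(grid[i]), upper = log(grid[i + 1]),
                        tol = tol)
    exp(r$root)
  }, numeric(1))
  roots <- sort(unique(c(roots, grid[exact])))
  if (length(roots) > 1) {
    warning("multiple crossings found; reporting the first (all in $all_roots)")
  }
  conc <- roots[1]
  structure(
    list(conc = conc, occupancy_at_cross = reference_fn(conc),
         bracket = bracket, all_roots = roots),
    class = "cross_point"
  )
}

#' Closed-form cross point for identical independent weak sites
#'
#' For `n` identical independent sites of affinity `kw` against a single
#' site of affinity `ks`: `c* = (kw - n ks) / (n - 1)` (valid when positive).
#'
#' @param n number of weak sites (>= 2).
#' @param kw,ks weak and strong K_d in nM.
#' @return concentration in nM (may be nonpositive, meaning no crossing on
#'   `c > 0`).
#' @export
cross_point_closed_form <- function(n, kw, ks) {
  stopifnot(n >= 2)
  (kw - n * ks) / (n - 1)
}

#' Fit the steric clash energy of a permissive binding model
#'
#' With per-site binding energies fixed from independent single-site
#' characterization, fits the permissive model's floating interaction energy
#' `epsilon_clash` (plus a signal scale) to a target's binding data by least
#' squares, and fits the exclusive model (signal scale only) for comparison.
#' Both fits carry RSS, AIC and BIC; `k` counts the noise variance in both
#' (exclusive k = 2, permissive k = 3) so the criterion difference reflects
#' only the clash parameter.
#'
#' @param measurements data.frame with `free_conc_nM` and `bound_rfu`.
#' @param design the [cluster_design()] measured, with >= 1 overlapping pair.
#' @param eps_max upper bound of the clash-energy search (k_BT).
#' @param conf_level profile-likelihood confidence level for the clash CI.
#' @return list with `eps_clash`, `eps_ci`, `scale`, and per-model fit lists
#'   `permissive` and `exclusive` (each with `rss`, `aic`, `bic`, `k`).
#' @export
fit_clash_energy <- function(measurements, design, eps_max = 30,
                             conf_level = 0.9) {
  cm <- clash_matrix(design)
  if (!any(cm)) stop("no clash parameter identifiable: design has no overlapping pair")
  c_nM <- measurements$free_conc_nM
  y <- dna_normalized_signal(measurements)
  n <- length(y)
  c_u <- sort(unique(c_nM))
  c_ix <- match(c_nM, c_u)
  occ_perm <- function(eps) {
    mean_occupancy(design, c_u,
                   statmech_model("permissive", clash_energy = eps))[c_ix]
  }
  # scale profiled analytically: least-squares slope of y on the occupancy
  rss_for <- function(occ) {
    s <- sum(occ * y) / sum(occ^2)
    list(scale = s, rss = sum((y - s * occ)^2))
  }
  obj <- function(eps) rss_for(occ_perm(eps))$rss
  # the RSS profile in eps need not be unimodal (the free signal scale can
  # trade off against curve shape), so scan a grid and refine locally
  grid <- seq(0, eps_max, length.out = 121L)
  rssv <- vapply(grid, obj, numeric(1))
  i <- which.min(rssv)
  opt <- stats::optimize(obj, c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
                         tol = 1e-6)
  eps_hat <- if (opt$objective <= rssv[i]) opt$minimum else grid[i]
  perm <- rss_for(occ_perm(eps_hat))
  # boundary handling: if eps_max fits essentially as well as the interior
  # optimum, the data carry no evidence against full exclusion
  if (rssv[length(grid)] <= perm$rss * (1 + 1e-9)) {
    eps_hat <- eps_max
    perm <- rss_for(occ_perm(eps_max))
  }
  occ_excl <- mean_occupancy(design, c_u, statmech_model("exclusive"))[c_ix]
  excl <- rss_for(occ_excl)
  # profile-likelihood CI on eps (Gaussian RSS profile, chi-square 1 df)
  cut <- perm$rss * exp(stats::qchisq(conf_level, 1) / n)
  lo <- if (obj(0) <= cut) 0 else
    stats::uniroot(function(e) obj(e) - cut, c(0, eps_hat), tol = 1e-6)$root
  hi <- if (obj(eps_max) <= cut) eps_max else
    stats::uniroot(function(e) obj(e) - cut, c(eps_hat, eps_max), tol = 1e-6)$root
  list(
    eps_clash = eps_hat,
    eps_ci = c(lo, hi),
    scale = perm$scale,
    permissive = list(rss = perm$rss, k = 3,
                      aic = aic_gaussian(perm$rss, n, 3),
                      bic = bic_gaussian(perm$rss, n, 3)),
    exclusive = list(rss = excl$rss, k = 2,
                     aic = aic_gaussian(excl$rss, n, 2),
                     bic = bic_gaussian(excl$rss, n, 2))
  )
}
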