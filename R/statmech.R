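#' Statistical-mechanical binding model for a cluster
#'
#' Three modes:
#' * `independent` — sites fill independently; mean occupancy is the Langmuir
#'   sum over sites, `sum_i c / (c + K_d,i)`.
#' * `exclusive` — full steric occlusion: configurations with two bound sites
#'   sharing any basepair are forbidden.
#' * `permissive` — all configurations allowed; every bound pair sharing
#'   >= 1 bp pays a steric clash penalty `clash_energy` (k_BT), applied
#'   multiplicatively per clashing pair. `clash_energy = 0` reduces to
#'   independent binding; `clash_energy = Inf` recovers the exclusive model.
#'
#' Statistical weights use the dimensionless per-site factor `c / K_d`
#' (equivalently a chemical-potential convention with reference concentration
#' `c_ref`; see [kd_to_energy()]), which makes the single-site occupancy
#' exactly `c / (K_d + c)`.
#'
#' @param mode one of `"independent"`, `"exclusive"`, `"permissive"`.
#' @param clash_energy steric clash energy in k_BT (>= 0; permissive mode).
#' @param c_ref reference concentration (nM) for the energy convention.
#' @return An object of class `statmech_model`.
#' @export
statmech_model <- function(mode = c("independent", "exclusive", "permissive"),
                           clash_energy = 0, c_ref = 1) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(clash_energy), length(clash_energy) == 1,
            clash_energy >= 0, c_ref > 0)
  structure(list(mode = mode, clash_energy = clash_energy, c_ref = c_ref),
            class = "statmech_model")
}

#' Convert a dissociation constant to a binding energy and back
#'
#' `epsilon_bs = ln(K_d / c_ref)` in k_BT units; the per-site statistical
#' weight is then `c / K_d = exp(ln(c / c_ref) - epsilon_bs)`.
#'
#' @param kd dissociation constant, nM (> 0).
#' @param c_ref reference concentration, nM (> 0).
#' @return energy in k_BT ([kd_to_energy()]) or K_d in nM ([energy_to_kd()]).
#' @export
kd_to_energy <- function(kd, c_ref = 1) {
  stopifnot(all(kd > 0), c_ref > 0)
  log(kd / c_ref)
}

#' @rdname kd_to_energy
#' @param energy binding energy in k_BT.
#' @export
energy_to_kd <- function(energy, c_ref = 1) {
  stopifnot(c_ref > 0)
  c_ref * exp(energy)
}

# Pairwise clash matrix (shared >= 1 bp) over the specific sites of a design.
clash_matrix <- function(design) {
  sp <- specific_sites(design)
  n <- length(sp)
  m <- matrix(FALSE, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- shared_basepairs(sp[[i]], sp[[j]]) >= 1
    }
  }
  m
}

#' Enumerate binding configurations of a cluster
#'
#' Enumerates subsets of the design's specific (non-NS) sites. Under the
#' permissive and independent modes all `2^n` subsets are states; under the
#' exclusive mode only subsets with no clashing pair (independent sets of the
#' overlap graph) remain. The empty configuration is always present.
#'
#' @param design a [cluster_design()].
#' @param mode model mode (see [statmech_model()]).
#' @param cap refuse enumeration above this site count (enumeration is 2^n).
#' @return data.frame with columns `state_id`, `bound` (comma-separated site
#'   indices, "" for empty), `n_bound`, `clash_pairs`.
#' @export
enumerate_states <- function(design,
                             mode = c("independent", "exclusive", "permissive"),
                             cap = 16L) {
  mode <- match.arg(mode)
  n <- design$n_sites
  if (n > cap) stop("design has ", n, " sites; enumeration capped at ", cap)
  cm <- clash_matrix(design)
  masks <- 0:(2^n - 1)
  member <- if (n > 0) {
    vapply(seq_len(n), function(i) bitwAnd(masks, bitwShiftL(1L, i - 1L)) > 0,
           logical(length(masks)))
  } else {
    matrix(FALSE, 1, 0)
  }
  if (is.null(dim(member))) member <- matrix(member, nrow = length(masks))
  n_bound <- rowSums(member)
  clash_pairs <- apply(member, 1, function(b) {
    idx <- which(b)
    if (length(idx) < 2) return(0L)
    sum(cm[idx, idx, drop = FALSE]) / 2L
  })
  keep <- if (mode == "exclusive") clash_pairs == 0 else rep(TRUE, length(masks))
  bound <- apply(member, 1, function(b) paste(which(b), collapse = ","))
  out <- data.frame(state_id = seq_len(sum(keep)),
                    bound = bound[keep],
                    n_bound = as.integer(n_bound[keep]),
                    clash_pairs = as.integer(clash_pairs[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "n_sites") <- n
  out
}

# Weight matrix: states x concentrations. kds indexed as in enumerate_states.
state_weight_matrix <- function(states, kds, conc, clash_energy) {
  idxs <- lapply(strsplit(states$bound, ","), as.integer)
  pen <- exp(-clash_energy * states$clash_pairs)
  W <- vapply(conc, function(cc) {
    vapply(seq_len(nrow(states)), function(k) {
      w <- if (length(idxs[[k]]) == 0) 1 else prod(cc / kds[idxs[[k]]])
      w * pen[k]
    }, numeric(1))
  }, numeric(nrow(states)))
  matrix(W, nrow = nrow(states), ncol = length(conc))
}

#' Statistical weight of one binding configuration
#'
#' `w = prod_{i in bound} (c / K_d,i) * exp(-clash_energy * clash_pairs)`;
#' the empty configuration has weight 1.
#'
#' @param config one row of [enumerate_states()] output (data.frame or list
#'   with `bound` and `clash_pairs`).
#' @param conc free TF concentration, nM (>= 0).
#' @param design the [cluster_design()] the configuration refers to.
#' @param model a [statmech_model()].
#' @return dimensionless weight.
#' @export
state_weight <- function(config, conc, design, model) {
  if (any(conc < 0)) stop("negative concentration")
  kds <- site_kds(design)
  idx <- as.integer(strsplit(as.character(config$bound), ",")[[1]])
  eps <- if (model$mode == "permissive") model$clash_energy else 0
  vapply(conc, function(cc) {
    w <- if (length(idx) == 0) 1 else prod(cc / kds[idx])
    w * exp(-eps * config$clash_pairs)
  }, numeric(1))
}

#' Partition function of a cluster
#'
#' `Z(c) = sum_sigma w(sigma)` over the model's configurations; `Z >= 1`
#' (the empty state contributes 1).
#'
#' @inheritParams state_weight
#' @param conc concentration grid, nM.
#' @return numeric vector, one Z per concentration.
#' @export
partition_function <- function(design, conc, model) {
  if (any(conc < 0)) stop("negative concentration")
  states <- enumerate_states(design, model$mode)
  eps <- if (model$mode == "permissive") model$clash_energy else 0
  W <- state_weight_matrix(states, site_kds(design), conc, eps)
  colSums(W)
}

#' Mean occupancy of a cluster
#'
#' `<N>(c) = sum_sigma N(sigma) w(sigma) / Z(c)` — the average number of TF
#' molecules bound per DNA molecule. For the independent mode this equals the
#' Langmuir sum `sum_i c / (c + K_d,i)` exactly (computed in closed form).
#'
#' @inheritParams partition_function
#' @return numeric vector of mean occupancies.
#' @export
mean_occupancy <- function(design, conc, model) {
  if (any(conc < 0)) stop("negative concentration")
  kds <- site_kds(design)
  if (model$mode == "independent") {
    return(vapply(conc, function(cc) sum(cc / (cc + kds)), numeric(1)))
  }
  states <- enumerate_states(design, model$mode)
  eps <- if (model$mode == "permissive") model$clash_energy else 0
  W <- state_weight_matrix(states, kds, conc, eps)
  as.numeric(colSums(W * states$n_bound) / colSums(W))
}

#' Per-configuration probabilities and occupancy contributions
#'
#' `P(sigma) = w(sigma) / Z`; probabilities sum to 1 at every concentration.
#'
#' @inheritParams partition_function
#' @return data.frame with columns `state_id`, `bound`, `n_bound`,
#'   `clash_pairs`, `conc_nM`, `prob`, `occ_contrib` (= n_bound * prob).
#' @export
state_probabilities <- function(design, conc, model) {
  if (any(conc < 0)) stop("negative concentration")
  states <- enumerate_states(design, model$mode)
  eps <- if (model$mode == "permissive") model$clash_energy else 0
  W <- state_weight_matrix(states, site_kds(design), conc, eps)
  P <- sweep(W, 2, colSums(W), "/")
  out <- do.call(rbind, lapply(seq_along(conc), function(j) {
    data.frame(states, conc_nM = conc[j], prob = P[, j],
               occ_contrib = states$n_bound * P[, j])
  }))
  rownames(out) <- NULL
  out
}

#' Occupancy curve over a concentration grid
#'
#' @inheritParams partition_function
#' @param conc strictly increasing, nonnegative concentration grid (nM).
#' @return data.frame with `conc_nM` and `n_mean`; attribute `n_max` holds
#'   the saturating-limit occupancy (`n_sites` for independent and permissive
#'   with finite clash energy; the maximum independent-set size for
#'   exclusive).
#' @export
occupancy_curve <- function(design, conc, model) {
  stopifnot(all(conc >= 0), all(diff(conc) > 0))
  nm <- mean_occupancy(design, conc, model)
  out <- data.frame(conc_nM = conc, n_mean = nm)
  n_max <- if (model$mode == "exclusive") {
    max(enumerate_states(design, "exclusive")$n_bound)
  } else {
    design$n_sites
  }
  attr(out, "n_max") <- n_max
  out
}
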