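# Independent brute-force oracles, coded directly from first principles and
# deliberately sharing no code path with the package internals.

# Shared basepairs by per-bp membership over explicit bp index sets.
bf_shared_bp <- function(start1, len1, start2, len2) {
  length(intersect(seq(start1, length.out = len1),
                   seq(start2, length.out = len2)))
}

# Brute-force partition function / mean occupancy: loop over all 2^n subsets
# of sites given as parallel vectors of starts, lengths, kds.
bf_statmech <- function(starts, lengths, kds, conc, eps = 0,
                        mode = c("permissive", "exclusive", "independent")) {
  mode <- match.arg(mode)
  n <- length(starts)
  subsets <- if (n == 0) list(integer(0)) else {
    unlist(lapply(0:n, function(k) {
      if (k == 0) list(integer(0)) else
        utils::combn(n, k, simplify = FALSE)
    }), recursive = FALSE)
  }
  Z <- 0; num <- 0; probs <- numeric(length(subsets))
  for (s in seq_along(subsets)) {
    idx <- subsets[[s]]
    clashes <- 0L
    if (length(idx) >= 2) {
      for (pair in utils::combn(idx, 2, simplify = FALSE)) {
        if (bf_shared_bp(starts[pair[1]], lengths[pair[1]],
                         starts[pair[2]], lengths[pair[2]]) >= 1) {
          clashes <- clashes + 1L
        }
      }
    }
    if (mode == "exclusive" && clashes > 0) { probs[s] <- NA; next }
    e <- if (mode == "permissive") eps else 0
    w <- prod(conc / kds[idx]) * exp(-e * clashes)
    probs[s] <- w
    Z <- Z + w
    num <- num + length(idx) * w
  }
  list(Z = Z, n_mean = num / Z,
       n_states = sum(!is.na(probs)),
       probs = probs[!is.na(probs)] / Z)
}

# Two-site permissive closed form: Z = 1 + x1 + x2 + x1*x2*exp(-eps).
bf_two_site_closed_form <- function(kd1, kd2, conc, eps) {
  x1 <- conc / kd1; x2 <- conc / kd2
  Z <- 1 + x1 + x2 + x1 * x2 * exp(-eps)
  list(Z = Z, n_mean = (x1 + x2 + 2 * x1 * x2 * exp(-eps)) / Z,
       probs = c(1, x1, x2, x1 * x2 * exp(-eps)) / Z)
}

# Small standard fixtures.
two_overlapping_sites <- function(kd = 10, shared = 3, len = 9) {
  cluster_design("two_ovl", list(
    binding_site("a", 0, len, "S", kd = kd),
    binding_site("b", len - shared, len, "S", kd = kd)
  ))
}

n_identical_sites <- function(n, kd = 100, len = 9, gap = 4) {
  sites <- lapply(seq_len(n), function(i) {
    binding_site(paste0("s", i), (i - 1) * (len + gap), len, "W", kd = kd)
  })
  cluster_design(paste0("ident", n), sites, target_length = n * (len + gap) + len)
}
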