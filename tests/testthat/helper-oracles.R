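# Shared fixtures and independent oracles.  Oracles deliberately avoid the
# code paths they check: finite differences for analytic Jacobians, direct
# block linear solves for clamped equilibria of affine systems.

euclid_dist <- function(a, b) sqrt(sum((a - b)^2))

# Central finite-difference Jacobian of the dynamics (step 1e-6).
fd_jacobian <- function(net, x, h = 1e-6) {
  n <- length(x)
  j <- matrix(0, n, n)
  for (k in seq_len(n)) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + h
    xm[k] <- xm[k] - h
    j[, k] <- (net_dynamics(net, xp) - net_dynamics(net, xm)) / (2 * h)
  }
  j
}

# Closed-form clamped equilibrium of an affine system dx/dt = A (x - x*):
# solve the free block directly (Schur-style), independent of the LM solver.
linear_clamped_equilibrium <- function(net, clamp_idx, clamp_val) {
  n <- net$n_genes
  free <- setdiff(seq_len(n), clamp_idx)
  x <- numeric(n)
  x[clamp_idx] <- clamp_val
  aff <- net$A[free, free, drop = FALSE]
  afc <- net$A[free, clamp_idx, drop = FALSE]
  x[free] <- net$x_star[free] -
    solve(aff, afc %*% (clamp_val - net$x_star[clamp_idx]))
  x
}

# True affine map of external genes in terms of internal genes for a linear
# network: x_E = intercept + C x_I on the clamped-equilibrium surface.
linear_true_external_map <- function(net, int_idx) {
  ext_idx <- setdiff(seq_len(net$n_genes), int_idx)
  aee <- net$A[ext_idx, ext_idx, drop = FALSE]
  aei <- net$A[ext_idx, int_idx, drop = FALSE]
  slope <- -solve(aee, aei)
  intercept <- net$x_star[ext_idx] - slope %*% net$x_star[int_idx]
  list(intercept = as.numeric(intercept), slope = slope,
       ext_idx = ext_idx)
}

# A tiny hand-built Hill influence network (bypasses the generator) for
# targeted unit tests.  All fields an influence_network needs.
manual_hill_network <- function(b, w, theta, basal, x_star,
                                hill_index = 2L) {
  n <- length(b)
  net <- structure(
    list(
      n_genes = n,
      gene_ids = paste0("g", seq_len(n)),
      cluster_of = rep(1L, n),
      b = b, theta = theta, w = w, basal = basal,
      hill_index = hill_index,
      x_star = x_star,
      jacobian_design = matrix(0, n, n),
      edges = which(w != 0, arr.ind = TRUE),
      config = network_config(n_clusters = 1, cluster_size = n, seed = 0),
      seed = 0L,
      stability_retries = 0L
    ),
    class = c("influence_network", "ees_network")
  )
  net
}

# Solve the single-knockout panel for a set of internal genes and fit the
# EES from the resulting training points.
fit_ees_from_network <- function(net, internal, ...) {
  kos <- vapply(internal, function(g) {
    ss <- solve_steady_state(net, knockout(g))
    stopifnot(ss$viable)
    ss$x
  }, numeric(net$n_genes))
  fit_ees(net$x_star, kos, internal, gene_ids = net$gene_ids, ...)
}

# Default-scale synthetic network cached per seed (building is cheap but
# repeated in many tests).
.net_cache <- new.env(parent = emptyenv())
cached_network <- function(seed) {
  key <- as.character(seed)
  if (is.null(.net_cache[[key]])) {
    .net_cache[[key]] <- build_synthetic_network(network_config(seed = seed))
  }
  .net_cache[[key]]
}
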