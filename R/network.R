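#' Sigmoidal Hill response
#'
#' The elementary regulatory interaction of the synthetic model:
#' `H_n(x; theta) = x^n / (theta^n + x^n)`.  Monotone non-decreasing in `x`,
#' equal to 1/2 at `x = theta`, and bounded in \[0, 1).
#'
#' @param x non-negative expression level(s); vectorized.
#' @param theta strictly positive half-saturation threshold.
#' @param n positive integer Hill index.
#' @return numeric vector of responses in \[0, 1).
#' @export
#' @examples
#' hill_response(1, 1, 2)   # 0.5: half-saturation at x = theta
#' hill_response(2, 1, 2)   # 0.8
hill_response <- function(x, theta, n) {
  if (!is.numeric(theta) || any(theta <= 0)) {
    abort_eesnet("theta must be strictly positive", "eesnet_domain_error")
  }
  if (!is.numeric(x) || any(x < 0)) {
    abort_eesnet("x must be non-negative", "eesnet_domain_error")
  }
  if (n < 1) abort_eesnet("n must be a positive integer", "eesnet_domain_error")
  x^n / (theta^n + x^n)
}

# Extension of the Hill response used inside solvers: identically 0 for
# x <= 0 so iterates that stray slightly negative stay well-defined and the
# interaction remains monotone.  The public hill_response() is strict.
hill_ext <- function(x, theta, n) {
  h <- numeric(length(x))
  pos <- x > 0
  h[pos] <- x[pos]^n / (theta[pos]^n + x[pos]^n)
  h
}

# Analytic derivative dH/dx, same x <= 0 extension.
hill_deriv <- function(x, theta, n) {
  d <- numeric(length(x))
  pos <- x > 0
  d[pos] <- n * theta[pos]^n * x[pos]^(n - 1) / (theta[pos]^n + x[pos]^n)^2
  d
}

#' Network dynamics and Jacobian generics
#'
#' `net_dynamics()` evaluates the right-hand side of the ODE system at a
#' state; `net_jacobian()` evaluates its analytic Jacobian.  Methods exist
#' for the synthetic Hill-function influence network
#' ([build_synthetic_network()]) and for the affine surrogate
#' ([linear_network()]) used as an exactly-solvable reference model.
#'
#' @param net a network object.
#' @param state numeric state vector of length `net$n_genes`.
#' @return `net_dynamics()`: the derivative vector; `net_jacobian()`: an
#'   N x N matrix.
#' @export
net_dynamics <- function(net, state) UseMethod("net_dynamics")

#' @rdname net_dynamics
#' @export
net_jacobian <- function(net, state) UseMethod("net_jacobian")

#' @export
net_dynamics.influence_network <- function(net, state) {
  check_numeric_vector(state, net$n_genes, "state")
  hmat <- matrix(0, net$n_genes, net$n_genes)
  e <- net$edges  # arr indices of w != 0, precomputed
  hmat[e] <- hill_ext(state[e[, 2]], net$theta[e], net$hill_index)
  as.numeric(net$basal - net$b * state + rowSums(net$w * hmat))
}

#' @export
net_jacobian.influence_network <- function(net, state) {
  check_numeric_vector(state, net$n_genes, "state")
  dmat <- matrix(0, net$n_genes, net$n_genes)
  e <- net$edges
  dmat[e] <- hill_deriv(state[e[, 2]], net$theta[e], net$hill_index)
  j <- net$w * dmat
  diag(j) <- diag(j) - net$b
  j
}

#' Random stable symmetric Jacobian
#'
#' Draws `Q D t(Q)` where `D` is diagonal with entries uniform in
#' `eig_range` (all negative) and `Q` is a random orthogonal matrix, i.e. a
#' diagonal matrix with negative entries under a random orthonormal
#' transformation.  The result is symmetric with spectrum exactly `diag(D)`.
#'
#' Uses the current RNG state; seed with [set.seed()] or call through
#' [build_synthetic_network()], which seeds locally.
#'
#' @param size matrix dimension.
#' @param eig_range length-2 strictly negative eigenvalue bounds.
#' @param eigenvalues optional explicit eigenvalues (overrides sampling).
#' @return a `size` x `size` symmetric negative definite matrix.
#' @export
make_stable_jacobian <- function(size, eig_range = c(-2, -0.5),
                                 eigenvalues = NULL) {
  if (any(eig_range >= 0)) {
    abort_eesnet("eig_range entries must be strictly negative",
                 "eesnet_config_error")
  }
  d <- eigenvalues %||% stats::runif(size, min(eig_range), max(eig_range))
  if (length(d) != size || any(d >= 0)) {
    abort_eesnet("eigenvalues must be `size` negative reals",
                 "eesnet_config_error")
  }
  q <- qr.Q(qr(matrix(stats::rnorm(size * size), size, size)))
  q %*% diag(d, size) %*% t(q)
}

# Draw from U(theta_range) resampling exact zeros, so every used edge has a
# strictly positive threshold.
draw_theta <- function(n, theta_range) {
  th <- stats::runif(n, theta_range[1], theta_range[2])
  while (any(th == 0)) {
    th[th == 0] <- stats::runif(sum(th == 0), theta_range[1], theta_range[2])
  }
  th
}

#' Generate a synthetic clustered Hill-function influence network
#'
#' Builds the ground-truth benchmark system: `n_clusters` strongly coupled
#' subnetworks wired by sparse weak inter-cluster edges, with dynamics
#' `dx_i/dt = beta_i - b_i x_i + sum_j w_ij H_n(x_j; theta_ij)`.
#'
#' Per cluster, the construction samples degradation rates `b` and Hill
#' thresholds `theta`, draws a stable symmetric Jacobian (negative diagonal
#' under a random orthonormal transformation), and inverts the Jacobian
#' relation at the designed equilibrium `x*` to obtain the interaction
#' weights `w` (`w_ij = J_ij / H'(x*_j)`, the diagonal absorbing `-b_i`).
#' Each node then receives exactly one incoming edge from each foreign
#' cluster, with random partner and sign, magnitudes rescaled so the mean
#' inter-cluster |w| is `inter_coupling_ratio` times the mean off-diagonal
#' intra-cluster |w|.  Finally the basal rates `beta` are set so `x*` is an
#' exact equilibrium, and full-network stability at `x*` is verified by an
#' eigenvalue check, resampling up to `max_stability_retries` times.
#'
#' @param config a [network_config()].
#' @return an object of class `influence_network` with fields `n_genes`,
#'   `gene_ids`, `cluster_of`, `b`, `theta`, `w`, `basal`, `hill_index`,
#'   `x_star`, `jacobian_design` (block-diagonal designed Jacobian), plus the
#'   config echo and the number of stability retries used.
#' @export
#' @examples
#' net <- build_synthetic_network(network_config(seed = 42))
#' max(abs(net_dynamics(net, net$x_star)))  # ~ 0: designed equilibrium
build_synthetic_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  with_local_seed(config$seed, {
    for (attempt in seq_len(config$max_stability_retries)) {
      net <- generate_network_once(config, attempt)
      jac <- net_jacobian(net, net$x_star)
      if (max(Re(eigen(jac, only.values = TRUE)$values)) < 0) {
        net$stability_retries <- attempt - 1L
        return(net)
      }
    }
    abort_eesnet(
      sprintf("no stable network found after %d retries",
              config$max_stability_retries),
      "eesnet_generation_error"
    )
  })
}

generate_network_once <- function(config, attempt) {
  k <- config$n_clusters
  s <- config$cluster_size
  n_genes <- k * s
  nn <- config$hill_index
  x_star <- config$x_star %||% rep(1, n_genes)
  cluster_of <- rep(seq_len(k), each = s)

  b <- stats::runif(n_genes, config$b_range[1], config$b_range[2])
  theta <- matrix(0, n_genes, n_genes)
  w <- matrix(0, n_genes, n_genes)
  jacobian_design <- matrix(0, n_genes, n_genes)

  for (c in seq_len(k)) {
    idx <- which(cluster_of == c)
    th <- matrix(draw_theta(s * s, config$theta_range), s, s)
    jblock <- make_stable_jacobian(s, config$eig_range)
    hp <- hill_deriv(rep(x_star[idx], each = s), as.numeric(t(th)), nn)
    hp <- matrix(hp, s, s, byrow = TRUE)  # hp[i,j] = H'(x*_j; th[i,j])
    wblock <- jblock / hp
    diag(wblock) <- (diag(jblock) + b[idx]) / diag(hp)
    theta[idx, idx] <- th
    w[idx, idx] <- wblock
    jacobian_design[idx, idx] <- jblock
  }

  # Sparse weak inter-cluster wiring: one incoming edge per foreign cluster
  # per node, random partner and sign; magnitudes rescaled afterwards so the
  # mean inter |w| hits the target ratio of the mean off-diagonal intra |w|.
  intra_mask <- outer(cluster_of, cluster_of, "==") & row(w) != col(w)
  mean_intra <- mean(abs(w[intra_mask]))
  inter_rows <- integer(0); inter_cols <- integer(0)
  for (i in seq_len(n_genes)) {
    for (c in setdiff(seq_len(k), cluster_of[i])) {
      j <- sample(which(cluster_of == c), 1L)
      inter_rows <- c(inter_rows, i); inter_cols <- c(inter_cols, j)
    }
  }
  idx_inter <- cbind(inter_rows, inter_cols)
  raw <- stats::runif(nrow(idx_inter), 0.5, 1.5)
  raw <- raw * (config$inter_coupling_ratio * mean_intra / mean(raw))
  signs <- sample(c(-1, 1), nrow(idx_inter), replace = TRUE)
  w[idx_inter] <- signs * raw
  theta[idx_inter] <- draw_theta(nrow(idx_inter), config$theta_range)

  edges <- which(w != 0, arr.ind = TRUE)
  hstar <- hill_ext(x_star[edges[, 2]], theta[edges], nn)
  hsum <- numeric(n_genes)
  contrib <- w[edges] * hstar
  for (r in seq_len(nrow(edges))) {
    hsum[edges[r, 1]] <- hsum[edges[r, 1]] + contrib[r]
  }
  basal <- b * x_star - hsum

  structure(
    list(
      n_genes = n_genes,
      gene_ids = paste0("g", seq_len(n_genes)),
      cluster_of = cluster_of,
      b = b, theta = theta, w = w, basal = basal,
      hill_index = nn,
      x_star = x_star,
      jacobian_design = jacobian_design,
      edges = edges,
      config = config,
      seed = config$seed,
      stability_retries = attempt - 1L
    ),
    class = c("influence_network", "ees_network")
  )
}

#' @export
print.influence_network <- function(x, ...) {
  cat("<influence_network>\n")
  cat(sprintf("  %d genes, %d clusters, Hill index %d, seed %d\n",
              x$n_genes, length(unique(x$cluster_of)), x$hill_index, x$seed))
  cat(sprintf("  equilibrium residual %.2e, %d inter-cluster edges\n",
              max(abs(net_dynamics(x, x$x_star))),
              sum(outer(x$cluster_of, x$cluster_of, "!=") & x$w != 0)))
  invisible(x)
}

#' Serialize / load an influence network as JSON
#'
#' The writer emits every parameter array plus a config echo and a
#' `format_version` field; the reader rebuilds the object and re-validates
#' the core invariants (equilibrium residual, stability, positive thresholds
#' on used edges).
#'
#' @param net an `influence_network`.
#' @param path file path for the JSON document.
#' @return `read_network()` returns the validated `influence_network`;
#'   `write_network()` returns `path` invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "influence_network"))
  doc <- list(
    format_version = FORMAT_VERSION,
    kind = "influence_network",
    seed = net$seed,
    n_genes = net$n_genes,
    gene_ids = net$gene_ids,
    cluster_of = net$cluster_of,
    hill_index = net$hill_index,
    b = net$b, basal = net$basal, x_star = net$x_star,
    theta = net$theta, w = net$w,
    jacobian_design = net$jacobian_design,
    stability_retries = net$stability_retries,
    config = unclass(net$config)
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_format_version(doc$format_version, "network JSON")
  cfg <- doc$config
  config <- network_config(
    n_clusters = cfg$n_clusters, cluster_size = cfg$cluster_size,
    b_range = cfg$b_range, theta_range = cfg$theta_range,
    hill_index = cfg$hill_index, eig_range = cfg$eig_range,
    inter_coupling_ratio = cfg$inter_coupling_ratio, seed = cfg$seed,
    max_stability_retries = cfg$max_stability_retries,
    viability_residual_tol = cfg$viability_residual_tol,
    x_star = if (length(cfg$x_star)) cfg$x_star else NULL
  )
  net <- structure(
    list(
      n_genes = doc$n_genes,
      gene_ids = doc$gene_ids,
      cluster_of = doc$cluster_of,
      b = doc$b,
      theta = matrix(unlist(doc$theta), doc$n_genes, doc$n_genes),
      w = matrix(unlist(doc$w), doc$n_genes, doc$n_genes),
      basal = doc$basal,
      hill_index = doc$hill_index,
      x_star = doc$x_star,
      jacobian_design = matrix(unlist(doc$jacobian_design),
                               doc$n_genes, doc$n_genes),
      config = config,
      seed = doc$seed,
      stability_retries = doc$stability_retries
    ),
    class = c("influence_network", "ees_network")
  )
  net$edges <- which(net$w != 0, arr.ind = TRUE)
  validate_network(net)
  net
}

validate_network <- function(net) {
  if (any(net$theta[net$edges] <= 0)) {
    abort_eesnet("used edge with non-positive theta", "eesnet_format_error")
  }
  res <- max(abs(net_dynamics(net, net$x_star)))
  if (res > 1e-10) {
    abort_eesnet(sprintf("equilibrium residual %.3e exceeds 1e-10", res),
                 "eesnet_format_error")
  }
  ev <- eigen(net_jacobian(net, net$x_star), only.values = TRUE)$values
  if (max(Re(ev)) >= 0) {
    abort_eesnet("loaded network is not stable at x_star",
                 "eesnet_format_error")
  }
  invisible(net)
}
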