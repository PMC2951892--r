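#' Configuration for the synthetic clustered influence network
#'
#' Bundles every tunable of the synthetic Hill-function network generator.
#' Defaults reproduce the published benchmark scale: 21 genes in 3 clusters
#' of 7, degradation rates uniform in \[0.5, 1.5\], Hill thresholds uniform
#' in (0, 2\], Hill index 2, and inter-cluster couplings whose mean magnitude
#' is 0.1 of the mean intra-cluster coupling magnitude.
#'
#' @param n_clusters number of strongly-coupled gene clusters.
#' @param cluster_size genes per cluster.
#' @param b_range length-2 positive bounds for the uniform draw of the
#'   degradation rates `b`.
#' @param theta_range length-2 non-negative bounds for the uniform draw of
#'   the Hill thresholds `theta`; exact zeros on used edges are resampled.
#' @param hill_index positive integer Hill coefficient `n`.
#' @param eig_range length-2 strictly negative bounds for the eigenvalues of
#'   the designed per-cluster Jacobian.
#' @param inter_coupling_ratio target ratio of mean inter-cluster to mean
#'   intra-cluster interaction magnitude.
#' @param seed integer seed; identical seeds give bit-identical networks.
#' @param max_stability_retries how many times the generator may resample a
#'   network whose full Jacobian is not stable at the designed equilibrium.
#' @param viability_residual_tol RMS residual below which a clamped
#'   steady-state solve counts as converged (mutant viable).
#' @param x_star designed equilibrium expression vector; defaults to the
#'   all-ones vector (expression measured relative to wildtype).
#'
#' @return An object of class `network_config`.
#' @export
#' @examples
#' cfg <- network_config(seed = 1)
#' cfg$n_clusters * cfg$cluster_size  # 21 genes
network_config <- function(n_clusters = 3L,
                           cluster_size = 7L,
                           b_range = c(0.5, 1.5),
                           theta_range = c(0, 2),
                           hill_index = 2L,
                           eig_range = c(-2.0, -0.5),
                           inter_coupling_ratio = 0.1,
                           seed = 1L,
                           max_stability_retries = 50L,
                           viability_residual_tol = 1e-8,
                           x_star = NULL) {
  n_clusters <- as.integer(n_clusters)
  cluster_size <- as.integer(cluster_size)
  if (n_clusters < 1L || cluster_size < 1L) {
    abort_eesnet("n_clusters and cluster_size must be positive integers",
                 "eesnet_config_error")
  }
  check_numeric_vector(b_range, 2, "b_range")
  check_numeric_vector(theta_range, 2, "theta_range")
  check_numeric_vector(eig_range, 2, "eig_range")
  if (b_range[1] <= 0 || b_range[2] < b_range[1]) {
    abort_eesnet("b_range must be positive with lower <= upper",
                 "eesnet_config_error")
  }
  if (theta_range[1] < 0 || theta_range[2] <= theta_range[1]) {
    abort_eesnet("theta_range must satisfy upper > lower >= 0",
                 "eesnet_config_error")
  }
  if (any(eig_range >= 0)) {
    abort_eesnet("eig_range entries must be strictly negative",
                 "eesnet_config_error")
  }
  if (hill_index < 1L) {
    abort_eesnet("hill_index must be a positive integer", "eesnet_config_error")
  }
  if (inter_coupling_ratio <= 0) {
    abort_eesnet("inter_coupling_ratio must be positive", "eesnet_config_error")
  }
  if (viability_residual_tol <= 0) {
    abort_eesnet("viability_residual_tol must be positive",
                 "eesnet_config_error")
  }
  n_genes <- n_clusters * cluster_size
  if (!is.null(x_star)) {
    check_numeric_vector(x_star, n_genes, "x_star")
    if (any(x_star <= 0)) {
      abort_eesnet("x_star entries must be positive", "eesnet_config_error")
    }
  }
  structure(
    list(
      n_clusters = n_clusters,
      cluster_size = cluster_size,
      b_range = as.numeric(b_range),
      theta_range = as.numeric(theta_range),
      hill_index = as.integer(hill_index),
      eig_range = as.numeric(sort(eig_range)),
      inter_coupling_ratio = inter_coupling_ratio,
      seed = as.integer(seed),
      max_stability_retries = as.integer(max_stability_retries),
      viability_residual_tol = viability_residual_tol,
      x_star = x_star
    ),
    class = "network_config"
  )
}

#' @export
print.network_config <- function(x, ...) {
  cat("<network_config>\n")
  cat(sprintf("  %d clusters x %d genes = %d nodes, Hill index %d\n",
              x$n_clusters, x$cluster_size, x$n_clusters * x$cluster_size,
              x$hill_index))
  cat(sprintf("  b in [%g, %g], theta in (%g, %g], eig in [%g, %g]\n",
              x$b_range[1], x$b_range[2], x$theta_range[1], x$theta_range[2],
              x$eig_range[1], x$eig_range[2]))
  cat(sprintf("  inter/intra coupling ratio %g, seed %d\n",
              x$inter_coupling_ratio, x$seed))
  invisible(x)
}
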