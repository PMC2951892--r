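#' Affine surrogate network
#'
#' An exactly-solvable reference model with dynamics
#' `dx/dt = A (x - x_star)`, `A` stable (typically symmetric negative
#' definite).  Its steady-state surface under clamping is exactly affine, so
#' the EES plane reproduces every clamped equilibrium to machine precision;
#' the class exists to check the pipeline against closed-form linear algebra.
#'
#' @param A stable N x N interaction matrix.
#' @param x_star unconstrained equilibrium (positive vector).
#' @param gene_ids optional character gene identifiers.
#' @return an object of class `linear_network`.
#' @export
#' @examples
#' net <- random_linear_network(6, seed = 1)
#' max(abs(net_dynamics(net, net$x_star)))  # 0
linear_network <- function(A, x_star, gene_ids = NULL) {
  n <- length(x_star)
  stopifnot(is.matrix(A), nrow(A) == n, ncol(A) == n)
  if (max(Re(eigen(A, only.values = TRUE)$values)) >= 0) {
    abort_eesnet("A must be a stable matrix", "eesnet_config_error")
  }
  structure(
    list(
      n_genes = n,
      gene_ids = gene_ids %||% paste0("g", seq_len(n)),
      A = A,
      x_star = as.numeric(x_star)
    ),
    class = c("linear_network", "ees_network")
  )
}

#' @rdname linear_network
#' @param n number of genes.
#' @param seed integer seed.
#' @export
random_linear_network <- function(n, seed = 1L) {
  with_local_seed(seed, {
    m <- matrix(stats::rnorm(n * n), n, n)
    A <- -(m %*% t(m) / n + 0.5 * diag(n))
    x_star <- stats::runif(n, 0.5, 1.5)
    linear_network(A, x_star)
  })
}

#' @export
net_dynamics.linear_network <- function(net, state) {
  check_numeric_vector(state, net$n_genes, "state")
  as.numeric(net$A %*% (state - net$x_star))
}

#' @export
net_jacobian.linear_network <- function(net, state) {
  check_numeric_vector(state, net$n_genes, "state")
  net$A
}

#' @export
print.linear_network <- function(x, ...) {
  cat(sprintf("<linear_network> %d genes, max Re(eig) = %.3g\n", x$n_genes,
              max(Re(eigen(x$A, only.values = TRUE)$values))))
  invisible(x)
}
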