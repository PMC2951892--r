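#' Project a target expression state onto the EES plane
#'
#' Given a prescribed target state `Q`, finds the internal-gene settings
#' whose plane point `Pr` is closest to `Q` in (optionally weighted)
#' Euclidean distance over all N genes.  Solved through the normal
#' equations of the affine parametrization, so the residual `Q - Pr` is
#' orthogonal to every spanning direction of the plane.
#'
#' Negative internal settings are biologically unreachable (expression
#' cannot go below zero); they are reported but flagged, never silently
#' constrained.
#'
#' @param ees a fitted `ees_model`.
#' @param Q numeric target vector, length N (order of `ees$gene_ids`).
#' @param weights optional positive per-gene weights for the distance.
#' @return an object of class `steering_result` with `target_Q`,
#'   `projection_Pr`, `internal_settings`, `negative_settings` flag, and a
#'   `distances` list (`d_P0_Q`, `d_Pr_Q`).
#' @export
#' @examples
#' \dontrun{
#' pr <- project_onto_plane(ees, Q)
#' pr$distances$d_Pr_Q  # how close the plane can get to the target
#' }
project_onto_plane <- function(ees, Q, weights = NULL) {
  n <- length(ees$gene_ids)
  m <- length(ees$internal)
  check_numeric_vector(Q, n, "Q")
  if (!all(is.finite(Q))) {
    abort_eesnet("Q must be finite", "eesnet_domain_error")
  }
  w <- rep(1, n)
  if (!is.null(weights)) {
    check_numeric_vector(weights, n, "weights")
    if (any(weights <= 0)) {
      abort_eesnet("weights must be positive", "eesnet_domain_error")
    }
    w <- weights
  }
  # plane: x(s) = base + V s,  V[internal,] = I_m, V[external,] = coeffs
  base <- plane_point(ees, rep(0, m))
  v <- matrix(0, n, m)
  v[ees$internal_idx, ] <- diag(m)
  if (length(ees$external) > 0) {
    v[-ees$internal_idx, ] <- ees$external_coeffs[, -1, drop = FALSE]
  }
  vw <- v * w
  gram <- crossprod(v, vw)
  cond <- kappa(gram, exact = TRUE)
  if (!is.finite(cond) || cond > ees$cond_cap^2) {
    abort_eesnet(
      sprintf("plane parametrization rank-deficient (condition %.3g)", cond),
      "eesnet_steering_error"
    )
  }
  s <- as.numeric(solve(gram, crossprod(vw, Q - base)))
  pr <- base + as.numeric(v %*% s)
  p0 <- ees$training_points[, 1]
  structure(
    list(
      target_Q = Q,
      projection_Pr = pr,
      internal_settings = stats::setNames(s, ees$internal),
      negative_settings = any(s < 0),
      realized_Qprime = NULL,
      weights = if (is.null(weights)) NULL else w,
      distances = list(
        d_P0_Q = weighted_euclid(p0, Q, w),
        d_Pr_Q = weighted_euclid(pr, Q, w)
      )
    ),
    class = "steering_result"
  )
}

weighted_euclid <- function(a, b, w) sqrt(sum(w * (a - b)^2))

#' Steer the full network toward a target state
#'
#' Computes the plane projection `Pr` of the target `Q`, then clamps all
#' internal genes of the full model at the projection's internal settings
#' and solves for the realized equilibrium `Q'`.  The distance quartet
#' d(P0,Q), d(Pr,Q), d(Q',Pr), d(Q',Q) quantifies how far the equilibrium
#' could be moved and how faithfully the plane anticipated the move.
#'
#' @param net the full `ees_network` the EES was fitted on.
#' @param ees the fitted `ees_model`.
#' @param Q numeric target vector, length N.
#' @param weights optional positive per-gene distance weights.
#' @inheritParams solve_steady_state
#' @return a `steering_result` with `realized_Qprime` and all four
#'   distances filled; if the clamped solve is not viable, `realized_Qprime`
#'   is `NULL` and `clamped_solve_failed = TRUE` (with a warning).
#' @export
evaluate_steering <- function(net, ees, Q, weights = NULL, tol = NULL,
                              max_iter = 500L) {
  res <- project_onto_plane(ees, Q, weights)
  w <- res$weights %||% rep(1, length(Q))
  # steering may ask for (flagged) negative settings; bypass the >= 0 guard
  spec <- structure(list(clamps = res$internal_settings,
                         label = "steering-clamp"),
                    class = "mutant_spec")
  ss <- solve_steady_state(net, spec, tol = tol, max_iter = max_iter)
  if (!ss$viable) {
    warning("clamped steering solve did not converge to a viable state")
    res$clamped_solve_failed <- TRUE
    return(res)
  }
  res$realized_Qprime <- ss$x
  res$clamped_solve_failed <- FALSE
  res$distances$d_Qprime_Pr <- weighted_euclid(ss$x, res$projection_Pr, w)
  res$distances$d_Qprime_Q <- weighted_euclid(ss$x, Q, w)
  res
}

#' @export
print.steering_result <- function(x, ...) {
  cat("<steering_result>\n")
  d <- x$distances
  cat(sprintf("  d(P0,Q) = %.4g   d(Pr,Q) = %.4g\n", d$d_P0_Q, d$d_Pr_Q))
  if (!is.null(x$realized_Qprime)) {
    cat(sprintf("  d(Q',Pr) = %.4g  d(Q',Q) = %.4g\n",
                d$d_Qprime_Pr, d$d_Qprime_Q))
  }
  if (x$negative_settings) {
    cat("  note: some internal settings are negative (unreachable)\n")
  }
  invisible(x)
}

#' Serialize a steering result as JSON
#'
#' @param result a `steering_result`.
#' @param path JSON file path.
#' @export
write_steering <- function(result, path) {
  stopifnot(inherits(result, "steering_result"))
  doc <- list(
    format_version = FORMAT_VERSION,
    kind = "steering_result",
    target_Q = result$target_Q,
    projection_Pr = result$projection_Pr,
    internal_settings = as.list(result$internal_settings),
    negative_settings = result$negative_settings,
    realized_Qprime = result$realized_Qprime,
    distances = result$distances
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
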