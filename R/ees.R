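#' Fit the effective empirical subnetwork (EES)
#'
#' Constructs the affine model whose solution set is the unique
#' m-dimensional plane through the wildtype steady state `P0` and the m
#' single-knockout steady states `P_1..P_m` of the chosen internal genes.
#'
#' Two families of coefficients are solved, both by square linear systems:
#'
#' * each external gene j is an affine function of the internal levels,
#'   `x_j = c_j0 + sum_k c_jk s_k`, fitted through all m+1 training points;
#' * each internal gene k satisfies an affine inter-relation
#'   `x_k = a_k0 + sum_{l != k} a_kl x_l`, fitted through the m points
#'   `{P0} U {P_l : l != k}` — exactly the points at which gene k is itself
#'   determined by the network (knocking out k makes it external, so its
#'   own training point is excluded).
#'
#' The knocked-out gene's own measured level is forced to 0 in its training
#' point before fitting (microarrays report non-functional transcript for
#' deleted genes); disable with `zero_knockout_level = FALSE`.
#'
#' @param wildtype length-N named (or `gene_ids`-ordered) wildtype levels
#'   (the point `P0`).
#' @param knockouts N x m matrix (or list of m vectors) of single-knockout
#'   steady states, column k the knockout of `internal[k]`.
#' @param internal character vector of the m internal gene identifiers
#'   (the controllable set S).
#' @param gene_ids gene identifiers; defaults to `names(wildtype)` or
#'   `rownames(knockouts)`.
#' @param zero_knockout_level force knockout gene's own level to 0 before
#'   fitting (default TRUE).
#' @param cond_cap condition-number cap above which the fit aborts as
#'   degenerate (default 1e8: microarray-scale noise makes ill-conditioned
#'   planes meaningless).
#' @return an object of class `ees_model` with fields `gene_ids`,
#'   `internal`, `external`, `external_coeffs` ((N-m) x (m+1): intercept
#'   then coefficients), `internal_coeffs` (m x m: intercept then
#'   coefficients over the other internals in order), `training_points`
#'   (N x (m+1) matrix, wildtype first), `condition_report`.
#' @export
#' @examples
#' # two genes, one internal: the plane is the line through (1,1), (0,0.4)
#' ees <- fit_ees(c(g1 = 1, g2 = 1), cbind(c(0, 0.4)), internal = "g1")
#' ees$external_coeffs  # intercept 0.4, slope 0.6
fit_ees <- function(wildtype, knockouts, internal, gene_ids = NULL,
                    zero_knockout_level = TRUE, cond_cap = 1e8) {
  if (is.list(knockouts)) knockouts <- do.call(cbind, knockouts)
  if (!is.matrix(knockouts)) knockouts <- as.matrix(knockouts)
  gene_ids <- gene_ids %||% names(wildtype) %||% rownames(knockouts)
  if (is.null(gene_ids)) {
    abort_eesnet("gene identifiers required (names/rownames or gene_ids)",
                 "eesnet_config_error")
  }
  n <- length(gene_ids)
  m <- length(internal)
  if (m < 1) abort_eesnet("need at least one internal gene",
                          "eesnet_config_error")
  check_numeric_vector(wildtype, n, "wildtype")
  if (nrow(knockouts) != n || ncol(knockouts) != m) {
    abort_eesnet(sprintf("knockouts must be %d x %d", n, m),
                 "eesnet_shape_error")
  }
  int_idx <- match(internal, gene_ids)
  if (anyNA(int_idx)) {
    abort_eesnet("internal genes not all present in gene_ids",
                 "eesnet_index_error")
  }
  external <- gene_ids[-int_idx]

  p <- cbind(unname(wildtype), unname(knockouts))  # N x (m+1), P0 first
  if (zero_knockout_level) {
    for (k in seq_len(m)) p[int_idx[k], k + 1] <- 0
  }
  s <- t(p[int_idx, , drop = FALSE])               # (m+1) x m internal coords

  design <- cbind(1, s)
  cond_ext <- kappa(design, exact = TRUE)
  if (!is.finite(cond_ext) || cond_ext > cond_cap) {
    abort_eesnet(
      sprintf(paste0("training points are affinely degenerate in internal ",
                     "coordinates (condition number %.3g > %.3g)"),
              cond_ext, cond_cap),
      "eesnet_fit_error"
    )
  }
  external_coeffs <- if (length(external) > 0) {
    ext_rhs <- t(p[-int_idx, , drop = FALSE])      # (m+1) x (N-m)
    t(solve(design, ext_rhs))                      # (N-m) x (m+1)
  } else {
    matrix(0, 0, m + 1)                            # m = N: no externals
  }

  internal_coeffs <- matrix(0, m, m)
  cond_int <- numeric(m)
  for (k in seq_len(m)) {
    pts <- c(1, setdiff(seq_len(m), k) + 1)        # P0 and P_l, l != k
    dk <- cbind(1, t(p[int_idx[-k], pts, drop = FALSE]))  # m x m
    cond_int[k] <- kappa(dk, exact = TRUE)
    if (!is.finite(cond_int[k]) || cond_int[k] > cond_cap) {
      abort_eesnet(
        sprintf("internal relation for %s degenerate (condition %.3g)",
                internal[k], cond_int[k]),
        "eesnet_fit_error"
      )
    }
    internal_coeffs[k, ] <- solve(dk, p[int_idx[k], pts])
  }

  colnames(external_coeffs) <- c("intercept", internal)
  rownames(external_coeffs) <- external
  rownames(internal_coeffs) <- internal
  rownames(p) <- gene_ids
  colnames(p) <- c("wildtype", paste0("ko_", internal))

  structure(
    list(
      gene_ids = gene_ids,
      internal = internal,
      external = external,
      internal_idx = int_idx,
      external_coeffs = external_coeffs,
      internal_coeffs = internal_coeffs,
      training_points = p,
      condition_report = list(external = cond_ext, internal = cond_int),
      cond_cap = cond_cap
    ),
    class = "ees_model"
  )
}

#' @export
print.ees_model <- function(x, ...) {
  cat(sprintf("<ees_model> %d genes, %d internal (%s)\n",
              length(x$gene_ids), length(x$internal),
              paste(x$internal, collapse = ", ")))
  cat(sprintf("  fit condition numbers: external %.3g, internal max %.3g\n",
              x$condition_report$external, max(x$condition_report$internal)))
  invisible(x)
}

#' Evaluate a point of the EES plane
#'
#' Maps internal coordinates to the full expression vector: internal genes
#' take the given values, each external gene its affine function of them.
#' The image over all internal coordinates is exactly the plane `P_E`.
#'
#' @param ees a fitted `ees_model`.
#' @param internal_values numeric vector of length m.
#' @return named numeric vector of length N in `gene_ids` order.
#' @export
plane_point <- function(ees, internal_values) {
  m <- length(ees$internal)
  check_numeric_vector(internal_values, m, "internal_values")
  x <- numeric(length(ees$gene_ids))
  names(x) <- ees$gene_ids
  x[ees$internal_idx] <- internal_values
  if (length(ees$external) > 0) {
    x[-ees$internal_idx] <-
      ees$external_coeffs %*% c(1, internal_values)
  }
  x
}

#' Predict the expression profile of a clamped mutant
#'
#' Clamps a subset of the internal genes (e.g. both genes of a double
#' knockout at 0), solves the remaining internal genes from the linear
#' system of their inter-relations with the clamped values substituted, and
#' finally evaluates the external genes on the plane.
#'
#' @param ees a fitted `ees_model`.
#' @param clamps named numeric vector; names must be internal gene ids.
#' @return named numeric vector of length N: the predicted steady state.
#' @export
#' @examples
#' \dontrun{
#' predict_mutant(ees, c(fnr = 0, arcA = 0))  # double-knockout prediction
#' }
predict_mutant <- function(ees, clamps) {
  m <- length(ees$internal)
  if (length(clamps) < 1) {
    abort_eesnet("at least one clamp required", "eesnet_config_error")
  }
  check_numeric_vector(clamps, what = "clamps")
  pos <- match(names(clamps), ees$internal)
  if (anyNA(pos)) {
    abort_eesnet(
      paste0("clamped gene(s) not internal: ",
             paste(names(clamps)[is.na(pos)], collapse = ", ")),
      "eesnet_domain_error"
    )
  }
  s <- numeric(m)
  s[pos] <- unname(clamps)
  free <- setdiff(seq_len(m), pos)
  if (length(free) > 0) {
    # relation k:  x_k - sum_{l != k} a_kl x_l = a_k0
    r <- diag(m)
    a0 <- ees$internal_coeffs[, 1]
    for (k in seq_len(m)) {
      r[k, -k] <- -ees$internal_coeffs[k, -1]
    }
    rff <- r[free, free, drop = FALSE]
    cond <- kappa(rff, exact = TRUE)
    if (!is.finite(cond) || cond > ees$cond_cap) {
      abort_eesnet(
        sprintf("reduced internal system is singular (condition %.3g)", cond),
        "eesnet_prediction_error"
      )
    }
    rhs <- a0[free] - r[free, pos, drop = FALSE] %*% s[pos]
    s[free] <- solve(rff, rhs)
  }
  plane_point(ees, s)
}

#' Post-fit consistency audit
#'
#' Recomputes the residuals of both coefficient families on the training
#' points: every training point must satisfy the external-plane relations,
#' and each internal relation must hold at the wildtype and at every
#' knockout other than its own gene.  Used as a gate after fitting; a
#' perturbed coefficient shows up as a nonzero residual.
#'
#' @param ees a fitted `ees_model`.
#' @return list with `max_external_residual`, `max_internal_residual`, and
#'   the full residual matrices.
#' @export
training_consistency_check <- function(ees) {
  p <- ees$training_points
  m <- length(ees$internal)
  s <- t(p[ees$internal_idx, , drop = FALSE])
  ext_res <- if (length(ees$external) > 0) {
    fitted <- ees$external_coeffs %*% t(cbind(1, s))
    abs(p[-ees$internal_idx, , drop = FALSE] - fitted)
  } else matrix(0, 0, ncol(p))
  int_res <- matrix(NA_real_, m, ncol(p))
  for (k in seq_len(m)) {
    pts <- c(1, setdiff(seq_len(m), k) + 1)
    pred <- ees$internal_coeffs[k, 1] +
      as.numeric(ees$internal_coeffs[k, -1, drop = FALSE] %*%
                   p[ees$internal_idx[-k], pts, drop = FALSE])
    int_res[k, pts] <- abs(p[ees$internal_idx[k], pts] - pred)
  }
  list(
    max_external_residual = if (length(ext_res)) max(ext_res) else 0,
    max_internal_residual = max(int_res, na.rm = TRUE),
    external_residuals = ext_res,
    internal_residuals = int_res
  )
}

#' Rank candidate internal genes
#'
#' Convenience for choosing the controllable set S: ranks genes by
#' single-knockout viability (non-viable genes are excluded — they cannot
#' be clamped to zero) and solver residual, optionally balancing picks
#' across network clusters.  The choice of S is a biological decision; this
#' helper proposes, it never auto-selects silently.
#'
#' @param net an `influence_network`.
#' @param panel a [knockout_panel()] over `net$gene_ids` (one single
#'   knockout per gene, in gene order).
#' @param m number of internal genes to propose.
#' @param spread_clusters pick round-robin across clusters when cluster
#'   assignments exist (default TRUE).
#' @return character vector of m proposed gene ids, best-ranked first.
#' @export
select_internal_genes <- function(net, panel, m, spread_clusters = TRUE) {
  viable <- vapply(panel, function(s) s$viable, logical(1))
  residual <- vapply(panel, function(s) s$residual, numeric(1))
  if (sum(viable) < m) {
    abort_eesnet(
      sprintf("only %d viable single knockouts, need %d", sum(viable), m),
      "eesnet_config_error"
    )
  }
  cand <- which(viable)
  cand <- cand[order(residual[cand])]
  if (spread_clusters && !is.null(net$cluster_of)) {
    picked <- integer(0)
    by_cluster <- split(cand, net$cluster_of[cand])
    while (length(picked) < m) {
      for (cl in seq_along(by_cluster)) {
        pool <- setdiff(by_cluster[[cl]], picked)
        if (length(pool) > 0 && length(picked) < m) {
          picked <- c(picked, pool[1])
        }
      }
      if (all(vapply(by_cluster, function(p) all(p %in% picked),
                     logical(1)))) break
    }
    cand <- c(picked, setdiff(cand, picked))
  }
  net$gene_ids[cand[seq_len(m)]]
}

#' Serialize / load an EES model as JSON
#'
#' @param ees a fitted `ees_model`.
#' @param path JSON file path.
#' @return `read_ees()` returns the `ees_model`; `write_ees()` returns
#'   `path` invisibly.
#' @export
write_ees <- function(ees, path) {
  stopifnot(inherits(ees, "ees_model"))
  doc <- list(
    format_version = FORMAT_VERSION,
    kind = "ees_model",
    gene_ids = ees$gene_ids,
    internal = ees$internal,
    external = ees$external,
    external_coeffs = ees$external_coeffs,
    internal_coeffs = ees$internal_coeffs,
    training_points = ees$training_points,
    condition_report = ees$condition_report,
    cond_cap = ees$cond_cap
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ees
#' @export
read_ees <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_format_version(doc$format_version, "EES JSON")
  n <- length(doc$gene_ids)
  m <- length(doc$internal)
  ext <- matrix(unlist(doc$external_coeffs), n - m, m + 1)
  intc <- matrix(unlist(doc$internal_coeffs), m, m)
  p <- matrix(unlist(doc$training_points), n, m + 1)
  colnames(ext) <- c("intercept", doc$internal)
  rownames(ext) <- doc$external
  rownames(intc) <- doc$internal
  rownames(p) <- doc$gene_ids
  colnames(p) <- c("wildtype", paste0("ko_", doc$internal))
  ees <- structure(
    list(
      gene_ids = doc$gene_ids,
      internal = doc$internal,
      external = doc$external,
      internal_idx = match(doc$internal, doc$gene_ids),
      external_coeffs = ext,
      internal_coeffs = intc,
      training_points = p,
      condition_report = doc$condition_report,
      cond_cap = doc$cond_cap
    ),
    class = "ees_model"
  )
  chk <- training_consistency_check(ees)
  if (chk$max_external_residual > 1e-6 || chk$max_internal_residual > 1e-6) {
    abort_eesnet("loaded EES fails training consistency", "eesnet_format_error")
  }
  ees
}
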