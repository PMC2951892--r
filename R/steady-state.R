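#' Mutant specification
#'
#' A set of genes clamped at fixed expression values.  The empty spec is the
#' wildtype; a knockout clamps a gene at 0; a heterozygote clamps it at half
#' its wildtype level.
#'
#' @param clamps named numeric vector, names are gene identifiers (or
#'   integer indices as strings), values the clamped expression levels
#'   (>= 0).
#' @param label free-text identifier; defaults to a canonical one derived
#'   from the clamps.
#' @return an object of class `mutant_spec`.
#' @export
#' @examples
#' mutant_spec()                       # wildtype
#' mutant_spec(c(g3 = 0), "ko-g3")    # single knockout of gene g3
#' mutant_spec(c(g1 = 0, g4 = 0))     # double knockout
mutant_spec <- function(clamps = numeric(0), label = NULL) {
  if (length(clamps) > 0) {
    check_numeric_vector(clamps, what = "clamps")
    if (is.null(names(clamps)) || any(names(clamps) == "")) {
      abort_eesnet("clamps must be named by gene id", "eesnet_index_error")
    }
    if (anyDuplicated(names(clamps))) {
      abort_eesnet("clamped genes must be distinct", "eesnet_index_error")
    }
    if (any(clamps < 0)) {
      abort_eesnet("clamp values must be >= 0", "eesnet_domain_error")
    }
  }
  if (is.null(label)) {
    label <- if (length(clamps) == 0) "wildtype" else {
      paste0("clamp[", paste(sprintf("%s=%g", names(clamps), clamps),
                             collapse = ","), "]")
    }
  }
  structure(list(clamps = clamps, label = label), class = "mutant_spec")
}

#' @rdname mutant_spec
#' @param genes gene identifiers to knock out (clamp at 0).
#' @export
knockout <- function(genes) {
  mutant_spec(stats::setNames(rep(0, length(genes)), genes),
              label = paste0("ko[", paste(genes, collapse = ","), "]"))
}

resolve_clamp_idx <- function(net, genes) {
  idx <- match(genes, net$gene_ids)
  if (anyNA(idx)) {
    suppressWarnings(as_int <- as.integer(genes[is.na(idx)]))
    if (!anyNA(as_int) && all(as_int >= 1 & as_int <= net$n_genes)) {
      idx[is.na(idx)] <- as_int
    } else {
      abort_eesnet(
        paste0("unknown gene(s): ", paste(genes[is.na(idx)], collapse = ", ")),
        "eesnet_index_error"
      )
    }
  }
  idx
}

#' Solve the clamped steady-state problem
#'
#' Holds the mutant's clamped genes at their imposed values and solves the
#' remaining components of the ODE right-hand side as a nonlinear least
#' squares problem (damped Gauss-Newton / Levenberg-Marquardt with the
#' analytic Jacobian), started from the wildtype equilibrium with clamps
#' substituted.  Non-convergence never raises: the returned state carries
#' `viable = FALSE` when the RMS residual of the unclamped components stays
#' above the viability tolerance, or when any component is meaningfully
#' negative.
#'
#' @param net an `influence_network` or `linear_network`.
#' @param mutant a [mutant_spec()]; default wildtype.
#' @param init optional start vector (length N, no NAs).
#' @param tol RMS residual tolerance for viability; defaults to the
#'   network config's `viability_residual_tol` (1e-8).
#' @param max_iter iteration cap for the damped least-squares solver.
#' @return an object of class `steady_state`: fields `x`, `residual` (RMS
#'   over unclamped components), `viable`, `mutant`, `iterations`.
#' @export
#' @examples
#' net <- build_synthetic_network(network_config(seed = 2))
#' ss <- solve_steady_state(net)           # wildtype: x = x_star
#' ko <- solve_steady_state(net, knockout("g1"))
#' ko$viable
solve_steady_state <- function(net, mutant = mutant_spec(), init = NULL,
                               tol = NULL, max_iter = 500L) {
  stopifnot(inherits(net, "ees_network"), inherits(mutant, "mutant_spec"))
  tol <- tol %||% net$config$viability_residual_tol %||% 1e-8
  n <- net$n_genes
  clamp_idx <- resolve_clamp_idx(net, names(mutant$clamps))
  clamp_val <- unname(mutant$clamps)
  if (is.null(init)) {
    init <- net$x_star
  }
  check_numeric_vector(init, n, "init")
  x <- init
  x[clamp_idx] <- clamp_val
  free <- setdiff(seq_len(n), clamp_idx)

  if (length(free) == 0) {
    return(new_steady_state(x, 0, TRUE, mutant, 0L, tol))
  }

  resid_fun <- function(x) net_dynamics(net, x)[free]
  r <- resid_fun(x)
  lambda <- 1e-3
  iter <- 0L
  while (iter < max_iter) {
    rms <- sqrt(mean(r^2))
    if (rms < tol * 1e-2) break  # solve well below the viability threshold
    j <- net_jacobian(net, x)[free, free, drop = FALSE]
    jtj <- crossprod(j)
    g <- crossprod(j, r)
    step_ok <- FALSE
    for (k in 1:25) {
      h <- jtj + lambda * diag(diag(jtj), nrow(jtj))
      delta <- tryCatch(solve(h, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        x_new <- x
        x_new[free] <- x[free] + as.numeric(delta)
        r_new <- resid_fun(x_new)
        if (all(is.finite(r_new)) && sum(r_new^2) < sum(r^2)) {
          x <- x_new; r <- r_new
          lambda <- max(lambda / 3, 1e-12)
          step_ok <- TRUE
          break
        }
      }
      lambda <- lambda * 5
    }
    iter <- iter + 1L
    if (!step_ok) break  # stalled at a local minimum of the residual
  }
  new_steady_state(x, sqrt(mean(r^2)), NA, mutant, iter, tol)
}

new_steady_state <- function(x, residual, viable, mutant, iterations, tol) {
  if (is.na(viable)) {
    viable <- residual < tol && min(x) > -1e-9
  }
  structure(
    list(x = x, residual = residual, viable = viable, mutant = mutant,
         iterations = iterations, tol = tol),
    class = "steady_state"
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> %s: %s (RMS residual %.3e, %d iterations)\n",
              x$mutant$label, if (x$viable) "viable" else "NOT viable",
              x$residual, x$iterations))
  invisible(x)
}

#' Single-knockout panel
#'
#' Solves the clamped steady state for each requested single knockout and
#' reports viability.
#'
#' @param net an `ees_network`.
#' @param genes gene identifiers to knock out one at a time; defaults to
#'   all genes.
#' @param include_wildtype prepend the unclamped solve.
#' @inheritParams solve_steady_state
#' @return a list of `steady_state` objects, in input order, with class
#'   `knockout_panel`.
#' @export
knockout_panel <- function(net, genes = net$gene_ids,
                           include_wildtype = FALSE, tol = NULL,
                           max_iter = 500L) {
  specs <- lapply(genes, knockout)
  if (include_wildtype) specs <- c(list(mutant_spec()), specs)
  out <- lapply(specs, function(sp) {
    solve_steady_state(net, sp, tol = tol, max_iter = max_iter)
  })
  structure(out, class = "knockout_panel")
}

#' @export
print.knockout_panel <- function(x, ...) {
  nv <- sum(vapply(x, function(s) s$viable, logical(1)))
  cat(sprintf("<knockout_panel> %d mutants, %d viable / %d non-viable\n",
              length(x), nv, length(x) - nv))
  invisible(x)
}

#' All double knockouts over an internal gene set
#'
#' Solves every unordered pair of knockouts among the supplied genes
#' (expected to be singly-viable) and flags viability of each pair.
#'
#' @param net an `ees_network`.
#' @param internal_genes at least two gene identifiers.
#' @inheritParams solve_steady_state
#' @return a list of `steady_state` objects, one per pair, with class
#'   `knockout_panel`.
#' @export
viable_double_knockouts <- function(net, internal_genes, tol = NULL,
                                    max_iter = 500L) {
  if (length(internal_genes) < 2) {
    abort_eesnet("need at least two internal genes", "eesnet_config_error")
  }
  pairs <- utils::combn(internal_genes, 2, simplify = FALSE)
  out <- lapply(pairs, function(p) {
    solve_steady_state(net, knockout(p), tol = tol, max_iter = max_iter)
  })
  structure(out, class = "knockout_panel")
}

#' Panel export helpers
#'
#' `panel_expression()` assembles a genes x mutants expression matrix;
#' `write_panel_tsv()` writes it together with a viability sidecar table.
#'
#' @param panel a list of `steady_state` objects.
#' @param net the network the panel was solved on.
#' @return `panel_expression()`: a numeric matrix with gene ids as row
#'   names and mutant labels as column names.
#' @export
panel_expression <- function(panel, net) {
  m <- vapply(panel, function(s) s$x, numeric(net$n_genes))
  rownames(m) <- net$gene_ids
  colnames(m) <- vapply(panel, function(s) s$mutant$label, character(1))
  m
}

#' @rdname panel_expression
#' @param expr_path path for the genes x mutants TSV.
#' @param viability_path path for the viability sidecar TSV.
#' @export
write_panel_tsv <- function(panel, net, expr_path, viability_path) {
  m <- panel_expression(panel, net)
  df <- data.frame(gene = rownames(m), format_num_df(m),
                   check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  via <- data.frame(
    mutant = colnames(m),
    viable = vapply(panel, function(s) s$viable, logical(1)),
    residual = vapply(panel, function(s) s$residual, numeric(1)),
    iterations = vapply(panel, function(s) s$iterations, integer(1))
  )
  utils::write.table(via, viability_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(expr_path)
}

format_num_df <- function(m) {
  as.data.frame(apply(m, 2, function(col) format_num(col)),
                optional = TRUE)
}
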