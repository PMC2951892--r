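#' End-to-end synthetic double-knockout study
#'
#' Runs the full benchmark pipeline on one synthetic network: build the
#' clustered Hill-function system, solve the single-knockout panel, choose
#' an internal gene set among the viable knockouts, fit the EES, solve
#' every double knockout of internal genes in the full model, and compare
#' the EES predictions with the ground-truth equilibria.  The EES error is
#' contrasted with the naive wildtype-baseline predictor (which predicts
#' that nothing changes except the clamped genes).
#'
#' @param config a [network_config()]; its seed drives everything.
#' @param m number of internal genes (default 6, two per cluster at paper
#'   scale).
#' @param genes_per_relerr genes used in the relative-error summaries:
#'   "all" or "external".
#' @return list of class `ees_study`: the network, panel, internal set,
#'   fitted EES, double-knockout states and predictions, and per-pair
#'   median relative errors for EES and baseline.
#' @export
#' @examples
#' \donttest{
#' st <- run_synthetic_study(network_config(seed = 11))
#' st$summary$median_relerr_ees < st$summary$median_relerr_baseline
#' }
run_synthetic_study <- function(config = network_config(), m = 6,
                                genes_per_relerr = c("all", "external")) {
  genes_per_relerr <- match.arg(genes_per_relerr)
  net <- build_synthetic_network(config)
  panel <- knockout_panel(net)
  internal <- select_internal_genes(net, panel, m)
  int_idx <- match(internal, net$gene_ids)
  kos <- vapply(int_idx, function(i) panel[[i]]$x, numeric(net$n_genes))
  ees <- fit_ees(net$x_star, kos, internal, gene_ids = net$gene_ids)

  doubles <- viable_double_knockouts(net, internal)
  pair_labels <- vapply(doubles, function(s) s$mutant$label, character(1))
  viable <- vapply(doubles, function(s) s$viable, logical(1))

  relerr <- function(pred, truth, drop_idx) {
    keep <- setdiff(seq_along(truth), drop_idx)
    if (genes_per_relerr == "external") {
      keep <- setdiff(keep, int_idx)
    }
    abs(pred[keep] - truth[keep]) / pmax(abs(truth[keep]), 1e-12)
  }
  err_ees <- err_base <- rep(NA_real_, length(doubles))
  predictions <- vector("list", length(doubles))
  for (i in which(viable)) {
    pair <- names(doubles[[i]]$mutant$clamps)
    truth <- doubles[[i]]$x
    pred <- predict_mutant(ees, stats::setNames(c(0, 0), pair))
    base <- net$x_star
    base[match(pair, net$gene_ids)] <- 0
    drop_idx <- match(pair, net$gene_ids)
    err_ees[i] <- stats::median(relerr(pred, truth, drop_idx))
    err_base[i] <- stats::median(relerr(base, truth, drop_idx))
    predictions[[i]] <- pred
  }

  structure(
    list(
      net = net, panel = panel, internal = internal, ees = ees,
      doubles = doubles, predictions = predictions,
      summary = list(
        seed = config$seed,
        n_viable_single = sum(vapply(panel, function(s) s$viable,
                                     logical(1))),
        n_viable_double = sum(viable),
        n_double_attempted = length(doubles),
        pair_labels = pair_labels,
        per_pair_relerr_ees = err_ees,
        per_pair_relerr_baseline = err_base,
        median_relerr_ees = stats::median(err_ees, na.rm = TRUE),
        median_relerr_baseline = stats::median(err_base, na.rm = TRUE),
        relerr_quantiles_ees = stats::quantile(
          err_ees, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
      )
    ),
    class = "ees_study"
  )
}

#' @export
print.ees_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ees_study> seed %d: %d/%d single KOs viable, %d/%d double\n",
              s$seed, s$n_viable_single, x$net$n_genes,
              s$n_viable_double, s$n_double_attempted))
  cat(sprintf("  median relative error: EES %.4f vs wildtype baseline %.4f\n",
              s$median_relerr_ees, s$median_relerr_baseline))
  invisible(x)
}

#' Synthetic replicate dataset from a fitted model
#'
#' Builds an `expression_dataset` shaped like a microarray validation
#' study: replicate measurements drawn as (condition mean) x (1 +
#' multiplicative Gaussian noise), for the wildtype, the single knockouts
#' of the internal genes, and optionally a double knockout.  Purely
#' synthetic — a stand-in for real array data in tests and examples.
#'
#' @param net an `ees_network`.
#' @param internal internal gene ids (single knockouts simulated per gene).
#' @param double_pair optional pair of internal genes for a double-KO
#'   condition.
#' @param n_wt,n_mut replicate counts (defaults 4 and 3, the usual design).
#' @param noise_sd multiplicative noise standard deviation (default 0.1,
#'   typical array-scale relative error).
#' @param seed integer seed.
#' @return an [expression_dataset()] (raw scale, not rescaled).
#' @export
simulate_replicate_dataset <- function(net, internal, double_pair = NULL,
                                       n_wt = 4L, n_mut = 3L,
                                       noise_sd = 0.1, seed = 1L) {
  specs <- list(wildtype = mutant_spec())
  annotation <- list()
  for (g in internal) {
    lab <- paste0("ko_", g)
    specs[[lab]] <- knockout(g)
    annotation[[lab]] <- g
  }
  if (!is.null(double_pair)) {
    lab <- paste0("ko_", paste(double_pair, collapse = "_"))
    specs[[lab]] <- knockout(double_pair)
    annotation[[lab]] <- double_pair
  }
  with_local_seed(seed, {
    conditions <- lapply(names(specs), function(lab) {
      ss <- solve_steady_state(net, specs[[lab]])
      if (!ss$viable) {
        abort_eesnet(sprintf("condition '%s' is not viable", lab),
                     "eesnet_data_error")
      }
      nrep <- if (lab == "wildtype") n_wt else n_mut
      mt <- vapply(seq_len(nrep), function(r) {
        ss$x * (1 + stats::rnorm(net$n_genes, 0, noise_sd))
      }, numeric(net$n_genes))
      rownames(mt) <- net$gene_ids
      mt
    })
    names(conditions) <- names(specs)
    expression_dataset(conditions, wildtype = "wildtype",
                       knockout_annotation = annotation)
  })
}
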