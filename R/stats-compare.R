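#' Replicate expression dataset keyed by condition
#'
#' Container for replicate-level expression tables: one genes x replicates
#' matrix per condition (wildtype plus mutants), with an annotation of
#' which genes are knocked out in each mutant condition.
#'
#' @param conditions named list of numeric matrices (genes x replicates),
#'   identical row sets; names are condition labels.
#' @param wildtype label of the wildtype condition (default "wildtype").
#' @param knockout_annotation named list: condition label -> character
#'   vector of knocked-out gene ids.
#' @param rescaled whether levels are already wildtype-rescaled.
#' @return an object of class `expression_dataset`.
#' @export
expression_dataset <- function(conditions, wildtype = "wildtype",
                               knockout_annotation = list(),
                               rescaled = FALSE) {
  if (!wildtype %in% names(conditions)) {
    abort_eesnet(sprintf("wildtype condition '%s' absent", wildtype),
                 "eesnet_data_error")
  }
  gene_ids <- rownames(conditions[[wildtype]])
  if (is.null(gene_ids)) {
    abort_eesnet("condition matrices must have gene row names",
                 "eesnet_data_error")
  }
  if (anyDuplicated(gene_ids)) {
    abort_eesnet("duplicate gene ids", "eesnet_data_error")
  }
  for (cond in names(conditions)) {
    mt <- conditions[[cond]]
    if (!is.matrix(mt) || !identical(rownames(mt), gene_ids)) {
      abort_eesnet(
        sprintf("condition '%s' rows do not match wildtype", cond),
        "eesnet_data_error"
      )
    }
    if (ncol(mt) < 2) {
      abort_eesnet(sprintf("condition '%s' needs >= 2 replicates", cond),
                   "eesnet_data_error")
    }
  }
  for (cond in names(knockout_annotation)) {
    missing <- setdiff(knockout_annotation[[cond]], gene_ids)
    if (length(missing) > 0) {
      abort_eesnet(
        paste0("annotated knockout gene(s) absent from table: ",
               paste(missing, collapse = ", ")),
        "eesnet_annotation_error"
      )
    }
  }
  structure(
    list(gene_ids = gene_ids, conditions = conditions, wildtype = wildtype,
         knockout_annotation = knockout_annotation, rescaled = rescaled),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  reps <- vapply(x$conditions, ncol, integer(1))
  cat(sprintf("<expression_dataset> %d genes, %d conditions%s\n",
              length(x$gene_ids), length(x$conditions),
              if (x$rescaled) " (wildtype-rescaled)" else ""))
  cat("  replicates:", paste(sprintf("%s=%d", names(reps), reps),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Rescale all conditions by the wildtype per-gene mean
#'
#' Because the EES is affine, expression is analysed relative to the
#' wildtype: every replicate of every condition is divided gene-wise by the
#' wildtype replicate mean, making the rescaled wildtype mean exactly 1 for
#' every gene.
#'
#' @param data an `expression_dataset`, not yet rescaled.
#' @return the rescaled `expression_dataset`.
#' @export
rescale_by_wildtype <- function(data) {
  stopifnot(inherits(data, "expression_dataset"))
  if (data$rescaled) {
    abort_eesnet("dataset is already rescaled", "eesnet_normalization_error")
  }
  wt_mean <- rowMeans(data$conditions[[data$wildtype]])
  bad <- data$gene_ids[wt_mean <= 0]
  if (length(bad) > 0) {
    abort_eesnet(
      paste0("non-positive wildtype mean for gene(s): ",
             paste(bad, collapse = ", ")),
      "eesnet_normalization_error"
    )
  }
  data$conditions <- lapply(data$conditions, function(mt) mt / wt_mean)
  data$rescaled <- TRUE
  data
}

#' Zero the measured levels of knocked-out genes
#'
#' Deleted genes can still show nonzero array signal (non-functional
#' transcript analogs); before fitting or comparing, each mutant
#' condition's knocked-out genes are set to 0 in all replicates.  The
#' wildtype and unannotated genes are untouched.
#'
#' @param data an `expression_dataset` with `knockout_annotation` set.
#' @return the modified `expression_dataset`.
#' @export
zero_knocked_out_levels <- function(data) {
  stopifnot(inherits(data, "expression_dataset"))
  for (cond in names(data$knockout_annotation)) {
    genes <- data$knockout_annotation[[cond]]
    if (!cond %in% names(data$conditions)) {
      abort_eesnet(sprintf("annotated condition '%s' absent", cond),
                   "eesnet_annotation_error")
    }
    data$conditions[[cond]][genes, ] <- 0
  }
  data
}

#' One-sample t test of replicates against a model prediction
#'
#' Tests the null that the replicates come from a normal distribution whose
#' mean equals the predicted expression level: two-sided one-sample t with
#' `df = n - 1` (three mutant replicates give the Student distribution with
#' two degrees of freedom).  Zero replicate spread is handled explicitly:
#' the t statistic is undefined and rejection is decided by exact equality
#' of mean and prediction — relevant because zeroed knockout genes have
#' sd 0.
#'
#' @param replicates numeric vector, length >= 2.
#' @param predicted predicted expression level.
#' @param alpha two-sided test level (default 0.05).
#' @return one-row data.frame: `predicted`, `observed_mean`, `observed_sd`,
#'   `n_rep`, `t_stat`, `df`, `critical`, `rejected`, `degenerate`.
#' @export
#' @examples
#' ttest_vs_prediction(c(1, 2, 3), 0)  # |t| = 3.46 < 4.30: not rejected
ttest_vs_prediction <- function(replicates, predicted, alpha = 0.05) {
  check_numeric_vector(replicates, what = "replicates")
  if (length(replicates) < 2) {
    abort_eesnet("need at least two replicates", "eesnet_test_error")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort_eesnet("alpha must be in (0, 1)", "eesnet_test_error")
  }
  n <- length(replicates)
  mu <- mean(replicates)
  sdv <- stats::sd(replicates)  # n - 1 convention
  df <- n - 1L
  crit <- stats::qt(1 - alpha / 2, df)
  if (sdv == 0) {
    # zero spread: the t statistic is undefined unless the deviation is
    # also exactly zero; rejection is decided by exact equality
    return(data.frame(
      predicted = predicted, observed_mean = mu, observed_sd = 0,
      n_rep = n, t_stat = if (mu == predicted) 0 else NA_real_,
      df = df, critical = crit,
      rejected = mu != predicted, degenerate = TRUE
    ))
  }
  t_stat <- (mu - predicted) / (sdv / sqrt(n))
  data.frame(
    predicted = predicted, observed_mean = mu, observed_sd = sdv,
    n_rep = n, t_stat = t_stat, df = df, critical = crit,
    rejected = abs(t_stat) > crit, degenerate = FALSE
  )
}

#' Compare EES double-knockout predictions with measured replicates
#'
#' Predicts the double-knockout steady state from the EES (both genes
#' clamped at 0: remaining internal genes from their inter-relations,
#' external genes from the plane) and tests each gene's prediction against
#' the double-mutant replicates with [ttest_vs_prediction()].  The two
#' clamped genes themselves are excluded from testing.
#'
#' @param data a rescaled, knockout-zeroed `expression_dataset` whose gene
#'   set matches `ees$gene_ids`.
#' @param ees a fitted `ees_model`.
#' @param ko_pair character vector of the two knocked-out internal genes.
#' @param condition label of the double-mutant condition; defaults to the
#'   condition annotated with exactly `ko_pair`.
#' @param alpha test level.
#' @param breaks histogram break specification for the t statistics.
#' @param bh_adjust apply Benjamini-Hochberg across genes before deciding
#'   rejections (off by default: raw per-gene 5% decisions).
#' @return list of class `ees_comparison`: `table` (per-gene results with a
#'   `group` column internal/external), `rejection_fraction`, `n_rejected`,
#'   `n_tested`, `histogram` (data.frame of bin edges and counts).
#' @export
compare_double_knockout <- function(data, ees, ko_pair, condition = NULL,
                                    alpha = 0.05, breaks = "Sturges",
                                    bh_adjust = FALSE) {
  stopifnot(inherits(data, "expression_dataset"), inherits(ees, "ees_model"))
  if (!data$rescaled) {
    abort_eesnet("dataset must be wildtype-rescaled first",
                 "eesnet_data_error")
  }
  if (length(ko_pair) != 2 || !all(ko_pair %in% ees$internal)) {
    abort_eesnet("ko_pair must be two internal gene ids",
                 "eesnet_domain_error")
  }
  if (is.null(condition)) {
    hits <- names(Filter(function(g) setequal(g, ko_pair),
                         data$knockout_annotation))
    if (length(hits) != 1) {
      abort_eesnet("cannot identify the double-mutant condition; pass it",
                   "eesnet_data_error")
    }
    condition <- hits
  }
  if (!condition %in% names(data$conditions)) {
    abort_eesnet(sprintf("condition '%s' absent from dataset", condition),
                 "eesnet_data_error")
  }
  if (!setequal(data$gene_ids, ees$gene_ids)) {
    abort_eesnet("dataset and EES gene sets differ", "eesnet_data_error")
  }

  pred <- predict_mutant(ees, stats::setNames(c(0, 0), ko_pair))
  reps <- data$conditions[[condition]]
  genes <- setdiff(ees$gene_ids, ko_pair)
  rows <- lapply(genes, function(g) {
    row <- ttest_vs_prediction(reps[g, ], pred[[g]], alpha)
    row$gene <- g
    row$group <- if (g %in% ees$internal) "internal" else "external"
    row
  })
  tab <- do.call(rbind, rows)
  tab <- tab[, c("gene", "group", setdiff(names(tab), c("gene", "group")))]
  if (bh_adjust) {
    p <- 2 * stats::pt(abs(tab$t_stat), tab$df, lower.tail = FALSE)
    adj <- stats::p.adjust(p, method = "BH")
    tab$rejected <- ifelse(tab$degenerate, tab$rejected, adj < alpha)
  }
  t_finite <- tab$t_stat[is.finite(tab$t_stat)]
  h <- graphics::hist(t_finite, breaks = breaks, plot = FALSE)
  structure(
    list(
      table = tab,
      condition = condition,
      ko_pair = ko_pair,
      n_tested = nrow(tab),
      n_rejected = sum(tab$rejected),
      rejection_fraction = mean(tab$rejected),
      histogram = data.frame(
        bin_left = utils::head(h$breaks, -1),
        bin_right = utils::tail(h$breaks, -1),
        count = h$counts
      )
    ),
    class = "ees_comparison"
  )
}

#' @export
print.ees_comparison <- function(x, ...) {
  cat(sprintf(
    "<ees_comparison> %s vs EES: %d/%d genes rejected (%.1f%%)\n",
    x$condition, x$n_rejected, x$n_tested, 100 * x$rejection_fraction
  ))
  invisible(x)
}

#' Largest mutant deviation in wildtype standard-deviation units
#'
#' For each gene, the maximum over mutant conditions of
#' `|mutant mean - wildtype mean| / wildtype sd` — the paper-style check
#' that good prediction agreement is not explained by a lack of variation
#' between wildtype and mutants.  Genes with zero wildtype sd are flagged
#' infinite-degenerate (`Inf`).
#'
#' @param data a rescaled `expression_dataset`.
#' @param conditions mutant conditions to scan; defaults to all
#'   non-wildtype conditions.
#' @return named numeric vector, one value per gene.
#' @export
max_normalized_deviation <- function(data, conditions = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  if (!data$rescaled) {
    abort_eesnet("dataset must be wildtype-rescaled first",
                 "eesnet_data_error")
  }
  conditions <- conditions %||% setdiff(names(data$conditions), data$wildtype)
  wt <- data$conditions[[data$wildtype]]
  wt_mean <- rowMeans(wt)
  wt_sd <- apply(wt, 1, stats::sd)
  dev <- sapply(conditions, function(cond) {
    abs(rowMeans(data$conditions[[cond]]) - wt_mean)
  })
  if (is.null(dim(dev))) dev <- matrix(dev, ncol = length(conditions))
  max_dev <- apply(dev, 1, max)
  out <- ifelse(wt_sd == 0, ifelse(max_dev == 0, 0, Inf), max_dev / wt_sd)
  stats::setNames(out, data$gene_ids)
}
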