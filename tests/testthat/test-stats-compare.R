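make_toy_dataset <- function() {
  genes <- c("gA", "gB", "gC")
  wt <- matrix(c(2, 2, 2, 2,
                 4, 4, 4, 4,
                 1, 1, 1, 1), nrow = 3, byrow = TRUE,
               dimnames = list(genes, NULL))
  mut <- matrix(c(1, 3,
                  2, 6,
                  0.3, 0.5), nrow = 3, byrow = TRUE,
                dimnames = list(genes, NULL))
  expression_dataset(
    list(wildtype = wt, ko_gA = mut),
    knockout_annotation = list(ko_gA = "gA")
  )
}

test_that("wildtype rescaling normalizes means to one and is single-shot", {
  ds <- rescale_by_wildtype(make_toy_dataset())
  expect_equal(unname(rowMeans(ds$conditions$wildtype)), c(1, 1, 1))
  # wildtype mean 2 with mutant replicates (1, 3) -> (0.5, 1.5)
  expect_equal(unname(ds$conditions$ko_gA["gA", ]), c(0.5, 1.5))
  expect_equal(unname(ds$conditions$ko_gA["gB", ]), c(0.5, 1.5))
  expect_error(rescale_by_wildtype(ds), class = "eesnet_normalization_error")
  bad <- make_toy_dataset()
  bad$conditions$wildtype["gB", ] <- 0
  err <- expect_error(rescale_by_wildtype(bad),
                      class = "eesnet_normalization_error")
  expect_match(conditionMessage(err), "gB")
})

test_that("knockout zeroing hits only annotated genes in mutant conditions", {
  ds <- zero_knocked_out_levels(make_toy_dataset())
  expect_equal(unname(ds$conditions$ko_gA["gA", ]), c(0, 0))
  expect_equal(unname(ds$conditions$ko_gA["gB", ]), c(2, 6))   # untouched
  expect_equal(unname(ds$conditions$wildtype["gA", ]), rep(2, 4))
  expect_error(
    expression_dataset(
      list(wildtype = make_toy_dataset()$conditions$wildtype),
      knockout_annotation = list(wildtype = "missing_gene")
    ),
    class = "eesnet_annotation_error"
  )
})

test_that("one-sample t test matches its closed form, df = n - 1", {
  r0 <- ttest_vs_prediction(c(1, 1, 1), 1)
  expect_equal(r0$t_stat, 0)
  expect_false(r0$rejected)
  expect_true(r0$degenerate)
  # t = (2 - 0) / (1 / sqrt(3)) = 3.4641 < qt(0.975, 2) = 4.3027
  r1 <- ttest_vs_prediction(c(1, 2, 3), 0)
  expect_equal(r1$t_stat, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(r1$df, 2L)
  expect_equal(r1$critical, stats::qt(0.975, 2))
  expect_false(r1$rejected)
  # same spread, larger shift: rejected
  r2 <- ttest_vs_prediction(c(1, 2, 3), -1)
  expect_true(r2$rejected)
  # degenerate spread: decision by exact equality
  r3 <- ttest_vs_prediction(c(5, 5, 5), 4)
  expect_true(r3$degenerate)
  expect_true(r3$rejected)
  r4 <- ttest_vs_prediction(c(5, 5, 5), 5)
  expect_false(r4$rejected)
  expect_error(ttest_vs_prediction(c(1), 0), class = "eesnet_test_error")
  expect_error(ttest_vs_prediction(c(1, 2), 0, alpha = 1),
               class = "eesnet_test_error")
})

test_that("agreement with stats::t.test on random replicates", {
  set.seed(40)
  for (r in 1:20) {
    reps <- rnorm(3, 1, 0.3)
    mu <- runif(1, 0, 2)
    ours <- ttest_vs_prediction(reps, mu)
    ref <- stats::t.test(reps, mu = mu)
    expect_equal(ours$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$rejected, ref$p.value < 0.05)
  }
})

test_that("double-knockout comparison: exact replicates give zero rejections", {
  net <- cached_network(1)
  internal <- select_internal_genes(net, knockout_panel(net), 6)
  ees <- fit_ees_from_network(net, internal)
  pair <- internal[1:2]
  pred <- predict_mutant(ees, stats::setNames(c(0, 0), pair))
  # zero-noise replicates exactly equal to the prediction: every gene is
  # degenerate with zero deviation, nothing can be rejected
  reps <- vapply(1:3, function(r) unname(pred), numeric(net$n_genes))
  rownames(reps) <- net$gene_ids
  wt <- matrix(1, net$n_genes, 4, dimnames = list(net$gene_ids, NULL))
  ds <- expression_dataset(
    list(wildtype = wt, dko = reps),
    knockout_annotation = stats::setNames(list(pair), "dko"),
    rescaled = TRUE
  )
  cmp <- compare_double_knockout(ds, ees, pair)
  expect_equal(cmp$n_tested, net$n_genes - 2L)
  expect_equal(sum(cmp$table$group == "internal"), length(internal) - 2L)
  expect_equal(cmp$rejection_fraction, 0)
  expect_equal(sum(cmp$histogram$count),
               sum(is.finite(cmp$table$t_stat)))
})

test_that("end-to-end synthetic validation study behaves like the real design", {
  net <- cached_network(2)
  internal <- select_internal_genes(net, knockout_panel(net), 6)
  ees <- fit_ees_from_network(net, internal)
  pair <- internal[1:2]
  ds <- simulate_replicate_dataset(net, internal, double_pair = pair,
                                   noise_sd = 0.05, seed = 9)
  ds <- zero_knocked_out_levels(rescale_by_wildtype(ds))
  cmp <- compare_double_knockout(ds, ees, pair)
  # predictions track the true double-KO equilibrium, so most genes accept
  expect_lt(cmp$rejection_fraction, 0.3)
  mnd <- max_normalized_deviation(ds)
  expect_length(mnd, net$n_genes)
  expect_true(all(mnd >= 0))
})

test_that("rejection decisions are invariant to gene-wise positive rescaling", {
  net <- cached_network(1)
  internal <- select_internal_genes(net, knockout_panel(net), 6)
  ees <- fit_ees_from_network(net, internal)
  pair <- internal[c(3, 5)]
  raw <- simulate_replicate_dataset(net, internal, double_pair = pair,
                                    noise_sd = 0.1, seed = 21)
  set.seed(22)
  scale <- runif(net$n_genes, 0.2, 5)
  scaled <- raw
  scaled$conditions <- lapply(raw$conditions, function(mt) mt * scale)
  d1 <- zero_knocked_out_levels(rescale_by_wildtype(raw))
  d2 <- zero_knocked_out_levels(rescale_by_wildtype(scaled))
  c1 <- compare_double_knockout(d1, ees, pair)
  c2 <- compare_double_knockout(d2, ees, pair)
  expect_equal(c1$table$rejected, c2$table$rejected)
  expect_equal(c1$table$t_stat, c2$table$t_stat, tolerance = 1e-6)
})

test_that("max normalized deviation follows its arithmetic definition", {
  genes <- c("g1", "g2")
  wt <- matrix(c(0.5, 1.5, 2.5,   1, 1, 1), nrow = 2, byrow = TRUE,
               dimnames = list(genes, NULL))  # g1: mean 1.5, sd 1.0
  m1 <- matrix(c(2.5, 2.5,  1, 1), nrow = 2, byrow = TRUE,
               dimnames = list(genes, NULL))
  m2 <- matrix(c(0.5, 0.5,  1, 1), nrow = 2, byrow = TRUE,
               dimnames = list(genes, NULL))
  ds <- expression_dataset(list(wildtype = wt, m1 = m1, m2 = m2),
                           rescaled = TRUE)
  mnd <- max_normalized_deviation(ds)
  expect_equal(unname(mnd[["g1"]]), 1.0)         # max(1, 1) / 1.0
  expect_true(is.infinite(mnd[["g2"]]) || mnd[["g2"]] == 0)
  expect_equal(unname(mnd[["g2"]]), 0)           # no deviation, sd 0 -> 0
  # single mutant condition reduces to that condition's deviation
  ds1 <- expression_dataset(list(wildtype = wt, m1 = m1), rescaled = TRUE)
  expect_equal(unname(max_normalized_deviation(ds1)[["g1"]]), 1.0)
  # flagged infinite when wildtype sd is 0 but the mutant deviates
  m3 <- matrix(c(2.5, 2.5,  3, 3), nrow = 2, byrow = TRUE,
               dimnames = list(genes, NULL))
  ds3 <- expression_dataset(list(wildtype = wt, m3 = m3), rescaled = TRUE)
  expect_true(is.infinite(max_normalized_deviation(ds3)[["g2"]]))
})

test_that("Benjamini-Hochberg option only ever reduces rejections", {
  net <- cached_network(1)
  internal <- select_internal_genes(net, knockout_panel(net), 6)
  ees <- fit_ees_from_network(net, internal)
  pair <- internal[1:2]
  ds <- simulate_replicate_dataset(net, internal, double_pair = pair,
                                   noise_sd = 0.15, seed = 30)
  ds <- zero_knocked_out_levels(rescale_by_wildtype(ds))
  raw <- compare_double_knockout(ds, ees, pair)
  bh <- compare_double_knockout(ds, ees, pair, bh_adjust = TRUE)
  expect_lte(bh$n_rejected, raw$n_rejected)
})
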