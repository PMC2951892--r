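test_that("two-gene fit reproduces the hand-derived line", {
  # line through P0 = (1,1) and P1 = (0, 0.4): x2 = 0.4 + 0.6 x1
  ees <- fit_ees(c(g1 = 1, g2 = 1), cbind(c(0, 0.4)), internal = "g1")
  expect_equal(unname(ees$external_coeffs[1, ]), c(0.4, 0.6))
  expect_equal(unname(plane_point(ees, 2)), c(2, 1.6))
})

test_that("degenerate training points are refused with diagnostics", {
  wt <- c(g1 = 1, g2 = 1, g3 = 1)
  # both knockout points collapse to internal coords (0, 0) after zeroing
  kos <- cbind(c(0.2, 0, 0.7), c(0, 0.1, 0.7))
  err <- expect_error(fit_ees(wt, kos, internal = c("g1", "g2")),
                      class = "eesnet_fit_error")
  expect_match(conditionMessage(err), "condition number")
  expect_error(fit_ees(wt, kos[, 1, drop = FALSE], internal = character(0)),
               class = "eesnet_config_error")
})

test_that("fit recovers the exact affine map of a linear ground truth", {
  for (seed in 1:5) {
    net <- random_linear_network(10, seed = seed)
    internal <- net$gene_ids[c(2, 5, 8)]
    ees <- fit_ees_from_network(net, internal)
    truth <- linear_true_external_map(net, c(2, 5, 8))
    expect_lt(max(abs(ees$external_coeffs[, 1] - truth$intercept)), 1e-9)
    expect_lt(max(abs(ees$external_coeffs[, -1] - truth$slope)), 1e-9)
  }
})

test_that("the plane interpolates every training point", {
  net <- cached_network(1)
  panel <- knockout_panel(net)
  internal <- select_internal_genes(net, panel, 6)
  ees <- fit_ees_from_network(net, internal)
  p <- ees$training_points
  for (col in seq_len(ncol(p))) {
    s <- p[ees$internal_idx, col]
    expect_lt(max(abs(plane_point(ees, s) - p[, col])), 1e-8)
  }
  expect_error(plane_point(ees, rep(1, 3)), class = "eesnet_shape_error")
})

test_that("with no external genes the plane map is the identity", {
  wt <- c(a = 1, b = 1)
  kos <- cbind(c(0, 0.8), c(0.6, 0))
  ees <- fit_ees(wt, kos, internal = c("a", "b"))
  expect_length(ees$external, 0)
  expect_equal(unname(plane_point(ees, c(0.3, 1.7))), c(0.3, 1.7))
})

test_that("predict_mutant closes the single-knockout round trip", {
  net <- cached_network(2)
  panel <- knockout_panel(net)
  internal <- select_internal_genes(net, panel, 6)
  ees <- fit_ees_from_network(net, internal)
  for (k in seq_along(internal)) {
    pred <- predict_mutant(ees, stats::setNames(0, internal[k]))
    expect_lt(max(abs(pred - ees$training_points[, k + 1])), 1e-8)
  }
  # clamping every internal gene at wildtype returns the wildtype point
  wt_clamps <- stats::setNames(ees$training_points[ees$internal_idx, 1],
                               internal)
  expect_lt(max(abs(predict_mutant(ees, wt_clamps) -
                      ees$training_points[, 1])), 1e-8)
  expect_error(predict_mutant(ees, c(gX = 0)),
               class = "eesnet_domain_error")
  expect_error(predict_mutant(ees, numeric(0)),
               class = "eesnet_config_error")
})

test_that("EES equals the generator equilibrium for every clamp pattern on affine truth", {
  net <- random_linear_network(12, seed = 21)
  int_idx <- c(1, 4, 7, 10)
  internal <- net$gene_ids[int_idx]
  ees <- fit_ees_from_network(net, internal)
  set.seed(77)
  # all doubles plus random non-zero clamp patterns
  patterns <- c(
    utils::combn(int_idx, 2, simplify = FALSE),
    lapply(1:5, function(i) sample(int_idx, sample(1:4, 1)))
  )
  for (idx in patterns) {
    vals <- if (runif(1) < 0.5) rep(0, length(idx)) else
      runif(length(idx), 0, 1.5)
    pred <- predict_mutant(ees, stats::setNames(vals, net$gene_ids[idx]))
    oracle <- linear_clamped_equilibrium(net, idx, vals)
    expect_lt(max(abs(pred - oracle)), 1e-8)
  }
})

test_that("training consistency audit reports exact fits and detects tampering", {
  net <- cached_network(1)
  internal <- select_internal_genes(net, knockout_panel(net), 6)
  ees <- fit_ees_from_network(net, internal)
  chk <- training_consistency_check(ees)
  expect_lt(chk$max_external_residual, 1e-8)
  expect_lt(chk$max_internal_residual, 1e-8)
  broken <- ees
  broken$external_coeffs[3, 2] <- broken$external_coeffs[3, 2] + 0.01
  expect_gt(training_consistency_check(broken)$max_external_residual, 1e-4)
})

test_that("predictions transform covariantly under gene-wise rescaling", {
  net <- random_linear_network(8, seed = 10)
  int_idx <- c(1, 5)
  internal <- net$gene_ids[int_idx]
  ees <- fit_ees_from_network(net, internal)
  set.seed(12)
  scale <- runif(8, 0.5, 2)
  wt_s <- net$x_star * scale
  kos <- vapply(internal, function(g) {
    solve_steady_state(net, knockout(g))$x
  }, numeric(8))
  ees_s <- fit_ees(wt_s, kos * scale, internal, gene_ids = net$gene_ids)
  clamps <- stats::setNames(c(0, 0.4), internal)
  clamps_s <- clamps * scale[int_idx]
  expect_lt(
    max(abs(predict_mutant(ees_s, clamps_s) -
              predict_mutant(ees, clamps) * scale)),
    1e-8
  )
})

test_that("knocked-out gene's own level is zeroed before fitting (flag on)", {
  wt <- c(g1 = 1, g2 = 1)
  ko <- cbind(c(0.07, 0.4))  # residual probe signal on the deleted gene
  ees <- fit_ees(wt, ko, internal = "g1")
  expect_equal(unname(ees$training_points["g1", 2]), 0)
  ees_raw <- fit_ees(wt, ko, internal = "g1", zero_knockout_level = FALSE)
  expect_equal(unname(ees_raw$training_points["g1", 2]), 0.07)
})

test_that("select_internal_genes excludes non-viable knockouts and spreads clusters", {
  net <- cached_network(1)
  panel <- knockout_panel(net)
  viable <- net$gene_ids[vapply(panel, function(s) s$viable, logical(1))]
  internal <- select_internal_genes(net, panel, 6)
  expect_true(all(internal %in% viable))
  picked_clusters <- net$cluster_of[match(internal, net$gene_ids)]
  expect_equal(as.integer(table(picked_clusters)), c(2L, 2L, 2L))
  expect_error(select_internal_genes(net, panel, 100),
               class = "eesnet_config_error")
})

test_that("EES JSON round-trips with consistency re-validation", {
  net <- cached_network(1)
  internal <- select_internal_genes(net, knockout_panel(net), 6)
  ees <- fit_ees_from_network(net, internal)
  path <- withr::local_tempfile(fileext = ".json")
  write_ees(ees, path)
  ees2 <- read_ees(path)
  expect_lt(max(abs(ees2$external_coeffs - ees$external_coeffs)), 1e-12)
  expect_lt(max(abs(ees2$internal_coeffs - ees$internal_coeffs)), 1e-12)
  expect_equal(ees2$internal, ees$internal)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$format_version <- "9.1"
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  expect_error(read_ees(path), class = "eesnet_format_error")
})
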