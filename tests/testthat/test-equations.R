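test_that("stage quantiles interpolate, flip and extrapolate as stated", {
  x <- c(1, 2, 3, 4)
  expect_equal(stage_quantile(x, c(0, 1, 0.5), "ascending"), c(1, 4, 2.5))
  expect_equal(stage_quantile(x, 0, "descending"), 4)
  expect_equal(stage_quantile(x, 1, "descending"), 1)
  # linear extension through the 0/1 quantiles
  expect_equal(stage_quantile(x, -4, "ascending"), 1 - 4 * 3)
  expect_equal(stage_quantile(x, 5, "ascending"), 1 + 5 * 3)
  expect_equal(stage_quantile(x, -4, "descending"), 4 - 4 * (1 - 4))
  # agreement with type-7 empirical quantiles inside [0, 1]
  set.seed(1)
  v <- rnorm(11)
  p <- c(0, 0.17, 0.5, 0.83, 1)
  expect_equal(stage_quantile(v, p, "ascending"),
               unname(quantile(v, p, type = 7)))
  expect_error(stage_quantile(3, 0.5, "ascending"), "2 samples")
})

test_that("fraction equation counts follow the bootstrap accounting", {
  d <- make_toy_staged(n_genes = 4, n_per_stage = c(20, 30, 20, 30))
  tr <- estimate_trends(d)
  cfg <- dcm_config(n_bootstrap_groups = 200, group_size = 16,
                    equation_set = "fraction")
  eqs <- build_equations(d, tr, fraction_config(), cfg, seed = 1)
  # 200 groups x (3 interpolation + 2 extrapolation settings) per family
  expect_equal(n_equations(eqs, gene = 1, stage = 1), 1000L)
  expect_equal(length(eqs$fraction_settings), 5L)
  # study-sized accounting: 5 bootstraps x 5 settings = 25 per gene family;
  # 52 genes give 1300 equations for one stage family
  d2 <- make_toy_staged(n_genes = 52, n_per_stage = rep(14, 5), seed = 3)
  tr2 <- estimate_trends(d2)
  cfg2 <- dcm_config(n_bootstrap_groups = 5, group_size = 7,
                     equation_set = "fraction")
  eqs2 <- build_equations(d2, tr2, fraction_config(), cfg2, seed = 2)
  expect_equal(n_equations(eqs2, gene = 1, stage = 1), 25L)
  expect_equal(n_equations(eqs2, stage = 1), 1300L)
})

test_that("rho = 0 collapses the fraction cascade to next-stage quantiles", {
  d <- make_toy_staged(n_genes = 3, n_per_stage = c(10, 10))
  tr <- estimate_trends(d)
  cfg <- dcm_config(rho = 0, n_bootstrap_groups = 4, group_size = 10,
                    equation_set = "fraction")
  eqs <- build_equations(d, tr, fraction_config(), cfg, seed = 1)
  fam <- eqs$families[[1, 1]]
  # group_size = stage size -> subsample is the full stage; responses must
  # equal gene 1's stage-2 quantiles at the fraction settings
  want <- as.vector(replicate(4, stage_quantile(
    d$matrices[[2]][1, ], eqs$fraction_settings, tr$direction[1, 2])))
  expect_equal(fam$y, want)
})

test_that("ladder equations implement the per-step cascade", {
  d <- make_toy_staged(n_genes = 3, n_per_stage = c(8, 8))
  tr <- estimate_trends(d)
  m <- 8
  cfg <- dcm_config(rho = 0.6, n_bootstrap_groups = 3, group_size = m)
  eqs <- build_ladder_equations(d, tr, cfg = cfg, seed = 1)
  fam <- eqs$families[[2, 1]]
  expect_equal(length(fam$y), 3 * (m - 1))
  expect_equal(ncol(fam$Z), 2L)          # predictors exclude the target
  expect_false("g2" %in% colnames(fam$Z))
  # with group_size = stage size the ladder is the sorted stage itself
  v <- sort(d$matrices[[1]][2, ])
  if (tr$direction[2, 1] == "descending") v <- rev(v)
  rs <- 0.6^(1 / (m - 1))
  expect_equal(fam$y[1:(m - 1)], v[-1] - rs * v[-m])
  # row metadata: fractions are the ladder check-points, groups blocked
  expect_equal(fam$fraction[1:(m - 1)], (0:(m - 2)) / (m - 1))
  expect_equal(fam$group, rep(1:3, each = m - 1))
})

test_that("equation builders are deterministic under a fixed seed", {
  d <- make_toy_staged()
  tr <- estimate_trends(d)
  cfg <- dcm_config(n_bootstrap_groups = 5, group_size = 6)
  expect_identical(build_ladder_equations(d, tr, cfg = cfg, seed = 9),
                   build_ladder_equations(d, tr, cfg = cfg, seed = 9))
  cfgf <- dcm_config(n_bootstrap_groups = 5, group_size = 6,
                     equation_set = "fraction")
  expect_identical(build_equations(d, tr, fraction_config(), cfgf, seed = 9),
                   build_equations(d, tr, fraction_config(), cfgf, seed = 9))
})
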