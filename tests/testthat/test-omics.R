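test_that("vectorised OLS agrees with a normal-equations oracle", {
  set.seed(2)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    cna <- matrix(x, 1, dimnames = list("g", sprintf("s%d", 1:n)))
    resp <- matrix(y, 1, dimnames = list("g", sprintf("s%d", 1:n)))
    fit <- cis_scan(cna, resp, "expression")
    # independent route: solve the normal equations explicitly
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    resid <- y - X %*% beta
    sigma2 <- sum(resid^2) / (n - 2)
    se <- sqrt(sigma2 * solve(t(X) %*% X)[2, 2])
    t_oracle <- beta[2] / se
    expect_equal(fit$slope, beta[2], tolerance = 1e-10)
    expect_equal(fit$t_stat, t_oracle, tolerance = 1e-10)
    expect_equal(fit$p_value, 2 * pt(abs(t_oracle), n - 2, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("cis scan: exact fit, null calibration, skipped constants", {
  genes <- sprintf("g%02d", 1:3)
  cna <- matrix(sample(-2:2, 60, TRUE), 3, dimnames = list(genes, NULL))
  cna[2, ] <- 0  # constant dosage: unfittable
  colnames(cna) <- sprintf("s%02d", 1:20)
  resp <- 2 * cna + 1
  resp[2, ] <- rnorm(20)
  suppressMessages(fit <- cis_scan(cna, resp, "expression"))
  expect_identical(nrow(fit), 2L)
  expect_equal(fit$slope, c(2, 2), tolerance = 1e-12)
  expect_true(all(fit$p_value < 1e-30))
  expect_identical(attr(fit, "n_skipped"), 1L)

  set.seed(14)
  g <- 800
  cna_null <- matrix(sample(-2:2, g * 50, TRUE), g,
                     dimnames = list(sprintf("g%04d", 1:g), sprintf("s%d", 1:50)))
  resp_null <- matrix(rnorm(g * 50), g, dimnames = dimnames(cna_null))
  scan <- cis_scan(cna_null, resp_null, "expression")
  expect_gt(mean(scan$p_value < 0.05), 0.03)
  expect_lt(mean(scan$p_value < 0.05), 0.07)
  expect_equal(attr(scan, "bonferroni"), 0.05 / attr(scan, "n_scanned"))
})

test_that("cis scan has power at the planted effect size", {
  # |slope| = 0.5 * noise_sd at n = 500 concurrent samples
  cfg <- sim_config(cis_beta_expr = 0.5, cis_beta_meth = 0.5, seed = 17,
                    n_trans_targets = 0)
  b <- simulate_multiomics(cfg)
  scan <- cis_scan(b$cna, b$expr, "expression")
  cis <- b$truth$cis_effect_genes$gene
  power <- mean(scan$significant[match(cis, scan$response_gene)])
  expect_gte(power, 0.9)
  # family-wise control on the null genes
  null_sig <- scan$significant[!scan$response_gene %in% cis]
  expect_lte(sum(null_sig), 1)
})

test_that("trans scan recovers the driver's targets and handles nulls", {
  cfg <- sim_config(n_genes = 200, n_tsg = 10, n_normal = 300,
                    n_cancer = c(300), n_flipped_pairs = 20,
                    n_trans_targets = 30, trans_beta = 1.5, frac_cis = 0,
                    seed = 23)
  b <- simulate_multiomics(cfg)
  driver <- names(b$truth$trans_targets)
  scan <- trans_scan(driver, b$cna, b$expr, "expression")
  targets <- b$truth$trans_targets[[driver]]
  expect_gte(sum(scan$significant[match(targets, scan$response_gene)]), 27)

  # a null predictor produces at most the family-wise expected false calls
  null_gene <- setdiff(rownames(b$cna), c(driver, targets))[1]
  null_scan <- trans_scan(null_gene, b$cna, b$expr, "expression")
  expect_lte(sum(null_scan$significant[!null_scan$response_gene %in% targets]), 1)

  flat <- b$cna
  flat[null_gene, ] <- 1L
  expect_message(empty <- trans_scan(null_gene, flat, b$expr, "expression"),
                 "zero variance")
  expect_identical(nrow(empty), 0L)
})

test_that("probe selection picks the most anti-correlated probe", {
  set.seed(31)
  n <- 200
  expr <- matrix(rnorm(n), 1, dimnames = list("g1", sprintf("s%d", 1:n)))
  meth <- rbind(
    p_true = -0.8 * expr[1, ] + sqrt(1 - 0.64) * rnorm(n),  # corr about -0.8
    p_decoy1 = rnorm(n), p_decoy2 = rnorm(n)
  )
  colnames(meth) <- colnames(expr)
  sel <- select_probe_for_gene(meth, expr, list(g1 = rownames(meth)))
  expect_identical(sel$probe, "p_true")
  expect_lt(sel$correlation, -0.5)

  one <- select_probe_for_gene(meth, expr, list(g1 = "p_decoy1"))
  expect_identical(one$probe, "p_decoy1")

  both <- rbind(pa = rnorm(n), pb = rnorm(n))
  colnames(both) <- colnames(expr)
  fixed <- rbind(pa = both["pa", ], pb = both["pa", ])  # identical probes: tie
  colnames(fixed) <- colnames(expr)
  tie <- select_probe_for_gene(fixed, expr, list(g1 = c("pb", "pa")))
  expect_identical(tie$probe, "pa")  # probe identifier order breaks the tie
})

test_that("probe recovery holds across repeated simulations", {
  set.seed(32)
  hits <- replicate(200, {
    n <- 200
    e <- rnorm(n)
    meth <- rbind(p1 = -0.8 * e + sqrt(1 - 0.64) * rnorm(n),
                  p2 = rnorm(n), p3 = rnorm(n))
    colnames(meth) <- sprintf("s%d", 1:n)
    expr <- matrix(e, 1, dimnames = list("g", colnames(meth)))
    select_probe_for_gene(meth, expr, list(g = rownames(meth)))$probe == "p1"
  })
  expect_gte(mean(hits), 0.95)
})

test_that("TSG representation test reproduces the cohort odds ratio", {
  # 9272 significant CNA-expression genes of 18,090, 405 of the 491 TSGs
  universe <- sprintf("u%05d", 1:18090)
  tsg <- universe[1:491]
  significant <- c(universe[1:405], universe[492:(492 + 8866)])
  ct <- tsg_representation_test(significant, universe, tsg)
  expect_identical(c(ct$a, ct$b, ct$c, ct$d), c(405L, 8867L, 86L, 8732L))
  expect_equal(round(ct$odds_ratio, 2), 4.64)
  expect_lt(ct$p_value, 1e-40)

  empty <- tsg_representation_test(character(), universe, tsg)
  expect_identical(empty$odds_ratio, 0)
  expect_true(empty$degenerate)

  all_sig <- tsg_representation_test(universe, universe, tsg)
  expect_true(all_sig$degenerate)
})

test_that("random labels give an odds ratio of about 1 in expectation", {
  set.seed(41)
  universe <- sprintf("u%04d", 1:1000)
  significant <- universe[1:300]
  ors <- replicate(200, {
    tsg_representation_test(significant, universe,
                            sample(universe, 100))$odds_ratio
  })
  expect_gt(mean(ors), 0.9)
  expect_lt(mean(ors), 1.15)
})

test_that("scan p-value distributions can be compared between label groups", {
  set.seed(51)
  fits <- tibble::tibble(
    response_gene = sprintf("g%03d", 1:200),
    p_value = c(runif(50, 0, 0.2), runif(150))
  )
  cmp <- compare_pvalue_distributions(fits, fits$response_gene[1:50])
  expect_lt(cmp$p_value, 0.01)
  expect_lt(cmp$median_p_tsg, cmp$median_p_other)
})
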