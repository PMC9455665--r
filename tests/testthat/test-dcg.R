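test_that("pearson_cc matches the product-moment formula", {
  expect_equal(pearson_cc(1:3, 1:3), 1)
  expect_equal(pearson_cc(1:3, 3:1), -1)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  # hand evaluation: deviation cross-products sum to 4, each sum of squares 5
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(oracle, 0.8)
  expect_equal(pearson_cc(x, y), 0.8)
  expect_error(pearson_cc(c(1, 1, 1), 1:3), "constant")
})

test_that("pcc_pvalue matches a numerically integrated t tail", {
  expect_equal(pcc_pvalue(0, 10), 1)
  t_stat <- 0.8 * sqrt(2) / sqrt(1 - 0.64)
  dens <- function(u, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  oracle <- 2 * integrate(dens, t_stat, Inf, df = 2)$value
  expect_equal(pcc_pvalue(0.8, 4), oracle, tolerance = 1e-8)
  expect_identical(pcc_pvalue(1, 5), 0)
})

test_that("pcc_pvalue is uniform under the bivariate-normal null", {
  set.seed(8)
  r <- replicate(2000, sample_cor(50, 0))
  p <- pcc_pvalue(r, 50)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("fisher_z closed form, antisymmetry and clipping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_warning(z <- fisher_z(1), "clipped")
  expect_true(is.finite(z))
})

test_that("delta_z difference test: nulls, antisymmetry, hand evaluation", {
  null <- delta_z_test(0.4, 100, 0.4, 250)
  expect_equal(null$dz, 0)
  expect_equal(null$p_value, 1)

  a <- delta_z_test(0.7, 80, 0.2, 120)
  b <- delta_z_test(0.2, 120, 0.7, 80)
  expect_equal(a$dz, -b$dz)
  expect_equal(a$p_value, b$p_value)

  # the strongest reversed pair in the cohorts: r = 0.84 in 459 normal
  # samples vs r = -0.10 in the 1246-sample tumor set
  hand <- (atanh(0.84) - atanh(-0.10)) / sqrt(1 / 456 + 1 / 1243)
  mras <- delta_z_test(0.84, 459, -0.10, 1246)
  expect_equal(mras$dz, hand)
  expect_equal(round(mras$dz, 1), 24.1)

  expect_error(delta_z_test(0.5, 3, 0.2, 10), ">= 4")
})

test_that("delta_z type-I error is nominal under equal correlations", {
  set.seed(12)
  n_pairs <- 4000
  r1 <- replicate(n_pairs, sample_cor(100, 0.4))
  r2 <- replicate(n_pairs, sample_cor(100, 0.4))
  p <- delta_z_test(r1, 100, r2, 100)$p_value
  expect_gt(mean(p < 0.05), 0.035)
  expect_lt(mean(p < 0.05), 0.065)
})

test_that("dcg_screen recovers flipped pairs and controls false positives", {
  cfg <- sim_config(seed = 3)  # default study conditions
  sim <- simulate_expression(cfg)
  dcg <- dcg_screen(sim$datasets$normal, sim$datasets[-1],
                    candidate_genes = sim$truth$down_genes)
  truth_keys <- paste(sim$truth$flipped_pairs$gene_a,
                      sim$truth$flipped_pairs$gene_b)
  found_keys <- paste(dcg$gene_a, dcg$gene_b)[dcg$significant]
  expect_gte(sum(found_keys %in% truth_keys), 45)
  expect_identical(setdiff(found_keys, truth_keys), character(0))

  # every retained pair re-satisfies the hard threshold and the per-dataset
  # Bonferroni screen
  expect_true(all(abs(dcg$r_normal) > 0.3))
  screen_alpha <- attr(dcg, "screen_alpha")
  for (col in grep("^r_cancer", names(dcg), value = TRUE)) {
    expect_true(all(pcc_pvalue(dcg[[col]], cfg$n_cancer[1]) < screen_alpha))
  }
})

test_that("dcg_screen is invariant to gene and dataset order", {
  cfg <- tiny_config(n_normal = 120, n_cancer = c(120, 120))
  sim <- simulate_expression(cfg)
  cand <- sim$truth$down_genes
  a <- dcg_screen(sim$datasets$normal, sim$datasets[-1], cand)
  b <- dcg_screen(sim$datasets$normal[rev(rownames(sim$datasets$normal)), ],
                  sim$datasets[-1], rev(cand))
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))

  perm <- dcg_screen(sim$datasets$normal, sim$datasets[c(3, 2)], cand)
  expect_equal(sort(paste(perm$gene_a, perm$gene_b)),
               sort(paste(a$gene_a, a$gene_b)))
})

test_that("dcg_screen degenerate inputs", {
  cfg <- tiny_config(n_normal = 80, n_cancer = c(80))
  sim <- simulate_expression(cfg)
  two <- sim$truth$flipped_pairs[1, ]
  out <- dcg_screen(sim$datasets$normal, sim$datasets[-1],
                    candidate_genes = c(two$gene_a, two$gene_b))
  expect_lte(nrow(out), 1)
  expect_warning(
    dcg_screen(sim$datasets$normal, sim$datasets[-1],
               candidate_genes = two$gene_a),
    "fewer than 2"
  )
})

test_that("per-gene partner statistics flag TSG-linked hubs", {
  records <- tibble::tibble(
    gene_a = c("hub", "hub", "hub", "x1"),
    gene_b = c("t1", "t2", "t3", "x2"),
    p_combined = 1e-12, significant = TRUE
  )
  bg <- c("hub", "x1", "x2", sprintf("t%d", 1:3), sprintf("n%02d", 1:30))
  stats_tbl <- per_gene_partner_stats(records, tsg_labels = c("t1", "t2", "t3"),
                                      background = bg)
  hub <- stats_tbl[stats_tbl$gene == "hub", ]
  # partners are exactly the TSG set: maximal (infinite sample) odds ratio
  # and the minimal achievable hypergeometric p for this margin
  expect_identical(hub$odds_ratio, Inf)
  expect_equal(hub$p_value, 1 / choose(35, 3), tolerance = 1e-10)
  expect_equal(attr(stats_tbl, "mean_partner_count"), 2 * 4 / 36)
})

test_that("random TSG labels yield no partner-enrichment calls", {
  cfg <- tiny_config(n_normal = 200, n_cancer = c(200, 200))
  sim <- simulate_expression(cfg)
  dcg <- dcg_screen(sim$datasets$normal, sim$datasets[-1],
                    sim$truth$down_genes)
  set.seed(99)
  shuffled <- sample(sim$truth$down_genes, length(sim$truth$tsg_labels))
  ps <- suppressMessages(
    per_gene_partner_stats(dcg, shuffled, sim$truth$down_genes)
  )
  expect_lte(sum(ps$significant), 1)
})
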