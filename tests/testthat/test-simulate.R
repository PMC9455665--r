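test_that("generation is byte-identical under a fixed seed", {
  cfg <- tiny_config()
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1, s2)
  b1 <- simulate_multiomics(cfg)
  b2 <- simulate_multiomics(cfg)
  expect_identical(b1, b2)
})

test_that("config validation rejects impossible study conditions", {
  expect_error(sim_config(n_normal = 3), "sample sizes")
  expect_error(sim_config(rho_normal = 1), "positive definite")
  expect_error(sim_config(rho_cancer = 0.2), "rho_cancer")
  expect_error(sim_config(frac_down = 1.2), "frac_down")
  expect_error(sim_config(n_genes = 100, frac_down = 0.1, n_flipped_pairs = 20),
               "flipped pairs")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
})

test_that("flipped pairs hit their target correlations", {
  # low noise: the latent construction gives the target correlation exactly,
  # so the sample correlation at n = 500 sits within Monte-Carlo error
  cfg <- sim_config(n_genes = 80, n_tsg = 8, n_normal = 500,
                    n_cancer = c(500), n_flipped_pairs = 15,
                    rho_normal = 0.9, noise_sd = 0.1, seed = 5)
  sim <- simulate_expression(cfg)
  fp <- sim$truth$flipped_pairs
  r_norm <- purrr::map2_dbl(fp$gene_a, fp$gene_b, function(a, b) {
    cor(sim$datasets$normal[a, ], sim$datasets$normal[b, ])
  })
  expect_true(all(abs(r_norm - 0.9) < 0.05))
})

test_that("pair correlations converge to the configured targets", {
  cfg <- sim_config(n_genes = 120, n_normal = 2000, n_cancer = c(2000),
                    n_flipped_pairs = 25, seed = 9)
  sim <- simulate_expression(cfg)
  fp <- sim$truth$flipped_pairs
  r_n <- purrr::map2_dbl(fp$gene_a, fp$gene_b,
                         ~ cor(sim$datasets$normal[.x, ], sim$datasets$normal[.y, ]))
  r_c <- purrr::map2_dbl(fp$gene_a, fp$gene_b,
                         ~ cor(sim$datasets$cancer1[.x, ], sim$datasets$cancer1[.y, ]))
  expect_lt(abs(mean(r_n) - cfg$rho_normal), 0.03)
  expect_lt(abs(mean(r_c) - cfg$rho_cancer), 0.03)
  expect_true(all(abs(r_n - cfg$rho_normal) < 0.1))
  expect_true(all(abs(r_c - cfg$rho_cancer) < 0.1))
})

test_that("batch distortion is strictly increasing within each sample", {
  for (vt in c("normalized", "counts")) {
    cfg <- tiny_config(batch_strength = 1.5, value_type = vt)
    cfg0 <- tiny_config(batch_strength = 0, value_type = vt)
    m1 <- simulate_expression(cfg)$datasets$normal
    m0 <- simulate_expression(cfg0)$datasets$normal
    for (j in c(1, 10, 40)) {
      expect_identical(order(m1[, j]), order(m0[, j]))
    }
  }
})

test_that("downregulated genes shift down and null DEG calls are calibrated", {
  cfg <- sim_config(n_genes = 200, n_tsg = 10, n_normal = 60,
                    n_cancer = c(60), frac_down = 0, n_flipped_pairs = 0,
                    seed = 21)
  sim <- simulate_expression(cfg)
  deg <- wilcoxon_deg(rank_transform(sim$datasets$normal),
                      rank_transform(sim$datasets$cancer1))
  # with no planted signal the raw p-values flag ~5% of genes at 0.05
  expect_gt(mean(deg$p_value < 0.05), 0.01)
  expect_lt(mean(deg$p_value < 0.05), 0.10)

  cfg2 <- tiny_config()
  sim2 <- simulate_expression(cfg2)
  down <- sim2$truth$down_genes
  lower <- rowMeans(sim2$datasets$cancer1[down, ]) <
    rowMeans(sim2$datasets$normal[down, ])
  expect_gt(mean(lower), 0.9)
})

test_that("multi-omics bundle respects its value domains and cis effects", {
  cfg <- tiny_config()
  b <- simulate_multiomics(cfg)
  expect_true(all(b$cna %in% -2:2))
  expect_true(all(b$meth >= 0 & b$meth <= 1))

  # near-noiseless regression recovers the configured cis slope exactly
  cfg0 <- sim_config(n_genes = 40, n_tsg = 4, n_normal = 50, n_cancer = c(50),
                     n_flipped_pairs = 5, cis_beta_expr = 2,
                     n_trans_targets = 0, noise_sd = 1e-9, seed = 2)
  b0 <- simulate_multiomics(cfg0)
  g <- b0$truth$cis_effect_genes$gene[1]
  fit <- lm(b0$expr[g, ] ~ b0$cna[g, ])
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 1e-6)

  # zero cis effect everywhere: the scan rejects at about the nominal rate
  cfg_null <- sim_config(n_genes = 300, n_tsg = 10, n_normal = 100,
                         n_cancer = c(100), n_flipped_pairs = 0,
                         frac_down = 0, frac_cis = 0, n_trans_targets = 0,
                         seed = 13)
  b_null <- simulate_multiomics(cfg_null)
  scan <- cis_scan(b_null$cna, b_null$expr, "expression")
  expect_lt(mean(scan$p_value < 0.05), 0.10)
  expect_gt(mean(scan$p_value < 0.05), 0.01)
})

test_that("gene sets carry planted signal terms and round-trip through GMT", {
  cfg <- tiny_config()
  sim <- simulate_expression(cfg)
  sets <- simulate_gene_sets(cfg, sim$truth, n_terms = 12, term_size = 25)
  expect_length(sets, 12)
  signal <- attr(sets, "signal_terms")
  driver <- names(signal)
  expect_true(all(sim$truth$trans_targets[[driver]] %in% sets[[signal[driver]]]))

  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(back[names(sets)], sets[names(sets)], ignore_attr = TRUE)

  expect_error(simulate_gene_sets(cfg, sim$truth, term_size = 1e5),
               "universe")
})

test_that("matrices and truth survive TSV / JSON round trips", {
  cfg <- tiny_config()
  sim <- simulate_expression(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(sim$datasets$normal, path)
  back <- read_matrix_tsv(path, condition = "normal")
  expect_equal(unclass(back), unclass(sim$datasets$normal),
               ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(sim$datasets$normal))

  jpath <- withr::local_tempfile(fileext = ".json")
  write_sim_truth(sim$truth, jpath)
  back_truth <- read_sim_truth(jpath)
  expect_identical(back_truth$down_genes, sim$truth$down_genes)
  expect_equal(back_truth$flipped_pairs, sim$truth$flipped_pairs)
  expect_identical(back_truth$trans_targets, sim$truth$trans_targets)
})
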