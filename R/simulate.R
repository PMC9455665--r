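#' Configuration for the synthetic multi-omics generator
#'
#' The generator emulates the statistical structure of the public breast
#' cohorts the pipeline is designed for: one normal-tissue expression matrix
#' plus several cancer matrices over a shared gene universe, per-sample
#' strictly monotone batch distortion, gene pairs whose positive normal-tissue
#' coexpression flips to negative in cancer, a labelled TSG subset enriched in
#' those flipped pairs, and a multi-omics bundle in which copy-number dosage
#' drives methylation and expression in cis, and one driver TSG's dosage
#' drives a block of trans targets.
#'
#' Coexpressed pairs are built from a shared latent factor per pair: with
#' residual scale `noise_sd`, the factor loading is
#' `noise_sd * sqrt(rho / (1 - rho))`, so the latent (log-scale) correlation
#' equals the target `rho` exactly for any `noise_sd > 0`; the cancer flip
#' negates one loading. Defaults are the package's study conditions: 500
#' samples per dataset (desk-scale match to the 459-sample normal and
#' 405-3409-sample cancer cohorts), `rho_normal = 0.8` and
#' `rho_cancer = -0.3` (the magnitudes seen in the strongest reversed pairs).
#'
#' @param n_genes Number of genes in the shared universe.
#' @param n_tsg Number of genes carrying the TSG label (drawn mostly from the
#'   sign-flipped pairs, so TSGs carry a stronger differential-coexpression
#'   signal).
#' @param n_normal,n_cancer Normal sample count and vector of cancer-dataset
#'   sample counts (all at least 4: the Fisher-z difference test needs
#'   `n - 3 > 0`).
#' @param frac_down Fraction of genes given a negative location shift in
#'   cancer.
#' @param down_shift Size of that shift on the latent log scale.
#' @param n_flipped_pairs Number of disjoint gene pairs whose correlation
#'   flips sign between normal and cancer; both members are downregulated.
#' @param rho_normal Target normal-tissue correlation, in (0, 1).
#' @param rho_cancer Target cancer correlation, in (-1, 0].
#' @param batch_strength Magnitude of the per-sample strictly increasing
#'   distortion (0 disables it).
#' @param cis_beta_expr,cis_beta_meth Cis effect of copy-number dosage on
#'   expression (linear) and on the methylation logit.
#' @param frac_cis Fraction of genes with a true cis effect in the bundle.
#' @param n_trans_targets,trans_beta Number of genes whose expression and
#'   methylation logit respond to the driver TSG's copy number, and the size
#'   of that trans effect.
#' @param noise_sd Residual scale of the latent values, > 0.
#' @param value_type `"normalized"` returns latent log-scale values (log-TPM
#'   like); `"counts"` exponentiates and rounds them to count-like values.
#' @param seed Master seed; per-dataset sub-streams are derived from it
#'   deterministically.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 240,
                       n_tsg = 24,
                       n_normal = 500,
                       n_cancer = c(500, 500, 500),
                       frac_down = 0.5,
                       down_shift = 1,
                       n_flipped_pairs = 50,
                       rho_normal = 0.8,
                       rho_cancer = -0.3,
                       batch_strength = 0,
                       cis_beta_expr = 1,
                       cis_beta_meth = 1,
                       frac_cis = 0.3,
                       n_trans_targets = 30,
                       trans_beta = 1.5,
                       noise_sd = 1,
                       value_type = c("normalized", "counts"),
                       seed = 1L) {
  value_type <- match.arg(value_type)
  cfg <- list(
    n_genes = as.integer(n_genes), n_tsg = as.integer(n_tsg),
    n_normal = as.integer(n_normal), n_cancer = as.integer(n_cancer),
    frac_down = frac_down, down_shift = down_shift,
    n_flipped_pairs = as.integer(n_flipped_pairs),
    rho_normal = rho_normal, rho_cancer = rho_cancer,
    batch_strength = batch_strength,
    cis_beta_expr = cis_beta_expr, cis_beta_meth = cis_beta_meth,
    frac_cis = frac_cis,
    n_trans_targets = as.integer(n_trans_targets), trans_beta = trans_beta,
    noise_sd = noise_sd, value_type = value_type, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 2) stop("n_genes must be >= 2", call. = FALSE)
    if (n_tsg < 0 || n_tsg > n_genes) stop("need 0 <= n_tsg <= n_genes", call. = FALSE)
    if (frac_down < 0 || frac_down > 1) stop("frac_down must be in [0, 1]", call. = FALSE)
    if (any(c(n_normal, n_cancer) < 4) || length(n_cancer) < 1) {
      stop("all sample sizes must be >= 4 (the z-difference test needs n - 3 > 0)",
           call. = FALSE)
    }
    n_down <- round(frac_down * n_genes)
    if (2 * n_flipped_pairs > n_down) {
      stop("flipped pairs must fit inside the downregulated genes: ",
           "need 2 * n_flipped_pairs <= round(frac_down * n_genes)", call. = FALSE)
    }
    # the pairwise latent-factor construction implies a positive-definite
    # correlation matrix only for |rho| < 1
    if (rho_normal <= 0 || rho_normal >= 1) {
      stop("rho_normal must be in (0, 1); the implied pair correlation matrix ",
           "is not positive definite otherwise", call. = FALSE)
    }
    if (rho_cancer > 0 || rho_cancer <= -1) {
      stop("rho_cancer must be in (-1, 0]", call. = FALSE)
    }
    if (batch_strength < 0) stop("batch_strength must be >= 0", call. = FALSE)
    if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
    if (frac_cis < 0 || frac_cis > 1) stop("frac_cis must be in [0, 1]", call. = FALSE)
    if (n_trans_targets > n_genes - 1) stop("n_trans_targets too large", call. = FALSE)
  })
  invisible(cfg)
}

# Ground truth is a pure function of the config (master seed), so the
# expression datasets and the multi-omics bundle agree on it.
build_truth <- function(cfg) {
  withr::with_seed(cfg$seed, {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    n_down <- round(cfg$frac_down * cfg$n_genes)
    down <- sort(sample(genes, n_down))
    flip_genes <- if (cfg$n_flipped_pairs > 0) {
      sample(down, 2 * cfg$n_flipped_pairs)
    } else character()
    pairs <- if (cfg$n_flipped_pairs > 0) {
      m <- matrix(flip_genes, ncol = 2)
      tibble::tibble(gene_a = pmin(m[, 1], m[, 2]), gene_b = pmax(m[, 1], m[, 2]))
    } else {
      tibble::tibble(gene_a = character(), gene_b = character())
    }
    # TSG labels sit mostly inside the flipped pairs so the label set carries
    # the stronger differential-coexpression signal seen in the real cohorts
    n_in_flip <- min(length(flip_genes), ceiling(2 / 3 * cfg$n_tsg))
    tsg <- character()
    if (cfg$n_tsg > 0) {
      tsg <- c(
        sample(flip_genes, n_in_flip),
        sample(setdiff(genes, flip_genes), cfg$n_tsg - n_in_flip)
      )
      tsg <- sort(tsg)
    }
    n_cis <- round(cfg$frac_cis * cfg$n_genes)
    cis <- sort(sample(genes, n_cis))
    cis_tbl <- tibble::tibble(
      gene = cis,
      beta_expr = rep(cfg$cis_beta_expr, n_cis),
      beta_meth = rep(cfg$cis_beta_meth, n_cis)
    )
    driver <- if (cfg$n_tsg > 0 && cfg$n_trans_targets > 0) tsg[1] else character()
    trans_targets <- if (length(driver)) {
      stats::setNames(
        list(sort(sample(setdiff(genes, driver), cfg$n_trans_targets))),
        driver
      )
    } else {
      list()
    }
    structure(
      list(
        genes = genes, down_genes = down, flipped_pairs = pairs,
        tsg_labels = tsg, cis_effect_genes = cis_tbl,
        trans_targets = trans_targets,
        mu = stats::setNames(rnorm(cfg$n_genes, mean = 5, sd = 1), genes),
        gamma = stats::setNames(rnorm(cfg$n_genes, mean = 0, sd = 1), genes),
        # one stream per dataset, plus one for the bundle and one for gene sets
        sub_seeds = sample.int(.Machine$integer.max - 1L,
                               length(cfg$n_cancer) + 3L)
      ),
      class = "sim_truth"
    )
  })
}

pair_loading <- function(rho, noise_sd) {
  if (rho == 0) 0 else noise_sd * sqrt(abs(rho) / (1 - abs(rho)))
}

# Per-sample strictly increasing distortion, applied as the very last step.
# On the normalized (log) scale it is affine with a positive slope; on counts
# it is a scale-power map that preserves non-negativity. Both reduce to the
# identity when strength = 0 without touching the random stream, so latent
# data are identical across batch settings under one seed.
apply_batch <- function(values, strength, value_type) {
  n <- ncol(values)
  u1 <- runif(n, -1, 1)
  u2 <- runif(n, -1, 1)
  v <- rnorm(n)
  if (value_type == "normalized") {
    sweep(sweep(values, 2, exp(strength * u1), `*`), 2, strength * v, `+`)
  } else {
    s <- exp(strength * u1)
    g <- exp(strength * u2)
    sweep(sweep(values, 2, g, `^`), 2, s, `*`)
  }
}

simulate_one_dataset <- function(cfg, truth, n, condition, sub_seed) {
  cancer <- condition != "normal"
  rho <- if (cancer) cfg$rho_cancer else cfg$rho_normal
  loading <- pair_loading(rho, cfg$noise_sd)
  withr::with_seed(sub_seed, {
    latent <- truth$mu + matrix(rnorm(cfg$n_genes * n, sd = cfg$noise_sd),
                                nrow = cfg$n_genes,
                                dimnames = list(truth$genes, NULL))
    if (cancer && length(truth$down_genes)) {
      latent[truth$down_genes, ] <- latent[truth$down_genes, ] - cfg$down_shift
    }
    if (nrow(truth$flipped_pairs) > 0 && loading != 0) {
      f <- matrix(rnorm(nrow(truth$flipped_pairs) * n),
                  nrow = nrow(truth$flipped_pairs))
      latent[truth$flipped_pairs$gene_a, ] <-
        latent[truth$flipped_pairs$gene_a, ] + loading * f
      # the cancer flip is one negated loading on the second pair member
      sgn <- if (cancer) -1 else 1
      latent[truth$flipped_pairs$gene_b, ] <-
        latent[truth$flipped_pairs$gene_b, ] + sgn * loading * f
    }
    values <- if (cfg$value_type == "counts") round(exp(latent)) else latent
    values <- apply_batch(values, cfg$batch_strength, cfg$value_type)
    colnames(values) <- sprintf("%s_s%04d", condition, seq_len(n))
    set_condition(values, condition)
  })
}

#' Generate linked normal and cancer expression datasets with known truth
#'
#' Produces one normal and `length(n_cancer)` cancer gene-by-sample matrices
#' over a shared gene universe. Sign-flipped pairs have latent correlation
#' exactly `rho_normal` in normal tissue and `rho_cancer` in every cancer
#' dataset; downregulated genes get a negative location shift in cancer; each
#' sample is finally passed through an independent strictly increasing
#' distortion scaled by `batch_strength`.
#'
#' @param config A [sim_config()].
#' @return A list with `datasets` (named list of matrices, first element
#'   `normal`) and `truth` (a `sim_truth` with the planted downregulated
#'   genes, flipped pairs, TSG labels, cis-effect genes and trans targets).
#' @export
simulate_expression <- function(config) {
  validate_sim_config(config)
  truth <- build_truth(config)
  sizes <- c(config$n_normal, config$n_cancer)
  conditions <- c("normal", sprintf("cancer%d", seq_along(config$n_cancer)))
  datasets <- purrr::map(seq_along(sizes), function(i) {
    simulate_one_dataset(config, truth, sizes[i], conditions[i],
                         truth$sub_seeds[i])
  })
  names(datasets) <- conditions
  list(datasets = datasets, truth = truth)
}

#' Generate a linked CNA / methylation / expression bundle
#'
#' Copy-number levels are drawn from the five dosage classes -2..2. For genes
#' with a true cis effect, expression is `mu + cis_beta_expr * CNA + noise`
#' and methylation is `plogis(gamma + cis_beta_meth * CNA + noise)`; null
#' genes have zero slope. The driver TSG's copy number additionally shifts
#' the expression and methylation logit of its trans targets by
#' `trans_beta * CNA`. Sample count is the first cancer size in the config
#' (the bundle emulates the concurrent-sample tumor cohort).
#'
#' @param config A [sim_config()].
#' @return A list with `cna`, `meth`, `expr` matrices over shared genes and
#'   samples, and `truth`.
#' @export
simulate_multiomics <- function(config) {
  validate_sim_config(config)
  truth <- build_truth(config)
  n <- config$n_cancer[1]
  g <- config$n_genes
  withr::with_seed(truth$sub_seeds[length(truth$sub_seeds) - 1L], {
    samples <- sprintf("tumor_s%04d", seq_len(n))
    cna <- matrix(
      sample(-2:2, g * n, replace = TRUE,
             prob = c(0.05, 0.2, 0.5, 0.2, 0.05)),
      nrow = g, dimnames = list(truth$genes, samples)
    )
    beta_e <- beta_m <- stats::setNames(numeric(g), truth$genes)
    beta_e[truth$cis_effect_genes$gene] <- truth$cis_effect_genes$beta_expr
    beta_m[truth$cis_effect_genes$gene] <- truth$cis_effect_genes$beta_meth
    trans_e <- matrix(0, g, n, dimnames = list(truth$genes, samples))
    for (driver in names(truth$trans_targets)) {
      tgt <- truth$trans_targets[[driver]]
      trans_e[tgt, ] <- trans_e[tgt, ] +
        config$trans_beta * rep(cna[driver, ], each = length(tgt))
    }
    expr <- truth$mu + beta_e * cna + trans_e +
      matrix(rnorm(g * n, sd = config$noise_sd), g, n)
    meth_logit <- truth$gamma + beta_m * cna + trans_e +
      matrix(rnorm(g * n, sd = config$noise_sd), g, n)
    meth <- pmin(pmax(stats::plogis(meth_logit), 0), 1)
    dimnames(expr) <- dimnames(meth) <- list(truth$genes, samples)
    list(
      cna = set_condition(cna, "cancer1"),
      meth = set_condition(meth, "cancer1"),
      expr = set_condition(expr, "cancer1"),
      truth = truth
    )
  })
}

#' Generate gene sets with planted signal terms
#'
#' Builds a GMT-writable collection over the simulated gene universe. For
#' each trans-driver TSG in the truth, one "signal" term is a super-set of
#' that TSG's differential-coexpression partners and trans targets (padded
#' with random genes up to `term_size`), so downstream enrichment and
#' integration can recover it; the remaining terms are random draws.
#'
#' @param config A [sim_config()].
#' @param truth The `sim_truth` the data were generated with.
#' @param n_terms Total number of terms.
#' @param term_size Members per term (must not exceed the universe size).
#' @return Named list of character vectors with attributes `descriptions` and
#'   `signal_terms` (named character: driver TSG -> its signal term).
#' @export
simulate_gene_sets <- function(config, truth, n_terms = 30, term_size = 40) {
  if (term_size > length(truth$genes)) {
    stop("term_size exceeds the gene universe", call. = FALSE)
  }
  withr::with_seed(truth$sub_seeds[length(truth$sub_seeds)], {
    sets <- list()
    signal <- character()
    for (driver in names(truth$trans_targets)) {
      fp <- truth$flipped_pairs
      partners <- c(fp$gene_b[fp$gene_a == driver], fp$gene_a[fp$gene_b == driver])
      core <- unique(c(truth$trans_targets[[driver]], partners))
      pad <- max(0, term_size - length(core))
      term_id <- paste0("SIG_", driver)
      sets[[term_id]] <- sort(c(core, sample(setdiff(truth$genes, core), pad)))
      signal[driver] <- term_id
    }
    while (length(sets) < n_terms) {
      id <- sprintf("TERM_%04d", length(sets) + 1L)
      sets[[id]] <- sort(sample(truth$genes, term_size))
    }
    attr(sets, "descriptions") <- names(sets)
    attr(sets, "signal_terms") <- signal
    sets
  })
}
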