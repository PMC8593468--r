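make_design_fixture <- function(n = 120, m_snp = 40, m_cnv = 6, seed = 1,
                                weights = NULL, k_pcs = 0) {
  set.seed(seed)
  p <- runif(m_snp, 0.1, 0.5)
  geno <- matrix(rbinom(n * m_snp, 2, rep(p, each = n)), n, m_snp)
  panel <- make_panel(geno)
  cls <- matrix(2L, n, m_cnv)
  for (j in seq_len(m_cnv)) cls[sample(n, max(3, rbinom(1, n, 0.06))), j] <-
      sample(c(1L, 3L), 1)
  rownames(cls) <- panel$animals$animal_id
  ls <- if (m_cnv > 0) make_locus_set(cls) else NULL
  w <- weights %||% rep(1, n)
  traits <- tibble::tibble(animal_id = panel$animals$animal_id,
                           debv = rnorm(n), weight = w)
  pcs <- if (k_pcs > 0) {
    g <- compute_grm(code_snps(panel))
    grm_pca(g, k_pcs)
  } else NULL
  list(panel = panel, ls = ls, traits = traits,
       design = build_design(panel, ls, pcs, NULL, traits, k_pcs = k_pcs))
}

test_that("design bookkeeping: columns, weighting, standardization", {
  fx <- make_design_fixture(n = 100, m_snp = 30, m_cnv = 4, k_pcs = 0)
  d <- fx$design
  expect_equal(ncol(d$X), 1 + 30 + 4)
  expect_equal(d$y, fx$traits$debv)          # unit weights: y is raw dEBV
  expect_equal(sum(d$penalty == 0), 1)
  mark <- which(d$penalty == 1)
  expect_lt(max(abs(colMeans(d$X[, mark]))), 1e-12)
  expect_equal(unname(colMeans(d$X[, mark]^2)), rep(1, length(mark)),
               tolerance = 1e-12)

  fx_pc <- make_design_fixture(n = 100, m_snp = 30, m_cnv = 4, k_pcs = 3)
  expect_equal(ncol(fx_pc$design$X), 1 + 3 + 30 + 4)
  expect_equal(sum(fx_pc$design$penalty == 0), 4)

  w <- runif(100, 0.5, 2)
  fx_w <- make_design_fixture(n = 100, m_snp = 10, m_cnv = 2, weights = w)
  expect_equal(fx_w$design$y, sqrt(w) * fx_w$traits$debv)
})

test_that("mixed loci contribute separate deletion and duplication columns", {
  n <- 60
  panel <- make_panel(matrix(rbinom(n * 10, 2, 0.3), n, 10))
  cls <- matrix(2L, n, 1)
  cls[1:4, 1] <- 1L; cls[5:7, 1] <- 3L
  rownames(cls) <- panel$animals$animal_id
  ls <- make_locus_set(cls)
  traits <- tibble::tibble(animal_id = panel$animals$animal_id,
                           debv = rnorm(n), weight = 1)
  d <- build_design(panel, ls, NULL, NULL, traits, k_pcs = 0)
  cnv_cols <- d$columns[d$columns$type == "cnv", ]
  expect_setequal(cnv_cols$column, c("locus0001_del", "locus0001_dup"))
  expect_equal(cnv_cols$p_i, c(4 / 60, 3 / 60), ignore_attr = TRUE)
})

test_that("lambda at or above lambda_max zeroes every marker", {
  fx <- make_design_fixture(n = 100, m_snp = 30, m_cnv = 4, seed = 5)
  lmax <- lambda_max(fx$design)
  fit <- fit_lasso(fx$design, lambda_grid = c(lmax * 1.0001, lmax * 0.5),
                   cv_folds = 4, seed = 9)
  path <- fit$path
  expect_true(all(path[fx$design$penalty == 1, 1] == 0))
  just_below <- fit$path[fx$design$penalty == 1, 2]
  expect_gt(sum(just_below != 0), 0)
})

test_that("single standardized predictor matches the soft threshold", {
  set.seed(11)
  n <- 200
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- 0.7 * x + rnorm(n)
  b <- sum(x * y) / n
  for (lam in c(0.05, 0.3, abs(b) * 1.5)) {
    sol <- cnvherit:::lasso_cd_path(matrix(x, ncol = 1), y, 1, lam,
                                    tol = 1e-12)
    expect_equal(sol$beta[1, 1], sign(b) * max(abs(b) - lam, 0),
                 tolerance = 1e-8)
  }
})

test_that("returned solutions satisfy the KKT conditions", {
  fx <- make_design_fixture(n = 150, m_snp = 50, m_cnv = 6, seed = 13,
                            k_pcs = 2)
  fit <- fit_lasso(fx$design, cv_folds = 5, seed = 17)
  expect_true(check_kkt(fx$design, fit, tol = 1e-6))
  ## and along the tightly solved part of the path
  mid <- max(1, floor(length(fit$tight_columns) / 2))
  expect_true(check_kkt(fx$design, fit$path[, mid],
                        lambda = fit$lambda_grid[mid], tol = 1e-6))
})

test_that("coordinate descent agrees with glmnet on a shared objective", {
  skip_if_not_installed("glmnet")
  set.seed(19)
  n <- 120; p <- 25
  X <- scale(matrix(rnorm(n * p), n, p))
  X <- X / sqrt(colMeans(X^2))[col(X)]
  y <- as.numeric(X[, 1:3] %*% c(1, -0.5, 0.25) + rnorm(n))
  y <- y - mean(y)
  lam <- 0.1
  ours <- cnvherit:::lasso_cd_path(X, y, rep(1, p), lam, tol = 1e-13)$beta[, 1]
  gn <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                       intercept = FALSE, thresh = 1e-14)
  expect_equal(ours, as.numeric(gn$beta), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("relaxed refit debiases on an orthonormal-style design", {
  set.seed(23)
  n <- 400
  fx <- make_design_fixture(n = n, m_snp = 8, m_cnv = 0, seed = 23)
  d <- fx$design
  beta_true <- c(rep(0.8, 3), rep(0, 5))
  d$y <- as.numeric(d$X[, -1] %*% beta_true + rnorm(n, 0, 0.5))
  fit <- fit_lasso(d, cv_folds = 5, seed = 29)
  res <- relaxed_refit(d, fit)
  expect_gt(nrow(res), 0)
  sel_cols <- match(paste0(res$variant_id), d$columns$column)
  ## near-orthogonal columns: refit exceeds the shrunken magnitudes
  lasso_std <- fit$beta[sel_cols]
  debiased_std <- res$debiased_beta * d$columns$scale[sel_cols]
  expect_true(all(abs(debiased_std) >= abs(lasso_std) - 1e-8))

  ## empty selection gives an empty result
  fit0 <- fit_lasso(d, lambda_grid = lambda_max(d) * c(1.001, 1.0005),
                    cv_folds = 4, seed = 31)
  expect_equal(nrow(relaxed_refit(d, fit0)), 0)
})

test_that("duplicated selected columns are dropped as aliased", {
  set.seed(37)
  n <- 100
  geno <- matrix(rbinom(n * 6, 2, 0.4), n, 6)
  geno[, 6] <- geno[, 5]                     # perfect alias
  panel <- make_panel(geno)
  traits <- tibble::tibble(animal_id = panel$animals$animal_id,
                           debv = as.numeric(scale(geno[, 5])) + rnorm(n, 0, 0.3),
                           weight = 1)
  d <- build_design(panel, NULL, NULL, NULL, traits, k_pcs = 0)
  fit <- fit_lasso(d, cv_folds = 4, seed = 41)
  if (all(c("s005", "s006") %in% fit$selected)) {
    expect_warning(res <- relaxed_refit(d, fit), "aliased")
    expect_false("s006" %in% res$variant_id)
  } else {
    succeed("collinear pair not jointly selected at the CV lambda")
  }
})

test_that("variance explained follows 2p(1-p)a^2 / sigma_g^2", {
  res <- tibble::tibble(variant_id = c("c1", "c2", "c3"), type = "cnv",
                        p_i = c(0.5, 0.1, 0.2),
                        debiased_beta = c(1, 2, 0))
  out <- variance_explained(res, sigma_g2 = 1)
  expect_equal(out$var_fraction[1], 0.5)
  expect_equal(out$var_fraction[3], 0)
  out4 <- variance_explained(res, sigma_g2 = 4)
  expect_equal(out4$var_fraction[2], 2 * 0.1 * 0.9 * 4 / 4)
  expect_equal(sum(out$var_fraction), 0.5 + 2 * 0.1 * 0.9 * 4)
  expect_error(variance_explained(res, 0), "positive")
  res$p_i[1] <- 1
  expect_error(variance_explained(res, 1), "strictly")
})

test_that("mixed-model t-test reduces to OLS in the identity limit", {
  set.seed(43)
  n <- 80
  x <- rbinom(n, 2, 0.4) - 1
  y <- 0.4 * x + rnorm(n)
  g_id <- structure(list(G = diag(n), animal_ids = sprintf("a%02d", 1:n),
                         denominator = 1, p = NULL, n_markers = 1,
                         n_monomorphic = 0, coding = "snp"), class = "grm")
  mm <- single_marker_mlm(x, g_id, y, per_marker_reml = TRUE)
  ols <- summary(lm(y ~ x))$coefficients
  expect_equal(mm$t, ols["x", "t value"], tolerance = 1e-6)
  expect_equal(mm$effect, ols["x", "Estimate"], tolerance = 1e-6)
  expect_error(single_marker_mlm(rep(1, n), g_id, y), "zero-variance")
})

test_that("mixed-model p-values are calibrated under the null", {
  set.seed(47)
  n <- 150; m_test <- 400
  g <- random_snp_grm(n, 300)
  y <- draw_mixed(g$G, 0.4, 0.6)
  null_fit <- fit_reml(y, list(snp = g))
  pvals <- vapply(seq_len(m_test), function(j) {
    x <- rbinom(n, 2, runif(1, 0.1, 0.5)) - 1
    if (sd(x) == 0) return(NA_real_)
    single_marker_mlm(x, g, y, null_fit = null_fit)$p_value
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})
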