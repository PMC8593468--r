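#' Joint SNP + CNV association by relaxed LASSO
#'
#' The design couples the full marker set (SNP codes plus collapsed CNV
#' carrier indicators) with unpenalized stratification covariates (top
#' principal components of the SNP- and CNV-derived GRMs) and an intercept.
#' The response and every column are premultiplied by `sqrt(w)` so the
#' weighted least-squares objective is preserved; marker columns are then
#' standardized to mean 0, variance 1. An L1 penalty with cross-validated
#' `lambda` selects markers; the selected set is refit jointly without the
#' penalty (the relaxed LASSO) to debias the allele substitution effects.
#'
#' @name assoc
NULL

#' Build the weighted, standardized association design
#'
#' Marker columns are SNP codes (-1/0/+1) plus one 0/1 carrier-indicator
#' column per collapsed CNV locus; a mixed locus contributes a deletion
#' column and a duplication column. The intercept and the top `k_pcs`
#' principal components of each GRM enter unpenalized.
#'
#' @param panel an imputation-complete [snp_panel()] (animals must match
#'   `traits`).
#' @param locus_set a collapsed `cnv_locus_set` (may have zero loci).
#' @param pcs_snp,pcs_cnv `grm_pca` tibbles (or `NULL`).
#' @param traits tibble with `animal_id`, `debv` and `weight` columns,
#'   aligned with the panel animal order.
#' @param k_pcs components taken from each PCA (default 10).
#' @return An object of class `assoc_design`: response `y`, matrix `X`,
#'   `penalty` mask (0 = unpenalized), `columns` metadata tibble (`column`,
#'   `type`, `variant_id`, `chrom`, `pos_bp`, `start_bp`, `end_bp`, `p_i`,
#'   `center`, `scale`), and `n`.
#' @export
build_design <- function(panel, locus_set = NULL, pcs_snp = NULL,
                         pcs_cnv = NULL, traits, k_pcs = 10) {
  stopifnot(inherits(panel, "snp_panel"))
  if (!all(c("animal_id", "debv", "weight") %in% names(traits))) {
    stop("traits must carry animal_id, debv and weight", call. = FALSE)
  }
  if (!identical(traits$animal_id, panel$animals$animal_id)) {
    stop("traits and panel animal order differ", call. = FALSE)
  }
  if (anyNA(panel$geno)) stop("impute missing genotypes first", call. = FALSE)
  n <- nrow(panel$geno)
  sw <- sqrt(traits$weight)
  y <- sw * traits$debv

  take_pcs <- function(pcs, tag) {
    if (is.null(pcs) || k_pcs == 0) return(NULL)
    cols <- grep("^PC", names(pcs), value = TRUE)
    cols <- cols[seq_len(min(k_pcs, length(cols)))]
    m <- as.matrix(pcs[, cols])
    colnames(m) <- paste0(tag, "_", cols)
    m
  }
  pc_block <- cbind(take_pcs(pcs_snp, "snp"), take_pcs(pcs_cnv, "cnv"))

  snp_block <- panel$geno - 1
  colnames(snp_block) <- panel$map$snp_id
  snp_meta <- tibble::tibble(
    column = panel$map$snp_id, type = "snp", variant_id = panel$map$snp_id,
    chrom = panel$map$chrom, pos_bp = panel$map$pos_bp,
    start_bp = panel$map$pos_bp, end_bp = panel$map$pos_bp,
    p_i = unname(colMeans(snp_block + 1) / 2)
  )

  cnv_block <- NULL
  cnv_meta <- NULL
  if (!is.null(locus_set) && nrow(locus_set$loci) > 0) {
    cols <- list()
    metas <- list()
    for (j in seq_len(nrow(locus_set$loci))) {
      li <- locus_set$loci[j, ]
      cl <- locus_set$classes[, j]
      sides <- if (li$type == "mixed") c("del", "dup")
               else if (li$type == "deletion") "del" else "dup"
      for (s in sides) {
        ind <- if (s == "del") as.numeric(cl < 2) else as.numeric(cl > 2)
        nm <- if (li$type == "mixed") paste0(li$locus_id, "_", s) else li$locus_id
        cols[[nm]] <- ind
        metas[[nm]] <- tibble::tibble(
          column = nm, type = "cnv", variant_id = nm, chrom = li$chrom,
          pos_bp = li$start_bp, start_bp = li$start_bp, end_bp = li$end_bp,
          p_i = mean(ind)
        )
      }
    }
    cnv_block <- do.call(cbind, cols)
    rownames(cnv_block) <- rownames(locus_set$classes)
    cnv_meta <- dplyr::bind_rows(metas)
  }

  X_unpen <- cbind(intercept = rep(1, n), pc_block)
  X_mark <- cbind(snp_block, cnv_block)
  X <- cbind(X_unpen, X_mark) * sw
  meta_unpen <- tibble::tibble(
    column = colnames(X_unpen),
    type = c("intercept", rep("pc", ncol(X_unpen) - 1)),
    variant_id = NA_character_, chrom = NA_integer_, pos_bp = NA_real_,
    start_bp = NA_real_, end_bp = NA_real_, p_i = NA_real_
  )
  columns <- dplyr::bind_rows(meta_unpen, snp_meta, cnv_meta)
  columns$center <- 0
  columns$scale <- 1
  penalty <- as.numeric(columns$type %in% c("snp", "cnv"))

  ## standardize marker columns (mean 0, variance 1); drop zero-variance ones
  mark_idx <- which(penalty == 1)
  ctr <- colMeans(X[, mark_idx, drop = FALSE])
  X[, mark_idx] <- sweep(X[, mark_idx, drop = FALSE], 2, ctr, `-`)
  sds <- sqrt(colMeans(X[, mark_idx, drop = FALSE]^2))
  zero_var <- sds <= .Machine$double.eps^0.5
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance marker column(s) dropped",
            call. = FALSE)
    drop_cols <- mark_idx[zero_var]
    X <- X[, -drop_cols, drop = FALSE]
    columns <- columns[-drop_cols, ]
    penalty <- penalty[-drop_cols]
    mark_idx <- which(penalty == 1)
    ctr <- ctr[!zero_var]
    sds <- sds[!zero_var]
  }
  X[, mark_idx] <- sweep(X[, mark_idx, drop = FALSE], 2, sds, `/`)
  columns$center[mark_idx] <- ctr
  columns$scale[mark_idx] <- sds

  structure(list(y = y, X = X, penalty = penalty, columns = columns,
                 n = n, sqrt_w = sw),
            class = "assoc_design")
}

#' @export
print.assoc_design <- function(x, ...) {
  cat(sprintf("<assoc_design> n = %d, %d columns (%d penalized markers)\n",
              x$n, ncol(x$X), sum(x$penalty == 1)))
  invisible(x)
}

#' Smallest penalty that zeroes every marker coefficient
#'
#' `lambda_max = max_j |x_j' r0| / N` over penalized columns, where `r0` is
#' the residual of `y` on the unpenalized columns alone.
#'
#' @param design an [build_design()] object.
#' @return A single number.
#' @export
lambda_max <- function(design) {
  unpen <- which(design$penalty == 0)
  r0 <- if (length(unpen)) {
    stats::lm.fit(design$X[, unpen, drop = FALSE], design$y)$residuals
  } else design$y
  max(abs(crossprod(design$X[, design$penalty == 1, drop = FALSE], r0))) /
    design$n
}

solve_path <- function(X, y, penalty, lambda, tol = 1e-10, fdev = 1e-5,
                       max_sweeps = 10000) {
  fit <- lasso_cd_path(X, y, penalty, lambda, tol = tol, fdev = fdev,
                       max_sweeps = max_sweeps)
  fit$beta <- matrix(fit$beta, ncol = length(lambda))
  rownames(fit$beta) <- colnames(X)
  ## early-stopped paths return their last solved column for deeper lambdas
  if (fit$n_lambda < length(lambda)) {
    deeper <- (fit$n_lambda + 1):length(lambda)
    fit$beta[, deeper] <- fit$beta[, fit$n_lambda]
  }
  fit
}

#' Fit the penalized model over a lambda path with cross-validation
#'
#' Coordinate descent over a decreasing, warm-started `lambda` grid;
#' `lambda` is selected by k-fold cross-validation minimizing the mean
#' squared prediction error (`rule = "min"`) or by the one-standard-error
#' rule (`rule = "1se"`). Fold assignment is seeded, so the whole stage is
#' deterministic given (data, grid, folds, seed). Karush-Kuhn-Tucker
#' conditions at the returned solution can be checked with [check_kkt()].
#'
#' @param design an [build_design()] object.
#' @param lambda_grid optional decreasing grid; default 100 values from
#'   `lambda_max` down to `1e-3 * lambda_max` on a log scale.
#' @param cv_folds number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param rule `"min"` or `"1se"`.
#' @param tol coordinate-descent tolerance for the returned solution and
#'   the path up to the selected `lambda`.
#' @param cv_tol tolerance for the fold paths and the exploratory full
#'   path; prediction errors are insensitive to the last digits of the
#'   coefficients, so those run looser than the returned solution.
#' @param df_max stop the path once more than this many penalized columns
#'   are active (the near-saturated tail of the path is never selected by
#'   cross-validation and is expensive to iterate to convergence); default
#'   90% of the unpenalized residual degrees of freedom.
#' @param cv_max_sweeps per-lambda sweep budget for the exploratory and
#'   fold paths; the ill-conditioned saturated tail is cut off rather than
#'   iterated to convergence there.
#' @return An object of class `lasso_fit`: `lambda` (selected), `beta`
#'   (at the selected lambda, standardized scale), `selected` (marker
#'   columns with non-zero coefficients), `cv` trace tibble, `path`,
#'   `lambda_grid`, `seed`.
#' @export
fit_lasso <- function(design, lambda_grid = NULL, cv_folds = 10, seed = 1L,
                      rule = c("min", "1se"), tol = 1e-10, cv_tol = 1e-6,
                      df_max = NULL, cv_max_sweeps = 200) {
  stopifnot(inherits(design, "assoc_design"))
  rule <- match.arg(rule)
  n <- design$n
  n_pen <- sum(design$penalty == 1)
  n_unpen <- sum(design$penalty == 0)
  if (n < cv_folds) stop("fewer animals than folds", call. = FALSE)
  if (is.null(lambda_grid)) {
    lmax <- lambda_max(design)
    ## wider grid when n exceeds p; shallower when p > n (dense solutions
    ## near the bottom of the path are then ill-determined)
    ratio <- if (n > n_pen) 1e-3 else 1e-2
    lambda_grid <- exp(seq(log(lmax), log(lmax * ratio), length.out = 100))
  }
  if (is.unsorted(rev(lambda_grid))) {
    lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  }
  if (is.null(df_max)) {
    df_max <- min(n_pen, floor(0.9 * max(1, n - n_unpen)))
  }

  ## exploratory loose path on the full data: locates the saturation point
  explore <- solve_path(design$X, design$y, design$penalty, lambda_grid,
                        tol = cv_tol, max_sweeps = cv_max_sweeps)
  n_active <- colSums(explore$beta[design$penalty == 1, , drop = FALSE] != 0)
  limit <- min(if (any(n_active > df_max)) min(which(n_active > df_max))
               else length(lambda_grid),
               explore$n_lambda)
  keep <- seq_len(limit)
  lambda_grid <- lambda_grid[keep]
  explore$beta <- explore$beta[, keep, drop = FALSE]

  set.seed(seed)
  foldid <- sample(rep(seq_len(cv_folds), length.out = n))
  cv_err <- matrix(NA_real_, cv_folds, length(lambda_grid))
  for (f in seq_len(cv_folds)) {
    tr <- foldid != f
    fit_f <- solve_path(design$X[tr, , drop = FALSE], design$y[tr],
                        design$penalty, lambda_grid, tol = cv_tol,
                        max_sweeps = cv_max_sweeps)
    pred <- design$X[!tr, , drop = FALSE] %*% fit_f$beta
    cv_err[f, ] <- colMeans((design$y[!tr] - pred)^2)
  }
  cvm <- colMeans(cv_err)
  cvse <- apply(cv_err, 2, stats::sd) / sqrt(cv_folds)
  i_min <- which.min(cvm)
  i_sel <- if (rule == "min") i_min else {
    ## largest lambda with CV error within one SE of the minimum
    min(which(cvm <= cvm[i_min] + cvse[i_min]))
  }

  ## tight solve of the path down to the selected lambda; looser tail kept
  ## for inspection only
  tight <- solve_path(design$X, design$y, design$penalty,
                      lambda_grid[seq_len(i_sel)], tol = tol, fdev = 0)
  path <- explore$beta
  path[, seq_len(i_sel)] <- tight$beta
  beta <- path[, i_sel]
  sel <- which(design$penalty == 1 & beta != 0)
  structure(list(
    lambda = lambda_grid[i_sel], lambda_index = i_sel,
    beta = beta, selected = design$columns$column[sel],
    cv = tibble::tibble(lambda = lambda_grid, cvm = cvm, cvse = cvse),
    path = path, lambda_grid = lambda_grid, tight_columns = seq_len(i_sel),
    rule = rule, seed = seed
  ), class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> lambda = %.5g (%s rule), %d markers selected\n",
              x$lambda, x$rule, length(x$selected)))
  invisible(x)
}

#' Verify Karush-Kuhn-Tucker conditions of a penalized solution
#'
#' For every zero penalized coefficient, `|x_j' r / N| <= lambda + tol`;
#' for active penalized coefficients, `x_j' r / N = lambda * sign(beta_j)`
#' within `tol`; unpenalized columns have `x_j' r / N = 0` within `tol`.
#'
#' @param design the design the fit was computed on.
#' @param fit a `lasso_fit` (or a coefficient vector plus `lambda`).
#' @param lambda penalty used (taken from `fit` by default).
#' @param tol violation tolerance.
#' @return Invisibly `TRUE`; attributes carry the worst violations.
#' @export
check_kkt <- function(design, fit, lambda = fit$lambda, tol = 1e-6) {
  beta <- if (inherits(fit, "lasso_fit")) fit$beta else fit
  r <- design$y - design$X %*% beta
  g <- as.numeric(crossprod(design$X, r)) / design$n
  pen <- design$penalty
  zero_pen <- pen == 1 & beta == 0
  active_pen <- pen == 1 & beta != 0
  unpen <- pen == 0
  viol_zero <- if (any(zero_pen)) max(abs(g[zero_pen])) - lambda else -Inf
  viol_active <- if (any(active_pen)) {
    max(abs(g[active_pen] - lambda * sign(beta[active_pen])))
  } else 0
  viol_unpen <- if (any(unpen)) max(abs(g[unpen])) else 0
  ok <- (viol_zero <= tol) && (viol_active <= tol) && (viol_unpen <= tol)
  if (!ok) {
    stop(sprintf(
      "KKT violation: zero %.3g, active %.3g, unpenalized %.3g (tol %.1g)",
      viol_zero, viol_active, viol_unpen, tol), call. = FALSE)
  }
  structure(invisible(TRUE), violations = c(zero = viol_zero,
                                            active = viol_active,
                                            unpenalized = viol_unpen))
}

#' Unpenalized joint refit of the selected markers (relaxed LASSO)
#'
#' Ordinary weighted least squares of the response on the intercept, the
#' principal-component covariates and the selected markers jointly, with the
#' marker columns on their original (unstandardized) scale so the refit
#' coefficients are allele substitution effects `a_i`. Aliased columns are
#' dropped and reported. When more markers are selected than animals, a
#' ridge-stabilized refit is used and flagged.
#'
#' @param design an [build_design()] object.
#' @param fit a `lasso_fit` on that design.
#' @return A tibble of class `assoc_result`: `variant_id`, `type`, `chrom`,
#'   `pos_bp`, `start_bp`, `end_bp`, `p_i`, `lasso_beta` (original scale),
#'   `debiased_beta`, `se`, `t`, `p_value`, plus attributes `dropped`
#'   (aliased columns) and `ridge` (logical).
#' @export
relaxed_refit <- function(design, fit) {
  stopifnot(inherits(design, "assoc_design"), inherits(fit, "lasso_fit"))
  cols <- design$columns
  sel_idx <- match(fit$selected, cols$column)
  empty <- tibble::tibble(
    variant_id = character(), type = character(), chrom = integer(),
    pos_bp = double(), start_bp = double(), end_bp = double(),
    p_i = double(), lasso_beta = double(), debiased_beta = double(),
    se = double(), t = double(), p_value = double()
  )
  if (length(sel_idx) == 0) {
    return(structure(empty, class = c("assoc_result", class(empty)),
                     dropped = character(), ridge = FALSE))
  }
  unpen_idx <- which(design$penalty == 0)
  ## markers back on the original scale
  Xm <- sweep(design$X[, sel_idx, drop = FALSE], 2, cols$scale[sel_idx], `*`)
  Xm <- sweep(Xm, 2, cols$center[sel_idx], `+`)
  Xr <- cbind(design$X[, unpen_idx, drop = FALSE], Xm)
  colnames(Xr) <- c(cols$column[unpen_idx], cols$column[sel_idx])

  ridge <- ncol(Xr) >= design$n
  if (!ridge) {
    qr_x <- qr(Xr)
    aliased_all <- rep(FALSE, ncol(Xr))
    if (qr_x$rank < ncol(Xr)) {
      aliased_all[qr_x$pivot[-seq_len(qr_x$rank)]] <- TRUE
    }
    dropped <- colnames(Xr)[aliased_all]
    if (length(dropped)) {
      warning("aliased columns dropped from the refit: ",
              paste(dropped, collapse = ", "), call. = FALSE)
      Xr <- Xr[, !aliased_all, drop = FALSE]
    }
    ls <- stats::lm.fit(Xr, design$y)
    dfres <- design$n - ncol(Xr)
    s2 <- sum(ls$residuals^2) / dfres
    XtXinv <- chol2inv(chol(crossprod(Xr)))
    se_all <- sqrt(s2 * diag(XtXinv))
    names(se_all) <- colnames(Xr)
    coefs <- ls$coefficients
  } else {
    warning("selected set not smaller than n: ridge-stabilized refit",
            call. = FALSE)
    dropped <- character()
    lam_r <- 1e-6 * design$n
    XtX <- crossprod(Xr) + diag(lam_r, ncol(Xr))
    XtXinv <- chol2inv(chol(XtX))
    coefs <- drop(XtXinv %*% crossprod(Xr, design$y))
    dfres <- max(1, design$n - ncol(Xr))
    s2 <- sum((design$y - Xr %*% coefs)^2) / dfres
    se_all <- sqrt(s2 * diag(XtXinv))
    names(coefs) <- colnames(Xr)
    names(se_all) <- colnames(Xr)
  }
  keep_sel <- cols$column[sel_idx][cols$column[sel_idx] %in% colnames(Xr)]
  est <- coefs[keep_sel]
  se <- se_all[keep_sel]
  tt <- est / se
  meta <- cols[match(keep_sel, cols$column), ]
  out <- tibble::tibble(
    variant_id = meta$variant_id, type = meta$type, chrom = meta$chrom,
    pos_bp = meta$pos_bp, start_bp = meta$start_bp, end_bp = meta$end_bp,
    p_i = meta$p_i,
    lasso_beta = fit$beta[match(keep_sel, cols$column)] / meta$scale,
    debiased_beta = unname(est), se = unname(se), t = unname(tt),
    p_value = 2 * stats::pt(-abs(tt), df = max(1, design$n - ncol(Xr)))
  )
  structure(out, class = c("assoc_result", class(out)),
            dropped = dropped, ridge = ridge)
}

#' Variance explained by an associated variant
#'
#' `2 p_i (1 - p_i) a_i^2 / sigma_g^2`, with `p_i` the population frequency
#' of the variant (carrier proportion for a collapsed CNV class) and `a_i`
#' the debiased allele substitution effect. The per-trait cumulative value
#' is the sum over that trait's associated CNVs.
#'
#' @param result an `assoc_result` tibble (needs `p_i` and
#'   `debiased_beta`).
#' @param sigma_g2 additive genetic variance of the trait (> 0).
#' @return `result` with a `var_fraction` column appended.
#' @export
variance_explained <- function(result, sigma_g2) {
  if (!is.numeric(sigma_g2) || sigma_g2 <= 0) {
    stop("sigma_g2 must be positive", call. = FALSE)
  }
  if (nrow(result) > 0 &&
      any(!is.na(result$p_i) & (result$p_i <= 0 | result$p_i >= 1))) {
    stop("p_i must lie strictly in (0, 1)", call. = FALSE)
  }
  dplyr::mutate(result, var_fraction = 2 * .data$p_i * (1 - .data$p_i) *
                  .data$debiased_beta^2 / sigma_g2)
}

#' Single-variant mixed-model t-test
#'
#' Re-analyses one marker under the fitted null covariance
#' `V = G_snp sigma_g^2 + D^{-1} sigma_e^2` (variance components estimated
#' once on the null model and reused across markers). The marker effect is
#' the generalized least-squares estimate alongside an intercept; the
#' two-sided t-test (Wald form) uses `n - 2` degrees of freedom.
#'
#' @param x marker column on the original scale (one value per animal).
#' @param g_snp `grm` (or matrix) for the polygenic covariance.
#' @param y deregressed EBVs.
#' @param weights dEBV weights (diagonal of `D`).
#' @param null_fit optional pre-computed null `varcomp_fit` (P3D reuse);
#'   fitted here when missing.
#' @param per_marker_reml re-estimate the variance components with the
#'   marker as a fixed effect (exact route; slower), instead of reusing the
#'   null-model components across markers.
#' @return tibble `effect`, `se`, `t`, `p_value`, `df`.
#' @export
single_marker_mlm <- function(x, g_snp, y, weights = NULL, null_fit = NULL,
                              per_marker_reml = FALSE) {
  n <- length(y)
  if (stats::sd(x) == 0) stop("zero-variance marker", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (per_marker_reml) {
    fit <- fit_reml(y, list(snp = g_snp), weights = weights,
                    X = cbind(intercept = 1, marker = x))
    eff <- fit$beta[2]
    se <- sqrt(fit$beta_cov[2, 2])
    tt <- eff / se
    return(tibble::tibble(effect = unname(eff), se = unname(se),
                          t = unname(tt),
                          p_value = 2 * stats::pt(-abs(tt), df = n - 2),
                          df = n - 2))
  }
  if (is.null(null_fit)) {
    null_fit <- fit_reml(y, list(snp = g_snp), weights = weights)
  }
  G <- if (inherits(g_snp, "grm")) g_snp$G else g_snp
  d <- sqrt(weights)
  yt <- d * y
  Xt <- cbind(intercept = d, marker = d * x)
  Gt <- G * tcrossprod(d)
  sg <- null_fit$sigma2[1]
  se2 <- null_fit$sigma2[length(null_fit$sigma2)]
  V <- sg * Gt + diag(se2, n)
  R <- chol(V)
  Vinv <- chol2inv(R)
  XtVinvX <- crossprod(Xt, Vinv %*% Xt)
  cov_beta <- chol2inv(chol(XtVinvX))
  beta <- cov_beta %*% crossprod(Xt, Vinv %*% yt)
  eff <- beta[2]
  se <- sqrt(cov_beta[2, 2])
  tt <- eff / se
  tibble::tibble(effect = eff, se = se, t = tt,
                 p_value = 2 * stats::pt(-abs(tt), df = n - 2), df = n - 2)
}
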