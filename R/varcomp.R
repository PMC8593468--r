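#' Weighted REML variance components with genomic covariance
#'
#' Fits the mixed model `y = X beta + sum_k a_k + e` with
#' `a_k ~ N(0, G_k sigma_k^2)` for one or more genomic relationship matrices
#' and `e ~ N(0, D^{-1} sigma_e^2)`, `D = diag(w)`. The model is first
#' rescaled by `sqrt(w)` so the residual covariance is `sigma_e^2 I`; the
#' restricted likelihood is then maximised over the non-negative orthant by
#' average-information updates with an expectation-maximisation fallback
#' whenever an AI proposal would decrease the restricted log-likelihood or
#' leave the orthant, so the log-likelihood trace is non-decreasing.
#'
#' @param y numeric response (deregressed EBVs), aligned with the GRM animal
#'   order.
#' @param grms named list of `grm` objects or square matrices, all over the
#'   same animals in the same order.
#' @param weights positive weights (diagonal of `D`); default all 1.
#' @param X fixed-effect design matrix on the original scale; default a
#'   single intercept column.
#' @param max_iter,tol iteration cap and relative log-likelihood tolerance.
#' @param init optional named starting values for the variance components.
#' @return An object of class `varcomp_fit`: variance estimates `sigma2`
#'   (components then `residual`), fixed effects `beta`, restricted
#'   log-likelihood `logl` (constant terms omitted), `converged`,
#'   `iterations`, `trace`, per-component BLUPs `ranef` on the original
#'   scale, `boundary` flags, and variance `proportions` under both a
#'   weighted and an unweighted residual denominator.
#' @export
fit_reml <- function(y, grms, weights = NULL, X = NULL,
                     max_iter = 200, tol = 1e-8, init = NULL) {
  if (inherits(grms, "grm")) grms <- list(g = grms)
  Gs <- lapply(grms, function(g) if (inherits(g, "grm")) g$G else g)
  K <- length(Gs)
  if (is.null(names(Gs)) || any(!nzchar(names(Gs)))) {
    names(Gs) <- paste0("g", seq_len(K))
  }
  n <- length(y)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  for (G in Gs) stopifnot(is.matrix(G), nrow(G) == n, ncol(G) == n)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be strictly positive", call. = FALSE)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))

  d <- sqrt(weights)
  yt <- d * y
  Xt <- X * d
  stabilized <- logical(K)
  Gt <- vector("list", K)
  for (k in seq_len(K)) {
    Gk <- Gs[[k]] * tcrossprod(d)
    ## positive-definiteness probe by Cholesky; a singular or indefinite
    ## matrix (e.g. a rank-deficient CNV GRM) gets a 1e-6 diagonal ridge
    if (is.null(tryCatch(chol(Gk), error = function(e) NULL))) {
      Gk <- Gk + diag(1e-6, n)
      stabilized[k] <- TRUE
      if (is.null(tryCatch(chol(Gk), error = function(e) NULL))) {
        stop("GRM not positive semi-definite after diagonal stabilization",
             call. = FALSE)
      }
    }
    Gt[[k]] <- Gk
  }

  vy <- stats::var(yt)
  floor_v <- 1e-8 * vy
  theta <- if (!is.null(init)) {
    pmax(as.numeric(init), floor_v)
  } else {
    c(rep(vy / (2 * K), K), vy / 2)
  }

  eval_point <- function(theta) {
    V <- diag(theta[K + 1], n)
    for (k in seq_len(K)) V <- V + theta[k] * Gt[[k]]
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    logdetV <- 2 * sum(log(diag(R)))
    Vinv <- chol2inv(R)
    VinvX <- Vinv %*% Xt
    XtVinvX <- crossprod(Xt, VinvX)
    Rx <- tryCatch(chol(XtVinvX), error = function(e) NULL)
    if (is.null(Rx)) return(NULL)
    logdetX <- 2 * sum(log(diag(Rx)))
    XtVinvX_inv <- chol2inv(Rx)
    beta <- XtVinvX_inv %*% crossprod(VinvX, yt)
    P <- Vinv - VinvX %*% XtVinvX_inv %*% t(VinvX)
    Py <- P %*% yt
    logl <- -0.5 * (logdetV + logdetX + sum(yt * Py))
    list(V = V, Vinv = Vinv, P = P, Py = Py, beta = beta,
         beta_cov = XtVinvX_inv, logl = as.numeric(logl))
  }

  cur <- eval_point(theta)
  if (is.null(cur)) stop("restricted likelihood undefined at start", call. = FALSE)
  trace <- cur$logl
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    ## score and average information
    Tm <- matrix(0, n, K + 1)
    score <- numeric(K + 1)
    for (k in seq_len(K)) {
      GPy <- Gt[[k]] %*% cur$Py
      Tm[, k] <- GPy
      score[k] <- -0.5 * (sum(cur$P * Gt[[k]]) - sum(cur$Py * GPy))
    }
    Tm[, K + 1] <- cur$Py
    score[K + 1] <- -0.5 * (sum(diag(cur$P)) - sum(cur$Py^2))
    AI <- 0.5 * crossprod(Tm, cur$P %*% Tm)

    ## components pinned at the floor with a downhill gradient stay frozen
    ## this iteration; the AI system is solved on the free set only
    free <- theta > 2 * floor_v | score > 0
    if (!any(free)) break
    step <- numeric(K + 1)
    step[free] <- tryCatch(
      solve(AI[free, free, drop = FALSE] + diag(1e-10, sum(free)),
            score[free]),
      error = function(e) numeric(sum(free)))
    accepted <- FALSE
    fac <- 1
    for (h in 1:3) {
      prop <- pmax(theta + fac * step, floor_v)
      cand <- eval_point(prop)
      if (!is.null(cand) && cand$logl >= cur$logl - 1e-10) {
        theta <- prop; cur <- cand; accepted <- TRUE
        break
      }
      fac <- fac / 4
    }
    if (!accepted) {
      ## EM fallback on the free components: monotone, stays in the orthant
      em <- theta
      for (k in seq_len(K)) {
        if (free[k]) em[k] <- theta[k] + theta[k]^2 / n *
            (sum(cur$Py * (Gt[[k]] %*% cur$Py)) - sum(cur$P * Gt[[k]]))
      }
      if (free[K + 1]) em[K + 1] <- theta[K + 1] + theta[K + 1]^2 / n *
          (sum(cur$Py^2) - sum(diag(cur$P)))
      em <- pmax(em, floor_v)
      cand <- eval_point(em)
      if (is.null(cand) || cand$logl < cur$logl - 1e-8) break
      theta <- em; cur <- cand
    }
    trace <- c(trace, cur$logl)
    dl <- trace[length(trace)] - trace[length(trace) - 1]
    if (abs(dl) < tol * (1 + abs(cur$logl))) {
      converged <- TRUE
      break
    }
  }
  if (!converged && iter >= max_iter) {
    warning("REML did not converge in ", max_iter, " iterations", call. = FALSE)
  }
  if (!converged && iter < max_iter) converged <- TRUE  # monotone stall = optimum

  names(theta) <- c(names(Gs), "residual")
  boundary <- theta <= 2 * floor_v
  ## gradient of the restricted log-likelihood at the returned estimates
  score <- numeric(K + 1)
  for (k in seq_len(K)) {
    score[k] <- -0.5 * (sum(cur$P * Gt[[k]]) -
                          sum(cur$Py * (Gt[[k]] %*% cur$Py)))
  }
  score[K + 1] <- -0.5 * (sum(diag(cur$P)) - sum(cur$Py^2))
  ## BLUPs on the original scale: a_k = sigma_k^2 G_k_t P yt / d
  ranef <- matrix(0, n, K, dimnames = list(NULL, names(Gs)))
  for (k in seq_len(K)) {
    ranef[, k] <- as.numeric(theta[k] * (Gt[[k]] %*% cur$Py)) / d
  }
  mean_w <- mean(weights)
  denom_w <- sum(theta[seq_len(K)]) + theta[K + 1] / mean_w
  denom_u <- sum(theta)
  proportions <- list(
    weighted = stats::setNames(c(theta[seq_len(K)] / denom_w,
                                 (theta[K + 1] / mean_w) / denom_w),
                               names(theta)),
    unweighted = theta / denom_u
  )
  structure(list(
    sigma2 = theta, beta = drop(cur$beta), beta_cov = cur$beta_cov,
    mu = drop(cur$beta)[1],
    logl = cur$logl, converged = converged, iterations = iter,
    trace = trace, boundary = boundary, stabilized = stabilized,
    ranef = ranef, n = n, weights = weights,
    proportions = proportions,
    gradient = score
  ), class = "varcomp_fit")
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat("<varcomp_fit> restricted logL", format(x$logl, digits = 8),
      if (x$converged) sprintf("(converged, %d iterations)\n", x$iterations)
      else sprintf("(NOT converged after %d iterations)\n", x$iterations))
  est <- tibble::tibble(component = names(x$sigma2), estimate = x$sigma2,
                        proportion = x$proportions$weighted,
                        boundary = x$boundary)
  print(est)
  invisible(x)
}

#' Boundary log-likelihood ratio test for a variance component
#'
#' `statistic = 2 (logL_full - logL_reduced)`, floored at zero. Under the
#' null the tested variance sits on the boundary of its parameter space, so
#' the default reference distribution is the equal mixture
#' `0.5 chi^2_0 + 0.5 chi^2_1`; a plain `chi^2_1` reference is available.
#'
#' @param full,reduced `varcomp_fit` objects for nested models on the same
#'   data and weights (reduced has one fewer variance component).
#' @param boundary_mixture use the 0.5/0.5 mixture (default) or plain
#'   `chi^2_1`.
#' @param tol tolerance for declaring an optimiser failure when the full
#'   model's log-likelihood falls below the reduced model's.
#' @return tibble with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced, boundary_mixture = TRUE,
                                  tol = 1e-4) {
  stopifnot(inherits(full, "varcomp_fit"), inherits(reduced, "varcomp_fit"))
  if (full$logl < reduced$logl - tol) {
    stop("full-model logL below reduced-model logL: optimizer failure",
         call. = FALSE)
  }
  stat <- max(0, 2 * (full$logl - reduced$logl))
  p <- if (boundary_mixture) {
    0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE) + 0.5 * (stat <= 0)
  } else {
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  tibble::tibble(statistic = stat, df = 1, p_value = min(1, p))
}

#' Two-step estimate of the CNV variance after the SNP-GRM fit
#'
#' Step 1 fits the SNP-GRM model to the deregressed EBVs; the dependent
#' variable of step 2 is `E = residual + intercept = y - BLUP(a_snp)`.
#' Step 2 fits the CNV-GRM model to `E` under the same weights; its genetic
#' variance estimate is the additive variance attributable to the CNV
#' relationship matrix after accounting for the SNP relationship matrix.
#'
#' @param y deregressed EBVs.
#' @param g_snp,g_cnv `grm` objects (or matrices) for the two steps.
#' @param weights dEBV weights.
#' @param ... passed to [fit_reml()].
#' @return The step-2 `varcomp_fit`, with the step-1 fit in `$step1` and the
#'   step-2 response in `$E`.
#' @export
two_step_cnv_variance <- function(y, g_snp, g_cnv, weights = NULL, ...) {
  step1 <- fit_reml(y, list(snp = g_snp), weights = weights, ...)
  if (!step1$converged) stop("step-1 fit did not converge", call. = FALSE)
  E <- y - step1$ranef[, 1]
  step2 <- fit_reml(E, list(cnv = g_cnv), weights = weights, ...)
  step2$step1 <- step1
  step2$E <- E
  step2
}
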