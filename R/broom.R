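#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a variance-component fit
#'
#' @param x a `varcomp_fit`.
#' @param proportions which residual-denominator convention to report:
#'   `"weighted"` divides the residual variance by the mean weight,
#'   `"unweighted"` uses it as-is.
#' @param ... unused.
#' @return tibble `component`, `estimate`, `proportion`, `boundary`.
#' @export
tidy.varcomp_fit <- function(x, proportions = c("weighted", "unweighted"),
                             ...) {
  proportions <- match.arg(proportions)
  tibble::tibble(
    component = names(x$sigma2),
    estimate = unname(x$sigma2),
    proportion = unname(x$proportions[[proportions]]),
    boundary = unname(x$boundary)
  )
}

#' @rdname tidy.varcomp_fit
#' @export
glance.varcomp_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logl, converged = x$converged,
                 iterations = x$iterations, n = x$n,
                 mu = unname(x$mu))
}

#' Tidy a penalized fit
#'
#' @param x a `lasso_fit`.
#' @param ... unused.
#' @return tibble of non-zero coefficients at the selected `lambda`
#'   (standardized scale), with the penalty status of each column.
#' @export
tidy.lasso_fit <- function(x, ...) {
  nz <- which(x$beta != 0)
  tibble::tibble(column = names(x$beta)[nz], estimate = unname(x$beta[nz]),
                 selected = names(x$beta)[nz] %in% x$selected)
}

#' @rdname tidy.lasso_fit
#' @export
glance.lasso_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, rule = x$rule,
                 n_selected = length(x$selected),
                 cv_error = x$cv$cvm[x$lambda_index])
}
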