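#' Weight on a deregressed EBV
#'
#' The weight placed on animal `i`'s deregressed EBV in the mixed-model
#' residual (diagonal of `D`) is
#' `w = (1 - h2) / ((c + (1 - r2) / r2) * h2)`,
#' where `h2` is the trait heritability, `r2` the reliability of the
#' animal's EBV, and `c` the fraction of genetic variance not explained by
#' the markers (0.9 by default). The weight grows with reliability and
#' shrinks with heritability.
#'
#' @param h2 trait heritability in (0, 1).
#' @param r2 EBV reliability in (0, 1]; vectorized.
#' @param c unexplained-variance fraction, >= 0.
#' @return Numeric vector of weights.
#' @examples
#' garrick_weight(0.5, 0.5, 0.9)   # 0.5263158
#' @export
garrick_weight <- function(h2, r2, c = 0.9) {
  if (any(!is.finite(h2)) || any(h2 <= 0) || any(h2 >= 1)) {
    stop("h2 must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(r2)) || any(r2 <= 0) || any(r2 > 1)) {
    stop("r2 must lie in (0, 1]", call. = FALSE)
  }
  if (any(c < 0)) stop("c must be non-negative", call. = FALSE)
  (1 - h2) / ((c + (1 - r2) / r2) * h2)
}

#' Augment a trait table with dEBV weights
#'
#' @param traits tibble with a `reliability` column.
#' @param h2 trait heritability.
#' @param c unexplained-variance fraction (default 0.9).
#' @return `traits` with a `weight` column appended.
#' @export
add_weights <- function(traits, h2, c = 0.9) {
  if (!"reliability" %in% names(traits)) {
    stop("traits must have a `reliability` column", call. = FALSE)
  }
  dplyr::mutate(traits, weight = garrick_weight(h2, .data$reliability, c))
}
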