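#' Genomic relationship matrices (VanRaden method 1)
#'
#' Markers are recoded to -1/0/+1, centred by twice the deviation of the
#' +1-allele frequency from one half, and cross-multiplied:
#' `G = (M - P)(M - P)' / (2 * sum(p_i * (1 - p_i)))`, where column `i` of
#' `P` is `2 * (p_i - 0.5)`. SNPs use the standard genotype recode; CNV loci
#' enter under one of two recoding procedures (see [code_cnvs_proc1()] and
#' [code_cnvs_proc2()]); a combined matrix concatenates SNP and CNV markers
#' under a single shared denominator.
#'
#' @name grm
NULL

#' Within-breed mean imputation of missing genotypes
#'
#' Missing genotype codes are replaced by the per-SNP mean of the called
#' genotypes within the animal's breed (fractional codes are legal
#' downstream). A SNP with every value missing within some breed falls back
#' to the across-breed mean; a SNP missing everywhere is an error.
#'
#' @param panel a [snp_panel()].
#' @return The panel with a numeric, complete genotype matrix.
#' @export
impute_missing <- function(panel) {
  stopifnot(inherits(panel, "snp_panel"))
  geno <- panel$geno
  storage.mode(geno) <- "double"
  all_missing <- colSums(!is.na(geno)) == 0
  if (any(all_missing)) {
    stop(sprintf("%d SNP(s) have no called genotypes", sum(all_missing)),
         call. = FALSE)
  }
  overall <- colMeans(geno, na.rm = TRUE)
  for (b in unique(panel$animals$breed)) {
    rows <- which(panel$animals$breed == b)
    sub <- geno[rows, , drop = FALSE]
    mu <- colMeans(sub, na.rm = TRUE)
    mu[is.nan(mu)] <- overall[is.nan(mu)]
    na_idx <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(na_idx)) {
      sub[na_idx] <- mu[na_idx[, 2]]
      geno[rows, ] <- sub
    }
  }
  panel$geno <- geno
  panel
}

new_marker_matrix <- function(M, coding, marker_type = NULL) {
  stopifnot(is.matrix(M), !anyNA(M))
  structure(list(M = M, animal_ids = rownames(M), marker_ids = colnames(M),
                 coding = coding,
                 marker_type = marker_type %||% rep("marker", ncol(M))),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("<marker_matrix> %d animals x %d markers, coding '%s'\n",
              nrow(x$M), ncol(x$M), x$coding))
  invisible(x)
}

#' Recode SNP genotypes to -1/0/+1
#'
#' Genotype codes 0/1/2 map to -1/0/+1 (homozygote, heterozygote, other
#' homozygote). Mean-imputed fractional codes map to fractional coded values.
#'
#' @param panel an imputation-complete [snp_panel()].
#' @return A `marker_matrix` with coding tag `"snp"`.
#' @export
code_snps <- function(panel) {
  stopifnot(inherits(panel, "snp_panel"))
  if (anyNA(panel$geno)) stop("impute missing genotypes first", call. = FALSE)
  M <- panel$geno - 1
  new_marker_matrix(M, "snp", rep("snp", ncol(M)))
}

#' CNV recoding, procedure 1: double classes at -1, mixed loci split
#'
#' Double-deletions and double-duplications are recoded -1, single classes
#' 0, and the normal state +1. Each mixed locus is split into a deletion
#' locus (duplication carriers recoded normal) and a duplication locus
#' (deletion carriers recoded normal), so deletions and duplications are
#' never treated as the same allele.
#'
#' @param locus_set a `cnv_locus_set` from [build_loci()].
#' @return A `marker_matrix` with coding tag `"cnv_proc1"`.
#' @export
code_cnvs_proc1 <- function(locus_set) {
  stopifnot(inherits(locus_set, "cnv_locus_set"))
  classes <- locus_set$classes
  bad <- setdiff(unique(as.vector(classes)), 0:4)
  if (length(bad)) stop("unknown copy class: ", paste(bad, collapse = ", "), call. = FALSE)
  recode_side <- function(col, side) {
    ## the other side's carriers count as normal for this locus
    if (side == "deletion") col[col > 2] <- 2L else col[col < 2] <- 2L
    out <- rep(1, length(col))          # normal -> +1
    out[col %in% c(1L, 3L)] <- 0        # single class -> 0
    out[col %in% c(0L, 4L)] <- -1       # double class -> -1
    out
  }
  cols <- list()
  types <- character()
  for (j in seq_len(nrow(locus_set$loci))) {
    lid <- locus_set$loci$locus_id[j]
    type <- locus_set$loci$type[j]
    col <- classes[, j]
    if (type == "mixed") {
      cols[[paste0(lid, "_del")]] <- recode_side(col, "deletion")
      cols[[paste0(lid, "_dup")]] <- recode_side(col, "duplication")
      types <- c(types, "cnv", "cnv")
    } else {
      side <- if (type == "deletion") "deletion" else "duplication"
      cols[[lid]] <- recode_side(col, side)
      types <- c(types, "cnv")
    }
  }
  M <- do.call(cbind, cols)
  rownames(M) <- rownames(classes)
  new_marker_matrix(M, "cnv_proc1", types)
}

#' CNV recoding, procedure 2: deletions -1, normal 0, duplications +1
#'
#' One locus per CNV regardless of mixing: any deletion carrier is recoded
#' -1, the normal state 0, and any duplication carrier +1.
#'
#' @param locus_set a `cnv_locus_set` from [build_loci()].
#' @return A `marker_matrix` with coding tag `"cnv_proc2"`.
#' @export
code_cnvs_proc2 <- function(locus_set) {
  stopifnot(inherits(locus_set, "cnv_locus_set"))
  classes <- locus_set$classes
  bad <- setdiff(unique(as.vector(classes)), 0:4)
  if (length(bad)) stop("unknown copy class: ", paste(bad, collapse = ", "), call. = FALSE)
  M <- matrix(0, nrow(classes), ncol(classes),
              dimnames = dimnames(classes))
  M[classes < 2] <- -1
  M[classes > 2] <- 1
  new_marker_matrix(M, "cnv_proc2", rep("cnv", ncol(M)))
}

#' Column-wise combination of SNP and CNV marker matrices
#'
#' @param snp,cnv `marker_matrix` objects over the same animals in the same
#'   order.
#' @return A `marker_matrix` with coding tag `"combined"`; the GRM built
#'   from it uses a single denominator over all markers.
#' @export
combine_markers <- function(snp, cnv) {
  stopifnot(inherits(snp, "marker_matrix"), inherits(cnv, "marker_matrix"))
  if (!identical(snp$animal_ids, cnv$animal_ids)) {
    stop("animal sets differ between marker matrices", call. = FALSE)
  }
  if (ncol(cnv$M) == 0) {
    return(new_marker_matrix(snp$M, "combined", snp$marker_type))
  }
  new_marker_matrix(cbind(snp$M, cnv$M), "combined",
                    c(snp$marker_type, cnv$marker_type))
}

#' Compute a genomic relationship matrix (VanRaden method 1)
#'
#' The +1-allele frequency `p_i` of marker `i` is estimated from the coded
#' matrix as `mean((m_i + 1) / 2)`; monomorphic markers (where
#' `p_i (1 - p_i)` vanishes) are excluded from both the numerator and the
#' denominator. Then `G = W W' / (2 * sum(p_i (1 - p_i)))` with
#' `W = M - P`, `P[, i] = 2 (p_i - 0.5)`.
#'
#' @param m a `marker_matrix`.
#' @return An object of class `grm`: list with the symmetric matrix `G`,
#'   `animal_ids`, `denominator`, `p` (allele frequencies of retained
#'   markers) and the source `coding` tag.
#' @export
compute_grm <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  p <- colMeans((m$M + 1) / 2)
  keep <- p * (1 - p) > 0
  if (sum(keep) < 1) stop("no polymorphic markers", call. = FALSE)
  M <- m$M[, keep, drop = FALSE]
  p <- p[keep]
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("zero GRM denominator", call. = FALSE)
  W <- sweep(M, 2, 2 * (p - 0.5), `-`)
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  mean_diag <- mean(diag(G))
  if (m$coding == "snp" && abs(mean_diag - 1) > 0.2) {
    message(sprintf("mean GRM diagonal %.3f departs from 1", mean_diag))
  }
  structure(list(G = G, animal_ids = m$animal_ids, denominator = denom,
                 p = p, n_markers = sum(keep), n_monomorphic = sum(!keep),
                 coding = m$coding),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d animals, %d markers (coding '%s'), denominator %.3f\n",
              length(x$animal_ids), x$n_markers, x$coding, x$denominator))
  cat(sprintf("  mean diagonal %.4f\n", mean(diag(x$G))))
  invisible(x)
}

#' Principal components of a genomic relationship matrix
#'
#' Eigen-decomposition of `G`; the percent variance of component `j` is
#' `lambda_j / sum(lambda)` with negative eigenvalues floored at zero for
#' the shares (raw eigenvalues are returned as well). Component scores are
#' `u_j * sqrt(max(lambda_j, 0))` and components are ordered by descending
#' eigenvalue.
#'
#' @param g a `grm`.
#' @param k number of components to return.
#' @param animals optional tibble `animal_id`, `breed` to join breed labels.
#' @return A tibble of class `grm_pca` (`animal_id`, `PC1..PCk`) with
#'   attributes `percent_var` (all components) and `eigenvalues`.
#' @export
grm_pca <- function(g, k = 10, animals = NULL) {
  stopifnot(inherits(g, "grm"))
  if (!all(is.finite(g$G))) stop("non-finite GRM entries", call. = FALSE)
  n <- nrow(g$G)
  if (k > n) stop("k exceeds the number of animals", call. = FALSE)
  eig <- eigen(g$G, symmetric = TRUE)
  lam <- eig$values
  lam_floor <- pmax(lam, 0)
  pct <- 100 * lam_floor / sum(lam_floor)
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lam_floor[seq_len(k)]), k)
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- dplyr::bind_cols(tibble::tibble(animal_id = g$animal_ids),
                          tibble::as_tibble(scores))
  if (!is.null(animals)) {
    out <- dplyr::left_join(out, animals[, c("animal_id", "breed")],
                            by = "animal_id")
  }
  attr(out, "percent_var") <- pct
  attr(out, "eigenvalues") <- lam
  class(out) <- c("grm_pca", class(out))
  out
}

#' Write / read a GRM as GCTA-style plain text
#'
#' `<stem>.grm.txt` holds the lower triangle (row index, column index,
#' number of markers, value); `<stem>.grm.id` the animal ids.
#'
#' @param g a `grm`.
#' @param stem file path stem.
#' @return `write_grm` returns `stem` invisibly; `read_grm` a `grm`.
#' @export
write_grm <- function(g, stem) {
  n <- length(g$animal_ids)
  idx <- which(lower.tri(g$G, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tab <- data.frame(i = idx[, 1], j = idx[, 2], n = g$n_markers,
                    value = g$G[idx])
  utils::write.table(tab, paste0(stem, ".grm.txt"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(g$animal_ids, paste0(stem, ".grm.id"))
  invisible(stem)
}

#' @rdname write_grm
#' @export
read_grm <- function(stem) {
  ids <- readLines(paste0(stem, ".grm.id"))
  tab <- utils::read.table(paste0(stem, ".grm.txt"), sep = "\t")
  n <- length(ids)
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  G[cbind(tab$V1, tab$V2)] <- tab$V4
  G[cbind(tab$V2, tab$V1)] <- tab$V4
  structure(list(G = G, animal_ids = ids, denominator = NA_real_,
                 p = NULL, n_markers = tab$V3[1], n_monomorphic = NA_integer_,
                 coding = "file"),
            class = "grm")
}
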