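# Fixture builders and independent oracles shared across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny panel built by hand: geno is animals x snps, chrom/pos optional.
make_panel <- function(geno, chrom = NULL, pos = NULL, breed = NULL) {
  n <- nrow(geno); p <- ncol(geno)
  map <- tibble::tibble(
    snp_id = sprintf("s%03d", seq_len(p)),
    chrom = chrom %||% rep(1L, p),
    pos_bp = pos %||% seq(1000, by = 1000, length.out = p),
    index = seq_len(p)
  )
  animals <- tibble::tibble(
    animal_id = sprintf("a%03d", seq_len(n)),
    breed = breed %||% rep("B1", n)
  )
  snp_panel(geno, map, animals)
}

# Fabricate a cnv_locus_set directly from a copy-number matrix.
make_locus_set <- function(classes, chrom = NULL) {
  n <- nrow(classes); L <- ncol(classes)
  if (is.null(rownames(classes))) rownames(classes) <- sprintf("a%03d", 1:n)
  if (is.null(colnames(classes))) colnames(classes) <- sprintf("locus%04d", 1:L)
  type <- vapply(seq_len(L), function(j) {
    cl <- classes[, j]
    has_del <- any(cl < 2); has_dup <- any(cl > 2)
    if (has_del && has_dup) "mixed" else if (has_del) "deletion"
    else if (has_dup) "duplication" else "deletion"
  }, character(1))
  animals <- tibble::tibble(animal_id = rownames(classes), breed = "B1")
  loci <- tibble::tibble(
    locus_id = colnames(classes), chrom = chrom %||% rep(1L, L),
    start_index = 10L * seq_len(L), end_index = 10L * seq_len(L) + 4L,
    start_bp = 1e5 * seq_len(L), end_bp = 1e5 * seq_len(L) + 4e3,
    n_snps = 5L, type = type,
    n_carriers = colSums(classes != 2L),
    max_breed_carriers = colSums(classes != 2L),
    collapsed_del = FALSE, collapsed_dup = FALSE
  )
  structure(list(loci = loci, classes = classes,
                 carriers_by_breed = tibble::tibble(),
                 conflicts = tibble::tibble(), animals = animals),
            class = "cnv_locus_set")
}

# Naive double-loop VanRaden GRM: the brute-force oracle for compute_grm.
naive_grm <- function(M) {
  p <- colMeans((M + 1) / 2)
  keep <- p * (1 - p) > 0
  M <- M[, keep, drop = FALSE]; p <- p[keep]
  denom <- 2 * sum(p * (1 - p))
  n <- nrow(M)
  G <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    s <- 0
    for (k in seq_along(p)) {
      s <- s + (M[i, k] - 2 * (p[k] - 0.5)) * (M[j, k] - 2 * (p[k] - 0.5))
    }
    G[i, j] <- s / denom
  }
  G
}

# Closed-form profile restricted likelihood for a single genomic random
# effect, on the eigen-rotated model, maximized by golden-section/parabolic
# search over the variance ratio. Independent of fit_reml.
reml_eigen_oracle <- function(y, G, weights = NULL, X = NULL) {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(X)) X <- matrix(1, n, 1)
  d <- sqrt(weights)
  yt <- d * y; Xt <- X * d
  Gt <- G * tcrossprod(d)
  ev <- eigen(Gt, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    Gt <- Gt + diag(1e-6, n)
    ev <- eigen(Gt, symmetric = TRUE)
  }
  lam <- ev$values
  z <- crossprod(ev$vectors, yt)
  W <- crossprod(ev$vectors, Xt)
  p <- ncol(X)
  prof <- function(log_phi) {
    phi <- exp(log_phi)
    Dk <- phi * lam + 1
    WtW <- crossprod(W / Dk, W)
    Winv <- solve(WtW)
    beta <- Winv %*% crossprod(W / Dk, z)
    r <- z - W %*% beta
    q <- sum(r^2 / Dk)
    -0.5 * ((n - p) * log(q / (n - p)) + sum(log(Dk)) +
              as.numeric(determinant(WtW, logarithm = TRUE)$modulus) + (n - p))
  }
  opt <- stats::optimize(prof, c(log(1e-8), log(1e8)), maximum = TRUE,
                         tol = 1e-12)
  phi <- exp(opt$maximum)
  Dk <- phi * lam + 1
  WtW <- crossprod(W / Dk, W)
  beta <- solve(WtW) %*% crossprod(W / Dk, z)
  q <- sum((z - W %*% beta)^2 / Dk)
  sigma_e <- q / (n - p)
  list(sigma_g = phi * sigma_e, sigma_e = sigma_e, logl = opt$objective,
       phi = phi)
}

# Draw y = mu + a + e with a ~ N(0, G sg2), e ~ N(0, diag(1/w) se2).
draw_mixed <- function(G, sg2, se2, weights = NULL, mu = 0) {
  n <- nrow(G)
  if (is.null(weights)) weights <- rep(1, n)
  ev <- eigen(G, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  a <- ev$vectors %*% (sqrt(lam * sg2) * stats::rnorm(n))
  mu + as.numeric(a) + stats::rnorm(n, 0, sqrt(se2 / weights))
}

# GRM from fresh binomial genotypes (used when only a relationship matrix,
# not a full panel, is needed).
random_snp_grm <- function(n, m, maf = c(0.05, 0.5)) {
  p <- stats::runif(m, maf[1], maf[2])
  geno <- matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n, m)
  M <- geno - 1
  rownames(M) <- sprintf("a%04d", 1:n)
  colnames(M) <- sprintf("s%04d", 1:m)
  compute_grm(cnvherit:::new_marker_matrix(M, "snp"))
}

# Rare-carrier CNV coded matrix -> GRM (carriers at low frequency).
random_cnv_grm <- function(n, L, carrier = c(0.02, 0.1)) {
  f <- stats::runif(L, carrier[1], carrier[2])
  cls <- matrix(2L, n, L)
  for (j in 1:L) {
    car <- which(stats::runif(n) < f[j])
    if (length(car)) cls[car, j] <- sample(c(1L, 3L), length(car), TRUE)
  }
  # guarantee polymorphism
  for (j in 1:L) if (all(cls[, j] == 2L)) cls[sample(n, 2), j] <- 1L
  rownames(cls) <- sprintf("a%04d", 1:n)
  colnames(cls) <- sprintf("locus%04d", 1:L)
  compute_grm(code_cnvs_proc2(make_locus_set(cls)))
}

# Rare-carrier CNV locus set (single-direction loci) and its procedure-1
# GRM; carrier frequencies default to the 3-10 carriers-per-locus regime of
# low-frequency CNVs.
rare_cnv_classes <- function(n, L, carrier = c(0.003, 0.01)) {
  f <- stats::runif(L, carrier[1], carrier[2])
  cls <- matrix(2L, n, L)
  for (j in 1:L) {
    car <- which(stats::runif(n) < f[j])
    if (length(car)) cls[car, j] <- sample(c(1L, 3L), 1)
  }
  for (j in 1:L) if (all(cls[, j] == 2L)) cls[sample(n, 2), j] <- 1L
  rownames(cls) <- sprintf("a%04d", 1:n)
  colnames(cls) <- sprintf("locus%04d", 1:L)
  cls
}

rare_cnv_grm <- function(n, L, carrier = c(0.003, 0.01)) {
  compute_grm(code_cnvs_proc1(make_locus_set(rare_cnv_classes(n, L, carrier))))
}

# Naive pairwise single-linkage QTL merge: the oracle for build_qtls.
naive_qtl_merge <- function(v, flank) {
  v <- v[order(v$chrom, v$start_bp), ]
  n <- nrow(v)
  cluster <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || cluster[i] == cluster[j]) next
      if (v$type[i] != v$type[j] || v$chrom[i] != v$chrom[j]) next
      gap <- max(0, max(v$start_bp[i], v$start_bp[j]) -
                   min(v$end_bp[i], v$end_bp[j]))
      if (gap <= flank) {
        cluster[cluster == cluster[j]] <- cluster[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- lapply(split(seq_len(n), paste(v$type, cluster)), function(ix) {
    data.frame(type = v$type[ix[1]], chrom = v$chrom[ix[1]],
               start_bp = max(1, min(v$start_bp[ix]) - flank),
               end_bp = max(v$end_bp[ix]) + flank,
               n_members = length(ix))
  })
  out <- do.call(rbind, out)
  out[order(out$type, out$chrom, out$start_bp), , drop = FALSE]
}

random_variants <- function(m, n_chrom = 3, span_max = 2e6) {
  chrom <- sample.int(n_chrom, m, replace = TRUE)
  start <- sample.int(span_max, m, replace = TRUE)
  type <- sample(c("snp", "cnv"), m, replace = TRUE)
  end <- ifelse(type == "cnv", start + sample.int(3e4, m, replace = TRUE), start)
  tibble::tibble(variant_id = sprintf("v%04d", seq_len(m)), type = type,
                 chrom = chrom, pos_bp = start, start_bp = start, end_bp = end)
}
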