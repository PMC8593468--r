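test_that("mean imputation fills missing codes within breed", {
  geno <- matrix(c(0L, 2L, NA, 1L, 1L, 1L), 3, 2)
  panel <- make_panel(geno)
  imp <- impute_missing(panel)
  expect_equal(imp$geno[3, 1], 1.0)  # mean of {0, 2}
  expect_equal(imp$geno[, 2], c(1, 1, 1), ignore_attr = TRUE)
  expect_identical(impute_missing(imp)$geno, imp$geno)

  two_breed <- make_panel(matrix(c(0L, 0L, NA, 2L, 2L, NA, 1L, 1L, 1L,
                                   1L, 1L, 1L), 6, 2),
                          breed = rep(c("X", "Y"), each = 3))
  imp2 <- impute_missing(two_breed)
  expect_equal(imp2$geno[3, 1], 0)   # breed X mean
  expect_equal(imp2$geno[6, 1], 2)   # breed Y mean

  all_na <- make_panel(matrix(NA_integer_, 3, 1))
  expect_error(impute_missing(all_na), "no called genotypes")
})

test_that("SNP and CNV codings follow the -1/0/+1 conventions", {
  panel <- make_panel(matrix(c(0L, 1L, 2L), 3, 1))
  expect_equal(as.vector(code_snps(panel)$M), c(-1, 0, 1))

  # mixed locus: A single-del, B single-dup, C normal
  cls <- matrix(c(1L, 3L, 2L), 3, 1)
  ls <- make_locus_set(cls)
  m1 <- code_cnvs_proc1(ls)
  expect_equal(colnames(m1$M), c("locus0001_del", "locus0001_dup"))
  expect_equal(unname(m1$M[, "locus0001_del"]), c(0, 1, 1))
  expect_equal(unname(m1$M[, "locus0001_dup"]), c(1, 0, 1))
  m2 <- code_cnvs_proc2(ls)
  expect_equal(unname(m2$M[, 1]), c(-1, 1, 0))

  # pure deletion locus with a double-deletion carrier
  del <- make_locus_set(matrix(c(0L, 1L, 2L), 3, 1))
  expect_equal(unname(code_cnvs_proc1(del)$M[, 1]), c(-1, 0, 1))

  bad <- make_locus_set(matrix(c(1L, 2L, 2L), 3, 1))
  bad$classes[1, 1] <- 7L
  expect_error(code_cnvs_proc1(bad), "unknown copy class")
})

test_that("single-marker GRM reproduces the closed-form values", {
  M <- matrix(c(1, 0, -1), 3, 1,
              dimnames = list(c("a", "b", "c"), "m1"))
  g <- compute_grm(cnvherit:::new_marker_matrix(M, "snp"))
  expect_equal(g$denominator, 0.5)
  expect_equal(unname(g$G),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3))
})

test_that("identical coded rows give identical relationships", {
  set.seed(42)
  M <- matrix(sample(c(-1, 0, 1), 5 * 20, TRUE), 5, 20)
  M[2, ] <- M[1, ]
  rownames(M) <- letters[1:5]; colnames(M) <- sprintf("m%02d", 1:20)
  g <- compute_grm(cnvherit:::new_marker_matrix(M, "snp"))
  expect_equal(g$G[1, ], g$G[2, ], ignore_attr = TRUE)
  expect_equal(g$G[1, 1], g$G[1, 2])
  expect_equal(g$G[1, 1], g$G[2, 2])
})

test_that("GRM agrees with the naive double-loop oracle", {
  set.seed(7)
  for (rep in 1:3) {
    M <- matrix(sample(c(-1, 0, 1), 20 * 50, TRUE), 20, 50)
    rownames(M) <- sprintf("a%02d", 1:20); colnames(M) <- sprintf("m%02d", 1:50)
    g <- compute_grm(cnvherit:::new_marker_matrix(M, "snp"))
    expect_lt(max(abs(g$G - naive_grm(M))), 1e-10)
  }
})

test_that("GRM is marker-permutation invariant and animal equivariant", {
  set.seed(9)
  M <- matrix(sample(c(-1, 0, 1), 12 * 30, TRUE), 12, 30)
  rownames(M) <- sprintf("a%02d", 1:12); colnames(M) <- sprintf("m%02d", 1:30)
  g <- compute_grm(cnvherit:::new_marker_matrix(M, "snp"))
  pm <- sample(30)
  g_pm <- compute_grm(cnvherit:::new_marker_matrix(M[, pm], "snp"))
  expect_equal(g$G, g_pm$G, tolerance = 1e-12)
  pa <- sample(12)
  g_pa <- compute_grm(cnvherit:::new_marker_matrix(M[pa, ], "snp"))
  expect_equal(unname(g_pa$G), unname(g$G[pa, pa]), tolerance = 1e-12)
})

test_that("combined marker sets share one denominator", {
  set.seed(11)
  Ms <- matrix(sample(c(-1, 0, 1), 15 * 40, TRUE), 15, 40,
               dimnames = list(sprintf("a%02d", 1:15), sprintf("s%02d", 1:40)))
  Mc <- matrix(sample(c(-1, 0, 1), 15 * 6, TRUE), 15, 6,
               dimnames = list(sprintf("a%02d", 1:15), sprintf("c%02d", 1:6)))
  snp <- cnvherit:::new_marker_matrix(Ms, "snp")
  cnv <- cnvherit:::new_marker_matrix(Mc, "cnv_proc1")
  comb <- combine_markers(snp, cnv)
  expect_equal(ncol(comb$M), 46)
  g <- compute_grm(comb)
  expect_lt(max(abs(g$G - naive_grm(cbind(Ms, Mc)))), 1e-10)

  ## algebraic identity: combined GRM is the denominator-weighted average
  gs <- compute_grm(snp); gc <- compute_grm(cnv)
  avg <- (gs$G * gs$denominator + gc$G * gc$denominator) /
    (gs$denominator + gc$denominator)
  expect_equal(g$G, avg, tolerance = 1e-10)

  empty <- cnvherit:::new_marker_matrix(Ms[, 0, drop = FALSE], "cnv_proc1")
  expect_equal(compute_grm(combine_markers(snp, empty))$G, gs$G)
  wrong <- cnvherit:::new_marker_matrix(Mc[c(2:15, 1), ], "cnv_proc1")
  expect_error(combine_markers(snp, wrong), "animal sets differ")
})

test_that("GRM principal components normalize and separate clusters", {
  set.seed(13)
  g_id <- structure(list(G = diag(6), animal_ids = letters[1:6],
                         denominator = 1, p = NULL, n_markers = 1,
                         n_monomorphic = 0, coding = "snp"), class = "grm")
  pca_id <- grm_pca(g_id, k = 6)
  pct <- attr(pca_id, "percent_var")
  expect_equal(sum(pct), 100)
  expect_true(all(abs(pct - 100 / 6) < 1e-8))

  ## two breeds with disjoint allele-frequency profiles
  n <- 40; m <- 300
  p1 <- runif(m, 0.05, 0.25); p2 <- runif(m, 0.75, 0.95)
  geno <- rbind(
    matrix(rbinom(n / 2 * m, 2, rep(p1, each = n / 2)), n / 2, m),
    matrix(rbinom(n / 2 * m, 2, rep(p2, each = n / 2)), n / 2, m)
  )
  rownames(geno) <- sprintf("a%02d", 1:n); colnames(geno) <- sprintf("s%03d", 1:m)
  g <- compute_grm(cnvherit:::new_marker_matrix(geno - 1, "snp"))
  pca <- grm_pca(g, k = 2)
  side <- sign(pca$PC1)
  expect_true(all(side[1:(n / 2)] == side[1]) &&
                all(side[(n / 2 + 1):n] == -side[1]))
  expect_error(grm_pca(g, k = n + 1), "k exceeds")
})

test_that("GRM text round trip preserves the matrix", {
  set.seed(15)
  g <- random_snp_grm(8, 30)
  stem <- tempfile()
  write_grm(g, stem)
  g2 <- read_grm(stem)
  expect_equal(g2$G, g$G, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(g2$animal_ids, g$animal_ids)
})
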