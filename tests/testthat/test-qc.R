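test_that("animal call-rate filter uses a strict less-than rule", {
  set.seed(1)
  geno <- matrix(1L, 4, 1000)
  geno[1, 1:51] <- NA   # 94.9% called -> removed
  geno[2, 1:50] <- NA   # exactly 95.0% -> retained
  panel <- make_panel(geno)
  out <- filter_call_rate(panel, animal_threshold = 0.95, snp_threshold = 0.5)
  expect_equal(out$panel$animals$animal_id, c("a002", "a003", "a004"))
  expect_equal(out$report$n_removed[out$report$stage == "animal_call_rate"], 1L)
})

test_that("SNP call rate is computed on retained animals", {
  geno <- matrix(1L, 10, 10)
  geno[1, ] <- NA                    # animal removed entirely
  geno[1:10, 1] <- NA                # SNP 1: 0/9 called after removal
  geno[2:5, 2] <- NA                 # SNP 2: 5/9 called -> removed at 0.95
  panel <- make_panel(geno)
  out <- filter_call_rate(panel, 0.5, 0.95)
  expect_false(any(c("s001", "s002") %in% out$panel$map$snp_id))
  expect_equal(ncol(out$panel$geno), 8)
})

test_that("a complete panel passes call-rate filtering unchanged", {
  geno <- matrix(rep(0:2, length.out = 60), 6, 10)
  panel <- make_panel(geno)
  out <- filter_call_rate(panel)
  expect_identical(out$panel$geno, panel$geno)
  expect_true(all(out$report$n_removed == 0))
  expect_error(filter_call_rate(subset_panel(panel, animal_keep = integer(0))),
               "empty panel")
})

test_that("positional filter keeps autosomal placed SNPs only", {
  geno <- matrix(1L, 3, 5)
  panel <- make_panel(geno, chrom = c(1L, NA, 30L, 2L, 29L),
                      pos = c(100, 200, 300, NA, 500))
  out <- filter_positions(panel, n_autosomes = 29)
  expect_equal(out$panel$map$snp_id, c("s001", "s005"))
  expect_equal(out$report$n_removed, 3L)
  auto <- make_panel(matrix(1L, 3, 4), chrom = c(1L, 1L, 2L, 2L))
  expect_identical(filter_positions(auto)$panel$geno, auto$geno)
})

test_that("Mendelian filter counts opposing homozygotes only, strict rule", {
  # 100 pairs; snp1: 3 conflicts (>2%), snp2: 2 conflicts (=2%), snp3:
  # parent heterozygous everywhere, snp4: conflicts diluted by missingness
  n_pairs <- 100
  geno <- matrix(1L, 2 * n_pairs, 4)
  parents <- 1:n_pairs; progeny <- n_pairs + (1:n_pairs)
  geno[parents, 1] <- 0L; geno[progeny, 1] <- 0L
  geno[parents[1:3], 1] <- 0L; geno[progeny[1:3], 1] <- 2L
  geno[parents, 2] <- 0L; geno[progeny, 2] <- 0L
  geno[parents[1:2], 2] <- 2L; geno[progeny[1:2], 2] <- 0L
  geno[parents, 3] <- 1L; geno[progeny, 3] <- sample(c(0L, 2L), n_pairs, TRUE)
  geno[parents, 4] <- 0L; geno[progeny, 4] <- 0L
  geno[parents[1:2], 4] <- 0L; geno[progeny[1:2], 4] <- 2L
  geno[parents[50:99], 4] <- NA  # informative pairs: 50; 2/50 = 4% -> removed
  panel <- make_panel(geno)
  pairs <- tibble::tibble(parent = panel$animals$animal_id[parents],
                          progeny = panel$animals$animal_id[progeny])
  conf <- mendelian_conflicts(panel, pairs)
  expect_equal(conf$n_conflicts, c(3L, 2L, 0L, 2L))
  expect_equal(conf$n_informative, c(100L, 100L, 100L, 50L))
  out <- filter_mendelian(panel, pairs, max_conflict_fraction = 0.02)
  expect_setequal(out$panel$map$snp_id, c("s002", "s003"))
})

test_that("Mendelian filter with no pairs warns and passes through", {
  panel <- make_panel(matrix(1L, 4, 3))
  expect_warning(out <- filter_mendelian(panel, tibble::tibble()), "empty pair")
  expect_identical(out$panel$geno, panel$geno)
})

test_that("ERC exclusion is strict and reported", {
  traits <- tibble::tibble(animal_id = c("a", "b", "c"),
                           erc = c(0.99, 1.0, 5))
  out <- filter_erc(traits, min_erc = 1)
  expect_equal(out$animal_id, c("b", "c"))
  expect_equal(attr(out, "qc_report")$n_removed, 1L)
  all_ok <- tibble::tibble(animal_id = "x", erc = 2)
  expect_equal(filter_erc(all_ok)$animal_id, "x")
  expect_error(filter_erc(tibble::tibble(animal_id = "x")), "erc")
})

test_that("filters are idempotent and reports reconcile", {
  cfg <- sim_config(n_animals = 150, n_snps = 400, n_chrom = 3,
                    n_cnv_loci = 5, missing_rate = 0.05, seed = 23)
  sim <- simulate_population(cfg)
  once <- filter_call_rate(sim$panel, 0.97, 0.97)
  twice <- filter_call_rate(once$panel, 0.97, 0.97)
  expect_identical(once$panel$geno, twice$panel$geno)
  expect_true(all(once$report$n_in - once$report$n_removed ==
                    once$report$n_out))
  expect_equal(once$report$n_out[2], ncol(once$panel$geno))
  pos_once <- filter_positions(sim$panel)
  expect_identical(filter_positions(pos_once$panel)$panel$geno,
                   pos_once$panel$geno)
})

test_that("tampered SNPs are recovered exactly when conflicts exceed 2%", {
  cfg <- sim_config(n_animals = 200, n_snps = 400, n_chrom = 3,
                    n_cnv_loci = 5, missing_rate = 0, founder_frac = 0.5,
                    seed = 29)
  sim <- simulate_population(cfg)
  expect_gte(nrow(sim$pairs), 100)
  tam <- inject_mendelian_errors(sim$panel, sim$pairs, n_tampered = 8,
                                 conflict_fraction = 0.05, seed = 31)
  out <- filter_mendelian(tam$panel, sim$pairs, 0.02)
  removed <- setdiff(sim$panel$map$snp_id, out$panel$map$snp_id)
  expect_setequal(removed, tam$tampered$snp_id)

  low <- inject_mendelian_errors(sim$panel, sim$pairs, n_tampered = 8,
                                 conflict_fraction = 0.02, seed = 31)
  out_low <- filter_mendelian(low$panel, sim$pairs, 0.02)
  expect_equal(ncol(out_low$panel$geno), ncol(sim$panel$geno))
})
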