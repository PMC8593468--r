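map5 <- tibble::tibble(
  snp_id = sprintf("s%02d", 1:30),
  chrom = rep(1:2, each = 15),
  pos_bp = rep(seq(10000, by = 2500, length.out = 15), 2),
  index = 1:30
)

call_row <- function(animal, chrom, s_idx, e_idx, cn, caller = "A",
                     map = map5) {
  tibble::tibble(
    animal_id = animal, chrom = chrom, start_index = s_idx, end_index = e_idx,
    start_bp = map$pos_bp[s_idx], end_bp = map$pos_bp[e_idx],
    copy_number = cn, n_snps = e_idx - s_idx + 1L, caller = caller
  )
}

test_that("rawcnv records parse with span resolution and rejections", {
  path <- tempfile()
  writeLines(c(
    "chr1:10500-20400 numsnp=5 length=9,901 state2,cn=1 A17 startsnp=s01 endsnp=s05",
    "chr1:10000-15000 numsnp=3 state5,cn=3 A02",
    "chr1:22600-25000 numsnp=1 state2,cn=2 A03",
    "chr2:1-5000 numsnp=2 state2,cn=1 A04"
  ), path)
  calls <- read_rawcnv(path, map5)
  # record 1: positions 10500-20400 cover SNPs at 12500..20000 (indices 2..5)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$copy_number, c(1L, 3L))
  expect_equal(calls$n_snps[1], 4L)
  expect_equal(calls$start_index[1], 2L)
  rej <- attr(calls, "rejected")
  expect_equal(unname(rej["cn2"]), 1)
  expect_equal(unname(rej["unmapped"]), 1)

  bad <- tempfile()
  writeLines(c("chr1:100-200 numsnp=2 state2,cn=1 A01", "not a record"), bad)
  expect_error(read_rawcnv(bad, map5), "line 2")
})

test_that("consensus matching honours the one-SNP endpoint tolerance", {
  a <- call_row("x", 1L, 10L, 14L, 1L, "A")
  b1 <- call_row("x", 1L, 11L, 15L, 1L, "B")   # both endpoints within 1
  m1 <- consensus_merge(a, b1)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$caller, "both")
  expect_equal(c(m1$start_index, m1$end_index), c(10L, 15L))  # union extent

  b2 <- call_row("x", 1L, 12L, 14L, 1L, "B")   # start differs by 2
  m2 <- consensus_merge(a, b2)
  expect_equal(nrow(m2), 2)

  # same span, opposite direction: never the same event
  b3 <- call_row("x", 1L, 10L, 14L, 3L, "B")
  m3 <- consensus_merge(a, b3)
  expect_equal(nrow(m3), 2)

  # a 2-SNP call is dropped regardless of caller
  short <- call_row("x", 1L, 10L, 11L, 1L, "A")
  m4 <- consensus_merge(short, b1)
  expect_equal(nrow(m4), 1)
  expect_equal(m4$caller, "B")
})

test_that("consensus merge is symmetric with the union-span convention", {
  set.seed(3)
  a <- dplyr::bind_rows(lapply(1:8, function(i) {
    s <- sample(1:10, 1)
    call_row(sprintf("an%d", sample(3, 1)), 1L, s, s + sample(4:6, 1),
             sample(c(1L, 3L), 1), "A")
  }))
  b <- dplyr::bind_rows(lapply(1:8, function(i) {
    s <- sample(1:10, 1)
    call_row(sprintf("an%d", sample(3, 1)), 1L, s, s + sample(4:6, 1),
             sample(c(1L, 3L), 1), "B")
  }))
  ab <- consensus_merge(a, b)
  ba <- consensus_merge(b, a)
  key <- function(x) sort(paste(x$animal_id, x$chrom, x$start_index,
                                x$end_index, x$copy_number))
  expect_identical(key(ab), key(ba))
})

test_that("locus construction applies the within-breed carrier filter", {
  animals <- tibble::tibble(animal_id = sprintf("an%d", 1:10),
                            breed = rep("B1", 10))
  calls <- dplyr::bind_rows(
    call_row("an1", 1L, 5L, 9L, 1L), call_row("an2", 1L, 5L, 9L, 1L),
    call_row("an3", 1L, 6L, 10L, 3L),                     # mixed, 3 carriers
    call_row("an4", 1L, 20L, 24L, 1L), call_row("an5", 1L, 20L, 24L, 1L)
  )
  ls <- build_loci(calls, animals, map5, min_carriers = 3)
  expect_equal(nrow(ls$loci), 1)            # 2-carrier locus dropped
  expect_equal(ls$loci$type, "mixed")
  expect_equal(ls$loci$n_carriers, 3L)
  expect_equal(unname(ls$classes[1:3, 1]), c(1L, 1L, 3L))
  expect_equal(unname(ls$classes[4, 1]), 2L)

  exact3 <- build_loci(calls[1:3, ], animals, map5, min_carriers = 3)
  expect_equal(nrow(exact3$loci), 1)        # boundary: exactly 3 retained
})

test_that("copy-class conflicts resolve by larger call, then deletion", {
  animals <- tibble::tibble(animal_id = sprintf("an%d", 1:5),
                            breed = rep("B1", 5))
  calls <- dplyr::bind_rows(
    call_row("an1", 1L, 5L, 9L, 1L),
    call_row("an1", 1L, 5L, 10L, 0L, "B"),   # larger call wins: cn 0
    call_row("an2", 1L, 5L, 9L, 1L),
    call_row("an3", 1L, 5L, 9L, 1L)
  )
  ls <- build_loci(calls, animals, map5, min_carriers = 3)
  expect_equal(unname(ls$classes[1, 1]), 0L)
  expect_equal(nrow(ls$conflicts), 1)

  tie <- dplyr::bind_rows(
    call_row("an1", 1L, 5L, 9L, 3L),
    call_row("an1", 1L, 5L, 9L, 1L, "B"),    # tie on size: deletion wins
    call_row("an2", 1L, 5L, 9L, 1L),
    call_row("an3", 1L, 5L, 9L, 1L)
  )
  ls2 <- build_loci(tie, animals, map5, min_carriers = 3)
  expect_equal(unname(ls2$classes[1, 1]), 1L)
})

test_that("rare double classes collapse symmetrically", {
  # 3 double-del + 4 single-del: neither reaches 5 -> one deletion class
  cls <- matrix(2L, 12, 1)
  cls[1:3, 1] <- 0L; cls[4:7, 1] <- 1L
  ls <- collapse_copy_classes(make_locus_set(cls), min_class_carriers = 5)
  expect_true(all(ls$classes[1:7, 1] == 1L))
  expect_true(ls$loci$collapsed_del)

  # 6 single-del, 0 double-del: a class reaches 5 -> unchanged
  cls2 <- matrix(2L, 12, 1); cls2[1:6, 1] <- 1L
  ls2 <- collapse_copy_classes(make_locus_set(cls2), min_class_carriers = 5)
  expect_equal(ls2$classes, cls2, ignore_attr = TRUE)
  expect_false(ls2$loci$collapsed_del)

  # all-normal locus unchanged
  cls3 <- matrix(2L, 12, 1)
  ls3 <- collapse_copy_classes(make_locus_set(cls3))
  expect_equal(ls3$classes, cls3, ignore_attr = TRUE)

  # duplications collapse on the same rule
  cls4 <- matrix(2L, 12, 1); cls4[1:2, 1] <- 4L; cls4[3:5, 1] <- 3L
  ls4 <- collapse_copy_classes(make_locus_set(cls4), min_class_carriers = 5)
  expect_true(all(ls4$classes[1:5, 1] == 3L))
  expect_true(ls4$loci$collapsed_dup)
})

test_that("carrier counts reconcile with an independent recount", {
  cfg <- sim_config(n_animals = 150, n_snps = 400, n_chrom = 3,
                    n_cnv_loci = 15, cnv_carrier_freq_range = c(0.03, 0.1),
                    seed = 37)
  sim <- simulate_population(cfg)
  fa <- tempfile(); fb <- tempfile()
  emit_caller_files(sim, fa, fb, jitter_prob = 0.1)
  cons <- consensus_merge(read_rawcnv(fa, sim$panel$map, "A"),
                          read_rawcnv(fb, sim$panel$map, "B"))
  ls <- build_loci(cons, sim$panel$animals, sim$panel$map)
  recount <- colSums(ls$classes != 2L)
  expect_equal(unname(recount), ls$loci$n_carriers)
  expect_equal(sum(ls$carriers_by_breed$carriers), sum(recount))
})
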