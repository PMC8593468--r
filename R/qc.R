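#' Genotype and phenotype quality-control filters
#'
#' The edit sequence applied to a [snp_panel()] before relationship matrices
#' are built: animal call-rate, SNP call-rate (computed on retained animals),
#' autosome/position completeness, Mendelian-inconsistency SNP removal, and
#' the effective-record-contribution exclusion on the trait table. Each
#' filter returns the reduced panel together with a `qc_report` tibble whose
#' removed + retained counts reconcile with the input dimensions.
#'
#' @name qc
NULL

qc_stage <- function(stage, unit, n_in, n_removed, detail = NA_character_) {
  tibble::tibble(stage = stage, unit = unit, n_in = n_in,
                 n_removed = n_removed, n_out = n_in - n_removed,
                 detail = detail)
}

#' Animal and SNP call-rate filter
#'
#' Animals with a called fraction below `animal_threshold` are removed first;
#' SNP call rates are then computed over the retained animals and SNPs below
#' `snp_threshold` are removed. Both comparisons are strict ("less than"), so
#' an animal or SNP at exactly the threshold is retained.
#'
#' @param panel a [snp_panel()].
#' @param animal_threshold,snp_threshold call-rate thresholds in (0, 1].
#' @return list with elements `panel` and `report`.
#' @export
filter_call_rate <- function(panel, animal_threshold = 0.95,
                             snp_threshold = 0.95) {
  stopifnot(inherits(panel, "snp_panel"))
  if (nrow(panel$geno) == 0 || ncol(panel$geno) == 0) {
    stop("empty panel", call. = FALSE)
  }
  stopifnot(animal_threshold > 0, animal_threshold <= 1,
            snp_threshold > 0, snp_threshold <= 1)
  called <- !is.na(panel$geno)
  animal_cr <- rowMeans(called)
  keep_animal <- animal_cr >= animal_threshold
  rep1 <- qc_stage("animal_call_rate", "animal", nrow(panel$geno),
                   sum(!keep_animal),
                   sprintf("threshold %.3f (strict <)", animal_threshold))
  panel <- subset_panel(panel, animal_keep = keep_animal)
  snp_cr <- colMeans(!is.na(panel$geno))
  keep_snp <- snp_cr >= snp_threshold
  rep2 <- qc_stage("snp_call_rate", "snp", ncol(panel$geno), sum(!keep_snp),
                   sprintf("threshold %.3f on retained animals", snp_threshold))
  panel <- subset_panel(panel, snp_keep = keep_snp)
  list(panel = panel, report = dplyr::bind_rows(rep1, rep2))
}

#' Autosome and position completeness filter
#'
#' Retains only SNPs with a chromosome in `1..n_autosomes` and a positive,
#' non-missing bp position. Sex chromosomes may be encoded as 0, `NA`, or any
#' value outside the autosome range.
#'
#' @param panel a [snp_panel()].
#' @param n_autosomes number of autosomes (29 for cattle).
#' @return list with elements `panel` and `report`.
#' @export
filter_positions <- function(panel, n_autosomes = 29) {
  stopifnot(inherits(panel, "snp_panel"))
  chrom <- suppressWarnings(as.integer(panel$map$chrom))
  keep <- !is.na(chrom) & chrom >= 1 & chrom <= n_autosomes &
    !is.na(panel$map$pos_bp) & panel$map$pos_bp > 0
  report <- qc_stage("position", "snp", ncol(panel$geno), sum(!keep),
                     sprintf("autosomes 1-%d, positive position", n_autosomes))
  list(panel = subset_panel(panel, snp_keep = keep), report = report)
}

#' Per-SNP opposing-homozygote conflict counts
#'
#' A conflict is a parent-progeny pair with opposing homozygotes (0 vs 2);
#' heterozygote-involving pairs are never conflicts. Pairs with either
#' genotype missing at a SNP are excluded from that SNP's denominator.
#'
#' @param panel a [snp_panel()].
#' @param pairs tibble with `parent` and `progeny` animal id columns.
#' @return tibble `snp_id`, `n_conflicts`, `n_informative`, `conflict_rate`.
#' @export
mendelian_conflicts <- function(panel, pairs) {
  stopifnot(inherits(panel, "snp_panel"))
  pr <- match(pairs$parent, panel$animals$animal_id)
  cr <- match(pairs$progeny, panel$animals$animal_id)
  keep <- !is.na(pr) & !is.na(cr)
  gp <- panel$geno[pr[keep], , drop = FALSE]
  gc <- panel$geno[cr[keep], , drop = FALSE]
  conflict <- (gp == 0 & gc == 2) | (gp == 2 & gc == 0)
  informative <- !is.na(gp) & !is.na(gc)
  n_conf <- colSums(conflict, na.rm = TRUE)
  n_inf <- colSums(informative)
  tibble::tibble(
    snp_id = panel$map$snp_id,
    n_conflicts = as.integer(n_conf),
    n_informative = as.integer(n_inf),
    conflict_rate = ifelse(n_inf > 0, n_conf / n_inf, 0)
  )
}

#' Mendelian-inconsistency SNP filter
#'
#' Removes SNPs whose opposing-homozygote conflict rate over informative
#' parent-progeny pairs exceeds `max_conflict_fraction` (strictly greater
#' than; a SNP at exactly the threshold is retained).
#'
#' @param panel a [snp_panel()].
#' @param pairs tibble with `parent` and `progeny` columns; an empty pair
#'   list returns the panel unchanged with a warning.
#' @param max_conflict_fraction removal threshold (default 0.02).
#' @return list with elements `panel`, `report` and `conflicts` (the per-SNP
#'   count table).
#' @export
filter_mendelian <- function(panel, pairs, max_conflict_fraction = 0.02) {
  stopifnot(inherits(panel, "snp_panel"))
  if (is.null(pairs) || nrow(pairs) == 0) {
    warning("empty pair list: Mendelian filter skipped", call. = FALSE)
    return(list(panel = panel,
                report = qc_stage("mendelian", "snp", ncol(panel$geno), 0L,
                                  "skipped: no pairs"),
                conflicts = NULL))
  }
  conf <- mendelian_conflicts(panel, pairs)
  keep <- !(conf$conflict_rate > max_conflict_fraction)
  report <- qc_stage("mendelian", "snp", ncol(panel$geno), sum(!keep),
                     sprintf("conflict rate > %.3f over informative pairs",
                             max_conflict_fraction))
  list(panel = subset_panel(panel, snp_keep = keep), report = report,
       conflicts = conf)
}

#' Effective-record-contribution exclusion
#'
#' Drops trait records whose effective record contribution falls strictly
#' below `min_erc`; a record at exactly `min_erc` is retained.
#'
#' @param traits tibble with at least an `erc` column.
#' @param min_erc exclusion threshold (default 1).
#' @return The filtered trait tibble, with the stage report attached as
#'   attribute `"qc_report"`.
#' @export
filter_erc <- function(traits, min_erc = 1) {
  if (!"erc" %in% names(traits)) stop("traits must have an `erc` column", call. = FALSE)
  keep <- traits$erc >= min_erc
  out <- traits[keep, , drop = FALSE]
  attr(out, "qc_report") <- qc_stage("erc", "animal", nrow(traits),
                                     sum(!keep),
                                     sprintf("erc < %g excluded", min_erc))
  out
}

#' Run the full edit sequence in the canonical order
#'
#' Applies, in order: animal call-rate, SNP call-rate, positional, Mendelian
#' and (on the trait table) the ERC filter, and binds the per-stage reports.
#'
#' @param panel a [snp_panel()].
#' @param traits trait tibble with an `erc` column (optional).
#' @param pairs parent-progeny pair tibble (optional).
#' @param animal_call_rate,snp_call_rate,n_autosomes,mendel_max,min_erc
#'   filter thresholds.
#' @return list with `panel`, `traits` and the combined `report`.
#' @export
run_qc <- function(panel, traits = NULL, pairs = NULL,
                   animal_call_rate = 0.95, snp_call_rate = 0.95,
                   n_autosomes = 29, mendel_max = 0.02, min_erc = 1) {
  s1 <- filter_call_rate(panel, animal_call_rate, snp_call_rate)
  s2 <- filter_positions(s1$panel, n_autosomes)
  s3 <- filter_mendelian(s2$panel, pairs, mendel_max)
  report <- dplyr::bind_rows(s1$report, s2$report, s3$report)
  if (!is.null(traits)) {
    traits <- filter_erc(traits, min_erc)
    report <- dplyr::bind_rows(report, attr(traits, "qc_report"))
    traits <- traits[traits$animal_id %in% s3$panel$animals$animal_id, ,
                     drop = FALSE]
  }
  list(panel = s3$panel, traits = traits, report = report)
}
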