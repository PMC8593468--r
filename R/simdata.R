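#' Configuration for the synthetic sire population generator
#'
#' Collects every knob of the simulator in one validated object. Defaults
#' describe a desk-scale multi-breed sire population: high-reliability
#' deregressed EBVs, CNVs at low carrier frequency, and a small CNV share of
#' the additive genetic variance next to a dominant SNP polygenic share.
#'
#' @param n_animals animals per breed.
#' @param n_snps number of autosomal SNPs on the array.
#' @param n_chrom number of autosomes the SNPs are spread over.
#' @param maf_range allele-frequency bounds in (0, 0.5] for per-breed,
#'   per-SNP frequencies.
#' @param n_cnv_loci number of true CNV loci.
#' @param cnv_carrier_freq_range carrier-frequency bounds in (0, 0.5).
#' @param n_causal_snps,n_causal_cnvs causal variant counts.
#' @param var_snp,var_cnv variances of the SNP polygenic and CNV parts of the
#'   true breeding value, on the trait scale.
#' @param var_total_genetic total additive genetic variance sigma_g^2 used as
#'   the denominator downstream and in the dEBV noise model.
#' @param reliability_range per-animal EBV reliability r^2 bounds in (0, 1].
#' @param caller_endpoint_jitter_prob probability that each emitted call
#'   endpoint is shifted by one SNP in a caller file.
#' @param mendelian_error_rate fraction of parent-progeny pairs tampered per
#'   tampered SNP by [inject_mendelian_errors()].
#' @param n_breeds number of breeds (each with its own allele-frequency
#'   profile).
#' @param missing_rate genotype missingness injected completely at random.
#' @param founder_frac fraction of animals per breed that are founders; the
#'   remainder are progeny of a recorded founder parent, so genotypes obey
#'   Mendelian transmission and the pedigree pair list is conflict-free
#'   before tampering.
#' @param erc_range effective-record-contribution bounds (>= 1 by default).
#' @param cnv_span_snps bounds on the number of SNPs a true CNV locus spans;
#'   the lower bound must be >= 5 so a one-SNP jitter at both endpoints can
#'   never push a true call below the 3-SNP consensus filter.
#' @param mixed_frac fraction of CNV loci segregating as both deletions and
#'   duplications.
#' @param seed integer seed; identical configurations reproduce bit-identical
#'   output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 950, n_snps = 5000, n_chrom = 29,
                       maf_range = c(0.05, 0.5), n_cnv_loci = 100,
                       cnv_carrier_freq_range = c(0.005, 0.05),
                       n_causal_snps = 50, n_causal_cnvs = 5,
                       var_snp = 0.25, var_cnv = 0.01,
                       var_total_genetic = 0.3,
                       reliability_range = c(0.7, 0.99),
                       caller_endpoint_jitter_prob = 0.1,
                       mendelian_error_rate = 0.05,
                       n_breeds = 1, missing_rate = 0.01,
                       founder_frac = 0.5, erc_range = c(1, 10),
                       cnv_span_snps = c(5, 12), mixed_frac = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_animals = as.integer(n_animals), n_snps = as.integer(n_snps),
    n_chrom = as.integer(n_chrom), maf_range = as.numeric(maf_range),
    n_cnv_loci = as.integer(n_cnv_loci),
    cnv_carrier_freq_range = as.numeric(cnv_carrier_freq_range),
    n_causal_snps = as.integer(n_causal_snps),
    n_causal_cnvs = as.integer(n_causal_cnvs),
    var_snp = var_snp, var_cnv = var_cnv,
    var_total_genetic = var_total_genetic,
    reliability_range = as.numeric(reliability_range),
    caller_endpoint_jitter_prob = caller_endpoint_jitter_prob,
    mendelian_error_rate = mendelian_error_rate,
    n_breeds = as.integer(n_breeds), missing_rate = missing_rate,
    founder_frac = founder_frac, erc_range = as.numeric(erc_range),
    cnv_span_snps = as.integer(cnv_span_snps), mixed_frac = mixed_frac,
    seed = as.integer(seed)
  )
  ranges <- c("maf_range", "cnv_carrier_freq_range", "reliability_range",
              "erc_range", "cnv_span_snps")
  for (r in ranges) {
    if (length(cfg[[r]]) != 2 || cfg[[r]][1] > cfg[[r]][2]) {
      stop(sprintf("%s must be an ordered pair", r), call. = FALSE)
    }
  }
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5) {
    stop("maf_range must lie in (0, 0.5]", call. = FALSE)
  }
  if (cfg$reliability_range[1] <= 0 || cfg$reliability_range[2] > 1) {
    stop("reliability_range must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$var_snp < 0 || cfg$var_cnv < 0 ||
      cfg$var_snp + cfg$var_cnv > cfg$var_total_genetic + 1e-12) {
    stop("need var_snp + var_cnv <= var_total_genetic, both non-negative",
         call. = FALSE)
  }
  if (cfg$n_causal_snps > cfg$n_snps) {
    stop("n_causal_snps exceeds n_snps", call. = FALSE)
  }
  if (cfg$n_causal_cnvs > cfg$n_cnv_loci) {
    stop("n_causal_cnvs exceeds n_cnv_loci", call. = FALSE)
  }
  if (cfg$cnv_span_snps[1] < 3) {
    stop("CNV loci must span at least 3 SNPs", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a sire population with a known SNP/CNV variance split
#'
#' Generates a multi-breed SNP panel, true CNV loci with per-animal copy
#' classes, true breeding values `tbv = snp polygenic part + cnv part` whose
#' sample variances are scaled exactly to `var_snp` and `var_cnv`, and
#' deregressed EBVs `debv_i = tbv_i + e_i` with
#' `e_i ~ N(0, sigma_g^2 (1 - r_i^2) / r_i^2)` given per-animal reliabilities.
#' Non-founder animals receive one gamete from a recorded founder parent so
#' the returned pedigree pair list is Mendelian-consistent by construction.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_population` with elements
#'   \describe{
#'     \item{panel}{[snp_panel()] with injected missingness.}
#'     \item{cnv_loci}{tibble of true loci (`locus_id`, `chrom`,
#'       `start_index`, `end_index`, `start_bp`, `end_bp`, `n_snps`,
#'       `direction`).}
#'     \item{cnv_classes}{animals-by-loci integer matrix of copy numbers
#'       (0/1/2/3/4; 2 = normal).}
#'     \item{truth}{list with `true_bv`, `causal_snps`, `causal_cnvs`,
#'       `reliability`.}
#'     \item{traits}{tibble `animal_id`, `breed`, `debv`, `reliability`,
#'       `erc`.}
#'     \item{pairs}{tibble of parent-progeny pairs.}
#'   }
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_total <- cfg$n_animals * cfg$n_breeds

  ## SNP map: SNPs split evenly over autosomes, positions by cumulative gaps
  per_chrom <- diff(floor(seq(0, cfg$n_snps, length.out = cfg$n_chrom + 1)))
  chrom <- rep(seq_len(cfg$n_chrom), per_chrom)
  pos_bp <- unlist(lapply(per_chrom, function(k) {
    cumsum(sample(500:5000, k, replace = TRUE))
  }), use.names = FALSE)
  map <- tibble::tibble(
    snp_id = sprintf("snp%05d", seq_len(cfg$n_snps)),
    chrom = chrom, pos_bp = pos_bp, index = seq_len(cfg$n_snps)
  )

  breeds <- sprintf("B%d", seq_len(cfg$n_breeds))
  animals <- tibble::tibble(
    animal_id = sprintf("A%05d", seq_len(n_total)),
    breed = rep(breeds, each = cfg$n_animals)
  )

  ## genotypes: founders binomial(2, p_breed); progeny get one transmitted
  ## gamete from a recorded parent and one population gamete
  geno <- matrix(0L, n_total, cfg$n_snps)
  pairs_list <- vector("list", cfg$n_breeds)
  freqs <- matrix(stats::runif(cfg$n_breeds * cfg$n_snps,
                               cfg$maf_range[1], cfg$maf_range[2]),
                  nrow = cfg$n_breeds)
  for (b in seq_len(cfg$n_breeds)) {
    rows <- which(animals$breed == breeds[b])
    p <- freqs[b, ]
    n_found <- max(2L, ceiling(cfg$founder_frac * cfg$n_animals))
    founders <- rows[seq_len(n_found)]
    progeny <- setdiff(rows, founders)
    for (i in founders) {
      geno[i, ] <- stats::rbinom(cfg$n_snps, 2L, p)
    }
    if (length(progeny)) {
      par_of <- sample(founders, length(progeny), replace = TRUE)
      for (k in seq_along(progeny)) {
        transmitted <- stats::rbinom(cfg$n_snps, 1L, geno[par_of[k], ] / 2)
        geno[progeny[k], ] <- transmitted + stats::rbinom(cfg$n_snps, 1L, p)
      }
      pairs_list[[b]] <- tibble::tibble(
        parent = animals$animal_id[par_of],
        progeny = animals$animal_id[progeny]
      )
    }
  }
  pairs <- dplyr::bind_rows(pairs_list)

  ## CNV truth: loci of >= cnv_span_snps[1] SNPs, carriers drawn per breed at
  ## a shared carrier frequency, copy classes by locus direction
  loci <- vector("list", cfg$n_cnv_loci)
  classes <- matrix(2L, n_total, cfg$n_cnv_loci)
  directions <- sample(c("deletion", "duplication", "mixed"), cfg$n_cnv_loci,
                       replace = TRUE,
                       prob = c((1 - cfg$mixed_frac) / 2,
                                (1 - cfg$mixed_frac) / 2, cfg$mixed_frac))
  occupied <- vector("list", cfg$n_chrom)  # placed spans, per chromosome
  for (l in seq_len(cfg$n_cnv_loci)) {
    ## place loci at least 4 SNPs apart so that endpoint jitter (<= 1 SNP)
    ## plus the 1-SNP consensus tolerance can never bridge two true loci
    span <- sample(cfg$cnv_span_snps[1]:cfg$cnv_span_snps[2], 1)
    placed <- FALSE
    for (attempt in 1:200) {
      ch <- sample(which(per_chrom >= span + 2), 1)
      ch_idx <- which(map$chrom == ch)
      start <- ch_idx[sample(length(ch_idx) - span, 1) + 1L]
      end <- start + span - 1L
      clash <- any(vapply(occupied[[ch]], function(iv) {
        start <= iv[2] + 4L && iv[1] <= end + 4L
      }, logical(1)))
      if (!clash) {
        occupied[[ch]] <- c(occupied[[ch]], list(c(start, end)))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place CNV loci without overlap; ",
                      "reduce n_cnv_loci or increase n_snps", call. = FALSE)
    f <- stats::runif(1, cfg$cnv_carrier_freq_range[1],
                      cfg$cnv_carrier_freq_range[2])
    carriers <- which(stats::runif(n_total) < f)
    if (length(carriers)) {
      dir_l <- directions[l]
      cls <- vapply(carriers, function(i) {
        d <- if (dir_l == "mixed") sample(c("deletion", "duplication"), 1) else dir_l
        if (d == "deletion") sample(c(1L, 0L), 1, prob = c(0.9, 0.1))
        else sample(c(3L, 4L), 1, prob = c(0.9, 0.1))
      }, integer(1))
      classes[carriers, l] <- cls
    }
    loci[[l]] <- tibble::tibble(
      locus_id = sprintf("cnv%04d", l), chrom = ch,
      start_index = start, end_index = end,
      start_bp = map$pos_bp[start], end_bp = map$pos_bp[end],
      n_snps = span, direction = directions[l]
    )
  }
  cnv_loci <- dplyr::bind_rows(loci)
  colnames(classes) <- cnv_loci$locus_id
  rownames(classes) <- animals$animal_id

  ## true breeding values: parts rescaled so sample variances equal the
  ## configured var_snp / var_cnv exactly
  scale_part <- function(x, v) {
    s <- stats::sd(x)
    if (v <= 0 || s == 0) list(g = rep(0, length(x)), mult = 0)
    else list(g = x * sqrt(v) / s, mult = sqrt(v) / s)
  }
  causal_snp_idx <- sort(sample(cfg$n_snps, cfg$n_causal_snps))
  u_snp <- stats::rnorm(cfg$n_causal_snps)
  g_snp_raw <- as.vector(scale(geno[, causal_snp_idx, drop = FALSE],
                               scale = FALSE) %*% u_snp)
  snp_part <- scale_part(g_snp_raw, cfg$var_snp)
  causal_cnv_idx <- sort(sample(cfg$n_cnv_loci, cfg$n_causal_cnvs))
  u_cnv <- stats::rnorm(cfg$n_causal_cnvs)
  dosage <- classes[, causal_cnv_idx, drop = FALSE] - 2
  g_cnv_raw <- as.vector(dosage %*% u_cnv)
  cnv_part <- scale_part(g_cnv_raw, cfg$var_cnv)
  true_bv <- snp_part$g + cnv_part$g

  reliability <- stats::runif(n_total, cfg$reliability_range[1],
                              cfg$reliability_range[2])
  noise_sd <- sqrt(cfg$var_total_genetic * (1 - reliability) / reliability)
  debv <- true_bv + stats::rnorm(n_total, 0, noise_sd)
  erc <- stats::runif(n_total, cfg$erc_range[1], cfg$erc_range[2])

  if (cfg$missing_rate > 0) {
    n_miss <- round(cfg$missing_rate * length(geno))
    geno[sample(length(geno), n_miss)] <- NA
  }

  structure(list(
    panel = snp_panel(geno, map, animals),
    cnv_loci = cnv_loci,
    cnv_classes = classes,
    truth = list(
      true_bv = stats::setNames(true_bv, animals$animal_id),
      causal_snps = tibble::tibble(snp_id = map$snp_id[causal_snp_idx],
                                   effect = u_snp * snp_part$mult),
      causal_cnvs = tibble::tibble(locus_id = cnv_loci$locus_id[causal_cnv_idx],
                                   effect = u_cnv * cnv_part$mult),
      reliability = stats::setNames(reliability, animals$animal_id)
    ),
    traits = tibble::tibble(animal_id = animals$animal_id,
                            breed = animals$breed, debv = debv,
                            reliability = reliability, erc = erc),
    pairs = pairs,
    config = cfg
  ), class = "sim_population")
}

#' Emit two noisy caller files from the true CNV calls
#'
#' Every true per-animal call appears in both files in a PennCNV-style text
#' dialect; each endpoint is independently shifted by one SNP (direction at
#' random, clamped to the chromosome) with probability `jitter_prob`, and a
#' configurable fraction of 2-SNP decoy calls is appended. Decoys fall below
#' the 3-SNP consensus filter by construction.
#'
#' @param sim a `sim_population` from [simulate_population()].
#' @param path_a,path_b output file paths for the two callers.
#' @param jitter_prob per-endpoint shift probability; defaults to the
#'   configured `caller_endpoint_jitter_prob`.
#' @param decoy_frac decoy calls added per file, as a fraction of true calls.
#' @param seed integer seed.
#' @return Invisibly, a tibble of the true (animal, locus) calls emitted.
#' @export
emit_caller_files <- function(sim, path_a, path_b,
                              jitter_prob = sim$config$caller_endpoint_jitter_prob,
                              decoy_frac = 0.05,
                              seed = sim$config$seed + 1L) {
  stopifnot(inherits(sim, "sim_population"))
  if (any(sim$cnv_loci$n_snps < 3)) stop("truth loci must span >= 3 SNPs", call. = FALSE)
  set.seed(seed)
  map <- sim$panel$map
  chrom_range <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(lo = min(.data$index), hi = max(.data$index))
  lo <- stats::setNames(chrom_range$lo, chrom_range$chrom)
  hi <- stats::setNames(chrom_range$hi, chrom_range$chrom)

  idx <- which(sim$cnv_classes != 2L, arr.ind = TRUE)
  truth_calls <- tibble::tibble(
    animal_id = rownames(sim$cnv_classes)[idx[, 1]],
    locus_id = colnames(sim$cnv_classes)[idx[, 2]],
    copy_number = sim$cnv_classes[idx]
  ) |>
    dplyr::left_join(sim$cnv_loci, by = "locus_id") |>
    dplyr::arrange(.data$locus_id, .data$animal_id)

  jitter_ends <- function(start, end, chr) {
    n <- length(start)
    shift <- function(x) {
      moved <- stats::runif(n) < jitter_prob
      x + ifelse(moved, sample(c(-1L, 1L), n, replace = TRUE), 0L)
    }
    s <- pmax(shift(start), lo[as.character(chr)])
    e <- pmin(shift(end), hi[as.character(chr)])
    list(start = pmin(s, e), end = pmax(s, e))
  }

  emit <- function(calls, path) {
    j <- jitter_ends(calls$start_index, calls$end_index, calls$chrom)
    ## decoys: 2-SNP spans on random chromosomes, below the min-SNP filter
    n_decoy <- round(decoy_frac * nrow(calls))
    if (n_decoy > 0) {
      dch <- sample(chrom_range$chrom, n_decoy, replace = TRUE)
      dstart <- vapply(dch, function(ch) {
        lo[as.character(ch)] + sample.int(hi[as.character(ch)] - lo[as.character(ch)] - 1L, 1) - 1L
      }, integer(1))
      decoys <- tibble::tibble(
        animal_id = sample(rownames(sim$cnv_classes), n_decoy, replace = TRUE),
        chrom = dch, start = dstart, end = dstart + 1L,
        copy_number = sample(c(1L, 3L), n_decoy, replace = TRUE)
      )
    } else {
      decoys <- NULL
    }
    all_calls <- dplyr::bind_rows(
      tibble::tibble(animal_id = calls$animal_id, chrom = calls$chrom,
                     start = j$start, end = j$end,
                     copy_number = calls$copy_number),
      decoys
    )
    state_of <- c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)
    lines <- sprintf(
      "chr%d:%d-%d numsnp=%d length=%s state%d,cn=%d %s startsnp=%s endsnp=%s",
      all_calls$chrom, map$pos_bp[all_calls$start], map$pos_bp[all_calls$end],
      all_calls$end - all_calls$start + 1L,
      formatC(map$pos_bp[all_calls$end] - map$pos_bp[all_calls$start] + 1L,
              big.mark = ",", format = "d"),
      state_of[as.character(all_calls$copy_number)], all_calls$copy_number,
      all_calls$animal_id, map$snp_id[all_calls$start], map$snp_id[all_calls$end]
    )
    writeLines(lines, path)
  }
  emit(truth_calls, path_a)
  emit(truth_calls, path_b)
  invisible(truth_calls[, c("animal_id", "locus_id", "copy_number")])
}

#' Inject opposing-homozygote Mendelian conflicts into a panel
#'
#' For each tampered SNP, a recorded fraction of parent-progeny pairs is
#' forced to the opposing-homozygote state (parent 0, progeny 2), so the QC
#' Mendelian filter has a known positive set to recover.
#'
#' @param panel a [snp_panel()].
#' @param pairs tibble with `parent` and `progeny` animal id columns.
#' @param n_tampered number of SNPs to tamper (ignored when `snp_ids` given).
#' @param conflict_fraction fraction of pairs forced into conflict per SNP.
#' @param snp_ids optional explicit SNP ids to tamper.
#' @param seed integer seed.
#' @return list with elements `panel` (modified) and `tampered`, a tibble of
#'   SNPs actually modified with the number of pairs forced per SNP.
#' @export
inject_mendelian_errors <- function(panel, pairs, n_tampered = 10,
                                    conflict_fraction = 0.05,
                                    snp_ids = NULL, seed = 1L) {
  stopifnot(inherits(panel, "snp_panel"))
  if (nrow(pairs) == 0) stop("empty pair list", call. = FALSE)
  miss <- setdiff(c(pairs$parent, pairs$progeny), panel$animals$animal_id)
  if (length(miss)) stop("pairs reference unknown animals", call. = FALSE)
  set.seed(seed)
  if (is.null(snp_ids)) {
    snp_ids <- sample(panel$map$snp_id, n_tampered)
  }
  n_force <- round(conflict_fraction * nrow(pairs))
  parent_row <- match(pairs$parent, panel$animals$animal_id)
  progeny_row <- match(pairs$progeny, panel$animals$animal_id)
  tampered <- list()
  for (s in snp_ids) {
    if (n_force == 0) next
    col <- match(s, panel$map$snp_id)
    sel <- sample(nrow(pairs), n_force)
    panel$geno[parent_row[sel], col] <- 0L
    panel$geno[progeny_row[sel], col] <- 2L
    ## a forced parent may have other progeny; make those heterozygous so the
    ## realised conflict count stays exactly at the recorded fraction
    other <- setdiff(which(parent_row %in% parent_row[sel]), sel)
    if (length(other)) panel$geno[progeny_row[other], col] <- 1L
    tampered[[s]] <- tibble::tibble(snp_id = s, n_pairs_forced = n_force)
  }
  list(panel = panel,
       tampered = if (length(tampered)) dplyr::bind_rows(tampered)
                  else tibble::tibble(snp_id = character(), n_pairs_forced = integer()))
}
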