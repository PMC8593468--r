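#' SNP panel: genotype matrix plus positional map
#'
#' A `snp_panel` bundles an animals-by-SNPs genotype matrix (codes 0/1/2,
#' `NA` = missing) with its SNP map (chromosome and 1-based bp position) and
#' an animal table carrying breed labels. It is the substrate for quality
#' control, genomic relationship matrices and association design matrices.
#'
#' @param geno integer/numeric matrix, animals in rows (rownames = animal
#'   ids), SNPs in columns (colnames = SNP ids). Legal values 0, 1, 2 or `NA`;
#'   fractional values are permitted after mean imputation.
#' @param map tibble with columns `snp_id`, `chrom` (autosome integer; 0 or
#'   `NA` marks an unplaced SNP), `pos_bp` (1-based position; `NA` allowed for
#'   unplaced SNPs) and `index` (column index into `geno`).
#' @param animals tibble with columns `animal_id` and `breed`.
#'
#' @return An object of class `snp_panel`.
#' @export
snp_panel <- function(geno, map, animals) {
  stopifnot(is.matrix(geno), nrow(map) == ncol(geno), nrow(animals) == nrow(geno))
  if (!all(c("snp_id", "chrom", "pos_bp", "index") %in% names(map))) {
    stop("map must have columns snp_id, chrom, pos_bp, index", call. = FALSE)
  }
  if (!all(c("animal_id", "breed") %in% names(animals))) {
    stop("animals must have columns animal_id, breed", call. = FALSE)
  }
  vals <- geno[is.finite(geno)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 2)) {
    stop("genotype codes must lie in [0, 2]", call. = FALSE)
  }
  if (any(duplicated(map$index))) stop("map indices must be unique", call. = FALSE)
  rownames(geno) <- animals$animal_id
  colnames(geno) <- map$snp_id
  structure(
    list(geno = geno, map = tibble::as_tibble(map),
         animals = tibble::as_tibble(animals)),
    class = "snp_panel"
  )
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("<snp_panel> %d animals x %d SNPs (%d breed%s)\n",
              nrow(x$geno), ncol(x$geno),
              dplyr::n_distinct(x$animals$breed),
              if (dplyr::n_distinct(x$animals$breed) == 1) "" else "s"))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  chromosomes: %s; missing: %.2f%%\n",
              paste(range(x$map$chrom, na.rm = TRUE), collapse = "-"),
              100 * miss))
  invisible(x)
}

#' @export
dim.snp_panel <- function(x) dim(x$geno)

#' Subset a panel by animals and/or SNP map rows
#'
#' @param panel a [snp_panel()].
#' @param animal_keep logical or integer index over animals.
#' @param snp_keep logical or integer index over SNPs (map rows).
#' @return A `snp_panel` with `map$index` renumbered to stay contiguous.
#' @export
subset_panel <- function(panel, animal_keep = NULL, snp_keep = NULL) {
  geno <- panel$geno
  map <- panel$map
  animals <- panel$animals
  if (!is.null(animal_keep)) {
    geno <- geno[animal_keep, , drop = FALSE]
    animals <- animals[animal_keep, , drop = FALSE]
  }
  if (!is.null(snp_keep)) {
    geno <- geno[, snp_keep, drop = FALSE]
    map <- map[snp_keep, , drop = FALSE]
    map$index <- seq_len(nrow(map))
  }
  snp_panel(geno, map, animals)
}

#' Write / read a panel as plain-text TSV files
#'
#' The genotype matrix goes to `<stem>_geno.tsv` (animal_id column followed
#' by one column per SNP), the map to `<stem>_map.tsv` and the animal table
#' to `<stem>_animals.tsv`.
#'
#' @param panel a [snp_panel()].
#' @param stem file path stem.
#' @return `write_panel` returns `stem` invisibly; `read_panel` a `snp_panel`.
#' @export
write_panel <- function(panel, stem) {
  geno_df <- tibble::as_tibble(panel$geno, .name_repair = "minimal")
  names(geno_df) <- panel$map$snp_id
  geno_df <- dplyr::bind_cols(tibble::tibble(animal_id = panel$animals$animal_id), geno_df)
  readr::write_tsv(geno_df, paste0(stem, "_geno.tsv"))
  readr::write_tsv(panel$map, paste0(stem, "_map.tsv"))
  readr::write_tsv(panel$animals, paste0(stem, "_animals.tsv"))
  invisible(stem)
}

#' @rdname write_panel
#' @export
read_panel <- function(stem) {
  geno_df <- readr::read_tsv(paste0(stem, "_geno.tsv"), show_col_types = FALSE)
  map <- readr::read_tsv(paste0(stem, "_map.tsv"), show_col_types = FALSE)
  animals <- readr::read_tsv(paste0(stem, "_animals.tsv"), show_col_types = FALSE)
  geno <- as.matrix(geno_df[, -1, drop = FALSE])
  rownames(geno) <- geno_df$animal_id
  snp_panel(geno, map, animals)
}
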