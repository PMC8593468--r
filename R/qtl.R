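#' QTL window designation, merging and annotation
#'
#' Each associated variant receives a window of `flank_bp` (50 kb by
#' default) on each side. Same-type variants (SNP with SNP, CNV with CNV)
#' whose positions lie within `flank_bp` of each other are merged by single
#' linkage; the merged window runs from the outermost members +/- the
#' flank. CNV distances are measured from the span edges. SNP-QTLs and
#' CNV-QTLs that overlap are cross-referenced as one shared region but are
#' never re-merged across type.
#'
#' @name qtl
NULL

#' Build QTL windows from associated variants
#'
#' @param variants tibble with `variant_id`, `type` (`"snp"`/`"cnv"`),
#'   `chrom` and positions: `pos_bp` for SNPs, `start_bp`/`end_bp` for CNVs
#'   (SNPs may carry `start_bp = end_bp = pos_bp`).
#' @param flank_bp window flank; inter-variant distance <= `flank_bp`
#'   (inclusive) merges.
#' @return A tibble of class `qtl_set`: `qtl_id`, `type`, `chrom`,
#'   `start_bp` (floored at 1), `end_bp`, `n_members`, `members` (list
#'   column, sorted by position) and `shared_region` (id linking
#'   overlapping SNP- and CNV-QTLs, `NA` otherwise).
#' @export
build_qtls <- function(variants, flank_bp = 50000) {
  needed <- c("variant_id", "type", "chrom")
  if (!all(needed %in% names(variants))) {
    stop("variants needs variant_id, type, chrom and positions", call. = FALSE)
  }
  v <- tibble::as_tibble(variants)
  if (!"start_bp" %in% names(v)) v$start_bp <- v$pos_bp
  if (!"end_bp" %in% names(v)) v$end_bp <- v$pos_bp
  v$start_bp <- ifelse(is.na(v$start_bp) & !is.na(v$pos_bp), v$pos_bp, v$start_bp)
  v$end_bp <- ifelse(is.na(v$end_bp) & !is.na(v$pos_bp), v$pos_bp, v$end_bp)
  if (any(is.na(v$start_bp) | is.na(v$end_bp) | is.na(v$chrom))) {
    stop("variant without a position", call. = FALSE)
  }

  qtls <- v |>
    dplyr::group_by(.data$type, .data$chrom) |>
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$start_bp, .data$end_bp)
      ## single linkage on sorted intervals: a new cluster starts when the
      ## gap to everything seen so far exceeds the flank
      cluster <- integer(nrow(g))
      cur <- 1L
      max_end <- g$end_bp[1]
      cluster[1] <- cur
      for (i in seq_len(nrow(g))[-1]) {
        if (g$start_bp[i] - max_end > flank_bp) cur <- cur + 1L
        cluster[i] <- cur
        max_end <- max(max_end, g$end_bp[i])
      }
      g$cluster <- cluster
      g |>
        dplyr::group_by(.data$cluster) |>
        dplyr::summarise(
          start_bp = max(1, min(.data$start_bp) - flank_bp),
          end_bp = max(.data$end_bp) + flank_bp,
          n_members = dplyr::n(),
          members = list(.data$variant_id),
          .groups = "drop"
        ) |>
        dplyr::select(-"cluster")
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$start_bp, .data$type)
  qtls$qtl_id <- sprintf("qtl_%s_%03d", qtls$type,
                         as.integer(stats::ave(seq_len(nrow(qtls)), qtls$type,
                                               FUN = seq_along)))
  qtls <- qtls[, c("qtl_id", "type", "chrom", "start_bp", "end_bp",
                   "n_members", "members")]

  ## cross-reference overlapping SNP- and CNV-QTLs without re-merging
  qtls$shared_region <- NA_character_
  snp_q <- which(qtls$type == "snp")
  cnv_q <- which(qtls$type == "cnv")
  shared <- 0L
  for (i in snp_q) {
    for (j in cnv_q) {
      if (qtls$chrom[i] == qtls$chrom[j] &&
          qtls$start_bp[i] <= qtls$end_bp[j] &&
          qtls$start_bp[j] <= qtls$end_bp[i]) {
        if (is.na(qtls$shared_region[i]) && is.na(qtls$shared_region[j])) {
          shared <- shared + 1L
          id <- sprintf("shared_%03d", shared)
          qtls$shared_region[i] <- id
          qtls$shared_region[j] <- id
        } else {
          id <- stats::na.omit(c(qtls$shared_region[i], qtls$shared_region[j]))[1]
          qtls$shared_region[i] <- id
          qtls$shared_region[j] <- id
        }
      }
    }
  }
  class(qtls) <- c("qtl_set", class(qtls))
  qtls
}

#' Report genes overlapping each QTL window
#'
#' A gene is reported iff its interval overlaps the QTL window by at least
#' 1 bp (half-open arithmetic internally; coordinates are 1-based inclusive
#' on input and output). The annotation may be a BED/GFF3 file path (read
#' with rtracklayer), a `GRanges`, or a tibble with `gene`, `chrom`,
#' `start_bp`, `end_bp` columns.
#'
#' @param qtls a `qtl_set` from [build_qtls()].
#' @param annotation gene annotation (see above). BED input is converted
#'   from 0-based half-open to 1-based inclusive by the reader.
#' @return `qtls` with a `genes` list column appended.
#' @export
annotate_qtls <- function(qtls, annotation) {
  ann <- normalize_annotation(annotation)
  if (nrow(ann) > 1 && is.unsorted(order(ann$chrom, ann$start_bp))) {
    warning("annotation not position-sorted; sorting internally", call. = FALSE)
    ann <- dplyr::arrange(ann, .data$chrom, .data$start_bp)
  }
  if (nrow(ann) == 0) {
    qtls$genes <- rep(list(character()), nrow(qtls))
    return(qtls)
  }
  q_gr <- GenomicRanges::GRanges(
    seqnames = as.character(qtls$chrom),
    ranges = IRanges::IRanges(start = qtls$start_bp, end = qtls$end_bp)
  )
  a_gr <- GenomicRanges::GRanges(
    seqnames = as.character(ann$chrom),
    ranges = IRanges::IRanges(start = ann$start_bp, end = ann$end_bp)
  )
  hits <- GenomicRanges::findOverlaps(q_gr, a_gr, minoverlap = 1L)
  genes <- vector("list", nrow(qtls))
  for (i in seq_len(nrow(qtls))) genes[[i]] <- character()
  if (length(hits)) {
    sp <- split(ann$gene[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    for (q in names(sp)) genes[[as.integer(q)]] <- unique(sp[[q]])
  }
  qtls$genes <- genes
  qtls
}

normalize_annotation <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1) {
    gr <- rtracklayer::import(annotation)
    nm <- if (!is.null(gr$name)) gr$name
          else if (!is.null(gr$gene_name)) gr$gene_name
          else if (!is.null(gr$Name)) gr$Name
          else if (!is.null(gr$ID)) gr$ID
          else as.character(seq_along(gr))
    return(tibble::tibble(
      gene = nm,
      chrom = sub("^chr", "", as.character(GenomicRanges::seqnames(gr))),
      start_bp = GenomicRanges::start(gr),
      end_bp = GenomicRanges::end(gr)
    ))
  }
  if (methods::is(annotation, "GRanges")) {
    nm <- if (!is.null(annotation$name)) annotation$name
          else as.character(seq_along(annotation))
    return(tibble::tibble(
      gene = nm,
      chrom = sub("^chr", "", as.character(GenomicRanges::seqnames(annotation))),
      start_bp = GenomicRanges::start(annotation),
      end_bp = GenomicRanges::end(annotation)
    ))
  }
  ann <- tibble::as_tibble(annotation)
  stopifnot(all(c("gene", "chrom", "start_bp", "end_bp") %in% names(ann)))
  ann$chrom <- sub("^chr", "", as.character(ann$chrom))
  ann
}

#' Write QTL windows as BED (0-based half-open) and TSV (1-based inclusive)
#'
#' @param qtls a `qtl_set`.
#' @param stem file path stem; writes `<stem>.bed` and `<stem>.tsv`.
#' @return `stem` invisibly.
#' @export
write_qtls <- function(qtls, stem) {
  bed <- data.frame(chrom = paste0("chr", qtls$chrom),
                    start = qtls$start_bp - 1L, end = qtls$end_bp,
                    name = qtls$qtl_id)
  utils::write.table(bed, paste0(stem, ".bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tsv <- qtls
  tsv$members <- vapply(tsv$members, paste, character(1), collapse = ",")
  if ("genes" %in% names(tsv)) {
    tsv$genes <- vapply(tsv$genes, paste, character(1), collapse = ",")
  }
  readr::write_tsv(tibble::as_tibble(tsv), paste0(stem, ".tsv"))
  invisible(stem)
}
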