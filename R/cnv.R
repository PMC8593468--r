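#' CNV call parsing, consensus merging and locus construction
#'
#' Calls from two CNV callers are parsed from PennCNV-style text, matched
#' under a one-SNP endpoint tolerance, filtered to a minimum SNP count, and
#' grouped into population loci with per-animal copy classes and a
#' minimum-carrier filter. Copy classes are double-deletion (0 copies),
#' single-deletion (1), normal (2), single-duplication (3) and
#' double-duplication (4); a call never has copy number 2.
#'
#' @name cnv
NULL

copy_class_labels <- c(`0` = "double_del", `1` = "single_del", `2` = "normal",
                       `3` = "single_dup", `4` = "double_dup")

call_direction <- function(cn) {
  out <- rep("deletion", length(cn))
  out[cn > 2] <- "duplication"
  out
}

#' Read a PennCNV-style raw CNV call file
#'
#' Expected line shape:
#' `chr1:10500-20400 numsnp=5 length=9,901 state2,cn=1 A17 startsnp=... endsnp=...`
#' (the `length`, `state` and `startsnp`/`endsnp` fields are optional). The
#' bp span is resolved against the SNP map; `n_snps` is the number of mapped
#' SNPs inside the span. Records with copy number 2 (the normal state) and
#' records whose span contains no mapped SNPs are rejected and counted.
#'
#' @param path file path.
#' @param snp_map SNP map tibble (`snp_id`, `chrom`, `pos_bp`, `index`).
#' @param caller caller tag attached to each call.
#' @return tibble of calls (`animal_id`, `chrom`, `start_index`, `end_index`,
#'   `start_bp`, `end_bp`, `copy_number`, `n_snps`, `caller`) with attribute
#'   `"rejected"` = c(cn2 = ..., unmapped = ...).
#' @export
read_rawcnv <- function(path, snp_map, caller = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pat <- "^chr([0-9XY]+):([0-9]+)-([0-9]+)\\s+numsnp=([0-9]+)\\s+(?:length=[0-9,]+\\s+)?(?:state[0-9]+,)?cn=([0-9]+)\\s+(\\S+)"
  m <- regmatches(lines, regexec(pat, lines))
  bad <- which(lengths(m) == 0)
  if (length(bad)) {
    stop(sprintf("malformed rawcnv record at line %d: %s",
                 bad[1], lines[bad[1]]), call. = FALSE)
  }
  rec <- do.call(rbind, lapply(m, function(x) x[-1]))
  calls <- tibble::tibble(
    animal_id = rec[, 6],
    chrom = suppressWarnings(as.integer(rec[, 1])),
    start_bp = as.numeric(rec[, 2]),
    end_bp = as.numeric(rec[, 3]),
    copy_number = as.integer(rec[, 5])
  )
  n_cn2 <- sum(calls$copy_number == 2, na.rm = TRUE)
  calls <- calls[!is.na(calls$copy_number) & calls$copy_number != 2, ]

  ## resolve bp spans to SNP-map index spans, chromosome by chromosome
  calls$start_index <- NA_integer_
  calls$end_index <- NA_integer_
  for (ch in unique(calls$chrom)) {
    rows <- which(calls$chrom == ch)
    sm <- snp_map[snp_map$chrom == ch, ]
    if (nrow(sm) == 0) next
    pos <- sm$pos_bp
    lo <- findInterval(calls$start_bp[rows] - 1, pos) + 1L
    hi <- findInterval(calls$end_bp[rows], pos)
    ok <- lo <= hi & lo <= length(pos) & hi >= 1
    calls$start_index[rows[ok]] <- sm$index[lo[ok]]
    calls$end_index[rows[ok]] <- sm$index[hi[ok]]
  }
  n_unmapped <- sum(is.na(calls$start_index))
  calls <- calls[!is.na(calls$start_index), ]
  calls$start_bp <- snp_map$pos_bp[match(calls$start_index, snp_map$index)]
  calls$end_bp <- snp_map$pos_bp[match(calls$end_index, snp_map$index)]
  calls$n_snps <- calls$end_index - calls$start_index + 1L
  calls$caller <- caller
  out <- calls[, c("animal_id", "chrom", "start_index", "end_index",
                   "start_bp", "end_bp", "copy_number", "n_snps", "caller")]
  attr(out, "rejected") <- c(cn2 = n_cn2, unmapped = n_unmapped)
  out
}

#' Consensus-merge calls from two callers
#'
#' A call from caller A and one from caller B are the same event iff they
#' come from the same animal, same chromosome and same direction (deletion
#' vs duplication) and both endpoints agree to within
#' `endpoint_tolerance_snps` SNP-map indices. Calls spanning fewer than
#' `min_snps` SNPs are dropped first. Matched pairs are emitted once (never
#' double counted) with the union extent of the two spans, which keeps the
#' merge symmetric in its two inputs and preserves each caller's endpoint
#' evidence; unmatched calls from either caller are retained (union rule).
#'
#' @param calls_a,calls_b call tibbles from [read_rawcnv()].
#' @param endpoint_tolerance_snps endpoint tolerance in SNP indices.
#' @param min_snps minimum SNPs per retained call.
#' @return A deduplicated call tibble; matched pairs carry caller `"both"`.
#' @export
consensus_merge <- function(calls_a, calls_b, endpoint_tolerance_snps = 1,
                            min_snps = 3) {
  a <- calls_a[calls_a$n_snps >= min_snps, ]
  b <- calls_b[calls_b$n_snps >= min_snps, ]
  a$direction <- call_direction(a$copy_number)
  b$direction <- call_direction(b$copy_number)
  a <- dplyr::arrange(a, .data$animal_id, .data$chrom, .data$start_index)
  b <- dplyr::arrange(b, .data$animal_id, .data$chrom, .data$start_index)
  b_key <- paste(b$animal_id, b$chrom, b$direction)
  b_used <- rep(FALSE, nrow(b))
  a$caller_out <- a$caller
  for (i in seq_len(nrow(a))) {
    cand <- which(!b_used &
                    b_key == paste(a$animal_id[i], a$chrom[i], a$direction[i]) &
                    abs(b$start_index - a$start_index[i]) <= endpoint_tolerance_snps &
                    abs(b$end_index - a$end_index[i]) <= endpoint_tolerance_snps)
    if (length(cand)) {
      k <- cand[1]
      b_used[k] <- TRUE
      a$caller_out[i] <- "both"
      if (b$start_index[k] < a$start_index[i]) {
        a$start_index[i] <- b$start_index[k]
        a$start_bp[i] <- b$start_bp[k]
      }
      if (b$end_index[k] > a$end_index[i]) {
        a$end_index[i] <- b$end_index[k]
        a$end_bp[i] <- b$end_bp[k]
      }
      a$n_snps[i] <- a$end_index[i] - a$start_index[i] + 1L
    }
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(a, caller = .data$caller_out),
    b[!b_used, ]
  )
  out$caller_out <- NULL
  out$direction <- NULL
  dplyr::arrange(out, .data$chrom, .data$start_index, .data$animal_id)
}

## union-find over calls: two calls join the same locus iff both endpoints
## match within the tolerance (transitive closure; direction-agnostic, so a
## locus can be mixed)
cluster_spans <- function(chrom, start, end, tol) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(chrom, start, end)
  for (k in seq_len(n)) {
    i <- ord[k]
    j <- k + 1L
    while (j <= n) {
      jj <- ord[j]
      if (chrom[jj] != chrom[i] || start[jj] - start[i] > tol) break
      if (abs(end[jj] - end[i]) <= tol) {
        ri <- find(i); rj <- find(jj)
        if (ri != rj) parent[ri] <- rj
      }
      j <- j + 1L
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Group consensus calls into population CNV loci
#'
#' Calls whose spans match under the endpoint tolerance (transitive closure)
#' form one locus. The locus span is the modal (start, end) among member
#' calls (ties to the smallest span). Per-animal copy classes come from the
#' calls (conflicts resolved by larger `n_snps`, then deletion before
#' duplication); uncalled animals are normal. Loci carried by fewer than
#' `min_carriers` animals in every breed are dropped.
#'
#' @param calls consensus call tibble.
#' @param animals tibble `animal_id`, `breed` for the full animal set.
#' @param snp_map SNP map tibble.
#' @param min_carriers within-breed minimum carrier count.
#' @param endpoint_tolerance_snps endpoint tolerance in SNP indices.
#' @return list of class `cnv_locus_set`: `loci` tibble (`locus_id`, `chrom`,
#'   `start_index`, `end_index`, `start_bp`, `end_bp`, `n_snps`, `type`,
#'   `n_carriers`, `max_breed_carriers`, `collapsed_del`, `collapsed_dup`),
#'   `classes` animals-by-loci copy-number matrix, `carriers_by_breed`
#'   tibble, and `conflicts` (per-animal class conflicts resolved).
#' @export
build_loci <- function(calls, animals, snp_map, min_carriers = 3,
                       endpoint_tolerance_snps = 1) {
  stopifnot(all(c("animal_id", "breed") %in% names(animals)))
  if (nrow(calls) == 0) {
    return(structure(list(
      loci = tibble::tibble(), classes = matrix(2L, nrow(animals), 0,
                                                dimnames = list(animals$animal_id, NULL)),
      carriers_by_breed = tibble::tibble(), conflicts = tibble::tibble()
    ), class = "cnv_locus_set"))
  }
  cl <- cluster_spans(calls$chrom, calls$start_index, calls$end_index,
                      endpoint_tolerance_snps)
  calls$cluster <- cl

  conflicts <- list()
  loci <- list()
  classes <- matrix(2L, nrow(animals), 0)
  rownames(classes) <- animals$animal_id
  cids <- unique(calls$cluster[order(calls$chrom, calls$start_index)])
  keep_cols <- list()
  for (ci in seq_along(cids)) {
    sub <- calls[calls$cluster == cids[ci], ]
    span_tab <- dplyr::count(sub, .data$start_index, .data$end_index)
    span_tab <- span_tab[order(-span_tab$n, span_tab$start_index,
                               span_tab$end_index), ]
    s0 <- span_tab$start_index[1]; e0 <- span_tab$end_index[1]

    ## one class per animal: larger n_snps wins, then deletion < duplication
    sub <- sub[order(sub$animal_id, -sub$n_snps, sub$copy_number), ]
    dup_animal <- duplicated(sub$animal_id)
    if (any(dup_animal)) {
      extra <- sub[dup_animal, ]
      first <- sub[!dup_animal, ]
      confl <- extra[extra$copy_number !=
                       first$copy_number[match(extra$animal_id, first$animal_id)], ]
      if (nrow(confl)) {
        conflicts[[length(conflicts) + 1L]] <-
          tibble::tibble(cluster = cids[ci], animal_id = confl$animal_id,
                         dropped_cn = confl$copy_number)
      }
    }
    sub <- sub[!dup_animal, ]

    col <- rep(2L, nrow(animals))
    col[match(sub$animal_id, animals$animal_id)] <- sub$copy_number
    by_breed <- tapply(col != 2L, animals$breed, sum)
    if (max(by_breed) < min_carriers) next

    has_del <- any(col < 2); has_dup <- any(col > 2)
    type <- if (has_del && has_dup) "mixed" else if (has_del) "deletion" else "duplication"
    lid <- sprintf("locus%04d", length(loci) + 1L)
    loci[[length(loci) + 1L]] <- tibble::tibble(
      locus_id = lid, chrom = sub$chrom[1],
      start_index = s0, end_index = e0,
      start_bp = snp_map$pos_bp[match(s0, snp_map$index)],
      end_bp = snp_map$pos_bp[match(e0, snp_map$index)],
      n_snps = e0 - s0 + 1L, type = type,
      n_carriers = sum(col != 2L),
      max_breed_carriers = max(by_breed),
      collapsed_del = FALSE, collapsed_dup = FALSE
    )
    keep_cols[[lid]] <- col
  }
  if (length(keep_cols)) {
    classes <- do.call(cbind, keep_cols)
    rownames(classes) <- animals$animal_id
  }
  loci_tbl <- if (length(loci)) dplyr::bind_rows(loci) else tibble::tibble()
  cbb <- if (length(keep_cols)) {
    purrr::map_dfr(loci_tbl$locus_id, function(lid) {
      cnt <- tapply(classes[, lid] != 2L, animals$breed, sum)
      tibble::tibble(locus_id = lid, breed = names(cnt),
                     carriers = as.integer(cnt))
    })
  } else tibble::tibble()
  structure(list(loci = loci_tbl, classes = classes,
                 carriers_by_breed = cbb,
                 conflicts = if (length(conflicts)) dplyr::bind_rows(conflicts)
                             else tibble::tibble(),
                 animals = tibble::as_tibble(animals)),
            class = "cnv_locus_set")
}

#' @export
print.cnv_locus_set <- function(x, ...) {
  cat(sprintf("<cnv_locus_set> %d loci x %d animals\n",
              nrow(x$loci), nrow(x$classes)))
  if (nrow(x$loci)) print(dplyr::count(x$loci, .data$type))
  invisible(x)
}

#' Collapse rare double copy classes for association coding
#'
#' For each locus: when neither deletion class (double or single deletion)
#' reaches `min_class_carriers` carriers in any breed, the two classes merge
#' into one deletion class (copy number 1); duplications are treated
#' symmetrically (merged to copy number 3). The collapse is recorded per
#' locus in `collapsed_del` / `collapsed_dup`.
#'
#' @param locus_set a `cnv_locus_set` from [build_loci()].
#' @param min_class_carriers class-level carrier threshold (default 5).
#' @return The modified `cnv_locus_set`.
#' @export
collapse_copy_classes <- function(locus_set, min_class_carriers = 5) {
  stopifnot(inherits(locus_set, "cnv_locus_set"))
  breeds <- locus_set$animals$breed
  for (j in seq_len(nrow(locus_set$loci))) {
    col <- locus_set$classes[, j]
    max_by_class <- function(cn) {
      if (!any(col == cn)) return(0L)
      max(tapply(col == cn, breeds, sum))
    }
    if (any(col < 2) && max_by_class(0L) < min_class_carriers &&
        max_by_class(1L) < min_class_carriers) {
      locus_set$classes[col == 0L, j] <- 1L
      locus_set$loci$collapsed_del[j] <- TRUE
    }
    if (any(col > 2) && max_by_class(4L) < min_class_carriers &&
        max_by_class(3L) < min_class_carriers) {
      locus_set$classes[col == 4L, j] <- 3L
      locus_set$loci$collapsed_dup[j] <- TRUE
    }
  }
  locus_set
}

#' Tidy per-animal copy classes
#'
#' @param locus_set a `cnv_locus_set`.
#' @return Long tibble `animal_id`, `locus_id`, `copy_number`, `class`.
#' @export
tidy_classes <- function(locus_set) {
  m <- locus_set$classes
  tibble::tibble(
    animal_id = rep(rownames(m), ncol(m)),
    locus_id = rep(colnames(m), each = nrow(m)),
    copy_number = as.integer(m)
  ) |>
    dplyr::mutate(class = copy_class_labels[as.character(.data$copy_number)])
}
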