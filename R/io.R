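#' Read a gene-by-sample count matrix from TSV
#'
#' Expects genes in rows with a `gene_id` first column (or row names) and
#' one column per sample. Duplicate gene or sample IDs and negative counts
#' are rejected.
#'
#' @param path TSV file.
#' @return integer matrix with gene row names and sample column names.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] %in% c("gene_id", "gene", "")) {
    genes <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  } else {
    genes <- rownames(df)
  }
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  validate_counts(m)
  m
}

#' @rdname read_counts
#' @param counts integer matrix as returned by [read_counts()].
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene row names and sample column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene IDs", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate sample IDs", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  invisible(counts)
}

#' Read/validate a sample sheet
#'
#' Columns: `sample_id`, `individual`, `side` (L/R), `structure`,
#' `age_pcw` (> 0), `sex` (M/F).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sheet(sheet)
  sheet
}

validate_sheet <- function(sheet) {
  need <- c("sample_id", "individual", "side", "structure", "age_pcw", "sex")
  miss <- setdiff(need, colnames(sheet))
  if (length(miss)) {
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample IDs", call. = FALSE)
  if (!all(sheet$side %in% c("L", "R"))) stop("side must be L or R", call. = FALSE)
  if (!all(sheet$sex %in% c("M", "F"))) stop("sex must be M or F", call. = FALSE)
  if (any(sheet$age_pcw <= 0)) stop("ages must be positive", call. = FALSE)
  invisible(sheet)
}

# Check L/R pairing within a structure; returns individuals in pair order or
# errors naming the offender.
check_pairing <- function(sheet) {
  tab <- table(sheet$individual, sheet$side)
  bad <- rownames(tab)[tab[, "L"] != 1 | tab[, "R"] != 1]
  if (length(bad)) {
    stop("individual(s) without exactly one L and one R sample: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sort(unique(sheet$individual))
}

#' log2 counts-per-million transformation
#'
#' `log2((count + prior_count) / (lib_size + 2 * prior_count) * 1e6)`, with
#' library sizes taken as column sums unless supplied.
#'
#' @param counts count matrix.
#' @param prior_count offset avoiding log of zero (default 0.5).
#' @param lib_sizes optional per-sample library sizes; defaults to column
#'   sums, which must be positive.
#' @return numeric matrix of log2-CPM values, same dimnames as `counts`.
#' @export
log2_cpm <- function(counts, prior_count = 0.5, lib_sizes = NULL) {
  validate_counts(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("zero library size", call. = FALSE)
  y <- sweep(counts + prior_count, 2, lib_sizes + 2 * prior_count, "/")
  log2(y * 1e6)
}

#' Filter to expressed genes
#'
#' Keeps a gene iff its count is at least `min_reads` in at least
#' `min_libraries` samples (applied to the samples present in `counts`, i.e.
#' per structure when called per structure). Defaults: at least 5 reads in
#' at least 3 libraries. Idempotent.
#'
#' @param counts count matrix.
#' @param min_reads minimum count per qualifying library (>= 0).
#' @param min_libraries minimum number of qualifying libraries (>= 1, <=
#'   number of samples).
#' @return the filtered count matrix.
#' @export
filter_expressed <- function(counts, min_reads = 5, min_libraries = 3) {
  validate_counts(counts)
  stop_if_not_scalar(min_reads, "min_reads", integerish = TRUE, min = 0)
  stop_if_not_scalar(min_libraries, "min_libraries", integerish = TRUE, min = 1)
  if (min_libraries > ncol(counts)) {
    stop("min_libraries exceeds the number of samples", call. = FALSE)
  }
  keep <- rowSums(counts >= min_reads) >= min_libraries
  counts[keep, , drop = FALSE]
}

#' Merge split sequencing libraries by summing counts
#'
#' Some libraries are sequenced in several runs; this sums the integer
#' counts of columns mapped to the same final sample.
#'
#' @param counts count matrix whose columns are library IDs.
#' @param mapping named character vector: names = library IDs (columns of
#'   `counts`), values = final sample IDs.
#' @return count matrix with one column per final sample.
#' @export
merge_libraries <- function(counts, mapping) {
  validate_counts(counts)
  if (!all(colnames(counts) %in% names(mapping))) {
    stop("mapping must cover every column of counts", call. = FALSE)
  }
  grp <- factor(mapping[colnames(counts)],
                levels = unique(mapping[colnames(counts)]))
  out <- vapply(levels(grp), function(g) {
    as.integer(rowSums(counts[, grp == g, drop = FALSE]))
  }, integer(nrow(counts)))
  rownames(out) <- rownames(counts)
  out
}

#' Expression-based sex confirmation
#'
#' Infers sex per sample from the X-inactivation transcript XIST and two
#' Y-chromosomal genes (EIF1AY, KDM5D): female iff XIST is above
#' `xist_threshold` and both Y markers below `y_threshold`; male iff the
#' reverse; otherwise indeterminate. Compares against the annotated sex.
#'
#' @param expr log2-CPM matrix (see [log2_cpm()]).
#' @param sheet sample sheet with annotated `sex`.
#' @param markers character vector of length 3: XIST-like gene then two Y
#'   genes (configurable IDs).
#' @param xist_threshold,y_threshold log2-CPM thresholds (defaults 2 and 1).
#' @return data.frame with `sample_id`, `annotated_sex`, `inferred_sex`
#'   (`M`, `F` or `indeterminate`) and `pass` (NA when indeterminate). When
#'   markers are absent from `expr`, every sample is indeterminate (no
#'   error).
#' @export
confirm_sex <- function(expr, sheet,
                        markers = c("XIST", "EIF1AY", "KDM5D"),
                        xist_threshold = 2, y_threshold = 1) {
  stopifnot(length(markers) == 3)
  sheet <- sheet[match(colnames(expr), sheet$sample_id), , drop = FALSE]
  out <- data.frame(sample_id = colnames(expr),
                    annotated_sex = sheet$sex,
                    inferred_sex = "indeterminate",
                    pass = NA,
                    stringsAsFactors = FALSE)
  if (!all(markers %in% rownames(expr))) {
    return(out)
  }
  x <- expr[markers[1], ]
  y1 <- expr[markers[2], ]
  y2 <- expr[markers[3], ]
  f <- x > xist_threshold & y1 < y_threshold & y2 < y_threshold
  m <- x < xist_threshold & y1 > y_threshold & y2 > y_threshold
  out$inferred_sex[f] <- "F"
  out$inferred_sex[m] <- "M"
  det <- out$inferred_sex != "indeterminate"
  out$pass[det] <- out$inferred_sex[det] == out$annotated_sex[det]
  out
}

#' MDS-based quality control
#'
#' Classical (Torgerson) multidimensional scaling of Euclidean distances
#' between samples over the most variable genes, with per-dimension
#' association tests (unpaired t for sex, paired-by-individual t for side,
#' Pearson correlation for age; Bonferroni over the dimensions tested) and a
#' quantified outlier rule: a sample is flagged when its distance to its
#' structure centroid in MDS space exceeds median + `outlier_mad` * MAD of
#' those distances within the structure.
#'
#' @param expr log2-CPM matrix.
#' @param sheet sample sheet covering the columns of `expr`.
#' @param k_dims number of MDS dimensions (reduced with a warning when more
#'   than n - 1 are requested).
#' @param n_top_genes number of top-variance genes used for the distances.
#' @param outlier_mad MAD multiplier `c` in the outlier rule (default 5).
#' @return list with `coords` (samples x k), `tests` (per-dimension p-values
#'   and Bonferroni-adjusted p for sex, side, age), `outliers` (data.frame
#'   with distances and flags), and `dist` (the distance object used).
#' @export
mds_qc <- function(expr, sheet, k_dims = 8, n_top_genes = 500,
                   outlier_mad = 5) {
  if (ncol(expr) < 3) stop("need at least 3 samples for MDS QC", call. = FALSE)
  sheet <- sheet[match(colnames(expr), sheet$sample_id), , drop = FALSE]
  v <- apply(expr, 1, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(min(n_top_genes, nrow(expr)))]
  d <- stats::dist(t(expr[top, , drop = FALSE]))
  kmax <- ncol(expr) - 1L
  if (k_dims > kmax) {
    warning(sprintf("k_dims reduced from %d to %d (n - 1)", k_dims, kmax))
    k_dims <- kmax
  }
  cmd <- stats::cmdscale(d, k = k_dims, eig = TRUE)
  coords <- cmd$points
  if (ncol(coords) < k_dims) k_dims <- ncol(coords) # degenerate eigenvalues
  colnames(coords) <- sprintf("dim%d", seq_len(ncol(coords)))

  tests <- do.call(rbind, lapply(seq_len(k_dims), function(k) {
    z <- coords[, k]
    p_sex <- tryCatch(stats::t.test(z ~ factor(sheet$sex))$p.value,
                      error = function(e) NA_real_)
    p_side <- tryCatch({
      wide <- split(data.frame(z = z, side = sheet$side), sheet$individual)
      dif <- vapply(wide, function(w) {
        w$z[w$side == "R"] - w$z[w$side == "L"]
      }, numeric(1))
      stats::t.test(dif)$p.value
    }, error = function(e) NA_real_)
    ct <- tryCatch(stats::cor.test(z, sheet$age_pcw),
                   error = function(e) list(estimate = NA_real_, p.value = NA_real_))
    data.frame(dim = k, p_sex = p_sex, p_side = p_side,
               r_age = unname(ct$estimate), p_age = ct$p.value)
  }))
  for (col in c("p_sex", "p_side", "p_age")) {
    tests[[paste0(col, "_bonf")]] <- pmin(1, tests[[col]] * k_dims)
  }

  # outliers: per-structure centroid distance in MDS space
  dists <- rep(NA_real_, ncol(expr))
  for (st in unique(sheet$structure)) {
    idx <- which(sheet$structure == st)
    centroid <- colMeans(coords[idx, , drop = FALSE])
    dists[idx] <- sqrt(rowSums(sweep(coords[idx, , drop = FALSE], 2, centroid)^2))
  }
  flags <- rep(FALSE, ncol(expr))
  for (st in unique(sheet$structure)) {
    idx <- which(sheet$structure == st)
    thr <- stats::median(dists[idx]) + outlier_mad * stats::mad(dists[idx])
    flags[idx] <- dists[idx] > thr
  }
  outliers <- data.frame(sample_id = colnames(expr), structure = sheet$structure,
                         centroid_dist = dists, outlier = flags,
                         stringsAsFactors = FALSE)
  list(coords = coords, tests = tests, outliers = outliers, dist = d)
}
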