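#' Jaccard index of two sets
#'
#' \eqn{|a \cap b| / |a \cup b|}; defined as 0 when both sets are empty (a
#' declared convention avoiding spurious perfect overlap between structures
#' with no enrichments).
#'
#' @param a,b character vectors (duplicates ignored).
#' @return a number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Lateralized gene sets from a GSEA result
#'
#' Given enrichment on a side-contrast ranking (positive t = higher right),
#' positive-NES sets passing the FDR threshold are right-lateralized,
#' negative-NES sets left-lateralized.
#'
#' @param gsea a `gsea_result`.
#' @param structure structure label.
#' @param fdr_threshold FDR cut (default 0.05).
#' @return list of class `lateralized_sets`: structure, threshold, `R` and
#'   `L` character vectors of set names.
#' @export
lateralized_sets <- function(gsea, structure, fdr_threshold = 0.05) {
  pass <- !is.na(gsea$FDR) & gsea$FDR < fdr_threshold
  out <- list(structure = structure, fdr_threshold = fdr_threshold,
              R = gsea$set[pass & gsea$NES > 0],
              L = gsea$set[pass & gsea$NES < 0])
  class(out) <- "lateralized_sets"
  out
}

#' Side-stratified Jaccard overlap matrices
#'
#' Pairwise Jaccard indices of the lateralized set lists across structures,
#' one symmetric matrix per side, plus a summary comparing the mean
#' off-diagonal overlap between the right and left sides.
#'
#' @param lists list of [lateralized_sets()] objects (>= 2, all computed at
#'   the same FDR threshold — mixed thresholds are rejected).
#' @return list with `R`, `L` (matrices) and `summary` (mean off-diagonal
#'   Jaccard per side).
#' @export
overlap_matrix <- function(lists) {
  if (length(lists) < 2) stop("need at least 2 structures", call. = FALSE)
  thr <- vapply(lists, `[[`, numeric(1), "fdr_threshold")
  if (length(unique(thr)) != 1) stop("mixed FDR thresholds", call. = FALSE)
  sts <- vapply(lists, `[[`, character(1), "structure")
  mats <- lapply(c(R = "R", L = "L"), function(side) {
    m <- outer(seq_along(lists), seq_along(lists),
               Vectorize(function(i, j) jaccard(lists[[i]][[side]],
                                                lists[[j]][[side]])))
    dimnames(m) <- list(sts, sts)
    diag(m) <- ifelse(vapply(lists, function(l) length(l[[side]]) > 0,
                             logical(1)), 1, 0)
    m
  })
  offdiag_mean <- vapply(mats, function(m) mean(m[upper.tri(m)]), numeric(1))
  list(R = mats$R, L = mats$L,
       summary = data.frame(side = names(offdiag_mean),
                            mean_offdiag_jaccard = offdiag_mean,
                            row.names = NULL))
}

#' Default pipeline configuration
#'
#' Thresholds used throughout: expression filter (>= 5 reads in >= 3
#' libraries), GSEA size window 15-500, lateralization FDR 0.05 and
#' permutation-count FDR 0.25.
#'
#' @param structures structure names to simulate/analyse.
#' @param sim a [sim_config()] describing the synthetic study.
#' @param min_reads,min_libraries expression filter.
#' @param gsea_min_size,gsea_max_size,n_perm_gsea GSEA controls.
#' @param fdr_lateral,fdr_perm FDR thresholds.
#' @param run_flips whether to run the sign-flip permutations per structure.
#' @param n_perm_gsea_flips GSEA permutations inside the flip pipeline.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(structures = c("forebrain", "midbrain", "hindbrain"),
                            sim = sim_config(),
                            min_reads = 5, min_libraries = 3,
                            gsea_min_size = 15, gsea_max_size = 500,
                            n_perm_gsea = 500, fdr_lateral = 0.05,
                            fdr_perm = 0.25, run_flips = TRUE,
                            n_perm_gsea_flips = 0, seed = 1) {
  stopifnot(min_reads >= 0, min_libraries >= 1, gsea_min_size > 0,
            gsea_max_size >= gsea_min_size, fdr_lateral > 0, fdr_perm > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full laterality pipeline on a simulated study
#'
#' Per structure: QC (sex confirmation, MDS outlier screen) -> expression
#' filter -> paired side DE -> age DE -> GSEA on the side ranking ->
#' side-age correlation -> sign-flip permutations (direction call uses the
#' permutation p); then cross-structure Jaccard overlap matrices and a
#' summary table (leading side and top-2 enriched sets per side by |NES|
#' among FDR-passing sets). Deterministic under a fixed config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, all tables are written as
#'   TSV.
#' @return list with per-structure results (`qc`, `side_de`, `age_de`,
#'   `gsea`, `asynchrony`, `flips`), `overlap`, and `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  sim$seed <- derive_seed(config$seed, 1L)
  study <- simulate_study(sim, config$structures)
  results <- list()
  for (st in config$structures) {
    ds <- study$datasets[[st]]
    if (length(unique(ds$sheet$individual)) < 2) {
      stop("structure ", st, ": need at least 2 pairs for the side contrast",
           call. = FALSE)
    }
    expr_all <- log2_cpm(ds$counts)
    qc <- list(sex = confirm_sex(expr_all, ds$sheet),
               mds = mds_qc(expr_all, ds$sheet,
                            k_dims = min(8, ncol(ds$counts) - 1)))
    counts_f <- filter_expressed(ds$counts, config$min_reads,
                                 config$min_libraries)
    side_de <- side_contrast(counts_f, ds$sheet)
    age_de <- age_contrast(counts_f, ds$sheet)
    gsea <- gsea_preranked(ranked_scores(side_de), study$sets,
                           n_perm = config$n_perm_gsea,
                           min_size = config$gsea_min_size,
                           max_size = config$gsea_max_size,
                           seed = derive_seed(config$seed, 20L + match(st, config$structures)))
    flips <- NULL
    perm_p <- NULL
    if (config$run_flips) {
      flips <- flip_pipeline(
        counts_f, ds$sheet,
        sets = if (config$n_perm_gsea_flips > 0) study$sets else NULL,
        age_de = age_de, n_perm_gsea = config$n_perm_gsea_flips,
        fdr_threshold = config$fdr_perm,
        seed = derive_seed(config$seed, 40L + match(st, config$structures)))
      perm_p <- flips$p_abs_r
    }
    asyn <- side_age_correlation(side_de, age_de, perm_p = perm_p,
                                 structure = st)
    results[[st]] <- list(qc = qc, side_de = side_de, age_de = age_de,
                          gsea = gsea, asynchrony = asyn, flips = flips,
                          lateral = lateralized_sets(gsea, st,
                                                     config$fdr_lateral))
  }
  overlap <- if (length(config$structures) >= 2) {
    overlap_matrix(lapply(results, `[[`, "lateral"))
  } else NULL

  summary <- do.call(rbind, lapply(config$structures, function(st) {
    res <- results[[st]]
    g <- res$gsea
    top2 <- function(side) {
      pass <- !is.na(g$FDR) & g$FDR < config$fdr_lateral &
        (if (side == "R") g$NES > 0 else g$NES < 0)
      nm <- g$set[pass][order(-abs(g$NES[pass]))]
      paste(utils::head(nm, 2), collapse = ";")
    }
    # leading_side is descriptive (sign of r); direction_call additionally
    # requires the sign-flip permutation p to pass
    data.frame(structure = st,
               n_pairs = length(unique(study$datasets[[st]]$sheet$individual)),
               r_side_age = res$asynchrony$r,
               perm_p = res$asynchrony$perm_p,
               leading_side = ifelse(res$asynchrony$r > 0, "right", "left"),
               direction_call = res$asynchrony$direction,
               top_right_sets = top2("R"),
               top_left_sets = top2("L"),
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  out <- list(structures = results, overlap = overlap, summary = summary,
              config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(df, file.path(out_dir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  for (st in names(res$structures)) {
    r <- res$structures[[st]]
    write_de(r$side_de, file.path(out_dir, paste0(st, "_side_de.tsv")))
    write_de(r$age_de, file.path(out_dir, paste0(st, "_age_de.tsv")))
    wt(r$gsea[, setdiff(colnames(r$gsea), "leading_edge")],
       paste0(st, "_gsea.tsv"))
    wt(r$asynchrony, paste0(st, "_asynchrony.tsv"))
    wt(r$qc$sex, paste0(st, "_sex_qc.tsv"))
    wt(r$qc$mds$outliers, paste0(st, "_mds_outliers.tsv"))
    if (!is.null(r$flips)) wt(r$flips$table, paste0(st, "_flips.tsv"))
  }
  wt(res$summary, "summary.tsv")
  if (!is.null(res$overlap)) {
    wt(data.frame(side = "R", structure = rownames(res$overlap$R),
                  res$overlap$R, check.names = FALSE), "overlap_R.tsv")
    wt(data.frame(side = "L", structure = rownames(res$overlap$L),
                  res$overlap$L, check.names = FALSE), "overlap_L.tsv")
    wt(res$overlap$summary, "overlap_summary.tsv")
  }
  invisible(out_dir)
}
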