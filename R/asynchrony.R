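#' Side-age correlation: the developmental-asynchrony statistic
#'
#' Correlates per-gene left-right t-values with per-gene age t-values over
#' the genes shared by both analyses (the two sets of t-values may come from
#' different sample sets). A positive correlation means genes that rise with
#' age are higher on the right side, i.e. the right side leads the left
#' along the shared developmental trajectory; negative means the left side
#' leads.
#'
#' The nominal two-sided p-value uses the usual t approximation but is
#' flagged as biased (genes are not independent data points); the direction
#' call therefore requires a sign-flip permutation p-value
#' ([flip_pipeline()]), not the nominal p. Without a permutation p the
#' direction is `"none"`.
#'
#' @param side_de,age_de `de_result` data.frames (or any data.frames with
#'   `gene_id` and `t` columns).
#' @param perm_p optional sign-flip permutation p-value for `|r|`.
#' @param alpha significance level for the direction call (default 0.05).
#' @param structure optional label carried into the report.
#' @return one-row data.frame (class `asynchrony_report`): structure,
#'   n_genes, r, p_nominal, perm_p, direction, caveat.
#' @export
side_age_correlation <- function(side_de, age_de, perm_p = NULL,
                                 alpha = 0.05, structure = NA_character_) {
  shared <- intersect(side_de$gene_id, age_de$gene_id)
  if (length(shared) < 3) {
    stop("need at least 3 shared genes (found ", length(shared), ")",
         call. = FALSE)
  }
  ts <- side_de$t[match(shared, side_de$gene_id)]
  ta <- age_de$t[match(shared, age_de$gene_id)]
  if (stats::sd(ts) == 0 || stats::sd(ta) == 0) {
    stop("zero variance in t-values", call. = FALSE)
  }
  r <- stats::cor(ts, ta)
  n <- length(shared)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  direction <- "none"
  if (!is.null(perm_p) && is.finite(perm_p) && perm_p < alpha) {
    direction <- if (r > 0) "right-leads" else "left-leads"
  }
  out <- data.frame(structure = structure, n_genes = n, r = r,
                    p_nominal = p,
                    perm_p = if (is.null(perm_p)) NA_real_ else perm_p,
                    direction = direction,
                    caveat = "genes non-independent",
                    stringsAsFactors = FALSE)
  class(out) <- c("asynchrony_report", "data.frame")
  out
}

#' Side-versus-age t-value scatter and table
#'
#' Writes the per-gene (side t, age t) table and a scatter plot with the
#' side t-value on the x axis (positive = higher on the right) and the age
#' t-value on the y axis (positive = increases with age).
#'
#' @inheritParams side_age_correlation
#' @param out path prefix; writes `<out>.tsv` and `<out>.pdf` (or `.png`
#'   with `device = "png"`).
#' @param device `"pdf"` (default, always available headless) or `"png"`.
#' @return invisibly, the data.frame written.
#' @export
scatter_report <- function(side_de, age_de, out, device = c("pdf", "png")) {
  device <- match.arg(device)
  shared <- intersect(side_de$gene_id, age_de$gene_id)
  if (length(shared) == 0) stop("zero shared genes between the two analyses",
                                call. = FALSE)
  df <- data.frame(gene_id = shared,
                   side_t = side_de$t[match(shared, side_de$gene_id)],
                   age_t = age_de$t[match(shared, age_de$gene_id)],
                   stringsAsFactors = FALSE)
  utils::write.table(df, paste0(out, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fig <- paste0(out, ".", device)
  if (device == "png") grDevices::png(fig, width = 800, height = 800)
  else grDevices::pdf(fig, width = 6, height = 6)
  on.exit(grDevices::dev.off())
  graphics::plot(df$side_t, df$age_t, pch = 16, cex = 0.4,
                 col = grDevices::rgb(0, 0, 0, 0.4),
                 xlab = "left-right differential expression t (positive = higher right)",
                 ylab = "age differential expression t (positive = up with age)")
  graphics::abline(h = 0, v = 0, col = "grey70")
  r <- stats::cor(df$side_t, df$age_t)
  graphics::mtext(sprintf("Pearson r = %.3f (n = %d genes)", r, nrow(df)),
                  side = 3, line = 0.5)
  invisible(df)
}
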