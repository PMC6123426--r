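#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: \eqn{q_{(i)} = \min_{j \ge i} (m/j) p_{(j)}}, capped at
#' 1, returned in the input order. NA/NaN p-values or values outside
#' `[0, 1]` are rejected.
#'
#' @param p numeric vector of p-values.
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p))) stop("p-values must be finite (no NA/NaN)", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Solve trigamma(y) = x by Newton iteration.
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) stop("trigamma_inverse needs x > 0", call. = FALSE)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Empirical-Bayes shrinkage of residual variances
#'
#' Assumes per-gene residual variances follow a scaled F distribution
#' \eqn{s_g^2 \sim s_0^2 F(d_g, d_0)} and estimates the hyperparameters
#' \eqn{(d_0, s_0^2)} by moment-matching the mean and variance of
#' \eqn{\log s_g^2} against the known moments of the log-F (digamma /
#' trigamma identities). Posterior variances are
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}.
#' When the moment estimator of the log-F excess variance is non-positive,
#' \eqn{d_0 = \infty} (full shrinkage). Genes with zero residual variance
#' are excluded from hyperparameter estimation and assigned
#' \eqn{\tilde s^2 = s_0^2}.
#'
#' @param s2 per-gene residual variances.
#' @param df per-gene residual degrees of freedom (recycled).
#' @param prior_df optional override of \eqn{d_0}: 0 gives the classical
#'   (unmoderated) variances, `Inf` full shrinkage; `NULL` (default)
#'   estimates it.
#' @return list with `var_post`, `var_prior`, `df_prior`.
#' @export
squeeze_var <- function(s2, df, prior_df = NULL) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (!any(ok)) stop("no positive residual variances", call. = FALSE)
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  if (is.null(prior_df)) {
    evar <- if (sum(ok) > 1) stats::var(e) - mean(trigamma(df[ok] / 2)) else -1
    if (!is.finite(evar) || evar <= 0) {
      df_prior <- Inf
    } else {
      df_prior <- 2 * trigamma_inverse(evar)
    }
  } else {
    df_prior <- prior_df
  }
  var_prior <- if (is.infinite(df_prior) || df_prior <= 0) {
    exp(emean)
  } else {
    exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  }
  var_post <- if (is.infinite(df_prior)) {
    rep(var_prior, length(s2))
  } else if (df_prior == 0) {
    s2
  } else {
    (df_prior * var_prior + df * s2) / (df_prior + df)
  }
  var_post[!ok] <- var_prior
  list(var_post = var_post, var_prior = var_prior, df_prior = df_prior)
}

#' Design specifications for the two contrasts
#'
#' `design_side()` builds the paired left/right design: one intercept per
#' individual plus a single side indicator (R = 1, L = 0); no further
#' covariates enter the side model. `design_age()` builds the unpaired
#' model: intercept, age (linear, in pcw) and sex, plus structure dummies
#' when more than one structure is present.
#'
#' @param sheet sample sheet (rows in the sample order of the matrix the
#'   design will be fitted to).
#' @return list of class `design_spec` with elements `X` (model matrix),
#'   `coef` (name of the tested coefficient), `type`, and for the side
#'   design the pairing indices `idx_L`, `idx_R` (one per individual).
#' @export
design_side <- function(sheet) {
  validate_sheet(sheet)
  individuals <- check_pairing(sheet)
  if (length(individuals) < 2) {
    stop("side contrast needs at least 2 paired individuals ",
         "(no residual degrees of freedom with ", length(individuals), ")",
         call. = FALSE)
  }
  X <- stats::model.matrix(~ 0 + factor(individual, levels = individuals) +
                             I(side == "R"), data = sheet)
  colnames(X) <- c(individuals, "sideR")
  idx_L <- match(paste0(individuals, ".L"), paste0(sheet$individual, ".", sheet$side))
  idx_R <- match(paste0(individuals, ".R"), paste0(sheet$individual, ".", sheet$side))
  structure(list(X = X, coef = "sideR", type = "side",
                 individuals = individuals, idx_L = idx_L, idx_R = idx_R),
            class = "design_spec")
}

#' @rdname design_side
#' @export
design_age <- function(sheet) {
  validate_sheet(sheet)
  if (length(unique(sheet$age_pcw)) < 3) {
    stop("age contrast needs at least 3 distinct ages", call. = FALSE)
  }
  if (length(unique(sheet$structure)) > 1) {
    X <- stats::model.matrix(~ age_pcw + factor(sex) + factor(structure),
                             data = sheet)
  } else {
    X <- stats::model.matrix(~ age_pcw + factor(sex), data = sheet)
  }
  structure(list(X = X, coef = "age_pcw", type = "age"),
            class = "design_spec")
}

#' Precision weights from the mean-variance trend
#'
#' Fits per-gene ordinary least squares on log2-CPM, lowess-smooths the
#' square-root residual standard deviations against mean log2 count, and
#' assigns each observation the weight `trend(fitted log2 count)^-4`,
#' with the trend evaluated at fitted values clamped to the observed
#' mean-count range. This is the classical precision-weighting scheme that
#' stops low-count genes (noisy on the log scale) from dominating the
#' linear-model fit.
#'
#' @param counts filtered count matrix.
#' @param design a `design_spec` (or bare model matrix).
#' @param span lowess span for the trend (default 0.5).
#' @param prior_count offset for the log2-CPM transform.
#' @return list with `E` (log2-CPM matrix), `weights` (positive finite
#'   matrix, same shape), and `trend` (the lowess curve).
#' @export
voom_weights <- function(counts, design, span = 0.5, prior_count = 0.5) {
  X <- if (inherits(design, "design_spec")) design$X else design
  validate_counts(counts)
  n <- ncol(counts)
  p <- qr(X)$rank
  if (p < ncol(X)) stop("design is not full rank", call. = FALSE)
  if (n - p <= 0) stop("no residual degrees of freedom", call. = FALSE)
  lib <- colSums(counts)
  E <- log2_cpm(counts, prior_count = prior_count)
  if (inherits(design, "design_spec") && design$type == "side") {
    # closed-form paired OLS: residuals are computed per physical sample so
    # a global L/R relabel leaves fitted values and weights bit-identical
    iL <- design$idx_L
    iR <- design$idx_R
    d <- E[, iR, drop = FALSE] - E[, iL, drop = FALSE]
    beta <- rowMeans(d)
    resid <- matrix(0, nrow(E), n, dimnames = dimnames(E))
    resid[, iL] <- (beta - d) / 2
    resid[, iR] <- (d - beta) / 2
    fitted_cpm <- E - resid
    sigma <- sqrt(rowSums(resid^2) / (n - p))
  } else {
    fit <- stats::lm.fit(X, t(E))
    fitted_cpm <- t(fit$fitted.values)      # G x n
    sigma <- sqrt(colSums(fit$residuals^2) / (n - p))
  }
  sy <- sqrt(sigma)
  sx <- rowMeans(E) + mean(log2(lib + 1)) - log2(1e6)  # mean log2 count
  l <- stats::lowess(sx, sy, f = span)
  fitted_count <- sweep(fitted_cpm, 2, log2(lib + 1) - log2(1e6), "+")
  fitted_count <- pmin(pmax(fitted_count, min(sx)), max(sx))
  trend_val <- stats::approx(l$x, l$y, xout = as.vector(fitted_count),
                             rule = 2, ties = "ordered")$y
  w <- matrix(pmax(trend_val, 1e-6)^(-4), nrow(counts), n,
              dimnames = dimnames(counts))
  list(E = E, weights = w, trend = l)
}

# Generic per-gene weighted least squares: one .lm.fit per gene.
fit_wls_generic <- function(E, W, X, coef) {
  G <- nrow(E)
  n <- ncol(E)
  p <- ncol(X)
  ci <- match(coef, colnames(X))
  if (is.na(ci)) stop("coefficient not in design: ", coef, call. = FALSE)
  beta <- s2 <- u <- numeric(G)
  for (g in seq_len(G)) {
    sw <- sqrt(W[g, ])
    Xs <- X * sw
    fit <- stats::.lm.fit(Xs, E[g, ] * sw)
    beta[g] <- fit$coefficients[ci]
    s2[g] <- sum(fit$residuals^2) / (n - p)
    R <- qr.R(structure(list(qr = fit$qr, rank = fit$rank,
                             qraux = fit$qraux, pivot = fit$pivot),
                        class = "qr"))
    # unscaled covariance from R'R = X'WX; guard pivoting
    XtWX_inv <- chol2inv(R)
    u[g] <- sqrt(XtWX_inv[which(fit$pivot == ci), which(fit$pivot == ci)])
  }
  list(beta = beta, s2 = s2, u = u, df = n - p)
}

# Closed-form weighted paired regression: for a design of individual
# intercepts plus a side indicator, profiling out the intercepts gives
# beta = sum(h d)/sum(h), RSS = sum(h (d - beta)^2) with d the per-pair R-L
# difference and h the pairwise harmonic weight. Algebraically identical to
# fit_wls_generic on the same design; vectorized across genes and exactly
# antisymmetric under a global L/R relabel.
fit_wls_paired <- function(E, W, idx_L, idx_R, coef_ignored = NULL) {
  d <- E[, idx_R, drop = FALSE] - E[, idx_L, drop = FALSE]
  wl <- W[, idx_L, drop = FALSE]
  wr <- W[, idx_R, drop = FALSE]
  h <- wl * wr / (wl + wr)
  sh <- rowSums(h)
  beta <- rowSums(h * d) / sh
  rss <- rowSums(h * (d - beta)^2)
  df <- length(idx_L) - 1L
  list(beta = beta, s2 = rss / df, u = 1 / sqrt(sh), df = df)
}

#' Moderated t-statistics from weighted least squares
#'
#' Per-gene weighted least squares on the supplied design, empirical-Bayes
#' variance shrinkage ([squeeze_var()]), moderated t
#' \eqn{\tilde t = \hat\beta / (\tilde s_g u_g)} with \eqn{u_g} the
#' unscaled standard-error factor, two-sided p from a t distribution with
#' \eqn{d_0 + d_g} degrees of freedom, and BH-FDR q-values.
#'
#' For the paired side design a closed-form paired-regression engine is
#' used (identical results, vectorized); set `engine = "generic"` to force
#' the per-gene least-squares path.
#'
#' @param expr log2-CPM matrix (`E` from [voom_weights()]).
#' @param weights observation weight matrix.
#' @param design a `design_spec`.
#' @param prior_df optional \eqn{d_0} override (see [squeeze_var()]).
#' @param engine `"auto"`, `"paired"` or `"generic"`.
#' @return data.frame (class `de_result`): gene_id, logFC, t, P.Value,
#'   adj.P.Val, df_residual, df_prior, df_total, s2_post.
#' @export
fit_moderated <- function(expr, weights, design, prior_df = NULL,
                          engine = c("auto", "paired", "generic")) {
  engine <- match.arg(engine)
  stopifnot(inherits(design, "design_spec"))
  if (engine == "auto") {
    engine <- if (design$type == "side") "paired" else "generic"
  }
  fit <- if (engine == "paired") {
    if (design$type != "side") stop("paired engine needs a side design", call. = FALSE)
    fit_wls_paired(expr, weights, design$idx_L, design$idx_R)
  } else {
    fit_wls_generic(expr, weights, design$X, design$coef)
  }
  if (fit$df <= 0) stop("no residual degrees of freedom", call. = FALSE)
  sq <- squeeze_var(fit$s2, fit$df, prior_df = prior_df)
  tstat <- fit$beta / (sqrt(sq$var_post) * fit$u)
  df_total <- sq$df_prior + fit$df
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(
    gene_id = rownames(expr),
    logFC = fit$beta,
    t = tstat,
    P.Value = pval,
    adj.P.Val = bh_fdr(pval),
    df_residual = fit$df,
    df_prior = sq$df_prior,
    df_total = df_total,
    s2_post = sq$var_post,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Paired left-right differential expression for one structure
#'
#' Runs [voom_weights()] and [fit_moderated()] on the paired side design.
#' Positive log-fold changes and t-values indicate higher expression on the
#' right side. Counts should already be filtered ([filter_expressed()]).
#'
#' @param counts filtered count matrix (samples of one structure).
#' @param sheet matching sample sheet; every individual must contribute
#'   exactly one L and one R sample (a hard error names any unpaired
#'   individual).
#' @param structure optional structure name to subset to.
#' @param prior_df,span,prior_count passed through.
#' @param engine fitting engine, see [fit_moderated()].
#' @return a `de_result` data.frame.
#' @export
side_contrast <- function(counts, sheet, structure = NULL, prior_df = NULL,
                          span = 0.5, prior_count = 0.5,
                          engine = c("auto", "paired", "generic")) {
  sub <- subset_structure(counts, sheet, structure)
  design <- design_side(sub$sheet)
  v <- voom_weights(sub$counts, design, span = span, prior_count = prior_count)
  fit_moderated(v$E, v$weights, design, prior_df = prior_df,
                engine = match.arg(engine))
}

#' Age (and sex) differential expression
#'
#' Unpaired model with a linear age effect and sex as a factor; structure is
#' added as a categorical factor automatically when samples from several
#' structures are pooled. Positive t-values indicate expression increasing
#' with age.
#'
#' @inheritParams side_contrast
#' @return a `de_result` data.frame for the age coefficient.
#' @export
age_contrast <- function(counts, sheet, structure = NULL, prior_df = NULL,
                         span = 0.5, prior_count = 0.5) {
  sub <- subset_structure(counts, sheet, structure)
  design <- design_age(sub$sheet)
  v <- voom_weights(sub$counts, design, span = span, prior_count = prior_count)
  fit_moderated(v$E, v$weights, design, prior_df = prior_df, engine = "generic")
}

subset_structure <- function(counts, sheet, structure = NULL) {
  validate_sheet(sheet)
  sheet <- sheet[match(colnames(counts), sheet$sample_id), , drop = FALSE]
  if (any(is.na(sheet$sample_id))) {
    stop("sample sheet does not cover all count columns", call. = FALSE)
  }
  if (!is.null(structure)) {
    keep <- sheet$structure == structure
    if (!any(keep)) stop("no samples for structure ", structure, call. = FALSE)
    counts <- counts[, keep, drop = FALSE]
    sheet <- sheet[keep, , drop = FALSE]
  }
  list(counts = counts, sheet = sheet)
}

#' Turn a DE result into a ranked list for enrichment
#'
#' Genes sorted by t-value, descending, ties broken lexicographically by
#' gene ID (stable, locale-independent).
#'
#' @param de a `de_result`.
#' @return named numeric vector of t-values, descending.
#' @export
ranked_scores <- function(de) {
  s <- stats::setNames(de$t, de$gene_id)
  as_ranked_list(s)
}

#' Write DE results / ranked lists to disk
#'
#' `write_de()` writes the standard TSV (gene_id, logFC, t, P.Value,
#' adj.P.Val, df); `write_rnk()` writes the two-column RNK file understood
#' by enrichment tools.
#'
#' @param de a `de_result`.
#' @param path output file.
#' @export
write_de <- function(de, path) {
  utils::write.table(
    de[, c("gene_id", "logFC", "t", "P.Value", "adj.P.Val", "df_residual")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de
#' @export
write_rnk <- function(de, path) {
  s <- if (is.data.frame(de)) ranked_scores(de) else as_ranked_list(de)
  utils::write.table(data.frame(gene_id = names(s), score = s),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
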