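#' Enumerate left/right sign-flip assignments
#'
#' All distinct ways of flipping, or leaving unflipped, the left and right
#' samples of each individual. Because flipping every individual merely
#' negates every side statistic, the first individual is fixed unflipped,
#' giving exactly \eqn{2^{n-1}} distinct assignments, enumerated in binary
#' counting order (row 1 is the identity). The similarity of an assignment
#' to the truth is \eqn{\max(k, n-k)/n} with \eqn{k} the number of
#' unflipped individuals, so a globally-flipped near-duplicate scores high.
#'
#' @param individuals character vector of individual IDs (n >= 2).
#' @param cap maximum n for exhaustive enumeration (default 20); beyond it,
#'   `n_monte_carlo` seeded random assignments must be requested explicitly.
#' @param n_monte_carlo,seed Monte-Carlo subsampling controls for n > cap.
#' @return logical matrix (assignments x individuals, TRUE = flipped) with a
#'   `similarity` attribute.
#' @export
enumerate_flips <- function(individuals, cap = 20, n_monte_carlo = NULL,
                            seed = NULL) {
  n <- length(individuals)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  if (n > cap) {
    if (is.null(n_monte_carlo)) {
      stop("n > ", cap, ": exhaustive enumeration disabled; ",
           "pass n_monte_carlo for seeded subsampling", call. = FALSE)
    }
    warning("Monte-Carlo subsampling of flip assignments (n > ", cap, ")")
    flips <- with_seed(seed, {
      m <- matrix(stats::runif(n_monte_carlo * (n - 1)) < 0.5,
                  n_monte_carlo, n - 1)
      cbind(FALSE, m)
    })
    flips[1, ] <- FALSE # keep the identity in the sample
  } else {
    m <- 2^(n - 1)
    flips <- matrix(FALSE, m, n)
    for (i in seq_len(n - 1)) {
      flips[, i + 1] <- bitwAnd(seq_len(m) - 1L, as.integer(2^(i - 1))) > 0
    }
  }
  colnames(flips) <- individuals
  k <- rowSums(!flips)
  attr(flips, "similarity") <- pmax(k, ncol(flips) - k) / ncol(flips)
  flips
}

#' Sign-flip permutation pipeline
#'
#' Re-runs the side differential expression, (optionally) the gene-set
#' enrichment FDR < `fdr_threshold` count, and the side-age correlation for
#' every left/right flip assignment, exactly as for the true labels. The age
#' contrast is flip-invariant and computed once (or supplied). Empirical
#' p-values use the add-one estimator
#' \eqn{p = (1 + \#\{perm \ge obs\}) / (1 + \#perm)} over the non-identity
#' assignments, so p is never 0.
#'
#' @param counts filtered count matrix for one structure.
#' @param sheet matching sample sheet (paired individuals).
#' @param sets optional gene-set collection; when supplied, GSEA is run per
#'   assignment and sets with FDR < `fdr_threshold` are counted.
#' @param age_de optional precomputed age `de_result` (may come from other
#'   samples); computed from `counts`/`sheet` when NULL.
#' @param flips optional assignment matrix from [enumerate_flips()].
#' @param n_perm_gsea GSEA permutations per assignment (default 200, kept
#'   small because GSEA runs once per assignment).
#' @param fdr_threshold GSEA FDR threshold for the set count (default 0.25).
#' @param min_size,max_size GSEA size window.
#' @param seed RNG seed (GSEA nulls and any Monte-Carlo flips).
#' @return list of class `permutation_summary`: `table` (per-assignment
#'   similarity, r, n_sets_fdr), `observed` (true-data row), `p_abs_r`,
#'   `p_set_count`, and `age_de`.
#' @export
flip_pipeline <- function(counts, sheet, sets = NULL, age_de = NULL,
                          flips = NULL, n_perm_gsea = 200,
                          fdr_threshold = 0.25, min_size = 15, max_size = 500,
                          seed = NULL) {
  sub <- subset_structure(counts, sheet)
  sheet <- sub$sheet
  individuals <- check_pairing(sheet)
  if (is.null(flips)) flips <- enumerate_flips(individuals, seed = seed)
  if (is.null(age_de)) age_de <- age_contrast(counts, sheet)
  sim <- attr(flips, "similarity")

  n_assign <- nrow(flips)
  r <- numeric(n_assign)
  n_sets_fdr <- rep(NA_real_, n_assign)
  for (a in seq_len(n_assign)) {
    fl <- stats::setNames(flips[a, ], colnames(flips))
    sh <- sheet
    flipped <- fl[sh$individual]
    sh$side <- ifelse(flipped, c(L = "R", R = "L")[sh$side], sh$side)
    de <- side_contrast(counts, sh)
    r[a] <- side_age_correlation(de, age_de)$r
    if (!is.null(sets)) {
      g <- gsea_preranked(ranked_scores(de), sets, n_perm = n_perm_gsea,
                          min_size = min_size, max_size = max_size,
                          seed = if (is.null(seed)) NULL else derive_seed(seed, a))
      n_sets_fdr[a] <- sum(g$FDR < fdr_threshold, na.rm = TRUE)
    }
  }
  tab <- data.frame(assignment = seq_len(n_assign), similarity = sim,
                    r = r, n_sets_fdr = n_sets_fdr)
  obs <- tab[1, ]
  perm <- tab[-1, , drop = FALSE]
  p_abs_r <- (1 + sum(abs(perm$r) >= abs(obs$r))) / (1 + nrow(perm))
  p_set_count <- if (is.null(sets)) NA_real_ else {
    (1 + sum(perm$n_sets_fdr >= obs$n_sets_fdr)) / (1 + nrow(perm))
  }
  out <- list(table = tab, observed = obs, p_abs_r = p_abs_r,
              p_set_count = p_set_count, age_de = age_de,
              fdr_threshold = fdr_threshold)
  class(out) <- "permutation_summary"
  out
}

#' t-value randomization null for gene-set enrichment
#'
#' Randomly reassigns the observed differential-expression t-values to the
#' expressed genes (breaking any gene-set coherence while keeping the score
#' distribution), reruns preranked GSEA each time, and counts gene sets with
#' FDR below `fdr_threshold`. A true-data count that dwarfs the randomized
#' counts indicates that whole functional programs, not scattered genes, are
#' lateralized. The ratio is reported raw and with add-one smoothing
#' `(obs + 1) / (mean null + 1)` (defined even when no null set passes).
#'
#' @param side_de a `de_result` (or named score vector).
#' @param sets gene-set collection.
#' @param n_reps number of randomizations (default 10).
#' @param n_perm,min_size,max_size,fdr_threshold GSEA controls.
#' @param seed RNG seed.
#' @return list: `observed` count, `null_counts` (length `n_reps`), `ratio`
#'   (raw), `ratio_smoothed`.
#' @export
tvalue_randomization <- function(side_de, sets, n_reps = 10, n_perm = 1000,
                                 min_size = 15, max_size = 500,
                                 fdr_threshold = 0.25, seed = NULL) {
  stop_if_not_scalar(n_reps, "n_reps", integerish = TRUE, min = 1)
  scores <- if (is.data.frame(side_de)) ranked_scores(side_de) else as_ranked_list(side_de)
  count_fdr <- function(s, sd) {
    g <- gsea_preranked(s, sets, n_perm = n_perm, min_size = min_size,
                        max_size = max_size, seed = sd)
    sum(g$FDR < fdr_threshold, na.rm = TRUE)
  }
  observed <- count_fdr(scores, if (is.null(seed)) NULL else derive_seed(seed, 0L))
  null_counts <- vapply(seq_len(n_reps), function(i) {
    shuffled <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, i),
                          stats::setNames(scores, sample(names(scores))))
    count_fdr(shuffled, if (is.null(seed)) NULL else derive_seed(seed, 10000L + i))
  }, numeric(1))
  list(observed = observed, null_counts = null_counts,
       ratio = observed / mean(null_counts),
       ratio_smoothed = (observed + 1) / (mean(null_counts) + 1))
}
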