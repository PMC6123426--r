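#' Coerce scores to a ranked list
#'
#' Sorts a named score vector descending; ties are broken lexicographically
#' by gene ID (radix sort, locale-independent) so ranking is
#' bit-reproducible. Duplicate gene names and non-finite scores are
#' rejected.
#'
#' @param scores named numeric vector.
#' @return named numeric vector, descending.
#' @export
as_ranked_list <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stop("scores must carry unique gene names", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  scores[order(-scores, names(scores), method = "radix")]
}

# NES normalization: each (observed or null) ES is divided by the mean |null
# ES| of its own sign for its own set, so NES is invariant to duplicating
# every null permutation.
gsea_normalize <- function(es_obs, null_es) {
  ns <- length(es_obs)
  mean_pos <- vapply(seq_len(ns), function(j) {
    v <- null_es[, j][null_es[, j] > 0]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  mean_neg <- vapply(seq_len(ns), function(j) {
    v <- null_es[, j][null_es[, j] < 0]
    if (length(v)) mean(abs(v)) else NA_real_
  }, numeric(1))
  nes_obs <- ifelse(es_obs >= 0, es_obs / mean_pos, es_obs / mean_neg)
  null_nes <- null_es
  for (j in seq_len(ns)) {
    pos <- null_es[, j] > 0
    null_nes[pos, j] <- null_es[pos, j] / mean_pos[j]
    null_nes[!pos, j] <- null_es[!pos, j] / mean_neg[j]
  }
  list(nes_obs = nes_obs, null_nes = null_nes,
       mean_pos = mean_pos, mean_neg = mean_neg)
}

# ES from hit positions only. The running sum changes slope only at hits, so
# the signed maximal deviation is attained either right after a hit (upper
# candidates) or just before one (lower candidates). O(k) per set.
# `wfull` = |score|^p over the whole list. Ties between the positive and
# negative extremum (within 1e-9, so that paths with different rounding
# agree) resolve positive.
ES_TIE_TOL <- 1e-9

es_from_positions <- function(pos, wfull, N) {
  pos <- sort.int(pos)
  k <- length(pos)
  w <- wfull[pos]
  D <- sum(w)
  if (D == 0) stop("all member scores are zero: hit normalization undefined",
                   call. = FALSE)
  denom <- max(N - k, 1L)
  H <- cumsum(w) / D
  miss <- (pos - seq_len(k)) / denom
  upper <- H - miss
  lower <- upper - w / D
  maxR <- max(upper)
  minB <- min(lower)
  if (maxR >= -minB - ES_TIE_TOL) {
    j <- which.max(upper)
    list(es = maxR, extremum = pos[j], hit_rank = j, positive = TRUE, pos = pos)
  } else {
    j <- which.min(lower)
    list(es = minB, extremum = pos[j], hit_rank = j, positive = FALSE, pos = pos)
  }
}

#' Running-sum enrichment score
#'
#' Walks the ranked list; each set member ("hit") increments the running sum
#' by \eqn{|s_i|^p / \sum_{hits} |s|^p}, each miss decrements it by
#' \eqn{1/(N - N_H)}. The enrichment score is the running-sum value of
#' maximal absolute deviation from zero (signed; a tie between the positive
#' and negative extremum, judged with a 1e-9 tolerance, resolves to the
#' positive one). The leading edge contains
#' the set members at or before the extremum (at or after it, for negative
#' ES).
#'
#' @param ranked named numeric scores; re-sorted via [as_ranked_list()].
#' @param gene_set character vector of member gene IDs; must intersect the
#'   ranked list.
#' @param weight_p score weighting exponent \eqn{p} (default 1; 0 gives the
#'   rank-only Kolmogorov-Smirnov-style statistic).
#' @return list with `es`, `running_sum` (length N), `leading_edge`,
#'   `size` (detected members).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  ranked <- as_ranked_list(ranked)
  N <- length(ranked)
  pos <- which(names(ranked) %in% gene_set)
  if (length(pos) == 0) stop("gene set has no members in the ranked list",
                             call. = FALSE)
  wfull <- abs(ranked)^weight_p
  hit <- es_from_positions(pos, wfull, N)
  k <- length(pos)
  incr <- rep(-1 / max(N - k, 1L), N)
  if (N == k) incr[] <- 0
  incr[pos] <- wfull[pos] / sum(wfull[pos])
  running <- cumsum(incr)
  le <- if (hit$positive) {
    names(ranked)[pos[pos <= hit$extremum]]
  } else {
    names(ranked)[pos[pos >= hit$extremum]]
  }
  list(es = hit$es, running_sum = running, leading_edge = le, size = k)
}

#' Preranked weighted gene-set enrichment
#'
#' For every gene set detected within the size window, computes the weighted
#' running-sum enrichment score on the ranked list, a gene-set permutation
#' null (`n_perm` random same-size draws of positions from the list), the
#' normalized enrichment score NES = ES / mean(|null ES| of matching sign),
#' a nominal p (fraction of same-sign null ES at least as extreme), a
#' family-wise error rate (fraction of permutations whose most extreme
#' same-sign normalized null ES across all sets beats the observed NES), and
#' an FDR q estimated as the ratio of the pooled-null and observed tail
#' fractions at the set's NES, within sign class, clipped to `[0, 1]`.
#' Deterministic under a fixed seed.
#'
#' @param ranked named numeric scores (re-sorted internally).
#' @param sets named list of character vectors (e.g. from [read_gmt()] or
#'   [simulate_gene_sets()]).
#' @param n_perm number of null draws per set (>= 1, default 1000).
#' @param min_size,max_size detected-size window (defaults 15 and 500).
#' @param weight_p score weighting exponent (default 1).
#' @param seed optional RNG seed.
#' @return data.frame (class `gsea_result`): set, size, ES, NES, p_nominal,
#'   FWER, FDR, leading_edge (comma-separated); attribute `filtered` lists
#'   the sets removed by the size window. Empty (with a warning) when no set
#'   survives the filter.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, min_size = 15,
                           max_size = 500, weight_p = 1, seed = NULL) {
  stop_if_not_scalar(n_perm, "n_perm", integerish = TRUE, min = 1)
  ranked <- as_ranked_list(ranked)
  N <- length(ranked)
  wfull <- abs(ranked)^weight_p
  sizes <- vapply(sets, function(s) sum(names(ranked) %in% s), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  filtered <- names(sets)[!keep]
  if (!any(keep)) {
    warning("no gene sets within the size window")
    out <- data.frame(set = character(0), size = integer(0), ES = numeric(0),
                      NES = numeric(0), p_nominal = numeric(0),
                      FWER = numeric(0), FDR = numeric(0),
                      leading_edge = character(0), stringsAsFactors = FALSE)
    attr(out, "filtered") <- filtered
    class(out) <- c("gsea_result", "data.frame")
    return(out)
  }
  sets <- sets[keep]
  sizes <- sizes[keep]
  ns <- length(sets)

  obs <- lapply(sets, function(s) {
    es_from_positions(which(names(ranked) %in% s), wfull, N)
  })
  es_obs <- vapply(obs, `[[`, numeric(1), "es")

  null_es <- with_seed(seed, {
    m <- matrix(0, n_perm, ns)
    for (j in seq_len(ns)) {
      k <- sizes[j]
      for (t in seq_len(n_perm)) {
        m[t, j] <- es_from_positions(sample.int(N, k), wfull, N)$es
      }
    }
    m
  })

  norm <- gsea_normalize(es_obs, null_es)
  nes_obs <- norm$nes_obs
  null_nes <- norm$null_nes

  p_nom <- vapply(seq_len(ns), function(j) {
    v <- null_es[, j]
    if (es_obs[j] >= 0) {
      np <- sum(v > 0)
      if (np == 0) return(0)
      sum(v >= es_obs[j]) / np
    } else {
      nn <- sum(v < 0)
      if (nn == 0) return(0)
      sum(v <= es_obs[j]) / nn
    }
  }, numeric(1))

  max_pos <- apply(null_nes, 1, function(r) {
    v <- r[is.finite(r) & r > 0]
    if (length(v)) max(v) else -Inf
  })
  min_neg <- apply(null_nes, 1, function(r) {
    v <- r[is.finite(r) & r < 0]
    if (length(v)) min(v) else Inf
  })
  fwer <- ifelse(es_obs >= 0,
                 colMeans(outer(max_pos, nes_obs, ">=")),
                 colMeans(outer(min_neg, nes_obs, "<=")))

  pool <- as.vector(null_nes)
  pool <- pool[is.finite(pool)]
  pool_pos <- pool[pool >= 0]
  pool_neg <- pool[pool < 0]
  obs_pos <- nes_obs[nes_obs >= 0 & is.finite(nes_obs)]
  obs_neg <- nes_obs[nes_obs < 0 & is.finite(nes_obs)]
  fdr <- vapply(seq_len(ns), function(j) {
    s <- nes_obs[j]
    if (!is.finite(s)) return(NA_real_)
    if (s >= 0) {
      num <- if (length(pool_pos)) mean(pool_pos >= s) else 0
      den <- mean(obs_pos >= s)
    } else {
      num <- if (length(pool_neg)) mean(pool_neg <= s) else 0
      den <- mean(obs_neg <= s)
    }
    min(1, num / den)
  }, numeric(1))

  le <- vapply(obs, function(o) {
    idx <- if (o$positive) o$pos[o$pos <= o$extremum] else o$pos[o$pos >= o$extremum]
    paste(names(ranked)[idx], collapse = ",")
  }, character(1))

  out <- data.frame(set = names(sets), size = sizes, ES = es_obs,
                    NES = nes_obs, p_nominal = p_nom, FWER = fwer, FDR = fdr,
                    leading_edge = le, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "filtered") <- filtered
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Read / write GMT gene-set files
#'
#' GMT: one set per line, tab-separated: name, description, member gene IDs.
#' Duplicate genes within a set are deduplicated; duplicate set names are an
#' error; an empty file yields an empty collection.
#'
#' @param path file path.
#' @return named list of character vectors with a `description` attribute
#'   (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- stats::setNames(list(), character(0))
    attr(out, "description") <- character(0)
    class(out) <- "gene_set_collection"
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) stop("duplicate set names in GMT", call. = FALSE)
  desc <- vapply(parts, function(x) if (length(x) >= 2) x[2] else "", character(1))
  out <- lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  names(out) <- nm
  attr(out, "description") <- stats::setNames(desc, nm)
  class(out) <- "gene_set_collection"
  out
}

#' @rdname read_gmt
#' @param sets a named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write RNK ranked-list files
#'
#' Two tab-separated columns (gene ID, numeric score), no header. On read,
#' the list is re-sorted descending with lexicographic tie-break; an empty
#' file yields an empty list; non-numeric scores are an error.
#'
#' @param path file path.
#' @return named numeric vector, descending.
#' @export
read_rnk <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(parts, `[[`, character(1), 1)
  sc <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  if (any(is.na(sc))) stop("non-numeric scores in RNK file", call. = FALSE)
  as_ranked_list(stats::setNames(sc, genes))
}
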