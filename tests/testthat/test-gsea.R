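ranked_fx <- function(n = 20, seed = 1) {
  set.seed(seed)
  as_ranked_list(stats::setNames(rnorm(n), sprintf("g%03d", seq_len(n))))
}

test_that("ranked-list coercion sorts descending with lexicographic ties", {
  s <- c(B = 1.0, A = 1.0, C = 2.0)
  r <- as_ranked_list(s)
  expect_identical(names(r), c("C", "A", "B"))
  expect_error(as_ranked_list(c(1, 2)), "names")
  expect_error(as_ranked_list(c(A = 1, A = 2)), "unique")
  expect_error(as_ranked_list(c(A = 1, B = NA)), "finite")
})

test_that("enrichment score behaves at the construction extremes", {
  r <- ranked_fx()
  # top-k set with positive scores: ES > 0, extremum at position k
  rpos <- as_ranked_list(stats::setNames(seq(3, 0.1, length.out = 20),
                                         sprintf("g%03d", 1:20)))
  k <- 5
  es <- enrichment_score(rpos, names(rpos)[1:k])
  expect_gt(es$es, 0)
  expect_equal(which.max(es$running_sum), k)
  expect_identical(es$leading_edge, names(rpos)[1:k])
  # whole-list set: no misses, running sum climbs to 1
  es_all <- enrichment_score(rpos, names(rpos))
  expect_equal(es_all$es, 1)
  # reversing order and negating scores negates ES
  r2 <- as_ranked_list(stats::setNames(-unname(r), names(r)))
  set <- names(r)[c(2, 5, 9)]
  expect_equal(enrichment_score(r2, set)$es, -enrichment_score(r, set)$es,
               tolerance = 1e-12)
  # all member scores zero with p > 0 is an error
  rz <- as_ranked_list(stats::setNames(c(2, 1, 0, 0, -1), LETTERS[1:5]))
  expect_error(enrichment_score(rz, c("C", "D")), "zero")
  # no members present
  expect_error(enrichment_score(r, c("nope")), "no members")
})

test_that("ES equals the brute-force oracle and stays within [-1, 1]", {
  set.seed(42)
  for (N in c(5, 9, 12)) {
    sc <- as_ranked_list(stats::setNames(rnorm(N), sprintf("g%02d", 1:N)))
    for (rep in 1:60) {
      k <- sample(seq_len(N - 1), 1)
      set <- sample(names(sc), k)
      e_impl <- enrichment_score(sc, set)$es
      e_fast <- lateralyzer:::es_from_positions(
        which(names(sc) %in% set), abs(sc)^1, N)$es
      e_orc <- es_oracle(sc, set)
      expect_equal(e_impl, e_orc, tolerance = 1e-12)
      expect_equal(e_fast, e_orc, tolerance = 1e-12)
      expect_gte(e_impl, -1)
      expect_lte(e_impl, 1)
    }
  }
})

test_that("p = 0 reduces to a rank-only statistic", {
  r <- ranked_fx(30, seed = 3)
  set <- names(r)[c(1, 4, 9, 22)]
  e1 <- enrichment_score(r, set, weight_p = 0)$es
  # magnitudes are irrelevant at p = 0
  r2 <- as_ranked_list(stats::setNames(unname(r) * 17, names(r)))
  expect_equal(enrichment_score(r2, set, weight_p = 0)$es, e1,
               tolerance = 1e-12)
  # rank-only oracle: hit increment 1/Nh, miss 1/(N - Nh)
  ks_oracle <- function(scores, set) {
    N <- length(scores)
    hits <- names(scores) %in% set
    run <- cumsum(ifelse(hits, 1 / sum(hits), -1 / (N - sum(hits))))
    mx <- max(run); mn <- min(run)
    if (mx >= -mn - 1e-9) mx else mn
  }
  expect_equal(e1, ks_oracle(r, set), tolerance = 1e-12)
})

test_that("preranked GSEA filters, ranks and normalizes correctly", {
  r <- ranked_fx(200, seed = 5)
  sets <- list(SMALL = names(r)[1:10],           # below min_size
               BIG = names(r)[1:40],
               RAND = sample(names(r), 25))
  res <- gsea_preranked(r, sets, n_perm = 200, min_size = 15, max_size = 500,
                        seed = 7)
  expect_identical(attr(res, "filtered"), "SMALL")
  expect_setequal(res$set, c("BIG", "RAND"))
  expect_true(all(sign(res$NES) == sign(res$ES)))
  # determinism
  res2 <- gsea_preranked(r, sets, n_perm = 200, min_size = 15, max_size = 500,
                         seed = 7)
  expect_identical(res, res2)
  # no sets survive: empty result with warning
  expect_warning(out <- gsea_preranked(r, sets["SMALL"], n_perm = 10),
                 "size window")
  expect_equal(nrow(out), 0)
})

test_that("an extreme front-loaded set gets FWER 0 and FDR 0", {
  sc <- as_ranked_list(stats::setNames(seq(5, 0.1, length.out = 20) +
                                         rnorm(20, 0, 0.01),
                                       sprintf("g%02d", 1:20)))
  res <- gsea_preranked(sc, list(TOP = names(sc)[1:6]), n_perm = 1000,
                        min_size = 2, max_size = 50, seed = 5)
  expect_equal(res$FWER, 0)
  expect_equal(res$p_nominal, 0)
  expect_gte(res$FWER, res$p_nominal) # FWER >= nominal p
})

test_that("nominal p is calibrated for random sets on exchangeable scores", {
  set.seed(7)
  sc <- ranked_fx(100, seed = 7)
  ps <- vapply(1:200, function(i) {
    gsea_preranked(sc, list(S = sample(names(sc), 10)), n_perm = 200,
                   min_size = 2, max_size = 50, seed = 1000 + i)$p_nominal
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("NES is invariant to duplicating every null permutation", {
  set.seed(11)
  es_obs <- c(0.4, -0.3)
  null_es <- matrix(rnorm(200, 0, 0.2), 100, 2)
  n1 <- lateralyzer:::gsea_normalize(es_obs, null_es)
  n2 <- lateralyzer:::gsea_normalize(es_obs, rbind(null_es, null_es))
  expect_equal(n1$nes_obs, n2$nes_obs, tolerance = 1e-12)
})

test_that("GMT and RNK I/O honor their dialects", {
  tmp <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB\tA", "S2\tother\tC\tD"), tmp)
  g <- read_gmt(tmp)
  expect_identical(g$S1, c("A", "B")) # dedup
  expect_identical(attr(g, "description")[["S2"]], "other")
  writeLines(c("S1\td\tA", "S1\td\tB"), tmp)
  expect_error(read_gmt(tmp), "duplicate")
  writeLines(character(0), tmp)
  expect_length(read_gmt(tmp), 0) # empty file is fine
  # roundtrip
  sets <- list(X = c("A", "B"), Y = c("C"))
  write_gmt(sets, tmp)
  expect_equal(unclass(read_gmt(tmp))[c("X", "Y")], sets, ignore_attr = TRUE)

  rnk <- tempfile(fileext = ".rnk")
  writeLines(c("B\t1.0", "A\t1.0", "C\t3"), rnk)
  r <- read_rnk(rnk)
  expect_identical(names(r), c("C", "A", "B")) # lexicographic tie-break
  writeLines(c("A\tx"), rnk)
  expect_error(read_rnk(rnk), "non-numeric")
  writeLines(character(0), rnk)
  expect_length(read_rnk(rnk), 0)
})
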