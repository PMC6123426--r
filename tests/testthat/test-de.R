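test_that("BH step-up matches hand computation and the literal oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)                 # single p
  expect_equal(bh_fdr(rep(0.4, 5)), rep(0.4, 5)) # all equal
  expect_error(bh_fdr(c(0.1, NaN)), "finite")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  set.seed(1)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("variance shrinkage recovers hyperparameters on scaled-F draws", {
  set.seed(4)
  d0 <- 8
  s02 <- 2
  dg <- 5
  s2 <- s02 * rf(20000, dg, d0)
  sq <- squeeze_var(s2, dg)
  expect_equal(sq$df_prior, d0, tolerance = 0.3)
  expect_equal(sq$var_prior, s02, tolerance = 0.1)
  # overrides
  expect_identical(squeeze_var(s2, dg, prior_df = 0)$var_post, s2)
  expect_equal(length(unique(squeeze_var(s2, dg, prior_df = Inf)$var_post)), 1L)
  # zero-variance genes excluded but assigned the prior
  s2z <- c(0, s2[1:50])
  sqz <- squeeze_var(s2z, dg)
  expect_equal(sqz$var_post[1], sqz$var_prior)
})

paired_fixture <- function(n_ind = 6, n_genes = 120, seed = 1, delta = 0.3) {
  cfg <- sim_config(n_individuals = n_ind, n_genes = max(n_genes, 10),
                    asynchrony_delta = delta, seed = seed,
                    n_sets = 5, set_size_range = c(5, 10))
  sim <- simulate_dataset(cfg)
  counts <- filter_expressed(sim$counts, 1, 2)
  list(sim = sim, counts = counts, sheet = sim$sheet)
}

test_that("voom weights are positive, finite and relabeling-invariant", {
  fx <- paired_fixture()
  des <- design_side(fx$sheet)
  v <- voom_weights(fx$counts, des)
  expect_true(all(is.finite(v$weights)) && all(v$weights > 0))
  # permuting sample order with a permuted design gives identical
  # per-observation weights
  perm <- sample(ncol(fx$counts))
  sheet_p <- fx$sheet[perm, ]
  des_p <- design_side(sheet_p)
  v_p <- voom_weights(fx$counts[, perm], des_p)
  expect_equal(v_p$weights[, colnames(v$weights)], v$weights,
               tolerance = 1e-12)
  # low-count genes sit higher on the trend and get lower weights on average
  mean_cnt <- rowMeans(fx$counts)
  low <- mean_cnt <= quantile(mean_cnt, 0.2)
  high <- mean_cnt >= quantile(mean_cnt, 0.8)
  expect_lt(mean(v$weights[low, ]), mean(v$weights[high, ]))
})

test_that("flat mean-variance structure gives near-equal weights", {
  set.seed(8)
  cts <- matrix(rpois(100 * 8, 200), 100, 8)
  rownames(cts) <- sprintf("g%03d", 1:100)
  colnames(cts) <- sprintf("s%d", 1:8)
  sheet <- data.frame(sample_id = colnames(cts),
                      individual = rep(sprintf("i%d", 1:4), each = 2),
                      side = rep(c("L", "R"), 4), structure = "b",
                      age_pcw = rep(8:11, each = 2),
                      sex = rep(c("M", "F"), 4))
  storage.mode(cts) <- "integer"
  v <- voom_weights(cts, design_side(sheet))
  # trend is flat up to lowess sampling noise: weights within a tight band
  expect_lt(diff(range(v$weights)) / mean(v$weights), 1)
})

test_that("moderated t with d0 = 0 equals the classical weighted paired t", {
  fx <- paired_fixture(n_genes = 60)
  des <- design_side(fx$sheet)
  v <- voom_weights(fx$counts, des)
  f0 <- fit_moderated(v$E, v$weights, des, prior_df = 0)
  sheet_o <- fx$sheet[match(colnames(fx$counts), fx$sheet$sample_id), ]
  for (g in seq(1, nrow(v$E), by = 7)) {
    t_oracle <- weighted_paired_t_oracle(v$E[g, ], v$weights[g, ], sheet_o)
    expect_equal(f0$t[g], t_oracle, tolerance = 1e-10)
  }
  # d0 -> Inf: constant posterior variance
  fI <- fit_moderated(v$E, v$weights, des, prior_df = Inf)
  expect_equal(length(unique(fI$s2_post)), 1L)
})

test_that("paired and generic engines agree", {
  fx <- paired_fixture(seed = 5)
  d1 <- side_contrast(fx$counts, fx$sheet, engine = "paired")
  d2 <- side_contrast(fx$counts, fx$sheet, engine = "generic")
  expect_equal(d1$t, d2$t, tolerance = 1e-10)
  expect_equal(d1$logFC, d2$logFC, tolerance = 1e-10)
})

test_that("moderated p-values are calibrated on null genes", {
  # DERIVED Monte-Carlo calibration: gaussian data, no side effect
  set.seed(123)
  n_ind <- 8
  G <- 500
  E <- matrix(rnorm(G * 2 * n_ind, mean = 5), G, 2 * n_ind)
  rownames(E) <- sprintf("g%03d", 1:G)
  colnames(E) <- sprintf("s%02d", 1:(2 * n_ind))
  sheet <- data.frame(sample_id = colnames(E),
                      individual = rep(sprintf("i%d", 1:n_ind), each = 2),
                      side = rep(c("L", "R"), n_ind), structure = "b",
                      age_pcw = rep(seq(8, 12, length.out = n_ind), each = 2),
                      sex = rep(c("M", "F"), n_ind))
  des <- design_side(sheet)
  W <- matrix(1, G, 2 * n_ind)
  f <- fit_moderated(E, W, des)
  frac <- mean(f$P.Value <= 0.05)
  ci <- qbinom(c(0.025, 0.975), G, 0.05) / G
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("side contrast obeys its sign conventions and pairing contract", {
  fx <- paired_fixture(seed = 6)
  de <- side_contrast(fx$counts, fx$sheet)
  expect_true(all(sign(de$t) == sign(de$logFC)))
  expect_true(all(de$adj.P.Val >= de$P.Value - 1e-12))
  # BH monotone in p
  o <- order(de$P.Value)
  expect_true(all(diff(de$adj.P.Val[o]) >= -1e-12))
  # global L/R swap negates t bit-exactly
  sheet_sw <- fx$sheet
  sheet_sw$side <- ifelse(sheet_sw$side == "L", "R", "L")
  de_sw <- side_contrast(fx$counts, sheet_sw)
  expect_identical(de$t, -de_sw$t)
  # unpaired individual is a named hard error
  sheet_bad <- fx$sheet[-2, ]
  expect_error(side_contrast(fx$counts[, -2], sheet_bad), "ind01")
})

test_that("age contrast recovers a strong planted slope", {
  # one gene with slope +1 log2/week, n = 12 individuals, phi = 0.05
  set.seed(21)
  n_ind <- 12
  ages <- seq(7, 13, length.out = n_ind)
  G <- 150
  mu <- matrix(2^8, G, 2 * n_ind)
  # modest baseline so the planted gene never dominates the library
  mu[1, ] <- 2^(-2 + rep(ages, each = 2)) # a = +1
  cts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.05), G, 2 * n_ind)
  rownames(cts) <- sprintf("g%03d", 1:G)
  colnames(cts) <- sprintf("s%02d", 1:(2 * n_ind))
  storage.mode(cts) <- "integer"
  sheet <- data.frame(sample_id = colnames(cts),
                      individual = rep(sprintf("i%02d", 1:n_ind), each = 2),
                      side = rep(c("L", "R"), n_ind), structure = "b",
                      age_pcw = rep(ages, each = 2),
                      sex = rep(c("M", "F"), n_ind))
  de <- age_contrast(cts, sheet)
  expect_gt(de$t[1], 0)
  expect_lt(de$adj.P.Val[1], 0.05)
  expect_equal(de$logFC[1], 1, tolerance = 0.25)
  expect_error(age_contrast(cts, transform(sheet, age_pcw = rep(c(8, 9), n_ind))),
               "distinct ages")
})

test_that("side effect size tracks the injected asynchrony", {
  # regression of side logFC on the age slope recovers Delta within 20%;
  # a single dataset has slope s.e. ~0.09, so average over 10 seeds
  slopes <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = s) # Delta = 0.25
    sim <- simulate_dataset(cfg)
    cts <- filter_expressed(sim$counts)
    de <- side_contrast(cts, sim$sheet)
    a <- sim$truth$a[match(de$gene_id, sim$truth$gene_ids)]
    unname(coef(lm(de$logFC ~ a))[2])
  }, numeric(1))
  expect_equal(mean(slopes), 0.25, tolerance = 0.2)
})

test_that("our moderated pipeline tracks the reference implementation", {
  fx <- paired_fixture(seed = 9, n_ind = 5)
  de <- side_contrast(fx$counts, fx$sheet)
  des <- design_side(fx$sheet[match(colnames(fx$counts), fx$sheet$sample_id), ])
  v <- limma::voom(fx$counts, des$X)
  fit <- limma::eBayes(limma::lmFit(v, des$X))
  tt <- limma::topTable(fit, coef = "sideR", number = Inf, sort.by = "none")
  expect_gt(cor(de$t, tt$t), 0.999)
  expect_equal(de$logFC, tt$logFC, tolerance = 0.05)
})

test_that("DE results round-trip as TSV and RNK", {
  fx <- paired_fixture(seed = 2, n_genes = 40)
  de <- side_contrast(fx$counts, fx$sheet)
  tmp <- tempfile(fileext = ".tsv")
  write_de(de, tmp)
  back <- read.delim(tmp)
  expect_equal(back$t, de$t, tolerance = 1e-6)
  rnk <- tempfile(fileext = ".rnk")
  write_rnk(de, rnk)
  r <- read_rnk(rnk)
  expect_equal(unname(r), unname(sort(de$t, decreasing = TRUE)),
               tolerance = 1e-6)
})
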