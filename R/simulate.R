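#' Simulation configuration for paired left/right RNA-seq data
#'
#' Builds the configuration object consumed by [simulate_dataset()] and
#' [simulate_gene_sets()]. Defaults echo the scale of a paired embryonic
#' brain study: a handful of individuals each contributing one left and one
#' right sample of a structure, ages spanning mid-gestation in
#' post-conception weeks (pcw), negative-binomial counts, and a
#' side-specific maturation offset.
#'
#' The expression model for gene \eqn{g}, individual \eqn{i}, side
#' \eqn{s \in \{-1, +1\}} (L/R) is
#' \deqn{q_{gis} = 2^{\mu_g + a_g (T_i + s\Delta/2) + \epsilon_{gs}}}
#' with counts drawn NB(mean = libsize * q / column total, dispersion
#' \eqn{\phi}) so that variance = m + \eqn{\phi} m^2 (\eqn{\phi = 0} is
#' Poisson). \eqn{\Delta} (`asynchrony_delta`) is the number of weeks by
#' which the right side leads the left along the shared age trajectory
#' (negative values mean the left side leads); it is injected symmetrically
#' (+/- \eqn{\Delta}/2 per side) so the individual's nominal age stays the
#' midpoint and age-effect estimation is unbiased. \eqn{\epsilon_{gs}} is an
#' age-independent side effect with sd `side_noise_sd`, shared across
#' individuals (consistent laterality).
#'
#' Three reserved marker genes `XIST`, `EIF1AY` and `KDM5D` get
#' sex-determined expression (XIST high in females, the Y genes absent in
#' females) and carry no age or side effects.
#'
#' @param n_individuals number of embryos/foetuses; each contributes one L
#'   and one R sample. Must be >= 2.
#' @param n_genes number of genes including the three sex markers (>= 10).
#' @param age_range length-2 numeric, ages in pcw; individuals are evenly
#'   spaced over it. Must span a positive width.
#' @param frac_age_genes fraction in `[0,1]` of genes given a nonzero age
#'   slope.
#' @param slope_sd sd of the age slopes, log2 units per week.
#' @param asynchrony_delta weeks by which the right side leads (\eqn{\Delta}).
#' @param side_noise_sd sd of age-independent per-gene side effects (log2).
#' @param dispersion NB dispersion \eqn{\phi \ge 0}; 0 gives Poisson counts.
#' @param lib_size_mean,lib_size_cv mean and coefficient of variation of the
#'   log-normal library-size distribution.
#' @param n_sets,set_size_range,frac_coherent_sets gene-set collection
#'   parameters for [simulate_gene_sets()].
#' @param sex_ratio fraction of individuals that are male.
#' @param structure label written into the sample sheet.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 6,
                       n_genes = 2000,
                       age_range = c(7.5, 13),
                       frac_age_genes = 0.3,
                       slope_sd = 0.2,
                       asynchrony_delta = 0.25,
                       side_noise_sd = 0.05,
                       dispersion = 0.1,
                       lib_size_mean = 2e6,
                       lib_size_cv = 0.2,
                       n_sets = 50,
                       set_size_range = c(15, 100),
                       frac_coherent_sets = 0.2,
                       sex_ratio = 0.5,
                       structure = "brain",
                       seed = 1) {
  stop_if_not_scalar(n_individuals, "n_individuals", integerish = TRUE, min = 2)
  stop_if_not_scalar(n_genes, "n_genes", integerish = TRUE, min = 10)
  if (!is.numeric(age_range) || length(age_range) != 2L ||
      !all(is.finite(age_range)) || diff(age_range) <= 0) {
    stop("'age_range' must be two increasing finite ages (pcw)", call. = FALSE)
  }
  stop_if_not_scalar(frac_age_genes, "frac_age_genes", min = 0)
  if (frac_age_genes > 1) stop("'frac_age_genes' must be <= 1", call. = FALSE)
  stop_if_not_scalar(slope_sd, "slope_sd", min = 0)
  stop_if_not_scalar(asynchrony_delta, "asynchrony_delta")
  stop_if_not_scalar(side_noise_sd, "side_noise_sd", min = 0)
  stop_if_not_scalar(dispersion, "dispersion", min = 0)
  stop_if_not_scalar(lib_size_mean, "lib_size_mean", min = 1)
  stop_if_not_scalar(lib_size_cv, "lib_size_cv", min = 0)
  stop_if_not_scalar(n_sets, "n_sets", integerish = TRUE, min = 0)
  if (!is.numeric(set_size_range) || length(set_size_range) != 2L ||
      set_size_range[1] < 2 || set_size_range[2] < set_size_range[1] ||
      set_size_range[2] > n_genes) {
    stop("'set_size_range' must lie within [2, n_genes]", call. = FALSE)
  }
  stop_if_not_scalar(frac_coherent_sets, "frac_coherent_sets", min = 0)
  if (frac_coherent_sets > 1) stop("'frac_coherent_sets' must be <= 1", call. = FALSE)
  stop_if_not_scalar(sex_ratio, "sex_ratio", min = 0)
  if (sex_ratio > 1) stop("'sex_ratio' must be <= 1", call. = FALSE)
  stop_if_not_scalar(seed, "seed", integerish = TRUE)
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_genes = as.integer(n_genes),
    age_range = as.numeric(age_range),
    frac_age_genes = frac_age_genes,
    slope_sd = slope_sd,
    asynchrony_delta = asynchrony_delta,
    side_noise_sd = side_noise_sd,
    dispersion = dispersion,
    lib_size_mean = lib_size_mean,
    lib_size_cv = lib_size_cv,
    n_sets = as.integer(n_sets),
    set_size_range = as.integer(round(set_size_range)),
    frac_coherent_sets = frac_coherent_sets,
    sex_ratio = sex_ratio,
    structure = as.character(structure),
    seed = as.integer(seed)
  ), class = "sim_config")
}

MARKER_GENES <- c("XIST", "EIF1AY", "KDM5D")

# NB draw with the mean/dispersion parameterization var = m + phi m^2.
# phi = 0 degenerates to Poisson.
rnb_counts <- function(n, mu, phi) {
  if (phi == 0) return(stats::rpois(n, lambda = mu))
  stats::rnbinom(n, mu = mu, size = 1 / phi)
}

# Draw the per-gene program (baseline, age slopes) shared by every structure
# of a study. Marker genes get NA baselines (handled per sex later), zero
# slopes.
draw_gene_program <- function(config) {
  ng <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(ng))
  gene_ids[seq_along(MARKER_GENES)] <- MARKER_GENES
  mu <- stats::rnorm(ng, mean = 4, sd = 2)
  n_age <- round(config$frac_age_genes * ng)
  eligible <- setdiff(seq_len(ng), seq_along(MARKER_GENES))
  n_age <- min(n_age, length(eligible))
  age_idx <- sort(sample(eligible, n_age))
  a <- numeric(ng)
  a[age_idx] <- stats::rnorm(n_age, mean = 0, sd = config$slope_sd)
  mu[seq_along(MARKER_GENES)] <- 0 # replaced per-sex at count time
  list(gene_ids = gene_ids, mu = mu, a = a, age_gene = seq_len(ng) %in% age_idx)
}

draw_individuals <- function(config) {
  n <- config$n_individuals
  ages <- seq(config$age_range[1], config$age_range[2], length.out = n)
  n_male <- round(config$sex_ratio * n)
  sex <- rep("F", n)
  if (n_male > 0) sex[sample.int(n, n_male)] <- "M"
  list(individual = sprintf("ind%02d", seq_len(n)), age = ages, sex = sex)
}

# Core count draw for one structure given a gene program and individuals.
simulate_counts_core <- function(config, program, indiv) {
  n <- config$n_individuals
  ng <- config$n_genes
  sides <- c("L", "R")
  side_sign <- c(L = -1, R = 1)
  sample_id <- as.vector(vapply(seq_len(n), function(i) {
    sprintf("%s_%s_%s", config$structure, indiv$individual[i], sides)
  }, character(2)))
  samp_ind <- rep(seq_len(n), each = 2)
  samp_side <- rep(sides, n)

  # age-independent side effects, one per gene per side, shared across
  # individuals (consistent laterality)
  eps <- matrix(stats::rnorm(ng * 2, 0, config$side_noise_sd), ng, 2,
                dimnames = list(NULL, sides))
  eps[seq_along(MARKER_GENES), ] <- 0

  lib_meanlog <- log(config$lib_size_mean) - log1p(config$lib_size_cv^2) / 2
  lib_sdlog <- sqrt(log1p(config$lib_size_cv^2))
  lib <- stats::rlnorm(2 * n, meanlog = lib_meanlog, sdlog = lib_sdlog)

  log2q <- matrix(0, ng, 2 * n)
  for (j in seq_len(2 * n)) {
    i <- samp_ind[j]
    s <- side_sign[[samp_side[j]]]
    eff_age <- indiv$age[i] + s * config$asynchrony_delta / 2
    log2q[, j] <- program$mu + program$a * eff_age + eps[, samp_side[j]]
  }
  q <- 2^log2q
  # sex-marker relative expression: XIST high in F, Y genes absent in F
  is_f <- indiv$sex[samp_ind] == "F"
  q[match("XIST", program$gene_ids), ] <- ifelse(is_f, 2^10, 0)
  q[match("EIF1AY", program$gene_ids), ] <- ifelse(is_f, 0, 2^7)
  q[match("KDM5D", program$gene_ids), ] <- ifelse(is_f, 0, 2^7)

  mean_mat <- sweep(q, 2, colSums(q), "/")
  mean_mat <- sweep(mean_mat, 2, lib, "*")
  counts <- matrix(rnb_counts(length(mean_mat), as.vector(mean_mat),
                              config$dispersion),
                   ng, 2 * n, dimnames = list(program$gene_ids, sample_id))
  storage.mode(counts) <- "integer"

  sheet <- data.frame(
    sample_id = sample_id,
    individual = indiv$individual[samp_ind],
    side = samp_side,
    structure = config$structure,
    age_pcw = indiv$age[samp_ind],
    sex = indiv$sex[samp_ind],
    stringsAsFactors = FALSE
  )
  delta_g <- program$a * config$asynchrony_delta + eps[, "R"] - eps[, "L"]
  truth <- list(
    gene_ids = program$gene_ids,
    mu = program$mu,
    a = program$a,
    delta_g = delta_g,
    eps = eps,
    age_gene = program$age_gene,
    delta = config$asynchrony_delta,
    expected_mean = mean_mat,
    lib_sizes = lib
  )
  class(truth) <- "ground_truth"
  list(counts = counts, sheet = sheet, truth = truth)
}

#' Simulate one paired left/right count dataset
#'
#' Draws a gene program (baselines, age slopes), individuals (evenly spaced
#' ages, sexes by `sex_ratio`), library sizes, and NB counts under the model
#' described in [sim_config()]. Bit-identical output under identical
#' config + seed.
#'
#' @param config a [sim_config()] object.
#' @return list with `counts` (integer matrix genes x samples), `sheet`
#'   (sample metadata data.frame: sample_id, individual, side, structure,
#'   age_pcw, sex) and `truth` (per-gene baseline `mu`, age slope `a`,
#'   expected R-L log2 fold change `delta_g`, injected `delta`, expected NB
#'   mean matrix).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    program <- draw_gene_program(config)
    indiv <- draw_individuals(config)
    simulate_counts_core(config, program, indiv)
  })
}

#' Simulate a gene-set collection matched to a simulated dataset
#'
#' A fraction `frac_coherent_sets` of the sets are "coherent": their members
#' are drawn with probability proportional to the positive part of the age
#' slope \eqn{a_g}, so they consist of genes that rise together with age.
#' Under a right-leading asynchrony (\eqn{\Delta > 0}) those genes are
#' systematically higher on the right side, and the coherent sets are the
#' ground-truth lateralized sets downstream enrichment should recover. The
#' remaining sets are uniform draws from all genes.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element returned by [simulate_dataset()] for the
#'   same config.
#' @return named list of character vectors (class `gene_set_collection`)
#'   with attributes `coherent` (logical per set) and `description`.
#' @export
simulate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (config$set_size_range[2] > config$n_genes) {
    stop("set sizes exceed n_genes", call. = FALSE)
  }
  with_seed(derive_seed(config$seed, 101L), {
    n_sets <- config$n_sets
    n_coh <- round(config$frac_coherent_sets * n_sets)
    sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                    n_sets, replace = TRUE)
    coherent <- seq_len(n_sets) <= n_coh
    w <- pmax(truth$a, 0)
    if (all(w == 0)) w <- abs(truth$a)
    pool <- which(w > 0)
    sets <- vector("list", n_sets)
    for (k in seq_len(n_sets)) {
      if (coherent[k] && length(pool) > 0) {
        take <- min(sizes[k], length(pool))
        members <- pool[sample.int(length(pool), take, prob = w[pool])]
        if (take < sizes[k]) {
          members <- c(members, sample(setdiff(seq_along(truth$gene_ids), members),
                                       sizes[k] - take))
        }
      } else {
        members <- sample.int(length(truth$gene_ids), sizes[k])
      }
      sets[[k]] <- truth$gene_ids[sort(members)]
    }
    names(sets) <- sprintf("SET_%04d", seq_len(n_sets))
    attr(sets, "coherent") <- stats::setNames(coherent, names(sets))
    attr(sets, "description") <- stats::setNames(
      ifelse(coherent, "coherent age-program set", "random set"), names(sets))
    class(sets) <- "gene_set_collection"
    sets
  })
}

#' Simulate a multi-structure study
#'
#' Shares one gene program (baselines and age slopes) and one cohort of
#' individuals across several structures, so age-coherent gene sets are
#' lateralized the same way in every structure; counts, library sizes and
#' side noise are drawn independently per structure.
#'
#' @param config a [sim_config()]; its `structure` field is ignored.
#' @param structures character vector of structure names.
#' @return list with per-structure `datasets` (each as [simulate_dataset()]),
#'   a shared `sets` collection, and the shared `program`.
#' @export
simulate_study <- function(config, structures = c("forebrain", "midbrain", "hindbrain")) {
  stopifnot(inherits(config, "sim_config"), length(structures) >= 1)
  program <- with_seed(config$seed, draw_gene_program(config))
  indiv <- with_seed(derive_seed(config$seed, 7L), draw_individuals(config))
  datasets <- lapply(seq_along(structures), function(k) {
    cfg <- config
    cfg$structure <- structures[k]
    with_seed(derive_seed(config$seed, 1000L + k),
              simulate_counts_core(cfg, program, indiv))
  })
  names(datasets) <- structures
  truth0 <- datasets[[1]]$truth
  sets <- simulate_gene_sets(config, truth0)
  list(datasets = datasets, sets = sets, program = program)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `counts.tsv` (genes in rows, header = sample IDs), `samples.tsv`
#' (sample sheet), `truth.tsv` (per-gene ground truth) and `config.json`
#' into `dir`.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param config the [sim_config()] used (optional, written as JSON).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_counts(sim$counts, paths["counts"])
  utils::write.table(sim$sheet, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- data.frame(gene_id = sim$truth$gene_ids, mu = sim$truth$mu,
                   a = sim$truth$a, delta_g = sim$truth$delta_g,
                   age_gene = sim$truth$age_gene)
  utils::write.table(tr, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(config)) {
    cfg_path <- file.path(dir, "config.json")
    jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, config = cfg_path)
  }
  invisible(paths)
}
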