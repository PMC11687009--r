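# Synthetic-data generators with known ground truth: a 2x2 factorial
# (knockdown x cytokine) negative-binomial count experiment, and a paired
# +/- cytokine cohort of cell lines carrying a latent dedifferentiation
# gradient coupled to a MITF-like marker and an inducible PD-L1-like target.

SIM_CLASSES <- c("null", "A_only", "B_only", "additive_both",
                 "nonadd_from_neither", "nonadd_from_A", "nonadd_from_B",
                 "nonadd_from_both")

# run expr with a private RNG stream seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Configuration for the factorial count simulator
#'
#' Defines a 2x2 factorial experiment (factor A = knockdown, factor B =
#' cytokine) with replicated conditions. Counts are drawn as
#' \eqn{K_{gj} \sim NB(s_j q_g 2^{a_g x_A + b_g x_B + d_g x_A x_B}, \alpha)}
#' with variance \eqn{\mu + \alpha \mu^2}. Genes are partitioned into eight
#' ground-truth classes by `class_fractions`: no effect, single main effects,
#' both main effects without interaction, and four non-additive classes
#' (interaction term `d` present) distinguished by which main effects
#' accompany it. Effect signs are Bernoulli(1/2) and recorded in the truth
#' table.
#'
#' @param n_genes number of genes.
#' @param n_reps replicates per condition (4 conditions total).
#' @param baseline_mean_range interval for per-gene expected baseline counts
#'   (drawn log-uniform).
#' @param dispersion NB dispersion alpha (variance = mu + alpha * mu^2).
#' @param class_fractions named proportions over the eight classes; must sum
#'   to 1.
#' @param effect_size_log2 magnitude of main effects a, b (log2 units).
#' @param interaction_size_log2 magnitude of the interaction d (log2 units).
#' @param size_factor_range interval for per-sample size factors (drawn
#'   log-uniform); unequal factors exercise normalization downstream.
#' @param seed integer RNG seed.
#' @return a `sim_factorial_config` list.
#' @export
sim_factorial_config <- function(n_genes = 2000, n_reps = 3,
                                 baseline_mean_range = c(20, 500),
                                 dispersion = 0.05,
                                 class_fractions = c(
                                   null = 0.60, A_only = 0.10, B_only = 0.10,
                                   additive_both = 0.05,
                                   nonadd_from_neither = 0.0375,
                                   nonadd_from_A = 0.0375,
                                   nonadd_from_B = 0.0375,
                                   nonadd_from_both = 0.0375),
                                 effect_size_log2 = 2,
                                 interaction_size_log2 = 2,
                                 size_factor_range = c(0.7, 1.4),
                                 seed = 1L) {
  if (!setequal(names(class_fractions), SIM_CLASSES))
    stop("class_fractions must be named over: ",
         paste(SIM_CLASSES, collapse = ", "))
  class_fractions <- class_fractions[SIM_CLASSES]
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1 (got ", sum(class_fractions), ")")
  if (any(class_fractions < 0)) stop("class_fractions must be non-negative")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (length(baseline_mean_range) != 2 || any(baseline_mean_range <= 0) ||
      diff(baseline_mean_range) < 0)
    stop("baseline_mean_range must be a positive, non-decreasing interval")
  structure(list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
                 baseline_mean_range = baseline_mean_range,
                 dispersion = dispersion, class_fractions = class_fractions,
                 effect_size_log2 = effect_size_log2,
                 interaction_size_log2 = interaction_size_log2,
                 size_factor_range = size_factor_range,
                 seed = as.integer(seed)),
            class = "sim_factorial_config")
}

# deterministic allocation of n genes to classes by fractions
allocate_classes <- function(fractions, n) {
  cum <- round(cumsum(fractions) * n)
  counts <- diff(c(0L, cum))
  rep(names(fractions), counts)
}

#' Simulate a replicated 2x2 factorial RNA-seq count experiment
#'
#' @param config a [sim_factorial_config()].
#' @return list with elements `counts` (integer gene-by-sample matrix),
#'   `design` (data.frame: sample, knockdown, cytokine, replicate),
#'   `truth` (data.frame: gene, class, a, b, d, baseline) and
#'   `size_factors` (the true per-sample factors used).
#' @export
simulate_factorial <- function(config) {
  stopifnot(inherits(config, "sim_factorial_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    genes <- sprintf("G%05d", seq_len(n))
    cls <- allocate_classes(config$class_fractions, n)
    cls <- sample(cls)
    e <- config$effect_size_log2
    i <- config$interaction_size_log2
    sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
    a <- b <- d <- numeric(n)
    has_a <- cls %in% c("A_only", "additive_both", "nonadd_from_A",
                        "nonadd_from_both")
    has_b <- cls %in% c("B_only", "additive_both", "nonadd_from_B",
                        "nonadd_from_both")
    has_d <- startsWith(cls, "nonadd")
    a[has_a] <- e * sgn(sum(has_a))
    b[has_b] <- e * sgn(sum(has_b))
    d[has_d] <- i * sgn(sum(has_d))
    q <- exp(stats::runif(n, log(config$baseline_mean_range[[1]]),
                          log(config$baseline_mean_range[[2]])))

    n_samp <- 4L * config$n_reps
    xA <- rep(c(0L, 1L, 0L, 1L), each = config$n_reps)
    xB <- rep(c(0L, 0L, 1L, 1L), each = config$n_reps)
    repid <- rep(seq_len(config$n_reps), times = 4L)
    samples <- sprintf("s%s%s_r%d", c("C", "A")[xA + 1L],
                       c("U", "B")[xB + 1L], repid)
    s <- exp(stats::runif(n_samp, log(config$size_factor_range[[1]]),
                          log(config$size_factor_range[[2]])))

    mu <- outer(q, rep(1, n_samp)) *
      2^(a %o% xA + b %o% xB + d %o% (xA * xB)) *
      rep(s, each = n)
    counts <- if (config$dispersion > 0) {
      matrix(stats::rnbinom(n * n_samp, size = 1 / config$dispersion, mu = mu),
             nrow = n)
    } else {
      matrix(stats::rpois(n * n_samp, lambda = mu), nrow = n)
    }
    dimnames(counts) <- list(genes, samples)
    attr(counts, "unit") <- "counts"
    list(counts = counts,
         design = data.frame(sample = samples, knockdown = xA, cytokine = xB,
                             replicate = repid, stringsAsFactors = FALSE),
         truth = data.frame(gene = genes, class = cls, a = a, b = b, d = d,
                            baseline = q, stringsAsFactors = FALSE),
         size_factors = stats::setNames(s, samples))
  })
}

#' Configuration for the paired-cohort abundance simulator
#'
#' Emulates a panel of patient-derived cell lines profiled with and without
#' cytokine treatment. Each wild-type line carries a latent dedifferentiation
#' value in \[0, 1\] that (i) suppresses a MITF-like marker gene, (ii)
#' amplifies the induction of a panel of interferon-stimulated genes (ISGs)
#' and (iii) increases the induced expression of a PD-L1-like target.
#' Additional lines flagged as genetically engineered or treated with another
#' stimulus are appended so the wild-type filter is exercised; defaults give
#' 58 lines of which 45 survive filtering.
#'
#' @param n_lines wild-type, cytokine-treated lines (default 45).
#' @param n_genes background genes in addition to the marker/ISG panel.
#' @param n_isg size of the inducible ISG panel.
#' @param latent_dediff optional per-line latent values in \[0,1\]; drawn
#'   uniform if `NULL`.
#' @param coupling_mitf strength of the negative latent-to-MITF coupling
#'   (0 = none, 1 = full 6 log2-unit dynamic range).
#' @param coupling_isg latent amplification of ISG induction (fractional
#'   increase at full dedifferentiation).
#' @param coupling_pdl1 strength of the positive latent-to-PD-L1-induction
#'   coupling (slope up to 3 log2 units).
#' @param isg_effect_log2 baseline ISG induction (log2 units).
#' @param noise_sd log2-scale Gaussian noise SD.
#' @param n_engineered,n_other_treated extra non-wild-type lines appended.
#' @param seed integer RNG seed.
#' @return a `sim_cohort_config` list.
#' @export
sim_cohort_config <- function(n_lines = 45, n_genes = 400, n_isg = 20,
                              latent_dediff = NULL,
                              coupling_mitf = 0.8, coupling_isg = 0.5,
                              coupling_pdl1 = 0.8, isg_effect_log2 = 1,
                              noise_sd = 0.2,
                              n_engineered = 9, n_other_treated = 4,
                              seed = 1L) {
  if (n_lines < 4) stop("n_lines must be >= 4")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (!is.null(latent_dediff)) {
    if (length(latent_dediff) != n_lines ||
        any(latent_dediff < 0 | latent_dediff > 1))
      stop("latent_dediff must be n_lines values in [0, 1]")
  }
  structure(list(n_lines = as.integer(n_lines), n_genes = as.integer(n_genes),
                 n_isg = as.integer(n_isg), latent_dediff = latent_dediff,
                 coupling_mitf = coupling_mitf, coupling_isg = coupling_isg,
                 coupling_pdl1 = coupling_pdl1,
                 isg_effect_log2 = isg_effect_log2, noise_sd = noise_sd,
                 n_engineered = as.integer(n_engineered),
                 n_other_treated = as.integer(n_other_treated),
                 seed = as.integer(seed)),
            class = "sim_cohort_config")
}

#' Simulate a paired +/- cytokine cohort on TPM scale
#'
#' @param config a [sim_cohort_config()].
#' @return list with `untreated` and `treated` gene-by-line TPM matrices
#'   (columns sum to 1e6), `metadata` (data.frame: line, engineered,
#'   treatment) and `truth` (data.frame: line, latent_dediff).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_cohort_config"))
  with_seed(config$seed, {
    n_wt <- config$n_lines
    n_all <- n_wt + config$n_engineered + config$n_other_treated
    lines <- sprintf("L%03d", seq_len(n_all))
    u <- c(if (is.null(config$latent_dediff)) stats::runif(n_wt)
           else config$latent_dediff,
           stats::runif(n_all - n_wt))
    genes <- c("MITF", "CD274", sprintf("ISG%02d", seq_len(config$n_isg)),
               sprintf("BG%04d", seq_len(config$n_genes)))
    noise <- function() stats::rnorm(n_all, 0, config$noise_sd)

    base_bg <- stats::runif(config$n_genes, 1, 9)
    base_isg <- stats::runif(config$n_isg, 3, 7)

    log2_untreated <- rbind(
      MITF = 9 - 6 * config$coupling_mitf * u + noise(),
      CD274 = 2 + noise(),
      matrix(rep(base_isg, n_all), ncol = n_all) +
        stats::rnorm(config$n_isg * n_all, 0, config$noise_sd),
      matrix(rep(base_bg, n_all), ncol = n_all) +
        stats::rnorm(config$n_genes * n_all, 0, config$noise_sd))
    isg_gain <- config$isg_effect_log2 *
      (1 + config$coupling_isg * rep(u, each = config$n_isg))
    log2_treated <- rbind(
      MITF = 9 - 6 * config$coupling_mitf * u + noise(),
      CD274 = 2 + 1 + 3 * config$coupling_pdl1 * u + noise(),
      matrix(rep(base_isg, n_all), ncol = n_all) +
        matrix(isg_gain, ncol = n_all) +
        stats::rnorm(config$n_isg * n_all, 0, config$noise_sd),
      matrix(rep(base_bg, n_all), ncol = n_all) +
        stats::rnorm(config$n_genes * n_all, 0, config$noise_sd))
    dimnames(log2_untreated) <- dimnames(log2_treated) <- list(genes, lines)

    to_tpm <- function(l2) {
      x <- 2^l2
      x <- sweep(x, 2, colSums(x), "/") * 1e6
      attr(x, "unit") <- "TPM"
      x
    }
    metadata <- data.frame(
      line = lines,
      engineered = c(rep(FALSE, n_wt), rep(TRUE, config$n_engineered),
                     rep(FALSE, config$n_other_treated)),
      treatment = c(rep("IFNG", n_wt + config$n_engineered),
                    rep("other", config$n_other_treated)),
      stringsAsFactors = FALSE)
    list(untreated = to_tpm(log2_untreated), treated = to_tpm(log2_treated),
         metadata = metadata,
         truth = data.frame(line = lines, latent_dediff = u,
                            stringsAsFactors = FALSE))
  })
}

#' Write a factorial simulation to disk as a fixture bundle
#'
#' Writes the count matrix, design and truth tables as TSV and the planted
#' gene classes as a GMT (one set per non-empty, non-null class). Everything
#' round-trips losslessly through [read_matrix_tsv()], [read_design_tsv()]
#' and [read_gmt()].
#'
#' @param sim result of [simulate_factorial()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_fixture_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.tsv"),
             classes = file.path(dir, "classes.gmt"))
  write_matrix_tsv(sim$counts, paths[["counts"]])
  write_design_tsv(sim$design, paths[["design"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cls_sets <- split(sim$truth$gene, sim$truth$class)
  cls_sets <- cls_sets[setdiff(names(cls_sets), "null")]
  cls_sets <- cls_sets[vapply(cls_sets, length, 1L) > 0]
  write_gmt(cls_sets, paths[["classes"]])
  paths
}
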