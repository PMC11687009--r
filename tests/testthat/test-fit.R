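test_that("size factors: identical samples give equal factors", {
  m <- matrix(rep(c(10L, 20L, 30L), 3), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(estimate_size_factors(m)), rep(1, 3), tolerance = 1e-12)
})

test_that("size factors: doubled sample splits the ratio geometrically", {
  m <- matrix(c(10L, 50L, 200L, 20L, 100L, 400L), 3, 2,
              dimnames = list(paste0("g", 1:3), c("A", "B")))
  s <- estimate_size_factors(m)
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-9)
})

test_that("size factors: genes with any zero are excluded from the
           reference", {
  base <- matrix(c(10L, 50L, 10L, 50L), 2, 2,
                 dimnames = list(c("g1", "g2"), c("A", "B")))
  withzero <- rbind(base, g3 = c(0L, 1000L))
  expect_equal(estimate_size_factors(withzero), estimate_size_factors(base))
  allzero <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
                    dimnames = list(c("g1", "g2"), c("A", "B")))
  expect_error(estimate_size_factors(allzero), "pseudo-reference")
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  # independent cross-check against the established implementation
  sim <- simulate_factorial(sim_factorial_config(n_genes = 300, seed = 41))
  ours <- estimate_size_factors(sim$counts)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(sim$counts)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("dispersion estimates recover the truth", {
  d <- toy_design(10)
  set.seed(43)
  pois <- matrix(rpois(60 * 40, 100), 60, 40,
                 dimnames = list(sprintf("g%02d", 1:60), d$sample))
  sf <- setNames(rep(1, 40), d$sample)
  a_pois <- estimate_dispersion(pois, d, sf)
  expect_lte(median(a_pois), 0.05)

  d50 <- toy_design(50)
  nb <- matrix(rnbinom(40 * 200, size = 2, mu = 100), 40, 200,
               dimnames = list(sprintf("g%02d", 1:40), d50$sample))
  sf50 <- setNames(rep(1, 200), d50$sample)
  a_nb <- estimate_dispersion(nb, d50, sf50)
  expect_gte(median(a_nb), 0.35)
  expect_lte(median(a_nb), 0.65)
})

test_that("constant genes hit the dispersion floor", {
  d <- toy_design(3)
  m <- matrix(100L, 2, 12, dimnames = list(c("g1", "g2"), d$sample))
  a <- estimate_dispersion(m, d, setNames(rep(1, 12), d$sample))
  expect_equal(unname(a), rep(1e-8, 2))
})

test_that("dispersion estimation requires replication", {
  d <- toy_design(1)
  m <- matrix(10L, 1, 4, dimnames = list("g1", d$sample))
  expect_error(estimate_dispersion(m, d, setNames(rep(1, 4), d$sample)),
               "replicates")
})

test_that("saturated zero-dispersion fit recovers closed-form log-ratios", {
  counts <- toy_counts_exact(c(10, 20, 30, 120))
  d <- toy_design(3)
  sf <- setNames(rep(1, 12), d$sample)
  fit <- fit_interaction(counts, d, sf, setNames(1e-8, "g1"))
  # betaAB = log2(120 * 10 / (20 * 30)) = 1 exactly
  expect_equal(fit$betaAB, 1, tolerance = 1e-6)
  expect_equal(fit$lfc_A, 1, tolerance = 1e-6)
  expect_equal(fit$lfc_B, log2(3), tolerance = 1e-6)
  expect_equal(fit$lfc_AB, log2(12), tolerance = 1e-6)
  expect_equal(fit$mu_ctrl, 10, tolerance = 1e-6)
  expect_equal(fit$mu_AB, 120, tolerance = 1e-6)
})

test_that("all-equal counts give null coefficient estimates", {
  counts <- toy_counts_exact(c(50, 50, 50, 50))
  d <- toy_design(3)
  fit <- fit_interaction(counts, d, setNames(rep(1, 12), d$sample),
                         setNames(1e-8, "g1"))
  expect_equal(fit$betaA, 0, tolerance = 1e-6)
  expect_equal(fit$betaB, 0, tolerance = 1e-6)
  expect_equal(fit$betaAB, 0, tolerance = 1e-6)
  expect_equal(fit$lrt_stat, 0, tolerance = 1e-6)
})

test_that("Poisson-limit fits equal observed-mean log-ratios with one
           replicate", {
  d <- toy_design(1)
  counts <- matrix(c(11L, 23L, 37L, 91L), 1, 4,
                   dimnames = list("g1", d$sample))
  fit <- fit_interaction(counts, d, setNames(rep(1, 4), d$sample),
                         setNames(1e-8, "g1"))
  expect_equal(fit$betaA, log2(23 / 11), tolerance = 1e-6)
  expect_equal(fit$betaB, log2(37 / 11), tolerance = 1e-6)
  expect_equal(fit$lfc_AB, log2(91 / 11), tolerance = 1e-6)
})

test_that("GeneFit invariants hold on simulated data", {
  sim <- simulate_factorial(sim_factorial_config(n_genes = 150, seed = 47))
  sf <- estimate_size_factors(sim$counts)
  disp <- estimate_dispersion(sim$counts, sim$design, sf)
  fits <- fit_interaction(sim$counts, sim$design, sf, disp)
  expect_true(all(fits$lrt_stat >= 0))
  expect_true(all(fits$alpha >= 0))
  ok <- !is.na(fits$p_interaction)
  expect_true(all(fits$padj_interaction[ok] >= fits$p_interaction[ok]))
  # the combined contrast decomposes exactly into main effects + interaction
  expect_equal(fits$lfc_AB, fits$betaA + fits$betaB + fits$betaAB,
               tolerance = 1e-12)
})

test_that("fit_interaction validates design/counts alignment", {
  sim <- simulate_factorial(sim_factorial_config(n_genes = 10, seed = 1))
  sf <- estimate_size_factors(sim$counts)
  disp <- setNames(rep(0.1, 10), rownames(sim$counts))
  bad <- sim$design
  bad$sample[1] <- "nonexistent"
  expect_error(fit_interaction(sim$counts, bad, sf, disp), "match")
})

test_that("adjust_bh reproduces the step-up adjustment", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # missing values propagate and do not count toward m
  p <- c(0.01, NA, 0.02)
  got <- adjust_bh(p)
  expect_true(is.na(got[2]))
  expect_equal(got[c(1, 3)], adjust_bh(c(0.01, 0.02)))
  # monotone after sorting, for arbitrary input
  set.seed(5)
  x <- runif(100)
  expect_true(all(diff(sort(adjust_bh(x))) >= -1e-15))
})

test_that("call_degs applies a strict threshold and flags missing fits", {
  fits <- make_fit_row(gene = c("a", "b", "c"),
                       padj_A = c(0.049, 0.05, NA))
  calls <- call_degs(fits, "A")
  expect_identical(unname(as.logical(calls)), c(TRUE, FALSE, FALSE))
  expect_identical(attr(calls, "undetermined"), "c")
  expect_error(call_degs(fits, "X"), "arg")
})

test_that("response_gene_filter enforces expression and fold-change
           floors", {
  fits <- make_fit_row(gene = c("lowtpm", "lowfc", "keep", "notsig"),
                       lfc_B = c(2, 0.9, 1.5, 3),
                       padj_B = c(0.01, 0.01, 0.01, 0.9))
  tpm <- matrix(c(1.9, 50, 10, 50), 4, 1,
                dimnames = list(fits$gene, "s1"))
  attr(tpm, "unit") <- "TPM"
  expect_identical(response_gene_filter(fits, tpm), "keep")
  expect_error(response_gene_filter(fits, tpm[1:2, , drop = FALSE]),
               "lacks fitted gene")
})
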