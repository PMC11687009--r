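test_that("wild-type filter retains only untouched, cytokine-treated
           lines", {
  co <- simulate_cohort(sim_cohort_config(n_genes = 30, seed = 61))
  expect_equal(ncol(co$treated), 58)
  expect_equal(sum(co$metadata$engineered |
                     co$metadata$treatment != "IFNG"), 13)
  wt <- filter_wildtype(co, co$metadata)
  expect_equal(ncol(wt$treated), 45)
  expect_equal(ncol(wt$untreated), 45)
  expect_identical(colnames(wt$treated), colnames(wt$untreated))

  # nothing flagged: identity
  meta_ok <- co$metadata
  meta_ok$engineered <- FALSE
  meta_ok$treatment <- "IFNG"
  expect_equal(ncol(filter_wildtype(co, meta_ok)$treated), 58)
  # everything flagged: empty with warning
  meta_bad <- co$metadata
  meta_bad$engineered <- TRUE
  expect_warning(empty <- filter_wildtype(co, meta_bad), "no lines")
  expect_equal(ncol(empty$treated), 0)
  expect_error(filter_wildtype(co, meta_ok[, 1, drop = FALSE]), "columns")
})

test_that("cytokine response score is the mean over present set members", {
  m <- rbind(g1 = c(3, 1), g2 = c(5, 7), g3 = c(100, 100))
  colnames(m) <- c("l1", "l2")
  attr(m, "unit") <- "log2TPM1"
  sc <- ifng_response_score(m, c("g1", "g2"))
  expect_equal(unname(sc), c(4, 4))
  # score ignores genes outside the set
  m2 <- m
  m2["g3", ] <- 0
  expect_equal(ifng_response_score(m2, c("g1", "g2")), sc)
  expect_warning(sc2 <- ifng_response_score(m, c("g1", "g2", "absent")),
                 "absent")
  expect_equal(sc2, sc)
  expect_error(ifng_response_score(m, "nope"), "none")
})

test_that("halves and quartile splits reproduce the documented sizes", {
  set.seed(14)
  v45 <- setNames(rnorm(45), sprintf("L%02d", 1:45))
  h <- rank_and_split(v45, "halves")
  expect_equal(unname(table(h)[c("upper", "lower")]), c(22L, 23L),
               ignore_attr = TRUE)
  # the median line lands in the lower group
  med_line <- names(sort(v45, decreasing = TRUE))[23]
  expect_identical(unname(h[med_line]), "lower")
  q <- rank_and_split(v45, "quartiles")
  expect_equal(sum(q == "high", na.rm = TRUE), 12)
  expect_equal(sum(q == "low", na.rm = TRUE), 12)
  expect_false(any(names(which(q == "high")) %in% names(which(q == "low"))))

  v4 <- setNames(c(4, 3, 2, 1), paste0("L", 1:4))
  expect_equal(unname(table(rank_and_split(v4, "halves"))), c(2L, 2L),
               ignore_attr = TRUE)
  expect_error(rank_and_split(v4[1:3], "quartiles"), ">= 4")
})

test_that("halves partition and boundary ties resolve by line id", {
  for (n in c(4, 7, 45)) {
    v <- setNames(seq_len(n), sprintf("L%02d", seq_len(n)))
    h <- rank_and_split(v, "halves")
    expect_equal(sum(h == "upper") + sum(h == "lower"), n)
    if (n %% 2 == 1)
      expect_equal(sum(h == "upper"), sum(h == "lower") - 1)
  }
  tied <- setNames(c(2, 1, 1, 0), c("La", "Lb", "Lc", "Ld"))
  expect_message(h <- rank_and_split(tied, "halves"), "tie")
  expect_identical(unname(h[c("La", "Lb")]), c("upper", "upper"))
})

test_that("high/low splits cut at threshold, largest gap, or median", {
  v <- setNames(c(1, 1.1, 1.2, 5, 5.1), paste0("L", 1:5))
  g <- split_high_low(v, "largest_gap")
  expect_identical(as.vector(g), c("low", "low", "low", "high", "high"))
  t3 <- split_high_low(setNames(c(1, 2, 4), paste0("L", 1:3)),
                       "threshold", threshold = 3)
  expect_identical(as.vector(t3), c("low", "low", "high"))
  flat <- setNames(rep(2, 3), paste0("L", 1:3))
  expect_error(split_high_low(flat, "largest_gap"), "distinct")
  expect_identical(as.vector(split_high_low(flat, "threshold",
                                            threshold = 5)),
                   rep("low", 3))
  med <- split_high_low(v, "median")
  expect_equal(sum(med == "high"), 2)
})

test_that("associate: monotone sequences give |r_s| = 1; ties match the
           average-rank oracle", {
  x <- 1:10
  expect_equal(associate(x, x + 3, "spearman")$estimate, 1)
  expect_equal(associate(x, -2 * x, "spearman")$estimate, -1)
  # 6-point tied toy against the explicit average-rank formula
  xt <- c(1, 2, 2, 3, 4, 4)
  yt <- c(5, 3, 4, 4, 1, 2)
  rx <- rank(xt); ry <- rank(yt)
  r_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(associate(xt, yt, "spearman")$estimate, r_oracle,
               tolerance = 1e-12)
  const <- associate(rep(1, 5), 1:5, "spearman")
  expect_true(const$undefined)
  expect_error(associate(1:2, 1:2), ">= 3")
})

test_that("associate: linear regression recovers slope and intercept", {
  set.seed(15)
  x <- rnorm(30)
  y <- 2.5 * x + 1 + rnorm(30, sd = 0.1)
  fit <- associate(x, y, "linreg")
  expect_equal(unname(fit$estimate["slope"]), 2.5, tolerance = 0.1)
  expect_equal(unname(fit$estimate["intercept"]), 1, tolerance = 0.1)
  expect_lt(fit$p, 1e-6)
})

test_that("group comparisons: separation, null calibration inputs, and
           degenerate pairs", {
  sep <- compare_groups(c(rnorm(10) + 100, rnorm(10)),
                        rep(c("a", "b"), each = 10), "two_group")
  expect_lt(sep$p, 0.001)
  paired0 <- compare_groups(c(1, 2, 3), c(1, 2, 3), "paired")
  expect_true(paired0$undefined)
  expect_true(is.na(paired0$p))
  kw <- compare_groups(c(rnorm(8), rnorm(8) + 5, rnorm(8)),
                       rep(c("a", "b", "c"), each = 8), "multi_group")
  expect_s3_class(kw$posthoc, "data.frame")
  expect_equal(nrow(kw$posthoc), 3)
  expect_true(all(kw$posthoc$padj >= kw$posthoc$p - 1e-15))
  expect_error(compare_groups(1:4, rep("a", 4), "two_group"), "2 groups")
})

test_that("Dunn post-hoc agrees with the Kruskal-Wallis ordering on a
           separated toy", {
  set.seed(16)
  vals <- c(rnorm(12), rnorm(12) + 10, rnorm(12) + 20)
  labs <- rep(c("lo", "mid", "hi"), each = 12)
  kw <- compare_groups(vals, labs, "multi_group")
  ph <- kw$posthoc
  extreme <- ph[(ph$group1 == "lo" & ph$group2 == "hi") |
                  (ph$group1 == "hi" & ph$group2 == "lo"), ]
  expect_lt(extreme$padj, 0.01)
})

test_that("correlation matrix: twins correlate at 1, independence stays
           near 0, Bonferroni multiplies", {
  set.seed(17)
  base <- matrix(rnorm(3000), 1000, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  dup <- cbind(base, d = base[, "a"])
  cm <- correlation_matrix(dup)
  expect_equal(cm$r["a", "d"], 1, tolerance = 1e-12)
  off <- abs(cm$r[upper.tri(cm$r)])
  expect_lt(mean(off[off < 0.99]), 0.1)
  # bonferroni: adjusted = raw * m, clamped
  cm3 <- correlation_matrix(base)
  m <- 3
  raw <- cor.test(base[, "a"], base[, "b"])$p.value
  expect_equal(cm3$padj["a", "b"], min(1, raw * m), tolerance = 1e-9)
  expect_error(correlation_matrix(base[, 1:2]), ">= 3")
})

test_that("PCA embedding: rank-1 data loads on one component with a
           deterministic sign", {
  set.seed(18)
  v <- rexp(50)
  w <- c(1, 2, 3, 4)
  m <- outer(v, w)
  dimnames(m) <- list(sprintf("g%02d", 1:50), paste0("s", 1:4))
  p <- pca_embed(m, k_top = 50)
  expect_gte(p$explained[1], 0.999)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_gt(p$loadings[1, 1], 0)  # sign convention
  # orthonormal loadings
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_error(pca_embed(m, k_top = 100), "exceeds")
})

test_that("synthetic cohorts recover the planted marker couplings", {
  hits_r <- 0L; hits_med <- 0L
  for (seed in 1:10) {
    co <- simulate_cohort(sim_cohort_config(n_genes = 40, seed = seed))
    wt <- filter_wildtype(co, co$metadata)
    l2t <- log2_tpm1(wt$treated)
    l2u <- log2_tpm1(wt$untreated)
    mitf <- l2t["MITF", ]
    ind <- l2t["CD274", ] - l2u["CD274", ]
    if (associate(mitf, ind, "spearman")$estimate < -0.3)
      hits_r <- hits_r + 1L
    q <- rank_and_split(mitf, "quartiles")
    if (median(ind[!is.na(q) & q == "low"]) >
          median(ind[!is.na(q) & q == "high"]))
      hits_med <- hits_med + 1L
  }
  expect_gte(hits_r, 6)
  expect_gte(hits_med, 6)
})
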