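# Per-gene negative-binomial GLM engine for the 2x2 factorial design:
# median-of-ratios size factors, Cox-Reid adjusted profile-likelihood
# dispersion, interaction likelihood-ratio test and log2 fold-change
# contrasts. Model (log2 scale):
#   log2 mu_gj = beta0 + betaA x_A + betaB x_B + betaAB x_A x_B + log2 s_j
# with NB variance mu + alpha mu^2. The full model is saturated on the four
# conditions, so its MLE reduces to four one-dimensional condition-mean
# problems; the reduced model (no interaction) is fitted by IRLS.

DISP_FLOOR <- 1e-8

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across reference genes of
#' the ratio of its count to the gene's geometric mean across samples. Genes
#' with a zero count in any sample are excluded from the reference set.
#'
#' @param counts integer gene-by-sample count matrix.
#' @return named numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  ref <- rowSums(counts == 0) == 0
  if (!any(ref))
    stop("no gene has nonzero counts in every sample; supply size factors ",
         "computed with a pseudo-reference instead")
  lc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(lc)
  s <- apply(lc, 2, function(x) exp(stats::median(x - loggeo)))
  stats::setNames(s, colnames(counts))
}

# condition index 1..4 (CU, AU, CB, AB) from a design data.frame
design_condition <- function(design) {
  need <- c("sample", "knockdown", "cytokine")
  if (!all(need %in% names(design)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  cond <- 1L + design$knockdown + 2L * design$cytokine
  if (length(unique(cond)) != 4L)
    stop("all four knockdown x cytokine combinations must be present")
  cond
}

nb_ll <- function(y, mu, alpha) {
  mu <- pmax(mu, 1e-10)
  if (alpha < DISP_FLOOR) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

# MLE of the condition mean m (for size factor 1) solving the NB score
# equation sum_j (y_j - s_j m) / (1 + alpha s_j m) = 0 by Newton iteration
cond_mean_mle <- function(y, s, alpha) {
  m <- sum(y) / sum(s)
  if (m <= 0) return(0)
  for (it in 1:100) {
    mu <- s * m
    num <- sum((y - mu) / (1 + alpha * mu))
    den <- -sum(s * (1 + alpha * y) / (1 + alpha * mu)^2)
    m2 <- m - num / den
    if (!is.finite(m2) || m2 <= 0) m2 <- m / 2
    if (abs(m2 - m) < 1e-12 * (m + 1e-8)) { m <- m2; break }
    m <- m2
  }
  m
}

# full-model (saturated) profile log-likelihood at dispersion alpha;
# cr adds the Cox-Reid adjustment -1/2 log det(X'WX) (diagonal per condition)
full_model_ll <- function(y, s, cond, alpha, cr = FALSE) {
  ll <- 0
  for (c in 1:4) {
    idx <- cond == c
    m <- cond_mean_mle(y[idx], s[idx], alpha)
    mu <- s[idx] * m
    ll <- ll + nb_ll(y[idx], mu, alpha)
    if (cr) ll <- ll - 0.5 * log(max(sum(mu / (1 + alpha * mu)), 1e-10))
  }
  ll
}

#' Per-gene NB dispersion by adjusted profile likelihood
#'
#' A method-of-moments estimate seeds the search interval; the estimate is
#' then refined by maximizing the Cox-Reid adjusted profile likelihood of
#' the full (saturated) factorial model over the dispersion, per gene. The
#' adjustment compensates the downward bias of plain ML when four condition
#' means are estimated from few replicates. Estimates are floored at 1e-8.
#'
#' @param counts integer gene-by-sample count matrix.
#' @param design factorial design data.frame (sample, knockdown, cytokine).
#' @param size_factors per-sample size factors.
#' @return named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(counts, design, size_factors) {
  cond <- design_condition(design)
  if (max(table(cond)) < 2)
    stop("dispersion estimation needs >= 2 replicates in some condition")
  s <- size_factors[design$sample]
  apply_gene <- function(y) {
    if (all(y == y[1])) return(DISP_FLOOR)
    z <- y / s
    mom <- max((stats::var(z) - mean(z)) / mean(z)^2, 0)
    hi <- log(max(10, 4 * mom + 1))
    opt <- stats::optimize(function(la) full_model_ll(y, s, cond, exp(la),
                                                      cr = TRUE),
                           c(log(DISP_FLOOR), hi), maximum = TRUE, tol = 1e-4)
    max(exp(opt$maximum), DISP_FLOOR)
  }
  stats::setNames(apply(counts, 1, apply_gene), rownames(counts))
}

# IRLS for NB regression with log link and offset; returns beta (natural
# log), log-likelihood and convergence flag
nb_irls <- function(y, X, offset, alpha, max_iter = 100, tol = 1e-8) {
  beta <- tryCatch(qr.solve(X, log(pmax(y, 0.5)) - offset),
                   error = function(e) rep(0, ncol(X)))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(solve(crossprod(X * w, X), crossprod(X * w, z)),
                    error = function(e) NULL)
    if (is.null(fit)) break
    beta_new <- drop(fit)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new
      converged <- TRUE; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta) + offset
  list(beta = beta, ll = nb_ll(y, exp(eta), alpha), converged = converged)
}

#' Fit the two-factor interaction model per gene
#'
#' Full model: condition means for control, knockdown-only, cytokine-only
#' and combined (saturated 2x2). Reduced model drops the interaction. The
#' likelihood-ratio statistic is referred by default to F(1, n - 4), which
#' accounts for per-gene dispersion estimation at small replicate numbers;
#' `lrt_ref = "chisq"` gives the asymptotic chi-square(1) reference.
#' Coefficients and contrasts are reported on log2 scale; by construction
#' `lfc_AB = betaA + betaB + betaAB` exactly. Contrast p-values are Wald
#' tests from the saturated model's expected information. Conditions with an
#' all-zero fitted mean yield missing fold-changes and a `zero_condition`
#' flag.
#'
#' @param counts integer gene-by-sample count matrix.
#' @param design factorial design data.frame.
#' @param size_factors per-sample size factors.
#' @param dispersions per-gene NB dispersions.
#' @param lrt_ref reference distribution for the interaction LRT
#'   (`"f"` or `"chisq"`).
#' @return data.frame with one row per gene: gene, beta0, betaA, betaB,
#'   betaAB, alpha, lrt_stat, p_interaction, padj_interaction, lfc_A, padj_A,
#'   lfc_B, padj_B, lfc_AB, padj_AB, converged, plus raw contrast p-values
#'   (p_A, p_B, p_AB), fitted condition means (mu_ctrl, mu_A, mu_B, mu_AB)
#'   and the zero_condition flag.
#' @export
fit_interaction <- function(counts, design, size_factors, dispersions,
                            lrt_ref = c("f", "chisq")) {
  lrt_ref <- match.arg(lrt_ref)
  if (!setequal(design$sample, colnames(counts)) ||
      nrow(design) != ncol(counts))
    stop("design samples do not match count matrix columns")
  counts <- counts[, design$sample, drop = FALSE]
  cond <- design_condition(design)
  s <- size_factors[design$sample]
  if (any(!is.finite(s)) || any(s <= 0)) stop("size factors must be > 0")
  Xr <- cbind(1, design$knockdown, design$cytokine)
  offset <- log(s)
  ln2 <- log(2)
  df_res <- nrow(design) - 4L

  fit_gene <- function(y, alpha) {
    ms <- vs <- numeric(4)
    ll_full <- 0
    for (c in 1:4) {
      idx <- cond == c
      m <- cond_mean_mle(y[idx], s[idx], alpha)
      ms[c] <- m
      mu <- s[idx] * m
      ll_full <- ll_full + nb_ll(y[idx], mu, alpha)
      w <- sum(mu / (1 + alpha * mu))
      vs[c] <- if (w > 0) 1 / w else Inf   # var of log m_c
    }
    red <- nb_irls(y, Xr, offset, alpha)
    lrt <- max(0, 2 * (ll_full - red$ll))
    # no residual df (single replicate) leaves only the asymptotic reference
    p_int <- if (lrt_ref == "f" && df_res >= 1)
               stats::pf(lrt, 1, df_res, lower.tail = FALSE)
             else stats::pchisq(lrt, 1, lower.tail = FALSE)
    zero <- ms <= 0
    lm2 <- ifelse(zero, NA_real_, log2(pmax(ms, 1e-300)))
    beta0 <- lm2[1]; betaA <- lm2[2] - lm2[1]; betaB <- lm2[3] - lm2[1]
    betaAB <- lm2[4] - lm2[3] - lm2[2] + lm2[1]
    lfc_AB <- lm2[4] - lm2[1]
    se <- sqrt(c(A = vs[2] + vs[1], B = vs[3] + vs[1],
                 AB = vs[4] + vs[1])) / ln2
    wald <- function(est, se) {
      if (is.na(est) || !is.finite(se)) NA_real_
      else 2 * stats::pnorm(-abs(est) / se)
    }
    c(beta0 = beta0, betaA = betaA, betaB = betaB, betaAB = betaAB,
      alpha = alpha, lrt_stat = lrt, p_interaction = p_int,
      lfc_A = betaA, p_A = wald(betaA, se[["A"]]),
      lfc_B = betaB, p_B = wald(betaB, se[["B"]]),
      lfc_AB = lfc_AB, p_AB = wald(lfc_AB, se[["AB"]]),
      converged = as.numeric(red$converged),
      zero_condition = as.numeric(any(zero)),
      mu_ctrl = ms[1], mu_A = ms[2], mu_B = ms[3], mu_AB = ms[4])
  }

  res <- t(vapply(seq_len(nrow(counts)),
                  function(g) fit_gene(counts[g, ], dispersions[[g]]),
                  numeric(19)))
  out <- data.frame(gene = rownames(counts), res, stringsAsFactors = FALSE,
                    row.names = NULL)
  out$converged <- out$converged > 0
  out$zero_condition <- out$zero_condition > 0
  out$p_interaction[!out$converged] <- NA_real_
  out$padj_interaction <- adjust_bh(out$p_interaction)
  out$padj_A <- adjust_bh(out$p_A)
  out$padj_B <- adjust_bh(out$p_B)
  out$padj_AB <- adjust_bh(out$p_AB)
  out[, c("gene", "beta0", "betaA", "betaB", "betaAB", "alpha", "lrt_stat",
          "p_interaction", "padj_interaction", "lfc_A", "p_A", "padj_A",
          "lfc_B", "p_B", "padj_B", "lfc_AB", "p_AB", "padj_AB",
          "converged", "zero_condition",
          "mu_ctrl", "mu_A", "mu_B", "mu_AB")]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjustment via [stats::p.adjust()]; missing values propagate
#' as missing and are excluded from the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call differentially expressed genes on one contrast
#'
#' A gene responds when its BH-adjusted contrast p-value is strictly below
#' the threshold; genes with a missing adjusted p (e.g. non-converged fits)
#' are non-responders and flagged.
#'
#' @param fits data.frame from [fit_interaction()].
#' @param contrast one of `"A"`, `"B"`, `"AB"`.
#' @param padj_threshold significance threshold (default 0.05).
#' @return logical vector named by gene, with attribute `undetermined`
#'   listing genes whose adjusted p was missing.
#' @export
call_degs <- function(fits, contrast = c("A", "B", "AB"),
                      padj_threshold = 0.05) {
  contrast <- match.arg(contrast)
  padj <- fits[[paste0("padj_", contrast)]]
  calls <- !is.na(padj) & padj < padj_threshold
  names(calls) <- fits$gene
  attr(calls, "undetermined") <- fits$gene[is.na(padj)]
  calls
}

#' Response-gene filter: expression floor and fold-change floor
#'
#' Restricts significant genes (BH-adjusted p below `padj_threshold` on any
#' of the three contrasts) to those expressed at `min_tpm` or more in at
#' least one sample and with at least one contrast of absolute log2
#' fold-change `min_lfc` or more.
#'
#' @param fits data.frame from [fit_interaction()].
#' @param tpm TPM matrix covering the fitted genes.
#' @param min_tpm expression floor (default 2 TPM).
#' @param min_lfc absolute log2 fold-change floor (default 1).
#' @param padj_threshold contrast significance threshold (default 0.05).
#' @return character vector of retained gene ids.
#' @export
response_gene_filter <- function(fits, tpm, min_tpm = 2, min_lfc = 1,
                                 padj_threshold = 0.05) {
  missing <- setdiff(fits$gene, rownames(tpm))
  if (length(missing) > 0)
    stop("TPM matrix lacks fitted gene(s): ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ...")
  sig <- rep(FALSE, nrow(fits))
  for (ct in c("A", "B", "AB")) {
    padj <- fits[[paste0("padj_", ct)]]
    sig <- sig | (!is.na(padj) & padj < padj_threshold)
  }
  max_tpm <- apply(tpm[fits$gene, , drop = FALSE], 1, max)
  lfc <- abs(as.matrix(fits[, c("lfc_A", "lfc_B", "lfc_AB")]))
  max_lfc <- apply(lfc, 1, function(x) if (all(is.na(x))) NA_real_
                                       else max(x, na.rm = TRUE))
  keep <- sig & max_tpm >= min_tpm & !is.na(max_lfc) & max_lfc >= min_lfc
  fits$gene[keep]
}
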