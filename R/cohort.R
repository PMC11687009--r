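# Cohort re-analysis stage: wild-type filtering, cytokine response scores,
# marker-based stratification, rank association statistics, correlation
# matrices and PCA over paired +/- treatment expression profiles.

#' Restrict a paired cohort to wild-type, cytokine-treated lines
#'
#' Drops lines flagged as genetically engineered or whose treated arm
#' received a stimulus other than the cytokine of interest.
#'
#' @param cohort list with `untreated` and `treated` gene-by-line matrices.
#' @param metadata data.frame with columns `line`, `engineered` (logical),
#'   `treatment` (`"IFNG"` or other).
#' @param treatment_keep treated-arm label to retain (default `"IFNG"`).
#' @return the cohort list with both matrices and the metadata subset to the
#'   retained lines.
#' @export
filter_wildtype <- function(cohort, metadata, treatment_keep = "IFNG") {
  need <- c("line", "engineered", "treatment")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  keep <- metadata$line[!metadata$engineered &
                          metadata$treatment == treatment_keep]
  if (length(keep) == 0) warning("no lines retained by the wild-type filter")
  subset_m <- function(m) {
    out <- m[, intersect(colnames(m), keep), drop = FALSE]
    attr(out, "unit") <- attr(m, "unit")
    out
  }
  list(untreated = subset_m(cohort$untreated),
       treated = subset_m(cohort$treated),
       metadata = metadata[metadata$line %in% keep, , drop = FALSE])
}

#' Per-line cytokine response score
#'
#' The mean log2(TPM + 1) expression over the members of a response gene set
#' (e.g. the interferon-gamma response hallmark set), per line. Set members
#' absent from the matrix are ignored with a warning naming them.
#'
#' @param expr gene-by-line matrix in log2(TPM+1).
#' @param set character vector of response-set gene ids.
#' @return named numeric vector of per-line scores.
#' @export
ifng_response_score <- function(expr, set) {
  check_unit(expr, "log2TPM1")
  present <- intersect(set, rownames(expr))
  if (length(present) == 0)
    stop("none of the response-set genes are in the matrix")
  absent <- setdiff(set, present)
  if (length(absent) > 0)
    warning("response-set gene(s) absent from matrix: ",
            paste(absent, collapse = ", "))
  colMeans(expr[present, , drop = FALSE])
}

#' Rank lines by a marker and split into halves or quartiles
#'
#' Halves: upper/lower 50%, with the median element assigned to the lower
#' group for odd n (45 lines split 22 upper / 23 lower). Quartiles: top and
#' bottom ceiling(n/4) lines labelled `high`/`low`, the middle left
#' unlabelled (45 lines give 12 per extreme). Ties crossing a boundary are
#' resolved by line-id order and reported in a message.
#'
#' @param values named per-line numeric vector (names = line ids).
#' @param mode `"halves"` or `"quartiles"`.
#' @return character vector named by line: `"upper"`/`"lower"` for halves;
#'   `"high"`/`"low"`/`NA` for quartiles.
#' @export
rank_and_split <- function(values, mode = c("halves", "quartiles")) {
  mode <- match.arg(mode)
  n <- length(values)
  if (mode == "quartiles" && n < 4) stop("quartiles need >= 4 lines")
  ids <- names(values)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(-values, ids)   # descending value, ties by line id
  ranked <- ids[ord]
  v_sorted <- values[ord]
  labels <- rep(NA_character_, n)
  names(labels) <- ids
  if (mode == "halves") {
    n_upper <- floor(n / 2)    # median element goes to the lower group
    labels[ranked[seq_len(n_upper)]] <- "upper"
    labels[ranked[(n_upper + 1):n]] <- "lower"
    if (n_upper >= 1 && v_sorted[n_upper] == v_sorted[n_upper + 1])
      message("tie at the halves boundary resolved by line-id order")
  } else {
    k <- ceiling(n / 4)
    labels[ranked[seq_len(k)]] <- "high"
    labels[ranked[(n - k + 1):n]] <- "low"
    if (v_sorted[k] == v_sorted[k + 1] ||
        v_sorted[n - k] == v_sorted[n - k + 1])
      message("tie at a quartile boundary resolved by line-id order")
  }
  labels
}

#' Split lines into high/low groups by threshold, largest gap, or median
#'
#' `threshold`: values >= the threshold are `high`. `largest_gap`: cut at
#' the maximal adjacent gap in the sorted values. `median`: upper/lower as
#' in [rank_and_split()] halves, relabelled `high`/`low`.
#'
#' @param values named per-line numeric vector.
#' @param method `"threshold"`, `"largest_gap"` or `"median"`.
#' @param threshold cut value (required for `method = "threshold"`).
#' @return character vector of `"high"`/`"low"` named by line, with
#'   attribute `cut` (the realized cut point).
#' @export
split_high_low <- function(values, method = c("largest_gap", "threshold",
                                              "median"), threshold = NULL) {
  method <- match.arg(method)
  if (method == "threshold") {
    if (is.null(threshold)) stop("threshold method requires a threshold")
    cut <- threshold
  } else if (method == "largest_gap") {
    v <- sort(unique(values))
    if (length(v) < 2)
      stop("largest_gap needs >= 2 distinct values")
    gaps <- diff(v)
    i <- which.max(gaps)
    cut <- (v[i] + v[i + 1]) / 2
  } else {
    half <- rank_and_split(values, "halves")
    out <- ifelse(half == "upper", "high", "low")
    names(out) <- names(values)
    attr(out, "cut") <- stats::median(values)
    return(out)
  }
  out <- ifelse(values >= cut, "high", "low")
  names(out) <- names(values)
  attr(out, "cut") <- cut
  out
}

#' Pairwise association between two per-line variables
#'
#' `spearman`: rank correlation with average-rank tie handling and a
#' two-sided p-value; `linreg`: simple least-squares regression of y on x
#' with the slope's two-sided p.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @param method `"spearman"` or `"linreg"`.
#' @return list: `method`, `estimate` (r_s, or c(slope, intercept)), `p`,
#'   `n`, and `undefined` flag (constant input under spearman).
#' @export
associate <- function(x, y, method = c("spearman", "linreg")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 paired observations")
  if (method == "spearman") {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(list(method = method, estimate = NA_real_, p = NA_real_, n = n,
                  undefined = TRUE))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           alternative = "two.sided",
                                           exact = FALSE))
    list(method = method, estimate = unname(ct$estimate), p = ct$p.value,
         n = n, undefined = FALSE)
  } else {
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)$coefficients
    list(method = method,
         estimate = c(slope = unname(stats::coef(fit)[2]),
                      intercept = unname(stats::coef(fit)[1])),
         p = unname(sm["x", "Pr(>|t|)"]), n = n, undefined = FALSE)
  }
}

# Dunn's post-hoc z tests on the pooled ranks after Kruskal-Wallis,
# with the usual tie correction; pairwise p-values BH-adjusted.
dunn_posthoc <- function(values, labels) {
  r <- rank(values)
  n <- length(values)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  groups <- split(r, labels)
  means <- vapply(groups, mean, 1)
  sizes <- vapply(groups, length, 1)
  pairs <- utils::combn(names(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[[1]]; j <- pr[[2]]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / sizes[[i]] + 1 / sizes[[j]]))
    z <- (means[[i]] - means[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = res["z", ],
             p = res["p", ], padj = adjust_bh(res["p", ]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Nonparametric group comparisons
#'
#' `two_group`: two-sided Mann-Whitney U. `multi_group`: Kruskal-Wallis,
#' followed by Dunn's post-hoc z tests with BH adjustment. `paired`:
#' two-sided Wilcoxon signed-rank on the paired differences (all-zero
#' differences yield a flagged, missing p).
#'
#' @param values numeric vector (or, for `paired`, the first member of each
#'   pair).
#' @param labels group labels (`two_group`/`multi_group`); for `paired`,
#'   the second member of each pair instead.
#' @param design `"two_group"`, `"multi_group"` or `"paired"`.
#' @return list: `design`, `statistic`, `p`, `n`, plus `posthoc`
#'   (data.frame) for `multi_group` and `undefined` flag for degenerate
#'   paired input.
#' @export
compare_groups <- function(values, labels, design = c("two_group",
                                                      "multi_group",
                                                      "paired")) {
  design <- match.arg(design)
  if (design == "paired") {
    y <- labels
    if (!is.numeric(y) || length(y) != length(values))
      stop("paired design needs two equal-length numeric vectors")
    d <- values - y
    if (all(d == 0))
      return(list(design = design, statistic = NA_real_, p = NA_real_,
                  n = length(d), undefined = TRUE))
    wt <- suppressWarnings(stats::wilcox.test(values, y, paired = TRUE,
                                              alternative = "two.sided"))
    return(list(design = design, statistic = unname(wt$statistic),
                p = wt$p.value, n = length(d), undefined = FALSE))
  }
  labels <- as.character(labels)
  groups <- unique(labels)
  if (design == "two_group") {
    if (length(groups) != 2) stop("two_group design needs exactly 2 groups")
    wt <- suppressWarnings(stats::wilcox.test(
      values[labels == groups[[1]]], values[labels == groups[[2]]],
      alternative = "two.sided"))
    list(design = design, statistic = unname(wt$statistic), p = wt$p.value,
         n = length(values), undefined = FALSE)
  } else {
    if (length(groups) < 3) stop("multi_group design needs >= 3 groups")
    kw <- stats::kruskal.test(values, factor(labels))
    list(design = design, statistic = unname(kw$statistic), p = kw$p.value,
         n = length(values), posthoc = dunn_posthoc(values, labels),
         undefined = FALSE)
  }
}

#' Sample-sample correlation matrix with adjusted p-values and clustered
#' ordering
#'
#' Pearson correlations between columns, two-sided p-values from the
#' t-distribution, adjusted for the k(k-1)/2 distinct pairs by Bonferroni or
#' BH. Columns are ordered by average-linkage hierarchical clustering on
#' 1 - r. Constant columns get missing correlations and are reported in the
#' `undefined` attribute.
#'
#' @param expr gene-by-sample matrix (>= 3 columns).
#' @param correction `"bonferroni"` or `"bh"`.
#' @return list: `r` (reordered correlation matrix), `padj` (matching
#'   adjusted p matrix, NA diagonal), `order` (column order), `undefined`
#'   (constant columns).
#' @export
correlation_matrix <- function(expr, correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  k <- ncol(expr)
  if (k < 3) stop("need >= 3 columns")
  sds <- apply(expr, 2, stats::sd)
  const <- colnames(expr)[sds == 0]
  r <- suppressWarnings(stats::cor(expr))
  diag(r) <- 1
  n <- nrow(expr)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  praw <- 2 * stats::pt(-abs(tt), df = n - 2)
  up <- upper.tri(praw)
  m <- sum(!is.na(praw[up]))
  padj <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  pv <- praw[up]
  adj <- if (correction == "bonferroni") pmin(pv * m, 1)
         else adjust_bh(pv)
  padj[up] <- adj
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  d_r <- r
  d_r[is.na(d_r)] <- 0
  ord <- stats::hclust(stats::as.dist(1 - d_r), method = "average")$order
  list(r = r[ord, ord], padj = padj[ord, ord], order = colnames(expr)[ord],
       undefined = const)
}

#' PCA embedding of the top expressed genes
#'
#' Restricts to the `k_top` genes with highest mean expression (see
#' [select_top_expressed()]), then runs centred PCA on samples. Loadings
#' follow a deterministic sign convention: the first nonzero loading of each
#' component is positive.
#'
#' @param expr gene-by-sample matrix (z-scores in the canonical pipeline).
#' @param k_top number of top genes to keep (default 2000).
#' @return list: `scores` (samples x components), `loadings` (genes x
#'   components), `explained` (proportion of variance per component,
#'   non-increasing).
#' @export
pca_embed <- function(expr, k_top = 2000) {
  if (nrow(expr) < 2 || ncol(expr) < 2) stop("need >= 2 genes and samples")
  top <- select_top_expressed(expr, min(k_top, nrow(expr)))
  if (k_top > nrow(expr))
    stop("k_top (", k_top, ") exceeds gene count (", nrow(expr), ")")
  pc <- stats::prcomp(t(top), center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) {
    nz <- v[v != 0]
    if (length(nz) > 0 && nz[[1]] < 0) -1 else 1
  })
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loadings, explained = explained)
}
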