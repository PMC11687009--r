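# Directional non-additive response classification. A gene is non-additive
# when its interaction term is significant (BH-adjusted LRT p < 0.05) and
# the non-additive effect is substantial (|delta| > 1 log2 unit), where
# delta = observed combined log2 FC minus the sum of the single-factor
# log2 FCs; by the model's construction delta equals the interaction
# coefficient betaAB. Non-additive genes are assigned an emergence category
# by which single factors they respond to, and a direction: positive
# synergism (delta > 0, combined response above additive expectation) or
# antagonism (delta < 0).

NONADD_CATEGORIES <- c("from_neither", "from_A_only", "from_B_only",
                       "from_both")

#' Expected vs observed combined response
#'
#' The additive expectation for the combined condition is the sum of the two
#' single-factor log2 fold-changes; the non-additive effect delta is the
#' observed combined log2 fold-change minus that expectation.
#'
#' @param fits data.frame from [fit_interaction()].
#' @return data.frame with columns gene, expected_log2fc, observed_log2fc,
#'   delta.
#' @export
expected_vs_observed <- function(fits) {
  need <- c("lfc_A", "lfc_B", "lfc_AB")
  if (!all(need %in% names(fits)))
    stop("fits lack contrast column(s): ",
         paste(setdiff(need, names(fits)), collapse = ", "))
  expected <- fits$lfc_A + fits$lfc_B
  observed <- fits$lfc_AB
  data.frame(gene = fits$gene, expected_log2fc = expected,
             observed_log2fc = observed, delta = observed - expected,
             stringsAsFactors = FALSE)
}

#' Classify genes as non-additive responders
#'
#' Applies the joint rule (interaction `padj < padj_threshold` and
#' `|delta| > delta_threshold`), determines single-factor responder status
#' from the contrast adjusted p-values, and assigns emergence category and
#' direction. Non-converged fits yield a missing `is_nonadditive` with
#' category and direction unset.
#'
#' @param fits data.frame from [fit_interaction()] (one or more rows).
#' @param padj_threshold interaction significance threshold (default 0.05).
#' @param delta_threshold non-additive effect floor, log2 units, strict
#'   (default 1).
#' @param deg_threshold single-factor responder threshold on adjusted p
#'   (default 0.05).
#' @return data.frame with columns gene, responder_A, responder_B, delta,
#'   padj_interaction, is_nonadditive, category, direction.
#' @export
classify_genes <- function(fits, padj_threshold = 0.05, delta_threshold = 1,
                           deg_threshold = 0.05) {
  evo <- expected_vs_observed(fits)
  delta <- evo$delta
  padj <- fits$padj_interaction
  conv <- if ("converged" %in% names(fits)) fits$converged & !is.na(padj)
          else !is.na(padj)
  resp_A <- as.logical(call_degs(fits, "A", deg_threshold))
  resp_B <- as.logical(call_degs(fits, "B", deg_threshold))
  is_na_call <- ifelse(conv, padj < padj_threshold &
                               !is.na(delta) & abs(delta) > delta_threshold,
                       NA)
  category <- rep(NA_character_, nrow(fits))
  direction <- rep("none", nrow(fits))
  hit <- !is.na(is_na_call) & is_na_call
  category[hit] <- ifelse(resp_A[hit] & resp_B[hit], "from_both",
                   ifelse(resp_A[hit], "from_A_only",
                   ifelse(resp_B[hit], "from_B_only", "from_neither")))
  direction[hit] <- ifelse(delta[hit] > 0, "positive_synergism", "antagonism")
  direction[is.na(is_na_call)] <- NA_character_
  data.frame(gene = fits$gene, responder_A = resp_A, responder_B = resp_B,
             delta = delta, padj_interaction = padj,
             is_nonadditive = is_na_call, category = category,
             direction = direction, stringsAsFactors = FALSE)
}

#' Classify a single gene fit
#'
#' @param fit one-row data.frame from [fit_interaction()].
#' @inheritParams classify_genes
#' @return one-row data.frame as in [classify_genes()].
#' @export
classify_gene <- function(fit, padj_threshold = 0.05, delta_threshold = 1,
                          deg_threshold = 0.05) {
  stopifnot(nrow(fit) == 1)
  classify_genes(fit, padj_threshold, delta_threshold, deg_threshold)
}

#' Classify all response genes and summarize emergence categories
#'
#' Restricts classification to a retained response-gene set (typically from
#' [response_gene_filter()]), then counts non-additive genes per emergence
#' category. The four categories are disjoint and partition the non-additive
#' set, so the summary counts always sum to the non-additive total.
#'
#' @param fits data.frame from [fit_interaction()].
#' @param retained character vector of gene ids to classify; `NULL` uses all
#'   fitted genes.
#' @inheritParams classify_genes
#' @return list with `calls` (per-gene data.frame) and `summary` (named
#'   counts per category plus `total`).
#' @export
classify_all <- function(fits, retained = NULL, padj_threshold = 0.05,
                         delta_threshold = 1, deg_threshold = 0.05) {
  if (!is.null(retained)) {
    missing <- setdiff(retained, fits$gene)
    if (length(missing) > 0)
      stop("no fit for retained gene(s): ", paste(missing, collapse = ", "))
    fits <- fits[fits$gene %in% retained, , drop = FALSE]
  }
  if (nrow(fits) == 0) {
    empty <- stats::setNames(integer(length(NONADD_CATEGORIES)),
                             NONADD_CATEGORIES)
    return(list(calls = classify_genes(fits[0, , drop = FALSE]),
                summary = c(empty, total = 0L)))
  }
  calls <- classify_genes(fits, padj_threshold, delta_threshold,
                          deg_threshold)
  hit <- !is.na(calls$is_nonadditive) & calls$is_nonadditive
  counts <- table(factor(calls$category[hit], levels = NONADD_CATEGORIES))
  summary <- c(stats::setNames(as.integer(counts), NONADD_CATEGORIES),
               total = sum(hit))
  list(calls = calls, summary = summary)
}
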