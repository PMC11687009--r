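# Gene-set enrichment: signal-to-noise ranking, weighted running-sum
# enrichment score (weight exponent 1), gene-set permutation null with
# sign-stratified NES and FDR, leading-edge subsets, core genes across
# leading edges, and hypergeometric overlap enrichment.

#' Rank genes by signal-to-noise ratio between two groups
#'
#' Per gene: (mean1 - mean2) / (sd1 + sd2), with each group SD floored at
#' max(sd, 0.2 |mean|, 0.2) to avoid blow-ups on low-variance genes. The
#' result is sorted descending; ties are broken by lexicographic gene id.
#'
#' @param expr gene-by-sample matrix (z-scores of log2(TPM+1) in the
#'   canonical pipeline, but any scale works).
#' @param groups vector of two group labels aligned to columns.
#' @param ref label treated as group 1 (positive scores = higher there);
#'   defaults to the first level encountered.
#' @return named numeric vector of scores, sorted descending.
#' @export
rank_genes <- function(expr, groups, ref = NULL) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  if (is.null(ref)) ref <- lev[[1]]
  g1 <- groups == ref
  if (sum(g1) < 2 || sum(!g1) < 2) stop("each group needs >= 2 samples")
  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m2 <- rowMeans(expr[, !g1, drop = FALSE])
  s1 <- apply(expr[, g1, drop = FALSE], 1, stats::sd)
  s2 <- apply(expr[, !g1, drop = FALSE], 1, stats::sd)
  floor_sd <- function(s, m) pmax(s, 0.2 * abs(m), 0.2)
  score <- (m1 - m2) / (floor_sd(s1, m1) + floor_sd(s2, m2))
  score <- score[order(-score, names(score))]
  score
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list; at a set member ("hit") the running sum rises by
#' |score|^1 normalized by the sum over all hits, at a non-member it falls
#' by 1/(N - N_hit). The enrichment score is the running-sum value of
#' maximal absolute deviation from zero (signed).
#'
#' @param scores named numeric vector sorted descending (from
#'   [rank_genes()]).
#' @param set character vector of member gene ids.
#' @return list with `es`, `running` (the full running sum) and `peak`
#'   (index of the extreme deviation).
#' @export
enrichment_score <- function(scores, set) {
  genes <- names(scores)
  hits <- genes %in% set
  n_hit <- sum(hits)
  if (n_hit == 0) stop("gene set does not intersect the ranked universe")
  if (n_hit == length(genes))
    stop("gene set equals the ranked universe; misses are undefined")
  w <- abs(scores)
  denom <- sum(w[hits])
  inc <- ifelse(hits, if (denom > 0) w / denom else 1 / n_hit,
                -1 / (length(genes) - n_hit))
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  list(es = running[[peak]], running = unname(running), peak = peak)
}

#' Gene-set enrichment with a gene-set permutation null
#'
#' For each set, the null distribution of the enrichment score is built from
#' `n_perm` random gene sets of equal size drawn from the ranked universe.
#' The permutation p-value is the fraction of same-sign null scores at least
#' as extreme, with +1 smoothing in numerator and denominator. NES divides
#' the score by the mean magnitude of same-sign null scores. FDR q is the
#' sign-stratified ratio of the null tail fraction (pooled across sets) to
#' the observed tail fraction at each set's |NES|, clamped to \[0, 1\].
#'
#' @param scores named numeric vector sorted descending.
#' @param sets named list of gene sets.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer RNG seed.
#' @return data.frame: set, size (members in universe), es, nes, p_perm,
#'   q_fdr, peak, leading_edge (comma-joined gene ids).
#' @export
gsea_permutation <- function(scores, sets, n_perm = 1000, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  genes <- names(scores)
  sizes <- vapply(sets, function(s) sum(genes %in% s), 1L)
  if (any(sizes == 0))
    stop("set(s) with empty universe intersection: ",
         paste(names(sets)[sizes == 0], collapse = ", "))
  if (any(sizes >= length(genes)))
    stop("set(s) as large as the universe: ",
         paste(names(sets)[sizes >= length(genes)], collapse = ", "))

  obs <- lapply(sets, function(s) enrichment_score(scores, s))
  es <- vapply(obs, function(o) o$es, 1)

  null_es <- with_seed(seed, {
    lapply(unique(sizes), function(k) {
      vapply(seq_len(n_perm), function(i)
        enrichment_score(scores, sample(genes, k))$es, 1)
    })
  })
  names(null_es) <- as.character(unique(sizes))

  nes <- p_perm <- numeric(length(sets))
  null_nes_all <- numeric(0)
  nulls_by_set <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    nul <- null_es[[as.character(sizes[[i]])]]
    same <- if (es[[i]] >= 0) nul[nul >= 0] else nul[nul < 0]
    p_perm[[i]] <- (sum(abs(same) >= abs(es[[i]])) + 1) / (length(same) + 1)
    scale <- mean(abs(same))
    nes[[i]] <- if (length(same) > 0 && scale > 0) es[[i]] / scale else NA_real_
    nulls_by_set[[i]] <- if (length(same) > 0 && scale > 0) same / scale
                         else numeric(0)
  }
  null_nes_all <- unlist(nulls_by_set)

  q_fdr <- vapply(seq_along(sets), function(i) {
    if (is.na(nes[[i]])) return(NA_real_)
    null_frac <- mean(abs(null_nes_all) >= abs(nes[[i]]))
    obs_frac <- mean(abs(nes) >= abs(nes[[i]]), na.rm = TRUE)
    if (obs_frac == 0) return(NA_real_)
    min(1, max(0, null_frac / obs_frac))
  }, 1)

  le <- vapply(seq_along(sets), function(i)
    paste(leading_edge(obs[[i]], scores, sets[[i]]), collapse = ","),
    character(1))
  data.frame(set = names(sets), size = as.integer(sizes), es = es, nes = nes,
             p_perm = p_perm, q_fdr = q_fdr,
             peak = vapply(obs, function(o) o$peak, 1L),
             leading_edge = le, stringsAsFactors = FALSE, row.names = NULL)
}

#' Leading-edge subset of a gene set
#'
#' For a positive enrichment score, the set members ranked at or before the
#' running-sum peak; for a negative score, the members at or after the peak.
#' A zero score yields an empty subset (flagged with a warning).
#'
#' @param result list from [enrichment_score()] (elements `es`, `peak`).
#' @param scores the ranked scores the result was computed on.
#' @param set the gene set.
#' @return character vector of leading-edge gene ids (in rank order).
#' @export
leading_edge <- function(result, scores, set) {
  genes <- names(scores)
  hits <- genes %in% set
  if (result$es == 0) {
    warning("enrichment score is zero; leading edge undefined")
    return(character(0))
  }
  idx <- if (result$es > 0) seq_len(result$peak)
         else result$peak:length(genes)
  genes[idx][hits[idx]]
}

#' Core genes across leading-edge subsets
#'
#' Genes present in at least `min_occurrence` of the supplied leading-edge
#' subsets, sorted by occurrence (descending) then gene id.
#'
#' @param leading_edges list of character vectors.
#' @param min_occurrence minimum number of subsets (default 3).
#' @return data.frame with columns gene, occurrences.
#' @export
core_genes <- function(leading_edges, min_occurrence = 3) {
  if (length(leading_edges) < min_occurrence)
    stop("need at least min_occurrence (", min_occurrence, ") subsets")
  tab <- table(unlist(lapply(leading_edges, unique)))
  keep <- tab[tab >= min_occurrence]
  if (length(keep) == 0)
    return(data.frame(gene = character(0), occurrences = integer(0),
                      stringsAsFactors = FALSE))
  df <- data.frame(gene = names(keep), occurrences = as.integer(keep),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$occurrences, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Hypergeometric overlap enrichment of a query set against a collection
#'
#' For each collection set, p = P(X >= observed overlap) under the
#' hypergeometric distribution on the universe; q is the BH adjustment
#' across the collection.
#'
#' @param query character vector of gene ids (subset of universe).
#' @param collection named list of gene sets.
#' @param universe character vector of all eligible gene ids.
#' @return data.frame: set, set_size (in universe), overlap, p, q.
#' @export
overlap_enrichment <- function(query, collection, universe) {
  if (length(universe) == 0) stop("universe is empty")
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query contains gene(s) outside the universe")
  res <- t(vapply(collection, function(s) {
    s <- intersect(unique(s), universe)
    ov <- length(intersect(query, s))
    p <- if (ov == 0) 1
         else stats::phyper(ov - 1, length(s), length(universe) - length(s),
                            length(query), lower.tail = FALSE)
    c(set_size = length(s), overlap = ov, p = p)
  }, numeric(3)))
  data.frame(set = names(collection), set_size = as.integer(res[, "set_size"]),
             overlap = as.integer(res[, "overlap"]), p = res[, "p"],
             q = adjust_bh(res[, "p"]), stringsAsFactors = FALSE,
             row.names = NULL)
}
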