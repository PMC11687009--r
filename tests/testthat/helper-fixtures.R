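# Shared fixtures and independent oracles used across test files.

# A GeneFit-shaped row built directly from stated quantities, bypassing the
# fitting engine, so classifier rules can be checked in isolation.
make_fit_row <- function(gene = "g1", lfc_A = 0, lfc_B = 0, lfc_AB = 0,
                         padj_interaction = 1, padj_A = 1, padj_B = 1,
                         padj_AB = 1, converged = TRUE) {
  data.frame(gene = gene, lfc_A = lfc_A, lfc_B = lfc_B, lfc_AB = lfc_AB,
             padj_interaction = padj_interaction, padj_A = padj_A,
             padj_B = padj_B, padj_AB = padj_AB, converged = converged,
             stringsAsFactors = FALSE)
}

# Independent brute-force running-sum oracle for the enrichment score:
# a literal element-by-element walk, no vectorization shared with the
# implementation.
es_bruteforce <- function(scores, set) {
  genes <- names(scores)
  n <- length(genes)
  n_hit <- sum(genes %in% set)
  denom <- 0
  for (g in seq_len(n)) if (genes[g] %in% set) denom <- denom + abs(scores[[g]])
  running <- numeric(n)
  acc <- 0
  for (g in seq_len(n)) {
    if (genes[g] %in% set) acc <- acc + abs(scores[[g]]) / denom
    else acc <- acc - 1 / (n - n_hit)
    running[g] <- acc
  }
  best <- 1
  for (g in seq_len(n)) if (abs(running[g]) > abs(running[best])) best <- g
  list(es = running[best], peak = best)
}

# A tiny balanced 2x2 design with r replicates per condition.
toy_design <- function(r = 3) {
  data.frame(sample = sprintf("s%02d", seq_len(4 * r)),
             knockdown = rep(c(0L, 1L, 0L, 1L), each = r),
             cytokine = rep(c(0L, 0L, 1L, 1L), each = r),
             replicate = rep(seq_len(r), 4),
             stringsAsFactors = FALSE)
}

# Counts whose condition means are exactly the given values (every replicate
# equal to the mean), for closed-form checks at zero dispersion.
toy_counts_exact <- function(means, r = 3, genes = "g1") {
  d <- toy_design(r)
  m <- matrix(rep(rep(means, each = r), length(genes)),
              nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, d$sample))
  storage.mode(m) <- "integer"
  m
}
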