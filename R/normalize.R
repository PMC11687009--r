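# Abundance-unit conversions, expression filters and qPCR relative
# quantification. Matrices carry a declared unit in attr(, "unit"); each
# operation checks it when present and stamps its output.

check_unit <- function(m, expected) {
  u <- attr(m, "unit")
  if (!is.null(u) && !u %in% expected)
    stop("matrix unit is '", u, "', expected ",
         paste(expected, collapse = " or "))
  invisible(TRUE)
}

stamp <- function(m, unit) { attr(m, "unit") <- unit; m }

#' Convert FPKM to TPM
#'
#' Per sample j: \eqn{TPM_i = FPKM_i / \sum_k FPKM_k \cdot 10^6}, so every
#' column of the result sums to one million and within-sample proportions are
#' preserved.
#'
#' @param m non-negative gene-by-sample matrix in FPKM.
#' @return matrix in TPM (unit attribute set to `"TPM"`).
#' @export
fpkm_to_tpm <- function(m) {
  check_unit(m, "FPKM")
  if (any(m < 0)) stop("FPKM values must be non-negative")
  cs <- colSums(m)
  if (any(cs == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(m)[cs == 0], collapse = ", "))
  stamp(sweep(m, 2, cs, "/") * 1e6, "TPM")
}

#' Log-transform TPM as log2(TPM + 1)
#'
#' @param m non-negative matrix in TPM.
#' @return matrix of log2(TPM + 1) values (unit `"log2TPM1"`).
#' @export
log2_tpm1 <- function(m) {
  check_unit(m, "TPM")
  if (any(m < 0)) stop("TPM values must be non-negative")
  stamp(log2(m + 1), "log2TPM1")
}

#' Row-standardize genes to z-scores
#'
#' Each gene row is centred and scaled by its sample standard deviation
#' (divisor n - 1). Genes with zero variance are returned as all-zero rows
#' and listed in the `constant_genes` attribute.
#'
#' @param m matrix (log2-scale expected) with >= 2 samples.
#' @return z-score matrix (unit `"zscore"`) with attribute `constant_genes`.
#' @export
zscore_genes <- function(m) {
  check_unit(m, c("log2TPM1", "TPM", "zscore"))
  if (ncol(m) < 2) stop("z-scoring requires >= 2 samples")
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  const <- sd == 0 | !is.finite(sd)
  sd[const] <- 1
  z <- (m - mu) / sd
  z[const, ] <- 0
  z <- stamp(z, "zscore")
  attr(z, "constant_genes") <- rownames(m)[const]
  z
}

#' Drop genes below a TPM floor in every sample
#'
#' A gene is excluded when its expression is below `threshold` TPM in every
#' sample; any single sample at or above the threshold retains it. Gene order
#' is preserved.
#'
#' @param m matrix in TPM.
#' @param threshold TPM floor (default 3).
#' @return filtered matrix, same unit.
#' @export
filter_min_tpm <- function(m, threshold = 3) {
  check_unit(m, "TPM")
  if (nrow(m) == 0) return(m)
  keep <- apply(m, 1, max) >= threshold
  stamp(m[keep, , drop = FALSE], attr(m, "unit") %||% "TPM")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Keep the top k genes by mean expression
#'
#' Ranks genes by mean expression across all samples, descending; ties at
#' the cutoff are broken by lexicographic gene id so the selection is
#' deterministic.
#'
#' @param m gene-by-sample matrix.
#' @param k number of genes to keep (default 2000).
#' @return matrix restricted to the selected genes (highest mean first).
#' @export
select_top_expressed <- function(m, k = 2000) {
  if (k > nrow(m))
    stop("k (", k, ") exceeds the number of genes (", nrow(m), ")")
  ord <- order(-rowMeans(m), rownames(m))
  out <- m[ord[seq_len(k)], , drop = FALSE]
  attr(out, "unit") <- attr(m, "unit")
  out
}

#' Relative qPCR quantification by the 2^-ddCT method
#'
#' CT values are normalized to a housekeeping gene within each sample
#' (dCT = CT_target - CT_housekeeping), referenced to a calibrator sample
#' (ddCT = dCT_sample - dCT_calibrator) and expressed as fold-change
#' 2^-ddCT. Technical replicates (duplicated sample x gene rows) are averaged
#' before quantification. The calibrator maps to fold-change 1 for every gene.
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct`.
#' @param housekeeping housekeeping gene id (present in every sample).
#' @param calibrator calibrator sample id.
#' @return data.frame with columns `sample`, `gene`, `ddct`, `fold` for all
#'   non-housekeeping genes.
#' @export
ddct_quantify <- function(ct, housekeeping, calibrator) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  if (any(!is.finite(ct$ct))) stop("CT values must be finite")
  ag <- stats::aggregate(ct ~ sample + gene, data = ct, FUN = mean)
  samples <- unique(ag$sample)
  if (!calibrator %in% samples) stop("calibrator sample '", calibrator,
                                     "' not found")
  hk <- ag[ag$gene == housekeeping, ]
  missing_hk <- setdiff(samples, hk$sample)
  if (length(missing_hk) > 0)
    stop("housekeeping gene '", housekeeping, "' missing for sample(s): ",
         paste(missing_hk, collapse = ", "))
  hk_ct <- stats::setNames(hk$ct, hk$sample)
  tg <- ag[ag$gene != housekeeping, ]
  tg$dct <- tg$ct - hk_ct[tg$sample]
  cal <- tg[tg$sample == calibrator, ]
  cal_dct <- stats::setNames(cal$dct, cal$gene)
  missing_cal <- setdiff(unique(tg$gene), names(cal_dct))
  if (length(missing_cal) > 0)
    stop("calibrator lacks CT for gene(s): ",
         paste(missing_cal, collapse = ", "))
  tg$ddct <- tg$dct - cal_dct[tg$gene]
  tg$fold <- 2^(-tg$ddct)
  rownames(tg) <- NULL
  tg[, c("sample", "gene", "ddct", "fold")]
}
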