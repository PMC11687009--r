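# TSV readers/writers for the matrix-with-gene-id-column convention used
# throughout: header row = sample ids, first column = gene ids.

#' Write a gene-by-sample matrix as TSV
#'
#' First column holds gene ids (header `gene`), remaining columns one per
#' sample. The declared unit attribute, if any, is not serialized; callers
#' re-declare it on read.
#'
#' @param m numeric matrix with rownames (gene ids) and colnames (sample ids).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample matrix from TSV
#'
#' @param path TSV file written by [write_matrix_tsv()] (first column gene
#'   ids, header row sample ids).
#' @param unit optional unit label to attach (`"FPKM"`, `"TPM"`,
#'   `"log2TPM1"`, `"zscore"`, or `"counts"`).
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path, unit = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!is.null(unit)) attr(m, "unit") <- unit
  m
}

#' Write / read a factorial design table
#'
#' Columns: `sample`, `knockdown` (0/1), `cytokine` (0/1), `replicate`.
#' @param design data.frame as above.
#' @param path file path.
#' @return `path` (write) or the design data.frame (read).
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT format: one set per line, tab-separated fields `name`, `description`,
#' then member gene ids. Duplicate members within a set are collapsed with a
#' warning; duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": expected >= 3 tab-separated fields")
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop("malformed GMT line ", i, ": set '", f[[1]], "' has no members")
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", f[[1]], "' collapsed")
      members <- unique(members)
    }
    attr(members, "description") <- f[[2]]
    sets[[i]] <- members
    nms[[i]] <- f[[1]]
  }
  if (anyDuplicated(nms))
    stop("duplicate set name(s) in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute per set).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    d <- attr(sets[[nm]], "description")
    if (is.null(d)) d <- nm
    paste(c(nm, d, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
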