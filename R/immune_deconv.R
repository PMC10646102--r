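# Signature-matrix deconvolution of bulk expression into absolute cell-type
# fractions plus an uncharacterized remainder ("other"), in the style of
# quanTIseq: constrained (non-negative) least squares on marker genes.

#' Default immune signature matrix
#'
#' Restricts a reference profile matrix (see
#' [generate_reference_profiles()]) to the ten immune cell types and their
#' marker genes, yielding the packaged default deconvolution signature. A
#' user-supplied matrix (e.g. a published immune signature such as TIL10)
#' is a drop-in replacement via a genes x cell-types TSV.
#'
#' @param reference genes x cell-types matrix including a "Tumor" column.
#' @return marker genes x ten immune types matrix.
#' @export
default_signature_matrix <- function(reference) {
  immune <- setdiff(colnames(reference), "Tumor")
  markers <- rownames(reference)[grepl("^MK\\.", rownames(reference)) &
                                   !grepl("^MK\\.Tumor\\.", rownames(reference))]
  reference[markers, immune, drop = FALSE]
}

#' Deconvolve bulk expression into cell-type fractions
#'
#' For each sample, solves a non-negative least-squares problem on the
#' signature marker genes: the sample's TPM-renormalized expression vector
#' is regressed on the signature columns (expected TPM profiles per cell
#' type), giving absolute cell-type weights. Weights are divided by the
#' per-type mRNA-content scale (default 1 for all types, which preserves
#' the ranking and correlation structure used downstream), the remainder
#' `other = max(0, 1 - sum(weights))` absorbs unexplained signal, and rows
#' are renormalized to the simplex.
#'
#' Marker genes missing from the mixture are dropped from both sides (not
#' zero-filled); if more than half the signature markers are absent the
#' call errors.
#'
#' @param expr genes x samples TPM matrix.
#' @param sig marker genes x cell types signature matrix (TPM-scale
#'   expected expression; no zero columns, no duplicated markers).
#' @param mrna_scale optional named per-type mRNA content scale.
#' @return samples x (cell types + "other") fraction matrix; every entry in
#'   `[0, 1]`, rows sum to 1.
#' @export
deconvolve <- function(expr, sig, mrna_scale = NULL) {
  if (anyDuplicated(rownames(sig))) abort("duplicate marker genes in signature")
  if (any(colSums(sig) == 0)) abort("signature has an all-zero cell-type column")
  types <- colnames(sig)
  if (is.null(mrna_scale)) mrna_scale <- stats::setNames(rep(1, length(types)), types)
  markers <- intersect(rownames(sig), rownames(expr))
  if (length(markers) < 0.5 * nrow(sig)) {
    abort("only ", length(markers), "/", nrow(sig),
          " signature marker genes present in expression matrix (>= 50% required)")
  }
  if (length(markers) < nrow(sig)) {
    message("deconvolve: dropping ", nrow(sig) - length(markers),
            " signature marker(s) absent from the mixture")
  }
  S <- sig[markers, , drop = FALSE]
  out <- matrix(0, ncol(expr), length(types) + 1,
                dimnames = list(colnames(expr), c(types, "other")))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    tot <- sum(x)
    if (tot == 0) abort("all-zero expression vector for sample '",
                        colnames(expr)[j], "'")
    x <- x[markers] * (1e6 / tot)      # renormalize to TPM over supplied genes
    w <- pracma::lsqnonneg(S, x)$x
    w <- pmax(w, 0) / mrna_scale[types]
    other <- max(0, 1 - sum(w))
    out[j, ] <- c(w, other) / max(1, sum(w) + other)
  }
  out
}

#' Read a signature matrix from TSV
#'
#' First column marker gene symbols, remaining columns cell types.
#'
#' @param path TSV path.
#' @return genes x cell types numeric matrix.
#' @export
read_signature_matrix <- function(path) {
  df <- read_tsv_table(path)
  mat <- as.matrix(as.data.frame(lapply(df[-1], function(col)
    parse_numeric(col, "signature value"))))
  rownames(mat) <- trimws(df[[1]])
  colnames(mat) <- names(df)[-1]
  if (any(mat < 0)) abort("validation error: negative signature value")
  mat
}
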