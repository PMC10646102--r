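# Readers, writers, and validation for every on-disk artifact the pipeline
# touches. All tables are UTF-8 TSV with a header row; gene symbols are
# matched case-sensitively after whitespace trimming (no alias resolution).

VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "splice",
                     "synonymous", "other")
PATHOGENICITY_LEVELS <- c("pathogenic", "likely_pathogenic", "VUS",
                          "likely_benign", "benign")

#' Read a TPM expression matrix
#'
#' Reads a tab-separated genes x samples matrix: first column gene symbols,
#' header row sample ids, cells non-negative TPM values. Duplicate gene
#' symbols are collapsed by taking the per-cell maximum TPM, with a warning
#' (a deterministic, conservative choice for signature scoring).
#'
#' @param path path to a TSV file.
#' @return A numeric matrix (genes x samples) with gene symbols as rownames
#'   and sample ids as colnames.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "TP53\t1.5\t2", "PTEN\t0\t7"), f)
#' read_expression(f)
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0 || !grepl("\t", first)) {
    abort("format error in ", basename(path),
          ": expected a tab-separated header row of sample ids")
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) abort("format error: expression matrix needs >= 1 sample column")
  genes <- trimws(df[[1]])
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) {
    abort("duplicate sample id in header: ",
          samples[duplicated(samples)][1])
  }
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    col <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(col))
    if (length(bad) > 0) {
      abort("validation error: non-numeric value '", df[[j + 1]][bad[1]],
            "' at gene '", genes[bad[1]], "', sample '", samples[j], "'")
    }
    vals[, j] <- col
  }
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort("validation error: negative TPM ", vals[neg[1, 1], neg[1, 2]],
          " at gene '", genes[neg[1, 1]], "', sample '",
          samples[neg[1, 2]], "'")
  }
  if (any(!is.finite(vals))) abort("validation error: non-finite TPM value")
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dup),
            " duplicated gene symbol(s) by maximum TPM: ",
            paste(utils::head(dup, 5), collapse = ", "),
            if (length(dup) > 5) ", ..." else "")
    vals <- do.call(rbind, lapply(split(seq_along(genes), genes), function(i) {
      apply(vals[i, , drop = FALSE], 2, max)
    }))
    # split() orders by factor level; restore first-appearance order
    vals <- vals[unique(genes), , drop = FALSE]
  } else {
    rownames(vals) <- genes
  }
  validate_expression(vals)
}

#' Validate an expression matrix
#'
#' Checks the invariants of the TPM matrix container: unique gene and sample
#' ids, finite non-negative values.
#'
#' @param mat numeric matrix, genes x samples, with dimnames.
#' @return the validated matrix, invisibly unchanged.
#' @export
validate_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) abort("expression must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    abort("expression matrix requires gene rownames and sample colnames")
  if (anyDuplicated(rownames(mat))) abort("duplicate gene symbols in expression matrix")
  if (anyDuplicated(colnames(mat))) abort("duplicate sample ids in expression matrix")
  if (any(!is.finite(mat))) abort("expression matrix contains non-finite values")
  if (any(mat < 0)) abort("expression matrix contains negative values")
  mat
}

#' Write a TPM expression matrix
#'
#' Inverse of [read_expression()]: full-precision round trip.
#'
#' @param mat genes x samples numeric matrix.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  validate_expression(mat)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  # 17 significant digits round-trip doubles exactly
  for (j in seq(2, ncol(df))) df[[j]] <- sprintf("%.17g", df[[j]])
  write_tsv_table(df, path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description field is
#' discarded; duplicate genes within a line are deduplicated.
#'
#' @param path path to a GMT file.
#' @return A named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (length(fields) < 3) {
      abort("format error in ", basename(path), " at line ", i,
            ": expected >= 3 tab-separated fields, found ", length(fields))
    }
    sets[[fields[1]]] <- unique(fields[-c(1, 2)])
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field per line (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' Required columns `sample_id` and `group` (PCM, MBM, or ECM); optional
#' columns `pdl1_positive` (logical), `age_band`, `sex` (empty string for
#' missing).
#'
#' @param path path to a TSV file.
#' @return data.frame with one row per sample.
#' @export
read_manifest <- function(path) {
  df <- read_tsv_table(path, required = c("sample_id", "group"))
  validate_manifest(data.frame(
    sample_id = trimws(df$sample_id),
    group = trimws(df$group),
    pdl1_positive = if ("pdl1_positive" %in% names(df))
      parse_logical(df$pdl1_positive, "pdl1_positive") else NA,
    age_band = if ("age_band" %in% names(df)) df$age_band else "",
    sex = if ("sex" %in% names(df)) df$sex else "",
    stringsAsFactors = FALSE))
}

#' Validate a cohort manifest
#' @param df data.frame with at least `sample_id` and `group`.
#' @return the validated data.frame.
#' @export
validate_manifest <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    abort("validation error: duplicate sample id in manifest: ",
          df$sample_id[duplicated(df$sample_id)][1])
  }
  check_enum(df$group, COHORT_GROUPS, "group label")
  df
}

#' Read a MAF-like somatic mutation table
#'
#' Required columns: `sample_id`, `gene`, `variant_class` (missense,
#' nonsense, frameshift, splice, synonymous, other), `pathogenicity`
#' (pathogenic, likely_pathogenic, VUS, likely_benign, benign),
#' `germline_flagged` (logical).
#'
#' @param path path to a TSV file.
#' @return data.frame of mutation records.
#' @export
read_mutations <- function(path) {
  df <- read_tsv_table(path, required = c("sample_id", "gene", "variant_class",
                                          "pathogenicity", "germline_flagged"))
  out <- data.frame(
    sample_id = trimws(df$sample_id),
    gene = trimws(df$gene),
    variant_class = check_enum(trimws(df$variant_class), VARIANT_CLASSES,
                               "variant_class"),
    pathogenicity = check_enum(trimws(df$pathogenicity), PATHOGENICITY_LEVELS,
                               "pathogenicity"),
    germline_flagged = parse_logical(df$germline_flagged, "germline_flagged"),
    stringsAsFactors = FALSE)
  if (any(is.na(out$germline_flagged)))
    abort("validation error: missing germline_flagged value")
  out
}

#' Read an HLA genotype table
#'
#' Required columns: `sample_id`, `locus` (one of the seven assessed HLA
#' loci), `allele1`, `allele2`.
#'
#' @param path path to a TSV file.
#' @return data.frame of genotype records.
#' @export
read_hla <- function(path) {
  df <- read_tsv_table(path, required = c("sample_id", "locus",
                                          "allele1", "allele2"))
  out <- data.frame(
    sample_id = trimws(df$sample_id),
    locus = check_enum(trimws(df$locus), HLA_LOCI, "HLA locus"),
    allele1 = trimws(df$allele1),
    allele2 = trimws(df$allele2),
    stringsAsFactors = FALSE)
  empty <- which(!nzchar(out$allele1) | !nzchar(out$allele2))
  if (length(empty) > 0) {
    abort("validation error: empty allele at row ", empty[1],
          " (sample ", out$sample_id[empty[1]], ")")
  }
  out
}

#' Read a neoantigen table
#'
#' Required columns: `sample_id`, `peptide`, `ic50` (binding affinity in
#' nmol/L; must be positive and finite).
#'
#' @param path path to a TSV file.
#' @return data.frame of neoantigen records.
#' @export
read_neoantigens <- function(path) {
  df <- read_tsv_table(path, required = c("sample_id", "peptide", "ic50"))
  ic50 <- parse_numeric(df$ic50, "ic50")
  bad <- which(!is.finite(ic50) | ic50 <= 0)
  if (length(bad) > 0) {
    abort("validation error: ic50 must be positive and finite; got ",
          df$ic50[bad[1]], " at row ", bad[1])
  }
  data.frame(sample_id = trimws(df$sample_id),
             peptide = trimws(df$peptide),
             ic50 = ic50, stringsAsFactors = FALSE)
}
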