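# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed cohort percentages use
#' conventional half-up rounding (47.826 -> 47.8, 21.978 -> 22.0).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop() with a consistent prefix and no call
abort <- function(...) stop(..., call. = FALSE)

# read a TSV with a header, keeping strings as-is
read_tsv_table <- function(path, required = NULL) {
  if (!file.exists(path)) abort("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = NULL, colClasses = "character")
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      abort("missing required column(s) in ", basename(path), ": ",
            paste(missing, collapse = ", "))
    }
  }
  df
}

# write a data.frame as UTF-8 TSV with header, no quoting, no row names
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# parse a character vector as numeric, error naming the offender
parse_numeric <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(x %in% c("NA", "")))
  if (length(bad) > 0) {
    abort("non-numeric value in ", what, ": '", x[bad[1]], "' (entry ", bad[1], ")")
  }
  out
}

# parse "TRUE"/"FALSE"/"1"/"0" flags
parse_logical <- function(x, what) {
  up <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[up %in% c("FALSE", "F", "0", "NO")] <- FALSE
  bad <- which(is.na(out) & !(up %in% c("", "NA")))
  if (length(bad) > 0) {
    abort("invalid logical value in ", what, ": '", x[bad[1]], "'")
  }
  out
}

check_enum <- function(x, allowed, what) {
  bad <- which(!(x %in% allowed))
  if (length(bad) > 0) {
    abort("invalid ", what, ": '", x[bad[1]], "' (row ", bad[1],
          "); allowed: ", paste(allowed, collapse = ", "))
  }
  x
}
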