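#' @keywords internal
"_PACKAGE"

# shared internal helpers: input checks, variant keys, vectorized Welch t,
# and TSV conventions (UTF-8, tab-delimited, "." for missing)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_input(sprintf("`%s` must be a single proportion in [0,1], got %s",
                       name, deparse(x)))
  invisible(x)
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop_input(sprintf("`%s` must be a positive integer, got %s",
                       name, deparse(x)))
  invisible(as.integer(x))
}

# genomic key identifying one variant allele
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Vectorized two-sided Welch t-test across matrix rows
#'
#' Computes, for every row of `mat`, the Welch (unequal-variance) t statistic
#' comparing samples in group 2 vs group 1, with Welch-Satterthwaite degrees
#' of freedom and two-sided p-values. This is the shared engine for both
#' differential methylation (beta values) and differential expression
#' (log2 values).
#'
#' @param mat numeric matrix, features x samples.
#' @param labels vector of length `ncol(mat)` with exactly two distinct
#'   values; the sorted second level is "group 2" (effect = mean2 - mean1).
#' @return data.frame with columns `mean1`, `mean2`, `delta` (mean2 - mean1),
#'   `t`, `df`, `p`.
#' @keywords internal
row_welch <- function(mat, labels) {
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L)
    stop_input("`labels` must contain exactly two groups, got ",
               length(lev))
  i1 <- which(as.character(labels) == lev[1L])
  i2 <- which(as.character(labels) == lev[2L])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L)
    stop_input("each group needs >= 2 samples for a Welch test")
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  v1 <- rowSums((mat[, i1, drop = FALSE] - m1)^2) / (n1 - 1L)
  v2 <- rowSums((mat[, i2, drop = FALSE] - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(tt), df)
  # constant rows in both groups: no evidence either way
  degenerate <- se2 == 0
  tt[degenerate] <- 0
  p[degenerate] <- 1
  df[degenerate] <- n1 + n2 - 2
  data.frame(mean1 = m1, mean2 = m2, delta = m2 - m1,
             t = tt, df = df, p = p)
}

#' Read / write the package's tab-delimited table format
#'
#' All on-disk tables are UTF-8 TSV with a header row and "." for missing.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_tsv_table` returns a data.frame.
#' @export
read_tsv_table <- function(path) {
  out <- utils::read.delim(path, sep = "\t", na.strings = ".",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  # conservative type conversion: plain "T"/"F" alleles stay character
  for (j in seq_along(out)) {
    v <- out[[j]]
    nonmiss <- v[!is.na(v)]
    if (!length(nonmiss)) next
    if (all(grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$",
                  nonmiss))) {
      out[[j]] <- as.numeric(v)
    } else if (all(nonmiss %in% c("TRUE", "FALSE"))) {
      out[[j]] <- as.logical(v)
    }
  }
  out
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  out <- x
  for (j in seq_along(out)) {
    v <- out[[j]]
    v <- as.character(v)
    v[is.na(v)] <- "."
    out[[j]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
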