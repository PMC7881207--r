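#' Pearson product-moment correlation with a total-function policy
#'
#' Standard Pearson correlation of two equal-length vectors. If either
#' vector is constant the correlation is undefined; the package defines it
#' as 0 and emits a warning so that QC reports stay total.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y))
  }
  if (length(x) < 3L) stop("pearson needs vectors of length >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant vector: correlation defined as 0")
    return(0)
  }
  stats::cor(x, y)
}

#' Replicate-pair correlation QC report
#'
#' Mirrors the replicate-sample quality check used for microarray cohorts:
#' each supplied sample pair passes when its Pearson correlation strictly
#' exceeds `threshold` ("over 0.9").
#'
#' @param m expression matrix.
#' @param pairs a data.frame/matrix with two columns of sample ids, or a
#'   list of length-2 character vectors. May be empty.
#' @param threshold pass threshold for r (default 0.9, strict `>`).
#' @return data.frame with columns `sample_a`, `sample_b`, `r`, `pass`.
#' @export
qc_report <- function(m, pairs, threshold = 0.9) {
  validate_expression_matrix(m)
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) {
      if (length(p) != 2L) stop("each QC pair must have exactly 2 sample ids")
      as.character(p)
    }))
  }
  if (is.null(pairs) || NROW(pairs) == 0L) {
    return(data.frame(sample_a = character(), sample_b = character(),
                      r = numeric(), pass = logical()))
  }
  pairs <- as.matrix(pairs)
  ids <- unique(as.character(pairs))
  unknown <- setdiff(ids, colnames(m))
  if (length(unknown)) {
    stop("unknown sample id(s) in QC pairs: ", paste(unknown, collapse = ", "))
  }
  a <- as.character(pairs[, 1L])
  b <- as.character(pairs[, 2L])
  if (any(a == b)) stop("QC pair with identical samples: ", a[a == b][1L])
  r <- mapply(function(i, j) pearson(m[, i], m[, j]), a, b, USE.NAMES = FALSE)
  data.frame(sample_a = a, sample_b = b, r = r, pass = r > threshold)
}

#' Write a QC report to TSV
#' @param report data.frame from [qc_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
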