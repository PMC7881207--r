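#' Ranked score-accumulation curve
#'
#' Sorts per-gene scores ascending (ties broken by gene identifier) and
#' returns the running sums — the cumulative profile whose plus/minus gap
#' tracks tumor-stage progression in the scoring narrative.
#'
#' @param scores named numeric vector (gene -> score), all finite.
#' @param kind optional label (`"s_plus"`, `"s_minus"`, `"n_plus"`,
#'   `"n_minus"`) stored on the result.
#' @return object of class `accumulation_curve`: data.frame with columns
#'   `rank`, `gene`, `score`, `cumulative`.
#' @export
accumulate_scores <- function(scores, kind = NULL) {
  if (length(scores) == 0L) stop("empty score map")
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("scores must be named by gene")
  }
  if (!all(is.finite(scores))) stop("scores must be finite")
  ord <- order(scores, names(scores))
  out <- data.frame(rank = seq_along(scores),
                    gene = names(scores)[ord],
                    score = unname(scores[ord]),
                    cumulative = cumsum(unname(scores[ord])))
  if (!is.null(kind)) attr(out, "kind") <- kind
  class(out) <- c("accumulation_curve", class(out))
  out
}

#' Largest gap between two accumulation curves
#'
#' Maximum over ranks of `plus$cumulative - minus$cumulative`, the summary
#' used to compare positive and negative network influence globally.
#'
#' @param plus,minus `accumulation_curve`s of equal length.
#' @return the largest pointwise difference (may be negative).
#' @export
largest_gap <- function(plus, minus) {
  stopifnot(inherits(plus, "accumulation_curve"),
            inherits(minus, "accumulation_curve"))
  if (nrow(plus) != nrow(minus)) {
    stop("curve length mismatch: ", nrow(plus), " vs ", nrow(minus))
  }
  max(plus$cumulative - minus$cumulative)
}

#' Write an accumulation curve to TSV
#' @param curve an `accumulation_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_accumulation_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
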