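#' TS-by-DE Pearson correlation matrix
#'
#' Correlates every TS gene row with every DE gene row across the scoped
#' samples. With `sample_scope = "all"` the correlation is computed across
#' normal and tumor samples jointly (cross-condition co-variation, the
#' default); `"tumor_only"` restricts to tumor samples and isolates
#' within-condition co-expression.
#'
#' @param ts_expr expression matrix of TS genes (rows).
#' @param de_expr expression matrix of DE genes (rows); must share identical
#'   sample columns with `ts_expr`.
#' @param sample_scope `"all"` or `"tumor_only"`.
#' @param samples sample table; required for `"tumor_only"`.
#' @return object of class `correlation_matrix`: list with `r` (TS x DE
#'   matrix), `ts_ids`, `de_ids`, `n_samples`. Constant rows yield r = 0
#'   with a warning.
#' @export
correlation_matrix <- function(ts_expr, de_expr,
                               sample_scope = c("all", "tumor_only"),
                               samples = NULL) {
  sample_scope <- match.arg(sample_scope)
  validate_expression_matrix(ts_expr)
  validate_expression_matrix(de_expr)
  if (!identical(colnames(ts_expr), colnames(de_expr))) {
    stop("TS and DE matrices must share identical sample columns")
  }
  if (sample_scope == "tumor_only") {
    if (is.null(samples)) stop("tumor_only scope needs a sample table")
    idx <- match(colnames(ts_expr), samples$sample_id)
    if (anyNA(idx)) stop("sample(s) missing from sample table")
    keep <- samples$condition[idx] == "tumor"
    ts_expr <- ts_expr[, keep, drop = FALSE]
    de_expr <- de_expr[, keep, drop = FALSE]
  }
  n <- ncol(ts_expr)
  if (n < 3L) stop("need >= 3 scoped samples, have ", n)
  const_ts <- apply(ts_expr, 1L, function(x) all(x == x[1L]))
  const_de <- apply(de_expr, 1L, function(x) all(x == x[1L]))
  r <- suppressWarnings(stats::cor(t(ts_expr), t(de_expr)))
  if (any(const_ts) || any(const_de)) {
    warning(sum(const_ts) + sum(const_de),
            " constant row(s): correlations defined as 0")
    r[const_ts, ] <- 0
    r[, const_de] <- 0
  }
  structure(list(r = r, ts_ids = rownames(ts_expr), de_ids = rownames(de_expr),
                 n_samples = n),
            class = "correlation_matrix")
}

#' Bonferroni-calibrated correlation threshold T
#'
#' The correlation cutoff corresponding to a Bonferroni-adjusted
#' t-distribution quantile: with `df = n_samples - 2` and cutoff probability
#' `p = alpha / m_tests` (halved first when `tails = "two"`), take
#' `t = qt(p, df)` and map it to the correlation scale via
#' `T = |t| / sqrt(t^2 + df)`. The one-tailed variant is the literal reading
#' of the published recipe; the two-tailed variant matches standard
#' critical-r tables.
#'
#' @param alpha family-wise significance level (default 0.05).
#' @param m_tests number of tests Bonferroni-corrected for (typically the
#'   number of DE genes at the stage).
#' @param n_samples number of samples entering each correlation (>= 3).
#' @param tails `"one"` (default) or `"two"`.
#' @return object of class `threshold_spec`: list with `alpha`, `m_tests`,
#'   `n_samples`, `tails`, `df`, `p`, `t`, `T` (strictly in \[0, 1)).
#' @export
correlation_threshold <- function(alpha = 0.05, m_tests, n_samples,
                                  tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (m_tests < 1L) stop("m_tests must be >= 1")
  if (n_samples < 3L) stop("n_samples must be >= 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  p <- alpha / m_tests
  if (p >= 1) stop("alpha/m_tests must be < 1")
  if (tails == "two") p <- p / 2
  df <- n_samples - 2L
  t <- stats::qt(p, df)
  Tval <- abs(t) / sqrt(t^2 + df)
  structure(list(alpha = alpha, m_tests = as.integer(m_tests),
                 n_samples = as.integer(n_samples), tails = tails,
                 df = df, p = p, t = t, T = Tval),
            class = "threshold_spec")
}

#' Positive correlation-mass score S+
#'
#' Proportion of a TS gene's positive correlation mass that clears the
#' threshold: `sum(r_j | r_j >= T) / sum(r_j | r_j > 0)`. Defined as 0 when
#' the gene has no positively correlated DE partner.
#'
#' @param row numeric vector of correlation coefficients.
#' @param T threshold in (0, 1).
#' @return score in \[0, 1\].
#' @export
s_plus <- function(row, T) {
  .check_T(T)
  den <- sum(row[row > 0])
  if (den == 0) return(0)
  sum(row[row >= T]) / den
}

#' Negative correlation-mass score S-
#'
#' Mirror of [s_plus()] on the negative side:
#' `sum(r_j | r_j <= -T) / sum(r_j | r_j < 0)` (a ratio of two negative
#' sums, hence in \[0, 1\]); 0 when there is no negative entry.
#'
#' @inheritParams s_plus
#' @return score in \[0, 1\].
#' @export
s_minus <- function(row, T) {
  .check_T(T)
  den <- sum(row[row < 0])
  if (den == 0) return(0)
  sum(row[row <= -T]) / den
}

#' Signed supra-threshold correlation sum S
#'
#' `sum(r_j | |r_j| >= T)`: positive when the supra-threshold positive mass
#' (association with down-regulation) outweighs the negative mass.
#'
#' @inheritParams s_plus
#' @return unbounded signed sum.
#' @export
s_score <- function(row, T) {
  .check_T(T)
  sum(row[abs(row) >= T])
}

.check_T <- function(T) {
  if (!is.numeric(T) || length(T) != 1L || T <= 0 || T >= 1) {
    stop("T must be a single value in (0, 1)")
  }
}

#' Per-TS-gene S-score table
#'
#' Applies [s_plus()], [s_minus()] and [s_score()] to every row of a
#' TS-by-DE correlation matrix and records the counts backing each ratio.
#'
#' @param R a `correlation_matrix`.
#' @param T threshold in (0, 1) (see [correlation_threshold()]).
#' @return data.frame with columns `gene`, `s_plus`, `s_minus`, `s`,
#'   `n_pos_sig` (count of r >= T), `n_neg_sig` (count of r <= -T).
#' @export
score_table <- function(R, T) {
  stopifnot(inherits(R, "correlation_matrix"))
  .check_T(T)
  rows <- lapply(seq_along(R$ts_ids), function(i) {
    r <- R$r[i, ]
    data.frame(gene = R$ts_ids[i],
               s_plus = s_plus(r, T),
               s_minus = s_minus(r, T),
               s = s_score(r, T),
               n_pos_sig = sum(r >= T),
               n_neg_sig = sum(r <= -T))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
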