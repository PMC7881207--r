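#' Benjamini-Hochberg step-up adjustment
#'
#' Hand-rolled step-up procedure: for the ascending order statistics,
#' `q_(i) = min_{j >= i} p_(j) * n / j`, capped at 1, returned in the input
#' order. Authored here (rather than delegated) so it can be checked against
#' an independent brute-force oracle.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- pmin(1, rev(cummin(rev(ps * n / seq_len(n)))))
  out <- numeric(n)
  out[ord] <- q
  out
}

#' Tumor-vs-normal differential expression (Welch t + BH)
#'
#' The shipped surrogate for the differential-expression stage: per-probe
#' Welch unequal-variance t-test (tumor minus normal on the log scale)
#' followed by Benjamini-Hochberg adjustment; a probe is significant when
#' `q < fdr`. The default test is unpaired; `paired = TRUE` uses the
#' subject pairing from the sample table instead.
#'
#' Degenerate probes are made total: zero variance in both groups with
#' equal means gives p = 1; zero variance with unequal means gives the
#' machine-minimum p and is flagged in the `degenerate` column.
#'
#' @param m expression matrix.
#' @param samples sample table covering the columns of `m` with >= 2 samples
#'   per condition.
#' @param fdr significance level on BH-adjusted q (default 0.01).
#' @param paired use a paired t-test over `subject_id` pairs.
#' @return data.frame sorted by `q` ascending (ties by `probe_id`) with
#'   columns `probe_id`, `statistic`, `mean_diff`, `p`, `q`, `significant`,
#'   `direction`, `degenerate`.
#' @export
de_test <- function(m, samples, fdr = 0.01, paired = FALSE) {
  validate_expression_matrix(m)
  idx <- match(colnames(m), samples$sample_id)
  if (anyNA(idx)) {
    stop("sample(s) missing from sample table: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  }
  st <- samples[idx, , drop = FALSE]
  tum <- st$condition == "tumor"
  nrm <- st$condition == "normal"
  if (sum(tum) < 2L || sum(nrm) < 2L) {
    stop("need >= 2 samples per condition (tumor: ", sum(tum),
         ", normal: ", sum(nrm), ")")
  }
  if (paired) {
    res <- .paired_t(m, st, tum, nrm)
  } else {
    res <- .welch_t(m[, tum, drop = FALSE], m[, nrm, drop = FALSE])
  }
  q <- bh_adjust(res$p)
  significant <- q < fdr
  direction <- rep("none", nrow(m))
  direction[significant & res$mean_diff > 0] <- "up"
  direction[significant & res$mean_diff < 0] <- "down"
  out <- data.frame(probe_id = rownames(m),
                    statistic = res$statistic,
                    mean_diff = res$mean_diff,
                    p = res$p, q = q,
                    significant = significant,
                    direction = direction,
                    degenerate = res$degenerate)
  out <- out[order(out$q, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# vectorized Welch unequal-variance t-test, tumor (x) minus normal (y)
.welch_t <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1L)
  v2 <- rowSums((y - m2)^2) / (n2 - 1L)
  diff <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  se <- sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  stat <- diff / se
  p <- 2 * stats::pt(-abs(stat), df)
  degenerate <- se == 0
  # totality on degenerate rows
  zero_eq <- degenerate & diff == 0
  zero_ne <- degenerate & diff != 0
  stat[zero_eq] <- 0;               p[zero_eq] <- 1
  stat[zero_ne] <- sign(diff[zero_ne]) * Inf
  p[zero_ne] <- .Machine$double.xmin
  degenerate <- zero_ne  # only the unequal-mean case is worth flagging
  list(statistic = unname(stat), mean_diff = unname(diff),
       p = unname(p), degenerate = unname(degenerate))
}

.paired_t <- function(m, st, tum, nrm) {
  subj_t <- st$subject_id[tum]
  subj_n <- st$subject_id[nrm]
  common <- intersect(subj_t, subj_n)
  if (length(common) < 2L) stop("paired test needs >= 2 complete subject pairs")
  xt <- m[, tum, drop = FALSE][, match(common, subj_t), drop = FALSE]
  xn <- m[, nrm, drop = FALSE][, match(common, subj_n), drop = FALSE]
  d <- xt - xn
  k <- ncol(d)
  md <- rowMeans(d)
  sd_d <- sqrt(rowSums((d - md)^2) / (k - 1L))
  se <- sd_d / sqrt(k)
  stat <- md / se
  p <- 2 * stats::pt(-abs(stat), k - 1L)
  degenerate <- se == 0
  zero_eq <- degenerate & md == 0
  zero_ne <- degenerate & md != 0
  stat[zero_eq] <- 0; p[zero_eq] <- 1
  stat[zero_ne] <- sign(md[zero_ne]) * Inf
  p[zero_ne] <- .Machine$double.xmin
  list(statistic = unname(stat), mean_diff = unname(md),
       p = unname(p), degenerate = unname(zero_ne))
}

#' Partition significant probes by direction
#'
#' @param results data.frame from [de_test()].
#' @return list with `gene_list`s `down` and `up` (either may be empty).
#' @export
classify_regulation <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  list(down = gene_list("down", sig$probe_id[sig$mean_diff < 0],
                        provenance = "de_test"),
       up = gene_list("up", sig$probe_id[sig$mean_diff > 0],
                      provenance = "de_test"))
}

#' Overlap counts between two gene lists
#'
#' @param a,b `gene_list` objects.
#' @return list with counts `only_a`, `only_b`, `both`.
#' @export
stage_overlap <- function(a, b) {
  stopifnot(inherits(a, "gene_list"), inherits(b, "gene_list"))
  both <- length(intersect(a$members, b$members))
  list(only_a = length(a$members) - both,
       only_b = length(b$members) - both,
       both = both)
}

#' Write a DE result table to TSV
#' @param results data.frame from [de_test()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
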