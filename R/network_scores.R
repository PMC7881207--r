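#' Binarize a correlation matrix into a TS-DE network
#'
#' Builds the 0/1 bipartite adjacency G used by the N-scores. The
#' significance-level networks use strict inequalities against T
#' (`pos_sig`: r > T, `neg_sig`: r < -T) and the insignificance-level
#' networks use the sign alone (`pos_any`: r > 0, `neg_any`: r < 0) —
#' deliberately strict, exactly as the network formulas are written, even
#' though the S-score formulas use >= / <=.
#'
#' @param R a `correlation_matrix`.
#' @param T threshold in (0, 1); ignored (may be `NULL`) for the `*_any`
#'   modes.
#' @param mode one of `"pos_sig"`, `"pos_any"`, `"neg_sig"`, `"neg_any"`.
#' @return object of class `network_matrix`: list with binary matrix `g`,
#'   `ts_ids`, `de_ids`, `mode`, `T`.
#' @export
binarize <- function(R, T = NULL,
                     mode = c("pos_sig", "pos_any", "neg_sig", "neg_any")) {
  stopifnot(inherits(R, "correlation_matrix"))
  mode <- match.arg(mode)
  if (mode %in% c("pos_sig", "neg_sig")) .check_T(T) else T <- NULL
  g <- switch(mode,
              pos_sig = R$r > T,
              pos_any = R$r > 0,
              neg_sig = R$r < -T,
              neg_any = R$r < 0)
  storage.mode(g) <- "integer"
  structure(list(g = g, ts_ids = R$ts_ids, de_ids = R$de_ids,
                 mode = mode, T = T),
            class = "network_matrix")
}

#' Shared-node count for one TS gene
#'
#' Number of DE genes connected to TS gene `i` that are also connected to
#' at least one other TS gene in the same network — the sum over DE genes j
#' of `max_{k != i}(g_ij * g_kj)`. A single-row network has no other TS
#' gene, so the count is 0.
#'
#' @param G a `network_matrix`.
#' @param i TS gene row index.
#' @return non-negative integer count.
#' @export
shared_node_count <- function(G, i) {
  stopifnot(inherits(G, "network_matrix"))
  n <- nrow(G$g)
  if (i < 1L || i > n) stop("TS index out of range: ", i)
  if (n == 1L) return(0L)
  others <- colSums(G$g[-i, , drop = FALSE]) > 0L
  sum(G$g[i, ] == 1L & others)
}

#' Shared-node N-scores for all TS genes
#'
#' For each TS gene, the ratio of its shared-node count in the
#' significance-level network to that in the sign-only network:
#' `N+ = C+ / C+0` from (r > T) vs (r > 0), and `N- = C- / C-0` from
#' (r < -T) vs (r < 0). A zero denominator yields a score of 0 (genes with
#' no shared partner at any level).
#'
#' @param R a `correlation_matrix` (n >= 2 TS rows for meaningful ratios;
#'   a single row yields all zeros).
#' @param T threshold in (0, 1).
#' @return data.frame with columns `gene`, `n_plus`, `n_minus`, `c_plus`,
#'   `c_plus0`, `c_minus`, `c_minus0`.
#' @export
n_scores <- function(R, T) {
  stopifnot(inherits(R, "correlation_matrix"))
  .check_T(T)
  nets <- list(pos_sig = binarize(R, T, "pos_sig"),
               pos_any = binarize(R, mode = "pos_any"),
               neg_sig = binarize(R, T, "neg_sig"),
               neg_any = binarize(R, mode = "neg_any"))
  n <- length(R$ts_ids)
  counts <- vapply(seq_len(n), function(i) {
    c(c_plus = shared_node_count(nets$pos_sig, i),
      c_plus0 = shared_node_count(nets$pos_any, i),
      c_minus = shared_node_count(nets$neg_sig, i),
      c_minus0 = shared_node_count(nets$neg_any, i))
  }, integer(4L))
  c_plus <- counts["c_plus", ]; c_plus0 <- counts["c_plus0", ]
  c_minus <- counts["c_minus", ]; c_minus0 <- counts["c_minus0", ]
  data.frame(gene = R$ts_ids,
             n_plus = ifelse(c_plus0 == 0L, 0, c_plus / c_plus0),
             n_minus = ifelse(c_minus0 == 0L, 0, c_minus / c_minus0),
             c_plus = c_plus, c_plus0 = c_plus0,
             c_minus = c_minus, c_minus0 = c_minus0)
}

#' Export a binarized network as an edge table
#'
#' One row per TS-DE edge (g_ij = 1) with the edge sign; when
#' `shared_annotation` is set, each edge also records whether its DE node
#' is connected to two or more TS genes (the multi-line vs single-line node
#' distinction).
#'
#' @param G a `network_matrix`.
#' @param shared_annotation add the `shared` column (default TRUE).
#' @return data.frame with columns `ts_gene`, `de_gene`, `sign` and
#'   optionally `shared` (0/1).
#' @export
export_network <- function(G, shared_annotation = TRUE) {
  stopifnot(inherits(G, "network_matrix"))
  sign_chr <- if (G$mode %in% c("pos_sig", "pos_any")) "+" else "-"
  idx <- which(G$g == 1L, arr.ind = TRUE)
  out <- data.frame(ts_gene = G$ts_ids[idx[, 1L]],
                    de_gene = G$de_ids[idx[, 2L]],
                    sign = rep(sign_chr, nrow(idx)))
  if (shared_annotation) {
    deg <- colSums(G$g)
    out$shared <- as.integer(deg[idx[, 2L]] >= 2L)
  }
  ord <- order(out$ts_gene, out$de_gene)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
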