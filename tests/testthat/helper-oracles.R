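# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths (and vectorized shortcuts): definitional
# formulas, double loops and explicit set operations only.

# Pearson correlation straight from the covariance/sd definition.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  cov <- sum((x - mx) * (y - my)) / (n - 1)
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  cov / (sx * sy)
}

# Brute-force BH: q_i = min over the upper tail of p_(j) * n / j.
oracle_bh <- function(p) {
  n <- length(p)
  ranks <- rank(p, ties.method = "first")
  sapply(seq_len(n), function(i) {
    tail_vals <- sapply(seq_len(n), function(j) {
      if (ranks[j] >= ranks[i]) p[j] * n / ranks[j] else Inf
    })
    min(1, min(tail_vals))
  })
}

# Naive per-row S-score table: explicit loops over matrix entries.
oracle_score_table <- function(r, T) {
  out <- NULL
  for (i in seq_len(nrow(r))) {
    num_p <- 0; den_p <- 0; num_m <- 0; den_m <- 0; s <- 0
    npos <- 0L; nneg <- 0L
    for (j in seq_len(ncol(r))) {
      v <- r[i, j]
      if (v > 0) den_p <- den_p + v
      if (v < 0) den_m <- den_m + v
      if (v >= T) { num_p <- num_p + v; npos <- npos + 1L }
      if (v <= -T) { num_m <- num_m + v; nneg <- nneg + 1L }
      if (abs(v) >= T) s <- s + v
    }
    out <- rbind(out, data.frame(
      gene = rownames(r)[i],
      s_plus = if (den_p == 0) 0 else num_p / den_p,
      s_minus = if (den_m == 0) 0 else num_m / den_m,
      s = s, n_pos_sig = npos, n_neg_sig = nneg))
  }
  rownames(out) <- NULL
  out
}

# N-scores via explicit column sets: for each TS gene, the shared count is
# the size of the intersection of its neighbor set with the union of all
# other TS genes' neighbor sets. No matrix algebra.
oracle_n_scores <- function(r, T) {
  n <- nrow(r)
  neighbor_sets <- function(pred) {
    lapply(seq_len(n), function(i) which(pred(r[i, ])))
  }
  shared <- function(sets, i) {
    others <- unique(unlist(sets[-i]))
    length(intersect(sets[[i]], others))
  }
  pos_sig <- neighbor_sets(function(v) v > T)
  pos_any <- neighbor_sets(function(v) v > 0)
  neg_sig <- neighbor_sets(function(v) v < -T)
  neg_any <- neighbor_sets(function(v) v < 0)
  res <- NULL
  for (i in seq_len(n)) {
    cp <- if (n == 1L) 0L else shared(pos_sig, i)
    cp0 <- if (n == 1L) 0L else shared(pos_any, i)
    cm <- if (n == 1L) 0L else shared(neg_sig, i)
    cm0 <- if (n == 1L) 0L else shared(neg_any, i)
    res <- rbind(res, data.frame(
      gene = rownames(r)[i],
      n_plus = if (cp0 == 0) 0 else cp / cp0,
      n_minus = if (cm0 == 0) 0 else cm / cm0,
      c_plus = cp, c_plus0 = cp0, c_minus = cm, c_minus0 = cm0))
  }
  rownames(res) <- NULL
  res
}

# Random fixtures ------------------------------------------------------

rand_expr <- function(n_probes, n_samples, probe_prefix = "P",
                      sample_prefix = "S") {
  m <- matrix(rnorm(n_probes * n_samples, mean = 8, sd = 2),
              nrow = n_probes,
              dimnames = list(sprintf("%s%03d", probe_prefix, seq_len(n_probes)),
                              sprintf("%s%03d", sample_prefix, seq_len(n_samples))))
  m
}

rand_corr_matrix <- function(n_ts, m_de) {
  r <- matrix(runif(n_ts * m_de, -1, 1), nrow = n_ts,
              dimnames = list(sprintf("TS%02d", seq_len(n_ts)),
                              sprintf("DE%02d", seq_len(m_de))))
  structure(list(r = r, ts_ids = rownames(r), de_ids = colnames(r),
                 n_samples = 10L),
            class = "correlation_matrix")
}

# Minimal paired cohort sample table for a matrix with N normals then
# T tumors named N*/T*.
cohort_samples <- function(n_normal, n_tumor, stage = 2L) {
  data.frame(
    sample_id = c(sprintf("N%03d", seq_len(n_normal)),
                  sprintf("T%03d", seq_len(n_tumor))),
    condition = rep(c("normal", "tumor"), c(n_normal, n_tumor)),
    stage = stage,
    subject_id = c(sprintf("S%03d", seq_len(n_normal)),
                   sprintf("S%03d", seq_len(n_tumor))),
    smoking = "no")
}
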