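# build a correlation_matrix whose pos_sig / pos_any networks at T = 0.5
# are exactly the given binary patterns (sig = 0.8, any-only = 0.2, none = -0.1)
corr_from_patterns <- function(sig, any) {
  stopifnot(all(sig <= any))
  r <- matrix(-0.1, nrow(sig), ncol(sig))
  r[any == 1] <- 0.2
  r[sig == 1] <- 0.8
  dimnames(r) <- list(sprintf("TS%02d", seq_len(nrow(r))),
                      sprintf("DE%02d", seq_len(ncol(r))))
  structure(list(r = r, ts_ids = rownames(r), de_ids = colnames(r),
                 n_samples = 10L),
            class = "correlation_matrix")
}

test_that("binarize applies the strict-inequality modes", {
  R <- structure(list(r = matrix(c(0.8, 0.1, -0.9), 1, 3,
                                 dimnames = list("A", c("d1", "d2", "d3"))),
                      ts_ids = "A", de_ids = c("d1", "d2", "d3"),
                      n_samples = 10L),
                 class = "correlation_matrix")
  expect_identical(unname(binarize(R, 0.5, "pos_sig")$g), matrix(c(1L, 0L, 0L), 1))
  expect_identical(unname(binarize(R, 0.5, "neg_sig")$g), matrix(c(0L, 0L, 1L), 1))
  expect_identical(unname(binarize(R, mode = "pos_any")$g), matrix(c(1L, 1L, 0L), 1))
  expect_identical(unname(binarize(R, mode = "neg_any")$g), matrix(c(0L, 0L, 1L), 1))
  # boundary is strict: r == T excluded
  Rb <- R; Rb$r[1, 1] <- 0.5
  expect_identical(unname(binarize(Rb, 0.5, "pos_sig")$g)[1, 1], 0L)
  expect_error(binarize(R, 0.5, "sideways"))

  set.seed(41)
  for (i in 1:20) {
    RR <- rand_corr_matrix(5, 20)
    T <- runif(1, 0.2, 0.8)
    expect_true(all(binarize(RR, T, "pos_sig")$g <= binarize(RR, mode = "pos_any")$g))
    expect_true(all(binarize(RR, T, "neg_sig")$g <= binarize(RR, mode = "neg_any")$g))
  }
})

test_that("shared_node_count evaluates the max-product formula", {
  sig <- rbind(A = c(1, 1, 0, 0), B = c(1, 0, 1, 0), C = c(0, 0, 0, 0))
  G <- binarize(corr_from_patterns(sig, sig), 0.5, "pos_sig")
  expect_identical(shared_node_count(G, 1), 1L)
  expect_identical(shared_node_count(G, 2), 1L)
  expect_identical(shared_node_count(G, 3), 0L)
  expect_error(shared_node_count(G, 4), "out of range")

  # single-row network: no k != i exists
  G1 <- binarize(corr_from_patterns(sig[1, , drop = FALSE],
                                    sig[1, , drop = FALSE]), 0.5, "pos_sig")
  expect_identical(shared_node_count(G1, 1), 0L)

  # two identical rows of weight w share everything
  two <- rbind(X = c(1, 1, 1, 0), Y = c(1, 1, 1, 0))
  G2 <- binarize(corr_from_patterns(two, two), 0.5, "pos_sig")
  expect_identical(shared_node_count(G2, 1), 3L)
  expect_identical(shared_node_count(G2, 2), 3L)
})

test_that("n_scores reproduces the hand-evaluated example", {
  sig <- rbind(A = c(1, 1, 0, 0), B = c(1, 0, 1, 0), C = c(0, 0, 0, 0))
  any <- rbind(A = c(1, 1, 1, 0), B = c(1, 1, 1, 1), C = c(0, 1, 1, 0))
  ns <- n_scores(corr_from_patterns(sig, any), 0.5)
  expect_equal(ns$n_plus[1], 1 / 3)
  # C has an empty significant row but non-empty any-level sharing
  expect_identical(ns$c_plus[3], 0L)
  expect_gt(ns$c_plus0[3], 0L)
  expect_identical(ns$n_plus[3], 0)
})

test_that("n_scores equals the explicit set-intersection oracle", {
  set.seed(42)
  for (i in 1:50) {
    R <- rand_corr_matrix(sample(1:10, 1), sample(2:50, 1))
    T <- runif(1, 0.2, 0.8)
    got <- n_scores(R, T)
    want <- oracle_n_scores(R$r, T)
    expect_equal(got$n_plus, want$n_plus, tolerance = 1e-15)
    expect_equal(got$n_minus, want$n_minus, tolerance = 1e-15)
    expect_identical(as.integer(got$c_plus), as.integer(want$c_plus))
    expect_identical(as.integer(got$c_minus0), as.integer(want$c_minus0))
    expect_true(all(got$n_plus >= 0 & got$n_plus <= 1))
    expect_true(all(got$n_minus >= 0 & got$n_minus <= 1))
  }
})

test_that("n_scores is invariant to DE column permutation and anti-monotone in T", {
  set.seed(43)
  for (i in 1:10) {
    R <- rand_corr_matrix(6, 30)
    T <- runif(1, 0.2, 0.6)
    base <- n_scores(R, T)
    perm <- sample(ncol(R$r))
    Rp <- R
    Rp$r <- Rp$r[, perm]
    Rp$de_ids <- Rp$de_ids[perm]
    expect_equal(n_scores(Rp, T), base, tolerance = 1e-15)

    hi <- n_scores(R, min(0.95, T + 0.3))
    expect_true(all(hi$c_plus <= base$c_plus))
    expect_true(all(hi$c_minus <= base$c_minus))
  }
})

test_that("export_network emits one row per edge with shared annotation", {
  eye <- diag(2); rownames(eye) <- c("A", "B")
  G <- binarize(corr_from_patterns(eye, eye), 0.5, "pos_sig")
  ed <- export_network(G)
  expect_identical(nrow(ed), 2L)
  expect_true(all(ed$shared == 0L))
  expect_true(all(ed$sign == "+"))

  two <- rbind(A = c(1, 1, 0), B = c(1, 1, 0))
  G2 <- binarize(corr_from_patterns(two, two), 0.5, "neg_sig")
  # neg_sig of this pattern is empty; use pos_sig for shared flags
  G2 <- binarize(corr_from_patterns(two, two), 0.5, "pos_sig")
  ed2 <- export_network(G2)
  expect_true(all(ed2$shared == 1L))

  set.seed(44)
  for (i in 1:20) {
    R <- rand_corr_matrix(4, 15)
    T <- runif(1, 0.2, 0.8)
    G <- binarize(R, T, "pos_sig")
    expect_identical(nrow(export_network(G)), sum(G$g))
  }
})
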