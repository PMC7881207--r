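#' Pipeline configuration
#'
#' Exactly one of `simulate` (a [simulation_config()]) or `expression_path`
#' (+ `sample_path`) must be supplied. Candidate TS lists are `gene_list`
#' objects or file paths; in simulate mode the planted TS genes (strong +
#' weak) are used as the candidate list when none is given.
#'
#' @param simulate a `simulation_config`, or `NULL` for file inputs.
#' @param expression_path,sample_path input TSVs (file mode).
#' @param ts_lists list of up to three candidate TS `gene_list`s or paths.
#' @param denylist optional `gene_list` or path of manually excluded genes.
#' @param stage tumor stage analyzed (default 2).
#' @param fdr DE significance level on BH q (default 0.01).
#' @param alpha family-wise level for the correlation threshold (default
#'   0.05).
#' @param tails `"one"` or `"two"` for the threshold quantile.
#' @param sample_scope `"all"` or `"tumor_only"` for the correlations.
#' @param direction_rule TS definition rule, `"down_only"` or
#'   `"any_direction"`.
#' @param score_all_candidates score every candidate-list gene found in the
#'   matrix (default TRUE, matching the practice of scoring the defined TS
#'   set at every stage even where a member is not DE); `FALSE` scores only
#'   the stage-defined TS set.
#' @param linear_scale passed to [read_expression_matrix()] in file mode.
#' @param qc_pairs optional replicate pairs for [qc_report()].
#' @param out_dir output directory (created if absent).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL,
                            expression_path = NULL, sample_path = NULL,
                            ts_lists = NULL, denylist = NULL,
                            stage = 2L, fdr = 0.01, alpha = 0.05,
                            tails = "one",
                            sample_scope = "all",
                            direction_rule = "down_only",
                            score_all_candidates = TRUE,
                            linear_scale = FALSE,
                            qc_pairs = NULL,
                            out_dir) {
  sim_mode <- !is.null(simulate)
  file_mode <- !is.null(expression_path)
  if (sim_mode == file_mode) {
    stop("exactly one of 'simulate' or 'expression_path' must be given")
  }
  if (sim_mode) stopifnot(inherits(simulate, "simulation_config"))
  if (file_mode && is.null(sample_path)) stop("file mode needs sample_path")
  structure(list(simulate = simulate,
                 expression_path = expression_path,
                 sample_path = sample_path,
                 ts_lists = ts_lists, denylist = denylist,
                 stage = as.integer(stage), fdr = fdr, alpha = alpha,
                 tails = match.arg(tails, c("one", "two")),
                 sample_scope = match.arg(sample_scope,
                                          c("all", "tumor_only")),
                 direction_rule = match.arg(direction_rule,
                                            c("down_only", "any_direction")),
                 score_all_candidates = isTRUE(score_all_candidates),
                 linear_scale = isTRUE(linear_scale),
                 qc_pairs = qc_pairs,
                 out_dir = out_dir),
            class = "pipeline_config")
}

.as_gene_list <- function(x, name) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "gene_list")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_gene_list(x, name))
  stop("expected a gene_list or a file path for ", name)
}

#' Run the scoring pipeline end to end
#'
#' Stage order: (simulate or load) -> optional QC -> differential
#' expression -> TS definition -> correlation threshold -> S-scores ->
#' N-scores -> accumulation curves -> network edge exports. All artifacts
#' are written as TSV under `cfg$out_dir` together with `run_report.txt`
#' listing every effective parameter; identical configurations (including
#' the seed) produce byte-identical outputs.
#'
#' @param cfg a `pipeline_config`.
#' @return invisible list with the in-memory artifacts (`de`, `ts_set`,
#'   `threshold`, `scores`, `curves`, `edges`, `files`, `params`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  files <- character(0)

  ## -- inputs ---------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- simulate_cohort(cfg$simulate)
    m <- sim$matrix
    samples <- sim$samples
    truth <- sim$truth
    write_truth_table(truth, out("truth.tsv"))
    files <- c(files, "truth.tsv")
    candidates <- cfg$ts_lists
    if (is.null(candidates)) {
      planted <- truth$gene[truth$role %in% c("strong_ts", "weak_ts")]
      candidates <- list(gene_list("planted_ts", planted, "simulate"))
    }
  } else {
    m <- read_expression_matrix(cfg$expression_path,
                                linear_scale = cfg$linear_scale)
    samples <- read_sample_table(cfg$sample_path)
    if (is.null(cfg$ts_lists)) stop("file mode needs ts_lists")
    candidates <- cfg$ts_lists
  }
  candidates <- lapply(seq_along(candidates), function(i) {
    .as_gene_list(candidates[[i]], paste0("list", i))
  })
  deny <- .as_gene_list(cfg$denylist, "denylist")

  ## -- QC -------------------------------------------------------------
  if (!is.null(cfg$qc_pairs)) {
    qc <- qc_report(m, cfg$qc_pairs)
    write_qc_report(qc, out("qc_report.tsv"))
    files <- c(files, "qc_report.tsv")
  }

  ## -- differential expression at the analyzed stage -------------------
  sub <- subset_stage(m, samples, cfg$stage, include_normals = TRUE)
  de <- de_test(sub$matrix, sub$samples, fdr = cfg$fdr)
  write_de_table(de, out("de_table.tsv"))
  files <- c(files, "de_table.tsv")
  reg <- classify_regulation(de)

  ## -- TS definition ----------------------------------------------------
  de_by_stage <- stats::setNames(list(reg), as.character(cfg$stage))
  ts_set <- suppressWarnings(
    define_ts_genes(de_by_stage,
                    list1 = candidates[[1L]],
                    list2 = if (length(candidates) >= 2L) candidates[[2L]],
                    list3 = if (length(candidates) >= 3L) candidates[[3L]],
                    denylist = deny,
                    direction_rule = cfg$direction_rule))
  write_ts_set(ts_set, out("ts_set.tsv"))
  files <- c(files, "ts_set.tsv")

  ## -- correlation scoring ---------------------------------------------
  scored_genes <- if (cfg$score_all_candidates) {
    sort(unique(unlist(lapply(candidates, `[[`, "members"))))
  } else {
    ts_set$members
  }
  scored_genes <- setdiff(scored_genes, if (!is.null(deny)) deny$members)
  scored_genes <- intersect(scored_genes, rownames(sub$matrix))
  if (length(scored_genes) == 0L) stop("no TS gene available for scoring")
  de_genes <- setdiff(de$probe_id[de$significant], scored_genes)
  if (length(de_genes) == 0L) stop("no DE gene available for scoring")

  R <- correlation_matrix(sub$matrix[scored_genes, , drop = FALSE],
                          sub$matrix[de_genes, , drop = FALSE],
                          sample_scope = cfg$sample_scope,
                          samples = sub$samples)
  thr <- correlation_threshold(cfg$alpha, m_tests = length(de_genes),
                               n_samples = R$n_samples, tails = cfg$tails)
  s_tab <- score_table(R, thr$T)
  n_tab <- n_scores(R, thr$T)
  scores <- merge(s_tab, n_tab, by = "gene", sort = TRUE)
  scores$T <- thr$T
  scores$n_samples <- thr$n_samples
  scores$m_tests <- thr$m_tests
  utils::write.table(scores, out("score_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  thr_df <- data.frame(alpha = thr$alpha, m_tests = thr$m_tests,
                       n_samples = thr$n_samples, tails = thr$tails,
                       df = thr$df, p = thr$p, t = thr$t, T = thr$T)
  utils::write.table(thr_df, out("threshold.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, "score_table.tsv", "threshold.tsv")

  ## -- accumulation curves ---------------------------------------------
  curves <- list(
    s_plus = accumulate_scores(stats::setNames(scores$s_plus, scores$gene),
                               "s_plus"),
    s_minus = accumulate_scores(stats::setNames(scores$s_minus, scores$gene),
                                "s_minus"),
    n_plus = accumulate_scores(stats::setNames(scores$n_plus, scores$gene),
                               "n_plus"),
    n_minus = accumulate_scores(stats::setNames(scores$n_minus, scores$gene),
                                "n_minus"))
  acc <- do.call(rbind, lapply(names(curves), function(k) {
    cbind(kind = k, as.data.frame(curves[[k]]))
  }))
  utils::write.table(acc, out("accumulation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, "accumulation.tsv")
  gaps <- c(s = largest_gap(curves$s_plus, curves$s_minus),
            n = largest_gap(curves$n_plus, curves$n_minus))

  ## -- edge lists -------------------------------------------------------
  edges_pos <- export_network(binarize(R, thr$T, "pos_sig"))
  edges_neg <- export_network(binarize(R, thr$T, "neg_sig"))
  utils::write.table(edges_pos, out("edges_pos.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(edges_neg, out("edges_neg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, "edges_pos.tsv", "edges_neg.tsv")

  ## -- run report: every effective parameter ----------------------------
  params <- c(
    mode = if (is.null(cfg$simulate)) "files" else "simulate",
    seed = if (is.null(cfg$simulate)) NA else cfg$simulate$seed,
    stage = cfg$stage, fdr = cfg$fdr, alpha = cfg$alpha, tails = cfg$tails,
    sample_scope = cfg$sample_scope, direction_rule = cfg$direction_rule,
    score_all_candidates = cfg$score_all_candidates,
    n_probes = nrow(m), n_samples_total = ncol(m),
    n_samples_scoped = thr$n_samples,
    n_de = length(de_genes), n_ts_defined = length(ts_set$members),
    n_ts_scored = length(scored_genes),
    threshold_T = sprintf("%.6f", thr$T),
    largest_gap_s = sprintf("%.6f", gaps[["s"]]),
    largest_gap_n = sprintf("%.6f", gaps[["n"]]))
  writeLines(paste(names(params), unname(params), sep = "\t"),
             out("run_report.txt"))
  files <- c(files, "run_report.txt")

  invisible(list(de = de, ts_set = ts_set, threshold = thr, scores = scores,
                 curves = curves, gaps = gaps,
                 edges = list(pos = edges_pos, neg = edges_neg),
                 files = files, params = params))
}
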