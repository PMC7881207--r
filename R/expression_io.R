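#' Read a probe-by-sample expression matrix from TSV
#'
#' The file dialect is a GEO-series-matrix-like table without the metadata
#' banner: a header line `probe_id<TAB>sample1<TAB>...` followed by one probe
#' per row. All values must parse as finite numbers; cells equal to `"NA"` or
#' the empty string are treated according to `missing_policy`.
#'
#' @param path path to a UTF-8 TSV file.
#' @param missing_policy `"error"` (default) aborts on the first probe row
#'   containing an unparseable/missing cell, naming the probe; `"drop"`
#'   removes such rows with a warning. Downstream correlation formulas
#'   assume complete vectors, hence the strict default.
#' @param linear_scale set `TRUE` for linear-scale input (e.g. RNA-seq RPKM):
#'   values are transformed to `log2(x + 1)` at load so Pearson correlations
#'   are comparable with log-scale microarray intensities.
#' @return numeric matrix, rows named by probe id, columns by sample id.
#' @export
read_expression_matrix <- function(path,
                                   missing_policy = c("error", "drop"),
                                   linear_scale = FALSE) {
  missing_policy <- match.arg(missing_policy)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("expression matrix file has no data rows: ", path)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (length(sample_ids) < 1L) {
    stop("expression matrix header has no sample columns")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nfield <- lengths(body)
  bad <- which(nfield != length(header))
  if (length(bad)) {
    stop("ragged row in expression matrix at line ", bad[[1L]] + 1L,
         ": expected ", length(header), " fields, found ", nfield[bad[[1L]]])
  }
  probe_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe id: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  }
  raw <- vapply(body, function(f) f[-1L], character(length(sample_ids)))
  # raw is samples x probes (vapply binds by column); transpose to probes x samples
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  m <- t(vals)
  dimnames(m) <- list(probe_ids, sample_ids)
  incomplete <- !is.finite(m)
  if (any(incomplete)) {
    bad_rows <- rownames(m)[apply(incomplete, 1L, any)]
    if (missing_policy == "error") {
      stop("missing or unparseable value(s) in probe row(s): ",
           paste(utils::head(bad_rows, 5L), collapse = ", "))
    }
    warning("dropping ", length(bad_rows),
            " probe row(s) with missing/unparseable values")
    m <- m[setdiff(rownames(m), bad_rows), , drop = FALSE]
    if (nrow(m) == 0L) stop("all probe rows dropped by missing-value policy")
  }
  if (linear_scale) {
    if (any(m < 0)) stop("linear-scale input contains negative values")
    m <- log2(m + 1)
  }
  m
}

#' Write an expression matrix to TSV
#'
#' Values are serialized with 17 significant digits so that
#' `read_expression_matrix(write_expression_matrix(m))` is bit-exact.
#'
#' @param m numeric matrix with probe rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  validate_expression_matrix(m)
  header <- paste(c("probe_id", colnames(m)), collapse = "\t")
  fmt <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  rows <- paste(rownames(m), apply(fmt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' @keywords internal
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix must carry probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate probe ids")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  if (!all(is.finite(m))) stop("expression matrix contains non-finite values")
  invisible(m)
}

.conditions <- c("normal", "tumor")
.stages <- c("1", "2", "3", "4")
.smoking <- c("yes", "no")

#' Read a sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `condition`, `stage`,
#' `subject_id`, `smoking`. Unknown stage/smoking are encoded `NA`.
#' `condition` must be `normal` or `tumor`; any other token is an error.
#'
#' @param path path to the TSV file.
#' @return data.frame with character `sample_id`/`condition`/`subject_id`/
#'   `smoking` and integer `stage` (NA = unknown).
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = "NA",
                          check.names = FALSE)
  required <- c("sample_id", "condition", "stage", "subject_id", "smoking")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("sample table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  validate_sample_table(df)
}

#' @keywords internal
validate_sample_table <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad_cond <- setdiff(unique(df$condition), .conditions)
  if (length(bad_cond)) {
    stop("condition outside {normal, tumor}: ", paste(bad_cond, collapse = ", "))
  }
  stage_chr <- as.character(df$stage)
  bad_stage <- setdiff(unique(stage_chr[!is.na(stage_chr)]), .stages)
  if (length(bad_stage)) {
    stop("stage outside {1,2,3,4,NA}: ", paste(bad_stage, collapse = ", "))
  }
  bad_smk <- setdiff(unique(df$smoking[!is.na(df$smoking)]), .smoking)
  if (length(bad_smk)) {
    stop("smoking outside {yes,no,NA}: ", paste(bad_smk, collapse = ", "))
  }
  df$stage <- as.integer(stage_chr)
  rownames(df) <- NULL
  df
}

#' Write a sample table to TSV
#' @param df sample table as returned by [read_sample_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Construct a gene list
#'
#' A named set of gene/probe identifiers with a provenance tag. Members must
#' be unique; an empty member set is permitted (e.g. "no significant probes"),
#' though file-backed lists must be non-empty.
#'
#' @param name short label for the list.
#' @param members character vector of identifiers, no duplicates.
#' @param provenance free-text origin tag.
#' @return object of class `gene_list`.
#' @export
gene_list <- function(name, members, provenance = "") {
  members <- as.character(members)
  if (anyDuplicated(members)) {
    stop("duplicate members in gene list '", name, "': ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  structure(list(name = name, members = members, provenance = provenance),
            class = "gene_list")
}

#' Read a gene list file (one identifier per line, `#` comments allowed)
#' @param path path to the list file.
#' @param name label for the list; defaults to the file name.
#' @return object of class `gene_list`.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("gene list file is empty: ", path)
  if (anyDuplicated(lines)) {
    warning("duplicate identifiers in ", path, " collapsed")
    lines <- unique(lines)
  }
  gene_list(name, lines, provenance = path)
}

#' Write a gene list file
#' @param gl a `gene_list`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(gl, path) {
  stopifnot(inherits(gl, "gene_list"))
  writeLines(gl$members, path, useBytes = TRUE)
  invisible(path)
}

#' Restrict a cohort to one tumor stage
#'
#' Keeps the tumor samples annotated at `stage` and, when
#' `include_normals`, all normal samples. Column order of `m` is preserved;
#' no column is duplicated.
#'
#' @param m expression matrix.
#' @param samples sample table covering the columns of `m`.
#' @param stage tumor stage, one of 1:4.
#' @param include_normals keep all normal samples alongside (default TRUE).
#' @return list with elements `matrix` and `samples`, both restricted.
#' @export
subset_stage <- function(m, samples, stage, include_normals = TRUE) {
  validate_expression_matrix(m)
  if (!stage %in% 1:4) stop("stage must be one of 1,2,3,4")
  idx <- match(colnames(m), samples$sample_id)
  if (anyNA(idx)) {
    stop("sample(s) missing from sample table: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  }
  st <- samples[idx, , drop = FALSE]
  is_tumor_stage <- st$condition == "tumor" & !is.na(st$stage) & st$stage == stage
  if (!any(is_tumor_stage)) stop("no tumor sample at stage ", stage)
  keep <- is_tumor_stage | (include_normals & st$condition == "normal")
  list(matrix = m[, keep, drop = FALSE],
       samples = st[keep, , drop = FALSE])
}

#' Row-wise z-score transform
#'
#' Centers and scales each probe row to mean 0 and unit sample standard
#' deviation (denominator n-1), the convention used for heatmap displays.
#' Constant rows cannot be scaled and are mapped to all-zero rows with a
#' warning.
#'
#' @param m expression matrix with at least two sample columns.
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  validate_expression_matrix(m)
  if (ncol(m) < 2L) stop("z-score needs at least 2 samples")
  mu <- rowMeans(m)
  centered <- m - mu
  s <- sqrt(rowSums(centered^2) / (ncol(m) - 1L))
  const <- s == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) mapped to zeros")
    s[const] <- 1
  }
  centered / s
}

#' Collapse probes to genes by maximum-variance representative
#'
#' For every gene covered by `probe2gene`, keeps the row of the mapped probe
#' with the largest sample variance (ties broken by probe id). Unmapped
#' probes are dropped.
#'
#' @param m expression matrix (probe rows).
#' @param probe2gene named character vector: names are probe ids, values are
#'   gene symbols. May cover a subset of the probes.
#' @return expression matrix with one row per gene, gene rownames, genes in
#'   lexicographic order.
#' @export
collapse_probes <- function(m, probe2gene) {
  validate_expression_matrix(m)
  probes <- intersect(rownames(m), names(probe2gene))
  if (length(probes) == 0L) stop("probe-to-gene map covers none of the probes")
  v <- apply(m[probes, , drop = FALSE], 1L, stats::var)
  ord <- order(probe2gene[probes], -v, probes)
  probes <- probes[ord]
  genes <- probe2gene[probes]
  pick <- probes[!duplicated(genes)]
  out <- m[pick, , drop = FALSE]
  rownames(out) <- unname(genes[!duplicated(genes)])
  out
}
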