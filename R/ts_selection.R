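#' Define the tumor-suppressor gene set
#'
#' A gene enters the TS set when it is differentially expressed at at least
#' one stage (under `direction_rule`) and appears in at least one of the
#' three candidate lists, and is not on the manual denylist. The denylist
#' models the manual biological curation step (an external knowledge check),
#' which is not algorithmic.
#'
#' @param de_by_stage named list: stage label -> list(down = `gene_list`,
#'   up = `gene_list`), as produced by [classify_regulation()] per stage.
#' @param list1,list2,list3 candidate TS `gene_list`s (`list2`/`list3` may be
#'   `NULL`).
#' @param denylist `gene_list` of manually excluded genes, or `NULL`.
#' @param direction_rule `"down_only"` (default: TS genes are the
#'   down-expressed candidates) or `"any_direction"`.
#' @return object of class `ts_gene_set`: list with `members` (lexicographic),
#'   `provenance` (member -> subset of list names) and `stage_found`
#'   (member -> stages where DE).
#' @export
define_ts_genes <- function(de_by_stage, list1, list2 = NULL, list3 = NULL,
                            denylist = NULL,
                            direction_rule = c("down_only", "any_direction")) {
  direction_rule <- match.arg(direction_rule)
  cand_lists <- Filter(Negate(is.null), list(list1 = list1, list2 = list2,
                                             list3 = list3))
  stopifnot(length(cand_lists) >= 1L,
            all(vapply(cand_lists, inherits, logical(1L), "gene_list")))
  candidates <- unique(unlist(lapply(cand_lists, `[[`, "members")))

  de_genes <- character(0)
  stage_found <- list()
  for (stage in names(de_by_stage)) {
    de <- de_by_stage[[stage]]
    genes <- de$down$members
    if (direction_rule == "any_direction") genes <- union(genes, de$up$members)
    de_genes <- union(de_genes, genes)
    for (g in genes) stage_found[[g]] <- c(stage_found[[g]], stage)
  }

  members <- intersect(de_genes, candidates)
  if (!is.null(denylist)) members <- setdiff(members, denylist$members)
  members <- sort(members)
  if (length(members) == 0L) warning("TS gene set is empty")

  provenance <- lapply(members, function(g) {
    names(cand_lists)[vapply(cand_lists, function(l) g %in% l$members,
                             logical(1L))]
  })
  names(provenance) <- members
  structure(list(members = members,
                 provenance = provenance,
                 stage_found = stage_found[members]),
            class = "ts_gene_set")
}

#' Write a TS gene set to TSV
#'
#' Columns: gene, provenance (semicolon-joined list names), stages
#' (comma-joined stage labels).
#'
#' @param ts a `ts_gene_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ts_set <- function(ts, path) {
  stopifnot(inherits(ts, "ts_gene_set"))
  df <- data.frame(
    gene = ts$members,
    provenance = vapply(ts$provenance, paste, character(1L), collapse = ";"),
    stages = vapply(ts$stage_found, function(s) paste(sort(s), collapse = ","),
                    character(1L)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
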