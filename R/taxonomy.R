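#' Construct a taxonomy map
#'
#' Maps organism names (as they appear in annotation text) to an ordered
#' lineage.  Lookup is case-sensitive exact match; organisms missing from
#' the map fall into an `"unclassified"` bucket during rollup.  A `domain`
#' column, when present, lets concordance analyses restrict to bacteria.
#'
#' @param df data frame with column `organism` plus any of `domain`,
#'   `phylum`, `class`, `order`, `family`, `genus`.
#' @return An object of class `taxonomy_map` (a validated data frame).
#' @export
taxonomy_map <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"organism" %in% names(df))
    abort_samsa("taxonomy map needs an 'organism' column",
                "samsa_validation_error")
  if (anyDuplicated(df$organism))
    abort_samsa("duplicate organism names in taxonomy map",
                "samsa_validation_error")
  keep <- intersect(c("organism", "domain", TAX_RANKS), names(df))
  df <- df[, keep, drop = FALSE]
  rownames(df) <- df$organism
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' Read / write a taxonomy map TSV
#'
#' Plain tab-delimited table with columns `organism`, optionally `domain`,
#' and the five ranks phylum..genus.
#'
#' @param file path.
#' @return [read_taxonomy_tsv()]: a `taxonomy_map`.
#' @export
read_taxonomy_tsv <- function(file) {
  taxonomy_map(read.delim(file, comment.char = "#",
                          stringsAsFactors = FALSE))
}

#' @rdname read_taxonomy_tsv
#' @param tax a `taxonomy_map`.
#' @export
write_taxonomy_tsv <- function(tax, file) {
  write.table(as.data.frame(tax), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Roll an organism-level abundance table up to a coarser taxonomic rank
#'
#' Counts are summed per rank name; organisms absent from the map (or with
#' an empty entry at the requested rank) pool into `"unclassified"`.  The
#' table total is conserved exactly.  Without a map, only `rank = "genus"`
#' is available through a documented fallback: the genus is taken to be
#' the first whitespace-delimited token of the organism name (binomial
#' convention); coarser ranks require lineage data the annotation text
#' does not carry.
#'
#' @param table an organism-level [abundance_table()].
#' @param tax a [taxonomy_map()], or `NULL` for the genus fallback.
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return An [abundance_table()] keyed by rank name.
#' @export
#' @examples
#' tab <- abundance_table(c("Escherichia coli" = 5, "Shigella flexneri" = 2))
#' rollup_rank(tab, NULL, "genus")$counts
rollup_rank <- function(table, tax, rank) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.character(rank) || length(rank) != 1L || !(rank %in% TAX_RANKS))
    abort_samsa(sprintf("unknown rank '%s'", paste(rank, collapse = ",")),
                "samsa_validation_error")
  orgs <- names(table$counts)
  if (is.null(tax)) {
    if (rank != "genus")
      abort_samsa("rollup above genus requires a taxonomy map",
                  "samsa_validation_error")
    groups <- vapply(strsplit(orgs, "[[:space:]]+"), `[[`, character(1), 1L)
  } else {
    stopifnot(inherits(tax, "taxonomy_map"))
    if (!rank %in% names(tax))
      abort_samsa(sprintf("taxonomy map lacks rank '%s'", rank),
                  "samsa_validation_error")
    groups <- tax[[rank]][match(orgs, tax$organism)]
    groups[is.na(groups) | !nzchar(groups)] <- "unclassified"
  }
  counts <- tapply(table$counts, groups, sum)
  out <- abundance_table(setNames(as.numeric(counts), names(counts)),
                         table$sample_id, table$source_db)
  attr(out, "rank") <- rank
  out
}

#' Merge per-sample abundance tables into a count matrix
#'
#' The feature set is the union over samples; entries absent from a sample
#' are zero.  Column sums therefore equal the table totals.  Every sample
#' must carry a condition label before differential testing.
#'
#' @param tables list of [abundance_table()]s sharing one source database,
#'   with unique sample ids.
#' @param groups named character vector mapping sample id to condition
#'   label (may be `NULL` for purely descriptive matrices).
#' @return An object of class `count_matrix`: list with `counts` (features
#'   x samples numeric matrix), `groups`, `source_db`.
#' @export
merge_to_matrix <- function(tables, groups = NULL) {
  if (inherits(tables, "abundance_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "abundance_table")))
  ids <- vapply(tables, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    abort_samsa("duplicate sample_id among tables", "samsa_validation_error")
  src <- unique(vapply(tables, `[[`, character(1), "source_db"))
  if (length(src) != 1L)
    abort_samsa("tables mix source databases", "samsa_validation_error")
  feats <- sort(unique(unlist(lapply(tables, function(t) names(t$counts)))),
                method = "radix")
  m <- matrix(0, nrow = length(feats), ncol = length(tables),
              dimnames = list(feats, ids))
  for (j in seq_along(tables))
    m[names(tables[[j]]$counts), j] <- tables[[j]]$counts
  if (!is.null(groups)) {
    missing <- setdiff(ids, names(groups))
    if (length(missing))
      abort_samsa(sprintf("no group label for sample(s): %s",
                          paste(missing, collapse = ", ")),
                  "samsa_validation_error")
    groups <- groups[ids]
  }
  count_matrix(m, groups, src)
}

#' Construct a count matrix directly
#' @param counts features x samples non-negative numeric matrix with
#'   dimnames.
#' @param groups named character vector sample id -> condition, or `NULL`.
#' @param source_db reference database label.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, groups = NULL, source_db = "refseq_org") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_samsa("count matrix needs feature and sample names",
                "samsa_validation_error")
  if (any(counts < 0))
    abort_samsa("counts must be non-negative", "samsa_validation_error")
  if (!is.null(groups)) {
    groups <- setNames(as.character(groups), names(groups))
    if (!setequal(names(groups), colnames(counts)))
      abort_samsa("group labels must cover exactly the matrix samples",
                  "samsa_validation_error")
    groups <- groups[colnames(counts)]
  }
  structure(list(counts = counts, groups = groups,
                 source_db = match_source_db(source_db)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts), x$source_db))
  if (!is.null(x$groups)) {
    cat("groups:\n")
    print(table(x$groups))
  }
  invisible(x)
}

#' Write / read a count matrix with its group-label sidecar
#'
#' The matrix TSV holds a `feature` column followed by one column per
#' sample; the sidecar TSV holds `sample`, `group`.
#'
#' @param matrix a `count_matrix`.
#' @param file matrix TSV path.
#' @param groups_file sidecar path; default replaces the extension with
#'   `.groups.tsv`.
#' @return `file`, invisibly.
#' @export
write_count_matrix <- function(matrix, file,
                               groups_file = paste0(sub("\\.tsv$", "", file),
                                                    ".groups.tsv")) {
  stopifnot(inherits(matrix, "count_matrix"))
  df <- data.frame(feature = rownames(matrix$counts), matrix$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(matrix$groups))
    write.table(data.frame(sample = names(matrix$groups),
                           group = unname(matrix$groups)),
                groups_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_count_matrix
#' @param source_db reference database label for the rebuilt object.
#' @export
read_count_matrix <- function(file,
                              groups_file = paste0(sub("\\.tsv$", "", file),
                                                   ".groups.tsv"),
                              source_db = "refseq_org") {
  df <- read.delim(file, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature
  groups <- NULL
  if (file.exists(groups_file)) {
    g <- read.delim(groups_file, stringsAsFactors = FALSE)
    groups <- setNames(g$group, g$sample)
  }
  count_matrix(m, groups, source_db)
}
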