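#' Construct an abundance table
#'
#' An abundance table holds, for one sample and one reference database, the
#' number of reads matched to each unique annotation.  Counts are real to
#' accommodate the fractional tie policy; under `count_all` they are
#' integers.
#'
#' @param counts named non-negative numeric vector, one entry per unique
#'   annotation.
#' @param sample_id sample label.
#' @param source_db reference database the annotations came from.
#' @return An object of class `abundance_table` with fields `sample_id`,
#'   `source_db`, `counts` and `total`.
#' @export
abundance_table <- function(counts, sample_id = "sample",
                            source_db = "refseq_org") {
  source_db <- match_source_db(source_db)
  counts <- unlist(counts)
  if (length(counts) > 0L && (is.null(names(counts)) ||
                              any(!nzchar(names(counts)))))
    abort_samsa("counts must be named by annotation",
                "samsa_validation_error")
  if (anyDuplicated(names(counts)))
    abort_samsa("annotation keys must be unique", "samsa_validation_error")
  if (any(counts < 0))
    abort_samsa("counts must be non-negative", "samsa_validation_error")
  storage.mode(counts) <- "double"
  structure(list(sample_id = as.character(sample_id),
                 source_db = source_db,
                 counts = counts,
                 total = sum(counts)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: sample '%s', %s, %d unique annotations, total %s\n",
              x$sample_id, x$source_db, length(x$counts),
              format(x$total, big.mark = ",")))
  top <- head(sort_abundance(x), 5L)
  if (nrow(top) > 0L) {
    cat("top annotations:\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' Aggregate per-read annotation records into an abundance table
#'
#' Each unique annotation accumulates the number of records carrying it.
#' Reads with tied best hits appear as several records sharing a read id;
#' under `tie_policy = "count_all"` each tied record contributes a full
#' count (every tied match enters the results), under `"fractional"` each
#' of a read's k records contributes 1/k so every read has unit weight.
#'
#' @param records annotation record data frame sharing one `source_db`.
#' @param tie_policy `"count_all"` or `"fractional"`.
#' @param sample_id sample label stored on the table.
#' @return An [abundance_table()].  Its `total` equals the record count
#'   (count_all) or the distinct-read count (fractional).
#' @export
#' @examples
#' recs <- parse_annotations(text = c("r1\tm\t99\t100\t0\tA;B",
#'                                    "r2\tm\t99\t100\t0\tA"),
#'                           source_db = "refseq_org")
#' aggregate_counts(recs, tie_policy = "fractional")$counts
aggregate_counts <- function(records,
                             tie_policy = c("count_all", "fractional"),
                             sample_id = "sample") {
  tie_policy <- match.arg(tie_policy)
  if (nrow(records) == 0L)
    return(abundance_table(setNames(numeric(), character()), sample_id,
                           records$source_db[1] %||% "refseq_org"))
  src <- unique(records$source_db)
  if (length(src) != 1L)
    abort_samsa("records mix source databases; split them first",
                "samsa_validation_error")
  w <- if (tie_policy == "count_all") {
    rep(1, nrow(records))
  } else {
    k <- table(records$read_id)
    1 / as.numeric(k[records$read_id])
  }
  counts <- tapply(w, records$annotation_text, sum)
  counts <- setNames(as.numeric(counts), names(counts))
  tab <- abundance_table(counts, sample_id, src)
  attr(tab, "tie_policy") <- tie_policy
  tab
}

#' Sort an abundance table by decreasing count
#'
#' Ties are broken lexicographically by annotation key (byte order), so the
#' output is deterministic across runs and platforms.
#'
#' @param table an [abundance_table()].
#' @return Data frame with columns `annotation`, `count`, sorted.
#' @export
sort_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  keys <- names(table$counts)
  o <- c_order(-table$counts, keys)
  data.frame(annotation = keys[o], count = unname(table$counts[o]),
             stringsAsFactors = FALSE)
}

#' Relative abundances of an abundance table
#'
#' @param table an [abundance_table()] with positive total.
#' @return Named vector of proportions summing to one.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$total <= 0)
    abort_samsa("cannot form proportions: table total is zero",
                "samsa_validation_error")
  table$counts / table$total
}

#' Keep the top-N annotations, pooling or dropping the rest
#'
#' Display convention for long-tailed community profiles: the `n` most
#' abundant annotations are kept and the remainder is either summed into a
#' catch-all `"Other"` category (totals conserved) or removed from display
#' (totals not conserved).  An input annotation literally named `"Other"`
#' is escaped to `"Other (annotation)"` so the catch-all stays
#' unambiguous.
#'
#' @param table an [abundance_table()].
#' @param n number of annotations to keep (default 30, the usual stacked
#'   bar-graph convention).
#' @param mode `"other_bucket"` or `"drop"`.
#' @return An [abundance_table()].
#' @export
top_n_other <- function(table, n = 30L, mode = c("other_bucket", "drop")) {
  stopifnot(inherits(table, "abundance_table"))
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    abort_samsa("n must be a positive integer", "samsa_validation_error")
  counts <- table$counts
  if ("Other" %in% names(counts))
    names(counts)[names(counts) == "Other"] <- "Other (annotation)"
  tab2 <- abundance_table(counts, table$sample_id, table$source_db)
  sorted <- sort_abundance(tab2)
  if (nrow(sorted) <= n) return(tab2)
  keep <- sorted[seq_len(n), ]
  out <- setNames(keep$count, keep$annotation)
  if (mode == "other_bucket") {
    rest <- sum(sorted$count[-seq_len(n)])
    if (rest > 0 || nrow(sorted) > n) out <- c(out, Other = rest)
  }
  abundance_table(out, table$sample_id, table$source_db)
}

#' Write an abundance table as sorted TSV
#'
#' Columns `annotation`, `count`, `relative_abundance`, sorted by
#' decreasing count.  Sample id, source database and any extra parameters
#' are recorded in `#`-prefixed header comments so the file round-trips.
#'
#' @param table an [abundance_table()].
#' @param file output path.
#' @param extra_header named character vector of extra `key=value` header
#'   fields (e.g. seed, parameters).
#' @return `file`, invisibly.
#' @export
write_abundance_tsv <- function(table, file, extra_header = character()) {
  stopifnot(inherits(table, "abundance_table"))
  sorted <- sort_abundance(table)
  sorted$relative_abundance <-
    if (table$total > 0) sorted$count / table$total else 0
  hdr <- c(sprintf("# samsa abundance_table v%s",
                   as.character(utils::packageVersion("samsa"))),
           sprintf("# sample_id=%s", table$sample_id),
           sprintf("# source_db=%s", table$source_db),
           if (length(extra_header))
             sprintf("# %s=%s", names(extra_header), extra_header))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(sorted), collapse = "\t"), con)
  write.table(sorted, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

read_header_fields <- function(file) {
  lines <- readLines(file, n = 50L)
  lines <- lines[startsWith(lines, "# ")]
  kv <- regmatches(lines, regexec("^# ([A-Za-z0-9_]+)=(.*)$", lines))
  kv <- kv[lengths(kv) == 3L]
  setNames(vapply(kv, `[[`, character(1), 3L),
           vapply(kv, `[[`, character(1), 2L))
}

#' Read an abundance-table TSV written by [write_abundance_tsv()]
#' @param file path to the TSV.
#' @return An [abundance_table()].
#' @export
read_abundance_tsv <- function(file) {
  hdr <- read_header_fields(file)
  get <- function(key, default) {
    v <- unname(hdr[key])
    if (is.na(v)) default else v
  }
  df <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  abundance_table(setNames(df$count, df$annotation),
                  sample_id = get("sample_id", "sample"),
                  source_db = get("source_db", "refseq_org"))
}
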