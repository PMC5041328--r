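#' Describe the layout of a tab-delimited annotation download
#'
#' MG-RAST-style annotation downloads are tab-delimited, one best-hit match
#' per line, but the exact column order varies between export routes.  A
#' dialect names the columns in file order; it must place `read_id` and
#' `annotation_text` somewhere.  The default is the BLAST-tabular-like
#' layout (read id, match id, percent identity, alignment length, e-value,
#' annotation text).  Cells in the annotation column may hold several
#' annotations separated by `annotation_delim` (ties for best match); the
#' parser expands these into one record each.
#'
#' @param columns character vector naming the columns in file order.
#'   Recognized names: `read_id`, `match_id`, `percent_identity`,
#'   `alignment_length`, `evalue`, `annotation_text`.
#' @param annotation_delim single character separating multiple annotations
#'   within one annotation cell.
#' @param comment_prefix lines starting with this string are skipped.
#' @return An object of class `annotation_dialect`.
#' @export
#' @examples
#' annotation_dialect()
#' annotation_dialect(columns = c("read_id", "annotation_text"))
annotation_dialect <- function(columns = c("read_id", "match_id",
                                           "percent_identity",
                                           "alignment_length", "evalue",
                                           "annotation_text"),
                               annotation_delim = ";",
                               comment_prefix = "#") {
  columns <- as.character(columns)
  if (!all(c("read_id", "annotation_text") %in% columns))
    abort_samsa("dialect must place both 'read_id' and 'annotation_text'",
                "samsa_dialect_error")
  if (anyDuplicated(columns))
    abort_samsa("dialect columns must be unique", "samsa_dialect_error")
  if (nchar(annotation_delim) != 1L)
    abort_samsa("annotation_delim must be a single character",
                "samsa_dialect_error")
  structure(list(columns = columns,
                 annotation_delim = annotation_delim,
                 comment_prefix = comment_prefix),
            class = "annotation_dialect")
}

empty_records <- function() {
  data.frame(read_id = character(), match_id = character(),
             percent_identity = numeric(), alignment_length = numeric(),
             evalue = numeric(), annotation_text = character(),
             source_db = character(), stringsAsFactors = FALSE)
}

#' Parse a tab-delimited annotation download into per-read records
#'
#' Reads one best-hit match per line.  Annotation cells holding several
#' delimiter-separated entries (tied best hits) expand into one record per
#' entry, all sharing the read id, mirroring how MG-RAST reports ties.
#' Comment lines are skipped.  Lines with fewer columns than the dialect
#' requires are counted as malformed and dropped (or rejected outright with
#' `strict = TRUE`); the count is attached as attribute `"malformed"`.
#'
#' @param file path to a tab-delimited annotation file (plain or gzip), or
#'   a connection.  Alternatively pass the text itself via `text`.
#' @param dialect an [annotation_dialect()].
#' @param source_db which reference database the file was annotated
#'   against: one of `"refseq_org"`, `"refseq_func"`, `"subsystems"`,
#'   `"silva_ssu"`.
#' @param text optional character vector of lines, used instead of `file`.
#' @param strict if `TRUE`, any malformed line is an error.
#' @return A data frame of annotation records with columns `read_id`,
#'   `match_id`, `percent_identity`, `alignment_length`, `evalue`,
#'   `annotation_text`, `source_db`, and attribute `malformed` (number of
#'   dropped lines).
#' @export
#' @examples
#' recs <- parse_annotations(
#'   text = "r1\tm5_1\t98.5\t150\t1e-40\tEscherichia coli",
#'   source_db = "refseq_org")
#' recs$annotation_text
parse_annotations <- function(file, dialect = annotation_dialect(),
                              source_db, text = NULL, strict = FALSE) {
  stopifnot(inherits(dialect, "annotation_dialect"))
  source_db <- match_source_db(source_db)
  lines <- if (!is.null(text)) as.character(text) else readLines(file)
  lines <- lines[nzchar(lines)]
  if (nzchar(dialect$comment_prefix))
    lines <- lines[!startsWith(lines, dialect$comment_prefix)]
  if (length(lines) == 0L) {
    out <- empty_records()
    attr(out, "malformed") <- 0L
    return(out)
  }

  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_req <- length(dialect$columns)
  ok <- lengths(parts) >= ncol_req
  n_bad <- sum(!ok)
  if (n_bad > 0L && strict)
    abort_samsa(sprintf("%d malformed line(s) (fewer than %d columns)",
                        n_bad, ncol_req), "samsa_parse_error")
  parts <- parts[ok]

  fields <- c("read_id", "match_id", "percent_identity",
              "alignment_length", "evalue", "annotation_text")
  col_at <- match(fields, dialect$columns)
  get_col <- function(i) {
    if (is.na(i)) rep(NA_character_, length(parts))
    else vapply(parts, `[[`, character(1), i)
  }
  raw <- lapply(col_at, get_col)
  names(raw) <- fields

  ann_entries <- strsplit(raw$annotation_text, dialect$annotation_delim,
                          fixed = TRUE)
  ann_entries <- lapply(ann_entries, function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
  k <- lengths(ann_entries)
  if (any(k == 0L)) {
    # an empty annotation cell carries no information: malformed
    drop <- k == 0L
    if (strict)
      abort_samsa(sprintf("%d line(s) with empty annotation cell",
                          sum(drop)), "samsa_parse_error")
    n_bad <- n_bad + sum(drop)
    raw <- lapply(raw, function(x) x[!drop])
    ann_entries <- ann_entries[!drop]
    k <- k[!drop]
  }

  idx <- rep.int(seq_along(k), k)
  out <- data.frame(
    read_id = raw$read_id[idx],
    match_id = raw$match_id[idx],
    percent_identity = suppressWarnings(as.numeric(raw$percent_identity[idx])),
    alignment_length = suppressWarnings(as.numeric(raw$alignment_length[idx])),
    evalue = suppressWarnings(as.numeric(raw$evalue[idx])),
    annotation_text = unlist(ann_entries, use.names = FALSE),
    source_db = source_db,
    stringsAsFactors = FALSE)
  attr(out, "malformed") <- as.integer(n_bad)
  out
}

#' Write annotation records back to tab-delimited form
#'
#' Emits one line per record (tied hits are not re-merged into
#' multi-annotation cells), so `parse_annotations()` on the output
#' reproduces the input field for field.  Records whose annotation text
#' embeds a tab, newline, or the dialect's annotation delimiter are
#' refused, since they could not be re-read unambiguously.
#'
#' @param records annotation record data frame (see [parse_annotations()]).
#' @param file path or connection to write to.
#' @param dialect an [annotation_dialect()].
#' @return `file`, invisibly.
#' @export
write_annotations <- function(records, file,
                              dialect = annotation_dialect()) {
  stopifnot(inherits(dialect, "annotation_dialect"))
  bad <- grepl("[\t\n]", records$annotation_text, perl = TRUE) |
    grepl(dialect$annotation_delim, records$annotation_text, fixed = TRUE) |
    grepl("[\t\n]", records$read_id, perl = TRUE)
  if (any(bad))
    abort_samsa(sprintf(
      "%d record(s) embed a tab, newline or '%s' in a text field",
      sum(bad), dialect$annotation_delim), "samsa_write_error")
  cols <- lapply(dialect$columns, function(nm) {
    v <- records[[nm]]
    if (is.null(v)) rep("", nrow(records)) else {
      v <- as.character(v)
      v[is.na(v)] <- ""
      v
    }
  })
  header <- paste0(dialect$comment_prefix, " ",
                   paste(dialect$columns, collapse = "\t"))
  lines <- c(header,
             if (nrow(records) > 0L) do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, file)
  invisible(file)
}

#' Default keywords marking ribosomal-RNA annotations
#' @export
RRNA_KEYWORDS <- c("ribosomal RNA", "rRNA", "16S", "23S", "5S", "SSU", "LSU")

#' Partition annotation records into mRNA and rRNA sets
#'
#' rRNA reads surviving ribosomal depletion skew abundance estimates and
#' should be discarded before functional analysis.  A record is ribosomal
#' if it was annotated against the SILVA SSU database, or if its annotation
#' text contains any of the keywords (case-insensitive substring match).
#' Every record lands in exactly one partition.
#'
#' @param records annotation record data frame.
#' @param keywords character vector of ribosomal keywords; extend it to
#'   match local annotation vocabularies.
#' @return `list(mrna = ..., rrna = ...)` of record data frames.
#' @export
filter_rrna <- function(records, keywords = RRNA_KEYWORDS) {
  if (nrow(records) == 0L)
    return(list(mrna = records, rrna = records))
  is_rrna <- records$source_db == "silva_ssu"
  if (length(keywords) > 0L) {
    txt <- tolower(records$annotation_text)
    for (kw in tolower(keywords))
      is_rrna <- is_rrna | grepl(kw, txt, fixed = TRUE)
  }
  list(mrna = records[!is_rrna, , drop = FALSE],
       rrna = records[is_rrna, , drop = FALSE])
}

#' Build an MG-RAST RESTful API annotation-download request string
#'
#' Constructs the URL used to download per-read best-hit annotations for a
#' dataset.  No network call is made; the string can be fed to any HTTP
#' client.
#'
#' @param dataset_id MG-RAST dataset (metagenome) identifier.
#' @param source_db reference database to pull annotations from.
#' @param annotation_type `"organism"`, `"function"`, or `"ontology"`.
#' @param auth_key MG-RAST webkey authorizing access.
#' @param base_url API root.
#' @return The request URL string.
#' @export
#' @examples
#' build_api_request("4537xyz.3", "refseq_org", "organism", "SECRET")
build_api_request <- function(dataset_id, source_db,
                              annotation_type = c("organism", "function",
                                                  "ontology"),
                              auth_key,
                              base_url = "https://api.mg-rast.org/annotation/sequence") {
  annotation_type <- match.arg(annotation_type)
  source_db <- match_source_db(source_db)
  if (!is.character(dataset_id) || length(dataset_id) != 1L ||
      !nzchar(dataset_id))
    abort_samsa("dataset_id must be a non-empty string",
                "samsa_validation_error")
  if (!is.character(auth_key) || length(auth_key) != 1L || !nzchar(auth_key))
    abort_samsa("auth_key must be a non-empty string",
                "samsa_validation_error")
  source_token <- c(refseq_org = "RefSeq", refseq_func = "RefSeq",
                    subsystems = "Subsystems", silva_ssu = "SSU")[[source_db]]
  sprintf("%s/%s?source=%s&type=%s&auth=%s",
          base_url, dataset_id, source_token, annotation_type, auth_key)
}
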