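#' Stacked bar graph of community composition across samples
#'
#' One bar per sample, split by annotation category.  Only the `top_n`
#' categories (ranked by summed abundance across samples) are shown
#' individually; the remainder is pooled into a final `"Other"` category,
#' so the legend never exceeds `top_n + 1` entries.  In `"percent"` mode
#' every bar sums to 100; `"counts"` mode shows absolute annotation
#' totals.  The numbers behind the plot are returned (and can be written
#' as TSV), so downstream checks assert on data rather than pixels.
#'
#' @param x a list of [abundance_table()]s or a [count_matrix()].
#' @param file output image path (`.png`); a sibling `.tsv` with the
#'   plotted matrix is written alongside unless `data_file = NA`.
#' @param mode `"percent"` or `"counts"`.
#' @param top_n categories displayed individually (default 30).
#' @param data_file path for the data sidecar (default: `file` with
#'   `.tsv` extension; `NA` suppresses it).
#' @return Invisibly, the plotted category x sample matrix.
#' @export
plot_stacked_bars <- function(x, file, mode = c("percent", "counts"),
                              top_n = 30L,
                              data_file = paste0(tools::file_path_sans_ext(file),
                                                 ".tsv")) {
  mode <- match.arg(mode)
  if (inherits(x, "count_matrix")) {
    m <- x$counts
  } else {
    if (inherits(x, "abundance_table")) x <- list(x)
    if (length(x) == 0L)
      abort_samsa("no samples to plot", "samsa_validation_error")
    m <- merge_to_matrix(x)$counts
  }
  if (ncol(m) < 1L || sum(m) == 0)
    abort_samsa("nothing to plot: empty input", "samsa_validation_error")
  top_n <- as.integer(top_n)
  if (is.na(top_n) || top_n < 1L)
    abort_samsa("top_n must be >= 1", "samsa_validation_error")

  o <- c_order(-rowSums(m), rownames(m))
  m <- m[o, , drop = FALSE]
  if (nrow(m) > top_n) {
    other <- colSums(m[-seq_len(top_n), , drop = FALSE])
    m <- rbind(m[seq_len(top_n), , drop = FALSE], Other = other)
  }
  if (mode == "percent")
    m <- sweep(m, 2, colSums(m), "/") * 100

  if (!is.na(data_file)) {
    df <- data.frame(category = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, data_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  grDevices::png(file, width = 1200, height = 800, res = 120)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mar = c(6, 4, 2, 14), xpd = TRUE)
  on.exit(graphics::par(old), add = TRUE, after = FALSE)
  cols <- grDevices::hcl.colors(nrow(m), "Spectral")
  if (nrow(m) > top_n) cols[nrow(m)] <- "#9467bd"   # "Other" in purple
  graphics::barplot(m, col = cols, border = NA, las = 2,
                    ylab = if (mode == "percent")
                      "% of annotations" else "annotations")
  graphics::legend("topright", inset = c(-0.35, 0), legend = rownames(m),
                   fill = cols, cex = 0.55, bty = "n")
  invisible(m)
}

#' Sample dendrogram on Bray-Curtis dissimilarity
#'
#' Hierarchically clusters samples on the Bray-Curtis dissimilarity of
#' their relative abundance profiles (average linkage by default).
#' Distance and linkage are configurable since the convention varies
#' between studies.
#'
#' @param matrix a [count_matrix()] with at least 3 samples.
#' @param file output image path (`.png`), or `NULL` to skip rendering.
#' @param distance a `vegan::vegdist` method name.
#' @param linkage an `hclust` agglomeration method.
#' @return Invisibly, the `hclust` object (leaf labels = sample ids).
#' @export
plot_dendrogram <- function(matrix, file = NULL, distance = "bray",
                            linkage = "average") {
  stopifnot(inherits(matrix, "count_matrix"))
  m <- matrix$counts
  if (ncol(m) < 3L)
    abort_samsa("need at least 3 samples for a dendrogram",
                "samsa_validation_error")
  rel <- sweep(m, 2, colSums(m), "/")
  d <- vegan::vegdist(t(rel), method = distance)
  hc <- hclust(d, method = linkage)
  if (!is.null(file)) {
    grDevices::png(file, width = 1000, height = 700, res = 120)
    on.exit(grDevices::dev.off())
    plot(hc, xlab = "", sub = "",
         main = sprintf("%s / %s linkage", distance, linkage))
  }
  invisible(hc)
}
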