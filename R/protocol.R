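#' Per-taxon ribosomal depletion percentage between paired libraries
#'
#' Hybridization-based ribodepletion does not remove rRNA uniformly across
#' taxa, which skews the surviving rRNA profile.  This metric quantifies
#' that bias per taxon from paired control/depleted libraries.  For pair i
#' and taxon t,
#' \deqn{d_i(t) = 100 (1 - rel_{dep,i}(t) / rel_{ctl,i}(t))}
#' where `rel` are within-library relative abundances (so the metric is
#' invariant to library size).  The reported depletion percentage is the
#' mean of d_i(t) over pairs.  Negative values mean apparent enrichment.
#' Taxa absent from every control library cannot be normalized; they are
#' excluded and listed in the `"control_absent"` attribute.  A taxon
#' absent from a depleted library scores 100 for that pair.
#'
#' @param control,depleted an [abundance_table()] each, or parallel lists
#'   of tables (pairs aligned by position).  Roll both up to the rank of
#'   interest (phylum, typically) first.
#' @return Data frame with one row per taxon: per-pair control and
#'   depleted counts, `depletion_percent`; sorted by decreasing control
#'   abundance.
#' @export
depletion_percent <- function(control, depleted) {
  if (inherits(control, "abundance_table")) control <- list(control)
  if (inherits(depleted, "abundance_table")) depleted <- list(depleted)
  stopifnot(all(vapply(control, inherits, logical(1), "abundance_table")),
            all(vapply(depleted, inherits, logical(1), "abundance_table")))
  if (length(control) != length(depleted))
    abort_samsa("control and depleted lists must pair up",
                "samsa_validation_error")
  if (length(control) == 0L || all(vapply(control, `[[`, numeric(1),
                                          "total") == 0))
    abort_samsa("control libraries are empty", "samsa_validation_error")

  taxa_ctl <- unique(unlist(lapply(control, function(t) names(t$counts))))
  taxa_all <- unique(c(taxa_ctl,
                       unlist(lapply(depleted,
                                     function(t) names(t$counts)))))
  absent <- setdiff(taxa_all, taxa_ctl)
  taxa <- sort(taxa_ctl, method = "radix")

  n_pairs <- length(control)
  d <- matrix(NA_real_, length(taxa), n_pairs, dimnames = list(taxa, NULL))
  ctl_counts <- dep_counts <- matrix(0, length(taxa), n_pairs,
                                     dimnames = list(taxa, NULL))
  for (i in seq_len(n_pairs)) {
    rc <- relative_abundance(control[[i]])
    rd <- if (depleted[[i]]$total > 0) relative_abundance(depleted[[i]])
          else setNames(numeric(), character())
    ctl_counts[names(control[[i]]$counts), i] <- control[[i]]$counts
    dep_counts[intersect(names(depleted[[i]]$counts), taxa), i] <-
      depleted[[i]]$counts[intersect(names(depleted[[i]]$counts), taxa)]
    for (t in taxa) {
      rel_c <- unname(rc[t])
      if (is.na(rel_c) || rel_c == 0) next  # not normalizable in this pair
      rel_d <- unname(rd[t])
      if (is.na(rel_d)) rel_d <- 0
      d[t, i] <- 100 * (1 - rel_d / rel_c)
    }
  }
  out <- data.frame(taxon = taxa, stringsAsFactors = FALSE)
  for (i in seq_len(n_pairs)) {
    out[[sprintf("control_%d", i)]] <- ctl_counts[, i]
    out[[sprintf("depleted_%d", i)]] <- dep_counts[, i]
  }
  out$depletion_percent <- rowMeans(d, na.rm = TRUE)
  out <- out[c_order(-rowSums(ctl_counts), out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "control_absent") <- sort(absent, method = "radix")
  out
}

#' Concordance of organism abundances between two annotation routes
#'
#' Compares organism abundance estimates derived from mRNA annotations
#' with those derived from rRNA annotations (or any two routes) after
#' rolling both up to a common taxonomic rank.  The Pearson correlation is
#' computed on relative abundances over the union of rank-level taxa, with
#' absent taxa entered as zero so dropout is penalized; an
#' intersection-only mode is available.
#'
#' @param mrna,rrna organism-level [abundance_table()]s.
#' @param tax a [taxonomy_map()] (may be `NULL` for the genus fallback of
#'   [rollup_rank()]).
#' @param rank taxonomic rank at which to compare.
#' @param bacteria_only drop taxa whose mapped `domain` is not
#'   `"Bacteria"` (requires a map with a `domain` column); unmapped
#'   organisms are dropped too, since their domain is unknown.
#' @param mode `"union"` (absent taxa count as zero) or `"intersection"`.
#' @return The Pearson correlation coefficient.
#' @export
rank_correlation <- function(mrna, rrna, tax = NULL, rank = "genus",
                             bacteria_only = FALSE,
                             mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mrna, "abundance_table"),
            inherits(rrna, "abundance_table"))
  if (bacteria_only) {
    if (is.null(tax) || !"domain" %in% names(tax))
      abort_samsa("bacteria_only needs a taxonomy map with a 'domain' column",
                  "samsa_validation_error")
    keep_orgs <- tax$organism[tax$domain == "Bacteria"]
    restrict <- function(t) {
      k <- intersect(names(t$counts), keep_orgs)
      abundance_table(t$counts[k], t$sample_id, t$source_db)
    }
    mrna <- restrict(mrna)
    rrna <- restrict(rrna)
  }
  a <- rollup_rank(mrna, tax, rank)
  b <- rollup_rank(rrna, tax, rank)
  if (a$total == 0 || b$total == 0)
    abort_samsa("a table is empty after rollup/filtering",
                "samsa_validation_error")
  ra <- relative_abundance(a)
  rb <- relative_abundance(b)
  taxa <- if (mode == "union") union(names(ra), names(rb))
          else intersect(names(ra), names(rb))
  x <- ifelse(is.na(ra[taxa]), 0, ra[taxa])
  y <- ifelse(is.na(rb[taxa]), 0, rb[taxa])
  shared <- sum(x > 0 & y > 0)
  if (shared < 3L)
    abort_samsa(sprintf(
      "only %d taxa shared at rank '%s'; correlation unstable", shared,
      rank), "samsa_validation_error")
  cor(x, y)
}

#' Compare paired-end and single-read annotation outcomes
#'
#' Summarizes how much annotation yield and profile agreement is lost when
#' the same library is processed as truncated single reads instead of
#' joined/paired reads: total and unique annotation counts per route, the
#' number of shared features, and the Pearson correlation of
#' log10(count + 1) over the union of features (absent = 0; intersection
#' mode available).
#'
#' @param pe,sr [abundance_table()]s from the paired-end and single-read
#'   routes, same source database.
#' @param mode `"union"` or `"intersection"` feature handling for the
#'   correlation.
#' @return A list of class `pe_sr_comparison`: `total_pe`, `total_sr`,
#'   `unique_pe`, `unique_sr`, `shared_features`, `pearson_r_log`.
#' @export
compare_pe_sr <- function(pe, sr, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pe, "abundance_table"),
            inherits(sr, "abundance_table"))
  if (pe$source_db != sr$source_db)
    abort_samsa("tables come from different source databases",
                "samsa_validation_error")
  if (pe$total == 0 && sr$total == 0)
    abort_samsa("both tables are empty", "samsa_validation_error")
  feats <- if (mode == "union") union(names(pe$counts), names(sr$counts))
           else intersect(names(pe$counts), names(sr$counts))
  x <- pe$counts[feats]; x[is.na(x)] <- 0
  y <- sr$counts[feats]; y[is.na(y)] <- 0
  r <- if (length(feats) >= 3L) cor(log10(x + 1), log10(y + 1))
       else NA_real_
  structure(list(total_pe = pe$total, total_sr = sr$total,
                 unique_pe = length(pe$counts),
                 unique_sr = length(sr$counts),
                 shared_features = length(intersect(names(pe$counts),
                                                    names(sr$counts))),
                 pearson_r_log = r),
            class = "pe_sr_comparison")
}

#' @export
print.pe_sr_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "paired-end vs single-read comparison\n",
    "  total annotations : %s vs %s\n",
    "  unique annotations: %s vs %s (shared %s)\n",
    "  Pearson r on log10(count+1): %.3f\n"),
    format(x$total_pe, big.mark = ","), format(x$total_sr, big.mark = ","),
    format(x$unique_pe, big.mark = ","), format(x$unique_sr, big.mark = ","),
    format(x$shared_features, big.mark = ","), x$pearson_r_log))
  invisible(x)
}
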