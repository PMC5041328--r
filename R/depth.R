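#' Specify a subsampling experiment
#'
#' Defaults follow the operational depth-evaluation design: subset sizes
#' of 1, 5, 10, 20, ..., 90 percent of the parent, 100 replicate subsets
#' per size.
#'
#' @param fractions strictly increasing proportions in (0, 1].
#' @param replicates subsets drawn per fraction.
#' @param seed RNG seed controlling all draws.
#' @return An object of class `subsample_spec`.
#' @export
subsample_spec <- function(fractions = c(0.01, 0.05, 0.10, 0.20, 0.30,
                                         0.40, 0.50, 0.60, 0.70, 0.80,
                                         0.90),
                           replicates = 100L, seed = 1L) {
  fractions <- as.numeric(fractions)
  if (any(fractions <= 0 | fractions > 1))
    abort_samsa("fractions must lie in (0, 1]", "samsa_validation_error")
  if (is.unsorted(fractions, strictly = TRUE))
    abort_samsa("fractions must be sorted ascending and unique",
                "samsa_validation_error")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    abort_samsa("replicates must be >= 1", "samsa_validation_error")
  structure(list(fractions = fractions, replicates = replicates,
                 seed = as.integer(seed)),
            class = "subsample_spec")
}

# Multivariate hypergeometric draw: n reads without replacement from a
# population whose composition is `counts`.  Sequential conditional
# hypergeometric draws; O(#features).
rmvhyper <- function(counts, n) {
  k <- length(counts)
  out <- numeric(k)
  remaining <- sum(counts)
  for (i in seq_len(k)) {
    if (n <= 0) break
    ci <- counts[i]
    drawn <- rhyper(1L, ci, remaining - ci, n)
    out[i] <- drawn
    n <- n - drawn
    remaining <- remaining - ci
  }
  out
}

#' Draw a random subset of an abundance table
#'
#' Emulates sequencing fewer reads: `round(fraction * total)` reads are
#' drawn without replacement from the read population the counts imply
#' (multivariate hypergeometric), so no feature can exceed its parent
#' count and the subset total is exact.
#'
#' @param full parent [abundance_table()] with integer counts.
#' @param fraction proportion of reads to keep, in (0, 1].
#' @param seed RNG seed; the same seed reproduces the same subset.
#' @return An [abundance_table()] (zero-count features dropped).
#' @export
subsample_table <- function(full, fraction, seed = NULL) {
  stopifnot(inherits(full, "abundance_table"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    abort_samsa("fraction must lie in (0, 1]", "samsa_validation_error")
  counts <- full$counts
  if (any(counts != round(counts)))
    abort_samsa("subsampling requires integer counts (count_all policy)",
                "samsa_validation_error")
  if (full$total < 1)
    abort_samsa("parent table is empty", "samsa_validation_error")
  n <- round(fraction * full$total)
  sub <- with_seed_opt(seed, rmvhyper(counts, n))
  keep <- sub > 0
  abundance_table(setNames(sub[keep], names(counts)[keep]),
                  full$sample_id, full$source_db)
}

#' Default abundance-class specification
#'
#' Three strata of the parent's sorted feature list: `high` = the 5 most
#' abundant features; `medium` = features inside the top half of the
#' sorted list, excluding `high`; `low` = the bottom tenth of the sorted
#' list.
#'
#' @param high_n number of top features forming the high class.
#' @param medium_top_frac fraction of the sorted list whose members (minus
#'   the high class) form the medium class.
#' @param low_bottom_frac fraction of the sorted list, from the bottom,
#'   forming the low class.
#' @return A list understood by [classify_abundance()].
#' @export
class_spec <- function(high_n = 5L, medium_top_frac = 0.5,
                       low_bottom_frac = 0.1) {
  list(high_n = as.integer(high_n),
       medium_top_frac = medium_top_frac,
       low_bottom_frac = low_bottom_frac)
}

#' Stratify features of a table into high / medium / low abundance classes
#'
#' Classes are taken on the deterministic sorted order of
#' [sort_abundance()] (count-descending, lexicographic tie-break), so
#' equal-count features are assigned reproducibly.  Classes are disjoint;
#' features falling in none of the strata are unassigned.
#'
#' @param full an [abundance_table()] with at least `high_n + 1` features.
#' @param spec a [class_spec()].
#' @return Named list of character vectors `high`, `medium`, `low`.
#' @export
classify_abundance <- function(full, spec = class_spec()) {
  stopifnot(inherits(full, "abundance_table"))
  sorted <- sort_abundance(full)
  k <- nrow(sorted)
  if (k < spec$high_n + 1L)
    abort_samsa(sprintf(
      "only %d features; need more than %d for distinct abundance classes",
      k, spec$high_n), "samsa_validation_error")
  high_idx <- seq_len(spec$high_n)
  top_end <- ceiling(spec$medium_top_frac * k)
  medium_idx <- setdiff(seq_len(top_end), high_idx)
  low_n <- ceiling(spec$low_bottom_frac * k)
  low_idx <- setdiff(seq.int(k - low_n + 1L, k), c(high_idx, medium_idx))
  list(high = sorted$annotation[high_idx],
       medium = sorted$annotation[medium_idx],
       low = sorted$annotation[low_idx])
}

# Accuracy of a subset's abundance estimate for one feature, given parent
# and subset relative abundances: 100 * (1 - |rel_s - rel_full|/rel_full),
# clamped to [0, 100] because the relative deviation of a rare feature can
# exceed 100%.
accuracy_pct <- function(rel_sub, rel_full) {
  pmin(100, pmax(0, 100 * (1 - abs(rel_sub - rel_full) / rel_full)))
}

#' Accuracy of abundance estimates as a function of sequencing depth
#'
#' For each subset fraction and replicate, a random subset is drawn and
#' each classified feature's relative abundance is compared with the
#' parent's: accuracy = 100 minus the percentage deviation from the
#' parent value, clamped to [0, 100].  Accuracies are averaged (unweighted
#' over features and replicates) within each abundance class.
#'
#' @param full parent [abundance_table()] (integer counts, total >= 10).
#' @param spec a [subsample_spec()].
#' @param classes a [class_spec()].
#' @return An `accuracy_curve` data frame with columns `fraction`,
#'   `reads`, `class`, `mean_accuracy`, `sd_accuracy`, `n_features`,
#'   `n_replicates`; attribute `total_reads` carries the parent depth.
#' @export
accuracy_curve <- function(full, spec = subsample_spec(),
                           classes = class_spec()) {
  stopifnot(inherits(full, "abundance_table"),
            inherits(spec, "subsample_spec"))
  if (full$total < 10)
    abort_samsa("parent table too small (< 10 reads)",
                "samsa_validation_error")
  strata <- classify_abundance(full, classes)
  strata <- strata[lengths(strata) > 0L]
  rel_full <- relative_abundance(full)
  feats <- names(full$counts)

  rows <- with_seed_opt(spec$seed, {
    lapply(spec$fractions, function(f) {
      acc <- matrix(NA_real_, nrow = length(feats),
                    ncol = spec$replicates, dimnames = list(feats, NULL))
      n_sub <- round(f * full$total)
      for (r in seq_len(spec$replicates)) {
        sub <- rmvhyper(full$counts, n_sub)
        acc[, r] <- accuracy_pct(sub / n_sub, rel_full)
      }
      do.call(rbind, lapply(names(strata), function(cl) {
        vals <- acc[strata[[cl]], , drop = FALSE]
        data.frame(fraction = f, reads = n_sub, class = cl,
                   mean_accuracy = mean(vals),
                   sd_accuracy = sd(as.numeric(vals)),
                   n_features = length(strata[[cl]]),
                   n_replicates = spec$replicates,
                   stringsAsFactors = FALSE)
      }))
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "total_reads") <- full$total
  class(out) <- c("accuracy_curve", "data.frame")
  out
}

#' Minimum depth at which a class reaches an accuracy threshold
#'
#' Scans an accuracy curve for the smallest subset size whose mean
#' accuracy for the given class meets the threshold, and converts it to an
#' absolute read count.  Defaults target the low-abundance class at 90%
#' accuracy, the usual sufficiency yardstick.
#'
#' @param curve an [accuracy_curve()] result.
#' @param class `"high"`, `"medium"`, or `"low"`.
#' @param threshold percent accuracy required.
#' @return List with `fraction` and `reads`, or `NULL` if the threshold is
#'   never reached.
#' @export
min_depth <- function(curve, class = "low", threshold = 90) {
  stopifnot(inherits(curve, "accuracy_curve"), nrow(curve) > 0)
  if (!class %in% curve$class)
    abort_samsa(sprintf("unknown abundance class '%s'", class),
                "samsa_validation_error")
  sub <- curve[curve$class == class & curve$mean_accuracy >= threshold, ,
               drop = FALSE]
  if (nrow(sub) == 0L) return(NULL)
  i <- which.min(sub$fraction)
  list(fraction = sub$fraction[i], reads = sub$reads[i])
}

#' Write an accuracy curve as TSV
#' @param curve an [accuracy_curve()] result.
#' @param file output path.
#' @param extra_header named character vector of `key=value` header fields.
#' @return `file`, invisibly.
#' @export
write_accuracy_tsv <- function(curve, file, extra_header = character()) {
  hdr <- c(sprintf("# samsa accuracy_curve v%s",
                   as.character(utils::packageVersion("samsa"))),
           sprintf("# total_reads=%s", attr(curve, "total_reads")),
           if (length(extra_header))
             sprintf("# %s=%s", names(extra_header), extra_header))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(curve), collapse = "\t"), con)
  write.table(curve, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}
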