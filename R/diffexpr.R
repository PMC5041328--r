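#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: each sample's factor is the median,
#' over features expressed in every sample, of the ratio between that
#' sample's count and the feature's geometric mean across samples.
#' Features with any zero are excluded from the reference geometric means.
#'
#' @param matrix a [count_matrix()].
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(matrix) {
  stopifnot(inherits(matrix, "count_matrix"))
  m <- matrix$counts
  log_geo <- rowMeans(log(m))       # -Inf whenever a feature has a zero
  use <- is.finite(log_geo)
  if (!any(use))
    abort_samsa(paste(
      "no feature has nonzero counts in every sample;",
      "size factors are undefined (try filtering rare features",
      "or merging more deeply sequenced samples)"),
      "samsa_validation_error")
  sf <- apply(m, 2, function(cnts)
    exp(median((log(cnts) - log_geo)[use])))
  setNames(sf, colnames(m))
}

#' Estimate negative-binomial dispersions with trend shrinkage
#'
#' A transparent method-of-moments pipeline for the NB variance model
#' Var = mu + alpha * mu^2.  Per feature, the raw dispersion is
#' alpha_hat = max(0, (s^2 - mu) / mu^2) computed on normalized counts
#' within each condition group and pooled across groups (weighted by
#' degrees of freedom).  A mean-dispersion trend alpha(mu) = a0 + a1/mu
#' is fit by robust regression on the raw estimates, and the final
#' dispersion is a weighted geometric combination of raw and trend values,
#' floored at 1e-8.
#'
#' @param matrix a two-group [count_matrix()] with >= 2 samples per group.
#' @param factors size factors from [size_factors()].
#' @param trend_weight weight of the trend in the log-scale combination,
#'   in [0, 1]; 0.5 balances per-feature signal against the stabilizing
#'   trend.
#' @return An object of class `dispersion_model`: `raw`, `trend_coef`
#'   (a0, a1), `trend`, `final` (all per feature), `mean` (normalized
#'   feature means).
#' @export
estimate_dispersions <- function(matrix, factors = size_factors(matrix),
                                 trend_weight = 0.5) {
  stopifnot(inherits(matrix, "count_matrix"))
  groups <- matrix$groups
  if (is.null(groups))
    abort_samsa("count matrix has no group labels", "samsa_validation_error")
  lv <- unique(groups)
  sizes <- table(groups)
  if (any(sizes < 2L))
    abort_samsa("each group needs at least 2 samples to estimate dispersion",
                "samsa_validation_error")
  norm <- sweep(matrix$counts, 2, factors, "/")
  mu_bar <- rowMeans(norm)

  num <- den <- numeric(nrow(norm))
  for (g in lv) {
    sub <- norm[, groups == g, drop = FALSE]
    n_g <- ncol(sub)
    mu_g <- rowMeans(sub)
    var_g <- apply(sub, 1, var)
    a_g <- ifelse(mu_g > 0, (var_g - mu_g) / mu_g^2, 0)
    num <- num + (n_g - 1) * a_g
    den <- den + (n_g - 1)
  }
  raw <- pmax(0, num / den)
  names(raw) <- rownames(norm)

  floor_a <- 1e-8
  fit_ok <- mu_bar > 0
  trend_coef <- c(a0 = 0, a1 = 0)
  if (sum(fit_ok) >= 10L && any(raw[fit_ok] > 0)) {
    df_fit <- data.frame(a = raw[fit_ok], inv_mu = 1 / mu_bar[fit_ok])
    fit <- tryCatch(
      suppressWarnings(MASS::rlm(a ~ inv_mu, data = df_fit, maxit = 50L)),
      error = function(e) lm(a ~ inv_mu, data = df_fit))
    cf <- coef(fit)
    trend_coef <- c(a0 = max(0, unname(cf[1])), a1 = max(0, unname(cf[2])))
  }
  trend <- ifelse(mu_bar > 0,
                  trend_coef["a0"] + trend_coef["a1"] / mu_bar, 0)
  w <- trend_weight
  # a zero raw estimate carries no per-feature signal (the moment
  # estimator truncated at zero); such features take the trend value
  # outright instead of dragging the geometric mean to the floor
  raw_eff <- ifelse(raw > floor_a, raw, pmax(trend, floor_a))
  final <- exp((1 - w) * log(pmax(raw_eff, floor_a)) +
               w * log(pmax(trend, floor_a)))
  final <- pmax(final, floor_a)
  structure(list(raw = raw, trend_coef = trend_coef,
                 trend = setNames(trend, names(raw)),
                 final = setNames(final, names(raw)),
                 mean = setNames(mu_bar, names(raw)),
                 trend_weight = w),
            class = "dispersion_model")
}

#' Per-feature negative-binomial Wald tests between two groups
#'
#' For each feature, group means on the normalized scale are estimated as
#' q_g = mean over samples j in g of count_j / s_j; the log2 fold
#' change is log2(q2 / q1) with the second group label (in the order the
#' labels appear in the matrix) as numerator.  When a group mean is zero,
#' a pseudo-mean of 0.5 normalized counts is added to both groups so the
#' fold change stays finite (flagged in column `pseudo`).  The standard
#' error comes from the NB Fisher information
#' I_g = sum_j mu_gj / (1 + alpha mu_gj), mu_gj = s_j q_g, and the
#' two-sided p-value from the normal tail of log2fc / se.  All-zero
#' features are reported with log2fc 0 and p 1 rather than dropped.
#'
#' @param matrix a two-group [count_matrix()].
#' @param factors size factors.
#' @param dispersions a `dispersion_model` (its `final` slot is used) or a
#'   per-feature numeric vector.
#' @return Data frame with columns `feature`, `base_mean`, `log2fc`, `se`,
#'   `wald_p`, `pseudo`, in matrix feature order.
#' @export
nb_wald_test <- function(matrix, factors = size_factors(matrix),
                         dispersions = estimate_dispersions(matrix, factors)) {
  stopifnot(inherits(matrix, "count_matrix"))
  groups <- matrix$groups
  if (is.null(groups) || length(unique(groups)) != 2L)
    abort_samsa("exactly two group labels are required",
                "samsa_validation_error")
  alpha <- if (inherits(dispersions, "dispersion_model"))
    dispersions$final else dispersions
  m <- matrix$counts
  lv <- unique(groups)         # first label = reference (denominator)
  j1 <- groups == lv[1]
  j2 <- groups == lv[2]
  s1 <- factors[j1]; s2 <- factors[j2]
  norm <- sweep(m, 2, factors, "/")
  # group means on the normalized scale; scale-equivariant, so rescaling
  # any one sample leaves fold changes untouched
  q1 <- rowMeans(norm[, j1, drop = FALSE])
  q2 <- rowMeans(norm[, j2, drop = FALSE])
  base_mean <- rowMeans(norm)

  pseudo <- (q1 == 0 | q2 == 0)
  q1s <- ifelse(pseudo, q1 + 0.5, q1)
  q2s <- ifelse(pseudo, q2 + 0.5, q2)
  log2fc <- log2(q2s / q1s)

  info <- function(q, s, alpha) {
    mu <- outer(q, s)                      # features x samples in group
    rowSums(mu / (1 + alpha * mu))
  }
  i1 <- info(q1s, s1, alpha)
  i2 <- info(q2s, s2, alpha)
  se <- sqrt(1 / i1 + 1 / i2) / log(2)
  z <- log2fc / se
  wald_p <- 2 * pnorm(-abs(z))

  all_zero <- q1 == 0 & q2 == 0
  log2fc[all_zero] <- 0
  se[all_zero] <- NA_real_
  wald_p[all_zero] <- 1

  data.frame(feature = rownames(m), base_mean = base_mean,
             log2fc = log2fc, se = se, wald_p = wald_p, pseudo = pseudo,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group differential abundance with BH correction
#'
#' Full differential stage: size factors, dispersion estimation, Wald
#' tests, Benjamini-Hochberg step-up adjustment over all tested features,
#' and sorting by adjusted p-value (ties broken by raw p, then feature
#' name).
#'
#' @param matrix a two-group [count_matrix()].
#' @param trend_weight passed to [estimate_dispersions()].
#' @return Data frame of class `de_result` with columns `feature`,
#'   `base_mean`, `log2fc`, `se`, `wald_p`, `padj`, `pseudo`, sorted by
#'   `padj`.  The contrast (numerator vs denominator group) is recorded in
#'   attribute `contrast`.
#' @export
run_differential <- function(matrix, trend_weight = 0.5) {
  stopifnot(inherits(matrix, "count_matrix"))
  factors <- size_factors(matrix)
  disp <- estimate_dispersions(matrix, factors, trend_weight)
  res <- nb_wald_test(matrix, factors, disp)
  res$padj <- p.adjust(res$wald_p, method = "BH")
  res <- res[c_order(res$padj, res$wald_p, res$feature),
             c("feature", "base_mean", "log2fc", "se", "wald_p", "padj",
               "pseudo")]
  rownames(res) <- NULL
  lv <- unique(matrix$groups)
  attr(res, "contrast") <- sprintf("%s vs %s", lv[2], lv[1])
  class(res) <- c("de_result", "data.frame")
  res
}

#' Write differential results as sorted TSV
#' @param results a `de_result` from [run_differential()].
#' @param file output path.
#' @param extra_header named character vector of `key=value` header fields.
#' @return `file`, invisibly.
#' @export
write_de_tsv <- function(results, file, extra_header = character()) {
  hdr <- c(sprintf("# samsa de_result v%s",
                   as.character(utils::packageVersion("samsa"))),
           sprintf("# contrast=%s", attr(results, "contrast") %||% ""),
           if (length(extra_header))
             sprintf("# %s=%s", names(extra_header), extra_header))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(results), collapse = "\t"), con)
  write.table(results, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}
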