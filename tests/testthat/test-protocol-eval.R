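test_that("identical profiles show zero depletion everywhere", {
  ctl <- abundance_table(c(F1 = 100, F2 = 300, F3 = 600), "c")
  dep <- abundance_table(c(F1 = 50, F2 = 150, F3 = 300), "d")
  rows <- depletion_percent(ctl, dep)
  expect_true(all(abs(rows$depletion_percent) < 1e-12))
})

test_that("a taxon lost from the depleted library scores 100", {
  ctl <- abundance_table(c(F1 = 100, F2 = 100), "c")
  dep <- abundance_table(c(F1 = 100), "d")
  rows <- depletion_percent(ctl, dep)
  expect_equal(rows$depletion_percent[rows$taxon == "F2"], 100)
})

test_that("depletion is invariant to library-size rescaling", {
  ctl <- abundance_table(c(A = 120, B = 60, C = 20), "c")
  dep <- abundance_table(c(A = 90, B = 10, C = 20), "d")
  base <- depletion_percent(ctl, dep)$depletion_percent
  dep10 <- abundance_table(dep$counts * 10, "d")
  scaled <- depletion_percent(ctl, dep10)$depletion_percent
  expect_equal(base, scaled)
})

test_that("taxa absent from control are excluded and reported", {
  ctl <- abundance_table(c(A = 100), "c")
  dep <- abundance_table(c(A = 50, Z = 50), "d")
  rows <- depletion_percent(ctl, dep)
  expect_false("Z" %in% rows$taxon)
  expect_equal(attr(rows, "control_absent"), "Z")
  expect_error(depletion_percent(abundance_table(setNames(
    numeric(), character()), "c"), dep),
    class = "samsa_validation_error")
})

test_that("multiple pairs average per-pair depletion", {
  c1 <- abundance_table(c(A = 100, B = 100), "c1")
  d1 <- abundance_table(c(A = 100, B = 100), "d1")   # 0 %
  c2 <- abundance_table(c(A = 100, B = 100), "c2")
  d2 <- abundance_table(c(A = 100), "d2")            # B: 100 %
  rows <- depletion_percent(list(c1, c2), list(d1, d2))
  b <- rows[rows$taxon == "B", ]
  # pair 1: 0; pair 2: 100 -> mean 50.  A gains share in pair 2: -100.
  expect_equal(b$depletion_percent, 50)
  expect_equal(rows$depletion_percent[rows$taxon == "A"], -50)
})

test_that("planted retention factors are recovered from simulated pairs", {
  retention <- c(Firmicutes = 0.3)
  prof <- sim_community(n_taxa = 20, rrna_fraction = 0.9,
                        retention = retention, seed = 61)
  tx <- profile_taxonomy(prof)
  per_pair <- vapply(1:4, function(i) {
    pair <- sim_depleted_pair(prof, 30000, seed = 70 + i)
    ctl <- rollup_rank(aggregate_counts(filter_rrna(pair$control)$rrna,
                                        sample_id = "c"), tx, "phylum")
    dep <- rollup_rank(aggregate_counts(filter_rrna(pair$depleted)$rrna,
                                        sample_id = "d"), tx, "phylum")
    rows <- depletion_percent(ctl, dep)
    rows$depletion_percent[rows$taxon == "Firmicutes"]
  }, numeric(1))
  truth <- sim_depleted_pair(prof, 100, seed = 1)$truth
  expected <- truth$expected_depletion[["Firmicutes"]]
  se <- sd(per_pair) / sqrt(length(per_pair))
  expect_equal(mean(per_pair), expected, tolerance = 3 * se / abs(expected))
})

test_that("proportional tables correlate perfectly at any rank", {
  m <- abundance_table(c("Escherichia coli" = 40, "Shigella flexneri" = 30,
                         "Bacteroides fragilis" = 20, "Homo sapiens" = 10))
  r <- abundance_table(c("Escherichia coli" = 400,
                         "Shigella flexneri" = 300,
                         "Bacteroides fragilis" = 200,
                         "Homo sapiens" = 100))
  expect_equal(rank_correlation(m, r, toy_taxonomy(), "genus"), 1.0)
})

test_that("the four-taxon anti-ordered case gives exactly -1", {
  m <- abundance_table(c(A = 0.4, B = 0.3, C = 0.2, D = 0.1) * 1000)
  r <- abundance_table(c(A = 0.1, B = 0.2, C = 0.3, D = 0.4) * 1000)
  got <- rank_correlation(m, r, NULL, "genus")
  expect_equal(got, -1.0)
  expect_equal(got, hand_pearson(c(0.4, 0.3, 0.2, 0.1),
                                 c(0.1, 0.2, 0.3, 0.4)))
})

test_that("rank correlation is symmetric and scale-invariant", {
  m <- random_table(12L, seed = 18L)
  r <- random_table(12L, seed = 19L)
  ab <- rank_correlation(m, r, NULL, "genus")
  ba <- rank_correlation(r, m, NULL, "genus")
  expect_equal(ab, ba)
  m2 <- abundance_table(m$counts * 7, m$sample_id)
  expect_equal(rank_correlation(m2, r, NULL, "genus"), ab)
})

test_that("bacteria-only filtering drops non-bacterial lineages", {
  m <- abundance_table(c("Escherichia coli" = 40, "Shigella flexneri" = 30,
                         "Bacteroides fragilis" = 20, "Homo sapiens" = 500))
  r <- abundance_table(c("Escherichia coli" = 35, "Shigella flexneri" = 32,
                         "Bacteroides fragilis" = 25, "Homo sapiens" = 2))
  with_host <- rank_correlation(m, r, toy_taxonomy(), "genus")
  without <- rank_correlation(m, r, toy_taxonomy(), "genus",
                              bacteria_only = TRUE)
  expect_lt(with_host, 0)       # host reads dominate and anti-correlate
  expect_gt(without, 0.9)
  expect_error(rank_correlation(m, r, NULL, "genus", bacteria_only = TRUE),
               class = "samsa_validation_error")
})

test_that("too few shared taxa is an error", {
  m <- abundance_table(c(A = 10, B = 10, X = 1))
  r <- abundance_table(c(C = 10, D = 10, X = 1))
  expect_error(rank_correlation(m, r, NULL, "genus"),
               class = "samsa_validation_error")
})

test_that("coupled mRNA/rRNA libraries from one community agree at genus", {
  prof <- sim_community(n_taxa = 25, rrna_fraction = 0.5, seed = 81)
  recs <- sim_annotations(prof, 60000, seed = 82)
  parts <- filter_rrna(recs)
  mrna <- aggregate_counts(parts$mrna, sample_id = "m")
  rrna_tab <- abundance_table(
    aggregate_counts(parts$rrna, sample_id = "r")$counts, "r", "refseq_org")
  r <- rank_correlation(mrna, rrna_tab, profile_taxonomy(prof), "genus")
  expect_gte(r, 0.95)
})

test_that("identical tables compare as identical", {
  tab <- random_table(25L, seed = 20L)
  cmp <- compare_pe_sr(tab, tab)
  expect_equal(cmp$total_pe, cmp$total_sr)
  expect_equal(cmp$unique_pe, cmp$unique_sr)
  expect_equal(cmp$shared_features, cmp$unique_pe)
  expect_equal(cmp$pearson_r_log, 1.0)
})

test_that("disjoint feature sets share nothing", {
  a <- abundance_table(c(A = 1, B = 2, C = 1))
  b <- abundance_table(c(X = 3, Y = 1, Z = 2))
  expect_equal(compare_pe_sr(a, b)$shared_features, 0L)
  expect_error(compare_pe_sr(abundance_table(setNames(numeric(),
                                                      character())),
                             abundance_table(setNames(numeric(),
                                                      character()))),
               class = "samsa_validation_error")
})

test_that("the log-scale correlation matches a hand computation", {
  pe <- random_table(50L, seed = 22L)
  counts <- pe$counts
  withr::with_seed(23, {
    drop <- sample.int(50L, 10L)                        # 20 % dropout
    noisy <- pmax(round(counts * exp(rnorm(50, 0, 0.4))), 0)
    noisy[drop] <- 0
  })
  sr <- abundance_table(noisy[noisy > 0], "sr")
  cmp <- compare_pe_sr(pe, sr)
  feats <- union(names(pe$counts), names(sr$counts))
  x <- ifelse(is.na(pe$counts[feats]), 0, pe$counts[feats])
  y <- ifelse(is.na(sr$counts[feats]), 0, sr$counts[feats])
  expect_equal(cmp$pearson_r_log,
               hand_pearson(log10(x + 1), log10(y + 1)))
  expect_equal(cmp$shared_features, sum(x > 0 & y > 0))
})

test_that("digital truncation keeps the first bases of forward reads only", {
  fq <- sim_fastq(10, 150, seed = 31)
  sr <- simulate_single_end(fq$r1, fq$r2, keep_length = 100)
  expect_length(sr, 10L)
  expect_true(all(Biostrings::width(sr) == 100L))
  expect_true(all(Biostrings::width(Biostrings::quality(sr)) == 100L))
  expect_equal(as.character(sr[[1]]),
               substr(as.character(fq$r1[[1]]), 1, 100))
})

test_that("short reads pass unchanged and truncation is idempotent", {
  fq <- sim_fastq(5, 80, seed = 32)
  sr <- simulate_single_end(fq$r1, fq$r2, keep_length = 100)
  expect_equal(as.character(sr), as.character(fq$r1))
  twice <- simulate_single_end(simulate_single_end(fq$r1, NULL, 60),
                               NULL, 60)
  expect_equal(as.character(twice),
               as.character(simulate_single_end(fq$r1, NULL, 60)))
  expect_error(simulate_single_end(fq$r1, NULL, 0),
               class = "samsa_validation_error")
})

test_that("FASTQ round-trips through disk with qualities intact", {
  fq <- sim_fastq(8, 120, seed = 33)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(fq$r1, path)
  back <- read_fastq(path)
  expect_equal(as.character(back), as.character(fq$r1), ignore_attr = TRUE)
  expect_equal(as.character(Biostrings::quality(back)),
               as.character(Biostrings::quality(fq$r1)),
               ignore_attr = TRUE)
})
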