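test_that("each record contributes one count under count_all", {
  recs <- parse_annotations(text = c("r1\tm\t99\t100\t0\tE coli",
                                     "r2\tm\t99\t100\t0\tE coli",
                                     "r3\tm\t99\t100\t0\tB fragilis"),
                            source_db = "refseq_org")
  tab <- aggregate_counts(recs)
  expect_equal(tab$counts, c("B fragilis" = 1, "E coli" = 2))
  expect_equal(tab$total, 3)
})

test_that("a tied read contributes 1/k per record under fractional", {
  recs <- parse_annotations(text = "r1\tm\t99\t100\t0\tA;B",
                            source_db = "refseq_org")
  tab <- aggregate_counts(recs, tie_policy = "fractional")
  expect_equal(tab$counts, c(A = 0.5, B = 0.5))
  expect_equal(tab$total, 1)
})

test_that("tie policies conserve their respective totals on generator data", {
  prof <- sim_community(n_taxa = 15, rrna_fraction = 0, seed = 21)
  recs <- sim_annotations(prof, 2000, tie_rate = 0.2, seed = 22)
  n_reads <- length(unique(recs$read_id))
  expect_equal(aggregate_counts(recs)$total, nrow(recs))
  expect_equal(aggregate_counts(recs, "fractional")$total, n_reads)
})

test_that("aggregated proportions recover planted community proportions", {
  prof <- sim_community(n_taxa = 10, rrna_fraction = 0, seed = 31)
  recs <- sim_annotations(prof, 10000, seed = 32)
  tab <- aggregate_counts(recs)
  p <- setNames(prof$taxa$proportion, prof$taxa$organism)
  obs <- tab$counts[names(p)]
  obs[is.na(obs)] <- 0
  sd3 <- 3 * sqrt(10000 * p * (1 - p))
  expect_true(all(abs(obs - 10000 * p) <= pmax(sd3, 3)))
})

test_that("mixed source databases are rejected", {
  recs <- tiny_records()
  recs$source_db[1] <- "silva_ssu"
  expect_error(aggregate_counts(recs), class = "samsa_validation_error")
})

test_that("sorting is count-descending with lexicographic tie-break", {
  tab <- abundance_table(c(A = 1, C = 3, B = 3))
  expect_equal(sort_abundance(tab),
               data.frame(annotation = c("B", "C", "A"),
                          count = c(3, 3, 1)))
  expect_equal(nrow(sort_abundance(abundance_table(setNames(
    numeric(), character())))), 0L)
})

test_that("sorted output is a non-increasing permutation of the table", {
  for (seed in c(1, 2, 3)) {
    tab <- random_table(30L, seed = seed)
    s <- sort_abundance(tab)
    expect_setequal(s$annotation, names(tab$counts))
    expect_true(all(diff(s$count) <= 0))
    expect_equal(sum(s$count), tab$total)
  }
})

test_that("rank rollup sums lineages and conserves totals", {
  tab <- abundance_table(c("Escherichia coli" = 5, "Shigella flexneri" = 2))
  fam <- rollup_rank(tab, toy_taxonomy(), "family")
  expect_equal(fam$counts, c(Enterobacteriaceae = 7))
  # unmapped organisms pool into unclassified
  tab2 <- abundance_table(c("Escherichia coli" = 5, "Mystery bug" = 4))
  phy <- rollup_rank(tab2, toy_taxonomy(), "phylum")
  expect_equal(phy$counts[["unclassified"]], 4)
  expect_equal(phy$total, tab2$total)
  expect_error(rollup_rank(tab, toy_taxonomy(), "kingdom"),
               class = "samsa_validation_error")
})

test_that("genus fallback takes the first token; coarser ranks need a map", {
  tab <- abundance_table(c("Escherichia coli" = 5, "Escherichia albertii" = 1,
                           "Bacteroides fragilis" = 3))
  gen <- rollup_rank(tab, NULL, "genus")
  expect_equal(gen$counts, c(Bacteroides = 3, Escherichia = 6))
  expect_error(rollup_rank(tab, NULL, "family"),
               class = "samsa_validation_error")
})

test_that("rollup conserves totals on random lineage fixtures", {
  prof <- sim_community(n_taxa = 25, seed = 41)
  tab <- sim_abundance_table(prof, 5000, seed = 42)
  tx <- profile_taxonomy(prof)
  for (rank in c("phylum", "order", "family", "genus"))
    expect_equal(rollup_rank(tab, tx, rank)$total, tab$total)
})

test_that("top-N keeps n categories plus a conserving Other bucket", {
  tab <- random_table(40L, seed = 8L)
  kept <- top_n_other(tab, 30)
  expect_length(kept$counts, 31L)
  expect_true("Other" %in% names(kept$counts))
  expect_equal(kept$total, tab$total)
  # drop mode loses the remainder
  dropped <- top_n_other(tab, 30, mode = "drop")
  expect_length(dropped$counts, 30L)
  expect_lt(dropped$total, tab$total)
  # fewer taxa than n: unchanged, no Other row
  small <- random_table(5L, seed = 9L)
  expect_equal(top_n_other(small, 30)$counts[names(small$counts)],
               small$counts)
  expect_false("Other" %in% names(top_n_other(small, 30)$counts))
  expect_error(top_n_other(tab, 0), class = "samsa_validation_error")
})

test_that("default display cut-off keeps the 30 most abundant categories", {
  expect_equal(eval(formals(top_n_other)$n), 30L)
  tab <- random_table(45L, seed = 10L)
  expect_length(top_n_other(tab)$counts, 31L)
})

test_that("an input key named Other is escaped, not absorbed", {
  tab <- abundance_table(setNames(c(50, rep(1, 35)),
                                  c("Other", sprintf("t%02d", 1:35))))
  kept <- top_n_other(tab, 10)
  expect_true("Other (annotation)" %in% names(kept$counts))
  expect_equal(kept$total, tab$total)
})

test_that("relative abundances are proportions summing to one", {
  expect_equal(relative_abundance(abundance_table(c(A = 3, B = 1))),
               c(A = 0.75, B = 0.25))
  expect_equal(relative_abundance(abundance_table(c(X = 7))), c(X = 1))
  for (seed in 1:3)
    expect_equal(sum(relative_abundance(random_table(seed = seed))), 1,
                 tolerance = 1e-9)
  expect_error(relative_abundance(abundance_table(setNames(
    numeric(), character()))), class = "samsa_validation_error")
})

test_that("matrix merging unions features with zeros off-support", {
  t1 <- abundance_table(c(A = 1), sample_id = "s1")
  t2 <- abundance_table(c(B = 2), sample_id = "s2")
  m <- merge_to_matrix(list(t1, t2), c(s1 = "ctl", s2 = "trt"))
  expect_equal(dim(m$counts), c(2L, 2L))
  expect_equal(m$counts["A", "s2"], 0)
  expect_equal(m$counts["B", "s1"], 0)
  expect_equal(unname(colSums(m$counts)), c(1, 2))
})

test_that("a single table round-trips through the matrix", {
  tab <- random_table(12L, seed = 3L, sample_id = "only")
  m <- merge_to_matrix(tab)
  expect_equal(sort(m$counts[, "only"]), sort(tab$counts))
})

test_that("column sums equal table totals across generator samples", {
  prof <- sim_community(n_taxa = 18, seed = 51)
  tabs <- lapply(1:10, function(i)
    sim_abundance_table(prof, 800, sample_id = sprintf("s%d", i),
                        seed = 60 + i))
  m <- merge_to_matrix(tabs)
  expect_equal(unname(colSums(m$counts)),
               vapply(tabs, `[[`, numeric(1), "total"))
})

test_that("duplicate sample ids and missing labels are rejected", {
  t1 <- abundance_table(c(A = 1), sample_id = "s1")
  expect_error(merge_to_matrix(list(t1, t1)),
               class = "samsa_validation_error")
  t2 <- abundance_table(c(B = 2), sample_id = "s2")
  expect_error(merge_to_matrix(list(t1, t2), c(s1 = "ctl")),
               class = "samsa_validation_error")
})

test_that("abundance tables round-trip through their TSV form", {
  tab <- random_table(20L, seed = 13L, sample_id = "rt")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_tsv(tab, path, extra_header = c(seed = "13"))
  back <- read_abundance_tsv(path)
  expect_equal(back$sample_id, "rt")
  expect_equal(sort(back$counts), sort(tab$counts))
  expect_equal(back$total, tab$total)
})
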