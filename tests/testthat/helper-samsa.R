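# Shared fixture builders.  Everything is generated in code at test time;
# seeds are fixed so assertions are reproducible.

# a small record set written by hand, one tied read
tiny_records <- function() {
  parse_annotations(text = c(
    "r1\tm5_a\t98.5\t150\t1e-40\tEscherichia coli",
    "r2\tm5_b\t97.0\t140\t1e-35\tEscherichia coli",
    "r3\tm5_c\t96.0\t130\t1e-30\tBacteroides fragilis",
    "r4\tm5_d\t95.0\t120\t1e-25\tEscherichia coli;Shigella flexneri"),
    source_db = "refseq_org")
}

# random records with known annotation pool, for round-trip checks
random_records <- function(n = 500L, seed = 99L) {
  withr::with_seed(seed, {
    anns <- sprintf("Organism %02d str. X%d", sample(1:40, n, TRUE),
                    sample(1:5, n, TRUE))
    data.frame(
      read_id = sprintf("r%05d", seq_len(n)),
      match_id = sprintf("m5_%05d", sample.int(99999L, n)),
      percent_identity = round(runif(n, 80, 100), 1),
      alignment_length = sample(60:150, n, TRUE),
      evalue = signif(10^runif(n, -60, -5), 3),
      annotation_text = anns,
      source_db = "refseq_org",
      stringsAsFactors = FALSE)
  })
}

# a two-lineage toy taxonomy covering the organisms used in hand tests
toy_taxonomy <- function() {
  taxonomy_map(data.frame(
    organism = c("Escherichia coli", "Shigella flexneri",
                 "Bacteroides fragilis", "Homo sapiens"),
    domain = c("Bacteria", "Bacteria", "Bacteria", "Eukaryota"),
    phylum = c("Proteobacteria", "Proteobacteria", "Bacteroidetes",
               "Chordata"),
    class = c("Gammaproteobacteria", "Gammaproteobacteria", "Bacteroidia",
              "Mammalia"),
    order = c("Enterobacterales", "Enterobacterales", "Bacteroidales",
              "Primates"),
    family = c("Enterobacteriaceae", "Enterobacteriaceae",
               "Bacteroidaceae", "Hominidae"),
    genus = c("Escherichia", "Shigella", "Bacteroides", "Homo"),
    stringsAsFactors = FALSE))
}

random_table <- function(n_feat = 25L, seed = 7L, sample_id = "s") {
  withr::with_seed(seed, {
    counts <- rpois(n_feat, lambda = 40) + 1L
    abundance_table(setNames(as.numeric(counts),
                             sprintf("taxon_%03d", seq_len(n_feat))),
                    sample_id = sample_id)
  })
}

# Benjamini-Hochberg step-up written independently of stats::p.adjust,
# used as the oracle for adjusted p-values.
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Pearson correlation from the textbook sum formula, independent of cor()
hand_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}
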