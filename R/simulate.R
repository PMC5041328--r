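# Synthetic metatranscriptome generator.  Every generator is a pure
# function of its seed and emits its ground truth alongside the data, so
# recovery tests never have to re-derive it.

#' Built-in mock taxonomy
#'
#' A small fixed taxonomy (6 bacterial phyla, 30 genera, plus a few
#' non-bacterial entries to exercise domain filtering).  Real lineages are
#' unnecessary for correctness testing; names are representative gut
#' taxa.
#'
#' @return A [taxonomy_map()] with a `domain` column.
#' @export
mock_taxonomy <- function() {
  phyla <- list(
    Firmicutes = list(class = "Clostridia", order = "Eubacteriales",
      family = c("Lachnospiraceae", "Ruminococcaceae", "Clostridiaceae"),
      genus = c("Blautia", "Roseburia", "Butyrivibrio", "Lachnoclostridium",
                "Ruminococcus", "Faecalibacterium", "Clostridium",
                "Anaerostipes")),
    Bacteroidetes = list(class = "Bacteroidia", order = "Bacteroidales",
      family = c("Bacteroidaceae", "Prevotellaceae", "Rikenellaceae"),
      genus = c("Bacteroides", "Phocaeicola", "Prevotella", "Paraprevotella",
                "Alistipes", "Rikenella")),
    Proteobacteria = list(class = "Gammaproteobacteria",
      order = "Enterobacterales",
      family = c("Enterobacteriaceae", "Morganellaceae"),
      genus = c("Escherichia", "Shigella", "Klebsiella", "Providencia",
                "Proteus")),
    Actinobacteria = list(class = "Actinomycetia", order = "Bifidobacteriales",
      family = c("Bifidobacteriaceae", "Coriobacteriaceae"),
      genus = c("Bifidobacterium", "Gardnerella", "Collinsella",
                "Eggerthella")),
    Verrucomicrobia = list(class = "Verrucomicrobiae",
      order = "Verrucomicrobiales", family = c("Akkermansiaceae"),
      genus = c("Akkermansia", "Luteolibacter")),
    Spirochaetes = list(class = "Spirochaetia", order = "Spirochaetales",
      family = c("Spirochaetaceae", "Brachyspiraceae"),
      genus = c("Treponema", "Brachyspira", "Borrelia", "Leptonema",
                "Spirochaeta")))
  rows <- do.call(rbind, lapply(names(phyla), function(p) {
    ph <- phyla[[p]]
    fam <- rep(ph$family, length.out = length(ph$genus))
    data.frame(organism = paste(ph$genus, "sp."), domain = "Bacteria",
               phylum = p, class = ph$class, order = ph$order,
               family = fam, genus = ph$genus, stringsAsFactors = FALSE)
  }))
  extra <- data.frame(
    organism = c("Homo sapiens", "Arabidopsis thaliana",
                 "Methanobrevibacter smithii"),
    domain = c("Eukaryota", "Eukaryota", "Archaea"),
    phylum = c("Chordata", "Streptophyta", "Euryarchaeota"),
    class = c("Mammalia", "Magnoliopsida", "Methanobacteria"),
    order = c("Primates", "Brassicales", "Methanobacteriales"),
    family = c("Hominidae", "Brassicaceae", "Methanobacteriaceae"),
    genus = c("Homo", "Arabidopsis", "Methanobrevibacter"),
    stringsAsFactors = FALSE)
  taxonomy_map(rbind(rows, extra))
}

# catalog of function names shared across taxa, with taxon-specific usage
FUNCTION_POOL <- c(
  "DNA-directed RNA polymerase beta subunit",
  "Elongation factor Tu", "Chaperone protein DnaK",
  "ATP synthase F1 beta subunit", "Glyceraldehyde-3-phosphate dehydrogenase",
  "Pyruvate kinase", "Glutamine synthetase", "Flagellin",
  "ABC transporter ATP-binding protein", "Butyrate kinase",
  "Methyl-accepting chemotaxis protein", "Superoxide dismutase",
  "Cold shock protein CspA", "Phosphoenolpyruvate carboxykinase",
  "Beta-galactosidase", "Glycoside hydrolase family 2 protein",
  "Nitrogenase iron protein", "Catalase", "Enolase",
  "Ribose-phosphate pyrophosphokinase")

#' Simulate a microbial community profile
#'
#' Draws taxon proportions from a heavy-tailed abundance law (lognormal by
#' default, with the power law as an alternative), assigns lineages from
#' the built-in mock taxonomy, and equips each taxon with a function
#' catalog.  The profile also fixes the community's rRNA content and the
#' per-phylum rRNA retention factors a ribodepletion step would apply.
#'
#' @param n_taxa number of taxa (>= 2; recycled over the mock taxonomy
#'   with numbered species when larger).
#' @param abundance_law `"lognormal"` (params: `sigma`, default 1.5) or
#'   `"power"` (params: `exponent`, default 1.5).
#' @param params parameters of the abundance law.
#' @param rrna_fraction expected fraction of reads that are ribosomal.
#'   The default 0.9 reflects non-ribodepleted total-RNA libraries, where
#'   rRNA dominates.
#' @param retention named per-phylum rRNA retention probabilities in
#'   [0, 1] applied by [sim_depleted_pair()] (0 = complete depletion);
#'   default 1 (no depletion bias).
#' @param n_functions functions in each taxon's catalog.
#' @param seed RNG seed.
#' @return An object of class `community_profile`: `taxa` (data frame
#'   with lineage and `proportion`), `functions` (per-taxon named
#'   proportion vectors), `rrna_fraction`, `retention`.
#' @export
sim_community <- function(n_taxa = 20L,
                          abundance_law = c("lognormal", "power"),
                          params = list(), rrna_fraction = 0.9,
                          retention = NULL, n_functions = 5L, seed = 1L) {
  abundance_law <- match.arg(abundance_law)
  n_taxa <- as.integer(n_taxa)
  if (is.na(n_taxa) || n_taxa < 2L)
    abort_samsa("n_taxa must be >= 2", "samsa_validation_error")
  if (rrna_fraction < 0 || rrna_fraction >= 1)
    abort_samsa("rrna_fraction must lie in [0, 1)", "samsa_validation_error")
  tax <- as.data.frame(mock_taxonomy())
  tax <- tax[tax$domain == "Bacteria", , drop = FALSE]
  with_seed_opt(seed, {
    pool <- rep_len(sample.int(nrow(tax)), n_taxa)
    rows <- tax[pool, , drop = FALSE]
    dup <- duplicated(rows$organism)
    if (any(dup)) {
      idx <- ave(seq_len(n_taxa), rows$organism, FUN = seq_along)
      rows$organism <- ifelse(idx > 1L,
                              sprintf("%s sp. %d",
                                      sub(" sp\\.$", "", rows$organism),
                                      idx),
                              rows$organism)
    }
    props <- switch(abundance_law,
      lognormal = {
        sigma <- params$sigma %||% 1.5
        if (sigma <= 0) abort_samsa("sigma must be positive",
                                    "samsa_validation_error")
        rlnorm(n_taxa, meanlog = 0, sdlog = sigma)
      },
      power = {
        expo <- params$exponent %||% 1.5
        if (expo <= 0) abort_samsa("exponent must be positive",
                                   "samsa_validation_error")
        seq_len(n_taxa)^(-expo)
      })
    props <- props / sum(props)
    rows$proportion <- props
    rownames(rows) <- NULL

    funs <- lapply(seq_len(n_taxa), function(i) {
      fn <- sample(FUNCTION_POOL, min(n_functions, length(FUNCTION_POOL)))
      w <- rlnorm(length(fn), 0, 1)
      setNames(w / sum(w), fn)
    })
    names(funs) <- rows$organism

    phyla <- unique(rows$phylum)
    ret <- setNames(rep(1, length(phyla)), phyla)
    if (!is.null(retention)) {
      if (any(retention < 0 | retention > 1))
        abort_samsa("retention factors must lie in [0, 1]",
                    "samsa_validation_error")
      ret[names(retention)] <- retention
    }
    structure(list(taxa = rows, functions = funs,
                   rrna_fraction = rrna_fraction, retention = ret),
              class = "community_profile")
  })
}

#' Taxonomy map of a simulated community
#'
#' Communities may carry numbered duplicate species beyond the built-in
#' mock taxonomy, so rollups of simulated data should use the lineage the
#' profile itself records.
#'
#' @param profile a [sim_community()] profile.
#' @return A [taxonomy_map()] covering exactly the profile's taxa.
#' @export
profile_taxonomy <- function(profile) {
  stopifnot(inherits(profile, "community_profile"))
  taxonomy_map(profile$taxa[, c("organism", "domain", TAX_RANKS)])
}

# internal: read-level simulation shared by sim_annotations / sim_depleted_pair
sim_reads <- function(profile, n_reads) {
  taxa <- profile$taxa
  t_idx <- sample.int(nrow(taxa), n_reads, replace = TRUE,
                      prob = taxa$proportion)
  is_rrna <- runif(n_reads) < profile$rrna_fraction
  data.frame(read = seq_len(n_reads), taxon = t_idx, is_rrna = is_rrna)
}

reads_to_records <- function(profile, reads, source_db, tie_rate) {
  taxa <- profile$taxa
  n <- nrow(reads)
  org <- taxa$organism[reads$taxon]
  ann <- character(n)
  ann[reads$is_rrna] <- org[reads$is_rrna]
  if (any(!reads$is_rrna)) {
    idx <- which(!reads$is_rrna)
    ann[idx] <- if (source_db == "refseq_org") org[idx] else
      vapply(reads$taxon[idx], function(t) {
        f <- profile$functions[[t]]
        sample(names(f), 1L, prob = f)
      }, character(1))
  }
  src <- ifelse(reads$is_rrna, "silva_ssu", source_db)
  rec <- data.frame(
    read_id = sprintf("read_%07d", reads$read),
    match_id = sprintf("m5_%07d", reads$read),
    percent_identity = round(runif(n, 80, 100), 1),
    alignment_length = sample(60:150, n, replace = TRUE),
    evalue = signif(10^runif(n, -60, -10), 3),
    annotation_text = ann,
    source_db = src,
    stringsAsFactors = FALSE)
  if (tie_rate > 0) {
    tied <- which(runif(n) < tie_rate)
    if (length(tied)) {
      alt <- rec[tied, , drop = FALSE]
      # the tied second-best hit goes to a different random taxon/function
      alt_taxon <- sample.int(nrow(taxa), length(tied), replace = TRUE,
                              prob = taxa$proportion)
      alt$annotation_text <- if (source_db == "refseq_org")
        taxa$organism[alt_taxon]
      else vapply(alt_taxon, function(t) {
        f <- profile$functions[[t]]
        sample(names(f), 1L, prob = f)
      }, character(1))
      same <- alt$annotation_text == rec$annotation_text[tied]
      alt <- alt[!same, , drop = FALSE]
      rec <- rbind(rec, alt)
      rec <- rec[c_order(rec$read_id, rec$annotation_text), , drop = FALSE]
      rownames(rec) <- NULL
    }
  }
  rec
}

#' Simulate an annotation download
#'
#' Reads are assigned to taxa multinomially by the community's true
#' proportions; each read is ribosomal with probability `rrna_fraction`
#' (such records carry the SILVA SSU source and the organism name as
#' annotation), otherwise it carries an mRNA annotation from the given
#' source database (organism name, or a function drawn from the taxon's
#' catalog).  A `tie_rate` fraction of reads gain a second tied record
#' with a different annotation.  The generating profile is attached as
#' attribute `"truth"`.
#'
#' @param profile a [sim_community()] profile.
#' @param n_reads reads to simulate.
#' @param source_db mRNA source database for the records.
#' @param tie_rate probability a read has a tied second-best hit.
#' @param seed RNG seed.
#' @return Annotation record data frame (see [parse_annotations()]).
#' @export
sim_annotations <- function(profile, n_reads, source_db = "refseq_org",
                            tie_rate = 0, seed = 1L) {
  stopifnot(inherits(profile, "community_profile"))
  source_db <- match_source_db(source_db)
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 1L)
    abort_samsa("n_reads must be >= 1", "samsa_validation_error")
  rec <- with_seed_opt(seed, {
    reads <- sim_reads(profile, n_reads)
    reads_to_records(profile, reads, source_db, tie_rate)
  })
  attr(rec, "truth") <- list(profile = profile, n_reads = n_reads,
                             tie_rate = tie_rate)
  rec
}

#' Simulate an organism abundance table directly
#'
#' Multinomial counts over the community's taxa, bypassing record-level
#' simulation; convenient for deep parents in subsampling studies where
#' only the count vector matters.
#'
#' @param profile a [sim_community()] profile.
#' @param n_reads total reads.
#' @param sample_id,source_db table metadata.
#' @param seed RNG seed.
#' @return An [abundance_table()] with attribute `"truth"` holding the
#'   generating proportions.
#' @export
sim_abundance_table <- function(profile, n_reads, sample_id = "sim",
                                source_db = "refseq_org", seed = 1L) {
  stopifnot(inherits(profile, "community_profile"))
  counts <- with_seed_opt(seed,
    as.numeric(rmultinom(1L, n_reads, profile$taxa$proportion)))
  keep <- counts > 0
  tab <- abundance_table(setNames(counts[keep],
                                  profile$taxa$organism[keep]),
                         sample_id, source_db)
  attr(tab, "truth") <- setNames(profile$taxa$proportion,
                                 profile$taxa$organism)
  tab
}

#' Simulate a control / ribodepleted library pair
#'
#' The control library is an ordinary annotation simulation.  For the
#' depleted library, each ribosomal read of phylum p survives with the
#' profile's retention probability for p (mRNA reads always survive);
#' survivors are then resampled with replacement back to `n_reads`,
#' mimicking fixed sequencing throughput -- which realistically inflates
#' the non-depleted fraction.  The truth element reports the per-phylum
#' depletion percentages expected from [depletion_percent()] applied to
#' the rRNA fractions of the pair:
#' 100 * (1 - retention(p) / R), R = sum over phyla of
#' control-rRNA-share(p) * retention(p).
#'
#' @param profile a [sim_community()] profile with retention factors set.
#' @param n_reads reads per library.
#' @param source_db mRNA source database.
#' @param seed RNG seed.
#' @return List with `control` and `depleted` record data frames and
#'   `truth` (retention factors, expected per-phylum depletion, the
#'   profile).
#' @export
sim_depleted_pair <- function(profile, n_reads, source_db = "refseq_org",
                              seed = 1L) {
  stopifnot(inherits(profile, "community_profile"))
  source_db <- match_source_db(source_db)
  with_seed_opt(seed, {
    ctl_reads <- sim_reads(profile, n_reads)
    phylum <- profile$taxa$phylum[ctl_reads$taxon]
    keep_p <- ifelse(ctl_reads$is_rrna,
                     profile$retention[phylum], 1)
    survivors <- ctl_reads[runif(n_reads) < keep_p, , drop = FALSE]
    dep_reads <- survivors[sample.int(nrow(survivors), n_reads,
                                      replace = TRUE), , drop = FALSE]
    dep_reads$read <- seq_len(n_reads)

    control <- reads_to_records(profile, ctl_reads, source_db, 0)
    depleted <- reads_to_records(profile, dep_reads, source_db, 0)

    # expected depletion of each phylum's share of the surviving rRNA pool
    share <- tapply(profile$taxa$proportion, profile$taxa$phylum, sum)
    share <- share / sum(share)
    ret <- profile$retention[names(share)]
    R <- sum(share * ret)
    expected <- 100 * (1 - ret / R)
    list(control = control, depleted = depleted,
         truth = list(retention = profile$retention,
                      expected_depletion = setNames(as.numeric(expected),
                                                    names(share)),
                      profile = profile))
  })
}

#' Simulate a two-group count matrix with planted effects
#'
#' Negative-binomial counts (Poisson when `dispersion = 0`) with
#' lognormal baseline means, lognormal sample depth factors, and planted
#' log2 fold changes applied to the second group.
#'
#' @param n_features features.
#' @param n_per_group samples per group (>= 2).
#' @param planted_log2fc named numeric vector feature -> log2 fold change
#'   (features named `"feat_00001"`...); unnamed features are null.
#'   `NULL` for a global null.
#' @param dispersion NB dispersion alpha (Var = mu + alpha mu^2).
#' @param base_meanlog,base_sdlog lognormal law of baseline means.
#' @param depth_sdlog lognormal spread of true per-sample depth factors.
#' @param group_labels two condition labels (second carries the effects).
#' @param seed RNG seed.
#' @return List with `matrix` (a [count_matrix()]) and `truth` (data
#'   frame `feature`, `log2fc`, plus true depth factors as attribute).
#' @export
sim_count_matrix <- function(n_features = 2000L, n_per_group = 8L,
                             planted_log2fc = NULL, dispersion = 0.05,
                             base_meanlog = log(100), base_sdlog = 1,
                             depth_sdlog = 0.15,
                             group_labels = c("control", "case"),
                             seed = 1L) {
  n_features <- as.integer(n_features)
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 2L)
    abort_samsa("n_per_group must be >= 2", "samsa_validation_error")
  if (dispersion < 0)
    abort_samsa("dispersion must be >= 0", "samsa_validation_error")
  feats <- sprintf("feat_%05d", seq_len(n_features))
  lfc <- setNames(numeric(n_features), feats)
  if (!is.null(planted_log2fc)) {
    unknown <- setdiff(names(planted_log2fc), feats)
    if (length(unknown))
      abort_samsa("planted_log2fc names features outside the matrix",
                  "samsa_validation_error")
    lfc[names(planted_log2fc)] <- planted_log2fc
  }
  n <- 2L * n_per_group
  samples <- sprintf("s%02d", seq_len(n))
  groups <- setNames(rep(group_labels, each = n_per_group), samples)

  with_seed_opt(seed, {
    mu0 <- rlnorm(n_features, base_meanlog, base_sdlog)
    depth <- rlnorm(n, 0, depth_sdlog)
    mu <- outer(mu0, depth)                   # features x samples
    mu[, groups == group_labels[2]] <-
      mu[, groups == group_labels[2]] * 2^lfc
    counts <- if (dispersion == 0) {
      matrix(rpois(length(mu), mu), nrow = n_features)
    } else {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             nrow = n_features)
    }
    dimnames(counts) <- list(feats, samples)
    truth <- data.frame(feature = feats, log2fc = unname(lfc),
                        base_mean = mu0, stringsAsFactors = FALSE)
    attr(truth, "depth") <- setNames(depth, samples)
    list(matrix = count_matrix(counts, groups), truth = truth)
  })
}

#' Simulate a paired-end FASTQ library
#'
#' Random-base paired reads of exact length with constant quality; no
#' sequence-level realism (no error model, no GC bias) -- sufficient for
#' exercising FASTQ plumbing and digital truncation.
#'
#' @param n_reads read pairs.
#' @param read_length bases per read.
#' @param seed RNG seed.
#' @return List with `r1` and `r2` `QualityScaledDNAStringSet`s.
#' @export
sim_fastq <- function(n_reads = 100L, read_length = 150L, seed = 1L) {
  n_reads <- as.integer(n_reads)
  read_length <- as.integer(read_length)
  if (is.na(read_length) || read_length < 1L)
    abort_samsa("read_length must be >= 1", "samsa_validation_error")
  with_seed_opt(seed, {
    mk <- function(mate) {
      seqs <- vapply(seq_len(n_reads), function(i)
        paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
              collapse = ""), character(1))
      s <- Biostrings::DNAStringSet(seqs)
      names(s) <- sprintf("read_%06d/%d", seq_len(n_reads), mate)
      q <- Biostrings::PhredQuality(
        Biostrings::BStringSet(rep(strrep("I", read_length), n_reads)))
      Biostrings::QualityScaledDNAStringSet(s, q)
    }
    list(r1 = mk(1L), r2 = mk(2L))
  })
}
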