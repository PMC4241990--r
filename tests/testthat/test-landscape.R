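# Integration-landscape statistics.

test_that("genome occupancy counts union basepairs above the length rule", {
  expect_identical(genome_occupancy(empty_hits(), 10000)$fraction, 0)
  h <- data.frame(host_seq = "c", start = c(0L, 200L),
                  end = c(300L, 500L))
  occ <- genome_occupancy(h, 10000)
  expect_identical(occ$bp, 500L)
  expect_identical(occ$fraction, 0.05)
  # invariant to hit order, idempotent under duplication
  occ2 <- genome_occupancy(h[2:1, ], 10000)
  expect_identical(occ2$bp, 500L)
  occ3 <- genome_occupancy(rbind(h, h), 10000)
  expect_identical(occ3$bp, 500L)
  # strictly-greater length rule
  h200 <- data.frame(host_seq = "c", start = 0L, end = 200L)
  expect_identical(genome_occupancy(h200, 10000, min_hit_len = 200)$bp, 0L)
  expect_error(genome_occupancy(h, 0), "positive")
})

test_that("TA detector handles elementary cases and matches its oracle", {
  r <- find_ta_repeats(strrep("TA", 10), min_units = 10)
  expect_identical(nrow(r), 1L)
  expect_identical(r$start, 0L)
  expect_identical(r$end, 20L)
  expect_identical(r$n_units, 10L)
  expect_identical(r$purity, 1)
  expect_identical(nrow(find_ta_repeats("ACGTACGT", min_units = 2)), 0L)
  expect_error(find_ta_repeats("TATA", min_units = 1), "min_units")

  set.seed(33)
  g <- random_dna(30000)
  for (i in 1:12) {  # plant interrupted runs
    p <- 1 + floor(runif(1) * 29900)
    run <- paste0(strrep("TA", 8), sample(c("", "G", "CC"), 1),
                  strrep("AT", 7))
    substr(g, p, p + nchar(run) - 1) <- run
  }
  got <- find_ta_repeats(g, min_units = 5, max_interruption = 3)
  want <- oracle_ta(g, min_units = 5, max_interruption = 3)
  expect_equal(got[, c("start", "end", "n_units")],
               want[, c("start", "end", "n_units")], ignore_attr = TRUE)
})

test_that("feature distances honor merging and half-open adjacency", {
  eve <- data.frame(host_seq = "c", start = 100L, end = 200L)
  te <- data.frame(host_seq = "c", start = 200L, end = 300L)
  fd <- feature_distances(eve, list(TE = te), cluster_join = 0)
  expect_identical(fd$per_locus$dist_TE, 0)  # adjacent => distance 0
  gene <- data.frame(host_seq = "c", start = 0L, end = 1000L)
  fd2 <- feature_distances(eve, list(gene = gene))
  expect_identical(fd2$per_locus$dist_gene, 0)  # contained => 0
  # planted offsets: mean distance equals the offset
  off <- 750L
  eves <- data.frame(host_seq = "c",
                     start = c(10000L, 20000L, 30000L))
  eves$end <- eves$start + 500L
  tes <- data.frame(host_seq = "c", start = eves$end + off)
  tes$end <- tes$start + 400L
  fd3 <- feature_distances(eves, list(TE = tes), cluster_join = 200)
  expect_equal(fd3$summary$mean, off)
  expect_equal(fd3$summary$median, off)
  expect_error(feature_distances(eves, list()), "empty")
})

test_that("intron overlap accounting is exact for crafted gene models", {
  gm <- data.frame(gene_id = "g1", host_seq = "c",
                   start = c(1000L, 2000L, 3000L),
                   end = c(1500L, 2500L, 3600L), exon = 1:3)
  # locus wholly inside the first intron
  in_intron <- data.frame(host_seq = "c", start = 1600L, end = 1900L)
  ov <- intron_overlap(in_intron, gm)
  expect_identical(ov$fraction_loci_in_genes, 1)
  expect_identical(ov$fraction_genic_bp_in_introns, 1)
  expect_identical(ov$genic_bp, 300L)
  # wholly intergenic locus contributes to neither
  out <- intron_overlap(data.frame(host_seq = "c", start = 5000L,
                                   end = 5400L), gm)
  expect_identical(out$fraction_loci_in_genes, 0)
  expect_identical(out$genic_bp, 0L)
  # mixed: half in exon, half in intron
  mix <- data.frame(host_seq = "c", start = 1400L, end = 1600L)
  ovm <- intron_overlap(mix, gm)
  expect_identical(ovm$genic_bp, 200L)
  expect_identical(ovm$intronic_bp, 100L)
  expect_identical(ovm$fraction_genic_bp_in_introns, 0.5)
})

test_that("simulator intron placement drives the genic fraction", {
  v <- fixture_virus()
  tr <- simulate_endogenization(v, n_host_seqs = 2, host_size = 150000,
                                n_insertions = 40,
                                fragment_len_range = c(300, 600),
                                full_length_prob = 0, ta_bias = 0,
                                intron_bias = 0.3,
                                gene_density = 1 / 8000,
                                te_density = 0, seed = 91)
  loci <- tr$insertions[, c("host_seq", "start", "end")]
  ov <- intron_overlap(loci, tr$gene_models)
  # expected genic fraction: the biased share plus chance intron hits
  # among the unbiased share (placement avoids exons)
  gm <- tr$gene_models
  intron_bp <- sum(vapply(split(gm, gm$gene_id), function(ex) {
    ex <- ex[order(ex$start), ]
    sum(ex$start[-1] - ex$end[-nrow(ex)])
  }, numeric(1)))
  exon_bp <- sum(gm$end - gm$start)
  placeable <- sum(nchar(tr$host_sequences)) - exon_bp
  p_expect <- 0.3 + 0.7 * intron_bp / placeable
  sd3 <- 3 * sqrt(p_expect * (1 - p_expect) / 40)
  expect_lt(abs(ov$fraction_loci_in_genes - p_expect), sd3 + 0.05)
  # what lands in genes lands (almost) entirely in introns
  expect_gte(ov$fraction_genic_bp_in_introns, 0.95)
})

test_that("ta_enrichment yields the forced-extreme p and is reproducible", {
  set.seed(44)
  g <- random_dna(120000)
  starts <- seq(5000, 115000, by = 10000)
  for (p in starts) substr(g, p + 1, p + 30) <- strrep("TA", 15)
  genome <- c(chr = g)
  tas <- find_ta_repeats(genome)
  expect_identical(nrow(tas), length(starts))
  # every locus adjacent to a TA run; TA covers < 1% of the genome
  loci <- data.frame(host_seq = "chr", start = starts + 30L)
  loci$end <- loci$start + 600L
  e <- ta_enrichment(loci, tas, genome, R = 99, seed = 9)
  expect_identical(e$observed_proximal_fraction, 1)
  expect_identical(e$empirical_p, 1 / 100)
  expect_identical(length(e$replicate_fractions), 99L)
  expect_lt(e$rank_test_p, 0.01)
  e2 <- ta_enrichment(loci, tas, genome, R = 99, seed = 9)
  expect_identical(e$replicate_fractions, e2$replicate_fractions)
  expect_identical(e$empirical_p, e2$empirical_p)
  # add-one rule keeps p positive even when observed is minimal
  far <- data.frame(host_seq = "chr", start = 500L, end = 1200L)
  efar <- ta_enrichment(far, tas, genome, R = 99, seed = 10)
  expect_gt(efar$empirical_p, 0)
  # zero qualifying loci is signaled
  tiny <- data.frame(host_seq = "chr", start = 0L, end = 100L)
  expect_error(ta_enrichment(tiny, tas, genome, R = 99, seed = 1),
               "qualifying")
  expect_error(ta_enrichment(loci, tas, genome, R = 10), "19")
})

test_that("flank clustering finds duplicated integration sites", {
  set.seed(55)
  site <- random_dna(3000)   # duplicated segmental context
  eve1 <- random_dna(1500)
  eve2 <- random_dna(1500)
  g <- paste0(random_dna(4000),
              substr(site, 1, 1500), eve1, substr(site, 1501, 3000),
              random_dna(4000),
              substr(site, 1, 1500), eve2, substr(site, 1501, 3000),
              random_dna(4000))
  genome <- c(chr = g)
  loci <- data.frame(host_seq = "chr",
                     start = c(4000L + 1500L,
                               4000L + 3000L + 1500L + 4000L + 1500L))
  loci$end <- loci$start + 1500L
  cf <- cluster_flanks(loci, genome, min_locus = 1000, flank = 500,
                       identity_threshold = 0.80)
  expect_identical(nrow(cf$flanks), 4L)
  sizes <- table(cf$flanks$cluster)
  expect_identical(sort(as.integer(sizes)), c(2L, 2L))
  expect_identical(cf$singleton_fraction, 0)
  # independent random sites: all-singleton flank complement
  set.seed(56)
  g2 <- random_dna(60000)
  starts <- seq(5000, 50000, by = 5000)
  loci2 <- data.frame(host_seq = "chr", start = starts,
                      end = starts + 1200L)
  cf2 <- cluster_flanks(loci2, c(chr = g2), identity_threshold = 0.80)
  expect_gte(cf2$singleton_fraction, 0.95)
  # a stricter threshold never yields fewer clusters
  cf3 <- cluster_flanks(loci, genome, identity_threshold = 0.90)
  expect_gte(length(unique(cf3$flanks$cluster)),
             length(unique(cf$flanks$cluster)))
})

test_that("join_nested connects collinear parts across young insertions", {
  ann <- data.frame(
    host_seq = "c",
    start = c(1000L, 2000L, 2500L, 6000L, 9000L),
    end = c(2000L, 2500L, 3500L, 7000L, 10000L),
    strand = c("+", "+", "+", "+", "+"),
    probe_id = c("vA", "vB", "vA", "vA", "vC"),
    probe_start = c(0L, 0L, 1000L, 3000L, 0L),
    probe_end = c(1000L, 500L, 2000L, 4000L, 1000L),
    annot_id = c("old1", "young", "old2", "farA", "other"),
    stringsAsFactors = FALSE)
  j <- join_nested(ann, ann, tolerance = 100)
  joined <- j[grepl("old1", j$members), ]
  expect_identical(joined$members, "old1,old2")
  expect_identical(joined$start, 1000L)
  expect_identical(joined$end, 3500L)
  expect_identical(joined$interrupted_by, "young")
  # separated by plain host sequence: not joined
  expect_false(any(grepl("farA", joined$members)))
  # collinearity violated: element coordinates far apart
  ann2 <- ann
  ann2$probe_start[3] <- 2500L
  j2 <- join_nested(ann2, ann2, tolerance = 100)
  expect_false(any(grepl("old1,old2", j2$members)))
})

test_that("join_nested repairs simulator-nested insertions", {
  v <- fixture_virus()
  tr <- simulate_endogenization(v, n_host_seqs = 1, host_size = 80000,
                                n_insertions = 12,
                                fragment_len_range = c(1000, 2500),
                                full_length_prob = 0,
                                substitution_rate = 0, indel_rate = 0,
                                nested_prob = 0.5, ta_bias = 0,
                                gene_density = 0, te_density = 0,
                                seed = 21)
  ins <- tr$insertions
  ann <- data.frame(host_seq = ins$host_seq, start = ins$start,
                    end = ins$end, strand = ins$strand,
                    probe_id = "virus", probe_start = ins$v_start,
                    probe_end = ins$v_start + ins$v_len,
                    annot_id = paste(ins$locus_id, ins$part, sep = "."),
                    stringsAsFactors = FALSE)
  j <- join_nested(ann, ann, tolerance = 50)
  split_loci <- names(which(table(ins$locus_id) == 2))
  expect_gt(length(split_loci), 0)
  for (l in split_loci) {
    row <- j[grepl(paste0(l, ".1"), j$members, fixed = TRUE), ]
    expect_identical(row$members, paste0(l, ".1,", l, ".2"))
  }
})

test_that("exact-match small-RNA mapping conserves coverage", {
  set.seed(66)
  cons <- random_dna(2000)
  r1 <- substr(cons, 101, 121)              # 21 nt plus strand
  r2 <- revcomp(substr(cons, 201, 224))     # 24 nt minus strand
  r3 <- substr(cons, 301, 322)
  substr(r3, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                              substr(r3, 5, 5))[1]  # one mismatch
  r4 <- substr(cons, 401, 430)              # 30 nt: outside size class
  r5 <- chartr("T", "U", substr(cons, 501, 522))  # RNA alphabet
  m <- map_srnas(c(r1, r2, r3, r4, r5), cons)
  expect_identical(m$n_reads_used, 4L)   # r4 excluded
  expect_identical(m$n_mapped, 3L)       # r3 unmapped (mismatch)
  expect_identical(sum(m$plus), 21 + 22)
  expect_identical(sum(m$minus), 24)
  expect_equal(sum(m$plus) + sum(m$minus), as.numeric(m$mapped_bases))
  expect_true(all(m$plus[101:121] == 1))
  expect_true(all(m$minus[201:224] == 1))
  expect_true(all(m$plus[301:322] == 0))
})

test_that("sRNA coverage exports as a wiggle-style TSV", {
  set.seed(67)
  cons <- random_dna(500)
  m <- map_srnas(substr(cons, 51, 72), cons)
  f <- tempfile(fileext = ".tsv")
  write_srna_coverage(m, f)
  df <- read.table(f, header = TRUE, sep = "\t")
  expect_identical(nrow(df), 500L)
  expect_identical(sum(df$plus), 22L)
  expect_identical(df$pos[1], 0L)
})
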