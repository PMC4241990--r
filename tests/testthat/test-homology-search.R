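# Translated and nucleotide homology search, and hit chaining.

back_translate <- function(aa) {
  # one codon per residue, deterministic choice
  code <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(aa, "")[[1]], function(r)
    names(code)[code == r][1], character(1)), collapse = "")
}

test_that("an exact back-translated probe is found with identity 1", {
  set.seed(101)
  probe <- paste(sample(setdiff(rownames(naive_blosum()),
                                c("B", "J", "Z", "X", "*")),
                        60, replace = TRUE), collapse = "")
  insert <- back_translate(probe)
  for (strand in c("+", "-")) {
    g <- random_dna(3000)
    at <- 1001L  # 0-based insertion offset, frame (1001 %% 3) = 2
    planted <- if (strand == "+") insert else revcomp(insert)
    genome <- c(chr = paste0(substr(g, 1, at),
                             planted,
                             substr(g, at + 1, nchar(g))))
    hits <- translated_search(genome, probe, min_score = 150)
    hit <- hits[hits$identity == 1, ]
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$strand, strand)
    expect_equal(hit$start, at)
    expect_equal(hit$end, at + nchar(insert))
    expect_identical(hit$probe_start, 0L)
    expect_identical(hit$probe_end, 60L)
    # frame is codon-exact on the hit's own strand
    L <- nchar(genome)
    expected_frame <- if (strand == "+") at %% 3 else (L - hit$end) %% 3
    expect_identical(hit$frame, as.integer(expected_frame))
  }
})

test_that("a random genome yields no hits at the probe self-score", {
  set.seed(7)
  probe <- paste(sample(setdiff(rownames(naive_blosum()),
                                c("B", "J", "Z", "X", "*")),
                        60, replace = TRUE), collapse = "")
  genome <- c(chr = random_dna(100000))
  hits <- translated_search(genome, probe,
                            min_score = probe_self_score(probe))
  expect_identical(nrow(hits), 0L)
  expect_error(translated_search(genome, "MK", k = 4), "shorter")
  expect_error(translated_search(genome, "MKO1"), "amino-acid")
})

test_that("exhaustive search matches the naive Smith-Waterman oracle", {
  bl <- naive_blosum()
  set.seed(202)
  for (case in 1:4) {
    probe <- paste(sample(setdiff(rownames(bl), c("B", "J", "Z", "X", "*")),
                          40, replace = TRUE), collapse = "")
    ins <- back_translate(probe)
    ch <- strsplit(ins, "")[[1]]  # decay the planted copy a little
    idx <- sample(length(ch), round(0.1 * length(ch)))
    for (i in idx) ch[i] <- sample(c("A", "C", "G", "T"), 1)
    ins <- paste(ch, collapse = "")
    g <- random_dna(2000)
    at <- 500 + case  # varies the frame across cases
    genome <- paste0(substr(g, 1, at), ins, substr(g, at + 1, nchar(g)))
    hits <- translated_search(c(chr = genome), probe, min_score = 60)
    # oracle: best local score over all six conceptual translations
    rc <- revcomp(genome)
    best <- 0
    for (s in c(genome, rc)) for (f in 0:2) {
      prot <- translate_frame(s, f)
      if (nchar(prot) < 1) next
      best <- max(best, naive_local(probe, prot, bl)$score)
    }
    expect_gt(nrow(hits), 0)
    expect_identical(max(hits$score), best)
  }
})

test_that("seeded search equals exhaustive search on larger genomes", {
  v <- fixture_virus()
  tr <- simulate_endogenization(v, n_host_seqs = 1, host_size = 30000,
                                n_insertions = 5,
                                fragment_len_range = c(900, 2500),
                                substitution_rate = 0.08,
                                gene_density = 0, te_density = 0,
                                seed = 31)
  probe <- fixture_probes()[["RT"]]
  ex <- translated_search(tr$host_sequences, probe, min_score = 100,
                          exhaustive_below = 1e9)
  se <- translated_search(tr$host_sequences, probe, min_score = 100,
                          exhaustive_below = 0)
  rownames(ex) <- rownames(se) <- NULL
  expect_identical(se, ex)
})

test_that("lowering min_score never removes a translated hit", {
  v <- fixture_virus()
  tr <- simulate_endogenization(v, n_host_seqs = 1, host_size = 20000,
                                n_insertions = 4,
                                substitution_rate = 0.1,
                                gene_density = 0, te_density = 0,
                                seed = 17)
  probe <- fixture_probes()[["RT"]]
  hi <- translated_search(tr$host_sequences, probe, min_score = 400)
  lo <- translated_search(tr$host_sequences, probe, min_score = 150)
  key <- function(h) paste(h$host_seq, h$start, h$end, h$strand)
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("nucleotide mask recovers planted insertions and applies filters", {
  v <- fixture_virus()
  lib <- c(virus = v$sequence)
  # 10% substitutions: recovered over >= 90% of the true span
  tr <- simulate_endogenization(v, n_host_seqs = 1, host_size = 40000,
                                n_insertions = 1,
                                fragment_len_range = c(3000, 3000),
                                full_length_prob = 0,
                                substitution_rate = 0.10, indel_rate = 0,
                                gene_density = 0, te_density = 0,
                                seed = 41)
  ins <- tr$insertions
  hits <- nucleotide_mask(tr$host_sequences, lib, max_divergence = 20)
  cov <- sum(pmin(hits$end, ins$end) - pmax(hits$start, ins$start))
  expect_gte(cov, 0.9 * (ins$end - ins$start))
  # 30% substitutions: filtered out by the divergence cutoff
  tr2 <- simulate_endogenization(v, n_host_seqs = 1, host_size = 40000,
                                 n_insertions = 1,
                                 fragment_len_range = c(3000, 3000),
                                 full_length_prob = 0,
                                 substitution_rate = 0.30, indel_rate = 0,
                                 gene_density = 0, te_density = 0,
                                 seed = 42)
  expect_identical(nrow(nucleotide_mask(tr2$host_sequences, lib,
                                        max_divergence = 20)), 0L)
  # 150 bp fragment: below the counting rule
  tr3 <- simulate_endogenization(v, n_host_seqs = 1, host_size = 20000,
                                 n_insertions = 1,
                                 fragment_len_range = c(150, 150),
                                 full_length_prob = 0,
                                 substitution_rate = 0, indel_rate = 0,
                                 gene_density = 0, te_density = 0,
                                 seed = 43)
  expect_identical(nrow(nucleotide_mask(tr3$host_sequences, lib,
                                        cutoff = 100,
                                        min_hit_len = 200)), 0L)
  expect_identical(nrow(nucleotide_mask(character(0), lib)), 0L)
  expect_error(nucleotide_mask(tr3$host_sequences, character(0)),
               "empty")
})

test_that("searching the reverse complement mirrors hit coordinates", {
  v <- fixture_virus()
  tr <- simulate_endogenization(v, n_host_seqs = 1, host_size = 30000,
                                n_insertions = 3,
                                fragment_len_range = c(800, 2000),
                                substitution_rate = 0.05,
                                gene_density = 0, te_density = 0,
                                seed = 51)
  lib <- c(virus = v$sequence)
  fwd <- nucleotide_mask(tr$host_sequences, lib)
  L <- nchar(tr$host_sequences[[1]])
  rev_genome <- setNames(revcomp(tr$host_sequences), names(tr$host_sequences))
  rev <- nucleotide_mask(rev_genome, lib)
  key <- function(h, flip = FALSE) {
    s <- if (flip) L - h$end else h$start
    e <- if (flip) L - h$start else h$end
    st <- if (flip) ifelse(h$strand == "+", "-", "+") else h$strand
    sort(paste(s, e, st))
  }
  expect_identical(key(rev, flip = TRUE), key(fwd))
})

test_that("merge_hits chains by gap and matches the linkage oracle", {
  h2 <- data.frame(host_seq = "c", start = c(0L, 150L),
                   end = c(100L, 250L), strand = "+", frame = NA,
                   probe_id = "p", probe_start = 0L, probe_end = 10L,
                   score = 50, identity = 1)
  one <- merge_hits(h2, 200)
  expect_identical(nrow(one$loci), 1L)
  expect_identical(one$loci$start, 0L)
  expect_identical(one$loci$end, 250L)
  two <- merge_hits(h2, 20)
  expect_identical(nrow(two$loci), 2L)
  expect_error(merge_hits(h2, -1))

  # random hits vs brute-force single-linkage over the gap graph
  set.seed(77)
  n <- 300L
  rh <- data.frame(host_seq = sample(c("c1", "c2"), n, TRUE),
                   start = sample.int(50000, n), strand = "+",
                   frame = NA, probe_id = "p", probe_start = 0L,
                   probe_end = 10L, score = 10, identity = 1)
  rh$end <- rh$start + sample.int(400, n)
  for (d in c(0L, 50L, 500L)) {
    res <- merge_hits(rh, d)
    expect_identical(nrow(res$hits), n)  # member count conserved
    comp <- oracle_merge_partition(res$hits, d)
    # identical partitions
    expect_identical(
      unname(split(seq_len(n), res$hits$locus_id)[
        unique(res$hits$locus_id)]),
      unname(split(seq_len(n), comp)[as.character(unique(comp))]))
    # loci are disjoint per host sequence
    for (sq in unique(res$loci$host_seq)) {
      l <- res$loci[res$loci$host_seq == sq, ]
      l <- l[order(l$start), ]
      if (nrow(l) > 1) expect_true(all(l$start[-1] >= l$end[-nrow(l)]))
    }
  }
  # increasing join distance never increases the locus count
  counts <- vapply(c(0L, 20L, 100L, 1000L, 5000L),
                   function(d) nrow(merge_hits(rh, d)$loci), integer(1))
  expect_true(all(diff(counts) <= 0))
})
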