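# ORF finding, domain annotation, distances, species demarcation,
# component classification/pairing, replication-competency scanning.

test_that("find_orfs handles the elementary cases", {
  o <- find_orfs("ATGAAATAA", min_len_aa = 1)
  expect_identical(nrow(o), 1L)
  expect_identical(o$start, 0L)
  expect_identical(o$end, 9L)        # three codons including the stop
  expect_identical(o$frame, 0L)
  expect_identical(o$strand, "+")
  expect_identical(o$length_aa, 2L)  # residues excluding the stop
  # no ATG at all (on either strand): CAT on the reverse is a start
  expect_identical(nrow(find_orfs("CCCCCCCCCCCC", min_len_aa = 1)), 0L)
})

test_that("circular ORF enumeration equals the exhaustive oracle", {
  set.seed(19)
  for (rep in 1:3) {
    s <- random_dna(1500)
    for (circ in c(FALSE, TRUE)) {
      got <- find_orfs(s, min_len_aa = 20, circular = circ)
      want <- oracle_orfs(s, min_len_aa = 20, circular = circ)
      expect_equal(got[, c("start", "end", "strand", "length_aa")],
                   want[, c("start", "end", "strand", "length_aa")],
                   ignore_attr = TRUE)
    }
  }
  # an ORF spanning the origin is only found in circular mode
  s2 <- paste0("GAAATAACCC", random_dna(50), "TTTATGAAA")
  # ORF wraps: ATGAAA | GAAATAA at the origin
  got <- find_orfs(s2, min_len_aa = 3, circular = TRUE)
  wrap <- got[got$end > nchar(s2), ]
  expect_gte(nrow(wrap), 1)
  lin <- find_orfs(s2, min_len_aa = 3, circular = FALSE)
  expect_true(all(lin$end <= nchar(s2)))
})

test_that("pdistance implements pairwise deletion", {
  expect_identical(pdistance("ACGT", "ACGT"), 0)
  expect_identical(pdistance("ACGT", "ACGA"), 0.25)
  expect_identical(pdistance("AC-T", "ACGT", aligned = TRUE), 0)
  expect_identical(pdistance("AC-T", "ACGA", aligned = TRUE), 1 / 3)
  expect_error(pdistance("AC-T", "ACGTT", aligned = TRUE), "equal")
  expect_warning(d <- pdistance("----", "AAAA", aligned = TRUE),
                 "no comparable")
  expect_true(is.na(d))
  # symmetry, bounds, unaligned route
  set.seed(5)
  for (i in 1:5) {
    a <- random_dna(300)
    b <- paste(sample(strsplit(a, "")[[1]]), collapse = "")
    d1 <- pdistance(a, b)
    d2 <- pdistance(b, a)
    expect_equal(d1, d2, tolerance = 1e-12)
    expect_true(d1 >= 0 && d1 <= 1)
  }
})

test_that("species demarcation is single-linkage at 80% identity", {
  # crafted identities: A-B 0.85, B-C 0.85, A-C 0.70 -> one chained
  # cluster under single linkage, two under complete linkage
  set.seed(23)
  base <- random_dna(200)
  alter <- function(s, at) {
    ch <- strsplit(s, "")[[1]]
    for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                          ch[p]), 1)
    paste(ch, collapse = "")
  }
  # isolated scattered mismatches survive global alignment unchanged
  B <- base
  A <- alter(base, seq(3, 177, by = 6))    # 30 sites
  C <- alter(base, seq(6, 180, by = 6))    # 30 disjoint sites
  genomes <- c(A = A, B = B, C = C)
  regions <- list(A = c(0, 200), B = c(0, 200), C = c(0, 200))
  cl <- demarcate_species(genomes, regions, threshold = 0.80)
  expect_identical(length(unique(cl$membership$cluster)), 1L)
  expect_equal(cl$identity["A", "B"], 0.85)
  expect_equal(cl$identity["A", "C"], 0.70)
  cl2 <- demarcate_species(genomes, regions, threshold = 0.80,
                           linkage = "complete")
  expect_gt(length(unique(cl2$membership$cluster)), 1L)
  # identical genomes cluster together; missing regions are set aside
  expect_warning(
    cl3 <- demarcate_species(c(genomes, D = base),
                             regions, threshold = 0.80),
    "set aside")
  expect_identical(cl3$set_aside, "D")
  # raising the threshold never merges clusters
  for (th in c(0.85, 0.95)) {
    clh <- demarcate_species(genomes, regions, threshold = th)
    expect_gte(length(unique(clh$membership$cluster)),
               length(unique(cl$membership$cluster)))
  }
})

test_that("component classification follows the domain inventory", {
  expect_identical(
    classify_component(c("MP", "CP", "AP", "RT", "RH1"))$value,
    "complete")
  expect_identical(classify_component(c("AP", "RT", "RH1", "ORF2"))$value,
                   "A")
  expect_identical(classify_component(c("MP", "CP", "AP", "ORF2"))$value,
                   "B")
  expect_identical(classify_component(c("MP", "RT"))$value,
                   "unclassifiable")
  ev <- classify_component(c("RT", "RH1"))
  expect_identical(ev$evidence$absent, c("MP", "CP", "AP"))
})

test_that("simulated bipartite components are annotated and classified", {
  v <- fixture_virus()
  probes <- fixture_probes()
  doms <- annotate_domains(v$sequence, probes)
  core <- doms[doms$domain != "ORF2", ]
  expect_identical(attr(doms, "domain_order")[
    attr(doms, "domain_order") != "ORF2"],
    c("MP", "CP", "AP", "RT", "RH1"))
  # placements within +-30 bp of the simulated layout
  for (d in core$domain) {
    tru <- v$domain_layout[v$domain_layout$domain == d, ]
    got <- core[core$domain == d, ]
    expect_lte(abs(got$start - tru$start), 30)
    expect_lte(abs(got$end - tru$end), 30)
  }
  expect_identical(classify_component(doms)$value, "complete")

  ab <- derive_bipartite_components(v)
  dom_a <- annotate_domains(ab$A$sequence, probes)
  dom_b <- annotate_domains(ab$B$sequence, probes)
  expect_identical(classify_component(dom_a)$value, "A")
  expect_identical(classify_component(dom_b)$value, "B")
  # absent probes stay absent
  expect_false("CP" %in% dom_a$domain)
  expect_false("RT" %in% dom_b$domain)
})

test_that("conspecific components pair by IG and MP identity", {
  v <- fixture_virus()
  v2 <- simulate_ancestral_virus(seed = 99)   # unrelated virus
  ab <- derive_bipartite_components(v)
  ab2 <- derive_bipartite_components(v2)
  ig <- function(s) {
    iv <- ig_region(s)
    substr(s, iv[1] + 1, iv[2])
  }
  mp <- function(s, virus) {
    d <- annotate_domains(s, fixture_probes()["MP"])
    if (nrow(d) == 0) return(NULL)
    substr(s, d$start + 1, d$end)
  }
  gA <- list(id = "A1", component = "A", ig_seq = ig(ab$A$sequence),
             mp_seq = NULL)
  gB <- list(id = "B1", component = "B", ig_seq = ig(ab$B$sequence),
             mp_seq = mp(ab$B$sequence, v))
  gA2 <- list(id = "A2", component = "A", ig_seq = ig(ab2$A$sequence),
              mp_seq = NULL)
  pairs <- pair_components(list(gA, gB, gA2))
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$A_id, "A1")
  expect_identical(pairs$B_id, "B1")
  expect_gt(pairs$ig_identity, 0.99)
  # unrelated virus alone: no pairing
  expect_identical(nrow(pair_components(list(gA2, gB))), 0L)
  # best-match rule: a slightly decayed A loses to the exact A
  iga <- ig(ab$A$sequence)
  ch <- strsplit(iga, "")[[1]]
  at <- seq(5, length(ch), by = 20)
  for (p in at) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  gA3 <- list(id = "A3", component = "A",
              ig_seq = paste(ch, collapse = ""), mp_seq = NULL)
  pairs2 <- pair_components(list(gA3, gA, gB))
  expect_identical(pairs2$A_id, "A1")
  # A lacking an IG region is excluded with a warning
  gAbad <- list(id = "A4", component = "A", ig_seq = "", mp_seq = NULL)
  expect_warning(pair_components(list(gAbad, gB)), "lacking")
})

test_that("replication-competency scan measures copy multiplicity", {
  v <- fixture_virus()
  L <- v$length
  one <- c(full = v$sequence)
  # 1.2-mer: starts at ORF2, runs through the origin, then a full copy
  orf2 <- v$orf_layout$start[2]
  tandem <- c(mer12 = paste0(substr(v$sequence, orf2 + 1, L), v$sequence))
  decayed <- c(dec = mutate_seq(v$sequence, 0.1)$seq)
  rep <- scan_replication_competency(c(one, tandem, decayed), v$sequence)
  expect_equal(rep$copy_multiplicity[rep$locus_id == "full"], 1,
               tolerance = 0.01)
  m12 <- rep[rep$locus_id == "mer12", ]
  expect_equal(m12$copy_multiplicity, 1 + (L - orf2) / L,
               tolerance = 0.02)
  expect_true(m12$tandem_structure)
  expect_true(rep$has_uninterrupted_orfs[rep$locus_id == "full"])
  expect_false(rep$has_uninterrupted_orfs[rep$locus_id == "dec"])
  expect_false(rep$tandem_structure[rep$locus_id == "full"])
})

test_that("strain-level clusters refine species clusters", {
  set.seed(29)
  base <- random_dna(600)
  mk <- function(s, rate) mutate_seq(s, rate)$seq
  spA <- mk(base, 0.25)
  genomes <- c(a1 = spA, a2 = mk(spA, 0.02),     # one strain cluster
               a3 = mk(spA, 0.15),               # same species, new strain
               b1 = base)                        # second species
  regions <- setNames(rep(list(c(0, 600)), 4), names(genomes))
  cl <- demarcate_species(genomes, regions, threshold = 0.80,
                          strain_threshold = 0.91)
  m <- cl$membership
  expect_identical(length(unique(m$cluster)), 2L)
  expect_identical(m$strain_cluster[m$id == "a1"],
                   m$strain_cluster[m$id == "a2"])
  expect_false(m$strain_cluster[m$id == "a1"] ==
                 m$strain_cluster[m$id == "a3"])
})

test_that("consensus annotations export as parseable GFF3", {
  v <- fixture_virus()
  orfs <- find_orfs(v$sequence, min_len_aa = 100, circular = TRUE)
  doms <- annotate_domains(v$sequence, fixture_probes())
  f <- tempfile(fileext = ".gff3")
  write_annotations_gff3(orfs, doms, f, seqname = "cons",
                         seqlen = v$length)
  gff <- rtracklayer::import(f)
  expect_identical(length(gff), nrow(orfs) + nrow(doms))
  dom_gff <- gff[gff$type == "polypeptide_domain"]
  expect_setequal(dom_gff$ID, doms$domain)
  expect_identical(sort(GenomicRanges::start(dom_gff)),
                   sort(doms$start + 1L))
})
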