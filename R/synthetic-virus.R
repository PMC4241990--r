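# Simulation of an ancestral circular pararetrovirus genome with the
# canonical florendovirus-like layout: a tRNA-Met primer-binding-site
# motif at position 0, a short leader, ORF1 encoding the
# MP-CP-AP-RT-RH1 polyprotein, ORF2 in a different translational
# frame, and a non-coding intergenic region closing the circle.

.default_domain_fracs <- c(MP = 0.22, CP = 0.18, AP = 0.08,
                           RT = 0.26, RH1 = 0.12)

#' Simulate an ancestral circular virus genome
#'
#' Generates a random genome satisfying the canonical layout
#' invariants: the origin motif at position 0, ORF1 with the five
#' polyprotein domains in order MP, CP, AP, RT, RH1 (stop-free by
#' construction), ORF2 in a different frame, and an intergenic region
#' running from the ORF2 stop back to the origin.  The origin motif is
#' guaranteed unique in the genome up to `motif_protect` mismatches so
#' rotation recovery is well defined.
#'
#' @param length_range genome length range in bp (within 3-20 kb).
#' @param domain_fracs named fractions of the ORF1 protein allotted to
#'   MP, CP, AP, RT, RH1 (must sum to < 0.9; the rest is linker).
#' @param origin_motif tRNA-Met primer-binding-site consensus (ACGT).
#' @param orf1_frac,orf2_frac fractions of the genome occupied by the
#'   two ORFs.
#' @param motif_protect the motif is unique up to this many mismatches.
#' @param seed RNG seed.
#' @return object of class `ancestral_virus`: list with `sequence`,
#'   `length`, `orf_layout` (data.frame `orf_id`, `start`, `end`,
#'   `frame`), `domain_layout` (data.frame `domain`, `start`, `end`),
#'   `origin_motif`, `origin_offset` (always 0).
#' @export
simulate_ancestral_virus <- function(length_range = c(7200L, 8500L),
                                     domain_fracs = .default_domain_fracs,
                                     origin_motif = "TGGTATCAGAGC",
                                     orf1_frac = 0.70, orf2_frac = 0.17,
                                     motif_protect = 2L, seed = NULL) {
  if (length_range[1] < 3000 || length_range[2] > 20000 ||
      length_range[1] > length_range[2])
    stop("length_range must lie within [3000, 20000]", call. = FALSE)
  stopifnot_scalar_string(origin_motif, "origin_motif")
  origin_motif <- toupper(origin_motif)
  if (nchar(origin_motif) == 0 || grepl("[^ACGT]", origin_motif))
    stop("origin_motif must be non-empty and ACGT-only", call. = FALSE)
  need <- c("MP", "CP", "AP", "RT", "RH1")
  if (!all(need %in% names(domain_fracs)))
    stop("domain_fracs must name MP, CP, AP, RT, RH1", call. = FALSE)
  if (sum(domain_fracs[need]) >= 0.9)
    stop("domain fractions sum exceeds ORF1 coding capacity",
         call. = FALSE)
  if (orf1_frac + orf2_frac >= 0.95)
    stop("ORF fractions exceed genome capacity", call. = FALSE)

  with_seed(seed, {
    codons <- sense_codons()
    for (attempt in 1:25) {
      L <- rint(length_range[1], length_range[2])
      ml <- nchar(origin_motif)
      leader <- sample(40:80, 1L)
      orf1_nt <- 3L * ((round(orf1_frac * L)) %/% 3L)
      orf2_nt <- 3L * ((round(orf2_frac * L)) %/% 3L)
      s1 <- ml + leader
      gap <- sample(4:30, 1L)
      s2 <- s1 + orf1_nt + gap
      while ((s2 %% 3L) == (s1 %% 3L)) s2 <- s2 + 1L
      ig_len <- L - (s2 + orf2_nt)
      if (ig_len < 100L) next

      orf_seq <- function(nt) {
        ncod <- nt %/% 3L
        paste0("ATG",
               paste(sample(codons, ncod - 2L, replace = TRUE),
                     collapse = ""),
               sample(.stop_codons, 1L))
      }
      seq <- paste0(origin_motif, random_dna(leader), orf_seq(orf1_nt),
                    random_dna(s2 - (s1 + orf1_nt)), orf_seq(orf2_nt),
                    random_dna(ig_len))
      stopifnot(nchar(seq) == L)
      # origin motif must be unique up to motif_protect mismatches
      mm <- Biostrings::neditStartingAt(
        Biostrings::DNAString(origin_motif),
        Biostrings::DNAString(paste0(seq, substr(seq, 1L, ml - 1L))),
        starting.at = 2:L, with.indels = FALSE)
      if (min(mm) <= motif_protect) next

      orf1_aa <- orf1_nt %/% 3L - 1L  # residues excluding stop
      fr <- domain_fracs[need]
      linker <- (1 - sum(fr)) / (length(need) + 1L)
      aa_cursor <- linker * orf1_aa
      dom <- list()
      for (d in need) {
        a0 <- round(aa_cursor)
        a1 <- round(aa_cursor + fr[[d]] * orf1_aa)
        dom[[d]] <- c(s1 + 3L * a0, s1 + 3L * a1)
        aa_cursor <- aa_cursor + (fr[[d]] + linker) * orf1_aa
      }
      domain_layout <- data.frame(
        domain = c(need, "ORF2"),
        start = c(vapply(dom, `[`, numeric(1), 1), s2),
        end = c(vapply(dom, `[`, numeric(1), 2), s2 + orf2_nt),
        stringsAsFactors = FALSE)
      orf_layout <- data.frame(
        orf_id = c("ORF1", "ORF2"),
        start = c(s1, s2), end = c(s1 + orf1_nt, s2 + orf2_nt),
        frame = c(s1 %% 3L, s2 %% 3L), stringsAsFactors = FALSE)
      return(structure(list(sequence = seq, length = L,
                            orf_layout = orf_layout,
                            domain_layout = domain_layout,
                            origin_motif = origin_motif,
                            origin_offset = 0L),
                       class = "ancestral_virus"))
    }
    stop("could not generate a genome with a unique origin motif",
         call. = FALSE)
  })
}

#' @export
print.ancestral_virus <- function(x, ...) {
  cat("Ancestral virus genome:", x$length, "bp, origin motif",
      x$origin_motif, "\n")
  print(x$orf_layout)
  invisible(x)
}

#' Extract the amino-acid probe for a domain of a simulated virus
#'
#' Translates the ORF1 (or ORF2) region recorded in the domain layout,
#' giving the probes used by [annotate_domains()] and
#' [translated_search()] in simulation studies.
#'
#' @param virus an `ancestral_virus`.
#' @param domains domain names (default: all in the layout).
#' @return named character vector of amino-acid sequences.
#' @export
domain_probes <- function(virus, domains = virus$domain_layout$domain) {
  out <- vapply(domains, function(d) {
    iv <- virus$domain_layout[virus$domain_layout$domain == d, ]
    if (nrow(iv) == 0) stop("unknown domain: ", d, call. = FALSE)
    orf <- if (d == "ORF2") virus$orf_layout[2, ] else virus$orf_layout[1, ]
    # snap to the ORF's codon grid
    a0 <- orf$start + 3L * ((iv$start - orf$start) %/% 3L)
    a1 <- orf$start + 3L * ((iv$end - orf$start) %/% 3L)
    translate_frame(substr(virus$sequence, a0 + 1L, a1), 0L)
  }, character(1))
  gsub("\\*", "", out)
}

#' Derive bipartite A and B component genomes from a complete virus
#'
#' Component A deletes the CP domain (truncating the ORF1 amino
#' terminus); component B deletes the RT domain and the amino-terminal
#' portion of RH1.  Both retain the complete intergenic region and the
#' origin motif, mirroring the complementary domain inventories of a
#' bipartite pararetrovirus genome.
#'
#' @param virus an `ancestral_virus`.
#' @param rh1_cut fraction of RH1 removed (from its start) in B.
#' @return list with elements `A` and `B`, each a list with `sequence`
#'   and `deleted` (the removed interval, 0-based half-open).
#' @export
derive_bipartite_components <- function(virus, rh1_cut = 0.4) {
  dl <- virus$domain_layout
  iv <- function(d) unlist(dl[dl$domain == d, c("start", "end")])
  cut_out <- function(s, from, to)
    paste0(substr(s, 1L, from), substr(s, to + 1L, nchar(s)))
  cp <- iv("CP")
  a_seq <- cut_out(virus$sequence, cp[1], cp[2])
  rt <- iv("RT"); rh1 <- iv("RH1")
  b_to <- round(rh1[1] + rh1_cut * (rh1[2] - rh1[1]))
  b_seq <- cut_out(virus$sequence, rt[1], b_to)
  list(A = list(sequence = a_seq, deleted = c(cp[1], cp[2])),
       B = list(sequence = b_seq, deleted = c(rt[1], b_to)))
}
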