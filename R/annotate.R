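# Annotation and classification of reconstructed virus genomes:
# ORF finding (circular-aware), polyprotein domain placement by probe
# alignment, pairwise uncorrected distances, species demarcation in the
# RT-RH1 region, bipartite A/B component classification and pairing,
# and replication-competency scanning of genomic loci.

.stop_codons <- c("TAA", "TAG", "TGA")

#' Find open reading frames
#'
#' Reports all maximal start(ATG)-to-stop ORFs of at least `min_len_aa`
#' residues on both strands.  In circular mode the scan runs over the
#' doubled sequence so ORFs may span the origin; such ORFs have
#' `end > nchar(sequence)` (coordinates stay 0-based half-open on the
#' forward strand, with `start` normalized into `[0, L)`).
#'
#' @param sequence nucleotide string (ACGTN).
#' @param min_len_aa minimum ORF length in residues (excluding the stop
#'   codon).
#' @param circular allow ORFs spanning the origin.
#' @return data.frame with `orf_id`, `start`, `end` (end exclusive,
#'   includes the stop codon), `strand`, `frame` (on the ORF's own
#'   strand), `length_aa`, `uninterrupted`.
#' @export
find_orfs <- function(sequence, min_len_aa = 100L, circular = FALSE) {
  s <- toupper(sequence)
  L <- nchar(s)
  rows <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else revcomp(s)
    scan <- if (circular) paste0(ss, ss) else ss
    for (f in 0:2) {
      cps <- seq.int(f + 1L, nchar(scan) - 2L, by = 3L)
      if (length(cps) == 0) next
      cod <- substring(scan, cps, cps + 2L)
      is_stop <- cod %in% .stop_codons
      is_atg <- cod == "ATG"
      prev_stop <- 0L
      for (kk in which(is_stop)) {
        cand <- which(is_atg[(prev_stop + 1L):(kk - 1L)])
        if (kk - 1L >= prev_stop + 1L && length(cand) > 0) {
          a <- prev_stop + cand[1]
          s0 <- cps[a] - 1L          # 0-based on scanned strand
          e0 <- cps[kk] + 2L
          ok <- if (circular) (s0 < L && (e0 - s0) <= L) else TRUE
          if (ok && (kk - a) >= min_len_aa) {
            if (strand == "+") { fs <- s0; fe <- e0 }
            else {
              fs <- L - e0
              fe <- L - s0
              if (fs < 0) { fs <- fs + L; fe <- fe + L }
            }
            rows[[length(rows) + 1L]] <- data.frame(
              start = fs, end = fe, strand = strand, frame = f,
              length_aa = (kk - a), uninterrupted = TRUE,
              stringsAsFactors = FALSE)
          }
        }
        prev_stop <- kk
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), strand = character(),
               frame = integer(), length_aa = integer(),
               uninterrupted = logical(), stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("start", "end", "strand")]), ,
             drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  if (nrow(out))
    out <- cbind(orf_id = sprintf("orf_%02d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
  else out <- cbind(orf_id = character(), out)
  rownames(out) <- NULL
  out
}

#' Annotate polyprotein domains on a consensus genome by probe alignment
#'
#' Places each supplied amino-acid domain probe by exhaustive six-frame
#' local alignment and keeps the best placement per domain above the
#' score threshold.  Overlapping best placements of two domains are
#' both kept and flagged.
#'
#' @param consensus a `virus_consensus` or nucleotide string.
#' @param domain_probes named character vector of amino-acid probes;
#'   names from the controlled vocabulary (MP, CP, AP, RT, RH1, ORF2).
#' @param min_score_frac score threshold as a fraction of each probe's
#'   self-score.
#' @return data.frame with `domain`, `start`, `end` (nt, 0-based
#'   half-open), `strand`, `frame`, `score`, `identity`,
#'   `source_probe`, `overlaps_other`; the domain order along the
#'   genome is available as `attr(, "domain_order")`.
#' @export
annotate_domains <- function(consensus, domain_probes,
                             min_score_frac = 0.25) {
  seq <- if (inherits(consensus, "virus_consensus")) consensus$sequence
         else consensus
  if (is.null(names(domain_probes)))
    stop("domain_probes must be named by domain", call. = FALSE)
  rows <- list()
  for (dom in names(domain_probes)) {
    hits <- translated_search(setNames(seq, "consensus"),
                              domain_probes[[dom]], probe_id = dom,
                              min_score = min_score_frac *
                                probe_self_score(domain_probes[[dom]]))
    if (nrow(hits) == 0) next
    best <- hits[order(-hits$score, hits$start), ][1, ]
    rows[[length(rows) + 1L]] <- data.frame(
      domain = dom, start = best$start, end = best$end,
      strand = best$strand, frame = best$frame, score = best$score,
      identity = best$identity, source_probe = dom,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(domain = character(), start = integer(), end = integer(),
               strand = character(), frame = integer(), score = numeric(),
               identity = numeric(), source_probe = character(),
               stringsAsFactors = FALSE)
  out$overlaps_other <- FALSE
  if (nrow(out) > 1) {
    for (i in seq_len(nrow(out))) {
      for (j in seq_len(nrow(out))[-i]) {
        if (min(out$end[i], out$end[j]) >
            max(out$start[i], out$start[j]))
          out$overlaps_other[i] <- TRUE
      }
    }
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "domain_order") <- out$domain
  out
}

#' Uncorrected pairwise distance with pairwise deletion of gaps
#'
#' Proportion of mismatched sites among aligned columns where neither
#' sequence has a gap (or N).  Unaligned inputs are globally aligned
#' first.
#'
#' @param seq_a,seq_b nucleotide strings; if `aligned`, equal-length
#'   rows of an alignment using `-` for gaps.
#' @param aligned are the inputs already aligned?
#' @return the p-distance, or `NA` (with a warning) when no comparable
#'   sites exist.
#' @export
pdistance <- function(seq_a, seq_b, aligned = FALSE) {
  a <- toupper(seq_a); b <- toupper(seq_b)
  if (aligned) {
    if (nchar(a) != nchar(b))
      stop("aligned sequences must have equal length", call. = FALSE)
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
  } else {
    r <- align_pair(a, b, "global")
    ca <- cb <- character(length(r$a_cols))
    aa <- strsplit(a, "")[[1]]
    bb <- strsplit(b, "")[[1]]
    ca <- ifelse(r$a_cols > 0, aa[pmax(r$a_cols, 1)], "-")
    cb <- ifelse(r$b_cols > 0, bb[pmax(r$b_cols, 1)], "-")
  }
  use <- ca != "-" & cb != "-" & ca != "N" & cb != "N"
  n <- sum(use)
  if (n == 0) {
    warning("no comparable sites; p-distance undefined")
    return(NA_real_)
  }
  sum(ca[use] != cb[use]) / n
}

#' Demarcate virus species by RT-RH1 identity clustering
#'
#' Clusters consensus genomes by nucleotide identity
#' (`1 - pdistance`) over their RT-RH1 region, single-linkage at the
#' family species-demarcation threshold (80% identity by default).
#'
#' @param consensus_set named character vector of genome sequences.
#' @param regions named list (or data.frame with `id`, `start`, `end`)
#'   giving each genome's RT-RH1 interval, 0-based half-open.  Members
#'   without a region are set aside and reported.
#' @param threshold identity threshold in `[0, 1]`.
#' @param strain_threshold identity threshold for within-species
#'   strain-level sequence clusters.
#' @param linkage `"single"` (default) or `"complete"`.
#' @return an object of class `species_clusters`: list with
#'   `membership` (data.frame `id`, `cluster`, `strain_cluster`,
#'   `representative`), `identity` (matrix), `threshold`,
#'   `set_aside` (ids lacking a region).
#' @export
demarcate_species <- function(consensus_set, regions, threshold = 0.80,
                              strain_threshold = 0.91,
                              linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  ids <- names(consensus_set)
  if (is.data.frame(regions)) {
    rg <- setNames(lapply(seq_len(nrow(regions)), function(i)
      c(regions$start[i], regions$end[i])), regions$id)
  } else rg <- regions
  has <- ids %in% names(rg)
  set_aside <- ids[!has]
  if (length(set_aside))
    warning("members without an RT-RH1 region set aside: ",
            paste(set_aside, collapse = ", "))
  ids <- ids[has]
  n <- length(ids)
  if (n == 0) stop("no members with an RT-RH1 region", call. = FALSE)
  seqs <- vapply(ids, function(id) {
    iv <- rg[[id]]
    substr(consensus_set[[id]], iv[1] + 1L, iv[2])
  }, character(1))
  idm <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- pdistance(seqs[i], seqs[j])
      idm[i, j] <- idm[j, i] <- 1 - d
    }
  }
  if (n == 1) {
    cl <- setNames(1L, ids)
  } else {
    hc <- hclust(as.dist(1 - idm), method = linkage)
    cl <- cutree(hc, h = 1 - threshold)
  }
  membership <- data.frame(id = ids, cluster = as.integer(cl),
                           stringsAsFactors = FALSE)
  # strain-level sequence clusters within each species
  membership$strain_cluster <- NA_character_
  for (sp in unique(membership$cluster)) {
    idx <- which(membership$cluster == sp)
    scl <- if (length(idx) == 1) 1L else {
      hc2 <- hclust(as.dist(1 - idm[idx, idx, drop = FALSE]),
                    method = linkage)
      as.integer(cutree(hc2, h = 1 - strain_threshold))
    }
    membership$strain_cluster[idx] <- sprintf("%d-sc%d", sp, scl)
  }
  rep_of <- vapply(split(membership$id, membership$cluster),
                   function(m) m[which.max(nchar(consensus_set[m]))],
                   character(1))
  membership$representative <- rep_of[as.character(membership$cluster)]
  structure(list(membership = membership, identity = idm,
                 threshold = threshold, set_aside = set_aside),
            class = "species_clusters")
}

#' @export
print.species_clusters <- function(x, ...) {
  cat("Species clusters:", length(unique(x$membership$cluster)),
      "clusters over", nrow(x$membership), "genomes at identity >=",
      x$threshold, "\n")
  invisible(x)
}

#' Classify a genome as complete or bipartite component A/B
#'
#' Deterministic mapping from the domain inventory: `complete` needs
#' all of MP, CP, AP, RT, RH1; component A needs RT and RH1 with CP
#' absent; component B needs MP, CP and AP with RT absent; anything
#' else is `unclassifiable`.
#'
#' @param domains an [annotate_domains()] result, or a character vector
#'   of present domain names.
#' @return list with `value` (one of `complete`, `A`, `B`,
#'   `unclassifiable`) and `evidence` (present/absent inventory).
#' @export
classify_component <- function(domains) {
  present <- if (is.data.frame(domains)) unique(domains$domain)
             else unique(as.character(domains))
  core <- c("MP", "CP", "AP", "RT", "RH1")
  has <- core %in% present
  names(has) <- core
  value <- if (all(has)) "complete"
  else if (has["RT"] && has["RH1"] && !has["CP"]) "A"
  else if (has["MP"] && has["CP"] && has["AP"] && !has["RT"]) "B"
  else "unclassifiable"
  list(value = value,
       evidence = list(present = core[has], absent = core[!has]))
}

#' Intergenic region of an origin-rotated circular genome
#'
#' The IG runs from the stop of the last forward-strand ORF to the
#' origin (position 0, the tRNA-Met motif), i.e. `[last_orf_end, L)`.
#'
#' @param sequence origin-rotated genome string.
#' @param min_len_aa ORF size floor used to locate the last ORF.
#' @return `c(start, end)`, 0-based half-open.
#' @export
ig_region <- function(sequence, min_len_aa = 100L) {
  seq <- if (inherits(sequence, "virus_consensus")) sequence$sequence
         else sequence
  orfs <- find_orfs(seq, min_len_aa = min_len_aa, circular = FALSE)
  orfs <- orfs[orfs$strand == "+", , drop = FALSE]
  L <- nchar(seq)
  if (nrow(orfs) == 0) return(c(0L, L))
  c(min(max(orfs$end), L), L)
}

#' Pair bipartite A and B components by shared intergenic region
#'
#' An (A, B) pair is emitted iff the intergenic-region identity exceeds
#' `ig_threshold` and, when both carry an MP domain, the MP identity
#' exceeds `mp_threshold`; each B pairs with its best A by IG identity.
#'
#' @param genomes a list; each element a list with `id`, `component`
#'   (from [classify_component()]), `ig_seq`, and optionally `mp_seq`.
#' @param ig_threshold,mp_threshold identity thresholds in `[0, 1]`.
#' @return data.frame `A_id`, `B_id`, `ig_identity`, `mp_identity`
#'   (NA when either member lacks MP).
#' @export
pair_components <- function(genomes, ig_threshold = 0.90,
                            mp_threshold = 0.87) {
  comp <- vapply(genomes, function(g) g$component, character(1))
  ids <- vapply(genomes, function(g) g$id, character(1))
  As <- which(comp == "A")
  Bs <- which(comp == "B")
  ok_ig <- vapply(genomes, function(g)
    !is.null(g$ig_seq) && nchar(g$ig_seq) > 0, logical(1))
  if (any(!ok_ig[As])) {
    warning("component A genome(s) lacking an IG region excluded: ",
            paste(ids[As[!ok_ig[As]]], collapse = ", "))
    As <- As[ok_ig[As]]
  }
  Bs <- Bs[ok_ig[Bs]]
  rows <- list()
  for (b in Bs) {
    best <- NULL
    for (a in As) {
      ig_id <- 1 - pdistance(genomes[[a]]$ig_seq, genomes[[b]]$ig_seq)
      if (is.na(ig_id) || ig_id <= ig_threshold) next
      mp_id <- NA_real_
      if (!is.null(genomes[[a]]$mp_seq) && !is.null(genomes[[b]]$mp_seq)) {
        mp_id <- 1 - pdistance(genomes[[a]]$mp_seq, genomes[[b]]$mp_seq)
        if (mp_id <= mp_threshold) next
      }
      if (is.null(best) || ig_id > best$ig_identity)
        best <- data.frame(A_id = ids[a], B_id = ids[b],
                           ig_identity = ig_id, mp_identity = mp_id,
                           stringsAsFactors = FALSE)
    }
    if (!is.null(best)) rows[[length(rows) + 1L]] <- best
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(A_id = character(), B_id = character(),
               ig_identity = numeric(), mp_identity = numeric(),
               stringsAsFactors = FALSE)
}

#' Scan loci for replication-competency signals
#'
#' Aligns the consensus repeatedly against each locus sequence to
#' measure copy multiplicity (aligned consensus-equivalents), detects
#' greater-than-unit-length tandem structure (coverage wrapping past
#' the origin between adjacent copies), and checks whether the locus
#' retains uninterrupted ORFs matching the consensus ORF complement.
#'
#' @param locus_seqs named character vector of locus sequences.
#' @param consensus a `virus_consensus` or string.
#' @param min_score minimum per-copy alignment score.
#' @param orf_frac a locus ORF must reach this fraction of the
#'   corresponding consensus ORF length to count as intact.
#' @param wrap_tol coordinate tolerance (bp) for wrap detection.
#' @return data.frame `locus_id`, `copy_multiplicity`,
#'   `has_uninterrupted_orfs`, `tandem_structure`.
#' @export
scan_replication_competency <- function(locus_seqs, consensus,
                                        min_score = 200,
                                        orf_frac = 0.9,
                                        wrap_tol = 100L) {
  cseq <- if (inherits(consensus, "virus_consensus")) consensus$sequence
          else consensus
  Lc <- nchar(cseq)
  corfs <- find_orfs(cseq, min_len_aa = 100L, circular = FALSE)
  corfs <- corfs[corfs$length_aa >= 100, , drop = FALSE]
  alpha <- .nt_alphabet
  smat <- nt_score_matrix()
  if (is.null(names(locus_seqs)))
    names(locus_seqs) <- paste0("locus", seq_along(locus_seqs))
  rows <- lapply(names(locus_seqs), function(id) {
    lseq <- toupper(locus_seqs[[id]])
    hits <- list()
    for (orient in c("+", "-")) {
      q <- if (orient == "+") cseq else revcomp(cseq)
      h <- iterated_local(q, lseq, alpha, smat, -5, -2, min_score)
      if (nrow(h)) {
        if (orient == "-") {
          tmp <- Lc - h$q_end + 1L
          h$q_end <- Lc - h$q_start + 1L
          h$q_start <- tmp
        }
        h$orient <- orient
        hits[[length(hits) + 1L]] <- h
      }
    }
    hits <- if (length(hits)) do.call(rbind, hits) else NULL
    mult <- if (is.null(hits)) 0 else
      sum(hits$q_end - hits$q_start + 1L) / Lc
    tandem <- FALSE
    if (!is.null(hits) && nrow(hits) >= 2) {
      hits <- hits[order(hits$s_start), ]
      for (i in 1:(nrow(hits) - 1)) {
        a <- hits[i, ]; b <- hits[i + 1, ]
        if (a$orient != b$orient) next
        gap <- b$s_start - a$s_end
        if (gap > 2L * wrap_tol) next
        wraps <- if (a$orient == "+")
          a$q_end >= Lc - wrap_tol && b$q_start <= wrap_tol
        else
          a$q_start <= wrap_tol && b$q_end >= Lc - wrap_tol
        if (wraps) tandem <- TRUE
      }
    }
    intact <- if (nrow(corfs) == 0) NA else {
      lorfs <- find_orfs(lseq, min_len_aa = 50L, circular = FALSE)
      all(vapply(corfs$length_aa, function(need) {
        any(lorfs$length_aa >= orf_frac * need)
      }, logical(1)))
    }
    data.frame(locus_id = id, copy_multiplicity = mult,
               has_uninterrupted_orfs = intact,
               tandem_structure = tandem, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export ORF and domain annotations as GFF3 on consensus coordinates
#'
#' @param orfs a [find_orfs()] result (may be NULL).
#' @param domains an [annotate_domains()] result (may be NULL).
#' @param path output GFF3 file.
#' @param seqname consensus sequence name used in column 1.
#' @param seqlen consensus length (clips origin-wrapping ORF ends).
#' @return `path`, invisibly.
#' @export
write_annotations_gff3 <- function(orfs, domains, path,
                                   seqname = "consensus",
                                   seqlen = NULL) {
  grs <- list()
  if (!is.null(orfs) && nrow(orfs)) {
    e <- orfs$end
    if (!is.null(seqlen)) e <- pmin(e, seqlen)
    gr <- GenomicRanges::GRanges(seqname,
                                 IRanges::IRanges(orfs$start + 1L, e),
                                 strand = orfs$strand)
    S4Vectors::mcols(gr)$type <- "ORF"
    S4Vectors::mcols(gr)$ID <- orfs$orf_id
    grs[[length(grs) + 1L]] <- gr
  }
  if (!is.null(domains) && nrow(domains)) {
    gr <- GenomicRanges::GRanges(seqname,
                                 IRanges::IRanges(domains$start + 1L,
                                                  domains$end),
                                 strand = domains$strand)
    S4Vectors::mcols(gr)$type <- "polypeptide_domain"
    S4Vectors::mcols(gr)$ID <- domains$domain
    grs[[length(grs) + 1L]] <- gr
  }
  if (length(grs) == 0) stop("nothing to export", call. = FALSE)
  rtracklayer::export(suppressWarnings(do.call(c, grs)), path,
                      format = "gff3")
  invisible(path)
}
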