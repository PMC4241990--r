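# Homology search: translated (protein probe vs six conceptual
# translations) and nucleotide (consensus library vs genome) discovery
# of virus-derived intervals, and chaining of hits into loci.
#
# Hits are data.frames with columns
#   host_seq, start, end   (0-based half-open, forward strand),
#   strand ("+"/"-"), frame (0:2 for translated hits, NA otherwise),
#   probe_id, probe_start, probe_end (0-based half-open, in probe
#   units: amino acids for translated hits, nt for nucleotide hits),
#   score, identity.

empty_hits <- function() {
  data.frame(host_seq = character(), start = integer(), end = integer(),
             strand = character(), frame = integer(),
             probe_id = character(), probe_start = integer(),
             probe_end = integer(), score = numeric(),
             identity = numeric(), stringsAsFactors = FALSE)
}

sort_hits <- function(hits) {
  hits[order(hits$host_seq, hits$start, hits$end), , drop = FALSE]
}

#' Translated homology search of a protein probe against a genome
#'
#' Finds local alignments of an amino-acid probe against all six
#' conceptual translations of the genome, the seeded re-implementation
#' of a tBLASTN-style discovery search.  For subjects up to
#' `exhaustive_below` nt the search is exhaustive (full Smith-Waterman
#' in every frame); above that, exact `k`-mer amino-acid seeds gated by
#' ungapped x-drop extension restrict the dynamic programming to
#' candidate windows, with identical results whenever a seed exists
#' within a reportable alignment.
#'
#' @param genome named character vector of host sequences (or a single
#'   unnamed string).
#' @param probe amino-acid probe (single string).
#' @param probe_id label recorded in hits.
#' @param k amino-acid seed word size.
#' @param min_score minimum reported alignment score (BLOSUM62 units);
#'   default 25% of the probe self-score.
#' @param xdrop x-drop used during ungapped seed extension.
#' @param gap_open,gap_ext affine gap penalties (amino-acid level).
#' @param exhaustive_below subjects at most this many nt are searched
#'   exhaustively in every frame.
#' @param overlap_frac HSPs from this probe overlapping an
#'   already-accepted, higher-scoring HSP by more than this fraction of
#'   the shorter hit are dropped (greedy resolution, ties to the
#'   leftmost start).
#' @return hit data.frame (see file header), sorted by
#'   (host_seq, start).  Translated hits carry a frame; coordinates map
#'   codon-exactly to the genome strand/frame.
#' @export
translated_search <- function(genome, probe, probe_id = "probe",
                              k = 4L, min_score = NULL, xdrop = 20,
                              gap_open = -11, gap_ext = -1,
                              exhaustive_below = 20000L,
                              overlap_frac = 0.5) {
  if (is.null(names(genome)) && length(genome) == 1L)
    names(genome) <- "seq1"
  stopifnot_scalar_string(probe, "probe")
  probe <- toupper(probe)
  if (nchar(probe) < k)
    stop("probe is shorter than the seed word size k", call. = FALSE)
  if (grepl(sprintf("[^%s]", gsub("([*])", "\\\\\\1", aa_alphabet())),
            probe))
    stop("probe must be amino-acid alphabet", call. = FALSE)
  if (is.null(min_score)) min_score <- 0.25 * probe_self_score(probe)
  alpha <- aa_alphabet()
  smat <- aa_score_matrix()
  gate <- min(min_score, max(30, 2 * k))

  rows <- list()
  for (sq in names(genome)) {
    gseq <- toupper(genome[[sq]])
    L <- nchar(gseq)
    if (L < 3L) next
    exhaustive <- L <= exhaustive_below
    tr <- six_frame_translate(gseq)
    for (strand in c("+", "-")) {
      frames <- if (strand == "+") tr$fwd else tr$rev
      for (f in 0:2) {
        prot <- frames[[f + 1L]]
        if (nchar(prot) < 1L) next
        if (exhaustive) {
          win <- data.frame(start = 1L, end = nchar(prot),
                            q_start = 1L, q_end = nchar(probe))
        } else {
          win <- seed_windows(probe, prot, k, alpha, smat, xdrop,
                              gate, pad = 150L)
        }
        for (w in seq_len(nrow(win))) {
          wseq <- substr(prot, win$start[w], win$end[w])
          qsub <- substr(probe, win$q_start[w], win$q_end[w])
          h <- iterated_local(qsub, wseq, alpha, smat,
                              gap_open, gap_ext, min_score)
          if (nrow(h) == 0) next
          h$q_start <- h$q_start + win$q_start[w] - 1L
          h$q_end <- h$q_end + win$q_start[w] - 1L
          # protein coords (1-based) within full-frame translation
          p1 <- h$s_start + win$start[w] - 1L
          p2 <- h$s_end + win$start[w] - 1L
          # map to forward-strand genome nt, 0-based half-open
          nt1 <- f + 3L * (p1 - 1L)
          nt2 <- f + 3L * p2
          if (strand == "-") {
            tmp <- L - nt2
            nt2 <- L - nt1
            nt1 <- tmp
          }
          rows[[length(rows) + 1L]] <- data.frame(
            host_seq = sq, start = nt1, end = nt2, strand = strand,
            frame = f, probe_id = probe_id,
            probe_start = h$q_start - 1L, probe_end = h$q_end,
            score = h$score, identity = h$identity,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits()
  hits <- resolve_overlaps(hits, overlap_frac)
  rownames(hits) <- NULL
  sort_hits(hits)
}

# greedy resolution of overlapping HSPs from the same probe:
# keep by decreasing score (ties: leftmost start), drop hits whose
# genome overlap with a kept hit exceeds overlap_frac of the shorter
resolve_overlaps <- function(hits, overlap_frac = 0.5) {
  if (nrow(hits) <= 1L) return(hits)
  out <- logical(nrow(hits))
  for (pid in unique(hits$probe_id)) {
    idx <- which(hits$probe_id == pid)
    ord <- idx[order(-hits$score[idx], hits$start[idx])]
    kept <- integer(0)
    for (i in ord) {
      drop <- FALSE
      for (j in kept) {
        if (hits$host_seq[i] != hits$host_seq[j]) next
        ov <- min(hits$end[i], hits$end[j]) -
          max(hits$start[i], hits$start[j])
        shorter <- min(hits$end[i] - hits$start[i],
                       hits$end[j] - hits$start[j])
        if (ov > overlap_frac * shorter) { drop <- TRUE; break }
      }
      if (!drop) kept <- c(kept, i)
    }
    out[kept] <- TRUE
  }
  hits[out, , drop = FALSE]
}

#' Nucleotide masking search of a consensus library against a genome
#'
#' RepeatMasker-style recovery of virus-derived intervals: seeded local
#' alignment of each library sequence (both strands) against each host
#' sequence, filtered by score cutoff, maximum divergence and minimum
#' hit length.  Divergence is `100 * (1 - identity)` over gap-free
#' aligned columns.
#'
#' @param genome named character vector of host sequences.
#' @param consensus_library named character vector of virus consensus
#'   sequences (the masking library).
#' @param cutoff minimum alignment score.
#' @param max_divergence maximum percent divergence of reported hits.
#' @param min_hit_len hits must be strictly longer than this many bp on
#'   the genome to be reported (the coverage-counting rule).
#' @param k nucleotide seed word size.
#' @param match,mismatch,gap_open,gap_ext nucleotide scoring.
#' @param exhaustive_below subjects at most this many nt skip seeding.
#' @return hit data.frame with `frame = NA`; `probe_start`/`probe_end`
#'   are forward-strand library coordinates (0-based half-open).
#' @export
nucleotide_mask <- function(genome, consensus_library,
                            cutoff = 250, max_divergence = 20,
                            min_hit_len = 200L, k = 12L,
                            match = 2L, mismatch = -3L,
                            gap_open = -5, gap_ext = -2,
                            exhaustive_below = 5000L) {
  if (length(genome) == 0) return(empty_hits())
  if (is.null(names(genome)) && length(genome) == 1L)
    names(genome) <- "seq1"
  if (length(consensus_library) == 0)
    stop("consensus library is empty", call. = FALSE)
  if (is.null(names(consensus_library)))
    names(consensus_library) <- paste0("lib", seq_along(consensus_library))
  alpha <- .nt_alphabet
  smat <- nt_score_matrix(match, mismatch)
  gate <- min(cutoff, 60)
  rows <- list()
  for (sq in names(genome)) {
    gseq <- toupper(genome[[sq]])
    L <- nchar(gseq)
    for (lib in names(consensus_library)) {
      lseq <- toupper(consensus_library[[lib]])
      Lq <- nchar(lseq)
      for (strand in c("+", "-")) {
        qseq <- if (strand == "+") lseq else revcomp(lseq)
        if (L <= exhaustive_below) {
          win <- data.frame(start = 1L, end = L,
                            q_start = 1L, q_end = Lq)
        } else {
          win <- seed_windows(qseq, gseq, k, alpha, smat,
                              xdrop = 30, gate = gate, pad = 600L)
        }
        for (w in seq_len(nrow(win))) {
          wseq <- substr(gseq, win$start[w], win$end[w])
          qsub <- substr(qseq, win$q_start[w], win$q_end[w])
          h <- iterated_local(qsub, wseq, alpha, smat,
                              gap_open, gap_ext, cutoff)
          if (nrow(h) == 0) next
          h$q_start <- h$q_start + win$q_start[w] - 1L
          h$q_end <- h$q_end + win$q_start[w] - 1L
          g1 <- h$s_start + win$start[w] - 2L  # 0-based
          g2 <- h$s_end + win$start[w] - 1L
          q1 <- h$q_start - 1L
          q2 <- h$q_end
          if (strand == "-") {
            tmp <- Lq - q2
            q2 <- Lq - q1
            q1 <- tmp
          }
          rows[[length(rows) + 1L]] <- data.frame(
            host_seq = sq, start = g1, end = g2, strand = strand,
            frame = NA_integer_, probe_id = lib,
            probe_start = q1, probe_end = q2,
            score = h$score, identity = h$identity,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits()
  hits <- hits[(hits$end - hits$start) > min_hit_len &
                 100 * (1 - hits$identity) <= max_divergence, ,
               drop = FALSE]
  rownames(hits) <- NULL
  sort_hits(hits)
}

#' Merge homology hits into loci by gap chaining
#'
#' Two hits on the same host sequence belong to one locus iff they are
#' chained by inter-hit gaps strictly below `join_distance`
#' (single-linkage along the sequence).  Locus strand is the majority
#' strand of member hits (ties resolved to "+").
#'
#' @param hits hit data.frame.
#' @param join_distance non-negative chaining distance in bp.
#' @return an object of class `eve_loci`: a list with `loci` (data.frame
#'   `locus_id, host_seq, start, end, strand, n_hits`) and `hits` (the
#'   input hits with a `locus_id` column).
#' @export
merge_hits <- function(hits, join_distance) {
  stopifnot(join_distance >= 0)
  hits <- sort_hits(hits)
  hits$locus_id <- rep(NA_character_, nrow(hits))
  loci <- list()
  n <- 0L
  for (sq in unique(hits$host_seq)) {
    idx <- which(hits$host_seq == sq)
    cur <- integer(0)
    cur_end <- -Inf
    flush <- function(cur) {
      if (length(cur) == 0) return(invisible())
      n <<- n + 1L
      id <- sprintf("L%04d", n)
      hits$locus_id[cur] <<- id
      strands <- hits$strand[cur]
      maj <- if (sum(strands == "-") > sum(strands == "+")) "-" else "+"
      loci[[n]] <<- data.frame(
        locus_id = id, host_seq = sq,
        start = min(hits$start[cur]), end = max(hits$end[cur]),
        strand = maj, n_hits = length(cur), stringsAsFactors = FALSE)
      invisible()
    }
    for (i in idx) {
      gap <- hits$start[i] - cur_end
      if (length(cur) > 0 && gap >= join_distance) {
        flush(cur)
        cur <- integer(0)
        cur_end <- -Inf
      }
      cur <- c(cur, i)
      cur_end <- max(cur_end, hits$end[i])
    }
    flush(cur)
  }
  loci <- if (n > 0) do.call(rbind, loci) else
    data.frame(locus_id = character(), host_seq = character(),
               start = integer(), end = integer(), strand = character(),
               n_hits = integer(), stringsAsFactors = FALSE)
  structure(list(loci = loci, hits = hits), class = "eve_loci")
}

#' @export
print.eve_loci <- function(x, ...) {
  cat("EVE loci:", nrow(x$loci), "loci from", nrow(x$hits), "hits\n")
  if (nrow(x$loci)) print(utils::head(x$loci, 10))
  invisible(x)
}

#' Export loci to a BED file (0-based half-open)
#' @param loci an `eve_loci` object or a locus data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  df <- if (inherits(loci, "eve_loci")) loci$loci else loci
  bed <- data.frame(df$host_seq, df$start, df$end,
                    if ("locus_id" %in% names(df)) df$locus_id else ".",
                    0L,
                    if ("strand" %in% names(df)) df$strand else ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
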