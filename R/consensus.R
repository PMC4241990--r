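# Ancestral ("modal") virus genome reconstruction from recruited
# endogenous fragments: tolerant anchored assembly followed by
# per-column majority consensus, with rotation of the circular result
# to the tRNA-Met primer-binding-site origin.

#' Recruit and orient fragments from merged loci
#'
#' Extracts the genomic slice of every locus, reverse-complements minus
#' strand loci so that all fragments are in probe (virus) orientation,
#' and estimates an anchor offset on the virus coordinate frame from
#' the member hits' probe coordinates.
#'
#' @param loci an [merge_hits()] result (`eve_loci`).
#' @param genome named character vector of host sequences.
#' @param min_fragment_len fragments shorter than this are dropped.
#' @return an object of class `fragment_set`: a data.frame with columns
#'   `locus_id`, `sequence`, `anchor` (estimated 0-based virus
#'   coordinate of the fragment start; NA when unknown) and `length`.
#'   An empty set (no fragment survives) is a zero-row `fragment_set`,
#'   not an error.
#' @export
recruit_and_orient <- function(loci, genome, min_fragment_len = 200L) {
  stopifnot(inherits(loci, "eve_loci"))
  out <- list()
  for (i in seq_len(nrow(loci$loci))) {
    lc <- loci$loci[i, ]
    gseq <- genome[[lc$host_seq]]
    mem <- loci$hits[!is.na(loci$hits$locus_id) &
                       loci$hits$locus_id == lc$locus_id, , drop = FALSE]
    unit <- ifelse(is.na(mem$frame), 1L, 3L)  # aa probes -> nt
    per_hit <- if (nrow(mem) == 0) numeric(0) else if (lc$strand == "+") {
      unit * mem$probe_start - (mem$start - lc$start)
    } else {
      unit * mem$probe_start - (lc$end - mem$end)
    }
    consistent <- length(per_hit) > 0 && diff(range(per_hit)) <= 300 &&
      all(mem$strand == lc$strand)
    if (consistent || nrow(mem) <= 1) {
      # one contiguous copy: recruit the whole locus slice
      frag <- substr(gseq, lc$start + 1L, lc$end)
      if (nchar(frag) < min_fragment_len) next
      if (lc$strand == "-") frag <- revcomp(frag)
      anchor <- if (length(per_hit)) median(per_hit) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        locus_id = lc$locus_id, sequence = frag, anchor = anchor,
        length = nchar(frag), stringsAsFactors = FALSE)
    } else {
      # inconsistent anchors: distinct copies merged into one locus,
      # or a full-length copy wrapping the circular origin -- recruit
      # each member hit as its own fragment with its own anchor
      for (h in seq_len(nrow(mem))) {
        frag <- substr(gseq, mem$start[h] + 1L, mem$end[h])
        if (nchar(frag) < min_fragment_len) next
        if (mem$strand[h] == "-") frag <- revcomp(frag)
        out[[length(out) + 1L]] <- data.frame(
          locus_id = sprintf("%s.%d", lc$locus_id, h),
          sequence = frag, anchor = unit[h] * mem$probe_start[h],
          length = nchar(frag), stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(locus_id = character(), sequence = character(),
               anchor = numeric(), length = integer(),
               stringsAsFactors = FALSE)
  class(res) <- c("fragment_set", "data.frame")
  res
}

# vote bookkeeping: votes is a 4 x L integer matrix (A,C,G,T)
.base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)

#' Build a majority consensus from oriented fragments
#'
#' Iterative anchored extension: the longest fragment seeds the
#' scaffold; remaining fragments are placed by best local alignment
#' (accepted while the mismatch-plus-gap budget stays within
#' `error_clearance`), or, failing that, by their anchor offset when
#' the implied scaffold gap is at most `max_gap` (the gap is bridged
#' with N).  Fragments that can neither be aligned nor anchored are
#' assembled separately and reported as additional contigs, never
#' silently merged.
#'
#' Each aligned fragment base votes for its scaffold column; the final
#' base per column is the modal base when depth >= `min_depth` (ties
#' broken by `tie_rule`), the single observed base (flagged
#' low-confidence) at depth 1, and N over bridged gaps.
#'
#' @param fragments a `fragment_set` (or data.frame with `sequence`,
#'   optionally `anchor`, `locus_id`).
#' @param max_gap largest unaligned interior gap bridged with N, bp.
#' @param error_clearance maximum mismatch+gap columns tolerated in a
#'   fragment-to-scaffold alignment.
#' @param min_depth minimum depth for an unflagged consensus call.
#' @param tie_rule `"alphabetical"` (deterministic base) or `"n"`
#'   (emit N) at exactly tied columns.
#' @param min_overlap minimum aligned columns to accept a placement.
#' @param min_identity minimum alignment identity to accept a placement.
#' @return an object of class `virus_consensus`: list with `sequence`,
#'   `depth`, `agreement`, `low_conf`, `n_fragments`, `origin_rotated`,
#'   `placements` (per-fragment voted base counts) and `contigs` (list
#'   of secondary `virus_consensus` objects).
#' @export
build_consensus <- function(fragments, max_gap = 200L,
                            error_clearance = 500L, min_depth = 2L,
                            tie_rule = c("alphabetical", "n"),
                            min_overlap = 100L, min_identity = 0.55) {
  tie_rule <- match.arg(tie_rule)
  frags <- as.data.frame(fragments, stringsAsFactors = FALSE)
  if (nrow(frags) == 0) stop("no fragments to assemble", call. = FALSE)
  if (is.null(frags$anchor)) frags$anchor <- NA_real_
  if (is.null(frags$locus_id))
    frags$locus_id <- paste0("F", seq_len(nrow(frags)))
  frags <- frags[order(-nchar(frags$sequence)), , drop = FALSE]

  seed <- toupper(frags$sequence[1])
  Lsc <- nchar(seed)
  votes <- matrix(0L, 4L, Lsc)
  scaf <- strsplit(seed, "")[[1]]
  vote_bases <- function(chars, cols) {
    ok <- chars %in% names(.base_idx) & cols >= 1L & cols <= ncol(votes)
    if (any(ok)) {
      m <- cbind(.base_idx[chars[ok]], cols[ok])
      # accumulate (duplicated cells impossible: one vote per column
      # per fragment)
      votes[m] <<- votes[m] + 1L
    }
    sum(ok)
  }
  grow_left <- function(n) {
    votes <<- cbind(matrix(0L, 4L, n), votes)
    scaf <<- c(rep("N", n), scaf)
    scaffold_anchor <<- scaffold_anchor - n
  }
  grow_right <- function(n) {
    votes <<- cbind(votes, matrix(0L, 4L, n))
    scaf <<- c(scaf, rep("N", n))
  }
  scaffold_anchor <- frags$anchor[1]
  placements <- data.frame(locus_id = frags$locus_id[1],
                           n_voted = 0L, mode = "seed",
                           stringsAsFactors = FALSE)
  sv <- strsplit(seed, "")[[1]]
  placements$n_voted[1] <- vote_bases(sv, seq_len(Lsc))

  acceptable <- function(r) {
    length(r$a_cols) >= min_overlap && !is.na(r$identity) &&
      r$identity >= min_identity &&
      (r$n_mismatch + r$n_gapcols) <= error_clearance
  }
  # align a fragment to the scaffold, trying an anchor-guided slice
  # first (cheap) and falling back to the full scaffold
  place_align <- function(frag, anchor) {
    scafseq <- paste(scaf, collapse = "")
    fl <- nchar(frag)
    if (!is.na(anchor) && !is.na(scaffold_anchor)) {
      p0 <- round(anchor - scaffold_anchor) + 1L
      lo <- max(1L, p0 - 600L)
      hi <- min(length(scaf), p0 + fl + 600L)
      if (hi - lo + 1L >= min_overlap) {
        r <- align_pair(frag, substr(scafseq, lo, hi), "local")
        if (acceptable(r)) {
          r$b_start <- r$b_start + lo - 1L
          r$b_end <- r$b_end + lo - 1L
          r$b_cols <- ifelse(r$b_cols > 0, r$b_cols + lo - 1L, 0L)
          return(r)
        }
      }
    }
    r <- align_pair(frag, scafseq, "local")
    if (acceptable(r)) r else NULL
  }

  deferred <- integer(0)
  for (i in seq_len(nrow(frags))[-1]) {
    frag <- toupper(frags$sequence[i])
    fl <- nchar(frag)
    r <- place_align(frag, frags$anchor[i])
    if (!is.null(r)) {
      fchars <- strsplit(frag, "")[[1]]
      # left overhang: frag bases before a_start projected ungapped
      la <- r$a_start                      # 0-based: count of bases
      need_left <- la - r$b_start
      shift <- 0L
      if (need_left > 0) { grow_left(need_left); shift <- need_left }
      # right overhang
      ra <- fl - r$a_end
      room_right <- length(scaf) - (r$b_end + shift)
      if (ra > room_right) grow_right(ra - room_right)
      acols <- r$a_cols
      bcols <- r$b_cols
      sel <- acols > 0 & bcols > 0
      cols <- bcols[sel] + shift
      chars <- fchars[acols[sel]]
      if (la > 0) {
        cols <- c((r$b_start + shift - la + 1L):(r$b_start + shift), cols)
        chars <- c(fchars[seq_len(la)], chars)
      }
      if (ra > 0) {
        cols <- c(cols, (r$b_end + shift + 1L):(r$b_end + shift + ra))
        chars <- c(chars, fchars[(r$a_end + 1L):fl])
      }
      nv <- vote_bases(chars, cols)
      # extend scaffold characters over freshly grown regions
      grown <- cols[scaf[cols] == "N" & cols >= 1 & cols <= length(scaf)]
      scaf[grown] <- chars[match(grown, cols)]
      placements <- rbind(placements, data.frame(
        locus_id = frags$locus_id[i], n_voted = nv, mode = "aligned",
        stringsAsFactors = FALSE))
    } else if (!is.na(frags$anchor[i]) && !is.na(scaffold_anchor)) {
      p0 <- round(frags$anchor[i] - scaffold_anchor) + 1L  # scaffold col
      if (p0 > length(scaf) + max_gap + 1L ||
          p0 + fl - 1L < -max_gap) {
        deferred <- c(deferred, i)
        next
      }
      if (p0 + fl - 1L > length(scaf))
        grow_right(p0 + fl - 1L - length(scaf))
      if (p0 < 1L) { grow_left(1L - p0); p0 <- 1L }
      cols <- p0:(p0 + fl - 1L)
      chars <- strsplit(frag, "")[[1]]
      nv <- vote_bases(chars, cols)
      grown <- cols[scaf[cols] == "N"]
      scaf[grown] <- chars[match(grown, cols)]
      placements <- rbind(placements, data.frame(
        locus_id = frags$locus_id[i], n_voted = nv, mode = "anchored",
        stringsAsFactors = FALSE))
    } else {
      deferred <- c(deferred, i)
    }
  }

  # fold terminal redundancy: fragments wrapping the circular origin
  # extend the linear scaffold with a rotated duplicate of its start;
  # merge those tail votes back onto the matching head columns.  The
  # window is capped at half the scaffold so head and tail are
  # disjoint (otherwise the shared middle aligns to itself).
  n_fold_dropped <- 0L
  for (fold_round in 1:3) {
    len <- ncol(votes)
    W <- len %/% 2L
    if (W < 300L) break
    t0 <- len - W
    r <- align_pair(paste(scaf[(t0 + 1L):len], collapse = ""),
                    paste(scaf[seq_len(W)], collapse = ""), "local")
    if (length(r$a_cols) < 300L || is.na(r$identity) ||
        r$identity < 0.85 || (W - r$a_end) > 30L) break
    sel <- r$a_cols > 0 & r$b_cols > 0
    from <- t0 + r$a_cols[sel]
    to <- r$b_cols[sel]
    votes[, to] <- votes[, to] + votes[, from]
    keep <- seq_len(t0 + r$a_start)
    # dropped: tail columns that aligned to a head gap or fell outside
    # the alignment (their votes cannot be projected onto a column)
    lost <- setdiff((t0 + 1L):len, c(keep, from))
    n_fold_dropped <- n_fold_dropped +
      sum(votes[, lost, drop = FALSE])
    votes <- votes[, keep, drop = FALSE]
    scaf <- scaf[keep]
  }

  depth <- colSums(votes)
  agreement <- ifelse(depth > 0, apply(votes, 2, max) / pmax(depth, 1L), 0)
  base <- character(ncol(votes))
  low_conf <- logical(ncol(votes))
  for (j in seq_len(ncol(votes))) {
    d <- depth[j]
    if (d == 0) { base[j] <- "N"; next }
    v <- votes[, j]
    top <- which(v == max(v))
    if (length(top) > 1 && tie_rule == "n" && d >= min_depth) {
      base[j] <- "N"
    } else {
      base[j] <- names(.base_idx)[min(top)]  # alphabetical tie-break
    }
    if (d < min_depth) low_conf[j] <- TRUE
  }
  contigs <- list()
  if (length(deferred) > 0) {
    sub <- frags[deferred, , drop = FALSE]
    class(sub) <- c("fragment_set", "data.frame")
    contigs <- list(build_consensus(sub, max_gap, error_clearance,
                                    min_depth, tie_rule, min_overlap,
                                    min_identity))
  }
  structure(list(sequence = paste(base, collapse = ""),
                 depth = as.integer(depth), agreement = agreement,
                 low_conf = low_conf,
                 n_fragments = nrow(frags) - length(deferred),
                 n_fold_dropped = n_fold_dropped,
                 origin_rotated = FALSE, placements = placements,
                 contigs = contigs),
            class = "virus_consensus")
}

#' @export
print.virus_consensus <- function(x, ...) {
  cat("Virus consensus:", nchar(x$sequence), "bp from", x$n_fragments,
      "fragments; mean depth", round(mean(x$depth), 2),
      if (x$origin_rotated) "(origin-rotated)" else "", "\n")
  if (length(x$contigs))
    cat("  +", length(x$contigs), "secondary contig group(s)\n")
  invisible(x)
}

#' Rotate a circular consensus so the origin motif starts at position 0
#'
#' Scans all rotations of the (circular) consensus for the best match
#' to the tRNA-Met primer-binding-site motif; if the best match has at
#' most `max_mismatches` mismatches the sequence (and its per-column
#' statistics) is rotated so the motif starts the genome.  Ties go to
#' the leftmost position, with a warning.
#'
#' @param consensus a `virus_consensus` (or a bare sequence string).
#' @param origin_motif the origin motif (ACGT string).
#' @param max_mismatches maximum mismatches for an accepted match.
#' @return the rotated `virus_consensus`; `origin_rotated` is TRUE iff
#'   the motif was found (the sequence is unchanged otherwise).
#' @export
rotate_to_origin <- function(consensus, origin_motif, max_mismatches = 2L) {
  bare <- is.character(consensus)
  if (bare)
    consensus <- structure(list(sequence = consensus,
                                depth = integer(nchar(consensus)),
                                agreement = numeric(nchar(consensus)),
                                low_conf = logical(nchar(consensus)),
                                n_fragments = NA_integer_,
                                origin_rotated = FALSE,
                                placements = NULL, contigs = list()),
                           class = "virus_consensus")
  s <- consensus$sequence
  L <- nchar(s)
  if (L == 0) stop("consensus is empty", call. = FALSE)
  motif <- toupper(origin_motif)
  doubled <- paste0(s, s)
  mm <- Biostrings::neditStartingAt(Biostrings::DNAString(motif),
                                    Biostrings::DNAString(doubled),
                                    starting.at = seq_len(L),
                                    with.indels = FALSE, fixed = TRUE)
  best <- min(mm)
  if (best > max_mismatches) {
    consensus$origin_rotated <- FALSE
    return(consensus)
  }
  at <- which(mm == best)
  if (length(at) > 1)
    warning("multiple equally good origin-motif matches; leftmost used")
  p <- at[1]
  rot <- function(v) if (p == 1L) v else c(v[p:L], v[seq_len(p - 1L)])
  chars <- strsplit(s, "")[[1]]
  consensus$sequence <- paste(rot(chars), collapse = "")
  consensus$depth <- rot(consensus$depth)
  consensus$agreement <- rot(consensus$agreement)
  consensus$low_conf <- rot(consensus$low_conf)
  consensus$origin_rotated <- TRUE
  consensus
}

#' Write consensus sequences and per-column statistics
#' @param consensus a `virus_consensus`.
#' @param fasta_path,stats_path output files (either may be NULL).
#' @param name FASTA record name.
#' @return invisibly, a list of written paths.
#' @export
write_consensus <- function(consensus, fasta_path = NULL,
                            stats_path = NULL, name = "consensus") {
  if (!is.null(fasta_path))
    write_fasta(setNames(consensus$sequence, name), fasta_path)
  if (!is.null(stats_path)) {
    df <- data.frame(pos = seq_len(nchar(consensus$sequence)) - 1L,
                     depth = consensus$depth,
                     agreement = round(consensus$agreement, 4),
                     low_conf = consensus$low_conf)
    write.table(df, stats_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(list(fasta = fasta_path, stats = stats_path))
}
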