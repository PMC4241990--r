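# Pairwise alignment wrappers around the compiled affine-gap aligner.
#
# Nucleotide scoring defaults follow discontiguous-blastn conventions
# (match +2, mismatch -3, gap open -5, gap extend -2); protein scoring
# uses BLOSUM62.  'N' is neutral (score 0 against everything), and the
# '#' masking character scores an effective -Inf so masked subject
# regions cannot be re-aligned.

.nt_alphabet <- "ACGTN"

nt_score_matrix <- function(match = 2L, mismatch = -3L) {
  K <- nchar(.nt_alphabet)
  m <- matrix(mismatch, K, K)
  diag(m) <- match
  m[5, ] <- 0L  # N neutral
  m[, 5] <- 0L
  storage.mode(m) <- "integer"
  m
}

.aa_cache <- new.env(parent = emptyenv())

aa_score_matrix <- function() {
  if (is.null(.aa_cache$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    storage.mode(m) <- "integer"
    .aa_cache$mat <- m
    .aa_cache$alphabet <- paste(rownames(m), collapse = "")
  }
  .aa_cache$mat
}

aa_alphabet <- function() {
  aa_score_matrix()
  .aa_cache$alphabet
}

#' Pairwise sequence alignment with affine gaps
#'
#' Local (Smith-Waterman) or global (Needleman-Wunsch) alignment of two
#' sequences.  Coordinates in the result are 0-based half-open.
#'
#' @param a,b sequences (single strings).
#' @param type `"local"` or `"global"`.
#' @param alphabet `"dna"` or `"protein"` (BLOSUM62).
#' @param match,mismatch nucleotide scores (ignored for protein).
#' @param gap_open,gap_ext gap penalties (non-positive; a gap of length
#'   L costs `gap_open + (L-1)*gap_ext`).
#' @return a list with `score`, `a_start`, `a_end`, `b_start`, `b_end`
#'   (0-based half-open), `n_match`, `n_mismatch`, `n_gapcols`,
#'   `identity` (matches over gap-free aligned columns), and the
#'   per-column position maps `a_cols`/`b_cols` (1-based, 0 = gap).
#' @export
align_pair <- function(a, b, type = c("local", "global"),
                       alphabet = c("dna", "protein"),
                       match = 2L, mismatch = -3L,
                       gap_open = -5, gap_ext = -2) {
  type <- match.arg(type)
  alphabet <- match.arg(alphabet)
  if (alphabet == "dna") {
    alpha <- .nt_alphabet
    smat <- nt_score_matrix(match, mismatch)
  } else {
    alpha <- aa_alphabet()
    smat <- aa_score_matrix()
  }
  r <- cpp_align(a, b, alpha, smat, gap_open, gap_ext, type)
  ncmp <- r$n_match + r$n_mismatch
  r$identity <- if (ncmp > 0) r$n_match / ncmp else NA_real_
  r$a_start <- r$a_start - 1L
  r$b_start <- r$b_start - 1L
  r
}

# self-score of a protein probe under BLOSUM62 (used for relative
# score thresholds)
probe_self_score <- function(probe) {
  m <- aa_score_matrix()
  ch <- strsplit(probe, "")[[1]]
  idx <- match(ch, rownames(m))
  if (anyNA(idx)) idx <- idx[!is.na(idx)]
  sum(m[cbind(idx, idx)])
}

# Iterated extraction of local alignments of `query` against `subject`:
# best local alignment, mask, repeat while score >= min_score.
# Returns a data.frame with 1-based inclusive subject/query coordinates.
iterated_local <- function(query, subject, alpha, smat,
                           gap_open, gap_ext, min_score,
                           max_rounds = 64L) {
  out <- list()
  sub <- subject
  for (i in seq_len(max_rounds)) {
    r <- cpp_align(query, sub, alpha, smat, gap_open, gap_ext, "local")
    if (r$score < min_score || r$b_end == 0) break
    ncmp <- r$n_match + r$n_mismatch
    out[[length(out) + 1L]] <- data.frame(
      q_start = r$a_start, q_end = r$a_end,
      s_start = r$b_start, s_end = r$b_end,
      score = r$score,
      identity = if (ncmp > 0) r$n_match / ncmp else NA_real_,
      stringsAsFactors = FALSE)
    substr(sub, r$b_start, r$b_end) <-
      strrep("#", r$b_end - r$b_start + 1L)
  }
  if (length(out) == 0)
    return(data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      score = numeric(), identity = numeric()))
  do.call(rbind, out)
}

# Candidate windows from exact k-mer seeds, gated by ungapped x-drop
# extension.  Returns 1-based subject intervals plus the query span of
# the member seeds (padded), so dynamic programming can be restricted
# on both sides.
seed_windows <- function(query, subject, k, alpha, smat, xdrop,
                         gate, pad) {
  empty <- data.frame(start = integer(), end = integer(),
                      q_start = integer(), q_end = integer())
  seeds <- cpp_kmer_seeds(query, subject, k, alpha)
  if (nrow(seeds) == 0) return(empty)
  iv <- IRanges::IRanges(pmax(1L, seeds[, 2] - pad),
                         pmin(nchar(subject), seeds[, 2] + k - 1L + pad))
  red <- IRanges::reduce(iv)
  ov <- IRanges::findOverlaps(IRanges::IRanges(seeds[, 2],
                                               seeds[, 2] + k - 1L), red)
  sh <- S4Vectors::subjectHits(ov)
  qh <- S4Vectors::queryHits(ov)
  out <- lapply(seq_along(red), function(w) {
    members <- qh[sh == w]
    if (length(members) == 0) return(NULL)
    # probe a few member seeds spread across the window
    pick <- members[unique(round(seq(1, length(members),
                                     length.out = min(3, length(members)))))]
    sc <- vapply(pick, function(si) {
      cpp_ungapped_extend(query, subject, seeds[si, 1], seeds[si, 2],
                          k, alpha, smat, xdrop)
    }, numeric(1))
    if (max(sc) < gate) return(NULL)
    data.frame(start = IRanges::start(red)[w], end = IRanges::end(red)[w],
               q_start = max(1L, min(seeds[members, 1]) - pad),
               q_end = min(nchar(query),
                           max(seeds[members, 1]) + k - 1L + pad))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}
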