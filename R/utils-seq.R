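# Sequence and coordinate utilities shared across modules.
#
# All interval coordinates in this package are 0-based, half-open
# ([start, end)), on the forward strand of the named host sequence.
# Conversion to 1-based systems (GRanges, GFF3, R's substr()) happens
# only at the boundaries, via the helpers below.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the given seed and restores the caller's RNG state
#' afterwards, so seeded generators never perturb the global stream.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# uniform random integer in [a, b], safe for a == b (unlike sample())
rint <- function(a, b) {
  if (a >= b) return(as.integer(a))
  as.integer(a + floor(runif(1) * (b - a + 1L)))
}

#' Random i.i.d. uniform DNA sequence
#' @param n length in bp.
#' @return a single character string of A/C/G/T.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# translate a DNA string in a given forward frame (0,1,2); trailing
# partial codon dropped; fuzzy/ambiguous codons become X
translate_frame <- function(x, frame = 0L) {
  s <- substr(x, frame + 1L, nchar(x))
  s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
  if (nchar(s) < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "solve"))
}

# all six conceptual translations; returns list with frames 0:2 for the
# forward strand and 0:2 for the reverse complement
six_frame_translate <- function(x) {
  rc <- revcomp(x)
  list(fwd = lapply(0:2, function(f) translate_frame(x, f)),
       rev = lapply(0:2, function(f) translate_frame(rc, f)))
}

# 61 sense codons (standard code), used by the virus simulator
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write named sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# data.frame with host_seq/start/end (0-based half-open) -> GRanges
gr0 <- function(df, strand = NULL) {
  if (nrow(df) == 0) return(GenomicRanges::GRanges())
  st <- if (!is.null(strand)) strand
        else if ("strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(df$host_seq,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = st)
}

df0 <- function(gr) {
  data.frame(host_seq = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# merge intervals whose gap is strictly below `join`; overlapping or
# adjacent intervals always merge
merge_intervals <- function(df, join = 0L) {
  if (nrow(df) == 0) return(df[, c("host_seq", "start", "end")])
  gr <- GenomicRanges::reduce(gr0(df), min.gapwidth = max(join, 0L) + 0L,
                              ignore.strand = TRUE)
  df0(gr)
}

stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
}
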