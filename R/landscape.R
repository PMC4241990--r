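# Integration-landscape statistics for EVE loci: genome occupancy,
# (TA)n dinucleotide repeat detection, distances to annotated
# features, intron overlap, TA-proximity enrichment against a
# randomized null, flank-redundancy clustering, nested-insertion
# joining, and exact-match small-RNA mapping.
#
# Interval conventions: 0-based half-open everywhere; under these
# coordinates two adjacent intervals (gap 0) are at distance 0.

#' Genome occupancy of masking hits
#'
#' Union length of hits strictly longer than `min_hit_len`, divided by
#' genome length; overlapping hits count once.
#'
#' @param mask_hits hit data.frame (host_seq/start/end).
#' @param genome_length total assembly length in bp.
#' @param min_hit_len counting rule: only hits with length strictly
#'   greater than this contribute.
#' @return list with `bp` (union basepairs) and `fraction`.
#' @export
genome_occupancy <- function(mask_hits, genome_length,
                             min_hit_len = 200L) {
  if (genome_length <= 0)
    stop("genome_length must be positive", call. = FALSE)
  hits <- mask_hits[(mask_hits$end - mask_hits$start) > min_hit_len, ,
                    drop = FALSE]
  bp <- if (nrow(hits) == 0) 0L else
    sum(IRanges::width(GenomicRanges::reduce(gr0(hits),
                                             ignore.strand = TRUE)))
  list(bp = bp, fraction = bp / genome_length)
}

#' Detect (TA)n dinucleotide repeats
#'
#' Period-2 scanner: perfect TA/AT alternation runs are found first;
#' runs separated by at most `max_interruption` off-pattern bases are
#' chained; chains with at least `min_units` perfect units are
#' reported.  Purity is the fraction of the reported span in perfect
#' alternation.
#'
#' @param genome named character vector (or single string).
#' @param min_units minimum number of perfect TA units (default
#'   approximates a tandem-repeat-finder score cutoff of 50 at match
#'   weight 2, i.e. 25 matching bp).
#' @param max_interruption maximum run of consecutive off-pattern
#'   bases bridged inside one repeat.
#' @return data.frame `host_seq`, `start`, `end` (0-based half-open),
#'   `n_units`, `purity`.
#' @export
find_ta_repeats <- function(genome, min_units = 13L,
                            max_interruption = 3L) {
  if (min_units < 2) stop("min_units must be >= 2", call. = FALSE)
  if (is.null(names(genome)) && length(genome) == 1L)
    names(genome) <- "seq1"
  out <- lapply(names(genome), function(sq) {
    s <- toupper(genome[[sq]])
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    if (n < 2) return(NULL)
    at <- ch %in% c("A", "T")
    alt <- c(at[-n] & at[-1] & ch[-n] != ch[-1], FALSE)
    # perfect runs: maximal stretches where consecutive pairs alternate
    r <- rle(alt)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values],
                       pend = ends[r$values] + 1L)  # 1-based inclusive
    if (nrow(runs) == 0) return(NULL)
    # chain runs whose gap <= max_interruption (vectorized grouping)
    chain_id <- cumsum(c(1L, (runs$start[-1] - runs$pend[-nrow(runs)] - 1L)
                         > max_interruption))
    first <- !duplicated(chain_id)
    last <- rev(!duplicated(rev(chain_id)))
    perfect <- as.vector(rowsum(runs$pend - runs$start + 1L, chain_id))
    span0 <- runs$start[first] - 1L
    span1 <- runs$pend[last]
    res <- data.frame(host_seq = sq, start = span0, end = span1,
                      n_units = perfect %/% 2L,
                      purity = perfect / (span1 - span0),
                      stringsAsFactors = FALSE)
    res[res$n_units >= min_units, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(host_seq = character(), start = integer(),
                      end = integer(), n_units = integer(),
                      purity = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Nearest distances from EVE loci to annotated features
#'
#' Both the EVE loci and each feature set are merged at `cluster_join`
#' (gaps strictly below it) before computing per-locus nearest
#' distances; overlap or adjacency gives distance 0.
#'
#' @param eve_loci data.frame of loci (host_seq/start/end) or an
#'   `eve_loci` object.
#' @param feature_annotations named list of feature data.frames
#'   (e.g. `list(TE = ..., gene = ...)`).
#' @param cluster_join merge distance, bp.
#' @return list with `per_locus` (data.frame `host_seq`, `start`,
#'   `end`, one distance column per feature; NA when the feature is
#'   absent from that host sequence) and `summary` (mean/median per
#'   feature).
#' @export
feature_distances <- function(eve_loci, feature_annotations,
                              cluster_join = 200L) {
  loci <- if (inherits(eve_loci, "eve_loci")) eve_loci$loci else eve_loci
  if (length(feature_annotations) == 0 ||
      all(vapply(feature_annotations, nrow, integer(1)) == 0))
    stop("empty feature set; distances undefined", call. = FALSE)
  ml <- merge_intervals(loci, cluster_join)
  gl <- gr0(ml)
  per <- ml
  for (feat in names(feature_annotations)) {
    fd <- feature_annotations[[feat]]
    d <- rep(NA_real_, nrow(ml))
    if (!is.null(fd) && nrow(fd) > 0) {
      mf <- merge_intervals(fd, cluster_join)
      gf <- gr0(mf)
      hit <- GenomicRanges::distanceToNearest(gl, gf,
                                              ignore.strand = TRUE)
      d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
    }
    per[[paste0("dist_", feat)]] <- d
  }
  sm <- do.call(rbind, lapply(names(feature_annotations), function(f) {
    d <- per[[paste0("dist_", f)]]
    data.frame(feature = f, mean = mean(d, na.rm = TRUE),
               median = median(d, na.rm = TRUE),
               n = sum(!is.na(d)), stringsAsFactors = FALSE)
  }))
  list(per_locus = per, summary = sm)
}

#' Overlap of EVE loci with genes and introns
#'
#' @param eve_loci loci data.frame or `eve_loci` object.
#' @param gene_models exon rows (`gene_id`, `host_seq`, `start`,
#'   `end`); gene spans are exon ranges, introns the gaps between
#'   exons of a gene.
#' @return list with `fraction_loci_in_genes` (fraction of merged loci
#'   overlapping a gene span), `fraction_genic_bp_in_introns`
#'   (fraction of the genic overlap basepairs that fall in introns),
#'   `genic_bp`, `intronic_bp`.
#' @export
intron_overlap <- function(eve_loci, gene_models) {
  loci <- if (inherits(eve_loci, "eve_loci")) eve_loci$loci else eve_loci
  ml <- merge_intervals(loci, 0L)
  gl <- gr0(ml)
  genes <- split(gene_models, gene_models$gene_id)
  spans <- introns <- list()
  for (g in names(genes)) {
    ex <- genes[[g]][order(genes[[g]]$start), ]
    if (nrow(ex) == 0) { warning("gene without exons skipped: ", g); next }
    spans[[g]] <- data.frame(host_seq = ex$host_seq[1],
                             start = min(ex$start), end = max(ex$end))
    if (nrow(ex) > 1)
      introns[[g]] <- data.frame(host_seq = ex$host_seq[1],
                                 start = ex$end[-nrow(ex)],
                                 end = ex$start[-1])
  }
  if (length(spans) == 0)
    return(list(fraction_loci_in_genes = 0,
                fraction_genic_bp_in_introns = NA_real_,
                genic_bp = 0L, intronic_bp = 0L))
  gspan <- GenomicRanges::reduce(gr0(do.call(rbind, spans)))
  gintr <- if (length(introns))
    GenomicRanges::reduce(gr0(do.call(rbind, introns)))
  else GenomicRanges::GRanges()
  ov <- GenomicRanges::countOverlaps(gl, gspan, ignore.strand = TRUE)
  genic <- GenomicRanges::intersect(gl, gspan, ignore.strand = TRUE)
  genic_bp <- sum(IRanges::width(genic))
  intr_bp <- if (length(gintr) == 0) 0L else
    sum(IRanges::width(GenomicRanges::intersect(genic, gintr,
                                                ignore.strand = TRUE)))
  list(fraction_loci_in_genes = mean(ov > 0),
       fraction_genic_bp_in_introns =
         if (genic_bp > 0) intr_bp / genic_bp else NA_real_,
       genic_bp = genic_bp, intronic_bp = intr_bp)
}

#' (TA)n-proximity enrichment of EVE loci with a randomized null
#'
#' Merges EVE annotations at `merge_join`, keeps loci strictly longer
#' than `min_locus`, and compares the fraction of loci lying within
#' `proximity` of a (TA)n repeat against `R` replicates of an equal
#' number of fixed-length (500 bp) loci placed uniformly at random
#' (N-free positions; overlaps permitted).  The empirical p-value uses
#' the add-one rule, so it is never 0; a Mann-Whitney rank test on the
#' per-locus nearest-distance sets (observed vs pooled random) is
#' reported alongside.
#'
#' @param eve_loci loci/hits data.frame or `eve_loci` object.
#' @param ta_repeats a [find_ta_repeats()] result.
#' @param genome named character vector of host sequences, or a named
#'   integer vector of sequence lengths (no N exclusion then).
#' @param merge_join,min_locus,proximity rule parameters, bp.
#' @param R number of random replicates (>= 19).
#' @param random_locus_len length of the random loci.
#' @param seed RNG seed.
#' @return object of class `ta_enrichment`: list with `n_loci`,
#'   `observed_proximal_fraction`, `replicate_fractions`,
#'   `empirical_p`, `rank_test_p`, `observed_distances`,
#'   `random_distances`.
#' @export
ta_enrichment <- function(eve_loci, ta_repeats, genome,
                          merge_join = 20L, min_locus = 500L,
                          proximity = 1000L, R = 999L,
                          random_locus_len = 500L, seed = NULL) {
  if (R < 19) stop("R must be at least 19", call. = FALSE)
  loci <- if (inherits(eve_loci, "eve_loci")) eve_loci$loci else eve_loci
  ml <- merge_intervals(loci, merge_join)
  ml <- ml[(ml$end - ml$start) > min_locus, , drop = FALSE]
  if (nrow(ml) == 0)
    stop("no qualifying loci after merging and length filtering",
         call. = FALSE)
  if (nrow(ta_repeats) == 0)
    stop("no TA repeats supplied", call. = FALSE)
  # fast nearest-distance to the (sorted, disjoint) TA intervals via
  # findInterval: adjacency is distance 0 under half-open coordinates
  ta_by <- split(ta_repeats[, c("start", "end")], ta_repeats$host_seq)
  ta_by <- lapply(ta_by, function(d) d[order(d$start), , drop = FALSE])
  ndist <- function(df) {
    d <- rep(Inf, nrow(df))
    for (sq in unique(df$host_seq)) {
      ta <- ta_by[[sq]]
      sel <- which(df$host_seq == sq)
      if (is.null(ta) || nrow(ta) == 0) next
      s <- df$start[sel]; e <- df$end[sel]
      i1 <- findInterval(e - 1L, ta$start)   # TAs starting before locus end
      i2 <- findInterval(s, ta$end)          # TAs ending at/before locus start
      dl <- ifelse(i2 >= 1, s - ta$end[pmax(i2, 1L)], Inf)
      dr <- ifelse(i1 + 1L <= nrow(ta),
                   ta$start[pmin(i1 + 1L, nrow(ta))] - e, Inf)
      d[sel] <- ifelse(i1 > i2, 0, pmin(dl, dr))
    }
    d
  }
  obs_d <- ndist(ml)
  obs_frac <- mean(obs_d < proximity)
  n <- nrow(ml)

  is_seq <- is.character(genome)
  lens <- if (is_seq) vapply(genome, nchar, numeric(1)) else genome
  if (is.null(names(lens)))
    stop("genome must be named", call. = FALSE)
  has_n <- is_seq && any(vapply(genome, function(s)
    grepl("N", s, fixed = TRUE), logical(1)))
  avail <- pmax(lens - random_locus_len + 1, 0)
  if (sum(avail) <= 0)
    stop("genome too short for random loci", call. = FALSE)

  draw_random <- function() {
    sq <- sample(names(lens), n, replace = TRUE, prob = avail)
    st <- vapply(sq, function(s) {
      for (try in 1:50) {
        p <- rint(0L, as.integer(avail[[s]] - 1))
        if (!has_n) return(p)
        if (!grepl("N", substr(genome[[s]], p + 1L,
                               p + random_locus_len), fixed = TRUE))
          return(p)
      }
      p
    }, numeric(1))
    data.frame(host_seq = sq, start = st,
               end = st + random_locus_len, stringsAsFactors = FALSE)
  }

  with_seed(seed, {
    reps <- numeric(R)
    rand_d <- vector("list", R)
    for (r in seq_len(R)) {
      d <- ndist(draw_random())
      rand_d[[r]] <- d
      reps[r] <- mean(d < proximity)
    }
    emp_p <- (1 + sum(reps >= obs_frac)) / (R + 1)
    pooled <- unlist(rand_d)
    rank_p <- tryCatch(
      wilcox.test(obs_d, pooled, alternative = "less",
                  exact = FALSE)$p.value,
      error = function(e) NA_real_)
    structure(list(n_loci = n, observed_proximal_fraction = obs_frac,
                   replicate_fractions = reps, empirical_p = emp_p,
                   rank_test_p = rank_p, observed_distances = obs_d,
                   random_distances = pooled),
              class = "ta_enrichment")
  })
}

#' @export
print.ta_enrichment <- function(x, ...) {
  cat(sprintf(
    "TA enrichment: %d loci, %.1f%% proximal (null mean %.1f%%), p = %.4g (rank p = %.3g)\n",
    x$n_loci, 100 * x$observed_proximal_fraction,
    100 * mean(x$replicate_fractions), x$empirical_p, x$rank_test_p))
  invisible(x)
}

#' Cluster the flanks of large EVE loci by identity
#'
#' Extracts `flank`-bp stretches on both sides of every locus at least
#' `min_locus` long and clusters them single-linkage by
#' global-alignment identity; a redundant flank complement (clusters
#' larger than 1) indicates segmental duplication rather than
#' independent integration.
#'
#' @param eve_loci loci data.frame or `eve_loci` object.
#' @param genome named character vector of host sequences.
#' @param min_locus minimum locus length, bp.
#' @param flank flank length, bp.
#' @param identity_threshold 0.80 or 0.90 by convention.
#' @return list with `flanks` (data.frame `flank_id`, `locus`, `side`,
#'   `truncated`, `cluster`), `cluster_sizes` (table),
#'   `singleton_fraction`.
#' @export
cluster_flanks <- function(eve_loci, genome, min_locus = 1000L,
                           flank = 500L, identity_threshold = 0.80) {
  loci <- if (inherits(eve_loci, "eve_loci")) eve_loci$loci else eve_loci
  loci <- loci[(loci$end - loci$start) >= min_locus, , drop = FALSE]
  if (nrow(loci) == 0)
    return(list(flanks = data.frame(), cluster_sizes = table(integer(0)),
                singleton_fraction = NA_real_))
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    sq <- genome[[loci$host_seq[i]]]
    L <- nchar(sq)
    lid <- if ("locus_id" %in% names(loci)) loci$locus_id[i] else
      sprintf("locus%03d", i)
    ls <- max(0L, loci$start[i] - flank)
    lseq <- substr(sq, ls + 1L, loci$start[i])
    rs <- min(L, loci$end[i] + flank)
    rseq <- substr(sq, loci$end[i] + 1L, rs)
    rows[[length(rows) + 1L]] <- data.frame(
      locus = lid, side = "left", sequence = lseq,
      truncated = nchar(lseq) < flank, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      locus = lid, side = "right", sequence = rseq,
      truncated = nchar(rseq) < flank, stringsAsFactors = FALSE)
  }
  fl <- do.call(rbind, rows)
  fl <- fl[nchar(fl$sequence) >= 0.5 * flank, , drop = FALSE]
  cl <- flank_clusters(fl$sequence, identity_threshold)
  fl$cluster <- cl
  fl$flank_id <- paste(fl$locus, fl$side, sep = "_")
  sizes <- table(table(cl))
  list(flanks = fl[, c("flank_id", "locus", "side", "truncated",
                       "cluster")],
       cluster_sizes = table(cl),
       singleton_fraction = mean(table(cl)[as.character(cl)] == 1))
}

#' Join same-element fragments split by younger nested insertions
#'
#' Two annotations of the same element are joined when (i) they are
#' element-collinear: on "+" the element end of the upstream part
#' matches the element start of the downstream part within
#' `tolerance` (mirrored on "-"), and (ii) the genomic gap between
#' them is covered (at `min_cover` fraction) by other annotated
#' insertions, i.e. younger interrupting elements.  Joins chain
#' transitively; ambiguous multi-way joins resolve to the best
#' collinearity.
#'
#' @param eve_annotations data.frame with `host_seq`, `start`, `end`,
#'   `strand`, `probe_id`, `probe_start`, `probe_end` and an id column
#'   (`locus_id` or `annot_id`).
#' @param all_annotations annotations that may cover the interruption
#'   (typically all EVE annotations, any element).
#' @param tolerance element-coordinate tolerance, bp.
#' @param min_cover fraction of the gap that must be annotated.
#' @return data.frame of joined loci: `joined_id`, `host_seq`,
#'   `start`, `end`, `strand`, `members` (comma-separated),
#'   `interrupted_by` (comma-separated ids of covering annotations).
#' @export
join_nested <- function(eve_annotations, all_annotations = eve_annotations,
                        tolerance = 100L, min_cover = 0.9) {
  ann <- eve_annotations
  if (is.null(ann$annot_id))
    ann$annot_id <- if ("locus_id" %in% names(ann)) ann$locus_id else
      sprintf("a%03d", seq_len(nrow(ann)))
  ann <- ann[order(ann$host_seq, ann$start), , drop = FALSE]
  n <- nrow(ann)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  interrupters <- vector("list", n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      cands <- list()
      for (j in (i + 1):n) {
        if (ann$host_seq[j] != ann$host_seq[i]) break
        if (ann$start[j] <= ann$end[i]) next
        if (ann$probe_id[j] != ann$probe_id[i]) next
        if (ann$strand[j] != ann$strand[i]) next
        delta <- if (ann$strand[i] == "+")
          ann$probe_start[j] - ann$probe_end[i]
        else ann$probe_start[i] - ann$probe_end[j]
        if (abs(delta) > tolerance) next
        # gap must be covered by other annotations
        gap <- IRanges::IRanges(ann$end[i] + 1L, ann$start[j])
        if (IRanges::width(gap) <= 0) next
        others <- all_annotations[all_annotations$host_seq ==
                                    ann$host_seq[i], , drop = FALSE]
        oiv <- IRanges::IRanges(others$start + 1L, others$end)
        cov <- IRanges::intersect(gap, IRanges::reduce(oiv))
        covered <- sum(IRanges::width(cov)) / IRanges::width(gap)
        if (covered < min_cover) next
        oid <- others[S4Vectors::queryHits(
          IRanges::findOverlaps(oiv, gap)), , drop = FALSE]
        oid <- setdiff(
          if ("annot_id" %in% names(oid)) oid$annot_id else
            if ("locus_id" %in% names(oid)) oid$locus_id else character(0),
          ann$annot_id[c(i, j)])
        cands[[length(cands) + 1L]] <- list(j = j, delta = abs(delta),
                                            by = oid)
      }
      if (length(cands)) {
        best <- cands[[which.min(vapply(cands, `[[`, numeric(1),
                                        "delta"))]]
        ri <- find(i); rj <- find(best$j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        interrupters[[i]] <- best$by
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  rows <- lapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    data.frame(
      joined_id = paste0("J", min(idx)),
      host_seq = ann$host_seq[idx[1]],
      start = min(ann$start[idx]), end = max(ann$end[idx]),
      strand = ann$strand[idx[1]],
      members = paste(ann$annot_id[idx], collapse = ","),
      interrupted_by = paste(unique(unlist(interrupters[idx])),
                             collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map small RNAs onto a consensus by exact matching
#'
#' A read contributes to coverage iff it matches the consensus exactly
#' (zero mismatches), forward (plus-strand coverage) or as the reverse
#' complement (minus-strand coverage); each exact occurrence
#' contributes once.  Reads outside the 21-24 nt size class are
#' excluded; U is normalized to T.
#'
#' @param reads character vector of read sequences.
#' @param consensus a `virus_consensus` or sequence string.
#' @param min_len,max_len size class bounds, nt.
#' @return list with `plus`, `minus` (per-position coverage vectors),
#'   `n_reads_used`, `n_mapped` (mapping events), `mapped_bases`.
#' @export
map_srnas <- function(reads, consensus, min_len = 21L, max_len = 24L) {
  cseq <- if (inherits(consensus, "virus_consensus")) consensus$sequence
          else consensus
  L <- nchar(cseq)
  subj <- Biostrings::DNAString(cseq)
  reads <- toupper(chartr("U", "T", reads))
  reads <- reads[nchar(reads) >= min_len & nchar(reads) <= max_len]
  reads <- reads[!grepl("[^ACGT]", reads)]
  plus <- minus <- numeric(L)
  n_mapped <- 0L
  bases <- 0L
  for (rd in reads) {
    m <- Biostrings::matchPattern(rd, subj)
    if (length(m)) {
      for (k in seq_along(m)) {
        i <- Biostrings::start(m)[k]
        plus[i:(i + nchar(rd) - 1L)] <- plus[i:(i + nchar(rd) - 1L)] + 1
        n_mapped <- n_mapped + 1L
        bases <- bases + nchar(rd)
      }
    }
    mrc <- Biostrings::matchPattern(revcomp(rd), subj)
    if (length(mrc)) {
      for (k in seq_along(mrc)) {
        i <- Biostrings::start(mrc)[k]
        minus[i:(i + nchar(rd) - 1L)] <- minus[i:(i + nchar(rd) - 1L)] + 1
        n_mapped <- n_mapped + 1L
        bases <- bases + nchar(rd)
      }
    }
  }
  list(plus = plus, minus = minus, n_reads_used = length(reads),
       n_mapped = n_mapped, mapped_bases = bases)
}

#' Write per-position small-RNA coverage as a wiggle-style TSV
#'
#' @param srna a [map_srnas()] result.
#' @param path output file (columns: pos, plus, minus; 0-based).
#' @return `path`, invisibly.
#' @export
write_srna_coverage <- function(srna, path) {
  df <- data.frame(pos = seq_along(srna$plus) - 1L,
                   plus = srna$plus, minus = srna$minus)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
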