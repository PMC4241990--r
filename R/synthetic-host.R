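# Simulation of endogenization: fragmented, mutationally decayed,
# optionally (TA)n-biased and nested insertions of an ancestral virus
# genome into random host sequences, with exact ground-truth
# provenance for every inserted base.
#
# Decay model: per-site independent substitutions (uniform over the 3
# alternative bases) plus geometric-length indels.  Host background is
# i.i.d. uniform ACGT with planted divergent reverse-transcriptase-like
# TE decoys to exercise masking specificity.

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n_sub = 0L))
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate & ch %in% c("A", "C", "G", "T"))
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  list(seq = paste(ch, collapse = ""), n_sub = length(hit))
}

apply_indels <- function(seq, rate, geom_p = 0.4) {
  if (rate <= 0) return(list(seq = seq, n_indel = 0L))
  ch <- strsplit(seq, "")[[1]]
  sites <- which(runif(length(ch)) < rate)
  for (i in rev(sites)) {
    len <- rgeom(1L, geom_p) + 1L
    if (runif(1) < 0.5) {  # deletion
      ch <- ch[-(i:min(i + len - 1L, length(ch)))]
    } else {               # insertion
      ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      ch <- append(ch, ins, after = i)
    }
  }
  list(seq = paste(ch, collapse = ""), n_indel = length(sites))
}

# shift interval tables after inserting `len` bp at `pos` (0-based cut
# point) on host sequence `sq`; intervals spanning the cut are extended
shift_table <- function(df, sq, pos, len) {
  if (is.null(df) || nrow(df) == 0) return(df)
  on <- df$host_seq == sq
  after <- on & df$start >= pos
  span <- on & df$start < pos & df$end > pos
  df$start[after] <- df$start[after] + len
  df$end[after] <- df$end[after] + len
  df$end[span] <- df$end[span] + len
  df
}

#' Simulate endogenization of a virus into host genomes
#'
#' Plants `n_insertions` decayed virus fragments into i.i.d. random
#' host sequences.  Each insertion samples a contiguous virus
#' sub-interval (full-length insertions start anywhere on the circle),
#' a strand, per-site substitutions and geometric-length indels; with
#' probability `ta_bias` a (TA)n run is created at the integration site
#' so the insertion is TA-flanked, and with probability `nested_prob`
#' the insertion lands inside an older insertion, splitting it into
#' two collinear parts.  Host annotation (gene models with
#' exon/intron structure, planted TE decoys) is generated alongside,
#' and every insertion records its exact provenance.
#'
#' @param virus an `ancestral_virus`.
#' @param n_host_seqs,host_size number and size (bp; recycled) of host
#'   sequences.
#' @param n_insertions number of insertions.
#' @param fragment_len_range sampled fragment length range, bp.
#' @param full_length_prob probability an insertion is the full
#'   (rotated) genome.
#' @param substitution_rate,indel_rate per-site decay rates in `[0,1]`.
#' @param ta_bias probability an insertion is TA-flanked.
#' @param ta_units_range units of created (TA)n runs.
#' @param nested_prob probability of nesting into an older insertion.
#' @param allow_wrap sample fragment starts uniformly on the circle
#'   (fragments may span the origin); otherwise only linear
#'   sub-intervals of the unrotated genome are drawn.
#' @param intron_bias probability an insertion is placed inside an
#'   intron of a simulated gene model.
#' @param gene_density,te_density genes / TE decoys per bp.
#' @param te_divergence divergence of planted RT-like TE decoys.
#' @param seed RNG seed.
#' @return object of class `endogenization_truth`: list with
#'   `host_sequences` (named character), `insertions` (data.frame, one
#'   row per contiguous part: `locus_id`, `part`, `host_seq`, `start`,
#'   `end`, `strand`, `v_start`, `v_len`, `n_substitutions`,
#'   `n_indels`, `ta_flanked`, `nested_in`), `gene_models` (exon
#'   rows), `te_annotations`, `ta_runs`, `virus`, `params`.
#' @export
simulate_endogenization <- function(virus,
                                    n_host_seqs = 2L,
                                    host_size = 100000L,
                                    n_insertions = 20L,
                                    fragment_len_range = c(400L, 6000L),
                                    full_length_prob = 0.05,
                                    substitution_rate = 0.03,
                                    indel_rate = 0.002,
                                    ta_bias = 0.2,
                                    ta_units_range = c(10L, 30L),
                                    nested_prob = 0,
                                    intron_bias = 0,
                                    gene_density = 1 / 20000,
                                    te_density = 1 / 30000,
                                    te_divergence = 0.35,
                                    allow_wrap = TRUE,
                                    seed = NULL) {
  rates <- c(substitution_rate, indel_rate, ta_bias, nested_prob,
             intron_bias, full_length_prob)
  if (any(rates < 0 | rates > 1))
    stop("rates and probabilities must be in [0, 1]", call. = FALSE)
  sizes <- rep_len(host_size, n_host_seqs)
  L <- virus$length
  maxfrag <- min(fragment_len_range[2], L)
  if (n_insertions * (maxfrag + 2 * max(ta_units_range)) * 0.5 >
      0.9 * sum(sizes) ||
      n_insertions * fragment_len_range[1] > 0.6 * sum(sizes))
    stop("host too small for requested insertions", call. = FALSE)

  with_seed(seed, {
    hosts <- setNames(lapply(sizes, random_dna),
                      sprintf("chr%02d", seq_len(n_host_seqs)))
    empty_iv <- function(...) data.frame(..., stringsAsFactors = FALSE)
    genes <- empty_iv(gene_id = character(), host_seq = character(),
                      start = integer(), end = integer(),
                      exon = integer())
    tes <- empty_iv(te_id = character(), host_seq = character(),
                    start = integer(), end = integer())
    tas <- empty_iv(host_seq = character(), start = integer(),
                    end = integer())

    # gene models: 3 exons separated by 2 introns
    gid <- 0L
    for (sq in names(hosts)) {
      n_genes <- rpois(1L, gene_density * sizes[[match(sq, names(hosts))]])
      occupied <- IRanges::IRanges()
      for (g in seq_len(n_genes)) {
        glen <- sample(2400:4200, 1L)
        for (try in 1:50) {
          gs <- sample.int(nchar(hosts[[sq]]) - glen, 1L) - 1L
          iv <- IRanges::IRanges(gs + 1L, gs + glen)
          if (length(IRanges::findOverlaps(iv, occupied)) == 0) break
          gs <- NA
        }
        if (is.na(gs)) next
        occupied <- c(occupied, iv)
        gid <- gid + 1L
        cuts <- sort(sample(seq(200L, glen - 200L, by = 50L), 4L))
        exon_iv <- rbind(c(0L, cuts[1]), c(cuts[2], cuts[3]),
                         c(cuts[4], glen))
        genes <- rbind(genes, data.frame(
          gene_id = sprintf("gene%03d", gid), host_seq = sq,
          start = gs + exon_iv[, 1], end = gs + exon_iv[, 2],
          exon = 1:3, stringsAsFactors = FALSE))
      }
    }

    # planted TE decoys: divergent RT-like sequence
    rt_iv <- virus$domain_layout[virus$domain_layout$domain == "RT", ]
    rt_seq <- substr(virus$sequence, rt_iv$start + 1L, rt_iv$end)
    tid <- 0L
    for (sq in names(hosts)) {
      n_te <- rpois(1L, te_density * nchar(hosts[[sq]]))
      for (t in seq_len(n_te)) {
        dec <- mutate_seq(rt_seq, te_divergence)$seq
        dlen <- nchar(dec)
        ds <- sample.int(nchar(hosts[[sq]]) - dlen, 1L) - 1L
        substr(hosts[[sq]], ds + 1L, ds + dlen) <- dec
        tid <- tid + 1L
        tes <- rbind(tes, data.frame(te_id = sprintf("te%03d", tid),
                                     host_seq = sq, start = ds,
                                     end = ds + dlen,
                                     stringsAsFactors = FALSE))
      }
    }

    ins <- empty_iv(locus_id = character(), part = integer(),
                    host_seq = character(), start = integer(),
                    end = integer(), strand = character(),
                    v_start = integer(), v_len = integer(),
                    n_substitutions = integer(), n_indels = integer(),
                    ta_flanked = logical(), nested_in = character())
    doubled <- paste0(virus$sequence, virus$sequence)

    pos_ok <- function(sq, pos) {
      if (nrow(ins)) {
        on <- ins$host_seq == sq
        if (any(on & ins$start < pos & ins$end > pos)) return(FALSE)
      }
      if (nrow(genes)) {
        on <- genes$host_seq == sq
        if (any(on & genes$start < pos & genes$end > pos)) return(FALSE)
      }
      if (nrow(tas)) {
        on <- tas$host_seq == sq
        if (any(on & tas$start < pos & tas$end > pos)) return(FALSE)
      }
      TRUE
    }

    introns_of <- function() {
      if (nrow(genes) == 0) return(NULL)
      out <- list()
      for (g in unique(genes$gene_id)) {
        ex <- genes[genes$gene_id == g, ]
        ex <- ex[order(ex$start), ]
        if (nrow(ex) < 2) next
        out[[g]] <- data.frame(host_seq = ex$host_seq[1],
                               start = ex$end[-nrow(ex)],
                               end = ex$start[-1])
      }
      if (length(out)) do.call(rbind, out) else NULL
    }

    for (i in seq_len(n_insertions)) {
      id <- sprintf("ins%03d", i)
      full <- runif(1) < full_length_prob
      flen <- if (full) L else rint(fragment_len_range[1], maxfrag)
      # uniform start on the circle; wrapping reads the doubled genome
      v0 <- if (allow_wrap) sample.int(L, 1L) - 1L
            else sample.int(L - flen + 1L, 1L) - 1L
      frag <- substr(doubled, v0 + 1L, v0 + flen)
      ms <- mutate_seq(frag, substitution_rate)
      mi <- apply_indels(ms$seq, indel_rate)
      strand <- sample(c("+", "-"), 1L)
      fseq <- if (strand == "-") revcomp(mi$seq) else mi$seq
      ta <- runif(1) < ta_bias
      ta_seq <- if (ta) strrep("TA", sample(ta_units_range[1]:
                                              ta_units_range[2], 1L)) else ""
      insert_seq <- paste0(ta_seq, fseq)
      ilen <- nchar(insert_seq)

      nested_target <- NA_character_
      nest <- nrow(ins) > 0 && runif(1) < nested_prob
      pos <- NA
      sq <- NA
      if (nest) {
        wide <- which(ins$end - ins$start >= 300L)
        if (length(wide)) {
          w <- if (length(wide) == 1) wide else sample(wide, 1L)
          sq <- ins$host_seq[w]
          pos <- rint(ins$start[w] + 100L, ins$end[w] - 100L)
          nested_target <- ins$locus_id[w]
        }
      }
      if (is.na(pos) && intron_bias > 0 && runif(1) < intron_bias) {
        intr <- introns_of()
        if (!is.null(intr) && nrow(intr)) {
          k <- sample.int(nrow(intr), 1L)
          if (intr$end[k] - intr$start[k] > 2L) {
            sq <- intr$host_seq[k]
            pos <- rint(intr$start[k] + 1L, intr$end[k] - 1L)
            if (!pos_ok(sq, pos)) { pos <- NA; sq <- NA }
          }
        }
      }
      if (is.na(pos)) {
        for (try in 1:200) {
          sq <- sample(names(hosts), 1L,
                       prob = vapply(hosts, nchar, numeric(1)))
          cand <- sample.int(nchar(hosts[[sq]]) + 1L, 1L) - 1L
          inside_exon <- nrow(genes) > 0 &&
            any(genes$host_seq == sq & genes$start < cand &
                  genes$end > cand)
          if (!inside_exon && pos_ok(sq, cand)) { pos <- cand; break }
        }
        if (is.na(pos))
          stop("host too small for requested insertions", call. = FALSE)
      }

      # split an interrupted older insertion into collinear parts
      if (!is.na(nested_target)) {
        w <- which(ins$host_seq == sq & ins$start < pos & ins$end > pos)
        for (ww in w) {
          left_len <- pos - ins$start[ww]
          row <- ins[ww, ]
          p2 <- row
          if (row$strand == "+") {
            p2$v_start <- row$v_start + left_len
            p2$v_len <- row$v_len - left_len
            ins$v_len[ww] <- left_len
          } else {
            ins$v_start[ww] <- row$v_start + (row$v_len - left_len)
            ins$v_len[ww] <- left_len
            p2$v_len <- row$v_len - left_len
          }
          ins$end[ww] <- pos
          p2$part <- max(ins$part[ins$locus_id == row$locus_id]) + 1L
          p2$start <- pos
          ins <- rbind(ins, p2)
        }
      }

      ins <- shift_table(ins, sq, pos, ilen)
      genes <- shift_table(genes, sq, pos, ilen)
      tes <- shift_table(tes, sq, pos, ilen)
      tas <- shift_table(tas, sq, pos, ilen)
      hosts[[sq]] <- paste0(substr(hosts[[sq]], 1L, pos), insert_seq,
                            substr(hosts[[sq]], pos + 1L,
                                   nchar(hosts[[sq]])))
      if (ta)
        tas <- rbind(tas, data.frame(host_seq = sq, start = pos,
                                     end = pos + nchar(ta_seq),
                                     stringsAsFactors = FALSE))
      ins <- rbind(ins, data.frame(
        locus_id = id, part = 1L, host_seq = sq,
        start = pos + nchar(ta_seq), end = pos + ilen, strand = strand,
        v_start = v0, v_len = flen, n_substitutions = ms$n_sub,
        n_indels = mi$n_indel, ta_flanked = ta,
        nested_in = nested_target, stringsAsFactors = FALSE))
    }

    ins <- ins[order(ins$locus_id, ins$part), ]
    rownames(ins) <- NULL
    structure(list(host_sequences = unlist(hosts),
                   insertions = ins, gene_models = genes,
                   te_annotations = tes, ta_runs = tas, virus = virus,
                   params = list(n_insertions = n_insertions,
                                 substitution_rate = substitution_rate,
                                 indel_rate = indel_rate,
                                 ta_bias = ta_bias,
                                 nested_prob = nested_prob,
                                 intron_bias = intron_bias)),
              class = "endogenization_truth")
  })
}

#' @export
print.endogenization_truth <- function(x, ...) {
  cat("Endogenization truth:", length(x$host_sequences),
      "host sequence(s),",
      length(unique(x$insertions$locus_id)), "insertions (",
      nrow(x$insertions), "parts )\n")
  invisible(x)
}

#' Extract the (oriented) sequence of a truth insertion part
#' @param truth an `endogenization_truth`.
#' @param locus_id insertion id.
#' @param part part number.
#' @param orient reverse-complement minus-strand parts to virus
#'   orientation.
#' @return nucleotide string.
#' @export
truth_insertion_seq <- function(truth, locus_id, part = 1L,
                                orient = TRUE) {
  r <- truth$insertions[truth$insertions$locus_id == locus_id &
                          truth$insertions$part == part, ]
  if (nrow(r) != 1) stop("unknown insertion part", call. = FALSE)
  s <- substr(truth$host_sequences[[r$host_seq]], r$start + 1L, r$end)
  if (orient && r$strand == "-") s <- revcomp(s)
  s
}

#' Write endogenization truth to standard formats
#'
#' Host genome as FASTA; insertion/gene/TE/TA annotations as GFF3
#' (1-based inclusive) and insertions additionally as BED (0-based
#' half-open).
#'
#' @param truth an `endogenization_truth`.
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of written paths.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "host.fasta")
  write_fasta(truth$host_sequences, fa)
  grs <- list()
  add <- function(df, type, id) {
    if (nrow(df) == 0) return()
    gr <- gr0(df)
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- id
    grs[[length(grs) + 1L]] <<- gr
  }
  add(truth$insertions, "viral_insertion",
      sprintf("%s.%d", truth$insertions$locus_id,
              truth$insertions$part))
  add(truth$gene_models, "exon",
      sprintf("%s.exon%d", truth$gene_models$gene_id,
              truth$gene_models$exon))
  add(truth$te_annotations, "transposable_element",
      truth$te_annotations$te_id)
  if (nrow(truth$ta_runs))
    add(truth$ta_runs, "TA_repeat",
        sprintf("ta%03d", seq_len(nrow(truth$ta_runs))))
  gff <- file.path(dir, "truth.gff3")
  all_gr <- suppressWarnings(do.call(c, grs))
  rtracklayer::export(all_gr, gff, format = "gff3")
  bed <- file.path(dir, "insertions.bed")
  write_loci_bed(data.frame(host_seq = truth$insertions$host_seq,
                            start = truth$insertions$start,
                            end = truth$insertions$end,
                            locus_id = truth$insertions$locus_id,
                            strand = truth$insertions$strand), bed)
  invisible(c(fasta = fa, gff3 = gff, bed = bed))
}
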