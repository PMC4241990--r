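# Independent oracles (brute force / enumeration / regex) used to
# check the package's optimized implementations, plus shared fixtures.

# ---- shared fixtures (built once per test run) -------------------------

.fixtures <- new.env(parent = emptyenv())

fixture_virus <- function() {
  if (is.null(.fixtures$virus))
    .fixtures$virus <- simulate_ancestral_virus(seed = 1)
  .fixtures$virus
}

fixture_probes <- function() {
  if (is.null(.fixtures$probes))
    .fixtures$probes <- domain_probes(fixture_virus())
  .fixtures$probes
}

# ---- naive affine-gap Smith-Waterman (pure R, full matrices) -----------

naive_blosum <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# returns best local score plus 0-based half-open coordinates
naive_local <- function(a, b, smat, gap_open = -11, gap_ext = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- M[, 1] <- 0
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- smat[A[i], B[j]]
      prev <- max(M[i, j], X[i, j], Y[i, j], 0)
      M[i + 1, j + 1] <- prev + s
      X[i + 1, j + 1] <- max(M[i + 1, j] + gap_open,
                             X[i + 1, j] + gap_ext)
      Y[i + 1, j + 1] <- max(M[i, j + 1] + gap_open,
                             Y[i, j + 1] + gap_ext)
      if (M[i + 1, j + 1] > best) {
        best <- M[i + 1, j + 1]; bi <- i; bj <- j
      }
    }
  }
  list(score = best, a_end = bi, b_end = bj)
}

# nucleotide scoring matrix in lookup form for naive_local
naive_nt_matrix <- function(match = 2, mismatch = -3) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

# ---- exhaustive ORF enumeration (regex over translations) --------------

oracle_orfs <- function(sequence, min_len_aa, circular = FALSE) {
  s <- toupper(sequence)
  L <- nchar(s)
  rows <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    scan <- if (circular) paste0(ss, ss) else ss
    for (f in 0:2) {
      sub <- substr(scan, f + 1, nchar(scan))
      sub <- substr(sub, 1, 3 * (nchar(sub) %/% 3))
      if (nchar(sub) < 3) next
      prot <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "solve"))
      mm <- gregexpr("M[^*]*\\*", prot)[[1]]
      if (mm[1] == -1) next
      for (k in seq_along(mm)) {
        aa0 <- mm[k]
        alen <- attr(mm, "match.length")[k]
        if (alen - 1 < min_len_aa) next
        s0 <- f + 3 * (aa0 - 1)
        e0 <- f + 3 * (aa0 - 1 + alen)
        if (circular && !(s0 < L && (e0 - s0) <= L)) next
        if (strand == "+") { fs <- s0; fe <- e0 }
        else {
          fs <- L - e0; fe <- L - s0
          if (fs < 0) { fs <- fs + L; fe <- fe + L }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          start = fs, end = fe, strand = strand,
          length_aa = alen - 1, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(),
               strand = character(), length_aa = integer())
  out <- out[!duplicated(out[, c("start", "end", "strand")]), ]
  out[order(out$start, out$end), ]
}

# ---- (TA)n detection oracle (regex + chained gaps) ---------------------

oracle_ta <- function(sequence, min_units, max_interruption) {
  s <- toupper(sequence)
  mm <- gregexpr("(?:TA)+T?|(?:AT)+A?", s)[[1]]
  if (mm[1] == -1)
    return(data.frame(start = integer(), end = integer(),
                      n_units = integer()))
  st <- as.integer(mm)
  len <- attr(mm, "match.length")
  keep <- len >= 2
  st <- st[keep]; len <- len[keep]
  if (length(st) == 0)
    return(data.frame(start = integer(), end = integer(),
                      n_units = integer()))
  res <- list()
  cs <- st[1]; ce <- st[1] + len[1] - 1; perfect <- len[1]
  flush <- function() {
    res[[length(res) + 1L]] <<- data.frame(
      start = cs - 1L, end = ce, n_units = perfect %/% 2L)
  }
  for (k in seq_along(st)[-1]) {
    gap <- st[k] - ce - 1
    if (gap <= max_interruption) {
      ce <- st[k] + len[k] - 1
      perfect <- perfect + len[k]
    } else {
      flush()
      cs <- st[k]; ce <- st[k] + len[k] - 1; perfect <- len[k]
    }
  }
  flush()
  out <- do.call(rbind, res)
  out[out$n_units >= min_units, , drop = FALSE]
}

# ---- brute-force single-linkage hit chaining ---------------------------

oracle_merge_partition <- function(hits, join) {
  n <- nrow(hits)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (hits$host_seq[i] != hits$host_seq[j]) next
    gap <- max(hits$start[i], hits$start[j]) -
      min(hits$end[i], hits$end[j])
    adj[i, j] <- gap < join
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# ---- exhaustive Dollo placement ----------------------------------------

# tips below each node, via an explicit stack (independent of the
# recursion used in the package)
oracle_tipsets <- function(phy) {
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  sets <- vector("list", nn)
  for (t in seq_len(ntip)) sets[[t]] <- t
  edge <- phy$edge
  done <- c(rep(TRUE, ntip), rep(FALSE, nn - ntip))
  while (!all(done)) {
    for (nd in (ntip + 1):nn) {
      if (done[nd]) next
      kids <- edge[edge[, 1] == nd, 2]
      if (all(done[kids])) {
        sets[[nd]] <- sort(unlist(sets[kids]))
        done[nd] <- TRUE
      }
    }
  }
  sets
}

# minimum number of losses over all single-gain placements, and the
# loss count of the MRCA placement
oracle_dollo <- function(phy, pattern) {
  tips <- phy$tip.label
  p <- toupper(substr(as.character(pattern[tips]), 1, 1))
  present <- which(p == "P")
  sets <- oracle_tipsets(phy)
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  losses_under <- function(v) {
    # maximal subtrees under v whose non-missing tips are all absent
    count <- 0
    stack <- v
    while (length(stack)) {
      nd <- stack[length(stack)]
      stack <- stack[-length(stack)]
      tp <- p[sets[[nd]]]
      if (!any(tp == "P")) {
        if (any(tp == "A")) count <- count + 1
      } else if (nd > ntip) {
        stack <- c(stack, phy$edge[phy$edge[, 1] == nd, 2])
      }
    }
    count
  }
  best <- Inf
  for (v in seq_len(nn)) {
    if (!all(present %in% sets[[v]])) next
    lv <- losses_under(v)
    if (lv < best) best <- lv
  }
  mrca <- if (length(present) == 1) present else
    ape::getMRCA(phy, tips[present])
  list(min_losses = best, mrca_losses = losses_under(mrca))
}

# ---- misc --------------------------------------------------------------

# identity of a linear reconstruction to a circular truth genome
circular_identity <- function(seq, truth) {
  r <- align_pair(seq, paste0(truth, truth), "local")
  list(identity = r$identity, aligned = r$a_end - r$a_start)
}

# fragment set straight from simulator truth (skips discovery)
truth_fragments <- function(truth) {
  ins <- truth$insertions
  out <- data.frame(
    locus_id = paste(ins$locus_id, ins$part, sep = "."),
    sequence = vapply(seq_len(nrow(ins)), function(i)
      truth_insertion_seq(truth, ins$locus_id[i], ins$part[i]),
      character(1)),
    anchor = ifelse(ins$strand == "+", ins$v_start,
                    ins$v_start),
    length = ins$end - ins$start,
    stringsAsFactors = FALSE)
  class(out) <- c("fragment_set", "data.frame")
  out
}
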