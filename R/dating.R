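# Insertion dating by ortholog sharing: calibrated ultrametric trees,
# flank-based orthology matching into presence/absence matrices,
# single-gain (Dollo) parsimony placement, and minimum-age brackets.

#' Parse a calibrated ultrametric tree
#'
#' Reads a Newick tree with branch lengths in MY, computes node ages
#' (root age minus root-to-node path length) and verifies
#' ultrametricity: every tip must sit at age 0 within `tol`.
#'
#' @param newick a Newick string, a file path, or a `phylo`.
#' @param tol ultrametricity tolerance in MY.
#' @return object of class `dated_tree`: list with `phylo`, `node_age`
#'   (ages for nodes `1..Ntip+Nnode`), `root_age`.
#' @export
parse_dated_tree <- function(newick, tol = 1e-6) {
  phy <- if (inherits(newick, "phylo")) newick
  else if (grepl("\\(", newick)) ape::read.tree(text = newick)
  else ape::read.tree(newick)
  if (is.null(phy) || is.null(phy$edge.length))
    stop("invalid Newick input or missing branch lengths", call. = FALSE)
  depth <- ape::node.depth.edgelength(phy)
  root_age <- max(depth)
  age <- root_age - depth
  ntip <- ape::Ntip(phy)
  tip_dev <- abs(age[seq_len(ntip)])
  if (any(tip_dev > tol)) {
    worst <- which.max(tip_dev)
    stop(sprintf(
      "tree is not ultrametric: tip %s deviates by %.6g MY",
      phy$tip.label[worst], tip_dev[worst]), call. = FALSE)
  }
  age[seq_len(ntip)] <- 0
  structure(list(phylo = phy, node_age = age, root_age = root_age),
            class = "dated_tree")
}

as_dated_tree <- function(x, tol = 1e-6) {
  if (inherits(x, "dated_tree")) x else parse_dated_tree(x, tol)
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("Dated tree:", ape::Ntip(x$phylo), "tips, root age",
      round(x$root_age, 4), "MY\n")
  invisible(x)
}

#' Write a dated tree as Newick
#' @param tree a `dated_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dated_tree <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path, digits = 12)
  invisible(path)
}

#' The calibrated Oryza species tree used in the worked dating example
#'
#' An ultrametric tree of eleven Oryza taxa (nine AA-genome species,
#' the BB genome O. punctata and the FF genome O. brachyantha) encoded
#' from published node ages (root fixed at 15 MY), bundled as a
#' plain-text Newick file.
#'
#' @return a `dated_tree`.
#' @export
oryza_dated_tree <- function() {
  parse_dated_tree(system.file("extdata", "oryza_dated_tree.nwk",
                               package = "paleovir", mustWork = TRUE))
}

# ---- orthology matching ------------------------------------------------

# single-linkage clusters of sequences at a global-alignment identity
# threshold, with a shared-k-mer prefilter
flank_clusters <- function(seqs, threshold, k = 16L) {
  n <- length(seqs)
  if (n == 1) return(1L)
  idm <- matrix(0, n, n)
  diag(idm) <- 1
  kmers <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  })
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (!any(kmers[[i]] %in% kmers[[j]])) next
    r <- align_pair(seqs[i], seqs[j], "global")
    idm[i, j] <- idm[j, i] <-
      if (is.na(r$identity)) 0 else
        r$n_match / max(nchar(seqs[i]), nchar(seqs[j]))
  }
  hc <- hclust(as.dist(1 - idm), method = "single")
  as.integer(cutree(hc, h = 1 - threshold))
}

#' Match orthologous EVE loci across genomes by flank identity
#'
#' Loci from different genomes are grouped when both their left and
#' right flanks align above the identity threshold (single-linkage per
#' side; a group is the combination of a left- and a right-flank
#' cluster).  A locus whose two flanks disagree about group membership
#' is ambiguous and set aside.  For genomes without a member locus,
#' the group's flanks are searched in the genome sequence when
#' available: both flanks found directly adjacent (gap at most
#' `empty_gap_max`, room for a residual (TA)n run but not an EVE)
#' record an absent-with-empty-site "A"; otherwise the genome records
#' missing "M".
#'
#' @param locus_tables named list (one element per genome) of
#'   data.frames with `locus_id`, `left_flank`, `right_flank` and
#'   optionally `component`.
#' @param genomes optional named character vector of genome sequences
#'   for empty-site detection.
#' @param identity_threshold flank identity threshold.
#' @param empty_gap_max maximum gap (bp) between adjacent flank
#'   matches at an empty site.
#' @return a character matrix (class `presence_absence_matrix`) of
#'   "P"/"A"/"M", loci groups x genomes, with attributes `members`
#'   (list of genome:locus ids per group), `component` (per-group A/B/
#'   mixed label when provided) and `ambiguous` (set-aside loci).
#' @export
match_orthologous_loci <- function(locus_tables, genomes = NULL,
                                   identity_threshold = 0.90,
                                   empty_gap_max = 200L) {
  gnames <- names(locus_tables)
  all <- do.call(rbind, lapply(gnames, function(g) {
    df <- locus_tables[[g]]
    if (is.null(df) || nrow(df) == 0) return(NULL)
    data.frame(genome = g, locus_id = df$locus_id,
               left_flank = df$left_flank,
               right_flank = df$right_flank,
               component = if ("component" %in% names(df))
                 df$component else NA_character_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all) || nrow(all) == 0)
    stop("no loci supplied", call. = FALSE)
  lcl <- flank_clusters(all$left_flank, identity_threshold)
  rcl <- flank_clusters(all$right_flank, identity_threshold)
  # ambiguity: a left cluster spanning several right clusters (or vice
  # versa) cannot be resolved into one group
  amb <- rep(FALSE, nrow(all))
  for (c1 in unique(lcl)) {
    if (length(unique(rcl[lcl == c1])) > 1) amb[lcl == c1] <- TRUE
  }
  for (c1 in unique(rcl)) {
    if (length(unique(lcl[rcl == c1])) > 1) amb[rcl == c1] <- TRUE
  }
  ambiguous <- all[amb, c("genome", "locus_id")]
  ok <- all[!amb, , drop = FALSE]
  okl <- lcl[!amb]
  if (nrow(ok) == 0)
    stop("all loci ambiguous; no groups formed", call. = FALSE)
  groups <- split(seq_len(nrow(ok)), okl)
  names(groups) <- sprintf("og%03d", seq_along(groups))
  mat <- matrix("M", length(groups), length(gnames),
                dimnames = list(names(groups), gnames))
  members <- comp <- setNames(vector("list", length(groups)),
                              names(groups))
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    mat[gi, unique(ok$genome[idx])] <- "P"
    members[[gi]] <- paste(ok$genome[idx], ok$locus_id[idx], sep = ":")
    cc <- unique(stats::na.omit(ok$component[idx]))
    comp[[gi]] <- if (length(cc) == 0) NA_character_
                  else if (length(cc) == 1) cc else "mixed"
  }
  if (!is.null(genomes)) {
    for (gi in seq_along(groups)) {
      idx <- groups[[gi]][1]
      lf <- ok$left_flank[idx]
      rf <- ok$right_flank[idx]
      for (g in gnames[mat[gi, ] != "P"]) {
        if (!g %in% names(genomes)) next
        hl <- best_flank_hit(lf, genomes[[g]], identity_threshold)
        hr <- best_flank_hit(rf, genomes[[g]], identity_threshold)
        if (is.null(hl) || is.null(hr)) next
        if (hl$strand != hr$strand) next
        gap <- if (hl$strand == "+") hr$start - hl$end
               else hl$start - hr$end
        if (gap >= -10 && gap <= empty_gap_max) mat[gi, g] <- "A"
      }
    }
  }
  structure(mat, class = c("presence_absence_matrix", class(mat)),
            members = members,
            component = unlist(comp),
            ambiguous = ambiguous)
}

#' @export
print.presence_absence_matrix <- function(x, ...) {
  cat("Presence/absence matrix:", nrow(x), "ortholog groups x",
      ncol(x), "genomes\n")
  print(matrix(unclass(x), nrow(x), ncol(x), dimnames = dimnames(x)),
        quote = FALSE)
  amb <- attr(x, "ambiguous")
  if (!is.null(amb) && nrow(amb))
    cat(nrow(amb), "locus/loci set aside as ambiguous\n")
  invisible(x)
}

# best local hit of a flank in a genome string (both strands), or NULL
# if none reaches the identity threshold over >= 80% of the flank
best_flank_hit <- function(flank, genome, identity_threshold) {
  alpha <- .nt_alphabet
  smat <- nt_score_matrix()
  fl <- nchar(flank)
  best <- NULL
  for (strand in c("+", "-")) {
    if (strand == "-" && !is.null(best) && best$score >= 1.9 * fl)
      break  # near-perfect forward hit; skip the reverse scan
    q <- if (strand == "+") flank else revcomp(flank)
    win <- if (nchar(genome) <= 4000L)
      data.frame(start = 1L, end = nchar(genome))
    else seed_windows(q, genome, 14L, alpha, smat, xdrop = 30,
                      gate = 50, pad = fl + 100L)
    for (w in seq_len(nrow(win))) {
      wseq <- substr(genome, win$start[w], win$end[w])
      r <- cpp_align(q, wseq, alpha, smat, -5, -2, "local")
      if (r$b_end == 0) next
      ncmp <- r$n_match + r$n_mismatch
      if (ncmp < 0.8 * fl) next
      if (r$n_match / ncmp < identity_threshold) next
      cand <- list(start = r$b_start - 1L + win$start[w] - 1L,
                   end = r$b_end + win$start[w] - 1L,
                   score = r$score, strand = strand)
      if (is.null(best) || cand$score > best$score) best <- cand
    }
  }
  best
}

# ---- Dollo placement ---------------------------------------------------

normalize_pattern <- function(pattern, tips) {
  p <- as.character(pattern)
  names(p) <- names(pattern)
  p <- toupper(substr(p, 1, 1))
  map <- c(P = "P", A = "A", M = "M", "1" = "P", "0" = "A")
  p <- unname(map[p])
  names(p) <- names(pattern)
  if (anyNA(p)) stop("pattern entries must be present/absent/missing",
                     call. = FALSE)
  if (!all(tips %in% names(p)))
    stop("pattern must cover every tip", call. = FALSE)
  p[tips]
}

#' Place an insertion on a dated tree under single-gain parsimony
#'
#' The gain is placed on the branch subtending the MRCA of all
#' present tips (Dollo: one gain, any number of losses); losses are
#' the maximal subtrees under the gain node whose non-missing tips are
#' all absent.  Missing tips neither support nor penalize the
#' placement.  No other single-gain placement has fewer losses.
#'
#' @param tree a `dated_tree`.
#' @param pattern named vector over tips with entries
#'   present/absent/missing (or "P"/"A"/"M", or 1/0).
#' @return list with `gain_node` (the child node of the gain branch;
#'   tips are nodes `1..Ntip`), `n_losses`, `homoplasy_flag` (TRUE iff
#'   losses are required; under incomplete lineage sorting the pattern
#'   may reflect ancestral polymorphism rather than true loss), and
#'   `n_gains_alternative` (gains needed under a no-loss multiple-gain
#'   model, for sensitivity).
#' @export
place_insertion <- function(tree, pattern) {
  dt <- as_dated_tree(tree)
  phy <- dt$phylo
  tips <- phy$tip.label
  p <- normalize_pattern(pattern, tips)
  present <- which(p == "P")
  if (length(present) == 0)
    stop("no present tips; nothing to place", call. = FALSE)
  ntip <- ape::Ntip(phy)
  gain <- if (length(present) == 1) unname(present) else
    ape::getMRCA(phy, tips[present])
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  # status: "P" subtree contains a present tip, "A" all non-missing
  # absent (>=1), "M" only missing tips
  status <- character(ntip + ape::Nnode(phy))
  po <- ape::reorder.phylo(phy, "postorder")
  nodes_post <- unique(po$edge[, 1])  # children before parents
  status[seq_len(ntip)] <- p
  for (nd in nodes_post) {
    st <- status[kids[[as.character(nd)]]]
    status[nd] <- if (any(st == "P")) "P"
                  else if (any(st == "A")) "A" else "M"
  }
  count_losses <- function(node) {
    if (status[node] == "M") return(0L)
    if (status[node] == "A") return(1L)
    if (node <= ntip) return(0L)
    sum(vapply(kids[[as.character(node)]], count_losses, integer(1)))
  }
  n_losses <- if (gain <= ntip) 0L else count_losses(gain)
  # no-loss alternative: number of maximal all-present subtrees
  all_present <- logical(ntip + ape::Nnode(phy))
  all_present[seq_len(ntip)] <- p != "A"  # missing tolerated
  for (nd in nodes_post)
    all_present[nd] <- all(all_present[kids[[as.character(nd)]]])
  count_gains <- function(node) {
    if (status[node] == "M") return(0L)
    if (all_present[node] && status[node] == "P") return(1L)
    if (node <= ntip) return(0L)
    sum(vapply(kids[[as.character(node)]], count_gains, integer(1)))
  }
  root <- ntip + 1L
  list(gain_node = gain, n_losses = n_losses,
       homoplasy_flag = n_losses >= 1L,
       n_gains_alternative = count_gains(root))
}

#' Age bracket of a placed insertion
#'
#' The insertion occurred somewhere on the gain branch, so its age is
#' bracketed by the ages of the nodes bounding that branch: the gain
#' node below (0 for a tip) and its parent above.  A gain on the root
#' branch is unbounded above (`Inf`).
#'
#' @param tree a `dated_tree`.
#' @param placement a [place_insertion()] result (or a node id).
#' @return `c(min_age, max_age)` in MY.
#' @export
age_bracket <- function(tree, placement) {
  dt <- as_dated_tree(tree)
  phy <- dt$phylo
  node <- if (is.list(placement)) placement$gain_node else placement
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  min_age <- dt$node_age[node]
  if (node == root) return(c(min_age = min_age, max_age = Inf))
  parent <- phy$edge[phy$edge[, 2] == node, 1]
  c(min_age = min_age, max_age = dt$node_age[parent])
}

#' Date every locus of a presence/absence matrix
#'
#' Runs [place_insertion()] and [age_bracket()] for each row.
#'
#' @param tree a `dated_tree`.
#' @param pam a `presence_absence_matrix` (or plain P/A/M matrix with
#'   genomes as columns matching the tree's tips).
#' @return data.frame `locus`, `gain_node`, `n_losses`,
#'   `homoplasy_flag`, `min_age`, `max_age`.
#' @export
date_insertions <- function(tree, pam) {
  dt <- as_dated_tree(tree)
  rows <- lapply(rownames(pam), function(l) {
    pl <- place_insertion(dt, pam[l, ])
    br <- age_bracket(dt, pl)
    data.frame(locus = l, gain_node = pl$gain_node,
               n_losses = pl$n_losses,
               homoplasy_flag = pl$homoplasy_flag,
               min_age = br[["min_age"]], max_age = br[["max_age"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a presence/absence matrix as TSV
#' @param pam matrix from [match_orthologous_loci()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(pam, path) {
  write.table(unclass(pam), path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}

#' Annotate a tree with per-branch insertion counts
#'
#' Returns the phylo with node labels of the form `n=<count>` counting
#' the placements whose gain branch subtends each internal node
#' (a Newick-exportable summary of where insertions landed).
#'
#' @param tree a `dated_tree`.
#' @param placements a [date_insertions()] result.
#' @return a `phylo` with `node.label` set.
#' @export
annotate_tree_with_gains <- function(tree, placements) {
  dt <- as_dated_tree(tree)
  phy <- dt$phylo
  ntip <- ape::Ntip(phy)
  counts <- table(placements$gain_node)
  lab <- rep("n=0", ape::Nnode(phy))
  for (nd in as.integer(names(counts))) {
    if (nd > ntip) lab[nd - ntip] <- paste0("n=", counts[[as.character(nd)]])
  }
  phy$node.label <- lab
  phy
}
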