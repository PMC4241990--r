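# Simulation of ortholog gain/loss histories on a dated tree, and of
# per-tip genomes realizing those histories (shared flanks, insertion
# present / empty-site absent / unassembled missing), so the
# flank-matching and Dollo-dating stages can be tested against exact
# truth.

#' Simulate single-gain ortholog histories on a dated tree
#'
#' Each locus gains once, on a branch sampled proportionally to branch
#' duration (including a root stem), at a uniform time along the
#' branch; losses then occur along descendant lineages as a Poisson
#' process with rate `loss_rate` per MY, and a lost lineage stays
#' lost.  Tip observations are set to "missing" with probability
#' `missing_prob`, emulating unassembled genomes.
#'
#' @param tree a `dated_tree` (see [parse_dated_tree()]), or a phylo /
#'   Newick string coercible to one.
#' @param loss_rate losses per MY per lineage.
#' @param n_loci number of loci.
#' @param missing_prob probability a tip observation is missing.
#' @param root_stem duration (MY) of the stem branch above the root on
#'   which gains may also occur; default a quarter of the root age.
#' @param seed RNG seed.
#' @return object of class `ortholog_history`: list with `tree`,
#'   `loci` (data.frame `locus_id`, `gain_node`, `gain_time`,
#'   `n_losses`, `true_min`, `true_max`), `tip_presence` (matrix loci
#'   x tips with entries "P", "A", "M").
#' @export
simulate_ortholog_history <- function(tree, loss_rate = 0.05,
                                      n_loci = 50L, missing_prob = 0,
                                      root_stem = NULL, seed = NULL) {
  dt <- as_dated_tree(tree)
  phy <- dt$phylo
  if (dt$root_age <= 0)
    stop("tree has zero depth; cannot simulate histories", call. = FALSE)
  if (is.null(root_stem)) root_stem <- 0.25 * dt$root_age
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  age <- dt$node_age
  # branches: one per non-root node (edge above it), plus the root stem
  nodes <- setdiff(seq_len(ntip + ape::Nnode(phy)), root)
  parent <- integer(max(nodes))
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  dur <- age[parent[nodes]] - age[nodes]
  branch_nodes <- c(nodes, root)
  branch_dur <- c(dur, root_stem)

  kids <- split(phy$edge[, 2], phy$edge[, 1])

  with_seed(seed, {
    loci <- vector("list", n_loci)
    pres <- matrix("A", n_loci, ntip,
                   dimnames = list(sprintf("locus%03d", seq_len(n_loci)),
                                   phy$tip.label))
    for (i in seq_len(n_loci)) {
      b <- sample.int(length(branch_nodes), 1L,
                      prob = branch_dur / sum(branch_dur))
      gnode <- branch_nodes[b]
      lo <- age[gnode]
      hi <- lo + branch_dur[b]
      gain_time <- runif(1, lo, hi)
      n_losses <- 0L
      # propagate presence from the gain node toward the tips
      walk <- function(node, t_top) {
        # lineage enters the branch above `node` alive at time t_top
        span <- t_top - age[node]
        if (span > 0 && runif(1) < 1 - exp(-loss_rate * span)) {
          n_losses <<- n_losses + 1L
          return()
        }
        if (node <= ntip) {
          pres[i, node] <<- "P"
        } else {
          for (k in kids[[as.character(node)]]) walk(k, age[node])
        }
      }
      # survival along the remainder of the gain branch itself
      span0 <- gain_time - age[gnode]
      lost0 <- runif(1) < 1 - exp(-loss_rate * span0)
      if (!lost0) {
        if (gnode <= ntip) pres[i, gnode] <- "P"
        else for (k in kids[[as.character(gnode)]]) walk(k, age[gnode])
      } else n_losses <- n_losses + 1L
      loci[[i]] <- data.frame(
        locus_id = rownames(pres)[i], gain_node = gnode,
        gain_time = gain_time, n_losses = n_losses,
        true_min = age[gnode],
        true_max = if (gnode == root) Inf else age[parent[gnode]],
        stringsAsFactors = FALSE)
    }
    if (missing_prob > 0) {
      miss <- matrix(runif(length(pres)) < missing_prob, n_loci, ntip)
      pres[miss] <- "M"
    }
    # retain the invariant: at least one present tip per locus
    keep <- rowSums(pres == "P") > 0
    loci <- do.call(rbind, loci)[keep, , drop = FALSE]
    rownames(loci) <- NULL
    structure(list(tree = dt, loci = loci,
                   tip_presence = pres[keep, , drop = FALSE]),
              class = "ortholog_history")
  })
}

#' @export
print.ortholog_history <- function(x, ...) {
  cat("Ortholog history:", nrow(x$loci), "loci on",
      ape::Ntip(x$tree$phylo), "tips\n")
  invisible(x)
}

#' Realize per-tip genomes from an ortholog history
#'
#' Each locus gets an ancestral flank pair; tips where the locus is
#' present carry `left + EVE + right`, tips with an empty site carry
#' `left + (TA)n + right`, and missing tips omit the region entirely.
#' Regions are concatenated with random spacers into one sequence per
#' tip.  With `flank_divergence > 0` each tip's flanks decay
#' independently at that per-site rate.
#'
#' @param history an `ortholog_history`.
#' @param virus optional `ancestral_virus`; inserted sequences are then
#'   fragments of it (random sequence otherwise).
#' @param flank_len flank length, bp.
#' @param eve_len_range inserted-fragment length range, bp.
#' @param spacer_len spacer between consecutive regions, bp.
#' @param empty_ta_units (TA)n units left at empty sites.
#' @param flank_divergence per-site flank decay rate per tip.
#' @param seed RNG seed.
#' @return list with `genomes` (named character, one per tip),
#'   `locus_tables` (per tip, data.frame `locus_id`, `host_seq`,
#'   `start`, `end`, `left_flank`, `right_flank`, `true_locus`), and
#'   `history`.
#' @export
simulate_ortholog_genomes <- function(history, virus = NULL,
                                      flank_len = 500L,
                                      eve_len_range = c(600L, 1500L),
                                      spacer_len = 1500L,
                                      empty_ta_units = 12L,
                                      flank_divergence = 0,
                                      seed = NULL) {
  stopifnot(inherits(history, "ortholog_history"))
  tips <- colnames(history$tip_presence)
  loci <- rownames(history$tip_presence)
  with_seed(seed, {
    anc <- lapply(loci, function(l) {
      el <- rint(eve_len_range[1], eve_len_range[2])
      eve <- if (is.null(virus)) random_dna(el) else {
        v0 <- rint(0L, virus$length - el)
        substr(virus$sequence, v0 + 1L, v0 + el)
      }
      list(left = random_dna(flank_len), right = random_dna(flank_len),
           eve = eve)
    })
    names(anc) <- loci
    genomes <- setNames(vector("list", length(tips)), tips)
    tables <- setNames(vector("list", length(tips)), tips)
    for (tp in tips) {
      parts <- character(0)
      rows <- list()
      cursor <- 0L
      k <- 0L
      for (l in loci) {
        st <- history$tip_presence[l, tp]
        if (st == "M") next
        a <- anc[[l]]
        lf <- mutate_seq(a$left, flank_divergence)$seq
        rf <- mutate_seq(a$right, flank_divergence)$seq
        sp <- random_dna(spacer_len)
        mid <- if (st == "P") a$eve else strrep("TA", empty_ta_units)
        region <- paste0(sp, lf, mid, rf)
        if (st == "P") {
          k <- k + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            locus_id = sprintf("%s_L%02d", tp, k), host_seq = tp,
            start = cursor + spacer_len + flank_len,
            end = cursor + spacer_len + flank_len + nchar(a$eve),
            left_flank = lf, right_flank = rf, true_locus = l,
            stringsAsFactors = FALSE)
        }
        parts <- c(parts, region)
        cursor <- cursor + nchar(region)
      }
      parts <- c(parts, random_dna(spacer_len))
      genomes[[tp]] <- paste(parts, collapse = "")
      tables[[tp]] <- if (length(rows)) do.call(rbind, rows) else
        data.frame(locus_id = character(), host_seq = character(),
                   start = integer(), end = integer(),
                   left_flank = character(), right_flank = character(),
                   true_locus = character(), stringsAsFactors = FALSE)
    }
    list(genomes = unlist(genomes), locus_tables = tables,
         history = history)
  })
}

#' Write an ortholog history as TSV + Newick
#' @param history an `ortholog_history`.
#' @param dir output directory.
#' @return invisibly, named vector of written paths.
#' @export
write_ortholog_history <- function(history, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "tip_presence.tsv")
  write.table(history$tip_presence, tsv, sep = "\t", quote = FALSE,
              col.names = NA)
  loci <- file.path(dir, "loci.tsv")
  write.table(history$loci, loci, sep = "\t", quote = FALSE,
              row.names = FALSE)
  nwk <- file.path(dir, "tree.nwk")
  write_dated_tree(history$tree, nwk)
  invisible(c(presence = tsv, loci = loci, newick = nwk))
}
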