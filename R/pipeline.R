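# Pipeline orchestration: stages wired in dependency order behind a
# single flat key=value config, with pre-flight validation, a
# checksummed run manifest, and seeded reproducibility.  The
# subcommand-style entry point (inst/scripts/evepipe.R) is a thin
# wrapper over run_pipeline().

.pipeline_stages <- c("simulate", "search", "consensus", "annotate",
                      "landscape", "date")

#' Read a flat key = value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment; values that
#' parse as numbers are coerced.
#'
#' @param path config file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

validate_config <- function(config) {
  problems <- character(0)
  stages <- config$stages
  if (is.null(stages)) stages <- "simulate,search,consensus,annotate"
  stages <- trimws(strsplit(as.character(stages), ",")[[1]])
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad))
    problems <- c(problems, paste("unknown stage(s):",
                                  paste(bad, collapse = ", ")))
  if (is.null(config$outdir))
    problems <- c(problems, "outdir is required")
  stochastic <- c("simulate", "landscape")
  if (any(stages %in% stochastic) && is.null(config$seed))
    problems <- c(problems,
                  "seed is required for stochastic stages (simulate, landscape)")
  if (!"simulate" %in% stages) {
    if (any(stages %in% c("search", "consensus", "annotate", "landscape")) &&
        is.null(config$genome_fasta))
      problems <- c(problems,
                    "genome_fasta is required when simulate is not run")
    if ("search" %in% stages && is.null(config$probe_fasta))
      problems <- c(problems,
                    "probe_fasta is required when simulate is not run")
  }
  if ("date" %in% stages) {
    if (is.null(config$tree_newick))
      problems <- c(problems, "tree_newick is required for the date stage")
    if (!"simulate" %in% stages && is.null(config$presence_tsv))
      problems <- c(problems,
                    "presence_tsv is required for the date stage without simulate")
  }
  for (p in c("genome_fasta", "probe_fasta", "tree_newick",
              "presence_tsv", "reads_fasta")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]]))
      problems <- c(problems, paste("missing input file:", config[[p]]))
  }
  list(stages = stages, problems = problems)
}

cfg <- function(config, key, default) {
  v <- config[[key]]
  if (is.null(v)) default else v
}

#' Run the EVE discovery/reconstruction/dating pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate -> search -> consensus -> annotate -> landscape -> date).
#' Pre-flight validation fails before any stage runs, listing every
#' gap.  All outputs are written under `outdir` and checksummed into a
#' manifest (`manifest.json`) that is bit-identical across reruns of
#' the same config.
#'
#' @param config named list or path to a key = value config file.
#'   Recognized keys include `stages` (comma-separated), `outdir`,
#'   `seed`, input paths (`genome_fasta`, `probe_fasta`,
#'   `tree_newick`, `presence_tsv`, `reads_fasta`) and stage parameter
#'   overrides (`n_insertions`, `host_size`, `substitution_rate`,
#'   `ta_bias`, `join_distance`, `cutoff`, `max_divergence`,
#'   `n_random`, ...).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  v <- validate_config(config)
  if (length(v$problems))
    stop("pre-flight validation failed:\n  ",
         paste(v$problems, collapse = "\n  "), call. = FALSE)
  stages <- .pipeline_stages[.pipeline_stages %in% v$stages]
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else NULL
  files <- character(0)
  stage_params <- list()
  state <- list()

  note <- function(...) message("[paleovir] ", ...)
  t_all <- proc.time()[3]

  for (st in stages) {
    t0 <- proc.time()[3]
    note("stage ", st, " ...")
    if (st == "simulate") {
      virus <- simulate_ancestral_virus(seed = seed)
      truth <- simulate_endogenization(
        virus,
        n_host_seqs = cfg(config, "n_host_seqs", 2L),
        host_size = cfg(config, "host_size", 60000L),
        n_insertions = cfg(config, "n_insertions", 18L),
        substitution_rate = cfg(config, "substitution_rate", 0.03),
        indel_rate = cfg(config, "indel_rate", 0.001),
        ta_bias = cfg(config, "ta_bias", 0.3),
        seed = seed + 1L)
      paths <- write_truth(truth, outdir)
      write_fasta(setNames(virus$sequence, "ancestral_virus"),
                  file.path(outdir, "ancestral_virus.fasta"))
      files <- c(files, paths,
                 file.path(outdir, "ancestral_virus.fasta"))
      state$virus <- virus
      state$truth <- truth
      state$genome <- truth$host_sequences
      stage_params$simulate <- truth$params
    } else if (st == "search") {
      if (is.null(state$genome))
        state$genome <- read_fasta(config$genome_fasta)
      if (!is.null(state$virus)) {
        pr <- domain_probes(state$virus, c("AP", "RT", "RH1"))
        probe <- paste(pr, collapse = "")
        probe_id <- "AP-RT-RH1"
      } else {
        pf <- read_fasta(config$probe_fasta)
        probe <- pf[[1]]
        probe_id <- names(pf)[1]
      }
      hits <- translated_search(state$genome, probe,
                                probe_id = probe_id,
                                min_score = cfg(config, "min_score", 100))
      loci <- merge_hits(hits, cfg(config, "join_distance", 1000L))
      hp <- file.path(outdir, "hits.tsv")
      write.table(hits, hp, sep = "\t", quote = FALSE, row.names = FALSE)
      lp <- file.path(outdir, "loci.bed")
      write_loci_bed(loci, lp)
      files <- c(files, hp, lp)
      state$loci <- loci
      stage_params$search <- list(probe_id = probe_id,
                                  join_distance = cfg(config,
                                                      "join_distance",
                                                      1000L))
    } else if (st == "consensus") {
      if (is.null(state$loci))
        stop("consensus stage needs search results", call. = FALSE)
      frags <- recruit_and_orient(state$loci, state$genome,
                                  min_fragment_len =
                                    cfg(config, "min_fragment_len", 200L))
      cons <- build_consensus(frags)
      motif <- if (!is.null(state$virus)) state$virus$origin_motif
               else cfg(config, "origin_motif", "TGGTATCAGAGC")
      cons <- rotate_to_origin(cons, motif)
      cp <- file.path(outdir, "consensus.fasta")
      sp <- file.path(outdir, "consensus_stats.tsv")
      write_consensus(cons, cp, sp)
      files <- c(files, cp, sp)
      state$consensus <- cons
    } else if (st == "annotate") {
      if (is.null(state$consensus))
        stop("annotate stage needs a consensus", call. = FALSE)
      orfs <- find_orfs(state$consensus$sequence, circular = TRUE)
      doms <- if (!is.null(state$virus))
        annotate_domains(state$consensus, domain_probes(state$virus))
      else data.frame()
      cls <- classify_component(doms)
      op <- file.path(outdir, "orfs.tsv")
      dp <- file.path(outdir, "domains.tsv")
      write.table(orfs, op, sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(doms, dp, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, op, dp)
      state$domains <- doms
      stage_params$annotate <- list(component = cls$value)
    } else if (st == "landscape") {
      if (is.null(state$consensus) || is.null(state$genome))
        stop("landscape stage needs genome and consensus", call. = FALSE)
      mask <- nucleotide_mask(state$genome,
                              setNames(state$consensus$sequence, "cons"),
                              cutoff = cfg(config, "cutoff", 250),
                              max_divergence = cfg(config,
                                                   "max_divergence", 20))
      occ <- genome_occupancy(mask, sum(nchar(state$genome)))
      tas <- find_ta_repeats(state$genome)
      enr <- tryCatch(
        ta_enrichment(merge_hits(mask, 20L), tas, state$genome,
                      R = cfg(config, "n_random", 99L),
                      seed = seed + 2L),
        error = function(e) NULL)
      lp <- file.path(outdir, "landscape.tsv")
      df <- data.frame(
        metric = c("occupancy_bp", "occupancy_fraction", "n_ta_repeats",
                   "ta_proximal_fraction", "ta_empirical_p"),
        value = c(occ$bp, occ$fraction, nrow(tas),
                  if (is.null(enr)) NA else enr$observed_proximal_fraction,
                  if (is.null(enr)) NA else enr$empirical_p))
      write.table(df, lp, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, lp)
      stage_params$landscape <- list(cutoff = cfg(config, "cutoff", 250))
    } else if (st == "date") {
      tree <- parse_dated_tree(config$tree_newick)
      pam <- as.matrix(read.table(config$presence_tsv, sep = "\t",
                                  header = TRUE, row.names = 1,
                                  check.names = FALSE))
      dated <- date_insertions(tree, pam)
      dp <- file.path(outdir, "insertion_ages.tsv")
      write.table(dated, dp, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files <- c(files, dp)
    }
    note("stage ", st, " done in ",
         sprintf("%.1f", proc.time()[3] - t0), " s")
  }

  manifest <- list(
    package = "paleovir",
    version = as.character(utils::packageVersion("paleovir")),
    stages = stages,
    seed = seed,
    parameters = stage_params,
    config = config[order(names(config))],
    files = lapply(setNames(nm = basename(unname(files))), function(f)
      unname(tools::md5sum(file.path(outdir, f))))
  )
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  note("pipeline finished in ",
       sprintf("%.1f", proc.time()[3] - t_all), " s")
  invisible(manifest)
}
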