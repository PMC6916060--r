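# Pipeline orchestration: simulate -> mine -> classify -> gainloss ->
# stats, with a validated flat config, per-stage seeding derived from one
# master seed, stage-resume markers and a checksum manifest.

.CONFIG_DEFAULTS <- list(
  mode = "synthetic",            # or "user"
  seed = 1L,
  # simulation
  ancestral_family_count = 830L,
  beta = 0.003, delta = 0.003,
  contig_count = 30L, contig_length = 30000L, gc_fraction = 0.42,
  decoy_gpcr_count = 8L,
  pseudogenization_fraction = 0.30, truncation_fraction = 0.05,
  mut_rate = 5e-4,
  marine_beta = 4e-4, marine_delta = 0.017, marine_override = FALSE,
  # mining (study-standard thresholds)
  evalue1 = 1e-10, evalue2 = 1e-20,
  min_aa = 250L, tm_gap_max = 5L, nterm_min = 21L, nterm_max = 34L,
  trunc_dist = 30L, identity_ceiling = 0.5,
  # classification
  mcl_inflation = 1.5, sim_threshold = 0.4,
  bootstrap = 1000L, support_floor = 70L, class_support = 90L,
  # user-data mode inputs
  genomes_dir = NA_character_, tree_file = NA_character_,
  queries_fasta = NA_character_, tm_tsv = NA_character_,
  outgroups_fasta = NA_character_, habitats_tsv = NA_character_)

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a flat named list; fills defaults (the
#' study-standard thresholds: 250 aa minimum length, 5 aa TM gap, 21-34 aa
#' N-terminus, 30 bp contig-end rule, E-values 1e-10 / 1e-20, bootstrap
#' 1000, singleton support floor 70), rejects unknown keys and reports
#' type mismatches itemized.
#'
#' @param config path to a YAML file, a named list, or NULL (defaults)
#' @return normalized named list
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (file.exists(config)) yaml::read_yaml(config) else
      stop("config file not found: ", config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  out <- .CONFIG_DEFAULTS
  errors <- character(0)
  for (k in names(config)) {
    v <- config[[k]]
    tmpl <- .CONFIG_DEFAULTS[[k]]
    if (is.numeric(tmpl)) {
      vn <- suppressWarnings(as.numeric(v))
      if (length(vn) != 1L || is.na(vn)) {
        errors <- c(errors, sprintf("%s: expected a number, got '%s'", k,
                                    paste(v, collapse = ",")))
        next
      }
      out[[k]] <- if (is.integer(tmpl)) as.integer(round(vn)) else vn
    } else if (is.logical(tmpl)) {
      vl <- as.logical(v)
      if (length(vl) != 1L || is.na(vl)) {
        errors <- c(errors, sprintf("%s: expected TRUE/FALSE", k))
        next
      }
      out[[k]] <- vl
    } else {
      out[[k]] <- as.character(v)
    }
  }
  if (length(errors)) {
    stop("config validation failed:\n  ", paste(errors, collapse = "\n  "))
  }
  if (!out$mode %in% c("synthetic", "user")) {
    stop("mode must be 'synthetic' or 'user'")
  }
  out
}

stage_done <- function(dir) file.exists(file.path(dir, ".done"))
mark_done <- function(dir) {
  writeLines(format(Sys.time()), file.path(dir, ".done"))
}

#' Run the full pipeline
#'
#' Synthetic mode generates ground-truthed genomes first; user mode takes
#' genome FASTAs, a reference set and a dated tree from the config. Each
#' stage writes its outputs into its own subdirectory of `out_dir`; a
#' manifest with the config, derived seeds and md5 checksums of every
#' output file is written last. With `resume = TRUE`, stages whose
#' `.done` marker exists are skipped and their outputs re-read, so deleted
#' downstream outputs are regenerated identically.
#'
#' @param config config list / YAML path (see [validate_config()])
#' @param out_dir run directory
#' @param resume skip completed stages (default FALSE)
#' @return the manifest list, invisibly
#' @export
run_pipeline <- function(config = NULL, out_dir, resume = FALSE) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_dirs <- file.path(out_dir, c("01_simulate", "02_mine",
                                     "03_classify", "04_gainloss",
                                     "05_stats"))
  names(stage_dirs) <- c("simulate", "mine", "classify", "gainloss",
                         "stats")
  timings <- list()

  # ---- stage 1: inputs -----------------------------------------------------
  t0 <- Sys.time()
  d1 <- stage_dirs["simulate"]
  if (cfg$mode == "synthetic") {
    if (!(resume && stage_done(d1))) {
      dir.create(d1, showWarnings = FALSE)
      tree <- if (!is.na(cfg$tree_file)) read_dated_tree(cfg$tree_file) else
        mammal_like_tree()
      overrides <- if (cfg$marine_override) {
        hab <- if (!is.na(cfg$habitats_tsv)) read_tsv(cfg$habitats_tsv) else
          mammal_habitats()
        marine_rate_overrides(hab, cfg$marine_beta, cfg$marine_delta)
      } else NULL
      sc <- sim_config(tree = tree,
                       ancestral_family_count = cfg$ancestral_family_count,
                       beta = cfg$beta, delta = cfg$delta,
                       rate_overrides = overrides,
                       contig_count = cfg$contig_count,
                       contig_length = cfg$contig_length,
                       gc_fraction = cfg$gc_fraction,
                       decoy_gpcr_count = cfg$decoy_gpcr_count,
                       pseudogenization_fraction =
                         cfg$pseudogenization_fraction,
                       truncation_fraction = cfg$truncation_fraction,
                       mut_rate = cfg$mut_rate, seed = cfg$seed)
      simulate_dataset(sc, out_dir = d1)
      mark_done(d1)
    }
    tree <- read_dated_tree(file.path(d1, "species_tree.nwk"))
    refset <- read_reference_set(file.path(d1, "or_references.fa"),
                                 file.path(d1, "or_references_tm.tsv"))
    # class labels of the synthetic references are reconstructible from
    # the config seed
    proto <- make_or_prototypes(cfg$ancestral_family_count,
                                seed = derive_seed(cfg$seed, "prototypes"))
    refset$class <- proto$class
    outgroups <- Biostrings::readAAStringSet(
      file.path(d1, "decoy_gpcrs.fa"))
    genome_files <- file.path(d1, paste0(tree$phylo$tip.label, ".fa"))
    habitats <- if (!is.na(cfg$habitats_tsv)) read_tsv(cfg$habitats_tsv) else
      mammal_habitats()
  } else {
    if (is.na(cfg$genomes_dir)) stop("stage mine: genomes_dir not set")
    if (is.na(cfg$queries_fasta) || is.na(cfg$tm_tsv)) {
      stop("stage mine: queries_fasta / tm_tsv not set")
    }
    if (is.na(cfg$tree_file)) {
      stop("stage gainloss preflight: tree_file not set")
    }
    tree <- read_dated_tree(cfg$tree_file)
    refset <- read_reference_set(cfg$queries_fasta, cfg$tm_tsv)
    outgroups <- if (!is.na(cfg$outgroups_fasta)) {
      Biostrings::readAAStringSet(cfg$outgroups_fasta)
    } else Biostrings::AAStringSet()
    genome_files <- list.files(cfg$genomes_dir, pattern = "\\.fa$",
                               full.names = TRUE)
    habitats <- if (!is.na(cfg$habitats_tsv)) read_tsv(cfg$habitats_tsv)
      else NULL
  }
  timings$simulate <- as.numeric(Sys.time() - t0, units = "secs")

  # ---- stage 2: mine -------------------------------------------------------
  t0 <- Sys.time()
  d2 <- stage_dirs["mine"]
  if (!(resume && stage_done(d2))) {
    dir.create(d2, showWarnings = FALSE)
    all_calls <- list()
    for (gf in genome_files) {
      sp <- sub("\\.fa$", "", basename(gf))
      genome <- Biostrings::readDNAStringSet(gf)
      res <- mine_genome(genome, refset, outgroups, species = sp,
                         evalue1 = cfg$evalue1, evalue2 = cfg$evalue2,
                         min_aa = cfg$min_aa, tm_gap_max = cfg$tm_gap_max,
                         nterm_min = cfg$nterm_min,
                         nterm_max = cfg$nterm_max,
                         trunc_dist = cfg$trunc_dist,
                         identity_ceiling = cfg$identity_ceiling)
      all_calls[[sp]] <- res$calls
    }
    calls <- do.call(rbind, all_calls)
    rownames(calls) <- NULL
    write_tsv(calls, file.path(d2, "gene_calls.tsv"))
    mark_done(d2)
  }
  calls <- read_tsv(file.path(d2, "gene_calls.tsv"))
  timings$mine <- as.numeric(Sys.time() - t0, units = "secs")

  # ---- stage 3: classify ---------------------------------------------------
  t0 <- Sys.time()
  d3 <- stage_dirs["classify"]
  if (!(resume && stage_done(d3))) {
    dir.create(d3, showWarnings = FALSE)
    cls <- classify_repertoire(calls, refset, outgroups,
                               inflation = cfg$mcl_inflation,
                               sim_threshold = cfg$sim_threshold,
                               support_floor = cfg$support_floor,
                               replicates = cfg$bootstrap,
                               seed = derive_seed(cfg$seed, "classify"))
    write_tsv(cls$ogg_table, file.path(d3, "ogg_table.tsv"))
    mark_done(d3)
  }
  ogg_table <- read_tsv(file.path(d3, "ogg_table.tsv"))
  timings$classify <- as.numeric(Sys.time() - t0, units = "secs")

  # ---- stage 4: gain/loss --------------------------------------------------
  t0 <- Sys.time()
  d4 <- stage_dirs["gainloss"]
  if (!(resume && stage_done(d4))) {
    dir.create(d4, showWarnings = FALSE)
    species <- tree$phylo$tip.label
    counts <- ogg_count_matrix(ogg_table, species)
    content <- reconstruct_ancestral(counts, tree)
    events <- count_branch_events(content, tree)
    rates <- estimate_rates(events)
    write_tsv(as.data.frame(content), file.path(d4, "content.tsv"))
    write_tsv(events, file.path(d4, "events.tsv"))
    write_tsv(rates, file.path(d4, "rates.tsv"))
    if (!is.null(habitats)) {
      write_tsv(summarize_rates(rates, habitats),
                file.path(d4, "rate_summary.tsv"))
    }
    write_tsv(ogg_event_totals(content, tree),
              file.path(d4, "ogg_event_totals.tsv"))
    mark_done(d4)
  }
  rates <- read_tsv(file.path(d4, "rates.tsv"))
  timings$gainloss <- as.numeric(Sys.time() - t0, units = "secs")

  # ---- stage 5: stats ------------------------------------------------------
  t0 <- Sys.time()
  d5 <- stage_dirs["stats"]
  if (!(resume && stage_done(d5))) {
    dir.create(d5, showWarnings = FALSE)
    summ <- repertoire_summary(calls, ogg_table, habitats)
    write_tsv(summ, file.path(d5, "species_summary.tsv"))
    tests <- list()
    if (!is.null(habitats) &&
        all(c("marine", "terrestrial") %in% summ$habitat)) {
      mw <- mann_whitney(summ$intact[summ$habitat == "marine"],
                         summ$intact[summ$habitat == "terrestrial"])
      tests[[1]] <- data.frame(test = "intact_marine_vs_terrestrial",
                               statistic = mw$U, p = mw$p,
                               n = sum(summ$habitat %in%
                                         c("marine", "terrestrial")))
    }
    if (nrow(summ) >= 3 && stats::sd(summ$intact) > 0 &&
        stats::sd(summ$pseudogene) > 0) {
      pc <- pearson(summ$intact, summ$pseudogene)
      tests[[length(tests) + 1]] <-
        data.frame(test = "pseudogene_vs_intact_r", statistic = pc$r,
                   p = pc$p, n = pc$n)
    }
    if (length(tests)) {
      write_tsv(do.call(rbind, tests), file.path(d5, "tests.tsv"))
    }
    mark_done(d5)
  }
  timings$stats <- as.numeric(Sys.time() - t0, units = "secs")

  # ---- manifest ------------------------------------------------------------
  cfg_file <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(cfg, cfg_file)
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  sums <- tools::md5sum(files)
  names(sums) <- sub(paste0("^", out_dir, "/?"), "", names(sums))
  manifest <- list(config_hash = unname(tools::md5sum(cfg_file)),
                   seed = cfg$seed,
                   stage_seconds = timings,
                   checksums = as.list(sums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
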