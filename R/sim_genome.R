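# Emission of synthetic genome assemblies with planted OR genes.
#
# Every surviving gene of the family simulation is planted as an intronless
# ORF (ATG ... stop) on a random contig and strand, mutated away from its
# OGG root coding sequence in proportion to the species' root-to-tip path
# length (uniform Jukes-Cantor-style substitutions, no indels in intact
# genes). Designated fractions are converted to pseudogenes (internal stop
# or 1-2 bp frameshift) or truncated genes (disruption-free ORF cut by a
# contig end, ending within 30 bp of the boundary). Decoy non-OR GPCRs are
# planted alongside. Intergenic flanks are random DNA at the configured GC.

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

translate_codons <- function(chars) {
  n <- length(chars) %/% 3L
  codons <- vapply(seq_len(n), function(i) {
    paste(chars[(3L * i - 2L):(3L * i)], collapse = "")
  }, character(1))
  unname(Biostrings::GENETIC_CODE[codons])
}

# Substitute positions of an intact CDS at per-site probability p, keeping
# the start codon, the terminal stop and intactness (codons mutating into a
# premature stop are reverted to the ancestral codon).
mutate_cds <- function(chars, p) {
  n <- length(chars)
  eligible <- seq.int(4L, n - 3L)
  nmut <- stats::rbinom(1L, length(eligible), p)
  if (nmut == 0L) return(chars)
  pos <- sample(eligible, nmut)
  orig <- chars
  for (i in pos) chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  aa <- translate_codons(chars[seq_len(n - 3L)])
  bad <- which(aa == "*")
  for (b in bad) {
    idx <- (3L * b - 2L):(3L * b)
    chars[idx] <- orig[idx]
  }
  chars
}

# does any forward frame contain an ATG..stop ORF translating to >=
# min_aa residues? (used to guarantee planted pseudogenes can never
# satisfy the intactness definition)
has_long_orf <- function(chars, min_aa = 250L) {
  s <- paste(chars, collapse = "")
  n <- nchar(s)
  for (off in 0:2) {
    n_cod <- (n - off) %/% 3L
    if (n_cod < min_aa + 1L) next
    starts <- off + 3L * (seq_len(n_cod) - 1L) + 1L
    cods <- substring(s, starts, starts + 2L)
    stop_at <- which(cods %in% STOP_CODONS)
    atg_at <- which(cods == "ATG")
    if (!length(atg_at)) next
    bounds <- c(0L, stop_at, n_cod + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      seg_atg <- atg_at[atg_at > bounds[b] & atg_at < bounds[b + 1L]]
      if (!length(seg_atg)) next
      # ORF length from first ATG to the closing stop; an open-ended
      # segment could keep extending into flanking sequence, so use a
      # safety margin there
      lim <- if (b + 1L == length(bounds)) min_aa - 60L else min_aa
      if (bounds[b + 1L] - min(seg_atg) >= lim) return(TRUE)
    }
  }
  FALSE
}

disrupt_cds_once <- function(chars) {
  n_codon <- length(chars) %/% 3L
  if (stats::runif(1L) < 0.5) {
    # nonsense mutation well inside the coding region
    codon <- sample(seq.int(10L, n_codon - 10L), 1L)
    stop_codon <- strsplit(sample(c("TAA", "TAG", "TGA"), 1L), "")[[1]]
    chars[(3L * codon - 2L):(3L * codon)] <- stop_codon
    list(chars = chars, kind = "nonsense")
  } else {
    # 1-2 bp frameshift indel inside the coding region
    at <- sample(seq.int(31L, length(chars) - 31L), 1L)
    if (stats::runif(1L) < 0.5) {
      chars <- chars[-at]
    } else {
      ins <- random_dna(sample(1:2, 1L), 0.5)
      chars <- append(chars, ins, after = at)
    }
    list(chars = chars, kind = "frameshift")
  }
}

# disrupt, redrawing until no frame retains an intact-length ORF
disrupt_cds <- function(chars, min_aa = 250L, max_tries = 50L) {
  for (k in seq_len(max_tries)) {
    res <- disrupt_cds_once(chars)
    if (!has_long_orf(res$chars, min_aa)) return(res)
  }
  # fall back to an early guaranteed-disruptive stop
  stop_codon <- strsplit(sample(c("TAA", "TAG", "TGA"), 1L), "")[[1]]
  chars[28:30] <- stop_codon
  list(chars = chars, kind = "nonsense")
}

#' Emit synthetic genome assemblies with a ground-truth table
#'
#' @param content integer matrix species x OGGs of surviving intact-gene
#'   counts, as from [tip_content()]
#' @param config the `sim_config` used for the family simulation
#' @param refset OR reference prototypes (`or_reference_set`); generated
#'   from the config seed when omitted. Column count must match `content`.
#' @param decoys AAStringSet of decoy GPCR prototypes; generated when
#'   omitted
#' @param out_dir optional directory; when given, one FASTA per species,
#'   `truth.tsv` (1-based inclusive coordinates) and the reference set are
#'   written there
#' @return list with `genomes` (named list of DNAStringSet), `truth`
#'   (data frame: species, gene_id, ogg_id, status, class, contig, start,
#'   end, strand; coordinates 0-based half-open), `refset`, `decoys`
#' @export
emit_genomes <- function(content, config, refset = NULL, decoys = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_ogg <- ncol(content)
  if (is.null(refset)) {
    refset <- make_or_prototypes(n_ogg,
                                 seed = derive_seed(config$seed, "prototypes"))
  }
  stopifnot(length(refset$proteins) == n_ogg)
  if (is.null(decoys)) {
    decoys <- make_decoy_gpcrs(max(1L, config$decoy_gpcr_count),
                               seed = derive_seed(config$seed, "decoys"))
  }

  ogg_ids <- colnames(content)
  # fixed root CDS per OGG (and per decoy prototype)
  root_cds <- with_seed(derive_seed(config$seed, "root_cds"), {
    lapply(seq_len(n_ogg), function(k) {
      strsplit(reverse_translate(refset$proteins[[k]]), "")[[1]]
    })
  })
  decoy_cds <- with_seed(derive_seed(config$seed, "decoy_cds"), {
    lapply(seq_along(decoys), function(k) {
      strsplit(reverse_translate(decoys[[k]]), "")[[1]]
    })
  })

  ages <- config$tree$ages
  root_age <- max(ages)
  species_list <- rownames(content)
  genomes <- list()
  truth_rows <- list()

  for (sp in species_list) {
    res <- with_seed(derive_seed(config$seed, paste0("genome/", sp)), {
      emit_one_genome(sp, content[sp, ], config, refset, root_cds,
                      decoys, decoy_cds, path_my = root_age, ogg_ids)
    })
    genomes[[sp]] <- res$contigs
    truth_rows[[sp]] <- res$truth
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sp in species_list) {
      Biostrings::writeXStringSet(genomes[[sp]],
                                  file.path(out_dir, paste0(sp, ".fa")))
    }
    out <- truth
    out$start <- out$start + 1L  # 1-based inclusive in written reports
    write_tsv(out, file.path(out_dir, "truth.tsv"))
    write_reference_set(refset, file.path(out_dir, "or_references.fa"),
                        file.path(out_dir, "or_references_tm.tsv"))
    Biostrings::writeXStringSet(decoys, file.path(out_dir, "decoy_gpcrs.fa"))
  }
  list(genomes = genomes, truth = truth, refset = refset, decoys = decoys)
}

# build one species' contigs; runs inside that species' RNG substream
emit_one_genome <- function(sp, counts, config, refset, root_cds,
                            decoys, decoy_cds, path_my, ogg_ids) {
  p_sub <- config$mut_rate * path_my
  genes <- list()
  gi <- 0L
  for (k in which(counts > 0L)) {
    for (j in seq_len(counts[k])) {
      gi <- gi + 1L
      genes[[gi]] <- list(ogg = ogg_ids[k],
                          class = unname(refset$class[k]),
                          chars = mutate_cds(root_cds[[k]], p_sub))
    }
  }
  n <- length(genes)
  statuses <- character(n)
  if (n > 0L) {
    n_pseudo <- round(config$pseudogenization_fraction * n)
    n_trunc <- round(config$truncation_fraction * n)
    statuses <- rep("intact", n)
    pick <- sample.int(n, n_pseudo + n_trunc)
    statuses[pick[seq_len(n_pseudo)]] <- "pseudogene"
    if (n_trunc > 0L) statuses[pick[n_pseudo + seq_len(n_trunc)]] <- "truncated"
  }

  planted <- list()
  pi <- 0L
  for (i in seq_len(n)) {
    g <- genes[[i]]
    chars <- g$chars
    status <- statuses[i]
    if (status == "pseudogene") {
      chars <- disrupt_cds(chars)$chars
    } else if (status == "truncated") {
      keep <- floor(stats::runif(1L, 0.45, 0.85) * (length(chars) %/% 3L))
      chars <- chars[seq_len(3L * keep)]
    }
    pi <- pi + 1L
    planted[[pi]] <- list(id = sprintf("%s_g%04d", sp, i), ogg = g$ogg,
                          class = g$class, status = status,
                          seq = paste(chars, collapse = ""),
                          strand = sample(c("+", "-"), 1L))
  }
  # decoys, always intact-like ORFs
  for (d in seq_len(config$decoy_gpcr_count)) {
    k <- ((d - 1L) %% length(decoy_cds)) + 1L
    chars <- mutate_cds(decoy_cds[[k]], p_sub)
    pi <- pi + 1L
    planted[[pi]] <- list(id = sprintf("%s_decoy%02d", sp, d),
                          ogg = names(decoys)[k], class = "nonOR",
                          status = "decoy",
                          seq = paste(chars, collapse = ""),
                          strand = sample(c("+", "-"), 1L))
  }

  is_trunc <- vapply(planted, function(x) x$status == "truncated", logical(1))
  n_contig <- max(config$contig_count, sum(is_trunc) + 1L)
  contig_parts <- rep(list(list()), n_contig)      # interior genes
  end_gene <- rep(list(NULL), n_contig)            # truncated gene per contig

  trunc_contigs <- if (any(is_trunc)) sample.int(n_contig, sum(is_trunc))
                   else integer(0)
  ti <- 0L
  interior <- which(!is_trunc)
  assign_contig <- if (length(interior)) {
    sample(rep_len(seq_len(n_contig), length(interior)))
  } else integer(0)
  for (j in seq_along(interior)) {
    i <- interior[j]
    contig_parts[[assign_contig[j]]] <-
      c(contig_parts[[assign_contig[j]]], planted[i])
  }
  for (i in which(is_trunc)) {
    ti <- ti + 1L
    end_gene[[trunc_contigs[ti]]] <- planted[[i]]
  }

  gc <- config$gc_fraction
  contigs <- character(n_contig)
  truth <- list()
  tri <- 0L
  for (c_idx in seq_len(n_contig)) {
    cname <- sprintf("%s_contig%03d", sp, c_idx)
    parts <- character(0)
    pos <- 0L
    tg <- end_gene[[c_idx]]
    # a minus-strand truncated gene is cut by the contig *start*
    lead_trunc <- !is.null(tg) && tg$strand == "-"
    if (lead_trunc) {
      d <- sample(0:20, 1L)
      lead <- paste(random_dna(d, gc), collapse = "")
      seq_fwd <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(tg$seq)))
      parts <- c(lead, seq_fwd)
      tri <- tri + 1L
      truth[[tri]] <- data.frame(species = sp, gene_id = tg$id,
                                 ogg_id = tg$ogg, status = tg$status,
                                 class = tg$class, contig = cname,
                                 start = d, end = d + nchar(seq_fwd),
                                 strand = "-", stringsAsFactors = FALSE)
      pos <- d + nchar(seq_fwd)
    }
    for (g in contig_parts[[c_idx]]) {
      flank <- paste(random_dna(sample(400:1500, 1L), gc), collapse = "")
      parts <- c(parts, flank)
      pos <- pos + nchar(flank)
      seq_fwd <- if (g$strand == "+") g$seq else {
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(g$seq)))
      }
      parts <- c(parts, seq_fwd)
      tri <- tri + 1L
      truth[[tri]] <- data.frame(species = sp, gene_id = g$id,
                                 ogg_id = g$ogg, status = g$status,
                                 class = g$class, contig = cname,
                                 start = pos, end = pos + nchar(seq_fwd),
                                 strand = g$strand, stringsAsFactors = FALSE)
      pos <- pos + nchar(seq_fwd)
    }
    if (!is.null(tg) && !lead_trunc) {
      flank <- paste(random_dna(sample(400:1500, 1L), gc), collapse = "")
      parts <- c(parts, flank)
      pos <- pos + nchar(flank)
      parts <- c(parts, tg$seq)
      tri <- tri + 1L
      truth[[tri]] <- data.frame(species = sp, gene_id = tg$id,
                                 ogg_id = tg$ogg, status = tg$status,
                                 class = tg$class, contig = cname,
                                 start = pos, end = pos + nchar(tg$seq),
                                 strand = "+", stringsAsFactors = FALSE)
      pos <- pos + nchar(tg$seq)
      d <- sample(0:20, 1L)
      parts <- c(parts, paste(random_dna(d, gc), collapse = ""))
    } else {
      pad <- max(0L, config$contig_length - pos)
      pad <- min(pad, 4000L)
      parts <- c(parts, paste(random_dna(max(pad, 300L), gc), collapse = ""))
    }
    contigs[c_idx] <- paste(parts, collapse = "")
  }
  names(contigs) <- sprintf("%s_contig%03d", sp, seq_len(n_contig))
  list(contigs = Biostrings::DNAStringSet(contigs),
       truth = if (tri > 0L) do.call(rbind, truth) else
         data.frame(species = character(0), gene_id = character(0),
                    ogg_id = character(0), status = character(0),
                    class = character(0), contig = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0), stringsAsFactors = FALSE))
}

#' Run the full synthetic-data stage
#'
#' Convenience wrapper: simulates family evolution, emits genomes and
#' returns everything downstream stages need.
#'
#' @param config a `sim_config`
#' @param out_dir optional output directory (FASTA per species, truth.tsv,
#'   references, tree Newick)
#' @return list(sim, genomes, truth, refset, decoys, config)
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  sim <- simulate_family_evolution(config)
  emitted <- emit_genomes(tip_content(sim, config), config,
                          out_dir = out_dir)
  if (!is.null(out_dir)) {
    write_dated_tree(config$tree, file.path(out_dir, "species_tree.nwk"))
    write_tsv(sim$events, file.path(out_dir, "true_events.tsv"))
  }
  c(list(sim = sim, config = config), emitted)
}
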