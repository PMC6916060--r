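# OR gene mining from a genome assembly.
#
# First pass: translated search with a dereplicated OR reference set,
# collapse to best regions, extend each to the longest in-frame ORF
# (ATG..stop), apply the intactness filters (>= 250 aa, no TM segment with
# an alignment gap > 5 aa, N-terminus of 21-34 aa before TM1) and confirm
# OR identity against non-OR GPCR outgroups. Second pass: translated
# search with the species' own intact genes at a stricter E-value; regions
# not overlapping intact calls are classified as pseudogenes (internal
# stop or frameshift) or truncated genes (disruption-free, ending within
# 30 bp of a contig end).

#' Dereplicate protein queries by pairwise identity
#'
#' Greedy longest-first selection: proteins are visited in decreasing
#' length order (ties broken by id) and retained unless they share at
#' least `identity_ceiling` global-alignment identity with an already
#' retained protein.
#'
#' @param proteins AAStringSet
#' @param identity_ceiling retention requires identity strictly below this
#'   fraction (default 0.5)
#' @return AAStringSet subset
#' @export
dereplicate_queries <- function(proteins, identity_ceiling = 0.5) {
  if (!length(proteins)) return(proteins)
  ord <- order(-Biostrings::nchar(proteins), names(proteins))
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (protein_identity(proteins[[i]], proteins[[j]]) >=
          identity_ceiling) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  proteins[sort(kept)]
}

# in-frame codon vector of a strand sequence for a given frame offset
frame_codons <- function(src_str, off, L) {
  n <- (L - off) %/% 3L
  starts <- off + 3L * (seq_len(n) - 1L) + 1L
  substring(src_str, starts, starts + 2L)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Extend a hit to the longest in-frame open reading frame
#'
#' Walks in-frame from the hit: upstream to the first in-frame stop
#' (collecting every ATG beyond which extension is uninterrupted) and
#' downstream to the first stop codon. Returns the ATG options, the stop,
#' and whether the frame runs off the contig end without a stop.
#'
#' @param hit one row of a [translated_search()] hit table
#' @param genome DNAStringSet of contigs
#' @param min_aa minimum translated length of the longest ORF (default
#'   250); shorter candidates are rejected (`ok = FALSE`)
#' @return list(ok, reason, contig, strand, frame, atg_ci (0-based codon
#'   indices, ascending = farthest upstream first), stop_ci, off_end,
#'   codons, L)
#' @export
extend_to_orf <- function(hit, genome, min_aa = 250L) {
  contig <- genome[[hit$contig]]
  L <- length(contig)
  src <- if (hit$strand == "+") contig else
    Biostrings::reverseComplement(contig)
  s <- if (hit$strand == "+") hit$start else L - hit$end
  off <- s %% 3L
  codons <- frame_codons(as.character(src), off, L)
  start_ci <- (s - off) %/% 3L          # 0-based codon index of hit start
  n_cod <- length(codons)

  # downstream: first stop at or after the hit start
  down <- which(codons[(start_ci + 1L):n_cod] %in% STOP_CODONS)
  off_end <- !length(down)
  stop_ci <- if (off_end) NA_integer_ else start_ci + down[1] - 1L

  # upstream: ATGs until the first in-frame stop
  atg_ci <- integer(0)
  j <- start_ci
  while (j >= 0L) {
    cod <- codons[j + 1L]
    if (cod %in% STOP_CODONS) break
    if (cod == "ATG") atg_ci <- c(j, atg_ci)
    j <- j - 1L
  }
  # ATGs inside the hit/ORF (downstream of hit start, before the stop)
  if (!off_end && stop_ci > start_ci + 1L) {
    rng <- (start_ci + 2L):(stop_ci)
    atg_ci <- c(atg_ci, start_ci + which(codons[rng] == "ATG") + 1L - 1L)
  }
  atg_ci <- sort(unique(atg_ci))

  if (off_end) {
    return(list(ok = FALSE, reason = "runs_off_contig", contig = hit$contig,
                strand = hit$strand, frame = off, atg_ci = atg_ci,
                stop_ci = NA_integer_, off_end = TRUE, codons = codons,
                L = L))
  }
  if (!length(atg_ci)) {
    return(list(ok = FALSE, reason = "no_start_codon", contig = hit$contig,
                strand = hit$strand, frame = off, atg_ci = atg_ci,
                stop_ci = stop_ci, off_end = FALSE, codons = codons, L = L))
  }
  longest_aa <- stop_ci - atg_ci[1]
  if (longest_aa < min_aa) {
    return(list(ok = FALSE, reason = "below_min_length", contig = hit$contig,
                strand = hit$strand, frame = off, atg_ci = atg_ci,
                stop_ci = stop_ci, off_end = FALSE, codons = codons, L = L))
  }
  list(ok = TRUE, reason = NULL, contig = hit$contig, strand = hit$strand,
       frame = off, atg_ci = atg_ci, stop_ci = stop_ci, off_end = FALSE,
       codons = codons, L = L)
}

orf_protein <- function(ext, atg) {
  aa <- Biostrings::GENETIC_CODE[ext$codons[(atg + 1L):ext$stop_ci]]
  paste(aa, collapse = "")
}

# strand-frame codon interval -> genomic 0-based half-open (stop included)
orf_genome_coords <- function(ext, atg) {
  s <- ext$frame + 3L * atg
  e <- ext$frame + 3L * (ext$stop_ci + 1L)
  if (ext$strand == "+") c(s, e) else c(ext$L - e, ext$L - s)
}

#' Transfer the seven-TM segmentation from the closest reference
#'
#' Aligns the candidate to its closest reference (shared amino-acid k-mer
#' count) with the reference global / candidate local, maps the reference
#' TM intervals through the alignment, and rejects candidates in which any
#' TM region contains an alignment gap longer than `tm_gap_max` residues
#' (gaps in extramembrane loops are ignored).
#'
#' @param candidate protein sequence (character or AAString)
#' @param refset an `or_reference_set`
#' @param tm_gap_max maximum tolerated in-TM gap length (default 5)
#' @return list(ok, reason, ref_id, tm1_start, tm) where `tm` holds the
#'   transferred intervals in candidate coordinates
#' @export
segment_tm <- function(candidate, refset, tm_gap_max = 5L) {
  cand <- as.character(candidate)
  ref_ids <- names(refset$proteins)
  cand_codes <- unique(aa_kmer_codes(cand))
  shared <- vapply(ref_ids, function(id) {
    sum(unique(aa_kmer_codes(as.character(refset$proteins[[id]]))) %in%
          cand_codes)
  }, numeric(1))
  ref_id <- ref_ids[which.max(shared)]
  ref <- refset$proteins[[ref_id]]

  pa <- Biostrings::pairwiseAlignment(
    ref, Biostrings::AAString(cand), type = "global-local",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  cand_off <- Biostrings::start(Biostrings::subject(pa)) - 1L

  ref_pos <- cumsum(ap != "-")
  cand_pos <- cand_off + cumsum(as_ != "-")

  tmtab <- refset$tm[refset$tm$id == ref_id, ]
  tmtab <- tmtab[order(tmtab$tm_index), ]
  out <- data.frame(tm_index = tmtab$tm_index, start = NA_integer_,
                    end = NA_integer_)
  for (i in seq_len(nrow(tmtab))) {
    cols <- which(ref_pos >= tmtab$start[i] & ref_pos <= tmtab$end[i] &
                    ap != "-")
    ins_cols <- which(ref_pos >= tmtab$start[i] & ref_pos < tmtab$end[i] &
                        ap == "-")
    if (length(cols) == 0L) {
      return(list(ok = FALSE, reason = "tm_not_covered", ref_id = ref_id))
    }
    # longest run of gap characters inside this TM (either direction)
    gap_flags <- as_[sort(c(cols, ins_cols))] == "-" |
      ap[sort(c(cols, ins_cols))] == "-"
    if (any(gap_flags)) {
      runs <- rle(gap_flags)
      if (max(runs$lengths[runs$values]) > tm_gap_max) {
        return(list(ok = FALSE, reason = "tm_gap_exceeded", ref_id = ref_id))
      }
    }
    aligned <- cols[as_[cols] != "-"]
    if (!length(aligned)) {
      return(list(ok = FALSE, reason = "tm_not_covered", ref_id = ref_id))
    }
    out$start[i] <- cand_pos[aligned[1]]
    out$end[i] <- cand_pos[aligned[length(aligned)]]
  }
  list(ok = TRUE, reason = NULL, ref_id = ref_id,
       tm1_start = out$start[1], tm = out)
}

#' Choose the start codon by the N-terminus rule
#'
#' Among candidate start positions, selects the one whose N-terminal
#' segment (residues before TM1) has length within `[nterm_min,
#' nterm_max]`; when several qualify, the longest N-terminus wins.
#'
#' @param nterm_lengths integer vector of N-terminal lengths implied by
#'   each candidate start
#' @param nterm_min,nterm_max inclusive bounds (defaults 21 and 34)
#' @return index of the chosen start, or NA when none qualifies
#' @export
choose_start <- function(nterm_lengths, nterm_min = 21L, nterm_max = 34L) {
  ok <- which(nterm_lengths >= nterm_min & nterm_lengths <= nterm_max)
  if (!length(ok)) return(NA_integer_)
  ok[which.max(nterm_lengths[ok])]
}

#' Confirm OR identity against non-OR GPCR outgroups
#'
#' Builds a neighbor-joining tree (Poisson distances) over candidates, OR
#' references and outgroup GPCRs; a candidate whose nearest patristic
#' neighbor among the labeled leaves is an outgroup is removed as non-OR.
#' With fewer than 4 sequences in total the decision falls back to plain
#' nearest-neighbor distance (logged via message).
#'
#' @param candidates AAStringSet
#' @param or_refs AAStringSet of known OR proteins
#' @param outgroups AAStringSet of non-OR GPCRs (may be empty: everything
#'   is kept)
#' @return logical vector: TRUE for candidates confirmed as OR
#' @export
confirm_or_identity <- function(candidates, or_refs, outgroups) {
  n_c <- length(candidates)
  if (n_c == 0L) return(logical(0))
  if (length(outgroups) == 0L) return(rep(TRUE, n_c))
  all_seq <- c(candidates, or_refs, outgroups)
  names(all_seq) <- c(paste0("cand_", seq_len(n_c)),
                      paste0("ref_", seq_along(or_refs)),
                      paste0("out_", seq_along(outgroups)))
  if (length(all_seq) < 4L) {
    message("fewer than 4 sequences; OR identity by nearest-neighbor distance")
    return(vapply(seq_len(n_c), function(i) {
      dref <- min(vapply(seq_along(or_refs), function(j)
        1 - protein_identity(candidates[[i]], or_refs[[j]]), numeric(1)))
      dout <- min(vapply(seq_along(outgroups), function(j)
        1 - protein_identity(candidates[[i]], outgroups[[j]]), numeric(1)))
      dref <= dout
    }, logical(1)))
  }
  simm <- protein_similarity_matrix(all_seq)$identity
  D <- poisson_distance_matrix(1 - simm)
  tree <- build_nj_tree(D)
  pat <- stats::cophenetic(tree)
  vapply(seq_len(n_c), function(i) {
    me <- paste0("cand_", i)
    drefs <- pat[me, grep("^ref_", colnames(pat)), drop = TRUE]
    douts <- pat[me, grep("^out_", colnames(pat)), drop = TRUE]
    min(drefs) <= min(douts)
  }, logical(1))
}

# merge adjacent second-pass regions in different frames on the same
# strand whose query coverage is complementary: frameshift evidence
merge_frameshift_regions <- function(best, gap = 60L) {
  if (nrow(best) < 2) { best$frameshift <- rep(FALSE, nrow(best)); return(best) }
  best <- best[order(best$contig, best$strand, best$start), ]
  best$frameshift <- FALSE
  i <- 1L
  while (i < nrow(best)) {
    a <- best[i, ]; b <- best[i + 1L, ]
    same <- a$contig == b$contig && a$strand == b$strand
    near <- same && (b$start - a$end) < gap
    q_olap <- min(a$q_end, b$q_end) - max(a$q_start, b$q_start) + 1L
    q_small <- min(a$q_end - a$q_start, b$q_end - b$q_start) + 1L
    complementary <- q_olap < 0.5 * q_small
    if (near && a$frame != b$frame && complementary &&
        a$query == b$query) {
      best$end[i] <- max(a$end, b$end)
      best$start[i] <- min(a$start, b$start)
      best$q_start[i] <- min(a$q_start, b$q_start)
      best$q_end[i] <- max(a$q_end, b$q_end)
      best$score[i] <- a$score + b$score
      best$frameshift[i] <- TRUE
      best <- best[-(i + 1L), ]
    } else i <- i + 1L
  }
  best
}

# classify one non-intact region; returns list(status, pseudo_kind,
# trunc_flag, start, end, protein)
classify_region <- function(region, genome, trunc_dist = 30L) {
  contig <- genome[[region$contig]]
  L <- length(contig)
  src <- if (region$strand == "+") contig else
    Biostrings::reverseComplement(contig)
  s <- if (region$strand == "+") region$start else L - region$end
  e <- if (region$strand == "+") region$end else L - region$start
  # project the unmatched query span onto the genome, staying in frame and
  # trimming each extension at the first in-frame stop (a stop bounding
  # the region is a normal ORF end, not a disruption)
  up_aa <- region$q_start - 1L
  down_aa <- region$q_len - region$q_end
  off <- s %% 3L
  srcchr <- as.character(src)
  e_in <- s + 3L * ((e - s) %/% 3L)
  hit_codons <- substring(srcchr, seq(s + 1L, e_in - 2L, by = 3L),
                          seq(s + 3L, e_in, by = 3L))
  aa_hit <- unname(Biostrings::GENETIC_CODE[hit_codons])
  internal_stop <- any(aa_hit[seq_len(max(0L, length(aa_hit) - 1L))] == "*",
                       na.rm = TRUE)
  walk <- function(from, to, by) {
    # returns bp actually extended before hitting a stop codon
    if (by > 0 && to <= from) return(0L)
    if (by < 0 && to >= from) return(0L)
    pos <- from
    while ((by > 0 && pos + 3L <= to) || (by < 0 && pos - 3L >= to)) {
      nxt <- if (by > 0) substring(srcchr, pos + 1L, pos + 3L) else
        substring(srcchr, pos - 2L, pos)
      pos <- pos + sign(by) * 3L
      if (nxt %in% STOP_CODONS) break
    }
    abs(pos - from)
  }
  s_ext <- s - walk(s, max(s - 3L * up_aa, off), -3L)
  e_ext <- e_in + walk(e_in, min(e_in + 3L * down_aa + 3L, L - 2L), 3L)
  frameshift <- isTRUE(region$frameshift)
  disrupted <- internal_stop || frameshift
  codons <- substring(srcchr, seq(s_ext + 1L, e_ext - 2L, by = 3L),
                      seq(s_ext + 3L, e_ext, by = 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"

  g <- if (region$strand == "+") c(s_ext, e_ext) else
    c(L - e_ext, L - s_ext)
  # the contig-end distance is measured from the matched region itself
  g_hit <- if (region$strand == "+") c(s, e_in) else c(L - e_in, L - s)
  near_end <- (L - g_hit[2] < trunc_dist) || (g_hit[1] < trunc_dist)
  status <- if (!disrupted && near_end) "truncated" else "pseudogene"
  prot <- paste(ifelse(aa == "*", "X", aa), collapse = "")
  list(status = status,
       pseudo_kind = if (internal_stop) "nonsense" else
         if (frameshift) "frameshift" else "none",
       trunc_flag = near_end, start = g[1], end = g[2], protein = prot)
}

#' Second-pass scan for pseudogenes and truncated genes
#'
#' Searches the genome with the species' own intact OR genes at a stricter
#' E-value, removes regions overlapping intact calls (same strand, >= 1 bp)
#' and classifies the remainder: regions with an internal stop codon or a
#' frameshift are pseudogenes; disruption-free regions ending within
#' `trunc_dist` bp of a contig end are truncated genes (which may also
#' carry the pseudogene flag); all remaining regions are pseudogenes.
#'
#' @param genome DNAStringSet
#' @param intact_calls data frame of intact calls (contig, strand, start,
#'   end) whose regions are excluded
#' @param intact_proteins AAStringSet used as queries; the dereplicated
#'   reference queries should be appended so that pseudogenes of OGGs
#'   without an intact member in this species are still found
#' @param evalue_cutoff second-pass E-value (default 1e-20)
#' @param trunc_dist contig-end distance bound in bp (default 30,
#'   exclusive)
#' @param species species label for gene ids
#' @return data frame of non-intact calls
#' @export
second_pass_scan <- function(genome, intact_calls, intact_proteins,
                             evalue_cutoff = 1e-20, trunc_dist = 30L,
                             species = "sp") {
  empty <- data.frame(species = character(0), gene_id = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      status = character(0), pseudo_kind = character(0),
                      trunc_flag = logical(0), query = character(0),
                      protein = character(0), stringsAsFactors = FALSE)
  if (!length(intact_proteins)) return(empty)
  hits <- translated_search(genome, intact_proteins, evalue_cutoff)
  if (!nrow(hits)) return(empty)
  best <- select_best_regions(hits)
  best <- merge_frameshift_regions(best)
  # drop regions overlapping an intact call on the same strand
  if (nrow(intact_calls)) {
    drop <- vapply(seq_len(nrow(best)), function(i) {
      any(intact_calls$contig == best$contig[i] &
            intact_calls$strand == best$strand[i] &
            intact_calls$start < best$end[i] &
            intact_calls$end > best$start[i])
    }, logical(1))
    best <- best[!drop, , drop = FALSE]
  }
  if (!nrow(best)) return(empty)
  rows <- lapply(seq_len(nrow(best)), function(i) {
    cl <- classify_region(best[i, ], genome, trunc_dist)
    data.frame(species = species, gene_id = NA_character_,
               contig = best$contig[i], start = cl$start, end = cl$end,
               strand = best$strand[i], status = cl$status,
               pseudo_kind = cl$pseudo_kind, trunc_flag = cl$trunc_flag,
               query = best$query[i], protein = cl$protein,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$gene_id <- sprintf("%s_ps%03d", species, seq_len(nrow(out)))
  out
}

#' Mine one genome for OR genes
#'
#' Runs the full two-pass procedure on one species' assembly: dereplicated
#' reference search, best-region selection, ORF extension, TM and
#' N-terminus filters, OR-identity confirmation, then the second pass for
#' pseudogenes and truncated genes.
#'
#' @param genome DNAStringSet of contigs
#' @param refset an `or_reference_set` of query proteins with TM intervals
#' @param outgroups AAStringSet of non-OR GPCRs for identity confirmation
#' @param species species label
#' @param evalue1,evalue2 first/second-pass E-value cutoffs (defaults
#'   1e-10 and 1e-20)
#' @param min_aa minimum intact protein length (default 250)
#' @param tm_gap_max maximum in-TM alignment gap (default 5)
#' @param nterm_min,nterm_max N-terminus bounds (defaults 21, 34)
#' @param trunc_dist contig-end distance bound (default 30)
#' @param identity_ceiling query dereplication ceiling (default 0.5)
#' @return list(calls = data frame of all calls, intact_proteins =
#'   AAStringSet, rejected = data frame of first-pass rejections)
#' @export
mine_genome <- function(genome, refset, outgroups = NULL, species = "sp",
                        evalue1 = 1e-10, evalue2 = 1e-20, min_aa = 250L,
                        tm_gap_max = 5L, nterm_min = 21L, nterm_max = 34L,
                        trunc_dist = 30L, identity_ceiling = 0.5) {
  queries <- dereplicate_queries(refset$proteins, identity_ceiling)
  hits <- translated_search(genome, queries, evalue1)
  best <- select_best_regions(hits)

  intact <- list(); rejected <- list()
  if (nrow(best)) for (i in seq_len(nrow(best))) {
    hit <- best[i, ]
    ext <- extend_to_orf(hit, genome, min_aa)
    if (!ext$ok) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(contig = hit$contig, start = hit$start, end = hit$end,
                   strand = hit$strand, reason = ext$reason,
                   stringsAsFactors = FALSE)
      next
    }
    prot_longest <- orf_protein(ext, ext$atg_ci[1])
    seg <- segment_tm(prot_longest, refset, tm_gap_max)
    if (!seg$ok) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(contig = hit$contig, start = hit$start, end = hit$end,
                   strand = hit$strand, reason = seg$reason,
                   stringsAsFactors = FALSE)
      next
    }
    offs <- ext$atg_ci - ext$atg_ci[1]          # codons into longest ORF
    nterm <- seg$tm1_start - 1L - offs
    pick <- choose_start(nterm, nterm_min, nterm_max)
    if (is.na(pick)) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(contig = hit$contig, start = hit$start, end = hit$end,
                   strand = hit$strand, reason = "nterm_out_of_range",
                   stringsAsFactors = FALSE)
      next
    }
    atg <- ext$atg_ci[pick]
    if (ext$stop_ci - atg < min_aa) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(contig = hit$contig, start = hit$start, end = hit$end,
                   strand = hit$strand, reason = "below_min_length",
                   stringsAsFactors = FALSE)
      next
    }
    g <- orf_genome_coords(ext, atg)
    intact[[length(intact) + 1L]] <- data.frame(
      species = species, contig = hit$contig, start = g[1], end = g[2],
      strand = hit$strand, status = "intact", pseudo_kind = "none",
      trunc_flag = FALSE, query = hit$query,
      protein = orf_protein(ext, atg), stringsAsFactors = FALSE)
  }
  intact_df <- if (length(intact)) do.call(rbind, intact) else
    data.frame(species = character(0), contig = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               status = character(0), pseudo_kind = character(0),
               trunc_flag = logical(0), query = character(0),
               protein = character(0), stringsAsFactors = FALSE)
  # de-duplicate intact calls that extended to the same ORF
  if (nrow(intact_df)) {
    key <- paste(intact_df$contig, intact_df$strand, intact_df$start,
                 intact_df$end)
    intact_df <- intact_df[!duplicated(key), , drop = FALSE]
  }

  if (nrow(intact_df) && !is.null(outgroups) && length(outgroups)) {
    prot <- Biostrings::AAStringSet(intact_df$protein)
    is_or <- confirm_or_identity(prot, refset$proteins, outgroups)
    intact_df <- intact_df[is_or, , drop = FALSE]
  }
  if (nrow(intact_df)) {
    intact_df$gene_id <- sprintf("%s_or%03d", species,
                                 seq_len(nrow(intact_df)))
  } else intact_df$gene_id <- character(0)

  intact_proteins <- Biostrings::AAStringSet(
    stats::setNames(intact_df$protein, intact_df$gene_id))
  pass2_queries <- c(intact_proteins, queries)
  nonintact <- second_pass_scan(genome, intact_df, pass2_queries,
                                evalue2, trunc_dist, species)
  cols <- c("species", "gene_id", "contig", "start", "end", "strand",
            "status", "pseudo_kind", "trunc_flag", "query", "protein")
  calls <- rbind(intact_df[, cols], nonintact[, cols])
  rownames(calls) <- NULL
  list(calls = calls, intact_proteins = intact_proteins,
       rejected = if (length(rejected)) do.call(rbind, rejected) else NULL)
}

#' Write gene calls as TSV (1-based inclusive coordinates) and FASTA
#'
#' @param result result of [mine_genome()]
#' @param out_dir output directory
#' @return invisibly, the paths written
#' @export
write_mining_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  calls <- result$calls
  calls$start <- calls$start + 1L
  p1 <- file.path(out_dir, "gene_calls.tsv")
  write_tsv(calls[, setdiff(names(calls), "protein")], p1)
  p2 <- file.path(out_dir, "intact_proteins.fa")
  Biostrings::writeXStringSet(result$intact_proteins, p2)
  invisible(c(p1, p2))
}
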