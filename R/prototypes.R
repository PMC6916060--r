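# Synthetic OR protein prototypes with annotated seven-transmembrane layout.
#
# Real OR references (human/mouse repertoires with the Man et al. TM
# segmentation) are not shipped; the generator builds class-structured
# prototypes on a fixed hydrophobicity-patterned template so that TM
# segmentation, class assignment and dereplication are all meaningful on
# synthetic data. Layout (1-based aa positions, total 309 aa):
#   N-terminal segment: 1..34 (Met at 1)
#   TM_i (i = 1..7): 21 aa each, separated by 18-aa loops
#   C-terminal tail: 20 aa

HYDROPHOBIC_AA <- strsplit("AILMFVWYC", "")[[1]]
ALL_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Coordinate layout of the synthetic OR template
#'
#' @return list with `length` (total aa) and `tm` (data frame of the seven
#'   TM intervals, 1-based inclusive)
#' @export
or_template_layout <- function() {
  nterm <- 34L; tm_len <- 21L; loop <- 18L; cterm <- 20L
  starts <- nterm + (0:6) * (tm_len + loop) + 1L
  tm <- data.frame(tm_index = 1:7, start = starts, end = starts + tm_len - 1L)
  list(length = max(tm$end) + cterm, tm = tm, nterm_len = nterm)
}

rand_protein <- function(n, tm_mask) {
  aa <- character(n)
  aa[tm_mask] <- sample(HYDROPHOBIC_AA, sum(tm_mask), replace = TRUE)
  aa[!tm_mask] <- sample(ALL_AA, sum(!tm_mask), replace = TRUE)
  aa
}

tm_mask_from_layout <- function(layout) {
  mask <- rep(FALSE, layout$length)
  for (i in seq_len(nrow(layout$tm))) {
    mask[layout$tm$start[i]:layout$tm$end[i]] <- TRUE
  }
  mask
}

#' Generate a class-structured synthetic OR reference set
#'
#' Builds `n` OR protein prototypes on the shared template: one random base
#' sequence per class (I and II), then each prototype derived from its class
#' base by resampling a fraction of positions (TM positions stay within the
#' hydrophobic alphabet). Prototypes are therefore mutually divergent (well
#' under the 50% dereplication ceiling) while retaining a class signal and a
#' valid seven-TM annotation.
#'
#' @param n number of prototypes (one per ancestral OGG)
#' @param class1_fraction fraction assigned to Class I (default 0.15,
#'   mammal-like minority)
#' @param divergence fraction of positions resampled relative to the class
#'   base (default 0.55)
#' @param seed integer seed
#' @return an `or_reference_set`: list with `proteins` (AAStringSet),
#'   `class` (named character vector, "I"/"II"), `tm` (data frame: id,
#'   tm_index, start, end), `nterm_len`
#' @export
make_or_prototypes <- function(n, class1_fraction = 0.15, divergence = 0.55,
                               seed = 1L) {
  layout <- or_template_layout()
  mask <- tm_mask_from_layout(layout)
  with_seed(seed, {
    bases <- list(I = rand_protein(layout$length, mask),
                  II = rand_protein(layout$length, mask))
    n1 <- max(1L, round(n * class1_fraction))
    classes <- c(rep("I", n1), rep("II", n - n1))
    seqs <- character(n)
    for (k in seq_len(n)) {
      aa <- bases[[classes[k]]]
      flip <- runif(layout$length) < divergence
      flip[1] <- FALSE  # keep the initiator Met
      aa[flip & mask] <- sample(HYDROPHOBIC_AA, sum(flip & mask), replace = TRUE)
      aa[flip & !mask] <- sample(ALL_AA, sum(flip & !mask), replace = TRUE)
      aa[1] <- "M"
      seqs[k] <- paste(aa, collapse = "")
    }
    ids <- sprintf("OR_proto_%03d", seq_len(n))
    proteins <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
    tm <- do.call(rbind, lapply(ids, function(id) {
      cbind(data.frame(id = id), layout$tm)
    }))
    structure(list(proteins = proteins,
                   class = stats::setNames(classes, ids),
                   tm = tm, nterm_len = layout$nterm_len),
              class = "or_reference_set")
  })
}

#' Generate decoy non-OR GPCR prototypes
#'
#' Decoys share the broad seven-TM hydrophobicity layout (they are GPCRs)
#' but are drawn from an independent random base, so they carry no OR
#' sequence signal. They play the role of the non-OR GPCR outgroup set used
#' to confirm OR identity by tree placement.
#'
#' @param n number of decoy prototypes
#' @param seed integer seed
#' @return AAStringSet of decoy proteins
#' @export
make_decoy_gpcrs <- function(n, seed = 2L) {
  layout <- or_template_layout()
  mask <- tm_mask_from_layout(layout)
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(k) {
      aa <- rand_protein(layout$length, mask)
      aa[1] <- "M"
      paste(aa, collapse = "")
    }, character(1))
    Biostrings::AAStringSet(stats::setNames(
      seqs, sprintf("GPCR_decoy_%02d", seq_len(n))))
  })
}

# codon table keyed by amino acid, stops excluded
.codons_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

#' Reverse-translate a protein into an intact coding sequence
#'
#' Chooses uniformly among synonymous codons and appends a stop codon.
#' The result always begins with ATG (the protein must begin with Met) and
#' contains no internal stop.
#'
#' @param protein character scalar or AAString
#' @param stop_codon one of "TAA", "TAG", "TGA" (default sampled)
#' @return character scalar DNA sequence
#' @export
reverse_translate <- function(protein, stop_codon = NULL) {
  aa <- strsplit(as.character(protein), "")[[1]]
  stopifnot(aa[1] == "M")
  codons <- vapply(aa, function(a) {
    pool <- .codons_by_aa[[a]]
    if (is.null(pool)) stop("no codon for amino acid: ", a)
    pool[sample.int(length(pool), 1L)]
  }, character(1))
  if (is.null(stop_codon)) stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
  paste0(paste(codons, collapse = ""), stop_codon)
}

#' Write a reference set to FASTA plus a TM-interval TSV
#'
#' @param refset an `or_reference_set`
#' @param fasta_path output protein FASTA
#' @param tm_path output TSV (id, tm_index, start, end; 1-based inclusive)
#' @return invisibly, the two paths
#' @export
write_reference_set <- function(refset, fasta_path, tm_path) {
  Biostrings::writeXStringSet(refset$proteins, fasta_path)
  write_tsv(refset$tm, tm_path)
  invisible(c(fasta_path, tm_path))
}

#' Read a reference set from FASTA plus a TM-interval TSV
#'
#' @param fasta_path protein FASTA
#' @param tm_path TSV with columns id, tm_index, start, end (1-based
#'   inclusive); every protein must carry exactly seven ordered, disjoint
#'   TM intervals
#' @param class optional named character vector of class labels ("I"/"II")
#' @return an `or_reference_set`
#' @export
read_reference_set <- function(fasta_path, tm_path, class = NULL) {
  proteins <- Biostrings::readAAStringSet(fasta_path)
  tm <- read_tsv(tm_path)
  stopifnot(all(c("id", "tm_index", "start", "end") %in% names(tm)))
  for (id in names(proteins)) {
    rows <- tm[tm$id == id, ]
    rows <- rows[order(rows$tm_index), ]
    if (nrow(rows) != 7L) stop("reference ", id, " does not have 7 TM intervals")
    if (any(diff(rows$start) <= 0) || any(rows$end < rows$start) ||
        any(rows$start[-1] <= rows$end[-7])) {
      stop("TM intervals of ", id, " are not ordered and disjoint")
    }
  }
  if (is.null(class)) class <- stats::setNames(rep("II", length(proteins)),
                                               names(proteins))
  nterm <- min(tm$start[tm$tm_index == 1]) - 1L
  structure(list(proteins = proteins, class = class, tm = tm,
                 nterm_len = nterm),
            class = "or_reference_set")
}
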