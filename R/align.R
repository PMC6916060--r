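# Internal translated-search engine and protein similarity utilities.
#
# The search is a six-frame translation + seeded Smith-Waterman: exact
# amino-acid k-mer seeds (rolling-hash match against the query set) define
# candidate loci, each locus window is aligned locally against its seeding
# queries with BLOSUM62 and affine gaps (open 11, extend 1), and raw scores
# are converted to bit scores / E-values with the standard gapped BLOSUM62
# Karlin-Altschul constants (lambda = 0.267, K = 0.041).

.KA_LAMBDA <- 0.267
.KA_K <- 0.041

score_to_bits <- function(score) {
  (.KA_LAMBDA * score - log(.KA_K)) / log(2)
}

bits_to_evalue <- function(bits, m, n) m * n * 2^(-bits)

# rolling k-mer codes of an amino-acid string (base-50 polynomial over
# character codes); identical function used for queries and subjects
aa_kmer_codes <- function(s, k = 5L) {
  v <- utf8ToInt(s) - 40
  n <- length(v) - k + 1L
  if (n < 1L) return(numeric(0))
  codes <- numeric(n)
  mult <- 1
  for (j in seq_len(k)) {
    codes <- codes + v[j:(j + n - 1L)] * mult
    mult <- mult * 50
  }
  codes
}

# translate all six frames of one contig; returns list of frames with
# strand, offset (0..2) and the aa string
six_frames <- function(contig) {
  L <- length(contig)
  rc <- Biostrings::reverseComplement(contig)
  frames <- list()
  for (strand in c("+", "-")) {
    src <- if (strand == "+") contig else rc
    for (off in 0:2) {
      n_codon <- (L - off) %/% 3L
      if (n_codon < 1L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::subseq(src, start = off + 1L,
                           end = off + 3L * n_codon)))
      frames[[length(frames) + 1L]] <-
        list(strand = strand, off = off, aa = aa, n_codon = n_codon)
    }
  }
  frames
}

# frame aa interval [a_start, a_end] (1-based inclusive) -> genomic
# 0-based half-open interval
frame_to_genome <- function(aa_start, aa_end, off, strand, L) {
  s <- off + 3L * (aa_start - 1L)
  e <- off + 3L * aa_end
  if (strand == "+") c(s, e) else c(L - e, L - s)
}

#' Six-frame translated search of a genome against protein queries
#'
#' @param genome DNAStringSet of contigs
#' @param queries AAStringSet of protein queries
#' @param evalue_cutoff maximum E-value of a reported hit (default 1e-10)
#' @param seed_k amino-acid seed length (default 5)
#' @param min_seeds minimum seeds per (locus, query) before alignment
#'   (default 2)
#' @param locus_gap_aa seeds further apart than this start a new locus
#'   (default 150 aa)
#' @return data frame of hits: contig, strand, frame offset, query, raw
#'   score, bit score, evalue, aa_start/aa_end (frame coordinates),
#'   start/end (genomic, 0-based half-open), q_start/q_end (query
#'   coordinates), n_seeds
#' @export
translated_search <- function(genome, queries, evalue_cutoff = 1e-10,
                              seed_k = 5L, min_seeds = 2L,
                              locus_gap_aa = 150L) {
  stopifnot(length(queries) > 0)
  qnames <- names(queries)
  qcode_list <- lapply(seq_along(queries), function(i) {
    unique(aa_kmer_codes(as.character(queries[[i]]), seed_k))
  })
  # code -> integer vector of query indices sharing that seed
  qmap <- split(rep(seq_along(queries), lengths(qcode_list)),
                as.character(unlist(qcode_list)))
  db_aa <- 2 * sum(Biostrings::nchar(genome))  # searched aa per strand pair

  hits <- list()
  for (ci in seq_along(genome)) {
    contig <- genome[[ci]]
    L <- length(contig)
    if (L < 3L) {
      message("contig ", names(genome)[ci], " shorter than one codon; skipped")
      next
    }
    for (fr in six_frames(contig)) {
      codes <- as.character(aa_kmer_codes(fr$aa, seed_k))
      if (!length(codes)) next
      pos <- which(codes %in% names(qmap))
      if (!length(pos)) next
      qs <- qmap[codes[pos]]
      seed_df <- data.frame(pos = rep(pos, lengths(qs)),
                            query = unlist(qs, use.names = FALSE))
      # cluster seed positions into loci
      upos <- sort(unique(seed_df$pos))
      locus_id <- cumsum(c(1L, diff(upos) > locus_gap_aa))
      seed_df$locus <- locus_id[match(seed_df$pos, upos)]
      for (loc in split(seed_df, seed_df$locus)) {
        qtab <- table(loc$query)
        for (q in as.integer(names(qtab)[qtab >= min_seeds])) {
          qlen <- Biostrings::nchar(queries)[q]
          w_start <- max(1L, min(loc$pos[loc$query == q]) - qlen)
          w_end <- min(fr$n_codon,
                       max(loc$pos[loc$query == q]) + qlen + seed_k)
          window <- substr(fr$aa, w_start, w_end)
          pa <- Biostrings::pairwiseAlignment(
            queries[[q]], Biostrings::AAString(window), type = "local",
            substitutionMatrix = "BLOSUM62",
            gapOpening = 11, gapExtension = 1)
          bits <- score_to_bits(Biostrings::score(pa))
          ev <- bits_to_evalue(bits, qlen, db_aa)
          if (ev > evalue_cutoff) next
          sub <- Biostrings::subject(pa)
          aa_start <- w_start + Biostrings::start(sub) - 1L
          aa_end <- w_start + Biostrings::end(sub) - 1L
          g <- frame_to_genome(aa_start, aa_end, fr$off, fr$strand, L)
          pat <- Biostrings::pattern(pa)
          hits[[length(hits) + 1L]] <- data.frame(
            contig = names(genome)[ci], strand = fr$strand, frame = fr$off,
            query = qnames[q], score = Biostrings::score(pa), bits = bits,
            evalue = ev, aa_start = aa_start, aa_end = aa_end,
            start = g[1], end = g[2],
            q_start = Biostrings::start(pat), q_end = Biostrings::end(pat),
            q_len = qlen, n_seeds = sum(loc$query == q),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) return(empty_hits())
  out <- do.call(rbind, hits)
  out[order(out$contig, out$strand, out$start, -out$score, out$query), ]
}

empty_hits <- function() {
  data.frame(contig = character(0), strand = character(0),
             frame = integer(0), query = character(0), score = numeric(0),
             bits = numeric(0), evalue = numeric(0), aa_start = integer(0),
             aa_end = integer(0), start = integer(0), end = integer(0),
             q_start = integer(0), q_end = integer(0), q_len = integer(0),
             n_seeds = integer(0), stringsAsFactors = FALSE)
}

#' Collapse overlapping hits to the highest-scoring region
#'
#' Hits sharing at least 1 bp on the same contig and strand are collapsed
#' to the single highest-scoring one; ties are broken by lower start
#' coordinate, then lexicographic query id.
#'
#' @param hits data frame from [translated_search()]
#' @return the retained subset of `hits`
#' @export
select_best_regions <- function(hits) {
  if (!nrow(hits)) return(hits)
  keep <- logical(nrow(hits))
  for (key in unique(paste(hits$contig, hits$strand))) {
    idx <- which(paste(hits$contig, hits$strand) == key)
    ord <- idx[order(-hits$score[idx], hits$start[idx], hits$query[idx])]
    kept_s <- integer(0); kept_e <- integer(0)
    for (i in ord) {
      if (!any(hits$start[i] < kept_e & hits$end[i] > kept_s)) {
        keep[i] <- TRUE
        kept_s <- c(kept_s, hits$start[i])
        kept_e <- c(kept_e, hits$end[i])
      }
    }
  }
  hits[keep, , drop = FALSE]
}

# ---- protein similarity ---------------------------------------------------

.blosum62 <- local({
  e <- new.env()
  e$m <- NULL
  function() {
    if (is.null(e$m)) {
      e$m <- get(utils::data("BLOSUM62", package = "Biostrings",
                             envir = e)[1], envir = e)
    }
    e$m
  }
})

# identity and normalized BLOSUM62 score for one pair; gapless fast path
# for equal-length sequences, global alignment otherwise
pair_similarity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  B <- .blosum62()
  if (length(ca) == length(cb)) {
    ident <- mean(ca == cb)
    s_ab <- sum(B[cbind(ca, cb)])
    s_aa <- sum(B[cbind(ca, ca)])
    s_bb <- sum(B[cbind(cb, cb)])
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    ident <- Biostrings::pid(pa, type = "PID1") / 100
    s_ab <- Biostrings::score(pa)
    s_aa <- sum(B[cbind(ca, ca)])
    s_bb <- sum(B[cbind(cb, cb)])
  }
  c(identity = ident,
    norm_score = max(0, s_ab) / sqrt(s_aa * s_bb))
}

#' Pairwise identity and normalized similarity matrices
#'
#' @param proteins AAStringSet
#' @return list(identity, norm_score): symmetric matrices with unit
#'   diagonal. Identity is fraction of identical aligned positions;
#'   norm_score is the BLOSUM62 alignment score normalized by the
#'   geometric mean of the self-scores.
#' @export
protein_similarity_matrix <- function(proteins) {
  n <- length(proteins)
  ids <- names(proteins)
  chars <- as.character(proteins)
  idm <- diag(1, n); nsm <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        s <- pair_similarity(chars[i], chars[j])
        idm[i, j] <- idm[j, i] <- s["identity"]
        nsm[i, j] <- nsm[j, i] <- s["norm_score"]
      }
    }
  }
  dimnames(idm) <- dimnames(nsm) <- list(ids, ids)
  list(identity = idm, norm_score = nsm)
}

#' Global pairwise protein identity
#'
#' Identity on a global pairwise alignment: identical positions over
#' alignment length (gapped columns included in the denominator).
#'
#' @param a,b protein sequences (character or AAString)
#' @return fraction in `[0, 1]`
#' @export
protein_identity <- function(a, b) {
  unname(pair_similarity(as.character(a), as.character(b))["identity"])
}
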