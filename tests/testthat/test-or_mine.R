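# Miner: dereplication, translated search, region selection, ORF
# extension, TM/N-terminus filters, second-pass classification.

test_that("dereplication keeps one of an identical pair, both at 49%", {
  set.seed(21)
  a <- random_protein(100)
  twins <- Biostrings::AAStringSet(c(x = a, y = a))
  expect_equal(length(dereplicate_queries(twins)), 1L)

  b <- strsplit(a, "")[[1]]
  flip <- sample(100, 51)  # 49% identity
  pool <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in flip) b[i] <- sample(setdiff(pool, b[i]), 1)
  pairset <- Biostrings::AAStringSet(c(x = a, y = paste(b, collapse = "")))
  expect_lt(protein_identity(pairset[[1]], pairset[[2]]), 0.5)
  expect_equal(length(dereplicate_queries(pairset)), 2L)
})

test_that("dereplication chain follows greedy longest-first selection", {
  # A~B and B~C above the ceiling, A~C far below; lengths A > B > C
  set.seed(22)
  base <- random_protein(120)
  A <- base
  B <- substr(random_protein(118, from = substr(base, 1, 118), p = 0.35),
              1, 118)
  C_ <- random_protein(116)  # unrelated to A
  # make B~C similar by construction: C shares B's tail heavily
  C_ <- paste0(substr(B, 1, 100), substr(random_protein(16), 1, 16))
  seqs <- Biostrings::AAStringSet(c(A = A, B = B, C = C_))
  idAB <- protein_identity(seqs[["A"]], seqs[["B"]])
  idBC <- protein_identity(seqs[["B"]], seqs[["C"]])
  idAC <- protein_identity(seqs[["A"]], seqs[["C"]])
  expect_gt(idAB, 0.5); expect_gt(idBC, 0.5); expect_lt(idAC, 0.5)

  # independent oracle: greedy longest-first over the identity matrix
  ids <- c("A", "B", "C")
  lens <- Biostrings::nchar(seqs)
  ord <- ids[order(-lens, ids)]
  kept <- character(0)
  for (s in ord) {
    if (all(vapply(kept, function(k)
      protein_identity(seqs[[s]], seqs[[k]]) < 0.5, logical(1)))) {
      kept <- c(kept, s)
    }
  }
  expect_setequal(kept, c("A", "C"))
  expect_setequal(names(dereplicate_queries(seqs)), kept)
})

test_that("translated search finds exact and reverse-complement copies", {
  set.seed(23)
  prot <- make_or_prototypes(1, seed = 77)$proteins
  cds <- with_seed(5, reverse_translate(prot[[1]]))
  fwd <- paste0(random_dna_str(500), cds, random_dna_str(500))
  genome <- Biostrings::DNAStringSet(c(
    plus = fwd,
    minus = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fwd)))))
  hits <- translated_search(genome, prot, 1e-10)
  plus_hit <- hits[hits$contig == "plus", ][1, ]
  minus_hit <- hits[hits$contig == "minus", ][1, ]
  expect_equal(plus_hit$strand, "+")
  expect_equal(minus_hit$strand, "-")
  expect_equal(plus_hit$score, minus_hit$score)
  # mirrored coordinates
  L <- nchar(fwd)
  expect_equal(minus_hit$start, L - plus_hit$end)
  expect_equal(minus_hit$end, L - plus_hit$start)
  # covers the full protein
  expect_lte(plus_hit$start, 500 + 3)
  expect_gte(plus_hit$end, 500 + 3 * 309 - 3)
})

test_that("relaxing the E-value cutoff never shrinks the hit set", {
  ds <- fixture_dataset()
  genome <- ds$genomes[["C"]]
  q <- ds$refset$proteins[1:5]
  strict <- translated_search(genome, q, 1e-30)
  loose <- translated_search(genome, q, 1e-5)
  key <- function(h) paste(h$contig, h$strand, h$start, h$end, h$query)
  expect_true(all(key(strict) %in% key(loose)))
  expect_gte(nrow(loose), nrow(strict))
})

test_that("best-region selection keeps top scores with stated tie-breaks", {
  mk <- function(start, end, score, query, frame = 0) {
    data.frame(contig = "c", strand = "+", frame = frame, query = query,
               score = score, bits = score, evalue = 0, aa_start = 1,
               aa_end = 2, start = start, end = end, q_start = 1,
               q_end = 100, q_len = 100, n_seeds = 3,
               stringsAsFactors = FALSE)
  }
  h <- rbind(mk(0, 900, 500, "q1"), mk(100, 950, 300, "q2"))
  expect_equal(select_best_regions(h)$score, 500)
  h <- rbind(mk(0, 900, 500, "q1"), mk(2000, 2900, 300, "q2"))
  expect_equal(nrow(select_best_regions(h)), 2L)
  # three mutually overlapping equal scores: lower start, then query id
  h <- rbind(mk(10, 900, 400, "qb"), mk(5, 890, 400, "qz"),
             mk(5, 880, 400, "qa"))
  kept <- select_best_regions(h)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$start, 5)
  expect_equal(kept$query, "qa")
})

# build a contig containing a planted ORF with controlled layout and an
# upstream in-frame stop; returns the genome and a synthetic hit row
planted_orf_fixture <- function(protein_aa, lead = 300) {
  cds <- with_seed(8, reverse_translate(protein_aa))
  # upstream in-frame stop right before the ATG keeps extension bounded
  pre <- paste0(random_dna_str(lead), "TAA")
  contig <- paste0(pre, cds, random_dna_str(300))
  genome <- Biostrings::DNAStringSet(c(ctg = contig))
  hit <- data.frame(contig = "ctg", strand = "+", frame = nchar(pre) %% 3,
                    query = "q", score = 1000, bits = 300, evalue = 0,
                    aa_start = 1, aa_end = 2,
                    start = nchar(pre) + 30, end = nchar(pre) + 300,
                    q_start = 1, q_end = 90, q_len = 300, n_seeds = 5,
                    stringsAsFactors = FALSE)
  list(genome = genome, hit = hit, cds_start = nchar(pre),
       cds_end = nchar(pre) + nchar(cds))
}

test_that("ORF extension enforces the 250-aa bound inclusively", {
  set.seed(31)
  p249 <- paste0("M", random_protein(248))
  p250 <- paste0("M", random_protein(249))
  fx <- planted_orf_fixture(p249)
  expect_false(extend_to_orf(fx$hit, fx$genome)$ok)
  expect_equal(extend_to_orf(fx$hit, fx$genome)$reason, "below_min_length")
  fx <- planted_orf_fixture(p250)
  ext <- extend_to_orf(fx$hit, fx$genome)
  expect_true(ext$ok)
  prot <- with(ext, paste(Biostrings::GENETIC_CODE[
    codons[(atg_ci[1] + 1):stop_ci]], collapse = ""))
  expect_equal(prot, p250)
})

test_that("planted intact genes round-trip to exact truth coordinates", {
  ds <- fixture_dataset()
  calls <- fixture_calls()
  truth <- ds$truth[ds$truth$status == "intact", ]
  hitkey <- paste(calls$species, calls$contig, calls$start, calls$end,
                  calls$strand)[calls$status == "intact"]
  truthkey <- paste(truth$species, truth$contig, truth$start, truth$end,
                    truth$strand)
  expect_true(all(truthkey %in% hitkey))
})

test_that("TM gap filter applies to TM regions only, bound of 5 inclusive", {
  refset <- make_or_prototypes(2, seed = 55)
  ref <- as.character(refset$proteins[[1]])
  tm3 <- refset$tm[refset$tm$id == names(refset$proteins)[1] &
                     refset$tm$tm_index == 3, ]
  # deletion of 6 aa inside TM3 -> rejected
  del6 <- paste0(substr(ref, 1, tm3$start + 4),
                 substr(ref, tm3$start + 11, nchar(ref)))
  seg <- segment_tm(del6, refset)
  expect_false(seg$ok)
  expect_equal(seg$reason, "tm_gap_exceeded")
  # deletion of 5 aa inside a TM -> retained
  del5 <- paste0(substr(ref, 1, tm3$start + 4),
                 substr(ref, tm3$start + 10, nchar(ref)))
  expect_true(segment_tm(del5, refset)$ok)
  # deletion of 10 aa in the loop between TM3 and TM4 -> retained
  loop_start <- tm3$end + 3
  del_loop <- paste0(substr(ref, 1, loop_start),
                     substr(ref, loop_start + 11, nchar(ref)))
  expect_true(segment_tm(del_loop, refset)$ok)
})

test_that("start-codon choice follows the 21-34 N-terminus rule", {
  expect_equal(choose_start(c(18, 25, 40)), 2L)
  expect_equal(choose_start(c(21, 34)), 2L)   # longest qualifying
  expect_equal(choose_start(c(34, 21)), 1L)
  expect_true(is.na(choose_start(c(18, 40))))
  expect_true(is.na(choose_start(c(20, 35))))  # both just outside
  expect_equal(choose_start(c(20, 21)), 2L)
  expect_equal(choose_start(c(34, 35)), 1L)
})

test_that("second pass classifies nonsense, frameshift and truncation", {
  ds <- fixture_dataset()
  calls <- fixture_calls()
  truth <- ds$truth[ds$truth$status %in% c("pseudogene", "truncated"), ]
  matched <- match_calls_to_truth(calls, truth)
  expect_true(all(matched$called == matched$status))
})

test_that("contig-end rule: 29 bp is truncated, 30 bp is a pseudogene", {
  set.seed(33)
  proto <- make_or_prototypes(1, seed = 91)
  cds <- with_seed(12, reverse_translate(proto$proteins[[1]]))
  partial <- substr(cds, 1, 600)   # disruption-free 200-codon fragment
  intact_q <- proto$proteins
  names(intact_q) <- "q1"
  for (tail_bp in c(29, 30)) {
    contig <- paste0(random_dna_str(400), partial, random_dna_str(tail_bp))
    genome <- Biostrings::DNAStringSet(c(ctg = contig))
    calls <- second_pass_scan(genome,
                              intact_calls = data.frame(contig = character(0),
                                                        strand = character(0),
                                                        start = integer(0),
                                                        end = integer(0)),
                              intact_proteins = intact_q,
                              evalue_cutoff = 1e-20, species = "t")
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$status,
                 if (tail_bp < 30) "truncated" else "pseudogene")
  }
})

test_that("regions with an internal stop are pseudogenes", {
  set.seed(34)
  proto <- make_or_prototypes(1, seed = 92)
  cds <- strsplit(with_seed(13, reverse_translate(proto$proteins[[1]])),
                  "")[[1]]
  cds[(3 * 150 - 2):(3 * 150)] <- c("T", "A", "A")  # internal TAA
  contig <- paste0(random_dna_str(400), paste(cds, collapse = ""),
                   random_dna_str(400))
  genome <- Biostrings::DNAStringSet(c(ctg = contig))
  calls <- second_pass_scan(genome,
                            intact_calls = data.frame(contig = character(0),
                                                      strand = character(0),
                                                      start = integer(0),
                                                      end = integer(0)),
                            intact_proteins = proto$proteins,
                            evalue_cutoff = 1e-20, species = "t")
  expect_true(nrow(calls) >= 1)
  expect_true(all(calls$status == "pseudogene"))
  expect_true("nonsense" %in% calls$pseudo_kind)
})

test_that("OR identity confirmation removes decoys and keeps ORs", {
  ds <- fixture_dataset()
  set.seed(35)
  or_like <- ds$refset$proteins[1:3]
  decoy_like <- ds$decoys[1:2]
  cands <- c(or_like, decoy_like)
  names(cands) <- paste0("cand", 1:5)
  keep <- confirm_or_identity(cands, ds$refset$proteins, ds$decoys)
  expect_identical(unname(keep), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(confirm_or_identity(Biostrings::AAStringSet(),
                                       ds$refset$proteins, ds$decoys),
                   logical(0))
})

test_that("mining a genome and its reverse complement gives mirrored calls", {
  ds <- fixture_dataset()
  genome <- ds$genomes[["D"]]
  rc <- Biostrings::reverseComplement(genome)
  names(rc) <- names(genome)
  res_f <- mine_genome(genome, ds$refset, ds$decoys, species = "D")
  res_r <- mine_genome(rc, ds$refset, ds$decoys, species = "D")
  L <- Biostrings::width(genome)[match(res_r$calls$contig, names(genome))]
  mirrored <- data.frame(contig = res_r$calls$contig,
                         start = L - res_r$calls$end,
                         end = L - res_r$calls$start,
                         strand = ifelse(res_r$calls$strand == "+", "-", "+"),
                         status = res_r$calls$status)
  key <- function(d) sort(paste(d$contig, d$start, d$end, d$strand,
                                d$status))
  expect_identical(key(res_f$calls), key(mirrored))
})

test_that("every call is labeled and intact calls are disjoint from pseudo", {
  calls <- fixture_calls()
  expect_true(all(calls$status %in% c("intact", "pseudogene", "truncated")))
  intact <- calls[calls$status == "intact", ]
  other <- calls[calls$status != "intact", ]
  if (nrow(intact) && nrow(other)) {
    for (i in seq_len(nrow(intact))) {
      overlap <- other$contig == intact$contig[i] &
        other$strand == intact$strand[i] &
        other$start < intact$end[i] & other$end > intact$start[i]
      expect_false(any(overlap))
    }
  }
})
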