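# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env()

# small 4-species dated tree (MY)
fixture_tree <- function() {
  dated_tree(ape::read.tree(text = "((A:40,B:40):30,(C:50,D:50):20);"))
}

# ground-truthed synthetic dataset: 20 ancestral OGGs, modest turnover,
# ~15 genes per species incl. pseudogenes/truncated, 4 decoys
fixture_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    cfg <- sim_config(tree = fixture_tree(), ancestral_family_count = 20,
                      beta = 0.002, delta = 0.002, contig_count = 10,
                      contig_length = 15000,
                      pseudogenization_fraction = 0.2,
                      truncation_fraction = 0.1, decoy_gpcr_count = 4,
                      seed = 11)
    .fixture_env$ds <- c(list(config = cfg), simulate_dataset(cfg))
  }
  .fixture_env$ds
}

# mined calls for all four fixture species (runs the miner once)
fixture_calls <- function() {
  if (is.null(.fixture_env$calls)) {
    ds <- fixture_dataset()
    sp <- ds$config$tree$phylo$tip.label
    .fixture_env$calls <- do.call(rbind, lapply(sp, function(s) {
      mine_genome(ds$genomes[[s]], ds$refset, ds$decoys, species = s)$calls
    }))
  }
  .fixture_env$calls
}

# match calls against the truth table by coordinate overlap; returns the
# truth table with a `called` column ("missed" or the call status)
match_calls_to_truth <- function(calls, truth) {
  truth$called <- vapply(seq_len(nrow(truth)), function(i) {
    m <- calls$contig == truth$contig[i] &
      calls$strand == truth$strand[i] &
      calls$start < truth$end[i] & calls$end > truth$start[i]
    if (!any(m)) return("missed")
    paste(sort(unique(calls$status[m])), collapse = "+")
  }, character(1))
  truth
}

# adjusted Rand index between two partitions (vectors of labels)
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c_ <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c_ / choose(n, 2)
  maxi <- (b + c_) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}

# random protein of length n (optionally mutated copy of another)
random_protein <- function(n, from = NULL, p = 0) {
  aa_pool <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(from)) {
    paste(sample(aa_pool, n, replace = TRUE), collapse = "")
  } else {
    ch <- strsplit(from, "")[[1]]
    flip <- runif(length(ch)) < p
    ch[flip] <- sample(aa_pool, sum(flip), replace = TRUE)
    paste(ch, collapse = "")
  }
}

# random DNA string
random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
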