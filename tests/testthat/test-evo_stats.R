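# Comparative statistics: Mann-Whitney, Pearson, similarity, variability,
# NG86 dN/dS.

# independent brute-force oracle for the exact two-sided Mann-Whitney p
mw_brute <- function(a, b) {
  m <- length(a); N <- m + length(b)
  vals <- c(a, b)
  r <- rank(vals)
  U_of <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  U <- U_of(seq_len(m))
  mu <- m * (N - m) / 2
  combos <- utils::combn(N, m)
  Us <- apply(combos, 2, U_of)
  mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
}

test_that("Mann-Whitney exact p matches enumeration on the worked example", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)          # 2 of the C(6,3)=20 assignments
  expect_equal(mw$method, "exact")
  same <- mann_whitney(c(2, 2, 2), c(2, 2))
  expect_equal(same$p, 1)
})

test_that("Mann-Whitney matches the brute-force oracle on small samples", {
  set.seed(61)
  for (k in 1:12) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    a <- sample(1:6, m, replace = TRUE)   # ties included
    b <- sample(1:6, n, replace = TRUE)
    got <- mann_whitney(a, b)
    expect_equal(got$p, mw_brute(a, b), tolerance = 1e-12,
                 info = sprintf("case %d", k))
  }
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(62)
  a <- rnorm(30); b <- rnorm(25) + 0.4
  got <- mann_whitney(a, b)
  expect_equal(got$method, "normal")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-6)
})

test_that("marine-vs-terrestrial contrasts are well powered at n = 11 + 11", {
  # repertoire sizes like the study's: marine means far below terrestrial
  set.seed(63)
  hits <- replicate(100, {
    marine <- rpois(11, 150)
    terrestrial <- rpois(11, 800)
    mann_whitney(marine, terrestrial)$p < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Pearson correlation matches closed forms and affine invariance", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  set.seed(64)
  a <- rnorm(15); b <- a + rnorm(15)
  p1 <- pearson(a, b)
  ref <- stats::cor.test(a, b)
  expect_equal(p1$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(p1$p, ref$p.value, tolerance = 1e-12)
  p2 <- pearson(3 * a - 7, 0.5 * b + 2)
  expect_equal(p2$r, p1$r, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), rnorm(5)), "zero-variance")
  expect_error(pearson(1:2, 2:3), "at least 3")
})

test_that("OGG similarity counts identical aligned positions", {
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("C", 10), rep("A", 90)), collapse = "")
  expect_equal(ogg_similarity(Biostrings::AAStringSet(c(a, a))), 1)
  expect_equal(ogg_similarity(Biostrings::AAStringSet(c(a, b))), 0.9)
  expect_error(ogg_similarity(Biostrings::AAStringSet(a)), "2 members")
})

test_that("similarity decreases with OGG size when divergence scales with size", {
  # regime where larger families carry longer duplication histories:
  # members of a size-k OGG are mutated at p ~ k/40 from the prototype
  set.seed(65)
  sizes <- c(2, 3, 4, 6, 8, 10, 12)
  sim <- vapply(sizes, function(k) {
    proto <- random_protein(150)
    members <- Biostrings::AAStringSet(vapply(seq_len(k), function(i)
      random_protein(150, from = proto, p = k / 40), character(1)))
    ogg_similarity(members)
  }, numeric(1))
  expect_lt(stats::cor(sizes, sim, method = "spearman"), 0)
})

test_that("size variability: SD over the zero-padded species vector", {
  m <- matrix(0L, nrow = 23, ncol = 2,
              dimnames = list(paste0("sp", 1:23), c("o1", "o2")))
  m[, "o1"] <- 3L
  m[1, "o2"] <- 5L
  sv <- size_variability(m)
  expect_equal(sv$table$sd[sv$table$ogg == "o1"], 0)
  expect_equal(sv$table$sd[sv$table$ogg == "o2"],
               stats::sd(c(5, rep(0, 22))))
})

test_that("SD grows with OGG size in birth-death simulations", {
  cfg <- sim_config(tree = mammal_like_tree(), ancestral_family_count = 150,
                    beta = 0.004, delta = 0.004, seed = 17)
  sim <- simulate_family_evolution(cfg)
  tc <- tip_content(sim, cfg)
  sv <- size_variability(tc)
  expect_gt(sv$r, 0)
  expect_lt(sv$p, 0.05)
})

# brute-force NG86 site/difference oracle for a single codon pair
ng86_oracle <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  sites <- function(codon) {
    S <- 0
    for (pos in 1:3) {
      muts <- vapply(setdiff(c("A", "C", "G", "T"),
                             substr(codon, pos, pos)), function(b) {
        x <- codon; substr(x, pos, pos) <- b; gc[[x]]
      }, character(1))
      keep <- muts != "*"
      if (any(keep)) S <- S + sum(muts[keep] == gc[[codon]]) / sum(keep)
    }
    S
  }
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- switch(as.character(length(pos)),
                  "0" = list(), "1" = list(pos),
                  "2" = list(pos, rev(pos)),
                  list())
  sd_nd <- c(0, 0)
  if (length(pos) > 0) {
    paths <- lapply(perms, function(order) {
      cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
      for (p in order) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (gc[[nxt]] == "*" && nxt != c2) ok <- FALSE
        if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      list(sd = sd, nd = nd, ok = ok)
    })
    use <- Filter(function(x) x$ok, paths)
    if (!length(use)) use <- paths
    sd_nd <- c(mean(vapply(use, `[[`, numeric(1), "sd")),
               mean(vapply(use, `[[`, numeric(1), "nd")))
  }
  list(S = (sites(c1) + sites(c2)) / 2, Sd = sd_nd[1], Nd = sd_nd[2])
}

test_that("NG86 site and difference counts match a hand-count oracle", {
  cases <- list(c("GGT", "GGC"),  # 4-fold synonymous third position
                c("TTT", "TTA"),  # Phe -> Leu, nonsynonymous
                c("AAA", "AGG"),  # two differences
                c("ATG", "ATG"))  # identical
  for (cs in cases) {
    # identical shared tail keeps sequences long enough without adding
    # differences
    got <- ng86_pair(paste0(cs[1], "GGTGGC"), paste0(cs[2], "GGTGGC"))
    orc <- ng86_oracle(cs[1], cs[2])
    tail_sites <- ng86_oracle("GGT", "GGT")$S + ng86_oracle("GGC", "GGC")$S
    expect_equal(got$Sd, orc$Sd, tolerance = 1e-9)
    expect_equal(got$Nd, orc$Nd, tolerance = 1e-9)
    expect_equal(got$S, orc$S + tail_sites, tolerance = 1e-9)
  }
})

test_that("omega is 0 for synonymous-only and flagged for nonsyn-only pairs", {
  # ten codons, one 4-fold synonymous difference
  s1 <- paste(rep("GGT", 10), collapse = "")
  s2 <- paste(c(rep("GGT", 9), "GGC"), collapse = "")
  r <- ng86_pair(s1, s2)
  expect_equal(r$Nd, 0)
  expect_equal(r$omega, 0)
  # nonsynonymous-only differences: dS = 0 -> Inf sentinel, and the OGG
  # aggregate flags when no usable pair remains
  s3 <- paste(c(rep("GGT", 9), "TGT"), collapse = "")  # Gly -> Cys
  r2 <- ng86_pair(s1, s3)
  expect_true(is.infinite(r2$omega))
  po <- pairwise_omega(Biostrings::DNAStringSet(c(s1, s1, s3)))
  expect_true(po$flagged)
  # identical sequences: no usable pairs
  po2 <- pairwise_omega(Biostrings::DNAStringSet(c(s1, s1, s1)))
  expect_true(po2$flagged)
  # below the member floor
  expect_true(pairwise_omega(Biostrings::DNAStringSet(c(s1, s2)))$flagged)
})

test_that("neutral substitution yields omega near 1", {
  set.seed(66)
  mut_neutral <- function(cds, p) {
    ch <- strsplit(cds, "")[[1]]
    n <- length(ch)
    repeat {
      out <- ch
      flip <- which(runif(n) < p)
      for (i in flip) out[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                               out[i]), 1)
      cods <- substring(paste(out, collapse = ""),
                        seq(1, n - 2, 3), seq(3, n, 3))
      if (!any(Biostrings::GENETIC_CODE[cods] == "*", na.rm = TRUE)) {
        return(paste(out, collapse = ""))
      }
    }
  }
  om <- vapply(1:100, function(k) {
    proto <- make_or_prototypes(1, seed = 7000 + k)$proteins[[1]]
    anc <- with_seed(8000 + k, reverse_translate(proto))
    anc <- substr(anc, 1, nchar(anc) - 3)
    trio <- Biostrings::DNAStringSet(vapply(1:3, function(i)
      mut_neutral(anc, 0.06), character(1)))
    pairwise_omega(trio)$omega
  }, numeric(1))
  expect_gte(stats::median(om, na.rm = TRUE), 0.8)
  expect_lte(stats::median(om, na.rm = TRUE), 1.25)
})

test_that("omega correlates with turnover in a relaxed-constraint regime", {
  # high-turnover OGGs admit more nonsynonymous change
  set.seed(67)
  n <- 40
  gains <- rpois(n, 5)
  omega <- pmax(0.05, 0.1 + 0.05 * gains + rnorm(n, 0, 0.05))
  tabs <- data.frame(ogg = paste0("o", 1:n), omega = omega)
  stats_tab <- data.frame(ogg = paste0("o", 1:n), intact = rpois(n, 10),
                          gains = gains, losses = rpois(n, 3),
                          class = rep(c("I", "II"), length.out = n))
  res <- omega_correlates(tabs, stats_tab)
  expect_gt(res$omega_vs_gains$r, 0)
  expect_lt(res$omega_vs_gains$p, 0.05)
  expect_true(!is.null(res$class_test))
  # constant omega: correlation undefined -> flagged as NA
  tabs$omega <- 0.5
  res2 <- omega_correlates(tabs, stats_tab)
  expect_true(is.na(res2$omega_vs_gains$r))
  # insufficient overlap errors
  expect_error(omega_correlates(tabs[0, ], stats_tab), "insufficient")
})

test_that("repertoire summary reconciles exactly with the call table", {
  calls <- fixture_calls()
  ds <- fixture_dataset()
  summ <- repertoire_summary(calls)
  for (s in summ$species) {
    expect_equal(summ$intact[summ$species == s],
                 sum(calls$species == s & calls$status == "intact"))
    expect_equal(summ$pseudogene[summ$species == s],
                 sum(calls$species == s & calls$status == "pseudogene"))
    expect_equal(summ$truncated[summ$species == s],
                 sum(calls$species == s & calls$status == "truncated"))
  }
  tot <- summ$intact + summ$pseudogene + summ$truncated
  expect_equal(sum(tot), nrow(calls))
  expect_true(all(summ$pseudogene_proportion >= 0 &
                    summ$pseudogene_proportion <= 1))
  expect_equal(summ$pseudogene_proportion, summ$pseudogene / tot)
})
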