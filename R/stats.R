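# Comparative statistics: Mann-Whitney U (exact permutation for small
# samples), Pearson correlation, per-OGG similarity and size variability,
# and a Nei-Gojobori (NG86) pairwise dN/dS estimator with Jukes-Cantor
# correction.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For combined sample sizes up to
#' `exact_threshold` the p value is computed by exact enumeration of all
#' group assignments (midranks handle ties); larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors (non-empty)
#' @param exact_threshold switch point on the combined sample size
#'   (default 20)
#' @return list(U, p, method)
#' @export
mann_whitney <- function(a, b, exact_threshold = 20L) {
  stopifnot(length(a) > 0, length(b) > 0)
  m <- length(a); n <- length(b); N <- m + n
  vals <- c(a, b)
  r <- rank(vals)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  if (all(vals == vals[1])) {
    return(list(U = U, p = 1, method = "degenerate"))
  }
  if (N <= exact_threshold) {
    idx <- utils::combn(N, m)
    rsums <- colSums(matrix(r[idx], nrow = m))
    Us <- rsums - m * (m + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    list(U = U, p = p, method = "exact")
  } else {
    ties <- table(vals)
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(U = U, p = p, method = "normal")
  }
}

#' Pearson product-moment correlation with t-based p value
#'
#' @param x,y numeric vectors, length >= 3, finite variance
#' @return list(r, p, n)
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("pearson requires at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson undefined for zero-variance input")
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Mean pairwise amino-acid identity of an OGG
#'
#' Identity of a pair is identical positions over aligned positions
#' (global pairwise alignment; alignment length includes gapped columns).
#'
#' @param proteins AAStringSet with at least 2 members
#' @return mean pairwise identity in `[0, 1]`
#' @export
ogg_similarity <- function(proteins) {
  k <- length(proteins)
  if (k < 2) stop("ogg_similarity needs at least 2 members")
  pairs <- utils::combn(k, 2)
  ids <- vapply(seq_len(ncol(pairs)), function(j) {
    pa <- Biostrings::pairwiseAlignment(
      proteins[[pairs[1, j]]], proteins[[pairs[2, j]]],
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    Biostrings::pid(pa, type = "PID1") / 100
  }, numeric(1))
  mean(ids)
}

#' Per-OGG size variability across species
#'
#' For each OGG, the total gene count and the standard deviation (n - 1
#' denominator) of the per-species count vector, zeros included for absent
#' species; reports the Pearson correlation of SD with total.
#'
#' @param count_matrix integer matrix species x OGGs (e.g. from
#'   [ogg_count_matrix()])
#' @return list(table = data frame (ogg, total, sd), r, p)
#' @export
size_variability <- function(count_matrix) {
  tot <- colSums(count_matrix)
  sds <- apply(count_matrix, 2, stats::sd)
  tab <- data.frame(ogg = colnames(count_matrix), total = tot, sd = sds,
                    row.names = NULL, stringsAsFactors = FALSE)
  ct <- tryCatch(pearson(tab$total, tab$sd),
                 error = function(e) list(r = NA_real_, p = NA_real_))
  list(table = tab, r = ct$r, p = ct$p)
}

# ---- NG86 dN/dS -----------------------------------------------------------

.GC <- Biostrings::GENETIC_CODE

codon_split <- function(seq) {
  chars <- strsplit(as.character(seq), "")[[1]]
  n <- length(chars) %/% 3L
  vapply(seq_len(n), function(i) paste(chars[(3 * i - 2):(3 * i)],
                                       collapse = ""), character(1))
}

# synonymous site count of one codon (stop-bound mutations excluded)
ng86_sites <- function(codon) {
  aa <- .GC[[codon]]
  if (is.na(aa) || aa == "*") return(c(S = 0, N = 0))
  S <- 0
  for (pos in 1:3) {
    alts <- setdiff(DNA_BASES, substr(codon, pos, pos))
    muts <- vapply(alts, function(b) {
      x <- codon; substr(x, pos, pos) <- b; .GC[[x]]
    }, character(1))
    keep <- muts != "*"
    if (any(keep)) S <- S + sum(muts[keep] == aa) / sum(keep)
  }
  c(S = S, N = 3 - S)
}

# synonymous/nonsynonymous difference counts between two codons, averaged
# over all mutational pathways (pathways through stop codons dropped when
# any stop-free pathway exists)
ng86_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(Sd = 0, Nd = 0))
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- if (length(pos) == 1) list(pos) else
    if (length(pos) == 2) list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2),
                  c(3,2,1)), function(o) pos[o])
  paths <- lapply(perms, function(order) {
    cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      a1 <- .GC[[cur]]; a2 <- .GC[[nxt]]
      if (a2 == "*" && nxt != c2) ok <- FALSE
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, ok = ok)
  })
  use <- Filter(function(x) x$ok, paths)
  if (!length(use)) use <- paths
  c(Sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    Nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

#' NG86 dN/dS for one pair of in-frame codon sequences
#'
#' Counts synonymous and nonsynonymous sites and differences (Nei-Gojobori
#' 1986), applies the Jukes-Cantor correction to the proportions and
#' returns dN/dS. Terminal stop codons are ignored.
#'
#' @param s1,s2 DNA sequences of equal length, in frame
#' @return list(S, N, Sd, Nd, pS, pN, dS, dN, omega)
#' @export
ng86_pair <- function(s1, s2) {
  cod1 <- codon_split(s1); cod2 <- codon_split(s2)
  stopifnot(length(cod1) == length(cod2))
  keep <- .GC[cod1] != "*" & .GC[cod2] != "*" &
    !is.na(.GC[cod1]) & !is.na(.GC[cod2])
  cod1 <- cod1[keep]; cod2 <- cod2[keep]
  sites1 <- rowSums(vapply(cod1, ng86_sites, numeric(2)))
  sites2 <- rowSums(vapply(cod2, ng86_sites, numeric(2)))
  S <- (sites1["S"] + sites2["S"]) / 2
  N <- (sites1["N"] + sites2["N"]) / 2
  dif <- rowSums(vapply(seq_along(cod1),
                        function(i) ng86_diffs(cod1[i], cod2[i]),
                        numeric(2)))
  pS <- unname(dif["Sd"] / S); pN <- unname(dif["Nd"] / N)
  jc <- function(p) if (is.nan(p) || p >= 0.75) NA_real_ else
    -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  omega <- if (is.na(dS) || is.na(dN)) NA_real_ else
    if (dS == 0 && dN == 0) NA_real_ else
      if (dS == 0) Inf else dN / dS
  list(S = unname(S), N = unname(N), Sd = unname(dif["Sd"]),
       Nd = unname(dif["Nd"]), pS = unname(pS), pN = unname(pN),
       dS = dS, dN = dN, omega = omega)
}

#' Per-OGG pairwise dN/dS estimate
#'
#' Median of pairwise NG86 omega values over all member pairs; pairs with
#' dS = 0 (or saturated distances) are excluded. Defined only for OGGs with
#' at least `min_members` in-frame coding sequences.
#'
#' @param codon_seqs DNAStringSet of in-frame CDSs (equal lengths; the
#'   simulator's intact genes satisfy this)
#' @param min_members minimum member count (default 3)
#' @return list(omega, n_pairs, flagged) where `flagged` is TRUE when no
#'   usable pair exists
#' @export
pairwise_omega <- function(codon_seqs, min_members = 3L) {
  k <- length(codon_seqs)
  if (k < min_members) {
    return(list(omega = NA_real_, n_pairs = 0L, flagged = TRUE))
  }
  pairs <- utils::combn(k, 2)
  om <- vapply(seq_len(ncol(pairs)), function(j) {
    ng86_pair(codon_seqs[[pairs[1, j]]], codon_seqs[[pairs[2, j]]])$omega
  }, numeric(1))
  om <- om[is.finite(om)]
  if (!length(om)) return(list(omega = NA_real_, n_pairs = 0L,
                               flagged = TRUE))
  list(omega = stats::median(om), n_pairs = length(om), flagged = FALSE)
}

#' Correlations of per-OGG omega with repertoire dynamics
#'
#' Joins an omega table with per-OGG intact counts and gain/loss event
#' totals and reports Pearson correlations (omega vs intact count, vs
#' gains, vs losses) plus a Class I vs Class II Mann-Whitney comparison
#' when class labels are present.
#'
#' @param omega_tab data frame (ogg, omega); NA omegas dropped
#' @param ogg_stats data frame (ogg, intact, gains, losses, optionally
#'   class)
#' @return list of correlation results and optional `class_test`
#' @export
omega_correlates <- function(omega_tab, ogg_stats) {
  d <- merge(omega_tab, ogg_stats, by = "ogg")
  d <- d[is.finite(d$omega), ]
  if (nrow(d) < 3) stop("insufficient overlap between omega and OGG tables")
  res <- list(
    omega_vs_intact = tryCatch(pearson(d$omega, d$intact),
                               error = function(e) list(r = NA, p = NA)),
    omega_vs_gains = tryCatch(pearson(d$omega, d$gains),
                              error = function(e) list(r = NA, p = NA)),
    omega_vs_losses = tryCatch(pearson(d$omega, d$losses),
                               error = function(e) list(r = NA, p = NA)),
    n = nrow(d))
  if ("class" %in% names(d) && length(unique(d$class)) == 2) {
    cls <- sort(unique(d$class))
    res$class_test <- mann_whitney(d$omega[d$class == cls[1]],
                                   d$omega[d$class == cls[2]])
  }
  res
}

#' Per-species repertoire summary
#'
#' Counts intact genes, pseudogenes and truncated genes per species, the
#' pseudogene proportion (pseudogenes over all OR genes, truncated genes
#' included in the denominator) and the number of OGGs with intact members.
#'
#' @param calls gene-call data frame (species, gene_id, status)
#' @param ogg_table OGG membership table (ogg_name, species, gene_id,
#'   status); optional
#' @param habitats data frame (species, habitat); optional
#' @return data frame per species
#' @export
repertoire_summary <- function(calls, ogg_table = NULL, habitats = NULL) {
  sp <- sort(unique(calls$species))
  cnt <- function(st) vapply(sp, function(s)
    sum(calls$species == s & calls$status == st), integer(1))
  out <- data.frame(species = sp,
                    intact = cnt("intact"),
                    pseudogene = cnt("pseudogene"),
                    truncated = cnt("truncated"),
                    row.names = NULL, stringsAsFactors = FALSE)
  tot <- out$intact + out$pseudogene + out$truncated
  out$pseudogene_proportion <- ifelse(tot > 0, out$pseudogene / tot, NA)
  if (!is.null(ogg_table)) {
    tab <- ogg_table[ogg_table$status == "intact", ]
    out$ogg_count <- vapply(sp, function(s)
      length(unique(tab$ogg_name[tab$species == s])), integer(1))
  }
  if (!is.null(habitats)) {
    out$habitat <- habitats$habitat[match(out$species, habitats$species)]
  }
  out
}
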