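# Class I/II assignment and orthologous gene group (OGG) construction.
#
# Intact genes are clustered by Markov clustering (MCL) of a normalized
# similarity graph; leftover singletons are re-examined on a bootstrapped
# neighbor-joining tree (Poisson distances) rooted with non-OR GPCR
# outgroups, and clades with bootstrap support > 70 become additional
# OGGs. Non-intact genes join the OGG of their best-scoring intact hit.
# OGGs are named OGG<class>-<rank> by decreasing intact-member count.

#' Poisson-corrected distance between two aligned proteins
#'
#' `d = -ln(1 - p)` where p is the fraction of differing sites among
#' columns where neither sequence has a gap. p = 1 maps to a large finite
#' sentinel (50) so downstream tree building stays defined.
#'
#' @param a,b aligned sequences of equal length (characters; `-` for gaps)
#' @return non-negative distance
#' @export
poisson_distance <- function(a, b) {
  ca <- strsplit(as.character(a), "")[[1]]
  cb <- strsplit(as.character(b), "")[[1]]
  stopifnot(length(ca) == length(cb))
  use <- ca != "-" & cb != "-"
  if (!any(use)) stop("no aligned (gap-free) sites between the pair")
  p <- mean(ca[use] != cb[use])
  if (p >= 1) return(50)
  -log(1 - p)
}

#' Poisson-correct a matrix of p-distances
#'
#' @param p symmetric matrix of site-difference fractions
#' @return matrix of `-ln(1 - p)` with p >= 1 capped at sentinel 50
#' @export
poisson_distance_matrix <- function(p) {
  d <- -log(pmax(1 - p, 0))
  d[!is.finite(d)] <- 50
  d[p >= 1] <- 50
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via `ape::nj`, deterministic for a
#' fixed matrix). Fewer than 3 taxa yield a trivial star tree.
#'
#' @param D symmetric distance matrix with dimnames
#' @return an `ape::phylo`
#' @export
build_nj_tree <- function(D) {
  n <- nrow(D)
  if (n < 2) stop("need at least 2 taxa")
  if (n == 2) {
    txt <- sprintf("(%s:%f,%s:%f);", rownames(D)[1], D[1, 2] / 2,
                   rownames(D)[2], D[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  ape::nj(as.dist(D))
}

# stack sequences into a character matrix; unequal lengths are projected
# onto the longest sequence by pairwise alignment (insertions relative to
# the reference are dropped) -- an internal star-alignment stand-in for a
# full multiple alignment, adequate for distance and bootstrap resampling
star_align <- function(seqs) {
  widths <- Biostrings::nchar(seqs)
  n <- length(seqs)
  if (length(unique(widths)) == 1L) {
    m <- do.call(rbind, strsplit(as.character(seqs), ""))
    rownames(m) <- names(seqs)
    return(m)
  }
  ref_i <- order(-widths, names(seqs))[1]
  ref <- seqs[[ref_i]]
  ref_len <- widths[ref_i]
  m <- matrix("-", nrow = n, ncol = ref_len,
              dimnames = list(names(seqs), NULL))
  for (i in seq_len(n)) {
    if (i == ref_i) { m[i, ] <- strsplit(as.character(ref), "")[[1]]; next }
    pa <- Biostrings::pairwiseAlignment(
      ref, seqs[[i]], type = "global-local",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    ref_pos <- cumsum(ap != "-")
    keep <- ap != "-"
    m[i, ref_pos[keep]] <- as_[keep]
  }
  m
}

aln_pdist <- function(m) {
  n <- nrow(m)
  p <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    use <- m[i, ] != "-" & m[j, ] != "-"
    p[i, j] <- p[j, i] <- if (any(use)) mean(m[i, use] != m[j, use]) else 1
  }
  p
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the NJ tree on Poisson distances from an alignment matrix, then
#' resamples alignment columns with replacement, rebuilds the tree per
#' replicate and reports, for each internal node, the percentage of
#' replicates containing its bipartition.
#'
#' @param alnmat character matrix (sequences x columns) or AAStringSet
#'   (stacked via the internal star alignment)
#' @param replicates bootstrap replicate count (0 flags supports as NA)
#' @param seed RNG seed for the column resampling
#' @return list(tree, support (numeric per internal node, percent),
#'   replicates)
#' @export
bootstrap_support <- function(alnmat, replicates = 100L, seed = 1L) {
  if (!is.matrix(alnmat)) alnmat <- star_align(alnmat)
  if (ncol(alnmat) < 2) stop("alignment must have at least 2 columns")
  ref <- build_nj_tree(poisson_distance_matrix(aln_pdist(alnmat)))
  if (replicates < 1) {
    return(list(tree = ref, support = rep(NA_real_, ref$Nnode),
                replicates = 0L))
  }
  boots <- with_seed(seed, {
    lapply(seq_len(replicates), function(b) {
      cols <- sample.int(ncol(alnmat), replace = TRUE)
      build_nj_tree(poisson_distance_matrix(aln_pdist(
        alnmat[, cols, drop = FALSE])))
    })
  })
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  list(tree = ref, support = 100 * counts / replicates,
       replicates = replicates)
}

# tip labels under each internal node of a rooted phylo
clade_tips <- function(phy) {
  ntip <- ape::Ntip(phy)
  res <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) res[[i]] <- phy$tip.label[i]
  for (e in ape::postorder(phy)) {
    p <- phy$edge[e, 1]; c_ <- phy$edge[e, 2]
    res[[p]] <- c(res[[p]], res[[c_]])
  }
  res
}

#' Assign Class I / Class II labels by anchored tree placement
#'
#' Builds an NJ tree (Poisson distances) over the genes plus the labeled
#' anchor references and assigns each gene the class of the anchor it
#' joins, operationalized as the patristically nearest anchor leaf on the
#' tree (deterministic; ties favor Class I, the basal class).
#'
#' @param genes AAStringSet
#' @param anchors an `or_reference_set` with `class` labels
#' @return character vector of class labels named by gene id
#' @export
assign_class <- function(genes, anchors) {
  if (!length(anchors$proteins)) stop("no class anchors supplied")
  if (!length(genes)) return(stats::setNames(character(0), character(0)))
  all_seq <- c(genes, anchors$proteins)
  ids <- c(paste0("g|", names(genes)), paste0("a|", names(anchors$proteins)))
  names(all_seq) <- ids
  if (length(all_seq) < 4) {
    # too few leaves for a meaningful tree: nearest anchor by identity
    out <- vapply(seq_along(genes), function(i) {
      d <- vapply(seq_along(anchors$proteins), function(j)
        1 - protein_identity(genes[[i]], anchors$proteins[[j]]), numeric(1))
      unname(anchors$class[which.min(d)])
    }, character(1))
    return(stats::setNames(out, names(genes)))
  }
  simm <- protein_similarity_matrix(all_seq)$identity
  D <- poisson_distance_matrix(1 - simm)
  tree <- build_nj_tree(D)
  pat <- stats::cophenetic(tree)
  anchor_ids <- paste0("a|", names(anchors$proteins))
  out <- vapply(names(genes), function(g) {
    d <- pat[paste0("g|", g), anchor_ids]
    best <- min(d)
    cand <- anchors$class[which(d <= best + 1e-12)]
    if ("I" %in% cand) "I" else unname(cand[1])
  }, character(1))
  stats::setNames(out, names(genes))
}

#' Markov clustering of a similarity graph
#'
#' Plain MCL: column-normalize the (self-looped) adjacency matrix, then
#' alternate expansion (matrix square) and inflation (elementwise power
#' then renormalization) until convergence. Clusters are the connected
#' components of the converged nonzero structure.
#'
#' @param adj symmetric non-negative similarity matrix with dimnames
#' @param inflation inflation exponent (default 1.5)
#' @param max_iter,tol iteration controls
#' @return list of character vectors (cluster members), ordered by
#'   decreasing size then lexicographic first member
#' @export
mcl_cluster <- function(adj, inflation = 1.5, max_iter = 100L, tol = 1e-6) {
  stopifnot(nrow(adj) == ncol(adj))
  n <- nrow(adj)
  if (n == 0) return(list())
  M <- adj
  diag(M) <- pmax(diag(M), 1e-6)
  norm_cols <- function(m) sweep(m, 2, pmax(colSums(m), 1e-300), "/")
  M <- norm_cols(M)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- norm_cols(M2^inflation)
    M2[M2 < 1e-9] <- 0
    M2 <- norm_cols(M2)
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  # connected components of the symmetrized support
  S <- (M + t(M)) > 1e-8
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      stack <- c(stack, which(S[v, ] & is.na(comp)))
    }
  }
  cl <- split(rownames(adj), comp)
  cl <- lapply(cl, sort)
  cl[order(-lengths(cl), vapply(cl, `[`, character(1), 1))]
}

#' Cluster intact OR proteins into OGGs
#'
#' All-vs-all normalized similarity scores (BLOSUM62 alignment score over
#' the geometric mean of self-scores) are thresholded into a graph and
#' clustered with MCL. Clusters with >= 2 members become OGGs; the rest
#' are singletons for [place_singletons()].
#'
#' @param proteins AAStringSet of intact genes
#' @param inflation MCL inflation (default 1.5)
#' @param sim_threshold minimum normalized score for a graph edge
#'   (default 0.4)
#' @return list(clusters = list of member-id vectors (size >= 2),
#'   singletons = character vector, similarity = the similarity matrices)
#' @export
cluster_oggs <- function(proteins, inflation = 1.5, sim_threshold = 0.4) {
  if (!length(proteins)) {
    return(list(clusters = list(), singletons = character(0),
                similarity = NULL))
  }
  simm <- protein_similarity_matrix(proteins)
  adj <- simm$norm_score
  adj[adj < sim_threshold] <- 0
  cl <- mcl_cluster(adj, inflation)
  multi <- cl[lengths(cl) >= 2]
  singles <- sort(unlist(cl[lengths(cl) < 2], use.names = FALSE))
  list(clusters = multi, singletons = singles, similarity = simm)
}

#' Group leftover singletons into OGGs by supported clades
#'
#' Builds a bootstrapped NJ tree over the singletons plus non-OR GPCR
#' outgroups (used to root), and turns every maximal clade consisting only
#' of singletons with bootstrap support strictly greater than
#' `support_floor` into a new OGG; remaining genes stay single-gene OGGs.
#'
#' @param singletons AAStringSet
#' @param outgroups AAStringSet of non-OR GPCRs
#' @param support_floor merge threshold, strict (default 70)
#' @param replicates bootstrap replicates (default 100)
#' @param seed RNG seed
#' @return list of character vectors (each a new OGG's member ids)
#' @export
place_singletons <- function(singletons, outgroups, support_floor = 70,
                             replicates = 100L, seed = 1L) {
  ids <- names(singletons)
  if (length(singletons) < 2L) return(lapply(ids, identity))
  all_seq <- c(singletons, outgroups)
  alnmat <- star_align(all_seq)
  bs <- bootstrap_support(alnmat, replicates, seed)
  ref <- bs$tree
  out_ids <- intersect(names(outgroups), ref$tip.label)
  if (length(out_ids)) {
    ref <- ape::root(ref, outgroup = out_ids[1], resolve.root = TRUE)
  }
  # bipartition support of the rooted tree's clades, counted against the
  # bootstrap replicates directly
  support <- if (bs$replicates > 0) {
    boots <- with_seed(seed, {
      lapply(seq_len(bs$replicates), function(b) {
        cols <- sample.int(ncol(alnmat), replace = TRUE)
        build_nj_tree(poisson_distance_matrix(aln_pdist(
          alnmat[, cols, drop = FALSE])))
      })
    })
    counts <- ape::prop.clades(ref, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0
    100 * counts / bs$replicates
  } else rep(NA_real_, ref$Nnode)

  tips_by_node <- clade_tips(ref)
  ntip <- ape::Ntip(ref)
  merged <- character(0)
  groups <- list()
  # larger clades first => maximal supported clades win
  node_order <- (ntip + 1L):(ntip + ref$Nnode)
  node_order <- node_order[order(-lengths(tips_by_node[node_order]))]
  for (v in node_order) {
    tips <- tips_by_node[[v]]
    if (!all(tips %in% ids)) next
    if (length(tips) < 2) next
    if (any(tips %in% merged)) next
    sup <- support[v - ntip]
    if (!is.na(sup) && sup > support_floor) {
      groups[[length(groups) + 1L]] <- sort(tips)
      merged <- c(merged, tips)
    }
  }
  rest <- setdiff(ids, merged)
  c(groups, lapply(rest, identity))
}

#' Assign non-intact genes to the OGG of their best intact hit
#'
#' Each pseudogene / truncated gene's (conceptually translated) sequence is
#' compared against all intact genes (amino-acid k-mer prescreen, then
#' local alignment of the top candidates); it joins the OGG of the single
#' best-scoring intact gene. Ties break by higher identity, then
#' lexicographic gene id. Sequences with no scoring hit are reported
#' unassigned (NA).
#'
#' @param nonintact_proteins AAStringSet (translated regions; X for stops)
#' @param intact_proteins AAStringSet
#' @param ogg_of named character vector: intact gene id -> OGG name
#' @param min_score minimum raw alignment score to accept (default 50)
#' @param top_k candidates aligned after the k-mer prescreen (default 5)
#' @return named character vector: non-intact gene id -> OGG name or NA
#' @export
assign_nonintact <- function(nonintact_proteins, intact_proteins, ogg_of,
                             min_score = 50, top_k = 5L) {
  out <- stats::setNames(rep(NA_character_, length(nonintact_proteins)),
                         names(nonintact_proteins))
  if (!length(nonintact_proteins) || !length(intact_proteins)) return(out)
  int_codes <- lapply(seq_along(intact_proteins), function(i)
    unique(aa_kmer_codes(as.character(intact_proteins[[i]]))))
  for (i in seq_along(nonintact_proteins)) {
    codes <- unique(aa_kmer_codes(as.character(nonintact_proteins[[i]])))
    shared <- vapply(int_codes, function(qc) sum(qc %in% codes), numeric(1))
    cand <- order(-shared, names(intact_proteins))[seq_len(
      min(top_k, length(intact_proteins)))]
    cand <- cand[shared[cand] > 0]
    if (!length(cand)) next
    best_score <- -Inf; best_ident <- -Inf; best_id <- NA_character_
    for (j in cand) {
      pa <- Biostrings::pairwiseAlignment(
        nonintact_proteins[[i]], intact_proteins[[j]], type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
      sc <- Biostrings::score(pa)
      idp <- Biostrings::pid(pa, type = "PID1")
      id <- names(intact_proteins)[j]
      better <- sc > best_score ||
        (sc == best_score && (idp > best_ident ||
                                (idp == best_ident && id < best_id)))
      if (better) { best_score <- sc; best_ident <- idp; best_id <- id }
    }
    if (best_score >= min_score) out[i] <- unname(ogg_of[best_id])
  }
  out
}

#' Name OGGs by class and size rank
#'
#' Within each class, OGGs are ranked by decreasing intact-member count
#' (ties: higher mean pairwise similarity, then lexicographically smallest
#' member id) and named `OGG1-<rank>` (Class I) or `OGG2-<rank>`
#' (Class II).
#'
#' @param members list of character vectors (intact member ids per OGG)
#' @param class character vector, class per OGG ("I"/"II")
#' @param mean_similarity numeric vector per OGG (NA allowed)
#' @return character vector of names, parallel to `members`
#' @export
name_oggs <- function(members, class, mean_similarity = NULL) {
  n <- length(members)
  if (is.null(mean_similarity)) mean_similarity <- rep(NA_real_, n)
  sizes <- lengths(members)
  first_id <- vapply(members, function(m) sort(m)[1], character(1))
  nm <- character(n)
  for (cl in unique(class)) {
    idx <- which(class == cl)
    key <- order(-sizes[idx],
                 -ifelse(is.na(mean_similarity[idx]), -Inf,
                         mean_similarity[idx]),
                 first_id[idx])
    prefix <- if (cl == "I") "OGG1" else "OGG2"
    nm[idx[key]] <- sprintf("%s-%d", prefix, seq_along(idx))
  }
  nm
}

#' OGG census: component counts and mean size
#'
#' @param ogg_table data frame (ogg_name, gene_id, status); intact members
#'   define OGG sizes
#' @return list(n_multi, n_singleton, n_total, n_intact_genes,
#'   mean_multi_size)
#' @export
ogg_census <- function(ogg_table) {
  tab <- ogg_table[ogg_table$status == "intact", ]
  sizes <- table(tab$ogg_name)
  n_multi <- sum(sizes >= 2)
  n_single <- sum(sizes == 1)
  list(n_multi = n_multi, n_singleton = n_single,
       n_total = n_multi + n_single,
       n_intact_genes = sum(sizes),
       mean_multi_size = if (n_multi > 0)
         sum(sizes[sizes >= 2]) / n_multi else NA_real_)
}

#' Full repertoire classification
#'
#' Runs class assignment, MCL clustering, singleton placement, OGG naming
#' and non-intact assignment over a combined multi-species call set.
#'
#' @param calls gene-call data frame with columns species, gene_id,
#'   status, protein (as produced by [mine_genome()], rows of all species
#'   concatenated)
#' @param anchors an `or_reference_set` with class labels
#' @param outgroups AAStringSet of non-OR GPCRs
#' @param inflation,sim_threshold MCL graph parameters
#' @param support_floor,replicates,seed singleton-placement parameters
#' @return list(ogg_table, gene_class, ogg_names, members, census)
#' @export
classify_repertoire <- function(calls, anchors, outgroups,
                                inflation = 1.5, sim_threshold = 0.4,
                                support_floor = 70, replicates = 100L,
                                seed = 1L) {
  intact <- calls[calls$status == "intact", ]
  nonint <- calls[calls$status %in% c("pseudogene", "truncated"), ]
  proteins <- Biostrings::AAStringSet(
    stats::setNames(intact$protein, intact$gene_id))
  gene_class <- assign_class(proteins, anchors)

  cl <- cluster_oggs(proteins, inflation, sim_threshold)
  singles <- Biostrings::AAStringSet(
    stats::setNames(intact$protein[match(cl$singletons, intact$gene_id)],
                    cl$singletons))
  extra <- place_singletons(singles, outgroups, support_floor,
                            replicates, seed)
  members <- c(cl$clusters, extra)

  ogg_class <- vapply(members, function(m) {
    cls <- gene_class[m]
    if (sum(cls == "I") > sum(cls == "II")) "I" else "II"
  }, character(1))
  mean_sim <- vapply(members, function(m) {
    if (length(m) < 2 || is.null(cl$similarity)) return(NA_real_)
    sub <- cl$similarity$identity[m, m, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  ogg_names <- name_oggs(members, ogg_class, mean_sim)

  ogg_of <- stats::setNames(rep(ogg_names, lengths(members)),
                            unlist(members, use.names = FALSE))
  rows <- data.frame(ogg_name = unname(ogg_of[intact$gene_id]),
                     class = unname(ogg_class[match(
                       unname(ogg_of[intact$gene_id]), ogg_names)]),
                     species = intact$species, gene_id = intact$gene_id,
                     status = "intact", stringsAsFactors = FALSE)
  if (nrow(nonint)) {
    ni_prot <- Biostrings::AAStringSet(
      stats::setNames(nonint$protein, nonint$gene_id))
    ni_ogg <- assign_nonintact(ni_prot, proteins, ogg_of)
    ni_rows <- data.frame(ogg_name = unname(ni_ogg),
                          class = unname(ogg_class[match(
                            unname(ni_ogg), ogg_names)]),
                          species = nonint$species,
                          gene_id = nonint$gene_id,
                          status = nonint$status, stringsAsFactors = FALSE)
    rows <- rbind(rows, ni_rows)
  }
  list(ogg_table = rows, gene_class = gene_class, ogg_names = ogg_names,
       members = stats::setNames(members, ogg_names),
       census = ogg_census(rows),
       mean_similarity = stats::setNames(mean_sim, ogg_names))
}
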