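# Forward simulation of OR family (OGG content) evolution on a dated tree.
#
# Each gene, independently, duplicates at rate beta and dies at rate delta
# per MY (a linear birth-death process), so the expected total count obeys
# dn/dt = n (beta - delta) and the gain/loss trajectories obey
# dg/dt = n(t) beta, dl/dt = n(t) delta -- exactly the growth model whose
# closed-form inversion the rate estimator implements. Events are drawn by
# a Gillespie algorithm (exponential waiting times on the total intensity),
# which makes the estimator's model assumptions literally true in the
# simulated data.

#' Simulation configuration
#'
#' Bundles the dated species tree, the ancestral repertoire size, per-branch
#' gain/loss rates and genome-emission parameters. Defaults mirror the
#' study conditions of marine-vs-terrestrial OR comparisons: 830 ancestral
#' OGGs and terrestrial-like baseline rates beta = delta = 0.003 per gene
#' per MY; marine-like loss regimes are expressed through `rate_overrides`.
#'
#' @param tree a `dated_tree` (default [mammal_like_tree()])
#' @param ancestral_family_count number of OGGs (one gene each) at the root
#' @param beta,delta baseline gain/loss rates, per gene per MY, applied to
#'   every branch not listed in `rate_overrides`
#' @param rate_overrides optional data frame (branch, beta, delta); branch
#'   labels as in [branch_table()] (species names for terminal branches)
#' @param contig_count,contig_length contigs per species genome and their
#'   nominal length in bp
#' @param gc_fraction GC content of intergenic flanking sequence
#' @param decoy_gpcr_count non-OR GPCR decoy genes planted per species
#' @param pseudogenization_fraction,truncation_fraction fractions of each
#'   species' surviving genes emitted as pseudogenes / truncated genes
#'   (must sum to at most 1)
#' @param mut_rate nucleotide substitution rate per site per MY applied
#'   along each species' root-to-tip path
#' @param seed master integer seed; identical configs are bit-reproducible
#' @return object of class `sim_config`
#' @export
sim_config <- function(tree = mammal_like_tree(),
                       ancestral_family_count = 830L,
                       beta = 0.003, delta = 0.003,
                       rate_overrides = NULL,
                       contig_count = 30L, contig_length = 30000L,
                       gc_fraction = 0.42,
                       decoy_gpcr_count = 8L,
                       pseudogenization_fraction = 0.30,
                       truncation_fraction = 0.05,
                       mut_rate = 5e-4,
                       seed = 1L) {
  stopifnot(inherits(tree, "dated_tree"),
            ancestral_family_count >= 1,
            beta >= 0, delta >= 0,
            pseudogenization_fraction >= 0, truncation_fraction >= 0,
            pseudogenization_fraction + truncation_fraction <= 1,
            mut_rate >= 0)
  if (!is.null(rate_overrides)) {
    stopifnot(all(c("branch", "beta", "delta") %in% names(rate_overrides)))
    if (any(rate_overrides$beta < 0) || any(rate_overrides$delta < 0)) {
      stop("negative gain/loss rates are not allowed")
    }
    known <- branch_table(tree)$branch
    bad <- setdiff(rate_overrides$branch, known)
    if (length(bad)) stop("unknown branches in rate_overrides: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(tree = tree,
                 ancestral_family_count = as.integer(ancestral_family_count),
                 beta = beta, delta = delta, rate_overrides = rate_overrides,
                 contig_count = as.integer(contig_count),
                 contig_length = as.integer(contig_length),
                 gc_fraction = gc_fraction,
                 decoy_gpcr_count = as.integer(decoy_gpcr_count),
                 pseudogenization_fraction = pseudogenization_fraction,
                 truncation_fraction = truncation_fraction,
                 mut_rate = mut_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Per-branch rates implied by a configuration
#'
#' @param config a `sim_config`
#' @return [branch_table()] of the tree with beta and delta columns
#' @export
per_branch_rates <- function(config) {
  bt <- branch_table(config$tree)
  bt$beta <- config$beta
  bt$delta <- config$delta
  ov <- config$rate_overrides
  if (!is.null(ov)) {
    idx <- match(ov$branch, bt$branch)
    bt$beta[idx] <- ov$beta
    bt$delta[idx] <- ov$delta
  }
  bt
}

#' Marine/terrestrial rate overrides
#'
#' Convenience builder for the contrast studied in marine-mammal OR
#' evolution: elevated loss (and optionally depressed gain) on the terminal
#' branches of marine species.
#'
#' @param habitats data frame (species, habitat) as from [mammal_habitats()]
#' @param beta,delta rates applied to marine terminal branches (defaults
#'   0.0004 and 0.017 per gene per MY, the marine-like regime)
#' @return data frame usable as `rate_overrides` in [sim_config()]
#' @export
marine_rate_overrides <- function(habitats = mammal_habitats(),
                                  beta = 4e-4, delta = 0.017) {
  sp <- habitats$species[habitats$habitat == "marine"]
  data.frame(branch = sp, beta = beta, delta = delta,
             stringsAsFactors = FALSE)
}

# Gillespie realisation of one branch. counts: integer vector per OGG.
# Returns new counts plus per-OGG gain/loss tallies and totals.
sim_branch <- function(counts, beta, delta, T) {
  gains <- integer(length(counts))
  losses <- integer(length(counts))
  if (T > 0 && (beta + delta) > 0) {
    t <- 0
    repeat {
      n <- sum(counts)
      if (n == 0L) break
      t <- t + stats::rexp(1L, n * (beta + delta))
      if (t > T) break
      ogg <- sample.int(length(counts), 1L, prob = counts)
      if (stats::runif(1L) < beta / (beta + delta)) {
        counts[ogg] <- counts[ogg] + 1L
        gains[ogg] <- gains[ogg] + 1L
      } else {
        counts[ogg] <- counts[ogg] - 1L
        losses[ogg] <- losses[ogg] + 1L
      }
    }
  }
  list(counts = counts, gains = gains, losses = losses,
       G = sum(gains), L = sum(losses))
}

#' Simulate OR family evolution on the species tree
#'
#' Evolves per-OGG gene counts from the root (one gene per ancestral OGG)
#' down every branch under the per-branch birth-death rates, recording the
#' full content matrix at every node and the true per-branch event counts.
#'
#' @param config a `sim_config`
#' @return list with elements
#'   * `content`: integer matrix nodes x OGGs (rownames are node labels as
#'     in [branch_table()], plus the root)
#'   * `events`: data frame per branch (branch, parent, child, T, beta,
#'     delta, G_true, L_true)
#'   * `ogg_gains`, `ogg_losses`: integer matrices OGGs x branches
#'   * `ogg_ids`: OGG identifiers
#' @export
simulate_family_evolution <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  phy <- config$tree$phylo
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  rates <- per_branch_rates(config)
  n_ogg <- config$ancestral_family_count
  ogg_ids <- sprintf("sOGG%04d", seq_len(n_ogg))

  content <- matrix(0L, nrow = nnode, ncol = n_ogg,
                    dimnames = list(node_label(phy, seq_len(nnode)), ogg_ids))
  ogg_gains <- matrix(0L, nrow = n_ogg, ncol = nrow(rates),
                      dimnames = list(ogg_ids, rates$branch))
  ogg_losses <- ogg_gains
  root <- ntip + 1L
  content[root, ] <- 1L
  events <- rates
  events$G_true <- 0L
  events$L_true <- 0L

  with_seed(derive_seed(config$seed, "family_evolution"), {
    # preorder over edges: ape's edge matrix from read.tree is already
    # parent-before-child for rooted trees, but sort defensively
    ord <- order(config$tree$ages[rates$parent], decreasing = TRUE)
    for (i in ord) {
      parent <- rates$parent[i]; child <- rates$child[i]
      res <- sim_branch(content[parent, ], rates$beta[i], rates$delta[i],
                        rates$T[i])
      content[child, ] <- res$counts
      ogg_gains[, i] <- res$gains
      ogg_losses[, i] <- res$losses
      events$G_true[i] <- res$G
      events$L_true[i] <- res$L
    }
  })
  list(content = content, events = events,
       ogg_gains = ogg_gains, ogg_losses = ogg_losses, ogg_ids = ogg_ids)
}

#' Tip OGG content from a family simulation
#'
#' @param sim result of [simulate_family_evolution()]
#' @param config the `sim_config` used
#' @return integer matrix species x OGGs
#' @export
tip_content <- function(sim, config) {
  tips <- config$tree$phylo$tip.label
  sim$content[tips, , drop = FALSE]
}
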