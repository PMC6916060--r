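# Dated species trees: rooted ape::phylo topology plus node ages in
# million years (MY). Tips are forced to age 0; the duration of a branch is
# T = age(parent) - age(child).

#' Construct a dated species tree
#'
#' @param phylo a rooted `ape::phylo` with branch lengths in MY
#' @param ages optional numeric vector of node ages (MY) indexed by node
#'   number (tips 1..Ntip, then internals). When omitted, ages are computed
#'   from root-to-node path lengths assuming an ultrametric tree; tips are
#'   forced to age 0.
#' @return object of class `dated_tree`: list(phylo, ages)
#' @export
dated_tree <- function(phylo, ages = NULL) {
  if (!inherits(phylo, "phylo")) stop("phylo must be an ape::phylo")
  if (!ape::is.rooted(phylo)) stop("the species tree must be rooted")
  ntip <- ape::Ntip(phylo)
  nnode <- ntip + phylo$Nnode
  if (is.null(ages)) {
    depth <- ape::node.depth.edgelength(phylo)
    ages <- max(depth) - depth
    ages[seq_len(ntip)] <- 0
  }
  if (length(ages) != nnode) stop("ages must have one entry per node")
  parent_age <- ages[phylo$edge[, 1]]
  child_age <- ages[phylo$edge[, 2]]
  if (any(parent_age <= child_age - 1e-9)) {
    stop("every parent must be older than its child")
  }
  structure(list(phylo = phylo, ages = as.numeric(ages)),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("dated_tree:", ape::Ntip(x$phylo), "tips, root age",
      round(max(x$ages), 2), "MY\n")
  invisible(x)
}

#' Per-branch table of a dated tree
#'
#' @param dt a `dated_tree`
#' @return data frame with columns parent, child (node numbers), branch
#'   (child node label: species name for terminal branches, `node<k>`
#'   otherwise), T (duration in MY), terminal (logical)
#' @export
branch_table <- function(dt) {
  phy <- dt$phylo
  ntip <- ape::Ntip(phy)
  child <- phy$edge[, 2]
  parent <- phy$edge[, 1]
  lab <- ifelse(child <= ntip, phy$tip.label[child],
                paste0("node", child))
  data.frame(parent = parent, child = child, branch = lab,
             T = dt$ages[parent] - dt$ages[child],
             terminal = child <= ntip,
             stringsAsFactors = FALSE)
}

node_label <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  ifelse(node <= ntip, phy$tip.label[node], paste0("node", node))
}

#' Read a dated tree from Newick (plus optional node-age TSV)
#'
#' @param newick_path Newick file; branch lengths in MY
#' @param ages_path optional TSV with columns `node` (tip label or
#'   `node<k>`) and `age` (MY) overriding the ultrametric reconstruction
#' @return a `dated_tree`
#' @export
read_dated_tree <- function(newick_path, ages_path = NULL) {
  phy <- ape::read.tree(newick_path)
  dt <- dated_tree(phy)
  if (!is.null(ages_path)) {
    tab <- read_tsv(ages_path)
    ntip <- ape::Ntip(phy)
    labs <- node_label(phy, seq_len(ntip + phy$Nnode))
    idx <- match(tab$node, labs)
    if (anyNA(idx)) stop("unknown node labels in ages file")
    ages <- dt$ages
    ages[idx] <- tab$age
    dt <- dated_tree(phy, ages)
  }
  dt
}

#' Write a dated tree as Newick
#'
#' Branch lengths encode the age differences, so the Newick file alone
#' round-trips through [read_dated_tree()].
#'
#' @param dt a `dated_tree`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_dated_tree <- function(dt, path) {
  ape::write.tree(dt$phylo, path)
  invisible(path)
}

.MAMMAL_NEWICK <- paste0(
  "(opossum:160,(((elephant:60,manatee:60):15,",
  "(golden_mole:69,elephant_shrew:69):6):24,",
  "((alpaca:64,(pig:62,((cattle:25,goat:25):30,",
  "((bowhead_whale:25,minke_whale:25):11,(sperm_whale:33,",
  "(river_dolphin:28,(beluga:19,(killer_whale:13,bottlenose_dolphin:13):6)",
  ":9):5):3):19):7):2):16,",
  "(horse:78,(dog:45,(ferret:42,(panda:40,((weddell_seal:15,monk_seal:15)",
  ":7,walrus:22):18):2):3):33):2):19):61);")

.MARINE_SPECIES <- c("manatee", "bowhead_whale", "minke_whale", "sperm_whale",
                     "river_dolphin", "beluga", "killer_whale",
                     "bottlenose_dolphin", "weddell_seal", "monk_seal",
                     "walrus")

#' A 23-tip dated mammal-like species tree
#'
#' A synthetic ultrametric tree mirroring the study design of marine-mammal
#' OR comparisons: 11 marine tips from three independent aquatic lineages
#' (cetaceans, pinnipeds, a sirenian), 11 related terrestrial tips and a
#' marsupial outgroup, with divergence-time-like node ages in MY (root 160
#' MY). Ages are round figures in the range of published divergence-time
#' estimates, not a lookup of any database.
#'
#' @return a `dated_tree`
#' @export
mammal_like_tree <- function() {
  dated_tree(ape::read.tree(text = .MAMMAL_NEWICK))
}

#' Habitat metadata for [mammal_like_tree()]
#'
#' @return data frame with columns species, habitat
#'   (marine / terrestrial / outgroup)
#' @export
mammal_habitats <- function() {
  tips <- mammal_like_tree()$phylo$tip.label
  habitat <- ifelse(tips %in% .MARINE_SPECIES, "marine",
                    ifelse(tips == "opossum", "outgroup", "terrestrial"))
  data.frame(species = tips, habitat = habitat, stringsAsFactors = FALSE)
}
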