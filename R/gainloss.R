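# Ancestral OGG content reconstruction, per-branch gain/loss counting and
# closed-form estimation of gain (beta) and loss (delta) rates.
#
# Model: on a branch of duration T starting from A0 genes, gains g(t) and
# losses l(t) accumulate as dg/dt = (A0 + g - l) beta and
# dl/dt = (A0 + g - l) delta with constant per-branch rates. Writing
# G = g(T), L = l(T), the inversion is
#   beta  = G / ((G - L) T) * ln(1 + (G - L) / A0)
#   delta = L / ((G - L) T) * ln(1 + (G - L) / A0)
# with the continuous limit beta = G/(A0 T), delta = L/(A0 T) at G = L.

#' Reconstruct ancestral OGG content on a dated tree
#'
#' Presence/absence follows Dollo parsimony (an OGG arises once, at the
#' MRCA of the tips carrying it, and may only be lost afterwards); copy
#' numbers on the present nodes follow linear-cost (unit per gene copy)
#' parsimony, computed by the interval method on the (binary) species tree.
#' Ambiguities are resolved deterministically: each node takes the value in
#' its optimal interval closest to its parent's value, and the root takes
#' the smallest optimal value (so expansions are dated as late as the data
#' allow).
#'
#' @param tip_counts integer matrix species x OGGs (rows must cover all
#'   tips of the tree)
#' @param dt a `dated_tree`
#' @return integer matrix nodes x OGGs; rownames are species names for tips
#'   and `node<k>` for internal nodes
#' @export
reconstruct_ancestral <- function(tip_counts, dt) {
  phy <- dt$phylo
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  if (!all(phy$tip.label %in% rownames(tip_counts))) {
    stop("tip_counts must contain a row for every tip of the tree")
  }
  tab <- tabulate(phy$edge[, 1], nbins = nnode)
  if (any(tab[tab > 0] != 2L)) {
    stop("reconstruction requires a strictly binary species tree")
  }
  n_ogg <- ncol(tip_counts)
  kids <- split(phy$edge[, 2], phy$edge[, 1])

  lo <- matrix(0, nrow = nnode, ncol = n_ogg)
  hi <- lo
  below <- matrix(FALSE, nrow = nnode, ncol = n_ogg)
  tipm <- tip_counts[phy$tip.label, , drop = FALSE]
  lo[seq_len(ntip), ] <- tipm
  hi[seq_len(ntip), ] <- tipm
  below[seq_len(ntip), ] <- tipm > 0

  # postorder: internal nodes sorted by increasing age work for dated trees
  internal <- order(dt$ages[(ntip + 1L):nnode]) + ntip
  for (v in internal) {
    ch <- kids[[as.character(v)]]
    a <- pmax(lo[ch[1], ], lo[ch[2], ])
    b <- pmin(hi[ch[1], ], hi[ch[2], ])
    lo[v, ] <- pmin(a, b)
    hi[v, ] <- pmax(a, b)
    below[v, ] <- below[ch[1], ] | below[ch[2], ]
  }

  # Dollo presence: a node carries the OGG iff it lies inside the minimal
  # subtree connecting the tips that carry it
  present <- matrix(FALSE, nrow = nnode, ncol = n_ogg)
  present[seq_len(ntip), ] <- tipm > 0
  root <- ntip + 1L
  outside <- matrix(FALSE, nrow = nnode, ncol = n_ogg)  # present tip outside
  for (v in rev(internal)) {  # preorder (root first)
    ch <- kids[[as.character(v)]]
    two_sides <- below[ch[1], ] & below[ch[2], ]
    present[v, ] <- below[v, ] & (outside[v, ] | two_sides)
    outside[ch[1], ] <- outside[v, ] | below[ch[2], ]
    outside[ch[2], ] <- outside[v, ] | below[ch[1], ]
  }

  val <- matrix(0L, nrow = nnode, ncol = n_ogg)
  val[seq_len(ntip), ] <- tipm
  v <- root
  rootval <- lo[root, ]
  rootval[present[root, ] & rootval < 1] <- 1
  rootval[!present[root, ]] <- 0
  val[root, ] <- as.integer(rootval)
  for (v in rev(internal)) {
    ch <- kids[[as.character(v)]]
    for (c_ in ch) {
      if (c_ <= ntip) next
      x <- pmin(pmax(val[v, ], lo[c_, ]), hi[c_, ])
      x[present[c_, ] & x < 1] <- 1
      x[!present[c_, ]] <- 0
      val[c_, ] <- as.integer(x)
    }
  }
  dimnames(val) <- list(node_label(phy, seq_len(nnode)), colnames(tip_counts))
  val
}

#' Count per-branch gene and OGG events
#'
#' For every branch, compares reconstructed (or simulated) content at the
#' two ends: per-OGG differences are split into gene gains
#' `G = sum(max(0, child - parent))` and losses
#' `L = sum(max(0, parent - child))`; at the OGG level, gains are OGGs that
#' grew, losses are OGGs going extinct on the branch and contractions are
#' OGGs that shrank but survived.
#'
#' @param content integer matrix nodes x OGGs as from
#'   [reconstruct_ancestral()] (or a simulation's content matrix)
#' @param dt the `dated_tree`
#' @return data frame per branch: branch, parent, child, T, A0 (genes at
#'   branch start), G, L, end (genes at branch end), ogg_parent, ogg_child
#'   (OGGs present at the two ends), ogg_gains, ogg_contractions,
#'   ogg_losses, terminal
#' @export
count_branch_events <- function(content, dt) {
  bt <- branch_table(dt)
  phy <- dt$phylo
  rows <- lapply(seq_len(nrow(bt)), function(i) {
    p <- content[node_label(phy, bt$parent[i]), ]
    c_ <- content[node_label(phy, bt$child[i]), ]
    d <- c_ - p
    data.frame(branch = bt$branch[i], parent = bt$parent[i],
               child = bt$child[i], T = bt$T[i],
               A0 = sum(p), G = sum(pmax(d, 0)), L = sum(pmax(-d, 0)),
               end = sum(c_),
               ogg_parent = sum(p > 0), ogg_child = sum(c_ > 0),
               ogg_gains = sum(d > 0),
               ogg_contractions = sum(p > c_ & c_ > 0),
               ogg_losses = sum(p > 0 & c_ == 0),
               terminal = bt$terminal[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# stable ln(1+x)/x
log1p_over_x <- function(x) {
  out <- ifelse(x == 0, 1, log1p(x) / x)
  out
}

#' Estimate gain and loss rates from branch event counts
#'
#' Applies the closed-form inversion of the constant-rate growth model (see
#' the module header) to each branch. The degenerate case G = L uses the
#' analytic limit beta = G/(A0 T). A branch losing its entire repertoire
#' (L = A0 + G) yields an infinite loss rate and is reported as `Inf` with
#' a warning; L > A0 + G is impossible under the model and is an error.
#'
#' @param counts data frame with columns branch, A0, G, L, T (as from
#'   [count_branch_events()]); `unit = "oggs"` instead uses ogg_gains /
#'   ogg_losses with A0 = ogg_parent, i.e. rates of whole-OGG turnover
#' @param unit "genes" (default; gene copies gained/lost per gene per MY)
#'   or "oggs"
#' @return the input with beta and delta columns appended
#' @export
estimate_rates <- function(counts, unit = c("genes", "oggs")) {
  unit <- match.arg(unit)
  if (unit == "oggs") {
    stopifnot(all(c("ogg_gains", "ogg_losses", "ogg_parent") %in%
                    names(counts)))
    A0 <- counts$ogg_parent; G <- counts$ogg_gains; L <- counts$ogg_losses
  } else {
    A0 <- counts$A0; G <- counts$G; L <- counts$L
  }
  T_ <- counts$T
  beta <- delta <- rep(NA_real_, length(A0))
  for (i in seq_along(A0)) {
    if (is.na(A0[i]) || A0[i] <= 0 || T_[i] <= 0) next
    x <- (G[i] - L[i]) / A0[i]
    if (x < -1) {
      stop("branch ", counts$branch[i], ": L exceeds A0 + G (L=", L[i],
           ", A0=", A0[i], ", G=", G[i], "); invalid under the growth model")
    }
    if (x == -1) {
      warning("branch ", counts$branch[i],
              ": complete repertoire loss; delta reported as Inf")
      beta[i] <- if (G[i] == 0) 0 else Inf
      delta[i] <- Inf
      next
    }
    f <- log1p_over_x(x)
    beta[i] <- G[i] / (A0[i] * T_[i]) * f
    delta[i] <- L[i] / (A0[i] * T_[i]) * f
  }
  counts$beta <- beta
  counts$delta <- delta
  counts
}

#' Forward integration of the gain/loss growth model
#'
#' Numerically integrates dg/dt = (A0 + g - l) beta,
#' dl/dt = (A0 + g - l) delta from g(0) = l(0) = 0 with `deSolve::ode`
#' (lsoda, tight tolerances). Serves as the independent oracle for the
#' closed-form estimator: `estimate_rates` applied to this output recovers
#' (beta, delta).
#'
#' @param beta,delta non-negative rates per gene per MY
#' @param A0 starting gene count
#' @param T branch duration in MY
#' @return named numeric vector c(G, L)
#' @export
ode_forward_oracle <- function(beta, delta, A0, T) {
  stopifnot(beta >= 0, delta >= 0, A0 > 0, T >= 0)
  if (T == 0) return(c(G = 0, L = 0))
  deriv <- function(t, y, parms) {
    n <- A0 + y[1] - y[2]
    list(c(n * beta, n * delta))
  }
  sol <- deSolve::ode(y = c(g = 0, l = 0), times = c(0, T), func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-12)
  c(G = unname(sol[2, "g"]), L = unname(sol[2, "l"]))
}

#' Group means of per-species gain/loss rates
#'
#' Averages terminal-branch rate estimates within habitat groups (and over
#' marine + terrestrial combined), mirroring the comparison of marine and
#' terrestrial repertoire turnover.
#'
#' @param rates data frame from [estimate_rates()] (must include `branch`
#'   and `terminal`)
#' @param habitats data frame (species, habitat)
#' @return data frame: group, n, mean_beta, mean_delta
#' @export
summarize_rates <- function(rates, habitats) {
  term <- rates[rates$terminal, ]
  term$habitat <- habitats$habitat[match(term$branch, habitats$species)]
  groups <- c("marine", "terrestrial")
  rows <- lapply(groups, function(g) {
    sub <- term[!is.na(term$habitat) & term$habitat == g, ]
    data.frame(group = g, n = nrow(sub),
               mean_beta = mean(sub$beta), mean_delta = mean(sub$delta))
  })
  sub <- term[!is.na(term$habitat) & term$habitat %in% groups, ]
  rows <- c(rows, list(data.frame(group = "all", n = nrow(sub),
                                  mean_beta = mean(sub$beta),
                                  mean_delta = mean(sub$delta))))
  out <- do.call(rbind, rows)
  if (any(out$n == 0)) warning("empty habitat group in rate summary")
  out
}

#' Per-OGG totals of gene gains and losses across all branches
#'
#' @param content nodes x OGGs matrix from [reconstruct_ancestral()]
#' @param dt the `dated_tree`
#' @return data frame (ogg, gains, losses)
#' @export
ogg_event_totals <- function(content, dt) {
  bt <- branch_table(dt)
  phy <- dt$phylo
  gains <- losses <- stats::setNames(rep(0L, ncol(content)),
                                     colnames(content))
  for (i in seq_len(nrow(bt))) {
    d <- content[node_label(phy, bt$child[i]), ] -
      content[node_label(phy, bt$parent[i]), ]
    gains <- gains + pmax(d, 0L)
    losses <- losses + pmax(-d, 0L)
  }
  data.frame(ogg = colnames(content), gains = as.integer(gains),
             losses = as.integer(losses), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-species OGG count matrix from an OGG membership table
#'
#' @param ogg_table data frame with columns ogg_name, species, gene_id and
#'   status; only intact members are counted
#' @param species character vector fixing the row order (absent species get
#'   zero rows)
#' @return integer matrix species x OGGs
#' @export
ogg_count_matrix <- function(ogg_table, species) {
  tab <- ogg_table[ogg_table$status == "intact", ]
  oggs <- sort(unique(tab$ogg_name))
  m <- matrix(0L, nrow = length(species), ncol = length(oggs),
              dimnames = list(species, oggs))
  if (nrow(tab)) {
    cnt <- table(factor(tab$species, levels = species),
                 factor(tab$ogg_name, levels = oggs))
    m[] <- as.integer(cnt)
  }
  m
}
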