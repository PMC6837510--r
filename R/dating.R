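# Neighbor-joining topology plumbing and simplified strict-clock dating.

#' Jukes-Cantor distance correction
#'
#' Maps an observed proportion of differences to an expected number of
#' substitutions per site, `d = -(3/4) log(1 - (4/3) p)`. Undefined at or
#' beyond the saturation bound `p = 3/4`.
#'
#' @param p Proportion(s) of differing sites in `[0, 0.75)`.
#' @return Corrected distance(s), `d >= p`.
#' @examples
#' jc_correct(0.1)  # ~0.10732
#' @export
jc_correct <- function(p) {
  if (any(p < 0)) stop("p must be non-negative", call. = FALSE)
  if (any(p >= 0.75)) {
    stop("saturation: p >= 0.75 has no Jukes-Cantor correction", call. = FALSE)
  }
  -0.75 * log(1 - (4 / 3) * p)
}

#' Neighbor-joining topology rooted on an outgroup
#'
#' Standard neighbor-joining agglomeration of a symmetric distance matrix,
#' rooted at the midpoint of the branch leading to the declared outgroup.
#'
#' @param distance_matrix Symmetric numeric matrix, zero diagonal, taxon
#'   dimnames, >= 3 taxa (2 taxa return the single cherry).
#' @param outgroup Outgroup taxon name; `NULL` leaves the tree unrooted.
#' @return An [ape::phylo] tree.
#' @export
nj_topology <- function(distance_matrix, outgroup = NULL) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (is.null(rownames(d))) stop("distance matrix needs taxon names", call. = FALSE)
  if (nrow(d) == 2L) {
    return(ape::read.tree(text = sprintf("(%s:%g,%s:%g);", rownames(d)[1],
                                         d[1, 2] / 2, rownames(d)[2],
                                         d[1, 2] / 2)))
  }
  tr <- ape::nj(stats::as.dist(d))
  if (is.null(outgroup)) return(tr)
  if (!outgroup %in% tr$tip.label) {
    stop("outgroup '", outgroup, "' not among taxa", call. = FALSE)
  }
  tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  # split the outgroup branch evenly around the new root
  root_node <- length(tr$tip.label) + 1L
  og_tip <- which(tr$tip.label == outgroup)
  root_edges <- which(tr$edge[, 1] == root_node)
  if (length(root_edges) == 2L) {
    total <- sum(tr$edge.length[root_edges])
    tr$edge.length[root_edges] <- total / 2
  }
  tr
}

#' Node ages of a chronogram
#'
#' Ages (time before present) of every node of an ultrametric tree, computed
#' from root-to-tip path lengths.
#'
#' @param tree Rooted [ape::phylo] with branch lengths in time units.
#' @param tol Relative tolerance for the ultrametricity check.
#' @return Numeric vector of ages indexed by node id (tips first); tip ages 0.
#' @export
node_ages <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)
  root_age <- max(depth)
  tip_depths <- depth[seq_along(tree$tip.label)]
  if (root_age > 0 && any(abs(tip_depths - root_age) > tol * root_age)) {
    stop("tree is not ultrametric", call. = FALSE)
  }
  ages <- root_age - depth
  ages[seq_along(tree$tip.label)] <- 0
  ages
}

# Pool-adjacent-violators on the tree partial order: node ages must not exceed
# parent ages. Merges a violating node into its parent's block (weighted mean)
# until consistent.
isotonic_tree_ages <- function(raw, weights, parent, nodes) {
  block <- stats::setNames(as.character(nodes), nodes)
  repeat {
    val <- tapply(raw * weights, block[as.character(nodes)], sum) /
      tapply(weights, block[as.character(nodes)], sum)
    cur <- val[block[as.character(nodes)]]
    names(cur) <- nodes
    violated <- FALSE
    for (nd in nodes) {
      p <- parent[[as.character(nd)]]
      if (is.na(p)) next
      if (cur[[as.character(nd)]] > cur[[as.character(p)]] + 1e-12) {
        block[block == block[[as.character(nd)]]] <- block[[as.character(p)]]
        violated <- TRUE
        break
      }
    }
    if (!violated) return(cur)
  }
}

#' Strict-clock least-squares chronogram fit
#'
#' Deterministic stand-in for Bayesian clock dating: given a rooted topology
#' and Jukes-Cantor-corrected neutral-site distances, each internal node's age
#' is fit by least squares against `d_ij = 2 mu t_MRCA(i,j)` — the
#' unconstrained solution is the mean pairwise distance over the node's tip
#' pairs divided by `2 mu`, then projected onto the child-age <= parent-age
#' constraints (pool-adjacent-violators on the tree order). With a root
#' calibration the relative ages are kept, the root is pinned to the
#' calibration age, and the clock rate is re-estimated as a by-product.
#'
#' @param topology Rooted [ape::phylo]; tip labels must match the matrix.
#' @param distance_matrix Symmetric matrix of JC-corrected distances
#'   (substitutions/site). Saturated (non-finite) entries are an error.
#' @param rate Strict-clock rate, substitutions/site/year.
#' @param root_calibration_age Optional root age in years.
#' @return List with `chronogram` (ultrametric [ape::phylo], branch lengths in
#'   years), `ages` (per-node, years), `rate_used` (input or re-estimated), and
#'   `residual_ss`.
#' @examples
#' d <- matrix(c(0, 0.062, 0.062, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' tr <- ape::read.tree(text = "(a:1,b:1);")
#' strict_clock_fit(tr, d, rate = 6.2e-7)$ages  # root age 50,000 years
#' @export
strict_clock_fit <- function(topology, distance_matrix, rate = 6.2e-7,
                             root_calibration_age = NULL) {
  stopifnot(inherits(topology, "phylo"))
  d <- as.matrix(distance_matrix)
  taxa <- topology$tip.label
  if (!all(taxa %in% rownames(d))) {
    stop("distance matrix missing taxa: ",
         paste(setdiff(taxa, rownames(d)), collapse = ", "), call. = FALSE)
  }
  d <- d[taxa, taxa]
  bad <- which(!is.finite(d) & row(d) != col(d), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    prs <- apply(bad, 1, function(ij) paste(taxa[ij[1]], taxa[ij[2]], sep = "-"))
    stop("saturated/undefined distances for pairs: ",
         paste(unique(prs), collapse = ", "), call. = FALSE)
  }
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  ntip <- length(taxa)
  nnode <- topology$Nnode
  internal <- ntip + seq_len(nnode)
  mrca <- ape::mrca(topology)[taxa, taxa]
  # unconstrained per-node divergence-time (in substitutions/site units)
  raw <- numeric(nnode)
  wt <- numeric(nnode)
  for (u in internal) {
    sel <- which(mrca == u & upper.tri(mrca))
    if (length(sel) == 0L) next
    raw[u - ntip] <- mean(d[sel]) / 2
    wt[u - ntip] <- length(sel)
  }
  # nodes with no tip pair (shouldn't happen in a binary rooted tree)
  if (any(wt == 0)) stop("topology has internal nodes without tip pairs",
                         call. = FALSE)
  # parent map over internal nodes
  parent <- stats::setNames(rep(NA_integer_, nnode), internal)
  for (e in seq_len(nrow(topology$edge))) {
    child <- topology$edge[e, 2]
    if (child > ntip) parent[[as.character(child)]] <- topology$edge[e, 1]
  }
  tau <- isotonic_tree_ages(raw, wt, parent, internal)  # subst/site units
  tau <- pmax(tau, 0)
  root <- ntip + 1L
  if (is.null(root_calibration_age)) {
    ages_internal <- tau / rate
    rate_used <- rate
  } else {
    if (root_calibration_age <= 0) stop("calibration must be positive",
                                        call. = FALSE)
    tau_root <- tau[[as.character(root)]]
    if (tau_root <= 0) stop("root divergence is zero; cannot calibrate",
                            call. = FALSE)
    ages_internal <- tau * (root_calibration_age / tau_root)
    rate_used <- tau_root / root_calibration_age
  }
  ages <- c(stats::setNames(rep(0, ntip), seq_len(ntip)), ages_internal)
  names(ages) <- c(seq_len(ntip), internal)
  chrono <- topology
  chrono$edge.length <- ages[as.character(topology$edge[, 1])] -
    ages[as.character(topology$edge[, 2])]
  fitted <- 2 * (rate_used * ages[as.character(mrca)])
  dim(fitted) <- dim(mrca)
  resid <- (d - fitted)[upper.tri(d)]
  list(chronogram = chrono, ages = ages, rate_used = rate_used,
       residual_ss = sum(resid^2))
}
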