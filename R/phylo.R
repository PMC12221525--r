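# Phylogenetic comparative post-processing: Brownian-motion ancestral
# states by generalized least squares, tip-minus-ancestor lineage shifts,
# and a simulation-based phylogenetically corrected ANOVA.

#' Read a dated tree from Newick
#'
#' Parses Newick text (or a file) into an `ape` phylo object and checks
#' that branch lengths are present; warns if the tree is not ultrametric
#' within tolerance, as expected for a dated tree in Myr.
#'
#' @param source Newick string or path to a Newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(source) {
  tree <- tryCatch(suppressWarnings(
    if (file.exists(source)) ape::read.tree(source)
    else ape::read.tree(text = source)),
    error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("could not parse Newick input")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    warning("tree is not ultrametric; branch lengths may not be dates")
  tree
}

# Internal: tree covariance rooted at an arbitrary node, from patristic
# distances: C_ij(r) = (d(r,i) + d(r,j) - d(i,j)) / 2 over tips i, j.
rerooted_vcv <- function(d, tips, r) {
  (outer(d[r, tips], rep(1, length(tips))) +
     outer(rep(1, length(tips)), d[r, tips]) - d[tips, tips]) / 2
}

#' Brownian-motion ancestral states by GLS
#'
#' Maximum-likelihood ancestral values at every internal node under
#' Brownian motion: each node's estimate is the generalized-least-squares
#' root state of the tree re-rooted at that node,
#' `(1' C^-1 y) / (1' C^-1 1)` with C the re-rooted tip covariance built
#' from patristic distances. The variance reported is
#' `sigma2 / (1' C^-1 1)` with `sigma2` the ML rate estimate at the root.
#' Estimates are equivariant under shifting all tip values by a constant.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param traits named numeric vector, names matching `tree$tip.label`.
#' @return A list with `ace` (named vector over internal node numbers),
#'   `var` (estimation variances) and `sigma2` (ML Brownian rate).
#' @export
bm_ancestral_states <- function(tree, traits) {
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 2)
  miss <- setdiff(tree$tip.label, names(traits))
  if (length(miss)) stop("traits missing for tips: ",
                         paste(miss, collapse = ", "))
  y <- traits[tree$tip.label]
  ntip <- length(tree$tip.label)
  nodes <- ntip + seq_len(tree$Nnode)
  d <- ape::dist.nodes(tree)
  est <- vr <- setNames(numeric(length(nodes)), nodes)
  for (k in seq_along(nodes)) {
    C <- rerooted_vcv(d, seq_len(ntip), nodes[k])
    Ci <- tryCatch(solve(C), error = function(e)
      stop("singular tree covariance at node ", nodes[k]))
    one <- rep(1, ntip)
    denom <- as.numeric(one %*% Ci %*% one)
    est[k] <- as.numeric(one %*% Ci %*% y) / denom
    vr[k] <- 1 / denom
  }
  root <- ntip + 1L
  Cr <- rerooted_vcv(d, seq_len(ntip), root)
  r <- y - est[as.character(root)]
  sigma2 <- as.numeric(r %*% solve(Cr) %*% r) / ntip
  list(ace = est, var = vr * sigma2, sigma2 = sigma2)
}

#' Lineage-specific trait shifts
#'
#' The signed difference between each tip's trait value and the BM
#' ancestral estimate at its parent node (and, optionally, between each
#' internal node and its parent).
#'
#' @param tree a `phylo` object.
#' @param traits named numeric vector of tip values.
#' @param ancestral result of [bm_ancestral_states()]; computed if NULL.
#' @param internal if TRUE, also return shifts along internal edges.
#' @return data.frame with `label`, `node`, `shift`.
#' @export
lineage_shifts <- function(tree, traits, ancestral = NULL,
                           internal = FALSE) {
  if (is.null(ancestral)) ancestral <- bm_ancestral_states(tree, traits)
  ntip <- length(tree$tip.label)
  parent <- setNames(tree$edge[, 1], tree$edge[, 2])
  tipnum <- seq_len(ntip)
  shifts <- traits[tree$tip.label] -
    ancestral$ace[as.character(parent[as.character(tipnum)])]
  out <- data.frame(label = tree$tip.label, node = tipnum,
                    shift = unname(shifts))
  if (internal) {
    inner <- setdiff(ntip + seq_len(tree$Nnode), ntip + 1L)
    out <- rbind(out, data.frame(
      label = NA_character_, node = inner,
      shift = unname(ancestral$ace[as.character(inner)] -
                       ancestral$ace[as.character(parent[as.character(inner)])])))
  }
  out
}

# Internal: one-way ANOVA F statistic, vectorized over the columns of Y.
anova_f <- function(Y, g) {
  g <- as.factor(g)
  n <- nrow(Y); k <- nlevels(g)
  gm <- colMeans(Y)
  sums <- rowsum(Y, g)
  cnt <- as.vector(table(g))
  means <- sums / cnt
  ssb <- colSums(cnt * (means - rep(gm, each = k))^2)
  ssw <- colSums((Y - means[g, , drop = FALSE])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Simulation-based phylogenetically corrected ANOVA
#'
#' The observed statistic is the ordinary one-way ANOVA F of the trait on
#' the group labels; its null distribution is generated by simulating the
#' trait under Brownian motion on the tree (rate estimated from the data)
#' and recomputing F for each simulated data set. The p-value is
#' `(1 + #{F_sim >= F_obs}) / (n_sim + 1)`.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param groups group labels, named by tip or ordered as `tree$tip.label`.
#' @param traits named numeric vector of tip values.
#' @param n_sim number of Brownian simulations.
#' @param seed RNG seed.
#' @param method `"REML"` (default) or `"ML"` rate estimate for the null.
#' @return A list with `F_obs`, `p_value`, `sigma2`, `n_sim`.
#' @export
phylo_anova <- function(tree, groups, traits, n_sim = 1000, seed = NULL,
                        method = c("REML", "ML")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  y <- traits[tree$tip.label]
  if (!is.null(names(groups))) groups <- groups[tree$tip.label]
  g <- as.factor(as.character(groups))
  if (nlevels(g) < 2) stop("at least two groups are required")
  n <- length(y)
  C <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- as.numeric(one %*% Ci %*% y) / as.numeric(one %*% Ci %*% one)
  r <- y - mu
  q <- as.numeric(r %*% Ci %*% r)
  sigma2 <- if (method == "REML") q / (n - 1) else q / n
  F_obs <- anova_f(matrix(y, ncol = 1), g)
  if (is.nan(F_obs)) return(list(F_obs = 0, p_value = 1,
                                 sigma2 = sigma2, n_sim = n_sim))
  L <- chol(sigma2 * C)
  Z <- matrix(rnorm(n * n_sim), n, n_sim)
  Y <- mu + crossprod(L, Z)
  F_sim <- anova_f(Y, g)
  list(F_obs = as.numeric(F_obs),
       p_value = (1 + sum(F_sim >= as.numeric(F_obs))) / (n_sim + 1),
       sigma2 = sigma2, n_sim = n_sim)
}
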