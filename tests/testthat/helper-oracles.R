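# Independent oracles used across the suite. These deliberately share no
# code with the package implementation paths they check.

# plain R pruning with Matrix::expm (independent of the C++ kernel)
r_pruning <- function(phy, tip_idx, Q, pi) {
  po <- ape::reorder.phylo(phy, "postorder")
  k <- nrow(Q)
  n_tip <- length(po$tip.label)
  L <- matrix(1, max(po$edge), k)
  for (i in seq_len(n_tip)) {
    L[i, ] <- 0
    L[i, tip_idx[[po$tip.label[i]]]] <- 1
  }
  for (e in seq_len(nrow(po$edge))) {
    P <- as.matrix(Matrix::expm(Q * po$edge.length[e]))
    L[po$edge[e, 1], ] <- L[po$edge[e, 1], ] * as.numeric(P %*% L[po$edge[e, 2], ])
  }
  root <- po$edge[nrow(po$edge), 1]
  log(sum(pi * L[root, ]))
}

# brute-force likelihood by enumeration over all internal-state assignments
enumeration_loglik <- function(phy, tip_idx, Q, pi) {
  k <- nrow(Q)
  n_tip <- length(phy$tip.label)
  Ps <- lapply(seq_len(nrow(phy$edge)),
               function(e) as.matrix(Matrix::expm(Q * phy$edge.length[e])))
  internals <- (n_tip + 1):(n_tip + phy$Nnode)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  states <- integer(n_tip + phy$Nnode)
  states[seq_len(n_tip)] <- vapply(phy$tip.label, function(l) as.integer(tip_idx[[l]]), integer(1))
  tot <- 0
  for (i in seq_len(nrow(grid))) {
    states[internals] <- grid[i, ]
    p <- pi[states[n_tip + 1L]]
    for (e in seq_len(nrow(phy$edge))) {
      p <- p * Ps[[e]][states[phy$edge[e, 1]], states[phy$edge[e, 2]]]
    }
    tot <- tot + p
  }
  log(tot)
}

# partial correlations by the residual-regression definition
residual_partial_cor <- function(m) {
  p <- ncol(m)
  out <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      rest <- m[, -c(i, j), drop = FALSE]
      ri <- if (ncol(rest)) stats::resid(stats::lm(m[, i] ~ rest)) else m[, i]
      rj <- if (ncol(rest)) stats::resid(stats::lm(m[, j] ~ rest)) else m[, j]
      out[i, j] <- out[j, i] <- stats::cor(ri, rj)
    }
  }
  dimnames(out) <- list(colnames(m), colnames(m))
  out
}

# exhaustive maximum-BIC-gain forest over all edge subsets (small p only)
exhaustive_best_forest <- function(R, n) {
  p <- nrow(R)
  pairs <- t(utils::combn(p, 2))
  w <- -n * log(1 - R[pairs]^2) - log(n)
  m <- nrow(pairs)
  best <- 0
  best_set <- integer(0)
  for (code in seq_len(2^m) - 1L) {
    sel <- which(bitwAnd(code, 2^(seq_len(m) - 1L)) > 0)
    if (!length(sel)) next
    g <- igraph::graph_from_edgelist(pairs[sel, , drop = FALSE], directed = FALSE)
    if (igraph::ecount(g) > igraph::vcount(g) - igraph::count_components(g)) next
    tw <- sum(w[sel])
    if (tw > best) {
      best <- tw
      best_set <- sel
    }
  }
  edges <- pairs[best_set, , drop = FALSE]
  list(weight = best,
       edges = edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# canonical sorted edge-key set of a trait_graph, for structure comparisons
edge_keys <- function(g) {
  if (!nrow(g$edges)) return(character(0))
  sort(paste(pmin(g$edges$from, g$edges$to), pmax(g$edges$from, g$edges$to), sep = "~"))
}

# randomly rotate children at internal nodes (topology-preserving)
rotate_random <- function(phy, seed) {
  set.seed(seed)
  n_tip <- length(phy$tip.label)
  nodes <- sample((n_tip + 1):(n_tip + phy$Nnode), size = max(1, phy$Nnode %/% 2))
  for (nd in nodes) phy <- ape::rotate(phy, nd)
  # serialize/reparse so the edge ordering really changes
  ape::read.tree(text = ape::write.tree(phy))
}

# small fixture: 4-taxon species tree with unit branch lengths
fixture_tree4 <- function(time_calibrated = FALSE) {
  phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  as_species_tree(phy, time_calibrated = time_calibrated)
}

# hand-built interaction_features object (for model tests that need exact
# control over the design matrix)
make_features <- function(X, fit_branches = rownames(X)) {
  structure(list(X = X,
                 center = stats::setNames(rep(0, ncol(X)), colnames(X)),
                 scale = stats::setNames(rep(1, ncol(X)), colnames(X)),
                 fit_branches = fit_branches, fill = "zero",
                 standardized = TRUE, dropped = character(0)),
            class = "interaction_features")
}

# random valid dependent-model rate vector
random_dep_rates <- function(lo = 0.05, hi = 1) {
  r <- runif(8, lo, hi)
  names(r) <- c("q00_10", "q00_01", "q01_11", "q01_00",
                "q10_11", "q10_00", "q11_01", "q11_10")
  r
}
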