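#' Simulate a time-calibrated species tree under a birth-death process
#'
#' Forward Gillespie simulation: the process starts at the root with two
#' lineages; each extant lineage speciates at `birth` and goes extinct at
#' `death` (events per lineage per Ma). Simulation stops the moment the
#' extant count reaches `n_taxa`; the present is then drawn as the waiting
#' time to the next event, so no zero-length pendant edges are created.
#' Extinct lineages are pruned and unifurcations collapsed, yielding an
#' ultrametric tree with `n_taxa` leaves and durations in Ma. Runs in which
#' the clade dies out before reaching `n_taxa` are discarded and restarted.
#'
#' Under pure birth (`death = 0`) the expected depth is
#' `(1/birth) * sum_{k=2..n} 1/k`, which the test suite checks against a
#' Monte-Carlo estimate.
#'
#' @param n_taxa number of extant leaves (>= 2).
#' @param birth,death per-lineage rates (per Ma).
#' @param seed integer seed.
#' @return a time-calibrated [as_species_tree()] object with leaf labels
#'   `t1..tn`.
#' @export
simulate_species_tree <- function(n_taxa, birth = 0.05, death = 0, seed = 1L) {
  stopifnot(n_taxa >= 2L, birth > 0, death >= 0)
  set.seed(seed)
  repeat {
    parent <- c(0L, 0L)            # lineage records; root = two initial lineages
    t_start <- c(0, 0)
    t_end <- c(NA_real_, NA_real_)
    alive <- c(TRUE, TRUE)
    t <- 0
    failed <- FALSE
    while (sum(alive) < n_taxa) {
      n_alive <- sum(alive)
      if (n_alive == 0L) { failed <- TRUE; break }
      t <- t + rexp(1L, n_alive * (birth + death))
      lin <- which(alive)[sample.int(n_alive, 1L)]
      if (runif(1L) < birth / (birth + death)) {  # speciation
        t_end[lin] <- t; alive[lin] <- FALSE
        parent <- c(parent, lin, lin)
        t_start <- c(t_start, t, t)
        t_end <- c(t_end, NA_real_, NA_real_)
        alive <- c(alive, TRUE, TRUE)
      } else {                                    # extinction
        t_end[lin] <- t; alive[lin] <- FALSE
      }
    }
    if (failed) next
    present <- t + rexp(1L, n_taxa * (birth + death))
    nwk <- .bd_to_newick(parent, t_start, t_end, alive, present)
    phy <- ape::read.tree(text = nwk)
    if (!is.null(phy) && length(phy$tip.label) == n_taxa)
      return(as_species_tree(phy, time_calibrated = TRUE))
  }
}

# assemble newick from Gillespie lineage records, pruning extinct lineages
# and collapsing unifurcations (returns NULL-safe string)
.bd_to_newick <- function(parent, t_start, t_end, alive, present) {
  children <- split(seq_along(parent), parent)
  tip_counter <- 0L
  recurse <- function(i) {
    len <- (if (alive[i]) present else t_end[i]) - t_start[i]
    kids <- children[[as.character(i)]]
    if (is.null(kids)) {           # terminal lineage
      if (!alive[i]) return(NULL)  # extinct, prune
      tip_counter <<- tip_counter + 1L
      return(list(str = sprintf("t%d", tip_counter), len = len))
    }
    sub <- Filter(Negate(is.null), lapply(kids, recurse))
    if (length(sub) == 0L) return(NULL)
    if (length(sub) == 1L)          # unifurcation: merge branch lengths
      return(list(str = sub[[1L]]$str, len = sub[[1L]]$len + len))
    list(str = sprintf("(%s:%.10f,%s:%.10f)",
                       sub[[1L]]$str, sub[[1L]]$len, sub[[2L]]$str, sub[[2L]]$len),
         len = len)
  }
  roots <- Filter(Negate(is.null), lapply(which(parent == 0L), recurse))
  if (length(roots) == 2L) {
    sprintf("(%s:%.10f,%s:%.10f);", roots[[1L]]$str, roots[[1L]]$len,
            roots[[2L]]$str, roots[[2L]]$len)
  } else if (length(roots) == 1L) {
    # one side of the root died out: the surviving side's basal split is the root
    paste0(roots[[1L]]$str, ";")
  } else {
    "();"
  }
}

#' Simulate a Brownian latent trait along a tree, valued at branch midpoints
#'
#' Node values follow Brownian motion (`child = parent + N(0, sigma2 * t)`);
#' the branch-level value is the Brownian path at the branch midpoint, drawn
#' from the Brownian bridge between the endpoint values
#' (`N((z_parent + z_child)/2, sigma2 * t / 4)`). The branch is the unit of
#' observation throughout the pipeline, so traits live on branches, not
#' nodes; the observed trait of a terminal taxon is `exp(z)` of its terminal
#' branch.
#'
#' @param tree a time-calibrated `species_tree`.
#' @param sigma2 Brownian variance per Ma (log-trait scale).
#' @param root_value trait value (log scale) at the root.
#' @param seed integer seed.
#' @return list: `branch` (named z per branch id), `node` (z per node
#'   number), `tip` (named by taxon, equal to the terminal branch values).
#' @export
simulate_trait_on_tree <- function(tree, sigma2 = 0.1, root_value = 0, seed = 1L) {
  stopifnot(inherits(tree, "species_tree"))
  if (!tree$time_calibrated) .stopf("need a time-calibrated tree")
  set.seed(seed)
  phy <- tree$phylo
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  z_node <- rep(NA_real_, n_tip + phy$Nnode)
  z_node[root] <- root_value
  # preorder: parents before children
  pre <- ape::reorder.phylo(phy, "cladewise")
  ord <- match(apply(pre$edge, 1L, paste, collapse = "-"),
               apply(phy$edge, 1L, paste, collapse = "-"))
  z_branch <- rep(NA_real_, length(tree$ids))
  names(z_branch) <- tree$ids
  for (k in seq_len(nrow(pre$edge))) {
    p <- pre$edge[k, 1L]; ch <- pre$edge[k, 2L]
    t_br <- tree$durations[[ord[k]]]
    z_node[ch] <- z_node[p] + rnorm(1L, 0, sqrt(sigma2 * t_br))
    z_branch[ord[k]] <- (z_node[p] + z_node[ch]) / 2 +
      rnorm(1L, 0, sqrt(sigma2 * t_br / 4))
  }
  tip <- z_branch[phy$tip.label]
  list(branch = z_branch, node = z_node, tip = tip)
}

#' Simulate a gene-branch matrix with known decomposition and causal genes
#'
#' Generates the full forward model the pipeline inverts: a latent
#' log-trait `z` evolving on the tree (Brownian), gene-branch interactions
#' `log e[g, j] = gamma_g * z_std[j] + N(0, sigma_e^2)` for a sparse causal
#' gene set (pure noise otherwise), double-centered to satisfy the
#' decomposition's identifiability constraints; log-normal branch and gene
#' effects (gene effects centered); and `b = R * r * e`. The observed trait
#' of a terminal branch is `exp(z)`.
#'
#' @param tree a time-calibrated `species_tree`, or `NULL` to simulate one.
#' @param n_taxa taxa for the simulated tree when `tree` is `NULL`.
#' @param n_genes,n_causal total and causal gene counts.
#' @param gamma_range magnitude range of causal effects (signs random).
#' @param sigma_e interaction noise sd (log scale).
#' @param mu_logR,sd_logR log-normal parameters of branch effects
#'   (substitutions/site scale).
#' @param sd_logr log-normal sd of gene effects.
#' @param sigma2_trait Brownian variance of the latent trait (per Ma).
#' @param birth speciation rate for the simulated tree.
#' @param seed integer seed (sub-seeds are derived deterministically).
#' @return list: `matrix` (a [gene_branch_matrix()]), `traits` (a
#'   [trait_table()] of the observed terminal trait, named `trait`), and
#'   `truth` (tree, true `R`, `r`, `e`, causal gene ids, `gamma`, latent `z`
#'   and standardized `z_std`, seeds, config).
#' @export
simulate_decomposition <- function(tree = NULL, n_taxa = 89L, n_genes = 100L,
                                   n_causal = 5L, gamma_range = c(0.5, 1),
                                   sigma_e = 0.3, mu_logR = -3, sd_logR = 0.8,
                                   sd_logr = 0.5, sigma2_trait = 0.02,
                                   birth = 0.05, seed = 1L) {
  stopifnot(n_genes >= 1L, n_causal >= 0L, n_causal <= n_genes, sigma_e >= 0)
  if (is.null(tree)) tree <- simulate_species_tree(n_taxa, birth = birth, seed = seed)
  z <- simulate_trait_on_tree(tree, sigma2 = sigma2_trait, seed = seed + 1L)
  set.seed(seed + 2L)
  J <- length(tree$ids); G <- n_genes
  z_std <- as.numeric(scale(z$branch))
  names(z_std) <- names(z$branch)

  gene_ids <- sprintf("gene_%d", seq_len(G))
  causal <- sort(sample.int(G, n_causal))
  gamma <- stats::setNames(rep(0, G), gene_ids)
  if (n_causal > 0L)
    gamma[causal] <- runif(n_causal, gamma_range[1L], gamma_range[2L]) *
      sample(c(-1, 1), n_causal, replace = TRUE)

  loge <- outer(gamma, z_std) + matrix(rnorm(G * J, 0, sigma_e), G, J)
  # double-center so the decomposition's identifiability constraints hold
  loge <- loge - rowMeans(loge)
  loge <- sweep(loge, 2L, colMeans(loge), "-")
  logR <- rnorm(J, mu_logR, sd_logR)
  logr <- rnorm(G, 0, sd_logr)
  logr <- logr - mean(logr)

  b <- exp(outer(logr, logR, "+") + loge)
  dimnames(b) <- list(gene_ids, tree$ids)
  m <- gene_branch_matrix(b, tree, min_coverage = 0)

  term <- terminal_branches(tree)
  tv <- data.frame(trait = exp(z$branch[term]), row.names = term)
  traits <- trait_table(tv, types = c(trait = "continuous"))

  list(matrix = m, traits = traits,
       truth = list(tree = tree,
                    R = stats::setNames(exp(logR), tree$ids),
                    r = stats::setNames(exp(logr), gene_ids),
                    e = exp(loge),
                    log_R = stats::setNames(logR, tree$ids),
                    log_r = stats::setNames(logr, gene_ids),
                    log_e = loge,
                    causal_genes = gene_ids[causal],
                    gamma = gamma, z = z$branch, z_std = z_std,
                    seed = seed,
                    config = list(n_genes = n_genes, n_causal = n_causal,
                                  gamma_range = gamma_range, sigma_e = sigma_e,
                                  mu_logR = mu_logR, sd_logR = sd_logR,
                                  sd_logr = sd_logr, sigma2_trait = sigma2_trait,
                                  rng = "Mersenne-Twister")))
}

#' "Paper-like" preset for structural sanity checks
#'
#' The scale of the mammalian study the pipeline emulates: 89 taxa and 1204
#' single-copy genes, with a few dozen trait-coupled genes.
#' @param seed integer seed.
#' @param ... overrides passed to [simulate_decomposition()].
#' @export
simulate_paper_like <- function(seed = 1L, ...) {
  args <- list(n_taxa = 89L, n_genes = 1204L, n_causal = 25L,
               gamma_range = c(0.4, 0.8), sigma_e = 0.3, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulate_decomposition, args)
}

#' Simulate a multi-trait table from a tree-structured Gaussian model
#'
#' Variables are generated over a user-specified dependence forest: roots
#' are standard normal and each child equals `rho * parent + sqrt(1 - rho^2)
#' * noise`, so every edge carries its declared correlation and the joint
#' model is a Gaussian tree. Continuous traits are exponentiated (log-normal
#' on the original scale); binary traits are thresholded at their median.
#'
#' @param n_rows sample size.
#' @param traits character vector of trait names.
#' @param edges data.frame `from`, `to`, `rho` describing the forest (may be
#'   empty for mutually independent traits).
#' @param binary names of traits to threshold into 0/1.
#' @param seed integer seed.
#' @return a [trait_table()] with rows `row_1..row_n`.
#' @export
simulate_trait_table <- function(n_rows, traits, edges = NULL, binary = character(0),
                                 seed = 1L) {
  stopifnot(n_rows >= 1L, length(traits) >= 1L)
  if (is.null(edges)) edges <- data.frame(from = character(0), to = character(0),
                                          rho = numeric(0))
  stopifnot(all(edges$from %in% traits), all(edges$to %in% traits),
            all(abs(edges$rho) < 1))
  # check the edge set is a forest
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE,
                                       vertices = data.frame(name = traits))
    if (any(igraph::count_triangles(g) > 0) ||
        igraph::ecount(g) > igraph::vcount(g) - igraph::count_components(g))
      .stopf("'edges' must describe a forest (acyclic)")
  }
  set.seed(seed)
  x <- matrix(NA_real_, n_rows, length(traits), dimnames = list(NULL, traits))
  adj <- lapply(stats::setNames(traits, traits), function(v) {
    rbind(edges[edges$from == v, c("to", "rho")],
          stats::setNames(edges[edges$to == v, c("from", "rho")], c("to", "rho")))
  })
  todo <- traits
  while (length(todo)) {
    root <- todo[1L]
    x[, root] <- rnorm(n_rows)
    queue <- root
    done <- root
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]]
      for (i in seq_len(nrow(nb))) {
        w <- nb$to[i]
        if (w %in% done) next
        x[, w] <- nb$rho[i] * x[, v] + sqrt(1 - nb$rho[i]^2) * rnorm(n_rows)
        done <- c(done, w); queue <- c(queue, w)
      }
    }
    todo <- setdiff(todo, done)
  }
  vals <- as.data.frame(x)
  types <- stats::setNames(rep("continuous", length(traits)), traits)
  for (b in binary) {
    vals[[b]] <- as.numeric(x[, b] > stats::median(x[, b]))
    types[[b]] <- "binary"
  }
  for (j in setdiff(traits, binary)) vals[[j]] <- exp(vals[[j]])
  rownames(vals) <- sprintf("row_%d", seq_len(n_rows))
  trait_table(vals, types = types)
}

#' Simulate a pair of binary traits under a 4-state CTMC on a tree
#'
#' Exact stochastic simulation: the root state is drawn from `pi`, then each
#' branch is traversed with exponential waiting times and single-trait
#' transitions drawn from the rate matrix rows. Dual transitions never occur
#' because the corresponding entries of `Q` are zero by construction.
#'
#' @param tree a time-calibrated `species_tree`.
#' @param Q 4 x 4 rate matrix from [build_rate_matrix()].
#' @param pi root distribution over `(00, 01, 10, 11)`.
#' @param seed integer seed.
#' @return list: `tips` (taxa x 2 matrix of 0/1, columns `A`, `B`),
#'   `node_states` (state label per node), `events` (data.frame `branch`,
#'   `time_Ma`, `from`, `to`).
#' @export
simulate_binary_pair_ctmc <- function(tree, Q, pi = rep(0.25, 4), seed = 1L) {
  stopifnot(inherits(tree, "species_tree"))
  if (!tree$time_calibrated) .stopf("need a time-calibrated tree")
  states <- .coev_states
  set.seed(seed)
  phy <- tree$phylo
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  node_state <- rep(NA_integer_, n_tip + phy$Nnode)
  node_state[root] <- sample.int(4L, 1L, prob = pi)
  pre <- ape::reorder.phylo(phy, "cladewise")
  ord <- match(apply(pre$edge, 1L, paste, collapse = "-"),
               apply(phy$edge, 1L, paste, collapse = "-"))
  events <- list()
  for (k in seq_len(nrow(pre$edge))) {
    p <- pre$edge[k, 1L]; ch <- pre$edge[k, 2L]
    t_total <- tree$durations[[ord[k]]]
    s <- node_state[p]
    t_at <- 0
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      w <- rexp(1L, rate)
      if (t_at + w > t_total) break
      t_at <- t_at + w
      s_new <- sample.int(4L, 1L, prob = pmax(Q[s, ], 0) / rate)
      events[[length(events) + 1L]] <-
        data.frame(branch = tree$ids[ord[k]], time_Ma = t_at,
                   from = states[s], to = states[s_new], stringsAsFactors = FALSE)
      s <- s_new
    }
    node_state[ch] <- s
  }
  tip_states <- states[node_state[seq_len(n_tip)]]
  tips <- cbind(A = as.numeric(substr(tip_states, 1L, 1L)),
                B = as.numeric(substr(tip_states, 2L, 2L)))
  rownames(tips) <- phy$tip.label
  list(tips = tips,
       node_states = stats::setNames(states[node_state],
                                     seq_len(n_tip + phy$Nnode)),
       events = if (length(events)) do.call(rbind, events)
                else data.frame(branch = character(0), time_Ma = numeric(0),
                                from = character(0), to = character(0)))
}
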