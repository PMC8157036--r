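test_that("generators are deterministic given config and seed", {
  t1 <- simulate_species_tree(12, birth = 0.1, seed = 5)
  t2 <- simulate_species_tree(12, birth = 0.1, seed = 5)
  expect_identical(ape::write.tree(t1$phylo), ape::write.tree(t2$phylo))
  expect_identical(t1$durations, t2$durations)

  s1 <- simulate_decomposition(n_taxa = 15, n_genes = 20, n_causal = 2, seed = 9)
  s2 <- simulate_decomposition(n_taxa = 15, n_genes = 20, n_causal = 2, seed = 9)
  expect_identical(unclass(s1$matrix), unclass(s2$matrix))
  expect_identical(s1$truth$gamma, s2$truth$gamma)

  c1 <- simulate_binary_pair_ctmc(t1, build_rate_matrix(
    c(qA01 = .05, qA10 = .05, qB01 = .05, qB10 = .05)), seed = 3)
  c2 <- simulate_binary_pair_ctmc(t1, build_rate_matrix(
    c(qA01 = .05, qA10 = .05, qB01 = .05, qB10 = .05)), seed = 3)
  expect_identical(c1$tips, c2$tips)
  expect_identical(c1$events, c2$events)
})

test_that("birth-death trees are ultrametric with the requested taxon count", {
  tr2 <- simulate_species_tree(2, birth = 0.2, seed = 1)
  expect_length(terminal_branches(tr2), 2L)
  for (s in 1:5) {
    tr <- simulate_species_tree(25, birth = 0.1, death = 0.03, seed = 100 + s)
    expect_length(tr$phylo$tip.label, 25L)
    expect_true(is_ultrametric(tr, tol = 1e-6))
    expect_true(all(tr$durations >= 0))
  }
})

test_that("pure-birth tree depth matches the Yule closed form", {
  n <- 10; lambda <- 0.1
  depths <- vapply(1:150, function(s) {
    tr <- simulate_species_tree(n, birth = lambda, seed = 7000 + s)
    phy <- tr$phylo
    phy$edge.length <- unname(tr$durations)
    max(ape::node.depth.edgelength(phy))
  }, numeric(1))
  expected <- sum(1 / (2:n)) / lambda  # sum of Exp(k*lambda) waits + stop draw
  expect_lt(abs(mean(depths) - expected) / expected, 0.2)
})

test_that("Brownian branch values have the midpoint mean/variance structure", {
  tr <- read_species_tree(
    withr::local_tempfile(lines = "((A:2,B:2):1,C:3);"), time_calibrated = TRUE)
  z0 <- simulate_trait_on_tree(tr, sigma2 = 0, root_value = 1.7, seed = 1)
  expect_true(all(z0$branch == 1.7))

  zs <- vapply(1:400, function(s) {
    z <- simulate_trait_on_tree(tr, sigma2 = 1, root_value = 0, seed = s)
    c(z$branch[["A"]], z$branch[["B"]])
  }, numeric(2))
  # var at a terminal-branch midpoint = sigma2 * (root-to-midpoint time) = 1 + 2/2
  expect_lt(abs(var(zs[1, ]) - 2) / 2, 0.15)
  # sibling covariance = sigma2 * shared path time (the {A,B} stem, 1 Ma)
  expect_lt(abs(cov(zs[1, ], zs[2, ]) - 1), 0.2)
})

test_that("decomposition simulations honour the identifiability constraints", {
  sim <- simulate_decomposition(n_taxa = 20, n_genes = 30, n_causal = 3, seed = 13)
  expect_true(all(sim$matrix > 0))
  expect_lt(abs(mean(sim$truth$log_r)), 1e-12)
  expect_lt(max(abs(rowMeans(sim$truth$log_e))), 1e-12)
  expect_lt(max(abs(colMeans(sim$truth$log_e))), 1e-12)
  # outputs pass the package's own readers/validators unchanged
  f <- withr::local_tempfile()
  write_matrix(unclass(sim$matrix), f)
  m2 <- read_gene_branch_matrix(f, sim$truth$tree)
  expect_equal(unclass(m2), unclass(sim$matrix), ignore_attr = TRUE)
  ft <- withr::local_tempfile()
  write_species_tree(sim$truth$tree, ft)
  tr2 <- read_species_tree(ft, time_calibrated = TRUE)
  expect_setequal(tr2$ids, sim$truth$tree$ids)
})

test_that("a noiseless single causal gene is recovered through the whole chain", {
  sim <- simulate_decomposition(n_taxa = 40, n_genes = 30, n_causal = 1,
                                sigma_e = 0, gamma_range = c(1, 1), seed = 3)
  d <- decompose_rates(sim$matrix, pseudocount = 1e-12)
  expect_lt(max(abs(d$log_interaction - sim$truth$log_e)), 1e-8)
  term <- terminal_branches(sim$truth$tree)
  fe <- interaction_features(d, term)
  m <- fit_trait_model(fe, sim$traits, "trait", lambda = 1e-5)
  sel <- selected_genes(m)
  # with zero interaction noise the centering step makes every gene's feature
  # exactly collinear with the causal one, so the fit is recovered through
  # whichever representative the LASSO picks
  causal_col <- fe$X[, sim$truth$causal_genes]
  expect_true(all(abs(abs(cor(fe$X[, sel$gene, drop = FALSE], causal_col)) - 1) < 1e-10))
  pred <- predict_branches(m, fe, sim$truth$tree$ids)
  expect_lt(max(abs(log(pred$value) - sim$truth$z[pred$branch])), 1e-3)
})

test_that("null decompositions rarely select genes at the CV-chosen penalty", {
  few <- vapply(1:20, function(rep) {
    sim <- simulate_decomposition(n_taxa = 40, n_genes = 60, n_causal = 0,
                                  seed = 400 + rep)
    d <- decompose_rates(sim$matrix)
    term <- terminal_branches(sim$truth$tree)
    fe <- interaction_features(d, term)
    m <- fit_trait_model(fe, sim$traits, "trait", seed = rep)
    sum(m$beta != 0) <= 5
  }, logical(1))
  expect_gte(mean(few), 0.9)
})

test_that("trait tables from a dependence forest carry the declared structure", {
  tt0 <- simulate_trait_table(5000, paste0("t", 1:4), seed = 21)
  m0 <- trait_matrix(tt0)
  r0 <- cor(m0)
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.05)

  chain <- data.frame(from = c("t1", "t2"), to = c("t2", "t3"), rho = c(0.7, 0.5))
  tt <- simulate_trait_table(5000, paste0("t", 1:3), edges = chain,
                             binary = "t3", seed = 22)
  expect_true(all(trait_values(tt)$t3 %in% c(0, 1)))
  expect_true(all(trait_values(tt)$t1 > 0))
  m <- trait_matrix(tt, c("t1", "t2"))
  expect_lt(abs(cor(m[, "t1"], m[, "t2"]) - 0.7), 0.05)

  expect_error(simulate_trait_table(
    100, paste0("t", 1:3),
    edges = data.frame(from = c("t1", "t2", "t3"), to = c("t2", "t3", "t1"),
                       rho = 0.5)), "forest")
})

test_that("CTMC tip simulation matches the chain's stationary behaviour", {
  Q0 <- build_rate_matrix(c(qA01 = 0, qA10 = 0, qB01 = 0, qB10 = 0))
  tr <- simulate_species_tree(8, birth = 0.1, seed = 2)
  sim0 <- simulate_binary_pair_ctmc(tr, Q0, pi = c(0, 0, 1, 0), seed = 1)
  expect_true(all(sim0$tips[, "A"] == 1 & sim0$tips[, "B"] == 0))
  expect_identical(nrow(sim0$events), 0L)

  # long branches: tip states approach the stationary distribution
  deep <- as_species_tree(
    ape::read.tree(text = "((A:500,B:500):500,(C:500,D:500):500);"),
    time_calibrated = TRUE)
  Q <- build_rate_matrix(c(qA01 = .05, qA10 = .02, qB01 = .03, qB10 = .04))
  states <- unlist(lapply(1:500, function(s) {
    sim <- simulate_binary_pair_ctmc(deep, Q, seed = 5000 + s)
    paste0(sim$tips[, 1], sim$tips[, 2])
  }))
  emp <- table(factor(states, levels = c("00", "01", "10", "11"))) / length(states)
  statio <- Re(eigen(t(Q))$vectors[, 4])
  statio <- statio / sum(statio)
  expect_lt(max(abs(as.numeric(emp) - statio)), 0.05)

  # no dual transitions are ever recorded
  simd <- simulate_binary_pair_ctmc(deep, Q, seed = 77)
  flips <- mapply(function(f, t) sum(strsplit(f, "")[[1]] != strsplit(t, "")[[1]]),
                  simd$events$from, simd$events$to)
  expect_true(all(flips == 1))
})

test_that("realized transition rates match the generator's rates on deep trees", {
  # single long branch pair: occupancy-weighted event counts estimate Q
  deep <- as_species_tree(ape::read.tree(text = "(A:20000,B:1);"),
                          time_calibrated = TRUE)
  Q <- build_rate_matrix(c(qA01 = .04, qA10 = .06, qB01 = .05, qB10 = .03))
  sim <- simulate_binary_pair_ctmc(deep, Q, seed = 11)
  ev <- sim$events[sim$events$branch == "A", ]
  root_state <- sim$node_states[[as.character(3)]]
  # walk the branch to accumulate per-state occupancy
  occ <- stats::setNames(rep(0, 4), c("00", "01", "10", "11"))
  cnt <- matrix(0, 4, 4, dimnames = list(names(occ), names(occ)))
  cur <- root_state; last <- 0
  for (i in seq_len(nrow(ev))) {
    occ[cur] <- occ[cur] + ev$time_Ma[i] - last
    cnt[ev$from[i], ev$to[i]] <- cnt[ev$from[i], ev$to[i]] + 1
    cur <- ev$to[i]; last <- ev$time_Ma[i]
  }
  occ[cur] <- occ[cur] + 20000 - last
  for (s in names(occ)) {
    for (s2 in setdiff(names(occ), s)) {
      if (Q[s, s2] > 0)
        expect_lt(abs(cnt[s, s2] / occ[s] - Q[s, s2]) / Q[s, s2], 0.2)
    }
  }
})
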