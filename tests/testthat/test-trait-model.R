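make_trait_table <- function(values, branches, name = "y",
                             type = c(y = "continuous")) {
  names(type) <- name
  df <- data.frame(v = values, row.names = branches)
  names(df) <- name
  trait_table(df, types = type)
}

test_that("a constant trait yields an intercept-only model predicting that constant", {
  set.seed(1)
  X <- matrix(rnorm(12 * 5), 12, 5,
              dimnames = list(paste0("b", 1:12), paste0("g", 1:5)))
  fe <- make_features(X)
  tt <- make_trait_table(rep(3.7, 12), rownames(X))
  expect_warning(m <- fit_trait_model(fe, tt, "y", seed = 1), "constant")
  expect_true(all(m$beta == 0))
  expect_equal(m$intercept, log(3.7))
  pred <- predict_branches(m, fe, rownames(X))
  expect_equal(pred$value, rep(3.7, 12), tolerance = 1e-12)
})

test_that("a single causal gene is recovered from noiseless data", {
  set.seed(7)
  n <- 60; p <- 200
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("b", 1:n), paste0("g", 1:p)))
  X <- scale(X)
  logy <- 2 * X[, "g17"] + 5
  fit_idx <- 1:40
  fe <- make_features(X, fit_branches = rownames(X)[fit_idx])
  tt <- make_trait_table(exp(logy[fit_idx]), rownames(X)[fit_idx])
  m <- fit_trait_model(fe, tt, "y", lambda = 1e-4)
  sel <- selected_genes(m)
  expect_true("g17" %in% sel$gene)
  expect_identical(sel$gene[1], "g17")
  expect_gt(sel$coefficient[1], 0)
  held <- rownames(X)[41:60]
  pred <- predict_branches(m, fe, held)
  expect_lt(sqrt(mean((log(pred$value) - logy[41:60])^2)), 0.05)
})

test_that("the coordinate-descent solution satisfies the LASSO KKT conditions", {
  set.seed(21)
  n <- 12; p <- 5
  X <- scale(matrix(rnorm(n * p), n, p,
                    dimnames = list(paste0("b", 1:n), paste0("g", 1:p))))
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  y <- rnorm(n)
  fe <- make_features(X)
  tt <- make_trait_table(exp(y), rownames(X))
  lam <- 0.1
  m <- fit_trait_model(fe, tt, "y", lambda = lam, thresh = 1e-14)
  # KKT for (1/2n)||y - b0 - X beta||^2 + lambda ||beta||_1:
  # (1/n) x_j' r = lambda * sign(beta_j) for active j, |.| <= lambda otherwise
  r <- y - m$intercept - drop(X %*% m$beta)
  grad <- drop(crossprod(X, r)) / n
  active <- m$beta != 0
  expect_lt(max(abs(grad[active] - lam * sign(m$beta[active]))), 1e-6)
  expect_lt(max(abs(grad[!active])), lam + 1e-6)
  expect_lt(abs(mean(r)), 1e-10)  # intercept optimality
})

test_that("the null model selects almost nothing under CV", {
  set.seed(33)
  n <- 100; p <- 50
  hits <- vapply(1:20, function(rep) {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("b", 1:n), paste0("g", 1:p)))
    fe <- make_features(scale(X))
    y <- sample(rep(c(0, 1), n / 2))   # labels independent of features
    tt <- make_trait_table(y, rownames(X), type = c(y = "binary"))
    m <- fit_trait_model(fe, tt, "y", seed = rep)
    sum(m$beta != 0)
  }, numeric(1))
  expect_gte(mean(hits <= 5), 0.9)
})

test_that("a separating feature is selected with the correct sign", {
  n <- 40
  set.seed(5)
  x1 <- c(rnorm(n / 2, -2, 0.3), rnorm(n / 2, 2, 0.3))
  X <- cbind(g1 = x1, g2 = rnorm(n), g3 = rnorm(n))
  rownames(X) <- paste0("b", 1:n)
  fe <- make_features(scale(X))
  y <- rep(c(0, 1), each = n / 2)
  tt <- make_trait_table(y, rownames(X), type = c(y = "binary"))
  m <- fit_trait_model(fe, tt, "y", lambda = 0.05)
  sel <- selected_genes(m)
  expect_true("g1" %in% sel$gene)
  expect_gt(m$beta[["g1"]], 0)
})

test_that("binary traits coupled to a CTMC history are recovered", {
  tr <- simulate_species_tree(100, birth = 0.05, seed = 77)
  Q2 <- build_rate_matrix(c(qA01 = 0.02, qA10 = 0.02, qB01 = 0.02, qB10 = 0.02))
  recalls <- vapply(1:20, function(rep) {
    sim <- simulate_binary_pair_ctmc(tr, Q2, seed = 1000 + rep)
    y <- sim$tips[, "A"]
    set.seed(2000 + rep)
    p <- 100
    causal <- paste0("g", 1:5)
    # causal gene features shift with the trait: logistic effect 1.5
    X <- matrix(rnorm(100 * p), 100, p,
                dimnames = list(rownames(sim$tips), paste0("g", 1:p)))
    X[, causal] <- X[, causal] + 1.5 * (y - 0.5)
    fe <- make_features(scale(X))
    tt <- make_trait_table(y, rownames(X), type = c(y = "binary"))
    m <- fit_trait_model(fe, tt, "y", seed = rep)
    length(intersect(selected_genes(m)$gene, causal)) / 5
  }, numeric(1))
  expect_gte(median(recalls), 0.6)
})

test_that("predictions back-transform consistently and respect the fitted scale", {
  sim <- simulate_decomposition(n_taxa = 40, n_genes = 60, n_causal = 5,
                                gamma_range = c(0.8, 1.2), sigma_e = 0.3, seed = 11)
  d <- decompose_rates(sim$matrix)
  term <- terminal_branches(sim$truth$tree)
  fe <- interaction_features(d, term)
  m <- fit_trait_model(fe, sim$traits, "trait", seed = 3)
  pred <- predict_branches(m, fe, term)
  expect_equal(log(pred$value), pred$linear_predictor, tolerance = 1e-15)
  # applying the model to its own fitting branches reproduces fitted values
  manual <- drop(fe$X[term, names(m$beta)] %*% m$beta) + m$intercept
  expect_equal(pred$linear_predictor, unname(manual), tolerance = 1e-10)
  expect_true(all(pred$value > 0))
  expect_error(predict_branches(m, fe, c(term[1], "no_such_branch")), "no_such_branch")

  # internal-branch predictions track the true latent trait
  anc <- predict_branches(m, fe, internal_branches(sim$truth$tree))
  truth <- sim$truth$z[anc$branch]
  expect_gt(cor(log(anc$value), truth), 0.5)
})

test_that("imputation fills only missing terminal cells and flags them", {
  sim <- simulate_decomposition(n_taxa = 30, n_genes = 40, n_causal = 4, seed = 13)
  d <- decompose_rates(sim$matrix)
  term <- terminal_branches(sim$truth$tree)
  tt <- sim$traits
  m0 <- fit_trait_model(interaction_features(d, term), tt, "trait", seed = 1)
  fe <- interaction_features(d, term)

  # no missing cells -> unchanged
  expect_identical(impute_missing_terminals(m0, fe, tt), tt)

  # one missing cell -> exactly one imputed flag
  tt1 <- tt
  tt1$values$trait[4] <- NA
  tt1$provenance[4, "trait"] <- NA
  obs_branches <- setdiff(rownames(tt1$values), rownames(tt1$values)[4])
  m1 <- fit_trait_model(interaction_features(d, obs_branches), tt1, "trait", seed = 1)
  fe1 <- interaction_features(d, obs_branches)
  out <- impute_missing_terminals(m1, fe1, tt1)
  expect_identical(sum(out$provenance == "imputed", na.rm = TRUE), 1L)
  expect_false(anyNA(out$values$trait))
  expect_identical(out$values$trait[-4], tt$values$trait[-4])
})

test_that("masked observed values are imputed close to the model's CV error", {
  sim <- simulate_decomposition(n_taxa = 100, n_genes = 80, n_causal = 8,
                                gamma_range = c(0.8, 1.2), sigma_e = 0.4, seed = 17)
  d <- decompose_rates(sim$matrix)
  term <- terminal_branches(sim$truth$tree)
  set.seed(5)
  masked <- sample(term, 10)
  kept <- setdiff(term, masked)
  tt <- sim$traits
  tt$values[masked, "trait"] <- NA
  tt$provenance[masked, "trait"] <- NA
  fe <- interaction_features(d, kept)
  m <- fit_trait_model(fe, tt, "trait", seed = 2)
  # CV RMSE on the log scale at the chosen lambda
  set.seed(2)
  foldid <- sample(rep(1:10, length.out = length(kept)))
  cv <- glmnet::cv.glmnet(fe$X[kept, ], log(sim$traits$values[kept, "trait"]),
                          foldid = foldid, standardize = FALSE)
  cv_rmse <- sqrt(cv$cvm[cv$lambda == m$lambda])
  out <- impute_missing_terminals(m, fe, tt)
  rmse <- sqrt(mean((log(out$values[masked, "trait"]) -
                       log(sim$traits$values[masked, "trait"]))^2))
  expect_lt(rmse, 1.5 * cv_rmse)
})

test_that("increasing the penalty never increases the selected-gene count", {
  set.seed(41)
  n <- 50; p <- 30
  X <- scale(matrix(rnorm(n * p), n, p,
                    dimnames = list(paste0("b", 1:n), paste0("g", 1:p))))
  beta_true <- c(rep(1.5, 3), rep(0, p - 3))
  y <- drop(X %*% beta_true) + rnorm(n, 0, 0.5)
  fe <- make_features(X)
  tt <- make_trait_table(exp(y), rownames(X))
  lambdas <- exp(seq(log(2), log(0.001), length.out = 20))
  counts <- vapply(lambdas, function(l) {
    sum(fit_trait_model(fe, tt, "y", lambda = l)$beta != 0)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))  # lambda decreasing -> count non-decreasing
})

test_that("branches with missing trait values carry no influence on the fit", {
  sim <- simulate_decomposition(n_taxa = 30, n_genes = 40, n_causal = 4, seed = 19)
  d <- decompose_rates(sim$matrix)
  term <- terminal_branches(sim$truth$tree)
  tt_missing <- sim$traits
  tt_missing$values$trait[c(2, 9)] <- NA
  tt_missing$provenance[c(2, 9), "trait"] <- NA
  tt_dropped <- trait_table(
    tt_missing$values[-c(2, 9), , drop = FALSE],
    tt_missing$types,
    tt_missing$provenance[-c(2, 9), , drop = FALSE])
  usable <- rownames(tt_dropped$values)
  fe <- interaction_features(d, usable)
  m_missing <- fit_trait_model(fe, tt_missing, "trait", seed = 4)
  m_dropped <- fit_trait_model(fe, tt_dropped, "trait", seed = 4)
  expect_identical(m_missing$beta, m_dropped$beta)
  expect_identical(m_missing$intercept, m_dropped$intercept)
})

test_that("models serialize to JSON and back without loss", {
  set.seed(51)
  X <- scale(matrix(rnorm(40 * 10), 40, 10,
                    dimnames = list(paste0("b", 1:40), paste0("g", 1:10))))
  y <- drop(X[, 1] * 2) + rnorm(40, 0, 0.1)
  fe <- make_features(X)
  tt <- make_trait_table(exp(y), rownames(X))
  m <- fit_trait_model(fe, tt, "y", seed = 6)
  f <- withr::local_tempfile(fileext = ".json")
  write_trait_model(m, f)
  m2 <- read_trait_model(f)
  expect_equal(m2$beta, m$beta)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$lambda, m$lambda)
  p1 <- predict_branches(m, fe, rownames(X))
  p2 <- predict_branches(structure(m2, class = "fitted_trait_model"), fe, rownames(X))
  expect_equal(p2$value, p1$value)
})
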