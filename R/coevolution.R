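#' Correlated evolution of two binary traits
#'
#' The joint evolution of a pair of binary traits (A, B) is modelled as a
#' 4-state continuous-time Markov chain over the states `00, 01, 10, 11`
#' (state `ab`: trait A in state `a`, trait B in state `b`), in which
#' simultaneous transitions of both traits are forbidden
#' (`Q[00,11] = Q[11,00] = Q[01,10] = Q[10,01] = 0`). Under the
#' *independent* model each trait's gain/loss rates ignore the other trait
#' (4 free rates `qA01, qA10, qB01, qB10`); under the *dependent* model each
#' of the 8 allowed transitions has its own rate, so a trait's transition
#' rate may depend on the state of the other. Rates are in events per Ma on
#' a time-calibrated tree.
#'
#' @param rates named non-negative rates. Independent model:
#'   `qA01, qA10, qB01, qB10`. Dependent model:
#'   `q00_10, q00_01, q01_11, q01_00, q10_11, q10_00, q11_01, q11_10`
#'   (`qXY_ZW` = rate of transition from state XY to state ZW).
#' @param model `"independent"` or `"dependent"`.
#' @return 4 x 4 rate matrix `Q` with dimnames `c("00","01","10","11")`.
#' @export
build_rate_matrix <- function(rates, model = c("independent", "dependent")) {
  model <- match.arg(model)
  need <- if (model == "independent") .indep_rate_names else .dep_rate_names
  if (!all(need %in% names(rates)))
    .stopf("missing rate(s): %s", paste(setdiff(need, names(rates)), collapse = ", "))
  rates <- rates[need]
  if (any(rates < 0) || any(!is.finite(rates))) .stopf("rates must be finite and >= 0")
  if (model == "independent") rates <- expand_independent_rates(rates)
  st <- .coev_states
  Q <- matrix(0, 4, 4, dimnames = list(st, st))
  Q["00", "10"] <- rates[["q00_10"]]; Q["00", "01"] <- rates[["q00_01"]]
  Q["01", "11"] <- rates[["q01_11"]]; Q["01", "00"] <- rates[["q01_00"]]
  Q["10", "11"] <- rates[["q10_11"]]; Q["10", "00"] <- rates[["q10_00"]]
  Q["11", "01"] <- rates[["q11_01"]]; Q["11", "10"] <- rates[["q11_10"]]
  diag(Q) <- -rowSums(Q)
  Q
}

.coev_states <- c("00", "01", "10", "11")
.indep_rate_names <- c("qA01", "qA10", "qB01", "qB10")
.dep_rate_names <- c("q00_10", "q00_01", "q01_11", "q01_00",
                     "q10_11", "q10_00", "q11_01", "q11_10")

#' Embed independent-model rates in the 8-rate dependent parameterization
#' @param rates named vector `qA01, qA10, qB01, qB10`.
#' @return named vector of the 8 dependent-model rates.
#' @export
expand_independent_rates <- function(rates) {
  c(q00_10 = unname(rates[["qA01"]]), q00_01 = unname(rates[["qB01"]]),
    q01_11 = unname(rates[["qA01"]]), q01_00 = unname(rates[["qB10"]]),
    q10_11 = unname(rates[["qB01"]]), q10_00 = unname(rates[["qA10"]]),
    q11_01 = unname(rates[["qA10"]]), q11_10 = unname(rates[["qB10"]]))
}

# tips -> validated 2-column 0/1 matrix over the tree's taxa; taxa with any
# missing state are dropped (with a pruned copy of the tree)
.coev_prepare <- function(tree, tips) {
  stopifnot(inherits(tree, "species_tree"))
  if (!tree$time_calibrated)
    .stopf("the coevolution model needs a time-calibrated tree (durations in Ma)")
  tips <- as.matrix(tips)
  if (ncol(tips) != 2L) .stopf("'tips' must have exactly two binary trait columns")
  if (is.null(rownames(tips))) .stopf("'tips' must have taxon rownames")
  taxa <- tree$phylo$tip.label
  present <- intersect(taxa, rownames(tips))
  state <- matrix(NA_real_, length(taxa), 2L, dimnames = list(taxa, colnames(tips)))
  state[present, ] <- tips[present, ]
  ok <- stats::complete.cases(state) &
    apply(state, 1L, function(v) all(is.na(v) | v %in% c(0, 1)))
  bad_vals <- apply(state, 1L, function(v) any(!is.na(v) & !v %in% c(0, 1)))
  if (any(bad_vals)) .stopf("binary states outside {0,1}: %s",
                            paste(taxa[bad_vals], collapse = ", "))
  if (!all(ok)) {
    .warnf("dropping %d taxa with missing states", sum(!ok))
    phy <- tree$phylo
    phy$edge.length <- unname(tree$durations)
    phy <- ape::keep.tip(phy, taxa[ok])
    tree <- as_species_tree(phy, time_calibrated = TRUE)
    state <- state[tree$phylo$tip.label, , drop = FALSE]
  }
  if (length(tree$phylo$tip.label) < 3L) .stopf("fewer than 3 usable taxa")
  list(tree = tree, state = state)
}

#' Pruning-algorithm log-likelihood of a binary trait pair
#'
#' Felsenstein's pruning algorithm with per-branch transition matrices
#' `expm(Q * t)` (t = branch duration in Ma), conditional likelihoods
#' rescaled in log space, and the root weighted by `pi`.
#'
#' @param tree a time-calibrated `species_tree`.
#' @param tips matrix/data.frame with taxon rownames and two 0/1 columns
#'   (trait A, trait B); taxa with missing states are dropped with a warning.
#' @param Q 4 x 4 rate matrix from [build_rate_matrix()].
#' @param pi root state distribution over `(00, 01, 10, 11)`.
#' @return log-likelihood (scalar; `-Inf` for impossible data).
#' @export
pruning_loglik <- function(tree, tips, Q, pi = rep(0.25, 4)) {
  prep <- .coev_prepare(tree, tips)
  idx <- 1L + 2L * prep$state[, 1L] + prep$state[, 2L]
  .pruning_generic(prep$tree, idx, Q, pi)
}

# postorder traversal context, computed once per tree so repeated
# likelihood evaluations (optimization, MCMC) skip the reorder cost
.pruning_ctx <- function(tree) {
  phy <- tree$phylo
  phy$edge.length <- unname(tree$durations)
  po <- ape::reorder.phylo(phy, "postorder")
  list(edge = po$edge, len = po$edge.length,
       n_tip = length(po$tip.label), tips = po$tip.label)
}

.pruning_ll <- function(ctx, tip_idx_ordered, Q, pi) {
  cpp_pruning_loglik(ctx$edge, ctx$len, ctx$n_tip, tip_idx_ordered, Q, pi)
}

# generic k-state pruning on a species_tree with durations
.pruning_generic <- function(tree, tip_state_idx, Q, pi) {
  if (abs(sum(pi) - 1) > 1e-8) .stopf("root distribution must sum to 1")
  ctx <- .pruning_ctx(tree)
  .pruning_ll(ctx, as.integer(tip_state_idx[ctx$tips]), Q, pi)
}

#' Maximum-likelihood rates for the correlated-evolution model
#'
#' Optimizes the log-likelihood over log-rates with L-BFGS-B, restarting
#' from `restarts` seeded log-uniform draws in `[1e-3, 10]` events/Ma and
#' keeping the best solution.
#'
#' @inheritParams pruning_loglik
#' @param model `"independent"` (4 rates) or `"dependent"` (8 rates).
#' @param restarts number of random restarts.
#' @param seed integer seed for the restart draws.
#' @param pi root distribution (`"uniform"` default; a numeric vector to
#'   override).
#' @return a `coevolution_fit`: `rates` (named, per Ma), `loglik`, `model`,
#'   `n_taxa`, `convergence` (0 = success for the best restart), `restarts`.
#' @export
fit_ml <- function(tree, tips, model = c("independent", "dependent"),
                   restarts = 3L, seed = 1L, pi = "uniform") {
  model <- match.arg(model)
  prep <- .coev_prepare(tree, tips)
  n_taxa <- length(prep$tree$phylo$tip.label)
  if (n_taxa < 10L) .warnf("only %d taxa; rate estimates will be unstable", n_taxa)
  idx <- 1L + 2L * prep$state[, 1L] + prep$state[, 2L]
  pi_vec <- if (identical(pi, "uniform")) rep(0.25, 4) else pi
  par_names <- if (model == "independent") .indep_rate_names else .dep_rate_names
  npar <- length(par_names)

  ctx <- .pruning_ctx(prep$tree)
  idx_ord <- as.integer(idx[ctx$tips])
  negll <- function(logq) {
    q <- exp(logq)
    names(q) <- par_names
    ll <- .pruning_ll(ctx, idx_ord, build_rate_matrix(q, model), pi_vec)
    if (!is.finite(ll)) 1e10 else -ll
  }
  set.seed(seed)
  starts <- matrix(runif(restarts * npar, log(1e-3), log(10)), nrow = restarts)
  best <- NULL
  fails <- character(0)
  for (s in seq_len(restarts)) {
    res <- tryCatch(
      optim(starts[s, ], negll, method = "L-BFGS-B",
            lower = log(1e-8), upper = log(1e3),
            control = list(maxit = 200L)),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails <- c(fails, conditionMessage(res))
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    .stopf("all %d restarts failed: %s", restarts, paste(unique(fails), collapse = "; "))
  rates <- stats::setNames(exp(best$par), par_names)
  structure(list(rates = rates, loglik = -best$value, model = model,
                 n_taxa = n_taxa, pi = pi_vec,
                 convergence = best$convergence, restarts = restarts),
            class = "coevolution_fit")
}

#' @export
print.coevolution_fit <- function(x, ...) {
  cat(sprintf("coevolution_fit (%s model): logLik = %.4f, %d taxa\n",
              x$model, x$loglik, x$n_taxa))
  print(round(x$rates, 5))
  invisible(x)
}

#' Likelihood-ratio test of dependent vs independent evolution
#'
#' Fits both models by ML and compares `2 * (logLik_dep - logLik_indep)`
#' against a chi-squared distribution with 4 degrees of freedom (8 vs 4 free
#' rates).
#'
#' @inheritParams fit_ml
#' @return list with both fits, `statistic`, `df = 4`, `p_value`.
#' @export
lrt_correlated_evolution <- function(tree, tips, restarts = 3L, seed = 1L,
                                     pi = "uniform") {
  fit_i <- fit_ml(tree, tips, "independent", restarts = restarts, seed = seed, pi = pi)
  fit_d <- fit_ml(tree, tips, "dependent", restarts = restarts, seed = seed + 1L, pi = pi)
  stat <- max(0, 2 * (fit_d$loglik - fit_i$loglik))
  list(independent = fit_i, dependent = fit_d, statistic = stat, df = 4L,
       p_value = pchisq(stat, df = 4L, lower.tail = FALSE))
}

#' Metropolis-Hastings MCMC over transition rates
#'
#' Fixed-dimension random-walk sampler: each rate receives a log-normal
#' proposal (normal increment on the log scale) in a componentwise sweep per
#' iteration, with independent exponential priors on the rates. The proposal
#' scale adapts towards a 20-50% acceptance rate during burn-in only, so the
#' post-burn-in chain is a valid fixed-kernel sampler. Deterministic given
#' the seed.
#'
#' @inheritParams fit_ml
#' @param prior_mean mean of the exponential prior on each rate (per Ma).
#' @param iterations total iterations (> 0).
#' @param burn_in iterations used for adaptation (default a quarter).
#' @param init optional named initial rates (default: prior means).
#' @return an `mcmc_trace`: `samples` (iterations x rates matrix),
#'   `log_posterior`, `log_likelihood`, `acceptance_rate` (post burn-in),
#'   `proposal_scale`, `burn_in`, `seed`, `model`, `prior_mean`.
#' @export
run_mcmc <- function(tree, tips, model = c("independent", "dependent"),
                     prior_mean = 1, iterations = 10000L,
                     burn_in = NULL, seed = 1L, init = NULL, pi = "uniform") {
  model <- match.arg(model)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) .stopf("iterations must be a positive integer")
  if (prior_mean <= 0) .stopf("prior mean must be > 0")
  burn_in <- as.integer(burn_in %||% max(1L, iterations %/% 4L))
  prep <- .coev_prepare(tree, tips)
  idx <- 1L + 2L * prep$state[, 1L] + prep$state[, 2L]
  pi_vec <- if (identical(pi, "uniform")) rep(0.25, 4) else pi
  par_names <- if (model == "independent") .indep_rate_names else .dep_rate_names
  npar <- length(par_names)

  ctx <- .pruning_ctx(prep$tree)
  idx_ord <- as.integer(idx[ctx$tips])
  loglik_fun <- function(logq) {
    q <- exp(logq); names(q) <- par_names
    .pruning_ll(ctx, idx_ord, build_rate_matrix(q, model), pi_vec)
  }
  # posterior over log-rates: loglik + exponential prior + Jacobian (sum logq)
  logpost_fun <- function(logq, ll) ll + sum(stats::dexp(exp(logq), 1 / prior_mean,
                                                         log = TRUE)) + sum(logq)
  set.seed(seed)
  logq <- log(init[par_names] %||% rep(prior_mean, npar))
  ll <- loglik_fun(logq)
  lp <- logpost_fun(logq, ll)
  scale_ <- rep(0.5, npar)
  samples <- matrix(NA_real_, iterations, npar, dimnames = list(NULL, par_names))
  ll_trace <- lp_trace <- numeric(iterations)
  acc <- rep(0L, npar)    # post burn-in acceptances
  acc_win <- rep(0L, npar)  # window acceptances for adaptation
  win <- 0L
  for (it in seq_len(iterations)) {
    for (j in seq_len(npar)) {
      prop <- logq
      prop[j] <- prop[j] + rnorm(1L, 0, scale_[j])
      ll_p <- loglik_fun(prop)
      lp_p <- logpost_fun(prop, ll_p)
      if (is.finite(lp_p) && log(runif(1L)) < lp_p - lp) {
        logq <- prop; ll <- ll_p; lp <- lp_p
        if (it > burn_in) acc[j] <- acc[j] + 1L else acc_win[j] <- acc_win[j] + 1L
      }
    }
    win <- win + 1L
    if (it <= burn_in && win == 50L) {  # adapt during burn-in only
      rate <- acc_win / 50
      scale_ <- scale_ * ifelse(rate > 0.5, 1.5, ifelse(rate < 0.2, 0.6, 1))
      acc_win[] <- 0L; win <- 0L
    }
    samples[it, ] <- exp(logq)
    ll_trace[it] <- ll
    lp_trace[it] <- lp
  }
  n_post <- max(1L, iterations - burn_in)
  structure(list(samples = samples, log_likelihood = ll_trace,
                 log_posterior = lp_trace,
                 acceptance_rate = mean(acc) / n_post,
                 proposal_scale = scale_, burn_in = burn_in, seed = seed,
                 model = model, prior_mean = prior_mean,
                 iterations = iterations),
            class = "mcmc_trace")
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat(sprintf("mcmc_trace (%s model): %d iterations (burn-in %d), acceptance %.2f\n",
              x$model, x$iterations, x$burn_in, x$acceptance_rate))
  invisible(x)
}

#' Posterior means of MCMC-sampled rates
#' @param trace an `mcmc_trace`.
#' @param discard_burn_in drop the burn-in samples (default TRUE).
#' @return named vector of posterior mean rates (per Ma).
#' @export
posterior_means <- function(trace, discard_burn_in = TRUE) {
  stopifnot(inherits(trace, "mcmc_trace"))
  keep <- if (discard_burn_in && trace$iterations > trace$burn_in)
    seq(trace$burn_in + 1L, trace$iterations) else seq_len(trace$iterations)
  colMeans(trace$samples[keep, , drop = FALSE])
}

#' Report the eight allowed transitions with their rates
#'
#' Fixed ordering matching the state diagram; dual transitions (both traits
#' changing at once) are structurally absent. Units: events per million
#' years. Independent-model fits are expanded to the 8-transition table via
#' [expand_independent_rates()].
#'
#' @param fit a `coevolution_fit` (ML point estimates).
#' @param trace optional `mcmc_trace`; adds posterior mean rates.
#' @return data.frame `from`, `to`, `transition`, `rate_per_Ma` and
#'   optionally `posterior_mean_per_Ma`.
#' @export
transition_rate_report <- function(fit, trace = NULL) {
  stopifnot(inherits(fit, "coevolution_fit"))
  rates <- if (fit$model == "independent") expand_independent_rates(fit$rates) else fit$rates
  rates <- rates[.dep_rate_names]
  from <- substr(sub("^q", "", .dep_rate_names), 1L, 2L)
  to <- substr(sub("^q", "", .dep_rate_names), 4L, 5L)
  out <- data.frame(from = from, to = to,
                    transition = paste(from, "->", to),
                    rate_per_Ma = unname(rates), stringsAsFactors = FALSE)
  if (!is.null(trace)) {
    pm <- posterior_means(trace)
    if (trace$model == "independent") pm <- expand_independent_rates(pm)
    out$posterior_mean_per_Ma <- unname(pm[.dep_rate_names])
  }
  out
}
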