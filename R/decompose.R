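#' Decompose branch lengths into branch, gene and interaction effects
#'
#' Models the observed per-gene branch length as a product of three rates,
#' `b[g, j] = R[j] * r[g] * e[g, j]`: a genome-wide branch effect `R[j]`
#' (generation length, mutagen exposure), a gene effect `r[g]` (the gene's
#' overall level of functional constraint), and a gene-branch interaction
#' `e[g, j]` capturing lineage-specific fluctuation of the gene's rate. The
#' fit is an additive two-way least-squares decomposition of
#' `log(b + pseudocount)`: row/column means for complete data, alternating
#' row/column centering iterated to convergence when entries are missing.
#' Identifiability: `mean(log r) = 0` over genes and `mean(log R)` equals the
#' fitted grand mean, so interactions are centered.
#'
#' @param M a [gene_branch_matrix()].
#' @param pseudocount added inside the log to protect zero-length branches
#'   (> 0, default `1e-9` substitutions/site).
#' @param method `"ls"` (two-way least squares, default) or
#'   `"median-polish"` ([stats::medpolish()], robust to outlying cells; its
#'   effects satisfy median, not mean, centering).
#' @param max_iter,tol iteration cap and convergence tolerance (max absolute
#'   change of any effect) for the incomplete-data alternating fit.
#' @return a `rate_decomposition`: list with `branch_effect` (named `R`),
#'   `gene_effect` (named `r`), `interaction` (G x J matrix `e`, NA where `b`
#'   missing), `log_*` components, `pseudocount`, `method`, `iterations`,
#'   `max_change`.
#' @export
decompose_rates <- function(M, pseudocount = 1e-9, method = c("ls", "median-polish"),
                            max_iter = 500L, tol = 1e-10) {
  method <- match.arg(method)
  stopifnot(is.matrix(M))
  if (!is.numeric(pseudocount) || pseudocount <= 0) .stopf("pseudocount must be > 0")
  b <- unclass(M)
  attr(b, "min_coverage") <- NULL
  attr(b, "skipped") <- NULL
  obs <- !is.na(b)
  bad_g <- rownames(b)[rowSums(obs) == 0L]
  if (length(bad_g)) .stopf("gene(s) with no observed branch lengths: %s",
                            paste(bad_g, collapse = ", "))
  bad_j <- colnames(b)[colSums(obs) == 0L]
  if (length(bad_j)) .stopf("branch(es) with no observed branch lengths: %s",
                            paste(bad_j, collapse = ", "))
  L <- log(b + pseudocount)

  if (method == "median-polish") {
    mp <- stats::medpolish(L, eps = tol, maxiter = max_iter, trace.iter = FALSE,
                           na.rm = TRUE)
    mu <- mp$overall; alpha <- mp$row; beta <- mp$col
    gamma <- L - mu - outer(alpha, rep(1, ncol(L))) - outer(rep(1, nrow(L)), beta)
    iters <- NA_integer_; max_change <- NA_real_
  } else {
    mu <- mean(L[obs])
    alpha <- rep(0, nrow(L)); beta <- rep(0, ncol(L))
    iters <- 0L; max_change <- Inf
    complete <- all(obs)
    while (iters < max_iter) {
      iters <- iters + 1L
      Lc <- sweep(L, 2L, beta, "-") - mu
      alpha_new <- rowMeans(Lc, na.rm = TRUE)
      Lr <- sweep(L, 1L, alpha_new, "-") - mu
      beta_new <- colMeans(Lr, na.rm = TRUE)
      max_change <- max(max(abs(alpha_new - alpha)), max(abs(beta_new - beta)))
      alpha <- alpha_new; beta <- beta_new
      if (complete || max_change <= tol) break
    }
    if (max_change > tol && !all(obs))
      .stopf("alternating fit did not converge in %d iterations (last change %.3g)",
             max_iter, max_change)
    # fold residual means into mu so that mean(alpha) = 0 and mean(beta) = 0
    a0 <- mean(alpha); alpha <- alpha - a0; mu <- mu + a0
    b0 <- mean(beta);  beta <- beta - b0;  mu <- mu + b0
    gamma <- L - mu - outer(alpha, rep(1, ncol(L))) - outer(rep(1, nrow(L)), beta)
    names(alpha) <- rownames(L); names(beta) <- colnames(L)
  }
  gamma[!obs] <- NA_real_

  structure(list(
    branch_effect = stats::setNames(exp(mu + beta), colnames(L)),
    gene_effect = stats::setNames(exp(alpha), rownames(L)),
    interaction = exp(gamma),
    log_grand_mean = mu,
    log_gene_effect = stats::setNames(alpha, rownames(L)),
    log_branch_effect = stats::setNames(mu + beta, colnames(L)),
    log_interaction = gamma,
    pseudocount = pseudocount,
    method = method,
    iterations = iters,
    max_change = max_change
  ), class = "rate_decomposition")
}

#' @export
print.rate_decomposition <- function(x, ...) {
  cat(sprintf("rate_decomposition (%s): %d genes x %d branches, pseudocount %.1e\n",
              x$method, length(x$gene_effect), length(x$branch_effect), x$pseudocount))
  if (!is.na(x$iterations))
    cat(sprintf("  converged in %d iteration(s), max change %.2e\n",
                x$iterations, x$max_change))
  invisible(x)
}

#' Build the standardized interaction feature matrix
#'
#' Arranges `log e[g, j]` as a branches x genes matrix `X`, fills missing
#' entries, and standardizes each gene column using mean/sd computed on the
#' fitting branches only; the same constants are applied to every branch, so
#' ancestral branches are expressed on the scale the model was fit on.
#'
#' @param D a [decompose_rates()] result.
#' @param fit_branches branch ids defining the standardization subset
#'   (normally the terminal branches used for model fitting).
#' @param fill policy for missing interactions: `"zero"` (log e = 0, i.e. no
#'   deviation; unbiased under the centering constraint, default) or
#'   `"gene-mean"` (the gene's mean log e over the fitting branches).
#' @param standardize set `FALSE` to keep raw (filled) log-interactions.
#' @return an `interaction_features` object: `X` (branches x genes),
#'   `center`, `scale`, `fit_branches`, `fill`, `dropped` (zero-variance
#'   genes removed).
#' @export
interaction_features <- function(D, fit_branches, fill = c("zero", "gene-mean"),
                                 standardize = TRUE) {
  stopifnot(inherits(D, "rate_decomposition"))
  fill <- match.arg(fill)
  X <- t(D$log_interaction)                 # branches x genes
  if (!all(fit_branches %in% rownames(X)))
    .stopf("fit_branches absent from the decomposition: %s",
           paste(setdiff(fit_branches, rownames(X)), collapse = ", "))
  if (anyNA(X)) {
    if (fill == "zero") {
      X[is.na(X)] <- 0
    } else {
      gm <- colMeans(X[fit_branches, , drop = FALSE], na.rm = TRUE)
      gm[is.nan(gm)] <- 0
      idx <- which(is.na(X), arr.ind = TRUE)
      X[idx] <- gm[idx[, 2L]]
    }
  }
  center <- rep(0, ncol(X)); scale_ <- rep(1, ncol(X))
  names(center) <- names(scale_) <- colnames(X)
  dropped <- character(0)
  if (standardize) {
    sub <- X[fit_branches, , drop = FALSE]
    center <- colMeans(sub)
    scale_ <- apply(sub, 2L, sd)
    dropped <- colnames(X)[scale_ < 1e-12 | is.na(scale_)]
    if (length(dropped)) {
      .warnf("dropping %d gene(s) with zero variance on the fitting branches", length(dropped))
      keep <- setdiff(colnames(X), dropped)
      X <- X[, keep, drop = FALSE]
      center <- center[keep]; scale_ <- scale_[keep]
    }
    X <- sweep(sweep(X, 2L, center, "-"), 2L, scale_, "/")
  }
  structure(list(X = X, center = center, scale = scale_,
                 fit_branches = fit_branches, fill = fill,
                 standardized = standardize, dropped = dropped),
            class = "interaction_features")
}

#' @export
print.interaction_features <- function(x, ...) {
  cat(sprintf("interaction_features: %d branches x %d genes (fill=%s%s)\n",
              nrow(x$X), ncol(x$X), x$fill,
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}
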