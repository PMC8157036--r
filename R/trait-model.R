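#' Fit a LASSO-penalized trait model on gene-branch interactions
#'
#' Regresses a trait observed at terminal branches on the standardized
#' log-interaction features of those branches. Continuous traits are
#' modelled on the natural-log scale with squared-error loss; binary traits
#' with logistic deviance. The L1 penalty shrinks the coefficients of
#' uninformative genes exactly to zero, so the non-zero set is the list of
#' predictor genes. Branches with a missing trait value are excluded from
#' fitting (they can be imputed afterwards with
#' [impute_missing_terminals()]).
#'
#' The penalty is chosen by k-fold cross-validation with an explicit seeded
#' fold assignment (`lambda.min` by default, the 1-SE rule optionally), or
#' fixed via `lambda`.
#'
#' @param features an [interaction_features()] object.
#' @param traits a [trait_table()] with observations at terminal branches.
#' @param trait trait name to model.
#' @param family `"auto"` (from the declared trait type), `"linear"`
#'   (log-scale Gaussian) or `"logistic"`.
#' @param nfolds folds for cross-validation (default 10; reduced with a
#'   warning when fewer usable branches are available).
#' @param seed integer seed controlling the fold assignment.
#' @param use_1se use the 1-SE rule instead of the CV minimum.
#' @param lambda optional fixed penalty, skipping cross-validation.
#' @param ... passed to [glmnet::glmnet()]/[glmnet::cv.glmnet()] (e.g.
#'   `thresh`).
#' @return a `fitted_trait_model`: trait, family, `intercept`, named sparse
#'   coefficient vector `beta` (standardized-feature scale), `lambda`,
#'   `cv` metadata, `fit_branches`, `transform`.
#' @export
fit_trait_model <- function(features, traits, trait,
                            family = c("auto", "linear", "logistic"),
                            nfolds = 10L, seed = 1L, use_1se = FALSE,
                            lambda = NULL, ...) {
  stopifnot(inherits(features, "interaction_features"), inherits(traits, "trait_table"))
  family <- match.arg(family)
  if (!trait %in% names(traits$values)) .stopf("trait '%s' not in trait table", trait)
  type <- traits$types[[trait]]
  if (family == "auto") family <- if (type == "binary") "logistic" else "linear"

  y_all <- traits$values[[trait]]
  names(y_all) <- rownames(traits$values)
  usable <- names(y_all)[!is.na(y_all) & names(y_all) %in% rownames(features$X)]
  if (length(usable) < 10L)
    .stopf("only %d branches with an observed '%s' value; need >= 10", length(usable), trait)
  X <- features$X[usable, , drop = FALSE]
  y <- if (family == "linear") log(y_all[usable]) else y_all[usable]

  if (family == "logistic") {
    tab <- table(factor(y, levels = c(0, 1)))
    if (min(tab) == 0L) {
      .warnf("trait '%s' is constant on the fitting branches; intercept-only model", trait)
      p <- mean(y)
      return(.intercept_only_model(trait, family, qlogis(min(max(p, 1e-6), 1 - 1e-6)),
                                   colnames(X), usable))
    }
    if (max(tab) / min(tab) > 9)
      .warnf("trait '%s': class imbalance exceeds 9:1 (%d vs %d)", trait, tab[1], tab[2])
  } else if (var(y) == 0) {
    .warnf("trait '%s' is constant on the fitting branches; intercept-only model", trait)
    return(.intercept_only_model(trait, family, unname(y[1L]), colnames(X), usable))
  }

  glmnet_family <- if (family == "logistic") "binomial" else "gaussian"
  cv_meta <- list(nfolds = NA_integer_, seed = seed, one_se = use_1se, chosen = "fixed")
  if (is.null(lambda)) {
    nfolds <- as.integer(nfolds)
    if (length(usable) < nfolds) {
      nfolds <- max(3L, length(usable) %/% 2L)
      .warnf("fewer usable branches than folds; reducing to %d folds", nfolds)
    }
    set.seed(seed)
    foldid <- sample(rep(seq_len(nfolds), length.out = length(usable)))
    cvfit <- glmnet::cv.glmnet(X, y, family = glmnet_family, foldid = foldid,
                               standardize = FALSE,
                               type.measure = if (family == "logistic") "deviance" else "mse",
                               ...)
    lambda <- if (use_1se) cvfit$lambda.1se else cvfit$lambda.min
    cv_meta <- list(nfolds = nfolds, seed = seed, one_se = use_1se,
                    chosen = if (use_1se) "lambda.1se" else "lambda.min")
  }
  # refit along a decreasing path ending at the chosen lambda: glmnet's
  # coordinate descent is only reliable with warm starts down a path
  lam_seq <- exp(seq(log(lambda * 1e4), log(lambda), length.out = 60))
  lam_seq[length(lam_seq)] <- lambda
  fit <- glmnet::glmnet(X, y, family = glmnet_family, lambda = lam_seq,
                        standardize = FALSE, ...)
  cf <- coef(fit, s = lambda)
  beta <- stats::setNames(as.numeric(cf[-1L]), rownames(cf)[-1L])
  structure(list(trait = trait, family = family,
                 intercept = as.numeric(cf[1L]), beta = beta,
                 lambda = lambda, cv = cv_meta,
                 fit_branches = usable,
                 transform = if (family == "linear") "log" else "identity"),
            class = "fitted_trait_model")
}

.intercept_only_model <- function(trait, family, intercept, genes, fit_branches) {
  structure(list(trait = trait, family = family, intercept = intercept,
                 beta = stats::setNames(rep(0, length(genes)), genes),
                 lambda = Inf,
                 cv = list(nfolds = NA_integer_, seed = NA_integer_,
                           one_se = FALSE, chosen = "degenerate"),
                 fit_branches = fit_branches,
                 transform = if (family == "linear") "log" else "identity"),
            class = "fitted_trait_model")
}

#' @export
print.fitted_trait_model <- function(x, ...) {
  cat(sprintf("fitted_trait_model '%s' (%s): %d/%d non-zero genes, lambda = %.4g\n",
              x$trait, x$family, sum(x$beta != 0), length(x$beta), x$lambda))
  invisible(x)
}

#' Predict trait values for a set of branches
#'
#' Applies a fitted model to the interaction features of arbitrary branches
#' (typically the internal branches, giving rate-based ancestral state
#' predictions). Continuous predictions are back-transformed with `exp`;
#' binary predictions report the logistic probability and a hard 0/1 call at
#' 0.5.
#'
#' @param model a [fit_trait_model()] result.
#' @param features the [interaction_features()] the model was fit on (same
#'   standardization constants).
#' @param branch_ids branches to predict; all must be present in `features`.
#' @return an `ancestral_prediction` data.frame: `branch`, `linear_predictor`
#'   and `value` (plus `probability`, `call` for binary), with attributes
#'   `trait` and `provenance = "predicted-ancestral"`.
#' @export
predict_branches <- function(model, features, branch_ids) {
  stopifnot(inherits(model, "fitted_trait_model"),
            inherits(features, "interaction_features"))
  missing_ids <- setdiff(branch_ids, rownames(features$X))
  if (length(missing_ids))
    .stopf("branch(es) absent from the feature matrix: %s",
           paste(missing_ids, collapse = ", "))
  genes <- names(model$beta)
  if (!all(genes %in% colnames(features$X)))
    .stopf("feature matrix lacks genes used by the model")
  eta <- drop(features$X[branch_ids, genes, drop = FALSE] %*% model$beta) + model$intercept
  out <- data.frame(branch = branch_ids, linear_predictor = unname(eta),
                    stringsAsFactors = FALSE)
  if (model$family == "linear") {
    out$value <- exp(out$linear_predictor)
  } else {
    out$probability <- plogis(out$linear_predictor)
    out$call <- as.integer(out$probability >= 0.5)
    out$value <- out$call
  }
  structure(out, class = c("ancestral_prediction", "data.frame"),
            trait = model$trait, provenance = "predicted-ancestral")
}

#' Impute missing terminal trait values from the fitted model
#'
#' Only cells that are missing in `traits` (for the model's trait) and whose
#' branch has interaction features are filled; observed cells are never
#' touched. Filled cells are flagged `imputed`.
#'
#' @inheritParams predict_branches
#' @param traits the `trait_table` to complete.
#' @return the updated `trait_table`.
#' @export
impute_missing_terminals <- function(model, features, traits) {
  stopifnot(inherits(traits, "trait_table"))
  trait <- model$trait
  if (!trait %in% names(traits$values)) .stopf("trait '%s' not in table", trait)
  miss <- rownames(traits$values)[is.na(traits$values[[trait]])]
  miss <- intersect(miss, rownames(features$X))
  if (!length(miss)) return(traits)
  pred <- predict_branches(model, features, miss)
  for (i in seq_len(nrow(pred))) {
    traits <- .set_trait_cell(traits, pred$branch[i], trait, pred$value[i], "imputed")
  }
  traits
}

#' Genes selected as predictors of a trait
#'
#' @param model a `fitted_trait_model`.
#' @return data.frame `gene`, `coefficient` (standardized scale), restricted
#'   to non-zero coefficients, sorted by decreasing `|coefficient|` with ties
#'   broken by gene id.
#' @export
selected_genes <- function(model) {
  stopifnot(inherits(model, "fitted_trait_model"))
  nz <- model$beta[model$beta != 0]
  if (!length(nz))
    return(data.frame(gene = character(0), coefficient = numeric(0),
                      stringsAsFactors = FALSE))
  ord <- order(-abs(nz), names(nz))
  data.frame(gene = names(nz)[ord], coefficient = unname(nz[ord]),
             stringsAsFactors = FALSE)
}

#' Serialize / restore a fitted trait model as JSON
#'
#' Stores gene ids, coefficients, intercept, penalty, CV metadata, fitting
#' branches and the standardization provenance, so a model can be re-applied
#' without refitting.
#' @param model a `fitted_trait_model`.
#' @param path JSON file.
#' @export
write_trait_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_trait_model"))
  obj <- unclass(model)
  obj$genes <- names(obj$beta)
  obj$beta <- unname(obj$beta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trait_model
#' @export
read_trait_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$beta <- stats::setNames(as.numeric(obj$beta), obj$genes)
  obj$genes <- NULL
  structure(obj, class = "fitted_trait_model")
}
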