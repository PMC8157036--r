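#' Numeric trait matrix for correlation analyses
#'
#' Continuous traits enter on the natural-log scale, binary traits as 0/1.
#' Rows can be restricted by provenance (e.g. observed terminals only, or
#' terminals plus predicted-ancestral branches as in the coevolution-network
#' analysis).
#'
#' @param traits a [trait_table()].
#' @param which_traits trait names (default: all).
#' @param provenance provenance flags whose rows/cells are admitted.
#' @return numeric matrix, rows = branches, cols = traits, NA where missing
#'   or excluded by provenance.
#' @export
trait_matrix <- function(traits, which_traits = NULL,
                         provenance = c("observed", "imputed", "predicted-ancestral")) {
  stopifnot(inherits(traits, "trait_table"))
  which_traits <- which_traits %||% names(traits$values)
  if (!all(which_traits %in% names(traits$values)))
    .stopf("unknown trait(s): %s",
           paste(setdiff(which_traits, names(traits$values)), collapse = ", "))
  m <- as.matrix(traits$values[, which_traits, drop = FALSE])
  prov <- traits$provenance[, which_traits, drop = FALSE]
  m[!(prov %in% provenance)] <- NA  # matrix-indexed logical keeps shape
  for (j in which_traits) {
    if (traits$types[[j]] == "continuous") m[, j] <- log(m[, j])
  }
  m
}

#' Pairwise Pearson correlations among traits
#'
#' Continuous traits are log-transformed first; binary traits enter as 0/1.
#' Each pair uses its complete rows (listwise within the pair).
#'
#' @inheritParams trait_matrix
#' @return a `correlation_result` with `traits`, `pairwise` (p x p), `n`
#'   (complete rows across all traits), and `partial = NULL`.
#' @export
pairwise_correlations <- function(traits, which_traits = NULL,
                                  provenance = c("observed", "imputed",
                                                 "predicted-ancestral")) {
  m <- trait_matrix(traits, which_traits, provenance)
  const <- colnames(m)[apply(m, 2L, function(v) {
    v <- v[!is.na(v)]; length(v) > 0L && sd(v) == 0
  })]
  if (length(const))
    .stopf("constant trait column(s), correlation undefined: %s",
           paste(const, collapse = ", "))
  for (j in seq_len(ncol(m))) for (k in seq_len(ncol(m))) {
    if (k > j && sum(stats::complete.cases(m[, c(j, k)])) < 3L)
      .stopf("fewer than 3 complete rows for pair (%s, %s)",
             colnames(m)[j], colnames(m)[k])
  }
  r <- cor(m, use = "pairwise.complete.obs")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(traits = colnames(m), pairwise = r, partial = NULL,
                 n = sum(stats::complete.cases(m))),
            class = "correlation_result")
}

#' Partial correlations among traits
#'
#' The partial correlation of traits i and j given all others is computed
#' from the inverse of the complete-case pairwise correlation matrix:
#' `rho[i, j] = -P[i, j] / sqrt(P[i, i] * P[j, j])` with `P = solve(R)`.
#' Rows with any missing value across the selected traits are dropped
#' (complete-case deletion).
#'
#' @inheritParams trait_matrix
#' @return a `correlation_result` with both `pairwise` and `partial`
#'   matrices, `n` (complete cases) and `condition_number` of `R`.
#' @export
partial_correlations <- function(traits, which_traits = NULL,
                                 provenance = c("observed", "imputed",
                                                "predicted-ancestral")) {
  m <- trait_matrix(traits, which_traits, provenance)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  p <- ncol(m)
  if (nrow(m) < p + 3L)
    .stopf("need at least p + 3 = %d complete rows, have %d", p + 3L, nrow(m))
  sds <- apply(m, 2L, sd)
  if (any(sds == 0))
    .stopf("constant trait column(s) on complete cases: %s",
           paste(colnames(m)[sds == 0], collapse = ", "))
  R <- cor(m)
  kappa_R <- kappa(R, exact = TRUE)
  P <- tryCatch(solve(R), error = function(e)
    .stopf("correlation matrix is singular (condition number %.3g); remove a redundant trait",
           kappa_R))
  d <- sqrt(diag(P))
  rho <- -P / outer(d, d)
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2
  structure(list(traits = colnames(m), pairwise = R, partial = rho,
                 n = nrow(m), condition_number = kappa_R),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result: %d traits, n = %d%s\n", length(x$traits), x$n,
              if (!is.null(x$partial)) " (pairwise + partial)" else ""))
  invisible(x)
}

#' Minimum-BIC forest over traits
#'
#' Builds the sparse trait-coevolution graph: in a Gaussian graphical model,
#' adding edge (i, j) to the empty model improves the fit by
#' `-n * log(1 - r[i, j]^2)` at the cost of one parameter (`log n` in BIC),
#' so the edge's BIC gain is `w[i, j] = -n * log(1 - r[i, j]^2) - log(n)`.
#' The maximum-weight spanning forest over the positive-gain edges (Kruskal's
#' algorithm, ties broken by the lexicographic trait-name pair) is the
#' minimum-BIC forest (Chow-Liu with a BIC penalty). Edges are annotated with
#' the partial correlations computed on the same complete-case rows.
#'
#' @inheritParams trait_matrix
#' @return a `trait_graph`: `nodes`, `edges` data.frame (`from`, `to`,
#'   `pairwise_cor`, `partial_cor`, `bic_gain`), `n`, `forest = TRUE`.
#' @export
min_bic_forest <- function(traits, which_traits = NULL,
                           provenance = c("observed", "imputed",
                                          "predicted-ancestral")) {
  m <- trait_matrix(traits, which_traits, provenance)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 20L) .stopf("need at least 20 complete rows, have %d", n)
  R <- cor(m)
  pc <- tryCatch(partial_correlations(traits, which_traits, provenance)$partial,
                 error = function(e) NULL)
  nodes <- colnames(m)
  p <- length(nodes)
  cand <- NULL
  for (i in seq_len(p - 1L)) for (j in seq((i + 1L), p)) {
    w <- -n * log(max(1 - R[i, j]^2, .Machine$double.xmin)) - log(n)
    cand <- rbind(cand, data.frame(from = nodes[i], to = nodes[j],
                                   pairwise_cor = R[i, j],
                                   partial_cor = if (is.null(pc)) NA_real_ else pc[i, j],
                                   bic_gain = w, stringsAsFactors = FALSE))
  }
  cand <- cand[cand$bic_gain > 0, , drop = FALSE]
  # Kruskal, deterministic: sort by gain desc, then lexicographic pair
  if (nrow(cand)) {
    cand <- cand[order(-cand$bic_gain, cand$from, cand$to), , drop = FALSE]
    comp <- stats::setNames(seq_len(p), nodes)   # union-find by relabelling
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      ci <- comp[[cand$from[k]]]; cj <- comp[[cand$to[k]]]
      if (ci != cj) {
        keep[k] <- TRUE
        comp[comp == cj] <- ci
      }
    }
    cand <- cand[keep, , drop = FALSE]
    rownames(cand) <- NULL
  }
  structure(list(nodes = nodes,
                 edges = cand %||% data.frame(from = character(0), to = character(0),
                                              pairwise_cor = numeric(0),
                                              partial_cor = numeric(0),
                                              bic_gain = numeric(0)),
                 n = n, forest = TRUE),
            class = "trait_graph")
}

#' @export
print.trait_graph <- function(x, ...) {
  cat(sprintf("trait_graph: %d nodes, %d edges (min-BIC forest, n = %d)\n",
              length(x$nodes), nrow(x$edges), x$n))
  invisible(x)
}

#' Convert a trait graph to igraph
#' @param g a `trait_graph`.
#' @return an [igraph::graph_from_data_frame()] undirected graph.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "trait_graph"))
  igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                vertices = data.frame(name = g$nodes))
}

#' Export a trait graph
#'
#' @param g a `trait_graph`.
#' @param path output file.
#' @param format `"tsv"` (edge list), `"graphml"`, or `"dot"`.
#' @export
write_trait_graph <- function(g, path, format = c("tsv", "graphml", "dot")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(g$edges, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA", fileEncoding = "UTF-8")
  } else if (format == "graphml") {
    igraph::write_graph(as_igraph(g), path, format = "graphml")
  } else {
    lines <- c("graph traits {",
               sprintf("  \"%s\";", g$nodes),
               if (nrow(g$edges))
                 sprintf("  \"%s\" -- \"%s\" [label=\"%.3f\"];",
                         g$edges$from, g$edges$to, g$edges$partial_cor),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}
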