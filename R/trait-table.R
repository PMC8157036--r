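#' Trait tables keyed by branch identifier
#'
#' Rows are branches (terminal rows keyed by taxon name; internal rows appear
#' after ancestral prediction), columns are traits. Each trait is declared
#' `continuous` (positive real on its original scale; models log-transform it)
#' or `binary` (0/1). Every non-missing cell carries a provenance flag:
#' `observed`, `imputed`, or `predicted-ancestral`.
#'
#' @param values data.frame of numeric columns, rownames = branch ids.
#' @param types named character vector mapping each trait to `"continuous"`
#'   or `"binary"`. If `NULL`, columns whose values are all in \{0, 1\} are
#'   inferred binary, the rest continuous.
#' @param provenance character matrix of the same shape as `values`, or
#'   `NULL` to flag every non-missing cell `observed`.
#' @return a `trait_table` object.
#' @export
trait_table <- function(values, types = NULL, provenance = NULL) {
  stopifnot(is.data.frame(values))
  if (nrow(values) == 0L || ncol(values) == 0L) .stopf("empty trait table")
  if (is.null(rownames(values))) .stopf("trait table rows must be named by branch id")
  for (j in names(values)) values[[j]] <- as.double(values[[j]])
  if (is.null(types)) {
    types <- vapply(values, function(v) {
      if (all(v[!is.na(v)] %in% c(0, 1))) "binary" else "continuous"
    }, character(1))
  }
  if (!all(names(values) %in% names(types)))
    .stopf("missing type declaration for trait(s): %s",
           paste(setdiff(names(values), names(types)), collapse = ", "))
  types <- types[names(values)]
  if (!all(types %in% c("continuous", "binary")))
    .stopf("trait types must be 'continuous' or 'binary'")
  for (j in names(values)) {
    v <- values[[j]]
    if (types[[j]] == "continuous" && any(v <= 0, na.rm = TRUE))
      .stopf("continuous trait '%s' has non-positive values (log transform undefined)", j)
    if (types[[j]] == "binary" && !all(v[!is.na(v)] %in% c(0, 1)))
      .stopf("binary trait '%s' has values outside {0, 1, NA}", j)
  }
  if (is.null(provenance)) {
    provenance <- matrix(NA_character_, nrow(values), ncol(values),
                         dimnames = list(rownames(values), names(values)))
    provenance[!is.na(as.matrix(values))] <- "observed"
  } else {
    stopifnot(identical(dim(provenance), dim(as.matrix(values))))
    dimnames(provenance) <- list(rownames(values), names(values))
    ok <- is.na(provenance) | provenance %in% c("observed", "imputed", "predicted-ancestral")
    if (!all(ok)) .stopf("invalid provenance flags")
    if (any(!is.na(as.matrix(values)) & is.na(provenance)))
      .stopf("every non-missing entry needs a provenance flag")
  }
  structure(list(values = values, types = types, provenance = provenance),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d branches x %d traits (%d continuous, %d binary)\n",
              nrow(x$values), ncol(x$values),
              sum(x$types == "continuous"), sum(x$types == "binary")))
  prov <- table(x$provenance)
  if (length(prov)) cat("  provenance:", paste(names(prov), prov, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trait_table <- function(x) dim(x$values)

#' Accessors for trait tables
#' @param x a `trait_table`.
#' @name trait_table-accessors
#' @export
trait_types <- function(x) x$types

#' @rdname trait_table-accessors
#' @export
trait_values <- function(x) x$values

#' @rdname trait_table-accessors
#' @export
trait_provenance <- function(x) x$provenance

#' Read a trait table from TSV
#'
#' The first column must hold taxon (branch) names, remaining columns one
#' trait each; `NA` or empty cells are missing. Files written by
#' [write_trait_table()] carry `<trait>__provenance` sidecar columns, which
#' are recognised and restored.
#'
#' @param path TSV file with a header row.
#' @param types named character vector of trait type declarations (see
#'   [trait_table()]), or `NULL` to infer.
#' @export
read_trait_table <- function(path, types = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), fileEncoding = "UTF-8")
  if (nrow(df) == 0L || ncol(df) < 2L) .stopf("empty or malformed trait table '%s'", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) .stopf("duplicate branch ids in trait table")
  df <- df[, -1L, drop = FALSE]
  prov_cols <- grep("__provenance$", names(df), value = TRUE)
  prov <- NULL
  if (length(prov_cols)) {
    traits <- sub("__provenance$", "", prov_cols)
    vals <- df[, setdiff(names(df), prov_cols), drop = FALSE]
    if (!setequal(traits, names(vals))) .stopf("provenance columns do not match traits")
    prov <- as.matrix(as.data.frame(lapply(df[prov_cols], as.character),
                                    check.names = FALSE))
    colnames(prov) <- traits
    prov <- prov[, names(vals), drop = FALSE]
    df <- vals
  }
  rownames(df) <- ids
  if (!is.null(prov)) rownames(prov) <- ids
  trait_table(df, types = types, provenance = prov)
}

#' Write a trait table (values + provenance) to TSV
#'
#' @param x a `trait_table`.
#' @param path output file.
#' @export
write_trait_table <- function(x, path) {
  stopifnot(inherits(x, "trait_table"))
  if (nrow(x$values) == 0L || ncol(x$values) == 0L) .stopf("refusing to write an empty trait table")
  out <- data.frame(branch = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (j in names(x$values)) out[[paste0(j, "__provenance")]] <- x$provenance[, j]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA",
              fileEncoding = "UTF-8")
  invisible(path)
}

# set one cell with provenance; internal
.set_trait_cell <- function(x, branch, trait, value, provenance) {
  if (!branch %in% rownames(x$values)) {
    new <- x$values[1, , drop = FALSE]
    new[1, ] <- NA
    rownames(new) <- branch
    x$values <- rbind(x$values, new)
    x$provenance <- rbind(x$provenance,
                          matrix(NA_character_, 1, ncol(x$provenance),
                                 dimnames = list(branch, colnames(x$provenance))))
  }
  x$values[branch, trait] <- value
  x$provenance[branch, trait] <- provenance
  x
}

#' Append predicted-ancestral rows to a trait table
#'
#' @param x a `trait_table` of terminal observations.
#' @param prediction an `ancestral_prediction` from [predict_branches()].
#' @return the augmented `trait_table`.
#' @export
add_ancestral_rows <- function(x, prediction) {
  stopifnot(inherits(x, "trait_table"), inherits(prediction, "ancestral_prediction"))
  trait <- attr(prediction, "trait")
  if (!trait %in% names(x$values)) .stopf("trait '%s' not in table", trait)
  for (i in seq_len(nrow(prediction))) {
    x <- .set_trait_cell(x, prediction$branch[i], trait, prediction$value[i],
                         "predicted-ancestral")
  }
  x
}

#' Expand a categorical vector into one-vs-rest binary columns
#'
#' Used for traits with more than two states (e.g. diet: carnivory,
#' herbivory, omnivory) so they can enter correlation networks and
#' correlated-evolution models as binary indicators.
#'
#' @param x character or factor vector (names preserved).
#' @param prefix optional column-name prefix.
#' @return a 0/1 matrix with one column per level.
#' @export
one_vs_rest <- function(x, prefix = NULL) {
  f <- as.factor(x)
  m <- sapply(levels(f), function(l) as.integer(f == l))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(f), dimnames = list(NULL, levels(f)))
  rownames(m) <- names(x)
  if (!is.null(prefix)) colnames(m) <- paste0(prefix, colnames(m))
  m
}
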