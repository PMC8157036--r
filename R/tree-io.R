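#' Species trees with stable branch identifiers
#'
#' A `species_tree` wraps an [ape::read.tree()] `phylo` object together with a
#' canonical identifier for every branch. The identifier of a terminal branch
#' is its taxon name; the identifier of an internal branch is the sorted list
#' of the taxon names descending from it, joined by `"|"`. Identifiers are
#' therefore a pure function of the topology and do not depend on how the
#' newick string happens to be rotated. All downstream objects (gene-branch
#' matrices, trait tables, predictions) are keyed by these identifiers, so the
#' branch -- not the node -- is the unit of observation throughout.
#'
#' @param phy a rooted `phylo` object with unique tip labels.
#' @param time_calibrated logical; if `TRUE` the branch lengths of `phy` are
#'   interpreted as durations in Ma and stored as such.
#'
#' @return An object of class `species_tree`: a list with elements `phylo`,
#'   `ids` (one identifier per edge, in `phy$edge` row order), `leafsets`
#'   (descendant taxa per edge), `durations` (numeric, Ma, or `NULL`) and
#'   `time_calibrated`.
#' @export
as_species_tree <- function(phy, time_calibrated = FALSE) {
  if (!inherits(phy, "phylo")) .stopf("'phy' must be a 'phylo' object")
  if (anyDuplicated(phy$tip.label))
    .stopf("duplicate leaf labels: %s",
           paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (!ape::is.rooted(phy))
    .stopf("tree is unrooted (root is a polytomy); root the tree first")
  leafsets <- .edge_leafsets(phy)
  n_tip <- length(phy$tip.label)
  ids <- vapply(seq_len(nrow(phy$edge)), function(k) {
    child <- phy$edge[k, 2L]
    if (child <= n_tip) phy$tip.label[child] else paste(leafsets[[k]], collapse = "|")
  }, character(1))
  if (anyDuplicated(ids)) .stopf("branch identifiers are not unique (degenerate topology?)")
  durations <- NULL
  if (time_calibrated) {
    if (is.null(phy$edge.length))
      .stopf("time-calibrated tree requested but the tree has no branch lengths")
    if (any(phy$edge.length < 0)) .stopf("negative branch durations")
    durations <- phy$edge.length
    names(durations) <- ids
  }
  structure(
    list(phylo = phy, ids = ids, leafsets = leafsets,
         durations = durations, time_calibrated = time_calibrated),
    class = "species_tree"
  )
}

# descendant tip labels (sorted) for every edge, postorder accumulation
.edge_leafsets <- function(phy) {
  n_tip <- length(phy$tip.label)
  sets <- vector("list", n_tip + phy$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- phy$tip.label[i]
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]
    ch <- po$edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(seq_len(nrow(phy$edge)), function(k) sort(sets[[phy$edge[k, 2L]]]))
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("species_tree: %d taxa, %d branches%s\n",
              length(x$phylo$tip.label), length(x$ids),
              if (x$time_calibrated) ", time-calibrated (Ma)" else ""))
  invisible(x)
}

#' Read a rooted species tree from a newick file
#'
#' @param path path to a newick file containing a single rooted tree.
#' @param time_calibrated logical; treat branch lengths as durations in Ma.
#' @return a [as_species_tree()] object.
#' @export
read_species_tree <- function(path, time_calibrated = FALSE) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) .stopf("expected a single tree, found %d", length(tr))
    tr <- tr[[1L]]
  }
  if (is.null(tr)) .stopf("could not parse newick file '%s'", path)
  as_species_tree(tr, time_calibrated = time_calibrated)
}

#' Write a species tree to newick
#'
#' Durations (when present) are written as branch lengths.
#' @param tree a `species_tree`.
#' @param path output file.
#' @export
write_species_tree <- function(tree, path) {
  phy <- tree$phylo
  if (tree$time_calibrated) phy$edge.length <- unname(tree$durations)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Branch table of a species tree
#'
#' @param tree a `species_tree`.
#' @return a data.frame with one row per branch: `id`, `parent_node`,
#'   `child_node`, `terminal`, and `duration` (NA when not time-calibrated).
#' @export
branches <- function(tree) {
  stopifnot(inherits(tree, "species_tree"))
  n_tip <- length(tree$phylo$tip.label)
  data.frame(
    id = tree$ids,
    parent_node = tree$phylo$edge[, 1L],
    child_node = tree$phylo$edge[, 2L],
    terminal = tree$phylo$edge[, 2L] <= n_tip,
    duration = if (tree$time_calibrated) unname(tree$durations) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' @rdname branches
#' @export
terminal_branches <- function(tree) {
  b <- branches(tree)
  b$id[b$terminal]
}

#' @rdname branches
#' @export
internal_branches <- function(tree) {
  b <- branches(tree)
  b$id[!b$terminal]
}

#' Check that a time tree is ultrametric
#'
#' All root-to-tip duration sums must agree within `tol` (Ma).
#' @param tree a time-calibrated `species_tree`.
#' @param tol tolerance in Ma.
#' @return logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "species_tree"))
  if (!tree$time_calibrated) .stopf("tree is not time-calibrated")
  phy <- tree$phylo
  phy$edge.length <- unname(tree$durations)
  depths <- ape::node.depth.edgelength(phy)
  tip_depths <- depths[seq_len(length(phy$tip.label))]
  diff(range(tip_depths)) <= tol
}

# ---------------------------------------------------------------------------
# gene trees -> gene-branch matrix

#' Gene x branch matrix of per-gene branch lengths
#'
#' Validating constructor: rows are genes, columns are exactly the branch set
#' of `species`, entries are branch lengths in substitutions/site (NA =
#' missing). Genes whose fraction of non-missing entries falls below
#' `min_coverage` are dropped.
#'
#' @param m numeric matrix with rownames (gene ids) and colnames (branch ids).
#' @param species the associated `species_tree`.
#' @param min_coverage minimum fraction of non-missing entries per gene row.
#' @return a `gene_branch_matrix` (a numeric matrix with attributes).
#' @export
gene_branch_matrix <- function(m, species, min_coverage = 0.8) {
  stopifnot(is.matrix(m), inherits(species, "species_tree"))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    .stopf("gene-branch matrix must have gene rownames and branch colnames")
  if (!setequal(colnames(m), species$ids))
    .stopf("matrix columns do not match the branch set of the species tree")
  m <- m[, species$ids, drop = FALSE]
  if (any(m < 0, na.rm = TRUE)) .stopf("negative branch lengths in gene-branch matrix")
  cov <- rowMeans(!is.na(m))
  keep <- cov >= min_coverage
  if (!all(keep))
    message(sprintf("dropping %d gene(s) with coverage < %.2f", sum(!keep), min_coverage))
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) .stopf("no genes retained after coverage filtering")
  structure(m, class = c("gene_branch_matrix", "matrix", "array"),
            min_coverage = min_coverage)
}

#' Read per-gene trees and map their branch lengths onto the species tree
#'
#' Each gene tree must contain a subset of the species-tree taxa and, on the
#' shared taxa, the same topology as the species tree restricted to them.
#' Branch lengths are assigned to species-tree branches by matching the set of
#' descendant taxa: when a gene-tree branch spans a path of several
#' species-tree branches (because intervening taxa are missing from the gene),
#' its length is assigned to the most tipward branch of the path and the
#' remaining branches of the path are recorded as missing. Genes whose
#' topology conflicts with the species tree are skipped with a warning.
#'
#' @param path a multi-newick file, one tree per line.
#' @param species the `species_tree` defining the branch universe.
#' @param min_coverage per-gene minimum fraction of non-missing branches.
#' @return a [gene_branch_matrix()]; attribute `skipped` counts genes dropped
#'   for topology conflicts.
#' @export
read_gene_trees <- function(path, species, min_coverage = 0.8) {
  trs <- ape::read.tree(path)
  if (inherits(trs, "phylo")) trs <- structure(list(trs), class = "multiPhylo")
  if (is.null(trs) || length(trs) == 0L) .stopf("no trees parsed from '%s'", path)
  gene_ids <- names(trs) %||% sprintf("gene_%d", seq_along(trs))
  if (is.null(names(trs)) || any(names(trs) == ""))
    gene_ids <- sprintf("gene_%d", seq_along(trs))

  rows <- vector("list", length(trs))
  keep <- logical(length(trs))
  skipped <- 0L
  for (i in seq_along(trs)) {
    row <- tryCatch(.map_gene_tree(trs[[i]], species),
                    error = function(e) e)
    if (inherits(row, "error")) {
      .warnf("gene '%s' skipped: %s", gene_ids[i], conditionMessage(row))
      skipped <- skipped + 1L
    } else {
      rows[[i]] <- row
      keep[i] <- TRUE
    }
  }
  if (!any(keep)) .stopf("zero genes retained from '%s'", path)
  m <- do.call(rbind, rows[keep])
  rownames(m) <- gene_ids[keep]
  colnames(m) <- species$ids
  out <- gene_branch_matrix(m, species, min_coverage = min_coverage)
  attr(out, "skipped") <- skipped
  out
}

# map one gene tree's branch lengths onto the species branch ids
.map_gene_tree <- function(gt, species) {
  sp_taxa <- species$phylo$tip.label
  if (!all(gt$tip.label %in% sp_taxa))
    stop("gene tree contains taxa absent from the species tree: ",
         paste(setdiff(gt$tip.label, sp_taxa), collapse = ", "))
  if (is.null(gt$edge.length)) stop("gene tree has no branch lengths")
  gt_st <- as_species_tree(gt)      # also checks rootedness/uniqueness
  gene_taxa <- gt$tip.label

  # species branches restricted to the gene's taxa
  restr <- lapply(species$leafsets, function(s) s[s %in% gene_taxa])
  restr_key <- vapply(restr, paste, character(1), collapse = "|")
  full_size <- lengths(species$leafsets)

  # topology check: the gene tree's branch leafsets must coincide with the
  # distinct non-empty proper restricted leafsets of the species tree (a
  # species branch ancestral to ALL of the gene's taxa has no gene-tree
  # counterpart: the gene tree's root carries no incoming branch)
  gene_key <- vapply(gt_st$leafsets, paste, character(1), collapse = "|")
  full_key <- paste(sort(gene_taxa), collapse = "|")
  sp_nonempty <- unique(restr_key[restr_key != "" & restr_key != full_key])
  if (!setequal(gene_key, sp_nonempty))
    stop("topology conflicts with the species tree on the shared taxa")

  out <- rep(NA_real_, length(species$ids))
  gt_len <- gt$edge.length
  for (k in seq_along(gene_key)) {
    hits <- which(restr_key == gene_key[k])
    if (length(hits) == 0L) next
    target <- hits[which.min(full_size[hits])]  # most tipward branch of the path
    out[target] <- gt_len[k]
  }
  out
}

# ---------------------------------------------------------------------------
# generic TSV matrix I/O

#' Write a numeric matrix (or gene-branch matrix) as TSV
#'
#' First column holds rownames under the header `id`; missing values are
#' written as `NA`. Empty objects are an error.
#' @param x matrix with dimnames.
#' @param path output file.
#' @export
write_matrix <- function(x, path) {
  if (is.null(dim(x)) || nrow(x) == 0L || ncol(x) == 0L)
    .stopf("refusing to write an empty matrix")
  df <- data.frame(id = rownames(x), as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA",
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix()]
#' @param path input file.
#' @return a numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), fileEncoding = "UTF-8")
  if (nrow(df) == 0L || ncol(df) < 2L) .stopf("empty or malformed matrix file '%s'", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' Read a gene-branch matrix from TSV and bind it to a species tree
#' @param path TSV file (genes in rows, branch ids in columns).
#' @param species the `species_tree` whose branch set the columns must match.
#' @param min_coverage per-gene coverage filter.
#' @export
read_gene_branch_matrix <- function(path, species, min_coverage = 0.8) {
  gene_branch_matrix(read_matrix(path), species, min_coverage = min_coverage)
}
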