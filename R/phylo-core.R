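#' Normalize taxon names to the newick dialect convention
#'
#' Trims surrounding whitespace and converts internal spaces to underscores so
#' that species names in trait/occupancy tables match tree tip labels, which
#' cannot contain spaces in standard newick.
#'
#' @param x character vector of names.
#' @return character vector of normalized names.
#' @export
normalize_taxon_names <- function(x) {
  x <- trimws(as.character(x))
  gsub(" ", "_", x, fixed = TRUE)
}

#' Read and validate a phylogeny
#'
#' Parses a single rooted newick tree (from a file or a literal string),
#' validates it (unique tip labels, single statement, branch lengths present)
#' and normalizes tip labels. Trees with polytomies are accepted; only the
#' simulators in this package guarantee binary trees.
#'
#' @param file path to a newick file containing exactly one tree.
#' @param text a newick string; overrides `file` when supplied.
#' @param missing_lengths what to do when branch lengths are absent:
#'   `"error"` (default) or `"one"` to substitute 1.0 for every edge.
#' @return an object of class `phylo` (see [ape::read.tree()]).
#' @export
read_phylogeny <- function(file = NULL, text = NULL,
                           missing_lengths = c("error", "one")) {
  missing_lengths <- match.arg(missing_lengths)
  if (is.null(text)) {
    if (is.null(file)) stop("supply either `file` or `text`")
    if (!file.exists(file)) stop("tree file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("empty newick input")
  if (!grepl(";", text, fixed = TRUE)) {
    stop("newick parse error: no ';' terminator (at position ", nchar(text), ")")
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("newick parse error: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, "')')")
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error: not a valid tree statement")
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("expected a single tree, found ", length(tree))
    tree <- tree[[1L]]
  }
  validate_phylogeny(tree, missing_lengths = missing_lengths)
}

validate_phylogeny <- function(tree, missing_lengths = "error") {
  stopifnot(inherits(tree, "phylo"))
  tree$tip.label <- normalize_taxon_names(tree$tip.label)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    if (missing_lengths == "one") {
      tree$edge.length <- rep(1, nrow(tree$edge))
    } else {
      stop("tree has no branch lengths; re-read with missing_lengths = \"one\" ",
           "to substitute 1.0")
    }
  }
  if (anyNA(tree$edge.length)) stop("tree has NA branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 tips")
  tree
}

#' Write a phylogeny to newick
#'
#' @param tree a `phylo` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_phylogeny <- function(tree, file) {
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' Clamp zero-length terminal branches
#'
#' Maximum-likelihood trees routinely contain zero-length branches; a zero
#' terminal branch makes the phylogenetic covariance matrix singular, which
#' breaks Blomberg's K and PGLS. Zero terminal branches are clamped to
#' `eps_frac` times the maximum root-to-tip depth, with a warning.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param eps_frac clamp value as a fraction of tree depth (default 1e-8).
#' @return the sanitized tree.
#' @export
sanitize_branch_lengths <- function(tree, eps_frac = 1e-8) {
  tree <- validate_phylogeny(tree)
  ntip <- length(tree$tip.label)
  terminal <- tree$edge[, 2] <= ntip
  zero_term <- terminal & tree$edge.length == 0
  if (any(zero_term)) {
    depth <- max(ape::node.depth.edgelength(tree))
    if (depth <= 0) stop("tree has zero total depth; cannot sanitize")
    tree$edge.length[zero_term] <- eps_frac * depth
    warning(sum(zero_term), " zero-length terminal branch(es) clamped to ",
            format(eps_frac * depth, digits = 3))
  }
  tree
}

#' Prune a phylogeny to a taxon subset
#'
#' Keeps only the named tips; internal degree-2 nodes created by pruning are
#' collapsed with their branch lengths summed, so the path length between any
#' two kept tips is unchanged.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to keep (at least 2).
#' @return the pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  tree <- validate_phylogeny(tree)
  keep <- normalize_taxon_names(keep)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2L) stop("need at least 2 taxa to keep")
  ape::keep.tip(tree, keep)
}

#' Phylogenetic variance-covariance matrix
#'
#' Computes the tip-by-tip matrix V whose diagonal holds root-to-tip path
#' lengths and whose off-diagonal (i, j) entry is the path length from the
#' root to the most recent common ancestor of tips i and j -- the shared
#' evolutionary history under Brownian motion. Valid for non-ultrametric
#' trees and trees with polytomies.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return a symmetric numeric matrix with dimnames equal to the tip labels,
#'   in tree tip order.
#' @export
phylo_vcv <- function(tree) {
  tree <- validate_phylogeny(tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  # depth of every node measured from the root along branch lengths
  depth <- numeric(ntip + nnode)
  edge <- tree$edge
  # parents precede children in the order returned by reorder(, "cladewise")
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tree_cw$edge))) {
    p <- tree_cw$edge[k, 1]
    ch <- tree_cw$edge[k, 2]
    depth[ch] <- depth[p] + tree_cw$edge.length[k]
  }
  children <- split(edge[, 2], edge[, 1])
  V <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  diag(V) <- depth[seq_len(ntip)]
  # tips below each node, computed bottom-up in postorder
  tree_po <- ape::reorder.phylo(tree, "postorder")
  tipsets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) tipsets[[i]] <- i
  internal_po <- unique(tree_po$edge[, 1])
  for (node in internal_po) {
    ch <- children[[as.character(node)]]
    tipsets[[node]] <- unlist(tipsets[ch], use.names = FALSE)
    # pairs of tips whose MRCA is exactly this node span different children
    if (length(ch) >= 2L) {
      for (a in seq_len(length(ch) - 1L)) {
        for (b in seq(a + 1L, length(ch))) {
          ta <- tipsets[[ch[a]]]
          tb <- tipsets[[ch[b]]]
          V[ta, tb] <- depth[node]
          V[tb, ta] <- depth[node]
        }
      }
    }
  }
  V
}

#' Pairwise tip path lengths from a covariance matrix
#'
#' d(i, j) = V(i, i) + V(j, j) - 2 V(i, j); the patristic distance.
#'
#' @param V a phylogenetic covariance matrix.
#' @return a symmetric distance matrix.
#' @export
vcv_to_distances <- function(V) {
  d <- outer(diag(V), diag(V), "+") - 2 * V
  dimnames(d) <- dimnames(V)
  d
}

#' Reconcile species names between tree and tables
#'
#' @param tree_taxa tip labels.
#' @param table_taxa species names from a data table.
#' @param on_mismatch `"error"` (default) or `"drop"`: drop reports and
#'   returns only the intersection.
#' @return character vector of reconciled names (tree order).
#' @keywords internal
reconcile_taxa <- function(tree_taxa, table_taxa, on_mismatch = c("error", "drop")) {
  on_mismatch <- match.arg(on_mismatch)
  table_taxa <- normalize_taxon_names(table_taxa)
  only_tree <- setdiff(tree_taxa, table_taxa)
  only_table <- setdiff(table_taxa, tree_taxa)
  if (length(only_tree) || length(only_table)) {
    msg <- paste0(
      "species name mismatch between tree and tables.\n",
      if (length(only_tree)) paste0("  in tree only: ",
                                    paste(only_tree, collapse = ", "), "\n"),
      if (length(only_table)) paste0("  in tables only: ",
                                     paste(only_table, collapse = ", "), "\n"))
    if (on_mismatch == "error") stop(msg)
    warning(msg, "dropping unmatched names")
  }
  intersect(tree_taxa, table_taxa)
}
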