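#' Fixed postorder branch enumeration of a tree
#'
#' Establishes the branch ordering that every profile and metric kernel in
#' the package indexes against: the tree's edges in postorder (children
#' before parents) followed by one entry for the root's own edge. The
#' enumeration is computed once per tree and can be cached on the tree with
#' \code{cache_branches()}; all downstream matrix builders reuse a cached
#' enumeration when present, so repeated rarefaction iterations never
#' re-derive branch structure.
#'
#' @param tree a rooted \code{phylo} with branch lengths (see
#'   \code{\link{read_newick}}).
#' @return a \code{branch_enum} list with elements \code{edge} (postorder
#'   edge matrix), \code{lengths} (per-branch lengths, root edge last),
#'   \code{n_branch}, \code{n_tip}, \code{root}, \code{tip_label} and a
#'   compatibility \code{token}.
#' @export
branch_enumeration <- function(tree) {
  cached <- attr(tree, "branch_cache")
  if (!is.null(cached)) return(cached)
  tree <- validate_tree(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(po$tip.label)
  root <- n_tip + 1L
  lengths <- c(po$edge.length, po$root.edge %||% 0)
  enum <- list(edge = po$edge,
               lengths = lengths,
               n_branch = nrow(po$edge) + 1L,
               n_tip = n_tip,
               root = root,
               tip_label = po$tip.label,
               token = paste(c(po$tip.label, sprintf("%.12g", lengths)),
                             collapse = "\r"))
  class(enum) <- "branch_enum"
  enum
}

#' @rdname branch_enumeration
#' @export
cache_branches <- function(tree) {
  attr(tree, "branch_cache") <- branch_enumeration(tree)
  tree
}

#' Align a count table to a tree
#'
#' Every table taxon must map to exactly one leaf; a taxon absent from the
#' tree is an error (never a silent drop). Leaves absent from the table are
#' assigned zero abundance in every sample — they contribute nothing to any
#' UniFrac sum, which is why pruning the tree to the observed taxa is never
#' required for correctness.
#'
#' @param tree a \code{phylo}.
#' @param table a \code{\link{count_table}}.
#' @return list with \code{tree}, \code{table} (columns expanded and
#'   reordered to tip-label order) and \code{zero_taxa} (leaves assigned 0).
#' @export
align_tree_table <- function(tree, table) {
  tree <- validate_tree(tree)
  stopifnot(inherits(table, "count_table"))
  missing <- setdiff(colnames(table), tree$tip.label)
  if (length(missing))
    stop("table taxa missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  zero_taxa <- setdiff(tree$tip.label, colnames(table))
  m <- unclass(table)
  if (length(zero_taxa)) {
    zeros <- matrix(0, nrow(m), length(zero_taxa),
                    dimnames = list(rownames(m), zero_taxa))
    m <- cbind(m, zeros)
  }
  m <- m[, tree$tip.label, drop = FALSE]
  list(tree = tree,
       table = count_table(m, mode = abund_mode(table)),
       zero_taxa = zero_taxa)
}

# Branch-by-sample cumulative abundance matrix: one postorder accumulation
# pass shared by all samples. `tab` must already be aligned to
# enum$tip_label order (samples x tips).
profile_matrix <- function(enum, tab) {
  n_node <- max(enum$edge)
  ns <- nrow(tab)
  vals <- matrix(0, n_node, ns)
  vals[seq_len(enum$n_tip), ] <- t(tab)
  e <- enum$edge
  for (k in seq_len(nrow(e))) {
    vals[e[k, 1L], ] <- vals[e[k, 1L], ] + vals[e[k, 2L], ]
  }
  out <- vals[c(e[, 2L], enum$root), , drop = FALSE]
  colnames(out) <- rownames(tab)
  out
}

#' Per-branch cumulative abundance profile of one sample
#'
#' Entry \eqn{i} is the summed abundance of all leaves descending from
#' branch \eqn{i} of the fixed postorder enumeration; the final entry (the
#' root's own edge) is the sample total. This is the vector \eqn{p_i}
#' (relative mode) or \eqn{c_i} (absolute mode) that every UniFrac formula
#' operates on.
#'
#' @param tree a \code{phylo}.
#' @param counts named per-taxon abundances (names are leaf labels; leaves
#'   not named get 0), or an unnamed vector in tip-label order.
#' @param mode \code{"relative"} or \code{"absolute"}.
#' @return a \code{branch_profile}: numeric vector with the branch lengths,
#'   mode and enumeration token attached.
#' @export
branch_profile <- function(tree, counts, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  enum <- branch_enumeration(tree)
  if (is.null(names(counts))) {
    if (length(counts) != enum$n_tip)
      stop("unnamed counts must have one entry per leaf", call. = FALSE)
    names(counts) <- enum$tip_label
  }
  bad <- setdiff(names(counts), enum$tip_label)
  if (length(bad))
    stop("taxa missing from tree: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(counts < 0)) stop("abundances must be nonnegative", call. = FALSE)
  full <- stats::setNames(numeric(enum$n_tip), enum$tip_label)
  full[names(counts)] <- counts
  prof <- profile_matrix(enum, matrix(full, nrow = 1,
                                      dimnames = list("s", enum$tip_label)))
  new_branch_profile(prof[, 1L], enum, mode)
}

new_branch_profile <- function(values, enum, mode) {
  structure(as.numeric(values),
            lengths = enum$lengths,
            mode = mode,
            token = enum$token,
            class = "branch_profile")
}

check_profile_pair <- function(pa, pb) {
  stopifnot(inherits(pa, "branch_profile"), inherits(pb, "branch_profile"))
  if (!identical(attr(pa, "token"), attr(pb, "token")))
    stop("profiles come from different branch enumerations", call. = FALSE)
  if (!identical(attr(pa, "mode"), attr(pb, "mode")))
    stop("profile mode mismatch: ", attr(pa, "mode"), " vs ",
         attr(pb, "mode"), call. = FALSE)
  invisible(TRUE)
}

#' Prune a tree to a taxon subset
#'
#' Returns the minimal subtree spanning the requested taxa and the original
#' root. Collapsed unbranched paths have their lengths summed (including
#' into the root edge), so every retained leaf keeps its exact root-to-leaf
#' path length — the property that makes UniFrac distances identical on the
#' full and pruned trees when the removed taxa carry zero abundance.
#'
#' @param tree a \code{phylo}.
#' @param taxa non-empty character vector, a subset of the leaf labels.
#' @return a pruned \code{phylo}.
#' @export
prune_to_taxa <- function(tree, taxa) {
  tree <- validate_tree(tree)
  if (length(taxa) == 0) stop("cannot prune to an empty taxon set",
                              call. = FALSE)
  bad <- setdiff(taxa, tree$tip.label)
  if (length(bad))
    stop("taxa not in tree: ", paste(bad, collapse = ", "), call. = FALSE)
  drop <- setdiff(tree$tip.label, taxa)
  if (!length(drop)) return(tree)
  root_edge0 <- tree$root.edge %||% 0
  if (length(taxa) == 1L) {
    # degenerate one-leaf tree: whole root-to-leaf path becomes the pendant
    depth <- ape::node.depth.edgelength(tree)
    len <- depth[match(taxa, tree$tip.label)]
    out <- list(edge = matrix(c(2L, 1L), 1, 2), edge.length = len,
                tip.label = taxa, Nnode = 1L)
    class(out) <- "phylo"
    out$root.edge <- root_edge0
    return(out)
  }
  pruned <- ape::drop.tip(tree, drop, trim.internal = TRUE,
                          collapse.singles = TRUE)
  # basal edges collapsed away by the prune are restored as root-edge
  # length, determined by root-to-leaf path conservation
  depth0 <- ape::node.depth.edgelength(tree)[match(taxa, tree$tip.label)]
  depth1 <- ape::node.depth.edgelength(pruned)[match(taxa,
                                                     pruned$tip.label)]
  gap <- (depth0 + root_edge0) - depth1
  if (diff(range(gap)) > 1e-9)
    stop("internal error: pruning altered relative leaf depths",
         call. = FALSE)
  pruned$root.edge <- max(gap[1], 0)
  pruned
}
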