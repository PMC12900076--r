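# Independent brute-force oracles. These deliberately avoid the package's
# postorder accumulation: every branch value is obtained by explicitly
# enumerating the branch's descendant leaf set and summing over it.

strip_mode <- function(ct) {
  m <- unclass(ct)
  attr(m, "abund_mode") <- NULL
  m
}

two_leaf_tree <- function() read_newick("(A:1,B:1):0;", text = TRUE)

four_leaf_tree <- function()
  read_newick("((A:1,B:1):0.5,(C:1,D:1):0.5):0;", text = TRUE)

# descendant tip labels of `node`, by walking the edge matrix recursively
descendant_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

# per-branch (length, descendant leaf-set sum) pairs, one entry per edge
# plus the root edge; `counts` is named by leaf label. Branches are listed
# in the package's enumeration order (aligned by child node), but each
# value comes from explicit leaf-set summation, not accumulation.
oracle_branches <- function(tree, counts) {
  full <- stats::setNames(numeric(length(tree$tip.label)), tree$tip.label)
  full[names(counts)] <- counts
  enum <- branch_enumeration(tree)
  ord <- match(enum$edge[, 2], tree$edge[, 2])
  vals <- vapply(ord, function(k) {
    sum(full[descendant_tips(tree, tree$edge[k, 2])])
  }, numeric(1))
  list(lengths = c(tree$edge.length[ord], tree$root.edge %||% 0),
       values = c(vals, sum(full)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_wuf <- function(tree, ca, cb) {
  oa <- oracle_branches(tree, ca)
  ob <- oracle_branches(tree, cb)
  sum(oa$lengths * abs(oa$values - ob$values)) /
    sum(oa$lengths * (oa$values + ob$values))
}

oracle_gu <- function(tree, ca, cb, alpha) {
  oa <- oracle_branches(tree, ca)
  ob <- oracle_branches(tree, cb)
  s <- oa$values + ob$values
  keep <- s > 0
  w <- oa$lengths[keep] * s[keep]^alpha
  sum(w * abs(oa$values[keep] - ob$values[keep]) / s[keep]) / sum(w)
}

oracle_uw <- function(tree, ca, cb) {
  oa <- oracle_branches(tree, ca)
  ob <- oracle_branches(tree, cb)
  ia <- oa$values > 0
  ib <- ob$values > 0
  sum(oa$lengths[xor(ia, ib)]) / sum(oa$lengths[ia | ib])
}

oracle_bc <- function(a, b) sum(abs(a - b)) / sum(a + b)

# exhaustive permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub)
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# exhaustive-permutation Mantel p-value (add-one convention, matching the
# contract but recomputed from scratch on every relabeling)
oracle_mantel_exhaustive <- function(m1, m2) {
  v1 <- m1[upper.tri(m1)]
  r <- stats::cor(v1, m2[upper.tri(m2)])
  perms <- all_perms(nrow(m1))
  rs <- vapply(perms, function(p) {
    mp <- m2[p, p]
    stats::cor(v1, mp[upper.tri(mp)])
  }, numeric(1))
  list(r = r, p_exhaustive = mean(abs(rs) >= abs(r) - 1e-12))
}

# from-scratch one-way PERMANOVA sums of squares via explicit double loops
oracle_permanova_ss <- function(d, groups) {
  n <- nrow(d)
  ss_t <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    ss_t <- ss_t + d[i, j]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1)
      for (a in seq_len(length(idx) - 1))
        for (b in seq.int(a + 1, length(idx)))
          ss_w <- ss_w + d[idx[a], idx[b]]^2 / length(idx)
  }
  c(between = ss_t - ss_w, within = ss_w, total = ss_t)
}

oracle_permanova_exhaustive <- function(d, groups) {
  n <- nrow(d)
  g <- length(unique(groups))
  fstat_of <- function(lab) {
    ss <- oracle_permanova_ss(d, lab)
    (ss["between"] / (g - 1)) / (ss["within"] / (n - g))
  }
  f0 <- fstat_of(groups)
  fs <- vapply(all_perms(n), function(p) fstat_of(groups[p]), numeric(1))
  list(f = unname(f0), r2 = unname(
         oracle_permanova_ss(d, groups)["between"] /
           oracle_permanova_ss(d, groups)["total"]),
       p_exhaustive = mean(fs >= f0 - 1e-12))
}

# random tree + a pair of integer count vectors over a subset of its taxa
random_pair_fixture <- function(seed, max_taxa = 50) {
  set.seed(seed)
  n <- sample(3:max_taxa, 1)
  fx <- random_fixture(n_taxa = n, n_samples = 2, seed = seed,
                       mean_reads = 500)
  list(tree = fx$tree,
       ca = unclass(fx$table)[1, ],
       cb = unclass(fx$table)[2, ])
}

# random tree with every leaf at the same depth and all branch lengths 1:
# a random chain of branching factors (allowing multifurcations), so the
# family spans stars, balanced binary trees and mixed-arity balanced trees
equal_depth_unit_tree <- function() {
  d <- sample(1:4, 1)
  factors <- sample(2:4, d, replace = TRUE)
  while (prod(factors) > 48) factors <- factors[-length(factors)]
  build <- function(level) {
    if (level > length(factors)) return("X")
    paste0("(", paste(rep(build(level + 1), factors[level]),
                      collapse = ","), "):1")
  }
  nwk <- build(1)
  n <- prod(factors)
  for (i in seq_len(n)) nwk <- sub("X", paste0("L", i, ":1"), nwk,
                                   fixed = TRUE)
  # strip the root's own ":1" so the root edge is zero
  read_newick(paste0(sub(":1$", "", nwk), ":0;"), text = TRUE)
}
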