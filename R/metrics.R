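#' Weighted UniFrac between two branch profiles
#'
#' The normalized weighted UniFrac
#' \deqn{U = \frac{\sum_i b_i |x_i^a - x_i^b|}{\sum_i b_i (x_i^a + x_i^b)}}
#' where \eqn{b_i} is the length of branch \eqn{i} and \eqn{x_i} the
#' cumulative abundance of leaves descending from it. With relative-mode
#' profiles (\eqn{x = p}) this is the conventional weighted UniFrac
#' \eqn{U^R}; with absolute-mode profiles (\eqn{x = c}, load-scaled counts)
#' it is absolute UniFrac \eqn{U^A}, which additionally registers
#' differences in total microbial load: two samples with identical
#' composition but a \eqn{k}-fold load difference are at distance
#' \eqn{(k-1)/(k+1)}.
#'
#' @param pa,pb \code{\link{branch_profile}}s sharing one tree enumeration
#'   and one mode.
#' @return dissimilarity in [0, 1]; 0 for identical profiles.
#' @export
weighted_unifrac <- function(pa, pb) {
  check_profile_pair(pa, pb)
  wuf_kernel(as.numeric(pa), as.numeric(pb), attr(pa, "lengths"))
}

wuf_kernel <- function(xa, xb, b) {
  den <- sum(b * (xa + xb))
  if (den == 0)
    stop("weighted UniFrac undefined: both profiles are all-zero",
         call. = FALSE)
  sum(b * abs(xa - xb)) / den
}

#' Generalized UniFrac between two branch profiles
#'
#' \deqn{GU(\alpha) = \frac{\sum_i b_i (x_i^a + x_i^b)^\alpha
#'   \left|\frac{x_i^a - x_i^b}{x_i^a + x_i^b}\right|}
#'   {\sum_i b_i (x_i^a + x_i^b)^\alpha}}
#' The exponent \eqn{\alpha \in [0,1]} modulates how strongly abundant
#' lineages dominate: \eqn{\alpha = 1} is exactly weighted UniFrac, while
#' \eqn{\alpha \to 0} approaches incidence-like behavior. Branches with
#' \eqn{x_i^a + x_i^b = 0} are excluded from numerator and denominator —
#' the abundance ratio is undefined there, and this matches the reference
#' generalized-UniFrac construction (rather than defining \eqn{0^0 = 1}).
#' Relative profiles give \eqn{GU^R}, absolute profiles \eqn{GU^A}.
#'
#' @inheritParams weighted_unifrac
#' @param alpha a single exponent in [0, 1].
#' @return dissimilarity in [0, 1].
#' @export
generalized_unifrac <- function(pa, pb, alpha) {
  check_profile_pair(pa, pb)
  gu_kernel(as.numeric(pa), as.numeric(pb), attr(pa, "lengths"), alpha)
}

gu_kernel <- function(xa, xb, b, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha > 1)
    stop("`alpha` must be a single value in [0, 1]", call. = FALSE)
  s <- xa + xb
  keep <- s > 0
  if (!any(keep))
    stop("generalized UniFrac undefined: both profiles are all-zero",
         call. = FALSE)
  w <- b[keep] * s[keep]^alpha
  den <- sum(w)
  if (den == 0) return(0)  # only zero-length branches carry abundance
  sum(w * abs(xa[keep] - xb[keep]) / s[keep]) / den
}

#' Unweighted UniFrac between two branch profiles
#'
#' Fraction of covered branch length unique to one sample: branches whose
#' descendant abundance is positive in exactly one profile, over branches
#' positive in at least one. Only incidence matters, so the result is
#' invariant to any positive rescaling of either sample (relative and
#' absolute modes coincide).
#'
#' @inheritParams weighted_unifrac
#' @return dissimilarity in [0, 1].
#' @export
unweighted_unifrac <- function(pa, pb) {
  check_profile_pair(pa, pb)
  uw_kernel(as.numeric(pa), as.numeric(pb), attr(pa, "lengths"))
}

uw_kernel <- function(xa, xb, b) {
  ia <- xa > 0
  ib <- xb > 0
  union_len <- sum(b[ia | ib])
  if (union_len == 0)
    stop("unweighted UniFrac undefined: both profiles are all-zero",
         call. = FALSE)
  sum(b[xor(ia, ib)]) / union_len
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{\sum_j |a_j - b_j| / \sum_j (a_j + b_j)} over per-taxon abundances
#' (no tree). On relative abundances this is \eqn{BC^R}; on load-scaled
#' absolute abundances, \eqn{BC^A}.
#'
#' @param a,b equal-length nonnegative numeric vectors, not both all-zero.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b))
    stop("abundance vectors differ in length", call. = FALSE)
  den <- sum(a + b)
  if (den == 0)
    stop("Bray-Curtis undefined: both samples are all-zero", call. = FALSE)
  sum(abs(a - b)) / den
}

# ---- all-pairs builders ---------------------------------------------------

#' All-pairs distance matrix under a metric specification
#'
#' Applies the mode pipeline the spec demands (raw reads are row-normalized
#' to proportions; absolute weighting multiplies proportions by each
#' sample's load \eqn{N_s}), computes all branch profiles once against the
#' tree's cached postorder enumeration, and evaluates the requested metric
#' for every unordered sample pair.
#'
#' @param table a \code{\link{count_table}}.
#' @param tree a \code{phylo}; required for the UniFrac families.
#' @param spec a \code{\link{metric_spec}}.
#' @param loads a \code{\link{load_vector}}; required when
#'   \code{spec$weighting == "absolute"} and the table is not already in
#'   absolute mode.
#' @return a \code{\link{distance_matrix}}, or a named list of them (one
#'   per alpha) when the generalized family is requested with several
#'   alphas.
#' @export
pairwise_distances <- function(table, tree = NULL, spec, loads = NULL) {
  stopifnot(inherits(table, "count_table"), inherits(spec, "metric_spec"))
  tab <- resolve_mode(table, spec, loads)
  if (spec$family == "bray_curtis") return(bc_matrix(tab))
  if (is.null(tree))
    stop("UniFrac metrics require a tree", call. = FALSE)
  al <- align_tree_table(tree, tab)
  enum <- branch_enumeration(al$tree)
  P <- profile_matrix(enum, unclass(al$table))
  b <- enum$lengths
  switch(spec$family,
         unifrac_weighted = wuf_matrix(P, b),
         unifrac_unweighted = uw_matrix(P, b),
         unifrac_generalized = {
           out <- lapply(spec$alpha, function(a) gu_matrix(P, b, a))
           names(out) <- paste0("alpha_", spec$alpha)
           if (length(out) == 1L) out[[1L]] else out
         })
}

resolve_mode <- function(table, spec, loads) {
  if (spec$family == "unifrac_unweighted") return(table)
  target <- spec$weighting
  mode <- abund_mode(table)
  if (target == "relative") {
    as_relative(table)
  } else {
    if (mode == "absolute") return(table)
    if (is.null(loads))
      stop("absolute weighting needs `loads` when the table mode is '",
           mode, "'", call. = FALSE)
    as_absolute(table, loads)
  }
}

finish_metric_matrix <- function(m, labels) {
  dimnames(m) <- list(labels, labels)
  if (any(m > 1 + 1e-12))
    stop("internal error: metric exceeded 1 beyond tolerance", call. = FALSE)
  m[m > 1] <- 1
  distance_matrix(m)
}

# Sum_i b_i |x_ia - x_ib| is the Manhattan distance between load-weighted
# profile columns; the denominator splits into per-sample totals.
wuf_matrix <- function(P, b) {
  w <- colSums(P * b)
  num <- as.matrix(stats::dist(t(P * b), method = "manhattan"))
  den <- outer(w, w, "+")
  if (any(den == 0 & upper.tri(den)))
    stop("weighted UniFrac undefined: two all-zero samples", call. = FALSE)
  m <- num / den
  diag(m) <- 0
  finish_metric_matrix(m, colnames(P))
}

uw_matrix <- function(P, b) {
  I <- (P > 0) * 1
  s <- colSums(I * b)
  uniq <- as.matrix(stats::dist(t(I * b), method = "manhattan"))
  union_len <- (outer(s, s, "+") + uniq) / 2
  if (any(union_len == 0 & upper.tri(union_len)))
    stop("unweighted UniFrac undefined: two all-zero samples", call. = FALSE)
  m <- uniq / union_len
  diag(m) <- 0
  finish_metric_matrix(m, colnames(P))
}

gu_matrix <- function(P, b, alpha) {
  ns <- ncol(P)
  m <- matrix(0, ns, ns)
  for (i in seq_len(ns - 1L)) {
    xi <- P[, i]
    for (j in seq.int(i + 1L, ns)) {
      m[i, j] <- m[j, i] <- gu_kernel(xi, P[, j], b, alpha)
    }
  }
  finish_metric_matrix(m, colnames(P))
}

bc_matrix <- function(tab) {
  m <- unclass(tab)
  tot <- rowSums(m)
  den <- outer(tot, tot, "+")
  if (any(den == 0 & upper.tri(den)))
    stop("Bray-Curtis undefined: two all-zero samples", call. = FALSE)
  num <- as.matrix(stats::dist(m, method = "manhattan"))
  d <- num / den
  diag(d) <- 0
  finish_metric_matrix(d, rownames(m))
}
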