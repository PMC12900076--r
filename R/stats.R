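#' Pairwise load-difference matrix
#'
#' Entry \eqn{(a,b) = |N_a - N_b|}: the distance matrix of absolute
#' abundances alone, used to quantify how strongly a beta-diversity metric
#' is driven by microbial load (via \code{\link{mantel_test}}).
#'
#' @param loads a \code{\link{load_vector}} over at least two samples.
#' @param log10 take differences of \code{log10(N)} instead of raw loads;
#'   off by default.
#' @return a \code{\link{distance_matrix}} (unbounded; not constrained to
#'   [0, 1]).
#' @export
load_difference_matrix <- function(loads, log10 = FALSE) {
  loads <- load_vector(loads)
  if (length(loads) < 2L) stop("need at least two samples", call. = FALSE)
  v <- if (log10) base::log10(unclass(loads)) else unclass(loads)
  m <- abs(outer(v, v, "-"))
  dimnames(m) <- list(names(loads), names(loads))
  distance_matrix(m)
}

align_dm <- function(d1, d2) {
  l1 <- rownames(d1)
  l2 <- rownames(d2)
  if (!setequal(l1, l2) || length(l1) != length(l2))
    stop("distance matrices do not share a sample set", call. = FALSE)
  unclass(d2)[l1, l1]
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the strictly-upper-triangle vectors, with the
#' permutation p-value obtained by simultaneous row/column permutation of
#' the second matrix. Matrices are matched by sample label, not position.
#' The p-value uses the add-one convention
#' \eqn{p = (1 + \#\{|R^*| \ge |R|\}) / (1 + permutations)} and is
#' therefore never exactly zero.
#'
#' @param d1,d2 \code{\link{distance_matrix}} objects over the same samples.
#' @param permutations number of random permutations (default 999).
#' @param seed optional seed for the permutation draw.
#' @return a \code{mantel_result} list: \code{r}, \code{p},
#'   \code{permutations}, \code{seed}, \code{n}.
#' @export
mantel_test <- function(d1, d2, permutations = 999L, seed = NULL) {
  stopifnot(inherits(d1, "distance_matrix"), inherits(d2, "distance_matrix"))
  m2 <- align_dm(d1, d2)
  m1 <- unclass(d1)
  v1 <- upper_vec(m1)
  if (stats::sd(v1) == 0 || stats::sd(upper_vec(m2)) == 0)
    stop("Mantel correlation undefined: a matrix has a constant triangle",
         call. = FALSE)
  r <- stats::cor(v1, upper_vec(m2))
  n <- nrow(m1)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(permutations), function(k) {
      p <- sample.int(n)
      rp <- stats::cor(v1, upper_vec(m2[p, p]))
      abs(rp) >= abs(r) - 1e-12
    }, logical(1)))
  })
  structure(list(r = r, p = (1 + hits) / (1 + permutations),
                 permutations = as.integer(permutations), seed = seed,
                 n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: R = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$r, x$p, x$permutations, x$n))
  invisible(x)
}

permanova_ss <- function(d2, groups, n) {
  ss_total <- sum(upper_vec(d2)) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L)
      ss_within <- ss_within +
        sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Partitions the sum of squared distances among categorical groups:
#' \eqn{SS_T = \sum_{i<j} d_{ij}^2 / n},
#' \eqn{SS_W = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g},
#' \eqn{SS_B = SS_T - SS_W}, pseudo-F
#' \eqn{= (SS_B/(g-1)) / (SS_W/(n-g))} and \eqn{R^2 = SS_B / SS_T}.
#' Significance is assessed by permuting group labels, with the add-one
#' p-value convention.
#'
#' @param dm a \code{\link{distance_matrix}}.
#' @param groups group labels: named by sample, or unnamed in the matrix's
#'   sample order.
#' @param permutations number of label permutations (default 999).
#' @param seed optional seed.
#' @return a \code{permanova_result} list: \code{r2}, \code{f}, \code{p},
#'   \code{ss} (between/within/total), \code{group_sizes},
#'   \code{permutations}, \code{seed}.
#' @export
permanova <- function(dm, groups, permutations = 999L, seed = NULL) {
  stopifnot(inherits(dm, "distance_matrix"))
  n <- nrow(dm)
  if (!is.null(names(groups))) {
    missing <- setdiff(rownames(dm), names(groups))
    if (length(missing))
      stop("no group label for sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    groups <- groups[rownames(dm)]
  } else if (length(groups) != n) {
    stop("`groups` must be named by sample or match the matrix order",
         call. = FALSE)
  }
  groups <- as.character(groups)
  g <- length(unique(groups))
  if (g < 2L) stop("PERMANOVA needs at least two groups", call. = FALSE)
  if (g > n) stop("more groups than samples", call. = FALSE)
  d2 <- unclass(dm)^2
  ss <- permanova_ss(d2, groups, n)
  fstat <- (ss["between"] / (g - 1)) / (ss["within"] / (n - g))
  hits <- with_seed(seed, {
    sum(vapply(seq_len(permutations), function(k) {
      sp <- permanova_ss(d2, groups[sample.int(n)], n)
      fp <- (sp["between"] / (g - 1)) / (sp["within"] / (n - g))
      fp >= fstat - 1e-12
    }, logical(1)))
  })
  structure(list(r2 = unname(ss["between"] / ss["total"]),
                 f = unname(fstat),
                 p = (1 + hits) / (1 + permutations),
                 ss = ss,
                 group_sizes = table(groups),
                 permutations = as.integer(permutations),
                 seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: R2 = %.4f, pseudo-F = %.3f, p = %.4g (%d permutations)\n",
    x$r2, x$f, x$p, x$permutations))
  cat("group sizes:", paste(names(x$group_sizes), x$group_sizes,
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Sensitivity of an absolute-weighted metric to load quantification error
#'
#' Emulates measurement noise in absolute-abundance estimates: in each
#' iteration every sample's load is multiplied by \eqn{1 + u} with
#' \eqn{u \sim \mathrm{Uniform}(-e, +e)}, the distance matrix is recomputed
#' and compared entrywise to the unperturbed matrix. For each error level
#' \eqn{e} the mean and maximum absolute deviation over off-diagonal
#' entries are averaged across iterations.
#'
#' @param table a \code{\link{count_table}}.
#' @param tree a \code{phylo} (UniFrac families) or \code{NULL}
#'   (Bray-Curtis).
#' @param loads a \code{\link{load_vector}}.
#' @param spec an absolute-weighted \code{\link{metric_spec}} with a single
#'   alpha if generalized.
#' @param error_levels proportional error magnitudes, each in [0, 1) (0.01
#'   means +/-1\%).
#' @param iterations perturbation replicates per error level (default 50).
#' @param seed optional master seed.
#' @return data.frame with one row per error level: \code{error},
#'   \code{mean_dev}, \code{max_dev}, \code{sd_mean_dev}, \code{sd_max_dev}.
#' @export
error_sensitivity <- function(table, tree = NULL, loads, spec,
                              error_levels, iterations = 50L, seed = NULL) {
  stopifnot(inherits(spec, "metric_spec"))
  if (spec$family == "unifrac_unweighted" || spec$weighting != "absolute")
    stop("error sensitivity applies to absolute-weighted metrics",
         call. = FALSE)
  if (!is.null(spec$alpha) && length(spec$alpha) != 1L)
    stop("use a single alpha per sensitivity run", call. = FALSE)
  if (any(error_levels < 0 | error_levels >= 1))
    stop("error levels must lie in [0, 1): loads must stay positive",
         call. = FALSE)
  if (abund_mode(table) == "absolute")
    stop("supply raw or relative counts plus `loads`; an absolute table ",
         "already has its loads baked in", call. = FALSE)
  loads <- load_vector(loads)
  base <- unclass(pairwise_distances(table, tree, spec, loads))
  ut <- upper.tri(base)
  ns <- length(loads)
  with_seed(seed, {
    rows <- lapply(error_levels, function(e) {
      devs <- vapply(seq_len(iterations), function(k) {
        pert <- load_vector(unclass(loads) * (1 + stats::runif(ns, -e, e)))
        d <- unclass(pairwise_distances(table, tree, spec, pert))
        delta <- abs(d - base)[ut]
        c(mean(delta), max(delta))
      }, numeric(2))
      data.frame(error = e,
                 mean_dev = mean(devs[1, ]),
                 max_dev = mean(devs[2, ]),
                 sd_mean_dev = stats::sd(devs[1, ]),
                 sd_max_dev = stats::sd(devs[2, ]))
    })
    do.call(rbind, rows)
  })
}
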