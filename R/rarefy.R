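#' Configuration for the rarefaction-averaging workflow
#'
#' @param depth target number of reads per sample; \code{NULL} (default)
#'   uses the minimum read total among retained samples, the recommended
#'   choice.
#' @param iterations number of rarefaction iterations to average (default
#'   100).
#' @param seed master seed; iteration \code{k} uses \code{seed + k}, so any
#'   single iteration is reproducible in isolation.
#' @param min_depth samples with fewer total reads are dropped (with a
#'   warning) before the depth is fixed; \code{NULL} drops nothing.
#' @return a \code{rarefaction_config} list.
#' @export
rarefaction_config <- function(depth = NULL, iterations = 100L, seed = 1L,
                               min_depth = NULL) {
  if (!is.null(depth) &&
      (!is.numeric(depth) || depth < 1 || !is_whole(depth)))
    stop("`depth` must be a positive integer", call. = FALSE)
  if (!is.numeric(iterations) || iterations < 1 || !is_whole(iterations))
    stop("`iterations` must be a positive integer", call. = FALSE)
  structure(list(depth = if (!is.null(depth)) as.integer(round(depth)),
                 iterations = as.integer(round(iterations)),
                 seed = seed,
                 min_depth = min_depth),
            class = "rarefaction_config")
}

#' Rarefy one sample's read counts to a fixed depth
#'
#' Draws \code{depth} reads without replacement (multivariate
#' hypergeometric) from the sample's reads, via sequential conditional
#' hypergeometric draws. The result is elementwise at most \code{counts}
#' and sums exactly to \code{depth}.
#'
#' @param counts nonnegative integer per-taxon read counts.
#' @param depth number of reads to draw; must not exceed the sample total.
#' @param seed optional seed for reproducibility (the caller's RNG stream
#'   is left untouched when a seed is given).
#' @return integer vector, same length and names as \code{counts}.
#' @export
rarefy_sample <- function(counts, depth, seed = NULL) {
  if (!is_whole(counts) || any(counts < 0))
    stop("read counts must be nonnegative integers", call. = FALSE)
  counts <- round(counts)
  total <- sum(counts)
  if (total < depth)
    stop(sprintf("sample total (%d) is below the rarefaction depth (%d)",
                 as.integer(total), as.integer(depth)), call. = FALSE)
  with_seed(seed, {
    out <- counts
    remaining <- total
    need <- as.integer(depth)
    for (j in seq_along(counts)) {
      if (need == 0L) {
        out[j:length(out)] <- 0
        break
      }
      if (remaining == counts[j]) {
        x <- need  # all remaining reads sit in the tail starting here
      } else {
        x <- stats::rhyper(1L, counts[j], remaining - counts[j], need)
      }
      out[j] <- x
      need <- need - x
      remaining <- remaining - counts[j]
    }
    out
  })
}

#' Rarefaction-averaged distance matrix
#'
#' The absolute-abundance rarefaction workflow: in each iteration every
#' sample is subsampled without replacement to a common depth, divided by
#' that depth to give relative abundance (no rounding), multiplied by the
#' sample's microbial load when the metric is absolute-weighted, and the
#' requested distance matrix is computed. The final matrix is the
#' elementwise mean over all iterations. The tree's branch enumeration is
#' established once and shared by every iteration.
#'
#' @param table a \code{\link{count_table}} in \code{"raw_reads"} mode with
#'   integer entries.
#' @param tree a \code{phylo}; required for UniFrac families.
#' @param loads a \code{\link{load_vector}}; required for absolute
#'   weighting.
#' @param spec a \code{\link{metric_spec}}.
#' @param config a \code{\link{rarefaction_config}}.
#' @return a \code{\link{distance_matrix}} (or a named list of them for a
#'   multi-alpha generalized spec).
#' @export
rarefied_distance <- function(table, tree = NULL, loads = NULL, spec,
                              config = rarefaction_config()) {
  stopifnot(inherits(table, "count_table"),
            inherits(config, "rarefaction_config"))
  if (abund_mode(table) != "raw_reads")
    stop("rarefaction applies to raw read counts (mode 'raw_reads')",
         call. = FALSE)
  m <- unclass(table)
  if (!is_whole(m))
    stop("raw read counts must be integers for rarefaction", call. = FALSE)
  m <- round(m)
  totals <- rowSums(m)
  if (!is.null(config$min_depth)) {
    low <- totals < config$min_depth
    if (any(low)) {
      warning("dropping sample(s) below the minimum-depth threshold: ",
              paste(rownames(m)[low], collapse = ", "), call. = FALSE)
      m <- m[!low, , drop = FALSE]
      totals <- totals[!low]
    }
  }
  if (nrow(m) < 2L) stop("fewer than two samples retained", call. = FALSE)
  depth <- config$depth %||% as.integer(min(totals))
  if (any(totals < depth))
    stop("sample(s) below the rarefaction depth: ",
         paste(rownames(m)[totals < depth], collapse = ", "), call. = FALSE)
  if (!is.null(tree)) tree <- cache_branches(tree)

  acc <- NULL
  for (k in seq_len(config$iterations)) {
    it_seed <- if (is.null(config$seed)) NULL else config$seed + k
    rar <- with_seed(it_seed, {
      t(apply(m, 1L, rarefy_sample, depth = depth))
    })
    dimnames(rar) <- dimnames(m)
    rel <- count_table(rar / depth, mode = "relative")
    d <- pairwise_distances(rel, tree = tree, spec = spec, loads = loads)
    if (is.null(acc)) {
      acc <- if (is.list(d)) lapply(d, unclass) else unclass(d)
    } else if (is.list(d)) {
      acc <- Map(`+`, acc, lapply(d, unclass))
    } else {
      acc <- acc + unclass(d)
    }
  }
  if (is.list(acc)) {
    lapply(acc, function(a) distance_matrix(a / config$iterations))
  } else {
    distance_matrix(acc / config$iterations)
  }
}
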