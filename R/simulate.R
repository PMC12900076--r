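#' Full-factorial abundance-grid communities
#'
#' Generates one community per element of \code{levels^n_taxa}: every
#' combination of the given absolute abundance levels across the taxa. The
#' defaults reproduce the four-taxon design in which each ASV takes
#' abundance 1, 10 or 100, giving \eqn{3^4 = 81} unique communities and
#' \eqn{\binom{81}{2} = 3240} pairwise comparisons. Ordering and sample
#' naming are deterministic lexicographic (first taxon varies slowest);
#' each sample is named by its abundance pattern.
#'
#' @param levels positive abundance levels (default \code{c(1, 10, 100)}).
#' @param n_taxa number of taxa (default 4; taxa are named
#'   \code{ASV_1 ... ASV_n}).
#' @return a \code{\link{count_table}} in \code{"absolute"} mode.
#' @export
grid_communities <- function(levels = c(1, 10, 100), n_taxa = 4L) {
  if (length(levels) == 0) stop("`levels` must be non-empty", call. = FALSE)
  if (any(levels <= 0)) stop("`levels` must be positive", call. = FALSE)
  if (n_taxa < 1) stop("`n_taxa` must be at least 1", call. = FALSE)
  # expand.grid varies its first factor fastest; build over reversed taxon
  # order and flip columns so taxon 1 varies slowest (lexicographic rows)
  combos <- as.matrix(expand.grid(rep(list(levels), n_taxa)))
  combos <- combos[, n_taxa:1, drop = FALSE]
  colnames(combos) <- paste0("ASV_", seq_len(n_taxa))
  rownames(combos) <- apply(combos, 1L, function(r)
    paste0("S_", paste(r, collapse = "_")))
  count_table(combos, mode = "absolute")
}

#' Default four-taxon tree for the grid simulation
#'
#' Balanced topology \code{((ASV_1,ASV_2),(ASV_3,ASV_4))} with unit branch
#' lengths throughout. The unit lengths are an explicit placeholder, not an
#' estimate of any published phylogeny: cross-metric correlations on the
#' grid depend on the branch lengths, so analyses that need a particular
#' phylogeny should pass their own tree (or \code{branch_lengths}).
#'
#' @param branch_lengths optional numeric vector of 6 lengths in the order
#'   (pendant ASV_1, ASV_2, ASV_3, ASV_4, internal over \{1,2\}, internal
#'   over \{3,4\}).
#' @return a rooted \code{phylo} with 4 leaves and a zero-length root edge.
#' @export
grid_tree <- function(branch_lengths = NULL) {
  b <- branch_lengths %||% rep(1, 6)
  if (length(b) != 6 || any(b < 0))
    stop("`branch_lengths` must be 6 nonnegative values", call. = FALSE)
  nwk <- sprintf("((ASV_1:%.17g,ASV_2:%.17g):%.17g,(ASV_3:%.17g,ASV_4:%.17g):%.17g):0;",
                 b[1], b[2], b[5], b[3], b[4], b[6])
  read_newick(nwk, text = TRUE)
}

#' Cross-metric comparison over all sample pairs
#'
#' For every unordered sample pair computes Bray-Curtis and weighted
#' UniFrac in both relative and absolute weightings (\eqn{BC^R, BC^A, U^R,
#' U^A}), optionally generalized UniFrac at requested alphas, and
#' summarizes how absolute UniFrac co-varies with the other metrics as
#' Pearson correlations over the pair vectors.
#'
#' @param table a \code{\link{count_table}}; if not already absolute-mode,
#'   \code{loads} are required.
#' @param tree a \code{phylo} covering the table's taxa.
#' @param loads optional \code{\link{load_vector}}; for an absolute-mode
#'   table the row totals are the loads by construction.
#' @param alpha optional generalized-UniFrac alphas to append (absolute
#'   weighting), as columns \code{gu_a_<alpha>}.
#' @return list with \code{pairs} (a long data.frame, one row per unordered
#'   pair) and \code{correlations} (named vector: Pearson r of \code{u_a}
#'   against \code{bc_a}, \code{bc_r}, \code{u_r}; \code{NA} when a metric
#'   is constant across pairs).
#' @export
compare_metrics <- function(table, tree, loads = NULL, alpha = NULL) {
  stopifnot(inherits(table, "count_table"))
  if (nrow(table) < 2L) stop("need at least two samples", call. = FALSE)
  abs_tab <- if (abund_mode(table) == "absolute") table
             else as_absolute(table, loads)
  dms <- list(
    bc_r = pairwise_distances(abs_tab, spec = metric_spec("bray_curtis",
                                                          "relative")),
    bc_a = pairwise_distances(abs_tab, spec = metric_spec("bray_curtis",
                                                          "absolute")),
    u_r = pairwise_distances(abs_tab, tree,
                             metric_spec("unifrac_weighted", "relative")),
    u_a = pairwise_distances(abs_tab, tree,
                             metric_spec("unifrac_weighted", "absolute")))
  if (!is.null(alpha)) {
    gu <- pairwise_distances(abs_tab, tree,
                             metric_spec("unifrac_generalized", "absolute",
                                         alpha = alpha))
    if (!is.list(gu)) gu <- stats::setNames(list(gu),
                                            paste0("alpha_", alpha))
    names(gu) <- sub("^alpha_", "gu_a_", names(gu))
    dms <- c(dms, gu)
  }
  labs <- rownames(table)
  idx <- which(upper.tri(diag(length(labs))), arr.ind = TRUE)
  # upper.tri runs column-major: order by (i, j) for readability
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  pairs <- data.frame(sample_a = labs[idx[, 1]], sample_b = labs[idx[, 2]],
                      stringsAsFactors = FALSE)
  for (nm in names(dms)) pairs[[nm]] <- unclass(dms[[nm]])[idx]
  cors <- vapply(c("bc_a", "bc_r", "u_r"), function(other) {
    sd_a <- stats::sd(pairs$u_a)
    sd_o <- stats::sd(pairs[[other]])
    if (is.na(sd_a) || is.na(sd_o) || sd_a == 0 || sd_o == 0)
      return(NA_real_)
    stats::cor(pairs$u_a, pairs[[other]])
  }, numeric(1))
  list(pairs = pairs, correlations = cors)
}

#' Random tree / read-count table / load fixture
#'
#' A seed-deterministic generator of realistically shaped test data:
#' a random binary topology from sequential joins with exponential branch
#' lengths (mean 0.1 substitutions/site, typical of 16S ASV trees),
#' Dirichlet sample compositions, lognormal read depths and lognormal
#' microbial loads spanning a requested log10 range (the span observed
#' across published quantitative profiling datasets runs from roughly 4e5
#' cells/mL to 2e12 16S copies/g).
#'
#' @param n_taxa number of leaves/taxa (>= 2).
#' @param n_samples number of samples.
#' @param load_log10_range length-2 range of log10 microbial load (default
#'   \code{c(5.6, 12.3)}); loads are lognormal with ~95\% of mass inside
#'   the range.
#' @param seed integer seed; identical seeds give identical fixtures.
#' @param concentration Dirichlet concentration per taxon (default 0.5,
#'   giving the skewed compositions typical of amplicon data).
#' @param mean_reads median read depth (default 20000).
#' @return list with \code{tree} (a \code{phylo}), \code{table}
#'   (\code{raw_reads} \code{count_table}), \code{loads}
#'   (\code{\link{load_vector}}).
#' @export
random_fixture <- function(n_taxa, n_samples,
                           load_log10_range = c(5.6, 12.3),
                           seed = 1L, concentration = 0.5,
                           mean_reads = 20000) {
  if (n_taxa < 2) stop("`n_taxa` must be at least 2", call. = FALSE)
  if (n_samples < 1) stop("`n_samples` must be at least 1", call. = FALSE)
  if (length(load_log10_range) != 2 || diff(load_log10_range) < 0)
    stop("`load_log10_range` must be an increasing length-2 range",
         call. = FALSE)
  with_seed(seed, {
    tree <- ape::rtree(n_taxa, rooted = TRUE,
                       tip.label = paste0("ASV_", seq_len(n_taxa)),
                       br = function(n) stats::rexp(n, rate = 10))
    tree$root.edge <- 0
    comp <- matrix(stats::rgamma(n_samples * n_taxa, shape = concentration),
                   n_samples, n_taxa)
    comp <- comp / rowSums(comp)
    depths <- pmax(50L, round(stats::rlnorm(n_samples, log(mean_reads),
                                            0.35)))
    reads <- t(vapply(seq_len(n_samples), function(i)
      as.numeric(stats::rmultinom(1, depths[i], comp[i, ])),
      numeric(n_taxa)))
    dimnames(reads) <- list(sprintf("sample_%02d", seq_len(n_samples)),
                            tree$tip.label)
    mu <- mean(load_log10_range) * log(10)
    sdl <- diff(load_log10_range) / 4 * log(10)
    loads <- stats::setNames(stats::rlnorm(n_samples, mu, sdl),
                             rownames(reads))
    list(tree = validate_tree(tree),
         table = count_table(reads, mode = "raw_reads"),
         loads = load_vector(loads))
  })
}
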