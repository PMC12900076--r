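#' Construct a count table
#'
#' A count table is a numeric samples-by-taxa matrix with unique sample and
#' taxon identifiers and a mode tag recording what its entries mean:
#' \describe{
#'   \item{\code{"raw_reads"}}{sequencing read counts (integrality is only
#'     enforced when the table enters rarefaction);}
#'   \item{\code{"relative"}}{proportions, each sample row summing to 1;}
#'   \item{\code{"absolute"}}{load-scaled abundances (cells/mL, 16S copies/g
#'     or any absolute unit), possibly non-integer.}
#' }
#'
#' @param x numeric matrix (samples as rows) with complete dimnames, or an
#'   object coercible to one.
#' @param mode one of \code{"raw_reads"}, \code{"relative"},
#'   \code{"absolute"}.
#' @return a \code{count_table} object (a classed matrix).
#' @export
count_table <- function(x, mode = c("raw_reads", "relative", "absolute")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("count table must be numeric", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count table needs sample rownames and taxon colnames", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate taxon identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(x) || any(x < 0))
    stop("count table entries must be nonnegative and non-missing",
         call. = FALSE)
  if (mode == "relative") {
    rs <- rowSums(x)
    if (any(rs == 0))
      stop("relative-mode table has all-zero sample(s): ",
           paste(rownames(x)[rs == 0], collapse = ", "), call. = FALSE)
    if (any(abs(rs - 1) > 1e-9))
      stop("relative-mode rows must sum to 1 (tolerance 1e-9); offending: ",
           paste(rownames(x)[abs(rs - 1) > 1e-9], collapse = ", "),
           call. = FALSE)
  }
  structure(x, class = c("count_table", class(x)), abund_mode = mode)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa, mode = %s\n",
              nrow(x), ncol(x), abund_mode(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 8L)), drop = FALSE]))
  invisible(x)
}

#' Abundance mode of a count table
#' @param x a \code{count_table}.
#' @return \code{"raw_reads"}, \code{"relative"} or \code{"absolute"}.
#' @export
abund_mode <- function(x) attr(x, "abund_mode")

#' Convert a count table to relative abundance
#'
#' Divides each sample row by its total. All-zero samples are an error:
#' a sample with no observations has no defined composition.
#'
#' @param x a \code{count_table}.
#' @return a \code{count_table} in \code{"relative"} mode.
#' @export
as_relative <- function(x) {
  stopifnot(inherits(x, "count_table"))
  if (abund_mode(x) == "relative") return(x)
  rs <- rowSums(x)
  if (any(rs == 0))
    stop("cannot normalize all-zero sample(s): ",
         paste(rownames(x)[rs == 0], collapse = ", "), call. = FALSE)
  count_table(sweep(unclass(x), 1, rs, "/"), mode = "relative")
}

#' Rescale a count table to absolute abundance
#'
#' Each sample's relative abundances are multiplied by its total microbial
#' load \eqn{N_s} (total cell count or 16S copy number). Raw read counts are
#' first converted to proportions; no rounding is performed at any step, so
#' absolute tables are generally non-integer.
#'
#' @param x a \code{count_table} in \code{"raw_reads"} or \code{"relative"}
#'   mode (an \code{"absolute"} table is returned unchanged).
#' @param loads a \code{\link{load_vector}} covering every sample of \code{x}.
#' @return a \code{count_table} in \code{"absolute"} mode.
#' @export
as_absolute <- function(x, loads) {
  stopifnot(inherits(x, "count_table"))
  if (abund_mode(x) == "absolute") return(x)
  loads <- load_vector(loads)
  missing <- setdiff(rownames(x), names(loads))
  if (length(missing))
    stop("no load for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rel <- as_relative(x)
  count_table(sweep(unclass(rel), 1, loads[rownames(x)], "*"),
              mode = "absolute")
}

#' Construct a per-sample microbial load vector
#'
#' @param x named numeric vector of strictly positive total abundances
#'   (cells/mL, 16S copies/g, ...), one per sample.
#' @return a validated named numeric vector of class \code{load_vector}.
#' @export
load_vector <- function(x) {
  if (inherits(x, "load_vector")) return(x)
  x <- unlist(x)
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop("loads must be a named numeric vector", call. = FALSE)
  if (anyDuplicated(names(x)))
    stop("duplicate sample identifiers in loads", call. = FALSE)
  bad <- !is.finite(x) | x <= 0
  if (any(bad))
    stop("non-positive or non-finite load for sample(s): ",
         paste(names(x)[bad], collapse = ", "), call. = FALSE)
  structure(x, class = "load_vector")
}

#' Construct a labeled distance matrix
#'
#' Validates symmetry, a zero diagonal and nonnegativity. Bounds (e.g. the
#' [0, 1] range of UniFrac and Bray-Curtis) are asserted by the metric
#' builders, not here, so that unbounded matrices such as pairwise
#' load differences share the same container.
#'
#' @param m square numeric matrix with matching row/column labels.
#' @param tol symmetry tolerance.
#' @return a \code{distance_matrix} (classed matrix).
#' @export
distance_matrix <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(m)) && is.null(colnames(m)))
    stop("distance matrix needs sample labels", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels disagree", call. = FALSE)
  if (any(abs(m - t(m)) > tol))
    stop("matrix is asymmetric beyond tolerance ", tol, call. = FALSE)
  m <- (m + t(m)) / 2
  if (any(abs(diag(m)) > tol)) stop("diagonal must be zero", call. = FALSE)
  diag(m) <- 0
  if (anyNA(m) || any(m < -tol))
    stop("distances must be nonnegative and non-missing", call. = FALSE)
  m[m < 0] <- 0
  structure(m, class = c("distance_matrix", class(m)))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d samples\n", nrow(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE]))
  invisible(x)
}

#' Describe a metric and its weighting
#'
#' @param family one of \code{"unifrac_weighted"}, \code{"unifrac_generalized"},
#'   \code{"unifrac_unweighted"}, \code{"bray_curtis"}.
#' @param weighting \code{"relative"} or \code{"absolute"}; ignored by the
#'   unweighted family, which only sees incidence.
#' @param alpha numeric vector of generalized-UniFrac exponents in [0, 1];
#'   required iff \code{family = "unifrac_generalized"}. All alphas share one
#'   branch-profile computation.
#' @return a \code{metric_spec} list.
#' @export
metric_spec <- function(family = c("unifrac_weighted", "unifrac_generalized",
                                   "unifrac_unweighted", "bray_curtis"),
                        weighting = c("relative", "absolute"),
                        alpha = NULL) {
  family <- match.arg(family)
  weighting <- match.arg(weighting)
  if (family == "unifrac_generalized") {
    if (is.null(alpha)) stop("generalized UniFrac requires `alpha`",
                             call. = FALSE)
    if (!is.numeric(alpha) || any(!is.finite(alpha)) ||
        any(alpha < 0 | alpha > 1))
      stop("`alpha` values must lie in [0, 1]", call. = FALSE)
  } else if (!is.null(alpha)) {
    stop("`alpha` only applies to family = \"unifrac_generalized\"",
         call. = FALSE)
  }
  structure(list(family = family, weighting = weighting, alpha = alpha),
            class = "metric_spec")
}

# ---- file I/O -------------------------------------------------------------

read_numeric_tsv <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  num <- suppressWarnings(array(as.numeric(m), dim(m), dimnames(m)))
  bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                 m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
                 colnames(m)[bad[1, 2]], path), call. = FALSE)
  num
}

#' Read a count table from a dense TSV
#'
#' The file holds one header row of identifiers, one leading identifier
#' column, and a numeric body. Orientation is normalized so the returned
#' table is always samples x taxa.
#'
#' @param path TSV file path.
#' @param orientation whether the file stores samples as rows (default) or
#'   taxa as rows.
#' @param mode mode tag to stamp on the result; defaults to
#'   \code{"raw_reads"}.
#' @return a \code{\link{count_table}}.
#' @export
read_count_table <- function(path,
                             orientation = c("samples_as_rows",
                                             "taxa_as_rows"),
                             mode = "raw_reads") {
  orientation <- match.arg(orientation)
  m <- read_numeric_tsv(path)
  if (orientation == "taxa_as_rows") m <- t(m)
  count_table(m, mode = mode)
}

#' Write a count table to TSV
#'
#' Full double precision, samples as rows; \code{read_count_table()} on the
#' result reproduces the table exactly.
#'
#' @param x a \code{count_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  write_labeled_tsv(unclass(x), path, corner = "sample_id")
  invisible(path)
}

write_labeled_tsv <- function(m, path, corner = "id") {
  body <- apply(m, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(m),
                                         dimnames = dimnames(m))
  out <- cbind(rownames(m), body)
  colnames(out) <- c(corner, colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read a rooted phylogenetic tree from Newick
#'
#' Branch lengths are required. A tree whose basal node is a multifurcation
#' (the usual export form of an unrooted tree) is adopted as rooted at that
#' node with a zero-length root edge; this choice is recorded in the
#' \code{"rooting_note"} attribute because a zero-length root edge
#' contributes nothing to any branch-length sum.
#'
#' @param path Newick file path (or a length-1 string containing Newick when
#'   \code{text = TRUE}).
#' @param text interpret \code{path} as Newick text instead of a file path.
#' @return an \code{ape} \code{phylo} object with a defined \code{root.edge}.
#' @export
read_newick <- function(path, text = FALSE) {
  tree <- if (text) ape::read.tree(text = path) else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  if (inherits(tree, "multiPhylo"))
    stop("expected a single tree, found several", call. = FALSE)
  validate_tree(tree)
}

#' @rdname read_newick
#' @param tree a \code{phylo} object to validate in place.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; lengths are required", call. = FALSE)
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be nonnegative and non-missing", call. = FALSE)
  if (!ape::is.rooted(tree))
    attr(tree, "rooting_note") <-
      "basal multifurcation adopted as root with a zero-length root edge"
  if (is.null(tree$root.edge)) tree$root.edge <- 0
  tree
}

#' Read per-sample microbial loads from a metadata TSV
#'
#' @param path metadata TSV with a header row.
#' @param column name of the numeric load column.
#' @param id_column name of the sample-identifier column; defaults to the
#'   first column.
#' @return a \code{\link{load_vector}}; samples whose load is missing
#'   (\code{NA}) are dropped, while zero or negative loads are an error.
#' @export
read_loads <- function(path, column, id_column = NULL) {
  md <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (is.null(id_column)) id_column <- colnames(md)[1]
  for (col in c(id_column, column))
    if (!col %in% colnames(md))
      stop(sprintf("column '%s' not found; available: %s", col,
                   paste(colnames(md), collapse = ", ")), call. = FALSE)
  ids <- as.character(md[[id_column]])
  vals <- suppressWarnings(as.numeric(md[[column]]))
  keep <- !is.na(vals)
  bad <- keep & vals <= 0
  if (any(bad))
    stop("non-positive load for sample(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  load_vector(stats::setNames(vals[keep], ids[keep]))
}

#' Write / read a square labeled distance matrix as TSV
#'
#' The full square matrix is written at double precision so that
#' \code{read_distance_matrix(write_distance_matrix(d))} reproduces \code{d}
#' to 1e-12, labels and order included.
#'
#' @param dm a \code{\link{distance_matrix}}.
#' @param path file path.
#' @return \code{path} (write) or a \code{distance_matrix} (read).
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "distance_matrix"))
  write_labeled_tsv(unclass(dm), path, corner = "sample_id")
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  m <- read_numeric_tsv(path)
  if (nrow(m) != ncol(m))
    stop("distance matrix file is not square: ", nrow(m), " x ", ncol(m),
         call. = FALSE)
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels disagree in ", path, call. = FALSE)
  distance_matrix(m)
}
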