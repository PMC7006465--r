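#' Read phylogenies from Newick text or file
#'
#' Reads one or more rooted phylogenies and validates them for comparative
#' analysis. In strict mode (the default) every tree must be fully resolved:
#' polytomies are rejected with an error naming the offending node, matching
#' the usual requirement of PGLS and independent-contrast methods. Trees must
#' carry branch lengths on every edge and have unique tip labels.
#'
#' @param x a Newick string, or the path to a file containing one or more
#'   Newick trees (one per line).
#' @param strict logical; reject polytomies (default `TRUE`).
#' @param underscores how to treat underscores in tip labels: `"keep"`
#'   (default) or `"to_space"` to replace them with spaces so labels match a
#'   trait table that uses spaced binomials.
#' @return a list of `phylo` objects (always a list, even for one tree).
#' @examples
#' read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(x, strict = TRUE, underscores = c("keep", "to_space")) {
  underscores <- match.arg(underscores)
  stopifnot(is.character(x), length(x) == 1L)
  if (file.exists(x)) {
    trees <- ape::read.tree(file = x, keep.multi = TRUE)
  } else {
    trees <- ape::read.tree(text = x, keep.multi = TRUE)
  }
  if (is.null(trees)) stop("could not parse any Newick tree from input")
  trees <- unclass(trees) # multiPhylo -> plain list of phylo
  attr(trees, "TipLabel") <- NULL
  trees <- lapply(trees, function(tr) {
    if (underscores == "to_space") {
      tr$tip.label <- gsub("_", " ", tr$tip.label, fixed = TRUE)
    }
    validate_phylo(tr, strict = strict)
    tr
  })
  trees
}

#' Write phylogenies to a Newick file
#'
#' @param trees a `phylo` object or list of them.
#' @param file output path; if `NULL` the Newick strings are returned.
#' @return invisibly, the Newick strings.
#' @export
write_newick <- function(trees, file = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  txt <- vapply(trees, function(tr) ape::write.tree(tr), character(1))
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

validate_phylo <- function(tr, strict = TRUE) {
  if (!inherits(tr, "phylo")) stop("not a 'phylo' object")
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    stop("tree has missing branch lengths")
  }
  if (any(tr$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (strict) {
    nchild <- tabulate(tr$edge[, 1], nbins = ape::Ntip(tr) + tr$Nnode)
    poly <- which(nchild > 2L)
    if (length(poly)) {
      stop("tree is not fully resolved: polytomy at node ",
           paste(poly, collapse = ", "))
    }
  }
  invisible(tr)
}

#' Phylogenetic (Brownian) covariance matrix of a tree
#'
#' Returns the matrix `V` whose entry (i, j) is the shared path length from
#' the root to the most recent common ancestor of tips i and j; the diagonal
#' holds each tip's root-to-tip depth. This is the trait covariance implied
#' by Brownian motion along the tree and the error covariance used by PGLS.
#'
#' Path lengths are measured from the node the Newick string is anchored
#' at; a basal multichotomy (e.g. a star phylogeny) is a valid root for
#' this purpose, so covariance matrices of star trees are well defined.
#'
#' @param tree a `phylo` with branch lengths.
#' @return a symmetric numeric matrix with tip labels as dimnames.
#' @export
vcv_matrix <- function(tree) {
  validate_phylo(tree, strict = FALSE)
  ape::vcv(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal elements of `V` by `lambda`, leaving the
#' diagonal untouched. `lambda = 1` returns the Brownian covariance
#' unchanged; `lambda = 0` removes all phylogenetic covariance (star
#' phylogeny). The domain is restricted to \[0, 1\], the statistically
#' interpretable range searched by the maximum-likelihood estimator.
#'
#' @param V symmetric covariance matrix (e.g. from [vcv_matrix()]).
#' @param lambda real in \[0, 1\].
#' @return the transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  stopifnot(is.matrix(V), nrow(V) == ncol(V))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]")
  }
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

#' Test ultrametricity within a relative tolerance
#'
#' @param tree a `phylo` object with branch lengths.
#' @param tol maximum allowed relative spread of root-to-tip depths.
#' @return logical.
#' @export
is_ultrametric_tol <- function(tree, tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(d)
  if (h == 0) return(TRUE)
  (h - min(d)) / h <= tol
}

#' Rescale an ultrametric tree by Pagel's lambda to a unit tree
#'
#' Applies the branch-length version of the lambda transform: internal
#' branches are multiplied by `lambda` and each terminal branch is extended
#' so that every tip keeps its original depth. The covariance matrix of the
#' transformed tree equals `lambda_transform(vcv_matrix(tree), lambda)`.
#' The tree is then (optionally) scaled so that the root-to-tip height is 1
#' — the "unit tree" used for variable-specific contrast transforms.
#'
#' With `lambda = 0` all internal branches collapse to length zero, leaving
#' an effective star phylogeny (the bifurcating topology is retained with
#' zero-length internal edges).
#'
#' @param tree ultrametric rooted `phylo`.
#' @param lambda real in \[0, 1\].
#' @param unit_height scale to height 1 after the transform (default `TRUE`).
#' @param tol ultrametricity tolerance passed to [is_ultrametric_tol()].
#' @return a `phylo` object.
#' @export
lambda_rescale_tree <- function(tree, lambda, unit_height = TRUE, tol = 1e-6) {
  validate_phylo(tree, strict = FALSE)
  if (!is_ultrametric_tol(tree, tol)) {
    stop("tree is not ultrametric within tolerance ", tol)
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]")
  }
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_len(n)])
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  el <- tree$edge.length
  tip_edge <- child <= n
  el[!tip_edge] <- el[!tip_edge] * lambda
  el[tip_edge] <- el[tip_edge] + (1 - lambda) * depth[parent[tip_edge]]
  if (unit_height && h > 0) el <- el / h
  tree$edge.length <- el
  tree
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's standardized contrasts: at each internal node the difference
#' between the two daughter values divided by the square root of the summed
#' (corrected) branch lengths, with ancestral values and branch-length
#' corrections propagated toward the root. A resolved tree with n tips gives
#' exactly n - 1 contrasts.
#'
#' @param tree fully resolved rooted `phylo` with branch lengths.
#' @param x numeric vector of trait values named by tip label (a value for
#'   every tip is required; filter missing species first).
#' @return named numeric vector of contrasts, names = internal node numbers.
#' @export
pic_contrasts <- function(tree, x) {
  validate_phylo(tree, strict = TRUE)
  if (is.null(names(x))) stop("trait vector must be named by tip label")
  missing <- setdiff(tree$tip.label, names(x))
  if (length(missing)) {
    stop("missing trait values for tips: ", paste(missing, collapse = ", "))
  }
  x <- x[tree$tip.label]
  if (anyNA(x)) stop("trait vector contains NA; drop incomplete species first")
  ape::pic(x, tree)
}

#' Match a trait table to a tree, pruning both to shared species
#'
#' Species labels are the join key between the table's `species` column and
#' the tree's tip labels; matching is exact string comparison after optional
#' underscore normalization. Unmatched rows/tips are dropped with a message
#' reporting the counts.
#'
#' @param table data frame with a `species` column.
#' @param tree a `phylo` object.
#' @param underscores `"keep"` or `"to_space"` applied to tip labels.
#' @return list with elements `table` (rows ordered as the pruned tree's
#'   tips) and `tree`.
#' @export
match_tree_table <- function(table, tree, underscores = c("keep", "to_space")) {
  underscores <- match.arg(underscores)
  stopifnot(is.data.frame(table), "species" %in% names(table))
  if (underscores == "to_space") {
    tree$tip.label <- gsub("_", " ", tree$tip.label, fixed = TRUE)
  }
  shared <- intersect(tree$tip.label, table$species)
  if (!length(shared)) stop("no species shared between table and tree")
  n_drop_rows <- nrow(table) - length(shared)
  n_drop_tips <- ape::Ntip(tree) - length(shared)
  if (n_drop_rows || n_drop_tips) {
    message("match_tree_table: dropped ", n_drop_rows, " table rows and ",
            n_drop_tips, " tree tips without a counterpart")
  }
  tree <- ape::keep.tip(tree, shared)
  table <- table[match(tree$tip.label, table$species), , drop = FALSE]
  rownames(table) <- NULL
  list(table = table, tree = tree)
}
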