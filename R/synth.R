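#' Simulate a pure-birth (Yule) phylogeny of unit height
#'
#' Generates a fully resolved, ultrametric pure-birth tree and rescales it
#' to root-to-tip height 1, giving a neutral scaffold with the covariance
#' structure the comparative analyses assume. Deterministic for a given
#' seed. Tips are labelled `sp001`, `sp002`, ...
#'
#' @param n_species number of tips (>= 2).
#' @param seed optional integer seed.
#' @return a `phylo` object.
#' @export
simulate_yule_tree <- function(n_species, seed = NULL) {
  if (n_species < 2) stop("need at least 2 species")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  h <- max(ape::node.depth.edgelength(tree)[seq_len(n_species)])
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Simulate a trait under lambda-structured Brownian motion
#'
#' Draws one realization from a zero-mean multivariate Gaussian with
#' covariance `sigma2 * lambda_transform(vcv_matrix(tree), lambda)` — the
#' generative counterpart of the Pagel's-lambda error model assumed by
#' PGLS. `lambda = 1` is plain Brownian motion; `lambda = 0` is independent
#' noise with Brownian tip variances.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param sigma2 rate (variance per unit branch length), >= 0.
#' @param lambda phylogenetic signal of the error, in \[0, 1\].
#' @param seed optional integer seed.
#' @return named numeric vector (names = tip labels).
#' @export
simulate_lambda_bm <- function(tree, sigma2 = 1, lambda = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(sigma2 >= 0)
  n <- ape::Ntip(tree)
  if (sigma2 == 0) {
    return(stats::setNames(numeric(n), tree$tip.label))
  }
  V <- sigma2 * lambda_transform(vcv_matrix(tree), lambda)
  R <- chol(V)
  x <- drop(crossprod(R, stats::rnorm(n)))
  stats::setNames(x, tree$tip.label)
}

#' Simulation configuration for a causal trait study
#'
#' Bundles everything needed to generate a synthetic comparative study:
#' the species count, the generative DAG, one linear coefficient per edge,
#' and a per-vertex lambda and sigma for the error process. Defaults
#' emulate the empirical study conditions: 201 species, the ASR-driven
#' causal structure (`model2`), error signal lambda 0.9, unit error
#' variance, sign pattern ASR -> SSD and ASR -> polygamy negative, SSD and
#' polygamy -> maturation positive with magnitude 0.5 (standardized
#' units), and the adult sex ratio missing for 10% of species.
#'
#' @param n_species number of species.
#' @param dag generative `dag_model`.
#' @param edge_coefs named numeric vector, names `"from->to"`, one per
#'   edge; `NULL` uses the default sign pattern at magnitude 0.5.
#' @param error_lambdas per-vertex lambda, single value recycled.
#' @param error_sigmas per-vertex error SD, single value recycled.
#' @param missing_asr_fraction fraction of species with the ASR masked.
#' @param include_confounds also simulate `mortality_bias`, `log_mass`,
#'   and `dev_mode` (independent of the DAG) so the full regression
#'   protocol can run.
#' @param seed integer seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_species = 201, dag = builtin_models()$model2,
                       edge_coefs = NULL, error_lambdas = 0.9,
                       error_sigmas = 1, missing_asr_fraction = 0.1,
                       include_confounds = TRUE, seed = 1) {
  stopifnot(inherits(dag, "dag_model"))
  edge_ids <- paste0(dag$edges[, 1], "->", dag$edges[, 2])
  if (is.null(edge_coefs)) {
    edge_coefs <- stats::setNames(
      ifelse(dag$edges[, 1] == "asr_t", -0.5, 0.5), edge_ids
    )
  }
  if (!setequal(names(edge_coefs), edge_ids)) {
    stop("edge_coefs must name every edge exactly once ('from->to')")
  }
  v <- dag$vertices
  recycle <- function(x, what, lo, hi) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, length(v)), v)
    if (!setequal(names(x), v)) stop(what, " must cover every vertex")
    if (any(x < lo | x > hi)) stop(what, " out of range")
    x[v]
  }
  structure(list(
    n_species = n_species, dag = dag,
    edge_coefs = edge_coefs[edge_ids],
    error_lambdas = recycle(error_lambdas, "error_lambdas", 0, 1),
    error_sigmas = recycle(error_sigmas, "error_sigmas", 1e-12, Inf),
    missing_asr_fraction = missing_asr_fraction,
    include_confounds = include_confounds,
    seed = seed
  ), class = "sim_config")
}

#' Simulate a comparative study under a causal path model
#'
#' Generates a unit-height Yule tree and trait values vertex-by-vertex in
#' topological order of the configured DAG:
#' `value(v) = sum over parents of coef * value(parent) + error(v)`, where
#' `error(v)` is a lambda-structured Brownian draw with the vertex's lambda
#' and sigma. The ASR column is then masked at the configured missingness
#' rate (mirroring the sparser availability of sex-ratio estimates), so a
#' 201-species table with 10% missing ASR yields roughly 181 complete cases
#' for four-variable models. Optionally adds confound columns
#' (`mortality_bias`, `log_mass` as independent lambda-BM traits;
#' `dev_mode` sampled independently of the phylogeny).
#'
#' @param config a `sim_config`.
#' @return list of class `"simulated_study"`: `tree`, `table` (trait table
#'   with `species` column), `truth` (the config).
#' @export
simulate_path_model <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- simulate_yule_tree(config$n_species)
  V1 <- vcv_matrix(tree)
  dag <- config$dag
  tab <- data.frame(species = tree$tip.label, stringsAsFactors = FALSE)
  draw <- function(lambda, sigma) {
    R <- chol(sigma^2 * lambda_transform(V1, lambda))
    drop(crossprod(R, stats::rnorm(config$n_species)))
  }
  for (v in topological_order(dag)) {
    x <- draw(config$error_lambdas[v], config$error_sigmas[v])
    pa <- dag_parents(dag, v)
    for (p in pa) {
      x <- x + config$edge_coefs[paste0(p, "->", v)] * tab[[p]]
    }
    tab[[v]] <- x
  }
  if (config$missing_asr_fraction > 0 && "asr_t" %in% names(tab)) {
    mask <- stats::runif(config$n_species) < config$missing_asr_fraction
    tab$asr_t[mask] <- NA_real_
  }
  if (config$include_confounds) {
    tab$mortality_bias <- draw(0.9, 0.15)
    tab$log_mass <- 2 + draw(0.9, 0.5)
    tab$dev_mode <- factor(
      sample(dev_mode_levels, config$n_species, replace = TRUE,
             prob = c(0.5, 0.2, 0.3)),
      levels = dev_mode_levels
    )
  }
  structure(list(tree = tree, table = tab, truth = config),
            class = "simulated_study")
}

#' Simulate a set of perturbed phylogenies sharing one tip set
#'
#' Stands in for a posterior sample of candidate trees: each tree is the
#' base topology perturbed by a random number of nearest-neighbour
#' interchange (NNI) moves, with ultrametric branch lengths reassigned and
#' internal node ages jittered on the logit scale, then normalized to unit
#' height. `jitter = 0` returns identical copies of the base tree. The
#' expected number of NNI moves per tree is `jitter * n_tips`.
#'
#' @param tree base ultrametric `phylo` (e.g. from [simulate_yule_tree()]).
#' @param n_trees number of trees to generate.
#' @param jitter nonnegative perturbation intensity.
#' @param seed optional integer seed.
#' @return list of `phylo` objects with identical tip sets.
#' @export
simulate_tree_set <- function(tree, n_trees, jitter = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_trees >= 1, jitter >= 0)
  if (jitter == 0) return(replicate(n_trees, tree, simplify = FALSE))
  lapply(seq_len(n_trees), function(i) {
    moves <- stats::rpois(1, jitter * ape::Ntip(tree))
    t2 <- if (moves > 0) phangorn::rNNI(tree, moves = moves) else tree
    if (!ape::is.rooted(t2)) t2 <- phangorn::midpoint(t2)
    if (!ape::is.binary(t2)) t2 <- ape::multi2di(t2)
    jitter_ultrametric(t2, jitter)
  })
}

# Reassign ultrametric branch lengths to a (possibly NNI-perturbed) binary
# topology: Grafen node ages, each child/parent age ratio jittered on the
# logit scale, height normalized to 1.
jitter_ultrametric <- function(tree, jitter) {
  tree <- ape::compute.brlen(tree, method = "Grafen")
  n <- ape::Ntip(tree)
  nnode <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_len(n)])
  age <- (h - depth) / h
  root <- n + 1L
  new_age <- numeric(n + nnode)
  new_age[root] <- 1
  internal <- setdiff(order(age, decreasing = TRUE), seq_len(n))
  for (node in internal) {
    if (node == root) next
    parent <- tree$edge[tree$edge[, 2] == node, 1]
    ratio <- age[node] / age[parent]
    ratio <- stats::plogis(stats::qlogis(ratio) + stats::rnorm(1, 0, jitter))
    new_age[node] <- ratio * new_age[parent]
  }
  tree$edge.length <- new_age[tree$edge[, 1]] - new_age[tree$edge[, 2]]
  tree
}
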