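#' Define a causal path model (DAG)
#'
#' A path model is a directed acyclic graph over named trait variables.
#' Edges are cause -> effect pairs; acyclicity is validated at construction.
#' The declared vertex order is retained and used as the tie-break when a
#' d-separation claim involves two vertices at equal topological depth.
#'
#' @param name label for the model (e.g. `"model2"`).
#' @param edges two-column character matrix, or list of length-2 character
#'   vectors, `c(from, to)`.
#' @param vertices optional character vector fixing the vertex order;
#'   defaults to order of first appearance in `edges`.
#' @return object of class `"dag_model"`.
#' @export
path_model <- function(name, edges, vertices = NULL) {
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- matrix(as.character(edges), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  seen <- unique(as.vector(t(edges)))
  if (is.null(vertices)) vertices <- seen
  if (!all(seen %in% vertices)) {
    stop("edges reference unknown vertices: ",
         paste(setdiff(seen, vertices), collapse = ", "))
  }
  if (anyDuplicated(vertices)) stop("duplicate vertices")
  if (any(edges[, 1] == edges[, 2])) stop("self-loop edge")
  model <- structure(
    list(name = name, vertices = vertices, edges = edges),
    class = "dag_model"
  )
  if (is.null(topological_order(model))) {
    stop("graph has a cycle; path models must be acyclic")
  }
  model
}

# Kahn topological sort; NULL if cyclic.
topological_order <- function(model) {
  v <- model$vertices
  indeg <- stats::setNames(integer(length(v)), v)
  for (i in seq_len(nrow(model$edges))) {
    indeg[model$edges[i, 2]] <- indeg[model$edges[i, 2]] + 1L
  }
  order <- character(0)
  queue <- v[indeg == 0L]
  while (length(queue)) {
    x <- queue[1]
    queue <- queue[-1]
    order <- c(order, x)
    kids <- model$edges[model$edges[, 1] == x, 2]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, v[v == k])
    }
  }
  if (length(order) == length(v)) order else NULL
}

dag_parents <- function(model, v) model$edges[model$edges[, 2] == v, 1]

# Longest directed path from any root; used to pick the claim response.
dag_depth <- function(model) {
  depth <- stats::setNames(integer(length(model$vertices)), model$vertices)
  for (v in topological_order(model)) {
    pa <- dag_parents(model, v)
    if (length(pa)) depth[v] <- max(depth[pa]) + 1L
  }
  depth
}

#' Number of parameters of a path model
#'
#' Counted as number of edges plus number of vertices (each edge
#' coefficient plus one free variance per variable). Other conventions
#' exist; this one matches standard CICc-based phylogenetic path analysis.
#'
#' @param model a `dag_model`.
#' @return integer.
#' @export
q_params <- function(model) nrow(model$edges) + length(model$vertices)

#' @export
print.dag_model <- function(x, ...) {
  cat("Path model", x$name, "-", length(x$vertices), "vertices,",
      nrow(x$edges), "edges\n")
  cat(paste(x$edges[, 1], "->", x$edges[, 2]), sep = "\n")
  invisible(x)
}

#' The five built-in causal models for maturation bias
#'
#' Competing hypotheses for the causal structure linking the adult sex
#' ratio (`asr_t`), sexual size dimorphism (`ssd`), polygamy bias
#' (`polygamy_bias`), and maturation bias (`maturation_bias`):
#' \describe{
#'   \item{model1}{multiple regression — ASR, SSD, and polygamy bias each
#'     point directly at maturation bias.}
#'   \item{model2}{ASR drives SSD and polygamy bias, which in turn drive
#'     maturation bias (no direct ASR effect).}
#'   \item{model3}{maturation bias drives ASR, which drives SSD and
#'     polygamy bias.}
#'   \item{model4}{ASR and polygamy bias drive SSD, which drives maturation
#'     bias.}
#'   \item{model5}{ASR drives polygamy bias, polygamy bias drives
#'     maturation bias, and maturation bias drives SSD.}
#' }
#'
#' @return named list of five `dag_model` objects.
#' @export
builtin_models <- function() {
  v <- c("asr_t", "ssd", "polygamy_bias", "maturation_bias")
  mk <- function(name, ...) path_model(name, list(...), vertices = v)
  list(
    model1 = mk("model1",
                c("asr_t", "maturation_bias"),
                c("ssd", "maturation_bias"),
                c("polygamy_bias", "maturation_bias")),
    model2 = mk("model2",
                c("asr_t", "ssd"),
                c("asr_t", "polygamy_bias"),
                c("ssd", "maturation_bias"),
                c("polygamy_bias", "maturation_bias")),
    model3 = mk("model3",
                c("maturation_bias", "asr_t"),
                c("asr_t", "ssd"),
                c("asr_t", "polygamy_bias")),
    model4 = mk("model4",
                c("asr_t", "ssd"),
                c("polygamy_bias", "ssd"),
                c("ssd", "maturation_bias")),
    model5 = mk("model5",
                c("asr_t", "polygamy_bias"),
                c("polygamy_bias", "maturation_bias"),
                c("maturation_bias", "ssd"))
  )
}

#' d-separation basis set of a DAG
#'
#' One conditional-independence claim per non-adjacent vertex pair,
#' conditioned on the union of both vertices' parents. The claim's response
#' (the variable regressed on the other pair member plus the conditioning
#' set) is the topologically deeper pair member; for pairs at equal depth
#' the earlier vertex in the model's declared order is the response. The
#' basis-set size is `choose(|V|, 2) - |E|`.
#'
#' @param model a `dag_model`.
#' @return list of claims, each a list with `response`, `other`,
#'   `conditioning`.
#' @export
basis_set <- function(model) {
  stopifnot(inherits(model, "dag_model"))
  v <- model$vertices
  depth <- dag_depth(model)
  adjacent <- function(a, b) {
    any(model$edges[, 1] == a & model$edges[, 2] == b) ||
      any(model$edges[, 1] == b & model$edges[, 2] == a)
  }
  claims <- list()
  if (length(v) >= 2) {
    pairs <- utils::combn(v, 2)
    for (i in seq_len(ncol(pairs))) {
      a <- pairs[1, i]
      b <- pairs[2, i]
      if (adjacent(a, b)) next
      if (depth[a] > depth[b]) {
        resp <- a; other <- b
      } else if (depth[b] > depth[a]) {
        resp <- b; other <- a
      } else {
        resp <- a; other <- b # equal depth: first in declared order
      }
      cond <- setdiff(union(dag_parents(model, a), dag_parents(model, b)),
                      c(a, b))
      claims[[length(claims) + 1L]] <-
        list(response = resp, other = other, conditioning = cond)
    }
  }
  claims
}

#' Test the independence claims of a basis set with PGLS
#'
#' Each claim (X independent of Y given Z) is tested by a PGLS of the
#' response on the other pair member plus the conditioning set, with Pagel's
#' lambda re-estimated by maximum likelihood inside every regression; the
#' claim's p-value is the two-tailed p of the other pair member's
#' coefficient. P-values are floored at 1e-300 so Fisher's C stays finite.
#'
#' @param claims list from [basis_set()].
#' @param table trait table (complete cases are taken per the full variable
#'   set by the caller; rows with missing values in a claim's variables are
#'   dropped here as well).
#' @param tree rooted `phylo`.
#' @param se_denominator passed to [pgls()].
#' @return numeric vector of claim p-values.
#' @export
test_claims <- function(claims, table, tree, se_denominator = "ml") {
  vapply(claims, function(cl) {
    fml <- stats::reformulate(c(cl$other, cl$conditioning),
                              response = cl$response)
    fit <- pgls(fml, table, tree, se_denominator = se_denominator)
    p <- fit$coefficients$p[fit$coefficients$term == cl$other]
    max(p, 1e-300)
  }, numeric(1))
}

#' Fisher's C statistic for a set of independence-claim p-values
#'
#' `C = -2 * sum(log p_i)`, chi-squared distributed with `2k` degrees of
#' freedom when all k claims hold; the model has acceptable fit when the
#' upper-tail p-value exceeds the chosen alpha.
#'
#' @param pvals claim p-values in (0, 1].
#' @return list with `C`, `df`, `p`.
#' @export
fishers_c <- function(pvals) {
  if (!length(pvals)) return(list(C = 0, df = 0L, p = 1))
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("claim p-values must lie in (0, 1]")
  }
  C <- -2 * sum(log(pvals))
  df <- 2L * length(pvals)
  list(C = C, df = df, p = stats::pchisq(C, df, lower.tail = FALSE))
}

#' C-statistic information criterion with small-sample correction
#'
#' `CICc = C + 2 q n / (n - 1 - q)`, where `q` is the number of model
#' parameters (edges + vertices) and `n` the number of species. As
#' `n -> Inf` this tends to `C + 2q`.
#'
#' @param C Fisher's C statistic.
#' @param q number of parameters.
#' @param n sample size; must exceed `q + 1`.
#' @return numeric.
#' @export
cicc <- function(C, q, n) {
  stopifnot(is.numeric(C), is.numeric(q), is.numeric(n))
  if (any(n <= q + 1)) stop("CICc requires n > q + 1")
  C + 2 * q * n / (n - 1 - q)
}

#' Rank path models by CICc
#'
#' Adds `delta_cicc` (difference from the lowest CICc) and Akaike-style
#' weights `w_i = exp(-delta_i / 2) / sum(exp(-delta_j / 2))`, and sorts
#' ascending by CICc. Differences larger than 2 (and 10) units are
#' conventionally read as acceptable (and very strong) support for the
#' best model.
#'
#' @param results data frame with at least `model` and `cicc` columns.
#' @return the data frame sorted by CICc with `delta_cicc` and `weight`.
#' @export
rank_models <- function(results) {
  stopifnot(is.data.frame(results), "cicc" %in% names(results))
  results$delta_cicc <- results$cicc - min(results$cicc)
  rel <- exp(-results$delta_cicc / 2)
  results$weight <- rel / sum(rel)
  results <- results[order(results$cicc), , drop = FALSE]
  rownames(results) <- NULL
  results
}

#' Standardized path coefficients of a DAG
#'
#' For every vertex with parents, fits a PGLS of that vertex on all its
#' parents with every variable centered and scaled to unit variance on the
#' complete-case subset, yielding standardized regression coefficients.
#' 95% confidence intervals use the normal multiplier 1.96.
#'
#' @param model a `dag_model`.
#' @param table trait table.
#' @param tree rooted `phylo`.
#' @param se_denominator passed to [pgls()].
#' @return data frame: `from`, `to`, `coef`, `se`, `lower`, `upper`,
#'   `lambda`, `n`.
#' @export
fit_path_coefficients <- function(model, table, tree, se_denominator = "ml") {
  vars <- model$vertices
  ad <- align_data_tree(table, tree, vars)
  std <- ad$data
  for (v in vars) std[[v]] <- as.numeric(scale(std[[v]]))
  rows <- list()
  for (v in topological_order(model)) {
    pa <- dag_parents(model, v)
    if (!length(pa)) next
    fit <- pgls(stats::reformulate(pa, response = v), std, ad$tree,
                se_denominator = se_denominator)
    cf <- fit$coefficients
    for (p in pa) {
      i <- which(cf$term == p)
      rows[[length(rows) + 1L]] <- data.frame(
        from = p, to = v, coef = cf$estimate[i], se = cf$se[i],
        lower = cf$estimate[i] - 1.96 * cf$se[i],
        upper = cf$estimate[i] + 1.96 * cf$se[i],
        lambda = fit$lambda, n = fit$n, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Confirmatory phylogenetic path analysis over a model set
#'
#' Runs the full d-separation analysis: for each candidate DAG, derives the
#' basis set, tests every claim with PGLS (ML lambda per regression),
#' computes Fisher's C and its chi-squared p-value, applies the CICc
#' small-sample criterion with n = number of complete-case species, and
#' ranks the models by CICc with delta values and weights. Standardized
#' path coefficients are fitted for the best-ranked model.
#'
#' @param table trait table containing all model vertices.
#' @param tree rooted `phylo`.
#' @param models list of `dag_model` objects (default [builtin_models()]).
#' @param fit_best fit path coefficients of the best model (default `TRUE`).
#' @param se_denominator passed to [pgls()].
#' @return object of class `"phylo_path"`: `summary` (one row per model:
#'   model, C, k, q, p, cicc, delta_cicc, weight, sorted ascending by
#'   CICc), `claims` (per-model claim p-values), `n`, and `best_coefs`.
#' @export
phylo_path <- function(table, tree, models = builtin_models(),
                       fit_best = TRUE, se_denominator = "ml") {
  stopifnot(length(models) >= 1)
  vars <- unique(unlist(lapply(models, function(m) m$vertices)))
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols)) {
    stop("trait table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  ad <- align_data_tree(table, tree, vars)
  n <- nrow(ad$data)
  claim_p <- list()
  rows <- lapply(models, function(m) {
    claims <- basis_set(m)
    pv <- test_claims(claims, ad$data, ad$tree,
                      se_denominator = se_denominator)
    fc <- fishers_c(pv)
    claim_p[[m$name]] <<- pv
    data.frame(model = m$name, C = fc$C, k = length(claims),
               q = q_params(m), p = fc$p,
               cicc = cicc(fc$C, q_params(m), n), stringsAsFactors = FALSE)
  })
  summary <- rank_models(do.call(rbind, rows))
  best <- models[[which(vapply(models, function(m) m$name, "") ==
                          summary$model[1])]]
  out <- list(
    summary = summary,
    claims = claim_p,
    n = n,
    best_model = best,
    best_coefs = if (fit_best) {
      fit_path_coefficients(best, ad$data, ad$tree,
                            se_denominator = se_denominator)
    } else NULL,
    method = "directional"
  )
  class(out) <- "phylo_path"
  out
}

#' @export
print.phylo_path <- function(x, ...) {
  cat(sprintf("Phylogenetic path analysis (%s method), n = %d species\n",
              x$method, x$n))
  s <- x$summary
  s$C <- round(s$C, 3)
  s$p <- signif(s$p, 3)
  s$cicc <- round(s$cicc, 3)
  s$delta_cicc <- round(s$delta_cicc, 3)
  s$weight <- round(s$weight, 3)
  print(s, row.names = FALSE)
  if (!is.null(x$best_coefs)) {
    cat("\nStandardized coefficients of best model (", x$summary$model[1],
        "):\n", sep = "")
    print(format(x$best_coefs, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Nondirectional path analysis via lambda-rescaled contrasts
#'
#' PGLS-based d-separation estimates lambda within directed regressions, so
#' the estimate depends on which variable is treated as the response. This
#' variant removes the directionality: (1) the phylogenetic signal lambda
#' of each variable is estimated by maximum likelihood from an
#' intercept-only model; (2) the tree is lambda-rescaled to a unit tree per
#' variable; (3) phylogenetically independent contrasts are computed on
#' that variable-specific tree. Claim tests and coefficient fits are then
#' ordinary through-origin regressions on the contrast-transformed
#' variables. C, CICc, and ranking are computed as in [phylo_path()];
#' `n` in CICc defaults to the species count.
#'
#' @param table trait table.
#' @param tree ultrametric rooted `phylo`.
#' @param models list of `dag_model` objects.
#' @param n_method sample size used in CICc: `"species"` (default) or
#'   `"contrasts"`.
#' @param fit_best fit standardized coefficients of the best model.
#' @return object of class `"phylo_path"` with `method = "santos"`.
#' @export
santos_path_fit <- function(table, tree, models = builtin_models(),
                            n_method = c("species", "contrasts"),
                            fit_best = TRUE) {
  n_method <- match.arg(n_method)
  if (!is_ultrametric_tol(tree)) {
    stop("nondirectional variant requires an ultrametric tree")
  }
  vars <- unique(unlist(lapply(models, function(m) m$vertices)))
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols)) {
    stop("trait table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  ad <- align_data_tree(table, tree, vars)
  n_sp <- nrow(ad$data)
  ones <- matrix(1, n_sp, 1, dimnames = list(NULL, "(Intercept)"))
  V <- vcv_matrix(ad$tree)
  contrast_tbl <- list()
  lambdas <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    x <- ad$data[[v]]
    if (stats::sd(x) == 0) {
      stop("variable '", v, "' is constant; lambda cannot be estimated")
    }
    fit <- profile_lambda_ml(ones, x, V = V)
    lambdas[v] <- fit$lambda
    tr_v <- lambda_rescale_tree(ad$tree, fit$lambda, unit_height = TRUE)
    contrast_tbl[[v]] <- as.numeric(
      pic_contrasts(tr_v, stats::setNames(x, ad$tree$tip.label))
    )
  }
  ctab <- as.data.frame(contrast_tbl)
  n_used <- if (n_method == "species") n_sp else nrow(ctab)
  origin_lm_p <- function(resp, preds) {
    X <- as.matrix(ctab[, preds, drop = FALSE])
    fit <- stats::summary.lm(stats::lm(ctab[[resp]] ~ 0 + X))
    stats::setNames(fit$coefficients[, 4], preds)
  }
  claim_p <- list()
  rows <- lapply(models, function(m) {
    claims <- basis_set(m)
    pv <- vapply(claims, function(cl) {
      p <- origin_lm_p(cl$response, c(cl$other, cl$conditioning))[cl$other]
      max(p, 1e-300)
    }, numeric(1))
    fc <- fishers_c(pv)
    claim_p[[m$name]] <<- pv
    data.frame(model = m$name, C = fc$C, k = length(claims),
               q = q_params(m), p = fc$p,
               cicc = cicc(fc$C, q_params(m), n_used),
               stringsAsFactors = FALSE)
  })
  summary <- rank_models(do.call(rbind, rows))
  best <- models[[which(vapply(models, function(m) m$name, "") ==
                          summary$model[1])]]
  best_coefs <- NULL
  if (fit_best) {
    sctab <- as.data.frame(lapply(ctab, function(x) x / stats::sd(x)))
    rows_c <- list()
    for (v in topological_order(best)) {
      pa <- dag_parents(best, v)
      if (!length(pa)) next
      X <- as.matrix(sctab[, pa, drop = FALSE])
      sfit <- stats::summary.lm(stats::lm(sctab[[v]] ~ 0 + X))
      for (i in seq_along(pa)) {
        est <- sfit$coefficients[i, 1]
        se <- sfit$coefficients[i, 2]
        rows_c[[length(rows_c) + 1L]] <- data.frame(
          from = pa[i], to = v, coef = est, se = se,
          lower = est - 1.96 * se, upper = est + 1.96 * se,
          lambda = lambdas[v], n = n_sp, stringsAsFactors = FALSE
        )
      }
    }
    best_coefs <- do.call(rbind, rows_c)
  }
  out <- list(summary = summary, claims = claim_p, n = n_used,
              lambdas = lambdas, best_model = best,
              best_coefs = best_coefs, method = "santos")
  class(out) <- "phylo_path"
  out
}
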