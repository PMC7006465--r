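#' Generalized least squares with a known error covariance
#'
#' Fits `y = X beta + e`, `Var(e) = sigma2 * V`, by whitening with the
#' Cholesky factor of `V` and solving the resulting ordinary least-squares
#' problem: `beta = (X' V^-1 X)^-1 X' V^-1 y`. The scale is estimated by
#' maximum likelihood, `sigma2 = r' V^-1 r / n`, and the Gaussian
#' log-likelihood is reported. Standard errors come from
#' `sigma2 * (X' V^-1 X)^-1`; with `se_denominator = "residual"` the scale
#' used for the standard errors is the unbiased `n / (n - p)` rescaling.
#'
#' @param X design matrix (including the intercept column).
#' @param y response vector.
#' @param V positive-definite covariance matrix aligned with the rows.
#' @param se_denominator `"ml"` (divide the residual sum of squares by `n`;
#'   default) or `"residual"` (`n - p`).
#' @return list with `betas`, `ses`, `loglik`, `sigma2`, `n`, `p`.
#' @export
gls_fit <- function(X, y, V, se_denominator = c("ml", "residual")) {
  se_denominator <- match.arg(se_denominator)
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(V) == length(y))
  R <- tryCatch(chol(V), error = function(e) {
    stop("V is not positive definite: ", conditionMessage(e))
  })
  Xw <- backsolve(R, X, transpose = TRUE)
  colnames(Xw) <- colnames(X)
  yw <- backsolve(R, y, transpose = TRUE)
  whitened_fit(Xw, yw, logdetV = 2 * sum(log(diag(R))),
               se_denominator = se_denominator)
}

# OLS on whitened data; shared by the Cholesky and eigen routes.
whitened_fit <- function(Xw, yw, logdetV, se_denominator = "ml") {
  n <- nrow(Xw)
  p <- ncol(Xw)
  qx <- qr(Xw)
  if (qx$rank < p) {
    bad <- colnames(Xw)[qx$pivot[seq(qx$rank + 1L, p)]]
    stop("design matrix is singular; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qx, yw)
  r <- yw - Xw %*% betas
  rss <- sum(r^2)
  sigma2 <- rss / n
  XtXi <- chol2inv(qr.R(qx)[, order(qx$pivot), drop = FALSE])
  scale2 <- if (se_denominator == "residual") rss / (n - p) else sigma2
  ses <- sqrt(pmax(diag(XtXi), 0) * scale2)
  names(ses) <- names(betas)
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetV + n)
  list(betas = betas, ses = ses, loglik = loglik, sigma2 = sigma2,
       n = n, p = p)
}

# Profile log-likelihood machinery for Pagel's lambda. When all tip depths
# are (numerically) equal, V(lambda) = lambda*V + (1-lambda)*h*I shares the
# eigenvectors of V, so a single eigendecomposition serves every lambda;
# otherwise each evaluation re-whitens through a Cholesky factorization.
lambda_profile_fun <- function(X, y, V, se_denominator = "ml") {
  d <- diag(V)
  h <- mean(d)
  if (h > 0 && (max(d) - min(d)) / h < 1e-10) {
    e <- eigen(V, symmetric = TRUE)
    Xe <- crossprod(e$vectors, X)
    colnames(Xe) <- colnames(X)
    ye <- drop(crossprod(e$vectors, y))
    function(lam) {
      w <- lam * e$values + (1 - lam) * h
      if (any(w <= 0)) stop("V(lambda) is not positive definite")
      sw <- 1 / sqrt(w)
      whitened_fit(Xe * sw, ye * sw, logdetV = sum(log(w)),
                   se_denominator = se_denominator)
    }
  } else {
    function(lam) gls_fit(X, y, lambda_transform(V, lam),
                          se_denominator = se_denominator)
  }
}

#' Maximum-likelihood estimation of Pagel's lambda in a GLS model
#'
#' Profiles the Gaussian log-likelihood of the GLS model over
#' `V(lambda) = lambda-transform of V` and maximizes it on \[0, 1\] by
#' bounded one-dimensional optimization (tolerance `tol`), with both
#' endpoints checked explicitly. On a star phylogeny (all off-diagonal
#' covariances zero) lambda is unidentifiable; the fit is returned at
#' `lambda = 0` with `flat_lambda = TRUE`.
#'
#' @param X design matrix with intercept.
#' @param y response vector.
#' @param tree rooted `phylo` aligned with the rows (alternative to `V`).
#' @param V phylogenetic covariance matrix (used if `tree` is missing).
#' @param tol optimizer tolerance on lambda.
#' @param se_denominator passed to [gls_fit()].
#' @return list: fields of [gls_fit()] at the optimum plus `lambda` and
#'   `flat_lambda`.
#' @export
profile_lambda_ml <- function(X, y, tree = NULL, V = NULL, tol = 1e-6,
                              se_denominator = "ml") {
  if (is.null(V)) {
    if (is.null(tree)) stop("supply either a tree or a covariance matrix")
    V <- vcv_matrix(tree)
  }
  X <- as.matrix(X)
  n <- length(y)
  if (n < ncol(X) + 2L) stop("need at least p + 2 complete rows")
  f <- lambda_profile_fun(X, y, V, se_denominator)
  offmax <- max(abs(V[upper.tri(V)]), 0)
  if (offmax <= 1e-12 * mean(diag(V))) {
    fit <- f(0)
    fit$lambda <- 0
    fit$flat_lambda <- TRUE
    return(fit)
  }
  ll <- function(lam) f(lam)$loglik
  opt <- stats::optimise(ll, c(0, 1), maximum = TRUE, tol = tol)
  cand <- c(0, opt$maximum, 1)
  vals <- c(ll(0), opt$objective, ll(1))
  lam_hat <- cand[which.max(vals)]
  fit <- f(lam_hat)
  fit$lambda <- lam_hat
  fit$flat_lambda <- FALSE
  fit
}

#' Standardize predictors by two standard deviations (Gelman scaling)
#'
#' Numeric predictors are centered and divided by twice their standard
#' deviation, so that their coefficients are comparable with those of
#' (centered) binary indicators; columns with exactly two distinct values
#' are centered only. This makes slopes from predictors on different scales
#' directly comparable as effect sizes.
#'
#' @param x numeric matrix or data frame of predictor columns.
#' @return object of the same shape with scaled columns.
#' @export
gelman_standardize <- function(x) {
  scale_col <- function(v) {
    u <- unique(v[!is.na(v)])
    if (length(u) < 2L) stop("cannot standardize a zero-variance column")
    if (length(u) == 2L) return(v - mean(v, na.rm = TRUE))
    (v - mean(v, na.rm = TRUE)) / (2 * stats::sd(v, na.rm = TRUE))
  }
  if (is.data.frame(x)) {
    x[] <- lapply(x, scale_col)
    x
  } else {
    apply(as.matrix(x), 2, scale_col)
  }
}

# Align a trait table with a tree without chatter: complete cases on `vars`,
# intersect with tip labels, prune, order rows as tips.
align_data_tree <- function(data, tree, vars) {
  stopifnot("species" %in% names(data))
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  data <- data[keep, , drop = FALSE]
  shared <- intersect(tree$tip.label, data$species)
  if (length(shared) < 3L) stop("fewer than 3 species shared with the tree")
  tree <- ape::keep.tip(tree, shared)
  data <- data[match(tree$tip.label, data$species), , drop = FALSE]
  list(data = data, tree = tree)
}

#' Phylogenetic generalized least squares with ML Pagel's lambda
#'
#' Fits a PGLS regression: complete cases are taken on the model variables,
#' the tree is pruned to those species, lambda is estimated by maximum
#' likelihood (or fixed), and two-tailed p-values are computed from the t
#' distribution with `n - p` degrees of freedom on `beta / SE`.
#'
#' @param formula model formula in terms of trait-table columns.
#' @param data trait table with a `species` column matching tip labels.
#' @param tree rooted `phylo` with branch lengths.
#' @param standardize apply [gelman_standardize()] to the predictor columns
#'   of the design matrix (intercept excluded) before fitting.
#' @param lambda `"ML"` (default) or a fixed value in \[0, 1\].
#' @param se_denominator passed to [gls_fit()].
#' @return object of class `"pgls_fit"`: coefficient table (estimate, SE,
#'   t, two-tailed p), `lambda`, `loglik`, `sigma2`, `n`.
#' @export
pgls <- function(formula, data, tree, standardize = FALSE, lambda = "ML",
                 se_denominator = "ml") {
  vars <- all.vars(formula)
  unknown <- setdiff(vars, names(data))
  if (length(unknown)) {
    stop("variable(s) not in table: ", paste(unknown, collapse = ", "))
  }
  ad <- align_data_tree(data, tree, vars)
  mf <- stats::model.frame(formula, ad$data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (nrow(X) < ncol(X) + 2L) {
    stop("too few species (", nrow(X), ") for ", ncol(X), " parameters")
  }
  if (standardize) {
    pred <- setdiff(colnames(X), "(Intercept)")
    if (length(pred)) X[, pred] <- gelman_standardize(X[, pred, drop = FALSE])
  }
  V <- vcv_matrix(ad$tree)
  if (identical(lambda, "ML")) {
    fit <- profile_lambda_ml(X, y, V = V, se_denominator = se_denominator)
  } else {
    fit <- gls_fit(X, y, lambda_transform(V, lambda),
                   se_denominator = se_denominator)
    fit$lambda <- lambda
    fit$flat_lambda <- FALSE
  }
  tval <- fit$betas / fit$ses
  df <- fit$n - fit$p
  pval <- 2 * stats::pt(-abs(tval), df)
  out <- list(
    call = match.call(),
    formula = formula,
    coefficients = data.frame(
      term = names(fit$betas), estimate = unname(fit$betas),
      se = unname(fit$ses), t = unname(tval), p = unname(pval),
      stringsAsFactors = FALSE
    ),
    lambda = fit$lambda,
    flat_lambda = fit$flat_lambda,
    loglik = fit$loglik,
    sigma2 = fit$sigma2,
    n = fit$n,
    df_residual = df
  )
  class(out) <- "pgls_fit"
  out
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit:", deparse(x$formula), "\n")
  cat(sprintf("n = %d, lambda = %.4f%s, logLik = %.3f\n", x$n, x$lambda,
              if (x$flat_lambda) " (flat likelihood)" else "", x$loglik))
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.pgls_fit <- function(object, ...) object$loglik

#' Repeat a PGLS model over a sample of phylogenies
#'
#' Refits the model on every supplied tree (lambda re-estimated per tree)
#' and summarizes, per predictor, the mean slope and mean two-tailed p
#' together with their spread across trees. Two spread measures are
#' reported: the standard error of the mean across trees (`se_*`, the
#' default headline uncertainty) and the raw standard deviation (`sd_*`).
#'
#' @param formula,data,standardize,lambda,se_denominator as in [pgls()].
#' @param trees non-empty list of `phylo` objects.
#' @return object of class `"multi_pgls"` with a per-term `summary` data
#'   frame, per-tree `lambdas`, and `n_trees`.
#' @export
multi_tree_pgls <- function(formula, data, trees, standardize = FALSE,
                            lambda = "ML", se_denominator = "ml") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("empty tree list")
  fits <- lapply(trees, function(tr) {
    pgls(formula, data, tr, standardize = standardize, lambda = lambda,
         se_denominator = se_denominator)
  })
  terms <- fits[[1]]$coefficients$term
  B <- vapply(fits, function(f) f$coefficients$estimate, numeric(length(terms)))
  P <- vapply(fits, function(f) f$coefficients$p, numeric(length(terms)))
  B <- matrix(B, nrow = length(terms))
  P <- matrix(P, nrow = length(terms))
  nt <- length(fits)
  row_sd <- function(M) apply(M, 1, stats::sd)
  sd_b <- if (nt > 1) row_sd(B) else rep(0, length(terms))
  sd_p <- if (nt > 1) row_sd(P) else rep(0, length(terms))
  out <- list(
    formula = formula,
    summary = data.frame(
      term = terms,
      mean_beta = rowMeans(B), se_beta = sd_b / sqrt(nt), sd_beta = sd_b,
      mean_p = rowMeans(P), se_p = sd_p / sqrt(nt), sd_p = sd_p,
      stringsAsFactors = FALSE
    ),
    lambdas = vapply(fits, function(f) f$lambda, numeric(1)),
    n = fits[[1]]$n,
    n_trees = nt
  )
  class(out) <- "multi_pgls"
  out
}

#' @export
print.multi_pgls <- function(x, ...) {
  cat("PGLS over", x$n_trees, "trees:", deparse(x$formula),
      sprintf("(n = %d, mean lambda = %.3f)\n", x$n, mean(x$lambdas)))
  print(format(x$summary, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Variance inflation factors from ordinary regressions
#'
#' `VIF_j = 1 / (1 - R^2_j)`, where `R^2_j` comes from an ordinary
#' (non-phylogenetic) linear regression of predictor j on all the others —
#' the standard collinearity diagnostic for the predictor set of a model.
#' Perfectly collinear predictors are reported as `Inf`.
#'
#' @param x data frame or numeric matrix of predictors (factors expanded to
#'   indicators; no intercept column).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(x) {
  if (is.data.frame(x)) {
    x <- stats::model.matrix(~., data = x)[, -1, drop = FALSE]
  }
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2L) return(stats::setNames(rep(1, p), colnames(x)))
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    tss <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(x))
}

#' The four-step PGLS modelling protocol
#'
#' Runs the full regression protocol for maturation bias over a sample of
#' trees: step 1, separate bivariate models against `polygamy_bias`, `ssd`,
#' and `asr_t`; step 2, the same predictors each with the life-history
#' confounds (`dev_mode`, `mortality_bias`, `log_mass`); step 3, additive
#' models `polygamy_bias + asr_t` and `ssd + asr_t`; step 4, the additive
#' models plus confounds. Polygamy bias and SSD are never entered together
#' (collinearity between the two sexual-selection indices). Predictors are
#' Gelman-standardized; each model uses its own complete-case sample, and
#' ordinary-regression VIFs are reported for every multipredictor model.
#'
#' @param table derived trait table.
#' @param trees list of `phylo` objects.
#' @param standardize Gelman-scale predictors (default `TRUE`).
#' @param se_denominator passed to [pgls()].
#' @return object of class `"pgls_protocol"`: named list of model entries,
#'   each with `step`, `formula`, `fit` (a `multi_pgls`), `n`, `vif`.
#' @export
run_protocol <- function(table, trees, standardize = TRUE,
                         se_denominator = "ml") {
  confounds <- c("dev_mode", "mortality_bias", "log_mass")
  required <- c("species", "maturation_bias", "polygamy_bias", "ssd", "asr_t",
                confounds)
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("trait table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  rhs <- list(
    s1_polygamy = "polygamy_bias",
    s1_ssd = "ssd",
    s1_asr = "asr_t",
    s2_polygamy = c("polygamy_bias", confounds),
    s2_ssd = c("ssd", confounds),
    s2_asr = c("asr_t", confounds),
    s3_polygamy_asr = c("polygamy_bias", "asr_t"),
    s3_ssd_asr = c("ssd", "asr_t"),
    s4_polygamy_asr = c("polygamy_bias", "asr_t", confounds),
    s4_ssd_asr = c("ssd", "asr_t", confounds)
  )
  out <- lapply(names(rhs), function(nm) {
    preds <- rhs[[nm]]
    fml <- stats::reformulate(preds, response = "maturation_bias")
    vars <- c("maturation_bias", preds)
    cc <- table[stats::complete.cases(table[, vars, drop = FALSE]), ,
                drop = FALSE]
    fit <- multi_tree_pgls(fml, table, trees, standardize = standardize,
                           se_denominator = se_denominator)
    v <- if (length(preds) > 1L) vif(cc[, preds, drop = FALSE]) else NULL
    list(step = as.integer(substr(nm, 2, 2)), name = nm, formula = fml,
         fit = fit, n = fit$n, vif = v)
  })
  names(out) <- names(rhs)
  class(out) <- "pgls_protocol"
  out
}

#' @export
print.pgls_protocol <- function(x, ...) {
  for (entry in x) {
    cat(sprintf("[step %d] %s  (n = %d)\n", entry$step,
                deparse(entry$formula), entry$n))
    print(format(entry$fit$summary, digits = 3), row.names = FALSE)
    if (!is.null(entry$vif)) {
      cat("  VIF:", paste(sprintf("%s = %.2f", names(entry$vif), entry$vif),
                          collapse = ", "), "\n")
    }
    cat("\n")
  }
  invisible(x)
}
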