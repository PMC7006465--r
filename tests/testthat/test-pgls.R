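test_that("gls_fit reduces to OLS at V = identity and matches the
           explicit-inverse oracle", {
  set.seed(12)
  n <- 30
  X <- cbind("(Intercept)" = 1, x1 = rnorm(n), x2 = rnorm(n))
  y <- 1 + 0.5 * X[, 2] - 0.2 * X[, 3] + rnorm(n)

  fit <- gls_fit(X, y, diag(n))
  ols <- lm(y ~ X[, 2] + X[, 3])
  expect_equal(unname(fit$betas), unname(coef(ols)), tolerance = 1e-10)
  # SEs agree up to the ML vs residual df convention
  expect_equal(unname(fit$ses) * sqrt(n / (n - 3)),
               unname(summary(ols)$coefficients[, 2]), tolerance = 1e-10)
  fit_r <- gls_fit(X, y, diag(n), se_denominator = "residual")
  expect_equal(unname(fit_r$ses),
               unname(summary(ols)$coefficients[, 2]), tolerance = 1e-10)

  # n = 2 simple regression interpolates: zero residual variance
  f2 <- gls_fit(cbind(1, c(0, 1)), c(3, 5), diag(2))
  expect_equal(f2$sigma2, 0, tolerance = 1e-20)

  # 15-species fixture vs brute-force (X' V^-1 X)^-1 X' V^-1 y
  t15 <- simulate_yule_tree(15, seed = 44)
  V <- vcv_matrix(t15)
  X15 <- cbind(1, rnorm(15))
  y15 <- X15 %*% c(1, 2) + simulate_lambda_bm(t15, 1, 1)
  g <- gls_fit(X15, y15, V)
  Vi <- solve(V)
  beta_oracle <- solve(t(X15) %*% Vi %*% X15, t(X15) %*% Vi %*% y15)
  expect_equal(unname(g$betas), drop(beta_oracle), tolerance = 1e-8)

  # collinear design named in the error
  Xc <- cbind("(Intercept)" = 1, a = rnorm(n), dup = 0)
  Xc[, "dup"] <- Xc[, "a"]
  expect_error(gls_fit(Xc, y, diag(n)), "dup")

  # non-positive-definite V rejected
  expect_error(gls_fit(X, y, matrix(1, n, n)), "positive definite")
})

test_that("profile_lambda_ml maximizes the profile likelihood on [0,1]", {
  tr <- simulate_yule_tree(60, seed = 10)
  V <- vcv_matrix(tr)
  X <- matrix(1, 60, 1, dimnames = list(NULL, "(Intercept)"))
  y <- simulate_lambda_bm(tr, 1, 0.6, seed = 8)
  fit <- profile_lambda_ml(X, y, V = V)

  # optimum beats both endpoints (up to tolerance)
  ll <- function(lam) gls_fit(X, y, lambda_transform(V, lam))$loglik
  expect_gte(fit$loglik, max(ll(0), ll(1)) - 1e-6)

  # global maximum on a 1001-point grid within 1e-4
  grid <- seq(0, 1, length.out = 1001)
  expect_gte(fit$loglik, max(vapply(grid, ll, numeric(1))) - 1e-4)

  # eigen fast path agrees with the Cholesky route at fixed lambda
  f_fast <- lambda_profile_fun(X, y, V)
  expect_equal(f_fast(0.37)$loglik, ll(0.37), tolerance = 1e-8)

  # star tree: lambda unidentifiable, flagged
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  ystar <- stats::setNames(rnorm(5), star$tip.label)
  sfit <- profile_lambda_ml(matrix(1, 5, 1), ystar, V = vcv_matrix(star))
  expect_equal(sfit$lambda, 0)
  expect_true(sfit$flat_lambda)
})

test_that("lambda estimates track the generative signal", {
  tr <- simulate_yule_tree(100, seed = 21)
  V <- vcv_matrix(tr)
  X <- matrix(1, 100, 1)
  set.seed(22)
  lam_bm <- replicate(20, {
    profile_lambda_ml(X, simulate_lambda_bm(tr, 1, 1), V = V)$lambda
  })
  expect_gte(median(lam_bm), 0.9)
  lam_iid <- replicate(20, {
    profile_lambda_ml(X, stats::setNames(rnorm(100), tr$tip.label),
                      V = V)$lambda
  })
  expect_lte(median(lam_iid), 0.1)
})

test_that("gelman_standardize scales numeric columns by 2 SD and centers
           binaries", {
  set.seed(33)
  x <- rnorm(500)
  z <- gelman_standardize(cbind(x = x))
  expect_equal(sd(z), 0.5, tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)

  # sd = 0.5 column: dividing by 2 sd = 1 leaves scale unchanged
  h <- x * (0.5 / sd(x))
  zh <- gelman_standardize(cbind(h = h))
  expect_equal(sd(zh), sd(h), tolerance = 1e-12)

  # balanced binary -> centered to +/- 0.5
  b <- rep(c(0, 1), 10)
  expect_equal(unique(as.vector(gelman_standardize(cbind(b = b)))),
               c(-0.5, 0.5))

  expect_error(gelman_standardize(cbind(k = rep(2, 5))), "zero-variance")
})

test_that("pgls respects symmetries and sample-size guards", {
  tab <- study50$table
  tr <- study50$tree
  f <- pgls(maturation_bias ~ ssd, tab, tr)
  tab_neg <- tab
  tab_neg$maturation_bias <- -tab_neg$maturation_bias
  f_neg <- pgls(maturation_bias ~ ssd, tab_neg, tr)
  expect_equal(f_neg$coefficients$estimate, -f$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(f_neg$coefficients$p, f$coefficients$p, tolerance = 1e-10)
  expect_equal(f_neg$lambda, f$lambda, tolerance = 1e-6)

  # too few species for the parameter count
  tiny <- tab[1:3, ]
  expect_error(pgls(maturation_bias ~ ssd + polygamy_bias + asr_t,
                    tiny, tr), "species")
  expect_error(pgls(maturation_bias ~ nope, tab, tr), "nope")
})

test_that("pgls agrees with the nlme::gls corPagel oracle", {
  skip_if_not_installed("nlme")
  tab <- study50$table
  rownames(tab) <- tab$species
  f <- pgls(maturation_bias ~ ssd, tab, study50$tree)
  g <- nlme::gls(maturation_bias ~ ssd, data = tab, method = "ML",
                 correlation = ape::corPagel(0.5, study50$tree,
                                             form = ~species))
  expect_equal(f$lambda, unname(coef(g$modelStruct$corStruct)),
               tolerance = 1e-4)
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
})

test_that("multi_tree_pgls aggregates slope and p across trees", {
  tab <- study50$table
  tr <- study50$tree
  single <- pgls(maturation_bias ~ polygamy_bias, tab, tr)

  # identical trees: zero SE, mean equals the single fit
  mt <- multi_tree_pgls(maturation_bias ~ polygamy_bias, tab,
                        replicate(10, tr, simplify = FALSE))
  expect_equal(mt$summary$se_beta, c(0, 0))
  expect_equal(mt$summary$mean_beta, single$coefficients$estimate)
  expect_equal(mt$n_trees, 10)

  # two trees: arithmetic average of the two fits
  tr2 <- simulate_tree_set(tr, 1, jitter = 0.3, seed = 77)[[1]]
  f2 <- pgls(maturation_bias ~ polygamy_bias, tab, tr2)
  mt2 <- multi_tree_pgls(maturation_bias ~ polygamy_bias, tab,
                         list(tr, tr2))
  expect_equal(mt2$summary$mean_beta,
               (single$coefficients$estimate + f2$coefficients$estimate) / 2,
               tolerance = 1e-10)
  expect_error(multi_tree_pgls(maturation_bias ~ ssd, tab, list()), "empty")
})

test_that("vif matches the 1/(1 - R^2) definition", {
  set.seed(55)
  n <- 200
  # orthogonal predictors (orthogonal polynomials: mutually orthogonal
  # and orthogonal to the intercept)
  q <- unclass(poly(seq_len(n), 3))
  colnames(q) <- c("a", "b", "c")
  expect_equal(unname(vif(q)), rep(1, 3), tolerance = 1e-10)

  # duplicated column -> infinite
  d <- cbind(a = rnorm(n), b = 0)
  d[, "b"] <- d[, "a"]
  expect_equal(unname(vif(d)), c(Inf, Inf))

  # correlated columns vs direct R^2 oracle
  x1 <- rnorm(n)
  x2 <- 0.7 * x1 + rnorm(n)
  x3 <- 0.3 * x1 - 0.5 * x2 + rnorm(n)
  M <- cbind(x1 = x1, x2 = x2, x3 = x3)
  v <- vif(M)
  oracle <- vapply(1:3, function(j) {
    1 / (1 - summary(lm(M[, j] ~ M[, -j]))$r.squared)
  }, numeric(1))
  expect_equal(unname(v), oracle, tolerance = 1e-10)
})

test_that("run_protocol fits the full four-step model set", {
  trees <- simulate_tree_set(study50$tree, 2, jitter = 0.1, seed = 9)
  prot <- run_protocol(study50$table, trees)
  expect_length(prot, 10)
  expect_equal(vapply(prot, function(e) e$step, integer(1)),
               c(s1_polygamy = 1L, s1_ssd = 1L, s1_asr = 1L,
                 s2_polygamy = 2L, s2_ssd = 2L, s2_asr = 2L,
                 s3_polygamy_asr = 3L, s3_ssd_asr = 3L,
                 s4_polygamy_asr = 4L, s4_ssd_asr = 4L))
  # polygamy bias and SSD never enter the same model
  for (entry in prot) {
    vars <- all.vars(entry$formula)
    expect_false(all(c("polygamy_bias", "ssd") %in% vars))
    # n equals the complete-case count for the model's variable set
    expect_equal(entry$n, sum(stats::complete.cases(
      study50$table[, vars, drop = FALSE]
    )))
  }
  # multipredictor models carry VIF diagnostics
  expect_true(all(vif(study50$table[, c("polygamy_bias", "asr_t")]) >= 1))
  expect_false(is.null(prot$s3_polygamy_asr$vif))
  expect_error(run_protocol(study50$table[, 1:3], trees), "lacks column")
})
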