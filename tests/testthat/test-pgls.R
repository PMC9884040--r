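# PGLS fitting, ANCOVA, bootstrap, allometry calls, size correction.

test_that("GLS reduces to OLS on a star phylogeny", {
  set.seed(1)
  n <- 20
  star <- ape::stree(n, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  star$tip.label <- sprintf("sp%03d", 1:n)
  d <- data.frame(species_id = star$tip.label,
                  x = rnorm(n), g = rep(c("a", "b"), n / 2))
  d$y <- 1 + 0.5 * d$x + rnorm(n, 0, 0.3)
  fit <- fit_pgls(y ~ x + g, d, star, lambda = 1)
  ols <- lm(y ~ x + g, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(residuals(fit)), unname(residuals(ols)), tolerance = 1e-8)
})

test_that("coefficients, SEs and log-likelihood match the dense GLS oracle", {
  for (i in 1:6) {
    n <- sample(5:8, 1)
    tr <- rand_tree(n, seed = 300 + i)
    set.seed(400 + i)
    d <- data.frame(species_id = tr$tip.label, x = rnorm(n))
    d$y <- 0.5 + 0.8 * d$x + rnorm(n, 0, 0.2)
    V <- phylo_vcv(tr)$V[d$species_id, d$species_id]
    X <- cbind(1, d$x)
    for (lam in c(0, 0.3, 0.7, 1)) {
      fit <- fit_pgls(y ~ x, d, tr, lambda = lam)
      orc <- oracle_gls(X, d$y, V, lam)
      expect_equal(unname(coef(fit)), orc$beta, tolerance = 1e-8)
      expect_equal(fit$logLik, orc$logLik, tolerance = 1e-8)
      expect_equal(unname(sqrt(diag(fit$vcov))), orc$se, tolerance = 1e-8)
    }
  }
})

test_that("ML lambda beats a 101-point profile grid", {
  for (i in 1:4) {
    n <- 30
    tr <- rand_tree(n, seed = 500 + i)
    V <- phylo_vcv(tr)$V
    set.seed(600 + i)
    lam_true <- c(0.2, 0.5, 0.8, 1)[i]
    Vl <- lam_true * V; diag(Vl) <- diag(V)
    d <- data.frame(species_id = rownames(V), x = rnorm(n))
    d$y <- 1 + 0.4 * d$x + drop(crossprod(chol(Vl), rnorm(n))) * 0.3
    fit <- fit_pgls(y ~ x, d, tr)
    X <- cbind(1, d$x)
    grid_ll <- vapply(seq(0, 1, length.out = 101), function(l)
      oracle_gls(X, d$y, V[d$species_id, d$species_id], l)$logLik, 0)
    expect_gte(fit$logLik, max(grid_ll) - 1e-6)
  }
})

test_that("residuals satisfy the GLS normal equations in the V-metric", {
  tr <- rand_tree(25, seed = 77)
  set.seed(78)
  d <- data.frame(species_id = tr$tip.label, x = rnorm(25),
                  g = sample(c("u", "v"), 25, TRUE))
  d$y <- rnorm(25)
  fit <- fit_pgls(y ~ x * g, d, tr)
  Vl <- phylo_vcv(tr)$V[d$species_id, d$species_id] * fit$lambda
  diag(Vl) <- diag(phylo_vcv(tr)$V)
  score <- t(fit$X) %*% solve(Vl, unname(fit$residuals))
  expect_lt(max(abs(score)), 1e-8)
})

test_that("agreement with nlme::gls under corPagel (independent implementation)", {
  # n large enough that the ML lambda is interior to [0, 1]; corPagel is
  # unconstrained, so boundary cases would not be comparable
  tr <- rand_tree(60, seed = 31)
  set.seed(32)
  d <- data.frame(species_id = tr$tip.label, x = rnorm(60))
  V <- phylo_vcv(tr)$V
  Vl <- 0.7 * V; diag(Vl) <- diag(V)
  d$y <- 2 - 0.5 * d$x + drop(crossprod(chol(Vl), rnorm(60))) * 0.4
  fit <- fit_pgls(y ~ x, d, tr)
  gf <- nlme::gls(y ~ x, data = d, method = "ML",
                  correlation = ape::corPagel(0.5, tr, form = ~species_id))
  lam_nlme <- coef(gf$modelStruct$corStruct, unconstrained = FALSE)
  expect_equal(unname(coef(fit)), unname(coef(gf)), tolerance = 1e-5)
  expect_equal(fit$lambda, unname(lam_nlme), tolerance = 1e-3)
  expect_equal(fit$logLik, as.numeric(logLik(gf)), tolerance = 1e-6)
})

test_that("type II SS equal sequential SS in balanced orthogonal designs", {
  n <- 24
  star <- ape::stree(n, "star"); star$edge.length <- rep(1, nrow(star$edge))
  star$tip.label <- sprintf("s%02d", 1:n)
  set.seed(10)
  g <- rep(c("a", "b"), each = n / 2)
  x <- rep(c(-1, 1), n / 2)                   # orthogonal to g
  d <- data.frame(species_id = star$tip.label, g = g, x = x,
                  y = rnorm(n))
  fit <- fit_pgls(y ~ x + g, d, star, lambda = 1)
  tab <- type2_anova(fit)
  seq_tab <- anova(lm(y ~ x + g, d))
  expect_equal(tab$SS, seq_tab[c("x", "g"), "Sum Sq"], tolerance = 1e-8)
  expect_equal(tab$F, seq_tab[c("x", "g"), "F value"], tolerance = 1e-8)
})

test_that("type II SS match explicit nested-model refits (unbalanced, phylogenetic)", {
  tr <- rand_tree(18, seed = 55)
  set.seed(56)
  d <- data.frame(species_id = tr$tip.label,
                  x = rnorm(18),
                  g = sample(c("a", "b", "c"), 18, TRUE, prob = c(.5, .3, .2)))
  d$y <- 0.3 * d$x + (d$g == "b") * 0.5 + rnorm(18, 0, 0.4)
  fit <- fit_pgls(y ~ x * g, d, tr)
  tab <- type2_anova(fit)
  V <- phylo_vcv(tr)$V[d$species_id, d$species_id]
  lam <- fit$lambda
  rss_of <- function(form) {
    X <- model.matrix(form, d)
    oracle_gls(X, d$y, V, lam)$rss
  }
  ss_x <- rss_of(y ~ g) - rss_of(y ~ x + g)
  ss_g <- rss_of(y ~ x) - rss_of(y ~ x + g)
  ss_xg <- rss_of(y ~ x + g) - rss_of(y ~ x * g)
  expect_equal(tab$SS[tab$term == "x"], ss_x, tolerance = 1e-8)
  expect_equal(tab$SS[tab$term == "g"], ss_g, tolerance = 1e-8)
  expect_equal(tab$SS[tab$term == "x:g"], ss_xg, tolerance = 1e-8)

  fit2 <- fit_pgls(y ~ x + x:g, d, tr)
  expect_error(type2_anova(fit2), class = "squamorph_marginality")
})

test_that("classify_allometry follows the CI exclusion rule", {
  expect_equal(classify_allometry(0.12, c(0.06, 0.19))$call, "positive")
  expect_equal(classify_allometry(-0.11, c(-0.15, -0.06))$call, "negative")
  expect_equal(classify_allometry(-0.02, c(-0.08, 0.03))$call, "not_significant")
  # zero-width CI exactly at the isometric slope is not significant
  expect_equal(classify_allometry(0, c(0, 0))$call, "not_significant")
  expect_equal(classify_allometry(0.2, c(0.1, 0.3), isometric_slope = 0.25)$call,
               "not_significant")
  expect_equal(classify_allometry(0.15, c(0.1, 0.2), isometric_slope = 0.25)$call,
               "negative")
})

test_that("per-group slopes equal within-group OLS slopes without phylogeny", {
  n <- 40
  star <- ape::stree(n, "star"); star$edge.length <- rep(1, nrow(star$edge))
  star$tip.label <- sprintf("s%02d", 1:n)
  d <- toy_traits(star, seed = 3)
  d$species_id <- star$tip.label
  fit <- fit_pgls(ln_hbER ~ ln_body_size * ecotype, d, star, lambda = 1)
  pg <- per_group_slopes(fit)
  for (g in names(pg$slopes)) {
    sub <- lm(ln_hbER ~ ln_body_size, d[d$ecotype == g, ])
    expect_equal(pg$slopes[[g]], unname(coef(sub)[2]), tolerance = 1e-8)
  }
  # all-zero interactions give the common slope
  fit0 <- fit_pgls(ln_hbER ~ ln_body_size * ecotype, d, star, lambda = 1)
  fit0$coefficients[grep(":", names(fit0$coefficients))] <- 0
  pg0 <- per_group_slopes(fit0)
  expect_true(all(abs(pg0$slopes - pg0$slopes[[1]]) < 1e-12))
  # contract error without an interaction
  fitm <- fit_pgls(ln_hbER ~ ln_body_size + ecotype, d, star, lambda = 1)
  expect_error(per_group_slopes(fitm), class = "squamorph_contract")
})

test_that("compare_group_slopes implements the symmetric exclusion rule", {
  sl <- c(a = 0.3, b = -0.3, c = 0.28)
  ci <- rbind(a = c(0.25, 0.35), b = c(-0.35, -0.25), c = c(0.2, 0.36))
  colnames(ci) <- c("lower", "upper")
  cmp <- compare_group_slopes(sl, ci)
  expect_true(cmp$different["a", "b"])
  expect_false(cmp$different["a", "c"])   # a's slope inside c's CI
  expect_false(any(diag(cmp$different)))
  expect_true(isSymmetric(cmp$different))
})

test_that("size correction returns V-orthogonal residuals; exact fit gives zeros", {
  tr <- rand_tree(15, seed = 81)
  d <- data.frame(species_id = tr$tip.label)
  set.seed(82)
  d$ln_body_size <- rnorm(15, 3.5, 0.4)
  d$ln_trait <- 0.7 + 1.2 * d$ln_body_size          # exact line, no noise
  sc <- size_correct(d, "ln_trait", "ln_body_size", tr)
  expect_lt(max(abs(sc$residuals)), 1e-10)

  d$ln_trait2 <- d$ln_trait + rnorm(15, 0, 0.3)
  sc2 <- size_correct(d, "ln_trait2", "ln_body_size", tr)
  fit <- sc2$fit
  Vl <- phylo_vcv(tr)$V[d$species_id, d$species_id] * fit$lambda
  diag(Vl) <- diag(phylo_vcv(tr)$V)
  expect_lt(max(abs(t(fit$X) %*% solve(Vl, unname(sc2$residuals)))), 1e-8)
})

test_that("degenerate zero-noise bootstrap collapses to the point estimate", {
  tr <- rand_tree(12, seed = 91)
  d <- data.frame(species_id = tr$tip.label)
  set.seed(92)
  d$x <- rnorm(12)
  d$y <- 2 + 0.5 * d$x                    # zero residual variance
  fit <- fit_pgls(y ~ x, d, tr, lambda = 0.5)
  boot <- bootstrap_cis(fit, n_reps = 50, seed = 5)
  expect_lt(max(abs(sweep(boot$replicates, 2, coef(fit)))), 1e-8)
  expect_lt(max(boot$ci[, "upper"] - boot$ci[, "lower"]), 1e-8)
})

test_that("bootstrap and group-mean results are seed-deterministic", {
  tr <- rand_tree(16, seed = 95)
  d <- toy_traits(tr, seed = 96)
  fit <- fit_pgls(ln_hbER ~ ln_body_size * ecotype, d, tr)
  b1 <- bootstrap_cis(fit, n_reps = 60, seed = 42)
  b2 <- bootstrap_cis(fit, n_reps = 60, seed = 42)
  expect_identical(b1, b2)
  b3 <- bootstrap_cis(fit, n_reps = 60, seed = 43)
  expect_false(identical(b1$ci, b3$ci))

  g1 <- group_mean_comparison(d, "ln_hbER", "ecotype", tr, n_reps = 40, seed = 7)
  g2 <- group_mean_comparison(d, "ln_hbER", "ecotype", tr, n_reps = 40, seed = 7)
  expect_identical(g1$ci, g2$ci)
})

test_that("group_mean_comparison flags a strongly shifted group", {
  tr <- rand_tree(24, seed = 99)
  set.seed(100)
  d <- data.frame(species_id = tr$tip.label,
                  grp = rep(c("a", "b", "c"), each = 8))
  d$y <- rnorm(24, 0, 0.1) + ifelse(d$grp == "b", 5, 0)   # ~50 SD shift
  gm <- group_mean_comparison(d, "y", "grp", tr, n_reps = 100, seed = 1)
  expect_true(all(gm$one_way["b", c("a", "c")]))
  expect_true(all(gm$different["b", c("a", "c")]))
  expect_false(gm$different["a", "c"])

  # identical constant groups: no flags
  d$z <- 1
  gm0 <- suppressWarnings(group_mean_comparison(d, "z", "grp", tr,
                                                n_reps = 50, seed = 2))
  expect_false(any(gm0$different))
})

test_that("collinear designs raise an error naming the aliased term", {
  tr <- rand_tree(10, seed = 101)
  d <- data.frame(species_id = tr$tip.label, x = rnorm(10))
  d$x2 <- 2 * d$x
  d$y <- rnorm(10)
  expect_error(fit_pgls(y ~ x + x2, d, tr), class = "squamorph_collinearity")
})
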