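# Independent oracles and small fixtures used across the suite. These
# deliberately use naive dense-matrix algebra / brute force, never the
# package's own fitting paths.

# dense GLS at fixed lambda: direct textbook formulas
oracle_gls <- function(X, y, V, lambda = 1) {
  d <- diag(V)
  Vl <- lambda * V
  diag(Vl) <- d
  Vi <- solve(Vl)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  n <- length(y)
  sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + determinant(Vl)$modulus + n)
  list(beta = drop(beta), rss = rss, sigma2 = sigma2,
       logLik = as.numeric(ll),
       se = sqrt(diag(solve(A) * rss / (n - ncol(X)))))
}

# random ultrametric tree fixture
rand_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$tip.label <- sprintf("sp%03d", seq_len(n))
  tr
}

# brute-force exhaustive RRPP p-value for a single-predictor model with
# identity covariance: permute the centered response over all n!
# orderings and recompute F with lm each time
oracle_exhaustive_p <- function(y, x) {
  n <- length(y)
  f_of <- function(yy) {
    fit <- stats::lm(yy ~ x)
    stats::anova(fit)[1, "F value"]
  }
  # reduced model = intercept: residuals are the centered response
  e <- y - mean(y)
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v))
    do.call(cbind, lapply(seq_along(v), function(i) rbind(v[i], perms(v[-i]))))
  }
  P <- perms(seq_len(n))
  F_obs <- f_of(y)
  Fs <- apply(P, 2, function(p) f_of(mean(y) + e[p]))
  mean(Fs >= F_obs - 1e-12)
}

# step-up BH by the closed form, written independently of bh_adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj[o[i]] <- min(1, min(m * p[o[js]] / js))
  }
  adj
}

# small four-ecotype species table on a given tree, non-phylogenetic noise
toy_traits <- function(tree, seed = 1, b = c(chipmunk = 0.3, gliding = 0.1,
                                             ground = -0.2, tree = 0)) {
  set.seed(seed)
  n <- length(tree$tip.label)
  eco <- rep(names(b), length.out = n)
  x <- rnorm(n, 3.5, 0.5)
  y <- 1 + b[eco] * x + rnorm(n, 0, 0.05)
  data.frame(species_id = tree$tip.label, ecotype = eco,
             ln_body_size = x, ln_hbER = unname(y))
}
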