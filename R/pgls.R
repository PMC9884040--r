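# Phylogenetic generalized least squares with maximum-likelihood Pagel's
# lambda, profile-optimized over [0, 1].
#
# For ultrametric covariances (constant diagonal d) the lambda family
# shares one eigenbasis: V(lambda) = U (lambda*L + (1-lambda)*d I) U', so
# the data are rotated once and every lambda evaluation is O(n p). For
# non-ultrametric trees a Cholesky factorization is taken per lambda.

# ---- internal machinery -----------------------------------------------

.pgls_prep <- function(X, y, V) {
  n <- nrow(X)
  d <- diag(V)
  ultra <- (max(d) - min(d)) <= 1e-8 * mean(d)
  if (ultra) {
    eg <- eigen(V, symmetric = TRUE)
    list(ultra = TRUE, n = n, p = ncol(X),
         U = eg$vectors, ev = pmax(eg$values, 0), d0 = mean(d),
         tX = crossprod(eg$vectors, X), ty = drop(crossprod(eg$vectors, y)),
         X = X, y = y, V = V)
  } else {
    list(ultra = FALSE, n = n, p = ncol(X), D = d, X = X, y = y, V = V)
  }
}

# GLS at fixed lambda; returns beta, RSS in the V-metric, log|V|, profile
# ML log-likelihood, and the unscaled coefficient covariance (X'V^-1X)^-1
.pgls_core <- function(prep, lambda, cols = NULL) {
  n <- prep$n
  if (prep$ultra) {
    tX <- if (is.null(cols)) prep$tX else prep$tX[, cols, drop = FALSE]
    ty <- prep$ty
    w <- lambda * prep$ev + (1 - lambda) * prep$d0
    w <- pmax(w, 1e-12)
    Xw <- tX / w
    A <- crossprod(tX, Xw)
    b <- crossprod(Xw, ty)
    Ainv <- tryCatch(solve(A), error = function(e)
      stop("singular design in GLS (collinearity?)"))
    beta <- drop(Ainv %*% b)
    r <- ty - drop(tX %*% beta)
    rss <- sum(r^2 / w)
    logdet <- sum(log(w))
  } else {
    X <- if (is.null(cols)) prep$X else prep$X[, cols, drop = FALSE]
    Vl <- .lambda_V(prep$V, lambda)
    R <- chol(Vl)
    wX <- backsolve(R, X, transpose = TRUE)
    wy <- backsolve(R, prep$y, transpose = TRUE)
    A <- crossprod(wX)
    Ainv <- tryCatch(solve(A), error = function(e)
      stop("singular design in GLS (collinearity?)"))
    beta <- drop(Ainv %*% crossprod(wX, wy))
    r <- wy - drop(wX %*% beta)
    rss <- sum(r^2)
    logdet <- 2 * sum(log(diag(R)))
  }
  sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(beta = beta, rss = rss, logdet = logdet, logLik = ll,
       sigma2_ml = sigma2, Ainv = Ainv)
}

# profile lambda-hat: 101-point grid then bounded scalar refinement
.pgls_profile_lambda <- function(prep, cols = NULL, grid_n = 101L) {
  grid <- seq(0, 1, length.out = grid_n)
  ll <- vapply(grid, function(l) .pgls_core(prep, l, cols)$logLik, 0)
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_n, i + 1L)]
  opt <- stats::optimize(function(l) .pgls_core(prep, l, cols)$logLik,
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-8)
  if (opt$objective >= ll[i]) opt$maximum else grid[i]
}

.check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop(errorCondition(
      paste0("rank-deficient design; aliased term(s): ",
             paste(aliased, collapse = ", ")),
      class = c("squamorph_collinearity", "error", "condition")))
  }
}

# align a covariance object/matrix/tree to the data's species order
.align_cov <- function(phy, species) {
  if (inherits(phy, "phylo")) phy <- phylo_vcv(prune_phylogeny(phy, species))
  if (is.matrix(phy)) phy <- structure(list(taxa = rownames(phy), V = phy,
                                            lambda = 1), class = "phylo_cov")
  stopifnot(inherits(phy, "phylo_cov"))
  sn <- .normalize_labels(species)
  tn <- .normalize_labels(phy$taxa)
  if (anyDuplicated(sn)) stop("duplicate species in trait table")
  miss <- species[!sn %in% tn]
  if (length(miss))
    stop(errorCondition(
      paste0("species not in covariance/tree: ", paste(miss, collapse = ", ")),
      class = c("squamorph_taxa_mismatch", "error", "condition")))
  idx <- match(sn, tn)
  V <- phy$V[idx, idx, drop = FALSE]
  dimnames(V) <- list(species, species)
  structure(list(taxa = species, V = V, lambda = phy$lambda),
            class = "phylo_cov")
}

# ---- user-facing fits --------------------------------------------------

#' Fit a phylogenetic generalized least squares regression
#'
#' Fits `formula` by GLS with residual covariance `sigma^2 * V(lambda)`,
#' where `V` is the Brownian-motion covariance of the phylogeny and
#' `lambda` scales the off-diagonal entries (Pagel's lambda). By default
#' `lambda` is estimated by maximum likelihood, profile-optimized on
#' `[0, 1]` (101-point grid plus bounded refinement). Coefficients at the
#' optimum are exact GLS via a triangular/eigen factorization of
#' `V(lambda)`.
#'
#' @param formula Model formula on columns of `data` (traits are expected
#'   on the natural-log scale, e.g. `ln_hbER ~ ln_body_size * ecotype`).
#' @param data Species-level data frame; one row per species.
#' @param phy An `ape::phylo` tree, a `phylo_cov`, or a covariance
#'   matrix with taxa dimnames. Trees are pruned to the data.
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @param species_col Column of `data` holding species identifiers that
#'   match the tree's tip labels.
#' @return An object of class `pgls_fit` with components `coefficients`,
#'   `lambda`, `sigma2` (ML), `sigma2_unbiased`, `logLik`, `vcov`,
#'   `residuals` (response scale, named by species), `fitted`, `R2`,
#'   `adj_R2`, `n`, and fitting metadata used by [bootstrap_cis()] and
#'   [type2_anova()].
#' @export
fit_pgls <- function(formula, data, phy, lambda = "ML",
                     species_col = "species_id") {
  stopifnot(species_col %in% names(data))
  species <- as.character(data[[species_col]])
  cov <- .align_cov(phy, species)
  mf <- stats::model.frame(formula, data)
  if (nrow(mf) != nrow(data))
    stop("missing values in model variables; drop incomplete species first")
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  .check_full_rank(X)
  prep <- .pgls_prep(X, y, cov$V)

  lam <- if (identical(lambda, "ML")) .pgls_profile_lambda(prep)
         else {
           if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
             stop("fixed lambda must lie in [0, 1]")
           lambda
         }
  core <- .pgls_core(prep, lam)
  n <- prep$n; p <- ncol(X)
  names(core$beta) <- colnames(X)
  fitted <- drop(X %*% core$beta)
  resid <- stats::setNames(y - fitted, species)

  has_int <- "(Intercept)" %in% colnames(X)
  rss0 <- if (has_int) {
    .pgls_core(prep, lam, cols = match("(Intercept)", colnames(X)))$rss
  } else sum(if (prep$ultra) prep$ty^2 / (lam * prep$ev + (1 - lam) * prep$d0)
             else {
               R <- chol(.lambda_V(prep$V, lam))
               backsolve(R, y, transpose = TRUE)^2
             })
  R2 <- 1 - core$rss / rss0
  k <- p - as.integer(has_int)
  adj_R2 <- 1 - (1 - R2) * (n - 1) / (n - k - 1)
  s2u <- core$rss / (n - p)

  structure(list(coefficients = core$beta,
                 lambda = lam, lambda_estimated = identical(lambda, "ML"),
                 sigma2 = core$sigma2_ml, sigma2_unbiased = s2u,
                 logLik = core$logLik,
                 vcov = s2u * core$Ainv,
                 residuals = resid, fitted = fitted,
                 R2 = R2, adj_R2 = adj_R2, n = n, p = p,
                 formula = formula, terms = stats::terms(mf),
                 xlevels = stats::.getXlevels(stats::terms(mf), mf),
                 model = mf, X = X, y = y, species = species,
                 prep = prep, cov = cov),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, digits = 4, ...) {
  cat("Phylogenetic GLS (Pagel's lambda)\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d, lambda = %.3f%s, sigma2 = %.4g, logLik = %.3f\n",
              x$n, x$lambda, if (x$lambda_estimated) " (ML)" else " (fixed)",
              x$sigma2, x$logLik))
  cat(sprintf("  R2 = %.3f, adjusted R2 = %.3f\n", x$R2, x$adj_R2))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' @export
residuals.pgls_fit <- function(object, ...) object$residuals

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$logLik, df = object$p + 2, class = "logLik")
}

# ---- ANCOVA (Type II) --------------------------------------------------

#' Type II ANOVA table for a PGLS fit
#'
#' Each term's sum of squares is the whitened residual-SS difference
#' between the model containing all terms that do not contain it and
#' that model plus the term, with `lambda` held at the fitted value.
#' F-ratios use the full model's residual mean square.
#'
#' @param fit A `pgls_fit` from an ANCOVA-style model.
#' @return Data frame with `term`, `df`, `SS`, `F`, `p`.
#' @export
type2_anova <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  tl <- attr(fit$terms, "term.labels")
  if (!length(tl)) stop("model has no non-intercept terms")
  # marginality check: every interaction needs both mains in the model
  for (t in tl) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    if (length(parts) > 1 && !all(parts %in% tl))
      stop(errorCondition(
        paste0("interaction '", t, "' without all its main effects"),
        class = c("squamorph_marginality", "error", "condition")))
  }
  asgn <- attr(fit$X, "assign")
  lam <- fit$lambda
  contains <- function(a, b) { # does term b contain term a?
    pa <- strsplit(a, ":", fixed = TRUE)[[1]]
    pb <- strsplit(b, ":", fixed = TRUE)[[1]]
    all(pa %in% pb)
  }
  rss_for <- function(terms_keep) {
    cols <- which(asgn %in% c(0L, match(terms_keep, tl)))
    .pgls_core(fit$prep, lam, cols = cols)$rss
  }
  full <- .pgls_core(fit$prep, lam)
  df_res <- fit$n - fit$p
  ms_res <- full$rss / df_res
  rows <- lapply(tl, function(t) {
    others <- tl[!vapply(tl, function(b) contains(t, b), TRUE)]
    ss <- rss_for(others) - rss_for(c(others, t))
    df <- sum(asgn == match(t, tl))
    Fv <- (ss / df) / ms_res
    data.frame(term = t, df = df, SS = ss, F = Fv,
               p = stats::pf(Fv, df, df_res, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  attr(out, "df_residual") <- df_res
  attr(out, "SS_residual") <- full$rss
  out
}

# ---- bootstrap ---------------------------------------------------------

# vectorized parametric-bootstrap refits on the rotated (ultrametric)
# scale: one pass over a lambda grid for all replicates, then a bounded
# per-replicate refinement
.boot_refit_ultra <- function(prep, Ystar, grid_n = 101L, refine = TRUE) {
  grid <- seq(0, 1, length.out = grid_n)
  n <- prep$n; B <- ncol(Ystar); p <- prep$p
  best_ll <- rep(-Inf, B); best_lam <- numeric(B)
  best_beta <- matrix(0, p, B)
  for (l in grid) {
    w <- pmax(l * prep$ev + (1 - l) * prep$d0, 1e-12)
    Xw <- prep$tX / w
    A <- crossprod(prep$tX, Xw)
    H <- solve(A, t(Xw))                  # p x n
    Beta <- H %*% Ystar                   # p x B
    Res <- Ystar - prep$tX %*% Beta
    rss <- colSums(Res^2 / w)
    ll <- -0.5 * (n * log(2 * pi * rss / n) + sum(log(w)) + n)
    upd <- ll > best_ll
    if (any(upd)) {
      best_ll[upd] <- ll[upd]
      best_lam[upd] <- l
      best_beta[, upd] <- Beta[, upd, drop = FALSE]
    }
  }
  if (refine) {
    step <- 1 / (grid_n - 1)
    for (b in seq_len(B)) {
      yb <- Ystar[, b]
      f <- function(l) {
        w <- pmax(l * prep$ev + (1 - l) * prep$d0, 1e-12)
        Xw <- prep$tX / w
        beta <- solve(crossprod(prep$tX, Xw), crossprod(Xw, yb))
        r <- yb - drop(prep$tX %*% beta)
        -0.5 * (n * log(2 * pi * sum(r^2 / w) / n) + sum(log(w)) + n)
      }
      opt <- stats::optimize(f, lower = max(0, best_lam[b] - step),
                             upper = min(1, best_lam[b] + step),
                             maximum = TRUE, tol = 1e-6)
      if (opt$objective > best_ll[b]) {
        best_ll[b] <- opt$objective
        best_lam[b] <- opt$maximum
        w <- pmax(opt$maximum * prep$ev + (1 - opt$maximum) * prep$d0, 1e-12)
        Xw <- prep$tX / w
        best_beta[, b] <- solve(crossprod(prep$tX, Xw), crossprod(Xw, yb))
      }
    }
  }
  list(beta = t(best_beta), lambda = best_lam, logLik = best_ll)
}

#' Parametric bootstrap confidence intervals for a PGLS fit
#'
#' Simulates `n_reps` response vectors from the fitted model
#' (`N(X beta, sigma2 * V(lambda))`, with the unbiased residual-variance
#' estimate, which avoids the `(n - p)/n` CI shrinkage the ML variance
#' would cause), refits the full model -- including
#' re-estimation of lambda -- to each, and returns percentile 95%
#' confidence intervals of every coefficient. When the model contains a
#' size-by-group interaction, per-group slopes and their intervals are
#' derived from replicate-level coefficient sums (see
#' [per_group_slopes()]).
#'
#' @param fit A `pgls_fit`.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param level Confidence level (default 0.95).
#' @param groups Optional list `list(size = , group = )` naming the
#'   continuous size variable and grouping factor for per-group slopes;
#'   auto-detected from the formula when `NULL`.
#' @return An object of class `pgls_boot`: replicate coefficient matrix,
#'   percentile CIs, per-group slope replicates and CIs (if applicable),
#'   `n_reps`, `seed`.
#' @export
bootstrap_cis <- function(fit, n_reps = 1000, seed = 1, level = 0.95,
                          groups = NULL) {
  stopifnot(inherits(fit, "pgls_fit"))
  set.seed(as.integer(seed))
  prep <- fit$prep
  n <- fit$n
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)

  # simulate with the unbiased variance estimate: the ML variance is low
  # by (n - p)/n, which systematically shrinks percentile CIs
  s2 <- fit$sigma2_unbiased
  if (prep$ultra) {
    # simulate directly on the rotated scale: rotated noise is independent
    # with variance sigma2 * (lambda*ev + (1-lambda)*d0)
    w <- pmax(fit$lambda * prep$ev + (1 - fit$lambda) * prep$d0, 0)
    mu <- drop(prep$tX %*% fit$coefficients)
    noise_sd <- sqrt(s2 * w)
    Ystar <- mu + matrix(stats::rnorm(n * n_reps), n, n_reps) * noise_sd
    rf <- .boot_refit_ultra(prep, Ystar)
    beta_rep <- rf$beta
    lam_rep <- rf$lambda
  } else {
    Vl <- .lambda_V(fit$cov$V, fit$lambda)
    L <- t(chol(s2 * Vl + diag(1e-12, n)))
    mu <- fit$fitted
    beta_rep <- matrix(NA_real_, n_reps, fit$p)
    lam_rep <- numeric(n_reps)
    for (b in seq_len(n_reps)) {
      ystar <- mu + drop(L %*% stats::rnorm(n))
      pr <- .pgls_prep(fit$X, ystar, fit$cov$V)
      lam <- .pgls_profile_lambda(pr, grid_n = 21L)
      core <- .pgls_core(pr, lam)
      beta_rep[b, ] <- core$beta
      lam_rep[b] <- lam
    }
  }
  colnames(beta_rep) <- names(fit$coefficients)
  ci <- t(apply(beta_rep, 2, stats::quantile, probs = probs, names = FALSE))
  colnames(ci) <- c("lower", "upper")

  slopes <- NULL
  if (is.null(groups)) groups <- .detect_size_group(fit)
  if (!is.null(groups)) {
    pg <- per_group_slopes(fit, size = groups$size, group = groups$group)
    srep <- beta_rep %*% pg$contrasts          # n_reps x n_groups
    sci <- t(apply(srep, 2, stats::quantile, probs = probs, names = FALSE))
    colnames(sci) <- c("lower", "upper")
    slopes <- list(point = pg$slopes, replicates = srep, ci = sci,
                   replicate_mean = colMeans(srep))
  }
  structure(list(n_reps = n_reps, seed = seed, level = level,
                 coefficients = fit$coefficients,
                 replicates = beta_rep, lambda_replicates = lam_rep,
                 ci = ci, group_slopes = slopes),
            class = "pgls_boot")
}

#' @export
print.pgls_boot <- function(x, digits = 3, ...) {
  cat(sprintf("Parametric bootstrap: %d replicates (seed %d), %.0f%% percentile CIs\n",
              x$n_reps, x$seed, 100 * x$level))
  tab <- cbind(estimate = x$coefficients, x$ci)
  print(round(tab, digits))
  if (!is.null(x$group_slopes)) {
    cat("Per-group slopes:\n")
    print(round(cbind(slope = x$group_slopes$point, x$group_slopes$ci), digits))
  }
  invisible(x)
}

# find a continuous x factor interaction in the fitted terms
.detect_size_group <- function(fit) {
  tl <- attr(fit$terms, "term.labels")
  ints <- tl[grepl(":", tl, fixed = TRUE)]
  for (t in ints) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) next
    fac <- parts[parts %in% names(fit$xlevels)]
    con <- setdiff(parts, fac)
    if (length(fac) == 1 && length(con) == 1)
      return(list(size = con, group = fac))
  }
  NULL
}

#' Per-group allometric slopes from an interaction model
#'
#' For a fit of the form `y ~ size * group` (treatment contrasts), the
#' reference group's slope is the `size` coefficient and every other
#' group's slope adds its interaction coefficient.
#'
#' @param fit A `pgls_fit` containing a `size:group` interaction.
#' @param size,group Variable names; auto-detected when omitted.
#' @return List with `slopes` (named numeric) and `contrasts` (a
#'   coefficient-by-group matrix such that `t(contrasts) %*% coef` gives
#'   the slopes; used to propagate bootstrap replicates).
#' @export
per_group_slopes <- function(fit, size = NULL, group = NULL) {
  stopifnot(inherits(fit, "pgls_fit"))
  if (is.null(size) || is.null(group)) {
    sg <- .detect_size_group(fit)
    if (is.null(sg))
      stop(errorCondition("model has no size-by-group interaction term",
                          class = c("squamorph_contract", "error", "condition")))
    size <- sg$size; group <- sg$group
  }
  lv <- fit$xlevels[[group]]
  if (is.null(lv)) stop("'", group, "' is not a factor in the model")
  cn <- names(fit$coefficients)
  if (!size %in% cn) stop("'", size, "' coefficient not found")
  contr <- matrix(0, length(cn), length(lv), dimnames = list(cn, lv))
  contr[size, ] <- 1
  for (g in lv[-1]) {
    cand <- c(paste0(size, ":", group, g), paste0(group, g, ":", size))
    hit <- cand[cand %in% cn]
    if (!length(hit))
      stop(errorCondition(
        paste0("no interaction coefficient for group '", g, "'"),
        class = c("squamorph_contract", "error", "condition")))
    contr[hit[1], g] <- 1
  }
  list(slopes = drop(crossprod(contr, fit$coefficients)), contrasts = contr)
}

# ---- allometry classification and slope comparison ---------------------

#' Classify allometry from a slope confidence interval
#'
#' For a dimensionless shape ratio regressed on ln size, isometry is a
#' slope of zero: a CI entirely above the isometric slope is positive
#' allometry, entirely below is negative, otherwise not significant.
#'
#' @param slope Point estimate.
#' @param ci Length-2 numeric `c(lower, upper)`.
#' @param isometric_slope Isometry reference (default 0).
#' @return List (class `allometry_call`) with `slope`, `ci`,
#'   `isometric_slope`, and `call` in
#'   `{"positive", "negative", "not_significant"}`.
#' @export
classify_allometry <- function(slope, ci, isometric_slope = 0) {
  stopifnot(length(ci) == 2, ci[1] <= ci[2])
  call <- if (ci[1] > isometric_slope) "positive"
          else if (ci[2] < isometric_slope) "negative"
          else "not_significant"
  structure(list(slope = slope, ci = ci, isometric_slope = isometric_slope,
                 call = call),
            class = "allometry_call")
}

#' @export
print.allometry_call <- function(x, ...) {
  cat(sprintf("slope %.3f [%.3f:%.3f] vs isometry %.3g -> %s\n",
              x$slope, x$ci[1], x$ci[2], x$isometric_slope, x$call))
  invisible(x)
}

#' Compare per-group slopes via CI exclusion
#'
#' Two groups are flagged as different under the symmetric rule when each
#' group's slope lies outside the other's 95% CI; the one-directional
#' rule (row group's slope outside column group's CI) is also reported.
#'
#' @param slopes Named numeric vector of group slopes.
#' @param cis Matrix with rows named like `slopes` and columns
#'   `lower`, `upper`.
#' @return List with logical matrices `different` (symmetric) and
#'   `one_way` (`[g, h]`: slope of g outside CI of h).
#' @export
compare_group_slopes <- function(slopes, cis) {
  g <- names(slopes)
  stopifnot(!is.null(g), all(g %in% rownames(cis)))
  one <- outer(g, g, Vectorize(function(a, b)
    slopes[[a]] < cis[b, "lower"] || slopes[[a]] > cis[b, "upper"]))
  dimnames(one) <- list(g, g)
  diag(one) <- FALSE
  list(different = one & t(one), one_way = one)
}

# ---- size correction and group means -----------------------------------

#' Phylogenetic size correction of a trait
#'
#' Returns the residuals of a PGLS regression of `trait` on `size`
#' (both ln scale), i.e. the trait with allometric scaling removed. The
#' residuals satisfy the GLS normal equations `X' V(lambda)^-1 e = 0`.
#'
#' @param data Species trait data frame.
#' @param trait,size Column names (ln scale).
#' @param phy Tree / covariance as in [fit_pgls()].
#' @param species_col Species identifier column.
#' @return List with `residuals` (named by species) and the underlying
#'   `fit`.
#' @export
size_correct <- function(data, trait, size, phy, species_col = "species_id") {
  f <- stats::reformulate(size, response = trait)
  fit <- fit_pgls(f, data, phy, species_col = species_col)
  list(residuals = fit$residuals, fit = fit)
}

#' Compare group means of a (size-corrected) trait
#'
#' Fits the phylogenetic group-means model `trait ~ 0 + group`, bootstraps
#' the group means, and flags group g as different from group h when g's
#' mean lies outside h's bootstrap CI.
#'
#' @param data Data frame with the trait and group columns.
#' @param trait,group Column names.
#' @param phy Tree / covariance.
#' @param n_reps,seed,level Bootstrap controls.
#' @param species_col Species identifier column.
#' @return List with `means`, `ci`, `different` / `one_way` flag
#'   matrices, the `fit`, and the `boot` object.
#' @export
group_mean_comparison <- function(data, trait, group, phy,
                                  n_reps = 1000, seed = 1, level = 0.95,
                                  species_col = "species_id") {
  sizes <- table(data[[group]])
  if (length(sizes) < 2) stop("need >= 2 groups")
  if (any(sizes < 2))
    warning("singleton group(s): ",
            paste(names(sizes)[sizes < 2], collapse = ", "),
            "; their CIs are unreliable")
  f <- stats::as.formula(paste(trait, "~ 0 +", group))
  fit <- fit_pgls(f, data, phy, species_col = species_col)
  boot <- bootstrap_cis(fit, n_reps = n_reps, seed = seed, level = level,
                        groups = NULL)
  means <- fit$coefficients
  names(means) <- sub(paste0("^", group), "", names(means))
  ci <- boot$ci
  rownames(ci) <- names(means)
  cmp <- compare_group_slopes(means, ci)
  list(means = means, ci = ci, different = cmp$different,
       one_way = cmp$one_way, fit = fit, boot = boot)
}
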