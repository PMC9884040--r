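# Phylogenetic multiple regression with the randomized residual
# permutation procedure (RRPP): sequential (entry-order) sums of squares
# on phylogenetically whitened data, per-term null distributions built by
# permuting reduced-model residuals, log-F effect sizes (Z), and
# Benjamini-Hochberg adjustment within the model's table.

#' Phylogenetic multiple regression with RRPP
#'
#' The response and design (including the intercept column) are whitened
#' by a triangular factor of the phylogenetic covariance `V(lambda)`
#' (`lambda = 1` by default; the covariance is not re-estimated inside
#' the permutation procedure). Terms are entered in formula order and
#' assessed by sequential SS. For each term, a null distribution of its
#' F statistic is built by permuting the residuals of the reduced model
#' (all preceding terms), adding them back to the reduced fitted values,
#' and recomputing F; the observed statistic is included in its own null,
#' so `p >= 1/(n_iter + 1)`.
#'
#' @param formula Model formula; predictor order fixes the sequential
#'   decomposition.
#' @param data Species-level data frame.
#' @param phy Tree / `phylo_cov` / covariance matrix, or `NULL` for an
#'   identity covariance (ordinary residual permutation).
#' @param lambda Lambda applied to the covariance before whitening
#'   (default 1).
#' @param n_iter Number of random permutations (default 1000).
#' @param seed Integer seed; identical seeds give identical results.
#' @param exact If `TRUE` and `n! <= 40320` (n <= 8), enumerate all
#'   permutations instead of sampling; `n_iter` is ignored.
#' @param species_col Species identifier column (used only when `phy`
#'   is given).
#' @return Object of class `rrpp_result`: `table` (term, df, SS, R2, F,
#'   Z, p_perm, p_adjusted), `SS_total`, `SS_residual`, `df_residual`,
#'   `n_iterations`, `seed`.
#' @export
rrpp_multiple_regression <- function(formula, data, phy = NULL, lambda = 1,
                                     n_iter = 1000, seed = 1, exact = FALSE,
                                     species_col = "species_id") {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  .check_full_rank(X)
  if (!exact && n_iter < 99)
    warning("n_iter < 99 gives a very coarse permutation p-value")

  if (!is.null(phy)) {
    species <- as.character(data[[species_col]])
    cov <- .align_cov(phy, species)
    Vl <- .lambda_V(cov$V, lambda)
    R <- chol(Vl)
    yw <- backsolve(R, y, transpose = TRUE)
    Xw <- backsolve(R, X, transpose = TRUE)
  } else {
    yw <- y
    Xw <- X
  }

  tl <- attr(stats::terms(mf), "term.labels")
  if (!length(tl)) stop("model has no predictors")
  asgn <- attr(X, "assign")
  K <- length(tl)
  # nested model column sets: intercept, +term1, +term1+term2, ...
  cols <- lapply(0:K, function(k) which(asgn <= k))
  Qs <- lapply(cols, function(cc) qr.Q(qr(Xw[, cc, drop = FALSE])))
  rss <- function(Q, Y) {
    Y <- as.matrix(Y)
    colSums(Y^2) - colSums(crossprod(Q, Y)^2)
  }
  rss_obs <- vapply(Qs, function(Q) rss(Q, yw), 0)
  SS_total <- rss_obs[1]
  SS_res <- rss_obs[K + 1]
  df_term <- vapply(seq_len(K), function(k) length(cols[[k + 1]]) - length(cols[[k]]), 0L)
  df_res <- n - length(cols[[K + 1]])
  SS_term <- rss_obs[seq_len(K)] - rss_obs[seq_len(K) + 1]
  F_obs <- (SS_term / df_term) / (SS_res / df_res)

  # permutation indices, shared across terms within an iteration
  set.seed(as.integer(seed))
  if (exact) {
    if (factorial(n) > 40320)
      stop("exact enumeration only supported for n <= 8")
    P <- .all_permutations(n)           # n! columns, identity included
  } else {
    P <- replicate(n_iter, sample.int(n))
  }
  nP <- ncol(P)

  p_perm <- numeric(K)
  Z <- numeric(K)
  eps <- .Machine$double.eps
  for (k in seq_len(K)) {
    Qr <- Qs[[k]]
    fit_red <- Qr %*% crossprod(Qr, yw)
    e_red <- drop(yw - fit_red)
    Ystar <- matrix(e_red[P], n, nP) + drop(fit_red)
    rss_red <- rss(Qr, Ystar)
    rss_k <- rss(Qs[[k + 1]], Ystar)
    rss_full <- rss(Qs[[K + 1]], Ystar)
    F_star <- ((rss_red - rss_k) / df_term[k]) / (rss_full / df_res)
    if (exact) {
      # identity permutation reproduces the observed statistic
      p_perm[k] <- mean(F_star >= F_obs[k] - 1e-12)
      logf <- log(pmax(F_star, eps))
      Z[k] <- (log(pmax(F_obs[k], eps)) - mean(logf)) /
        max(stats::sd(logf), eps)
    } else {
      allF <- c(F_obs[k], F_star)
      p_perm[k] <- mean(allF >= F_obs[k] - 1e-12)
      logf <- log(pmax(allF, eps))
      Z[k] <- (logf[1] - mean(logf)) / max(stats::sd(logf), eps)
    }
  }

  tab <- data.frame(term = tl, df = df_term, SS = SS_term,
                    R2 = SS_term / SS_total, F = F_obs, Z = Z,
                    p_perm = p_perm,
                    p_adjusted = bh_adjust(p_perm))
  structure(list(table = tab, SS_total = SS_total, SS_residual = SS_res,
                 df_residual = df_res,
                 R2_residual = SS_res / SS_total,
                 n_iterations = if (exact) nP else n_iter,
                 exact = exact, seed = seed),
            class = "rrpp_result")
}

.all_permutations <- function(n) {
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v))
    do.call(cbind, lapply(seq_along(v), function(i)
      rbind(v[i], perms(v[-i]))))
  }
  perms(seq_len(n))
}

#' @export
print.rrpp_result <- function(x, digits = 4, ...) {
  cat(sprintf("RRPP multiple regression: %d iterations%s (seed %d)\n",
              x$n_iterations, if (x$exact) " (exhaustive)" else "", x$seed))
  tab <- x$table
  tab[, -1] <- lapply(tab[, -1], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  cat(sprintf("Residual SS %.4g (df %d), Total SS %.4g\n",
              x$SS_residual, x$df_residual, x$SS_total))
  invisible(x)
}

#' Rank model terms by explained variance
#'
#' Orders the terms of an RRPP table by descending R-squared; ties keep
#' the model's entry order (and are reported via a message).
#'
#' @param result An `rrpp_result`.
#' @return Data frame `term`, `R2`, sorted.
#' @export
rank_components <- function(result) {
  stopifnot(inherits(result, "rrpp_result"))
  tab <- result$table
  o <- order(-tab$R2)   # stable: ties keep entry order
  if (anyDuplicated(tab$R2))
    message("tied R2 values; ties broken by term entry order")
  data.frame(term = tab$term[o], R2 = tab$R2[o])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate adjustment: with p-values ranked
#' ascending, `p_adj(i) = min_{j >= i} (m / j) * p(j)`, capped at 1;
#' input order is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))
  adj[ro]
}
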