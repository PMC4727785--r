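#' Pearson correlation on pairwise-complete cases
#'
#' Product-moment correlation with a two-tailed p-value from the t
#' distribution with n - 2 degrees of freedom, computed on the cases where
#' both variables are observed.
#'
#' @param x,y numeric vectors of equal length; `NA`s allowed.
#' @return List with `r`, `n` (pairwise-complete count) and `p`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 pairwise-complete cases")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, n = n, p = p)
}

#' Partial correlation controlling for one or two covariates
#'
#' Correlation of the least-squares residuals of `x` and `y` after
#' regressing each on the covariate set (complete cases across all
#' variables involved). Identical to the recursive first/second-order
#' partial-correlation formulas. The p-value uses n - 2 - k degrees of
#' freedom, k the number of covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric vector, matrix or data frame of covariates;
#'   `NULL` or zero columns reduces to [pearson()].
#' @return List with `r`, `n`, `df`, `p`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    out <- pearson(x, y)
    return(list(r = out$r, n = out$n, df = out$n - 2, p = out$p))
  }
  Z <- as.matrix(as.data.frame(covariates))
  if (ncol(Z) == 0) {
    out <- pearson(x, y)
    return(list(r = out$r, n = out$n, df = out$n - 2, p = out$p))
  }
  stopifnot(length(x) == length(y), nrow(Z) == length(x))
  ok <- stats::complete.cases(x, y, Z)
  n <- sum(ok)
  k <- ncol(Z)
  if (n < k + 4) stop("need at least ", k + 4, " complete cases")
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  X <- cbind(1, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("collinear covariates")
  rx <- stats::residuals(stats::lm.fit(X, x))
  ry <- stats::residuals(stats::lm.fit(X, y))
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero residual variance")
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tval), df = df)
  }
  list(r = r, n = n, df = df, p = p)
}

#' Fisher r-to-Z transform
#'
#' The variance-stabilizing transform `z = arctanh(r)`.
#'
#' @param r correlation, strictly inside (-1, 1).
#' @return The transformed value.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  atanh(r)
}

#' Williams's test for two dependent correlations sharing one variable
#'
#' Tests whether r12 and r13 differ, given the correlation r23 between the
#' two non-shared variables, using Williams's t (Steiger's T2 form) with
#' n - 3 degrees of freedom. Because the source literature on this design
#' reports Z statistics under the same name, Steiger's Z (on
#' Fisher-transformed correlations, with the pooled-correlation covariance
#' term) is returned alongside.
#'
#' @param r12,r13 the two dependent correlations (variable 1 shared).
#' @param r23 correlation between variables 2 and 3.
#' @param n sample size (at least 4).
#' @return List with `t`, `df`, `p` (Williams's t) and `z`, `p_z`
#'   (Steiger's Z), all two-tailed.
#' @export
williams_t <- function(r12, r13, r23, n) {
  stopifnot(n >= 4, abs(r12) <= 1, abs(r13) <= 1, abs(r23) <= 1)
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR < -1e-10)
    stop("the correlation triple is not positive semi-definite")
  detR <- max(detR, 0)
  rbar <- (r12 + r13) / 2
  denom <- 2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3
  tval <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  df <- n - 3
  p <- 2 * stats::pt(-abs(tval), df = df)

  rbar2 <- rbar^2
  psi <- r23 * (1 - 2 * rbar2) - 0.5 * rbar2 * (1 - 2 * rbar2 - r23^2)
  cov_z <- psi / (1 - rbar2)^2
  z12 <- atanh(min(max(r12, -1 + 1e-12), 1 - 1e-12))
  z13 <- atanh(min(max(r13, -1 + 1e-12), 1 - 1e-12))
  zval <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * cov_z))
  p_z <- 2 * stats::pnorm(-abs(zval))
  list(t = tval, df = df, p = p, z = zval, p_z = p_z)
}

#' Paired-samples t test
#'
#' One-sample t on the paired differences with n - 1 degrees of freedom.
#' Constant nonzero differences are reported as an infinite statistic with
#' p = 0 rather than an error.
#'
#' @param x,y numeric vectors of equal length (n >= 2); pairs with missing
#'   values are dropped.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1
  if (s == 0) {
    if (m == 0) return(list(t = 0, df = df, p = 1, mean_diff = 0))
    return(list(t = sign(m) * Inf, df = df, p = 0, mean_diff = m))
  }
  tval <- m / (s / sqrt(n))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df = df),
       mean_diff = m)
}

#' Standardized-residual outlier screen for a correlation
#'
#' Fits the simple regression of `y` on `x` and standardizes the residuals
#' by the root mean squared error; cases beyond +/-1.96 are flagged. A
#' perfectly linear relation yields no flags.
#'
#' @param x,y numeric vectors (n >= 3, complete cases used).
#' @param threshold flag limit on |standardized residual|.
#' @return Data frame with `index` (position in the input), `residual`,
#'   `z`, `flag`.
#' @export
outlier_screen <- function(x, y, threshold = 1.96) {
  stopifnot(length(x) == length(y))
  ok <- which(stats::complete.cases(x, y))
  n <- length(ok)
  if (n < 3) stop("need at least 3 complete cases")
  fit <- stats::lm.fit(cbind(1, x[ok]), y[ok])
  e <- fit$residuals
  mse <- sum(e^2) / (n - 2)
  z <- if (mse < 1e-20) rep(0, n) else e / sqrt(mse)
  data.frame(index = ok, residual = e, z = z,
             flag = abs(z) > threshold)
}

#' Run the full correlation battery on a score table
#'
#' Bivariate Pearson correlations of the gating ratio with every task index
#' and covariate (pairwise deletion, so each pair keeps its own n), partial
#' correlations controlling fluid intelligence, working memory, and both
#' (listwise across the involved variables), Williams's t comparisons of
#' the dependent correlations among the significantly correlated measures,
#' and a standardized-residual outlier screen per significant pair.
#'
#' @param scores data frame with a `gating_ratio` column and any subset of
#'   the other [measure_names()] columns (`iq` and `ospan` needed for the
#'   partial correlations).
#' @param config pipeline configuration (significance level, optional
#'   multiplicity adjustment for the bivariate p-values).
#' @return A `correlation_report`: list of data frames `bivariate`,
#'   `partial`, `williams`, `outliers`.
#' @export
correlation_battery <- function(scores, config = default_config()) {
  stopifnot("gating_ratio" %in% names(scores))
  gate <- scores$gating_ratio
  vars <- intersect(setdiff(measure_names(), "gating_ratio"),
                    names(scores))
  alpha <- config$stats$alpha

  biv <- do.call(rbind, lapply(vars, function(v) {
    res <- tryCatch(pearson(gate, scores[[v]]), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(measure = v, r = res$r, n = res$n, p = res$p,
               stringsAsFactors = FALSE)
  }))
  if (config$stats$p_adjust != "none")
    biv$p_adjusted <- stats::p.adjust(biv$p, method = config$stats$p_adjust)

  covsets <- list(iq = "iq", ospan = "ospan", both = c("iq", "ospan"))
  part <- NULL
  for (set_name in names(covsets)) {
    cv <- covsets[[set_name]]
    if (!all(cv %in% names(scores))) next
    tasks <- setdiff(vars, cv)
    rows <- lapply(tasks, function(v) {
      res <- tryCatch(
        partial_corr(gate, scores[[v]], scores[, cv, drop = FALSE]),
        error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(measure = v, controlling = set_name, r = res$r,
                 n = res$n, df = res$df, p = res$p,
                 stringsAsFactors = FALSE)
    })
    part <- rbind(part, do.call(rbind, rows))
  }

  sig <- biv$measure[biv$p < alpha]
  wil <- NULL
  if (length(sig) >= 2) {
    pairs <- utils::combn(sig, 2)
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      v2 <- pairs[1, j]; v3 <- pairs[2, j]
      ok <- stats::complete.cases(gate, scores[[v2]], scores[[v3]])
      n <- sum(ok)
      if (n < 4) return(NULL)
      r12 <- stats::cor(gate[ok], scores[[v2]][ok])
      r13 <- stats::cor(gate[ok], scores[[v3]][ok])
      r23 <- stats::cor(scores[[v2]][ok], scores[[v3]][ok])
      w <- williams_t(r12, r13, r23, n)
      data.frame(measure_a = v2, measure_b = v3,
                 r_gate_a = r12, r_gate_b = r13, r_ab = r23, n = n,
                 t = w$t, df = w$df, p = w$p, z = w$z, p_z = w$p_z,
                 stringsAsFactors = FALSE)
    })
    wil <- do.call(rbind, rows)
  }

  outl <- do.call(rbind, lapply(sig, function(v) {
    sc <- outlier_screen(gate, scores[[v]])
    if (!any(sc$flag)) return(NULL)
    cbind(measure = v, sc[sc$flag, , drop = FALSE])
  }))

  structure(list(bivariate = biv, partial = part, williams = wil,
                 outliers = outl, alpha = alpha),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report>\n\nBivariate correlations with the gating ratio:\n")
  b <- x$bivariate
  b$r <- round(b$r, 3)
  b$p <- signif(b$p, 3)
  print(b, row.names = FALSE)
  if (!is.null(x$partial)) {
    cat("\nPartial correlations (r by covariate set):\n")
    wide <- stats::reshape(
      x$partial[, c("measure", "controlling", "r")],
      direction = "wide", idvar = "measure", timevar = "controlling")
    names(wide) <- sub("^r\\.", "r|", names(wide))
    wide[-1] <- lapply(wide[-1], round, 3)
    print(wide, row.names = FALSE)
  }
  if (!is.null(x$williams)) {
    cat("\nWilliams comparisons of dependent correlations:\n")
    w <- x$williams
    w[c("r_gate_a", "r_gate_b", "r_ab", "t", "z")] <-
      lapply(w[c("r_gate_a", "r_gate_b", "r_ab", "t", "z")], round, 3)
    w[c("p", "p_z")] <- lapply(w[c("p", "p_z")], signif, 3)
    print(w, row.names = FALSE)
  }
  n_flag <- if (is.null(x$outliers)) 0 else nrow(x$outliers)
  cat("\nOutlier screen: ", n_flag,
      " standardized residual(s) beyond +/-1.96\n", sep = "")
  invisible(x)
}
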