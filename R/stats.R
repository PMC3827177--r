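#' Within-subject statistics
#'
#' Repeated-measures ANOVA (fully within-subject, up to three factors) with
#' Greenhouse-Geisser sphericity correction, Tukey HSD / Fisher LSD
#' post-hocs on the matching subject-by-effect error term, paired Wilcoxon
#' signed-rank, permutation Spearman correlation, and ordinary least-squares
#' multiple regression of band power on stimulus descriptors.
#'
#' @name stats_inference
NULL

# orthonormal contrast matrix (k x (k-1)) for a k-level factor
orthonormal_contrasts <- function(k) {
  qr.Q(qr(stats::contr.helmert(k)))
}

# wide subject x cell matrix; cells ordered so factor 1 varies fastest
rm_wide <- function(data, dv, subject, within) {
  for (f in c(subject, within)) data[[f]] <- factor(data[[f]])
  levs <- lapply(within, function(f) levels(data[[f]]))
  names(levs) <- within
  cells <- do.call(expand.grid,
                   c(levs, list(KEEP.OUT.ATTRS = FALSE,
                                stringsAsFactors = FALSE)))
  subj <- levels(data[[subject]])
  key <- do.call(paste, c(lapply(within, function(f) as.character(data[[f]])),
                          list(sep = "\r")))
  cell_key <- do.call(paste, c(lapply(cells, as.character), list(sep = "\r")))
  y <- matrix(NA_real_, length(subj), nrow(cells),
              dimnames = list(subj, cell_key))
  idx <- cbind(match(as.character(data[[subject]]), subj),
               match(key, cell_key))
  if (anyNA(idx)) stop("unexpected factor levels")
  counts <- matrix(0L, length(subj), nrow(cells))
  for (i in seq_len(nrow(data))) {
    counts[idx[i, 1], idx[i, 2]] <- counts[idx[i, 1], idx[i, 2]] + 1L
    y[idx[i, 1], idx[i, 2]] <- data[[dv]][i]
  }
  if (any(counts != 1L)) {
    bad <- which(counts != 1L, arr.ind = TRUE)
    stop("design is not balanced/complete: subject ", subj[bad[1, 1]],
         " has ", counts[bad[1, 1], bad[1, 2]], " observation(s) in cell '",
         gsub("\r", ":", cell_key[bad[1, 2]]), "'")
  }
  list(y = y, cells = cells, levs = levs)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' All factors are within-subject; every main effect and interaction is
#' tested against its own effect-by-subject error term. The
#' Greenhouse-Geisser epsilon of each effect is computed from the covariance
#' of its orthonormal contrast scores (epsilon = 1 for single-df effects, so
#' the corrected p equals the raw p for two-level factors).
#'
#' @param data long-format data.frame with one row per subject x cell.
#' @param dv name of the dependent-variable column.
#' @param subject name of the subject identifier column.
#' @param within character vector of 1-3 within-subject factor names.
#' @return object of class `rm_anova`: data.frame with one row per effect
#'   (effect, df1, df2, F, p, epsilon, p_gg, ms_error) plus attributes
#'   `cell_means` and `design` used by [posthoc].
#' @export
rm_anova <- function(data, dv, subject, within) {
  stopifnot(length(within) >= 1, length(within) <= 3)
  w <- rm_wide(data, dv, subject, within)
  y <- w$y
  n <- nrow(y)
  if (n < 2) stop("need at least 2 subjects")
  k <- vapply(w$levs, length, 0L)
  # sums of squares below this are floating-point dust from constant data
  ss_tol <- 1e-12 * max(sum((y - mean(y))^2), .Machine$double.eps)
  effects <- unlist(lapply(seq_along(within), function(m)
    utils::combn(within, m, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(effects, function(eff) {
    mats <- lapply(within, function(f) {
      kk <- k[[f]]
      if (f %in% eff) orthonormal_contrasts(kk)
      else matrix(1 / kk, kk, 1)
    })
    # cells were built with factor 1 varying fastest -> kron in reverse order
    m <- Reduce(`%x%`, rev(mats))
    z <- y %*% m
    d <- ncol(z)
    zbar <- colMeans(z)
    ss_eff <- n * sum(zbar^2)
    resid <- sweep(z, 2, zbar)
    ss_err <- sum(resid^2)
    if (ss_eff < ss_tol) ss_eff <- 0
    if (ss_err < ss_tol) ss_err <- 0
    df1 <- d
    df2 <- d * (n - 1)
    fval <- if (ss_err > 0) (ss_eff / df1) / (ss_err / df2)
      else if (ss_eff == 0) 0 else Inf
    if (d > 1) {
      s <- stats::cov(z)
      eps <- sum(diag(s))^2 / (d * sum(s * s))
      if (!is.finite(eps)) eps <- 1     # zero-variance contrast scores
      eps <- min(1, max(1 / d, eps))
    } else eps <- 1
    data.frame(effect = paste(eff, collapse = ":"),
               df1 = df1, df2 = df2, F = fval,
               p = stats::pf(fval, df1, df2, lower.tail = FALSE),
               epsilon = eps,
               p_gg = stats::pf(fval, eps * df1, eps * df2,
                                lower.tail = FALSE),
               ms_error = ss_err / df2)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rm_anova", "data.frame")
  attr(out, "design") <- list(y = y, cells = w$cells, levs = w$levs,
                              within = within, n = n)
  cm <- stats::aggregate(data[[dv]],
                         by = lapply(within, function(f) data[[f]]),
                         FUN = mean)
  names(cm) <- c(within, "mean")
  attr(out, "cell_means") <- cm
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (Greenhouse-Geisser corrected)\n")
  df <- as.data.frame(x)
  df$F <- round(df$F, 3)
  df$p <- signif(df$p, 3)
  df$epsilon <- round(df$epsilon, 3)
  df$p_gg <- signif(df$p_gg, 3)
  df$ms_error <- signif(df$ms_error, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Post-hoc pairwise comparisons for a within-subject effect
#'
#' Compares the cell means of the named effect (means over subjects and over
#' the levels of any other factors) using the effect-by-subject interaction
#' error term. Tukey HSD uses the studentized range; Fisher LSD uses a
#' t test on the same error term (so LSD p-values are never larger than HSD
#' p-values for the same contrast).
#'
#' @param fit an [rm_anova] result.
#' @param effect character vector of factor names defining the cells (e.g.
#'   `c("humanness", "gradient")`).
#' @param method `"tukey_hsd"` or `"fisher_lsd"`.
#' @return data.frame: cell_a, cell_b, diff, se, statistic, p.
#' @export
posthoc <- function(fit, effect, method = c("tukey_hsd", "fisher_lsd")) {
  method <- match.arg(method)
  des <- attr(fit, "design")
  if (is.null(des)) stop("fit lacks design information")
  stopifnot(all(effect %in% des$within))
  # subject x effect-cell means, averaging over the other factors
  cells <- des$cells
  grp <- do.call(paste, c(lapply(effect, function(f) as.character(cells[[f]])),
                          list(sep = ":")))
  ug <- unique(grp)
  yp <- vapply(ug, function(g)
    rowMeans(des$y[, grp == g, drop = FALSE]), numeric(des$n))
  n <- nrow(yp); m <- ncol(yp)
  if (m < 2) stop("effect has fewer than 2 cells")
  gm <- mean(yp)
  ss_err <- sum((yp - outer(rowMeans(yp), rep(1, m)) -
                   outer(rep(1, n), colMeans(yp)) + gm)^2)
  df_err <- (n - 1) * (m - 1)
  ms_err <- ss_err / df_err
  means <- colMeans(yp)
  pairs <- utils::combn(m, 2)
  out <- data.frame(
    cell_a = ug[pairs[1, ]], cell_b = ug[pairs[2, ]],
    diff = means[pairs[1, ]] - means[pairs[2, ]]
  )
  if (method == "tukey_hsd") {
    out$se <- sqrt(ms_err / n)
    out$statistic <- abs(out$diff) / out$se
    out$p <- stats::ptukey(out$statistic, m, df_err, lower.tail = FALSE)
  } else {
    out$se <- sqrt(2 * ms_err / n)
    out$statistic <- out$diff / out$se
    out$p <- 2 * stats::pt(abs(out$statistic), df_err, lower.tail = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (standard signed-rank practice); the p-value
#' is exact for up to 25 non-zero pairs without ties. If every difference is
#' zero the test is degenerate and returns W = 0, p = 1 with a warning.
#'
#' @param x,y paired samples (n >= 5).
#' @return list with `W` (sum of positive-difference ranks), `p`, `n_nonzero`.
#' @export
wilcoxon_paired <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need at least 5 pairs")
  d <- x - y
  nz <- sum(d != 0)
  if (nz == 0) {
    warning("all paired differences are zero; no evidence of an effect")
    return(list(W = 0, p = 1, n_nonzero = 0L))
  }
  res <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = nz <= 25))
  list(W = unname(res$statistic), p = res$p.value, n_nonzero = nz)
}

#' Spearman correlation with a seeded permutation p-value
#'
#' Rank correlation with midranks for ties; the two-sided p-value is
#' estimated by randomly permuting one variable (`(1 + #{|rho*| >= |rho|}) /
#' (n_perm + 1)`).
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @param n_perm number of permutations (default 10000).
#' @param rng_seed seed for the permutations.
#' @return list with `rho`, `p`, `n`, `n_perm`.
#' @export
spearman_perm <- function(x, y, n_perm = 10000L, rng_seed = 1L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  rxc <- (rx - mean(rx)) / stats::sd(rx)
  ryc <- (ry - mean(ry)) / stats::sd(ry)
  obs <- abs(sum(rxc * ryc) / (n - 1))
  count <- with_seed(rng_seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      r <- abs(sum(rxc * ryc[sample.int(n)]) / (n - 1))
      if (r >= obs - 1e-12) hits <- hits + 1L
    }
    hits
  })
  list(rho = rho, p = (1 + count) / (n_perm + 1), n = n, n_perm = n_perm)
}

#' Multiple regression of band power on stimulus descriptors
#'
#' Ordinary least squares of a per-stimulus response (e.g. mean band power)
#' on per-stimulus acoustic descriptors, with the overall F test and
#' per-coefficient t tests.
#'
#' @param descriptors data.frame of predictors (one row per stimulus).
#' @param response numeric vector, one value per stimulus.
#' @param kappa_warn condition-number threshold for a collinearity warning
#'   (default 30, on the scaled design).
#' @return list: r_squared, F, df1, df2, p, coefficients (data.frame with
#'   estimate, t, p per predictor).
#' @export
feature_regression <- function(descriptors, response, kappa_warn = 30) {
  stopifnot(is.data.frame(descriptors))
  n <- nrow(descriptors)
  if (n < 10) stop("need at least 10 stimuli")
  if (length(response) != n) stop("response length mismatch")
  X <- as.matrix(descriptors)
  if (kappa(scale(X), exact = TRUE) > kappa_warn)
    warning("collinear design: condition number exceeds ", kappa_warn)
  fit <- stats::lm(response ~ ., data = cbind(descriptors, response = response))
  sm <- summary(fit)
  fstat <- sm$fstatistic
  coefs <- stats::coef(sm)
  list(
    r_squared = sm$r.squared,
    F = unname(fstat[1]), df1 = unname(fstat[2]), df2 = unname(fstat[3]),
    p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    coefficients = data.frame(term = rownames(coefs),
                              estimate = coefs[, 1], t = coefs[, 3],
                              p = coefs[, 4], row.names = NULL)
  )
}
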