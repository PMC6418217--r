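#' Hellinger transformation of a community matrix
#'
#' Square root of relative abundance per sample: y'_ij = sqrt(y_ij /
#' rowsum_i). Each transformed row has unit sum of squares, which makes
#' Euclidean-distance ordination (PCA/RDA) appropriate for species data.
#'
#' @param x samples x taxa matrix of non-negative abundances.
#' @return transformed matrix.
#' @export
hellinger <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be non-negative")
  rs <- rowSums(x)
  zero <- rs == 0
  if (any(zero))
    stop("zero row sum for sample(s): ",
         paste(rownames(x)[zero] %||% which(zero), collapse = ", "))
  sqrt(sweep(x, 1, rs, "/"))
}

# Shared eigen-analysis: PCA of a (samples x variables) matrix via the
# column-centered covariance matrix (divisor n - 1). Sign convention: the
# largest-magnitude loading on each axis is positive.
pca_core <- function(x, center_on = x) {
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(center_on), "-")
  cv <- crossprod(xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  r <- sum(eg$values > max(eg$values[1], 0) * 1e-12)
  if (r == 0) stop("matrix has rank 0 after centering")
  vec <- eg$vectors[, seq_len(r), drop = FALSE]
  flip <- apply(vec, 2, function(v) sign(v[which.max(abs(v))]))
  vec <- sweep(vec, 2, flip, "*")
  list(eigenvalues = eg$values[seq_len(r)], loadings = vec,
       scores = xc %*% vec, total_variance = sum(diag(cv)))
}

#' Principal components analysis of a community matrix
#'
#' Eigen-decomposition of the column-centered covariance matrix. Axes are
#' sign-fixed so the largest-magnitude loading on each axis is positive.
#'
#' @param x samples x variables matrix (typically Hellinger-transformed).
#' @return object of class `loac_ordination` with `method`, `eigenvalues`,
#'   `proportion` (of total variance), `scores`, `loadings`.
#' @export
pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 samples and >= 2 variables")
  core <- pca_core(x)
  structure(list(method = "PCA", eigenvalues = core$eigenvalues,
                 proportion = core$eigenvalues / core$total_variance,
                 total_variance = core$total_variance,
                 scores = core$scores, loadings = core$loadings),
            class = "loac_ordination")
}

#' @export
print.loac_ordination <- function(x, ...) {
  cat("<", x$method, "> eigenvalues: ",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "),
      if (length(x$eigenvalues) > 5) ", ..." else "", "\n", sep = "")
  if (!is.null(x$selected_variables))
    cat("  selected:", paste(x$selected_variables, collapse = ", "), "\n")
  if (!is.null(x$constrained_proportion))
    cat(sprintf("  constrained proportion: %.3f\n", x$constrained_proportion))
  invisible(x)
}

#' Redundancy analysis (RDA)
#'
#' Multivariate least-squares regression of the (centered) response matrix
#' on the predictors, followed by a PCA of the fitted values: the
#' constrained eigenvalues are the covariance eigenvalues of the fitted
#' responses. With predictors spanning the response row space, RDA equals
#' PCA of the response.
#'
#' @param Y samples x species response matrix (transformed as desired).
#' @param X samples x predictors matrix; standardized with
#'   [standardize_env()] by convention.
#' @return `loac_ordination` with constrained `eigenvalues`,
#'   `constrained_proportion` (of the total response variance), site
#'   `scores` and species `loadings` on the constrained axes.
#' @export
rda <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  if (nrow(X) != n) stop("Y and X row counts differ")
  if (n <= ncol(X) + 1) stop("need more samples than predictors")
  Xc <- cbind(1, X)
  qr_x <- qr(Xc)
  if (qr_x$rank < ncol(Xc))
    stop("predictors collinear to machine precision; screen with vif() first")
  fitted <- qr.fitted(qr_x, Y)
  core <- pca_core(fitted)
  total <- sum(diag(stats::cov(Y)))
  structure(list(method = "RDA", eigenvalues = core$eigenvalues,
                 constrained_proportion = sum(core$eigenvalues) / total,
                 total_variance = total,
                 scores = core$scores, loadings = core$loadings,
                 fitted = fitted),
            class = "loac_ordination")
}

#' Standardize environmental variables
#'
#' Centers each column to mean 0 and scales to SD 1.
#'
#' @param X samples x variables matrix or data frame.
#' @return standardized matrix.
#' @export
standardize_env <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant environmental variable(s): ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  scale(X)[, , drop = FALSE]
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing predictor j on all others.
#' Perfect collinearity is reported as `Inf`.
#'
#' @param X samples x predictors matrix (>= 2 columns).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need >= 2 predictors")
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    sst <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - sum(fit$residuals^2) / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(colnames(X))
}

# AIC convention for the multivariate regression underlying an RDA:
# n * m * log(RSS / (n * m)) + 2 * m * (k + 1), with RSS the total squared
# residual over all m response columns and m * (k + 1) the regression
# coefficient count (every added predictor contributes one coefficient per
# response column).
rda_aic <- function(Y, X) {
  n <- nrow(Y); m <- ncol(Y)
  Xc <- if (is.null(X) || ncol(X) == 0) matrix(1, n, 1) else cbind(1, X)
  rss <- sum(qr.resid(qr(Xc), Y)^2)
  n * m * log(rss / (n * m)) + 2 * m * ncol(Xc)
}

#' Forward selection of RDA predictors by AIC
#'
#' Greedy forward addition: at each step the candidate variable whose
#' addition most lowers the AIC of the underlying multivariate regression
#' is brought in; selection stops when no candidate lowers AIC. Ties are
#' broken by column order.
#'
#' @param Y response matrix (transformed).
#' @param X standardized predictor matrix with column names.
#' @return the reduced-model [rda()] result with `selected_variables` and
#'   the `aic_path`; when nothing beats the intercept-only model, a list
#'   with empty `selected_variables`.
#' @export
forward_select_rda <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  selected <- character(0)
  aic_cur <- rda_aic(Y, NULL)
  path <- data.frame(step = 0L, variable = "(none)", aic = aic_cur)
  repeat {
    remaining <- setdiff(colnames(X), selected)
    if (!length(remaining)) break
    aics <- vapply(remaining, function(v)
      rda_aic(Y, X[, c(selected, v), drop = FALSE]), numeric(1))
    best <- which.min(aics)   # first minimum wins: ties by column order
    if (aics[best] >= aic_cur) break
    selected <- c(selected, remaining[best])
    aic_cur <- aics[best]
    path <- rbind(path, data.frame(step = length(selected),
                                   variable = remaining[best], aic = aic_cur))
  }
  if (!length(selected))
    return(structure(list(method = "RDA", selected_variables = character(0),
                          aic_path = path, eigenvalues = numeric(0)),
                     class = "loac_ordination"))
  out <- rda(Y, X[, selected, drop = FALSE])
  out$selected_variables <- selected
  out$aic_path <- path
  out
}

#' Regression of first-axis scores on an environmental variable
#'
#' Ordinary least squares of PC1 (or RDA1) site scores against a single
#' environmental gradient; r^2 equals the squared Pearson correlation.
#'
#' @param pc1_scores,env_values equal-length numeric vectors, n >= 3.
#' @return list `slope`, `intercept`, `r2`, `p`.
#' @export
pc1_env_regression <- function(pc1_scores, env_values) {
  stopifnot(length(pc1_scores) == length(env_values), length(env_values) >= 3)
  if (stats::sd(env_values) == 0) stop("environmental variable has zero variance")
  fit <- stats::lm(pc1_scores ~ env_values)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       p = sm$coefficients[2, 4])
}

#' Taxon richness per season and season-unique taxa
#'
#' A taxon is present where its abundance exceeds zero. Counts taxa present
#' in each season and the number found exclusively in that season.
#'
#' @param x samples x taxa abundance matrix.
#' @param season character vector, one entry per sample (row).
#' @return data frame `season`, `n_taxa`, `n_unique`.
#' @export
richness_summary <- function(x, season) {
  x <- as.matrix(x)
  stopifnot(length(season) == nrow(x))
  present <- lapply(split(seq_len(nrow(x)), season), function(i) {
    cols <- colSums(x[i, , drop = FALSE] > 0) > 0
    (colnames(x) %||% as.character(seq_len(ncol(x))))[cols]
  })
  out <- data.frame(season = names(present),
                    n_taxa = vapply(present, length, integer(1)))
  out$n_unique <- vapply(names(present), function(s) {
    others <- unlist(present[setdiff(names(present), s)])
    sum(!present[[s]] %in% others)
  }, integer(1))
  rownames(out) <- NULL
  out
}
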