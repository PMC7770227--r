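# Mass-univariate GLM on rate maps: four-level group ANCOVA contrasts,
# one-sample tests at covariate means, and t -> z conversion.
#
# Group membership uses cell-means coding (one indicator per group, no
# global intercept) so contrast weights are direct group-mean differences.
# Nuisance covariates are mean-centered so intercept/group columns are
# evaluated at covariate means.

Z_CLAMP <- 38  # |z| ceiling for zero-residual-variance voxels

#' Voxel-wise statistic map
#'
#' @param data 3-D statistic array (NA outside the mask).
#' @param stat_kind One of "t", "F", "z".
#' @param df Degrees of freedom (length 2 for F).
#' @param contrast Human-readable contrast description.
#' @param mask The `analysis_mask` the statistics live on.
#' @param voxel_size_mm Voxel edge length in mm.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(data, stat_kind = c("t", "F", "z"), df, contrast = "",
                     mask = NULL, voxel_size_mm = 1) {
  stat_kind <- match.arg(stat_kind)
  structure(list(data = data, stat_kind = stat_kind, df = df,
                 contrast = contrast, mask = mask,
                 voxel_size_mm = voxel_size_mm),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map (%s, df = %s): %s; range [%.3g, %.3g]\n",
              x$stat_kind, paste(x$df, collapse = ", "), x$contrast,
              min(x$data, na.rm = TRUE), max(x$data, na.rm = TRUE)))
  invisible(x)
}

#' Build a design matrix for voxel-wise models
#'
#' Cell-means group coding plus mean-centered nuisance covariates. With
#' `groups = NULL` the design is an intercept plus centered covariates
#' (one-sample layout).
#'
#' @param groups Factor (or NULL) of group labels, one per subject.
#' @param covariates Data frame or matrix of nuisance covariates (may be
#'   NULL or zero-column).
#' @return List with the design matrix `X`, `colnames`, `groups`.
#' @export
make_design <- function(groups = NULL, covariates = NULL) {
  blocks <- list()
  if (is.null(groups)) {
    blocks$mean <- matrix(1, nrow = if (is.null(covariates)) 0L else nrow(covariates),
                          ncol = 1L, dimnames = list(NULL, "mean"))
  } else {
    groups <- droplevels(as.factor(groups))
    g <- stats::model.matrix(~ 0 + groups)
    colnames(g) <- levels(groups)
    blocks$groups <- g
  }
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cv <- as.matrix(covariates)
    storage.mode(cv) <- "double"
    cv <- scale(cv, center = TRUE, scale = FALSE)
    if (is.null(colnames(cv))) colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
    if (is.null(groups)) {
      blocks$mean <- matrix(1, nrow(cv), 1L, dimnames = list(NULL, "mean"))
    }
    blocks$cov <- cv
  }
  X <- do.call(cbind, unname(blocks))
  if (nrow(X) < ncol(X) + 1L) stopf("need more subjects than design columns")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stopf("rank-deficient design; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  list(X = X, colnames = colnames(X), groups = groups)
}

# Stack rate maps into an n x V matrix.
rate_matrix <- function(rate_maps) {
  d <- dim(rate_maps[[1]]$data)
  t(vapply(rate_maps, function(m) as.vector(m$data), numeric(prod(d))))
}

# Core mass-univariate OLS: Y is n x V. Returns per-voxel contrast t (or F
# for a contrast matrix), df, and optionally residuals.
fit_glm_matrix <- function(Y, X, contrast, keep_residuals = FALSE) {
  n <- nrow(X)
  p <- ncol(X)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  beta <- xtx_inv %*% crossprod(X, Y)           # p x V
  resid <- Y - X %*% beta
  df <- n - p
  ss_res <- colSums(resid^2)
  # residuals at numerical zero count as zero variance (perfect fit)
  ss_res[ss_res <= 1e-20 * pmax(colSums(Y^2), .Machine$double.xmin)] <- 0
  sigma2 <- ss_res / df
  if (is.matrix(contrast)) {
    # omnibus F for a q x p contrast matrix
    q <- nrow(contrast)
    cb <- contrast %*% beta                     # q x V
    cvc <- contrast %*% xtx_inv %*% t(contrast) # q x q
    cvc_inv <- chol2inv(chol(cvc))
    quad <- colSums(cvc_inv %*% cb * cb)
    stat <- (quad / q) / sigma2
    out <- list(stat = stat, kind = "F", df = c(q, df))
  } else {
    cvec <- as.numeric(contrast)
    cb <- as.vector(cvec %*% beta)
    se <- sqrt(sigma2 * as.numeric(t(cvec) %*% xtx_inv %*% cvec))
    stat <- ifelse(se > 0, cb / se, sign(cb) * Inf)
    stat[se == 0 & cb == 0] <- 0
    out <- list(stat = stat, kind = "t", df = df)
  }
  if (keep_residuals) out$residuals <- resid
  out
}

# Expand a named contrast over design columns to a full weight vector.
expand_contrast <- function(contrast, design) {
  if (!is.null(names(contrast))) {
    w <- stats::setNames(rep(0, length(design$colnames)), design$colnames)
    missing <- setdiff(names(contrast), design$colnames)
    if (length(missing)) {
      stopf("contrast names not in design: %s", paste(missing, collapse = ", "))
    }
    w[names(contrast)] <- contrast
    w
  } else {
    if (length(contrast) != length(design$colnames)) {
      stopf("contrast length %d != %d design columns", length(contrast),
            length(design$colnames))
    }
    contrast
  }
}

#' Voxel-wise group ANCOVA contrast on rate maps
#'
#' Ordinary least-squares fit of each voxel's rate on group indicators and
#' centered nuisance covariates; returns the t map of the requested
#' contrast (or the omnibus F map for a contrast matrix).
#'
#' @param rate_maps List of [rate_map()]s, one per design row.
#' @param design A design from [make_design()].
#' @param contrast Named numeric (e.g. `c(MCIp = 1, MCIs = -1)`), a
#'   full-length weight vector, or a contrast matrix for an F test.
#' @param mask An `analysis_mask`.
#' @param keep_residuals Attach the n-x-V residual matrix (needed for
#'   smoothness estimation) as attribute `"residuals"`.
#' @return A [stat_map()] (t or F) with NA outside the mask.
#' @export
fit_ancova <- function(rate_maps, design, contrast, mask,
                       keep_residuals = FALSE) {
  Y <- rate_matrix(rate_maps)
  if (nrow(Y) != nrow(design$X)) stopf("one rate map per design row required")
  inmask <- as.vector(mask$data)
  cw <- if (is.matrix(contrast)) contrast else expand_contrast(contrast, design)
  fit <- fit_glm_matrix(Y[, inmask, drop = FALSE], design$X, cw,
                        keep_residuals = keep_residuals)
  d <- dim(rate_maps[[1]]$data)
  out <- array(NA_real_, dim = d)
  out[inmask] <- fit$stat
  sm <- stat_map(out, fit$kind, fit$df,
                 contrast = contrast_label(contrast), mask = mask,
                 voxel_size_mm = rate_maps[[1]]$voxel_size_mm)
  if (keep_residuals) attr(sm, "residuals") <- fit$residuals
  sm
}

contrast_label <- function(contrast) {
  if (is.matrix(contrast)) return("omnibus F")
  if (!is.null(names(contrast))) {
    paste(sprintf("%+g*%s", contrast, names(contrast)), collapse = " ")
  } else "custom contrast"
}

#' One-sample t-test of mean rate within a group
#'
#' Regression of rate on centered nuisance covariates; the intercept t
#' tests mean rate != 0 at covariate means.
#'
#' @param rate_maps List of [rate_map()]s for one group (n >= 3).
#' @param covariates Data frame of nuisance covariates (or NULL).
#' @param mask An `analysis_mask`.
#' @param keep_residuals See [fit_ancova()].
#' @return A t [stat_map()].
#' @export
fit_one_sample <- function(rate_maps, covariates = NULL, mask,
                           keep_residuals = FALSE) {
  if (length(rate_maps) < 3L) stopf("one-sample test needs n >= 3")
  design <- make_design(groups = NULL,
                        covariates = if (is.null(covariates)) {
                          matrix(numeric(0), length(rate_maps), 0)
                        } else covariates)
  if (nrow(design$X) == 0L) {
    design$X <- matrix(1, length(rate_maps), 1L, dimnames = list(NULL, "mean"))
    design$colnames <- "mean"
  }
  fit_ancova(rate_maps, design, c(mean = 1), mask,
             keep_residuals = keep_residuals)
}

#' Convert a t map to a z map
#'
#' Probability-preserving, sign-symmetric transform
#' `z = qnorm(pt(t, df))`, computed on the log scale for tail accuracy and
#' clamped at +/-38 (the clamp also makes infinite t from zero-variance
#' voxels representable).
#'
#' @param map A t [stat_map()] with positive df.
#' @return A z `stat_map`.
#' @export
t_to_z <- function(map) {
  stopifnot(inherits(map, "stat_map"))
  if (map$stat_kind != "t") stopf("t_to_z() needs a t map")
  if (map$df <= 0) stopf("df must be positive")
  tt <- map$data
  z <- tt
  ok <- !is.na(tt)
  # upper-tail log p for |t|, mapped back with the sign of t
  logp <- stats::pt(abs(tt[ok]), df = map$df, lower.tail = FALSE, log.p = TRUE)
  zz <- -stats::qnorm(logp, log.p = TRUE)
  zz[!is.finite(zz) | zz > Z_CLAMP] <- Z_CLAMP
  z[ok] <- sign(tt[ok]) * zz
  if (any(!is.finite(tt[ok]))) {
    warnf("zero-residual-variance voxels: z clamped to +/-%g", Z_CLAMP)
  }
  stat_map(z, "z", df = Inf, contrast = map$contrast, mask = map$mask,
           voxel_size_mm = map$voxel_size_mm)
}

# Residual rows -> list of 3-D maps on the mask grid (0 outside mask).
residual_maps <- function(residuals, mask) {
  d <- dim(mask$data)
  inmask <- as.vector(mask$data)
  lapply(seq_len(nrow(residuals)), function(i) {
    m <- array(0, dim = d)
    m[inmask] <- residuals[i, ]
    m
  })
}
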