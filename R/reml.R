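#' Fit the additive polygenic mixed model by fast REML
#'
#' Fits \eqn{y = X\beta + a + e} with \eqn{a \sim N(0, G\sigma_g^2)} and
#' \eqn{e \sim N(0, I\sigma_e^2)}, where G is the identity-by-state genomic
#' relationship matrix. Because the model has a single random effect, the
#' restricted likelihood is profiled on the heritability ratio
#' \eqn{h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)} after rotating the data by
#' the eigenvectors of G, and maximised by one-dimensional search on
#' \eqn{h^2 \in [0, 0.999]}. Returns GRAMMAR residuals
#' \eqn{\hat e = y - X\hat\beta - \hat a} with \eqn{\hat a} the BLUP of the
#' polygenic values.
#'
#' @param data Data frame holding the trait and covariate columns plus an
#'   `id` column matching the GRM sample ids. Rows with a missing trait value
#'   or covariate are dropped for this trait only.
#' @param trait Name of the trait column (string).
#' @param grm A [build_grm()] result covering (at least) the samples in
#'   `data`.
#' @param covariates Character vector of fixed-effect columns; character
#'   columns are treated as class factors, numeric columns as covariates.
#'   Use `character(0)` for an intercept-only model.
#' @param eig Optional precomputed [grm_eigen()] for the full GRM sample set
#'   (reused across traits when all traits share the same complete cases).
#' @return An object of class `polygenic_fit`.
#' @export
fit_polygenic <- function(data, trait, grm,
                          covariates = c("herd_date", "parity_class", "dim_class"),
                          eig = NULL) {
  stopifnot(inherits(grm, "grm"))
  if (!trait %in% names(data)) abort(paste0("Trait column not found: ", trait))
  if (!"id" %in% names(data)) abort("`data` needs an `id` column.")
  covariates <- intersect(covariates, names(data))
  df <- data[, c("id", trait, covariates), drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  idx <- match(df$id, grm$sample_ids)
  if (anyNA(idx)) abort("Some samples in `data` are absent from the GRM.")
  y <- as.numeric(df[[trait]])
  n <- length(y)
  if (length(unique(y)) < 2) abort("Need at least 2 distinct phenotype values.")

  X <- .design_matrix(df, covariates)
  p <- ncol(X)
  if (n - p < 2) abort("Too few residual degrees of freedom for REML.")

  if (is.null(eig) || length(idx) != length(grm$sample_ids) || any(idx != seq_along(grm$sample_ids))) {
    sub <- grm$matrix[idx, idx, drop = FALSE]
    sc <- mean(diag(sub))
    if (!is.finite(sc) || sc <= 0) abort("GRM has non-positive mean diagonal.")
    eg <- eigen(sub, symmetric = TRUE)
    eg$values <- pmax(eg$values, 0) / sc
  } else {
    eg <- eig
  }
  U <- eg$vectors
  d <- eg$values
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)

  negloglik <- function(h2) .reml_nll(h2, ys, Xs, d, n, p)
  opt <- optimize(negloglik, interval = c(0, 0.999), tol = 1e-9)
  # guard the boundaries: optimize() can miss a minimum at the edge
  cand_h2 <- c(opt$minimum, 0, 0.999)
  nll <- vapply(cand_h2, negloglik, numeric(1))
  h2 <- cand_h2[which.min(nll)]
  loglik <- -min(nll)

  w <- h2 * d + (1 - h2)
  XtWiX <- crossprod(Xs, Xs / w)
  beta <- solve(XtWiX, crossprod(Xs, ys / w))
  r <- ys - Xs %*% beta
  sigma2 <- sum(r^2 / w) / (n - p)
  sigma_g2 <- h2 * sigma2
  sigma_e2 <- (1 - h2) * sigma2
  # GRAMMAR residuals: e_hat = y - X beta - BLUP(a) = U ((1 - h2)/w * r)
  resid <- as.numeric(U %*% ((1 - h2) / w * r))

  structure(
    list(
      trait = trait,
      sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
      h2 = if (sigma_g2 + sigma_e2 > 0) sigma_g2 / (sigma_g2 + sigma_e2) else 0,
      loglik = loglik,
      beta = setNames(as.numeric(beta), colnames(X)),
      residuals = setNames(resid, df$id),
      sample_ids = df$id,
      n = n, n_fixed = p,
      eigenvalues = d, eigenvectors = U, weights = w,
      covariates = covariates
    ),
    class = "polygenic_fit"
  )
}

# REML negative log-likelihood profiled on h2 (constants dropped)
.reml_nll <- function(h2, ys, Xs, d, n, p) {
  w <- h2 * d + (1 - h2)
  if (any(w <= 0)) return(Inf)
  XtWiX <- crossprod(Xs, Xs / w)
  ch <- tryCatch(chol(XtWiX), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xs, ys / w)))
  r <- ys - Xs %*% beta
  rss <- sum(r^2 / w)
  if (rss <= 0) return(Inf)
  sigma2 <- rss / (n - p)
  0.5 * ((n - p) * log(sigma2) + sum(log(w)) + 2 * sum(log(diag(ch))) + (n - p))
}

# model matrix with characters as factors; aliased columns dropped via QR
.design_matrix <- function(df, covariates) {
  if (length(covariates) == 0) {
    return(matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)")))
  }
  mf <- df[, covariates, drop = FALSE]
  for (cn in names(mf)) {
    if (is.character(mf[[cn]]) || is.logical(mf[[cn]])) mf[[cn]] <- factor(mf[[cn]])
  }
  X <- model.matrix(~ ., data = mf)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    warn(paste0("Dropping collinear fixed-effect column(s): ",
                paste(dropped, collapse = ", ")))
    X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  X
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat(sprintf(
    "<polygenic_fit> trait %s: sigma_g2 = %.4f, sigma_e2 = %.4f, h2 = %.3f (n = %d)\n",
    x$trait, x$sigma_g2, x$sigma_e2, x$h2, x$n
  ))
  invisible(x)
}

#' @rdname fit_polygenic
#' @param x A `polygenic_fit`.
#' @param ... Unused.
#' @export
tidy.polygenic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("sigma_g2", "sigma_e2", "h2"),
    estimate = c(x$sigma_g2, x$sigma_e2, x$h2)
  )
}

#' @rdname fit_polygenic
#' @export
glance.polygenic_fit <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
    h2 = x$h2, loglik = x$loglik, n = x$n, n_fixed = x$n_fixed
  )
}
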