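# Kinship-adjusted association: y = mu + g + e with cov(g) = sigma_g^2 K,
# fitted by REML through the eigendecomposition of K, and generalized
# least-squares Wald tests for single variants. Binary phenotypes are
# analyzed quantitatively on the 0/1 scale.

#' Fit the null kinship mixed model by REML
#'
#' Variance components of `y = mu + g + e`, `g ~ N(0, sigma_g^2 K)`,
#' `e ~ N(0, sigma_e^2 I)`, estimated by restricted maximum likelihood via
#' a one-dimensional profile optimization over the variance ratio after
#' eigendecomposition of `K`. Eigenvalues below `eig_tol` are clipped to
#' `eig_tol` (this handles duplicated-sample kinship columns); matrices
#' with eigenvalues below `-psd_tol` are rejected as non-PSD.
#'
#' @param y numeric phenotype vector (a 0/1 case status is analyzed
#'   quantitatively); must be non-constant
#' @param K kinship (or GRM) covariance matrix aligned to `y`
#' @param eig_tol eigenvalue clipping floor (default 1e-8)
#' @param psd_tol tolerated negative-eigenvalue magnitude (default 1e-6)
#' @return an object of class `lmm_null`: variance components `sigma_g2`,
#'   `sigma_e2`, heritability `h2` on the observed scale, the REML
#'   log-likelihood, and the cached eigendecomposition for reuse in
#'   [wald_test()]
#' @export
fit_lmm_null <- function(y, K, eig_tol = 1e-8, psd_tol = 1e-6) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n, n >= 10)
  if (stats::sd(y) == 0) stop("phenotype is constant")
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eig$values) < -psd_tol)
    stop("kinship matrix is not positive semi-definite (min eigenvalue ",
         signif(min(eig$values), 3), ")")
  d <- pmax(eig$values, eig_tol)
  U <- eig$vectors
  yr <- crossprod(U, y)
  xr <- crossprod(U, rep(1, n))

  # REML log-likelihood profiled over sigma^2 at ratio lambda = sg2/se2
  reml_ll <- function(log_lambda) {
    lam <- exp(log_lambda)
    v <- lam * d + 1                       # cov = se2 * (lam K + I)
    xvx <- sum(xr^2 / v)
    beta <- sum(xr * yr / v) / xvx
    r <- yr - xr * beta
    rss <- sum(r^2 / v)
    se2 <- rss / (n - 1)
    -0.5 * ((n - 1) * log(2 * pi * se2) + sum(log(v)) + log(xvx) +
              rss / se2)
  }
  opt <- stats::optimize(reml_ll, interval = c(-12, 12), maximum = TRUE)
  # compare against the boundary (no genetic variance)
  ll0 <- reml_ll(-30)
  if (ll0 >= opt$objective) {
    lam <- 0; ll <- ll0
  } else {
    lam <- exp(opt$maximum); ll <- opt$objective
  }
  v <- lam * d + 1
  xvx <- sum(xr^2 / v)
  beta <- sum(xr * yr / v) / xvx
  rss <- sum((yr - xr * beta)^2 / v)
  se2 <- rss / (n - 1)
  sg2 <- lam * se2
  structure(list(sigma_g2 = sg2, sigma_e2 = se2,
                 h2 = sg2 / (sg2 + se2), lambda = lam, logREML = ll,
                 n = n, eigenvalues = d, U = U, ids = rownames(K)),
            class = "lmm_null")
}

#' @export
print.lmm_null <- function(x, ...) {
  cat("Kinship mixed model (REML), n = ", x$n, "\n",
      "  sigma_g^2 = ", signif(x$sigma_g2, 4),
      ",  sigma_e^2 = ", signif(x$sigma_e2, 4),
      ",  h2 (observed scale) = ", round(x$h2, 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.lmm_null <- function(object, ...) {
  out <- c(sigma_g2 = object$sigma_g2, sigma_e2 = object$sigma_e2,
           h2 = object$h2, logREML = object$logREML, n = object$n)
  class(out) <- "summary.lmm_null"
  out
}

#' @export
print.summary.lmm_null <- function(x, ...) {
  print(unclass(x)); invisible(x)
}

#' Wald test of a variant under the kinship mixed model
#'
#' Generalized least squares of `y` on an intercept and the dosage `x`
#' with covariance `sigma_g^2 K + sigma_e^2 I` taken from the fitted null
#' model; two-sided P from the standard normal on `beta / se`.
#'
#' @param y phenotype vector
#' @param x genotype dosage vector (must vary)
#' @param vc a fitted `lmm_null` (for the same `y` ordering)
#' @return list with `beta`, `se`, `z`, `p`, `n`
#' @export
wald_test <- function(y, x, vc) {
  stopifnot(inherits(vc, "lmm_null"), length(y) == vc$n, length(x) == vc$n)
  if (stats::sd(x) == 0) stop("monomorphic predictor")
  v <- vc$lambda * vc$eigenvalues + 1     # up to the factor sigma_e^2
  Xr <- crossprod(vc$U, cbind(1, x))
  yr <- crossprod(vc$U, y)
  XtVX <- crossprod(Xr, Xr / v)
  XtVy <- crossprod(Xr, yr / v)
  beta <- solve(XtVX, XtVy)
  # residual variance re-estimated under the alternative (with the variance
  # ratio held at the null REML value), so that with K = I the test reduces
  # exactly to the OLS Wald test
  rss <- sum((yr - Xr %*% beta)^2 / v)
  s2 <- rss / (vc$n - 2)
  cov_beta <- s2 * solve(XtVX)
  se <- sqrt(cov_beta[2, 2])
  z <- beta[2] / se
  list(beta = beta[2], se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)), n = vc$n)
}

#' Minimum theoretical association P value for a pedigree
#'
#' The best-case Wald P value attainable by a variant segregating to all
#' affected individuals and no terminal unaffected individuals (unaffected
#' with no affected descendants). The dosage vector is 1 for every
#' affected individual, 0 for terminal unaffected individuals, and,
#' resolving transmission-path ambiguity toward carriage, 1 for connecting
#' individuals (non-affected with at least one affected descendant) --- the
#' most conservative consistent fill.
#'
#' @param ped a `Pedigree` containing unaffected individuals
#' @param K kinship covariance aligned to `ped$id` (e.g.
#'   `2 * pedigree_kinship(ped)`)
#' @param affected optional id set overriding the pedigree affection status
#' @return list with `p`, `beta`, `se`, the constructed `dosage` vector and
#'   the fitted null model `vc`
#' @export
min_theoretical_p <- function(ped, K, affected = NULL) {
  stopifnot(inherits(ped, "Pedigree"))
  if (is.null(affected)) affected <- ped$id[ped$affection == "affected"]
  if (!any(!(ped$id %in% affected))) stop("no unaffected individuals")
  has_aff_desc <- .has_affected_descendant(ped, affected)
  x <- ifelse(ped$id %in% affected | has_aff_desc, 1, 0)
  y <- as.numeric(ped$id %in% affected)
  K <- K[ped$id, ped$id]
  vc <- fit_lmm_null(y, K)
  wt <- wald_test(y, x, vc)
  c(wt, list(dosage = stats::setNames(x, ped$id), vc = vc))
}

# TRUE for individuals with >= 1 affected descendant.
.has_affected_descendant <- function(ped, affected) {
  n <- nrow(ped)
  has <- ped$id %in% affected
  out <- rep(FALSE, n)
  # children come after parents, so one child-to-parent sweep in reverse
  # topological order propagates all the way up
  for (i in rev(seq_len(n))) {
    if (!is.na(ped$father[i]) && (out[i] || has[i])) {
      out[match(ped$father[i], ped$id)] <- TRUE
      out[match(ped$mother[i], ped$id)] <- TRUE
    }
  }
  out
}

#' Write association results as a tab-delimited table
#' @param results data.frame of per-variant association output (variant,
#'   beta, se, p, n, unit columns)
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_assoc <- function(results, path) {
  utils::write.table(results, path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  invisible(path)
}
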