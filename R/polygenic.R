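#' Fit the polygenic variance-components model
#'
#' Maximum-likelihood estimation of narrow-sense heritability from family
#' data. The phenotype is modelled as multivariate normal with mean
#' \eqn{X\beta} and covariance \eqn{\Omega = 2\Phi\sigma^2_a + I\sigma^2_e},
#' where \eqn{2\Phi} is the additive relationship matrix from [kinship()].
#' Writing \eqn{\sigma^2_p = \sigma^2_a + \sigma^2_e} and
#' \eqn{h^2 = \sigma^2_a/\sigma^2_p}, the covariance is
#' \eqn{\sigma^2_p [h^2 K + (1-h^2) I]} and the likelihood is profiled over
#' \eqn{h^2 \in [0,1]}: the relationship matrix is spectrally decomposed
#' (block-wise over its connected families), phenotype and design are rotated
#' by the eigenvectors, and for each candidate \eqn{h^2} the GLS fixed
#' effects and the closed-form \eqn{\sigma^2_p} are plugged in. The 1-D
#' profile is maximized by deterministic bounded search (tolerance 1e-8).
#'
#' The standard error of \eqn{\hat h^2} comes from the numerical curvature of
#' the profile log-likelihood; the p-value for \eqn{h^2 = 0} is a
#' likelihood-ratio test against the boundary null using the 50:50 mixture of
#' a point mass at zero and \eqn{\chi^2_1} (see [lrt_pvalue()]).
#'
#' @param y Numeric phenotype vector.
#' @param X Design matrix (including intercept), rows aligned with `y` and
#'   `K`; must have full column rank.
#' @param K Additive relationship matrix (from [kinship()]), rows/columns
#'   aligned with `y`. Must be positive semidefinite and contain some
#'   relatedness: with `K = I` the two variance components are exchangeable
#'   and \eqn{h^2} is unidentifiable (an error).
#' @param method `"ML"` (default; the reference analysis) or `"REML"`.
#' @param se Compute the curvature-based standard error? Default `TRUE`.
#' @param tol Convergence tolerance of the bounded search. Default 1e-8.
#' @return Object of class `polygenic`; see [summary.polygenic()]. Fields
#'   include `h2`, `se_h2`, `sigma2_a`, `sigma2_e`, `sigma2_p`, `beta`,
#'   `vcov_beta`, `loglik`, `loglik_null`, `p_value`, `n`, `boundary`.
#' @export
fit_polygenic <- function(y, X, K, method = c("ML", "REML"), se = TRUE,
                          tol = 1e-8) {
  method <- match.arg(method)
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (n < 3) stop("need at least 3 individuals, got ", n)
  if (nrow(X) != n || nrow(K) != n || ncol(K) != n)
    stop("y, X and K must have aligned rows")
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix X is rank deficient")
  offdiag <- K; diag(offdiag) <- 0
  if (max(abs(offdiag)) < 1e-10)
    stop("h2 unidentifiable: all individuals mutually unrelated (K = I)")

  sp <- spectral_blocks(K)
  if (min(sp$values) < -1e-8 * max(1, max(sp$values)))
    stop("relationship matrix is not positive semidefinite (min eigenvalue ",
         format(min(sp$values)), ")")
  d <- pmax(sp$values, 0)
  yr <- rotate_blocks(sp, y)
  Xr <- rotate_blocks(sp, X)

  prof <- function(h2) profile_loglik(h2, yr, Xr, d, n, p, method)
  opt <- stats::optimize(function(h2) -prof(h2)$loglik, c(0, 1), tol = tol)
  cand <- list(prof(opt$minimum), prof(0), prof(1))
  best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "loglik"))]]
  h2 <- best$h2
  boundary <- h2 < 1e-6 || h2 > 1 - 1e-6

  null_ll <- prof(0)$loglik
  lrt <- max(0, 2 * (best$loglik - null_ll))
  p_value <- lrt_pvalue(best$loglik, null_ll)

  se_h2 <- if (se) profile_se(prof, h2, best$loglik) else NA_real_

  sigma2_p <- best$sigma2_p
  vcov_beta <- sigma2_p * solve(best$XtWX)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  beta <- drop(best$beta)
  names(beta) <- colnames(X)

  structure(list(
    h2 = h2, se_h2 = se_h2,
    sigma2_a = h2 * sigma2_p, sigma2_e = (1 - h2) * sigma2_p,
    sigma2_p = sigma2_p,
    beta = beta, vcov_beta = vcov_beta,
    loglik = best$loglik, loglik_null = null_ll,
    lrt = lrt, p_value = p_value,
    n = n, df = p, method = method, boundary = boundary,
    y = y, X = X, blocks = sp,
    call = sys.call()
  ), class = "polygenic")
}

# connected components of the nonzero structure of K, with a spectral
# decomposition per block (families are independent, so the full-eigen cost
# collapses to many small symmetric problems)
spectral_blocks <- function(K) {
  n <- nrow(K)
  nz <- abs(K) > 1e-12
  comp <- integer(n)
  nc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      nb <- which(nz[i, ] & comp == 0L)
      comp[nb] <- nc
      queue <- c(queue, nb)
    }
  }
  blocks <- split(seq_len(n), comp)
  eig <- lapply(blocks, function(ix) {
    if (length(ix) == 1L) {
      list(vectors = matrix(1, 1, 1), values = K[ix, ix])
    } else {
      eigen(K[ix, ix, drop = FALSE], symmetric = TRUE)
    }
  })
  list(blocks = blocks,
       eig = eig,
       values = unlist(lapply(eig, `[[`, "values"), use.names = FALSE))
}

# t(U) %*% v applied block-wise; v may be a vector or a matrix of columns
rotate_blocks <- function(sp, v) {
  v <- as.matrix(v)
  out <- matrix(0, nrow(v), ncol(v))
  pos <- 1L
  for (b in seq_along(sp$blocks)) {
    ix <- sp$blocks[[b]]
    out[pos:(pos + length(ix) - 1L), ] <-
      crossprod(sp$eig[[b]]$vectors, v[ix, , drop = FALSE])
    pos <- pos + length(ix)
  }
  out
}

# inverse rotation U %*% v (for simulation)
unrotate_blocks <- function(sp, v) {
  v <- as.matrix(v)
  out <- matrix(0, nrow(v), ncol(v))
  pos <- 1L
  for (b in seq_along(sp$blocks)) {
    ix <- sp$blocks[[b]]
    out[ix, ] <- sp$eig[[b]]$vectors %*% v[pos:(pos + length(ix) - 1L), , drop = FALSE]
    pos <- pos + length(ix)
  }
  out
}

profile_loglik <- function(h2, yr, Xr, d, n, p, method) {
  w <- pmax(h2 * d + (1 - h2), 1e-12)
  Xw <- Xr / w
  XtWX <- crossprod(Xr, Xw)
  beta <- solve(XtWX, crossprod(Xw, yr))
  r <- yr - Xr %*% beta
  rss <- sum(r^2 / w)
  if (method == "ML") {
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi) + sum(log(w)) + n * log(sigma2) + n)
  } else {
    sigma2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi) + sum(log(w)) +
                    determinant(XtWX, logarithm = TRUE)$modulus +
                    (n - p) * log(sigma2) + (n - p))
    ll <- as.numeric(ll)
  }
  list(h2 = h2, loglik = ll, beta = beta, sigma2_p = sigma2, XtWX = XtWX)
}

# SE from the numerical curvature of the profile log-likelihood; at a
# boundary optimum the second difference is taken on the inward side
profile_se <- function(prof, h2, ll0, h = 1e-4) {
  pts <- c(h2 - h, h2, h2 + h)
  if (pts[1] < 0) pts <- c(0, h, 2 * h)
  if (pts[3] > 1) pts <- c(1 - 2 * h, 1 - h, 1)
  ll <- vapply(pts, function(x) prof(x)$loglik, numeric(1))
  d2 <- (ll[1] - 2 * ll[2] + ll[3]) / h^2
  if (!is.finite(d2) || d2 >= 0) return(NA_real_)
  sqrt(-1 / d2)
}

#' Boundary-corrected likelihood-ratio p-value for h2 = 0
#'
#' The null hypothesis \eqn{h^2 = 0} lies on the boundary of the parameter
#' space, so the LRT statistic is asymptotically distributed as a 50:50
#' mixture of a point mass at 0 and \eqn{\chi^2_1}. The p-value is
#' \eqn{0.5\,P(\chi^2_1 \ge 2\Delta\ell)} (equal to 0.5 at \eqn{\Delta\ell = 0}).
#'
#' @param loglik_alt Maximized log-likelihood of the polygenic model.
#' @param loglik_null Log-likelihood at \eqn{h^2 = 0} (same fixed effects).
#' @return Two-sided... strictly, the one-sided mixture tail probability.
#' @export
lrt_pvalue <- function(loglik_alt, loglik_null) {
  if (loglik_alt < loglik_null - 1e-6)
    stop("alternative log-likelihood is below the null beyond tolerance (",
         format(loglik_alt - loglik_null), ")")
  stat <- max(0, 2 * (loglik_alt - loglik_null))
  0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Polygenic heritability model with a formula interface
#'
#' High-level wrapper around [fit_polygenic()]: builds the fixed-effect
#' design from a formula and data frame, aligns individuals with a
#' [pedigree()], drops incomplete cases (per-model complete-case analysis,
#' so `n` varies with the covariate set), and for numerical conditioning
#' centres and scales continuous covariates internally (coefficients are
#' reported on the original scale).
#'
#' @param formula Model formula, e.g. `meq_total ~ sex + age`.
#' @param data Data frame with the phenotype, covariates, and an id column.
#' @param ped A [pedigree()] containing (at least) the ids in `data`.
#' @param id Name of the id column in `data`. Default `"individual_id"`.
#' @param method `"ML"` or `"REML"`.
#' @param K Optional precomputed [kinship()] matrix for `ped` (saves
#'   recomputation when fitting several models on one pedigree).
#' @param ... Passed to [fit_polygenic()].
#' @return A `polygenic` object (see [fit_polygenic()]) with the call,
#'   formula and ids attached.
#' @examples
#' cfg <- sim_config(n_families = 30, seed = 7)
#' coh <- simulate_cohort(cfg)
#' fit <- polygenic(meq_total ~ sex + age, coh$phenotypes, coh$pedigree)
#' summary(fit)
#' @export
polygenic <- function(formula, data, ped, id = "individual_id",
                      method = c("ML", "REML"), K = NULL, ...) {
  method <- match.arg(method)
  stopifnot(inherits(ped, "pedigree"))
  if (!id %in% names(data)) stop("data lacks id column '", id, "'")
  unknown <- setdiff(as.character(data[[id]]), ped$id)
  if (length(unknown))
    stop("phenotype ids absent from pedigree: ",
         paste(utils::head(unknown, 3), collapse = ", "))

  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  mf <- mf[keep, , drop = FALSE]
  ids <- as.character(data[[id]])[keep]
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)

  std <- standardize_design(X)
  if (is.null(K)) K <- kinship(ped)
  fit <- fit_polygenic(y, std$X, K[ids, ids], method = method, ...)

  # back-transform coefficients and their covariance to the original scale
  fit$beta <- drop(std$Tmat %*% fit$beta)
  names(fit$beta) <- colnames(X)
  fit$vcov_beta <- std$Tmat %*% fit$vcov_beta %*% t(std$Tmat)
  dimnames(fit$vcov_beta) <- list(colnames(X), colnames(X))
  fit$X <- X
  fit$ids <- ids
  fit$formula <- formula
  fit$call <- match.call()
  fit
}

# centre/scale columns with >2 distinct values (keeps indicators intact);
# returns transformed design and the matrix T with beta_orig = T beta_std
standardize_design <- function(X) {
  p <- ncol(X)
  Tmat <- diag(p)
  Xs <- X
  icpt <- which(colnames(X) == "(Intercept)")
  for (j in seq_len(p)) {
    if (length(icpt) && j == icpt) next
    xj <- X[, j]
    if (length(unique(xj)) <= 2L) next
    m <- mean(xj); s <- stats::sd(xj)
    if (s == 0) next
    Xs[, j] <- (xj - m) / s
    Tmat[j, j] <- 1 / s
    if (length(icpt)) Tmat[icpt, j] <- -m / s
  }
  list(X = Xs, Tmat = Tmat)
}

#' @export
print.polygenic <- function(x, digits = 3, ...) {
  cat("Polygenic variance-components model (", x$method, ")\n", sep = "")
  cat(sprintf("  n = %d, logLik = %.4f\n", x$n, x$loglik))
  cat(sprintf("  h2 = %.*f (SE %.*f)%s, sigma2_a = %.*f, sigma2_e = %.*f\n",
              digits, x$h2, digits, x$se_h2,
              if (x$boundary) " [boundary]" else "",
              digits, x$sigma2_a, digits, x$sigma2_e))
  cat(sprintf("  LRT (h2 = 0): chi2 = %.*f, p = %.3g\n", digits, x$lrt,
              x$p_value))
  invisible(x)
}

#' Summary of a polygenic model fit
#'
#' @param object A `polygenic` fit.
#' @param ... Unused.
#' @return The object, invisibly, after printing variance components,
#'   heritability with its standard error and boundary-corrected LRT
#'   p-value, and the fixed-effect table (GLS estimates, SEs, Wald z).
#' @export
summary.polygenic <- function(object, ...) {
  print(object)
  se <- sqrt(diag(object$vcov_beta))
  z <- object$beta / se
  tab <- cbind(Estimate = object$beta, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  cat("\nFixed effects:\n")
  stats::printCoefmat(tab, P.values = TRUE, has.Pvalue = TRUE)
  invisible(object)
}

#' @export
coef.polygenic <- function(object, ...) object$beta

#' @export
vcov.polygenic <- function(object, ...) object$vcov_beta

#' @export
logLik.polygenic <- function(object, ...) {
  structure(object$loglik, df = object$df + 2, nobs = object$n,
            class = "logLik")
}

#' @export
fitted.polygenic <- function(object, ...)
  unname(drop(object$X %*% object$beta))

#' @export
residuals.polygenic <- function(object, ...) object$y - fitted(object)

#' @export
confint.polygenic <- function(object, parm = "h2", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- max(0, object$h2 - z * object$se_h2)
  hi <- min(1, object$h2 + z * object$se_h2)
  out <- matrix(c(lo, hi), 1, 2,
                dimnames = list("h2", paste0(100 * c((1 - level) / 2,
                                                     1 - (1 - level) / 2), " %")))
  out
}

#' Simulate phenotypes from a fitted polygenic model
#'
#' Draws from the fitted multivariate normal
#' \eqn{N(X\hat\beta,\; \hat\sigma^2_p[\hat h^2 K + (1-\hat h^2)I])} using the
#' spectral decomposition stored in the fit.
#'
#' @param object A `polygenic` fit.
#' @param nsim Number of replicate phenotype vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns (`sim_1`, ...).
#' @export
simulate.polygenic <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  n <- object$n
  w <- pmax(object$h2 * pmax(object$blocks$values, 0) + (1 - object$h2), 0)
  z <- matrix(stats::rnorm(n * nsim), n, nsim) * sqrt(w * object$sigma2_p)
  out <- as.data.frame(mu + unrotate_blocks(object$blocks, z))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Fit the standard four-covariate-model heritability suite
#'
#' Fits the polygenic model under the four conventional covariate sets used
#' for chronotype heritability reporting: (1) unadjusted; (2) sex + age;
#' (3) sex + age + age^2 + sex:age; (4) sex + age + residence. Each model
#' uses its own complete cases, so `n` can differ across rows.
#'
#' @param phenotypes Data frame with columns `individual_id`, `meq_total`,
#'   `sex`, `age`, and (for model 4) `residence`.
#' @param ped A [pedigree()].
#' @param models Optional named list of model formulas overriding the
#'   standard four.
#' @param method `"ML"` or `"REML"`.
#' @return Object of class `polygenic_suite`: a data frame with one row per
#'   model (`model`, `covariates`, `n`, `h2`, `se_h2`, `sigma2_a`,
#'   `sigma2_e`, `loglik`, `p_value`) and the full fits in
#'   `attr(, "fits")`.
#' @export
polygenic_suite <- function(phenotypes, ped, models = NULL,
                            method = c("ML", "REML")) {
  method <- match.arg(method)
  if (is.null(models)) {
    need <- c("individual_id", "meq_total", "sex", "age", "residence")
    missing_cols <- setdiff(need, names(phenotypes))
    if (length(missing_cols))
      stop("phenotype table lacks column(s): ",
           paste(missing_cols, collapse = ", "))
    models <- list(
      unadjusted = meq_total ~ 1,
      sex_age = meq_total ~ sex + age,
      sex_age_age2_sexage = meq_total ~ sex + age + I(age^2) + sex:age,
      sex_age_residence = meq_total ~ sex + age + residence
    )
  }
  for (v in c("sex", "residence"))
    if (v %in% names(phenotypes) && !is.factor(phenotypes[[v]]))
      phenotypes[[v]] <- factor(phenotypes[[v]])
  K <- kinship(ped)
  fits <- lapply(models, function(f)
    polygenic(f, phenotypes, ped, method = method, K = K))
  tab <- data.frame(
    model = names(models),
    covariates = vapply(models, function(f)
      paste(attr(stats::terms(f), "term.labels"), collapse = " + "),
      character(1)),
    n = vapply(fits, `[[`, integer(1), "n"),
    h2 = vapply(fits, `[[`, numeric(1), "h2"),
    se_h2 = vapply(fits, `[[`, numeric(1), "se_h2"),
    sigma2_a = vapply(fits, `[[`, numeric(1), "sigma2_a"),
    sigma2_e = vapply(fits, `[[`, numeric(1), "sigma2_e"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab$covariates[tab$covariates == ""] <- "none"
  structure(tab, fits = fits, class = c("polygenic_suite", "data.frame"))
}

#' @export
print.polygenic_suite <- function(x, digits = 2, ...) {
  cat("Heritability by covariate model:\n")
  out <- data.frame(
    Covariates = x$covariates, N = x$n,
    `h2 +- SE` = sprintf("%.*f +- %.*f", digits, x$h2, digits, x$se_h2),
    `P-value` = sprintf("%.2g", x$p_value),
    check.names = FALSE
  )
  print(out, row.names = FALSE)
  invisible(x)
}

#' Write a heritability suite to disk
#'
#' @param x A [polygenic_suite()] result.
#' @param path Output path.
#' @param format `"tsv"` or `"json"` (the JSON variant also carries the
#'   fixed-effect estimates per model).
#' @export
write_polygenic_suite <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    fits <- attr(x, "fits")
    payload <- lapply(seq_len(nrow(x)), function(i) {
      row <- as.list(as.data.frame(x)[i, ])
      row$beta <- as.list(fits[[i]]$beta)
      row
    })
    names(payload) <- x$model
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
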