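#' @export
print.reml_fit <- function(x, digits = 4, ...) {
  cat("Multi-kernel REML fit (", x$n, " individuals, ",
      x$n_components, " variance components)\n", sep = "")
  cat(sprintf("  REML logL: %.4f  (%s in %d iterations)\n",
              x$logL_reml,
              if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  tab <- data.frame(sigma2 = signif(x$sigma2, digits),
                    se = signif(x$se_sigma2, digits),
                    h2 = signif(x$h2, digits),
                    bounded = x$bounded)
  print(tab)
  invisible(x)
}

#' Summarize a REML fit
#'
#' @param object a [reml_fit()] object.
#' @param ... unused.
#' @return A list of class `summary.reml_fit` with the variance-component
#'   table, heritabilities, fixed-effect estimates and fit diagnostics.
#' @export
summary.reml_fit <- function(object, ...) {
  h <- heritabilities(object)
  beta_se <- sqrt(diag(object$cov_beta))
  structure(list(
    varcomp = data.frame(component = object$component_names,
                         sigma2 = unname(object$sigma2),
                         se = unname(object$se_sigma2),
                         h2 = unname(h),
                         bounded = unname(object$bounded)),
    total_genetic_h2 = attr(h, "total_genetic"),
    fixef = data.frame(estimate = object$beta, se = beta_se,
                       z = object$beta / beta_se),
    logL_reml = object$logL_reml, converged = object$converged,
    n_iter = object$n_iter, n = object$n),
    class = "summary.reml_fit")
}

#' @export
print.summary.reml_fit <- function(x, digits = 4, ...) {
  cat("Variance components:\n")
  print(format(x$varcomp, digits = digits), row.names = FALSE)
  cat(sprintf("Total genetic h2: %.4f\n", x$total_genetic_h2))
  cat("\nFixed effects (generalized least squares):\n")
  print(format(x$fixef, digits = digits))
  cat(sprintf("\nREML logL %.4f, n = %d, %s in %d iterations\n",
              x$logL_reml, x$n,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' @export
coef.reml_fit <- function(object, ...) object$beta

#' @export
vcov.reml_fit <- function(object, ...) object$cov_beta

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$logL_reml,
            df = object$n_components + length(object$beta),
            nobs = object$n, class = "logLik")
}

#' @export
fitted.reml_fit <- function(object, ...) object$fitted

#' @export
residuals.reml_fit <- function(object, ...) object$y - object$fitted

#' Variance components of a REML fit
#'
#' @param fit a [reml_fit()].
#' @return Named numeric vector of variance-component estimates.
#' @export
varcomp <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  fit$sigma2
}

#' Simulate responses from a fitted variance-component model
#'
#' Draws \eqn{y^* \sim N(X\hat\beta, \hat V)} with
#' \eqn{\hat V = \sum_c \hat\sigma^2_c K_c + \hat\sigma^2_e I}.  Requires
#' the fit to have been made with `keep_kernels = TRUE`.
#'
#' @param object a [reml_fit()].
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns, as [stats::simulate()].
#' @export
simulate.reml_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$kernels) && object$n_components > 1)
    stop("fit was made with keep_kernels = FALSE")
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  k <- object$n_components - 1
  V <- diag(object$sigma2[k + 1], n)
  if (k > 0) for (c in seq_len(k))
    V <- V + object$sigma2[c] * object$kernels[[c]]
  L <- chol(V + diag(1e-10 * sum(object$sigma2), n))
  out <- as.data.frame(
    object$fitted + t(L) %*% matrix(stats::rnorm(n * nsim), n, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
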