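#' Fixed-effects specification
#'
#' Describes how the fixed-effect design matrix is built from a phenotype
#' table: categorical factors (treatment coding, first level reference),
#' continuous covariates, and nested slopes such as a separate age
#' regression within each sex.
#'
#' @param factors character vector of factor column names.
#' @param covariates character vector of continuous column names.
#' @param nested_slopes list of length-2 character vectors
#'   `c(continuous, factor)`, each expanding to one slope column per factor
#'   level.
#' @return A list of class `fixed_effects_spec`.
#' @export
fixed_effects_spec <- function(factors = character(),
                               covariates = character(),
                               nested_slopes = list()) {
  structure(list(factors = factors, covariates = covariates,
                 nested_slopes = nested_slopes),
            class = "fixed_effects_spec")
}

#' Build a fixed-effects design matrix
#'
#' Treatment coding with the first level as reference; nested slopes expand
#' to one covariate column per factor level (zero outside that level).
#' Factors with a single observed level are dropped with a warning, as are
#' columns aliased with earlier ones (rank deficiency detected by pivoted
#' QR).  Rows with missing values in any used column are dropped with a
#' warning.
#'
#' @param pheno data frame with the named columns.
#' @param spec a [fixed_effects_spec()].
#' @return A list: `X` (design matrix incl. intercept), `labels` (column
#'   names), `rows` (indices of `pheno` rows retained), `dropped_columns`.
#' @export
build_design_matrix <- function(pheno, spec = fixed_effects_spec()) {
  stopifnot(inherits(spec, "fixed_effects_spec"))
  used <- unique(c(spec$factors, spec$covariates,
                   unlist(spec$nested_slopes)))
  miss <- setdiff(used, names(pheno))
  if (length(miss)) stop("phenotype table lacks columns: ",
                         paste(miss, collapse = ", "))
  keep <- if (length(used))
    stats::complete.cases(pheno[, used, drop = FALSE])
  else rep(TRUE, nrow(pheno))
  if (!all(keep))
    warning(sum(!keep), " row(s) dropped for missing covariate values")
  ph <- pheno[keep, , drop = FALSE]

  X <- matrix(1, nrow(ph), 1, dimnames = list(NULL, "(Intercept)"))
  dropped <- character()
  for (f in spec$factors) {
    fac <- droplevels(factor(ph[[f]]))
    if (nlevels(fac) < 2) {
      warning("factor '", f, "' has one observed level: dropped")
      dropped <- c(dropped, f)
      next
    }
    mm <- stats::model.matrix(~fac)[, -1, drop = FALSE]
    colnames(mm) <- paste0(f, levels(fac)[-1])
    X <- cbind(X, mm)
  }
  for (v in spec$covariates) {
    X <- cbind(X, stats::setNames(data.frame(as.numeric(ph[[v]])), v))
    colnames(X)[ncol(X)] <- v
  }
  X <- as.matrix(X)
  for (ns in spec$nested_slopes) {
    v <- ns[1]; f <- ns[2]
    fac <- droplevels(factor(ph[[f]]))
    for (lev in levels(fac)) {
      col <- as.numeric(ph[[v]]) * (fac == lev)
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0(v, ".", f, lev)
    }
  }
  storage.mode(X) <- "double"
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    alias <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    warning("aliased column(s) dropped: ", paste(alias, collapse = ", "))
    dropped <- c(dropped, alias)
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  list(X = X, labels = colnames(X), rows = which(keep),
       dropped_columns = dropped)
}

kernel_values <- function(k) {
  v <- if (inherits(k, "grm")) k$values else as.matrix(k)
  (v + t(v)) / 2
}

#' Fit a multi-kernel variance-component mixed model by REML
#'
#' Fits \eqn{y = X\beta + \sum_c u_c + e} with
#' \eqn{u_c \sim N(0, \sigma^2_c K_c)} and \eqn{e \sim N(0, \sigma^2_e I)},
#' maximizing the restricted log-likelihood
#' \deqn{\ell = -\tfrac12\left(\log|V| + \log|X'V^{-1}X| + y'Py\right)}
#' (additive constant omitted) where \eqn{V = \sum_c \sigma^2_c K_c +
#' \sigma^2_e I} and \eqn{P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}}.
#'
#' The optimizer is average-information REML with EM warm-up iterations and
#' step-halving: an AI step that decreases the likelihood or drives a
#' variance negative is halved (negative proposals clamped to zero).
#' Components on the zero bound with negative gradient are held there but
#' kept in the model, so likelihoods remain comparable across models.
#' Convergence is declared when the likelihood improves by less than `tol`.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (default intercept only); must be
#'   full column rank.
#' @param kernels list of covariance kernels (`grm` objects or symmetric
#'   matrices), e.g. `list(genomic = G, regional = Q)`.  The residual
#'   identity kernel is implicit.
#' @param tol convergence tolerance on the REML log-likelihood change.
#' @param max_iter maximum iterations.
#' @param em_iter number of EM warm-up iterations before AI steps.
#' @param fixed_sigma2 optional named numeric vector fixing some components
#'   at given values (two-step mode: e.g. fix the genomic variance from a
#'   genome-only fit).
#' @param keep_kernels retain kernel matrices on the fit (needed by
#'   [simulate.reml_fit()]).
#' @return An object of class `reml_fit`; see [summary.reml_fit()].
#' @export
reml_fit <- function(y, X = NULL, kernels = list(), tol = 1e-6,
                     max_iter = 200, em_iter = 3, fixed_sigma2 = NULL,
                     keep_kernels = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("missing values in y")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("nrow(X) != length(y)")
  if (qr(X)$rank < ncol(X)) stop("X is not full column rank")
  K <- lapply(kernels, kernel_values)
  k <- length(K)
  for (Kc in K) if (!all(dim(Kc) == n))
    stop("kernel dimensions do not match length(y)")
  p <- ncol(X)
  if (n < p + k + 1) stop("too few observations for ", k + 1,
                          " variance components and ", p, " fixed effects")
  comp_names <- names(K)
  if (is.null(comp_names)) comp_names <- rep("", k)
  comp_names[comp_names == ""] <-
    paste0("kernel", seq_len(k))[comp_names == ""]
  comp_names <- c(comp_names, "residual")

  # starting values: OLS residual variance split evenly over components
  r0 <- stats::lm.fit(X, y)$residuals
  s2p0 <- sum(r0^2) / (n - p)
  theta <- rep(s2p0 / (k + 1), k + 1)
  names(theta) <- comp_names
  fixed_mask <- rep(FALSE, k + 1)
  if (!is.null(fixed_sigma2)) {
    j <- match(names(fixed_sigma2), comp_names)
    if (anyNA(j)) stop("fixed_sigma2 names do not match components")
    theta[j] <- fixed_sigma2
    fixed_mask[j] <- TRUE
  }

  eval_at <- function(theta, ridge = 0) {
    V <- diag(theta[k + 1] + ridge, n)
    for (c in seq_len(k)) V <- V + theta[c] * K[[c]]
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) return(NULL)
    Vinv <- chol2inv(L)
    W <- Vinv %*% X
    XtVX <- crossprod(X, W)
    cX <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(cX)) return(NULL)
    P <- Vinv - W %*% chol2inv(cX) %*% t(W)
    Py <- drop(P %*% y)
    logL <- -0.5 * (2 * sum(log(diag(L))) + 2 * sum(log(diag(cX))) +
                    sum(y * Py))
    if (!is.finite(logL)) return(NULL)
    list(logL = logL, P = P, Py = Py, Vinv = Vinv, XtVX = XtVX, cX = cX)
  }
  eval_state <- function(theta) {
    st <- eval_at(theta)
    if (is.null(st)) {
      st <- eval_at(theta, ridge = 1e-8 * sum(theta))
      if (is.null(st)) stop("REML likelihood not finite (singular V)")
    }
    st
  }

  st <- eval_state(theta)
  converged <- FALSE
  iter <- 0
  AI <- NULL
  repeat {
    if (iter >= max_iter) break
    iter <- iter + 1
    P <- st$P; Py <- st$Py
    # per-component quantities: t_c = K_c Py, trace(P K_c), y'P K_c P y
    Tc <- vector("list", k + 1)
    trPK <- numeric(k + 1); yPKPy <- numeric(k + 1)
    for (c in seq_len(k)) {
      Tc[[c]] <- drop(K[[c]] %*% Py)
      trPK[c] <- sum(P * K[[c]])
      yPKPy[c] <- sum(Py * Tc[[c]])
    }
    Tc[[k + 1]] <- Py
    trPK[k + 1] <- sum(diag(P))
    yPKPy[k + 1] <- sum(Py * Py)
    grad <- -0.5 * (trPK - yPKPy)

    PT <- lapply(Tc, function(t) drop(P %*% t))
    AI <- matrix(0, k + 1, k + 1)
    for (c in seq_len(k + 1))
      for (d in c:(k + 1))
        AI[c, d] <- AI[d, c] <- 0.5 * sum(Tc[[c]] * PT[[d]])

    floor_scale <- 1e-8 * sum(theta)
    on_bound <- theta <= floor_scale & grad < 0
    free <- !(on_bound | fixed_mask)
    if (!any(free)) { converged <- TRUE; break }

    if (iter <= em_iter) {
      delta <- theta^2 * (yPKPy - trPK) / n
      delta[!free] <- 0
      prop <- pmax(theta + delta, 0)
      prop[fixed_mask] <- theta[fixed_mask]
      st_new <- eval_at(prop)
      if (!is.null(st_new)) { theta <- prop; st <- st_new }
      next
    }

    dir <- rep(0, k + 1)
    sol <- tryCatch(solve(AI[free, free, drop = FALSE], grad[free]),
                    error = function(e) NULL)
    if (is.null(sol)) sol <- grad[free] / pmax(diag(AI)[free], 1e-12)
    dir[free] <- sol

    step <- 1
    improved <- FALSE
    for (h in 1:30) {
      prop <- theta + step * dir
      prop <- pmax(prop, 0)
      prop[fixed_mask] <- theta[fixed_mask]
      st_new <- eval_at(prop)
      if (!is.null(st_new) && st_new$logL >= st$logL - 1e-12) {
        dL <- st_new$logL - st$logL
        theta <- prop; st <- st_new; improved <- TRUE
        if (dL < tol) converged <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }  # no uphill step exists
    if (converged || iter >= max_iter) break
  }

  s2p <- sum(theta)
  bounded <- theta <= 1e-8 * max(s2p, .Machine$double.eps)
  se <- rep(NA_real_, k + 1)
  if (!is.null(AI)) {
    cov_theta <- tryCatch(solve(AI), error = function(e) NULL)
    if (!is.null(cov_theta)) {
      d <- diag(cov_theta)
      se <- ifelse(d > 0, sqrt(d), NA_real_)
    }
  }
  beta_cov <- chol2inv(st$cX)
  beta <- drop(beta_cov %*% crossprod(X, st$Vinv %*% y))
  names(beta) <- colnames(X)
  dimnames(beta_cov) <- list(colnames(X), colnames(X))
  h2 <- theta / s2p
  fit <- structure(list(
    sigma2 = theta, se_sigma2 = stats::setNames(se, comp_names),
    logL_reml = st$logL, h2 = h2, bounded = bounded,
    converged = converged, n_iter = iter,
    beta = beta, cov_beta = beta_cov,
    fitted = drop(X %*% beta), y = y, X = X,
    n = n, n_components = k + 1,
    component_names = comp_names,
    kernels = if (keep_kernels) K else NULL),
    class = "reml_fit")
  fit
}

#' Likelihood-ratio statistic between nested REML fits
#'
#' `LRT = 2 (logL1 - logL0)`, floored at zero so that tiny numerical
#' deficits of the larger model never produce negative statistics.  The
#' fits must share the response and fixed-effect design (REML likelihoods
#' are only comparable for identical `X`).
#'
#' @param null_fit,alt_fit `reml_fit` objects; the null must be nested in
#'   the alternative (kernel subset).
#' @return The likelihood-ratio test statistic (non-negative scalar).
#' @export
lrt <- function(null_fit, alt_fit) {
  stopifnot(inherits(null_fit, "reml_fit"), inherits(alt_fit, "reml_fit"))
  if (null_fit$n != alt_fit$n ||
      !isTRUE(all.equal(null_fit$y, alt_fit$y, tolerance = 1e-12)))
    stop("fits are not on the same response")
  if (!isTRUE(all.equal(unname(null_fit$X), unname(alt_fit$X),
                        tolerance = 1e-12)))
    stop("fits are not on the same fixed-effect design")
  if (null_fit$n_components > alt_fit$n_components)
    stop("null model has more components than the alternative")
  max(0, 2 * (alt_fit$logL_reml - null_fit$logL_reml))
}

#' Heritability fractions from a REML fit
#'
#' Each variance component divided by the phenotypic variance
#' \eqn{\sigma^2_p = \sum_c \sigma^2_c}; the residual fraction completes
#' the unit sum.  `total_genetic` is the sum of all non-residual fractions
#' (regional plus genomic in a two-kernel window model).
#'
#' @param fit a `reml_fit`.
#' @return Named numeric vector of fractions, with attribute
#'   `"total_genetic"`.
#' @export
heritabilities <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  s2p <- sum(fit$sigma2)
  if (s2p <= 0) stop("phenotypic variance is zero")
  h <- fit$sigma2 / s2p
  attr(h, "total_genetic") <- sum(h[-length(h)])
  h
}
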