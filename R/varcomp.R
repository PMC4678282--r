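#' Variance components of the polygenic model
#'
#' Container for the five parameters of the polygenic covariance
#' decomposition \eqn{\Omega = 2\sigma_a^2\Phi + \sigma_d^2\Delta +
#' \sigma_e^2\Gamma} with separate male/female trait means.
#'
#' @param sigma_a2 additive genetic variance (>= 0).
#' @param sigma_d2 dominance genetic variance (>= 0).
#' @param sigma_e2 environmental variance (>= 0).
#' @param mu_m,mu_f male and female trait means.
#' @return Object of class `variance_components`.
#' @export
variance_components <- function(sigma_a2, sigma_d2 = 0, sigma_e2 = 0,
                                mu_m = 0, mu_f = 0) {
  if (any(c(sigma_a2, sigma_d2, sigma_e2) < 0))
    stop("variance components must be nonnegative")
  if (sigma_a2 + sigma_d2 + sigma_e2 <= 0)
    stop("total variance must be positive")
  structure(list(sigma_a2 = sigma_a2, sigma_d2 = sigma_d2,
                 sigma_e2 = sigma_e2, mu_m = mu_m, mu_f = mu_f),
            class = "variance_components")
}

#' Narrow- and broad-sense heritability implied by variance components
#'
#' @param vc a [variance_components] object (or list with the same fields).
#' @return list with `h2` = \eqn{\sigma_a^2/\sigma_p^2} and `H2` =
#'   \eqn{(\sigma_a^2+\sigma_d^2)/\sigma_p^2}, where \eqn{\sigma_p^2} is the
#'   total variance.
#' @export
heritability <- function(vc) {
  tot <- vc$sigma_a2 + vc$sigma_d2 + vc$sigma_e2
  list(h2 = vc$sigma_a2 / tot, H2 = (vc$sigma_a2 + vc$sigma_d2) / tot)
}

# Group families with identical (Phi, Delta, Gamma) so one Cholesky serves
# the whole group; trait NAs drop the subject by marginalizing the family's
# relatedness block (a multivariate-normal marginal is the sub-matrix).
vc_prepare <- function(blocks, trait, sex) {
  stopifnot(length(trait) == length(sex))
  groups <- list()
  n_used <- 0L
  n_dropped <- 0L
  for (b in blocks) {
    keep <- which(!is.na(trait[b$rows]))
    n_dropped <- n_dropped + length(b$rows) - length(keep)
    if (!length(keep)) next
    rows <- b$rows[keep]
    phi <- b$phi[keep, keep, drop = FALSE]
    delta <- b$delta[keep, keep, drop = FALSE]
    gamma <- b$gamma[keep, keep, drop = FALSE]
    sig <- paste(length(keep),
                 paste(signif(c(phi, delta, gamma), 10), collapse = ","))
    n_used <- n_used + length(keep)
    entry <- groups[[sig]]
    if (is.null(entry)) {
      groups[[sig]] <- list(phi = phi, delta = delta, gamma = gamma,
                            idx = list(rows),
                            male = list(sex[rows] == 1L))
    } else {
      entry$idx[[length(entry$idx) + 1L]] <- rows
      entry$male[[length(entry$male) + 1L]] <- sex[rows] == 1L
      groups[[sig]] <- entry
    }
  }
  groups <- lapply(groups, function(g) {
    g$IDX <- do.call(cbind, g$idx)
    g$Y <- matrix(trait[g$IDX], nrow(g$IDX), ncol(g$IDX))
    g$MALE <- do.call(cbind, g$male)
    g$idx <- g$male <- NULL
    g
  })
  list(groups = groups, n_used = n_used, n_dropped = n_dropped,
       has_male = any(sex[!is.na(trait)] == 1L),
       has_female = any(sex[!is.na(trait)] == 2L))
}

# Re-fill the trait values of a prepared grouping (same NA pattern assumed);
# lets cross-validation reuse one grouping across many derived traits.
vc_refill <- function(prep, trait) {
  prep$groups <- lapply(prep$groups, function(g) {
    g$Y <- matrix(trait[g$IDX], nrow(g$IDX), ncol(g$IDX))
    g
  })
  prep
}

# Blockwise Gaussian log likelihood at theta = (sa2, sd2, se2, mu_m, mu_f).
# Returns NA when some family covariance is not positive definite.
vc_loglik_theta <- function(theta, prep) {
  ll <- 0
  for (g in prep$groups) {
    omega <- 2 * theta[1] * g$phi + theta[2] * g$delta + theta[3] * g$gamma
    ch <- tryCatch(chol(omega), error = function(e) NULL)
    if (is.null(ch)) return(NA_real_)
    r <- g$Y - ifelse(g$MALE, theta[4], theta[5])
    z <- forwardsolve(t(ch), r)
    ll <- ll - 0.5 * (ncol(g$Y) * 2 * sum(log(diag(ch))) + sum(z * z))
  }
  ll
}

# Analytic score of the log likelihood with respect to theta.
vc_score_theta <- function(theta, prep) {
  gr <- numeric(5)
  for (g in prep$groups) {
    omega <- 2 * theta[1] * g$phi + theta[2] * g$delta + theta[3] * g$gamma
    ch <- tryCatch(chol(omega), error = function(e) NULL)
    if (is.null(ch)) return(rep(NA_real_, 5))
    oinv <- chol2inv(ch)
    nfam <- ncol(g$Y)
    r <- g$Y - ifelse(g$MALE, theta[4], theta[5])
    s <- oinv %*% r
    gr[1] <- gr[1] - nfam * sum(oinv * g$phi) + sum((g$phi %*% s) * s)
    gr[2] <- gr[2] - 0.5 * nfam * sum(oinv * g$delta) +
      0.5 * sum((g$delta %*% s) * s)
    gr[3] <- gr[3] - 0.5 * nfam * sum(oinv * g$gamma) +
      0.5 * sum((g$gamma %*% s) * s)
    gr[4] <- gr[4] + sum(s[g$MALE])
    gr[5] <- gr[5] + sum(s[!g$MALE])
  }
  gr
}

#' Log likelihood of a trait under the polygenic model
#'
#' Evaluates the multivariate-normal log likelihood family by family using
#' the block structure of the relatedness matrices; the full sample
#' covariance matrix is never formed. The additive constant
#' \eqn{-(n/2)\log 2\pi} is omitted, as is conventional for
#' variance-components likelihoods (it does not affect the maximizer or
#' likelihood ratios).
#'
#' @param vc a [variance_components] object.
#' @param trait numeric vector, one value per pedigree member (`NA` drops the
#'   subject by marginalization).
#' @param blocks [relatedness_blocks()] for the same pedigree.
#' @param sex integer vector (1 = male, 2 = female), one per member.
#' @return scalar log likelihood.
#' @export
polygenic_loglik <- function(vc, trait, blocks, sex) {
  prep <- vc_prepare(blocks, trait, sex)
  theta <- c(vc$sigma_a2, vc$sigma_d2, vc$sigma_e2, vc$mu_m, vc$mu_f)
  ll <- vc_loglik_theta(theta, prep)
  if (is.na(ll))
    stop("family covariance matrix is not positive definite for these components")
  ll
}

#' Residualize a trait on covariates
#'
#' Ordinary least squares with an intercept; the returned residuals are
#' orthogonal to every covariate column. Heritability of a covariate-adjusted
#' trait is estimated on these residuals.
#'
#' @param trait numeric vector (NAs propagate).
#' @param covariates data.frame or matrix of covariates (no intercept column
#'   needed). `NULL` or zero columns returns the trait unchanged.
#' @return numeric vector of residuals.
#' @export
residualize <- function(trait, covariates) {
  if (is.null(covariates) || NCOL(covariates) == 0) return(trait)
  z <- as.matrix(as.data.frame(covariates))
  storage.mode(z) <- "double"
  zi <- cbind(`(intercept)` = 1, z)
  ok <- stats::complete.cases(zi) & !is.na(trait)
  qz <- qr(zi[ok, , drop = FALSE])
  if (qz$rank < ncol(zi)) {
    bad <- colnames(zi)[qz$pivot[(qz$rank + 1):ncol(zi)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  out <- rep(NA_real_, length(trait))
  out[ok] <- qr.resid(qz, trait[ok])
  out
}

#' Maximum-likelihood polygenic fit and heritability estimate
#'
#' Maximizes the blockwise Gaussian log likelihood over
#' \eqn{(\sigma_a^2, \sigma_d^2, \sigma_e^2, \mu_m, \mu_f)} subject to
#' nonnegative variance components (box-constrained quasi-Newton with the
#' analytic score). Covariates, when given, are removed by least-squares
#' residualization before fitting; sex enters through the separate means.
#' The p-value tests \eqn{\sigma_a^2 = 0} by a likelihood-ratio statistic
#' referred to the boundary mixture \eqn{\tfrac12\chi^2_0 +
#' \tfrac12\chi^2_1}.
#'
#' @param trait numeric vector, one value per pedigree member, or named by
#'   individual id. `NA` drops the subject (count reported).
#' @param pedigree a [pedigree]; ignored when `blocks` is supplied.
#' @param sex per-member sex codes; defaults to the pedigree's `sex` column.
#' @param covariates optional data.frame/matrix of covariates to residualize
#'   out (do not include sex: it is modelled through the means).
#' @param model `"ADE"` (additive + dominance + environment, default) or
#'   `"AE"` (dominance fixed at zero).
#' @param blocks optional precomputed [relatedness_blocks()] (caching hook).
#' @param compute_se report a delta-method observed-information standard
#'   error for h2 (default `TRUE`).
#' @param compute_p report the boundary LRT p-value (default `TRUE`).
#' @param max_iter optimizer iteration cap.
#' @return Object of class `polygenic_fit`: `vc` ([variance_components]),
#'   `h2`, `H2`, `loglik`, `p_value`, `se_h2`, `n_used`, `n_dropped`,
#'   `converged`, `model`.
#' @export
fit_polygenic <- function(trait, pedigree = NULL, sex = NULL,
                          covariates = NULL, model = c("ADE", "AE"),
                          blocks = NULL, compute_se = TRUE, compute_p = TRUE,
                          max_iter = 500) {
  model <- match.arg(model)
  if (is.null(blocks)) {
    if (is.null(pedigree)) stop("supply either a pedigree or relatedness blocks")
    blocks <- relatedness_blocks(pedigree)
  }
  if (is.null(sex)) {
    if (is.null(pedigree)) stop("supply sex when fitting from blocks")
    sex <- pedigree$members$sex
  }
  if (!is.null(names(trait)) && !is.null(pedigree))
    trait <- trait[pedigree$members$individual_id]
  trait <- as.numeric(trait)
  if (sum(!is.na(trait)) < 2) stop("need at least 2 phenotyped subjects")
  if (!is.null(covariates)) trait <- residualize(trait, covariates)
  prep <- vc_prepare(blocks, trait, sex)
  two_means <- prep$has_male && prep$has_female

  fit <- vc_ml(prep, model = model, null_sa2 = FALSE, two_means = two_means,
               max_iter = max_iter)
  her <- heritability(fit$vc)

  p_value <- NA_real_
  if (compute_p) {
    null_fit <- vc_ml(prep, model = model, null_sa2 = TRUE,
                      two_means = two_means, max_iter = max_iter)
    lrt <- max(0, 2 * (fit$loglik - null_fit$loglik))
    p_value <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  se_h2 <- if (compute_se) vc_se_h2(fit, prep, two_means) else NA_real_

  structure(list(vc = fit$vc, h2 = her$h2, H2 = her$H2, loglik = fit$loglik,
                 p_value = p_value, se_h2 = se_h2, n_used = prep$n_used,
                 n_dropped = prep$n_dropped, converged = fit$converged,
                 model = model),
            class = "polygenic_fit")
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat(sprintf("polygenic %s fit: n = %d (dropped %d)\n", x$model, x$n_used,
              x$n_dropped))
  cat(sprintf("  sigma_a2 = %.4f  sigma_d2 = %.4f  sigma_e2 = %.4f\n",
              x$vc$sigma_a2, x$vc$sigma_d2, x$vc$sigma_e2))
  cat(sprintf("  mu_m = %.4f  mu_f = %.4f\n", x$vc$mu_m, x$vc$mu_f))
  cat(sprintf("  h2 = %.4f (se %.4f)  H2 = %.4f  logLik = %.3f  p = %.3g\n",
              x$h2, x$se_h2, x$H2, x$loglik, x$p_value))
  invisible(x)
}

# Map the free parameter vector of a model variant onto full theta.
vc_theta_map <- function(model, null_sa2, two_means) {
  vars <- c(if (!null_sa2) "sa2", if (model == "ADE") "sd2", "se2")
  means <- if (two_means) c("mu_m", "mu_f") else "mu"
  list(
    names = c(vars, means),
    n_var = length(vars),
    expand = function(p) {
      th <- c(0, 0, 0, 0, 0)
      i <- 1L
      if (!null_sa2) { th[1] <- p[i]; i <- i + 1L }
      if (model == "ADE") { th[2] <- p[i]; i <- i + 1L }
      th[3] <- p[i]; i <- i + 1L
      if (two_means) { th[4] <- p[i]; th[5] <- p[i + 1L] }
      else { th[4] <- th[5] <- p[i] }
      th
    },
    reduce_grad = function(g5) {
      out <- c(if (!null_sa2) g5[1], if (model == "ADE") g5[2], g5[3])
      if (two_means) c(out, g5[4], g5[5]) else c(out, g5[4] + g5[5])
    })
}

vc_start <- function(prep, map) {
  y <- unlist(lapply(prep$groups, function(g) as.vector(g$Y)))
  male <- unlist(lapply(prep$groups, function(g) as.vector(g$MALE)))
  mu_m <- if (any(male)) mean(y[male]) else mean(y)
  mu_f <- if (any(!male)) mean(y[!male]) else mean(y)
  v <- stats::var(y - ifelse(male, mu_m, mu_f))
  if (!is.finite(v) || v <= 0) v <- 1
  th <- c(v / 2, v / 4, v / 4, mu_m, mu_f)
  # a null fit re-apportions the additive share to the environment
  nm <- map$names
  p <- numeric(length(nm))
  p[nm == "sa2"] <- th[1]
  p[nm == "sd2"] <- th[2]
  p[nm == "se2"] <- if ("sa2" %in% nm) th[3] else th[1] + th[3]
  p[nm == "mu_m"] <- th[4]
  p[nm == "mu_f"] <- th[5]
  p[nm == "mu"] <- mean(y)
  p
}

vc_ml <- function(prep, model, null_sa2, two_means, max_iter = 500) {
  map <- vc_theta_map(model, null_sa2, two_means)
  start <- vc_start(prep, map)
  bad_value <- 1e10
  negll <- function(p) {
    ll <- vc_loglik_theta(map$expand(p), prep)
    if (is.na(ll)) bad_value else -ll
  }
  neggrad <- function(p) {
    g <- vc_score_theta(map$expand(p), prep)
    if (anyNA(g)) rep(0, length(p)) else -map$reduce_grad(g)
  }
  lower <- c(rep(0, map$n_var), rep(-Inf, length(start) - map$n_var))
  scale <- pmax(abs(start), max(abs(start[seq_len(map$n_var)])) / 10, 1e-3)
  opt <- stats::optim(start, negll, neggrad, method = "L-BFGS-B",
                      lower = lower,
                      control = list(maxit = max_iter, factr = 1e7,
                                     parscale = scale))
  converged <- opt$convergence == 0
  if (!converged)
    warning("polygenic likelihood maximization stopped before convergence (",
            opt$message, "); returning the best iterate")
  th <- map$expand(opt$par)
  list(vc = variance_components(th[1], th[2], th[3], th[4], th[5]),
       loglik = -opt$value, converged = converged,
       par = opt$par, map = map, negll = negll)
}

# Delta-method standard error of h2 from the observed information of the
# free parameters; NA when the information matrix cannot be inverted.
vc_se_h2 <- function(fit, prep, two_means) {
  tryCatch({
    h2_of <- function(p) {
      th <- fit$map$expand(p)
      th[1] / (th[1] + th[2] + th[3])
    }
    hess <- pracma::hessian(fit$negll, fit$par)
    cov <- solve(hess)
    g <- pracma::grad(h2_of, fit$par)
    v <- drop(t(g) %*% cov %*% g)
    if (v < 0) NA_real_ else sqrt(v)
  }, error = function(e) NA_real_)
}
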