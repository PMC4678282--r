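#' Residualize a feature matrix on covariates
#'
#' Replaces the design matrix X by M, the componentwise least-squares
#' residual of each feature on the covariates (with intercept). Deriving a
#' maximally heritable combination from M is equivalent to maximizing the
#' heritability of the covariate-adjusted combined trait: adjusting the
#' trait for fixed effects commutes with adjusting the design matrix.
#'
#' @param X n x d numeric feature matrix.
#' @param Z covariate data.frame/matrix (n rows), or `NULL` for no
#'   correction.
#' @return n x d matrix M with every column orthogonal to every covariate
#'   column and to the intercept.
#' @export
correct_covariates <- function(X, Z) {
  X <- as.matrix(X)
  if (is.null(Z) || NCOL(Z) == 0) return(X)
  z <- as.matrix(as.data.frame(Z))
  storage.mode(z) <- "double"
  stopifnot(nrow(z) == nrow(X))
  zi <- cbind(`(intercept)` = 1, z)
  qz <- qr(zi)
  if (qz$rank < ncol(zi)) {
    bad <- colnames(zi)[qz$pivot[(qz$rank + 1):ncol(zi)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  m <- qr.resid(qz, X)
  dimnames(m) <- dimnames(X)
  m
}

#' Build the per-family design blocks for heritability maximization
#'
#' Assembles the quadratic forms of the optimization problem: with the
#' split-variable parameter vector \eqn{\gamma = (u, v, \mu_m, \mu_f)} and
#' per-family design \eqn{K_i = [X_i^\top, -X_i^\top, m_i, f_i]^\top} (where
#' the indicator vectors carry -1 at the positions of the matching sex), the
#' objective matrix is \eqn{A = \sum_i K_i \Phi_i^{-1} K_i^\top} and the
#' variance-constraint matrix is \eqn{B = K K^\top}. Unrelated singletons
#' contribute to both (for a singleton \eqn{\Phi_i^{-1} = 2}): they inform
#' the total phenotypic variance even though they carry no covariance
#' information.
#'
#' @param X n x d feature matrix (rows aligned with the pedigree members).
#'   Subjects with any missing feature or covariate are dropped with a
#'   message.
#' @param pedigree a [pedigree] covering every row of `X`.
#' @param sex per-member sex codes; defaults to the pedigree's.
#' @param covariates optional covariate table; features are residualized on
#'   it (see [correct_covariates()]) before the blocks are formed.
#' @param standardize z-score the features first (default `TRUE`); weights
#'   are reported on both scales by [hca_fit()].
#' @param blocks optional precomputed [relatedness_blocks()].
#' @return Object of class `hca_blocks` with elements `A`, `B`, `b` (list of
#'   mean-constraint vectors), `K` (stacked design), `M`, `n`, `d`, `n_mu`,
#'   `sex`, `kept`, `center`, `scale`, `feature_names`.
#' @export
hca_blocks <- function(X, pedigree, sex = NULL, covariates = NULL,
                       standardize = TRUE, blocks = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != nrow(pedigree$members))
    stop("feature matrix rows must align with the pedigree members")
  if (is.null(sex)) sex <- pedigree$members$sex
  if (is.null(blocks)) blocks <- relatedness_blocks(pedigree)
  d <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(d))

  keep <- stats::complete.cases(X)
  if (!is.null(covariates))
    keep <- keep & stats::complete.cases(as.data.frame(covariates))
  if (!all(keep))
    message("dropping ", sum(!keep), " subject(s) with missing features/covariates")
  Xk <- X[keep, , drop = FALSE]
  sexk <- sex[keep]

  center <- if (standardize) colMeans(Xk) else rep(0, d)
  scl <- if (standardize) apply(Xk, 2, stats::sd) else rep(1, d)
  if (any(scl == 0)) stop("constant feature column(s): ",
                          paste(colnames(X)[scl == 0], collapse = ", "))
  M <- sweep(sweep(Xk, 2, center), 2, scl, `/`)
  if (!is.null(covariates))
    M <- correct_covariates(M, as.data.frame(covariates)[keep, , drop = FALSE])

  sexes <- sort(unique(sexk))
  if (length(sexes) < 2) {
    warning("only one sex present; collapsing to a single mean parameter")
    ind <- list(rep(TRUE, length(sexk)))
    mean_labels <- "mu"
  } else {
    ind <- list(sexk == 1L, sexk == 2L)
    mean_labels <- c("mu_m", "mu_f")
  }
  n_mu <- length(ind)
  n <- nrow(M)

  K <- rbind(t(M), -t(M),
             do.call(rbind, lapply(ind, function(g) -as.numeric(g))))
  B <- tcrossprod(K)

  # A = sum_i K_i Phi_i^{-1} K_i^T via the block-diagonal kinship inverse
  kept_idx <- which(keep)
  pos <- match(seq_len(nrow(pedigree$members)), kept_idx)  # member -> column
  A <- matrix(0, nrow(K), nrow(K))
  single_cols <- integer(0)
  for (b in blocks) {
    cols <- pos[b$rows]
    present <- !is.na(cols)
    if (!any(present)) next
    cols <- cols[present]
    if (length(cols) == 1L && length(b$rows) == 1L) {
      single_cols <- c(single_cols, cols)
    } else {
      phi_inv <- if (all(present)) b$phi_inv
                 else solve(b$phi[present, present, drop = FALSE])
      Kb <- K[, cols, drop = FALSE]
      A <- A + Kb %*% phi_inv %*% t(Kb)
    }
  }
  if (length(single_cols))
    A <- A + 2 * tcrossprod(K[, single_cols, drop = FALSE])

  bvec <- lapply(seq_len(n_mu), function(g) {
    xbar <- colMeans(M[ind[[g]], , drop = FALSE])
    mu_part <- numeric(n_mu); mu_part[g] <- -1
    c(xbar, -xbar, mu_part)
  })

  structure(list(A = A, B = B, b = bvec, K = K, M = M, n = n, d = d,
                 n_mu = n_mu,
                 mean_labels = mean_labels, sex_ind = ind, sex = sexk,
                 kept = kept_idx, center = center, scale = scl,
                 standardize = standardize,
                 has_covariates = !is.null(covariates),
                 feature_names = colnames(X)),
            class = "hca_blocks")
}

#' Objective of the regularized heritability-maximization program
#'
#' \eqn{f(\gamma) = \gamma^\top A \gamma + \lambda \sum_{j=1}^{2d} \gamma_j},
#' the blockwise kinship-weighted sum of squares plus the l1 penalty (the
#' sum of the split variables equals \eqn{\|w\|_1} at any complementary
#' point).
#'
#' @param gamma parameter vector of length `2d + n_mu`.
#' @param blocks an [hca_blocks()] object.
#' @param lambda regularization weight (>= 0).
#' @return scalar objective value.
#' @export
hca_objective <- function(gamma, blocks, lambda = 0) {
  stopifnot(length(gamma) == 2 * blocks$d + blocks$n_mu)
  drop(crossprod(gamma, blocks$A %*% gamma)) +
    lambda * sum(gamma[seq_len(2 * blocks$d)])
}

# Convexified Lagrangian Hessian: symmetric eigenvalue clipping.
convexify <- function(W, floor_frac = 1e-8) {
  es <- eigen((W + t(W)) / 2, symmetric = TRUE)
  floor_val <- floor_frac * max(1, abs(es$values[1]))
  out <- es$vectors %*% (pmax(es$values, floor_val) * t(es$vectors))
  (out + t(out)) / 2
}

# Convex QP solver: min 1/2 p' W p + g' p  s.t.  E p = b,  p_j >= l_j for
# j in J (other coordinates free), with W positive definite. Primal-dual
# interior-point iteration with infeasible start; returns the solution and
# the multipliers (y for the equalities, z >= 0 for the bounds).
solve_qp <- function(W, g, E, b, l, J, tol = 1e-10, max_iter = 60) {
  m <- length(g)
  k <- nrow(E)
  nJ <- length(J)
  PJ <- function(x) x[J]
  p <- numeric(m)
  y <- numeric(k)
  s <- pmax(p[J] - l, 1)
  z <- rep(1, nJ)
  scale <- max(1, max(abs(g)), max(abs(b)))
  for (it in seq_len(max_iter)) {
    rd <- drop(W %*% p) + g - drop(crossprod(E, y))
    rd[J] <- rd[J] - z
    rp <- drop(E %*% p) - b
    rg <- p[J] - l - s
    mu <- sum(s * z) / nJ
    if (max(abs(rd), abs(rp), abs(rg), mu) < tol * scale) break
    sigma <- if (max(abs(rd), abs(rp), abs(rg)) < tol * scale) 0.1 else 0.2
    rc <- s * z - sigma * mu
    M <- W
    diagM <- diag(M)
    diagM[J] <- diagM[J] + z / s
    diag(M) <- diagM
    rhs1 <- -rd
    rhs1[J] <- rhs1[J] - (rc + z * rg) / s
    KKT <- rbind(cbind(M, -t(E)), cbind(E, matrix(0, k, k)))
    sol <- tryCatch(solve(KKT, c(rhs1, -rp)), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    dp <- sol[seq_len(m)]
    dy <- sol[m + seq_len(k)]
    ds <- dp[J] + rg
    dz <- -(rc + z * ds) / s
    astep <- 0.995 * min(1 / 0.995,
                         if (any(ds < 0)) min(-s[ds < 0] / ds[ds < 0]) else Inf,
                         if (any(dz < 0)) min(-z[dz < 0] / dz[dz < 0]) else Inf)
    p <- p + astep * dp
    y <- y + astep * dy
    s <- s + astep * ds
    z <- z + astep * dz
  }
  list(p = p, y = y, z = z)
}

# One SQP subproblem: minimize the quadratic model of the Lagrangian under
# linearized constraints; returns the step p and subproblem multipliers q
# (quadratic constraint first, then mean constraints, then the 2d sign
# bounds).
qp_subproblem <- function(gamma, alpha, blocks, lambda, floor_frac = 1e-8) {
  d2 <- 2 * blocks$d
  m <- length(gamma)
  cvec <- c(rep(1, d2), rep(0, blocks$n_mu))
  Bg <- drop(blocks$B %*% gamma)
  grad_f <- 2 * drop(blocks$A %*% gamma) + lambda * cvec
  g1 <- sum(gamma * Bg) - blocks$n
  g_mu <- vapply(blocks$b, function(b) sum(b * gamma), numeric(1))

  W <- if (is.na(floor_frac)) {
    # fallback model when the Lagrangian Hessian is hopeless (for example a
    # badly overshot multiplier makes it negative definite): a scaled
    # identity calibrated so the unconstrained step has unit-order length
    diag(max(1, max(abs(grad_f))) / max(1, max(abs(gamma))), m)
  } else {
    convexify(2 * blocks$A - 2 * alpha[1] * blocks$B, floor_frac)
  }
  E <- rbind(2 * Bg, do.call(rbind, blocks$b))
  beq <- c(-g1, -g_mu)
  J <- seq_len(d2)

  sol <- solve_qp(W, grad_f, E, beq, l = -gamma[J], J = J)
  if (is.null(sol) || anyNA(sol$p)) return(NULL)
  q <- c(sol$y, pmax(sol$z, 0))
  list(p = sol$p, q = q, grad_f = grad_f, g1 = g1, g_mu = g_mu, Bg = Bg)
}

# l1 exact-penalty merit function and its constraint-violation part.
merit_violation <- function(gamma, blocks) {
  d2 <- 2 * blocks$d
  g1 <- drop(crossprod(gamma, blocks$B %*% gamma)) - blocks$n
  g_mu <- vapply(blocks$b, function(b) sum(b * gamma), numeric(1))
  abs(g1) + sum(abs(g_mu)) + sum(pmax(0, -gamma[seq_len(d2)]))
}

#' Fit a maximally heritable linear combination by SQP
#'
#' Solves the l1-regularized heritability-maximization program with a
#' sequential quadratic programming loop: at each iteration the Lagrangian
#' is expanded to second order (Hessian \eqn{2\sum_i K_i\Phi_i^{-1}K_i^\top
#' - 2\alpha_1 K K^\top}, convexified by eigenvalue clipping), the
#' constraints are linearized, the convex QP subproblem yields a step and
#' multiplier estimates, and an Armijo backtracking line search on an l1
#' exact-penalty merit function sets the step size. The returned weights are
#' rescaled so the unit-variance constraint holds exactly, with the sign
#' convention that the largest-magnitude weight is positive.
#'
#' @param blocks an [hca_blocks()] object.
#' @param lambda l1 regularization weight (>= 0).
#' @param max_iter iteration cap (default 200).
#' @param tol KKT residual tolerance (stationarity scaled by the gradient
#'   magnitude; constraint violation with the variance constraint scaled by
#'   n; complementarity).
#' @param gamma0,alpha0 optional warm starts; defaults follow the canonical
#'   initialization u = 1, v = 0, means of the unit-weight trait, alpha = 1.
#' @param keep_trace record per-iteration objective/merit values.
#' @return Object of class `hca_model`: `weights` (standardized scale),
#'   `weights_raw` and `raw_offset` (original scale), `mu` (named vector of
#'   sex means of the derived trait), `lambda`, `objective`, `converged`,
#'   `n_iter`, `kkt`, `gamma`, `alpha`, standardization info, `trace`.
#' @export
hca_fit <- function(blocks, lambda = 0, max_iter = 200, tol = 1e-6,
                    gamma0 = NULL, alpha0 = NULL, keep_trace = FALSE) {
  stopifnot(inherits(blocks, "hca_blocks"), lambda >= 0)
  d <- blocks$d
  d2 <- 2 * d
  nmu <- blocks$n_mu
  e <- d2 + 1 + nmu

  if (is.null(gamma0)) {
    y0 <- rowSums(blocks$M)
    mu0 <- vapply(blocks$sex_ind, function(g) mean(y0[g]), numeric(1))
    gamma <- c(rep(1, d), rep(0, d), mu0)
  } else gamma <- gamma0
  alpha <- if (is.null(alpha0)) rep(1, e) else alpha0

  converged <- FALSE
  kkt <- Inf
  rho <- 1
  trace <- if (keep_trace) vector("list", max_iter) else NULL
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    sub <- NULL
    for (floor_frac in c(1e-8, 1e-4, NA)) {
      sub <- qp_subproblem(gamma, alpha, blocks, lambda, floor_frac)
      if (!is.null(sub) &&
          max(abs(sub$p)) <= 1e2 * max(1, max(abs(gamma)))) break
      sub <- NULL
    }
    if (is.null(sub)) break  # subproblem infeasible beyond repair

    kkt <- kkt_residual(gamma, sub$q, sub, blocks, lambda)
    viol0 <- merit_violation(gamma, blocks)
    step_scale <- max(1, max(abs(gamma)))
    if (kkt < tol ||
        (viol0 < 1e-8 * max(1, blocks$n) &&
         max(abs(sub$p)) < 1e-8 * step_scale)) {
      alpha <- sub$q
      converged <- TRUE  # KKT point or fixed point of the iteration
      break
    }

    # exact-penalty weight tracks the current multipliers; it may decrease
    # again once early, poorly scaled multiplier estimates die out
    rho <- max(1.5 * max(abs(sub$q)), 0.5 * rho, 1)
    f0 <- hca_objective(gamma, blocks, lambda)
    merit0 <- f0 + rho * viol0
    descent <- sum(sub$grad_f * sub$p) - rho * viol0
    merit_at <- function(g) hca_objective(g, blocks, lambda) +
      rho * merit_violation(g, blocks)

    s <- 1
    gnext <- NULL
    repeat {
      gnew <- gamma + s * sub$p
      if (merit_at(gnew) <= merit0 + 1e-4 * s * min(0, descent)) {
        gnext <- gnew
        break
      }
      if (s == 1) {
        # second-order correction: the quadratic variance constraint curves
        # away from its linearization (Maratos effect); restore it radially
        g1_new <- drop(crossprod(gnew, blocks$B %*% gnew)) - blocks$n
        grad_g1 <- 2 * sub$Bg
        soc <- gnew - grad_g1 * (g1_new / sum(grad_g1^2))
        d2 <- 2 * blocks$d
        soc[seq_len(d2)] <- pmax(soc[seq_len(d2)], 0)
        if (merit_at(soc) <= merit0 + 1e-4 * min(0, descent)) {
          gnext <- soc
          break
        }
      }
      s <- s / 2
      if (s < 1e-12) break
    }
    if (is.null(gnext)) break  # line-search stall

    gamma <- gnext
    alpha <- alpha + s * (sub$q - alpha)
    if (keep_trace)
      trace[[iter]] <- c(iter = iter, objective = f0, merit_before = merit0,
                         merit_after = merit_at(gnext), step = s, kkt = kkt)
  }

  # exact variance rescale; canonical complementary split and sign
  q2 <- drop(crossprod(gamma, blocks$B %*% gamma))
  if (q2 <= 0) stop("degenerate solution: zero-variance combination")
  gamma <- gamma * sqrt(blocks$n / q2)
  w <- gamma[seq_len(d)] - gamma[d + seq_len(d)]
  if (all(w == 0)) stop("degenerate solution: all-zero weights")
  if (w[which.max(abs(w))] < 0) w <- -w
  y <- drop(blocks$M %*% w)
  mu <- vapply(blocks$sex_ind, function(g) mean(y[g]), numeric(1))
  names(mu) <- blocks$mean_labels
  gamma <- c(pmax(w, 0), pmax(-w, 0), mu)
  objective <- hca_objective(gamma, blocks, lambda)

  names(w) <- blocks$feature_names
  weights_raw <- w / blocks$scale
  raw_offset <- -sum(w * blocks$center / blocks$scale)

  structure(list(weights = w, weights_raw = weights_raw,
                 raw_offset = raw_offset, mu = mu, lambda = lambda,
                 objective = objective, converged = converged,
                 n_iter = iter, kkt = kkt, gamma = gamma, alpha = alpha,
                 center = blocks$center, scale = blocks$scale,
                 standardize = blocks$standardize,
                 has_covariates = blocks$has_covariates,
                 feature_names = blocks$feature_names,
                 n = blocks$n, d = d,
                 trace = if (keep_trace)
                   do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
                 else NULL),
            class = "hca_model")
}

# KKT residual of the original nonlinear program at gamma with multiplier
# estimates q; stationarity and complementarity are scaled by the gradient
# magnitude, the variance constraint by n.
kkt_residual <- function(gamma, q, sub, blocks, lambda) {
  d2 <- 2 * blocks$d
  nmu <- blocks$n_mu
  grad_g <- cbind(2 * sub$Bg, do.call(cbind, blocks$b),
                  diag(length(gamma))[, seq_len(d2), drop = FALSE])
  stat <- sub$grad_f - drop(grad_g %*% q)
  scale_f <- max(1, max(abs(sub$grad_f)))
  comp <- if (d2 > 0)
    max(abs(q[1 + nmu + seq_len(d2)] * gamma[seq_len(d2)])) else 0
  max(max(abs(stat)) / scale_f,
      abs(sub$g1) / max(1, blocks$n),
      max(abs(sub$g_mu)),
      max(0, -min(gamma[seq_len(d2)])),
      comp / scale_f)
}

#' @export
print.hca_model <- function(x, ...) {
  cat(sprintf("heritable-component model: d = %d, lambda = %g, n = %d\n",
              x$d, x$lambda, x$n))
  cat(sprintf("  objective = %.4f, converged = %s (%d iterations, kkt %.2e)\n",
              x$objective, x$converged, x$n_iter, x$kkt))
  cat(sprintf("  nonzero weights: %d of %d\n",
              sum(abs(x$weights) > 1e-8), x$d))
  invisible(x)
}

#' Apply a fitted model to feature data
#'
#' Pure projection: standardizes `X` with the training-time center/scale and
#' returns \eqn{y = X w}. No refit is needed for held-out subjects.
#'
#' @param model an [hca_fit()] result.
#' @param X feature matrix with the model's `d` columns (matched by name
#'   when column names are present).
#' @param sex optional per-subject sex codes; when given, the sex-centered
#'   residual `y - mu_sex` is returned instead.
#' @return numeric trait vector (NA where features are missing).
#' @export
derive_trait <- function(model, X, sex = NULL) {
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && all(model$feature_names %in% colnames(X)))
    X <- X[, model$feature_names, drop = FALSE]
  if (ncol(X) != model$d)
    stop("feature count mismatch: model has ", model$d, ", data has ", ncol(X))
  storage.mode(X) <- "double"
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  y <- drop(Xs %*% model$weights)
  if (!is.null(sex)) {
    if (length(model$mu) == 2)
      y <- y - ifelse(sex == 1L, model$mu[["mu_m"]], model$mu[["mu_f"]])
    else y <- y - model$mu[[1]]
  }
  y
}
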