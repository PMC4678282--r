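# Independent oracles: dense multivariate-normal likelihood, dense design
# assembly, feasible-circle grid search at d = 2, and exhaustive active-set
# enumeration for the QP subproblem. These deliberately use naive dense
# linear algebra, not the package's blockwise code paths.

# log N(y; mu, Sigma) without the -(n/2) log 2*pi constant
dense_mvn_loglik <- function(y, mu, sigma) {
  r <- y - mu
  -0.5 * as.numeric(determinant(sigma, logarithm = TRUE)$modulus) -
    0.5 * drop(t(r) %*% solve(sigma) %*% r)
}

# Dense assembly of sum_i H_i Phi_i^{-1} H_i^T from raw ingredients: the
# full block-diagonal Phi^{-1} is materialized explicitly.
dense_quadform_oracle <- function(M, sex, blocks_list) {
  n <- nrow(M)
  H <- rbind(t(M), -as.numeric(sex == 1L), -as.numeric(sex == 2L))
  phi_inv_full <- matrix(0, n, n)
  for (b in blocks_list)
    phi_inv_full[b$rows, b$rows] <- solve(b$phi)
  H %*% phi_inv_full %*% t(H)
}

# Feasible points of the d = 2 problem form a circle of directions; scan it.
grid_oracle_d2 <- function(hb, lambda, n_points = 3600) {
  stopifnot(hb$d == 2)
  best <- Inf
  for (theta in seq(0, pi, length.out = n_points)) {  # w and -w are equivalent
    w <- c(cos(theta), sin(theta))
    y <- drop(hb$M %*% w)
    mu <- vapply(hb$sex_ind, function(g) mean(y[g]), numeric(1))
    resid <- y
    for (g in seq_along(hb$sex_ind))
      resid[hb$sex_ind[[g]]] <- resid[hb$sex_ind[[g]]] - mu[g]
    scale <- sqrt(hb$n / sum(resid^2))
    gamma <- scale * c(pmax(w, 0), pmax(-w, 0), mu)
    val <- hca_objective(gamma, hb, lambda)
    if (val < best) best <- val
  }
  best
}

# Exhaustive active-set enumeration for the QP subproblem:
# min 1/2 p' W p + g' p s.t. E p = b, p_j >= l_j (j in J). For every subset
# S of J, solve the equality-constrained KKT system with the bounds in S
# tight, and keep the best primal-dual feasible solution.
qp_enumeration_oracle <- function(W, g, E, b, l, J) {
  m <- length(g)
  best <- NULL
  for (mask in 0:(2^length(J) - 1)) {
    S <- J[bitwAnd(mask, 2^(seq_along(J) - 1)) > 0]
    G <- rbind(E, diag(m)[S, , drop = FALSE])
    rhs <- c(b, l[match(S, J)])
    KKT <- rbind(cbind(W, t(G)), cbind(G, matrix(0, nrow(G), nrow(G))))
    sol <- tryCatch(solve(KKT, c(-g, rhs)), error = function(e) NULL)
    if (is.null(sol)) next
    p <- sol[seq_len(m)]
    mult <- -sol[m + nrow(E) + seq_along(S)]
    if (any(p[J] < l - 1e-8)) next              # primal feasibility
    if (length(S) && any(mult < -1e-8)) next    # dual feasibility
    val <- 0.5 * drop(t(p) %*% W %*% p) + sum(g * p)
    if (is.null(best) || val < best$value)
      best <- list(p = p, value = val)
  }
  best
}
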