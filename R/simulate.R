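#' Simulation scenario
#'
#' All knobs of the synthetic-data protocol: a sample of about `n_total`
#' subjects of which about `n_in_families` sit in small nuclear families
#' (two founder parents plus children, total size drawn uniformly from
#' `family_size_range`) and the rest are unrelated singletons; a
#' family-correlated trait drawn from the polygenic model with components
#' `vc`; `d_relevant` features carrying an implanted linear model with
#' nonzero weights plus `d_total - d_relevant` irrelevant standard-normal
#' features; and optional fixed covariate effects on a second trait.
#'
#' @param n_total total number of subjects.
#' @param n_in_families subjects belonging to nuclear families.
#' @param family_size_range inclusive range of nuclear-family sizes.
#' @param vc [variance_components] of the simulated trait (defaults imply
#'   narrow-sense heritability 0.8).
#' @param d_relevant number of features with nonzero implanted weights.
#' @param d_total total number of features (>= `d_relevant`).
#' @param true_weights optional length-`d_relevant` nonzero weights; when
#'   `NULL` they are drawn once per dataset with magnitudes uniform on
#'   [0.5, 1.5] and random signs (bounded away from zero, as the balancing
#'   construction divides by them).
#' @param covariate_effects named vector `c(age = ..., race = ...)` of fixed
#'   effects added to form the second trait.
#' @param n_drop_relevant how many relevant feature columns to remove
#'   (sensitivity scenario, 0-5).
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_total = 6810, n_in_families = 1915,
                         family_size_range = c(3, 6),
                         vc = variance_components(0.8, 0.1, 0.1, 0.9, 0.3),
                         d_relevant = 10, d_total = 10, true_weights = NULL,
                         covariate_effects = c(age = 1.1, race = 0.7),
                         n_drop_relevant = 0) {
  stopifnot(n_in_families <= n_total, d_total >= d_relevant,
            n_drop_relevant >= 0, n_drop_relevant <= d_relevant)
  if (!is.null(true_weights)) {
    stopifnot(length(true_weights) == d_relevant)
    if (any(true_weights == 0)) stop("true weights must be nonzero")
  }
  structure(list(n_total = n_total, n_in_families = n_in_families,
                 family_size_range = family_size_range, vc = vc,
                 d_relevant = d_relevant, d_total = d_total,
                 true_weights = true_weights,
                 covariate_effects = covariate_effects,
                 n_drop_relevant = n_drop_relevant),
            class = "sim_scenario")
}

#' Synthesize a pedigree of nuclear families plus singletons
#'
#' Families of two founder parents and children are generated with sizes
#' drawn uniformly from the scenario's range until the family-member count
#' reaches `n_in_families` (the last family may overshoot by a few members);
#' the remaining subjects are unrelated singletons. Children's sex is
#' Bernoulli(1/2); every subject receives an integer age uniform on 18-65
#' and a binary race code Bernoulli(1/2), carried as extra member columns.
#'
#' @param scenario a [sim_scenario].
#' @param seed optional integer seed (restores the RNG state afterwards).
#' @return A [pedigree] with extra member columns `age` and `race`.
#' @export
synth_pedigree <- function(scenario = sim_scenario(), seed = NULL) {
  if (!is.null(seed)) return(withr::with_seed(seed, synth_pedigree(scenario)))
  lo <- scenario$family_size_range[1]
  hi <- scenario$family_size_range[2]
  rows <- list()
  fam_members <- 0L
  f <- 0L
  while (fam_members < scenario$n_in_families) {
    f <- f + 1L
    size <- sample(lo:hi, 1L)
    size <- min(size, scenario$n_total - fam_members)
    if (size < 3L) break
    fid <- sprintf("F%04d", f)
    father <- paste0(fid, "_1"); mother <- paste0(fid, "_2")
    kids <- paste0(fid, "_", 2L + seq_len(size - 2L))
    rows[[length(rows) + 1L]] <- data.frame(
      family_id = fid,
      individual_id = c(father, mother, kids),
      father_id = c(NA, NA, rep(father, size - 2L)),
      mother_id = c(NA, NA, rep(mother, size - 2L)),
      sex = c(1L, 2L, sample(1:2, size - 2L, replace = TRUE)),
      stringsAsFactors = FALSE)
    fam_members <- fam_members + size
  }
  n_single <- scenario$n_total - fam_members
  if (n_single < 0) stop("infeasible scenario counts")
  if (n_single > 0) {
    sid <- sprintf("S%05d", seq_len(n_single))
    rows[[length(rows) + 1L]] <- data.frame(
      family_id = sid, individual_id = sid,
      father_id = NA_character_, mother_id = NA_character_,
      sex = sample(1:2, n_single, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  members <- do.call(rbind, rows)
  members$age <- sample(18:65, nrow(members), replace = TRUE)
  members$race <- stats::rbinom(nrow(members), 1, 0.5)
  pedigree(members, validate = FALSE)
}

#' Draw a family-correlated trait from the polygenic model
#'
#' Each family's trait vector is drawn from \eqn{N(\mu, \Omega)} with
#' \eqn{\Omega = 2\sigma_a^2\Phi + \sigma_d^2\Delta + \sigma_e^2 I} and mean
#' entries \eqn{\mu_m}/\eqn{\mu_f} by member sex; singletons are univariate
#' normal with the total variance.
#'
#' @param pedigree a [pedigree].
#' @param vc [variance_components].
#' @param seed optional integer seed.
#' @param blocks optional precomputed [relatedness_blocks()].
#' @return numeric trait vector aligned with the pedigree members.
#' @export
simulate_trait <- function(pedigree, vc = variance_components(0.8, 0.1, 0.1, 0.9, 0.3),
                           seed = NULL, blocks = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, simulate_trait(pedigree, vc, blocks = blocks)))
  if (is.null(blocks)) blocks <- relatedness_blocks(pedigree)
  sex <- pedigree$members$sex
  n <- nrow(pedigree$members)
  tot <- vc$sigma_a2 + vc$sigma_d2 + vc$sigma_e2
  y <- numeric(n)
  mu <- ifelse(sex == 1L, vc$mu_m, vc$mu_f)
  singles <- vapply(blocks, function(b) length(b$rows) == 1L, logical(1))
  srows <- unlist(lapply(blocks[singles], `[[`, "rows"))
  # draw in member order so results do not depend on the family/singleton mix
  chol_cache <- list()
  for (b in blocks) {
    m <- length(b$rows)
    if (m == 1L) {
      y[b$rows] <- mu[b$rows] + stats::rnorm(1L, sd = sqrt(tot))
    } else {
      sig <- paste(signif(c(b$phi, b$delta, b$gamma), 10), collapse = ",")
      ch <- chol_cache[[sig]]
      if (is.null(ch)) {
        omega <- 2 * vc$sigma_a2 * b$phi + vc$sigma_d2 * b$delta +
          vc$sigma_e2 * b$gamma
        # eigen square root: valid also for singular omega (e.g. identical
        # twins with no environmental variance)
        es <- eigen(omega, symmetric = TRUE)
        if (min(es$values) < -1e-8 * max(abs(es$values)))
          stop("family covariance is not positive semidefinite")
        ch <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
        chol_cache[[sig]] <- ch
      }
      y[b$rows] <- mu[b$rows] + drop(ch %*% stats::rnorm(m))
    }
  }
  y
}

#' Implant a linear feature model around a trait
#'
#' For each subject one of the `length(true_weights)` relevant features is
#' picked uniformly as the balancing feature; the others are drawn i.i.d.
#' standard normal and the balancing one is set to
#' \eqn{(y - \sum_{j \ne k} w_j x_j)/w_k}, so that \eqn{X w = y} holds
#' exactly. Columns beyond the relevant block are irrelevant i.i.d. standard
#' normal with implied weight zero.
#'
#' @param y trait vector.
#' @param true_weights nonzero weights of the relevant features.
#' @param d_total total number of feature columns.
#' @param seed optional integer seed.
#' @return `length(y)` x `d_total` matrix with columns `F1..Fd`.
#' @export
simulate_features <- function(y, true_weights, d_total = length(true_weights),
                              seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, simulate_features(y, true_weights, d_total)))
  if (any(true_weights == 0)) stop("true weights must be nonzero")
  d_rel <- length(true_weights)
  stopifnot(d_total >= d_rel)
  n <- length(y)
  x <- matrix(stats::rnorm(n * d_rel), n, d_rel)
  k <- sample.int(d_rel, n, replace = TRUE)
  ik <- cbind(seq_len(n), k)
  partial <- drop(x %*% true_weights) - true_weights[k] * x[ik]
  x[ik] <- (y - partial) / true_weights[k]
  if (d_total > d_rel)
    x <- cbind(x, matrix(stats::rnorm(n * (d_total - d_rel)), n))
  colnames(x) <- paste0("F", seq_len(d_total))
  x
}

#' Add fixed covariate effects to a trait
#'
#' @param y1 base trait.
#' @param age,race covariate vectors.
#' @param c1,c2 effect sizes for age and race.
#' @return `y1 + c1 * age + c2 * race`.
#' @export
add_covariate_effects <- function(y1, age, race, c1 = 1.1, c2 = 0.7) {
  stopifnot(length(age) == length(y1), length(race) == length(y1))
  y1 + c1 * age + c2 * race
}

#' Remove randomly chosen relevant feature columns
#'
#' Sensitivity scenario: the implanted linear model is broken by deleting
#' `n_drop` of the relevant columns.
#'
#' @param x feature matrix from [simulate_features()].
#' @param n_drop how many relevant columns to remove.
#' @param d_relevant number of leading relevant columns.
#' @param seed optional integer seed.
#' @return list with `x` (reduced matrix) and `dropped` (column indices).
#' @export
drop_relevant_features <- function(x, n_drop, d_relevant = 10, seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, drop_relevant_features(x, n_drop, d_relevant)))
  if (n_drop > d_relevant) stop("cannot drop more than the relevant features")
  if (n_drop == 0) return(list(x = x, dropped = integer(0)))
  dropped <- sort(sample.int(d_relevant, n_drop))
  list(x = x[, -dropped, drop = FALSE], dropped = dropped)
}

#' Weight- and trait-recovery error of a fitted model
#'
#' Compares the learned combination against the implanted one after
#' matching sign and scale: the learned raw-scale weights are sign-aligned
#' with the true weights and rescaled so both derived traits have equal
#' sample variance (both conventions normalize to a unit-variance trait).
#' Reports the squared weight distance and the sum of squared residuals
#' between the (mean-centered) derived and simulated traits.
#'
#' @param model an [hca_fit()] result.
#' @param X feature matrix on the original scale.
#' @param w_true implanted weights (original scale, relevant features
#'   first); padded with zeros to `ncol(X)` when shorter.
#' @param y_true the simulated trait.
#' @return list with `se_w` (squared weight distance), `se_trait` (trait
#'   residual sum of squares) and `w_matched` (the matched learned weights).
#' @export
weight_recovery_error <- function(model, X, w_true, y_true) {
  X <- as.matrix(X)
  if (length(w_true) < ncol(X))
    w_true <- c(w_true, rep(0, ncol(X) - length(w_true)))
  w_hat <- model$weights_raw
  if (sum(w_true * w_hat) < 0) w_hat <- -w_hat
  v_true <- stats::var(drop(X %*% w_true))
  v_hat <- stats::var(drop(X %*% w_hat))
  w_hat <- w_hat * sqrt(v_true / v_hat)
  y_hat <- drop(X %*% w_hat)
  list(se_w = sum((w_true - w_hat)^2),
       se_trait = sum((y_true - mean(y_true) - (y_hat - mean(y_hat)))^2),
       w_matched = w_hat)
}

#' Generate a complete synthetic dataset
#'
#' Runs the full protocol: pedigree with sex/age/race, family-correlated
#' trait `y1`, implanted feature matrix `X` with `y1 = X w` exact, second
#' trait `y2 = y1 + c1 age + c2 race`, and optional relevant-feature
#' removal. Bit-reproducible from (`scenario`, `seed`).
#'
#' @param scenario a [sim_scenario].
#' @param seed integer seed.
#' @return Object of class `sim_dataset`: `pedigree`, `blocks`, `sex`,
#'   `age`, `race`, `y1`, `y2`, `X` (after any dropping), `X_full`,
#'   `true_weights`, `dropped`, `scenario`, `seed`.
#' @export
simulate_dataset <- function(scenario = sim_scenario(), seed = 1L) {
  withr::with_seed(seed, {
    ped <- synth_pedigree(scenario)
    blocks <- relatedness_blocks(ped)
    w <- scenario$true_weights
    if (is.null(w))
      w <- stats::runif(scenario$d_relevant, 0.5, 1.5) *
        sample(c(-1, 1), scenario$d_relevant, replace = TRUE)
    y1 <- simulate_trait(ped, scenario$vc, blocks = blocks)
    x <- simulate_features(y1, w, scenario$d_total)
    y2 <- add_covariate_effects(y1, ped$members$age, ped$members$race,
                                scenario$covariate_effects[["age"]],
                                scenario$covariate_effects[["race"]])
    drop <- drop_relevant_features(x, scenario$n_drop_relevant,
                                   scenario$d_relevant)
    structure(list(pedigree = ped, blocks = blocks,
                   sex = ped$members$sex, age = ped$members$age,
                   race = ped$members$race, y1 = y1, y2 = y2,
                   X = drop$x, X_full = x, true_weights = w,
                   dropped = drop$dropped, scenario = scenario, seed = seed),
              class = "sim_dataset")
  })
}
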