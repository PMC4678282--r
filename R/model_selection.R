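#' Family-aware k-fold split
#'
#' Assigns whole families to folds so that no family is ever split across
#' training and validation. Multi-member families and unrelated singletons
#' are shuffled and dealt round-robin into the folds separately, balancing
#' the counts of each kind across folds whenever possible.
#'
#' @param pedigree a [pedigree].
#' @param k number of folds (>= 2).
#' @param seed optional integer seed (deterministic assignment).
#' @return integer vector of fold labels (1..k), one per pedigree member,
#'   with the per-family assignment as attribute `"family_fold"`.
#' @export
family_aware_split <- function(pedigree, k = 3, seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, family_aware_split(pedigree, k)))
  stopifnot(k >= 2)
  sizes <- lengths(pedigree$families)
  fam_ids <- names(pedigree$families)
  if (length(fam_ids) < k) stop("fewer families than folds")
  multi <- fam_ids[sizes > 1]
  single <- fam_ids[sizes == 1]
  if (length(multi) && length(multi) < k)
    warning("fewer multi-member families (", length(multi),
            ") than folds (", k, ")")
  deal <- function(ids) {
    if (!length(ids)) return(integer(0))
    stats::setNames(rep_len(seq_len(k), length(ids)), sample(ids))
  }
  fam_fold <- c(deal(multi), deal(single))
  fold <- fam_fold[pedigree$members$family_id]
  names(fold) <- pedigree$members$individual_id
  attr(fold, "family_fold") <- fam_fold
  fold
}

# Subset precomputed relatedness blocks to whole families, remapping the
# member row indices to the subset ordering.
subset_blocks <- function(blocks, pedigree, family_ids) {
  keep_rows <- which(pedigree$members$family_id %in% family_ids)
  fams <- pedigree$members$family_id[vapply(blocks, function(b) b$rows[1],
                                            integer(1))]
  out <- lapply(blocks[fams %in% family_ids], function(b) {
    b$rows <- match(b$rows, keep_rows)
    b
  })
  structure(out, class = "relatedness_blocks")
}

#' Cross-validate the regularization weight
#'
#' Repeats family-aware k-fold cross-validation over a lambda grid: for each
#' (repeat, fold), the heritable-component model is fitted on the training
#' folds by [hca_fit()] (features standardized on the training folds only;
#' covariates, when given, residualized out of the training design), the
#' held-out subjects' trait is derived by pure projection, and its
#' narrow-sense heritability is estimated on the validation fold by the
#' polygenic maximum-likelihood model (sex through the means, other
#' covariates residualized). The selected lambda maximizes the mean
#' validation heritability; ties go to the smallest lambda.
#'
#' @param X n x d feature matrix aligned with the pedigree members.
#' @param pedigree a [pedigree].
#' @param sex per-member sex codes; defaults to the pedigree's.
#' @param covariates optional covariate data.frame (n rows), used both for
#'   design-matrix correction and validation heritability estimation.
#' @param k folds (default 3).
#' @param repeats random splits (default 10).
#' @param lambda_grid lambda values (default `0:50`).
#' @param seed integer seed controlling all splits.
#' @param warm_start reuse the previous lambda's solution as the SQP start
#'   along the grid (default `TRUE`; a non-converged warm fit is retried
#'   from the canonical start).
#' @param blocks optional precomputed [relatedness_blocks()].
#' @return Object of class `hca_cv`: `results` (data.frame lambda, repeat,
#'   fold, h2_val, p_value), `summary` (lambda, mean_h2, sd_h2 across
#'   repeat means, n_ok), `best_lambda`.
#' @export
cross_validate <- function(X, pedigree, sex = NULL, covariates = NULL,
                           k = 3, repeats = 10, lambda_grid = 0:50,
                           seed = 1L, warm_start = TRUE, blocks = NULL) {
  X <- as.matrix(X)
  if (is.null(sex)) sex <- pedigree$members$sex
  if (is.null(blocks)) blocks <- relatedness_blocks(pedigree)
  covariates <- if (!is.null(covariates)) as.data.frame(covariates)
  lambda_grid <- sort(unique(lambda_grid))
  split_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, repeats))

  members <- pedigree$members
  res <- list()
  for (r in seq_len(repeats)) {
    fold <- family_aware_split(pedigree, k, seed = split_seeds[r])
    fam_fold <- attr(fold, "family_fold")
    for (f in seq_len(k)) {
      tr_f <- names(fam_fold)[fam_fold != f]
      va_f <- names(fam_fold)[fam_fold == f]
      tr_rows <- which(members$family_id %in% tr_f)
      va_rows <- which(members$family_id %in% va_f)
      ped_tr <- subset_pedigree(pedigree, tr_f)
      bl_tr <- subset_blocks(blocks, pedigree, tr_f)
      bl_va <- subset_blocks(blocks, pedigree, va_f)
      hb <- hca_blocks(X[tr_rows, , drop = FALSE], ped_tr,
                       covariates = covariates[tr_rows, , drop = FALSE],
                       blocks = bl_tr)
      va_sizes <- vapply(bl_va, function(b) length(b$rows), integer(1))
      if (!any(va_sizes > 1)) {
        warning("fold ", f, " of repeat ", r,
                " has no multi-member family; excluded")
        next
      }
      prep_va <- NULL
      prev <- NULL
      for (lam in lambda_grid) {
        model <- tryCatch({
          m <- if (warm_start && !is.null(prev))
            hca_fit(hb, lam, gamma0 = prev$gamma, alpha0 = prev$alpha)
          else hca_fit(hb, lam)
          if (!m$converged && warm_start && !is.null(prev))
            m <- hca_fit(hb, lam)
          m
        }, error = function(e) NULL)
        if (is.null(model)) next
        prev <- model
        y_va <- derive_trait(model, X[va_rows, , drop = FALSE])
        if (!is.null(covariates))
          y_va <- residualize(y_va, covariates[va_rows, , drop = FALSE])
        if (is.null(prep_va)) {
          prep_va <- vc_prepare(bl_va, y_va, sex[va_rows])
        } else prep_va <- vc_refill(prep_va, y_va)
        two_means <- prep_va$has_male && prep_va$has_female
        fit <- vc_ml(prep_va, model = "ADE", null_sa2 = FALSE,
                     two_means = two_means)
        null_fit <- vc_ml(prep_va, model = "ADE", null_sa2 = TRUE,
                          two_means = two_means)
        lrt <- max(0, 2 * (fit$loglik - null_fit$loglik))
        res[[length(res) + 1L]] <- data.frame(
          lambda = lam, rep = r, fold = f,
          h2_val = heritability(fit$vc)$h2,
          p_value = 0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE))
      }
    }
  }
  results <- do.call(rbind, res)
  if (is.null(results)) stop("cross-validation produced no results")

  rep_means <- stats::aggregate(h2_val ~ lambda + rep, results, mean)
  summ <- do.call(rbind, lapply(split(rep_means, rep_means$lambda), function(g)
    data.frame(lambda = g$lambda[1], mean_h2 = mean(g$h2_val),
               sd_h2 = stats::sd(g$h2_val), n_ok = nrow(g))))
  summ <- summ[order(summ$lambda), , drop = FALSE]
  rownames(summ) <- NULL
  best <- summ$lambda[which.max(summ$mean_h2)]  # ties: first = smallest

  structure(list(results = results, summary = summ, best_lambda = best,
                 k = k, repeats = repeats, lambda_grid = lambda_grid,
                 seed = seed),
            class = "hca_cv")
}

#' @export
print.hca_cv <- function(x, ...) {
  i <- which(x$summary$lambda == x$best_lambda)
  cat(sprintf(paste0("cross-validation: %d-fold x %d repeats over %d lambda",
                     " values\n  best lambda = %g with mean validation h2 =",
                     " %.3f (sd %.3f)\n"),
              x$k, x$repeats, length(x$lambda_grid), x$best_lambda,
              x$summary$mean_h2[i], x$summary$sd_h2[i]))
  invisible(x)
}

#' Heritability of a derived trait on held-out subjects
#'
#' Projects the fitted model onto the test features and estimates the
#' narrow-sense heritability of the resulting trait on the test pedigree.
#' At least one multi-member family is required: on singletons alone the
#' genetic covariance is unidentifiable.
#'
#' @param model an [hca_fit()] result.
#' @param X_test feature matrix aligned with the test pedigree members.
#' @param pedigree_test test [pedigree] (families disjoint from training).
#' @param sex per-member sex; defaults to the pedigree's.
#' @param covariates optional covariate data.frame for the test subjects.
#' @param ... passed to [fit_polygenic()].
#' @return A `polygenic_fit`.
#' @export
evaluate_holdout <- function(model, X_test, pedigree_test, sex = NULL,
                             covariates = NULL, ...) {
  if (all(lengths(pedigree_test$families) == 1))
    stop("heritability is not estimable on singletons only: ",
         "no family carries genetic covariance information")
  y <- derive_trait(model, X_test)
  fit_polygenic(y, pedigree_test, sex = sex, covariates = covariates, ...)
}
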