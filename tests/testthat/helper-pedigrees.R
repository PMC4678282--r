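# Minimal pedigrees encoding the canonical relationship pairs, plus small
# constructors shared across test files.

ped_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(family_id = "f1", individual_id = r[[1]],
               father_id = if (r[[2]] == "0") NA else r[[2]],
               mother_id = if (r[[3]] == "0") NA else r[[3]],
               sex = as.integer(r[[4]]), stringsAsFactors = FALSE)))
}

# Each entry: family members + the pair of ids whose (phi, delta) the
# relationship row asserts.
relationship_pedigrees <- function() {
  list(
    parent_child = list(
      fam = ped_df(list("f", "0", "0", 1), list("m", "0", "0", 2),
                   list("c", "f", "m", 1)),
      pair = c("f", "c"), phi = 1 / 4, delta = 0),
    full_siblings = list(
      fam = ped_df(list("f", "0", "0", 1), list("m", "0", "0", 2),
                   list("c1", "f", "m", 1), list("c2", "f", "m", 2)),
      pair = c("c1", "c2"), phi = 1 / 4, delta = 1 / 4),
    half_siblings = list(
      fam = ped_df(list("f", "0", "0", 1), list("m1", "0", "0", 2),
                   list("m2", "0", "0", 2), list("c1", "f", "m1", 1),
                   list("c2", "f", "m2", 2)),
      pair = c("c1", "c2"), phi = 1 / 8, delta = 0),
    grandparent_grandchild = list(
      fam = ped_df(list("gf", "0", "0", 1), list("gm", "0", "0", 2),
                   list("f", "gf", "gm", 1), list("m", "0", "0", 2),
                   list("c", "f", "m", 2)),
      pair = c("gf", "c"), phi = 1 / 8, delta = 0),
    avuncular = list(
      fam = ped_df(list("gf", "0", "0", 1), list("gm", "0", "0", 2),
                   list("u", "gf", "gm", 1), list("f", "gf", "gm", 1),
                   list("m", "0", "0", 2), list("c", "f", "m", 1)),
      pair = c("u", "c"), phi = 1 / 8, delta = 0),
    first_cousins = list(
      fam = ped_df(list("gf", "0", "0", 1), list("gm", "0", "0", 2),
                   list("f1", "gf", "gm", 1), list("f2", "gf", "gm", 1),
                   list("m1", "0", "0", 2), list("m2", "0", "0", 2),
                   list("c1", "f1", "m1", 1), list("c2", "f2", "m2", 2)),
      pair = c("c1", "c2"), phi = 1 / 16, delta = 0),
    double_first_cousins = list(
      fam = ped_df(list("gfa", "0", "0", 1), list("gma", "0", "0", 2),
                   list("gfb", "0", "0", 1), list("gmb", "0", "0", 2),
                   list("f1", "gfa", "gma", 1), list("f2", "gfa", "gma", 1),
                   list("m1", "gfb", "gmb", 2), list("m2", "gfb", "gmb", 2),
                   list("c1", "f1", "m1", 1), list("c2", "f2", "m2", 2)),
      pair = c("c1", "c2"), phi = 1 / 8, delta = 1 / 16),
    spouses = list(
      fam = ped_df(list("f", "0", "0", 1), list("m", "0", "0", 2),
                   list("c", "f", "m", 1)),
      pair = c("f", "m"), phi = 0, delta = 0))
}

mz_twin_family <- function() {
  fam <- ped_df(list("f", "0", "0", 1), list("m", "0", "0", 2),
                list("t1", "f", "m", 1), list("t2", "f", "m", 1))
  fam$mz_group <- c(NA, NA, "tw1", "tw1")
  fam
}

# Monte-Carlo gene dropping: founders get unique allele labels, children
# inherit one random allele from each parent; estimates P(random allele
# pair IBD) and P(both alleles IBD) for every pair. Vectorized over
# replicates.
gene_drop_oracle <- function(fam, n_rep = 2e5, seed = 1) {
  withr::with_seed(seed, {
    ids <- fam$individual_id
    n <- length(ids)
    ord <- hericomp:::topological_order(fam)
    fidx <- match(fam$father_id, ids)
    midx <- match(fam$mother_id, ids)
    pat <- mat <- matrix(0L, n_rep, n)
    next_allele <- 1L
    for (j in ord) {
      for (side in c("pat", "mat")) {
        pidx <- if (side == "pat") fidx[j] else midx[j]
        al <- if (is.na(pidx)) {
          next_allele <- next_allele + 1L
          matrix(next_allele, n_rep, 1)  # unique founder allele (constant)
        } else {
          pick <- stats::runif(n_rep) < 0.5
          ifelse(pick, pat[, pidx], mat[, pidx])
        }
        if (side == "pat") pat[, j] <- al else mat[, j] <- al
      }
    }
    phi_hat <- delta_hat <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (b > a) next
      ibd_pairs <- (pat[, a] == pat[, b]) + (pat[, a] == mat[, b]) +
        (mat[, a] == pat[, b]) + (mat[, a] == mat[, b])
      if (a == b) ibd_pairs <- 2 + 2 * (pat[, a] == mat[, a])
      phi_hat[a, b] <- phi_hat[b, a] <- mean(ibd_pairs) / 4
      both <- (pat[, a] == pat[, b] & mat[, a] == mat[, b]) |
        (pat[, a] == mat[, b] & mat[, a] == pat[, b])
      delta_hat[a, b] <- delta_hat[b, a] <- mean(both)
    }
    list(phi = phi_hat, delta = delta_hat, n_rep = n_rep)
  })
}

# All full-sib row-index pairs of a simulated dataset.
sib_pairs <- function(ds) {
  m <- ds$pedigree$members
  key <- paste(m$family_id, m$father_id, m$mother_id)
  kids <- which(!is.na(m$father_id) & !is.na(m$mother_id))
  out <- list()
  for (grp in split(kids, key[kids])) {
    if (length(grp) < 2) next
    cmb <- utils::combn(grp, 2)
    out[[length(out) + 1L]] <- t(cmb)
  }
  do.call(rbind, out)
}

matched_weight_error <- function(model, ds) {
  err <- weight_recovery_error(model, ds$X, ds$true_weights, ds$y1)
  list(se_w = err$se_w, se_trait = err$se_trait)
}

# A small synthetic dataset for solver tests (kept quick).
small_dataset <- function(seed = 1, n_total = 450, n_in_families = 180,
                          d_total = 10, ...) {
  extra <- list(...)
  if (is.null(extra$d_relevant)) extra$d_relevant <- min(10, d_total)
  scen <- do.call(sim_scenario, c(list(n_total = n_total,
                                       n_in_families = n_in_families,
                                       d_total = d_total), extra))
  simulate_dataset(scen, seed = seed)
}
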