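#' Construct a pedigree object
#'
#' A pedigree is an ordered collection of families, each an ordered collection
#' of individuals with optional parent links. Parent ids that are `NA` (or
#' `"0"` in `.fam` files) denote founders. Individuals with one known and one
#' unknown parent are treated as having a unique, unrelated phantom founder in
#' place of the unknown parent, which keeps the kinship recursion total.
#'
#' @param members data.frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id` (character; `NA` or `"0"` = founder) and `sex`
#'   (1 = male, 2 = female, or `"male"`/`"female"`). Optional columns
#'   `household` and `mz_group` (monozygotic-twin tag) are honoured; any
#'   further columns (e.g. `age`, `race`) are carried along untouched.
#' @param validate logical; run structural validation (default `TRUE`).
#' @return An object of class `pedigree`: a list with elements `members`
#'   (the normalized data.frame) and `families` (named list of row indices,
#'   one entry per family in order of first appearance).
#' @export
pedigree <- function(members, validate = TRUE) {
  req <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  missing_cols <- setdiff(req, names(members))
  if (length(missing_cols))
    stop("pedigree members lack column(s): ", paste(missing_cols, collapse = ", "))
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  for (col in c("family_id", "individual_id", "father_id", "mother_id"))
    members[[col]] <- as.character(members[[col]])
  members$father_id[members$father_id %in% c("0", "")] <- NA_character_
  members$mother_id[members$mother_id %in% c("0", "")] <- NA_character_
  members$sex <- normalize_sex(members$sex)
  fam <- factor(members$family_id, levels = unique(members$family_id))
  ped <- structure(
    list(members = members, families = split(seq_len(nrow(members)), fam)),
    class = "pedigree")
  if (validate) validate_pedigree(ped)
  ped
}

normalize_sex <- function(sex) {
  if (is.character(sex) || is.factor(sex)) {
    s <- tolower(as.character(sex))
    out <- ifelse(s %in% c("1", "m", "male"), 1L,
           ifelse(s %in% c("2", "f", "female"), 2L, NA_integer_))
  } else {
    out <- as.integer(sex)
    out[!out %in% c(1L, 2L)] <- NA_integer_
  }
  if (anyNA(out)) stop("sex must be coded 1/male or 2/female")
  out
}

validate_pedigree <- function(ped) {
  m <- ped$members
  if (anyDuplicated(m$individual_id))
    stop("duplicated individual ids: ",
         paste(unique(m$individual_id[duplicated(m$individual_id)]), collapse = ", "))
  for (fi in ped$families) {
    fam <- m[fi, , drop = FALSE]
    ids <- fam$individual_id
    for (parent_col in c("father_id", "mother_id")) {
      pid <- fam[[parent_col]]
      known <- !is.na(pid)
      if (any(known & !(pid %in% ids))) {
        bad <- pid[known & !(pid %in% ids)]
        if (any(bad %in% m$individual_id))
          stop("parent(s) of family ", fam$family_id[1],
               " belong to another family: ", paste(unique(bad), collapse = ", "))
        stop("unknown parent id(s) in family ", fam$family_id[1], ": ",
             paste(unique(bad), collapse = ", "))
      }
      expected <- if (parent_col == "father_id") 1L else 2L
      psex <- fam$sex[match(pid[known], ids)]
      if (any(psex != expected))
        stop(if (expected == 1L) "father " else "mother ",
             paste(unique(pid[known][psex != expected]), collapse = ", "),
             " has the wrong sex")
    }
    # acyclicity == topological orderability
    topological_order(fam)
  }
  invisible(ped)
}

#' Read a PLINK-style .fam pedigree file
#'
#' Whitespace-delimited columns: family id, individual id, father id,
#' mother id, sex (1 = male, 2 = female). A parent id of `0` marks a founder.
#' Two optional trailing columns are recognised: a household id (for the
#' shared-environment matrix) and a monozygotic-twin group tag.
#'
#' @param path path to the pedigree file.
#' @param dialect currently only `"fam"`.
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path, dialect = "fam") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("pedigree file is empty: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 5L | nf > 7L)
  if (length(bad))
    stop("malformed pedigree line ", bad[1], ": expected 5-7 fields, got ", nf[bad[1]])
  if (length(unique(nf)) > 1L)
    stop("malformed pedigree line ", which(nf != nf[1])[1],
         ": inconsistent field count")
  mat <- do.call(rbind, fields)
  members <- data.frame(
    family_id = mat[, 1], individual_id = mat[, 2],
    father_id = mat[, 3], mother_id = mat[, 4], sex = mat[, 5],
    stringsAsFactors = FALSE)
  if (nf[1] >= 6L) members$household <- mat[, 6]
  if (nf[1] >= 7L) {
    members$mz_group <- mat[, 7]
    members$mz_group[members$mz_group %in% c("0", "")] <- NA_character_
  }
  pedigree(members)
}

#' Write a pedigree in the .fam dialect
#'
#' @param ped a [pedigree].
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  m <- ped$members
  out <- data.frame(
    m$family_id, m$individual_id,
    ifelse(is.na(m$father_id), "0", m$father_id),
    ifelse(is.na(m$mother_id), "0", m$mother_id),
    m$sex)
  if (!is.null(m$household)) out <- cbind(out, m$household)
  if (!is.null(m$mz_group))
    out <- cbind(out, ifelse(is.na(m$mz_group), "0", m$mz_group))
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  sizes <- lengths(x$families)
  cat("pedigree: ", nrow(x$members), " individuals in ", length(x$families),
      " families (", sum(sizes > 1), " multi-member, ", sum(sizes == 1),
      " singletons)\n", sep = "")
  invisible(x)
}

# Founders-first ordering of one family's members; errors on cycles.
topological_order <- function(family) {
  ids <- family$individual_id
  n <- length(ids)
  placed <- logical(n)
  order <- integer(0)
  repeat {
    ready <- which(!placed & vapply(seq_len(n), function(j) {
      ok <- TRUE
      for (pid in c(family$father_id[j], family$mother_id[j]))
        if (!is.na(pid)) ok <- ok && placed[match(pid, ids)]
      ok
    }, logical(1)))
    if (!length(ready)) {
      if (all(placed)) break
      stop("family ", family$family_id[1],
           " is not topologically orderable (cyclic ancestry among: ",
           paste(ids[!placed], collapse = ", "), ")")
    }
    placed[ready] <- TRUE
    order <- c(order, ready)
  }
  order
}

#' Kinship matrix of one family
#'
#' Recursive computation under random mating: founders have self-kinship 1/2
#' and pairwise kinship 0; a non-founder with parents f and m has
#' \eqn{\Phi(j,k) = (\Phi(f,k)+\Phi(m,k))/2} for previously processed k, and
#' \eqn{\Phi(j,j) = (1+\Phi(f,m))/2}. An unknown parent contributes 0 (a
#' phantom unrelated founder). Members sharing a monozygotic-twin tag are set
#' to pairwise kinship 1/2.
#'
#' @param family data.frame of one family's members (as in
#'   `pedigree()$members`).
#' @return Symmetric matrix with individual ids as dimnames.
#' @export
kinship_matrix <- function(family) {
  ids <- family$individual_id
  n <- length(ids)
  ord <- topological_order(family)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  fidx <- match(family$father_id, ids)
  midx <- match(family$mother_id, ids)
  done <- integer(0)
  for (j in ord) {
    f <- fidx[j]; m <- midx[j]
    pf <- function(a, b) if (is.na(a)) 0 else phi[a, b]
    for (k in done) {
      phi[j, k] <- phi[k, j] <- 0.5 * (pf(f, k) + pf(m, k))
    }
    phi[j, j] <- 0.5 * (1 + if (is.na(f) || is.na(m)) 0 else phi[f, m])
    done <- c(done, j)
  }
  phi <- apply_mz_override(phi, family, value = 0.5)
  phi
}

#' Fraternity matrix of one family
#'
#' Probability that two members share both alleles identical by descent at a
#' locus. For non-inbred pairs with parents \eqn{(f_j,m_j)} and
#' \eqn{(f_k,m_k)}:
#' \eqn{\Delta(j,k) = \Phi(f_j,f_k)\Phi(m_j,m_k) + \Phi(f_j,m_k)\Phi(m_j,f_k)}.
#' Founders are pairwise 0, the diagonal is 1, and monozygotic twins are 1.
#' The formula is exact only for non-inbred pairs; a warning is emitted if any
#' member's parents are themselves related.
#'
#' @param family data.frame of one family's members.
#' @param phi kinship matrix from [kinship_matrix()] (computed if missing).
#' @return Symmetric matrix with individual ids as dimnames.
#' @export
fraternity_matrix <- function(family, phi = kinship_matrix(family)) {
  ids <- family$individual_id
  n <- length(ids)
  fidx <- match(family$father_id, ids)
  midx <- match(family$mother_id, ids)
  inbred <- vapply(seq_len(n), function(j) {
    !is.na(fidx[j]) && !is.na(midx[j]) && phi[fidx[j], midx[j]] > 0
  }, logical(1))
  if (any(inbred))
    warning("family ", family$family_id[1], " contains inbred member(s); ",
            "the non-inbred fraternity formula is approximate there")
  pf <- function(a, b) {
    if (is.na(a) || is.na(b)) 0 else phi[a, b]
  }
  delta <- diag(1, n)
  dimnames(delta) <- list(ids, ids)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (k >= j) next
    d <- pf(fidx[j], fidx[k]) * pf(midx[j], midx[k]) +
         pf(fidx[j], midx[k]) * pf(midx[j], fidx[k])
    delta[j, k] <- delta[k, j] <- d
  }
  apply_mz_override(delta, family, value = 1)
}

apply_mz_override <- function(mat, family, value) {
  mz <- family$mz_group
  if (is.null(mz) || all(is.na(mz))) return(mat)
  for (g in unique(mz[!is.na(mz)])) {
    idx <- which(!is.na(mz) & mz == g)
    if (length(idx) < 2) next
    for (a in idx) for (b in idx) if (a != b) mat[a, b] <- value
  }
  mat
}

#' Shared-environment indicator matrix of one family
#'
#' 1 where two members share a household, 0 otherwise; the diagonal is 1.
#' Without household data the identity matrix is returned, the convention
#' used throughout the simulations here.
#'
#' @param family data.frame of one family's members.
#' @param households optional vector of household labels, one per member;
#'   defaults to the family's `household` column when present.
#' @return Symmetric 0/1 matrix.
#' @export
environment_matrix <- function(family, households = family$household) {
  ids <- family$individual_id
  n <- length(ids)
  if (is.null(households)) {
    gam <- diag(1, n)
  } else {
    gam <- outer(households, households, `==`) * 1
    diag(gam) <- 1
  }
  dimnames(gam) <- list(ids, ids)
  gam
}

#' Per-family relatedness blocks
#'
#' Computes, for every family, the kinship matrix \eqn{\Phi}, fraternity
#' matrix \eqn{\Delta}, shared-environment indicator \eqn{\Gamma}, and the
#' cached inverse \eqn{\Phi^{-1}}. The full-sample kinship matrix is
#' block-diagonal over families and never materialized densely.
#'
#' @param ped a [pedigree].
#' @param use_households logical; use the `household` column for
#'   \eqn{\Gamma} when present (default), else \eqn{\Gamma = I}.
#' @return Object of class `relatedness_blocks`: list with one element per
#'   family (`ids`, `rows`, `phi`, `delta`, `gamma`, `phi_inv`).
#' @export
relatedness_blocks <- function(ped, use_households = TRUE) {
  blocks <- lapply(ped$families, function(fi) {
    fam <- ped$members[fi, , drop = FALSE]
    phi <- kinship_matrix(fam)
    delta <- fraternity_matrix(fam, phi)
    hh <- if (use_households) fam$household else NULL
    gam <- environment_matrix(fam, hh)
    # monozygotic twins duplicate kinship rows, so phi can be exactly
    # singular; fall back to the Moore-Penrose inverse in that case
    phi_inv <- tryCatch(solve(phi), error = function(e) pracma::pinv(phi))
    list(ids = fam$individual_id, rows = fi, phi = phi, delta = delta,
         gamma = gam, phi_inv = phi_inv)
  })
  structure(blocks, class = "relatedness_blocks")
}

#' Relatedness in long format
#'
#' @param blocks a [relatedness_blocks()] result.
#' @param include_self include the diagonal entries (default `TRUE`).
#' @return data.frame with columns `id1`, `id2`, `phi`, `delta` (unordered
#'   within-family pairs; between-family pairs are 0 and omitted).
#' @export
relatedness_table <- function(blocks, include_self = TRUE) {
  out <- lapply(blocks, function(b) {
    n <- length(b$ids)
    idx <- which(upper.tri(b$phi, diag = include_self), arr.ind = TRUE)
    data.frame(id1 = b$ids[idx[, 1]], id2 = b$ids[idx[, 2]],
               phi = b$phi[idx], delta = b$delta[idx],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Subset a pedigree to whole families. Individual-level subsetting is
# deliberately not offered: dropping a member must marginalize the
# relatedness blocks, not re-run the kinship recursion on a broken family.
subset_pedigree <- function(ped, family_ids) {
  m <- ped$members
  pedigree(m[m$family_id %in% family_ids, , drop = FALSE], validate = FALSE)
}
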