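#' Validate and normalise a pedigree table
#'
#' A pedigree is an ordinary data frame with one row per individual and
#' columns `id`, `father`, `mother` (character; `"0"` or `NA` for a missing
#' parent), `sex` (1 = male, 2 = female), and `zygosity` (`"MZ"`, `"DZ"` or
#' `NA` for non-twins; twins are individuals in the same sibship carrying the
#' same tag). Extra columns (e.g. `family`, `generation` from the simulator)
#' are carried along untouched.
#'
#' @param ped A data frame with at least columns `id`, `father`, `mother`.
#' @return A tibble with `id`, `father`, `mother` as character, missing
#'   parents encoded `NA`, plus `sex` and `zygosity` columns.
#' @export
as_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  need <- c("id", "father", "mother")
  miss <- setdiff(need, names(ped))
  if (length(miss) > 0) {
    stop("pedigree is missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- tibble::as_tibble(ped)
  out$id <- as.character(out$id)
  out$father <- as.character(out$father)
  out$mother <- as.character(out$mother)
  out$father[out$father %in% c("0", "")] <- NA_character_
  out$mother[out$mother %in% c("0", "")] <- NA_character_
  if (!"sex" %in% names(out)) out$sex <- NA_integer_
  if (!"zygosity" %in% names(out)) out$zygosity <- NA_character_
  if (anyDuplicated(out$id)) stop("duplicated individual ids in pedigree")
  # each individual has 0 or 2 recorded parents
  one_parent <- xor(is.na(out$father), is.na(out$mother))
  if (any(one_parent)) {
    stop("individuals with exactly one recorded parent: ",
         paste(utils::head(out$id[one_parent], 5), collapse = ", "))
  }
  known <- c(NA_character_, out$id)
  bad <- !(out$father %in% known) | !(out$mother %in% known)
  if (any(bad)) {
    stop("parent link to unknown id for: ",
         paste(utils::head(out$id[bad], 5), collapse = ", "))
  }
  out
}

# Generation depth per row (founders 0); errors on cycles.
ped_depth <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  depth <- rep(NA_integer_, n)
  get_depth <- function(i, seen = integer(0)) {
    if (!is.na(depth[i])) return(depth[i])
    if (i %in% seen) stop("pedigree contains a cycle involving id ", ped$id[i])
    if (is.na(fa[i]) && is.na(mo[i])) {
      depth[i] <<- 0L
    } else {
      depth[i] <<- 1L + max(get_depth(fa[i], c(seen, i)),
                            get_depth(mo[i], c(seen, i)))
    }
    depth[i]
  }
  for (i in seq_len(n)) get_depth(i)
  depth
}

# Topologically order row indices so parents precede children.
ped_order <- function(ped) {
  order(ped_depth(ped))
}

# Kinship over a set of rows given parent indices (no validation).
# id: character ids; fa, mo: integer indices into id (NA for founders).
kinship_core <- function(id, fa, mo) {
  n <- length(id)
  depth <- rep(NA_integer_, n)
  repeat {
    todo <- which(is.na(depth))
    if (length(todo) == 0) break
    for (i in todo) {
      if (is.na(fa[i])) depth[i] <- 0L
      else if (!is.na(depth[fa[i]]) && !is.na(depth[mo[i]])) {
        depth[i] <- 1L + max(depth[fa[i]], depth[mo[i]])
      }
    }
  }
  ord <- order(depth)
  K <- matrix(0, n, n, dimnames = list(id, id))
  for (pos in seq_len(n)) {
    i <- ord[pos]
    if (is.na(fa[i])) {
      K[i, i] <- 0.5
    } else {
      prev <- ord[seq_len(pos - 1L)]
      v <- (K[fa[i], prev] + K[mo[i], prev]) / 2
      K[i, prev] <- v
      K[prev, i] <- v
      K[i, i] <- 0.5 + K[fa[i], mo[i]] / 2
    }
  }
  K
}

#' Kinship matrix from recorded ancestry
#'
#' Computes the full kinship matrix over a pedigree with the recursive
#' founder-based algorithm: founders are unrelated and non-inbred,
#' phi(i,i) = 1/2, and phi(i,j) = (phi(father_i, j) + phi(mother_i, j)) / 2
#' for a non-founder i not an ancestor of j.
#'
#' @param ped A pedigree data frame (see [as_pedigree()]).
#' @return A symmetric numeric matrix of kinship coefficients with
#'   dimnames = individual ids.
#' @export
kinship_matrix <- function(ped) {
  ped <- as_pedigree(ped)
  ped_depth(ped)  # validates acyclicity
  kinship_core(ped$id, match(ped$father, ped$id), match(ped$mother, ped$id))
}

#' Expected additive genetic relatedness between two individuals
#'
#' Twice the kinship coefficient from recorded ancestry: 1 for an individual
#' with itself (non-inbred), 0.5 for full siblings and parent-offspring,
#' 0.25 for half siblings, 0.125 for first cousins.
#'
#' @param ped A pedigree data frame.
#' @param id1,id2 Individual ids.
#' @return A single numeric value in `[0, 1]` (can exceed 1 under inbreeding).
#' @export
expected_relatedness <- function(ped, id1, id2) {
  ped <- as_pedigree(ped)
  id1 <- as.character(id1); id2 <- as.character(id2)
  if (!id1 %in% ped$id) stop("unknown id: ", id1)
  if (!id2 %in% ped$id) stop("unknown id: ", id2)
  K <- kinship_matrix(ped)
  unname(2 * K[id1, id2])
}

# Connected components of the family graph (parent-child edges), as an
# integer label per row. Avoids all-pairs work across unrelated families.
ped_components <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  parent <- idx
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  for (i in idx) {
    if (!is.na(fa[i])) union2(i, fa[i])
    if (!is.na(mo[i])) union2(i, mo[i])
  }
  roots <- vapply(idx, find, integer(1))
  match(roots, unique(roots))
}

#' Enumerate and classify relative pairs
#'
#' Enumerates every unordered pair of study individuals that falls in one of
#' the analysis relationship classes — MZ twin, DZ twin, full sibling,
#' first cousin — exactly once, and attaches the pedigree-expected genetic
#' correlation `r_g` (1 for MZ, 0.5 for DZ/full siblings, 0.125 for first
#' cousins) and the environment-sharing class label `r_c_label` (`"sib"` for
#' twins and full siblings, `"cousin"` for first cousins). Pairs of any other
#' relationship are labelled `"other"` and are excluded unless
#' `keep_other = TRUE`.
#'
#' @param ped A pedigree data frame.
#' @param ids Optional character vector restricting enumeration to a study
#'   cohort (e.g. the phenotyped generation); relationships are still derived
#'   from the full pedigree. Default: all individuals.
#' @param keep_other Keep pairs classified `"other"`? Default `FALSE`.
#' @return A tibble with columns `id1`, `id2`, `relationship`, `r_g`,
#'   `r_c_label`.
#' @export
classify_pairs <- function(ped, ids = NULL, keep_other = FALSE) {
  ped <- as_pedigree(ped)
  if (is.null(ids)) ids <- ped$id
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("ids contains duplicates (individual paired with itself)")
  if (!all(ids %in% ped$id)) stop("ids not in pedigree: ",
                                  paste(utils::head(setdiff(ids, ped$id), 5), collapse = ", "))
  ped_depth(ped)  # validates acyclicity once
  comp <- ped_components(ped)
  keep <- ped$id %in% ids
  rows <- split(which(keep), comp[keep])
  comp_rows <- split(seq_len(nrow(ped)), comp)
  all_id <- ped$id
  fa_i <- match(ped$father, all_id)
  mo_i <- match(ped$mother, all_id)
  zyg <- ped$zygosity
  # vectorized full-sib test on row indices (shared recorded parent couple)
  sib_idx <- function(u, v) {
    !is.na(u) & !is.na(v) & u != v &
      !is.na(fa_i[u]) & !is.na(fa_i[v]) &
      fa_i[u] == fa_i[v] & mo_i[u] == mo_i[v]
  }
  out <- purrr::map(names(rows), function(cp) {
    ix <- rows[[cp]]
    m <- length(ix)
    if (m < 2) return(NULL)
    cix <- comp_rows[[cp]]
    K <- kinship_core(all_id[cix], match(ped$father[cix], all_id[cix]),
                      match(ped$mother[cix], all_id[cix]))
    pr <- utils::combn(m, 2)
    ia <- ix[pr[1, ]]; ib <- ix[pr[2, ]]
    a <- all_id[ia]; b <- all_id[ib]
    r2k <- 2 * K[cbind(match(ia, cix), match(ib, cix))]
    sib <- sib_idx(ia, ib)
    both_mz <- !is.na(zyg[ia]) & !is.na(zyg[ib]) & zyg[ia] == "MZ" & zyg[ib] == "MZ"
    both_dz <- !is.na(zyg[ia]) & !is.na(zyg[ib]) & zyg[ia] == "DZ" & zyg[ib] == "DZ"
    rel <- rep("other", length(a))
    rel[sib] <- "fullsib"
    rel[sib & both_dz] <- "DZ"
    rel[sib & both_mz] <- "MZ"
    # first cousins: not sibs, relatedness 0.125, linked through sib parents
    cousin <- !sib & abs(r2k - 0.125) < 1e-12 &
      (sib_idx(fa_i[ia], fa_i[ib]) | sib_idx(fa_i[ia], mo_i[ib]) |
         sib_idx(mo_i[ia], fa_i[ib]) | sib_idx(mo_i[ia], mo_i[ib]))
    rel[cousin] <- "first_cousin"
    rg <- unname(r2k)
    rg[rel == "MZ"] <- 1
    rcl <- rep("other", length(a))
    rcl[rel %in% c("MZ", "DZ", "fullsib")] <- "sib"
    rcl[rel == "first_cousin"] <- "cousin"
    tibble::tibble(id1 = a, id2 = b, relationship = rel, r_g = rg,
                   r_c_label = rcl)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(id1 = character(), id2 = character(),
                          relationship = character(), r_g = numeric(),
                          r_c_label = character())
  }
  if (!keep_other) res <- dplyr::filter(res, .data$relationship != "other")
  res
}

#' Empirical genome sharing for relative pairs (KING-robust)
#'
#' Estimates the realised genetic correlation r_g = 2 * phi for each pair from
#' dosage data with the within-family robust kinship estimator
#' phi = (N_both_het - 2 N_opposite_hom) / (N_het1 + N_het2),
#' which does not require allele-frequency estimates. Estimates are clipped to
#' `[0, 1]`.
#'
#' @param genos A genotype object from [sim_genotypes()] or a dosage matrix
#'   (individuals x SNPs, values 0/1/2, rownames = ids).
#' @param pairs A pair tibble from [classify_pairs()] (columns `id1`, `id2`).
#' @param min_snps Minimum number of SNPs where both members are genotyped for
#'   the estimate to be considered reliable; pairs below it get `NA`.
#' @return `pairs` with added columns `r_g_hat` (clipped), `n_snp_used`.
#' @export
estimate_ibd_sharing <- function(genos, pairs, min_snps = 1000) {
  X <- dosage_matrix(genos)
  ids <- rownames(X)
  miss <- setdiff(unique(c(pairs$id1, pairs$id2)), ids)
  if (length(miss) > 0) stop("no genotypes for: ", paste(utils::head(miss, 5), collapse = ", "))
  i1 <- match(pairs$id1, ids)
  i2 <- match(pairs$id2, ids)
  n <- nrow(pairs)
  rhat <- numeric(n)
  nused <- integer(n)
  # chunk over pairs to bound memory
  chunk <- max(1L, floor(2e7 / max(1L, ncol(X))))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    A <- X[i1[s:e], , drop = FALSE]
    B <- X[i2[s:e], , drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    het1 <- rowSums((A == 1L) & ok)
    het2 <- rowSums((B == 1L) & ok)
    both <- rowSums((A == 1L) & (B == 1L) & ok)
    opp <- rowSums((abs(A - B) == 2L) & ok)
    den <- het1 + het2
    phi <- ifelse(den > 0, (both - 2 * opp) / den, NA_real_)
    rhat[s:e] <- pmin(1, pmax(0, 2 * phi))
    nused[s:e] <- rowSums(ok)
  }
  rhat[nused < min_snps] <- NA_real_
  dplyr::mutate(pairs, r_g_hat = rhat, n_snp_used = nused)
}

#' Read / write pedigree TSV
#'
#' Plain TSV with columns `id`, `father`, `mother`, `sex`, `zygosity`;
#' a missing parent is encoded `0`, a non-twin has empty zygosity.
#'
#' @param path File path.
#' @return `read_pedigree()` returns a pedigree tibble.
#' @export
read_pedigree <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), father = readr::col_character(),
    mother = readr::col_character(), sex = readr::col_integer(),
    zygosity = readr::col_character()))
  as_pedigree(raw)
}

#' @rdname read_pedigree
#' @param ped A pedigree data frame.
#' @export
write_pedigree <- function(ped, path) {
  ped <- as_pedigree(ped)
  out <- ped
  out$father[is.na(out$father)] <- "0"
  out$mother[is.na(out$mother)] <- "0"
  readr::write_tsv(out, path)
  invisible(path)
}
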