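#' Pedigree additive relationship matrix (A-matrix)
#'
#' Computes the numerator relationship matrix by the tabular method after an
#' internal topological sort: `A[i,i] = 1 + A[sire, dam] / 2` and
#' `A[i,j] = (A[j, sire] + A[j, dam]) / 2`, with founders unrelated and
#' non-inbred. Fails on pedigree cycles (naming the individuals involved) and
#' on parent ids absent from the pedigree.
#'
#' @param pedigree A data frame with columns `id`, `sire`, `dam` (parent
#'   entries `NA` when unknown). Ids may be character or numeric.
#' @return A dense symmetric matrix with ids as dimnames, of class
#'   `relatedness_matrix` with attribute `kind = "pedigree_A"`.
#' @examples
#' ped <- tibble::tibble(id = c("a", "b", "x"), sire = c(NA, NA, "a"),
#'                       dam = c(NA, NA, "b"))
#' compute_A_matrix(ped)["a", "x"]  # 0.5
#' @export
compute_A_matrix <- function(pedigree) {
  ped <- normalize_pedigree(pedigree)
  ord <- pedigree_toposort(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  sire_i <- match(ped$sire, ped$id)
  dam_i <- match(ped$dam, ped$id)
  for (i in ord) {
    s <- sire_i[i]; d <- dam_i[i]
    row_s <- if (!is.na(s)) A[s, ] else numeric(n)
    row_d <- if (!is.na(d)) A[d, ] else numeric(n)
    a_row <- (row_s + row_d) / 2
    A[i, ] <- a_row
    A[, i] <- a_row
    A[i, i] <- 1 + (if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0)
  }
  structure(A, kind = "pedigree_A", class = c("relatedness_matrix", class(A)))
}

#' Prune a pedigree to the individuals informative about a phenotyped set
#'
#' Keeps the phenotyped individuals and all of their ancestors (the links
#' through which phenotyped individuals can covary); everything else is
#' dropped. Relatedness among the phenotyped individuals is unchanged by the
#' pruning.
#'
#' @param pedigree A pedigree data frame (`id`, `sire`, `dam`).
#' @param phenotyped_ids Ids of individuals with phenotype records; must be a
#'   subset of `pedigree$id`.
#' @return The pruned pedigree tibble (possibly empty).
#' @export
prune_pedigree <- function(pedigree, phenotyped_ids) {
  ped <- normalize_pedigree(pedigree)
  phen <- as.character(phenotyped_ids)
  unknown <- setdiff(phen, ped$id)
  if (length(unknown)) {
    abort(sprintf("phenotyped ids not in pedigree: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  if (!length(phen)) return(ped[0, ])
  keep <- unique(phen)
  frontier <- keep
  repeat {
    rows <- ped[ped$id %in% frontier, ]
    parents <- setdiff(unique(c(rows$sire, rows$dam)), c(NA, keep))
    if (!length(parents)) break
    keep <- c(keep, parents)
    frontier <- parents
  }
  ped[ped$id %in% keep, ]
}

# Coerce ids to character, validate structure, check parent ids exist.
normalize_pedigree <- function(pedigree) {
  check_columns(pedigree, c("id", "sire", "dam"), "pedigree")
  ped <- tibble::tibble(
    id = as.character(pedigree$id),
    sire = as.character(pedigree$sire),
    dam = as.character(pedigree$dam)
  )
  extra <- setdiff(names(pedigree), c("id", "sire", "dam"))
  for (col in extra) ped[[col]] <- pedigree[[col]]
  if (anyDuplicated(ped$id)) {
    abort(sprintf("duplicated pedigree ids: %s",
                  paste(head(unique(ped$id[duplicated(ped$id)]), 5), collapse = ", ")))
  }
  parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(parents)) {
    abort(sprintf("unknown parent id(s): %s", paste(head(parents, 5), collapse = ", ")))
  }
  ped
}

# Kahn topological sort; errors naming a cycle if one exists.
pedigree_toposort <- function(ped) {
  n <- nrow(ped)
  sire_i <- match(ped$sire, ped$id)
  dam_i <- match(ped$dam, ped$id)
  n_unresolved <- (!is.na(sire_i)) + (!is.na(dam_i))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_i[i], dam_i[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(n_unresolved == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      n_unresolved[ch] <- n_unresolved[ch] - 1L
      if (n_unresolved[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    cyc <- setdiff(seq_len(n), ord)
    abort(sprintf("pedigree contains a cycle involving: %s",
                  paste(head(ped$id[cyc], 10), collapse = ", ")))
  }
  ord
}
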