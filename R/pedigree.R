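#' Construct a pedigree from parent-link vectors
#'
#' Builds a validated [Pedigree-class] object. Parents referenced but not
#' listed as individuals are materialised as founders of unknown sex (with a
#' warning). Generation indices (longest-path depth from founders) and family
#' components are computed here; a cycle in the parent graph is a structural
#' error naming the individuals involved.
#'
#' @param id character vector of unique identifiers.
#' @param father,mother character vectors; use `NA`, `""` or `"0"` for an
#'   unknown parent.
#' @param sex integer/numeric (1 male, 2 female, 0/NA unknown) or character
#'   (`"male"`, `"female"`, `"unknown"`, or `"M"`/`"F"` prefixes).
#' @param partners optional two-column matrix or data.frame of declared
#'   partner links (for childless couples).
#' @return A [Pedigree-class] object.
#' @examples
#' ped <- pedigree(
#'   id = c("f", "m", "c1", "c2"),
#'   father = c(NA, NA, "f", "f"),
#'   mother = c(NA, NA, "m", "m"),
#'   sex = c(1, 2, 1, 2)
#' )
#' ped
#' @export
pedigree <- function(id, father, mother, sex = NULL, partners = NULL) {
  id <- as.character(id)
  father <- normalizeParent(father)
  mother <- normalizeParent(mother)
  if (anyDuplicated(id)) {
    stop(
      "duplicate individual id(s): ",
      paste(unique(id[duplicated(id)]), collapse = ", ")
    )
  }
  self <- !is.na(father) & id == father | !is.na(mother) & id == mother
  if (any(self)) {
    stop("individual(s) recorded as own parent: ",
         paste(id[self], collapse = ", "))
  }
  sex <- normalizeSex(sex, length(id))

  # materialize unknown parents as founders
  extra <- setdiff(c(father, mother), c(id, NA))
  if (length(extra)) {
    warning(
      "parent id(s) not listed as individuals, added as founders: ",
      paste(extra, collapse = ", ")
    )
    exSex <- ifelse(extra %in% father, 1L, 2L)
    id <- c(id, extra)
    father <- c(father, rep(NA_character_, length(extra)))
    mother <- c(mother, rep(NA_character_, length(extra)))
    sex <- c(sex, exSex)
  }

  gen <- generationIndex(id, father, mother)
  partners <- normalizePartners(partners, id)
  fam <- familyComponents(id, father, mother, partners)
  new("Pedigree",
    id = id, father = father, mother = mother, sex = sex,
    generation = gen, familyId = fam, partners = partners
  )
}

normalizeParent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "0" | x == ""] <- NA_character_
  x
}

normalizeSex <- function(sex, n) {
  if (is.null(sex)) return(rep(0L, n))
  if (is.character(sex) || is.factor(sex)) {
    s <- tolower(substr(as.character(sex), 1, 1))
    out <- ifelse(s == "m", 1L, ifelse(s == "f", 2L, 0L))
    out[is.na(out)] <- 0L
    return(out)
  }
  out <- as.integer(sex)
  out[is.na(out) | !(out %in% c(0L, 1L, 2L))] <- 0L
  out
}

normalizePartners <- function(partners, id) {
  if (is.null(partners) || NROW(partners) == 0L) {
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("id1", "id2"))))
  }
  p <- as.matrix(partners)
  storage.mode(p) <- "character"
  if (ncol(p) != 2L) stop("'partners' must have two columns")
  miss <- setdiff(as.vector(p), id)
  if (length(miss)) {
    stop("partner id(s) not in pedigree: ", paste(miss, collapse = ", "))
  }
  colnames(p) <- c("id1", "id2")
  p
}

# longest-path generation index; errors on cycles naming the individuals
generationIndex <- function(id, father, mother) {
  n <- length(id)
  fi <- match(father, id)
  mi <- match(mother, id)
  gen <- rep(NA_integer_, n)
  gen[is.na(fi) & is.na(mi)] <- 0L
  repeat {
    pending <- which(is.na(gen))
    if (!length(pending)) break
    gf <- gen[fi[pending]]
    gm <- gen[mi[pending]]
    ready <- (is.na(fi[pending]) | !is.na(gf)) &
             (is.na(mi[pending]) | !is.na(gm))
    if (!any(ready)) {
      stop(
        "cycle detected in pedigree involving: ",
        paste(id[pending], collapse = ", ")
      )
    }
    upd <- pending[ready]
    gen[upd] <- pmax(ifelse(is.na(fi[upd]), -1L, gen[fi[upd]]),
                     ifelse(is.na(mi[upd]), -1L, gen[mi[upd]])) + 1L
  }
  gen
}

# connected components of the undirected parent/partner graph (union-find)
familyComponents <- function(id, father, mother, partners = NULL) {
  n <- length(id)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  fi <- match(father, id)
  mi <- match(mother, id)
  for (k in seq_len(n)) {
    if (!is.na(fi[k])) unite(k, fi[k])
    if (!is.na(mi[k])) unite(k, mi[k])
  }
  if (!is.null(partners) && nrow(partners)) {
    p1 <- match(partners[, 1L], id)
    p2 <- match(partners[, 2L], id)
    for (k in seq_along(p1)) unite(p1[k], p2[k])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))
  sprintf("fam%03d", labels)
}

#' Partition a pedigree into families
#'
#' Families are the connected components of the undirected parent-link and
#' partner-link graph; every individual belongs to exactly one family.
#' Families are the exchangeable clustering unit for robust variance and the
#' bootstrap downstream.
#'
#' @param ped A [Pedigree-class].
#' @return Named character vector: family label per individual id.
#' @export
families <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  setNames(ped@familyId, ped@id)
}

#' Number of individuals in a pedigree
#' @param x A [Pedigree-class].
#' @export
setMethod("length", "Pedigree", function(x) length(x@id))

#' Pedigree accessors
#'
#' `pedIds()`, `pedFather()`, `pedMother()`, `pedSex()`, `generations()` and
#' `isFounder()` expose the pedigree slots without direct slot access.
#'
#' @param ped A [Pedigree-class].
#' @return Vectors parallel to `pedIds(ped)`.
#' @name pedigree-accessors
NULL

#' @rdname pedigree-accessors
#' @export
pedIds <- function(ped) ped@id

#' @rdname pedigree-accessors
#' @export
pedFather <- function(ped) setNames(ped@father, ped@id)

#' @rdname pedigree-accessors
#' @export
pedMother <- function(ped) setNames(ped@mother, ped@id)

#' @rdname pedigree-accessors
#' @export
pedSex <- function(ped) setNames(ped@sex, ped@id)

#' @rdname pedigree-accessors
#' @export
generations <- function(ped) setNames(ped@generation, ped@id)

#' @rdname pedigree-accessors
#' @export
isFounder <- function(ped) {
  setNames(is.na(ped@father) & is.na(ped@mother), ped@id)
}

#' Classify relative pairs
#'
#' Enumerates parent-offspring, full-sibling and spouse pairs. First-degree
#' relatives are parent-offspring and full siblings (both parents shared and
#' recorded); half-siblings and remoter kin are "other" and excluded from
#' first-degree analyses. Spouses are two individuals with at least one
#' common child, plus any declared partner links. Spouse pairs that are also
#' blood relatives (shared ancestor, or one an ancestor of the other) are
#' flagged consanguineous; spouse-based analyses exclude them.
#'
#' Pairs are listed once, in canonical order (pedigree order of the first
#' member; for parent-offspring the parent is `id1`).
#'
#' @param ped A [Pedigree-class].
#' @return data.frame with columns `id1`, `id2`, `relation` (one of
#'   `"parent-offspring"`, `"full-sibling"`, `"spouse"`) and `consanguineous`
#'   (logical, `NA` for non-spouse pairs).
#' @export
classifyPairs <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  id <- ped@id
  fi <- match(ped@father, id)
  mi <- match(ped@mother, id)
  n <- length(id)

  po <- rbind(
    cbind(fi[!is.na(fi)], which(!is.na(fi))),
    cbind(mi[!is.na(mi)], which(!is.na(mi)))
  )

  # full siblings: both parents recorded and identical
  both <- which(!is.na(fi) & !is.na(mi))
  sib <- NULL
  if (length(both) > 1L) {
    key <- paste(fi[both], mi[both])
    grp <- split(both, key)
    grp <- grp[lengths(grp) > 1L]
    sib <- do.call(rbind, lapply(grp, function(g) t(utils::combn(sort(g), 2L))))
  }

  # spouses: a common child, or a declared partner link
  sp <- NULL
  if (length(both)) {
    couples <- unique(cbind(fi[both], mi[both]))
    sp <- couples
  }
  if (nrow(ped@partners)) {
    pl <- cbind(match(ped@partners[, 1L], id), match(ped@partners[, 2L], id))
    sp <- rbind(sp, pl)
  }
  if (!is.null(sp) && nrow(sp)) {
    sp <- t(apply(sp, 1L, sort))
    sp <- unique(sp)
  }

  out <- data.frame(
    id1 = character(), id2 = character(), relation = character(),
    consanguineous = logical(), stringsAsFactors = FALSE
  )
  addPairs <- function(mat, rel, consang = NA) {
    if (is.null(mat) || !nrow(mat)) return(NULL)
    data.frame(
      id1 = id[mat[, 1L]], id2 = id[mat[, 2L]], relation = rel,
      consanguineous = consang, stringsAsFactors = FALSE
    )
  }
  consang <- logical(0)
  if (!is.null(sp) && nrow(sp)) {
    anc <- ancestorSets(ped)
    consang <- vapply(seq_len(nrow(sp)), function(k) {
      i <- sp[k, 1L]; j <- sp[k, 2L]
      length(intersect(anc[[i]], anc[[j]])) > 0L
    }, logical(1))
  }
  out <- rbind(
    addPairs(po, "parent-offspring"),
    addPairs(sib, "full-sibling"),
    if (!is.null(sp) && nrow(sp)) {
      data.frame(
        id1 = id[sp[, 1L]], id2 = id[sp[, 2L]], relation = "spouse",
        consanguineous = consang, stringsAsFactors = FALSE
      )
    }
  )
  if (is.null(out)) {
    out <- data.frame(
      id1 = character(), id2 = character(), relation = character(),
      consanguineous = logical(), stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}

# ancestor index sets including self, per individual
ancestorSets <- function(ped) {
  id <- ped@id
  fi <- match(ped@father, id)
  mi <- match(ped@mother, id)
  ord <- order(ped@generation)
  anc <- vector("list", length(id))
  for (k in ord) {
    a <- k
    if (!is.na(fi[k])) a <- c(a, anc[[fi[k]]])
    if (!is.na(mi[k])) a <- c(a, anc[[mi[k]]])
    anc[[k]] <- unique(a)
  }
  anc
}

#' Additive genetic relationship matrix
#'
#' Computes the expected additive relationship matrix A by the tabular
#' method, processing individuals in generation order so that parents precede
#' offspring: off-diagonals a_ij = (a_{j,father(i)} + a_{j,mother(i)})/2 and
#' diagonals a_ii = 1 + a_{father(i),mother(i)}/2 (1 + inbreeding). The
#' matrix is computed over the full pedigree, family block by family block,
#' and only then restricted to `ids`, so unphenotyped connecting ancestors
#' still contribute relatedness.
#'
#' Below `sparseThreshold` individuals a dense base matrix is returned; above
#' it, a sparse symmetric [Matrix::Matrix] assembled from the family blocks
#' (the entries are identical; A is block diagonal by family under any
#' ordering that groups families).
#'
#' @param ped A [Pedigree-class].
#' @param ids optional character vector: restrict the returned matrix to
#'   these individuals (in this order). Unknown ids are an error.
#' @param sparse logical or `NULL` (auto by `sparseThreshold`).
#' @param sparseThreshold integer; default 2000.
#' @return Symmetric matrix with `ids` dimnames.
#' @examples
#' ped <- pedigree(c("f", "m", "c"), c(NA, NA, "f"), c(NA, NA, "m"),
#'                 sex = c(1, 2, 2))
#' relationshipMatrix(ped)
#' @export
relationshipMatrix <- function(ped, ids = NULL, sparse = NULL,
                               sparseThreshold = 2000L) {
  stopifnot(is(ped, "Pedigree"))
  if (!is.null(ids)) {
    miss <- setdiff(ids, ped@id)
    if (length(miss)) {
      stop("subset id(s) not in pedigree: ", paste(miss, collapse = ", "))
    }
  }
  n <- length(ped@id)
  if (is.null(sparse)) sparse <- n > sparseThreshold

  blocks <- relationshipBlocks(ped)
  if (sparse) {
    A <- Matrix::bdiag(lapply(blocks, function(b) b$A))
    ord <- unlist(lapply(blocks, function(b) b$idx), use.names = FALSE)
    perm <- match(seq_len(n), ord)
    A <- as(A[perm, perm, drop = FALSE], "symmetricMatrix")
    dimnames(A) <- list(ped@id, ped@id)
  } else {
    A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
    for (b in blocks) A[b$idx, b$idx] <- b$A
  }
  if (!is.null(ids)) A <- A[ids, ids, drop = FALSE]
  A
}

# per-family tabular-method blocks; list of (idx into pedigree order, A)
relationshipBlocks <- function(ped) {
  famSplit <- split(seq_along(ped@id), ped@familyId)
  fiAll <- match(ped@father, ped@id)
  miAll <- match(ped@mother, ped@id)
  lapply(famSplit, function(idx) {
    m <- length(idx)
    ord <- idx[order(ped@generation[idx])]
    loc <- match(seq_along(ped@id), ord)        # pedigree index -> local row
    A <- matrix(0, m, m)
    for (r in seq_len(m)) {
      i <- ord[r]
      f <- loc[fiAll[i]]
      mo <- loc[miAll[i]]
      if (r > 1L) {
        prev <- seq_len(r - 1L)
        af <- if (!is.na(fiAll[i])) A[prev, f] else rep(0, r - 1L)
        am <- if (!is.na(miAll[i])) A[prev, mo] else rep(0, r - 1L)
        A[prev, r] <- (af + am) / 2
        A[r, prev] <- A[prev, r]
      }
      A[r, r] <- 1 + if (!is.na(fiAll[i]) && !is.na(miAll[i])) {
        A[f, mo] / 2
      } else 0
    }
    back <- order(match(ord, idx))
    list(idx = idx, A = A[back, back, drop = FALSE])
  })
}

#' Inbreeding coefficients
#'
#' Diagonal of the additive relationship matrix minus one.
#'
#' @param ped A [Pedigree-class].
#' @return Named numeric vector of inbreeding coefficients F.
#' @export
inbreeding <- function(ped) {
  blocks <- relationshipBlocks(ped)
  f <- numeric(length(ped@id))
  for (b in blocks) f[b$idx] <- diag(b$A) - 1
  setNames(f, ped@id)
}

#' Monte-Carlo relatedness by gene dropping
#'
#' Independent check of the tabular relationship matrix: two distinct allele
#' labels are assigned to every founder, transmitted to offspring uniformly
#' at random, and expected identity-by-descent sharing is estimated over many
#' replicates. The estimated a_ij is twice the realised kinship; diagonals
#' are 1 plus realised inbreeding. Returns Monte-Carlo standard errors so the
#' tabular entries can be compared at a stated number of MC standard
#' deviations.
#'
#' @param ped A [Pedigree-class] (intended for small pedigrees).
#' @param nrep number of gene-dropping replicates.
#' @param seed optional integer seed (local to this call).
#' @return list with `A` (estimated relationship matrix), `se` (elementwise
#'   Monte-Carlo standard errors) and `nrep`.
#' @export
geneDropRelatedness <- function(ped, nrep = 200000L, seed = NULL) {
  stopifnot(is(ped, "Pedigree"))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  id <- ped@id
  n <- length(id)
  fi <- match(ped@father, id)
  mi <- match(ped@mother, id)
  ord <- order(ped@generation)

  al1 <- vector("list", n)
  al2 <- vector("list", n)
  lab <- 0L
  for (k in ord) {
    if (is.na(fi[k]) && is.na(mi[k])) {
      al1[[k]] <- rep.int(lab + 1L, nrep)
      al2[[k]] <- rep.int(lab + 2L, nrep)
      lab <- lab + 2L
    } else {
      # an unknown single parent acts as a unique unrelated founder: the
      # transmitted allele is a fresh label never IBD with anything else
      if (!is.na(fi[k])) {
        pf <- runif(nrep) < 0.5
        al1[[k]] <- ifelse(pf, al1[[fi[k]]], al2[[fi[k]]])
      } else {
        al1[[k]] <- rep.int(lab + 1L, nrep)
        lab <- lab + 1L
      }
      if (!is.na(mi[k])) {
        pm <- runif(nrep) < 0.5
        al2[[k]] <- ifelse(pm, al1[[mi[k]]], al2[[mi[k]]])
      } else {
        al2[[k]] <- rep.int(lab + 1L, nrep)
        lab <- lab + 1L
      }
    }
  }

  A <- matrix(0, n, n, dimnames = list(id, id))
  SE <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    fRep <- as.numeric(al1[[i]] == al2[[i]])
    A[i, i] <- 1 + mean(fRep)
    SE[i, i] <- sd(fRep) / sqrt(nrep)
    for (j in seq_len(i - 1L)) {
      s <- (al1[[i]] == al1[[j]]) + (al1[[i]] == al2[[j]]) +
           (al2[[i]] == al1[[j]]) + (al2[[i]] == al2[[j]])
      aRep <- s / 2
      A[i, j] <- A[j, i] <- mean(aRep)
      SE[i, j] <- SE[j, i] <- sd(aRep) / sqrt(nrep)
    }
  }
  list(A = A, se = SE, nrep = nrep)
}
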