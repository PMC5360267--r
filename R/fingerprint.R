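# Circular (Morgan-style) 2D fingerprints over hashed atom environments,
# radius 0..2 bonds. This approximates the atom-environment fingerprints
# used for chemotype clustering: each heavy atom contributes one feature per
# radius, built from canonical (sorted) neighbour invariants, so the feature
# set is invariant under atom reordering. Stereochemistry does not enter.

# FNV-1a 32-bit hash of a string, kept in double arithmetic (R integers are
# 32-bit signed); returns a non-negative double < 2^31.
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h %% 2147483648
}

bitwXor_dbl <- function(a, b) {
  # a < 2^32, b < 256: xor of the low byte only
  lo <- a %% 256
  a - lo + bitwXor(as.integer(lo), as.integer(b))
}

#' Circular-environment fingerprint of one ligand
#'
#' Returns the set of hashed atom-environment identifiers (radius 0 to
#' `radius` bonds) of the molecule's heavy atoms. Identical molecules yield
#' identical sets irrespective of atom order.
#'
#' @param mol A parsed connection table (one element of a ligand tibble's
#'   `mol` column).
#' @param radius Maximum environment radius in bonds (default 2).
#' @return Sorted numeric vector of distinct feature hashes.
#' @export
fingerprint <- function(mol, radius = 2) {
  stopifnot(is.list(mol), n_heavy(mol) >= 1)
  at <- mol$atoms
  deg <- mol_degree(mol)
  inv <- paste(at$elem, at$charge, deg, at$nH, sep = "|")
  nbrs <- lapply(seq_len(nrow(at)), function(i) mol_neighbors(mol, i))
  bond_ord <- function(i, j) {
    b <- mol$bonds
    o <- b$order[(b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i)]
    o[1]
  }
  feats <- vapply(inv, function(s) fnv1a(paste0("0:", s)), numeric(1))
  cur <- inv
  for (r in seq_len(radius)) {
    nxt <- character(length(cur))
    for (i in seq_along(cur)) {
      if (!length(nbrs[[i]])) {
        nxt[i] <- NA_character_
        next
      }
      env <- sort(vapply(nbrs[[i]], function(j) {
        paste0(bond_ord(i, j), "~", cur[j])
      }, character(1)))
      nxt[i] <- paste0(cur[i], ";", paste(env, collapse = ","))
    }
    keep <- !is.na(nxt)
    if (!any(keep)) break
    feats <- c(feats, vapply(nxt[keep], function(s) {
      fnv1a(paste0(r, ":", s))
    }, numeric(1)))
    cur[keep] <- nxt[keep]
  }
  sort(unique(unname(feats)))
}

#' Add fingerprints to a ligand table
#'
#' @param ligands Ligand tibble with a `mol` column.
#' @param radius Environment radius in bonds.
#' @return Input tibble with an `fp` list-column of feature-hash sets.
#' @export
add_fingerprints <- function(ligands, radius = 2) {
  stopifnot(is.data.frame(ligands), "mol" %in% names(ligands))
  ligands$fp <- purrr::map(ligands$mol, fingerprint, radius = radius)
  ligands
}

#' Tanimoto similarity of two feature sets
#'
#' `|A intersect B| / |A union B|` over fingerprint feature sets.
#'
#' @param a,b Feature sets (numeric vectors) as returned by [fingerprint()].
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 2, 3, 4), c(2, 3, 9)) # 2 / (4 + 3 - 2) = 0.4
#' @export
tanimoto <- function(a, b) {
  if (!length(a) || !length(b)) {
    stop("tanimoto is undefined for empty fingerprints", call. = FALSE)
  }
  i <- length(intersect(a, b))
  i / (length(a) + length(b) - i)
}

#' Pairwise Tanimoto similarity / distance matrices
#'
#' @param ligands Ligand tibble carrying an `fp` column (see
#'   [add_fingerprints()]), or a plain named list of feature sets.
#' @return `tanimoto_matrix()`: symmetric similarity matrix with unit
#'   diagonal. `tanimoto_dist()`: the corresponding `1 - T` distance matrix.
#' @export
tanimoto_matrix <- function(ligands) {
  fps <- if (is.data.frame(ligands)) {
    stats::setNames(ligands$fp, ligands$id)
  } else {
    ligands
  }
  n <- length(fps)
  m <- diag(1, n)
  dimnames(m) <- list(names(fps), names(fps))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- tanimoto(fps[[i]], fps[[j]])
    }
  }
  m
}

#' @rdname tanimoto_matrix
#' @export
tanimoto_dist <- function(ligands) {
  1 - tanimoto_matrix(ligands)
}
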