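# Internal small-molecule representation.
#
# A "mol" is a plain list with two tibbles:
#   atoms: idx, elem, charge, nH (implicit hydrogens), x, y, z,
#          in_ring, in_arom_ring
#   bonds: a1, a2, order (kekulized; 1.5 used for unkekulizable aromatic input)
# Heavy atoms only; explicit hydrogens from input files are folded into nH.
# Parsing of SMILES/SDF is delegated to ChemmineR/ChemmineOB; everything
# downstream (typing, fingerprints, descriptors) works off this list.

# default valences used to assign implicit hydrogen counts; the effective
# valence is adjusted by the formal charge (N+ -> 4, O- -> 1, C+/- -> 3)
.default_valence <- c(
  C = 4, N = 3, O = 2, S = 2, P = 3, B = 3, Si = 4,
  F = 1, Cl = 1, Br = 1, I = 1
)

# standard atomic masses (most-abundant-isotope-weighted, g/mol)
.atomic_mass <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.086, P = 30.974, S = 32.065,
  Cl = 35.453, K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904,
  Fe = 55.845, Zn = 65.38
)

.effective_valence <- function(elem, charge) {
  v <- unname(.default_valence[elem])
  v[is.na(v)] <- 0
  adj <- ifelse(elem %in% c("N", "P", "O", "S"), charge,
    ifelse(elem %in% c("C", "B"), -abs(charge), 0)
  )
  pmax(v + adj, 0)
}

# Convert one ChemmineR SDF object into a mol list. Explicit hydrogens are
# absorbed into the nH count of their heavy neighbour.
mol_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(ab)) || nrow(ab) == 0) {
    stop("structure has no atoms", call. = FALSE)
  }
  elem <- sub("_.*$", "", rownames(ab))
  chg_code <- ab[, "C6"]
  charge <- ifelse(chg_code == 0, 0L, as.integer(4 - chg_code))
  xyz <- ab[, c("C1", "C2", "C3"), drop = FALSE]

  if (is.null(dim(bb)) || nrow(bb) == 0) {
    bonds <- tibble::tibble(a1 = integer(), a2 = integer(), order = numeric())
  } else {
    ord <- as.numeric(bb[, "C3"])
    ord[ord == 4] <- 1.5 # aromatic order in non-kekulized input
    bonds <- tibble::tibble(
      a1 = as.integer(bb[, "C1"]), a2 = as.integer(bb[, "C2"]), order = ord
    )
  }

  heavy <- elem != "H"
  n_exp_h <- vapply(seq_along(elem), function(i) {
    nb <- c(bonds$a2[bonds$a1 == i], bonds$a1[bonds$a2 == i])
    sum(elem[nb] == "H")
  }, integer(1))

  # re-index to heavy atoms
  map <- cumsum(heavy)
  keep <- bonds$a1 <= length(elem) & bonds$a2 <= length(elem) &
    heavy[bonds$a1] & heavy[bonds$a2]
  bonds <- bonds[keep, , drop = FALSE]
  bonds$a1 <- map[bonds$a1]
  bonds$a2 <- map[bonds$a2]

  atoms <- tibble::tibble(
    idx = seq_len(sum(heavy)),
    elem = elem[heavy],
    charge = charge[heavy],
    x = unname(xyz[heavy, 1]), y = unname(xyz[heavy, 2]),
    z = unname(xyz[heavy, 3])
  )
  bond_sum <- vapply(atoms$idx, function(i) {
    sum(bonds$order[bonds$a1 == i | bonds$a2 == i])
  }, numeric(1))
  implicit <- pmax(
    round(.effective_valence(atoms$elem, atoms$charge) - bond_sum -
      n_exp_h[heavy]), 0
  )
  atoms$nH <- as.integer(implicit + n_exp_h[heavy])

  mol <- list(atoms = atoms, bonds = bonds)
  mol <- mol_flag_rings(mol, sdf = sdf)
  mol
}

# Ring membership flags. When the originating SDF object is available,
# ChemmineR's ring perception (incl. aromaticity) is used; otherwise rings
# are taken from the fundamental cycles of the bond graph and flagged
# aromatic when 5/6-membered and composed of C/N/O/S only.
mol_flag_rings <- function(mol, sdf = NULL) {
  n <- nrow(mol$atoms)
  in_ring <- rep(FALSE, n)
  in_arom <- rep(FALSE, n)
  rings <- list()
  if (!is.null(sdf) && n >= 3 && nrow(mol$bonds) >= 3) {
    r <- tryCatch(
      ChemmineR::rings(sdf, upper = 8, type = "all", arom = TRUE),
      error = function(e) NULL
    )
    if (!is.null(r) && length(r$RINGS)) {
      for (k in seq_along(r$RINGS)) {
        idx <- as.integer(sub("^[^_]*_", "", r$RINGS[[k]]))
        rings[[length(rings) + 1]] <- idx
        in_ring[idx] <- TRUE
        if (isTRUE(r$AROMATIC[[k]])) in_arom[idx] <- TRUE
      }
    }
  } else if (n >= 3 && nrow(mol$bonds) >= 3) {
    rings <- find_rings(mol$bonds, n)
    for (idx in rings) {
      in_ring[idx] <- TRUE
      if (length(idx) %in% c(5L, 6L) &&
        all(mol$atoms$elem[idx] %in% c("C", "N", "O", "S"))) {
        in_arom[idx] <- TRUE
      }
    }
  }
  mol$atoms$in_ring <- in_ring
  mol$atoms$in_arom_ring <- in_arom
  mol$rings <- rings
  mol
}

# Fundamental cycles of the bond graph (spanning tree + chord paths).
find_rings <- function(bonds, n_atoms) {
  if (nrow(bonds) == 0 || n_atoms < 3) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = bonds$a1, to = bonds$a2),
    directed = FALSE, vertices = data.frame(name = seq_len(n_atoms))
  )
  tr <- igraph::mst(g)
  tr_edges <- igraph::as_edgelist(tr, names = TRUE)
  tr_key <- paste(
    pmin(as.integer(tr_edges[, 1]), as.integer(tr_edges[, 2])),
    pmax(as.integer(tr_edges[, 1]), as.integer(tr_edges[, 2]))
  )
  all_key <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
  chords <- which(!all_key %in% tr_key)
  out <- list()
  for (i in chords) {
    p <- igraph::shortest_paths(
      tr, from = as.character(bonds$a1[i]), to = as.character(bonds$a2[i])
    )$vpath[[1]]
    if (length(p)) out[[length(out) + 1]] <- as.integer(names(p))
  }
  out
}

# Connected components of the bond graph; returns a list of atom-index sets.
mol_components <- function(mol) {
  n <- nrow(mol$atoms)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      a <- queue[1]
      queue <- queue[-1]
      nb <- c(mol$bonds$a2[mol$bonds$a1 == a], mol$bonds$a1[mol$bonds$a2 == a])
      nb <- nb[comp[nb] == 0]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  split(seq_len(n), comp)
}

# Salt stripping: keep the largest connected fragment (ties -> the fragment
# containing the lowest atom index). Parent compounds are what ligand tables
# list, so counter-ions and co-crystallised fragments are dropped.
mol_largest_fragment <- function(mol) {
  comps <- mol_components(mol)
  if (length(comps) <= 1) return(mol)
  sizes <- lengths(comps)
  keep <- comps[[which.max(sizes)]] # which.max takes the first maximum
  mol_subset(mol, keep)
}

mol_subset <- function(mol, keep) {
  keep <- sort(keep)
  map <- match(seq_len(nrow(mol$atoms)), keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  atoms$idx <- seq_len(nrow(atoms))
  bk <- !is.na(map[mol$bonds$a1]) & !is.na(map[mol$bonds$a2])
  bonds <- mol$bonds[bk, , drop = FALSE]
  bonds$a1 <- map[bonds$a1]
  bonds$a2 <- map[bonds$a2]
  rings <- lapply(mol$rings, function(r) {
    r2 <- map[r]
    if (anyNA(r2)) NULL else as.integer(r2)
  })
  list(atoms = atoms, bonds = bonds, rings = Filter(Negate(is.null), rings))
}

n_heavy <- function(mol) nrow(mol$atoms)

# heavy-atom degree of every atom
mol_degree <- function(mol) {
  n <- nrow(mol$atoms)
  tab <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = n)
  as.integer(tab)
}

mol_neighbors <- function(mol, i) {
  c(mol$bonds$a2[mol$bonds$a1 == i], mol$bonds$a1[mol$bonds$a2 == i])
}

# Parse SMILES strings one by one so individual failures can be reported.
# Returns list(mols = named list, failures = tibble(input, reason)).
parse_smiles <- function(smiles, ids = names(smiles)) {
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  mols <- vector("list", length(smiles))
  fail <- list()
  for (i in seq_along(smiles)) {
    m <- tryCatch(
      {
        # explicit hydrogens (-h) keep single-heavy-atom molecules valid
        # and make donor counts observable
        txt <- suppressWarnings(ChemmineOB::convertFormat(
          "SMI", "SDF", paste0(smiles[i], "\n"),
          options = data.frame(names = "h", args = "")
        ))
        if (!nzchar(txt)) stop("invalid SMILES")
        sdf <- suppressWarnings(
          ChemmineR::read.SDFset(unlist(strsplit(txt, "\n", fixed = TRUE)))
        )
        mol_largest_fragment(mol_from_sdf(sdf[[1]]))
      },
      error = function(e) e
    )
    if (inherits(m, "error") || n_heavy(m) == 0) {
      fail[[length(fail) + 1]] <- tibble::tibble(
        id = ids[i], input = unname(smiles[i]),
        reason = if (inherits(m, "error")) conditionMessage(m) else "no heavy atoms"
      )
      mols[i] <- list(NULL)
    } else {
      mols[[i]] <- m
    }
  }
  names(mols) <- ids
  list(
    mols = mols,
    failures = if (length(fail)) dplyr::bind_rows(fail) else
      tibble::tibble(id = character(), input = character(), reason = character())
  )
}

# Rebuild a ChemmineR SDF object from a mol (used for Open Babel property
# calculation on the salt-stripped fragment, and for writing pose files).
mol_to_sdf <- function(mol, name = "mol") {
  n <- nrow(mol$atoms)
  ab <- cbind(
    mol$atoms$x, mol$atoms$y, mol$atoms$z,
    matrix(0, n, 12)
  )
  colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
  rownames(ab) <- paste(mol$atoms$elem, seq_len(n), sep = "_")
  chg <- mol$atoms$charge
  ab[, "C6"] <- ifelse(chg == 0, 0, 4 - chg)
  nb <- nrow(mol$bonds)
  if (nb > 0) {
    bb <- cbind(mol$bonds$a1, mol$bonds$a2, ceiling(mol$bonds$order),
      matrix(0, nb, 4))
  } else {
    bb <- matrix(0, 0, 7)
  }
  colnames(bb) <- paste0("C", 1:7)
  if (nb > 0) rownames(bb) <- seq_len(nb)
  cl <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  sdf <- methods::new("SDF",
    header = c(Molecule_Name = name, Source = "ligsel", Comment = "",
      Counts_Line = cl),
    atomblock = ab, bondblock = bb, datablock = character(0)
  )
  methods::new("SDFset", SDF = list(sdf), ID = name)
}
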