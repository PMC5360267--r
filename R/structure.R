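# Protein structures and ligand poses.
#
# A structure_model is a list(model_id, atoms, numbering) where atoms is a
# tibble: chain, resno, insert, resid (3-letter), elety (atom name), elem,
# x, y, z. residue_key = "chain:resno<insert>" identifies a residue.
#
# A ligand_pose is a list(ligand_id, atoms, bonds, donors, acceptors, rings,
# charged): atoms carries elem/x/y/z/charge (explicit H retained), typed
# groups reference atom indices. Typed groups are derived from the documented
# donor/acceptor rules and ring perception unless supplied explicitly.

residue_key <- function(chain, resno, insert = "") {
  ins <- ifelse(is.na(insert) | insert == "", "", insert)
  paste0(chain, ":", resno, ins)
}

#' Construct a protein structure model
#'
#' @param atoms Tibble with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`; optional `insert`, `elem`.
#' @param model_id Identifier (e.g. `"c1_m2_4oo9"`).
#' @return A `structure_model` object.
#' @export
structure_model <- function(atoms, model_id = "model") {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms lack columns: ", paste(miss, collapse = ", "),
    call. = FALSE)
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (!"elem" %in% names(atoms)) {
    atoms$elem <- guess_element(atoms$elety)
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in structure", call. = FALSE)
  }
  if (nrow(atoms) == 0) stop("structure has no atoms", call. = FALSE)
  atoms$residue_key <- residue_key(atoms$chain, atoms$resno, atoms$insert)
  structure(
    list(model_id = model_id, atoms = tibble::as_tibble(atoms),
      numbering = NULL),
    class = "structure_model"
  )
}

guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", elety)
  two <- toupper(substr(e, 1, 2))
  one <- toupper(substr(e, 1, 1))
  ifelse(two %in% c("CL", "BR", "ZN", "FE", "MG", "NA", "SE"),
    paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))), one)
}

#' @export
print.structure_model <- function(x, ...) {
  res <- unique(x$atoms$residue_key)
  cat("<structure_model> ", x$model_id, ": ", length(res), " residues, ",
    nrow(x$atoms), " atoms",
    if (!is.null(x$numbering)) " (numbered)" else "", "\n", sep = "")
  invisible(x)
}

#' Read a protein model from PDB
#'
#' Keeps `ATOM` records with alternate location blank or `"A"`; insertion
#' codes are preserved in residue keys; hydrogens are kept when present.
#'
#' @param path PDB file path.
#' @param model_id Model identifier; defaults to the file stem.
#' @return A `structure_model`.
#' @export
read_protein <- function(path, model_id = NULL) {
  if (!file.exists(path)) stop("protein file not found: ", path, call. = FALSE)
  if (is.null(model_id)) model_id <- sub("\\.pdb$", "", basename(path),
    ignore.case = TRUE)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- tibble::as_tibble(pdb$atom)
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path, call. = FALSE)
  atoms <- tibble::tibble(
    chain = at$chain, resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid, elety = at$elety,
    elem = ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
      guess_element(at$elety), trimws(at$elesy)),
    x = at$x, y = at$y, z = at$z
  )
  structure_model(atoms, model_id = model_id)
}

# ---- ligand poses ----------------------------------------------------------

#' Construct a ligand pose
#'
#' Typed interaction groups (hydrogen-bond donors/acceptors, aromatic rings,
#' charged atoms) are derived from the connection table using the package's
#' donor/acceptor rules and ring perception; any can be overridden.
#'
#' @param atoms Tibble `elem`, `x`, `y`, `z`, optional `charge` (explicit
#'   hydrogens allowed and used for hydrogen-bond geometry).
#' @param bonds Tibble `a1`, `a2`, `order` (indices into `atoms`); may be
#'   `NULL`, in which case bonds are inferred from covalent distances.
#' @param ligand_id Identifier.
#' @param rings Optional list of heavy-atom index vectors forming aromatic
#'   rings (overrides detection).
#' @return A `ligand_pose` object.
#' @export
ligand_pose <- function(atoms, bonds = NULL, ligand_id = "ligand",
                        rings = NULL) {
  stopifnot(all(c("elem", "x", "y", "z") %in% names(atoms)))
  atoms <- tibble::as_tibble(atoms)
  if (!"charge" %in% names(atoms)) atoms$charge <- 0L
  heavy <- which(atoms$elem != "H")
  if (!length(heavy)) stop("ligand pose has no heavy atoms", call. = FALSE)
  if (is.null(bonds)) bonds <- infer_bonds(atoms)
  bonds <- tibble::as_tibble(bonds)
  if (!"order" %in% names(bonds)) bonds$order <- 1

  nbr_h <- lapply(seq_len(nrow(atoms)), function(i) {
    nb <- c(bonds$a2[bonds$a1 == i], bonds$a1[bonds$a2 == i])
    nb[atoms$elem[nb] == "H"]
  })
  # implicit hydrogens from valence arithmetic (bond orders + explicit H)
  ord_sum <- vapply(seq_len(nrow(atoms)), function(i) {
    sum(bonds$order[bonds$a1 == i | bonds$a2 == i])
  }, numeric(1))
  imp_h <- pmax(round(.effective_valence(atoms$elem, atoms$charge) - ord_sum),
    0)
  # donors: N/O with >= 1 hydrogen. Explicit hydrogens are recorded for the
  # D-H...A angle test; donors known only through implicit hydrogens fall
  # back to the distance-only criterion.
  donors <- purrr::map_dfr(heavy, function(i) {
    if (!atoms$elem[i] %in% c("N", "O")) return(NULL)
    hs <- nbr_h[[i]]
    if (length(hs)) {
      tibble::tibble(atom = i, h = hs)
    } else if (imp_h[i] >= 1) {
      tibble::tibble(atom = i, h = NA_integer_)
    } else {
      NULL
    }
  })
  # acceptors: N/O not positively charged, excluding amide/pyrrole-type N
  hmol <- list(
    atoms = tibble::tibble(
      idx = seq_along(heavy), elem = atoms$elem[heavy],
      charge = atoms$charge[heavy],
      nH = vapply(nbr_h[heavy], length, integer(1)) +
        as.integer(imp_h[heavy]),
      x = atoms$x[heavy], y = atoms$y[heavy], z = atoms$z[heavy]
    ),
    bonds = {
      hmap <- match(seq_len(nrow(atoms)), heavy)
      bb <- bonds[atoms$elem[bonds$a1] != "H" & atoms$elem[bonds$a2] != "H", ,
        drop = FALSE]
      tibble::tibble(a1 = hmap[bb$a1], a2 = hmap[bb$a2], order = bb$order)
    }
  )
  hmol <- mol_flag_rings(hmol)
  acc_heavy <- heavy[atom_is_acceptor(hmol)]
  if (is.null(rings)) {
    rings <- lapply(
      Filter(function(r) {
        length(r) %in% c(5L, 6L) &&
          all(hmol$atoms$elem[r] %in% c("C", "N", "O", "S"))
      }, hmol$rings),
      function(r) heavy[r]
    )
  }
  charged <- heavy[atoms$charge[heavy] != 0]

  structure(
    list(
      ligand_id = ligand_id, atoms = atoms, bonds = bonds,
      donors = if (nrow(donors)) donors else
        tibble::tibble(atom = integer(), h = integer()),
      acceptors = acc_heavy, rings = rings, charged = charged
    ),
    class = "ligand_pose"
  )
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat("<ligand_pose> ", x$ligand_id, ": ",
    sum(x$atoms$elem != "H"), " heavy atoms, ",
    nrow(x$donors), " donor(s), ", length(x$acceptors), " acceptor(s), ",
    length(x$rings), " ring(s)\n", sep = "")
  invisible(x)
}

# covalent-distance bond inference for poses read without a bond table
infer_bonds <- function(atoms) {
  rad <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
    F = 0.57, Cl = 1.02, Br = 1.2, I = 1.39)
  n <- nrow(atoms)
  out <- list()
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      d <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
        (atoms$z[i] - atoms$z[j])^2)
      lim <- 1.3 * sum(rad[c(atoms$elem[i], atoms$elem[j])], na.rm = TRUE)
      if (is.finite(lim) && lim > 0 && d <= lim) {
        out[[length(out) + 1]] <- tibble::tibble(a1 = i, a2 = j, order = 1)
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(a1 = integer(), a2 = integer(), order = numeric())
}

#' Read a ligand pose from SDF or PDB
#'
#' @param path Pose file (`.sdf` with bonds and charges, or a PDB whose
#'   HETATM records form the ligand; bonds then inferred from distances).
#' @param ligand_id Identifier; defaults to the SDF molecule name or file
#'   stem.
#' @return A `ligand_pose`.
#' @export
read_ligand_pose <- function(path, ligand_id = NULL) {
  if (!file.exists(path)) stop("ligand file not found: ", path, call. = FALSE)
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    sdfset <- ChemmineR::read.SDFset(path)
    if (length(sdfset) > 1) {
      warning("pose file contains ", length(sdfset),
        " entries; using the first", call. = FALSE)
    }
    sdf <- sdfset[[1]]
    if (is.null(ligand_id)) {
      ligand_id <- unname(ChemmineR::sdfid(sdfset)[1])
      if (is.na(ligand_id) || !nzchar(ligand_id)) {
        ligand_id <- sub("\\.sdf$", "", basename(path), ignore.case = TRUE)
      }
    }
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elem <- sub("_.*$", "", rownames(ab))
    chg <- ifelse(ab[, "C6"] == 0, 0L, as.integer(4 - ab[, "C6"]))
    atoms <- tibble::tibble(
      elem = elem, x = unname(ab[, "C1"]), y = unname(ab[, "C2"]),
      z = unname(ab[, "C3"]), charge = chg
    )
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) NULL else tibble::tibble(
      a1 = as.integer(bb[, "C1"]), a2 = as.integer(bb[, "C2"]),
      order = ifelse(bb[, "C3"] == 4, 1.5, as.numeric(bb[, "C3"]))
    )
    ligand_pose(atoms, bonds, ligand_id = ligand_id)
  } else {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    at <- tibble::as_tibble(pdb$atom)
    at <- at[at$type == "HETATM" | at$type == "ATOM", , drop = FALSE]
    at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
    if (nrow(at) == 0) stop("no atoms in ", path, call. = FALSE)
    if (is.null(ligand_id)) {
      ligand_id <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
    }
    atoms <- tibble::tibble(
      elem = ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
        guess_element(at$elety), trimws(at$elesy)),
      x = at$x, y = at$y, z = at$z,
      charge = suppressWarnings(
        ifelse(is.na(as.numeric(at$charge)), 0, as.numeric(at$charge))
      )
    )
    ligand_pose(atoms, bonds = NULL, ligand_id = ligand_id)
  }
}

#' Read a protein-ligand complex
#'
#' @param protein_path PDB file of the protein model.
#' @param ligand_path SDF or PDB file of the docked ligand pose.
#' @param model_id,ligand_id Optional identifiers.
#' @return List with elements `model` ([structure_model]) and `pose`
#'   ([ligand_pose]).
#' @export
read_complex <- function(protein_path, ligand_path, model_id = NULL,
                         ligand_id = NULL) {
  list(
    model = read_protein(protein_path, model_id = model_id),
    pose = read_ligand_pose(ligand_path, ligand_id = ligand_id)
  )
}
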