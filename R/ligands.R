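#' Read a ligand library from a SMILES or SDF file
#'
#' Reads a compound library and attaches a role label to every record.
#' SMILES files hold one record per line, `SMILES<whitespace>id`; lines whose
#' structure cannot be parsed are reported (message + `failures` attribute),
#' never silently dropped. Multi-fragment inputs (salts) are reduced to their
#' largest fragment, since ligand tables list parent compounds.
#'
#' @param path Path to a `.smi`/`.smiles` (SMILES) or `.sdf` file.
#' @param role Role label attached to every record: one of `"active"`,
#'   `"inactive"`, `"decoy"`, `"candidate"`.
#' @param format File format; `"auto"` (default) decides from the extension.
#' @return A ligand tibble with columns `id`, `role`, `smiles` (when read from
#'   SMILES), `n_heavy` and a `mol` list-column holding parsed connection
#'   tables. Unparsable records are in `attr(, "failures")`.
#' @examples
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("CCO ethanol", "c1ccccc1 benzene"), f)
#' read_ligands(f, role = "active")
#' @export
read_ligands <- function(path, role = c("active", "inactive", "decoy", "candidate"),
                         format = c("auto", "smiles", "sdf")) {
  role <- match.arg(role)
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("ligand file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smiles"
  }
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stop("no records in ", path, call. = FALSE)
    toks <- strsplit(lines, "[[:space:]]+")
    smiles <- vapply(toks, `[[`, character(1), 1)
    ids <- vapply(seq_along(toks), function(i) {
      if (length(toks[[i]]) >= 2) toks[[i]][[2]] else paste0("mol", i)
    }, character(1))
    parsed <- parse_smiles(smiles, ids)
  } else {
    sdfset <- ChemmineR::read.SDFset(path)
    ids <- unname(ChemmineR::sdfid(sdfset))
    ids[is.na(ids) | !nzchar(ids)] <- paste0("mol", which(is.na(ids) | !nzchar(ids)))
    mols <- vector("list", length(sdfset))
    fail <- list()
    for (i in seq_along(sdfset)) {
      m <- tryCatch(mol_largest_fragment(mol_from_sdf(sdfset[[i]])),
        error = function(e) e)
      if (inherits(m, "error") || n_heavy(m) == 0) {
        fail[[length(fail) + 1]] <- tibble::tibble(
          id = ids[i], input = NA_character_,
          reason = if (inherits(m, "error")) conditionMessage(m) else "no heavy atoms"
        )
        mols[i] <- list(NULL)
      } else {
        mols[[i]] <- m
      }
    }
    names(mols) <- ids
    parsed <- list(
      mols = mols,
      failures = if (length(fail)) dplyr::bind_rows(fail) else
        tibble::tibble(id = character(), input = character(), reason = character())
    )
    smiles <- rep(NA_character_, length(ids))
  }

  ok <- !vapply(parsed$mols, is.null, logical(1))
  if (!any(ok)) {
    stop("no parsable records in ", path, call. = FALSE)
  }
  if (nrow(parsed$failures)) {
    message(
      nrow(parsed$failures), " record(s) failed to parse in ", basename(path),
      ": ", paste(parsed$failures$id, collapse = ", ")
    )
  }
  out <- ligand_tbl(
    id = names(parsed$mols)[ok],
    mol = parsed$mols[ok],
    smiles = smiles[ok],
    role = role
  )
  attr(out, "failures") <- parsed$failures
  out
}

#' Build a ligand tibble from SMILES strings
#'
#' Convenience constructor used throughout the package and its tests.
#'
#' @param smiles Character vector of SMILES strings (named or with `id`).
#' @param id Record identifiers; must be unique.
#' @param role Role label recycled across records.
#' @param mol Optional pre-parsed connection tables (internal use).
#' @return A ligand tibble (`id`, `role`, `smiles`, `n_heavy`, `mol`).
#' @export
ligand_tbl <- function(smiles = NULL, id = names(smiles),
                       role = "candidate", mol = NULL) {
  if (is.null(mol)) {
    if (is.null(id)) id <- paste0("mol", seq_along(smiles))
    parsed <- parse_smiles(smiles, id)
    bad <- vapply(parsed$mols, is.null, logical(1))
    if (any(bad)) {
      stop("unparsable structure(s): ", paste(id[bad], collapse = ", "),
        call. = FALSE)
    }
    mol <- parsed$mols
  }
  if (is.null(id)) id <- names(mol)
  if (anyDuplicated(id)) {
    stop("ligand ids must be unique; duplicated: ",
      paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  role <- rep_len(role, length(id))
  stopifnot(all(role %in% c("active", "inactive", "decoy", "candidate")))
  tibble::tibble(
    id = id,
    role = role,
    smiles = if (is.null(smiles)) NA_character_ else unname(smiles),
    n_heavy = unname(vapply(mol, n_heavy, integer(1))),
    mol = unname(mol)
  )
}

# ---- atom typing rules -----------------------------------------------------
# Documented DUD-era conventions:
#   donor:    N or O carrying at least one hydrogen (explicit or implicit)
#   acceptor: N or O that is not positively charged, excluding amide-type N
#             (N single-bonded to a C that is double-bonded to O or S) and
#             pyrrole-type N (ring N with no double bond inside the ring,
#             i.e. its lone pair is part of the aromatic sextet)
#   rotatable bond: non-ring single bond between two heavy atoms that each
#             have >= 2 heavy neighbours, excluding amide C-N bonds

atom_is_donor <- function(mol) {
  mol$atoms$elem %in% c("N", "O") & mol$atoms$nH >= 1
}

atom_is_acceptor <- function(mol) {
  at <- mol$atoms
  acc <- at$elem %in% c("N", "O") & at$charge <= 0
  if (!any(acc)) return(acc)
  for (i in which(acc & at$elem == "N")) {
    nb <- mol_neighbors(mol, i)
    # amide-type N
    amide <- any(vapply(nb, function(j) {
      if (at$elem[j] != "C") return(FALSE)
      jb <- mol$bonds[(mol$bonds$a1 == j | mol$bonds$a2 == j), ]
      other <- ifelse(jb$a1 == j, jb$a2, jb$a1)
      any(jb$order == 2 & at$elem[other] %in% c("O", "S"))
    }, logical(1)))
    # pyrrole-type N: in a ring with no double bond at the N itself
    nb_bonds <- mol$bonds[mol$bonds$a1 == i | mol$bonds$a2 == i, ]
    pyrrole <- at$in_ring[i] && all(nb_bonds$order < 2) && at$nH[i] >= 1
    if (amide || pyrrole) acc[i] <- FALSE
  }
  acc
}

bond_in_ring <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0) return(logical(0))
  keys <- lapply(mol$rings, function(r) {
    rr <- c(r, r[1])
    paste(pmin(rr[-length(rr)], rr[-1]), pmax(rr[-length(rr)], rr[-1]))
  })
  keys <- unlist(keys)
  paste(pmin(mol$bonds$a1, mol$bonds$a2), pmax(mol$bonds$a1, mol$bonds$a2)) %in% keys
}

count_rotatable <- function(mol) {
  if (nrow(mol$bonds) == 0) return(0L)
  deg <- mol_degree(mol)
  inring <- bond_in_ring(mol)
  at <- mol$atoms
  rot <- 0L
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a1[b]
    j <- mol$bonds$a2[b]
    if (mol$bonds$order[b] != 1 || inring[b]) next
    if (deg[i] < 2 || deg[j] < 2) next
    # amide C-N exclusion
    is_amide <- function(c_at, n_at) {
      if (at$elem[c_at] != "C" || at$elem[n_at] != "N") return(FALSE)
      cb <- mol$bonds[mol$bonds$a1 == c_at | mol$bonds$a2 == c_at, ]
      other <- ifelse(cb$a1 == c_at, cb$a2, cb$a1)
      any(cb$order == 2 & at$elem[other] == "O")
    }
    if (is_amide(i, j) || is_amide(j, i)) next
    rot <- rot + 1L
  }
  rot
}

mol_weight <- function(mol) {
  m <- .atomic_mass[mol$atoms$elem]
  m[is.na(m)] <- 0
  sum(m) + sum(mol$atoms$nH) * .atomic_mass[["H"]]
}

# ---- descriptors -----------------------------------------------------------

#' Compute physicochemical descriptors for a ligand table
#'
#' Adds the six descriptors used for DUD-style property matching: molecular
#' weight, calculated logP, hydrogen-bond donor and acceptor counts, rotatable
#' bond count and formal net charge at the drawn protonation state (no pKa
#' model is applied). Donor/acceptor/rotatable typing follows the documented
#' rules in the package (see Details).
#'
#' @details Donors are N/O atoms with at least one hydrogen; acceptors are
#' N/O atoms that are not positively charged, excluding amide- and
#' pyrrole-type nitrogens; rotatable bonds are acyclic single bonds between
#' two non-terminal heavy atoms, excluding amide C-N bonds. logP is Open
#' Babel's partition-coefficient estimate on the salt-stripped structure.
#'
#' @param ligands A ligand tibble (from [read_ligands()] or [ligand_tbl()]).
#' @return The input tibble with columns `mw`, `clogp`, `hbd`, `hba`, `rotb`,
#'   `net_charge` added.
#' @examples
#' ligand_tbl(c(ethanol = "CCO")) |> add_descriptors()
#' @export
add_descriptors <- function(ligands) {
  stopifnot(is.data.frame(ligands), "mol" %in% names(ligands))
  desc <- purrr::map(ligands$mol, descriptor_row)
  dplyr::bind_cols(ligands, dplyr::bind_rows(desc))
}

descriptor_row <- function(mol) {
  tibble::tibble(
    mw = mol_weight(mol),
    clogp = clogp_ob(mol),
    hbd = sum(atom_is_donor(mol)),
    hba = sum(atom_is_acceptor(mol)),
    rotb = count_rotatable(mol),
    net_charge = as.integer(sum(mol$atoms$charge))
  )
}

# Open Babel logP on the salt-stripped structure (via ChemmineR/ChemmineOB).
clogp_ob <- function(mol) {
  out <- tryCatch(
    suppressWarnings(ChemmineR::propOB(mol_to_sdf(mol))$logP),
    error = function(e) NA_real_
  )
  as.numeric(out)[1]
}

#' Write a ligand manifest CSV
#'
#' @param ligands Ligand tibble; descriptor columns are included when present.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ligand_manifest <- function(ligands, path) {
  keep <- intersect(
    c("id", "role", "cluster_id", "mw", "clogp", "hbd", "hba", "rotb",
      "net_charge"),
    names(ligands)
  )
  readr::write_csv(dplyr::select(ligands, dplyr::all_of(keep)), path)
  invisible(path)
}
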