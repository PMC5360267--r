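# Structural interaction fingerprints (SIFt): per-residue 9-bit interaction
# vectors from a protein-ligand complex, aggregation into any-contact
# profiles with binding-site retention and hotspot calling, and the grid-box
# pose QC check.

# residue classification used for the polar / hydrophobic / charged /
# aromatic bits (explicit so counts are reproducible)
.res_class <- list(
  polar = c("SER", "THR", "CYS", "TYR", "ASN", "GLN", "HIS"),
  charged = c("ASP", "GLU", "LYS", "ARG"),
  hydrophobic = c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO",
    "GLY"),
  aromatic = c("PHE", "TYR", "TRP", "HIS")
)

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

# side-chain ring atoms of the aromatic residues
.ring_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

# protein hydrogen-bond capable atoms: donor heavy atoms (with the names of
# hydrogens that may sit on them) and acceptor heavy atoms
.prot_donor <- list(
  backbone = list(N = c("H", "HN")),
  SER = list(OG = "HG"), THR = list(OG1 = "HG1"), TYR = list(OH = "HH"),
  CYS = list(SG = "HG"), ASN = list(ND2 = c("HD21", "HD22")),
  GLN = list(NE2 = c("HE21", "HE22")), HIS = list(ND1 = "HD1", NE2 = "HE2"),
  LYS = list(NZ = c("HZ1", "HZ2", "HZ3")),
  ARG = list(NE = "HE", NH1 = c("HH11", "HH12"), NH2 = c("HH21", "HH22")),
  TRP = list(NE1 = "HE1")
)
.prot_acceptor <- list(
  backbone = c("O", "OXT"),
  SER = "OG", THR = "OG1", TYR = "OH",
  ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), MET = "SD"
)

# formally charged protein side-chain atoms at pH 7.4
.prot_charge <- list(
  ASP = list(atoms = c("OD1", "OD2"), sign = -1),
  GLU = list(atoms = c("OE1", "OE2"), sign = -1),
  LYS = list(atoms = "NZ", sign = 1),
  ARG = list(atoms = c("NE", "NH1", "NH2"), sign = 1)
)

#' Geometry thresholds for SIFt computation
#'
#' @param contact_cutoff Heavy-atom contact distance cutoff in Angstrom
#'   (inclusive; default 4.0).
#' @param hb_dist Donor-acceptor heavy-atom distance ceiling for hydrogen
#'   bonds (default 3.5).
#' @param hb_angle Minimum D-H...A angle in degrees when the hydrogen is
#'   present (default 120); distance-only fallback when it is not.
#' @return A `sift_params` list.
#' @export
sift_params <- function(contact_cutoff = 4.0, hb_dist = 3.5, hb_angle = 120) {
  stopifnot(contact_cutoff > 0, hb_dist > 0, hb_angle >= 0, hb_angle <= 180)
  structure(list(contact_cutoff = contact_cutoff, hb_dist = hb_dist,
    hb_angle = hb_angle), class = "sift_params")
}

.dist3 <- function(p, q) {
  sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2 + (p[3] - q[3])^2)
}

.angle_deg <- function(a, b, c) {
  # angle at b, degrees
  u <- a - b
  v <- c - b
  cosv <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
}

#' Residues in contact with a ligand pose
#'
#' A residue is in contact when the minimum heavy-atom to heavy-atom
#' distance to the ligand is at or below the cutoff (the 4 Angstrom boundary
#' is inclusive).
#'
#' @param model A [structure_model].
#' @param pose A [ligand_pose].
#' @param cutoff Contact cutoff in Angstrom.
#' @return Tibble `residue_key`, `chain`, `resno`, `insert`, `resid`,
#'   `min_dist`, sorted by chain and residue number.
#' @export
contacts <- function(model, pose, cutoff = 4.0) {
  stopifnot(inherits(model, "structure_model"), inherits(pose, "ligand_pose"),
    cutoff > 0)
  pat <- model$atoms[model$atoms$elem != "H", , drop = FALSE]
  lat <- pose$atoms[pose$atoms$elem != "H", , drop = FALSE]
  dm <- dist_matrix(pat, lat)
  min_d <- apply(dm, 1, min)
  out <- pat |>
    dplyr::mutate(min_dist = min_d) |>
    dplyr::group_by(.data$residue_key, .data$chain, .data$resno,
      .data$insert, .data$resid) |>
    dplyr::summarise(min_dist = min(.data$min_dist), .groups = "drop") |>
    dplyr::filter(.data$min_dist <= cutoff) |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert)
  out
}

dist_matrix <- function(a, b) {
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rep(1, nrow(bx))) +
    outer(rep(1, nrow(ax)), rowSums(bx^2)) - 2 * ax %*% t(bx)
  sqrt(pmax(d2, 0))
}

#' Compute the 9-bit SIFt of a ligand pose in a protein model
#'
#' For every residue within the contact cutoff the nine interaction bits are
#' evaluated: any contact, backbone, side chain, polar, hydrophobic,
#' hydrogen-bond donor (ligand donates), hydrogen-bond acceptor (ligand
#' accepts), aromatic, charged. Polar/hydrophobic/aromatic/charged use the
#' explicit residue classification shipped with the package; hydrogen bonds
#' use a distance ceiling plus a D-H...A angle test whenever the donor
#' hydrogen is present in the input. Unknown residue names get generic
#' side-chain typing with a warning.
#'
#' @param model A [structure_model]; if numbering has been attached with
#'   [assign_numbers()], a `position` column is included.
#' @param pose A [ligand_pose].
#' @param params A [sift_params()].
#' @return Tibble with one row per contacted residue: identifiers, the nine
#'   logical bit columns, `min_dist` and `ligand_id`/`model_id`.
#' @export
sift_bits <- function(model, pose, params = sift_params()) {
  con <- contacts(model, pose, cutoff = params$contact_cutoff)
  if (nrow(con) == 0) {
    return(empty_bits(model, pose))
  }
  known <- con$resid %in% unique(c(unlist(.res_class), "GLY"))
  if (any(!known)) {
    warning("unknown residue name(s): ",
      paste(unique(con$resid[!known]), collapse = ", "),
      "; using generic side-chain typing", call. = FALSE)
  }
  lat <- pose$atoms
  lheavy <- which(lat$elem != "H")
  rows <- purrr::map_dfr(seq_len(nrow(con)), function(i) {
    rk <- con$residue_key[i]
    resid <- con$resid[i]
    rat <- model$atoms[model$atoms$residue_key == rk, , drop = FALSE]
    rat_h <- rat[rat$elem != "H", , drop = FALSE]
    bb <- rat_h$elety %in% .backbone_atoms
    dm <- dist_matrix(rat_h, lat[lheavy, , drop = FALSE])
    within <- dm <= params$contact_cutoff

    backbone_bit <- any(within[bb, , drop = FALSE])
    side_bit <- any(within[!bb, , drop = FALSE])
    polar_bit <- resid %in% c(.res_class$polar, .res_class$charged)
    hydro_bit <- resid %in% .res_class$hydrophobic

    # --- hydrogen bonds ---
    don_bit <- FALSE # ligand donates
    acc_names <- c(.prot_acceptor$backbone, .prot_acceptor[[resid]])
    acc_rows <- which(rat_h$elety %in% acc_names)
    if (nrow(pose$donors) && length(acc_rows)) {
      for (d in seq_len(nrow(pose$donors))) {
        datom <- pose$donors$atom[d]
        dpos <- c(lat$x[datom], lat$y[datom], lat$z[datom])
        hidx <- pose$donors$h[d]
        for (ar in acc_rows) {
          apos <- c(rat_h$x[ar], rat_h$y[ar], rat_h$z[ar])
          if (.dist3(dpos, apos) > params$hb_dist) next
          if (!is.na(hidx)) {
            hpos <- c(lat$x[hidx], lat$y[hidx], lat$z[hidx])
            if (.angle_deg(dpos, hpos, apos) < params$hb_angle) next
          }
          don_bit <- TRUE
        }
      }
    }
    lacc_bit <- FALSE # ligand accepts
    don_spec <- c(.prot_donor$backbone, .prot_donor[[resid]])
    if (length(pose$acceptors) && length(don_spec)) {
      for (dn in names(don_spec)) {
        drow <- which(rat_h$elety == dn)
        if (!length(drow)) next
        dpos <- c(rat_h$x[drow[1]], rat_h$y[drow[1]], rat_h$z[drow[1]])
        hrow <- which(rat$elety %in% don_spec[[dn]] & rat$elem == "H")
        for (ai in pose$acceptors) {
          apos <- c(lat$x[ai], lat$y[ai], lat$z[ai])
          if (.dist3(dpos, apos) > params$hb_dist) next
          if (length(hrow)) {
            ok_angle <- any(vapply(hrow, function(hr) {
              hpos <- c(rat$x[hr], rat$y[hr], rat$z[hr])
              .angle_deg(dpos, hpos, apos) >= params$hb_angle
            }, logical(1)))
            if (!ok_angle) next
          }
          lacc_bit <- TRUE
        }
      }
    }

    # --- aromatic: both rings contribute atoms within the contact cutoff ---
    arom_bit <- FALSE
    if (resid %in% .res_class$aromatic && length(pose$rings)) {
      ring_rows <- which(rat_h$elety %in% .ring_atoms[[resid]])
      if (length(ring_rows)) {
        for (ring in pose$rings) {
          sub <- dm[ring_rows, match(ring, lheavy), drop = FALSE]
          if (any(sub <= params$contact_cutoff)) arom_bit <- TRUE
        }
      }
    }

    # --- charged: opposite formal charges within the contact cutoff ---
    chg_bit <- FALSE
    pc <- .prot_charge[[resid]]
    if (!is.null(pc) && length(pose$charged)) {
      crow <- which(rat_h$elety %in% pc$atoms)
      lchg <- pose$charged[sign(lat$charge[pose$charged]) == -pc$sign]
      if (length(crow) && length(lchg)) {
        sub <- dm[crow, match(lchg, lheavy), drop = FALSE]
        if (any(sub <= params$contact_cutoff)) chg_bit <- TRUE
      }
    }

    tibble::tibble(
      residue_key = rk, chain = con$chain[i], resno = con$resno[i],
      insert = con$insert[i], resid = resid, min_dist = con$min_dist[i],
      any_contact = TRUE, backbone = backbone_bit, side_chain = side_bit,
      polar = polar_bit, hydrophobic = hydro_bit,
      hbond_donor = don_bit, hbond_acceptor = lacc_bit,
      aromatic = arom_bit, charged = chg_bit
    )
  })
  rows$ligand_id <- pose$ligand_id
  rows$model_id <- model$model_id
  rows$position <- map_positions(model, rows$resno, rows$chain)
  rows
}

empty_bits <- function(model, pose) {
  tibble::tibble(
    residue_key = character(), chain = character(), resno = integer(),
    insert = character(), resid = character(), min_dist = numeric(),
    any_contact = logical(), backbone = logical(), side_chain = logical(),
    polar = logical(), hydrophobic = logical(), hbond_donor = logical(),
    hbond_acceptor = logical(), aromatic = logical(), charged = logical(),
    ligand_id = character(), model_id = character(), position = character()
  )
}

# generic-number label for residues of a numbered model; residues outside
# the helix spans keep their raw residue key so loop contacts (e.g. EL2)
# are not silently lost
map_positions <- function(model, resno, chain) {
  if (is.null(model$numbering)) {
    return(residue_key(chain, resno))
  }
  lab <- model$numbering$label[match(resno, model$numbering$resno)]
  ifelse(is.na(lab), residue_key(chain, resno), lab)
}

.bit_names <- c("any_contact", "backbone", "side_chain", "polar",
  "hydrophobic", "hbond_donor", "hbond_acceptor", "aromatic", "charged")

#' Aggregate SIFt bit sets into an any-contact profile
#'
#' The profile frequency of a position is the fraction of ligands (distinct
#' `model_id`/`ligand_id` pairs in the input) whose fingerprint has the
#' any-contact bit set there. Positions above the retention cutoff
#' (strictly, "more than 50 percent of the ligands") define the consensus
#' binding site; positions at or above the hotspot threshold are flagged
#' hotspots.
#'
#' @param bits Tibble of SIFt rows (stacked [sift_bits()] output).
#' @param cutoff Retention cutoff on the any-contact frequency (strict `>`;
#'   default 0.5).
#' @param hotspot Hotspot threshold (inclusive `>=`; default 0.95).
#' @param profile_id Label stored with the profile.
#' @return A `sift_profile` tibble: `position`, `freq`, `retained`,
#'   `hotspot`, with attributes `n_ligands`, `cutoff`,
#'   `hotspot_threshold`, `profile_id`.
#' @export
sift_profile <- function(bits, cutoff = 0.5, hotspot = 0.95,
                         profile_id = "SIFt") {
  stopifnot(is.data.frame(bits))
  if (nrow(bits) == 0) stop("empty SIFt bit input", call. = FALSE)
  if (!"model_id" %in% names(bits)) bits$model_id <- "model"
  lig_key <- paste(bits$model_id, bits$ligand_id)
  n_lig <- dplyr::n_distinct(lig_key)
  sub <- tibble::tibble(
    position = bits$position[bits$any_contact],
    key = lig_key[bits$any_contact]
  )
  freq_tbl <- sub |>
    dplyr::distinct() |>
    dplyr::count(.data$position, name = "n_contact") |>
    dplyr::mutate(freq = .data$n_contact / n_lig)
  call_binding_site(freq_tbl[, c("position", "freq")], cutoff = cutoff,
    hotspot = hotspot, profile_id = profile_id, n_ligands = n_lig)
}

#' Apply retention and hotspot rules to a frequency table
#'
#' Shared site-calling step for computed profiles and published frequency
#' tables: retained positions have `freq > cutoff`, hotspots have
#' `freq >= hotspot` (a hotspot is always retained when
#' `hotspot > cutoff`).
#'
#' @param freq_tbl Tibble with `position` and `freq` columns (frequencies in
#'   `[0, 1]`).
#' @inheritParams sift_profile
#' @param n_ligands Optional ligand count stored as an attribute.
#' @return A `sift_profile` tibble.
#' @export
call_binding_site <- function(freq_tbl, cutoff = 0.5, hotspot = 0.95,
                              profile_id = "SIFt", n_ligands = NA_integer_) {
  stopifnot(all(c("position", "freq") %in% names(freq_tbl)))
  if (any(freq_tbl$freq < 0 | freq_tbl$freq > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  out <- tibble::as_tibble(freq_tbl[, c("position", "freq")])
  out$retained <- out$freq > cutoff
  out$hotspot <- out$freq >= hotspot
  out <- out[order(out$position), , drop = FALSE]
  structure(out,
    class = c("sift_profile", class(tibble::tibble())),
    n_ligands = n_ligands, cutoff = cutoff, hotspot_threshold = hotspot,
    profile_id = profile_id
  )
}

# ---- named profile presets -------------------------------------------------

# model ids follow the c<cluster>_m<index>_<template> convention
parse_model_id <- function(model_id) {
  m <- regmatches(model_id,
    regexec("^c([0-9]+)_m([0-9]+)_([0-9a-z]+)$", tolower(model_id)))
  tibble::tibble(
    model_id = model_id,
    model_cluster = vapply(m, function(x) {
      if (length(x) == 4) as.integer(x[2]) else NA_integer_
    }, integer(1)),
    template = vapply(m, function(x) {
      if (length(x) == 4) x[4] else NA_character_
    }, character(1))
  )
}

.profile_presets <- list(
  sift8 = list(label = "SIFt(8)", template = c("1u19", "4or2", "4oo9"),
    cluster = NULL),
  sift7 = list(label = "SIFt(7)", template = c("4or2", "4oo9"), cluster = NULL),
  sift_1u19 = list(label = "SIFt(1U19)", template = "1u19", cluster = NULL),
  sift_4or2 = list(label = "SIFt(4OR2)", template = "4or2", cluster = NULL),
  sift_4oo9 = list(label = "SIFt(4OO9)", template = "4oo9", cluster = NULL),
  sift_c1 = list(label = "SIFt(C1)", template = NULL, cluster = 1L),
  sift_c2 = list(label = "SIFt(C2)", template = NULL, cluster = 2L),
  sift_c4 = list(label = "SIFt(C4)", template = NULL, cluster = 4L),
  sift_c5 = list(label = "SIFt(C5)", template = NULL, cluster = 5L)
)

#' Named SIFt profile over a model/cluster subset
#'
#' Reproduces the standard profile definitions over a stacked bit store:
#' the general profiles (`"sift8"`: all selected models; `"sift7"`: class C
#' template models only), the template-specific profiles (`"sift_1u19"`,
#' `"sift_4or2"`, `"sift_4oo9"`) and the cluster-specific profiles
#' (`"sift_c1"`, `"sift_c2"`, `"sift_c4"`, `"sift_c5"`). Bit rows are kept
#' when the ligand's cluster matches the model's cluster (ligands docked
#' into their own models), then filtered by template and/or cluster.
#'
#' @param bits Stacked [sift_bits()] rows with `model_id` (in the
#'   `c<cluster>_m<index>_<template>` convention) and `cluster_id` columns.
#' @param preset One of the preset names above.
#' @inheritParams sift_profile
#' @return A `sift_profile`.
#' @export
profile_subset <- function(bits, preset = names(.profile_presets),
                           cutoff = 0.5, hotspot = 0.95) {
  preset <- match.arg(preset)
  ps <- .profile_presets[[preset]]
  meta <- parse_model_id(bits$model_id)
  keep <- rep(TRUE, nrow(bits))
  if ("cluster_id" %in% names(bits)) {
    keep <- keep & (is.na(meta$model_cluster) |
      bits$cluster_id == meta$model_cluster)
  }
  if (!is.null(ps$template)) keep <- keep & meta$template %in% ps$template
  if (!is.null(ps$cluster) && "cluster_id" %in% names(bits)) {
    keep <- keep & bits$cluster_id %in% ps$cluster
  }
  sub <- bits[keep, , drop = FALSE]
  if (nrow(sub) == 0) stop("preset '", preset, "' selects no ligands",
    call. = FALSE)
  sift_profile(sub, cutoff = cutoff, hotspot = hotspot, profile_id = ps$label)
}

# ---- grid box QC -----------------------------------------------------------

#' Docking grid box centred on a residue side chain
#'
#' Axis-aligned cubic outer/inner boxes centred on the side-chain heavy-atom
#' centroid of a named residue (CA for glycine).
#'
#' @param model A [structure_model].
#' @param resno Residue number of the centring residue.
#' @param chain Chain id (default first chain).
#' @param outer,inner Edge lengths in Angstrom (inner <= outer).
#' @return A `grid_box` list: `center`, `outer`, `inner`.
#' @export
grid_box <- function(model, resno, chain = NULL, outer = 30, inner = 10) {
  stopifnot(inherits(model, "structure_model"), inner <= outer)
  at <- model$atoms
  if (is.null(chain)) chain <- at$chain[1]
  rat <- at[at$resno == resno & at$chain == chain & at$elem != "H", ,
    drop = FALSE]
  if (nrow(rat) == 0) {
    stop("centre residue ", chain, ":", resno, " not found in model",
      call. = FALSE)
  }
  sc <- rat[!rat$elety %in% .backbone_atoms, , drop = FALSE]
  if (nrow(sc) == 0) sc <- rat[rat$elety == "CA", , drop = FALSE]
  if (nrow(sc) == 0) sc <- rat
  structure(
    list(center = c(x = mean(sc$x), y = mean(sc$y), z = mean(sc$z)),
      outer = outer, inner = inner),
    class = "grid_box"
  )
}

#' Check a docked pose against a grid box
#'
#' A pose passes when its heavy-atom centroid lies inside the inner cube;
#' per-atom occupancy of the outer cube is also reported.
#'
#' @param pose A [ligand_pose].
#' @param box A [grid_box()].
#' @return List: `inside` (logical), `centroid`, `atom_report` (tibble with
#'   per-heavy-atom `in_outer` flags).
#' @export
box_check <- function(pose, box) {
  stopifnot(inherits(pose, "ligand_pose"), inherits(box, "grid_box"))
  at <- pose$atoms[pose$atoms$elem != "H", , drop = FALSE]
  cen <- c(mean(at$x), mean(at$y), mean(at$z))
  off <- abs(cen - box$center)
  inside <- all(off <= box$inner / 2)
  rep_tbl <- tibble::tibble(
    atom = seq_len(nrow(at)), elem = at$elem,
    in_outer = abs(at$x - box$center[1]) <= box$outer / 2 &
      abs(at$y - box$center[2]) <= box$outer / 2 &
      abs(at$z - box$center[3]) <= box$outer / 2
  )
  list(inside = inside, centroid = cen, atom_report = rep_tbl)
}
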