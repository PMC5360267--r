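# Toy binding pockets with planted interactions.
#
# Residues are placed on well-separated rays from the ligand (icosahedron
# vertex directions, pairwise >= 63 degrees) so that each planted
# interaction is realised exactly and no unintended cross-ray interaction
# can change a fingerprint bit: residue atoms on one ray stay > 4 A from
# ligand atoms belonging to other rays, and distance windows for the
# charged intents sit above the hydrogen-bond ceiling. Geometry is
# idealised (only the atoms the SIFt rules inspect), not rotameric.

# unit icosahedron vertex directions
.pocket_dirs <- local({
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1)
  )
  v / sqrt(rowSums(v^2))
})

.intents <- c("hydrophobic", "backbone", "polar", "hbond_donor",
  "hbond_acceptor", "aromatic", "charged_pos", "charged_neg", "none")

# expected fingerprint bits per intent (NULL = residue absent from the
# contact set)
.intent_bits <- list(
  hydrophobic = c("any_contact", "side_chain", "hydrophobic"),
  backbone = c("any_contact", "backbone", "hydrophobic"),
  polar = c("any_contact", "side_chain", "polar"),
  hbond_donor = c("any_contact", "side_chain", "polar", "hbond_donor"),
  hbond_acceptor = c("any_contact", "side_chain", "polar", "hbond_acceptor"),
  aromatic = c("any_contact", "side_chain", "hydrophobic", "aromatic"),
  charged_pos = c("any_contact", "side_chain", "polar", "charged"),
  charged_neg = c("any_contact", "side_chain", "polar", "charged"),
  none = NULL
)

.intent_resid <- c(
  hydrophobic = "LEU", backbone = "GLY", polar = "SER",
  hbond_donor = "SER", hbond_acceptor = "SER", aromatic = "PHE",
  charged_pos = "ASP", charged_neg = "LYS", none = "LEU"
)

# allowed planting distance (arm heavy atom to residue contact atom, A);
# charged intents sit above the H-bond ceiling so only the charge bit fires
.intent_dist_range <- list(
  hydrophobic = c(3.0, 4.0), backbone = c(3.0, 4.0), polar = c(3.0, 4.0),
  hbond_donor = c(2.6, 3.5), hbond_acceptor = c(2.6, 3.5),
  aromatic = c(3.0, 3.9), charged_pos = c(3.6, 4.0),
  charged_neg = c(3.6, 4.0), none = c(4.5, 8.0)
)

#' Recipe for a synthetic binding pocket
#'
#' @param intent Character vector of planted interactions, drawn from
#'   `"hydrophobic"`, `"backbone"`, `"polar"`, `"hbond_donor"`,
#'   `"hbond_acceptor"`, `"aromatic"`, `"charged_pos"`, `"charged_neg"`,
#'   `"none"`.
#' @param distance Planting distances in Angstrom (defaults to the midpoint
#'   of each intent's admissible window).
#' @return Tibble `intent`, `resid`, `distance`.
#' @export
pocket_recipe <- function(intent, distance = NULL) {
  stopifnot(all(intent %in% .intents), length(intent) <= nrow(.pocket_dirs))
  if (is.null(distance)) {
    distance <- vapply(intent, function(i) mean(.intent_dist_range[[i]]),
      numeric(1))
  }
  stopifnot(length(distance) == length(intent))
  for (i in seq_along(intent)) {
    rng <- .intent_dist_range[[intent[i]]]
    if (distance[i] < rng[1] || distance[i] > rng[2]) {
      stop("intent '", intent[i], "' is not realisable at ", distance[i],
        " A (allowed ", rng[1], "-", rng[2], ")", call. = FALSE)
    }
  }
  tibble::tibble(intent = intent, resid = unname(.intent_resid[intent]),
    distance = distance)
}

#' Build a toy protein-ligand complex with planted interaction bits
#'
#' Constructs an idealised pocket in which each recipe row becomes one
#' residue realising exactly its intended fingerprint bits. With zero
#' jitter the SIFt computed from the geometry equals the planted ground
#' truth bit-for-bit; `jitter` adds seeded Gaussian noise to the residue
#' coordinates for robustness experiments.
#'
#' @param recipe A [pocket_recipe()] (at most 12 residues).
#' @param jitter Coordinate noise SD in Angstrom (default 0).
#' @param seed Integer seed (used only when `jitter > 0`).
#' @param model_id,ligand_id Identifiers for the emitted objects.
#' @return List with `model` ([structure_model]), `pose` ([ligand_pose]),
#'   `expected_bits` (tibble: `residue_key`, `resid`, `intent` and the nine
#'   bit columns) and `recipe`.
#' @export
build_pocket <- function(recipe, jitter = 0, seed = 1,
                         model_id = "toy_pocket", ligand_id = "toy_ligand") {
  stopifnot(is.data.frame(recipe),
    all(c("intent", "resid", "distance") %in% names(recipe)),
    nrow(recipe) >= 1, nrow(recipe) <= nrow(.pocket_dirs))

  lig_atoms <- list(tibble::tibble(elem = "C", x = 0, y = 0, z = 0,
    charge = 0L))
  lig_bonds <- list()
  lig_rings <- list()
  prot <- list()
  arm_r <- 1.5

  basis <- function(u) {
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    p <- ref - sum(ref * u) * u
    p <- p / sqrt(sum(p^2))
    q <- c(u[2] * p[3] - u[3] * p[2], u[3] * p[1] - u[1] * p[3],
      u[1] * p[2] - u[2] * p[1])
    list(p = p, q = q)
  }
  add_lig <- function(elem, pos, charge = 0L) {
    lig_atoms[[length(lig_atoms) + 1]] <<- tibble::tibble(
      elem = elem, x = pos[1], y = pos[2], z = pos[3],
      charge = as.integer(charge))
    length(lig_atoms)
  }
  add_bond <- function(a1, a2, order = 1) {
    lig_bonds[[length(lig_bonds) + 1]] <<- tibble::tibble(
      a1 = a1, a2 = a2, order = order)
  }
  add_res <- function(resno, resid, elety, pos) {
    prot[[length(prot) + 1]] <<- tibble::tibble(
      chain = "A", resno = resno, insert = "", resid = resid,
      elety = elety, elem = guess_element(elety),
      x = pos[1], y = pos[2], z = pos[3])
  }
  # generic backbone placed beyond the side chain, > 4 A from every ligand
  # atom (except for the backbone intent, which brings its own)
  add_backbone <- function(resno, resid, u, r_far, b) {
    add_res(resno, resid, "CA", u * r_far)
    add_res(resno, resid, "N", u * r_far + 0.8 * b$p)
    add_res(resno, resid, "C", u * r_far - 0.8 * b$p)
    add_res(resno, resid, "O", u * (r_far + 1.2))
  }

  for (i in seq_len(nrow(recipe))) {
    u <- .pocket_dirs[i, ]
    b <- basis(u)
    d <- recipe$distance[i]
    intent <- recipe$intent[i]
    resid <- recipe$resid[i]
    contact_r <- arm_r + d

    if (intent == "hydrophobic" || intent == "none") {
      arm <- add_lig("C", arm_r * u)
      add_bond(1, arm)
      add_res(i, resid, "CD1", contact_r * u)
      add_res(i, resid, "CG", (contact_r + 1.2) * u)
      add_res(i, resid, "CB", (contact_r + 2.4) * u)
      add_backbone(i, resid, u, contact_r + 3.6, b)
    } else if (intent == "backbone") {
      arm <- add_lig("C", arm_r * u)
      add_bond(1, arm)
      add_res(i, resid, "O", contact_r * u)
      add_res(i, resid, "C", (contact_r + 1.0) * u)
      add_res(i, resid, "CA", (contact_r + 2.2) * u)
      add_res(i, resid, "N", (contact_r + 3.2) * u)
    } else if (intent == "polar") {
      arm <- add_lig("C", arm_r * u)
      add_bond(1, arm)
      add_res(i, resid, "OG", contact_r * u)
      add_res(i, resid, "CB", (contact_r + 1.2) * u)
      add_backbone(i, resid, u, contact_r + 2.6, b)
    } else if (intent == "hbond_donor") {
      # ammonium-type: positive charge keeps the arm out of the ligand
      # acceptor set, so only the donation direction is planted
      arm <- add_lig("N", arm_r * u, charge = 1L)
      h <- add_lig("H", (arm_r + 1.0) * u)
      add_bond(1, arm)
      add_bond(arm, h)
      add_res(i, resid, "OG", contact_r * u)
      add_res(i, resid, "CB", (contact_r + 1.2) * u)
      add_backbone(i, resid, u, contact_r + 2.6, b)
    } else if (intent == "hbond_acceptor") {
      arm <- add_lig("O", arm_r * u) # carbonyl-like acceptor
      add_bond(1, arm, order = 2)
      add_res(i, resid, "OG", contact_r * u)
      add_res(i, resid, "HG", (contact_r - 1.0) * u) # donor H toward ligand
      add_res(i, resid, "CB", (contact_r + 1.2) * u)
      add_backbone(i, resid, u, contact_r + 2.6, b)
    } else if (intent == "aromatic") {
      centre <- arm_r * u
      ring <- integer(6)
      for (k in 0:5) {
        ang <- k * pi / 3
        ring[k + 1] <- add_lig("C",
          centre + 0.7 * (cos(ang) * b$p + sin(ang) * b$q))
      }
      for (k in 1:6) add_bond(ring[k], ring[k %% 6 + 1],
        order = if (k %% 2) 2 else 1)
      add_bond(1, ring[1])
      lig_rings[[length(lig_rings) + 1]] <- ring
      pc <- (arm_r + d) * u
      ring_names <- .ring_atoms$PHE
      for (k in 0:5) {
        ang <- k * pi / 3
        add_res(i, resid, ring_names[k + 1],
          pc + 1.39 * (cos(ang) * b$p + sin(ang) * b$q))
      }
      add_res(i, resid, "CB", (arm_r + d + 2.0) * u)
      add_backbone(i, resid, u, arm_r + d + 3.6, b)
    } else if (intent == "charged_pos") {
      arm <- add_lig("N", arm_r * u, charge = 1L) # ammonium-type
      add_bond(1, arm)
      add_res(i, resid, "OD1", contact_r * u)
      add_res(i, resid, "OD2", contact_r * u + 1.1 * b$p)
      add_res(i, resid, "CG", (contact_r + 1.2) * u)
      add_res(i, resid, "CB", (contact_r + 2.4) * u)
      add_backbone(i, resid, u, contact_r + 3.6, b)
    } else if (intent == "charged_neg") {
      arm <- add_lig("O", arm_r * u, charge = -1L) # carboxylate-type
      add_bond(1, arm)
      add_res(i, resid, "NZ", contact_r * u)
      add_res(i, resid, "CE", (contact_r + 1.2) * u)
      add_res(i, resid, "CD", (contact_r + 2.4) * u)
      add_backbone(i, resid, u, contact_r + 3.6, b)
    }
  }

  atoms <- dplyr::bind_rows(prot)
  if (jitter > 0) {
    withr::with_seed(seed, {
      atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, jitter)
      atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, jitter)
      atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, jitter)
    })
  }
  model <- structure_model(atoms, model_id = model_id)
  pose <- ligand_pose(dplyr::bind_rows(lig_atoms),
    dplyr::bind_rows(lig_bonds), ligand_id = ligand_id,
    rings = if (length(lig_rings)) lig_rings else NULL)

  expected <- purrr::map_dfr(seq_len(nrow(recipe)), function(i) {
    on_bits <- .intent_bits[[recipe$intent[i]]]
    if (is.null(on_bits)) return(NULL)
    row <- tibble::as_tibble(stats::setNames(
      as.list(.bit_names %in% on_bits), .bit_names))
    dplyr::bind_cols(
      tibble::tibble(residue_key = residue_key("A", i),
        resid = recipe$resid[i], intent = recipe$intent[i]),
      row
    )
  })
  list(model = model, pose = pose, expected_bits = expected, recipe = recipe)
}

#' Draw a random pocket recipe
#'
#' @param n_residues Number of residues (1-12).
#' @param seed Integer seed.
#' @param intents Intent pool to draw from.
#' @return A [pocket_recipe()].
#' @export
random_pocket_recipe <- function(n_residues = 6, seed = 1,
                                 intents = .intents) {
  stopifnot(n_residues >= 1, n_residues <= nrow(.pocket_dirs))
  withr::with_seed(seed, {
    intent <- sample(intents, n_residues, replace = TRUE)
    distance <- vapply(intent, function(it) {
      rng <- .intent_dist_range[[it]]
      stats::runif(1, rng[1], rng[2])
    }, numeric(1))
  })
  pocket_recipe(intent, distance)
}

#' Write a pocket to PDB + SDF files
#'
#' Emits the same dialects the pipeline reads back with [read_complex()]:
#' the protein as a PDB file and the ligand pose (with explicit hydrogens,
#' bond orders and formal charges) as an SDF file. Output is byte-identical
#' for identical input objects.
#'
#' @param pocket A [build_pocket()] result.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Named character vector with the `protein` and `ligand` paths.
#' @export
write_pocket <- function(pocket, dir, stem = pocket$model$model_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  at <- pocket$model$atoms
  pdb_path <- file.path(dir, paste0(stem, ".pdb"))
  bio3d::write.pdb(
    file = pdb_path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resno, chain = at$chain, resid = at$resid,
    elety = at$elety, eleno = seq_len(nrow(at))
  )
  sdf_path <- file.path(dir, paste0(stem, "_ligand.sdf"))
  ChemmineR::write.SDF(pose_to_sdf(pocket$pose), sdf_path)
  c(protein = pdb_path, ligand = sdf_path)
}

pose_to_sdf <- function(pose) {
  at <- pose$atoms
  n <- nrow(at)
  ab <- cbind(at$x, at$y, at$z, matrix(0, n, 12))
  colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
  rownames(ab) <- paste(at$elem, seq_len(n), sep = "_")
  ab[, "C6"] <- ifelse(at$charge == 0, 0, 4 - at$charge)
  bb <- pose$bonds
  nb <- nrow(bb)
  bmat <- if (nb) {
    cbind(bb$a1, bb$a2, ceiling(bb$order), matrix(0, nb, 4))
  } else {
    matrix(0, 0, 7)
  }
  colnames(bmat) <- paste0("C", 1:7)
  if (nb) rownames(bmat) <- seq_len(nb)
  sdf <- methods::new("SDF",
    header = c(Molecule_Name = pose$ligand_id, Source = "ligsel",
      Comment = "",
      Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)),
    atomblock = ab, bondblock = bmat, datablock = character(0)
  )
  methods::new("SDFset", SDF = list(sdf), ID = pose$ligand_id)
}
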