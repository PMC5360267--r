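# DUD-style decoy selection: candidates must match an active's
# physicochemical descriptors within tolerances while being topologically
# dissimilar (Tanimoto ceiling) to *every* active of the cluster.

#' Descriptor-matching specification for decoy selection
#'
#' Tolerances echo DUD-era practice; none are stated in typical source
#' datasets so all are exposed here.
#'
#' @param mw Molecular-weight window, +/- g/mol.
#' @param clogp logP window.
#' @param hbd,hba,rotb Count windows.
#' @param net_charge Charge window (0 = exact match).
#' @param max_tanimoto Topological dissimilarity ceiling in (0, 1): a
#'   candidate is rejected if its Tanimoto similarity to any active exceeds
#'   this value.
#' @param decoys_per_active Number of decoys drawn per active.
#' @return A `match_spec` list.
#' @export
match_spec <- function(mw = 25, clogp = 1.0, hbd = 1, hba = 2, rotb = 2,
                       net_charge = 0, max_tanimoto = 0.6,
                       decoys_per_active = 36) {
  tol <- c(mw = mw, clogp = clogp, hbd = hbd, hba = hba, rotb = rotb,
    net_charge = net_charge)
  if (any(tol < 0)) stop("tolerances must be >= 0", call. = FALSE)
  if (max_tanimoto <= 0 || max_tanimoto >= 1) {
    stop("max_tanimoto must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(mw = mw, clogp = clogp, hbd = hbd, hba = hba, rotb = rotb,
      net_charge = net_charge, max_tanimoto = max_tanimoto,
      decoys_per_active = decoys_per_active),
    class = "match_spec"
  )
}

.descriptor_cols <- c("mw", "clogp", "hbd", "hba", "rotb", "net_charge")

# eligibility of one candidate row against one active row
within_tolerances <- function(cand, act, spec) {
  all(vapply(.descriptor_cols, function(col) {
    abs(cand[[col]] - act[[col]]) <= spec[[col]]
  }, logical(1)))
}

#' Select property-matched, topology-dissimilar decoys
#'
#' For each active, candidates within every descriptor tolerance *and* with
#' Tanimoto similarity `<= max_tanimoto` to all actives of that cluster are
#' eligible; up to `decoys_per_active` are sampled without replacement.
#' Candidates sharing an id with an active are never eligible, and a
#' candidate drawn for several actives is kept once. Output is deterministic
#' for a given `seed`.
#'
#' @param actives Ligand tibble with descriptor columns and an `fp`
#'   list-column; an optional `cluster_id` column splits the selection per
#'   chemotype cluster.
#' @param candidates Candidate ligand tibble with the same columns.
#' @param spec A [match_spec()].
#' @param seed Integer seed controlling the sampling.
#' @return A `decoy_set` object: list with `decoys` (tibble, role `"decoy"`,
#'   with `cluster_id` and `matched_active`), `actives`, `ratios`, `spec`,
#'   `seed`.
#' @export
match_decoys <- function(actives, candidates, spec = match_spec(), seed = 1) {
  stopifnot(is.data.frame(actives), is.data.frame(candidates))
  need <- c("id", .descriptor_cols, "fp")
  miss <- setdiff(need, names(actives))
  if (length(miss)) stop("actives lack columns: ", paste(miss, collapse = ", "),
    call. = FALSE)
  miss <- setdiff(need, names(candidates))
  if (length(miss)) stop("candidates lack columns: ",
    paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(candidates) == 0) stop("empty candidate pool", call. = FALSE)
  if (!"cluster_id" %in% names(actives)) actives$cluster_id <- 1L

  candidates <- candidates[!candidates$id %in% actives$id, , drop = FALSE]
  picks <- list()
  withr::with_seed(seed, {
    for (cl in sort(unique(actives$cluster_id))) {
      act_cl <- actives[actives$cluster_id == cl, , drop = FALSE]
      act_cl <- act_cl[order(act_cl$id), , drop = FALSE]
      # dissimilarity ceiling against all actives of the cluster
      sim_ok <- vapply(seq_len(nrow(candidates)), function(i) {
        all(vapply(act_cl$fp, function(afp) {
          tanimoto(candidates$fp[[i]], afp) <= spec$max_tanimoto
        }, logical(1)))
      }, logical(1))
      taken <- character(0)
      for (a in seq_len(nrow(act_cl))) {
        elig <- sim_ok & vapply(seq_len(nrow(candidates)), function(i) {
          within_tolerances(candidates[i, ], act_cl[a, ], spec)
        }, logical(1))
        pool <- sort(setdiff(candidates$id[elig], taken))
        n_take <- min(spec$decoys_per_active, length(pool))
        sel <- if (n_take == 0) character(0) else
          sort(sample(pool, n_take, replace = FALSE))
        taken <- c(taken, sel)
        if (length(sel)) {
          rows <- candidates[match(sel, candidates$id), , drop = FALSE]
          rows$role <- "decoy"
          rows$cluster_id <- cl
          rows$matched_active <- act_cl$id[a]
          picks[[length(picks) + 1]] <- rows
        }
      }
    }
  })
  decoys <- if (length(picks)) {
    dplyr::bind_rows(picks)
  } else {
    empty <- candidates[0, , drop = FALSE]
    empty$cluster_id <- integer(0)
    empty$matched_active <- character(0)
    empty
  }
  new_decoy_set(decoys, actives, spec, seed)
}

new_decoy_set <- function(decoys, actives, spec, seed) {
  ds <- structure(
    list(
      decoys = tibble::as_tibble(decoys),
      actives = tibble::as_tibble(actives[, intersect(
        c("id", "cluster_id", "role"), names(actives)), drop = FALSE]),
      spec = spec,
      seed = seed
    ),
    class = "decoy_set"
  )
  ds$ratios <- decoy_ratios(ds)
  ds
}

decoy_ratios <- function(ds) {
  act <- dplyr::count(ds$actives, .data$cluster_id, name = "n_actives")
  dec <- if (nrow(ds$decoys) && "cluster_id" %in% names(ds$decoys)) {
    dplyr::count(ds$decoys, .data$cluster_id, name = "n_decoys")
  } else {
    tibble::tibble(cluster_id = integer(), n_decoys = integer())
  }
  out <- dplyr::left_join(act, dec, by = "cluster_id")
  out$n_decoys[is.na(out$n_decoys)] <- 0L
  out$ratio <- paste0("1:", round(out$n_decoys / out$n_actives))
  if (any(out$n_decoys == 0)) {
    warning("cluster(s) with zero decoys: ",
      paste(out$cluster_id[out$n_decoys == 0], collapse = ", "), call. = FALSE)
  }
  out
}

#' Merge property-matched decoys with known inactives
#'
#' Known experimentally inactive compounds join the property-matched decoys
#' of their cluster into one decoy set; ids already present are kept once
#' (first occurrence wins). Actives:decoys ratios are reported per cluster
#' as `1:round(n_decoys / n_actives)`.
#'
#' @param ds A `decoy_set` from [match_decoys()].
#' @param inactives Ligand tibble of known inactives with `id` and
#'   `cluster_id` columns.
#' @return An updated `decoy_set` with recomputed `ratios`.
#' @export
merge_decoy_sets <- function(ds, inactives) {
  stopifnot(inherits(ds, "decoy_set"), is.data.frame(inactives))
  if (nrow(inactives)) {
    if (!"cluster_id" %in% names(inactives)) inactives$cluster_id <- 1L
    if (!"role" %in% names(inactives)) inactives$role <- "inactive"
    combined <- dplyr::bind_rows(ds$decoys, inactives)
    combined <- combined[!duplicated(combined$id), , drop = FALSE]
    ds$decoys <- combined
  }
  ds$ratios <- decoy_ratios(ds)
  ds
}

#' @export
print.decoy_set <- function(x, ...) {
  cat("<decoy_set> ", nrow(x$decoys), " decoys for ", nrow(x$actives),
    " actives (seed ", x$seed, ")\n", sep = "")
  print(x$ratios)
  invisible(x)
}
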