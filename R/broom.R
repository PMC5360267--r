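# tidy()/glance() methods for the package's fitted-object classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a ligand clustering
#'
#' @param x A `ligand_clustering` from [cluster_ligands()].
#' @param ... Unused.
#' @return The cluster assignment as a tibble (`id`, `cluster`).
#' @method tidy ligand_clustering
#' @export
tidy.ligand_clustering <- function(x, ...) {
  x$assignment
}

#' @rdname tidy.ligand_clustering
#' @return `glance()`: one-row tibble with `n`, `k`, `method_note` and, when
#'   the Kelley step ran, the penalty-minimising `k_kelley`.
#' @method glance ligand_clustering
#' @export
glance.ligand_clustering <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$assignment), k = x$k, method_note = x$method_note,
    k_kelley = if (is.null(x$profile)) NA_integer_ else
      x$profile$k[which.min(x$profile$penalty)]
  )
}

#' Tidy an enrichment result
#'
#' @param x An `enrichment_result` from [bedroc()].
#' @param ... Unused.
#' @return One-row tibble `model_id`, `cluster_id`, `alpha`, `n`, `N`,
#'   `rie`, `bedroc`.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id, cluster_id = x$cluster_id, alpha = x$alpha,
    n = x$n, N = x$N, rie = x$rie, bedroc = x$bedroc
  )
}

#' @rdname tidy.enrichment_result
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tidy.enrichment_result(x)
}

#' Tidy a decoy set
#'
#' @param x A `decoy_set` from [match_decoys()].
#' @param ... Unused.
#' @return The decoy records (without fingerprint list-columns).
#' @method tidy decoy_set
#' @export
tidy.decoy_set <- function(x, ...) {
  dplyr::select(x$decoys, -dplyr::any_of(c("fp", "mol")))
}

#' @rdname tidy.decoy_set
#' @return `glance()`: per-cluster counts and actives:decoys ratio strings.
#' @method glance decoy_set
#' @export
glance.decoy_set <- function(x, ...) {
  x$ratios
}
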