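# BEDROC / RIE early-recognition scoring of ranked docking tables, the
# exponential-weight contribution diagnostic, model shortlisting, and a pose
# spread statistic used in place of the by-eye constancy check.

#' Rank a screening table by docking score
#'
#' Orders ligands by ascending score (lower = better, rank 1 = best). Ties
#' are broken by lexicographic ligand id so the ranking is deterministic.
#' Ligands without a pose (`docked == FALSE` or `NA` score) are either
#' dropped from the ranked list (and reported in the `undocked` attribute)
#' or assigned the worst ranks.
#'
#' @param screen Tibble with columns `ligand_id`, `score`, `role` and
#'   optionally `docked` (logical).
#' @param undocked `"drop"` (default) excludes undocked ligands from the
#'   ranked list; `"worst"` places them, ordered by id, after all docked
#'   ligands.
#' @return The table sorted by rank with a `rank` column; undocked ligands
#'   that were dropped are in `attr(, "undocked")`.
#' @export
rank_table <- function(screen, undocked = c("drop", "worst")) {
  undocked <- match.arg(undocked)
  stopifnot(is.data.frame(screen),
    all(c("ligand_id", "score", "role") %in% names(screen)))
  if (nrow(screen) == 0) stop("empty screening table", call. = FALSE)
  if (anyDuplicated(screen$ligand_id)) {
    stop("duplicate ligand_id in screening table", call. = FALSE)
  }
  no_pose <- if ("docked" %in% names(screen)) {
    !screen$docked | is.na(screen$score)
  } else {
    is.na(screen$score)
  }
  if (any(!no_pose & !is.finite(screen$score))) {
    stop("non-finite docking scores", call. = FALSE)
  }
  docked_tbl <- screen[!no_pose, , drop = FALSE]
  docked_tbl <- docked_tbl[order(docked_tbl$score, docked_tbl$ligand_id), ,
    drop = FALSE]
  undocked_tbl <- screen[no_pose, , drop = FALSE]
  undocked_tbl <- undocked_tbl[order(undocked_tbl$ligand_id), , drop = FALSE]
  if (undocked == "worst" && nrow(undocked_tbl)) {
    out <- dplyr::bind_rows(docked_tbl, undocked_tbl)
    attr_un <- undocked_tbl[0, , drop = FALSE]
  } else {
    out <- docked_tbl
    attr_un <- undocked_tbl
  }
  out$rank <- seq_len(nrow(out))
  out <- tibble::as_tibble(out)
  attr(out, "undocked") <- tibble::as_tibble(attr_un)
  out
}

#' BEDROC and RIE early-recognition enrichment
#'
#' Computes the robust initial enhancement (RIE) and its bounded rescaling
#' BEDROC from the ranks of the actives in a ranked list of `N` ligands:
#' \deqn{RIE = \frac{\frac{1}{n}\sum_i e^{-\alpha r_i / N}}
#'            {\frac{1}{N}\,\frac{1 - e^{-\alpha}}{e^{\alpha/N} - 1}}}
#' \deqn{BEDROC = RIE \cdot
#'   \frac{R_a \sinh(\alpha/2)}{\cosh(\alpha/2) - \cosh(\alpha/2 - \alpha R_a)}
#'   + \frac{1}{1 - e^{\alpha (1 - R_a)}}, \quad R_a = n/N.}
#' With the default exponent `alpha = 20` roughly 80\% of the attainable
#' score comes from the top 8\% of the list (see
#' [contribution_fraction()]).
#'
#' @param ranks Integer ranks (1 = best) of the actives; distinct, in
#'   `1..N`.
#' @param N Total number of ranked ligands.
#' @param alpha Early-recognition exponent (> 0).
#' @param n Number of actives; defaults to `length(ranks)`.
#' @param model_id,cluster_id Optional provenance labels carried through.
#' @return An `enrichment_result` object with fields `model_id`,
#'   `cluster_id`, `alpha`, `n`, `N`, `rie`, `bedroc`.
#' @examples
#' bedroc(ranks = 1:5, N = 500)$bedroc # near-perfect early recognition
#' @export
bedroc <- function(ranks, N, alpha = 20, n = length(ranks),
                   model_id = NA_character_, cluster_id = NA) {
  if (length(ranks) == 0 || n == 0) {
    stop("BEDROC is undefined without actives (n = 0)", call. = FALSE)
  }
  if (n >= N) {
    stop("BEDROC is undefined when all ligands are active (n = N)",
      call. = FALSE)
  }
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (anyDuplicated(ranks)) stop("active ranks must be distinct", call. = FALSE)
  if (any(ranks < 1 | ranks > N)) {
    stop("active ranks must lie in 1..N", call. = FALSE)
  }
  ra <- n / N
  rie <- mean(exp(-alpha * ranks / N)) /
    ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  scale_fac <- ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra))
  bed <- rie * scale_fac + 1 / (1 - exp(alpha * (1 - ra)))
  structure(
    list(model_id = model_id, cluster_id = cluster_id, alpha = alpha,
      n = as.integer(n), N = as.integer(N), rie = rie,
      bedroc = min(max(bed, 0), 1)),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> model %s | n = %d actives of N = %d | alpha = %g | RIE = %.3f | BEDROC = %.4f\n",
    x$model_id, x$n, x$N, x$alpha, x$rie, x$bedroc
  ))
  invisible(x)
}

#' Score one screening table
#'
#' Convenience wrapper: [rank_table()] then [bedroc()] on the active ranks.
#' Known inactives and property-matched decoys together form the negative
#' class; anything with role `"active"` is positive.
#'
#' @inheritParams rank_table
#' @inheritParams bedroc
#' @export
bedroc_screen <- function(screen, alpha = 20, undocked = c("drop", "worst"),
                          model_id = NA_character_, cluster_id = NA) {
  ranked <- rank_table(screen, undocked = undocked)
  bedroc(
    ranks = ranked$rank[ranked$role == "active"],
    N = nrow(ranked), alpha = alpha,
    model_id = model_id, cluster_id = cluster_id
  )
}

#' Score many models' screening tables
#'
#' @param scores Tibble with columns `model_id`, `ligand_id`, `score`,
#'   `role` and optionally `cluster_id` and `docked`.
#' @inheritParams bedroc_screen
#' @return Tibble with one row per model: `model_id`, `cluster_id`, `alpha`,
#'   `n`, `N`, `rie`, `bedroc`.
#' @export
bedroc_table <- function(scores, alpha = 20, undocked = c("drop", "worst")) {
  undocked <- match.arg(undocked)
  stopifnot("model_id" %in% names(scores))
  purrr::map_dfr(split(scores, scores$model_id), function(tab) {
    cl <- if ("cluster_id" %in% names(tab)) tab$cluster_id[1] else NA
    res <- bedroc_screen(tab, alpha = alpha, undocked = undocked,
      model_id = tab$model_id[1], cluster_id = cl)
    generics::tidy(res)
  })
}

#' Fraction of the maximum BEDROC contribution in the top of the list
#'
#' `f(alpha, x) = (1 - exp(-alpha x)) / (1 - exp(-alpha))`: the share of the
#' attainable exponential weight carried by the top fraction `x` of a ranked
#' list. At `alpha = 20`, `f = 0.798` for the top 8 percent, i.e. about 80
#' percent of the score is decided there.
#'
#' @param alpha Early-recognition exponent (> 0).
#' @param x Top fraction of the ranked list, in `[0, 1]`; vectorised.
#' @return Fraction in `[0, 1]`.
#' @examples
#' round(100 * contribution_fraction(20, 0.08))
#' @export
contribution_fraction <- function(alpha, x) {
  if (any(alpha <= 0)) stop("alpha must be > 0", call. = FALSE)
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]", call. = FALSE)
  (1 - exp(-alpha * x)) / (1 - exp(-alpha))
}

#' Shortlist models by early-recognition performance
#'
#' Per ligand cluster, the union of the `top_k` models by BEDROC and all
#' models exceeding `floor` is shortlisted. Clusters whose best model does
#' not exceed the floor are flagged `"below floor"` (no model would be
#' carried forward for them), mirroring the situation where a chemotype
#' cannot be enriched by any model.
#'
#' @param results Tibble with `model_id`, `cluster_id`, `bedroc` (e.g. from
#'   [bedroc_table()]).
#' @param top_k Number of best-ranked models always included.
#' @param floor BEDROC threshold.
#' @param strict If `TRUE` (default) the floor comparison is strict (`>`).
#' @return Tibble of shortlisted rows with `shortlist_rank` and
#'   `below_floor`; per-cluster status in `attr(, "cluster_status")`.
#' @export
shortlist_models <- function(results, top_k = 10, floor = 0.5, strict = TRUE) {
  stopifnot(is.data.frame(results),
    all(c("model_id", "cluster_id", "bedroc") %in% names(results)))
  if (nrow(results) == 0) stop("no enrichment results supplied", call. = FALSE)
  above <- function(b) if (strict) b > floor else b >= floor
  out <- list()
  status <- list()
  for (cl in unique(results$cluster_id)) {
    sub <- results[results$cluster_id %in% cl, , drop = FALSE]
    sub <- sub[order(-sub$bedroc, sub$model_id), , drop = FALSE]
    keep <- seq_len(nrow(sub)) <= top_k | above(sub$bedroc)
    sel <- sub[keep, , drop = FALSE]
    sel$shortlist_rank <- seq_len(nrow(sel))
    sel$below_floor <- !above(max(sub$bedroc))
    out[[length(out) + 1]] <- sel
    status[[length(status) + 1]] <- tibble::tibble(
      cluster_id = cl, best_bedroc = max(sub$bedroc),
      below_floor = !above(max(sub$bedroc)),
      note = if (above(max(sub$bedroc))) "ok" else "no model selected"
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "cluster_status") <- dplyr::bind_rows(status)
  res
}

#' Spread of docked poses of one ligand set
#'
#' Mean pairwise distance between heavy-atom centroids of the poses; 0 for
#' identical poses, larger for inconsistent binding modes. This quantifies
#' the "constancy of orientations" criterion applied when choosing between
#' models with similar enrichment.
#'
#' @param poses List of ligand poses (each with an `atoms` tibble carrying
#'   `elem`, `x`, `y`, `z`), each with at least 3 heavy atoms.
#' @return Mean pairwise centroid distance in Angstrom.
#' @export
pose_consistency <- function(poses) {
  if (length(poses) < 2) stop("need at least 2 poses", call. = FALSE)
  cents <- vapply(poses, function(p) {
    at <- p$atoms[p$atoms$elem != "H", , drop = FALSE]
    if (nrow(at) < 3) stop("pose with fewer than 3 heavy atoms", call. = FALSE)
    c(mean(at$x), mean(at$y), mean(at$z))
  }, numeric(3))
  d <- stats::dist(t(cents))
  mean(d)
}
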