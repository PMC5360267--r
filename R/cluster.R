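# Hierarchical chemotype clustering: average-linkage (UPGMA) trees on
# 1 - Tanimoto distance, Kelley-Gardner-Sutcliffe selection of the cluster
# count, and merging down to a target number of chemotype clusters.

#' Average-linkage (UPGMA) tree from a distance matrix
#'
#' Thin, validating wrapper around [stats::hclust()] with
#' `method = "average"`. Input must be a symmetric matrix (or `dist`) with a
#' zero diagonal and finite non-negative entries.
#'
#' @param d Distance matrix or `dist` object (typically [tanimoto_dist()]).
#' @return An `hclust` tree.
#' @export
linkage_average <- function(d) {
  m <- as.matrix(d)
  if (anyNA(m) || any(!is.finite(m))) {
    stop("distance matrix contains NA/NaN/Inf", call. = FALSE)
  }
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be zero", call. = FALSE)
  if (any(m < 0)) stop("distances must be non-negative", call. = FALSE)
  stats::hclust(stats::as.dist(m), method = "average")
}

#' Kelley-Gardner-Sutcliffe cluster-count selection
#'
#' For every cut of the tree into `k = 2 .. n-1` clusters, the average
#' within-cluster spread (mean pairwise distance, over clusters with at least
#' two members) is rescaled across cuts to `[1, n-1]` and penalised by `k`
#' itself; the chosen `k` minimises the penalty, ties going to the smallest
#' `k`. The penalty profile is scale-free: multiplying all distances by a
#' constant does not change the argmin.
#'
#' @param tree An `hclust` tree from [linkage_average()].
#' @param d The distance matrix the tree was built from.
#' @return List with `k` (chosen count) and `profile`, a tibble of
#'   `k`, `spread`, `penalty`.
#' @export
kelley_k <- function(tree, d) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 3) stop("kelley_k needs at least 3 leaves", call. = FALSE)
  ks <- 2:(n - 1)
  spread <- vapply(ks, function(k) {
    cut <- stats::cutree(tree, k = k)
    per <- vapply(unique(cut), function(cl) {
      idx <- which(cut == cl)
      if (length(idx) < 2) return(NA_real_)
      sub <- m[idx, idx]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    if (all(is.na(per))) 0 else mean(per, na.rm = TRUE)
  }, numeric(1))
  rng <- range(spread)
  scaled <- if (diff(rng) == 0) {
    rep(1, length(spread))
  } else {
    (spread - rng[1]) / diff(rng) * (n - 2) + 1
  }
  penalty <- scaled + ks
  k <- ks[which.min(penalty)] # which.min -> first (smallest k) on ties
  list(k = k, profile = tibble::tibble(k = ks, spread = spread, penalty = penalty))
}

#' Merge clusters down to a target count
#'
#' Iteratively merges the pair of clusters with the smallest average
#' inter-cluster distance (mean over all cross pairs) until `target_k`
#' clusters remain. Labels are relabelled contiguously `1..k` in order of
#' each cluster's first member.
#'
#' @param assignment Tibble with columns `id` and `cluster`.
#' @param d Distance matrix with dimnames matching `id`.
#' @param target_k Desired number of clusters (`1 <= target_k <= k`).
#' @return Tibble `id`, `cluster` with a `merge_history` attribute
#'   (tibble `step`, `from`, `into`, `height`).
#' @export
merge_to_target <- function(assignment, d, target_k) {
  stopifnot(is.data.frame(assignment), all(c("id", "cluster") %in% names(assignment)))
  m <- as.matrix(d)[assignment$id, assignment$id]
  cl <- assignment$cluster
  k <- length(unique(cl))
  if (target_k < 1 || target_k > k) {
    stop("target_k must be between 1 and the current number of clusters",
      call. = FALSE)
  }
  history <- list()
  step <- 0L
  while (length(unique(cl)) > target_k) {
    labs <- sort(unique(cl))
    best <- NULL
    for (i in seq_along(labs)[-length(labs)]) {
      for (j in (i + 1):length(labs)) {
        h <- mean(m[cl == labs[i], cl == labs[j], drop = FALSE])
        if (is.null(best) || h < best$h) {
          best <- list(a = labs[i], b = labs[j], h = h)
        }
      }
    }
    step <- step + 1L
    history[[step]] <- tibble::tibble(
      step = step, from = best$b, into = best$a, height = best$h
    )
    cl[cl == best$b] <- best$a
  }
  # contiguous labels in order of first appearance
  cl <- match(cl, unique(cl))
  out <- tibble::tibble(id = assignment$id, cluster = as.integer(cl))
  attr(out, "merge_history") <- if (length(history)) {
    dplyr::bind_rows(history)
  } else {
    tibble::tibble(step = integer(), from = integer(), into = integer(),
      height = numeric())
  }
  out
}

#' Cluster a ligand library into chemotypes
#'
#' Full clustering pipeline: Tanimoto distance on circular fingerprints,
#' average-linkage tree, Kelley-Gardner-Sutcliffe choice of the cluster count
#' (unless `k` is given), then optional merging of the most similar clusters
#' down to `target_k` chemotype groups.
#'
#' @param ligands Ligand tibble; fingerprints are computed when absent.
#' @param target_k Optional final number of chemotype clusters.
#' @param k Optional fixed initial cluster count (skips the Kelley step).
#' @return A `ligand_clustering` object: list with `tree`, `assignment`
#'   (tibble `id`, `cluster`), `k`, `profile`, `method_note`,
#'   `merge_history`, `dist`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
cluster_ligands <- function(ligands, target_k = NULL, k = NULL) {
  if (!"fp" %in% names(ligands)) ligands <- add_fingerprints(ligands)
  d <- tanimoto_dist(ligands)
  tree <- linkage_average(d)
  profile <- NULL
  if (is.null(k)) {
    kel <- kelley_k(tree, d)
    k <- kel$k
    profile <- kel$profile
    note <- "kelley"
  } else {
    note <- "fixed-k"
  }
  cut <- stats::cutree(tree, k = k)
  assignment <- tibble::tibble(id = ligands$id, cluster = as.integer(cut))
  history <- NULL
  if (!is.null(target_k) && target_k < k) {
    assignment <- merge_to_target(assignment, d, target_k)
    history <- attr(assignment, "merge_history")
    note <- paste0(note, "+merged-to-target")
  }
  structure(
    list(
      tree = tree,
      assignment = assignment,
      k = length(unique(assignment$cluster)),
      profile = profile,
      method_note = note,
      merge_history = history,
      dist = d
    ),
    class = "ligand_clustering"
  )
}

#' @export
print.ligand_clustering <- function(x, ...) {
  cat("<ligand_clustering> ", nrow(x$assignment), " ligands in ", x$k,
    " clusters (", x$method_note, ")\n", sep = "")
  print(dplyr::count(x$assignment, .data$cluster))
  invisible(x)
}
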