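# Independent oracles used to validate the package's implementations.
# These are deliberately naive (direct formula evaluation, O(n^3) loops,
# exhaustive scans) and share no code with the functions they check.

# direct summation of the RIE/BEDROC closed form
naive_bedroc <- function(ranks, n, N, alpha) {
  ra <- n / N
  s <- 0
  for (r in ranks) s <- s + exp(-alpha * r / N)
  rie <- (s / n) / ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

# O(n^3) UPGMA: returns sorted merge heights and the cophenetic matrix
naive_upgma <- function(m) {
  n <- nrow(m)
  members <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  while (length(members) > 1) {
    best <- NULL
    for (i in seq_len(length(members) - 1)) {
      for (j in (i + 1):length(members)) {
        h <- mean(m[members[[i]], members[[j]]])
        if (is.null(best) || h < best$h) best <- list(i = i, j = j, h = h)
      }
    }
    heights <- c(heights, best$h)
    coph[members[[best$i]], members[[best$j]]] <- best$h
    coph[members[[best$j]], members[[best$i]]] <- best$h
    members[[best$i]] <- c(members[[best$i]], members[[best$j]])
    members[[best$j]] <- NULL
  }
  list(heights = sort(heights), coph = coph)
}

# exhaustive KGS penalty evaluation over all cuts of a tree
naive_kelley <- function(tree, m) {
  n <- nrow(m)
  ks <- 2:(n - 1)
  spread <- sapply(ks, function(k) {
    cut <- stats::cutree(tree, k = k)
    per <- sapply(unique(cut), function(cl) {
      idx <- which(cut == cl)
      if (length(idx) < 2) return(NA_real_)
      sub <- m[idx, idx]
      mean(sub[upper.tri(sub)])
    })
    if (all(is.na(per))) 0 else mean(per, na.rm = TRUE)
  })
  rng <- range(spread)
  scaled <- if (diff(rng) == 0) rep(1, length(spread)) else
    (spread - rng[1]) / diff(rng) * (n - 2) + 1
  ks[which.min(scaled + ks)]
}

# brute-force decoy eligibility: candidate row vs one active row + the full
# active set of the cluster
decoy_is_eligible <- function(cand, act, cluster_actives, spec) {
  cols <- c("mw", "clogp", "hbd", "hba", "rotb", "net_charge")
  within <- all(sapply(cols, function(cl) {
    abs(cand[[cl]] - act[[cl]]) <= spec[[cl]]
  }))
  dissim <- all(sapply(cluster_actives$fp, function(afp) {
    tanimoto(cand$fp[[1]], afp) <= spec$max_tanimoto
  }))
  within && dissim
}

# brute-force any-contact frequency recount from stacked bit rows
recount_profile <- function(bits) {
  key <- paste(bits$model_id, bits$ligand_id)
  n <- length(unique(key))
  pos <- unique(bits$position[bits$any_contact])
  data.frame(
    position = pos,
    freq = sapply(pos, function(p) {
      length(unique(key[bits$any_contact & bits$position == p])) / n
    })
  )
}

# distance-based block distance matrix with tight within-blob and wide
# between-blob separations
blob_dist <- function(sizes, within = 0.05, between = 0.9, seed = 1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  withr::with_seed(seed, {
    m <- matrix(0, n, n)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        base <- if (lab[i] == lab[j]) within else between
        m[i, j] <- m[j, i] <- base + stats::runif(1, 0, 0.02)
      }
    }
  })
  dimnames(m) <- list(paste0("L", 1:n), paste0("L", 1:n))
  m
}
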