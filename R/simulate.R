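# Synthetic screening outcomes and compound libraries with known ground
# truth. Active ranks follow an exponential tilt over the unit interval:
# beta = 0 gives exchangeable (uniform) ranks with a closed-form expected
# BEDROC, larger beta concentrates actives at the top of the list.

#' Simulate a ranked virtual-screening outcome
#'
#' Latent positions `u` in `[0, 1]` double as docking scores (lower =
#' better). Decoys draw `u` uniformly; actives draw from the tilted density
#' proportional to `exp(-beta * u)`, so `beta = 0` is a random ranking and
#' large `beta` pushes all actives to the top. Deterministic per seed.
#'
#' @param n_actives,n_decoys Ligand counts (>= 1).
#' @param beta Enrichment strength (>= 0).
#' @param seed Integer seed.
#' @return Screening tibble `ligand_id`, `score`, `role` with attributes
#'   `beta` and `seed`.
#' @export
simulate_screen <- function(n_actives, n_decoys, beta = 0, seed = 1) {
  stopifnot(n_actives >= 1, n_decoys >= 1, beta >= 0)
  withr::with_seed(seed, {
    u_act <- if (beta == 0) {
      stats::runif(n_actives)
    } else {
      v <- stats::runif(n_actives)
      -log(1 - v * (1 - exp(-beta))) / beta
    }
    u_dec <- stats::runif(n_decoys)
  })
  out <- tibble::tibble(
    ligand_id = c(sprintf("act%04d", seq_len(n_actives)),
      sprintf("dec%05d", seq_len(n_decoys))),
    score = c(u_act, u_dec),
    role = rep(c("active", "decoy"), c(n_actives, n_decoys))
  )
  attr(out, "beta") <- beta
  attr(out, "seed") <- seed
  out
}

#' Expected BEDROC of a random ranking
#'
#' Under exchangeable (uniform) active ranks the expected RIE is exactly 1,
#' so the expected BEDROC follows in closed form from the BEDROC scaling:
#' `Ra sinh(a/2) / (cosh(a/2) - cosh(a/2 - a Ra)) + 1 / (1 - exp(a(1-Ra)))`.
#'
#' @param n Number of actives.
#' @param N Total ranked ligands.
#' @param alpha Early-recognition exponent.
#' @return Expected BEDROC under the null of no enrichment.
#' @export
expected_random_bedroc <- function(n, N, alpha = 20) {
  ra <- n / N
  ra * sinh(alpha / 2) / (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

#' Simulate a candidate compound library with controlled properties
#'
#' Descriptor-only records (no structures): descriptors are drawn from
#' normal distributions (counts rounded and truncated at zero), net charge
#' from a small categorical distribution, and each record gets a random
#' fingerprint feature set so Tanimoto comparisons are defined.
#'
#' @param n Library size (>= 1).
#' @param seed Integer seed.
#' @param mw_mean,mw_sd,clogp_mean,clogp_sd,hbd_mean,hba_mean,rotb_mean
#'   Property distribution parameters.
#' @param charge_probs Probabilities of net charge -1, 0, +1.
#' @param fp_universe,fp_size Feature-hash universe and set size for the
#'   random fingerprints.
#' @return Candidate ligand tibble with descriptor columns and an `fp`
#'   list-column.
#' @export
simulate_library <- function(n, seed = 1, mw_mean = 350, mw_sd = 60,
                             clogp_mean = 2.5, clogp_sd = 1.2,
                             hbd_mean = 1.5, hba_mean = 4, rotb_mean = 5,
                             charge_probs = c(0.15, 0.7, 0.15),
                             fp_universe = 2^20, fp_size = 30) {
  if (n < 1) stop("library size must be >= 1", call. = FALSE)
  withr::with_seed(seed, {
    tibble::tibble(
      id = sprintf("cand%05d", seq_len(n)),
      role = "candidate",
      mw = pmax(stats::rnorm(n, mw_mean, mw_sd), 80),
      clogp = stats::rnorm(n, clogp_mean, clogp_sd),
      hbd = pmax(round(stats::rnorm(n, hbd_mean, 1)), 0),
      hba = pmax(round(stats::rnorm(n, hba_mean, 1.5)), 0),
      rotb = pmax(round(stats::rnorm(n, rotb_mean, 2)), 0),
      net_charge = sample(c(-1L, 0L, 1L), n, replace = TRUE,
        prob = charge_probs),
      fp = lapply(seq_len(n), function(i) {
        sort(sample.int(fp_universe, fp_size))
      })
    )
  })
}

#' Plant eligible decoy candidates around a set of actives
#'
#' Builds a candidate pool in which exactly `n_eligible` candidates per
#' active satisfy a [match_spec()] by construction (descriptors perturbed
#' within half the tolerance, fingerprints drawn from a feature range
#' disjoint from the actives' so Tanimoto is 0) and `n_background`
#' candidates violate the weight tolerance by a wide margin.
#'
#' @param actives Ligand tibble with descriptor columns and `fp`.
#' @param n_eligible Planted eligible candidates per active.
#' @param n_background Ineligible background candidates.
#' @param spec The [match_spec()] the planting targets.
#' @param seed Integer seed.
#' @return Candidate tibble with `planted_for` (active id or `NA`).
#' @export
plant_candidates <- function(actives, n_eligible, n_background = 50,
                             spec = match_spec(), seed = 1) {
  stopifnot(all(c("id", .descriptor_cols, "fp") %in% names(actives)))
  fp_lo <- 2^21 # actives' fingerprints are hashes < 2^31; use a dedicated
  fp_hi <- 2^21 + 2^16 # disjoint block for planted candidates
  used <- unique(unlist(actives$fp))
  withr::with_seed(seed, {
    elig <- purrr::map_dfr(seq_len(nrow(actives)), function(a) {
      act <- actives[a, ]
      purrr::map_dfr(seq_len(n_eligible), function(k) {
        tibble::tibble(
          id = sprintf("plant_%s_%02d", act$id, k),
          role = "candidate",
          mw = act$mw + stats::runif(1, -spec$mw / 2, spec$mw / 2),
          clogp = act$clogp + stats::runif(1, -spec$clogp / 2, spec$clogp / 2),
          hbd = act$hbd, hba = act$hba, rotb = act$rotb,
          net_charge = act$net_charge,
          fp = list(sort(setdiff(
            sample(seq(fp_lo, fp_hi), 30), used))),
          planted_for = act$id
        )
      })
    })
    bg <- if (n_background > 0) {
      tibble::tibble(
        id = sprintf("bg%05d", seq_len(n_background)),
        role = "candidate",
        mw = max(actives$mw) + spec$mw * 10 +
          stats::runif(n_background, 0, 100),
        clogp = stats::rnorm(n_background, 2, 1),
        hbd = sample(0:3, n_background, replace = TRUE),
        hba = sample(0:6, n_background, replace = TRUE),
        rotb = sample(0:8, n_background, replace = TRUE),
        net_charge = 0L,
        fp = lapply(seq_len(n_background), function(i) {
          sort(sample(seq(fp_lo, fp_hi), 30))
        }),
        planted_for = NA_character_
      )
    } else {
      NULL
    }
  })
  dplyr::bind_rows(elig, bg)
}
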