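---
title: "Ligand-guided model selection: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-guided model selection: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligsel)
```

This vignette documents the statistical model and procedure behind
`ligsel`, every tunable parameter with its default and rationale, what the
synthetic-data generators emulate (and deliberately do not), and the
numerical conventions — tie-breaks, thresholds, boundary strictness — that
determine reproducibility.

## 1. The pipeline

Given a set of known actives for a receptor without an experimental
structure, and a set of candidate homology models:

1. cluster the actives into chemotypes (`cluster_ligands()`);
2. build a property-matched decoy set per chemotype cluster
   (`match_decoys()`, `merge_decoy_sets()`);
3. dock actives + decoys into each model, rank by score
   (`rank_table()`), and score early recognition (`bedroc_screen()`);
4. shortlist models per cluster (`shortlist_models()`);
5. map the consensus binding site from the shortlisted poses with
   structural interaction fingerprints (`sift_bits()`, `sift_profile()`,
   `call_binding_site()`);
6. express the site in generic residue numbers so it cross-maps to
   related receptors (`assign_numbers()`, `cross_map()`).

Docking itself is out of scope: the package consumes ranked score tables
and docked poses (SDF/PDB) produced elsewhere.

## 2. Fingerprints and chemotype clustering

**Fingerprints.** `fingerprint()` computes circular substructure
fingerprints of radius 0–2. The atom invariant is
`element | formal charge | heavy degree | H count`; at each iteration the
invariant is concatenated with the sorted invariants of the neighbours and
hashed (FNV-1a, 32-bit) into a sparse feature set. This is a
Morgan/ECFP-style approximation of MOLPRINT2D atom environments: the
original MOLPRINT2D's exact radius and hashing are not published in a
reproducible form, so we use the standard circular construction with
radius 2 (environments up to two bonds, the common ECFP4-equivalent
choice). Similarity is the Tanimoto coefficient on feature sets;
distance is `1 − Tc`.

**Tree.** `linkage_average()` is a validating wrapper around
`stats::hclust(method = "average")` (UPGMA). The tests verify it against
a naive O(n³) UPGMA oracle on random matrices (merge heights and the full
cophenetic matrix).

**Cluster count.** `kelley_k()` implements the
Kelley–Gardner–Sutcliffe penalty: for each cut `k = 2..n−1`, the average
within-cluster spread (mean pairwise distance over clusters with ≥ 2
members) is linearly rescaled across cuts to `[1, n−1]` and penalised by
adding `k`; the chosen `k` minimises the penalty, ties going to the
smallest `k`. The criterion is scale-free (multiplying all distances by a
constant leaves the argmin unchanged). Two documented consequences:

- *All-identical input* (flat spread profile) maps every cut to penalty
  `1 + k`, so the degenerate answer is `k = 2`.
- *Planted `k = 2` is unrecoverable.* Because `k = 1` is excluded from
  the scan and spread is non-increasing in `k`, the `k = 2` cut always
  carries the maximal rescaled spread (`n−1`) unless the profile is flat,
  so `penalty(2) = n+1 > penalty(n−1) = n`. The criterion is therefore
  only meaningful for libraries with ≥ 3 chemotypes; the test fixtures
  plant 3–4 blobs.

**Merging.** `merge_to_target()` merges, at each step, the pair of
clusters with the smallest average inter-cluster distance until the
target count is reached, recording a merge history. Ties go to the
lowest cluster label. This is an automatic rule; when a published
analysis merged clusters manually, the composition may differ.

## 3. Decoy sets

`match_spec()` defaults (DUD-era tolerances; the source data sets do not
state them, so all are exposed):

| parameter | default | meaning |
|---|---|---|
| `mw` | 25 | molecular weight window, ± g/mol |
| `clogp` | 1.0 | Open Babel logP window |
| `hbd`, `hba` | 1, 2 | donor/acceptor count windows |
| `rotb` | 2 | rotatable-bond window |
| `net_charge` | 0 | exact formal-charge match |
| `max_tanimoto` | 0.6 | similarity ceiling vs *every* active of the cluster |
| `decoys_per_active` | 36 | sample size per active |

Descriptor conventions (documented in `add_descriptors()`): donors are
N/O with ≥ 1 hydrogen (explicit or implicit); acceptors are N/O with
non-positive charge excluding amide-type N (N–C(=O/S)) and pyrrole-type N
(ring N whose lone pair is in the aromatic sextet); rotatable bonds are
acyclic single bonds between two non-terminal heavy atoms excluding amide
C–N. Net charge is the formal charge of the drawn structure — no pKa
model is applied. Salts are reduced to the largest fragment at parse
time.

Sampling is deterministic per seed: clusters are processed in sorted
order, actives in sorted id order, eligible pools are sorted before
`sample()`, and a candidate drawn for one active is excluded for later
actives (kept once). Merged actives:decoys ratios are reported per
cluster as `1:round(n_decoys / n_actives)`; a cluster with zero decoys
yields `1:0` plus a warning rather than an error.

## 4. Early recognition: RIE and BEDROC

For actives at ranks `r_i` among `N` compounds, with exponent `α`:

- `RIE = mean_i(e^(−α r_i / N)) / [(1/N) · (1 − e^(−α)) / (e^(α/N) − 1)]`
- `BEDROC` is the Truchon–Bayly normalisation of RIE to `[0, 1]`.

Defaults and conventions:

- `alpha = 20`: the exponential weight then concentrates ~80 % of the
  attainable score in the top 8 % of the list
  (`contribution_fraction(20, 0.08)` = `r round(contribution_fraction(20, 0.08), 4)`);
  this is the standard "early recognition" calibration.
- Ranking ties are broken by ligand id (ascending), making
  `rank_table()` invariant to input row order.
- Undocked ligands are either dropped with a report
  (`undocked = "drop"`, the attribute `"undocked"` lists them) or sent
  to the bottom of the list (`"worst"`); never silently ignored.
- Degenerate inputs (`n = 0`, `n = N`, duplicate or out-of-range ranks)
  are explicit errors.
- `expected_random_bedroc()` gives the exact expectation under random
  ranking (E[RIE] = 1 for exchangeable ranks).

**Shortlisting.** `shortlist_models()` keeps, per cluster, the union of
the top-`k` models by BEDROC and all models above a floor (defaults
`top_k = 10`, `floor = 0.5`). The literature mixes "BEDROC > 0.5" and
"< 0.5" phrasing, leaving an exact-0.5 value undefined; we implement a
strict `>` comparison by default with a `strict = FALSE` switch for `≥`.
Clusters where no model passes the floor are flagged in the
`"cluster_status"` attribute (`note = "no model selected"`) rather than
silently dropped.

## 5. Structural interaction fingerprints

`sift_params()` defaults:

- `contact_cutoff = 4.0` Å, **inclusive** (≤): "within 4 Å" is read as a
  closed boundary and tested at exactly 4.0.
- `hbond_dist = 3.5` Å donor–acceptor distance.
- `hbond_angle = 120`°: when an explicit hydrogen is present on the
  donor, the D–H…A angle must be ≥ 120°; when the pose carries no
  hydrogens (common for docking output), a distance-only criterion is
  applied. The original SIFt software's exact angle threshold is not
  published; 120° is the common permissive choice and is exposed.

Nine bits per residue: any contact, backbone, side chain, polar,
hydrophobic, H-bond donor (protein donates), H-bond acceptor (protein
accepts), aromatic (ring-atom contact with a ligand ring atom), charged.
Residue classes are explicit tables (polar: S, T, C, Y, N, Q, H;
charged: D, E, K, R; hydrophobic contacts via side-chain carbons), so any
count that depends on the classification is reproducible from the code.

`sift_profile()` averages the any-contact bit per position across
ligand–model pairs; `call_binding_site()` labels positions **retained**
when the frequency is strictly `> 0.5` (a residue contacted by exactly
half the poses is *not* retained) and **hotspot** when `≥ 0.95`
(19 of 20 poses qualifies). Both thresholds are parameters.

Residues with a generic number are reported under it; unmapped residues
(loops) keep their raw `chain:resno` key so extracellular-loop contacts
are not lost.

## 6. Generic numbering (class C)

`numbering_map()` assigns each helix an anchor residue labelled
`h.50x50`; other residues in the span count offsets from it
(`3.40x40` is ten residues before the TM3 anchor). Bulge/constriction
corrections shift only the x-part (`1.52x53`). Maps validate that the
anchor lies in its span and spans do not overlap; labelling is a
bijection over the spans, and `cross_map()` errors on labels absent from
a registry instead of returning empty rows.

## 7. Synthetic generators: what they emulate

- `simulate_screen()` draws active scores with an exponential rank tilt
  of strength `beta` (`beta = 0` is exactly random); it emulates the
  *rank distribution* of a docking screen, not docking scores'
  physical meaning. Used to verify BEDROC against planted enrichment and
  the random-baseline expectation.
- `simulate_library()` / `plant_candidates()` generate descriptor
  tables with known eligible decoy pools: planted candidates sit inside
  every tolerance window with fingerprints from a disjoint feature block
  (Tanimoto 0 to all actives); background compounds violate the MW
  window by construction. They emulate the *selection problem*, not
  chemistry — the records carry descriptors and fingerprints, not
  structures.
- `pocket_recipe()` / `build_pocket()` place up to 12 residues on
  icosahedron vertices around a central ligand, each realising one
  planted interaction intent (hydrophobic, polar, H-bond donor/acceptor,
  aromatic, charged, backbone-only, none) with distance windows chosen
  so intents cannot cross-talk (e.g. charged contacts at 3.6–4.0 Å sit
  above the 3.5 Å H-bond ceiling). The planted bit matrix is returned as
  `expected_bits` and must equal the computed SIFt exactly — including
  after a PDB/SDF round-trip. The pockets are geometric toys: no
  sterics, no force field, no real side-chain rotamers.
- `table1_fixture()` ships a curated allosteric-site profile table for
  three class-C receptors with per-receptor residue registries and
  numbering maps. Only the tabulated positions plus anchors consistent
  with them are encoded; full helix spans are not public.

## 8. Problem sizes and performance

The test suite exercises: libraries up to ~100 ligands for clustering;
candidate pools of ~10² for decoy selection (the eligibility scan is
O(actives × candidates) with a fingerprint comparison per pair); ranked
lists of N = 1000 with 2,500 simulated screens for the BEDROC
calibration checks (seconds); exhaustive BEDROC configurations for small
N against the naive oracle; and 50 random pockets for SIFt recovery.
All generator outputs are deterministic per seed (`withr::with_seed`).

## 9. Limitations

- No pKa/protonation model: net charge is read from the drawn structure.
- logP comes from Open Babel; single-atom and exotic structures may
  return `NA`.
- The H-bond criterion is distance-only when poses lack hydrogens.
- The KGS criterion cannot return `k = 2` on non-degenerate data (see
  §2) and cluster-merging follows an automatic closest-pair rule.
- Aromaticity handling relies on the input conventions (kekulised SDF
  bonds or aromatic flags); no aromaticity perception beyond ring
  detection is performed.
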