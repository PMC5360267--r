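# Packaged fixture: the published consensus allosteric-site table for the
# GABA_B2 7TM domain (25 generic positions with their residues in GABA_B2,
# mGlu1 and mGlu5, and the SIFt(8)/SIFt(7) any-contact frequencies), plus
# numbering maps consistent with it.

#' Published allosteric-site profile fixture
#'
#' Returns the 25 consensus binding-site positions of the GABA_B2
#' transmembrane domain with their generic numbers, the corresponding
#' residues in GABA_B2, mGlu1 and mGlu5, and the any-contact frequencies of
#' the two general SIFt profiles (over the eight selected models, and over
#' the seven mGlu-template models only). Also builds per-receptor residue
#' registries and generic-numbering maps consistent with the table, for use
#' with [cross_map()] and [assign_numbers()].
#'
#' @return List with elements:
#'   * `profiles`: tibble `position`, `sift8`, `sift7`;
#'   * `residues`: long tibble `position`, `receptor`, `resno`, `aa`;
#'   * `registries`: named list (GABAB2, mGlu1, mGlu5) of residue
#'     registries for [cross_map()];
#'   * `numbering`: named list of [numbering_map()] objects (helices 3, 5,
#'     6, 7; spans restricted to the neighbourhood of the tabulated
#'     positions).
#' @examples
#' fx <- table1_fixture()
#' call_binding_site(
#'   data.frame(position = fx$profiles$position, freq = fx$profiles$sift8)
#' )
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "allosteric_site_profiles.csv",
    package = "ligsel", mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE)

  receptors <- c(GABAB2 = "gabab2", mGlu1 = "mglu1", mGlu5 = "mglu5")
  residues <- purrr::map_dfr(names(receptors), function(r) {
    res <- tab[[receptors[[r]]]]
    tibble::tibble(
      position = tab$position, receptor = r,
      resno = as.integer(sub("^[A-Z]", "", res)),
      aa = sub("[0-9]+$", "", res)
    )
  })
  registries <- lapply(split(residues, residues$receptor), function(d) {
    tibble::tibble(label = d$position, resno = d$resno, aa = d$aa)
  })[names(receptors)]

  numbering <- lapply(names(receptors), function(r) {
    d <- residues[residues$receptor == r, ]
    d$helix <- tab$helix
    d$seq_part <- tab$seq_part
    d$x_part <- tab$x_part
    hx <- purrr::map_dfr(split(d, d$helix), function(h) {
      anchor <- h$resno[1] - (h$seq_part[1] - 50L)
      tibble::tibble(
        helix = h$helix[1], anchor = anchor,
        start = min(h$resno), end = max(c(h$resno, anchor))
      )
    })
    xc <- d[d$x_part != d$seq_part, c("resno", "x_part")]
    names(xc) <- c("resno", "x")
    numbering_map(hx, if (nrow(xc)) xc else NULL)
  })
  names(numbering) <- names(receptors)

  list(
    profiles = tab[, c("position", "sift8", "sift7")],
    residues = residues,
    registries = registries,
    numbering = numbering
  )
}
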