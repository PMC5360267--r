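# GPCRdb class C generic residue numbering (T.NNxMM): sequence-based labels
# anchored at the most conserved (.50) position of each transmembrane helix,
# with an x-part correcting for helical bulges and constrictions.

#' Build a generic-numbering map from helix anchors
#'
#' @param helices Tibble with one row per helix: `helix` (1-7), `anchor`
#'   (residue index of the .50 position), `start`, `end` (helix span).
#' @param x_corrections Optional tibble `resno`, `x` overriding the
#'   structure-corrected part for individual residues (bulges and
#'   constrictions); by default the x-part equals the sequence part.
#' @return A `numbering_map` object.
#' @export
numbering_map <- function(helices, x_corrections = NULL) {
  stopifnot(is.data.frame(helices),
    all(c("helix", "anchor", "start", "end") %in% names(helices)))
  if (any(helices$anchor < helices$start | helices$anchor > helices$end)) {
    stop("anchor outside helix span", call. = FALSE)
  }
  spans <- helices[order(helices$start), ]
  if (nrow(spans) > 1 &&
    any(spans$start[-1] <= spans$end[-nrow(spans)])) {
    stop("overlapping helix spans", call. = FALSE)
  }
  if (!is.null(x_corrections)) {
    stopifnot(all(c("resno", "x") %in% names(x_corrections)))
  }
  structure(
    list(helices = tibble::as_tibble(helices),
      x_corrections = if (is.null(x_corrections)) {
        tibble::tibble(resno = integer(), x = integer())
      } else {
        tibble::as_tibble(x_corrections)
      }),
    class = "numbering_map"
  )
}

#' Read a numbering map from YAML
#'
#' Expected layout: a `helices` mapping keyed by helix number, each with
#' `anchor_index`, `span` (two-element list) and optional `x_corrections`
#' (residue index to x value).
#'
#' @param path YAML file path.
#' @return A `numbering_map`.
#' @export
read_anchors <- function(path) {
  if (!file.exists(path)) stop("anchor file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  hx <- y$helices
  helices <- purrr::map_dfr(names(hx), function(h) {
    tibble::tibble(
      helix = as.integer(h),
      anchor = as.integer(hx[[h]]$anchor_index),
      start = as.integer(hx[[h]]$span[[1]]),
      end = as.integer(hx[[h]]$span[[2]])
    )
  })
  xc <- purrr::map_dfr(names(hx), function(h) {
    cor <- hx[[h]]$x_corrections
    if (is.null(cor)) return(NULL)
    tibble::tibble(resno = as.integer(names(cor)),
      x = as.integer(unlist(cor)))
  })
  numbering_map(helices, if (nrow(xc)) xc else NULL)
}

#' Residue labels of a numbering map
#'
#' Expands a map into one label per residue in the helix spans:
#' sequence part `50 + (resno - anchor)`, x-part equal to the sequence part
#' unless overridden by a correction.
#'
#' @param map A [numbering_map()].
#' @return Tibble `resno`, `helix`, `seq_part`, `x_part`, `label`.
#' @export
numbering_labels <- function(map) {
  stopifnot(inherits(map, "numbering_map"))
  out <- purrr::map_dfr(seq_len(nrow(map$helices)), function(i) {
    h <- map$helices[i, ]
    resno <- h$start:h$end
    seq_part <- 50L + (resno - h$anchor)
    tibble::tibble(resno = resno, helix = h$helix, seq_part = seq_part)
  })
  out$x_part <- out$seq_part
  hit <- match(out$resno, map$x_corrections$resno)
  out$x_part[!is.na(hit)] <- map$x_corrections$x[hit[!is.na(hit)]]
  out$label <- sprintf("%d.%02dx%02d", out$helix, out$seq_part, out$x_part)
  if (anyDuplicated(out$label)) {
    stop("numbering map produces duplicate labels", call. = FALSE)
  }
  out
}

#' Attach generic numbers to a structure model
#'
#' Every residue inside a helix span receives its generic label; residues
#' outside the spans (loops, termini) stay unlabeled and keep their raw
#' residue keys in downstream SIFt output.
#'
#' @param model A [structure_model].
#' @param map A [numbering_map()] (anchor residues must exist in the model).
#' @return The model with a `numbering` tibble attached and a `position`
#'   column added to its atoms.
#' @export
assign_numbers <- function(model, map) {
  stopifnot(inherits(model, "structure_model"))
  labs <- numbering_labels(map)
  missing_anchor <- setdiff(map$helices$anchor, model$atoms$resno)
  if (length(missing_anchor)) {
    stop("anchor residue(s) absent from model: ",
      paste(missing_anchor, collapse = ", "), call. = FALSE)
  }
  model$numbering <- labs
  model$atoms$position <- labs$label[match(model$atoms$resno, labs$resno)]
  model
}

#' Map a generic number across receptors
#'
#' Looks up the residue holding a generic label in each of several residue
#' registries (tibbles with `label`/`position`, `resno` and `aa` columns,
#' e.g. from [table1_fixture()] or built by combining [numbering_labels()]
#' with a sequence).
#'
#' @param registries Named list of residue registries.
#' @param label Generic number, e.g. `"6.50x50"`.
#' @return Tibble with one row per registry: `receptor`, `label`, `resno`,
#'   `aa`, `residue` (e.g. `"C703"`).
#' @export
cross_map <- function(registries, label) {
  stopifnot(is.list(registries), length(registries) >= 1)
  purrr::map_dfr(names(registries), function(nm) {
    reg <- registries[[nm]]
    lab_col <- if ("label" %in% names(reg)) "label" else "position"
    hit <- which(reg[[lab_col]] == label)
    if (!length(hit)) {
      stop("label ", label, " absent from registry '", nm, "'", call. = FALSE)
    }
    tibble::tibble(
      receptor = nm, label = label,
      resno = reg$resno[hit[1]], aa = reg$aa[hit[1]],
      residue = paste0(reg$aa[hit[1]], reg$resno[hit[1]])
    )
  })
}
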