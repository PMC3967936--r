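# ---- Region-wise reachability on the epithelium ---------------------------

#' Asynchronous reachability of cell fates per epithelial region
#'
#' Emulates inserting a naive cell at each position of the epithelium: the
#' single-cell model's inputs are fixed to the values realised at that
#' position in the given epithelial configuration (pattern inputs from their
#' fields, extracellular inputs from the neighbours), the asynchronous state
#' transition graph is built from the initial state, and the reachable
#' attractors are collected. Cells are grouped by fate region and, within a
#' region, by realised input sub-combination.
#'
#' Before signal extinction the initial state is naive (all internal
#' components at 0); after extinction it is the fate the cell carried at the
#' end of the previous phase, with the extinguished input now at 0 in the
#' realised inputs.
#'
#' @param model the single-cell model (Mid as input), see
#'   [mechanistic_single_cell()].
#' @param epi epithelium at the attractor of the analysed phase.
#' @param fields the wild-type (pre-extinction) input fields defining the
#'   regions.
#' @param map region map from [region_map()].
#' @param table fate table.
#' @param phase `"pre"` or `"post"` (extinction).
#' @param slow components at lower asynchronous priority (e.g. `"Pnt"` for
#'   the delayed-Pnt variant).
#' @param epi_pre for `phase = "post"`: the pre-extinction attractor
#'   configuration supplying each cell's initial state.
#' @return data.frame with one row per (region, input sub-combination,
#'   initial state): realised inputs, number of cells, number of reachable
#'   attractors and the sorted fate labels.
#' @export
region_reachability <- function(model, epi, fields, map, table = fate_table(),
                                phase = c("pre", "post"), slow = character(),
                                epi_pre = NULL) {
  phase <- match.arg(phase)
  if (phase == "post" && is.null(epi_pre)) {
    stop("phase 'post' needs `epi_pre`, the pre-extinction configuration")
  }
  epi <- compute_integration(epi)
  n <- n_cells(epi$grid)
  regions <- cell_regions(fields, map)
  inputs <- model_inputs(model)
  internals <- model_internals(model)

  iv <- vapply(inputs, function(nm) as.vector(epi$levels[[nm]]), numeric(n))
  init <- if (phase == "pre") {
    matrix(0L, n, length(internals), dimnames = list(NULL, internals))
  } else {
    vapply(internals, function(nm) as.vector(epi_pre$levels[[nm]]), numeric(n))
  }

  key <- paste(regions, apply(cbind(iv, init), 1, paste, collapse = ","))
  groups <- split(seq_len(n), key)
  rows <- lapply(groups, function(cells) {
    i <- cells[1]
    fx <- stats::setNames(as.integer(iv[i, ]), inputs)
    st <- model_state(model, stats::setNames(
      as.integer(c(iv[i, ], init[i, ])), c(inputs, internals)))
    rf <- reachable_fates(model, fx, st, table, slow = slow)
    data.frame(region = regions[i], as.list(fx),
               init = paste(init[i, ], collapse = ","),
               n_cells = length(cells),
               n_attractors = length(rf$attractors),
               fates = paste(rf$fates, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(match(out$region, map$region))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Regions with a deterministic reachable fate
#'
#' A region is counted as single-fate when every realised input
#' sub-combination admits exactly one reachable attractor.
#'
#' @param report output of [region_reachability()].
#' @return character vector of single-fate region labels.
#' @export
single_fate_regions <- function(report) {
  agg <- tapply(report$n_attractors, report$region, function(x) all(x == 1L))
  names(agg)[agg]
}
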