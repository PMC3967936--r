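# ---- Bundled eggshell-patterning models ----------------------------------

#' Load a bundled eggshell model
#'
#' @param name `"phenomenological"` (fate-level model: Roof/Floor/Operculum
#'   reading EGF, BMP, the anterior competence region and roof contact) or
#'   `"mechanistic"` (the EGF/BMP genetic network with Mid, dpERK, Mirr,
#'   Pnt, Rho, Aos and Br).
#' @return a `logical_model`.
#' @export
eggshell_model <- function(name = c("mechanistic", "phenomenological")) {
  name <- match.arg(name)
  path <- system.file("models", paste0(name, ".ylm"), package = "epilogic")
  if (path == "") stop("bundled model '", name, "' not found")
  read_model(path)
}

#' Single-cell analysis form of the mechanistic model
#'
#' For single-cell attractor and reachability analyses the anterior module
#' is collapsed: Mid becomes an input (its level in the epithelium is set by
#' the early signals and then maintained), and the early signal inputs are
#' dropped. The six single-cell inputs are then Grk, Dpp, Mid, Aos_ext,
#' Rho_ext and Br_adj.
#'
#' @param model the mechanistic `logical_model` (default: bundled).
#' @return a `logical_model` with Mid as an input.
#' @export
mechanistic_single_cell <- function(model = eggshell_model("mechanistic")) {
  ct <- model$components
  ct$input[ct$name == "Mid"] <- TRUE
  drop <- c("early_EGF", "early_BMP")
  keep <- !(ct$name %in% drop)
  model$components <- ct[keep, , drop = FALSE]
  rownames(model$components) <- NULL
  model$rules[["Mid"]] <- NULL
  model$priorities <- lapply(model$priorities, function(cl) setdiff(cl, "Mid"))
  model$priorities <- model$priorities[lengths(model$priorities) > 0]
  model$name <- paste0(model$name, "_single_cell")
  model
}

# ---- Wild-type input patterns --------------------------------------------

#' Default geometry parameters for the wild-type input fields
#'
#' All lengths are in cells and scale with the grid so that the fate-region
#' layout is preserved when the grid is refined. On the reference 24 x 40
#' grid: the Dpp band covers the 2 anterior rows plus one extra dorsal row
#' (the band is slightly wider at the dorsal side); the Grk source sits on
#' the dorsal midline at row 5 with level rings of hex radius 3/5/7; the
#' posterior Mid domain (absence of the anterior competence region) starts
#' at row 8, set by early posterior EGF (from row 5) minus the early BMP
#' domain (rows 0..7).
#'
#' @param grid a `hex_grid`.
#' @export
wildtype_params <- function(grid) {
  sr <- grid$n_rows / 24
  sc <- grid$n_cols / 40
  s <- (sr + sc) / 2
  list(midline_col = grid$n_cols %/% 2L,
       dpp_rows = max(1L, round(2 * sr)),
       dpp_extra_rows = max(1L, round(1 * sr)),
       dpp_extra_halfwidth = max(2L, round(6 * sc)),
       grk_center_row = round(5 * sr),
       grk_radii = pmax(c(1L, 2L, 3L), round(c(3, 5, 7) * s)),
       mid_from_row = round(8 * sr),
       early_egf_from_row = round(5 * sr))
}

.grk_field <- function(grid, center, radii, maxlev = 3L) {
  n <- n_cells(grid)
  co <- cell_coords(grid, seq_len(n))
  d <- hex_distance(grid, center, co[, "row"], co[, "col"])
  # radii are increasing, levels decreasing: assign from the outside in
  lev <- rep(0L, n)
  for (k in rev(seq_along(radii))) lev[d <= radii[k]] <- (maxlev - k + 1L)
  matrix(lev, grid$n_rows, grid$n_cols)
}

#' Wild-type input pattern fields
#'
#' Generates the input fields of the mechanistic epithelial model: a graded
#' Grk field (levels 3..1 on hex-distance rings around a dorsal source), an
#' anterior Dpp band slightly wider at the dorsal side, the early posterior
#' EGF and early anterior BMP fields, and the resulting posterior Mid
#' domain. The realised (Grk, Dpp, Mid) triples partition the epithelium
#' into fate regions.
#'
#' @param grid a `hex_grid`.
#' @param params geometry parameters, see [wildtype_params()].
#' @param require_all_regions error when fewer than 12 distinct
#'   (Grk, Dpp, Mid) triples are realised (the grid is then too small).
#' @return named list of level matrices: `Grk`, `Dpp`, `Mid`, `early_EGF`,
#'   `early_BMP`.
#' @export
wildtype_inputs <- function(grid, params = wildtype_params(grid),
                            require_all_regions = TRUE) {
  p <- params
  rows <- matrix(seq_len(grid$n_rows) - 1L, grid$n_rows, grid$n_cols)
  cols <- matrix(rep(seq_len(grid$n_cols) - 1L, each = grid$n_rows),
                 grid$n_rows, grid$n_cols)
  # ring distance of every column to the dorsal midline column (wrapping)
  dcol <- pmin(abs(cols - p$midline_col),
               grid$n_cols - abs(cols - p$midline_col))

  dpp <- matrix(0L, grid$n_rows, grid$n_cols)
  dpp[rows < p$dpp_rows] <- 1L
  dorsal_extra <- rows >= p$dpp_rows &
    rows < p$dpp_rows + p$dpp_extra_rows &
    dcol <= p$dpp_extra_halfwidth
  dpp[dorsal_extra] <- 1L

  grk <- .grk_field(grid, c(p$grk_center_row, p$midline_col), p$grk_radii)

  early_egf <- matrix(0L, grid$n_rows, grid$n_cols)
  early_egf[rows >= p$early_egf_from_row] <- 1L
  early_bmp <- matrix(0L, grid$n_rows, grid$n_cols)
  early_bmp[rows < p$mid_from_row] <- 1L
  mid <- matrix(as.integer(early_egf == 1L & early_bmp == 0L),
                grid$n_rows, grid$n_cols)

  fields <- list(Grk = grk, Dpp = dpp, Mid = mid,
                 early_EGF = early_egf, early_BMP = early_bmp)
  if (require_all_regions) {
    nreg <- nrow(unique(data.frame(g = as.vector(grk), d = as.vector(dpp),
                                   m = as.vector(mid))))
    if (nreg < 12L) {
      stop("grid too small: only ", nreg,
           " distinct (Grk, Dpp, Mid) regions realised (need 12)")
    }
  }
  fields
}

#' Input fields for the phenomenological epithelial model
#'
#' EGF activity is graded around the dorsal source (level 2 on the inner
#' ring, 1 on the outer), BMP follows the anterior Dpp band, and the
#' anterior competence field covers the rows anterior to the Mid domain.
#'
#' @inheritParams wildtype_inputs
#' @return named list of matrices `EGF`, `BMP`, `anterior`.
#' @export
phenomenological_inputs <- function(grid, params = wildtype_params(grid)) {
  wf <- wildtype_inputs(grid, params, require_all_regions = FALSE)
  egf <- wf$Grk
  egf[] <- 0L
  egf[wf$Grk >= 1L] <- 1L
  egf[wf$Grk >= 3L] <- 2L
  list(EGF = egf, BMP = wf$Dpp,
       anterior = matrix(as.integer(wf$Mid == 0L), grid$n_rows, grid$n_cols))
}

# ---- Region map ----------------------------------------------------------

#' Fate regions realised by a wild-type input configuration
#'
#' Regions are the distinct (Grk, Dpp, Mid) level triples realised on the
#' grid, numbered canonically: the anterior Dpp band first, then the
#' competence region, then the posterior Mid domain, each ordered by
#' decreasing Grk (so on the default geometry R1 is the dorsal-anterior
#' band, R5 the Grk peak, R6-R7 the presumptive roof, R8 the lateral
#' competence region and R9-R12 the posterior domain).
#'
#' @param fields input fields from [wildtype_inputs()].
#' @return data.frame with columns `region`, `Grk`, `Dpp`, `Mid`, `n_cells`.
#' @export
region_map <- function(fields) {
  df <- data.frame(Grk = as.vector(fields$Grk), Dpp = as.vector(fields$Dpp),
                   Mid = as.vector(fields$Mid))
  agg <- stats::aggregate(list(n_cells = rep(1L, nrow(df))), df, sum)
  agg <- agg[order(agg$Mid, -agg$Dpp, -agg$Grk), , drop = FALSE]
  agg$region <- paste0("R", seq_len(nrow(agg)))
  rownames(agg) <- NULL
  agg[, c("region", "Grk", "Dpp", "Mid", "n_cells")]
}

#' Region id of every cell
#' @param fields wild-type input fields.
#' @param map a region map from [region_map()].
#' @return character vector of region labels, one per cell (linear index).
#' @export
cell_regions <- function(fields, map) {
  key <- paste(as.vector(fields$Grk), as.vector(fields$Dpp),
               as.vector(fields$Mid))
  map$region[match(key, paste(map$Grk, map$Dpp, map$Mid))]
}

# ---- Pattern classification ----------------------------------------------

#' Classify the cells of an epithelium against a fate table
#'
#' Labels every cell by the fate whose signature matches its current levels
#' of the fate-table components; unmatched cells are labelled `"other"`,
#' never dropped. The summary reports the geometry used by the pattern
#' assertions: number of connected roof patches (Br-positive, hex
#' adjacency), floor size (high-Rho, non-roof cells), how many floor cells
#' touch a roof cell, and whether the floor is single-cell wide (no three
#' mutually adjacent floor cells).
#'
#' @param epi an `epithelium` (typically at an attractor).
#' @param table a fate table, see [fate_table()].
#' @return list with `fates` (matrix of labels), `summary`.
#' @export
classify_pattern <- function(epi, table = fate_table()) {
  comps <- setdiff(names(table), c("fate", "description"))
  n <- n_cells(epi$grid)
  states <- as.data.frame(lapply(epi$levels[comps], as.vector))
  labs <- classify_fates(states, table)
  fates <- matrix(labs, epi$grid$n_rows, epi$grid$n_cols)

  nb1 <- epi$nb[["1"]]
  if (is.null(nb1)) nb1 <- neighbor_index(epi$grid, 1L)
  roof <- as.vector(epi$levels$Br >= 1L)
  floorc <- as.vector(epi$levels$Rho >= 2L) & !roof

  # connected components of the roof set under hex adjacency
  patch <- rep(NA_integer_, n)
  np <- 0L
  for (i in which(roof)) {
    if (!is.na(patch[i])) next
    np <- np + 1L
    queue <- i
    patch[i] <- np
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nbs <- nb1[v, ]
      nbs <- nbs[!is.na(nbs)]
      nbs <- nbs[roof[nbs] & is.na(patch[nbs])]
      patch[nbs] <- np
      queue <- c(queue, nbs)
    }
  }

  floor_idx <- which(floorc)
  touches <- vapply(floor_idx, function(v) {
    nbs <- nb1[v, ]; nbs <- nbs[!is.na(nbs)]
    any(roof[nbs])
  }, logical(1))
  # single-cell width: no triangle of mutually adjacent floor cells
  triangle <- FALSE
  for (v in floor_idx) {
    nbs <- nb1[v, ]; nbs <- nbs[!is.na(nbs)]
    fnb <- nbs[floorc[nbs]]
    if (length(fnb) >= 2) {
      for (a in seq_along(fnb)) {
        bn <- nb1[fnb[a], ]; bn <- bn[!is.na(bn)]
        if (any(fnb[-a] %in% bn)) { triangle <- TRUE; break }
      }
    }
    if (triangle) break
  }

  list(fates = fates,
       summary = list(
         n_roof_cells = sum(roof),
         n_roof_patches = np,
         roof_patch_id = matrix(patch, epi$grid$n_rows, epi$grid$n_cols),
         n_floor_cells = length(floor_idx),
         floor_cells = floor_idx,
         floor_touching_roof = sum(touches),
         floor_single_width = !triangle))
}

#' Mirror symmetry of a logical cell set about the dorsal midline
#'
#' @param grid a `hex_grid`.
#' @param flag logical or 0/1 matrix over the grid.
#' @param midline_col dorsal midline column (0-based).
#' @return fraction of flagged cells whose mirror image is flagged.
#' @export
mirror_symmetry <- function(grid, flag, midline_col) {
  flag <- matrix(as.logical(flag), grid$n_rows, grid$n_cols)
  cols <- seq_len(grid$n_cols) - 1L
  mcol <- (2L * midline_col - cols) %% grid$n_cols
  mirrored <- flag[, mcol + 1L, drop = FALSE]
  if (!any(flag)) return(1)
  sum(flag & mirrored) / sum(flag)
}
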