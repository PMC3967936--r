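# ---- Epithelium: coupled single-cell models on a hex grid ---------------

#' Neighbourhood-integration rules
#'
#' An integration rule computes one extracellular input field from the
#' neighbourhood of each cell. Methods: `"any"` sets level 1 as soon as one
#' neighbour within `range` expresses the source (level >= 1) — the
#' juxtacrine case; `"max"` takes the maximum source level over the
#' neighbourhood (short-range paracrine, e.g. level 2 iff some neighbour is
#' at 2); `"count"` counts source-positive neighbours within `range` and
#' thresholds the count (long-range paracrine; `thresholds[k]` cells give
#' level k).
#'
#' @param var name of the extracellular input component to fill.
#' @param source name of the intracellular component read from neighbours.
#' @param range neighbourhood radius in hex steps (>= 1).
#' @param method `"any"`, `"max"` or `"count"`.
#' @param thresholds strictly increasing neighbour counts for `"count"`.
#' @param hi_count for `"max"`: how many neighbours at the source's level 2
#'   are needed before the field reports level 2 (default 1; a higher value
#'   means only a saturated source region registers as a high signal).
#' @export
integration_rule <- function(var, source, range = 1L,
                             method = c("any", "max", "count"),
                             thresholds = NULL, hi_count = 1L) {
  method <- match.arg(method)
  stopifnot(range >= 1, hi_count >= 1)
  if (method == "count") {
    stopifnot(!is.null(thresholds), all(diff(thresholds) > 0))
  }
  structure(list(var = var, source = source, range = as.integer(range),
                 method = method,
                 thresholds = if (!is.null(thresholds)) as.integer(thresholds),
                 hi_count = as.integer(hi_count)),
            class = "integration_rule")
}

#' Default integration configuration for the mechanistic eggshell model
#'
#' `Br_adj` is juxtacrine (one Br-positive distance-1 neighbour suffices);
#' `Rho_ext` has a short range (distance 1): level 1 as soon as one
#' neighbour expresses Rho, level 2 only when at least `rho_hi_count`
#' neighbours release Spitz at the high level (a saturated local source);
#' `Aos_ext` acts at a distance (radius 3), with level thresholds on the
#' count of Aos-positive cells in range.
#'
#' @param rho_range neighbourhood radius for `Rho_ext` (default 1).
#' @param rho_hi_count how many Rho = 2 neighbours give `Rho_ext` level 2
#'   (default 5: only a saturated high-Rho region registers as a high
#'   extracellular Spitz signal).
#' @param aos_range neighbourhood radius for `Aos_ext` (default 3).
#' @param aos_thresholds counts of Aos-positive neighbours for `Aos_ext`
#'   levels 1 and 2 (default `c(1, 4)`).
#' @param br_range neighbourhood radius for `Br_adj` (default 1).
#' @return a list of [integration_rule()]s.
#' @export
integration_config <- function(rho_range = 1L, rho_hi_count = 5L,
                               aos_range = 3L, aos_thresholds = c(1L, 4L),
                               br_range = 1L) {
  list(integration_rule("Br_adj", "Br", br_range, "any"),
       integration_rule("Rho_ext", "Rho", rho_range, "max",
                        hi_count = rho_hi_count),
       integration_rule("Aos_ext", "Aos", aos_range, "count",
                        thresholds = aos_thresholds))
}

#' Create an epithelium
#'
#' Every cell of the grid carries the same logical model; input components
#' are set from pattern fields (level matrices).
#'
#' @param model a `logical_model`.
#' @param grid a `hex_grid`.
#' @param inputs named list of input pattern fields: each entry a
#'   `n_rows x n_cols` integer matrix, or a scalar recycled over the grid.
#'   Unlisted inputs (including the integration variables, which are
#'   recomputed every tick) start at 0.
#' @param integration an [integration_config()]; `NULL` disables neighbour
#'   integration (the extracellular inputs then stay as given).
#' @param perturbations list of [perturbation()] specs.
#' @return an object of class `epithelium`.
#' @export
new_epithelium <- function(model, grid, inputs = list(),
                           integration = integration_config(),
                           perturbations = list()) {
  ct <- model$components
  zero <- matrix(0L, grid$n_rows, grid$n_cols)
  levels <- stats::setNames(rep(list(zero), nrow(ct)), ct$name)
  for (nm in names(inputs)) {
    j <- match(nm, ct$name)
    if (is.na(j)) stop("input field for unknown component '", nm, "'")
    f <- inputs[[nm]]
    if (length(f) == 1L) f <- matrix(as.integer(f), grid$n_rows, grid$n_cols)
    if (!all(dim(f) == c(grid$n_rows, grid$n_cols))) {
      stop("field '", nm, "' has wrong dimensions")
    }
    storage.mode(f) <- "integer"
    if (any(f < 0L | f > ct$max[j])) {
      stop("field '", nm, "' has levels outside 0..", ct$max[j])
    }
    levels[[nm]] <- f
  }
  delayed <- delayed_components(model)
  counters <- lapply(delayed, function(nm) list(count = zero, dir = zero))
  names(counters) <- delayed
  epi <- structure(list(model = model, grid = grid, levels = levels,
                        derived = list(), counters = counters,
                        integration = integration,
                        perturbations = perturbations,
                        tick = 0L, phase = 0L, converged = FALSE,
                        nb = list()),
                   class = "epithelium")
  if (!is.null(integration)) {
    for (k in unique(vapply(integration, function(r) r$range, integer(1)))) {
      epi$nb[[as.character(k)]] <- neighbor_index(grid, k)
    }
  }
  enforce_perturbations(epi)
}

#' @export
print.epithelium <- function(x, ...) {
  cat("Epithelium: model '", x$model$name, "' on ", x$grid$n_rows, "x",
      x$grid$n_cols, " cells; tick ", x$tick, ", phase ", x$phase,
      if (length(x$perturbations)) paste0(", ", length(x$perturbations),
                                          " perturbation(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Define a perturbation (loss/gain of function, clone or whole tissue)
#'
#' @param component name of a model component or derived variable.
#' @param mode `"clamp"` (hold at `value`) or `"range"` (restrict to
#'   `[min, max]`; targets outside are truncated to the nearest bound).
#' @param value clamp level.
#' @param min,max range bounds.
#' @param mask `NULL` for the whole grid, or integer cell indices / a logical
#'   matrix selecting the clone.
#' @param phases `NULL` for all phases, or integer phases where the
#'   perturbation is active.
#' @export
perturbation <- function(component, mode = c("clamp", "range"), value = NULL,
                         min = NULL, max = NULL, mask = NULL, phases = NULL) {
  mode <- match.arg(mode)
  if (mode == "clamp" && is.null(value)) stop("clamp needs a value")
  if (mode == "range" && (is.null(min) || is.null(max))) {
    stop("range needs min and max")
  }
  structure(list(component = component, mode = mode,
                 value = if (!is.null(value)) as.integer(value),
                 min = if (!is.null(min)) as.integer(min),
                 max = if (!is.null(max)) as.integer(max),
                 mask = mask, phases = phases),
            class = "perturbation")
}

.mask_indices <- function(epi, mask) {
  if (is.null(mask)) return(seq_len(n_cells(epi$grid)))
  if (is.logical(mask)) return(which(mask))
  as.integer(mask)
}

.apply_spec_field <- function(epi, field, spec) {
  idx <- .mask_indices(epi, spec$mask)
  if (spec$mode == "clamp") {
    field[idx] <- spec$value
  } else {
    field[idx] <- pmin(pmax(field[idx], spec$min), spec$max)
  }
  field
}

# re-impose all active perturbations on the current level/derived fields;
# called after every update stage so clones are airtight against transients
enforce_perturbations <- function(epi) {
  for (spec in epi$perturbations) {
    if (!is.null(spec$phases) && !(epi$phase %in% spec$phases)) next
    nm <- spec$component
    if (!is.null(epi$levels[[nm]])) {
      epi$levels[[nm]] <- .apply_spec_field(epi, epi$levels[[nm]], spec)
    } else if (!is.null(epi$derived[[nm]])) {
      epi$derived[[nm]] <- .apply_spec_field(epi, epi$derived[[nm]], spec)
    } else if (!(nm %in% names(epi$model$derived))) {
      stop("perturbation targets unknown component '", nm, "'")
    }
  }
  epi
}

#' Attach a perturbation to an epithelium
#'
#' @param epi an `epithelium`.
#' @param spec a [perturbation()].
#' @return the modified epithelium, with the perturbation enforced on the
#'   current configuration.
#' @export
apply_perturbation <- function(epi, spec) {
  nm <- spec$component
  known <- c(names(epi$levels), names(epi$model$derived))
  if (!(nm %in% known)) stop("perturbation targets unknown component '", nm, "'")
  for (old in epi$perturbations) {
    if (old$component == nm && old$mode == "clamp" && spec$mode == "clamp" &&
        !identical(old$value, spec$value)) {
      a <- .mask_indices(epi, old$mask); b <- .mask_indices(epi, spec$mask)
      if (length(intersect(a, b))) {
        stop("contradictory clamps on '", nm, "' over overlapping cells")
      }
    }
  }
  epi$perturbations <- c(epi$perturbations, list(spec))
  enforce_perturbations(epi)
}

#' Compute the neighbour-integration variables
#'
#' Stage 1 of a tick: fills the extracellular input fields (`Rho_ext`,
#' `Aos_ext`, `Br_adj`) from the current grid configuration, then evaluates
#' the model's derived integration variables (S, A, X) per cell. The values
#' are stored on the epithelium and held fixed for the remaining stages of
#' the tick.
#'
#' @param epi an `epithelium`.
#' @return the epithelium with updated integration fields.
#' @export
compute_integration <- function(epi) {
  cfg <- epi$integration
  lv <- epi$levels
  if (!is.null(cfg)) {
    shape <- dim(lv[[1]])
    for (rule in cfg) {
      if (is.null(lv[[rule$var]]) || is.null(lv[[rule$source]])) next
      nb <- epi$nb[[as.character(rule$range)]]
      src <- lv[[rule$source]]
      out <- switch(rule$method,
        any = as.integer(neighbor_any(nb, src >= 1L)),
        max = {
          hi <- neighbor_count(nb, src >= 2L) >= rule$hi_count
          lo <- neighbor_any(nb, src >= 1L)
          ifelse(hi, 2L, ifelse(lo, 1L, 0L))
        },
        count = {
          cnt <- neighbor_count(nb, src >= 1L)
          lev <- rep(0L, length(cnt))
          for (k in seq_along(rule$thresholds)) {
            lev[cnt >= rule$thresholds[k]] <- k
          }
          lev
        })
      lv[[rule$var]] <- matrix(out, shape[1], shape[2])
    }
  }
  epi$levels <- lv
  epi <- enforce_perturbations(epi)
  # derived integration variables (instantaneous, frozen for this tick)
  vals <- compute_derived(epi$model, epi$levels)
  epi$derived <- vals[names(epi$model$derived)]
  enforce_perturbations(epi)
}

#' Advance the epithelium by one tick
#'
#' One tick applies three staged sub-updates to all cells: (1) recompute the
#' integration variables; (2) update the first priority class synchronously
#' (unit step); (3) update the remaining classes. Components with a declared
#' delay move only after their target has pointed the same way for `delay`
#' consecutive ticks. Perturbation clamps and ranges are re-imposed after
#' every stage.
#'
#' @param epi an `epithelium`.
#' @return the advanced epithelium.
#' @export
step <- function(epi) {
  epi <- compute_integration(epi)
  model <- epi$model
  delayed <- delayed_components(model)
  for (class_comps in model$priorities) {
    vals <- c(epi$levels, epi$derived)
    new_fields <- list()
    for (nm in class_comps) {
      tgt <- eval_clause_list(model$rules[[nm]], vals)
      cur <- epi$levels[[nm]]
      dirm <- sign(tgt - cur)
      if (nm %in% delayed) {
        d <- model$components$delay[match(nm, model$components$name)]
        cs <- epi$counters[[nm]]
        zero <- dirm == 0L
        rev <- !zero & (dirm != cs$dir)
        wait <- !zero & !rev & (cs$count < d)
        go <- !zero & !rev & !wait
        cs$count <- ifelse(zero, 0L, ifelse(rev, 1L,
                    ifelse(wait, cs$count + 1L, cs$count)))
        cs$dir <- ifelse(zero, 0L, dirm)
        epi$counters[[nm]] <- cs
        dirm <- dirm * go
      }
      new_fields[[nm]] <- cur + dirm
    }
    for (nm in class_comps) epi$levels[[nm]] <- new_fields[[nm]]
    epi <- enforce_perturbations(epi)
  }
  epi$tick <- epi$tick + 1L
  epi$converged <- FALSE
  epi
}

.config_hash <- function(epi) {
  parts <- c(unlist(epi$levels, use.names = FALSE),
             unlist(lapply(epi$counters, function(cs)
               c(cs$count, cs$dir)), use.names = FALSE))
  paste(parts, collapse = ",")
}

#' Iterate the epithelium to an attractor
#'
#' Steps the model, hashing the full configuration (including delay
#' counters) each tick, and stops at the first repeat: period 1 is a fixed
#' point, a longer period a cyclic attractor. Hitting `max_ticks` without a
#' repeat returns outcome `"undecided"`.
#'
#' @param epi an `epithelium`.
#' @param max_ticks cap on the number of ticks (default 300).
#' @param record_every optionally keep a snapshot of the level fields every
#'   `record_every` ticks (stored in the `trajectory` element).
#' @return list with `epi` (final configuration), `outcome`
#'   (`"fixed_point"`, `"cycle"` or `"undecided"`), `period`, `ticks`, and
#'   optionally `trajectory`.
#' @export
run_to_attractor <- function(epi, max_ticks = 300L, record_every = NULL) {
  seen <- character(0)
  traj <- list()
  t0 <- epi$tick
  for (i in 0:max_ticks) {
    h <- .config_hash(epi)
    prev <- match(h, seen)
    if (!is.na(prev)) {
      period <- (epi$tick - t0) - (prev - 1L)
      epi$converged <- TRUE
      return(list(epi = epi,
                  outcome = if (period == 1L) "fixed_point" else "cycle",
                  period = period, ticks = epi$tick - t0,
                  trajectory = if (length(traj)) traj))
    }
    seen <- c(seen, h)  # position k corresponds to tick t0 + k - 1
    if (!is.null(record_every) && (epi$tick - t0) %% record_every == 0L) {
      traj[[length(traj) + 1L]] <- epi$levels
    }
    if (i < max_ticks) epi <- step(epi)
  }
  list(epi = epi, outcome = "undecided", period = NA_integer_,
       ticks = epi$tick - t0, trajectory = if (length(traj)) traj)
}

#' Extinguish an input signal over the whole epithelium
#'
#' Models the withdrawal of a ligand (by default Grk, at vitelline-membrane
#' formation): the input's pattern field is set to 0 everywhere, all other
#' per-cell states are preserved, and the phase tag advances.
#'
#' @param epi an `epithelium`.
#' @param component input component to zero (default `"Grk"`).
#' @param check warn when called before the current phase has converged.
#' @return the modified epithelium.
#' @export
extinguish_grk <- function(epi, component = "Grk", check = TRUE) {
  if (check && !isTRUE(epi$converged)) {
    warning("extinguishing '", component,
            "' before the current phase converged")
  }
  epi$levels[[component]][] <- 0L
  epi$phase <- epi$phase + 1L
  enforce_perturbations(epi)
}

#' Per-cell input combinations realised on the epithelium
#'
#' For each cell, reads off the single-cell model's input levels: the
#' pattern inputs from their fields and the extracellular variables from the
#' current configuration (integration is recomputed first so the values are
#' consistent with the state).
#'
#' @param epi an `epithelium`.
#' @param inputs which input components to report (default: all).
#' @return data.frame with `row`, `col`, `cell` and one column per input.
#' @export
realized_inputs <- function(epi, inputs = NULL) {
  epi <- compute_integration(epi)
  if (is.null(inputs)) inputs <- model_inputs(epi$model)
  n <- n_cells(epi$grid)
  co <- cell_coords(epi$grid, seq_len(n))
  out <- data.frame(cell = seq_len(n), row = co[, "row"], col = co[, "col"])
  for (nm in inputs) out[[nm]] <- as.vector(epi$levels[[nm]])
  out
}
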