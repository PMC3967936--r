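# ---- Scenario presets and the phase-schedule runner -----------------------

#' A hexagonal blob of cells (clone mask)
#'
#' @param grid a `hex_grid`.
#' @param center `c(row, col)`, 0-based.
#' @param radius hex radius (0 = single cell).
#' @return integer vector of linear cell indices.
#' @export
hex_blob <- function(grid, center, radius) {
  if (radius == 0) return(cell_index(grid, center[1], center[2]))
  sort(c(cell_index(grid, center[1], center[2]),
         neighbors(grid, center, radius)))
}

# standard clone positions on the reference geometry, scaled with the grid
.clone_sites <- function(grid) {
  sr <- grid$n_rows / 24; sc <- grid$n_cols / 40
  mk <- function(row, col, r = 2L) {
    hex_blob(grid, c(round(row * sr), round(col * sc) %% grid$n_cols),
             max(1L, round(r * (sr + sc) / 2)))
  }
  list(roof = mk(5, 25),          # inside a presumptive roof patch
       midline = mk(5, 20),       # on the Grk peak / dorsal midline
       ventral = mk(5, 0),        # ventral anterior, away from the source
       anterior = mk(1, 25),      # in the anterior Dpp band, dorsal-lateral
       roofspan = mk(4, 25, 3),   # large clone spanning roof and anterior
       boundary = mk(9, 24),      # straddling the posterior Mid border
       posterior = mk(14, 20, 3)) # deep posterior domain
}

.preset_registry <- function() {
  cl <- function(comp, value, mask = NULL, phases = NULL) {
    perturbation(comp, "clamp", value = value, mask = mask, phases = phases)
  }
  rg <- function(comp, min, max, mask = NULL) {
    perturbation(comp, "range", min = min, max = max, mask = mask)
  }
  list(
    WT = list(desc = "wild type"),
    GR1_dpp = list(
      desc = "mild dpp overexpression (GR1 driver, early and late); asymmetry maintained",
      params = function(p, grid) {
        sr <- grid$n_rows / 24; sc <- grid$n_cols / 40
        p$dpp_rows <- round(3 * sr)
        p$dpp_extra_halfwidth <- round(10 * sc)
        p$mid_from_row <- round(12 * sr)
        p
      }),
    CY2_dpp = list(
      desc = "strong, late dpp overexpression (CY2 driver, from stage 8): whole-grid Dpp, early BMP unchanged",
      fields = function(f, grid) { f$Dpp[] <- 1L; f }),
    tub_grk = list(
      desc = "grk overexpression (Tub driver): ubiquitous saturating Grk signal",
      fields = function(f, grid) { f$Grk[] <- 3L; f }),
    GR1_dpp_tub_grk = list(
      desc = "mild dpp overexpression combined with grk overexpression",
      params = function(p, grid) {
        sr <- grid$n_rows / 24; sc <- grid$n_cols / 40
        p$dpp_rows <- round(3 * sr)
        p$dpp_extra_halfwidth <- round(10 * sc)
        p$mid_from_row <- round(12 * sr)
        p
      },
      fields = function(f, grid) { f$Grk[] <- 3L; f }),
    CY2_dpp_tub_grk = list(
      desc = "strong late dpp overexpression combined with grk overexpression",
      fields = function(f, grid) { f$Dpp[] <- 1L; f$Grk[] <- 3L; f }),
    Aos_LOF = list(desc = "aos loss of function", perturb = list(cl("Aos", 0L))),
    Aos_GOF = list(desc = "aos gain of function (endogenous level)",
                   perturb = list(cl("Aos", 1L))),
    Br_LOF = list(desc = "br loss of function", perturb = list(cl("Br", 0L))),
    Br_GOF = list(desc = "br ectopic expression", perturb = list(cl("Br", 1L))),
    dpERK_LOF = list(desc = "EGFR partial loss of function: dpERK capped at level 1",
                     perturb = list(rg("dpERK", 0L, 1L))),
    dpERK_GOF = list(desc = "constitutive EGFR activation: dpERK at level 2",
                     perturb = list(cl("dpERK", 2L))),
    Mirr_LOF = list(desc = "mirr loss of function", perturb = list(cl("Mirr", 0L))),
    Mirr_GOF = list(desc = "mirr ectopic expression", perturb = list(cl("Mirr", 1L))),
    Pnt_LOF = list(desc = "pnt loss of function", perturb = list(cl("Pnt", 0L))),
    Pnt_GOF = list(desc = "pnt ectopic expression", perturb = list(cl("Pnt", 1L))),
    Rho_LOF = list(desc = "rho loss of function", perturb = list(cl("Rho", 0L))),
    Rho_GOF = list(desc = "rho ectopic expression: level constrained between 1 and 2",
                   perturb = list(rg("Rho", 1L, 2L))),
    X_LOF = list(desc = "juxtacrine signal X disabled", perturb = list(cl("X", 0L))),
    X_GOF = list(desc = "juxtacrine signal X constitutive", perturb = list(cl("X", 1L)))
  )
}

.clone_registry <- function(sites) {
  cl <- function(comp, value, where, phases = NULL) {
    perturbation(comp, "clamp", value = value, mask = sites[[where]],
                 phases = phases)
  }
  rg <- function(comp, min, max, where) {
    perturbation(comp, "range", min = min, max = max, mask = sites[[where]])
  }
  list(
    clone_Br_LOF = list(desc = "br loss-of-function clone in the roof",
                        perturb = list(cl("Br", 0L, "roof"))),
    clone_Br_GOF = list(desc = "br gain-of-function clone on the midline",
                        perturb = list(cl("Br", 1L, "midline"))),
    clone_dpERK_LOF = list(desc = "EGF pathway disruption clone in the roof",
                           perturb = list(cl("dpERK", 0L, "roof"))),
    clone_dpERK_GOF = list(desc = "ectopic EGF pathway activation clone in the roof",
                           perturb = list(cl("dpERK", 2L, "roof"))),
    clone_Mirr_LOF = list(desc = "mirr loss-of-function clone overlapping the roof",
                          perturb = list(cl("Mirr", 0L, "roof"))),
    clone_Mirr_GOF = list(desc = "mirr ectopic-expression clone, ventral",
                          perturb = list(cl("Mirr", 1L, "ventral"))),
    clone_Pnt_LOF = list(desc = "pnt loss-of-function clone on the midline",
                         perturb = list(cl("Pnt", 0L, "midline"))),
    clone_Pnt_GOF = list(desc = "pnt gain-of-function clone in the roof",
                         perturb = list(cl("Pnt", 1L, "roof"))),
    clone_Rho_LOF = list(desc = "rho loss-of-function clone on the midline",
                         perturb = list(cl("Rho", 0L, "midline"))),
    clone_Rho_GOF = list(desc = "ectopic rho clone, ventral/lateral",
                         perturb = list(rg("Rho", 1L, 2L, "ventral"))),
    clone_X_LOF = list(desc = "clone lacking the juxtacrine signal, lateral roof",
                       perturb = list(cl("X", 0L, "roof"))),
    clone_X_GOF = list(desc = "constitutive juxtacrine signal, dorsal-anterior clone",
                       perturb = list(cl("X", 1L, "midline"))),
    BMP_LOF_early_clone = list(
      desc = "BMP pathway disruption before Mid repression: early and late signal off in a large clone spanning roof and anterior",
      perturb = list(cl("early_BMP", 0L, "roofspan"), cl("Dpp", 0L, "roofspan"))),
    BMP_LOF_late_clone = list(
      desc = "BMP pathway disruption after Mid repression (only the late Dpp input off, anterior clone)",
      perturb = list(cl("Dpp", 0L, "anterior"))),
    BMP_GOF_clone = list(
      desc = "constitutive BMP pathway activation in a clone at the posterior border",
      perturb = list(cl("early_BMP", 1L, "boundary"), cl("Dpp", 1L, "boundary"))),
    Mid_LOF_clone = list(desc = "mid loss-of-function clone in the posterior region",
                         perturb = list(cl("Mid", 0L, "boundary"))),
    Mid_GOF_clone = list(desc = "mid gain-of-function clone in the anterior region",
                         perturb = list(cl("Mid", 1L, "roof")))
  )
}

#' Names of the bundled simulation presets
#' @export
preset_names <- function() {
  grid <- hex_grid(24, 40)
  c(names(.preset_registry()), names(.clone_registry(.clone_sites(grid))))
}

#' Retrieve a bundled scenario preset
#'
#' Presets cover the wild type, the input overexpression series (mild/strong
#' dpp, grk, and their combinations), whole-epithelium loss/gain of function
#' for the six core components and the juxtacrine signal X, the
#' early-versus-late BMP disruption clones, and clonal perturbations.
#'
#' @param name preset name, see [preset_names()].
#' @param grid a `hex_grid` (clone masks are placed relative to it).
#' @return a scenario: list with `name`, `desc`, `grid`, `params`,
#'   `fields` (input fields), `perturbations`.
#' @export
preset_scenario <- function(name, grid = hex_grid(24, 40)) {
  reg <- c(.preset_registry(), .clone_registry(.clone_sites(grid)))
  if (!name %in% names(reg)) {
    stop("unknown preset '", name, "'; see preset_names()")
  }
  entry <- reg[[name]]
  params <- wildtype_params(grid)
  if (!is.null(entry$params)) params <- entry$params(params, grid)
  fields <- wildtype_inputs(grid, params, require_all_regions = FALSE)
  if (!is.null(entry$fields)) fields <- entry$fields(fields, grid)
  list(name = name, desc = entry$desc, grid = grid, params = params,
       fields = fields,
       perturbations = if (is.null(entry$perturb)) list() else entry$perturb)
}

#' Run a scenario through the full phase schedule
#'
#' Phase 0 (anterior specification): only the early signal fields are
#' applied and the epithelium relaxes, which establishes and freezes the
#' posterior Mid domain. Phase 1: the late Grk and Dpp patterns are applied
#' and the epithelium is iterated to its attractor. Phase 2: the Grk field
#' is extinguished grid-wide and the simulation resumes to the final
#' attractor.
#'
#' @param scenario a scenario from [preset_scenario()], or a preset name.
#' @param grid grid used when `scenario` is a name.
#' @param max_ticks per-phase tick cap.
#' @param record_every optionally record level snapshots every so many ticks.
#' @return list with elements `scenario`, `fields`, `pre` and `post` (each a
#'   [run_to_attractor()] result), and `epi0` (end of phase 0).
#' @export
run_scenario <- function(scenario, grid = hex_grid(24, 40), max_ticks = 200L,
                         record_every = NULL) {
  if (is.character(scenario)) scenario <- preset_scenario(scenario, grid)
  model <- eggshell_model("mechanistic")
  g <- scenario$grid
  f <- scenario$fields

  epi <- new_epithelium(model, g,
                        inputs = f[c("early_EGF", "early_BMP")],
                        perturbations = scenario$perturbations)
  r0 <- run_to_attractor(epi, max_ticks = max_ticks)
  epi <- r0$epi

  epi$levels$Grk <- f$Grk
  epi$levels$Dpp <- f$Dpp
  epi$phase <- 1L
  epi <- enforce_perturbations(epi)
  pre <- run_to_attractor(epi, max_ticks = max_ticks,
                          record_every = record_every)

  epi2 <- extinguish_grk(pre$epi, check = FALSE)
  post <- run_to_attractor(epi2, max_ticks = max_ticks,
                           record_every = record_every)

  list(scenario = scenario[c("name", "desc", "params")], fields = f,
       epi0 = r0$epi, pre = pre, post = post)
}

#' Run the phenomenological model on the epithelium
#'
#' @param grid a `hex_grid`.
#' @param max_ticks tick cap.
#' @return a [run_to_attractor()] result.
#' @export
run_phenomenological <- function(grid = hex_grid(24, 40), max_ticks = 100L) {
  model <- eggshell_model("phenomenological")
  fields <- phenomenological_inputs(grid)
  epi <- new_epithelium(model, grid, inputs = fields,
                        integration = list(
                          integration_rule("Roof_adj", "Roof", 1L, "any")))
  run_to_attractor(epi, max_ticks = max_ticks)
}
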