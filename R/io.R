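# ---- File formats: level matrices, manifests, fixtures --------------------

#' Write a pattern field as a tab-separated integer matrix
#'
#' @param field integer level matrix (rows = grid rows, anterior first).
#' @param path output file.
#' @export
write_grid_tsv <- function(field, path) {
  utils::write.table(field, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a pattern field from a tab-separated integer matrix
#'
#' @param path input file.
#' @param grid optional `hex_grid`; when given, dimensions are validated.
#' @param max_level optional upper bound for level validation.
#' @return integer matrix.
#' @export
read_grid_tsv <- function(path, grid = NULL, max_level = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  if (length(unique(lengths(rows))) != 1L) {
    stop("ragged rows in grid file '", path, "'")
  }
  suppressWarnings(vals <- lapply(rows, as.integer))
  if (any(vapply(vals, anyNA, logical(1)))) {
    stop("non-integer entries in grid file '", path, "'")
  }
  m <- do.call(rbind, vals)
  if (!is.null(grid) && !all(dim(m) == c(grid$n_rows, grid$n_cols))) {
    stop("grid file is ", nrow(m), "x", ncol(m), ", expected ",
         grid$n_rows, "x", grid$n_cols)
  }
  if (any(m < 0L) || (!is.null(max_level) && any(m > max_level))) {
    stop("levels outside 0..", max_level, " in grid file '", path, "'")
  }
  m
}

# small FNV-1a content hash (hex string); used for run manifests
content_hash <- function(x) {
  if (!is.character(x)) x <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run manifest for a completed simulation
#'
#' A small JSON-serialisable record sufficient to reproduce a run: content
#' hashes of the model and scenario, grid shape, per-phase tick counts and
#' outcomes, attractor period, and the package version.
#'
#' @param result output of [run_scenario()].
#' @param model the `logical_model` used.
#' @param seed RNG seed if the scenario used one (fixtures only).
#' @return a named list.
#' @export
run_manifest <- function(result, model, seed = NULL) {
  man <- list(
    schema = 1L,
    model = model$name,
    model_hash = content_hash(write_model(model)),
    scenario = result$scenario$name,
    scenario_hash = content_hash(paste(
      result$scenario$name,
      paste(deparse(result$scenario$params), collapse = ""))),
    grid = dim(result$pre$epi$levels[[1]]),
    phases = list(
      pre = list(outcome = result$pre$outcome, ticks = result$pre$ticks,
                 period = result$pre$period),
      post = list(outcome = result$post$outcome, ticks = result$post$ticks,
                  period = result$post$period)),
    version = as.character(utils::packageVersion("epilogic")))
  if (!is.null(seed)) man$seed <- seed
  man
}

#' Write simulation outputs to a directory
#'
#' One tab-separated matrix per component per recorded phase end, plus a
#' JSON run manifest.
#'
#' @param result output of [run_scenario()].
#' @param dir output directory (created if needed).
#' @param components which components to dump (default: all).
#' @return `dir`, invisibly.
#' @export
write_run <- function(result, dir, components = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (phase in c("pre", "post")) {
    lv <- result[[phase]]$epi$levels
    if (is.null(components)) components <- names(lv)
    for (nm in components) {
      write_grid_tsv(lv[[nm]], file.path(dir, paste0(phase, "_", nm, ".tsv")))
    }
  }
  model <- eggshell_model("mechanistic")
  jsonlite::write_json(run_manifest(result, model),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

# ---- Random fixtures for property tests ----------------------------------

#' Generate a random logical model
#'
#' Seeded generator of small random models for oracle-based property tests:
#' random maximum levels, random ordered clause lists built from random
#' conditions over randomly chosen regulators.
#'
#' @param n_components total number of components.
#' @param n_inputs how many of them are inputs.
#' @param max_level maximum level a component may take (each component draws
#'   its own maximum from 1..max_level).
#' @param max_clauses at most this many clauses per rule.
#' @param seed RNG seed (generation is reproducible).
#' @return a `logical_model`.
#' @export
random_model <- function(n_components = 4, n_inputs = 1, max_level = 2,
                         max_clauses = 2, seed = 1) {
  stopifnot(n_components >= 2, n_inputs >= 0, n_inputs < n_components)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nms <- paste0("V", seq_len(n_components))
  maxes <- sample(max_level, n_components, replace = TRUE)
  inputs <- seq_len(n_components) <= n_inputs

  atom <- function() {
    j <- sample(n_components, 1)
    lv <- sample(maxes[j], 1)
    if (stats::runif(1) < 0.25) paste0(nms[j], "=", lv)
    else if (lv == 1L) nms[j]
    else paste0(nms[j], ":", lv)
  }
  cond <- function() {
    k <- sample(2, 1)
    parts <- vapply(seq_len(k), function(i) {
      a <- atom()
      if (stats::runif(1) < 0.3) paste0("!", a) else a
    }, character(1))
    paste(parts, collapse = if (stats::runif(1) < 0.5) " & " else " | ")
  }
  doc <- list(schema = 1L, name = paste0("random_seed", seed),
              components = lapply(seq_len(n_components), function(j) {
                out <- list(name = nms[j], max = maxes[j])
                if (inputs[j]) out$input <- TRUE
                out
              }),
              rules = stats::setNames(lapply(which(!inputs), function(j) {
                nc <- sample(max_clauses, 1)
                tgts <- sample(maxes[j], nc, replace = TRUE)
                lapply(seq_len(nc), function(i) {
                  list(`if` = cond(), to = tgts[i])
                })
              }), nms[!inputs]))
  parse_model(yaml::as.yaml(doc))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a small toy-grid fixture
#'
#' A 5 x 8 (default) cylinder with a simple two-level gradient input field,
#' for topology and integration tests.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param seed RNG seed for the random field.
#' @return list with `grid` and `field` (random levels 0..2).
#' @export
toy_grid_fixture <- function(n_rows = 5, n_cols = 8, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  grid <- hex_grid(n_rows, n_cols)
  field <- matrix(sample(0:2, n_rows * n_cols, replace = TRUE),
                  n_rows, n_cols)
  list(grid = grid, field = field)
}
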