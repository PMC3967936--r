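# Small inline models and cached heavy runs shared across test files.

# one Boolean component negating itself: asynchronous 2-cycle
toggle_model <- function() {
  parse_model("
schema: 1
name: toggle
components:
  - {name: A, max: 1}
rules:
  A:
    - {if: '!A', to: 1}
")
}

# one Boolean component copying itself: two stable states
identity_model <- function() {
  parse_model("
schema: 1
name: identity
components:
  - {name: A, max: 1}
rules:
  A:
    - {if: 'A', to: 1}
")
}

# two independent self-maintaining switches: four stable states
two_switch_model <- function() {
  parse_model("
schema: 1
name: two_switch
components:
  - {name: A, max: 1}
  - {name: B, max: 1}
rules:
  A:
    - {if: 'A', to: 1}
  B:
    - {if: 'B', to: 1}
")
}

# a multi-valued component with delayed response, driven by an input
delayed_model <- function(delay = 2) {
  parse_model(sprintf("
schema: 1
name: delayed
components:
  - {name: In, max: 1, input: true}
  - {name: Slow, max: 2, delay: %d}
rules:
  Slow:
    - {if: 'In', to: 2}
", delay))
}

# cache expensive shared computations (one evaluation per test session)
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

wt_run <- function() cached("wt_run", run_scenario("WT"))

wt_fields <- function() cached("wt_fields", wildtype_inputs(hex_grid(24, 40)))

wt_map <- function() cached("wt_map", region_map(wt_fields()))

mech_census <- function() {
  cached("mech_census",
         enumerate_input_fates(mechanistic_single_cell(), table = fate_table()))
}

run_preset <- function(name) {
  cached(paste0("preset_", name), run_scenario(name))
}

# independent scalar-evaluation oracle for stable states: loops over every
# state and re-evaluates each rule clause by clause, without the vectorised
# batch machinery used by stable_states()
oracle_stable_states <- function(model) {
  ct <- model$components
  grids <- lapply(ct$max, function(m) 0:m)
  names(grids) <- ct$name
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  keep <- logical(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    st <- stats::setNames(as.integer(combos[i, ]), ct$name)
    vals <- as.list(st)
    for (nm in names(model$derived)) {
      vals[[nm]] <- oracle_eval_clauses(model$derived[[nm]]$clauses, vals)
    }
    ok <- TRUE
    for (nm in names(model$rules)) {
      tgt <- oracle_eval_clauses(model$rules[[nm]], vals)
      if (tgt != st[[nm]]) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- combos[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# oracle restricted to a fixed input assignment
oracle_stable_states_fixed <- function(model, fixed) {
  ct <- model$components
  grids <- lapply(seq_len(nrow(ct)), function(j) {
    if (ct$name[j] %in% names(fixed)) fixed[[ct$name[j]]] else 0:ct$max[j]
  })
  names(grids) <- ct$name
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  keep <- logical(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    st <- stats::setNames(as.integer(combos[i, ]), ct$name)
    vals <- as.list(st)
    for (nm in names(model$derived)) {
      vals[[nm]] <- oracle_eval_clauses(model$derived[[nm]]$clauses, vals)
    }
    keep[i] <- all(vapply(names(model$rules), function(nm) {
      oracle_eval_clauses(model$rules[[nm]], vals) == st[[nm]]
    }, logical(1)))
  }
  out <- combos[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_eval_clauses <- function(clauses, vals) {
  for (cl in clauses) {
    if (isTRUE(eval(cl$expr, vals, baseenv()))) return(cl$target)
  }
  0L
}

# distance-1 neighbour table and connected-patch counter for pattern tests
neighbor_index_for_test <- function(grid) {
  cached(paste0("nb1_", grid$n_rows, "_", grid$n_cols), {
    n <- n_cells(grid)
    lists <- lapply(seq_len(n), function(i) neighbors(grid, i, 1))
    width <- max(lengths(lists))
    out <- matrix(NA_integer_, n, width)
    for (i in seq_len(n)) out[i, seq_along(lists[[i]])] <- lists[[i]]
    out
  })
}

count_patches <- function(flag, nb1) {
  flag <- as.vector(flag)
  seen <- logical(length(flag))
  np <- 0L
  for (i in which(flag)) {
    if (seen[i]) next
    np <- np + 1L
    queue <- i; seen[i] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nbs <- nb1[v, ]; nbs <- nbs[!is.na(nbs)]
      nbs <- nbs[flag[nbs] & !seen[nbs]]
      seen[nbs] <- TRUE
      queue <- c(queue, nbs)
    }
  }
  np
}

# brute-force neighbourhood oracle: grow the distance-1 adjacency k times
oracle_neighbors <- function(grid, cell_idx, k) {
  adj <- function(idx) {
    co <- cell_coords(grid, idx)
    out <- integer(0)
    for (i in seq_len(nrow(co))) {
      r <- co[i, "row"]; c <- co[i, "col"]
      odd <- r %% 2L
      cand <- rbind(c(r, c - 1), c(r, c + 1),
                    c(r - 1, c - 1 + odd), c(r - 1, c + odd),
                    c(r + 1, c - 1 + odd), c(r + 1, c + odd))
      cand <- cand[cand[, 1] >= 0 & cand[, 1] < grid$n_rows, , drop = FALSE]
      cand[, 2] <- cand[, 2] %% grid$n_cols
      out <- c(out, cell_index(grid, cand[, 1], cand[, 2]))
    }
    unique(out)
  }
  reach <- cell_idx
  for (i in seq_len(k)) reach <- unique(c(reach, adj(reach)))
  sort(setdiff(reach, cell_idx))
}
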