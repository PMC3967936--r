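# ---- Rule evaluation ----------------------------------------------------
#
# All evaluation is array-based: a "value set" is a named list binding every
# component to an integer array, and every array has the same shape (length-1
# for a single state, length-n for a batch of states, a matrix for a grid).
# Derived variables are instantaneous functions of the current values and are
# recomputed, in declaration order, before any rule is evaluated.

eval_clause_list <- function(clauses, values) {
  proto <- values[[1]]
  res <- proto
  res[] <- 0L
  undecided <- rep(TRUE, length(proto))
  for (cl in clauses) {
    cond <- eval(cl$expr, values, baseenv())
    sel <- undecided & cond
    res[sel] <- cl$target
    undecided <- undecided & !cond
    if (!any(undecided)) break
  }
  res
}

compute_derived <- function(model, values) {
  for (nm in names(model$derived)) {
    values[[nm]] <- eval_clause_list(model$derived[[nm]]$clauses, values)
  }
  values
}

#' Target levels of all regulated components
#'
#' Applies each non-input component's ordered clause list to a state (or a
#' batch of states): the target is the `to` level of the first clause whose
#' condition holds, and 0 when no clause matches. Input components keep their
#' level. Derived integration variables are recomputed from the supplied
#' values first.
#'
#' @param model a `logical_model`.
#' @param state a named integer vector (one level per component), or a named
#'   list of equal-length integer arrays for batch evaluation.
#' @return an object shaped like `state` holding target levels.
#' @export
evaluate_targets <- function(model, state) {
  vec <- !is.list(state)
  values <- if (vec) as.list(state) else state
  values <- compute_derived(model, values)
  targets <- values[model$components$name]
  for (nm in names(model$rules)) {
    targets[[nm]] <- eval_clause_list(model$rules[[nm]], values)
  }
  if (vec) {
    out <- vapply(targets, function(v) as.integer(v[1]), integer(1))
    out
  } else {
    targets
  }
}

unit_step <- function(level, target) level + sign(target - level)

# ---- States -------------------------------------------------------------

#' Construct a model state
#'
#' @param model a `logical_model`.
#' @param ... component levels by name; unnamed components default to 0.
#' @return a named integer vector with one entry per component.
#' @export
model_state <- function(model, ...) {
  lv <- stats::setNames(integer(nrow(model$components)), model$components$name)
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && !is.null(names(dots[[1]]))) {
    dots <- as.list(dots[[1]])
  }
  for (nm in names(dots)) {
    j <- match(nm, model$components$name)
    if (is.na(j)) stop("unknown component '", nm, "'")
    v <- as.integer(dots[[nm]])
    if (v < 0L || v > model$components$max[j]) {
      stop("level ", v, " out of range for '", nm, "'")
    }
    lv[nm] <- v
  }
  lv
}

validate_state <- function(model, state) {
  ct <- model$components
  if (length(state) != nrow(ct) || !all(names(state) == ct$name)) {
    stop("state must be a named vector over exactly the model components")
  }
  if (any(state < 0L | state > ct$max)) stop("state level out of range")
  invisible(TRUE)
}

#' Synchronous successor state
#'
#' All regulated components whose target differs from their level move one
#' unit toward the target (unit-step semantics). Priority classes update in
#' order within the tick: later classes see the levels already updated by
#' earlier classes, while derived integration variables are computed once
#' from the entering state and held fixed for the whole tick. Components with
#' a declared delay move only after their target has pointed the same way for
#' `delay` consecutive ticks (tracked in the `delay_counters` attribute).
#'
#' @param model a `logical_model`.
#' @param state named integer vector, optionally carrying a `delay_counters`
#'   attribute from a previous call.
#' @return the successor state (with updated `delay_counters` when the model
#'   has delayed components).
#' @export
successor_synchronous <- function(model, state) {
  validate_state(model, state)
  values <- compute_derived(model, as.list(state))
  delayed <- delayed_components(model)
  counters <- attr(state, "delay_counters")
  if (length(delayed) && is.null(counters)) {
    counters <- list(count = stats::setNames(integer(length(delayed)), delayed),
                     dir = stats::setNames(integer(length(delayed)), delayed))
  }
  out <- state
  for (class_comps in model$priorities) {
    # evaluate this class against current values (earlier classes applied)
    for (nm in class_comps) {
      tgt <- as.integer(eval_clause_list(model$rules[[nm]], values)[1])
      cur <- as.integer(values[[nm]][1])
      dir <- sign(tgt - cur)
      if (nm %in% delayed) {
        d <- model$components$delay[match(nm, model$components$name)]
        if (dir == 0L) {
          counters$count[nm] <- 0L
          counters$dir[nm] <- 0L
        } else if (dir != counters$dir[nm]) {
          counters$dir[nm] <- dir
          counters$count[nm] <- 1L
          dir <- 0L                       # reversal: restart the clock
        } else if (counters$count[nm] < d) {
          counters$count[nm] <- counters$count[nm] + 1L
          dir <- 0L                       # still waiting
        }
      }
      out[nm] <- cur + dir
    }
    for (nm in class_comps) values[[nm]][] <- out[nm]
  }
  attributes(out) <- attributes(state)[setdiff(names(attributes(state)), "delay_counters")]
  names(out) <- names(state)
  if (length(delayed)) attr(out, "delay_counters") <- counters
  out
}

#' Asynchronous successor states
#'
#' One successor per regulated component whose target differs from its level;
#' each successor moves that single component one unit toward its target. A
#' stable state has no successors. Components listed in `slow` form a lower
#' priority class: they are allowed to update only when no other component is
#' unstable (the asynchronous realisation of a slow synthesis/activation).
#'
#' @param model a `logical_model`.
#' @param state named integer vector.
#' @param slow character vector of component names updating at lower priority.
#' @return a list of successor states (possibly empty).
#' @export
successors_asynchronous <- function(model, state, slow = character()) {
  validate_state(model, state)
  tgt <- evaluate_targets(model, state)
  internals <- model_internals(model)
  unstable <- internals[tgt[internals] != state[internals]]
  if (length(slow)) {
    fast <- setdiff(unstable, slow)
    if (length(fast)) unstable <- fast
  }
  lapply(unstable, function(nm) {
    s2 <- state
    s2[nm] <- unit_step(state[nm], tgt[nm])
    s2
  })
}

# ---- State-space enumeration -------------------------------------------

# mixed-radix encoding over the given components (first component = least
# significant digit); codes are doubles, valid well beyond 2^31 states.
state_codec <- function(maxes) {
  radix <- maxes + 1
  mult <- cumprod(c(1, radix[-length(radix)]))
  list(radix = radix, mult = mult, n = prod(radix))
}

encode_states <- function(codec, mat) as.vector(mat %*% codec$mult)

decode_states <- function(codec, codes) {
  k <- length(codec$radix)
  out <- matrix(0L, nrow = length(codes), ncol = k)
  rem <- codes
  for (j in seq_len(k)) {
    out[, j] <- as.integer(rem %% codec$radix[j])
    rem <- (rem - out[, j]) %/% codec$radix[j]
  }
  out
}

#' Enumerate all states of a model
#'
#' @param model a `logical_model`.
#' @param fixed named integer vector of components pinned to a level
#'   (typically the inputs).
#' @param cap refuse enumeration above this many states.
#' @return a data.frame with one column per component and one row per state.
#' @export
state_space <- function(model, fixed = NULL, cap = 1e7) {
  ct <- model$components
  free <- setdiff(ct$name, names(fixed))
  n <- prod(ct$max[match(free, ct$name)] + 1)
  if (n > cap) {
    stop("state space has ", format(n, big.mark = ","),
         " states, above the cap of ", format(cap, big.mark = ","))
  }
  codec <- state_codec(ct$max[match(free, ct$name)])
  mat <- decode_states(codec, seq_len(codec$n) - 1)
  colnames(mat) <- free
  df <- as.data.frame(mat)
  for (nm in names(fixed)) df[[nm]] <- as.integer(fixed[[nm]])
  df[, ct$name, drop = FALSE]
}

#' All stable states of a model
#'
#' Exhaustively enumerates the state space (restricted by `fixed_inputs`) and
#' returns the states in which every regulated component's target equals its
#' current level. Enumeration order (and hence row order) is lexicographic by
#' component declaration order.
#'
#' @param model a `logical_model`.
#' @param fixed_inputs named integer vector assigning levels to a subset of
#'   the input components; unassigned inputs are enumerated over their range.
#' @param cap refuse enumeration above this many states (default 1e7).
#' @return a data.frame of stable states (one column per component).
#' @export
stable_states <- function(model, fixed_inputs = NULL, cap = 1e7) {
  if (!is.null(fixed_inputs)) {
    bad <- setdiff(names(fixed_inputs), model_inputs(model))
    if (length(bad)) stop("fixed_inputs names non-input component: ", bad[1])
  }
  df <- state_space(model, fixed = fixed_inputs, cap = cap)
  values <- lapply(df, as.integer)
  targets <- evaluate_targets(model, values)
  ok <- rep(TRUE, nrow(df))
  for (nm in model_internals(model)) ok <- ok & (targets[[nm]] == values[[nm]])
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Is a state stable?
#' @param model a `logical_model`.
#' @param state named integer vector.
#' @export
is_stable <- function(model, state) {
  tgt <- evaluate_targets(model, state)
  internals <- model_internals(model)
  all(tgt[internals] == state[internals])
}
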