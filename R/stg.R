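# ---- State transition graphs -------------------------------------------

# Vectorised successor computation on encoded states. `codes` are mixed-radix
# encodings of the regulated components; inputs are held at `fixed_inputs`.
.successor_codes <- function(model, codec, internals, fixed_inputs, codes,
                             scheme, slow = character()) {
  n <- length(codes)
  mat <- decode_states(codec, codes)
  colnames(mat) <- internals
  values <- lapply(seq_along(internals), function(j) mat[, j])
  names(values) <- internals
  for (nm in names(fixed_inputs)) {
    values[[nm]] <- rep(as.integer(fixed_inputs[[nm]]), n)
  }
  values <- values[model$components$name]

  if (scheme == "sync") {
    # derived integration variables are computed once from the entering
    # state and held fixed across the priority stages of the tick
    vals <- compute_derived(model, values)
    nxt <- mat
    for (class_comps in model$priorities) {
      for (nm in class_comps) {
        tgt <- eval_clause_list(model$rules[[nm]], vals)
        nxt[, nm] <- unit_step(vals[[nm]], tgt)
      }
      for (nm in class_comps) vals[[nm]] <- nxt[, nm]
    }
    to <- encode_states(codec, nxt)
    keep <- to != codes
    return(list(from = codes[keep], to = to[keep]))
  }

  targets <- evaluate_targets(model, values)
  dirs <- lapply(internals, function(nm) sign(targets[[nm]] - values[[nm]]))
  names(dirs) <- internals
  if (length(slow)) {
    fast <- setdiff(internals, slow)
    fast_unstable <- rep(FALSE, n)
    for (nm in fast) fast_unstable <- fast_unstable | dirs[[nm]] != 0
    for (nm in intersect(slow, internals)) {
      dirs[[nm]][fast_unstable] <- 0L
    }
  }
  from <- numeric(0); to <- numeric(0)
  for (j in seq_along(internals)) {
    d <- dirs[[internals[j]]]
    sel <- d != 0
    if (any(sel)) {
      from <- c(from, codes[sel])
      to <- c(to, codes[sel] + d[sel] * codec$mult[j])
    }
  }
  list(from = from, to = to)
}

#' Build a state transition graph
#'
#' Nodes are the states of the model restricted to a full input assignment;
#' edges follow the chosen update scheme (asynchronous: one edge per unstable
#' component; synchronous: the unique staged-priority successor). With
#' `initial` the graph is restricted to the states reachable from it.
#'
#' @param model a `logical_model`.
#' @param fixed_inputs named integer vector assigning every input component.
#' @param initial optional initial state (named vector); `NULL` enumerates the
#'   full restricted space.
#' @param scheme `"async"` or `"sync"`.
#' @param slow components updating only when nothing else can (async only).
#' @param cap refuse spaces larger than this.
#' @return an object of class `stg` with fields `states` (data.frame),
#'   `from`/`to` (edge indices), `codes`, `scheme`.
#' @export
build_stg <- function(model, fixed_inputs, initial = NULL,
                      scheme = c("async", "sync"), slow = character(),
                      cap = 1e7) {
  scheme <- match.arg(scheme)
  inputs <- model_inputs(model)
  if (length(setdiff(inputs, names(fixed_inputs)))) {
    stop("fixed_inputs must assign every input component")
  }
  internals <- model_internals(model)
  ct <- model$components
  codec <- state_codec(ct$max[match(internals, ct$name)])
  if (codec$n > cap) stop("state space above cap")

  if (is.null(initial)) {
    codes <- seq_len(codec$n) - 1
    e <- .successor_codes(model, codec, internals, fixed_inputs, codes,
                          scheme, slow)
  } else {
    init_code <- encode_states(codec, matrix(as.integer(initial[internals]),
                                             nrow = 1))
    known <- init_code
    frontier <- init_code
    from <- numeric(0); to <- numeric(0)
    while (length(frontier)) {
      e <- .successor_codes(model, codec, internals, fixed_inputs, frontier,
                            scheme, slow)
      from <- c(from, e$from); to <- c(to, e$to)
      fresh <- setdiff(unique(e$to), known)
      known <- c(known, fresh)
      frontier <- fresh
    }
    codes <- sort(known)
    e <- list(from = from, to = to)
  }

  idx_from <- match(e$from, codes)
  idx_to <- match(e$to, codes)
  states <- decode_states(codec, codes)
  colnames(states) <- internals
  states <- as.data.frame(states)
  for (nm in inputs) states[[nm]] <- as.integer(fixed_inputs[[nm]])
  structure(list(states = states[, ct$name, drop = FALSE], codes = codes,
                 from = idx_from, to = idx_to, scheme = scheme,
                 internals = internals, fixed_inputs = fixed_inputs,
                 model_name = model$name),
            class = "stg")
}

#' @export
print.stg <- function(x, ...) {
  cat("State transition graph (", x$scheme, "): ", nrow(x$states),
      " states, ", length(x$from), " transitions\n", sep = "")
  invisible(x)
}

# ---- Strongly connected components --------------------------------------

# Iterative Tarjan SCC (explicit stack, no recursion), returning a component
# id per node. Robust on graphs of 1e4-1e5 nodes where recursive descent
# would overflow R's call stack.
tarjan_scc <- function(n, from, to) {
  ord <- order(from)
  from_s <- from[ord]; to_s <- to[ord]
  ptr <- c(0L, cumsum(tabulate(from_s, nbins = n))) # CSR offsets
  index <- integer(n); low <- integer(n)
  index[] <- NA_integer_
  onstack <- logical(n)
  comp <- integer(n); comp[] <- NA_integer_
  stack <- integer(0)
  counter <- 0L; ncomp <- 0L

  # explicit DFS state: node and position in its edge list
  for (root in seq_len(n)) {
    if (!is.na(index[root])) next
    dfs_node <- root
    dfs_edge <- ptr[root]
    node_st <- integer(0); edge_st <- integer(0)
    counter <- counter + 1L
    index[root] <- counter; low[root] <- counter
    stack <- c(stack, root); onstack[root] <- TRUE
    repeat {
      if (dfs_edge < ptr[dfs_node + 1L]) {
        dfs_edge <- dfs_edge + 1L
        w <- to_s[dfs_edge]
        if (is.na(index[w])) {
          node_st <- c(node_st, dfs_node); edge_st <- c(edge_st, dfs_edge)
          dfs_node <- w; dfs_edge <- ptr[w]
          counter <- counter + 1L
          index[w] <- counter; low[w] <- counter
          stack <- c(stack, w); onstack[w] <- TRUE
        } else if (onstack[w]) {
          low[dfs_node] <- min(low[dfs_node], index[w])
        }
      } else {
        if (low[dfs_node] == index[dfs_node]) {
          ncomp <- ncomp + 1L
          repeat {
            w <- stack[length(stack)]
            stack <- stack[-length(stack)]
            onstack[w] <- FALSE
            comp[w] <- ncomp
            if (w == dfs_node) break
          }
        }
        if (!length(node_st)) break
        parent <- node_st[length(node_st)]
        node_st <- node_st[-length(node_st)]
        pedge <- edge_st[length(edge_st)]
        edge_st <- edge_st[-length(edge_st)]
        low[parent] <- min(low[parent], low[dfs_node])
        dfs_node <- parent; dfs_edge <- pedge
      }
    }
  }
  comp
}

#' Attractors of a state transition graph
#'
#' Attractors are the terminal strongly connected components of the graph:
#' singleton components with no outgoing edge are fixed points (stable
#' states), larger ones are cyclic attractors.
#'
#' @param stg an `stg` object from [build_stg()].
#' @return a list of attractors; each has `kind` (`"fixed_point"` or
#'   `"cyclic"`) and `states` (data.frame of member states).
#' @export
attractors <- function(stg) {
  n <- nrow(stg$states)
  if (!length(stg$from)) {
    comp <- seq_len(n)
  } else {
    comp <- tarjan_scc(n, stg$from, stg$to)
  }
  # terminal components: no edge leaving the component
  leaving <- unique(comp[stg$from][comp[stg$from] != comp[stg$to]])
  terminal <- setdiff(unique(comp), leaving)
  out <- lapply(terminal, function(cid) {
    members <- which(comp == cid)
    # a singleton SCC is an attractor only if it has no outgoing edge at all
    # (a self-loop-free singleton with an exit is transient, but terminal
    # singletons by construction have no exits, hence are stable states)
    st <- stg$states[members, , drop = FALSE]
    rownames(st) <- NULL
    list(kind = if (length(members) == 1L) "fixed_point" else "cyclic",
         states = st,
         codes = sort(stg$codes[members]))
  })
  # canonical order: by smallest member code
  out[order(vapply(out, function(a) a$codes[1], numeric(1)))]
}

# canonical identity of an attractor, projected on the internal components
attractor_key <- function(att, internals) {
  sig <- att$states[, internals, drop = FALSE]
  rows <- apply(as.matrix(sig), 1, paste, collapse = ",")
  paste(sort(unique(rows)), collapse = ";")
}

# ---- Fate classification -------------------------------------------------

#' Read the bundled fate table
#'
#' The fate table maps the expression signature of the core network
#' components (dpERK, Mirr, Pnt, Rho, Aos, Br) to the named cell fates
#' F1..F8 used throughout the eggshell analyses.
#'
#' @param path optional path to a tab-separated fate table; defaults to the
#'   table bundled with the package.
#' @return a data.frame with a `fate` column plus one column per component.
#' @export
fate_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fate_table.tsv", package = "epilogic")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  sig <- tab[, setdiff(names(tab), c("fate", "description")), drop = FALSE]
  if (anyDuplicated(apply(sig, 1, paste, collapse = ","))) {
    stop("fate table signatures are not pairwise distinct")
  }
  tab
}

#' Classify states against a fate table
#'
#' @param states a data.frame of states (or a single named vector).
#' @param table a fate table (see [fate_table()]).
#' @return character vector of fate labels; unmatched signatures are `"other"`.
#' @export
classify_fates <- function(states, table) {
  if (!is.data.frame(states)) states <- as.data.frame(as.list(states))
  comps <- setdiff(names(table), c("fate", "description"))
  key <- apply(as.matrix(table[, comps, drop = FALSE]), 1, paste, collapse = ",")
  skey <- apply(as.matrix(states[, comps, drop = FALSE]), 1, paste, collapse = ",")
  lab <- table$fate[match(skey, key)]
  lab[is.na(lab)] <- "other"
  lab
}

#' Fates reachable from an initial state
#'
#' Builds the asynchronous state transition graph from `initial`, finds its
#' attractors, and labels them: fixed points through the fate table, cyclic
#' attractors as `"cyclic"`.
#'
#' @inheritParams build_stg
#' @param initial named state vector.
#' @param table fate table for labelling stable states.
#' @return list with `fates` (sorted unique labels), `attractors`.
#' @export
reachable_fates <- function(model, fixed_inputs, initial, table,
                            slow = character()) {
  stg <- build_stg(model, fixed_inputs, initial = initial, scheme = "async",
                   slow = slow)
  atts <- attractors(stg)
  labs <- vapply(atts, function(a) {
    if (a$kind == "cyclic") "cyclic" else classify_fates(a$states, table)
  }, character(1))
  list(fates = sort(unique(labs)), attractors = atts, labels = labs)
}

# ---- Input-combination census -------------------------------------------

#' Attractor census over all input combinations
#'
#' Enumerates every combination of input levels, builds the full asynchronous
#' state transition graph for each, and collects its attractors. The census
#' reports, per combination, the stable fates and the number of cyclic
#' attractors, plus the global tallies of distinct stable fates and distinct
#' cyclic attractors (both compared on the internal components only).
#'
#' @param model a `logical_model`.
#' @param table optional fate table for labelling stable states.
#' @param slow components at lower asynchronous priority.
#' @param cap per-combination state-space cap.
#' @return list with `table` (one row per input combination),
#'   `stable_signatures` (distinct stable internal states, canonically
#'   ordered), `cyclic_keys`, `n_stable`, `n_cyclic`.
#' @export
enumerate_input_fates <- function(model, table = NULL, slow = character(),
                                  cap = 1e7) {
  inputs <- model_inputs(model)
  ct <- model$components
  ranges <- lapply(inputs, function(nm) 0:ct$max[match(nm, ct$name)])
  names(ranges) <- inputs
  combos <- expand.grid(ranges, KEEP.OUT.ATTRS = FALSE)
  internals <- model_internals(model)

  sig_seen <- character(0)
  sig_states <- list()
  cyc_seen <- character(0)
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    fx <- stats::setNames(as.integer(combos[i, ]), inputs)
    stg <- build_stg(model, fx, scheme = "async", slow = slow, cap = cap)
    atts <- attractors(stg)
    stable <- atts[vapply(atts, function(a) a$kind == "fixed_point", logical(1))]
    cyc <- atts[vapply(atts, function(a) a$kind == "cyclic", logical(1))]
    skeys <- vapply(stable, attractor_key, character(1), internals = internals)
    for (j in seq_along(skeys)) {
      if (!(skeys[j] %in% sig_seen)) {
        sig_seen <- c(sig_seen, skeys[j])
        sig_states[[skeys[j]]] <- stable[[j]]$states[, internals, drop = FALSE]
      }
    }
    ckeys <- vapply(cyc, attractor_key, character(1), internals = internals)
    cyc_seen <- unique(c(cyc_seen, ckeys))
    lab <- if (is.null(table)) {
      vapply(stable, attractor_key, character(1), internals = internals)
    } else {
      vapply(stable, function(a) classify_fates(a$states, table), character(1))
    }
    rows[[i]] <- data.frame(combos[i, , drop = FALSE],
                            stable_fates = paste(sort(lab), collapse = ","),
                            n_stable = length(stable),
                            n_cyclic = length(cyc),
                            stringsAsFactors = FALSE)
  }
  sigs <- do.call(rbind, sig_states[sort(sig_seen)])
  rownames(sigs) <- NULL
  list(table = do.call(rbind, rows),
       stable_signatures = sigs,
       cyclic_keys = sort(cyc_seen),
       n_stable = length(sig_seen),
       n_cyclic = length(cyc_seen))
}
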