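test_that("a self-negating switch gives a two-state cyclic attractor", {
  m <- toggle_model()
  stg <- build_stg(m, fixed_inputs = stats::setNames(integer(0), character(0)))
  expect_equal(nrow(stg$states), 2L)
  expect_equal(length(stg$from), 2L)
  atts <- attractors(stg)
  expect_length(atts, 1L)
  expect_equal(atts[[1]]$kind, "cyclic")
  expect_equal(nrow(atts[[1]]$states), 2L)
})

test_that("independent switches give one fixed point per stable state", {
  m <- two_switch_model()
  stg <- build_stg(m, fixed_inputs = stats::setNames(integer(0), character(0)))
  atts <- attractors(stg)
  expect_length(atts, 4L)
  expect_true(all(vapply(atts, function(a) a$kind, "") == "fixed_point"))
})

test_that("a stable initial state yields a single-node graph", {
  m <- eggshell_model("phenomenological")
  fx <- c(EGF = 1L, BMP = 0L, anterior = 1L, Roof_adj = 0L)
  ss <- stable_states(m, fixed_inputs = fx)
  s <- model_state(m, stats::setNames(as.integer(ss[1, ]), names(ss)))
  stg <- build_stg(m, fx, initial = s)
  expect_equal(nrow(stg$states), 1L)
  expect_length(stg$from, 0L)
})

test_that("asynchronous STG edges match per-state successor recomputation", {
  sc <- mechanistic_single_cell()
  fx <- c(Grk = 3L, Dpp = 1L, Aos_ext = 2L, Rho_ext = 2L, Br_adj = 0L,
          Mid = 0L)  # anterior-band (R1-like) inputs
  naive <- model_state(sc, fx)
  stg <- build_stg(sc, fx, initial = naive)
  internals <- model_internals(sc)
  for (i in seq_len(nrow(stg$states))) {
    s <- model_state(sc, stats::setNames(as.integer(stg$states[i, ]),
                                         names(stg$states)))
    succ <- successors_asynchronous(sc, s)
    want <- sort(vapply(succ, function(x) paste(x[internals], collapse = ","),
                        character(1)))
    got <- sort(apply(stg$states[stg$to[stg$from == i], internals,
                                 drop = FALSE], 1, paste, collapse = ","))
    expect_equal(unname(got), unname(want))
  }
})

test_that("terminal SCCs match an independent graph-library oracle", {
  sc <- mechanistic_single_cell()
  combos <- list(
    c(Grk = 1L, Dpp = 0L, Aos_ext = 1L, Rho_ext = 2L, Br_adj = 0L, Mid = 0L),
    c(Grk = 2L, Dpp = 1L, Aos_ext = 1L, Rho_ext = 2L, Br_adj = 0L, Mid = 0L),
    c(Grk = 2L, Dpp = 0L, Aos_ext = 2L, Rho_ext = 0L, Br_adj = 1L, Mid = 0L),
    c(Grk = 0L, Dpp = 0L, Aos_ext = 0L, Rho_ext = 0L, Br_adj = 0L, Mid = 1L))
  for (fx in combos) {
    stg <- build_stg(sc, fx)
    atts <- attractors(stg)
    g <- igraph::graph_from_edgelist(cbind(stg$from, stg$to))
    g <- igraph::add_vertices(g, max(0, nrow(stg$states) - igraph::vcount(g)))
    comp <- igraph::components(g, mode = "strong")$membership
    cross <- comp[stg$from] != comp[stg$to]
    terminal <- setdiff(unique(comp), unique(comp[stg$from][cross]))
    want <- sort(vapply(terminal, function(cid) {
      paste(sort(stg$codes[comp == cid]), collapse = ";")
    }, character(1)))
    got <- sort(vapply(atts, function(a) paste(a$codes, collapse = ";"),
                       character(1)))
    expect_equal(got, want)
  }
})

test_that("attractors are invariant under random node reordering", {
  m <- toggle_model()
  # permuting the edge list must not change the attractor set
  stg <- build_stg(m, fixed_inputs = stats::setNames(integer(0), character(0)))
  perm <- rev(seq_along(stg$from))
  stg2 <- stg
  stg2$from <- stg$from[perm]; stg2$to <- stg$to[perm]
  expect_equal(attractors(stg2), attractors(stg))
})

test_that("fate classification is total with an explicit 'other' label", {
  tab <- fate_table()
  sig <- tab[3, setdiff(names(tab), c("fate", "description"))]
  expect_equal(classify_fates(sig, tab), tab$fate[3])
  odd <- sig; odd$dpERK <- 2; odd$Br <- 1; odd$Pnt <- 1; odd$Mirr <- 1
  expect_equal(classify_fates(odd, tab), "other")
})
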