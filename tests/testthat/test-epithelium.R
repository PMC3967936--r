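make_epi <- function(grid = hex_grid(5, 8), inputs = list(), perturbations = list()) {
  new_epithelium(eggshell_model("mechanistic"), grid, inputs = inputs,
                 perturbations = perturbations)
}

test_that("juxtacrine X fires in non-roof cells touching one roof cell", {
  grid <- hex_grid(5, 8)
  epi <- make_epi(grid)
  epi$levels$Br[cell_index(grid, 2, 3)] <- 1L
  epi <- compute_integration(epi)
  x <- epi$derived$X
  nb <- neighbors(grid, c(2, 3), 1)
  expect_true(all(x[nb] == 1L))            # every neighbour sees the roof cell
  expect_equal(x[cell_index(grid, 2, 3)], 0L)  # the roof cell itself never
  far <- cell_index(grid, 0, 7)
  expect_equal(x[far], 0L)
})

test_that("a cell with Br on has X = 0 regardless of its neighbours", {
  grid <- hex_grid(5, 8)
  epi <- make_epi(grid)
  epi$levels$Br[] <- 1L
  epi <- compute_integration(epi)
  expect_true(all(epi$derived$X == 0L))
})

test_that("an isolated cell sees zero extracellular signal", {
  epi <- make_epi()
  epi <- compute_integration(epi)
  expect_true(all(epi$levels$Rho_ext == 0L))
  expect_true(all(epi$levels$Aos_ext == 0L))
  expect_true(all(epi$levels$Br_adj == 0L))
})

test_that("extracellular fields threshold neighbour counts", {
  grid <- hex_grid(5, 8)
  epi <- make_epi(grid)
  ctr <- cell_index(grid, 2, 3)
  nb1 <- neighbors(grid, c(2, 3), 1)
  # one weak Rho neighbour -> level 1; few strong ones stay level 1 until
  # the high-count threshold is reached
  epi$levels$Rho[nb1[1]] <- 1L
  epi <- compute_integration(epi)
  expect_equal(epi$levels$Rho_ext[ctr], 1L)
  epi$levels$Rho[nb1[1:4]] <- 2L
  epi <- compute_integration(epi)
  expect_equal(epi$levels$Rho_ext[ctr], 1L)
  epi$levels$Rho[nb1[1:5]] <- 2L
  epi <- compute_integration(epi)
  expect_equal(epi$levels$Rho_ext[ctr], 2L)
  # Aos_ext: 1 cell in range 3 -> level 1; 4 cells -> level 2
  epi2 <- make_epi(grid)
  nb3 <- neighbors(grid, c(2, 3), 3)
  epi2$levels$Aos[nb3[1]] <- 1L
  epi2 <- compute_integration(epi2)
  expect_equal(epi2$levels$Aos_ext[ctr], 1L)
  epi2$levels$Aos[nb3[1:4]] <- 1L
  epi2 <- compute_integration(epi2)
  expect_equal(epi2$levels$Aos_ext[ctr], 2L)
})

test_that("an all-zero epithelium is an immediate fixed point", {
  epi <- make_epi()
  r <- run_to_attractor(epi, max_ticks = 5)
  expect_equal(r$outcome, "fixed_point")
  expect_equal(r$ticks, 1L)
})

test_that("stepping a converged configuration changes nothing", {
  res <- wt_run()
  epi <- res$post$epi
  epi2 <- step(epi)
  expect_equal(epi2$levels, epi$levels)
})

test_that("the staged update order matters", {
  # moving dpERK out of its early priority class changes the trajectory on a
  # small fixture with a steep Grk border
  grid <- hex_grid(5, 8)
  grk <- matrix(0L, 5, 8); grk[2:4, 3:5] <- 3L
  model_fast <- eggshell_model("mechanistic")
  model_flat <- model_fast
  model_flat$priorities <- list(model_internals(model_flat))
  run3 <- function(model) {
    epi <- new_epithelium(model, grid, inputs = list(Grk = grk))
    traj <- list()
    for (i in 1:4) { epi <- step(epi); traj[[i]] <- epi$levels }
    traj
  }
  t_fast <- run3(model_fast)
  t_flat <- run3(model_flat)
  expect_false(identical(t_fast, t_flat))
})

test_that("perturbations clamp and truncate, and clamping the status quo is inert", {
  grid <- hex_grid(5, 8)
  grk <- matrix(2L, 5, 8)
  # clamping a component at its resting level leaves the dynamics unchanged
  epi_ref <- make_epi(grid, inputs = list(Grk = grk))
  epi_cl <- make_epi(grid, inputs = list(Grk = grk),
                     perturbations = list(perturbation("Mid", "clamp", value = 0L)))
  r_ref <- run_to_attractor(epi_ref, 50)
  r_cl <- run_to_attractor(epi_cl, 50)
  expect_equal(r_cl$epi$levels, r_ref$epi$levels)
  # range restriction truncates targets to the nearest bound
  epi_rg <- make_epi(grid, inputs = list(Grk = grk),
                     perturbations = list(perturbation("dpERK", "range",
                                                       min = 0L, max = 1L)))
  r_rg <- run_to_attractor(epi_rg, 50)
  expect_true(all(r_rg$epi$levels$dpERK <= 1L))
  expect_true(any(r_rg$epi$levels$dpERK == 1L))
})

test_that("contradictory overlapping clamps are rejected", {
  grid <- hex_grid(5, 8)
  epi <- make_epi(grid,
                  perturbations = list(perturbation("Br", "clamp", value = 1L,
                                                    mask = 1:5)))
  expect_error(apply_perturbation(epi, perturbation("Br", "clamp", value = 0L,
                                                    mask = 4:8)),
               "contradictory")
})

test_that("signal extinction zeroes the field, keeps cell states, and is idempotent", {
  res <- wt_run()
  epi <- res$pre$epi
  post <- extinguish_grk(epi)
  expect_true(all(post$levels$Grk == 0L))
  for (nm in model_internals(epi$model)) {
    expect_equal(post$levels[[nm]], epi$levels[[nm]])
  }
  expect_equal(post$phase, epi$phase + 1L)
  post2 <- extinguish_grk(post, check = FALSE)
  expect_true(all(post2$levels$Grk == 0L))
  # warning when extinguishing before convergence
  fresh <- make_epi()
  expect_warning(extinguish_grk(fresh), "before")
})

test_that("cycle detection distinguishes delay-counter states", {
  # a delayed component about to move is not the same configuration as one
  # freshly exposed: hashing must include the counters
  m <- delayed_model(delay = 2)
  grid <- hex_grid(2, 2)
  epi <- new_epithelium(m, grid, inputs = list(In = matrix(1L, 2, 2)),
                        integration = NULL)
  r <- run_to_attractor(epi, 10)
  expect_equal(r$outcome, "fixed_point")
  expect_true(all(r$epi$levels$Slow == 2L))
  expect_gte(r$ticks, 4L)  # 2 waiting ticks + 2 unit steps
})
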