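# In-silico mutant and clone suite: each block asserts the qualitative
# outcome the corresponding experiment (or the model's documented behaviour)
# shows, by comparison with the cached wild-type run.

test_that("Aos loss blocks the post-extinction splitting but spares Br", {
  res <- run_preset("Aos_LOF")
  wt <- wt_run()
  expect_equal(res$post$epi$levels$Br, wt$post$epi$levels$Br)
  # wild type: the high-EGF-activity domain shrinks after extinction (the
  # operculum interior shuts off: splitting)
  expect_lt(sum(wt$post$epi$levels$dpERK == 2),
            sum(wt$pre$epi$levels$dpERK == 2))
  # Aos LOF: within the competence region the high-activity domain persists
  # unchanged after extinction (the posterior Mid-domain activity is lost in
  # either genotype once its ligand is gone)
  comp <- res$fields$Mid == 0
  expect_equal(res$post$epi$levels$dpERK == 2 & comp,
               res$pre$epi$levels$dpERK == 2 & comp)
  expect_gt(sum(res$post$epi$levels$dpERK == 2), 0L)
})

test_that("Aos overexpression at the endogenous level has no effect (documented failure)", {
  res <- run_preset("Aos_GOF")
  wt <- wt_run()
  expect_equal(res$post$epi$levels$Br, wt$post$epi$levels$Br)
  expect_equal(res$post$epi$levels$Rho, wt$post$epi$levels$Rho)
})

test_that("strong late dpp overexpression abolishes Br (thin experimental band not reproduced)", {
  res <- run_preset("CY2_dpp")
  expect_equal(sum(res$pre$epi$levels$Br), 0L)
  expect_equal(sum(res$post$epi$levels$Br), 0L)
})

test_that("saturating grk abolishes Br while anterior Rho persists before extinction", {
  res <- run_preset("tub_grk")
  expect_equal(sum(res$post$epi$levels$Br), 0L)
  expect_gt(sum(res$pre$epi$levels$Rho >= 1), 0L)
})

test_that("mild dpp overexpression joins the roof patches into a horseshoe", {
  res <- run_preset("GR1_dpp")
  wt <- wt_run()
  grid <- hex_grid(24, 40)
  nb1 <- neighbor_index_for_test(grid)
  br <- res$post$epi$levels$Br > 0
  expect_equal(count_patches(br, nb1), 1L)                # joined
  expect_gt(sum(br), sum(wt$post$epi$levels$Br > 0))      # expanded
  # expansion is toward the posterior: Br rows extend beyond the wild type
  rows <- cell_coords(grid, which(br))[, "row"]
  wt_rows <- cell_coords(grid, which(wt$post$epi$levels$Br > 0))[, "row"]
  expect_gt(max(rows), max(wt_rows))
  # joined over the dorsal midline
  mid_col <- hex_grid(24, 40)$n_cols %/% 2L
  expect_true(any(br[, mid_col + 1L]))
})

test_that("removing the juxtacrine signal eliminates the post-extinction floor", {
  res <- run_preset("X_LOF")
  expect_equal(sum(res$post$epi$levels$Rho >= 2), 0L)
  # before extinction Grk still drives EGF activity, so Rho is present
  expect_gt(sum(res$pre$epi$levels$Rho >= 1), 0L)
})

test_that("constitutive juxtacrine signalling enlarges the midline-type domain at Br's expense", {
  res <- run_preset("X_GOF")
  wt <- wt_run()
  expect_lt(sum(res$post$epi$levels$Br), sum(wt$post$epi$levels$Br))
  expect_gt(sum(res$post$epi$levels$Rho >= 2),
            sum(wt$post$epi$levels$Rho >= 2))
})

test_that("whole-tissue Br loss erases the pattern after extinction", {
  res <- run_preset("Br_LOF")
  wt <- wt_run()
  # before extinction: enlarged Rho/EGF-activity domain (no Br repression)
  expect_gt(sum(res$pre$epi$levels$Rho >= 1), sum(wt$pre$epi$levels$Rho >= 1))
  # after extinction everything is lost
  for (nm in c("dpERK", "Mirr", "Pnt", "Rho", "Aos")) {
    expect_true(sum(res$post$epi$levels[[nm]]) == 0L, info = nm)
  }
})

test_that("partial EGFR loss fuses the roof domains like Pnt loss", {
  erk <- run_preset("dpERK_LOF")
  pnt <- run_preset("Pnt_LOF")
  grid <- hex_grid(24, 40)
  nb1 <- neighbor_index_for_test(grid)
  expect_equal(count_patches(erk$post$epi$levels$Br > 0, nb1), 1L)
  expect_equal(count_patches(pnt$post$epi$levels$Br > 0, nb1), 1L)
  expect_equal(erk$post$epi$levels$Br, pnt$post$epi$levels$Br)
})

test_that("constitutive EGFR activation removes Br and spreads its targets", {
  res <- run_preset("dpERK_GOF")
  wt <- wt_run()
  expect_equal(sum(res$post$epi$levels$Br), 0L)
  for (nm in c("Rho", "Mirr", "Pnt", "Aos")) {
    expect_true(sum(res$post$epi$levels[[nm]] > 0) >
                  sum(wt$post$epi$levels[[nm]] > 0), info = nm)
  }
})

test_that("Rho loss spares Br but silences the floor after extinction", {
  res <- run_preset("Rho_LOF")
  wt <- wt_run()
  expect_equal(res$post$epi$levels$Br, wt$post$epi$levels$Br)
  expect_equal(sum(res$post$epi$levels$dpERK), 0L)
})

test_that("a Br-null clone gains Rho strictly inside its own boundary", {
  res <- run_preset("clone_Br_LOF")
  wt <- wt_run()
  mask <- preset_scenario("clone_Br_LOF")$perturbations[[1]]$mask
  ectopic <- which(res$post$epi$levels$Rho > 0 & wt$post$epi$levels$Rho == 0)
  expect_gt(length(ectopic), 0L)
  expect_true(all(ectopic %in% mask))
  # and Br is lost only inside the clone
  lost <- which(res$post$epi$levels$Br == 0 & wt$post$epi$levels$Br > 0)
  expect_true(all(lost %in% mask))
})

test_that("Mid clones move the competence border cell-autonomously", {
  wt <- wt_run()
  lof <- run_preset("Mid_LOF_clone")
  mask_lof <- preset_scenario("Mid_LOF_clone")$perturbations[[1]]$mask
  gained <- which(lof$post$epi$levels$Br > 0 & wt$post$epi$levels$Br == 0)
  expect_gt(length(gained), 0L)            # anterior fates expand into the clone
  expect_true(all(gained %in% mask_lof))
  gof <- run_preset("Mid_GOF_clone")
  mask_gof <- preset_scenario("Mid_GOF_clone")$perturbations[[1]]$mask
  lost <- which(gof$post$epi$levels$Br == 0 & wt$post$epi$levels$Br > 0)
  expect_gt(length(lost), 0L)              # anterior fates repressed in the clone
  expect_true(all(lost %in% mask_gof))
})

test_that("early versus late BMP-pathway clones reconcile the conflicting reports", {
  wt <- wt_run()
  early <- run_preset("BMP_LOF_early_clone")
  mask_e <- preset_scenario("BMP_LOF_early_clone")$perturbations[[1]]$mask
  # disrupting the pathway before Mid repression suppresses roof Br in the clone
  lost <- which(early$post$epi$levels$Br == 0 & wt$post$epi$levels$Br > 0)
  expect_gt(length(lost), 0L)
  expect_true(all(lost %in% mask_e))
  late <- run_preset("BMP_LOF_late_clone")
  mask_l <- preset_scenario("BMP_LOF_late_clone")$perturbations[[1]]$mask
  # disrupting it after Mid repression leaves the roof intact ...
  expect_true(all(late$post$epi$levels$Br[wt$post$epi$levels$Br > 0] > 0))
  # ... and de-represses Br in the anterior-most clone cells
  gained <- which(late$post$epi$levels$Br > 0 & wt$post$epi$levels$Br == 0)
  expect_gt(length(gained), 0L)
  expect_true(all(gained %in% mask_l))
})
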