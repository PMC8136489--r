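test_that("Kd conversion hits closed forms and is log-additive", {
  expect_identical(kd_from_dg(0), 1)
  # RT ln(10) at 298.15 K is 1.3642 kcal/mol: one order of magnitude
  expect_equal(kd_from_dg(-1.3642, 298.15), 0.1, tolerance = 1e-3)
  expect_equal(kd_from_dg(-8, 298.15), 1.36756e-6, tolerance = 1e-4)
  # strict monotonicity in dG
  dgs <- seq(-12, 0, by = 0.5)
  expect_true(all(diff(kd_from_dg(dgs)) > 0))
  # log-additivity
  rt <- R_KCAL * 298.15
  a <- -7.3; b <- 1.1
  expect_equal(kd_from_dg(a + b), kd_from_dg(a) * exp(b / rt),
               tolerance = 1e-12)
  expect_error(kd_from_dg(-5, temperature = 0), "positive")
  expect_error(kd_from_dg(Inf), "finite")
})

test_that("Vina-style logs parse into ranked docking records", {
  log <- c(
    "AutoDock Vina v1",
    "mode |   affinity | dist from best mode",
    "     | (kcal/mol) | rmsd l.b.| rmsd u.b.",
    "-----+------------+----------+----------",
    "   1       -8.3          0.000      0.000",
    "   2       -7.9          1.902      3.012",
    "   3       -6.1          2.511      5.320")
  f <- file.path(tempdir(), "humanCD1a__DDM.log")
  writeLines(log, f)
  rec <- parse_vina_output(f, ligand_class = "exogenous")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$receptor, rep("humanCD1a", 3))
  expect_equal(rec$ligand, rep("DDM", 3))
  expect_equal(rec$pose_rank, 1:3)
  expect_equal(min(rec$delta_g), rec$delta_g[rec$pose_rank == 1])

  # round trip through the CSV table format
  csv <- tempfile(fileext = ".csv")
  write_dg_table(rec, csv)
  back <- read_dg_table(csv)
  expect_equal(back$delta_g, rec$delta_g)
  expect_equal(back$ligand_class, rec$ligand_class)

  writeLines("no table here", f)
  expect_error(parse_vina_output(f), "no Vina affinity table")
})

test_that("swap verdicts follow the Kd fold rule", {
  rt <- R_KCAL * 298.15
  dg_of <- function(kd) rt * log(kd)
  tab <- docking_table(
    receptor = "r", ligand = c("sm", "sulf", "DDM"),
    ligand_class = c("endogenous", "endogenous", "exogenous"),
    delta_g = dg_of(c(1e-6, 1e-7, 1e-8)))
  call <- swap_feasibility(tab, "DDM")
  expect_equal(call$fold, 10, tolerance = 1e-9)
  expect_equal(call$verdict, "swap")
  expect_equal(call$best_endogenous$ligand, "sulf")

  # tie: exogenous exactly as tight as best endogenous swaps at threshold 1
  tie <- docking_table("r", c("sm", "DDM"), c("endogenous", "exogenous"),
                       dg_of(c(1e-7, 1e-7)))
  expect_equal(swap_feasibility(tie, "DDM")$verdict, "swap")

  # tenfold weaker exogenous: no swap
  weak <- docking_table("r", c("sm", "DDM"), c("endogenous", "exogenous"),
                        dg_of(c(1e-7, 1e-6)))
  wk <- swap_feasibility(weak, "DDM")
  expect_equal(wk$fold, 0.1, tolerance = 1e-9)
  expect_equal(wk$verdict, "no_swap")

  expect_error(swap_feasibility(
    docking_table("r", "DDM", "exogenous", -8), "DDM"), "endogenous")
})

test_that("verdicts are invariant to common Kd rescaling and extra poses", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      dg <- runif(4, -10, -4)
      tab <- docking_table("r", c("e1", "e2", "e3", "x"),
                           c(rep("endogenous", 3), "exogenous"), dg)
      v1 <- swap_feasibility(tab, "x")$verdict
      # common rescaling of all Kd = common dG shift
      shifted <- tab; shifted$delta_g <- tab$delta_g + 2.5
      expect_equal(swap_feasibility(shifted, "x")$verdict, v1)
      # higher-energy poses never change the call
      extra <- rbind(tab, docking_table("r", c("e1", "x"),
                                        c("endogenous", "exogenous"),
                                        dg[c(1, 4)] + runif(2, 0.5, 3), 2L))
      class(extra) <- c("docking_table", "data.frame")
      expect_equal(swap_feasibility(extra, "x")$verdict, v1)
    }
  })
})

test_that("mutational scans report per-ligand folds and verdict flips", {
  rt <- R_KCAL * 298.15
  dg_of <- function(kd) rt * log(kd)
  wt <- docking_table("wt", c("e1", "e2", "x"),
                      c("endogenous", "endogenous", "exogenous"),
                      dg_of(c(1e-6, 3e-7, 1e-7)))
  # identical tables: folds 1, verdict unchanged
  same <- mutational_scan(wt, wt, "x")
  expect_equal(same$per_ligand$fold_change, rep(1, 3), tolerance = 1e-12)
  expect_false(same$verdict_change)

  # endogenous tightened 10x, exogenous fixed: swap flips to no_swap
  mut <- wt
  mut$receptor <- "mut"
  endo <- mut$ligand_class == "endogenous"
  mut$delta_g[endo] <- dg_of(c(1e-7, 3e-8))
  sc <- mutational_scan(wt, mut, "x")
  expect_equal(sc$wt_call$verdict, "swap")
  expect_equal(sc$mut_call$verdict, "no_swap")
  expect_true(sc$verdict_change)
  expect_equal(sc$summary, "increased affinity for all endogenous ligands")

  # exogenous affinity up, endogenous unchanged: fold spread increases
  mut2 <- wt
  mut2$receptor <- "mut2"
  mut2$delta_g[mut2$ligand == "x"] <- dg_of(1e-9)
  sc2 <- mutational_scan(wt, mut2, "x")
  expect_gt(sc2$mut_call$fold, sc2$wt_call$fold)

  bad <- docking_table("m", c("e1", "zzz"), c("endogenous", "exogenous"),
                       c(-7, -8))
  expect_error(mutational_scan(wt, bad, "x"), "zzz")
})
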