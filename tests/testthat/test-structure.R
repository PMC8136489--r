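test_that("PDB reading parses records, altlocs and waters", {
  df <- data.frame(
    type = "ATOM", serial = 1:3, atom = c("N", "CA", "C"), alt = " ",
    resname = "ALA", chain = "A", resno = 1L,
    x = c(1.234, 2.345, 3.456), y = c(0.1, 0.2, 0.3), z = c(-1, -2, -3),
    occ = 1, b = 10, element = c("N", "C", "C"))
  st <- read_structure(write_mini_pdb(df))
  expect_equal(nrow(st$atoms), 3)
  expect_equal(st$atoms$x, df$x, tolerance = 1e-9)
  expect_equal(st$atoms$z, df$z, tolerance = 1e-9)

  # altloc: keep the highest-occupancy record
  alt <- data.frame(
    type = "ATOM", serial = 1:2, atom = "CA", alt = c("A", "B"),
    resname = "ALA", chain = "A", resno = 1L,
    x = c(1, 9), y = 0, z = 0, occ = c(0.6, 0.4), b = 0, element = "C")
  st2 <- read_structure(write_mini_pdb(alt))
  expect_equal(nrow(st2$atoms), 1)
  expect_equal(st2$atoms$x, 1)

  # waters excluded by default
  wat <- rbind(df, data.frame(type = "HETATM", serial = 4, atom = "O",
                              alt = " ", resname = "HOH", chain = "A",
                              resno = 2L, x = 5, y = 5, z = 5, occ = 1,
                              b = 0, element = "O"))
  expect_equal(nrow(read_structure(write_mini_pdb(wat))$atoms), 3)
  expect_equal(nrow(read_structure(write_mini_pdb(wat),
                                   keep_waters = TRUE)$atoms), 4)
})

test_that("PDB writing round-trips coordinates to 3 decimals", {
  withr::with_seed(3, {
    n <- 20
    st <- structure_model(data.frame(
      x = round(runif(n, -40, 40), 3), y = round(runif(n, -40, 40), 3),
      z = round(runif(n, -40, 40), 3), resno = 1:n, atom = "CA",
      resname = "GLY", b = round(runif(n, 0, 50), 2)))
    f <- tempfile(fileext = ".pdb")
    write_structure(st, f)
    back <- read_structure(f)
    expect_equal(back$atoms$x, st$atoms$x, tolerance = 1e-9)
    expect_equal(back$atoms$y, st$atoms$y, tolerance = 1e-9)
    expect_equal(back$atoms$z, st$atoms$z, tolerance = 1e-9)
    expect_equal(back$atoms$b, st$atoms$b, tolerance = 1e-9)
  })
})

test_that("Kabsch superposition recovers rigid motions", {
  withr::with_seed(21, {
    A <- matrix(rnorm(30), ncol = 3)
    sp <- kabsch_superpose(A, A)
    expect_equal(sp$rmsd, 0, tolerance = 1e-10)
    expect_equal(sp$rotation, diag(3), tolerance = 1e-8)

    # 90 degree rotation about z plus translation: rmsd 0
    Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
    B <- sweep(A %*% Rz, 2, c(5, -3, 2), "+")
    sp2 <- kabsch_superpose(A, B)
    expect_equal(sp2$rmsd, 0, tolerance = 1e-10)
    expect_equal(det(sp2$rotation), 1, tolerance = 1e-9)
    expect_equal(apply_superposition(sp2, B), A, tolerance = 1e-9)

    # symmetry of the rmsd
    C <- A + matrix(rnorm(30, 0, 0.3), ncol = 3)
    expect_equal(kabsch_superpose(A, C)$rmsd, kabsch_superpose(C, A)$rmsd,
                 tolerance = 1e-9)

    # invariance to rigid pre-transforms of either input
    R1 <- random_rotation(); R2 <- random_rotation()
    r0 <- kabsch_superpose(A, C)$rmsd
    r1 <- kabsch_superpose(sweep(A %*% R1, 2, c(1, 2, 3), "+"),
                           sweep(C %*% R2, 2, c(-4, 0, 9), "+"))$rmsd
    expect_equal(r0, r1, tolerance = 1e-9)
  })

  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  coll <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(coll, coll), "collinear")
})

test_that("4-point displaced case matches the analytic least-squares solution", {
  # A: symmetric planar cross; B: same with the (0,-1,0) point pulled to
  # (0,-1-d,0). By the mirror symmetry the optimal rotation is the identity
  # and the optimal translation is the centroid shift, giving deviations
  # (d/4, d/4, d/4, 3d/4) and rmsd = d*sqrt(3)/4.
  d <- 0.8
  A <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  B <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1 - d, 0))
  sp <- kabsch_superpose(A, B)
  expect_equal(sp$rmsd, d * sqrt(3) / 4, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)
})

test_that("outlier refinement drops gross outliers and never increases rmsd", {
  withr::with_seed(8, {
    A <- matrix(rnorm(150), ncol = 3)
    B <- A + matrix(rnorm(150, 0, 0.02), ncol = 3)
    B[7, ] <- B[7, ] + c(15, -12, 9)
    plain <- kabsch_superpose(A, B)
    ref <- refined_superpose(A, B)
    expect_false(7 %in% ref$used)
    expect_lt(ref$rmsd, plain$rmsd)
    # refined rmsd at the inlier noise level, not the outlier-dominated one
    inl <- kabsch_superpose(A[-7, ], B[-7, ])
    expect_lte(ref$rmsd, inl$rmsd * 1.05)
    expect_gte(ref$rmsd, inl$rmsd * 0.5)

    # identical sets: no refinement needed, matches plain Kabsch
    same <- refined_superpose(A, A)
    expect_equal(same$rmsd, 0, tolerance = 1e-10)
    expect_equal(same$n_atoms_used, nrow(A))

    # monotonicity across random noisy fixtures
    for (rep in 1:5) {
      X <- matrix(rnorm(60), ncol = 3)
      Y <- X %*% random_rotation() + matrix(rnorm(60, 0, 0.4), ncol = 3)
      expect_lte(refined_superpose(X, Y)$rmsd,
                 kabsch_superpose(X, Y)$rmsd + 1e-12)
    }
  })
})

test_that("alignment pairing maps columns to residues both ways", {
  paln <- paln_from_strings(c(m1 = "MKVLAG", m2 = "MK-LAG", m3 = "MKVL-G"))
  mk_struct <- function(seq1, label) {
    res <- which(strsplit(seq1, "")[[1]] != "-")
    aa3 <- lipidshift:::.aa_one_to_three[strsplit(gsub("-", "", seq1), "")[[1]]]
    structure_model(data.frame(
      atom = "CA", resname = unname(aa3), chain = "A",
      resno = seq_along(res) + 10L,
      x = seq_along(res), y = 0, z = 0), label = label)
  }
  sts <- list(mk_struct("MKVLAG", "m1"), mk_struct("MK-LAG", "m2"),
              mk_struct("MKVL-G", "m3"))
  pr <- pair_by_alignment(paln, sts)
  expect_equal(pr$columns, c(1, 2, 4, 6))
  expect_equal(nrow(pr$map), 4)
  # column -> residue -> column round trip for m2 (gap at column 3)
  expect_equal(pr$map$m2_resno, c(11, 12, 13, 15))
  expect_equal(dim(pr$coords$m1), c(4, 3))

  # m2's structure carries I where its alignment row says L
  bad <- list(mk_struct("MKVLAG", "m1"), mk_struct("MKIAG", "m2"),
              mk_struct("MKVL-G", "m3"))
  expect_error(pair_by_alignment(paln, bad), "mismatch.*'m2'")
})

test_that("divergence profiles separate mobile from rigid residues", {
  base <- cbind(sin(1:30), cos(1:30), (1:30) * 1.5)
  ident <- per_residue_divergence(list(a = base, b = base, c = base))
  expect_equal(ident$divergence, rep(0, 30))
  expect_equal(ident$conservation, rep(1, 30))

  shifted <- per_residue_divergence(list(a = base, b = sweep(base, 2, c(2, 0, 0), "+")))
  expect_equal(shifted$divergence, rep(2, 30), tolerance = 1e-12)

  # input order invariance
  withr::with_seed(4, {
    pert <- base; pert[10:14, ] <- pert[10:14, ] + matrix(rnorm(15), ncol = 3)
    p1 <- per_residue_divergence(list(a = base, b = pert, c = base))
    p2 <- per_residue_divergence(list(c = base, b = pert, a = base))
    expect_equal(p1$divergence, p2$divergence)
    expect_equal(which.max(p1$divergence) %in% 10:14, TRUE)
  })
  expect_error(per_residue_divergence(list(a = base)), "at least 2")
})

test_that("conservation painting writes scores and sentinels to B-factors", {
  st <- structure_model(data.frame(
    atom = rep(c("N", "CA", "C"), 2), resname = "ALA", chain = "A",
    resno = rep(1:2, each = 3), x = 1:6, y = 0, z = 0))
  prof <- data.frame(resno = 1, score = 1.0)
  painted <- write_conservation_bfactor(st, prof)
  expect_equal(painted$atoms$b, c(1, 1, 1, 99.99, 99.99, 99.99))

  f <- tempfile(fileext = ".pdb")
  write_conservation_bfactor(st, data.frame(resno = 1:2, score = c(0.25, 0.8)), f)
  back <- read_structure(f)
  expect_equal(back$atoms$b, c(0.25, 0.25, 0.25, 0.8, 0.8, 0.8))
})

test_that("stub point mutations rename, truncate and guard the source residue", {
  st <- structure_model(data.frame(
    atom = c("N", "CA", "C", "O", "CB", "CG1", "CG2"), resname = "VAL",
    chain = "A", resno = 98L, x = 1:7, y = 0, z = 0))
  mut <- apply_point_mutation(st, mutation_spec(98, "V", "W"))
  expect_true(all(mut$atoms$resname == "TRP"))
  expect_equal(sort(trimws(mut$atoms$atom)), sort(c("N", "CA", "C", "O", "CB")))
  expect_match(mut$remarks, "STUB MUTATION V98W")

  gly <- structure_model(data.frame(
    atom = c("N", "CA", "C", "O"), resname = "GLY", chain = "A",
    resno = 98L, x = 1:4, y = 0, z = 0))
  mg <- apply_point_mutation(gly, mutation_spec(98, "G", "A"))
  expect_true(all(mg$atoms$resname == "ALA"))
  expect_match(mg$remarks, "rename only")

  expect_error(apply_point_mutation(st, mutation_spec(98, "A", "W")),
               "VAL")
})
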