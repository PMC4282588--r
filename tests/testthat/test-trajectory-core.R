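# PDB I/O, Kabsch superposition, trajectory fitting.

test_that("multi-model PDB files read as multi-frame trajectories", {
  a <- data.frame(elety = c("N", "CA", "C"), resid = "GLY", chain = "A",
                  resno = 1, x = c(0, 1.4, 2.4), y = c(0, 0.3, 1.1), z = 0)
  frames <- list(a, transform(a, x = x + 1), transform(a, x = x + 2))
  tf <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(tf, frames)
  s <- read_structure(tf)
  expect_equal(nrow(s$trajectory), 3)
  expect_equal(nrow(s$topology), 3)
  expect_equal(s$trajectory[2, 1] - s$trajectory[1, 1], 1, tolerance = 1e-3)
  unlink(tf)
})

test_that("inconsistent models are rejected naming the model", {
  a <- data.frame(elety = c("N", "CA", "C"), resid = "GLY", chain = "A",
                  resno = 1, x = c(0, 1.4, 2.4), y = 0, z = 0)
  tf <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(tf, list(a, a[-2, ]))
  expect_error(read_structure(tf), "model 2")
  unlink(tf)
})

test_that("alternate locations resolve to highest occupancy then altloc A", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA ASER A   1       1.400   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BSER A   1       1.600   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C   SER A   1       2.400   1.000   0.000  1.00  0.00           C",
    "END"), tf)
  expect_warning(s <- read_structure(tf), "alternate-location")
  expect_equal(nrow(s$topology), 3)
  # occupancy 0.60 wins over altloc A
  xyz1 <- matrix(s$trajectory[1, ], ncol = 3, byrow = TRUE)
  expect_equal(xyz1[2, 1], 1.6, tolerance = 1e-3)
  unlink(tf)
})

test_that("kabsch_superpose recovers exact transforms", {
  set.seed(7)
  x <- matrix(rnorm(30), ncol = 3)
  # identity
  s0 <- kabsch_superpose(x, x)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-8)
  # pure translation
  s1 <- kabsch_superpose(x, sweep(x, 2, c(5, 0, 0), "+"))
  expect_equal(s1$rmsd, 0, tolerance = 1e-10)
  expect_equal(s1$translation, c(5, 0, 0), tolerance = 1e-8)
  # translated copy fits back with translation -5 on x
  s1b <- kabsch_superpose(sweep(x, 2, c(5, 0, 0), "+"), x)
  expect_equal(s1b$translation, c(-5, 0, 0), tolerance = 1e-8)
  # planar 4-point set rotated 90 degrees
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  s2 <- kabsch_superpose(sq, sq %*% rot_z(pi / 2))
  expect_equal(s2$rmsd, 0, tolerance = 1e-10)
  expect_equal(s2$rotation, rot_z(pi / 2), tolerance = 1e-8)
  # rotation is always proper and orthonormal
  y <- matrix(rnorm(30), ncol = 3)
  s3 <- kabsch_superpose(x, y)
  expect_equal(det(s3$rotation), 1, tolerance = 1e-8)
  expect_equal(crossprod(s3$rotation), diag(3), tolerance = 1e-8)
})

test_that("kabsch_superpose RMSD matches the bio3d least-squares oracle", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(4:6, 1)
    x <- matrix(rnorm(3 * n), ncol = 3)
    y <- matrix(rnorm(3 * n), ncol = 3)
    mine <- kabsch_superpose(x, y, refine = FALSE)$rmsd
    xy <- matrix(as.numeric(t(x)), nrow = 1)
    yy <- matrix(as.numeric(t(y)), nrow = 1)
    fitted <- bio3d::fit.xyz(fixed = as.numeric(yy), mobile = xy,
                             fixed.inds = 1:(3 * n), mobile.inds = 1:(3 * n))
    oracle <- sqrt(mean(colSums(matrix((fitted - as.numeric(yy))^2,
                                       nrow = 3))))
    expect_equal(mine, oracle, tolerance = 1e-6)
  }
})

test_that("kabsch_superpose rejects degenerate inputs", {
  x <- matrix(rnorm(30), ncol = 3)
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "3 matched pairs")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("outlier rejection drops deviating pairs and reports both RMSDs", {
  set.seed(31)
  x <- matrix(rnorm(60), ncol = 3)
  y <- sweep(x %*% rot_z(0.4), 2, c(1, 2, 3), "+")
  y[3, ] <- y[3, ] + c(6, 0, 0)   # one planted outlier
  s <- kabsch_superpose(x, y, refine = TRUE, cycles = 5, cutoff = 2)
  expect_equal(s$n_pairs_refined, 19)
  expect_false(3 %in% s$refined_pairs)
  expect_lt(s$rmsd, 1e-8)
  expect_gt(s$rmsd_all, 1)
})

test_that("fit_trajectory removes rigid-body motion and is idempotent", {
  base <- gen_trajectory(fluctuation_spec(sigma = rep(0, 4), frames = 1,
                                          seed = 1), chains = "A")
  ref <- base$trajectory[1, ]
  # rigidly translated copies: fitted frames identical, B-factors zero
  drift <- t(vapply(0:9, function(k) ref + rep(c(k, 2 * k, 0), length(ref) / 3),
                    numeric(length(ref))))
  ft <- fit_trajectory(trajectory(drift),
                       which(base$topology$elety == "CA"))
  for (f in 2:10) expect_equal(ft[f, ], ft[1, ], tolerance = 1e-9)
  b <- residue_bfactors(ft, base$topology)
  expect_true(all(b$bfactor < 1e-18))
  # idempotency
  tr <- gen_trajectory(fluctuation_spec(sigma = rep(0.4, 6), frames = 30,
                                        seed = 8), chains = "A")
  sel <- which(tr$topology$elety == "CA")
  f1 <- fit_trajectory(tr$trajectory, sel)
  f2 <- fit_trajectory(f1, sel)
  expect_lt(max(abs(f2 - f1)), 1e-9)
  # error cases
  one <- trajectory(tr$trajectory[1, , drop = FALSE])
  expect_error(fit_trajectory(one, sel), "2 frames")
  expect_error(fit_trajectory(tr$trajectory, integer(0)), "empty")
})

test_that("fitting drift-free synthetic data barely changes B-factors", {
  tr <- gen_trajectory(fluctuation_spec(sigma = rep(0.5, 300), frames = 1000,
                                        seed = 13), chains = "A")
  sel <- which(tr$topology$elety == "CA")
  b0 <- residue_bfactors(tr$trajectory, tr$topology)
  b1 <- residue_bfactors(fit_trajectory(tr$trajectory, sel), tr$topology)
  expect_lt(mean(abs(b1$bfactor - b0$bfactor) / b0$bfactor), 0.01)
})

test_that("write_bfactor_pdb writes the fixed-point B column and round-trips", {
  tr <- gen_trajectory(fluctuation_spec(sigma = c(0, 0), frames = 1, seed = 1))
  top <- tr$topology
  vals <- data.frame(chain = c("A", "A", "B"), resno = c(1, 2, 1),
                     value = c(1.0, 2.658, -3.1))
  tf <- tempfile(fileext = ".pdb")
  write_bfactor_pdb(top, tr$trajectory[1, ], vals, tf)
  lines <- grep("^ATOM", readLines(tf), value = TRUE)
  bcol <- substr(lines, 61, 66)
  # every atom of residue A:1 reads 1.00; A:2 reads the rounded 2.66
  expect_true(all(bcol[top$chain == "A" & top$resno == 1] == "  1.00"))
  expect_true(all(bcol[top$chain == "A" & top$resno == 2] == "  2.66"))
  # residue without a value gets 0.00
  expect_true(all(bcol[top$chain == "B" & top$resno == 2] == "  0.00"))
  # round-trip preserves atom order, residue keys and coordinates
  s <- read_structure(tf)
  expect_equal(s$topology$elety, top$elety)
  expect_equal(s$topology$resno, top$resno)
  expect_equal(s$topology$chain, top$chain)
  expect_equal(max(abs(s$trajectory[1, ] - tr$trajectory[1, ])), 0,
               tolerance = 1e-3)
  # clamping warning
  vals$value[1] <- 99999
  expect_warning(write_bfactor_pdb(top, tr$trajectory[1, ], vals, tf),
                 "clamped")
  unlink(tf)
})

test_that("superpose_structures pairs chains by sequence alignment", {
  set.seed(91)
  ref_seq <- paste(sample(AA20, 40, replace = TRUE), collapse = "")
  # mobile: same fold with a 3-residue insertion after position 20
  mob_seq <- paste0(substr(ref_seq, 1, 20), "WWW", substr(ref_seq, 21, 40))
  ref <- make_ca_structure(list(A = ref_seq, B = ref_seq), seed = 3)
  mob <- make_ca_structure(list(A = mob_seq, B = mob_seq), seed = 3)
  # give the mobile's matched residues the reference geometry, rigidly
  # transformed; the insertion keeps its own (arbitrary) coordinates
  R <- rot_z(0.7)
  tr <- c(3, -2, 1)
  ref_xyz <- matrix(ref$trajectory[1, ], ncol = 3, byrow = TRUE)
  mob_xyz <- matrix(mob$trajectory[1, ], ncol = 3, byrow = TRUE)
  match_rows <- c(1:20, 24:43, 43 + c(1:20, 24:43))
  ref_rows <- c(1:40, 41:80)
  mob_xyz[match_rows, ] <- sweep(ref_xyz[ref_rows, ] %*% R, 2, tr, "+")
  mob$trajectory <- trajectory(matrix(as.numeric(t(mob_xyz)), nrow = 1))
  s <- superpose_structures(mob, ref)
  expect_equal(s$n_pairs, 80)
  expect_lt(s$rmsd, 1e-6)
  expect_equal(s$rotation %*% R, diag(3), tolerance = 1e-6)
})
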