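minimal_pdb <- function() {
  paste(c(pdb_line(serial = 1, resno = 1, x = 0, y = 0, z = 0),
          pdb_line(serial = 2, resno = 2, x = 3.8, y = 0, z = 0),
          pdb_line(serial = 3, resno = 3, x = 7.6, y = 0, z = 0),
          "END"), collapse = "\n")
}

test_that("a minimal PDB parses to one C-alpha per residue in file order", {
  m <- read_calpha(minimal_pdb())
  expect_s3_class(m, "calpha_model")
  expect_equal(n_residues(m), 3)
  expect_equal(m$residues$resno, 1:3)
  expect_equal(m$xyz[, 1], c(0, 3.8, 7.6))
})

test_that("an absent chain selection is an empty-selection error", {
  expect_error(read_calpha(minimal_pdb(), chains = "B"), "empty selection")
})

test_that("altloc duplicates resolve to highest occupancy, ties to altloc A", {
  txt <- paste(c(pdb_line(serial = 1, resno = 1, alt = "A", x = 1, occ = 0.4),
                 pdb_line(serial = 2, resno = 1, alt = "B", x = 2, occ = 0.6),
                 pdb_line(serial = 3, resno = 2, alt = "B", x = 5, occ = 0.5),
                 pdb_line(serial = 4, resno = 2, alt = "A", x = 6, occ = 0.5),
                 "END"), collapse = "\n")
  m <- read_calpha(txt)
  expect_equal(n_residues(m), 2)
  expect_equal(m$xyz[1, 1], 2)  # occ 0.6 beats 0.4
  expect_equal(m$xyz[2, 1], 6)  # tie -> altloc A
})

test_that("HETATM records are excluded by default but recoverable by name", {
  txt <- paste(c(pdb_line(serial = 1, resno = 1),
                 pdb_line(type = "HETATM", serial = 2, resid = "MSE",
                          resno = 2, x = 4),
                 pdb_line(serial = 3, resno = 3, x = 8),
                 pdb_line(type = "HETATM", serial = 4, resid = "HOH",
                          resno = 101, x = 20, element = " O", name = " O  "),
                 "END"), collapse = "\n")
  m <- read_calpha(txt)
  expect_equal(m$residues$resno, c(1, 3))
  m2 <- read_calpha(txt, het_include = "MSE")
  expect_equal(m2$residues$resno, c(1, 2, 3))
  expect_equal(m2$residues$resid[2], "MSE")
})

test_that("only the first MODEL of a multi-model file is used", {
  txt <- paste(c("MODEL        1",
                 pdb_line(serial = 1, resno = 1, x = 1),
                 pdb_line(serial = 2, resno = 2, x = 4),
                 "ENDMDL",
                 "MODEL        2",
                 pdb_line(serial = 1, resno = 1, x = 99),
                 pdb_line(serial = 2, resno = 2, x = 104),
                 "ENDMDL", "END"), collapse = "\n")
  m <- read_calpha(txt)
  expect_equal(n_residues(m), 2)
  expect_equal(m$xyz[, 1], c(1, 4))
})

test_that("community labels are written into the B-factor column", {
  m <- read_calpha(minimal_pdb())
  lines <- write_labeled_pdb(m, c(1, 1, 2))
  ca <- grep("^ATOM", lines, value = TRUE)
  b <- as.numeric(substr(ca, 61, 66))
  expect_equal(b, c(1, 1, 2))
  expect_error(write_labeled_pdb(m, c(1, 2)), "length")
})

test_that("relabeling an original keeps unmodeled residues at B = 0", {
  txt <- paste(c(pdb_line(serial = 1, resno = 1),
                 pdb_line(serial = 2, resno = 1, name = " CB ", x = 1.5),
                 pdb_line(serial = 3, resno = 2, x = 4),
                 pdb_line(type = "HETATM", serial = 4, resid = "LIG",
                          resno = 90, x = 30, name = " C1 "),
                 "END"), collapse = "\n")
  m <- read_calpha(txt)
  lines <- write_labeled_pdb(m, c(2, 1), original = txt)
  rec <- grep("^(ATOM|HETATM)", lines, value = TRUE)
  b <- as.numeric(substr(rec, 61, 66))
  resno <- as.integer(substr(rec, 23, 26))
  expect_equal(b[resno == 1], c(2, 2))  # every atom of the residue
  expect_equal(b[resno == 2], 1)
  expect_equal(b[resno == 90], 0)
})

test_that("parse -> write -> parse round-trips keys and coordinates", {
  td <- make_two_domain(n1 = 8, n2 = 8, seed = 3)
  lines <- write_labeled_pdb(td$model, rep(1, n_residues(td$model)))
  m2 <- read_calpha(paste(lines, collapse = "\n"))
  expect_equal(n_residues(m2), n_residues(td$model))
  expect_equal(m2$residues$chain, td$model$residues$chain)
  expect_equal(m2$residues$resno, td$model$residues$resno)
  expect_equal(m2$xyz, round(td$model$xyz, 3), tolerance = 1e-9)
})

test_that("trajectories write one MODEL block per frame", {
  m <- read_calpha(minimal_pdb())
  frames <- rep(list(m$xyz), 5)
  lines <- write_trajectory_pdb(frames, m)
  expect_equal(sum(grepl("^MODEL", lines)), 5)
  expect_equal(sum(grepl("^ENDMDL", lines)), 5)
  single <- write_trajectory_pdb(list(m$xyz), m)
  m2 <- read_calpha(paste(single, collapse = "\n"))
  expect_equal(m2$xyz, m$xyz, tolerance = 1e-9)
  expect_error(write_trajectory_pdb(list(), m), "non-empty")
  expect_error(write_trajectory_pdb(list(m$xyz[1:2, ]), m), "shape")
})

test_that("superposed RMSD is zero under rigid transforms and matches a
           direct Kabsch computation otherwise", {
  g <- random_globule(15, seed = 7)
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- g$xyz %*% t(rot) + matrix(rep(c(5, -3, 2), each = 15), ncol = 3)
  expect_equal(superposed_rmsd(g$xyz, moved), 0, tolerance = 1e-6)

  set.seed(11)
  noisy <- moved + matrix(rnorm(45, sd = 0.5), ncol = 3)
  # independent Kabsch: center both, SVD of covariance, proper rotation
  a <- scale(g$xyz, scale = FALSE)
  b <- scale(noisy, scale = FALSE)
  s <- svd(t(b) %*% a)
  dsign <- sign(det(s$u %*% t(s$v)))
  r <- s$u %*% diag(c(1, 1, dsign)) %*% t(s$v)
  ref <- sqrt(mean(rowSums((b %*% r - a)^2)))
  expect_equal(superposed_rmsd(g$xyz, noisy), ref, tolerance = 1e-3)
})
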