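test_that("an isolated sphere has its analytic area at any quadrature", {
  s <- make_toy_structure("single_atom")
  for (np in c(10, 96, 960))
    expect_equal(shrake_rupley(s, n_points = np)$atom$asa,
                 4 * pi * (1.76 + 1.4)^2)
  # custom radius: 4*pi*(1.88 + 1.4)^2
  s2 <- make_toy_structure("single_atom", radii = c(C = 1.88))
  expect_equal(shrake_rupley(s2)$atom$asa, 4 * pi * 3.28^2)
  expect_equal(round(shrake_rupley(s2)$atom$asa, 2), 135.19)
})

test_that("an atom enclosed by a shell has zero accessible area", {
  s <- make_toy_structure("shell")
  res <- shrake_rupley(s)
  expect_equal(res$atom$asa[1], 0)
})

test_that("two overlapping spheres agree with a 10^6-point oracle within 1%", {
  atoms <- data.frame(chain = "A", resno = 1:2, resname = "ALA",
                      atomname = c("C1", "C2"), element = "C",
                      x = c(0, 2.5), y = 0, z = 0, het = FALSE)
  s <- protein_structure(atoms)
  got <- shrake_rupley(s, n_points = 960)$atom$asa
  want <- oracle_sasa_atoms(structure_xyz(s), structure_radii(s),
                            probe = 1.4, n_z = 1000, n_phi = 1000)
  expect_equal(got, want, tolerance = 0.01)
})

test_that("ASA is invariant under rigid motion of the structure", {
  s <- make_toy_structure("tripeptide")
  base <- shrake_rupley(s, n_points = 480)$atom$asa
  # translation
  t_atoms <- s$atoms
  t_atoms[c("x", "y", "z")] <- t_atoms[c("x", "y", "z")] +
    rep(c(11.3, -4.2, 7.9), each = nrow(t_atoms))
  expect_equal(shrake_rupley(protein_structure(t_atoms),
                             n_points = 480)$atom$asa,
               base, tolerance = 1e-6)
  # rotation about an arbitrary axis
  th <- 1.1
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  ax <- 0.7
  rot2 <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)),
                 3, 3, byrow = TRUE)
  r_atoms <- s$atoms
  r_atoms[c("x", "y", "z")] <-
    as.matrix(s$atoms[c("x", "y", "z")]) %*% rot %*% rot2
  expect_equal(shrake_rupley(protein_structure(r_atoms),
                             n_points = 480)$atom$asa,
               base, tolerance = 1e-6)
})

test_that("quadrature refinement is stable below 0.5% at 960 points", {
  s <- make_toy_structure("tripeptide")
  t1 <- sum(shrake_rupley(s, n_points = 960)$atom$asa)
  t2 <- sum(shrake_rupley(s, n_points = 1920)$atom$asa)
  expect_lt(abs(t2 - t1) / t1, 0.005)
})

test_that("grid neighbor search equals the all-pairs reference", {
  # 400 atoms force the cell-list path (the all-pairs path is exact)
  set.seed(7)
  n <- 400
  atoms <- data.frame(chain = "A", resno = seq_len(n), resname = "ALA",
                      atomname = "CA", element = "C",
                      x = runif(n, 0, 35), y = runif(n, 0, 35),
                      z = runif(n, 0, 35), het = FALSE)
  s <- protein_structure(atoms)
  cell <- shrake_rupley(s, n_points = 96, neighbor_method = "cell")
  all <- shrake_rupley(s, n_points = 96, neighbor_method = "all")
  expect_identical(cell$atom$asa, all$atom$asa)
})

test_that("residue ASA equals the sum of its atoms", {
  s <- make_toy_structure("tripeptide")
  res <- shrake_rupley(s)
  by_res <- tapply(res$atom$asa, res$atom$resno, sum)
  expect_equal(as.numeric(by_res[as.character(res$residue$resno)]),
               res$residue$asa, tolerance = 1e-6)
})

test_that("relative accessibility normalizes, rounds and clamps", {
  fake <- function(asa, resname = "GLY") {
    structure(list(atom = NULL,
                   residue = data.frame(chain = "A", resno = 1,
                                        resname = resname, asa = asa)),
              class = "sasa_result")
  }
  expect_equal(relative_accessibility(fake(104))$residue$rsa, 100L)
  expect_equal(relative_accessibility(fake(0))$residue$rsa, 0L)
  expect_equal(relative_accessibility(fake(300))$residue$rsa, 100L)
  expect_equal(relative_accessibility(fake(52))$residue$rsa, 50L)
  expect_error(relative_accessibility(fake(10, "XYZ")), "XYZ")
})

test_that("exposure threshold is inclusive at 20%", {
  expect_equal(classify_exposure(0), "buried")
  expect_equal(classify_exposure(19), "buried")
  expect_equal(classify_exposure(20), "exposed")
  expect_equal(classify_exposure(29), "exposed")
  expect_equal(classify_exposure(c(5, 50), threshold_percent = 40),
               c("buried", "exposed"))
  expect_error(classify_exposure(120), "outside")
})

test_that("residue ASA in a complex never exceeds the isolated value", {
  dimer <- make_toy_dimer(contact_offset = 6)
  cplx <- shrake_rupley(dimer)$residue
  mono <- shrake_rupley(subset_chains(dimer, "A"))$residue
  a <- cplx[cplx$chain == "A", ]
  expect_true(all(a$asa <= mono$asa + 1e-9))
})

test_that("distant chains yield an empty interface", {
  dimer <- make_toy_dimer(contact_offset = 50)
  expect_equal(nrow(interface_residues(dimer, "A", "B")), 0)
})

test_that("toy-dimer interface equals the brute-force delta-ASA oracle", {
  dimer <- make_toy_dimer(contact_offset = 6)
  got <- interface_residues(dimer, "A", "B")
  want <- oracle_interface(dimer, "A", "B")
  expect_setequal(paste(got$chain, got$resno), want)
  expect_gt(nrow(got), 0)
  # symmetric dimer: chain A and chain B interface residues mirror
  expect_setequal(got$resno[got$chain == "A"],
                  got$resno[got$chain == "B"])
})

test_that("overlapping chain groups are rejected", {
  dimer <- make_toy_dimer()
  expect_error(interface_residues(dimer, c("A", "B"), "B"), "overlap")
  expect_error(interface_residues(dimer, character(0), "B"), "non-empty")
})
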