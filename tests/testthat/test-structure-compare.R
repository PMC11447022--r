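test_that("a hand-written 3-atom PDB round-trips exactly", {
  atoms <- tibble::tibble(chain = "A", resno = 1, resid = "ALA",
                          elety = c("N", "CA", "C"),
                          element = c("N", "C", "C"),
                          x = c(1.5, 2.25, 3.125), y = c(0, 1, 2),
                          z = c(-1, 0.5, 2), occupancy = 1, altloc = "")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(atoms, f)
  m <- parse_structure(f)
  expect_equal(nrow(m), 3)
  expect_equal(m$x, atoms$x)
  expect_equal(m$y, atoms$y)
  expect_equal(m$z, atoms$z)
  expect_equal(m$elety, atoms$elety)
  expect_error(parse_structure("/nonexistent.pdb"), "no such file")
})

test_that("only the highest-occupancy altloc survives parsing", {
  atoms <- tibble::tibble(chain = "A", resno = c(1, 1), resid = "SER",
                          elety = c("OG", "OG"), element = "O",
                          x = c(1, 9), y = 0, z = 0,
                          occupancy = c(0.4, 0.6), altloc = c("A", "B"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(atoms, f)
  m <- parse_structure(f)
  expect_equal(nrow(m), 1)
  expect_equal(m$x, 9) # the 0.6-occupancy conformer
  # occupancy tie resolves towards altloc A
  atoms$occupancy <- c(0.5, 0.5)
  write_toy_pdb(atoms, f)
  expect_equal(parse_structure(f)$x, 1)
})

test_that("PDB and mmCIF renderings of the same model parse identically", {
  atoms <- toy_model_atoms()
  fp <- withr::local_tempfile(fileext = ".pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  write_toy_pdb(atoms, fp)
  write_toy_cif(atoms, fc)
  mp <- parse_structure(fp)
  mc <- parse_structure(fc)
  for (col in c("chain", "resno", "resid", "elety", "x", "y", "z")) {
    expect_equal(mp[[col]], mc[[col]], tolerance = 1e-9)
  }
})

test_that("Kabsch superposition is exact on identity and pure rigid motions", {
  set.seed(1)
  A <- matrix(rnorm(30), 10, 3)
  sp <- kabsch(A, A)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)
  Q <- rotation_matrix(c(0, 0, 1), 90)
  B <- sweep(A %*% t(Q), 2, c(3, -1, 2), "+")
  sp2 <- kabsch(A, B)
  expect_lt(sp2$rmsd, 1e-10)
  # recovered rotation undoes the applied one (row convention: Bc %*% Q = Ac)
  expect_equal(sp2$rotation, Q, tolerance = 1e-8)
  expect_equal(apply_superposition(B, sp2), A, tolerance = 1e-8)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-10)
})

test_that("Kabsch agrees with the quaternion oracle on perturbed sets", {
  set.seed(2)
  for (i in 1:25) {
    A <- matrix(rnorm(12), 4, 3)
    B <- A %*% t(rotation_matrix(rnorm(3), runif(1, 0, 180)))
    B[1, 1] <- B[1, 1] + 1
    sp <- kabsch(A, B)
    orc <- quaternion_superpose(A, B)
    expect_equal(sp$rmsd, orc$rmsd, tolerance = 1e-6)
  }
})

test_that("Kabsch RMSD is invariant under joint rigid transforms and rejects degenerate input", {
  set.seed(3)
  A <- matrix(rnorm(21), 7, 3)
  B <- A + matrix(rnorm(21, sd = 0.3), 7, 3)
  r0 <- kabsch(A, B)$rmsd
  Q <- rotation_matrix(c(1, 1, 0), 77)
  shift <- c(5, 6, 7)
  r1 <- kabsch(sweep(A %*% t(Q), 2, shift, "+"),
               sweep(B %*% t(Q), 2, shift, "+"))$rmsd
  expect_equal(r0, r1, tolerance = 1e-9)
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch(line, line), "degenerate")
  expect_error(kabsch(A[1:2, ], B[1:2, ]), "at least 3")
  expect_error(kabsch(A, B[1:5, ]), "paired")
})

test_that("matched C-alpha RMSD pairs by residue and is symmetric", {
  m <- toy_structure_model()
  sp <- matched_ca_rmsd(m, m)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$n_pairs, sum(tibble::as_tibble(m)$elety == "CA"))
  # perturb + remove one residue from the copy: pairing drops it
  atoms <- toy_model_atoms()
  atoms2 <- atoms[!(atoms$chain == "B" & atoms$resno == 6), ]
  set.seed(4)
  atoms2$x <- atoms2$x + rnorm(nrow(atoms2), sd = 0.4)
  m2 <- gamdr:::as_structure_model(atoms2, "toy2")
  expect_message(spAB <- matched_ca_rmsd(m, m2), "unmatched")
  expect_equal(spAB$n_pairs, sp$n_pairs - 1)
  spBA <- suppressMessages(matched_ca_rmsd(m2, m))
  expect_equal(spAB$rmsd, spBA$rmsd, tolerance = 1e-8)
})

test_that("atom displacement reports planted helix-tip motion after anchoring", {
  atoms <- toy_model_atoms()
  m <- gamdr:::as_structure_model(atoms, "ref")
  moved <- atoms
  tip <- moved$chain == "B" & moved$resno == 6
  moved$x[tip] <- moved$x[tip] + 16
  m2 <- gamdr:::as_structure_model(moved, "moved")
  # identical models: zero displacement
  expect_equal(as.numeric(atom_displacement(
    m, m, list(chain = "B", resno = 6, elety = "CA"))), 0, tolerance = 1e-10)
  # global translation removed by superposition on all atoms
  shifted <- atoms; shifted$x <- shifted$x + 2
  m3 <- gamdr:::as_structure_model(shifted, "shifted")
  expect_equal(as.numeric(atom_displacement(
    m, m3, list(chain = "B", resno = 6, elety = "CA"))), 0, tolerance = 1e-9)
  # tip moved 16 A with the anchor held on chain A
  d <- atom_displacement(m, m2, list(chain = "B", resno = 6, elety = "CA"),
                         superpose_selection = list(chain = "A"))
  expect_equal(as.numeric(d), 16, tolerance = 1e-6)
})

test_that("salt bridges form and break with distance, and the charge-centre convention holds", {
  atoms <- toy_model_atoms()
  m <- toy_structure_model(atoms)
  asp <- list(chain = "A", resno = 4)
  arg <- list(chain = "A", resno = 5)
  sb <- salt_bridge(m, asp, arg, cutoff = 4.0)
  # oracle: brute-force min over carboxylate O x guanidinium N
  od <- atoms[atoms$resno == 4 & atoms$elety %in% c("OD1", "OD2"), ]
  ns <- atoms[atoms$resno == 5 & atoms$elety %in% c("NH1", "NH2", "NE"), ]
  dmin <- min(sqrt(outer(seq_len(nrow(od)), seq_len(nrow(ns)),
    Vectorize(function(i, j) sum((c(od$x[i], od$y[i], od$z[i]) -
                                    c(ns$x[j], ns$y[j], ns$z[j]))^2)))))
  expect_equal(sb$distance, dmin, tolerance = 1e-10)
  expect_true(sb$formed)
  # pull the Arg far away: bridge broken
  pulled <- atoms
  sel <- pulled$resno == 5
  pulled$x[sel] <- pulled$x[sel] + 20
  m2 <- gamdr:::as_structure_model(pulled, "pulled")
  expect_false(salt_bridge(m2, asp, arg, cutoff = 4.0)$formed)
  # charge-centre convention: CZ for Arg, CG for Asp
  ctr <- salt_bridge(m, asp, arg, method = "centers")
  cg <- unlist(atoms[atoms$resno == 4 & atoms$elety == "CG", c("x", "y", "z")])
  cz <- unlist(atoms[atoms$resno == 5 & atoms$elety == "CZ", c("x", "y", "z")])
  expect_equal(ctr$distance, sqrt(sum((cg - cz)^2)), tolerance = 1e-10)
  expect_error(salt_bridge(m, arg, asp), "not an acidic")
})

test_that("domain motion recovers planted rotations and translations", {
  atoms <- toy_model_atoms()
  m <- gamdr:::as_structure_model(atoms, "ref")
  expect_equal(domain_motion(m, m, list(chain = "A"),
                             list(chain = "B"))$angle_deg, 0,
               tolerance = 1e-6)
  # rotate chain B by exactly 77 degrees about a fixed axis
  rot <- atoms
  selB <- rot$chain == "B"
  Q <- rotation_matrix(c(0.2, 1, -0.5), 77)
  xyz <- as.matrix(rot[selB, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  rot[selB, c("x", "y", "z")] <- sweep(sweep(xyz, 2, ctr) %*% t(Q), 2, ctr, "+")
  m2 <- gamdr:::as_structure_model(rot, "rot")
  dm <- domain_motion(m, m2, list(chain = "A"), list(chain = "B"))
  expect_equal(dm$angle_deg, 77, tolerance = 1e-6)
  expect_lt(dm$displacement, 1e-8) # rotation about its own mass centre
  # pure translation by 38 A
  shift <- atoms
  shift$y[shift$chain == "B"] <- shift$y[shift$chain == "B"] + 38
  m3 <- gamdr:::as_structure_model(shift, "shift")
  dm2 <- domain_motion(m, m3, list(chain = "A"), list(chain = "B"))
  expect_lt(dm2$angle_deg, 1e-4)
  expect_equal(dm2$displacement, 38, tolerance = 1e-9)
})

test_that("interface contacts match brute-force enumeration and validate groups", {
  atoms <- dplyr::bind_rows(
    tibble::tibble(chain = "A", resno = 1:3, resid = c("ALA", "GLY", "SER"),
                   elety = "CA", element = "C",
                   x = c(0, 4, 8), y = 0, z = 0, occupancy = 1, altloc = ""),
    tibble::tibble(chain = "B", resno = 1:3, resid = c("LEU", "VAL", "ILE"),
                   elety = "CA", element = "C",
                   x = c(0, 4, 30), y = 3.5, z = 0, occupancy = 1,
                   altloc = ""))
  m <- gamdr:::as_structure_model(atoms, "iface")
  cts <- interface_contacts(m, list(chain = "A"), list(chain = "B"),
                            cutoff = 4.5)
  # brute-force oracle over all cross pairs
  a <- atoms[atoms$chain == "A", ]; b <- atoms[atoms$chain == "B", ]
  expected <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
    if (d <= 4.5) expected[[length(expected) + 1]] <-
        c(a$resno[i], b$resno[j], d)
  }
  exp_pairs <- do.call(rbind, expected)
  expect_equal(nrow(cts), nrow(exp_pairs))
  expect_setequal(paste(cts$resno_a, cts$resno_b),
                  paste(exp_pairs[, 1], exp_pairs[, 2]))
  expect_equal(sort(cts$min_dist), sort(exp_pairs[, 3]), tolerance = 1e-10)
  # groups far apart: empty result; overlapping groups: error
  far <- interface_contacts(m, list(chain = "A", resno = 1),
                            list(chain = "B", resno = 3), cutoff = 4.5)
  expect_equal(nrow(far), 0)
  expect_error(interface_contacts(m, list(chain = "A"), list(resno = 1)),
               "disjoint")
})
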