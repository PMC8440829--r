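# PDB parsing, ligand selection/stripping, coarse-graining, superposition,
# transplantation and B-factor output.

test_that("parse_pdb reads single records and rejects files without coordinates", {
  txt <- c(pdb_line(serial = 1, x = 0, y = 0, z = 0, occ = 1, b = 10), "END")
  m <- parse_pdb(txt)
  expect_s3_class(m, "gnm_structure")
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$record, "ATOM")
  expect_equal(unlist(m$atoms[1, c("x", "y", "z")], use.names = FALSE),
               c(0, 0, 0))
  expect_error(parse_pdb(c("HEADER    junk", "END")), "no ATOM/HETATM")
  expect_error(parse_pdb(c("ATOM      1  CA  ALA A   1      bad coords")),
               "line 1")
})

test_that("parse_pdb keeps only the requested coordinate model", {
  txt <- c("MODEL        1",
           pdb_line(x = 0, y = 0, z = 0),
           "ENDMDL",
           "MODEL        2",
           pdb_line(x = 9, y = 9, z = 9),
           "ENDMDL", "END")
  m1 <- parse_pdb(txt, model_number = 1)
  m2 <- parse_pdb(txt, model_number = 2)
  expect_equal(nrow(m1$atoms), 1)
  expect_equal(m1$atoms$x, 0)
  expect_equal(m2$atoms$x, 9)
  expect_error(parse_pdb(txt, model_number = 3), "model_number 3")
})

test_that("altlocs resolve to highest occupancy, ties to smallest altloc id", {
  txt <- c(pdb_line(serial = 1, altloc = "A", x = 1, occ = 0.6),
           pdb_line(serial = 2, altloc = "B", x = 2, occ = 0.4),
           pdb_line(serial = 3, resno = 2, altloc = "B", x = 5, occ = 0.5),
           pdb_line(serial = 4, resno = 2, altloc = "A", x = 6, occ = 0.5),
           "END")
  m <- parse_pdb(txt)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[m$atoms$resno == 1], 1)   # occupancy 0.6 wins
  expect_equal(m$atoms$occ[m$atoms$resno == 1], 0.6)
  expect_equal(m$atoms$x[m$atoms$resno == 2], 6)   # tie -> altloc A
})

test_that("ligand selection honours codes, chains, heavy atoms and waters", {
  ca <- matrix(rnorm(30), 10, 3) * 2
  lig <- matrix(rnorm(9), 3, 3)
  txt <- protein_ligand_pdb(ca, lig, lig_resid = "ATP")
  # add a ligand hydrogen and a magnesium ion
  txt <- c(head(txt, -1),
           pdb_line(record = "HETATM", serial = 90, name = "H1",
                    resid = "ATP", resno = 901, x = 1, elem = "H"),
           pdb_line(record = "HETATM", serial = 91, name = "MG",
                    resid = "MG", resno = 902, x = 3, elem = "MG"),
           "END")
  m <- parse_pdb(txt)
  atp <- select_ligand_atoms(m, ligand_spec("ATP"))
  expect_equal(nrow(atp), 3)              # hydrogens excluded
  expect_true(all(atp$resid == "ATP"))
  mg <- select_ligand_atoms(m, ligand_spec("MG"))
  expect_equal(nrow(mg), 1)               # single-atom ion ligand is valid
  err <- expect_error(select_ligand_atoms(m, ligand_spec("XYZ")),
                      class = "gnmflux_empty_selection")
  expect_match(conditionMessage(err), "XYZ")
  expect_error(ligand_spec("HOH"), "water")
  none <- select_ligand_atoms(m, ligand_spec("ATP", chains = "A"))
  expect_equal(nrow(none), 3)
  expect_error(select_ligand_atoms(m, ligand_spec("ATP", chains = "B")),
               class = "gnmflux_empty_selection")
})

test_that("strip_ligands removes exactly the selected residues", {
  ca <- matrix(seq_len(30), 10, 3) * 1.0
  lig <- matrix(c(50, 0, 0, 51, 0, 0), 2, 3, byrow = TRUE)
  txt <- c(head(protein_ligand_pdb(ca, lig, lig_resid = "ATP"), -1),
           pdb_line(record = "HETATM", serial = 99, name = "MG",
                    resid = "MG", resno = 902, x = 60, elem = "MG"),
           "END")
  m <- parse_pdb(txt)
  stripped <- strip_ligands(m, ligand_spec("ATP"))
  expect_equal(nrow(stripped$atoms), 11)           # 10 CA + MG retained
  expect_true("MG" %in% stripped$atoms$resid)
  # set-difference invariant: stripped = all minus selected, order preserved
  sel <- select_ligand_atoms(m, ligand_spec("ATP"))
  expect_equal(stripped$atoms$serial,
               setdiff(m$atoms$serial, sel$serial))
  # stripping twice: nothing left to match
  expect_error(strip_ligands(stripped, ligand_spec("ATP")),
               class = "gnmflux_empty_selection")
})

test_that("coarse model counts residues with CA plus ligand heavy atoms", {
  h <- make_helix_chain(30)
  cm <- build_coarse_model(h)
  expect_equal(nrow(cm$xyz), 30)
  expect_true(all(cm$role == "RESIDUE"))

  lig <- matrix(rnorm(36), 12, 3) + 5
  txt <- protein_ligand_pdb(as.matrix(h$atoms[, c("x", "y", "z")]), lig,
                            lig_resid = "ATP")
  m <- parse_pdb(txt)
  cm2 <- build_coarse_model(m, ligand_spec("ATP"))
  expect_equal(nrow(cm2$xyz), 42)
  expect_equal(sum(cm2$role == "LIGAND"), 12)
  expect_equal(tail(cm2$role, 12), rep("LIGAND", 12))

  # a residue whose CA is missing is skipped with a warning
  drop_ca <- m
  drop_ca$atoms <- drop_ca$atoms[-(5:5), , drop = FALSE]
  drop_ca$atoms <- rbind(drop_ca$atoms,
                         parse_pdb(c(pdb_line(serial = 500, name = "CB",
                                              resno = 5, x = 1), "END"))$atoms)
  expect_warning(cm3 <- build_coarse_model(drop_ca), "lack a CA")
  expect_equal(sum(cm3$role == "RESIDUE"), 29)
})

test_that("kabsch superposition recovers rigid motions exactly", {
  set.seed(42)
  pts <- matrix(rnorm(30), 10, 3) * 4
  fit0 <- kabsch_superpose(pts, pts)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)

  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)  # 90 deg z
  ref <- pts %*% t(Rz) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(pts, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  aligned <- pts %*% t(fit$rotation) +
    matrix(fit$translation, 10, 3, byrow = TRUE)
  expect_equal(aligned, ref, tolerance = 1e-8)

  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("kabsch rmsd matches a brute-force rotational search on noisy points", {
  set.seed(7)
  for (rep in 1:3) {
    pts <- matrix(rnorm(12), 4, 3) * 3
    noisy <- pts + matrix(rnorm(12, sd = 0.1), 4, 3)
    fit <- kabsch_superpose(noisy, pts)
    expect_equal(fit$rmsd, brute_fit_rmsd(noisy, pts), tolerance = 1e-4)
  }
})

test_that("kabsch rmsd is invariant under a common rigid motion", {
  set.seed(11)
  a <- matrix(rnorm(24), 8, 3)
  b <- a + matrix(rnorm(24, sd = 0.3), 8, 3)
  base <- kabsch_superpose(a, b)$rmsd
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  shift <- matrix(c(4, -2, 9), 8, 3, byrow = TRUE)
  moved <- kabsch_superpose(a %*% t(R) + shift, b %*% t(R) + shift)$rmsd
  expect_equal(moved, base, tolerance = 1e-8)
})

test_that("transplant_ligand maps the donor ligand into the acceptor frame", {
  set.seed(3)
  ca <- matrix(rnorm(30), 10, 3) * 4
  lig <- matrix(rnorm(9, sd = 0.5), 3, 3) + 2
  donor <- parse_pdb(protein_ligand_pdb(ca, lig, lig_resid = "ATP"))
  anchors <- list(donor = data.frame(chain = "A", resno = 1:10),
                  acceptor = data.frame(chain = "A", resno = 1:10))

  # identity: donor onto itself reproduces the ligand coordinates
  same <- transplant_ligand(donor, strip_ligands(donor, ligand_spec("ATP")),
                            ligand_spec("ATP"), anchors)
  out_lig <- select_ligand_atoms(same, ligand_spec("ATP"))
  donor_lig <- as.matrix(select_ligand_atoms(donor,
                                             ligand_spec("ATP"))[,
                                             c("x", "y", "z")])
  expect_lt(max(abs(as.matrix(out_lig[, c("x", "y", "z")]) - donor_lig)),
            1e-8)

  # commutation: acceptor = rigidly moved donor -> ligand lands in the
  # moved pocket, equal to directly moving the donor ligand
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3,
              byrow = TRUE)
  shift <- c(5, 6, 7)
  acceptor <- strip_ligands(donor, ligand_spec("ATP"))
  moved <- as.matrix(acceptor$atoms[, c("x", "y", "z")]) %*% t(R) +
    matrix(shift, nrow(acceptor$atoms), 3, byrow = TRUE)
  acceptor$atoms$x <- moved[, 1]
  acceptor$atoms$y <- moved[, 2]
  acceptor$atoms$z <- moved[, 3]
  res <- transplant_ligand(donor, acceptor, ligand_spec("ATP"), anchors)
  got <- as.matrix(select_ligand_atoms(res, ligand_spec("ATP"))[,
                                       c("x", "y", "z")])
  want <- donor_lig %*% t(R) + matrix(shift, 3, 3, byrow = TRUE)
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("B-factor painting formats, clamps and round-trips", {
  ca <- cbind(seq(0, 36, by = 4), 0, 0)
  m <- parse_pdb(protein_ligand_pdb(ca))
  zero_map <- data.frame(chain = "A", resno = 1:10, value = 0)
  lines <- write_bfactor_pdb(m, zero_map)
  expect_true(all(substr(lines[1:10], 61, 66) == "  0.00"))
  one_map <- data.frame(chain = "A", resno = 1:10, value = 0.1528)
  lines <- write_bfactor_pdb(m, one_map)
  expect_true(all(substr(lines[1:10], 61, 66) == "  0.15"))

  vals <- data.frame(chain = "A", resno = 1:10, value = seq(-0.2, 0.7, by = 0.1))
  back <- parse_pdb(write_bfactor_pdb(m, vals))
  expect_lt(max(abs(back$atoms$b - vals$value)), 0.006)

  expect_error(write_bfactor_pdb(m, data.frame(chain = "B", resno = 1,
                                               value = 1)),
               "not present")
})

test_that("parse -> write -> parse round-trip preserves the structure", {
  set.seed(5)
  ca <- matrix(rnorm(60), 20, 3) * 5
  lig <- matrix(rnorm(9), 3, 3)
  m <- parse_pdb(protein_ligand_pdb(ca, lig, lig_resid = "GTP", lig_elem = "P"))
  m2 <- parse_pdb(write_pdb(m))
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(m2$atoms$name, m$atoms$name)
  expect_equal(m2$atoms$resid, m$atoms$resid)
  expect_equal(as.matrix(m2$atoms[, c("x", "y", "z")]),
               as.matrix(m$atoms[, c("x", "y", "z")]), tolerance = 1e-3,
               ignore_attr = TRUE)
})
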