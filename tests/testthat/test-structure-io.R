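# PDB io, cell geometry, Matthews coefficient, solvent content, chain mass

test_that("parse/write round-trips coordinates and identities", {
  toy <- make_toy_crystal(n_res = 8, ligand = list(distance = 2.9))
  st <- toy$structure
  txt <- write_pdb(st)
  st2 <- parse_pdb(paste(txt, collapse = "\n"))
  expect_equal(nrow(st2$atoms), nrow(st$atoms))
  expect_equal(as.matrix(st2$atoms[, c("x", "y", "z")]),
               as.matrix(st$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_identical(st2$atoms$name, st$atoms$name)
  expect_identical(st2$atoms$resname, st$atoms$resname)
  expect_identical(st2$atoms$chain, st$atoms$chain)
  expect_identical(st2$atoms$het, st$atoms$het)
  # second round trip is exact: fixed-column precision already applied
  txt2 <- write_pdb(st2)
  expect_identical(txt2, txt)
})

test_that("CRYST1 parsing yields cell and space-group operators", {
  pdb <- c(
    "CRYST1   87.500  139.500  189.900  90.00  90.00  90.00 I 2 2 2      8",
    "ATOM      1  N   GLY A   1      11.000  12.000  13.000  1.00 20.00           N",
    "ATOM      2  CA  GLY A   1      12.400  12.500  13.000  1.00 20.00           C",
    "ATOM      3  C   GLY A   1      13.600  12.900  13.500  1.00 20.00           C",
    "END")
  st <- parse_pdb(paste(pdb, collapse = "\n"))
  expect_equal(nrow(st$atoms), 3)
  expect_equal(st$cell$a, 87.5)
  expect_equal(st$cell$b, 139.5)
  expect_equal(st$cell$c, 189.9)
  expect_equal(unlist(st$cell[c("alpha", "beta", "gamma")]),
               c(alpha = 90, beta = 90, gamma = 90))
  expect_length(st$space_group$ops, 8)
})

test_that("structure without CRYST1 refuses cell-dependent operations", {
  pdb <- paste(
    "ATOM      1  N   GLY A   1      11.000  12.000  13.000  1.00 20.00           N",
    "END", sep = "\n")
  st <- parse_pdb(pdb)
  expect_null(st$cell)
  expect_error(apply_symop(st, parse_symop("X,Y,Z")), "cell required")
  expect_error(crystal_summary(st), "cell required")
})

test_that("malformed fixed-column records are rejected with a line number", {
  good <- "ATOM      1  N   GLY A   1      11.000  12.000  13.000  1.00 20.00           N"
  blank_occ <- sub("  1.00 20.00", "       20.00", good, fixed = TRUE)
  expect_error(parse_pdb(paste(good, blank_occ, "END", sep = "\n")),
               "line 2.*occupancy")
  bad_x <- sub("11.000", "1x.000", good, fixed = TRUE)
  expect_error(parse_pdb(paste(bad_x, "END", sep = "\n")), "line 1")
  trunc <- substr(good, 1, 40)
  expect_error(parse_pdb(paste(good, trunc, "END", sep = "\n")),
               "line 2.*truncated")
})

test_that("unknown space-group symbols error and list supported groups", {
  expect_error(space_group_ops("P 63"), "supported")
  expect_length(space_group_ops("P212121"), 4)
  expect_length(space_group_ops("p 21"), 2)
})

test_that("altloc collapse keeps the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  OG ASER A   1       0.000   0.000   0.000  0.40 20.00           O",
    "ATOM      2  OG BSER A   1       1.000   0.000   0.000  0.60 20.00           O",
    "ATOM      3  OG ASER A   2       0.000   5.000   0.000  0.50 20.00           O",
    "ATOM      4  OG BSER A   2       1.000   5.000   0.000  0.50 20.00           O",
    "END")
  st <- parse_pdb(paste(lines, collapse = "\n"))
  expect_equal(nrow(st$atoms), 2)
  expect_equal(st$atoms$x, c(1, 0))  # B wins on occ; tie goes to A
})

test_that("cell volume matches closed forms and the printed cells", {
  expect_equal(cell_volume(unit_cell(1, 1, 1)), 1)
  expect_equal(cell_volume(unit_cell(87.5, 139.5, 189.9)),
               87.5 * 139.5 * 189.9)
  v_mono <- cell_volume(unit_cell(59.3, 83.7, 65.1, 90, 112.8, 90))
  expect_equal(v_mono, 59.3 * 83.7 * 65.1 * sin(112.8 * pi / 180),
               tolerance = 1e-12)
  expect_equal(v_mono, 297870.6, tolerance = 1e-5)
  expect_error(cell_volume(unit_cell(1, 1, 1, 1, 1, 179.5)), "degenerate")
})

test_that("cell volume equals the orthogonalization determinant (property)", {
  set.seed(11)
  for (k in 1:100) {
    cl <- unit_cell(runif(1, 20, 200), runif(1, 20, 200), runif(1, 20, 200),
                    runif(1, 60, 120), runif(1, 60, 120), runif(1, 60, 120))
    v1 <- tryCatch(cell_volume(cl), error = function(e) NA)
    if (is.na(v1)) next
    v2 <- det(ipolectin:::.orth_matrix(cl))
    expect_equal(v1, v2, tolerance = 1e-6)
  }
})

test_that("Matthews coefficient reproduces the reported packing analysis", {
  V <- cell_volume(unit_cell(87.5, 139.5, 189.9))
  expect_equal(matthews(V, 5 * 8, 16510), 3.51, tolerance = 0.002)
  expect_equal(matthews(V, 8 * 8, 16510), 2.19, tolerance = 0.002)
  expect_equal(matthews(1000, 1, 1000), 1)
  expect_error(matthews(1000, 1, 0), "mass")
  # homogeneity: doubling V and chain count leaves Vm unchanged
  expect_equal(matthews(2 * V, 2 * 40, 16510), matthews(V, 40, 16510))
})

test_that("solvent content matches the reported values and is monotone", {
  expect_equal(solvent_content(3.51), 0.650, tolerance = 5e-4)
  expect_equal(solvent_content(2.21), 0.444, tolerance = 5e-4)
  expect_error(solvent_content(1.2284), "non-positive")
  vm <- seq(1.3, 5, by = 0.01)
  expect_true(all(diff(vapply(vm, solvent_content, 0)) > 0))
})

test_that("chain mass sums residue masses minus peptide waters", {
  expect_equal(as.numeric(chain_mass("GLY")), 75.07)
  expect_equal(as.numeric(chain_mass(c("GLY", "GLY"))), 132.12)
  expect_warning(m <- chain_mass(c("GLY", "XYZ", "ALA")), "XYZ")
  expect_equal(as.numeric(m), 75.07 + 89.09 - 18.02)
  expect_identical(attr(m, "unknown"), "XYZ")
  # a 154-residue chain of typical globular composition lands near the
  # ~16.5 kDa monomer implied by the crystal packing analysis
  comp <- c(ALA = 12, ARG = 7, ASN = 7, ASP = 8, CYS = 2, GLU = 9,
            GLN = 5, GLY = 12, HIS = 3, ILE = 8, LEU = 13, LYS = 9,
            MET = 3, PHE = 6, PRO = 7, SER = 10, THR = 9, TRP = 2,
            TYR = 5, VAL = 17)
  seqres <- rep(names(comp), comp)
  expect_length(seqres, 154)
  expect_equal(as.numeric(chain_mass(seqres)) / 1000, 16.5,
               tolerance = 0.03)
})

test_that("crystal_summary wires volume, multiplicity and mass together", {
  toy <- make_toy_crystal(n_res = 10, cell = unit_cell(60, 60, 60),
                          space_group = "I222")
  cs <- crystal_summary(toy$structure, n_chains_asym = 1,
                        monomer_mass = 16510)
  expect_equal(cs$multiplicity, 8)
  expect_equal(cs$matthews, 60^3 / (8 * 16510))
  expect_equal(cs$solvent_fraction, solvent_content(cs$matthews))
})
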