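# hydrogen-bond, methyl-pi and metal-coordination detection

test_that("a backbone N to sugar O5 pair at 2.9 A is one hydrogen bond", {
  at <- rbind(
    atom_df("N", "N", 0, 0, 0, resname = "GLY", resno = 1, het = FALSE),
    atom_df("O5", "O", 2.9, 0, 0, resname = "LIG", resno = 2))
  at$serial <- 1:2
  hb <- find_hbonds(at, 1, 2, cutoff = 3.5)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9)
  expect_equal(hb$atom_1, "N")
  expect_equal(hb$atom_2, "O5")
})

test_that("carbon pairs are never hydrogen bonds", {
  at <- rbind(
    atom_df("CA", "C", 0, 0, 0, resname = "GLY", resno = 1, het = FALSE),
    atom_df("C1", "C", 2.8, 0, 0, resname = "LIG", resno = 2))
  at$serial <- 1:2
  expect_equal(nrow(find_hbonds(at, 1, 2)), 0)
})

test_that("sugar O1/O5 are acceptors only while hydroxyls donate", {
  d <- donor_acceptor_dictionary(c("LIG", "GLY", "ASP", "HOH"))
  expect_false("O1" %in% d$LIG$donors)
  expect_false("O5" %in% d$LIG$donors)
  expect_true(all(c("O2", "O3", "O4", "O6") %in% d$LIG$donors))
  expect_true(all(c("O1", "O5") %in% d$LIG$acceptors))
  expect_identical(d$GLY$donors, "N")
  expect_true("O" %in% d$GLY$acceptors)
  expect_true(all(c("OD1", "OD2") %in% d$ASP$acceptors))
  expect_false(any(c("OD1", "OD2") %in% d$ASP$donors))  # carboxylate
  expect_identical(d$ASP$donors, "N")  # backbone amide only
})

test_that("detected bonds match the designed fixture exactly", {
  toy <- make_toy_crystal(n_res = 15, ligand = list(distance = 2.9))
  hb <- find_hbonds(toy$structure, toy$selections$protein,
                    toy$selections$ligand)
  expect_identical(contact_keys(hb), contact_keys(toy$truth$hbonds))
  expect_equal(hb$distance_exact, toy$truth$hbonds$distance_exact,
               tolerance = 1e-9)
})

test_that("brute-force all-pairs oracle agrees exactly", {
  toy <- make_toy_crystal(n_res = 20, ligand = list(distance = 3.2))
  at <- toy$structure$atoms
  for (cutoff in c(3.0, 3.5, 4.5)) {
    hb <- find_hbonds(at, toy$selections$protein, toy$selections$ligand,
                      cutoff = cutoff)
    bf <- brute_force_hbonds(at, toy$selections$protein,
                             toy$selections$ligand, cutoff = cutoff)
    expect_equal(nrow(hb), nrow(bf))
    if (nrow(bf) > 0) {
      bf_keys <- sort(paste(
        pmin(paste(at$chain[bf$i], at$resno[bf$i], at$name[bf$i]),
             paste(at$chain[bf$j], at$resno[bf$j], at$name[bf$j])),
        pmax(paste(at$chain[bf$i], at$resno[bf$i], at$name[bf$i]),
             paste(at$chain[bf$j], at$resno[bf$j], at$name[bf$j]))))
      expect_identical(contact_keys(hb), bf_keys)
    }
  }
})

test_that("hydrogen-bond sets are monotone in the cutoff", {
  toy <- make_toy_crystal(n_res = 20, ligand = list(distance = 3.0))
  at <- toy$structure$atoms
  prev <- character(0)
  for (cutoff in c(2.5, 3.0, 3.5, 4.0, 5.0)) {
    keys <- contact_keys(find_hbonds(at, toy$selections$protein,
                                     toy$selections$ligand, cutoff))
    expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("contacts are invariant under rigid motion", {
  set.seed(42)
  toy <- make_toy_crystal(n_res = 12, ligand = list(distance = 2.9),
                          metal = list(n_oxygens = 4),
                          me_pi = list(distance = 3.8))
  at <- toy$structure$atoms
  base_h <- find_hbonds(at, toy$selections$protein, toy$selections$ligand)
  base_p <- find_me_pi(at, toy$selections$ligand, toy$selections$protein)
  base_m <- find_metal_coordination(at)
  for (k in 1:5) {
    at2 <- random_rigid_motion(at)
    h <- find_hbonds(at2, toy$selections$protein, toy$selections$ligand)
    p <- find_me_pi(at2, toy$selections$ligand, toy$selections$protein)
    m <- find_metal_coordination(at2)
    expect_identical(contact_keys(h), contact_keys(base_h))
    expect_equal(h$distance_exact[order(h$atom_1, h$atom_2)],
                 base_h$distance_exact[order(base_h$atom_1, base_h$atom_2)],
                 tolerance = 1e-6)
    expect_identical(contact_keys(p), contact_keys(base_p))
    expect_identical(attr(m, "coordination"),
                     attr(base_m, "coordination"))
  }
})

test_that("methyl-pi requires both distance and elevation", {
  ring <- ipolectin:::.toy_indole(c(0, 0, 0), "A", 1L, 0L)
  above <- atom_df("C7", "C", 0, 0, 3.8, resname = "LIG", resno = 9)
  above$serial <- max(ring$serial) + 1L
  at <- rbind(ring, above)
  hits <- find_me_pi(at, which(at$name == "C7"), which(at$resname == "TRP"))
  expect_true("ring6" %in% hits$atom_2)
  # same distance but in the ring plane: rejected by the angle filter
  inplane <- above
  inplane$x <- 3.8; inplane$z <- 0
  at2 <- rbind(ring, inplane)
  hits2 <- find_me_pi(at2, which(at2$name == "C7"),
                      which(at2$resname == "TRP"))
  expect_false("ring6" %in% hits2$atom_2)
  # beyond the distance cutoff: nothing
  far <- above
  far$z <- 5.0
  at3 <- rbind(ring, far)
  expect_equal(nrow(find_me_pi(at3, which(at3$name == "C7"),
                               which(at3$resname == "TRP"))), 0)
})

test_that("metal coordination counts O/N ligands within the cutoff", {
  toy <- make_toy_crystal(n_res = 8, metal = list(n_oxygens = 5,
                                                  distance = 2.3))
  mc <- find_metal_coordination(toy$structure)
  expect_equal(unname(attr(mc, "coordination")), 5)
  expect_identical(contact_keys(mc), contact_keys(toy$truth$metal_coord))
  # nearest O beyond the cutoff: empty sphere
  toy2 <- make_toy_crystal(n_res = 8, metal = list(n_oxygens = 3,
                                                   distance = 4.0))
  mc2 <- find_metal_coordination(toy2$structure, cutoff = 3.0)
  expect_equal(unname(attr(mc2, "coordination")), 0)
  expect_equal(nrow(mc2), 0)
})

test_that("contact_table pivots records into a residue-by-complex matrix", {
  empty <- contact_table(ipolectin:::.empty_contacts())
  expect_equal(nrow(empty), 0)
  expect_match(attr(empty, "tsv")[1], "atom")
  toyA <- make_toy_crystal(n_res = 10, ligand = list(distance = 2.9))
  toyB <- make_toy_crystal(n_res = 10, ligand = list(distance = 3.1))
  recs <- list(
    "Me-Glc" = find_hbonds(toyA$structure, toyA$selections$protein,
                           toyA$selections$ligand),
    "Me-Man" = find_hbonds(toyB$structure, toyB$selections$protein,
                           toyB$selections$ligand))
  tab <- contact_table(recs)
  expect_equal(colnames(tab), c("Me-Glc", "Me-Man"))
  expect_equal(nrow(tab), 1)  # same designed pocket atom in both
  expect_match(tab[1, "Me-Glc"], "O5, 2.9 A")
  expect_match(tab[1, "Me-Man"], "O5, 3.1 A")
})
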