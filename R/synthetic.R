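# Synthetic fixtures with known ground truth: toy crystal structures with
# designed contacts, simulated titrations, and SEC standards. Everything
# is deterministic for a fixed seed, so tests never need external files.

.toy_backbone <- function(n_res, origin = c(0, 0, 0), chain = "A",
                          serial0 = 0L, resno0 = 0L) {
  # idealized extended backbone: 3.8 A CA spacing along +x, all glycine
  rows <- list()
  for (i in seq_len(n_res)) {
    bx <- origin[1] + 3.8 * (i - 1)
    rows[[i]] <- data.frame(
      name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      x = bx + c(-1.45, 0, 1.2, 1.2),
      y = origin[2] + c(0.5, 0, 0.9, 2.13),
      z = origin[3],
      resno = resno0 + i,
      stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  data.frame(serial = serial0 + seq_len(nrow(at)), name = at$name,
             element = at$element, resname = "GLY", resno = at$resno,
             chain = chain, x = at$x, y = at$y, z = at$z,
             occ = 1, b = 20, het = FALSE, stringsAsFactors = FALSE)
}

# idealized planar indole: 6-ring regular hexagon (1.40 A bonds) fused to
# the pyrrole 5-ring, lying in the z = origin[3] plane
.toy_indole <- function(origin, chain, resno, serial0) {
  # hexagon vertices at 0..300 deg; the CD2-CE2 fusion edge faces +y
  hex_ang <- c(0, 60, 120, 180, 240, 300) * pi / 180
  six <- data.frame(
    name = c("CE3", "CD2", "CE2", "CZ2", "CH2", "CZ3"),
    x = 1.40 * cos(hex_ang), y = 1.40 * sin(hex_ang),
    stringsAsFactors = FALSE)
  r5 <- 1.40 / (2 * sin(36 * pi / 180))
  c5y <- 1.40 * sin(60 * pi / 180) + r5 * cos(36 * pi / 180)
  pent_ang <- c(18, 90, 162) * pi / 180  # CG, CD1, NE1
  five <- data.frame(
    name = c("CG", "CD1", "NE1"),
    x = r5 * cos(pent_ang), y = c5y + r5 * sin(pent_ang),
    stringsAsFactors = FALSE)
  at <- rbind(six, five)
  at$element <- ifelse(at$name == "NE1", "N", "C")
  ca <- data.frame(name = "CA", x = 2.5, y = -1.5, element = "C",
                   stringsAsFactors = FALSE)
  at <- rbind(at, ca)
  data.frame(serial = serial0 + seq_len(nrow(at)), name = at$name,
             element = at$element, resname = "TRP", resno = resno,
             chain = chain, x = origin[1] + at$x, y = origin[2] + at$y,
             z = origin[3], occ = 1, b = 20, het = FALSE,
             stringsAsFactors = FALSE)
}

#' Generate a toy crystal structure with designed contacts
#'
#' Builds a small glycine chain with idealized backbone geometry
#' (3.8 Angstrom CA spacing) inside a chosen unit cell, optionally adding:
#' a pyranoside-like ligand whose O5 acceptor sits at a designed distance
#' from a chosen backbone nitrogen; a metal ion with `k` water oxygens at
#' 2.3 Angstrom; a tryptophan ring with the ligand methyl carbon C7 at a
#' designed elevation above the six-ring centroid; and a placement such
#' that one space-group operator generates a symmetry mate in contact with
#' the chain. The returned ground truth lists every designed hydrogen
#' bond, methyl-pi and coordination contact; the construction guarantees
#' no other donor-acceptor pair approaches the hydrogen-bond cutoff.
#'
#' Deterministic: regenerating with the same arguments gives byte-identical
#' PDB text ([write_pdb]).
#'
#' @param n_res Number of backbone residues (default 15).
#' @param cell A [unit_cell] (default 100 Angstrom cube).
#' @param space_group Space-group symbol (default "P1").
#' @param ligand `NULL` or a list with `distance` (N...O5 Angstrom,
#'   default 2.9) and `attach_resno` (default middle residue).
#' @param metal `NULL` or list with `n_oxygens` (default 5) and `distance`
#'   (default 2.3).
#' @param me_pi `NULL` or list with `distance` (C7 height above the
#'   tryptophan six-ring centroid, default 3.8).
#' @param symmetry_contact `NULL` or list with `op` (triplet string, must
#'   belong to the space group, default "X,-Y,-Z") and `distance`
#'   (closest approach to the mate, default 3.5).
#' @param hbond_cutoff Cutoff the designed geometry is validated against
#'   (default 3.5).
#' @return List with `structure` (a [crystal_structure]), `truth` (lists
#'   `hbonds`, `me_pi`, `metal_coord` data frames and `assembly_size`),
#'   and `selections` (protein/ligand row indices).
#' @export
make_toy_crystal <- function(n_res = 15,
                             cell = unit_cell(100, 100, 100),
                             space_group = "P1",
                             ligand = NULL, metal = NULL, me_pi = NULL,
                             symmetry_contact = NULL,
                             hbond_cutoff = 3.5) {
  if (!is.null(symmetry_contact)) {
    sc_op <- symmetry_contact$op %||% "X,-Y,-Z"
    sc_d <- symmetry_contact$distance %||% 3.5
    # chain CA row sits at y = d/2 so the mate under y -> -y approaches to d
    origin <- c(15, sc_d / 2, 0)
  } else {
    origin <- c(5, 5, 5)
  }
  atoms <- .toy_backbone(n_res, origin)
  truth_h <- .empty_contacts()
  truth_m <- .empty_contacts()
  truth_p <- .empty_contacts()

  lig_rows <- NULL
  if (!is.null(ligand)) {
    d <- ligand$distance %||% 2.9
    k <- ligand$attach_resno %||% ceiling(n_res / 2)
    rmin <- .vdw_radii[["N"]] + .vdw_radii[["O"]] - 0.5
    if (d < rmin) {
      stop(sprintf("unphysical fixture: N...O5 distance %.2f below %.2f",
                   d, rmin))
    }
    ai <- which(atoms$resno == k & atoms$name == "N")
    p <- c(atoms$x[ai], atoms$y[ai], atoms$z[ai])
    # O5 straight above the donor; the rest of the pyranoside stacked
    # higher so only the designed pair is inside the cutoff
    lig <- data.frame(
      name = c("O5", "C1", "C2", "C3", "C4", "C5", "O1", "O2", "O3",
               "O4", "O6", "C6", "C7"),
      element = c("O", "C", "C", "C", "C", "C", "O", "O", "O", "O", "O",
                  "C", "C"),
      dx = c(0, 0.9, 1.3, 0.6, -0.8, -1.2, 1.9, 2.5, 1.2, -1.5, -2.3,
             -1.9, 2.6),
      dy = c(0, 0.9, 0.2, -0.9, -0.9, 0.4, 1.7, 0.4, -1.9, -1.8, 0.9,
             1.5, 1.8),
      dz = d + c(0, 1.1, 2.4, 3.1, 2.6, 1.4, 1.5, 2.9, 3.8, 3.1, 1.8,
                 1.6, 1.4),
      stringsAsFactors = FALSE)
    lig_rows <- data.frame(
      serial = max(atoms$serial) + seq_len(nrow(lig)), name = lig$name,
      element = lig$element, resname = "LIG", resno = 201L, chain = "A",
      x = p[1] + lig$dx, y = p[2] + lig$dy, z = p[3] + lig$dz,
      occ = 1, b = 30, het = TRUE, stringsAsFactors = FALSE)
    truth_h <- rbind(truth_h, data.frame(
      kind = "hbond", chain_1 = "A", res_1 = "GLY", resno_1 = k,
      atom_1 = "N", chain_2 = "A", res_2 = "LIG", resno_2 = 201L,
      atom_2 = "O5", distance = round(d, 1), distance_exact = d,
      stringsAsFactors = FALSE))
  }

  trp_rows <- NULL
  if (!is.null(me_pi)) {
    dz <- me_pi$distance %||% 3.8
    trp_origin <- origin + c(3.8 * (n_res - 1) / 2, 14, 0)
    trp_rows <- .toy_indole(trp_origin, "A", n_res + 1L,
                            max(atoms$serial,
                                if (!is.null(lig_rows)) lig_rows$serial else 0))
    # C7 above the six-ring centroid (hexagon centred at trp_origin)
    c7 <- data.frame(serial = max(trp_rows$serial) + 1L, name = "C7",
                     element = "C", resname = "LIG", resno = 201L,
                     chain = "A", x = trp_origin[1], y = trp_origin[2],
                     z = trp_origin[3] + dz, occ = 1, b = 30, het = TRUE,
                     stringsAsFactors = FALSE)
    ring6 <- trp_rows[trp_rows$name %in% c("CE3", "CD2", "CE2", "CZ2",
                                           "CH2", "CZ3"), ]
    ring5 <- trp_rows[trp_rows$name %in% c("CG", "CD1", "NE1", "CE2",
                                           "CD2"), ]
    c6 <- colMeans(ring6[, c("x", "y", "z")])
    c5 <- colMeans(ring5[, c("x", "y", "z")])
    d6 <- sqrt(sum((c(c7$x, c7$y, c7$z) - c6)^2))
    d5 <- sqrt(sum((c(c7$x, c7$y, c7$z) - c5)^2))
    mk <- function(ring_name, dist) data.frame(
      kind = "me_pi", chain_1 = "A", res_1 = "LIG", resno_1 = 201L,
      atom_1 = "C7", chain_2 = "A", res_2 = "TRP",
      resno_2 = n_res + 1L, atom_2 = ring_name,
      distance = round(dist, 1), distance_exact = dist,
      stringsAsFactors = FALSE)
    truth_p <- rbind(truth_p, mk("ring6", d6))
    # both centroids of the coplanar indole can satisfy the criterion
    if (d5 <= 4.5 && asin(dz / d5) * 180 / pi >= 30) {
      truth_p <- rbind(truth_p, mk("ring5", d5))
    }
    if (is.null(lig_rows)) lig_rows <- c7 else lig_rows <- rbind(lig_rows, c7)
  }

  met_rows <- NULL
  if (!is.null(metal)) {
    k <- metal$n_oxygens %||% 5
    dm <- metal$distance %||% 2.3
    mp <- origin + c(3.8 * (n_res - 1) / 2, -12, 0)
    dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))[seq_len(min(k, 6)), , drop = FALSE]
    s0 <- max(atoms$serial, if (!is.null(lig_rows)) lig_rows$serial else 0,
              if (!is.null(trp_rows)) trp_rows$serial else 0)
    met_rows <- data.frame(
      serial = s0 + 1L, name = "CD", element = "CD", resname = "CD",
      resno = 301L, chain = "A", x = mp[1], y = mp[2], z = mp[3],
      occ = 1, b = 25, het = TRUE, stringsAsFactors = FALSE)
    wat <- data.frame(
      serial = s0 + 1L + seq_len(nrow(dirs)), name = "O", element = "O",
      resname = "HOH", resno = 400L + seq_len(nrow(dirs)), chain = "A",
      x = mp[1] + dm * dirs[, 1], y = mp[2] + dm * dirs[, 2],
      z = mp[3] + dm * dirs[, 3], occ = 1, b = 30, het = TRUE,
      stringsAsFactors = FALSE)
    met_rows <- rbind(met_rows, wat)
    truth_m <- rbind(truth_m, data.frame(
      kind = "metal_coord", chain_1 = "A", res_1 = "CD", resno_1 = 301L,
      atom_1 = "CD", chain_2 = "A", res_2 = "HOH",
      resno_2 = 400L + seq_len(nrow(dirs)), atom_2 = "O",
      distance = round(dm, 1), distance_exact = dm,
      stringsAsFactors = FALSE))
  }

  atoms <- rbind(atoms, trp_rows, lig_rows, met_rows)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  st <- structure(list(atoms = atoms, cell = cell,
                       space_group = list(
                         symbol = .normalize_sg_symbol(space_group),
                         ops = space_group_ops(space_group)),
                       chains = unique(atoms$chain)),
                  class = "crystal_structure")

  # defensive check: no undesigned protein-ligand donor/acceptor approach
  if (!is.null(ligand)) {
    prot <- which(!atoms$het)
    lig <- which(atoms$resname == "LIG")
    found <- suppressWarnings(
      find_hbonds(atoms, prot, lig, cutoff = hbond_cutoff))
    if (nrow(found) != nrow(truth_h)) {
      stop("internal: toy geometry produced undesigned contacts")
    }
  }

  assembly_size <- if (!is.null(symmetry_contact)) 2L else 1L
  list(structure = st,
       truth = list(hbonds = truth_h, me_pi = truth_p,
                    metal_coord = truth_m, assembly_size = assembly_size),
       selections = list(protein = which(!atoms$het),
                         ligand = which(atoms$resname == "LIG"),
                         metal = which(atoms$element == "CD")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic ITC dataset with recorded truth
#'
#' Wraps [simulate_titration] with the standard iTC200 protocol (280 ul
#' cell, 18 x 2 ul injections, 25 C); the noise level is specified as a
#' fraction of the first-injection heat so it scales with the signal.
#'
#' @param K_A Association constant, M^-1.
#' @param n Stoichiometry.
#' @param dH Binding enthalpy, kcal/mol.
#' @param protocol An [itc_protocol].
#' @param noise_frac Noise sd as a fraction of the noise-free
#'   first-injection heat (default 0).
#' @param seed Integer seed.
#' @return List with `data` (an `itc_data`) and `truth`.
#' @export
make_itc_dataset <- function(K_A = 7040, n = 1, dH = -5.56,
                             protocol = itc_protocol(), noise_frac = 0,
                             seed = NULL) {
  clean <- simulate_titration(K_A, n, dH, protocol)
  noise_sd <- noise_frac * abs(clean$heats[1])
  data <- if (noise_sd > 0) {
    simulate_titration(K_A, n, dH, protocol, noise_sd = noise_sd,
                       seed = seed)
  } else {
    clean
  }
  list(data = data,
       truth = list(K_A = K_A, n = n, dH = dH, noise_sd = noise_sd))
}

#' Generate synthetic SEC calibration standards
#'
#' Elution volumes are placed on a chosen truth line
#' `log10(kDa) = intercept + slope * ml`, plus Gaussian noise in ml.
#'
#' @param slope Truth slope, per ml (must be negative).
#' @param intercept Truth intercept, log10(kDa).
#' @param masses Marker masses in kDa (default the Bio-Rad standard set).
#' @param noise_sd_ml Gaussian noise on elution volumes, ml.
#' @param seed Integer seed.
#' @return List with `standards` (data frame `mass_kda`, `elution_ml`)
#'   and `truth`.
#' @export
make_sec_standards <- function(slope = -0.0423, intercept = 5.1333,
                               masses = biorad_standard_masses,
                               noise_sd_ml = 0, seed = NULL) {
  if (slope >= 0) stop("slope must be negative for a physical column")
  elution <- (log10(masses) - intercept) / slope
  if (noise_sd_ml > 0) {
    if (!is.null(seed)) set.seed(seed)
    elution <- elution + stats::rnorm(length(elution), 0, noise_sd_ml)
  }
  list(standards = data.frame(mass_kda = unname(masses),
                              elution_ml = unname(elution)),
       truth = list(slope = slope, intercept = intercept))
}
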