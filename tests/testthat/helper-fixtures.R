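# shared fixture builders; everything is generated in code, no data files

atom_df <- function(name, element, x, y, z, resname = "LIG", resno = 1L,
                    chain = "A", het = TRUE) {
  data.frame(serial = seq_along(name), name = name, element = element,
             resname = resname, resno = as.integer(resno), chain = chain,
             x = x, y = y, z = z, occ = 1, b = 0, het = het,
             stringsAsFactors = FALSE)
}

backbone_chain <- function(n_res, origin = c(0, 0, 0), chain = "A") {
  ipolectin:::.toy_backbone(n_res, origin, chain = chain)
}

as_structure <- function(atoms, cell = NULL, space_group = NULL) {
  sg <- if (!is.null(space_group)) {
    list(symbol = space_group, ops = space_group_ops(space_group))
  }
  structure(list(atoms = atoms, cell = cell, space_group = sg,
                 chains = unique(atoms$chain)),
            class = "crystal_structure")
}

# independent brute-force hydrogen-bond oracle: plain double loop over all
# atom pairs, donor/acceptor roles looked up directly in the dictionary
brute_force_hbonds <- function(atoms, ia, ib, cutoff = 3.5) {
  dict <- donor_acceptor_dictionary(unique(atoms$resname))
  is_role <- function(i, what) {
    dd <- dict[[toupper(atoms$resname[i])]]
    !is.null(dd) && atoms$name[i] %in% dd[[what]]
  }
  hits <- list()
  for (i in ia) for (j in ib) {
    if (atoms$chain[i] == atoms$chain[j] &&
        atoms$resno[i] == atoms$resno[j]) next
    d <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                (atoms$z[i] - atoms$z[j])^2)
    if (d > cutoff) next
    if ((is_role(i, "donors") && is_role(j, "acceptors")) ||
        (is_role(j, "donors") && is_role(i, "acceptors"))) {
      hits[[length(hits) + 1]] <- c(i, j, d)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  }
  m <- do.call(rbind, hits)
  data.frame(i = m[, 1], j = m[, 2], d = m[, 3])
}

# canonical unordered pair keys of a contact table, for set comparisons
contact_keys <- function(tab) {
  if (nrow(tab) == 0) return(character(0))
  a <- paste(tab$chain_1, tab$resno_1, tab$atom_1)
  b <- paste(tab$chain_2, tab$resno_2, tab$atom_2)
  sort(paste(pmin(a, b), pmax(a, b)))
}

# reference SASA total via biotite's independent Shrake-Rupley, using the
# same radii so only the implementations differ
biotite_sasa_total <- function(atoms, probe = 1.4, n_points = 960) {
  st <- as_structure(atoms)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  write_pdb(st, tf)
  radii <- ipolectin:::.vdw_radii
  rad_py <- paste(sprintf('"%s":%.2f', names(radii), radii), collapse = ",")
  py <- sprintf(paste0(
    "import biotite.structure.io.pdb as pdb, biotite.structure as bs, ",
    "numpy as np\n",
    "f = pdb.PDBFile.read(%s)\n",
    "arr = f.get_structure(model=1)\n",
    "radii = {%s}\n",
    "vr = np.array([radii.get(e, 1.70) for e in arr.element])\n",
    "s = bs.sasa(arr, probe_radius=%f, point_number=%d, vdw_radii=vr)\n",
    "print(float(np.nansum(s)))\n"), deparse(tf), rad_py, probe, n_points)
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE,
                 stderr = FALSE)
  as.numeric(out[length(out)])
}

random_rigid_motion <- function(atoms) {
  ang <- stats::runif(3, 0, 2 * pi)
  rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
  ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, byrow = TRUE)
  rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0,
                 sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, byrow = TRUE)
  R <- rx %*% ry %*% rz
  t <- stats::runif(3, -20, 20)
  xyz <- t(R %*% t(as.matrix(atoms[, c("x", "y", "z")]))) +
    rep(t, each = nrow(atoms))
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}
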