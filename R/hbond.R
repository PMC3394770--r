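# Heavy-atom contact geometry: hydrogen bonds, methyl-pi contacts and
# metal coordination. The deposited lectin structures contain no
# hydrogens, so the criteria are distance-based on donor/acceptor heavy
# atoms (no angle term at the donor).

# donor / acceptor heavy atoms per standard residue; backbone N donates
# (except proline) and backbone O accepts for every residue.
.sidechain_da <- list(
  SER = list(d = "OG", a = "OG"),
  THR = list(d = "OG1", a = "OG1"),
  TYR = list(d = "OH", a = "OH"),
  CYS = list(d = "SG", a = character(0)),
  TRP = list(d = "NE1", a = character(0)),
  HIS = list(d = c("ND1", "NE2"), a = c("ND1", "NE2")),
  ASN = list(d = "ND2", a = "OD1"),
  GLN = list(d = "NE2", a = "OE1"),
  LYS = list(d = "NZ", a = character(0)),
  ARG = list(d = c("NE", "NH1", "NH2"), a = character(0)),
  ASP = list(d = character(0), a = c("OD1", "OD2")),
  GLU = list(d = character(0), a = c("OE1", "OE2")),
  MET = list(d = character(0), a = "SD")
)

# methyl-pyranoside ligand codes recognized by default (methyl alpha-D-
# manno/gluco/galactopyranosides and their parent sugars, plus the toy
# fixture code).
.sugar_codes <- c("MMA", "AMG", "MGC", "MBG", "GYP", "GLC", "GAL", "MAN",
                  "BGC", "LIG", "PYR")

#' Donor/acceptor dictionary for a set of residue codes
#'
#' Standard residues get backbone N (donor, except proline) and backbone O
#' (acceptor) plus their side-chain donors/acceptors. Pyranoside ligands
#' get the glycosidic O1 and ring O5 as acceptors only and the hydroxyls
#' O2, O3, O4, O6 as both donor and acceptor. Water O is both.
#'
#' @param codes Character vector of residue/ligand codes.
#' @param sugar_codes Codes treated as pyranoside sugars.
#' @return Named list: for each code, list of `donors` and `acceptors`
#'   atom-name vectors. Codes not covered map to `NULL`.
#' @export
donor_acceptor_dictionary <- function(codes,
                                      sugar_codes = .sugar_codes) {
  codes <- unique(toupper(codes))
  out <- stats::setNames(vector("list", length(codes)), codes)
  for (cd in codes) {
    if (cd %in% names(.residue_masses)) {
      sc <- .sidechain_da[[cd]]
      d <- if (cd == "PRO") character(0) else "N"
      a <- "O"
      if (!is.null(sc)) {
        d <- c(d, sc$d)
        a <- c(a, sc$a)
      }
      out[[cd]] <- list(donors = d, acceptors = c(a, "OXT"))
    } else if (cd %in% toupper(sugar_codes)) {
      out[[cd]] <- list(donors = c("O2", "O3", "O4", "O6"),
                        acceptors = c("O1", "O2", "O3", "O4", "O5", "O6"))
    } else if (cd == "HOH") {
      out[[cd]] <- list(donors = "O", acceptors = "O")
    }
  }
  out
}

.atom_label <- function(atoms, i) {
  sprintf("%s/%s%d/%s", atoms$chain[i], atoms$resname[i], atoms$resno[i],
          atoms$name[i])
}

.resolve_selection <- function(atoms, sel) {
  if (is.logical(sel)) return(which(sel))
  if (is.numeric(sel)) return(as.integer(sel))
  if (is.character(sel)) return(which(atoms$chain %in% sel))
  stop("selection must be logical, integer indices, or chain ids")
}

#' Detect hydrogen bonds between two atom selections
#'
#' A contact is reported for every donor-acceptor pair (in either
#' direction) whose heavy-atom distance is at most `cutoff`, excluding
#' pairs within one residue. Distances are carried at full precision and
#' rounded to 0.1 Angstrom only in the `distance` column.
#'
#' @param atoms Atom data frame or [crystal_structure].
#' @param group_a,group_b Disjoint selections: logical mask, integer
#'   indices, or chain ids.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 3.5).
#' @param dictionary Donor/acceptor dictionary; defaults to
#'   [donor_acceptor_dictionary] over the residue codes present. Residues
#'   absent from the dictionary are skipped with a warning.
#' @return Data frame of class `contact_table` with columns `kind`,
#'   `chain_1`, `res_1`, `resno_1`, `atom_1`, `chain_2`, `res_2`,
#'   `resno_2`, `atom_2`, `distance` (rounded 0.1 A), `distance_exact`;
#'   sorted by (resno_1, atom_1, resno_2, atom_2).
#' @export
find_hbonds <- function(atoms, group_a, group_b, cutoff = 3.5,
                        dictionary = NULL) {
  if (inherits(atoms, "crystal_structure")) atoms <- atoms$atoms
  ia <- .resolve_selection(atoms, group_a)
  ib <- .resolve_selection(atoms, group_b)
  if (length(intersect(ia, ib)) > 0) stop("selections must be disjoint")
  if (length(ia) == 0 || length(ib) == 0) return(.empty_contacts())
  if (is.null(dictionary)) {
    dictionary <- donor_acceptor_dictionary(
      unique(atoms$resname[c(ia, ib)]))
  }
  covered <- names(Filter(Negate(is.null), dictionary))
  unknown <- setdiff(unique(toupper(atoms$resname[c(ia, ib)])), covered)
  if (length(unknown) > 0) {
    warning("residues missing from donor/acceptor dictionary, skipped: ",
            paste(unknown, collapse = ", "))
  }

  role <- function(idx, what) {
    vapply(idx, function(i) {
      dd <- dictionary[[toupper(atoms$resname[i])]]
      !is.null(dd) && atoms$name[i] %in% dd[[what]]
    }, TRUE)
  }
  rec <- list()
  da <- ia[role(ia, "donors")]
  aa <- ia[role(ia, "acceptors")]
  db <- ib[role(ib, "donors")]
  ab <- ib[role(ib, "acceptors")]
  pair_up <- function(don, acc) {
    for (i in don) {
      if (length(acc) == 0) next
      d <- sqrt((atoms$x[acc] - atoms$x[i])^2 +
                  (atoms$y[acc] - atoms$y[i])^2 +
                  (atoms$z[acc] - atoms$z[i])^2)
      ok <- which(d <= cutoff &
                    !(atoms$chain[acc] == atoms$chain[i] &
                        atoms$resno[acc] == atoms$resno[i]))
      for (k in ok) {
        rec[[length(rec) + 1]] <<- data.frame(
          kind = "hbond",
          chain_1 = atoms$chain[i], res_1 = atoms$resname[i],
          resno_1 = atoms$resno[i], atom_1 = atoms$name[i],
          chain_2 = atoms$chain[acc[k]], res_2 = atoms$resname[acc[k]],
          resno_2 = atoms$resno[acc[k]], atom_2 = atoms$name[acc[k]],
          distance_exact = d[k], stringsAsFactors = FALSE)
      }
    }
  }
  pair_up(da, ab)
  pair_up(db, aa)
  .finish_contacts(rec)
}

.empty_contacts <- function() {
  out <- data.frame(kind = character(0), chain_1 = character(0),
                    res_1 = character(0), resno_1 = integer(0),
                    atom_1 = character(0), chain_2 = character(0),
                    res_2 = character(0), resno_2 = integer(0),
                    atom_2 = character(0), distance = numeric(0),
                    distance_exact = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("contact_table", "data.frame")
  out
}

.finish_contacts <- function(rec) {
  if (length(rec) == 0) return(.empty_contacts())
  out <- do.call(rbind, rec)
  # donor/acceptor double role can report the same unordered pair twice
  key <- apply(out, 1, function(r) {
    a <- paste(r[["chain_1"]], r[["resno_1"]], r[["atom_1"]])
    b <- paste(r[["chain_2"]], r[["resno_2"]], r[["atom_2"]])
    paste(r[["kind"]], min(a, b), max(a, b))
  })
  out <- out[!duplicated(key), , drop = FALSE]
  out$distance <- round(out$distance_exact, 1)
  out <- out[order(out$resno_1, out$atom_1, out$resno_2, out$atom_2),
             c("kind", "chain_1", "res_1", "resno_1", "atom_1",
               "chain_2", "res_2", "resno_2", "atom_2",
               "distance", "distance_exact")]
  rownames(out) <- NULL
  class(out) <- c("contact_table", "data.frame")
  out
}

# aromatic ring atom sets; TRP contributes both the pyrrole and benzene
# rings, evaluated separately.
.ring_atoms <- list(
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(ring5 = c("CG", "CD1", "NE1", "CE2", "CD2"),
             ring6 = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

.ring_geometry <- function(coords) {
  cen <- colMeans(coords)
  m <- sweep(coords, 2, cen)
  sv <- svd(m)
  normal <- sv$v[, 3]
  list(centroid = cen, normal = normal / sqrt(sum(normal^2)))
}

#' Detect methyl-pi (CH-pi) contacts with aromatic rings
#'
#' A methyl carbon is in contact with an aromatic ring when its distance
#' to the ring centroid is at most `cutoff` and its elevation angle above
#' the ring plane is at least `min_elevation`. Tryptophan contributes both
#' its five- and six-membered ring centroids.
#'
#' @param atoms Atom data frame or [crystal_structure].
#' @param methyl_carbons Selection of candidate methyl carbon atoms.
#' @param aromatic_residues Selection covering the aromatic residues to
#'   test (any atom of the residue selects it).
#' @param cutoff Carbon-centroid distance cutoff (Angstrom, default 4.5).
#' @param min_elevation Minimum elevation angle from the ring plane in
#'   degrees (default 30).
#' @return A `contact_table` with `kind = "me_pi"`; `atom_2` names the
#'   ring ("ring", "ring5", "ring6") and `extra` identifies it.
#' @export
find_me_pi <- function(atoms, methyl_carbons, aromatic_residues,
                       cutoff = 4.5, min_elevation = 30) {
  if (inherits(atoms, "crystal_structure")) atoms <- atoms$atoms
  im <- .resolve_selection(atoms, methyl_carbons)
  ir <- .resolve_selection(atoms, aromatic_residues)
  im <- im[atoms$element[im] == "C"]
  if (length(im) == 0 || length(ir) == 0) return(.empty_contacts())
  res_keys <- unique(paste(atoms$chain[ir], atoms$resno[ir],
                           atoms$resname[ir]))
  rec <- list()
  for (rk in res_keys) {
    parts <- strsplit(rk, " ")[[1]]
    rn <- parts[3]
    if (!rn %in% names(.ring_atoms)) next
    sel <- which(atoms$chain == parts[1] &
                   atoms$resno == as.integer(parts[2]) &
                   atoms$resname == rn)
    for (ring_name in names(.ring_atoms[[rn]])) {
      want <- .ring_atoms[[rn]][[ring_name]]
      ridx <- sel[match(want, atoms$name[sel])]
      if (any(is.na(ridx))) next
      g <- .ring_geometry(as.matrix(atoms[ridx, c("x", "y", "z")]))
      for (i in im) {
        v <- c(atoms$x[i], atoms$y[i], atoms$z[i]) - g$centroid
        d <- sqrt(sum(v^2))
        if (d > cutoff || d < 1e-6) next
        elev <- asin(min(1, abs(sum(v * g$normal)) / d)) * 180 / pi
        if (elev < min_elevation) next
        rec[[length(rec) + 1]] <- data.frame(
          kind = "me_pi",
          chain_1 = atoms$chain[i], res_1 = atoms$resname[i],
          resno_1 = atoms$resno[i], atom_1 = atoms$name[i],
          chain_2 = parts[1], res_2 = rn, resno_2 = as.integer(parts[2]),
          atom_2 = ring_name, distance_exact = d,
          stringsAsFactors = FALSE)
      }
    }
  }
  .finish_contacts(rec)
}

#' Detect metal coordination spheres
#'
#' Reports every O or N atom within `cutoff` of each metal atom in the
#' selection, together with the per-metal coordination number.
#'
#' @param atoms Atom data frame or [crystal_structure].
#' @param metals Selection of metal atoms (default: any atom whose element
#'   is a common metal: Cd, Zn, Mg, Ca, Mn, Fe, Na, K).
#' @param cutoff Coordination distance cutoff (Angstrom, default 3.0).
#' @return A `contact_table` with `kind = "metal_coord"`; the attribute
#'   `coordination` is a named integer vector (one entry per metal atom).
#' @export
find_metal_coordination <- function(atoms, metals = NULL, cutoff = 3.0) {
  if (inherits(atoms, "crystal_structure")) atoms <- atoms$atoms
  if (is.null(metals)) {
    metals <- which(atoms$element %in% c("CD", "ZN", "MG", "CA", "MN",
                                         "FE", "NA", "K"))
  } else {
    metals <- .resolve_selection(atoms, metals)
  }
  rec <- list()
  coord <- integer(0)
  for (i in metals) {
    lig <- which(atoms$element %in% c("O", "N"))
    lig <- setdiff(lig, i)
    d <- sqrt((atoms$x[lig] - atoms$x[i])^2 +
                (atoms$y[lig] - atoms$y[i])^2 +
                (atoms$z[lig] - atoms$z[i])^2)
    ok <- which(d <= cutoff)
    coord[.atom_label(atoms, i)] <- length(ok)
    for (k in ok) {
      rec[[length(rec) + 1]] <- data.frame(
        kind = "metal_coord",
        chain_1 = atoms$chain[i], res_1 = atoms$resname[i],
        resno_1 = atoms$resno[i], atom_1 = atoms$name[i],
        chain_2 = atoms$chain[lig[k]], res_2 = atoms$resname[lig[k]],
        resno_2 = atoms$resno[lig[k]], atom_2 = atoms$name[lig[k]],
        distance_exact = d[k], stringsAsFactors = FALSE)
    }
  }
  out <- .finish_contacts(rec)
  attr(out, "coordination") <- coord
  out
}

#' Pivot contact records into a publication-style table
#'
#' Rows are protein atoms (`chain/RESn/atom`), columns are complex labels,
#' cells list the partner atom and distance ("O5, 2.9 A"; multiple
#' contacts separated by "; ").
#'
#' @param records A `contact_table` or list of them.
#' @param labels Complex label per table (recycled names for a list
#'   input); defaults to "complex_1", ...
#' @return A character matrix with protein-atom rownames, plus TSV lines
#'   in attribute `tsv`.
#' @export
contact_table <- function(records, labels = NULL) {
  if (is.data.frame(records)) records <- list(records)
  if (is.null(labels)) {
    labels <- if (!is.null(names(records))) names(records) else
      paste0("complex_", seq_along(records))
  }
  rows <- character(0)
  cells <- list()
  for (t in seq_along(records)) {
    r <- records[[t]]
    if (nrow(r) > 0) {
      key <- sprintf("%s %s%d %s", r$chain_1, r$res_1, r$resno_1, r$atom_1)
      val <- sprintf("%s %s, %.1f A", r$res_2, r$atom_2, r$distance)
      for (i in seq_along(key)) {
        rows <- union(rows, key[i])
        slot <- paste0(key[i], "\r", labels[t])
        cells[[slot]] <- c(cells[[slot]], val[i])
      }
    }
  }
  m <- matrix("-", nrow = length(rows), ncol = length(labels),
              dimnames = list(rows, labels))
  for (i in seq_along(rows)) for (j in seq_along(labels)) {
    v <- cells[[paste0(rows[i], "\r", labels[j])]]
    if (!is.null(v)) m[i, j] <- paste(v, collapse = "; ")
  }
  tsv <- c(paste(c("atom", labels), collapse = "\t"),
           vapply(seq_len(nrow(m)), function(i)
             paste(c(rows[i], m[i, ]), collapse = "\t"), ""))
  attr(m, "tsv") <- tsv
  m
}
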