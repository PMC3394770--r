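# Supported space groups: operator triplets in International Tables settings.
# Centred groups carry their centring translations expanded explicitly, so
# length(ops) equals the general-position multiplicity.
.space_groups <- list(
  "P 1" = c("X,Y,Z"),
  "P 21" = c("X,Y,Z", "-X,Y+1/2,-Z"),
  "P 21 21 21" = c(
    "X,Y,Z", "X+1/2,-Y+1/2,-Z", "-X,Y+1/2,-Z+1/2", "-X+1/2,-Y,Z+1/2"
  ),
  "C 2 2 21" = c(
    "X,Y,Z", "-X,-Y,Z+1/2", "-X,Y,-Z+1/2", "X,-Y,-Z",
    "X+1/2,Y+1/2,Z", "-X+1/2,-Y+1/2,Z+1/2",
    "-X+1/2,Y+1/2,-Z+1/2", "X+1/2,-Y+1/2,-Z"
  ),
  "I 2 2 2" = c(
    "X,Y,Z", "-X,-Y,Z", "-X,Y,-Z", "X,-Y,-Z",
    "X+1/2,Y+1/2,Z+1/2", "-X+1/2,-Y+1/2,Z+1/2",
    "-X+1/2,Y+1/2,-Z+1/2", "X+1/2,-Y+1/2,-Z+1/2"
  )
)

.normalize_sg_symbol <- function(symbol) {
  s <- toupper(gsub("[[:space:]_]", "", symbol))
  key <- vapply(names(.space_groups), function(k) gsub(" ", "", k), "")
  hit <- match(s, key)
  if (is.na(hit)) {
    stop("unsupported space group '", symbol, "'; supported: ",
         paste(names(.space_groups), collapse = ", "), call. = FALSE)
  }
  names(.space_groups)[hit]
}

#' Space-group operator list
#'
#' Returns the general-position symmetry operators of a supported space
#' group as a list of `symop` objects. Centred lattices (C, I) have their
#' centring translations expanded, so the list length equals the
#' space-group multiplicity used in Matthews-coefficient bookkeeping.
#'
#' @param symbol Space-group symbol, e.g. `"I222"`, `"C2221"`, `"P21"`,
#'   `"P212121"`, `"P1"` (spaces/underscores ignored, case-insensitive).
#' @return List of [symop] objects.
#' @export
#' @examples
#' length(space_group_ops("I222"))  # 8
space_group_ops <- function(symbol) {
  key <- .normalize_sg_symbol(symbol)
  lapply(.space_groups[[key]], parse_symop)
}

#' Unit cell constructor
#'
#' @param a,b,c Cell edge lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @return An object of class `unit_cell`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  v <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(v))) stop("unit cell parameters must be finite")
  if (any(v[1:3] <= 0)) stop("unit cell edges must be positive")
  if (any(v[4:6] <= 0 | v[4:6] >= 180)) {
    stop("unit cell angles must lie in (0, 180) degrees")
  }
  structure(as.list(v), class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.2f b=%.2f c=%.2f  alpha=%.1f beta=%.1f gamma=%.1f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Unit-cell volume
#'
#' General triclinic volume
#' \eqn{V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma
#'  + 2\cos\alpha\cos\beta\cos\gamma}},
#' which reduces to \eqn{abc} for orthorhombic and \eqn{abc\sin\beta} for
#' monoclinic cells.
#'
#' @param cell A [unit_cell].
#' @return Volume in cubic Angstrom.
#' @export
#' @examples
#' cell_volume(unit_cell(87.5, 139.5, 189.9))
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) stop("degenerate unit cell: non-positive volume")
  cell$a * cell$b * cell$c * sqrt(disc)
}

# Orthogonalization matrix (fractional -> Angstrom), a along x convention.
.orth_matrix <- function(cell) {
  al <- cell$alpha * pi / 180
  be <- cell$beta * pi / 180
  ga <- cell$gamma * pi / 180
  v <- cell_volume(cell) / (cell$a * cell$b * cell$c)
  matrix(c(
    cell$a, cell$b * cos(ga), cell$c * cos(be),
    0, cell$b * sin(ga), cell$c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0, 0, cell$c * v / sin(ga)
  ), nrow = 3, byrow = TRUE)
}

.frac_matrix <- function(cell) solve(.orth_matrix(cell))

#' Matthews coefficient
#'
#' Crystal volume per Dalton of protein, \eqn{V_m = V / (N \cdot M)}, where
#' `n_total_chains` is the number of chains in the whole unit cell (chains
#' per asymmetric unit times space-group multiplicity).
#'
#' @param V Unit-cell volume, cubic Angstrom.
#' @param n_total_chains Protein chains in the full unit cell.
#' @param M Monomer mass in Dalton.
#' @return Matthews coefficient in Angstrom^3/Da.
#' @export
#' @examples
#' matthews(cell_volume(unit_cell(87.5, 139.5, 189.9)), 5 * 8, 16510)
matthews <- function(V, n_total_chains, M) {
  if (V <= 0) stop("cell volume must be positive")
  if (n_total_chains <= 0) stop("chain count must be positive")
  if (M <= 0) stop("monomer mass must be positive")
  V / (n_total_chains * M)
}

# 1.66 Da -> g conversion x 0.74 cm^3/g protein partial specific volume.
.VS_CONST <- 1.66 * 0.74

#' Solvent content from the Matthews coefficient
#'
#' \eqn{V_s = 1 - 1.2284 / V_m}, using the standard protein partial
#' specific volume of 0.74 cm^3/g.
#'
#' @param Vm Matthews coefficient, Angstrom^3/Da.
#' @return Solvent fraction in (0, 1).
#' @export
#' @examples
#' solvent_content(3.51)  # ~0.65
solvent_content <- function(Vm) {
  if (Vm <= .VS_CONST) stop("solvent fraction non-positive (Vm <= 1.2284)")
  1 - .VS_CONST / Vm
}

# Average (free amino acid) residue masses, Da.
.residue_masses <- c(
  ALA = 89.09, ARG = 174.20, ASN = 132.12, ASP = 133.10, CYS = 121.16,
  GLU = 147.13, GLN = 146.15, GLY = 75.07, HIS = 155.15, ILE = 131.17,
  LEU = 131.17, LYS = 146.19, MET = 149.21, PHE = 165.19, PRO = 115.13,
  SER = 105.09, THR = 119.12, TRP = 204.23, TYR = 181.19, VAL = 117.15
)
.WATER_MASS <- 18.02

#' Polypeptide mass from a residue sequence
#'
#' Sum of free amino-acid average masses minus one water per peptide bond.
#' Unknown residue codes are excluded from the sum and reported in the
#' `unknown` attribute (with a warning).
#'
#' @param residues Character vector of 3-letter residue codes, or a
#'   `crystal_structure` (the residue sequence of `chain` is used).
#' @param chain For a structure input, which chain to weigh (default: the
#'   longest protein chain).
#' @return Mass in Dalton, with attribute `unknown` listing skipped codes.
#' @export
#' @examples
#' chain_mass(c("GLY", "GLY"))  # 132.12
chain_mass <- function(residues, chain = NULL) {
  if (inherits(residues, "crystal_structure")) {
    at <- residues$atoms[!residues$atoms$het, , drop = FALSE]
    if (nrow(at) == 0) stop("structure has no protein atoms")
    if (is.null(chain)) {
      chain <- names(which.max(table(at$chain)))
    }
    at <- at[at$chain == chain, , drop = FALSE]
    residues <- at$resname[!duplicated(at$resno)]
  }
  residues <- toupper(residues)
  known <- residues %in% names(.residue_masses)
  if (any(!known)) {
    warning("unknown residue codes excluded from mass: ",
            paste(unique(residues[!known]), collapse = ", "))
  }
  res <- residues[known]
  if (length(res) == 0) stop("no standard residues in sequence")
  m <- sum(.residue_masses[res]) - (length(res) - 1) * .WATER_MASS
  attr(m, "unknown") <- unique(residues[!known])
  m
}

#' Crystal summary: Matthews coefficient and solvent content
#'
#' @param structure A [crystal_structure] with a unit cell and space group.
#' @param n_chains_asym Chains per asymmetric unit (default: number of
#'   protein chains present in the file).
#' @param monomer_mass Monomer mass in Da (default: [chain_mass] of the
#'   longest protein chain).
#' @return A list of class `crystal_summary` with `cell_volume`,
#'   `n_chains_asym`, `multiplicity`, `monomer_mass`, `matthews`,
#'   `solvent_fraction`.
#' @export
crystal_summary <- function(structure, n_chains_asym = NULL,
                            monomer_mass = NULL) {
  stopifnot(inherits(structure, "crystal_structure"))
  if (is.null(structure$cell)) stop("cell required: structure has no CRYST1")
  if (is.null(structure$space_group)) stop("space group required")
  if (is.null(n_chains_asym)) {
    n_chains_asym <- length(unique(structure$atoms$chain[!structure$atoms$het]))
  }
  if (is.null(monomer_mass)) monomer_mass <- as.numeric(chain_mass(structure))
  V <- cell_volume(structure$cell)
  mult <- length(structure$space_group$ops)
  vm <- matthews(V, n_chains_asym * mult, monomer_mass)
  structure(list(
    cell_volume = V, n_chains_asym = n_chains_asym, multiplicity = mult,
    monomer_mass = monomer_mass, matthews = vm,
    solvent_fraction = solvent_content(vm)
  ), class = "crystal_summary")
}

#' @export
print.crystal_summary <- function(x, ...) {
  cat(sprintf("V = %.0f A^3, %d chains x %d ops, M = %.0f Da\n",
              x$cell_volume, x$n_chains_asym, x$multiplicity, x$monomer_mass))
  cat(sprintf("Vm = %.2f A^3/Da, solvent content = %.1f%%\n",
              x$matthews, 100 * x$solvent_fraction))
  invisible(x)
}

.parse_num_field <- function(s, lineno, what, allow_blank = FALSE) {
  s2 <- trimws(s)
  if (s2 == "") {
    if (allow_blank) return(NA_real_)
    stop(sprintf("parse error at line %d: blank %s field", lineno, what),
         call. = FALSE)
  }
  v <- suppressWarnings(as.numeric(s2))
  if (is.na(v)) {
    stop(sprintf("parse error at line %d: bad %s field '%s'", lineno, what, s2),
         call. = FALSE)
  }
  v
}

.guess_element <- function(name) {
  # PDB v2 files often lack columns 77-78; fall back on the atom name.
  nm <- gsub("[0-9']", "", trimws(name))
  if (nchar(nm) >= 2 && toupper(nm) %in% c("CD", "ZN", "CA", "MG", "MN",
                                           "FE", "NA", "CL", "SE")) {
    # only trust 2-letter metals when the raw name starts in column 13
    return(toupper(nm))
  }
  toupper(substr(nm, 1, 1))
}

#' Parse a PDB-format coordinate file
#'
#' Reads fixed-column `ATOM`/`HETATM` records plus the optional `CRYST1`
#' record. Alternate locations are collapsed to the conformer with the
#' highest occupancy (ties: first altloc label alphabetically). Waters
#' (`HOH`) and any `HETATM` residue are flagged as hetero.
#'
#' @param x Path to a PDB file, or a character vector of PDB lines (a
#'   single string is split on newlines).
#' @return A `crystal_structure`: list with `atoms` (data frame), `cell`
#'   ([unit_cell] or `NULL`), `space_group` (list of `symbol`, `ops`, or
#'   `NULL`), `chains` (ordered chain ids).
#' @export
parse_pdb <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records found")

  cell <- NULL
  sg <- NULL
  icr <- which(rec == "CRYST1")
  if (length(icr) > 0) {
    l <- lines[icr[1]]
    n <- icr[1]
    cell <- unit_cell(
      .parse_num_field(substr(l, 7, 15), n, "a"),
      .parse_num_field(substr(l, 16, 24), n, "b"),
      .parse_num_field(substr(l, 25, 33), n, "c"),
      .parse_num_field(substr(l, 34, 40), n, "alpha"),
      .parse_num_field(substr(l, 41, 47), n, "beta"),
      .parse_num_field(substr(l, 48, 54), n, "gamma")
    )
    sym <- trimws(substr(l, 56, 66))
    if (nzchar(sym)) {
      sg <- list(symbol = .normalize_sg_symbol(sym),
                 ops = space_group_ops(sym))
    }
  }

  idx <- which(is_atom)
  nl <- length(idx)
  ln <- lines[idx]
  if (any(nchar(ln) < 54)) {
    bad <- idx[which(nchar(ln) < 54)[1]]
    stop(sprintf("parse error at line %d: truncated atom record", bad),
         call. = FALSE)
  }
  serial <- vapply(seq_len(nl), function(i)
    .parse_num_field(substr(ln[i], 7, 11), idx[i], "serial"), 0)
  name <- trimws(substr(ln, 13, 16))
  altloc <- substr(ln, 17, 17)
  resname <- trimws(substr(ln, 18, 20))
  chain <- substr(ln, 22, 22)
  resno <- vapply(seq_len(nl), function(i)
    .parse_num_field(substr(ln[i], 23, 26), idx[i], "residue number"), 0)
  xyz <- vapply(seq_len(nl), function(i) c(
    .parse_num_field(substr(ln[i], 31, 38), idx[i], "x"),
    .parse_num_field(substr(ln[i], 39, 46), idx[i], "y"),
    .parse_num_field(substr(ln[i], 47, 54), idx[i], "z")), numeric(3))
  occ <- vapply(seq_len(nl), function(i)
    .parse_num_field(substr(ln[i], 55, 60), idx[i], "occupancy"), 0)
  bfac <- vapply(seq_len(nl), function(i)
    .parse_num_field(substr(ln[i], 61, 66), idx[i], "B-factor",
                     allow_blank = TRUE), 0)
  elem <- trimws(substr(ln, 77, 78))
  miss <- !nzchar(elem)
  if (any(miss)) elem[miss] <- vapply(name[miss], .guess_element, "")
  if (any(occ < 0 | occ > 1)) {
    bad <- idx[which(occ < 0 | occ > 1)[1]]
    stop(sprintf("parse error at line %d: occupancy outside [0,1]", bad),
         call. = FALSE)
  }

  atoms <- data.frame(
    serial = as.integer(serial), name = name, element = toupper(elem),
    resname = resname, resno = as.integer(resno), chain = chain,
    x = xyz[1, ], y = xyz[2, ], z = xyz[3, ],
    occ = occ, b = ifelse(is.na(bfac), 0, bfac),
    het = rec[idx] == "HETATM" | resname == "HOH",
    altloc = altloc,
    stringsAsFactors = FALSE
  )

  # altloc collapse: highest occupancy wins, ties to first label.
  if (any(atoms$altloc != " ")) {
    key <- paste(atoms$chain, atoms$resno, atoms$resname, atoms$name)
    keep <- rep(TRUE, nrow(atoms))
    for (k in unique(key[atoms$altloc != " "])) {
      grp <- which(key == k)
      if (length(grp) > 1) {
        ord <- grp[order(-atoms$occ[grp], atoms$altloc[grp])]
        keep[setdiff(grp, ord[1])] <- FALSE
      }
    }
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL
  }
  atoms$altloc <- NULL

  structure(list(atoms = atoms, cell = cell, space_group = sg,
                 chains = unique(atoms$chain)),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("crystal structure: %d atoms, chains %s\n",
              nrow(x$atoms), paste(x$chains, collapse = " ")))
  if (!is.null(x$cell)) print(x$cell)
  if (!is.null(x$space_group)) {
    cat(sprintf("space group %s (%d operators)\n",
                x$space_group$symbol, length(x$space_group$ops)))
  }
  invisible(x)
}

#' Write a structure as PDB-format text
#'
#' Emits standard 80-column `CRYST1`, `ATOM`/`HETATM` and `END` records.
#'
#' @param structure A [crystal_structure].
#' @param path Optional file path; if `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the character
#'   vector of PDB lines.
#' @export
write_pdb <- function(structure, path = NULL) {
  stopifnot(inherits(structure, "crystal_structure"))
  out <- character(0)
  if (!is.null(structure$cell)) {
    cl <- structure$cell
    sym <- if (!is.null(structure$space_group)) {
      structure$space_group$symbol
    } else "P 1"
    out <- c(out, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
      cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma, sym, 1L))
  }
  a <- structure$atoms
  nm <- ifelse(nchar(a$name) < 4 & nchar(a$element) == 1,
               paste0(" ", a$name), a$name)
  out <- c(out, sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$het, "HETATM", "ATOM"), a$serial %% 100000L, nm, " ",
    a$resname, a$chain, a$resno %% 10000L, " ",
    a$x, a$y, a$z, a$occ, a$b, a$element))
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
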