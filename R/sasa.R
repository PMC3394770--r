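# Shrake-Rupley solvent-accessible surface area and PISA-style buried
# interfaces.

# NACCESS-style van der Waals radii (Angstrom); unknown elements fall back
# to 1.70.
.vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  CD = 1.58, ZN = 1.39, MG = 1.73, CA = 1.97, MN = 1.73, FE = 1.70,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)
.VDW_DEFAULT <- 1.70

#' Van der Waals radii used for surface calculations
#'
#' @param elements Character vector of element symbols.
#' @param strict If `TRUE`, unknown elements are an error; otherwise they
#'   receive the default 1.70 Angstrom.
#' @return Numeric vector of radii (Angstrom).
#' @export
vdw_radius <- function(elements, strict = FALSE) {
  el <- toupper(elements)
  r <- .vdw_radii[el]
  if (any(is.na(r))) {
    if (strict) {
      stop("no van der Waals radius for element(s): ",
           paste(unique(el[is.na(r)]), collapse = ", "))
    }
    r[is.na(r)] <- .VDW_DEFAULT
  }
  unname(r)
}

# Deterministic quasi-uniform unit-sphere points (Fibonacci lattice).
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, a quasi-uniform Fibonacci lattice of `n_points` test
#' points is placed on the sphere of radius \eqn{r_{vdw} + probe}; the
#' accessible fraction (points not inside any neighbour's expanded sphere)
#' times the sphere area gives the per-atom SASA. Deterministic: no random
#' number generation is involved.
#'
#' @param atoms Atom data frame (as in a [crystal_structure]); hydrogens
#'   and waters should be excluded upstream.
#' @param probe Probe radius in Angstrom (1.4 = water).
#' @param n_points Sphere sampling count (default 960).
#' @param strict_elements Error on elements without a tabulated radius.
#' @return A `sasa_result`: list with `per_atom` (Angstrom^2, file order),
#'   `per_residue` (named by "chain resno resname"), `total`,
#'   `probe_radius`, `n_points`.
#' @export
#' @examples
#' a <- data.frame(serial = 1L, name = "C", element = "C", resname = "LIG",
#'                 resno = 1L, chain = "A", x = 0, y = 0, z = 0,
#'                 occ = 1, b = 0, het = TRUE)
#' sasa(a)$total  # 4*pi*(1.70+1.4)^2
sasa <- function(atoms, probe = 1.4, n_points = 960, strict_elements = FALSE) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  rad <- vdw_radius(atoms$element, strict = strict_elements) + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- .fibonacci_sphere(n_points)
  per_atom <- numeric(n)
  # neighbour lists via squared-distance threshold
  maxr <- max(rad)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    sp <- pts * rad[i]
    sp[, 1] <- sp[, 1] + xyz[i, 1]
    sp[, 2] <- sp[, 2] + xyz[i, 2]
    sp[, 3] <- sp[, 3] + xyz[i, 3]
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      # boundary ties (a point exactly on a neighbour's surface) go to the
      # lower-index atom, so exactly coincident spheres keep one sphere's
      # worth of area between them instead of two or zero
      buried <- dj2 < rad[j]^2 - 1e-9 | (dj2 < rad[j]^2 + 1e-9 & j < i)
      acc <- acc & !buried
    }
    per_atom[i] <- sum(acc) / n_points * 4 * pi * rad[i]^2
  }
  key <- paste(atoms$chain, atoms$resno, atoms$resname)
  per_residue <- tapply(per_atom, factor(key, levels = unique(key)), sum)
  structure(list(per_atom = per_atom,
                 per_residue = per_residue[unique(key)],
                 total = sum(per_atom),
                 probe_radius = probe, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA: %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$per_atom), x$probe_radius, x$n_points))
  invisible(x)
}

#' Buried interface between two chains
#'
#' PISA-convention interface area,
#' \eqn{(SASA(A) + SASA(B) - SASA(A \cup B)) / 2}, with interface residues
#' defined as those losing more than `residue_threshold` of SASA upon
#' complexation. Waters, ions and other hetero groups are excluded, so the
#' area refers to the protein-protein interface.
#'
#' @param chain_a,chain_b Atom data frames with disjoint chain ids, or a
#'   [crystal_structure] plus chain ids via `chains`.
#' @param probe Probe radius (Angstrom, default 1.4).
#' @param n_points Sphere sampling count.
#' @param residue_threshold Minimum per-residue SASA loss (Angstrom^2) to
#'   call a residue part of the interface (default 0.1).
#' @param chains Optional pair of chain ids when `chain_a` is a
#'   `crystal_structure`.
#' @return An `interface_report`: `chain_pair`, `buried_area`,
#'   `interface_residues` (per-chain data frames of resno, resname,
#'   delta_sasa), `n_interface_hbonds` (NA until filled by the hydrogen
#'   bond module).
#' @export
buried_interface <- function(chain_a, chain_b = NULL, probe = 1.4,
                             n_points = 960, residue_threshold = 0.1,
                             chains = NULL) {
  if (inherits(chain_a, "crystal_structure")) {
    if (is.null(chains) || length(chains) != 2) {
      stop("supply chains = c(id_a, id_b) with a structure input")
    }
    at <- chain_a$atoms
    chain_a <- at[at$chain == chains[1], , drop = FALSE]
    chain_b <- at[at$chain == chains[2], , drop = FALSE]
  }
  chain_a <- chain_a[!chain_a$het & chain_a$element != "H", , drop = FALSE]
  chain_b <- chain_b[!chain_b$het & chain_b$element != "H", , drop = FALSE]
  if (nrow(chain_a) == 0 || nrow(chain_b) == 0) {
    stop("both chains must contain protein atoms")
  }
  ida <- unique(chain_a$chain)
  idb <- unique(chain_b$chain)
  if (any(ida %in% idb)) stop("chain ids must be disjoint")

  sa <- sasa(chain_a, probe, n_points)
  sb <- sasa(chain_b, probe, n_points)
  sab <- sasa(rbind(chain_a, chain_b), probe, n_points)
  buried <- (sa$total + sb$total - sab$total) / 2

  na <- nrow(chain_a)
  iface <- function(free, idx, atoms) {
    key <- paste(atoms$chain, atoms$resno, atoms$resname)
    complexed <- tapply(sab$per_atom[idx], factor(key, levels = unique(key)),
                        sum)[unique(key)]
    d <- as.numeric(free$per_residue) - as.numeric(complexed)
    sel <- which(d > residue_threshold)
    info <- atoms[!duplicated(key), c("chain", "resno", "resname")]
    out <- info[sel, , drop = FALSE]
    out$delta_sasa <- d[sel]
    rownames(out) <- NULL
    out
  }
  res <- list(
    a = iface(sa, seq_len(na), chain_a),
    b = iface(sb, na + seq_len(nrow(chain_b)), chain_b)
  )
  names(res) <- c(paste(ida, collapse = "+"), paste(idb, collapse = "+"))
  structure(list(chain_pair = c(paste(ida, collapse = "+"),
                                paste(idb, collapse = "+")),
                 buried_area = buried,
                 interface_residues = res,
                 n_interface_hbonds = NA_integer_,
                 probe_radius = probe, n_points = n_points),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("interface %s : %s  buried area %.0f A^2\n",
              x$chain_pair[1], x$chain_pair[2], x$buried_area))
  for (nm in names(x$interface_residues)) {
    r <- x$interface_residues[[nm]]
    cat(sprintf("  chain %s: %d interface residues\n", nm, nrow(r)))
  }
  if (!is.na(x$n_interface_hbonds)) {
    cat(sprintf("  interface hydrogen bonds: %d\n", x$n_interface_hbonds))
  }
  invisible(x)
}
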