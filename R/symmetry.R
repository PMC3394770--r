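# Crystallographic symmetry: operator algebra in the fractional frame and
# contact-based oligomer assembly.

#' Symmetry operator constructor
#'
#' @param rotation 3x3 integer-valued rotation matrix (fractional frame).
#' @param translation Length-3 numeric translation (fractions of cell edges).
#' @return Object of class `symop`.
#' @export
symop <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  d <- det(rotation)
  if (abs(abs(d) - 1) > 1e-9) stop("rotation must have determinant +/-1")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation must be orthogonal")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "symop")
}

#' Parse a symmetry-operator triplet string
#'
#' Accepts the conventional `"x, y, z"` notation with signs and integer or
#' fractional offsets, e.g. `"-X-1, -Y, Z"` or `"X+1/2, -Y, Z"`. Offsets
#' enter the translation vector; signs on X/Y/Z enter the rotation.
#'
#' @param text A triplet string.
#' @return A [symop].
#' @export
#' @examples
#' parse_symop("-X-1, -Y, Z")
parse_symop <- function(text) {
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  if (length(parts) != 3) {
    stop("expected 3 comma-separated components in '", text, "'")
  }
  rot <- matrix(0, 3, 3)
  trans <- numeric(3)
  for (i in 1:3) {
    comp <- gsub("[[:space:]]", "", toupper(parts[i]))
    if (!nzchar(comp)) stop("empty component in '", text, "'")
    # tokenize into signed terms: axis terms (+-X/Y/Z) or numeric offsets
    toks <- regmatches(comp, gregexpr("[+-]?[^+-]+", comp))[[1]]
    for (tok in toks) {
      sgn <- if (startsWith(tok, "-")) -1 else 1
      body <- sub("^[+-]", "", tok)
      if (body %in% c("X", "Y", "Z")) {
        j <- match(body, c("X", "Y", "Z"))
        rot[i, j] <- rot[i, j] + sgn
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        pq <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
        trans[i] <- trans[i] + sgn * pq[1] / pq[2]
      } else if (grepl("^[0-9]+(\\.[0-9]+)?$", body)) {
        trans[i] <- trans[i] + sgn * as.numeric(body)
      } else {
        stop("unparsable token '", tok, "' in '", text, "'")
      }
    }
  }
  symop(rot, trans)
}

#' Format a symmetry operator as a triplet string
#'
#' Inverse of [parse_symop] up to whitespace: `symop_string(parse_symop(s))`
#' reproduces `s` in canonical form.
#'
#' @param op A [symop].
#' @return A string like `"-X-1,-Y,Z"`.
#' @export
symop_string <- function(op) {
  stopifnot(inherits(op, "symop"))
  ax <- c("X", "Y", "Z")
  comp <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      r <- op$rotation[i, j]
      if (abs(r) > 1e-9) {
        s <- paste0(s, if (r > 0 && nzchar(s)) "+" else if (r < 0) "-" else "",
                    ax[j])
      }
    }
    t <- op$translation[i]
    if (abs(t) > 1e-9) {
      frac <- .as_fraction(t)
      s <- paste0(s, if (t > 0) "+" else "-", frac)
    }
    comp[i] <- s
  }
  paste(comp, collapse = ",")
}

.as_fraction <- function(t) {
  t <- abs(t)
  for (q in c(1, 2, 3, 4, 6)) {
    p <- t * q
    if (abs(p - round(p)) < 1e-9) {
      p <- round(p)
      return(if (q == 1) as.character(p) else paste0(p, "/", q))
    }
  }
  format(t)
}

#' @export
print.symop <- function(x, ...) {
  cat("symop:", symop_string(x), "\n")
  invisible(x)
}

#' Compose two symmetry operators
#'
#' Returns the operator equivalent to applying `b` first, then `a`.
#'
#' @param a,b [symop] objects.
#' @return A [symop].
#' @export
compose_symop <- function(a, b) {
  symop(a$rotation %*% b$rotation,
        as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a symmetry operator
#'
#' @param op A [symop].
#' @return The inverse [symop]; `compose_symop(op, invert_symop(op))` is
#'   the identity.
#' @export
invert_symop <- function(op) {
  rinv <- t(op$rotation)  # orthogonal integer rotation
  symop(rinv, -as.numeric(rinv %*% op$translation))
}

.is_identity_op <- function(op, mod_lattice = FALSE) {
  t <- op$translation
  if (mod_lattice) t <- t - round(t)
  max(abs(op$rotation - diag(3))) < 1e-9 && max(abs(t)) < 1e-9
}

#' Apply a symmetry operator to one chain of a structure
#'
#' Coordinates are fractionalized, transformed as
#' \eqn{x' = R x + t + s} (with `s` an integer lattice shift) and
#' orthogonalized back to Angstrom. Atom identities, occupancies and
#' B-factors are preserved.
#'
#' @param structure A [crystal_structure] with a unit cell.
#' @param op A [symop].
#' @param shift Integer lattice translation, length 3 (default no shift).
#' @param chain Chain id to transform (default: all chains).
#' @return A `symmetry_mate`: list with `atoms` (transformed data frame),
#'   `op`, `shift`, `source_chain`.
#' @export
apply_symop <- function(structure, op, shift = c(0, 0, 0), chain = NULL) {
  stopifnot(inherits(structure, "crystal_structure"), inherits(op, "symop"))
  if (is.null(structure$cell)) stop("cell required for symmetry")
  atoms <- structure$atoms
  if (!is.null(chain)) {
    if (!chain %in% atoms$chain) stop("no such chain: ", chain)
    atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  }
  orth <- .orth_matrix(structure$cell)
  frac <- solve(orth)
  xyz <- t(as.matrix(atoms[, c("x", "y", "z")]))
  fr <- op$rotation %*% (frac %*% xyz) + op$translation + as.numeric(shift)
  ou <- orth %*% fr
  atoms$x <- ou[1, ]; atoms$y <- ou[2, ]; atoms$z <- ou[3, ]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, op = op, shift = as.integer(shift),
                 source_chain = chain),
            class = "symmetry_mate")
}

#' @export
print.symmetry_mate <- function(x, ...) {
  cat(sprintf("symmetry mate: chain %s via %s + (%d,%d,%d), %d atoms\n",
              if (is.null(x$source_chain)) "*" else x$source_chain,
              symop_string(x$op), x$shift[1], x$shift[2], x$shift[3],
              nrow(x$atoms)))
  invisible(x)
}

# atoms used for packing contacts: protein heavy atoms only (waters, free
# ions and sugars excluded; interface significance is judged downstream).
.contact_atoms <- function(atoms) {
  atoms[!atoms$het & atoms$element != "H", , drop = FALSE]
}

.min_dist2 <- function(a, b) {
  # minimum squared distance between two coordinate matrices (n x 3)
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    m <- min(d2)
    if (m < best) best <- m
  }
  best
}

#' Assemble oligomers from crystal contacts
#'
#' Generates all symmetry mates of each protein chain over the space-group
#' operators and a lattice-shift search range, links two mates whenever any
#' inter-chain heavy-atom distance falls below `contact_cutoff`, and
#' returns the connected components that involve at least one identity
#' mate, deduplicated under crystal symmetry and sorted by size.
#'
#' @param structure A [crystal_structure] with cell and space group.
#' @param contact_cutoff Heavy-atom contact distance in Angstrom
#'   (default 5.0).
#' @param shifts Integer lattice shifts searched per axis (default -1:1).
#' @return List of `assembly` objects (fields `members`, `n_chains`,
#'   `contacts`), largest first.
#' @export
assemble_oligomers <- function(structure, contact_cutoff = 5.0,
                               shifts = -1:1) {
  stopifnot(inherits(structure, "crystal_structure"))
  if (is.null(structure$cell)) stop("cell required for symmetry")
  ops <- if (!is.null(structure$space_group)) {
    structure$space_group$ops
  } else {
    list(parse_symop("X,Y,Z"))
  }
  prot <- .contact_atoms(structure$atoms)
  if (nrow(prot) == 0) return(list())
  chains <- unique(prot$chain)
  base <- structure
  base$atoms <- prot

  # generate mates
  members <- list()
  for (ch in chains) for (k in seq_along(ops)) {
    for (sx in shifts) for (sy in shifts) for (sz in shifts) {
      members[[length(members) + 1]] <-
        apply_symop(base, ops[[k]], c(sx, sy, sz), chain = ch)
    }
  }
  n <- length(members)
  coords <- lapply(members, function(m) as.matrix(m$atoms[, c("x", "y", "z")]))
  cent <- t(vapply(coords, colMeans, numeric(3)))
  rad <- vapply(seq_len(n), function(i) {
    sqrt(max(rowSums((coords[[i]] - rep(cent[i, ], each = nrow(coords[[i]])))^2)))
  }, 0)

  # union-find over contacting mates
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  cut2 <- contact_cutoff^2
  edges <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dc <- sqrt(sum((cent[i, ] - cent[j, ])^2))
    if (dc > rad[i] + rad[j] + contact_cutoff) next
    if (.min_dist2(coords[[i]], coords[[j]]) < cut2) {
      pi_ <- find(i); pj <- find(j)
      if (pi_ != pj) parent[pi_] <- pj
      edges[[length(edges) + 1]] <- c(i, j)
    }
  }
  comp <- vapply(seq_len(n), find, 0L)

  # keep components containing an identity mate of some chain
  ident <- which(vapply(members, function(m)
    .is_identity_op(m$op) && all(m$shift == 0), TRUE))
  keep_comp <- unique(comp[ident])

  assemblies <- lapply(keep_comp, function(cc) {
    idx <- which(comp == cc)
    mem <- members[idx]
    structure(list(members = mem, n_chains = length(mem),
                   contacts = Filter(function(e) all(comp[e] == cc), edges)),
              class = "assembly")
  })

  # dedupe assemblies equivalent under symmetry: canonical signature is the
  # lexicographically smallest sorted list of member ops expressed relative
  # to each member in turn.
  sig <- vapply(assemblies, .assembly_signature, "")
  assemblies <- assemblies[!duplicated(sig)]
  assemblies[order(-vapply(assemblies, function(a) a$n_chains, 0))]
}

.member_affine <- function(m) {
  symop(m$op$rotation, m$op$translation + as.numeric(m$shift))
}

.assembly_signature <- function(a) {
  affs <- lapply(a$members, .member_affine)
  chs <- vapply(a$members, function(m)
    if (is.null(m$source_chain)) "*" else m$source_chain, "")
  best <- NULL
  for (r in seq_along(affs)) {
    inv <- invert_symop(affs[[r]])
    rel <- vapply(seq_along(affs), function(i)
      paste0(chs[i], "|", symop_string(compose_symop(inv, affs[[i]]))), "")
    cand <- paste(sort(rel), collapse = ";")
    if (is.null(best) || cand < best) best <- cand
  }
  best
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("assembly of %d chains:\n", x$n_chains))
  for (m in x$members) {
    cat(sprintf("  chain %s  %s + (%d,%d,%d)\n",
                if (is.null(m$source_chain)) "*" else m$source_chain,
                symop_string(m$op), m$shift[1], m$shift[2], m$shift[3]))
  }
  invisible(x)
}
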