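# Internal-coordinate representation of a molecule for torsion-space search.
# Bond lengths and bond angles stay frozen at their input values; only the
# user-declared dihedral angles are variable (the building-block
# approximation common in conformer searches).

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector", call. = FALSE)
  v / n
}

#' Derive covalent connectivity from interatomic distances
#'
#' Two atoms are bonded when their distance is below `scale` times the sum
#' of their single-bond covalent radii.
#'
#' @param elements Character vector of element symbols.
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param scale Distance cutoff scale factor (default 1.2).
#' @return Two-column integer matrix of 1-based bonded atom pairs (i < j).
#' @export
derive_connectivity <- function(elements, coords, scale = 1.2) {
  n <- length(elements)
  r <- element_radii(elements)
  bonds <- matrix(integer(0), 0, 2)
  if (n < 2) return(bonds)
  d <- as.matrix(stats::dist(coords))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (d[i, j] < scale * (r[i] + r[j]))
        bonds <- rbind(bonds, c(i, j))
    }
  }
  bonds
}

bond_graph <- function(n_atoms, bonds) {
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  if (igraph::vcount(g) < n_atoms)
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  g
}

# Atoms that move when the b-c bond rotates: the connected component of c
# after deleting edge b-c. A ring containing b-c makes the bond
# non-rotatable.
downstream_atoms <- function(n_atoms, bonds, b, c) {
  g <- bond_graph(n_atoms, bonds)
  eid <- igraph::get_edge_ids(g, c(b, c))
  if (eid == 0)
    stop(sprintf("atoms %d and %d are not bonded", b, c), call. = FALSE)
  g2 <- igraph::delete_edges(g, eid)
  comp <- igraph::components(g2)$membership
  if (comp[b] == comp[c])
    stop(sprintf("bond %d-%d lies in a ring and is not rotatable", b, c),
         call. = FALSE)
  which(comp == comp[c])
}

#' Build a molecule model for torsion-space search
#'
#' Captures a reference geometry together with its bond graph and the
#' rotatable dihedral angles to be searched. Bond lengths and angles are
#' frozen at the reference values; [set_torsions()] changes only the listed
#' dihedrals.
#'
#' @param elements Character vector of element symbols.
#' @param coords n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param dihedrals List of length-4 integer vectors (1-based atom indices
#'   a-b-c-d); each defines one searchable dihedral about the b-c bond.
#' @param bonds Optional two-column matrix of bonded pairs; when `NULL`,
#'   connectivity is derived from covalent radii ([derive_connectivity()]).
#'   An explicit bond list always wins over auto-derivation.
#' @param masses Optional numeric vector of atomic masses (amu); defaults
#'   to standard atomic weights looked up from the element symbols.
#' @return An object of class `molecule_model`.
#' @export
molecule_model <- function(elements, coords, dihedrals, bonds = NULL,
                           masses = NULL) {
  coords <- as.matrix(coords)
  n <- length(elements)
  stopifnot(nrow(coords) == n, ncol(coords) == 3)
  if (is.null(bonds)) bonds <- derive_connectivity(elements, coords)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (is.null(masses)) masses <- element_masses(elements)
  if (!is.list(dihedrals)) dihedrals <- list(dihedrals)
  if (!length(dihedrals)) stop("at least one searchable dihedral is required",
                               call. = FALSE)
  moving <- vector("list", length(dihedrals))
  for (k in seq_along(dihedrals)) {
    q <- as.integer(dihedrals[[k]])
    if (length(q) != 4 || anyDuplicated(q) || any(q < 1) || any(q > n))
      stop("dihedral ", k, ": need 4 distinct atom indices in 1..", n,
           call. = FALSE)
    dihedrals[[k]] <- q
    moving[[k]] <- downstream_atoms(n, bonds, q[2], q[3])
  }
  structure(list(elements = elements, coords = coords, bonds = bonds,
                 masses = masses, dihedrals = dihedrals, moving = moving),
            class = "molecule_model")
}

#' @export
print.molecule_model <- function(x, ...) {
  cat(sprintf("molecule_model: %d atoms, %d bonds, %d searchable dihedral(s)\n",
              length(x$elements), nrow(x$bonds), length(x$dihedrals)))
  invisible(x)
}

# Signed dihedral a-b-c-d, IUPAC convention (right-hand rule sighting from
# atom b to atom c), degrees in [-180, 180).
dihedral_angle <- function(coords, idx) {
  p <- coords[idx, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("degenerate geometry: collinear atom triplet in dihedral definition",
         call. = FALSE)
  y <- sum(cross3(n1, n2) * unit3(b2))
  x <- sum(n1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Measure the searchable dihedral angles of a geometry
#'
#' @param coords n x 3 coordinate matrix, or a `molecule_model` (whose
#'   reference coordinates are then measured).
#' @param dihedrals List of 4-atom index vectors; taken from the model when
#'   a `molecule_model` is given.
#' @return Numeric vector of signed dihedral angles in degrees, wrapped to
#'   [-180, 180).
#' @export
measure_torsions <- function(coords, dihedrals = NULL) {
  if (inherits(coords, "molecule_model")) {
    if (is.null(dihedrals)) dihedrals <- coords$dihedrals
    coords <- coords$coords
  }
  if (!is.list(dihedrals)) dihedrals <- list(dihedrals)
  vapply(dihedrals, function(q) dihedral_angle(coords, as.integer(q)),
         numeric(1))
}

# Rodrigues rotation of rows of `pts` about the axis through `origin` with
# unit direction `u`, by `phi` degrees (right-hand rule).
rotate_about_axis <- function(pts, origin, u, phi) {
  th <- phi * pi / 180
  ct <- cos(th); st <- sin(th)
  rel <- sweep(pts, 2, origin)
  # r' = r ct + (u x r) st + u (u.r)(1-ct)
  ux <- cbind(u[2] * rel[, 3] - u[3] * rel[, 2],
              u[3] * rel[, 1] - u[1] * rel[, 3],
              u[1] * rel[, 2] - u[2] * rel[, 1])
  udot <- rel %*% u
  out <- rel * ct + ux * st + (udot %*% t(u)) * (1 - ct)
  sweep(out, 2, origin, `+`)
}

#' Construct Cartesian coordinates for a torsion vector
#'
#' Starting from the model's reference geometry, rotates the atoms
#' downstream of each searchable bond so that every searchable dihedral
#' takes the requested value. All bond lengths and bond angles are left
#' exactly at their reference values (rigid-body rotations only).
#'
#' @param model A [molecule_model()].
#' @param torsions Numeric vector of target dihedral angles in degrees,
#'   one per searchable dihedral (any real values; wrapped internally).
#' @return n x 3 coordinate matrix (Angstrom).
#' @export
set_torsions <- function(model, torsions) {
  stopifnot(inherits(model, "molecule_model"))
  torsions <- wrap_angle(as.numeric(torsions))
  if (length(torsions) != length(model$dihedrals))
    stop("torsion vector length ", length(torsions), " != number of ",
         "searchable dihedrals ", length(model$dihedrals), call. = FALSE)
  coords <- model$coords
  for (k in seq_along(model$dihedrals)) {
    q <- model$dihedrals[[k]]
    cur <- dihedral_angle(coords, q)
    delta <- wrap_angle(torsions[k] - cur)
    if (abs(delta) < 1e-12) next
    u <- unit3(coords[q[3], ] - coords[q[2], ])
    mv <- model$moving[[k]]
    coords[mv, ] <- rotate_about_axis(coords[mv, , drop = FALSE],
                                      coords[q[3], ], u, delta)
  }
  coords
}

# --- internal-coordinate bookkeeping -----------------------------------

# All bond lengths of the model measured on a coordinate set.
bond_lengths <- function(coords, bonds) {
  sqrt(rowSums((coords[bonds[, 1], , drop = FALSE] -
                coords[bonds[, 2], , drop = FALSE])^2))
}

# All bond angles j-i-k (degrees) over atoms i with >= 2 bonded neighbours.
bond_angles <- function(coords, bonds) {
  n <- max(bonds)
  nb <- lapply(seq_len(n), function(i)
    sort(unique(c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))))
  out <- numeric(0)
  for (i in seq_len(n)) {
    nbrs <- nb[[i]]
    if (length(nbrs) < 2) next
    prs <- utils::combn(nbrs, 2)
    for (m in seq_len(ncol(prs))) {
      v1 <- unit3(coords[prs[1, m], ] - coords[i, ])
      v2 <- unit3(coords[prs[2, m], ] - coords[i, ])
      out <- c(out, acos(pmin(1, pmax(-1, sum(v1 * v2)))) * 180 / pi)
    }
  }
  out
}

#' Compute a Z-matrix (internal coordinates) from a molecule model
#'
#' Atoms are described in input order; atom k > 1 gets a bond length to a
#' previously placed bonded neighbour, atom k > 2 additionally a bond
#' angle, and atom k > 3 a dihedral angle. Reference atoms are chosen by
#' walking the bond graph towards lower indices.
#'
#' @param model A [molecule_model()], or a coordinate matrix together with
#'   `bonds`.
#' @param bonds Bond matrix when `model` is a plain coordinate matrix.
#' @param elements Element symbols when `model` is a coordinate matrix.
#' @return A data frame with columns `element`, `ref_bond`, `length`,
#'   `ref_angle`, `angle`, `ref_dihedral`, `dihedral` (Angstrom/degrees;
#'   NA where not applicable).
#' @export
zmatrix <- function(model, bonds = NULL, elements = NULL) {
  if (inherits(model, "molecule_model")) {
    coords <- model$coords; bonds <- model$bonds; elements <- model$elements
  } else coords <- as.matrix(model)
  n <- nrow(coords)
  nb <- lapply(seq_len(n), function(i)
    sort(unique(c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))))
  parent <- rep(NA_integer_, n)
  for (i in 2:n) {
    prev <- nb[[i]][nb[[i]] < i]
    parent[i] <- if (length(prev)) prev[1] else i - 1L
  }
  zm <- data.frame(element = elements, ref_bond = NA_integer_,
                   length = NA_real_, ref_angle = NA_integer_,
                   angle = NA_real_, ref_dihedral = NA_integer_,
                   dihedral = NA_real_)
  for (i in 2:n) {
    j <- parent[i]
    zm$ref_bond[i] <- j
    zm$length[i] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (i >= 3) {
      k <- if (!is.na(parent[j]) && parent[j] != i) parent[j]
           else setdiff(which(seq_len(n) < i), c(i, j))[1]
      zm$ref_angle[i] <- k
      v1 <- unit3(coords[i, ] - coords[j, ])
      v2 <- unit3(coords[k, ] - coords[j, ])
      zm$angle[i] <- acos(pmin(1, pmax(-1, sum(v1 * v2)))) * 180 / pi
      if (i >= 4) {
        l <- if (!is.na(parent[k]) && !(parent[k] %in% c(i, j, k)))
               parent[k] else setdiff(seq_len(i - 1), c(i, j, k))[1]
        zm$ref_dihedral[i] <- l
        zm$dihedral[i] <- dihedral_angle(coords, c(i, j, k, l))
      }
    }
  }
  zm
}

#' Serialize a Z-matrix to text
#' @param zm Data frame from [zmatrix()].
#' @return Character vector, one line per atom.
#' @export
format_zmatrix <- function(zm) {
  vapply(seq_len(nrow(zm)), function(i) {
    parts <- zm$element[i]
    if (!is.na(zm$ref_bond[i]))
      parts <- paste(parts, zm$ref_bond[i], sprintf("%.6f", zm$length[i]))
    if (!is.na(zm$ref_angle[i]))
      parts <- paste(parts, zm$ref_angle[i], sprintf("%.4f", zm$angle[i]))
    if (!is.na(zm$ref_dihedral[i]))
      parts <- paste(parts, zm$ref_dihedral[i], sprintf("%.4f", zm$dihedral[i]))
    parts
  }, character(1))
}
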