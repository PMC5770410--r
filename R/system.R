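#' Molecular system container
#'
#' A `molecular_system` holds one peptide chain (or small molecule) as a
#' table of atoms, a residue table and a covalent bond list. It is the common
#' currency of the whole package: readers produce it, fragmentation cuts it,
#' kinematics rebuilds its coordinates, energetics and contact scoring
#' consume it.
#'
#' @param atoms data.frame with columns serial, name, element, x, y, z,
#'   vdw_radius, partial_charge, residue_index, residue_name, residue_label.
#' @param bonds two-column integer matrix of atom serials (unordered pairs).
#' @param chain_id single chain identifier string.
#' @return an object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, bonds, chain_id = "A") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("serial", "name", "element", "x", "y", "z", "vdw_radius",
            "partial_charge", "residue_index", "residue_name", "residue_label")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$serial)) stop("duplicate atom serials")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$vdw_radius <= 0)) stop("vdw_radius must be positive")
  bonds <- normalize_bonds(bonds)
  if (nrow(bonds) && !all(bonds %in% atoms$serial))
    stop("bond endpoint refers to unknown atom serial")
  if (nrow(bonds) && any(bonds[, 1] == bonds[, 2])) stop("self-bond not allowed")
  res <- unique(atoms[, c("residue_index", "residue_name", "residue_label")])
  res <- res[order(res$residue_index), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(atoms = atoms, residues = res, bonds = bonds,
                 chain_id = chain_id),
            class = "molecular_system")
}

normalize_bonds <- function(bonds) {
  if (is.null(bonds) || length(bonds) == 0)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  bonds <- matrix(as.integer(bonds), ncol = 2)
  bonds <- t(apply(bonds, 1, sort))
  bonds <- unique(bonds)
  colnames(bonds) <- c("i", "j")
  bonds
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("molecular_system: %d atoms, %d residues, %d bonds, chain %s\n",
              nrow(x$atoms), nrow(x$residues), nrow(x$bonds), x$chain_id))
  invisible(x)
}

#' Coordinate matrix of a system
#' @param system a `molecular_system`.
#' @return numeric matrix n x 3 with atom serials as rownames.
#' @export
coords <- function(system) {
  m <- as.matrix(system$atoms[, c("x", "y", "z")])
  rownames(m) <- system$atoms$serial
  m
}

#' Replace coordinates of a system
#' @param system a `molecular_system`.
#' @param xyz numeric n x 3 matrix in the system's atom order.
#' @return the system with updated coordinates.
#' @export
set_coords <- function(system, xyz) {
  stopifnot(nrow(xyz) == nrow(system$atoms), ncol(xyz) == 3)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  system$atoms$x <- xyz[, 1]
  system$atoms$y <- xyz[, 2]
  system$atoms$z <- xyz[, 3]
  system
}

#' Subset a system to a set of atoms
#'
#' Keeps the named atom serials (e.g. the first three residues plus the
#' backbone of the fourth -- a "3.5 residue" selection) and re-infers bonds
#' within the selection.
#'
#' @param system a `molecular_system`.
#' @param serials atom serials to keep.
#' @return a new `molecular_system`.
#' @export
subset_atoms <- function(system, serials) {
  keep <- system$atoms$serial %in% serials
  if (!any(keep)) stop("selection is empty")
  sys <- molecular_system(system$atoms[keep, , drop = FALSE], NULL,
                          chain_id = system$chain_id)
  sys$bonds <- infer_bonds(sys)
  sys
}

atom_index <- function(system, serial) {
  ix <- match(serial, system$atoms$serial)
  if (anyNA(ix)) stop("unknown atom serial(s): ",
                      paste(serial[is.na(ix)], collapse = ","))
  ix
}

atom_pos <- function(system, serial) {
  unname(as.numeric(system$atoms[atom_index(system, serial),
                                 c("x", "y", "z")]))
}

# serial of a named atom in a residue, NA if absent
find_atom <- function(system, residue_index, name) {
  a <- system$atoms
  hit <- which(a$residue_index == residue_index & a$name == name)
  if (length(hit) == 0) return(NA_integer_)
  a$serial[hit[1]]
}

bond_igraph <- function(system) {
  ids <- as.character(system$atoms$serial)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(system$bonds))
    g <- igraph::add_edges(g, rbind(as.character(system$bonds[, 1]),
                                    as.character(system$bonds[, 2])))
  g
}
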