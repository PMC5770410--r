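# Reading and writing molecular structures. PDB handling is delegated to
# bio3d; this layer selects, attaches radii/charges and infers connectivity.

#' Read a peptide chain from a PDB file
#'
#' Reads the first MODEL, keeps the highest-occupancy alternate location,
#' selects one chain and an optional residue window, attaches element-derived
#' van der Waals radii and residue-template partial charges, and infers the
#' covalent bond list (CONECT records are honored when present).
#'
#' @param path PDB file path.
#' @param chain chain identifier; defaults to the first chain in the file.
#' @param residue_range `NULL` for all residues, or `c(first, last)` positions
#'   (1-based, counted within the selected chain).
#' @param include_hydrogens keep hydrogen atoms? Default `FALSE`, matching the
#'   heavy-atom physical models this package targets.
#' @return a [molecular_system()].
#' @export
read_pdb <- function(path, chain = NULL, residue_range = NULL,
                     include_hydrogens = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  if (!any(at$chain %in% chain))
    stop("chain '", chain, "' not present in ", path)
  at <- at[at$chain %in% chain, , drop = FALSE]
  # altloc: keep the highest-occupancy conformer per (residue, atom name)
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$resno, at$insert, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      ix[which.max(occ[ix])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  elem <- trimws(at$elesy)
  no_elem <- is.na(elem) | elem == ""
  elem[no_elem] <- element_from_name(at$elety[no_elem])
  if (!include_hydrogens) {
    keep <- !(toupper(elem) %in% c("H", "D"))
    at <- at[keep, , drop = FALSE]
    elem <- elem[keep]
  }
  if (nrow(at) == 0) stop("selection is empty")
  reskey <- paste(at$resno, at$insert)
  ridx <- match(reskey, unique(reskey))
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2)
    keep <- ridx >= residue_range[1] & ridx <= residue_range[2]
    at <- at[keep, , drop = FALSE]
    elem <- elem[keep]
    ridx <- ridx[keep] - residue_range[1] + 1L
  }
  q <- charge_of(at$resid, at$elety)
  unknown_res <- unique(at$resid[!at$resid %in% residue_table("charges")$res])
  if (length(unknown_res)) {
    warning("no charge template for residue(s) ",
            paste(unknown_res, collapse = ","), "; charges set to 0")
  }
  q[is.na(q)] <- 0
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety),
                      element = elem, x = at$x, y = at$y, z = at$z,
                      vdw_radius = vdw_radius_of(elem), partial_charge = q,
                      residue_index = ridx, residue_name = at$resid,
                      residue_label = at$resno, stringsAsFactors = FALSE)
  bonds <- read_conect(path, atoms$serial)
  sys <- molecular_system(atoms, bonds, chain_id = chain[1])
  if (nrow(sys$bonds) == 0) sys$bonds <- infer_bonds(sys)
  sys
}

read_conect <- function(path, serials) {
  lines <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lines)) return(NULL)
  out <- list()
  for (ln in lines) {
    flds <- suppressWarnings(as.integer(substring(
      ln, seq(7, 27, by = 5), seq(11, 31, by = 5))))
    flds <- flds[!is.na(flds)]
    if (length(flds) >= 2)
      out[[length(out) + 1]] <- cbind(flds[1], flds[-1])
  }
  if (!length(out)) return(NULL)
  b <- do.call(rbind, out)
  b <- b[b[, 1] %in% serials & b[, 2] %in% serials, , drop = FALSE]
  if (nrow(b) == 0) return(NULL)
  b
}

#' Write a system to a single-model PDB file
#'
#' Atom order is preserved; residue labels are the original PDB numbering
#' carried by the system.
#'
#' @param system a [molecular_system()].
#' @param path output file path.
#' @param coordinates optional n x 3 matrix overriding the system coordinates
#'   (e.g. a rebuilt conformation).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(system, path, coordinates = NULL) {
  if (nrow(system$atoms) == 0) stop("cannot write an empty system")
  a <- system$atoms
  if (!is.null(coordinates)) {
    stopifnot(nrow(coordinates) == nrow(a), ncol(coordinates) == 3)
    if (!all(is.finite(coordinates))) stop("non-finite coordinates")
    a$x <- coordinates[, 1]; a$y <- coordinates[, 2]; a$z <- coordinates[, 3]
  }
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  n <- nrow(a)
  bio3d::write.pdb(file = path, xyz = xyz, eleno = a$serial, elety = a$name,
                   resid = a$residue_name, resno = a$residue_label,
                   chain = rep(system$chain_id, n), o = rep(1, n),
                   b = rep(0, n), elesy = a$element)
  invisible(path)
}

#' Read a TRIPOS mol2 file
#'
#' Bonds are taken verbatim from the BOND section and charges from the mol2
#' charge column when present; a file without a BOND section falls back to
#' distance-based bond inference with a warning.
#'
#' @param path mol2 file path.
#' @return a [molecular_system()].
#' @export
read_mol2 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- bio3d::read.mol2(path)
  at <- m$atom
  # mol2 atom types (elety) are element or element.hybridization
  elem <- toupper(sub("\\..*$", "", at$elety))
  elem <- ifelse(nchar(elem) > 2, element_from_name(at$elena), elem)
  elem <- paste0(substr(elem, 1, 1), tolower(substr(elem, 2, 10)))
  q <- if ("charge" %in% names(at) && !all(is.na(at$charge))) at$charge else 0
  resname <- if ("resid" %in% names(at)) toupper(substr(at$resid, 1, 3)) else "UNK"
  ridx <- if ("resno" %in% names(at)) match(at$resno, unique(at$resno)) else 1L
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elena),
                      element = elem, x = at$x, y = at$y, z = at$z,
                      vdw_radius = vdw_radius_of(elem), partial_charge = q,
                      residue_index = ridx, residue_name = resname,
                      residue_label = if ("resno" %in% names(at)) at$resno else 1L,
                      stringsAsFactors = FALSE)
  bonds <- NULL
  if (!is.null(m$bond) && nrow(m$bond) > 0) {
    bonds <- cbind(m$bond$origin, m$bond$target)
  }
  sys <- molecular_system(atoms, bonds, chain_id = "A")
  if (nrow(sys$bonds) == 0) {
    warning("mol2 file has no BOND records; inferring bonds from distances")
    sys$bonds <- infer_bonds(sys)
  }
  sys
}

#' Infer covalent bonds of a system
#'
#' Standard residues get their template connectivity plus inter-residue
#' peptide bonds C(i)-N(i+1) guarded by a 1.8 Angstrom distance check (a
#' longer gap is treated as a chain break and logged). Atoms of non-standard
#' residues, and hydrogens, are bonded by a covalent-radius distance rule.
#'
#' @param system a [molecular_system()].
#' @param max_peptide_bond maximum C-N distance accepted as a peptide bond
#'   (Angstrom).
#' @return two-column matrix of bonded atom serial pairs.
#' @export
infer_bonds <- function(system, max_peptide_bond = 1.8) {
  a <- system$atoms
  tb <- residue_table("bonds")
  out <- list()
  for (ri in system$residues$residue_index) {
    sel <- a[a$residue_index == ri, , drop = FALSE]
    rname <- sel$residue_name[1]
    tpl <- tb[tb$res == rname, , drop = FALSE]
    if (nrow(tpl)) {
      s1 <- sel$serial[match(tpl$atom1, sel$name)]
      s2 <- sel$serial[match(tpl$atom2, sel$name)]
      ok <- !is.na(s1) & !is.na(s2)
      if (any(ok)) out[[length(out) + 1]] <- cbind(s1[ok], s2[ok])
      # hydrogens are not in the heavy-atom template: attach to nearest heavy
      hyd <- sel[toupper(sel$element) == "H", , drop = FALSE]
      if (nrow(hyd)) {
        heavy <- sel[toupper(sel$element) != "H", , drop = FALSE]
        for (k in seq_len(nrow(hyd))) {
          d <- sqrt((heavy$x - hyd$x[k])^2 + (heavy$y - hyd$y[k])^2 +
                      (heavy$z - hyd$z[k])^2)
          j <- which.min(d)
          if (d[j] < 1.3)
            out[[length(out) + 1]] <- cbind(hyd$serial[k], heavy$serial[j])
        }
      }
    } else {
      out[[length(out) + 1]] <- distance_bonds(sel)
    }
  }
  # peptide bonds between consecutive residues
  ridx <- system$residues$residue_index
  for (k in seq_along(ridx)[-1]) {
    cs <- find_atom(system, ridx[k - 1], "C")
    ns <- find_atom(system, ridx[k], "N")
    if (is.na(cs) || is.na(ns)) next
    d <- vnorm(atom_pos(system, cs) - atom_pos(system, ns))
    if (d < max_peptide_bond) {
      out[[length(out) + 1]] <- cbind(cs, ns)
    } else {
      message(sprintf("chain break between residues %d and %d (C-N %.2f A); bond omitted",
                      ridx[k - 1], ridx[k], d))
    }
  }
  normalize_bonds(if (length(out)) do.call(rbind, out) else NULL)
}

covalent_radii <- c(H = 0.37, C = 0.77, N = 0.75, O = 0.73, S = 1.02, P = 1.06)

distance_bonds <- function(sel) {
  n <- nrow(sel)
  if (n < 2) return(NULL)
  rc <- covalent_radii[toupper(sel$element)]
  rc[is.na(rc)] <- 0.77
  xyz <- as.matrix(sel[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  lim <- outer(rc, rc, "+") * 1.3
  hit <- which(d < lim & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit) == 0) return(NULL)
  cbind(sel$serial[hit[, 1]], sel$serial[hit[, 2]])
}
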