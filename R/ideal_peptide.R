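# Ab-initio construction of ideal-geometry peptides. The backbone is grown
# atom by atom with the natural extension reference frame (NeRF) from a
# fixed table of bond lengths and angles; side chains come from the bundled
# internal-coordinate templates and are then rotated onto the requested
# chi values. Torsions of the output therefore equal the request exactly
# (up to floating point).

# backbone ideal values (Engh-Huber style)
# default backbone torsions: beta-strand-like extension, which stays
# clash-free at radius scale 0.7 for every residue type
DEFAULT_PHI <- -120
DEFAULT_PSI <- 140
BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
           ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
           ang_ca_c_o = 120.8, n_h = 1.01, ang_c_n_h = 119.5)

#' Build an ideal-geometry peptide
#'
#' Constructs a single peptide chain with standard bond lengths and angles
#' for a one-letter sequence. Backbone torsions default to an extended
#' beta-strand-like chain (phi = -120, psi = 140, omega = 180; omega is
#' planar-locked in nature and treated as fixed downstream); side-chain
#' torsions default to each
#' residue's template rotamer (chi values of the bundled ideal-coordinate
#' table), which keeps even tryptophan clash-free in the extended chain.
#' Proline's ring always keeps its template geometry.
#'
#' @param sequence one-letter residue string, e.g. `"GAVEK"`.
#' @param torsions optional per-residue overrides: a list indexed by residue
#'   position, each element a named list with any of `phi`, `psi`, `omega`,
#'   `chi1` .. `chi4` in degrees, e.g. `list(`2` = list(phi = -60, psi = -45))`.
#' @param include_hydrogens add backbone amide hydrogens (residues 2..n,
#'   not proline). Side-chain hydrogens are never built; partial charges are
#'   united-atom so added hydrogens carry charge 0.
#' @return a [molecular_system()] with bonds inferred from the residue
#'   templates.
#' @export
build_ideal_peptide <- function(sequence, torsions = NULL,
                                include_hydrogens = FALSE) {
  res3 <- seq_to_three(sequence)
  n_res <- length(res3)
  tor <- function(i, what, default) {
    v <- torsions[[as.character(i)]][[what]]
    if (is.null(v)) default else v
  }
  zmat <- residue_table("zmat")
  chit <- residue_table("chi")
  rows <- list()
  serial <- 0L
  add_atom <- function(name, element, pos, ri, rname) {
    serial <<- serial + 1L
    rows[[length(rows) + 1]] <<- data.frame(
      serial = serial, name = name, element = element,
      x = pos[1], y = pos[2], z = pos[3],
      vdw_radius = vdw_radius_of(element),
      partial_charge = {
        q <- charge_of(rname, name); if (is.na(q)) 0 else q
      },
      residue_index = ri, residue_name = rname, residue_label = ri,
      stringsAsFactors = FALSE)
    serial
  }
  pos <- list()  # name "<ri>:<atom>" -> position
  P <- function(ri, nm) pos[[paste0(ri, ":", nm)]]
  setP <- function(ri, nm, p) pos[[paste0(ri, ":", nm)]] <<- p

  for (i in seq_len(n_res)) {
    rn <- res3[i]
    phi <- tor(i, "phi", DEFAULT_PHI)
    psi <- tor(i, "psi", DEFAULT_PSI)
    omega <- tor(i, "omega", 180)
    if (i == 1) {
      setP(1, "N", c(0, 0, 0))
      setP(1, "CA", c(BB$n_ca, 0, 0))
      th <- deg2rad(180 - BB$ang_n_ca_c)
      setP(1, "C", P(1, "CA") + BB$ca_c * c(cos(th), sin(th), 0))
    } else {
      # N(i) placed by psi(i-1), CA(i) by omega(i-1), C(i) by phi(i)
      psi_prev <- tor(i - 1, "psi", DEFAULT_PSI)
      omega_prev <- tor(i - 1, "omega", 180)
      setP(i, "N", place_atom(P(i - 1, "N"), P(i - 1, "CA"), P(i - 1, "C"),
                              BB$c_n, BB$ang_ca_c_n, psi_prev))
      setP(i, "CA", place_atom(P(i - 1, "CA"), P(i - 1, "C"), P(i, "N"),
                               BB$n_ca, BB$ang_c_n_ca, omega_prev))
      setP(i, "C", place_atom(P(i - 1, "C"), P(i, "N"), P(i, "CA"),
                              BB$ca_c, BB$ang_n_ca_c, phi))
    }
    # carbonyl O: anti-planar to the next amide N, i.e. torsion psi + 180
    setP(i, "O", place_atom(P(i, "N"), P(i, "CA"), P(i, "C"),
                            BB$c_o, BB$ang_ca_c_o, normalize_angle(psi + 180)))
    add_atom("N", "N", P(i, "N"), i, rn)
    if (include_hydrogens && i > 1 && rn != "PRO") {
      h <- place_atom(P(i - 1, "CA"), P(i - 1, "C"), P(i, "N"),
                      BB$n_h, BB$ang_c_n_h, 0)
      add_atom("H", "H", h, i, rn)
    }
    add_atom("CA", "C", P(i, "CA"), i, rn)
    add_atom("C", "C", P(i, "C"), i, rn)
    add_atom("O", "O", P(i, "O"), i, rn)
    # side chain from internal-coordinate template
    z <- zmat[zmat$res == rn, , drop = FALSE]
    if (nrow(z)) {
      for (k in seq_len(nrow(z))) {
        p <- place_atom(P(i, z$a3[k]), P(i, z$a2[k]), P(i, z$a1[k]),
                        z$length_A[k], z$angle_deg[k], z$torsion_deg[k])
        setP(i, z$atom[k], p)
      }
      # rotate side-chain subtrees onto requested chi values (PRO ring fixed)
      ch <- chit[chit$res == rn, , drop = FALSE]
      if (rn == "PRO") {
        for (k in 1:4) {
          if (!is.null(torsions[[as.character(i)]][[paste0("chi", k)]]))
            stop("proline chi angles are ring-locked and cannot be set")
        }
      } else if (nrow(ch)) {
        for (k in seq_len(nrow(ch))) {
          req <- tor(i, paste0("chi", ch$chi[k]), NULL)
          if (is.null(req)) next  # default: keep the template rotamer
          cur <- measure_torsion(P(i, ch$a[k]), P(i, ch$b[k]),
                                 P(i, ch$c[k]), P(i, ch$d[k]))
          delta <- normalize_angle(req - cur)
          if (abs(delta) < 1e-12) next
          axis_b <- P(i, ch$b[k]); axis_c <- P(i, ch$c[k])
          R <- rotation_about_axis(axis_c - axis_b, delta)
          distal <- sidechain_distal_atoms(z, ch$c[k])
          for (nm in distal) {
            setP(i, nm, as.numeric(R %*% (P(i, nm) - axis_c)) + axis_c)
          }
        }
      }
      for (k in seq_len(nrow(z))) add_atom(z$atom[k], z_element(rn, z$atom[k]),
                                           P(i, z$atom[k]), i, rn)
    }
    chi_names <- paste0("chi", seq_len(4))
    asked <- intersect(names(torsions[[as.character(i)]]), chi_names)
    have <- paste0("chi", chit$chi[chit$res == rn])
    extra <- setdiff(asked, have)
    if (length(extra))
      stop(rn, " at position ", i, " has no ", paste(extra, collapse = ","))
  }
  atoms <- do.call(rbind, rows)
  sys <- molecular_system(atoms, NULL, chain_id = "A")
  sys$bonds <- infer_bonds(sys)
  sys
}

z_element <- function(res, atom) {
  at <- residue_table("atoms")
  e <- at$element[match(paste(res, atom), paste(at$res, at$atom))]
  if (is.na(e)) element_from_name(atom) else e
}

# atoms of the side-chain template strictly distal to (and including nothing
# on the proximal side of) the rotation axis ending at atom `c_name`:
# everything whose construction chain passes through c_name
sidechain_distal_atoms <- function(z, c_name) {
  parent <- stats::setNames(z$a1, z$atom)
  distal <- character(0)
  for (nm in z$atom) {
    cur <- nm
    repeat {
      if (identical(cur, c_name)) { distal <- c(distal, nm); break }
      cur <- parent[[cur]]
      if (is.null(cur) || is.na(cur)) break
      if (cur %in% c("N", "CA", "C")) break
    }
  }
  setdiff(distal, c_name)
}
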