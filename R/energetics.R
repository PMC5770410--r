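# Nonbonded energetics: Lennard-Jones + Coulomb with the conventional Amber
# exclusion treatment (1-2 and 1-3 excluded, 1-4 scaled), hard-sphere
# feasibility at scaled van der Waals radii, and two-torsion grid scans.
# Bonded terms are deliberately absent: fragments are rigid by construction,
# so only the nonbonded terms vary with conformation.

#' Nonbonded energy model
#'
#' @param dielectric relative dielectric constant D in the Coulomb term
#'   k q_i q_j / (D r); default 1.
#' @param coulomb_constant electrostatic constant, kcal A / (mol e^2).
#' @param scale14_lj,scale14_coul divisors applied to 1-4 (three bonds apart)
#'   pair terms; Amber convention 2.0 and 1.2.
#' @return object of class `energy_model`.
#' @export
energy_model <- function(dielectric = 1, coulomb_constant = 332.0636,
                         scale14_lj = 2.0, scale14_coul = 1.2) {
  stopifnot(dielectric > 0)
  structure(list(lj = element_table(), coulomb_constant = coulomb_constant,
                 dielectric = dielectric, scale14_lj = scale14_lj,
                 scale14_coul = scale14_coul),
            class = "energy_model")
}

#' Nonbonded pair list
#'
#' All atom pairs at bonded separation >= 3 bonds; pairs exactly 3 bonds
#' apart are flagged `one_four` for scaling. Separations 1 (bonded) and 2
#' (angle) are excluded.
#'
#' @param system a [molecular_system()] with bonds.
#' @return data.frame with columns i, j (atom serials) and one_four.
#' @export
nonbonded_pairs <- function(system) {
  g <- bond_igraph(system)
  dmat <- igraph::distances(g)
  ser <- as.integer(rownames(dmat))
  ut <- which(upper.tri(dmat) & dmat >= 3, arr.ind = TRUE)
  data.frame(i = ser[ut[, 1]], j = ser[ut[, 2]],
             one_four = dmat[ut] == 3)
}

pair_geometry <- function(system, pairs, coordinates = NULL) {
  xyz <- if (is.null(coordinates)) coords(system) else coordinates
  ii <- match(pairs$i, system$atoms$serial)
  jj <- match(pairs$j, system$atoms$serial)
  dx <- xyz[ii, , drop = FALSE] - xyz[jj, , drop = FALSE]
  list(ii = ii, jj = jj, r = sqrt(rowSums(dx * dx)))
}

#' Total nonbonded energy with per-term breakdown
#'
#' E = sum eps_ij ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6) / s_lj
#'   + sum k q_i q_j / (D r) / s_coul,
#' with the s divisors applied to 1-4 pairs only. Lorentz-Berthelot style
#' combination: rmin_ij = rmin2_i + rmin2_j, eps_ij = sqrt(eps_i eps_j).
#' An electrostatic-only heat map is simply the `coulomb` component.
#'
#' @param system a [molecular_system()].
#' @param coordinates optional coordinate override (n x 3).
#' @param model an [energy_model()].
#' @param pairs optional precomputed [nonbonded_pairs()] list.
#' @return list with `total`, `lj`, `coulomb` (kcal/mol) and `clash`
#'   (TRUE when a pair distance is exactly zero; energy is +Inf).
#' @export
total_energy <- function(system, coordinates = NULL, model = energy_model(),
                         pairs = NULL) {
  if (is.null(pairs)) pairs <- nonbonded_pairs(system)
  if (nrow(pairs) == 0)
    return(list(total = 0, lj = 0, coulomb = 0, clash = FALSE))
  pg <- pair_geometry(system, pairs, coordinates)
  et <- model$lj
  eix <- match(system$atoms$element, et$element)
  rmin2 <- et$lj_rmin2[eix]; eps <- et$lj_eps[eix]
  rmin2[is.na(rmin2)] <- 1.9; eps[is.na(eps)] <- 0.1
  rmin <- rmin2[pg$ii] + rmin2[pg$jj]
  epsij <- sqrt(eps[pg$ii] * eps[pg$jj])
  q <- system$atoms$partial_charge
  zero <- pg$r == 0
  r <- pg$r
  r[zero] <- NA
  x6 <- (rmin / r)^6
  lj_terms <- epsij * (x6 * x6 - 2 * x6)
  coul_terms <- model$coulomb_constant * q[pg$ii] * q[pg$jj] /
    (model$dielectric * r)
  lj_terms[pairs$one_four] <- lj_terms[pairs$one_four] / model$scale14_lj
  coul_terms[pairs$one_four] <- coul_terms[pairs$one_four] / model$scale14_coul
  lj_terms[zero] <- Inf
  coul_terms[zero] <- Inf * sign(q[pg$ii[zero]] * q[pg$jj[zero]])
  lj <- sum(lj_terms); coul <- sum(coul_terms)
  list(total = lj + coul, lj = lj, coulomb = coul, clash = any(zero))
}

#' Hard-sphere feasibility at scaled radii
#'
#' A conformation is infeasible iff any non-excluded pair (bonded separation
#' >= 3) sits closer than `radius_scale` times the sum of the two van der
#' Waals radii. The physical models print spheres at the same scale (0.7 by
#' default), so this predicate is exactly "the printed parts collide".
#'
#' @param system a [molecular_system()].
#' @param coordinates optional coordinate override.
#' @param radius_scale multiplicative factor on vdW radii; default 0.7.
#' @param pairs optional precomputed pair list.
#' @return list with `feasible` (logical) and `offending` (data.frame of
#'   pairs i, j, r, limit).
#' @export
feasible <- function(system, coordinates = NULL, radius_scale = 0.7,
                     pairs = NULL) {
  if (is.null(pairs)) pairs <- nonbonded_pairs(system)
  if (nrow(pairs) == 0)
    return(list(feasible = TRUE,
                offending = data.frame(i = integer(0), j = integer(0),
                                       r = numeric(0), limit = numeric(0))))
  pg <- pair_geometry(system, pairs, coordinates)
  rad <- system$atoms$vdw_radius
  limit <- radius_scale * (rad[pg$ii] + rad[pg$jj])
  bad <- pg$r < limit
  list(feasible = !any(bad),
       offending = data.frame(i = pairs$i[bad], j = pairs$j[bad],
                              r = pg$r[bad], limit = limit[bad]))
}

#' Two-torsion grid scan (Ramachandran-style)
#'
#' Sweeps two unlocked torsions over the full circle in fixed increments
#' (default 20 degrees, giving 18 values per axis and 324 cells), recording
#' the nonbonded energy and hard-sphere feasibility of every combination.
#' Axes are reported as deviations (delta) from the native angles, the
#' native cell sitting at (0, 0).
#'
#' @param system a [molecular_system()].
#' @param graph fragment graph whose joints include the two torsions.
#' @param torsion_a,torsion_b joint ids to sweep.
#' @param increment grid step in degrees; must divide 360.
#' @param model an [energy_model()].
#' @param radius_scale hard-sphere radius scale; default 0.7.
#' @param term which energy to store: total, coulomb-only or LJ-only.
#' @return list of class `grid_scan`: `axis_a`, `axis_b` (delta degrees),
#'   `energy` and `feasible` matrices (rows = delta a), `native` angles,
#'   `radius_scale`, `term`.
#' @export
grid_scan <- function(system, graph, torsion_a, torsion_b, increment = 20,
                      model = energy_model(), radius_scale = 0.7,
                      term = c("total", "coulomb", "lj")) {
  term <- match.arg(term)
  if (360 %% increment != 0) stop("increment must divide 360")
  jt <- graph$joints
  for (t in c(torsion_a, torsion_b))
    if (!t %in% jt$joint_id) stop("torsion ", t, " is not a joint of the graph")
  n <- as.integer(360 / increment)
  deltas <- sort(normalize_angle(increment * (seq_len(n) - 1)))
  native <- extract_conformation(system, graph$torsions)
  pairs <- nonbonded_pairs(system)
  E <- matrix(NA_real_, n, n, dimnames = list(deltas, deltas))
  FS <- matrix(NA, n, n, dimnames = list(deltas, deltas))
  state <- native[jt$joint_id]
  for (ia in seq_len(n)) {
    for (ib in seq_len(n)) {
      st <- state
      st[torsion_a] <- normalize_angle(native[torsion_a] + deltas[ia])
      st[torsion_b] <- normalize_angle(native[torsion_b] + deltas[ib])
      s2 <- apply_conformation(system, graph, st)
      en <- total_energy(s2, model = model, pairs = pairs)
      E[ia, ib] <- en[[term]]
      FS[ia, ib] <- feasible(s2, radius_scale = radius_scale,
                             pairs = pairs)$feasible
    }
  }
  structure(list(axis_a = deltas, axis_b = deltas, energy = E, feasible = FS,
                 native = native[c(torsion_a, torsion_b)],
                 radius_scale = radius_scale, term = term,
                 torsion_a = torsion_a, torsion_b = torsion_b),
            class = "grid_scan")
}

#' Write a grid scan as CSV matrices
#'
#' Two files: an energy matrix (rows = delta of the first torsion, columns =
#' delta of the second, with axis headers) and a companion 0/1 feasibility
#' matrix.
#'
#' @param scan a [grid_scan()] result.
#' @param energy_path,feasible_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_grid_csv <- function(scan, energy_path, feasible_path) {
  e <- as.data.frame(scan$energy)
  names(e) <- scan$axis_b
  utils::write.csv(cbind(delta_a = scan$axis_a, e), energy_path,
                   row.names = FALSE)
  f <- as.data.frame(scan$feasible * 1L)
  names(f) <- scan$axis_b
  utils::write.csv(cbind(delta_a = scan$axis_a, f), feasible_path,
                   row.names = FALSE)
  invisible(c(energy_path, feasible_path))
}
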