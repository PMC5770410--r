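# Discrete dot-surface contact scoring against a molded receptor template.
#
# The template ("semi-perfect" receptor) is the implicit CSG solid
#   box  MINUS  atom spheres  MINUS  their upward sweep cylinders,
# the shape obtained by pouring a mold over the ligand and lifting it out
# vertically. Surface marks are near-equidistant points on the printed atom
# spheres; the match score of a conformation is the number of marks lying on
# (within a paint-film tolerance of) the template material.

#' Deterministic near-uniform points on the unit sphere
#'
#' Fibonacci spiral lattice; deterministic for a given count.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * k
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z * z))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Generate surface marks on every atom sphere
#'
#' Places round(density * 4 pi R^2) marks per atom on its printed sphere
#' (radius `radius_scale` times the vdW radius, matching the fabricated
#' model) with a deterministic Fibonacci lattice, then prunes marks strictly
#' buried inside any other atom sphere of the same molecule.
#'
#' @param system a [molecular_system()].
#' @param density target marks per square Angstrom of sphere surface.
#' @param radius_scale radius scale of the printed spheres; default 0.7.
#' @return object of class `surface_marks`: list with `points` (m x 3
#'   matrix), `atom` (serial per mark), `density`, `radius_scale`.
#' @export
generate_surface_marks <- function(system, density = 1, radius_scale = 0.7) {
  if (density <= 0) stop("density must be positive")
  a <- system$atoms
  rad <- a$vdw_radius * radius_scale
  centers <- coords(system)
  pts <- list(); owner <- list()
  for (k in seq_len(nrow(a))) {
    n <- max(1L, as.integer(round(density * 4 * pi * rad[k]^2)))
    p <- fibonacci_sphere(n) * rad[k]
    p <- sweep(p, 2, centers[k, ], "+")
    # prune marks strictly inside another sphere of the same molecule
    keep <- rep(TRUE, n)
    for (m in seq_len(nrow(a))) {
      if (m == k) next
      d2 <- rowSums(sweep(p, 2, centers[m, ])^2)
      keep <- keep & d2 >= (rad[m] - 1e-9)^2
    }
    if (any(keep)) {
      pts[[length(pts) + 1]] <- p[keep, , drop = FALSE]
      owner[[length(owner) + 1]] <- rep(a$serial[k], sum(keep))
    }
  }
  structure(list(points = do.call(rbind, pts),
                 atom = unlist(owner), density = density,
                 radius_scale = radius_scale),
            class = "surface_marks")
}

#' Build the semi-perfect receptor template of a ligand
#'
#' Subtracts the ligand's (scaled) atom spheres and their upward sweeps from
#' a rectangular box: the box footprint is the bounding box of the atom
#' centers in the two axes perpendicular to `up_axis`, padded by the largest
#' sphere radius; its height is the lower half of the center bounding box
#' along `up_axis` (the mold is poured up to half height, so the native
#' ligand rests in it and can be lifted straight out). The geometry is kept
#' implicit (box, carve spheres, sweep cylinders) and queried through
#' [point_in_material()].
#'
#' @param system ligand [molecular_system()] in its native conformation.
#' @param up_axis pull direction of the mold, default +z. Must currently be
#'   a coordinate axis direction or any unit vector; internally the solid is
#'   stored in a frame whose z axis is `up_axis`.
#' @param radius_scale sphere radius scale; default 0.7.
#' @return object of class `template_solid`.
#' @export
make_template <- function(system, up_axis = c(0, 0, 1), radius_scale = 0.7) {
  if (nrow(system$atoms) < 2) stop("template needs at least 2 atoms")
  u <- unit(up_axis)
  # rotation taking up_axis to +z
  z <- c(0, 0, 1)
  if (max(abs(u - z)) < 1e-12) {
    Q <- diag(3)
  } else if (max(abs(u + z)) < 1e-12) {
    Q <- diag(c(1, -1, -1))
  } else {
    v <- cross3(u, z); s <- vnorm(v); c_ <- sum(u * z)
    Vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    Q <- diag(3) + Vx + Vx %*% Vx * ((1 - c_) / s^2)
  }
  centers <- coords(system) %*% t(Q)
  rad <- system$atoms$vdw_radius * radius_scale
  pad <- max(rad)
  zmin <- min(centers[, 3]); zmax <- max(centers[, 3])
  if (zmax - zmin < 1e-9) stop("degenerate bounding box along the pull axis")
  box <- list(xmin = min(centers[, 1]) - pad, xmax = max(centers[, 1]) + pad,
              ymin = min(centers[, 2]) - pad, ymax = max(centers[, 2]) + pad,
              zmin = zmin, zmax = zmin + (zmax - zmin) / 2)
  structure(list(box = box, centers = centers, radii = rad,
                 up_rotation = Q, offset = c(0, 0, 0),
                 radius_scale = radius_scale,
                 atom_serials = system$atoms$serial),
            class = "template_solid")
}

#' Rigidly transform a template solid
#'
#' Moves the solid with the same rigid transform applied to the molecule, so
#' membership and contact queries are exactly invariant under a common
#' motion of ligand and template.
#'
#' @param solid a `template_solid`.
#' @param transform a [rigid_transform()].
#' @return the transformed solid.
#' @export
transform_template <- function(solid, transform) {
  R <- transform$rotation; t <- transform$translation
  solid$up_rotation <- solid$up_rotation %*% t(R)
  solid$offset <- solid$offset - as.numeric(solid$up_rotation %*% t)
  solid
}

# molecule-frame points -> the solid's internal (pull-axis) frame
solid_frame <- function(solid, p) {
  sweep(p %*% t(solid$up_rotation), 2, solid$offset, "+")
}

#' CSG membership test of the template solid
#'
#' TRUE iff the point is inside the box and outside every carve sphere and
#' outside every upward sweep cylinder (the infinite extension of a sphere
#' from its center along +up, clipped by the box). Boundary points are not
#' material, so a point exactly on a carved sphere surface is a touching,
#' non-colliding contact.
#'
#' @param solid a [make_template()] result.
#' @param p length-3 point or n x 3 matrix (molecule frame).
#' @return logical vector.
#' @export
point_in_material <- function(solid, p) {
  p <- if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
  q <- solid_frame(solid, p)
  b <- solid$box
  inside <- q[, 1] > b$xmin & q[, 1] < b$xmax &
    q[, 2] > b$ymin & q[, 2] < b$ymax &
    q[, 3] > b$zmin & q[, 3] < b$zmax
  if (!any(inside)) return(inside)
  for (k in seq_along(solid$radii)) {
    if (!any(inside)) break
    c_k <- solid$centers[k, ]; r_k <- solid$radii[k] + 1e-9
    d2 <- rowSums(sweep(q, 2, c_k)^2)
    in_sphere <- d2 < r_k^2
    dr2 <- (q[, 1] - c_k[1])^2 + (q[, 2] - c_k[2])^2
    in_sweep <- q[, 3] >= c_k[3] - 1e-9 & dr2 < r_k^2
    inside <- inside & !in_sphere & !in_sweep
  }
  inside
}

# distance from points to the material region (0 when inside). Candidate
# nearest points are generated analytically on each primitive surface (box
# faces, carve sphere surfaces, sweep cylinder walls), then validated
# against the membership function; the minimum valid candidate distance is
# returned. Points deep inside a carve void are handled exactly by the
# sphere/cylinder surface candidates. With surfaces = "pocket" only the
# carved (mold pocket) surfaces are considered -- the painted region of the
# physical experiment -- and the box outer faces are ignored.
distance_to_material <- function(solid, p, surfaces = c("all", "pocket")) {
  surfaces <- match.arg(surfaces)
  p <- if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
  q <- solid_frame(solid, p)
  n <- nrow(q)
  b <- solid$box
  inm <- point_in_material(solid, p)
  eps <- 1e-7
  out <- rep(Inf, n)
  out[inm] <- 0
  todo <- which(!inm)
  if (!length(todo)) return(out)
  qt <- q[todo, , drop = FALSE]
  m <- nrow(qt)
  best <- rep(Inf, m)
  # internal-frame probe -> molecule frame, membership check, update best
  consider <- function(d, probe) {
    better <- is.finite(d) & d < best
    if (!any(better)) return(invisible(NULL))
    pm <- sweep(probe[better, , drop = FALSE], 2, solid$offset) %*%
      solid$up_rotation
    ok <- point_in_material(solid, pm)
    ix <- which(better)[ok]
    best[ix] <<- pmin(best[ix], d[better][ok])
    invisible(NULL)
  }
  if (surfaces == "all") {
    # nearest point of the closed box; probe nudged toward the box interior
    box_mid <- c((b$xmin + b$xmax) / 2, (b$ymin + b$ymax) / 2,
                 (b$zmin + b$zmax) / 2)
    lo <- c(b$xmin, b$ymin, b$zmin); hi <- c(b$xmax, b$ymax, b$zmax)
    cl <- pmin(pmax(qt, rep(lo, each = m)), rep(hi, each = m))
    d <- sqrt(rowSums((qt - cl)^2))
    dir <- sweep(-cl, 2, box_mid, "+")
    nd <- sqrt(rowSums(dir^2))
    dir <- dir / pmax(nd, 1e-12)
    consider(d, cl + dir * eps)
  }
  for (k in seq_along(solid$radii)) {
    ck <- solid$centers[k, ]; rk <- solid$radii[k]
    v <- sweep(qt, 2, ck)
    nv <- sqrt(rowSums(v * v))
    nv_safe <- pmax(nv, 1e-12)
    # carve sphere surface; material lies just outside the sphere
    d_s <- abs(nv - rk)
    probe_s <- sweep(v * ((rk + eps) / nv_safe), 2, ck, "+")
    d_s[nv < 1e-12] <- Inf
    consider(d_s, probe_s)
    # sweep cylinder wall at the point's height clamped to the wall span
    # (from the sphere center up to the box top); the probe is pushed just
    # inside the box when the wall point sits on its top face
    nvr <- sqrt(v[, 1]^2 + v[, 2]^2)
    nvr_safe <- pmax(nvr, 1e-12)
    zc <- pmin(pmax(qt[, 3], ck[3]), b$zmax)
    d_w <- sqrt((nvr - rk)^2 + (qt[, 3] - zc)^2)
    probe_w <- cbind(ck[1] + v[, 1] / nvr_safe * (rk + eps),
                     ck[2] + v[, 2] / nvr_safe * (rk + eps),
                     pmin(pmax(zc, b$zmin + eps), b$zmax - eps))
    d_w[nvr < 1e-12] <- Inf
    consider(d_w, probe_w)
    # the sphere surface clipped by the box floor/top: nearest point on the
    # circle where the carve sphere meets a horizontal box plane (covers
    # marks at or below the floor, whose radial projection leaves the box)
    for (zplane in c(b$zmin, b$zmax)) {
      dz <- zplane - ck[3]
      if (abs(dz) >= rk) next
      rc <- sqrt(rk^2 - dz^2)
      ring <- cbind(ck[1] + v[, 1] / nvr_safe * rc,
                    ck[2] + v[, 2] / nvr_safe * rc, zplane)
      d_r <- sqrt((nvr - rc)^2 + (qt[, 3] - zplane)^2)
      zp <- if (zplane == b$zmin) zplane + eps else zplane - eps
      probe_r <- cbind(ck[1] + v[, 1] / nvr_safe * (rc + eps),
                       ck[2] + v[, 2] / nvr_safe * (rc + eps), zp)
      d_r[nvr < 1e-12] <- Inf
      consider(d_r, probe_r)
    }
  }
  out[todo] <- best
  out
}

#' Count surface marks in contact with the template
#'
#' A mark counts iff it is not inside the material and its distance to the
#' painted pocket surface (the carved sphere and sweep-cylinder walls; the
#' box outer faces are not part of the binding site) is at most `tolerance`,
#' the paint-film thickness of the physical experiment. A collision flag is
#' raised when any mark or atom center penetrates material.
#'
#' @param marks a [generate_surface_marks()] result (same frame as solid).
#' @param solid a [make_template()] result.
#' @param tolerance contact tolerance in Angstrom; default 0.5.
#' @param atom_centers optional n x 3 matrix of atom centers for the
#'   collision flag.
#' @return list with `count`, `per_atom` (named integer vector),
#'   `collision`.
#' @export
contact_count <- function(marks, solid, tolerance = 0.5, atom_centers = NULL) {
  inm <- point_in_material(solid, marks$points)
  d <- distance_to_material(solid, marks$points, surfaces = "pocket")
  hit <- !inm & d <= tolerance
  collision <- any(inm)
  if (!is.null(atom_centers))
    collision <- collision || any(point_in_material(solid, atom_centers))
  per_atom <- tapply(hit, marks$atom, sum)
  list(count = sum(hit),
       per_atom = stats::setNames(as.integer(per_atom), names(per_atom)),
       collision = collision)
}

#' Contact profile over a set of conformations
#'
#' For each conformation state: rebuild coordinates holding the designated
#' anchor fragment at its native pose (the rigid placement rule used in the
#' physical comparison), regenerate the surface marks, and count contacts
#' against the template. Colliding poses are flagged but still reported.
#'
#' @param system ligand in native conformation.
#' @param graph fragment graph of the ligand.
#' @param template the [make_template()] solid.
#' @param conformations named list of conformation states (each a named
#'   vector as in [extract_conformation()]).
#' @param anchor_fragment fragment held fixed; default the graph's first.
#' @param density,tolerance mark density and contact tolerance.
#' @return data.frame of class `contact_report`: state, count, collision.
#' @export
match_profile <- function(system, graph, template, conformations,
                          anchor_fragment = NULL, density = 1,
                          tolerance = 0.5) {
  if (is.null(names(conformations)))
    names(conformations) <- sprintf("state_%d", seq_along(conformations))
  rows <- lapply(names(conformations), function(nm) {
    s2 <- apply_conformation(system, graph, conformations[[nm]],
                             anchor_fragment = anchor_fragment)
    mk <- generate_surface_marks(s2, density = density,
                                 radius_scale = template$radius_scale)
    cc <- contact_count(mk, template, tolerance = tolerance,
                        atom_centers = coords(s2))
    data.frame(state = nm, count = cc$count, collision = cc$collision,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("contact_report", "data.frame")
  out
}
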