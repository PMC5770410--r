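# Conformation kinematics: measuring torsions from coordinates and
# rebuilding coordinates from a set of reported torsion values, fragment by
# fragment, exactly as the physical model is manipulated (hold the anchor
# piece, turn every joint downstream of it).

#' Extract the current conformation of a system
#'
#' Measures every unlocked torsion of `torsions` from the system's current
#' coordinates.
#'
#' @param system a [molecular_system()].
#' @param torsions a torsion set from [identify_torsions()].
#' @return named numeric vector, torsion id to angle in degrees (-180, 180].
#' @export
extract_conformation <- function(system, torsions) {
  tt <- torsions[!torsions$locked, , drop = FALSE]
  out <- numeric(nrow(tt))
  for (k in seq_len(nrow(tt))) {
    out[k] <- measure_torsion(atom_pos(system, tt$a[k]),
                              atom_pos(system, tt$b[k]),
                              atom_pos(system, tt$c[k]),
                              atom_pos(system, tt$d[k]))
  }
  stats::setNames(out, tt$id)
}

#' Rebuild coordinates from a conformation state
#'
#' Holds the anchor fragment fixed and, walking the joint tree breadth-first
#' away from it, rotates each downstream fragment subtree about its joint
#' axis until the measured torsion equals the requested value. Rotations are
#' rigid, so all intra-fragment distances and all bond lengths are preserved.
#'
#' @param system a [molecular_system()].
#' @param graph a [fragment_graph] from [fine_fragment()]/[coarse_fragment()].
#' @param state named numeric vector (torsion id -> degrees) covering every
#'   unlocked joint of the graph; see [extract_conformation()].
#' @param anchor_fragment id of the fragment held fixed; default the
#'   N-terminal (first) fragment.
#' @return the system with rebuilt coordinates.
#' @export
apply_conformation <- function(system, graph, state, anchor_fragment = NULL) {
  jt <- graph$joints
  if (is.null(anchor_fragment)) anchor_fragment <- graph$fragments[[1]]$id
  frag_ids <- vapply(graph$fragments, function(f) f$id, character(1))
  if (!anchor_fragment %in% frag_ids)
    stop("unknown anchor fragment: ", anchor_fragment)
  missing <- setdiff(jt$joint_id, names(state))
  if (length(missing))
    stop("state missing angle(s) for joint(s): ", paste(missing, collapse = ","))
  rng_bad <- vapply(seq_len(nrow(jt)), function(k) {
    v <- normalize_angle(state[[jt$joint_id[k]]])
    v < jt$range_min[k] - 1e-9 || v > jt$range_max[k] + 1e-9
  }, logical(1))
  if (any(rng_bad))
    stop("angle outside allowed range for joint(s): ",
         paste(jt$joint_id[rng_bad], collapse = ","))
  # fragment adjacency over joints
  adj <- lapply(stats::setNames(frag_ids, frag_ids), function(f) {
    k <- which(jt$male_fragment == f | jt$female_fragment == f)
    k[order(jt$joint_id[k])]
  })
  xyz <- coords(system)
  serial_of_row <- system$atoms$serial
  frag_atoms <- lapply(graph$fragments, function(f) f$atom_serials)
  names(frag_atoms) <- frag_ids
  # BFS over fragments; each joint visited once, moving the far side
  visited <- stats::setNames(rep(FALSE, length(frag_ids)), frag_ids)
  visited[anchor_fragment] <- TRUE
  queue <- anchor_fragment
  done_joints <- character(0)
  while (length(queue)) {
    f <- queue[1]; queue <- queue[-1]
    for (k in adj[[f]]) {
      jid <- jt$joint_id[k]
      if (jid %in% done_joints) next
      done_joints <- c(done_joints, jid)
      other <- if (jt$male_fragment[k] == f) jt$female_fragment[k] else jt$male_fragment[k]
      if (visited[other]) next
      # subtree beyond this joint = fragments reachable from `other`
      # without crossing the joint
      sub_frags <- reachable_fragments(jt, adj, other, jid)
      moving_serials <- unlist(frag_atoms[sub_frags], use.names = FALSE)
      rows <- match(moving_serials, serial_of_row)
      pa <- xyz[match(jt$a[k], serial_of_row), ]
      pb <- xyz[match(jt$b[k], serial_of_row), ]
      pc <- xyz[match(jt$c[k], serial_of_row), ]
      pd <- xyz[match(jt$d[k], serial_of_row), ]
      cur <- measure_torsion(pa, pb, pc, pd)
      delta <- normalize_angle(state[[jid]] - cur)
      if (abs(delta) > 1e-13) {
        # rotating the d-side by +delta about the b->c axis increases the
        # dihedral by delta; the b-side moves with the opposite sign
        d_side <- jt$c[k] %in% moving_serials
        ax <- if (d_side) pc - pb else pb - pc
        org <- if (d_side) pc else pb
        R <- rotation_about_axis(ax, delta)
        xyz[rows, ] <- sweep(sweep(xyz[rows, , drop = FALSE], 2, org) %*% t(R),
                             2, org, "+")
      }
      visited[other] <- TRUE
      queue <- c(queue, other)
    }
  }
  set_coords(system, xyz)
}

reachable_fragments <- function(jt, adj, start, blocked_joint) {
  seen <- start
  queue <- start
  while (length(queue)) {
    f <- queue[1]; queue <- queue[-1]
    for (k in adj[[f]]) {
      if (jt$joint_id[k] == blocked_joint) next
      other <- if (jt$male_fragment[k] == f) jt$female_fragment[k] else jt$male_fragment[k]
      if (!other %in% seen) { seen <- c(seen, other); queue <- c(queue, other) }
    }
  }
  seen
}

#' Rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric, Angstrom.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(t(rotation) %*% rotation - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to a whole system
#'
#' @param system a [molecular_system()].
#' @param transform a [rigid_transform()].
#' @return the transformed system; all pairwise distances are preserved.
#' @export
transform_system <- function(system, transform) {
  if (!inherits(transform, "rigid_transform"))
    transform <- rigid_transform(transform$rotation, transform$translation)
  xyz <- coords(system) %*% t(transform$rotation)
  xyz <- sweep(xyz, 2, transform$translation, "+")
  set_coords(system, xyz)
}

transform_points <- function(points, transform) {
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}
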