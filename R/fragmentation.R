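# Rotatable-torsion perception and rigid-fragment decomposition. Cutting the
# axis bond of every unlocked torsion splits the covalent graph into the
# rigid pieces that are 3D printed; each cut bond becomes a revolute joint
# with one gendered, keyed port on each side.

#' Identify rotatable torsions of a peptide system
#'
#' Emits one spec per defined backbone torsion (phi, psi, omega) and, from
#' the bundled chi-definition table, chi1..chi4 per residue. Omega is always
#' emitted locked (the peptide bond is planar at ~0/180 degrees). Chi specs
#' are locked unless their residue is listed in `mobile_side_chains`;
#' receptor side-chain mobility is obtained by passing the receptor system
#' here with the residues of interest selected. Torsions whose axis bond
#' lies in a ring (e.g. proline phi and chi) are emitted locked, since
#' cutting them cannot disconnect the graph. Specs whose four atoms are not
#' all present (chain termini, missing atoms) are suppressed.
#'
#' @param system a [molecular_system()] with bonds.
#' @param mobile_side_chains `"none"` (default), `"all"`, or an integer
#'   vector of residue indices whose chi torsions are unlocked.
#' @return data.frame of class `torsion_set`: id, kind, residue_index,
#'   a, b, c, d (atom serials; b-c is the axis), locked, range_min, range_max.
#' @export
identify_torsions <- function(system, mobile_side_chains = "none") {
  ridx <- system$residues$residue_index
  mobile <- if (identical(mobile_side_chains, "all")) ridx
            else if (identical(mobile_side_chains, "none")) integer(0)
            else as.integer(mobile_side_chains)
  chit <- residue_table("chi")
  specs <- list()
  emit <- function(id, kind, ri, a, b, c, d, locked) {
    if (anyNA(c(a, b, c, d))) {
      message("torsion ", id, " suppressed: defining atoms incomplete")
      return(invisible(NULL))
    }
    specs[[length(specs) + 1]] <<- data.frame(
      id = id, kind = kind, residue_index = ri, a = a, b = b, c = c, d = d,
      locked = locked, range_min = -180, range_max = 180,
      stringsAsFactors = FALSE)
  }
  for (pos in seq_along(ridx)) {
    ri <- ridx[pos]
    rn <- system$residues$residue_name[pos]
    prev <- if (pos > 1) ridx[pos - 1] else NA
    nxt <- if (pos < length(ridx)) ridx[pos + 1] else NA
    N <- find_atom(system, ri, "N"); CA <- find_atom(system, ri, "CA")
    C <- find_atom(system, ri, "C")
    Cprev <- if (!is.na(prev)) find_atom(system, prev, "C") else NA
    Nnext <- if (!is.na(nxt)) find_atom(system, nxt, "N") else NA
    CAnext <- if (!is.na(nxt)) find_atom(system, nxt, "CA") else NA
    if (!is.na(Cprev))
      emit(sprintf("phi_%d", ri), "phi", ri, Cprev, N, CA, C,
           locked = identical(rn, "PRO"))
    if (!is.na(Nnext))
      emit(sprintf("psi_%d", ri), "psi", ri, N, CA, C, Nnext, locked = FALSE)
    if (!is.na(CAnext))
      emit(sprintf("omega_%d", ri), "omega", ri, CA, C, Nnext, CAnext,
           locked = TRUE)
    ch <- chit[chit$res == rn, , drop = FALSE]
    for (k in seq_len(nrow(ch))) {
      quad <- c(find_atom(system, ri, ch$a[k]), find_atom(system, ri, ch$b[k]),
                find_atom(system, ri, ch$c[k]), find_atom(system, ri, ch$d[k]))
      lock_chi <- !(ri %in% mobile) || identical(rn, "PRO")
      emit(sprintf("chi%d_%d", ch$chi[k], ri), paste0("chi", ch$chi[k]), ri,
           quad[1], quad[2], quad[3], quad[4], locked = lock_chi)
    }
  }
  out <- if (length(specs)) do.call(rbind, specs) else
    data.frame(id = character(0), kind = character(0),
               residue_index = integer(0), a = integer(0), b = integer(0),
               c = integer(0), d = integer(0), locked = logical(0),
               range_min = numeric(0), range_max = numeric(0))
  # ring safety: a torsion whose axis is not a bridge of the bond graph can
  # never be cut; emit it locked
  if (nrow(out)) {
    g <- bond_igraph(system)
    br <- igraph::bridges(g)
    bridge_keys <- apply(igraph::ends(g, br), 1, function(e)
      paste(sort(as.integer(e)), collapse = "-"))
    axis_keys <- vapply(seq_len(nrow(out)), function(k)
      paste(sort(c(out$b[k], out$c[k])), collapse = "-"), character(1))
    in_ring <- !(axis_keys %in% bridge_keys)
    if (any(in_ring & !out$locked)) {
      message("torsion(s) ", paste(out$id[in_ring & !out$locked], collapse = ","),
              " locked: axis bond lies in a ring")
      out$locked[in_ring] <- TRUE
    }
  }
  class(out) <- c("torsion_set", "data.frame")
  out
}

#' Fine (automatic) fragmentation
#'
#' Removes the axis bond of every unlocked torsion from the covalent graph;
#' the connected components are the rigid fragments, each removed bond a
#' revolute joint. Ports are assigned by [assign_ports()].
#'
#' @param system a [molecular_system()].
#' @param torsions torsion set from [identify_torsions()].
#' @return a `fragment_graph`: list with `fragments` (each id, atom_serials,
#'   role, ports), `joints` (one row per cut torsion with gendered fragment
#'   assignment and key index) and the originating torsion set.
#' @export
fine_fragment <- function(system, torsions) {
  cut <- torsions[!torsions$locked, , drop = FALSE]
  build_fragment_graph(system, torsions, cut)
}

#' Coarse (user-defined) fragmentation
#'
#' Cuts only the named subset of torsions; everything else stays rigid. This
#' is how a ~21-residue ligand becomes 3 printable pieces of about 7
#' residues: keep two backbone torsions, cut nothing else.
#'
#' @param system a [molecular_system()].
#' @param torsions torsion set from [identify_torsions()].
#' @param keep character vector of torsion ids to keep as joints; must be a
#'   subset of the unlocked torsions.
#' @return a `fragment_graph`; see [fine_fragment()].
#' @export
coarse_fragment <- function(system, torsions, keep) {
  bad <- setdiff(keep, torsions$id)
  if (length(bad)) stop("unknown torsion id(s): ", paste(bad, collapse = ","))
  locked_kept <- intersect(keep, torsions$id[torsions$locked])
  if (length(locked_kept))
    stop("cannot cut locked torsion(s): ", paste(locked_kept, collapse = ","))
  cut <- torsions[torsions$id %in% keep, , drop = FALSE]
  build_fragment_graph(system, torsions, cut)
}

build_fragment_graph <- function(system, torsions, cut) {
  g <- bond_igraph(system)
  # every cut must be a bridge, otherwise removal cannot disconnect
  if (nrow(cut)) {
    br <- igraph::bridges(g)
    bridge_keys <- apply(igraph::ends(g, br), 1, function(e)
      paste(sort(as.integer(e)), collapse = "-"))
    for (k in seq_len(nrow(cut))) {
      key <- paste(sort(c(cut$b[k], cut$c[k])), collapse = "-")
      if (!key %in% bridge_keys)
        stop("torsion ", cut$id[k], ": axis bond lies in a ring and cannot be cut")
    }
  }
  g2 <- g
  if (nrow(cut)) {
    eids <- igraph::get_edge_ids(g2, rbind(as.character(cut$b),
                                           as.character(cut$c)))
    if (any(eids == 0)) stop("torsion axis bond missing from bond graph")
    g2 <- igraph::delete_edges(g2, eids)
  }
  comp <- igraph::components(g2)$membership
  serials <- as.integer(names(comp))
  backbone_names <- c("N", "CA", "C", "O", "OXT", "H")
  frag_list <- split(serials, comp)
  # deterministic ids ordered by smallest contained serial
  ord <- order(vapply(frag_list, min, numeric(1)))
  frag_list <- frag_list[ord]
  fragments <- vector("list", length(frag_list))
  memb <- integer(0)
  for (k in seq_along(frag_list)) {
    ser <- sort(frag_list[[k]])
    nm <- system$atoms$name[match(ser, system$atoms$serial)]
    role <- if (any(nm %in% backbone_names)) "main_chain" else "side_chain"
    fragments[[k]] <- list(id = sprintf("F%d", k), atom_serials = ser,
                           role = role, ports = list())
    memb[as.character(ser)] <- k
  }
  joints <- if (nrow(cut)) data.frame(
    joint_id = cut$id, kind = cut$kind, a = cut$a, b = cut$b, c = cut$c,
    d = cut$d, range_min = cut$range_min, range_max = cut$range_max,
    male_fragment = sprintf("F%d", memb[as.character(cut$b)]),
    female_fragment = sprintf("F%d", memb[as.character(cut$c)]),
    key_index = key_index_of(cut$kind),
    stringsAsFactors = FALSE
  ) else data.frame(joint_id = character(0), kind = character(0),
                    a = integer(0), b = integer(0), c = integer(0),
                    d = integer(0), range_min = numeric(0),
                    range_max = numeric(0), male_fragment = character(0),
                    female_fragment = character(0), key_index = integer(0))
  rownames(joints) <- NULL
  graph <- structure(list(fragments = fragments, joints = joints,
                          torsions = torsions),
                     class = "fragment_graph")
  assign_ports(graph, system)
}

# one keying class per joint kind so a phi pin never fits a psi hole
key_index_of <- function(kind) {
  ix <- c(phi = 1L, psi = 2L, omega = 4L, custom = 4L)
  out <- unname(ix[kind])
  out[startsWith(kind, "chi")] <- 3L
  out[is.na(out)] <- 4L
  out
}

#' Assign gendered ports to every joint of a fragment graph
#'
#' The fragment containing the N-proximal axis atom (atom `b` of the quad,
#' written N- to C-terminal) carries the male port; for side-chain joints
#' that is the fragment containing CA. The port axis points from the male
#' anchor atom toward the female anchor; the key index is shared by all
#' joints of the same kind, so only matching joint kinds can mate.
#'
#' @param graph a `fragment_graph`.
#' @param system the originating [molecular_system()] (for anchor positions).
#' @return the graph with `ports` filled in on every fragment.
#' @export
assign_ports <- function(graph, system) {
  for (k in seq_along(graph$fragments)) graph$fragments[[k]]$ports <- list()
  jt <- graph$joints
  frag_ids <- vapply(graph$fragments, function(f) f$id, character(1))
  for (k in seq_len(nrow(jt))) {
    mi <- match(jt$male_fragment[k], frag_ids)
    fi <- match(jt$female_fragment[k], frag_ids)
    if (is.na(mi) || is.na(fi) || mi == fi)
      stop("joint ", jt$joint_id[k], ": axis atoms not split across two fragments")
    axis <- unit(atom_pos(system, jt$c[k]) - atom_pos(system, jt$b[k]))
    male <- list(gender = "male", joint_id = jt$joint_id[k],
                 anchor_atom = jt$b[k], axis_direction = axis,
                 key_index = jt$key_index[k])
    female <- list(gender = "female", joint_id = jt$joint_id[k],
                   anchor_atom = jt$c[k], axis_direction = axis,
                   key_index = jt$key_index[k])
    graph$fragments[[mi]]$ports <- c(graph$fragments[[mi]]$ports, list(male))
    graph$fragments[[fi]]$ports <- c(graph$fragments[[fi]]$ports, list(female))
  }
  graph
}

#' @export
print.fragment_graph <- function(x, ...) {
  cat(sprintf("fragment_graph: %d fragments, %d joints\n",
              length(x$fragments), nrow(x$joints)))
  for (f in x$fragments)
    cat(sprintf("  %s: %d atoms, %s, %d port(s)\n", f$id,
                length(f$atom_serials), f$role, length(f$ports)))
  invisible(x)
}

#' Serialize a fragment graph to JSON
#'
#' Writes fragments (atom serials, role, ports), joints and torsion specs in
#' a documented JSON structure consumed by the CAD and kinematics layers.
#'
#' @param graph a `fragment_graph`.
#' @param path output file; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
fragment_graph_json <- function(graph, path = NULL) {
  obj <- list(
    fragments = lapply(graph$fragments, function(f)
      list(id = f$id, atom_serials = f$atom_serials, role = f$role,
           ports = f$ports)),
    joints = graph$joints,
    torsions = as.data.frame(graph$torsions)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
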