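# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; no binary data.

# residue pool for random peptides: no proline (ring handling is exercised
# separately), no glycine bias
FIXTURE_LETTERS <- c("A", "G", "S", "V", "L", "T", "E", "K", "N", "Q")

random_sequence <- function(n_res) {
  paste(sample(FIXTURE_LETTERS, n_res, replace = TRUE), collapse = "")
}

random_torsions <- function(n_res) {
  tors <- lapply(seq_len(n_res), function(i)
    list(phi = runif(1, -180, 180), psi = runif(1, -180, 180)))
  names(tors) <- as.character(seq_len(n_res))
  tors
}

random_peptide <- function(n_res) {
  build_ideal_peptide(random_sequence(n_res), torsions = random_torsions(n_res))
}

# the synthetic stand-in for the worked example's N-terminal peptide:
# 4 ideal-geometry residues with valine at position 2, helix-like native
# torsions; "3.5 residues" = residues 1-3 plus the backbone of residue 4
synthetic_nterm_peptide <- function() {
  build_ideal_peptide("GVSA", torsions = list(
    `1` = list(psi = -45), `2` = list(phi = -60, psi = -45),
    `3` = list(phi = -70, psi = -40), `4` = list(phi = -65)))
}

select_3p5_residues <- function(system) {
  a <- system$atoms
  keep <- a$serial[a$residue_index <= 3 |
                     (a$residue_index == 4 & a$name %in% c("N", "CA", "C", "O"))]
  subset_atoms(system, keep)
}

# a 3-residue, 3-piece fixture in the style of the contact-scoring
# demonstration: one joint at each residue boundary, so the pieces are
# roughly residue-sized; returns the system, graph and the two joint ids
draw_three_piece_fixture <- function() {
  repeat {
    s <- build_ideal_peptide(random_sequence(3),
                             torsions = random_torsions(3))
    tor <- identify_torsions(s)
    keep <- c(sample(c("psi_1", "phi_2"), 1), sample(c("psi_2", "phi_3"), 1))
    if (all(keep %in% tor$id[!tor$locked]) && feasible(s)$feasible) {
      return(list(system = s, torsions = tor,
                  graph = coarse_fragment(s, tor, keep = keep),
                  keep = keep))
    }
  }
}

# fixed two-atom system used by the golden-file CAD checks
two_golden_system <- function() {
  molecular_system(data.frame(
    serial = 1:2, name = c("C1", "C2"), element = "C",
    x = c(0, 2.5), y = 0, z = c(0, 0.8), vdw_radius = 1.7,
    partial_charge = 0, residue_index = 1, residue_name = "UNK",
    residue_label = 1), rbind(c(1, 2)))
}

# --- independent oracles -------------------------------------------------

# flood-fill connected components over an explicit adjacency list; no igraph
oracle_components <- function(serials, bonds) {
  adj <- stats::setNames(vector("list", length(serials)),
                         as.character(serials))
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- as.character(bonds[k, 1]); j <- as.character(bonds[k, 2])
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  comp <- stats::setNames(rep(NA_integer_, length(serials)),
                          as.character(serials))
  cur <- 0L
  for (s in as.character(serials)) {
    if (!is.na(comp[[s]])) next
    cur <- cur + 1L
    queue <- s
    comp[[s]] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(comp[[w]])) {
        comp[[w]] <- cur; queue <- c(queue, w)
      }
    }
  }
  comp
}

# second dihedral implementation: explicit plane normals, acos magnitude and
# triple-product sign (independent of the atan2 path in the package)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  cosv <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, cosv))) * 180 / pi
  if (sum(n1 * b3) < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

# BFS bond-graph distances up to a cap, by hand
oracle_bond_distance <- function(serials, bonds, cap = 4) {
  n <- length(serials)
  idx <- stats::setNames(seq_len(n), as.character(serials))
  adj <- vector("list", n)
  if (nrow(bonds)) for (k in seq_len(nrow(bonds))) {
    i <- idx[[as.character(bonds[k, 1])]]; j <- idx[[as.character(bonds[k, 2])]]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    for (d in seq_len(cap)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[D[s, nxt] == Inf]
      if (!length(nxt)) break
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  dimnames(D) <- list(serials, serials)
  D
}

# direct-from-definition CSG membership, written against the template fields
# (independent of the package's point_in_material code path)
oracle_in_material <- function(solid, p) {
  q <- as.numeric(p %*% t(solid$up_rotation))
  b <- solid$box
  if (!(q[1] > b$xmin && q[1] < b$xmax && q[2] > b$ymin && q[2] < b$ymax &&
        q[3] > b$zmin && q[3] < b$zmax)) return(FALSE)
  for (k in seq_along(solid$radii)) {
    ck <- solid$centers[k, ]; rk <- solid$radii[k] + 1e-9
    if (sum((q - ck)^2) < rk^2) return(FALSE)
    if (q[3] >= ck[3] - 1e-9 &&
        (q[1] - ck[1])^2 + (q[2] - ck[2])^2 < rk^2) return(FALSE)
  }
  TRUE
}

# brute-force distance of a point to the pocket surfaces by dense sampling
# of the carve sphere / cylinder walls, keeping only samples on the material
# boundary; resolution ~`step` Angstrom
oracle_pocket_distance <- function(solid, p, step = 0.05) {
  q <- as.numeric(p %*% t(solid$up_rotation))
  best <- Inf
  for (k in seq_along(solid$radii)) {
    ck <- solid$centers[k, ]; rk <- solid$radii[k]
    npts <- max(200L, as.integer(round(4 * pi * rk^2 / step^2)))
    sp <- fibonacci_sphere(npts) * (rk + 1e-6)
    sp <- sweep(sp, 2, ck, "+")
    # keep boundary samples adjacent to material
    probe <- sweep(sp, 2, ck) * ((rk + 1e-4) / (rk + 1e-6))
    probe <- sweep(probe, 2, ck, "+")
    ok <- vapply(seq_len(nrow(sp)), function(i)
      oracle_in_material(solid, matrix(probe[i, ] %*% solid$up_rotation, 1)),
      logical(1))
    if (any(ok)) {
      d <- sqrt(rowSums(sweep(sp[ok, , drop = FALSE], 2, q)^2))
      best <- min(best, min(d))
    }
    # cylinder wall samples from the sphere equator up to the box top
    if (ck[3] > solid$box$zmax) next
    zs <- seq(ck[3], solid$box$zmax, by = step)
    ths <- seq(0, 2 * pi, length.out = max(16, ceiling(2 * pi * rk / step)))
    for (z in zs) {
      wall <- cbind(ck[1] + rk * cos(ths), ck[2] + rk * sin(ths), z)
      pr <- cbind(ck[1] + (rk + 1e-4) * cos(ths),
                  ck[2] + (rk + 1e-4) * sin(ths), z)
      ok <- vapply(seq_len(nrow(wall)), function(i)
        oracle_in_material(solid, matrix(pr[i, ] %*% solid$up_rotation, 1)),
        logical(1))
      if (any(ok)) {
        d <- sqrt(rowSums(sweep(wall[ok, , drop = FALSE], 2, q)^2))
        best <- min(best, min(d))
      }
    }
  }
  best
}
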