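one_atom_system <- function(r_elem = "C") {
  molecular_system(data.frame(
    serial = 1L, name = "C1", element = r_elem, x = 0, y = 0, z = 0,
    vdw_radius = vdw_radius_of(r_elem), partial_charge = 0,
    residue_index = 1, residue_name = "UNK", residue_label = 1), NULL)
}

two_atom_system <- function(dx, dz = 0) {
  molecular_system(data.frame(
    serial = 1:2, name = c("C1", "C2"), element = "C",
    x = c(0, dx), y = 0, z = c(0, dz), vdw_radius = 1.7,
    partial_charge = 0, residue_index = 1, residue_name = "UNK",
    residue_label = 1), rbind(c(1, 2)))
}

test_that("mark counts follow the density formula on an isolated sphere", {
  s <- one_atom_system()
  for (d in c(0.5, 1, 3)) {
    mk <- generate_surface_marks(s, density = d)
    R <- 1.7 * mk$radius_scale
    expect_equal(nrow(mk$points), round(d * 4 * pi * R^2))
    expect_lt(max(abs(sqrt(rowSums(mk$points^2)) - R)), 1e-9)
  }
  expect_error(generate_surface_marks(s, density = 0), "density")
})

test_that("buried-mark pruning matches the spherical-cap expectation", {
  # identical spheres, centers half a radius apart: the retained fraction of
  # each sphere is 1 - cap/(4 pi R^2) = 1 - (R - d/2) / (2 R)
  R <- 1.7 * 0.7
  d <- R / 2
  s <- two_atom_system(dx = d)  # centers half a printed radius apart
  s$atoms$vdw_radius <- 1.7
  mk <- generate_surface_marks(s, density = 6)
  n_each <- round(6 * 4 * pi * R^2)
  frac <- as.numeric(table(mk$atom)) / n_each
  want <- 1 - (R - d / 2) / (2 * R)
  # Monte-Carlo oracle for the same quantity
  set.seed(4)
  u <- matrix(rnorm(3 * 20000), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * R
  mc <- mean(sqrt((u[, 1] - d)^2 + u[, 2]^2 + u[, 3]^2) >= R)
  expect_equal(mc, want, tolerance = 0.02)
  expect_equal(frac[1], want, tolerance = 0.05)
  expect_equal(frac[2], want, tolerance = 0.05)
})

test_that("the spherical lattice is near-uniform (low nn-distance spread)", {
  p <- fibonacci_sphere(300)
  d <- as.matrix(dist(p))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_lt(sd(nn) / mean(nn), 0.25)
  # versus random placement, which is markedly less even
  set.seed(8)
  u <- matrix(rnorm(900), ncol = 3); u <- u / sqrt(rowSums(u^2))
  dr <- as.matrix(dist(u)); diag(dr) <- Inf
  nnr <- apply(dr, 1, min)
  expect_gt(sd(nnr) / mean(nnr), sd(nn) / mean(nn))
})

test_that("template membership equals the direct CSG oracle", {
  s <- two_atom_system(dx = 2.5, dz = 0.8)
  tpl <- make_template(s)
  expect_false(point_in_material(tpl, c(1000, 0, 0)))
  expect_false(point_in_material(tpl, tpl$centers[1, ] %*% tpl$up_rotation))
  set.seed(17)
  b <- tpl$box
  probes <- cbind(runif(1000, b$xmin - 1, b$xmax + 1),
                  runif(1000, b$ymin - 1, b$ymax + 1),
                  runif(1000, b$zmin - 1, b$zmax + 1))
  got <- point_in_material(tpl, probes)
  want <- vapply(seq_len(1000), function(i)
    oracle_in_material(tpl, matrix(probes[i, ], 1)), logical(1))
  expect_identical(got, want)
})

test_that("box geometry: footprint padded by max radius, lower-half height", {
  s <- build_ideal_peptide("GAG")
  tpl <- make_template(s, radius_scale = 0.7)
  cz <- coords(s)
  pad <- max(s$atoms$vdw_radius) * 0.7
  expect_equal(tpl$box$xmin, min(cz[, 1]) - pad)
  expect_equal(tpl$box$xmax, max(cz[, 1]) + pad)
  expect_equal(tpl$box$zmax - tpl$box$zmin,
               (max(cz[, 3]) - min(cz[, 3])) / 2)
  expect_equal(tpl$box$zmin, min(cz[, 3]))
  expect_error(make_template(one_atom_system(), radius_scale = 0.7),
               "at least 2")
})

test_that("the native ligand rests in its own mold without collision", {
  s <- build_ideal_peptide("GVSA", torsions = list(
    `2` = list(phi = -60, psi = -45), `3` = list(phi = -70, psi = -40)))
  tpl <- make_template(s)
  expect_false(any(point_in_material(tpl, coords(s))))
  mk <- generate_surface_marks(s, density = 1)
  cc <- contact_count(mk, tpl, atom_centers = coords(s))
  expect_false(cc$collision)
  expect_gt(cc$count, 0)
})

test_that("contact counting: zero far away, tolerance-monotone, oracle match", {
  s <- two_atom_system(dx = 2.5, dz = 0.4)
  tpl <- make_template(s)
  mk <- generate_surface_marks(s, density = 1.5)
  far <- mk
  far$points <- sweep(mk$points, 2, c(100, 0, 0), "+")
  expect_equal(contact_count(far, tpl)$count, 0L)

  counts <- vapply(c(0.1, 0.3, 0.5, 1), function(tol)
    contact_count(mk, tpl, tolerance = tol)$count, integer(1))
  expect_true(all(diff(counts) >= 0))

  # per-mark classification against the dense-sampling oracle (0.05 A
  # resolution; marks within the oracle's resolution of the threshold are
  # classified by construction and skipped)
  tol <- 0.5
  cc <- contact_count(mk, tpl, tolerance = tol)
  inm <- point_in_material(tpl, mk$points)
  d_oracle <- vapply(seq_len(nrow(mk$points)), function(i)
    oracle_pocket_distance(tpl, matrix(mk$points[i, ], 1)), numeric(1))
  hit_oracle <- !inm & d_oracle <= tol
  decisive <- abs(d_oracle - tol) > 0.06
  got <- !inm & vapply(seq_len(nrow(mk$points)), function(i) TRUE, logical(1))
  # recompute per-mark hits the way contact_count does
  d_pkg <- pepfab:::distance_to_material(tpl, mk$points, surfaces = "pocket")
  hit_pkg <- !inm & d_pkg <= tol
  expect_identical(hit_pkg[decisive], hit_oracle[decisive])
  expect_equal(cc$count, sum(hit_pkg))
})

test_that("contact count is invariant under a common rigid motion", {
  s <- build_ideal_peptide("GAG")
  tpl <- make_template(s)
  mk <- generate_surface_marks(s, density = 1.2)
  set.seed(31)
  R <- rotation_about_axis(rnorm(3), runif(1, 0, 360))
  tr <- rigid_transform(R, rnorm(3, sd = 4))
  tpl2 <- transform_template(tpl, tr)
  mk2 <- mk
  mk2$points <- pepfab:::transform_points(mk$points, tr)
  c1 <- contact_count(mk, tpl)
  c2 <- contact_count(mk2, tpl2)
  expect_equal(c2$count, c1$count)
  expect_equal(c2$per_atom, c1$per_atom)
})

test_that("match profiles: native maximal over the four flip conformations", {
  s <- build_ideal_peptide("GVSA", torsions = list(
    `2` = list(phi = -60, psi = -45), `3` = list(phi = -70, psi = -40)))
  tor <- identify_torsions(s)
  g <- coarse_fragment(s, tor, keep = c("phi_2", "psi_2"))
  tpl <- make_template(s)
  native <- extract_conformation(s, tor)[g$joints$joint_id]
  states <- list(native = native)
  for (nm in list(c(180, 0), c(0, 180), c(180, 180))) {
    st <- native
    st["phi_2"] <- normalize_angle(st["phi_2"] + nm[1])
    st["psi_2"] <- normalize_angle(st["psi_2"] + nm[2])
    states[[sprintf("flip_%d_%d", nm[1], nm[2])]] <- st
  }
  rep <- match_profile(s, g, tpl, states, anchor_fragment = "F3")
  expect_equal(nrow(rep), 4L)
  expect_true(all(rep$count[1] > rep$count[-1]))
  # duplicated state gives identical counts
  rep2 <- match_profile(s, g, tpl, states[c(1, 1)], anchor_fragment = "F3")
  expect_equal(rep2$count[1], rep2$count[2])
})

test_that("self-mold maximality holds across seeded random fixtures", {
  set.seed(2024)
  n_draws <- 25
  wins <- 0
  for (draw in seq_len(n_draws)) {
    fx <- draw_three_piece_fixture()
    s <- fx$system; g <- fx$graph; keep <- fx$keep
    tpl <- make_template(s)
    native <- extract_conformation(s, fx$torsions)[g$joints$joint_id]
    states <- list(native = native)
    for (k in 1:6) {
      st <- native
      st[keep] <- normalize_angle(native[keep] +
                                    sample(c(-1, 1), 2, TRUE) *
                                    runif(2, 40, 180))
      states[[paste0("pert", k)]] <- st
    }
    rep <- match_profile(s, g, tpl, states, density = 0.8)
    if (all(rep$count[1] > rep$count[-1])) wins <- wins + 1
  }
  expect_gte(wins / n_draws, 0.95)
})
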