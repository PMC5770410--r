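# Deterministic OpenSCAD-dialect script emission. Only a restricted
# primitive set is used (sphere, cylinder, cube, union, difference,
# intersection, translate, rotate) so that any CSG renderer can consume the
# scripts; every number is printed with fixed 6-decimal formatting, making
# the output byte-deterministic for fixed inputs. STL rendering and slicing
# stay external (OpenSCAD + slicer), exactly as a print shop would run them.

#' CAD emission options
#'
#' @param scale millimetres of printed model per Angstrom of molecule. The
#'   default (3.5) prints a carbon sphere at radius scale 0.7 just over 8 mm
#'   in diameter, comfortable to handle.
#' @param radius_scale multiplicative factor on vdW radii (default 0.7, the
#'   trade-off between space-filling realism and reachable conformation
#'   space).
#' @param joint_diameter_mm,joint_depth_mm,joint_clearance_mm revolute joint
#'   pin diameter, depth, and radial clearance added to the female hole.
#' @param tick_increment_deg angular spacing of the measurement marks around
#'   each female port; must divide 360. Every third tick is cut deeper as an
#'   index mark.
#' @param charge_unit_e partial charge per charge glyph (elementary charges).
#' @param glyph_size_mm edge length of a charge glyph.
#' @param sphere_facets tessellation level passed to the renderer ($fn).
#' @return object of class `cad_options`.
#' @export
cad_options <- function(scale = 3.5, radius_scale = 0.7,
                        joint_diameter_mm = 5, joint_depth_mm = 5,
                        joint_clearance_mm = 0.2, tick_increment_deg = 20,
                        charge_unit_e = 0.1, glyph_size_mm = 2,
                        sphere_facets = 48) {
  stopifnot(scale > 0, radius_scale > 0, charge_unit_e > 0,
            360 %% tick_increment_deg == 0)
  structure(list(scale = scale, radius_scale = radius_scale,
                 joint_diameter_mm = joint_diameter_mm,
                 joint_depth_mm = joint_depth_mm,
                 joint_clearance_mm = joint_clearance_mm,
                 tick_increment_deg = tick_increment_deg,
                 charge_unit_e = charge_unit_e, glyph_size_mm = glyph_size_mm,
                 sphere_facets = sphere_facets),
            class = "cad_options")
}

num <- function(x) sprintf("%.6f", x)
vec3 <- function(v) sprintf("[%s, %s, %s]", num(v[1]), num(v[2]), num(v[3]))

# rotate([0, polar, azimuth]) aligns the +z axis of a primitive with v
align_angles <- function(v) {
  u <- unit(v)
  c(0, rad2deg(acos(max(-1, min(1, u[3])))), rad2deg(atan2(u[2], u[1])))
}

scad_sphere <- function(center_mm, r_mm, fn) {
  sprintf("translate(%s) sphere(r = %s, $fn = %d);",
          vec3(center_mm), num(r_mm), fn)
}

scad_cylinder_along <- function(base_mm, axis, h_mm, r_mm, fn) {
  ang <- align_angles(axis)
  sprintf("translate(%s) rotate(%s) cylinder(h = %s, r = %s, $fn = %d);",
          vec3(base_mm), vec3(ang), num(h_mm), num(r_mm), fn)
}

#' Charge glyph placements for one atom
#'
#' The number of glyphs is round(|q| / charge_unit_e); their positions are
#' spread on the printed atom sphere with the deterministic Fibonacci
#' lattice. The glyph shape encodes the sign: a cross for positive partial
#' charge, a bar for negative.
#'
#' @param atom one-row slice of a system's atom table.
#' @param options a [cad_options()].
#' @return data.frame with columns x, y, z (molecule-space positions on the
#'   sphere), sign ("+"/"-"); zero rows when the charge rounds to nothing.
#' @export
embed_charge_marks <- function(atom, options = cad_options()) {
  q <- atom$partial_charge
  n <- round(abs(q) / options$charge_unit_e)
  if (n < 1)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      sign = character(0)))
  r <- atom$vdw_radius * options$radius_scale
  p <- fibonacci_sphere(n) * r
  data.frame(x = atom$x + p[, 1], y = atom$y + p[, 2], z = atom$z + p[, 3],
             sign = rep(if (q > 0) "+" else "-", n),
             stringsAsFactors = FALSE)
}

glyph_scad <- function(center_mm, outward, sign, options) {
  g <- options$glyph_size_mm
  ang <- align_angles(outward)
  bar <- sprintf("cube([%s, %s, %s], center = true);",
                 num(g), num(g / 3), num(g / 3))
  body <- if (sign == "+")
    paste0("union() { ", bar, " ",
           sprintf("cube([%s, %s, %s], center = true);",
                   num(g / 3), num(g), num(g / 3)), " }")
  else bar
  sprintf("translate(%s) rotate(%s) %s", vec3(center_mm), vec3(ang), body)
}

#' Emit the printable solid of one rigid fragment
#'
#' The script is the union of the fragment's atom spheres (scaled positions
#' and radii) and its male port pins (keyed polygonal collar + cylindrical
#' pin along the joint axis), minus the female port holes (pin plus radial
#' clearance), minus a ring of measurement tick notches around each female
#' port rim (one notch per `tick_increment_deg`, every third notch deeper as
#' an index), plus embossed charge glyphs. Output is byte-deterministic.
#'
#' @param fragment one fragment of a `fragment_graph`.
#' @param system the originating [molecular_system()].
#' @param options a [cad_options()].
#' @return single string, the OpenSCAD-dialect script.
#' @export
fragment_to_scad <- function(fragment, system, options = cad_options()) {
  sc <- options$scale
  fn <- options$sphere_facets
  a <- system$atoms[match(fragment$atom_serials, system$atoms$serial), ,
                    drop = FALSE]
  adds <- character(0); subs <- character(0)
  for (k in seq_len(nrow(a))) {
    adds <- c(adds, scad_sphere(c(a$x[k], a$y[k], a$z[k]) * sc,
                                a$vdw_radius[k] * options$radius_scale * sc,
                                fn))
    gm <- embed_charge_marks(a[k, ], options)
    for (m in seq_len(nrow(gm))) {
      out_dir <- c(gm$x[m] - a$x[k], gm$y[m] - a$y[k], gm$z[m] - a$z[k])
      adds <- c(adds, glyph_scad(c(gm$x[m], gm$y[m], gm$z[m]) * sc,
                                 out_dir, gm$sign[m], options))
    }
  }
  for (port in fragment$ports) {
    anchor <- atom_pos(system, port$anchor_atom) * sc
    ax <- port$axis_direction
    if (vnorm(ax) < 1e-12) stop("port axis of zero length")
    pin_r <- options$joint_diameter_mm / 2
    depth <- options$joint_depth_mm
    key_sides <- 3 + port$key_index
    if (port$gender == "male") {
      adds <- c(adds,
                scad_cylinder_along(anchor, ax, depth, pin_r, fn),
                # keyed collar: low-facet cylinder = keying polygon prism
                scad_cylinder_along(anchor, ax, depth / 2, pin_r * 1.4,
                                    key_sides))
    } else {
      hole_r <- pin_r + options$joint_clearance_mm
      subs <- c(subs,
                scad_cylinder_along(anchor, -ax, depth, hole_r, fn),
                scad_cylinder_along(anchor, -ax, depth / 2,
                                    pin_r * 1.4 + options$joint_clearance_mm,
                                    key_sides))
      subs <- c(subs, tick_notches(anchor, ax, options))
    }
  }
  paste0(c(sprintf("// fragment %s: %d atoms, %d port(s)", fragment$id,
                   nrow(a), length(fragment$ports)),
           "difference() {",
           "  union() {",
           paste0("    ", adds),
           "  }",
           paste0("  ", subs),
           "}"), collapse = "\n")
}

# measurement marks: notches around the female port rim, deeper every third
tick_notches <- function(anchor_mm, axis, options) {
  inc <- options$tick_increment_deg
  nticks <- as.integer(360 / inc)
  rim_r <- options$joint_diameter_mm / 2 * 1.6
  # local frame perpendicular to the axis
  u <- unit(axis)
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit(cross3(u, ref)); e2 <- cross3(u, e1)
  out <- character(nticks)
  for (t in seq_len(nticks)) {
    th <- deg2rad((t - 1) * inc)
    depth <- if ((t - 1) %% 3 == 0) 1.0 else 0.5
    pos <- anchor_mm + (cos(th) * e1 + sin(th) * e2) * rim_r
    out[t] <- sprintf("translate(%s) cube([%s, %s, %s], center = true);",
                      vec3(pos), num(0.6), num(0.6), num(depth * 2))
  }
  out
}

#' Emit the semi-perfect template as a CSG script
#'
#' difference(box, carve spheres..., upward sweep cylinders...), all
#' dimensions multiplied by the print scale.
#'
#' @param solid a [make_template()] result.
#' @param options a [cad_options()].
#' @return single string, the OpenSCAD-dialect script.
#' @export
template_to_scad <- function(solid, options = cad_options()) {
  sc <- options$scale
  fn <- options$sphere_facets
  b <- solid$box
  size <- c(b$xmax - b$xmin, b$ymax - b$ymin, b$zmax - b$zmin) * sc
  org <- c(b$xmin, b$ymin, b$zmin) * sc
  lines <- c("difference() {",
             sprintf("  translate(%s) cube(%s);", vec3(org), vec3(size)))
  top <- b$zmax
  for (k in seq_along(solid$radii)) {
    ck <- solid$centers[k, ] * sc
    rk <- solid$radii[k] * sc
    lines <- c(lines, paste0("  ", scad_sphere(ck, rk, fn)))
    h <- (top * sc - ck[3]) + rk  # sweep from center to above the box top
    if (h > 0)
      lines <- c(lines, paste0("  ", scad_cylinder_along(ck, c(0, 0, 1),
                                                         h, rk, fn)))
  }
  paste0(c(lines, "}"), collapse = "\n")
}

#' Split a solid into printable segments along an axis
#'
#' Intersects the script of a solid (template) or of a whole system's
#' space-filling model with `n_segments` equal slabs along one axis; the
#' union of the segments reproduces the original solid.
#'
#' @param x a `template_solid` or a [molecular_system()].
#' @param n_segments number of slabs (>= 2).
#' @param axis one of "x", "y", "z".
#' @param options a [cad_options()].
#' @return character vector of `n_segments` scripts.
#' @export
split_for_print <- function(x, n_segments, axis = "z",
                            options = cad_options()) {
  if (n_segments < 2) stop("n_segments must be at least 2")
  axis_i <- match(axis, c("x", "y", "z"))
  if (is.na(axis_i)) stop("axis must be x, y or z")
  sc <- options$scale
  if (inherits(x, "template_solid")) {
    base <- template_to_scad(x, options)
    b <- x$box
    lo <- c(b$xmin, b$ymin, b$zmin); hi <- c(b$xmax, b$ymax, b$zmax)
  } else {
    base <- system_to_scad(x, options)
    xyz <- coords(x)
    pad <- max(x$atoms$vdw_radius) * options$radius_scale
    lo <- apply(xyz, 2, min) - pad; hi <- apply(xyz, 2, max) + pad
  }
  width <- (hi[axis_i] - lo[axis_i]) / n_segments
  if (width * sc < 1) stop("segments thinner than 1 mm; reduce n_segments")
  margin <- (hi - lo) + 2  # slab extends past the solid in the other axes
  vapply(seq_len(n_segments), function(k) {
    org <- lo - 1
    org[axis_i] <- lo[axis_i] + (k - 1) * width
    size <- margin
    size[axis_i] <- width
    paste0(c(sprintf("// segment %d of %d along %s", k, n_segments, axis),
             "intersection() {",
             paste0("  ", strsplit(base, "\n", fixed = TRUE)[[1]]),
             sprintf("  translate(%s) cube(%s);", vec3(org * sc),
                     vec3(size * sc)),
             "}"), collapse = "\n")
  }, character(1))
}

#' Space-filling script of a whole system (receptor model)
#'
#' @param system a [molecular_system()].
#' @param options a [cad_options()].
#' @return single string, union of all scaled atom spheres.
#' @export
system_to_scad <- function(system, options = cad_options()) {
  sc <- options$scale
  a <- system$atoms
  lines <- vapply(seq_len(nrow(a)), function(k)
    paste0("  ", scad_sphere(c(a$x[k], a$y[k], a$z[k]) * sc,
                             a$vdw_radius[k] * options$radius_scale * sc,
                             options$sphere_facets)), character(1))
  paste0(c("union() {", lines, "}"), collapse = "\n")
}

#' Printed-size report of a fragment over several scales
#'
#' @param fragment one fragment of a `fragment_graph`.
#' @param system the originating system.
#' @param scales numeric vector of mm-per-Angstrom scale factors.
#' @param options a [cad_options()] (for the radius scale).
#' @return data.frame with scale and the printed bounding box (mm) per axis:
#'   atom-center extent plus twice the largest printed sphere radius.
#' @export
scale_preview <- function(fragment, system, scales, options = cad_options()) {
  stopifnot(all(scales > 0))
  a <- system$atoms[match(fragment$atom_serials, system$atoms$serial), ,
                    drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rmax <- max(a$vdw_radius) * options$radius_scale
  ext <- apply(xyz, 2, function(v) diff(range(v))) + 2 * rmax
  out <- data.frame(scale = scales,
                    x_mm = ext[1] * scales, y_mm = ext[2] * scales,
                    z_mm = ext[3] * scales)
  rownames(out) <- NULL
  out
}

#' Write every part of a fragment graph as .scad files with a manifest
#'
#' @param graph a `fragment_graph`.
#' @param system the originating system.
#' @param dir output directory (created if needed).
#' @param options a [cad_options()].
#' @param template optional `template_solid` to emit alongside.
#' @return path of the manifest JSON, invisibly.
#' @export
export_cad <- function(graph, system, dir, options = cad_options(),
                       template = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parts <- list()
  for (f in graph$fragments) {
    file <- file.path(dir, paste0(f$id, ".scad"))
    writeLines(fragment_to_scad(f, system, options), file)
    parts[[length(parts) + 1]] <-
      list(id = f$id, file = basename(file), role = f$role,
           n_atoms = length(f$atom_serials),
           ports = lapply(f$ports, function(p)
             list(joint_id = p$joint_id, gender = p$gender,
                  key_index = p$key_index)))
  }
  if (!is.null(template)) {
    file <- file.path(dir, "template.scad")
    writeLines(template_to_scad(template, options), file)
    parts[[length(parts) + 1]] <- list(id = "template",
                                       file = basename(file),
                                       role = "receptor_template")
  }
  manifest <- list(n_fragments = length(graph$fragments),
                   joints = graph$joints, options = unclass(options),
                   parts = parts)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}
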