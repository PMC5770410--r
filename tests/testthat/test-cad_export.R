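scad_numbers <- function(line, key) {
  m <- regmatches(line, gregexpr("-?[0-9]+\\.[0-9]{6}", line))[[1]]
  as.numeric(m)
}

test_that("a single-atom, portless fragment is exactly one sphere", {
  s <- molecular_system(data.frame(
    serial = 1L, name = "C1", element = "C", x = 1, y = -2, z = 0.5,
    vdw_radius = 1.7, partial_charge = 0, residue_index = 1,
    residue_name = "UNK", residue_label = 1), NULL)
  frag <- list(id = "F1", atom_serials = 1L, role = "main_chain",
               ports = list())
  opt <- cad_options(scale = 2)
  sc <- fragment_to_scad(frag, s, opt)
  expect_equal(length(gregexpr("sphere(", sc, fixed = TRUE)[[1]]), 1L)
  sphere_line <- grep("sphere(", strsplit(sc, "\n")[[1]], fixed = TRUE,
                      value = TRUE)
  nums <- scad_numbers(sphere_line)
  expect_equal(nums[1:3], c(1, -2, 0.5) * 2, tolerance = 1e-6)
  expect_equal(nums[4], 1.7 * opt$radius_scale * 2, tolerance = 1e-6)
})

test_that("script emission is byte-deterministic (golden)", {
  s <- build_ideal_peptide("GAG", torsions = list(`2` = list(phi = -60,
                                                             psi = -45)))
  g <- fine_fragment(s, identify_torsions(s))
  opt <- cad_options()
  sc1 <- fragment_to_scad(g$fragments[[2]], s, opt)
  sc2 <- fragment_to_scad(g$fragments[[2]], s, opt)
  expect_identical(sc1, sc2)
  tpl <- make_template(s)
  expect_identical(template_to_scad(tpl, opt), template_to_scad(tpl, opt))
  golden <- test_path("golden_template.scad")
  expect_identical(template_to_scad(make_template(two_golden_system()), opt),
                   paste(readLines(golden), collapse = "\n"))
})

test_that("emitted dimensions are molecule-space values times scale", {
  s <- build_ideal_peptide("GAG")
  g <- fine_fragment(s, identify_torsions(s))
  for (scale in c(1, 3.5)) {
    opt <- cad_options(scale = scale)
    for (f in g$fragments) {
      sc <- fragment_to_scad(f, s, opt)
      lines <- grep(") sphere(", strsplit(sc, "\n")[[1]], fixed = TRUE,
                    value = TRUE)
      a <- s$atoms[match(f$atom_serials, s$atoms$serial), ]
      expect_equal(length(lines), nrow(a))
      for (k in seq_along(lines)) {
        nums <- scad_numbers(lines[k])
        expect_equal(nums[1:3], c(a$x[k], a$y[k], a$z[k]) * scale,
                     tolerance = 1e-6)
        expect_equal(nums[4], a$vdw_radius[k] * opt$radius_scale * scale,
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("ports are complementary and female rims carry the tick ring", {
  s <- build_ideal_peptide("GAG")
  g <- fine_fragment(s, identify_torsions(s))
  opt <- cad_options(tick_increment_deg = 20)
  jt <- g$joints
  frag_of <- function(id) g$fragments[[match(id, vapply(g$fragments,
                                                        `[[`, "", "id"))]]
  for (k in seq_len(nrow(jt))) {
    male <- frag_of(jt$male_fragment[k])
    female <- frag_of(jt$female_fragment[k])
    msc <- strsplit(fragment_to_scad(male, s, opt), "\n")[[1]]
    fsc <- strsplit(fragment_to_scad(female, s, opt), "\n")[[1]]
    pin <- grep(sprintf("r = %.6f", opt$joint_diameter_mm / 2), msc,
                fixed = TRUE)
    hole <- grep(sprintf("r = %.6f", opt$joint_diameter_mm / 2 +
                           opt$joint_clearance_mm), fsc, fixed = TRUE)
    expect_true(length(pin) >= 1)
    expect_true(length(hole) >= 1)
    # keying polygon side count matches across the pair
    key_fn <- sprintf("$fn = %d", 3 + jt$key_index[k])
    expect_true(any(grepl(key_fn, msc, fixed = TRUE)))
    expect_true(any(grepl(key_fn, fsc, fixed = TRUE)))
  }
  # tick count = 360 / increment per female port
  f2 <- g$fragments[[2]]
  n_female <- sum(vapply(f2$ports, function(p) p$gender == "female",
                         logical(1)))
  sc <- strsplit(fragment_to_scad(f2, s, opt), "\n")[[1]]
  ticks <- grep("cube([0.600000", sc, fixed = TRUE)
  expect_equal(length(ticks), n_female * 360 / 20)
})

test_that("charge glyph population follows the rounding rule and sign", {
  opt <- cad_options(charge_unit_e = 0.1)
  atom <- data.frame(x = 0, y = 0, z = 0, vdw_radius = 1.7,
                     partial_charge = 0)
  expect_equal(nrow(embed_charge_marks(atom, opt)), 0L)
  atom$partial_charge <- -0.51
  gm <- embed_charge_marks(atom, opt)
  expect_equal(nrow(gm), 5L)
  expect_true(all(gm$sign == "-"))
  atom$partial_charge <- 0.34
  expect_equal(nrow(embed_charge_marks(atom, opt)), 3L)
  # glutamate vs lysine side-chain atoms carry opposite glyphs
  s <- build_ideal_peptide("EK")
  oe <- s$atoms[s$atoms$name == "OE1", ]
  nz <- s$atoms[s$atoms$name == "NZ", ]
  expect_equal(unique(embed_charge_marks(oe, opt)$sign), "-")
  expect_equal(unique(embed_charge_marks(nz, opt)$sign), "+")
})

test_that("template script census: one box, a sphere and sweep per atom", {
  s <- two_golden_system()
  sc <- template_to_scad(make_template(s), cad_options())
  cnt <- function(pat) length(gregexpr(pat, sc, fixed = TRUE)[[1]])
  expect_equal(cnt("cube("), 1L)
  expect_equal(cnt("sphere("), 2L)
  expect_equal(cnt("cylinder("), 2L)
})

test_that("print splitting preserves membership and rejects degenerate n", {
  s <- build_ideal_peptide("GAG")
  tpl <- make_template(s)
  segs <- split_for_print(tpl, 3, axis = "x")
  expect_length(segs, 3L)
  expect_error(split_for_print(tpl, 1), "at least 2")
  # membership of the union of slabs equals the unsplit membership
  set.seed(12)
  b <- tpl$box
  probes <- cbind(runif(500, b$xmin - 1, b$xmax + 1),
                  runif(500, b$ymin - 1, b$ymax + 1),
                  runif(500, b$zmin - 1, b$zmax + 1))
  whole <- point_in_material(tpl, probes)
  width <- (b$xmax - b$xmin) / 3
  in_slab <- function(p, k)
    p[, 1] > b$xmin + (k - 1) * width & p[, 1] <= b$xmin + k * width
  union_slabs <- (point_in_material(tpl, probes) & in_slab(probes, 1)) |
    (point_in_material(tpl, probes) & in_slab(probes, 2)) |
    (point_in_material(tpl, probes) & in_slab(probes, 3))
  expect_identical(whole, union_slabs)
})

test_that("scale preview scales linearly from the molecule-space box", {
  s <- build_ideal_peptide("GAG")
  g <- fine_fragment(s, identify_torsions(s))
  opt <- cad_options()
  rep4 <- scale_preview(g$fragments[[1]], s, c(1, 2, 3.5, 5), opt)
  expect_equal(nrow(rep4), 4L)
  expect_equal(rep4$x_mm, rep4$x_mm[1] * c(1, 2, 3.5, 5))
  a <- s$atoms[match(g$fragments[[1]]$atom_serials, s$atoms$serial), ]
  want <- diff(range(a$x)) + 2 * max(a$vdw_radius) * opt$radius_scale
  expect_equal(rep4$x_mm[1], want)
})

test_that("CAD export writes one part per fragment plus a manifest", {
  s <- build_ideal_peptide("GAG")
  g <- fine_fragment(s, identify_torsions(s))
  dir <- withr::local_tempdir()
  export_cad(g, s, dir, template = make_template(s))
  files <- list.files(dir)
  expect_true(all(sprintf("F%d.scad", seq_along(g$fragments)) %in% files))
  expect_true("template.scad" %in% files)
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  expect_equal(mf$n_fragments, length(g$fragments))
})
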