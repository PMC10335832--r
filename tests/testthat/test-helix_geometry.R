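test_that("structure reader round-trips generated helices and handles altlocs", {
  h <- generate_helix(40, chain_id = "B", first_resno = 100)
  tf <- tempfile(fileext = ".pdb")
  write_helix_pdb(h, tf)
  models <- read_structure(tf)
  expect_named(models, "B")
  expect_equal(models$B$xyz, h$xyz, tolerance = 1e-3)
  expect_equal(models$B$resno, 100:139)
  # chain and range selection
  sel <- read_structure(tf, chain = "B", range = c(110, 120))
  expect_equal(sel$B$resno, 110:120)
  expect_error(read_structure(tf, chain = "Z"), "not found")
  expect_error(read_structure(tf, range = c(100, 102)), "fewer than 4")

  # alternate locations: first kept, count unchanged
  lines <- readLines(tf)
  atom1 <- lines[1]
  altA <- sub("^(.{16}).", "\\1A", atom1)
  altB <- sub("^(.{16}).", "\\1B", atom1)
  writeLines(c(altA, altB, lines[-1]), tf)
  models2 <- read_structure(tf)
  expect_equal(length(models2$B$resno), 40)
  expect_equal(models2$B$xyz, models$B$xyz, tolerance = 1e-9)
})

test_that("local axis is straight for ideal helices and symmetric under reversal", {
  h <- generate_helix(50)
  ax <- helix_axis(h)
  d1 <- ax$directions[1, ]
  dots <- ax$directions %*% d1
  expect_true(all(abs(dots - 1) < 1e-6))       # all parallel
  expect_equal(mean(ax$twist_deg), 100, tolerance = 1e-6)
  expect_equal(mean(ax$radius), 2.3, tolerance = 1e-6)

  rev_model <- helix_model(h$resno, h$xyz[nrow(h$xyz):1, ])
  axr <- helix_axis(rev_model)
  expect_equal(axr$directions[1, ], -d1, tolerance = 1e-9)
})

test_that("imposed uniform curvature is recovered within 2%", {
  R <- 300
  h <- generate_helix(80, curvature_radius = R)
  g <- measure_geometry(h)
  curv_rad_per_A <- mean(g$curvature$curvature_deg_per_res) * pi / 180 / 1.5
  expect_equal(curv_rad_per_A, 1 / R, tolerance = 0.02)
  # curved region spans essentially the whole helix at threshold below truth
  g2 <- measure_geometry(h, curvature_threshold = 0.2)
  expect_false(is.null(g2$curved_region))
  expect_gt(diff(range(g2$curved_region)), 60)
})

test_that("geometry measures: ideal-helix closed forms and edge cases", {
  g <- measure_geometry(generate_helix(86))
  # closed form: rise component 85*1.5; chord of the residual 220 deg phase
  chord <- 2 * 2.3 * sin((85 * 100 %% 360) * pi / 180 / 2)
  expect_equal(g$end_to_end_A, sqrt((85 * 1.5)^2 + chord^2), tolerance = 1e-9)
  expect_equal(g$end_to_end_A, 127.5, tolerance = 0.1)
  expect_equal(g$n_turns, 86 * 100 / 360, tolerance = 1e-6)  # ~23.9
  expect_equal(g$axis_arc_A, 85 * 1.5, tolerance = 0.1)
  expect_true(g$axis_arc_A >= g$end_to_end_A - 0.005 * g$end_to_end_A)
  expect_null(g$curved_region)

  g4 <- measure_geometry(generate_helix(4))
  expect_equal(g4$n_turns, 4 / 3.6, tolerance = 0.02)

  # invariance under a global rigid transformation
  h <- generate_helix(40, curvature_radius = 500)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  hr <- helix_model(h$resno, h$xyz %*% R + rep(c(10, -4, 2), each = 40))
  ga <- measure_geometry(h); gb <- measure_geometry(hr)
  expect_equal(gb$end_to_end_A, ga$end_to_end_A, tolerance = 1e-9)
  expect_equal(gb$axis_arc_A, ga$axis_arc_A, tolerance = 1e-9)
  expect_equal(gb$n_turns, ga$n_turns, tolerance = 1e-9)
})

test_that("axis arc exceeds end-to-end for curved helices", {
  for (R in c(150, 300, 1000)) {
    g <- measure_geometry(generate_helix(80, curvature_radius = R))
    expect_gte(g$axis_arc_A, g$end_to_end_A - 1e-6)
  }
  # strong curvature: arc clearly exceeds the chord
  g <- measure_geometry(generate_helix(80, curvature_radius = 100))
  expect_gt(g$axis_arc_A, g$end_to_end_A * 1.02)
})

test_that("pairwise RMSD is a superposition metric", {
  h <- generate_helix(60)
  M <- pairwise_rmsd(list(a = h, b = h))
  expect_equal(M["a", "b"], 0, tolerance = 1e-12)
  expect_equal(diag(M), c(a = 0, b = 0))

  # rigid transform invariance
  th <- 0.8
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3)
  hr <- helix_model(h$resno, h$xyz %*% R + 12)
  expect_lt(pairwise_rmsd(list(h, hr))[1, 2], 1e-9)

  # symmetry and congruence
  hc <- generate_helix(60, curvature_radius = 250)
  M2 <- pairwise_rmsd(list(s = h, c = hc))
  expect_equal(M2["s", "c"], M2["c", "s"])
  expect_gt(M2["s", "c"], 0.1)

  # common-residue intersection, with a range restriction
  part <- helix_model(h$resno[10:50], h$xyz[10:50, ])
  M3 <- pairwise_rmsd(list(h, part))
  expect_lt(M3[1, 2], 1e-9)
  expect_error(pairwise_rmsd(list(h, helix_model(200:240, h$xyz[10:50, ]))),
               "common residues")
})

test_that("SVD superposition agrees with the rotation-grid oracle and bio3d", {
  h1 <- generate_helix(80)
  h2 <- generate_helix(80, curvature_radius = 300)
  own <- sahdna:::kabsch_rmsd(h1$xyz, h2$xyz)
  oracle <- rotation_grid_rmsd(h1$xyz, h2$xyz)
  expect_equal(own, oracle, tolerance = 0.05)
  expect_lte(own, oracle + 1e-6)  # SVD is the global optimum
  ref <- bio3d::rmsd(as.vector(t(h1$xyz)), as.vector(t(h2$xyz)),
                     fit = TRUE)
  expect_equal(own, ref, tolerance = 0.002)
})
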