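test_that("SASA matches the isolated-sphere closed form", {
  toy <- make_sasa_toy(matrix(c(0, 0, 0), 1), radii = 1.9)
  s <- compute_sasa(toy$model, probe_radius = 1.4, n_points = 960,
                    radii = toy$radii_set)
  expect_equal(unname(s$residue_asa), 4 * pi * 3.3^2, tolerance = 1e-6)
  expect_equal(unname(s$residue_asa), unname(toy$expected_asa),
               tolerance = 1e-6)
})

test_that("SASA matches the two-sphere spherical-cap oracle within 1%", {
  toy <- make_sasa_toy(rbind(c(0, 0, 0), c(4, 0, 0)), radii = c(1.9, 1.7))
  s <- compute_sasa(toy$model, probe_radius = 1.4, n_points = 960,
                    radii = toy$radii_set)
  expect_equal(unname(s$residue_asa), unname(toy$expected_asa),
               tolerance = 0.01)
  # engulfed sphere has zero area
  toy0 <- make_sasa_toy(rbind(c(0, 0, 0), c(0.5, 0, 0)), radii = c(3.5, 0.4))
  s0 <- compute_sasa(toy0$model, probe_radius = 1.4, n_points = 960,
                     radii = toy0$radii_set)
  expect_equal(unname(s0$residue_asa[2]), 0)
  # beyond contact distance: two isolated spheres
  toy2 <- make_sasa_toy(rbind(c(0, 0, 0), c(10, 0, 0)), radii = c(1.9, 1.7))
  s2 <- compute_sasa(toy2$model, probe_radius = 1.4, n_points = 960,
                     radii = toy2$radii_set)
  expect_equal(unname(s2$residue_asa),
               4 * pi * c(3.3, 3.1)^2, tolerance = 1e-6)
})

test_that("SASA quadrature converges and unknown elements error", {
  toy <- make_sasa_toy(rbind(c(0, 0, 0), c(4, 0, 0)), radii = c(1.9, 1.7))
  s1 <- compute_sasa(toy$model, n_points = 480, radii = toy$radii_set)
  s2 <- compute_sasa(toy$model, n_points = 960, radii = toy$radii_set)
  expect_lt(max(abs(s1$residue_asa - s2$residue_asa)), 1)
  expect_error(compute_sasa(toy$model, radii = c(H = 1.2)), "radius")
})

test_that("rASA is area over MaxASA, unclamped, and errors on unknown residues", {
  sc <- maxasa_scales()$tien_theoretical
  expect_equal(compute_rasa(sc[["ALA"]], "ALA", sc), 1.0)
  expect_equal(compute_rasa(0, "GLY", sc), 0.0)
  expect_equal(compute_rasa(50, "ARG", sc), 50 / 274)
  expect_gt(compute_rasa(300, "GLY", sc), 1)  # not clamped
  expect_error(compute_rasa(10, "XYZ", sc), "missing")
})

test_that("region assignment follows the rASA threshold rules incl. boundaries", {
  t <- region_thresholds()
  expect_equal(assign_region(0.30, 0.10, t), "core")
  expect_equal(assign_region(0.20, 0.05, t), "support")
  expect_equal(assign_region(0.40, 0.30, t), "rim_interacting")
  expect_equal(assign_region(0.40, 0.38, t), "rim_nis")
  expect_equal(assign_region(0.10, 0.10, t), "interior")
  expect_equal(assign_region(0.50, 0.50, t), "surface")
  # strict inequalities: exactly 25% on both sides of the cut falls to rim
  expect_equal(assign_region(0.25, 0.20, t), "rim_nis")
  expect_equal(assign_region(0.25, 0.10, t), "rim_interacting")
  # delta exactly at the NIS cut stays NIS; just above moves to interacting
  expect_equal(assign_region(0.60, 0.55, t), "rim_nis")
  expect_equal(assign_region(0.60, 0.55 - 1e-6, t), "rim_interacting")
  expect_error(assign_region(-0.1, 0.2, t), "non-negative")
})

test_that("region assignment is monotone in burial at fixed monomer rASA", {
  t <- region_thresholds()
  iface <- c("core", "support", "rim_interacting", "rim_nis")
  for (rm in c(0.1, 0.2, 0.26, 0.5, 0.9)) {
    deltas <- seq(0, rm, length.out = 25)
    labs <- assign_region(rep(rm, 25), rm - deltas, t)
    at_interface <- labs %in% iface
    # once at the interface, increasing burial never leaves it
    expect_true(all(diff(at_interface) >= 0))
  }
})

test_that("consensus vote takes the majority and breaks ties by burial priority", {
  expect_equal(assign_region_consensus(c("core", "core", "rim_interacting")),
               "core")
  expect_equal(assign_region_consensus("core"), "core")
  expect_equal(assign_region_consensus(c("core", "support")), "core")
  expect_equal(assign_region_consensus(c("support", "rim_nis")), "support")
  expect_equal(assign_region_consensus(c("surface", "interior")), "surface")
  expect_equal(assign_region_consensus(c("rim_interacting", "rim_nis")),
               "rim_interacting")
  expect_error(assign_region_consensus(character(0)), "no region")
  expect_error(assign_region_consensus("downtown"), "unknown region")
})

test_that("burial dimers reproduce their prescribed region labels exactly", {
  bd <- make_burial_dimer(verify = FALSE)
  sp <- split_complex(bd$model, bd$group_a, bd$group_b)
  regions <- region_assignments(sp, n_points = 480)
  got <- regions$region[match(bd$expected$key, regions$key)]
  expect_equal(got, bd$expected$label)
})

test_that("buried surface area is conserved and matches the SASA identity", {
  bd <- make_burial_dimer(labels = c("core", "rim_interacting", "surface"),
                          verify = FALSE)
  sp <- split_complex(bd$model, "A", "B")
  regions <- region_assignments(sp, n_points = 480)
  bsa <- buried_surface_area(regions)
  expect_equal(sum(bsa$by_region), bsa$total, tolerance = 1e-9)
  # independent identity: BSA = ASA_A + ASA_B - ASA_complex
  sa <- compute_sasa(sp$monomer_a, n_points = 480)
  sb <- compute_sasa(sp$monomer_b, n_points = 480)
  sc_ <- compute_sasa(sp$complex, n_points = 480)
  ident <- sum(sa$residue_asa) + sum(sb$residue_asa) - sum(sc_$residue_asa)
  expect_equal(bsa$total, ident, tolerance = 1e-6)
  # far-apart chains bury nothing
  far <- make_burial_dimer(labels = "surface", verify = FALSE)
  spf <- split_complex(far$model, "A", "B")
  rf <- region_assignments(spf, n_points = 480)
  expect_equal(buried_surface_area(rf)$total, 0, tolerance = 1e-9)
})
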