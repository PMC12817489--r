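cfg <- geometry_config()

test_that("candidate pair list matches a brute-force scan on a 50-residue toy", {
  set.seed(7)
  pos_a <- matrix(stats::runif(75, 0, 30), ncol = 3)
  pos_b <- matrix(stats::runif(75, 0, 30), ncol = 3)
  model <- toy_ca_model(pos_a, pos_b)
  for (scope in c("inter_chain", "both")) {
    got <- enumerate_candidate_pairs(model, cfg, scope)
    # brute force O(n^2) oracle
    at <- model$atoms
    keys <- ppiface:::residue_key(at$chain, at$resno, at$insert)
    oracle <- character(0)
    for (i in seq_len(nrow(at) - 1)) {
      for (j in (i + 1):nrow(at)) {
        d <- sqrt(sum((c(at$x[i], at$y[i], at$z[i]) -
                       c(at$x[j], at$y[j], at$z[j]))^2))
        if (d > 14) next
        inter <- at$chain[i] != at$chain[j]
        if (scope == "inter_chain" && !inter) next
        if (!inter && abs(at$resno[i] - at$resno[j]) < 2) next
        oracle <- c(oracle, paste(keys[i], keys[j]))
      }
    }
    expect_setequal(paste(got$key1, got$key2), oracle)
  }
})

test_that("the 14 A candidate cutoff is inclusive", {
  mk <- function(d) toy_ca_model(matrix(c(0, 0, 0), 1),
                                 matrix(c(d, 0, 0), 1))
  expect_equal(nrow(enumerate_candidate_pairs(mk(13.9), cfg)), 1)
  expect_equal(nrow(enumerate_candidate_pairs(mk(14.0), cfg)), 1)
  expect_equal(nrow(enumerate_candidate_pairs(mk(14.1), cfg)), 0)
  single <- toy_ca_model(matrix(c(0, 0, 0), 1))
  expect_equal(nrow(enumerate_candidate_pairs(single, cfg, "both")), 0)
})

test_that("every detector fires on its positive fixture and not on its negatives", {
  angle_types <- c("hbond", "h_pi", "n_pi_star", "c_bond", "chalcogen",
                   "arg_arg_stacking")
  for (ty in INTERACTION_TYPES) {
    fx <- make_interaction_geometry(ty, positive = TRUE)
    det <- detect_all(fx$model, cfg)
    expect_true(ty %in% det$records$type, label = paste("positive", ty))
    fx_n <- make_interaction_geometry(ty, positive = FALSE,
                                      violate = "distance")
    det_n <- detect_all(fx_n$model, cfg)
    expect_false(ty %in% det_n$records$type,
                 label = paste("distance-negative", ty))
    if (ty %in% angle_types) {
      fx_a <- make_interaction_geometry(ty, positive = FALSE,
                                        violate = "angle")
      det_a <- detect_all(fx_a$model, cfg)
      expect_false(ty %in% det_a$records$type,
                   label = paste("angle-negative", ty))
    }
  }
})

test_that("detectors are sharp at the cutoff (margin zero fires, epsilon out does not)", {
  for (ty in c("hbond", "salt_bridge", "hydrophobic", "aromatic_aromatic")) {
    fx0 <- make_interaction_geometry(ty, positive = TRUE, margin = 1e-6)
    expect_true(ty %in% detect_all(fx0$model, cfg)$records$type,
                label = paste("at-cutoff", ty))
    fx1 <- make_interaction_geometry(ty, positive = FALSE,
                                     violate = "distance", margin = 0.01)
    expect_false(ty %in% detect_all(fx1$model, cfg)$records$type,
                 label = paste("just-beyond", ty))
  }
})

test_that("stacked arginine pairs are excluded from charge clash", {
  fx <- make_interaction_geometry("arg_arg_stacking", positive = TRUE)
  det <- detect_all(fx$model, cfg)
  expect_true("arg_arg_stacking" %in% det$records$type)
  expect_false("charge_clash" %in% det$records$type)
  expect_false("charge_repulsion" %in% det$records$type)
  # without stacking, the same two arginines do clash
  fx_n <- make_interaction_geometry("arg_arg_stacking", positive = FALSE,
                                    violate = "angle", margin = 30)
  det_n <- detect_all(fx_n$model, cfg)
  expect_false("arg_arg_stacking" %in% det_n$records$type)
  expect_true(any(c("charge_clash", "charge_repulsion") %in%
                    det_n$records$type))
})

test_that("detection is invariant under rigid motions", {
  set.seed(42)
  for (ty in c("hbond", "salt_bridge", "aromatic_aromatic", "chalcogen",
               "arg_arg_stacking")) {
    fx <- make_interaction_geometry(ty, positive = TRUE, margin = 0.6)
    base <- sort(detect_all(fx$model, cfg)$records$type)
    for (rep in 1:3) {
      R <- ppiface:::rot_z(stats::runif(1, 0, 360)) %*%
        ppiface:::rot_x(stats::runif(1, 0, 360)) %*%
        ppiface:::rot_y(stats::runif(1, 0, 360))
      t <- stats::runif(3, -50, 50)
      moved <- transform_model(fx$model, R, t)
      expect_equal(sort(detect_all(moved, cfg)$records$type), base,
                   label = paste("rigid motion", ty, rep))
    }
  }
})

test_that("detectors are symmetric in the order of the two residues", {
  for (ty in c("hbond", "salt_bridge", "chalcogen", "aromatic_cation")) {
    fx <- make_interaction_geometry(ty, positive = TRUE)
    geo <- ppiface:::residue_geometry(fx$model)
    fwd <- ppiface:::detect_pair(geo[[1]], geo[[2]], cfg)
    rev <- ppiface:::detect_pair(geo[[2]], geo[[1]], cfg)
    expect_setequal(
      paste(fwd$type, pmin(fwd$key1, fwd$key2), pmax(fwd$key1, fwd$key2)),
      paste(rev$type, pmin(rev$key1, rev$key2), pmax(rev$key1, rev$key2)))
  }
})

test_that("type routing: sulfur acceptors give S/Se bonds, not regular H-bonds", {
  fx <- make_interaction_geometry("sse_hbond", positive = TRUE)
  det <- detect_all(fx$model, cfg)
  expect_true("sse_hbond" %in% det$records$type)
  expect_false("hbond" %in% det$records$type)
})

test_that("capability gating: a LEU/SER contact is vdw but not hydrophobic", {
  # LEU against SER at van der Waals range
  a <- ppiface:::placed_residue("LEU", "A", 1)
  tpl <- ppiface:::residue_template("SER")
  coords <- ppiface:::transform_coords(tpl, ppiface:::rot_z(180),
                                       c(0, -8.6, 0))
  b <- ppiface:::fixture_atoms("B", 1, "SER", coords)
  model <- ppiface:::fixture_model("leu_ser", list(a, b))
  det <- detect_all(model, cfg)
  expect_true("vdw" %in% det$records$type)
  expect_false("hydrophobic" %in% det$records$type)
})

test_that("no interaction record exists beyond the candidate cutoff", {
  fx <- make_interaction_geometry("hbond", positive = TRUE)
  m <- fx$model
  # push chain B far away
  sel <- m$atoms$chain == "B"
  m$atoms$x[sel] <- m$atoms$x[sel] + 50
  det <- detect_all(m, cfg)
  expect_equal(nrow(det$records), 0)
  expect_equal(nrow(det$pairs), 0)
})

test_that("composed fixture yields the expected interacting pairs and records", {
  sb <- make_interaction_geometry("salt_bridge", positive = TRUE)
  hb <- make_interaction_geometry("hbond", positive = TRUE)
  # shift the H-bond pair away so the two pairs are independent
  hb_m <- transform_model(hb$model, diag(3), c(40, 0, 0))
  hb_at <- hb_m$atoms
  hb_at$resno <- hb_at$resno + 10L
  atoms <- rbind(sb$model$atoms, hb_at)
  model <- ppiface:::new_structure_model("composed", atoms,
                                         sb$model$provenance)
  det <- detect_all(model, cfg)
  expect_equal(nrow(det$pairs), 2)
  expect_true(any(grepl("salt_bridge", det$pairs$types)))
  expect_true(any(grepl("hbond", det$pairs$types)))
  # pairs materialize only with at least one record
  expect_true(all(det$pairs$n_interactions >= 1))
})
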