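# ---------------------------------------------------------------------------
# Synthetic fixtures: analytic SASA toys, burial-controlled dimers with
# known region labels, ideal/perturbed interaction geometries, and random
# pair-frequency tables with known entropy/PMI. Everything is generated in
# code from idealized residue templates (standard bond lengths and angles),
# so the package builds and tests without downloading a single structure.
# ---------------------------------------------------------------------------

# build an atoms data.frame from a named list of coordinates
fixture_atoms <- function(chain, resno, resname, coords) {
  nm <- names(coords)
  xyz <- do.call(rbind, coords)
  data.frame(
    chain = chain, resno = as.integer(resno), insert = "", resid = resname,
    elety = nm, element = substr(nm, 1, 1),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, alt = "", backbone = nm %in% BACKBONE_ATOMS,
    stringsAsFactors = FALSE
  )
}

fixture_model <- function(structure_id, residue_list) {
  atoms <- do.call(rbind, residue_list)
  new_structure_model(structure_id, atoms,
                      provenance = list(format = "synthetic", model_index = 1L,
                                        n_models = 1L, n_hetero_excluded = 0L))
}

# rotation matrices (degrees)
rot_z <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
rot_x <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}
rot_y <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

# apply R then translate t to a named coordinate list
transform_coords <- function(coords, R = diag(3), t = c(0, 0, 0)) {
  lapply(coords, function(p) as.numeric(R %*% p + t))
}

#' Rigidly transform a structure model
#'
#' @param model a `structure_model`.
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation.
#' @return transformed model.
#' @export
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  xyz <- t(R %*% t(as.matrix(model$atoms[, c("x", "y", "z")])) + t)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# Idealized residue templates in a local frame: CA at the origin, backbone
# along +x, side chain extending toward -y. Bond lengths are standard; ring
# geometries are regular polygons. These are scaffolds for geometry
# fixtures, not energy-minimized conformers.
residue_template <- function(resname) {
  bb <- list(N = c(-1.45, 0, 0), CA = c(0, 0, 0), C = c(1.52, 0, 0),
             O = c(2.05, 1.11, 0))
  sc <- switch(resname,
    GLY = list(),
    ALA = list(CB = c(0, -1.53, 0)),
    SER = list(CB = c(0, -1.53, 0), OG = c(0, -2.96, 0)),
    CYS = list(CB = c(0, -1.53, 0), SG = c(0, -3.33, 0)),
    THR = list(CB = c(0, -1.53, 0), OG1 = c(0.7, -2.7, 0),
               CG2 = c(-1.2, -2.5, 0)),
    VAL = list(CB = c(0, -1.53, 0), CG1 = c(1.25, -2.43, 0),
               CG2 = c(-1.25, -2.43, 0)),
    LEU = list(CB = c(0, -1.53, 0), CG = c(0, -3.05, 0),
               CD1 = c(1.25, -3.95, 0), CD2 = c(-1.25, -3.95, 0)),
    ILE = list(CB = c(0, -1.53, 0), CG1 = c(0.77, -2.98, 0),
               CG2 = c(-1.40, -2.30, 0), CD1 = c(0.77, -4.52, 0)),
    MET = list(CB = c(0, -1.53, 0), CG = c(0, -3.05, 0),
               SD = c(0, -4.85, 0), CE = c(1.45, -5.75, 0)),
    ASP = list(CB = c(0, -1.53, 0), CG = c(0, -3.05, 0),
               OD1 = c(-1.09, -3.68, 0), OD2 = c(1.09, -3.68, 0)),
    ASN = list(CB = c(0, -1.53, 0), CG = c(0, -3.05, 0),
               OD1 = c(-1.09, -3.68, 0), ND2 = c(1.09, -3.68, 0)),
    GLU = list(CB = c(0, -1.53, 0), CG = c(0, -3.05, 0),
               CD = c(0, -4.57, 0), OE1 = c(-1.09, -5.20, 0),
               OE2 = c(1.09, -5.20, 0)),
    GLN = list(CB = c(0, -1.53, 0), CG = c(0, -3.05, 0),
               CD = c(0, -4.57, 0), OE1 = c(-1.09, -5.20, 0),
               NE2 = c(1.09, -5.20, 0)),
    LYS = list(CB = c(0, -1.53, 0), CG = c(0, -3.05, 0),
               CD = c(0, -4.57, 0), CE = c(0, -6.09, 0),
               NZ = c(0, -7.49, 0)),
    ARG = list(CB = c(0, -1.53, 0), CG = c(0, -3.05, 0),
               CD = c(0, -4.57, 0), NE = c(0, -5.95, 0),
               CZ = c(0, -7.28, 0), NH1 = c(-1.15, -7.94, 0),
               NH2 = c(1.15, -7.94, 0)),
    PHE = list(CB = c(0, -1.53, 0), CG = c(0, -3.05, 0),
               CD1 = c(1.20, -3.745, 0), CD2 = c(-1.20, -3.745, 0),
               CE1 = c(1.20, -5.135, 0), CE2 = c(-1.20, -5.135, 0),
               CZ = c(0, -5.83, 0)),
    TYR = list(CB = c(0, -1.53, 0), CG = c(0, -3.05, 0),
               CD1 = c(1.20, -3.745, 0), CD2 = c(-1.20, -3.745, 0),
               CE1 = c(1.20, -5.135, 0), CE2 = c(-1.20, -5.135, 0),
               CZ = c(0, -5.83, 0), OH = c(0, -7.21, 0)),
    HIS = list(CB = c(0, -1.53, 0), CG = c(0, -3.05, 0),
               ND1 = c(1.13, -3.87, 0), CD2 = c(-1.13, -3.87, 0),
               CE1 = c(0.70, -5.20, 0), NE2 = c(-0.70, -5.20, 0)),
    TRP = list(CB = c(0, -1.53, 0), CG = c(0, -3.05, 0),
               CD1 = c(1.09, -3.90, 0), NE1 = c(0.71, -5.18, 0),
               CE2 = c(-0.68, -5.21, 0), CD2 = c(-1.15, -3.92, 0),
               CE3 = c(-2.50, -3.48, 0), CZ3 = c(-3.45, -4.45, 0),
               CH2 = c(-3.06, -5.79, 0), CZ2 = c(-1.70, -6.19, 0)),
    PRO = list(CB = c(0, -1.53, 0), CG = c(-0.8, -2.6, 0.5),
               CD = c(-1.9, -1.7, 0.3)),
    stop("no template for residue ", resname)
  )
  c(bb, sc)
}

placed_residue <- function(resname, chain, resno, R = diag(3),
                           t = c(0, 0, 0)) {
  fixture_atoms(chain, resno, resname,
                transform_coords(residue_template(resname), R, t))
}

# ---------------------------------------------------------------------------
# SASA toys with analytic expected values
# ---------------------------------------------------------------------------

#' Multi-sphere SASA toy with analytic expected areas
#'
#' Builds a toy "structure" of up to three single-atom residues (spheres)
#' whose solvent-accessible areas have closed forms: the isolated-sphere
#' area and the two-sphere spherical-cap overlap. Placements must avoid
#' triple overlaps (pairwise caps only), which is the regime where the
#' closed forms hold.
#'
#' @param centers numeric matrix (n x 3), n <= 3, sphere centers.
#' @param radii length-n vdW radii, Angstrom.
#' @param probe_radius probe radius used for the expected values (1.4).
#' @return list: `model` (single-atom residues on chain A), `radii_set`
#'   (named per-element radius vector to pass to [compute_sasa()]),
#'   `expected_asa` (named by residue key, Angstrom^2).
#' @export
make_sasa_toy <- function(centers, radii, probe_radius = 1.4) {
  centers <- rbind(centers)
  n <- nrow(centers)
  if (n > 3) stop("closed forms support at most 3 spheres")
  stopifnot(length(radii) == n)
  elements <- c("C", "N", "O")[seq_len(n)]
  names_ <- c("C", "N", "O")
  res <- lapply(seq_len(n), function(i) {
    fixture_atoms("A", i, "GLY",
                  stats::setNames(list(centers[i, ]), names_[i]))
  })
  model <- fixture_model("sasa_toy", res)
  radii_set <- stats::setNames(radii, elements)
  R <- radii + probe_radius
  expected <- numeric(n)
  for (i in seq_len(n)) {
    area <- 4 * pi * R[i]^2
    for (j in seq_len(n)) {
      if (j == i) next
      d <- vnorm(centers[i, ] - centers[j, ])
      if (d >= R[i] + R[j]) next
      if (d + R[i] <= R[j]) { area <- 0; break }  # engulfed
      if (d + R[j] <= R[i]) next                   # j inside i, no cap
      h <- R[i] - (d^2 + R[i]^2 - R[j]^2) / (2 * d)
      area <- area - 2 * pi * R[i] * h
    }
    expected[i] <- max(0, area)
  }
  keys <- residue_key(rep("A", n), seq_len(n), rep("", n))
  list(model = model, radii_set = radii_set,
       expected_asa = stats::setNames(expected, keys))
}

# ---------------------------------------------------------------------------
# Burial dimers with prescribed region labels
# ---------------------------------------------------------------------------

# single-atom glycine used as probe or blocker
point_residue <- function(chain, resno, pos) {
  fixture_atoms(chain, resno, "GLY", list(CA = pos))
}

octahedral_dirs <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
        c(0, 0, 1), c(0, 0, -1))
}

ring_dirs <- function(k = 8) {
  a <- 2 * pi * (seq_len(k) - 1) / k
  cbind(cos(a), sin(a), 0)
}

#' Burial-controlled dimer with known region labels
#'
#' Builds a two-chain toy structure in which each probe residue's solvent
#' accessibility before and after "binding" is controlled by shells of
#' blocker residues placed on chain A (intramolecular burial) or chain B
#' (burial upon complex formation), so the expected region label of every
#' probe is known by construction:
#' \describe{
#'   \item{surface}{probe fully exposed, no chain-B contact.}
#'   \item{interior}{probe enclosed by chain-A blockers, no chain-B contact.}
#'   \item{core}{probe exposed in the monomer, enclosed by chain-B blockers.}
#'   \item{support}{probe mostly enclosed by chain A with a polar opening
#'     capped by a chain-B blocker.}
#'   \item{rim_interacting}{one close chain-B blocker shaving more than 5%
#'     of relative accessibility.}
#'   \item{rim_nis}{one grazing chain-B blocker shaving under 5%.}
#' }
#' When `verify` is TRUE the construction is checked by running the full
#' SASA/region pipeline and an error is raised if any achieved label
#' deviates from its prescription.
#'
#' @param labels character vector of requested labels (any combination of
#'   the six regions).
#' @param verify check the construction with [region_assignments()] (TRUE).
#' @param n_points SASA quadrature used for verification.
#' @return list: `model`, `group_a`, `group_b`, `expected` (data.frame key,
#'   label for the probe residues).
#' @export
make_burial_dimer <- function(labels = c("core", "support",
                                         "rim_interacting", "rim_nis",
                                         "surface", "interior"),
                              verify = TRUE, n_points = 960) {
  bad <- setdiff(labels, REGION_LABELS)
  if (length(bad) > 0) stop("unachievable label(s): ",
                            paste(bad, collapse = ", "))
  residues <- list()
  resno_a <- 0L
  resno_b <- 0L
  expected <- data.frame(key = character(0), label = character(0))
  add_a <- function(pos) {
    resno_a <<- resno_a + 1L
    residues[[length(residues) + 1]] <<- point_residue("A", resno_a, pos)
    resno_a
  }
  add_b <- function(pos) {
    resno_b <<- resno_b + 1L
    residues[[length(residues) + 1]] <<- point_residue("B", resno_b, pos)
  }
  shell_ring <- ring_dirs(8) * 3.3
  poles <- rbind(c(0, 0, 3.3), c(0, 0, -3.3))
  for (i in seq_along(labels)) {
    p <- c(25 * (i - 1), 0, 0)
    lab <- labels[i]
    probe_no <- add_a(p)
    if (lab == "interior") {
      for (k in seq_len(8)) add_a(p + shell_ring[k, ])
      add_a(p + poles[1, ])
      add_a(p + poles[2, ])
    } else if (lab == "core") {
      for (k in seq_len(8)) add_b(p + shell_ring[k, ])
      add_b(p + poles[1, ])
      add_b(p + poles[2, ])
    } else if (lab == "support") {
      for (k in seq_len(8)) add_a(p + shell_ring[k, ])
      add_a(p + poles[2, ])       # open top pole in the monomer
      add_b(p + poles[1, ])       # capped by the partner chain
    } else if (lab == "rim_interacting") {
      add_b(p + c(0, 0, 3.2))
    } else if (lab == "rim_nis") {
      add_b(p + c(0, 0, 6.0))
    }                              # surface: nothing
    expected <- rbind(expected,
                      data.frame(key = residue_key("A", probe_no, ""),
                                 label = lab))
  }
  # chain B must exist: distant anchor far from everything
  add_b(c(-40, 0, 0))
  model <- fixture_model("burial_dimer", residues)
  out <- list(model = model, group_a = "A", group_b = "B",
              expected = expected)
  if (verify) {
    split <- split_complex(model, "A", "B")
    regions <- region_assignments(split, n_points = n_points)
    got <- regions$region[match(expected$key, regions$key)]
    if (any(got != expected$label))
      stop("burial band not achieved for label(s): ",
           paste(unique(expected$label[got != expected$label]),
                 collapse = ", "))
    out$regions <- regions
  }
  out
}

# ---------------------------------------------------------------------------
# Interaction geometry fixtures
# ---------------------------------------------------------------------------

#' Ideal or deliberately violating interaction geometry
#'
#' Builds a two-residue, two-chain model whose geometry either satisfies a
#' detector's documented criteria (positive) or violates exactly one
#' criterion (negative) by the given margin. Distances sit `margin`
#' Angstrom inside (positive) or outside (negative) the relevant cutoff;
#' angle violations sit `margin` degrees outside the angular window.
#'
#' @param type one of [INTERACTION_TYPES].
#' @param positive logical.
#' @param violate for negatives: "distance" or "angle" (angle only where
#'   the detector has an angular criterion).
#' @param margin Angstrom (distance) or degrees (angle), default 0.5.
#' @param cfg the [geometry_config()] whose thresholds the fixture targets.
#' @return list: `model` (chains A and B, one residue each unless noted),
#'   `type`, `positive`.
#' @export
make_interaction_geometry <- function(type, positive = TRUE,
                                      violate = c("distance", "angle"),
                                      margin = 0.5,
                                      cfg = geometry_config()) {
  violate <- match.arg(violate)
  if (!type %in% INTERACTION_TYPES) stop("unknown type: ", type)
  m <- margin
  res <- switch(type,
    hbond = fx_hbond(positive, violate, m, cfg),
    sse_hbond = fx_sse_hbond(positive, violate, m, cfg),
    h_pi = fx_h_pi(positive, violate, m, cfg),
    n_pi_star = fx_n_pi_star(positive, violate, m, cfg),
    c_bond = fx_c_bond(positive, violate, m, cfg),
    chalcogen = fx_chalcogen(positive, violate, m, cfg),
    aromatic_sse = fx_aromatic_sse(positive, violate, m, cfg),
    aromatic_aromatic = fx_aromatic_aromatic(positive, violate, m, cfg),
    amino_pi = fx_amino_pi(positive, violate, m, cfg),
    aromatic_cation = fx_aromatic_charge(positive, violate, m, cfg, "cation"),
    aromatic_anion = fx_aromatic_charge(positive, violate, m, cfg, "anion"),
    salt_bridge = fx_salt_bridge(positive, violate, m, cfg),
    vdw = fx_packing(positive, violate, m, cfg, "vdw"),
    hydrophobic = fx_packing(positive, violate, m, cfg, "hydrophobic"),
    arg_arg_stacking = fx_arg_arg(positive, violate, m, cfg),
    charge_clash = fx_clash_repulsion(positive, violate, m, cfg,
                                      "charge", "clash"),
    charge_repulsion = fx_clash_repulsion(positive, violate, m, cfg,
                                          "charge", "repulsion"),
    hydrophobic_hydrophilic_clash =
      fx_clash_repulsion(positive, violate, m, cfg, "hh", "clash"),
    hydrophobic_hydrophilic_repulsion =
      fx_clash_repulsion(positive, violate, m, cfg, "hh", "repulsion")
  )
  model <- fixture_model(paste0("fx_", type), res)
  list(model = model, type = type, positive = positive)
}

# direction at `deg` degrees from -y within the xy-plane
dir_from_minus_y <- function(deg) {
  a <- deg * pi / 180
  c(sin(a), -cos(a), 0)
}

fx_hbond <- function(positive, violate, m, cfg) {
  a <- placed_residue("SER", "A", 1)
  og <- c(0, -2.96, 0)
  d <- if (positive) cfg$d_hbond - m else
    if (violate == "distance") cfg$d_hbond + m else 2.8
  ang <- if (!positive && violate == "angle") cfg$a_hbond - m else 165
  # acceptor along a direction making `ang` with the OG->CB bond
  v <- dir_from_minus_y(180 - ang)
  p_acc <- og + d * v
  b <- place_by_atom("ASP", "B", 1, "OD1", p_acc, rot_z(180))
  list(a, b)
}

# place a residue template (optionally rotated) so that `atom` lands at `p`
place_by_atom <- function(resname, chain, resno, atom, p, R = diag(3)) {
  tpl <- transform_coords(residue_template(resname), R, c(0, 0, 0))
  t <- p - tpl[[atom]]
  fixture_atoms(chain, resno, resname, lapply(tpl, function(q) q + t))
}

fx_sse_hbond <- function(positive, violate, m, cfg) {
  a <- placed_residue("MET", "A", 1)
  sd <- c(0, -4.85, 0)
  d <- if (positive) cfg$d_sse_hbond - m else cfg$d_sse_hbond + m
  n_pos <- sd + c(0, -d, 0)
  # donor backbone N of chain B with its CA 165 degrees off the N...SD line
  w <- dir_from_minus_y(15)
  ca <- n_pos + 1.45 * w
  b <- fixture_atoms("B", 1, "GLY",
                     list(N = n_pos, CA = ca, C = ca + c(1.52, 0, 0),
                          O = ca + c(2.05, -1.11, 0)))
  list(a, b)
}

fx_h_pi <- function(positive, violate, m, cfg) {
  a <- placed_residue("PHE", "A", 1)
  centroid <- c(0, -4.44, 0)
  d <- if (positive) cfg$d_h_pi - m else
    if (violate == "distance") cfg$d_h_pi + m else 3.5
  cone <- if (!positive && violate == "angle") cfg$a_h_pi + m else 0
  dir <- as.numeric(rot_y(cone) %*% c(0, 0, 1))
  og <- centroid + d * dir
  cb <- og + c(0, 0, 1.43)
  ca <- cb + c(0, 1.1, 1.06)
  b <- fixture_atoms("B", 1, "SER",
                     list(N = ca + c(-1.45, 0, 0), CA = ca,
                          C = ca + c(1.52, 0, 0), O = ca + c(2.05, 1.11, 0),
                          CB = cb, OG = og))
  list(a, b)
}

fx_n_pi_star <- function(positive, violate, m, cfg) {
  a <- placed_residue("GLY", "A", 1)
  o_a <- c(2.05, 1.11, 0)
  d <- if (positive) cfg$d_n_pi_star - m else cfg$d_n_pi_star + m
  ang <- if (!positive && violate == "angle") 60 else 105
  c_b <- o_a + c(0, d, 0)
  w <- c(sin(ang * pi / 180), -cos(ang * pi / 180), 0)
  o_b <- c_b + 1.23 * w
  ca_b <- c_b + c(-1.47, 0.4, 0)
  b <- fixture_atoms("B", 1, "GLY",
                     list(N = ca_b + c(-1.0, 1.05, 0), CA = ca_b, C = c_b,
                          O = o_b))
  list(a, b)
}

fx_c_bond <- function(positive, violate, m, cfg) {
  a <- placed_residue("GLY", "A", 1)
  o_a <- c(2.05, 1.11, 0)
  d <- if (positive) cfg$d_c_bond - m else cfg$d_c_bond + m
  ang <- if (!positive && violate == "angle") cfg$a_c_bond - m else 180
  cb_b <- o_a + c(0, d, 0)
  w <- dir_from_minus_y(180 - ang)   # CA placed so angle(CA,CB,O) = ang
  ca_b <- cb_b - 1.53 * w
  c_b <- ca_b + c(1.52, 0.5, 0)
  b <- fixture_atoms("B", 1, "ALA",
                     list(N = ca_b + c(-1.45, 0.3, 0), CA = ca_b, C = c_b,
                          O = c_b + c(0.53, 1.11, 0), CB = cb_b))
  list(a, b)
}

fx_chalcogen <- function(positive, violate, m, cfg) {
  a <- placed_residue("MET", "A", 1)
  sd <- c(0, -4.85, 0)
  d <- if (positive) cfg$d_chalcogen - m else
    if (violate == "distance") cfg$d_chalcogen + m else 3.3
  ang <- if (!positive && violate == "angle") cfg$a_chalcogen - m else 180
  # target O along a direction `ang` degrees from the CG->SD bond extension
  v <- dir_from_minus_y(180 - ang)
  o_b <- sd + d * v
  c_b <- o_b + c(0, -1.23, 0)
  ca_b <- c_b + c(1.4, -0.6, 0)
  b <- fixture_atoms("B", 1, "GLY",
                     list(N = ca_b + c(0.1, -1.42, 0), CA = ca_b, C = c_b,
                          O = o_b))
  list(a, b)
}

fx_aromatic_sse <- function(positive, violate, m, cfg) {
  a <- placed_residue("PHE", "A", 1)
  centroid <- c(0, -4.44, 0)
  d <- if (positive) cfg$d_aromatic_sse - m else cfg$d_aromatic_sse + m
  dir <- as.numeric(rot_y(15) %*% c(0, 0, 1))  # 15 deg off normal: pi face
  sg <- centroid + d * dir
  cb <- sg + c(0, 0.4, 1.75)
  ca <- cb + c(0, 1.1, 1.06)
  b <- fixture_atoms("B", 1, "CYS",
                     list(N = ca + c(-1.45, 0, 0), CA = ca,
                          C = ca + c(1.52, 0, 0), O = ca + c(2.05, 1.11, 0),
                          CB = cb, SG = sg))
  list(a, b)
}

fx_aromatic_aromatic <- function(positive, violate, m, cfg) {
  a <- placed_residue("PHE", "A", 1)
  centroid <- c(0, -4.44, 0)
  d <- if (positive) cfg$d_aromatic - m else cfg$d_aromatic + m
  tilt <- 5
  tpl <- residue_template("PHE")
  ring_center_local <- Reduce(`+`, tpl[c("CG", "CD1", "CD2", "CE1", "CE2",
                                         "CZ")]) / 6
  R <- rot_x(tilt)
  target <- centroid + c(0, 0, d)
  coords <- lapply(tpl, function(p)
    as.numeric(R %*% (p - ring_center_local)) + target)
  b <- fixture_atoms("B", 1, "PHE", coords)
  list(a, b)
}

fx_amino_pi <- function(positive, violate, m, cfg) {
  a <- placed_residue("PHE", "A", 1)
  centroid <- c(0, -4.44, 0)
  d <- if (positive) cfg$d_amino_pi - m else cfg$d_amino_pi + m
  nd2 <- centroid + c(0, 0, d)
  cg <- nd2 + c(0, 0.8, 1.0)
  od1 <- cg + c(0, -0.6, 1.1)
  cb <- cg + c(0, 1.3, 0.8)
  ca <- cb + c(0, 1.1, 1.06)
  b <- fixture_atoms("B", 1, "ASN",
                     list(N = ca + c(-1.45, 0, 0), CA = ca,
                          C = ca + c(1.52, 0, 0), O = ca + c(2.05, 1.11, 0),
                          CB = cb, CG = cg, OD1 = od1, ND2 = nd2))
  list(a, b)
}

fx_aromatic_charge <- function(positive, violate, m, cfg, kind) {
  a <- placed_residue("TRP", "A", 1)
  centroid <- c(-2.09, -4.84, 0)  # six-ring centroid of the TRP template
  d <- if (positive) cfg$d_aromatic_charge - m else
    cfg$d_aromatic_charge + m
  target <- centroid + c(0, 0, d)
  if (kind == "cation") {
    nz <- target
    ce <- nz + c(0, 0.4, 1.35)
    cd <- ce + c(0, 1.0, 1.1)
    cg <- cd + c(0, 1.0, 1.1)
    cb <- cg + c(0, 1.0, 1.1)
    ca <- cb + c(0, 1.0, 1.1)
    b <- fixture_atoms("B", 1, "LYS",
                       list(N = ca + c(-1.45, 0, 0), CA = ca,
                            C = ca + c(1.52, 0, 0),
                            O = ca + c(2.05, 1.11, 0),
                            CB = cb, CG = cg, CD = cd, CE = ce, NZ = nz))
  } else {
    oe1 <- target + c(-1.09, 0, 0)
    oe2 <- target + c(1.09, 0, 0)
    cd <- target + c(0, 0.3, 0.6)
    cg <- cd + c(0, 1.0, 1.1)
    cb <- cg + c(0, 1.0, 1.1)
    ca <- cb + c(0, 1.0, 1.1)
    b <- fixture_atoms("B", 1, "GLU",
                       list(N = ca + c(-1.45, 0, 0), CA = ca,
                            C = ca + c(1.52, 0, 0),
                            O = ca + c(2.05, 1.11, 0),
                            CB = cb, CG = cg, CD = cd, OE1 = oe1, OE2 = oe2))
  }
  list(a, b)
}

fx_salt_bridge <- function(positive, violate, m, cfg) {
  a <- placed_residue("ARG", "A", 1)
  nh1 <- c(-1.15, -7.94, 0)
  cz <- c(0, -7.28, 0)
  d <- if (positive) cfg$d_salt_bridge - m else cfg$d_salt_bridge + m
  u <- unit(nh1 - cz)
  od1 <- nh1 + d * u
  cg <- od1 + 1.26 * u
  od2 <- cg + c(-0.24, 1.23, 0)
  cb <- cg + c(0.2, -1.5, 0)
  ca <- cb + c(1.2, -0.95, 0)
  b <- fixture_atoms("B", 1, "ASP",
                     list(N = ca + c(-1.0, -1.05, 0), CA = ca,
                          C = ca + c(1.5, 0.3, 0),
                          O = ca + c(2.0, -0.8, 0),
                          CB = cb, CG = cg, OD1 = od1, OD2 = od2))
  list(a, b)
}

fx_packing <- function(positive, violate, m, cfg, which) {
  a <- placed_residue("LEU", "A", 1)
  cd1 <- c(1.25, -3.95, 0)
  cutoff <- if (which == "vdw") 2 * vdw_radii()["C"] + cfg$vdw_slack
            else cfg$d_hydrophobic
  gap <- if (positive) cutoff - m else cutoff + m
  # ILE below, its CD1 approaching LEU's CD1 head-on along -y
  cd1_b <- cd1 + c(0, -gap, 0)
  cg1_b <- cd1_b + c(0, -1.54, 0)
  cb_b <- cg1_b + c(-0.77, -1.33, 0)
  cg2_b <- cb_b + c(-1.4, 0.1, 0.3)
  ca_b <- cb_b + c(0.5, -1.45, 0)
  b <- fixture_atoms("B", 1, "ILE",
                     list(N = ca_b + c(-1.45, 0, 0), CA = ca_b,
                          C = ca_b + c(1.52, 0, 0),
                          O = ca_b + c(2.05, 1.11, 0),
                          CB = cb_b, CG1 = cg1_b, CG2 = cg2_b, CD1 = cd1_b))
  list(a, b)
}

fx_arg_arg <- function(positive, violate, m, cfg) {
  a <- placed_residue("ARG", "A", 1)
  d <- if (positive) cfg$d_arg_arg - m else
    if (violate == "distance") cfg$d_arg_arg + m else 3.5
  tilt <- if (!positive && violate == "angle") cfg$a_arg_arg + m else 0
  # stack the second ARG directly above: flip z and x so the chain runs
  # parallel, guanidinium planes parallel at separation d
  R <- rot_x(tilt) %*% diag(c(-1, 1, -1))
  coords <- transform_coords(residue_template("ARG"), R, c(0, 0, d))
  b <- fixture_atoms("B", 1, "ARG", coords)
  list(a, b)
}

fx_clash_repulsion <- function(positive, violate, m, cfg, family, kind) {
  if (family == "charge") {
    res_a <- "GLU"
    res_b <- "ASP"
  } else {
    res_a <- "LEU"
    res_b <- "ASN"
  }
  a <- placed_residue(res_a, "A", 1)
  # slide B along +x until the realized minimum backbone-backbone distance
  # hits the target (solved numerically; the closest atom pair depends on
  # the side-chain orientation)
  bb_target <- if (positive) cfg$d_backbone - 1.5 else cfg$d_backbone + m
  toward <- kind == "clash"
  R <- if (toward) rot_z(-90) else rot_z(90)
  build <- function(tx) placed_residue(res_b, "B", 1, R, c(tx, -3, 0))
  bb_min <- function(tx) {
    b <- build(tx)
    a_bb <- as.matrix(a[a$backbone, c("x", "y", "z")])
    b_bb <- as.matrix(b[b$backbone, c("x", "y", "z")])
    min_cross_dist(a_bb, b_bb)
  }
  tx <- stats::uniroot(function(x) bb_min(x) - bb_target, c(3, 30),
                       tol = 1e-6)$root
  list(a, build(tx))
}

# ---------------------------------------------------------------------------
# Pair-frequency fixtures with known entropy / PMI
# ---------------------------------------------------------------------------

# representative residue per simplified class, so drawn class pairs can be
# fed through the same machinery as real pair records
CLASS_REPRESENTATIVE <- c(positive = "ARG", negative = "ASP",
                          polar = "SER", apolar = "LEU")

#' Random pair draws with a known PMI target
#'
#' Draws `n_draws` interacting pair classes from a mixture: with
#' probability 1 - beta the two classes are sampled independently from
#' `class_freqs`, and with probability beta the coupled pair is emitted.
#' The mixture weight beta is solved (numerically) so that the coupled
#' pair's frequency equals `coupling` times its independence baseline under
#' the post-mixture marginals — hence its asymptotic PMI is exactly
#' log2(coupling), for both the homogeneous and heterogeneous branch.
#'
#' @param class_freqs named probability vector over the four classes.
#' @param coupled_pair length-2 character vector of class names (NULL for
#'   no coupling).
#' @param coupling coupling factor c >= 1; the expected PMI of the coupled
#'   pair is log2(c).
#' @param n_draws number of pairs to draw.
#' @param seed integer seed.
#' @return list: `pairs` (data.frame res1/res2 using class-representative
#'   residues, plus region columns set to "core" so the frame is a valid
#'   pair-record input), `expected_pmi`, `beta`, `coupled_class`.
#' @export
make_frequency_fixture <- function(class_freqs = c(positive = 0.2,
                                                   negative = 0.2,
                                                   polar = 0.3,
                                                   apolar = 0.3),
                                   coupled_pair = NULL, coupling = 1,
                                   n_draws = 1000, seed = 1) {
  if (coupling <= 0) stop("coupling factor must be positive")
  if (coupling < 1) stop("only coupling factors >= 1 are supported")
  stopifnot(abs(sum(class_freqs) - 1) < 1e-9,
            setequal(names(class_freqs), PAIR_CLASSES))
  beta <- 0
  if (!is.null(coupled_pair) && coupling > 1) {
    a <- coupled_pair[1]
    b <- coupled_pair[2]
    fa <- class_freqs[a]
    fb <- class_freqs[b]
    homog <- a == b
    fn <- function(beta) {
      base_pair <- if (homog) fa * fb else 2 * fa * fb
      p_pair <- (1 - beta) * base_pair + beta
      fa2 <- (1 - beta) * fa + beta * (if (homog) 1 else 0.5)
      fb2 <- (1 - beta) * fb + beta * (if (homog) 1 else 0.5)
      base2 <- if (homog) fa2 * fb2 else 2 * fa2 * fb2
      p_pair - coupling * base2
    }
    if (fn(0) >= 0 || fn(0.999) <= 0)
      stop("coupling target unattainable for these class frequencies")
    beta <- stats::uniroot(fn, c(0, 0.999), tol = 1e-12)$root
  }
  set.seed(seed)
  coupled <- stats::runif(n_draws) < beta
  cls <- names(class_freqs)
  c1 <- sample(cls, n_draws, replace = TRUE, prob = class_freqs)
  c2 <- sample(cls, n_draws, replace = TRUE, prob = class_freqs)
  if (!is.null(coupled_pair)) {
    c1[coupled] <- coupled_pair[1]
    c2[coupled] <- coupled_pair[2]
  }
  pairs <- data.frame(
    res1 = unname(CLASS_REPRESENTATIVE[c1]),
    res2 = unname(CLASS_REPRESENTATIVE[c2]),
    region1 = "core", region2 = "core",
    stringsAsFactors = FALSE
  )
  list(pairs = pairs,
       expected_pmi = log2(coupling),
       beta = unname(beta),
       coupled_class = if (is.null(coupled_pair)) NULL else
         pair_class_label(coupled_pair[1], coupled_pair[2]))
}

# ---------------------------------------------------------------------------
# Plain-text structure writers (PDB and minimal mmCIF) so fixtures can
# exercise the full parser path
# ---------------------------------------------------------------------------

#' Write a structure model as a PDB file
#'
#' @param model a `structure_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_file <- function(model, path) {
  at <- model$atoms
  lines <- character(nrow(at))
  for (i in seq_len(nrow(at))) {
    name <- at$elety[i]
    name_f <- if (nchar(name) >= 4) substr(name, 1, 4)
              else sprintf(" %-3s", name)
    lines[i] <- sprintf(
      "ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, name_f, substr(paste0(at$alt[i], " "), 1, 1), at$resid[i],
      at$chain[i], at$resno[i], substr(paste0(at$insert[i], " "), 1, 1),
      at$x[i], at$y[i], at$z[i], at$o[i], 0, at$element[i])
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a structure model as a minimal mmCIF file
#'
#' Emits a single atom_site loop sufficient for round-tripping through an
#' mmCIF parser.
#'
#' @param model a `structure_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cif_file <- function(model, path) {
  at <- model$atoms
  header <- c(
    paste0("data_", model$structure_id),
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  rows <- vapply(seq_len(nrow(at)), function(i) {
    alt <- if (at$alt[i] == "") "." else at$alt[i]
    ins <- if (at$insert[i] == "") "?" else at$insert[i]
    sprintf("ATOM %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
            i, at$element[i], at$elety[i], alt, at$resid[i], at$chain[i],
            at$resno[i], ins, at$x[i], at$y[i], at$z[i], at$o[i], 0,
            at$resno[i], at$resid[i], at$chain[i], at$elety[i])
  }, character(1))
  writeLines(c(header, rows, "#"), path)
  invisible(path)
}
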