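# ---------------------------------------------------------------------------
# Non-bonded interaction detection.
#
# Candidate residue pairs (Calpha-Calpha <= 14 A) are screened by a family
# of geometric detectors covering 19 reported interaction types. All
# detectors work from heavy-atom geometry: where a criterion is defined via
# a donor hydrogen, the angle is evaluated at the donor heavy atom against
# its covalent antecedent, which is equivalent to placing the hydrogen at
# ideal geometry oriented toward the acceptor (rotatable donors) and avoids
# any dependence on hydrogens rarely present in X-ray files.
#
# All distance cutoffs use <= semantics and all angular windows are
# inclusive, so a contact built exactly at a cutoff fires.
# ---------------------------------------------------------------------------

#' Geometric thresholds for the interaction detectors
#'
#' Every criterion used by the detectors is a configurable value with a
#' literature-informed default. Distances in Angstrom, angles in degrees.
#'
#' @param ca_cutoff candidate-pair Calpha-Calpha cutoff (14 A).
#' @param d_hbond,a_hbond H-bond donor-acceptor heavy-atom distance (3.5)
#'   and minimum antecedent-donor-acceptor angle (90).
#' @param d_sse_hbond S/Se-mediated H-bond distance (4.2).
#' @param d_h_pi,a_h_pi donor-to-ring-centroid distance (4.5) and maximum
#'   angle from the ring normal (40).
#' @param d_n_pi_star,bd_window carbonyl O...C distance (3.6) and the
#'   inclusive Burgi-Dunitz approach-angle window (95-125).
#' @param d_c_bond,a_c_bond Csp3...O distance (3.6) and minimum sigma-hole
#'   alignment angle antecedent-C...O (140).
#' @param d_chalcogen,a_chalcogen S/Se...O/N distance (4.0) and minimum
#'   sigma-hole alignment angle (140).
#' @param d_aromatic_sse,a_face S/Se-to-centroid distance (5.5) and the
#'   normal-cone half-angle separating the pi face from the quadrupole edge
#'   (40).
#' @param d_aromatic centroid-centroid cutoff for aromatic-aromatic (7.0);
#'   `a_stacked` (30) and `a_tshaped` (60) split the subtypes by inter-plane
#'   angle.
#' @param d_amino_pi,a_amino_pi amide-N-to-centroid distance (5.5) and
#'   normal cone (45).
#' @param d_aromatic_charge charged-group-to-centroid cutoff (6.0).
#' @param d_salt_bridge charged-group N...O cutoff (4.0).
#' @param vdw_slack additive slack over the sum of vdW radii (0.5).
#' @param d_hydrophobic closest side-chain carbon-carbon cutoff (5.0).
#' @param d_arg_arg,a_arg_arg guanidinium centroid distance (5.0) and
#'   maximum inter-plane angle (30).
#' @param d_backbone,d_sidechain backbone and side-chain proximity cutoffs
#'   for clash/repulsion (8.0, 5.0).
#' @param min_seq_separation minimum |resno_i - resno_j| for intra-chain
#'   candidate pairs (2).
#' @param his_cation treat HIS as protonated (cation-capable) (TRUE).
#' @return named list of thresholds.
#' @export
geometry_config <- function(ca_cutoff = 14,
                            d_hbond = 3.5, a_hbond = 90,
                            d_sse_hbond = 4.2,
                            d_h_pi = 4.5, a_h_pi = 40,
                            d_n_pi_star = 3.6, bd_window = c(95, 125),
                            d_c_bond = 3.6, a_c_bond = 140,
                            d_chalcogen = 4.0, a_chalcogen = 140,
                            d_aromatic_sse = 5.5, a_face = 40,
                            d_aromatic = 7.0, a_stacked = 30, a_tshaped = 60,
                            d_amino_pi = 5.5, a_amino_pi = 45,
                            d_aromatic_charge = 6.0,
                            d_salt_bridge = 4.0,
                            vdw_slack = 0.5,
                            d_hydrophobic = 5.0,
                            d_arg_arg = 5.0, a_arg_arg = 30,
                            d_backbone = 8.0, d_sidechain = 5.0,
                            min_seq_separation = 2,
                            his_cation = TRUE) {
  cfg <- as.list(environment())
  dists <- unlist(cfg[grepl("^d_", names(cfg))])
  stopifnot(all(dists > 0), cfg$ca_cutoff >= max(dists))
  cfg
}

AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

# donor heavy atoms (those carrying at least one H) and their covalent
# antecedents, per residue type; backbone N handled separately
SIDECHAIN_DONORS <- list(
  SER = list(OG = "CB"), THR = list(OG1 = "CB"), TYR = list(OH = "CZ"),
  ASN = list(ND2 = "CG"), GLN = list(NE2 = "CD"), LYS = list(NZ = "CE"),
  ARG = list(NE = "CZ", NH1 = "CZ", NH2 = "CZ"),
  HIS = list(ND1 = "CG", NE2 = "CD2"), TRP = list(NE1 = "CD1"),
  CYS = list(SG = "CB")
)

SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = c("OD1"),
  GLN = c("OE1"), SER = c("OG"), THR = c("OG1"), TYR = c("OH"),
  HIS = c("ND1", "NE2"), MET = c("SD"), CYS = c("SG")
)

# covalent antecedents used for sigma-hole alignment at S/Se
SULFUR_BONDS <- list(MET = list(SD = c("CG", "CE")), CYS = list(SG = "CB"))

CATION_GROUP <- list(ARG = "CZ", LYS = "NZ")
ANION_GROUP <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# Precompute per-residue geometry used by the detectors.
residue_geometry <- function(model) {
  at <- model$atoms
  at <- at[at$element != "H", , drop = FALSE]
  key <- residue_key(at$chain, at$resno, at$insert)
  split_idx <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))
  lapply(split_idx, function(ii) {
    a <- at[ii, , drop = FALSE]
    xyz <- cbind(a$x, a$y, a$z)
    rownames(xyz) <- a$elety
    resname <- a$resid[1]
    canon <- canonical_resname(resname)
    coord <- function(name) if (name %in% rownames(xyz))
      xyz[name, , drop = FALSE][1, ] else NULL
    rings <- list()
    if (canon %in% names(AROMATIC_RINGS)) {
      for (ring in AROMATIC_RINGS[[canon]]) {
        if (all(ring %in% rownames(xyz))) {
          m <- xyz[ring, , drop = FALSE]
          rings[[length(rings) + 1]] <-
            list(centroid = colMeans(m), normal = plane_normal(m))
        }
      }
    }
    guanidinium <- NULL
    if (canon == "ARG" && all(c("CZ", "NE", "NH1", "NH2") %in% rownames(xyz))) {
      m <- xyz[c("CZ", "NE", "NH1", "NH2"), , drop = FALSE]
      guanidinium <- list(centroid = colMeans(m), normal = plane_normal(m))
    }
    list(
      key = key[ii[1]], resname = resname, canon = canon,
      chain = a$chain[1], resno = a$resno[1],
      xyz = xyz,
      ca = coord("CA"),
      backbone = xyz[a$backbone, , drop = FALSE],
      sidechain = xyz[!a$backbone, , drop = FALSE],
      elements = a$element,
      backbone_mask = a$backbone,
      rings = rings,
      guanidinium = guanidinium
    )
  })
}

#' Enumerate candidate residue pairs
#'
#' Among all residue pairs, only those with a Calpha-Calpha distance of
#' `ca_cutoff` (default 14 A) or less are retained for analysis. Intra-chain
#' pairs must additionally be separated in sequence by at least
#' `min_seq_separation` residues. Residues lacking a Calpha are skipped with
#' a warning. The output order is deterministic (chain, resno).
#'
#' @param model a `structure_model`.
#' @param cfg a [geometry_config()].
#' @param scope "inter_chain", "intra_chain" or "both".
#' @return data.frame: key1, key2, res1, res2, chain1, chain2,
#'   ca_distance, inter_chain.
#' @export
enumerate_candidate_pairs <- function(model, cfg = geometry_config(),
                                      scope = c("inter_chain", "intra_chain",
                                                "both")) {
  scope <- match.arg(scope)
  geo <- residue_geometry(model)
  has_ca <- vapply(geo, function(g) !is.null(g$ca), logical(1))
  if (any(!has_ca))
    warning(sum(!has_ca), " residue(s) lack a Calpha and were skipped")
  geo <- geo[has_ca]
  n <- length(geo)
  empty <- data.frame(key1 = character(0), key2 = character(0),
                      res1 = character(0), res2 = character(0),
                      chain1 = character(0), chain2 = character(0),
                      ca_distance = numeric(0), inter_chain = logical(0))
  if (n < 2) return(empty)
  ca <- t(vapply(geo, function(g) g$ca, numeric(3)))
  d <- as.matrix(stats::dist(ca))
  chains <- vapply(geo, function(g) g$chain, character(1))
  resno <- vapply(geo, function(g) g$resno, integer(1))
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] > cfg$ca_cutoff) next
      inter <- chains[i] != chains[j]
      if (scope == "inter_chain" && !inter) next
      if (scope == "intra_chain" && inter) next
      if (!inter && abs(resno[i] - resno[j]) < cfg$min_seq_separation) next
      out[[length(out) + 1]] <- data.frame(
        key1 = geo[[i]]$key, key2 = geo[[j]]$key,
        res1 = geo[[i]]$resname, res2 = geo[[j]]$resname,
        chain1 = chains[i], chain2 = chains[j],
        ca_distance = d[i, j], inter_chain = inter)
    }
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

# --- record collector ------------------------------------------------------

new_record <- function(type, subtype, gi, gj, distance, angle = NA_real_,
                       atoms = NA_character_) {
  data.frame(type = type, subtype = subtype,
             key1 = gi$key, key2 = gj$key,
             res1 = gi$resname, res2 = gj$resname,
             chain1 = gi$chain, chain2 = gj$chain,
             distance = distance, angle = angle, atoms = atoms,
             inter_chain = gi$chain != gj$chain,
             stringsAsFactors = FALSE)
}

bind_records <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (length(lst) == 0) return(empty_records())
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

empty_records <- function() {
  data.frame(type = character(0), subtype = character(0),
             key1 = character(0), key2 = character(0),
             res1 = character(0), res2 = character(0),
             chain1 = character(0), chain2 = character(0),
             distance = numeric(0), angle = numeric(0),
             atoms = character(0), inter_chain = logical(0))
}

# donors of a residue: list of (atom, antecedents, element)
donor_atoms <- function(g) {
  out <- list()
  if (g$canon != "PRO" && "N" %in% rownames(g$xyz) && "CA" %in% rownames(g$xyz))
    out[[length(out) + 1]] <- list(atom = "N", ante = "CA", element = "N")
  sd <- SIDECHAIN_DONORS[[g$canon]]
  for (nm in names(sd)) {
    if (nm %in% rownames(g$xyz) && all(sd[[nm]] %in% rownames(g$xyz))) {
      el <- g$elements[match(nm, rownames(g$xyz))]
      out[[length(out) + 1]] <- list(atom = nm, ante = sd[[nm]][1],
                                     element = el)
    }
  }
  out
}

acceptor_atoms <- function(g) {
  out <- list()
  for (nm in intersect(c("O", "OXT"), rownames(g$xyz)))
    out[[length(out) + 1]] <- list(atom = nm, element = "O")
  sa <- SIDECHAIN_ACCEPTORS[[g$canon]]
  for (nm in sa) {
    if (!is.null(nm) && nm %in% rownames(g$xyz)) {
      el <- g$elements[match(nm, rownames(g$xyz))]
      out[[length(out) + 1]] <- list(atom = nm, element = el)
    }
  }
  out
}

atom_pair_id <- function(gi, gj, ai, aj) {
  paste(gi$key, ai, gj$key, aj, sep = "|")
}

# --- detector families -----------------------------------------------------

#' Hydrogen-bond family detector
#'
#' Detects regular hydrogen bonds, S/Se-mediated hydrogen bonds and H-pi
#' bonds for one candidate pair. A regular H-bond requires a donor-acceptor
#' heavy-atom distance of at most `d_hbond` and an antecedent-donor-acceptor
#' angle of at least `a_hbond`; the same template with a sulfur or selenium
#' donor or acceptor and the longer `d_sse_hbond` cutoff yields an
#' S/Se-mediated bond. An H-pi bond places a donor within `d_h_pi` of an
#' aromatic ring centroid inside the `a_h_pi` cone around the ring normal.
#'
#' @param gi,gj residue geometries (internal).
#' @param cfg a [geometry_config()].
#' @return interaction record data.frame (possibly empty).
#' @export
detect_hbond_family <- function(gi, gj, cfg = geometry_config()) {
  recs <- list()
  for (pair in list(c(1, 2), c(2, 1))) {
    gd <- list(gi, gj)[[pair[1]]]
    ga <- list(gi, gj)[[pair[2]]]
    for (don in donor_atoms(gd)) {
      dpos <- gd$xyz[don$atom, ]
      apos_ante <- gd$xyz[don$ante, ]
      for (acc in acceptor_atoms(ga)) {
        apos <- ga$xyz[acc$atom, ]
        d <- dist3(dpos, apos)
        sse <- don$element %in% c("S", "SE") || acc$element %in% c("S", "SE")
        cutoff <- if (sse) cfg$d_sse_hbond else cfg$d_hbond
        if (d > cutoff) next
        ang <- angle_deg(apos_ante, dpos, apos)
        if (ang < cfg$a_hbond) next
        type <- if (sse) "sse_hbond" else "hbond"
        recs[[length(recs) + 1]] <- new_record(
          type, paste0(don$atom, ">", acc$atom),
          list(gi, gj)[[pair[1]]], list(gi, gj)[[pair[2]]], d, ang,
          atom_pair_id(gd, ga, don$atom, acc$atom))
      }
      # H-pi: donor against the partner's aromatic rings
      for (ring in ga$rings) {
        d <- dist3(dpos, ring$centroid)
        if (d > cfg$d_h_pi) next
        cone <- line_angle_deg(dpos - ring$centroid, ring$normal)
        if (cone > cfg$a_h_pi) next
        recs[[length(recs) + 1]] <- new_record(
          "h_pi", paste0(don$atom, ">ring"), gd, ga, d, cone,
          atom_pair_id(gd, ga, don$atom, "ring"))
      }
    }
  }
  fix_orientation(bind_records(recs), gi, gj)
}

# records are emitted donor-side first; re-orient them so key1/key2 match
# the (gi, gj) call order, keeping detect(i,j) == detect(j,i)
fix_orientation <- function(recs, gi, gj) {
  if (nrow(recs) == 0) return(recs)
  flip <- recs$key1 != gi$key
  if (any(flip)) {
    tmp <- recs[flip, c("key1", "res1", "chain1")]
    recs[flip, c("key1", "res1", "chain1")] <-
      recs[flip, c("key2", "res2", "chain2")]
    recs[flip, c("key2", "res2", "chain2")] <- tmp
  }
  recs
}

#' Backbone-carbonyl family: n->pi* and C-bonds
#'
#' An n->pi* contact is an interaction between the carbonyl groups of two
#' backbones: the donor oxygen approaches the acceptor carbonyl carbon
#' within `d_n_pi_star` along a Burgi-Dunitz-like trajectory (the
#' O...C=O angle falls inside `bd_window`). A C-bond is an n->sigma*
#' donation from an sp3 carbon to a carbonyl oxygen: Csp3...O within
#' `d_c_bond` with the oxygen lying along the extension of a covalent bond
#' of the carbon (angle >= `a_c_bond`).
#'
#' @inheritParams detect_hbond_family
#' @return interaction record data.frame.
#' @export
detect_carbonyl_family <- function(gi, gj, cfg = geometry_config()) {
  recs <- list()
  for (pair in list(list(gi, gj), list(gj, gi))) {
    gd <- pair[[1]]
    ga <- pair[[2]]
    # n->pi*: donor backbone O to acceptor backbone C(=O)
    if (all(c("O") %in% rownames(gd$xyz)) &&
        all(c("C", "O") %in% rownames(ga$xyz))) {
      op <- gd$xyz["O", ]
      cp <- ga$xyz["C", ]
      oa <- ga$xyz["O", ]
      d <- dist3(op, cp)
      if (d <= cfg$d_n_pi_star) {
        ang <- angle_deg(op, cp, oa)
        if (ang >= cfg$bd_window[1] && ang <= cfg$bd_window[2])
          recs[[length(recs) + 1]] <- new_record(
            "n_pi_star", "O>C", gd, ga, d, ang,
            atom_pair_id(gd, ga, "O", "C"))
      }
    }
    # C-bond: sp3 carbons of the donor against acceptor carbonyl O
    if ("O" %in% rownames(ga$xyz)) {
      op <- ga$xyz["O", ]
      sp3 <- setdiff(rownames(gd$xyz)[gd$elements == "C"], c("C"))
      for (cn in sp3) {
        # antecedent: CA for CB, CB for CG..., fall back to nearest bonded C
        ante <- sp3_antecedent(gd, cn)
        if (is.null(ante)) next
        cp <- gd$xyz[cn, ]
        d <- dist3(cp, op)
        if (d > cfg$d_c_bond) next
        ang <- angle_deg(gd$xyz[ante, ], cp, op)
        if (ang < cfg$a_c_bond) next
        recs[[length(recs) + 1]] <- new_record(
          "c_bond", paste0(cn, ">O"), gd, ga, d, ang,
          atom_pair_id(gd, ga, cn, "O"))
      }
    }
  }
  fix_orientation(bind_records(recs), gi, gj)
}

# crude covalent antecedent for an sp3 carbon: the nearest other heavy atom
# of the same residue within bonding distance
sp3_antecedent <- function(g, cn) {
  others <- setdiff(rownames(g$xyz), cn)
  if (length(others) == 0) return(NULL)
  d <- apply(g$xyz[others, , drop = FALSE], 1,
             function(p) dist3(p, g$xyz[cn, ]))
  cand <- others[d < 1.8]
  if (length(cand) == 0) return(NULL)
  cand[which.min(d[match(cand, others)])]
}

#' Sulfur/selenium family: chalcogen bonds and aromatic-S/Se
#'
#' A chalcogen bond aligns an electronegative atom (O or N) with the
#' sigma-hole of a sulfur or selenium atom: S/Se...X within `d_chalcogen`
#' and the contact lying along the extension of a covalent bond to S/Se
#' (angle B-S...X >= `a_chalcogen`). An aromatic-S/Se interaction places
#' S/Se within `d_aromatic_sse` of a ring centroid; the subtype is "pi" when
#' the atom sits inside the `a_face` cone around the ring normal and
#' "quadrupole" otherwise.
#'
#' @inheritParams detect_hbond_family
#' @return interaction record data.frame.
#' @export
detect_sulfur_family <- function(gi, gj, cfg = geometry_config()) {
  recs <- list()
  for (pair in list(list(gi, gj), list(gj, gi))) {
    gs <- pair[[1]]
    gx <- pair[[2]]
    sb <- SULFUR_BONDS[[gs$canon]]
    for (sn in names(sb)) {
      if (!sn %in% rownames(gs$xyz)) next
      sp <- gs$xyz[sn, ]
      antes <- intersect(sb[[sn]], rownames(gs$xyz))
      # chalcogen: against O/N atoms of the partner
      targets <- rownames(gx$xyz)[gx$elements %in% c("O", "N")]
      for (tn in targets) {
        tp <- gx$xyz[tn, ]
        d <- dist3(sp, tp)
        if (d > cfg$d_chalcogen) next
        ok <- FALSE
        best <- NA_real_
        for (an in antes) {
          ang <- angle_deg(gs$xyz[an, ], sp, tp)
          if (is.na(best) || ang > best) best <- ang
          if (ang >= cfg$a_chalcogen) ok <- TRUE
        }
        if (!ok) next
        recs[[length(recs) + 1]] <- new_record(
          "chalcogen", paste0(sn, ">", tn), gs, gx, d, best,
          atom_pair_id(gs, gx, sn, tn))
      }
      # aromatic-S/Se
      for (ring in gx$rings) {
        d <- dist3(sp, ring$centroid)
        if (d > cfg$d_aromatic_sse) next
        cone <- line_angle_deg(sp - ring$centroid, ring$normal)
        sub <- if (cone <= cfg$a_face) "pi" else "quadrupole"
        recs[[length(recs) + 1]] <- new_record(
          "aromatic_sse", sub, gs, gx, d, cone,
          atom_pair_id(gs, gx, sn, "ring"))
      }
    }
  }
  fix_orientation(bind_records(recs), gi, gj)
}

#' Aromatic family: ring-ring, amino-pi and aromatic-charge
#'
#' Aromatic-aromatic contacts are ring-centroid pairs within `d_aromatic`,
#' subtyped by the inter-plane angle: stacked (<= `a_stacked`), T-shaped
#' (>= `a_tshaped`) or quadrupole (in between). Amino-pi places the amide
#' nitrogen of ASN/GLN within `d_amino_pi` of a centroid inside the
#' `a_amino_pi` normal cone. Aromatic-cation / aromatic-anion place the
#' charged-group centroid (ARG CZ, LYS NZ, protonated HIS ring centroid;
#' ASP/GLU carboxylate midpoint) within `d_aromatic_charge` of a ring
#' centroid, subtyped pi/quadrupole by the normal cone `a_face`.
#'
#' @inheritParams detect_hbond_family
#' @return interaction record data.frame.
#' @export
detect_aromatic_family <- function(gi, gj, cfg = geometry_config()) {
  recs <- list()
  # aromatic-aromatic (each ring pair once)
  if (length(gi$rings) > 0 && length(gj$rings) > 0) {
    for (ri in gi$rings) {
      for (rj in gj$rings) {
        d <- dist3(ri$centroid, rj$centroid)
        if (d > cfg$d_aromatic) next
        plane <- line_angle_deg(ri$normal, rj$normal)
        sub <- if (plane <= cfg$a_stacked) "stacked"
               else if (plane >= cfg$a_tshaped) "t_shaped"
               else "quadrupole"
        recs[[length(recs) + 1]] <- new_record(
          "aromatic_aromatic", sub, gi, gj, d, plane,
          atom_pair_id(gi, gj, "ring", "ring"))
      }
    }
  }
  for (pair in list(list(gi, gj), list(gj, gi))) {
    gc_ <- pair[[1]] # charge / amide side
    gr <- pair[[2]]  # ring side
    if (length(gr$rings) == 0) next
    # amino-pi
    amide <- switch(gc_$canon, ASN = "ND2", GLN = "NE2", NULL)
    if (!is.null(amide) && amide %in% rownames(gc_$xyz)) {
      np <- gc_$xyz[amide, ]
      for (ring in gr$rings) {
        d <- dist3(np, ring$centroid)
        if (d > cfg$d_amino_pi) next
        cone <- line_angle_deg(np - ring$centroid, ring$normal)
        if (cone > cfg$a_amino_pi) next
        recs[[length(recs) + 1]] <- new_record(
          "amino_pi", paste0(amide, ">ring"), gc_, gr, d, cone,
          atom_pair_id(gc_, gr, amide, "ring"))
      }
    }
    # aromatic-cation / anion
    cg <- charged_group_centroid(gc_, cfg$his_cation)
    if (!is.null(cg)) {
      for (ring in gr$rings) {
        d <- dist3(cg$pos, ring$centroid)
        if (d > cfg$d_aromatic_charge) next
        cone <- line_angle_deg(cg$pos - ring$centroid, ring$normal)
        sub <- if (cone <= cfg$a_face) "pi" else "quadrupole"
        type <- if (cg$sign > 0) "aromatic_cation" else "aromatic_anion"
        recs[[length(recs) + 1]] <- new_record(
          type, sub, gc_, gr, d, cone,
          atom_pair_id(gc_, gr, cg$label, "ring"))
      }
    }
  }
  fix_orientation(bind_records(recs), gi, gj)
}

charged_group_centroid <- function(g, his_cation = TRUE) {
  canon <- g$canon
  if (canon %in% names(CATION_GROUP)) {
    nm <- CATION_GROUP[[canon]]
    if (nm %in% rownames(g$xyz))
      return(list(pos = g$xyz[nm, ], sign = 1, label = nm))
  }
  if (canon == "HIS" && his_cation && length(g$rings) > 0)
    return(list(pos = g$rings[[1]]$centroid, sign = 1, label = "ring"))
  if (canon %in% names(ANION_GROUP)) {
    nms <- intersect(ANION_GROUP[[canon]], rownames(g$xyz))
    if (length(nms) > 0)
      return(list(pos = colMeans(g$xyz[nms, , drop = FALSE]), sign = -1,
                  label = paste(nms, collapse = "+")))
  }
  NULL
}

#' Arginine-arginine stacking detector
#'
#' Fires when the guanidinium planes of two arginines are stacked: plane
#' centroids within `d_arg_arg` and inter-plane angle at most `a_arg_arg`.
#' A stacked ARG-ARG pair is excluded from the charge-clash category.
#'
#' @inheritParams detect_hbond_family
#' @return interaction record data.frame.
#' @export
detect_arg_arg_stacking <- function(gi, gj, cfg = geometry_config()) {
  if (is.null(gi$guanidinium) || is.null(gj$guanidinium))
    return(empty_records())
  d <- dist3(gi$guanidinium$centroid, gj$guanidinium$centroid)
  if (d > cfg$d_arg_arg) return(empty_records())
  plane <- line_angle_deg(gi$guanidinium$normal, gj$guanidinium$normal)
  if (plane > cfg$a_arg_arg) return(empty_records())
  new_record("arg_arg_stacking", "stacked", gi, gj, d, plane,
             atom_pair_id(gi, gj, "guanidinium", "guanidinium"))
}

#' Salt-bridge detector
#'
#' An electrostatic interaction combining an ionic bond and a hydrogen bond
#' between residues of opposite charge: the minimum charged-group
#' nitrogen...oxygen distance must be at most `d_salt_bridge` and the same
#' groups must satisfy the hydrogen-bond angle criterion.
#'
#' @inheritParams detect_hbond_family
#' @return interaction record data.frame (at most one record).
#' @export
detect_salt_bridge <- function(gi, gj, cfg = geometry_config()) {
  cations <- if (cfg$his_cation) c("ARG", "LYS", "HIS") else c("ARG", "LYS")
  pick <- function(a, b) {
    if (a$canon %in% cations && b$canon %in% c("ASP", "GLU")) list(a, b)
    else if (b$canon %in% cations && a$canon %in% c("ASP", "GLU")) list(b, a)
    else NULL
  }
  pb <- pick(gi, gj)
  if (is.null(pb)) return(empty_records())
  gc_ <- pb[[1]]
  ga <- pb[[2]]
  natoms <- switch(gc_$canon, ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                   HIS = c("ND1", "NE2"))
  natoms <- intersect(natoms, rownames(gc_$xyz))
  oatoms <- intersect(ANION_GROUP[[ga$canon]], rownames(ga$xyz))
  if (length(natoms) == 0 || length(oatoms) == 0) return(empty_records())
  best <- NULL
  for (nn in natoms) {
    ante <- switch(gc_$canon, ARG = "CZ", LYS = "CE",
                   HIS = if (nn == "ND1") "CG" else "CD2")
    if (!ante %in% rownames(gc_$xyz)) next
    for (on in oatoms) {
      d <- dist3(gc_$xyz[nn, ], ga$xyz[on, ])
      if (d > cfg$d_salt_bridge) next
      ang <- angle_deg(gc_$xyz[ante, ], gc_$xyz[nn, ], ga$xyz[on, ])
      if (ang < cfg$a_hbond) next
      if (is.null(best) || d < best$distance)
        best <- list(distance = d, angle = ang, atoms = c(nn, on))
    }
  }
  if (is.null(best)) return(empty_records())
  fix_orientation(
    new_record("salt_bridge", paste0(best$atoms[1], ">", best$atoms[2]),
               gc_, ga, best$distance, best$angle,
               atom_pair_id(gc_, ga, best$atoms[1], best$atoms[2])),
    gi, gj)
}

#' Packing family: van der Waals and hydrophobic contacts
#'
#' A van der Waals contact is recorded for every heavy-atom pair closer
#' than the sum of the two vdW radii plus `vdw_slack` that is not already
#' accounted for by a directional interaction between the same atoms
#' (passed via `used_atom_pairs`). A hydrophobic interaction fires once per
#' pair when both residues are hydrophobic-class and their closest
#' side-chain carbon-carbon distance is at most `d_hydrophobic`.
#'
#' @inheritParams detect_hbond_family
#' @param used_atom_pairs character vector of atom-pair ids already engaged
#'   in directional interactions.
#' @param radii vdW radius set.
#' @return interaction record data.frame.
#' @export
detect_packing_family <- function(gi, gj, cfg = geometry_config(),
                                  used_atom_pairs = character(0),
                                  radii = vdw_radii()) {
  recs <- list()
  tab <- residue_class_table()
  hydro <- tab$resname[tab$hydropathy == "hydrophobic"]
  ri <- radii[gi$elements]
  rj <- radii[gj$elements]
  ai <- rownames(gi$xyz)
  aj <- rownames(gj$xyz)
  for (p in seq_along(ai)) {
    for (q in seq_along(aj)) {
      d <- dist3(gi$xyz[p, ], gj$xyz[q, ])
      if (d > ri[p] + rj[q] + cfg$vdw_slack) next
      id <- atom_pair_id(gi, gj, ai[p], aj[q])
      id_rev <- atom_pair_id(gj, gi, aj[q], ai[p])
      if (id %in% used_atom_pairs || id_rev %in% used_atom_pairs) next
      recs[[length(recs) + 1]] <- new_record(
        "vdw", paste0(ai[p], ":", aj[q]), gi, gj, d, NA_real_, id)
    }
  }
  if (gi$canon %in% hydro && gj$canon %in% hydro) {
    sci <- gi$sidechain[gi$elements[!gi$backbone_mask] == "C", , drop = FALSE]
    scj <- gj$sidechain[gj$elements[!gj$backbone_mask] == "C", , drop = FALSE]
    d <- min_cross_dist(sci, scj)
    if (d <= cfg$d_hydrophobic)
      recs[[length(recs) + 1]] <- new_record(
        "hydrophobic", "cc", gi, gj, d, NA_real_,
        atom_pair_id(gi, gj, "sidechain", "sidechain"))
  }
  bind_records(recs)
}

#' Clash and repulsion detector
#'
#' Applies to like-charged pairs (both cations or both anions) and to
#' hydrophobe-hydrophile pairs. With the minimum backbone-backbone atom
#' distance at most `d_backbone`: the pair is a clash when the side chains
#' are also close (minimum side-chain distance <= `d_sidechain`) and a
#' repulsion when they are farther apart. Stacked ARG-ARG pairs are excluded
#' from the charge categories; glycine (no side chain) is skipped.
#'
#' @inheritParams detect_hbond_family
#' @param arg_stacked logical; TRUE when the pair carries an ARG-ARG
#'   stacking record.
#' @return interaction record data.frame (at most one record).
#' @export
detect_clash_repulsion <- function(gi, gj, cfg = geometry_config(),
                                   arg_stacked = FALSE) {
  cations <- if (cfg$his_cation) c("ARG", "LYS", "HIS") else c("ARG", "LYS")
  anions <- c("ASP", "GLU")
  tab <- residue_class_table()
  hydro <- tab$resname[tab$hydropathy == "hydrophobic"]
  phile <- tab$resname[tab$hydropathy == "hydrophilic"]
  like_charge <- (gi$canon %in% cations && gj$canon %in% cations) ||
    (gi$canon %in% anions && gj$canon %in% anions)
  hh <- (gi$canon %in% hydro && gj$canon %in% phile) ||
    (gi$canon %in% phile && gj$canon %in% hydro)
  if (!like_charge && !hh) return(empty_records())
  if (like_charge && arg_stacked) like_charge <- FALSE
  if (!like_charge && !hh) return(empty_records())
  if (nrow(gi$sidechain) == 0 || nrow(gj$sidechain) == 0) {
    warning("clash/repulsion skipped for pair with missing side chain: ",
            gi$key, " - ", gj$key)
    return(empty_records())
  }
  dbb <- min_cross_dist(gi$backbone, gj$backbone)
  if (dbb > cfg$d_backbone) return(empty_records())
  dsc <- min_cross_dist(gi$sidechain, gj$sidechain)
  kind <- if (dsc <= cfg$d_sidechain) "clash" else "repulsion"
  type <- if (like_charge) paste0("charge_", kind)
          else paste0("hydrophobic_hydrophilic_", kind)
  new_record(type, kind, gi, gj, dsc, NA_real_,
             atom_pair_id(gi, gj, "sidechain", "sidechain"))
}

# run every detector over one candidate pair
detect_pair <- function(gi, gj, cfg = geometry_config()) {
  rr <- detect_arg_arg_stacking(gi, gj, cfg)
  directional <- bind_records(list(
    detect_hbond_family(gi, gj, cfg),
    detect_carbonyl_family(gi, gj, cfg),
    detect_sulfur_family(gi, gj, cfg),
    detect_aromatic_family(gi, gj, cfg),
    detect_salt_bridge(gi, gj, cfg),
    rr
  ))
  packing <- detect_packing_family(gi, gj, cfg,
                                   used_atom_pairs = directional$atoms)
  cr <- detect_clash_repulsion(gi, gj, cfg, arg_stacked = nrow(rr) > 0)
  bind_records(list(directional, packing, cr))
}

#' Detect all interactions in a structure
#'
#' Enumerates candidate pairs (Calpha-Calpha <= 14 A) in the requested
#' scope and runs every detector on each. Pairs engaged in at least one
#' interaction are materialized as pair records.
#'
#' @param model a `structure_model` (typically the complex).
#' @param cfg a [geometry_config()].
#' @param regions optional data.frame from [region_assignments()]; when
#'   given, pair records carry the consensus region of each residue.
#' @param scope passed to [enumerate_candidate_pairs()].
#' @return list with `records` (one row per interaction instance), `pairs`
#'   (one row per interacting pair: keys, residue names, ca_distance,
#'   n_interactions, types, pair_type, regions, same_region) and
#'   `candidates` (all candidate pairs).
#' @export
detect_all <- function(model, cfg = geometry_config(), regions = NULL,
                       scope = c("inter_chain", "intra_chain", "both")) {
  scope <- match.arg(scope)
  cand <- enumerate_candidate_pairs(model, cfg, scope)
  geo <- residue_geometry(model)
  keys <- vapply(geo, function(g) g$key, character(1))
  recs <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    gi <- geo[[match(cand$key1[k], keys)]]
    gj <- geo[[match(cand$key2[k], keys)]]
    recs[[k]] <- detect_pair(gi, gj, cfg)
  }
  records <- bind_records(recs)
  pairs <- pair_records(records, cand, regions)
  list(records = records, pairs = pairs, candidates = cand)
}

pair_records <- function(records, candidates, regions = NULL) {
  if (nrow(records) == 0) {
    out <- candidates[0, , drop = FALSE]
    out$n_interactions <- integer(0)
    out$types <- character(0)
    out$pair_type <- character(0)
    out$region1 <- character(0)
    out$region2 <- character(0)
    out$same_region <- logical(0)
    return(out)
  }
  pid <- paste(records$key1, records$key2, sep = "||")
  cid <- paste(candidates$key1, candidates$key2, sep = "||")
  agg_n <- table(pid)
  out <- candidates[cid %in% names(agg_n), , drop = FALSE]
  cid <- cid[cid %in% names(agg_n)]
  out$n_interactions <- as.integer(agg_n[cid])
  out$types <- vapply(cid, function(id)
    paste(sort(unique(records$type[pid == id])), collapse = ","), character(1))
  out$pair_type <- paste(pmin(out$res1, out$res2),
                         pmax(out$res1, out$res2), sep = "-")
  if (!is.null(regions)) {
    out$region1 <- regions$region[match(out$key1, regions$key)]
    out$region2 <- regions$region[match(out$key2, regions$key)]
    out$same_region <- !is.na(out$region1) & out$region1 == out$region2
  } else {
    out$region1 <- NA_character_
    out$region2 <- NA_character_
    out$same_region <- NA
  }
  rownames(out) <- NULL
  out
}

#' Write an interaction record table as TSV
#'
#' @param records data.frame from [detect_all()].
#' @param path output file.
#' @param structure_id optional id column value.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(records, path, structure_id = NA) {
  records$structure_id <- structure_id
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
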