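# ---------------------------------------------------------------------------
# Solvent accessibility and interface regions.
#
# SASA is computed with the Shrake-Rupley sphere-sampling algorithm on a
# deterministic golden-spiral quadrature; rASA = ASA / MaxASA; residues are
# assigned to interior/surface/core/support/rim regions from the change of
# rASA upon complex formation, with a consensus vote over MaxASA scales.
# ---------------------------------------------------------------------------

REGION_LABELS <- c("core", "support", "rim_interacting", "rim_nis",
                   "surface", "interior")

# Priority used for consensus ties: the more-buried label wins.
REGION_PRIORITY <- c(core = 1, support = 2, rim_interacting = 3, rim_nis = 4,
                     surface = 5, interior = 6)

#' Region classification thresholds
#'
#' @param rasa_cut rASA boundary between buried and exposed (default 0.25).
#' @param nis_cut delta-rASA boundary between the interacting rim and the
#'   rim non-interacting surface (default 0.05).
#' @param interface_eps tolerance used for the interface test
#'   delta-rASA > 0, absorbing quadrature noise (default 1e-9).
#' @return list of thresholds.
#' @export
region_thresholds <- function(rasa_cut = 0.25, nis_cut = 0.05,
                              interface_eps = 1e-9) {
  stopifnot(nis_cut > 0, nis_cut < rasa_cut, rasa_cut < 1)
  list(rasa_cut = rasa_cut, nis_cut = nis_cut, interface_eps = interface_eps)
}

# Deterministic, roughly uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom and per-residue solvent-accessible surface area
#'
#' Shrake-Rupley algorithm: each atom is inflated by the probe radius and
#' sampled with a fixed spherical quadrature; a sample point is accessible
#' when it lies outside every neighboring inflated sphere. Deterministic for
#' a fixed number of points.
#'
#' @param model a `structure_model`.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param n_points quadrature points per atom (default 960).
#' @param radii named vdW radius set, Angstrom (default [vdw_radii()]).
#' @param include_hydrogens logical; hydrogens are ignored by default, the
#'   usual convention for X-ray structures deposited without them.
#' @return list with `atom_asa` (numeric per atom row of the model) and
#'   `residue_asa` (named numeric, residue key -> Angstrom^2).
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960,
                         radii = vdw_radii(), include_hydrogens = FALSE) {
  at <- model$atoms
  use <- if (include_hydrogens) rep(TRUE, nrow(at)) else at$element != "H"
  idx <- which(use)
  el <- at$element[idx]
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown) > 0)
    stop("no vdW radius for element(s): ", paste(unknown, collapse = ", "))
  xyz <- cbind(at$x[idx], at$y[idx], at$z[idx])
  r <- radii[el] + probe_radius
  n <- length(idx)
  pts <- sphere_points(n_points)
  asa <- numeric(n)
  if (n > 0) {
    # neighbor lists via a cell grid would be overkill at fixture scale; use
    # a distance prefilter per atom
    d2 <- as.matrix(stats::dist(xyz))^2
    for (i in seq_len(n)) {
      cand <- which(d2[i, ] < (r[i] + r)^2)
      cand <- cand[cand != i]
      p <- sweep(pts * r[i], 2, xyz[i, ], "+")
      acc <- rep(TRUE, n_points)
      for (j in cand) {
        if (!any(acc)) break
        dx <- p[acc, 1] - xyz[j, 1]
        dy <- p[acc, 2] - xyz[j, 2]
        dz <- p[acc, 3] - xyz[j, 3]
        acc[acc] <- dx * dx + dy * dy + dz * dz > r[j]^2
      }
      asa[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
    }
  }
  atom_asa <- numeric(nrow(at))
  atom_asa[idx] <- asa
  key <- residue_key(at$chain, at$resno, at$insert)
  res_keys <- unique(key)
  residue_asa <- vapply(res_keys, function(k) sum(atom_asa[key == k]),
                        numeric(1))
  list(atom_asa = atom_asa, residue_asa = residue_asa)
}

#' Relative accessible surface area
#'
#' rASA = ASA / MaxASA for the residue type. Values above 1 (extended
#' conformations, chain termini) are kept unclamped; clamping would bias the
#' burial signal delta-rASA.
#'
#' @param asa residue ASA, Angstrom^2.
#' @param resname 3-letter residue name.
#' @param scale named numeric MaxASA vector (one of [maxasa_scales()]).
#' @return fraction (possibly > 1).
#' @export
compute_rasa <- function(asa, resname, scale) {
  resname <- canonical_resname(resname)
  if (any(!resname %in% names(scale)))
    stop("residue missing from MaxASA scale: ",
         paste(setdiff(resname, names(scale)), collapse = ", "))
  unname(asa / scale[resname])
}

#' Assign the interface region of a residue
#'
#' A residue is part of the interface when its rASA drops upon complex
#' formation (delta-rASA > 0). Interface residues split into: support
#' (already buried in the monomer, rASA < 25%), core (exposed in the
#' monomer, buried in the complex), and rim (exposed in both), the rim
#' subdividing into the non-interacting surface (delta-rASA <= 5%) and the
#' interacting rim. Non-interface residues are interior (buried) or surface
#' (exposed). Boundary semantics are strict: a residue sitting exactly at
#' rASA = 25% on both sides falls into the rim.
#'
#' @param rasa_monomer,rasa_complex rASA fractions (>= 0).
#' @param t thresholds from [region_thresholds()].
#' @return one of "core", "support", "rim_interacting", "rim_nis",
#'   "surface", "interior". Vectorized over its first two arguments.
#' @export
assign_region <- function(rasa_monomer, rasa_complex, t = region_thresholds()) {
  if (any(rasa_monomer < 0) || any(rasa_complex < 0))
    stop("rASA values must be non-negative")
  delta <- rasa_monomer - rasa_complex
  n <- length(delta)
  out <- character(n)
  non_iface <- delta <= t$interface_eps
  out[non_iface & rasa_monomer < t$rasa_cut] <- "interior"
  out[non_iface & rasa_monomer >= t$rasa_cut] <- "surface"
  iface <- !non_iface
  out[iface & rasa_monomer < t$rasa_cut] <- "support"
  core <- iface & rasa_monomer > t$rasa_cut & rasa_complex < t$rasa_cut
  out[core] <- "core"
  rim <- iface & out == ""
  out[rim & delta <= t$nis_cut] <- "rim_nis"
  out[rim & delta > t$nis_cut] <- "rim_interacting"
  out
}

#' Consensus region over several MaxASA scales
#'
#' The classification is run once per MaxASA scale and the most frequently
#' assigned region wins; ties are broken by a fixed priority in which the
#' more-buried label prevails (core > support > rim_interacting > rim_nis >
#' surface > interior).
#'
#' @param labels character vector (or named vector by scale) of region
#'   labels for one residue.
#' @return consensus label.
#' @export
assign_region_consensus <- function(labels) {
  if (length(labels) == 0) stop("no region labels supplied")
  bad <- setdiff(labels, REGION_LABELS)
  if (length(bad) > 0) stop("unknown region label(s): ",
                            paste(bad, collapse = ", "))
  counts <- table(labels)
  top <- names(counts)[counts == max(counts)]
  top[which.min(REGION_PRIORITY[top])]
}

#' Region assignment table for a split complex
#'
#' Runs SASA on both monomers and on the complex, computes rASA under each
#' MaxASA scale, assigns per-scale regions and the consensus label.
#'
#' @param split list from [split_complex()].
#' @param scales list of MaxASA scales (default all of [maxasa_scales()]).
#' @param t thresholds from [region_thresholds()].
#' @param probe_radius,n_points passed to [compute_sasa()].
#' @return data.frame: key, chain, resno, insert, resname, asa_monomer,
#'   asa_complex, rasa_monomer, rasa_complex, delta_rasa (consensus-scale
#'   values use the first scale), one `region_<scale>` column per scale, and
#'   the consensus `region`.
#' @export
region_assignments <- function(split, scales = maxasa_scales(),
                               t = region_thresholds(), probe_radius = 1.4,
                               n_points = 960) {
  stopifnot(length(scales) >= 1)
  sasa_a <- compute_sasa(split$monomer_a, probe_radius, n_points)
  sasa_b <- compute_sasa(split$monomer_b, probe_radius, n_points)
  sasa_c <- compute_sasa(split$complex, probe_radius, n_points)
  mono_asa <- c(sasa_a$residue_asa, sasa_b$residue_asa)
  cplx_asa <- sasa_c$residue_asa
  if (!setequal(names(mono_asa), names(cplx_asa)))
    stop("residue keys differ between monomers and complex")
  rt <- model_residues(split$complex)
  rt$asa_monomer <- unname(mono_asa[rt$key])
  rt$asa_complex <- unname(cplx_asa[rt$key])
  region_by_scale <- matrix("", nrow(rt), length(scales),
                            dimnames = list(NULL, names(scales)))
  for (s in names(scales)) {
    rm_ <- compute_rasa(rt$asa_monomer, rt$resname, scales[[s]])
    rc_ <- compute_rasa(rt$asa_complex, rt$resname, scales[[s]])
    region_by_scale[, s] <- assign_region(rm_, rc_, t)
    if (s == names(scales)[1]) {
      rt$rasa_monomer <- rm_
      rt$rasa_complex <- rc_
      rt$delta_rasa <- rm_ - rc_
    }
  }
  for (s in names(scales)) rt[[paste0("region_", s)]] <- region_by_scale[, s]
  rt$region <- apply(region_by_scale, 1, assign_region_consensus)
  rt$n_atoms <- NULL
  rt
}

#' Buried surface area, total and by region
#'
#' The per-residue buried area is the ASA lost upon complex formation
#' (clamped at zero); the total BSA sums it over the residues of both
#' chains, and per-region BSA partitions it by consensus region so that the
#' per-region values sum exactly to the total.
#'
#' @param regions data.frame from [region_assignments()].
#' @return list with `total` (Angstrom^2), `per_residue` (named vector),
#'   `by_region` (named vector over interface regions) and `fractions`
#'   (by_region / total; NA when total is 0).
#' @export
buried_surface_area <- function(regions) {
  buried <- pmax(regions$asa_monomer - regions$asa_complex, 0)
  names(buried) <- regions$key
  total <- sum(buried)
  iface <- c("core", "support", "rim_interacting", "rim_nis")
  by_region <- vapply(iface, function(r) sum(buried[regions$region == r]),
                      numeric(1))
  # burial recorded for non-interface residues (below interface_eps) is kept
  # in the total only through the clamp at 0; tie the partition to the total
  other <- total - sum(by_region)
  if (other > 0) by_region <- c(by_region, other = other)
  list(total = total, per_residue = buried, by_region = by_region,
       fractions = if (total > 0) by_region / total else by_region * NA)
}
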