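# ---------------------------------------------------------------------------
# Region-resolved interface metrics: composition, partitioning, stickiness,
# interaction counting, mean count per capable pair and pair-vs-BSA scaling.
# ---------------------------------------------------------------------------

INTERFACE_REGIONS <- c("core", "support", "rim_interacting", "rim_nis")

#' Physicochemical composition of each region
#'
#' Percentage of residues belonging to each class of the chosen
#' classification dimension, per consensus region.
#'
#' @param regions data.frame from [region_assignments()].
#' @param dimension one of "charge", "polarity", "hydropathy", "aromatic",
#'   "aliphatic", "sidechain_hbond".
#' @param class_table from [residue_class_table()].
#' @return data.frame region x class with percentages summing to 100 per
#'   non-empty region; empty regions are dropped.
#' @export
region_composition <- function(regions,
                               dimension = c("charge", "polarity",
                                             "hydropathy", "aromatic",
                                             "aliphatic", "sidechain_hbond"),
                               class_table = residue_class_table()) {
  dimension <- match.arg(dimension)
  rownames(class_table) <- class_table$resname
  resn <- canonical_resname(regions$resname)
  known <- resn %in% rownames(class_table)
  if (any(!known))
    warning("excluding residues of unknown type: ",
            paste(unique(regions$resname[!known]), collapse = ", "))
  cls <- as.character(class_table[resn[known], dimension])
  reg <- regions$region[known]
  tab <- table(region = reg, class = cls)
  pct <- prop.table(tab, margin = 1) * 100
  out <- as.data.frame.matrix(pct)
  out$region <- rownames(out)
  rownames(out) <- NULL
  out[, c("region", setdiff(names(out), "region"))]
}

#' Partitioning of a residue class across interface regions
#'
#' For the residues of one class found at the interface, the fraction
#' located in each of core, support, rim_interacting, rim_nis; the four
#' fractions sum to 1.
#'
#' @param regions data.frame from [region_assignments()].
#' @param class_value class label, e.g. "positive".
#' @param dimension classification dimension (see [region_composition()]).
#' @param class_table from [residue_class_table()].
#' @return named numeric over the interface regions, or all-NA when the
#'   class is absent from the interface.
#' @export
partition_by_region <- function(regions, class_value,
                                dimension = "charge",
                                class_table = residue_class_table()) {
  rownames(class_table) <- class_table$resname
  resn <- canonical_resname(regions$resname)
  known <- resn %in% rownames(class_table)
  cls <- as.character(class_table[resn[known], dimension])
  reg <- regions$region[known]
  sel <- cls == class_value & reg %in% INTERFACE_REGIONS
  if (!any(sel))
    return(stats::setNames(rep(NA_real_, 4), INTERFACE_REGIONS))
  counts <- table(factor(reg[sel], levels = INTERFACE_REGIONS))
  stats::setNames(as.numeric(counts) / sum(counts), INTERFACE_REGIONS)
}

#' Residue stickiness per region
#'
#' Log-ratio propensity comparing the fractional contribution of each
#' amino-acid type to the interface (or region) area against its
#' contribution to the solvent-accessible surface area:
#' `s_i = ln(f_interface_i / f_surface_i)`. A pseudo-share epsilon is added
#' to both fractions so types observed on only one side stay finite; types
#' absent from both are reported NA.
#'
#' @param interface_area named vector: residue type -> area contributed to
#'   the interface (Angstrom^2).
#' @param surface_area named vector: residue type -> area contributed to
#'   the exposed surface.
#' @param eps pseudo-share (default 1e-6).
#' @return named numeric score per residue type present in either input.
#' @export
stickiness <- function(interface_area, surface_area, eps = 1e-6) {
  if (any(interface_area < 0) || any(surface_area < 0))
    stop("area contributions must be non-negative")
  if (sum(interface_area) <= 0 || sum(surface_area) <= 0)
    stop("zero total area")
  types <- union(names(interface_area), names(surface_area))
  fi <- stats::setNames(rep(0, length(types)), types)
  fs <- fi
  fi[names(interface_area)] <- interface_area / sum(interface_area)
  fs[names(surface_area)] <- surface_area / sum(surface_area)
  out <- log((fi + eps) / (fs + eps))
  out[fi == 0 & fs == 0] <- NA_real_
  out
}

#' Stickiness input areas from a region table
#'
#' Aggregates per-residue buried area by residue type for one region (the
#' interface side) and per-residue exposed area in the monomer for surface
#' residues (the reference side).
#'
#' @param regions data.frame from [region_assignments()].
#' @param region region whose buried area defines the interface side; use
#'   "interface" for all interface regions pooled.
#' @return list(interface_area, surface_area) suitable for [stickiness()].
#' @export
stickiness_areas <- function(regions, region = "interface") {
  sel <- if (region == "interface") regions$region %in% INTERFACE_REGIONS
         else regions$region == region
  buried <- pmax(regions$asa_monomer - regions$asa_complex, 0)
  resn <- canonical_resname(regions$resname)
  iface <- tapply(buried[sel], resn[sel], sum)
  surf_sel <- regions$region == "surface"
  surf <- tapply(regions$asa_monomer[surf_sel], resn[surf_sel], sum)
  list(interface_area = iface, surface_area = surf)
}

#' Interaction counts per type and region
#'
#' @param records interaction records from [detect_all()].
#' @param pairs pair records from [detect_all()] (with regions filled).
#' @param scope "same_region" counts only interactions whose residues share
#'   a consensus region, tabulated by that region; "cross_region" counts
#'   interactions bridging two different regions, tabulated by the
#'   unordered region pair.
#' @return data.frame: region (or region pair), type, count.
#' @export
count_interactions_by_region <- function(records, pairs,
                                         scope = c("same_region",
                                                   "cross_region")) {
  scope <- match.arg(scope)
  if (nrow(records) == 0)
    return(data.frame(region = character(0), type = character(0),
                      count = integer(0)))
  pid <- paste(records$key1, records$key2, sep = "||")
  qid <- paste(pairs$key1, pairs$key2, sep = "||")
  r1 <- pairs$region1[match(pid, qid)]
  r2 <- pairs$region2[match(pid, qid)]
  if (scope == "same_region") {
    sel <- !is.na(r1) & !is.na(r2) & r1 == r2
    if (!any(sel))
      return(data.frame(region = character(0), type = character(0),
                        count = integer(0)))
    tab <- table(region = r1[sel], type = records$type[sel])
  } else {
    sel <- !is.na(r1) & !is.na(r2) & r1 != r2
    if (!any(sel))
      return(data.frame(region = character(0), type = character(0),
                        count = integer(0)))
    rp <- paste(pmin(r1[sel], r2[sel]), pmax(r1[sel], r2[sel]), sep = "x")
    tab <- table(region = rp, type = records$type[sel])
  }
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("region", "type", "count")
  out[out$count > 0, ]
}

#' Mean interaction count per capable pair
#'
#' The average number of interactions of one type formed by residue pairs
#' that are chemically capable of forming it and located in a given region
#' (both residues in that region). Capable candidate pairs that form no
#' interaction contribute zeros to the mean. For binary interaction types
#' the mean is a proportion and the uncertainty is a 95% Wilson score
#' interval; for count-valued types a Student-t interval on the mean is
#' reported.
#'
#' @param records interaction records.
#' @param candidates candidate pairs (from [detect_all()]'s `candidates`).
#' @param regions data.frame from [region_assignments()], or NULL to ignore
#'   regions.
#' @param type interaction type.
#' @param region consensus region required for both residues (ignored when
#'   `regions` is NULL).
#' @param cap capability table.
#' @param binary logical; treat the type as binary presence/absence.
#'   Defaults to TRUE for all types except vdw, hbond, sse_hbond and c_bond,
#'   which are count-valued.
#' @param conf confidence level (default 0.95).
#' @return list(mean, lo, hi, n_capable, n_interacting) or NULL when no
#'   capable pair exists.
#' @export
mean_count_per_pair <- function(records, candidates, regions = NULL,
                                type = "hbond", region = NULL,
                                cap = capability_table(),
                                binary = NULL, conf = 0.95) {
  if (is.null(binary))
    binary <- !type %in% c("vdw", "hbond", "sse_hbond", "c_bond")
  capable <- mapply(function(r1, r2) pair_capable(type, r1, r2, cap),
                    candidates$res1, candidates$res2)
  sel <- capable
  if (!is.null(regions) && !is.null(region)) {
    reg1 <- regions$region[match(candidates$key1, regions$key)]
    reg2 <- regions$region[match(candidates$key2, regions$key)]
    sel <- sel & !is.na(reg1) & !is.na(reg2) & reg1 == region & reg2 == region
  }
  if (!any(sel)) return(NULL)
  cid <- paste(candidates$key1, candidates$key2, sep = "||")[sel]
  counts <- rep(0L, length(cid))
  if (nrow(records) > 0) {
    rsel <- records$type == type
    rid <- paste(records$key1[rsel], records$key2[rsel], sep = "||")
    tt <- table(rid)
    hit <- match(names(tt), cid)
    ok <- !is.na(hit)
    counts[hit[ok]] <- as.integer(tt[ok])
  }
  n <- length(counts)
  if (binary) {
    x <- sum(counts > 0)
    ci <- wilson_interval(x, n, conf)
    list(mean = x / n, lo = unname(ci[1]), hi = unname(ci[2]), n_capable = n,
         n_interacting = x, binary = TRUE)
  } else {
    m <- mean(counts)
    se <- stats::sd(counts) / sqrt(n)
    tq <- if (n > 1) stats::qt(1 - (1 - conf) / 2, df = n - 1) else NA_real_
    list(mean = m, lo = m - tq * se, hi = m + tq * se, n_capable = n,
         n_interacting = sum(counts > 0), binary = FALSE)
  }
}

#' Scaling of interacting-pair counts with buried surface area
#'
#' For each complex, the weighted number of interacting pairs in a region is
#' related to that region's buried surface area. Pairs whose two residues
#' belong to the same region are counted twice, as they cross the region's
#' buried surface once per protein chain; the rim and rim-NIS labels are
#' merged for this analysis.
#'
#' @param complex_data list of per-complex lists with elements `pairs`
#'   (pair records with regions) and `bsa_by_region` (named vector).
#' @param region one of "core", "support", "rim" (rim = rim_interacting +
#'   rim_nis merged).
#' @return list with `points` (data.frame x = BSA, y = weighted pair count,
#'   one row per complex) and `fit` (lm summary: slope, intercept,
#'   r_squared, p_value) or NULL fit when fewer than 2 points.
#' @export
pair_bsa_scaling <- function(complex_data, region = c("core", "support",
                                                      "rim")) {
  region <- match.arg(region)
  merge_rim <- function(r) ifelse(r %in% c("rim_interacting", "rim_nis"),
                                  "rim", r)
  pts <- lapply(complex_data, function(cd) {
    r1 <- merge_rim(cd$pairs$region1)
    r2 <- merge_rim(cd$pairs$region2)
    y <- 2 * sum(!is.na(r1) & !is.na(r2) & r1 == region & r2 == region)
    bsa <- cd$bsa_by_region
    x <- if (region == "rim")
      sum(bsa[c("rim_interacting", "rim_nis")], na.rm = TRUE)
    else unname(bsa[region])
    data.frame(x = ifelse(is.na(x), 0, x), y = y)
  })
  points <- do.call(rbind, pts)
  fit <- NULL
  if (nrow(points) >= 2 && stats::var(points$x) > 0) {
    lmfit <- stats::lm(y ~ x, data = points)
    # tiny or exactly collinear ensembles trip the perfect-fit warning;
    # the fit itself is still well-defined
    sm <- suppressWarnings(summary(lmfit))
    fit <- list(slope = unname(stats::coef(lmfit)[2]),
                intercept = unname(stats::coef(lmfit)[1]),
                r_squared = sm$r.squared,
                p_value = sm$coefficients[2, 4])
  }
  list(points = points, fit = fit)
}
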