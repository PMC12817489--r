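# ---------------------------------------------------------------------------
# Dataset pipeline: per-complex orchestration over a manifest, binding
# affinity based stability classification, and dataset-level aggregation.
# ---------------------------------------------------------------------------

#' Pipeline run configuration
#'
#' @param thresholds region thresholds ([region_thresholds()]).
#' @param geometry detector thresholds ([geometry_config()]).
#' @param scales MaxASA scale set ([maxasa_scales()]).
#' @param stability_cuts c(transient, stable) log10-affinity cutoffs
#'   (default -6, -9): affinities above the first are transient, below the
#'   second stable, in between intermediate.
#' @param probe_radius,n_points SASA parameters.
#' @param seed base seed for the stochastic aggregation statistics.
#' @return named list.
#' @export
run_config <- function(thresholds = region_thresholds(),
                       geometry = geometry_config(),
                       scales = maxasa_scales(),
                       stability_cuts = c(transient = -6, stable = -9),
                       probe_radius = 1.4, n_points = 960, seed = 1) {
  stopifnot(stability_cuts[1] > stability_cuts[2])
  list(thresholds = thresholds, geometry = geometry, scales = scales,
       stability_cuts = stability_cuts, probe_radius = probe_radius,
       n_points = n_points, seed = seed)
}

#' Classify a complex as stable, intermediate or transient
#'
#' Binding affinity is log10(Affinity) with the affinity a KD, IC50 or Ki in
#' molar units. Values above the transient cutoff (-6, i.e. weaker than
#' 1 uM) are transient, values below the stable cutoff (-9, stronger than
#' 1 nM) are stable, and everything in between — including the boundary
#' values themselves — is intermediate.
#'
#' @param log10_affinity numeric (vectorized).
#' @param cuts c(transient, stable) cutoffs.
#' @return character vector of labels.
#' @export
classify_stability <- function(log10_affinity,
                               cuts = c(transient = -6, stable = -9)) {
  if (any(!is.finite(log10_affinity))) stop("non-finite affinity")
  unname(ifelse(log10_affinity > cuts[1], "transient",
                ifelse(log10_affinity < cuts[2], "stable", "intermediate")))
}

#' Convert a manifest affinity to log10 molar units
#'
#' @param value affinity value (KD/IC50/Ki).
#' @param unit one of "M", "mM", "uM", "nM", "pM" (default "M").
#' @return log10 of the molar affinity.
#' @export
log10_affinity <- function(value, unit = "M") {
  fac <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
  if (any(!unit %in% names(fac)))
    stop("unknown affinity unit: ", paste(setdiff(unit, names(fac)),
                                          collapse = ", "))
  unname(log10(value * fac[unit]))
}

#' Read a complex manifest
#'
#' Tab-separated table with columns: structure_id, path, group_a, group_b
#' (chain ids, comma-separated within a group), affinity, affinity_kind
#' (KD/IC50/Ki), affinity_unit. Adds log10_affinity and the stability label.
#'
#' @param path manifest TSV.
#' @param cuts stability cutoffs.
#' @return data.frame, one row per complex.
#' @export
read_manifest <- function(path, cuts = c(transient = -6, stable = -9)) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("structure_id", "path", "group_a", "group_b", "affinity",
            "affinity_kind", "affinity_unit")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0)
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  m$log10_affinity <- unname(log10_affinity(m$affinity, m$affinity_unit))
  m$stability <- classify_stability(m$log10_affinity, cuts)
  m
}

#' Process one complex end to end
#'
#' load -> standardize -> split -> SASA/regions -> interaction detection ->
#' per-complex metrics.
#'
#' @param path structure file (PDB or mmCIF), or an already loaded
#'   `structure_model`.
#' @param group_a,group_b chain-id vectors.
#' @param config a [run_config()].
#' @param structure_id identifier for reporting.
#' @return a `complex_summary` list: structure_id, regions, records, pairs,
#'   candidates, bsa (from [buried_surface_area()]), region_counts (residues
#'   per region), interaction counts by region.
#' @export
run_complex <- function(path, group_a, group_b, config = run_config(),
                        structure_id = NULL) {
  model <- if (inherits(path, "structure_model")) path
           else load_structure(path, structure_id = structure_id)
  if (is.null(structure_id)) structure_id <- model$structure_id
  model <- standardize_residues(model)
  split <- split_complex(model, group_a, group_b)
  regions <- region_assignments(split, scales = config$scales,
                                t = config$thresholds,
                                probe_radius = config$probe_radius,
                                n_points = config$n_points)
  det <- detect_all(split$complex, cfg = config$geometry, regions = regions,
                    scope = "inter_chain")
  bsa <- buried_surface_area(regions)
  same_counts <- count_interactions_by_region(det$records, det$pairs,
                                              "same_region")
  structure(list(
    structure_id = structure_id,
    regions = regions,
    records = det$records,
    pairs = det$pairs,
    candidates = det$candidates,
    bsa = bsa,
    region_counts = table(factor(regions$region, levels = REGION_LABELS)),
    same_region_counts = same_counts
  ), class = "complex_summary")
}

#' @export
print.complex_summary <- function(x, ...) {
  cat("complex_summary", x$structure_id, "\n")
  cat("  residues by region:\n")
  print(x$region_counts)
  cat("  interface BSA:", round(x$bsa$total, 1), "A^2;",
      nrow(x$pairs), "interacting pair(s),",
      nrow(x$records), "interaction record(s)\n")
  invisible(x)
}

#' Run the pipeline over a manifest
#'
#' Per-complex failures are quarantined (recorded with their error message)
#' rather than aborting the run.
#'
#' @param manifest data.frame from [read_manifest()].
#' @param config a [run_config()].
#' @param verbose print per-complex progress.
#' @return list(summaries — named list of `complex_summary`, failures —
#'   named character of error messages, manifest).
#' @export
run_manifest <- function(manifest, config = run_config(), verbose = FALSE) {
  summaries <- list()
  failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$structure_id[i]
    if (verbose) message("processing ", id)
    res <- tryCatch(
      run_complex(manifest$path[i],
                  strsplit(manifest$group_a[i], ",")[[1]],
                  strsplit(manifest$group_b[i], ",")[[1]],
                  config, structure_id = id),
      error = function(e) e)
    if (inherits(res, "error")) failures[id] <- conditionMessage(res)
    else summaries[[id]] <- res
  }
  list(summaries = summaries, failures = failures, manifest = manifest)
}

#' Aggregate per-complex summaries into dataset tables
#'
#' @param run result of [run_manifest()].
#' @param config a [run_config()].
#' @return list with: `stability_counts`; `bsa_fractions` (mean interface
#'   BSA share per region, by stability group); `scaling` (pair-count vs
#'   BSA OLS fits per region over the dataset); `diversity` (per-group
#'   entropy/evenness of interface pair classes); `pmi` (region- and
#'   group-resolved PMI tables for core+support, rim, and interior pooled
#'   over the whole dataset).
#' @export
aggregate_dataset <- function(run, config = run_config()) {
  summaries <- run$summaries
  if (length(summaries) == 0) stop("no successful complexes to aggregate")
  man <- run$manifest
  stab <- stats::setNames(man$stability, man$structure_id)
  stab <- stab[names(summaries)]
  stability_counts <- table(factor(stab, levels = c("stable", "intermediate",
                                                    "transient")))
  # mean BSA fraction per region within each stability group
  frac_mat <- t(vapply(summaries, function(s) {
    f <- s$bsa$fractions[INTERFACE_REGIONS]
    stats::setNames(ifelse(is.na(f), 0, f), INTERFACE_REGIONS)
  }, numeric(4)))
  bsa_fractions <- lapply(split(as.data.frame(frac_mat), stab),
                          function(d) colMeans(as.matrix(d)))
  # pair count vs BSA scaling per region
  complex_data <- lapply(summaries, function(s)
    list(pairs = s$pairs, bsa_by_region = s$bsa$by_region))
  scaling <- lapply(c(core = "core", support = "support", rim = "rim"),
                    function(r) pair_bsa_scaling(complex_data, r))
  # diversity of interface pair classes per stability group
  groups <- stab[stab %in% c("stable", "transient")]
  diversity <- NULL
  if (length(groups) > 0) {
    diversity <- do.call(rbind, lapply(unique(groups), function(g) {
      ids <- names(groups)[groups == g]
      pooled <- do.call(rbind, lapply(summaries[ids], function(s) s$pairs))
      fr <- pair_class_frequencies(pooled)
      H <- if (length(fr$pair_freq) > 0) shannon_entropy(fr$pair_freq) else NA
      data.frame(group = g, H = H,
                 H_max = log2(length(all_pair_classes())),
                 J = if (is.na(H)) NA
                     else evenness(H, length(all_pair_classes())),
                 n_complexes = length(ids))
    }))
  }
  # PMI: core+support and rim for stable/transient; interior from everything
  complex_pairs <- lapply(summaries, function(s) s$pairs)
  pmi_tables <- list()
  if (length(groups) > 0 && length(unique(groups)) >= 1) {
    pmi_tables$core_support <- region_pmi_analysis(
      complex_pairs, groups, region_set = c("core", "support"))
    pmi_tables$rim <- region_pmi_analysis(
      complex_pairs, groups, region_set = c("rim_interacting", "rim_nis"))
  }
  list(stability_counts = stability_counts, bsa_fractions = bsa_fractions,
       scaling = scaling, diversity = diversity, pmi = pmi_tables)
}
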