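# ---------------------------------------------------------------------------
# Diversity and co-occurrence statistics of interacting pair classes:
# Shannon entropy and evenness, tf-idf filtering, pointwise mutual
# information, plus the generic uncertainty tools (Wilson interval,
# probability of superiority, bootstrap confidence intervals).
# ---------------------------------------------------------------------------

#' Shannon entropy of a frequency vector
#'
#' `H = -sum f log2 f`, in bits; zero entries contribute nothing.
#'
#' @param freqs non-negative frequencies summing to 1 (within `tol`).
#' @param tol tolerance on the sum (default 1e-6).
#' @return entropy in bits.
#' @export
shannon_entropy <- function(freqs, tol = 1e-6) {
  if (any(freqs < 0)) stop("negative frequency")
  if (abs(sum(freqs) - 1) > tol) stop("frequencies must sum to 1")
  nz <- freqs[freqs > 0]
  -sum(nz * log2(nz))
}

#' Evenness index
#'
#' `J = H / Hmax` with `Hmax = log2(k)`: the entropy of the pair-class
#' distribution normalized by the maximum attainable with `k` classes. The
#' degenerate single-class case (k = 1, H = 0) is defined as perfectly even
#' (J = 1).
#'
#' @param H entropy in bits.
#' @param k number of possible classes (>= 1).
#' @param tol tolerance for the impossible-input check H > log2(k).
#' @return J in [0, 1].
#' @export
evenness <- function(H, k, tol = 1e-9) {
  stopifnot(k >= 1, H >= 0)
  if (k == 1) {
    if (H > tol) stop("H > 0 impossible with a single class")
    return(1)
  }
  hmax <- log2(k)
  if (H > hmax + tol) stop("H exceeds log2(k)")
  H / hmax
}

#' tf-idf filter over pair types
#'
#' Treats each structure as a document and each pair type as a term:
#' `tfidf(t) = tf(t) * ln(N / df(t))` with tf the total count of the type
#' across the dataset, N the number of structures and df the number of
#' structures containing the type. Types whose tf-idf falls below the
#' threshold — notably types confined to few structures, and ubiquitous
#' types whose idf vanishes — are flagged removed.
#'
#' @param counts matrix or data.frame, structures x pair types, raw counts.
#' @param threshold retention threshold (default 1).
#' @return data.frame: pair_type, tf, df, tfidf, retained.
#' @export
tfidf_filter <- function(counts, threshold = 1) {
  counts <- as.matrix(counts)
  if (length(counts) == 0 || ncol(counts) == 0)
    return(data.frame(pair_type = character(0), tf = numeric(0),
                      df = integer(0), tfidf = numeric(0),
                      retained = logical(0)))
  n_struct <- nrow(counts)
  tf <- colSums(counts)
  df <- colSums(counts > 0)
  tfidf <- ifelse(df > 0, tf * log(n_struct / df), 0)
  data.frame(pair_type = colnames(counts), tf = unname(tf),
             df = unname(df), tfidf = unname(tfidf),
             retained = unname(tfidf >= threshold),
             stringsAsFactors = FALSE)
}

#' Pointwise mutual information of an interacting pair class
#'
#' Compares the observed frequency of a pair class with its independence
#' baseline. For a homogeneous pair (both residues of the same class) the
#' baseline is `f1 * f2`; for a heterogeneous pair the two orderings make
#' the baseline `2 * f1 * f2`:
#' `PMI = log2(f_pair / (f1 * f2))` or `log2(f_pair / (2 f1 f2))`.
#'
#' @param pair_freq frequency of the pair class, in (0, 1].
#' @param f1,f2 marginal frequencies of the two residue classes.
#' @param homogeneous logical.
#' @return PMI in bits; NA (missing) when any frequency is zero.
#' @export
pmi <- function(pair_freq, f1, f2, homogeneous) {
  if (any(c(pair_freq, f1, f2) < 0) || any(c(pair_freq, f1, f2) > 1))
    stop("frequencies must lie in [0, 1]")
  if (pair_freq == 0 || f1 == 0 || f2 == 0) return(NA_real_)
  base <- if (homogeneous) f1 * f2 else 2 * f1 * f2
  log2(pair_freq / base)
}

#' Pair-class and residue-class frequencies of one complex
#'
#' @param pairs pair records (with `res1`, `res2`), typically restricted to
#'   one region beforehand.
#' @param class_map from [pair_class_map()].
#' @return list(pair_freq  — named over observed pair classes, summing to 1;
#'   residue_freq — named over residue classes from the pair members).
#' @export
pair_class_frequencies <- function(pairs, class_map = pair_class_map()) {
  if (nrow(pairs) == 0)
    return(list(pair_freq = numeric(0), residue_freq = numeric(0)))
  c1 <- class_map[canonical_resname(pairs$res1)]
  c2 <- class_map[canonical_resname(pairs$res2)]
  pc <- pair_class_label(c1, c2)
  pair_freq <- table(pc) / length(pc)
  residue_freq <- table(c(c1, c2)) / (2 * length(pc))
  list(pair_freq = c(unclass(pair_freq)),
       residue_freq = c(unclass(residue_freq)))
}

#' Region- and group-resolved PMI analysis
#'
#' For each group of complexes (e.g., stable vs transient) and each region
#' grouping, per-complex pair-class and residue-class frequencies are
#' averaged across complexes (mean of frequencies, not pooled counts) and
#' the PMI of every pair class is computed from these means. Pair types are
#' first screened with the tf-idf filter; filtered cells are flagged and
#' carry no PMI. The core and support are analyzed together; interior
#' values are derived from the whole dataset.
#'
#' @param complex_pairs named list: complex id -> pair records (with
#'   regions).
#' @param groups named character: complex id -> group label; complexes with
#'   NA group are skipped.
#' @param region_set character vector of consensus regions pooled for this
#'   analysis (e.g., `c("core", "support")`).
#' @param class_map from [pair_class_map()].
#' @param tfidf_threshold passed to [tfidf_filter()].
#' @return data.frame per group: group, pair_class, pair_freq, f1, f2,
#'   homogeneous, pmi, tfidf, retained.
#' @export
region_pmi_analysis <- function(complex_pairs, groups,
                                region_set = c("core", "support"),
                                class_map = pair_class_map(),
                                tfidf_threshold = 1) {
  groups <- groups[!is.na(groups)]
  if (length(groups) == 0) stop("no complexes with a group label")
  out <- list()
  for (grp in unique(groups)) {
    ids <- names(groups)[groups == grp]
    sub <- lapply(complex_pairs[ids], function(p)
      p[!is.na(p$region1) & !is.na(p$region2) &
          p$region1 %in% region_set & p$region2 %in% region_set, ,
        drop = FALSE])
    if (length(sub) == 0) stop("group has zero complexes: ", grp)
    freqs <- lapply(sub, pair_class_frequencies, class_map = class_map)
    pcs <- all_pair_classes()
    rcs <- sort(PAIR_CLASSES)
    pair_mat <- t(vapply(freqs, function(f) {
      v <- stats::setNames(rep(0, length(pcs)), pcs)
      v[names(f$pair_freq)] <- f$pair_freq
      v
    }, numeric(length(pcs))))
    res_mat <- t(vapply(freqs, function(f) {
      v <- stats::setNames(rep(0, length(rcs)), rcs)
      v[names(f$residue_freq)] <- f$residue_freq
      v
    }, numeric(length(rcs))))
    used <- vapply(sub, nrow, integer(1)) > 0
    if (!any(used)) next
    mean_pair <- colMeans(pair_mat[used, , drop = FALSE])
    mean_res <- colMeans(res_mat[used, , drop = FALSE])
    # tf-idf over raw per-structure counts of each pair class
    count_mat <- t(vapply(sub, function(p) {
      f <- pair_class_frequencies(p, class_map)
      v <- stats::setNames(rep(0, length(pcs)), pcs)
      v[names(f$pair_freq)] <- f$pair_freq * max(1, nrow(p))
      v
    }, numeric(length(pcs))))
    filt <- tfidf_filter(count_mat, tfidf_threshold)
    for (pc in pcs) {
      parts <- strsplit(pc, "-", fixed = TRUE)[[1]]
      homog <- parts[1] == parts[2]
      retained <- filt$retained[filt$pair_type == pc]
      val <- if (isTRUE(retained) && mean_pair[pc] > 0 &&
                 mean_res[parts[1]] > 0 && mean_res[parts[2]] > 0)
        pmi(mean_pair[pc], mean_res[parts[1]], mean_res[parts[2]], homog)
      else NA_real_
      out[[length(out) + 1]] <- data.frame(
        group = grp, pair_class = pc, pair_freq = unname(mean_pair[pc]),
        f1 = unname(mean_res[parts[1]]), f2 = unname(mean_res[parts[2]]),
        homogeneous = homog, pmi = val,
        tfidf = filt$tfidf[filt$pair_type == pc],
        retained = isTRUE(retained), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes,n counts, `0 <= successes <= n`, `n >= 1`.
#' @param confidence confidence level (default 0.95).
#' @return c(lo, hi), clipped to [0, 1].
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  if (n < 1 || successes < 0 || successes > n)
    stop("invalid counts: ", successes, "/", n)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lo = max(0, center - half), hi = min(1, center + half))
}

#' Probability of superiority
#'
#' Nonparametric effect size `P(X > Y) + 0.5 P(X = Y)` over all cross
#' pairs of the two samples.
#'
#' @param xs,ys non-empty numeric samples.
#' @return fraction in [0, 1].
#' @export
probability_of_superiority <- function(xs, ys) {
  if (length(xs) == 0 || length(ys) == 0) stop("empty sample")
  cmp <- outer(xs, ys, ">") + 0.5 * outer(xs, ys, "==")
  mean(cmp)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the dataset units (complexes) with replacement and reports the
#' percentile interval of the statistic. Deterministic for a fixed seed.
#'
#' @param statistic function(dataset_subset) -> scalar.
#' @param dataset list or vector of resampling units (length >= 2).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param confidence confidence level (default 0.95).
#' @return list(lo, hi, estimate, degenerate) — degenerate is TRUE when the
#'   statistic is constant over replicates (zero-width interval).
#' @export
bootstrap_ci <- function(statistic, dataset, n_boot = 1000, seed = 1,
                         confidence = 0.95) {
  n <- if (is.data.frame(dataset)) nrow(dataset) else length(dataset)
  if (n < 2) stop("dataset must contain at least 2 units")
  pick <- function(idx) {
    if (is.data.frame(dataset)) dataset[idx, , drop = FALSE]
    else dataset[idx]
  }
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    statistic(pick(sample.int(n, n, replace = TRUE)))
  }, numeric(1))
  alpha <- (1 - confidence) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(lo = qs[1], hi = qs[2], estimate = statistic(pick(seq_len(n))),
       degenerate = qs[1] == qs[2])
}
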