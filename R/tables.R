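#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Reference tables: amino-acid classification, MaxASA scales, vdW radii,
# pair-class map and interaction capability predicates.
# ---------------------------------------------------------------------------

#' Standard amino acids handled by the package
#'
#' Twenty standard residues plus selenomethionine (MSE) and selenocysteine
#' (SEC), which are retained because their selenium atom participates in
#' chalcogen and S/Se-mediated interactions.
#' @export
STANDARD_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC"
)

# Map the seleno variants onto their sulfur parents for classification.
canonical_resname <- function(resname) {
  out <- resname
  out[out == "MSE"] <- "MET"
  out[out == "SEC"] <- "CYS"
  out
}

#' Physicochemical classification of the 20 standard amino acids
#'
#' One row per residue with the class labels used throughout the
#' region-composition and partitioning analyses, following the IMGT
#' physicochemical classes (Pommie et al. 2004, J Mol Recognit):
#' \describe{
#'   \item{charge}{positive (ARG, LYS, HIS), negative (ASP, GLU), neutral.}
#'   \item{polarity}{polar / apolar side chain.}
#'   \item{hydropathy}{hydrophobic, neutral or hydrophilic.}
#'   \item{aromatic, aliphatic}{ring-bearing (PHE, TRP, TYR, HIS) and
#'     branched-chain (ALA, ILE, LEU, VAL) flags.}
#'   \item{sidechain_hbond}{TRUE when the side chain can donate or accept a
#'     hydrogen bond.}
#' }
#' Note that tyrosine is polar with neutral hydropathy.
#'
#' @return A data.frame keyed by 3-letter residue name.
#' @export
residue_class_table <- function() {
  res <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
           "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
  positive <- c("ARG", "LYS", "HIS")
  negative <- c("ASP", "GLU")
  polar <- c("ARG", "ASN", "ASP", "GLN", "GLU", "HIS", "LYS", "SER", "THR", "TYR")
  hydrophobic <- c("ALA", "CYS", "PHE", "ILE", "LEU", "MET", "VAL", "TRP")
  hydrophilic <- c("ARG", "ASN", "ASP", "GLN", "GLU", "LYS")
  aromatic <- c("PHE", "TRP", "TYR", "HIS")
  aliphatic <- c("ALA", "ILE", "LEU", "VAL")
  sc_hbond <- c("ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "HIS", "LYS",
                "SER", "THR", "TRP", "TYR")
  data.frame(
    resname = res,
    charge = ifelse(res %in% positive, "positive",
                    ifelse(res %in% negative, "negative", "neutral")),
    polarity = ifelse(res %in% polar, "polar", "apolar"),
    hydropathy = ifelse(res %in% hydrophobic, "hydrophobic",
                        ifelse(res %in% hydrophilic, "hydrophilic", "neutral")),
    aromatic = res %in% aromatic,
    aliphatic = res %in% aliphatic,
    sidechain_hbond = res %in% sc_hbond,
    stringsAsFactors = FALSE
  )
}

#' Simplified pair-class map based on charge and polarity
#'
#' Collapses the 20 residues into four classes: charged residues keep their
#' charge sign (positive, negative) and the remainder split by side-chain
#' polarity (polar, apolar). Interacting pairs are then described by the
#' unordered pair of classes (10 possible pair classes).
#'
#' @return Named character vector: residue name -> class.
#' @export
pair_class_map <- function() {
  tab <- residue_class_table()
  cls <- ifelse(tab$charge != "neutral", tab$charge, tab$polarity)
  stats::setNames(cls, tab$resname)
}

#' The four simplified residue classes
#' @export
PAIR_CLASSES <- c("positive", "negative", "polar", "apolar")

#' Unordered pair-class label
#'
#' @param c1,c2 class labels from [pair_class_map()].
#' @return Canonical "a-b" label with classes sorted alphabetically.
#' @export
pair_class_label <- function(c1, c2) {
  paste(pmin(c1, c2), pmax(c1, c2), sep = "-")
}

#' All 10 unordered pair classes
#' @export
all_pair_classes <- function() {
  cl <- sort(PAIR_CLASSES)
  out <- character(0)
  for (i in seq_along(cl))
    for (j in i:length(cl))
      out <- c(out, paste(cl[i], cl[j], sep = "-"))
  out
}

#' Maximum accessible surface area scales
#'
#' Three published per-residue maximum ASA scales used to normalize residue
#' ASA into relative ASA (rASA): the theoretical Gly-X-Gly scale of Tien et
#' al. (2013, PLoS ONE), their empirical scale derived from observed
#' structures, and the empirical scale of Miller et al. (1987, J Mol Biol).
#' The region consensus vote runs the rASA classification once per scale.
#'
#' @return Named list of named numeric vectors (Angstrom^2), one value per
#'   standard residue.
#' @export
maxasa_scales <- function() {
  res <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
           "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
  tien_theoretical <- c(129.0, 274.0, 195.0, 193.0, 167.0, 225.0, 223.0, 104.0,
                        224.0, 197.0, 201.0, 236.0, 224.0, 240.0, 159.0, 155.0,
                        172.0, 285.0, 263.0, 174.0)
  tien_empirical <- c(121.0, 265.0, 187.0, 187.0, 148.0, 214.0, 214.0, 97.0,
                      216.0, 195.0, 191.0, 230.0, 203.0, 228.0, 154.0, 143.0,
                      163.0, 264.0, 255.0, 165.0)
  miller <- c(113.0, 241.0, 158.0, 151.0, 140.0, 189.0, 183.0, 85.0, 194.0,
              182.0, 180.0, 211.0, 204.0, 218.0, 143.0, 122.0, 146.0, 259.0,
              229.0, 160.0)
  list(
    tien_theoretical = stats::setNames(tien_theoretical, res),
    tien_empirical = stats::setNames(tien_empirical, res),
    miller_empirical = stats::setNames(miller, res)
  )
}

#' Van der Waals radii by element
#'
#' Bondi (1964) radii for the elements found in protein structures. Used by
#' the Shrake-Rupley surface calculation and the van der Waals contact
#' detector.
#'
#' @return Named numeric vector, Angstrom.
#' @export
vdw_radii <- function() {
  c(N = 1.55, C = 1.70, O = 1.52, S = 1.80, SE = 1.90, H = 1.20, P = 1.80)
}

# Interaction types reported by the detectors.
#' The 19 reported interaction types
#' @export
INTERACTION_TYPES <- c(
  "n_pi_star", "c_bond", "chalcogen", "sse_hbond", "hbond", "h_pi",
  "aromatic_aromatic", "amino_pi", "aromatic_sse", "aromatic_cation",
  "aromatic_anion", "salt_bridge", "vdw", "hydrophobic", "arg_arg_stacking",
  "charge_clash", "charge_repulsion", "hydrophobic_hydrophilic_clash",
  "hydrophobic_hydrophilic_repulsion"
)

#' Interaction capability table
#'
#' For every interaction type, a predicate deciding whether an unordered
#' residue-name pair is chemically capable of forming that interaction.
#' This defines the denominator of the mean-count-per-capable-pair
#' statistic: a capable pair that forms no interaction still counts as an
#' observation of zero.
#'
#' Backbone-mediated types (hydrogen bond, n->pi*, C-bond, van der Waals)
#' are open to every residue pair; side-chain-specific types are restricted
#' by the classification table (e.g., only ARG-ARG can arginine-stack, salt
#' bridges need opposite formal charges, aromatic types need a ring).
#'
#' @param his_cation logical; treat HIS as a cation (default TRUE).
#' @return Named list of functions `f(res1, res2) -> logical`.
#' @export
capability_table <- function(his_cation = TRUE) {
  tab <- residue_class_table()
  rownames(tab) <- tab$resname
  cls <- function(r) tab[canonical_resname(r), , drop = FALSE]
  cations <- if (his_cation) c("ARG", "LYS", "HIS") else c("ARG", "LYS")
  anions <- c("ASP", "GLU")
  sse <- c("CYS", "MET")
  arom <- c("PHE", "TRP", "TYR", "HIS")
  has <- function(r, set) canonical_resname(r) %in% set
  one_each <- function(r1, r2, set1, set2) {
    (has(r1, set1) && has(r2, set2)) || (has(r2, set1) && has(r1, set2))
  }
  always <- function(r1, r2) TRUE
  hydrophobe <- tab$resname[tab$hydropathy == "hydrophobic"]
  hydrophile <- tab$resname[tab$hydropathy == "hydrophilic"]
  like_charged <- function(r1, r2) {
    (has(r1, cations) && has(r2, cations)) || (has(r1, anions) && has(r2, anions))
  }
  list(
    n_pi_star = always,
    c_bond = always,
    chalcogen = function(r1, r2) has(r1, sse) || has(r2, sse),
    sse_hbond = function(r1, r2) has(r1, sse) || has(r2, sse),
    hbond = always,
    h_pi = function(r1, r2) has(r1, arom) || has(r2, arom),
    aromatic_aromatic = function(r1, r2) has(r1, arom) && has(r2, arom),
    amino_pi = function(r1, r2) one_each(r1, r2, c("ASN", "GLN"), arom),
    aromatic_sse = function(r1, r2) one_each(r1, r2, sse, arom),
    aromatic_cation = function(r1, r2) one_each(r1, r2, cations, arom),
    aromatic_anion = function(r1, r2) one_each(r1, r2, anions, arom),
    salt_bridge = function(r1, r2) one_each(r1, r2, cations, anions),
    vdw = always,
    hydrophobic = function(r1, r2) has(r1, hydrophobe) && has(r2, hydrophobe),
    arg_arg_stacking = function(r1, r2) {
      canonical_resname(r1) == "ARG" && canonical_resname(r2) == "ARG"
    },
    charge_clash = like_charged,
    charge_repulsion = like_charged,
    hydrophobic_hydrophilic_clash = function(r1, r2) {
      one_each(r1, r2, hydrophobe, hydrophile)
    },
    hydrophobic_hydrophilic_repulsion = function(r1, r2) {
      one_each(r1, r2, hydrophobe, hydrophile)
    }
  )
}

#' Test whether a residue pair is capable of an interaction type
#'
#' @param type interaction type name.
#' @param res1,res2 3-letter residue names.
#' @param cap table from [capability_table()].
#' @return logical.
#' @export
pair_capable <- function(type, res1, res2, cap = capability_table()) {
  if (!type %in% names(cap)) stop("unknown interaction type: ", type)
  cap[[type]](res1, res2)
}
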