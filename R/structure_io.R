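# ---------------------------------------------------------------------------
# Structure input: PDB/mmCIF reading, normalization into the internal model,
# and splitting of complexes into monomer and complex contexts.
# ---------------------------------------------------------------------------

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT",
                    "H", "H1", "H2", "H3", "HA", "HA2", "HA3")

# Heavy side-chain + backbone atoms expected for each residue type; used to
# flag incomplete residues.
expected_heavy_atoms <- function(resname) {
  bb <- c("N", "CA", "C", "O")
  sc <- switch(canonical_resname(resname),
    ALA = "CB",
    ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
    ASN = c("CB", "CG", "OD1", "ND2"),
    ASP = c("CB", "CG", "OD1", "OD2"),
    CYS = c("CB", "SG"),
    GLN = c("CB", "CG", "CD", "OE1", "NE2"),
    GLU = c("CB", "CG", "CD", "OE1", "OE2"),
    GLY = character(0),
    HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
    ILE = c("CB", "CG1", "CG2", "CD1"),
    LEU = c("CB", "CG", "CD1", "CD2"),
    LYS = c("CB", "CG", "CD", "CE", "NZ"),
    MET = c("CB", "CG", "SD", "CE"),
    PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    PRO = c("CB", "CG", "CD"),
    SER = c("CB", "OG"),
    THR = c("CB", "OG1", "CG2"),
    TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
    VAL = c("CB", "CG1", "CG2"),
    stop("no atom template for residue ", resname)
  )
  c(bb, sc)
}

residue_key <- function(chain, resno, insert) {
  ins <- ifelse(is.na(insert) | insert == "", "", as.character(insert))
  paste(chain, resno, ins, sep = ":")
}

new_structure_model <- function(structure_id, atoms, provenance) {
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$insert,
                       method = "radix", na.last = FALSE), ]
  rownames(atoms) <- NULL
  structure(list(structure_id = structure_id, atoms = atoms,
                 provenance = provenance),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  rt <- model_residues(x)
  cat("structure_model", x$structure_id, "-",
      length(unique(rt$chain)), "chain(s),", nrow(rt), "residues,",
      nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Load a protein structure from PDB or mmCIF
#'
#' Reads a structure file, keeps amino-acid residues only (waters, ions and
#' other heteroatoms are dropped but counted in the provenance record), and
#' normalizes it into the package's internal model. For multi-model files
#' (NMR ensembles) only the first model is used; the model count is recorded.
#' Non-standard residues other than MSE/SEC are excluded with a warning.
#'
#' @param path file path.
#' @param format one of "auto", "pdb", "mmcif". "auto" decides from the file
#'   extension (.cif/.mmcif -> mmCIF, otherwise PDB).
#' @param structure_id identifier stored in the model; defaults to the file
#'   base name.
#' @return A `structure_model`: list with `structure_id`, an `atoms`
#'   data.frame (chain, resno, insert, resid, elety, element, x, y, z, o,
#'   alt, backbone) and a `provenance` list.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           structure_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (is.null(structure_id))
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  n_models <- tryCatch(nrow(as.matrix(parsed$xyz)), error = function(e) 1L)
  if (is.null(n_models) || is.na(n_models)) n_models <- 1L

  is_aa <- at$resid %in% STANDARD_RESIDUES
  n_hetero <- sum(!is_aa & at$type == "HETATM" & !at$resid %in% STANDARD_RESIDUES)
  nonstd <- setdiff(unique(at$resid[!is_aa & at$type == "ATOM"]), character(0))
  if (length(nonstd) > 0)
    warning("excluding non-standard residue(s): ",
            paste(nonstd, collapse = ", "))
  at <- at[is_aa, , drop = FALSE]
  if (nrow(at) == 0) stop("no protein chains found in ", path)

  element <- toupper(at$elesy)
  miss <- is.na(element) | element == ""
  if (any(miss)) # derive from the atom name: strip digits, take leading letters
    element[miss] <- substr(gsub("[^A-Za-z].*$", "",
                                 sub("^[0-9]*", "", at$elety[miss])), 1, 1)
  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    element = element,
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    stringsAsFactors = FALSE
  )
  atoms$backbone <- atoms$elety %in% BACKBONE_ATOMS
  new_structure_model(
    structure_id, atoms,
    provenance = list(format = format, model_index = 1L, n_models = n_models,
                      n_hetero_excluded = n_hetero, path = path)
  )
}

#' Standardize residues: single conformer per atom, completeness flags
#'
#' Alternate locations are collapsed to one conformer per atom: the
#' highest-occupancy conformer is kept, with ties broken by altloc character
#' order. Residues missing expected heavy atoms are flagged incomplete but
#' retained. The operation is idempotent.
#'
#' @param model a `structure_model`.
#' @return The standardized model; per-chain completeness fractions are
#'   stored in `provenance$chain_completeness`.
#' @export
standardize_residues <- function(model) {
  at <- model$atoms
  gid <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  # order so that the kept conformer (max occupancy, then altloc) comes first
  ord <- order(gid, -at$o, at$alt, method = "radix")
  at <- at[ord, ]
  keep <- !duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                            sep = "\r"))
  at <- at[keep, ]
  at$alt <- ""

  model$atoms <- at
  rt <- model_residues(model)
  model$provenance$chain_completeness <- tapply(rt$complete, rt$chain, mean)
  new_structure_model(model$structure_id, at, model$provenance)
}

#' Per-residue summary table of a structure model
#'
#' @param model a `structure_model`.
#' @return data.frame with key, chain, resno, insert, resname, n_atoms and a
#'   `complete` flag (all expected heavy atoms present).
#' @export
model_residues <- function(model) {
  at <- model$atoms
  key <- residue_key(at$chain, at$resno, at$insert)
  idx <- !duplicated(key)
  rt <- data.frame(
    key = key[idx], chain = at$chain[idx], resno = at$resno[idx],
    insert = at$insert[idx], resname = at$resid[idx],
    stringsAsFactors = FALSE
  )
  heavy <- at$element != "H"
  rt$n_atoms <- as.integer(table(factor(key, levels = rt$key)))
  rt$complete <- vapply(seq_len(nrow(rt)), function(i) {
    names_i <- at$elety[key == rt$key[i] & heavy]
    all(expected_heavy_atoms(rt$resname[i]) %in% names_i)
  }, logical(1))
  rt
}

#' Split a complex into its two monomers and the full complex
#'
#' Free-solution monomers are approximated by extracting the chains of each
#' group from the complex with their coordinates untouched.
#'
#' @param model a `structure_model` of the complex.
#' @param group_a,group_b disjoint, non-empty character vectors of chain ids.
#' @return list(monomer_a, monomer_b, complex) of `structure_model`s; the
#'   complex contains exactly the union of the two groups.
#' @export
split_complex <- function(model, group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("chain groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0)
    stop("chain groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  chains <- unique(model$atoms$chain)
  unknown <- setdiff(c(group_a, group_b), chains)
  if (length(unknown) > 0)
    stop("unknown chain id(s): ", paste(unknown, collapse = ", "))
  subset_chains <- function(ids, tag) {
    at <- model$atoms[model$atoms$chain %in% ids, , drop = FALSE]
    new_structure_model(paste0(model$structure_id, tag), at, model$provenance)
  }
  list(
    monomer_a = subset_chains(group_a, "_A"),
    monomer_b = subset_chains(group_b, "_B"),
    complex = subset_chains(c(group_a, group_b), "")
  )
}

#' Write the normalized atom table as TSV
#'
#' @param model a `structure_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_atom_table <- function(model, path) {
  utils::write.table(model$atoms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
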