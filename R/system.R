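# MolecularSystem: atoms + residue classification + orthorhombic box.
#
# Internally everything is stored in Angstrom (PDB convention); nm-valued
# parameters from the literature (0.5 nm contact shell, 0.2 nm voxels) are
# converted once at the user-facing argument boundary, never inside kernels.

.registry <- new.env(parent = emptyenv())
.registry$lipids <- c("POPC", "PSM", "CHL", "POPI", "POPE", "POPS", "LLPC")
.registry$solvent <- c("HOH", "SOL", "WAT", "TIP3", "TIP", "SPC")
.registry$ions <- c("K", "CL", "NA", "SOD", "CLA", "POT", "MG", "CAL", "ZN")

.amino3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HSD",
  "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR",
  "TRP", "TYR", "VAL"
)

#' Register additional lipid residue names
#'
#' The built-in registry covers the heterogeneous bilayer composition used
#' throughout this package (POPC, PSM, CHL, POPI, POPE, POPS, LLPC). Systems
#' with other lipid types can extend it.
#'
#' @param names character vector of residue names to classify as lipids.
#' @return invisibly, the updated lipid name vector.
#' @export
register_lipids <- function(names) {
  .registry$lipids <- union(.registry$lipids, toupper(names))
  invisible(.registry$lipids)
}

#' List registered lipid residue names
#' @return character vector.
#' @export
lipid_registry <- function() .registry$lipids

#' Classify a residue name
#'
#' @param resname character vector of residue names.
#' @return character vector with entries \code{"protein"},
#'   \code{"lipid:<type>"}, \code{"solvent"}, \code{"ion"} or
#'   \code{"unknown"}.
#' @export
classify_residue <- function(resname) {
  rn <- toupper(resname)
  out <- rep("unknown", length(rn))
  out[rn %in% .amino3] <- "protein"
  is_lip <- rn %in% .registry$lipids
  out[is_lip] <- paste0("lipid:", rn[is_lip])
  out[rn %in% .registry$solvent] <- "solvent"
  out[rn %in% .registry$ions] <- "ion"
  out
}

#' Construct a MolecularSystem
#'
#' @param atoms data.frame with columns \code{id} (integer atom serial),
#'   \code{name} (atom name), \code{resid} (1-based residue id),
#'   \code{resname}, \code{chain}, \code{x}, \code{y}, \code{z} (Angstrom),
#'   and optionally \code{element} and \code{mass} (amu; derived from the
#'   element when absent).
#' @param box numeric length-3: orthorhombic box lengths Lx, Ly, Lz (Angstrom).
#' @return an object of class \code{molecular_system} with components
#'   \code{atoms} (data.frame, incl. \code{class}), \code{residues}
#'   (one row per residue, in order of first appearance) and \code{box}.
#' @export
molecular_system <- function(atoms, box) {
  req <- c("id", "name", "resid", "resname", "chain", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stopf("atoms is missing column(s): %s", paste(miss, collapse = ", "))
  if (!is.numeric(box) || length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stopf("box must be three positive lengths (Angstrom)")
  atoms$resid <- as.integer(atoms$resid)
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  # residue key: (chain, resid) pairs in order of first appearance
  key <- paste(atoms$chain, atoms$resid, sep = "\r")
  first <- !duplicated(key)
  residues <- data.frame(
    resid = atoms$resid[first],
    resname = atoms$resname[first],
    chain = atoms$chain[first],
    stringsAsFactors = FALSE
  )
  residues$class <- classify_residue(residues$resname)
  if (any(residues$class == "unknown"))
    warnf("unknown residue name(s): %s (classified 'unknown')",
          paste(unique(residues$resname[residues$class == "unknown"]), collapse = ", "))
  atoms$class <- residues$class[match(key, key[first])]
  structure(
    list(atoms = atoms, residues = residues, box = as.numeric(box)),
    class = "molecular_system"
  )
}

#' @export
print.molecular_system <- function(x, ...) {
  cls <- table(x$residues$class)
  cat(sprintf("<molecular_system> %d atoms, %d residues; box %.1f x %.1f x %.1f A\n",
              nrow(x$atoms), nrow(x$residues), x$box[1], x$box[2], x$box[3]))
  cat("  residues:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}

#' Coordinates of a system as an n x 3 matrix
#' @param system a \code{molecular_system}.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
coords <- function(system) {
  as.matrix(system$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a system
#' @param system a \code{molecular_system}.
#' @param xyz n x 3 matrix (Angstrom).
#' @return the modified system.
#' @export
set_coords <- function(system, xyz) {
  stopifnot(nrow(xyz) == nrow(system$atoms), ncol(xyz) == 3)
  system$atoms$x <- xyz[, 1]
  system$atoms$y <- xyz[, 2]
  system$atoms$z <- xyz[, 3]
  system
}

is_lipid_class <- function(class) startsWith(class, "lipid:")

#' Residue ids of all lipids in a system
#' @param system a \code{molecular_system}.
#' @return integer vector of residue ids (unique per chain-resid pair order).
#' @keywords internal
lipid_resids <- function(system) {
  system$residues$resid[is_lipid_class(system$residues$class)]
}
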