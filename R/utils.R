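#' @keywords internal
"_PACKAGE"

# Standard atomic masses (amu) for the elements that occur in membrane systems.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  K = 39.098, CL = 35.45, NA. = 22.990, MG = 24.305, ZN = 65.38, BR = 79.904,
  F = 18.998, FE = 55.845, CA = 40.078
)

#' Guess an element symbol from an atom name
#'
#' Digits and leading primes are stripped; two-letter ion/metal symbols are
#' recognised before falling back to the first letter.
#'
#' @param name character vector of atom names (e.g. "CA", "P", "1H").
#' @return character vector of element symbols.
#' @keywords internal
guess_element <- function(name) {
  nm <- toupper(gsub("[0-9' ]", "", name))
  two <- substr(nm, 1, 2)
  out <- substr(nm, 1, 1)
  known2 <- c("CL", "BR", "MG", "ZN", "FE")
  out[two %in% known2] <- two[two %in% known2]
  out[nm == "NA"] <- "NA"
  out
}

element_mass <- function(element) {
  key <- ifelse(element == "NA", "NA.", element)
  m <- .element_masses[key]
  m[is.na(m)] <- 0
  unname(m)
}

#' Wrap coordinates into the periodic box
#' @param x numeric vector of coordinates (Angstrom).
#' @param L box length along that axis (Angstrom).
#' @return coordinates wrapped into [0, L).
#' @keywords internal
wrap_pbc <- function(x, L) x - floor(x / L) * L

#' Minimum-image separation along one axis
#' @keywords internal
min_image <- function(dx, L) dx - round(dx / L) * L

#' Minimum-image squared distances between two coordinate sets
#'
#' @param a,b matrices with columns x, y, z (Angstrom).
#' @param box length-3 box vector, or NULL for no periodicity.
#' @return |a| x |b| matrix of squared distances.
#' @keywords internal
pair_dist2 <- function(a, b, box = NULL) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  if (!is.null(box)) {
    dx <- min_image(dx, box[1])
    dy <- min_image(dy, box[2])
    dz <- min_image(dz, box[3])
  }
  dx * dx + dy * dy + dz * dz
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
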