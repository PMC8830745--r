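# Per-residue secondary structure: a phi/psi-region frame classifier,
# propensity and the 70% consensus rule (residues below it are "dynamic"),
# per-domain composition, and external label-matrix loaders (CSV and
# DSSP-letter streams). Alphabet: H helix, E strand, T turn, C coil.

.ss_levels <- c("H", "E", "T", "C")

#' Backbone dihedral angle
#'
#' @param p1,p2,p3,p4 3-vectors or n x 3 matrices of positions.
#' @return torsion angle(s) in degrees, in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  as1 <- function(p) if (is.null(dim(p))) matrix(p, 1) else p
  p1 <- as1(p1); p2 <- as1(p2); p3 <- as1(p3); p4 <- as1(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(rowSums(b2^2)))
  x <- rowSums(n1 * n2); y <- rowSums(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  ifelse(ang <= -180, ang + 360, ang)
}

in_alpha <- function(phi, psi)
  !is.na(phi) & !is.na(psi) & phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
in_beta <- function(phi, psi)
  !is.na(phi) & !is.na(psi) & phi >= -180 & phi <= -90 &
    (psi >= 90 | psi <= -170)

run_lengths_at <- function(flag) {
  # for each position, the length of the maximal TRUE run covering it
  r <- rle(flag)
  rep(ifelse(r$values, r$lengths, 0L), r$lengths)
}

#' Assign secondary structure to one frame from backbone geometry
#'
#' A dihedral-region classifier: residues whose (phi, psi) fall in the
#' alpha region (phi in [-100, -30], psi in [-80, -5]) in runs of >= 4 are
#' helix; beta-region residues (phi in [-180, -90], psi in [90, 180] or
#' [-180, -170]) in runs of >= 3 are strand; shorter (>= 2) alpha/beta-region
#' stretches are turns; everything else, including residues with missing
#' backbone atoms (labelled with a warning), is coil.
#'
#' @param system a \code{\link{molecular_system}} with full backbone geometry
#'   (N, CA, C atoms); systems without it must supply labels externally.
#' @param xyz optional frame coordinates (default the system's).
#' @param selection protein selection (default all protein atoms).
#' @return named character vector of labels, one per residue.
#' @export
assign_ss_frame <- function(system, xyz = NULL, selection = "protein") {
  idx <- sel_or_all(system, selection)
  a <- system$atoms[idx, ]
  pos <- if (is.null(xyz)) coords(system)[idx, , drop = FALSE]
         else xyz[idx, , drop = FALSE]
  resids <- unique(a$resid)
  nres <- length(resids)
  get_atom <- function(rid, nm) {
    j <- which(a$resid == rid & toupper(a$name) == nm)
    if (length(j)) pos[j[1], ] else rep(NA_real_, 3)
  }
  N <- t(vapply(resids, get_atom, numeric(3), nm = "N"))
  CA <- t(vapply(resids, get_atom, numeric(3), nm = "CA"))
  C <- t(vapply(resids, get_atom, numeric(3), nm = "C"))
  missing_bb <- apply(is.na(N) | is.na(CA) | is.na(C), 1, any)
  if (any(missing_bb))
    warnf("%d residue(s) missing backbone atoms; labelled C", sum(missing_bb))
  phi <- psi <- rep(NA_real_, nres)
  for (i in seq_len(nres)) {
    if (missing_bb[i]) next
    if (i > 1 && !missing_bb[i - 1])
      phi[i] <- dihedral(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    if (i < nres && !missing_bb[i + 1])
      psi[i] <- dihedral(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
  }
  al <- in_alpha(phi, psi); be <- in_beta(phi, psi)
  lab <- rep("C", nres)
  arun <- run_lengths_at(al); brun <- run_lengths_at(be)
  lab[al & arun >= 4] <- "H"
  lab[be & brun >= 3 & lab == "C"] <- "E"
  lab[((al & arun >= 2 & arun < 4) | (be & brun == 2)) & lab == "C"] <- "T"
  names(lab) <- resids
  lab
}

#' Build a label matrix by classifying every frame
#'
#' @inheritParams assign_ss_frame
#' @param stream a \code{\link{frame_stream}}.
#' @return residues x frames \code{label_matrix}.
#' @export
assign_ss_stream <- function(stream, system, selection = "protein") {
  first <- assign_ss_frame(system, frame_coords(stream, 1), selection)
  m <- matrix("C", length(first), stream$n_frames,
              dimnames = list(names(first), NULL))
  m[, 1] <- first
  if (stream$n_frames > 1)
    for (k in 2:stream$n_frames)
      m[, k] <- suppressWarnings(
        assign_ss_frame(system, frame_coords(stream, k), selection))
  class(m) <- c("label_matrix", class(m))
  m
}

#' Per-residue secondary-structure propensities
#'
#' @param matrix residues x frames label matrix over \{H, E, T, C\}.
#' @return residues x 4 matrix of fractions (rows sum to 1).
#' @export
propensity <- function(matrix) {
  if (ncol(matrix) == 0) stopf("label matrix has no frames")
  bad <- setdiff(unique(as.vector(matrix)), .ss_levels)
  if (length(bad)) stopf("labels outside alphabet: %s", paste(bad, collapse = ", "))
  out <- vapply(.ss_levels, function(l) rowMeans(matrix == l),
                numeric(nrow(matrix)))
  if (nrow(matrix) == 1) out <- matrix(out, 1, 4, dimnames = list(rownames(matrix), .ss_levels))
  out
}

#' Consensus secondary-structure assignment (70% rule)
#'
#' A residue is assigned its most frequent class if that class holds for at
#' least \code{threshold} of the frames (boundary inclusive: exactly 70.0%
#' counts as assigned); otherwise it is DYNAMIC.
#'
#' @param matrix residues x frames label matrix.
#' @param threshold consensus fraction (default 0.70).
#' @return data.frame with \code{resid} (rownames when present),
#'   \code{label} in \{H, E, T, C, DYNAMIC\}, \code{max_fraction}, plus the
#'   four propensity columns.
#' @export
consensus <- function(matrix, threshold = 0.70) {
  p <- propensity(matrix)
  best <- max.col(p, ties.method = "first")
  frac <- p[cbind(seq_len(nrow(p)), best)]
  lab <- ifelse(frac >= threshold, .ss_levels[best], "DYNAMIC")
  rid <- rownames(matrix) %||% as.character(seq_len(nrow(matrix)))
  out <- data.frame(resid = as.integer(rid), label = lab, max_fraction = frac,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(p))
}

#' Per-domain and global secondary-structure composition
#'
#' Fractions of H / E / T / C / DYNAMIC consensus labels per domain and
#' globally. The global row is computed over all residues (domain-assigned or
#' not); an \code{"assigned_only"} global row restricted to domain-covered
#' residues is also included, since composition can be quoted either way.
#'
#' @param consensus a data.frame from \code{\link{consensus}}.
#' @param domain_table domain table (default \code{\link{abca1_domains}()}).
#' @return data.frame with \code{domain}, \code{n_residues} and fraction
#'   columns \code{H, E, T, C, DYNAMIC} (rows sum to 1). Domains with no
#'   residues are omitted with a warning.
#' @export
composition_report <- function(consensus, domain_table = abca1_domains()) {
  dom <- assign_domain(consensus$resid, domain_table)
  lv <- c(.ss_levels, "DYNAMIC")
  frac_of <- function(rows) {
    n <- length(rows)
    c(n = n, vapply(lv, function(l) mean(consensus$label[rows] == l), numeric(1)))
  }
  doms <- unique(domain_table$domain)
  rows <- list()
  for (d in doms) {
    r <- which(dom == d)
    if (!length(r)) { warnf("domain %s has no residues; omitted", d); next }
    rows[[d]] <- frac_of(r)
  }
  if (any(dom == "unassigned"))
    rows[["unassigned"]] <- frac_of(which(dom == "unassigned"))
  rows[["global"]] <- frac_of(seq_len(nrow(consensus)))
  if (any(dom != "unassigned"))
    rows[["assigned_only"]] <- frac_of(which(dom != "unassigned"))
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("n_residues", lv)
  cbind(domain = rownames(out), out, row.names = NULL)
}

#' Read an external label matrix
#'
#' CSV/TSV with rows = residues, columns = frames (no header), or a
#' DSSP-letter matrix mapped onto the package alphabet
#' (G, H, I -> H; E, B -> E; T -> T; S, blank, - , C -> C).
#'
#' @param path file path.
#' @param sep field separator ("," default; "\t" for TSV).
#' @param dssp logical: translate DSSP letters.
#' @return a \code{label_matrix}.
#' @export
read_label_matrix <- function(path, sep = ",", dssp = FALSE) {
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                   colClasses = "character",
                                   stringsAsFactors = FALSE))
  m <- gsub(" ", "", m)
  if (dssp) {
    map <- c(G = "H", H = "H", I = "H", E = "E", B = "E", T = "T",
             S = "C", "-" = "C", C = "C")
    blank <- m == ""
    m[] <- map[toupper(m)]
    m[blank] <- "C"
    if (any(is.na(m))) stopf("unmapped DSSP letters in '%s'", path)
  }
  bad <- setdiff(unique(as.vector(m)), .ss_levels)
  if (length(bad)) stopf("labels outside alphabet: %s", paste(bad, collapse = ", "))
  dimnames(m) <- NULL
  class(m) <- c("label_matrix", class(m))
  m
}

# ---- helix flexibility (bend-angle profiling) --------------------------------

#' Local helix axis from C-alpha coordinates
#'
#' Axis points are sliding-window centroids of consecutive C-alpha positions:
#' averaging over one helical turn cancels the helical wobble and leaves the
#' axis trace. The two helix ends are not resolved (an axis needs a full
#' window on both sides).
#'
#' @param ca_coords n x 3 matrix of consecutive C-alpha positions (n >=
#'   window + 2).
#' @param window centroid window in residues (default 4, about one turn).
#' @param smooth apply a second moving-average pass of the same window to the
#'   axis points (default TRUE); a single pass leaves a residual helical
#'   wobble of a few tenths of an Angstrom that the second pass suppresses.
#' @return m x 3 matrix of axis points.
#' @export
helix_axis <- function(ca_coords, window = 4, smooth = TRUE) {
  ca_coords <- as.matrix(ca_coords)
  n <- nrow(ca_coords)
  if (n < window + 2) stopf("helix too short: need >= %d residues", window + 2)
  slide <- function(x, w) {
    m <- nrow(x) - w + 1
    t(vapply(seq_len(m), function(i)
      colMeans(x[i:(i + w - 1), , drop = FALSE]), numeric(3)))
  }
  ax <- slide(ca_coords, window)
  if (smooth && nrow(ax) >= window + 2) ax <- slide(ax, window)
  ax
}

#' Bend-angle profile and flexibility classes along a helix axis
#'
#' The bend angle at an interior axis point is the angle between the mean
#' tangent over \code{span} points before it and after it (accumulating
#' curvature over a turn scale). Classes follow the red/white/blue semantics:
#' flexible > 15 degrees, intermediate (rigid_tol, 15] (the 15-degree boundary
#' inclusive to intermediate), rigid <= rigid_tol.
#'
#' @param axis m x 3 axis polyline from \code{\link{helix_axis}}.
#' @param span tangent-averaging span in axis points (default 4).
#' @param rigid_tol angles at or below this (degrees) are rigid (default 1).
#' @return data.frame with \code{point}, \code{angle_deg}, \code{class}.
#' @export
bend_profile <- function(axis, span = 4, rigid_tol = 1) {
  axis <- as.matrix(axis)
  m <- nrow(axis)
  if (m < 2 * span + 1) stopf("axis too short for span %d", span)
  idx <- (span + 1):(m - span)
  ang <- vapply(idx, function(i) {
    t1 <- axis[i, ] - axis[i - span, ]
    t2 <- axis[i + span, ] - axis[i, ]
    ct <- sum(t1 * t2) / sqrt(sum(t1^2) * sum(t2^2))
    acos(pmin(pmax(ct, -1), 1)) * 180 / pi
  }, numeric(1))
  cls <- ifelse(ang > 15, "flexible",
                ifelse(ang > rigid_tol, "intermediate", "rigid"))
  data.frame(point = idx, angle_deg = ang, class = cls)
}

#' Locate helices in a consensus assignment
#'
#' Contiguous runs of consensus label H of at least \code{min_length}
#' residues.
#'
#' @param consensus data.frame from \code{\link{consensus}}.
#' @param min_length minimum run length (default 6).
#' @return data.frame with \code{start}, \code{end} (residue ids).
#' @export
find_helices <- function(consensus, min_length = 6) {
  isH <- consensus$label == "H"
  r <- rle(isH)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_length
  data.frame(start = consensus$resid[starts[keep]],
             end = consensus$resid[ends[keep]])
}
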