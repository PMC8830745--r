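# Protein conformational metrics: Kabsch superposition, RMSD / radius of
# gyration series, per-residue RMSF, and essential dynamics (coordinate PCA)
# with conformer interpolation along a mode.
#
# Landscape axes and fluctuation metrics are reported in nm (the scale on
# which stabilised deviations of ~1.2 nm are discussed); coordinates stay in
# Angstrom internally.

#' Kabsch superposition
#'
#' Finds the proper rotation and translation minimising the (weighted) RMSD
#' between two coordinate sets, via SVD of the weighted covariance.
#'
#' @param mobile,reference n x 3 matrices (Angstrom), equal n >= 3.
#' @param weights optional non-negative weights (e.g. masses).
#' @return list with \code{rotation} (3 x 3, det = +1), \code{translation}
#'   (so that \code{aligned = mobile \%*\% t(rotation) + translation}),
#'   \code{rmsd} (Angstrom) and \code{aligned}.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stopf("coordinate sets differ in atom count")
  if (n < 3) stopf("need at least 3 atoms to superpose")
  w <- weights %||% rep(1, n)
  if (any(w < 0)) stopf("weights must be non-negative")
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stopf("degenerate (collinear) atom set: superposition ill-defined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((aligned - Q)^2)))
  list(rotation = R, translation = cr - as.vector(R %*% cm),
       rmsd = rmsd, aligned = sweep(aligned, 2, cr, "+"))
}

sel_or_all <- function(system, selection) {
  if (is.null(selection)) seq_len(nrow(system$atoms))
  else if (is.character(selection)) select_atoms(system, selection)
  else as.integer(selection)
}

#' RMSD time series
#'
#' RMSD of each frame from a reference after Kabsch superposition on the
#' selection.
#'
#' @param stream a \code{\link{frame_stream}}.
#' @param system the parent \code{\link{molecular_system}}.
#' @param reference reference coordinates (n_atoms x 3 matrix); default the
#'   first frame.
#' @param selection selection string or atom indices (default protein atoms).
#' @param weights optional per-atom weights over the selection.
#' @return data.frame with \code{frame}, \code{time_ps} and \code{rmsd_nm};
#'   attribute \code{"metric"} = "RMSD".
#' @export
rmsd_series <- function(stream, system, reference = NULL, selection = "protein",
                        weights = NULL) {
  idx <- sel_or_all(system, selection)
  if (!length(idx)) stopf("empty selection")
  ref <- (reference %||% frame_coords(stream, 1))[idx, , drop = FALSE]
  vals <- vapply(seq_len(stream$n_frames), function(k) {
    kabsch_superpose(stream$coords[idx, , k], ref, weights)$rmsd
  }, numeric(1))
  out <- data.frame(frame = seq_len(stream$n_frames) - 1L,
                    time_ps = (seq_len(stream$n_frames) - 1L) * stream$dt,
                    rmsd_nm = vals / 10)
  attr(out, "metric") <- "RMSD"
  out
}

#' Radius-of-gyration time series
#'
#' Mass-weighted Rg about the centre of mass of the selection.
#'
#' @inheritParams rmsd_series
#' @return data.frame with \code{frame}, \code{time_ps}, \code{rg_nm}.
#' @export
rgyr_series <- function(stream, system, selection = "protein") {
  idx <- sel_or_all(system, selection)
  if (!length(idx)) stopf("empty selection")
  m <- system$atoms$mass[idx]
  if (sum(m) <= 0) m <- rep(1, length(idx))
  vals <- vapply(seq_len(stream$n_frames), function(k) {
    xyz <- stream$coords[idx, , k]
    com <- colSums(xyz * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
  }, numeric(1))
  out <- data.frame(frame = seq_len(stream$n_frames) - 1L,
                    time_ps = (seq_len(stream$n_frames) - 1L) * stream$dt,
                    rg_nm = vals / 10)
  attr(out, "metric") <- "Rg"
  out
}

# superpose every frame of a selection onto its first frame; returns
# n_sel x 3 x n_frames array
superposed_coords <- function(stream, idx, superpose = TRUE) {
  ref <- stream$coords[idx, , 1, drop = TRUE]
  arr <- array(0, dim = c(length(idx), 3, stream$n_frames))
  for (k in seq_len(stream$n_frames)) {
    xyz <- stream$coords[idx, , k, drop = TRUE]
    arr[, , k] <- if (superpose && length(idx) >= 3)
      kabsch_superpose(xyz, ref)$aligned else xyz
  }
  arr
}

#' Root-mean-square fluctuation per residue
#'
#' Fluctuation of each atom about its time-mean position after per-frame
#' superposition, aggregated per residue as the mass-weighted mean over the
#' residue's selected atoms.
#'
#' @inheritParams rmsd_series
#' @param superpose superpose frames before measuring (default TRUE).
#' @return data.frame with \code{resid}, \code{chain}, \code{rmsf_nm}.
#' @export
rmsf <- function(stream, system, selection = "protein", superpose = TRUE) {
  idx <- sel_or_all(system, selection)
  if (!length(idx)) stopf("empty selection")
  arr <- superposed_coords(stream, idx, superpose)
  mean_xyz <- apply(arr, c(1, 2), mean)
  msf <- rowMeans(apply(arr, 3, function(x) rowSums((x - mean_xyz)^2)))
  a <- system$atoms[idx, ]
  m <- a$mass; m[m <= 0] <- 1
  key <- paste(a$chain, a$resid)
  agg <- rowsum(data.frame(wmsf = msf * m, w = m), key, reorder = FALSE)
  first <- !duplicated(key)
  data.frame(resid = a$resid[first], chain = a$chain[first],
             rmsf_nm = sqrt(agg$wmsf / agg$w) / 10)
}

#' Essential dynamics (coordinate PCA)
#'
#' Diagonalises the covariance matrix of superposed coordinates. Eigenvectors
#' are the collective modes of fluctuation; eigenvalues their variances.
#'
#' @inheritParams rmsd_series
#' @return an \code{essential_modes} object: \code{mean} (n x 3),
#'   \code{vectors} (3n x 3n, columns orthonormal), \code{values}
#'   (descending, Angstrom^2), \code{projections} (n_frames x 3n),
#'   \code{atom_index}.
#' @export
essential_dynamics <- function(stream, system, selection = "protein") {
  if (stream$n_frames < 2) stopf("need at least 2 frames")
  idx <- sel_or_all(system, selection)
  if (!length(idx)) stopf("empty selection")
  arr <- superposed_coords(stream, idx, superpose = TRUE)
  X <- t(apply(arr, 3, function(x) as.vector(t(x))))  # frames x 3n (x1 y1 z1 ...)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(X) - 1)
  eg <- eigen(C, symmetric = TRUE)
  structure(list(
    mean = matrix(mu, ncol = 3, byrow = TRUE),
    vectors = eg$vectors,
    values = pmax(eg$values, 0),
    projections = Xc %*% eg$vectors,
    atom_index = idx
  ), class = "essential_modes")
}

#' Interpolate conformers along an essential mode
#'
#' Sweeps the mean structure along eigenvector \code{k} from \code{-amplitude}
#' to \code{+amplitude}; write the result with
#' \code{\link{write_structure}(system, path, frames = )} to obtain a
#' multi-model PDB of the motion.
#'
#' @param modes an \code{essential_modes} object.
#' @param k mode number (1 = dominant).
#' @param n_conformers number of conformers (default 100).
#' @param amplitude sweep half-range (Angstrom); default twice the mode's
#'   standard deviation.
#' @return n_sel x 3 x n_conformers array.
#' @export
interpolate_mode <- function(modes, k = 1, n_conformers = 100, amplitude = NULL) {
  amp <- amplitude %||% (2 * sqrt(modes$values[k]))
  v <- matrix(modes$vectors[, k], ncol = 3, byrow = TRUE)
  steps <- seq(-amp, amp, length.out = n_conformers)
  out <- array(0, dim = c(nrow(modes$mean), 3, n_conformers))
  for (i in seq_len(n_conformers)) out[, , i] <- modes$mean + steps[i] * v
  out
}
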