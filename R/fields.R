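# Bilayer scalar fields on regular XY (or XZ) grids: leaflet assignment,
# phosphate-peak thickness, deformation maps, voxel partial densities,
# Fourier-filtered Monge-patch mean curvature, and area per lipid.
# All gridding is periodic in the orthorhombic box; frames are analysed in
# box coordinates (no global fit).

#' Construct a 2-D field on a regular periodic grid
#'
#' @param values nx x ny matrix of cell values.
#' @param cell length-2 cell size (Angstrom).
#' @param origin length-2 grid origin (box corner, Angstrom).
#' @param units units tag ("A", "amu/A^3", "1/A", "count", ...).
#' @param mask optional logical matrix (TRUE = masked cell, e.g.
#'   protein-occupied or interpolated-empty).
#' @return a \code{field2d} object.
#' @export
field2d <- function(values, cell, origin = c(0, 0), units = "", mask = NULL) {
  stopifnot(is.matrix(values), length(cell) == 2)
  structure(list(values = values, cell = as.numeric(cell),
                 origin = as.numeric(origin), units = units,
                 mask = mask %||% matrix(FALSE, nrow(values), ncol(values))),
            class = "field2d")
}

#' @export
print.field2d <- function(x, ...) {
  cat(sprintf("<field2d> %d x %d cells of %.2f x %.2f A [%s]; %d masked\n",
              nrow(x$values), ncol(x$values), x$cell[1], x$cell[2],
              x$units, sum(x$mask)))
  invisible(x)
}

#' Write a field as a CSV matrix plus a JSON sidecar header
#' @param field a \code{field2d}.
#' @param prefix output path prefix; writes \code{<prefix>.csv} and
#'   \code{<prefix>.json} (and \code{<prefix>_mask.csv} if any cell is
#'   masked).
#' @return invisibly, the CSV path.
#' @export
write_field2d <- function(field, prefix) {
  utils::write.table(field$values, paste0(prefix, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(cell = field$cell, origin = field$origin, units = field$units,
         dim = dim(field$values), n_masked = sum(field$mask)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  if (any(field$mask))
    utils::write.table(field$mask * 1L, paste0(prefix, "_mask.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, ".csv"))
}

# centroids (unweighted) of lipid residues for one frame; returns data.frame
lipid_centroids <- function(system, xyz = NULL) {
  a <- system$atoms
  pos <- if (is.null(xyz)) coords(system) else xyz
  keep <- is_lipid_class(a$class)
  key <- paste(a$chain[keep], a$resid[keep])
  cx <- rowsum(pos[keep, , drop = FALSE], key, reorder = FALSE)
  n <- as.vector(rowsum(rep(1, sum(keep)), key, reorder = FALSE))
  first <- !duplicated(key)
  data.frame(chain = a$chain[keep][first], resid = a$resid[keep][first],
             resname = a$resname[keep][first],
             x = cx[, 1] / n, y = cx[, 2] / n, z = cx[, 3] / n,
             stringsAsFactors = FALSE)
}

#' Assign lipids to leaflets for one frame
#'
#' Each lipid's (unweighted) centroid z is compared to the mean centroid z of
#' all lipids in that frame: above or equal is "top", below is "bottom". The
#' rule needs no phosphate, so cholesterol is assigned like any other lipid.
#'
#' @param system a \code{\link{molecular_system}}.
#' @param xyz optional frame coordinates (default the system's own).
#' @return data.frame with \code{chain}, \code{resid}, \code{resname},
#'   \code{z} and \code{leaflet} in \{top, bottom\}.
#' @export
assign_leaflets <- function(system, xyz = NULL) {
  cen <- lipid_centroids(system, xyz)
  if (!nrow(cen)) stopf("system contains no lipids")
  mid <- mean(cen$z)
  if (diff(range(cen$z)) < 1e-9)
    stopf("degenerate input: all lipid centroids at one z, leaflets unresolved")
  cen$leaflet <- ifelse(cen$z >= mid, "top", "bottom")
  cen[, c("chain", "resid", "resname", "z", "leaflet")]
}

refine_peak <- function(counts, mids, bin) {
  i <- which.max(counts)
  if (i > 1 && i < length(counts)) {
    den <- counts[i - 1] - 2 * counts[i] + counts[i + 1]
    if (den < 0) return(mids[i] + 0.5 * (counts[i - 1] - counts[i + 1]) / den * bin)
  }
  mids[i]
}

#' Average bilayer thickness from headgroup density peaks
#'
#' Per frame, a 1-D histogram of selected headgroup-atom z coordinates is
#' split at its midplane (the mean selected z); the thickness is the distance
#' between the highest histogram peak on each side, refined by 3-point
#' parabolic interpolation.
#'
#' @param stream a \code{\link{frame_stream}}.
#' @param system the parent system.
#' @param selection headgroup atoms (default \code{"name P and lipid"};
#'   cholesterol carries no phosphate and is naturally excluded).
#' @param bin histogram bin width (Angstrom, default 1).
#' @return list with \code{per_frame} (Angstrom), \code{mean}, \code{sd}.
#' @export
average_thickness <- function(stream, system, selection = "name P and lipid",
                              bin = 1) {
  idx <- sel_or_all(system, selection)
  if (!length(idx)) stopf("selection matches no atoms (no phosphate headgroups?)")
  vals <- vapply(seq_len(stream$n_frames), function(k) {
    z <- stream$coords[idx, 3, k]
    mid <- mean(z)
    up <- z[z >= mid]; dn <- z[z < mid]
    if (!length(up) || !length(dn))
      stopf("leaflets unresolved: headgroup z histogram is one-sided")
    breaks <- seq(floor(min(z)) - bin, ceiling(max(z)) + bin, by = bin)
    hu <- graphics::hist(up, breaks = breaks, plot = FALSE)
    hd <- graphics::hist(dn, breaks = breaks, plot = FALSE)
    refine_peak(hu$counts, hu$mids, bin) - refine_peak(hd$counts, hd$mids, bin)
  }, numeric(1))
  list(per_frame = vals, mean = mean(vals), sd = stats::sd(vals))
}

# periodic grid index: floor((x - origin)/cell) wrapped into 1..n
grid_index <- function(x, cell, n) {
  (floor(x / cell) %% n) + 1L
}

# accumulate mean of v per 2-D cell; returns list(sum, count) matrices
grid_accumulate <- function(ix, iy, v, nx, ny) {
  lin <- (iy - 1L) * nx + ix
  s <- rowsum(v, lin)
  cnt <- rowsum(rep(1, length(v)), lin)
  sum_m <- matrix(0, nx, ny); cnt_m <- matrix(0, nx, ny)
  sum_m[as.integer(rownames(s))] <- s
  cnt_m[as.integer(rownames(cnt))] <- cnt
  list(sum = sum_m, count = cnt_m)
}

# fill empty cells by iterative periodic neighbour averaging
fill_periodic <- function(m, empty) {
  while (any(empty)) {
    shifted <- function(M, di, dj) {
      nx <- nrow(M)
      M[((seq_len(nx) - 1 + di) %% nx) + 1, ((seq_len(ncol(M)) - 1 + dj) %% ncol(M)) + 1]
    }
    acc <- matrix(0, nrow(m), ncol(m)); cnt <- matrix(0, nrow(m), ncol(m))
    filled <- !empty
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      vals <- shifted(ifelse(filled, m, 0), d[1], d[2])
      ok <- shifted(filled, d[1], d[2])
      acc <- acc + vals
      cnt <- cnt + ok
    }
    newly <- empty & cnt > 0
    if (!any(newly)) break
    m[newly] <- acc[newly] / cnt[newly]
    empty <- empty & !newly
  }
  m
}

#' Time-averaged leaflet deformation map
#'
#' Per frame, headgroup-atom z minus the leaflet's mean headgroup z,
#' accumulated on a periodic XY grid and averaged over frames. The sign is
#' +1 for the top leaflet and -1 for the bottom, so positive always means the
#' leaflet moves outward (membrane expansion). Cells never visited are filled
#' by periodic neighbour interpolation and masked.
#'
#' @param stream a \code{\link{frame_stream}}.
#' @param system the parent system.
#' @param leaflet \code{"top"} or \code{"bottom"}.
#' @param cell grid cell edge (Angstrom, default 2).
#' @param head_atoms headgroup atom names (default P; cholesterol excluded).
#' @return a \code{\link{field2d}} in Angstrom.
#' @export
deformation_map <- function(stream, system, leaflet = c("top", "bottom"),
                            cell = 2, head_atoms = "P") {
  leaflet <- match.arg(leaflet)
  a <- system$atoms
  nx <- max(1L, floor(system$box[1] / cell))
  ny <- max(1L, floor(system$box[2] / cell))
  cw <- system$box[1:2] / c(nx, ny)
  sum_m <- matrix(0, nx, ny); cnt_m <- matrix(0, nx, ny)
  head_idx <- which(toupper(a$name) %in% toupper(head_atoms) &
                    is_lipid_class(a$class))
  if (!length(head_idx)) stopf("no headgroup atoms found")
  for (k in seq_len(stream$n_frames)) {
    xyz <- frame_coords(stream, k)
    lf <- assign_leaflets(system, xyz)
    want <- lf$resid[lf$leaflet == leaflet]
    sel <- head_idx[a$resid[head_idx] %in% want]
    z <- xyz[sel, 3]
    dz <- z - mean(z)
    ix <- grid_index(wrap_pbc(xyz[sel, 1], system$box[1]), cw[1], nx)
    iy <- grid_index(wrap_pbc(xyz[sel, 2], system$box[2]), cw[2], ny)
    g <- grid_accumulate(ix, iy, dz, nx, ny)
    sum_m <- sum_m + g$sum
    cnt_m <- cnt_m + g$count
  }
  vals <- matrix(0, nx, ny)
  seen <- cnt_m > 0
  vals[seen] <- sum_m[seen] / cnt_m[seen]
  vals <- fill_periodic(vals, !seen)
  sgn <- if (leaflet == "top") 1 else -1
  field2d(vals * sgn, cw, units = "A", mask = !seen)
}

#' Voxel partial density of a subset
#'
#' Column voxels span the box along the axis orthogonal to the chosen plane;
#' the value is the time-averaged mass in the voxel divided by the voxel
#' volume.
#'
#' @param stream a \code{\link{frame_stream}}.
#' @param system the parent system.
#' @param plane \code{"XY"} or \code{"XZ"}.
#' @param voxel in-plane voxel edge (Angstrom, default 2, i.e. ~0.2 nm).
#' @param selection subset (default \code{"lipid"}: only lipids counted).
#' @return a \code{\link{field2d}} in amu/A^3.
#' @export
partial_density <- function(stream, system, plane = c("XY", "XZ"), voxel = 2,
                            selection = "lipid") {
  plane <- match.arg(plane)
  if (voxel > min(system$box)) stopf("voxel larger than the box")
  ax <- if (plane == "XY") c(1, 2, 3) else c(1, 3, 2)
  idx <- sel_or_all(system, selection)
  m <- system$atoms$mass[idx]
  n1 <- max(1L, floor(system$box[ax[1]] / voxel))
  n2 <- max(1L, floor(system$box[ax[2]] / voxel))
  cw <- c(system$box[ax[1]] / n1, system$box[ax[2]] / n2)
  vol <- cw[1] * cw[2] * system$box[ax[3]]
  acc <- matrix(0, n1, n2)
  for (k in seq_len(stream$n_frames)) {
    xyz <- frame_coords(stream, k)
    i1 <- grid_index(wrap_pbc(xyz[idx, ax[1]], system$box[ax[1]]), cw[1], n1)
    i2 <- grid_index(wrap_pbc(xyz[idx, ax[2]], system$box[ax[2]]), cw[2], n2)
    g <- grid_accumulate(i1, i2, m, n1, n2)
    acc <- acc + g$sum
  }
  field2d(acc / stream$n_frames / vol, cw, units = "amu/A^3")
}

# spectral low-pass + derivatives of a periodic height field.
# filter = "gaussian": attenuate mode k by exp(-(|k|/q_modes)^2) (smooth,
# ring-free; the default); "sharp": brick-wall keep |k| <= q_modes per axis;
# "none" / q_modes = NULL: unfiltered.
spectral_surface <- function(z, Lx, Ly, q_modes = 4,
                             filter = c("gaussian", "sharp", "none")) {
  filter <- match.arg(filter)
  nx <- nrow(z); ny <- ncol(z)
  zh <- stats::fft(z)
  kx <- c(0:floor(nx / 2), -(ceiling(nx / 2) - 1):-1)
  ky <- c(0:floor(ny / 2), -(ceiling(ny / 2) - 1):-1)
  if (!is.null(q_modes) && filter != "none") {
    if (filter == "gaussian") {
      KR2 <- outer(kx^2, ky^2, "+")
      zh <- zh * exp(-KR2 / q_modes^2)
    } else {
      zh[abs(kx) > q_modes, ] <- 0
      zh[, abs(ky) > q_modes] <- 0
    }
  }
  qx <- 2 * pi * kx / Lx
  qy <- 2 * pi * ky / Ly
  # zero the Nyquist mode for odd derivatives (it has no well-defined sign)
  if (nx %% 2 == 0) qx[nx / 2 + 1] <- 0
  if (ny %% 2 == 0) qy[ny / 2 + 1] <- 0
  QX <- matrix(qx, nx, ny)
  QY <- matrix(qy, nx, ny, byrow = TRUE)
  re_ifft <- function(M) Re(stats::fft(M, inverse = TRUE)) / (nx * ny)
  list(
    z = re_ifft(zh),
    zx = re_ifft(1i * QX * zh),
    zy = re_ifft(1i * QY * zh),
    zxx = re_ifft(-QX^2 * zh),
    zyy = re_ifft(-QY^2 * zh),
    zxy = re_ifft(-QX * QY * zh)
  )
}

#' Fourier-filtered mean curvature of a leaflet surface
#'
#' Headgroup z coordinates are gridded to a height field z(x, y) (time-
#' averaged over the stream), low-pass filtered in Fourier space, and
#' differentiated spectrally. The Monge-patch mean curvature is
#' \deqn{H = \frac{(1+z_x^2) z_{yy} - 2 z_x z_y z_{xy} + (1+z_y^2) z_{xx}}
#'            {2 (1 + z_x^2 + z_y^2)^{3/2}}.}
#' With \code{leaflet = "top"} or \code{"bottom"} the sign is flipped so that
#' positive curvature means the leaflet bends away from the bilayer centre
#' (outward); \code{"none"} reports the raw Monge-patch sign (a dome-shaped
#' height field is then negative, e.g. -A/sigma^2 at a Gaussian apex).
#'
#' @param stream a \code{\link{frame_stream}}.
#' @param system the parent system.
#' @param leaflet \code{"top"}, \code{"bottom"} or \code{"none"} (raw sign;
#'   grids the top leaflet).
#' @param bins grid bins per axis (default 100).
#' @param q_modes low-pass scale in Fourier modes per box edge (default 4,
#'   suppressing single-lipid noise); NULL disables filtering (appropriate
#'   only for noise-free analytic surfaces).
#' @param filter \code{"gaussian"} (default; smooth attenuation
#'   \code{exp(-(k/q_modes)^2)}, free of Gibbs ringing and exact on quadratic
#'   surfaces), \code{"sharp"} (brick-wall cutoff) or \code{"none"}.
#' @param head_atoms headgroup atom names (default P).
#' @return a \code{\link{field2d}} in 1/Angstrom; never-visited cells are
#'   filled by periodic interpolation before filtering and masked.
#' @export
mean_curvature <- function(stream, system, leaflet = c("top", "bottom", "none"),
                           bins = 100, q_modes = 4,
                           filter = c("gaussian", "sharp", "none"),
                           head_atoms = "P") {
  leaflet <- match.arg(leaflet)
  filter <- match.arg(filter)
  geom_leaflet <- if (leaflet == "bottom") "bottom" else "top"
  a <- system$atoms
  nx <- ny <- bins
  cw <- system$box[1:2] / bins
  head_idx <- which(toupper(a$name) %in% toupper(head_atoms) &
                    is_lipid_class(a$class))
  if (!length(head_idx)) stopf("no headgroup atoms found")
  sum_m <- matrix(0, nx, ny); cnt_m <- matrix(0, nx, ny)
  for (k in seq_len(stream$n_frames)) {
    xyz <- frame_coords(stream, k)
    lf <- assign_leaflets(system, xyz)
    want <- lf$resid[lf$leaflet == geom_leaflet]
    sel <- head_idx[a$resid[head_idx] %in% want]
    ix <- grid_index(wrap_pbc(xyz[sel, 1], system$box[1]), cw[1], nx)
    iy <- grid_index(wrap_pbc(xyz[sel, 2], system$box[2]), cw[2], ny)
    g <- grid_accumulate(ix, iy, xyz[sel, 3], nx, ny)
    sum_m <- sum_m + g$sum
    cnt_m <- cnt_m + g$count
  }
  seen <- cnt_m > 0
  z <- matrix(0, nx, ny)
  z[seen] <- sum_m[seen] / cnt_m[seen]
  z <- fill_periodic(z, !seen)
  sp <- spectral_surface(z, system$box[1], system$box[2], q_modes, filter)
  H <- ((1 + sp$zx^2) * sp$zyy - 2 * sp$zx * sp$zy * sp$zxy +
        (1 + sp$zy^2) * sp$zxx) / (2 * (1 + sp$zx^2 + sp$zy^2)^1.5)
  sgn <- switch(leaflet, top = -1, bottom = 1, none = 1)
  field2d(H * sgn, cw, units = "1/A", mask = !seen)
}

#' Area per lipid
#'
#' Box XY area divided by the number of lipids in the chosen leaflet, per
#' frame. The protein footprint is deliberately not subtracted (recorded in
#' the result's \code{footprint_subtracted} flag).
#'
#' @param stream a \code{\link{frame_stream}}.
#' @param system the parent system.
#' @param leaflet \code{"top"} or \code{"bottom"}.
#' @return list with \code{per_frame} (Angstrom^2), \code{mean},
#'   \code{footprint_subtracted = FALSE}.
#' @export
area_per_lipid <- function(stream, system, leaflet = c("top", "bottom")) {
  leaflet <- match.arg(leaflet)
  vals <- vapply(seq_len(stream$n_frames), function(k) {
    lf <- assign_leaflets(system, frame_coords(stream, k))
    n <- sum(lf$leaflet == leaflet)
    if (n == 0) return(NA_real_)
    stream$box[k, 1] * stream$box[k, 2] / n
  }, numeric(1))
  list(per_frame = vals, mean = mean(vals, na.rm = TRUE),
       footprint_subtracted = FALSE)
}
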