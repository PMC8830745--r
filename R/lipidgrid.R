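# Lipid clustering on a square census grid: residue mean positions, mean-z
# monolayer split, per-type counts in 6-Angstrom square cells, and a
# protein-occupancy overlay. The analysed frame defaults to the last one;
# any frame (or a per-frame series) can be requested.

#' Arithmetic-mean residue positions
#'
#' The unweighted mean of a residue's atom coordinates (deliberately not
#' mass-weighted: a plain coordinate mean).
#'
#' @param system a \code{\link{molecular_system}}.
#' @param xyz optional frame coordinates.
#' @param classes residue classes to include: \code{"lipid"},
#'   \code{"protein"} or both (default both).
#' @return data.frame with \code{chain}, \code{resid}, \code{resname},
#'   \code{class}, \code{x}, \code{y}, \code{z}.
#' @export
residue_mean_positions <- function(system, xyz = NULL,
                                   classes = c("lipid", "protein")) {
  a <- system$atoms
  pos <- if (is.null(xyz)) coords(system) else xyz
  keep <- (("lipid" %in% classes) & is_lipid_class(a$class)) |
          (("protein" %in% classes) & a$class == "protein")
  if (!any(keep)) stopf("no residues of the requested classes")
  key <- paste(a$chain[keep], a$resid[keep])
  s <- rowsum(pos[keep, , drop = FALSE], key, reorder = FALSE)
  n <- as.vector(rowsum(rep(1, sum(keep)), key, reorder = FALSE))
  first <- !duplicated(key)
  data.frame(chain = a$chain[keep][first], resid = a$resid[keep][first],
             resname = a$resname[keep][first], class = a$class[keep][first],
             x = s[, 1] / n, y = s[, 2] / n, z = s[, 3] / n,
             stringsAsFactors = FALSE)
}

#' Square-cell lipid census of one monolayer
#'
#' Lipid residue centroids of the chosen monolayer (mean-z split, the same
#' rule as \code{\link{assign_leaflets}}) are binned into square cells of
#' edge \code{edge} tiling the box XY plane (origin at the box corner;
#' centroids wrapped periodically before binning). A cell's protein flag is
#' set when at least one protein residue centroid assigned to the monolayer
#' by its z coordinate falls in the cell; protein residues outside the
#' monolayer's lipid z range are extracellular/cytosolic and excluded.
#'
#' @param system a \code{\link{molecular_system}}.
#' @param lipid_type residue name to count (e.g. "POPC"), or NULL for all
#'   lipids.
#' @param monolayer \code{"top"} or \code{"bottom"}.
#' @param edge cell edge (Angstrom, default 6).
#' @param xyz optional frame coordinates (e.g. the last frame of a stream).
#' @return a \code{census_grid}: \code{counts} (nx x ny integer matrix),
#'   \code{protein} (logical matrix), \code{edge}, \code{origin},
#'   \code{monolayer}, \code{lipid_type}, \code{n_lipids} (total of the type
#'   in the monolayer).
#' @export
monolayer_census <- function(system, lipid_type = NULL,
                             monolayer = c("top", "bottom"), edge = 6,
                             xyz = NULL) {
  monolayer <- match.arg(monolayer)
  if (edge <= 0) stopf("edge must be > 0")
  cen <- residue_mean_positions(system, xyz)
  lip <- cen[startsWith(cen$class, "lipid:"), ]
  if (!nrow(lip)) stopf("system contains no lipids")
  mid <- mean(lip$z)
  lip$leaflet <- ifelse(lip$z >= mid, "top", "bottom")
  mono <- lip[lip$leaflet == monolayer, ]
  # the slab this monolayer occupies: z range of its lipids' atoms
  a <- system$atoms
  pos_z <- if (is.null(xyz)) a$z else xyz[, 3]
  mono_key <- paste(mono$chain, mono$resid)
  zr <- range(pos_z[paste(a$chain, a$resid) %in% mono_key])
  nx <- max(1L, floor(system$box[1] / edge))
  ny <- max(1L, floor(system$box[2] / edge))
  want <- if (is.null(lipid_type)) mono else mono[mono$resname == lipid_type, ]
  counts <- matrix(0L, nx, ny)
  if (nrow(want)) {
    ix <- grid_index(wrap_pbc(want$x, system$box[1]), edge, nx)
    iy <- grid_index(wrap_pbc(want$y, system$box[2]), edge, ny)
    tab <- table(factor((iy - 1L) * nx + ix, levels = seq_len(nx * ny)))
    counts <- matrix(as.integer(tab), nx, ny)
  }
  prot <- cen[cen$class == "protein", ]
  # protein residues inside this monolayer's z band
  pin <- prot[prot$z >= zr[1] & prot$z <= zr[2] &
              ((monolayer == "top" & prot$z >= mid) |
               (monolayer == "bottom" & prot$z < mid)), ]
  pflag <- matrix(FALSE, nx, ny)
  if (nrow(pin)) {
    ix <- grid_index(wrap_pbc(pin$x, system$box[1]), edge, nx)
    iy <- grid_index(wrap_pbc(pin$y, system$box[2]), edge, ny)
    pflag[cbind(ix, iy)] <- TRUE
  }
  structure(list(counts = counts, protein = pflag, edge = edge,
                 origin = c(0, 0), monolayer = monolayer,
                 lipid_type = lipid_type %||% "all", n_lipids = nrow(want)),
            class = "census_grid")
}

#' @export
print.census_grid <- function(x, ...) {
  cat(sprintf("<census_grid> %s/%s: %d x %d cells of %g A, %d lipids, %d protein cells\n",
              x$lipid_type, x$monolayer, nrow(x$counts), ncol(x$counts),
              x$edge, x$n_lipids, sum(x$protein)))
  invisible(x)
}

#' Write a census grid as CSV + JSON sidecar
#' @param grid a \code{census_grid}.
#' @param prefix output path prefix.
#' @return invisibly, the CSV path.
#' @export
write_census_grid <- function(grid, prefix) {
  utils::write.table(grid$counts, paste0(prefix, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(grid$protein * 1L, paste0(prefix, "_protein.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(edge = grid$edge, origin = grid$origin, monolayer = grid$monolayer,
         lipid_type = grid$lipid_type, n_lipids = grid$n_lipids),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, ".csv"))
}

#' Lipid counts per type, per monolayer and overall
#'
#' @param system a \code{\link{molecular_system}}.
#' @param xyz optional frame coordinates.
#' @return data.frame with \code{resname}, \code{top}, \code{bottom},
#'   \code{total}; zero rows for an empty system.
#' @export
census_totals <- function(system, xyz = NULL) {
  if (!any(is_lipid_class(system$residues$class)))
    return(data.frame(resname = character(0), top = integer(0),
                      bottom = integer(0), total = integer(0)))
  lf <- assign_leaflets(system, xyz)
  types <- sort(unique(lf$resname))
  top <- vapply(types, function(t) sum(lf$resname == t & lf$leaflet == "top"), integer(1))
  bot <- vapply(types, function(t) sum(lf$resname == t & lf$leaflet == "bottom"), integer(1))
  data.frame(resname = types, top = top, bottom = bot, total = top + bot,
             row.names = NULL, stringsAsFactors = FALSE)
}
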