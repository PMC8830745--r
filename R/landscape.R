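# Free-energy landscape over (RMSD, Rg): Gaussian-mixture density estimation
# (EM via mclust, K chosen by BIC), the free-energy surface
# F = -kT ln(rho / rho_max), and clustering of points into the basins of the
# mixture density's maxima by deterministic 8-neighbour hill climbing on an
# evaluation grid.

#' Boltzmann kT at 300 K in kJ/mol
#' @export
kT_300K <- 2.494

#' Synthetic 2-D order-parameter landscape with known modes
#'
#' Draws points from a K-component Gaussian mixture whose centres sit on a
#' fixed non-collinear layout with spacing \code{spacing} (so components are
#' \code{spacing / sigma} standard deviations apart; the default is 10 sigma,
#' comfortably beyond the 5-sigma separation regime in which density-maxima
#' clustering is exact). Ground truth for landscape-recovery tests.
#'
#' @param K number of modes (1..9).
#' @param n number of points.
#' @param seed integer seed.
#' @param sigma per-component isotropic standard deviation.
#' @param spacing centre grid spacing.
#' @return list with \code{points} (n x 2), \code{centers} (K x 2),
#'   \code{component} (true labels).
#' @export
synthetic_landscape <- function(K, n, seed = 1, sigma = 0.05, spacing = 0.5) {
  if (K < 1 || K > 9) stopf("K must be in 1..9")
  set.seed(seed)
  pos <- matrix(c(1, 1, 2, 2, 3, 1, 1, 3, 3, 3, 2, 1, 1, 2, 3, 2, 2, 3),
                ncol = 2, byrow = TRUE)
  cent <- pos[seq_len(K), , drop = FALSE] * spacing
  lab <- sample.int(K, n, replace = TRUE)
  pts <- cbind(cent[lab, 1] + stats::rnorm(n, 0, sigma),
               cent[lab, 2] + stats::rnorm(n, 0, sigma))
  list(points = pts, centers = cent, component = lab)
}

dmvnorm2 <- function(x, mu, S) {
  # bivariate normal density, closed form
  di <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  inv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2) / di
  d1 <- x[, 1] - mu[1]; d2 <- x[, 2] - mu[2]
  q <- inv[1, 1] * d1^2 + 2 * inv[1, 2] * d1 * d2 + inv[2, 2] * d2^2
  exp(-q / 2) / (2 * pi * sqrt(di))
}

#' Fit a Gaussian mixture density to 2-D order-parameter points
#'
#' EM fit via \pkg{mclust} with full covariances; when \code{K} is a range the
#' number of components is selected by BIC. Initialisation is seeded (and, for
#' large n, based on a seeded random subset), so the fit is deterministic
#' given the seed.
#'
#' @param points n x 2 matrix (e.g. RMSD and Rg in nm), n >= 10 * max(K).
#' @param K integer or integer range of component counts.
#' @param seed integer seed.
#' @return a \code{density_model}: \code{K}, \code{weights}, \code{means}
#'   (2 x K), \code{covariances} (2 x 2 x K), \code{bic}, \code{range}.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_density <- function(points, K = 1:8, seed = 1) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stopf("points must be n x 2")
  if (nrow(points) < 10 * max(K))
    stopf("need at least 10 * K points (%d given for K up to %d)",
          nrow(points), max(K))
  set.seed(seed)
  init <- if (nrow(points) > 2000)
    list(subset = sample.int(nrow(points), 1000)) else NULL
  fit <- mclust::Mclust(points, G = K, modelNames = "VVV",
                        initialization = init, verbose = FALSE)
  if (is.null(fit)) stopf("mixture fit failed for all K in range")
  p <- fit$parameters
  structure(list(
    K = fit$G,
    weights = p$pro,
    means = p$mean,
    covariances = p$variance$sigma,
    bic = fit$bic,
    range = apply(points, 2, range)
  ), class = "density_model")
}

#' Evaluate a mixture density at points
#' @param model a \code{density_model}.
#' @param x n x 2 matrix.
#' @return numeric vector of densities.
#' @export
mixture_density <- function(model, x) {
  x <- as.matrix(x)
  rho <- numeric(nrow(x))
  for (k in seq_len(model$K))
    rho <- rho + model$weights[k] *
      dmvnorm2(x, model$means[, k], model$covariances[, , k])
  rho
}

landscape_grid <- function(model, grid, pad = 0.05) {
  rg <- model$range
  span <- rg[2, ] - rg[1, ]
  gx <- seq(rg[1, 1] - pad * span[1], rg[2, 1] + pad * span[1], length.out = grid)
  gy <- seq(rg[1, 2] - pad * span[2], rg[2, 2] + pad * span[2], length.out = grid)
  list(x = gx, y = gy)
}

#' Free-energy surface of a fitted density
#'
#' \code{F = -kT ln(rho / rho_max)}, so the global density maximum sits at
#' F = 0. Grid cells with vanishing density are capped and flagged.
#'
#' @param model a \code{density_model}.
#' @param grid grid points per axis (default 100).
#' @param kT thermal energy in the desired units (default
#'   \code{\link{kT_300K}} kJ/mol).
#' @param cap free-energy value assigned where the density underflows.
#' @return list with \code{x}, \code{y}, \code{F} (grid x grid matrix),
#'   \code{density}, \code{capped} (logical matrix), \code{kT}.
#' @export
free_energy_surface <- function(model, grid = 100, kT = kT_300K, cap = 50) {
  g <- landscape_grid(model, grid)
  pts <- as.matrix(expand.grid(x = g$x, y = g$y))
  rho <- matrix(mixture_density(model, pts), grid, grid)
  rmax <- max(rho)
  capped <- rho <= rmax * exp(-cap / kT)
  F <- -kT * log(pmax(rho / rmax, exp(-cap / kT)))
  F[capped] <- cap
  list(x = g$x, y = g$y, F = F, density = rho, capped = capped, kT = kT)
}

# deterministic 8-neighbour hill climbing on a density grid; returns, per
# cell, the basin id of the density maximum it drains to (ids ordered by
# descending peak density; ties toward lower linear grid index)
grid_basins <- function(rho) {
  nx <- nrow(rho); ny <- ncol(rho)
  n <- nx * ny
  lin <- matrix(seq_len(n), nx, ny)
  best_v <- rho
  best_l <- lin
  for (dj in -1:1) for (di in -1:1) {
    if (di == 0 && dj == 0) next
    v_s <- matrix(-Inf, nx, ny)
    l_s <- matrix(n + 1L, nx, ny)
    si <- max(1, 1 + di):min(nx, nx + di)  # destination rows
    sj <- max(1, 1 + dj):min(ny, ny + dj)
    v_s[si - di, sj - dj] <- rho[si, sj]
    l_s[si - di, sj - dj] <- lin[si, sj]
    upd <- v_s > best_v | (v_s == best_v & l_s < best_l)
    best_v[upd] <- v_s[upd]
    best_l[upd] <- l_s[upd]
  }
  target <- as.integer(best_l)
  # resolve pointer chains; each hop strictly improves (density, -index)
  root <- target
  repeat {
    nxt <- target[root]
    if (all(nxt == root)) break
    root <- nxt
  }
  peaks <- sort(unique(root))
  ord <- order(rho[peaks], decreasing = TRUE)
  id_of_peak <- integer(n)
  id_of_peak[peaks[ord]] <- seq_along(peaks)
  list(basin = id_of_peak[root], peaks = peaks[ord], n_basins = length(peaks))
}

#' Cluster points into density-maxima basins
#'
#' Each point is assigned to the basin of the local density maximum reached by
#' steepest 8-neighbour ascent on an evaluation grid of the mixture density
#' (ties broken toward the lower grid index). Cluster 1 is the basin of the
#' global maximum.
#'
#' @param model a \code{density_model}.
#' @param points n x 2 matrix to label.
#' @param grid evaluation grid points per axis (default 100).
#' @return integer vector of cluster labels; attribute \code{"n_clusters"}
#'   gives the number of distinct basins of the grid.
#' @export
cluster_by_density <- function(model, points, grid = 100) {
  points <- as.matrix(points)
  g <- landscape_grid(model, grid)
  pts <- as.matrix(expand.grid(x = g$x, y = g$y))
  rho <- matrix(mixture_density(model, pts), grid, grid)
  bas <- grid_basins(rho)
  ix <- pmin(pmax(findInterval(points[, 1], g$x, all.inside = TRUE), 1), grid)
  iy <- pmin(pmax(findInterval(points[, 2], g$y, all.inside = TRUE), 1), grid)
  lab <- bas$basin[(iy - 1L) * grid + ix]
  attr(lab, "n_clusters") <- bas$n_basins
  lab
}
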