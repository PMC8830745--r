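# Synthetic bilayer + embedded-protein generator.
#
# Lipids are 3-atom stubs: a headgroup atom (P for phospholipids, O3 for
# cholesterol, which carries no phosphate) plus two tail pseudo-atoms whose
# masses make the residue total realistic. The analyses only consume headgroup
# positions, residue identity and masses, so fuller lipid geometry would add
# nothing testable. All generators are pure functions of (spec, seed).

.lipid_masses <- c(POPC = 760.1, PSM = 703.0, CHL = 386.7, POPI = 837.0,
                   POPE = 718.0, POPS = 762.0, LLPC = 495.6)

#' The heterogeneous-bilayer composition used throughout the package
#'
#' Counts per whole bilayer: POPC 482, PSM 108, CHL 48, POPI 36, POPE 30,
#' POPS 24, LLPC 18 (746 lipids in total).
#'
#' @return named integer vector of lipid counts.
#' @export
membrane_composition <- function() {
  c(POPC = 482L, PSM = 108L, CHL = 48L, POPI = 36L, POPE = 30L, POPS = 24L,
    LLPC = 18L)
}

#' Specify a synthetic bilayer
#'
#' @param composition named vector: lipid counts per whole bilayer (split
#'   50/50 per type between leaflets, odd remainders to the top leaflet).
#' @param box_xy length-2: Lx, Ly (Angstrom).
#' @param thickness target phosphate-to-phosphate distance T (Angstrom);
#'   headgroup planes sit at z = +T/2 and -T/2 (default 41.6, i.e. planes at
#'   +/-20.8 Angstrom).
#' @param min_spacing minimum in-plane spacing between lipids (Angstrom);
#'   used for the overcrowding check.
#' @return a \code{bilayer_spec} object.
#' @export
bilayer_spec <- function(composition = membrane_composition(),
                         box_xy = c(155, 155), thickness = 41.6,
                         min_spacing = 7.5) {
  if (any(composition < 0)) stopf("lipid counts must be >= 0")
  if (is.null(names(composition)) || any(names(composition) == ""))
    stopf("composition must be a named vector of counts")
  if (length(box_xy) != 2 || any(box_xy <= 0)) stopf("box_xy must be two positive lengths")
  if (thickness <= 0) stopf("thickness must be positive")
  structure(list(composition = composition, box_xy = as.numeric(box_xy),
                 thickness = thickness, min_spacing = min_spacing),
            class = "bilayer_spec")
}

# split counts between leaflets: ceiling to top
split_leaflets <- function(composition) {
  top <- ceiling(composition / 2)
  list(top = top, bottom = composition - top)
}

#' Build a synthetic bilayer system
#'
#' Lipids are placed on a per-leaflet jittered square lattice (seeded, hence
#' reproducible) with headgroup atoms exactly on the z = +/- T/2 planes and
#' tails pointing toward the bilayer centre. Each lipid is its own residue on
#' chain "L"; phospholipid headgroups are P atoms, cholesterol's is O3.
#'
#' @param spec a \code{\link{bilayer_spec}}.
#' @param seed integer seed.
#' @return a \code{\link{molecular_system}}; box Lz = thickness + 60.
#' @export
build_bilayer <- function(spec, seed = 1) {
  comp <- spec$composition[spec$composition > 0]
  halves <- split_leaflets(comp)
  n_leaf <- max(sum(halves$top), sum(halves$bottom))
  area <- prod(spec$box_xy)
  need <- n_leaf * spec$min_spacing^2
  if (need > area)
    stopf("overcrowded box: %d lipids per leaflet need at least %.0f A^2 (box has %.0f A^2)",
          n_leaf, need, area)
  set.seed(seed)
  half_t <- spec$thickness / 2
  place_leaflet <- function(counts, zsign) {
    n <- sum(counts)
    if (n == 0) return(NULL)
    # lattice with at least n sites
    ncell <- ceiling(sqrt(n))
    cw <- spec$box_xy / ncell
    sites <- expand.grid(ix = seq_len(ncell) - 0.5, iy = seq_len(ncell) - 0.5)
    sites <- sites[sample.int(nrow(sites), n), , drop = FALSE]
    jit <- matrix(stats::runif(2 * n, -0.15, 0.15), ncol = 2)
    x <- (sites$ix + jit[, 1]) * cw[1]
    y <- (sites$iy + jit[, 2]) * cw[2]
    types <- sample(rep(names(counts), counts))
    data.frame(type = types, x = x, y = y, z = zsign * half_t,
               stringsAsFactors = FALSE)
  }
  top <- place_leaflet(halves$top, +1)
  bot <- place_leaflet(halves$bottom, -1)
  heads <- rbind(top, bot)
  if (is.null(heads) || nrow(heads) == 0) stopf("empty composition")
  n_lip <- nrow(heads)
  # expand to 3-atom stubs; tails point toward bilayer centre
  tail_sign <- -sign(heads$z)
  head_name <- ifelse(heads$type == "CHL", "O3", "P")
  total_mass <- .lipid_masses[heads$type]
  total_mass[is.na(total_mass)] <- 700
  head_mass <- ifelse(heads$type == "CHL", 17.0, 94.97)  # OH / PO4 headgroup
  tail_mass <- (total_mass - head_mass) / 2
  atoms <- data.frame(
    id = seq_len(3 * n_lip),
    name = as.vector(rbind(head_name, "C1", "C2")),
    resid = rep(seq_len(n_lip), each = 3),
    resname = rep(heads$type, each = 3),
    chain = "L",
    x = rep(heads$x, each = 3),
    y = rep(heads$y, each = 3),
    z = as.vector(rbind(heads$z, heads$z + tail_sign * 4, heads$z + tail_sign * 8)),
    element = as.vector(rbind(ifelse(heads$type == "CHL", "O", "P"), "C", "C")),
    mass = as.vector(rbind(head_mass, tail_mass, tail_mass)),
    stringsAsFactors = FALSE
  )
  sys <- molecular_system(atoms, c(spec$box_xy, spec$thickness + 60))
  sys$meta <- list(spec = spec, seed = seed)
  sys
}

#' Embed a dummy transmembrane protein
#'
#' Places a C-alpha-only protein as a vertical helical cylinder through the
#' bilayer centre, spanning from below the bottom headgroup plane to above the
#' top one, and removes lipids whose headgroup lies within \code{radius} of
#' the cylinder axis (in-plane distance). Removed counts per lipid type are
#' recorded in \code{$meta$removed}.
#'
#' @param system a bilayer from \code{\link{build_bilayer}}.
#' @param n_residues number of protein residues.
#' @param radius lipid-exclusion radius (Angstrom); 0 removes nothing.
#' @param overhang how far the protein extends beyond each headgroup plane
#'   (Angstrom, default 10).
#' @return the combined \code{\link{molecular_system}} (protein on chain "P",
#'   residues 1..n_residues).
#' @export
embed_protein <- function(system, n_residues, radius = 12, overhang = 10) {
  if (radius >= min(system$box[1:2]) / 2)
    stopf("radius must be < half the smallest box edge (%.1f A)", min(system$box[1:2]) / 2)
  cx <- system$box[1] / 2; cy <- system$box[2] / 2
  a <- system$atoms
  half_t <- max(abs(a$z[a$name %in% c("P", "O3")]))
  zmin <- -half_t - overhang; zmax <- half_t + overhang
  # helical C-alpha trace about the axis
  th <- (seq_len(n_residues) - 1) * 100 * pi / 180
  r0 <- max(radius * 0.4, 3)
  prot <- data.frame(
    id = seq_len(n_residues),
    name = "CA",
    resid = seq_len(n_residues),
    resname = "ALA",
    chain = "P",
    x = cx + r0 * cos(th),
    y = cy + r0 * sin(th),
    z = seq(zmin, zmax, length.out = n_residues),
    element = "C",
    mass = 110,  # average residue mass carried on the C-alpha
    stringsAsFactors = FALSE
  )
  # remove lipids whose head is within radius of the axis (min-image, in-plane)
  heads <- a[a$name %in% c("P", "O3"), ]
  d2 <- min_image(heads$x - cx, system$box[1])^2 +
        min_image(heads$y - cy, system$box[2])^2
  gone <- heads$resid[d2 < radius^2]
  removed <- table(heads$resname[heads$resid %in% gone])
  keep <- !(a$resid %in% gone)
  lip <- a[keep, ]
  lip$class <- NULL  # reclassified by the constructor
  lip$id <- lip$id + n_residues
  atoms <- rbind(prot, lip)
  out <- molecular_system(atoms, system$box)
  out$meta <- c(system$meta, list(removed = removed, n_protein_residues = n_residues))
  out
}

#' Analytic leaflet surface deformations
#'
#' \code{surface_flat()} leaves the bilayer unchanged. A Gaussian bump
#' displaces headgroups by \code{A * exp(-r^2 / (2 sigma^2))} along z.
#' A spherical cap places headgroups within \code{r_cap} of the centre
#' exactly on a sphere of radius R (apex displacement
#' \code{sqrt(R^2 - r^2) - sqrt(R^2 - r_cap^2)} rescaled to meet the rim), and
#' blends smoothly to zero over \code{[r_cap, r_cap + taper]} with a cosine
#' ramp so the field is continuous across the periodic box.
#'
#' @param A bump amplitude (Angstrom; sign = outward for the top leaflet).
#' @param sigma bump width (Angstrom, > 0).
#' @param R sphere radius (Angstrom, > 0).
#' @param r_cap in-plane radius of the exact spherical region (Angstrom).
#' @param taper width of the cosine blending annulus (Angstrom).
#' @param center length-2 xy centre, or NULL for the box centre.
#' @param leaflet \code{"top"}, \code{"bottom"} or \code{"both"}.
#' @param outward logical: TRUE displaces away from the bilayer centre
#'   (expansion), FALSE toward it.
#' @return a \code{surface_deformation} object.
#' @name deformations
NULL

#' @rdname deformations
#' @export
surface_flat <- function() {
  structure(list(kind = "flat"), class = "surface_deformation")
}

#' @rdname deformations
#' @export
surface_gaussian_bump <- function(A, sigma, center = NULL, leaflet = "top",
                                  outward = TRUE) {
  if (sigma <= 0) stopf("sigma must be > 0")
  structure(list(kind = "gaussian_bump", A = A, sigma = sigma, center = center,
                 leaflet = leaflet, outward = outward),
            class = "surface_deformation")
}

#' @rdname deformations
#' @export
surface_spherical_cap <- function(R, r_cap = 0.5 * R, taper = 0.4 * R,
                                  center = NULL, leaflet = "top",
                                  outward = TRUE) {
  if (R <= 0) stopf("R must be > 0")
  if (r_cap >= R) stopf("r_cap must be < R")
  structure(list(kind = "spherical_cap", R = R, r_cap = r_cap, taper = taper,
                 center = center, leaflet = leaflet, outward = outward),
            class = "surface_deformation")
}

# height field h(r) of a deformation (positive = along the leaflet's outward z)
deformation_height <- function(def, r) {
  switch(def$kind,
    flat = rep(0, length(r)),
    gaussian_bump = def$A * exp(-r^2 / (2 * def$sigma^2)),
    spherical_cap = {
      rim <- sqrt(def$R^2 - def$r_cap^2)
      h <- numeric(length(r))
      core <- r <= def$r_cap
      h[core] <- sqrt(def$R^2 - r[core]^2) - rim
      ann <- r > def$r_cap & r < def$r_cap + def$taper
      if (any(ann)) {
        # cosine ramp from the rim height derivative region down to zero
        hc <- sqrt(pmax(def$R^2 - r[ann]^2, 0)) - rim
        w <- 0.5 * (1 + cos(pi * (r[ann] - def$r_cap) / def$taper))
        h[ann] <- hc * w
      }
      h
    },
    stopf("unknown deformation kind '%s'", def$kind)
  )
}

#' Apply an analytic surface deformation to a bilayer system
#'
#' Headgroup z coordinates are displaced by the deformation's height field;
#' each lipid's tail atoms follow rigidly. Displacement is applied along the
#' leaflet's outward normal when \code{outward = TRUE} (membrane expansion),
#' else toward the bilayer centre.
#'
#' @param system a bilayer \code{\link{molecular_system}}.
#' @param deformation a \code{surface_deformation}.
#' @return the deformed system.
#' @export
apply_deformation <- function(system, deformation) {
  if (deformation$kind == "flat") return(system)
  a <- system$atoms
  ctr <- deformation$center %||% (system$box[1:2] / 2)
  heads <- a$name %in% c("P", "O3")
  # leaflet of each lipid residue from its headgroup z sign
  head_z <- a$z[heads]
  head_res <- a$resid[heads]
  head_chain <- a$chain[heads]
  leaf <- ifelse(head_z >= mean(head_z), "top", "bottom")
  use <- if (deformation$leaflet == "both") rep(TRUE, length(leaf))
         else leaf == deformation$leaflet
  key_all <- paste(a$chain, a$resid)
  key_head <- paste(head_chain, head_res)[use]
  r <- sqrt(min_image(a$x[heads][use] - ctr[1], system$box[1])^2 +
            min_image(a$y[heads][use] - ctr[2], system$box[2])^2)
  h <- deformation_height(deformation, r)
  sgn <- ifelse(leaf[use] == "top", 1, -1)
  if (!deformation$outward) sgn <- -sgn
  dz <- h * sgn
  shift <- dz[match(key_all, key_head)]
  shift[is.na(shift)] <- 0
  a$z <- a$z + shift
  system$atoms <- a
  system
}

#' Contact schedule for scripted protein-lipid encounters
#'
#' During \code{[from, to)} (0-based frame indices) the lipid is placed so its
#' minimum distance to the named protein residue is at most 4 Angstrom; outside
#' the interval it is held at least 8 Angstrom away.
#'
#' @param protein_resid,lipid_resid residue ids (protein chain "P", lipid
#'   chain "L").
#' @param from,to 0-based frame interval, half-open.
#' @return data.frame with one row per scheduled episode.
#' @export
contact_schedule <- function(protein_resid, lipid_resid, from, to) {
  data.frame(protein_resid = protein_resid, lipid_resid = lipid_resid,
             from = from, to = to)
}

#' Motion model for synthetic trajectories
#'
#' @param jitter Gaussian positional jitter amplitude per coordinate
#'   (Angstrom; 0 freezes the system).
#' @param schedule optional \code{\link{contact_schedule}} rows.
#' @param jitter_selection optional atom indices the jitter applies to
#'   (default all atoms).
#' @return a \code{motion_model} object.
#' @export
motion_model <- function(jitter = 0.5, schedule = NULL, jitter_selection = NULL) {
  structure(list(jitter = jitter, schedule = schedule,
                 jitter_selection = jitter_selection),
            class = "motion_model")
}

#' Generate a synthetic trajectory
#'
#' Frame 1 (time 0) is the input coordinates exactly; later frames add seeded
#' zero-mean Gaussian jitter. Scheduled contacts override the scheduled
#' lipid's position every frame: within the interval its headgroup sits
#' 3 Angstrom from the partner residue; outside, 12 Angstrom away (so the
#' 4 / 8 Angstrom guarantees hold under jitter up to 0.3 Angstrom, to which
#' scheduled lipids are clamped).
#'
#' @param system a \code{\link{molecular_system}} (protein embedded if the
#'   schedule references protein residues).
#' @param n_frames number of frames.
#' @param motion a \code{\link{motion_model}}.
#' @param seed integer seed.
#' @param dt frame stride in ps (default 200).
#' @return a \code{\link{frame_stream}}.
#' @export
simulate_frames <- function(system, n_frames, motion = motion_model(),
                            seed = 1, dt = 200) {
  if (n_frames < 1) stopf("n_frames must be >= 1")
  sch <- motion$schedule
  if (!is.null(sch)) {
    if (any(sch$from < 0 | sch$to > n_frames | sch$from >= sch$to))
      stopf("schedule intervals must lie within [0, n_frames)")
    # conflict: same lipid scheduled to two different partners at the same time
    for (lid in unique(sch$lipid_resid)) {
      rows <- sch[sch$lipid_resid == lid, ]
      if (nrow(rows) > 1) {
        for (p in seq_len(nrow(rows) - 1)) for (q in (p + 1):nrow(rows)) {
          if (rows$from[p] < rows$to[q] && rows$from[q] < rows$to[p] &&
              rows$protein_resid[p] != rows$protein_resid[q])
            stopf("schedule conflict: lipid %d has overlapping incompatible intervals", lid)
        }
      }
    }
  }
  set.seed(seed)
  base <- coords(system)
  n_atoms <- nrow(base)
  a <- system$atoms
  arr <- array(0, dim = c(n_atoms, 3, n_frames))
  jit_idx <- motion$jitter_selection %||% seq_len(n_atoms)
  sched_prot_atoms <- which(a$chain == "P" & a$resid %in% unique(sch$protein_resid))
  for (k in seq_len(n_frames)) {
    xyz <- base
    if (motion$jitter > 0 && k > 1) {
      jit <- matrix(stats::rnorm(3 * length(jit_idx), 0, motion$jitter), ncol = 3)
      xyz[jit_idx, ] <- xyz[jit_idx, ] + jit
    }
    if (length(sched_prot_atoms)) {
      # clamp scheduled anchor residues' jitter so distance guarantees hold
      xyz[sched_prot_atoms, ] <- base[sched_prot_atoms, ] +
        pmin(pmax(xyz[sched_prot_atoms, , drop = FALSE] -
                    base[sched_prot_atoms, , drop = FALSE], -0.3), 0.3)
    }
    if (!is.null(sch)) {
      f0 <- k - 1  # 0-based index of this frame
      for (srow in seq_len(nrow(sch))) {
        lid <- sch$lipid_resid[srow]
        pid <- sch$protein_resid[srow]
        lat <- which(a$chain == "L" & a$resid == lid)
        pat <- which(a$chain == "P" & a$resid == pid)
        if (!length(lat) || !length(pat))
          stopf("schedule references missing residue (protein %d / lipid %d)", pid, lid)
        inside <- f0 >= sch$from[srow] && f0 < sch$to[srow]
        other <- sch$lipid_resid == lid & seq_len(nrow(sch)) != srow &
                 f0 >= sch$from & f0 < sch$to
        if (!inside && any(other)) next  # another episode of this lipid is active
        anchor <- base[pat[1], ]
        dist <- if (inside) 3 else 12
        # horizontal direction pointing outward from the protein axis through
        # the anchor (so the lipid cannot graze other residues), with a small
        # per-pair angular offset to keep concurrent partners apart
        ctr <- system$box[1:2] / 2
        u <- anchor[1:2] - ctr
        if (sqrt(sum(u^2)) < 1e-6) u <- c(1, 0)
        u <- u / sqrt(sum(u^2))
        delta <- (((lid * 53 + pid * 17) %% 45) - 22) * pi / 180
        rot <- matrix(c(cos(delta), -sin(delta), sin(delta), cos(delta)), 2, 2)
        head <- anchor + dist * c(rot %*% u, 0)
        off <- sweep(base[lat, , drop = FALSE], 2, base[lat[1], ])
        xyz[lat, ] <- sweep(off, 2, head, "+")
      }
    }
    arr[, , k] <- xyz
  }
  frame_stream(arr, system$box, dt = dt)
}

#' Scripted secondary-structure label plans
#'
#' A plan is a list of groups; each group fixes, for a set of residues, the
#' per-frame label fractions, either deterministically (exact counts via
#' largest-remainder apportionment, labels laid out in contiguous blocks) or
#' stochastically (i.i.d. multinomial draws). Residues in no group default to
#' all-coil.
#'
#' @param residues integer vector of residue indices (rows of the matrix).
#' @param probs named numeric vector over \{H, E, T, C\}, summing to 1.
#' @param mode \code{"deterministic"} or \code{"stochastic"}.
#' @return a plan group, to be collected in a list.
#' @export
ss_plan <- function(residues, probs, mode = c("deterministic", "stochastic")) {
  mode <- match.arg(mode)
  if (abs(sum(probs) - 1) > 1e-9) stopf("probs must sum to 1")
  if (!all(names(probs) %in% c("H", "E", "T", "C")))
    stopf("labels must be among H, E, T, C")
  list(residues = residues, probs = probs, mode = mode)
}

# exact integer apportionment by largest remainder
apportion <- function(probs, n) {
  raw <- probs * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  base
}

#' Emit a scripted secondary-structure label matrix
#'
#' @param n_residues,n_frames matrix dimensions.
#' @param plan list of \code{\link{ss_plan}} groups.
#' @param seed seed (used by stochastic groups only).
#' @return a residues x frames character matrix of labels in \{H, E, T, C\}
#'   (class \code{label_matrix}).
#' @export
emit_ss_labels <- function(n_residues, n_frames, plan, seed = 1) {
  if (n_frames < 1) stopf("n_frames must be >= 1")
  set.seed(seed)
  m <- matrix("C", n_residues, n_frames)
  for (g in plan) {
    if (any(g$residues < 1 | g$residues > n_residues))
      stopf("plan references residues outside 1..%d", n_residues)
    if (g$mode == "deterministic") {
      counts <- apportion(g$probs, n_frames)
      row <- rep(names(g$probs), counts)
      for (r in g$residues) m[r, ] <- row
    } else {
      for (r in g$residues)
        m[r, ] <- sample(names(g$probs), n_frames, replace = TRUE, prob = g$probs)
    }
  }
  class(m) <- c("label_matrix", class(m))
  m
}
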