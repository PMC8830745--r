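# Fixture builders and independent oracles shared across test files.
# Everything is generated in code at test time; nothing binary on disk.

# --- tiny structure files -----------------------------------------------------

write_water_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1           1",
    "HETATM    1  OH2 HOH A   1      10.000  10.000  10.000  1.00  0.00",
    "HETATM    2  H1  HOH A   1      10.800  10.200  10.000  1.00  0.00",
    "HETATM    3  H2  HOH A   1       9.500  10.700  10.300  1.00  0.00",
    "END"), path)
  path
}

write_popc_gro <- function(path = tempfile(fileext = ".gro")) {
  writeLines(c(
    "one POPC stub",
    "    3",
    "    1POPC    P     1   1.000   1.000   2.080",
    "    1POPC   C1     2   1.000   1.000   1.680",
    "    1POPC   C2     3   1.000   1.000   1.280",
    "   4.00000   4.00000   5.00000"), path)
  path
}

# --- independent quaternion superposition oracle ------------------------------

# Horn's closed-form quaternion method; algebraically unrelated to the SVD
# route used by kabsch_superpose().
quaternion_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  M <- t(P) %*% Q
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  Kq <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(Kq, symmetric = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

# --- independent basin-assignment oracle --------------------------------------

# naive per-point steepest-ascent on a density grid (one point at a time,
# following the single best 8-neighbour, ties to the lower linear index)
naive_basins <- function(rho, ixy) {
  nx <- nrow(rho); ny <- ncol(rho)
  climb <- function(i, j) {
    repeat {
      best <- c(i, j); bestv <- rho[i, j]
      for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
        better <- rho[ii, jj] > bestv ||
          (rho[ii, jj] == bestv &&
             (jj - 1) * nx + ii < (best[2] - 1) * nx + best[1])
        if (better) { best <- c(ii, jj); bestv <- rho[ii, jj] }
      }
      if (best[1] == i && best[2] == j) return((j - 1) * nx + i)
      i <- best[1]; j <- best[2]
    }
  }
  vapply(seq_len(nrow(ixy)), function(r) climb(ixy[r, 1], ixy[r, 2]), numeric(1))
}

# --- peptide backbone builder (NeRF internal coordinates) ---------------------

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

place_atom <- function(A, B, C, r, theta, chi) {
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(B - A, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  th <- theta * pi / 180; ch <- chi * pi / 180
  d <- c(-r * cos(th), r * sin(th) * cos(ch), -r * sin(th) * sin(ch))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# build an N/CA/C backbone with the given per-residue (phi, psi); omega 180
build_peptide <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  N <- CA <- C <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- place_atom(c(0, 1, 0), N[1, ], CA[1, ], 1.525, 111.2, -60)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi[i])
  }
  atoms <- data.frame(
    id = seq_len(3 * n),
    name = rep(c("N", "CA", "C"), n),
    resid = rep(seq_len(n), each = 3),
    resname = "ALA",
    chain = "P",
    x = as.vector(rbind(N[, 1], CA[, 1], C[, 1])),
    y = as.vector(rbind(N[, 2], CA[, 2], C[, 2])),
    z = as.vector(rbind(N[, 3], CA[, 3], C[, 3])),
    stringsAsFactors = FALSE
  )
  span <- apply(atoms[, c("x", "y", "z")], 2, function(v) diff(range(v)))
  atoms$x <- atoms$x - min(atoms$x) + 5
  atoms$y <- atoms$y - min(atoms$y) + 5
  atoms$z <- atoms$z - min(atoms$z) + 5
  molecular_system(atoms, span + 10)
}

# ideal straight alpha-helix C-alpha trace: radius 2.3 A, 100 deg/residue,
# rise 1.5 A/residue along +z
ideal_helix_ca <- function(n, rise = 1.5, radius = 2.3, twist = 100) {
  th <- (seq_len(n) - 1) * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), (seq_len(n) - 1) * rise)
}

# random small two-species system for contact-search equivalence tests
random_contact_system <- function(seed, n_prot = 5, n_lip = 12, box = c(30, 30, 30)) {
  set.seed(seed)
  n_pa <- n_prot * 2
  prot <- data.frame(
    id = seq_len(n_pa), name = rep(c("CA", "CB"), n_prot),
    resid = rep(seq_len(n_prot), each = 2), resname = "ALA", chain = "P",
    x = runif(n_pa, 0, box[1]), y = runif(n_pa, 0, box[2]),
    z = runif(n_pa, 0, box[3]), stringsAsFactors = FALSE)
  n_la <- n_lip * 3
  lip <- data.frame(
    id = n_pa + seq_len(n_la), name = rep(c("P", "C1", "C2"), n_lip),
    resid = rep(seq_len(n_lip), each = 3), resname = "POPC", chain = "L",
    x = runif(n_la, 0, box[1]), y = runif(n_la, 0, box[2]),
    z = runif(n_la, 0, box[3]), stringsAsFactors = FALSE)
  molecular_system(rbind(prot, lip), box)
}

# small bilayer + protein used by several field tests
small_membrane <- function(seed = 11, comp = c(POPC = 128, CHL = 16),
                           box = c(80, 80)) {
  build_bilayer(bilayer_spec(composition = comp, box_xy = box), seed = seed)
}
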