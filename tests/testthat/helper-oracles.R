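## Brute-force rotation-grid oracle for aligned RMSD, independent of the
## SVD-based Kabsch path: enumerates axis-angle rotations on a regular
## grid (axes on a theta/phi sphere grid, angles up to 180 degrees) and
## minimizes the centered RMSD via the trace identity
## ||A - B R'||^2 = ||A||^2 + ||B||^2 - 2 tr(R H),  H = B' A.
## A second enumeration pass refines a fine local grid around the coarse
## optimum, since near 180-degree angles the rotation-space resolution of
## a parameter grid is coarser than its nominal step.

## rows of rotation matrices (column-major as length-9 vectors) for all
## combinations of the given axis angles (th, ph) and rotation angles
rot_block <- function(th, ph, ang) {
  ax <- expand.grid(th = th, ph = ph)
  ux <- sin(ax$th) * cos(ax$ph)
  uy <- sin(ax$th) * sin(ax$ph)
  uz <- cos(ax$th)
  n_an <- length(ang)
  ux <- rep(ux, times = n_an)
  uy <- rep(uy, times = n_an)
  uz <- rep(uz, times = n_an)
  aa <- rep(ang, each = nrow(ax))
  ca <- cos(aa); sa <- sin(aa); vc <- 1 - ca
  list(G = cbind(ca + ux * ux * vc, uy * ux * vc + uz * sa,
                 uz * ux * vc - uy * sa,
                 ux * uy * vc - uz * sa, ca + uy * uy * vc,
                 uz * uy * vc + ux * sa,
                 ux * uz * vc + uy * sa, uy * uz * vc - ux * sa,
                 ca + uz * uz * vc),
       th = rep(ax$th, times = n_an), ph = rep(ax$ph, times = n_an),
       ang = aa)
}

rotation_grid <- function(step_deg = 2) {
  s <- step_deg * pi / 180
  rot_block(seq(0, pi, by = s), seq(0, 2 * pi - s, by = s),
            seq(0, pi, by = s))       # angle 0 included (identity)
}

grid_min_rmsd <- function(a, b, grid, refine_deg = 0.2) {
  A <- sweep(a, 2, colMeans(a))
  B <- sweep(b, 2, colMeans(b))
  H <- crossprod(B, A)
  hv <- as.vector(t(H))
  sc <- grid$G %*% hv
  i <- which.max(sc)
  best <- sc[i]
  # fine local pass around the coarse optimum
  s <- refine_deg * pi / 180
  wide <- 12L
  loc <- rot_block(grid$th[i] + s * (-wide:wide),
                   grid$ph[i] + s * (-wide:wide),
                   pmin(pi, pmax(0, grid$ang[i] + s * (-wide:wide))))
  best <- max(best, max(loc$G %*% hv))
  sqrt(max(0, (sum(A^2) + sum(B^2) - 2 * best) / nrow(a)))
}

## random atoms x 3 frame
rand_frame <- function(n_atoms, sd = 1) matrix(rnorm(n_atoms * 3, 0, sd),
                                               n_atoms, 3)

## rigid motion: rotate about z by angle, then translate
rigid_move <- function(frame, angle, shift = c(0, 0, 0)) {
  Rz <- matrix(c(cos(angle), sin(angle), 0,
                 -sin(angle), cos(angle), 0,
                 0, 0, 1), 3, 3)
  sweep(frame %*% t(Rz), 2, -shift)
}

## single-atom 1-D trajectory from x positions
traj_1d <- function(xs, dt = 1) {
  coords <- array(0, c(length(xs), 1L, 3L))
  coords[, 1L, 1L] <- xs
  new_trajectory(coords, frame_spacing_ps = dt)
}

## constant-coordinates trajectory (every frame identical)
constant_traj <- function(n_frames = 50L, n_atoms = 20L, seed = 1L) {
  fr <- withr::with_seed(seed, rand_frame(n_atoms))
  coords <- array(0, c(n_frames, n_atoms, 3L))
  for (i in seq_len(n_frames)) coords[i, , ] <- fr
  new_trajectory(coords, frame_spacing_ps = 1)
}

## write a small multi-model PDB by hand
write_toy_pdb <- function(path, frames, labels = NULL) {
  na <- nrow(frames[[1L]])
  if (is.null(labels)) labels <- c("N", "CA", "C", "O", "CB")[seq_len(na)]
  lines <- character(0)
  for (m in seq_along(frames)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    fr <- frames[[m]]
    for (i in seq_len(nrow(fr)))
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        i, labels[i], 1L, fr[i, 1L], fr[i, 2L], fr[i, 3L],
        substr(labels[i], 1L, 1L)))
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}
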