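# mesh and volume fixtures built in code

# regular triangulated grid in the xy-plane (or offset in z)
grid_mesh <- function(nx, ny, spacing = 1, z = 0) {
  v <- cbind(rep((seq_len(nx) - 1) * spacing, times = ny),
             rep((seq_len(ny) - 1) * spacing, each = nx),
             z)
  gi <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  tri <- rbind(cbind(gi(i, j), gi(i + 1L, j), gi(i + 1L, j + 1L)),
               cbind(gi(i, j), gi(i + 1L, j + 1L), gi(i, j + 1L)))
  surface_mesh(v, tri)
}

# closed cylinder tube of radius r about the y axis (open ends)
cylinder_mesh <- function(radius = 10, n_theta = 64, n_y = 40, length = 30) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  yy <- seq(0, length, length.out = n_y)
  v <- cbind(rep(radius * cos(th), times = n_y),
             rep(yy, each = n_theta),
             rep(radius * sin(th), times = n_y))
  gi <- function(i, j) (j - 1L) * n_theta + i
  i <- rep(seq_len(n_theta), times = n_y - 1L)
  j <- rep(seq_len(n_y - 1L), each = n_theta)
  ip <- ifelse(i == n_theta, 1L, i + 1L)
  tri <- rbind(cbind(gi(i, j), gi(i, j + 1L), gi(ip, j)),
               cbind(gi(ip, j), gi(i, j + 1L), gi(ip, j + 1L)))
  surface_mesh(v, tri)
}

# flat parallel slab pair: pial at z = z_top, white at z = z_top - thickness
slab_pair <- function(nx = 8, ny = 8, spacing = 0.5, z_top = 2,
                      thickness = 2) {
  pial <- grid_mesh(nx, ny, spacing, z = z_top)
  white <- grid_mesh(nx, ny, spacing, z = z_top - thickness)
  surface_pair(white = white, pial = pial)
}

# volume with intensity a + b*x + c*y + d*z (mm world coordinates)
ramp_volume <- function(dim = c(16, 16, 16), voxel_size_um = 250,
                        coef = c(0, 0, 0, 1)) {
  vs <- voxel_size_um / 1000
  x <- (seq_len(dim[1]) - 1) * vs
  y <- (seq_len(dim[2]) - 1) * vs
  z <- (seq_len(dim[3]) - 1) * vs
  arr <- coef[1] +
    coef[2] * array(rep(x, times = dim[2] * dim[3]), dim) +
    coef[3] * array(rep(rep(y, each = dim[1]), times = dim[3]), dim) +
    coef[4] * array(rep(z, each = dim[1] * dim[2]), dim)
  intensity_volume(arr, voxel_size_um)
}
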