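# Small fixture builders shared across tests. Everything is generated in
# code; no binary fixtures.

# Centered sphere phantom on an odd grid so the sphere centre coincides
# with a voxel centre (the placement convention of the recovery study).
sphere_spec <- function(r_mm, grid = 49L, spacing = 2, contrast = 50,
                        psf_sigma = 1, seed = 1L) {
  phantom_spec(
    grid_shape = rep(grid, 3L), voxel_spacing = rep(spacing, 3),
    adenoma_center = c(0, 0, 0), adenoma_radii = rep(r_mm, 3),
    thyroid_lobes = list(),
    uptake_early = c(adenoma = contrast, thyroid = (contrast + 1) / 2, background = 1),
    psf_sigma = psf_sigma, seed = seed
  )
}

# Tiny uniform volume for noise tests.
uniform_volume <- function(value = 50, n = 12L, spacing = 2) {
  activity_volume(array(value, dim = rep(n, 3L)), rep(spacing, 3))
}

# Independent ray-sum oracle: projected ROI-mean ratio computed directly
# from the 3-D ground-truth counts with explicit loops, bypassing
# project_planar / roi_mean.
ray_sum_ratio_oracle <- function(counts3d, roi_a, roi_b) {
  ray <- function(px) {
    v <- numeric(nrow(px))
    for (i in seq_len(nrow(px))) {
      z <- px[i, 1]; x <- px[i, 2]   # planar (row, col) = (z, x)
      s <- 0
      for (y in seq_len(dim(counts3d)[2])) s <- s + counts3d[x, y, z]
      v[i] <- s
    }
    mean(v)
  }
  ray(roi_a$pixels) / ray(roi_b$pixels)
}

# Independent connected-component oracle: label propagation by repeated
# 26-neighbourhood dilation of the peak seed until fixpoint.
flood_fill_oracle <- function(counts, thr, peak_loc) {
  n <- dim(counts)
  mask <- counts >= thr
  lab <- array(FALSE, dim = n)
  lab[matrix(peak_loc, ncol = 3)] <- TRUE
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  repeat {
    grown <- lab
    idx <- which(lab)
    ijk <- arrayInd(idx, n)
    for (o in seq_len(nrow(offs))) {
      nb <- sweep(ijk, 2, offs[o, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= n[1] & nb[, 2] >= 1 & nb[, 2] <= n[2] &
        nb[, 3] >= 1 & nb[, 3] <= n[3]
      nb <- nb[ok, , drop = FALSE]
      grown[nb] <- grown[nb] | mask[nb]
    }
    if (identical(grown, lab)) break
    lab <- grown
  }
  m <- arrayInd(which(lab), n)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

sorted_voxels <- function(voi) {
  v <- unname(voi$voxels)
  v[order(v[, 1], v[, 2], v[, 3]), , drop = FALSE]
}

# All-pairs tie-corrected Mann-Whitney oracle for the AUC identity.
u_statistic_oracle <- function(pos, neg) {
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Rank-then-Pearson Spearman oracle with hand-rolled mid-ranks.
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
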