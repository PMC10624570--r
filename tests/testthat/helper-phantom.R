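# Desk-scale anatomy presets used across tests: same physical field of view
# as the clinical-scale default (~96 mm), coarser voxels.

anatomy24 <- function(...) {
  anatomy_params(grid_shape = c(24, 24, 24), spacing_mm = c(4, 4, 4), ...)
}

anatomy16 <- function(...) {
  anatomy_params(grid_shape = c(16, 16, 16), spacing_mm = c(6, 6, 6),
                 rectum_z_extent = c(20, 70), ...)
}

cube_mask <- function(d, lo, hi) {
  m <- array(0, d)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  m
}

# independent brute-force trilinear sampler with border clamping
brute_trilinear_warp <- function(data, u_vox) {
  d <- dim(data)
  out <- array(0, d)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    p <- c(x - 1 + u_vox[x, y, z, 1], y - 1 + u_vox[x, y, z, 2],
           z - 1 + u_vox[x, y, z, 3])
    p <- pmin(pmax(p, 0), d - 1)
    i0 <- pmin(floor(p), d - 2)
    t <- p - i0
    acc <- 0
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      w <- prod(ifelse(c(cx, cy, cz) == 1, t, 1 - t))
      acc <- acc + w * data[i0[1] + cx + 1, i0[2] + cy + 1, i0[3] + cz + 1]
    }
    out[x, y, z] <- acc
  }
  out
}

# brute-force directed surface distances (pairwise, exact)
brute_surface_distances <- function(a, b, spacing) {
  surf <- function(m) {
    d <- dim(m)
    idx <- which(m == 1, arr.ind = TRUE)
    keep <- logical(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]
      nb <- rbind(v + c(1, 0, 0), v - c(1, 0, 0), v + c(0, 1, 0),
                  v - c(0, 1, 0), v + c(0, 0, 1), v - c(0, 0, 1))
      bg <- FALSE
      for (k in 1:6) {
        w <- nb[k, ]
        if (any(w < 1) || any(w > d)) { bg <- TRUE; break }
        if (m[w[1], w[2], w[3]] == 0) { bg <- TRUE; break }
      }
      keep[r] <- bg
    }
    idx[keep, , drop = FALSE]
  }
  sa <- sweep(surf(a), 2, spacing, `*`)
  sb <- sweep(surf(b), 2, spacing, `*`)
  dmat <- outer(seq_len(nrow(sa)), seq_len(nrow(sb)),
                Vectorize(function(i, j) sqrt(sum((sa[i, ] - sb[j, ])^2))))
  list(a_to_b = apply(dmat, 1, min), b_to_a = apply(dmat, 2, min))
}
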