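# fixture builders shared across the image-core tests

# straight axis-aligned tube through the middle of an isotropic-or-not grid
test_tube <- function(radius = 3, spacing = 1, shape = NULL,
                      length_mm = NULL, noise = 0L, seed = 1L) {
  if (is.null(shape)) {
    half <- ceiling((radius + 2 * max(spacing)) / min(spacing))
    nz <- ceiling((if (is.null(length_mm)) 8 * radius else length_mm) /
                    (if (length(spacing) == 3) spacing[3] else spacing)) + 4
    shape <- c(2 * half + 1, 2 * half + 1, nz)
  }
  g <- grid_spec(shape, spacing)
  ext <- (g$shape - 1) * g$spacing
  ctr <- ext / 2
  seg <- list(list(start = c(ctr[1], ctr[2], 0.08 * ext[3]),
                   end = c(ctr[1], ctr[2], 0.92 * ext[3]),
                   radius = radius))
  make_tube_phantom(phantom_spec(seg, g, noise_voxel_count = noise,
                                 seed = seed))
}

# a random multi-tube phantom for property tests
random_tube_phantom <- function(seed, shape = c(20, 20, 20), spacing = 1) {
  set.seed(seed)
  g <- grid_spec(shape, spacing)
  ext <- (g$shape - 1) * g$spacing
  nseg <- sample(1:2, 1)
  segs <- lapply(seq_len(nseg), function(i) {
    axis <- sample(1:3, 1)
    a <- runif(3, 0.3, 0.7) * ext
    b <- a
    a[axis] <- 0.12 * ext[axis]
    b[axis] <- 0.88 * ext[axis]
    list(start = a, end = b,
         radius = runif(1, max(spacing) * 1.1, max(spacing) * 2.5))
  })
  make_tube_phantom(phantom_spec(segs, g, noise_voxel_count = 0L,
                                 seed = seed))
}

# random blob mask for distance-transform property tests
random_mask <- function(seed, max_dim = 16, spacing = c(0.7, 0.7, 0.7),
                        p_fg = NULL) {
  set.seed(seed)
  shape <- sample(5:max_dim, 3, replace = TRUE)
  if (is.null(p_fg)) p_fg <- runif(1, 0.2, 0.8)
  arr <- array(as.integer(runif(prod(shape)) < p_fg), dim = shape)
  if (all(arr == 1L)) arr[1, 1, 1] <- 0L # keep a boundary
  binary_volume(arr, grid_spec(shape, spacing))
}

# 26-connected component count of a binary array (flood fill)
count_components26 <- function(arr) {
  dims <- dim(arr)
  lab <- array(0L, dims)
  ncomp <- 0L
  idx <- which(arr == 1L)
  for (start in idx) {
    if (lab[start] > 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    lab[start] <- ncomp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, dims)
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        i <- ci[1] + dx; j <- ci[2] + dy; k <- ci[3] + dz
        if (i < 1 || j < 1 || k < 1 ||
            i > dims[1] || j > dims[2] || k > dims[3]) next
        if (arr[i, j, k] == 1L && lab[i, j, k] == 0L) {
          lab[i, j, k] <- ncomp
          queue <- c(queue, (k - 1) * dims[1] * dims[2] + (j - 1) * dims[1] + i)
        }
      }
    }
  }
  ncomp
}

centerline_to_array <- function(cl) {
  arr <- array(0L, cl$grid$shape)
  if (nrow(cl$voxels)) arr[cl$voxels] <- 1L
  arr
}
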