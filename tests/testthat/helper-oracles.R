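# independent oracles: brute-force EDT, NIPALS PLS, and the reference
# 3-D thinning from scikit-image (called through python on tiny fixtures)

# O(n^2) exact nearest-background-center search
brute_edt <- function(mask) {
  arr <- mask$data
  sp <- mask$grid$spacing
  dims <- dim(arr)
  all_idx <- arrayInd(seq_len(prod(dims)), dims)
  world <- sweep(all_idx - 1, 2, sp, "*")
  bg <- world[arr == 0L, , drop = FALSE]
  out <- numeric(prod(dims))
  fg_lin <- which(arr == 1L)
  for (v in fg_lin) {
    d2 <- (bg[, 1] - world[v, 1])^2 + (bg[, 2] - world[v, 2])^2 +
      (bg[, 3] - world[v, 3])^2
    out[v] <- sqrt(min(d2))
  }
  array(out, dims)
}

# classic NIPALS PLS2 on preprocessed (centered X, normalized Y) matrices;
# deliberately a different algorithm from the kernel implementation
nipals_pls <- function(Xp, Yp, k, tol = 1e-12, maxit = 500) {
  Xp <- as.matrix(Xp); Yp <- as.matrix(Yp)
  p <- ncol(Xp); q <- ncol(Yp)
  W <- P <- matrix(0, p, k)
  Q <- matrix(0, q, k)
  Tm <- matrix(0, nrow(Xp), k)
  X <- Xp; Y <- Yp - matrix(colMeans(Yp), nrow(Yp), q, byrow = TRUE)
  for (a in seq_len(k)) {
    u <- Y[, which.max(apply(Y, 2, var))]
    t_old <- rep(Inf, nrow(X))
    for (it in seq_len(maxit)) {
      w <- crossprod(X, u); w <- w / sqrt(sum(w^2))
      tt <- X %*% w
      qv <- crossprod(Y, tt) / drop(crossprod(tt))
      u <- Y %*% qv / drop(crossprod(qv))
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    pv <- crossprod(X, tt) / drop(crossprod(tt))
    qv <- crossprod(Y, tt) / drop(crossprod(tt))
    X <- X - tt %*% t(pv)
    Y <- Y - tt %*% t(qv)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; Tm[, a] <- tt
  }
  beta <- W %*% solve(crossprod(P, W), t(Q))
  list(beta = beta, scores = Tm)
}

# reference 3-D skeletonization (Lee et al. thinning) via scikit-image;
# masks travel as flat text files, several fixtures per python call
skimage_skeletonize <- function(masks) {
  stopifnot(is.list(masks))
  tmp_in <- tempfile(fileext = ".txt")
  tmp_out <- tempfile(fileext = ".txt")
  con <- file(tmp_in, "w")
  writeLines(as.character(length(masks)), con)
  for (m in masks) {
    writeLines(paste(dim(m), collapse = " "), con)
    writeLines(paste(as.integer(m), collapse = " "), con)
  }
  close(con)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "from skimage.morphology import skeletonize",
    "inp, outp = sys.argv[1], sys.argv[2]",
    "with open(inp) as f:",
    "    nm = int(f.readline())",
    "    out = []",
    "    for _ in range(nm):",
    "        dims = [int(x) for x in f.readline().split()]",
    "        flat = np.array(f.readline().split(), dtype=np.uint8)",
    "        arr = flat.reshape(dims, order='F')",
    "        sk = skeletonize(arr.astype(bool)).astype(np.uint8)",
    "        out.append(' '.join(map(str, sk.flatten(order='F'))))",
    "with open(outp, 'w') as f:",
    "    f.write('\\n'.join(out) + '\\n')"), script)
  status <- system2("python", c(script, tmp_in, tmp_out),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("python scikit-image oracle failed")
  lines <- readLines(tmp_out)
  lapply(seq_along(masks), function(i)
    array(as.integer(strsplit(lines[i], " ")[[1]]), dim = dim(masks[[i]])))
}

have_python_skimage <- function() {
  nzchar(Sys.which("python")) &&
    system2("python", c("-c", shQuote("import skimage")),
            stdout = FALSE, stderr = FALSE) == 0
}

# symmetric Hausdorff distance between two voxel sets, in voxel steps
hausdorff_voxels <- function(a_idx, b_idx) {
  if (nrow(a_idx) == 0 || nrow(b_idx) == 0) return(Inf)
  one_way <- function(p, q) {
    max(vapply(seq_len(nrow(p)), function(i)
      sqrt(min(rowSums(sweep(q, 2, p[i, ])^2))), numeric(1)))
  }
  max(one_way(a_idx, b_idx), one_way(b_idx, a_idx))
}
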