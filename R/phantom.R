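# Synthetic inputs with known ground truth: tubular vessel phantoms on
# anisotropic grids, toy probabilistic atlases / territory / artery masks,
# and simulated risk-factor cohorts with a known linear effect structure.

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Canonical measurement names
#'
#' The 24 regional artery measurements: artery density (%) and mean
#' centerline radius (mm) per flow territory (ACA/MCA/PCA, left/right), and
#' mean radius (mm) in 12 small main-artery masks (ACA A1 L/R, ACA A2,
#' PCA L/R, MCA M1 L/R, MCA M2 L/R, ICA L/R, BA).
#'
#' @param set one of "all", "density", "territory_radius", "artery_radius".
#' @return Character vector of column names.
#' @export
measurement_names <- function(set = c("all", "density", "territory_radius",
                                      "artery_radius")) {
  set <- match.arg(set)
  density <- paste0("density_", c("ACA_L", "ACA_R", "MCA_L", "MCA_R",
                                  "PCA_L", "PCA_R"))
  tradius <- paste0("tradius_", c("ACA_L", "ACA_R", "MCA_L", "MCA_R",
                                  "PCA_L", "PCA_R"))
  aradius <- paste0("aradius_", c("ACA_A1_L", "ACA_A1_R", "ACA_A2",
                                  "PCA_L", "PCA_R", "MCA_M1_L", "MCA_M1_R",
                                  "MCA_M2_L", "MCA_M2_R", "ICA_L", "ICA_R",
                                  "BA"))
  switch(set,
         all = c(density, tradius, aradius),
         density = density,
         territory_radius = tradius,
         artery_radius = aradius)
}

#' Predictor names of the risk-factor design
#'
#' ICV (cm^3), sex (M = 1, F = 2), age (years), BMI (kg/m^2), WHR, systolic
#' blood pressure (mmHg), resting heart rate (BPM), drinks-per-day ordinal
#' category (0-5), smoking duration (years).
#'
#' @return Character vector of the 9 predictor column names.
#' @export
predictor_names <- function() {
  c("icv_cm3", "sex", "age", "bmi", "whr", "sbp", "heart_rate",
    "drinks", "smoking_years")
}

#' Specify a tubular vessel phantom
#'
#' A phantom is a set of straight capsule segments (cylinders with
#' spherical caps) of known radius rasterized onto a voxel grid, plus the
#' companion volumes the measurement pipeline needs: a toy probabilistic
#' vessel atlas (high probability on and near the true vessel, below 1%
#' elsewhere), flow-territory labels, small artery masks and an
#' intracranial mask. Optional isolated noise voxels are planted at
#' low-atlas-probability locations so the atlas refinement rule provably
#' removes exactly them.
#'
#' @param segments list of segments, each `list(start, end, radius)` with
#'   start/end world coordinates in mm and radius in mm. Every radius must
#'   resolve to at least one voxel on the coarsest axis, and both endpoints
#'   must lie inside the grid.
#' @param grid a [grid_spec()].
#' @param noise_voxel_count number of isolated stray foreground voxels to
#'   add (26-disconnected from the vessel and from each other).
#' @param seed integer; all stochastic placement flows from it.
#' @param icv_scale relative size of the intracranial ellipsoid (1 = the
#'   default ellipsoid inscribed in the grid), so simulated subjects can
#'   differ in head size.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(segments, grid, noise_voxel_count = 0L, seed = 1L,
                         icv_scale = 1) {
  if (icv_scale <= 0 || icv_scale > 1.05) stop("`icv_scale` must be in (0, 1.05]")
  if (!inherits(grid, "grid_spec")) stop("`grid` must be a grid_spec")
  if (length(segments) < 1L) stop("at least one segment is required")
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1) * grid$spacing
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    if (!all(c("start", "end", "radius") %in% names(s)))
      stop("each segment needs `start`, `end`, `radius`")
    if (s$radius <= 0 || s$radius < max(grid$spacing))
      stop(sprintf(
        "segment %d radius %.3g mm is under-resolved: must be > 0 and >= the coarsest spacing (%.3g mm)",
        i, s$radius, max(grid$spacing)))
    for (p in list(s$start, s$end))
      if (length(p) != 3 || any(p < lo) || any(p > hi))
        stop(sprintf("segment %d endpoint (%s) lies outside the grid box [%s] - [%s] mm",
                     i, paste(signif(p, 4), collapse = ", "),
                     paste(signif(lo, 4), collapse = ", "),
                     paste(signif(hi, 4), collapse = ", ")))
  }
  if (noise_voxel_count < 0) stop("`noise_voxel_count` must be >= 0")
  structure(list(segments = segments, grid = grid,
                 noise_voxel_count = as.integer(noise_voxel_count),
                 seed = as.integer(seed), icv_scale = icv_scale),
            class = "phantom_spec")
}

# distance from each row of `pts` (n x 3, mm) to segment [a, b]
point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  d <- sweep(pts, 2, a)
  if (len2 == 0) return(sqrt(rowSums(d^2)))
  t <- pmin(1, pmax(0, (d %*% ab)[, 1] / len2))
  proj <- outer(t, ab) # n x 3
  sqrt(rowSums((d - proj)^2))
}

voxel_centers <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid$origin[k] + (seq_len(grid$shape[k]) - 1) * grid$spacing[k])
  s <- grid$shape
  cbind(rep(ax[[1]], times = s[2] * s[3]),
        rep(rep(ax[[2]], each = s[1]), times = s[3]),
        rep(ax[[3]], each = s[1] * s[2]))
}

# nearest voxel index (1-based triple) for a world point
world_to_voxel <- function(p, grid) {
  pmin(grid$shape, pmax(1L, as.integer(round((p - grid$origin) / grid$spacing)) + 1L))
}

#' Generate a tube phantom
#'
#' Rasterizes the capsule segments of a [phantom_spec()] by the
#' voxel-center rule (a voxel is foreground iff its center lies within the
#' segment radius of the segment axis, inclusive), records the ground-truth
#' centerline voxels and radii, and builds the companion atlas, territory,
#' artery-mask and intracranial volumes. Deterministic given the spec seed.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom`: list with `mask` (binary_volume),
#'   `true_centerline` (list of ordered voxel index matrices, one per
#'   segment), `true_radius` (mm per segment), `noise_voxels`, `prob_atlas`,
#'   `territories`, `artery_masks`, `icv_mask`.
#' @export
make_tube_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  g <- spec$grid
  pts <- voxel_centers(g)
  n <- nrow(pts)

  dist_axis <- rep(Inf, n)   # distance to nearest segment axis
  inside <- rep(FALSE, n)    # within that segment's own radius
  for (s in spec$segments) {
    d <- point_segment_distance(pts, s$start, s$end)
    inside <- inside | (d <= s$radius)
    dist_axis <- pmin(dist_axis, d)
  }
  mask_arr <- array(as.integer(inside), dim = g$shape)

  # ground-truth centerline: voxels crossed by the axis, in order
  true_cl <- lapply(spec$segments, function(s) {
    len <- sqrt(sum((s$end - s$start)^2))
    nstep <- max(2L, ceiling(len / (min(g$spacing) / 4)))
    tt <- seq(0, 1, length.out = nstep)
    ijk <- t(vapply(tt, function(t)
      world_to_voxel(s$start + t * (s$end - s$start), g), integer(3)))
    ijk[!duplicated(ijk), , drop = FALSE]
  })

  # toy probabilistic atlas: high on/near the vessel, below 1% elsewhere
  maxrad <- max(vapply(spec$segments, function(s) s$radius, 0))
  atlas_arr <- array(ifelse(dist_axis <= maxrad + max(g$spacing), 0.95, 0.001),
                     dim = g$shape)

  # isolated noise voxels at sub-1% atlas probability, 26-disconnected
  noise_voxels <- matrix(integer(0), ncol = 3)
  if (spec$noise_voxel_count > 0) {
    # candidate: background voxel whose full 3x3x3 neighbourhood is background
    cand <- which(mask_arr == 0L & atlas_arr < 0.01)
    idx3 <- arrayInd(cand, g$shape)
    interior <- idx3[, 1] > 1 & idx3[, 1] < g$shape[1] &
                idx3[, 2] > 1 & idx3[, 2] < g$shape[2] &
                idx3[, 3] > 1 & idx3[, 3] < g$shape[3]
    cand <- cand[interior]
    idx3 <- idx3[interior, , drop = FALSE]
    has_fg_neigh <- vapply(seq_len(nrow(idx3)), function(r) {
      i <- idx3[r, 1]; j <- idx3[r, 2]; k <- idx3[r, 3]
      any(mask_arr[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)] == 1L)
    }, logical(1))
    cand <- cand[!has_fg_neigh]
    idx3 <- idx3[!has_fg_neigh, , drop = FALSE]
    picked <- with_seed(spec$seed, {
      sel <- integer(0)
      pool <- seq_along(cand)
      taken <- array(FALSE, dim = g$shape)
      while (length(sel) < spec$noise_voxel_count && length(pool) > 0) {
        p <- pool[sample.int(length(pool), 1L)]
        i <- idx3[p, 1]; j <- idx3[p, 2]; k <- idx3[p, 3]
        if (!any(taken[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)])) {
          sel <- c(sel, p)
          taken[i, j, k] <- TRUE
        }
        pool <- setdiff(pool, p)
      }
      sel
    })
    if (length(picked) < spec$noise_voxel_count)
      warning(sprintf("only %d of %d requested noise voxels could be placed",
                      length(picked), spec$noise_voxel_count))
    mask_arr[cand[picked]] <- 1L
    noise_voxels <- idx3[picked, , drop = FALSE]
  }

  # flow territories: left/right by the first axis, ACA/MCA/PCA by thirds
  # of the third axis; covers the whole grid
  ter <- array(0L, dim = g$shape)
  xs <- seq_len(g$shape[1]); zs <- seq_len(g$shape[3])
  left <- xs <= g$shape[1] / 2
  third <- cut(zs, 3, labels = FALSE)
  ter_names <- c(territory_ACA_L = 1L, territory_ACA_R = 2L,
                 territory_MCA_L = 3L, territory_MCA_R = 4L,
                 territory_PCA_L = 5L, territory_PCA_R = 6L)
  for (k in zs) {
    band <- third[k] # 1 = ACA, 2 = MCA, 3 = PCA
    lab_l <- c(1L, 3L, 5L)[band]
    ter[left, , k] <- lab_l
    ter[!left, , k] <- lab_l + 1L
  }

  # small artery masks: 3^3 boxes at 12 points spread along the segments
  art <- array(0L, dim = g$shape)
  art_names <- setNames(1:12, paste0("artery_", sub("^aradius_", "",
                                     measurement_names("artery_radius"))))
  anchors <- artery_anchor_points(spec$segments, 12L)
  for (m in 1:12) {
    v <- world_to_voxel(anchors[m, ], g)
    i <- max(2L, min(g$shape[1] - 1L, v[1]))
    j <- max(2L, min(g$shape[2] - 1L, v[2]))
    k <- max(2L, min(g$shape[3] - 1L, v[3]))
    art[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)] <- m
  }

  # intracranial mask: ellipsoid inscribed in the grid box
  ctr <- g$origin + (g$shape - 1) * g$spacing / 2
  semi <- pmax((g$shape - 1) * g$spacing / 2 * 0.95 * spec$icv_scale,
               g$spacing)
  rel <- sweep(pts, 2, ctr)
  icv_arr <- array(as.integer(rowSums(sweep(rel, 2, semi, "/")^2) <= 1),
                   dim = g$shape)

  structure(list(
    mask = binary_volume(mask_arr, g),
    true_centerline = true_cl,
    true_radius = vapply(spec$segments, function(s) s$radius, 0),
    noise_voxels = noise_voxels,
    prob_atlas = probability_volume(atlas_arr, g),
    territories = label_volume(ter, g, ter_names),
    artery_masks = label_volume(art, g, art_names),
    icv_mask = binary_volume(icv_arr, g),
    spec = spec
  ), class = "phantom")
}

# spread `k` anchor points along the concatenated arc length of segments;
# anchors stay in the central 70% of each segment so the masks sample
# characteristic mid-vessel locations, not the rounded caps
artery_anchor_points <- function(segments, k) {
  lens <- vapply(segments, function(s) sqrt(sum((s$end - s$start)^2)), 0)
  total <- sum(lens)
  pos <- (seq_len(k) - 0.5) / k * total
  cum <- cumsum(lens)
  out <- matrix(0, k, 3)
  for (m in seq_len(k)) {
    si <- which(pos[m] <= cum)[1]
    s <- segments[[si]]
    t0 <- if (si == 1) pos[m] else pos[m] - cum[si - 1]
    t <- if (lens[si] > 0) t0 / lens[si] else 0.5
    t <- 0.15 + 0.7 * t
    out[m, ] <- s$start + t * (s$end - s$start)
  }
  out
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d segment(s), radii %s mm, %d noise voxel(s)\n",
              length(x$true_radius),
              paste(signif(x$true_radius, 3), collapse = "/"),
              nrow(x$noise_voxels)))
  print(x$mask$grid)
  invisible(x)
}

# ---------------------------------------------------------------------------
# cohort simulation

default_predictor_corr <- function() {
  p <- predictor_names()
  R <- diag(9)
  dimnames(R) <- list(p, p)
  set_r <- function(a, b, r) { R[a, b] <<- r; R[b, a] <<- r }
  set_r("age", "sbp", 0.40)
  set_r("age", "bmi", 0.15)
  set_r("age", "whr", 0.25)
  set_r("bmi", "whr", 0.50)
  set_r("bmi", "sbp", 0.25)
  set_r("whr", "sbp", 0.20)
  set_r("sex", "whr", -0.45)     # males (code 1) have higher WHR
  set_r("sex", "icv_cm3", -0.40) # and larger ICV
  set_r("sex", "smoking_years", -0.15)
  set_r("sex", "drinks", -0.30)
  set_r("drinks", "smoking_years", 0.20)
  set_r("heart_rate", "sbp", 0.15)
  R
}

# Table-style marginal means/SDs used as default simulator anchors
default_predictor_marginals <- function() {
  list(mean = c(icv_cm3 = 1402.44, age = 50.23, bmi = 27.48, whr = 0.88,
                sbp = 126.52, heart_rate = 70.61, smoking_years = 9.55),
       sd = c(icv_cm3 = 136.10, age = 13.83, bmi = 4.39, whr = 0.09,
              sbp = 17.09, heart_rate = 10.40, smoking_years = 13.42),
       female_fraction = 0.544,
       drinks_prob = c(`0` = 0.071, `1` = 0.710, `2` = 0.182,
                       `3` = 0.028, `4` = 0.007, `5` = 0.002))
}

default_response_means <- function() {
  setNames(c(0.756, 1.177, 0.707, 0.852, 0.274, 0.308,
             0.761, 0.715, 0.688, 0.751, 0.618, 0.634,
             1.025, 0.992, 0.890, 0.906, 0.898, 1.193, 1.168,
             0.811, 0.787, 1.849, 1.848, 1.049),
           measurement_names("all"))
}

# group shift observed for the anatomical variant: smaller basilar radius,
# larger right internal carotid radius
default_variant_shift <- function() {
  c(aradius_BA = -0.087, aradius_ICA_R = 0.088)
}

#' Three-latent-factor effect design for simulation studies
#'
#' A canonical cohort design in which exactly three latent components carry
#' all predictor-response signal: three Gaussian predictor pairs (ICV+age,
#' BMI+WHR, systolic BP+heart rate) are correlated within-pair, and every
#' response loads on exactly one pair-sum direction with a fixed
#' standardized effect. Responses are assigned to the three factors
#' round-robin. Used to study PLSR component selection: the pair-sum
#' directions are (population) eigendirections of the predictor covariance,
#' so three PLS components capture all signal and further components only
#' overfit. Effects are kept off the discretised predictors (sex, drinks)
#' and the zero-clipped smoking duration, whose nonlinear distortion would
#' leak real signal into a fourth component.
#'
#' @param effect standardized effect size per predictor (response units per
#'   predictor SD) on the informative cells.
#' @param rho within-pair predictor correlation.
#' @return List with `predictor_corr` (9 x 9), `effect_matrix` (9 x 24) and
#'   `informative`, a logical 9 x 24 matrix marking the nonzero cells.
#' @export
factor_effect_design <- function(effect = 0.15, rho = 0.6) {
  pn <- predictor_names()
  R <- diag(9)
  dimnames(R) <- list(pn, pn)
  pairs <- list(c("icv_cm3", "age"), c("bmi", "whr"),
                c("sbp", "heart_rate"))
  for (b in pairs) {
    R[b[1], b[2]] <- rho
    R[b[2], b[1]] <- rho
  }
  B <- matrix(0, 9, 24, dimnames = list(pn, measurement_names("all")))
  for (j in seq_len(24))
    B[pairs[[(j - 1) %% 3 + 1]], j] <- effect
  list(predictor_corr = R, effect_matrix = B, informative = B != 0)
}

#' Specify a simulated risk-factor cohort
#'
#' Subjects get 9 correlated predictors (latent multivariate normal; sex and
#' drinks category discretised by thresholding their latent normals at the
#' marginal frequencies) and 24 regional measurements generated as a linear
#' model in the standardized observed predictors plus Gaussian noise:
#' `Y = mu + scale(X) %*% B + E`. Subjects carrying the fetal-PCA variant
#' (Bernoulli with `fetal_pca_fraction`) additionally receive `variant_shift`
#' on the named responses.
#'
#' @param n_subjects number of subjects (> 9).
#' @param predictor_corr 9 x 9 latent correlation matrix (symmetric positive
#'   definite, unit diagonal), rows/cols in [predictor_names()] order.
#' @param effect_matrix 9 x 24 matrix `B`: effect of one SD of each observed
#'   predictor on each response, in response units. Default 0.
#' @param noise_sd residual SD per response (scalar recycled).
#' @param fetal_pca_fraction probability a subject carries the variant.
#' @param variant_shift named numeric vector of response offsets applied to
#'   variant carriers; defaults to a smaller basilar and larger right
#'   internal carotid radius.
#' @param response_means baseline level per response.
#' @param seed integer master seed.
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_subjects,
                            predictor_corr = default_predictor_corr(),
                            effect_matrix = matrix(0, 9, 24),
                            noise_sd = 0.05,
                            fetal_pca_fraction = 0.125,
                            variant_shift = default_variant_shift(),
                            response_means = default_response_means(),
                            seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects <= 9L) stop("`n_subjects` must exceed the 9 predictors")
  if (!is.matrix(predictor_corr) || !all(dim(predictor_corr) == 9))
    stop("`predictor_corr` must be 9 x 9")
  if (max(abs(predictor_corr - t(predictor_corr))) > 1e-8)
    stop("`predictor_corr` must be symmetric")
  if (max(abs(diag(predictor_corr) - 1)) > 1e-8)
    stop("`predictor_corr` must have unit diagonal")
  ev <- eigen(predictor_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop(sprintf("`predictor_corr` is not positive definite (smallest eigenvalue %.3g)",
                 min(ev)))
  effect_matrix <- as.matrix(effect_matrix)
  if (!all(dim(effect_matrix) == c(9, 24)))
    stop("`effect_matrix` must be 9 x 24")
  noise_sd <- rep_len(as.numeric(noise_sd), 24L)
  if (any(noise_sd < 0)) stop("`noise_sd` must be >= 0")
  if (fetal_pca_fraction < 0 || fetal_pca_fraction > 1)
    stop("`fetal_pca_fraction` must be in [0, 1]")
  if (length(variant_shift) &&
      !all(names(variant_shift) %in% measurement_names("all")))
    stop("`variant_shift` names must be measurement names")
  structure(list(n_subjects = n_subjects, predictor_corr = predictor_corr,
                 effect_matrix = effect_matrix, noise_sd = noise_sd,
                 fetal_pca_fraction = fetal_pca_fraction,
                 variant_shift = variant_shift,
                 response_means = response_means, seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Simulate a cohort table
#'
#' @param spec a [cohort_sim_spec()].
#' @return A data.frame with `subject_id`, the 9 predictors
#'   ([predictor_names()]), `fetal_pca` (0/1) and the 24 measurements
#'   ([measurement_names()]). Deterministic given the spec seed.
#' @examples
#' cohort <- make_cohort(cohort_sim_spec(n_subjects = 50, seed = 7))
#' dim(cohort)
#' @export
make_cohort <- function(spec) {
  if (!inherits(spec, "cohort_sim_spec")) stop("`spec` must be a cohort_sim_spec")
  marg <- default_predictor_marginals()
  pn <- predictor_names()
  mn <- measurement_names("all")
  with_seed(spec$seed, {
    n <- spec$n_subjects
    Z <- MASS::mvrnorm(n, mu = rep(0, 9), Sigma = spec$predictor_corr)
    colnames(Z) <- pn
    X <- matrix(0, n, 9, dimnames = list(NULL, pn))
    for (v in names(marg$mean))
      X[, v] <- marg$mean[[v]] + marg$sd[[v]] * Z[, v]
    X[, "smoking_years"] <- pmax(0, X[, "smoking_years"])
    # sex: M = 1, F = 2; low latent tail = female at the marginal frequency
    X[, "sex"] <- ifelse(Z[, "sex"] < stats::qnorm(marg$female_fraction), 2, 1)
    # drinks: ordinal 0-5 from latent thresholds at cumulative frequencies
    cuts <- stats::qnorm(cumsum(marg$drinks_prob))[1:5]
    X[, "drinks"] <- findInterval(Z[, "drinks"], cuts)
    fetal <- rbinom(n, 1, spec$fetal_pca_fraction)
    Xs <- scale(X)
    # guard: a zero-variance column (e.g. all same sex at tiny n) stays 0
    Xs[, attr(Xs, "scaled:scale") == 0] <- 0
    E <- matrix(rnorm(n * 24), n, 24) %*% diag(spec$noise_sd)
    Y <- matrix(rep(spec$response_means[mn], each = n), n, 24) +
      Xs %*% spec$effect_matrix + E
    colnames(Y) <- mn
    for (v in names(spec$variant_shift))
      Y[fetal == 1, v] <- Y[fetal == 1, v] + spec$variant_shift[[v]]
    out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                      X, fetal_pca = fetal, Y, check.names = FALSE)
    rownames(out) <- NULL
    out
  })
}
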