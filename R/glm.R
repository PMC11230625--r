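#' Build a GLM design matrix from classified events
#'
#' Effects of interest are the interictal stimulations (blocks labeled
#' `baseline`), ictal stimulations (`fully_inside`), stimulations that ended
#' a seizure (`ended_seizure`), and seizures without stimulation; each is
#' convolved with all three gamma basis functions (three regressors per
#' condition). The remaining block labels are modeled the same way but
#' flagged as confounds of no interest, together with the six motion
#' parameters and an intercept.
#'
#' @param blocks classified stimulation blocks ([classify_stimulations()])
#' @param seizures merged seizure intervals (`start`, `end`); seizures with
#'   no overlapping stimulation block form the `seizure` condition
#' @param motion data frame of 6 motion parameters per frame (or `NULL`)
#' @param basis an [gamma_basis()] object
#' @param frame_times acquisition time of each frame (s), uniformly spaced
#' @return an object of class `design_matrix`: `matrix` (frames x
#'   regressors), `frame_times`, and a `columns` data frame (`name`,
#'   `condition`, `basis_index`, `confound`)
#' @export
build_design <- function(blocks, seizures, motion = NULL, basis,
                         frame_times) {
  if (length(frame_times) > 1) {
    d <- diff(frame_times)
    if (max(abs(d - d[1])) > 1e-6) stop("frame times must be uniform")
  }
  effect_map <- c(baseline = "interictal_stim", fully_inside = "ictal_stim",
                  ended_seizure = "stim_ended_seizure")
  confound_labels <- c("started_during_mostly_inside",
                       "started_during_mostly_outside",
                       "started_before_mostly_inside",
                       "started_before_mostly_outside",
                       "right_after_seizure")
  events <- data.frame(onset = numeric(0), duration = numeric(0),
                       condition = character(0), confound = logical(0))
  add_events <- function(onset, duration, condition, confound) {
    if (!length(onset)) return()
    events <<- rbind(events, data.frame(onset = onset, duration = duration,
                                        condition = condition,
                                        confound = confound))
  }
  if (nrow(blocks)) {
    for (lb in names(effect_map)) {
      sel <- blocks$label == lb
      add_events(blocks$onset[sel], blocks$duration[sel], effect_map[[lb]],
                 FALSE)
    }
    for (lb in confound_labels) {
      sel <- blocks$label == lb
      add_events(blocks$onset[sel], blocks$duration[sel],
                 paste0("confound_", lb), TRUE)
    }
  }
  if (nrow(seizures)) {
    unstim <- vapply(seq_len(nrow(seizures)), function(j) {
      if (!nrow(blocks)) return(TRUE)
      all(vapply(seq_len(nrow(blocks)), function(k)
        overlap_fraction(list(onset = blocks$onset[k],
                              duration = blocks$duration[k]),
                         seizures[j, ]) == 0, logical(1)))
    }, logical(1))
    add_events(seizures$start[unstim],
               seizures$end[unstim] - seizures$start[unstim], "seizure",
               FALSE)
  }
  cols <- list()
  meta <- data.frame(name = character(0), condition = character(0),
                     basis_index = integer(0), confound = logical(0))
  for (cond in unique(events$condition)) {
    ev <- events[events$condition == cond, ]
    reg <- convolve_events(ev$onset, ev$duration, basis, frame_times)
    if (all(abs(reg) < 1e-12)) {
      warning("condition ", cond, " produced all-zero regressors; omitted")
      next
    }
    for (j in 1:3) {
      cols[[length(cols) + 1]] <- reg[, j]
      meta <- rbind(meta, data.frame(name = paste0(cond, "_b", j),
                                     condition = cond, basis_index = j,
                                     confound = ev$confound[1]))
    }
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != length(frame_times))
      stop("motion must have one row per frame")
    for (j in seq_len(ncol(motion))) {
      cols[[length(cols) + 1]] <- motion[, j]
      meta <- rbind(meta, data.frame(name = paste0("motion_", j),
                                     condition = "motion", basis_index = NA,
                                     confound = TRUE))
    }
  }
  cols[[length(cols) + 1]] <- rep(1, length(frame_times))
  meta <- rbind(meta, data.frame(name = "intercept", condition = "intercept",
                                 basis_index = NA, confound = TRUE))
  X <- do.call(cbind, cols)
  colnames(X) <- meta$name
  structure(list(matrix = X, frame_times = frame_times, columns = meta,
                 basis = basis),
            class = "design_matrix")
}

# convolve boxcar events with each basis column on a dense grid, then sample
# at the frame times
convolve_events <- function(onsets, durations, basis, frame_times,
                            dense_dt = 0.1) {
  t_end <- max(frame_times) + dense_dt
  tg <- seq(0, t_end, by = dense_dt)
  box <- numeric(length(tg))
  for (k in seq_along(onsets))
    box[tg >= onsets[k] & tg < onsets[k] + durations[k]] <- 1
  out <- matrix(0, length(frame_times), 3)
  for (j in 1:3) {
    s <- basis$shapes[[j]]
    h <- gamma_unit_peak(seq(0, basis$duration, by = dense_dt), s[1], s[2])
    conv <- stats::filter(c(box, numeric(length(h))), h, method = "convolution",
                          sides = 1)
    conv <- conv[seq_along(tg)] * dense_dt
    conv[is.na(conv)] <- 0
    out[, j] <- approx_grid(tg, conv, frame_times)
  }
  out
}

approx_grid <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}

#' Mass-univariate ordinary least squares fit
#'
#' @param data numeric matrix, frames x voxels (use [flatten_volumes()] for
#'   4D arrays)
#' @param design a [build_design()] object
#' @return an object of class `glm_fit`: `betas` (regressors x voxels),
#'   `sigma2` (unbiased residual variance per voxel), `dof`, `design`
#' @export
fit_glm <- function(data, design) {
  X <- design$matrix
  if (nrow(X) != nrow(data)) stop("data frames must match the design")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  betas <- qr.coef(qx, data)
  resid <- data - X %*% betas
  dof <- nrow(X) - qx$rank
  if (dof <= 0) stop("no residual degrees of freedom")
  sigma2 <- colSums(resid^2) / dof
  structure(list(betas = betas, sigma2 = sigma2, dof = dof, design = design,
                 XtXinv = solve(crossprod(X))),
            class = "glm_fit")
}

#' F and T contrast maps
#'
#' For a modeled condition, jointly tests its three basis betas with an
#' F-contrast and additionally returns the T map of the first basis
#' function. Difference contrasts between two conditions (weights +1 / -1 on
#' matched basis columns, as in the interictal-minus-ictal comparison) are
#' requested by passing both condition names.
#'
#' @param fit a [fit_glm()] object
#' @param condition condition name, or `c(positive, negative)` for a
#'   difference contrast
#' @return list with `F` (voxel vector), `t_first` (T map of the first basis
#'   column), `df` (`c(q, dof)`), and the contrast matrix `C`
#' @export
f_contrast <- function(fit, condition) {
  meta <- fit$design$columns
  pick <- function(cond) {
    idx <- which(meta$condition == cond)
    if (!length(idx))
      stop("contrast spans omitted or unknown condition: ", cond)
    idx[order(meta$basis_index[idx])]
  }
  k <- ncol(fit$design$matrix)
  if (length(condition) == 1) {
    idx <- pick(condition)
    C <- matrix(0, length(idx), k)
    C[cbind(seq_along(idx), idx)] <- 1
  } else {
    ip <- pick(condition[1])
    im <- pick(condition[2])
    if (length(ip) != length(im)) stop("conditions have unmatched basis columns")
    C <- matrix(0, length(ip), k)
    C[cbind(seq_along(ip), ip)] <- 1
    C[cbind(seq_along(im), im)] <- -1
  }
  q <- nrow(C)
  cb <- C %*% fit$betas                       # q x voxels
  M <- C %*% fit$XtXinv %*% t(C)              # q x q
  Minv <- solve(M)
  quad <- colSums((Minv %*% cb) * cb)
  Fstat <- quad / (q * fit$sigma2)
  t1 <- drop(cb[1, ]) / sqrt(M[1, 1] * fit$sigma2)
  list(F = Fstat, t_first = t1, df = c(q, fit$dof), C = C)
}

#' Flatten / restore 4D volumes
#'
#' @param vol4d 4D array (x, y, z, t)
#' @return `flatten_volumes()`: list with `data` (frames x voxels) and
#'   `dims`; `unflatten_map()`: 3D array from a voxel vector
#' @export
flatten_volumes <- function(vol4d) {
  d <- dim(vol4d)
  list(data = t(matrix(vol4d, prod(d[1:3]), d[4])), dims = d[1:3])
}

#' @rdname flatten_volumes
#' @param v voxel vector
#' @param dims 3D dimensions
#' @export
unflatten_map <- function(v, dims) array(v, dims)

# 26-connected component labeling of a logical 3D array
label_clusters <- function(mask3d) {
  d <- dim(mask3d)
  lab <- array(0L, d)
  idx <- which(mask3d)
  if (!length(idx)) return(list(labels = lab, sizes = integer(0)))
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  current <- 0L
  sizes <- integer(0)
  coords <- arrayInd(idx, d)
  key <- function(co) (co[, 3] - 1) * d[1] * d[2] + (co[, 2] - 1) * d[1] + co[, 1]
  for (s in seq_along(idx)) {
    if (lab[idx[s]] != 0L) next
    current <- current + 1L
    queue <- idx[s]
    lab[idx[s]] <- current
    size <- 0L
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      size <- size + 1L
      co <- arrayInd(v, d)
      cand <- sweep(nb, 2, as.integer(co), `+`)
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      ki <- key(cand)
      ki <- ki[mask3d[ki] & lab[ki] == 0L]
      if (length(ki)) {
        lab[ki] <- current
        queue <- c(queue, ki)
      }
    }
    sizes[current] <- size
  }
  list(labels = lab, sizes = sizes)
}

#' Permutation cluster-level correction
#'
#' Thresholds the voxelwise F map of a condition at `voxel_p`, forms
#' 26-connected supra-threshold clusters, and retains those whose size
#' exceeds the `(1 - alpha)` quantile of the maximum cluster size under a
#' model-based null: a first-order autoregressive model (per-voxel lag-1
#' coefficient and innovation variance) is estimated from the full-model
#' residuals, fresh AR(1) noise is simulated from it, added onto the
#' reduced-model (confounds-only) fit, and the full model is refitted, so
#' serial correlation is honored and no effect signal leaks into the null.
#'
#' @param vol4d 4D data array (x, y, z, frames)
#' @param design a [build_design()] object
#' @param condition condition (or condition pair) passed to [f_contrast()]
#' @param mask optional logical 3D brain mask
#' @param voxel_p cluster-forming voxelwise p threshold
#' @param n_permutations number of null simulations (>= 20; a warning is
#'   issued below 100)
#' @param alpha cluster-level significance
#' @param seed RNG seed (permutations are deterministic given it)
#' @return list with `mask` (logical 3D array of significant voxels),
#'   `clusters` (table: id, size, max F, cluster p), `threshold_size`,
#'   `F_map` (3D), `t_map` (3D, first basis), `null_max_sizes`
#' @export
cluster_correct <- function(vol4d, design, condition, mask = NULL,
                            voxel_p = 0.01, n_permutations = 999,
                            alpha = 0.05, seed = 1) {
  if (n_permutations < 20) stop("n_permutations must be >= 20")
  if (n_permutations < 100)
    warning("fewer than 100 permutations: cluster p-values are coarse")
  fl <- flatten_volumes(vol4d)
  dims <- fl$dims
  if (is.null(mask)) mask <- array(TRUE, dims)
  vox <- which(as.vector(mask))
  data <- fl$data[, vox, drop = FALSE]
  fit <- fit_glm(data, design)
  con <- f_contrast(fit, condition)
  Fcrit <- qf(1 - voxel_p, con$df[1], con$df[2])
  make_mask <- function(Fv) {
    m <- array(FALSE, dims)
    m[vox[Fv > Fcrit]] <- TRUE
    m
  }
  obs <- label_clusters(make_mask(con$F))
  meta <- design$columns
  nfr <- nrow(design$matrix)
  X <- design$matrix
  resid_full <- data - X %*% fit$betas
  Xr <- X[, meta$confound, drop = FALSE]
  fitted_red <- if (ncol(Xr)) Xr %*% qr.coef(qr(Xr), data) else 0 * data
  rho <- colSums(resid_full[-1, , drop = FALSE] *
                   resid_full[-nfr, , drop = FALSE]) /
    pmax(colSums(resid_full[-nfr, , drop = FALSE]^2), .Machine$double.eps)
  rho <- pmin(pmax(rho, -0.95), 0.95)
  innov_sd <- sqrt(pmax(colSums(resid_full^2) / fit$dof * (1 - rho^2), 0))
  nvx <- ncol(resid_full)
  set.seed(seed)
  null_max <- vapply(seq_len(n_permutations), function(p) {
    eps <- matrix(rnorm(nfr * nvx), nfr) * rep(innov_sd, each = nfr)
    sim <- eps
    sim[1, ] <- sim[1, ] / sqrt(1 - rho^2)
    for (k in 2:nfr) sim[k, ] <- rho * sim[k - 1, ] + eps[k, ]
    fp <- fit_glm(fitted_red + sim, design)
    cp <- f_contrast(fp, condition)
    cl <- label_clusters(make_mask(cp$F))
    if (length(cl$sizes)) max(cl$sizes) else 0L
  }, integer(1))
  thr <- quantile(null_max, 1 - alpha, type = 1)
  keep <- which(obs$sizes > thr)
  sig <- array(FALSE, dims)
  if (length(keep)) sig[obs$labels %in% keep] <- TRUE
  Fmap <- array(0, dims)
  Fmap[vox] <- con$F
  tmap <- array(0, dims)
  tmap[vox] <- con$t_first
  tab <- data.frame(id = seq_along(obs$sizes), size = obs$sizes,
                    max_F = vapply(seq_along(obs$sizes), function(i)
                      if (obs$sizes[i] > 0) max(Fmap[obs$labels == i]) else NA_real_, 0),
                    p_cluster = vapply(obs$sizes, function(s)
                      (1 + sum(null_max >= s)) / (n_permutations + 1), 0))
  list(mask = sig, clusters = tab, threshold_size = unname(thr),
       F_map = Fmap, t_map = tmap, null_max_sizes = null_max)
}

#' Mask an F-contrast map with a directional T map
#'
#' Retains a voxel iff it is in the F mask and the first-basis T statistic is
#' positive, revealing where the positive condition of a difference contrast
#' responded with higher amplitude.
#'
#' @param f_mask logical 3D array
#' @param t_map_first_basis numeric 3D array on the same grid
#' @return logical 3D array
#' @export
mask_f_with_t <- function(f_mask, t_map_first_basis) {
  if (!all(dim(f_mask) == dim(t_map_first_basis)))
    stop("grid mismatch between F mask and T map")
  f_mask & (t_map_first_basis > 0)
}

#' Framewise displacement from motion parameters
#'
#' `FD_t` sums the absolute frame-to-frame differentials of the six motion
#' parameters; rotations are converted to millimeters. In `standard` mode
#' rotations (degrees) are converted to radians and multiplied by the brain
#' radius; `paper_literal` mode instead divides the degree differentials by
#' the radius, following the study's verbatim description (dimensionally
#' anomalous, kept for comparability).
#'
#' @param motion data frame / matrix with 6 columns: translations x, y, z
#'   (mm) then rotations x, y, z (deg)
#' @param radius_mm brain radius used for the rotation conversion
#' @param mode `"standard"` or `"paper_literal"`
#' @return FD series (mm), with `FD[1] = 0`
#' @export
framewise_displacement <- function(motion, radius_mm = 5,
                                   mode = c("standard", "paper_literal")) {
  mode <- match.arg(mode)
  motion <- as.matrix(motion)
  if (nrow(motion) < 2) stop("need at least 2 frames")
  d <- abs(diff(motion))
  rot <- d[, 4:6, drop = FALSE]
  rot_term <- if (mode == "standard") radius_mm * rot * pi / 180
  else rot / radius_mm
  fd <- rowSums(d[, 1:3, drop = FALSE]) + rowSums(rot_term)
  c(0, fd)
}

#' Drop stimulation blocks that coincide with motion
#'
#' A block is discarded when any frame within it has a displacement above
#' `threshold_fraction` times the in-plane voxel size.
#'
#' @param blocks stimulation blocks (`onset`, `duration`)
#' @param motion_metric per-frame displacement (mm), e.g.
#'   [framewise_displacement()]
#' @param voxel_size_mm in-plane voxel size (mm)
#' @param threshold_fraction motion threshold as a fraction of the voxel size
#' @param frame_times acquisition time of each frame (s)
#' @return the retained blocks
#' @export
scrub_stimulations <- function(blocks, motion_metric, voxel_size_mm,
                               threshold_fraction = 0.003, frame_times) {
  if (!nrow(blocks)) return(blocks)
  thr <- threshold_fraction * voxel_size_mm
  keep <- vapply(seq_len(nrow(blocks)), function(k) {
    fr <- frame_times >= blocks$onset[k] &
      frame_times <= blocks$onset[k] + blocks$duration[k]
    !any(motion_metric[fr] > thr)
  }, logical(1))
  blocks[keep, , drop = FALSE]
}

#' Compare per-session extreme betas between two conditions
#'
#' Two-sample two-tailed t-test on the per-session extreme (signed
#' maximum-magnitude) ROI beta values of two conditions.
#'
#' @param extremes_a,extremes_b numeric vectors of per-session extreme betas
#'   (>= 2 sessions each)
#' @return list with `t`, `p`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `n_a`,
#'   `n_b`
#' @export
roi_extreme_beta_test <- function(extremes_a, extremes_b) {
  if (length(extremes_a) < 2 || length(extremes_b) < 2)
    stop("need >= 2 sessions per condition")
  if (var(extremes_a) == 0 && var(extremes_b) == 0) {
    if (mean(extremes_a) == mean(extremes_b))
      return(list(t = 0, p = 1, mean_a = mean(extremes_a), sd_a = 0,
                  mean_b = mean(extremes_b), sd_b = 0,
                  n_a = length(extremes_a), n_b = length(extremes_b)))
    stop("zero within-group variance in both groups")
  }
  tt <- t.test(extremes_a, extremes_b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_a = mean(extremes_a), sd_a = sd(extremes_a),
       mean_b = mean(extremes_b), sd_b = sd(extremes_b),
       n_a = length(extremes_a), n_b = length(extremes_b))
}
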