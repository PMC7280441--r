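#' Registration parameters
#'
#' Settings for [estimate_normalization()]: a multi-resolution affine
#' stage followed by a fluid demons-style nonlinear refinement. The
#' contract of the estimator is field quality (round-trip residuals,
#' recovery of known transforms), not equivalence with any particular
#' neuroimaging suite.
#'
#' @param affine_stages Number of multi-resolution affine levels
#'   (coarse-to-fine; 0 skips the affine stage).
#' @param nonlinear_grid_spacings Strictly decreasing working resolutions
#'   in mm for the nonlinear stage (each level runs on a grid resampled
#'   to roughly that spacing). `NULL` or `numeric(0)` skips it.
#' @param similarity `"msd"` (mean squared difference, same-modality
#'   default) or `"nmi"` (normalized mutual information, affine stage
#'   only).
#' @param regularization_weight Gaussian sigma, in voxels of the working
#'   level, applied to each demons update (fluid regularization).
#' @param max_iterations Demons iterations at the coarsest level; finer
#'   levels run progressively fewer.
#' @param convergence_tol Relative similarity improvement below which a
#'   level stops early.
#' @return A `registration_params` list.
#' @export
registration_params <- function(affine_stages = 2L,
                                nonlinear_grid_spacings = c(8, 4, 2),
                                similarity = c("msd", "nmi"),
                                regularization_weight = 1.5,
                                max_iterations = 30L,
                                convergence_tol = 1e-4) {
  similarity <- match.arg(similarity)
  if (length(nonlinear_grid_spacings) &&
      any(diff(nonlinear_grid_spacings) >= 0))
    nq_stop("nonlinear_grid_spacings must be strictly decreasing",
            class = "validation_error")
  if (convergence_tol <= 0)
    nq_stop("convergence_tol must be > 0", class = "validation_error")
  if (regularization_weight < 0)
    nq_stop("regularization_weight must be >= 0", class = "validation_error")
  structure(list(affine_stages = as.integer(affine_stages),
                 nonlinear_grid_spacings = nonlinear_grid_spacings,
                 similarity = similarity,
                 regularization_weight = regularization_weight,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "registration_params")
}

# ---- affine stage -----------------------------------------------------

# theta = c(translation mm (3), rotation rad (3), log-scale (3), shear (3))
affine_from_theta <- function(theta, center) {
  t <- theta[1:3]; r <- theta[4:6]; s <- exp(theta[7:9]); h <- theta[10:12]
  Rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])),
              c(0, sin(r[1]), cos(r[1])))
  Ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0),
              c(-sin(r[2]), 0, cos(r[2])))
  Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0),
              c(0, 0, 1))
  Sh <- rbind(c(1, h[1], h[2]), c(0, 1, h[3]), c(0, 0, 1))
  M <- Rz %*% Ry %*% Rx %*% diag(s) %*% Sh
  A <- diag(4)
  A[1:3, 1:3] <- M
  A[1:3, 4] <- center + t - M %*% center
  A
}

affine_cost <- function(theta, fixed, moving, center, similarity) {
  A <- affine_from_theta(theta, center)
  xyz <- grid_world_coords(fixed$grid)
  pts <- sweep(xyz %*% t(A[1:3, 1:3]), 2L, A[1:3, 4], "+")
  mv <- sample_image_world(moving, pts, "trilinear")
  fv <- as.vector(fixed$values)
  if (similarity == "msd") {
    mean((mv - fv)^2)
  } else {
    -nmi_score(fv, mv)
  }
}

nmi_score <- function(a, b, nbins = 32L) {
  cut_idx <- function(v) {
    r <- range(v)
    if (r[2] <= r[1]) return(rep(1L, length(v)))
    pmin(pmax(1L, as.integer((v - r[1]) / (r[2] - r[1]) * nbins) + 1L), nbins)
  }
  ia <- cut_idx(a); ib <- cut_idx(b)
  joint <- tabulate((ia - 1L) * nbins + ib, nbins * nbins) / length(a)
  pa <- tabulate(ia, nbins) / length(a)
  pb <- tabulate(ib, nbins) / length(b)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (H(pa) + H(pb)) / max(H(joint), .Machine$double.eps)
}

intensity_centroid <- function(img) {
  w <- pmax(as.vector(img$values), 0)
  w <- w / sum(w)
  colSums(grid_world_coords(img$grid) * w)
}

estimate_affine <- function(moving, fixed, params) {
  center <- colMeans(voxel_to_world(
    fixed$grid, rbind(c(0, 0, 0), fixed$grid$shape - 1)))
  theta <- c(intensity_centroid(moving) - intensity_centroid(fixed),
             rep(0, 9))
  if (params$affine_stages == 0L)
    return(affine_from_theta(theta, center))
  # Coarse-to-fine working spacings in mm, halving per stage; each image
  # is decimated by its own integer factor to reach that spacing.
  target_sp <- min(fixed$grid$spacing) * rev(2^seq_len(params$affine_stages))
  for (tsp in target_sp) {
    fx <- downsample_volume(fixed, rep(max(1L, as.integer(
      round(tsp / min(fixed$grid$spacing)))), 3L))
    mv <- downsample_volume(moving, rep(max(1L, as.integer(
      round(tsp / min(moving$grid$spacing)))), 3L))
    method <- if (params$similarity == "msd") "BFGS" else "Nelder-Mead"
    opt <- stats::optim(theta, affine_cost, fixed = fx, moving = mv,
                        center = center, similarity = params$similarity,
                        method = method,
                        control = list(maxit = 200,
                                       parscale = c(rep(1, 3), rep(0.01, 9)),
                                       reltol = 1e-9))
    theta <- opt$par
  }
  affine_from_theta(theta, center)
}

# ---- nonlinear stage (fluid demons) -----------------------------------

demons_level <- function(moving, fixed_level, field, sigma_vox, n_iter,
                         tol) {
  grid <- fixed_level$grid
  xyz <- grid_world_coords(grid)
  fv <- as.vector(fixed_level$values)
  grad <- world_gradient(fixed_level$values, grid)
  g2 <- as.vector(grad[[1]])^2 + as.vector(grad[[2]])^2 +
    as.vector(grad[[3]])^2
  sp <- mean(grid$spacing)
  d <- cbind(as.vector(field$displacement[[1]]),
             as.vector(field$displacement[[2]]),
             as.vector(field$displacement[[3]]))
  msd_of <- function(dmat) {
    mv <- sample_image_world(moving, xyz + dmat, "trilinear")
    mean((mv - fv)^2)
  }
  trace <- numeric(0)
  cur <- msd_of(d)
  for (it in seq_len(n_iter)) {
    mv <- sample_image_world(moving, xyz + d, "trilinear")
    diffv <- mv - fv
    denom <- g2 + (diffv / sp)^2
    scale <- ifelse(denom > 1e-12, -diffv / denom, 0)
    u <- cbind(scale * as.vector(grad[[1]]), scale * as.vector(grad[[2]]),
               scale * as.vector(grad[[3]]))
    # Cap the raw step at one voxel, then smooth (fluid regularization).
    mags <- sqrt(rowSums(u^2))
    mmax <- max(mags)
    if (mmax > sp) u <- u * (sp / mmax)
    for (k in 1:3)
      u[, k] <- as.vector(gaussian_smooth(array(u[, k], dim = grid$shape),
                                          sigma_vox))
    step <- 1
    improved <- FALSE
    for (ls in 1:4) {
      cand <- d + step * u
      val <- msd_of(cand)
      if (val < cur) { d <- cand; cur <- val; improved <- TRUE; break }
      step <- step / 2
    }
    trace <- c(trace, cur)
    if (!improved) break
    if (length(trace) >= 2L &&
        (trace[length(trace) - 1L] - cur) < tol * max(cur, 1e-12)) break
  }
  s <- grid$shape
  list(field = deformation_field(
         list(array(d[, 1], dim = s), array(d[, 2], dim = s),
              array(d[, 3], dim = s)), grid, direction = field$direction),
       trace = trace)
}

#' Estimate the subject <-> template spatial normalization
#'
#' Registers a subject T1 volume to the template with a multi-resolution
#' affine stage followed by fluid demons-style nonlinear refinement under
#' the configured similarity, and returns both the forward field (on the
#' template grid, pulls subject images into MNI space) and its numerical
#' inverse (on the subject grid, pulls the atlas into native space).
#' The optimization is deterministic: identical inputs give identical
#' fields.
#'
#' @param t1 Subject-space [volume_image()] (structural contrast).
#' @param template MNI-space [volume_image()] (the atlas reference T1).
#' @param params A [registration_params()].
#' @param subject_grid Grid on which the inverse field is constructed
#'   (defaults to `t1$grid`).
#' @return A `normalization_result` with elements `forward`, `inverse`
#'   (both [deformation_field()]), `affine_component` (4x4), and
#'   `similarity_trace` (list of per-level iteration similarity values,
#'   non-increasing within each level for `"msd"`).
#' @export
estimate_normalization <- function(t1, template,
                                   params = registration_params(),
                                   subject_grid = t1$grid) {
  stopifnot(inherits(t1, "volume_image"), inherits(template, "volume_image"))
  for (im in list(t1, template))
    if (stats::sd(im$values) < .Machine$double.eps)
      nq_stop("cannot register a constant image", class = "validation_error")
  A <- estimate_affine(t1, template, params)

  # Initialize the forward field from the affine: d(y) = A y - y.
  xyz <- grid_world_coords(template$grid)
  disp <- sweep(xyz %*% t(A[1:3, 1:3]), 2L, A[1:3, 4], "+") - xyz
  s <- template$grid$shape
  fwd <- deformation_field(list(array(disp[, 1], dim = s),
                                array(disp[, 2], dim = s),
                                array(disp[, 3], dim = s)),
                           template$grid, direction = "forward")
  trace <- list()
  spacings <- params$nonlinear_grid_spacings
  if (length(spacings)) {
    if (params$similarity != "msd")
      nq_stop("nonlinear refinement supports similarity = \"msd\" only",
              class = "validation_error")
    base_sp <- min(template$grid$spacing)
    for (li in seq_along(spacings)) {
      f <- max(1L, as.integer(round(spacings[li] / base_sp)))
      fixed_level <- downsample_volume(template, rep(f, 3L))
      # Match the moving image's physical resolution to the level's
      # anti-alias smoothing so the residual reflects geometry, not a
      # sharp-versus-smoothed mismatch.
      sigma_mm <- f / 2 * base_sp
      sigma_vox <- sigma_mm / t1$grid$spacing
      moving_level <- if (max(sigma_vox) > 0.3)
        volume_image(gaussian_smooth(t1$values, sigma_vox), t1$grid,
                     units = t1$units, space = t1$space)
      else t1
      field_level <- resample_field_to_grid(fwd, fixed_level$grid)
      n_iter <- max(5L, ceiling(params$max_iterations / 2^(li - 1)))
      res <- demons_level(moving_level, fixed_level, field_level,
                          sigma_vox = params$regularization_weight,
                          n_iter = n_iter, tol = params$convergence_tol)
      fwd <- resample_field_to_grid(res$field, template$grid)
      trace[[li]] <- res$trace
    }
  }
  # Final similarity must not be worse than the identity map's.
  xyzw <- grid_world_coords(template$grid)
  msd_id <- mean((sample_image_world(t1, xyzw, "trilinear") -
                    as.vector(template$values))^2)
  dmat <- cbind(as.vector(fwd$displacement[[1]]),
                as.vector(fwd$displacement[[2]]),
                as.vector(fwd$displacement[[3]]))
  msd_final <- mean((sample_image_world(t1, xyzw + dmat, "trilinear") -
                       as.vector(template$values))^2)
  if (msd_final > msd_id) {
    cond <- errorCondition(
      paste0("registration failed to improve on the identity map (MSD ",
             signif(msd_final, 5), " vs ", signif(msd_id, 5), ")"),
      class = c("non_convergence_error", "neuroquant_error"))
    attr(cond, "similarity_trace") <- trace
    stop(cond)
  }
  inv <- invert_field(fwd, target_grid = subject_grid, tol = 0.5,
                      max_iter = 100L)
  structure(list(forward = fwd, inverse = inv, affine_component = A,
                 similarity_trace = trace),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat("<normalization_result>\n  forward:  max |d| =",
      signif(field_max_mm(x$forward), 4), "mm\n  inverse:  max |d| =",
      signif(field_max_mm(x$inverse), 4), "mm\n  iterations:",
      length(unlist(x$similarity_trace)), "\n")
  invisible(x)
}

#' Build a normalization result from known fields
#'
#' Wraps externally supplied (e.g. ground-truth phantom) forward/inverse
#' fields in the container [estimate_normalization()] returns, so the
#' segmentation pipelines can run on exact transforms.
#'
#' @param forward,inverse [deformation_field()] objects.
#' @param affine_component Optional 4x4 matrix (default identity).
#' @return A `normalization_result`.
#' @export
normalization_from_fields <- function(forward, inverse,
                                      affine_component = diag(4)) {
  stopifnot(inherits(forward, "deformation_field"),
            inherits(inverse, "deformation_field"),
            forward$direction == "forward", inverse$direction == "inverse")
  structure(list(forward = forward, inverse = inverse,
                 affine_component = affine_component,
                 similarity_trace = list()),
            class = "normalization_result")
}
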