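#' Solver hyperparameters for blind deblurring
#'
#' Collects every tunable of the extreme-channel-prior solver.  The weights
#' multiply the terms of the objective
#' \deqn{\|M \otimes h - Z\|_2^2 + \varphi \|h\|_2^2 +
#'   \vartheta\,[\theta\,\|S(A_M)\|_0 + \zeta\,\|1 - S(Z_M)\|_0] +
#'   \lambda_g \|\nabla M\|_0,}
#' where \eqn{S(A_M)} and \eqn{S(Z_M)} are the secondary sparse dark and
#' bright channels of the latent image \eqn{M}.
#'
#' @param phi kernel ridge weight \eqn{\varphi} (on \eqn{\|h\|_2^2}).
#' @param vartheta overall image-prior weight \eqn{\vartheta}; multiplies
#'   both channel terms.
#' @param theta dark-channel sparsity weight \eqn{\theta}.
#' @param zeta bright-channel (complement) sparsity weight \eqn{\zeta}.
#' @param grad_weight gradient-L0 weight \eqn{\lambda_g}; stabilizes kernel
#'   estimation.
#' @param patch_size odd window side (pixels) of the channel extremum.
#' @param kernel_size odd blur-kernel support side (pixels).
#' @param pyramid_levels number of coarse-to-fine levels, or `NULL` to choose
#'   the deepest pyramid whose coarsest kernel is still >= 5 px and whose
#'   coarsest image is >= 24 px per side.
#' @param scale_factor per-level downscaling factor in (0, 1).
#' @param outer_iters alternating latent/kernel iterations per level.
#' @param inner_iters half-quadratic splitting iterations per latent update;
#'   the splitting penalty for a term with weight \eqn{\lambda} starts at
#'   \eqn{2\lambda} and doubles each inner iteration.
#' @param kernel_threshold kernel entries below this fraction of the maximum
#'   are zeroed before renormalization.
#' @param restore_weight total-variation weight of the final non-blind
#'   restoration pass (L1 gradient sparsity; soft-threshold proximal step).
#'   Larger values suppress more speckle at the cost of detail.
#' @param prefilter_weight total-variation weight of the speckle prefilter
#'   applied to the observation for the blind estimation stage only (the
#'   final restoration always works on the raw observation); 0 disables.
#' @param noise_freeze_sigma noise threshold (intensity units) of the
#'   noise-adaptive kernel schedule: when the estimated observation noise
#'   exceeds it, kernel updates are confined to pyramid levels at scale
#'   `freeze_scale` and below, where decimation has averaged the speckle
#'   out; the finest levels then refine the latent image only.  Set to `Inf`
#'   to refine the kernel at every level regardless of noise.
#' @param freeze_scale pyramid scale above which kernel updates are skipped
#'   for noisy observations.
#' @param seed integer seed for any stochastic element (the solver itself is
#'   deterministic; the seed governs phantom generation when a spec derives
#'   from a control object).
#' @return A list of class `deblur_control`.
#' @export
deblur_control <- function(phi = 2, vartheta = 1, theta = 4e-3, zeta = 4e-3,
                           grad_weight = 4e-3, patch_size = 15L,
                           kernel_size = 15L, pyramid_levels = NULL,
                           scale_factor = 0.75, outer_iters = 5L,
                           inner_iters = 4L, kernel_threshold = 0.05,
                           restore_weight = 0.02, prefilter_weight = 0.01,
                           noise_freeze_sigma = 0.015, freeze_scale = 0.6,
                           seed = 1L) {
  ctl <- list(phi = phi, vartheta = vartheta, theta = theta, zeta = zeta,
              grad_weight = grad_weight, patch_size = as.integer(patch_size),
              kernel_size = as.integer(kernel_size),
              pyramid_levels = if (!is.null(pyramid_levels)) as.integer(pyramid_levels),
              scale_factor = scale_factor, outer_iters = as.integer(outer_iters),
              inner_iters = as.integer(inner_iters),
              kernel_threshold = kernel_threshold,
              restore_weight = restore_weight,
              prefilter_weight = prefilter_weight,
              noise_freeze_sigma = noise_freeze_sigma,
              freeze_scale = freeze_scale, seed = as.integer(seed))
  for (nm in c("phi", "vartheta", "theta", "zeta", "grad_weight",
               "restore_weight", "prefilter_weight"))
    if (!is.numeric(ctl[[nm]]) || length(ctl[[nm]]) != 1L || ctl[[nm]] < 0)
      stop(sprintf("`%s` must be a single non-negative number", nm), call. = FALSE)
  for (nm in c("patch_size", "kernel_size"))
    if (ctl[[nm]] < 3L || ctl[[nm]] %% 2L == 0L)
      stop(sprintf("`%s` must be odd and >= 3", nm), call. = FALSE)
  if (ctl$scale_factor <= 0 || ctl$scale_factor >= 1)
    stop("`scale_factor` must lie in (0, 1)", call. = FALSE)
  if (ctl$outer_iters < 1L || ctl$inner_iters < 1L)
    stop("iteration counts must be >= 1", call. = FALSE)
  if (ctl$kernel_threshold < 0 || ctl$kernel_threshold >= 1)
    stop("`kernel_threshold` must lie in [0, 1)", call. = FALSE)
  class(ctl) <- "deblur_control"
  ctl
}

#' @export
print.deblur_control <- function(x, ...) {
  cat("<deblur_control>\n")
  flat <- unclass(x)
  flat$pyramid_levels <- if (is.null(flat$pyramid_levels)) "auto" else flat$pyramid_levels
  for (nm in names(flat))
    cat(sprintf("  %-16s %s\n", nm, format(flat[[nm]])))
  invisible(x)
}
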