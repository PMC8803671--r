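#' Configuration for the synthetic cohort generator
#'
#' Collects and validates every knob of the synthetic cohort generator.  The
#' defaults reproduce the reference study conditions used throughout the
#' package: a 93-subject cohort with 46 fractured and 47 non-fractured
#' subjects, a weak class-conditional shape effect, a strong class-conditional
#' intensity (bone mineral density) effect and a shape-by-intensity
#' interaction, so that the qualitative ordering of discriminative power
#' SSM < aBMD analogue < SIM < SSIM is reproducible.
#'
#' Effect sizes are standardized mean differences: the class-conditional mean
#' shift of the latent score along the corresponding fixed unit direction, in
#' units of its within-class standard deviation (which is 1).
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param class_balance Fraction of subjects that are fractured, in (0, 1);
#'   class counts are `round(class_balance * n_subjects)` fractured and the
#'   rest non-fractured, both of which must be non-empty.
#' @param n_control_points Number `q` of control points of the shared
#'   deformation grid; must be a perfect cube (a regular lattice is used).
#' @param n_elements Target tetrahedral element count of the template mesh;
#'   the realised mesh has at least `0.8 * n_elements` elements.
#' @param shape_effect Effect size `d_s >= 0` of fracture status on the shape
#'   latent score.
#' @param intensity_effect Effect size `d_i >= 0` on the intensity latent
#'   score.
#' @param interaction_effect Strength `d_si >= 0` of the shape-by-intensity
#'   interaction term (activated when both latent scores are low, i.e. in the
#'   fracture-prone tail of both).
#' @param noise_sd Standard deviation of the i.i.d. Gaussian noise added to
#'   every moment coordinate and every element density; must be > 0.
#' @param n_latents Number of status-independent nuisance latent factors added
#'   to both the shape and intensity fields.
#' @param seed Integer seed; a single RNG stream seeded from it drives every
#'   random draw of the generator in documented order.
#'
#' @return An object of class `generator_config` (a validated list).
#' @seealso [sample_cohort()], [make_template()]
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 20, n_elements = 150, seed = 1)
#' cfg$n_subjects
generator_config <- function(n_subjects = 93L,
                             class_balance = 46 / 93,
                             n_control_points = 27L,
                             n_elements = 800L,
                             shape_effect = 0.3,
                             intensity_effect = 1.0,
                             interaction_effect = 1.0,
                             noise_sd = 0.05,
                             n_latents = 3L,
                             seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 4L)
    stop("n_subjects must be an integer >= 4", call. = FALSE)
  if (!is.finite(class_balance) || class_balance <= 0 || class_balance >= 1)
    stop("class_balance must lie strictly in (0, 1)", call. = FALSE)
  n_pos <- as.integer(round(class_balance * n_subjects))
  if (n_pos < 1L || n_pos > n_subjects - 1L)
    stop("class_balance leaves an empty class after rounding", call. = FALSE)
  n_control_points <- as.integer(n_control_points)
  k <- as.integer(round(n_control_points^(1 / 3)))
  if (k^3 != n_control_points)
    stop("n_control_points must be a perfect cube (regular lattice)",
         call. = FALSE)
  n_elements <- as.integer(n_elements)
  if (n_elements < 24L)
    stop("n_elements must be >= 24", call. = FALSE)
  effects <- c(shape_effect = shape_effect,
               intensity_effect = intensity_effect,
               interaction_effect = interaction_effect)
  if (any(!is.finite(effects)) || any(effects < 0))
    stop("effect sizes must be finite and >= 0", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be > 0", call. = FALSE)
  n_latents <- as.integer(n_latents)
  if (n_latents < 0L) stop("n_latents must be >= 0", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)

  structure(list(
    n_subjects = n_subjects,
    class_balance = class_balance,
    n_fractured = n_pos,
    n_control_points = n_control_points,
    n_elements = n_elements,
    shape_effect = shape_effect,
    intensity_effect = intensity_effect,
    interaction_effect = interaction_effect,
    noise_sd = noise_sd,
    n_latents = n_latents,
    seed = seed
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator configuration\n")
  cat(sprintf("  subjects: %d (%d fractured / %d non-fractured)\n",
              x$n_subjects, x$n_fractured, x$n_subjects - x$n_fractured))
  cat(sprintf("  control points q = %d, target elements n = %d\n",
              x$n_control_points, x$n_elements))
  cat(sprintf("  effects: shape %.3g, intensity %.3g, interaction %.3g\n",
              x$shape_effect, x$intensity_effect, x$interaction_effect))
  cat(sprintf("  noise sd %.3g, nuisance latents %d, seed %d\n",
              x$noise_sd, x$n_latents, x$seed))
  invisible(x)
}
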