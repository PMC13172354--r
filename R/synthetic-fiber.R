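#' Generate a synthetic oriented-fiber image
#'
#' Builds a grayscale test image for alignment quantification: a sinusoidal
#' stripe pattern whose fibers run at a controlled angle, blended with
#' uniform noise. `coherence = 1` gives pure parallel stripes, `coherence =
#' 0` pure isotropic noise; intermediate values interpolate linearly between
#' the two. Angles are measured in degrees from the image x axis (columns),
#' modulo 180.
#'
#' @param width,height Image size in pixels (>= 32).
#' @param angle Fiber orientation in degrees, in \[0, 180).
#' @param coherence Stripe/noise blend fraction in \[0, 1\].
#' @param frequency Stripe frequency in cycles per pixel (default 0.08).
#' @param seed Integer seed for the noise field.
#'
#' @return A `height` x `width` numeric matrix with values in \[0, 1\].
#' @export
#'
#' @examples
#' img <- generate_fiber_image(64, 64, angle = 30, coherence = 1, seed = 1)
#' dim(img)
generate_fiber_image <- function(width = 256, height = 256, angle = 0,
                                 coherence = 1, frequency = 0.08, seed = 1L) {
  if (width < 32 || height < 32) {
    td_abort("image must be at least 32 x 32 pixels", "trajdyn_input_error")
  }
  if (!is.numeric(angle) || length(angle) != 1L || angle < 0 || angle >= 180) {
    td_abort("`angle` must lie in [0, 180)", "trajdyn_input_error")
  }
  td_assert_scalar_number(coherence, "coherence", 0, 1)
  td_assert_scalar_number(frequency, "frequency", lower = 0, strict_lower = TRUE)
  set.seed(as.integer(seed))
  th <- angle * pi / 180
  i <- matrix(seq_len(height), height, width)          # rows (y)
  j <- matrix(seq_len(width), height, width, byrow = TRUE)  # cols (x)
  # intensity varies along the direction perpendicular to the fibers:
  # phase = 2*pi*f * (x*sin(theta) - y*cos(theta))
  stripes <- 0.5 + 0.5 * sin(2 * pi * frequency * (j * sin(th) - i * cos(th)))
  noise <- matrix(runif(height * width), height, width)
  coherence * stripes + (1 - coherence) * noise
}
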