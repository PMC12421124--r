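# Shared small helpers: rounding and report formatting conventions.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published clinical tables almost
#' always round half up. Used only when rendering tables, never in
#' computation.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.25, 0.35), 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a percentage for table rendering
#'
#' One decimal place, half-up, with a trailing percent sign.
#'
#' @param x Percentage values (already on the 0-100 scale).
#' @param digits Decimal places (default 1).
#' @return Character vector.
#' @export
fmt_pct <- function(x, digits = 1) {
  out <- sprintf(paste0("%.", digits, "f%%"), round_half_up(x, digits))
  out[is.na(x)] <- NA_character_
  out
}

#' Format a p-value for table rendering
#'
#' Four decimal places with a `<0.0001` floor.
#'
#' @param p Numeric p-values.
#' @return Character vector.
#' @export
fmt_p <- function(p) {
  out <- ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", round_half_up(p, 4)))
  out[is.na(p)] <- NA_character_
  out
}

#' Sphere-equivalent volume of a diameter
#'
#' Volume of a sphere with the given diameter, the standard conversion
#' between the two sizing scales for pulmonary nodules.
#'
#' @param diameter_mm Diameter in mm.
#' @return Volume in mm^3.
#' @export
sphere_volume <- function(diameter_mm) pi / 6 * diameter_mm^3

#' Sphere-equivalent diameter of a volume
#'
#' @param volume_mm3 Volume in mm^3.
#' @return Diameter in mm.
#' @export
sphere_diameter <- function(volume_mm3) (6 * volume_mm3 / pi)^(1 / 3)

# derive a reproducible sub-stream seed from a top-level seed and a stream
# label, so adding a new draw stream never perturbs earlier ones
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 997L)
}

with_substream <- function(seed, label, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(substream_seed(seed, label), code)
}

stop_domain <- function(msg, ...) abort(sprintf(msg, ...), class = "nodulestrat_domain_error")
stop_schema <- function(msg, ...) abort(sprintf(msg, ...), class = "nodulestrat_schema_error")
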