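# Nodule-management protocol configuration.

#' Define a nodule management protocol
#'
#' A protocol fixes the sizing mode and the size cut-offs used to classify
#' a baseline solid nodule. Rule-out sets are strict (`< cut-off`),
#' rule-in sets inclusive (`>= cut-off`), matching guideline notation.
#' Under a volumetric protocol, nodules without reliable segmentation are
#' classified by the fallback diameter cut-offs.
#'
#' @param mode `"volumetric"` (size is CAD-derived volume where reliable)
#'   or `"diameter"` (long-axis diameter throughout).
#' @param rule_out_volume_mm3,rule_in_volume_mm3 Volume cut-offs (mm^3).
#' @param rule_out_diameter_mm,rule_in_diameter_mm Diameter cut-offs (mm),
#'   used when `mode = "diameter"`.
#' @param fallback_rule_out_diameter_mm,fallback_rule_in_diameter_mm
#'   Diameter cut-offs applied to unsegmentable nodules under a volumetric
#'   protocol.
#' @param brock_threshold Brock probability at or above which a
#'   rule-in-sized nodule is referred (default 0.10); `NA` disables the
#'   gate so that rule-in size alone triggers referral.
#' @param growth_referral_volume_mm3 Interval-scan growth referral constant
#'   (mm^3); carried for completeness, no interval-scan logic is executed.
#' @return A `protocol_config` object.
#' @export
#' @examples
#' bts_protocol()
protocol_config <- function(mode = c("volumetric", "diameter"),
                            rule_out_volume_mm3 = 80,
                            rule_in_volume_mm3 = 300,
                            rule_out_diameter_mm = 5,
                            rule_in_diameter_mm = 8,
                            fallback_rule_out_diameter_mm = 6,
                            fallback_rule_in_diameter_mm = 8,
                            brock_threshold = 0.10,
                            growth_referral_volume_mm3 = 200) {
  mode <- match.arg(mode)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1) {
      stop_domain("%s must be a single number", nm)
    }
    x
  }
  cfg <- list(
    mode = mode,
    rule_out_volume_mm3 = num1(rule_out_volume_mm3, "rule_out_volume_mm3"),
    rule_in_volume_mm3 = num1(rule_in_volume_mm3, "rule_in_volume_mm3"),
    rule_out_diameter_mm = num1(rule_out_diameter_mm, "rule_out_diameter_mm"),
    rule_in_diameter_mm = num1(rule_in_diameter_mm, "rule_in_diameter_mm"),
    fallback_rule_out_diameter_mm =
      num1(fallback_rule_out_diameter_mm, "fallback_rule_out_diameter_mm"),
    fallback_rule_in_diameter_mm =
      num1(fallback_rule_in_diameter_mm, "fallback_rule_in_diameter_mm"),
    brock_threshold = brock_threshold,
    growth_referral_volume_mm3 =
      num1(growth_referral_volume_mm3, "growth_referral_volume_mm3")
  )
  structure(cfg, class = "protocol_config")
}

#' British Thoracic Society style volumetric protocol
#'
#' Volume-primary protocol: `<80` mm^3 rule-out, `>=300` mm^3 rule-in with
#' a 10% Brock gate. The guideline's own diameter fallback rule-out is
#' `<5` mm; the default here is `6` mm, the fallback categorisation used
#' when unsegmentable nodules are folded into a volumetric analysis. Pass
#' `fallback_rule_out_diameter_mm = 5` for the literal guideline value.
#'
#' @param ... Overrides passed to [protocol_config()].
#' @return A `protocol_config`.
#' @export
bts_protocol <- function(...) {
  protocol_config(mode = "volumetric", ...)
}

#' European position statement style volumetric protocol
#'
#' As [bts_protocol()] but with the 100 mm^3 rule-out threshold.
#'
#' @param ... Overrides passed to [protocol_config()].
#' @return A `protocol_config`.
#' @export
eups_protocol <- function(...) {
  protocol_config(mode = "volumetric", rule_out_volume_mm3 = 100, ...)
}

#' Diameter-primary protocol
#'
#' Long-axis diameter throughout: `<5` mm rule-out, `>=8` mm rule-in,
#' optionally Brock-gated.
#'
#' @param ... Overrides passed to [protocol_config()].
#' @return A `protocol_config`.
#' @export
diameter_protocol <- function(...) {
  protocol_config(mode = "diameter", ...)
}

#' Read / write a protocol configuration file
#'
#' Flat `key: value` YAML naming the [protocol_config()] fields.
#'
#' @param path File path.
#' @return [read_protocol()] a `protocol_config`; [write_protocol()]
#'   `path` invisibly.
#' @export
read_protocol <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(protocol_config, vals)
}

#' @param protocol A `protocol_config`.
#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  yaml::write_yaml(unclass(protocol), path)
  invisible(path)
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf("<protocol_config> mode=%s\n", x$mode))
  cat(sprintf("  rule-out: <%g mm^3 / <%g mm (fallback <%g mm)\n",
              x$rule_out_volume_mm3, x$rule_out_diameter_mm,
              x$fallback_rule_out_diameter_mm))
  cat(sprintf("  rule-in : >=%g mm^3 / >=%g mm (fallback >=%g mm)\n",
              x$rule_in_volume_mm3, x$rule_in_diameter_mm,
              x$fallback_rule_in_diameter_mm))
  cat(sprintf("  Brock gate: %s\n",
              if (is.na(x$brock_threshold)) "disabled"
              else sprintf(">=%g", x$brock_threshold)))
  invisible(x)
}
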