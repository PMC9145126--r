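#' @keywords internal
"_PACKAGE"

# Structured error helpers. Classes allow expect_error(class = ...) in tests
# and programmatic handling in the CLI.
stop_dmoct <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dmoct_error", "error", "condition")))
}

config_error     <- function(msg) stop_dmoct(msg, "dmoct_config_error")
format_error     <- function(msg) stop_dmoct(msg, "dmoct_format_error")
validation_error <- function(msg) stop_dmoct(msg, "dmoct_validation_error")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is_scalar_number(x))
    config_error(sprintf("'%s' must be a single finite number", name))
  ok <- if (strict) x > lower else x >= lower
  if (!ok)
    config_error(sprintf("'%s' must be %s %g (got %g)",
                         name, if (strict) ">" else ">=", lower, x))
  invisible(x)
}

#' Weight-per-volume concentration in percent
#'
#' Converts a dissolved mass in milligrams and a solvent volume in millilitres
#' to a percent weight-per-volume concentration (g per 100 mL). Used to check
#' exposure-solution definitions, e.g. 5 mg per 100 mL gives 0.005%.
#'
#' @param mass_mg dissolved mass in mg.
#' @param volume_ml solvent volume in mL.
#' @return concentration in percent w/v.
#' @examples
#' percent_w_v(5, 100)  # 0.005
#' @export
percent_w_v <- function(mass_mg, volume_ml) {
  check_scalar(mass_mg, "mass_mg", 0)
  check_scalar(volume_ml, "volume_ml", 0, strict = TRUE)
  (mass_mg / 1000) / volume_ml * 100
}

# Derive a 32-bit-safe stream seed from a master seed and stream labels.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 69069 + round(p * 131)) %% 2147483629
  as.integer(h)
}
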