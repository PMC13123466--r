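## Unit handling: all internal computation is strict SI (kg, m, s, N, Pa s).
## Configuration files may carry human units ("1.09 g/mL", "0.5 mm/s",
## "0.58 nN"); they are converted once, at the boundary.

# multiplicative factors to SI
.unit_table <- c(
  "m" = 1, "mm" = 1e-3, "cm" = 1e-2, "um" = 1e-6,
  "s" = 1, "min" = 60, "h" = 3600, "ms" = 1e-3,
  "m/s" = 1, "mm/s" = 1e-3, "cm/s" = 1e-2, "um/s" = 1e-6, "mm/min" = 1e-3 / 60,
  "kg/m^3" = 1, "kg/m3" = 1, "g/mL" = 1e3, "g/ml" = 1e3, "g/cm^3" = 1e3,
  "g/cm3" = 1e3, "g/L" = 1,
  "Pa.s" = 1, "Pa s" = 1, "Pa*s" = 1, "mPa.s" = 1e-3, "mPa s" = 1e-3,
  "N" = 1, "mN" = 1e-3, "uN" = 1e-6, "nN" = 1e-9, "pN" = 1e-12,
  "Hz" = 1, "1/s" = 1, "1/min" = 1 / 60, "/min" = 1 / 60, "/s" = 1,
  "m^3" = 1, "m3" = 1, "mm^3" = 1e-9, "mm3" = 1e-9, "uL" = 1e-9, "mL" = 1e-6,
  "m^2/s" = 1, "mm^2/s" = 1e-6,
  "m/s^2" = 1, "m/s2" = 1
)

#' Parse a physical quantity with an optional unit suffix
#'
#' Accepts a bare number, a numeric string, or a string of the form
#' `"<number> <unit>"` (e.g. `"0.5 mm/s"`, `"1.09 g/mL"`, `"0.58 nN"`,
#' `"4.78 mPa.s"`), and returns the value converted to SI base units.
#'
#' @param x number or character scalar.
#' @return numeric scalar in SI units.
#' @examples
#' parse_quantity("0.5 mm/s")   # 5e-4
#' parse_quantity("1.09 g/mL")  # 1090
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) || length(x) != 1L)
    stop("parse_quantity() expects a single number or string", call. = FALSE)
  x <- trimws(x)
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) return(num)
  m <- regmatches(x, regexec("^([-+0-9.eE]+)\\s*(.+)$", x))[[1]]
  if (length(m) != 3L)
    stop("cannot parse quantity: '", x, "'", call. = FALSE)
  val <- suppressWarnings(as.numeric(m[2]))
  unit <- trimws(m[3])
  if (is.na(val) || !(unit %in% names(.unit_table)))
    stop("cannot parse quantity: '", x, "' (unknown unit '", unit, "')",
         call. = FALSE)
  val * unname(.unit_table[unit])
}

# recursively convert quantity strings in a parsed config list
.parse_quantities <- function(x) {
  if (is.list(x)) return(lapply(x, .parse_quantities))
  if (is.character(x) && length(x) == 1L) {
    out <- tryCatch(parse_quantity(x), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  x
}

.check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(what, " must be a positive finite number", call. = FALSE)
  invisible(x)
}

.check_nonneg <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(what, " must be a non-negative finite number", call. = FALSE)
  invisible(x)
}
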