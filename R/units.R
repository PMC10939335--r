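#' Parse a quantity with an explicit unit suffix
#'
#' Configuration files accept quantities as strings with a unit suffix
#' (`"20 mm"`, `"400 kHz"`, `"30 mT"`).  Bare numbers are taken to be in SI
#' base units already.  Conversion to SI happens exactly once, here.
#'
#' @param x a number, or a string `"<value> <unit>"`.
#' @param kind quantity kind, used to restrict admissible units; one of
#'   `"length"`, `"frequency"`, `"flux_density"`, `"time"`,
#'   `"temperature"`, `"any"`.
#' @return numeric value in SI units (m, Hz, T, s, degC).
#' @examples
#' parse_quantity("25 mm", "length")      # 0.025
#' parse_quantity("400 kHz", "frequency") # 4e5
#' @export
parse_quantity <- function(x, kind = "any") {
  if (is.numeric(x)) return(as.numeric(x))
  if (length(x) != 1L || !is.character(x))
    stop("quantity must be a number or a single 'value unit' string")
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*([a-zA-Z]*)\\s*$", x))[[1]]
  if (length(m) != 3L || m[2] == "")
    stop("cannot parse quantity: ", x)
  val <- as.numeric(m[2])
  unit <- m[3]
  if (unit == "") return(val)
  factors <- c(
    mm = 1e-3, cm = 1e-2, m = 1, um = 1e-6,
    Hz = 1, kHz = 1e3, MHz = 1e6,
    T = 1, mT = 1e-3, uT = 1e-6,
    s = 1, min = 60, h = 3600,
    C = 1, degC = 1, K = 1,
    V = 1, mV = 1e-3, A = 1, W = 1
  )
  kinds <- list(
    length = c("mm", "cm", "m", "um"),
    frequency = c("Hz", "kHz", "MHz"),
    flux_density = c("T", "mT", "uT"),
    time = c("s", "min", "h"),
    temperature = c("C", "degC", "K")
  )
  if (!unit %in% names(factors)) stop("unknown unit: ", unit)
  if (kind != "any" && !unit %in% kinds[[kind]])
    stop("unit '", unit, "' is not a ", kind, " unit")
  val * factors[[unit]]
}

# format a length in metres as "x mm" for config output (full precision so
# configs round-trip exactly)
format_mm <- function(x) paste(format(x * 1e3, digits = 17, trim = TRUE), "mm")

# trapezoidal integral (thin wrapper so the rule used is in one place)
trapz_int <- function(x, y) pracma::trapz(x, y)
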