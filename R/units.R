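#' Parse a concentration with an optional unit suffix
#'
#' Concentrations are handled internally in molar. Assay tables and figure
#' legends in this field mix nM and uM freely, so user-facing entry points
#' accept strings like \code{"30nM"}, \code{"6.05uM"}, \code{"0.2mM"} or a
#' bare number (taken as molar).
#'
#' @param x numeric (molar) or character scalar/vector with suffix
#'   \code{"M"}, \code{"mM"}, \code{"uM"}/\code{"µM"} or \code{"nM"}
#'   (case-insensitive except M itself); whitespace between number and unit
#'   is allowed.
#' @return numeric vector of concentrations in molar.
#' @examples
#' parse_conc("30nM")
#' parse_conc(c("6.05uM", "5.39 uM"))
#' parse_conc(3e-8)
#' @export
parse_conc <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x)) stop("concentration must be numeric (M) or character with unit suffix")
  scale <- c(m = 1, mm = 1e-3, um = 1e-6, nm = 1e-9, pm = 1e-12)
  out <- vapply(x, function(s) {
    s <- gsub("\\s+", "", s)
    m <- regmatches(s, regexec("^([0-9.eE+-]+)([A-Za-zµ]*)$", s))[[1]]
    if (length(m) != 3L || m[2] == "")
      stop("cannot parse concentration: '", s, "'")
    val <- suppressWarnings(as.numeric(m[2]))
    if (is.na(val)) stop("cannot parse concentration: '", s, "'")
    unit <- tolower(chartr("µ", "u", m[3]))
    if (unit == "") return(val)
    if (!unit %in% names(scale)) stop("unknown concentration unit: '", m[3], "'")
    val * scale[[unit]]
  }, numeric(1), USE.NAMES = FALSE)
  out
}
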