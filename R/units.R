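#' Units used by the stock-accounting pipeline
#'
#' Areal stocks are expressed either per square metre (`g_per_m2`) or per
#' hectare (`Mg_per_ha`); the two differ by an exact factor of 100
#' (100 g m^-2 = 1 Mg ha^-1). Annual rates carry the same factor. `Mg`
#' (megagram = metric tonne) is an absolute mass used for water-body and
#' lagoon totals and is not convertible to an areal unit.
#'
#' @return Character vector of recognised unit codes.
#' @export
stock_units <- function() {
  c("g_per_m2", "Mg_per_ha", "g_per_m2_per_yr", "Mg_per_ha_per_yr", "Mg")
}

# dimension of each unit: areal standing stock, areal annual rate, absolute mass
.unit_dimension <- c(
  g_per_m2         = "areal",
  Mg_per_ha        = "areal",
  g_per_m2_per_yr  = "annual",
  Mg_per_ha_per_yr = "annual",
  Mg               = "mass"
)

# multiplier taking a value in this unit to the g m^-2 (or g m^-2 y^-1) scale
.unit_factor <- c(
  g_per_m2         = 1,
  Mg_per_ha        = 100,
  g_per_m2_per_yr  = 1,
  Mg_per_ha_per_yr = 100,
  Mg               = NA_real_
)

.check_unit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L || !unit %in% stock_units()) {
    stop("unknown unit: ", paste(unit, collapse = ", "),
         " (expected one of ", paste(stock_units(), collapse = ", "), ")",
         call. = FALSE)
  }
  unit
}

#' Convert a quantity between compatible units
#'
#' Conversions are exact powers of ten within a dimension (areal standing
#' stocks, areal annual rates). Converting between dimensions -- e.g. an
#' areal stock to an absolute mass in `Mg` -- is an error: that step needs
#' an area and is performed by [upscale()].
#'
#' @param value Numeric vector of quantities.
#' @param from,to Unit codes, see [stock_units()].
#' @return Numeric vector in the target unit.
#' @examples
#' convert_quantity(100, "g_per_m2", "Mg_per_ha")   # 1
#' convert_quantity(15.17, "Mg_per_ha", "g_per_m2") # 1517
#' @export
convert_quantity <- function(value, from, to) {
  .check_unit(from)
  .check_unit(to)
  if (.unit_dimension[[from]] != .unit_dimension[[to]]) {
    stop("cannot convert ", from, " to ", to,
         ": incompatible dimensions (", .unit_dimension[[from]], " vs ",
         .unit_dimension[[to]], ")", call. = FALSE)
  }
  if (from == to) return(value)
  value * .unit_factor[[from]] / .unit_factor[[to]]
}
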