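#' Read a CSV table into a TabularSeries
#'
#' Reads a header CSV and converts the declared columns to internal SI
#' (per-molecule for molar quantities, so enthalpy in kJ/mol becomes joule
#' per molecule).  The first entry of `schema` names the independent
#' variable, which must be strictly increasing with no duplicates.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping column names to unit
#'   strings, e.g. `c(T = "K", H = "kJ/mol")`; the first entry is the
#'   independent variable.
#' @return a [TabularSeries-class] with SI values.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write.csv(data.frame(T = c(100, 150), H = c(9, 10)), tmp, row.names = FALSE)
#' s <- readSeries(tmp, c(T = "K", H = "kJ/mol"))
#' seriesColumn(s, "H")   # J per molecule
#' @export
readSeries <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(schema) < 2 || is.null(names(schema)))
    stop("schema must name the independent variable and >= 1 dependent column")
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop("columns named in schema absent from '", path, "': ",
         paste(missing, collapse = ", "))
  for (u in schema) .lookupUnit(u)          # fail early on unknown units
  xName <- names(schema)[1]
  x <- df[[xName]]
  if (anyDuplicated(x))
    stop("duplicated values in independent variable '", xName, "'")
  if (is.unsorted(x, strictly = TRUE))
    stop("independent variable '", xName, "' must be strictly increasing")
  depNames <- names(schema)[-1]
  args <- c(list(x = x, xUnit = schema[[1]]),
            stats::setNames(lapply(depNames, function(nm) df[[nm]]), depNames),
            list(units = schema[-1]))
  do.call(makeSeries, args)
}

#' Write a TabularSeries to CSV in conventional units
#'
#' Inverse of [readSeries()]: converts the SI-stored columns back to the
#' units declared when the series was built and writes a header CSV whose
#' column names carry the unit (e.g. `T [K]`, `H [kJ/mol]`).
#'
#' @param series a [TabularSeries-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSeries <- function(series, path) {
  stopifnot(is(series, "TabularSeries"))
  out <- data.frame(fromSI(seriesX(series), series@xUnit))
  names(out) <- sprintf("%s [%s]", "x", series@xUnit)
  un <- seriesUnits(series)
  for (nm in names(series@data)) {
    out[[sprintf("%s [%s]", nm, un[[nm]])]] <- fromSI(series@data[[nm]], un[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
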