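## Accessor generics and show methods.  Slot access stays behind accessors.

#' Accessors for Frame objects
#'
#' @param object a [Frame-class].
#' @return `positions()` the wrapped n x 3 coordinate matrix (nm);
#'   `unwrappedPositions()` the unwrapped matrix (0-row when absent);
#'   `boxEdges()` the three box edges (nm); `frameTime()` the time (ps);
#'   `moleculeLabels()` the phase labels; `nMolecules()` the molecule count.
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname positions
#' @export
setGeneric("unwrappedPositions",
           function(object) standardGeneric("unwrappedPositions"))
#' @rdname positions
#' @export
setGeneric("boxEdges", function(object) standardGeneric("boxEdges"))
#' @rdname positions
#' @export
setGeneric("frameTime", function(object) standardGeneric("frameTime"))
#' @rdname positions
#' @export
setGeneric("moleculeLabels", function(object) standardGeneric("moleculeLabels"))
#' @rdname positions
#' @export
setGeneric("nMolecules", function(object) standardGeneric("nMolecules"))

#' @rdname positions
setMethod("positions", "Frame", function(object) object@coords)
#' @rdname positions
setMethod("unwrappedPositions", "Frame", function(object) object@unwrapped)
#' @rdname positions
setMethod("boxEdges", "Frame", function(object) object@box)
#' @rdname positions
setMethod("frameTime", "Frame", function(object) object@time)
#' @rdname positions
setMethod("moleculeLabels", "Frame", function(object) object@labels)
#' @rdname positions
setMethod("nMolecules", "Frame", function(object) nrow(object@coords))

#' Accessors for TabularSeries objects
#'
#' @param object a [TabularSeries-class].
#' @param column column name for `seriesColumn()`.
#' @return `seriesX()` the independent variable (SI); `seriesColumn()` one
#'   dependent column (SI); `seriesUnits()` the declared input units;
#'   `seriesLength()` the number of rows.
#' @export
setGeneric("seriesX", function(object) standardGeneric("seriesX"))
#' @rdname seriesX
#' @export
setGeneric("seriesColumn",
           function(object, column) standardGeneric("seriesColumn"))
#' @rdname seriesX
#' @export
setGeneric("seriesUnits", function(object) standardGeneric("seriesUnits"))
#' @rdname seriesX
#' @export
setGeneric("seriesLength", function(object) standardGeneric("seriesLength"))

#' @rdname seriesX
setMethod("seriesX", "TabularSeries", function(object) object@x)
#' @rdname seriesX
setMethod("seriesColumn", "TabularSeries", function(object, column) {
  if (!column %in% names(object@data))
    stop("no column '", column, "' in series")
  object@data[[column]]
})
#' @rdname seriesX
setMethod("seriesUnits", "TabularSeries", function(object) object@units)
#' @rdname seriesX
setMethod("seriesLength", "TabularSeries", function(object) length(object@x))

#' Accessors for MoleculeTemplate objects
#'
#' @param object a [MoleculeTemplate-class].
#' @return `atomPositions()` the 4 x 3 position matrix (nm); `charges()`
#'   the four partial charges (e); `bondLength()` the bond length (nm);
#'   `diagonals()` the named long/short diagonal lengths (nm).
#' @export
setGeneric("atomPositions", function(object) standardGeneric("atomPositions"))
#' @rdname atomPositions
#' @export
setGeneric("charges", function(object) standardGeneric("charges"))
#' @rdname atomPositions
#' @export
setGeneric("bondLength", function(object) standardGeneric("bondLength"))
#' @rdname atomPositions
#' @export
setGeneric("diagonals", function(object) standardGeneric("diagonals"))

#' @rdname atomPositions
setMethod("atomPositions", "MoleculeTemplate", function(object) object@positions)
#' @rdname atomPositions
setMethod("charges", "MoleculeTemplate", function(object) object@charges)
#' @rdname atomPositions
setMethod("bondLength", "MoleculeTemplate", function(object) object@bondLength)
#' @rdname atomPositions
setMethod("diagonals", "MoleculeTemplate",
          function(object) c(long = object@dLong, short = object@dShort))

#' Accessors for spectra and stiffness estimates
#'
#' @param object a [FluctuationSpectrum-class] or [StiffnessEstimate-class].
#' @return `wavenumbers()` the mode wavenumbers (nm^-1); `spectrumValues()`
#'   the averaged `<|h(q)|^2>` (nm^2); `stiffness()` the estimated (or
#'   injected) stiffness (mJ/m^2); `stiffnessSE()` its standard error;
#'   `qcSlope()` the unconstrained log-log slope of the fit window.
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))
#' @rdname wavenumbers
#' @export
setGeneric("spectrumValues", function(object) standardGeneric("spectrumValues"))
#' @rdname wavenumbers
#' @export
setGeneric("stiffness", function(object) standardGeneric("stiffness"))
#' @rdname wavenumbers
#' @export
setGeneric("stiffnessSE", function(object) standardGeneric("stiffnessSE"))
#' @rdname wavenumbers
#' @export
setGeneric("qcSlope", function(object) standardGeneric("qcSlope"))

#' @rdname wavenumbers
setMethod("wavenumbers", "FluctuationSpectrum", function(object) object@q)
#' @rdname wavenumbers
setMethod("spectrumValues", "FluctuationSpectrum", function(object) object@s2)
#' @rdname wavenumbers
setMethod("stiffness", "StiffnessEstimate", function(object) object@stiffness)
#' @rdname wavenumbers
setMethod("stiffness", "CapillaryEnsemble", function(object) object@stiffness)
#' @rdname wavenumbers
setMethod("stiffnessSE", "StiffnessEstimate", function(object) object@se)
#' @rdname wavenumbers
setMethod("qcSlope", "StiffnessEstimate", function(object) object@qcSlope)

#' Accessors for order fields and neighbor lists
#'
#' @param object an [OrderField-class] or [NeighborList-class].
#' @param i molecule index for `neighborIds()` / `neighborDisplacements()`.
#' @return `orderValues()` the per-molecule order parameter values;
#'   `neighborIds()` the neighbor index vector of molecule `i`;
#'   `neighborDisplacements()` its k x 3 minimum-image displacement matrix.
#' @export
setGeneric("orderValues", function(object) standardGeneric("orderValues"))
#' @rdname orderValues
#' @export
setGeneric("neighborIds", function(object, i) standardGeneric("neighborIds"))
#' @rdname orderValues
#' @export
setGeneric("neighborDisplacements",
           function(object, i) standardGeneric("neighborDisplacements"))

#' @rdname orderValues
setMethod("orderValues", "OrderField", function(object) object@values)
#' @rdname orderValues
setMethod("neighborIds", "NeighborList", function(object, i) object@idx[[i]])
#' @rdname orderValues
setMethod("neighborDisplacements", "NeighborList",
          function(object, i) object@disp[[i]])

#' Temperature grid of a temperature-indexed result
#'
#' @param object a [ThermoCurves-class], [DrivingForce-class],
#'   [GammaCurve-class] or [CNTResult-class].
#' @return the temperature grid, K.
#' @export
setGeneric("temperatureGrid",
           function(object) standardGeneric("temperatureGrid"))

#' @rdname temperatureGrid
setMethod("temperatureGrid", "ThermoCurves", function(object) object@temperature)
#' @rdname temperatureGrid
setMethod("temperatureGrid", "DrivingForce", function(object) object@temperature)
#' @rdname temperatureGrid
setMethod("temperatureGrid", "GammaCurve", function(object) object@temperature)
#' @rdname temperatureGrid
setMethod("temperatureGrid", "CNTResult", function(object) object@temperature)

#' Tabulate a temperature-indexed result as a data.frame
#'
#' @param object a [DrivingForce-class], [GammaCurve-class] or
#'   [CNTResult-class].
#' @return data.frame with one row per grid temperature; column units are
#'   those documented for the class slots.
#' @export
setGeneric("asTable", function(object) standardGeneric("asTable"))

#' @rdname asTable
setMethod("asTable", "DrivingForce", function(object)
  data.frame(T_K = object@temperature, dS_J_per_K = object@dS,
             dG_J = object@dG, dGv_J_per_m3 = object@dGv))
#' @rdname asTable
setMethod("asTable", "GammaCurve", function(object)
  data.frame(T_K = object@temperature, gamma_mJ_per_m2 = object@gamma))
#' @rdname asTable
setMethod("asTable", "CNTResult", function(object)
  data.frame(T_K = object@temperature, gamma_mJ_per_m2 = object@gamma,
             dG_J = object@dG, dGv_J_per_m3 = object@dGv, dW_J = object@dW,
             D_m2_per_s = object@D, A_U_m_per_s = object@aU,
             N_per_nm3_s = object@N, U_m_per_s = object@U,
             N_over_D = object@nOverD))

## ------------------------------- show ------------------------------------

setMethod("show", "Frame", function(object) {
  cat(sprintf("Frame: %d molecules, box %.3f x %.3f x %.3f nm, t = %g ps\n",
              nrow(object@coords), object@box[1], object@box[2],
              object@box[3], object@time))
  if (length(object@labels))
    cat("  labels:", paste(sprintf("%s=%d", names(table(object@labels)),
                                   table(object@labels)), collapse = ", "), "\n")
})

setMethod("show", "TabularSeries", function(object) {
  cat(sprintf("TabularSeries: %d rows, x in %s; columns: %s\n",
              length(object@x), object@xUnit,
              paste(sprintf("%s [%s]", names(object@data), object@units),
                    collapse = ", ")))
})

setMethod("show", "MoleculeTemplate", function(object) {
  d <- diagonals(object)
  cat(sprintf(paste0("MoleculeTemplate: rhombus, b = %.5f nm, ",
                     "diagonals %.5f / %.5f nm\n"),
              object@bondLength, d["long"], d["short"]))
  cat("  charges (e):", paste(sprintf("%+.3f", object@charges),
                              collapse = ", "), "\n")
})

setMethod("show", "CapillaryEnsemble", function(object) {
  cat(sprintf(paste0("CapillaryEnsemble: %d samples x %d bins, Lx = %g nm, ",
                     "Lz = %g nm,\n  T = %g K, injected stiffness %g mJ/m^2, ",
                     "%d modes, seed %d\n"),
              nrow(object@heights), ncol(object@heights), object@Lx,
              object@Lz, object@temperature, object@stiffness,
              object@nModes, object@seed))
})

setMethod("show", "FluctuationSpectrum", function(object) {
  cat(sprintf("FluctuationSpectrum: %d modes, %d fields averaged, Lx = %g nm\n",
              length(object@q), object@nFields, object@Lx))
})

setMethod("show", "StiffnessEstimate", function(object) {
  cat(sprintf("StiffnessEstimate: %.4g +- %.2g mJ/m^2 (modes %d-%d)\n",
              object@stiffness, object@se, min(object@window),
              max(object@window)))
  cat(sprintf("  QC unconstrained slope: %.3f%s\n", object@qcSlope,
              if (object@qcWarning) "  [deviates from -2 beyond tolerance]"
              else ""))
})

setMethod("show", "InterfaceProfileFit", function(object) {
  cat(sprintf(paste0("InterfaceProfileFit (%s form): oS = %.4f, oL = %.4f,\n",
                     "  h1 = %.3f nm (delta %.3f), h2 = %.3f nm (delta %.3f), ",
                     "residual %.3g\n"),
              object@form, object@oS, object@oL, object@h1, object@delta1,
              object@h2, object@delta2, object@residual))
})

setMethod("show", "OrderField", function(object) {
  v <- object@values[!object@flagged]
  cat(sprintf("OrderField: %s q%d, %d molecules (%d flagged), range %.3f-%.3f\n",
              if (object@averaged) "averaged" else "plain", object@l,
              length(object@values), sum(object@flagged),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "ThermoCurves", function(object) {
  cat(sprintf(paste0("ThermoCurves: %d grid points on [%g, %g] K, ",
                     "Tm = %g K, dHm = %.4g J/molecule\n"),
              length(object@temperature), min(object@temperature),
              max(object@temperature), object@Tm, object@dHm))
})

setMethod("show", "DrivingForce", function(object) {
  cat(sprintf("DrivingForce: %d grid points, max dG = %.4g J/molecule\n",
              length(object@temperature), max(object@dG)))
})

setMethod("show", "GammaCurve", function(object) {
  cat(sprintf("GammaCurve: gammaM = %g mJ/m^2, %d grid points\n",
              object@gammaM, length(object@temperature)))
})

setMethod("show", "VFTParams", function(object) {
  cat(sprintf("VFTParams: log10(1/D0) = %.4f, B = %.4g K, T0 = %.4g K\n",
              object@log10invD0, object@B, object@T0))
})

setMethod("show", "CNTResult", function(object) {
  cat(sprintf(paste0("CNTResult: %d grid points on [%g, %g] K\n",
                     "  argmax N at %g K, argmax U at %g K\n"),
              length(object@temperature), min(object@temperature),
              max(object@temperature), object@argmaxN, object@argmaxU))
})
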