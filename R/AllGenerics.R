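#' Accessors for grids, fields and stacks
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a ClimGrid, ClimField, SnapshotStack or related object.
#' @param ... unused.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("lonCenters", function(x) standardGeneric("lonCenters"))
#' @rdname accessors
#' @export
setGeneric("latCenters", function(x) standardGeneric("latCenters"))
#' @rdname accessors
#' @export
setGeneric("gridRes", function(x) standardGeneric("gridRes"))
#' @rdname accessors
#' @export
setGeneric("isPeriodicLon", function(x) standardGeneric("isPeriodicLon"))
#' @rdname accessors
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))
#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' @rdname accessors
#' @export
setGeneric("fieldMask", function(x) standardGeneric("fieldMask"))
#' @rdname accessors
#' @export
setGeneric("fieldUnits", function(x) standardGeneric("fieldUnits"))
#' @rdname accessors
#' @export
setGeneric("variableId", function(x) standardGeneric("variableId"))
#' @rdname accessors
#' @export
setGeneric("fieldMetadata", function(x) standardGeneric("fieldMetadata"))
#' @rdname accessors
#' @export
setGeneric("snapshotTimes", function(x) standardGeneric("snapshotTimes"))
#' @rdname accessors
#' @export
setGeneric("snapshotFields", function(x) standardGeneric("snapshotFields"))
#' @rdname accessors
#' @export
setGeneric("nMonths", function(x) standardGeneric("nMonths"))
#' @rdname accessors
#' @export
setGeneric("bioclimLayers", function(x) standardGeneric("bioclimLayers"))
#' @rdname accessors
#' @export
setGeneric("maskCategory", function(x) standardGeneric("maskCategory"))

setMethod("lonCenters", "ClimGrid", function(x) x@lon)
setMethod("latCenters", "ClimGrid", function(x) x@lat)
setMethod("gridRes", "ClimGrid", function(x) x@res)
setMethod("isPeriodicLon", "ClimGrid", function(x) x@periodicLon)
setMethod("gridOf", "ClimField", function(x) x@grid)
setMethod("gridOf", "LandMask", function(x) x@grid)
setMethod("gridOf", "IceMask", function(x) x@grid)
setMethod("fieldValues", "ClimField", function(x) x@values)
setMethod("fieldMask", "ClimField", function(x) x@mask)
setMethod("fieldUnits", "ClimField", function(x) x@units)
setMethod("variableId", "ClimField", function(x) x@variable)
setMethod("variableId", "SnapshotStack", function(x) x@variable)
setMethod("fieldMetadata", "ClimField", function(x) x@metadata)
setMethod("snapshotTimes", "SnapshotStack", function(x) x@times)
setMethod("snapshotFields", "SnapshotStack", function(x) x@fields)
setMethod("nMonths", "ClimField", function(x) {
  d <- dim(x@values)
  if (length(d) == 3L) d[3] else 1L
})
setMethod("bioclimLayers", "BioclimSet", function(x) x@layers)
setMethod("maskCategory", "LandMask", function(x) x@category)

#' Number of cells or layers
#'
#' @param x a ClimGrid.
#' @return integer cell counts.
#' @export
setGeneric("nLon", function(x) standardGeneric("nLon"))
#' @rdname nLon
#' @export
setGeneric("nLat", function(x) standardGeneric("nLat"))
setMethod("nLon", "ClimGrid", function(x) length(x@lon))
setMethod("nLat", "ClimGrid", function(x) length(x@lat))

setMethod("show", "ClimGrid", function(object) {
  cat(sprintf("ClimGrid: %d x %d cells, %.4g deg%s\n  lon %.4g..%.4g  lat %.4g..%.4g\n",
              nLon(object), nLat(object), object@res,
              if (object@periodicLon) " (periodic lon)" else "",
              min(object@lon), max(object@lon), min(object@lat), max(object@lat)))
})

setMethod("show", "ClimField", function(object) {
  cat(sprintf("ClimField '%s' [%s]: %d x %d cells, %s, %d/%d valid\n",
              object@variable, object@units, nLon(object@grid), nLat(object@grid),
              if (nMonths(object) == 12L) "12 months" else "1 layer",
              sum(object@mask), length(object@mask)))
})

setMethod("show", "SnapshotStack", function(object) {
  cat(sprintf("SnapshotStack '%s' [%s]: %d snapshots, %s..%s BP, grid %d x %d\n",
              object@variable, object@units, length(object@times),
              format(max(object@times), big.mark = ","),
              format(min(object@times), big.mark = ","),
              nLon(object@fields[[1]]@grid), nLat(object@fields[[1]]@grid)))
})

setMethod("show", "LandMask", function(object) {
  tab <- tabulate(object@category + 1L, nbins = 3L)
  cat(sprintf("LandMask at sea level %+.1f m: %d ocean, %d land, %d inland-below-sea-level\n",
              object@seaLevel, tab[1], tab[2], tab[3]))
})

setMethod("show", "BioclimSet", function(object) {
  cat(sprintf("BioclimSet: %d layers (%s)\n", length(object@layers),
              paste(names(object@layers), collapse = ", ")))
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf("SyntheticWorld (seed %d): variables %s; coarse %g deg, fine %g deg, obs %g deg\n",
              object@spec@seed, paste(object@spec@variables, collapse = ","),
              object@spec@coarseRes, object@spec@fineRes, object@spec@obsRes))
})

#' Arithmetic on fields
#'
#' Elementwise arithmetic between two fields on the same grid (masks are
#' intersected) or between a field and a scalar. Used pervasively by the
#' delta stages: the corrected field is literally `regrid(sim) + delta`.
#'
#' @param e1,e2 ClimField or numeric scalar.
#' @return a ClimField.
#' @name field-arith
NULL

#' @rdname field-arith
#' @export
setMethod("Arith", signature("ClimField", "ClimField"), function(e1, e2) {
  stopifnot(gridsIdentical(e1@grid, e2@grid))
  if (!identical(dim(e1@values), dim(e2@values)))
    stop("month-dimension mismatch between fields")
  v <- callGeneric(e1@values, e2@values)
  new("ClimField", grid = e1@grid, variable = e1@variable, values = v,
      mask = e1@mask & e2@mask, units = e1@units, metadata = e1@metadata)
})

#' @rdname field-arith
#' @export
setMethod("Arith", signature("ClimField", "numeric"), function(e1, e2) {
  v <- callGeneric(e1@values, e2)
  new("ClimField", grid = e1@grid, variable = e1@variable, values = v,
      mask = e1@mask, units = e1@units, metadata = e1@metadata)
})

#' @rdname field-arith
#' @export
setMethod("Arith", signature("numeric", "ClimField"), function(e1, e2) {
  v <- callGeneric(e1, e2@values)
  new("ClimField", grid = e2@grid, variable = e2@variable, values = v,
      mask = e2@mask, units = e2@units, metadata = e2@metadata)
})
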