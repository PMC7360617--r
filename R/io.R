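.TABLE1_REGISTRY <- list(
  monthly_temperature        = list(units = "degC",          monthly = TRUE),
  monthly_precipitation      = list(units = "mm month-1",    monthly = TRUE),
  monthly_cloudiness         = list(units = "%",             monthly = TRUE),
  minimum_annual_temperature = list(units = "degC",          monthly = FALSE),
  maximum_annual_temperature = list(units = "degC",          monthly = FALSE),
  monthly_relative_humidity  = list(units = "%",             monthly = TRUE),
  monthly_wind_speed         = list(units = "m s-1",         monthly = TRUE),
  BIO1  = list(units = "degC",          monthly = FALSE),
  BIO4  = list(units = "degC",          monthly = FALSE),
  BIO5  = list(units = "degC",          monthly = FALSE),
  BIO6  = list(units = "degC",          monthly = FALSE),
  BIO7  = list(units = "degC",          monthly = FALSE),
  BIO8  = list(units = "degC",          monthly = FALSE),
  BIO9  = list(units = "degC",          monthly = FALSE),
  BIO10 = list(units = "degC",          monthly = FALSE),
  BIO11 = list(units = "degC",          monthly = FALSE),
  BIO12 = list(units = "mm year-1",     monthly = FALSE),
  BIO13 = list(units = "mm month-1",    monthly = FALSE),
  BIO14 = list(units = "mm month-1",    monthly = FALSE),
  BIO15 = list(units = "1",             monthly = FALSE),
  BIO16 = list(units = "mm quarter-1",  monthly = FALSE),
  BIO17 = list(units = "mm quarter-1",  monthly = FALSE),
  BIO18 = list(units = "mm quarter-1",  monthly = FALSE),
  BIO19 = list(units = "mm quarter-1",  monthly = FALSE),
  net_primary_productivity   = list(units = "gC m-2 year-1", monthly = FALSE),
  leaf_area_index            = list(units = "gC m-2",        monthly = FALSE),
  biome                      = list(units = "categorical",   monthly = FALSE)
)

#' Dataset schema: declared variables, units and dimensions
#'
#' Describes a gridded output dataset: the grid, the time axis (years BP,
#' descending -- the "before present" convention is recorded as an
#' attribute), the declared variables with their canonical units, and a
#' fill value for masked cells. Variable names and units follow the
#' dataset's published layout (monthly climatic variables, annual extremes,
#' BIO1/BIO4-BIO19, vegetation variables); the full-production shape is
#' 720 x 300 cells x 12 months x 72 times for monthly variables and
#' 720 x 300 x 72 for annual ones. A variable written without its declared
#' unit string is rejected before any data is written.
#'
#' @param grid a [ClimGrid-class].
#' @param times numeric years BP, strictly decreasing.
#' @param variables character vector of variable names from the registry
#'   (see Details); defaults to all.
#' @param fillValue numeric fill value recorded for masked cells.
#' @return an object of class `DatasetSchema`.
#' @export
datasetSchema <- function(grid, times, variables = names(.TABLE1_REGISTRY),
                          fillValue = -9999) {
  unknown <- setdiff(variables, names(.TABLE1_REGISTRY))
  if (length(unknown))
    stop(sprintf("unknown variable(s): %s", paste(unknown, collapse = ", ")))
  if (length(times) > 1L && any(diff(times) >= 0))
    stop("times must be strictly decreasing years BP")
  structure(list(grid = grid, times = as.numeric(times),
                 variables = .TABLE1_REGISTRY[variables],
                 fillValue = fillValue,
                 timeConvention = "years before present, descending"),
            class = "DatasetSchema")
}

#' @export
print.DatasetSchema <- function(x, ...) {
  cat(sprintf("DatasetSchema: %d x %d cells, %d times, %d variables\n",
              nLon(x$grid), nLat(x$grid), length(x$times), length(x$variables)))
  invisible(x)
}

.checkAgainstSchema <- function(x, schema) {
  errs <- character()
  for (nm in names(x)) {
    decl <- schema$variables[[nm]]
    if (is.null(decl)) { errs <- c(errs, sprintf("%s: not declared in schema", nm)); next }
    obj <- x[[nm]]
    if (is(obj, "SnapshotStack")) {
      if (!identical(length(obj@times), length(schema$times)) ||
          max(abs(obj@times - schema$times)) > 1e-9)
        errs <- c(errs, sprintf("%s: time axis does not match schema", nm))
      f1 <- obj@fields[[1]]
    } else f1 <- obj
    if (!gridsIdentical(f1@grid, schema$grid))
      errs <- c(errs, sprintf("%s: grid does not match schema", nm))
    if (!identical(f1@units, decl$units))
      errs <- c(errs, sprintf("%s: units '%s' but schema declares '%s'",
                              nm, f1@units, decl$units))
    isMonthly <- nMonths(f1) == 12L
    if (isMonthly != decl$monthly)
      errs <- c(errs, sprintf("%s: %s layout but schema declares %s", nm,
                              if (isMonthly) "monthly" else "annual",
                              if (decl$monthly) "monthly" else "annual"))
  }
  errs
}

.fmtRow <- function(x) {
  s <- sprintf("%.17g", x)
  s[is.na(x)] <- "NA"
  paste(s, collapse = ",")
}

.writeFieldCSV <- function(con, field, t) {
  v <- .asMonthArray(field)
  v[array(!field@mask, dim = dim(v))] <- NA_real_
  nm <- dim(v)[3]
  for (m in seq_len(nm))
    writeLines(sprintf("%.17g,%d,%s", t, if (nm == 12L) m else NA_integer_,
                       .fmtRow(as.numeric(v[, , m]))), con)
}

#' Write a dataset to a self-describing text bundle
#'
#' Serializes stacks and fields against a [datasetSchema()] into a
#' directory: `schema.json` (grid, time axis, variables, units, fill value)
#' plus one CSV per variable holding full-precision (`%.17g`) values, one
#' row per time and month, masked cells as NA. Reading the bundle back with
#' [readDataset()] reproduces values and masks exactly (bit-identical).
#' Any variable whose units, grid, time axis or monthly/annual layout
#' disagree with the schema is rejected, listing every offending variable,
#' before anything is written.
#'
#' @param x named list of [SnapshotStack-class] (multi-time) and/or
#'   [ClimField-class] (single-time) objects; names must be declared in the
#'   schema.
#' @param schema a [datasetSchema()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
writeDataset <- function(x, schema, path) {
  errs <- .checkAgainstSchema(x, schema)
  if (length(errs))
    stop(paste(c("dataset does not conform to schema:", errs), collapse = "\n  "))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  g <- schema$grid
  jsonlite::write_json(
    list(lon = g@lon, lat = g@lat, res = g@res, periodicLon = g@periodicLon,
         times = schema$times, timeConvention = schema$timeConvention,
         fillValue = schema$fillValue,
         variables = lapply(schema$variables[names(schema$variables) %in% names(x)],
                            function(v) list(units = v$units, monthly = v$monthly))),
    file.path(path, "schema.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(x)) {
    con <- file(file.path(path, paste0(nm, ".csv")), "w")
    obj <- x[[nm]]
    if (is(obj, "SnapshotStack")) {
      for (i in seq_along(obj@times)) .writeFieldCSV(con, obj@fields[[i]], obj@times[i])
    } else .writeFieldCSV(con, obj, schema$times[1])
    close(con)
  }
  invisible(path)
}

#' Read a dataset bundle written by [writeDataset()]
#'
#' @param path bundle directory.
#' @return named list with `schema` (the reconstructed [datasetSchema()])
#'   and one [SnapshotStack-class] or [ClimField-class] per variable.
#' @export
readDataset <- function(path) {
  js <- jsonlite::read_json(file.path(path, "schema.json"), simplifyVector = TRUE)
  grid <- new("ClimGrid", lon = js$lon, lat = js$lat, res = js$res,
              periodicLon = js$periodicLon)
  schema <- datasetSchema(grid, js$times, names(js$variables),
                          fillValue = js$fillValue)
  out <- list(schema = schema)
  nl <- nLon(grid); np <- nLat(grid)
  for (nm in names(js$variables)) {
    decl <- js$variables[[nm]]
    lines <- readLines(file.path(path, paste0(nm, ".csv")))
    parts <- strsplit(lines, ",", fixed = TRUE)
    tcol <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
    vals <- lapply(parts, function(p) suppressWarnings(as.numeric(p[-(1:2)])))
    fields <- lapply(unique(tcol), function(t) {
      rows <- which(tcol == t)
      if (decl$monthly) {
        v <- array(NA_real_, dim = c(nl, np, 12L))
        for (m in seq_along(rows)) v[, , m] <- vals[[rows[m]]]
        msk <- !apply(is.na(v), c(1, 2), any)
      } else {
        v <- array(vals[[rows[1]]], dim = c(nl, np))
        msk <- !is.na(v)
      }
      climField(grid, v, variable = nm, units = decl$units, mask = msk)
    })
    out[[nm]] <- if (length(fields) > 1L)
      snapshotStack(unique(tcol), fields, nm) else fields[[1]]
  }
  out
}

# --- synthetic-world bundle -------------------------------------------------

.SYNTH_NAMES <- c(T = "monthly_temperature", P = "monthly_precipitation")

#' Write / read a complete synthetic input bundle
#'
#' `writeWorldBundle()` lays a [SyntheticWorld-class] out as a directory of
#' text files: `spec.json`, `co2.csv`, `sea_level.csv`, `elevation.csv`,
#' `ice.csv`, and one dataset bundle per variable and resolution
#' (`coarse_<v>/`, `fine_<v>/`, `obs_<v>/`). `readWorldBundle()` reads it
#' back into the plain inputs the pipeline needs (the analytic truth
#' function is not serialized).
#'
#' @param world a [SyntheticWorld-class].
#' @param path bundle directory.
#' @return `path` invisibly; for the reader, a named list.
#' @export
writeWorldBundle <- function(world, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sp <- world@spec
  jsonlite::write_json(
    list(seed = sp@seed, coarseRes = sp@coarseRes, fineRes = sp@fineRes,
         obsRes = sp@obsRes, latLimit = sp@latLimit, variables = sp@variables),
    file.path(path, "spec.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(world@co2, file.path(path, "co2.csv"), row.names = FALSE)
  utils::write.csv(world@seaLevel, file.path(path, "sea_level.csv"), row.names = FALSE)
  gO <- world@elevation@grid
  con <- file(file.path(path, "elevation.csv"), "w")
  writeLines(.fmtRow(as.numeric(world@elevation@values)), con)
  close(con)
  con <- file(file.path(path, "ice.csv"), "w")
  for (im in world@iceMasks)
    writeLines(sprintf("%.17g,%s", im@time,
                       paste(as.integer(im@cover), collapse = ",")), con)
  close(con)
  for (v in sp@variables) {
    nm <- .SYNTH_NAMES[[v]]
    writeDataset(stats::setNames(list(world@coarse[[v]]), nm),
                 datasetSchema(world@coarse[[v]]@fields[[1]]@grid, axis120k(), nm),
                 file.path(path, paste0("coarse_", v)))
    writeDataset(stats::setNames(list(world@fine[[v]]), nm),
                 datasetSchema(world@fine[[v]]@fields[[1]]@grid, axis21k(), nm),
                 file.path(path, paste0("fine_", v)))
    writeDataset(stats::setNames(list(world@obs[[v]]), nm),
                 datasetSchema(gO, 0, nm),
                 file.path(path, paste0("obs_", v)))
  }
  invisible(path)
}

#' @rdname writeWorldBundle
#' @export
readWorldBundle <- function(path) {
  js <- jsonlite::read_json(file.path(path, "spec.json"), simplifyVector = TRUE)
  co2 <- readCO2(file.path(path, "co2.csv"))
  seaLevel <- utils::read.csv(file.path(path, "sea_level.csv"))
  out <- list(spec = js, co2 = co2, seaLevel = seaLevel,
              coarse = list(), fine = list(), obs = list())
  for (v in js$variables) {
    nm <- .SYNTH_NAMES[[v]]
    out$coarse[[v]] <- readDataset(file.path(path, paste0("coarse_", v)))[[nm]]
    out$fine[[v]] <- readDataset(file.path(path, paste0("fine_", v)))[[nm]]
    out$obs[[v]] <- readDataset(file.path(path, paste0("obs_", v)))[[nm]]
  }
  gO <- out$obs[[js$variables[1]]]@grid
  elevVals <- as.numeric(strsplit(readLines(file.path(path, "elevation.csv")), ",")[[1]])
  out$elevation <- climField(gO, array(elevVals, dim = c(nLon(gO), nLat(gO))),
                             variable = "elevation", units = "m")
  iceLines <- strsplit(readLines(file.path(path, "ice.csv")), ",", fixed = TRUE)
  out$iceMasks <- lapply(iceLines, function(p) {
    iceMask(gO, matrix(as.integer(p[-1]) == 1L, nLon(gO), nLat(gO)),
            time = as.numeric(p[1]))
  })
  out
}
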