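#' Construct a region-week surveillance experiment
#'
#' @param schema a [ContaminantSchema-class].
#' @param values numeric matrix, indicators x tuples; NA marks unmeasured
#'   cells. Rows must match `nIndicators(schema)`.
#' @param regionId character region of each tuple (column).
#' @param week integer week index (0 = first study week) of each tuple.
#' @param population positive integer residents per tuple.
#' @param incidences integer matrix, tuples x diseases, nonnegative counts.
#' @param diseases character disease labels (columns of `incidences`).
#' @param week0Date optional ISO date of week 0 (metadata only).
#' @return a [SurveillanceExperiment-class].
#' @export
SurveillanceExperiment <- function(schema, values, regionId, week, population,
                                   incidences, diseases,
                                   week0Date = NA_character_) {
  values <- as.matrix(values)
  incidences <- as.matrix(incidences)
  nT <- ncol(values)
  stopIfNot(nrow(values) == nIndicators(schema),
            "values must have nIndicators(schema) rows")
  stopIfNot(length(regionId) == nT && length(week) == nT &&
            length(population) == nT,
            "per-tuple metadata must match the number of columns")
  stopIfNot(nrow(incidences) == nT && ncol(incidences) == length(diseases),
            "incidences must be tuples x diseases")
  stopIfNot(all(population > 0), "population must be positive")
  stopIfNot(all(incidences >= 0), "incidence counts must be nonnegative")
  stopIfNot(all(week >= 0), "week indices must be >= 0")
  key <- paste(regionId, week)
  if (anyDuplicated(key))
    stop("duplicate (region, week) tuple: ", key[duplicated(key)][1])
  colnames(incidences) <- diseases
  cd <- S4Vectors::DataFrame(region_id = as.character(regionId),
                             week = as.integer(week),
                             population = as.integer(population))
  cd$incidences <- incidences
  pair <- columnPair(schema, seq_len(nIndicators(schema)))
  rd <- S4Vectors::DataFrame(food = pair$food, contaminant = pair$contaminant)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = unname(values), observed = !is.na(unname(values))),
    colData = cd, rowData = rd,
    metadata = list(schema = schema, diseases = as.character(diseases),
                    week0_date = week0Date))
  colnames(se) <- paste(regionId, week, sep = ":")
  new("SurveillanceExperiment", se)
}

setValidity("SurveillanceExperiment", function(object) {
  msg <- NULL
  if (!all(c("values", "observed") %in%
           SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'values' and 'observed' are required")
  md <- S4Vectors::metadata(object)
  if (!is(md$schema, "ContaminantSchema"))
    msg <- c(msg, "metadata must carry the ContaminantSchema")
  if (is.null(md$diseases)) msg <- c(msg, "metadata must list the diseases")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("region_id", "week", "population") %in% colnames(cd)))
    msg <- c(msg, "colData must have region_id, week, population")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SurveillanceExperiment accessors for the surveillance container.
#' @param x a `SurveillanceExperiment`.
#' @export
surveillanceSchema <- function(x) S4Vectors::metadata(x)$schema

#' @rdname SurveillanceExperiment
#' @export
diseases <- function(x) S4Vectors::metadata(x)$diseases

#' @rdname SurveillanceExperiment
#' @export
featureValues <- function(x) SummarizedExperiment::assay(x, "values")

#' @rdname SurveillanceExperiment
#' @export
observedMask <- function(x) SummarizedExperiment::assay(x, "observed")

#' @rdname SurveillanceExperiment
#' @export
regionId <- function(x) SummarizedExperiment::colData(x)$region_id

#' @rdname SurveillanceExperiment
#' @export
weekIndex <- function(x) SummarizedExperiment::colData(x)$week

#' @rdname SurveillanceExperiment
#' @export
population <- function(x) SummarizedExperiment::colData(x)$population

#' @rdname SurveillanceExperiment
#' @export
incidences <- function(x) {
  inc <- SummarizedExperiment::colData(x)$incidences
  colnames(inc) <- diseases(x)
  inc
}

#' Weekly morbidity: incidence counts over resident population
#'
#' @param x a [SurveillanceExperiment-class].
#' @return numeric matrix, tuples x diseases, values in `[0, 1]`.
#' @export
morbidity <- function(x) {
  inc <- incidences(x)
  mb <- sweep(inc, 1L, population(x), "/")
  colnames(mb) <- diseases(x)
  mb
}

setMethod("show", "SurveillanceExperiment", function(object) {
  sc <- surveillanceSchema(object)
  obs <- mean(observedMask(object))
  cat("SurveillanceExperiment:", nrow(object), "contaminant indicators x",
      ncol(object), "region-week tuples\n")
  cat("  schema:", length(foods(sc)), "foods x", length(contaminants(sc)),
      "contaminants;", length(unique(regionId(object))), "regions,",
      length(unique(weekIndex(object))), "weeks\n")
  cat(sprintf("  observed cells: %.1f%%; diseases: %s\n", 100 * obs,
              paste(diseases(object), collapse = ", ")))
})
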