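## On-disk dataset layout (one directory):
##   schema.tsv   column_id <tab> food <tab> contaminant   (food-major order)
##   features.csv region_id,week,column_id,value   (long; absent row = missing)
##   targets.csv  region_id,week,disease,incidences,population
##   meta.yaml    diseases (ordered), week0_date
## All files UTF-8 with header rows. Feature values are printed with "%.17g"
## so a write -> read -> write cycle is byte-identical.

#' Write a surveillance dataset to a directory
#'
#' @param x a [SurveillanceExperiment-class].
#' @param path directory (created if absent).
#' @return `path`, invisibly.
#' @export
writeSurveillance <- function(x, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sc <- surveillanceSchema(x)
  n <- nIndicators(sc)
  pair <- columnPair(sc, seq_len(n))
  writeLines(c("column_id\tfood\tcontaminant",
               sprintf("%d\t%s\t%s", seq_len(n), pair$food, pair$contaminant)),
             file.path(path, "schema.tsv"), useBytes = TRUE)

  vals <- featureValues(x)
  idx <- which(!is.na(vals), arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  reg <- regionId(x); wk <- weekIndex(x)
  writeLines(c("region_id,week,column_id,value",
               if (nrow(idx)) sprintf("%s,%d,%d,%.17g",
                                      reg[idx[, 2L]], wk[idx[, 2L]],
                                      idx[, 1L], vals[idx])),
             file.path(path, "features.csv"), useBytes = TRUE)

  inc <- incidences(x)
  ds <- diseases(x)
  ord <- seq_len(ncol(x))
  lines <- unlist(lapply(ord, function(j)
    sprintf("%s,%d,%s,%d,%d", reg[j], wk[j], ds, inc[j, ], population(x)[j])))
  writeLines(c("region_id,week,disease,incidences,population", lines),
             file.path(path, "targets.csv"), useBytes = TRUE)

  yaml::write_yaml(list(diseases = as.list(ds),
                        week0_date = S4Vectors::metadata(x)$week0_date),
                   file.path(path, "meta.yaml"))
  invisible(path)
}

.parseError <- function(file, line, what)
  stop(sprintf("%s: line %d: %s", file, line, what), call. = FALSE)

.checkHeader <- function(file, expected) {
  hdr <- readLines(file, n = 1L)
  if (!identical(hdr, expected))
    .parseError(file, 1L, sprintf("unexpected header %s (want %s)",
                                  hdr, expected))
}

#' Read a surveillance dataset from a directory
#'
#' Inverse of [writeSurveillance()]; a write -> read round trip reproduces
#' every value, mask and metadata field exactly.
#'
#' @param path dataset directory.
#' @return a [SurveillanceExperiment-class].
#' @export
readSurveillance <- function(path) {
  fSchema <- file.path(path, "schema.tsv")
  fFeat <- file.path(path, "features.csv")
  fTarg <- file.path(path, "targets.csv")
  fMeta <- file.path(path, "meta.yaml")
  for (f in c(fSchema, fFeat, fTarg, fMeta))
    if (!file.exists(f)) stop("missing dataset file: ", f, call. = FALSE)

  sc <- read.delim(fSchema, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(sc), c("column_id", "food", "contaminant")))
    .parseError(fSchema, 1L, "expected header column_id, food, contaminant")
  schema <- ContaminantSchema(unique(sc$food), unique(sc$contaminant))
  if (!identical(sc$column_id,
                 columnId(schema, sc$food, sc$contaminant)) ||
      nrow(sc) != nIndicators(schema))
    .parseError(fSchema, 2L, "column ids are not the food-major bijection")

  meta <- yaml::read_yaml(fMeta)
  ds <- as.character(unlist(meta$diseases))
  if (length(ds) == 0) stop(fMeta, ": no diseases listed", call. = FALSE)

  .checkHeader(fTarg, "region_id,week,disease,incidences,population")
  targ <- read.csv(fTarg, stringsAsFactors = FALSE)
  key <- paste(targ$region_id, targ$week, targ$disease)
  if (anyDuplicated(key))
    .parseError(fTarg, which(duplicated(key))[1] + 1L,
                "duplicate (region, week, disease) row")
  unknown <- !targ$disease %in% ds
  if (any(unknown))
    .parseError(fTarg, which(unknown)[1] + 1L,
                paste("disease not in meta.yaml:", targ$disease[which(unknown)[1]]))
  grid <- unique(targ[, c("region_id", "week")])
  grid <- grid[order(grid$region_id, grid$week), , drop = FALSE]
  rownames(grid) <- NULL
  ti <- match(paste(targ$region_id, targ$week), paste(grid$region_id, grid$week))
  di <- match(targ$disease, ds)
  inc <- matrix(NA_integer_, nrow(grid), length(ds))
  inc[cbind(ti, di)] <- as.integer(targ$incidences)
  if (anyNA(inc))
    stop(fTarg, ": some (region, week) tuples lack counts for every disease",
         call. = FALSE)
  pop <- rep(NA_integer_, nrow(grid))
  pop[ti] <- as.integer(targ$population)
  popChk <- tapply(targ$population, ti, function(v) length(unique(v)))
  if (any(popChk > 1))
    stop(fTarg, ": conflicting populations within one (region, week)",
         call. = FALSE)

  .checkHeader(fFeat, "region_id,week,column_id,value")
  feat <- read.csv(fFeat, stringsAsFactors = FALSE)
  if (nrow(feat)) {
    fkey <- paste(feat$region_id, feat$week, feat$column_id)
    if (anyDuplicated(fkey))
      .parseError(fFeat, which(duplicated(fkey))[1] + 1L,
                  "duplicate (region, week, column) measurement cell")
  }
  vals <- aggregateMeasurements(feat, schema, grid)

  SurveillanceExperiment(schema, vals, grid$region_id, grid$week, pop, inc,
                         ds, week0Date = if (is.null(meta$week0_date))
                           NA_character_ else meta$week0_date)
}
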