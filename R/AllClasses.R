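#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Paired water/fat Dixon volumes
#'
#' Container for the two contrasts of a two-point Dixon acquisition on a
#' common voxel grid. Water and fat grids must agree in shape and share one
#' voxel spacing (mm per axis).
#'
#' @slot water 3-D numeric array, water contrast
#' @slot fat 3-D numeric array, fat contrast
#' @slot spacing numeric(3), voxel spacing in mm
#' @export
setClass("DixonVolumes",
  representation(water = "array", fat = "array", spacing = "numeric"))

setValidity("DixonVolumes", function(object) {
  msg <- character()
  if (length(dim(object@water)) != 3L || length(dim(object@fat)) != 3L)
    msg <- c(msg, "water and fat must be 3-D arrays")
  else if (!identical(dim(object@water), dim(object@fat)))
    msg <- c(msg, "water and fat grids must share their shape")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (!all(is.finite(object@water)) || !all(is.finite(object@fat)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct paired Dixon volumes
#' @param water,fat 3-D numeric arrays of equal shape
#' @param spacing voxel spacing in mm (length 3)
#' @return a \linkS4class{DixonVolumes} object
#' @export
DixonVolumes <- function(water, fat, spacing = c(1, 1, 1)) {
  new("DixonVolumes", water = water, fat = fat, spacing = as.numeric(spacing))
}

#' Integer label volume with a muscle/side label map
#'
#' @slot labels 3-D integer array; 0 is background
#' @slot labelMap data.frame with columns `label`, `muscle`, `side`
#' @slot spacing numeric(3), voxel spacing in mm
#' @export
setClass("LabelVolume",
  representation(labels = "array", labelMap = "data.frame",
                 spacing = "numeric"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3-D array")
  if (!all(c("label", "muscle", "side") %in% names(object@labelMap)))
    msg <- c(msg, "labelMap needs columns label, muscle, side")
  used <- setdiff(unique(as.integer(object@labels)), 0L)
  if (length(used) && !all(used %in% object@labelMap$label))
    msg <- c(msg, "every nonzero voxel label must appear in labelMap")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct a label volume
#' @param labels 3-D integer array (0 = background)
#' @param labelMap data.frame with columns `label`, `muscle`, `side`
#' @param spacing voxel spacing in mm (length 3)
#' @return a \linkS4class{LabelVolume}
#' @export
LabelVolume <- function(labels, labelMap, spacing = c(1, 1, 1)) {
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels, labelMap = labelMap,
      spacing = as.numeric(spacing))
}

#' Subject-by-feature radiomic table
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one assay
#' (`"features"`, features in rows, subjects in columns). `rowData` carries
#' the parsed feature key (muscle, side, contrast, variant, class, name);
#' `colData` the subject metadata (sex, age, height, weight, bmi and any
#' fat-fraction targets).
#'
#' @export
setClass("MuscleFeatureTable", contains = "SummarizedExperiment")

setValidity("MuscleFeatureTable", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate feature keys are not allowed")
  if (length(msg)) msg else TRUE
})

#' Construct a feature table
#'
#' @param values numeric matrix, subjects in rows, features in columns; column
#'   names are instance keys `<muscle>|<side>|<contrast>|<canonical>`
#' @param meta data.frame of subject metadata, one row per subject
#' @return a \linkS4class{MuscleFeatureTable}
#' @export
MuscleFeatureTable <- function(values, meta) {
  stopifnot(nrow(values) == nrow(meta))
  keys <- parseInstanceKey(colnames(values))
  parts <- strsplit(keys$canonical, "_", fixed = TRUE)
  keys$variant <- vapply(parts, `[`, "", 1L)
  keys$fclass <- vapply(parts, function(x) x[[length(x) - 1L]], "")
  keys$fname <- vapply(parts, function(x) x[[length(x)]], "")
  rd <- S4Vectors::DataFrame(keys)
  rownames(rd) <- colnames(values)
  cd <- S4Vectors::DataFrame(meta)
  if ("subject_id" %in% names(meta)) rownames(cd) <- meta$subject_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(values)), rowData = rd, colData = cd)
  new("MuscleFeatureTable", se)
}

#' Cross-validation fold assignment
#'
#' @slot k number of folds
#' @slot assignment named integer vector, subject id -> fold index in 1..k
#' @export
setClass("FoldSplit", representation(k = "integer", assignment = "integer"))

setValidity("FoldSplit", function(object) {
  msg <- character()
  if (object@k < 2L) msg <- c(msg, "k must be at least 2")
  if (is.null(names(object@assignment)))
    msg <- c(msg, "assignment must be named by subject id")
  tab <- tabulate(object@assignment, nbins = object@k)
  if (any(tab == 0L)) msg <- c(msg, "every fold must be non-empty")
  if (max(tab) - min(tab) > 1L)
    msg <- c(msg, "fold sizes may differ by at most 1")
  if (length(msg)) msg else TRUE
})

#' Record of the feature-selection cascade
#'
#' Stores the surviving feature sets after every cascade step: the global
#' cluster-representative set (step I) and, per fold and per target, the
#' survivors of the reproducibility filter (II), VIF pruning (III) and
#' shadow-feature selection (IV).
#'
#' @slot representatives character, step-I representative canonical names
#' @slot steps nested list: steps[[fold]][[step]] (character vectors); step IV
#'   entries are themselves lists per target
#' @slot counts data.frame summary of per-step survivor counts
#' @slot config list, the selection configuration used
#' @export
setClass("SelectionTrace",
  representation(representatives = "character", steps = "list",
                 counts = "data.frame", config = "list"))

#' Aggregated permutation-importance ranks
#'
#' @slot aggregate data.frame: feature, per-fold aggregate rank (in \[0,1\]),
#'   mean, median, q1, q3
#' @slot raw list of per-(fold, target, repeat) normalized ranks
#' @slot sizes data.frame of selected-set sizes per fold and target
#' @slot nRepeats integer
#' @slot targets character
#' @export
setClass("RankTable",
  representation(aggregate = "data.frame", raw = "list", sizes = "data.frame",
                 nRepeats = "integer", targets = "character"))

#' Classifier validation report
#'
#' @slot results data.frame: scope, contrast, target, split (train/validation,
#'   full/top-k), AUC mean/sd, accuracy mean/sd, chance accuracy
#' @export
setClass("EvalReport", representation(results = "data.frame"))

setMethod("show", "DixonVolumes", function(object) {
  d <- dim(object@water)
  cat(sprintf("DixonVolumes %dx%dx%d, spacing %s mm\n", d[1], d[2], d[3],
              paste(object@spacing, collapse = "x")))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  n <- sum(object@labels != 0L)
  cat(sprintf("LabelVolume %dx%dx%d, %d labelled voxels, %d labels\n",
              d[1], d[2], d[3], n, nrow(object@labelMap)))
})

setMethod("show", "FoldSplit", function(object) {
  cat(sprintf("FoldSplit: %d subjects in %d folds (sizes %s)\n",
              length(object@assignment), object@k,
              paste(tabulate(object@assignment, object@k), collapse = ", ")))
})

setMethod("show", "SelectionTrace", function(object) {
  cat(sprintf("SelectionTrace: %d representatives, %d folds\n",
              length(object@representatives), length(object@steps)))
  print(object@counts)
})

setMethod("show", "RankTable", function(object) {
  cat(sprintf("RankTable: %d features, %d targets, %d repeats\n",
              nrow(object@aggregate), length(object@targets),
              object@nRepeats))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  print(utils::head(object@results, 12))
})
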