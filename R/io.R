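#' Write volumes to NIfTI
#'
#' @param x \linkS4class{DixonVolumes} or \linkS4class{LabelVolume}
#' @param path for DixonVolumes a length-2 character (water, fat paths);
#'   otherwise one path. `.nii.gz` is used as-is.
#' @return invisibly, the paths written
#' @export
writeVolumes <- function(x, path) {
  asNii <- function(a, sp) {
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- sp
    img
  }
  if (is(x, "DixonVolumes")) {
    stopifnot(length(path) == 2)
    RNifti::writeNifti(asNii(waterVolume(x), voxelSpacing(x)), path[1])
    RNifti::writeNifti(asNii(fatVolume(x), voxelSpacing(x)), path[2])
  } else if (is(x, "LabelVolume")) {
    RNifti::writeNifti(asNii(labelArray(x), voxelSpacing(x)), path[1])
  } else stopf("unsupported class")
  invisible(path)
}

#' Read a Dixon volume pair from NIfTI
#' @param waterPath,fatPath NIfTI file paths
#' @return \linkS4class{DixonVolumes}
#' @export
readDixonVolumes <- function(waterPath, fatPath) {
  w <- RNifti::readNifti(waterPath)
  f <- RNifti::readNifti(fatPath)
  DixonVolumes(array(as.numeric(w), dim(w)), array(as.numeric(f), dim(f)),
               RNifti::pixdim(w))
}

#' Read a label volume from NIfTI
#' @param path NIfTI file path
#' @param labelMap data.frame with columns label, muscle, side
#' @return \linkS4class{LabelVolume}
#' @export
readLabelVolume <- function(path, labelMap) {
  img <- RNifti::readNifti(path)
  a <- array(as.integer(img), dim(img))
  LabelVolume(a, labelMap, RNifti::pixdim(img))
}

#' Write a feature table to TSV
#'
#' Subjects in rows; first column `subject_id`, then the metadata columns,
#' then one column per feature instance key.
#'
#' @param table \linkS4class{MuscleFeatureTable}
#' @param path output TSV path
#' @return invisibly, the path
#' @export
writeFeatureTable <- function(table, path) {
  meta <- subjectMeta(table)
  vals <- featureValues(table)
  df <- cbind(meta, as.data.frame(vals, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from TSV
#' @param path TSV written by [writeFeatureTable()]
#' @return \linkS4class{MuscleFeatureTable}
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  featCols <- grepl("|", names(df), fixed = TRUE)
  MuscleFeatureTable(as.matrix(df[, featCols, drop = FALSE]),
                     df[, !featCols, drop = FALSE])
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
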