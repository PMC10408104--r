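#' @useDynLib myotexture, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a deterministic sub-seed from a master seed and a tag
#'
#' Every stochastic stage of the pipeline consumes a seed derived from the
#' single run seed and a stage tag, so that stages are individually
#' reproducible and mutually decoupled.
#'
#' @param seed master integer seed
#' @param tag character tag naming the consumer
#' @return an integer seed in \[1, 2^31 - 2\]
#' @export
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483622 + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Canonical feature identifier
#'
#' Builds the canonical `<variant>_<class>_<name>` string used throughout,
#' e.g. `original_gldm_largedependencehighgraylevelemphasis`.
#'
#' @param variant image variant (`original`, `log-sigma-1-0`, `wavelet-lhl`, ...)
#' @param fclass feature class (`shape`, `firstorder`, `glcm`, ...)
#' @param fname lowercase feature name
#' @return character vector of canonical identifiers
#' @export
canonicalKey <- function(variant, fclass, fname) {
  paste(variant, fclass, fname, sep = "_")
}

#' Column identifier for a feature instance
#'
#' Builds the `<muscle>|<side>|<contrast>|<canonical>` column name used by
#' feature tables.
#'
#' @param muscle,side,contrast instance tags
#' @param canonical canonical feature identifier (see [canonicalKey()])
#' @return character vector of instance keys
#' @export
instanceKey <- function(muscle, side, contrast, canonical) {
  paste(muscle, side, contrast, canonical, sep = "|")
}

parseInstanceKey <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(
    muscle = vapply(parts, `[`, "", 1L),
    side = vapply(parts, `[`, "", 2L),
    contrast = vapply(parts, `[`, "", 3L),
    canonical = vapply(parts, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

# Variant priority for cluster representative choice: original first, then
# LoG variants, then wavelet sub-bands.
variantPriority <- function(canonical) {
  p <- rep(3L, length(canonical))
  p[startsWith(canonical, "original_")] <- 1L
  p[startsWith(canonical, "log-sigma")] <- 2L
  p
}

subcategoryOf <- function(canonical) {
  vapply(strsplit(canonical, "_", fixed = TRUE),
         function(x) x[[length(x) - 1L]], "")
}
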