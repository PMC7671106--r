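#' Functional jaw characters from linear cranial measurements
#'
#' Converts per-specimen linear measurements of the jaw and cranium into
#' seven dimensionless functional characters:
#' \describe{
#'   \item{antMA}{anterior closing mechanical advantage, in-lever / anterior
#'     out-lever (`InLr / AtOL`); force-speed trade-off of the jaw lever.}
#'   \item{postMA}{posterior closing mechanical advantage
#'     (`InLr / PoOL`).}
#'   \item{occlusalOffset}{offset of the tooth-row tangent from the jaw
#'     joint, normalized (`ArOS / PoOL` by default): scissor-like vs precise
#'     occlusion.}
#'   \item{toothAR}{tooth aspect ratio, height / width of a representative
#'     tooth: squat vs cuspidate teeth.}
#'   \item{symphHeight}{mandibular symphysis height relative to dentary
#'     length (`MaSH / DnLn`): jaw robustness.}
#'   \item{relHeadLen}{head length relative to standard length
#'     (`HdLn / SL`).}
#'   \item{protrusionRatio}{ascending-process length relative to premaxilla
#'     length (`AsPr / PMLn`): a proxy for jaw protrusion.}
#' }
#' Being ratios, all characters are invariant to uniform scaling of a
#' specimen.
#'
#' @param m Data frame with one row per specimen and columns `species`,
#'   `SL`, `AsPr`, `PMLn`, `HdLn`, `DnLn`, `AtOL`, `PoOL`, `ArOS`, `InLr`,
#'   `MaSH`, `tooth_height`, `tooth_width`.
#' @param occlusal_denominator `"PoOL"` (default) or `"DnLn"`.
#' @param symphysis_denominator `"DnLn"` (default) or another measurement
#'   column.
#' @param by_species Average specimen rows per species (default `TRUE`).
#' @return Data frame of the seven characters with species as row names.
#' @export
functional_characters <- function(m, occlusal_denominator = c("PoOL", "DnLn"),
                                  symphysis_denominator = "DnLn",
                                  by_species = TRUE) {
  occlusal_denominator <- match.arg(occlusal_denominator)
  need <- c("species", "SL", "AsPr", "PMLn", "HdLn", "DnLn", "AtOL", "PoOL",
            "ArOS", "InLr", "MaSH", "tooth_height", "tooth_width")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop_validation(paste("missing columns:", paste(miss, collapse = ", ")))
  pos <- setdiff(need, c("species", "ArOS"))
  for (col in pos) if (any(m[[col]] <= 0))
    stop_validation(paste("non-positive measurement in", col))
  if (any(m$ArOS < 0)) stop_validation("negative ArOS")
  chars <- data.frame(
    antMA = m$InLr / m$AtOL,
    postMA = m$InLr / m$PoOL,
    occlusalOffset = m$ArOS / m[[occlusal_denominator]],
    toothAR = m$tooth_height / m$tooth_width,
    symphHeight = m$MaSH / m[[symphysis_denominator]],
    relHeadLen = m$HdLn / m$SL,
    protrusionRatio = m$AsPr / m$PMLn)
  if (!all(is.finite(as.matrix(chars))))
    stop_validation("non-finite character value (zero denominator?)")
  if (by_species) {
    chars <- stats::aggregate(chars, list(species = m$species), mean)
    rownames(chars) <- chars$species
    chars$species <- NULL
  } else rownames(chars) <- make.unique(as.character(m$species))
  chars
}

#' Column-wise z-transformation
#'
#' Standardizes each column to mean 0 and unit variance, with the sample
#' (n - 1) standard deviation. Idempotent up to numerical noise.
#'
#' @param x Numeric matrix or data frame with at least two rows.
#' @return Matrix of standardized values.
#' @export
z_transform <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_validation("need at least 2 rows to standardize")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds <= 0)) {
    stop_validation(paste("zero-variance column:",
                          paste(colnames(x)[sds <= 0], collapse = ", ")))
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Normal quantile-quantile diagnostics
#'
#' Returns theoretical-vs-sample quantile pairs per column for normality
#' assessment by eye; no decision rule is applied. Constant columns are
#' flagged degenerate rather than plotted.
#'
#' @param x Numeric matrix or data frame (>= 3 rows).
#' @return Named list, one element per column, each a list with `theoretical`,
#'   `sample` and `degenerate`.
#' @export
qq_diagnostics <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop_validation("need at least 3 values")
  lapply(stats::setNames(seq_len(ncol(x)), colnames(x)), function(j) {
    v <- sort(x[, j])
    n <- length(v)
    if (stats::sd(v) == 0) {
      return(list(theoretical = numeric(0), sample = numeric(0),
                  degenerate = TRUE))
    }
    list(theoretical = stats::qnorm(stats::ppoints(n)), sample = v,
         degenerate = FALSE)
  })
}
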