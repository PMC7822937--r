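#' Optical porosity of a binary cortical mask
#'
#' Areal void fraction of a thresholded cortical-bone micrograph: the
#' percentage of pixels flagged as not occupied by bone tissue (vascular
#' canals plus any osteocyte lacunae captured by the threshold).
#'
#' @param mask A logical or 0/1 matrix with void pixels `TRUE`/1, or a
#'   numeric greyscale matrix in `[0, 1]` when `threshold` is given.
#' @param threshold Optional. `"otsu"` applies an Otsu threshold to a
#'   greyscale input (bright = void); a numeric value thresholds at that
#'   level. Binary input needs no threshold.
#'
#' @return Porosity in percent of the analysed region.
#' @export
#' @examples
#' m <- matrix(0, 10, 10); m[1:2, ] <- 1
#' porosity(m)
porosity <- function(mask, threshold = NULL) {
  if (length(mask) == 0) abort("Empty mask.", class = "rib_extract_error")
  if (!is.null(threshold)) {
    thr <- if (identical(threshold, "otsu")) otsu_threshold(mask) else threshold
    mask <- mask >= thr
  }
  v <- as.numeric(mask)
  if (any(is.na(v))) abort("Mask contains NA pixels.", class = "rib_extract_error")
  if (!all(v %in% c(0, 1))) {
    abort("Mask is not binary; supply `threshold` for greyscale input.",
          class = "rib_extract_error")
  }
  100 * sum(v) / length(v)
}

# Otsu's threshold on a [0, 1] greyscale matrix: maximise between-class
# variance over a 256-bin histogram.
otsu_threshold <- function(img, n_bins = 256) {
  x <- as.numeric(img)
  h <- tabulate(pmin(pmax(floor(x * n_bins) + 1, 1), n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) / n_bins
}

#' Specimen-level optical porosity
#'
#' Averages the quadrant porosities (two pleural, two cutaneous sampling
#' locations) into one specimen value.
#'
#' @param quadrant_pct Numeric vector of per-quadrant porosities in percent.
#' @param require_four Error (`TRUE`, default) or warn when fewer than four
#'   quadrants are supplied (thin cortices are sometimes measured manually
#'   on fewer fields).
#'
#' @return Mean porosity in percent.
#' @export
specimen_porosity <- function(quadrant_pct, require_four = TRUE) {
  if (length(quadrant_pct) < 4) {
    msg <- sprintf("Only %d quadrant value(s) supplied (4 expected).",
                   length(quadrant_pct))
    if (require_four) abort(msg, class = "rib_extract_error") else warn(msg)
  }
  mean(quadrant_pct)
}
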