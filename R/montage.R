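#' Standard 60-channel 10-10 montage
#'
#' Approximate 2-D head coordinates for a 60-electrode subset of the extended
#' 10-20 (10-10) system, used by the synthetic generator to build smooth
#' component topographies.  Coordinates live on a unit disc: x runs left (-)
#' to right (+), y runs posterior (-) to anterior (+).
#'
#' @return A data.frame with columns `label`, `x`, `y` (60 rows).
#' @examples
#' m <- aerp_montage()
#' m[m$label %in% c("Fz", "Cz", "Pz"), ]
#' @export
aerp_montage <- function() {
  rows <- list(
    # prefix, y, labels left-to-right
    list("Fp", 0.90, c("Fp1", "Fp2"), c(-0.25, 0.25)),
    list("AF", 0.70, c("AF7", "AF3", "AFz", "AF4", "AF8"),
         c(-0.60, -0.30, 0, 0.30, 0.60)),
    list("F", 0.50, c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
         c(-0.80, -0.60, -0.40, -0.20, 0, 0.20, 0.40, 0.60, 0.80)),
    list("FC", 0.25, c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4",
                       "FC6", "FT8"),
         c(-0.90, -0.65, -0.43, -0.21, 0, 0.21, 0.43, 0.65, 0.90)),
    list("C", 0.00, c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
         c(-1.00, -0.75, -0.50, -0.25, 0, 0.25, 0.50, 0.75, 1.00)),
    list("CP", -0.25, c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4",
                        "CP6", "TP8"),
         c(-0.90, -0.65, -0.43, -0.21, 0, 0.21, 0.43, 0.65, 0.90)),
    list("P", -0.50, c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
         c(-0.80, -0.60, -0.40, -0.20, 0, 0.20, 0.40, 0.60, 0.80)),
    list("PO", -0.70, c("PO7", "PO3", "POz", "PO4", "PO8"),
         c(-0.60, -0.30, 0, 0.30, 0.60)),
    list("O", -0.90, c("O1", "Oz", "O2"), c(-0.25, 0, 0.25))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(label = r[[3]], x = r[[4]], y = r[[2]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Smooth Gaussian scalp topography
#'
#' Per-channel weights falling off with distance from a focus electrode,
#' `exp(-d^2 / (2 * sigma^2))`, clipped to `[-1, 1]`.  Used as the spatial
#' projection of a simulated ERP component (e.g. P300 focused at Pz, P200 at
#' Fz).
#'
#' @param center Focus electrode label (must exist in `montage`).
#' @param sigma Spatial spread on the unit-disc scale (default 0.6).
#' @param montage Montage data.frame, see [aerp_montage()].
#' @return Named numeric vector of weights in `[0, 1]`, one per channel.
#' @examples
#' w <- topography_gaussian("Pz")
#' w["Pz"]   # 1
#' w["Fz"] < w["CPz"]
#' @export
topography_gaussian <- function(center, sigma = 0.6, montage = aerp_montage()) {
  i <- match(center, montage$label)
  if (is.na(i)) {
    stop("channel '", center, "' not found in montage", call. = FALSE)
  }
  d2 <- (montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2
  w <- exp(-d2 / (2 * sigma^2))
  names(w) <- montage$label
  w
}
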