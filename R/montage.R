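#' Electrode montage
#'
#' 64 scalp electrodes at standard extended 10/20 positions with schematic
#' 2-D coordinates (x: left negative / right positive, y: posterior negative
#' / anterior positive, head radius ~1), plus two mastoid reference channels
#' (M1, M2) and one EMG channel on the superior orbicularis muscle.
#'
#' @name montage
NULL

row_y <- c(Fp = 0.85, AF = 0.65, F = 0.45, FT = 0.25, FC = 0.25,
           C = 0.00, TP = -0.25, CP = -0.25, T = 0.00, P = -0.45,
           PO = -0.65, O = -0.85, I = -1.00)
lat_x <- c("1" = 0.14, "2" = 0.14, "3" = 0.34, "4" = 0.34,
           "5" = 0.54, "6" = 0.54, "7" = 0.78, "8" = 0.78,
           "9" = 0.95, "10" = 0.95)

electrode_xy <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z]+)(z|[0-9]+)$", name))[[1]]
  if (length(m) == 0) stop("cannot parse electrode name: ", name)
  prefix <- m[2]; suffix <- m[3]
  y <- unname(row_y[prefix])
  if (is.na(y)) stop("unknown electrode row: ", prefix)
  if (suffix == "z") return(c(0, y))
  num <- as.integer(suffix)
  x <- unname(lat_x[as.character(num)]) * if (num %% 2 == 1) -1 else 1
  c(x, y)
}

#' Standard 64-channel montage with mastoids and EMG
#'
#' @param scalp optional character vector of scalp electrode names; default
#'   is the standard 64-site layout.
#' @return data.frame with columns `name`, `x`, `y`, `type`
#'   (`scalp`/`mastoid`/`emg`).
#' @examples
#' mont <- default_montage()
#' nrow(mont)  # 64 scalp + 2 mastoids + 1 EMG
#' @export
default_montage <- function(scalp = NULL) {
  if (is.null(scalp)) {
    scalp <- c(
      "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
      "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
      "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
      "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
      "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
      "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
      "P10", "PO8", "PO4", "O2"
    )
  }
  if (anyDuplicated(scalp)) stop("duplicate electrode names in montage")
  xy <- t(vapply(scalp, electrode_xy, numeric(2)))
  rbind(
    data.frame(name = scalp, x = xy[, 1], y = xy[, 2], type = "scalp"),
    data.frame(name = c("M1", "M2"), x = c(-1.05, 1.05), y = c(-0.35, -0.35),
               type = "mastoid"),
    data.frame(name = "EMG", x = 0, y = 1.2, type = "emg")
  )
}

#' Region-of-interest electrode sets
#'
#' The six analysis regions: fronto-central, centro-parietal and
#' parieto-occipital, each split left/right, three electrodes each. The
#' fronto-central six-electrode union is used for the time-course analysis.
#'
#' @return named list of character vectors, plus attribute `gradient` /
#'   `side` lookups via [roi_region_info].
#' @export
default_roi <- function() {
  list(
    FC_L = c("F1", "F3", "FC1"),
    FC_R = c("F2", "F4", "FC2"),
    CP_L = c("C1", "C3", "CP1"),
    CP_R = c("C2", "C4", "CP2"),
    PO_L = c("PO3", "PO7", "O1"),
    PO_R = c("PO4", "PO8", "O2")
  )
}

#' Gradient and side of a region name
#' @param region region names like "FC_L".
#' @return data.frame with `region`, `gradient` (FC/CP/PO), `side` (L/R).
#' @export
roi_region_info <- function(region) {
  parts <- strsplit(region, "_", fixed = TRUE)
  data.frame(region = region,
             gradient = vapply(parts, `[`, "", 1),
             side = vapply(parts, `[`, "", 2))
}

#' Reduced montage containing only ROI electrodes
#'
#' Convenience montage (ROI electrodes + Fpz blink reference + mastoids +
#' EMG) for fast simulations.
#'
#' @param roi ROI list as from [default_roi].
#' @return montage data.frame.
#' @export
roi_montage <- function(roi = default_roi()) {
  default_montage(scalp = unique(c(unlist(roi), "Fpz")))
}
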