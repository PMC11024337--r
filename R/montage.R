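# Channel montages: labels + 3-D positions (mm, head frame: +x right,
# +y anterior, +z up) on an idealized spherical head, plus file loading.

#' Built-in 62-channel 10-10 template montage
#'
#' Idealized spherical-head positions (radius 85 mm) for a 62-channel
#' extended 10-20 ("10-10") layout, the standard stand-in when digitized
#' electrode positions are unavailable. Electrodes are laid out on an
#' anterior-posterior x lateral grid at 18 degree steps from the vertex;
#' grid square-rings map to spherical rings, which reproduces the familiar
#' circumferential outer ring (Fp1, F7, T7, P7, O1, ...).
#'
#' @param radius_mm head radius in mm (default 85).
#' @return a `montage` object: data.frame with columns label, x, y, z.
#' @export
standard_montage_62 <- function(radius_mm = 85) {
  # Each row: anterior-posterior grid index (+4 = Fp row, -5 = Iz),
  # labels left-to-right, and lateral grid indices (negative = left).
  # Grid step = 18 degrees of arc; square-ring index = max(|ap|, |lat|).
  rows <- list(
    list(ap = 4, lab = c("Fp1", "Fpz", "Fp2"), lat = c(-1, 0, 1)),
    list(ap = 3, lab = c("AF7", "AF3", "AFz", "AF4", "AF8"),
      lat = c(-4, -1.5, 0, 1.5, 4)),
    list(ap = 2, lab = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
      lat = -4:4),
    list(ap = 1,
      lab = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
      lat = -4:4),
    list(ap = 0, lab = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
      lat = -4:4),
    list(ap = -1,
      lab = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
      lat = -4:4),
    list(ap = -2,
      lab = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
      lat = -4:4),
    list(ap = -3, lab = c("PO7", "PO3", "POz", "PO4", "PO8"),
      lat = c(-4, -1.5, 0, 1.5, 4)),
    list(ap = -4, lab = c("O1", "Oz", "O2"), lat = c(-1, 0, 1)),
    list(ap = -5, lab = "Iz", lat = 0)
  )
  lab <- unlist(lapply(rows, `[[`, "lab"))
  ap <- unlist(lapply(rows, function(r) rep(r$ap, length(r$lab))))
  lat <- unlist(lapply(rows, `[[`, "lat"))
  k <- pmax(abs(ap), abs(lat)) # square-ring index; 18 deg per ring
  theta <- pmin(k * 18, 90) * pi / 180 # polar angle from vertex
  phi <- atan2(lat, ap) # azimuth: 0 = anterior, +pi/2 = right
  m <- data.frame(
    label = lab,
    x = radius_mm * sin(theta) * sin(phi),
    y = radius_mm * sin(theta) * cos(phi),
    z = radius_mm * cos(theta),
    stringsAsFactors = FALSE
  )
  as_montage(m)
}

as_montage <- function(df) {
  stopifnot(all(c("label", "x", "y", "z") %in% names(df)))
  if (anyDuplicated(df$label)) {
    stop("montage_duplicate_label: duplicate channel labels: ",
      paste(unique(df$label[duplicated(df$label)]), collapse = ", "))
  }
  if (!all(is.finite(as.matrix(df[c("x", "y", "z")])))) {
    stop("montage positions must be finite")
  }
  rownames(df) <- NULL
  class(df) <- c("montage", "data.frame")
  df
}

#' Load a channel montage
#'
#' Either the built-in 62-channel 10-10 template (`"standard-62"`) or an
#' `.sfp`-style whitespace-delimited text file with one `label x y z` row
#' per channel (coordinates in mm).
#'
#' @param name_or_path `"standard-62"` or a file path.
#' @return a `montage` object.
#' @export
load_montage <- function(name_or_path = "standard-62") {
  if (identical(name_or_path, "standard-62")) {
    return(standard_montage_62())
  }
  if (!file.exists(name_or_path)) {
    stop("montage file not found: ", name_or_path)
  }
  df <- utils::read.table(name_or_path,
    header = FALSE, stringsAsFactors = FALSE,
    col.names = c("label", "x", "y", "z")
  )
  if (nrow(df) < 2) stop("montage must have >= 2 channels")
  as_montage(df)
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels, e.g. %s\n", nrow(x),
    paste(utils::head(x$label, 6), collapse = " ")))
  invisible(x)
}
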