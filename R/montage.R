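# Idealized spherical electrode coordinates for the BioSemi 64-channel
# 10-10 montage. Positions are constructed geometrically on a unit sphere:
# inclination is measured from the vertex (Cz) in 18-degree steps (10% of
# the 180-degree nasion-inion arc), azimuth from the anterior midline
# (positive towards the right ear). Electrodes between the midline and the
# outer 10% ring are placed by spherical (great-circle) interpolation.
# These are schematic 10-10 positions, not digitized head shapes; they are
# used for nearest-neighbour channel interpolation and for the abstract
# topography gains of the simulator, both of which only need plausible
# relative geometry.

.sph2cart <- function(incl_deg, azim_deg) {
  th <- incl_deg * pi / 180
  ph <- azim_deg * pi / 180
  c(x = sin(th) * sin(ph), y = sin(th) * cos(ph), z = cos(th))
}

# great-circle interpolation between two unit vectors
.slerp <- function(a, b, f) {
  om <- acos(max(-1, min(1, sum(a * b))))
  if (om < 1e-12) return(a)
  (sin((1 - f) * om) * a + sin(f * om) * b) / sin(om)
}

.build_biosemi64 <- function() {
  pos <- list()
  add <- function(label, incl, azim) pos[[label]] <<- .sph2cart(incl, azim)

  # outer 10% ring (inclination 72), azimuth steps of 18 degrees
  ring <- c(Fpz = 0, Fp2 = 18, AF8 = 36, F8 = 54, FT8 = 72, T8 = 90,
            TP8 = 108, P8 = 126, PO8 = 144, O2 = 162, Oz = 180,
            O1 = -162, PO7 = -144, P7 = -126, TP7 = -108, T7 = -90,
            FT7 = -72, F7 = -54, AF7 = -36, Fp1 = -18)
  for (lb in names(ring)) add(lb, 72, ring[[lb]])

  # ring 10% below the outer ring
  add("P9", 90, -126); add("P10", 90, 126); add("Iz", 90, 180)

  # midline
  add("AFz", 54, 0); add("Fz", 36, 0); add("FCz", 18, 0); add("Cz", 0, 0)
  add("CPz", 18, 180); add("Pz", 36, 180); add("POz", 54, 180)

  # central coronal arc
  add("C1", 18, -90); add("C3", 36, -90); add("C5", 54, -90)
  add("C2", 18, 90);  add("C4", 36, 90);  add("C6", 54, 90)

  # intermediate rows: great-circle interpolation midline -> outer ring
  rows <- list(
    list(mid = "AFz", out = "AF7", labels = c("AF3"),            f = 0.5),
    list(mid = "Fz",  out = "F7",  labels = c("F1", "F3", "F5"), f = c(.25, .5, .75)),
    list(mid = "FCz", out = "FT7", labels = c("FC1", "FC3", "FC5"), f = c(.25, .5, .75)),
    list(mid = "CPz", out = "TP7", labels = c("CP1", "CP3", "CP5"), f = c(.25, .5, .75)),
    list(mid = "Pz",  out = "P7",  labels = c("P1", "P3", "P5"), f = c(.25, .5, .75)),
    list(mid = "POz", out = "PO7", labels = c("PO3"),            f = 0.5)
  )
  for (rw in rows) {
    for (i in seq_along(rw$labels)) {
      v <- .slerp(pos[[rw$mid]], pos[[rw$out]], rw$f[i])
      pos[[rw$labels[i]]] <- v
      # right-hemisphere mirror: odd digit -> even digit label
      rlab <- chartr("13579", "24680", rw$labels[i])
      pos[[rlab]] <- v * c(-1, 1, 1)
    }
  }

  # canonical BioSemi A1..A32, B1..B32 ordering
  order64 <- c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5",
               "FC3", "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3",
               "CP1", "P1", "P3", "P5", "P7", "P9", "PO7", "PO3", "O1",
               "Iz", "Oz", "POz", "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4",
               "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6", "FC4",
               "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6",
               "CP4", "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4",
               "O2")
  m <- t(vapply(pos[order64], identity, numeric(3)))
  data.frame(label = order64, x = m[, 1], y = m[, 2], z = m[, 3],
             stringsAsFactors = FALSE)
}

.biosemi64_cache <- new.env(parent = emptyenv())

#' BioSemi 64-channel montage coordinates
#'
#' Returns idealized unit-sphere coordinates for the 64-electrode BioSemi
#' 10-10 montage (labels `Fp1` ... `O2`, BioSemi A/B ordering). The y axis
#' points to the nasion, x to the right preauricular point, z to the vertex.
#'
#' @param labels Optional character vector restricting (and ordering) the
#'   returned electrodes, e.g. a 16-channel test subset. The zero-digit
#'   spelling sometimes seen in print for the parieto-occipital pair
#'   (`P07`/`P08`) is normalized to `PO7`/`PO8`.
#' @return A data.frame with columns `label`, `x`, `y`, `z`.
#' @examples
#' head(biosemi64_montage())
#' biosemi64_montage(c("Oz", "PO8"))
#' @export
biosemi64_montage <- function(labels = NULL) {
  if (is.null(.biosemi64_cache$m)) .biosemi64_cache$m <- .build_biosemi64()
  m <- .biosemi64_cache$m
  if (is.null(labels)) return(m)
  # normalize the zero-digit dialect sometimes seen in print (P07 -> PO7)
  labels <- sub("^P0([78])$", "PO\\1", labels)
  miss <- setdiff(labels, m$label)
  if (length(miss))
    stop("unknown electrode label(s): ", paste(miss, collapse = ", "))
  m[match(labels, m$label), , drop = FALSE]
}

#' Nearest neighbours of an electrode
#'
#' Finds the `k` spatially nearest electrodes (Euclidean distance on the
#' unit-sphere montage) among `candidates`. Distance ties are broken by
#' alphabetical label order.
#'
#' @param label Electrode whose neighbours are sought.
#' @param candidates Labels eligible as neighbours (defaults to all montage
#'   electrodes except `label`).
#' @param k Number of neighbours.
#' @return Character vector of `k` labels, nearest first.
#' @export
nearest_electrodes <- function(label, candidates = NULL, k = 3) {
  m <- biosemi64_montage()
  if (is.null(candidates)) candidates <- setdiff(m$label, label)
  candidates <- setdiff(candidates, label)
  p0 <- unlist(biosemi64_montage(label)[1, c("x", "y", "z")])
  pc <- biosemi64_montage(candidates)
  d <- sqrt((pc$x - p0[1])^2 + (pc$y - p0[2])^2 + (pc$z - p0[3])^2)
  ord <- order(d, pc$label)
  candidates[ord[seq_len(min(k, length(candidates)))]]
}

# default 16-channel subset used for desk-scale simulations: all ROI
# electrodes plus midline/frontal coverage
.default_channels16 <- c("Fp1", "Fp2", "Fz", "Cz", "Pz", "POz",
                         "P7", "P9", "PO7", "O1", "Oz", "Iz", "O2",
                         "PO8", "P10", "P8")
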