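#' Standard 32-channel 10-20 montage
#'
#' Returns the 32-channel extended 10-20 montage used throughout the package,
#' with approximate 2-D head coordinates (azimuthal projection, head radius 1,
#' x toward the right ear, y toward the nasion). The coordinates drive the
#' inverse-distance interpolation of rejected channels; only relative
#' distances matter.
#'
#' @param labels optional character vector restricting (and ordering) the
#'   returned montage to a subset of labels.
#' @return data.frame with columns `label`, `x`, `y`.
#' @export
montage_1020 <- function(labels = NULL) {
  m <- .montage32
  if (!is.null(labels)) {
    idx <- match(labels, m$label)
    if (anyNA(idx)) {
      stop("unknown channel label(s): ",
           paste(labels[is.na(idx)], collapse = ", "))
    }
    m <- m[idx, , drop = FALSE]
    rownames(m) <- NULL
  }
  m
}

.montage32 <- data.frame(
  label = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
            "FC5", "FC1", "FC2", "FC6",
            "T7", "C3", "Cz", "C4", "T8",
            "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
            "P7", "P3", "Pz", "P4", "P8",
            "PO9", "O1", "Oz", "O2", "PO10"),
  x = c(-0.28, 0.28, -0.73, -0.37, 0.00, 0.37, 0.73,
        -0.60, -0.21, 0.21, 0.60,
        -0.90, -0.45, 0.00, 0.45, 0.90,
        -0.98, -0.60, -0.21, 0.21, 0.60, 0.98,
        -0.73, -0.37, 0.00, 0.37, 0.73,
        -0.55, -0.28, 0.00, 0.28, 0.55),
  y = c(0.86, 0.86, 0.53, 0.45, 0.45, 0.45, 0.53,
        0.23, 0.23, 0.23, 0.23,
        0.00, 0.00, 0.00, 0.00, 0.00,
        -0.33, -0.23, -0.23, -0.23, -0.23, -0.33,
        -0.53, -0.45, -0.45, -0.45, -0.53,
        -0.78, -0.86, -0.90, -0.86, -0.78),
  stringsAsFactors = FALSE
)

#' Default channel labels for an n-channel montage
#'
#' The first `n` labels of the 32-channel montage, reordered so that the
#' sensorimotor channels C3, Cz and C4 are always present.
#'
#' @param n number of channels (3 to 32).
#' @return character vector of length `n`.
#' @export
default_channel_labels <- function(n = 32) {
  stopifnot(n >= 3, n <= 32)
  core <- c("C3", "Cz", "C4")
  rest <- setdiff(.montage32$label, core)
  labs <- c(core, rest)[seq_len(n)]
  # keep canonical montage order for readability
  .montage32$label[.montage32$label %in% labs]
}

# k nearest montage neighbours of `label` among `candidates` (inverse-distance
# weights). Returns list(labels, weights).
.nearest_neighbours <- function(label, candidates, k = 4) {
  m <- montage_1020()
  p0 <- m[m$label == label, c("x", "y")]
  cand <- m[m$label %in% candidates & m$label != label, , drop = FALSE]
  d <- sqrt((cand$x - p0$x)^2 + (cand$y - p0$y)^2)
  ord <- order(d)[seq_len(min(k, nrow(cand)))]
  w <- 1 / d[ord]
  list(labels = cand$label[ord], weights = w / sum(w))
}
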