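# Band-level biomarkers from dB-corrected ERSP maps:
#   ERO(t): frequency-band average of ERSP, a band-power time course;
#   ERI:    additional time average over an analysis window, one scalar per
#           channel and band (negative = desynchronization);
#   LI:     hemispheric lateralization (ERI_C3 - ERI_C4)/(ERI_C3 + ERI_C4).

#' Frequency band definition
#'
#' Defaults follow the analysis bands: alpha 7-13 Hz, beta 13-30 Hz. The
#' shared 13 Hz edge belongs to both bands.
#'
#' @param name "alpha", "beta" or a custom label.
#' @param f1,f2 band edges in Hz (`f1 < f2`); defaulted for alpha/beta.
#' @return list of class `freq_band`.
#' @export
freq_band <- function(name, f1 = NULL, f2 = NULL) {
  if (is.null(f1) || is.null(f2)) {
    if (name == "alpha") { f1 <- 7; f2 <- 13 }
    else if (name == "beta") { f1 <- 13; f2 <- 30 }
    else stop("custom bands need explicit f1 and f2")
  }
  if (!(f1 < f2)) stop("band edges must satisfy f1 < f2")
  structure(list(name = name, f1 = f1, f2 = f2), class = "freq_band")
}

#' Time window definition
#'
#' @param t1,t2 window edges in ms (`t1 < t2`); default 500-2000 ms, the
#'   interval of maximal group differences during the swallow.
#' @return list of class `time_window`.
#' @export
time_window <- function(t1 = 500, t2 = 2000) {
  if (!(t1 < t2)) stop("time window must satisfy t1 < t2")
  structure(list(t1 = t1, t2 = t2), class = "time_window")
}

# trapezoidal mean of y over x (uniform or not); assumes length >= 2
.trapz_mean <- function(x, y) {
  n <- length(x)
  if (n < 2) return(y[1])
  sum(diff(x) * (y[-1] + y[-n]) / 2) / (x[n] - x[1])
}

#' Event-related oscillation: band-averaged ERSP time course
#'
#' `ERO(t) = (1/(f2-f1)) * integral of ERSP(t, f) df` over the band,
#' trapezoidal rule over unmasked bins. Times where no bin in the band is
#' valid yield `NA`.
#'
#' @param map a `db_corrected` [tfr_map()].
#' @param band a [freq_band()].
#' @return list of class `band_trace`: `values` (dB), `time_ms`, `band`,
#'   `channel`.
#' @export
compute_ero <- function(map, band) {
  stopifnot(inherits(map, "tfr_map"), map$stage == "db_corrected",
            inherits(band, "freq_band"))
  sel <- which(map$freqs >= band$f1 - 1e-9 & map$freqs <= band$f2 + 1e-9)
  if (length(sel) == 0)
    stop("band [", band$f1, ", ", band$f2, "] contains no grid bins")
  vals <- vapply(seq_along(map$time_ms), function(ti) {
    ok <- sel[map$valid[ti, sel]]
    if (length(ok) == 0) return(NA_real_)
    if (length(ok) == 1) return(map$values[ti, ok])
    .trapz_mean(map$freqs[ok], map$values[ti, ok])
  }, numeric(1))
  structure(list(values = vals, time_ms = map$time_ms, band = band,
                 channel = map$channel), class = "band_trace")
}

#' Event-related index: band- and window-averaged ERSP scalar
#'
#' Double (time x frequency) trapezoidal average of the dB-corrected ERSP
#' over the band and window; computed as the time average of the ERO trace,
#' which on the discrete grid coincides with the double integral. Negative
#' values indicate desynchronization.
#'
#' @param map a `db_corrected` [tfr_map()].
#' @param band a [freq_band()].
#' @param window a [time_window()].
#' @return ERI scalar in dB.
#' @export
compute_eri <- function(map, band, window = time_window()) {
  stopifnot(inherits(window, "time_window"))
  ero <- compute_ero(map, band)
  ti <- which(ero$time_ms >= window$t1 - 1e-9 &
                ero$time_ms <= window$t2 + 1e-9 & !is.na(ero$values))
  if (length(ti) == 0)
    stop("no valid cells in the window [", window$t1, ", ", window$t2, "] ms")
  if (length(ti) == 1) return(ero$values[ti])
  .trapz_mean(ero$time_ms[ti], ero$values[ti])
}

#' Hemispheric lateralization index
#'
#' `LI = (ERI_C3 - ERI_C4) / (ERI_C3 + ERI_C4)`; C3 is the left and C4 the
#' right hemisphere, and LI = 0 indicates bilateral dominance. When the
#' denominator magnitude falls below `epsilon` the index is unbounded: the
#' value is reported as `NA` with `denominator_flag = TRUE` (flagged, not an
#' error).
#'
#' @param eri_c3,eri_c4 ERI values in dB (finite).
#' @param epsilon degeneracy guard on `|ERI_C3 + ERI_C4|` (dB).
#' @return list with `li` and `denominator_flag`.
#' @export
compute_li <- function(eri_c3, eri_c4, epsilon = 1e-3) {
  if (!is.finite(eri_c3) || !is.finite(eri_c4))
    stop("ERI inputs must be finite")
  den <- eri_c3 + eri_c4
  if (abs(den) < epsilon)
    return(list(li = NA_real_, denominator_flag = TRUE))
  list(li = (eri_c3 - eri_c4) / den, denominator_flag = FALSE)
}

#' Assemble the biomarker table for a cohort
#'
#' @param ersp_by_subject named list (subject id -> named list of
#'   `db_corrected` [tfr_map()]s per channel, as from [subject_ersp()]).
#' @param groups named character vector mapping subject id to group label.
#' @param bands list of [freq_band()]s (default alpha and beta).
#' @param window a [time_window()].
#' @param epsilon LI degeneracy guard.
#' @return list with `eri` (one row per subject x channel x band) and `li`
#'   (one row per subject x band; `li` is `NA` where flagged or where C3/C4
#'   is missing).
#' @export
build_biomarker_table <- function(ersp_by_subject, groups,
                                  bands = list(freq_band("alpha"),
                                               freq_band("beta")),
                                  window = time_window(), epsilon = 1e-3) {
  eri_rows <- list()
  li_rows <- list()
  for (sid in names(ersp_by_subject)) {
    maps <- ersp_by_subject[[sid]]
    chans <- intersect(c("C3", "Cz", "C4"), names(maps))
    if (length(chans) == 0) {
      warning("subject ", sid, " has no sensorimotor channel maps; excluded")
      next
    }
    grp <- unname(groups[sid])
    for (b in bands) {
      eri <- list()
      for (ch in chans) {
        val <- compute_eri(maps[[ch]], b, window)
        eri[[ch]] <- val
        eri_rows[[length(eri_rows) + 1]] <- data.frame(
          subject_id = sid, group = grp, channel = ch, band = b$name,
          eri_db = val, stringsAsFactors = FALSE)
      }
      if (all(c("C3", "C4") %in% chans)) {
        li <- compute_li(eri$C3, eri$C4, epsilon)
        li_rows[[length(li_rows) + 1]] <- data.frame(
          subject_id = sid, group = grp, band = b$name, li = li$li,
          denominator_flag = li$denominator_flag, stringsAsFactors = FALSE)
      }
    }
  }
  list(eri = do.call(rbind, eri_rows), li = do.call(rbind, li_rows))
}
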