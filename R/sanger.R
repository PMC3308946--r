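# Sanger chromatogram peak-height editing-frequency estimator.  At an
# editing site the gross editing frequency is the G-peak height divided by
# the summed A- and G-peak heights; the reported (calibrated) frequency
# multiplies the gross value by a site-specific factor.

#' Site calibration factors for the peak-height estimator
#'
#' @param factors named numeric vector over sites `A, B, E, C, D`; the
#'   defaults apply the empirical factors 1.114 (site A) and 1.009 (site B)
#'   and leave the remaining sites uncalibrated (1.0).
#' @return object of class `sanger_calibration`.
#' @export
sanger_calibration <- function(factors = c(A = 1.114, B = 1.009,
                                           E = 1, C = 1, D = 1)) {
  stopifnot(identical(sort(names(factors)), sort(EDIT_SITES)),
            all(factors > 0))
  structure(list(factors = factors[EDIT_SITES]), class = "sanger_calibration")
}

#' Gross editing frequency from peak heights
#'
#' `X = G height / (A height + G height)`.  Scale-invariant: multiplying
#' both heights by the same positive constant leaves X unchanged.
#'
#' @param a_height,g_height non-negative peak heights (vectorised).
#' @return gross editing frequencies in `[0, 1]`.
#' @export
#' @examples
#' gross_frequency(70, 30)   # 0.3
gross_frequency <- function(a_height, g_height) {
  if (any(a_height < 0) || any(g_height < 0)) {
    stop("peak heights must be non-negative", call. = FALSE)
  }
  if (any(a_height + g_height <= 0)) {
    stop("no A/G signal: both peak heights are zero", call. = FALSE)
  }
  g_height / (a_height + g_height)
}

#' Calibrated editing frequency
#'
#' Multiplies the gross frequency by the site's calibration factor and
#' clamps the result to `[0, 1]` (a frequency cannot exceed 1 even when the
#' factor pushes the raw product above it).
#'
#' @param site site letter in `A, B, E, C, D`.
#' @param gross gross frequency in `[0, 1]` (vectorised).
#' @param cal a [sanger_calibration()].
#' @return calibrated frequencies in `[0, 1]`.
#' @export
#' @examples
#' calibrated_frequency("A", 0.5)   # 0.557
calibrated_frequency <- function(site, gross, cal = sanger_calibration()) {
  if (!site %in% EDIT_SITES) stop("unknown site: ", site, call. = FALSE)
  stopifnot(all(gross >= 0), all(gross <= 1))
  pmin(1, pmax(0, cal$factors[[site]] * gross))
}

# Reverse-complement a trace: reverse position order, swap A<->T and C<->G
# channels, and complement the called bases.
.revcomp_trace <- function(trace) {
  out <- trace[rev(seq_len(nrow(trace))), , drop = FALSE]
  out <- data.frame(position = seq_len(nrow(out)),
                    A = out$T, C = out$G, G = out$C, T = out$A,
                    call = chartr("ACGT", "TGCA", out$call),
                    stringsAsFactors = FALSE)
  chromatogram_trace(out)
}

#' Per-site editing profile of a chromatogram trace
#'
#' Locates the cassette within the trace by aligning its called-base
#' sequence to the reference (both orientations are tried and the better
#' alignment score wins; a reverse-complement trace is flipped, swapping
#' the A/T and C/G channels) and computes the gross and calibrated editing
#' frequency at each site from the A- and G-channel heights at the aligned
#' position.
#'
#' @param trace a [chromatogram_trace()].
#' @param ref a [cassette_reference()].
#' @param cal a [sanger_calibration()].
#' @param p an [alignment_params()].
#' @return data frame with one row per site: `site`, `a_height`,
#'   `g_height`, `gross`, `calibrated`, `missing` (TRUE when the site is
#'   not covered by the trace).
#' @export
trace_editing_profile <- function(trace, ref = default_reference(),
                                  cal = sanger_calibration(),
                                  p = alignment_params()) {
  stopifnot(inherits(trace, "chromatogram_trace") || is.data.frame(trace))
  fwd_seq <- paste(trace$call, collapse = "")
  rc_trace <- .revcomp_trace(trace)
  rc_seq <- paste(rc_trace$call, collapse = "")
  al_f <- align_to_reference(fwd_seq, ref, p)
  al_r <- align_to_reference(rc_seq, ref, p)
  if (al_r$score > al_f$score) {
    trace <- rc_trace
    al <- al_r
  } else {
    al <- al_f
  }
  out <- data.frame(site = EDIT_SITES, a_height = NA_real_, g_height = NA_real_,
                    gross = NA_real_, calibrated = NA_real_, missing = TRUE,
                    stringsAsFactors = FALSE)
  for (k in seq_along(EDIT_SITES)) {
    pos <- al$map[ref$site_offsets[[EDIT_SITES[k]]]]
    if (is.na(pos) || pos > nrow(trace)) next
    a <- trace$A[pos]
    g <- trace$G[pos]
    if (a + g <= 0) next
    out$a_height[k] <- a
    out$g_height[k] <- g
    out$gross[k] <- gross_frequency(a, g)
    out$calibrated[k] <- calibrated_frequency(EDIT_SITES[k], out$gross[k], cal)
    out$missing[k] <- FALSE
  }
  out
}
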