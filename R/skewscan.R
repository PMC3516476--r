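# Windowed, length-weighted and cumulative GC skew, and the extrema-based
# replication origin/terminus call.
#
# Raw skew per window is (G - C) / (G + C).  The weighted variant multiplies
# by w/c, the ratio of window length to total molecule length, so that the
# contribution of each window is normalized to the whole molecule.  For
# circular molecules the ori/ter call uses the *detrended* cumulative curve
# (running sum minus its linear drift): on a circle the plain running sum
# depends on the arbitrary rotation of the deposited sequence, while the
# detrended curve is rotation-equivariant up to an additive constant, which
# makes the argmin/argmax well defined regardless of where the record starts.

#' Windowed GC skew profile
#'
#' @param x A [replicon()].
#' @param window_bp Window length w in bp.
#' @param step_bp Step between window starts (<= `window_bp`).
#' @param weighted Also report the w/c-weighted skew.
#' @return A data frame of class `skew_profile` with one row per window:
#'   `start`, `center`, `raw` ((G-C)/(G+C), 0 for windows without G or C),
#'   `weighted` (raw * w/c), `cumulative` (running sum of raw),
#'   `detrended` (cumulative minus linear drift) and `degenerate`
#'   (window had G+C = 0).
#' @export
window_skew <- function(x, window_bp = 500L, step_bp = 100L, weighted = TRUE) {
  stopifnot(inherits(x, "replicon"))
  L <- x$length
  window_bp <- as.integer(window_bp); step_bp <- as.integer(step_bp)
  if (L == 0L) stop("empty replicon")
  if (step_bp < 1L || step_bp > window_bp)
    stop("need 0 < step_bp <= window_bp")
  if (window_bp > L && !x$circular)
    stop("window_bp exceeds the length of a linear molecule")
  if (window_bp > L) stop("window_bp exceeds molecule length")

  if (x$circular) {
    starts <- seq(1L, L, by = step_bp)
    ch <- s2c(paste0(x$sequence, substr(x$sequence, 1L, window_bp - 1L)))
  } else {
    starts <- seq(1L, L - window_bp + 1L, by = step_bp)
    ch <- s2c(x$sequence)
  }
  cg <- cumsum(ch == "G")
  cc <- cumsum(ch == "C")
  ends <- starts + window_bp - 1L
  ng <- cg[ends] - c(0L, cg)[starts]
  nc <- cc[ends] - c(0L, cc)[starts]
  tot <- ng + nc
  degenerate <- tot == 0L
  raw <- ifelse(degenerate, 0, (ng - nc) / ifelse(degenerate, 1L, tot))
  cum <- cumsum(raw)
  n <- length(raw)
  detr <- cum - seq_len(n) * (cum[n] / n)
  centers <- if (x$circular)
    wrap_pos(starts + (window_bp - 1L) %/% 2L, L)
  else starts + (window_bp - 1L) %/% 2L
  out <- data.frame(start = starts, center = centers, raw = raw,
                    weighted = raw * (window_bp / L), cumulative = cum,
                    detrended = detr, degenerate = degenerate)
  attr(out, "window_bp") <- window_bp
  attr(out, "step_bp") <- step_bp
  attr(out, "length_bp") <- L
  attr(out, "circular") <- x$circular
  attr(out, "weighted_on") <- weighted
  class(out) <- c("skew_profile", class(out))
  out
}

#' Predict replication origin and terminus from a skew profile
#'
#' By convention the origin sits at the minimum of the cumulative GC-skew
#' curve and the terminus at its maximum; since the strand orientation of a
#' deposited plasmid sequence is arbitrary, `convention = "max_ori"` flips
#' the assignment.  On circular profiles the detrended cumulative curve is
#' used (see [window_skew()]); ties break toward the smallest coordinate.
#'
#' @param profile A `skew_profile` from [window_skew()].
#' @param convention `"min_ori"` (default) or `"max_ori"`.
#' @return A list of class `ori_ter_call`: `ori_position`, `ter_position`
#'   (window centers, `NA` for a no-call), `ori_value`, `ter_value`,
#'   `confidence` (max - min amplitude of the curve) and `no_call`.
#' @export
predict_ori_ter <- function(profile, convention = c("min_ori", "max_ori")) {
  stopifnot(inherits(profile, "skew_profile"))
  convention <- match.arg(convention)
  if (nrow(profile) < 3L) stop("profile needs at least 3 windows")
  if (all(profile$degenerate)) {
    out <- list(ori_position = NA_integer_, ter_position = NA_integer_,
                ori_value = NA_real_, ter_value = NA_real_,
                confidence = 0, no_call = TRUE)
    class(out) <- "ori_ter_call"
    return(out)
  }
  curve <- if (isTRUE(attr(profile, "circular"))) profile$detrended
  else profile$cumulative
  i_min <- which.min(curve)   # which.min/max take the first index on ties,
  i_max <- which.max(curve)   # and rows are ordered by coordinate
  if (convention == "max_ori") { tmp <- i_min; i_min <- i_max; i_max <- tmp }
  out <- list(ori_position = profile$center[i_min],
              ter_position = profile$center[i_max],
              ori_value = curve[i_min], ter_value = curve[i_max],
              confidence = max(curve) - min(curve), no_call = FALSE)
  class(out) <- "ori_ter_call"
  out
}

#' @export
print.ori_ter_call <- function(x, ...) {
  if (x$no_call) {
    cat("<ori/ter call> no call (degenerate profile)\n")
  } else {
    cat(sprintf("<ori/ter call> ori @ %d (%.4f), ter @ %d (%.4f), confidence %.4f\n",
                x$ori_position, x$ori_value, x$ter_position, x$ter_value,
                x$confidence))
  }
  invisible(x)
}

#' Plot a skew profile
#'
#' Draws the raw windowed skew and the cumulative (detrended, for circular
#' molecules) curve, with the ori/ter call marked when supplied.
#'
#' @param x A `skew_profile`.
#' @param call Optional `ori_ter_call` to mark.
#' @param ... Passed to [plot()].
#' @export
plot.skew_profile <- function(x, call = NULL, ...) {
  curve <- if (isTRUE(attr(x, "circular"))) x$detrended else x$cumulative
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$center, x$raw, type = "l", xlab = "position (bp)",
       ylab = "(G-C)/(G+C)", ...)
  graphics::abline(h = 0, lty = 3)
  plot(x$center, curve, type = "l", xlab = "position (bp)",
       ylab = "cumulative skew", ...)
  if (!is.null(call) && !call$no_call) {
    graphics::abline(v = call$ori_position, col = 2, lty = 2)
    graphics::abline(v = call$ter_position, col = 4, lty = 2)
  }
  invisible(x)
}
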