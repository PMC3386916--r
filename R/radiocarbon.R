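#' Load a radiocarbon calibration curve
#'
#' Reads a calibration curve in the standard `.14c` column layout: calendar
#' age (cal BP), conventional radiocarbon age of the curve (14C BP) and its
#' 1-sigma error, either comma- or whitespace-delimited, with `#` comment
#' lines.  Knots are sorted to ascending calendar age; duplicate calendar
#' knots are an error.  No curve is bundled with the package — the
#' southern-hemisphere curve (or any other) is a user-supplied file.
#'
#' @param path path to the curve file.
#' @return an object of class `calibration_curve` with fields `cal_bp`,
#'   `c14_bp`, `error`.
#' @export
load_curve <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[,[:space:]]+")
  bad <- lengths(fields) < 3
  if (any(bad)) stop("curve line(s) with fewer than 3 columns: line ",
                     which(bad)[1])
  m <- do.call(rbind, lapply(fields, function(f) as.numeric(f[1:3])))
  calibration_curve(m[, 1], m[, 2], m[, 3])
}

#' @rdname load_curve
#' @param cal_bp calendar ages (cal BP).
#' @param c14_bp curve radiocarbon ages (14C BP).
#' @param error curve 1-sigma errors (>= 0).
#' @export
calibration_curve <- function(cal_bp, c14_bp, error) {
  o <- order(cal_bp)
  cal_bp <- cal_bp[o]; c14_bp <- c14_bp[o]; error <- error[o]
  if (anyDuplicated(cal_bp)) stop("duplicate calendar knots in curve")
  if (any(error < 0)) stop("curve errors must be non-negative")
  structure(list(cal_bp = cal_bp, c14_bp = c14_bp, error = error),
            class = "calibration_curve")
}

#' @rdname load_curve
#' @param curve a `calibration_curve`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cal BP, 14C BP, error", con)
  writeLines(sprintf("%g,%g,%g", curve$cal_bp, curve$c14_bp, curve$error),
             con)
  invisible(path)
}

#' Identity calibration curve
#'
#' A synthetic straight-line curve with `mu(theta) = theta` and zero curve
#' error, useful as an analytic surrogate: calibrating `cra +/- sigma`
#' against it returns a plain Gaussian in calendar years.
#'
#' @param from,to calendar range (cal BP).
#' @param by knot spacing in years.
#' @param error curve error (default 0).
#' @return a `calibration_curve`.
#' @export
identity_curve <- function(from = 0, to = 10000, by = 10, error = 0) {
  g <- seq(from, to, by = by)
  calibration_curve(g, g, rep(error, length(g)))
}

# curve mean / error at arbitrary calendar ages (linear interpolation)
curve_at <- function(curve, theta) {
  list(mu = approx(curve$cal_bp, curve$c14_bp, theta, rule = 2)$y,
       sig = approx(curve$cal_bp, curve$error, theta, rule = 2)$y)
}

#' Calibrate a conventional radiocarbon age
#'
#' Computes the posterior density of the calendar age on a 1-year grid:
#' `p(theta) proportional to exp(-(cra - mu(theta))^2 /
#' (2 * (sigma^2 + sigma_curve(theta)^2)))`, normalised to total mass 1,
#' where `mu` and `sigma_curve` are the calibration curve interpolated
#' linearly between knots.  The evaluation grid covers every calendar age
#' whose curve value lies within 6 combined sigma of the measurement
#' (extended a further 6 sigma on each side), so multimodal posteriors on
#' wiggly curves are retained.  The 95.4% highest-density region is found
#' by accumulating years in decreasing density order until the mass
#' reaches 0.954, then merging the selected years into maximal contiguous
#' intervals.
#'
#' @param cra conventional radiocarbon age, yr BP; must lie within the
#'   curve's 14C range.
#' @param sigma measurement 1-sigma error (> 0).
#' @param curve a [calibration_curve()].
#' @param level probability mass for the highest-density region
#'   (default 0.954).
#' @return an object of class `calibrated_date` with fields `cra`, `sigma`,
#'   `cal_bp` (grid), `density` (sums to 1), `ranges` (data.frame
#'   `older`, `younger`, integer cal BP, older bound first), `mode`,
#'   `median`, `level`.
#' @export
calibrate <- function(cra, sigma, curve, level = 0.954) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (sigma <= 0) stop("sigma must be positive")
  rng <- range(curve$c14_bp)
  if (cra < rng[1] || cra > rng[2])
    stop("CRA ", cra, " outside curve 14C range [", rng[1], ", ", rng[2], "]")
  s_max <- sqrt(sigma^2 + max(curve$error)^2)
  near <- abs(curve$c14_bp - cra) <= 6 * s_max
  if (!any(near)) stop("CRA ", cra, " not reachable on this curve")
  lo <- max(min(curve$cal_bp), floor(min(curve$cal_bp[near]) - 6 * s_max))
  hi <- min(max(curve$cal_bp), ceiling(max(curve$cal_bp[near]) + 6 * s_max))
  grid <- seq(lo, hi, by = 1)
  cv <- curve_at(curve, grid)
  v <- sigma^2 + cv$sig^2
  dens <- exp(-(cra - cv$mu)^2 / (2 * v))
  tot <- sum(dens)
  if (tot == 0) stop("zero posterior mass; curve does not support CRA ", cra)
  dens <- dens / tot

  o <- order(dens, decreasing = TRUE)
  csum <- cumsum(dens[o])
  k <- which(csum >= level)[1]
  sel <- sort(grid[o[seq_len(k)]])
  breaks <- which(diff(sel) > 1)
  starts <- c(1, breaks + 1)
  ends <- c(breaks, length(sel))
  ranges <- data.frame(older = rev(sel[ends]), younger = rev(sel[starts]))

  structure(list(cra = cra, sigma = sigma,
                 cal_bp = grid, density = dens,
                 ranges = ranges,
                 mode = grid[which.max(dens)],
                 median = grid[which(cumsum(dens) >= 0.5)[1]],
                 level = level),
            class = "calibrated_date")
}

#' @export
print.calibrated_date <- function(x, ...) {
  cat("<calibrated_date> ", x$cra, " +/- ", x$sigma, " 14C BP -> ",
      format_cal_ranges(x), " cal BP (", 100 * x$level, "%)\n", sep = "")
  invisible(x)
}

#' Format highest-density ranges in publication style
#'
#' Renders the 95.4% ranges as `"older-younger"` (cal BP, older bound
#' first), multiple ranges separated by `"; "`.
#'
#' @param x a [calibrate()] result.
#' @return character scalar.
#' @export
format_cal_ranges <- function(x) {
  paste(sprintf("%d-%d", x$ranges$older, x$ranges$younger), collapse = "; ")
}

#' Do two calibrated dates overlap?
#'
#' TRUE when any highest-density interval of one date intersects any
#' interval of the other (closed intervals).  Both dates should be
#' calibrated against the same curve for the comparison to be meaningful.
#'
#' @param a,b [calibrate()] results.
#' @return logical.
#' @export
ranges_overlap <- function(a, b) {
  for (i in seq_len(nrow(a$ranges)))
    for (j in seq_len(nrow(b$ranges)))
      if (a$ranges$younger[i] <= b$ranges$older[j] &&
          b$ranges$younger[j] <= a$ranges$older[i])
        return(TRUE)
  FALSE
}

#' Calibrate a table of measurements
#'
#' @param dates data.frame with columns `sample` (or `coprolite`), `cra`,
#'   `error`.
#' @param curve a [calibration_curve()].
#' @return named list of `calibrated_date`, keyed by sample id.
#' @export
calibrate_table <- function(dates, curve) {
  id_col <- intersect(c("sample", "coprolite", "lab_code"), names(dates))[1]
  if (is.na(id_col)) stop("dates table needs a 'sample' or 'coprolite' column")
  out <- lapply(seq_len(nrow(dates)), function(i)
    calibrate(dates$cra[i], dates$error[i], curve))
  names(out) <- dates[[id_col]]
  out
}
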