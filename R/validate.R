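# Trajectory-level validation: internal-coordinate distributions,
# Gaussian summary fits, classical-vs-reference comparison, and
# equilibration / beta-sheet stability metrics.

#' Angle definitions
#'
#' @param label short name of the coordinate.
#' @param kind `"bond_angle"` (3 atoms), `"dihedral"` or `"improper"`
#'   (4 atoms; for impropers the third atom is the center).
#' @param atoms character vector of atom names.
#' @return an `angle_definition`.
#' @export
angle_definition <- function(label, kind, atoms) {
  kind <- match.arg(kind, c("bond_angle", "dihedral", "improper"))
  need <- if (kind == "bond_angle") 3L else 4L
  if (length(atoms) != need) {
    stop(kind, " '", label, "' needs ", need, " atom names, got ",
         length(atoms))
  }
  structure(list(label = label, kind = kind, atoms = atoms),
            class = "angle_definition")
}

#' Read an angle-definition file
#'
#' One definition per line: `label kind atom1 atom2 atom3 [atom4]`.
#'
#' @param x path or text.
#' @return list of [angle_definition()]s.
#' @export
read_angle_definitions <- function(x) {
  lines <- .as_lines(x)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")
  lapply(seq_along(toks), function(i) {
    t <- toks[[i]]
    if (length(t) < 5L) stop("angle-definition line ", i, " too short")
    angle_definition(t[1L], t[2L], t[-(1:2)])
  })
}

# wrap an angle series so a unimodal distribution is not split at +/-180:
# recenter every value onto the branch around the series' circular mean.
.recenter_circular <- function(x) {
  rad <- x * pi / 180
  mu <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  x + 360 * round((mu - x) / 360)
}

#' Per-frame internal-coordinate series
#'
#' Evaluates an [angle_definition()] in every frame of a structure.
#' Dihedral (and improper) series are reported on a branch recentered
#' at the series' circular mean, so values differ from the raw
#' (-180, 180] convention only by multiples of 360 degrees.
#'
#' @param structure a multi-frame [xfp_structure].
#' @param definition an [angle_definition()].
#' @return numeric vector, one value (degrees) per frame.
#' @export
angle_series <- function(structure, definition) {
  idx <- atom_index(structure, definition$atoms)
  nf <- n_frames(structure)
  fun <- switch(definition$kind,
                bond_angle = function(f) bond_angle(structure, idx[1L], idx[2L],
                                                    idx[3L], frame = f),
                dihedral = function(f) dihedral_angle(structure, idx[1L], idx[2L],
                                                      idx[3L], idx[4L], frame = f),
                improper = function(f) improper_angle(structure, idx[1L], idx[2L],
                                                      idx[3L], idx[4L], frame = f))
  out <- vapply(seq_len(nf), fun, 0)
  if (definition$kind != "bond_angle") out <- .recenter_circular(out)
  out
}

#' Gaussian summary of an angle distribution
#'
#' Histograms the series at the given bin width and fits
#' `amplitude * exp(-(x - center)^2 / (2 sigma^2))` to the bin counts
#' by nonlinear least squares, initialized at the sample mean and SD.
#' If the optimizer fails, the sample mean/SD are reported with
#' `converged = FALSE`.  Default bin widths in published comparisons:
#' 2 degrees for bond angles, 5 for intra-ring dihedrals, 15 for the
#' wide ring-planarity dihedral.
#'
#' @param series numeric vector (degrees), at least 100 values with
#'   spread exceeding the bin width.
#' @param bin_width histogram bin width (degrees).
#' @return a `gaussian_fit`: `center`, `sigma`, `amplitude`,
#'   `bin_width`, `n_samples`, `converged`.
#' @export
fit_gaussian <- function(series, bin_width = 2) {
  n <- length(series)
  if (n < 100L) stop("need at least 100 samples (got ", n, ")")
  spread <- diff(range(series))
  if (spread <= bin_width) {
    stop("degenerate series: spread (", format(spread),
         ") does not exceed the bin width (", bin_width, ")")
  }
  breaks <- seq(bin_width * floor(min(series) / bin_width),
                bin_width * ceiling(max(series) / bin_width),
                by = bin_width)
  h <- graphics::hist(series, breaks = breaks, plot = FALSE)
  xs <- h$mids
  ys <- h$counts
  m <- mean(series)
  s <- sd(series)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ys ~ A * exp(-(xs - c0)^2 / (2 * s0^2)),
      start = list(A = max(ys), c0 = m, s0 = s),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    res <- list(center = m, sigma = s, amplitude = max(ys),
                bin_width = bin_width, n_samples = n, converged = FALSE)
  } else {
    cf <- coef(fit)
    res <- list(center = unname(cf["c0"]), sigma = abs(unname(cf["s0"])),
                amplitude = unname(cf["A"]), bin_width = bin_width,
                n_samples = n, converged = TRUE)
  }
  structure(res, class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> center %.2f deg, sigma %.2f deg (bin %g, n=%d, %s)\n",
              x$center, x$sigma, x$bin_width, x$n_samples,
              if (x$converged) "converged" else "fallback"))
  invisible(x)
}

#' Compare two Gaussian distribution summaries
#'
#' @param classical,reference converged [fit_gaussian()] results
#'   (classical MD vs the reference, e.g. QM/MM).
#' @return a `distribution_comparison`: `delta_center`
#'   (classical - reference, degrees), `delta_center_in_sigma`
#'   (|delta| / reference sigma), `width_ratio`
#'   (classical sigma / reference sigma).
#' @export
#' @examples
#' a <- structure(list(center = 100, sigma = 4, amplitude = 1,
#'                     bin_width = 2, n_samples = 1000, converged = TRUE),
#'                class = "gaussian_fit")
#' b <- structure(list(center = 104, sigma = 8, amplitude = 1,
#'                     bin_width = 2, n_samples = 1000, converged = TRUE),
#'                class = "gaussian_fit")
#' compare_fits(a, b)$delta_center_in_sigma  # 0.5
compare_fits <- function(classical, reference) {
  if (!isTRUE(classical$converged) || !isTRUE(reference$converged)) {
    stop("compare_fits needs converged Gaussian fits on both sides")
  }
  dc <- classical$center - reference$center
  structure(
    list(delta_center = dc,
         delta_center_in_sigma = abs(dc) / reference$sigma,
         width_ratio = classical$sigma / reference$sigma),
    class = "distribution_comparison"
  )
}

#' Equilibration stability ratio
#'
#' Over the trailing `window` frames, compares the standard deviation of
#' the raw values to the slope of an ordinary least-squares line fit to
#' the same span.  The time axis is scaled so the window spans one time
#' unit, making the slope the total drift across the window; the
#' reported ratio `sd / |slope|` is therefore invariant under affine
#' rescaling of the series values.  A converged metric drifts by much
#' less than it fluctuates (ratios above ~50 were required of the RMSD
#' in the published equilibration protocol).
#'
#' @param series numeric vector (one value per frame).
#' @param window number of trailing frames (>= 3).
#' @param metric label recorded in the report.
#' @return a `stability_report`: `metric`, `window`, `sd`, `slope`
#'   (per window-time-unit), `sd_over_slope_ratio` (`Inf` flagged when
#'   the slope is 0).
#' @export
equilibration_ratio <- function(series, window = length(series),
                                metric = "series") {
  n <- length(series)
  if (window < 3L) stop("window must cover at least 3 points")
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")")
  y <- series[(n - window + 1L):n]
  x <- seq(0, 1, length.out = window)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  s <- sd(y)
  structure(
    list(metric = metric, window = window, sd = s, slope = slope,
         sd_over_slope_ratio = if (slope == 0) Inf else s / abs(slope)),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s over %d frames: sd %.4g, slope %.4g, ratio %.4g\n",
              x$metric, x$window, x$sd, x$slope, x$sd_over_slope_ratio))
  invisible(x)
}

#' Beta-sheet residue count slope
#'
#' Ordinary least-squares slope of per-frame beta-sheet residue counts
#' against time, in residues per microsecond, with the standard
#' deviation of the counts over a trailing window reported alongside.
#' The counts come from an external secondary-structure assignment;
#' this package does not assign secondary structure.
#'
#' @param counts nonnegative integer vector, one count per frame.
#' @param frame_interval_us time between frames in microseconds.
#' @param trailing_window frames in the trailing-SD window (default:
#'   all frames).
#' @return list with `slope_res_per_us`, `trailing_sd`, `n_frames`.
#' @export
beta_slope <- function(counts, frame_interval_us,
                       trailing_window = length(counts)) {
  n <- length(counts)
  if (n < 3L) stop("need at least 3 frames (got ", n, ")")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  stopifnot(frame_interval_us > 0, trailing_window >= 2L,
            trailing_window <= n)
  t_us <- (seq_len(n) - 1L) * frame_interval_us
  slope <- sum((t_us - mean(t_us)) * (counts - mean(counts))) /
    sum((t_us - mean(t_us))^2)
  list(
    slope_res_per_us = slope,
    trailing_sd = sd(counts[(n - trailing_window + 1L):n]),
    n_frames = n
  )
}

#' Compare angle distributions between two trajectories
#'
#' Convenience driver: evaluates each angle definition in both
#' trajectories, fits Gaussians, and tabulates the comparison.
#'
#' @param traj,ref_traj multi-frame [xfp_structure]s (classical and
#'   reference trajectories).
#' @param definitions list of [angle_definition()]s.
#' @param bin_widths numeric vector (recycled) of histogram bin widths.
#' @return data frame: label, kind, center/sigma for both trajectories,
#'   delta_center, delta_center_in_sigma, width_ratio.
#' @export
compare_angle_distributions <- function(traj, ref_traj, definitions,
                                        bin_widths = 2) {
  bin_widths <- rep_len(bin_widths, length(definitions))
  rows <- lapply(seq_along(definitions), function(i) {
    d <- definitions[[i]]
    f1 <- fit_gaussian(angle_series(traj, d), bin_widths[i])
    f2 <- fit_gaussian(angle_series(ref_traj, d), bin_widths[i])
    cmp <- compare_fits(f1, f2)
    data.frame(label = d$label, kind = d$kind,
               center = f1$center, sigma = f1$sigma,
               ref_center = f2$center, ref_sigma = f2$sigma,
               delta_center = cmp$delta_center,
               delta_center_in_sigma = cmp$delta_center_in_sigma,
               width_ratio = cmp$width_ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
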