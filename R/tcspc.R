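#' Multiexponential decay model
#'
#' Describes a fluorescence decay as a sum of exponential components
#' `sum_i a_i exp(-t / tau_i)` plus an optional flat background expressed as
#' a fraction of the total signal. Components are stored sorted by ascending
#' lifetime, matching the "short component / long component" language used
#' for biexponential fits.
#'
#' @param lifetimes Component lifetimes in ns (all > 0, distinct).
#' @param amplitudes Non-negative pre-exponential amplitudes, same length as
#'   `lifetimes`; only relative values matter. Default: equal amplitudes.
#' @param background_fraction Fraction of total detected signal that is flat
#'   (uncorrelated) background, in `[0, 1)`. Default 0.
#' @return An object of class `decay_components`.
#' @export
#' @examples
#' # the coupled donor-acceptor disk sample: 0.86/4.39 ns, 35.82% short
#' decay_components(c(0.86, 4.39), c(35.82, 64.18))
decay_components <- function(lifetimes, amplitudes = NULL,
                             background_fraction = 0) {
  if (length(lifetimes) < 1L || any(!is.finite(lifetimes)) ||
      any(lifetimes <= 0))
    stop("`lifetimes` must be positive and finite (ns)", call. = FALSE)
  if (is.null(amplitudes)) amplitudes <- rep(1, length(lifetimes))
  if (length(amplitudes) != length(lifetimes))
    stop("`amplitudes` and `lifetimes` lengths differ", call. = FALSE)
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0))
    stop("`amplitudes` must be non-negative and finite", call. = FALSE)
  if (sum(amplitudes) <= 0 && background_fraction <= 0)
    stop("amplitudes must be normalizable (sum > 0)", call. = FALSE)
  if (!is.finite(background_fraction) || background_fraction < 0 ||
      background_fraction >= 1)
    stop("`background_fraction` must lie in [0, 1)", call. = FALSE)
  ord <- order(lifetimes)
  lifetimes <- lifetimes[ord]; amplitudes <- amplitudes[ord]
  if (length(lifetimes) > 1L && any(diff(lifetimes) < 1e-9))
    stop("duplicate lifetimes (within 1e-9 ns) are not allowed",
         call. = FALSE)
  structure(list(lifetimes = lifetimes, amplitudes = amplitudes,
                 background_fraction = background_fraction),
            class = "decay_components")
}

#' @export
print.decay_components <- function(x, ...) {
  frac <- 100 * x$amplitudes / sum(x$amplitudes)
  cat("Multiexponential decay model:\n")
  for (i in seq_along(x$lifetimes))
    cat(sprintf("  tau = %.4g ns  (%.2f%% amplitude)\n",
                x$lifetimes[i], frac[i]))
  if (x$background_fraction > 0)
    cat(sprintf("  flat background: %.3g%% of signal\n",
                100 * x$background_fraction))
  invisible(x)
}

#' Gaussian instrument response function
#'
#' TCSPC instruments smear the true decay with their temporal response; here
#' the IRF is modelled as a Gaussian of given full width at half maximum
#' (FWHM), the minimal model consistent with quoting a single IRF width
#' (150 ps for the pulsed-diode system emulated by the defaults).
#'
#' @param fwhm_ps Full width at half maximum in picoseconds (default 150).
#' @param t0_ns Temporal offset (peak position) in ns (default 1.6).
#' @return An object of class `instrument_response`.
#' @export
gaussian_irf <- function(fwhm_ps = 150, t0_ns = 1.6) {
  if (!is.finite(fwhm_ps) || fwhm_ps <= 0)
    stop("`fwhm_ps` must be > 0", call. = FALSE)
  if (!is.finite(t0_ns))
    stop("`t0_ns` must be finite", call. = FALSE)
  structure(list(fwhm_ps = fwhm_ps, t0_ns = t0_ns,
                 sigma_ns = fwhm_ps / 1000 / (2 * sqrt(2 * log(2)))),
            class = "instrument_response")
}

#' @export
print.instrument_response <- function(x, ...) {
  cat(sprintf("Gaussian IRF: FWHM %g ps (sigma %.4g ns), peak at %g ns\n",
              x$fwhm_ps, x$sigma_ns, x$t0_ns))
  invisible(x)
}

#' Discretised IRF profile on a uniform time grid
#'
#' Samples the Gaussian IRF at the bin centres of a uniform grid and
#' normalises to unit sum, so that convolution with a decay conserves total
#' intensity.
#'
#' @param irf An [gaussian_irf()] object.
#' @param times Bin-centre times in ns (uniform grid).
#' @param shift_ns Extra temporal shift applied to the peak (used by the
#'   reconvolution fitter; default 0).
#' @return Numeric vector summing to 1.
#' @export
irf_profile <- function(irf, times, shift_ns = 0) {
  stopifnot(inherits(irf, "instrument_response"))
  p <- stats::dnorm(times, mean = irf$t0_ns + shift_ns, sd = irf$sigma_ns)
  s <- sum(p)
  if (s <= 0) stop("IRF profile vanishes on this grid", call. = FALSE)
  p / s
}

time_axis <- function(bin_width, n_bins) (seq_len(n_bins) - 0.5) * bin_width

check_uniform_grid <- function(times) {
  if (length(times) < 2L) stop("time grid too short", call. = FALSE)
  d <- diff(times)
  if (any(abs(d - d[1]) > 1e-9 * d[1]))
    stop("time grid must be uniform", call. = FALSE)
  d[1]
}

# Discrete causal convolution of a per-bin profile with exponential decays
# evaluated at lag times 0, h, 2h, ...; returns a vector on the same grid.
# FFT with zero-padding to a power of two (linear, not circular, convolution).
convolve_decay <- function(profile, lifetimes, amplitudes, bin_width) {
  n <- length(profile)
  lags <- (seq_len(n) - 1L) * bin_width
  d <- numeric(n)
  for (i in seq_along(lifetimes))
    d <- d + amplitudes[i] * exp(-lags / lifetimes[i])
  L <- 2^ceiling(log2(2 * n))
  fp <- stats::fft(c(profile, numeric(L - n)))
  fd <- stats::fft(c(d, numeric(L - n)))
  Re(stats::fft(fp * fd, inverse = TRUE))[seq_len(n)] / L
}

#' Expected TCSPC intensity profile of a decay model
#'
#' Computes the per-bin expected intensity of a multiexponential decay
#' convolved with the instrument response, plus a flat background: the model
#' curve that reconvolution fitting matches against measured counts.
#'
#' @param model A [decay_components()] object.
#' @param irf An [gaussian_irf()] object.
#' @param times Bin-centre times in ns (uniform grid); default the standard
#'   4096-channel, 16 ps grid.
#' @param normalize If `TRUE` (default) the profile sums to 1 and the
#'   background fraction of `model` is interpreted as a fraction of the total;
#'   if `FALSE` the convolution of the raw amplitudes is returned (background
#'   fraction must then be 0).
#' @return Numeric vector of non-negative per-bin intensities.
#' @export
#' @examples
#' m <- decay_components(4.11)
#' p <- model_intensity(m, gaussian_irf())
#' sum(p) # 1
model_intensity <- function(model, irf,
                            times = time_axis(0.016, 4096),
                            normalize = TRUE) {
  stopifnot(inherits(model, "decay_components"),
            inherits(irf, "instrument_response"))
  h <- check_uniform_grid(times)
  prof <- irf_profile(irf, times)
  conv <- convolve_decay(prof, model$lifetimes, model$amplitudes, h)
  conv[conv < 0] <- 0   # clip FFT round-off
  if (!normalize) {
    if (model$background_fraction > 0)
      stop("unnormalized profile does not support a background fraction",
           call. = FALSE)
    return(conv)
  }
  s <- sum(conv)
  bf <- model$background_fraction
  if (s <= 0) {
    if (bf > 0) return(rep(1 / length(times), length(times)))
    stop("decay profile vanishes on this grid", call. = FALSE)
  }
  (1 - bf) * conv / s + bf / length(times)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a TCSPC decay histogram
#'
#' Draws photon counts for each time bin from the expected intensity profile
#' of a decay model. The default noise model is multinomial: the total
#' recorded photon count is fixed (as when acquiring to a target count) and
#' bins share it according to the normalised profile. Independent per-bin
#' Poisson noise with the same expectation is available as an option.
#'
#' @param model A [decay_components()] object (the ground truth).
#' @param irf An [gaussian_irf()] object.
#' @param total_counts Total photons to record (> 0). Under Poisson noise
#'   this is the expected total.
#' @param seed Optional integer; identical seeds give identical histograms.
#' @param bin_width Channel width in ns (default 0.016).
#' @param n_bins Number of channels (default 4096, a ~65 ns window).
#' @param noise `"multinomial"` (default) or `"poisson"`.
#' @return A `decay_histogram`: list with `bin_width`, `n_bins`, integer
#'   `counts` and `total_counts`.
#' @export
#' @examples
#' h <- simulate_histogram(decay_components(4.11), gaussian_irf(),
#'                         total_counts = 1e5, seed = 1)
#' sum(h$counts) == h$total_counts
simulate_histogram <- function(model, irf, total_counts, seed = NULL,
                               bin_width = 0.016, n_bins = 4096,
                               noise = c("multinomial", "poisson")) {
  noise <- match.arg(noise)
  if (!is.finite(total_counts) || total_counts <= 0)
    stop("`total_counts` must be > 0", call. = FALSE)
  times <- time_axis(bin_width, n_bins)
  p <- model_intensity(model, irf, times, normalize = TRUE)
  counts <- with_seed(seed, {
    if (noise == "multinomial")
      as.integer(stats::rmultinom(1, size = total_counts, prob = p))
    else
      as.integer(stats::rpois(n_bins, lambda = total_counts * p))
  })
  decay_histogram(bin_width, counts)
}

#' Construct a decay histogram from counts
#'
#' @param bin_width Channel width in ns.
#' @param counts Non-negative integer counts, one per uniform bin; the time
#'   axis starts at 0 with bin centres at `(k + 1/2) * bin_width`.
#' @return A `decay_histogram` object.
#' @export
decay_histogram <- function(bin_width, counts) {
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("`bin_width` must be > 0", call. = FALSE)
  if (length(counts) < 1L || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("`counts` must be non-negative integers", call. = FALSE)
  structure(list(bin_width = bin_width, n_bins = length(counts),
                 counts = as.integer(counts),
                 total_counts = sum(as.integer(counts))),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf(
    "TCSPC histogram: %d bins x %g ns, %s counts (peak %d at %.3g ns)\n",
    x$n_bins, x$bin_width, format(x$total_counts, big.mark = ","),
    max(x$counts), time_axis(x$bin_width, x$n_bins)[which.max(x$counts)]))
  invisible(x)
}

#' Bin-centre time axis of a histogram
#' @param h A `decay_histogram`.
#' @return Numeric vector of bin-centre times in ns.
#' @export
histogram_times <- function(h) {
  stopifnot(inherits(h, "decay_histogram"))
  time_axis(h$bin_width, h$n_bins)
}

#' Write / read a decay histogram as two-column text
#'
#' The on-disk format is plain delimited text: comment lines
#' `# bin_width_ns=<w>` and `# total_counts=<N>`, then one
#' `time_ns<TAB>counts` row per bin (bin-centre times). `read_histogram()`
#' validates uniform binning, integer non-negative counts and header
#' consistency, reporting the first offending line.
#'
#' @param h A `decay_histogram`.
#' @param path File path.
#' @return `write_histogram()` returns `path` invisibly; `read_histogram()`
#'   returns a `decay_histogram`.
#' @export
write_histogram <- function(h, path) {
  stopifnot(inherits(h, "decay_histogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bin_width_ns=%.17g", h$bin_width),
               sprintf("# total_counts=%d", h$total_counts)), con)
  writeLines(sprintf("%.9g\t%d", histogram_times(h), h$counts), con)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), header, value = TRUE)
    if (length(m) == 0L) return(NA_real_)
    as.numeric(sub(paste0("^#\\s*", key, "="), "", m[1]))
  }
  hdr_bw <- get_field("bin_width_ns")
  hdr_total <- get_field("total_counts")
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(body_idx) < 2L)
    stop("histogram file has fewer than 2 data rows", call. = FALSE)
  parts <- strsplit(trimws(lines[body_idx]), "[\t ,;]+")
  bad_ncol <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad_ncol))
    stop("line ", body_idx[bad_ncol[1]],
         ": expected two columns (time_ns, counts)", call. = FALSE)
  mat <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = 2, byrow = TRUE)
  bad_num <- which(!is.finite(mat[, 1]) | !is.finite(mat[, 2]))
  if (length(bad_num))
    stop("line ", body_idx[bad_num[1]], ": non-numeric value",
         call. = FALSE)
  bad_count <- which(mat[, 2] < 0 | mat[, 2] != round(mat[, 2]))
  if (length(bad_count))
    stop("line ", body_idx[bad_count[1]],
         ": counts must be non-negative integers", call. = FALSE)
  dt <- diff(mat[, 1])
  bw <- if (is.finite(hdr_bw)) hdr_bw else stats::median(dt)
  bad_grid <- which(abs(dt - bw) > 1e-6 * bw)
  if (length(bad_grid))
    stop("line ", body_idx[bad_grid[1] + 1L],
         ": non-uniform time axis", call. = FALSE)
  counts <- as.integer(mat[, 2])
  if (is.finite(hdr_total) && sum(counts) != hdr_total)
    stop("header total_counts=", format(hdr_total, scientific = FALSE),
         " does not match column sum ", sum(counts), call. = FALSE)
  decay_histogram(bw, counts)
}

#' Read a plain-text key=value simulation config
#'
#' Accepts keys `lifetimes_ns`, `amplitudes`, `background_fraction`,
#' `irf_fwhm_ps`, `irf_t0_ns`, `total_counts`, `bin_width_ns`, `n_bins`,
#' `seed` (comma-separated values where vectors are expected); `#` starts a
#' comment. Unspecified keys fall back to the package defaults.
#'
#' @param path Config file path.
#' @return List with elements `model` ([decay_components()]), `irf`
#'   ([gaussian_irf()]), `total_counts`, `bin_width`, `n_bins`, `seed`.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=")
  bad <- which(vapply(kv, length, 1L) != 2L)
  if (length(bad))
    stop("config line not of the form key=value: ", lines[bad[1]],
         call. = FALSE)
  vals <- stats::setNames(
    lapply(kv, function(x) as.numeric(strsplit(trimws(x[2]), ",")[[1]])),
    vapply(kv, function(x) trimws(x[1]), ""))
  pick <- function(key, default) if (key %in% names(vals)) vals[[key]] else default
  lifetimes <- pick("lifetimes_ns", 4.11)
  list(
    model = decay_components(
      lifetimes,
      pick("amplitudes", rep(1, length(lifetimes))),
      pick("background_fraction", 0)),
    irf = gaussian_irf(pick("irf_fwhm_ps", 150), pick("irf_t0_ns", 1.6)),
    total_counts = pick("total_counts", 1e6),
    bin_width = pick("bin_width_ns", 0.016),
    n_bins = as.integer(pick("n_bins", 4096)),
    seed = {
      s <- pick("seed", NULL)
      if (is.null(s)) NULL else as.integer(s)
    })
}
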