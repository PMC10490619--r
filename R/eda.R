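#' Bateman parameter container
#' @param tau1 decay time constant (s), > 0.
#' @param tau2 rise time constant (s), > 0, different from `tau1`.
#' @return An object of class `bateman_params`.
#' @export
bateman_params <- function(tau1 = 3.75, tau2 = 1.0) {
  check_scalar(tau1, "tau1", lower = .Machine$double.eps)
  check_scalar(tau2, "tau2", lower = .Machine$double.eps)
  if (tau1 == tau2)
    stopf("tau1 and tau2 must differ", class = "distractr_invalid_argument")
  structure(list(tau1 = tau1, tau2 = tau2), class = "bateman_params")
}

#' Sampled Bateman kernel
#'
#' `b(t) = exp(-t/tau1) - exp(-t/tau2)`, sampled at `fs` and peak-normalized
#' to unit maximum so that deconvolved driver amplitudes stay in
#' microsiemens. The analytic peak sits at
#' `t* = log(tau1/tau2) * tau1*tau2/(tau1 - tau2)`.
#'
#' @param params a [bateman_params()].
#' @param fs sampling rate (Hz).
#' @param length kernel support (s); must be at least `5 * tau1`.
#' @return Numeric kernel samples starting at t = 0.
#' @export
bateman_kernel <- function(params, fs = 10, length = 8 * params$tau1) {
  stopifnot(inherits(params, "bateman_params"))
  if (length < 5 * params$tau1)
    stopf("kernel support must cover at least 5 * tau1 seconds",
          class = "distractr_invalid_argument")
  t <- seq(0, length, by = 1 / fs)
  b <- bateman_raw(t, params$tau1, params$tau2)
  b / max(b)
}

conv_fft <- function(x, k, nfft, kf = NULL) {
  xf <- fft(c(x, numeric(nfft - length(x))))
  if (is.null(kf)) kf <- fft(c(k, numeric(nfft - length(k))))
  Re(fft(xf * kf, inverse = TRUE))[seq_along(x)] / nfft
}

# Joint refinement: min ||y - T c - K d||^2 over (c, d >= 0) with T a
# smooth (natural cubic spline) tonic basis, by projected FISTA from the
# two-stage initial point. Returns the refined tonic and driver.
joint_refine <- function(y, k, Tb, c0, d0, tol = 1e-8, max_iter = 300) {
  n <- length(y)
  nfft <- nextn(n + length(k) - 1L, 2)
  kf <- fft(c(k, numeric(nfft - length(k))))
  corr <- function(z) {
    zf <- fft(c(z, numeric(nfft - length(z))))
    Re(fft(zf * Conj(kf), inverse = TRUE))[seq_len(n)] / nfft
  }
  # Lipschitz bound: ||A||^2 <= (||K|| + ||T||)^2
  L <- (max(Mod(kf)) + sqrt(max(colSums(Tb^2)) * ncol(Tb)))^2
  c_cur <- c0; d_cur <- d0
  zc <- c0; zd <- d0
  tk <- 1
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    r <- as.numeric(Tb %*% zc) + conv_fft(zd, k, nfft, kf) - y
    gc_ <- crossprod(Tb, r)
    gd <- corr(r)
    c_new <- zc - gc_ / L
    d_new <- pmax(zd - gd / L, 0)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zc <- c_new + (tk - 1) / tk_new * (c_new - c_cur)
    zd <- d_new + (tk - 1) / tk_new * (d_new - d_cur)
    c_cur <- c_new; d_cur <- d_new; tk <- tk_new
    if (it %% 10L == 0L) {
      obj <- sum((as.numeric(Tb %*% c_cur) +
                    conv_fft(d_cur, k, nfft, kf) - y)^2)
      if (is.finite(obj_old) && abs(obj_old - obj) <= tol * max(obj_old, 1e-30))
        break
      obj_old <- obj
    }
  }
  list(tonic = as.numeric(Tb %*% c_cur), driver = d_cur)
}

# Projected FISTA for min ||K d - y||^2, d >= 0, K = causal convolution.
nn_deconvolve <- function(y, k, tol = 1e-8, max_iter = 400) {
  n <- length(y)
  nfft <- nextn(n + length(k) - 1L, 2)
  kf <- fft(c(k, numeric(nfft - length(k))))
  L <- max(Mod(kf))^2
  corr <- function(z) {  # K^T z  (correlation with the kernel)
    zf <- fft(c(z, numeric(nfft - length(z))))
    Re(fft(zf * Conj(kf), inverse = TRUE))[seq_len(n)] / nfft
  }
  d <- pmax(numeric(n), 0)
  z <- d
  tk <- 1
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    r <- conv_fft(z, k, nfft, kf) - y
    g <- corr(r)
    d_new <- pmax(z - g / L, 0)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- d_new + (tk - 1) / tk_new * (d_new - d)
    d <- d_new
    tk <- tk_new
    if (it %% 10L == 0L) {
      obj <- sum((conv_fft(d, k, nfft, kf) - y)^2)
      if (is.finite(obj_old) && abs(obj_old - obj) <= tol * max(obj_old, 1e-30))
        break
      obj_old <- obj
    }
  }
  d
}

#' Continuous decomposition of a skin-conductance recording
#'
#' Splits the signal into a slowly varying tonic level and a nonnegative
#' phasic driver. The tonic curve is a 10 s-grid percentile baseline
#' (10th percentile per segment, cubic-spline interpolated); the
#' tonic-subtracted residual is then deconvolved against the Bateman
#' kernel by nonnegativity-constrained least squares (projected FISTA,
#' relative objective tolerance 1e-8), so that
#' `tonic + driver (*) kernel + residual` reconstructs the input.
#'
#' @param gsr a [gsr_recording()] covering its response window.
#' @param params a [bateman_params()].
#' @param smooth_s pre-smoothing moving-average width (s); default 0.5.
#' @param grid_s tonic-grid segment length (s); default 10.
#' @param tonic_q tonic percentile per segment; default 0.1.
#' @param refine jointly re-fit the tonic (20 s-knot natural spline) and
#'   the nonnegative driver by constrained least squares, warm-started at
#'   the two-stage solution (default TRUE; improves reconstruction in
#'   SCR-dense recordings).
#' @return An object of class `eda_decomposition` with `tonic`, `driver`,
#'   `residual`, `reconstruction` (all uS), plus `kernel`, `fs`, `time`.
#' @export
decompose_cda <- function(gsr, params = bateman_params(), smooth_s = 0.5,
                          grid_s = 10, tonic_q = 0.1, refine = TRUE) {
  stopifnot(inherits(gsr, "gsr_recording"))
  x <- gsr$samples
  if (any(!is.finite(x)))
    stopf("GSR samples must be finite", class = "distractr_data_error")
  fs <- gsr$fs
  n <- length(x)
  w <- max(1L, round(smooth_s * fs))
  xs <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  na <- is.na(xs)
  xs[na] <- x[na]

  # percentile baseline on a coarse grid; a rolling minimum over +/- 1
  # neighbouring segment keeps SCR decay tails (which outlast one segment)
  # from inflating the baseline
  seg <- floor((seq_len(n) - 1L) / round(grid_s * fs))
  mids <- as.numeric(tapply(seq_len(n), seg, function(i) mean(i)))
  qs <- as.numeric(tapply(xs, seg, quantile, probs = tonic_q,
                          names = FALSE))
  ns <- length(qs)
  if (ns >= 3)
    qs <- pmin(qs, c(qs[-1], qs[ns]), c(qs[1], qs[-ns]))
  if (ns >= 4) {
    tonic <- spline(mids, qs, xout = seq_len(n), method = "fmm")$y
  } else {
    tonic <- rep(mean(qs), n)
  }
  tonic <- pmin(tonic, xs)  # baseline never exceeds the (smoothed) signal

  k <- bateman_kernel(params, fs = fs)
  phasic <- xs - tonic
  # fewer warm-start iterations suffice when the joint refinement follows
  driver <- nn_deconvolve(phasic, k, max_iter = if (refine) 150 else 400)
  if (refine) {
    # joint constrained least squares: smooth spline tonic + nonneg driver,
    # warm-started at the two-stage solution so attribution is preserved
    knots <- seq(1, n, by = round(20 * fs))
    Tb <- cbind(1, splines::ns(seq_len(n), knots = knots[-c(1, length(knots))],
                               Boundary.knots = c(1, n)))
    c0 <- qr.coef(qr(Tb), tonic)
    c0[is.na(c0)] <- 0
    jr <- joint_refine(xs, k, Tb, c0, driver)
    tonic <- jr$tonic
    driver <- jr$driver
  }
  nfft <- nextn(n + length(k) - 1L, 2)
  recon_phasic <- conv_fft(driver, k, nfft)
  structure(list(tonic = tonic, driver = driver,
                 residual = x - tonic - recon_phasic,
                 reconstruction = tonic + recon_phasic,
                 kernel = k, params = params, fs = fs,
                 time = rec_time(gsr), window_start = gsr$window_start,
                 window_length = gsr$window_length),
            class = "eda_decomposition")
}

#' @export
print.eda_decomposition <- function(x, ...) {
  cat(sprintf("<eda_decomposition> %d samples @ %g Hz, residual RMS %.4g uS\n",
              length(x$driver), x$fs, sqrt(mean(x$residual^2))))
  invisible(x)
}

#' Detect skin conductance responses from a phasic driver
#'
#' Segments contiguous supra-floor bursts of the driver (bursts separated
#' by less than 1 s are merged), reconstructs each burst's conductance
#' deflection through the Bateman kernel, and keeps events whose
#' reconstructed amplitude reaches `threshold` inside the response window.
#'
#' @param decomp an [decompose_cda()] result.
#' @param threshold minimum SCR amplitude (uS); default 0.01.
#' @param floor driver activity floor (uS) for burst segmentation.
#' @return A data frame with one row per SCR: `onset`, `peak_time` (s) and
#'   `amplitude` (uS). Zero rows is a valid result.
#' @export
detect_scrs <- function(decomp, threshold = 0.01, floor = 1e-4) {
  stopifnot(inherits(decomp, "eda_decomposition"))
  check_scalar(threshold, "threshold", lower = .Machine$double.eps)
  d <- decomp$driver
  n <- length(d)
  active <- d > floor
  if (!any(active)) return(data.frame(onset = numeric(0),
                                      peak_time = numeric(0),
                                      amplitude = numeric(0)))
  # close gaps shorter than 1 s, then label runs
  gap <- round(decomp$fs)
  r <- rle(active)
  idx <- which(!r$values & r$lengths < gap)
  idx <- idx[idx > 1 & idx < length(r$values)]
  r$values[idx] <- TRUE
  active <- inverse.rle(r)
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  starts <- starts[keep]; ends <- ends[keep]

  nfft <- nextn(n + length(decomp$kernel) - 1L, 2)
  out <- lapply(seq_along(starts), function(i) {
    mask <- numeric(n)
    mask[starts[i]:ends[i]] <- d[starts[i]:ends[i]]
    rec <- conv_fft(mask, decomp$kernel, nfft)
    j <- which.max(rec)
    data.frame(onset = decomp$time[starts[i]],
               peak_time = decomp$time[j],
               amplitude = rec[j])
  })
  ev <- do.call(rbind, out)
  w0 <- decomp$window_start
  w1 <- w0 + decomp$window_length
  ev <- ev[ev$amplitude >= threshold & ev$onset >= w0 & ev$onset <= w1, ,
           drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Canonical names of the 7 electrodermal features
#' @return Character vector in canonical order.
#' @export
gsr_feature_names <- function() {
  c("SCR", "nSCR", "ISCR", "Latency", "AmpSum", "PhasicMax", "Tonic")
}

#' Compute the 7 electrodermal features within the response window
#'
#' @param decomp an [decompose_cda()] result.
#' @param events SCR table from [detect_scrs()] on the same recording.
#' @return Named numeric vector: `SCR` (mean phasic driver, uS), `nSCR`
#'   (count), `ISCR` (driver time-integral, uS*s; identically
#'   `SCR * window_length`), `Latency` (first-SCR onset minus window start,
#'   s; `NA` when no SCR), `AmpSum` (uS), `PhasicMax` (uS), `Tonic`
#'   (mean tonic level, uS).
#' @export
compute_gsr_features <- function(decomp, events) {
  stopifnot(inherits(decomp, "eda_decomposition"))
  w0 <- decomp$window_start
  w1 <- w0 + decomp$window_length
  win <- decomp$time >= w0 & decomp$time <= w1
  scr <- mean(decomp$driver[win])
  c(SCR = scr, nSCR = nrow(events),
    ISCR = scr * decomp$window_length,
    Latency = if (nrow(events)) min(events$onset) - w0 else NA_real_,
    AmpSum = sum(events$amplitude),
    PhasicMax = max(decomp$driver[win]),
    Tonic = mean(decomp$tonic[win]))
}

#' Extract the 7 electrodermal features from a raw GSR recording
#'
#' Convenience chain: [decompose_cda()], [detect_scrs()],
#' [compute_gsr_features()].
#'
#' @param gsr a [gsr_recording()].
#' @param threshold minimum SCR amplitude (uS).
#' @param params a [bateman_params()].
#' @return Named numeric vector of the 7 features.
#' @export
extract_eda <- function(gsr, threshold = 0.01, params = bateman_params()) {
  decomp <- decompose_cda(gsr, params)
  compute_gsr_features(decomp, detect_scrs(decomp, threshold))
}
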