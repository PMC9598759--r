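#' Scan conversion to a Cartesian pixel grid
#'
#' Maps per-scan-line samples into the output image. Linear arrays use a
#' direct lateral mapping; curvilinear arrays map each pixel to (angle,
#' radius) relative to the transducer arc, with pixels outside the fan set
#' to 0. Interpolation is nearest-neighbor or bilinear per the probe config;
#' label slices are always nearest (ids must not be blended).
#'
#' @param intensities samples x n_scanlines matrix (one column per line).
#' @param probe a [probe_config()].
#' @param labels treat values as structure ids (forces nearest).
#' @return image matrix `image_height_px` x `image_width_px`.
#' @export
scan_convert <- function(intensities, probe, labels = FALSE) {
  if (ncol(intensities) != probe$n_scanlines)
    stop("line count mismatch: got ", ncol(intensities), ", expected ",
         probe$n_scanlines, call. = FALSE)
  W <- probe$image_width_px; H <- probe$image_height_px
  psp <- probe$pixel_spacing_mm
  n <- probe$n_scanlines; S <- nrow(intensities)
  ss <- if (S > 1) probe$scanline_depth_mm / (S - 1) else probe$scanline_depth_mm
  px <- (seq_len(W) - 1 - (W - 1) / 2) * psp   # lateral mm per column
  py <- (seq_len(H) - 1) * psp                 # depth mm per row
  if (probe$kind == "linear") {
    lx <- if (n == 1) 0 else probe$footprint_mm / (n - 1)
    u <- if (n == 1) rep(1, W) else (px + probe$footprint_mm / 2) / lx + 1
    U <- matrix(u, H, W, byrow = TRUE)
    Vs <- matrix(py / ss + 1, H, W)
  } else {
    R <- probe$transducer_radius_mm
    half <- probe$fov_deg / 2 * pi / 180
    X <- matrix(px, H, W, byrow = TRUE)
    Y <- matrix(py, H, W)
    rr <- sqrt(X^2 + (Y + R)^2)
    th <- atan2(X, Y + R)
    dth <- if (n == 1) 1 else 2 * half / (n - 1)
    U <- (th + half) / dth + 1
    Vs <- (rr - R) / ss + 1
    U[abs(th) > half] <- NA
  }
  tol <- 1e-9
  out <- matrix(0, H, W)
  if (labels || probe$interpolation == "nearest") {
    ui <- round(U); vi <- round(Vs)
    ok <- !is.na(ui) & ui >= 1 - tol & ui <= n + tol &
          vi >= 1 - tol & vi <= S + tol
    ui <- pmin(pmax(ui, 1), n); vi <- pmin(pmax(vi, 1), S)
    idx <- which(ok)
    out[idx] <- intensities[cbind(vi[idx], ui[idx])]
  } else {
    ok <- !is.na(U) & U >= 1 - tol & U <= n + tol &
          Vs >= 1 - tol & Vs <= S + tol
    Uc <- pmin(pmax(U, 1), n); Vc <- pmin(pmax(Vs, 1), S)
    u0 <- pmin(floor(Uc), n - 1); v0 <- pmin(floor(Vc), S - 1)
    if (n == 1) u0[] <- 1
    if (S == 1) v0[] <- 1
    fu <- Uc - u0; fv <- Vc - v0
    idx <- which(ok)
    g <- function(vv, uu) intensities[cbind(vv[idx], uu[idx])]
    vals <- (1 - fu[idx]) * (1 - fv[idx]) * g(v0, u0) +
            fu[idx] * (1 - fv[idx]) * g(v0, pmin(u0 + 1, n)) +
            (1 - fu[idx]) * fv[idx] * g(pmin(v0 + 1, S), u0) +
            fu[idx] * fv[idx] * g(pmin(v0 + 1, S), pmin(u0 + 1, n))
    out[idx] <- vals
  }
  out
}
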