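# The mathematical core of the mechanism, as pure array functions:
#
#   local attention   A_j = C_j( B_j( sigma(A_G) ) )
#   gated features    Fbar_j = A_j (x) F_j + F_j
#
# where sigma is an elementwise logistic, B_j is half-pixel-center
# bilinear resampling to the feature map's spatial dims, C_j a single
# same-padded convolution producing c_j channels, and (x) the elementwise
# product. The same primitives back the autodiff graph used in training.

as_hwc <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or (h, w, c) array", call. = FALSE)
  if (length(d) == 2L) array(x, dim = c(d, 1L)) else x
}

#' Elementwise logistic of a raw attention map
#'
#' Maps the encoder-decoder's raw output into (0, 1); this bounded map is
#' what all scale-specific heads consume and what the heat-map
#' visualizations display.
#'
#' @param raw Matrix or (h, w, c) array of finite values.
#' @return Array of the same shape with values in (0, 1).
#' @export
sigmoid_map <- function(raw) {
  if (any(is.na(raw))) stop("sigmoid_map: NaN/NA in input", call. = FALSE)
  1 / (1 + exp(-raw))
}

#' Bilinear resampling with half-pixel centers
#'
#' Channelwise bilinear interpolation to a target spatial size, using the
#' half-pixel-center convention fixed package-wide (source coordinate
#' `(i + 0.5) * n_in / n_out - 0.5`, clamped). Interpolation is convex,
#' so output values never leave the input's range.
#'
#' @param map Matrix or (h, w, c) array.
#' @param target Integer vector `c(h, w)` of output spatial dims (>= 1).
#' @return Resized array; a matrix input returns a matrix.
#' @export
resize_bilinear <- function(map, target) {
  if (length(target) != 2L || any(target < 1)) {
    stop("resize_bilinear: target dims must be two integers >= 1", call. = FALSE)
  }
  was_mat <- length(dim(map)) == 2L || is.null(dim(map))
  x <- as_hwc(map)
  out <- .bilinear_fwd(x, as.integer(target[1]), as.integer(target[2]))
  if (was_mat) out[, , 1] else out
}

#' Per-scale projection convolution
#'
#' The single convolution layer that adapts the resized bounded global
#' map (`c_g` channels) to a scale's feature-map channel count `c_j`,
#' with same-padding so spatial dims are preserved.
#'
#' @param prior (h_j, w_j, c_g) array, typically `resize_bilinear(sigmoid_map(raw), ...)`.
#' @param weights Convolution kernel, dim `(k, k, c_g, c_j)`.
#' @param bias Numeric vector of length `c_j`.
#' @return (h_j, w_j, c_j) array.
#' @export
scale_projection <- function(prior, weights, bias) {
  x <- as_hwc(prior)
  wd <- dim(weights)
  if (length(wd) != 4L) stop("scale_projection: weights must be (k,k,c_in,c_out)",
                             call. = FALSE)
  if (wd[3] != dim(x)[3]) {
    stop("scale_projection: prior has ", dim(x)[3], " channels but weights expect ",
         wd[3], call. = FALSE)
  }
  if (length(bias) != wd[4]) stop("scale_projection: bias length != c_out",
                                  call. = FALSE)
  .conv2d_fwd(x, weights, as.numeric(bias), 1L)
}

#' Scale-specific local attention map
#'
#' Composes the three primitives: logistic bounding of the raw global
#' map, bilinear resampling to the feature map's spatial dims, and the
#' per-scale projection to its channel count. The feature map supplies
#' only the target shape.
#'
#' @param feature (h_j, w_j, c_j) feature map at scale j.
#' @param global_raw Raw (pre-logistic) global attention map.
#' @param weights,bias Per-scale projection parameters.
#' @return Local attention map with `dim(feature)`.
#' @export
local_attention <- function(feature, global_raw, weights, bias) {
  f <- as_hwc(feature)
  prior <- resize_bilinear(sigmoid_map(as_hwc(global_raw)), dim(f)[1:2])
  a <- scale_projection(prior, weights, bias)
  if (!identical(dim(a), dim(f))) {
    stop("local_attention: projected map shape (", paste(dim(a), collapse = "x"),
         ") does not match the feature map (", paste(dim(f), collapse = "x"), ")",
         call. = FALSE)
  }
  a
}

#' Residual attention gating
#'
#' Applies an attention map to a feature map with a residual connection:
#' `attended = attention * feature + feature`, elementwise. A zero
#' attention map leaves the features bit-exactly unchanged.
#'
#' @param feature Feature map array.
#' @param attention Attention map of identical shape.
#' @return Attended feature map of the same shape.
#' @export
apply_attention <- function(feature, attention) {
  if (!identical(dim(as_hwc(feature)), dim(as_hwc(attention)))) {
    stop("apply_attention: shape mismatch between feature and attention maps",
         call. = FALSE)
  }
  attention * feature + feature
}
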