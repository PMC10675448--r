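# Dyadic wavelet denoising of event-locked epochs.
#
# Default scheme: redundant (à-trous) filter bank with the quadratic
# B-spline smoothing kernel [1, 3, 3, 1] / 8. At each scale the running
# approximation is smoothed with the kernel dilated by 2^(j-1) (holes) and
# the detail is the difference between successive approximations, so the
# inverse transform — approximation plus the sum of all details — is exact
# by construction and every scale is time-aligned with the input. A
# decimated pyramid (orthogonal Haar) is provided as an alternative scheme.

bspline2_kernel <- c(1, 3, 3, 1) / 8

# Circular convolution with the kernel dilated by `dil`. The even-length
# B-spline kernel has a group delay of dil/2 samples; an integer circular
# shift re-centres each stage so all scales stay time-aligned to within
# half a sample (required by the cross-scale parent-child dependency and
# by applying one mask to many epochs).
atrous_smooth <- function(x, dil) {
  n <- length(x)
  offs <- c(-2, -1, 0, 1) * dil + round(dil / 2)
  out <- numeric(n)
  for (i in seq_along(bspline2_kernel)) {
    idx <- ((seq_len(n) - 1 + offs[i]) %% n) + 1
    out <- out + bspline2_kernel[i] * x[idx]
  }
  out
}

#' Dyadic wavelet decomposition
#'
#' Five-scale (by default) dyadic decomposition of one epoch channel.
#' `scheme = "atrous"` (default) is the redundant quadratic-B-spline filter
#' bank; `scheme = "decimated"` is an orthogonal Haar pyramid.
#'
#' @param x Numeric signal.
#' @param n_scales Number of detail scales (default 5).
#' @param scheme `"atrous"` or `"decimated"`.
#' @return Object of class `dyadic_dwt` with `details` (list, finest scale
#'   first), `approx`, `scheme` and `n_input`.
#' @export
dwt_forward <- function(x, n_scales = 5, scheme = c("atrous", "decimated")) {
  scheme <- match.arg(scheme)
  n <- length(x)
  if (scheme == "atrous") {
    if (n < 2^(n_scales - 1) * 3) {
      stopf("signal of %d samples is too short for %d a-trous scales", n, n_scales)
    }
    details <- vector("list", n_scales)
    approx <- x
    for (j in seq_len(n_scales)) {
      sm <- atrous_smooth(approx, 2^(j - 1))
      details[[j]] <- approx - sm
      approx <- sm
    }
  } else {
    if (n %% 2^n_scales != 0) {
      stopf("decimated scheme needs length divisible by 2^%d, got %d",
            n_scales, n)
    }
    details <- vector("list", n_scales)
    approx <- x
    for (j in seq_len(n_scales)) {
      even <- approx[seq(2, length(approx), by = 2)]
      odd <- approx[seq(1, length(approx), by = 2)]
      details[[j]] <- (odd - even) / sqrt(2)
      approx <- (odd + even) / sqrt(2)
    }
  }
  structure(list(details = details, approx = approx, scheme = scheme,
                 n_input = n, n_scales = n_scales), class = "dyadic_dwt")
}

#' @rdname dwt_forward
#' @param decomposition A `dyadic_dwt` object.
#' @export
dwt_inverse <- function(decomposition) {
  stopifnot(inherits(decomposition, "dyadic_dwt"))
  if (decomposition$scheme == "atrous") {
    Reduce(`+`, decomposition$details, decomposition$approx)
  } else {
    approx <- decomposition$approx
    for (j in rev(seq_len(decomposition$n_scales))) {
      d <- decomposition$details[[j]]
      odd <- (approx + d) / sqrt(2)
      even <- (approx - d) / sqrt(2)
      out <- numeric(2 * length(approx))
      out[seq(1, length(out), by = 2)] <- odd
      out[seq(2, length(out), by = 2)] <- even
      approx <- out
    }
    approx
  }
}

#' Robust per-scale noise level
#'
#' Median absolute deviation of the detail coefficients divided by 0.6745,
#' the Donoho-standard robust estimate of a Gaussian noise SD.
#'
#' @param detail_coeffs Numeric vector of detail coefficients at one scale.
#' @return Estimated noise SD at that scale.
#' @export
noise_sigma <- function(detail_coeffs) {
  if (!length(detail_coeffs)) stopf("empty coefficient vector")
  stats::median(abs(detail_coeffs)) / 0.6745
}

#' Scale-dependent squared threshold
#'
#' `T_j^2 = sigma_j^2 * 2 * log(N)` with `N` the number of coefficients.
#'
#' @param sigma_j Noise SD at scale j.
#' @param n_coeffs Number of wavelet coefficients `N` (>= 2).
#' @return The squared threshold.
#' @export
scale_threshold <- function(sigma_j, n_coeffs) {
  if (n_coeffs < 2) stopf("threshold needs N >= 2 coefficients")
  sigma_j^2 * 2 * log(n_coeffs)
}

# Thresholds for every detail scale of a decomposition. For the redundant
# scheme the threshold uses the number of independent (decimated-
# equivalent) coefficients at that scale, n / 2^j: the redundant transform
# oversamples each scale 2^j-fold, and feeding the raw count into the
# universal threshold would over-penalise exactly the coarse scales that
# carry the slow evoked-response energy.
compute_thresholds <- function(decomposition) {
  vapply(seq_along(decomposition$details), function(j) {
    d <- decomposition$details[[j]]
    n_eff <- if (decomposition$scheme == "atrous") {
      max(2, decomposition$n_input / 2^j)
    } else length(d)
    scale_threshold(noise_sigma(d), n_eff)
  }, numeric(1))
}

#' Neighbourhood thresholding mask
#'
#' A coefficient is kept iff the energy of its 3-coefficient neighbourhood
#' strictly exceeds the scale's squared threshold; boundary coefficients use
#' the neighbours that exist.
#'
#' @param decomposition A [dwt_forward()] result.
#' @param thresholds_sq Squared threshold per scale (finest first); default
#'   computed from the decomposition itself via [scale_threshold()].
#' @return Object of class `dwt_mask`: list `keep` of logical vectors
#'   congruent with the detail coefficients.
#' @export
neighbor_mask <- function(decomposition, thresholds_sq = compute_thresholds(decomposition)) {
  stopifnot(inherits(decomposition, "dyadic_dwt"))
  if (length(thresholds_sq) != decomposition$n_scales) {
    stopf("need one threshold per scale (%d), got %d",
          decomposition$n_scales, length(thresholds_sq))
  }
  keep <- vector("list", decomposition$n_scales)
  for (j in seq_len(decomposition$n_scales)) {
    d2 <- decomposition$details[[j]]^2
    n <- length(d2)
    energy <- d2 +
      c(0, d2[-n]) +     # left neighbour (0 at the first coefficient)
      c(d2[-1], 0)       # right neighbour (0 at the last coefficient)
    keep[[j]] <- energy > thresholds_sq[j]
  }
  structure(list(keep = keep, scheme = decomposition$scheme,
                 n_scales = decomposition$n_scales,
                 thresholds_sq = thresholds_sq),
            class = "dwt_mask")
}

#' Parent-child pruning of a coefficient mask
#'
#' Whenever a coefficient at a coarser scale is removed, the finer-scale
#' coefficients beneath it are removed as well, applied coarsest to finest
#' so removals cascade. In the decimated pyramid the parent at index k owns
#' children 2k-1 and 2k. In the redundant scheme every time index is
#' covered by a window of coarse coefficients (the parent support, one
#' dilation wide on each side); a child survives only while at least one
#' covering parent survives, which reduces to the decimated rule when the
#' redundancy is collapsed.
#'
#' @param mask A [neighbor_mask()] result.
#' @return The pruned `dwt_mask`.
#' @export
parent_child_prune <- function(mask) {
  stopifnot(inherits(mask, "dwt_mask"))
  J <- mask$n_scales
  if (J < 2) return(mask)
  for (j in seq(J, 2)) {               # scale j = parent, j-1 = child (finer)
    parent <- mask$keep[[j]]
    nc <- length(mask$keep[[j - 1]])
    if (mask$scheme == "atrous") {
      if (all(parent)) next
      r <- 2^(j - 1)                   # parent support radius, samples
      covered <- vapply(seq_len(nc), function(k) {
        any(parent[max(1L, k - r):min(length(parent), k + r)])
      }, logical(1))
      mask$keep[[j - 1]] <- mask$keep[[j - 1]] & covered
    } else {
      removed <- which(!parent)
      if (!length(removed)) next
      child_idx <- sort(unique(c(2L * removed - 1L, 2L * removed)))
      child_idx <- child_idx[child_idx <= nc]
      mask$keep[[j - 1]][child_idx] <- FALSE
    }
  }
  mask
}

#' Coefficient mask from the grand average
#'
#' Decomposes the per-channel grand average of the ErrP-labelled epochs,
#' applies the neighbourhood criterion and parent-child pruning, and
#' returns one mask per channel. The same masks then denoise every single
#' epoch, as the procedure fixes coefficients once per training set.
#'
#' @param epochs Training [epoch_set()].
#' @param n_scales,scheme Passed to [dwt_forward()].
#' @param label_filter Epochs entering the grand average (default 1 = ErrP).
#' @return Object of class `wavelet_fit`: list of per-channel masks.
#' @export
select_mask_from_grand_average <- function(epochs, n_scales = 5,
                                           scheme = "atrous",
                                           label_filter = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  ga <- grand_average(epochs, label_filter)
  masks <- vector("list", nrow(ga))
  for (ch in seq_len(nrow(ga))) {
    dec <- dwt_forward(ga[ch, ], n_scales, scheme)
    masks[[ch]] <- parent_child_prune(neighbor_mask(dec))
  }
  structure(list(masks = masks, n_scales = n_scales, scheme = scheme),
            class = "wavelet_fit")
}

#' Denoise one epoch channel with a fixed mask
#'
#' Forward transform, multiply the detail coefficients by the mask, keep the
#' approximation band (it carries the slow delta-band ErrP components),
#' inverse transform.
#'
#' @param epoch_channel Numeric vector.
#' @param mask A `dwt_mask`.
#' @param keep_approx Keep the coarsest approximation (default TRUE).
#' @return The denoised vector.
#' @export
denoise_epoch <- function(epoch_channel, mask, keep_approx = TRUE) {
  stopifnot(inherits(mask, "dwt_mask"))
  dec <- dwt_forward(epoch_channel, mask$n_scales, mask$scheme)
  for (j in seq_len(dec$n_scales)) {
    if (length(mask$keep[[j]]) != length(dec$details[[j]])) {
      stopf("mask scale %d has %d coefficients, decomposition has %d",
            j, length(mask$keep[[j]]), length(dec$details[[j]]))
    }
    dec$details[[j]] <- dec$details[[j]] * mask$keep[[j]]
  }
  if (!keep_approx) dec$approx <- dec$approx * 0
  dwt_inverse(dec)
}

#' Apply a fitted wavelet denoiser to an epoch set
#'
#' @param fit A [select_mask_from_grand_average()] result.
#' @param epochs An [epoch_set()].
#' @return The denoised `epoch_set` (labels untouched).
#' @export
wavelet_apply <- function(fit, epochs) {
  stopifnot(inherits(fit, "wavelet_fit"), inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[2] != length(fit$masks)) {
    stopf("fit has %d channels but epochs have %d", length(fit$masks), d[2])
  }
  for (i in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      epochs$data[i, ch, ] <- denoise_epoch(epochs$data[i, ch, ],
                                            fit$masks[[ch]])
    }
  }
  epochs
}

#' @rdname wavelet_apply
#' @inheritParams select_mask_from_grand_average
#' @export
wavelet_estimate_epochset <- function(epochs, n_scales = 5, scheme = "atrous") {
  wavelet_apply(select_mask_from_grand_average(epochs, n_scales, scheme),
                epochs)
}
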