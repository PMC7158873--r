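#' Multi-shell diffusion acquisition protocol
#'
#' Per-volume b-values (s/mm^2) and unit gradient directions. Volumes with
#' `b <= b0_threshold` are treated as non-diffusion-weighted (b = 0); their
#' direction vectors may be zero.
#'
#' @param bvals numeric vector of b-values, one per volume.
#' @param bvecs matrix of gradient directions (n_volumes x 3); rows for
#'   diffusion-weighted volumes must be unit vectors.
#' @param b0_threshold b-values at or below this are treated as b = 0
#'   (default 50 s/mm^2).
#' @return an object of class `diffusion_protocol`.
#' @export
diffusion_protocol <- function(bvals, bvecs, b0_threshold = 50) {
  bvecs <- as.matrix(bvecs)
  if (length(bvals) != nrow(bvecs))
    stop("`bvals` and `bvecs` must describe the same number of volumes")
  dw <- bvals > b0_threshold
  if (any(dw)) {
    nrm <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-4))
      stop("gradient directions of diffusion-weighted volumes must be unit vectors")
  }
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs,
                 b0_threshold = b0_threshold), class = "diffusion_protocol")
}

#' @export
print.diffusion_protocol <- function(x, ...) {
  sh <- protocol_shells(x)
  cat("<diffusion_protocol> ", length(x$bvals), " volumes: ",
      sum(x$bvals <= x$b0_threshold), " b=0, shells b = ",
      paste(sh, collapse = ", "), " s/mm^2\n", sep = "")
  invisible(x)
}

# Distinct nonzero shell b-values, ascending.
protocol_shells <- function(protocol) {
  sort(unique(protocol$bvals[protocol$bvals > protocol$b0_threshold]))
}

# Logical index of b=0 volumes.
protocol_b0 <- function(protocol) protocol$bvals <= protocol$b0_threshold

#' Default two-shell acquisition protocol
#'
#' b = 1000 and 2200 s/mm^2 with 60 non-collinear directions per shell and
#' 13 interleaved b = 0 volumes, mirroring a typical 3 T paediatric
#' multi-shell neuroimaging acquisition. For the standard 60 directions an
#' embedded electrostatically optimized scheme is used (the convention for
#' scanner gradient tables); other counts fall back to a Fibonacci set.
#'
#' @param shell_bvals nonzero shell b-values (s/mm^2).
#' @param n_dirs directions per shell.
#' @param n_b0 number of b = 0 volumes, interleaved through the series.
#' @return a `diffusion_protocol`.
#' @export
default_protocol <- function(shell_bvals = c(1000, 2200), n_dirs = 60,
                             n_b0 = 13) {
  base_dirs <- if (n_dirs == 60L) dirs60
    else fibonacci_sphere(n_dirs, hemisphere = TRUE)
  base_dirs <- base_dirs / sqrt(rowSums(base_dirs^2))
  dirs <- lapply(seq_along(shell_bvals), function(i) base_dirs)
  b_dw <- rep(shell_bvals, each = n_dirs)
  g_dw <- do.call(rbind, dirs)
  n_dw <- length(b_dw)
  # interleave b0s at (roughly) even intervals through the series
  pos_b0 <- round(seq(1, n_dw + n_b0, length.out = n_b0))
  bvals <- numeric(n_dw + n_b0)
  bvecs <- matrix(0, n_dw + n_b0, 3)
  is_b0 <- seq_len(n_dw + n_b0) %in% pos_b0
  bvals[!is_b0] <- b_dw
  bvecs[!is_b0, ] <- g_dw
  diffusion_protocol(bvals, bvecs)
}
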