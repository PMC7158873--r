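#' Fit the diffusion tensor and derive scalar maps
#'
#' Per-voxel log-linear weighted least-squares fit of the single tensor
#' model `ln S = ln S0 - b g' D g`, with squared-signal weights (the
#' standard variance stabilisation for log-transformed magnitude data),
#' followed by eigendecomposition. Scalars follow the usual definitions:
#' `MD = (l1+l2+l3)/3`, `AD = l1`, `RD = (l2+l3)/2`,
#' `FA = sqrt(3/2 * sum((l - MD)^2) / sum(l^2))`. Negative eigenvalues from
#' noisy fits are clamped to zero before scalar computation and the voxel is
#' flagged.
#'
#' @param signal a [signal_volume()].
#' @param protocol a [diffusion_protocol()] with at least 6 unique nonzero
#'   directions.
#' @param mask optional binary `vol3d` (or logical vector for matrix
#'   signals) restricting the fit.
#' @return an object of class `dti_maps`: a list of per-voxel vectors/arrays
#'   `FA`, `MD`, `AD`, `RD`, eigenvalues `L1..L3`, principal eigenvectors
#'   `V1` (n x 3) and logical flags `clamped` and `excluded`.
#' @export
fit_dti <- function(signal, protocol, mask = NULL) {
  stopifnot(inherits(signal, "signal_volume"),
            inherits(protocol, "diffusion_protocol"))
  S <- sv_matrix(signal)
  dw <- !protocol_b0(protocol)
  g <- protocol$bvecs[dw, , drop = FALSE]
  # unique up to antipodal symmetry
  gu <- unique(round(g * sign(ifelse(abs(g[, 3]) > 1e-12, g[, 3], 1)), 6))
  if (sum(dw) < 6L || nrow(gu) < 6L)
    stop("DTI requires >= 6 unique nonzero gradient directions")
  b <- protocol$bvals
  gx <- protocol$bvecs[, 1]; gy <- protocol$bvecs[, 2]; gz <- protocol$bvecs[, 3]
  X <- cbind(1, -b * gx^2, -b * gy^2, -b * gz^2,
             -2 * b * gx * gy, -2 * b * gx * gz, -2 * b * gy * gz)
  if (qr(X)$rank < 7L) stop("rank-deficient design: gradient directions are coplanar")

  nv <- nrow(S)
  sel <- mask_selector(mask, nv, signal$sdim)
  out <- list(FA = rep(NA_real_, nv), MD = rep(NA_real_, nv),
              AD = rep(NA_real_, nv), RD = rep(NA_real_, nv),
              L1 = rep(NA_real_, nv), L2 = rep(NA_real_, nv),
              L3 = rep(NA_real_, nv), V1 = matrix(NA_real_, nv, 3),
              clamped = rep(FALSE, nv), excluded = rep(FALSE, nv))
  for (v in which(sel)) {
    s <- S[v, ]
    if (any(!is.finite(s)) || any(s <= 0)) { out$excluded[v] <- TRUE; next }
    w <- s^2
    beta <- tryCatch(solve(crossprod(X, w * X), crossprod(X, w * log(s))),
                     error = function(e) NULL)
    if (is.null(beta)) { out$excluded[v] <- TRUE; next }
    D <- matrix(c(beta[2], beta[5], beta[6],
                  beta[5], beta[3], beta[7],
                  beta[6], beta[7], beta[4]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    l <- e$values
    if (any(l < 0)) { out$clamped[v] <- TRUE; l <- pmax(l, 0) }
    md <- mean(l)
    denom <- sum(l^2)
    out$FA[v] <- if (denom > 0) sqrt(1.5 * sum((l - md)^2) / denom) else 0
    out$MD[v] <- md; out$AD[v] <- l[1]; out$RD[v] <- (l[2] + l[3]) / 2
    out$L1[v] <- l[1]; out$L2[v] <- l[2]; out$L3[v] <- l[3]
    out$V1[v, ] <- e$vectors[, 1]
  }
  structure(c(out, list(sdim = signal$sdim, affine = signal$affine)),
            class = "dti_maps")
}

# Normalise the many accepted mask forms to a logical voxel selector.
mask_selector <- function(mask, nv, sdim) {
  if (is.null(mask)) return(rep(TRUE, nv))
  m <- if (inherits(mask, "vol3d")) as.vector(mask$data != 0) else as.vector(mask != 0)
  if (length(m) != nv) stop("mask does not match the signal grid")
  m
}

#' @export
print.dti_maps <- function(x, ...) {
  n <- sum(!is.na(x$FA))
  cat("<dti_maps> ", n, " fitted voxels; median FA ",
      signif(median(x$FA, na.rm = TRUE), 3), ", median MD ",
      signif(median(x$MD, na.rm = TRUE), 3), " mm^2/s\n", sep = "")
  invisible(x)
}

# Reshape a per-voxel vector from a fit object back onto its spatial grid.
map_as_vol <- function(fit, name) {
  vol3d(array(fit[[name]], fit$sdim), fit$affine)
}
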