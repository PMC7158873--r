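#' Role-to-label mapping for a parcellation
#'
#' Names the integer labels that play each anatomical role in a subject's
#' cortical/subcortical parcellation: per-hemisphere thalamus, the three
#' occipital cortical regions forming the composite target (lingual,
#' pericalcarine, lateral occipital), and the grey-matter set used for
#' contralateral exclusion.
#'
#' @param thalamus,lingual,pericalcarine,lateral_occipital named vectors
#'   `c(left = id, right = id)`.
#' @param gray_matter named vector (or list of vectors) of grey-matter label
#'   ids per hemisphere.
#' @return an object of class `parcellation_scheme`.
#' @export
parcellation_scheme <- function(thalamus, lingual, pericalcarine,
                                lateral_occipital, gray_matter) {
  roles <- list(thalamus = thalamus, lingual = lingual,
                pericalcarine = pericalcarine,
                lateral_occipital = lateral_occipital,
                gray_matter = gray_matter)
  for (r in names(roles)) {
    v <- roles[[r]]
    if (!all(c("left", "right") %in% names(unlist(as.list(v)))) &&
        !all(c("left", "right") %in% names(v)))
      stop("role `", r, "` must map both hemispheres (names left/right)")
  }
  ids <- unlist(roles, use.names = FALSE)
  if (anyDuplicated(ids)) stop("label ids must be disjoint across roles")
  structure(roles, class = "parcellation_scheme")
}

scheme_ids <- function(scheme, role, hemisphere) {
  v <- scheme[[role]]
  if (is.list(v)) v[[hemisphere]] else unname(v[hemisphere])
}

other_hemisphere <- function(h) if (h == "left") "right" else "left"

#' Seed region: posterior half of the thalamus
#'
#' The lateral geniculate nucleus is not delineated by standard
#' parcellations; as a surrogate, the thalamus label is split at the
#' anterior-posterior coordinate of its (unweighted) voxel centroid and the
#' posterior half retained as the tractography seed. "Posterior" is resolved
#' in world RAS coordinates (smaller Y), so oblique affines behave
#' correctly; voxels exactly at the centroid plane go to the anterior half
#' (strict inequality).
#'
#' @param parcellation an integer-label `vol3d`.
#' @param scheme a [parcellation_scheme()].
#' @param hemisphere `"left"` or `"right"`.
#' @return a binary `vol3d` mask.
#' @export
lgn_seed_from_thalamus <- function(parcellation, scheme,
                                   hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  ids <- scheme_ids(scheme, "thalamus", hemisphere)
  hit <- array(parcellation$data %in% ids, dim(parcellation$data))
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("thalamus label is empty for ", hemisphere)
  w <- vox_to_world(parcellation$affine, idx)
  com_y <- mean(w[, 2])
  keep <- w[, 2] < com_y
  if (!any(keep) || all(keep))
    stop("degenerate thalamus: all voxels in one anterior-posterior plane")
  m <- array(0, dim(parcellation$data))
  m[idx[keep, , drop = FALSE]] <- 1
  vol3d(m, parcellation$affine)
}

#' Composite occipital target region
#'
#' Union of the lingual, pericalcarine and lateral occipital labels of one
#' hemisphere. An empty constituent label raises a warning and the union of
#' the remaining labels is returned; all three empty is an error.
#'
#' @inheritParams lgn_seed_from_thalamus
#' @return a binary `vol3d` mask.
#' @export
composite_occipital_roi <- function(parcellation, scheme,
                                    hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  roles <- c("lingual", "pericalcarine", "lateral_occipital")
  m <- array(0, dim(parcellation$data))
  any_found <- FALSE
  for (r in roles) {
    ids <- scheme_ids(scheme, r, hemisphere)
    hit <- parcellation$data %in% ids
    if (!any(hit)) {
      warning("label `", r, "` is empty for ", hemisphere,
              "; proceeding without it")
    } else {
      m[hit] <- 1
      any_found <- TRUE
    }
  }
  if (!any_found) stop("all occipital labels empty for ", hemisphere)
  vol3d(m, parcellation$affine)
}

#' Exclusion regions: contralateral grey matter plus drawn planes
#'
#' Union of the contralateral hemisphere's grey-matter labels and any
#' user-specified axis-aligned half-spaces or slabs in world coordinates —
#' the reproducible counterpart of the hand-drawn sagittal/axial/coronal
#' exclusion ROIs used to remove lateral, callosal and brainstem
#' contributions.
#'
#' Each element of `planes` is a list with `axis` (`"x"`, `"y"` or `"z"`)
#' and either `coord` + `side` (`"below"`/`"above"`, half-space of world
#' coordinates strictly `<` / `>` `coord`) or `min` + `max` (slab,
#' inclusive).
#'
#' @inheritParams lgn_seed_from_thalamus
#' @param hemisphere the tract's hemisphere; exclusion uses the other side.
#' @param planes list of plane/slab specifications (possibly empty).
#' @return a binary `vol3d` mask.
#' @export
exclusion_regions <- function(parcellation, scheme,
                              hemisphere = c("left", "right"),
                              planes = list()) {
  hemisphere <- match.arg(hemisphere)
  contra <- other_hemisphere(hemisphere)
  ids <- scheme_ids(scheme, "gray_matter", contra)
  m <- (parcellation$data %in% ids) * 1
  dim(m) <- dim(parcellation$data)
  if (length(planes)) {
    world <- grid_world(vol3d(array(0, dim(parcellation$data)),
                              parcellation$affine))
    bbox <- grid_bbox(vol3d(array(0, dim(parcellation$data)),
                            parcellation$affine))
    for (pl in planes) {
      ax <- match(pl$axis, c("x", "y", "z"))
      if (is.na(ax)) stop("plane axis must be x, y or z")
      co <- world[, ax]
      if (!is.null(pl$coord)) {
        if (pl$coord < bbox[1, ax] || pl$coord > bbox[2, ax])
          stop("plane coordinate ", pl$coord, " lies outside the grid")
        hit <- if (identical(pl$side, "below")) co < pl$coord
               else if (identical(pl$side, "above")) co > pl$coord
               else stop("plane side must be 'below' or 'above'")
      } else {
        if (pl$max < bbox[1, ax] || pl$min > bbox[2, ax])
          stop("slab [", pl$min, ", ", pl$max, "] lies outside the grid")
        hit <- co >= pl$min & co <= pl$max
      }
      m[hit] <- 1
    }
  }
  vol3d(m, parcellation$affine)
}
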