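#' Augmentation settings
#'
#' Bundles the knobs of the geometric augmentation scheme.  Defaults reflect
#' the injury-focused study conditions: rotations up to 90 degrees, and peak
#' resultant velocities scaled into the band above the median concussive value
#' of 21.9 rad/s and below 40 rad/s.
#'
#' @param n_batches Number of augmentation batches; each batch contributes
#'   6 permuted, independently rotated/scaled copies of every base impact.
#' @param max_rotation_deg Upper bound of the random rotation angle (degrees).
#' @param v_min,v_max Open scaling band for the peak resultant velocity
#'   (rad/s).
#' @param apply_conjugate Replace motions whose post-rotation axis falls
#'   outside the sampled half-space (`|theta| > 90` degrees) by their
#'   mid-sagittal mirror image, which has the conjugate rotation axis.
#' @param seed Optional integer seed making [augment_dataset()] reproducible.
#'
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(n_batches = 2, max_rotation_deg = 90,
                                v_min = 21.9, v_max = 40,
                                apply_conjugate = TRUE, seed = NULL) {
  stopifnot(n_batches >= 1, v_min > 0, v_min < v_max,
            max_rotation_deg > 0, max_rotation_deg <= 180)
  structure(
    list(n_batches = as.integer(n_batches),
         max_rotation_deg = max_rotation_deg,
         v_min = v_min, v_max = v_max,
         apply_conjugate = isTRUE(apply_conjugate),
         seed = seed),
    class = "augmentation_config"
  )
}

# channel orderings, in the fixed order used throughout
PERMUTATIONS <- list(
  xyz = c(1L, 2L, 3L), xzy = c(1L, 3L, 2L), yxz = c(2L, 1L, 3L),
  yzx = c(2L, 3L, 1L), zxy = c(3L, 1L, 2L), zyx = c(3L, 2L, 1L)
)

#' Permute the velocity components of each impact
#'
#' Builds the 6 (= 3!) channel orderings `xyz`, `xzy`, `yxz`, `yzx`, `zxy`,
#' `zyx` of every impact, in that fixed order.  `impact_id` is suffixed with
#' the ordering, e.g. `"imp1_xzy"`.
#'
#' @param profiles Profile tibble.
#' @return Profile tibble with six permuted impacts per input impact.
#' @export
permute_components <- function(profiles) {
  split <- prof_split(profiles)
  dt <- prof_dt(profiles)
  ids <- character(0); mats <- list()
  for (i in seq_along(split$ids)) {
    for (pn in names(PERMUTATIONS)) {
      ids <- c(ids, paste0(split$ids[i], "_", pn))
      mats[[length(mats) + 1]] <- split$mats[[i]][PERMUTATIONS[[pn]], , drop = FALSE]
    }
  }
  prof_bind(ids, mats, dt)
}

# Rodrigues rotation matrix for axis u (any nonzero 3-vector), angle in radians
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) * cos(angle) + sin(angle) * K + (1 - cos(angle)) * tcrossprod(u)
}

# one random rotation: axis uniform on the sphere, angle uniform in [0, max]
draw_rotation <- function(max_angle_deg) {
  axis <- stats::rnorm(3)
  while (sum(axis^2) < 1e-12) axis <- stats::rnorm(3)
  angle <- stats::runif(1, 0, max_angle_deg * pi / 180)
  list(axis = axis / sqrt(sum(axis^2)), angle_deg = angle * 180 / pi,
       R = rotation_matrix(axis, angle))
}

#' Rigidly rotate each impact about a random axis
#'
#' Every 3-vector sample of an impact is premultiplied by one rotation matrix
#' whose axis is uniform on the unit sphere (through the head center of
#' gravity) and whose angle is uniform in `[0, max_angle]` degrees.  The
#' resultant magnitude at every sample is preserved exactly (orthogonality).
#' One independent rotation is drawn per impact from the current RNG state;
#' seed with [set.seed()] or use [augment_dataset()] for managed seeding.
#'
#' @param profiles Profile tibble.
#' @param max_angle Maximum rotation angle in degrees, in (0, 180].
#' @return Rotated profile tibble (same ids, same times).
#' @export
random_rotation <- function(profiles, max_angle = 90) {
  stopifnot(max_angle > 0, max_angle <= 180)
  split <- prof_split(profiles)
  dt <- prof_dt(profiles)
  mats <- lapply(split$mats, function(m) draw_rotation(max_angle)$R %*% m)
  prof_bind(split$ids, mats, dt)
}

#' Rotation axis at peak resultant velocity
#'
#' Returns the azimuth/elevation parameterization of the unit angular-velocity
#' direction at the peak-resultant sample of each impact: `theta` (degrees in
#' (-180, 180], measured in the x--y plane from +x toward +y) and `alpha`
#' (degrees in \[-90, 90\], from the x--y plane toward +z), so that the unit
#' axis is `(cos(a) cos(t), cos(a) sin(t), sin(a))`.
#'
#' @param profiles Profile tibble; every impact must have a nonzero peak.
#' @return Tibble with `impact_id`, `theta`, `alpha` (degrees).
#' @export
rotation_axis_at_peak <- function(profiles) {
  split <- prof_split(profiles)
  purrr::map2_dfr(split$ids, seq_along(split$ids), function(id, i) {
    m <- split$mats[[i]]
    r <- colnorms(m)
    k <- which.max(r)
    if (r[k] <= 0) {
      abort(paste0("impact '", id, "': zero peak magnitude, rotation axis undefined"))
    }
    u <- m[, k] / r[k]
    tibble::tibble(
      impact_id = id,
      theta = atan2(u[2], u[1]) * 180 / pi,
      alpha = asin(max(-1, min(1, u[3]))) * 180 / pi
    )
  })
}

#' Conjugate rotation axis
#'
#' Maps an axis `(theta, alpha)` to its conjugate `(180 - theta, -alpha)`
#' (degrees, azimuth wrapped into (-180, 180]).  By the head's mid-sagittal
#' symmetry, rotation about the conjugate axis produces the mirrored strain
#' field, with identical scalar strain summaries; axes outside the sampled
#' half-space `|theta| <= 90` are therefore redundant and folded back in.
#'
#' @param theta,alpha Numeric vectors of azimuth/elevation angles (degrees).
#' @return Tibble with wrapped `theta` and negated `alpha`.
#' @export
#' @examples
#' conjugate_axis(120, 30)  # theta 60, alpha -30
conjugate_axis <- function(theta, alpha) {
  th <- 180 - theta
  th <- ((th + 180) %% 360) - 180          # into [-180, 180)
  th[th == -180] <- 180                    # ... then (-180, 180]
  tibble::tibble(theta = th, alpha = -alpha)
}

#' Mirror an impact through the mid-sagittal plane
#'
#' Angular velocity is a pseudovector: reflecting the motion through the
#' mid-sagittal plane (normal along y) negates the `wx` and `wz` components
#' and keeps `wy`.  The rotation axis at peak of the mirrored impact is
#' exactly the [conjugate_axis()] of the input's axis, and the resultant time
#' series is unchanged.
#'
#' @param profiles Profile tibble.
#' @return Mirrored profile tibble.
#' @export
mirror_profile <- function(profiles) {
  profiles$wx <- -profiles$wx
  profiles$wz <- -profiles$wz
  profiles
}

#' Scale impacts into a target peak-velocity band
#'
#' Multiplies each impact by one scalar so its peak resultant velocity equals
#' a target drawn uniformly from the open interval `(v_min, v_max)`.  The
#' waveform shape (all inter-sample ratios) is preserved.  One draw per
#' impact from the current RNG state.
#'
#' @param profiles Profile tibble; zero-peak impacts are an error.
#' @param v_min,v_max Band bounds in rad/s.
#' @return Scaled profile tibble.
#' @export
scale_magnitude <- function(profiles, v_min = 21.9, v_max = 40) {
  stopifnot(v_min > 0, v_min < v_max)
  split <- prof_split(profiles)
  dt <- prof_dt(profiles)
  mats <- purrr::map2(split$ids, split$mats, function(id, m) {
    pk <- max(colnorms(m))
    if (pk <= 0) abort(paste0("impact '", id, "': zero peak, cannot scale"))
    m * (stats::runif(1, v_min, v_max) / pk)
  })
  prof_bind(split$ids, mats, dt)
}

#' Augment a base impact dataset
#'
#' Runs the full augmentation scheme: for each batch, each base impact is
#' expanded into its 6 channel permutations; each permuted copy is rigidly
#' rotated about an independent random axis; if the post-rotation axis falls
#' outside the sampled half-space (`|theta| > 90` degrees) the motion is
#' replaced by its mid-sagittal mirror image (conjugate axis); finally each
#' copy is scaled so its peak resultant lies strictly inside
#' `(v_min, v_max)`.  The output has `length(ids) * 6 * n_batches` impacts,
#' ids of the form `<parent>_b<batch>_<perm>`, and (with `apply_conjugate`)
#' every output axis satisfies `|theta| <= 90`.
#'
#' @param profiles Profile tibble of base impacts.
#' @param config An [augmentation_config()].  When `config$seed` is set the
#'   run is fully reproducible.
#' @return Augmented profile tibble.  The per-impact provenance (parent id,
#'   batch, permutation, rotation axis/angle, mirroring flag, scale factor,
#'   final peak) is attached as the `"provenance"` attribute; retrieve it with
#'   [augmentation_provenance()].
#' @export
#' @examples
#' base <- generate_profiles(profile_gen_params(n_impacts = 2, seed = 1))
#' aug <- augment_dataset(base, augmentation_config(n_batches = 2, seed = 1))
#' dplyr::n_distinct(aug$impact_id)  # 2 * 6 * 2 = 24
augment_dataset <- function(profiles, config = augmentation_config()) {
  stopifnot(inherits(config, "augmentation_config"))
  split <- prof_split(profiles)
  if (length(split$ids) == 0) abort("augment_dataset: empty input")
  dt <- prof_dt(profiles)
  if (!is.null(config$seed)) withr::local_seed(config$seed)

  n_out <- length(split$ids) * 6L * config$n_batches
  ids <- character(n_out); mats <- vector("list", n_out)
  prov <- vector("list", n_out)
  j <- 0L
  for (b in seq_len(config$n_batches)) {
    for (i in seq_along(split$ids)) {
      for (pn in names(PERMUTATIONS)) {
        j <- j + 1L
        m <- split$mats[[i]][PERMUTATIONS[[pn]], , drop = FALSE]
        rot <- draw_rotation(config$max_rotation_deg)
        m <- rot$R %*% m
        r <- colnorms(m)
        k <- which.max(r)
        if (r[k] <= 0) {
          abort(paste0("impact '", split$ids[i], "': zero peak, cannot augment"))
        }
        mirrored <- FALSE
        if (config$apply_conjugate) {
          theta <- atan2(m[2, k], m[1, k]) * 180 / pi
          if (abs(theta) > 90) {
            m <- m * c(-1, 1, -1)
            mirrored <- TRUE
          }
        }
        target <- stats::runif(1, config$v_min, config$v_max)
        s <- target / r[k]
        m <- m * s
        id <- paste0(split$ids[i], "_b", b, "_", pn)
        ids[j] <- id
        mats[[j]] <- m
        prov[[j]] <- tibble::tibble(
          impact_id = id, parent_id = split$ids[i], batch = b,
          permutation = pn,
          rot_axis_x = rot$axis[1], rot_axis_y = rot$axis[2],
          rot_axis_z = rot$axis[3], rot_angle_deg = rot$angle_deg,
          mirrored = mirrored, scale_factor = s, peak_resultant = target
        )
      }
    }
  }
  out <- prof_bind(ids, mats, dt)
  attr(out, "provenance") <- dplyr::bind_rows(prov)
  out
}

#' Provenance of an augmented dataset
#'
#' @param profiles The result of [augment_dataset()].
#' @return The provenance tibble recorded during augmentation.
#' @export
augmentation_provenance <- function(profiles) {
  prov <- attr(profiles, "provenance")
  if (is.null(prov)) abort("no provenance attribute; was this augmented with augment_dataset()?")
  prov
}
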