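#' Read rotational-velocity profiles from CSV
#'
#' Reads a long-format table of head rotational velocity samples and returns a
#' validated, uniformly sampled profile tibble.  The expected columns are
#' `impact_id`, `time_ms`, and the three angular-velocity components `wx`,
#' `wy`, `wz` in rad/s (x anterior, y left, z superior).  Time must be
#' strictly increasing within each impact; non-uniformly sampled impacts are
#' resampled to a uniform 1 ms grid by linear interpolation, the resolution
#' the downstream encoder expects.
#'
#' @param path Path to a CSV file.
#' @param dt_ms Target sampling interval in ms after resampling (default 1).
#'
#' @return A tibble with columns `impact_id`, `time_ms`, `wx`, `wy`, `wz`,
#'   one row per sample, impacts in order of first appearance, each impact
#'   starting at `time_ms = 0`.
#' @export
#' @seealso [write_profiles()], [peak_resultant()], [generate_profiles()]
read_profiles <- function(path, dt_ms = 1) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    impact_id = readr::col_character(),
    .default = readr::col_double()
  ))
  required <- c("impact_id", "time_ms", "wx", "wy", "wz")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("profile CSV is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  ids <- unique(raw$impact_id)
  pieces <- lapply(ids, function(id) {
    d <- raw[raw$impact_id == id, , drop = FALSE]
    if (any(!is.finite(d$time_ms)) || any(!is.finite(as.matrix(d[c("wx", "wy", "wz")])))) {
      abort(paste0("impact '", id, "': non-finite values"))
    }
    if (nrow(d) < 2) {
      abort(paste0("impact '", id, "': needs at least 2 samples"))
    }
    if (any(diff(d$time_ms) <= 0)) {
      abort(paste0("impact '", id, "': time_ms must be strictly increasing ",
                   "(duplicate or out-of-order timestamps)"))
    }
    span <- d$time_ms[nrow(d)] - d$time_ms[1]
    if (span > 200) {
      abort(paste0("impact '", id, "': span ", format(span),
                   " ms exceeds the 200 ms encoding window"))
    }
    tt <- seq(0, span, by = dt_ms)
    rel <- d$time_ms - d$time_ms[1]
    tibble::tibble(
      impact_id = id,
      time_ms = tt,
      wx = stats::approx(rel, d$wx, xout = tt)$y,
      wy = stats::approx(rel, d$wy, xout = tt)$y,
      wz = stats::approx(rel, d$wz, xout = tt)$y
    )
  })
  out <- dplyr::bind_rows(pieces)
  validate_profiles(out)
  out
}

#' Write rotational-velocity profiles to CSV
#'
#' @param profiles Profile tibble (`impact_id`, `time_ms`, `wx`, `wy`, `wz`).
#' @param path Output path.  UTF-8, `.` decimal separator.
#' @return `profiles`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  validate_profiles(profiles)
  readr::write_csv(profiles[, c("impact_id", "time_ms", "wx", "wy", "wz")], path)
  invisible(profiles)
}

#' Validate a profile tibble
#'
#' Checks the invariants every profile operation relies on: required columns,
#' finite values, at least two samples per impact, a uniform positive sampling
#' interval, and a span of at most 200 ms (the encoder's window).
#'
#' @param profiles Profile tibble.
#' @return `profiles`, invisibly; errors describe the offending impact.
#' @export
validate_profiles <- function(profiles) {
  required <- c("impact_id", "time_ms", "wx", "wy", "wz")
  missing <- setdiff(required, names(profiles))
  if (length(missing) > 0) {
    abort(paste0("profiles are missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  split <- prof_split(profiles)
  for (i in seq_along(split$ids)) {
    id <- split$ids[i]
    m <- split$mats[[i]]
    if (ncol(m) < 2) abort(paste0("impact '", id, "': needs at least 2 samples"))
    if (any(!is.finite(m))) abort(paste0("impact '", id, "': non-finite samples"))
    dts <- diff(split$times[[i]])
    if (any(dts <= 0)) {
      abort(paste0("impact '", id, "': time_ms must be strictly increasing"))
    }
    if (max(abs(dts - dts[1])) > 1e-9) {
      abort(paste0("impact '", id, "': non-uniform sampling; use read_profiles() ",
                   "to resample"))
    }
    if ((ncol(m) - 1) * dts[1] > 200 + 1e-9) {
      abort(paste0("impact '", id, "': span exceeds the 200 ms encoding window"))
    }
  }
  invisible(profiles)
}

#' Append the resultant angular-velocity magnitude
#'
#' Adds a `w_res` column: the sample-wise Euclidean norm of the three
#' components.  The resultant is invariant under any rigid rotation of the
#' motion, which is what makes the augmentation scheme magnitude-preserving.
#'
#' @param profiles Profile tibble.
#' @return The input tibble with an extra `w_res` column (rad/s).
#' @export
#' @examples
#' p <- tibble::tibble(impact_id = "a", time_ms = 0:1,
#'                     wx = c(3, 0), wy = c(4, 0), wz = c(0, 0))
#' add_resultant(p)$w_res  # 5, 0
add_resultant <- function(profiles) {
  profiles$w_res <- sqrt(profiles$wx^2 + profiles$wy^2 + profiles$wz^2)
  profiles
}

#' Peak resultant velocity per impact
#'
#' Finds, for each impact, the sample at which the resultant angular velocity
#' is largest.  Ties break to the earliest sample, so the result is
#' deterministic and independent of row order within a tie.
#'
#' @param profiles Profile tibble.
#' @return A tibble with one row per impact: `impact_id`, `peak_index`
#'   (1-based sample index), `peak_time_ms`, `peak_magnitude` (rad/s).
#' @export
peak_resultant <- function(profiles) {
  split <- prof_split(profiles)
  purrr::map2_dfr(split$ids, seq_along(split$ids), function(id, i) {
    r <- colnorms(split$mats[[i]])
    k <- which.max(r)  # which.max takes the earliest maximum
    tibble::tibble(
      impact_id = id,
      peak_index = k,
      peak_time_ms = split$times[[i]][k] - split$times[[i]][1],
      peak_magnitude = r[k]
    )
  })
}

## ---- internal representation -------------------------------------------
## Profiles travel as long tibbles at the API surface; internally each impact
## is a 3 x T matrix (rows x, y, z).  Order of first appearance is preserved
## everywhere -- no group_by, which would sort ids.

colnorms <- function(m) sqrt(colSums(m^2))

prof_split <- function(profiles) {
  ids <- unique(profiles$impact_id)
  idx <- split(seq_len(nrow(profiles)), factor(profiles$impact_id, levels = ids))
  mats <- lapply(idx, function(i) {
    rbind(profiles$wx[i], profiles$wy[i], profiles$wz[i])
  })
  times <- lapply(idx, function(i) profiles$time_ms[i])
  list(ids = ids, mats = unname(mats), times = unname(times))
}

prof_bind <- function(ids, mats, dt = 1) {
  dplyr::bind_rows(purrr::map2(ids, mats, function(id, m) {
    tibble::tibble(
      impact_id = id,
      time_ms = (seq_len(ncol(m)) - 1) * dt,
      wx = m[1, ], wy = m[2, ], wz = m[3, ]
    )
  }))
}

prof_dt <- function(profiles) {
  split <- prof_split(profiles)
  dts <- vapply(split$times, function(t) t[2] - t[1], 0)
  dts[1]
}
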