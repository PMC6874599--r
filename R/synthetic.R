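#' Synthetic impact generator settings
#'
#' Parameters of the impact-like pulse generator.  Defaults emulate measured
#' contact-sport head impacts: rotational pulses lasting tens of
#' milliseconds, peak resultant velocities of 5--40 rad/s, and an occasional
#' velocity reversal (deceleration followed by counter-rotation), the shape
#' feature that distinguishes on-field recordings from idealized laboratory
#' reconstructions.
#'
#' @param n_impacts Number of impacts to generate.
#' @param duration_range Pulse duration range in ms.
#' @param peak_range Peak resultant velocity range in rad/s.
#' @param reversal_prob Probability that a pulse is followed by a reversed
#'   (counter-rotating) pulse.
#' @param reversal_fraction Amplitude of the reversed pulse relative to the
#'   main pulse, in (0, 1).
#' @param seed Optional integer seed.
#' @return An object of class `profile_gen_params`.
#' @export
profile_gen_params <- function(n_impacts = 110, duration_range = c(10, 60),
                               peak_range = c(5, 40), reversal_prob = 0.3,
                               reversal_fraction = 0.4, seed = NULL) {
  stopifnot(n_impacts >= 1,
            duration_range[1] > 0, duration_range[1] < duration_range[2],
            peak_range[1] > 0, peak_range[1] < peak_range[2],
            reversal_prob >= 0, reversal_prob <= 1,
            reversal_fraction > 0, reversal_fraction < 1)
  structure(
    list(n_impacts = as.integer(n_impacts), duration_range = duration_range,
         peak_range = peak_range, reversal_prob = reversal_prob,
         reversal_fraction = reversal_fraction, seed = seed),
    class = "profile_gen_params"
  )
}

#' Generate synthetic impact-like velocity profiles
#'
#' Each impact is a raised-cosine-squared resultant pulse
#' `v(t) = A sin^2(pi t / T_d)` on `[0, T_d]` along one random unit
#' direction (uniform on the sphere), optionally followed by a
#' counter-rotating pulse of the same duration and amplitude
#' `reversal_fraction * A`, sampled at 1 ms.  The peak resultant of every
#' impact equals its drawn amplitude `A`.
#'
#' @param params A [profile_gen_params()].
#' @return Profile tibble with ids `imp001`, `imp002`, ...
#' @export
#' @examples
#' base <- generate_profiles(profile_gen_params(n_impacts = 5, seed = 1))
#' peak_resultant(base)
generate_profiles <- function(params = profile_gen_params()) {
  stopifnot(inherits(params, "profile_gen_params"))
  if (!is.null(params$seed)) withr::local_seed(params$seed)
  n <- params$n_impacts
  ids <- sprintf("imp%03d", seq_len(n))
  mats <- vector("list", n)
  for (i in seq_len(n)) {
    Td <- stats::runif(1, params$duration_range[1], params$duration_range[2])
    A <- stats::runif(1, params$peak_range[1], params$peak_range[2])
    u <- stats::rnorm(3)
    while (sum(u^2) < 1e-12) u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    t1 <- seq(0, floor(Td))
    v <- A * sin(pi * t1 / Td)^2
    v <- v * (A / max(v))  # sampled peak equals A exactly
    if (stats::runif(1) < params$reversal_prob) {
      t2 <- seq(1, floor(Td))
      vr <- params$reversal_fraction * A * sin(pi * t2 / Td)^2
      v <- c(v, -vr)
    }
    mats[[i]] <- outer(u, v)
  }
  prof_bind(ids, mats, dt = 1)
}

#' Strain-oracle settings
#'
#' Parameters of the closed-form strain oracle that stands in for
#' finite-element simulation when exercising the pipeline.  The oracle is a
#' smooth, saturating (Hill-type) function of peak resultant velocity,
#' modulated by the rotation direction at peak and by the waveform's total
#' variation, plus optional Gaussian noise.  It reproduces the two structural
#' properties the protocol relies on -- mid-sagittal mirror symmetry and
#' monotonicity in impact severity -- but its constants are artifact choices
#' with no biofidelity claim.
#'
#' @param eps_max Named numeric: strain ceiling per measure.
#' @param v50 Peak velocity (rad/s) at half-saturation.
#' @param hill_n Hill exponent (nonlinearity of the severity response).
#' @param direction_weights Named list of `(a_x, a_y, a_z)` per measure;
#'   different weights make the three regression tasks genuinely distinct.
#'   Only squared direction cosines enter, which is what makes the oracle
#'   exactly mirror-symmetric.
#' @param shape_gain Gain `b` on the total-variation shape term.
#' @param noise_sd Standard deviation of additive Gaussian strain noise;
#'   0 makes the oracle deterministic.
#' @param seed Optional integer seed for the noise.
#' @return An object of class `oracle_params`.
#' @export
oracle_params <- function(eps_max = c(MPS_WB_95 = 0.45, MPS_CC_95 = 0.35,
                                      FS_CC_95 = 0.25),
                          v50 = 30, hill_n = 3,
                          direction_weights = list(
                            MPS_WB_95 = c(0.2, 0.4, 0.3),
                            MPS_CC_95 = c(0.5, 0.1, 0.4),
                            FS_CC_95 = c(0.1, 0.6, 0.2)),
                          shape_gain = 0.3, noise_sd = 0.005, seed = NULL) {
  stopifnot(all(eps_max > 0), v50 > 0, hill_n >= 1, noise_sd >= 0)
  structure(
    list(eps_max = eps_max, v50 = v50, hill_n = hill_n,
         direction_weights = direction_weights, shape_gain = shape_gain,
         noise_sd = noise_sd, seed = seed),
    class = "oracle_params"
  )
}

#' Closed-form strain oracle
#'
#' Computes, for each impact, the surrogate strain
#' `eps = eps_max * H(p) * D(u) * S (+ noise)` where `p` is the peak
#' resultant velocity, `H(p) = p^n / (p^n + v50^n)` is a Hill-type
#' saturation, `u` is the unit velocity direction at peak with
#' `D(u) = (1 + a_x u_x^2 + a_y u_y^2 + a_z u_z^2) / (1 + max(a))`, and
#' `S = 1 + b * min(1, TV / (2 p))` with `TV` the total variation of the
#' resultant time series (motions are taken to start and end at rest).
#' Results are clamped at zero; an all-zero motion has zero strain.
#'
#' @param profiles Profile tibble.
#' @param measure One of [strain_measures()], or `"all"` for all three.
#' @param params An [oracle_params()].
#' @return Tibble with `impact_id` and one column per requested measure.
#' @export
oracle_strain <- function(profiles, measure = "all", params = oracle_params()) {
  stopifnot(inherits(params, "oracle_params"))
  measures <- if (identical(measure, "all")) strain_measures() else
    match.arg(measure, strain_measures(), several.ok = TRUE)
  if (!is.null(params$seed)) withr::local_seed(params$seed)
  split <- prof_split(profiles)
  out <- tibble::tibble(impact_id = split$ids)
  base <- lapply(seq_along(split$ids), function(i) {
    m <- split$mats[[i]]
    r <- colnorms(m)
    k <- which.max(r)
    p <- r[k]
    if (p == 0) return(list(p = 0, u = c(0, 0, 0), S = 0))
    tv <- sum(abs(diff(c(0, r, 0))))  # from rest, back to rest
    list(p = p, u = m[, k] / p, S = 1 + params$shape_gain * min(1, tv / (2 * p)))
  })
  for (ms in measures) {
    a <- params$direction_weights[[ms]]
    eps <- vapply(base, function(bb) {
      if (bb$p == 0) return(0)
      H <- bb$p^params$hill_n / (bb$p^params$hill_n + params$v50^params$hill_n)
      D <- (1 + sum(a * bb$u^2)) / (1 + max(a))
      params$eps_max[[ms]] * H * D * bb$S
    }, 0)
    if (params$noise_sd > 0) {
      eps <- eps + stats::rnorm(length(eps), 0, params$noise_sd)
    }
    out[[ms]] <- pmax(eps, 0)
  }
  out
}

#' Generate a labelled, encoded dataset end to end
#'
#' Chains the full data pipeline: generate base impacts, augment them, label
#' every augmented impact with the strain oracle (labels are recomputed after
#' augmentation, mimicking per-impact simulation of each augmented motion),
#' and encode the result for the network.
#'
#' @param gen A [profile_gen_params()].
#' @param oracle An [oracle_params()].
#' @param aug An [augmentation_config()].
#' @return A labelled `strain_input` (labels for all three measures).
#' @export
#' @examples
#' ds <- make_dataset(profile_gen_params(n_impacts = 4, seed = 1),
#'                    oracle_params(noise_sd = 0),
#'                    augmentation_config(n_batches = 1, seed = 2))
#' length(ds)  # 4 * 6 * 1 = 24
make_dataset <- function(gen = profile_gen_params(),
                         oracle = oracle_params(),
                         aug = augmentation_config()) {
  base <- generate_profiles(gen)
  augmented <- augment_dataset(base, aug)
  labels <- oracle_strain(augmented, "all", oracle)
  encode_profiles(augmented, labels = labels)
}
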