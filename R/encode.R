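#' Encode velocity profiles as fixed-size network inputs
#'
#' Reformats each impact into the 3 x 201 matrix the network consumes: 1 ms
#' resolution spanning 0--200 ms, with all three components synchronously
#' shifted so the resultant peak sits exactly at 100 ms (column 101).  The
#' borders are filled by replicating the first/last recorded sample of each
#' channel, i.e. the padding has exactly zero angular acceleration, and the
#' inter-channel timing of the recording is untouched.  Peak strains do not
#' depend on when the motion occurs, so pinning the peak removes nuisance
#' temporal variation from the learning problem.
#'
#' A profile whose peak placement would push recorded samples outside the
#' 0--200 ms window cannot be encoded and is an error (default) or dropped
#' with a warning (`on_error = "drop"`).
#'
#' @param profiles Profile tibble sampled at 1 ms (see [read_profiles()]).
#' @param labels Optional tibble of per-impact labels with an `impact_id`
#'   column (e.g. from [oracle_strain()]); carried into the result, aligned
#'   to the encoded impacts.
#' @param on_error `"abort"` (default) or `"drop"`: what to do with impacts
#'   that cannot be encoded.
#'
#' @return A `strain_input` object: list with `inputs` (N x 3 x 201 array,
#'   rad/s), `impact_id` (length-N character), `labels` (tibble or `NULL`)
#'   and `failures` (tibble of dropped impacts and reasons).
#' @export
#' @examples
#' base <- generate_profiles(profile_gen_params(n_impacts = 3, seed = 1))
#' enc <- encode_profiles(base)
#' dim(enc$inputs)  # 3 3 201
encode_profiles <- function(profiles, labels = NULL, on_error = c("abort", "drop")) {
  on_error <- match.arg(on_error)
  split <- prof_split(profiles)
  dts <- vapply(split$times, function(t) if (length(t) > 1) t[2] - t[1] else NA_real_, 0)
  ok <- logical(length(split$ids))
  reasons <- character(length(split$ids))
  enc <- vector("list", length(split$ids))
  for (i in seq_along(split$ids)) {
    res <- tryCatch({
      if (!isTRUE(abs(dts[i] - 1) < 1e-9)) {
        abort(paste0("impact '", split$ids[i],
                     "': sampling interval must be 1 ms for encoding"))
      }
      encode_matrix(split$mats[[i]], split$ids[i])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "abort") stop(res)
      ok[i] <- FALSE
      reasons[i] <- conditionMessage(res)
    } else {
      ok[i] <- TRUE
      enc[[i]] <- res
    }
  }
  kept <- which(ok)
  inputs <- array(0, c(length(kept), 3, 201))
  for (j in seq_along(kept)) inputs[j, , ] <- enc[[kept[j]]]
  failures <- tibble::tibble(impact_id = split$ids[!ok], reason = reasons[!ok])
  if (nrow(failures) > 0) {
    warn(paste0(nrow(failures), " impact(s) could not be encoded and were dropped"))
  }
  ids <- split$ids[kept]
  if (!is.null(labels)) {
    labels <- labels[match(ids, labels$impact_id), , drop = FALSE]
    if (anyNA(labels$impact_id)) abort("labels are missing some encoded impact_ids")
  }
  new_strain_input(inputs, ids, labels, failures)
}

# core single-impact encoder: 3 x T matrix -> 3 x 201, peak at column 101
encode_matrix <- function(m, id = "?") {
  T_ <- ncol(m)
  r <- colnorms(m)
  p <- which.max(r)
  off <- 101L - p
  if (off < 0 || off + T_ > 201L) {
    abort(paste0("impact '", id, "': cannot place peak at 100 ms without ",
                 "truncating samples (T=", T_, ", peak index ", p, ")"))
  }
  out <- matrix(0, 3, 201)
  if (off > 0) out[, seq_len(off)] <- m[, 1]
  out[, off + seq_len(T_)] <- m
  if (off + T_ < 201) out[, (off + T_ + 1):201] <- m[, T_]
  out
}

new_strain_input <- function(inputs, ids, labels = NULL,
                             failures = tibble::tibble(impact_id = character(0),
                                                       reason = character(0))) {
  structure(list(inputs = inputs, impact_id = ids, labels = labels,
                 failures = failures),
            class = "strain_input")
}

#' @export
print.strain_input <- function(x, ...) {
  cat("<strain_input> ", dim(x$inputs)[1], " impacts, 3 x ",
      dim(x$inputs)[3], " encoded samples\n", sep = "")
  if (!is.null(x$labels)) {
    cat("  labels: ", paste(setdiff(names(x$labels), "impact_id"),
                            collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$failures) > 0) cat("  dropped:", nrow(x$failures), "impact(s)\n")
  invisible(x)
}

#' Number of encoded impacts
#' @param x A `strain_input`.
#' @param ... Unused.
#' @export
length.strain_input <- function(x) dim(x$inputs)[1]

#' Peak resultant velocity of encoded inputs
#'
#' For encoded inputs the resultant peak sits at 100 ms by construction, so
#' the peak magnitude is read off directly.
#'
#' @param x A `strain_input`.
#' @return Numeric vector of peak resultant velocities (rad/s).
#' @export
encoded_peaks <- function(x) {
  stopifnot(inherits(x, "strain_input"))
  apply(x$inputs, 1, function(m) max(sqrt(colSums(m^2))))
}

#' Write/read an encoded dataset as a plain CSV container
#'
#' One row per impact: `impact_id`, any label columns, then the 603 flattened
#' input values (`v001` ... `v603`, channel-fastest).  A plain-text container
#' keeps encoded batches portable and diffable.
#'
#' @param x A `strain_input`.
#' @param path CSV path.
#' @return `write_encoded`: `x` invisibly.  `read_encoded`: a `strain_input`.
#' @export
write_encoded <- function(x, path) {
  stopifnot(inherits(x, "strain_input"))
  n <- dim(x$inputs)[1]
  flat <- matrix(0, n, 603)
  for (i in seq_len(n)) flat[i, ] <- as.vector(x$inputs[i, , ])
  colnames(flat) <- sprintf("v%03d", 1:603)
  df <- tibble::tibble(impact_id = x$impact_id)
  if (!is.null(x$labels)) {
    df <- dplyr::bind_cols(df, x$labels[, setdiff(names(x$labels), "impact_id"),
                                        drop = FALSE])
  }
  readr::write_csv(dplyr::bind_cols(df, tibble::as_tibble(flat)), path)
  invisible(x)
}

#' @rdname write_encoded
#' @export
read_encoded <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    impact_id = readr::col_character(), .default = readr::col_double()
  ))
  vcols <- grep("^v[0-9]{3}$", names(df), value = TRUE)
  stopifnot(length(vcols) == 603)
  labcols <- setdiff(names(df), c("impact_id", vcols))
  n <- nrow(df)
  inputs <- array(0, c(n, 3, 201))
  flat <- as.matrix(df[, vcols])
  for (i in seq_len(n)) inputs[i, , ] <- matrix(flat[i, ], 3, 201)
  labels <- NULL
  if (length(labcols) > 0) {
    labels <- dplyr::bind_cols(tibble::tibble(impact_id = df$impact_id),
                               df[, labcols, drop = FALSE])
  }
  new_strain_input(inputs, df$impact_id, labels)
}
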