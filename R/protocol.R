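#' Multi-delay pCASL acquisition protocol
#'
#' Describes the labelling and readout timing of a multi-delay
#' pseudo-continuous ASL acquisition with a 2D multi-slice readout:
#' label duration, the set of post-labelling delays (PLDs), the number
#' of repeats (averages) per PLD, and the per-slice readout increment.
#'
#' @param tau Label (bolus) duration in seconds.
#' @param plds Numeric vector of post-labelling delays in seconds,
#'   strictly increasing and positive.
#' @param n_repeats Number of repeats (averages) acquired per PLD.
#' @param slice_dt Readout time per slice in seconds; the effective PLD
#'   of slice `k` (0-based) is `plds + k * slice_dt`.
#' @param n_slices Number of slices in the 2D ascending readout.
#' @param tr Repetition time in seconds.
#'
#' @return An object of class `asl_protocol`.
#' @examples
#' asl_protocol()
#' @export
asl_protocol <- function(tau = 1.4,
                         plds = seq(0.25, 1.5, by = 0.25),
                         n_repeats = 8L,
                         slice_dt = 0.046,
                         n_slices = 24L,
                         tr = 4.1) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0)
  stopifnot(is.numeric(plds), length(plds) >= 1L, all(plds > 0))
  if (is.unsorted(plds, strictly = TRUE)) {
    stop("`plds` must be strictly increasing", call. = FALSE)
  }
  stopifnot(n_repeats >= 1L, slice_dt >= 0, n_slices >= 1L, tr > 0)
  structure(
    list(
      tau = tau, plds = as.numeric(plds),
      n_repeats = as.integer(n_repeats),
      slice_dt = slice_dt, n_slices = as.integer(n_slices), tr = tr
    ),
    class = "asl_protocol"
  )
}

#' @export
print.asl_protocol <- function(x, ...) {
  cat("<asl_protocol>\n")
  cat(sprintf("  label duration : %.3f s\n", x$tau))
  cat(sprintf("  PLDs           : %s s\n", paste(format(x$plds), collapse = ", ")))
  cat(sprintf("  repeats/PLD    : %d\n", x$n_repeats))
  cat(sprintf("  slices         : %d (%.0f ms/slice)\n", x$n_slices, 1000 * x$slice_dt))
  cat(sprintf("  TR             : %.2f s\n", x$tr))
  invisible(x)
}

#' Effective post-labelling delay of a slice
#'
#' In a 2D ascending readout each slice is acquired later than the
#' first, so its effective PLD grows linearly with slice position.
#'
#' @param protocol An [asl_protocol()].
#' @param pld_index 1-based index into `protocol$plds`.
#' @param slice_index 0-based slice position.
#' @return Effective PLD in seconds.
#' @examples
#' p <- asl_protocol()
#' effective_pld(p, 1, 10) # 0.25 + 10 * 0.046
#' @export
effective_pld <- function(protocol, pld_index, slice_index) {
  stopifnot(inherits(protocol, "asl_protocol"))
  if (any(pld_index < 1L) || any(pld_index > length(protocol$plds))) {
    stop(sprintf(
      "pld_index %s out of range [1, %d]",
      paste(pld_index[pld_index < 1L | pld_index > length(protocol$plds)],
            collapse = ", "),
      length(protocol$plds)
    ), call. = FALSE)
  }
  if (any(slice_index < 0L) || any(slice_index >= protocol$n_slices)) {
    stop(sprintf(
      "slice_index %s out of range [0, %d)",
      paste(slice_index[slice_index < 0L | slice_index >= protocol$n_slices],
            collapse = ", "),
      protocol$n_slices
    ), call. = FALSE)
  }
  protocol$plds[pld_index] + slice_index * protocol$slice_dt
}

#' Sampling times of the difference signal for one slice
#'
#' The difference signal is sampled at `tau + effective PLD` for each
#' PLD, i.e. measured from the start of labelling.
#'
#' @inheritParams effective_pld
#' @return Numeric vector, one time per PLD, in seconds.
#' @export
sample_times <- function(protocol, slice_index = 0L) {
  protocol$tau + effective_pld(protocol, seq_along(protocol$plds), slice_index)
}

#' Physiological and labelling constants
#'
#' Constants entering perfusion quantification: longitudinal relaxation
#' times of arterial blood and tissue, the blood-brain partition
#' coefficient of water, and the labelling (inversion) efficiency.
#' Defaults are consensus 3 T values with a labelling efficiency of
#' 0.85 for pCASL.
#'
#' @param t1_blood T1 of arterial blood in seconds.
#' @param t1_tissue T1 of tissue in seconds.
#' @param partition_lambda Blood-brain partition coefficient, ml/g.
#' @param label_efficiency_alpha Labelling efficiency in (0, 1].
#' @param perfusion_corrected_t1 If `TRUE`, the apparent tissue T1 used
#'   in the kinetic model includes the perfusion term,
#'   `1/T1' = 1/T1_tissue + f'/lambda`; by default the correction is
#'   omitted (negligible at physiological perfusion).
#' @return An object of class `asl_constants`.
#' @examples
#' asl_constants()
#' @export
asl_constants <- function(t1_blood = 1.65,
                          t1_tissue = 1.3,
                          partition_lambda = 0.9,
                          label_efficiency_alpha = 0.85,
                          perfusion_corrected_t1 = FALSE) {
  stopifnot(
    t1_blood > 0, t1_tissue > 0, partition_lambda > 0,
    label_efficiency_alpha > 0, label_efficiency_alpha <= 1
  )
  structure(
    list(
      t1_blood = t1_blood, t1_tissue = t1_tissue,
      partition_lambda = partition_lambda,
      label_efficiency_alpha = label_efficiency_alpha,
      perfusion_corrected_t1 = isTRUE(perfusion_corrected_t1)
    ),
    class = "asl_constants"
  )
}

#' @export
print.asl_constants <- function(x, ...) {
  cat("<asl_constants>\n")
  cat(sprintf("  T1 blood  : %.3f s\n", x$t1_blood))
  cat(sprintf("  T1 tissue : %.3f s%s\n", x$t1_tissue,
              if (x$perfusion_corrected_t1) " (perfusion-corrected apparent T1)" else ""))
  cat(sprintf("  lambda    : %.2f ml/g\n", x$partition_lambda))
  cat(sprintf("  alpha     : %.2f\n", x$label_efficiency_alpha))
  invisible(x)
}

# Apparent tissue T1 (optionally including the perfusion term).
# f is perfusion in ml/100g/min.
apparent_t1 <- function(consts, f = 0) {
  if (consts$perfusion_corrected_t1) {
    1 / (1 / consts$t1_tissue + (f / 6000) / consts$partition_lambda)
  } else {
    consts$t1_tissue
  }
}

#' Read or write a protocol as JSON
#'
#' The JSON layout uses explicit unit-suffixed keys:
#' `{"tau_s":1.4,"plds_s":[...],"repeats":8,"slice_dt_s":0.046,
#'   "n_slices":24,"tr_s":4.1}`.
#'
#' @param path File path.
#' @return `read_protocol()` returns an [asl_protocol()];
#'   `write_protocol()` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("tau_s", "plds_s", "repeats", "slice_dt_s", "n_slices", "tr_s")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("protocol JSON missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  asl_protocol(
    tau = x$tau_s, plds = x$plds_s, n_repeats = x$repeats,
    slice_dt = x$slice_dt_s, n_slices = x$n_slices, tr = x$tr_s
  )
}

#' @rdname read_protocol
#' @param protocol An [asl_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "asl_protocol"))
  jsonlite::write_json(
    list(
      tau_s = protocol$tau, plds_s = protocol$plds,
      repeats = protocol$n_repeats, slice_dt_s = protocol$slice_dt,
      n_slices = protocol$n_slices, tr_s = protocol$tr
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
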