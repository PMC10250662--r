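#' The four nested kinetic models
#'
#' The difference-signal forward model is the standard single-compartment
#' kinetic model for continuous labelling, optionally extended with
#' (i) bolus dispersion, modelled by convolving the arterial input with a
#' unit-area gamma-shaped kernel with sharpness `s` and time-to-peak `p`,
#' and (ii) a macrovascular (arterial) component scaled by the arterial
#' blood volume aBV. Crossing the two extensions gives four models:
#'
#' * `"noart_nodisp"` — tissue only, no dispersion (parameters f, ATT)
#' * `"art_nodisp"`   — + macrovascular component (f, ATT, aBV, ATTa)
#' * `"noart_disp"`   — + dispersion (f, ATT, log s, log s*p)
#' * `"art_disp"`     — both extensions (all six parameters)
#'
#' @param code Model code; one of the four above.
#' @return An object of class `asl_model` with fields `code`,
#'   `include_art`, `include_disp` and `parameter_names`.
#' @examples
#' asl_model("art_disp")
#' @export
asl_model <- function(code = c("noart_nodisp", "art_nodisp",
                               "noart_disp", "art_disp")) {
  valid <- c("noart_nodisp", "art_nodisp", "noart_disp", "art_disp")
  if (length(code) != 1L && !identical(code, valid)) {
    code <- code[1L]
  }
  code <- as.character(code)[1L]
  if (!code %in% valid) {
    stop(sprintf("unknown model code '%s'; valid codes: %s",
                 code, paste(valid, collapse = ", ")), call. = FALSE)
  }
  include_art <- grepl("^art", code)
  include_disp <- grepl("disp$", code) && !grepl("nodisp$", code)
  pars <- c("ftiss", "att")
  if (include_art) pars <- c(pars, "abv", "att_art")
  if (include_disp) pars <- c(pars, "log_s", "log_sp")
  structure(
    list(code = code, include_art = include_art,
         include_disp = include_disp, parameter_names = pars),
    class = "asl_model"
  )
}

#' @export
print.asl_model <- function(x, ...) {
  cat(sprintf("<asl_model> %s\n", x$code))
  cat(sprintf("  macrovascular component: %s\n",
              if (x$include_art) "yes (aBV, ATTa)" else "no"))
  cat(sprintf("  bolus dispersion       : %s\n",
              if (x$include_disp) "yes (gamma kernel, log s / log s*p)" else "no"))
  cat(sprintf("  parameters             : %s\n",
              paste(x$parameter_names, collapse = ", ")))
  invisible(x)
}

#' @rdname asl_model
#' @export
asl_model_codes <- function() {
  c("noart_nodisp", "art_nodisp", "noart_disp", "art_disp")
}

#' Per-voxel haemodynamic parameters
#'
#' Ground-truth or estimated physiology of one voxel: perfusion `f`
#' (ml/100g/min), tissue arterial transit time `att` (s), arterial
#' blood volume `abv` (% of voxel volume), arterial arrival time
#' `att_art` (s), and the dispersion kernel's sharpness `s` (1/s) and
#' time-to-peak `p` (s).
#'
#' @param f Perfusion, ml/100g/min.
#' @param att Tissue arterial transit time, seconds.
#' @param abv Arterial blood volume, percent of voxel volume.
#' @param att_art Arterial arrival time, seconds; at generation it must
#'   not exceed `att` (blood reaches the macrovasculature first).
#' @param s Dispersion sharpness, 1/s.
#' @param p Dispersion time-to-peak, seconds.
#' @param check If `TRUE` (default) enforce physical-range invariants;
#'   estimates from noisy fits may switch this off.
#' @return A named list of class `hemo_params`.
#' @examples
#' hemo_params(f = 60, att = 1.0)
#' @export
hemo_params <- function(f = 60, att = 1.0, abv = 0, att_art = 0.7,
                        s = exp(2), p = exp(-0.3) / exp(2), check = TRUE) {
  out <- list(f = f, att = att, abv = abv, att_art = att_art, s = s, p = p)
  if (isTRUE(check)) {
    if (f < 0) stop("f must be >= 0", call. = FALSE)
    if (abv < 0) stop("abv must be >= 0", call. = FALSE)
    if (att_art <= 0 || att_art > att) {
      stop("need 0 < att_art <= att", call. = FALSE)
    }
    if (s <= 0 || p <= 0) stop("s and p must be > 0", call. = FALSE)
  }
  structure(out, class = "hemo_params")
}
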