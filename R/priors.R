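#' Default parameter priors for a kinetic model
#'
#' Priors follow the defaults of the Bayesian ASL fitting methodology
#' the models come from:
#'
#' * perfusion amplitude `ftiss`: effectively non-informative
#'   (precision 1e-12 in relative-signal units);
#' * tissue transit time `att`: Gaussian, mean 1 s, precision 1;
#' * arterial blood volume `abv`: automatic relevancy determination
#'   (ARD) — the prior precision starts effectively flat (1e-12) and is
#'   re-estimated each iteration as `1 / (mean^2 + variance)`, shrinking
#'   the component to zero where the data do not support it;
#' * arterial arrival `att_art`: Gaussian, mean 0.7 s, precision 1
#'   (arterial arrival precedes tissue arrival);
#' * dispersion parameters, inferred in log space: `log(s)` mean 2 and
#'   `log(s*p)` mean -0.3, both with precision 1.
#'
#' @param model An [asl_model()] (or model code).
#' @return A tibble of class `asl_priors` with columns `param`, `mean`,
#'   `precision`, `transform` and `ard`.
#' @examples
#' default_priors(asl_model("art_disp"))
#' @export
default_priors <- function(model) {
  if (!inherits(model, "asl_model")) model <- asl_model(model)
  all <- tibble::tribble(
    ~param,     ~mean, ~precision, ~transform, ~ard,
    "ftiss",    0,     1e-12,      "identity", FALSE,
    "att",      1.0,   1.0,        "identity", FALSE,
    "abv",      0,     1e-12,      "identity", TRUE,
    "att_art",  0.7,   1.0,        "identity", FALSE,
    "log_s",    2.0,   1.0,        "log",      FALSE,
    "log_sp",   -0.3,  1.0,        "log",      FALSE
  )
  out <- all[match(model$parameter_names, all$param), , drop = FALSE]
  tibble::new_tibble(out, class = "asl_priors")
}

validate_priors <- function(priors, model) {
  stopifnot(is.data.frame(priors),
            all(c("param", "mean", "precision", "ard") %in% names(priors)))
  if (!setequal(priors$param, model$parameter_names) ||
      nrow(priors) != length(model$parameter_names)) {
    stop("priors must cover exactly the model's parameters: ",
         paste(model$parameter_names, collapse = ", "), call. = FALSE)
  }
  if (any(priors$precision <= 0)) {
    stop("prior precisions must be > 0", call. = FALSE)
  }
  if (any(priors$ard & priors$param != "abv")) {
    stop("ARD is only supported on abv", call. = FALSE)
  }
  priors[match(model$parameter_names, priors$param), , drop = FALSE]
}
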