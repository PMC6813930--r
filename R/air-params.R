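# Parameter registry for the acute inflammatory response (AIR) model.
#
# Canonical ordering matters: the compiled right-hand side indexes the
# parameter vector by position. .air_param_names, the C #define block in
# src/air_rhs.c, and air_params() must stay in step.

.air_param_names <- c(
  "S_P", "k_PT", "theta_P", "k_PTB", "k_PTMT", "k_PTNT",
  "S_MT", "M_v", "k_MT", "k_MTB",
  "S_NT", "N_v", "k_NTB", "k_NTMT", "k_NT",
  "S_B", "k_BPT", "k_BR", "k_BNT",
  "PT_plus", "PT_minus",
  "k_PBNA", "x_PN", "k_PS", "x_PS",
  "k_MP", "x_MP", "k_MD", "x_MD", "x_MTNF", "k_M6", "x_M6", "x_M10",
  "k_MR", "S_M", "k_MA",
  "k_NP", "x_NP", "k_ND", "x_ND", "k_NTNF", "x_NTNF", "k_N6", "x_N6",
  "x_N10", "k_NR", "S_N", "k_NA",
  "k_INOSN", "k_INOSM", "k_INOSEC", "x_INOSTNF", "k_INOSd", "k_INOS6",
  "x_INOS6", "x_INOS10", "x_INOSNO", "k_INOS",
  "k_ENOSEC", "x_ENOSTNF", "x_ENOSP", "k_ENOS",
  "k_NO3", "k_NOMA",
  "k_TNFN", "k_TNFM", "x_TNF10", "x_TNF6", "k_TNF",
  "k_6N", "k_6M", "k_6TNF", "x_6TNF", "k_6NO", "x_6NO", "x_610", "x_66",
  "k_6", "S_6",
  "k_10N", "k_10MA", "k_10TNF", "x_10TNF", "k_106", "x_106", "k_10R",
  "x_1012", "k_10", "S_10",
  "k_12M", "x_1210", "k_12",
  "k_D", "k_D6", "x_D6", "x_DNO",
  "kappa_PT", "TI_min", "x_BP", "h_BP", "b_B"
)

.air_param_defaults <- c(
  S_P = 0.60, k_PT = 3.7e4, theta_P = 1.35e-4, k_PTB = 3.1,
  k_PTMT = 6.3e-3, k_PTNT = 6.1e-4,
  S_MT = 2.6e-2, M_v = 0.3, k_MT = 6.43e-5, k_MTB = 36.0,
  S_NT = 7.0e-7, N_v = 1e8, k_NTB = 36.0, k_NTMT = 0.16, k_NT = 6.1e-2,
  S_B = 4.6e-2, k_BPT = 26.0, k_BR = 0.14, k_BNT = 4.0e-8,
  PT_plus = 2.0e6, PT_minus = 1e3,
  k_PBNA = 5.8, x_PN = 0.5, k_PS = 6.9e3, x_PS = 1.3e4,
  k_MP = 1.01, x_MP = 37.5, k_MD = 5.0e-2, x_MD = 0.75, x_MTNF = 0.4,
  k_M6 = 0.1, x_M6 = 1.0, x_M10 = 0.297,
  k_MR = 0.05, S_M = 1.0, k_MA = 0.2,
  k_NP = 33.75, x_NP = 56.25, k_ND = 0.05, x_ND = 0.4, k_NTNF = 0.2,
  x_NTNF = 2.0, k_N6 = 1.5, x_N6 = 1.0, x_N10 = 0.2,
  k_NR = 0.05, S_N = 1.0, k_NA = 0.5,
  k_INOSN = 1.5, k_INOSM = 0.1, k_INOSEC = 0.1, x_INOSTNF = 0.05,
  k_INOSd = 0.05, k_INOS6 = 2.0, x_INOS6 = 0.1, x_INOS10 = 0.1,
  x_INOSNO = 0.3, k_INOS = 0.101,
  k_ENOSEC = 0.05, x_ENOSTNF = 0.4, x_ENOSP = 1.015, k_ENOS = 4.0,
  k_NO3 = 0.46, k_NOMA = 2.0,
  k_TNFN = 2.97, k_TNFM = 0.1, x_TNF10 = 7.9e-2, x_TNF6 = 5.9e-2,
  k_TNF = 1.4,
  k_6N = 0.2, k_6M = 3.03, k_6TNF = 1.0, x_6TNF = 0.1, k_6NO = 2.97,
  x_6NO = 0.4, x_610 = 0.1782, x_66 = 0.5, k_6 = 0.7, S_6 = 1.0e-3,
  k_10N = 0.1, k_10MA = 0.1, k_10TNF = 1.485, x_10TNF = 0.05,
  k_106 = 5.1e-2, x_106 = 8.0e-2, k_10R = 0.1, x_1012 = 1.0e-2,
  k_10 = 0.35, S_10 = 1.0e-2,
  k_12M = 0.303, x_1210 = 0.2525, k_12 = 5.0e-2,
  k_D = 0.15, k_D6 = 0.125, x_D6 = 0.85, x_DNO = 0.5,
  kappa_PT = 3.0e6, TI_min = 0, x_BP = 8.2e6, h_BP = 16, b_B = 0.002
)

#' AIR model parameters
#'
#' Builds the named parameter vector of the acute inflammatory response
#' model: pathogen invasion and colonisation rates, immune-cell activation
#' and decay constants, Hill half-saturation constants for every cytokine
#' interaction, nitric-oxide synthase kinetics, the TLR switch thresholds
#' (`PT_plus`, `PT_minus`), the tissue-pathogen carrying capacity
#' `kappa_PT`, the barrier-erosion burden threshold `x_BP` with its Hill
#' steepness `h_BP`, and the tissue-integrity floor `TI_min`. Rates are per hour;
#' concentrations are in arbitrary units except pathogen counts (CFU/mL
#' scale).
#'
#' @param ... Named overrides of individual parameters. Unknown names are
#'   rejected.
#' @return A named numeric vector of class `air_params`.
#' @examples
#' p <- air_params(S_P = 0.65)
#' p[["PT_plus"]]
#' @seealso [write_air_params()], [read_air_params()]
#' @export
air_params <- function(...) {
  p <- .air_param_defaults[.air_param_names]
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) &&
      (is.list(over[[1L]]) || length(over[[1L]]) > 1L ||
       !is.null(names(over[[1L]])))) {
    over <- as.list(over[[1L]])
  }
  if (length(over)) {
    nm <- names(over)
    if (is.null(nm) || any(nm == ""))
      stop("all parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(nm, .air_param_names)
    if (length(unknown))
      stop("unknown AIR parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    vals <- vapply(over, function(v) as.numeric(v)[1L], numeric(1))
    p[nm] <- vals
  }
  validate_air_params(p)
  class(p) <- c("air_params", "numeric")
  p
}

validate_air_params <- function(p) {
  if (any(!is.finite(p)))
    stop("AIR parameters must be finite", call. = FALSE)
  rates <- setdiff(names(p), "TI_min")
  if (any(p[rates] < 0))
    stop("AIR rate constants and thresholds must be >= 0", call. = FALSE)
  if (p[["PT_minus"]] >= p[["PT_plus"]])
    stop("TLR thresholds require PT_minus < PT_plus", call. = FALSE)
  if (p[["TI_min"]] < 0 || p[["TI_min"]] >= 1)
    stop("TI_min must lie in [0, 1)", call. = FALSE)
  invisible(p)
}

#' @export
print.air_params <- function(x, ...) {
  cat("AIR model parameters (", length(x), " values, rates in 1/h)\n",
      sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Read and write AIR parameter files
#'
#' The registry serialises to a flat JSON key-value file whose keys are the
#' parameter symbol names (ASCII-normalised, e.g. `"k_PTMT"`, `"x_66"`).
#' Values round-trip at full double precision.
#'
#' @param params An `air_params` vector.
#' @param path File path.
#' @return `read_air_params()` returns an `air_params` vector;
#'   `write_air_params()` returns `path` invisibly.
#' @export
write_air_params <- function(params, path) {
  params <- air_params(params)
  body <- paste0('  "', names(params), '": ',
                 sprintf("%.17g", as.numeric(params)))
  writeLines(c("{", paste(body, collapse = ",\n"), "}"), path)
  invisible(path)
}

#' @rdname write_air_params
#' @export
read_air_params <- function(path) {
  vals <- jsonlite::fromJSON(path)
  if (!is.list(vals)) vals <- as.list(vals)
  air_params(vals)
}
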