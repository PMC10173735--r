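#' Model parameters for the CTL-melanoma model
#'
#' Constructs the full parameter set of the cell-cycle-resolved tumor model
#' with CTL dynamics and checkpoint-driven exhaustion.  Defaults are the
#' best-fitting values of the full model (all checkpoints included); bounds
#' are the permissive fitting bounds: checkpoint and IFNG disappearance
#' rates and the killing rate in 0.01--100 / day, CTL death in 0.01--10 /
#' day, everything else in 1e-3--1e3.  \code{kA} (IFNG contribution to
#' checkpoint induction) and \code{kex} (exhaustion half-effect scale) are
#' structurally non-identifiable and are flagged as fixed at 1; the fitting
#' machinery never frees them.
#'
#' @param ... named parameter overrides, e.g. \code{ctl_params(ke = 0.9)}.
#' @param bounds optional named list of \code{c(lower, upper)} overrides.
#' @return an object of class \code{ctl_params}: a named numeric vector with
#'   \code{bounds} (2 x 17 matrix) and \code{fixed} (character) attributes.
#' @examples
#' p <- ctl_params(ki = 8.1, ke = 0.9)
#' p["ki"]
#' @export
ctl_params <- function(..., bounds = NULL) {
  values <- c(
    s0 = 0.001, se = 8.41, dE = 0.80, di = 3.61,
    kgs = 1.64, ksg = 0.66, ki = 4.40, ke = 100,
    kA = 1, kex = 1,
    kl = 0.001, kt = 1.37, kp = 0.001,
    dl = 0.65, dt = 0.01, dp = 2.33, dpl = 2.48
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("parameter overrides must be named")
    bad <- setdiff(names(over), names(values))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    values[names(over)] <- as.numeric(unlist(over))
  }

  b <- default_bounds()
  if (!is.null(bounds)) {
    bad <- setdiff(names(bounds), names(values))
    if (length(bad))
      stop("bounds given for unknown parameter(s): ", paste(bad, collapse = ", "))
    for (nm in names(bounds)) b[, nm] <- bounds[[nm]]
  }

  structure(values, bounds = b, fixed = c("kA", "kex"),
            class = "ctl_params")
}

param_names <- function() {
  c("s0", "se", "dE", "di", "kgs", "ksg", "ki", "ke", "kA", "kex",
    "kl", "kt", "kp", "dl", "dt", "dp", "dpl")
}

default_bounds <- function() {
  nm <- param_names()
  b <- matrix(rep(c(1e-3, 1e3), length(nm)), nrow = 2,
              dimnames = list(c("lower", "upper"), nm))
  for (p in c("di", "dl", "dt", "dp", "dpl", "ke")) b[, p] <- c(0.01, 100)
  b[, "dE"] <- c(0.01, 10)
  b
}

#' Validate a parameter set
#'
#' Checks non-negativity, bound containment, and presence of the fixed-flag
#' metadata.  Called by the simulator and fitting code.
#'
#' @param params a \code{ctl_params} object.
#' @return \code{params}, invisibly, or an error.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "ctl_params")) stop("not a ctl_params object")
  v <- unclass(params)
  b <- attr(params, "bounds")
  if (any(!is.finite(v))) stop("non-finite parameter values")
  if (any(v < 0)) stop("negative parameter values: ",
                       paste(names(v)[v < 0], collapse = ", "))
  out_lo <- v < b["lower", names(v)] - 1e-12
  out_hi <- v > b["upper", names(v)] + 1e-12
  # exact zero switches a process off (untreated cohorts, reduced variants)
  # and is always admissible even when the fitting bound is positive
  ok_fixed <- names(v) %in% attr(params, "fixed") | v == 0
  bad <- (out_lo | out_hi) & !ok_fixed
  if (any(bad))
    stop("parameter(s) outside declared bounds: ",
         paste(names(v)[bad], collapse = ", "))
  invisible(params)
}

#' @export
print.ctl_params <- function(x, ...) {
  b <- attr(x, "bounds")
  df <- data.frame(value = as.numeric(x),
                   lower = b["lower", names(unclass(x))],
                   upper = b["upper", names(unclass(x))],
                   fixed = names(unclass(x)) %in% attr(x, "fixed"),
                   row.names = names(unclass(x)))
  cat("CTL-melanoma model parameters\n")
  print(df, ...)
  invisible(x)
}

#' Write / read parameter sets as JSON
#'
#' The JSON document is keyed by parameter symbol and stores the value, the
#' fitting bounds and whether the parameter is fixed before fitting.
#'
#' @param params a \code{ctl_params} object.
#' @param path file path.
#' @return \code{write_params_json}: the path, invisibly.
#'   \code{read_params_json}: a \code{ctl_params} object.
#' @export
write_params_json <- function(params, path) {
  validate_params(params)
  b <- attr(params, "bounds")
  doc <- lapply(names(unclass(params)), function(nm) {
    list(value = as.numeric(params[nm]),
         lower = as.numeric(b["lower", nm]),
         upper = as.numeric(b["upper", nm]),
         fixed = nm %in% attr(params, "fixed"))
  })
  names(doc) <- names(unclass(params))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  doc <- jsonlite::read_json(path)
  bad <- setdiff(names(doc), param_names())
  if (length(bad)) stop("unknown parameter(s) in JSON: ",
                        paste(bad, collapse = ", "))
  vals <- vapply(doc, function(d) as.numeric(d$value), numeric(1))
  bnds <- lapply(doc, function(d) c(as.numeric(d$lower), as.numeric(d$upper)))
  do.call(ctl_params, c(as.list(vals), list(bounds = bnds)))
}
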