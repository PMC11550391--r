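#' Model structures for heart-rate response dynamics
#'
#' The candidate family is a continuous-time transfer function with up to
#' two poles, one zero and a dead time,
#' \deqn{P_o(s) = k \frac{T_z s + 1}{(\tau_1 s + 1)(\tau_2 s + 1)} e^{-T_d s},}
#' constrained to seven named structures, plus the parallel connection of
#' two first-order branches (one delayed, one not),
#' \deqn{P_o(s) = \frac{k_{p1}}{\tau_{p1} s + 1} +
#'   \frac{k_{p2}}{\tau_{p2} s + 1} e^{-T_d s}.}
#'
#' `model_structures()` lists the structure names and their free parameters;
#' all other parameters are held at zero.
#'
#' @return Named list mapping each structure name to the character vector of
#'   its free parameter names, in canonical order.
#' @examples
#' model_structures()[["P1D"]]
#' @export
model_structures <- function() {
  list(
    P1       = c("k", "tau1"),
    P1D      = c("k", "tau1", "Td"),
    P2       = c("k", "tau1", "tau2"),
    P2D      = c("k", "tau1", "tau2", "Td"),
    P2Z      = c("k", "tau1", "tau2", "Tz"),
    P2ZD     = c("k", "tau1", "tau2", "Tz", "Td"),
    P1parP1D = c("kp1", "taup1", "kp2", "taup2", "Td")
  )
}

.all_param_names <- c("k", "tau1", "tau2", "Tz", "Td",
                      "kp1", "taup1", "kp2", "taup2")

#' Construct a validated process model
#'
#' Builds a `process_model` from a structure name and exactly that
#' structure's free parameters; constrained parameters are held at zero.
#' Time constants and the dead time must be non-negative; the zero time
#' constant `Tz` may take either sign (non-minimum-phase responses are
#' admissible).
#'
#' @param structure_name One of `names(model_structures())`.
#' @param params Named list or numeric vector supplying exactly the
#'   structure's free parameters. Gains are in bpm per input unit
#'   (bpm/(m/s) for treadmill, bpm/W for cycle ergometer); time constants,
#'   `Tz` and `Td` are in seconds.
#' @return An object of class `process_model`.
#' @examples
#' make_model("P1D", list(k = 25.0, tau1 = 47.7, Td = 13.1))
#' @export
make_model <- function(structure_name, params) {
  structs <- model_structures()
  if (!is.character(structure_name) || length(structure_name) != 1L ||
      !structure_name %in% names(structs)) {
    stop("unknown model structure: ", paste(structure_name, collapse = ", "),
         " (expected one of ", paste(names(structs), collapse = ", "), ")")
  }
  free <- structs[[structure_name]]
  params <- as.list(params)
  if (is.null(names(params)) || any(!nzchar(names(params)))) {
    stop("parameter error: params must be a fully named list/vector")
  }
  extra <- setdiff(names(params), free)
  missing <- setdiff(free, names(params))
  if (length(extra)) {
    stop("parameter error: parameter(s) not free for ", structure_name, ": ",
         paste(extra, collapse = ", "))
  }
  if (length(missing)) {
    stop("parameter error: missing parameter(s) for ", structure_name, ": ",
         paste(missing, collapse = ", "))
  }
  vals <- vapply(params, function(x) as.numeric(x)[1], numeric(1))
  if (any(!is.finite(vals))) stop("parameter error: non-finite parameter value")
  full <- setNames(numeric(length(.all_param_names)), .all_param_names)
  full[names(vals)] <- vals
  nonneg <- c("tau1", "tau2", "Td", "taup1", "taup2")
  bad <- nonneg[full[nonneg] < 0]
  if (length(bad)) {
    stop("domain error: negative value for ", paste(bad, collapse = ", "))
  }
  structure(
    list(structure = structure_name, free = free, params = full),
    class = "process_model"
  )
}

#' @export
print.process_model <- function(x, ...) {
  cat("<process_model> structure:", x$structure, "\n")
  p <- x$params[x$free]
  cat(paste0("  ", names(p), " = ", signif(p, 6), collapse = "\n"), "\n")
  invisible(x)
}

#' Free parameter values of a process model
#'
#' @param model A `process_model`.
#' @return Named numeric vector of the structure's free parameters.
#' @export
free_params <- function(model) {
  stopifnot(inherits(model, "process_model"))
  model$params[model$free]
}

#' Steady-state gain of a process model
#'
#' The asymptotic output change per unit sustained input change: `k` for the
#' single-branch structures, `kp1 + kp2` for the parallel form.
#'
#' @param model A `process_model`.
#' @return Gain in bpm per input unit.
#' @export
dc_gain <- function(model) {
  stopifnot(inherits(model, "process_model"))
  p <- model$params
  if (model$structure == "P1parP1D") unname(p["kp1"] + p["kp2"])
  else unname(p["k"])
}
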