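#' Parameters of the minimal Th1 activation switch
#'
#' The minimal model tracks a single variable, the Th1 activity `T` (read
#' interchangeably as the density of CD4+ effector T cells with the Th1
#' phenotype). It combines a net basal flux `beta_T - eps_T * T` with an
#' autocatalytic, sigmoidal activation term driven by antigen and by a lumped
#' cytokine pool held at a constant level `c`.
#'
#' Defaults are the published single-cell-switch demonstration values
#' (`theta_T = 1`, `beta_T = 0.02`, `eps_T = 1`, `c = 3`,
#' `eta1 = eta2 = 1`).
#'
#' @param theta_T Activation threshold of the sigmoidal term (dimensionless
#'   density). Must be > 0.
#' @param beta_T Basal influx rate of Teff cells.
#' @param eps_T First-order clearance rate constant. Must be > 0.
#' @param c Constant lumped cytokine density feeding the activation drive.
#' @param eta1,eta2 Non-negative coupling coefficients of antigen and
#'   cytokine into the activation drive.
#'
#' @return An object of class `minimal_params`: a named list of the six
#'   rate constants.
#' @seealso [detailed_params()], [minimal_rhs()], [bistable_range()]
#' @export
#' @examples
#' p <- minimal_params()
#' minimal_drive(4, p) # antigen 4 on top of cytokine 3 -> drive 7
minimal_params <- function(theta_T = 1, beta_T = 0.02, eps_T = 1,
                           c = 3, eta1 = 1, eta2 = 1) {
  p <- list(theta_T = theta_T, beta_T = beta_T, eps_T = eps_T,
            c = c, eta1 = eta1, eta2 = eta2)
  validate_minimal_params(p)
  structure(p, class = "minimal_params")
}

validate_minimal_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("all minimal-model parameters must be finite numeric scalars",
         call. = FALSE)
  }
  if (any(unlist(p) < 0)) {
    stop("all minimal-model parameters must be >= 0", call. = FALSE)
  }
  if (p$eps_T <= 0) stop("eps_T must be > 0", call. = FALSE)
  if (p$theta_T <= 0) stop("theta_T must be > 0", call. = FALSE)
  invisible(p)
}

#' Base parameters of the detailed six-variable immune network
#'
#' Returns the base rate constants of the granuloma network: effector T
#' cells (`T`), regulatory T cells (`R`), macrophages (`M`) and the
#' cytokines IL-2 (`delta`), IFN-gamma (`gamma`) and TNF-alpha (`alpha`).
#' Any subset of constants can be overridden by name, which is how the
#' perturbation experiments (for example raising the Treg IL-2 sensitivity
#' `k_2a` from 1 to 2.1) are expressed.
#'
#' Parameter roles:
#' \describe{
#'   \item{beta_*, eps_*}{basal influx and first-order clearance of each
#'     population / cytokine; the drive-free steady state of every variable
#'     is `beta/eps`.}
#'   \item{theta_T, theta_R, theta_M}{activation thresholds of the
#'     sigmoidal (autocatalytic) terms.}
#'   \item{k_1a, k_1b, k_1c}{coupling of antigen presentation (the product
#'     `A * M`), IL-2 and IFN-gamma into the Teff drive.}
#'   \item{k_1d}{Treg inhibition of Teff proliferation (denominator of the
#'     Teff drive).}
#'   \item{k_1e}{macrophage-mediated TNF-alpha suppression of Teffs
#'     (denominator term `k_1e * alpha * M`).}
#'   \item{k_2a, k_2b}{IL-2 dependence of Treg activation and the opposing
#'     TNF-alpha effect; the Treg drive is `delta * (k_2a - k_2b * alpha)`
#'     clamped at zero, so high TNF-alpha flips the Teff-to-Treg edge from
#'     activation to suppression.}
#'   \item{k_6, k_6b, k_6c}{IFN-gamma and TNF-alpha activation of
#'     macrophages and Treg inhibition of the same.}
#'   \item{k_3, k_4a, k_4b, k_5a, k_5b}{cytokine production: IL-2 from
#'     Teffs; IFN-gamma and TNF-alpha from Teffs and macrophages.}
#' }
#'
#' @param ... Named scalar overrides of any base constant.
#'
#' @return An object of class `detailed_params`: a named list of the 30
#'   rate constants.
#' @seealso [default_initial_state()], [detailed_rhs()], [scenario()]
#' @export
#' @examples
#' p <- detailed_params(k_2a = 2.1)
#' p$k_2a
detailed_params <- function(...) {
  p <- list(
    # Teff (T)
    beta_T = 0.05, eps_T = 1.0, theta_T = 1.0,
    k_1a = 1.0, k_1b = 20.5, k_1c = 10.0, k_1d = 1.0, k_1e = 0.1,
    # Treg (R)
    beta_R = 0.05, eps_R = 1.0, theta_R = 1.0, k_2a = 1.0, k_2b = 0.1,
    # Macrophage (M)
    beta_M = 0.05, eps_M = 1.0, theta_M = 1.0,
    k_6 = 1.0, k_6b = 1.0, k_6c = 0.1,
    # IL-2 (delta)
    beta_delta = 0.01, eps_delta = 10.0, k_3 = 1.0,
    # IFN-gamma (gamma)
    beta_gamma = 0.01, eps_gamma = 10.0, k_4a = 1.0, k_4b = 1.0,
    # TNF-alpha (alpha)
    beta_alpha = 0.01, eps_alpha = 10.0, k_5a = 1.0, k_5b = 1.0
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(over), names(p))
    if (length(unknown)) {
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(over)] <- over
  }
  validate_detailed_params(p)
  structure(p, class = "detailed_params")
}

validate_detailed_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("all parameters must be finite numeric scalars: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  if (any(unlist(p) < 0)) {
    stop("all parameters must be >= 0: ",
         paste(names(p)[unlist(p) < 0], collapse = ", "), call. = FALSE)
  }
  clear <- c("eps_T", "eps_R", "eps_M", "eps_delta", "eps_gamma", "eps_alpha")
  bad <- clear[vapply(clear, function(k) p[[k]] <= 0, logical(1))]
  if (length(bad)) {
    stop("clearance rates must be > 0: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(p)
}

#' State variable names of the detailed model
#' @keywords internal
state_names <- function() c("T", "R", "M", "delta", "gamma", "alpha")

#' Default initial state of the detailed model
#'
#' The published starting point for all simulations: small seed densities
#' for the three cell populations and near-basal cytokine levels
#' (`T = 0.01`, `R = 0.01`, `M = 0.001`, `delta = gamma = alpha = 0.001`).
#'
#' @return A named numeric vector over `T, R, M, delta, gamma, alpha`.
#' @export
default_initial_state <- function() {
  c(T = 0.01, R = 0.01, M = 0.001, delta = 0.001, gamma = 0.001,
    alpha = 0.001)
}

as_state <- function(x) {
  nm <- state_names()
  if (is.data.frame(x)) x <- unlist(x[1, intersect(nm, names(x))])
  if (is.null(names(x))) {
    if (length(x) != 6) stop("state must have 6 components", call. = FALSE)
    names(x) <- nm
  }
  missing <- setdiff(nm, names(x))
  if (length(missing)) {
    stop("state is missing component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  s <- as.numeric(x[nm])
  names(s) <- nm
  if (any(!is.finite(s))) stop("state must be finite", call. = FALSE)
  if (any(s < 0)) stop("state components must be >= 0", call. = FALSE)
  s
}

#' Write a parameter set to a flat key-value text file
#'
#' Serializes a parameter set as `name = value` lines using the canonical
#' symbol names (`beta_T`, `k_1a`, ...), so a configuration file can be
#' audited line by line against the published table of base values.
#'
#' @param params A [minimal_params()] or [detailed_params()] object.
#' @param path File to write.
#' @return `path`, invisibly.
#' @seealso [read_params()]
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, c("minimal_params", "detailed_params")))
  lines <- c(
    paste0("# sarcodyn parameter set (", class(params)[1], ")"),
    sprintf("%s = %.17g", names(params), unlist(params))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter set from a flat key-value text file
#'
#' @param path File written by [write_params()] (or hand-edited in the same
#'   format; `#` starts a comment). Every key must be a known parameter
#'   name; unknown keys are an error, protecting against silent typos such
#'   as `k_6b` vs `k_6c`.
#' @param model `"detailed"` or `"minimal"`.
#' @return A parameter object of the requested class.
#' @export
read_params <- function(path, model = c("detailed", "minimal")) {
  model <- match.arg(model)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop("malformed parameter line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2))))
  if (anyNA(vals)) {
    stop("non-numeric parameter value(s) for: ",
         paste(keys[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  args <- as.list(vals)
  names(args) <- keys
  if (model == "detailed") {
    do.call(detailed_params, args)
  } else {
    do.call(minimal_params, args)
  }
}

#' @export
print.detailed_params <- function(x, ...) {
  cat("<detailed_params> 6-variable granuloma network,",
      length(x), "rate constants\n")
  base <- unclass(detailed_params())
  delta <- names(x)[vapply(names(x), function(k) !identical(x[[k]], base[[k]]),
                           logical(1))]
  if (length(delta)) {
    cat("  overrides:",
        paste(sprintf("%s = %g", delta, unlist(x[delta])), collapse = ", "),
        "\n")
  } else {
    cat("  all constants at base values\n")
  }
  invisible(x)
}

#' @export
print.minimal_params <- function(x, ...) {
  cat("<minimal_params>",
      paste(sprintf("%s = %g", names(x), unlist(x)), collapse = ", "), "\n")
  invisible(x)
}
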