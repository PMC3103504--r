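#' Read a scenario from a YAML configuration file
#'
#' One schema serves both models. Top-level keys: `model`
#' (`minimal`/`detailed`), `params` (named overrides of base constants,
#' canonical symbol names), `initial_state` (named), `settle` (logical),
#' `horizon` (number), `pulses` (list of maps with keys `channel`,
#' `amplitude`, `t_on`, `t_off`). Unknown keys anywhere are errors, so a
#' typo like `k_6d` cannot silently change an experiment.
#'
#' @param path YAML file.
#' @return A [scenario()].
#' @seealso [write_scenario()], [paper_fixtures()]
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("no such scenario file: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  allowed <- c("model", "params", "initial_state", "settle", "horizon",
               "pulses")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  model <- cfg$model %||% "detailed"
  params <- if (model == "detailed") {
    do.call(detailed_params, as.list(cfg$params %||% list()))
  } else {
    do.call(minimal_params, as.list(cfg$params %||% list()))
  }
  init <- cfg$initial_state
  if (!is.null(init)) init <- unlist(init)
  pulses <- lapply(seq_along(cfg$pulses %||% list()), function(i) {
    p <- cfg$pulses[[i]]
    bad <- setdiff(names(p), c("channel", "amplitude", "t_on", "t_off"))
    if (length(bad)) {
      stop(sprintf("pulse %d: unknown key(s) %s", i,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    need <- setdiff(c("channel", "amplitude", "t_on", "t_off"), names(p))
    if (length(need)) {
      stop(sprintf("pulse %d: missing key(s) %s", i,
                   paste(need, collapse = ", ")), call. = FALSE)
    }
    tryCatch(square_pulse(p$channel, p$amplitude, p$t_on, p$t_off),
             error = function(e) {
               stop(sprintf("pulse %d: %s", i, conditionMessage(e)),
                    call. = FALSE)
             })
  })
  scenario(model = model, params = params, initial_state = init,
           pulses = pulses, horizon = cfg$horizon %||% 300,
           settle = cfg$settle %||% TRUE)
}

#' Write a scenario to a YAML configuration file
#'
#' Serializes the full parameter set (not only overrides) so the file is
#' a self-contained, auditable record of the experiment.
#'
#' @param scn A [scenario()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "sarco_scenario"))
  cfg <- list(
    model = scn$model,
    params = lapply(unclass(scn$params), as.numeric),
    initial_state = as.list(scn$initial_state),
    settle = scn$settle,
    horizon = scn$horizon,
    pulses = lapply(scn$pulses, function(p) {
      list(channel = p$channel, amplitude = p$amplitude, t_on = p$t_on,
           t_off = p$t_off)
    })
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
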