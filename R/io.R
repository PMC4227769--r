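#' Serialize rate constants or a mechanism to JSON
#'
#' @param x a [rate_constants] or [mechanism] object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_mechanism_json <- function(x, path) {
  if (inherits(x, "mechanism")) {
    obj <- list(type = "mechanism", rates = unclass(x$rates),
                occupancy_model = x$occupancy_model, chase = x$chase,
                occupancy = x$occupancy, site_capacity = x$site_capacity)
  } else if (inherits(x, "rate_constants")) {
    obj <- list(type = "rate_constants", rates = unclass(x))
  } else stop("`x` must be a rate_constants or mechanism object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read rate constants or a mechanism from JSON
#'
#' @param path JSON file written by [write_mechanism_json()]
#' @return a [rate_constants] or [mechanism] object
#' @export
read_mechanism_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  r <- obj$rates
  rates <- rate_constants(k_on = r$k_on, k_search = r$k_search,
                          k_escape = r$k_escape, k_off_ns = r$k_off_ns,
                          k_flip = r$k_flip, k_unflip = r$k_unflip,
                          k_chem = r$k_chem,
                          variant = if (is.null(r$variant)) NA_character_
                                    else r$variant)
  if (identical(obj$type, "mechanism"))
    mechanism(rates, obj$occupancy_model, chase = isTRUE(obj$chase),
              occupancy = obj$occupancy, site_capacity = obj$site_capacity)
  else rates
}

#' Serialize a phase fit to a plain list (for JSON reports)
#'
#' @param fit a `phase_fit`
#' @return a list of plain vectors
#' @export
phase_fit_record <- function(fit) {
  list(rates = fit$rates, amplitudes = fit$amplitudes, y_inf = fit$y_inf,
       se_rates = fit$se$rates, rms = fit$rms, n_phases = fit$n_used,
       converged = fit$converged, merged = fit$merged,
       identifiable = fit$identifiable)
}
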