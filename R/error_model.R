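#' Argos location-class error model
#'
#' Location error in each coordinate is modelled as a scaled Student-t,
#' with degrees of freedom `nu` and scales `tau_lon`, `tau_lat` (degrees)
#' specific to the Argos location class (3, 2, 1, 0, A, B). The package
#' ships a default table as editable YAML; pass a path to use your own
#' estimates.
#'
#' @param path Path to a YAML file with a `classes` map; `NULL` loads the
#'   shipped defaults.
#' @return An `argos_error_model`: data frame with rownames = classes and
#'   columns `nu`, `tau_lon`, `tau_lat`.
#' @export
argos_error_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "argos_error_model.yaml", package = "whaletrack")
  }
  cfg <- yaml::read_yaml(path)
  cls <- cfg$classes
  missing <- setdiff(argos_classes(), names(cls))
  if (length(missing)) {
    stop("error model is missing class(es): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  em <- do.call(rbind, lapply(argos_classes(), function(k) {
    p <- cls[[k]]
    if (any(c(p$nu, p$tau_lon, p$tau_lat) <= 0)) {
      stop("error model parameters must be positive (class ", k, ")", call. = FALSE)
    }
    data.frame(nu = p$nu, tau_lon = p$tau_lon, tau_lat = p$tau_lat)
  }))
  rownames(em) <- argos_classes()
  class(em) <- c("argos_error_model", "data.frame")
  em
}

# log density of a scaled t: x ~ tau * t_nu
dt_scaled_log <- function(x, nu, tau) {
  stats::dt(x / tau, df = nu, log = TRUE) - log(tau)
}
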