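#' Write an experiment configuration to YAML
#'
#' @param cfg An [experiment_config].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  unclass_pif <- function(p) p[c("amp1", "rate1", "amp2", "rate2", "label")]
  lst <- list(
    mode = cfg$mode,
    weights = unclass(cfg$weights),
    geometry = unclass(cfg$geometry),
    pif_targeted = unclass_pif(cfg$pif_targeted),
    pif_control = unclass_pif(cfg$pif_control),
    kinetics = unclass(cfg$kinetics),
    pulsatile = unclass(cfg$pulsatile),
    bit_depths = cfg$bit_depths,
    bit_depth = cfg$bit_depth,
    gauss_sigma_rel = cfg$gauss_sigma_rel,
    replicates = cfg$replicates,
    trunc = cfg$trunc,
    n_photons = cfg$n_photons,
    seed = cfg$seed)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' Missing fields fall back to the defaults of [experiment_config()].
#'
#' @param path YAML file written by [write_config()] (or hand-edited).
#' @return An [experiment_config].
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  d <- experiment_config()
  pick <- function(nm, def) if (!is.null(lst[[nm]])) lst[[nm]] else def
  mk_pif <- function(x, def) {
    if (is.null(x)) def
    else biexp_pif(x$amp1, x$rate1, x$amp2, x$rate2,
                   label = if (!is.null(x$label)) x$label else "")
  }
  experiment_config(
    mode = pick("mode", d$mode),
    weights = if (!is.null(lst$weights)) do.call(sensitivity_states, lst$weights)
              else d$weights,
    geometry = if (!is.null(lst$geometry)) do.call(finger_geometry, lst$geometry)
               else d$geometry,
    pif_targeted = mk_pif(lst$pif_targeted, d$pif_targeted),
    pif_control = mk_pif(lst$pif_control, d$pif_control),
    kinetics = if (!is.null(lst$kinetics)) do.call(kinetic_params, lst$kinetics)
               else d$kinetics,
    pulsatile = if (!is.null(lst$pulsatile)) do.call(pulsatile_config, lst$pulsatile)
                else d$pulsatile,
    bit_depths = pick("bit_depths", d$bit_depths),
    bit_depth = pick("bit_depth", d$bit_depth),
    gauss_sigma_rel = pick("gauss_sigma_rel", d$gauss_sigma_rel),
    replicates = pick("replicates", d$replicates),
    trunc = pick("trunc", d$trunc),
    n_photons = pick("n_photons", d$n_photons),
    seed = pick("seed", d$seed))
}
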