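#' Analysis configuration
#'
#' Bundles the thresholds and conventions of a pipeline run so they travel
#' with the outputs: display bounds, the binning rule, the minimum picks a
#' bin must hold, the exact-solver threshold for the optimal open path, the
#' distance scale of the choice model, and the random seed.
#'
#' @param display_width,display_height display bounds in pixels.
#' @param min_picks_per_bin minimum picks per time bin (default 4, the
#'   smallest count at which all four indicators are defined).
#' @param tsp_exact_max largest pick count solved exactly by the open-path
#'   dynamic program.
#' @param choice_scale distance standardization `s` of the proximity
#'   weight; default the display diagonal.
#' @param seed integer seed recorded with every output.
#' @return A classed list `"forage_config"`.
#' @export
forage_config <- function(display_width = 1400, display_height = 1050,
                          min_picks_per_bin = 4L, tsp_exact_max = 10L,
                          choice_scale = NULL, seed = 1L) {
  stopifnot(display_width > 0, display_height > 0, min_picks_per_bin > 0,
            tsp_exact_max > 0)
  if (is.null(choice_scale))
    choice_scale <- sqrt(display_width^2 + display_height^2)
  structure(list(display_width = display_width,
                 display_height = display_height,
                 min_picks_per_bin = as.integer(min_picks_per_bin),
                 tsp_exact_max = as.integer(tsp_exact_max),
                 choice_scale = choice_scale,
                 seed = as.integer(seed)),
            class = "forage_config")
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config` returns a [forage_config()]; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(forage_config, vals)
}

#' @rdname read_config
#' @param config a [forage_config()] object.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
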