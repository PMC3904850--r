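# YAML serialization of the threshold configuration (labseg.yaml).

#' Read / write a threshold configuration as YAML
#'
#' The YAML file carries the keys \code{c_cc}, \code{c_bs}, \code{c_3d},
#' \code{clahe_clip}, \code{clahe_tiles} and \code{cc_radius_frac}; missing
#' keys keep their defaults.
#'
#' @param path YAML file path.
#' @return \code{readThresholdConfig} returns a
#'   \code{\link{ThresholdConfig}}; \code{writeThresholdConfig} returns the
#'   path invisibly.
#' @export
readThresholdConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  keys <- intersect(names(obj), c("c_cc", "c_bs", "c_3d", "clahe_clip",
                                  "clahe_tiles", "cc_radius_frac"))
  do.call(thresholdConfig, obj[keys])
}

#' @param cfg a \code{\link{ThresholdConfig}}.
#' @rdname readThresholdConfig
#' @export
writeThresholdConfig <- function(cfg, path) {
  yaml::write_yaml(list(
    c_cc = cfg@c_cc, c_bs = cfg@c_bs, c_3d = cfg@c_3d,
    clahe_clip = cfg@clahe_clip, clahe_tiles = cfg@clahe_tiles,
    cc_radius_frac = cfg@cc_radius_frac), path)
  invisible(path)
}
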