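#' Published vitamin-D fortification schemes
#'
#' Optimized fortification levels from a published Danish vitamin-D
#' fortification study: eight scenarios (caps of 12-30 µg/10 MJ over varying
#' food-group allow-lists), each level printed both per 10 MJ of group
#' energy and per 100 g (3 decimals). The pair of bases makes the table a
#' reference for the µg/10 MJ to µg/100 g conversion: the implied group
#' conversion factor `k_g` is constant across scenarios.
#'
#' @return Data frame `group_id, scenario, cap_ug_per_10mj,
#'   level_ug_per_10mj, level_ug_per_100g`.
#' @export
published_scheme_levels <- function() {
  path <- system.file("extdata", "published_scheme_levels.csv",
                      package = "fortiplan", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$group_id <- as.character(df$group_id)
  df
}

#' Path to the bundled example run configuration
#'
#' Eight example scenarios mirroring the published study design, ready to
#' run against a survey written by [write_survey()] / `fortiplan simulate`.
#'
#' @return File path of the YAML config.
#' @export
example_config_path <- function() {
  system.file("extdata", "example_config.yaml", package = "fortiplan",
              mustWork = TRUE)
}
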