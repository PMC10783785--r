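#' Write simulation/extraction parameters to a YAML config
#'
#' Captures `slide_sim_params`, `cohort_sim_params` and `feature_config`
#' objects (matrices are stored as nested lists) so a run is fully
#' described by one file.
#'
#' @param params named list of parameter objects.
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
write_params_yaml <- function(params, path) {
  strip <- function(x) {
    if (is.matrix(x)) return(apply(x, 1, as.numeric, simplify = FALSE))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  yaml::write_yaml(lapply(params, strip), path, precision = 15)
  invisible(path)
}

#' Read a parameter YAML written by [write_params_yaml()]
#'
#' @param path YAML path.
#' @return named list; known parameter blocks (`slide`, `cohort`,
#'   `features`) are rebuilt into their parameter classes.
#' @export
read_params_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  rebuild <- function(name, x) {
    if (name == "slide") {
      x$axis_mean <- as.numeric(unlist(x$axis_mean))
      do.call(slide_sim_params, x)
    } else if (name == "cohort") {
      if (!is.null(x$gene_cov)) x$gene_cov <- do.call(rbind, x$gene_cov)
      do.call(cohort_sim_params, x)
    } else if (name == "features") do.call(feature_config, x)
    else x
  }
  out <- raw
  for (nm in intersect(names(raw), c("slide", "cohort", "features")))
    out[[nm]] <- rebuild(nm, raw[[nm]])
  out
}
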