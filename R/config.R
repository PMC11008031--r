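#' Default run configuration
#'
#' Every tunable of the pipeline in one nested list.  Values that the
#' underlying search protocol fixes (word size 7, match/mismatch +4/-5,
#' 75% identity, 90% coverage, the 100 bp hit floor, the 1500 bp flank pad)
#' are the defaults here; the rest are this package's documented choices.
#'
#' @param ... named overrides of top-level sections, e.g.
#'   `default_run_config(search = list(min_score = 40))` (partial lists are
#'   merged into the defaults).
#' @return nested list of settings.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    search = list(
      word_size = 7L, match = 4L, mismatch = -5L,
      gap_open = -8L, gap_extend = -2L,
      min_score = 100L, xdrop = 20L, band = 16L
    ),
    filter = list(min_identity = 0.75, min_coverage = 0.90, min_hit_len = 100L),
    structure = list(
      min_tir_len = 10L, max_tir_len = 30L, max_mismatch_frac = 0.2,
      tsd_min = 4L, tsd_max = 12L, orf_require_atg = TRUE,
      coverage_gap = -6L, orf_coding_aa = 600L
    ),
    landscape = list(bin_width = 1, exclude_simple = TRUE,
                     simple_period_max = 6L, simple_frac = 0.8),
    presence = list(pad = 1500L, min_flank = 200L, empty_gap_max = 50L,
                    gap_lo = 0.5, gap_hi = 1.5, flank_min_score = 100L),
    caller = list(htt_ratio_max = 0.5, vertical_min = 0.6, shared_max = 0L,
                  min_sites = 300L)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    cfg[[nm]][names(over[[nm]])] <- over[[nm]]
  }
  cfg
}

#' Read / write a run configuration
#'
#' Configurations are flat YAML files mirroring [default_run_config()];
#' unknown keys are an error so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return for `read_run_config`, the merged config list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_run_config, raw)
}

#' @rdname read_run_config
#' @param config a config list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration hash, the seed, and timestamps so that a
#' stochastic run can be reproduced exactly: identical (inputs, config,
#' seed) reproduce identical outputs everywhere in this package.
#'
#' @param config config list (see [default_run_config()]).
#' @param seed integer seed used for the run.
#' @param path output YAML path.
#' @param inputs optional named character vector of input file paths.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(config, seed, path, inputs = NULL) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  manifest <- list(
    config_md5 = unname(tools::md5sum(tmp)),
    seed = as.integer(seed),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(inputs %||% character(0))
  )
  yaml::write_yaml(manifest, path)
  invisible(manifest)
}
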