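#' Default pipeline configuration
#'
#' All stage parameters with their standard defaults: consensus peak support
#' (13 of 25 individuals) and 147 bp merge gap; CHT testability (15
#' allele-specific reads; 10 in replication mode) and FWER tiers (0.1
#' significant, 0.2 suggestive); enrichment with 10 x 10 MAF/TSS-distance
#' deciles and 1000 matching repetitions; cis-eQTL window (1 Mb), MAF >=
#' 0.05, CV >= 0.15, FDR <= 0.05, proxy pruning at r-squared 0.8; D-squared
#' permutation count 10,000; interaction LD independence (r-squared < 0.6
#' and D' < 0.6); loop filters (>= 4 PETs, span 5 kb - 2 Mb). Every random
#' operation draws its seed from the config.
#'
#' @param ... named overrides of any default.
#' @return a named list of class \code{chromqtl_config}.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    consensus = list(min_support = 13L, merge_gap = 147L),
    cht = list(min_as_reads = 15L, min_as_reads_replication = 10L,
               fwer_significant = 0.1, fwer_suggestive = 0.2,
               es_bound = 64),
    enrich = list(n_maf_bins = 10L, n_tss_bins = 10L, n_perm = 1000L,
                  exclude_hqtls_from_pool = TRUE),
    eqtl = list(window = 1e6, maf_min = 0.05, cv_min = 0.15, fdr = 0.05,
                r2_prune = 0.8),
    d2 = list(n_perm = 10000L, min_block_size = 6L, dprime_min = 0.8,
              r2_max = 0.6),
    interaction = list(r2_max = 0.6, dprime_max = 0.6, fdr = 0.05),
    loops = list(min_pets = 4L, min_len = 5e3, max_len = 2e6)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "chromqtl_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys override \code{\link{default_config}}.
#' @return a \code{chromqtl_config} list.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Write a pipeline configuration to YAML
#' @param cfg a config list.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the stage name, seed, parameters and output files of a pipeline
#' stage, for provenance.
#'
#' @param stage stage name.
#' @param params parameter list echoed into the manifest.
#' @param outputs character vector of output paths.
#' @param path manifest path (JSON).
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(stage, params, outputs, path) {
  jsonlite::write_json(list(stage = stage, params = params,
                            outputs = outputs,
                            timestamp = format(Sys.time(), tz = "UTC")),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
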