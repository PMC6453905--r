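#' Run configuration
#'
#' Flat key/value text configuration for the end-to-end analysis and the
#' simulator. Lines are `key = value`; blank lines and `#` comments are
#' ignored. Every analysis threshold defaults to its published value and is
#' overridable; the run report echoes the values actually used.
#'
#' @name run_config
NULL

# key registry: name -> coercion
RUN_CONFIG_KEYS <- list(
  samples = as.character,       # sample sheet TSV
  t2g = as.character,           # transcript-to-gene map TSV
  surfaceome = as.character,    # surfaceome catalogue TSV
  species = as.character,
  match_by = as.character,      # gene_id | symbol
  min_mean = as.numeric,        # differential expression gate (TPM)
  min_fold = as.numeric,        # differential fold gate
  candidate_min_tpm = as.numeric,
  candidate_min_fold = as.numeric,
  expression_call_threshold = as.numeric,
  log_base = as.numeric,
  pseudocount = as.numeric,
  n_components = as.integer,
  cor_method = as.character,    # pearson | spearman
  seed = as.integer
)

SIM_CONFIG_KEYS <- list(
  n_genes = as.integer, n_surfaceome = as.integer,
  transcripts_per_gene = as.integer, n_replicates = as.integer,
  baseline_log2_mean = as.numeric, baseline_log2_sd = as.numeric,
  stage_effect_sd = as.numeric, noise_sd = as.numeric,
  planted_n = as.integer, planted_log2_fc = as.numeric,
  planted_stages = as.character,  # e.g. "DN1&DN2&DN3&DN4"
  planted_direction = as.character,
  library_size = as.numeric, seed = as.integer
)

#' Default analysis configuration
#'
#' @return named list of all analysis keys at their default values (input
#'   paths unset).
#' @export
default_run_config <- function() {
  list(samples = NA_character_, t2g = NA_character_,
       surfaceome = NA_character_, species = "mouse", match_by = "gene_id",
       min_mean = 1, min_fold = 10,
       candidate_min_tpm = 20, candidate_min_fold = 5,
       expression_call_threshold = 4,
       log_base = 2, pseudocount = 1,
       n_components = 6L, cor_method = "pearson", seed = 1L)
}

default_sim_config <- function() {
  list(n_genes = 2000L, n_surfaceome = 300L, transcripts_per_gene = 2L,
       n_replicates = 3L, baseline_log2_mean = 3, baseline_log2_sd = 2.5,
       stage_effect_sd = 1.0, noise_sd = 0.2,
       planted_n = 12L, planted_log2_fc = 4.3,
       planted_stages = "DN1&DN2&DN3&DN4", planted_direction = "up",
       library_size = 5e6, seed = 1L)
}

parse_config_file <- function(path, registry, defaults) {
  if (!file.exists(path)) {
    sm_stop_validation("config file not found: %s", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- defaults
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      sm_stop_validation("config line is not 'key = value': %s", dQuote(ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    value <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(registry)) {
      sm_stop_validation("unknown config key: %s (known: %s)", key,
                         paste(names(registry), collapse = ", "))
    }
    coerced <- suppressWarnings(registry[[key]](value))
    if (is.na(coerced) && !identical(value, "NA")) {
      sm_stop_validation("config key %s: cannot parse value %s",
                         key, dQuote(value))
    }
    cfg[[key]] <- coerced
  }
  cfg
}

#' Read an analysis configuration file
#'
#' Relative input paths are resolved against the config file's directory.
#'
#' @param path config file path; `NULL` yields the defaults.
#' @param overrides named list applied on top of the file (CLI precedence:
#'   flags beat file values beat defaults).
#' @return validated config list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    cfg <- parse_config_file(path, RUN_CONFIG_KEYS, cfg)
    for (key in c("samples", "t2g", "surfaceome")) {
      if (!is.na(cfg[[key]]) && !grepl("^(/|[A-Za-z]:)", cfg[[key]])) {
        cfg[[key]] <- file.path(dirname(path), cfg[[key]])
      }
    }
  }
  cfg[names(overrides)] <- overrides
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  for (key in c("samples", "t2g", "surfaceome")) {
    if (is.na(cfg[[key]])) {
      sm_stop_validation("config key %s is required", key)
    }
    if (!file.exists(cfg[[key]])) {
      sm_stop_validation("config key %s: path does not exist: %s",
                         key, cfg[[key]])
    }
  }
  if (!cfg$match_by %in% c("gene_id", "symbol")) {
    sm_stop_validation("match_by must be gene_id or symbol")
  }
  if (!cfg$cor_method %in% c("pearson", "spearman")) {
    sm_stop_validation("cor_method must be pearson or spearman")
  }
  num <- c("min_mean", "min_fold", "candidate_min_tpm", "candidate_min_fold",
           "expression_call_threshold", "log_base", "pseudocount")
  for (key in num) {
    if (!is.finite(cfg[[key]]) || cfg[[key]] <= 0) {
      sm_stop_validation("config key %s must be positive", key)
    }
  }
  if (cfg$n_components < 1L) {
    sm_stop_validation("n_components must be >= 1")
  }
  cfg
}

#' Read a simulator configuration file
#'
#' @param path config file path; `NULL` yields the defaults.
#' @param overrides named list applied on top of the file.
#' @return a `SyntheticConfig`.
#' @export
read_sim_config <- function(path = NULL, overrides = list()) {
  cfg <- default_sim_config()
  if (!is.null(path)) {
    cfg <- parse_config_file(path, SIM_CONFIG_KEYS, cfg)
  }
  cfg[names(overrides)] <- overrides
  stages <- strsplit(cfg$planted_stages, "&", fixed = TRUE)[[1]]
  synthetic_config(
    n_genes = cfg$n_genes, n_surfaceome = cfg$n_surfaceome,
    transcripts_per_gene = cfg$transcripts_per_gene,
    n_replicates = cfg$n_replicates,
    baseline_log2_mean = cfg$baseline_log2_mean,
    baseline_log2_sd = cfg$baseline_log2_sd,
    stage_effect_sd = cfg$stage_effect_sd, noise_sd = cfg$noise_sd,
    planted = if (cfg$planted_n > 0L) {
      list(list(n = cfg$planted_n, stages = stages,
                log2_fc = cfg$planted_log2_fc,
                direction = cfg$planted_direction))
    } else {
      list()
    },
    library_size = cfg$library_size, seed = cfg$seed)
}
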