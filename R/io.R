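# io_config module: CSV readers with validation, analysis configuration.

SCHEMA_COLUMNS <- list(
  consumer = c("sample_id", "taxon", "taxon_group", "guild", "area",
               "season", "d13c", "d15n"),
  source = c("source", "area", "season", "d13c", "d15n"),
  environment = c("area", "season", "site", ENV_VARIABLES)
)

D13C_RANGE <- c(-60, 10)
D15N_RANGE <- c(-20, 40)

#' Read and validate a study table
#'
#' Reads a CSV in one of the three canonical schemas (consumer, source,
#' environment), optionally renaming columns first via `col_map` so that
#' real-world exports can be ingested without reshaping. Isotope values
#' outside the physical sanity envelope (d13c in \[-60, 10\], d15n in
#' \[-20, 40\] per-mil) are rejected with row-level messages, as are
#' unknown area/season/guild labels when vocabularies are supplied.
#'
#' @param path CSV file path.
#' @param schema one of `"consumer"`, `"source"`, `"environment"`.
#' @param col_map optional named character vector mapping file column names
#'   to schema names, e.g. `c("del13C" = "d13c")`.
#' @param areas,seasons,guilds optional character vocabularies to validate
#'   the corresponding columns against.
#' @return a validated data.frame; input row order preserved.
#' @export
load_samples <- function(path, schema = c("consumer", "source", "environment"),
                         col_map = NULL, areas = NULL, seasons = NULL,
                         guilds = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort_input("input error: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    hit <- names(df) %in% names(col_map)
    names(df)[hit] <- unname(col_map[names(df)[hit]])
  }
  validate_samples(df, schema, areas = areas, seasons = seasons,
                   guilds = guilds)
}

#' Validate an in-memory study table
#'
#' Same checks as [load_samples()] but on a data.frame already in memory
#' (used on generated tables and by the pipeline).
#'
#' @inheritParams load_samples
#' @param df the table to validate.
#' @return the validated data.frame.
#' @export
validate_samples <- function(df, schema = c("consumer", "source", "environment"),
                             areas = NULL, seasons = NULL, guilds = NULL) {
  schema <- match.arg(schema)
  cols <- SCHEMA_COLUMNS[[schema]]
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_input("input error: missing column(s) for ", schema, " schema: ",
                paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("0-row ", schema, " table", call. = FALSE)
    return(df)
  }
  numeric_cols <- if (schema == "environment") ENV_VARIABLES
                  else c("d13c", "d15n")
  for (cl in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad)) {
      abort_input("input error: unparseable number in column '", cl,
                  "' at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    }
    df[[cl]] <- v
  }
  if (schema != "environment") {
    check_envelope(df, "d13c", D13C_RANGE)
    check_envelope(df, "d15n", D15N_RANGE)
  }
  check_vocab <- function(col, vocab) {
    if (is.null(vocab) || !col %in% names(df)) return(invisible())
    bad <- which(!df[[col]] %in% vocab)
    if (length(bad)) {
      abort_input("input error: unknown ", col, " '", df[[col]][bad[1]],
                  "' at row ", bad[1])
    }
  }
  check_vocab("area", areas)
  check_vocab("season", seasons)
  check_vocab("guild", guilds)
  df
}

check_envelope <- function(df, col, range) {
  v <- df[[col]]
  bad <- which(!is.na(v) & (v < range[1] | v > range[2]))
  if (length(bad)) {
    abort_input("input error: ", col, " = ", v[bad[1]], " at row ", bad[1],
                " outside envelope [", range[1], ", ", range[2], "]")
  }
  invisible()
}

#' Default analysis configuration
#'
#' The analysis constants: per-trophic-level discrimination factors of
#' 0.4 per-mil (carbon) and 3.4 per-mil (nitrogen) used to de-enrich
#' consumers; a zero-mean model discrimination with SDs 1.3 (C) and 1.0 (N)
#' per-mil inside the mixing model; guild trophic levels (piscivore 3.0,
#' zoobenthivore 2.7, planktivore 2.6, omnivore 2.6, detritivore 2.4);
#' MCMC settings of 3 chains, 300,000 iterations, 200,000 burn-in,
#' thinning 100; 95% credibility; a 0.6 loading threshold for PCA
#' interpretation; alpha 0.05.
#'
#' @param seed root seed recorded in the config.
#' @return an object of class `analysis_config` (a named list).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    tdf_per_level = c(d13c = 0.4, d15n = 3.4),
    model_tdf = list(mean = c(d13c = 0, d15n = 0),
                     sd = c(d13c = 1.3, d15n = 1.0)),
    trophic_levels = c(piscivore = 3.0, zoobenthivore = 2.7,
                       planktivore = 2.6, omnivore = 2.6, detritivore = 2.4),
    mcmc = list(chains = 3L, iterations = 300000L, burn_in = 200000L,
                thin = 100L),
    credibility = 0.95,
    hypervolume = list(mass_quantile = 0.95, n_mc = 10000L,
                       point_density = 100, bootstrap_reps = 100L),
    correlation_threshold = 0.6,
    polygon_threshold = 0.05,
    lipid_cn_threshold = 3.5,
    pca_loading_threshold = 0.6,
    alpha = 0.05,
    reference_area = "RefM",
    seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Load an analysis configuration from YAML
#'
#' Unspecified keys fall back to [default_config()] values; the fully
#' resolved configuration is validated and returned. Resolution is
#' idempotent: loading a written resolved config reproduces it.
#'
#' @param path YAML file path; an empty file yields the defaults.
#' @param seed root seed used when the file does not set one.
#' @return an `analysis_config`.
#' @export
load_config <- function(path, seed = 1L) {
  user <- if (file.exists(path)) yaml::read_yaml(path) else
    abort_input("configuration error: file not found: ", path)
  if (is.null(user)) user <- list()
  cfg <- modify_defaults(unclass(default_config(seed)), user)
  cfg <- structure(cfg, class = "analysis_config")
  validate_config(cfg)
}

# recursive defaults <- user overlay
modify_defaults <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- modify_defaults(defaults[[k]], user[[k]])
    } else if (is.numeric(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
               is.list(user[[k]])) {
      v <- unlist(user[[k]])
      defaults[[k]][names(v)] <- v
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Write a configuration to YAML
#'
#' Serializes an `analysis_config` (or any configuration list) so that
#' named vectors become YAML maps and the file round-trips through
#' [load_config()] unchanged.
#'
#' @param config configuration list.
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(yamlable(unclass(config)), path)
  invisible(path)
}

# named atomic vectors must become lists to survive as YAML maps
yamlable <- function(x) {
  if (is.data.frame(x)) x
  else if (is.list(x)) lapply(x, yamlable)
  else if (is.atomic(x) && !is.null(names(x))) as.list(x)
  else x
}

#' Validate an analysis configuration
#'
#' Enforces the configuration invariants: burn-in shorter than the chain,
#' thinning at least 1, at least 2 chains, credibility in (0, 1), and
#' non-negative SDs.
#'
#' @param config an `analysis_config`.
#' @return the config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  m <- config$mcmc
  if (m$burn_in >= m$iterations) {
    abort_input("configuration error: mcmc burn_in must be < iterations")
  }
  if (m$thin < 1) abort_input("configuration error: mcmc thin must be >= 1")
  if (m$chains < 2) abort_input("configuration error: mcmc chains must be >= 2")
  if (config$credibility <= 0 || config$credibility >= 1) {
    abort_input("configuration error: credibility must be in (0, 1)")
  }
  if (any(config$model_tdf$sd < 0)) {
    abort_input("configuration error: model_tdf sd must be >= 0")
  }
  invisible(config)
}

#' Desk-scale MCMC profile
#'
#' A short sampling profile (3 chains, 30,000 iterations, 10,000 burn-in,
#' thinning 20; 1,000 retained draws per chain) adequate for K <= 5 sources
#' and used throughout the tests and examples. The long 300,000-iteration
#' profile of [default_config()] remains the default for full analyses.
#'
#' @return an MCMC settings list.
#' @export
mcmc_desk_profile <- function() {
  list(chains = 3L, iterations = 30000L, burn_in = 10000L, thin = 20L)
}
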