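# Run configuration (YAML/JSON) and the reproducibility manifest.

#' Read a run configuration file
#'
#' A run configuration bundles everything a pipeline stage needs: file
#' paths, normalization rules, classifier parameters, the match strategies
#' to run, an optional simulation section, and a seed. Any section may be
#' omitted, in which case package defaults apply. Strategies may be given
#' either as names of the six study strategies or as explicit
#' `{name, combinator, identifiers}` blocks.
#'
#' @param path Path to a YAML (or JSON — YAML is a superset) file.
#' @return A `run_config` list with elements `paths`, `rules`, `params`,
#'   `strategies`, `strategy`, `simulation`, `cohort`, `mode`, `seed`,
#'   `out_dir`, plus `config_path` for the manifest.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
      class = "fairlink_config_error"
    )
  }
  raw <- yaml::read_yaml(path)
  cfg <- build_run_config(raw)
  cfg$config_path <- path
  cfg
}

build_run_config <- function(raw) {
  raw <- raw %||% list()

  rules <- {
    nz <- raw$normalization %||% list()
    ins <- nz$insurance_rules
    ins_rules <- if (is.null(ins)) {
      default_insurance_rules()
    } else {
      lapply(ins, function(r) {
        insurance_rule(
          pattern = r$pattern, mode = r$mode,
          delimiter = r$delimiter, suffix_length = r$suffix_length
        )
      })
    }
    abbr <- nz$address_abbreviations
    normalization_rules(
      insurance_rules = ins_rules,
      phone_min_digits = nz$phone_min_digits %||% 10L,
      address_abbreviations = if (is.null(abbr)) {
        default_address_abbreviations()
      } else {
        unlist(abbr)
      }
    )
  }

  cl <- raw$classifier %||% list()
  reference_date <- as.Date(
    cl$reference_date %||% raw$reference_date %||% "2014-06-30"
  )
  params <- classifier_params(
    reference_date = reference_date,
    min_age_gap_years = cl$min_age_gap_years %||% 15L,
    max_age_gap_years = cl$max_age_gap_years %||% 50L,
    tie_break_cascade = if (is.null(cl$tie_break_cascade)) {
      list(c("insurance", "phone"), "insurance", "phone")
    } else {
      lapply(cl$tie_break_cascade, unlist)
    }
  )

  known <- study_strategies()
  as_strategy <- function(s) {
    if (is.character(s) && length(s) == 1) {
      if (!s %in% names(known)) {
        abort(
          paste0(
            "unknown strategy '", s, "'; valid names: ",
            paste(names(known), collapse = ", ")
          ),
          class = "fairlink_config_error"
        )
      }
      known[[s]]
    } else {
      match_strategy(s$name, s$combinator, unlist(s$identifiers))
    }
  }
  strategies <- lapply(raw$strategies %||% names(known), as_strategy)
  names(strategies) <- vapply(strategies, `[[`, character(1), "name")
  strategy <- as_strategy(raw$strategy %||% "insurance_or_phone")

  simulation <- NULL
  if (!is.null(raw$simulation)) {
    simulation <- do.call(simulation_config, raw$simulation)
  }

  co <- raw$cohort %||% list()
  cohort <- list(
    max_age_years = co$max_age_years %||% 17L,
    sample_size = co$sample_size,
    area_code = co$area_code
  )

  list(
    paths = raw$paths %||% list(),
    out_dir = raw$out_dir %||% ".",
    rules = rules,
    params = params,
    strategies = strategies,
    strategy = strategy,
    simulation = simulation,
    cohort = cohort,
    mode = raw$mode %||% "per_child",
    seed = as.integer(raw$seed %||% 1L)
  )
}

#' Write a reproducibility manifest for a run
#'
#' Records the configuration file's MD5 hash, the seed, and package and R
#' versions — enough to re-run the stage and obtain byte-identical outputs.
#'
#' @param out_dir Directory the manifest is written to.
#' @param config A `run_config` from [read_run_config()].
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(out_dir, config) {
  manifest <- list(
    config_path = config$config_path %||% NA_character_,
    config_md5 = if (!is.null(config$config_path)) {
      unname(tools::md5sum(config$config_path))
    } else {
      NA_character_
    },
    seed = config$seed,
    fairlink_version = as.character(utils::packageVersion("fairlink")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
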