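#' Read a covariate table
#'
#' Reads a tab-separated `participants.tsv`-style table with mandatory
#' columns `subject_id`, `group`, `age`, `site`. Ages are parsed as numeric
#' years; records with missing age are kept but flagged (`age_missing`) and
#' a warning is raised, so downstream probes can exclude them.
#'
#' @param path path to a TSV file.
#' @return A data frame with an extra logical column `age_missing`.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("NA", "n/a", ""))
  required <- c("subject_id", "group", "age", "site")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("covariate table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id in covariate table: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]),
               collapse = ", "))
  tab$age <- suppressWarnings(as.numeric(tab$age))
  tab$age_missing <- !is.finite(tab$age)
  if (any(tab$age_missing))
    warning(sum(tab$age_missing),
            " record(s) have missing age and are flagged; they will be",
            " excluded from age probes")
  tab
}

#' Read a run configuration from YAML
#'
#' Loads a nested configuration (sections `phantom`, `effect`, `cohort`,
#' `model`, `train`, `stats`, `probe`, plus optional top-level `seed` and
#' `output_dir`). Unknown sections or unknown keys within a section are
#' rejected, so typos fail loudly rather than silently using defaults.
#'
#' @param path path to a YAML file.
#' @return A list with `config` (an [experiment_config()]), `seed`,
#'   `output_dir`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 1L
  output_dir <- raw$output_dir
  raw$seed <- NULL; raw$output_dir <- NULL
  defaults <- experiment_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (nm in names(raw)) {
    bad <- setdiff(names(raw[[nm]]), names(defaults[[nm]]))
    if (length(bad))
      stop("unknown key(s) in section '", nm, "': ",
           paste(bad, collapse = ", "))
  }
  cfg <- do.call(experiment_config, raw)
  list(config = cfg, seed = as.integer(seed), output_dir = output_dir)
}

#' Write a run manifest
#'
#' Every artifact-producing command records its inputs, a hash of the
#' configuration, the seed, and the package version, so a report can be tied
#' to the exact run that produced it.
#'
#' @param dir output directory.
#' @param inputs character vector of input/output file names.
#' @param config the configuration list used.
#' @param seed the seed used.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, inputs = character(0), config = list(),
                           seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE), tmp)
  hash <- unname(tools::md5sum(tmp))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(files = inputs, config_md5 = hash, seed = seed,
                            package = "cyclemorph",
                            version = as.character(
                              utils::packageVersion("cyclemorph")),
                            timestamp = format(Sys.time(), tz = "UTC")),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
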