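# Readers and writers for the formats the pipeline exchanges: FASTA for
# sequences (via Biostrings; wrapped lines and mixed case tolerated,
# sequences upper-cased internally), TSV for CDR frequency tables, CSV for
# plates and verdicts, YAML for scenario configs, JSON for summaries and
# run manifests.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (DNA, RNA or protein; may be line-wrapped).
#' @return Tibble with `name`, `seq` (upper-cased).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  tibble::tibble(name = names(set), seq = unname(toupper(as.character(set))))
}

#' Write sequences to a FASTA file
#'
#' @param df Data frame with `name` and `seq` columns (or `clone_id` plus
#'   a column named by `seq_col`).
#' @param path Output path.
#' @param seq_col Column holding the sequence (default `"seq"`).
#' @param overwrite Allow replacing an existing file (default FALSE).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(df, path, seq_col = "seq", overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    abort(paste0(path, " exists; set overwrite = TRUE to replace it"))
  }
  nm <- if ("name" %in% names(df)) df$name else df$clone_id
  set <- Biostrings::BStringSet(setNames(toupper(df[[seq_col]]), nm))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a CDR frequency table from TSV
#'
#' Expects columns `position`, `residue`, `frequency` (and optionally
#' `cdr_id`); validates that frequencies sum to 1 per position.
#'
#' @param path TSV file.
#' @return Tibble.
#' @export
read_cdr_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  validate_cdr_table(tab)
  tab
}

#' Write a CDR frequency table to TSV
#'
#' @param tab Frequency tibble.
#' @param path Output path.
#' @param overwrite Allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_cdr_table <- function(tab, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    abort(paste0(path, " exists; set overwrite = TRUE to replace it"))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ELISA plate table from CSV
#'
#' @param path CSV with header `clone_id`, `a450_target`, `a450_control`.
#' @return Tibble.
#' @export
read_elisa_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Serialize a scenario to YAML
#'
#' @param scenario Output of [make_scenario()].
#' @param path Output path.
#' @param overwrite Allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    abort(paste0(path, " exists; set overwrite = TRUE to replace it"))
  }
  doc <- list(
    preset = scenario$preset,
    scaled = scenario$scaled,
    population = lapply(seq_len(nrow(scenario$population)), function(i) {
      as.list(scenario$population[i, ])
    }),
    classes = lapply(seq_len(nrow(scenario$classes)), function(i) {
      as.list(scenario$classes[i, ])
    }),
    rounds = lapply(scenario$rounds, function(cfg) {
      cfg <- unclass(cfg)
      cfg$detection <- unclass(cfg$detection)
      cfg
    }))
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Read a scenario from YAML
#'
#' @param path YAML file written by [write_scenario()].
#' @return Scenario list as produced by [make_scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  doc <- yaml::read_yaml(path)
  list(
    preset = doc$preset,
    scaled = doc$scaled,
    population = clone_population(purrr::map_dfr(doc$population, tibble::as_tibble)),
    classes = purrr::map_dfr(doc$classes, tibble::as_tibble),
    rounds = lapply(doc$rounds, function(cfg) {
      det <- do.call(pcr_model, cfg$detection)
      cfg$detection <- NULL
      cfg$input_size <- cfg$input_size %||% NULL
      do.call(panning_config, c(cfg, list(detection = det)))
    }))
}

#' Write a run manifest
#'
#' Records inputs, seed and package version alongside a run's outputs so a
#' result directory is self-describing.
#'
#' @param path Output JSON path.
#' @param inputs Named list or character vector of input descriptors.
#' @param seed Seed used for the run (may be NULL).
#' @param extra Optional named list of extra fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, inputs = list(), seed = NULL, extra = list()) {
  manifest <- c(list(
    package = "puredisplay",
    version = as.character(utils::packageVersion("puredisplay")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    inputs = inputs), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
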