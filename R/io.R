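# Readers and writers for the pipeline's tabular and image artifacts.
# Tables are CSV (diff-able, language-neutral); images are 16-bit TIFF.

#' Read and validate a plate layout
#'
#' Schema: columns `plate`, `well`, `role`, `gene`; one gene per well; roles
#' restricted to library / scrambled / PLK1 / OR10A5 / NCAPH2.
#'
#' @param path CSV file path.
#' @return Validated layout tibble.
#' @export
read_layout <- function(path) {
  layout <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  validate_layout(layout)
}

#' @rdname read_layout
#' @param layout An in-memory layout tibble.
#' @export
validate_layout <- function(layout) {
  required <- c("plate", "well", "role", "gene")
  miss <- setdiff(required, names(layout))
  if (length(miss) > 0L) {
    rlang::abort(sprintf("layout is missing column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  dup <- layout |>
    dplyr::count(.data$plate, .data$well) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    rlang::abort(sprintf("plate %s well %s is assigned more than one gene",
                         dup$plate[1], dup$well[1]))
  }
  bad_role <- setdiff(unique(layout$role),
                      c("library", "scrambled", "PLK1", "OR10A5", "NCAPH2"))
  if (length(bad_role) > 0L) {
    rlang::abort(sprintf("unknown layout role(s): %s",
                         paste(bad_role, collapse = ", ")))
  }
  layout
}

#' Write a table with a provenance header
#'
#' Prepends `# stage: <stage>` and `# config_hash: <hash>` comment lines so
#' every artifact names the stage that produced it.
#'
#' @param x Tibble to write.
#' @param path Output CSV path.
#' @param stage Producing stage name.
#' @param config_hash Hash of the run configuration.
#' @export
write_stage_csv <- function(x, path, stage, config_hash = "") {
  header <- c(sprintf("# stage: %s", stage),
              sprintf("# config_hash: %s", config_hash))
  writeLines(header, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_stage_csv
#' @export
read_stage_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Write / read a 16-bit TIFF image
#'
#' Integer counts are stored losslessly as 16-bit samples.
#'
#' @param image Numeric matrix with values in `[0, 65535]`.
#' @param path File path.
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  round(tiff::readTIFF(path) * 65535)
}

#' Read / write a run configuration
#'
#' Configurations are YAML key-value files; [run_pipeline()] validates them.
#'
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config Configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
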