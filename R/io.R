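#' Read a field-metadata dictionary
#'
#' Tab-separated with columns `field_id`, `field_type` (one of integer,
#' continuous, categorical-single, categorical-multiple), `ordering`
#' (ordered / unordered / unspecified), `reference` (baseline code, optional)
#' and `category_order` (comma-separated codes from lowest to highest,
#' optional).
#'
#' @param path Path to the TSV file.
#' @return A tibble with the columns above (all character except `field_id`,
#'   kept character too since biobank ids are opaque).
#' @export
read_field_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  required <- c("field_id", "field_type")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    abort(paste0("metadata lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(meta$field_type), field_types)
  if (length(bad)) {
    abort(paste0("unsupported field types: ", paste(bad, collapse = ", ")))
  }
  if (!"ordering" %in% names(meta)) meta$ordering <- "unspecified"
  meta$ordering[is.na(meta$ordering)] <- "unspecified"
  if (!"reference" %in% names(meta)) meta$reference <- NA_character_
  if (!"category_order" %in% names(meta)) meta$category_order <- NA_character_
  meta
}

#' Write a field-metadata dictionary
#' @param metadata Metadata tibble.
#' @param path Output TSV path.
#' @export
write_field_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path)
  invisible(path)
}

#' Read a participant phenotype table
#'
#' Tab- or comma-separated text with a header; must contain a
#' `participant_id` column with unique values.  Field columns are named
#' `f<field_id>` (categorical-multiple array slots `f<field_id>_<k>`); every
#' field column must be declared in the metadata.  Non-field columns
#' (covariates, strata, dosages) pass through unchanged.
#'
#' @param path Path to the delimited file.
#' @param metadata Field-metadata tibble ([read_field_metadata()]).
#'
#' @return A tibble, one row per participant.
#' @export
read_phenotypes <- function(path, metadata) {
  data <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!"participant_id" %in% names(data)) {
    abort("phenotype table lacks a 'participant_id' column")
  }
  dup <- data$participant_id[duplicated(data$participant_id)]
  if (length(dup)) {
    abort(paste0("duplicate participant ids: ",
                 paste(unique(dup), collapse = ", ")))
  }
  fcols <- grep("^f", names(data), value = TRUE)
  base <- sub("_[0-9]+$", "", fcols)
  ids <- unique(sub("^f", "", base))
  unknown <- setdiff(ids, metadata$field_id)
  if (length(unknown)) {
    abort(paste0("fields missing from metadata: ",
                 paste(unknown, collapse = ", ")))
  }
  data
}

#' Write a synthetic biobank to delimited files
#'
#' Emits `phenotypes.tsv`, `metadata.tsv` and `truth.tsv` into `dir`, in the
#' same formats [read_phenotypes()] and [read_field_metadata()] read.
#'
#' @param biobank A [simulate_biobank()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_biobank <- function(biobank, dir) {
  stopifnot(inherits(biobank, "synthetic_biobank"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(biobank$phenotypes, file.path(dir, "phenotypes.tsv"))
  readr::write_tsv(biobank$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(biobank$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Write a results table as TSV
#'
#' Fixed column order, UTF-8, `NA` for missing values, and P values in
#' scientific notation with three significant digits.
#'
#' @param results A `phewas_scan`, `gxe_ranking` or plain results tibble.
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  out <- tibble::as_tibble(results)
  for (col in intersect(c("p", "p_interaction"), names(out))) {
    out[[col]] <- format_p(out[[col]])
  }
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Compose a run summary text block
#'
#' @param n_tests Number of tests performed.
#' @param selection An [fdr_select()] result.
#' @param seed Seed used for the run (if any).
#' @param extra Optional named character vector of additional lines.
#' @return Character vector of summary lines.
#' @export
run_summary <- function(n_tests, selection, seed = NULL, extra = NULL) {
  lines <- c(
    sprintf("gxescan %s", as.character(utils::packageVersion("gxescan"))),
    sprintf("tests performed: %d", n_tests),
    sprintf("alpha: %g", selection$alpha),
    sprintf("Bonferroni threshold: %s", format_p(selection$bonferroni)),
    sprintf("FDR hits (step-up): %d", selection$k),
    sprintf("FDR threshold: %s",
            if (is.na(selection$threshold)) "not applicable"
            else format_p(selection$threshold)),
    sprintf("seed: %s", if (is.null(seed)) "none" else as.character(seed)))
  c(lines, if (!is.null(extra)) sprintf("%s: %s", names(extra), extra))
}

#' Write derived outcomes, one delimited file per data type
#'
#' Emits `continuous.csv`, `binary.csv`, `ordered.csv`, `unordered.csv`
#' (participants by outcomes; only types present are written), an
#' `outcomes.tsv` index (id, type, categories, reference, field id, value
#' code) and a `decisions.log` with one provenance record per outcome.
#'
#' @param derived A [derive_outcomes()] tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_derived_outcomes <- function(derived, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  info <- tibble::tibble(
    outcome_id = derived$outcome_id,
    field_id = derived$field_id,
    value_code = derived$value_code,
    data_type = derived$data_type,
    reference = derived$reference,
    categories = vapply(derived$categories, function(x) {
      if (is.null(x)) NA_character_ else paste(x, collapse = ",")
    }, character(1)))
  readr::write_tsv(info, file.path(dir, "outcomes.tsv"))
  for (dt in unique(derived$data_type)) {
    rows <- which(derived$data_type == dt)
    cols <- lapply(rows, function(i) as.character(derived$values[[i]]))
    names(cols) <- derived$outcome_id[rows]
    readr::write_csv(tibble::as_tibble(cols), file.path(dir,
                                                        paste0(dt, ".csv")),
                     na = "NA")
  }
  log_lines <- unlist(lapply(seq_len(nrow(derived)), function(i) {
    paste0(derived$outcome_id[i], ": ",
           paste(derived$provenance[[i]], collapse = "; "))
  }))
  dropped <- attr(derived, "dropped")
  if (!is.null(dropped) && nrow(dropped)) {
    log_lines <- c(log_lines,
                   paste0(dropped$field_id, ": dropped (", dropped$reason,
                          ")"))
  }
  writeLines(log_lines, file.path(dir, "decisions.log"))
  invisible(dir)
}

#' Read derived outcomes written by [write_derived_outcomes()]
#'
#' @param dir Directory produced by [write_derived_outcomes()].
#' @return A `derived_outcomes` tibble (provenance reduced to a pointer at
#'   the on-disk log).
#' @export
read_derived_outcomes <- function(dir) {
  info <- readr::read_tsv(file.path(dir, "outcomes.tsv"),
                          col_types = readr::cols(
                            .default = readr::col_character()))
  values <- vector("list", nrow(info))
  for (dt in unique(info$data_type)) {
    tab <- readr::read_csv(file.path(dir, paste0(dt, ".csv")),
                           col_types = readr::cols(
                             .default = readr::col_character()),
                           progress = FALSE)
    for (i in which(info$data_type == dt)) {
      v <- tab[[info$outcome_id[i]]]
      values[[i]] <- switch(
        dt,
        continuous = as.numeric(v),
        binary = {
          lev <- strsplit(info$categories[i], ",")[[1]]
          if (all(v %in% c("0", "1", NA))) as.integer(v)
          else factor(v, levels = lev)
        },
        ordered = factor(v, levels = strsplit(info$categories[i], ",")[[1]],
                         ordered = TRUE),
        unordered = factor(v, levels = strsplit(info$categories[i], ",")[[1]]))
    }
  }
  out <- tibble::tibble(
    outcome_id = info$outcome_id, field_id = info$field_id,
    value_code = info$value_code, data_type = info$data_type,
    values = values,
    categories = lapply(info$categories, function(x) {
      if (is.na(x)) NULL else strsplit(x, ",")[[1]]
    }),
    reference = info$reference,
    provenance = rep(list("see decisions.log"), nrow(info)))
  class(out) <- c("derived_outcomes", class(out))
  out
}
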