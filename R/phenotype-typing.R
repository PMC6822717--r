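#' Rule-based typing of raw biobank fields
#'
#' Converts heterogeneous biobank fields into typed, analysis-ready outcomes
#' using an automated rule tree in the PHESANT tradition.  Each raw field
#' carries a declared *field type* (`integer`, `continuous`,
#' `categorical-single`, `categorical-multiple`) in its metadata; the rules
#' assign each derived outcome one of four *data types* (`continuous`,
#' `binary`, `ordered`, `unordered`) that determines the regression model the
#' scan stage will fit.
#'
#' @name phenotype_typing
NULL

field_types <- c("integer", "continuous", "categorical-single",
                 "categorical-multiple")
data_types <- c("continuous", "binary", "ordered", "unordered")

#' Assign a data type to one raw field
#'
#' Deterministic rules: a `categorical-single` field with exactly two observed
#' values becomes `binary`; with more it follows its declared ordering
#' (`ordered`/`unordered`; an unspecified ordering is a configuration error,
#' since orderedness cannot be inferred from codes).  `integer` and
#' `continuous` fields become `continuous` unless they have at most
#' `max_ordered_levels` distinct values, in which case they are reassigned to
#' `ordered`.
#'
#' @param meta One-row field-metadata data frame (see
#'   [read_field_metadata()]).
#' @param values Raw value vector for the field.
#' @param max_ordered_levels Distinct-value cutoff below which an
#'   integer/continuous field is treated as ordered categorical.
#'
#' @return A list with `data_type` (or `NA` if the outcome is dropped) and a
#'   character `provenance` log of the rule decisions.
#' @export
assign_data_type <- function(meta, values, max_ordered_levels = 20) {
  ft <- meta$field_type
  if (!ft %in% field_types) {
    abort(sprintf("unsupported field type '%s' for field %s", ft,
                  meta$field_id))
  }
  obs <- unique(values[!is.na(values)])
  prov <- sprintf("field type '%s'; %d distinct observed values", ft,
                  length(obs))
  if (ft == "categorical-multiple") {
    abort("categorical-multiple fields must go through expand_categorical_multiple()")
  }
  if (ft == "categorical-single") {
    if (length(obs) < 2L) {
      return(list(data_type = NA_character_,
                  provenance = c(prov, "dropped: fewer than 2 observed values")))
    }
    if (length(obs) == 2L) {
      return(list(data_type = "binary",
                  provenance = c(prov, "two distinct values -> binary")))
    }
    ord <- meta$ordering %||% "unspecified"
    if (is.na(ord) || ord == "unspecified") {
      abort(sprintf(
        "field %s: multi-level categorical-single fields must declare 'ordered' or 'unordered' in the metadata",
        meta$field_id))
    }
    return(list(data_type = ord,
                provenance = c(prov, paste0("declared ordering -> ", ord))))
  }
  # integer / continuous field types
  if (length(obs) < 2L) {
    return(list(data_type = NA_character_,
                provenance = c(prov, "dropped: constant or empty")))
  }
  if (length(obs) <= max_ordered_levels) {
    list(data_type = "ordered",
         provenance = c(prov, sprintf(
           "<= %d distinct values -> ordered categorical",
           max_ordered_levels)))
  } else {
    list(data_type = "continuous",
         provenance = c(prov, "-> continuous"))
  }
}

#' Expand a categorical-multiple field into binary outcomes
#'
#' Emits one binary outcome per distinct recorded value: participants holding
#' the value (in any of the field's array columns) are `1`, everyone else is
#' `0`.  No participant is missing, mirroring the convention that absence of a
#' recorded code is treated as a negative rather than as missing data.
#'
#' @param meta One-row field-metadata data frame.
#' @param values A list-column or data frame of the field's array columns; a
#'   plain data frame of columns is interpreted one column per array slot.
#'
#' @return A tibble with one row per derived outcome: `outcome_id`,
#'   `field_id`, `value_code`, `data_type` ("binary") and a `values`
#'   list-column of 0/1 vectors.
#' @export
expand_categorical_multiple <- function(meta, values) {
  if (meta$field_type != "categorical-multiple") {
    abort("expand_categorical_multiple() requires a categorical-multiple field")
  }
  if (is.data.frame(values)) values <- as.list(values)
  if (!is.list(values)) values <- list(values)
  n <- length(values[[1]])
  codes <- sort(unique(unlist(lapply(values, function(v) v[!is.na(v)]))))
  if (length(codes) == 0L) {
    warn(sprintf("field %s: no recorded values; no outcomes derived",
                 meta$field_id))
    return(tibble::tibble(outcome_id = character(), field_id = character(),
                          value_code = character(), data_type = character(),
                          values = list()))
  }
  held <- matrix(FALSE, n, length(codes), dimnames = list(NULL, codes))
  for (v in values) {
    idx <- !is.na(v)
    held[cbind(which(idx), match(v[idx], codes))] <- TRUE
  }
  tibble::tibble(
    outcome_id = paste0(meta$field_id, "#", codes),
    field_id = meta$field_id,
    value_code = as.character(codes),
    data_type = "binary",
    values = lapply(seq_along(codes), function(j) as.integer(held[, j])))
}

#' Inverse normal rank transformation
#'
#' Replaces non-missing values by standard-normal quantiles of their rank
#' offsets, so that any continuous outcome is normally distributed before the
#' linear scan.  The default offset is `(rank - 0.5) / m` with `m` the
#' non-missing count; Blom's `(rank - 3/8) / (m + 1/4)` is available.  Ties
#' are broken by random permutation (average ranks would create point masses
#' and defeat the purpose of the transform); supply `seed` for a reproducible
#' break.
#'
#' @param values Numeric vector, possibly with missing entries.
#' @param offset Rank-offset convention, `"midpoint"` or `"blom"`.
#' @param seed Optional integer seed for the tie-breaking permutation.
#'
#' @return Numeric vector of the same length; missing entries stay missing.
#' @export
#' @examples
#' inverse_normal_transform(c(10, 20, 30))  # -0.967, 0, 0.967
inverse_normal_transform <- function(values,
                                     offset = c("midpoint", "blom"),
                                     seed = NULL) {
  offset <- match.arg(offset)
  obs <- !is.na(values)
  m <- sum(obs)
  if (m < 2L) abort("inverse normal transform needs at least 2 non-missing values")
  if (length(unique(values[obs])) == 1L) {
    abort("all non-missing values identical; transform undefined")
  }
  r <- with_seed_if(seed, rank(values[obs], ties.method = "random"))
  q <- switch(offset,
              midpoint = (r - 0.5) / m,
              blom = (r - 3 / 8) / (m + 1 / 4))
  out <- rep(NA_real_, length(values))
  out[obs] <- qnorm(q)
  out
}

#' Derive typed outcomes from a raw phenotype table
#'
#' Applies the typing rules to every field in the metadata: single-valued
#' fields via [assign_data_type()], categorical-multiple fields via
#' [expand_categorical_multiple()], and the inverse normal rank transform to
#' every outcome assigned the continuous data type.  Typing is performed once
#' on the full sample so that the same data types are used in every stratum
#' downstream.
#'
#' @param data Phenotype table; field columns are named `f<field_id>`
#'   (categorical-multiple array columns `f<field_id>_<slot>`).
#' @param metadata Field-metadata tibble (see [read_field_metadata()]).
#' @param max_ordered_levels Passed to [assign_data_type()].
#' @param int_offset Rank-offset convention for the inverse normal transform.
#' @param seed Optional integer seed governing tie-breaks in the transform.
#'
#' @return A tibble of class `derived_outcomes`: one row per derived outcome
#'   with `outcome_id`, `field_id`, `value_code`, `data_type`, a `values`
#'   list-column aligned to the rows of `data`, `categories`, `reference` and
#'   `provenance` list-columns.  Dropped fields are recorded in the
#'   `"dropped"` attribute with their reasons.
#' @export
derive_outcomes <- function(data, metadata, max_ordered_levels = 20,
                            int_offset = c("midpoint", "blom"), seed = NULL) {
  int_offset <- match.arg(int_offset)
  rows <- list()
  dropped <- list()
  with_seed_if(seed, {
    for (i in seq_len(nrow(metadata))) {
      meta <- metadata[i, ]
      fid <- meta$field_id
      if (meta$field_type == "categorical-multiple") {
        cols <- grep(paste0("^f", fid, "(_|$)"), names(data), value = TRUE)
        if (length(cols) == 0L) {
          dropped[[fid]] <- "field absent from phenotype table"
          next
        }
        exp <- expand_categorical_multiple(meta, data[cols])
        if (nrow(exp) > 0L) {
          exp$categories <- rep(list(c("0", "1")), nrow(exp))
          exp$reference <- "0"
          exp$provenance <- lapply(exp$value_code, function(v) {
            c("categorical-multiple field",
              sprintf("binary outcome for value '%s'; absence coded 0", v))
          })
          rows[[length(rows) + 1L]] <- exp
        }
        next
      }
      colname <- paste0("f", fid)
      if (!colname %in% names(data)) {
        dropped[[fid]] <- "field absent from phenotype table"
        next
      }
      values <- data[[colname]]
      typed <- assign_data_type(meta, values,
                                max_ordered_levels = max_ordered_levels)
      if (is.na(typed$data_type)) {
        dropped[[fid]] <- typed$provenance[length(typed$provenance)]
        next
      }
      dt <- typed$data_type
      prov <- typed$provenance
      categories <- NULL
      reference <- NA_character_
      if (dt == "continuous") {
        values <- inverse_normal_transform(as.numeric(values),
                                           offset = int_offset)
        prov <- c(prov, sprintf(
          "inverse normal rank transform (%s offset, random tie-break)",
          int_offset))
      } else if (dt == "ordered") {
        lev <- if (!is.na(meta$category_order %||% NA)) {
          strsplit(meta$category_order, ",")[[1]]
        } else {
          as.character(sort(unique(values[!is.na(values)])))
        }
        values <- factor(as.character(values), levels = lev, ordered = TRUE)
        categories <- lev
        prov <- c(prov, paste0("category order: {",
                               paste(lev, collapse = " < "), "}"))
      } else {
        lev <- as.character(sort(unique(values[!is.na(values)])))
        ref <- meta$reference %||% NA_character_
        if (is.na(ref) || !ref %in% lev) ref <- lev[1]
        lev <- c(ref, setdiff(lev, ref))
        values <- factor(as.character(values), levels = lev)
        categories <- lev
        reference <- ref
        prov <- c(prov, paste0("reference category: ", ref))
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        outcome_id = fid, field_id = fid, value_code = NA_character_,
        data_type = dt, values = list(values), categories = list(categories),
        reference = reference, provenance = list(prov))
    }
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(outcome_id = character(), field_id = character(),
                   value_code = character(), data_type = character(),
                   values = list(), categories = list(),
                   reference = character(), provenance = list())
  }
  if (!"categories" %in% names(out)) out$categories <- list(NULL)
  attr(out, "dropped") <- if (length(dropped)) {
    tibble::tibble(field_id = names(dropped),
                   reason = unlist(dropped, use.names = FALSE))
  } else {
    tibble::tibble(field_id = character(), reason = character())
  }
  class(out) <- c("derived_outcomes", class(out))
  out
}

#' Stratum-level testability filters
#'
#' An outcome is testable in a stratum only if it has at least `min_n`
#' non-missing participants there and, for binary and unordered categorical
#' outcomes, at least `min_per_category` participants in every category.
#'
#' @param outcomes A [derive_outcomes()] tibble.
#' @param stratum_mask Logical vector selecting the stratum's rows.
#' @param min_n Minimum non-missing participants per stratum.
#' @param min_per_category Minimum participants per category (binary and
#'   unordered outcomes only).
#'
#' @return A tibble with `outcome_id`, `include` and `reason`.
#' @export
apply_stratum_filters <- function(outcomes, stratum_mask, min_n = 500,
                                  min_per_category = 10) {
  res <- purrr::map2_dfr(outcomes$values, outcomes$data_type, function(v, dt) {
    vs <- v[stratum_mask]
    nn <- sum(!is.na(vs))
    if (nn < min_n) {
      return(tibble::tibble(include = FALSE,
                            reason = sprintf("%d non-missing < %d", nn, min_n)))
    }
    if (dt %in% c("binary", "unordered")) {
      counts <- table(vs[!is.na(vs)])
      if (length(counts) < 2L || any(counts < min_per_category)) {
        return(tibble::tibble(include = FALSE,
                              reason = sprintf("category count below %d",
                                               min_per_category)))
      }
    }
    tibble::tibble(include = TRUE, reason = NA_character_)
  })
  dplyr::bind_cols(tibble::tibble(outcome_id = outcomes$outcome_id), res)
}
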