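trials_schema_version <- "confarb_trials_v1"

trial_columns <- function() {
  c("subject_id", "trial_index", "condition_id", "coh_highest", "coh_second",
    "coh_lowest", "pos_highest", "pos_second", "pos_lowest",
    "choice_position", "choice_category", "confidence_raw", "rt_ms")
}

#' Write and read trial data
#'
#' Trial files are plain CSV in the package's documented schema, preceded by
#' a `#`-comment header carrying the schema version and a content hash.
#' `read_trials()` validates the header and column set, rejects malformed
#' rows by line number, recomputes each trial's choice category from its
#' arrangement and cross-checks it against the stored column.
#'
#' @param trials A trial tibble (see [generate_observer()] for the schema).
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` a
#'   validated trial tibble.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(trial_columns(), names(trials))
  if (length(miss) > 0) {
    abort(paste0("Missing trial columns: ", paste(miss, collapse = ", ")))
  }
  trials <- trials[, trial_columns()]
  header <- sprintf("# %s hash:%s", trials_schema_version,
                    rlang::hash(trials))
  writeLines(header, path)
  readr::write_csv(trials, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  first <- readLines(path, n = 1L)
  if (!startsWith(first, paste0("# ", trials_schema_version))) {
    abort(sprintf("File header does not declare schema %s.",
                  trials_schema_version))
  }
  out <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      choice_category = readr::col_character(),
      .default = readr::col_double()
    )
  )
  miss <- setdiff(trial_columns(), names(out))
  if (length(miss) > 0) {
    abort(paste0("File lacks columns: ", paste(miss, collapse = ", ")))
  }
  needed <- c("condition_id", "pos_highest", "pos_second", "pos_lowest",
              "choice_position", "confidence_raw")
  bad <- which(!complete.cases(out[, needed]))
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed row(s) at data line(s): %s (missing required fields).",
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  recomputed <- categorize_choice(out$pos_highest, out$pos_second,
                                  out$pos_lowest, out$choice_position)
  conflict <- which(recomputed != out$choice_category)
  if (length(conflict) > 0) {
    abort(sprintf(
      "Stored choice_category conflicts with arrangement for trial row(s): %s.",
      paste(head(conflict, 10), collapse = ", ")
    ))
  }
  out
}

#' Write and read an experiment design as JSON
#'
#' @param design An `experiment_design`.
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()` an
#'   `experiment_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "experiment_design"))
  payload <- list(
    schema = "confarb_design_v1",
    coherence_scale = attr(design, "coherence_scale"),
    tie_epsilon = attr(design, "tie_epsilon"),
    conditions = tibble::as_tibble(unclass_design(design))
  )
  payload$hash <- rlang::hash(payload)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "confarb_design_v1")) {
    abort("Not a confarb design file.")
  }
  cond <- tibble::as_tibble(payload$conditions)
  structure(cond, class = c("experiment_design", class(cond)),
            coherence_scale = payload$coherence_scale,
            tie_epsilon = payload$tie_epsilon)
}

#' Write an effect-size table with its ranking as CSV
#'
#' @param es An [cohens_d_map()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_effect_sizes <- function(es, path) {
  stopifnot(inherits(es, "effect_size_table"))
  ranking <- rank_conditions(es)
  key <- function(c1, c2, c3) {
    m <- t(apply(cbind(c1, c2, c3), 1L, sort))
    paste(m[, 1], m[, 2], m[, 3])
  }
  rk <- ranking[match(key(es$c1, es$c2, es$c3),
                      key(ranking$c1, ranking$c2, ranking$c3)), ]
  out <- dplyr::mutate(
    tibble::as_tibble(es),
    pair = paste(.data$model_a, .data$model_b, sep = "-"),
    summed_d = rk$summed_d, rank = rk$rank,
    excluded_reason = rk$excluded_reason
  )
  out <- out[, c("c1", "c2", "c3", "pair", "d", "summed_d", "rank",
                 "excluded_reason")]
  writeLines(sprintf("# confarb_effects_v1 hash:%s", rlang::hash(out)), path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
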