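# Scorecard document model: the eight-section template, validation, and
# canonical JSON / Markdown rendering.

scorecard_section_fields <- function() {
  list(
    section_1_general = c("name", "release_date", "version_history",
                          "dataset_size", "dataset_modality",
                          "dataset_provenance", "dataset_intended_use",
                          "dataset_labels", "attribution_licensing",
                          "point_of_contact"),
    section_3_task = c("task_performance", "task_specific_metrics"),
    section_4_human = c("human_study_design", "reader_study_results",
                        "observations_failure_cases"),
    section_5_ethics = c("privacy_anonymization", "biases", "limitations",
                         "recommendations"),
    section_6_usage = c("repository_access", "preprocessing_requirements",
                        "user_documentation", "intended_audience"),
    section_7_generation = c("generation_method",
                             "training_validation_process"),
    section_8_reference = c("purpose", "origin_source", "dataset_size",
                            "clinical_population", "acquisition_devices",
                            "reference_standard", "ground_truth_labels",
                            "metadata", "preprocessing", "known_limitations")
  )
}

scorecard_section_titles <- function() {
  c(section_1_general = "1. Synthetic Data General Information",
    section_2_quality = "2. Data Quality Evaluation (7 Cs Quantitative Results)",
    section_3_task = "3. Task-based Evaluation (Quantitative Results)",
    section_4_human = "4. Human-based Evaluation (Qualitative Results)",
    section_5_ethics = "5. Ethical, Legal, and Practical Considerations",
    section_6_usage = "6. Synthetic Dataset Usage",
    section_7_generation = "7. Synthetic Dataset Training & Validation Process",
    section_8_reference = "8. Reference Dataset General Information")
}

# Convert a criterion_score (or not-applicable marker) to the plain-list
# entry stored in scorecard section 2.
criterion_entry <- function(x, criterion) {
  if (is.null(x)) {
    return(list(status = "not-applicable",
                reason = "no inputs configured for this criterion"))
  }
  if (is.character(x)) {
    return(list(status = "not-applicable", reason = x))
  }
  stopifnot(inherits(x, "criterion_score"))
  metrics <- lapply(x$members, function(r) {
    spec <- tryCatch(lookup_metric(r$metric), error = function(e) NULL)
    list(name = r$metric,
         raw_value = if (length(r$raw_value) == 1L && is.na(r$raw_value))
           "not assessable" else r$raw_value,
         normalized = r$normalized,
         direction = if (!is.null(spec)) spec$direction else "unspecified",
         per_subgroup = r$per_subgroup,
         params = r$params)
  })
  list(status = "computed", score = x$score, label = x$label,
       method = x$method, weights = x$weights, metrics = metrics)
}

#' Assemble a scorecard document
#'
#' Builds the eight-section scorecard: descriptive sections come verbatim
#' from user-supplied fields (sections 1, 3-8; missing fields are filled
#' with the explicit marker `"not provided"` -- never silently dropped),
#' and section 2 holds one entry per quality criterion, each either a
#' computed [aggregate_criterion()] score (raw values, normalized scores,
#' weights and params all retained) or an explicit not-applicable reason.
#'
#' @param quality named list mapping criterion keys ([smd_criteria()]) to
#'   `criterion_score` objects, not-applicable reason strings, or `NULL`.
#' @param fields named list of descriptive sections
#'   (`section_1_general`, `section_3_task`, ..., `section_8_reference`),
#'   each a named list of free-text fields.
#' @param footer_note optional note appended to the document.
#' @return an object of class `smd_scorecard`.
#' @export
build_scorecard <- function(quality = list(), fields = list(),
                            footer_note = NULL) {
  sections <- list()
  spec_fields <- scorecard_section_fields()
  for (sec in names(spec_fields)) {
    supplied <- fields[[sec]] %||% list()
    filled <- stats::setNames(lapply(spec_fields[[sec]], function(f) {
      val <- supplied[[f]]
      if (is.null(val) || (is.character(val) && !nzchar(val))) "not provided"
      else val
    }), spec_fields[[sec]])
    sections[[sec]] <- filled
  }
  q <- stats::setNames(lapply(smd_criteria(), function(cr) {
    criterion_entry(quality[[cr]], cr)
  }), smd_criteria())
  doc <- c(sections["section_1_general"],
           list(section_2_quality = q),
           sections[setdiff(names(sections), "section_1_general")])
  note <- footer_note %||% paste(
    "Good/moderate/low labels apply one threshold scheme uniformly across",
    "all seven criteria; thresholds are task-specific and config-overridable.")
  structure(list(sections = doc, footer_note = note,
                 generator = "smdscorecard"),
            class = "smd_scorecard")
}

#' @export
print.smd_scorecard <- function(x, ...) {
  computed <- sum(vapply(x$sections$section_2_quality,
                         function(e) identical(e$status, "computed"), logical(1)))
  cat(sprintf("<smd_scorecard: 8 sections, %d/7 criteria computed>\n", computed))
  invisible(x)
}

#' Validate a scorecard document
#'
#' Checks the structural invariants the published schema encodes: exactly
#' eight top-level sections in template order, exactly seven criterion
#' entries in section 2, every template field present, computed entries
#' carrying score/label/metrics with raw and normalized values, and all
#' normalized scores within `[0, 1]`. Violations are returned, not raised.
#'
#' @param doc an `smd_scorecard` (or a plain list parsed back from JSON).
#' @return list with `pass` (logical) and `violations` (character vector).
#' @export
validate_scorecard <- function(doc) {
  sections <- if (inherits(doc, "smd_scorecard")) doc$sections else doc$sections
  violations <- character()
  expected_order <- names(scorecard_section_titles())
  if (is.null(sections) || !identical(names(sections), expected_order)) {
    violations <- c(violations, sprintf(
      "document must have exactly the 8 template sections in order (found: %s)",
      paste(names(sections), collapse = ", ")))
  }
  q <- sections$section_2_quality
  if (is.null(q) || !setequal(names(q), smd_criteria()) ||
      length(q) != 7L) {
    missing <- setdiff(smd_criteria(), names(q))
    violations <- c(violations,
                    if (length(missing))
                      sprintf("missing criterion: %s", paste(missing, collapse = ", "))
                    else "section 2 must have exactly 7 criterion entries")
  } else {
    for (cr in names(q)) {
      e <- q[[cr]]
      st <- e$status %||% ""
      if (!st %in% c("computed", "not-applicable")) {
        violations <- c(violations,
                        sprintf("criterion '%s' has invalid status '%s'", cr, st))
        next
      }
      if (st == "not-applicable") {
        if (is.null(e$reason) || !nzchar(e$reason)) {
          violations <- c(violations,
                          sprintf("criterion '%s' is not-applicable without a reason", cr))
        }
        next
      }
      if (is.null(e$score) || is.null(e$label)) {
        violations <- c(violations,
                        sprintf("criterion '%s' computed entry lacks score/label", cr))
      } else {
        if (e$score < 0 || e$score > 1) {
          violations <- c(violations,
                          sprintf("criterion '%s' score out of range: %g", cr, e$score))
        }
        if (!e$label %in% c("good", "moderate", "low")) {
          violations <- c(violations,
                          sprintf("criterion '%s' label invalid: %s", cr, e$label))
        }
      }
      for (m in e$metrics) {
        if (is.null(m$raw_value)) {
          violations <- c(violations, sprintf(
            "criterion '%s' metric '%s' lacks a raw value", cr, m$name %||% "?"))
        }
        if (!is.null(m$normalized) && !is.na(m$normalized) &&
            (m$normalized < 0 || m$normalized > 1)) {
          violations <- c(violations, sprintf(
            "criterion '%s' metric '%s' normalized score out of range", cr,
            m$name %||% "?"))
        }
      }
    }
  }
  spec_fields <- scorecard_section_fields()
  for (sec in names(spec_fields)) {
    for (f in spec_fields[[sec]]) {
      val <- sections[[sec]][[f]]
      if (is.null(val)) {
        violations <- c(violations,
                        sprintf("section '%s' missing field '%s'", sec, f))
      }
    }
  }
  list(pass = length(violations) == 0L, violations = violations)
}

# Recursively prepare an object for canonical serialization: strip classes,
# drop NULLs, sort names.
canonicalize <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    # NULLs and scalar NAs are dropped, not serialized: JSON null does not
    # survive a parse/render round trip
    drop <- vapply(x, function(el) {
      is.null(el) || (is.atomic(el) && length(el) == 1L && is.na(el))
    }, logical(1))
    x <- x[!drop]
    if (!is.null(names(x)) && all(nzchar(names(x)))) {
      x <- x[order(names(x))]
    }
    lapply(x, canonicalize)
  } else if (is.numeric(x)) {
    # 6 significant digits for diffable, idempotent float formatting;
    # vectors become lists so arrays serialize the same before and after a
    # parse round trip
    out <- signif(x, 6)
    if (!is.null(names(out)) || length(out) > 1L) as.list(out) else out
  } else if (length(x) > 1L) {
    as.list(x)
  } else {
    x
  }
}

#' Render a scorecard as canonical JSON or Markdown
#'
#' JSON output is canonical -- recursively sorted keys, floats at six
#' significant digits, a `schema` reference -- so two runs with identical
#' inputs are byte-identical and the format round-trips losslessly.
#' Markdown output presents all eight sections in template order, with the
#' quality section as a table of raw value, normalized score, direction and
#' label per metric; not-applicable criteria show their reason, never a
#' blank cell.
#'
#' @param doc a validated `smd_scorecard` (or parsed equivalent).
#' @param format `"json"` or `"markdown"`.
#' @return a single string.
#' @export
render_scorecard <- function(doc, format = c("json", "markdown")) {
  format <- match.arg(format)
  report <- validate_scorecard(doc)
  if (!report$pass) {
    stop_smd("invalid scorecard: %s", paste(report$violations, collapse = "; "))
  }
  sections <- if (inherits(doc, "smd_scorecard")) doc$sections else doc$sections
  footer <- (if (inherits(doc, "smd_scorecard")) doc$footer_note
             else doc$footer_note) %||% ""
  if (format == "json") {
    extras <- if (inherits(doc, "smd_scorecard") || is.list(doc)) {
      list(failure_notes = doc$failure_notes %||% character(),
           params = canonicalize(doc$params %||% list()))
    }
    payload <- list(schema = "smd-scorecard/v1",
                    sections = canonicalize(sections),
                    footer_note = footer,
                    failure_notes = extras$failure_notes,
                    params = extras$params)
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = NA, na = "null",
                                         pretty = TRUE)))
  }
  titles <- scorecard_section_titles()
  out <- c("# Synthetic Medical Data Scorecard", "")
  for (sec in names(titles)) {
    out <- c(out, paste0("## ", titles[[sec]]), "")
    if (sec == "section_2_quality") {
      for (cr in smd_criteria()) {
        e <- sections$section_2_quality[[cr]]
        label <- paste0(toupper(substring(cr, 1, 1)), substring(cr, 2))
        if (identical(e$status, "not-applicable")) {
          out <- c(out, sprintf("**%s**: not applicable — %s", label, e$reason), "")
          next
        }
        out <- c(out, sprintf("**%s**: score %.3f (%s, %s aggregation)",
                              label, e$score, e$label, e$method), "",
                 "| Metric | Raw value | Normalized | Direction |",
                 "|---|---|---|---|")
        for (m in e$metrics) {
          raw_txt <- if (is.character(m$raw_value)) m$raw_value
                     else sprintf("%.6g", m$raw_value)
          out <- c(out, sprintf("| %s | %s | %s | %s |", m$name, raw_txt,
                                if (is.null(m$normalized) || is.na(m$normalized))
                                  "—" else sprintf("%.3f", m$normalized),
                                m$direction))
        }
        out <- c(out, "")
      }
    } else {
      for (f in names(sections[[sec]])) {
        val <- sections[[sec]][[f]]
        out <- c(out, sprintf("- **%s**: %s", gsub("_", " ", f),
                              paste(format(val), collapse = "; ")))
      }
      out <- c(out, "")
    }
  }
  out <- c(out, "---", footer, "")
  paste(out, collapse = "\n")
}

#' Parse a scorecard back from its JSON rendering
#'
#' @param text JSON string produced by [render_scorecard()].
#' @return an `smd_scorecard`.
#' @export
parse_scorecard <- function(text) {
  parsed <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  structure(list(sections = parsed$sections,
                 footer_note = parsed$footer_note,
                 failure_notes = unlist(parsed$failure_notes) %||% character(),
                 params = parsed$params,
                 generator = "smdscorecard"),
            class = "smd_scorecard")
}
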