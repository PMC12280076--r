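#' Construct a feature matrix
#'
#' A `feature_matrix` is the n x d numeric embedding that most quality
#' metrics operate in: one row per sample, one column per feature. Optional
#' sample identifiers and subgroup labels ride along for local and
#' per-subgroup assessment. Missing values are not allowed here --
#' missingness is a property of tabular records (see
#' [tabular_dataset()]), not of an embedding.
#'
#' @param values numeric matrix (or coercible), n samples x d features.
#' @param sample_ids optional character vector of unique ids, length n.
#' @param subgroups optional vector of subgroup labels, length n.
#' @param feature_names optional character vector, length d.
#' @return an object of class `feature_matrix`.
#' @export
#' @examples
#' fm <- feature_matrix(matrix(rnorm(20), 5, 4), sample_ids = paste0("s", 1:5))
#' dim(fm$values)
feature_matrix <- function(values, sample_ids = NULL, subgroups = NULL,
                           feature_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); d <- ncol(values)
  if (n < 1L || d < 1L) stop_smd("feature_matrix needs n >= 1 and d >= 1")
  if (any(!is.finite(values))) {
    stop_smd("feature_matrix values must be finite (no NA/NaN/Inf)")
  }
  if (!is.null(sample_ids)) {
    sample_ids <- as.character(sample_ids)
    if (length(sample_ids) != n) stop_smd("sample_ids must have length n")
    if (anyDuplicated(sample_ids)) stop_smd("sample_ids must be unique")
  }
  if (!is.null(subgroups)) {
    subgroups <- as.character(subgroups)
    if (length(subgroups) != n) stop_smd("subgroups must have length n")
  }
  if (!is.null(feature_names)) {
    feature_names <- as.character(feature_names)
    if (length(feature_names) != d) stop_smd("feature_names must have length d")
    colnames(values) <- feature_names
  } else if (!is.null(colnames(values))) {
    feature_names <- colnames(values)
  }
  structure(
    list(values = values, sample_ids = sample_ids, subgroups = subgroups,
         feature_names = feature_names),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d samples x %d features%s%s>\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$sample_ids)) ", with ids" else "",
              if (!is.null(x$subgroups)) ", with subgroups" else ""))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Construct an image set
#'
#' A collection of 2-D grayscale intensity arrays sharing a dynamic range
#' `L` (255 for 8-bit data). Paired image metrics (PSNR, SSIM) require
#' equal counts and per-pair equal shapes.
#'
#' @param images list of 2-D numeric matrices with intensities in `[0, L]`.
#' @param dynamic_range maximum representable intensity L.
#' @param ids optional character ids, one per image.
#' @return an object of class `image_set`.
#' @export
image_set <- function(images, dynamic_range = 255, ids = NULL) {
  if (!is.list(images) || length(images) == 0L) {
    stop_smd("image_set needs a non-empty list of images")
  }
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (!is.matrix(img) || !is.numeric(img)) {
      stop_smd("image %d is not a 2-D numeric matrix", i)
    }
    if (any(!is.finite(img)) || any(img < 0) || any(img > dynamic_range)) {
      stop_smd("image %d has intensities outside [0, %g]", i, dynamic_range)
    }
  }
  if (!is.null(ids)) {
    ids <- as.character(ids)
    if (length(ids) != length(images)) stop_smd("ids must match image count")
  }
  structure(list(images = images, dynamic_range = dynamic_range, ids = ids),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set: %d images, dynamic range %g>\n",
              length(x$images), x$dynamic_range))
  invisible(x)
}

#' Construct a tabular dataset
#'
#' Typed records for completeness and privacy metrics. Cells may hold the
#' explicit missing marker `NA`. `required_fields` may name columns that do
#' not exist -- that absence is exactly what the required-fields metric
#' measures.
#'
#' @param data a data.frame of records.
#' @param column_kinds optional named character vector mapping column names
#'   to `"numeric"` or `"categorical"`; inferred from column classes when
#'   omitted.
#' @param required_fields character vector of column names the intended task
#'   requires (may reference absent columns).
#' @param quasi_identifiers character vector of columns that jointly risk
#'   re-identification; must all exist.
#' @param sensitive_attribute optional single column name holding the
#'   sensitive value for l-diversity / t-closeness.
#' @return an object of class `tabular_dataset`.
#' @export
tabular_dataset <- function(data, column_kinds = NULL,
                            required_fields = character(),
                            quasi_identifiers = character(),
                            sensitive_attribute = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(column_kinds)) {
    column_kinds <- vapply(data, function(col) {
      if (is.numeric(col)) "numeric" else "categorical"
    }, character(1))
  } else {
    if (is.null(names(column_kinds)) || !all(names(column_kinds) %in% names(data))) {
      stop_smd("column_kinds must be named by existing columns")
    }
    if (!all(column_kinds %in% c("numeric", "categorical"))) {
      stop_smd("column kinds must be 'numeric' or 'categorical'")
    }
    missing_kinds <- setdiff(names(data), names(column_kinds))
    inferred <- vapply(data[missing_kinds], function(col) {
      if (is.numeric(col)) "numeric" else "categorical"
    }, character(1))
    column_kinds <- c(column_kinds, inferred)[names(data)]
  }
  quasi_identifiers <- as.character(quasi_identifiers)
  if (!all(quasi_identifiers %in% names(data))) {
    stop_smd("quasi_identifiers must be existing columns: missing %s",
             paste(setdiff(quasi_identifiers, names(data)), collapse = ", "))
  }
  if (!is.null(sensitive_attribute)) {
    if (length(sensitive_attribute) != 1L ||
        !sensitive_attribute %in% names(data)) {
      stop_smd("sensitive_attribute must be a single existing column")
    }
  }
  structure(
    list(data = data, column_kinds = column_kinds,
         required_fields = as.character(required_fields),
         quasi_identifiers = quasi_identifiers,
         sensitive_attribute = sensitive_attribute),
    class = "tabular_dataset"
  )
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat(sprintf("<tabular_dataset: %d rows x %d columns, %d quasi-identifiers>\n",
              nrow(x$data), ncol(x$data), length(x$quasi_identifiers)))
  invisible(x)
}

#' Construct a metric specification
#'
#' One registry entry per quality metric: which of the seven criteria it
#' informs, the space it operates in, whether it needs a reference dataset
#' (binary) or works on the synthetic data alone (unary), and the direction
#' a better value moves in. `direction = "band"` marks a metric that is best
#' inside a target range rather than at an extreme.
#'
#' @param name unique registry name.
#' @param criterion one of congruence, coverage, constraint, completeness,
#'   compliance, comprehension, consistency.
#' @param space one of embedding, image, metadata, data_attribute,
#'   documentation, quality_metrics.
#' @param arity `"unary"` or `"binary"`.
#' @param direction one of maximize, minimize, band, stat_sig.
#' @param image_only logical; TRUE when the metric applies to images only.
#' @param display_name printed label (defaults to `name`).
#' @return an object of class `metric_spec`.
#' @export
metric_spec <- function(name, criterion, space, arity, direction,
                        image_only = FALSE, display_name = name) {
  criterion <- match.arg(tolower(criterion), smd_criteria())
  space <- match.arg(tolower(space),
                     c("embedding", "image", "metadata", "data_attribute",
                       "documentation", "quality_metrics"))
  arity <- match.arg(tolower(arity), c("unary", "binary"))
  direction <- match.arg(tolower(direction),
                         c("maximize", "minimize", "band", "stat_sig"))
  structure(
    list(name = name, criterion = criterion, space = space, arity = arity,
         direction = direction, image_only = isTRUE(image_only),
         display_name = display_name),
    class = "metric_spec"
  )
}

#' The seven quality criteria
#'
#' @return character vector of the seven criterion keys in canonical order.
#' @export
smd_criteria <- function() {
  c("congruence", "coverage", "constraint", "completeness", "compliance",
    "comprehension", "consistency")
}

#' Construct a metric result
#'
#' Carries the raw metric value, optional per-subgroup values, the
#' normalized `[0, 1]` score once calibration has been applied, and every
#' tunable parameter that affected the value (the reproducibility contract:
#' a scorecard must be recomputable from its params).
#'
#' @param metric registry name of the metric.
#' @param raw_value numeric raw value in metric-specific units.
#' @param per_subgroup optional named numeric vector of per-subgroup values.
#' @param normalized optional score in `[0, 1]`.
#' @param params named list of parameters used.
#' @return an object of class `metric_result`.
#' @export
metric_result <- function(metric, raw_value, per_subgroup = NULL,
                          normalized = NULL, params = list()) {
  if (!is.null(normalized)) {
    if (!is.na(normalized) && (normalized < 0 || normalized > 1)) {
      stop_smd("normalized score must lie in [0, 1]")
    }
  }
  structure(
    list(metric = metric, raw_value = raw_value, per_subgroup = per_subgroup,
         normalized = normalized, params = params),
    class = "metric_result"
  )
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("<metric_result %s: raw %.6g%s>\n", x$metric, x$raw_value,
              if (!is.null(x$normalized))
                sprintf(", normalized %.4f", x$normalized) else ""))
  invisible(x)
}

#' Construct a differential-privacy declaration
#'
#' Records the declared (epsilon, delta) budget of the generation mechanism.
#' This is a declared property, validated and carried into the scorecard --
#' it is never estimated from data.
#'
#' @param epsilon non-negative DP budget.
#' @param delta DP slack in `[0, 1)`.
#' @param mechanism free-text description of the mechanism (e.g. "DP-SGD").
#' @return an object of class `privacy_declaration`.
#' @export
privacy_declaration <- function(epsilon, delta = 0, mechanism = "") {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0) {
    stop_smd("epsilon must be a non-negative number")
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta >= 1) {
    stop_smd("delta must lie in [0, 1)")
  }
  structure(list(epsilon = epsilon, delta = delta,
                 mechanism = as.character(mechanism)),
            class = "privacy_declaration")
}

#' Construct an anonymity profile
#'
#' The (k, l, t) triple summarizing equivalence-class privacy: k = minimum
#' class size, l = minimum distinct sensitive values within a class,
#' t = maximum class-vs-global sensitive-distribution distance.
#'
#' @param k positive integer, minimum equivalence-class size.
#' @param l positive integer, `1 <= l <= k`.
#' @param t real in `[0, 1]`.
#' @return an object of class `anonymity_profile`.
#' @export
anonymity_profile <- function(k, l = 1L, t = 0) {
  if (k < 1L) stop_smd("k must be >= 1")
  if (l < 1L || l > k) stop_smd("l must satisfy 1 <= l <= k")
  if (t < 0 || t > 1) stop_smd("t must lie in [0, 1]")
  structure(list(k = as.integer(k), l = as.integer(l), t = t),
            class = "anonymity_profile")
}

# ---- metric registry -------------------------------------------------------

registry_env <- new.env(parent = emptyenv())

builtin_specs <- function() {
  row <- function(name, criterion, space, arity, direction,
                  image_only = FALSE, display_name = name) {
    metric_spec(name, criterion, space, arity, direction, image_only,
                display_name)
  }
  list(
    # congruence (8)
    row("Cosine Similarity", "congruence", "embedding", "binary", "maximize"),
    row("Earth Mover's Distance", "congruence", "embedding", "binary", "minimize"),
    row("Jensen-Shannon Divergence", "congruence", "embedding", "binary", "minimize"),
    row("Peak Signal-to-Noise Ratio", "congruence", "image", "binary", "maximize", TRUE),
    row("Structural Similarity Index", "congruence", "image", "binary", "maximize", TRUE),
    row("Fréchet Inception Distance", "congruence", "embedding", "binary", "minimize", TRUE),
    row("Distance to Centroid", "congruence", "embedding", "binary", "minimize"),
    row("Precision", "congruence", "embedding", "binary", "maximize"),
    # coverage (9)
    row("Inception Score", "coverage", "image", "unary", "maximize", TRUE),
    row("Recall", "coverage", "embedding", "binary", "maximize"),
    row("Coverage", "coverage", "embedding", "binary", "maximize"),
    row("Convex Hull Volume", "coverage", "embedding", "unary", "maximize"),
    row("Determinantal Point Processes Score", "coverage", "embedding", "unary", "maximize"),
    row("Vendi Score", "coverage", "embedding", "unary", "maximize"),
    row("Variance", "coverage", "embedding", "unary", "maximize"),
    row("Entropy", "coverage", "embedding", "unary", "maximize"),
    row("Clustering-Based Metrics", "coverage", "embedding", "unary", "maximize"),
    # constraint (3)
    row("Nearest Invalid Datapoint", "constraint", "embedding", "binary", "minimize"),
    row("Distance to Constraint Boundary", "constraint", "embedding", "binary", "minimize"),
    row("Constraint Violation Rate", "constraint", "embedding", "binary", "minimize"),
    # completeness (2)
    row("Proportion of Required Fields", "completeness", "metadata", "binary", "maximize"),
    row("Missing Data Percentage", "completeness", "metadata", "binary", "minimize"),
    # compliance (4)
    row("Differential Privacy Score", "compliance", "data_attribute", "unary", "minimize"),
    row("K-Anonymity Level", "compliance", "data_attribute", "unary", "maximize"),
    row("L-Diversity Score", "compliance", "data_attribute", "unary", "maximize"),
    row("T-Closeness Level", "compliance", "data_attribute", "unary", "maximize"),
    # comprehension (1)
    row("Documentation Clarity Score", "comprehension", "documentation", "unary", "maximize"),
    # consistency (3); registry names must be unique, so the subgroup
    # variance gets a qualified name while display_name keeps "Variance"
    row("Subgroup Variance", "consistency", "quality_metrics", "unary", "minimize",
        display_name = "Variance"),
    row("Maximum-Minimum Difference", "consistency", "quality_metrics", "unary", "minimize"),
    row("Analysis of Variance", "consistency", "quality_metrics", "unary", "stat_sig")
  )
}

ensure_registry <- function() {
  if (is.null(registry_env$specs)) {
    specs <- builtin_specs()
    names(specs) <- vapply(specs, `[[`, character(1), "name")
    registry_env$specs <- specs
  }
  invisible(registry_env$specs)
}

#' The built-in metric registry
#'
#' Thirty built-in metric specifications partitioned over the seven criteria
#' as 8/9/3/2/4/1/3 (congruence through consistency), plus any metrics added
#' with [register_metric()].
#'
#' @return named list of [metric_spec()] objects.
#' @export
#' @examples
#' length(builtin_registry())
#' builtin_registry()[["Vendi Score"]]$criterion
builtin_registry <- function() {
  ensure_registry()
  registry_env$specs
}

#' Look up a metric specification by name
#'
#' @param name registry name of the metric.
#' @return the matching [metric_spec()]; errors when absent.
#' @export
lookup_metric <- function(name) {
  specs <- builtin_registry()
  if (!name %in% names(specs)) {
    stop_smd("metric '%s' is not in the registry", name)
  }
  specs[[name]]
}

#' Register a user-defined metric
#'
#' User metrics must declare every field of the specification; nothing is
#' inferred, which keeps direction-aware normalization safe.
#'
#' @param spec a [metric_spec()].
#' @return the spec, invisibly.
#' @export
register_metric <- function(spec) {
  stopifnot(inherits(spec, "metric_spec"))
  ensure_registry()
  if (spec$name %in% names(registry_env$specs)) {
    stop_smd("metric '%s' is already registered", spec$name)
  }
  registry_env$specs[[spec$name]] <- spec
  invisible(spec)
}

#' Reset the registry to the built-in entries
#' @return invisibly, the built-in registry.
#' @export
reset_registry <- function() {
  registry_env$specs <- NULL
  invisible(ensure_registry())
}

#' Validate a metric request against its specification
#'
#' Enforces arity and space semantics before any computation: binary metrics
#' need a reference dataset, image-space metrics need image sets, and
#' embedding-space metrics need feature matrices of equal dimension.
#' Side-effect-free and idempotent.
#'
#' @param spec a [metric_spec()].
#' @param synthetic the synthetic dataset (feature_matrix or image_set).
#' @param reference optional reference dataset.
#' @return a list `(spec, synthetic, reference)` on success.
#' @export
validate_request <- function(spec, synthetic, reference = NULL) {
  stopifnot(inherits(spec, "metric_spec"))
  if (is.null(synthetic)) stop_smd("synthetic dataset is required")
  if (spec$arity == "binary" && is.null(reference)) {
    stop_smd("metric '%s' is binary and requires a reference dataset",
             spec$name)
  }
  check_space <- function(x, role) {
    if (spec$space == "image" && !inherits(x, "image_set")) {
      stop_smd("metric '%s' operates on images; %s is not an image_set",
               spec$name, role)
    }
    if (spec$space == "embedding" && !inherits(x, "feature_matrix")) {
      stop_smd("metric '%s' operates on embeddings; %s is not a feature_matrix",
               spec$name, role)
    }
  }
  check_space(synthetic, "synthetic")
  if (!is.null(reference)) {
    check_space(reference, "reference")
    if (spec$space == "embedding" &&
        ncol(synthetic$values) != ncol(reference$values)) {
      stop_smd("dimension mismatch: synthetic d=%d vs reference d=%d",
               ncol(synthetic$values), ncol(reference$values))
    }
  }
  list(spec = spec, synthetic = synthetic, reference = reference)
}

# ---- I/O -------------------------------------------------------------------

#' Read a feature matrix from CSV
#'
#' One row per sample; the reserved optional columns `sample_id` and
#' `subgroup` are lifted out, every other column must be numeric.
#'
#' @param path CSV file path.
#' @return a [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- if ("sample_id" %in% names(df)) as.character(df$sample_id) else NULL
  groups <- if ("subgroup" %in% names(df)) as.character(df$subgroup) else NULL
  feat <- df[, setdiff(names(df), c("sample_id", "subgroup")), drop = FALSE]
  non_num <- names(feat)[!vapply(feat, is.numeric, logical(1))]
  if (length(non_num)) {
    stop_smd("non-numeric feature columns in %s: %s", path,
             paste(non_num, collapse = ", "))
  }
  feature_matrix(as.matrix(feat), sample_ids = ids, subgroups = groups,
                 feature_names = names(feat))
}

#' Write a feature matrix to CSV
#'
#' @param fm a [feature_matrix()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm$values)
  names(df) <- fm$feature_names %||% paste0("f", seq_len(ncol(fm$values)))
  if (!is.null(fm$subgroups)) df <- cbind(subgroup = fm$subgroups, df)
  if (!is.null(fm$sample_ids)) df <- cbind(sample_id = fm$sample_ids, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tabular dataset from CSV
#'
#' Empty fields (and any strings listed in `na_strings`) are read as the
#' missing marker.
#'
#' @param path CSV file path (must have a header row).
#' @param required_fields,quasi_identifiers,sensitive_attribute see
#'   [tabular_dataset()].
#' @param na_strings strings treated as missing; the empty field always is.
#' @return a [tabular_dataset()].
#' @export
read_tabular_dataset <- function(path, required_fields = character(),
                                 quasi_identifiers = character(),
                                 sensitive_attribute = NULL,
                                 na_strings = "") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = unique(c("", na_strings)))
  tabular_dataset(df, required_fields = required_fields,
                  quasi_identifiers = quasi_identifiers,
                  sensitive_attribute = sensitive_attribute)
}

#' Read an image set from a directory of grayscale PNG files
#'
#' Files are ordered lexicographically; pixel values are rescaled from the
#' PNG unit interval to `[0, dynamic_range]`. RGB(A) images are converted to
#' grayscale by channel averaging.
#'
#' @param dir directory containing `.png` files.
#' @param dynamic_range intensity ceiling L of the returned set.
#' @return an [image_set()].
#' @export
read_image_set <- function(dir, dynamic_range = 255) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop_smd("no PNG files in %s", dir)
  images <- lapply(files, function(f) {
    arr <- png::readPNG(f)
    if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:min(3, dim(arr)[3])], c(1, 2), mean)
    arr * dynamic_range
  })
  image_set(images, dynamic_range = dynamic_range,
            ids = sub("\\.png$", "", basename(files)))
}

#' Write an image set to a directory of grayscale PNG files
#'
#' @param iset an [image_set()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_image_set <- function(iset, dir) {
  stopifnot(inherits(iset, "image_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- iset$ids %||% sprintf("img%04d", seq_along(iset$images))
  for (i in seq_along(iset$images)) {
    png::writePNG(iset$images[[i]] / iset$dynamic_range,
                  file.path(dir, paste0(ids[i], ".png")))
  }
  invisible(dir)
}
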