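# End-to-end orchestration: configuration -> metrics -> normalization ->
# aggregation -> scorecard.

#' Load an evaluation configuration
#'
#' @param path YAML file path.
#' @return the configuration as a named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

# Parse constraint entries from a config list into constraint_spec objects.
parse_constraints <- function(entries) {
  lapply(entries, function(e) {
    constraint_spec(id = e$id, target = e$target,
                    kind = e$kind %||% "interval",
                    lo = e$lo %||% -Inf, hi = e$hi %||% Inf,
                    allowed = e$allowed,
                    antecedent = e$antecedent, consequent = e$consequent)
  })
}

# Reference-aware default calibration anchors. Anchors that depend on the
# reference (its own diversity, dispersion, centroid spread) are marked
# reference-derived; the rest are package defaults, all config-overridable.
default_calibrations <- function(ctx) {
  cal <- list(
    "Fréchet Inception Distance" = calibration_entry(best = 0, worst = 100),
    "Earth Mover's Distance" = calibration_entry(best = 0, worst = 5),
    "Jensen-Shannon Divergence" = calibration_entry(best = 0, worst = 1),
    "Cosine Similarity" = calibration_entry(best = 1, worst = 0),
    "Peak Signal-to-Noise Ratio" = calibration_entry(best = 50, worst = 5),
    "Structural Similarity Index" = calibration_entry(best = 1, worst = 0),
    "Precision" = calibration_entry(best = 1, worst = 0),
    "Recall" = calibration_entry(best = 1, worst = 0),
    "Coverage" = calibration_entry(best = 1, worst = 0),
    "Convex Hull Volume" = calibration_entry(best = 1, worst = 0),
    "Inception Score" = calibration_entry(best = 10, worst = 1),
    "Clustering-Based Metrics" = calibration_entry(best = 1, worst = 0),
    "Constraint Violation Rate" = calibration_entry(best = 0, worst = 1),
    "Distance to Constraint Boundary" = calibration_entry(best = 0, worst = 1),
    "Proportion of Required Fields" = calibration_entry(best = 1, worst = 0),
    "Missing Data Percentage" = calibration_entry(best = 0, worst = 100),
    "Documentation Clarity Score" = calibration_entry(best = 1, worst = 0),
    "Differential Privacy Score" = calibration_entry(best = 0, worst = 10),
    "K-Anonymity Level" = calibration_entry(best = 10, worst = 1),
    "L-Diversity Score" = calibration_entry(best = 3, worst = 1),
    "T-Closeness Level" = calibration_entry(best = 0, worst = 1),
    "Re-identification Risk" = calibration_entry(best = 0, worst = 1),
    "Completeness Rating" = calibration_entry(best = 10, worst = 1)
  )
  if (!is.null(ctx$reference_emb)) {
    ref <- ctx$reference_emb
    tr_ref <- sum(diag(stats::cov(ref$values)))
    cal[["Variance"]] <- calibration_entry(best = tr_ref, worst = 0,
                                           source = "reference-derived")
    ref_ent <- metric_dispersion(ref, kind = "entropy")$raw_value
    cal[["Entropy"]] <- calibration_entry(best = max(ref_ent, 1e-6), worst = 0,
                                          source = "reference-derived")
    ref_vendi <- metric_kernel_diversity(ref, "vendi")$raw_value
    cal[["Vendi Score"]] <- calibration_entry(best = max(ref_vendi, 1 + 1e-6),
                                              worst = 1,
                                              source = "reference-derived")
    ref_dpp <- metric_kernel_diversity(ref, "dpp_logdet")$raw_value
    cal[["Determinantal Point Processes Score"]] <-
      calibration_entry(best = max(ref_dpp, -20) + 1e-9, worst = -25,
                        source = "reference-derived")
    ctr <- metric_centroid_alignment(ref, ref, kind = "distance")
    base <- ctr$params$reference_baseline
    cal[["Distance to Centroid"]] <-
      calibration_entry(best = base, worst = 5 * max(base, 1e-6),
                        source = "reference-derived")
  } else {
    cal[["Variance"]] <- calibration_entry(best = 10, worst = 0)
    cal[["Entropy"]] <- calibration_entry(best = 5, worst = 0)
    cal[["Vendi Score"]] <- calibration_entry(best = 20, worst = 1)
    cal[["Determinantal Point Processes Score"]] <-
      calibration_entry(best = 0, worst = -25)
    cal[["Distance to Centroid"]] <- calibration_entry(best = 0, worst = 10)
  }
  cal
}

# Merge user calibration overrides (plain lists) over the defaults.
merge_calibrations <- function(defaults, overrides) {
  for (nm in names(overrides)) {
    o <- overrides[[nm]]
    defaults[[nm]] <- calibration_entry(best = o$best, worst = o$worst,
                                        band_lo = o$band_lo,
                                        band_hi = o$band_hi,
                                        decay_width = o$decay_width,
                                        source = "configured")
  }
  defaults
}

# Direction used for normalization: registry direction unless overridden in
# config (e.g. band for a coverage metric, maximize for nearest-invalid).
effective_direction <- function(name, overrides) {
  if (!is.null(overrides[[name]])) return(overrides[[name]])
  if (name == "Nearest Invalid Datapoint") return("maximize")
  if (name == "T-Closeness Level") return("minimize")
  spec <- tryCatch(lookup_metric(name), error = function(e) NULL)
  if (is.null(spec)) {
    # non-registry extras keep their natural direction
    switch(name,
           "Re-identification Risk" = "minimize",
           "Completeness Rating" = "maximize",
           "maximize")
  } else {
    spec$direction
  }
}

#' Run a full scorecard evaluation
#'
#' Loads the configured data sources (or uses in-memory objects supplied
#' via `data`), builds the reference-fitted embedding pipeline, runs every
#' applicable metric for each of the seven criteria, normalizes raw values
#' against the calibration, aggregates them into per-criterion scores with
#' good/moderate/low labels, and assembles the eight-section scorecard.
#' A failing metric never aborts the run: it is recorded as a failure note
#' and the criterion aggregates over the remaining metrics (a criterion
#' with no usable metric is marked not-applicable with the reason).
#' Deterministic: identical config and seeds give byte-identical JSON.
#'
#' @param config configuration list (or YAML path). Recognized blocks:
#'   `seed`; `data` (paths: `reference_csv`, `synthetic_csv`,
#'   `reference_images`, `synthetic_images`, `tabular_csv`,
#'   `invalid_exemplars_csv`, `class_probabilities_csv`, plus
#'   `required_fields`, `quasi_identifiers`, `sensitive_attribute`);
#'   `features` (`embedding_dim`); `constraints`; `compliance`
#'   (`epsilon`, `delta`, `mechanism`, `theta`); `comprehension`
#'   (`rubric`, `rater`); `completeness` (`rating`, `scale_max`);
#'   `consistency` (`B`); `aggregation` (`method`, `thresholds`,
#'   `weights`, `calibration`, `directions`); `scorecard` (descriptive
#'   sections).
#' @param data optional named list of in-memory inputs overriding file
#'   loading: `reference`, `synthetic` ([feature_matrix()]),
#'   `reference_images`, `synthetic_images` ([image_set()]), `tabular`
#'   ([tabular_dataset()]), `invalid_exemplars`, `class_probabilities`.
#' @return an `smd_scorecard`.
#' @export
run_evaluation <- function(config = list(), data = list()) {
  if (is.character(config)) config <- read_config(config)
  seed <- config$seed %||% 1L
  dcfg <- config$data %||% list()

  reference <- data$reference %||% (
    if (!is.null(dcfg$reference_csv)) read_feature_matrix(dcfg$reference_csv))
  synthetic <- data$synthetic %||% (
    if (!is.null(dcfg$synthetic_csv)) read_feature_matrix(dcfg$synthetic_csv))
  ref_images <- data$reference_images %||% (
    if (!is.null(dcfg$reference_images)) read_image_set(dcfg$reference_images))
  syn_images <- data$synthetic_images %||% (
    if (!is.null(dcfg$synthetic_images)) read_image_set(dcfg$synthetic_images))
  tabular <- data$tabular %||% (
    if (!is.null(dcfg$tabular_csv)) {
      read_tabular_dataset(dcfg$tabular_csv,
                           required_fields = unlist(dcfg$required_fields) %||% character(),
                           quasi_identifiers = unlist(dcfg$quasi_identifiers) %||% character(),
                           sensitive_attribute = dcfg$sensitive_attribute)
    })
  invalid_ex <- data$invalid_exemplars %||% (
    if (!is.null(dcfg$invalid_exemplars_csv))
      read_feature_matrix(dcfg$invalid_exemplars_csv))
  class_probs <- data$class_probabilities %||% (
    if (!is.null(dcfg$class_probabilities_csv))
      as.matrix(utils::read.csv(dcfg$class_probabilities_csv)))

  # image-derived embeddings when no CSV embeddings are supplied
  if (is.null(reference) && !is.null(ref_images)) {
    reference <- extract_image_features(ref_images)
  }
  if (is.null(synthetic) && !is.null(syn_images)) {
    synthetic <- extract_image_features(syn_images)
  }

  k_dim <- config$features$embedding_dim
  pipeline <- NULL
  reference_emb <- reference; synthetic_emb <- synthetic
  if (!is.null(reference) && !is.null(synthetic)) {
    pipeline <- fit_embedding_pipeline(reference, k = k_dim)
    reference_emb <- apply_embedding(pipeline, reference)
    synthetic_emb <- apply_embedding(pipeline, synthetic)
  }

  ctx <- list(reference_emb = reference_emb, synthetic_emb = synthetic_emb)
  agg_cfg <- config$aggregation %||% list()
  cal <- merge_calibrations(default_calibrations(ctx), agg_cfg$calibration)
  dir_overrides <- agg_cfg$directions %||% list()
  thresholds <- c(good_min = agg_cfg$thresholds$good_min %||% 0.80,
                  moderate_min = agg_cfg$thresholds$moderate_min %||% 0.70)
  method <- agg_cfg$method %||% "arithmetic"

  notes <- character()
  run_metric <- function(criterion, name, fn) {
    tryCatch(fn(), error = function(e) {
      notes <<- c(notes, sprintf("[%s] %s: %s", criterion, name,
                                 conditionMessage(e)))
      NULL
    })
  }

  results <- stats::setNames(vector("list", 7L), smd_criteria())

  # --- congruence ---
  cong <- list()
  if (!is.null(reference_emb) && !is.null(synthetic_emb)) {
    r <- reference_emb; s <- synthetic_emb
    cong <- c(cong, list(
      run_metric("congruence", "fid", function() metric_fid(r, s)),
      run_metric("congruence", "emd", function()
        metric_marginal_divergence(r, s, kind = "emd")),
      run_metric("congruence", "jsd", function()
        metric_marginal_divergence(r, s, kind = "jsd")),
      run_metric("congruence", "cosine", function()
        metric_centroid_alignment(r, s, kind = "cosine")),
      run_metric("congruence", "centroid distance", function()
        metric_centroid_alignment(r, s, kind = "distance")),
      run_metric("congruence", "precision", function()
        metric_knn_precision(r, s, k = 3L))
    ))
  }
  if (!is.null(ref_images) && !is.null(syn_images)) {
    cong <- c(cong, list(
      run_metric("congruence", "psnr", function()
        metric_paired_image_similarity(ref_images, syn_images, "psnr")),
      run_metric("congruence", "ssim", function()
        metric_paired_image_similarity(ref_images, syn_images, "ssim"))
    ))
  }
  results$congruence <- Filter(Negate(is.null), cong)

  # --- coverage ---
  cov <- list()
  if (!is.null(reference_emb) && !is.null(synthetic_emb)) {
    r <- reference_emb; s <- synthetic_emb
    cov <- c(cov, list(
      run_metric("coverage", "recall", function()
        metric_knn_support(r, s, k = 3L, mode = "recall")),
      run_metric("coverage", "coverage", function()
        metric_knn_support(r, s, k = 3L, mode = "coverage")),
      run_metric("coverage", "hull", function() metric_hull_ratio(r, s)),
      run_metric("coverage", "vendi", function()
        metric_kernel_diversity(s, "vendi")),
      run_metric("coverage", "dpp", function()
        metric_kernel_diversity(s, "dpp_logdet")),
      run_metric("coverage", "variance", function()
        metric_dispersion(s, r, kind = "variance")),
      run_metric("coverage", "entropy", function()
        metric_dispersion(s, r, kind = "entropy")),
      run_metric("coverage", "cluster occupancy", function()
        metric_cluster_occupancy(r, s, n_clusters = config$coverage$n_clusters %||% 8L,
                                 seed = derive_seed(seed, "kmeans")))
    ))
  }
  if (!is.null(class_probs)) {
    cov <- c(cov, list(run_metric("coverage", "inception-style score",
                                  function() metric_inception_style_score(class_probs))))
  }
  results$coverage <- Filter(Negate(is.null), cov)

  # --- constraint ---
  cons <- list()
  specs <- if (!is.null(config$constraints)) parse_constraints(config$constraints)
           else data$constraints
  if (!is.null(specs) && length(specs)) {
    target_data <- data$constraint_data %||% tabular %||% synthetic
    vm <- run_metric("constraint", "constraint evaluation", function()
      evaluate_constraints(target_data, specs))
    if (!is.null(vm)) {
      cons <- c(cons, list(
        run_metric("constraint", "violation rate", function()
          metric_violation_rate(vm))))
      if (any(vm$is_interval)) {
        cons <- c(cons, list(
          run_metric("constraint", "boundary distance", function()
            metric_boundary_distance(vm, target_data))))
      }
    }
  }
  if (!is.null(invalid_ex) && !is.null(synthetic_emb)) {
    inv <- if (!is.null(pipeline) &&
               ncol(invalid_ex$values) == pipeline$d)
      apply_embedding(pipeline, invalid_ex) else invalid_ex
    cons <- c(cons, list(
      run_metric("constraint", "nearest invalid", function()
        metric_nearest_invalid(synthetic_emb, inv))))
  }
  results$constraint <- Filter(Negate(is.null), cons)

  # --- completeness ---
  comp <- list()
  if (!is.null(tabular)) {
    if (length(tabular$required_fields)) {
      comp <- c(comp, list(run_metric("completeness", "required fields",
                                      function() metric_required_fields(tabular))))
    }
    comp <- c(comp, list(run_metric("completeness", "missing percentage",
                                    function() metric_missing_pct(tabular))))
  }
  if (!is.null(config$completeness$rating)) {
    comp <- c(comp, list(run_metric("completeness", "human rating", function()
      record_completeness_rating(config$completeness$rating,
                                 config$completeness$scale_max %||% 10))))
  }
  results$completeness <- Filter(Negate(is.null), comp)

  # --- compliance ---
  cmpl <- list()
  if (!is.null(tabular) && length(tabular$quasi_identifiers)) {
    anon <- run_metric("compliance", "anonymity profile", function()
      metric_anonymity_profile(tabular))
    if (!is.null(anon)) {
      cmpl <- c(cmpl, list(anon))
      if (!is.na(anon$params$l %||% NA)) {
        cmpl <- c(cmpl, list(
          metric_result("L-Diversity Score", anon$params$l,
                        params = list(from = "anonymity profile")),
          metric_result("T-Closeness Level", anon$params$t,
                        params = list(from = "anonymity profile",
                                      ground_distance = anon$params$t_ground_distance,
                                      direction_note = "smaller t is safer; normalized as minimize"))))
      }
    }
  }
  if (!is.null(config$compliance$epsilon)) {
    cmpl <- c(cmpl, list(run_metric("compliance", "dp declaration", function()
      record_dp_declaration(privacy_declaration(
        config$compliance$epsilon, config$compliance$delta %||% 0,
        config$compliance$mechanism %||% "")))))
  }
  if (!is.null(reference_emb) && !is.null(synthetic_emb)) {
    cmpl <- c(cmpl, list(run_metric("compliance", "re-identification risk",
      function() metric_reidentification_risk(
        reference_emb, synthetic_emb,
        theta = config$compliance$theta %||% 0.1))))
  }
  results$compliance <- Filter(Negate(is.null), cmpl)

  # --- comprehension ---
  cmph <- list()
  if (!is.null(config$comprehension$rubric)) {
    cmph <- c(cmph, list(run_metric("comprehension", "doc clarity", function() {
      scores <- unlist(config$comprehension$rubric)
      metric_doc_clarity(clarity_rubric(scores,
                                        rater = config$comprehension$rater %||% "unspecified"))
    })))
  }
  results$comprehension <- Filter(Negate(is.null), cmph)

  # --- consistency ---
  cstn <- list()
  if (!is.null(synthetic_emb) && !is.null(synthetic_emb$subgroups) &&
      !is.null(reference_emb) && !is.null(reference_emb$subgroups)) {
    per_grp <- run_metric("consistency", "per-subgroup congruence", function()
      per_subgroup_metric(metric_fid, synthetic_emb, reference_emb,
                          metric_name = "per-subgroup FID"))
    if (!is.null(per_grp)) {
      disp_var <- run_metric("consistency", "subgroup variance", function()
        metric_subgroup_dispersion(per_grp, "variance"))
      disp_mm <- run_metric("consistency", "maxmin", function()
        metric_subgroup_dispersion(per_grp, "maxmin"))
      # relative anchors: dispersion is judged against the mean subgroup value
      mu <- mean(per_grp$per_subgroup)
      if (is.null(cal[["Subgroup Variance"]])) {
        cal[["Subgroup Variance"]] <- calibration_entry(
          best = 0, worst = max((mu / 2)^2, 1e-8), source = "reference-derived")
      }
      if (is.null(cal[["Maximum-Minimum Difference"]])) {
        cal[["Maximum-Minimum Difference"]] <- calibration_entry(
          best = 0, worst = max(mu, 1e-8), source = "reference-derived")
      }
      anova_res <- run_metric("consistency", "anova", function()
        metric_subgroup_anova(metric_fid, synthetic_emb, reference_emb,
                              B = config$consistency$B %||% 50L,
                              seed = derive_seed(seed, "anova")))
      # the per-subgroup table itself is reported, never scored
      cstn <- Filter(Negate(is.null),
                     list(disp_var, disp_mm, anova_res, per_grp))
    }
  }
  results$consistency <- cstn

  # --- normalize + aggregate ---
  weights_cfg <- agg_cfg$weights %||% list()
  quality <- stats::setNames(lapply(smd_criteria(), function(cr) {
    res <- results[[cr]]
    if (length(res) == 0L) {
      return(sprintf("no inputs configured for %s", cr))
    }
    report_only <- c("per-subgroup FID")
    normalized <- list(); extras <- list()
    for (rr in res) {
      dirn <- effective_direction(rr$metric, dir_overrides)
      if (dirn == "stat_sig" || rr$metric %in% report_only) {
        extras <- c(extras, list(rr))
        next
      }
      ce <- cal[[rr$metric]]
      if (is.null(ce)) {
        notes <<- c(notes, sprintf("[%s] %s: no calibration entry", cr, rr$metric))
        extras <- c(extras, list(rr))
        next
      }
      normalized <- c(normalized,
                      list(normalize_metric(rr, dirn, ce)))
    }
    if (length(normalized) == 0L) {
      return(sprintf("metrics ran for %s but none is normalizable", cr))
    }
    w <- weights_cfg[[cr]]
    cs <- aggregate_criterion(cr, normalized,
                              weights = if (!is.null(w)) as.numeric(unlist(w)),
                              method = method, thresholds = thresholds)
    cs$members <- c(cs$members, extras)  # dual reporting incl. stat_sig
    cs
  }), smd_criteria())

  sc_fields <- config$scorecard %||% list()
  doc <- build_scorecard(quality = quality, fields = sc_fields)
  doc$failure_notes <- notes
  doc$params <- list(seed = seed, embedding_dim = k_dim,
                     aggregation_method = method,
                     thresholds = as.list(thresholds))
  doc
}
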