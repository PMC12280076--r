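# Seeded synthetic-data generators with planted ground truth. Each
# generator draws from its own pseudo-random stream derived from
# (seed, generator name), so adding a generator never perturbs another's
# output, and regeneration with the same arguments is byte-identical.
# These are metrological phantoms for exercising the metrics, not clinical
# simulacra.

#' Generate a reference/synthetic embedding pair with known discrepancy
#'
#' The reference is an equal-weight Gaussian mixture with unit-variance
#' components at seeded locations. The synthetic set is the same mixture
#' with all component means shifted by `shift` along a fixed unit vector,
#' component standard deviation multiplied by `scale`, and
#' `drop_components` components removed (planted coverage gaps). With
#' `shift = 0`, `scale = 1`, `drop_components = 0` the two sets are draws
#' from the same distribution.
#'
#' @param n samples per dataset (>= 10).
#' @param d feature dimension.
#' @param shift mean shift applied to every synthetic component.
#' @param scale multiplier on the synthetic component standard deviation.
#' @param n_components mixture components (>= 1).
#' @param drop_components components removed from the synthetic mixture
#'   (< n_components).
#' @param seed integer seed.
#' @return list with elements `reference` and `synthetic`
#'   ([feature_matrix()] objects).
#' @export
gen_embedding_pair <- function(n, d, shift = 0, scale = 1, n_components = 3L,
                               drop_components = 0L, seed = 1L) {
  n <- as.integer(n); d <- as.integer(d)
  n_components <- as.integer(n_components)
  drop_components <- as.integer(drop_components)
  if (n < 10L) stop_smd("n must be >= 10")
  if (d < 1L || n_components < 1L) stop_smd("invalid sizes")
  if (drop_components >= n_components) {
    stop_smd("drop_components must be < n_components")
  }
  with_seed(derive_seed(seed, "gen_embedding_pair"), {
    # component centres spread to be well separated relative to unit noise
    centers <- matrix(stats::rnorm(n_components * d, sd = 4), n_components, d)
    dir <- stats::rnorm(d)
    dir <- dir / sqrt(sum(dir^2))
    draw <- function(n_draw, centers_use, sd_use, offset) {
      comp <- sample.int(nrow(centers_use), n_draw, replace = TRUE)
      pts <- centers_use[comp, , drop = FALSE] +
        matrix(stats::rnorm(n_draw * d, sd = sd_use), n_draw, d)
      sweep(pts, 2, offset, "+")
    }
    ref <- draw(n, centers, 1, rep(0, d))
    keep <- seq_len(n_components - drop_components)
    syn <- draw(n, centers[keep, , drop = FALSE], scale, shift * dir)
    list(reference = feature_matrix(ref,
                                    feature_names = paste0("f", seq_len(d))),
         synthetic = feature_matrix(syn,
                                    feature_names = paste0("f", seq_len(d))))
  })
}

#' Generate subgrouped embedding pairs with group-specific shifts
#'
#' One [gen_embedding_pair()] call per group (group-specific shift, shared
#' dimension), with subgroup labels attached -- the consistency-module
#' fixture. A group whose shift differs plants a detectable stability
#' violation.
#'
#' @param groups data.frame (or list of lists) with columns/fields
#'   `label`, `n`, `shift`; at least 2 groups, unique labels.
#' @param d feature dimension.
#' @param seed integer seed.
#' @return list with labelled `reference` and `synthetic`
#'   [feature_matrix()] objects.
#' @export
gen_subgrouped_embeddings <- function(groups, d, seed = 1L) {
  if (is.data.frame(groups)) {
    groups <- lapply(seq_len(nrow(groups)), function(i) as.list(groups[i, ]))
  }
  if (length(groups) < 2L) stop_smd("need >= 2 groups")
  labels <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop_smd("duplicate group labels")
  parts <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    pair <- gen_embedding_pair(g$n, d, shift = g$shift,
                               seed = derive_seed(seed, paste0("subgroup:", g$label)))
    list(ref = pair$reference$values, syn = pair$synthetic$values,
         lab = rep(g$label, g$n))
  })
  ref <- do.call(rbind, lapply(parts, `[[`, "ref"))
  syn <- do.call(rbind, lapply(parts, `[[`, "syn"))
  lab <- unlist(lapply(parts, `[[`, "lab"))
  list(reference = feature_matrix(ref, subgroups = lab),
       synthetic = feature_matrix(syn, subgroups = lab))
}

#' Generate toy lesion images with planted constraint violations
#'
#' Each image is a noisy dark background with one bright ellipse "lesion"
#' of seeded diameter inside `diameter_range`. Exactly
#' `floor(violation_fraction * n)` images are planted with a violation:
#' either a lesion diameter outside the allowed range or a second lesion.
#' The returned ground-truth table lists per-image lesion count and
#' diameter, so constraint metrics evaluated on it must recover the planted
#' fraction exactly.
#'
#' @param n image count.
#' @param size image side length in pixels.
#' @param diameter_range `(lo, hi)` valid lesion diameter in pixels.
#' @param violation_fraction fraction of images planted with a violation.
#' @param seed integer seed.
#' @return list with `images` ([image_set()]) and `truth` (data.frame with
#'   columns `id`, `lesion_count`, `lesion_diameter`, `violating`).
#' @export
gen_toy_images <- function(n, size = 48L, diameter_range = c(8, 16),
                           violation_fraction = 0, seed = 1L) {
  n <- as.integer(n); size <- as.integer(size)
  f <- violation_fraction
  if (f < 0 || f > 1) stop_smd("violation_fraction must be in [0, 1]")
  lo <- diameter_range[1]; hi <- diameter_range[2]
  if (hi * 1.5 + 4 > size) stop_smd("lesion cannot fit in image of size %d", size)
  n_bad <- floor(f * n)
  with_seed(derive_seed(seed, "gen_toy_images"), {
    bad_idx <- if (n_bad > 0) sort(sample.int(n, n_bad)) else integer()
    coords <- expand.grid(r = seq_len(size), c = seq_len(size))
    draw_lesion <- function(img, cx, cy, diam) {
      rad <- diam / 2
      mask <- (coords$r - cy)^2 + (coords$c - cx)^2 <= rad^2
      img[cbind(coords$r[mask], coords$c[mask])] <- 200
      img
    }
    truth <- data.frame(id = sprintf("img%04d", seq_len(n)),
                        lesion_count = 1L, lesion_diameter = 0,
                        violating = FALSE, stringsAsFactors = FALSE)
    images <- vector("list", n)
    for (i in seq_len(n)) {
      img <- matrix(pmin(pmax(stats::rnorm(size * size, 30, 8), 0), 255),
                    size, size)
      margin <- ceiling(hi * 0.75) + 2
      cx <- sample(seq(margin, size - margin), 1)
      cy <- sample(seq(margin, size - margin), 1)
      if (i %in% bad_idx) {
        if (stats::runif(1) < 0.5) {
          # diameter violation: outside the allowed range
          diam <- if (stats::runif(1) < 0.5) max(2, lo / 2) else hi * 1.5
          img <- draw_lesion(img, cx, cy, diam)
          truth$lesion_diameter[i] <- diam
        } else {
          # count violation: a second lesion
          diam <- stats::runif(1, lo, hi)
          img <- draw_lesion(img, cx, cy, diam)
          cx2 <- max(3, min(size - 2, cx + sample(c(-1, 1), 1) * margin))
          cy2 <- max(3, min(size - 2, cy - sample(c(-1, 1), 1) * margin))
          img <- draw_lesion(img, cx2, cy2, max(2, lo / 2))
          truth$lesion_count[i] <- 2L
          truth$lesion_diameter[i] <- diam
        }
        truth$violating[i] <- TRUE
      } else {
        diam <- stats::runif(1, lo, hi)
        img <- draw_lesion(img, cx, cy, diam)
        truth$lesion_diameter[i] <- diam
      }
      images[[i]] <- img
    }
    list(images = image_set(images, dynamic_range = 255, ids = truth$id),
         truth = truth)
  })
}

#' Generate a tabular dataset with a planted anonymity level
#'
#' Quasi-identifier tuples are constructed so the minimum equivalence class
#' has exactly `k_star` rows (one planted minimum class; all other classes
#' strictly larger). The sensitive attribute is drawn independently of the
#' classes. Exactly `floor(missing_rate * cells)` cells (over all table
#' cells) are set missing at seeded positions, never inside
#' quasi-identifier or sensitive columns, so the missing-percentage metric
#' recovers the rate to within one cell.
#'
#' @param n row count.
#' @param k_star planted minimum equivalence-class size (>= 1).
#' @param sensitive_kind `"categorical"` or `"numeric"`.
#' @param missing_rate target missing fraction over all table cells (must
#'   fit inside the free columns: `missing_rate <= 0.4` for this layout).
#' @param seed integer seed.
#' @return a [tabular_dataset()] with quasi-identifiers `age_band`, `zip`,
#'   sensitive attribute `diagnosis` (or `lab_value`), and two free
#'   columns `note_len`, `visit_count` that receive the planted missing
#'   cells.
#' @export
gen_anonymity_table <- function(n, k_star, sensitive_kind = c("categorical", "numeric"),
                                missing_rate = 0, seed = 1L) {
  sensitive_kind <- match.arg(sensitive_kind)
  n <- as.integer(n); k_star <- as.integer(k_star)
  if (k_star < 1L) stop_smd("k_star must be >= 1")
  if (n < k_star + (k_star + 1)) {
    stop_smd("n = %d too small to plant a minimum class of %d plus a larger class",
             n, k_star)
  }
  with_seed(derive_seed(seed, "gen_anonymity_table"), {
    # first class: exactly k_star rows; remaining rows split into classes of
    # size >= k_star + 1 so the planted class is the strict minimum
    sizes <- k_star
    remaining <- n - k_star
    while (remaining > 0) {
      take <- min(remaining, k_star + 1 + sample(0:2, 1))
      if (remaining - take != 0 && remaining - take < k_star + 1) {
        take <- remaining
      }
      sizes <- c(sizes, take)
      remaining <- remaining - take
    }
    class_id <- rep(seq_along(sizes), sizes)
    age_band <- paste0("age", 20 + 5 * class_id)
    zip <- sprintf("z%03d", 100 + class_id)
    sensitive <- if (sensitive_kind == "categorical") {
      sample(c("dxA", "dxB", "dxC"), n, replace = TRUE)
    } else {
      round(stats::rnorm(n, 100, 15), 1)
    }
    note_len <- sample(50:500, n, replace = TRUE)
    visit_count <- sample(1:20, n, replace = TRUE)
    df <- data.frame(age_band = age_band, zip = zip, note_len = note_len,
                     visit_count = visit_count, stringsAsFactors = FALSE)
    sens_name <- if (sensitive_kind == "categorical") "diagnosis" else "lab_value"
    df[[sens_name]] <- sensitive
    # planted count is a fraction of ALL table cells (so the missing
    # percentage metric recovers missing_rate exactly), but positions land
    # only in the free columns, never in quasi-identifiers or the
    # sensitive attribute
    free_cols <- c("note_len", "visit_count")
    n_miss <- floor(missing_rate * n * ncol(df))
    if (n_miss > n * length(free_cols)) {
      stop_smd("missing_rate %.2f needs more cells than the free columns hold",
               missing_rate)
    }
    if (n_miss > 0) {
      pos <- sample.int(n * length(free_cols), n_miss)
      for (p in pos) {
        col <- free_cols[((p - 1) %/% n) + 1]
        row <- ((p - 1) %% n) + 1
        df[row, col] <- NA
      }
    }
    tabular_dataset(df,
                    required_fields = c("age_band", "zip", sens_name,
                                        "note_len", "visit_count"),
                    quasi_identifiers = c("age_band", "zip"),
                    sensitive_attribute = sens_name)
  })
}

#' Plant missing cells into a tabular dataset
#'
#' Sets exactly `floor(rate * cells)` cells to the missing marker at seeded
#' positions drawn without replacement over the whole table.
#'
#' @param data a [tabular_dataset()].
#' @param rate missing fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return the dataset with planted missing cells.
#' @export
inject_missing <- function(data, rate, seed = 1L) {
  stopifnot(inherits(data, "tabular_dataset"))
  if (rate < 0 || rate > 1) stop_smd("rate must be in [0, 1]")
  df <- data$data
  cells <- nrow(df) * ncol(df)
  n_miss <- floor(rate * cells)
  if (n_miss > 0) {
    pos <- with_seed(derive_seed(seed, "inject_missing"),
                     sample.int(cells, n_miss))
    for (p in pos) {
      col <- ((p - 1) %/% nrow(df)) + 1
      row <- ((p - 1) %% nrow(df)) + 1
      df[row, col] <- NA
    }
  }
  tabular_dataset(df, column_kinds = data$column_kinds,
                  required_fields = data$required_fields,
                  quasi_identifiers = data$quasi_identifiers,
                  sensitive_attribute = data$sensitive_attribute)
}
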