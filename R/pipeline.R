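#' Configuration for a full stability study
#'
#' @param modalities subset of `c("T1w", "T2w")`.
#' @param analyses subset of `1:5`; selection needs 1-4, confirmation
#'   needs 5.
#' @param phantom_size voxels per axis of the simulated phantom.
#' @param phantom_seed,scenario_seed integer seeds; a run is fully
#'   reproducible from the configuration.
#' @param Ng gray levels for feature discretization.
#' @param threshold ICC stability threshold (strict `>`).
#' @param preprocess a [preprocess_config()].
#' @param n_slices central axial slices kept per ROI.
#' @param max_images optional named list (e.g. `list(analysis5 = 20)`)
#'   truncating the scenario list of an analysis for scaled-down runs; the
#'   canonical design sizes are those of [make_scenarios()].
#' @param output_dir optional directory; when set, feature tables, ICC
#'   tables and selected sets are persisted as CSV/JSON at each stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(modalities = c("T1w", "T2w"), analyses = 1:5,
                       phantom_size = 64, phantom_seed = 1,
                       scenario_seed = 1, Ng = 32, threshold = 0.75,
                       preprocess = preprocess_config(), n_slices = 11,
                       max_images = list(), output_dir = NULL) {
  modalities <- match.arg(modalities, c("T1w", "T2w"), several.ok = TRUE)
  stopifnot(all(analyses %in% 1:5))
  structure(list(modalities = modalities, analyses = sort(analyses),
                 phantom_size = phantom_size, phantom_seed = phantom_seed,
                 scenario_seed = scenario_seed, Ng = Ng,
                 threshold = threshold, preprocess = preprocess,
                 n_slices = n_slices, max_images = max_images,
                 output_dir = output_dir),
            class = "run_config")
}

# the preprocessing matched to each source of variability; analysis 5
# applies the full chain (acquisition-space corrections first, grid change,
# standardization last)
analysis_steps <- function(analysis_id) {
  switch(analysis_id,
         "zscore", "resample", "denoise", "bias",
         c("bias", "denoise", "resample", "zscore"))
}

# transfer native-grid ROI masks to an image grid (nearest neighbour)
transfer_masks <- function(masks, image) {
  lapply(masks, function(m) {
    if (isTRUE(all.equal(m$spacing, image$spacing, tolerance = 1e-12)) &&
        all(dim(m$mask) == dim(image$data)))
      return(m)
    v <- volume_image(array(as.numeric(m$mask), dim = dim(m$mask)),
                      m$spacing)
    r <- resample_volume(v, image$spacing, "nearest")
    md <- r$data > 0.5
    if (!any(md)) md[which.max(r$data)] <- TRUE
    roi_mask(md, m$tissue_id, m$name, image$spacing)
  })
}

extract_rois_features <- function(image, masks, Ng) {
  vapply(masks, function(m) {
    tryCatch(extract_all(image, m, Ng),
             error = function(e) {
               rep(NA_real_, nrow(feature_manifest()))
             })
  }, numeric(nrow(feature_manifest())))
}

#' Run one stability analysis end-to-end
#'
#' For each acquisition in the analysis design: simulate the scan, extract
#' all features from every ROI on the original image and on the image
#' preprocessed with the analysis-matched operator (the full chain for
#' analysis 5), then compute per-feature ICC(A,1) over the (ROI x
#' condition) matrices for both routes and Wilcoxon signed-rank
#' comparisons of ICC by feature class.
#'
#' @param config a [run_config()].
#' @param analysis_id integer 1-5.
#' @param modality `"T1w"` or `"T2w"`.
#' @param phantom,rois optionally a pre-built phantom and its ROI list (so
#'   several analyses can share them); built from `config` when `NULL`.
#' @return List with `feature_table` (long data.frame: modality, analysis,
#'   condition, route, roi, feature, class, value), `icc` (data.frame:
#'   feature, class, group, icc_original, icc_preprocessed), `wilcoxon`
#'   (per feature-group comparison of preprocessed vs original ICC) and
#'   `n_conditions`.
#' @export
run_analysis <- function(config, analysis_id, modality,
                         phantom = NULL, rois = NULL) {
  if (is.null(phantom))
    phantom <- build_default_phantom(config$phantom_size,
                                     config$phantom_seed)
  if (is.null(rois)) rois <- extract_rois(phantom, config$n_slices)
  scen <- make_scenarios(analysis_id, modality, config$scenario_seed)
  lim <- config$max_images[[paste0("analysis", analysis_id)]]
  if (!is.null(lim)) scen$params <- scen$params[seq_len(min(lim,
                                                   length(scen$params)))]
  manifest <- feature_manifest()
  steps <- analysis_steps(analysis_id)
  rows <- list()
  for (ci in seq_along(scen$params)) {
    p <- scen$params[[ci]]
    img <- simulate_acquisition(phantom, p)
    masks_acq <- transfer_masks(rois, img)
    f_orig <- extract_rois_features(img, masks_acq, config$Ng)
    pre <- apply_pipeline(img, masks_acq, steps, config$preprocess)
    f_pre <- extract_rois_features(pre$image, pre$masks, config$Ng)
    for (route in c("original", "preprocessed")) {
      f <- if (route == "original") f_orig else f_pre
      rows[[length(rows) + 1]] <- data.frame(
        modality = modality, analysis = analysis_id, condition = ci,
        route = route,
        roi = rep(names(rois), each = nrow(manifest)),
        feature = rep(manifest$feature, times = length(rois)),
        class = rep(manifest$class, times = length(rois)),
        value = as.numeric(f), stringsAsFactors = FALSE)
    }
  }
  ft <- do.call(rbind, rows)
  icc <- icc_table(ft, manifest)
  wil <- wilcoxon_by_group(icc, analysis_id)
  res <- list(feature_table = ft, icc = icc, wilcoxon = wil,
              n_conditions = length(scen$params),
              analysis_id = analysis_id, modality = modality)
  persist_analysis(res, config)
  res
}

# per-feature ICC over (roi x condition) matrices for each route
icc_table <- function(ft, manifest = feature_manifest()) {
  out <- manifest[, c("feature", "class", "group")]
  for (route in c("original", "preprocessed")) {
    vals <- vapply(manifest$feature, function(fe) {
      sub <- ft[ft$feature == fe & ft$route == route, ]
      m <- tapply(sub$value, list(sub$roi, sub$condition), mean)
      keep <- colSums(is.na(m)) == 0
      m <- m[, keep, drop = FALSE]
      if (ncol(m) < 2 || nrow(m) < 2) return(NA_real_)
      icc_a1(m)$icc
    }, numeric(1))
    out[[paste0("icc_", route)]] <- unname(vals)
  }
  names(out)[names(out) == "icc_original"] <- "icc_original"
  names(out)[names(out) == "icc_preprocessed"] <- "icc_preprocessed"
  out
}

# Wilcoxon signed-rank of preprocessed vs original ICC, pooled by feature
# group (FOS and textural always; SS only where the grid changes)
wilcoxon_by_group <- function(icc, analysis_id) {
  groups <- c("FOS", "textural")
  if (analysis_id %in% c(2, 5)) groups <- c("SS", groups)
  out <- list()
  for (g in groups) {
    sub <- icc[icc$group == g & !is.na(icc$icc_original) &
                 !is.na(icc$icc_preprocessed), ]
    if (nrow(sub) == 0) next
    out[[g]] <- wilcoxon_signed_rank(sub$icc_original, sub$icc_preprocessed)
  }
  out
}

persist_analysis <- function(res, config) {
  if (is.null(config$output_dir)) return(invisible(NULL))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  tag <- paste0(res$modality, "_analysis", res$analysis_id)
  write.csv(res$feature_table,
            file.path(config$output_dir, paste0("features_", tag, ".csv")),
            row.names = FALSE)
  write.csv(res$icc,
            file.path(config$output_dir, paste0("icc_", tag, ".csv")),
            row.names = FALSE)
  invisible(NULL)
}

#' Run the full stability study
#'
#' Simulates every enabled analysis for every enabled modality, selects the
#' stable feature set per modality (ICC above threshold in analyses 1-4 on
#' the preprocessed images; shape features judged on analysis 2), compares
#' modalities with the Jaccard index, and confirms the stable sets on the
#' random-parameter acquisitions (analysis 5).
#'
#' @param config a [run_config()].
#' @return Object of class `stability_report`: per-modality per-analysis
#'   results, `stable_sets`, `jaccard`, `confirmed` (sets and percentage
#'   fractions).
#' @export
run_full_study <- function(config = run_config()) {
  phantom <- build_default_phantom(config$phantom_size, config$phantom_seed)
  rois <- extract_rois(phantom, config$n_slices)
  results <- list()
  for (mod in config$modalities) {
    results[[mod]] <- list()
    for (a in config$analyses)
      results[[mod]][[paste0("analysis", a)]] <-
        run_analysis(config, a, mod, phantom, rois)
  }
  stable_sets <- list()
  confirmed <- list()
  for (mod in config$modalities) {
    if (all(paste0("analysis", 1:4) %in% names(results[[mod]]))) {
      # NA ICC means the feature could not be evaluated for some grid;
      # treated as unstable
      tabs <- lapply(results[[mod]][paste0("analysis", 1:4)], function(r)
        stats::setNames(ifelse(is.na(r$icc$icc_preprocessed), -Inf,
                               r$icc$icc_preprocessed), r$icc$feature))
      stable_sets[[mod]] <- select_stable(tabs, config$threshold)
      if (length(stable_sets[[mod]]) == 0)
        warning("no stable features for ", mod, " at threshold ",
                config$threshold)
      if ("analysis5" %in% names(results[[mod]]) &&
          length(stable_sets[[mod]]) > 0) {
        icc5 <- results[[mod]]$analysis5$icc
        v5 <- stats::setNames(ifelse(is.na(icc5$icc_preprocessed), -Inf,
                                     icc5$icc_preprocessed), icc5$feature)
        confirmed[[mod]] <- confirm_on_random(stable_sets[[mod]], v5,
                                              config$threshold)
      }
    }
  }
  jac <- if (length(stable_sets) == 2)
    jaccard_index(stable_sets[[1]], stable_sets[[2]]) else NA_real_
  report <- structure(list(config = config, results = results,
                           stable_sets = stable_sets, jaccard = jac,
                           confirmed = confirmed),
                      class = "stability_report")
  persist_report(report)
  report
}

persist_report <- function(report) {
  dir <- report$config$output_dir
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sets <- list(stable_sets = report$stable_sets,
               jaccard = report$jaccard,
               confirmed = lapply(report$confirmed, function(x)
                 list(confirmed = x$confirmed, fraction_pct = x$fraction)))
  jsonlite::write_json(sets, file.path(dir, "stable_sets.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  for (mod in names(x$stable_sets)) {
    cat("  ", mod, ": ", length(x$stable_sets[[mod]]),
        " stable features", sep = "")
    if (!is.null(x$confirmed[[mod]]))
      cat("; ", length(x$confirmed[[mod]]$confirmed), " confirmed (",
          sprintf("%.2f%%", x$confirmed[[mod]]$fraction), ")", sep = "")
    cat("\n")
  }
  if (!is.na(x$jaccard))
    cat("  Jaccard(T1w, T2w) =", sprintf("%.2f", x$jaccard), "\n")
  for (mod in names(x$results)) for (a in names(x$results[[mod]])) {
    w <- x$results[[mod]][[a]]$wilcoxon
    for (g in names(w)) {
      wi <- w[[g]]
      cat(sprintf("  %s %s %s: median ICC change %+0.3g [%0.3g-%0.3g], P = %0.3g%s\n",
                  mod, a, g, wi$median_diff, wi$iqr_diff[1], wi$iqr_diff[2],
                  wi$p, if (wi$degenerate) " (no change)" else ""))
    }
  }
  invisible(x)
}
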