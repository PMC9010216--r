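#' Configure an end-to-end analysis run
#'
#' Bundles every choice of the simulation -> connectivity -> GLM ->
#' inference pipeline into one validated object: input mode, ROI table,
#' seed/target configuration, model and tested term, inference tail,
#' TFNBS parameters, FDR level and the master seed from which all stage
#' seeds are derived (counter-based, so stages are independently
#' reproducible).
#'
#' @param mode \code{"synthetic"} (generate everything),
#'   \code{"fc"} (read per-subject connectivity TSVs) or
#'   \code{"timeseries"} (read time-series TSVs and compute
#'   connectivity).
#' @param output_dir directory for result files (created if needed).
#' @param roi_table_path ROI table TSV; \code{NULL} uses the packaged
#'   atlas transcription (real-data modes) or a synthetic label set.
#' @param config_name seed/target configuration for real-data modes; in
#'   synthetic mode all pairs of the synthetic atlas are tested.
#' @param model,term GLM model and tested column.
#' @param tail inference tail for FDR reporting and TFNBS.
#' @param tfnbs a [tfnbs_params()] (its tail/seed are overridden by
#'   \code{tail} and the derived stage seed).
#' @param fdr_q FDR level in (0, 1).
#' @param seed master integer seed.
#' @param cohort_path,fc_manifest_path,timeseries_dir real-data inputs:
#'   cohort TSV; manifest TSV with columns \code{subject_id},
#'   \code{path} pointing at per-subject FC (or time-series) TSVs.
#' @param spec,effects,n_rois synthetic-mode generator settings
#'   ([cohort_spec()], [effect_spec()], atlas size).
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(mode = c("synthetic", "fc", "timeseries"),
                            output_dir = tempfile("fcmod_run_"),
                            roi_table_path = NULL,
                            config_name = "SP-SP",
                            model = "full", term = "group_x_psqi",
                            tail = "two",
                            tfnbs = tfnbs_params(),
                            fdr_q = 0.05, seed = 1L,
                            cohort_path = NULL,
                            fc_manifest_path = NULL,
                            timeseries_dir = NULL,
                            spec = cohort_spec(),
                            effects = effect_spec(),
                            n_rois = 20L) {
  mode <- match.arg(mode)
  if (!.is_number(fdr_q) || fdr_q <= 0 || fdr_q >= 1) {
    stop("fdr_q must lie in (0, 1)")
  }
  if (mode != "synthetic") {
    if (is.null(cohort_path) || !file.exists(cohort_path)) {
      stop("cohort_path must point to an existing TSV in ", mode, " mode")
    }
    if (is.null(fc_manifest_path) || !file.exists(fc_manifest_path)) {
      stop("fc_manifest_path must point to an existing manifest TSV")
    }
  }
  if (!is.null(roi_table_path) && !file.exists(roi_table_path)) {
    stop("roi_table_path does not exist: ", roi_table_path)
  }
  structure(list(mode = mode, output_dir = output_dir,
                 roi_table_path = roi_table_path,
                 config_name = config_name, model = model, term = term,
                 tail = tail, tfnbs = tfnbs, fdr_q = fdr_q,
                 seed = as.integer(seed), cohort_path = cohort_path,
                 fc_manifest_path = fc_manifest_path,
                 timeseries_dir = timeseries_dir,
                 spec = spec, effects = effects,
                 n_rois = as.integer(n_rois)),
            class = "pipeline_config")
}

#' Validate pipeline inputs without running the analysis
#'
#' Checks subject alignment between the cohort and the FC/time-series
#' manifest, ROI label consistency against the ROI table, and missing
#' values, returning an actionable report instead of failing midway.
#'
#' @param config a [pipeline_config()].
#' @return list of class \code{"validation_report"} with a
#'   \code{failures} character vector (empty when everything is
#'   consistent).
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  failures <- character(0)
  if (config$mode == "synthetic") {
    return(structure(list(failures = failures),
                     class = "validation_report"))
  }
  cohort <- tryCatch(read_cohort(config$cohort_path), error = function(e) {
    failures <<- c(failures, paste("cohort:", conditionMessage(e)))
    NULL
  })
  manifest <- tryCatch(read.delim(config$fc_manifest_path,
                                  stringsAsFactors = FALSE),
                       error = function(e) {
                         failures <<- c(failures,
                                        paste("manifest:",
                                              conditionMessage(e)))
                         NULL
                       })
  if (!is.null(manifest) &&
      !all(c("subject_id", "path") %in% names(manifest))) {
    failures <- c(failures,
                  "manifest: needs columns subject_id and path")
    manifest <- NULL
  }
  if (!is.null(cohort) && !is.null(manifest)) {
    miss <- setdiff(cohort$subject_id, manifest$subject_id)
    if (length(miss) > 0L) {
      failures <- c(failures, paste("subject(s) missing from manifest:",
                                    paste(miss, collapse = ", ")))
    }
    extra <- setdiff(manifest$subject_id, cohort$subject_id)
    if (length(extra) > 0L) {
      failures <- c(failures, paste("manifest subject(s) not in cohort:",
                                    paste(extra, collapse = ", ")))
    }
    base <- dirname(config$fc_manifest_path)
    roi_names <- NULL
    if (!is.null(config$roi_table_path)) {
      rois <- tryCatch(load_roi_table(config$roi_table_path),
                       error = function(e) NULL)
      if (!is.null(rois)) roi_names <- rois$name
    }
    for (k in seq_len(nrow(manifest))) {
      f <- manifest$path[k]
      if (!file.exists(f)) f <- file.path(base, manifest$path[k])
      if (!file.exists(f)) {
        failures <- c(failures,
                      paste0("file for subject ", manifest$subject_id[k],
                             " not found: ", manifest$path[k]))
        next
      }
      labels <- tryCatch({
        if (config$mode == "fc") colnames(read_fc_matrix(f))
        else colnames(read_timeseries(f))
      }, error = function(e) {
        failures <<- c(failures,
                       paste0(manifest$subject_id[k], ": ",
                              conditionMessage(e)))
        NULL
      })
      if (!is.null(labels) && !is.null(roi_names) &&
          !all(labels %in% roi_names)) {
        bad <- setdiff(labels, roi_names)
        failures <- c(failures,
                      paste0("subject ", manifest$subject_id[k],
                             ": ROI label(s) not in ROI table: ",
                             paste(utils::head(bad, 5), collapse = ", ")))
      }
    }
  }
  structure(list(failures = failures), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (length(x$failures) == 0L) {
    cat("Input validation: OK (no failures)\n")
  } else {
    cat("Input validation:", length(x$failures), "failure(s)\n")
    for (f in x$failures) cat("  -", f, "\n")
  }
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages and writes the result files: per-edge results
#' TSV (GLM statistics, FDR-adjusted p, TFNBS score, FWE p), the
#' permutation null-maximum TSV, the cohort group-comparison TSV, and a
#' JSON provenance sidecar recording every parameter, all stage seeds
#' and the package version. Identical config + seed reproduce identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a result bundle: \code{cohort}, \code{fit}
#'   (the [edge_glm()] object), \code{fdr}, \code{tfnbs}
#'   (the [tfnbs_test()] result), \code{comparison}, \code{files}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  rep_v <- validate_inputs(config)
  if (length(rep_v$failures) > 0L) {
    stop("input validation failed:\n  ",
         paste(rep_v$failures, collapse = "\n  "))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(cohort = .derive_seed(config$seed, 1L),
                data = .derive_seed(config$seed, 2L),
                perm = .derive_seed(config$seed, 3L))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (config$mode == "synthetic") {
    spec <- config$spec
    spec$seed <- seeds$cohort
    cohort <- stage("simulate_cohort", simulate_cohort(spec))
    dat <- stage("simulate_fc",
                 simulate_fc(cohort, config$n_rois, config$effects,
                             seed = seeds$data))
    fc <- dat$fc_observed
    rois <- synthetic_roi_set(config$n_rois)
    dimnames(fc)[[1]] <- dimnames(fc)[[2]] <- rois$name
    mask <- stage("build_edge_mask",
                  build_edge_mask(config$config_name, rois))
  } else {
    cohort <- stage("read_cohort", read_cohort(config$cohort_path))
    manifest <- read.delim(config$fc_manifest_path,
                           stringsAsFactors = FALSE)
    manifest <- manifest[match(cohort$subject_id, manifest$subject_id), ]
    base <- dirname(config$fc_manifest_path)
    resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
    fc <- stage("load_connectivity", {
      if (config$mode == "fc") {
        mats <- lapply(manifest$path, function(p)
          read_fc_matrix(resolve(p)))
        p <- ncol(mats[[1]])
        array(unlist(mats), dim = c(p, p, length(mats)),
              dimnames = list(colnames(mats[[1]]), colnames(mats[[1]]),
                              cohort$subject_id))
      } else {
        ts_list <- lapply(manifest$path, function(p) {
          x <- read_timeseries(resolve(p))
          bandpass(to_percent_signal(x),
                   sampling_interval = attr(x, "sampling_interval"))
        })
        names(ts_list) <- cohort$subject_id
        compute_fc_stack(ts_list)
      }
    })
    rois <- stage("load_roi_table", load_roi_table(
      if (is.null(config$roi_table_path)) fcmod_roi_table()
      else config$roi_table_path))
    keep <- match(dimnames(fc)[[1]], rois$name)
    if (anyNA(keep)) stop("pipeline stage 'mask': FC ROI labels missing ",
                          "from the ROI table")
    mask <- stage("build_edge_mask",
                  .restrict_mask(build_edge_mask(config$config_name, rois),
                                 keep, dimnames(fc)[[1]]))
  }

  fit <- stage("edge_glm",
               edge_glm(fc, cohort, mask = mask, model = config$model,
                        term = config$term))
  p_raw <- switch(config$tail, two = fit$p_two, left = fit$p_left,
                  right = fit$p_right)
  fdr <- stage("bh_fdr", bh_fdr(ifelse(is.finite(p_raw), p_raw, 1),
                                q = config$fdr_q))
  params <- config$tfnbs
  params$tail <- config$tail
  params$seed <- seeds$perm
  tf <- stage("tfnbs_test",
              tfnbs_test(fc, cohort, mask = mask, model = config$model,
                         term = config$term, params = params))
  comparison <- stage("group_table", group_table(cohort))

  hash <- .config_hash(config[setdiff(names(config), "output_dir")])
  files <- list(
    edge_results = file.path(config$output_dir, "edge_results.tsv"),
    null_max = file.path(config$output_dir, "null_max.tsv"),
    comparison = file.path(config$output_dir, "group_comparison.tsv"),
    provenance = file.path(config$output_dir, "provenance.json")
  )
  res <- edge_results(fit, fdr_q = config$fdr_q)
  key_fit <- paste(fit$roi_labels[fit$edges[, 1]],
                   fit$roi_labels[fit$edges[, 2]])
  key_res <- paste(res$roi_i, res$roi_j)
  res$p_fdr_tail <- fdr$p_adjusted[match(key_res, key_fit)]
  res$tfnbs_score <- tf$score[match(key_res, key_fit)]
  res$p_fwe <- tf$p_fwe[match(key_res, key_fit)]
  res$provenance_hash <- hash
  .write_tsv(res, files$edge_results)
  write_null_max(tf, files$null_max)
  comparison$provenance_hash <- hash
  .write_tsv(comparison, files$comparison)
  prov <- list(package_version = as.character(packageVersion("fcmod")),
               hash = hash, mode = config$mode, seed = config$seed,
               stage_seeds = seeds, model = config$model,
               term = config$term, tail = config$tail,
               fdr_q = config$fdr_q,
               tfnbs = unclass(params),
               n_subjects = nrow(cohort),
               n_edges = nrow(fit$edges),
               mask_config = fit$mask_config)
  jsonlite::write_json(prov, files$provenance, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, fit = fit, fdr = fdr, tfnbs = tf,
                 comparison = comparison, files = files,
                 provenance = prov))
}

# Re-index a mask built on the full ROI table onto the ROI subset (and
# order) present in a connectivity stack.
.restrict_mask <- function(mask, keep, labels) {
  pos <- match(seq_along(attr(mask, "roi_names")), keep)  # roi_id -> stack idx
  i2 <- pos[mask$i]; j2 <- pos[mask$j]
  ok <- !is.na(i2) & !is.na(j2)
  out <- data.frame(i = pmin(i2[ok], j2[ok]), j = pmax(i2[ok], j2[ok]))
  out <- unique(out[order(out$i, out$j), ])
  rownames(out) <- NULL
  structure(out, config = attr(mask, "config"), n_tests = nrow(out),
            roi_names = labels, class = c("edge_mask", "data.frame"))
}
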