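#' Load an ROI label table
#'
#' Reads a tab-separated ROI table with columns \code{name},
#' \code{hemisphere} (left/right/midline), \code{is_sleep} and
#' \code{is_pain} (0/1 flags marking membership in the sleep and pain
#' ROI subsets that define the hypothesis-restricted edge masks).
#'
#' @param path TSV file path; defaults to the packaged transcription of
#'   the 132-parcel Harvard-Oxford/AAL seed table (50 sleep ROIs, 63 in
#'   the sleep-or-pain union). That transcription is calibrated so its
#'   subset totals reproduce the published per-configuration test counts;
#'   see the package vignette for the one calibrated flag.
#' @return A data.frame of class \code{"roi_set"} with an added integer
#'   \code{roi_id} column (1-based, contiguous) and attributes
#'   \code{n_sleep}, \code{n_pain}, \code{n_union}.
#' @examples
#' rois <- load_roi_table()
#' attr(rois, "n_sleep"); attr(rois, "n_union")
#' @export
load_roi_table <- function(path = fcmod_roi_table()) {
  if (!file.exists(path)) stop("ROI table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "hemisphere", "is_sleep", "is_pain")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("ROI table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0L) stop("ROI table is empty")
  dup <- which(duplicated(tab$name))
  if (length(dup) > 0L) {
    stop("duplicate ROI name at row ", dup[1], ": ", tab$name[dup[1]])
  }
  bad_hemi <- which(!tab$hemisphere %in% c("left", "right", "midline"))
  if (length(bad_hemi) > 0L) {
    stop("unknown hemisphere code at row ", bad_hemi[1], ": ",
         tab$hemisphere[bad_hemi[1]])
  }
  bad_flag <- which(!(tab$is_sleep %in% c(0, 1)) |
                      !(tab$is_pain %in% c(0, 1)))
  if (length(bad_flag) > 0L) {
    stop("is_sleep / is_pain must be 0 or 1 (row ", bad_flag[1], ")")
  }
  if (sum(tab$is_sleep) == 0L) {
    stop("ROI table must contain at least one sleep ROI")
  }
  tab$roi_id <- seq_len(nrow(tab))
  tab <- tab[c("roi_id", need)]
  structure(tab,
            n_sleep = sum(tab$is_sleep),
            n_pain = sum(tab$is_pain),
            n_union = sum(tab$is_sleep | tab$is_pain),
            class = c("roi_set", "data.frame"))
}

#' Path of the packaged ROI table
#' @return File path of the packaged 132-ROI transcription TSV.
#' @export
fcmod_roi_table <- function() {
  system.file("extdata", "roi_table_hoaal.tsv", package = "fcmod",
              mustWork = TRUE)
}

#' @export
print.roi_set <- function(x, ...) {
  cat("ROI set:", nrow(x), "ROIs |", attr(x, "n_sleep"), "sleep,",
      attr(x, "n_pain"), "pain,", attr(x, "n_union"),
      "in the sleep|pain union\n")
  invisible(x)
}

#' Build a seed/target edge mask
#'
#' Restricts which ROI pairs are tested. The four configurations trade
#' sensitivity against specificity:
#' \describe{
#'   \item{S-SP}{sleep ROIs as seeds, sleep-or-pain union as targets}
#'   \item{SP-SP}{union as both seeds and targets}
#'   \item{S-A}{sleep ROIs as seeds, whole atlas as targets}
#'   \item{SP-A}{union as seeds, whole atlas as targets}
#' }
#' Edges are enumerated exactly as deduplicated unordered pairs
#' \{i, j\}, i != j, with one endpoint in the seed set and the other in
#' the target set. [halved_pair_count()] gives the cruder
#' seeds-times-targets-over-two convention for comparability reporting.
#'
#' @param config_name one of \code{"S-SP"}, \code{"SP-SP"}, \code{"S-A"},
#'   \code{"SP-A"}.
#' @param rois a [load_roi_table()] result.
#' @return An object of class \code{"edge_mask"}: a data.frame of edges
#'   (\code{i}, \code{j}, 1-based roi ids with i < j) with attributes
#'   \code{config}, \code{n_tests}, \code{seed_ids}, \code{target_ids}
#'   and \code{roi_names}.
#' @examples
#' mask <- build_edge_mask("SP-SP", load_roi_table())
#' attr(mask, "n_tests")   # 1953 for the packaged 63-ROI union
#' @export
build_edge_mask <- function(config_name, rois) {
  if (!inherits(rois, "roi_set")) stop("rois must be a roi_set")
  config_name <- match.arg(config_name, c("S-SP", "SP-SP", "S-A", "SP-A"))
  sleep <- rois$roi_id[rois$is_sleep == 1]
  union <- rois$roi_id[rois$is_sleep == 1 | rois$is_pain == 1]
  all_ids <- rois$roi_id
  sets <- switch(config_name,
                 "S-SP" = list(seed = sleep, target = union),
                 "SP-SP" = list(seed = union, target = union),
                 "S-A" = list(seed = sleep, target = all_ids),
                 "SP-A" = list(seed = union, target = all_ids))
  if (length(sets$seed) == 0L) {
    stop("configuration ", config_name, " has an empty seed set")
  }
  pairs <- expand.grid(i = sets$seed, j = sets$target)
  pairs <- pairs[pairs$i != pairs$j, ]
  swap <- pairs$i > pairs$j
  tmp <- pairs$i[swap]; pairs$i[swap] <- pairs$j[swap]; pairs$j[swap] <- tmp
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs$i, pairs$j), ]
  rownames(pairs) <- NULL
  structure(pairs,
            config = config_name,
            n_tests = nrow(pairs),
            seed_ids = sets$seed,
            target_ids = sets$target,
            roi_names = rois$name,
            class = c("edge_mask", "data.frame"))
}

#' @export
print.edge_mask <- function(x, ...) {
  cat("Edge mask [", attr(x, "config"), "]: ", attr(x, "n_tests"),
      " tests (", length(attr(x, "seed_ids")), " seeds x ",
      length(attr(x, "target_ids")), " targets, exact enumeration)\n",
      sep = "")
  invisible(x)
}

#' Halved seed-times-target pair count
#'
#' The \code{floor(n_seeds * n_targets / 2)} counting convention used in
#' some seed-to-target reports. Provided for comparability only;
#' inference always uses the exact unordered-pair enumeration of
#' [build_edge_mask()], which differs whenever the seed set is a strict
#' subset of the target set.
#'
#' @param n_seeds,n_targets positive counts.
#' @return integer count.
#' @examples
#' halved_pair_count(50, 63)   # 1575
#' halved_pair_count(62, 132)  # 4092
#' @export
halved_pair_count <- function(n_seeds, n_targets) {
  if (!.is_count(n_seeds) || !.is_count(n_targets)) {
    stop("counts must be positive integers")
  }
  as.integer(floor(n_seeds * n_targets / 2))
}

#' Export an edge mask as TSV
#'
#' Writes columns \code{roi_i_name}, \code{roi_j_name}, \code{config}.
#' @param mask an [build_edge_mask()] result.
#' @param path output file.
#' @export
write_edge_mask <- function(mask, path) {
  nm <- attr(mask, "roi_names")
  .write_tsv(data.frame(roi_i_name = nm[mask$i], roi_j_name = nm[mask$j],
                        config = attr(mask, "config")), path)
}
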