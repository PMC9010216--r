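#' Convert ROI time series to zero-mean percent signal
#'
#' Each column (ROI) is transformed to \code{100 * (x - m) / m} with
#' \code{m} its temporal mean, then demeaned. Constant nonzero columns
#' map to all zeros; columns whose mean is numerically zero are
#' degenerate (percent change is undefined) and raise an error naming
#' the ROI.
#'
#' @param ts numeric time x ROI matrix (column names = ROI labels).
#' @param tol smallest |column mean| accepted as a valid baseline.
#' @return matrix of the same shape with column means 0.
#' @examples
#' to_percent_signal(cbind(a = c(90, 100, 110)))
#' @export
to_percent_signal <- function(ts, tol = 1e-8) {
  ts <- .as_ts_matrix(ts)
  m <- colMeans(ts)
  bad <- which(abs(m) <= tol)
  if (length(bad) > 0L) {
    stop("temporal mean numerically zero for ROI ",
         .roi_name(ts, bad[1]), "; percent signal undefined")
  }
  out <- 100 * sweep(ts, 2, m, "-") %*% diag(1 / m, length(m))
  dimnames(out) <- dimnames(ts)
  sweep(out, 2, colMeans(out), "-")
}

#' Band-pass filter ROI time series
#'
#' Zero-phase (forward-backward) Butterworth band-pass, the standard
#' resting-state filter retaining slow hemodynamic fluctuations; the
#' default band is 0.008-0.09 Hz at a 2-second sampling interval.
#' Forward-backward application preserves zero-lag correlation structure;
#' odd-reflection edge padding suppresses filter transients. Output
#' columns are demeaned.
#'
#' @param ts numeric time x ROI matrix.
#' @param low,high band edges in Hz; \code{0 <= low < high < Nyquist}.
#' @param sampling_interval seconds between samples (default 2).
#' @param order Butterworth order per band edge (default 4).
#' @return filtered matrix, same shape, zero-mean columns.
#' @export
bandpass <- function(ts, low = 0.008, high = 0.09,
                     sampling_interval = 2, order = 4) {
  ts <- .as_ts_matrix(ts)
  nyq <- 1 / (2 * sampling_interval)
  if (!(low >= 0 && low < high)) stop("need 0 <= low < high")
  if (high >= nyq) {
    stop("high edge (", high, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  n <- nrow(ts)
  npad <- min(n - 1L, 3L * (length(bf$b) - 1L) * 8L)
  out <- apply(ts, 2, function(x) {
    xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
    yp <- signal::filtfilt(bf, xp)
    yp[(npad + 1):(npad + n)]
  })
  dimnames(out) <- dimnames(ts)
  sweep(out, 2, colMeans(out), "-")
}

#' Weighted Pearson correlation
#'
#' Zero-lagged bivariate weighted temporal correlation:
#' \deqn{r_w = \frac{\sum w (x - \bar x_w)(y - \bar y_w)}
#'   {\sqrt{\sum w (x - \bar x_w)^2 \sum w (y - \bar y_w)^2}}}
#' with weighted means. Uniform weights (the default) reduce exactly to
#' the plain Pearson correlation; nonuniform weights allow condition
#' weighting of time points.
#'
#' @param x,y numeric series of equal length.
#' @param w nonnegative weights (default uniform); must sum to > 0.
#' @return correlation in \[-1, 1\].
#' @export
weighted_pearson <- function(x, y, w = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  w <- .check_weights(w, length(x))
  wn <- w / sum(w)
  xm <- x - sum(wn * x); ym <- y - sum(wn * y)
  vx <- sum(w * xm^2); vy <- sum(w * ym^2)
  if (vx <= 0 || vy <= 0) stop("zero weighted variance; correlation undefined")
  sum(w * xm * ym) / sqrt(vx * vy)
}

#' Fisher z-transform of a correlation
#'
#' \code{atanh(r) = 0.5 * log((1 + r) / (1 - r))}, the
#' variance-stabilising transform under which correlation coefficients
#' are approximately normal; the space in which the per-edge GLM is
#' fitted.
#'
#' @param r correlation(s) with |r| < 1.
#' @return Fisher-z value(s).
#' @examples
#' fisher_z(0.5)  # 0.5 * log(3)
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisher_z requires |r| < 1")
  }
  atanh(r)
}

#' Compute a Fisher-z ROI-to-ROI connectivity matrix
#'
#' Pairwise (optionally weighted) Pearson correlations between all ROI
#' columns, Fisher-z transformed. Correlations are clamped to
#' |r| <= 1 - 1e-12 before the transform so numerically perfect
#' correlations (e.g. duplicated columns) yield a large finite z instead
#' of infinity. The diagonal is stored as \code{NA} (self-connectivity is
#' undefined and must never enter downstream statistics).
#'
#' @param ts numeric time x ROI matrix, already preprocessed
#'   (percent-signal / band-pass as appropriate).
#' @param w optional nonnegative weight per time point.
#' @param subject_id optional label stored as an attribute.
#' @return symmetric ROI x ROI matrix of Fisher-z values, diagonal
#'   \code{NA}.
#' @export
compute_fc_matrix <- function(ts, w = NULL, subject_id = NULL) {
  ts <- .as_ts_matrix(ts)
  if (ncol(ts) < 2L) stop("need at least two ROI columns")
  w <- .check_weights(w, nrow(ts))
  wn <- w / sum(w)
  centered <- sweep(ts, 2, colSums(wn * ts), "-")
  C <- t(centered) %*% (w * centered)
  v <- diag(C)
  degenerate <- which(v <= 0)
  if (length(degenerate) > 0L) {
    stop("zero weighted variance for ROI ", .roi_name(ts, degenerate[1]))
  }
  R <- C / sqrt(outer(v, v))
  R <- pmin(pmax(R, -1 + 1e-12), 1 - 1e-12)
  z <- atanh(R)
  diag(z) <- NA_real_
  z <- (z + t(z)) / 2
  dimnames(z) <- list(colnames(ts), colnames(ts))
  if (!is.null(subject_id)) attr(z, "subject_id") <- subject_id
  z
}

#' Connectivity matrices for a set of subjects
#'
#' Applies [compute_fc_matrix()] to each subject's time series and stacks
#' the results into an ROI x ROI x subject array, the package's standard
#' connectivity container.
#'
#' @param ts_list named list of time x ROI matrices (names = subject
#'   ids), e.g. the \code{timeseries} element of [simulate_timeseries()].
#' @param w optional weight vector shared across subjects.
#' @return ROI x ROI x subject array.
#' @export
compute_fc_stack <- function(ts_list, w = NULL) {
  if (!is.list(ts_list) || length(ts_list) == 0L) {
    stop("ts_list must be a nonempty list of time x ROI matrices")
  }
  mats <- lapply(seq_along(ts_list), function(s) {
    compute_fc_matrix(ts_list[[s]], w = w)
  })
  p <- ncol(mats[[1]])
  labels <- colnames(mats[[1]])
  ids <- names(ts_list)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(ts_list))
  array(unlist(mats), dim = c(p, p, length(mats)),
        dimnames = list(labels, labels, ids))
}

#' Read / write ROI time series as TSV
#'
#' Rows are time points, the first column is the time index in seconds,
#' remaining columns are ROI labels.
#'
#' @param ts time x ROI matrix with a \code{sampling_interval} attribute
#'   (defaults to 2 s when absent).
#' @param path file path.
#' @return \code{read_timeseries} returns the matrix with ROI column
#'   names and the sampling interval attached.
#' @export
write_timeseries <- function(ts, path) {
  ts <- .as_ts_matrix(ts)
  si <- attr(ts, "sampling_interval")
  if (is.null(si)) si <- 2
  df <- data.frame(time = (seq_len(nrow(ts)) - 1) * si)
  df <- cbind(df, as.data.frame(ts))
  .write_tsv(df, path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (ncol(df) < 3L) stop("time-series TSV needs a time column and >= 2 ROIs")
  out <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(out)) stop("time-series TSV contains missing samples")
  si <- if (nrow(df) > 1L) df$time[2] - df$time[1] else 2
  attr(out, "sampling_interval") <- si
  out
}

#' Read / write a square Fisher-z connectivity matrix as TSV
#'
#' Square layout with an ROI-name header column and row; the diagonal is
#' written as \code{NA}.
#'
#' @param z symmetric ROI x ROI matrix.
#' @param path file path.
#' @export
write_fc_matrix <- function(z, path) {
  df <- data.frame(roi = rownames(z), as.data.frame(z, optional = TRUE),
                   check.names = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_fc_matrix
#' @export
read_fc_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (nrow(m) != ncol(m)) stop("FC matrix TSV is not square")
  m
}

#' Long-format export of a connectivity stack
#'
#' One row per (subject, edge): columns \code{subject}, \code{roi_i},
#' \code{roi_j}, \code{z}, upper triangle only.
#'
#' @param stack ROI x ROI x subject array.
#' @param path file path.
#' @export
write_fc_long <- function(stack, path) {
  labels <- dimnames(stack)[[1]]
  edges <- .all_pairs(dim(stack)[1])
  rows <- lapply(seq_len(dim(stack)[3]), function(s) {
    data.frame(subject = dimnames(stack)[[3]][s],
               roi_i = labels[edges[, 1]], roi_j = labels[edges[, 2]],
               z = stack[, , s][edges])
  })
  .write_tsv(do.call(rbind, rows), path)
}

.as_ts_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stop("time series must be numeric")
  if (nrow(ts) < 2L) stop("time series needs at least two time points")
  if (anyNA(ts)) stop("time series contains missing samples")
  ts
}

.roi_name <- function(ts, col) {
  nm <- colnames(ts)
  if (is.null(nm)) paste0("#", col) else nm[col]
}

.check_weights <- function(w, n) {
  if (is.null(w)) return(rep(1, n))
  if (length(w) != n) stop("weight vector length must equal time dimension")
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be nonnegative")
  if (sum(w) <= 0) stop("weights must sum to > 0")
  w
}
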