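#' Extract gray-matter voxel time courses
#'
#' Pulls the time series of every gray-matter voxel into a time x node
#' matrix. Columns follow a linear scan of the grid with x fastest
#' (column-major order of the mask array), and the node map records the
#' bijection between node index, 1-based grid index and mm coordinate
#' (through the session affine, which maps 0-based indices).
#'
#' @param session a [bold_session].
#' @param masks tissue masks on the session grid.
#' @return an object of class `voxel_matrix`: list with `values`
#'   (time x node matrix), `node_map` (data frame `node, i, j, k, x_mm,
#'   y_mm, z_mm` carrying the grid dimensions and affine as attributes)
#'   and `tr_seconds`.
#' @export
extract_gray_timeseries <- function(session, masks) {
  stopifnot(inherits(session, "bold_session"))
  dim4 <- dim(session$data)
  if (!all(dim(masks$gray) == dim4[1:3]))
    stop("gray mask grid ", paste(dim(masks$gray), collapse = "x"),
         " does not match session grid ", paste(dim4[1:3], collapse = "x"))
  keep <- which(masks$gray)
  if (length(keep) == 0L) stop("gray-matter mask is empty")
  flat <- matrix(session$data, nrow = prod(dim4[1:3]), ncol = dim4[4])
  values <- t(flat[keep, , drop = FALSE])
  ijk <- arrayInd(keep, dim4[1:3])
  mm <- t(session$affine %*% rbind(t(ijk - 1L), 1))[, 1:3, drop = FALSE]
  node_map <- data.frame(node = seq_along(keep),
                         i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                         x_mm = mm[, 1], y_mm = mm[, 2], z_mm = mm[, 3])
  attr(node_map, "grid_dim") <- dim4[1:3]
  attr(node_map, "affine") <- session$affine
  attr(node_map, "voxel_size_mm") <- session$voxel_size_mm
  structure(list(values = values, node_map = node_map,
                 tr_seconds = session$tr_seconds, filter = NULL),
            class = "voxel_matrix")
}

#' Construct a voxel matrix from a plain time x node matrix
#'
#' Wraps an arbitrary time x node matrix as a `voxel_matrix` so the
#' temporal filters and network construction can run on data that did
#' not come from a 4D volume (simulated series, extracted tables). The
#' node map defaults to a bare node index without grid coordinates, so
#' volume export is unavailable unless a grid-aware map is supplied.
#'
#' @param values time x node numeric matrix.
#' @param tr_seconds sampling interval in seconds.
#' @param node_map optional node map data frame.
#' @return a `voxel_matrix`.
#' @export
voxel_matrix <- function(values, tr_seconds, node_map = NULL) {
  values <- as.matrix(values)
  if (is.null(node_map))
    node_map <- data.frame(node = seq_len(ncol(values)))
  structure(list(values = values, node_map = node_map,
                 tr_seconds = tr_seconds, filter = NULL),
            class = "voxel_matrix")
}

#' @export
print.voxel_matrix <- function(x, ...) {
  cat(sprintf("<voxel_matrix> %d time points x %d nodes, TR %gs%s\n",
              nrow(x$values), ncol(x$values), x$tr_seconds,
              if (is.null(x$filter)) "" else
                sprintf(", band-passed %g-%g Hz", x$filter["low_hz"],
                        x$filter["high_hz"])))
  invisible(x)
}

# Zero-phase DFT band-pass: zero every Fourier bin whose frequency lies
# outside [low, high]. Applied to a time x series matrix at once.
.dft_bandpass <- function(x, tr, low_hz, high_hz) {
  n <- nrow(x)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) / (n * tr)
  keep <- freq >= low_hz & freq <= high_hz
  X <- stats::mvfft(x)
  X[!keep, ] <- 0
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

#' Temporal band-pass filter
#'
#' Applies a zero-phase discrete-Fourier-transform mask retaining only
#' frequencies inside `[low_hz, high_hz]` (defaults 0.009-0.08 Hz, the
#' conventional resting-state band). The DC component is always removed
#' when `low_hz > 0`, so filtered series are mean-zero; pass-band
#' periodic components keep unit gain exactly. The filter choice is
#' recorded in the returned object's `filter` field.
#'
#' @param matrix a `voxel_matrix`.
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 <= low_hz < high_hz < 1/(2 * tr)`.
#' @return the filtered `voxel_matrix`.
#' @export
bandpass <- function(matrix, low_hz = 0.009, high_hz = 0.08) {
  stopifnot(inherits(matrix, "voxel_matrix"))
  nyq <- 1 / (2 * matrix$tr_seconds)
  if (low_hz < 0 || low_hz >= high_hz || high_hz >= nyq)
    stop("band [", low_hz, ", ", high_hz,
         "] Hz must satisfy 0 <= low < high < Nyquist (", nyq, " Hz)")
  matrix$values <- .dft_bandpass(matrix$values, matrix$tr_seconds,
                                 low_hz, high_hz)
  matrix$filter <- list(type = "dft_mask", low_hz = low_hz, high_hz = high_hz)
  matrix
}

#' Regress nuisance signals from voxel time courses
#'
#' Replaces every column by its least-squares residual against the
#' design `[intercept, 6 motion parameters, global, white-matter, CSF
#' signal]`. When the matrix has been band-pass filtered and
#' `filter_regressors = TRUE` (the default), the nuisance regressors are
#' passed through the identical filter first so the projection acts
#' within the analysis band. Rank-deficient designs trigger a warning
#' and the dependent columns are effectively dropped by the pivoted QR
#' solve; zero-variance data columns pass through as zero columns (after
#' intercept removal) with a warning.
#'
#' @param matrix a `voxel_matrix`.
#' @param nuisance a nuisance set (`motion` matrix plus `global_signal`,
#'   `white_signal`, `csf_signal` series).
#' @param filter_regressors filter the regressors with the matrix's own
#'   band-pass before projecting?
#' @return the residual `voxel_matrix`.
#' @export
regress_nuisance <- function(matrix, nuisance, filter_regressors = TRUE) {
  stopifnot(inherits(matrix, "voxel_matrix"))
  n <- nrow(matrix$values)
  reg <- cbind(nuisance$motion, nuisance$global_signal,
               nuisance$white_signal, nuisance$csf_signal)
  if (nrow(reg) != n)
    stop("nuisance series length ", nrow(reg),
         " does not match time dimension ", n)
  if (filter_regressors && !is.null(matrix$filter))
    reg <- .dft_bandpass(reg, matrix$tr_seconds,
                         matrix$filter$low_hz, matrix$filter$high_hz)
  X <- cbind(1, reg)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    warning("nuisance design is rank deficient (rank ", qx$rank, " of ",
            ncol(X), "); dependent regressors dropped")
  zerovar <- apply(matrix$values, 2, function(v) all(v == v[1]))
  if (any(zerovar))
    warning(sum(zerovar), " zero-variance voxel time course(s) pass through as zero")
  matrix$values <- qr.resid(qx, matrix$values)
  matrix$nuisance_regressed <- TRUE
  matrix
}

#' Standard temporal preprocessing of one session
#'
#' Gray-matter extraction, band-pass filtering, then nuisance
#' regression, in that order (regressors are taken from the filtered
#' series).
#'
#' @inheritParams extract_gray_timeseries
#' @inheritParams regress_nuisance
#' @param low_hz,high_hz band edges in Hz.
#' @return the preprocessed `voxel_matrix`.
#' @export
preprocess_session <- function(session, masks, nuisance,
                               low_hz = 0.009, high_hz = 0.08,
                               filter_regressors = TRUE) {
  vm <- extract_gray_timeseries(session, masks)
  vm <- bandpass(vm, low_hz, high_hz)
  regress_nuisance(vm, nuisance, filter_regressors = filter_regressors)
}

#' Persist a voxel matrix as text
#'
#' Writes the node map as TSV (`node, i, j, k, x_mm, y_mm, z_mm`) and
#' the values as a plain TSV matrix (one row per time point).
#'
#' @param matrix a `voxel_matrix`.
#' @param stem output path stem; writes `<stem>_values.tsv` and
#'   `<stem>_nodes.tsv`.
#' @return named character vector of written paths.
#' @export
write_voxel_matrix <- function(matrix, stem) {
  paths <- c(values = paste0(stem, "_values.tsv"),
             nodes = paste0(stem, "_nodes.tsv"))
  write.table(matrix$values, paths[["values"]], sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(matrix$node_map, paths[["nodes"]], sep = "\t",
              row.names = FALSE, quote = FALSE)
  paths
}
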