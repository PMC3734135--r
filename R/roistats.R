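#' Spherical region-of-interest specification
#'
#' @param name ROI label.
#' @param centers_mm numeric matrix (or length-3 vector) of sphere
#'   centers in mm; multiple centers (e.g. bilateral spheres) are
#'   analysed as their union.
#' @param radius_mm sphere radius in mm (default 10).
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(name, centers_mm, radius_mm = 10) {
  centers_mm <- .as_center_matrix(centers_mm, "centers_mm")
  if (radius_mm < 0) stop("'radius_mm' must be >= 0")
  structure(list(name = name, centers_mm = centers_mm,
                 radius_mm = radius_mm), class = "roi_spec")
}

#' Spherical ROI mask on a voxel grid
#'
#' A voxel is included iff its center's mm coordinate (through the
#' affine, 0-based indices) lies within `radius_mm` of any listed
#' center (Euclidean distance); the mask is the union over centers.
#'
#' @param spec an [roi_spec()].
#' @param grid_dim integer vector of 3 grid dimensions.
#' @param affine 4x4 grid-to-mm transform.
#' @return logical 3D array; a warning is issued if the mask is empty
#'   (sphere entirely off-grid or between voxel centers).
#' @export
sphere_mask <- function(spec, grid_dim, affine) {
  stopifnot(inherits(spec, "roi_spec"))
  mm <- .grid_mm(grid_dim, affine)
  inside <- .sphere_voxels(spec$centers_mm, spec$radius_mm, mm)
  if (!any(inside))
    warning("ROI '", spec$name, "': no voxel center within ", spec$radius_mm,
            " mm of any sphere center; mask is empty")
  array(inside, dim = grid_dim)
}

#' ROI mean of a nodal metric
#'
#' Arithmetic mean of the metric over the gray-matter nodes that fall
#' inside the mask.
#'
#' @param metric a `metric_volume` with a grid-aware node map.
#' @param mask logical 3D array on the same grid.
#' @return list with `value` (the mean) and `n_voxels` (number of
#'   contributing voxels); errors if the mask intersects no node.
#' @export
roi_mean <- function(metric, mask) {
  nm <- metric$node_map
  inside <- mask[cbind(nm$i, nm$j, nm$k)]
  if (!any(inside))
    stop("ROI mask contains no gray-matter node")
  list(value = mean(metric$values[inside]), n_voxels = sum(inside))
}

#' Two-condition by S-session fully within-subjects ANOVA
#'
#' Repeated-measures ANOVA for a balanced subject x condition x session
#' table with every factor within-subject. The sums of squares are
#' decomposed into subject, condition, session, condition x session and
#' their subject-interaction error terms; each effect is tested against
#' its own subject-interaction error term (so with n subjects and 2
#' conditions the condition effect has df (1, n - 1)). Effect size is
#' partial eta squared, `SS_effect / (SS_effect + SS_error)`.
#'
#' Degenerate tables are flagged: a zero error SS with a positive
#' effect SS yields `F = Inf` and the boundary p-value 0 with a
#' warning; a zero effect and error SS yields `F = NaN` with a warning.
#'
#' @param table data frame with columns `subject`, `condition` (2
#'   levels), `session`, `value`; every subject must have every
#'   condition x session cell exactly once.
#' @param value_col name of the value column.
#' @return data frame of class `anova_rm` with one row per effect
#'   (`condition`, `session`, `condition:session`) and columns
#'   `effect`, `df_num`, `df_den`, `SS`, `SS_error`, `F`, `p`,
#'   `partial_eta_sq`.
#' @export
rm_anova_2xS <- function(table, value_col = "value") {
  need <- c("subject", "condition", "session", value_col)
  if (!all(need %in% names(table)))
    stop("table needs columns: ", paste(need, collapse = ", "))
  subj <- factor(table$subject)
  cond <- factor(table$condition)
  sess <- factor(table$session)
  y <- table[[value_col]]
  n <- nlevels(subj); C <- nlevels(cond); S <- nlevels(sess)
  if (C != 2L) stop("'condition' must have exactly 2 levels (got ", C, ")")
  if (n < 2L) stop("need at least 2 subjects")
  counts <- table(subj, cond, sess)
  if (any(counts != 1L)) {
    bad <- which(counts != 1L, arr.ind = TRUE)[1, ]
    stop("design is not a complete balanced crossing: subject ",
         dimnames(counts)[[1]][bad[1]], ", condition ",
         dimnames(counts)[[2]][bad[2]], ", session ",
         dimnames(counts)[[3]][bad[3]], " has ",
         counts[bad[1], bad[2], bad[3]], " observations")
  }
  gm <- mean(y)
  m_s <- tapply(y, subj, mean) - gm
  m_c <- tapply(y, cond, mean) - gm
  m_j <- tapply(y, sess, mean) - gm
  m_sc <- tapply(y, list(subj, cond), mean) - gm - outer(m_s, m_c, `+`)
  m_sj <- tapply(y, list(subj, sess), mean) - gm - outer(m_s, m_j, `+`)
  m_cj <- tapply(y, list(cond, sess), mean) - gm - outer(m_c, m_j, `+`)
  ss <- list(
    subject = C * S * sum(m_s^2),
    condition = n * S * sum(m_c^2),
    session = n * C * sum(m_j^2),
    cond_subj = S * sum(m_sc^2),
    sess_subj = C * sum(m_sj^2),
    cond_sess = n * sum(m_cj^2))
  ss_total <- sum((y - gm)^2)
  ss$cs_subj <- ss_total - sum(unlist(ss))
  eff <- data.frame(
    effect = c("condition", "session", "condition:session"),
    df_num = c(C - 1, S - 1, (C - 1) * (S - 1)),
    df_den = c((C - 1) * (n - 1), (S - 1) * (n - 1), (C - 1) * (S - 1) * (n - 1)),
    SS = c(ss$condition, ss$session, ss$cond_sess),
    SS_error = c(ss$cond_subj, ss$sess_subj, ss$cs_subj),
    stringsAsFactors = FALSE)
  eff$F <- (eff$SS / eff$df_num) / (eff$SS_error / eff$df_den)
  eff$p <- stats::pf(eff$F, eff$df_num, eff$df_den, lower.tail = FALSE)
  eff$partial_eta_sq <- ifelse(eff$SS + eff$SS_error > 0,
                               eff$SS / (eff$SS + eff$SS_error), NaN)
  degen_inf <- eff$SS_error <= 0 & eff$SS > 0
  degen_nan <- eff$SS_error <= 0 & eff$SS <= 0
  if (any(degen_inf)) {
    warning("zero error SS for effect(s) ",
            paste(eff$effect[degen_inf], collapse = ", "),
            "; F is infinite and p is reported at the boundary 0")
    eff$F[degen_inf] <- Inf
    eff$p[degen_inf] <- 0
  }
  if (any(degen_nan)) {
    warning("degenerate table (zero effect and error SS) for effect(s) ",
            paste(eff$effect[degen_nan], collapse = ", "),
            "; F is undefined")
    eff$F[degen_nan] <- NaN
    eff$p[degen_nan] <- NaN
  }
  attr(eff, "ss_total") <- ss_total
  attr(eff, "ss_components") <- unlist(ss)
  class(eff) <- c("anova_rm", "data.frame")
  eff
}
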