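#' Planted connectivity hub specification
#'
#' Describes one latent connectivity structure of the synthetic brain: a
#' set of spherical regions whose gray-matter voxels share a common
#' latent time course, with a condition-dependent shared-variance level,
#' plus an optional distal coupled region driven by the same latent at
#' its own (usually weaker) level.
#'
#' The shared-variance level `cor_*` is the target pairwise Pearson
#' correlation between two voxels of the hub before temporal filtering:
#' each hub voxel receives the latent with loading
#' `sqrt(cor / (1 - cor))` on top of unit-variance noise, so two hub
#' voxels share a fraction `cor` of their variance. The coupling level of
#' the distal region is interpreted the same way (its voxels load on the
#' hub latent with `sqrt(coupling / (1 - coupling))`), which makes
#' hub-to-distal correlations approximately `sqrt(cor * coupling)`.
#'
#' @param centers_mm numeric matrix (or vector of length 3), one sphere
#'   center per row, in mm (world coordinates of the study grid).
#' @param radius_mm sphere radius in mm.
#' @param cor_rest,cor_task target within-hub pairwise correlation in
#'   `[0, 1)` for the rest and task conditions.
#' @param coupled_centers_mm optional centers of a distal region coupled
#'   to this hub's latent (matrix or length-3 vector), or `NULL`.
#' @param coupled_radius_mm radius of the coupled region in mm.
#' @param coupling_rest,coupling_task shared-variance level of the
#'   coupled region per condition, in `[0, 1)`.
#' @return an object of class `hub_spec`.
#' @export
hub_spec <- function(centers_mm, radius_mm = 10,
                     cor_rest = 0.1, cor_task = 0.1,
                     coupled_centers_mm = NULL, coupled_radius_mm = radius_mm,
                     coupling_rest = 0, coupling_task = 0) {
  centers_mm <- .as_center_matrix(centers_mm, "centers_mm")
  if (!is.null(coupled_centers_mm))
    coupled_centers_mm <- .as_center_matrix(coupled_centers_mm, "coupled_centers_mm")
  for (nm in c("cor_rest", "cor_task", "coupling_rest", "coupling_task")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v >= 1)
      stop("hub_spec field '", nm, "' must be a single value in [0, 1)")
  }
  if (radius_mm < 0) stop("hub_spec field 'radius_mm' must be >= 0")
  structure(list(centers_mm = centers_mm, radius_mm = radius_mm,
                 cor_rest = cor_rest, cor_task = cor_task,
                 coupled_centers_mm = coupled_centers_mm,
                 coupled_radius_mm = coupled_radius_mm,
                 coupling_rest = coupling_rest, coupling_task = coupling_task),
            class = "hub_spec")
}

.as_center_matrix <- function(x, field) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != 3L || !is.numeric(x))
    stop("'", field, "' must be a numeric matrix with 3 columns (x, y, z in mm)")
  x
}

#' Configuration of a synthetic multi-session BOLD study
#'
#' Defines the study design (subjects, alternating rest/task sessions,
#' volumes, TR), the synthetic head geometry (grid, voxel size,
#' concentric gray/white/CSF shells), the planted connectivity hubs, and
#' the noise model (AR(1) voxel noise, sub-0.009 Hz scanner drift,
#' shared physiological confound, motion-coupled signal).
#'
#' Defaults emulate the design of a five-subject alternating
#' rest / 2-back study: 5 sessions per condition, 120 volumes at
#' TR = 2 s, a 14 x 14 x 10 grid of 4 x 4 x 5 mm voxels (about 1300
#' gray-matter voxels), a posterior-medial rest-dominant hub and a
#' bilateral frontal-lateral task-dominant hub coupled to a distal
#' parietal region during task.
#'
#' @param n_subjects number of subjects.
#' @param n_sessions_per_condition sessions per condition per subject.
#' @param n_volumes time points per session (>= 2).
#' @param tr_seconds repetition time in seconds.
#' @param grid_shape integer vector of 3 grid dimensions.
#' @param voxel_size_mm numeric vector of 3 voxel edge lengths in mm.
#' @param rest_hub_spec,task_hub_spec [hub_spec()] objects for the
#'   rest-dominant and task-dominant planted hubs.
#' @param rest_module_spec a [hub_spec()] describing a set of small
#'   coherent modules, one *independent* latent per listed center
#'   (emulating the many distinct networks coherent during rest, which
#'   raise whole-brain local efficiency at rest); `NULL` disables them.
#' @param ar1_coefficient lag-1 autocorrelation of voxel noise, in `[0, 1)`.
#' @param drift_amplitude standard deviation of the low-frequency scanner
#'   drift component, in units of the unit-variance voxel noise.
#' @param confound_weights named numeric vector with elements `global`
#'   (loading of every brain voxel on a shared physiological confound),
#'   `tissue` (loading on a tissue-specific confound, one independent
#'   series per tissue class, as cardiac/respiratory noise expresses
#'   differently in gray matter, white matter and CSF) and `motion`
#'   (scale of per-voxel loadings on the 6 motion series).
#' @param first_condition condition of the first session, `"rest"` or
#'   `"task"`; subsequent sessions alternate.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 5L,
                              n_sessions_per_condition = 5L,
                              n_volumes = 120L,
                              tr_seconds = 2,
                              grid_shape = c(14L, 14L, 10L),
                              voxel_size_mm = c(4, 4, 5),
                              rest_hub_spec = default_rest_hub(),
                              task_hub_spec = default_task_hub(),
                              rest_module_spec = default_rest_modules(),
                              ar1_coefficient = 0.3,
                              drift_amplitude = 2,
                              confound_weights = c(global = 0.5, tissue = 0.3,
                                                   motion = 0.15),
                              first_condition = c("rest", "task"),
                              seed = 1L) {
  first_condition <- match.arg(first_condition)
  chk_count <- function(x, nm, min) {
    if (!is.numeric(x) || length(x) != 1L || x < min || x != round(x))
      stop("simulation_config field '", nm, "' must be an integer >= ", min)
    as.integer(x)
  }
  n_subjects <- chk_count(n_subjects, "n_subjects", 1L)
  n_sessions_per_condition <- chk_count(n_sessions_per_condition,
                                        "n_sessions_per_condition", 1L)
  n_volumes <- chk_count(n_volumes, "n_volumes", 2L)
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("simulation_config field 'tr_seconds' must be > 0")
  if (length(grid_shape) != 3L || any(grid_shape < 1) ||
      any(grid_shape != round(grid_shape)))
    stop("simulation_config field 'grid_shape' must be 3 integers >= 1")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("simulation_config field 'voxel_size_mm' must be 3 positive lengths")
  if (!is.numeric(ar1_coefficient) || ar1_coefficient < 0 || ar1_coefficient >= 1)
    stop("simulation_config field 'ar1_coefficient' must be in [0, 1)")
  if (drift_amplitude < 0)
    stop("simulation_config field 'drift_amplitude' must be >= 0")
  if (!all(c("global", "tissue", "motion") %in% names(confound_weights)))
    stop("simulation_config field 'confound_weights' needs elements ",
         "'global', 'tissue' and 'motion'")
  stopifnot(inherits(rest_hub_spec, "hub_spec"), inherits(task_hub_spec, "hub_spec"))
  if (!is.null(rest_module_spec)) stopifnot(inherits(rest_module_spec, "hub_spec"))
  structure(list(n_subjects = n_subjects,
                 n_sessions_per_condition = n_sessions_per_condition,
                 n_volumes = n_volumes, tr_seconds = tr_seconds,
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 rest_hub_spec = rest_hub_spec, task_hub_spec = task_hub_spec,
                 rest_module_spec = rest_module_spec,
                 ar1_coefficient = ar1_coefficient,
                 drift_amplitude = drift_amplitude,
                 confound_weights = confound_weights,
                 first_condition = first_condition,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_rest_hub <- function() {
  hub_spec(centers_mm = rbind(c(0, -18, 8), c(-10, -18, 10), c(10, -18, 10)),
           radius_mm = 8, cor_rest = 0.70, cor_task = 0.10)
}

#' @rdname simulation_config
#' @export
default_task_hub <- function() {
  hub_spec(centers_mm = rbind(c(-16, 14, 10), c(16, 14, 10)),
           radius_mm = 7, cor_rest = 0.10, cor_task = 0.60,
           coupled_centers_mm = c(18, -10, 0), coupled_radius_mm = 7,
           coupling_rest = 0.05, coupling_task = 0.35)
}

#' @rdname simulation_config
#' @export
default_rest_modules <- function() {
  hub_spec(centers_mm = rbind(c(-14, -18, -17.5), c(18, -14, -17.5),
                              c(-6, -6, -17.5), c(6, 18, -17.5),
                              c(-22, 6, -2.5), c(22, 6, -2.5),
                              c(-6, -2, 12.5), c(2, 10, 17.5)),
           radius_mm = 6, cor_rest = 0.60, cor_task = 0.05)
}

# World-coordinate affine of the synthetic grid: voxel sizes on the
# diagonal, origin chosen so the grid center is at mm (0, 0, 0).
.grid_affine <- function(grid_shape, voxel_size_mm) {
  off <- -voxel_size_mm * (grid_shape - 1) / 2
  rbind(cbind(diag(voxel_size_mm), off), c(0, 0, 0, 1))
}

# mm coordinates of every voxel center, grid scanned x-fastest
# (column-major), 0-based indices through the affine.
.grid_mm <- function(grid_shape, affine) {
  idx <- as.matrix(expand.grid(i = 0:(grid_shape[1] - 1L),
                               j = 0:(grid_shape[2] - 1L),
                               k = 0:(grid_shape[3] - 1L)))
  t(affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

# Concentric superellipsoidal tissue shells. The "head" is a 4-norm
# ellipsoid slightly larger than the grid; white matter is the core,
# gray matter the thick middle shell, CSF a thin outer shell. The layout
# is arbitrary but fixed; on the default grid it yields 1280 gray,
# 144 white and 344 CSF voxels.
.tissue_shells <- function(grid_shape, voxel_size_mm, affine) {
  mm <- .grid_mm(grid_shape, affine)
  semi <- voxel_size_mm * (grid_shape - 1) / 2 + voxel_size_mm / 2
  rho <- rowSums(sweep(abs(mm), 2, semi, `/`)^4)^(1 / 4)
  dim3 <- grid_shape
  as_arr <- function(v) array(v, dim = dim3)
  list(gray = as_arr(rho > 0.45 & rho <= 0.95),
       white = as_arr(rho <= 0.45),
       csf = as_arr(rho > 0.95 & rho <= 1.04))
}

.sphere_voxels <- function(centers_mm, radius_mm, mm) {
  inside <- rep(FALSE, nrow(mm))
  for (r in seq_len(nrow(centers_mm))) {
    d2 <- rowSums(sweep(mm, 2, centers_mm[r, ], `-`)^2)
    inside <- inside | d2 <= radius_mm^2
  }
  inside
}

# Band-limited unit-variance latent series: a sum of sinusoids with
# random frequencies inside the analysis pass-band so the planted
# correlation structure survives band-pass filtering.
.latent_series <- function(n, tr, n_components = 8L,
                           band = c(0.012, 0.07)) {
  tt <- seq_len(n) * tr
  f <- runif(n_components, band[1], band[2])
  ph <- runif(n_components, 0, 2 * pi)
  x <- rowSums(sapply(seq_len(n_components),
                      function(m) cos(2 * pi * f[m] * tt + ph[m])))
  as.numeric(scale(x))
}

# Scanner drift built directly from DFT bins strictly below `max_hz`
# (DC excluded), so its power lies below the pass-band by construction.
.drift_series <- function(n, tr, max_hz = 0.009) {
  freq <- (1:(n - 1)) / (n * tr)
  bins <- which(freq < max_hz & freq > 0)
  if (length(bins) == 0L) bins <- 1L
  tt <- 0:(n - 1)
  x <- rep(0, n)
  for (k in bins)
    x <- x + rnorm(1) * cos(2 * pi * k * tt / n + runif(1, 0, 2 * pi))
  s <- sd(x)
  if (s > 0) x <- x / s
  x
}

.ar1_noise <- function(n, n_series, phi) {
  innov <- matrix(rnorm(n * n_series, sd = sqrt(1 - phi^2)), n, n_series)
  if (phi == 0) return(innov)
  out <- stats::filter(innov, filter = phi, method = "recursive")
  matrix(as.numeric(out), n, n_series)
}

#' Generate a complete synthetic multi-session BOLD study
#'
#' Simulates every session of the configured study: for each subject,
#' `2 * n_sessions_per_condition` sessions alternating between rest and
#' task (starting with `first_condition`). Each gray/white/CSF voxel
#' carries baseline + low-frequency drift + a shared physiological
#' confound + motion-coupled signal + AR(1) noise; voxels of the planted
#' hubs additionally load on a condition-dependent band-limited latent
#' series, which makes rest-hub voxels mutually correlated more strongly
#' at rest than at task and task-hub (plus coupled distal) voxels more
#' strongly correlated at task.
#'
#' @param config a [simulation_config()].
#' @return an object of class `voxnet_study`: a list with elements
#'   `sessions` (list of per-session lists with `bold`
#'   ([bold_session]), `masks` (tissue masks) and `nuisance`
#'   (motion + mean tissue signals)), `masks` (the shared tissue masks),
#'   `hubs` (ground-truth logical volumes `rest_hub`, `task_hub`,
#'   `task_coupled`), `affine` and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  dim3 <- config$grid_shape
  n <- config$n_volumes
  affine <- .grid_affine(dim3, config$voxel_size_mm)
  masks <- .tissue_shells(dim3, config$voxel_size_mm, affine)
  if (!any(masks$gray)) stop("synthetic gray-matter mask is empty; enlarge grid_shape")
  mm <- .grid_mm(dim3, affine)
  gray_v <- as.vector(masks$gray)
  brain_v <- gray_v | as.vector(masks$white) | as.vector(masks$csf)
  n_vox <- prod(dim3)

  hub_mask <- function(spec) {
    main <- .sphere_voxels(spec$centers_mm, spec$radius_mm, mm) & gray_v
    coupled <- if (!is.null(spec$coupled_centers_mm))
      .sphere_voxels(spec$coupled_centers_mm, spec$coupled_radius_mm, mm) & gray_v
    else rep(FALSE, n_vox)
    list(main = main, coupled = coupled)
  }
  rest_h <- hub_mask(config$rest_hub_spec)
  task_h <- hub_mask(config$task_hub_spec)
  mod_spec <- config$rest_module_spec
  mod_masks <- if (is.null(mod_spec)) list() else
    lapply(seq_len(nrow(mod_spec$centers_mm)), function(r)
      .sphere_voxels(mod_spec$centers_mm[r, , drop = FALSE],
                     mod_spec$radius_mm, mm) & gray_v)

  n_sess <- 2L * config$n_sessions_per_condition
  conds <- rep(c(config$first_condition,
                 setdiff(c("rest", "task"), config$first_condition)),
               length.out = n_sess)
  loading <- function(level) if (level <= 0) 0 else sqrt(level / (1 - level))

  sessions <- vector("list", config$n_subjects * n_sess)
  s_idx <- 0L
  for (subj in seq_len(config$n_subjects)) {
    # per-voxel confound loadings are a stable subject trait
    w_global <- rnorm(n_vox, mean = config$confound_weights[["global"]], sd = 0.1)
    w_tissue <- rnorm(n_vox, mean = config$confound_weights[["tissue"]], sd = 0.05)
    w_motion <- matrix(rnorm(6L * n_vox, sd = config$confound_weights[["motion"]] / sqrt(6)),
                       nrow = 6L)
    sess_count <- c(rest = 0L, task = 0L)
    for (ss in seq_len(n_sess)) {
      cond <- conds[ss]
      sess_count[cond] <- sess_count[cond] + 1L
      motion <- apply(matrix(rnorm(n * 6L, sd = rep(c(0.05, 0.002), each = 3L * n)), n, 6L),
                      2, cumsum)
      g_conf <- as.numeric(scale(.ar1_noise(n, 1L, config$ar1_coefficient)))
      tis_conf <- apply(.ar1_noise(n, 3L, config$ar1_coefficient), 2,
                        function(v) as.numeric(scale(v)))
      drift <- .drift_series(n, config$tr_seconds)
      lat_rest <- .latent_series(n, config$tr_seconds)
      lat_task <- .latent_series(n, config$tr_seconds)

      y <- .ar1_noise(n, n_vox, config$ar1_coefficient)      # time x voxel
      y <- y + drift %o% (runif(n_vox, 0.5, 1.5) * config$drift_amplitude)
      y[, brain_v] <- y[, brain_v] + g_conf %o% w_global[brain_v]
      tis_list <- list(gray_v, as.vector(masks$white), as.vector(masks$csf))
      for (ti in 1:3) {
        tv <- tis_list[[ti]]
        y[, tv] <- y[, tv] + tis_conf[, ti] %o% w_tissue[tv]
      }
      y[, brain_v] <- y[, brain_v] + motion %*% w_motion[, brain_v]

      lam_r <- loading(if (cond == "rest") config$rest_hub_spec$cor_rest
                       else config$rest_hub_spec$cor_task)
      mu_r <- loading(if (cond == "rest") config$rest_hub_spec$coupling_rest
                      else config$rest_hub_spec$coupling_task)
      lam_t <- loading(if (cond == "task") config$task_hub_spec$cor_task
                       else config$task_hub_spec$cor_rest)
      mu_t <- loading(if (cond == "task") config$task_hub_spec$coupling_task
                      else config$task_hub_spec$coupling_rest)
      if (any(rest_h$main)) y[, rest_h$main] <- y[, rest_h$main] + lam_r * lat_rest
      if (any(rest_h$coupled)) y[, rest_h$coupled] <- y[, rest_h$coupled] + mu_r * lat_rest
      if (any(task_h$main)) y[, task_h$main] <- y[, task_h$main] + lam_t * lat_task
      if (any(task_h$coupled)) y[, task_h$coupled] <- y[, task_h$coupled] + mu_t * lat_task
      if (length(mod_masks) > 0) {
        lam_m <- loading(if (cond == "rest") mod_spec$cor_rest
                         else mod_spec$cor_task)
        for (mk in mod_masks) {
          lat_m <- .latent_series(n, config$tr_seconds)
          if (any(mk)) y[, mk] <- y[, mk] + lam_m * lat_m
        }
      }

      y[, brain_v] <- y[, brain_v] + 100
      data <- array(as.numeric(t(y)), dim = c(dim3, n))

      nuisance <- list(
        motion = motion,
        global_signal = rowMeans(y[, brain_v, drop = FALSE]),
        white_signal = rowMeans(y[, as.vector(masks$white), drop = FALSE]),
        csf_signal = rowMeans(y[, as.vector(masks$csf), drop = FALSE]))
      class(nuisance) <- "nuisance_set"

      bold <- bold_session(data, voxel_size_mm = config$voxel_size_mm,
                           tr_seconds = config$tr_seconds, affine = affine,
                           subject_id = sprintf("sub-%02d", subj),
                           condition = cond,
                           session_index = sess_count[[cond]])
      s_idx <- s_idx + 1L
      sessions[[s_idx]] <- list(bold = bold, masks = masks, nuisance = nuisance)
    }
  }

  as_arr <- function(v) array(v, dim = dim3)
  structure(list(sessions = sessions, masks = masks,
                 hubs = list(rest_hub = as_arr(rest_h$main),
                             rest_coupled = as_arr(rest_h$coupled),
                             task_hub = as_arr(task_h$main),
                             task_coupled = as_arr(task_h$coupled),
                             rest_modules = as_arr(Reduce(`|`, c(mod_masks,
                               list(rep(FALSE, n_vox)))))),
                 affine = affine, config = config),
            class = "voxnet_study")
}

#' One session of 4D BOLD data
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param voxel_size_mm,tr_seconds grid spacing (mm) and sampling
#'   interval (s).
#' @param affine 4x4 grid-index-to-mm transform (0-based indices).
#' @param subject_id,condition,session_index session labels; `condition`
#'   is `"rest"` or `"task"`.
#' @return an object of class `bold_session`.
#' @export
bold_session <- function(data, voxel_size_mm, tr_seconds, affine,
                         subject_id, condition = c("rest", "task"),
                         session_index = 1L) {
  condition <- match.arg(condition)
  if (length(dim(data)) != 4L) stop("'data' must be a 4D array (x, y, z, t)")
  if (!all(dim(affine) == c(4L, 4L))) stop("'affine' must be a 4x4 matrix")
  steps <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (max(abs(steps - voxel_size_mm)) > 1e-6)
    stop("'affine' grid steps disagree with 'voxel_size_mm'")
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 tr_seconds = tr_seconds, affine = affine,
                 subject_id = subject_id, condition = condition,
                 session_index = as.integer(session_index)),
            class = "bold_session")
}

#' @export
print.bold_session <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_session> %s %s ses-%d: %dx%dx%d grid, %d volumes, TR %gs\n",
              x$subject_id, x$condition, x$session_index,
              d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' @export
print.voxnet_study <- function(x, ...) {
  cat(sprintf("<voxnet_study> %d subjects x %d sessions (%d gray voxels, %d volumes)\n",
              x$config$n_subjects, 2L * x$config$n_sessions_per_condition,
              sum(x$masks$gray), x$config$n_volumes))
  invisible(x)
}
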