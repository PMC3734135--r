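#' Configuration of an end-to-end study run
#'
#' @param mode `"synthetic"` (generate the study from `sim_config`) or
#'   `"files"` (load sessions listed in `manifest`).
#' @param sim_config a [simulation_config()] (synthetic mode).
#' @param manifest manifest path or list as written by [write_study()]
#'   (file mode).
#' @param low_hz,high_hz band-pass edges in Hz.
#' @param S_list density exponents to analyse; the first is the primary
#'   one used for consistency maps and ANOVAs.
#' @param top_fraction_map fraction defining "top nodes" for the
#'   whole-brain consistency maps (default 0.20).
#' @param top_fraction_roi fraction defining the top regional nodes
#'   whose connections are mapped (default 0.15).
#' @param session_min_fraction within-subject session-consistency
#'   threshold (default 0.6, i.e. at least 3 of 5 sessions).
#' @param subject_threshold cross-subject threshold for group
#'   connectivity maps (default 0.5).
#' @param roi_specs list of [roi_spec()]s; in synthetic mode `NULL`
#'   defaults to 10 mm spheres at the planted hub centers (`rest_hub`,
#'   `task_hub`).
#' @param filter_regressors band-pass the nuisance regressors with the
#'   data filter (default `TRUE`).
#' @param output_dir optional directory for on-disk outputs; `NULL`
#'   keeps everything in memory.
#' @param seed seed for synthetic mode (overrides the sim_config seed
#'   when given).
#' @return an object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       sim_config = simulation_config(),
                       manifest = NULL,
                       low_hz = 0.009, high_hz = 0.08,
                       S_list = 3.0,
                       top_fraction_map = 0.20,
                       top_fraction_roi = 0.15,
                       session_min_fraction = 0.6,
                       subject_threshold = 0.5,
                       roi_specs = NULL,
                       filter_regressors = TRUE,
                       output_dir = NULL,
                       seed = NULL) {
  mode <- match.arg(mode)
  for (nm in c("top_fraction_map", "top_fraction_roi",
               "session_min_fraction", "subject_threshold")) {
    v <- get(nm)
    if (v <= 0 || v > 1) stop("'", nm, "' must be in (0, 1]")
  }
  if (any(S_list <= 1)) stop("all 'S_list' values must be > 1")
  if (mode == "files" && is.null(manifest))
    stop("file mode requires a 'manifest'")
  if (!is.null(seed)) sim_config$seed <- as.integer(seed)
  structure(list(mode = mode, sim_config = sim_config, manifest = manifest,
                 low_hz = low_hz, high_hz = high_hz, S_list = S_list,
                 top_fraction_map = top_fraction_map,
                 top_fraction_roi = top_fraction_roi,
                 session_min_fraction = session_min_fraction,
                 subject_threshold = subject_threshold,
                 roi_specs = roi_specs,
                 filter_regressors = filter_regressors,
                 output_dir = output_dir),
            class = "run_config")
}

.load_sessions <- function(config) {
  if (config$mode == "synthetic") {
    study <- generate_study(config$sim_config)
    rois <- config$roi_specs
    if (is.null(rois)) {
      sc <- config$sim_config
      rois <- list(
        rest_hub = roi_spec("rest_hub", sc$rest_hub_spec$centers_mm, 10),
        task_hub = roi_spec("task_hub", sc$task_hub_spec$centers_mm, 10))
    }
    list(sessions = study$sessions, rois = rois, study = study)
  } else {
    man <- .read_manifest(config$manifest)
    sessions <- lapply(seq_len(nrow(man$sessions)), function(r) {
      row <- man$sessions[r, ]
      read_session(row$bold, unlist(man$masks), row$motion,
                   subject_id = row$subject, condition = row$condition,
                   session_index = row$session)
    })
    if (is.null(config$roi_specs))
      stop("file mode requires explicit 'roi_specs'")
    list(sessions = sessions, rois = config$roi_specs, study = NULL)
  }
}

#' Run the full analysis pipeline
#'
#' Executes data generation (or ingest), preprocessing, network
#' construction at each S, metric computation (K, Eglob, Eloc),
#' whole-brain and ROI summary tables, 2 x S repeated-measures ANOVAs,
#' per-subject session-consistency maps and cross-subject meta maps of
#' top-ranked nodes, and group maps of nodes connected to top regional
#' nodes. All stages are deterministic given the configuration and
#' seed.
#'
#' @param config a [run_config()].
#' @return an object of class `voxnet_results`: list with elements
#'   `summary` (whole-brain per-session metric means), `roi_table`
#'   (per-session ROI means), `anova` (whole-brain and per-ROI ANOVA
#'   tables), `consistency` (per condition x metric: per-subject
#'   session overlaps, thresholded sets, subject meta map),
#'   `roi_connectivity` (per condition x metric x ROI group maps),
#'   `network_info` (per-session N, r_threshold, realized K per S),
#'   `node_map`, `config`, and `study` (synthetic mode only; carries
#'   the ground-truth hub masks). When `output_dir` is set, tables,
#'   volumes and a provenance manifest are also written to disk.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  loaded <- .load_sessions(config)
  sessions <- loaded$sessions
  rois <- loaded$rois
  primary_S <- config$S_list[1]

  node_map <- NULL
  summary_rows <- list(); roi_rows <- list(); info_rows <- list()
  nodal <- list()   # nodal[[cond]][[subject]][[session]] -> list of metric values
  roi_masks <- NULL

  for (s in sessions) {
    id <- sprintf("%s|%s|%d", s$bold$subject_id, s$bold$condition,
                  s$bold$session_index)
    vm <- tryCatch(
      preprocess_session(s$bold, s$masks, s$nuisance,
                         low_hz = config$low_hz, high_hz = config$high_hz,
                         filter_regressors = config$filter_regressors),
      error = function(e) stop("stage preprocess failed for session ", id,
                               ": ", conditionMessage(e)))
    if (is.null(node_map)) {
      node_map <- vm$node_map
      roi_masks <- lapply(rois, sphere_mask,
                          grid_dim = attr(node_map, "grid_dim"),
                          affine = attr(node_map, "affine"))
    }
    for (S in config$S_list) {
      net <- tryCatch(build_network(vm, S),
                      error = function(e) stop("stage netbuild failed for session ",
                                               id, ": ", conditionMessage(e)))
      mets <- list(K = degree(net), Eglob = global_efficiency(net),
                   Eloc = local_efficiency(net))
      info_rows[[length(info_rows) + 1L]] <- data.frame(
        subject = s$bold$subject_id, condition = s$bold$condition,
        session = s$bold$session_index, S = S, n_nodes = net$n_nodes,
        n_edges = net$n_edges, mean_degree = net$mean_degree,
        r_threshold = net$r_threshold, stringsAsFactors = FALSE)
      for (mn in names(mets)) {
        mv <- mets[[mn]]
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          subject = s$bold$subject_id, condition = s$bold$condition,
          session = s$bold$session_index, S = S, scope = "wholebrain",
          metric = mn, value = unname(mv$summary["mean"]),
          sd = unname(mv$summary["sd"]), stringsAsFactors = FALSE)
        for (rn in names(roi_masks)) {
          rm_ <- roi_mean(mv, roi_masks[[rn]])
          roi_rows[[length(roi_rows) + 1L]] <- data.frame(
            subject = s$bold$subject_id, condition = s$bold$condition,
            session = s$bold$session_index, S = S, scope = rn,
            metric = mn, value = rm_$value, n_voxels = rm_$n_voxels,
            stringsAsFactors = FALSE)
        }
      }
      if (S == primary_S) {
        key <- s$bold$condition
        subj <- s$bold$subject_id
        if (is.null(nodal[[key]])) nodal[[key]] <- list()
        if (is.null(nodal[[key]][[subj]])) nodal[[key]][[subj]] <- list()
        nodal[[key]][[subj]][[s$bold$session_index]] <-
          list(K = mets$K$values, Eloc = mets$Eloc$values, net = net)
      }
    }
  }
  summary_tab <- do.call(rbind, summary_rows)
  roi_tab <- do.call(rbind, roi_rows)
  info_tab <- do.call(rbind, info_rows)

  # ANOVAs at the primary S: whole brain and each ROI, each metric
  # (requires at least 2 subjects; single-subject runs skip this stage)
  anova_tabs <- list()
  run_anova <- length(unique(summary_tab$subject)) >= 2L
  if (!run_anova)
    message("fewer than 2 subjects: repeated-measures ANOVAs skipped")
  for (scope in if (run_anova) unique(c("wholebrain", names(roi_masks)))
       else character(0)) {
    src <- if (scope == "wholebrain") summary_tab else roi_tab
    src <- src[src$S == primary_S & src$scope == scope, ]
    for (mn in unique(src$metric)) {
      tab <- src[src$metric == mn, ]
      anova_tabs[[paste(scope, mn, sep = ".")]] <-
        rm_anova_2xS(tab[, c("subject", "condition", "session", "value")])
    }
  }

  # Consistency maps of top whole-brain nodes (session then subject level)
  consistency <- list()
  for (cond in names(nodal)) {
    for (mn in c("K", "Eloc")) {
      per_subj <- lapply(nodal[[cond]], function(sess_list) {
        masks <- lapply(sess_list, function(x)
          top_fraction_mask(x[[mn]], config$top_fraction_map))
        ov <- session_overlap(masks, source_metric = mn,
                              top_fraction = config$top_fraction_map,
                              node_map = node_map)
        list(overlap = ov,
             thresholded = threshold_consistency(ov, config$session_min_fraction))
      })
      meta <- subject_meta_map(lapply(per_subj, `[[`, "thresholded"),
                               source_metric = mn,
                               top_fraction = config$top_fraction_map,
                               node_map = node_map)
      consistency[[paste(cond, mn, sep = ".")]] <-
        list(per_subject = per_subj, meta = meta,
             meta_thresholded = threshold_consistency(
               meta, config$session_min_fraction))
    }
  }

  # Nodes connected to the top regional nodes, session-overlapped per
  # subject then thresholded across subjects
  node_in_roi <- lapply(roi_masks, function(m)
    m[cbind(node_map$i, node_map$j, node_map$k)])
  roi_conn <- list()
  for (cond in names(nodal)) {
    for (mn in c("K", "Eloc")) {
      for (rn in names(roi_masks)) {
        subj_sets <- lapply(nodal[[cond]], function(sess_list) {
          conn <- lapply(sess_list, function(x) {
            vals <- x[[mn]]
            in_roi <- which(node_in_roi[[rn]])
            top_local <- top_fraction_mask(vals[in_roi],
                                           config$top_fraction_roi)
            top <- logical(length(vals))
            top[in_roi[top_local]] <- TRUE
            connected_to_top_nodes(x$net, top)
          })
          ov <- session_overlap(conn)
          threshold_consistency(ov, config$session_min_fraction)
        })
        roi_conn[[paste(cond, mn, rn, sep = ".")]] <-
          group_connectivity_map(subj_sets, config$subject_threshold)
      }
    }
  }

  res <- structure(list(summary = summary_tab, roi_table = roi_tab,
                        network_info = info_tab, anova = anova_tabs,
                        consistency = consistency,
                        roi_connectivity = roi_conn,
                        roi_masks = roi_masks, node_map = node_map,
                        config = config, study = loaded$study),
                   class = "voxnet_results")
  if (!is.null(config$output_dir)) .write_results(res, config$output_dir)
  res
}

#' @export
print.voxnet_results <- function(x, ...) {
  cat(sprintf("<voxnet_results> %d sessions, %d nodes, S = {%s}\n",
              nrow(unique(x$network_info[, 1:3])),
              x$network_info$n_nodes[1],
              paste(unique(x$network_info$S), collapse = ", ")))
  invisible(x)
}

.write_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    df_out <- df
    num <- vapply(df_out, is.numeric, TRUE)
    df_out[num] <- lapply(df_out[num], function(v) formatC(v, digits = 12,
                                                           format = "g"))
    write.table(df_out, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  files <- c(wt(res$summary, "summary_wholebrain.tsv"),
             wt(res$roi_table, "summary_roi.tsv"),
             wt(res$network_info, "network_info.tsv"))
  an <- do.call(rbind, lapply(names(res$anova), function(nm)
    cbind(analysis = nm, as.data.frame(res$anova[[nm]]))))
  files <- c(files, wt(an, "anova.tsv"))
  for (nm in names(res$consistency)) {
    p <- file.path(dir, sprintf("consistency_meta_%s.nii.gz", gsub("\\.", "_", nm)))
    write_consistency_volume(res$consistency[[nm]]$meta, p)
    files <- c(files, p)
  }
  for (nm in names(res$roi_connectivity)) {
    p <- file.path(dir, sprintf("connectivity_%s.nii.gz", gsub("\\.", "_", nm)))
    write_consistency_volume(res$roi_connectivity[[nm]], p,
                             node_map = res$node_map)
    files <- c(files, p)
  }
  cfg <- res$config
  prov <- list(package = "voxnet",
               version = as.character(utils::packageVersion("voxnet")),
               mode = cfg$mode,
               seed = if (cfg$mode == "synthetic") cfg$sim_config$seed else NULL,
               S_list = cfg$S_list, band = c(cfg$low_hz, cfg$high_hz),
               thresholds = list(top_fraction_map = cfg$top_fraction_map,
                                 top_fraction_roi = cfg$top_fraction_roi,
                                 session_min_fraction = cfg$session_min_fraction,
                                 subject_threshold = cfg$subject_threshold),
               network_info = res$network_info,
               files = unname(files))
  jsonlite::write_json(prov, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(files)
}

#' Validate a file-mode input manifest
#'
#' Checks that every listed file exists, that grids and affines agree
#' across sessions and masks, that volume counts match the manifest's
#' `n_volumes`, that motion files have 6 columns and one row per
#' volume, and that the tissue masks are pairwise disjoint.
#'
#' @param manifest manifest path or list (see [write_study()]).
#' @return data frame of violations (zero rows when the manifest is
#'   consistent) with columns `file` and `problem`.
#' @export
validate_inputs <- function(manifest) {
  man <- .read_manifest(manifest)
  bad <- list()
  note <- function(file, problem)
    bad[[length(bad) + 1L]] <<- data.frame(file = file, problem = problem,
                                           stringsAsFactors = FALSE)
  mask_arr <- list(); mask_dim <- NULL; ref_aff <- NULL
  for (m in names(man$masks)) {
    p <- man$masks[[m]]
    if (!file.exists(p)) { note(p, "missing mask file"); next }
    img <- readNifti(p)
    mask_arr[[m]] <- as.numeric(img) > 0.5
    if (is.null(mask_dim)) {
      mask_dim <- dim(img); ref_aff <- unclass(RNifti::xform(img))
    } else if (!all(dim(img) == mask_dim)) note(p, "mask grid mismatch")
  }
  if (length(mask_arr) == 3L) {
    overlap <- (mask_arr[[1]] & mask_arr[[2]]) |
      (mask_arr[[1]] & mask_arr[[3]]) | (mask_arr[[2]] & mask_arr[[3]])
    if (any(overlap)) note(man$masks[[1]], "tissue masks are not pairwise disjoint")
  }
  for (r in seq_len(nrow(man$sessions))) {
    row <- man$sessions[r, ]
    if (!file.exists(row$bold)) { note(row$bold, "missing BOLD file"); next }
    img <- readNifti(row$bold)
    d <- dim(img)
    if (length(d) != 4L) { note(row$bold, "not a 4D volume"); next }
    if (!is.null(man$n_volumes) && d[4] != man$n_volumes)
      note(row$bold, sprintf("has %d volumes, expected %d", d[4], man$n_volumes))
    if (!is.null(mask_dim) && !all(d[1:3] == mask_dim[1:3]))
      note(row$bold, "session grid does not match mask grid")
    aff <- unclass(RNifti::xform(img))
    if (!is.null(ref_aff) && max(abs(aff - ref_aff)) > 1e-4)
      note(row$bold, "affine mismatch with masks")
    if (!file.exists(row$motion)) { note(row$motion, "missing motion file"); next }
    mo <- tryCatch(as.matrix(read.table(row$motion)), error = function(e) NULL)
    if (is.null(mo) || ncol(mo) != 6L)
      note(row$motion, "motion file must have 6 columns")
    else if (nrow(mo) != d[4])
      note(row$motion, sprintf("motion rows (%d) != volumes (%d)", nrow(mo), d[4]))
  }
  if (length(bad) == 0L)
    data.frame(file = character(0), problem = character(0))
  else do.call(rbind, bad)
}
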