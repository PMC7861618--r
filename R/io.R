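# File formats: tracking-output pose tables (three header rows:
# scorer / bodyparts / coords with x,y,likelihood triplets, one file per
# view per trial), correspondence tables, camera-pair JSON, manifest YAML,
# and tidy CSV writers. Frames are 0-based in files; pixels have the image
# origin at the top-left; all 3D outputs are in mm.

#' Write a one-view pose table
#'
#' Writes the tracking-output CSV dialect: three header rows (scorer,
#' bodyparts, coords) over x,y,likelihood triplets per body part, frame
#' index (0-based) in the first column.
#'
#' @param view_df Data frame with columns frame, bodypart, u, v, confidence.
#' @param path Output file.
#' @param scorer Scorer tag placed in the first header row.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(view_df, path, scorer = "synthetic") {
  parts <- unique(view_df$bodypart)
  frames <- sort(unique(view_df$frame))
  header1 <- c("scorer", rep(scorer, 3 * length(parts)))
  header2 <- c("bodyparts", rep(parts, each = 3))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), length(parts)))
  M <- matrix(NA_real_, length(frames), 3 * length(parts))
  for (j in seq_along(parts)) {
    rows <- view_df[view_df$bodypart == parts[j], ]
    i <- match(rows$frame, frames)
    M[i, 3 * j - 2] <- rows$u
    M[i, 3 * j - 1] <- rows$v
    M[i, 3 * j] <- rows$confidence
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header1, collapse = ","),
               paste(header2, collapse = ","),
               paste(header3, collapse = ",")), con)
  utils::write.table(cbind(frames, format(M, digits = 17, trim = TRUE,
                                          scientific = FALSE)),
                     con, sep = ",", col.names = FALSE, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a one-view pose table
#'
#' Parses the three-header-row tracking CSV dialect written by
#' [write_pose_table()] (and produced by markerless-tracking exports).
#' Unknown body parts are rejected; confidences are clipped to \[0, 1\].
#'
#' @param path CSV file.
#' @param allowed_parts Body parts accepted (default [bodypart_names()]).
#' @return Data frame with columns frame, bodypart, u, v, confidence.
#' @export
read_pose_table <- function(path, allowed_parts = bodypart_names()) {
  lines <- readLines(path)
  if (length(lines) < 4) stop("pose table too short: ", path)
  h1 <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  h2 <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  h3 <- strsplit(lines[3], ",", fixed = TRUE)[[1]]
  if (tolower(h1[1]) != "scorer") {
    stop("malformed pose table header (row 1 must start with 'scorer'): ", path)
  }
  if (tolower(h2[1]) != "bodyparts") {
    stop("malformed pose table header (row 2 must start with 'bodyparts'): ", path)
  }
  if (tolower(h3[1]) != "coords" ||
      !all(h3[-1] %in% c("x", "y", "likelihood"))) {
    stop("malformed pose table header (row 3 must be the coords row of ",
         "x,y,likelihood triplets): ", path)
  }
  parts <- unique(h2[-1])
  bad <- setdiff(parts, allowed_parts)
  if (length(bad)) {
    stop("unknown body part(s) in ", path, ": ", paste(bad, collapse = ", "))
  }
  body <- utils::read.csv(text = lines[-(1:3)], header = FALSE,
                          colClasses = "character")
  num <- suppressWarnings(
    matrix(as.numeric(as.matrix(body)), nrow(body), ncol(body)))
  bad_cell <- which(is.na(num) & as.matrix(body) != "NA" &
                      as.matrix(body) != "", arr.ind = TRUE)
  if (nrow(bad_cell)) {
    stop(sprintf("non-numeric cell in %s at data row %d, column %d: '%s'",
                 path, bad_cell[1, 1], bad_cell[1, 2],
                 as.matrix(body)[bad_cell[1, , drop = FALSE]]))
  }
  frames <- as.integer(num[, 1])
  out <- vector("list", length(parts))
  for (j in seq_along(parts)) {
    conf <- pmin(pmax(num[, 3 * j + 1], 0), 1)
    out[[j]] <- data.frame(frame = frames, bodypart = parts[j],
                           u = num[, 3 * j - 1], v = num[, 3 * j],
                           confidence = conf)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble a two-view pose series from per-view tables
#'
#' @param direct,mirror Data frames as returned by [read_pose_table()].
#' @return A `pose2d_series`.
#' @export
pose2d_series <- function(direct, mirror) {
  structure(list(direct = direct, mirror = mirror,
                 mislabel_log = list(),
                 n_frames = length(unique(direct$frame))),
            class = "pose2d_series")
}

#' Write / read a calibrated camera pair as JSON
#'
#' @param pair A `camera_pair`.
#' @param path JSON file.
#' @return `path` (write) or the restored `camera_pair` (read).
#' @export
write_camera_pair <- function(pair, path) {
  obj <- list(K = pair$K, K_mirror = pair$K_mirror, R = pair$R, t = pair$t,
              s = pair$s, mirror_flip = pair$mirror_flip,
              cheirality_fraction = pair$cheirality_fraction,
              median_residual_px = pair$median_residual_px %||% NA,
              n_pairs = pair$n_pairs)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_camera_pair
#' @export
read_camera_pair <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- matrix(unlist(obj$K), 3, 3)
  Km <- matrix(unlist(obj$K_mirror), 3, 3)
  R <- matrix(unlist(obj$R), 3, 3)
  structure(list(K = K, K_mirror = Km, R = R, t = as.numeric(obj$t),
                 s = obj$s, P_direct = K %*% cbind(diag(3), 0),
                 P_mirror = Km %*% cbind(R, as.numeric(obj$t)),
                 mirror_flip = obj$mirror_flip,
                 cheirality_fraction = obj$cheirality_fraction,
                 median_residual_px = obj$median_residual_px,
                 n_pairs = obj$n_pairs),
            class = "camera_pair")
}

#' Write / read a correspondence table
#'
#' Columnar text table (pair_id, u_direct, v_direct, u_mirror, v_mirror).
#'
#' @param corr A `correspondence_set`.
#' @param path CSV file.
#' @return `path` (write) or a `correspondence_set` (read; without ground
#'   truth or adjacency).
#' @export
write_correspondences <- function(corr, path) {
  utils::write.csv(format(corr$points, digits = 17, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_correspondences
#' @export
read_correspondences <- function(path) {
  df <- utils::read.csv(path)
  correspondence_set(df)
}

#' Write / read a session manifest as YAML
#'
#' @param manifest Named list (rat, group, paw_side, sessions, file paths,
#'   intrinsics, seeds, ...).
#' @param path YAML file.
#' @return `path` (write) or the manifest list (read).
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  yaml::read_yaml(path)
}

#' Default pipeline configuration
#'
#' Every tunable threshold in one place: tracking-confidence and
#' reprojection-error cutoffs, gap-bridging limits, slot plane, reach
#' jitter rejection, pellet-reference window, and the moving-block window.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(conf_min = 0.9,
       reproj_threshold_px = 3,
       max_gap = 5,
       tol_px = 3,
       slot_z = -15,
       min_advance_mm = 2,
       min_duration_frames = 3,
       retract_eps_mm = 0.5,
       end_smooth = 3,
       trigger_frame = 300,
       pellet_window = 100,
       min_pellet_frames = 10,
       block_window = 10,
       square_size_mm = 4,
       sample_z_mm = 1,
       sample_z_short_mm = -7)
}

#' Write a generated experiment to a directory tree
#'
#' Writes per-trial pose tables (both views), a calibration correspondence
#' table, the camera intrinsics + manifest as YAML, and the ground truth as
#' a columnar table, for a `synth_experiment` generated with
#' `detail = "pose"`.
#'
#' @param exp A `synth_experiment` (detail "pose").
#' @param dir Output directory (created).
#' @param rig The `camera_rig` used for projection.
#' @return The manifest path, invisibly.
#' @export
write_experiment <- function(exp, dir, rig) {
  stopifnot(inherits(exp, "synth_experiment"))
  if (is.null(exp$sessions) || exp$detail != "pose") {
    stop("write_experiment needs an experiment generated with detail = 'pose'")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  corr <- generate_calibration_set(rig, square_size_mm = 4)
  write_correspondences(corr, file.path(dir, "calibration_corners.csv"))
  sessions <- list()
  for (ses in exp$sessions) {
    mf <- ses$manifest
    tag <- sprintf("%s_s%02d", mf$rat, mf$session)
    files <- list()
    for (tr in seq_along(ses$poses)) {
      fd <- file.path(dir, sprintf("%s_t%03d_direct.csv", tag, tr))
      fm <- file.path(dir, sprintf("%s_t%03d_mirror.csv", tag, tr))
      write_pose_table(ses$poses[[tr]]$direct, fd)
      write_pose_table(ses$poses[[tr]]$mirror, fm)
      files[[tr]] <- list(trial = tr, direct = basename(fd),
                          mirror = basename(fm))
    }
    gt <- do.call(rbind, lapply(seq_along(ses$ground_truth), function(tr) {
      g <- ses$ground_truth[[tr]]
      do.call(rbind, lapply(names(g$parts), function(bp) {
        data.frame(trial = tr, frame = 0:(nrow(g$parts[[bp]]) - 1),
                   bodypart = bp, x_mm = g$parts[[bp]][, 1],
                   y_mm = g$parts[[bp]][, 2], z_mm = g$parts[[bp]][, 3])
      }))
    }))
    utils::write.csv(gt, file.path(dir, sprintf("%s_groundtruth.csv", tag)),
                     row.names = FALSE)
    utils::write.csv(ses$trials, file.path(dir, sprintf("%s_trials.csv", tag)),
                     row.names = FALSE)
    sessions[[length(sessions) + 1]] <-
      c(mf, list(files = files,
                 outcomes = as.integer(ses$trials$outcome),
                 trials_table = sprintf("%s_trials.csv", tag)))
  }
  manifest <- list(
    intrinsics = list(focal_px = rig$K[1, 1],
                      principal_point = c(rig$K[1, 3], rig$K[2, 3]),
                      image_size = rig$image_size),
    square_size_mm = 4,
    calibration = "calibration_corners.csv",
    seed = exp$seed,
    sessions = sessions)
  path <- file.path(dir, "manifest.yaml")
  write_manifest(manifest, path)
  invisible(path)
}
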