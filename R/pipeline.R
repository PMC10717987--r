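# Two-arm comparison pipeline: per subject, calibrate with the redundant
# protocol, derive the Plugin arm by pure reduction (identical offsets and
# data minus 22 columns), solve both arms on identical trials, segment gait
# cycles, normalize, extract kinematic variables and MAV, then run the
# between-model (paired) and between-group (independent) statistics and the
# point-wise curve comparison.

.right_angles <- function() {
  paste0(c("hip_flexion", "hip_adduction", "hip_rotation", "knee_flexion",
           "knee_adduction", "knee_rotation", "ankle_dorsiflexion",
           "subtalar_inversion"), "_R")
}

.load_mts <- function(x) {
  if (inherits(x, "mts")) return(x)
  if (is.character(x) && length(x) == 1) return(read_trc(x))
  stop("trial must be a marker trajectory set or a TRC path")
}

# Events for one trial from the marker data (right heel vs pelvis centroid),
# unless annotated events are supplied.
.trial_events <- function(mk, annotated = NULL) {
  if (!is.null(annotated))
    return(detect_heel_strikes(NULL, NULL, NULL, events = annotated))
  pelv <- intersect(c("LASI", "RASI", "LPSI", "RPSI"), marker_names(mk))
  heel <- mk$positions[, "RHEE", 1]
  px <- rowMeans(mk$positions[, pelv, 1, drop = FALSE])
  detect_heel_strikes(heel, px, mk$times)
}

# Per-trial processing for one arm: IK, cycle segmentation, normalization.
# Returns the trial curve (mean over the trial's complete cycles) per angle.
.trial_curves <- function(cal, mk, events, angles, cfg) {
  solved <- solve_trajectory(cal, mk, cfg)
  cycles <- complete_cycles(solved, events)
  if (!length(cycles)) return(NULL)
  norm <- lapply(cycles, function(cy) time_normalize(solved, cy, angles))
  out <- norm[[1]]
  if (length(norm) > 1)
    for (a in angles)
      out[[a]] <- rowMeans(vapply(norm, function(m) m[[a]], numeric(101)))
  attr(out, "n_cycles") <- length(cycles)
  out
}

.safe_p <- function(expr) tryCatch(expr$p_value, error = function(e) NA_real_)

#' Run the two-arm marker-set comparison pipeline
#'
#' Per subject: calibrate with the redundant protocol from the standing
#' trial; derive the Plugin-arm model by [reduce_to_plugin()] (bit-identical
#' offsets for shared markers); solve IK on each walking trial with both
#' arms (the Plugin arm consumes the identical data minus the 22 extra
#' columns); segment gait cycles at right heel strikes; time-normalize to
#' 101 points; average cycles within each trial and trials within each
#' subject; extract kinematic variables and the per-angle MAV across
#' trials.  Then: paired t-tests between models within each group
#' (variables and MAV), independent t-tests between groups within each
#' model, and point-wise paired comparison of the subject curves.
#'
#' @param config List with elements:
#'   \describe{
#'     \item{subjects}{List of subject entries: `list(id, group, standing,
#'       trials, events = NULL)`; `standing`/`trials` are trajectory sets or
#'       TRC paths; `events` an optional list of annotated heel-strike time
#'       vectors per trial.}
#'     \item{alpha}{Significance level; default 0.05.}
#'     \item{min_cycles}{Minimum usable cycles per subject and arm;
#'       default 3.}
#'     \item{angles}{Angle columns analyzed; default the 8 right-leg joint
#'       angles.}
#'     \item{ik}{An [ik_config()]; default `ik_config()`.}
#'     \item{nominal}{Nominal model for calibration; default
#'       [build_model()].}
#'   }
#' @param out_dir Optional directory; when given, the result tables are
#'   written there as CSV files.
#' @return List of class `gait_comparison`: `variables` (long per-subject
#'   table), `mav` (long per-subject table), `model_comparison`,
#'   `group_comparison`, `mav_comparison` (test tables), `pointwise`
#'   (per group and angle significant-point counts), `curves` (per model /
#'   group subject-mean curves).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  alpha <- config$alpha %||% 0.05
  min_cycles <- config$min_cycles %||% 3
  angles <- config$angles %||% .right_angles()
  ikcfg <- config$ik %||% ik_config()
  nominal <- config$nominal %||% build_model()
  subjects <- config$subjects
  if (is.null(subjects) || !length(subjects)) stop("config$subjects is empty")

  groups <- vapply(subjects, function(s) s$group, character(1))
  tab <- table(groups)
  if (length(tab) != 2)
    stop("pipeline requires exactly 2 groups, got: ",
         paste(names(tab), collapse = ", "))
  if (any(tab < 2))
    stop("group statistics require at least 2 subjects per group; group '",
         names(tab)[which.min(tab)], "' has ", min(tab))

  proto_R <- redundant_marker_set(nominal)
  arms <- c(R = "redundant", P = "plugin")
  var_rows <- list(); mav_rows <- list()
  curves <- list(R = list(), P = list())

  for (s in subjects) {
    standing <- .load_mts(s$standing)
    cal_R <- calibrate(standing, proto_R, nominal)
    cal_P <- reduce_to_plugin(cal_R)
    trial_curves <- list(R = list(), P = list())
    for (ti in seq_along(s$trials)) {
      mk_R <- .load_mts(s$trials[[ti]])
      mk_P <- reduce_to_plugin(mk_R)
      ev <- .trial_events(mk_R, if (is.null(s$events)) NULL else s$events[[ti]])
      for (arm in names(arms)) {
        cal <- if (arm == "R") cal_R else cal_P
        mk <- if (arm == "R") mk_R else mk_P
        cur <- .trial_curves(cal, mk, ev, angles, ikcfg)
        if (!is.null(cur)) trial_curves[[arm]][[length(trial_curves[[arm]]) + 1]] <- cur
      }
    }
    for (arm in names(arms)) {
      tcs <- trial_curves[[arm]]
      if (length(tcs) < 1 ||
          sum(vapply(tcs, function(x) attr(x, "n_cycles"), numeric(1))) < min_cycles)
        stop("subject ", s$id, " (", arms[arm], " arm): fewer than ",
             min_cycles, " usable gait cycles")
      subj_curve <- tcs[[1]][, angles, drop = FALSE]
      if (length(tcs) > 1)
        for (a in angles)
          subj_curve[[a]] <- rowMeans(vapply(tcs, function(m) m[[a]],
                                             numeric(101)))
      curves[[arm]][[s$id]] <- subj_curve
      # variables: per trial, then averaged across trials
      vt <- lapply(tcs, function(m) extract_variables(m[, angles, drop = FALSE]))
      vmean <- vt[[1]]
      if (length(vt) > 1)
        for (col in c("initial_angle", "peak_max", "peak_min", "rom"))
          vmean[[col]] <- rowMeans(vapply(vt, function(v) v[[col]],
                                          numeric(nrow(vmean))))
      var_rows[[length(var_rows) + 1]] <- cbind(
        subject = s$id, group = s$group, model = arms[[arm]], vmean)
      for (a in angles)
        mav_rows[[length(mav_rows) + 1]] <- data.frame(
          subject = s$id, group = s$group, model = arms[[arm]], angle = a,
          mav = mav(t(vapply(tcs, function(m) m[[a]], numeric(101)))),
          stringsAsFactors = FALSE)
    }
  }

  variables <- do.call(rbind, var_rows); rownames(variables) <- NULL
  mav_tab <- do.call(rbind, mav_rows); rownames(mav_tab) <- NULL
  ids <- vapply(subjects, function(s) s$id, character(1))
  grp_of <- stats::setNames(groups, ids)
  gnames <- names(tab)
  vcols <- c("initial_angle", "peak_max", "peak_min", "rom")

  pick <- function(df, model, group = NULL) {
    i <- df$model == model
    if (!is.null(group)) i <- i & df$group == group
    df[i, , drop = FALSE]
  }
  # between models, within group (paired over subjects)
  mc <- list()
  for (g in gnames) for (a in angles) for (v in vcols) {
    dR <- pick(variables, "redundant", g); dP <- pick(variables, "plugin", g)
    dR <- dR[dR$angle == a, ]; dP <- dP[dP$angle == a, ]
    dP <- dP[match(dR$subject, dP$subject), ]
    mc[[length(mc) + 1]] <- data.frame(
      group = g, angle = a, variable = v,
      mean_R = mean(dR[[v]]), sd_R = stats::sd(dR[[v]]),
      mean_P = mean(dP[[v]]), sd_P = stats::sd(dP[[v]]),
      p_value = .safe_p(paired_t(dR[[v]], dP[[v]])), stringsAsFactors = FALSE)
  }
  model_comparison <- do.call(rbind, mc)
  # between groups, within model (independent)
  gc <- list()
  for (m in unname(arms)) for (a in angles) for (v in vcols) {
    d1 <- pick(variables, m, gnames[1]); d2 <- pick(variables, m, gnames[2])
    d1 <- d1[d1$angle == a, ]; d2 <- d2[d2$angle == a, ]
    gc[[length(gc) + 1]] <- data.frame(
      model = m, angle = a, variable = v,
      mean_1 = mean(d1[[v]]), sd_1 = stats::sd(d1[[v]]),
      mean_2 = mean(d2[[v]]), sd_2 = stats::sd(d2[[v]]),
      p_value = .safe_p(independent_t(d1[[v]], d2[[v]])),
      stringsAsFactors = FALSE)
  }
  group_comparison <- do.call(rbind, gc)
  names(group_comparison)[4:7] <- paste0(
    c("mean_", "sd_", "mean_", "sd_"), rep(gnames, each = 2))
  # MAV between models, within group
  mv <- list()
  for (g in gnames) for (a in angles) {
    dR <- mav_tab[mav_tab$model == "redundant" & mav_tab$group == g &
                    mav_tab$angle == a, ]
    dP <- mav_tab[mav_tab$model == "plugin" & mav_tab$group == g &
                    mav_tab$angle == a, ]
    dP <- dP[match(dR$subject, dP$subject), ]
    mv[[length(mv) + 1]] <- data.frame(
      group = g, angle = a,
      mav_R = mean(dR$mav), sd_R = stats::sd(dR$mav),
      mav_P = mean(dP$mav), sd_P = stats::sd(dP$mav),
      p_value = .safe_p(paired_t(dR$mav, dP$mav)), stringsAsFactors = FALSE)
  }
  mav_comparison <- do.call(rbind, mv)
  # point-wise curve comparison between models, within group
  pw <- list()
  for (g in gnames) for (a in angles) {
    sub_ids <- ids[grp_of[ids] == g]
    m1 <- t(vapply(sub_ids, function(id) curves$R[[id]][[a]], numeric(101)))
    m2 <- t(vapply(sub_ids, function(id) curves$P[[id]][[a]], numeric(101)))
    pc <- pointwise_compare(m1, m2, alpha = alpha)
    pw[[length(pw) + 1]] <- data.frame(
      group = g, angle = a, n_significant_points = pc$n_significant_points,
      stringsAsFactors = FALSE)
  }
  pointwise <- do.call(rbind, pw)

  res <- structure(list(variables = variables, mav = mav_tab,
                        model_comparison = model_comparison,
                        group_comparison = group_comparison,
                        mav_comparison = mav_comparison,
                        pointwise = pointwise, curves = curves,
                        alpha = alpha),
                   class = "gait_comparison")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("variables", "mav", "model_comparison", "group_comparison",
                 "mav_comparison", "pointwise"))
      utils::write.csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  res
}

#' @export
print.gait_comparison <- function(x, ...) {
  cat("gait_comparison:", length(unique(x$variables$subject)), "subjects,",
      length(unique(x$variables$angle)), "angles\n")
  cat("significant model-comparison variables (p <", x$alpha, "):",
      sum(x$model_comparison$p_value < x$alpha, na.rm = TRUE), "/",
      nrow(x$model_comparison), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
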