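# End-to-end paradigm runs ----------------------------------------------------

.titration_template <- function(paradigm) {
  switch(paradigm,
         amplitude = pulse_train("RECT", 1, 65, 100, 130),
         frequency = pulse_train("RECT", 1, 65, 100, 15),
         waveform = pulse_train("RECT", 1, 100, 100, 130))
}

.protocol_for <- function(paradigm, I0_ua) {
  switch(paradigm,
         amplitude = build_amplitude_protocol(I0_ua),
         frequency = build_frequency_protocol(I0_ua),
         waveform = build_waveform_protocol(
           charge_per_phase("RECT", I0_ua, 100)))
}

.AMP_MULT <- c(1, 1.25, 1.5, 1.75, 2)
.FREQS <- c(15, 50, 100, 130, 180, 250, 350)

# condition level used as x in the correlation analysis
.condition_levels <- function(paradigm, labels) {
  switch(paradigm,
         amplitude = as.numeric(sub("xI0$", "", labels)),
         frequency = as.numeric(sub("Hz$", "", labels)),
         waveform = as.numeric(sub("xQ0_.*$", "", labels)))
}

#' Run one full experimental paradigm on a synthetic cohort
#'
#' Composes the whole pipeline: draw the cohort, titrate each animal's
#' threshold (excluding dyskinesia-prone animals), build the per-animal
#' protocol, simulate the session, extract per-episode rotometry
#' features, aggregate per-level cohort means, correlate condition level
#' against each feature, and build the Euclidean-distance matrix of
#' cohort-mean rotation traces. For the waveform paradigm, paired t-tests
#' of Rect against each alternative shape at the 1.5x and 2x charge
#' levels are added and the similarity matrix is restricted to the 1x /
#' 1.5x / 2x charge blocks (the published comparison set).
#'
#' Everything derives deterministically from `config$seed`.
#'
#' @param paradigm `"amplitude"`, `"frequency"` or `"waveform"`.
#' @param config a [cohort_config()].
#' @param out_dir optional output directory; when given, trajectories,
#'   protocols, the feature table, the similarity matrix, the stats
#'   report and an md5 manifest are written there as plain text.
#' @param grid_step_ua titration grid step, uA (default 1 for reliable
#'   window detection; see [titrate_I0()]).
#' @param grid_n similarity-trace grid length.
#' @param units similarity units, `"rotations"` or `"degrees"`.
#' @param position simulate locomotion tracks (default TRUE; required for
#'   the distance feature).
#' @return List of class `paradigm_run`: `paradigm`, `animals`,
#'   `included` (ids), `excluded` (ids), `I0_ua` (named), `protocols`,
#'   `trajectories`, `features` (one row per animal x episode),
#'   `level_means` (per feature), `correlations` (data frame),
#'   `comparisons` (waveform paradigm only), `ed` (similarity matrix),
#'   `files` (manifest, when written).
#' @export
run_paradigm <- function(paradigm = c("amplitude", "frequency", "waveform"),
                         config = cohort_config(), out_dir = NULL,
                         grid_step_ua = 1, grid_n = 30,
                         units = c("rotations", "degrees"),
                         position = TRUE) {
  paradigm <- match.arg(paradigm)
  units <- match.arg(units)
  template <- .titration_template(paradigm)

  animals <- lapply(seq_len(config$n_animals),
                    function(i) sample_animal(config, i))
  names(animals) <- vapply(animals, `[[`, character(1), "id")
  titr <- lapply(animals, titrate_I0, config = config,
                 train_template = template, grid_step_ua = grid_step_ua)
  excl <- vapply(titr, is_excluded, logical(1))
  if (all(excl)) {
    stop("pipeline aborted at titration: every animal was excluded",
         call. = FALSE)
  }
  included <- animals[!excl]
  I0 <- vapply(titr[!excl], as.numeric, numeric(1))

  protocols <- lapply(I0, .protocol_for, paradigm = paradigm)
  trajs <- lapply(names(included), function(id) {
    simulate_session(included[[id]], protocols[[id]], config,
                     seed = config$seed, position = position)
  })
  names(trajs) <- names(included)

  feats <- do.call(rbind, lapply(names(included), function(id) {
    f <- session_features(trajs[[id]], protocols[[id]])
    cbind(animal = id, f)
  }))
  rownames(feats) <- NULL

  labels <- episode_windows(protocols[[1]])$label
  feature_cols <- c(max_rotation = "max_rotation", auc = "auc_rot_s",
                    distance = "distance_cm")
  if (!position) feature_cols <- feature_cols[1:2]
  lm_list <- lapply(feature_cols, level_means, feature_table = feats,
                    level_order = labels)

  correlations <- if (paradigm == "waveform") {
    do.call(rbind, lapply(PULSE_SHAPES, function(s) {
      sub_lab <- labels[grepl(paste0("_", shape_display(s), "$"), labels)]
      lm_s <- level_means(feats[feats$label %in% sub_lab, , drop = FALSE],
                          "max_rotation", level_order = sub_lab)
      r <- pearson(.condition_levels("waveform", lm_s$level), lm_s$mean)
      data.frame(test = shape_display(s), feature = "max_rotation",
                 rho = r$rho, n = r$n, t = r$t_stat, df = r$df,
                 p_two_tailed = r$p_two_tailed)
    }))
  } else {
    do.call(rbind, lapply(names(feature_cols), function(fc) {
      lm_f <- lm_list[[fc]]
      r <- pearson(.condition_levels(paradigm, lm_f$level), lm_f$mean)
      data.frame(test = paradigm, feature = fc, rho = r$rho, n = r$n,
                 t = r$t_stat, df = r$df, p_two_tailed = r$p_two_tailed)
    }))
  }

  comparisons <- NULL
  if (paradigm == "waveform") {
    grab <- function(lab, col) {
      v <- feats[feats$label == lab, c("animal", col)]
      stats::setNames(v[[col]], v$animal)
    }
    cmp_rows <- list()
    for (m in c(1.5, 2)) {
      for (s in c("SINE", "TRI", "LIN_DEC")) {
        for (col in intersect(c("auc_rot_s", "distance_cm"), names(feats))) {
          a <- grab(sprintf("%gxQ0_Rect", m), col)
          b <- grab(sprintf("%gxQ0_%s", m, shape_display(s)), col)
          if (anyNA(b) || anyNA(a)) next
          tt <- waveform_ttest(a, b[names(a)])
          cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
            contrast = sprintf("%gxQ0: Rect vs %s", m, shape_display(s)),
            feature = col, t = tt$t, df = tt$df,
            p_two_tailed = tt$p_two_tailed)
        }
      }
    }
    comparisons <- do.call(rbind, cmp_rows)
  }

  ed_labels <- if (paradigm == "waveform") {
    labels[grepl("^(1|1\\.5|2)xQ0_", labels)]
  } else {
    labels
  }
  traces <- lapply(ed_labels, function(L) {
    condition_trace(trajs, protocols[[1]], L, grid_n = grid_n,
                    units = units)
  })
  ed <- ed_matrix(traces)

  run <- structure(
    list(paradigm = paradigm, config = config, animals = animals,
         included = names(included),
         excluded = names(animals)[excl], I0_ua = I0,
         protocols = protocols, trajectories = trajs, features = feats,
         level_means = lm_list, correlations = correlations,
         comparisons = comparisons, ed = ed, files = NULL),
    class = "paradigm_run")

  if (!is.null(out_dir)) run$files <- .write_bundle(run, out_dir)
  run
}

#' @export
print.paradigm_run <- function(x, ...) {
  cat(sprintf(
    "<paradigm_run> '%s': %d/%d animals included, %d feature rows\n",
    x$paradigm, length(x$included), length(x$animals), nrow(x$features)))
  print(x$correlations)
  invisible(x)
}

.write_bundle <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add <- function(p) paths[[length(paths) + 1L]] <<- p
  for (id in run$included) {
    p <- file.path(out_dir, paste0("traj_", id, ".tsv"))
    write_trajectory(run$trajectories[[id]], p)
    add(p)
    if (file.exists(paste0(p, ".meta.json"))) add(paste0(p, ".meta.json"))
    pp <- file.path(out_dir, paste0("protocol_", id, ".json"))
    write_protocol(run$protocols[[id]], pp)
    add(pp)
  }
  fp <- file.path(out_dir, "features.tsv")
  utils::write.table(run$features, fp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  add(fp)
  ep <- file.path(out_dir, "ed_matrix.tsv")
  write_ed_matrix(run$ed, ep)
  add(ep)
  cp <- file.path(out_dir, "correlations.tsv")
  utils::write.table(run$correlations, cp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  add(cp)
  if (!is.null(run$comparisons)) {
    tp <- file.path(out_dir, "comparisons.tsv")
    utils::write.table(run$comparisons, tp, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    add(tp)
  }
  cfg <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(
    c(list(paradigm = run$paradigm), unclass(run$config),
      list(included = run$included, excluded = run$excluded)),
    cfg, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  add(cfg)
  paths <- unlist(paths)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  mp <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  manifest
}
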