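# Configuration-driven end-to-end runs of the two study chains
# (present/absent search; symmetric/asymmetric judgement), on synthetic or
# file-based inputs, with fully serialized provenance.

#' Default run configuration
#'
#' @param mode `"search_study"` or `"symmetry_study"`.
#' @return a config list; fields can be overridden before passing to
#'   [run_search_study()] / [run_symmetry_study()].
#' @export
default_config <- function(mode = c("search_study", "symmetry_study")) {
  mode <- match.arg(mode)
  search_mode <- mode == "search_study"
  list(
    mode = mode,
    seed = 1L,
    # synthetic generator (ignored when input paths are supplied)
    synthetic = list(
      n_objects = if (search_mode) 32L else 64L,
      k_true = if (search_mode) 5L else 3L,
      spread = 0.5, min_dist = 0.4, max_radius = 1.4,
      n_participants = 16L, trials_per_pair = 2L,
      search_noise_sigma = 0.1, decision_noise_frac = 0.1,
      t_max = 1.8, beta = 0.5, accuracy = 0.98),
    # file inputs (trial tables written by write_trials / write_displays)
    paths = list(search_trials = NULL, decision_trials = NULL,
                 displays = NULL),
    # analysis
    k = if (search_mode) 5L else 3L,
    mds = list(criterion = "metric_stress", n_init = 10L),
    filter = if (search_mode) {
      list(search = list(min_rt = 0.3, max_rt = 3),
           decision = list(min_rt = 0.3, max_rt = 3))
    } else {
      list(search = list(min_rt = 0.3, max_rt = 3),
           decision = list(min_rt = 0.1, max_rt = Inf, min_accuracy = 0.8))
    },
    weights = c(0.5, 0.5),
    fit = list(n_restarts = 20L, bounds_expand = 0.5),
    loocv = list(n_restarts = 5L),
    searchlight = list(enabled = FALSE, grid_shape = c(20L, 20L, 20L),
                       noise_sigma = 0.5, threshold = 0.5, min_cluster = 5L),
    out_dir = NULL)
}

#' Validate a run configuration
#'
#' Schema and cross-field checks; returns all violations, not just the
#' first.
#'
#' @param config a config list (see [default_config()]).
#' @return character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (is.null(config$mode) ||
      !config$mode %in% c("search_study", "symmetry_study")) {
    add("mode must be 'search_study' or 'symmetry_study'")
  }
  n <- config$synthetic$n_objects
  if (!is.null(n) && !is.null(config$k) && config$k > n - 1) {
    add(sprintf("k must satisfy k <= n-1 (k=%s, n_objects=%s)", config$k, n))
  }
  if (!is.null(config$k) && config$k < 1) add("k must be >= 1")
  if (!is.null(n) && n < 3) add("n_objects must be >= 3")
  if (!is.null(config$synthetic$trials_per_pair) &&
      config$synthetic$trials_per_pair < 1) {
    add("trials_per_pair must be >= 1")
  }
  if (!is.null(config$fit$bounds) && !all(is.finite(config$fit$bounds))) {
    add("fit bounds must be finite")
  }
  if (!is.null(config$seed) &&
      (length(config$seed) != 1 || !is.finite(config$seed))) {
    add("seed must be a single finite integer")
  }
  fs <- config$filter$search
  if (!is.null(fs) && fs$min_rt >= fs$max_rt) {
    add("search filter: min_rt must be below max_rt")
  }
  for (p in names(config$paths)) {
    path <- config$paths[[p]]
    if (!is.null(path) && !file.exists(path)) {
      add(sprintf("input path for %s does not exist: %s", p, path))
    }
  }
  errs
}

# shared study chain: inputs -> filter -> dissimilarity -> MDS -> display
# responses -> center fit -> LOOCV -> summaries (-> searchlight)
run_study <- function(config) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  }
  mode <- if (config$mode == "search_study") "search" else "symmetry"
  log_lines <- character(0)
  note <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  }

  # -- inputs -----------------------------------------------------------
  if (is.null(config$paths$search_trials)) {
    sy <- config$synthetic
    study <- gen_study(mode,
                       n_objects = sy$n_objects, k = sy$k_true,
                       spread = sy$spread, min_dist = sy$min_dist,
                       max_radius = sy$max_radius %||% Inf,
                       n_participants = sy$n_participants,
                       trials_per_pair = sy$trials_per_pair,
                       search_noise_sigma = sy$search_noise_sigma,
                       decision_noise_frac = sy$decision_noise_frac,
                       t_max = sy$t_max, beta = sy$beta,
                       weights = config$weights, accuracy = sy$accuracy,
                       seed = config$seed)
    search_trials <- study$search_trials
    decision_trials <- study$decision_trials
    displays <- study$displays
    note("input", sprintf("synthetic %s study, %d objects, seed %d",
                          mode, sy$n_objects, config$seed))
  } else {
    if (is.null(config$paths$decision_trials) ||
        is.null(config$paths$displays)) {
      stop("[input] file mode needs search_trials, decision_trials and displays paths")
    }
    search_trials <- read_trials(config$paths$search_trials)
    decision_trials <- read_trials(config$paths$decision_trials)
    displays <- read_displays(config$paths$displays)
    note("input", "loaded trial tables from disk")
  }

  # -- behavioural filtering -------------------------------------------
  fs <- config$filter$search
  search_f <- filter_trials(search_trials, fs$min_rt, fs$max_rt)
  note("filter", sprintf("search: removed fraction %.4f",
                         attr(search_f, "removed_fraction")))
  fd <- config$filter$decision
  decision_f <- filter_trials(decision_trials, fd$min_rt, fd$max_rt,
                              min_accuracy = fd$min_accuracy)
  note("filter", sprintf("decision: removed fraction %.4f",
                         attr(decision_f, "removed_fraction")))
  rts_tab <- aggregate_decision_rts(decision_f)
  rts_tab <- rts_tab[match(displays$display_id, rts_tab$display_id), ]
  if (anyNA(rts_tab$rt)) stop("[aggregate] displays without surviving decision trials")
  labels <- rts_tab$label
  if (mode == "symmetry" &&
      (!any(labels %in% GROUP_A_LABELS) || !any(labels %in% GROUP_B_LABELS))) {
    stop("[labeling] a decision group is empty (no ",
         if (!any(labels %in% GROUP_B_LABELS)) "symmetric" else "asymmetric",
         " displays)")
  }

  # -- perceptual space -------------------------------------------------
  dmat <- dissimilarity_from_trials(search_f)
  split_half <- tryCatch(split_half_consistency(search_f),
                         error = function(e) NA_real_)
  emb <- embed_mds(dmat, config$k, criterion = config$mds$criterion,
                   n_init = config$mds$n_init, seed = config$seed)
  note("mds", sprintf("k=%d stress=%.5f fit_r=%.4f", config$k, emb$stress,
                      emb$fit_r))

  # -- display model + VH fit ------------------------------------------
  responses <- build_display_responses(emb, displays,
                                       w_target = config$weights[1],
                                       w_distractor = config$weights[2])
  fit <- fit_center(responses, rts_tab$rt, labels,
                    n_restarts = config$fit$n_restarts, seed = config$seed)
  cv <- loocv_fit(responses, displays, rts_tab$rt, labels,
                  n_restarts = config$loocv$n_restarts, seed = config$seed)
  summ <- vh_group_summary(fit)
  note("fit", sprintf("objective=%.4f rA=%.4f rB=%.4f", fit$objective,
                      fit$r_groupA, fit$r_groupB))
  note("loocv", sprintf("rA=%.4f rB=%.4f", cv$r_groupA, cv$r_groupB))

  # -- optional searchlight on synthetic volumes -----------------------
  sl <- NULL
  if (isTRUE(config$searchlight$enabled)) {
    gs <- config$searchlight$grid_shape
    vh_z <- zscore_by_group(fit$vh, labels)
    rt_z <- zscore_by_group(rts_tab$rt, labels)
    layout <- voxel_layout(
      gs,
      vh_region = cuboid_indices(gs, 3:5, 3:5, 3:5),
      rt_region = cuboid_indices(gs, (gs[1] - 4):(gs[1] - 2),
                                 (gs[2] - 4):(gs[2] - 2),
                                 (gs[3] - 4):(gs[3] - 2)),
      noise_sigma = config$searchlight$noise_sigma)
    vox <- gen_voxel_data(layout,
                          setNames(vh_z, displays$display_id),
                          setNames(rt_z, displays$display_id),
                          seed = sub_seed(config$seed, "voxels"))
    vmap <- vh_correlation_map(vox, fit$vh, labels)
    rmap <- rt_correlation_map(vox, rts_tab$rt, labels)
    regions <- define_region(vmap, config$searchlight$threshold,
                             config$searchlight$min_cluster)
    sl <- list(layout = layout, vh_map = vmap, rt_map = rmap,
               regions = regions)
    note("searchlight", sprintf("%d cluster(s) above r=%.2f",
                                length(regions),
                                config$searchlight$threshold))
  }

  report <- list(
    config = config,
    mode = mode,
    versions = list(
      vishom = as.character(utils::packageVersion("vishom")),
      R = paste(R.version$major, R.version$minor, sep = ".")),
    split_half_r = as.numeric(split_half),
    mds = list(k = emb$k, stress = emb$stress, fit_r = emb$fit_r),
    fit = list(center = as.numeric(fit$center), objective = fit$objective,
               r_groupA = fit$r_groupA, r_groupB = fit$r_groupB),
    loocv = list(r_groupA = cv$r_groupA, r_groupB = cv$r_groupB),
    group_summary = summ$summary,
    ranksum_p = summ$p_value,
    log = log_lines)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    write_trials(search_trials, file.path(od, "search_trials.tsv"))
    write_trials(decision_trials, file.path(od, "decision_trials.tsv"))
    write_displays(displays, file.path(od, "displays.tsv"))
    write_dissimilarity(dmat, file.path(od, "dissimilarity.tsv"))
    write_embedding(emb, file.path(od, "embedding.tsv"))
    per_disp <- data.frame(display_id = displays$display_id,
                           label = labels, vh = as.numeric(fit$vh),
                           rt = rts_tab$rt,
                           loocv_vh = as.numeric(cv$vh_loocv))
    write.table(per_disp, file.path(od, "display_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(center = as.numeric(fit$center), objective = fit$objective,
           r_groupA = fit$r_groupA, r_groupB = fit$r_groupB,
           restarts = fit$restarts, seed = config$seed),
      file.path(od, "vh_fit.json"), auto_unbox = TRUE, digits = NA)
    report_out <- report
    report_out$config$searchlight <- NULL  # arrays re-serialized poorly
    jsonlite::write_json(report_out, file.path(od, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    writeLines(log_lines, file.path(od, "run.log"))
  }
  report$embedding <- emb
  report$vh_fit <- fit
  report$loocv_fit <- cv
  report$displays <- displays
  report$rts <- rts_tab
  report$dissimilarity <- dmat
  report$searchlight <- sl
  invisible(report)
}

#' Run the present/absent search study chain
#'
#' Filter search trials -> 1/RT dissimilarities -> MDS (default k = 5) ->
#' display responses (equal averaging weights) -> VH center fit -> LOOCV ->
#' group summaries, with an optional synthetic-voxel searchlight stage.
#' All artifacts plus a run log are written to `config$out_dir` when set.
#'
#' @param config config list; see [default_config()] for the fields.
#' @return report list (invisibly).
#' @export
run_search_study <- function(config = default_config("search_study")) {
  if (!identical(config$mode, "search_study")) stop("config mode mismatch")
  run_study(config)
}

#' Run the symmetry-judgement study chain
#'
#' As [run_search_study()] with singleton displays, asymmetric/symmetric
#' labels, default k = 3, and the symmetry-task decision filters (drop
#' RTs below 100 ms; drop a participant's RTs to an object when their
#' accuracy on it is below 80%).
#'
#' @param config config list; see [default_config()].
#' @return report list (invisibly).
#' @export
run_symmetry_study <- function(config = default_config("symmetry_study")) {
  if (!identical(config$mode, "symmetry_study")) stop("config mode mismatch")
  run_study(config)
}
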