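# Synthetic study generator.
#
# Produces every input the analysis consumes -- latent perceptual spaces,
# oddball-search trial tables (RT ~ 1/distance + noise), present/absent or
# symmetric/asymmetric decision trial tables (RT slowest near the decision
# boundary on the VH axis), and voxel volumes with planted VH- and
# RT-encoding regions -- under explicit seeds, so that each downstream stage
# has a ground truth to recover.

#' Sample a latent perceptual embedding
#'
#' Objects are drawn i.i.d. from an isotropic Gaussian `N(0, spread^2 I_k)`.
#' With `min_dist > 0`, points closer than `min_dist` to any other point are
#' resampled (rejection) until all pairwise distances clear the floor; this
#' emulates a stimulus set designed so that no search is impossibly hard
#' (search RT = 1/distance stays below the trial filter ceiling).
#'
#' @param n_objects number of objects (>= 3).
#' @param k latent dimensionality (>= 1).
#' @param spread Gaussian scale per dimension, in dissimilarity units
#'   (1/seconds).
#' @param seed integer seed; identical calls are bit-identical.
#' @param min_dist minimum allowed pairwise distance (0 disables).
#' @param max_radius maximum allowed distance from the origin (Inf
#'   disables); together with `min_dist` this bounds all pairwise
#'   distances into `[min_dist, 2 * max_radius]`, keeping 1/distance
#'   search RTs inside a physical measurement window.
#' @return numeric `n_objects x k` matrix with object ids as rownames.
#' @export
gen_embedding <- function(n_objects, k, spread = 1, seed = 1, min_dist = 0,
                          max_radius = Inf) {
  if (length(n_objects) != 1 || n_objects < 3) {
    stop("n_objects must be a single integer >= 3")
  }
  if (length(k) != 1 || k < 1) stop("k must be a single integer >= 1")
  if (spread < 0) stop("spread must be non-negative")
  with_seed(sub_seed(seed, "embedding"), {
    constrained <- spread > 0 && (min_dist > 0 || is.finite(max_radius))
    if (!constrained) {
      x <- matrix(rnorm(n_objects * k, sd = 1), n_objects, k) * spread
    } else {
      # sequential dart throwing: each point is redrawn until it clears the
      # norm cap and the separation floor against all accepted points
      x <- matrix(0, n_objects, k)
      for (i in seq_len(n_objects)) {
        placed <- FALSE
        for (try in 1:5000) {
          p <- rnorm(k, sd = 1) * spread
          if (is.finite(max_radius) && sqrt(sum(p * p)) > max_radius) next
          if (i > 1 && min_dist > 0) {
            prev <- x[seq_len(i - 1), , drop = FALSE]
            gap2 <- rowSums((prev - matrix(p, i - 1, k, byrow = TRUE))^2)
            if (min(gap2) < min_dist^2) next
          }
          x[i, ] <- p
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("cannot satisfy min_dist/max_radius for ", n_objects,
               " points; relax the constraints")
        }
      }
    }
    rownames(x) <- sprintf("obj%03d", seq_len(n_objects))
    colnames(x) <- sprintf("dim%d", seq_len(k))
    x
  })
}

#' Assemble a ground-truth generative model
#'
#' Bundles the latent embedding, the true VH center, the decision boundary
#' on the VH axis, and the RT link parameters. Decision RTs follow
#' `rt = t_max - beta * |VH - boundary_b| + noise` (slowest for displays
#' whose VH sits at the boundary), truncated below at a physical floor.
#'
#' @param embedding `n x k` coordinate matrix (see [gen_embedding()]).
#' @param center_true true center (defaults to the embedding centroid).
#' @param boundary_b decision boundary on the VH axis.
#' @param t_max peak decision RT, seconds.
#' @param beta RT drop per unit VH distance from the boundary, s per (1/s).
#' @param sigma trial-level decision-RT noise sd, seconds.
#' @param search_noise_sigma trial-level search-RT noise sd, seconds.
#' @param seed master seed carried by the generators.
#' @return object of class `vh_ground_truth`.
#' @export
ground_truth <- function(embedding, center_true = NULL, boundary_b = NULL,
                         t_max = 1.8, beta = 0.5, sigma = 0.05,
                         search_noise_sigma = 0.1, seed = 1) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) < 3) stop("need at least 3 objects")
  if (ncol(embedding) < 1) stop("need at least 1 dimension")
  if (t_max <= 0) stop("t_max must be positive")
  if (sigma < 0 || search_noise_sigma < 0) stop("noise sd must be >= 0")
  if (is.null(rownames(embedding))) {
    rownames(embedding) <- sprintf("obj%03d", seq_len(nrow(embedding)))
  }
  center_true <- center_true %||% colMeans(embedding)
  if (length(center_true) != ncol(embedding)) {
    stop("center_true must have one coordinate per embedding dimension")
  }
  if (is.null(boundary_b)) {
    boundary_b <- stats::median(sqrt(rowSums(
      sweep(embedding, 2, center_true)^2)))
  }
  structure(
    list(embedding_true = embedding,
         center_true = as.numeric(center_true),
         boundary_b = boundary_b,
         rt_link = list(t_max = t_max, beta = beta, sigma = sigma),
         search_noise_sigma = search_noise_sigma,
         seed = seed),
    class = "vh_ground_truth")
}

#' @export
print.vh_ground_truth <- function(x, ...) {
  cat(sprintf("vh_ground_truth: %d objects in %d dims; boundary %.3f; ",
              nrow(x$embedding_true), ncol(x$embedding_true), x$boundary_b),
      sprintf("link t_max=%.2fs beta=%.2f sigma=%.3fs; search sigma=%.3fs\n",
              x$rt_link$t_max, x$rt_link$beta, x$rt_link$sigma,
              x$search_noise_sigma), sep = "")
  invisible(x)
}

#' Build display specifications for a present/absent study
#'
#' One target-absent display (an array of identical items, modeled as a
#' singleton) per object, plus `n_present` target-present oddball arrays in
#' which each object appears once as target, paired with a random distinct
#' distractor.
#'
#' @param objects character vector of object ids.
#' @param n_present number of target-present displays (default one per
#'   object).
#' @param seed integer seed for the target/distractor pairing.
#' @return data.frame with columns `display_id`, `kind`, `target_id`,
#'   `distractor_id`, `label`.
#' @export
make_displays <- function(objects, n_present = length(objects), seed = 1) {
  n <- length(objects)
  if (n < 2) stop("need at least 2 objects")
  absent <- data.frame(
    display_id = paste0("abs_", objects),
    kind = "singleton",
    target_id = objects,
    distractor_id = NA_character_,
    label = "absent",
    stringsAsFactors = FALSE)
  with_seed(sub_seed(seed, "displays"), {
    # derangement: each object is a target once, distractor drawn without
    # self-pairing
    repeat {
      perm <- sample(n)
      if (all(perm != seq_len(n))) break
    }
    tgt <- objects[rep_len(seq_len(n), n_present)]
    dst <- objects[rep_len(perm, n_present)]
    present <- data.frame(
      display_id = paste0("prs_", tgt, "_", dst),
      kind = "oddball_array",
      target_id = tgt,
      distractor_id = dst,
      label = "present",
      stringsAsFactors = FALSE)
    rbind(present, absent)
  })
}

#' Build singleton display specifications for a symmetry study
#'
#' @param objects character vector of object ids.
#' @param labels per-object labels, `"asymmetric"` or `"symmetric"`;
#'   `NULL` leaves labels to the boundary rule at trial-generation time.
#' @return data.frame as in [make_displays()].
#' @export
make_symmetry_displays <- function(objects, labels = NULL) {
  data.frame(
    display_id = paste0("obj_", objects),
    kind = "singleton",
    target_id = objects,
    distractor_id = NA_character_,
    label = if (is.null(labels)) NA_character_ else as.character(labels),
    stringsAsFactors = FALSE)
}

#' Generate oddball-search trials
#'
#' For every unordered object pair, each participant contributes
#' `trials_per_pair` trials with the two items alternating target/distractor
#' roles. Trial RT is `1/distance + N(0, search_noise_sigma)`, truncated
#' below at `rt_floor`. Accuracy is Bernoulli with rate `accuracy`;
#' incorrect trials are flagged (not removed) so downstream filtering is
#' exercised.
#'
#' @param gt a [ground_truth()] object.
#' @param trials_per_pair trials per pair per participant (>= 1).
#' @param n_participants number of participants.
#' @param accuracy per-trial probability of a correct response.
#' @param rt_floor truncation floor, seconds.
#' @param seed seed; defaults to the ground truth's.
#' @return trial table: `participant`, `target_id`, `distractor_id`,
#'   `label` (`"search"`), `rt`, `correct`.
#' @export
gen_search_trials <- function(gt, trials_per_pair = 2, n_participants = 16,
                              accuracy = 0.98, rt_floor = 0.05, seed = NULL) {
  stopifnot(inherits(gt, "vh_ground_truth"))
  if (trials_per_pair < 1) stop("trials_per_pair must be >= 1")
  seed <- seed %||% gt$seed
  emb <- gt$embedding_true
  objs <- rownames(emb)
  dmat <- as.matrix(dist(emb))
  pairs <- combn(length(objs), 2)
  dpair <- dmat[t(pairs)]
  if (any(dpair == 0) && gt$search_noise_sigma == 0) {
    stop("zero inter-object distance with zero noise gives infinite RT; ",
         "perturb the embedding (e.g. spread > 0 or jitter coincident points)")
  }
  n_pairs <- ncol(pairs)
  reps <- trials_per_pair
  # layout: participant-major, then pair, then repetition
  idx_pair <- rep(rep(seq_len(n_pairs), each = reps), times = n_participants)
  idx_rep <- rep(rep(seq_len(reps), times = n_pairs), times = n_participants)
  participant <- rep(seq_len(n_participants), each = n_pairs * reps)
  i <- pairs[1, idx_pair]
  j <- pairs[2, idx_pair]
  # alternate which item plays target across repetitions
  swap <- idx_rep %% 2 == 0
  tgt <- ifelse(swap, j, i)
  dst <- ifelse(swap, i, j)
  base_rt <- 1 / dpair[idx_pair]
  with_seed(sub_seed(seed, "search_trials"), {
    rt <- pmax(rt_floor, base_rt + rnorm(length(base_rt),
                                         sd = gt$search_noise_sigma))
    correct <- rbinom(length(base_rt), 1, accuracy) == 1
    data.frame(participant = participant,
               target_id = objs[tgt],
               distractor_id = objs[dst],
               label = "search",
               rt = rt,
               correct = correct,
               stringsAsFactors = FALSE)
  })
}

#' Generate decision-task trials (present/absent or symmetric/asymmetric)
#'
#' Each display's true VH is the distance of its averaged response vector
#' to the true center; trial RT is
#' `t_max - beta * |VH - boundary_b| + N(0, sigma)`, truncated below at
#' `rt_floor`, i.e. slowest for displays whose VH sits at the decision
#' boundary. Labels default to the side of the boundary (`label_source =
#' "boundary"`); `"display"` uses the labels stored in `displays`.
#'
#' @param gt a [ground_truth()] object.
#' @param displays display table (see [make_displays()]).
#' @param weights length-2 target/distractor averaging weights for oddball
#'   arrays (normalized to sum to 1).
#' @param trials_per_display repetitions per display per participant.
#' @param n_participants number of participants.
#' @param label_source `"boundary"` or `"display"`.
#' @param label_names labels for the two boundary-rule groups
#'   (below-boundary group first).
#' @param accuracy per-trial probability of a correct response.
#' @param rt_floor truncation floor, seconds.
#' @param seed seed; defaults to the ground truth's.
#' @return trial table with columns `participant`, `display_id`,
#'   `target_id`, `distractor_id`, `label`, `rt`, `correct`; the per-display
#'   true VH is attached as attribute `"vh_true"`.
#' @export
gen_decision_trials <- function(gt, displays, weights = c(0.5, 0.5),
                                trials_per_display = 1, n_participants = 1,
                                label_source = c("boundary", "display"),
                                label_names = c("present", "absent"),
                                accuracy = 0.98, rt_floor = 0.05,
                                seed = NULL) {
  stopifnot(inherits(gt, "vh_ground_truth"))
  label_source <- match.arg(label_source)
  seed <- seed %||% gt$seed
  resp <- build_display_responses(gt$embedding_true, displays,
                                  w_target = weights[1],
                                  w_distractor = weights[2])
  vh <- visual_homogeneity(resp, gt$center_true)
  b <- gt$boundary_b
  link <- gt$rt_link
  rt0 <- link$t_max - link$beta * abs(vh - b)
  if (any(rt0 <= 0)) {
    warning("beta * max|VH - boundary| >= t_max: some pre-truncation RTs ",
            "are non-positive and will be clamped to the floor")
  }
  labels <- switch(label_source,
    boundary = ifelse(vh < b, label_names[1], label_names[2]),
    display = {
      if (anyNA(displays$label)) stop("displays carry NA labels; use label_source='boundary'")
      displays$label
    })
  nd <- nrow(displays)
  reps <- trials_per_display
  idx <- rep(rep(seq_len(nd), each = reps), times = n_participants)
  participant <- rep(seq_len(n_participants), each = nd * reps)
  with_seed(sub_seed(seed, "decision_trials"), {
    rt <- pmax(rt_floor, rt0[idx] + rnorm(length(idx), sd = link$sigma))
    correct <- rbinom(length(idx), 1, accuracy) == 1
    out <- data.frame(participant = participant,
                      display_id = displays$display_id[idx],
                      target_id = displays$target_id[idx],
                      distractor_id = displays$distractor_id[idx],
                      label = labels[idx],
                      rt = rt,
                      correct = correct,
                      stringsAsFactors = FALSE)
    attr(out, "vh_true") <- setNames(vh, displays$display_id)
    attr(out, "labels") <- setNames(labels, displays$display_id)
    out
  })
}

#' Aggregate decision trials to per-display mean RTs
#'
#' @param trials decision trial table.
#' @param correct_only drop incorrect trials before averaging.
#' @return data.frame `display_id`, `label`, `rt` (mean seconds), `n_trials`,
#'   in order of first appearance.
#' @export
aggregate_decision_rts <- function(trials, correct_only = TRUE) {
  if (correct_only) trials <- trials[trials$correct, , drop = FALSE]
  if (nrow(trials) == 0) stop("no trials left to aggregate")
  ids <- unique(trials$display_id)
  f <- factor(trials$display_id, levels = ids)
  rt <- tapply(trials$rt, f, mean)
  lab <- tapply(trials$label, f, function(x) x[1])
  n <- tapply(trials$rt, f, length)
  data.frame(display_id = ids, label = as.character(lab),
             rt = as.numeric(rt), n_trials = as.integer(n),
             stringsAsFactors = FALSE)
}

#' Mirror-symmetric decision design
#'
#' Constructs a 1-D (zero-padded to `k` dims) ground truth in which group-A
#' (asymmetric) singletons sit at VH = boundary - delta and group-B
#' (symmetric) singletons at VH = boundary + delta for the same deltas, so
#' that noiseless within-group VH-RT correlations are exactly +1 and -1
#' while the pooled correlation is exactly 0.
#'
#' @param n_per_group objects per group.
#' @param boundary boundary VH value (must exceed `delta_max`).
#' @param delta_max largest offset from the boundary.
#' @param k embedding dimensionality (extra dims are zero).
#' @param t_max,beta,sigma RT link parameters (see [ground_truth()]).
#' @param seed master seed.
#' @return list with elements `gt` and `displays`.
#' @export
gen_symmetric_design <- function(n_per_group = 32, boundary = 3,
                                 delta_max = 1, k = 1, t_max = 1.8,
                                 beta = 0.5, sigma = 0, seed = 1) {
  if (boundary <= delta_max) stop("boundary must exceed delta_max")
  delta <- seq(delta_max / n_per_group, delta_max, length.out = n_per_group)
  x <- c(boundary - delta, boundary + delta)
  emb <- cbind(x, matrix(0, length(x), k - 1))
  colnames(emb) <- sprintf("dim%d", seq_len(k))
  rownames(emb) <- c(sprintf("asym%03d", seq_len(n_per_group)),
                     sprintf("sym%03d", seq_len(n_per_group)))
  gt <- ground_truth(emb, center_true = rep(0, k), boundary_b = boundary,
                     t_max = t_max, beta = beta, sigma = sigma, seed = seed)
  displays <- make_symmetry_displays(
    rownames(emb), labels = rep(c("asymmetric", "symmetric"),
                                each = n_per_group))
  list(gt = gt, displays = displays)
}

#' Voxel grid layout with planted signal regions
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @param mask logical 3-D array (default: all voxels in-brain).
#' @param vh_region,rt_region integer vectors of linear voxel indices for
#'   the VH-encoding and RT-encoding regions; must lie inside the mask and
#'   be disjoint.
#' @param noise_sigma activation noise sd (GLM-beta units).
#' @return object of class `vh_voxel_layout`.
#' @export
voxel_layout <- function(grid_shape, mask = NULL, vh_region = integer(),
                         rt_region = integer(), noise_sigma = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    stop("grid_shape must be 3 positive integers")
  }
  if (is.null(mask)) mask <- array(TRUE, grid_shape)
  if (!all(dim(mask) == grid_shape)) stop("mask does not match grid_shape")
  vh_region <- as.integer(vh_region)
  rt_region <- as.integer(rt_region)
  if (length(intersect(vh_region, rt_region)) > 0) {
    stop("vh_region and rt_region overlap")
  }
  if (!all(mask[vh_region]) || !all(mask[rt_region])) {
    stop("signal regions must lie inside the mask")
  }
  structure(list(grid_shape = grid_shape, mask = mask,
                 vh_region = vh_region, rt_region = rt_region,
                 noise_sigma = noise_sigma),
            class = "vh_voxel_layout")
}

#' Linear voxel indices of a cuboid block
#'
#' Convenience for planting rectangular signal regions.
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @param x,y,z integer coordinate ranges of the block.
#' @return integer vector of linear indices.
#' @export
cuboid_indices <- function(grid_shape, x, y, z) {
  idx <- as.matrix(expand.grid(x = x, y = y, z = z))
  as.integer(idx[, 1] + (idx[, 2] - 1) * grid_shape[1] +
               (idx[, 3] - 1) * grid_shape[1] * grid_shape[2])
}

#' Generate per-condition voxel activation volumes
#'
#' In the VH region, activation is `intercept + slope_vh * vh + noise`; in
#' the RT region, `intercept + slope_rt * rt + noise`; elsewhere pure noise
#' (plus intercept). With `n_subjects > 1`, each subject gets independent
#' noise around the shared signal, and the dataset's `betas` are the
#' across-subject mean.
#'
#' @param layout a [voxel_layout()].
#' @param vh named per-condition VH values.
#' @param rt named per-condition RTs (same conditions as `vh`).
#' @param slope_vh,slope_rt signal slopes (`slope_vh > 0` plants the
#'   positive VH coding the analysis looks for).
#' @param intercept baseline activation.
#' @param n_subjects number of simulated participants.
#' @param seed integer seed.
#' @return a [voxel_dataset()] (with `subject_betas` when `n_subjects > 1`).
#' @export
gen_voxel_data <- function(layout, vh, rt, slope_vh = 1, slope_rt = 1,
                           intercept = 0, n_subjects = 1, seed = 1) {
  stopifnot(inherits(layout, "vh_voxel_layout"))
  if (is.null(names(vh)) || is.null(names(rt)) ||
      !identical(names(vh), names(rt))) {
    stop("vh and rt must be named by the same condition list")
  }
  conds <- names(vh)
  nc <- length(conds)
  gs <- layout$grid_shape
  nv <- prod(gs)
  signal <- matrix(intercept, nv, nc)
  if (length(layout$vh_region)) {
    signal[layout$vh_region, ] <- intercept +
      slope_vh * matrix(vh, length(layout$vh_region), nc, byrow = TRUE)
  }
  if (length(layout$rt_region)) {
    signal[layout$rt_region, ] <- intercept +
      slope_rt * matrix(rt, length(layout$rt_region), nc, byrow = TRUE)
  }
  subj <- with_seed(sub_seed(seed, "voxels"), {
    lapply(seq_len(n_subjects), function(s) {
      flat <- signal + matrix(rnorm(nv * nc, sd = layout$noise_sigma), nv, nc)
      flat[!layout$mask, ] <- NA_real_
      array(flat, c(gs, nc))
    })
  })
  betas <- if (n_subjects == 1) subj[[1]] else {
    acc <- subj[[1]]
    for (s in 2:n_subjects) acc <- acc + subj[[s]]
    acc / n_subjects
  }
  voxel_dataset(betas, layout$mask, conds,
                subject_betas = if (n_subjects > 1) subj else NULL)
}

#' Default synthetic study bundle
#'
#' Generates a complete study under the package's standard conditions: a
#' latent embedding, display set, search trials and decision trials, with
#' the boundary placed midway between the structural group VH means and the
#' decision-RT noise sd set to `decision_noise_frac` of the noiseless RT
#' range.
#'
#' @param mode `"search"` (32 objects, 5 dims, present/absent) or
#'   `"symmetry"` (64 objects, 3 dims, asymmetric/symmetric singletons).
#' @param n_objects,k,spread,min_dist,max_radius embedding parameters.
#' @param n_participants,trials_per_pair search-task sampling.
#' @param search_noise_sigma trial-level search RT noise sd (s).
#' @param decision_noise_frac decision RT noise sd as a fraction of the
#'   noiseless RT range (0 = noiseless).
#' @param decision_participants,decision_reps decision-task sampling.
#' @param t_max,beta RT link parameters.
#' @param weights true target/distractor averaging weights.
#' @param accuracy simulated accuracy.
#' @param seed master seed.
#' @return list with `gt`, `displays`, `search_trials`, `decision_trials`,
#'   `rts` (per-display aggregated), `labels`, `vh_true`.
#' @export
gen_study <- function(mode = c("search", "symmetry"),
                      n_objects = if (mode == "search") 32L else 64L,
                      k = if (mode == "search") 5L else 3L,
                      spread = 0.5, min_dist = 0.4, max_radius = 1.4,
                      n_participants = 16, trials_per_pair = 2,
                      search_noise_sigma = 0.1,
                      decision_noise_frac = 0.1,
                      decision_participants = 16, decision_reps = 1,
                      t_max = 1.8, beta = 0.5, weights = c(0.5, 0.5),
                      accuracy = 0.98, seed = 1) {
  mode <- match.arg(mode)
  emb <- gen_embedding(n_objects, k, spread = spread, seed = seed,
                       min_dist = min_dist, max_radius = max_radius)
  center <- colMeans(emb)
  displays <- if (mode == "search") {
    make_displays(rownames(emb), seed = seed)
  } else {
    make_symmetry_displays(rownames(emb))
  }
  resp <- build_display_responses(emb, displays, w_target = weights[1],
                                  w_distractor = weights[2])
  vh <- visual_homogeneity(resp, center)
  # median split: the boundary that balances the two response categories,
  # matching the balanced present/absent design of the scanner task
  boundary <- stats::median(vh)
  rt0 <- t_max - beta * abs(vh - boundary)
  sigma <- decision_noise_frac * diff(range(rt0))
  gt <- ground_truth(emb, center_true = center, boundary_b = boundary,
                     t_max = t_max, beta = beta, sigma = sigma,
                     search_noise_sigma = search_noise_sigma, seed = seed)
  search_trials <- gen_search_trials(gt, trials_per_pair = trials_per_pair,
                                     n_participants = n_participants,
                                     accuracy = accuracy)
  label_names <- if (mode == "search") c("present", "absent")
                 else c("asymmetric", "symmetric")
  decision_trials <- gen_decision_trials(
    gt, displays, weights = weights, trials_per_display = decision_reps,
    n_participants = decision_participants, label_source = "boundary",
    label_names = label_names, accuracy = accuracy)
  rts <- aggregate_decision_rts(decision_trials)
  rts <- rts[match(displays$display_id, rts$display_id), ]  # display order
  rownames(rts) <- NULL
  list(gt = gt, displays = displays, search_trials = search_trials,
       decision_trials = decision_trials, rts = rts,
       labels = attr(decision_trials, "labels"),
       vh_true = attr(decision_trials, "vh_true"))
}
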