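# Perceptual space reconstruction: trial filtering, 1/RT dissimilarities,
# multidimensional scaling, and consistency diagnostics.

#' Filter behavioural trials
#'
#' Keeps correct trials with `min_rt <= rt <= max_rt`. When `min_accuracy`
#' is set, additionally drops all of a participant's trials involving any
#' object for which that participant's accuracy (computed on the unfiltered
#' input) is below the threshold. The fraction of input trials removed is
#' attached as attribute `"removed_fraction"`.
#'
#' @param trials trial table (`participant`, `target_id`, `distractor_id`,
#'   `label`, `rt`, `correct`).
#' @param min_rt,max_rt RT window in seconds (defaults follow the oddball
#'   search convention of dropping trials below 0.3 s or above 3 s).
#' @param min_accuracy optional per-participant, per-object accuracy
#'   threshold in `[0, 1]`.
#' @return filtered trial table.
#' @export
filter_trials <- function(trials, min_rt = 0.3, max_rt = 3,
                          min_accuracy = NULL) {
  if (min_rt >= max_rt) stop("min_rt must be below max_rt")
  n0 <- nrow(trials)
  if (n0 == 0) stop("empty trial table")
  keep_acc <- rep(TRUE, n0)
  if (!is.null(min_accuracy)) {
    # accuracy per (participant, object), objects in either role
    roles <- rbind(
      data.frame(row = seq_len(n0), participant = trials$participant,
                 object = trials$target_id, correct = trials$correct),
      data.frame(row = seq_len(n0), participant = trials$participant,
                 object = trials$distractor_id, correct = trials$correct))
    roles <- roles[!is.na(roles$object), , drop = FALSE]
    key <- paste(roles$participant, roles$object, sep = "\r")
    acc <- tapply(roles$correct, key, mean)
    bad_keys <- names(acc)[acc < min_accuracy]
    if (length(bad_keys)) {
      keep_acc[unique(roles$row[key %in% bad_keys])] <- FALSE
    }
  }
  keep_correct <- trials$correct
  keep_rt <- trials$rt >= min_rt & trials$rt <= max_rt
  keep <- keep_acc & keep_correct & keep_rt
  if (!any(keep)) {
    removed_by <- c(accuracy = sum(!keep_acc), correctness = sum(!keep_correct),
                    rt_window = sum(!keep_rt))
    stop("all trials removed; dominant filter: ",
         names(which.max(removed_by)))
  }
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_fraction") <- 1 - nrow(out) / n0
  out
}

#' Perceptual dissimilarity matrix from search trials
#'
#' For each unordered object pair, pools trials across participants and
#' both target/distractor orderings, and sets dissimilarity
#' `d(i, j) = 1 / mean(RT)` (units 1/seconds). The diagonal is 0 and is
#' ignored by all downstream fits (no self-search exists).
#'
#' @param trials (filtered) search trial table.
#' @param objects optional ordered object-id vector; defaults to the sorted
#'   union of ids observed in the trials.
#' @return symmetric `n x n` matrix with object ids as dimnames.
#' @export
dissimilarity_from_trials <- function(trials, objects = NULL) {
  objects <- objects %||% sort(unique(c(trials$target_id,
                                        trials$distractor_id)))
  n <- length(objects)
  if (n < 2) stop("need at least 2 objects")
  i <- match(trials$target_id, objects)
  j <- match(trials$distractor_id, objects)
  if (anyNA(i) || anyNA(j)) stop("trials refer to objects outside the declared set")
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  key <- (lo - 1) * n + hi
  mean_rt <- tapply(trials$rt, key, mean)
  d <- matrix(0, n, n, dimnames = list(objects, objects))
  pairs <- t(combn(n, 2))
  pkey <- (pairs[, 1] - 1) * n + pairs[, 2]
  hit <- match(pkey, as.numeric(names(mean_rt)))
  if (anyNA(hit)) {
    missing <- pairs[is.na(hit), , drop = FALSE]
    stop("no surviving trials for pair(s): ",
         paste(objects[missing[, 1]], objects[missing[, 2]],
               sep = "-", collapse = ", "))
  }
  vals <- 1 / as.numeric(mean_rt)[hit]
  d[cbind(pairs[, 1], pairs[, 2])] <- vals
  d[cbind(pairs[, 2], pairs[, 1])] <- vals
  d
}

#' Split-half consistency of search RTs
#'
#' Pearson correlation between per-pair mean RTs of odd- and even-indexed
#' participants (1-based index in the sorted participant list). Pairs
#' missing from either half are excluded; their count is attached as
#' attribute `"n_pairs_excluded"`.
#'
#' @param trials search trial table (typically filtered).
#' @return Pearson r (length-1 numeric).
#' @export
split_half_consistency <- function(trials) {
  parts <- sort(unique(trials$participant))
  if (length(parts) < 2) stop("need at least 2 participants")
  odd <- parts[seq_along(parts) %% 2 == 1]
  pair_key <- ifelse(trials$target_id < trials$distractor_id,
                     paste(trials$target_id, trials$distractor_id),
                     paste(trials$distractor_id, trials$target_id))
  half <- ifelse(trials$participant %in% odd, "odd", "even")
  m_odd <- tapply(trials$rt[half == "odd"], pair_key[half == "odd"], mean)
  m_even <- tapply(trials$rt[half == "even"], pair_key[half == "even"], mean)
  common <- intersect(names(m_odd), names(m_even))
  n_excluded <- length(union(names(m_odd), names(m_even))) - length(common)
  if (length(common) < 3) stop("fewer than 3 pairs present in both halves")
  r <- fast_cor(as.numeric(m_odd[common]), as.numeric(m_even[common]))
  attr(r, "n_pairs_excluded") <- n_excluded
  r
}

# One run of SMACOF majorization for raw metric stress with unit weights.
# Returns coordinates, normalized stress sqrt(sum((dhat-d)^2)/sum(d^2)),
# and a convergence flag.
smacof_run <- function(delta, x0, tol = 1e-8, maxit = 500) {
  n <- nrow(delta)
  lt <- lower.tri(delta)
  denom <- sum(delta[lt]^2)
  x <- x0
  d <- as.matrix(dist(x))
  raw <- sum((d[lt] - delta[lt])^2)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    b <- matrix(0, n, n)
    nz <- d > 0
    b[nz] <- -delta[nz] / d[nz]
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x <- b %*% x / n
    d <- as.matrix(dist(x))
    raw_new <- sum((d[lt] - delta[lt])^2)
    if ((raw - raw_new) / max(denom, .Machine$double.eps) < tol) {
      raw <- raw_new
      converged <- TRUE
      break
    }
    raw <- raw_new
  }
  list(coords = x, stress = sqrt(raw / max(denom, .Machine$double.eps)),
       converged = converged)
}

#' Embed a dissimilarity matrix by multidimensional scaling
#'
#' Default criterion is metric stress (SMACOF majorization of the raw
#' stress, normalized by the sum of squared dissimilarities), initialized
#' from classical scaling with `n_init - 1` additional perturbed restarts;
#' `"nonmetric_stress"` uses Kruskal's stress-1 via [MASS::isoMDS()]. The
#' returned configuration is centered at the origin; orientation is
#' arbitrary, and every downstream VH quantity is invariant to it.
#'
#' @param d symmetric dissimilarity matrix (object ids as dimnames).
#' @param k embedding dimensionality, `1 <= k <= n - 1`.
#' @param criterion `"metric_stress"` or `"nonmetric_stress"`.
#' @param n_init number of restarts.
#' @param seed seed for the restart perturbations.
#' @return object of class `vh_embedding`: `objects`, `coords` (`n x k`),
#'   `k`, `stress`, `fit_r` (Pearson r between embedded and observed
#'   dissimilarities; `NA` with a note if `d` has zero variance),
#'   `criterion`.
#' @export
embed_mds <- function(d, k, criterion = c("metric_stress", "nonmetric_stress"),
                      n_init = 10, seed = 1) {
  criterion <- match.arg(criterion)
  d <- as.matrix(d)
  if (!all(is.finite(d))) stop("dissimilarity matrix has non-finite entries")
  if (max(abs(d - t(d))) > 1e-12) stop("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  if (k < 1 || k > n - 1) stop("k must satisfy 1 <= k <= n - 1")
  objects <- rownames(d) %||% sprintf("obj%03d", seq_len(n))
  init0 <- suppressWarnings(cmdscale(d, k = k))
  if (ncol(init0) < k) {
    init0 <- cbind(init0, matrix(0, n, k - ncol(init0)))
  }
  scale0 <- max(sd(as.numeric(init0)), max(d) / 10, .Machine$double.eps)
  runs <- with_seed(sub_seed(seed, "mds"), {
    lapply(seq_len(max(1, n_init)), function(r) {
      x0 <- if (r == 1) init0 else init0 + matrix(
        rnorm(n * k, sd = 0.25 * scale0), n, k)
      if (criterion == "metric_stress") {
        smacof_run(d, x0)
      } else {
        dd <- d
        # isoMDS rejects zero off-diagonal dissimilarities
        eps <- max(d) * 1e-9 + .Machine$double.eps
        dd[dd <= 0] <- eps
        diag(dd) <- 0
        fit <- tryCatch(
          MASS::isoMDS(stats::as.dist(dd), y = x0, k = k, trace = FALSE),
          error = function(e) NULL)
        if (is.null(fit)) return(list(coords = x0, stress = Inf,
                                      converged = FALSE))
        list(coords = fit$points, stress = fit$stress / 100,
             converged = TRUE)
      }
    })
  })
  stresses <- vapply(runs, `[[`, numeric(1), "stress")
  best <- runs[[which.min(stresses)]]
  if (!any(vapply(runs, `[[`, logical(1), "converged"))) {
    warning("no MDS restart converged; best stress ",
            format(best$stress), " over ", length(runs), " restarts")
  }
  coords <- sweep(best$coords, 2, colMeans(best$coords))
  rownames(coords) <- objects
  colnames(coords) <- sprintf("dim%d", seq_len(k))
  lt <- lower.tri(d)
  fit_r <- if (sd(d[lt]) == 0) NA_real_ else {
    fast_cor(as.matrix(dist(coords))[lt], d[lt])
  }
  structure(list(objects = objects, coords = coords, k = k,
                 stress = best$stress, fit_r = fit_r,
                 criterion = criterion,
                 fit_r_note = if (is.na(fit_r))
                   "zero variance in d; fit_r undefined" else NULL),
            class = "vh_embedding")
}

#' @export
print.vh_embedding <- function(x, ...) {
  cat(sprintf("vh_embedding: %d objects in %d dims (%s); stress %.4g; fit_r %s\n",
              length(x$objects), x$k, x$criterion, x$stress,
              ifelse(is.na(x$fit_r), "NA", sprintf("%.3f", x$fit_r))))
  invisible(x)
}

#' Leave-one-image-out sweep over embedding dimensionality
#'
#' For each candidate `k`: embed the search dissimilarities, build display
#' responses, run the leave-one-image-out center fit, and record
#' `|r_groupA| + |r_groupB|` on the assembled cross-validated VH values.
#' The selected dimensionality is the smallest `k` whose criterion is
#' within `tol` of the sweep maximum (the plateau rule).
#'
#' @param trials filtered search trial table.
#' @param displays display table.
#' @param rts per-display mean RTs (aligned with `displays`).
#' @param labels per-display decision labels.
#' @param k_range candidate dimensionalities.
#' @param weights averaging weights for oddball arrays.
#' @param n_init MDS restarts per `k`.
#' @param n_restarts center-fit restarts per fold.
#' @param tol plateau tolerance on the criterion.
#' @param seed seed.
#' @return list with `table` (data.frame `k`, `criterion`, `r_groupA`,
#'   `r_groupB`) and `k_selected`.
#' @export
dimension_sweep <- function(trials, displays, rts, labels, k_range,
                            weights = c(0.5, 0.5), n_init = 3,
                            n_restarts = 3, tol = 0.05, seed = 1) {
  d <- dissimilarity_from_trials(trials)
  n <- nrow(d)
  if (any(k_range < 1 | k_range > n - 1)) stop("k_range must lie in [1, n-1]")
  rows <- lapply(k_range, function(k) {
    emb <- embed_mds(d, k, n_init = n_init, seed = seed)
    resp <- build_display_responses(emb, displays, w_target = weights[1],
                                    w_distractor = weights[2])
    cv <- loocv_fit(resp, displays, rts, labels, n_restarts = n_restarts,
                    seed = seed)
    data.frame(k = k, criterion = abs(cv$r_groupA) + abs(cv$r_groupB),
               r_groupA = cv$r_groupA, r_groupB = cv$r_groupB)
  })
  tab <- do.call(rbind, rows)
  k_selected <- tab$k[which(tab$criterion >= max(tab$criterion) - tol)[1]]
  list(table = tab, k_selected = k_selected)
}
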