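# Visual homogeneity model: distance-to-center decision variable, the
# opposite-sign correlation objective, multi-start constrained center fit,
# leave-one-image-out cross-validation, the summation-weight sweep, and
# group summaries.

#' Visual homogeneity of display responses
#'
#' Euclidean distance of each display's response vector to a center point.
#'
#' @param responses `n_displays x k` response matrix (see
#'   [build_display_responses()]).
#' @param center k-vector.
#' @return named non-negative per-display vector.
#' @export
visual_homogeneity <- function(responses, center) {
  responses <- as.matrix(responses)
  if (length(center) != ncol(responses)) {
    stop("center dimensionality does not match responses")
  }
  sqrt(rowSums(sweep(responses, 2, center)^2))
}

# correlations of VH with RT in the two groups; NA where degenerate
obj_components <- function(center, responses, rts, ga, gb) {
  vh <- sqrt(rowSums(sweep(responses, 2, center)^2))
  list(vh = vh,
       r_groupA = fast_cor(vh[ga], rts[ga]),
       r_groupB = fast_cor(vh[gb], rts[gb]))
}

#' Opposite-sign correlation objective
#'
#' `r_groupA - r_groupB`, where `r_groupA` is the Pearson correlation of VH
#' with RT over group-A displays (target-present / asymmetric) and
#' `r_groupB` over group-B displays (target-absent / symmetric). The fitted
#' center maximizes this; its ceiling is 2 (`r_A = 1`, `r_B = -1`).
#'
#' @param center candidate center.
#' @param responses display response matrix.
#' @param rts per-display mean RTs (seconds).
#' @param labels per-display decision labels (see [vh_group()]).
#' @param method `"pearson"` or `"spearman"`.
#' @return the objective value, with attributes `r_groupA` and `r_groupB`.
#' @export
vh_objective <- function(center, responses, rts, labels,
                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  g <- vh_group(labels)
  ga <- which(g == "A")
  gb <- which(g == "B")
  if (length(ga) < 3 || length(gb) < 3) stop("need >= 3 displays per group")
  for (nm in c("A", "B")) {
    idx <- if (nm == "A") ga else gb
    if (sd(rts[idx]) == 0) {
      stop("undefined correlation: zero RT variance in group ", nm)
    }
  }
  vh <- visual_homogeneity(responses, center)
  if (method == "spearman") {
    rA <- fast_cor(rank(vh[ga]), rank(rts[ga]))
    rB <- fast_cor(rank(vh[gb]), rank(rts[gb]))
  } else {
    rA <- fast_cor(vh[ga], rts[ga])
    rB <- fast_cor(vh[gb], rts[gb])
  }
  if (is.na(rA)) stop("undefined correlation: zero VH variance in group A")
  if (is.na(rB)) stop("undefined correlation: zero VH variance in group B")
  structure(rA - rB, r_groupA = rA, r_groupB = rB)
}

# default box constraints: embedding/response bounding box expanded by
# `expand` of its width per dimension (width 0 -> expand by 1 unit)
default_bounds <- function(responses, expand = 0.5) {
  lo <- apply(responses, 2, min)
  hi <- apply(responses, 2, max)
  w <- pmax(hi - lo, 1)
  rbind(lower = lo - expand * w, upper = hi + expand * w)
}

#' Fit the visual homogeneity center
#'
#' Maximizes the opposite-sign correlation objective over center positions
#' inside box bounds, using derivative-free (Nelder-Mead; Brent in 1-D)
#' local search from the response centroid plus `n_restarts - 1` uniform
#' random starts within the bounds. All restart optima are reported so the
#' stability of the optimum is auditable. Among ties the smallest-norm
#' center is reported, and any center component orthogonal to the affine
#' span of the responses is projected out before reporting.
#'
#' @param responses display response matrix.
#' @param rts per-display mean RTs (seconds).
#' @param labels per-display decision labels.
#' @param bounds `2 x k` matrix (rows lower/upper); default is the response
#'   bounding box expanded by 50% per dimension.
#' @param n_restarts number of optimizer starts (>= 1).
#' @param seed seed for the random starts.
#' @param init optional matrix of additional start points (rows).
#' @param method correlation type.
#' @param maxit optimizer iteration cap per start.
#' @return object of class `vh_fit`: `center`, `vh` (per display),
#'   `r_groupA`, `r_groupB`, `objective`, `restarts` (per-restart
#'   objectives and convergence codes), `converged`, `bounds`, `labels`,
#'   `rts`, `seed`.
#' @export
fit_center <- function(responses, rts, labels, bounds = NULL,
                       n_restarts = 20, seed = 1, init = NULL,
                       method = c("pearson", "spearman"), maxit = 1000) {
  method <- match.arg(method)
  responses <- as.matrix(responses)
  k <- ncol(responses)
  g <- vh_group(labels)
  ga <- which(g == "A")
  gb <- which(g == "B")
  if (length(ga) < 3 || length(gb) < 3) stop("need >= 3 displays per group")
  if (sd(rts[ga]) == 0 || sd(rts[gb]) == 0) {
    stop("zero RT variance in a group; objective undefined")
  }
  bounds <- bounds %||% default_bounds(responses)
  if (!all(is.finite(bounds))) stop("bounds must be finite")
  lo <- bounds[1, ]
  hi <- bounds[2, ]
  clamp <- function(x) pmin(pmax(x, lo), hi)
  use_rank <- method == "spearman"
  rtsA <- if (use_rank) rank(rts[ga]) else rts[ga]
  rtsB <- if (use_rank) rank(rts[gb]) else rts[gb]
  fn <- function(center) {
    center <- clamp(center)
    vh <- sqrt(rowSums(sweep(responses, 2, center)^2))
    vA <- if (use_rank) rank(vh[ga]) else vh[ga]
    vB <- if (use_rank) rank(vh[gb]) else vh[gb]
    rA <- fast_cor(vA, rtsA)
    rB <- fast_cor(vB, rtsB)
    if (is.na(rA) || is.na(rB)) return(-4)
    rA - rB
  }
  starts <- rbind(colMeans(responses), init)
  if (n_restarts > nrow(starts)) {
    extra <- with_seed(sub_seed(seed, "fit_center"), {
      matrix(runif((n_restarts - nrow(starts)) * k, rep(lo, each = n_restarts - nrow(starts)),
                   rep(hi, each = n_restarts - nrow(starts))),
             ncol = k)
    })
    starts <- rbind(starts, extra)
  }
  res <- lapply(seq_len(nrow(starts)), function(s) {
    p0 <- clamp(starts[s, ])
    if (k == 1) {
      o <- optimize(function(x) fn(x), lower = lo, upper = hi, maximum = TRUE,
                    tol = 1e-10)
      list(par = clamp(o$maximum), value = o$objective, convergence = 0L)
    } else {
      o <- optim(p0, fn, method = "Nelder-Mead",
                 control = list(fnscale = -1, maxit = maxit, reltol = 1e-12))
      list(par = clamp(o$par), value = o$value, convergence = o$convergence)
    }
  })
  vals <- vapply(res, `[[`, numeric(1), "value")
  if (all(vals <= -4)) stop("all restarts degenerate; per-restart values: ",
                            paste(format(vals), collapse = ", "))
  best_val <- max(vals)
  ties <- which(vals >= best_val - 1e-9)
  norms <- vapply(ties, function(s) sqrt(sum(res[[s]]$par^2)), numeric(1))
  best <- res[[ties[which.min(norms)]]]
  # project out components orthogonal to the affine span of the responses
  mu <- colMeans(responses)
  rc <- sweep(responses, 2, mu)
  sv <- svd(rc)
  keep <- sv$d > max(sv$d[1], 1) * 1e-10
  center <- if (any(keep)) {
    v <- sv$v[, keep, drop = FALSE]
    as.numeric(mu + v %*% crossprod(v, best$par - mu))
  } else best$par
  comp <- obj_components(center, responses, rts, ga, gb)
  restarts <- data.frame(restart = seq_along(res),
                         objective = vals,
                         convergence = vapply(res, `[[`, integer(1),
                                              "convergence"))
  structure(
    list(center = setNames(center, colnames(responses)),
         vh = comp$vh,
         r_groupA = comp$r_groupA,
         r_groupB = comp$r_groupB,
         objective = comp$r_groupA - comp$r_groupB,
         restarts = restarts,
         converged = any(restarts$convergence == 0),
         bounds = bounds, labels = labels, rts = rts, seed = seed),
    class = "vh_fit")
}

#' @export
print.vh_fit <- function(x, ...) {
  cat(sprintf(
    "vh_fit: objective %.4f (r_groupA %.3f, r_groupB %.3f) over %d restarts\n",
    x$objective, x$r_groupA, x$r_groupB, nrow(x$restarts)))
  invisible(x)
}

#' Leave-one-image-out cross-validated visual homogeneity
#'
#' For each object: refit the center with every display involving that
#' object removed, then compute VH of the held-out displays under the
#' refitted center. Display predictions arising in more than one fold
#' (oddball arrays involve two objects) are averaged. Group correlations
#' are reported on the assembled cross-validated VH values.
#'
#' @param responses display response matrix.
#' @param displays display table (used to map displays to objects).
#' @param rts,labels per-display RTs and decision labels.
#' @param n_restarts restarts per fold (each fold also starts from the
#'   full-data fitted center).
#' @param seed seed.
#' @param bounds optional box constraints (shared across folds).
#' @return list: `vh_loocv` (per display), `r_groupA`, `r_groupB`,
#'   `folds` (per-object status), `full_fit`.
#' @export
loocv_fit <- function(responses, displays, rts, labels, n_restarts = 5,
                      seed = 1, bounds = NULL) {
  responses <- as.matrix(responses)
  bounds <- bounds %||% default_bounds(responses)
  full <- fit_center(responses, rts, labels, bounds = bounds,
                     n_restarts = n_restarts, seed = seed)
  objects <- unique(c(displays$target_id,
                      displays$distractor_id[!is.na(displays$distractor_id)]))
  pred_sum <- setNames(numeric(nrow(displays)), displays$display_id)
  pred_n <- setNames(integer(nrow(displays)), displays$display_id)
  folds <- data.frame(object = objects, n_test = NA_integer_,
                      skipped = FALSE, stringsAsFactors = FALSE)
  for (oi in seq_along(objects)) {
    obj <- objects[oi]
    test <- which(displays$target_id == obj |
                    (!is.na(displays$distractor_id) &
                       displays$distractor_id == obj))
    train <- setdiff(seq_len(nrow(displays)), test)
    gtr <- vh_group(labels[train])
    folds$n_test[oi] <- length(test)
    if (sum(gtr == "A") < 3 || sum(gtr == "B") < 3 ||
        sd(rts[train][gtr == "A"]) == 0 || sd(rts[train][gtr == "B"]) == 0) {
      warning("fold for object ", obj, " degenerate; skipped")
      folds$skipped[oi] <- TRUE
      next
    }
    f <- fit_center(responses[train, , drop = FALSE], rts[train],
                    labels[train], bounds = bounds,
                    n_restarts = n_restarts,
                    seed = sub_seed(seed, paste0("fold", oi)),
                    init = matrix(full$center, 1))
    vh_test <- visual_homogeneity(responses[test, , drop = FALSE], f$center)
    pred_sum[test] <- pred_sum[test] + vh_test
    pred_n[test] <- pred_n[test] + 1L
  }
  has <- pred_n > 0
  vh_loocv <- ifelse(has, pred_sum / pmax(pred_n, 1L), NA_real_)
  g <- vh_group(labels)
  rA <- fast_cor(vh_loocv[has & g == "A"], rts[has & g == "A"])
  rB <- fast_cor(vh_loocv[has & g == "B"], rts[has & g == "B"])
  list(vh_loocv = vh_loocv, r_groupA = rA, r_groupB = rB, folds = folds,
       full_fit = full)
}

#' Sweep the target/distractor summation weight
#'
#' Rebuilds oddball-array responses for each target weight `w` (distractor
#' weight `1 - w`), refits the center, and records the objective; reports
#' the argmax.
#'
#' @param emb embedding.
#' @param displays display table.
#' @param rts,labels per-display RTs and decision labels.
#' @param w_grid target weights in `[0, 1]` (endpoints included by the
#'   default grid).
#' @param n_restarts restarts per fit.
#' @param seed seed.
#' @param bounds optional shared box constraints.
#' @return list: `table` (data.frame `w_target`, `objective`, `r_groupA`,
#'   `r_groupB`), `w_best`.
#' @export
weight_sweep <- function(emb, displays, rts, labels,
                         w_grid = seq(0, 1, by = 0.025), n_restarts = 5,
                         seed = 1, bounds = NULL) {
  if (any(w_grid < 0 | w_grid > 1)) stop("w_grid must lie in [0, 1]")
  coords <- emb_coords(emb)
  bounds <- bounds %||% default_bounds(coords)
  rows <- lapply(w_grid, function(w) {
    resp <- build_display_responses(coords, displays, w_target = w,
                                    w_distractor = 1 - w)
    f <- fit_center(resp, rts, labels, bounds = bounds,
                    n_restarts = n_restarts, seed = seed)
    data.frame(w_target = w, objective = f$objective,
               r_groupA = f$r_groupA, r_groupB = f$r_groupB)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, w_best = tab$w_target[which.max(tab$objective)])
}

#' Per-group visual homogeneity summary
#'
#' Group means and standard deviations of VH plus a two-sided Wilcoxon
#' rank-sum test comparing the two groups (exact when group sizes permit
#' and there are no ties).
#'
#' @param fit a `vh_fit`, or a numeric VH vector.
#' @param labels decision labels (taken from the fit when omitted).
#' @return list: `summary` (data.frame `group`, `n`, `mean`, `sd`),
#'   `p_value`.
#' @export
vh_group_summary <- function(fit, labels = NULL) {
  vh <- if (inherits(fit, "vh_fit")) fit$vh else as.numeric(fit)
  labels <- labels %||% (if (inherits(fit, "vh_fit")) fit$labels else
    stop("labels required"))
  g <- vh_group(labels)
  if (any(table(g) == 0)) stop("both groups must be non-empty")
  s <- data.frame(
    group = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(vh, g, mean)),
    sd = as.numeric(tapply(vh, g, sd)))
  if (any(s$n < 2)) warning("group with fewer than 2 displays: sd undefined")
  p <- suppressWarnings(
    wilcox.test(vh[g == "A"], vh[g == "B"], alternative = "two.sided"))$p.value
  list(summary = s, p_value = p)
}
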