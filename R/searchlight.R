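# Searchlight procedures on masked voxel grids: mean-activation vs VH (or
# RT) correlation maps with group-wise z-scoring, local neural-dissimilarity
# vs perceptual-dissimilarity maps, cluster extraction, and region-level
# correlations with participant bootstrap.

#' Masked per-condition voxel dataset
#'
#' @param betas 4-D numeric array `(x, y, z, condition)` of GLM beta
#'   estimates (NA allowed outside the mask).
#' @param mask logical 3-D array.
#' @param conditions ordered condition (display) id vector, one per fourth
#'   dimension slice.
#' @param voxel_size voxel dimensions in mm (metadata only).
#' @param subject_betas optional list of per-subject 4-D beta arrays
#'   (required for the region bootstrap).
#' @return object of class `vh_voxel_dataset`.
#' @export
voxel_dataset <- function(betas, mask, conditions, voxel_size = c(3, 3, 3),
                          subject_betas = NULL) {
  betas <- as.array(betas)
  if (length(dim(betas)) != 4) stop("betas must be a 4-D array")
  if (!all(dim(betas)[1:3] == dim(mask))) stop("mask does not match betas")
  if (dim(betas)[4] != length(conditions)) {
    stop("condition list does not match betas")
  }
  flat <- matrix(betas, prod(dim(mask)), length(conditions))
  if (!all(is.finite(flat[as.logical(mask), ]))) {
    stop("betas must be finite inside the mask")
  }
  structure(list(betas = betas, mask = array(as.logical(mask), dim(mask)),
                 conditions = as.character(conditions),
                 voxel_size = voxel_size, subject_betas = subject_betas),
            class = "vh_voxel_dataset")
}

#' @export
print.vh_voxel_dataset <- function(x, ...) {
  cat(sprintf("vh_voxel_dataset: %s grid, %d in-mask voxels, %d conditions%s\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask),
              length(x$conditions),
              if (is.null(x$subject_betas)) "" else
                sprintf(", %d subjects", length(x$subject_betas))))
  invisible(x)
}

#' In-mask indices of a voxel's 3x3x3 neighborhood
#'
#' All in-mask voxels within the cube centered on `voxel` (center
#' included), clipped at grid edges; at most 27.
#'
#' @param mask logical 3-D array.
#' @param voxel integer length-3 voxel coordinate (1-based).
#' @return integer vector of linear indices into the grid.
#' @export
neighborhood_indices <- function(mask, voxel) {
  d <- dim(mask)
  voxel <- as.integer(voxel)
  if (length(voxel) != 3 || any(voxel < 1) || any(voxel > d)) {
    stop("voxel outside the grid")
  }
  if (!mask[voxel[1], voxel[2], voxel[3]]) stop("voxel outside the mask")
  rng <- lapply(1:3, function(i) max(1L, voxel[i] - 1L):min(d[i], voxel[i] + 1L))
  cube <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  lin <- cube[, 1] + (cube[, 2] - 1L) * d[1] + (cube[, 3] - 1L) * d[1] * d[2]
  lin[mask[lin]]
}

# zero-padded shift of the first three dims of a 3-D or 4-D array
shift3d <- function(a, s) {
  d <- dim(a)
  out <- array(0, d)
  dst <- src <- vector("list", 3)
  for (i in 1:3) {
    from <- max(1L, 1L + s[i])
    to <- min(d[i], d[i] + s[i])
    if (from > to) return(out)
    dst[[i]] <- from:to
    src[[i]] <- dst[[i]] - s[i]
  }
  if (length(d) == 3) {
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  } else {
    out[dst[[1]], dst[[2]], dst[[3]], ] <-
      a[src[[1]], src[[2]], src[[3]], , drop = FALSE]
  }
  out
}

# neighborhood (3x3x3, mask-clipped) mean activations for all in-mask
# voxels: returns list(x = n_mask x n_cond matrix, mask_lin, nb_count)
neighborhood_means <- function(betas, mask) {
  m <- array(as.numeric(mask), dim(mask))
  b0 <- betas
  b0[is.na(b0)] <- 0
  flatdim <- c(prod(dim(mask)), dim(betas)[4])
  b0 <- b0 * array(m, dim(betas))  # zero outside mask
  num <- array(0, dim(betas))
  den <- array(0, dim(mask))
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    s <- c(sx, sy, sz)
    num <- num + shift3d(b0, s)
    den <- den + shift3d(m, s)
  }
  mask_lin <- which(as.logical(mask))
  nf <- matrix(num, flatdim[1], flatdim[2])[mask_lin, , drop = FALSE]
  cnt <- as.numeric(den)[mask_lin]
  list(x = nf / cnt, mask_lin = mask_lin, nb_count = cnt)
}

#' Group-wise z-scoring
#'
#' Within each label group, subtracts the group mean and divides by the
#' group sample standard deviation, so each group ends with mean 0 and
#' sd 1. Used to remove overall activation-level differences between the
#' two decision groups before correlating with VH.
#'
#' @param values per-condition numeric vector.
#' @param labels per-condition group labels.
#' @return z-scored vector; a group with zero variance returns NaN for its
#'   entries, with a warning.
#' @export
zscore_by_group <- function(values, labels) {
  out <- as.numeric(values)
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) < 2) stop("group ", g, " has fewer than 2 conditions")
    s <- sd(out[idx])
    if (s == 0) {
      warning("zero within-group variance in group ", g)
      out[idx] <- NaN
    } else {
      out[idx] <- (out[idx] - mean(out[idx])) / s
    }
  }
  out
}

# shared engine for activation-predictor searchlight maps
activation_map <- function(data, predictor, labels, zscore, kind,
                           cond_keep = NULL) {
  stopifnot(inherits(data, "vh_voxel_dataset"))
  nc <- length(data$conditions)
  if (length(predictor) != nc) stop("predictor does not align with conditions")
  if (!is.null(names(predictor)) &&
      !identical(names(predictor), data$conditions)) {
    stop("predictor names do not match the dataset conditions")
  }
  cond_keep <- cond_keep %||% seq_len(nc)
  nb <- neighborhood_means(data$betas, data$mask)
  x <- nb$x[, cond_keep, drop = FALSE]
  pred <- predictor[cond_keep]
  labs <- labels[cond_keep]
  if (zscore) {
    if (is.null(labs)) stop("labels required for group z-scoring")
    pred <- zscore_by_group(pred, labs)
    for (g in unique(labs)) {
      idx <- which(labs == g)
      mu <- rowMeans(x[, idx, drop = FALSE])
      s <- sqrt(rowSums((x[, idx, drop = FALSE] - mu)^2) / (length(idx) - 1))
      s[s == 0] <- NA_real_
      x[, idx] <- (x[, idx, drop = FALSE] - mu) / s
    }
  }
  # rowwise Pearson r with pred
  xc <- x - rowMeans(x)
  pc <- pred - mean(pred)
  denom <- sqrt(rowSums(xc^2)) * sqrt(sum(pc^2))
  r <- as.numeric(xc %*% pc) / denom
  r[!is.finite(r)] <- NaN
  vals <- array(NaN, dim(data$mask))
  vals[nb$mask_lin] <- r
  structure(vals, kind = kind, n_degenerate = sum(is.nan(r)),
            class = "vh_searchlight_map")
}

#' Searchlight map: neighborhood mean activation vs visual homogeneity
#'
#' Per in-mask voxel: mean activation over the mask-clipped 3x3x3
#' neighborhood per condition, z-scored separately within each decision
#' group; VH z-scored the same way; Pearson correlation across conditions
#' stored at the voxel (NaN outside the mask or at degenerate voxels).
#'
#' @param data a [voxel_dataset()] (betas already averaged across subjects).
#' @param vh per-condition VH values (aligned with `data$conditions`).
#' @param labels per-condition decision labels.
#' @param zscore apply group-wise z-scoring (default TRUE).
#' @return 3-D array of class `vh_searchlight_map`.
#' @export
vh_correlation_map <- function(data, vh, labels = NULL,
                               zscore = !is.null(labels)) {
  activation_map(data, vh, labels, zscore, kind = "vh_correlation")
}

#' Searchlight map: neighborhood mean activation vs response time
#'
#' As [vh_correlation_map()] with RTs as the predictor. `scope` restricts
#' the correlation to one decision group.
#'
#' @param data a [voxel_dataset()].
#' @param rts per-condition mean RTs.
#' @param labels per-condition decision labels.
#' @param scope `"all"`, `"groupA"`, or `"groupB"`.
#' @param zscore apply group-wise z-scoring (default TRUE; within a single
#'   `scope` group this is plain z-scoring).
#' @return 3-D array of class `vh_searchlight_map`.
#' @export
rt_correlation_map <- function(data, rts, labels = NULL,
                               scope = c("all", "groupA", "groupB"),
                               zscore = !is.null(labels)) {
  scope <- match.arg(scope)
  keep <- if (scope == "all") NULL else {
    if (is.null(labels)) stop("labels required to restrict scope")
    which(vh_group(labels) == sub("group", "", scope))
  }
  activation_map(data, rts, labels, zscore, kind = "rt_correlation",
                 cond_keep = keep)
}

#' Searchlight map: local neural dissimilarity vs perceptual dissimilarity
#'
#' Per in-mask voxel, the response vector to each object is the activation
#' pattern over the voxel's mask-clipped 3x3x3 neighborhood (up to 27
#' dimensions; fewer at edges, recorded in attribute `"nb_dim"`); all
#' pairwise Euclidean distances between object response vectors are
#' correlated (Pearson) with the corresponding perceptual dissimilarities.
#'
#' @param data a [voxel_dataset()] whose conditions are the single-object
#'   (target-absent) displays named by the objects of `perceptual_d`.
#' @param perceptual_d symmetric object dissimilarity matrix (1/seconds).
#' @return 3-D array of class `vh_searchlight_map`.
#' @export
rdm_correlation_map <- function(data, perceptual_d) {
  stopifnot(inherits(data, "vh_voxel_dataset"))
  objs <- rownames(perceptual_d)
  if (length(objs) < 3) stop("need at least 3 objects")
  ci <- match(objs, data$conditions)
  if (anyNA(ci)) {
    stop("dataset conditions do not cover the objects of perceptual_d")
  }
  pvec <- perceptual_d[lower.tri(perceptual_d)]
  d <- dim(data$mask)
  flat <- matrix(data$betas, prod(d), dim(data$betas)[4])[, ci, drop = FALSE]
  mask_lin <- which(as.logical(data$mask))
  coords <- arrayInd(mask_lin, d)
  vals <- array(NaN, d)
  nb_dim <- array(NA_integer_, d)
  for (v in seq_along(mask_lin)) {
    nbr <- neighborhood_indices(data$mask, coords[v, ])
    nb_dim[mask_lin[v]] <- length(nbr)
    resp <- flat[nbr, , drop = FALSE]      # nb_dim x n_obj
    nd <- dist(t(resp))
    r <- fast_cor(as.numeric(nd), pvec)
    vals[mask_lin[v]] <- if (is.na(r)) NaN else r
  }
  structure(vals, kind = "rdm_correlation", nb_dim = nb_dim,
            class = "vh_searchlight_map")
}

#' Extract suprathreshold clusters from a searchlight map
#'
#' 26-connected clusters of voxels with map value above `threshold` and
#' size at least `min_cluster`.
#'
#' @param map a `vh_searchlight_map` (or 3-D array).
#' @param threshold correlation threshold in (0, 1).
#' @param min_cluster minimum cluster size in voxels.
#' @return list of clusters (largest first), each with `voxels` (linear
#'   indices), `size`, and `centroid` (1-based grid coordinates); empty
#'   list when nothing survives.
#' @export
define_region <- function(map, threshold, min_cluster = 1) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  vals <- unclass(map)
  d <- dim(vals)
  sup <- which(!is.na(vals) & vals > threshold)
  if (length(sup) == 0) return(list())
  coords <- arrayInd(sup, d)
  # half the 26-neighborhood offsets; the other half follows by symmetry
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  edges <- NULL
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[o, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] + (nb[ok, 3] - 1) * d[1] * d[2]
    hit <- match(lin, sup)
    src <- which(ok)[!is.na(hit)]
    if (length(src)) edges <- rbind(edges, cbind(src, hit[!is.na(hit)]))
  }
  g <- igraph::make_empty_graph(n = length(sup), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  clusters <- lapply(split(seq_along(sup), memb), function(idx) {
    list(voxels = sup[idx], size = length(idx),
         centroid = colMeans(coords[idx, , drop = FALSE]))
  })
  clusters <- clusters[vapply(clusters, `[[`, integer(1), "size") >=
                         min_cluster]
  clusters[order(-vapply(clusters, `[[`, integer(1), "size"))]
}

#' Region-level activation correlation with participant bootstrap
#'
#' Correlation between the region-mean activation per condition (z-scored
#' by group when labels are supplied) and a predictor (VH or RT), with a
#' bootstrap standard deviation over participants resampled with
#' replacement and a one-sided bootstrap p (fraction of resamples in which
#' the observed sign of the correlation is violated).
#'
#' @param data a [voxel_dataset()]; `subject_betas` must be present (length
#'   >= 2) for the bootstrap, otherwise the bootstrap is skipped with a
#'   warning.
#' @param region integer vector of linear voxel indices (e.g. a
#'   [define_region()] cluster's `voxels`).
#' @param predictor per-condition VH or RT values.
#' @param labels per-condition decision labels (enables group z-scoring).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed seed for the bootstrap.
#' @return list: `r`, `boot_sd`, `boot_p`, `n_boot`.
#' @export
region_mean_correlation <- function(data, region, predictor, labels = NULL,
                                    n_boot = 10000, seed = 1) {
  stopifnot(inherits(data, "vh_voxel_dataset"))
  region <- as.integer(region)
  if (length(region) == 0) stop("region is empty")
  nc <- length(data$conditions)
  flat <- matrix(data$betas, prod(dim(data$mask)), nc)
  prep <- function(v) if (is.null(labels)) v else zscore_by_group(v, labels)
  pred <- prep(as.numeric(predictor))
  mean_act <- colMeans(flat[region, , drop = FALSE])
  r_obs <- fast_cor(prep(mean_act), pred)
  if (is.null(data$subject_betas) || length(data$subject_betas) < 2) {
    warning("fewer than 2 subjects: bootstrap skipped")
    return(list(r = r_obs, boot_sd = NA_real_, boot_p = NA_real_,
                n_boot = 0L))
  }
  ns <- length(data$subject_betas)
  s_mat <- t(vapply(data$subject_betas, function(b) {
    colMeans(matrix(b, prod(dim(data$mask)), nc)[region, , drop = FALSE])
  }, numeric(nc)))
  rs <- with_seed(sub_seed(seed, "bootstrap"), {
    vapply(seq_len(n_boot), function(i) {
      pick <- sample.int(ns, ns, replace = TRUE)
      fast_cor(prep(colMeans(s_mat[pick, , drop = FALSE])), pred)
    }, numeric(1))
  })
  rs_ok <- rs[!is.na(rs)]
  boot_p <- if (r_obs >= 0) mean(rs_ok <= 0) else mean(rs_ok >= 0)
  list(r = r_obs, boot_sd = sd(rs_ok), boot_p = boot_p, n_boot = n_boot)
}
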