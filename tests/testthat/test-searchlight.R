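# shared small planted dataset: 6x6x6 grid, 20 conditions, VH coded in one
# cuboid, RT in another
planted_dataset <- function(noise = 0, n_subjects = 1, seed = 1,
                            n_cond = 20) {
  gs <- c(6, 6, 6)
  set.seed(seed)
  vh <- setNames(sort(runif(n_cond, 0.2, 1.5)), sprintf("c%02d", 1:n_cond))
  labels <- rep(c("present", "absent"), each = n_cond / 2)
  rt <- 1.8 - 0.5 * abs(vh - stats::median(vh)) +
    rnorm(n_cond, sd = 0.02 * (noise > 0))
  names(rt) <- names(vh)
  vh_reg <- cuboid_indices(gs, 2:3, 2:3, 2:3)
  rt_reg <- cuboid_indices(gs, 5:6, 5:6, 5:6)
  layout <- voxel_layout(gs, vh_region = vh_reg, rt_region = rt_reg,
                         noise_sigma = noise)
  vox <- gen_voxel_data(layout, vh, rt, n_subjects = n_subjects, seed = seed)
  list(vox = vox, vh = vh, rt = rt, labels = labels, layout = layout,
       vh_reg = vh_reg, rt_reg = rt_reg, gs = gs)
}

test_that("neighborhood indices clip to grid and mask", {
  mask <- array(TRUE, c(5, 5, 5))
  expect_length(neighborhood_indices(mask, c(3, 3, 3)), 27)
  expect_length(neighborhood_indices(mask, c(1, 1, 1)), 8)
  expect_length(neighborhood_indices(mask, c(1, 3, 3)), 18)

  half <- mask
  half[, , 4:5] <- FALSE  # mask out the upper z half
  nb <- neighborhood_indices(half, c(3, 3, 3))
  expect_length(nb, 18)   # cube intersected with the mask
  expect_true(all(half[nb]))

  expect_error(neighborhood_indices(mask, c(0, 1, 1)), "grid")
  expect_error(neighborhood_indices(half, c(3, 3, 5)), "mask")
})

test_that("group z-scoring centers and scales each group exactly", {
  expect_equal(zscore_by_group(c(1, 2, 3), rep("g", 3)), c(-1, 0, 1))

  v <- c(100, 103, 101, 0.1, 0.5, 0.2, 0.9)
  lab <- rep(c("A", "B"), c(3, 4))
  z <- zscore_by_group(v, lab)
  for (g in c("A", "B")) {
    expect_lt(abs(mean(z[lab == g])), 1e-12)
    expect_lt(abs(sd(z[lab == g]) - 1), 1e-12)
  }
  # idempotence
  expect_equal(zscore_by_group(z, lab), z, tolerance = 1e-12)
  expect_warning(z0 <- zscore_by_group(c(1, 1, 2, 3), rep(c("A", "B"), each = 2)),
                 "zero within-group variance")
  expect_true(all(is.nan(z0[1:2])))
})

test_that("noiseless planted regions give perfect map correlations", {
  pd <- planted_dataset(noise = 0)
  vmap <- vh_correlation_map(pd$vox, pd$vh, pd$labels)
  # voxels whose full 3x3x3 neighborhood lies inside the VH region code VH
  # perfectly; use the region's inner corner voxel (2:3 cube -> no interior,
  # so test a voxel whose neighborhood is region-dominated via r close to 1)
  expect_gt(vmap[2, 2, 2], 0.99)
  rmap <- rt_correlation_map(pd$vox, pd$rt, pd$labels)
  expect_gt(rmap[5, 5, 5], 0.99)
  expect_true(all(abs(unclass(vmap)) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("background voxels behave like the null distribution", {
  pd <- planted_dataset(noise = 0.5, seed = 3)
  vmap <- vh_correlation_map(pd$vox, pd$vh, pd$labels)
  bg <- setdiff(which(pd$layout$mask), c(pd$vh_reg, pd$rt_reg))
  # exclude neighbors of the planted regions (their neighborhoods overlap)
  near <- unique(unlist(lapply(c(pd$vh_reg, pd$rt_reg), function(v) {
    neighborhood_indices(pd$layout$mask, arrayInd(v, pd$gs))
  })))
  bg <- setdiff(bg, near)
  rs <- unclass(vmap)[bg]
  # Monte-Carlo null for |r| with 20 conditions after group z-scoring
  set.seed(4)
  null_r <- replicate(2000, {
    a <- zscore_by_group(rnorm(20), pd$labels)
    cor(a, zscore_by_group(pd$vh, pd$labels))
  })
  expect_lt(abs(mean(rs)), 3 * sd(null_r) / sqrt(length(rs)) + 3 * sd(rs) / sqrt(length(rs)))
  expect_lt(abs(sd(rs) - sd(null_r)), 0.1)
})

test_that("rt map scope restricts conditions to one group", {
  pd <- planted_dataset(noise = 0)
  mapA <- rt_correlation_map(pd$vox, pd$rt, pd$labels, scope = "groupA")
  # within group A alone the RT voxel still codes RT perfectly
  expect_gt(mapA[5, 5, 5], 0.99)
  expect_error(rt_correlation_map(pd$vox, pd$rt, scope = "groupA"),
               "labels")
})

test_that("rdm map is exact when neighborhood patterns mirror the embedding", {
  # single fully-masked 3x3x3 grid: the center voxel's neighborhood is the
  # whole grid, so planting coordinates as activations makes the neural
  # RDM equal the embedding RDM
  emb <- toy_embedding(6, 4, seed = 5)
  gs <- c(3, 3, 3)
  betas <- array(0, c(gs, 6))
  for (i in 1:6) {
    v <- numeric(27)
    v[1:4] <- emb[i, ]           # coordinates padded with zeros
    betas[, , , i] <- array(v, gs)
  }
  vox <- voxel_dataset(betas, array(TRUE, gs), rownames(emb))
  d <- as.matrix(dist(emb))
  dimnames(d) <- list(rownames(emb), rownames(emb))
  map <- rdm_correlation_map(vox, d)
  expect_equal(map[2, 2, 2], 1, tolerance = 1e-12)
  expect_equal(attr(map, "nb_dim")[2, 2, 2], 27L)
  expect_error(rdm_correlation_map(vox, d[1:2, 1:2]), "3 objects")
})

test_that("rdm map peaks inside a planted linear-readout region", {
  emb <- toy_embedding(8, 3, seed = 6)
  gs <- c(8, 8, 8)
  mask <- array(TRUE, gs)
  region <- cuboid_indices(gs, 3:5, 3:5, 3:5)
  set.seed(7)
  readout <- matrix(rnorm(length(region) * 3, sd = 1), length(region), 3)
  flat <- matrix(rnorm(prod(gs) * 8, sd = 0.35), prod(gs), 8)
  flat[region, ] <- flat[region, ] + readout %*% t(emb)
  vox <- voxel_dataset(array(flat, c(gs, 8)), mask, rownames(emb))
  d <- as.matrix(dist(emb))
  dimnames(d) <- list(rownames(emb), rownames(emb))
  map <- rdm_correlation_map(vox, d)
  peak <- which.max(unclass(map))
  expect_true(peak %in% region)
  expect_gt(mean(unclass(map)[region]), mean(unclass(map)[-region]))
})

test_that("define_region recovers planted clusters with 26-connectivity", {
  gs <- c(10, 10, 10)
  vals <- array(0.05, gs)
  blockA <- cuboid_indices(gs, 2:4, 2:4, 2:4)   # 27 voxels
  blockB <- cuboid_indices(gs, 7:9, 7:8, 7:9)   # 18 voxels
  vals[blockA] <- 0.9
  vals[blockB] <- 0.8
  regions <- define_region(vals, threshold = 0.5, min_cluster = 2)
  expect_length(regions, 2)
  expect_equal(regions[[1]]$size, 27)
  expect_equal(regions[[2]]$size, 18)
  expect_setequal(regions[[1]]$voxels, blockA)
  expect_equal(regions[[1]]$centroid, c(3, 3, 3))

  expect_length(define_region(vals, threshold = 0.95), 0)
  expect_error(define_region(vals, threshold = 1.5), "threshold")

  # diagonal touch merges under 26-connectivity
  vals2 <- array(0, c(4, 4, 4))
  vals2[1, 1, 1] <- 0.9
  vals2[2, 2, 2] <- 0.9
  expect_length(define_region(vals2, threshold = 0.5), 1)
})

test_that("region correlation is exact in the noiseless single-subject case", {
  pd <- planted_dataset(noise = 0)
  expect_warning(
    res <- region_mean_correlation(pd$vox, pd$vh_reg, pd$vh, pd$labels),
    "bootstrap skipped")
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_true(is.na(res$boot_sd))
})

test_that("bootstrap of identical subjects has zero spread", {
  pd <- planted_dataset(noise = 0)
  vox2 <- voxel_dataset(pd$vox$betas, pd$layout$mask, names(pd$vh),
                        subject_betas = list(pd$vox$betas, pd$vox$betas,
                                             pd$vox$betas))
  res <- region_mean_correlation(vox2, pd$vh_reg, pd$vh, pd$labels,
                                 n_boot = 200, seed = 1)
  expect_equal(res$boot_sd, 0, tolerance = 1e-12)
  expect_equal(res$r, 1, tolerance = 1e-12)
})

test_that("bootstrap sd tracks the true sampling sd of the region correlation", {
  n_subj <- 16
  make_r <- function(seed, n_boot = 0) {
    pd <- planted_dataset(noise = 1.5, n_subjects = n_subj, seed = seed)
    if (n_boot == 0) {
      suppressWarnings(region_mean_correlation(
        pd$vox, pd$vh_reg, pd$vh, pd$labels, n_boot = 10)$r)
    } else {
      region_mean_correlation(pd$vox, pd$vh_reg, pd$vh, pd$labels,
                              n_boot = n_boot, seed = seed)$boot_sd
    }
  }
  # truth: sd of the observed correlation across fresh datasets
  rs <- vapply(1:200, make_r, numeric(1))
  true_sd <- sd(rs)
  # bootstrap estimate, averaged over a handful of datasets to damp the
  # ~1/sqrt(2(n-1)) sampling error of a single bootstrap sd
  boot_sds <- vapply(1:25, function(s) make_r(300 + s, n_boot = 400),
                     numeric(1))
  expect_lt(abs(mean(boot_sds) - true_sd), 0.2 * true_sd)
})
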