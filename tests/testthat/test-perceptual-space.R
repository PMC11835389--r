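make_trials <- function(rt, correct = TRUE, participant = 1,
                        target = "a", distractor = "b") {
  data.frame(participant = participant, target_id = target,
             distractor_id = distractor, label = "search", rt = rt,
             correct = correct, stringsAsFactors = FALSE)
}

test_that("filter_trials applies the RT window and reports removals", {
  tr <- make_trials(c(0.25, 0.5, 3.5))
  out <- filter_trials(tr, 0.3, 3)
  expect_equal(out$rt, 0.5)
  expect_equal(attr(out, "removed_fraction"), 2 / 3)

  # all-in-bounds, all-correct input comes back unchanged
  tr2 <- make_trials(c(0.5, 1, 2))
  out2 <- filter_trials(tr2, 0.3, 3)
  attr(out2, "removed_fraction") <- NULL
  expect_identical(out2, tr2)

  expect_error(filter_trials(make_trials(10), 0.3, 3), "rt_window")
  expect_error(filter_trials(tr2, 3, 0.3), "min_rt")
})

test_that("filter_trials drops a participant's trials for low-accuracy objects", {
  # participant 1 is 70% correct on object A (as decision target), fine on B
  tr <- rbind(
    make_trials(rep(1, 10), correct = rep(c(TRUE, FALSE), c(7, 3)),
                participant = 1, target = "A", distractor = NA),
    make_trials(rep(1, 10), correct = TRUE, participant = 1, target = "B",
                distractor = NA),
    make_trials(rep(1, 10), correct = TRUE, participant = 2, target = "A",
                distractor = NA))
  out <- filter_trials(tr, 0.1, 3, min_accuracy = 0.8)
  expect_equal(sum(out$participant == 1 & out$target_id == "A"), 0)
  expect_equal(sum(out$participant == 1 & out$target_id == "B"), 10)
  expect_equal(sum(out$participant == 2 & out$target_id == "A"), 10)
})

test_that("dissimilarity pools both orderings and inverts the mean RT", {
  tr <- rbind(make_trials(1.0, target = "a", distractor = "b"),
              make_trials(1.5, target = "b", distractor = "a"),
              make_trials(c(2, 2), target = "a", distractor = "c"),
              make_trials(c(1, 1), target = "b", distractor = "c"))
  d <- dissimilarity_from_trials(tr)
  expect_equal(d["a", "b"], 1 / 1.25)  # mean(1.0, 1.5) = 1.25 s
  expect_equal(d["b", "a"], d["a", "b"])
  expect_equal(d["a", "c"], 0.5)
  expect_equal(diag(d), setNames(rep(0, 3), c("a", "b", "c")))

  # ordering does not matter when RTs match
  tr_rev <- rbind(make_trials(c(1.0, 1.5), target = "b", distractor = "a"),
                  make_trials(c(2, 2), target = "c", distractor = "a"),
                  make_trials(c(1, 1), target = "c", distractor = "b"))
  expect_equal(dissimilarity_from_trials(tr_rev), d)

  expect_error(
    dissimilarity_from_trials(tr, objects = c("a", "b", "c", "z")),
    "a-z")
})

test_that("noiseless generator round-trips to the exact ground-truth distances", {
  emb <- gen_embedding(8, 3, spread = 0.5, seed = 6, min_dist = 0.45)
  gt <- ground_truth(emb, search_noise_sigma = 0, seed = 6)
  tr <- gen_search_trials(gt, trials_per_pair = 2, n_participants = 2,
                          accuracy = 1)
  d <- dissimilarity_from_trials(tr)
  truth <- as.matrix(dist(emb))
  expect_equal(d[rownames(truth), colnames(truth)], truth,
               tolerance = 1e-12)
})

test_that("split-half consistency hits the analytic extremes", {
  pairs <- data.frame(t = c("a", "a", "b"), d = c("b", "c", "c"),
                      m = c(0.5, 1.0, 1.5))
  tr_for <- function(p, rts) {
    data.frame(participant = p, target_id = pairs$t, distractor_id = pairs$d,
               label = "search", rt = rts, correct = TRUE)
  }
  same <- rbind(tr_for(1, pairs$m), tr_for(2, pairs$m))
  expect_equal(as.numeric(split_half_consistency(same)), 1)
  # anti-correlated halves about the common mean
  anti <- rbind(tr_for(1, pairs$m), tr_for(2, rev(pairs$m)))
  expect_equal(as.numeric(split_half_consistency(anti)), -1)
  expect_error(split_half_consistency(tr_for(1, pairs$m)), "participants")
})

test_that("split-half consistency matches a Monte-Carlo oracle at study noise", {
  emb <- gen_embedding(10, 3, spread = 0.5, seed = 8, min_dist = 0.4)
  gt <- ground_truth(emb, search_noise_sigma = 0.1, seed = 8)
  obs <- as.numeric(split_half_consistency(
    gen_search_trials(gt, trials_per_pair = 2, n_participants = 16)))
  mc <- vapply(seq_len(300), function(i) {
    gti <- ground_truth(emb, search_noise_sigma = 0.1, seed = 10000 + i)
    as.numeric(split_half_consistency(
      gen_search_trials(gti, trials_per_pair = 2, n_participants = 16)))
  }, numeric(1))
  expect_lt(abs(obs - mean(mc)), 0.05)
})

test_that("embed_mds reproduces exactly embeddable configurations", {
  # 3 objects at mutual distance 1 -> equilateral triangle in the plane
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  e3 <- embed_mds(d3, 2, n_init = 2)
  expect_lt(e3$stress, 1e-6)
  expect_equal(as.numeric(dist(e3$coords)), rep(1, 3), tolerance = 1e-6)
  expect_true(is.na(e3$fit_r))  # zero variance in d, flagged
  expect_match(e3$fit_r_note, "zero variance")

  # 4 collinear points embed exactly in one dimension
  x <- c(0, 1, 3, 6)
  d4 <- as.matrix(dist(x))
  dimnames(d4) <- list(letters[1:4], letters[1:4])
  e4 <- embed_mds(d4, 1, n_init = 2)
  expect_lt(e4$stress, 1e-6)

  # distances from a random 5-D point set are recovered at r >= 0.999
  set.seed(13)
  pts <- matrix(rnorm(60), 12, 5)
  d5 <- as.matrix(dist(pts))
  dimnames(d5) <- list(sprintf("p%d", 1:12), sprintf("p%d", 1:12))
  e5 <- embed_mds(d5, 5, n_init = 3)
  expect_gte(e5$fit_r, 0.999)

  expect_error(embed_mds(d3 * NA, 2), "finite")
  expect_error(embed_mds(d3, 3), "k must")
})

test_that("nonmetric criterion recovers monotone structure", {
  set.seed(14)
  pts <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(pts))^1.7  # monotone distortion
  dimnames(d) <- list(sprintf("p%d", 1:10), sprintf("p%d", 1:10))
  e <- embed_mds(d, 2, criterion = "nonmetric_stress", n_init = 3)
  expect_gte(cor(as.numeric(dist(e$coords)), as.numeric(as.dist(d)),
                 method = "spearman"), 0.99)
})

test_that("metric stress is non-increasing in embedding dimension", {
  set.seed(15)
  pts <- matrix(rnorm(40), 10, 4)
  d <- as.matrix(dist(pts)) + 0.05  # not exactly embeddable
  diag(d) <- 0
  dimnames(d) <- list(sprintf("p%d", 1:10), sprintf("p%d", 1:10))
  stresses <- vapply(1:5, function(k) embed_mds(d, k, n_init = 3)$stress,
                     numeric(1))
  expect_true(all(diff(stresses) <= 1e-9))
})

test_that("embedding orientation does not affect downstream VH quantities", {
  prob <- toy_decision_problem(n = 8, seed = 16)
  k <- ncol(prob$responses)
  set.seed(17)
  q <- qr.Q(qr(matrix(rnorm(k * k), k)))
  shift <- rnorm(k)
  resp_rot <- prob$responses %*% q + matrix(shift, nrow(prob$responses), k,
                                            byrow = TRUE)
  c_rot <- as.numeric(prob$center %*% q + shift)
  o1 <- vh_objective(prob$center, prob$responses, prob$rts, prob$labels)
  o2 <- vh_objective(c_rot, resp_rot, prob$rts, prob$labels)
  expect_lt(abs(o1 - o2), 1e-9)
})

test_that("dimension sweep recovers the generating dimensionality plateau", {
  st <- gen_study("search", n_objects = 10, k = 3, spread = 0.6,
                  min_dist = 0.5, max_radius = 1.5, n_participants = 4,
                  search_noise_sigma = 0, decision_noise_frac = 0,
                  decision_participants = 1, accuracy = 1, seed = 18)
  sw <- dimension_sweep(st$search_trials, st$displays, st$rts$rt,
                        st$labels, k_range = 1:4, n_init = 2,
                        n_restarts = 2, seed = 18)
  expect_equal(nrow(sw$table), 4)
  crit <- sw$table$criterion
  # criterion at the true k sits at (or within tolerance of) the plateau max
  expect_gte(crit[3], max(crit) - 0.05)
  expect_gt(crit[3], crit[1])

  sw1 <- dimension_sweep(st$search_trials, st$displays, st$rts$rt,
                         st$labels, k_range = 1, n_init = 2,
                         n_restarts = 2, seed = 18)
  expect_equal(nrow(sw1$table), 1)
  expect_equal(sw1$k_selected, 1)
})
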