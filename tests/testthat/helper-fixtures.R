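# Shared fixtures and independent oracle helpers, built in code.

# small labelled embedding with reproducible coordinates
toy_embedding <- function(n = 8, k = 2, seed = 1, spread = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * k), n, k) * spread
  rownames(x) <- sprintf("t%02d", seq_len(n))
  colnames(x) <- sprintf("dim%d", seq_len(k))
  x
}

# independent objective evaluation used as an oracle against the package's
# optimizer: plain stats::dist / stats::cor, no shared code path
oracle_objective <- function(center, responses, rts, groupA) {
  vh <- sqrt(rowSums(sweep(responses, 2, center)^2))
  suppressWarnings(
    cor(vh[groupA], rts[groupA]) - cor(vh[!groupA], rts[!groupA]))
}

# a small noiseless present/absent problem with a known center: singletons
# plus midpoint arrays, RT = t_max - beta * |VH - b|
toy_decision_problem <- function(n = 8, k = 2, seed = 1, t_max = 1.8,
                                 beta = 0.5) {
  emb <- toy_embedding(n, k, seed)
  displays <- vishom::make_displays(rownames(emb), seed = seed)
  resp <- vishom::build_display_responses(emb, displays)
  center <- colMeans(emb)
  vh <- vishom::visual_homogeneity(resp, center)
  h <- length(vh) %/% 2
  b <- mean(sort(vh)[c(h, h + 1)])  # median split keeps the groups balanced
  rts <- t_max - beta * abs(vh - b)
  labels <- ifelse(vh < b, "present", "absent")
  list(emb = emb, displays = displays, responses = resp, center = center,
       vh = vh, boundary = b, rts = rts, labels = labels)
}
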