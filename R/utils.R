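# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so generator calls are deterministic without disturbing the session.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive an operation-specific seed from a master seed, so that random
# streams are split per operation (adding behavioural trials must not
# perturb voxel noise, and vice versa). Kept below 2^31 - 1.
sub_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483587)
}

# Labels understood by the two decision groups. Group A carries the
# positive expected VH-RT correlation (target-present / asymmetric),
# group B the negative one (target-absent / symmetric).
GROUP_A_LABELS <- c("present", "asymmetric", "groupA")
GROUP_B_LABELS <- c("absent", "symmetric", "groupB")

#' Map decision labels to the two correlation groups
#'
#' @param labels character vector of display labels; recognized values are
#'   `"present"`/`"asymmetric"`/`"groupA"` (group A) and
#'   `"absent"`/`"symmetric"`/`"groupB"` (group B).
#' @return factor with levels `"A"` and `"B"`.
#' @export
vh_group <- function(labels) {
  g <- ifelse(labels %in% GROUP_A_LABELS, "A",
              ifelse(labels %in% GROUP_B_LABELS, "B", NA_character_))
  if (anyNA(g)) {
    stop("unknown decision labels: ",
         paste(unique(labels[is.na(g)]), collapse = ", "))
  }
  factor(g, levels = c("A", "B"))
}

# Pearson correlation without the overhead/NA semantics of stats::cor;
# returns NA_real_ when either input has zero variance.
fast_cor <- function(x, y) {
  x <- x - mean(x)
  y <- y - mean(y)
  sx <- sqrt(sum(x * x))
  sy <- sqrt(sum(y * y))
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(x * y) / (sx * sy)
}

# Extract a coordinate matrix from either a vh_embedding or a plain matrix
# with object-id rownames.
emb_coords <- function(emb) {
  if (inherits(emb, "vh_embedding")) return(emb$coords)
  m <- as.matrix(emb)
  if (is.null(rownames(m))) stop("embedding matrix must have object ids as rownames")
  m
}
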