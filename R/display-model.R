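# Multiple-object averaging: predicted responses to displays from
# single-object embedding coordinates. The response to an array of
# identical items equals the single-item response; the response to an
# oddball array is a weighted average (default equal weights) of the
# target and distractor responses.

#' Response vector of a single-item (or target-absent) display
#'
#' @param emb a `vh_embedding` or coordinate matrix with object-id rownames.
#' @param i object id.
#' @return named k-vector (row `i` of the coordinates).
#' @export
singleton_response <- function(emb, i) {
  coords <- emb_coords(emb)
  if (!i %in% rownames(coords)) stop("unknown object id: ", i)
  coords[i, ]
}

#' Response vector of an oddball (target-present) array
#'
#' Weighted average of the target and distractor single-object responses.
#' Weights are normalized to sum to 1 on input, so the weighted variant is
#' a one-parameter family in the target weight.
#'
#' @param emb embedding (see [singleton_response()]).
#' @param target,distractor object ids.
#' @param w_target,w_distractor non-negative weights (not both zero).
#' @return k-vector `w_t * coords[target, ] + w_d * coords[distractor, ]`.
#' @export
array_response <- function(emb, target, distractor,
                           w_target = 0.5, w_distractor = 0.5) {
  coords <- emb_coords(emb)
  if (!target %in% rownames(coords)) stop("unknown object id: ", target)
  if (!distractor %in% rownames(coords)) stop("unknown object id: ", distractor)
  if (w_target < 0 || w_distractor < 0) stop("weights must be non-negative")
  s <- w_target + w_distractor
  if (s == 0) stop("weights must not both be zero")
  (w_target / s) * coords[target, ] + (w_distractor / s) * coords[distractor, ]
}

#' Batch display responses
#'
#' @param emb embedding.
#' @param displays display table (`display_id`, `kind`, `target_id`,
#'   `distractor_id`, `label`); `kind` is `"singleton"` or
#'   `"oddball_array"`.
#' @param w_target,w_distractor averaging weights for oddball arrays.
#' @return numeric `n_displays x k` matrix, rownames = display ids, order
#'   preserved.
#' @export
build_display_responses <- function(emb, displays, w_target = 0.5,
                                    w_distractor = 1 - w_target) {
  coords <- emb_coords(emb)
  if (nrow(displays) == 0) {
    return(matrix(numeric(0), 0, ncol(coords),
                  dimnames = list(NULL, colnames(coords))))
  }
  ti <- match(displays$target_id, rownames(coords))
  if (anyNA(ti)) {
    stop("unknown object id(s): ",
         paste(unique(displays$target_id[is.na(ti)]), collapse = ", "))
  }
  out <- coords[ti, , drop = FALSE]
  arr <- which(displays$kind == "oddball_array")
  if (length(arr)) {
    di <- match(displays$distractor_id[arr], rownames(coords))
    if (anyNA(di)) {
      stop("unknown object id(s): ",
           paste(unique(displays$distractor_id[arr][is.na(di)]),
                 collapse = ", "))
    }
    if (w_target < 0 || w_distractor < 0) stop("weights must be non-negative")
    s <- w_target + w_distractor
    if (s == 0) stop("weights must not both be zero")
    out[arr, ] <- (w_target / s) * coords[ti[arr], , drop = FALSE] +
      (w_distractor / s) * coords[di, , drop = FALSE]
  }
  rownames(out) <- displays$display_id
  out
}
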