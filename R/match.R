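# Greedy nearest-pair matching between ground-truth and detected point
# sets, used to score recovery on phantoms (precision / recall / F1 and
# localization error at a stated match radius).

#' Match detected points to ground truth
#'
#' Greedy one-to-one matching: all truth-detection pairs within
#' `radius_um` are sorted by distance and assigned greedily, each point
#' matched at most once. Reports precision, recall, F1 and the matched
#' localization errors.
#'
#' @param truth,detected n x 3 coordinate matrices (um) or objects
#'   accepted by [puncta_coords()].
#' @param radius_um maximum match distance (um).
#' @return list with `n_true`, `n_detected`, `n_matched`, `precision`,
#'   `recall`, `f1`, `errors` (matched distances, um), `median_error`,
#'   and the `matches` index matrix (truth, detected).
#' @export
match_points <- function(truth, detected, radius_um = 0.2) {
  tr <- puncta_coords(truth)
  de <- puncta_coords(detected)
  n_true <- nrow(tr)
  n_det <- nrow(de)
  matches <- matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("truth", "detected")))
  errors <- numeric(0)
  if (n_true > 0L && n_det > 0L) {
    d2 <- outer(tr[, 1L], de[, 1L], "-")^2 +
      outer(tr[, 2L], de[, 2L], "-")^2 +
      outer(tr[, 3L], de[, 3L], "-")^2
    cand <- which(d2 <= radius_um^2, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      ord <- order(d2[cand])
      cand <- cand[ord, , drop = FALSE]
      used_t <- logical(n_true)
      used_d <- logical(n_det)
      for (k in seq_len(nrow(cand))) {
        ti <- cand[k, 1L]
        di <- cand[k, 2L]
        if (!used_t[ti] && !used_d[di]) {
          used_t[ti] <- TRUE
          used_d[di] <- TRUE
          matches <- rbind(matches, c(ti, di))
          errors <- c(errors, sqrt(d2[ti, di]))
        }
      }
    }
  }
  n_matched <- nrow(matches)
  precision <- if (n_det > 0L) n_matched / n_det else NA_real_
  recall <- if (n_true > 0L) n_matched / n_true else NA_real_
  f1 <- if (is.na(precision) || is.na(recall) ||
            precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(n_true = n_true, n_detected = n_det, n_matched = n_matched,
       precision = precision, recall = recall, f1 = f1, errors = errors,
       median_error = if (n_matched > 0L) stats::median(errors)
         else NA_real_,
       matches = matches)
}
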