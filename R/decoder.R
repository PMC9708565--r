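# Consensus linear decoding of continuous behavior from population activity.
# A single decoder is the minimum-norm least-squares (Moore-Penrose) solution
# W = pinv(F) K mapping the population vector per time bin to position; the
# consensus decoder is the element-wise mean of a family of such decoders,
# each fit on a random subset of P permuted trials (a committee of weak
# decoders generalizes better than any single noisy fit).

#' Train a consensus linear decoder
#'
#' @param F time-bin x unit activity matrix.
#' @param K time-bin x 2 target matrix (x,y or angle,radius), row-aligned
#'   with `F`.
#' @param trial_id trial label per row of `F`.
#' @param n_folds N: number of decoders in the family.
#' @param trials_per_fold P: trials per fold (<= number of trials).
#' @param seed integer seed for the trial permutations.
#' @return object of class `fl_decoder`: `weights` (unit x 2 consensus),
#'   `fold_weights` (list), `n_folds`, `trials_per_fold`, `seed`.
#' @export
train_consensus_decoder <- function(F, K, trial_id = seq_len(nrow(F)),
                                    n_folds = 50, trials_per_fold = 75,
                                    seed = 1L) {
  F <- as.matrix(F); K <- as.matrix(K)
  if (nrow(F) != nrow(K) || nrow(F) != length(trial_id)) {
    fl_stop("`F`, `K` and `trial_id` must be row-aligned", "invalid_input")
  }
  trials <- unique(trial_id)
  if (trials_per_fold > length(trials)) {
    fl_stop("trials_per_fold exceeds the number of trials", "invalid_input")
  }
  set.seed(as.integer(seed))
  folds <- vector("list", n_folds)
  rank_deficient <- 0L
  for (b in seq_len(n_folds)) {
    sel_tr <- sample(trials, trials_per_fold)
    rows <- trial_id %in% sel_tr
    Ff <- F[rows, , drop = FALSE]
    if (qr(Ff)$rank < ncol(Ff)) rank_deficient <- rank_deficient + 1L
    folds[[b]] <- MASS::ginv(Ff) %*% K[rows, , drop = FALSE]
  }
  if (rank_deficient > 0L) {
    message(sprintf("%d/%d folds were rank-deficient; minimum-norm solution used",
                    rank_deficient, n_folds))
  }
  W <- Reduce(`+`, folds) / n_folds
  colnames(W) <- colnames(K)
  structure(list(weights = W, fold_weights = folds, n_folds = n_folds,
                 trials_per_fold = trials_per_fold, seed = as.integer(seed)),
            class = "fl_decoder")
}

#' Score decoder predictions
#'
#' Predicts `K_hat = F_test %*% W` and returns the coefficient of
#' determination per output channel.  `shuffle = TRUE` permutes the rows
#' (unit assignment) of the weight matrix first - the permuted-weights
#' control.
#'
#' @param model an `fl_decoder` (or a bare weight matrix).
#' @param F_test time-bin x unit activity matrix.
#' @param K_test time-bin x 2 target matrix.
#' @param shuffle permute weight rows before predicting.
#' @param seed seed for the permutation.
#' @return named numeric vector of R-squared per channel.
#' @export
decode_and_score <- function(model, F_test, K_test, shuffle = FALSE,
                             seed = 1L) {
  W <- if (inherits(model, "fl_decoder")) model$weights else as.matrix(model)
  F_test <- as.matrix(F_test); K_test <- as.matrix(K_test)
  if (ncol(F_test) != nrow(W)) fl_stop("shape mismatch", "invalid_input")
  if (shuffle) {
    set.seed(as.integer(seed))
    W <- W[sample(nrow(W)), , drop = FALSE]
  }
  K_hat <- F_test %*% W
  ss_tot <- colSums(sweep(K_test, 2, colMeans(K_test))^2)
  if (any(ss_tot == 0)) {
    fl_stop("zero-variance target channel; R^2 undefined", "invalid_input")
  }
  ss_res <- colSums((K_test - K_hat)^2)
  stats::setNames(1 - ss_res / ss_tot,
                  colnames(K_test) %||% paste0("ch", seq_len(ncol(K_test))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match ROI footprints across days
#'
#' Pairwise Pearson correlations between spatial footprints (already
#' registered to a common pixel grid); pairs with `r > r_threshold` are
#' greedily assigned one-to-one in descending correlation order.
#'
#' @param footprints_a,footprints_b lists of footprint matrices on a common
#'   pixel grid.
#' @param r_threshold minimum correlation for a match.
#' @return data.frame with `roi_a`, `roi_b`, `r`.
#' @export
match_rois_across_days <- function(footprints_a, footprints_b,
                                   r_threshold = 0.8) {
  va <- lapply(footprints_a, as.vector)
  vb <- lapply(footprints_b, as.vector)
  drop_a <- vapply(va, function(v) stats::sd(v) == 0 || !any(v != 0), logical(1))
  drop_b <- vapply(vb, function(v) stats::sd(v) == 0 || !any(v != 0), logical(1))
  if (any(drop_a) || any(drop_b)) {
    warning("empty or constant footprints skipped")
  }
  ia <- which(!drop_a); ib <- which(!drop_b)
  if (!length(ia) || !length(ib)) {
    return(data.frame(roi_a = integer(0), roi_b = integer(0), r = numeric(0)))
  }
  A <- vapply(va[ia], identity, numeric(length(va[[ia[1]]])))
  B <- vapply(vb[ib], identity, numeric(length(vb[[ib[1]]])))
  R <- stats::cor(A, B)
  cand <- which(R > r_threshold, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(data.frame(roi_a = integer(0), roi_b = integer(0), r = numeric(0)))
  }
  ord <- order(R[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(ncol(A)); used_b <- logical(ncol(B))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(roi_a = ia[cand[, 1]], roi_b = ib[cand[, 2]], r = R[cand])
}
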