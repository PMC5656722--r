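# Healthy-vs-diseased wall classification: shadow-feature relevance
# selection, boosted decision stumps, adjacent-frame majority voting and
# circular morphological cleanup.

#' Shadow-feature relevance selection
#'
#' Repeated Boruta-style screening: in each of `n_repeats` repeats a
#' random subset of labelled columns is drawn, and random-forest runs are
#' performed in which every feature is accompanied by a shuffled shadow
#' copy. A feature scores a hit whenever its importance exceeds the
#' maximum shadow importance; after each run a two-sided binomial test
#' (Bonferroni-corrected across features) confirms features with
#' significantly more than half hits and rejects those with significantly
#' fewer, stopping once every feature is decided or `max_iter` runs are
#' reached. A feature is relevant overall when confirmed in at least
#' `ceiling(n_repeats / 2)` repeats.
#'
#' @param X Feature matrix (named columns).
#' @param y Binary labels (healthy = 1, diseased = 0).
#' @param n_repeats Number of independent repeats (odd recommended).
#' @param max_iter Maximum random-forest runs per repeat.
#' @param alpha Significance level before Bonferroni correction.
#' @param subset_size Columns drawn per repeat.
#' @param num_trees Trees per random-forest run.
#' @param seed Integer seed; the procedure is deterministic given it.
#' @return List with `scores` (confirmation counts per feature),
#'   `relevant` (character vector) and the per-repeat `decisions` matrix
#'   (`"confirmed"`, `"rejected"` or `"tentative"`).
#' @export
boruta_select <- function(X, y, n_repeats = 51L, max_iter = 1000L,
                          alpha = 0.01, subset_size = 100L,
                          num_trees = 100L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  nf <- ncol(X)
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(nf))
  constant <- apply(X, 2, function(v) diff(range(v)) <= 0)
  decisions <- matrix("tentative", n_repeats, nf, dimnames = list(NULL, fn))
  set.seed(seed)
  alpha_c <- alpha / nf
  for (rep_i in seq_len(n_repeats)) {
    idx <- sample(nrow(X), min(subset_size, nrow(X)))
    tries <- 0L
    while (length(unique(y[idx])) < 2 && tries < 50L) {
      idx <- sample(nrow(X), min(subset_size, nrow(X)))
      tries <- tries + 1L
    }
    Xs <- X[idx, , drop = FALSE]
    ys <- factor(y[idx])
    hits <- integer(nf)
    undecided <- !constant
    dec <- ifelse(constant, "rejected", "tentative")
    run <- 0L
    while (any(undecided) && run < max_iter) {
      run <- run + 1L
      shadow <- apply(Xs, 2, sample)
      colnames(shadow) <- paste0("shadow_", fn)
      df <- data.frame(Xs, shadow, check.names = FALSE)
      colnames(df) <- c(fn, colnames(shadow))
      df$.label <- ys
      rf <- ranger::ranger(dependent.variable.name = ".label", data = df,
                           num.trees = num_trees, importance = "impurity",
                           seed = seed * 1000L + rep_i * 101L + run,
                           num.threads = 1L)
      imp <- rf$variable.importance
      shadow_max <- max(imp[grepl("^shadow_", names(imp))])
      hits <- hits + as.integer(imp[fn] > shadow_max)
      if (run >= 4L) {
        p_hi <- pbinom(hits - 1L, run, 0.5, lower.tail = FALSE)
        p_lo <- pbinom(hits, run, 0.5)
        newly_conf <- undecided & (p_hi < alpha_c)
        newly_rej <- undecided & (p_lo < alpha_c)
        dec[newly_conf] <- "confirmed"
        dec[newly_rej] <- "rejected"
        undecided <- undecided & !(newly_conf | newly_rej)
      }
    }
    decisions[rep_i, ] <- dec
  }
  scores <- colSums(decisions == "confirmed")
  names(scores) <- fn
  list(scores = scores,
       relevant = fn[scores >= ceiling(n_repeats / 2)],
       decisions = decisions)
}

# best weighted decision stump over all features; deterministic
# tie-breaks: lower error, then lower feature index, then lower
# threshold, polarity +1 preferred
best_stump <- function(X, s, w) {
  nf <- ncol(X)
  best <- list(err = Inf, feature = 1L, threshold = -Inf, polarity = 1L)
  Wp <- sum(w[s > 0]); Wn <- sum(w[s < 0])
  for (f in seq_len(nf)) {
    x <- X[, f]
    o <- order(x)
    xs <- x[o]; ws <- w[o]; ss <- s[o]
    cwp <- cumsum(ws * (ss > 0))
    cwn <- cumsum(ws * (ss < 0))
    # candidate splits after the last element of each distinct-value group
    grp_end <- which(c(xs[-1] != xs[-length(xs)], FALSE))
    ks <- c(0L, grp_end)           # 0 = everything on the right
    thr <- c(-Inf, (xs[grp_end] + xs[grp_end + 1L]) / 2)
    for (i in seq_along(ks)) {
      k <- ks[i]
      lp <- if (k == 0) 0 else cwp[k]
      ln <- if (k == 0) 0 else cwn[k]
      err_pos <- lp + (Wn - ln)     # predict +1 for x > thr
      err_neg <- (Wp - lp) + ln     # predict -1 for x > thr
      if (err_pos < best$err - 1e-12) {
        best <- list(err = err_pos, feature = f, threshold = thr[i],
                     polarity = 1L)
      }
      if (err_neg < best$err - 1e-12) {
        best <- list(err = err_neg, feature = f, threshold = thr[i],
                     polarity = -1L)
      }
    }
  }
  best
}

stump_predict <- function(stump, X) {
  h <- ifelse(X[, stump$feature] > stump$threshold, 1, -1)
  h * stump$polarity
}

#' Train a boosted-stump healthy-wall classifier
#'
#' Discrete AdaBoost with depth-1 decision stumps as base learners.
#' Training is deterministic: stump search breaks ties by feature index
#' and threshold, and boosting stops early once a round separates the
#' training data perfectly.
#'
#' @param X Normalised feature matrix (named columns).
#' @param y Binary labels (healthy = 1, diseased = 0); both classes must
#'   be present.
#' @param n_rounds Number of boosting rounds.
#' @param seed Stored in the model metadata (training itself is
#'   deterministic).
#' @return An `oct_adaboost` model with a `stumps` data frame (feature,
#'   threshold, polarity, alpha), the feature names, and training
#'   metadata.
#' @export
train_adaboost <- function(X, y, n_rounds = 100L, seed = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  s <- ifelse(y > 0, 1, -1)
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- vector("list", n_rounds)
  m <- 0L
  eps <- 1e-10
  for (round in seq_len(n_rounds)) {
    st <- best_stump(X, s, w)
    h <- stump_predict(st, X)
    err <- sum(w[h != s])
    err_c <- min(max(err, eps), 1 - eps)
    st$alpha <- log((1 - err_c) / err_c)
    m <- m + 1L
    stumps[[m]] <- st
    if (err <= eps) break
    w <- w * exp(st$alpha * (h != s))
    w <- w / sum(w)
  }
  stumps <- stumps[seq_len(m)]
  tab <- data.frame(
    feature = vapply(stumps, `[[`, integer(1), "feature"),
    threshold = vapply(stumps, `[[`, numeric(1), "threshold"),
    polarity = vapply(stumps, `[[`, integer(1), "polarity"),
    alpha = vapply(stumps, `[[`, numeric(1), "alpha"))
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(X)))
  tab$feature_name <- fn[tab$feature]
  structure(list(stumps = tab, feature_names = fn,
                 n_rounds = as.integer(n_rounds),
                 norm_stats = NULL,
                 meta = list(seed = seed, n_samples = n,
                             date = format(Sys.Date()))),
            class = "oct_adaboost")
}

#' @export
print.oct_adaboost <- function(x, ...) {
  cat(sprintf("<oct_adaboost> %d stumps over %d features (trained on %d columns)\n",
              nrow(x$stumps), length(x$feature_names), x$meta$n_samples))
  invisible(x)
}

#' Predict healthy/diseased labels for feature columns
#'
#' @param object An `oct_adaboost` model.
#' @param newdata Normalised feature matrix with the model's features.
#' @param type `"class"` for 0/1 labels (score ties fall to diseased) or
#'   `"score"` for the signed ensemble margin.
#' @param ... Ignored.
#' @return Numeric vector of labels or scores.
#' @export
predict.oct_adaboost <- function(object, newdata,
                                 type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) &&
      all(object$feature_names %in% colnames(X))) {
    X <- X[, object$feature_names, drop = FALSE]
  } else if (ncol(X) != length(object$feature_names)) {
    stop("feature mismatch between model and data")
  }
  score <- numeric(nrow(X))
  for (i in seq_len(nrow(object$stumps))) {
    st <- object$stumps[i, ]
    h <- ifelse(X[, st$feature] > st$threshold, 1, -1) * st$polarity
    score <- score + st$alpha * h
  }
  if (type == "score") score else as.integer(score > 0)
}

#' Adjacent-frame majority voting for one frame
#'
#' Applies the classifier independently to the current frame and (when
#' available) its two pullback neighbours, then takes the per-column
#' majority. At pullback ends the missing neighbour is dropped; a voting
#' tie falls back to the current frame's own label.
#'
#' @param model An `oct_adaboost`.
#' @param features_current Normalised features of frame k.
#' @param features_prev,features_next Features of frames k-1 / k+1, or
#'   `NULL` at pullback ends.
#' @param mask Optional logical guidewire mask; masked columns are
#'   returned as `NA`.
#' @return Integer labels per column (healthy = 1, diseased = 0, masked =
#'   `NA`).
#' @export
predict_columns <- function(model, features_current, features_prev = NULL,
                            features_next = NULL, mask = NULL) {
  own <- predict(model, features_current)
  votes <- list(own)
  if (!is.null(features_prev)) votes <- c(votes, list(predict(model, features_prev)))
  if (!is.null(features_next)) votes <- c(votes, list(predict(model, features_next)))
  V <- do.call(cbind, votes)
  tot <- rowSums(V)
  nv <- ncol(V)
  lab <- ifelse(tot * 2 > nv, 1L, ifelse(tot * 2 < nv, 0L, own))
  if (!is.null(mask)) lab[mask] <- NA_integer_
  as.integer(lab)
}

# circular binary erosion/dilation with a flat element of length K,
# anchored at floor(K / 2)
circ_morph <- function(x, K, op = c("erode", "dilate")) {
  op <- match.arg(op)
  n <- length(x)
  a <- K %/% 2L
  offs <- (-a):(K - 1L - a)
  M <- vapply(offs, function(o) x[((seq_len(n) - 1L + o) %% n) + 1L],
              numeric(n))
  if (op == "erode") as.integer(apply(M, 1, min)) else
    as.integer(apply(M, 1, max))
}

#' Circular morphological cleanup of per-column labels
#'
#' Erosion with a flat structuring element of length `K_E` followed by
#' dilation with length `K_D`, both circular and anchored at
#' `floor(K / 2)`. Masked columns are transparent: they temporarily take
#' the value of their nearest unmasked neighbour and are restored to
#' `NA` afterwards.
#'
#' @param labels Integer labels (healthy = 1, diseased = 0, `NA` =
#'   masked) on a circular domain.
#' @param K_E,K_D Erosion / dilation kernel lengths.
#' @return Cleaned labels, same encoding.
#' @export
morphological_cleanup <- function(labels, K_E = 4L, K_D = 9L) {
  n <- length(labels)
  masked <- is.na(labels)
  x <- as.numeric(labels)
  if (any(masked)) {
    if (all(masked)) return(labels)
    unm <- which(!masked)
    for (i in which(masked)) {
      dist <- pmin((unm - i) %% n, (i - unm) %% n)
      x[i] <- x[unm[order(dist, unm)[1]]]
    }
  }
  x <- circ_morph(x, K_E, "erode")
  x <- circ_morph(x, K_D, "dilate")
  x[masked] <- NA_integer_
  as.integer(x)
}

#' Classify every frame of a pullback
#'
#' Runs [predict_columns()] for each frame with its pullback neighbours
#' followed by [morphological_cleanup()].
#'
#' @param model An `oct_adaboost` whose `norm_stats` are applied to the
#'   raw features.
#' @param features List of raw (unnormalised) feature matrices, one per
#'   frame.
#' @param masks Optional list of guidewire masks per frame.
#' @param K_E,K_D Morphology kernel lengths.
#' @return Integer matrix `n_angles x n_frames` of labels (`NA` =
#'   masked).
#' @export
classify_pullback <- function(model, features, masks = NULL, K_E = 4L,
                              K_D = 9L) {
  nfr <- length(features)
  norm <- lapply(features, function(F) {
    Fa <- F[, model$feature_names, drop = FALSE]
    normalize_features(Fa, model$norm_stats)$features
  })
  out <- NULL
  for (k in seq_len(nfr)) {
    mask <- if (is.null(masks)) NULL else masks[[k]]
    lab <- predict_columns(model, norm[[k]],
                           if (k > 1) norm[[k - 1]] else NULL,
                           if (k < nfr) norm[[k + 1]] else NULL,
                           mask = mask)
    lab <- morphological_cleanup(lab, K_E, K_D)
    out <- cbind(out, lab)
  }
  colnames(out) <- NULL
  out
}
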