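#' Efference-copy state prediction (process model)
#'
#' Predicts the next articulatory state from the previous estimate and an
#' efference copy of the motor command by replicating the plant's
#' integrator exactly: the same Runge-Kutta step and the same range-box
#' clamping, but with zero motor noise and no knowledge of external
#' perturbations (a clamped jaw is predicted to move). Equality with the
#' noiseless plant is bit-level because the two share one integrator.
#'
#' @param prev_estimate List with `a` (positions) and `a_dot` (velocities);
#'   either length-10 vectors or 10 x n matrices (columns propagate in
#'   parallel, as for sigma points).
#' @param efference Commanded articulator accelerations (10-vector or
#'   10 x n matrix).
#' @param dt Step duration (s).
#' @return List with predicted `a` and `a_dot`.
#' @export
predict_state <- function(prev_estimate, efference, dt) {
  out <- rk4_double_integrator(prev_estimate$a, prev_estimate$a_dot, efference, dt)
  clamp_to_box(out$a, out$a_dot)
}

#' Sensory prediction from a predicted articulatory state
#'
#' The somatosensory prediction is the identity on the articulatory state
#' (positions and velocities); the auditory prediction runs the trained
#' articulatory-to-formant map.
#'
#' @param a_hat List with `a` and `a_dot` (10-vectors or 10 x n matrices).
#' @param map A trained [train_auditory_map()] model.
#' @return List with `y_somat` (20-vector or 20 x n) and `y_aud` (3-vector
#'   or 3 x n).
#' @export
predict_sensory <- function(a_hat, map) {
  if (is.null(map)) {
    abort("no trained auditory map supplied; train one with train_auditory_map()")
  }
  vec_in <- !is.matrix(a_hat$a)
  A <- if (vec_in) matrix(a_hat$a, ncol = 1) else a_hat$a
  aud <- predict_formants(map, t(A))
  y_somat <- if (vec_in) c(a_hat$a, a_hat$a_dot) else rbind(a_hat$a, a_hat$a_dot)
  y_aud <- if (vec_in) drop(aud) else t(aud)
  list(y_somat = y_somat, y_aud = y_aud)
}

#' Generate articulatory babbling data
#'
#' Draws articulator trajectories as low-pass-filtered random walks through
#' the articulator range box (reflected at the walls so the box is covered
#' densely, edges included) and pairs each visited posture with its
#' noise-free formants from the plant map. This emulates exploratory
#' babbling as the teacher signal for learning the auditory forward model.
#'
#' @param n Number of samples (>= 1000 recommended for training use).
#' @param seed Integer seed; the babble is fully reproducible from it.
#' @param step_sd Random-walk innovation s.d. in normalized box units.
#' @param smooth Width (samples) of the moving-average low-pass filter.
#' @param geom Geometry constants.
#' @return A tibble of class `sfc_babble` with columns `id`, the 10
#'   articulators, and `F1`, `F2`, `F3`; the seed is kept as attribute
#'   `seed`.
#' @export
babble <- function(n, seed = 1L, step_sd = 0.06, smooth = 9L,
                   geom = geometry_constants()) {
  stopifnot(n >= 1)
  arts <- articulator_inventory()
  box <- articulator_range_box()
  W <- with_seed(seed, {
    # unbounded random walks in normalized coordinates, then low-pass
    steps <- matrix(rnorm(n * 10, 0, step_sd), n, 10)
    steps[1, ] <- runif(10, 0, 2)  # random fold-phase start
    w <- apply(steps, 2, cumsum)
    if (smooth > 1 && n > smooth) {
      ker <- rep(1 / smooth, smooth)
      w <- apply(w, 2, function(col) {
        sm <- stats::filter(col, ker, sides = 2)
        idx <- which(is.na(sm))
        sm[idx] <- col[idx]
        as.numeric(sm)
      })
    }
    w
  })
  # reflect (triangle-wave fold) into [0, 1], then map to the box
  fold <- abs((W %% 2) - 1)
  A <- sweep(sweep(fold, 2, box["hi", arts] - box["lo", arts], "*"),
             2, box["lo", arts], "+")
  colnames(A) <- arts
  F <- t(synthesize(t(A), geom = geom))
  out <- tibble::as_tibble(as.data.frame(cbind(A, F)))
  out <- tibble::add_column(out, id = seq_len(n), .before = 1)
  class(out) <- c("sfc_babble", class(out))
  attr(out, "seed") <- seed
  out
}

#' Split babbling data into training and held-out sets
#'
#' Seeded random 90/10 (by default) split by sample.
#'
#' @param set An `sfc_babble` tibble.
#' @param prop Training proportion.
#' @param seed Integer seed for the split.
#' @return List with `train` and `heldout` babble tibbles.
#' @export
babble_split <- function(set, prop = 0.9, seed = 1L) {
  n <- nrow(set)
  idx <- with_seed(seed, sample.int(n, size = floor(prop * n)))
  list(train = set[sort(idx), ], heldout = set[sort(setdiff(seq_len(n), idx)), ])
}

#' Train the auditory forward model on babbling data
#'
#' Locally weighted projection regression: (1) a low-dimensional regression
#' subspace is identified from the data by probing local linear fits at
#' random anchors and taking the leading eigenvectors of the averaged
#' gradient outer product (the formant map varies along only a few
#' directions of the 10-dimensional articulator space); (2) Gaussian
#' receptive fields are placed at k-means centers of the projected inputs;
#' (3) each receptive field fits a local quadratic model by weighted ridge
#' regression; (4) predictions blend the local models with normalized
#' receptive-field weights. Inference is deterministic; the training seed
#' only controls anchor/k-means initialization.
#'
#' @param set Training babble (an `sfc_babble` tibble).
#' @param n_centers Number of receptive fields.
#' @param n_anchors Anchors for gradient probing.
#' @param k_anchor Neighborhood size per anchor.
#' @param bw_scale Receptive-field bandwidth as a multiple of the
#'   within-cluster RMS radius.
#' @param max_dim Cap on the regression-subspace dimension.
#' @param seed Seed for anchor sampling and k-means.
#' @return An object of class `sfc_auditory_map`.
#' @export
train_auditory_map <- function(set, n_centers = 2400, n_anchors = 400,
                               bw_scale = 0.8, max_dim = 5,
                               seed = 1L) {
  arts <- articulator_inventory()
  X <- as.matrix(set[, arts])
  Y <- as.matrix(set[, c("F1", "F2", "F3")])
  n <- nrow(X)
  if (n < 200) abort("too few babble samples to train the auditory map")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  ysd <- apply(Y, 2, sd)

  with_seed(seed, {
    # --- stage 1: regression subspace from the gradient outer product of a
    # global polynomial ridge fit. The babble dimensions are sampled
    # near-independently, so a global polynomial regression of a target
    # that varies only along a subspace keeps its gradient energy in that
    # subspace; its eigen-spectrum then shows a clean gap.
    Phi <- poly_features(Xs, degree = 3)
    lam <- 1e-6 * n
    beta_g <- solve(crossprod(Phi) + lam * diag(ncol(Phi)), crossprod(Phi, Y))
    anchors <- sample.int(n, min(n_anchors, n))
    Xa <- Xs[anchors, , drop = FALSE]
    h <- 1e-4
    grads <- lapply(1:10, function(j) {
      Xp <- Xa; Xp[, j] <- Xp[, j] + h
      Xm <- Xa; Xm[, j] <- Xm[, j] - h
      Gj <- (poly_features(Xp, 3) - poly_features(Xm, 3)) %*% beta_g / (2 * h)
      sweep(Gj, 2, ysd, "/")               # anchors x formants
    })
    C <- matrix(0, 10, 10)
    for (j in 1:10) {
      for (jj in j:10) {
        C[j, jj] <- C[jj, j] <- mean(rowSums(grads[[j]] * grads[[jj]]))
      }
    }
    eig <- eigen(C, symmetric = TRUE)
    ev <- pmax(eig$values, 0)
    r <- min(max(sum(ev > 1e-3 * ev[1]), 1L), max_dim)
    V <- eig$vectors[, seq_len(r), drop = FALSE]

    # --- stage 2: receptive-field centers in the projected space
    Z <- Xs %*% V
    km <- kmeans(Z, centers = min(n_centers, max(2, n %/% 10)),
                 iter.max = 40, nstart = 1)
    centers <- km$centers
    nC <- nrow(centers)
    # bandwidth per field: scaled RMS radius of its members
    wss <- km$withinss
    sizes <- pmax(km$size, 1)
    bw <- bw_scale * sqrt(pmax(wss / sizes, 1e-8))
    glob_bw <- stats::median(bw)
    bw <- pmax(bw, 0.25 * glob_bw)

    # --- stage 3: local quadratic models by weighted ridge, one pass
    p <- 1 + r + r * (r + 1) / 2
    AtA <- array(0, c(p, p, nC))
    AtY <- array(0, c(p, 3, nC))
    counts <- integer(nC)
    block <- 4000L
    for (b0 in seq(1, n, by = block)) {
      bi <- b0:min(b0 + block - 1, n)
      Zb <- Z[bi, , drop = FALSE]
      D2 <- outer(rowSums(Zb^2), rowSums(centers^2), "+") - 2 * Zb %*% t(centers)
      for (cdx in seq_len(nC)) {
        h <- bw[cdx]
        sel <- which(D2[, cdx] < (3 * h)^2)
        if (length(sel) == 0) next
        u <- sweep(Zb[sel, , drop = FALSE], 2, centers[cdx, ])
        w <- exp(-0.5 * D2[sel, cdx] / h^2)
        Phi <- local_features(u)
        Pw <- Phi * w
        AtA[, , cdx] <- AtA[, , cdx] + crossprod(Pw, Phi)
        AtY[, , cdx] <- AtY[, , cdx] + crossprod(Pw, Y[bi[sel], , drop = FALSE])
        counts[cdx] <- counts[cdx] + sum(D2[sel, cdx] < h^2)
      }
    }
    beta <- array(0, c(p, 3, nC))
    for (cdx in seq_len(nC)) {
      A <- AtA[, , cdx]
      lam <- 1e-7 * (sum(diag(A)) / p + 1)
      beta[, , cdx] <- solve(A + lam * diag(p), AtY[, , cdx])
    }
    # re-express every local model in the global monomial basis of z, so
    # prediction is a dense matrix product instead of a per-field loop
    gamma <- array(0, c(p, 3, nC))
    for (cdx in seq_len(nC)) {
      gamma[, , cdx] <- shift_quadratic(beta[, , cdx, drop = FALSE][, , 1],
                                        centers[cdx, ])
    }
  })

  fit <- structure(
    list(center = ctr, scale = scl, V = V, r = r,
         rf_centers = centers, rf_bw = bw, rf_counts = counts,
         beta = beta, gamma = gamma, n_train = n,
         train_seed = attr(set, "seed"), train_ids = set$id),
    class = "sfc_auditory_map"
  )
  res <- predict_formants(fit, X) - Y
  fit$train_mae <- colMeans(abs(res))
  fit
}

# full polynomial feature expansion up to `degree` (intercept, all
# monomials of total degree <= degree) of an m x d matrix
poly_features <- function(X, degree = 3) {
  d <- ncol(X)
  cols <- list(rep(1, nrow(X)))
  for (i in seq_len(d)) cols[[length(cols) + 1]] <- X[, i]
  if (degree >= 2) {
    for (i in seq_len(d)) for (j in i:d) {
      cols[[length(cols) + 1]] <- X[, i] * X[, j]
    }
  }
  if (degree >= 3) {
    for (i in seq_len(d)) for (j in i:d) for (k in j:d) {
      cols[[length(cols) + 1]] <- X[, i] * X[, j] * X[, k]
    }
  }
  do.call(cbind, cols)
}

# quadratic local feature expansion of centered projected inputs (m x r)
local_features <- function(u) {
  r <- ncol(u)
  quad <- matrix(0, nrow(u), r * (r + 1) / 2)
  k <- 1
  for (i in seq_len(r)) {
    for (j in i:r) {
      quad[, k] <- u[, i] * u[, j]
      k <- k + 1
    }
  }
  cbind(1, u, quad)
}

# rewrite a quadratic in u = z - c as the same quadratic in z.
# `beta` is p x 3 in the local_features() packing (1, u, u_i u_j for i <= j).
shift_quadratic <- function(beta, cc) {
  r <- length(cc)
  p <- nrow(beta)
  out <- matrix(0, p, ncol(beta))
  for (f in seq_len(ncol(beta))) {
    b0 <- beta[1, f]
    b <- beta[1 + seq_len(r), f]
    Cm <- matrix(0, r, r)
    k <- 1
    for (i in seq_len(r)) {
      for (j in i:r) {
        if (i == j) Cm[i, j] <- beta[1 + r + k, f]
        else { Cm[i, j] <- beta[1 + r + k, f] / 2; Cm[j, i] <- Cm[i, j] }
        k <- k + 1
      }
    }
    const <- b0 - sum(b * cc) + drop(cc %*% Cm %*% cc)
    lin <- b - 2 * drop(Cm %*% cc)
    quad <- numeric(r * (r + 1) / 2)
    k <- 1
    for (i in seq_len(r)) {
      for (j in i:r) {
        quad[k] <- if (i == j) Cm[i, j] else 2 * Cm[i, j]
        k <- k + 1
      }
    }
    out[, f] <- c(const, lin, quad)
  }
  out
}

#' Predict formants from articulator positions
#'
#' Blended prediction of the trained receptive-field ensemble. Defined for
#' every posture in the range box; deterministic (no randomness at
#' inference). When `localize = TRUE`, only receptive fields near the query
#' cloud's centroid are evaluated — numerically equivalent for tight query
#' clouds (such as sigma-point sets) and much faster inside the simulation
#' loop.
#'
#' @param map An `sfc_auditory_map`.
#' @param X Matrix of articulator positions (n x 10) or a single posture.
#' @param localize Restrict evaluation to receptive fields near the query
#'   centroid.
#' @return An n x 3 matrix of formants (Hz).
#' @export
predict_formants <- function(map, X, localize = FALSE) {
  if (!inherits(map, "sfc_auditory_map")) {
    abort("`map` is not a trained auditory map; train one with train_auditory_map()")
  }
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  Xs <- sweep(sweep(X, 2, map$center), 2, map$scale, "/")
  Z <- Xs %*% map$V
  centers <- map$rf_centers
  bw <- map$rf_bw
  idx <- seq_len(nrow(centers))
  if (localize) {
    zc <- colMeans(Z)
    d2c <- colSums((t(centers) - zc)^2)
    spread <- max(sqrt(rowSums(sweep(Z, 2, zc)^2)))
    near <- which(sqrt(d2c) < 7 * bw + spread)
    if (length(near) >= 1) idx <- near
  }
  D2 <- outer(rowSums(Z^2), rowSums(centers[idx, , drop = FALSE]^2), "+") -
    2 * Z %*% t(centers[idx, , drop = FALSE])
  Wt <- exp(-0.5 * sweep(D2, 2, bw[idx]^2, "/"))
  wsum <- rowSums(Wt)
  # degenerate queries (outside all fields): fall back to the nearest field
  far <- wsum < 1e-300
  if (any(far)) {
    nearest <- max.col(-D2[far, , drop = FALSE])
    Wt[cbind(which(far), nearest)] <- 1
    wsum <- rowSums(Wt)
  }
  Wn <- Wt / wsum
  # every local model lives in the same global monomial basis, so the blend
  # is three dense products: pred_f = rowSums(Wn * (Phi %*% Gamma_f))
  Phi <- local_features(Z)
  pred <- matrix(0, nrow(Z), 3)
  for (f in 1:3) {
    pred[, f] <- rowSums(Wn * (Phi %*% map$gamma[, f, idx]))
  }
  colnames(pred) <- c("F1", "F2", "F3")
  pred
}

#' Evaluate forward-model fit on held-out babble
#'
#' @param map An `sfc_auditory_map`.
#' @param heldout Held-out babble (must not overlap the training samples).
#' @return A tibble with one row per formant: mean and s.d. of the absolute
#'   prediction error (Hz) and the held-out sample size.
#' @export
evaluate_fit <- function(map, heldout) {
  if (identical(attr(heldout, "seed"), map$train_seed) &&
      any(heldout$id %in% map$train_ids)) {
    abort("held-out set overlaps the training samples; use babble_split()")
  }
  X <- as.matrix(heldout[, articulator_inventory()])
  Y <- as.matrix(heldout[, c("F1", "F2", "F3")])
  err <- abs(predict_formants(map, X) - Y)
  tibble::tibble(
    formant = c("F1", "F2", "F3"),
    mean_abs_error = colMeans(err),
    sd_abs_error = apply(err, 2, sd),
    n = nrow(heldout)
  )
}

#' @export
print.sfc_auditory_map <- function(x, ...) {
  cat("<sfc_auditory_map> ", nrow(x$rf_centers), " receptive fields in a ",
      x$r, "-dim regression subspace; trained on ", x$n_train, " samples\n",
      sep = "")
  cat("training mean |error| (Hz): ",
      paste(sprintf("%s %.2f", c("F1", "F2", "F3"), x$train_mae), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
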