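#' Backbone contract: image array to feature vector
#'
#' A backbone is any deterministic feature extractor mapping a square
#' intensity matrix to a fixed-length numeric vector; the classifier and
#' the linear transform block only see this contract, so a deep pretrained
#' network and a desk-scale extractor are interchangeable.
#'
#' [grid_backbone()] is the package's built-in desk-scale backbone: the
#' image is divided into a `grid x grid` lattice of cells and each cell
#' contributes its mean and its maximum intensity, giving `d = 2 * grid^2`
#' features. It has no parameters, is exactly deterministic, and is
#' sensitive to the localized bright structures (masses) the synthetic
#' generator plants.
#'
#' @param fn Function `matrix -> numeric(d)`.
#' @param d Feature dimension.
#' @param descriptor Short identifier.
#' @return An object of class `dv_backbone`.
#' @export
backbone <- function(fn, d, descriptor) {
  stopifnot(is.function(fn), d >= 1)
  structure(list(fn = fn, d = as.integer(d), descriptor = descriptor),
            class = "dv_backbone")
}

#' @rdname backbone
#' @param grid Cells per image side.
#' @export
grid_backbone <- function(grid = 6L) {
  grid <- as.integer(grid)
  stopifnot(grid >= 1L)
  backbone(function(m) {
    s <- nrow(m)
    stopifnot(is.matrix(m), ncol(m) == s)
    br <- findInterval(seq_len(s) - 1L, seq(0, s, length.out = grid + 1L),
                       rightmost.closed = TRUE)
    feats <- numeric(2L * grid * grid)
    k <- 0L
    for (i in seq_len(grid)) for (j in seq_len(grid)) {
      cell <- m[br == i, br == j, drop = FALSE]
      feats[k + 1L] <- mean(cell)
      feats[k + 2L] <- max(cell)
      k <- k + 2L
    }
    feats
  }, d = 2L * grid * grid, descriptor = sprintf("grid%d", grid))
}

#' Loss and training configuration
#'
#' @param alpha Weight of the cross-entropy term, in `[0, 1]`.
#' @param beta Weight of the cosine-alignment term, in `[0, 1]`. Defaults
#'   keep classification dominant with alignment as an auxiliary pull.
#' @param learning_rate Adam step size.
#' @param max_epochs Training epoch cap.
#' @param patience Early-stopping patience on validation loss, in epochs.
#' @param batch_size Minibatch size.
#' @param image_side Model input side passed to [resize_for_model()].
#' @param grid Grid of the default backbone (ignored when backbones are
#'   supplied to [train_dualview()] directly).
#' @param seed Seed controlling shuffling and initialization.
#' @return An object of class `dualview_config`.
#' @export
dualview_config <- function(alpha = 1.0, beta = 0.1, learning_rate = 3e-4,
                            max_epochs = 100L, patience = 10L,
                            batch_size = 32L, image_side = 64L,
                            grid = 6L, seed = 1L) {
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1)
    stop("alpha and beta must lie in [0, 1]")
  structure(list(alpha = alpha, beta = beta, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 image_side = as.integer(image_side),
                 grid = as.integer(grid), seed = as.integer(seed)),
            class = "dualview_config")
}

#' Apply the linear transformation block
#'
#' Maps an MLO feature vector toward CC feature space: `v* = w^T v_mlo`,
#' with `w` a learnable `d x d` matrix and no bias term.
#'
#' @param v_mlo Numeric feature vector of length `d`.
#' @param w Numeric `d x d` matrix.
#' @return Numeric vector of length `d`.
#' @export
transform_mlo <- function(v_mlo, w) {
  if (!is.matrix(w) || nrow(w) != ncol(w))
    stop("w must be a square matrix")
  if (length(v_mlo) != nrow(w))
    stop("length(v_mlo) must equal the transform dimension")
  if (any(!is.finite(w))) stop("w must have finite entries")
  as.numeric(crossprod(w, v_mlo))
}

#' Binary cross-entropy loss
#'
#' `-(1/N) * sum(y*log(p) + (1-y)*log(1-p))`, with predictions clamped to
#' `[eps, 1-eps]` for numerical safety.
#'
#' @param y Binary label vector.
#' @param y_hat Predicted probability vector of the same length.
#' @param eps Clamping constant.
#' @return Nonnegative scalar.
#' @export
cross_entropy_loss <- function(y, y_hat, eps = 1e-7) {
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  if (length(y) == 0) stop("empty batch")
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Cosine alignment loss between CC and transformed MLO features
#'
#' `1 - cos(v_cc, v_star_mlo)`, in `[0, 2]`: 0 for identical directions, 1
#' for orthogonal, 2 for opposite. For a zero-norm input the cosine is
#' undefined; the loss returns 0 for that sample with a warning, since
#' penalizing a degenerate extractor output in an arbitrary direction is
#' meaningless.
#'
#' @param v_cc,v_star_mlo Numeric vectors of equal length.
#' @return Scalar in `[0, 2]`.
#' @export
cosine_alignment_loss <- function(v_cc, v_star_mlo) {
  if (length(v_cc) != length(v_star_mlo))
    stop("feature vectors must have equal length")
  na <- sqrt(sum(v_cc^2)); nb <- sqrt(sum(v_star_mlo^2))
  if (na == 0 || nb == 0) {
    warning("zero-norm feature vector in cosine alignment loss; returning 0")
    return(0)
  }
  1 - sum(v_cc * v_star_mlo) / (na * nb)
}

#' Combined training loss
#'
#' `alpha * ce + beta * cos_loss`: weighted sum of the classification head's
#' cross-entropy and the transform block's cosine alignment loss.
#'
#' @param ce Cross-entropy term.
#' @param cos_loss Cosine alignment term.
#' @param cfg A [dualview_config()] (only `alpha`, `beta` are used).
#' @return Scalar.
#' @export
combined_loss <- function(ce, cos_loss, cfg) {
  cfg$alpha * ce + cfg$beta * cos_loss
}

#' Construct an untrained dual-view model
#'
#' Two backbones (one per view), the `d x d` transform block initialized at
#' the identity (a neutral prior for a view-to-view mapping), and a sigmoid
#' classification head on `concat(v_cc, v_star_mlo)` initialized at zero so
#' the untrained model outputs probability 0.5.
#'
#' @param backbone_cc,backbone_mlo [backbone()] contracts of equal `d`.
#' @param cfg A [dualview_config()].
#' @return An object of class `dualview_model`.
#' @export
dualview_model <- function(backbone_cc = grid_backbone(),
                           backbone_mlo = backbone_cc,
                           cfg = dualview_config()) {
  stopifnot(inherits(backbone_cc, "dv_backbone"),
            inherits(backbone_mlo, "dv_backbone"))
  if (backbone_cc$d != backbone_mlo$d)
    stop("backbones must share the feature dimension d")
  d <- backbone_cc$d
  structure(list(
    backbone_cc = backbone_cc, backbone_mlo = backbone_mlo,
    d = d, w = diag(d), head = numeric(2L * d), bias = 0,
    cfg = cfg, trained = FALSE, history = NULL
  ), class = "dualview_model")
}

# Extract per-view features for one exam after orientation standardization
# and square resize.
exam_features <- function(model, exam) {
  prep <- function(v) {
    sv <- if (v$standardized) v else standardize_orientation(v)
    resize_for_model(sv, model$cfg$image_side)
  }
  list(v_cc = model$backbone_cc$fn(prep(exam$cc)),
       v_mlo = model$backbone_mlo$fn(prep(exam$mlo)))
}

#' Forward pass of the dual-view classifier
#'
#' Standardizes and resizes both views, extracts per-view features,
#' transforms the MLO vector through the linear block, and scores the
#' concatenated `(v_cc, v_star_mlo)` vector (length `2d`) with the sigmoid
#' head.
#'
#' @param model A [dualview_model()].
#' @param exam A [breast_exam()].
#' @return List with `prob` and `bundle` (`v_cc`, `v_mlo`, `v_star_mlo`,
#'   `d`), the latter feeding the alignment loss.
#' @export
forward <- function(model, exam) {
  stopifnot(inherits(model, "dualview_model"), inherits(exam, "breast_exam"))
  f <- exam_features(model, exam)
  v_star <- transform_mlo(f$v_mlo, model$w)
  z <- sum(model$head * c(f$v_cc, v_star)) + model$bias
  list(prob = stats::plogis(z),
       bundle = list(v_cc = f$v_cc, v_mlo = f$v_mlo, v_star_mlo = v_star,
                     d = model$d))
}

#' Predict abnormality probabilities for a list of exams
#'
#' @param model A trained [dualview_model()].
#' @param exams List of [breast_exam()] objects.
#' @return Numeric probability vector.
#' @export
predict_prob <- function(model, exams) {
  vapply(exams, function(e) forward(model, e)$prob, numeric(1))
}

# Stack features of a list of exams into (n x d) matrices.
feature_matrices <- function(model, exams) {
  fs <- lapply(exams, exam_features, model = model)
  list(V_cc = do.call(rbind, lapply(fs, `[[`, "v_cc")),
       V_mlo = do.call(rbind, lapply(fs, `[[`, "v_mlo")))
}

# Combined loss and parameter gradients for a batch given precomputed
# feature matrices; everything vectorized over the batch.
batch_loss_grad <- function(par, V_cc, V_mlo, y, cfg, want_grad = TRUE) {
  n <- nrow(V_cc); d <- ncol(V_cc)
  U <- V_mlo %*% par$w                       # rows are v_star_mlo = w^T v_mlo
  X <- cbind(V_cc, U)
  z <- as.numeric(X %*% par$head) + par$bias
  p <- stats::plogis(z)
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  ce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  na <- sqrt(rowSums(V_cc^2)); nb <- sqrt(rowSums(U^2))
  dot <- rowSums(V_cc * U)
  ok <- na > 0 & nb > 0
  cosim <- ifelse(ok, dot / (na * nb), 1)    # loss contribution 0 when degenerate
  cosl <- mean(1 - cosim)
  loss <- cfg$alpha * ce + cfg$beta * cosl
  if (!want_grad)
    return(list(loss = loss, ce = ce, cos = cosl, prob = p))
  dz <- (p - y) / n                          # d(meanCE)/dz
  g_head <- cfg$alpha * as.numeric(crossprod(X, dz))
  g_bias <- cfg$alpha * sum(dz)
  dU_ce <- outer(dz, par$head[(d + 1):(2 * d)])
  # d(1 - cos)/dU, rowwise; zero rows where a norm vanishes
  dU_cos <- -(V_cc / (na * nb) - U * (dot / (na * nb^3)))
  dU_cos[!ok, ] <- 0
  dU <- cfg$alpha * dU_ce + cfg$beta * dU_cos / n
  g_w <- crossprod(V_mlo, dU)                # dL/dw_{jk} = sum_i v_mlo[i,j] dU[i,k]
  list(loss = loss, ce = ce, cos = cosl, prob = p,
       grad = list(w = g_w, head = g_head, bias = g_bias))
}

#' Train the dual-view classifier
#'
#' Minimizes the combined loss with Adam, minibatched, for at most
#' `max_epochs` epochs with early stopping on the validation combined loss
#' (the parameters achieving the minimum are restored). Backbones are
#' frozen feature extractors; the transform block `w` and the
#' classification head are learned. Training and validation sets must not
#' share a study.
#'
#' @param train_exams,val_exams Lists of labelled [breast_exam()] objects.
#' @param cfg A [dualview_config()].
#' @param backbone_cc,backbone_mlo Optional [backbone()] overrides; default
#'   is a [grid_backbone()] of `cfg$grid` shared across views.
#' @return A trained [dualview_model()] with a `history` data frame
#'   (per-epoch cross-entropy, cosine, combined and validation losses,
#'   validation AUC) and `best_epoch`.
#' @export
train_dualview <- function(train_exams, val_exams, cfg = dualview_config(),
                           backbone_cc = NULL, backbone_mlo = NULL) {
  if (length(train_exams) == 0 || length(val_exams) == 0)
    stop("train and validation sets must be nonempty")
  tr_studies <- vapply(train_exams, `[[`, "", "study_id")
  va_studies <- vapply(val_exams, `[[`, "", "study_id")
  if (length(intersect(tr_studies, va_studies)) > 0)
    stop("study leakage: train and validation sets share study ids")
  y_tr <- vapply(train_exams, `[[`, numeric(1), "label")
  y_va <- vapply(val_exams, `[[`, numeric(1), "label")
  if (anyNA(y_tr) || anyNA(y_va)) stop("all exams must carry labels")
  if (is.null(backbone_cc)) backbone_cc <- grid_backbone(cfg$grid)
  if (is.null(backbone_mlo)) backbone_mlo <- backbone_cc
  model <- dualview_model(backbone_cc, backbone_mlo, cfg)
  d <- model$d
  tr <- feature_matrices(model, train_exams)
  va <- feature_matrices(model, val_exams)
  par <- list(w = model$w, head = model$head, bias = model$bias)
  m1 <- list(w = 0 * par$w, head = 0 * par$head, bias = 0)
  m2 <- m1
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8; t <- 0
  set.seed(cfg$seed)
  n <- length(train_exams)
  hist <- vector("list", cfg$max_epochs)
  best <- list(loss = Inf, par = par, epoch = 0L)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      g <- batch_loss_grad(par, tr$V_cc[idx, , drop = FALSE],
                           tr$V_mlo[idx, , drop = FALSE], y_tr[idx], cfg)
      t <- t + 1
      for (nm in names(par)) {
        m1[[nm]] <- b1 * m1[[nm]] + (1 - b1) * g$grad[[nm]]
        m2[[nm]] <- b2 * m2[[nm]] + (1 - b2) * g$grad[[nm]]^2
        mhat <- m1[[nm]] / (1 - b1^t)
        vhat <- m2[[nm]] / (1 - b2^t)
        par[[nm]] <- par[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + aeps)
      }
    }
    tr_eval <- batch_loss_grad(par, tr$V_cc, tr$V_mlo, y_tr, cfg, want_grad = FALSE)
    va_eval <- batch_loss_grad(par, va$V_cc, va$V_mlo, y_va, cfg, want_grad = FALSE)
    val_auc <- if (length(unique(y_va)) == 2) auc_roc(y_va, va_eval$prob) else NA_real_
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_ce = tr_eval$ce, train_cos = tr_eval$cos,
      train_loss = tr_eval$loss, val_ce = va_eval$ce, val_cos = va_eval$cos,
      val_loss = va_eval$loss, val_auc = val_auc
    )
    if (va_eval$loss < best$loss - 1e-9) {
      best <- list(loss = va_eval$loss, par = par, epoch = epoch)
    } else if (epoch - best$epoch >= cfg$patience) {
      break
    }
  }
  model$w <- best$par$w
  model$head <- best$par$head
  model$bias <- best$par$bias
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model
}

#' Mean cosine distance between CC and transformed MLO features
#'
#' Diagnostic for the alignment term: averages
#' [cosine_alignment_loss()] over a list of exams under a given model.
#'
#' @inheritParams predict_prob
#' @return Scalar in `[0, 2]`.
#' @export
mean_cosine_distance <- function(model, exams) {
  mean(vapply(exams, function(e) {
    b <- forward(model, e)$bundle
    cosine_alignment_loss(b$v_cc, b$v_star_mlo)
  }, numeric(1)))
}
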