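#' Triplet margin loss
#'
#' `L = max(0, ||a - p|| - ||a - n|| + margin)` with Euclidean norms,
#' averaged over the batch. Anchors and positives share an identity; the
#' negative is a different individual.
#'
#' @param anchor_emb,positive_emb,negative_emb embedding matrices (n x d) or
#'   single vectors, equal dimensions.
#' @param margin positive margin.
#' @param squared use squared Euclidean distances instead.
#' @return mean loss (nonnegative scalar).
#' @export
triplet_loss <- function(anchor_emb, positive_emb, negative_emb, margin = 0.2,
                         squared = FALSE) {
  as_m <- function(x) if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  a <- as_m(anchor_emb); p <- as_m(positive_emb); n <- as_m(negative_emb)
  if (!all(dim(a) == dim(p)) || !all(dim(a) == dim(n)))
    .stopf("embedding dimensions do not match")
  dp <- sqrt(rowSums((a - p)^2))
  dn <- sqrt(rowSums((a - n)^2))
  if (squared) { dp <- dp^2; dn <- dn^2 }
  mean(pmax(0, dp - dn + margin))
}

#' Embedder architecture and training hyper-parameters
#'
#' Three blocks of two 3x3 convolutions with ReLU followed by a 2x2 max
#' pool, then two fully connected layers producing L2-normalized 64-d
#' embeddings.
#'
#' @param input_px square input size (must be divisible by 8).
#' @param channels feature channels per block.
#' @param embedding_dim output dimension (64).
#' @param margin triplet margin.
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param seed integer seed for initialization and batch sampling.
#' @return list of class `embedder_spec`.
#' @export
embedder_spec <- function(input_px = 64L, channels = c(8L, 16L, 32L),
                          embedding_dim = 64L, margin = 0.2, epochs = 62L,
                          batch_size = 32L, learning_rate = 1e-3, seed = 1L) {
  if (input_px %% 8L != 0L) .stopf("input_px must be divisible by 8")
  if (margin <= 0) .stopf("margin must be positive")
  structure(list(input_px = as.integer(input_px), channels = as.integer(channels),
                 embedding_dim = as.integer(embedding_dim), margin = margin,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "embedder_spec")
}

## --- minimal conv-net machinery (im2col + explicit backward) ---------------

.idx_env <- new.env(parent = emptyenv())

## 3x3 same-padding gather indices for an H x W map: HW x 9 (0 = zero pad),
## pixel index = (x-1)*H + y.
.conv_indices <- function(H, W) {
  key <- sprintf("c%d_%d", H, W)
  if (!is.null(.idx_env[[key]])) return(.idx_env[[key]])
  y <- rep(seq_len(H), W); x <- rep(seq_len(W), each = H)
  M <- matrix(0L, H * W, 9L)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    yy <- y + dy; xx <- x + dx
    ok <- yy >= 1L & yy <= H & xx >= 1L & xx <= W
    v <- integer(H * W)
    v[ok] <- (xx[ok] - 1L) * H + yy[ok]
    M[, k] <- v
  }
  .idx_env[[key]] <- M
  M
}

## 2x2 max-pool gather indices: (H/2 * W/2) x 4.
.pool_indices <- function(H, W) {
  key <- sprintf("p%d_%d", H, W)
  if (!is.null(.idx_env[[key]])) return(.idx_env[[key]])
  Ho <- H %/% 2L; Wo <- W %/% 2L
  yo <- rep(seq_len(Ho), Wo); xo <- rep(seq_len(Wo), each = Ho)
  at <- function(dy, dx) (2L * xo - 2L + dx - 1L + 1L - 1L) * H + (2L * yo - 2L + dy)
  M <- cbind(at(1L, 1L), at(2L, 1L), at(1L, 2L), at(2L, 2L))
  .idx_env[[key]] <- M
  M
}

## Batched gather indices: stack B maps of HW pixels; 0 stays 0 (pad row).
.batch_idx <- function(idx, B, HW) {
  key <- sprintf("b%d_%d_%d_%d", nrow(idx), ncol(idx), B, HW)
  if (!is.null(.idx_env[[key]])) return(.idx_env[[key]])
  out <- matrix(0L, nrow(idx) * B, ncol(idx))
  for (b in seq_len(B)) {
    blk <- idx
    blk[idx > 0L] <- idx[idx > 0L] + (b - 1L) * HW
    out[((b - 1L) * nrow(idx) + 1L):(b * nrow(idx)), ] <- blk
  }
  .idx_env[[key]] <- out
  out
}

## conv3x3 forward on stacked maps X ((B*HW) x Cin) -> ((B*HW) x Cout)
.conv_fwd <- function(X, Wm, b, bidx) {
  Xp <- rbind(0, X)
  n <- nrow(X); C <- ncol(X); K <- ncol(bidx)
  cols <- matrix(Xp[as.vector(bidx) + 1L, ], n, K * C)
  Y <- cols %*% Wm
  Y <- sweep(Y, 2, b, `+`)
  list(Y = Y, cols = cols)
}

.conv_bwd <- function(dY, cache_cols, Wm, bidx, n_in, C_in) {
  dW <- crossprod(cache_cols, dY)
  db <- colSums(dY)
  dcols <- dY %*% t(Wm)
  K <- ncol(bidx)
  dX <- matrix(0, n_in, C_in)
  for (k in seq_len(K)) {
    idx <- bidx[, k]
    ok <- idx > 0L
    # cols layout is k-fastest within each channel: column (c-1)*K + k
    dpart <- dcols[, (seq_len(C_in) - 1L) * K + k, drop = FALSE]
    dX[idx[ok], ] <- dX[idx[ok], ] + dpart[ok, , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

.pool_fwd <- function(X, pidx_b) {
  # X: (B*HW) x C ; pidx_b: (B*HW/4) x 4 batched indices
  C <- ncol(X)
  n_out <- nrow(pidx_b)
  Y <- X[pidx_b[, 1], , drop = FALSE]
  arg <- matrix(1L, n_out, C)
  for (k in 2:4) {
    cand <- X[pidx_b[, k], , drop = FALSE]
    upd <- cand > Y
    Y[upd] <- cand[upd]
    arg[upd] <- k
  }
  list(Y = Y, arg = arg)
}

.pool_bwd <- function(dY, arg, pidx_b, n_in) {
  C <- ncol(dY)
  dX <- matrix(0, n_in, C)
  for (k in 1:4) {
    sel <- arg == k
    if (!any(sel)) next
    rows <- pidx_b[, k]
    for (cc in seq_len(C)) {
      s <- sel[, cc]
      if (any(s)) dX[rows[s], cc] <- dX[rows[s], cc] + dY[s, cc]
    }
  }
  dX
}

.init_embedder_params <- function(spec) {
  ch <- c(1L, spec$channels)
  he <- function(nin, nout, fan) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / fan)),
                                        nin, nout)
  P <- list()
  for (b in 1:3) {
    P[[sprintf("W%da", b)]] <- he(9L * ch[b], ch[b + 1L], 9L * ch[b])
    P[[sprintf("b%da", b)]] <- numeric(ch[b + 1L])
    P[[sprintf("W%db", b)]] <- he(9L * ch[b + 1L], ch[b + 1L], 9L * ch[b + 1L])
    P[[sprintf("b%db", b)]] <- numeric(ch[b + 1L])
  }
  flat <- (spec$input_px / 8L)^2 * spec$channels[3]
  P$Wf1 <- he(flat, spec$embedding_dim, flat)
  P$bf1 <- numeric(spec$embedding_dim)
  P$Wf2 <- he(spec$embedding_dim, spec$embedding_dim, spec$embedding_dim)
  P$bf2 <- numeric(spec$embedding_dim)
  P
}

## Forward pass for a batch of B square crops (list of matrices).
## Returns embeddings (B x d) and, if train = TRUE, all caches.
.embedder_fwd <- function(P, crops, spec, train = FALSE) {
  B <- length(crops)
  s <- spec$input_px
  X <- matrix(unlist(lapply(crops, as.vector), use.names = FALSE) - 0.5,
              nrow = s * s * B, ncol = 1)
  # reorder: crops stacked as B blocks of HW rows
  dims <- c(s, s)
  caches <- list()
  H <- s; W <- s
  for (b in 1:3) {
    HW <- H * W
    bidx <- .batch_idx(.conv_indices(H, W), B, HW)
    pidx <- .batch_idx(.pool_indices(H, W), B, HW)
    ca <- .conv_fwd(X, P[[sprintf("W%da", b)]], P[[sprintf("b%da", b)]], bidx)
    Ya <- ca$Y; Ra <- Ya > 0; Ya[!Ra] <- 0
    cb <- .conv_fwd(Ya, P[[sprintf("W%db", b)]], P[[sprintf("b%db", b)]], bidx)
    Yb <- cb$Y; Rb <- Yb > 0; Yb[!Rb] <- 0
    pl <- .pool_fwd(Yb, pidx)
    if (train)
      caches[[b]] <- list(bidx = bidx, pidx = pidx, cols_a = ca$cols,
                          cols_b = cb$cols, Ra = Ra, Rb = Rb, arg = pl$arg,
                          n_in = nrow(X), C_in = ncol(X), C_mid = ncol(Ya))
    X <- pl$Y
    H <- H %/% 2L; W <- W %/% 2L
  }
  # flatten per image: rows are B blocks of H*W, columns channels
  HW <- H * W
  C <- ncol(X)
  F <- matrix(0, B, HW * C)
  for (b in seq_len(B))
    F[b, ] <- as.vector(X[((b - 1L) * HW + 1L):(b * HW), ])
  Z1 <- sweep(F %*% P$Wf1, 2, P$bf1, `+`)
  R1 <- Z1 > 0; A1 <- Z1; A1[!R1] <- 0
  Z2 <- sweep(A1 %*% P$Wf2, 2, P$bf2, `+`)
  nrm <- sqrt(rowSums(Z2^2)) + 1e-12
  E <- Z2 / nrm
  if (!train) return(list(E = E))
  list(E = E, caches = caches, F = F, A1 = A1, R1 = R1, Z2 = Z2, nrm = nrm,
       HW = HW, C = C, B = B)
}

## Backward pass from dE (B x d); returns gradients for all params.
.embedder_bwd <- function(P, fw, dE, spec) {
  B <- fw$B
  # through L2 normalization
  E <- fw$E
  dZ2 <- (dE - E * rowSums(dE * E)) / fw$nrm
  g <- list()
  g$Wf2 <- crossprod(fw$A1, dZ2); g$bf2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(P$Wf2)
  dZ1 <- dA1 * fw$R1
  g$Wf1 <- crossprod(fw$F, dZ1); g$bf1 <- colSums(dZ1)
  dF <- dZ1 %*% t(P$Wf1)
  # unflatten
  HW <- fw$HW; C <- fw$C
  dX <- matrix(0, B * HW, C)
  for (b in seq_len(B))
    dX[((b - 1L) * HW + 1L):(b * HW), ] <- matrix(dF[b, ], HW, C)
  for (b in 3:1) {
    cc <- fw$caches[[b]]
    dYb <- .pool_bwd(dX, cc$arg, cc$pidx, n_in = nrow(cc$Rb))
    dYb <- dYb * cc$Rb
    bw_b <- .conv_bwd(dYb, cc$cols_b, P[[sprintf("W%db", b)]], cc$bidx,
                      n_in = nrow(cc$Ra), C_in = cc$C_mid)
    g[[sprintf("W%db", b)]] <- bw_b$dW
    g[[sprintf("b%db", b)]] <- bw_b$db
    dYa <- bw_b$dX * cc$Ra
    bw_a <- .conv_bwd(dYa, cc$cols_a, P[[sprintf("W%da", b)]], cc$bidx,
                      n_in = cc$n_in, C_in = cc$C_in)
    g[[sprintf("W%da", b)]] <- bw_a$dW
    g[[sprintf("b%da", b)]] <- bw_a$db
    dX <- bw_a$dX
  }
  g
}

#' Build a temporally split identity dataset with augmentation
#'
#' The split is temporal, never random across time: crops from the earliest
#' `temporal_split_fraction` of frames generate the training images and the
#' remaining (later) frames generate the test images. Augmentation applies
#' random rotation, flips, brightness jitter and sub-crops.
#'
#' @param per_identity_crops named list, one element per identity: a list
#'   with `crops` (list of matrices) and `frames` (integer timestamps).
#' @param n_augmented_per_id augmented images generated per identity (split
#'   between train and test by the split fraction).
#' @param temporal_split_fraction fraction of frames (earliest) used for
#'   training.
#' @param seed integer seed.
#' @param crop_px output crop size.
#' @return list of class `identity_dataset` with `train` and `test`, each
#'   `list(crops, ids, frames)`.
#' @export
build_identity_dataset <- function(per_identity_crops, n_augmented_per_id = 250L,
                                   temporal_split_fraction = 0.8, seed = 1L,
                                   crop_px = 64L) {
  if (length(per_identity_crops) < 2L) .stopf("need at least 2 identities")
  for (nm in names(per_identity_crops))
    if (length(per_identity_crops[[nm]]$crops) < 2L)
      .stopf("identity '%s' has fewer than 2 source crops", nm)
  if (temporal_split_fraction >= 1)
    warning("split fraction 1.0 leaves an empty test set")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(.derive_seed(seed, 59L))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  n_train <- round(n_augmented_per_id * temporal_split_fraction)
  n_test <- n_augmented_per_id - n_train
  mk <- function(src_crops, n) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      img <- src_crops[[sample.int(length(src_crops), 1L)]]
      out[[i]] <- .augment_crop(img, crop_px)
    }
    out
  }
  train <- list(crops = list(), ids = integer(), frames = integer())
  test <- list(crops = list(), ids = integer(), frames = integer())
  for (id in seq_along(per_identity_crops)) {
    el <- per_identity_crops[[id]]
    frames <- el$frames
    if (is.null(frames)) frames <- seq_along(el$crops)
    ord <- order(frames)
    cut <- floor(length(ord) * temporal_split_fraction)
    cut <- max(1L, min(cut, length(ord) - as.integer(n_test > 0)))
    tr_src <- el$crops[ord[seq_len(cut)]]
    te_src <- if (cut < length(ord)) el$crops[ord[(cut + 1L):length(ord)]] else list()
    train$crops <- c(train$crops, mk(tr_src, n_train))
    train$ids <- c(train$ids, rep(id, n_train))
    train$frames <- c(train$frames, rep(max(frames[ord[seq_len(cut)]]), n_train))
    if (n_test > 0 && length(te_src)) {
      test$crops <- c(test$crops, mk(te_src, n_test))
      test$ids <- c(test$ids, rep(id, n_test))
      test$frames <- c(test$frames, rep(min(frames[ord[(cut + 1L):length(ord)]]),
                                        n_test))
    }
  }
  structure(list(train = train, test = test,
                 identities = names(per_identity_crops)),
            class = "identity_dataset")
}

.augment_crop <- function(img, crop_px) {
  ang <- stats::runif(1, -10, 10)
  out <- EBImage::rotate(img, ang, output.dim = dim(img),
                         bg.col = mean(img[c(1, nrow(img)), ]))
  out <- as.matrix(out)
  if (stats::runif(1) < 0.5) out <- out[rev(seq_len(nrow(out))), ]
  # random sub-crop (80-100% of extent), then resize to the target
  f <- stats::runif(1, 0.8, 1)
  h <- max(8L, floor(nrow(out) * f)); w <- max(8L, floor(ncol(out) * f))
  y0 <- sample.int(nrow(out) - h + 1L, 1L); x0 <- sample.int(ncol(out) - w + 1L, 1L)
  out <- out[y0:(y0 + h - 1L), x0:(x0 + w - 1L)]
  out <- as.matrix(EBImage::resize(out, w = crop_px, h = crop_px))
  out <- out * stats::runif(1, 0.85, 1.15)
  .clamp(out, 0, 1)
}

#' Train the triplet-loss identity embedder
#'
#' Minimizes the mean triplet loss with within-batch triplet sampling and
#' the Adam optimizer; deterministic given the spec's seed.
#'
#' @param dataset an [build_identity_dataset()] result (train split used).
#' @param spec an [embedder_spec()].
#' @param verbose print per-epoch loss.
#' @return object of class `identity_embedder` with `params`, `spec`,
#'   `loss_history`, `collapsed` (logical flag).
#' @export
train_embedder <- function(dataset, spec = embedder_spec(), verbose = FALSE) {
  tr <- dataset$train
  ids <- unique(tr$ids)
  if (length(ids) < 2L) .stopf("training set needs >= 2 identities")
  crops <- lapply(tr$crops, function(m) {
    if (!all(dim(m) == spec$input_px))
      m <- as.matrix(EBImage::resize(m, w = spec$input_px, h = spec$input_px))
    m
  })
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(.derive_seed(spec$seed, 97L))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  P <- .init_embedder_params(spec)
  adam_m <- lapply(P, function(x) x * 0)
  adam_v <- lapply(P, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  by_id <- split(seq_along(crops), tr$ids)
  iters <- max(1L, floor(length(crops) / spec$batch_size))
  loss_hist <- numeric(spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    ep_loss <- 0
    for (it in seq_len(iters)) {
      Bn <- spec$batch_size
      a_id <- sample(ids, Bn, replace = TRUE)
      tri <- lapply(seq_len(Bn), function(k) {
        pool <- by_id[[as.character(a_id[k])]]
        ap <- sample(pool, 2L, replace = length(pool) < 2L)
        neg_id <- sample(setdiff(ids, a_id[k]), 1L)
        c(ap, sample(by_id[[as.character(neg_id)]], 1L))
      })
      tri <- do.call(rbind, tri)          # Bn x 3 (anchor, positive, negative)
      batch <- crops[as.vector(t(tri))]   # a1 p1 n1 a2 p2 n2 ...
      fw <- .embedder_fwd(P, batch, spec, train = TRUE)
      E <- fw$E
      ia <- seq(1, 3 * Bn, by = 3); ip <- ia + 1L; in_ <- ia + 2L
      da <- E[ia, , drop = FALSE] - E[ip, , drop = FALSE]
      dn <- E[ia, , drop = FALSE] - E[in_, , drop = FALSE]
      ndp <- sqrt(rowSums(da^2)) + 1e-12
      ndn <- sqrt(rowSums(dn^2)) + 1e-12
      viol <- (ndp - ndn + spec$margin) > 0
      loss <- mean(pmax(0, ndp - ndn + spec$margin))
      if (!is.finite(loss))
        .stopf("NaN loss at epoch %d (lr %.2g); training diverged", ep,
               spec$learning_rate)
      ep_loss <- ep_loss + loss / iters
      dE <- matrix(0, 3 * Bn, spec$embedding_dim)
      w <- as.numeric(viol) / Bn
      ua <- da / ndp; un <- dn / ndn
      dE[ia, ] <- w * (ua - un)
      dE[ip, ] <- -w * ua
      dE[in_, ] <- w * un
      g <- .embedder_bwd(P, fw, dE, spec)
      step <- step + 1L
      for (nm in names(P)) {
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g[[nm]]
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g[[nm]]^2
        mh <- adam_m[[nm]] / (1 - beta1^step)
        vh <- adam_v[[nm]] / (1 - beta2^step)
        P[[nm]] <- P[[nm]] - spec$learning_rate * mh / (sqrt(vh) + eps)
      }
    }
    loss_hist[ep] <- ep_loss
    if (verbose) message(sprintf("epoch %d/%d: loss %.4f", ep, spec$epochs, ep_loss))
  }
  emb <- .embedder_fwd(P, crops[seq_len(min(64L, length(crops)))], spec)$E
  collapsed <- stats::sd(emb) < 1e-6
  if (collapsed) warning("embedding collapse: training images carry no identity signal")
  structure(list(params = P, spec = spec, loss_history = loss_hist,
                 collapsed = collapsed),
            class = "identity_embedder")
}

#' Embed image crops
#'
#' @param object an `identity_embedder`.
#' @param crops list of square matrices (resized to the spec input if
#'   needed).
#' @param ... unused.
#' @return matrix (n x embedding_dim) of L2-normalized embeddings.
#' @export
predict.identity_embedder <- function(object, crops, ...) {
  spec <- object$spec
  crops <- lapply(crops, function(m) {
    if (!all(dim(m) == spec$input_px))
      m <- as.matrix(EBImage::resize(m, w = spec$input_px, h = spec$input_px))
    m
  })
  # batch in chunks to bound memory
  out <- NULL
  for (i in seq(1, length(crops), by = 64L)) {
    idx <- i:min(i + 63L, length(crops))
    out <- rbind(out, .embedder_fwd(object$params, crops[idx], spec)$E)
  }
  out
}

#' Nearest-centroid identity assignment
#'
#' Reference embeddings are averaged per identity; each query embedding is
#' assigned the label of its nearest centroid (Euclidean). When ground
#' truth is supplied, purity is the fraction assigned correctly.
#'
#' @param embeddings query matrix (n x d).
#' @param reference_embeddings reference matrix (m x d).
#' @param reference_labels labels for the reference rows.
#' @param true_labels optional ground-truth labels for the queries.
#' @return list with `labels` (assigned) and `purity` (or `NA`).
#' @export
identity_assignment <- function(embeddings, reference_embeddings,
                                reference_labels, true_labels = NULL) {
  if (is.null(reference_embeddings) || nrow(reference_embeddings) == 0L)
    .stopf("empty reference set")
  labs <- unique(reference_labels)
  if (length(labs) == 1L)
    warning("single reference identity: purity is trivially 1")
  cent <- t(vapply(labs, function(l)
    colMeans(reference_embeddings[reference_labels == l, , drop = FALSE]),
    numeric(ncol(reference_embeddings))))
  d2 <- outer(rowSums(embeddings^2), rep(1, nrow(cent))) -
    2 * embeddings %*% t(cent) +
    outer(rep(1, nrow(embeddings)), rowSums(cent^2))
  assigned <- labs[max.col(-d2, ties.method = "first")]
  purity <- if (!is.null(true_labels)) mean(assigned == true_labels) else NA_real_
  list(labels = assigned, purity = purity)
}

#' Fraction of triplets satisfying the embedding margin ordering
#'
#' Samples identity-consistent triplets from labelled crops and reports the
#' fraction with `||a - p|| < ||a - n||`.
#'
#' @param embedder an `identity_embedder` (or `NULL` for raw-pixel
#'   embeddings, the chance-level control).
#' @param crops list of crops.
#' @param ids identity labels.
#' @param n_triplets number of sampled triplets.
#' @param seed integer seed.
#' @return fraction in \[0, 1\].
#' @export
triplet_satisfaction <- function(embedder, crops, ids, n_triplets = 500L,
                                 seed = 1L) {
  E <- predict(embedder, crops)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(.derive_seed(seed, 71L))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  by_id <- split(seq_along(ids), ids)
  uid <- names(by_id)
  ok <- logical(n_triplets)
  for (t in seq_len(n_triplets)) {
    aid <- sample(uid, 1L)
    ap <- sample(by_id[[aid]], 2L, replace = length(by_id[[aid]]) < 2L)
    ng <- sample(by_id[[sample(setdiff(uid, aid), 1L)]], 1L)
    ok[t] <- sum((E[ap[1], ] - E[ap[2], ])^2) < sum((E[ap[1], ] - E[ng, ])^2)
  }
  mean(ok)
}

#' Render per-identity fish crops with the simulator
#'
#' Convenience generator for identity experiments: each identity is a fish
#' with a persistent speckle (melanophore-like) texture seed observed over
#' several frames with small pose jitter. Crops emulate the
#' orientation-normalized body crops a tracker provides (real pipelines
#' align detections by the body axis before re-identification).
#'
#' @param n_ids number of identities.
#' @param n_frames frames (time points) per identity.
#' @param crop_px output crop size.
#' @param seed integer seed.
#' @return named list suitable for [build_identity_dataset()].
#' @export
simulate_identity_crops <- function(n_ids = 8L, n_frames = 6L, crop_px = 48L,
                                    seed = 1L) {
  config <- array_preset("desk6")
  out <- list()
  for (id in seq_len(n_ids)) {
    crops <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      set.seed(.derive_seed(seed, id, t))
      org <- organism_spec(kind = "fish", position_mm = c(0, 0),
                           heading_rad = stats::rnorm(1, 0, 0.15),
                           length_mm = 4.5, width_mm = 1.2,
                           articulation = stats::rnorm(2, 0, 0.12),
                           identity_texture_seed = .derive_seed(seed, id, 1234L))
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
      sc <- scene_spec(extent_mm = c(30, 25), organisms = list(org),
                       background = list(level = 0.85, contrast = 0.05,
                                         scale_mm = 2, seed = 9L))
      pc <- project_to_camera(c(0, 0, 0), config, 0L, 1L)
      half <- crop_px %/% 2L
      img <- render_camera_roi(sc, config, 0L, 1L,
                               roi = c(round(pc[1]) - half, round(pc[2]) - half,
                                       crop_px, crop_px),
                               seed = .derive_seed(seed, id, t, 2L))
      crops[[t]] <- img
    }
    out[[sprintf("id%02d", id)]] <- list(crops = crops, frames = seq_len(n_frames))
  }
  out
}
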