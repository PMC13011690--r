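# Attention-guided multiple instance learning over variable-size lymph-node
# bags. A bag is a patient; instances are per-node feature vectors; the
# label attaches to the bag only. Architecture: embedding layer
# (linear -> ReLU -> dropout, 32-dim), two-layer attention scorer
# (tanh hidden, softmax over instances), attention-pooled embedding,
# sigmoid classification head. Trained with focal loss + L1 on the
# embedding weights, Adam (lr 1e-4, weight decay 1e-6), batches of 32 bags.

#' MIL bag constructor
#'
#' @param x instance feature matrix (n_instances x d, n >= 1).
#' @param label bag-level binary label (or NA for unlabeled bags).
#' @param patient_id identifier.
#' @return a `mil_bag`.
#' @export
mil_bag <- function(x, label = NA_integer_, patient_id = NA_character_) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("a bag needs at least one instance", call. = FALSE)
  if (any(!is.finite(x))) stop("bag contains missing values", call. = FALSE)
  structure(list(x = x, label = as.integer(label), patient_id = patient_id),
            class = "mil_bag")
}

#' MIL network configuration
#'
#' Embedding width 32, learning rate 1e-4, weight decay 1e-6 and batch size
#' 32 are the method's fixed settings; the remaining knobs default to
#' standard values (focal alpha 0.25 / gamma 2, dropout 0.25, L1 1e-5,
#' attention hidden width 32).
#'
#' @param input_dim instance feature dimension d.
#' @param embed_dim embedding width (32).
#' @param attention_dim attention hidden width (default 32).
#' @param dropout dropout rate in the embedding layer (default 0.25).
#' @param alpha,gamma focal loss parameters (0.25, 2).
#' @param l1 L1 strength on the embedding weights (default 1e-5).
#' @param lr,weight_decay Adam settings (1e-4, 1e-6).
#' @param batch_size bags per batch (32).
#' @param max_epochs,patience early-stopping controls (200, 20).
#' @param val_fraction fraction of training bags held out for early
#'   stopping (default 0.15, stratified).
#' @param seed integer seed; training is deterministic given the seed.
#' @return a `mil_config`.
#' @export
mil_config <- function(input_dim, embed_dim = 32L, attention_dim = 32L,
                       dropout = 0.25, alpha = 0.25, gamma = 2,
                       l1 = 1e-5, lr = 1e-4, weight_decay = 1e-6,
                       batch_size = 32L, max_epochs = 200L, patience = 20L,
                       val_fraction = 0.15, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, gamma >= 0, dropout >= 0, dropout < 1)
  structure(list(input_dim = as.integer(input_dim),
                 embed_dim = as.integer(embed_dim),
                 attention_dim = as.integer(attention_dim),
                 dropout = dropout, alpha = alpha, gamma = gamma, l1 = l1,
                 lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "mil_config")
}

#' Focal loss
#'
#' `FL = -alpha * y * (1-p)^gamma * log(p) - (1-alpha) * (1-y) * p^gamma *
#' log(1-p)`, averaged over the batch. Probabilities are clipped at 1e-7.
#' With `gamma = 0, alpha = 0.5` this is exactly half the binary
#' cross-entropy.
#'
#' @param p predicted probabilities.
#' @param y binary labels.
#' @param alpha,gamma focal parameters.
#' @return mean loss (non-negative scalar).
#' @export
focal_loss <- function(p, y, alpha = 0.25, gamma = 2) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  mean(-alpha * y * (1 - p)^gamma * log(p) -
         (1 - alpha) * (1 - y) * p^gamma * log(1 - p))
}

# d(focal)/dp, elementwise (no batch averaging)
focal_grad_p <- function(p, y, alpha, gamma) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  gpos <- alpha * (gamma * (1 - p)^(pmax(gamma - 1, 0)) * log(p) -
                     (1 - p)^gamma / p)
  gneg <- (1 - alpha) * (gamma * p^(pmax(gamma - 1, 0)) * log(1 - p) -
                           p^gamma / (1 - p)) * -1
  y * gpos + (1 - y) * gneg
}

mil_init_params <- function(config) {
  d <- config$input_dim; e <- config$embed_dim; h <- config$attention_dim
  glorot <- function(nin, nout) {
    matrix(rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
  }
  list(We = glorot(d, e), be = numeric(e),
       W1 = glorot(e, h), b1 = numeric(h),
       w2 = as.numeric(glorot(h, 1L)),
       wc = as.numeric(glorot(e, 1L)), bc = 0)
}

# Forward pass over a batch of bags stacked as one instance matrix.
# X: N x d, g: integer bag index 1..nb per instance. Softmax is taken within
# each bag (equivalent to pad-and-mask batching with -Inf masked scores).
mil_forward_batch <- function(par, X, g, nb, dropout = 0, drop_mask = NULL) {
  H0 <- sweep(X %*% par$We, 2L, par$be, `+`)
  H <- pmax(H0, 0)
  if (!is.null(drop_mask)) H <- H * drop_mask / (1 - dropout)
  Tm <- tanh(sweep(H %*% par$W1, 2L, par$b1, `+`))
  s <- as.numeric(Tm %*% par$w2)
  mx <- vapply(split(s, g), max, numeric(1L))[as.character(seq_len(nb))]
  a <- exp(s - mx[g])
  asum <- rowsum(a, g)[, 1L]
  a <- a / asum[g]
  Z <- rowsum(a * H, g)
  u <- as.numeric(Z %*% par$wc) + par$bc
  p <- sigmoid(u)
  list(H0 = H0, H = H, Tm = Tm, s = s, a = a, Z = Z, u = u, p = p)
}

mil_backward_batch <- function(par, fw, X, g, y, config, drop_mask = NULL) {
  nb <- length(y)
  dLdp <- focal_grad_p(fw$p, y, config$alpha, config$gamma) / nb
  du <- dLdp * fw$p * (1 - fw$p)
  dwc <- as.numeric(t(fw$Z) %*% du)
  dbc <- sum(du)
  dZ <- outer(du, par$wc)                 # nb x e
  dZg <- dZ[g, , drop = FALSE]
  dH_pool <- fw$a * dZg
  da <- rowSums(fw$H * dZg)
  ds <- fw$a * (da - rowsum(fw$a * da, g)[g, 1L])
  dw2 <- as.numeric(t(fw$Tm) %*% ds)
  dpre1 <- outer(ds, par$w2) * (1 - fw$Tm^2)
  dW1 <- t(fw$H) %*% dpre1
  db1 <- colSums(dpre1)
  dH <- dH_pool + dpre1 %*% t(par$W1)
  if (!is.null(drop_mask)) dH <- dH * drop_mask / (1 - config$dropout)
  dpre0 <- dH * (fw$H0 > 0)
  dWe <- t(X) %*% dpre0 + config$l1 * sign(par$We)
  dbe <- colSums(dpre0)
  list(We = dWe, be = dbe, W1 = dW1, b1 = db1, w2 = dw2, wc = dwc, bc = dbc)
}

adam_step <- function(par, grad, state, lr, wd, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (nm in names(par)) {
    gr <- grad[[nm]] + wd * par[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

stack_bags <- function(bags) {
  X <- do.call(rbind, lapply(bags, function(b) b$x))
  g <- rep(seq_along(bags), vapply(bags, function(b) nrow(b$x), integer(1L)))
  list(X = X, g = g)
}

#' Train the attention-MIL network
#'
#' Minimizes mean focal loss plus an L1 penalty on the embedding weights
#' with Adam (learning rate 1e-4, weight decay 1e-6), batches of 32 bags,
#' early stopping on a stratified 15% validation split of the training
#' bags. Deterministic given `config$seed`.
#'
#' @param bags list of [mil_bag()]s; both classes must be present.
#' @param config a [mil_config()].
#' @return a fitted `mil_net` with the best-validation parameters and the
#'   training history.
#' @export
train_mil <- function(bags, config) {
  stopifnot(inherits(config, "mil_config"))
  y_all <- vapply(bags, function(b) b$label, integer(1L))
  if (length(unique(y_all)) < 2L) {
    stop("training bags must contain both classes", call. = FALSE)
  }
  dims <- unique(vapply(bags, function(b) ncol(b$x), integer(1L)))
  if (length(dims) != 1L || dims != config$input_dim) {
    stop("instance dimension mismatch across bags", call. = FALSE)
  }
  with_seed(config$seed, {
    # stratified validation split for early stopping
    n <- length(bags)
    val_idx <- unlist(lapply(unique(y_all), function(cls) {
      idx <- which(y_all == cls)
      k <- max(1L, round(length(idx) * config$val_fraction))
      sample(idx, k)
    }))
    tr_idx <- setdiff(seq_len(n), val_idx)
    tr_bags <- bags[tr_idx]; tr_y <- y_all[tr_idx]
    va <- stack_bags(bags[val_idx]); va_y <- y_all[val_idx]
    par <- mil_init_params(config)
    st <- list(m = lapply(par, function(z) z * 0),
               v = lapply(par, function(z) z * 0))
    best <- list(loss = Inf, par = par, epoch = 0L)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    t_step <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(length(tr_bags))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bt in batches) {
        sb <- stack_bags(tr_bags[bt])
        yb <- tr_y[bt]
        dm <- if (config$dropout > 0) {
          matrix(rbinom(length(sb$g) * config$embed_dim, 1L,
                        1 - config$dropout),
                 length(sb$g), config$embed_dim)
        } else NULL
        fw <- mil_forward_batch(par, sb$X, sb$g, length(bt),
                                config$dropout, dm)
        gr <- mil_backward_batch(par, fw, sb$X, sb$g, yb, config, dm)
        t_step <- t_step + 1L
        upd <- adam_step(par, gr, st, config$lr, config$weight_decay, t_step)
        par <- upd$par; st <- upd$state
        ep_loss <- ep_loss + focal_loss(fw$p, yb, config$alpha, config$gamma) *
          length(bt)
      }
      fv <- mil_forward_batch(par, va$X, va$g, length(va_y))
      vl <- focal_loss(fv$p, va_y, config$alpha, config$gamma)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = ep_loss / length(tr_bags),
                                     val_loss = vl))
      if (vl < best$loss - 1e-7) {
        best <- list(loss = vl, par = par, epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) break
    }
    structure(list(par = best$par, config = config, history = hist,
                   best_epoch = best$epoch, val_loss = best$loss),
              class = "mil_net")
  })
}

#' Forward pass for a single bag
#'
#' @param model a fitted `mil_net` (or a list with `par` and `config`).
#' @param bag a [mil_bag()].
#' @param training apply dropout (only meaningful during training).
#' @return list with `probability` and `attention` (non-negative weights
#'   summing to 1, one per instance).
#' @export
mil_forward <- function(model, bag, training = FALSE) {
  stopifnot(inherits(bag, "mil_bag"))
  if (ncol(bag$x) != model$config$input_dim) {
    stop("bag instance dimension does not match the model", call. = FALSE)
  }
  dm <- if (training && model$config$dropout > 0) {
    matrix(rbinom(nrow(bag$x) * model$config$embed_dim, 1L,
                  1 - model$config$dropout),
           nrow(bag$x), model$config$embed_dim)
  } else NULL
  fw <- mil_forward_batch(model$par, bag$x, rep(1L, nrow(bag$x)), 1L,
                          model$config$dropout, dm)
  list(probability = as.numeric(fw$p), attention = as.numeric(fw$a))
}

#' @export
predict.mil_net <- function(object, bags, type = c("prob", "attention"), ...) {
  type <- match.arg(type)
  if (inherits(bags, "mil_bag")) bags <- list(bags)
  sb <- stack_bags(bags)
  fw <- mil_forward_batch(object$par, sb$X, sb$g, length(bags))
  if (type == "prob") return(as.numeric(fw$p))
  split(as.numeric(fw$a), sb$g)
}

#' @export
print.mil_net <- function(x, ...) {
  cat(sprintf("Attention-MIL network: %d -> %d embedding, attention hidden %d\n",
              x$config$input_dim, x$config$embed_dim, x$config$attention_dim))
  cat(sprintf("trained %d epochs (best %d), validation focal loss %.4f\n",
              max(x$history$epoch), x$best_epoch, x$val_loss))
  invisible(x)
}

#' @export
coef.mil_net <- function(object, ...) object$par

#' Per-instance attention report for a set of bags
#'
#' @param model a fitted `mil_net`.
#' @param bags list of [mil_bag()]s.
#' @return data.frame (patient_id, node_index, weight).
#' @export
attention_report <- function(model, bags) {
  w <- predict(model, bags, type = "attention")
  do.call(rbind, lapply(seq_along(bags), function(i) {
    data.frame(patient_id = bags[[i]]$patient_id,
               node_index = seq_along(w[[i]]), weight = w[[i]])
  }))
}
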