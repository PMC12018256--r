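#' Two-head fusion network specification
#'
#' The detection network has two components. A representation head maps the
#' ten standardized pulsation ratios (the round's measurement signature)
#' through one linear layer with ReLU to a 16-dimensional round
#' representation. The classification head takes that representation
#' concatenated with the five per-round-standardized modulation ratios
#' (21 inputs) through four hidden linear+ReLU layers whose widths halve
#' from 128 to 16, then a single linear output unit with sigmoid.
#'
#' @param n_pulsation number of pulsation-ratio inputs.
#' @param n_modulation number of modulation-ratio inputs.
#' @param rep_width width of the representation head output.
#' @param class_widths hidden widths of the classification head; must halve
#'   from the first entry down to 16.
#' @param init_sd s.d. of the normal weight initialization (biases start 0).
#'   `NULL` (default) scales each layer as `sqrt(2 / fan_in)` (He init, the
#'   appropriate normal-distribution scale for ReLU stacks; a fixed small
#'   s.d. makes activations and gradients vanish through six layers).
#' @return object of class `network_spec`.
#' @export
network_spec <- function(n_pulsation = 10, n_modulation = 5, rep_width = 16,
                         class_widths = c(128, 64, 32, 16), init_sd = NULL) {
  if (length(class_widths) < 1 || utils::tail(class_widths, 1) != 16)
    stop("classification head must end at 16 neurons")
  if (length(class_widths) > 1 &&
      any(class_widths[-1] * 2 != class_widths[-length(class_widths)]))
    stop("hidden widths must halve from the first layer until 16")
  if (!is.null(init_sd) && length(init_sd) == 1 && is.na(init_sd))
    init_sd <- NULL   # JSON round trip turns NULL into NA
  if (!is.null(init_sd) && init_sd <= 0) stop("init_sd must be positive")
  structure(list(n_pulsation = n_pulsation, n_modulation = n_modulation,
                 rep_width = rep_width, class_widths = class_widths,
                 init_sd = init_sd),
            class = "network_spec")
}

#' Build (initialize) a fusion network
#'
#' Weights are drawn from a normal distribution with s.d. `init_sd`, biases
#' start at zero. The same seed yields identical parameters.
#'
#' @param spec a [network_spec()].
#' @param seed RNG seed.
#' @return object of class `tfo_mlp`: list of weight matrices `W` and bias
#'   vectors `b` (first entry = representation head, then the classification
#'   head layers, last entry the output unit).
#' @export
build_network <- function(spec = network_spec(), seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  dims_in <- c(spec$n_pulsation,
               spec$rep_width + spec$n_modulation,
               spec$class_widths)
  dims_out <- c(spec$rep_width, spec$class_widths, 1)
  with_seed(seed, {
    W <- mapply(function(i, o) {
      sd <- if (is.null(spec$init_sd)) sqrt(2 / i) else spec$init_sd
      matrix(stats::rnorm(i * o, 0, sd), i, o)
    }, dims_in, dims_out, SIMPLIFY = FALSE)
    b <- lapply(dims_out, numeric)
    structure(list(W = W, b = b, spec = spec), class = "tfo_mlp")
  })
}

#' @export
print.tfo_mlp <- function(x, ...) {
  shapes <- vapply(x$W, function(w) sprintf("%dx%d", nrow(w), ncol(w)), character(1))
  np <- sum(vapply(x$W, length, numeric(1))) + sum(lengths(x$b))
  cat(sprintf("Fusion MLP: representation %s | classification %s (%d parameters)\n",
              shapes[1], paste(shapes[-1], collapse = " -> "), np))
  invisible(x)
}

relu <- function(z) pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass; returns probabilities and layer activations for backprop
mlp_forward <- function(model, pr, mod) {
  nl <- length(model$W)
  acts <- vector("list", nl)        # post-ReLU activations (inputs to layer k+1)
  h <- relu(sweep(pr %*% model$W[[1]], 2, model$b[[1]], "+"))
  a <- cbind(h, mod)
  acts[[1]] <- a
  for (k in 2:(nl - 1)) {
    a <- relu(sweep(a %*% model$W[[k]], 2, model$b[[k]], "+"))
    acts[[k]] <- a
  }
  z <- sweep(acts[[nl - 1]] %*% model$W[[nl]], 2, model$b[[nl]], "+")
  list(prob = sigmoid(z)[, 1], acts = acts, pr = pr)
}

# weighted binary cross-entropy; w = per-sample weights
bce_loss <- function(prob, y, w) {
  eps <- 1e-12
  -mean(w * (y * log(prob + eps) + (1 - y) * log(1 - prob + eps)))
}

# gradients of the weighted BCE w.r.t. all parameters
mlp_gradients <- function(model, fwd, y, w, mod) {
  nl <- length(model$W)
  n <- length(y)
  gW <- vector("list", nl); gb <- vector("list", nl)
  delta <- matrix(w * (fwd$prob - y) / n, ncol = 1)          # d loss / d logit
  gW[[nl]] <- t(fwd$acts[[nl - 1]]) %*% delta
  gb[[nl]] <- colSums(delta)
  back <- delta %*% t(model$W[[nl]])
  for (k in (nl - 1):2) {
    dz <- back * (fwd$acts[[k]] > 0)
    gW[[k]] <- t(fwd$acts[[k - 1]]) %*% dz
    gb[[k]] <- colSums(dz)
    back <- dz %*% t(model$W[[k]])
  }
  # representation head: only the first rep_width columns of acts[[1]] came
  # through the ReLU; the appended modulation inputs take no gradient
  rw <- model$spec$rep_width
  dz <- back[, seq_len(rw), drop = FALSE] *
    (fwd$acts[[1]][, seq_len(rw), drop = FALSE] > 0)
  gW[[1]] <- t(fwd$pr) %*% dz
  gb[[1]] <- colSums(dz)
  list(W = gW, b = gb)
}

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param weight_decay L2 coefficient added to the gradient (Adam coupled
#'   weight decay).
#' @param max_epochs maximum epochs.
#' @param patience early-stopping patience on the validation loss; the best
#'   weights are restored.
#' @param batch_size mini-batch size (`NULL` = full batch). The default 128
#'   gives Adam enough update steps within 300 epochs at the 1e-4 learning
#'   rate; shuffling is seeded, so training stays deterministic.
#' @param class_weighted use inverse-frequency class weights
#'   `N_total / (2 * N_class)` in the BCE loss.
#' @param threshold decision threshold on the output probability.
#' @param seed RNG seed for initialization and shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-4, max_epochs = 300,
                         patience = 25, batch_size = 128,
                         class_weighted = TRUE, threshold = 0.5, seed = 1) {
  if (lr <= 0 || weight_decay < 0 || max_epochs <= 0 || patience <= 0)
    stop("training hyperparameters must be positive")
  if (patience >= max_epochs) stop("patience must be smaller than max_epochs")
  structure(list(lr = lr, weight_decay = weight_decay, max_epochs = max_epochs,
                 patience = patience, batch_size = batch_size,
                 class_weighted = class_weighted, threshold = threshold,
                 seed = seed),
            class = "train_config")
}

#' Train the fusion network
#'
#' Minimizes class-weighted binary cross-entropy with Adam, early stopping on
#' the validation loss, restoring the best-on-validation weights. The class
#' weight of class c is `N_total / (2 * N_c)`, so balanced classes get
#' weight 1.
#'
#' @param model a `tfo_mlp` from [build_network()].
#' @param pr,mod standardized training feature matrices (n x 10, n x 5).
#' @param y training labels (0/1 or logical).
#' @param pr_val,mod_val,y_val validation data for early stopping.
#' @param config a [train_config()].
#' @return list with `model` (best weights), `history` (data.frame epoch,
#'   train_loss, val_loss), `best_epoch`, `class_weights`.
#' @export
train_network <- function(model, pr, mod, y, pr_val, mod_val, y_val,
                          config = train_config()) {
  stopifnot(inherits(model, "tfo_mlp"), inherits(config, "train_config"))
  pr <- as.matrix(pr); mod <- as.matrix(mod); y <- as.numeric(y)
  pr_val <- as.matrix(pr_val); mod_val <- as.matrix(mod_val)
  y_val <- as.numeric(y_val)
  n <- length(y)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("training set must contain both classes")
  cw <- if (config$class_weighted)
    c(neg = n / (2 * n_neg), pos = n / (2 * n_pos)) else c(neg = 1, pos = 1)
  w <- ifelse(y == 1, cw[["pos"]], cw[["neg"]])
  w_val <- ifelse(y_val == 1, cw[["pos"]], cw[["neg"]])
  mW <- lapply(model$W, function(x) x * 0); vW <- mW
  mb <- lapply(model$b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best_loss <- Inf; best <- model; best_epoch <- 0L
  hist_tr <- hist_val <- numeric(0)
  step <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      batches <- if (is.null(config$batch_size)) list(seq_len(n)) else {
        idx <- sample.int(n)
        split(idx, ceiling(seq_along(idx) / config$batch_size))
      }
      for (bi in batches) {
        fwd <- mlp_forward(model, pr[bi, , drop = FALSE], mod[bi, , drop = FALSE])
        g <- mlp_gradients(model, fwd, y[bi], w[bi], mod[bi, , drop = FALSE])
        step <- step + 1L
        for (k in seq_along(model$W)) {
          gw <- g$W[[k]] + config$weight_decay * model$W[[k]]
          gbk <- g$b[[k]] + config$weight_decay * model$b[[k]]
          mW[[k]] <- beta1 * mW[[k]] + (1 - beta1) * gw
          vW[[k]] <- beta2 * vW[[k]] + (1 - beta2) * gw^2
          mb[[k]] <- beta1 * mb[[k]] + (1 - beta1) * gbk
          vb[[k]] <- beta2 * vb[[k]] + (1 - beta2) * gbk^2
          mhW <- mW[[k]] / (1 - beta1^step); vhW <- vW[[k]] / (1 - beta2^step)
          mhb <- mb[[k]] / (1 - beta1^step); vhb <- vb[[k]] / (1 - beta2^step)
          model$W[[k]] <- model$W[[k]] - config$lr * mhW / (sqrt(vhW) + eps)
          model$b[[k]] <- model$b[[k]] - config$lr * mhb / (sqrt(vhb) + eps)
        }
      }
      tr_loss <- bce_loss(mlp_forward(model, pr, mod)$prob, y, w)
      val_loss <- bce_loss(mlp_forward(model, pr_val, mod_val)$prob, y_val, w_val)
      hist_tr <- c(hist_tr, tr_loss); hist_val <- c(hist_val, val_loss)
      if (val_loss < best_loss - 1e-12) {
        best_loss <- val_loss; best <- model; best_epoch <- epoch
      } else if (epoch - best_epoch >= config$patience) {
        break
      }
    }
  })
  list(model = best,
       history = data.frame(epoch = seq_along(hist_tr),
                            train_loss = hist_tr, val_loss = hist_val),
       best_epoch = best_epoch, class_weights = cw)
}

#' Predict hypoxemia probabilities and labels
#'
#' @param model a trained `tfo_mlp`.
#' @param pr,mod standardized feature matrices.
#' @param threshold decision threshold; a sample is positive (hypoxemic) iff
#'   its probability is `>= threshold`.
#' @return data.frame with columns `prob` and `label`.
#' @export
predict_network <- function(model, pr, mod, threshold = 0.5) {
  stopifnot(inherits(model, "tfo_mlp"))
  pr <- as.matrix(pr); mod <- as.matrix(mod)
  if (max(abs(c(colMeans(pr), colMeans(mod)))) > 2)
    warning("inputs do not look standardized (|column mean| > 2); apply the standardizers first")
  prob <- mlp_forward(model, pr, mod)$prob
  data.frame(prob = prob, label = prob >= threshold)
}

#' Save / load a model as portable JSON
#'
#' Stores layer shapes, weights, biases and (optionally) the fitted
#' standardizers in a plain-text JSON file.
#'
#' @param model a `tfo_mlp`.
#' @param path file path.
#' @param standardizers optional named list of `standardizer` objects.
#' @return `path` invisibly / the restored list.
#' @export
save_model_json <- function(model, path, standardizers = NULL) {
  stopifnot(inherits(model, "tfo_mlp"))
  obj <- list(spec = unclass(model$spec),
              W = lapply(model$W, function(w) list(dim = dim(w), data = as.vector(w))),
              b = model$b,
              standardizers = lapply(standardizers, unclass))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model_json
#' @export
load_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # NULL spec fields (e.g. default init_sd) come back as empty lists or NA
  spec_args <- Filter(function(v) length(v) > 0 && !(length(v) == 1 && is.na(v)),
                      obj$spec)
  spec <- do.call(network_spec, spec_args)
  W <- lapply(seq_len(nrow(obj$W)), function(k)
    matrix(obj$W$data[[k]], obj$W$dim[[k]][1], obj$W$dim[[k]][2]))
  model <- structure(list(W = W, b = obj$b, spec = spec), class = "tfo_mlp")
  st <- NULL
  if (!is.null(obj$standardizers) && length(obj$standardizers))
    st <- lapply(obj$standardizers, function(s) structure(s, class = "standardizer"))
  list(model = model, standardizers = st)
}
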