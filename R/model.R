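#' Model architecture specification
#'
#' A shared dense encoder followed by one or two branch heads; each branch
#' is a stack of dense layers ending in a single linear output node. By
#' default a branch is exactly one dense layer straight to its output node
#' (a linear readout of the shared representation), which extrapolates
#' best from small conformer training sets; hidden branch layers can be
#' added via \code{branch}. Two branches yield two distinct CCS
#' predictions per peptide ion; the branches are ordered (branch 1 targets
#' the smaller conformer under the default loss) and predictions are
#' additionally sorted at emission.
#'
#' @param shared integer vector of shared hidden layer widths.
#' @param branch integer vector of per-branch hidden layer widths before
#'   the final 1-unit linear layer; empty (default) for a linear head.
#' @param n_outputs 1 (single CCS) or 2 (conformer pair).
#' @return list of class \code{model_spec}.
#' @export
model_spec <- function(shared = c(64L, 64L), branch = integer(0),
                       n_outputs = 2L) {
  stopifnot(n_outputs %in% c(1L, 2L), length(shared) >= 1L,
            all(shared >= 1L), all(branch >= 0L))
  structure(list(shared = as.integer(shared), branch = as.integer(branch),
                 n_outputs = as.integer(n_outputs)), class = "model_spec")
}

#' Training configuration
#'
#' @param loss_kind "multiconf" (assignment-aware two-target loss),
#'   "baseline_sum" (sum of the two branches' absolute errors against one
#'   target), or "single" (plain MAE, single-output spec).
#' @param loss_form for \code{loss_kind = "multiconf"}: "sorted" (default;
#'   branch 1 vs the smaller target, branch 2 vs the larger) or
#'   "assignment" (minimum over both pairings).
#' @param split train/validation/test fractions (default 0.81/0.09/0.10).
#' @param max_epochs training epoch cap (default 500).
#' @param patience early-stopping patience on validation loss (default 30
#'   epochs; best-validation weights are restored).
#' @param lr initial Adam learning rate.
#' @param lr_decay multiplicative learning-rate decay applied when the
#'   validation loss has not improved for \code{lr_patience} epochs.
#' @param lr_patience plateau length (epochs) triggering a decay step.
#' @param batch_size minibatch size cap; the effective size is shrunk for
#'   small training sets so every epoch takes at least ~20 optimizer steps.
#' @param seed RNG seed governing initialization, the split and batch
#'   shuffling; mandatory for reproducibility.
#' @return list of class \code{train_config}.
#' @export
train_config <- function(loss_kind = c("multiconf", "baseline_sum", "single"),
                         loss_form = c("sorted", "assignment"),
                         split = c(0.81, 0.09, 0.10),
                         max_epochs = 500L, patience = 50L,
                         lr = 2e-3, lr_decay = 0.5, lr_patience = 15L,
                         batch_size = 32L, seed = 42L) {
  stopifnot(abs(sum(split) - 1) < 1e-9, length(split) == 3L,
            max_epochs >= 1L, patience >= 1L, lr > 0, batch_size >= 1L,
            lr_decay > 0, lr_decay <= 1, lr_patience >= 1L)
  structure(list(loss_kind = match.arg(loss_kind),
                 loss_form = match.arg(loss_form),
                 split = split, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr = lr,
                 lr_decay = lr_decay, lr_patience = as.integer(lr_patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Split records into train/validation/test at the ion level
#'
#' Sizes are \code{floor(0.81 n)} / \code{floor(0.09 n)} / remainder; the
#' permutation is drawn from \code{cfg$seed}, so identical seeds give
#' identical splits. Each (peptidoform, charge) record lands in exactly one
#' subset.
#'
#' @param records curated record table.
#' @param cfg \code{\link{train_config}}.
#' @return list of integer row-index vectors \code{train}, \code{val},
#'   \code{test}.
#' @export
split_dataset <- function(records, cfg = train_config()) {
  n <- nrow(records)
  if (n < 10L) stop("split_dataset: need at least 10 records, got ", n)
  n_train <- floor(cfg$split[1] * n)
  n_val <- floor(cfg$split[2] * n)
  perm <- local({
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(cfg$seed)
    sample.int(n)
  })
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[(n_train + n_val + 1L):n]))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Assignment-aware loss for two conformer targets
#'
#' Under the default "sorted" form the targets are sorted ascending and
#' branch 1 is scored against the smaller target, branch 2 against the
#' larger; the loss is the mean of the two absolute errors. The
#' "assignment" form instead takes the better of the two possible
#' prediction-target pairings. Both forms are invariant to the order in
#' which the targets are supplied, nonnegative, and zero exactly when some
#' assignment matches both targets.
#'
#' @param predictions numeric length-2 vector (or n x 2 matrix).
#' @param targets numeric length-2 vector (or n x 2 matrix), any order.
#' @param form "sorted" or "assignment".
#' @return mean loss (scalar).
#' @export
multiconf_loss <- function(predictions, targets,
                           form = c("sorted", "assignment")) {
  form <- match.arg(form)
  p <- rbind_pair(predictions); t <- rbind_pair(targets)
  if (any(!is.finite(p)) || any(!is.finite(t)))
    stop("multiconf_loss: non-finite inputs")
  ts <- t_sorted(t)
  if (form == "sorted") {
    mean((abs(p[, 1] - ts[, 1]) + abs(p[, 2] - ts[, 2])) / 2)
  } else {
    direct <- abs(p[, 1] - ts[, 1]) + abs(p[, 2] - ts[, 2])
    crossed <- abs(p[, 1] - ts[, 2]) + abs(p[, 2] - ts[, 1])
    mean(pmin(direct, crossed) / 2)
  }
}

#' Baseline loss: sum of both branches' absolute errors against one target
#'
#' Used for the uniconformer-trained and random-conformer-trained baseline
#' models, whose architecture still has two output nodes.
#'
#' @param predictions length-2 vector or n x 2 matrix.
#' @param target scalar or length-n vector.
#' @return mean of \code{|p1 - t| + |p2 - t|} (scalar).
#' @export
baseline_sum_loss <- function(predictions, target) {
  p <- rbind_pair(predictions)
  if (any(!is.finite(p)) || any(!is.finite(target)))
    stop("baseline_sum_loss: non-finite inputs")
  mean(abs(p[, 1] - target) + abs(p[, 2] - target))
}

rbind_pair <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}
t_sorted <- function(t) {
  cbind(pmin(t[, 1], t[, 2]), pmax(t[, 1], t[, 2]))
}

## ---- dense network internals -------------------------------------------

init_layer <- function(n_in, n_out) {
  ## He-style initialization, suited to the ReLU hidden layers
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)),
                  n_in, n_out),
       b = rep(0, n_out))
}

init_params <- function(spec, n_features) {
  widths <- c(n_features, spec$shared)
  shared <- lapply(seq_along(spec$shared), function(i)
    init_layer(widths[i], widths[i + 1L]))
  last <- utils::tail(widths, 1L)
  branches <- lapply(seq_len(spec$n_outputs), function(k) {
    bw <- c(last, spec$branch, 1L)
    lapply(seq_len(length(bw) - 1L), function(i) init_layer(bw[i], bw[i + 1L]))
  })
  list(shared = shared, branches = branches)
}

relu <- function(x) (x + abs(x)) / 2

nn_forward <- function(params, X, cache = FALSE) {
  H <- X
  shared_pre <- list()
  for (i in seq_along(params$shared)) {
    Z <- sweep(H %*% params$shared[[i]]$W, 2L, -params$shared[[i]]$b)
    if (cache) shared_pre[[i]] <- list(input = H, pre = Z)
    H <- relu(Z)
  }
  outs <- matrix(0, nrow(X), length(params$branches))
  branch_pre <- vector("list", length(params$branches))
  for (k in seq_along(params$branches)) {
    B <- H
    pres <- list()
    layers <- params$branches[[k]]
    for (i in seq_along(layers)) {
      Z <- sweep(B %*% layers[[i]]$W, 2L, -layers[[i]]$b)
      if (cache) pres[[i]] <- list(input = B, pre = Z)
      B <- if (i < length(layers)) relu(Z) else Z
    }
    outs[, k] <- B[, 1L]
    if (cache) branch_pre[[k]] <- pres
  }
  if (cache) list(out = outs, shared = shared_pre, branch = branch_pre,
                  H_shared = H)
  else outs
}

## dY: n x n_outputs gradient of the loss wrt network outputs
nn_backward <- function(params, fw, dY) {
  grads <- list(shared = vector("list", length(params$shared)),
                branches = vector("list", length(params$branches)))
  dH_shared <- matrix(0, nrow(dY), ncol(fw$H_shared))
  for (k in seq_along(params$branches)) {
    layers <- params$branches[[k]]
    pres <- fw$branch[[k]]
    delta <- matrix(dY[, k], ncol = 1L)
    gb <- vector("list", length(layers))
    for (i in rev(seq_along(layers))) {
      if (i < length(layers)) delta <- delta * (pres[[i]]$pre > 0)
      gb[[i]] <- list(W = crossprod(pres[[i]]$input, delta),
                      b = colSums(delta))
      delta <- delta %*% t(layers[[i]]$W)
    }
    grads$branches[[k]] <- gb
    dH_shared <- dH_shared + delta
  }
  delta <- dH_shared
  for (i in rev(seq_along(params$shared))) {
    delta <- delta * (fw$shared[[i]]$pre > 0)
    grads$shared[[i]] <- list(W = crossprod(fw$shared[[i]]$input, delta),
                              b = colSums(delta))
    delta <- delta %*% t(params$shared[[i]]$W)
  }
  grads
}

## loss value and output gradient in scaled space; Y n x k, targets n x m
loss_and_grad <- function(Y, targets, loss_kind, loss_form) {
  n <- nrow(Y)
  if (loss_kind == "single") {
    r <- Y[, 1L] - targets[, 1L]
    list(loss = mean(abs(r)), dY = matrix(sign(r) / n, ncol = 1L))
  } else if (loss_kind == "baseline_sum") {
    r1 <- Y[, 1L] - targets[, 1L]; r2 <- Y[, 2L] - targets[, 1L]
    list(loss = mean(abs(r1) + abs(r2)),
         dY = cbind(sign(r1), sign(r2)) / n)
  } else {  # multiconf
    ts <- t_sorted(targets)
    if (loss_form == "sorted") {
      r1 <- Y[, 1L] - ts[, 1L]; r2 <- Y[, 2L] - ts[, 2L]
      list(loss = mean((abs(r1) + abs(r2)) / 2),
           dY = cbind(sign(r1), sign(r2)) / (2 * n))
    } else {
      d1 <- abs(Y[, 1L] - ts[, 1L]) + abs(Y[, 2L] - ts[, 2L])
      d2 <- abs(Y[, 1L] - ts[, 2L]) + abs(Y[, 2L] - ts[, 1L])
      use_direct <- d1 <= d2
      t1 <- ifelse(use_direct, ts[, 1L], ts[, 2L])
      t2 <- ifelse(use_direct, ts[, 2L], ts[, 1L])
      r1 <- Y[, 1L] - t1; r2 <- Y[, 2L] - t2
      list(loss = mean(pmin(d1, d2) / 2),
           dY = cbind(sign(r1), sign(r2)) / (2 * n))
    }
  }
}

## flat walk over parameter tensors, for Adam and weight copying
walk_params <- function(params, fn) {
  for (i in seq_along(params$shared)) {
    params$shared[[i]]$W <- fn(paste0("sW", i), params$shared[[i]]$W)
    params$shared[[i]]$b <- fn(paste0("sb", i), params$shared[[i]]$b)
  }
  for (k in seq_along(params$branches)) {
    for (i in seq_along(params$branches[[k]])) {
      params$branches[[k]][[i]]$W <-
        fn(paste0("B", k, "W", i), params$branches[[k]][[i]]$W)
      params$branches[[k]][[i]]$b <-
        fn(paste0("B", k, "b", i), params$branches[[k]][[i]]$b)
    }
  }
  params
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  get_grad <- function(key) {
    if (startsWith(key, "s")) {
      i <- as.integer(sub("s[Wb]", "", key))
      if (grepl("^sW", key)) grads$shared[[i]]$W else grads$shared[[i]]$b
    } else {
      k <- as.integer(sub("^B([0-9]+).*", "\\1", key))
      i <- as.integer(sub("^B[0-9]+[Wb]", "", key))
      if (grepl("W", key)) grads$branches[[k]][[i]]$W
      else grads$branches[[k]][[i]]$b
    }
  }
  new_params <- walk_params(params, function(key, value) {
    g <- get_grad(key)
    if (is.null(state$m[[key]])) {
      state$m[[key]] <<- g * 0
      state$v[[key]] <<- g * 0
    }
    state$m[[key]] <<- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <<- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / (1 - beta1^tt)
    vhat <- state$v[[key]] / (1 - beta2^tt)
    value - lr * mhat / (sqrt(vhat) + eps)
  })
  list(params = new_params, state = state)
}

## ---- target assembly ----------------------------------------------------

model_targets <- function(records, loss_kind) {
  if (loss_kind == "multiconf") {
    k <- vapply(records$ccs_values, length, integer(1))
    if (any(k != 2L))
      stop("multiconf training requires exactly two CCS values per record; ",
           sum(k != 2L), " record(s) violate this (filter first)")
    t(vapply(records$ccs_values, function(v) sort(v), numeric(2)))
  } else if (loss_kind == "baseline_sum") {
    if ("target_ccs" %in% names(records)) {
      matrix(records$target_ccs, ncol = 1L)
    } else {
      k <- vapply(records$ccs_values, length, integer(1))
      if (any(k != 1L))
        stop("baseline_sum training needs a single target per record; ",
             "use select_random_conformer() for multiconformer records")
      matrix(vapply(records$ccs_values, `[`, numeric(1), 1L), ncol = 1L)
    }
  } else {
    k <- vapply(records$ccs_values, length, integer(1))
    if (any(k != 1L)) stop("single-output training needs one CCS per record")
    matrix(vapply(records$ccs_values, `[`, numeric(1), 1L), ncol = 1L)
  }
}

#' Pick one conformer per multiconformer record as a single training target
#'
#' The choice is uniform over the record's conformers, seeded, and recorded
#' in the returned \code{target_ccs} column for reproducibility.
#'
#' @param records multiconformer record table.
#' @param seed RNG seed.
#' @return copy of \code{records} with a \code{target_ccs} column.
#' @export
select_random_conformer <- function(records, seed = 42L) {
  out <- data.table::copy(data.table::as.data.table(records))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  out[, target_ccs := vapply(ccs_values, function(v)
    v[sample.int(length(v), 1L)], numeric(1))]
  out
}

## ---- training -----------------------------------------------------------

#' Train a CCS regression model
#'
#' Trains the dense network defined by \code{spec} with minibatch Adam on
#' standardized features and targets, with early stopping on validation
#' loss (best-validation weights restored). All randomness (initialization,
#' split, shuffling) derives from \code{cfg$seed}, so training is fully
#' reproducible.
#'
#' @param records curated record table (list-column \code{ccs_values};
#'   optionally \code{target_ccs} for \code{loss_kind = "baseline_sum"}).
#' @param spec \code{\link{model_spec}}; its \code{n_outputs} must match the
#'   loss (2 for multiconf/baseline_sum, 1 for single).
#' @param cfg \code{\link{train_config}}.
#' @param warm_start optional parameter list used instead of fresh
#'   initialization (used by \code{\link{fine_tune}}).
#' @param splits optional precomputed \code{\link{split_dataset}} result.
#' @return object of class \code{ccs_model}: list with \code{spec},
#'   \code{params}, feature/target scaling, \code{history} (per-epoch
#'   train/val loss), \code{splits}, \code{cfg}.
#' @export
train_ccs_model <- function(records, spec = model_spec(), cfg = train_config(),
                            warm_start = NULL, splits = NULL) {
  records <- data.table::as.data.table(records)
  expected_out <- if (cfg$loss_kind == "single") 1L else 2L
  if (spec$n_outputs != expected_out)
    stop("spec$n_outputs = ", spec$n_outputs, " inconsistent with loss '",
         cfg$loss_kind, "'")
  if (is.null(splits)) splits <- split_dataset(records, cfg)

  X <- featurize_ions(records)
  Tm <- model_targets(records, cfg$loss_kind)

  mu <- colMeans(X[splits$train, , drop = FALSE])
  sdv <- apply(X[splits$train, , drop = FALSE], 2L, stats::sd)
  sdv[sdv < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  y_mu <- mean(Tm[splits$train, ])
  y_sd <- stats::sd(as.numeric(Tm[splits$train, ]))
  if (!is.finite(y_sd) || y_sd < 1e-8) y_sd <- 1
  Ts <- (Tm - y_mu) / y_sd

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  params <- if (is.null(warm_start)) init_params(spec, ncol(X))
            else warm_start
  state <- new.env()
  state$t <- 0L; state$m <- list(); state$v <- list()

  tr <- splits$train; va <- splits$val
  best_val <- Inf; best_params <- params; wait <- 0L; lr_wait <- 0L
  lr <- cfg$lr
  hist_tr <- numeric(0); hist_va <- numeric(0)
  ## small datasets get small batches so each epoch still makes progress
  bs <- max(4L, min(cfg$batch_size, length(tr) %/% 20L))
  nb <- max(1L, ceiling(length(tr) / bs))

  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample(tr)
    for (b in seq_len(nb)) {
      rows <- idx[((b - 1L) * bs + 1L):min(b * bs, length(idx))]
      rows <- rows[!is.na(rows)]
      if (!length(rows)) next
      fw <- nn_forward(params, Xs[rows, , drop = FALSE], cache = TRUE)
      lg <- loss_and_grad(fw$out, Ts[rows, , drop = FALSE],
                          cfg$loss_kind, cfg$loss_form)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      grads <- nn_backward(params, fw, lg$dY)
      up <- adam_update(params, grads, state, lr)
      params <- up$params; state <- up$state
    }
    tr_loss <- loss_and_grad(nn_forward(params, Xs[tr, , drop = FALSE]),
                             Ts[tr, , drop = FALSE],
                             cfg$loss_kind, cfg$loss_form)$loss
    va_loss <- loss_and_grad(nn_forward(params, Xs[va, , drop = FALSE]),
                             Ts[va, , drop = FALSE],
                             cfg$loss_kind, cfg$loss_form)$loss
    hist_tr <- c(hist_tr, tr_loss); hist_va <- c(hist_va, va_loss)
    if (va_loss < best_val - 1e-7) {
      best_val <- va_loss; best_params <- params; wait <- 0L; lr_wait <- 0L
    } else {
      wait <- wait + 1L
      lr_wait <- lr_wait + 1L
      if (wait >= cfg$patience) break
      if (lr_wait >= cfg$lr_patience && lr > 1e-5) {
        lr <- lr * cfg$lr_decay
        lr_wait <- 0L
      }
    }
  }

  structure(list(
    spec = spec, params = best_params,
    feat_center = mu, feat_scale = sdv, y_center = y_mu, y_scale = y_sd,
    history = data.table::data.table(epoch = seq_along(hist_tr),
                                     train_loss = hist_tr,
                                     val_loss = hist_va),
    best_val = best_val, splits = splits, cfg = cfg
  ), class = "ccs_model")
}

#' Fine-tune a two-output model from a pretrained single-output model
#'
#' The pretrained model's shared encoder weights are copied into the new
#' model's shared layers (verified shape by shape); the branch heads are
#' freshly initialized from \code{cfg$seed}, with each branch's final
#' output layer zeroed so that the first optimizer steps cannot disturb
#' the pretrained representation (the gradient into the shared layers is
#' zero while a head is zero). All parameters remain trainable.
#'
#' @param pretrained a single-output \code{ccs_model}.
#' @param records multiconformer record table (exactly two CCS values each).
#' @param spec two-output \code{\link{model_spec}} whose shared widths match
#'   the pretrained model's.
#' @param cfg \code{\link{train_config}} (loss_kind "multiconf").
#' @param splits optional precomputed split.
#' @return trained two-output \code{ccs_model}.
#' @export
fine_tune <- function(pretrained, records, spec = model_spec(n_outputs = 2L),
                      cfg = train_config(), splits = NULL) {
  stopifnot(inherits(pretrained, "ccs_model"))
  if (!identical(pretrained$spec$shared, spec$shared)) {
    stop("shared layer shape mismatch: pretrained (",
         paste(pretrained$spec$shared, collapse = ","),
         ") vs requested (", paste(spec$shared, collapse = ","), ")")
  }
  n_feat <- length(pretrained$feat_center)
  init <- local({
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(cfg$seed)
    init_params(spec, n_feat)
  })
  init$shared <- pretrained$params$shared
  for (k in seq_along(init$branches)) {
    last <- length(init$branches[[k]])
    init$branches[[k]][[last]]$W[] <- 0
    init$branches[[k]][[last]]$b[] <- 0
  }
  train_ccs_model(records, spec, cfg, warm_start = init, splits = splits)
}

#' Predict CCS values for peptide ions
#'
#' @param object trained \code{ccs_model}.
#' @param ions data.frame with \code{peptidoform}, \code{charge}.
#' @param ... unused.
#' @return data.table with \code{peptidoform}, \code{charge} and either
#'   \code{ccs} (single-output) or \code{ccs_small}, \code{ccs_large}
#'   (two-output, sorted so \code{ccs_small <= ccs_large}). Ions that fail
#'   to encode get NA predictions with a warning; the batch continues.
#' @export
predict.ccs_model <- function(object, ions, ...) {
  ions <- data.table::as.data.table(ions)
  n <- nrow(ions)
  X <- matrix(NA_real_, n, length(object$feat_center))
  ok <- logical(n)
  for (i in seq_len(n)) {
    row <- tryCatch(featurize_ions(ions[i]), error = function(e) {
      warning("skipping unencodable ion ", ions$peptidoform[i], " (",
              conditionMessage(e), ")", call. = FALSE)
      NULL
    })
    if (!is.null(row)) { X[i, ] <- row; ok[i] <- TRUE }
  }
  out <- data.table::data.table(peptidoform = ions$peptidoform,
                                charge = ions$charge)
  preds <- matrix(NA_real_, n, object$spec$n_outputs)
  if (any(ok)) {
    Xs <- sweep(sweep(X[ok, , drop = FALSE], 2L, object$feat_center), 2L,
                object$feat_scale, "/")
    Y <- nn_forward(object$params, Xs) * object$y_scale + object$y_center
    preds[ok, ] <- Y
  }
  if (object$spec$n_outputs == 1L) {
    out[, ccs := preds[, 1L]]
  } else {
    out[, ccs_small := pmin(preds[, 1L], preds[, 2L])]
    out[, ccs_large := pmax(preds[, 1L], preds[, 2L])]
  }
  out
}

#' @export
print.ccs_model <- function(x, ...) {
  cat("CCS model: shared [", paste(x$spec$shared, collapse = ", "),
      "], ", x$spec$n_outputs, " output(s)\n", sep = "")
  cat("  trained ", nrow(x$history), " epoch(s), best val loss ",
      signif(x$best_val, 4), " (scaled units)\n", sep = "")
  invisible(x)
}

#' Evaluate predictions against curated records
#'
#' Two modes. \code{"paired"}: two predictions against two sorted observed
#' conformer CCS values, metrics per output branch. \code{"closest"}: two
#' predictions against a single observed CCS, error taken as the smaller of
#' the two absolute errors (the rescoring protocol). Reported per output:
#' MAE, median relative error, Pearson r (NA for constant targets), and in
#' paired mode the fraction of predictions with absolute error below the
#' median observed inter-conformer gap.
#'
#' @param predictions data.table from \code{\link{predict.ccs_model}} with
#'   \code{ccs_small}, \code{ccs_large}.
#' @param records record table; paired mode uses two-value
#'   \code{ccs_values}, closest mode a single value (or \code{target_ccs}).
#' @param mode "paired" or "closest".
#' @return data.table of metrics (one row per output in paired mode, one
#'   row in closest mode).
#' @export
evaluate_predictions <- function(predictions, records,
                                 mode = c("paired", "closest")) {
  mode <- match.arg(mode)
  if (nrow(predictions) == 0L) stop("evaluate_predictions: empty input")
  p <- cbind(predictions$ccs_small, predictions$ccs_large)
  safe_cor <- function(a, b) {
    if (length(a) < 2L || anyNA(c(a, b))) return(NA_real_)
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
    stats::cor(a, b)
  }
  if (mode == "paired") {
    Tm <- t(vapply(records$ccs_values, function(v) sort(v)[1:2], numeric(2)))
    gap_median <- stats::median(Tm[, 2] - Tm[, 1])
    data.table::rbindlist(lapply(1:2, function(k) {
      err <- p[, k] - Tm[, k]
      data.table::data.table(
        output = c("small", "large")[k],
        mae = mean(abs(err)),
        median_rel_err = stats::median(abs(err) / Tm[, k]),
        pearson_r = safe_cor(p[, k], Tm[, k]),
        frac_below_median_gap = mean(abs(err) < gap_median))
    }))
  } else {
    tv <- if ("target_ccs" %in% names(records)) records$target_ccs
          else vapply(records$ccs_values, `[`, numeric(1), 1L)
    err <- pmin(abs(p[, 1] - tv), abs(p[, 2] - tv))
    closest <- ifelse(abs(p[, 1] - tv) <= abs(p[, 2] - tv), p[, 1], p[, 2])
    data.table::data.table(
      output = "closest",
      mae = mean(err),
      median_rel_err = stats::median(err / tv),
      pearson_r = safe_cor(closest, tv),
      frac_below_median_gap = NA_real_)
  }
}
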