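# Deep Cox proportional hazards: model fitting under the baseline,
# fairness-penalised and group-DRO objectives.

#' Training hyperparameters
#'
#' Defaults follow common practice for small tabular survival networks:
#' SGD with momentum 0.9, initial learning rate 0.01 decayed by a factor
#' of 0.1 every 5 epochs, weight decay 0.001, batch size 128, at most 100
#' epochs with early stopping (patience 5) on the validation objective.
#'
#' @param learning_rate Initial SGD learning rate.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 weight-decay coefficient.
#' @param lr_decay_factor,lr_decay_every Step learning-rate schedule:
#'   multiply by `lr_decay_factor` every `lr_decay_every` epochs.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param fair_lambda Weight of the group-mean fairness penalty (only
#'   used by the `"fair"` objective).
#' @param dro_rule Mini-batch update rule for the `"groupdro"`
#'   objective: `"eg"` (default) keeps exponentiated-gradient weights
#'   over the group terms (including the augmented full-cohort group),
#'   the standard group-DRO online rule, which is far less noisy than a
#'   per-batch hard max when small groups contribute only one or two
#'   events per batch; `"hardmax"` steps through the single worst
#'   group's term each batch. Reported and validation objectives are
#'   always the worst-case (max) value.
#' @param dro_step Exponentiated-gradient step size for
#'   `dro_rule = "eg"`.
#' @param seed Integer seed controlling initialisation and batch
#'   shuffling.
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(learning_rate = 0.01, momentum = 0.9,
                       weight_decay = 0.001, lr_decay_factor = 0.1,
                       lr_decay_every = 5L, batch_size = 128L,
                       max_epochs = 100L, patience = 5L,
                       fair_lambda = 1, dro_rule = c("eg", "hardmax"),
                       dro_step = 0.1, seed = 1L) {
  dro_rule <- match.arg(dro_rule)
  stopifnot(learning_rate > 0, momentum >= 0, weight_decay >= 0,
            lr_decay_factor > 0, lr_decay_every >= 1, batch_size >= 2,
            max_epochs >= 1, patience >= 1, fair_lambda >= 0,
            dro_step > 0)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 fair_lambda = fair_lambda, dro_rule = dro_rule,
                 dro_step = dro_step, seed = as.integer(seed)),
            class = "train_spec")
}

# objective value on a held-out cohort (full-cohort risk sets within it)
validation_objective <- function(objective, scores, cohort, fair_lambda) {
  base <- npll_terms(scores, cohort$time, cohort$event)
  switch(objective,
    baseline = base,
    fair = base + fair_lambda * fair_penalty(scores, cohort$group),
    groupdro = groupdro_terms(scores, cohort$time, cohort$event,
                              cohort$group)$value)
}

#' Fit a deep Cox proportional hazards model
#'
#' Trains a feed-forward log-hazard network by mini-batch SGD under one
#' of three objectives: `"baseline"` (mean negative Cox partial
#' log-likelihood), `"fair"` (baseline plus `fair_lambda` times the
#' group-mean penalty of [fair_penalty()]), or `"groupdro"` (the
#' worst-group objective of [groupdro_objective()], hard-max rule: each
#' step's gradient flows through the currently worst group's term, with
#' the augmented full-cohort group always in the running).
#'
#' Risk sets are computed within each mini-batch during stochastic
#' training (standard deep-Cox practice); every reported or validation
#' loss uses full-cohort risk sets within its cohort. Mini-batches with
#' zero events are skipped and counted, never fatal. Early stopping
#' monitors the model's own objective on the validation split and the
#' best-validation weights are restored. The sensitive attribute is used
#' only inside the fairness objectives, never as a network input.
#'
#' @param cohort A [survival_cohort()]; split internally unless `valid`
#'   is supplied.
#' @param objective `"baseline"`, `"fair"` or `"groupdro"`.
#' @param model A [model_spec()].
#' @param train A [train_spec()].
#' @param valid Optional pre-split validation `survival_cohort`; when
#'   supplied, `cohort` is used as the training split as-is.
#' @param train_fraction Internal split fraction when `valid` is `NULL`.
#' @param standardize Z-score continuous covariates with training-split
#'   statistics (stored and re-applied by `predict`).
#' @param stratify_batches_by_group Draw mini-batches stratified by group
#'   so small groups appear in every batch (off by default).
#' @param verbose Print a per-epoch line.
#' @return An object of class `dcph` with the fitted network, the
#'   preprocessing statistics, the per-epoch `log` (a data.frame with
#'   train/validation objective, learning rate and, for groupdro, the
#'   worst group), the Breslow baseline hazard fitted on the training
#'   split, and the specs used.
#' @examples
#' sim <- simulate_cohort(simulation_config(
#'   n = 400, group_probs = c(0.6, 0.4), beta = c(0.8, -0.5),
#'   group_log_hr = c(0, 0.3), censor_rate = 0.2, seed = 7))
#' fit <- dcph(sim$cohort, "baseline",
#'             model = model_spec(hidden_layers = 1, hidden_width = 8),
#'             train = train_spec(max_epochs = 3, seed = 7))
#' print(fit)
#' @export
dcph <- function(cohort, objective = c("baseline", "fair", "groupdro"),
                 model = model_spec(), train = train_spec(),
                 valid = NULL, train_fraction = 0.8, standardize = TRUE,
                 stratify_batches_by_group = FALSE, verbose = FALSE) {
  objective <- match.arg(objective)
  stopifnot(inherits(cohort, "survival_cohort"))
  if (is.null(valid)) {
    sp <- split_cohort(cohort, train_fraction, seed = train$seed)
    tr <- sp$train; va <- sp$valid
  } else {
    tr <- cohort; va <- valid
  }
  if (standardize) {
    st <- standardize_covariates(tr, va)
    tr <- st$train; va <- st$valid
    center <- st$center; scale <- st$scale
  } else {
    p0 <- ncol(tr$covariates)
    center <- rep(0, p0); scale <- rep(1, p0)
  }
  X <- tr$covariates
  model$input_dim <- ncol(X)
  if (model$input_dim < 1L) stop("cohort has no covariates to learn from")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(train$seed)
  net <- mlp_init(model)
  state <- sgd_state(net)
  n <- nrow(X)
  lam <- train$fair_lambda

  best <- list(net = net, value = Inf, epoch = 0L)
  log_rows <- list()
  stall <- 0L
  skipped_batches <- 0L
  # exponentiated-gradient weights over group terms (groupdro, rule "eg"):
  # the augmented full-cohort group "0" plus every group with events
  dro_ids <- c("0", as.character(sort(unique(tr$group[tr$event == 1]))))
  dro_w <- stats::setNames(rep(1 / length(dro_ids), length(dro_ids)),
                           dro_ids)

  for (epoch in seq_len(train$max_epochs)) {
    lr <- train$learning_rate *
      train$lr_decay_factor^((epoch - 1L) %/% train$lr_decay_every)
    idx <- if (stratify_batches_by_group)
      stratified_shuffle(tr$group) else sample.int(n)
    nb <- ceiling(n / train$batch_size)
    worst_tab <- integer(0)
    for (b in seq_len(nb)) {
      bi <- idx[(((b - 1L) * train$batch_size + 1L):min(b * train$batch_size, n))]
      bt <- tr$time[bi]; be <- tr$event[bi]; bg <- tr$group[bi]
      if (sum(be) == 0L) { skipped_batches <- skipped_batches + 1L; next }
      fw <- mlp_forward(net, X[bi, , drop = FALSE], cache = TRUE)
      if (objective == "groupdro") {
        if (train$dro_rule == "hardmax") {
          gt <- groupdro_terms(fw$scores, bt, be, bg, gradient = TRUE)
          dscore <- gt$grad
          worst_tab <- c(worst_tab, gt$worst_group)
        } else {
          present <- intersect(dro_ids,
                               c("0", as.character(unique(bg[be == 1]))))
          vals <- numeric(0); grads_k <- list()
          for (id in present) {
            sub <- if (id == "0") NULL else bg == as.integer(id)
            tk <- npll_terms(fw$scores, bt, be, subset = sub,
                             gradient = TRUE)
            vals[id] <- tk$value
            grads_k[[id]] <- tk$grad
          }
          dro_w[present] <- dro_w[present] * exp(train$dro_step * vals)
          dro_w <- dro_w / sum(dro_w)
          dscore <- Reduce(`+`, Map(`*`, dro_w[present], grads_k))
          worst_tab <- c(worst_tab, as.integer(names(which.max(vals))))
        }
      } else {
        dscore <- npll_terms(fw$scores, bt, be, gradient = TRUE)$grad
        if (objective == "fair")
          dscore <- dscore + lam * fair_penalty_grad(fw$scores, bg)
      }
      grads <- mlp_backward(net, fw, dscore)
      upd <- sgd_step(net, grads, state, lr, train$momentum,
                      train$weight_decay)
      net <- upd$net; state <- upd$state
    }
    tr_obj <- validation_objective(objective,
                                   mlp_forward(net, X), tr, lam)
    va_obj <- validation_objective(objective,
                                   mlp_forward(net, va$covariates), va, lam)
    worst <- if (objective == "groupdro" && length(worst_tab))
      as.integer(names(which.max(table(worst_tab)))) else NA_integer_
    log_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                    train_objective = tr_obj,
                                    valid_objective = va_obj,
                                    worst_group = worst)
    if (verbose)
      cat(sprintf("epoch %3d lr %.1e train %.5f valid %.5f\n",
                  epoch, lr, tr_obj, va_obj))
    if (va_obj < best$value - 1e-10) {
      best <- list(net = net, value = va_obj, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= train$patience) break
    }
  }

  net <- best$net
  tr_scores <- mlp_forward(net, X)
  fit <- structure(list(
    net = net, objective = objective, model_spec = model,
    train_spec = train, center = center, scale = scale,
    feature_names = tr$feature_names, group_names = tr$group_names,
    log = do.call(rbind, log_rows), best_epoch = best$epoch,
    valid_objective = best$value, skipped_batches = skipped_batches,
    baseline_hazard = breslow_fit(tr_scores, tr),
    train_cohort = tr, valid_cohort = va), class = "dcph")
  fit
}

# shuffle subject indices so every batch interleaves all groups
stratified_shuffle <- function(group) {
  parts <- split(seq_along(group), group)
  parts <- lapply(parts, sample)
  ord <- order(unlist(lapply(parts, function(ix) seq_along(ix) / length(ix))))
  unlist(parts, use.names = FALSE)[ord]
}

#' @export
print.dcph <- function(x, ...) {
  cat("<dcph> objective: ", x$objective, "\n", sep = "")
  sp <- x$model_spec
  cat("  network: ", sp$input_dim, " -> ",
      if (sp$hidden_layers == 0L && sp$activation == "linear") "1 (linear)"
      else paste0(paste(rep(sp$hidden_width, sp$hidden_layers + 1L),
                        collapse = "-"), " -> 1 (", sp$activation, ")"),
      "\n", sep = "")
  cat("  trained ", nrow(x$log), " epochs (best at ", x$best_epoch,
      "), validation objective ", sprintf("%.5f", x$valid_objective),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.dcph <- function(object, ...) {
  print(object)
  cat("  skipped zero-event batches:", object$skipped_batches, "\n")
  cat("  training log (last 5 epochs):\n")
  print(utils::tail(object$log, 5), row.names = FALSE)
  invisible(object)
}

#' Predict from a fitted deep Cox model
#'
#' @param object A [dcph()] fit.
#' @param newdata A `survival_cohort` or a numeric covariate matrix with
#'   the training layout (raw scale; the stored standardisation is
#'   applied).
#' @param type `"lp"` (log-hazard scores, the default), `"risk"`
#'   (`exp` of the scores) or `"survival"` (absolute survival curves via
#'   the stored Breslow baseline hazard).
#' @param times Evaluation grid for `type = "survival"`.
#' @param ... Unused.
#' @return A numeric vector for `"lp"`/`"risk"`; a `survival_curve` for
#'   `"survival"`.
#' @export
predict.dcph <- function(object, newdata,
                         type = c("lp", "risk", "survival"),
                         times = NULL, ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "survival_cohort")) newdata$covariates
       else as.matrix(newdata)
  if (ncol(X) != object$model_spec$input_dim)
    stop("newdata has ", ncol(X), " covariates; model expects ",
         object$model_spec$input_dim)
  X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  scores <- mlp_forward(object$net, X)
  switch(type,
         lp = scores,
         risk = exp(scores),
         survival = predict_survival(scores, object$baseline_hazard, times))
}

#' Martingale residuals of a fitted deep Cox model
#'
#' `delta_i - H0(o_i) * exp f(x_i)` with the stored Breslow cumulative
#' baseline hazard.
#'
#' @param object A [dcph()] fit.
#' @param cohort Cohort to compute residuals on (default: the training
#'   split, already standardised internally).
#' @param ... Unused.
#' @return Numeric vector of residuals.
#' @export
residuals.dcph <- function(object, cohort = NULL, ...) {
  if (is.null(cohort)) {
    ch <- object$train_cohort
    scores <- mlp_forward(object$net, ch$covariates)
  } else {
    ch <- cohort
    scores <- predict.dcph(object, cohort)
  }
  H0 <- cumulative_hazard_at(object$baseline_hazard, ch$time)
  ch$event - H0 * exp(scores)
}

#' Plot the training history of a deep Cox model
#'
#' @param x A [dcph()] fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.dcph <- function(x, ...) {
  graphics::matplot(x$log$epoch,
                    cbind(x$log$train_objective, x$log$valid_objective),
                    type = "b", pch = c(1, 19), lty = 1,
                    col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = paste(x$objective, "objective"),
                    ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"),
                   col = c("grey40", "firebrick"), pch = c(1, 19), lty = 1,
                   bty = "n")
  invisible(x)
}
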