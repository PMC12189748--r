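# Internal classifier families for detectability and TSTR protocols.
# Families: "lr" (ridge logistic/multinomial regression via glmnet, penalty
# comparable to unit-strength L2), "mlp" (one hidden layer of 100 units,
# trained with Adam on cross-entropy by the package's own engine), and "knn"
# (k-nearest neighbours, k = 5). A random-forest family is not available in
# this environment; knn stands in as the third, nonparametric family.

fit_classifier <- function(kind, X, y, seed = 1) {
  y <- factor(y)
  if (nlevels(y) < 2)
    se_stop("classifier training needs at least 2 classes",
            class = "synexpr_degenerate_error")
  set.seed(seed)
  if (kind == "lr") {
    fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
    fit <- glmnet::glmnet(X, y, family = fam, alpha = 0,
                          lambda = 1 / nrow(X), standardize = TRUE)
    list(kind = kind, fit = fit, levels = levels(y))
  } else if (kind == "mlp") {
    K <- nlevels(y)
    net <- new_mlp(c(ncol(X), 100, K), out_act = "identity")
    params <- list(W = net$W, b = net$b)
    state <- adam_init(params)
    Y <- diag(K)[as.integer(y), , drop = FALSE]
    mu <- colMeans(X); sdv <- apply(X, 2, sd); sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    nobs <- nrow(Xs)
    for (ep in seq_len(40)) {
      ord <- sample.int(nobs)
      for (s in seq(1, nobs, by = 64)) {
        idx <- ord[s:min(s + 63, nobs)]
        net$W <- params$W; net$b <- params$b
        fw <- mlp_forward(net, Xs[idx, , drop = FALSE], cache = TRUE)
        logits <- fw$out
        p <- exp(logits - apply(logits, 1, max))
        p <- p / rowSums(p)
        d <- (p - Y[idx, , drop = FALSE]) / length(idx)
        bw <- mlp_backward(net, fw$cache, d)
        upd <- adam_step(params, list(W = bw$dW, b = bw$db), state, lr = 1e-3)
        params <- upd$params; state <- upd$state
      }
    }
    net$W <- params$W; net$b <- params$b
    list(kind = kind, net = net, mu = mu, sd = sdv, levels = levels(y))
  } else if (kind == "knn") {
    list(kind = kind, X = X, y = as.integer(y), levels = levels(y), k = 5)
  } else se_stop(paste("unknown classifier", kind))
}

predict_classifier <- function(model, Xnew) {
  if (model$kind == "lr") {
    pr <- predict(model$fit, Xnew, type = "class")
    factor(as.character(pr), levels = model$levels)
  } else if (model$kind == "mlp") {
    Xs <- sweep(sweep(Xnew, 2, model$mu), 2, model$sd, "/")
    logits <- mlp_forward(model$net, Xs)$out
    factor(model$levels[max.col(logits, ties.method = "first")],
           levels = model$levels)
  } else {
    D <- cross_dist(Xnew, model$X)
    k <- min(model$k, ncol(D))
    pred <- apply(D, 1, function(dr) {
      nb <- model$y[order(dr)[seq_len(k)]]
      as.integer(names(which.max(table(nb))))
    })
    factor(model$levels[pred], levels = model$levels)
  }
}

# squared-euclidean-free cross distances (rows of A vs rows of B)
cross_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# macro-averaged F1 over the classes present in the truth
macro_f1 <- function(truth, pred) {
  lev <- levels(factor(truth))
  f1 <- vapply(lev, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

balanced_accuracy <- function(truth, pred) {
  lev <- levels(factor(truth))
  mean(vapply(lev, function(cl) {
    idx <- truth == cl
    if (!any(idx)) return(NA_real_)
    mean(pred[idx] == cl)
  }, numeric(1)), na.rm = TRUE)
}

# binary F1 with `positive` as the positive class
binary_f1 <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}
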