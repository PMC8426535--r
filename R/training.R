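#' Assign records to cross-validation folds
#'
#' @param records Record tibble.
#' @param k Number of folds (default 8).
#' @param mode `"random"`: seeded shuffle, fold sizes differing by at most
#'   one.  `"cluster"`: whole sequence-identity clusters are kept inside
#'   one fold (cluster ids must be precomputed, e.g. by CD-HIT, and carried
#'   in `cluster_col`); folds are balanced greedily by size.
#' @param seed Integer seed.
#' @param cluster_col Name of the cluster-id column for cluster mode.
#' @return Tibble `accession, fold` of class `loc_folds`.
#' @export
make_folds <- function(records, k = 8, mode = c("random", "cluster"),
                       seed = 1L, cluster_col = "cluster") {
  mode <- match.arg(mode)
  n <- nrow(records)
  if (k < 2) .stopf("k must be >= 2")
  if (k > n) .stopf("k = %d exceeds the number of records (%d)", k, n)
  set.seed(seed)
  if (mode == "random") {
    fold <- rep_len(seq_len(k), n)[sample.int(n)]
  } else {
    if (!cluster_col %in% names(records))
      .stopf("cluster mode requires a '%s' column on every record", cluster_col)
    cl <- records[[cluster_col]]
    if (anyNA(cl)) .stopf("cluster mode requires a '%s' column on every record", cluster_col)
    sizes <- table(cl)
    ord <- sample(names(sizes))                       # seeded cluster order
    ord <- ord[order(-as.integer(sizes[ord]))]        # largest first, ties seeded
    load <- rep(0L, k)
    assign <- integer(length(ord)); names(assign) <- ord
    for (cname in ord) {
      j <- which.min(load)
      assign[cname] <- j
      load[j] <- load[j] + as.integer(sizes[[cname]])
    }
    fold <- assign[as.character(cl)]
  }
  structure(tibble(accession = records$accession, fold = as.integer(fold)),
            class = c("loc_folds", class(tibble())))
}

#' Build a training dataset from records
#'
#' Encodes every record (BLOSUM62 fallback profile) and derives its network
#' targets from the hierarchy.  Records with suborganelle labels are
#' level-2 samples; records with only organelle labels are level-1 samples.
#'
#' @param records Record tibble.
#' @param hierarchy A `loc_hierarchy`.
#' @param cfg A `loc_config` (supplies the encoding length).
#' @param physchem Descriptor table.
#' @return A `loc_dataset` list: `x` (feature matrices), `tmat`, `torg`,
#'   `lv1_only`, `enc`, `records`, `hierarchy`, `cfg`.
#' @export
loc_dataset <- function(records, hierarchy, cfg, physchem = load_physchem()) {
  enc <- encode_records(records, physchem = physchem,
                        encode_len = cfg$encode_len)
  x <- lapply(enc, enc_to_x)
  tg <- lapply(seq_len(nrow(records)),
               function(i) labels_to_matrix(records[i, ], h = hierarchy))
  structure(list(
    x = x,
    tmat = lapply(tg, function(t) as.numeric(t$matrix)),
    torg = lapply(tg, function(t) as.numeric(t$org)),
    lv1_only = vapply(tg, function(t) t$lv1_only, TRUE),
    enc = enc, records = records, hierarchy = hierarchy, cfg = cfg
  ), class = "loc_dataset")
}

#' Train one sub-model with the alternating two-level scheme
#'
#' Each cycle runs one epoch over the level-1 samples (organelle loss only)
#' followed by one epoch over the level-2 samples (cell + organelle loss).
#' The production regime uses 80 cycles; small values are appropriate for
#' desk-scale experiments.
#'
#' @param data A `loc_dataset`.
#' @param cfg A `loc_config`; defaults to the one stored in `data`.
#' @param cycles Number of lv1/lv2 alternations (default 80).
#' @param verbose Print per-alternation losses.
#' @return A `loc_model`: list with `params`, `cfg`, `log` (tibble
#'   `alternation, phase, mean_loss`), `cycles`.
#' @export
train_submodel <- function(data, cfg = data$cfg, cycles = 80, verbose = FALSE) {
  idx_lv1 <- which(data$lv1_only)
  idx_lv2 <- which(!data$lv1_only)
  if (length(idx_lv2) == 0)
    .stopf("training requires at least one suborganelle-annotated (lv2) record")
  params <- init_params(cfg)
  adam_m <- zero_params(params)
  adam_v <- zero_params(params)
  adam_t <- 0L
  cmask <- cell_mask_vec(cfg, data$hierarchy)
  log <- list()
  epoch_counter <- 0L

  run_epoch <- function(idx) {
    epoch_counter <<- epoch_counter + 1L
    order <- idx[sample.int(length(idx))]
    res <- cpp_train_epoch(params, adam_m, adam_v, adam_t,
                           data$x, data$tmat, data$torg, data$lv1_only,
                           cmask, cfg$n_org, cfg$attention_reg_weight,
                           cfg$lr, cfg$beta1, cfg$beta2, cfg$adam_eps,
                           cfg$dropout_lstm, cfg$dropout_dense,
                           cfg$batch_size, cfg$grad_clip %||% 5,
                           cfg$weight_decay %||% 0, order,
                           (cfg$seed * 1009L + epoch_counter) %% .Machine$integer.max)
    params <<- res$params; adam_m <<- res$adam_m; adam_v <<- res$adam_v
    adam_t <<- res$adam_t
    res$mean_loss
  }

  set.seed(cfg$seed + 1L)
  if (cycles > 0) {
    for (cyc in seq_len(cycles)) {
      if (length(idx_lv1) > 0) {
        l1 <- run_epoch(idx_lv1)
        log[[length(log) + 1L]] <- tibble(alternation = cyc, phase = "lv1",
                                          mean_loss = l1)
      }
      l2 <- run_epoch(idx_lv2)
      log[[length(log) + 1L]] <- tibble(alternation = cyc, phase = "lv2",
                                        mean_loss = l2)
      if (verbose)
        message(sprintf("alternation %d: lv2 loss %.4f", cyc, l2))
    }
  }
  structure(list(params = params, cfg = cfg, cycles = cycles,
                 log = if (length(log)) dplyr::bind_rows(log)
                       else tibble(alternation = integer(0),
                                   phase = character(0),
                                   mean_loss = numeric(0)),
                 hierarchy = data$hierarchy),
            class = "loc_model")
}

#' @export
print.loc_model <- function(x, ...) {
  cat(sprintf("<loc_model> %d cycles, final lv2 loss %s\n", x$cycles,
              if (nrow(x$log)) sprintf("%.4f", utils::tail(
                x$log$mean_loss[x$log$phase == "lv2"], 1)) else "NA"))
  invisible(x)
}

#' Train an ensemble of sub-models with fold-held-out threshold tuning
#'
#' The training set is divided into `k` folds; sub-model *i* trains on all
#' folds but *i*.  The held-out fold of each sub-model provides
#' out-of-fold suborganelle scores from which per-cell decision thresholds
#' are tuned (capped at 0.5, favouring recall).  Ensemble predictions are
#' the cell-wise mean over sub-models.
#'
#' @param data A `loc_dataset`.
#' @param k Number of folds (default 8).
#' @param n_models Number of sub-models actually trained (default `k`);
#'   sub-model *i* trains on the complement of fold *i*, so desk-scale runs
#'   can keep the fold geometry (e.g. `k = 4`) while training only 2
#'   sub-models.
#' @param cycles Alternations per sub-model.
#' @param threshold_grid Candidate thresholds, all `<= 0.5`.
#' @param cfg Configuration; defaults to `data$cfg`.
#' @param verbose Print progress.
#' @return A `loc_ensemble`: `models`, `thresholds`, `cv` (out-of-fold
#'   scores), `folds`, `cfg`, `hierarchy`.
#' @export
train_ensemble <- function(data, k = 8, n_models = k, cycles = 80,
                           threshold_grid = seq(0.1, 0.5, by = 0.05),
                           cfg = data$cfg, verbose = FALSE) {
  stopifnot(n_models >= 1, n_models <= k)
  folds <- make_folds(data$records, k = k, seed = cfg$seed)
  models <- vector("list", n_models)
  cv <- list()
  h <- data$hierarchy
  for (i in seq_len(n_models)) {
    hold <- which(folds$fold == i)
    sub <- subset_dataset(data, setdiff(seq_along(data$x), hold))
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    models[[i]] <- train_submodel(sub, cfg = cfg_i, cycles = cycles,
                                  verbose = verbose)
    hold_lv2 <- hold[!data$lv1_only[hold]]
    for (j in hold_lv2) {
      sc <- forward(data$enc[[j]], cfg_i, models[[i]]$params, h)
      occ <- h$cells
      cv[[length(cv) + 1L]] <- tibble(
        accession = data$records$accession[j],
        suborganelle = occ$suborganelle,
        score = sc$sub[cbind(occ$row, occ$col)],
        target = as.numeric(matrix(data$tmat[[j]], nrow = 8)[cbind(occ$row, occ$col)]))
    }
  }
  cv <- if (length(cv)) dplyr::bind_rows(cv) else
    tibble(accession = character(0), suborganelle = character(0),
           score = numeric(0), target = numeric(0))
  thresholds <- tune_thresholds(cv, grid = threshold_grid, hierarchy = h)
  structure(list(models = models, thresholds = thresholds, cv = cv,
                 folds = folds, cfg = cfg, hierarchy = h, cycles = cycles),
            class = "loc_ensemble")
}

subset_dataset <- function(data, idx) {
  structure(list(x = data$x[idx], tmat = data$tmat[idx],
                 torg = data$torg[idx], lv1_only = data$lv1_only[idx],
                 enc = data$enc[idx], records = data$records[idx, ],
                 hierarchy = data$hierarchy, cfg = data$cfg),
            class = "loc_dataset")
}

#' @export
print.loc_ensemble <- function(x, ...) {
  cat(sprintf("<loc_ensemble> %d sub-models x %d cycles, %d tuned thresholds\n",
              length(x$models), x$cycles,
              sum(x$thresholds$threshold < 0.5)))
  invisible(x)
}

#' Ensemble prediction for one encoded protein
#'
#' The suborganelle score matrix is the arithmetic mean of the sub-models'
#' matrices; organelle scores are recomputed as column maxima of the
#' averaged matrix.
#'
#' @param ens A `loc_ensemble` (or a single `loc_model`).
#' @param enc A `loc_encoded` input.
#' @return A `loc_scores` object (attention averaged over sub-models).
#' @export
ensemble_predict <- function(ens, enc) {
  if (inherits(ens, "loc_model")) ens <- as_singleton_ensemble(ens)
  models <- ens$models
  if (length(models) < 1) .stopf("ensemble has no sub-models")
  dims <- vapply(models, function(m)
    c(m$cfg$n_org, m$cfg$hidden, m$cfg$heads, m$cfg$encode_len), numeric(4))
  if (nrow(unique(t(dims))) != 1)
    .stopf("sub-models have mismatching configurations")
  outs <- lapply(models, function(m)
    forward(enc, m$cfg, m$params, ens$hierarchy))
  sub <- Reduce(`+`, lapply(outs, `[[`, "sub")) / length(outs)
  A <- Reduce(`+`, lapply(outs, `[[`, "A")) / length(outs)
  org <- apply(sub, 2, max)
  structure(list(sub = sub, org = org, A = A, M = NULL,
                 n_valid = outs[[1]]$n_valid, accession = enc$accession),
            class = "loc_scores")
}

as_singleton_ensemble <- function(model) {
  structure(list(models = list(model), hierarchy = model$hierarchy,
                 cfg = model$cfg, cycles = model$cycles,
                 thresholds = threshold_set(model$hierarchy)),
            class = "loc_ensemble")
}

#' Tune per-cell decision thresholds on out-of-fold scores
#'
#' For each occupied hierarchy cell with at least one positive and one
#' negative out-of-fold sample, the grid candidate maximising the MCC is
#' chosen; ties break toward the smaller threshold (favouring recall).
#' Cells without both classes keep the 0.5 default.  Thresholds never
#' exceed 0.5.
#'
#' @param cv Tibble with columns `suborganelle, score, target`.
#' @param grid Candidate thresholds, all in `(0, 0.5]`.
#' @param hierarchy Optional `loc_hierarchy`; cells absent from `cv` are
#'   filled with the default.
#' @param default Default threshold (0.5).
#' @return Tibble `suborganelle, threshold, tuned`.
#' @export
tune_thresholds <- function(cv, grid = seq(0.1, 0.5, by = 0.05),
                            hierarchy = NULL, default = 0.5) {
  if (length(grid) == 0) .stopf("threshold grid is empty")
  if (any(grid > 0.5 | grid <= 0)) .stopf("threshold candidates must lie in (0, 0.5]")
  grid <- sort(grid)
  cells <- if (!is.null(hierarchy)) hierarchy$cells$suborganelle
           else unique(cv$suborganelle)
  out <- lapply(cells, function(cl) {
    d <- cv[cv$suborganelle == cl, ]
    if (nrow(d) == 0 || sum(d$target > 0) == 0 || sum(d$target == 0) == 0)
      return(tibble(suborganelle = cl, threshold = default, tuned = FALSE))
    mcc <- vapply(grid, function(th) {
      pred <- d$score >= th
      cc <- confusion_counts(pred, d$target > 0)
      v <- mcc_value(cc)
      if (is.na(v)) -Inf else v
    }, numeric(1))
    best <- grid[which.max(mcc)]  # which.max takes the first (smallest) tie
    tibble(suborganelle = cl, threshold = best, tuned = TRUE)
  })
  dplyr::bind_rows(out)
}

#' Default threshold set
#' @param hierarchy A `loc_hierarchy`.
#' @param default Threshold value for every occupied cell.
#' @return Tibble `suborganelle, threshold, tuned`.
#' @export
threshold_set <- function(hierarchy, default = 0.5) {
  tibble(suborganelle = hierarchy$cells$suborganelle,
         threshold = default, tuned = FALSE)
}

#' Gaussian-process hyperparameter search
#'
#' A reduced-scale Bayesian optimisation harness: a Gaussian-process
#' surrogate (squared-exponential kernel on inputs rescaled to the unit
#' cube, small nugget) with expected-improvement acquisition.  The
#' acquisition jitter (exploration/exploitation trade-off) defaults to
#' 0.05.  Initial points come from a Latin hypercube.  Failing objective
#' evaluations are logged and skipped.
#'
#' @param objective Function `function(config_list) -> numeric` to be
#'   maximised (e.g. validation accuracy).
#' @param space Named list of `c(lower, upper)` ranges.
#' @param n_trials Total evaluations (>= 1).
#' @param n_init Initial Latin-hypercube evaluations.
#' @param jitter Expected-improvement jitter, default 0.05.
#' @param integer_params Names of parameters rounded to integers.
#' @param seed Integer seed.
#' @return List with `best` (configuration), `best_value`, and `trials`
#'   (tibble log).
#' @export
bayes_search <- function(objective, space, n_trials = 20,
                         n_init = min(5, n_trials), jitter = 0.05,
                         integer_params = character(0), seed = 1L) {
  if (length(space) == 0) .stopf("search space is empty")
  if (n_trials < 1) .stopf("n_trials must be >= 1")
  d <- length(space)
  lo <- vapply(space, `[`, numeric(1), 1)
  hi <- vapply(space, `[`, numeric(1), 2)
  set.seed(seed)
  X01 <- lhs::randomLHS(max(n_init, 1), d)
  to_config <- function(u) {
    v <- lo + u * (hi - lo)
    names(v) <- names(space)
    v[integer_params] <- round(v[integer_params])
    as.list(v)
  }
  evals <- list(); X <- NULL; y <- numeric(0)
  run_trial <- function(u) {
    cfg <- to_config(u)
    val <- tryCatch(objective(cfg), error = function(e) NA_real_)
    evals[[length(evals) + 1L]] <<- tibble(
      trial = length(evals) + 1L, !!!cfg,
      value = val, failed = is.na(val))
    if (!is.na(val)) { X <<- rbind(X, u); y <<- c(y, val) }
  }
  for (i in seq_len(min(n_init, n_trials))) run_trial(X01[i, ])
  n_done <- min(n_init, n_trials)
  while (n_done < n_trials) {
    n_done <- n_done + 1L
    if (length(y) < 2) { run_trial(runif(d)); next }
    gp <- gp_fit(X, y)
    cand <- matrix(runif(500 * d), ncol = d)
    pr <- gp_predict(gp, cand)
    ei <- expected_improvement(pr$mean, pr$sd, max(y), jitter)
    run_trial(cand[which.max(ei), ])
  }
  trials <- dplyr::bind_rows(evals)
  ok <- which(!trials$failed)
  if (length(ok) == 0) .stopf("all objective evaluations failed")
  best_i <- ok[which.max(trials$value[ok])]
  best <- as.list(trials[best_i, names(space)])
  list(best = best, best_value = trials$value[best_i], trials = trials)
}

# Plain GP regression with a squared-exponential kernel; y standardised.
gp_fit <- function(X, y, lengthscale = 0.3, nugget = 1e-6) {
  mu <- mean(y); sdv <- stats::sd(y); if (!is.finite(sdv) || sdv == 0) sdv <- 1
  ys <- (y - mu) / sdv
  K <- gp_kern(X, X, lengthscale) + diag(nugget + 1e-8, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  list(X = X, L = L, alpha = alpha, mu = mu, sd = sdv, ls = lengthscale)
}

gp_kern <- function(A, B, ls) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  exp(-pmax(d2, 0) / (2 * ls^2))
}

gp_predict <- function(gp, Xnew) {
  Ks <- gp_kern(Xnew, gp$X, gp$ls)
  mean_s <- as.numeric(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$L), t(Ks))
  var_s <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = gp$mu + gp$sd * mean_s, sd = gp$sd * sqrt(var_s))
}

expected_improvement <- function(mu, sd, best, jitter) {
  z <- (mu - best - jitter) / sd
  (mu - best - jitter) * stats::pnorm(z) + sd * stats::dnorm(z)
}
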