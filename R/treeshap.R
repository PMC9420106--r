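# Double-precision path-dependent TreeSHAP over an xgboost tree dump.
# xgboost's built-in `predcontrib` explainer runs in single precision,
# which leaves ~1e-6 residuals in the local-accuracy identity; this
# implementation exists so the identity can be verified to double
# precision (and cross-checked against a brute-force Shapley oracle) on
# verification-scale models. Attribution rankings at pipeline scale use
# the fast built-in explainer.

# Round doubles to their nearest float32, replicating xgboost's internal
# comparison precision (ties at split values must break the same way).
as_float32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4L),
          what = "numeric", size = 4L, n = length(v))
}

# Parse an xgb.Booster into per-tree node tables with column indices.
parse_trees <- function(model, feature_names) {
  dt <- xgboost::xgb.model.dt.tree(model = model)
  dt <- as.data.frame(dt)
  cfg <- xgboost::xgb.config(model)
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
  lp <- cfg$learner$learner_model_param
  base <- as.numeric(lp$base_score)
  n_class <- max(1L, as.integer(lp$num_class))
  # binary logistic applies base_score through the logit link; softmax
  # objectives add it to the margin directly
  obj <- cfg$learner$objective$name %||% ""
  base_margin <- if (grepl("binary:logistic|reg:logistic", obj))
    log(base / (1 - base)) else base
  trees <- lapply(split(dt, dt$Tree), function(tt) {
    tt <- tt[order(tt$Node), ]
    list(
      feature = match(tt$Feature, feature_names),  # NA for leaves
      # the dump prints splits with enough digits to round-trip float32;
      # snap back so ties break exactly as inside xgboost
      split = as_float32(tt$Split),
      yes = match(tt$Yes, tt$ID), no = match(tt$No, tt$ID),
      value = tt$Gain, cover = tt$Cover,
      is_leaf = tt$Feature == "Leaf"
    )
  })
  list(trees = trees, base_margin = base_margin, n_class = n_class)
}

# class index (1-based) of each tree given the forest layout
tree_class <- function(n_trees, n_class, num_parallel_tree) {
  idx <- seq_len(n_trees) - 1L
  ((idx %/% num_parallel_tree) %% n_class) + 1L
}

# double-precision margin prediction for one sample from parsed trees
tree_margin <- function(parsed, x, num_parallel_tree = 1L) {
  cls <- tree_class(length(parsed$trees), parsed$n_class,
                    num_parallel_tree)
  out <- rep(parsed$base_margin, parsed$n_class)
  for (t in seq_along(parsed$trees)) {
    tr <- parsed$trees[[t]]
    j <- 1L
    while (!tr$is_leaf[j])
      j <- if (x[tr$feature[j]] < tr$split[j]) tr$yes[j] else tr$no[j]
    out[cls[t]] <- out[cls[t]] + tr$value[j]
  }
  out
}

# Path-dependent conditional expectation E[f_tree(x) | x_S] where
# features outside S are marginalized along the tree's cover proportions.
tree_cond_exp <- function(tr, x, s_mask) {
  rec <- function(j) {
    if (tr$is_leaf[j]) return(tr$value[j])
    f <- tr$feature[j]
    if (s_mask[f])
      return(rec(if (x[f] < tr$split[j]) tr$yes[j] else tr$no[j]))
    (tr$cover[tr$yes[j]] * rec(tr$yes[j]) +
       tr$cover[tr$no[j]] * rec(tr$no[j])) / tr$cover[j]
  }
  rec(1L)
}

# Brute-force Shapley values of one tree for one sample (oracle used in
# tests; exponential in the number of features).
tree_shap_brute <- function(tr, x, n_features) {
  phi <- numeric(n_features)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n_features))
  v <- apply(subsets, 1, function(s) tree_cond_exp(tr, x, as.logical(s)))
  sizes <- rowSums(subsets)
  for (i in seq_len(n_features)) {
    without <- which(!subsets[[i]])
    for (k in without) {
      with_i <- k + 2^(i - 1)
      s <- sizes[k]
      w <- factorial(s) * factorial(n_features - s - 1) /
        factorial(n_features)
      phi[i] <- phi[i] + w * (v[with_i] - v[k])
    }
  }
  phi
}

# TreeSHAP recursion (path-dependent) for one tree and one sample.
# The path is kept as parallel vectors (d = feature, z = zero fraction,
# o = one fraction, w = permutation weights).
tree_shap_one <- function(tr, x, n_features) {
  phi <- numeric(n_features)

  extend <- function(p, pz, po, pi) {
    l <- length(p$w)
    p$d <- c(p$d, pi); p$z <- c(p$z, pz); p$o <- c(p$o, po)
    p$w <- c(p$w, if (l == 0L) 1 else 0)
    if (l > 0L) for (i in l:1) {
      p$w[i + 1L] <- p$w[i + 1L] + po * p$w[i] * i / (l + 1L)
      p$w[i] <- pz * p$w[i] * (l + 1L - i) / (l + 1L)
    }
    p
  }
  unwind <- function(p, k) {
    # remove element k, recomputing the permutation weights
    l <- length(p$w) - 1L
    n <- p$w[l + 1L]
    o <- p$o[k]; z <- p$z[k]
    w <- p$w
    for (j in l:1) {
      if (o != 0) {
        t0 <- w[j]
        w[j] <- n * (l + 1L) / (j * o)
        n <- t0 - w[j] * z * (l + 1L - j) / (l + 1L)
      } else {
        w[j] <- w[j] * (l + 1L) / (z * (l + 1L - j))
      }
    }
    idx <- setdiff(seq_len(l + 1L), k)
    list(d = p$d[idx], z = p$z[idx], o = p$o[idx], w = w[seq_len(l)])
  }
  unwound_sum <- function(p, k) {
    l <- length(p$w) - 1L
    o <- p$o[k]; z <- p$z[k]
    n <- p$w[l + 1L]
    total <- 0
    if (l < 1L) return(0)
    for (j in l:1) {
      if (o != 0) {
        tmp <- n * (l + 1L) / (j * o)
        total <- total + tmp
        n <- p$w[j] - tmp * z * (l + 1L - j) / (l + 1L)
      } else {
        total <- total + p$w[j] * (l + 1L) / (z * (l + 1L - j))
      }
    }
    total
  }

  rec <- function(j, p, pz, po, pi) {
    p <- extend(p, pz, po, pi)
    if (tr$is_leaf[j]) {
      m <- length(p$w)
      if (m >= 2L) for (i in 2:m) {
        w <- unwound_sum(p, i)
        phi[p$d[i]] <<- phi[p$d[i]] +
          w * (p$o[i] - p$z[i]) * tr$value[j]
      }
      return(invisible())
    }
    f <- tr$feature[j]
    hot <- if (x[f] < tr$split[j]) tr$yes[j] else tr$no[j]
    cold <- if (hot == tr$yes[j]) tr$no[j] else tr$yes[j]
    iz <- 1; io <- 1
    k <- which(p$d == f)
    k <- k[k > 1L]
    if (length(k)) {
      k <- k[1]
      iz <- p$z[k]; io <- p$o[k]
      p <- unwind(p, k)
    }
    rc <- tr$cover
    rec(hot, p, iz * rc[hot] / rc[j], io, f)
    rec(cold, p, iz * rc[cold] / rc[j], 0, f)
    invisible()
  }

  p0 <- list(d = integer(0), z = numeric(0), o = numeric(0),
             w = numeric(0))
  rec(1L, p0, 1, 1, 0L)
  base <- tree_cond_exp(tr, x, rep(FALSE, n_features))
  c(phi, base)
}

#' Double-precision TreeSHAP attributions
#'
#' Path-dependent TreeSHAP (per-node cover weighting) computed in double
#' precision from an xgboost model's tree dump. Intended for
#' verification-scale problems: it is exact arithmetic on the stored tree
#' parameters, so the Shapley local-accuracy identity (attributions plus
#' base value equal the margin prediction) holds to double precision,
#' unlike the single-precision built-in explainer. Used by the test suite
#' to validate [importance_report()]'s fast explainer.
#'
#' @param model An `xgb.Booster` of tree ensembles.
#' @param x Numeric matrix of samples (columns must match the training
#'   features).
#' @param num_parallel_tree Parallel trees per boosting round (forest
#'   mode), needed to assign trees to classes; read from the model
#'   configuration when `NULL`.
#' @return Array `n_samples x n_class x (n_features + 1)`; the last slice
#'   is the per-class base value (expected margin).
#' @export
tree_shap <- function(model, x, num_parallel_tree = NULL) {
  stopifnot(inherits(model, "xgb.Booster"), is.matrix(x))
  num_parallel_tree <- num_parallel_tree %||% model_parallel_trees(model)
  x <- matrix(as_float32(x), nrow(x), ncol(x), dimnames = dimnames(x))
  parsed <- parse_trees(model, colnames(x))
  n_class <- parsed$n_class
  cls <- tree_class(length(parsed$trees), n_class, num_parallel_tree)
  p <- ncol(x)
  out <- array(0, dim = c(nrow(x), n_class, p + 1L))
  for (s in seq_len(nrow(x))) {
    for (t in seq_along(parsed$trees)) {
      contrib <- tree_shap_one(parsed$trees[[t]], x[s, ], p)
      out[s, cls[t], ] <- out[s, cls[t], ] + contrib
    }
    out[s, , p + 1L] <- out[s, , p + 1L] + parsed$base_margin
  }
  dimnames(out) <- list(NULL, NULL, c(colnames(x), "BIAS"))
  out
}

# double-precision margins for all samples (companion to tree_shap)
tree_margins <- function(model, x, num_parallel_tree = NULL) {
  num_parallel_tree <- num_parallel_tree %||% model_parallel_trees(model)
  x <- matrix(as_float32(x), nrow(x), ncol(x), dimnames = dimnames(x))
  parsed <- parse_trees(model, colnames(x))
  res <- vapply(seq_len(nrow(x)), function(i)
    tree_margin(parsed, x[i, ], num_parallel_tree),
    numeric(parsed$n_class))
  if (is.null(dim(res))) matrix(res, ncol = 1L) else t(res)
}

# parallel trees per round, from the model's stored training config
model_parallel_trees <- function(model) {
  cfg <- xgboost::xgb.config(model)
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
  npt <- cfg$learner$gradient_booster$gbtree_model_param$num_parallel_tree
  max(1L, as.integer(npt %||% 1L))
}
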