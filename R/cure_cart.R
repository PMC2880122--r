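## Cure survival CART.
##
## Recursive binary partitioning of subjects in which every node carries a
## parametric (exponential or Weibull) mixture cure model. The impurity of
## a node is its deviance residual R(h) = -2 maxloglik / n_root; a split's
## improvement is R(h) - R(l(h)) - R(r(h)), the likelihood-ratio reduction
## on the deviance scale. Trees are pruned by weakest-link cost-complexity
## pruning and a subtree is selected by replicated V-fold cross-validation
## (minimum rule or 1-SE rule).

#' Control options for cure survival CART
#'
#' @param max_terminal_nodes growth stops once this many leaves exist.
#' @param min_node_size minimum subjects in any child node.
#' @param min_events minimum events in any child node. Defaults reflect
#'   that each node must identify a 2-3 parameter cure model.
#' @param param_control \code{\link{param_cure_control}} for the node fits.
#' @return A list of class \code{cure_cart_control}.
#' @export
cure_cart_control <- function(max_terminal_nodes = 10, min_node_size = 20,
                              min_events = 5,
                              param_control = param_cure_control()) {
  structure(list(max_terminal_nodes = max_terminal_nodes,
                 min_node_size = min_node_size, min_events = min_events,
                 param_control = param_control),
            class = "cure_cart_control")
}

#' Candidate binary splits at a node
#'
#' Numeric covariates yield one candidate at the midpoint of each pair of
#' adjacent distinct observed values (a 0/1 covariate therefore yields the
#' single candidate 0.5); candidates whose children would violate the
#' minimum-size constraint are excluded.
#'
#' @param ds the node's \code{\link{survival_dataset}}.
#' @param covariates names of split candidates.
#' @param min_node_size minimum child size.
#' @return Data frame with columns \code{var}, \code{cut} (possibly empty).
#' @export
enumerate_splits <- function(ds, covariates, min_node_size = 1) {
  out <- list()
  for (v in covariates) {
    x <- ds$covariates[[v]]
    ux <- sort(unique(x))
    if (length(ux) < 2) next
    cuts <- (ux[-length(ux)] + ux[-1]) / 2
    keep <- vapply(cuts, function(ct) {
      nl <- sum(x <= ct)
      nl >= min_node_size && (length(x) - nl) >= min_node_size
    }, logical(1))
    if (any(keep))
      out[[v]] <- data.frame(var = v, cut = cuts[keep],
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(var = character(0), cut = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Evaluate one candidate split
#'
#' Fits the node's cure model in both children and returns the deviance
#' improvement \code{R(h) - R(l) - R(r)}. A split is inadmissible if a child
#' violates the size/event constraints or its fit does not converge.
#'
#' @param ds the node's data.
#' @param split list or one-row data frame with \code{var} and \code{cut}.
#' @param family \code{"exponential"} or \code{"weibull"}.
#' @param n_root root sample size (deviance divisor).
#' @param node_fit the node's own \code{param_cure_fit}.
#' @param control a \code{\link{cure_cart_control}}.
#' @return List with \code{admissible}, \code{improvement},
#'   \code{left_fit}, \code{right_fit}, \code{left_idx}, \code{right_idx}.
#' @export
evaluate_split <- function(ds, split, family, n_root, node_fit,
                           control = cure_cart_control()) {
  x <- ds$covariates[[split$var]]
  left <- x <= split$cut
  inadmissible <- list(admissible = FALSE, improvement = NA_real_)
  nl <- sum(left); nr <- sum(!left)
  if (nl < control$min_node_size || nr < control$min_node_size)
    return(inadmissible)
  if (sum(ds$event[left]) < control$min_events ||
      sum(ds$event[!left]) < control$min_events)
    return(inadmissible)
  lf <- tryCatch(fit_parametric_cure(subset_dataset(ds, left), family,
                                     control$param_control),
                 error = function(e) NULL)
  rf <- tryCatch(fit_parametric_cure(subset_dataset(ds, !left), family,
                                     control$param_control),
                 error = function(e) NULL)
  if (is.null(lf) || is.null(rf) || !lf$converged || !rf$converged)
    return(inadmissible)
  impr <- -2 * (node_fit$loglik - lf$loglik - rf$loglik) / n_root
  list(admissible = TRUE, improvement = impr, left_fit = lf, right_fit = rf,
       left_idx = which(left), right_idx = which(!left))
}

## Best admissible split at a node; ties broken by declared covariate
## order, then smaller cutpoint (determinism).
best_split <- function(ds_node, covariates, family, n_root, node_fit,
                       control) {
  cands <- enumerate_splits(ds_node, covariates, control$min_node_size)
  if (nrow(cands) == 0) return(NULL)
  ## declared covariate order, then cutpoint
  cands <- cands[order(match(cands$var, covariates), cands$cut), ,
                 drop = FALSE]
  best <- NULL
  for (r in seq_len(nrow(cands))) {
    ev <- evaluate_split(ds_node, cands[r, ], family, n_root, node_fit,
                         control)
    if (!ev$admissible) next
    if (is.null(best) || ev$improvement > best$improvement + 1e-12) {
      best <- ev
      best$var <- cands$var[r]
      best$cut <- cands$cut[r]
    }
  }
  best
}

#' Grow a cure survival tree
#'
#' Greedy best-first growth: at each step the admissible split with the
#' largest deviance improvement anywhere in the current tree is applied,
#' until no admissible split improves the fit or the maximum number of
#' terminal nodes is reached. Deterministic given data and options.
#'
#' @param ds a \code{\link{survival_dataset}}.
#' @param covariates names of split candidates.
#' @param family latency family of the node cure models.
#' @param control a \code{\link{cure_cart_control}}.
#' @return An object of class \code{cure_tree}.
#' @examples
#' sim <- simulate_partitioned_dataset(
#'   list(list(condition = function(r) r$g == 0, c = 0.85, mu = 0.15),
#'        list(condition = function(r) r$g == 1, c = 0.2,  mu = 0.15)),
#'   n = 400, covariate_spec = list(g = list(dist = "bernoulli", p = 0.5)),
#'   censoring = list(tau = 16), seed = 7)
#' grow_tree(sim$dataset, "g")
#' @export
grow_tree <- function(ds, covariates, family = c("exponential", "weibull"),
                      control = cure_cart_control()) {
  stopifnot(inherits(ds, "survival_dataset"))
  family <- match.arg(family)
  root_fit <- fit_parametric_cure(ds, family, control$param_control)
  n_root <- ds$n
  nodes <- list(`1` = list(id = 1L, parent = NA_integer_, children = NULL,
                           split = NULL, fit = root_fit, n = ds$n,
                           events = sum(ds$event), depth = 0L))
  idx_of <- list(`1` = seq_len(ds$n))
  pending <- list()  # cached best split per leaf id
  pending[["1"]] <- best_split(ds, covariates, family, n_root, root_fit,
                               control)
  next_id <- 2L
  repeat {
    leaves <- names(idx_of)
    if (length(leaves) >= control$max_terminal_nodes) break
    ## pick leaf whose cached best split has maximal improvement
    sel <- NULL
    for (lid in leaves) {
      bs <- pending[[lid]]
      if (is.null(bs) || bs$improvement <= 1e-12) next
      if (is.null(sel) || bs$improvement > pending[[sel]]$improvement + 1e-12)
        sel <- lid
    }
    if (is.null(sel)) break
    bs <- pending[[sel]]
    node_idx <- idx_of[[sel]]
    lid_int <- as.integer(sel)
    lchild <- next_id; rchild <- next_id + 1L
    next_id <- next_id + 2L
    nodes[[sel]]$split <- list(var = bs$var, cut = bs$cut)
    nodes[[sel]]$children <- c(lchild, rchild)
    depth <- nodes[[sel]]$depth + 1L
    li <- node_idx[bs$left_idx]; ri <- node_idx[bs$right_idx]
    nodes[[as.character(lchild)]] <-
      list(id = lchild, parent = lid_int, children = NULL, split = NULL,
           fit = bs$left_fit, n = length(li), events = sum(ds$event[li]),
           depth = depth)
    nodes[[as.character(rchild)]] <-
      list(id = rchild, parent = lid_int, children = NULL, split = NULL,
           fit = bs$right_fit, n = length(ri), events = sum(ds$event[ri]),
           depth = depth)
    idx_of[[sel]] <- NULL
    pending[[sel]] <- NULL
    idx_of[[as.character(lchild)]] <- li
    idx_of[[as.character(rchild)]] <- ri
    pending[[as.character(lchild)]] <-
      best_split(subset_dataset(ds, li), covariates, family, n_root,
                 bs$left_fit, control)
    pending[[as.character(rchild)]] <-
      best_split(subset_dataset(ds, ri), covariates, family, n_root,
                 bs$right_fit, control)
  }
  structure(list(nodes = nodes, root_id = 1L, family = family,
                 n_root = n_root, covariates = covariates,
                 control = control),
            class = "cure_tree")
}

## ---- tree utilities ------------------------------------------------------

tree_leaf_ids <- function(tree, id = tree$root_id) {
  node <- tree$nodes[[as.character(id)]]
  if (is.null(node$children)) return(id)
  c(tree_leaf_ids(tree, node$children[1]),
    tree_leaf_ids(tree, node$children[2]))
}

tree_internal_ids <- function(tree) {
  ids <- vapply(tree$nodes, function(nd) nd$id, integer(1))
  ids[vapply(tree$nodes, function(nd) !is.null(nd$children), logical(1))]
}

#' Number of terminal nodes of a tree
#' @param tree a \code{cure_tree}.
#' @return Integer count of leaves.
#' @export
n_terminal <- function(tree) length(tree_leaf_ids(tree))

node_R <- function(tree, id) {
  -2 * tree$nodes[[as.character(id)]]$fit$loglik / tree$n_root
}

## Total leaf deviance of the subtree rooted at `id`.
branch_leaf_R <- function(tree, id) {
  leaves <- tree_leaf_ids(tree, id)
  sum(vapply(leaves, function(l) node_R(tree, l), numeric(1)))
}

## Collapse the branch at `id` into a terminal node.
collapse_branch <- function(tree, id) {
  drop_ids <- setdiff(collect_descendants(tree, id), id)
  tree$nodes[[as.character(id)]]$children <- NULL
  tree$nodes[[as.character(id)]]$split <- NULL
  for (d in drop_ids) tree$nodes[[as.character(d)]] <- NULL
  tree
}

collect_descendants <- function(tree, id) {
  node <- tree$nodes[[as.character(id)]]
  if (is.null(node$children)) return(id)
  c(id, collect_descendants(tree, node$children[1]),
    collect_descendants(tree, node$children[2]))
}

#' Route subjects through a tree
#' @param tree a \code{cure_tree}.
#' @param covariates data frame of covariate values, one row per subject.
#' @return Integer vector of terminal node ids.
#' @export
route_subjects <- function(tree, covariates) {
  vapply(seq_len(nrow(covariates)), function(i) {
    id <- tree$root_id
    repeat {
      node <- tree$nodes[[as.character(id)]]
      if (is.null(node$children)) return(node$id)
      id <- if (covariates[[node$split$var]][i] <= node$split$cut)
        node$children[1] else node$children[2]
    }
  }, integer(1))
}

#' Weakest-link cost-complexity pruning path
#'
#' For each internal node h, \code{g(h)} is the average reduction in
#' deviance per split in the branch at h: \code{[R(h) - sum leaf R] /
#' (leaves(h) - 1)}. The branch with the smallest g is collapsed
#' (simultaneously for ties), repeatedly, yielding the nested sequence of
#' optimally pruned subtrees; each recorded penalty is the g value at which
#' the collapse occurs.
#'
#' @param tree a \code{cure_tree}.
#' @return An object of class \code{prune_sequence}: \code{gammas}
#'   (strictly increasing, starting at 0 for the full tree) and
#'   \code{trees} (ending with the root-only tree).
#' @export
prune_path <- function(tree) {
  gammas <- 0
  trees <- list(tree)
  cur <- tree
  while (length(tree_internal_ids(cur)) > 0) {
    internals <- tree_internal_ids(cur)
    g <- vapply(internals, function(h) {
      nl <- length(tree_leaf_ids(cur, h))
      (node_R(cur, h) - branch_leaf_R(cur, h)) / (nl - 1)
    }, numeric(1))
    gmin <- min(g)
    for (h in internals[g <= gmin + 1e-12]) {
      ## a tied node may already have been removed as a descendant
      if (!is.null(cur$nodes[[as.character(h)]]))
        cur <- collapse_branch(cur, h)
    }
    if (gmin <= gammas[length(gammas)] + 1e-12) {
      ## merged threshold: the previous member was never optimal on its own
      trees[[length(trees)]] <- cur
    } else {
      gammas <- c(gammas, gmin)
      trees <- c(trees, list(cur))
    }
  }
  structure(list(gammas = gammas, trees = trees), class = "prune_sequence")
}

#' @export
print.prune_sequence <- function(x, ...) {
  cat(sprintf("Pruning path: %d subtree(s)\n", length(x$trees)))
  for (k in seq_along(x$trees))
    cat(sprintf("  gamma >= %.6g: %d terminal node(s)\n",
                x$gammas[k], n_terminal(x$trees[[k]])))
  invisible(x)
}

## Penalized cost R_gamma(T) = sum leaf R + gamma * #leaves.
tree_cost <- function(tree, gamma) {
  branch_leaf_R(tree, tree$root_id) + gamma * n_terminal(tree)
}

## ---- cross-validation ----------------------------------------------------

stratified_folds <- function(event, V) {
  fold <- integer(length(event))
  for (grp in list(which(event == 1), which(event == 0))) {
    if (length(grp) > 0)
      fold[grp] <- sample(rep_len(seq_len(V), length(grp)))
  }
  fold
}

## Held-out log-likelihood of `ds_test` routed through `tree`, using the
## training node parameter estimates.
heldout_loglik <- function(tree, ds_test) {
  leaf <- route_subjects(tree, ds_test$covariates)
  ll <- 0
  for (id in unique(leaf)) {
    f <- tree$nodes[[as.character(id)]]$fit
    ll <- ll + parametric_cure_loglik(f$c, f$mu, f$rho,
                                      subset_dataset(ds_test, leaf == id))
  }
  ll
}

## Evaluation penalty grid: geometric means of successive pruning
## thresholds (grid[k] selects path member k), plus the last threshold
## itself so the root-only tree is evaluated too.
gamma_grid <- function(gammas) {
  K <- length(gammas)
  if (K == 1) return(gammas)
  c(sqrt(gammas[-K] * gammas[-1]), gammas[K])
}

## Index of the optimally pruned subtree at penalty `gamma`.
path_member_at <- function(gammas, gamma) {
  max(which(gammas <= gamma + 1e-15))
}

#' Replicated V-fold cross-validated deviance of the pruning path
#'
#' For each replication, a random event-stratified V-fold partition is
#' drawn; for each fold, a tree is grown and pruned on the training data
#' and every penalty on the evaluation grid is scored by the held-out
#' subjects' parametric cure log-likelihood at the training node estimates
#' (test subjects routed through the training tree). The replication's
#' deviance is \code{-2 * (summed held-out loglik) / n}; the mean and the
#' across-replication standard deviation are reported per penalty.
#'
#' @param ds a \code{\link{survival_dataset}}.
#' @param covariates split candidates.
#' @param family latency family.
#' @param control a \code{\link{cure_cart_control}}.
#' @param V number of folds (default 10).
#' @param replications number of replicated cross-validations. Published
#'   analyses of this kind use 500; the default keeps routine runs fast.
#' @param seed integer seed governing all fold draws.
#' @return An object of class \code{cv_result}: \code{gamma} (evaluation
#'   grid), \code{rcv}, \code{se}, \code{V}, \code{replications},
#'   \code{selected_gamma_min}, \code{selected_gamma_1se}, and the
#'   full-data \code{prune_seq}.
#' @export
cv_deviance <- function(ds, covariates, family = c("exponential", "weibull"),
                        control = cure_cart_control(), V = 10,
                        replications = 10, seed) {
  family <- match.arg(family)
  if (V < 2) stop("V must be at least 2")
  if (ds$n < 2 * V) stop("need n >= 2V subjects")
  if (!missing(seed)) set.seed(as.integer(seed))
  full <- grow_tree(ds, covariates, family, control)
  pseq <- prune_path(full)
  grid <- gamma_grid(pseq$gammas)
  K <- length(grid)
  rep_dev <- matrix(NA_real_, replications, K)
  for (r in seq_len(replications)) {
    hll <- rep(0, K)
    for (attempt in 1:10) {
      fold <- stratified_folds(ds$event, V)
      train_ok <- all(vapply(seq_len(V), function(v)
        sum(ds$event[fold != v]) > 0, logical(1)))
      if (train_ok) break
      if (attempt == 10) stop("could not draw folds with events in every training set")
    }
    for (v in seq_len(V)) {
      tr <- subset_dataset(ds, fold != v)
      te <- subset_dataset(ds, fold == v)
      tr_tree <- grow_tree(tr, covariates, family, control)
      tr_seq <- prune_path(tr_tree)
      for (k in seq_len(K)) {
        m <- path_member_at(tr_seq$gammas, grid[k])
        hll[k] <- hll[k] + heldout_loglik(tr_seq$trees[[m]], te)
      }
    }
    rep_dev[r, ] <- -2 * hll / ds$n
  }
  rcv <- colMeans(rep_dev)
  se <- if (replications > 1) apply(rep_dev, 2, stats::sd) else rep(0, K)
  kmin <- which.min(rcv)
  thresh <- rcv[kmin] + se[kmin]
  k1se <- max(which(rcv <= thresh + 1e-12))
  structure(list(gamma = grid, rcv = rcv, se = se, V = V,
                 replications = replications,
                 selected_gamma_min = grid[kmin],
                 selected_gamma_1se = grid[k1se],
                 k_min = kmin, k_1se = k1se, prune_seq = pseq),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validated deviance (%d-fold, %d replication(s))\n",
              x$V, x$replications))
  print(data.frame(gamma = signif(x$gamma, 4), rcv = round(x$rcv, 4),
                   se = round(x$se, 4)))
  cat(sprintf("  min rule: gamma = %.6g; 1-SE rule: gamma = %.6g\n",
              x$selected_gamma_min, x$selected_gamma_1se))
  invisible(x)
}

#' Select a pruned subtree from a cross-validated path
#'
#' The \code{"min"} rule takes the penalty minimizing the mean
#' cross-validated deviance; the \code{"one_se"} rule takes the smallest
#' subtree whose deviance is within one standard error of that minimum.
#'
#' @param prune_seq a \code{\link{prune_path}} result.
#' @param cv the matching \code{\link{cv_deviance}} result.
#' @param rule \code{"min"} or \code{"one_se"}.
#' @return The selected \code{cure_tree}.
#' @export
select_subtree <- function(prune_seq, cv, rule = c("min", "one_se")) {
  rule <- match.arg(rule)
  if (length(cv$gamma) != length(prune_seq$trees))
    stop("cross-validation grid is not aligned with the pruning sequence")
  k <- if (rule == "min") cv$k_min else cv$k_1se
  prune_seq$trees[[k]]
}

## ---- rendering and serialization ----------------------------------------

#' @export
print.cure_tree <- function(x, ...) {
  cat(sprintf("Cure survival tree (%s latency), %d terminal node(s), n = %d\n",
              x$family, n_terminal(x), x$n_root))
  render_node <- function(id, prefix) {
    nd <- x$nodes[[as.character(id)]]
    f <- nd$fit
    lab <- sprintf("n=%d events=%d c=%.3f mu=%.4f%s",
                   nd$n, nd$events, f$c, f$mu,
                   if (x$family == "weibull") sprintf(" rho=%.3f", f$rho) else "")
    if (is.null(nd$children)) {
      cat(prefix, "* ", lab, "\n", sep = "")
    } else {
      cat(prefix, "+ ", lab, "\n", sep = "")
      cat(prefix, "  [", nd$split$var, " <= ", format(nd$split$cut), "]\n",
          sep = "")
      render_node(nd$children[1], paste0(prefix, "  "))
      cat(prefix, "  [", nd$split$var, " > ", format(nd$split$cut), "]\n",
          sep = "")
      render_node(nd$children[2], paste0(prefix, "  "))
    }
  }
  render_node(x$root_id, "")
  invisible(x)
}

#' Serialize a cure tree to JSON
#' @param tree a \code{cure_tree}.
#' @param path optional file path; if given the JSON is written there.
#' @return JSON string (invisibly if written to file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  nodes <- lapply(tree$nodes, function(nd) {
    out <- list(id = nd$id, n = nd$n, events = nd$events, depth = nd$depth,
                fit = list(family = nd$fit$family, c = nd$fit$c,
                           mu = nd$fit$mu, rho = nd$fit$rho,
                           loglik = nd$fit$loglik, n_node = nd$fit$n_node,
                           events = nd$fit$events,
                           converged = nd$fit$converged))
    if (!is.na(nd$parent)) out$parent <- nd$parent
    if (!is.null(nd$children)) out$children <- nd$children
    if (!is.null(nd$split)) out$split <- nd$split
    out
  })
  js <- jsonlite::toJSON(list(family = tree$family, n_root = tree$n_root,
                              root_id = tree$root_id,
                              covariates = tree$covariates, nodes = nodes),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Rebuild a cure tree from its JSON serialization
#' @param json JSON string or file path produced by \code{tree_to_json}.
#' @return A \code{cure_tree} (control options take package defaults).
#' @export
tree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  nodes <- lapply(obj$nodes, function(nd) {
    fit <- structure(list(family = nd$fit$family, c = nd$fit$c,
                          mu = nd$fit$mu, rho = nd$fit$rho,
                          loglik = nd$fit$loglik, n_node = nd$fit$n_node,
                          events = nd$fit$events,
                          converged = isTRUE(nd$fit$converged)),
                     class = "param_cure_fit")
    list(id = as.integer(nd$id),
         parent = if (length(nd$parent) == 0) NA_integer_
                  else as.integer(nd$parent),
         children = if (length(nd$children) == 0) NULL
                    else as.integer(unlist(nd$children)),
         split = if (length(nd$split) == 0) NULL
                 else list(var = nd$split$var, cut = as.numeric(nd$split$cut)),
         fit = fit, n = as.integer(nd$n), events = as.integer(nd$events),
         depth = as.integer(nd$depth))
  })
  names(nodes) <- vapply(nodes, function(nd) as.character(nd$id), character(1))
  structure(list(nodes = nodes, root_id = as.integer(obj$root_id),
                 family = obj$family, n_root = as.integer(obj$n_root),
                 covariates = as.character(unlist(obj$covariates)),
                 control = cure_cart_control()),
            class = "cure_tree")
}
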