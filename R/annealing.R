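# Simulated-annealing search over logic trees, scored by least squares of a
# continuous response (stage-2 Pearson residuals) on the tree's 0/1 output.
#
# Because the score depends on the tree only through its values on the
# observed predictor patterns (at most 2^k for k lagged indicators), rows
# are collapsed to per-pattern sufficient statistics (count, sum, sum of
# squares) once; each candidate tree is then scored in O(2^k).

make_score_context <- function(x, r) {
  x <- as.matrix(x)
  keep <- stats::complete.cases(x) & is.finite(r)
  x <- x[keep, , drop = FALSE]
  r <- r[keep]
  n <- nrow(x)
  if (n < 10L) stop_invalid("need at least 10 complete rows to score trees")
  k <- ncol(x)
  pid <- as.integer(x %*% 2^(seq_len(k) - 1L)) + 1L
  upid <- sort(unique(pid))
  m <- match(pid, upid)
  n_p <- tabulate(m, length(upid))
  s_p <- as.numeric(rowsum(r, m))
  q_p <- as.numeric(rowsum(r^2, m))
  patterns <- matrix(0L, length(upid), k)
  for (j in seq_len(k)) patterns[, j] <- bitwAnd(upid - 1L, bitwShiftL(1L, j - 1L)) > 0L
  list(patterns = patterns, n_p = n_p, s_p = s_p, q_p = q_p,
       n = n, s = sum(s_p), q = sum(q_p), k = k,
       tss = sum(q_p) - sum(s_p)^2 / n)
}

# rss + group means for the truth values h (0/1 per pattern)
score_h <- function(ctx, h) {
  i1 <- h == 1L
  n1 <- sum(ctx$n_p[i1]); n0 <- ctx$n - n1
  if (n1 == 0L || n0 == 0L) {
    mu <- ctx$s / ctx$n
    return(list(rss = ctx$tss, intercept = mu, slope = 0, constant = TRUE))
  }
  s1 <- sum(ctx$s_p[i1]); s0 <- ctx$s - s1
  rss <- ctx$q - s0^2 / n0 - s1^2 / n1
  list(rss = rss, intercept = s0 / n0, slope = s1 / n1 - s0 / n0,
       constant = FALSE)
}

# held-out rss of a fitted (intercept, slope) rule on another context
holdout_rss <- function(ctx, h, intercept, slope) {
  fitted <- intercept + slope * (h == 1L)
  sum(ctx$q_p - 2 * fitted * ctx$s_p + ctx$n_p * fitted^2)
}

#' Score a logic tree against a residual series
#'
#' Least-squares fit of the response on the tree's binary output; the
#' residual sum of squares is the annealing objective. A constant tree
#' output scores the total sum of squares with zero slope.
#'
#' @param tree A `logic_tree`.
#' @param x Binary predictor matrix (days in rows).
#' @param r Numeric response (Pearson residuals).
#' @return List with `rss`, `coef` (intercept, slope) and `n`.
#' @export
score_tree <- function(tree, x, r) {
  ctx <- make_score_context(x, r)
  h <- evaluate_tree(tree, ctx$patterns)
  sc <- score_h(ctx, h)
  list(rss = sc$rss, coef = c(intercept = sc$intercept, slope = sc$slope),
       n = ctx$n)
}

# ---- tree moves -------------------------------------------------------------

# Enumerate node paths; a path is an integer vector (1 = left, 2 = right),
# empty for the root.
node_paths <- function(tree, path = integer()) {
  if (tree$type == "leaf") return(list(list(path = path, leaf = TRUE)))
  c(list(list(path = path, leaf = FALSE)),
    node_paths(tree$left, c(path, 1L)),
    node_paths(tree$right, c(path, 2L)))
}

get_node <- function(tree, path) {
  for (p in path) tree <- if (p == 1L) tree$left else tree$right
  tree
}

set_node <- function(tree, path, value) {
  if (length(path) == 0L) return(value)
  if (path[1] == 1L) tree$left <- set_node(tree$left, path[-1], value)
  else tree$right <- set_node(tree$right, path[-1], value)
  tree
}

random_leaf <- function(k) logic_leaf(sample.int(k, 1L), stats::runif(1) < 0.5)

#' Propose a neighboring logic tree
#'
#' Applies one uniformly chosen applicable move from the classical
#' neighborhood: alternate a leaf's predictor, complement a leaf, alternate
#' an operator, grow a branch (insert an operator above a subtree with a
#' new leaf sibling), prune a branch (replace an operator node by one of
#' its children), split a leaf, or delete a leaf. The result respects
#' `max_leaves` and remains a full binary tree; the input is unmodified.
#'
#' @param tree A `logic_tree`.
#' @param k Number of predictors.
#' @param max_leaves Leaf budget.
#' @return A new `logic_tree`.
#' @export
propose_move <- function(tree, k, max_leaves) {
  nodes <- node_paths(tree)
  leaves <- Filter(function(nd) nd$leaf, nodes)
  internals <- Filter(function(nd) !nd$leaf, nodes)
  nl <- length(leaves)
  moves <- c("complement_leaf",
             if (k >= 2L) "alternate_leaf",
             if (length(internals)) c("alternate_operator", "prune_branch",
                                      "delete_leaf"),
             if (nl < max_leaves) "split_leaf",
             if (nl < max_leaves && length(internals)) "grow_branch")
  move <- moves[[sample.int(length(moves), 1L)]]
  pick <- function(set) set[[sample.int(length(set), 1L)]]
  switch(move,
    alternate_leaf = {
      nd <- pick(leaves)
      leaf <- get_node(tree, nd$path)
      new_idx <- pick(as.list(setdiff(seq_len(k), leaf$index)))
      set_node(tree, nd$path, logic_leaf(new_idx, leaf$complemented))
    },
    complement_leaf = {
      nd <- pick(leaves)
      leaf <- get_node(tree, nd$path)
      set_node(tree, nd$path, logic_leaf(leaf$index, !leaf$complemented))
    },
    alternate_operator = {
      nd <- pick(internals)
      node <- get_node(tree, nd$path)
      node$op <- if (node$op == "and") "or" else "and"
      set_node(tree, nd$path, node)
    },
    grow_branch = {
      nd <- pick(internals)
      sub <- get_node(tree, nd$path)
      op <- if (stats::runif(1) < 0.5) "and" else "or"
      grown <- if (stats::runif(1) < 0.5) logic_node(op, sub, random_leaf(k))
               else logic_node(op, random_leaf(k), sub)
      set_node(tree, nd$path, grown)
    },
    prune_branch = {
      nd <- pick(internals)
      node <- get_node(tree, nd$path)
      child <- if (stats::runif(1) < 0.5) node$left else node$right
      set_node(tree, nd$path, child)
    },
    split_leaf = {
      nd <- pick(leaves)
      leaf <- get_node(tree, nd$path)
      op <- if (stats::runif(1) < 0.5) "and" else "or"
      split <- if (stats::runif(1) < 0.5) logic_node(op, leaf, random_leaf(k))
               else logic_node(op, random_leaf(k), leaf)
      set_node(tree, nd$path, split)
    },
    delete_leaf = {
      nd <- pick(leaves)
      parent_path <- nd$path[-length(nd$path)]
      parent <- get_node(tree, parent_path)
      sibling <- if (nd$path[length(nd$path)] == 1L) parent$right else parent$left
      set_node(tree, parent_path, sibling)
    })
}

#' Annealing schedule
#'
#' Geometric cooling from `start_temperature` to `end_temperature` over
#' `n_iterations`. When the temperatures are `NULL` they are calibrated
#' per run from the local score-change scale so that the initial
#' acceptance probability of an uphill move is about 0.9 and the terminal
#' one about 1e-3.
#'
#' @param start_temperature,end_temperature Positive reals,
#'   `end < start`, or `NULL` for auto-calibration.
#' @param n_iterations Number of annealing iterations (default 25000).
#' @return An `annealing_schedule` object.
#' @export
annealing_schedule <- function(start_temperature = NULL,
                               end_temperature = NULL,
                               n_iterations = 25000L) {
  if (!is.null(start_temperature) && !is.null(end_temperature) &&
      (start_temperature <= 0 || end_temperature <= 0 ||
       end_temperature >= start_temperature))
    stop_invalid("need 0 < end_temperature < start_temperature")
  structure(list(start_temperature = start_temperature,
                 end_temperature = end_temperature,
                 n_iterations = as.integer(n_iterations)),
            class = "annealing_schedule")
}

# canonical tie-break key for score-equal trees: fewer literals first, then
# the clauses' digit keys; locale-independent by construction
dnf_key <- function(tree) {
  d <- to_dnf(tree)
  if (length(d) == 0L) return("000|")
  keys <- vapply(d, function(cl)
    paste(sprintf("%02d%d", abs(cl), as.integer(cl < 0)), collapse = ""), "")
  sprintf("%03d|%s", sum(lengths(d)), paste(keys, collapse = "|"))
}

# one annealing run from a random single-leaf start; RNG state is the caller's
anneal_once <- function(ctx, max_leaves, schedule) {
  k <- ctx$k
  cur <- random_leaf(k)
  cur_rss <- score_h(ctx, evaluate_tree(cur, ctx$patterns))$rss
  t_start <- schedule$start_temperature
  t_end <- schedule$end_temperature
  if (is.null(t_start) || is.null(t_end)) {
    # probe the uphill score-change scale with a short random walk
    probe <- cur; deltas <- numeric(0)
    for (i in 1:60) {
      cand <- propose_move(probe, k, max_leaves)
      d <- score_h(ctx, evaluate_tree(cand, ctx$patterns))$rss -
           score_h(ctx, evaluate_tree(probe, ctx$patterns))$rss
      if (d > 0) deltas <- c(deltas, d)
      probe <- cand
    }
    d0 <- if (length(deltas)) stats::median(deltas) else ctx$tss * 1e-3
    d0 <- max(d0, ctx$tss * 1e-6, .Machine$double.eps)
    t_start <- d0 / -log(0.9)
    t_end <- d0 / -log(1e-3)
  }
  n_iter <- schedule$n_iterations
  cool <- (t_end / t_start)^(1 / max(1L, n_iter - 1L))
  best <- cur; best_rss <- cur_rss; best_key <- NULL
  temp <- t_start
  tol <- 1e-9 * (1 + ctx$tss)
  for (i in seq_len(n_iter)) {
    cand <- propose_move(cur, k, max_leaves)
    cand_rss <- score_h(ctx, evaluate_tree(cand, ctx$patterns))$rss
    d <- cand_rss - cur_rss
    if (d <= 0 || stats::runif(1) < exp(-d / temp)) {
      cur <- cand; cur_rss <- cand_rss
      if (cur_rss < best_rss - tol) {
        best <- cur; best_rss <- cur_rss; best_key <- NULL
      } else if (cur_rss <= best_rss + tol) {
        # tie: keep the lexicographically smallest canonical DNF
        if (is.null(best_key)) best_key <- dnf_key(best)
        ck <- dnf_key(cur)
        if (ck < best_key) { best <- cur; best_rss <- min(best_rss, cur_rss); best_key <- ck }
      }
    }
    temp <- temp * cool
  }
  list(tree = best, rss = best_rss)
}

#' Learn a logic tree by simulated annealing
#'
#' Metropolis search over the tree neighborhood of [propose_move()] with
#' geometric cooling, minimizing the residual sum of squares of the
#' response regressed on the tree output. The best tree visited across
#' `n_restarts` independent runs is returned; results are deterministic
#' given `seed`.
#'
#' @param x Binary predictor matrix (days in rows).
#' @param r Numeric response (Pearson residuals).
#' @param max_leaves Leaf budget for the tree.
#' @param schedule An [annealing_schedule()].
#' @param n_restarts Independent restarts (default 5).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `logic_tree` with attributes `rss` and `coef`.
#' @export
anneal_logic_tree <- function(x, r, max_leaves = 3L,
                              schedule = annealing_schedule(),
                              n_restarts = 5L, seed = NULL) {
  ctx <- make_score_context(x, r)
  with_seed(seed, {
    best <- NULL
    for (s in seq_len(n_restarts)) {
      run <- anneal_once(ctx, max_leaves, schedule)
      if (is.null(best) || run$rss < best$rss - 1e-12 ||
          (run$rss <= best$rss + 1e-12 && dnf_key(run$tree) < dnf_key(best$tree)))
        best <- run
    }
    sc <- score_h(ctx, evaluate_tree(best$tree, ctx$patterns))
    out <- best$tree
    attr(out, "rss") <- sc$rss
    attr(out, "coef") <- c(intercept = sc$intercept, slope = sc$slope)
    out
  })
}

# ---- exhaustive enumeration (test oracle for small instances) ---------------

#' Enumerate distinct Boolean functions representable by small logic trees
#'
#' Builds, by dynamic programming on leaf count with truth-table
#' deduplication, one representative tree per distinct Boolean function of
#' `k` predictors representable with at most `max_leaves` leaves.
#'
#' @param k Number of predictors (<= 4).
#' @param max_leaves Leaf budget (<= 4).
#' @return List with `trees` (representatives) and `tables` (matrix of
#'   truth tables, one row per function).
#' @export
enumerate_boolean_functions <- function(k, max_leaves) {
  if (k > 4 || max_leaves > 4)
    stop_invalid("exhaustive enumeration supported only for k <= 4, max_leaves <= 4")
  key_of <- function(tt) paste(tt, collapse = "")
  # by_size[[m]]: named list key -> tree with exactly m leaves (deduped)
  literals <- list()
  for (i in seq_len(k)) for (cmp in c(FALSE, TRUE)) {
    tr <- logic_leaf(i, cmp)
    literals[[key_of(truth_table(tr, k))]] <- tr
  }
  by_size <- list(literals)
  seen <- names(literals)
  if (max_leaves >= 2) for (m in 2:max_leaves) {
    new <- list()
    for (i in seq_len(m - 1)) {
      j <- m - i
      if (j > length(by_size) || i > length(by_size)) next
      for (a in by_size[[i]]) for (b in by_size[[j]]) for (op in c("and", "or")) {
        tr <- logic_node(op, a, b)
        ky <- key_of(truth_table(tr, k))
        if (!(ky %in% seen) && !(ky %in% names(new))) new[[ky]] <- tr
      }
    }
    by_size[[m]] <- new
    seen <- c(seen, names(new))
  }
  trees <- unlist(by_size, recursive = FALSE)
  tables <- do.call(rbind, lapply(trees, truth_table, k = k))
  list(trees = unname(trees), tables = unname(tables), keys = names(trees))
}

#' Exhaustively find the best-scoring small logic tree
#'
#' Enumerates every distinct Boolean function representable within the
#' leaf budget and returns the tree minimizing the residual sum of
#' squares; ties break to the lexicographically smallest canonical DNF.
#' Intended as an independent optimum reference for small instances.
#'
#' @inheritParams anneal_logic_tree
#' @return A `logic_tree` with attribute `rss`.
#' @export
exhaustive_best_tree <- function(x, r, max_leaves = 2L) {
  x <- as.matrix(x)
  k <- ncol(x)
  if (k > 4 || max_leaves > 4)
    stop_invalid("exhaustive search supported only for k <= 4, max_leaves <= 4")
  ctx <- make_score_context(x, r)
  enum <- enumerate_boolean_functions(k, max_leaves)
  best <- NULL; best_rss <- Inf; best_dnf <- NULL
  for (tr in enum$trees) {
    rss <- score_h(ctx, evaluate_tree(tr, ctx$patterns))$rss
    if (rss < best_rss - 1e-12) {
      best <- tr; best_rss <- rss; best_dnf <- NULL
    } else if (rss <= best_rss + 1e-12) {
      if (is.null(best_dnf)) best_dnf <- dnf_key(best)
      ck <- dnf_key(tr)
      if (ck < best_dnf) { best <- tr; best_dnf <- ck }
    }
  }
  attr(best, "rss") <- best_rss
  best
}

# ---- cross-validated size selection -----------------------------------------

#' Select the tree size by ten-fold cross-validation
#'
#' For each candidate leaf count, a tree is annealed on each training fold
#' and its fitted intercept/slope rule is evaluated on the held-out fold;
#' the size minimizing the average held-out residual sum of squares wins,
#' with ties going to the smaller size. Size 0 denotes the intercept-only
#' (no exposure) model and may be offered as a candidate.
#'
#' @param x Binary predictor matrix.
#' @param r Numeric response.
#' @param candidate_sizes Integer leaf counts to compare (default 1:3).
#' @param n_folds Number of folds (default 10), assigned at random by day.
#' @param schedule [annealing_schedule()] used for the per-fold annealing.
#' @param n_restarts Restarts per fold annealing (default 1).
#' @param seed Integer seed for fold assignment and annealing.
#' @return List with `size` (selected) and `cv` (data frame of sizes and
#'   mean held-out rss).
#' @export
select_tree_size <- function(x, r, candidate_sizes = 1:3, n_folds = 10L,
                             schedule = annealing_schedule(n_iterations = 2000L),
                             n_restarts = 1L, seed = NULL) {
  if (length(candidate_sizes) == 0L) stop_invalid("candidate_sizes is empty")
  x <- as.matrix(x)
  keep <- stats::complete.cases(x) & is.finite(r)
  x <- x[keep, , drop = FALSE]; r <- r[keep]
  n <- nrow(x)
  if (n < 2L * n_folds) stop_invalid("too few rows for ", n_folds, "-fold CV")
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(n_folds), n))
    cv_err <- numeric(length(candidate_sizes))
    for (si in seq_along(candidate_sizes)) {
      size <- candidate_sizes[si]
      tot <- 0
      for (f in seq_len(n_folds)) {
        tr_i <- fold != f
        ctx_te <- make_score_context(x[!tr_i, , drop = FALSE], r[!tr_i])
        if (size == 0L) {
          mu <- mean(r[tr_i])
          h_te <- rep(0L, nrow(ctx_te$patterns))
          tot <- tot + holdout_rss(ctx_te, h_te, mu, 0)
        } else {
          tree <- anneal_logic_tree(x[tr_i, , drop = FALSE], r[tr_i],
                                    max_leaves = size, schedule = schedule,
                                    n_restarts = n_restarts)
          cf <- attr(tree, "coef")
          h_te <- evaluate_tree(tree, ctx_te$patterns)
          tot <- tot + holdout_rss(ctx_te, h_te, cf[["intercept"]], cf[["slope"]])
        }
      }
      cv_err[si] <- tot / n
    }
    ord <- order(cv_err, candidate_sizes)
    list(size = candidate_sizes[ord[1]],
         cv = data.frame(size = candidate_sizes, cv_rss = cv_err))
  })
}
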