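#' Logic trees over binary heat indicators
#'
#' A logic tree is a full binary tree whose leaves are (possibly
#' complemented) binary predictors and whose internal nodes are AND/OR
#' operators. Evaluated on a day's indicator vector it yields the binary
#' exposure H(X). These constructors build trees programmatically; the
#' annealing search in [anneal_logic_tree()] learns them from data.
#'
#' @param index 1-based predictor column index.
#' @param complemented Logical; TRUE for the negated literal.
#' @name logic_tree
NULL

#' @rdname logic_tree
#' @export
logic_leaf <- function(index, complemented = FALSE) {
  stopifnot(is.numeric(index), index >= 1)
  structure(list(type = "leaf", index = as.integer(index),
                 complemented = isTRUE(complemented)),
            class = "logic_tree")
}

#' @rdname logic_tree
#' @param op `"and"` or `"or"`.
#' @param left,right Child `logic_tree` nodes.
#' @export
logic_node <- function(op, left, right) {
  op <- match.arg(op, c("and", "or"))
  stopifnot(inherits(left, "logic_tree"), inherits(right, "logic_tree"))
  structure(list(type = "op", op = op, left = left, right = right),
            class = "logic_tree")
}

#' Number of leaves of a logic tree
#' @param tree A `logic_tree`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(tree) {
  if (tree$type == "leaf") return(1L)
  n_leaves(tree$left) + n_leaves(tree$right)
}

#' Evaluate a logic tree on binary predictor rows
#'
#' @param tree A `logic_tree`.
#' @param x A binary vector (one day) or matrix (days in rows, predictors
#'   in columns) with values in \{0, 1, NA\}.
#' @return Integer 0/1 per row; NA where a referenced predictor is missing.
#' @export
evaluate_tree <- function(tree, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  out <- eval_rec(tree, x)
  as.integer(out)
}

eval_rec <- function(tree, x) {
  if (tree$type == "leaf") {
    v <- x[, tree$index] > 0
    if (tree$complemented) !v else v
  } else if (tree$op == "and") {
    eval_rec(tree$left, x) & eval_rec(tree$right, x)
  } else {
    eval_rec(tree$left, x) | eval_rec(tree$right, x)
  }
}

#' Truth table of a logic tree
#'
#' Evaluates the tree on all 2^k assignments of its predictors, in binary
#' counting order with predictor 1 varying fastest.
#'
#' @param tree A `logic_tree`.
#' @param k Number of predictors (<= 20).
#' @return Integer 0/1 vector of length 2^k.
#' @export
truth_table <- function(tree, k) {
  if (k > 20) stop_invalid("truth-table enumeration limited to k <= 20")
  grid <- as.matrix(expand.grid(rep(list(0:1), k)))
  evaluate_tree(tree, grid)
}

#' Test whether two logic trees classify identically
#'
#' Compares full truth tables over all 2^k assignments; feasible for the
#' small predictor counts used for lagged heat indicators.
#'
#' @param a,b `logic_tree` objects.
#' @param k Number of predictors spanned.
#' @return TRUE iff the trees agree on every assignment.
#' @export
trees_equivalent <- function(a, b, k) {
  identical(truth_table(a, k), truth_table(b, k))
}

#' Complement a logic tree
#'
#' De Morgan propagation: operators are swapped and leaves toggled, so the
#' result is a valid tree (complements only at leaves) computing the
#' pointwise negation.
#'
#' @param tree A `logic_tree`.
#' @return The complemented `logic_tree`.
#' @export
complement_tree <- function(tree) {
  if (tree$type == "leaf")
    return(logic_leaf(tree$index, !tree$complemented))
  logic_node(if (tree$op == "and") "or" else "and",
             complement_tree(tree$left), complement_tree(tree$right))
}

# ---- disjunctive normal form ------------------------------------------------

# A clause is an integer vector of signed indices: +i for X_i, -i for X_i^c,
# sorted by abs value. A DNF is a list of clauses.

clause_normalize <- function(lits) {
  lits <- unique(lits)
  if (any(lits %in% -lits)) return(NULL)  # contains X and X^c: always false
  lits[order(abs(lits), lits)]
}

dnf_rec <- function(tree) {
  if (tree$type == "leaf")
    return(list(if (tree$complemented) -tree$index else tree$index))
  l <- dnf_rec(tree$left); r <- dnf_rec(tree$right)
  if (tree$op == "or") return(c(l, r))
  out <- list()
  for (cl in l) for (cr in r) {
    cc <- clause_normalize(c(cl, cr))
    if (!is.null(cc)) out[[length(out) + 1L]] <- cc
  }
  out
}

#' Disjunctive normal form of a logic tree
#'
#' Expands the tree by the distributive law into an OR of AND-clauses of
#' literals, removes contradictory and duplicate clauses, applies
#' absorption (a clause implied by a subset clause is dropped), and sorts
#' clauses canonically. Two equivalent trees built from the same clauses
#' therefore render identically.
#'
#' @param tree A `logic_tree`.
#' @return Object of class `dnf`: list of integer clause vectors (signed
#'   predictor indices, negative = complemented).
#' @export
to_dnf <- function(tree) {
  clauses <- dnf_rec(tree)
  clauses <- unique(clauses)
  if (length(clauses) > 1L) {
    # absorption: drop any clause that is a superset of another
    keep <- rep(TRUE, length(clauses))
    for (i in seq_along(clauses)) for (j in seq_along(clauses)) {
      if (i != j && keep[j] && keep[i] &&
          all(clauses[[j]] %in% clauses[[i]]) &&
          length(clauses[[j]]) < length(clauses[[i]]))
        keep[i] <- FALSE
    }
    clauses <- clauses[keep]
  }
  # canonical clause order: by predictor index, complemented after plain;
  # digit-only keys keep the ordering locale-independent
  key <- vapply(clauses, function(cl)
    paste(sprintf("%02d%d", abs(cl), as.integer(cl < 0)), collapse = ""), "")
  clauses <- clauses[order(key)]
  structure(clauses, class = "dnf")
}

#' Render a DNF (or tree) as a human-readable exposure rule
#'
#' One AND-clause per OR term, e.g. `"(lag0 AND lag1) OR (lag1 AND lag3)"`;
#' complemented literals render as `NOT lag2`.
#'
#' @param x A `dnf` or `logic_tree`.
#' @param labels Character predictor labels; default `lag0`, `lag1`, ...
#' @return A single string ("FALSE" for an empty, never-true rule).
#' @export
dnf_string <- function(x, labels = NULL) {
  if (inherits(x, "logic_tree")) x <- to_dnf(x)
  if (length(x) == 0L) return("FALSE")
  if (is.null(labels)) {
    kmax <- max(vapply(x, function(cl) max(abs(cl)), 0))
    labels <- paste0("lag", seq_len(kmax) - 1L)
  }
  lit <- function(l) if (l < 0) paste("NOT", labels[-l]) else labels[l]
  cl_str <- vapply(x, function(cl) paste(vapply(cl, lit, ""), collapse = " AND "), "")
  if (length(cl_str) == 1L) return(cl_str)
  paste(paste0("(", cl_str, ")"), collapse = " OR ")
}

#' @export
format.dnf <- function(x, ...) dnf_string(x, ...)

#' @export
print.dnf <- function(x, ...) { cat(dnf_string(x), "\n"); invisible(x) }

#' Rebuild a logic tree from a DNF
#'
#' Left-deep AND chains joined by a left-deep OR chain; the result is
#' equivalent to the DNF by construction.
#'
#' @param dnf A `dnf` object (non-empty).
#' @return A `logic_tree`.
#' @export
dnf_to_tree <- function(dnf) {
  if (length(dnf) == 0L) stop_invalid("cannot build a tree from an empty DNF")
  build_chain <- function(nodes, op) Reduce(function(a, b) logic_node(op, a, b), nodes)
  clause_tree <- function(cl)
    build_chain(lapply(cl, function(l) logic_leaf(abs(l), l < 0)), "and")
  build_chain(lapply(dnf, clause_tree), "or")
}

#' @export
format.logic_tree <- function(x, ...) dnf_string(to_dnf(x), ...)

#' @export
print.logic_tree <- function(x, ...) {
  cat("logic tree (", n_leaves(x), " leaves): ", format(x), "\n", sep = "")
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

tree_to_list <- function(tree) {
  if (tree$type == "leaf")
    return(list(type = "leaf", index = tree$index,
                complemented = tree$complemented))
  list(type = "op", op = tree$op,
       left = tree_to_list(tree$left), right = tree_to_list(tree$right))
}

list_to_tree <- function(x) {
  if (x$type == "leaf") return(logic_leaf(x$index, isTRUE(x$complemented)))
  logic_node(x$op, list_to_tree(x$left), list_to_tree(x$right))
}

#' Serialize / deserialize a logic tree as JSON
#'
#' Round-trip is exact: `tree_from_json(tree_to_json(t))` reproduces `t`.
#'
#' @param tree A `logic_tree`.
#' @param path File path; `tree_to_json` returns the JSON string when
#'   `path` is NULL.
#' @return `tree_to_json`: JSON string (invisibly when written to file);
#'   `tree_from_json`: a `logic_tree`.
#' @export
tree_to_json <- function(tree, path = NULL) {
  js <- jsonlite::toJSON(tree_to_list(tree), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname tree_to_json
#' @param json JSON string or file path of a serialized tree.
#' @export
tree_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  list_to_tree(x)
}

#' Orient a tree so exposed days are the minority
#'
#' The reference group (H = 0) is defined as the type of day more
#' frequently observed; when a tree labels more than half the evaluable
#' days as exposed, its De Morgan complement is returned instead.
#'
#' @param tree A `logic_tree`.
#' @param x Binary predictor matrix of observed days.
#' @return A `logic_tree` with minority exposed days.
#' @export
orient_reference <- function(tree, x) {
  h <- evaluate_tree(tree, x)
  n1 <- sum(h == 1L, na.rm = TRUE)
  n <- sum(!is.na(h))
  if (n1 * 2L == n) {
    warning("exposure splits days exactly 50/50; tree returned unchanged")
    return(tree)
  }
  if (n1 * 2L > n) complement_tree(tree) else tree
}
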