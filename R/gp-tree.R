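# Expression trees for symbolic regression.
#
# Compact representation chosen for speed in the evolutionary loop:
#   - operator node: list(op, child) or list(op, left, right)
#   - leaf: a character scalar (feature name) or a numeric scalar (constant)

gp_binary_ops <- c("add", "sub", "mul", "div")
gp_unary_ops <- c("sqrt", "log", "inv")
gp_ops <- c(gp_binary_ops, gp_unary_ops)

gp_arity <- function(op) if (op %in% gp_binary_ops) 2L else 1L

#' Build an expression-tree node
#'
#' Constructors for the symbolic-regression function set
#' `{add, sub, mul, div, sqrt, log, inv}` over feature references and real
#' constants. `gp_var("x")` references feature `x`; `gp_const(2.5)` is a
#' constant; `gp_node("add", a, b)` applies an operator. Division, logarithm
#' and inversion have protected semantics at evaluation time (see
#' [evaluate_tree()]).
#'
#' @param op Operator name, one of `add`, `sub`, `mul`, `div` (binary),
#'   `sqrt`, `log`, `inv` (unary).
#' @param ... Child nodes (2 for binary, 1 for unary operators).
#' @return A tree node.
#' @export
gp_node <- function(op, ...) {
  op <- match.arg(op, gp_ops)
  kids <- list(...)
  if (length(kids) != gp_arity(op)) {
    stop("operator '", op, "' takes ", gp_arity(op), " argument(s), got ",
         length(kids), call. = FALSE)
  }
  c(list(op), kids)
}

#' @rdname gp_node
#' @param name Feature (column) name.
#' @export
gp_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  name
}

#' @rdname gp_node
#' @param value Numeric scalar constant.
#' @export
gp_const <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  as.numeric(value)
}

#' Number of nodes in an expression tree
#'
#' @param tree A tree node.
#' @return Integer node count (>= 1).
#' @export
tree_length <- function(tree) {
  if (!is.list(tree)) return(1L)
  n <- 1L
  for (i in 2:length(tree)) n <- n + tree_length(tree[[i]])
  n
}

#' Depth of an expression tree
#'
#' A single leaf has depth 0.
#'
#' @param tree A tree node.
#' @return Integer depth.
#' @export
tree_depth <- function(tree) {
  if (!is.list(tree)) return(0L)
  d <- 0L
  for (i in 2:length(tree)) d <- max(d, tree_depth(tree[[i]]))
  d + 1L
}

#' Evaluate an expression tree on a dataset
#'
#' Vectorised evaluation over the rows of `data`. The operators are
#' protected so evaluation is total on finite inputs:
#' `div(a, b) = 1` where `|b| < 1e-6`; `log(x) = log10(|x|)` with
#' `log(0) = 0`; `sqrt(x) = sqrt(|x|)`; `inv(x) = 1` where `|x| < 1e-6`,
#' else `1/x`. Logs are base 10, matching the response scale (decades of
#' relative rate).
#'
#' @param tree A tree node (see [gp_node()]).
#' @param data Data frame or named list of equal-length numeric columns.
#' @return Numeric vector of predictions, one per row.
#' @examples
#' evaluate_tree(gp_node("add", gp_var("x0"), gp_var("x1")),
#'               data.frame(x0 = c(1, 3), x1 = c(2, 4)))  # 3, 7
#' @export
evaluate_tree <- function(tree, data) {
  n <- length(data[[1]])
  gp_eval(tree, data, n)
}

gp_eval <- function(node, data, n) {
  if (!is.list(node)) {
    if (is.character(node)) {
      col <- data[[node]]
      if (is.null(col)) {
        stop("unknown feature name '", node, "'", call. = FALSE)
      }
      return(col)
    }
    return(rep.int(node, n))
  }
  op <- node[[1]]
  a <- gp_eval(node[[2]], data, n)
  if (op == "add") return(a + gp_eval(node[[3]], data, n))
  if (op == "sub") return(a - gp_eval(node[[3]], data, n))
  if (op == "mul") return(a * gp_eval(node[[3]], data, n))
  if (op == "div") {
    b <- gp_eval(node[[3]], data, n)
    r <- a / b
    r[abs(b) < 1e-6] <- 1
    return(r)
  }
  if (op == "sqrt") return(sqrt(abs(a)))
  if (op == "log") {
    r <- log10(abs(a))
    r[a == 0] <- 0
    return(r)
  }
  # inv
  r <- 1 / a
  r[abs(a) < 1e-6] <- 1
  r
}

# Uniformly indexed subtree access (preorder, 1-based).
get_subtree <- function(tree, k) {
  if (k == 1L) return(tree)
  k <- k - 1L
  for (i in 2:length(tree)) {
    sz <- tree_length(tree[[i]])
    if (k <= sz) return(get_subtree(tree[[i]], k))
    k <- k - sz
  }
  stop("subtree index out of range", call. = FALSE)
}

replace_subtree <- function(tree, k, new) {
  if (k == 1L) return(new)
  k <- k - 1L
  for (i in 2:length(tree)) {
    sz <- tree_length(tree[[i]])
    if (k <= sz) {
      tree[[i]] <- replace_subtree(tree[[i]], k, new)
      return(tree)
    }
    k <- k - sz
  }
  stop("subtree index out of range", call. = FALSE)
}

# Random tree generation. method "full" places operators at every level
# until `depth`; "grow" may stop early at a terminal.
random_tree <- function(feature_names, depth, method = c("grow", "full"),
                        const_range = c(-5, 5), p_const = 0.3) {
  method <- match.arg(method)
  if (depth <= 0L ||
      (method == "grow" && depth > 0L && stats::runif(1) < 0.3)) {
    if (stats::runif(1) < p_const) {
      return(gp_const(stats::runif(1, const_range[1], const_range[2])))
    }
    return(gp_var(sample(feature_names, 1L)))
  }
  op <- sample(gp_ops, 1L)
  if (gp_arity(op) == 2L) {
    gp_node(op,
            random_tree(feature_names, depth - 1L, method, const_range, p_const),
            random_tree(feature_names, depth - 1L, method, const_range, p_const))
  } else {
    gp_node(op,
            random_tree(feature_names, depth - 1L, method, const_range, p_const))
  }
}

#' Render an expression tree as text
#'
#' `tree_to_infix()` gives a conventional mathematical rendering;
#' `tree_to_prefix()` gives the s-expression form.
#'
#' @param tree A tree node.
#' @return A single string.
#' @export
tree_to_infix <- function(tree) {
  if (!is.list(tree)) {
    if (is.character(tree)) return(tree)
    return(format(tree, digits = 6))
  }
  op <- tree[[1]]
  if (op %in% gp_binary_ops) {
    sym <- c(add = "+", sub = "-", mul = "*", div = "/")[[op]]
    paste0("(", tree_to_infix(tree[[2]]), " ", sym, " ",
           tree_to_infix(tree[[3]]), ")")
  } else {
    fn <- c(sqrt = "sqrt", log = "log10", inv = "inv")[[op]]
    paste0(fn, "(", tree_to_infix(tree[[2]]), ")")
  }
}

#' @rdname tree_to_infix
#' @export
tree_to_prefix <- function(tree) {
  if (!is.list(tree)) {
    if (is.character(tree)) return(tree)
    return(format(tree, digits = 6))
  }
  paste0(tree[[1]], "(",
         paste(vapply(tree[-1], tree_to_prefix, character(1)),
               collapse = ", "), ")")
}
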