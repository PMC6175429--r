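# Linear L1 soft-margin SVM: thin R interface over the SMO solver in src/.

#' Fit a linear L1 soft-margin support vector machine
#'
#' Solves the standard C-SVC dual with a linear kernel by sequential minimal
#' optimization. The positive class (+1) is the alphabetically first label,
#' so signs of the weight vector are reproducible across fits.
#'
#' @param x Numeric matrix, observations x features.
#' @param y Binary labels (factor, character or numeric with two distinct
#'   values).
#' @param cost Box constraint `c`: the maximum penalty on margin-violating
#'   observations (default 1).
#' @param tol Duality-gap stopping tolerance of the SMO solver.
#' @param max_iter Iteration cap.
#' @return Object of class `linear_svm`: weight vector `w`, bias `b`,
#'   multipliers `alpha`, `support` indices, the support vectors `sv` with
#'   their signed labels `sv_y`, class `levels`, and flags `converged` and
#'   `separable` (FALSE when some margins are violated at the solution, e.g.
#'   for inconsistent labelings of identical rows).
#' @export
fit_svm <- function(x, y, cost = 1, tol = 1e-8, max_iter = 200000L) {
  x <- as.matrix(x)
  if (cost <= 0) stop("'cost' must be > 0", call. = FALSE)
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2) stop("'y' must contain exactly two classes", call. = FALSE)
  ys <- ifelse(as.character(y) == lev[1], 1, -1)
  if (nrow(x) != length(ys)) stop("nrow(x) != length(y)", call. = FALSE)
  fit <- .cpp_svm_fit(x, ys, cost, tol, as.integer(max_iter))
  sup <- which(fit$alpha > 1e-10)
  margins <- ys * (as.vector(x %*% fit$w) + fit$b)
  structure(list(
    w = as.vector(fit$w), b = fit$b, alpha = as.vector(fit$alpha),
    support = sup, sv = x[sup, , drop = FALSE], sv_y = ys[sup],
    levels = lev, cost = cost, converged = fit$converged,
    separable = all(margins >= 1 - 1e-6)), class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("Linear L1 soft-margin SVM (c =", x$cost, ")\n")
  cat("  classes: +1 =", x$levels[1], ", -1 =", x$levels[2], "\n")
  cat("  support vectors:", length(x$support),
      if (!x$separable) " [non-separable]", "\n")
  invisible(x)
}

#' Predict method for linear SVM fits
#'
#' @param object A `linear_svm` fit.
#' @param newdata Matrix of observations x features.
#' @param type `"class"` for labels, `"decision"` for decision values.
#' @param ... Unused.
#' @export
predict.linear_svm <- function(object, newdata,
                               type = c("class", "decision"), ...) {
  type <- match.arg(type)
  d <- as.vector(as.matrix(newdata) %*% object$w) + object$b
  if (type == "decision") return(d)
  object$levels[ifelse(d >= 0, 1L, 2L)]
}

#' Recover the SVM weight vector from its Lagrange multipliers
#'
#' Returns `w = sum_i alpha_i y_i x_i` over the support vectors. This is the
#' quantity fed into the weights-to-activation-pattern transformation.
#'
#' @param model A fitted `linear_svm`.
#' @return Numeric weight vector; attribute `"degenerate"` is `TRUE` when all
#'   multipliers are zero.
#' @export
svm_weight_vector <- function(model) {
  if (!inherits(model, "linear_svm"))
    stop("'model' must be a linear_svm fit", call. = FALSE)
  if (length(model$support) == 0L)
    return(structure(numeric(ncol(model$sv)), degenerate = TRUE))
  w <- colSums(model$alpha[model$support] * model$sv_y * model$sv)
  structure(as.vector(w), degenerate = all(w == 0))
}
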