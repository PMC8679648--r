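#' Full-factorial Lennard-Jones design grid
#'
#' Enumerates every combination of the supplied sigma and epsilon levels and
#' fixes the coded-value mapping from the level extremes: each axis is
#' mapped linearly so its smallest level codes to -1 and its largest to +1
#' (the standard response-surface convention).
#'
#' @param sigmaLevels strictly increasing sigma levels (nm), at least two.
#' @param epsilonLevels strictly increasing epsilon levels (kJ/mol), at
#'   least two.
#' @return an object of class \code{"designGrid"} with the level vectors,
#'   the full-factorial \code{points} data.frame (sigma, epsilon, x1, x2)
#'   and the coding bounds.
#' @export
#' @examples
#' g <- buildDesignGrid(seq(0.5, 0.625, 0.025), seq(0.05, 0.175, 0.025))
#' nrow(g$points)   # 36
buildDesignGrid <- function(sigmaLevels, epsilonLevels) {
  if (length(sigmaLevels) < 2 || length(epsilonLevels) < 2)
    stop("need at least two levels on each axis")
  if (any(diff(sigmaLevels) <= 0) || any(diff(epsilonLevels) <= 0))
    stop("levels must be strictly increasing")
  pts <- expand.grid(sigma = sigmaLevels, epsilon = epsilonLevels,
                     KEEP.OUT.ATTRS = FALSE)
  g <- structure(list(sigmaLevels = sigmaLevels,
                      epsilonLevels = epsilonLevels,
                      sigmaRange = range(sigmaLevels),
                      epsilonRange = range(epsilonLevels)),
                 class = "designGrid")
  coded <- codeValues(g, pts$sigma, pts$epsilon)
  g$points <- cbind(pts, x1 = coded$x1, x2 = coded$x2)
  g
}

#' @export
print.designGrid <- function(x, ...) {
  cat(sprintf("designGrid: %d x %d levels (%d design points); sigma [%g, %g] nm, epsilon [%g, %g] kJ/mol\n",
              length(x$sigmaLevels), length(x$epsilonLevels), nrow(x$points),
              x$sigmaRange[1], x$sigmaRange[2],
              x$epsilonRange[1], x$epsilonRange[2]))
  invisible(x)
}

#' Code and decode physical parameter values
#'
#' Linear map between physical (sigma, epsilon) and coded (x1, x2) values,
#' with the grid extremes at -1 and +1.  \code{decodeValues} is the exact
#' inverse.
#'
#' @param grid a \code{\link{buildDesignGrid}} object.
#' @param sigma,epsilon physical values.
#' @param x1,x2 coded values.
#' @return list with the transformed coordinates.
#' @export
codeValues <- function(grid, sigma, epsilon) {
  list(x1 = 2 * (sigma - mean(grid$sigmaRange)) / diff(grid$sigmaRange),
       x2 = 2 * (epsilon - mean(grid$epsilonRange)) / diff(grid$epsilonRange))
}

#' @rdname codeValues
#' @export
decodeValues <- function(grid, x1, x2) {
  list(sigma = mean(grid$sigmaRange) + x1 * diff(grid$sigmaRange) / 2,
       epsilon = mean(grid$epsilonRange) + x2 * diff(grid$epsilonRange) / 2)
}

#' Fit quadratic response-surface meta-models
#'
#' Fits each property's learning set (a response per design point) to a
#' second-order surface with cross-interaction term in the coded values,
#' \deqn{f(x_1, x_2) = b_0 + b_1 x_1 + b_2 x_2 + b_{11} x_1^2 + b_{22} x_2^2
#'  + b_{12} x_1 x_2,}
#' by least squares.  An exactly quadratic response is reproduced to
#' machine precision.
#'
#' @param design data.frame with coded columns \code{x1}, \code{x2} (e.g.
#'   \code{grid$points}).
#' @param responses numeric matrix or data.frame: one column per
#'   (molecule, property) response, one row per design point.
#' @return list of \code{"metaModel"} objects (one per response column),
#'   each with coefficients \code{b} (b0, b1, b2, b11, b22, b12), \code{r2}
#'   and a \code{predict} function.
#' @export
fitMetaModels <- function(design, responses) {
  responses <- as.matrix(responses)
  if (nrow(responses) != nrow(design))
    stop("one response row per design point is required")
  if (nrow(design) < 6)
    stop("at least six design points are needed for six coefficients")
  X <- cbind(1, design$x1, design$x2, design$x1^2, design$x2^2,
             design$x1 * design$x2)
  colnames(X) <- c("b0", "b1", "b2", "b11", "b22", "b12")
  qrX <- qr(X)
  if (qrX$rank < 6) stop("rank-deficient design: levels are collinear")
  out <- lapply(seq_len(ncol(responses)), function(j) {
    y <- responses[, j]
    b <- qr.coef(qrX, y)
    fittedv <- as.numeric(X %*% b)
    ss <- sum((y - mean(y))^2)
    structure(list(
      name = colnames(responses)[j] %||% paste0("response", j),
      b = b,
      r2 = if (ss > 0) 1 - sum((y - fittedv)^2) / ss else NA_real_),
      class = "metaModel")
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Evaluate a meta-model
#'
#' @param model a \code{"metaModel"}.
#' @param x1,x2 coded coordinates.
#' @return predicted response.
#' @export
predictMetaModel <- function(model, x1, x2) {
  b <- unname(model$b)
  b[1] + b[2] * x1 + b[3] * x2 + b[4] * x1^2 + b[5] * x2^2 + b[6] * x1 * x2
}

#' @export
print.metaModel <- function(x, ...) {
  cat(sprintf("metaModel '%s': f = %.4g %+.4g x1 %+.4g x2 %+.4g x1^2 %+.4g x2^2 %+.4g x1 x2 (R2 %s)\n",
              x$name, x$b[1], x$b[2], x$b[3], x$b[4], x$b[5], x$b[6],
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2))))
  invisible(x)
}

#' Optimization objective over the meta-model set
#'
#' Mean squared deviation between each meta-model prediction and its
#' experimental target, averaged over the \eqn{N_{mol} \times N_{prop}}
#' (molecule, property) pairs:
#' \deqn{F(x_1, x_2) = \frac{1}{N_{mol} N_{prop}} \sum_k
#'   \left(f_k(x_1, x_2) - y^{exp}_k\right)^2}
#' With \code{relative = TRUE} each deviation is divided by its target
#' before squaring (useful when properties with different units are mixed;
#' requires nonzero targets).  The objective is non-negative and zero
#' exactly when every surface matches its target at the point.
#'
#' @param metamodels list of \code{"metaModel"} objects.
#' @param targets numeric vector of experimental targets, one per model
#'   (matched by name when both are named).
#' @param x1,x2 coded coordinates.
#' @param relative use fractional deviations.
#' @return scalar objective value.
#' @export
ljObjective <- function(metamodels, targets, x1, x2, relative = FALSE) {
  if (length(metamodels) != length(targets))
    stop("one target per meta-model is required")
  if (!is.null(names(targets)) && !is.null(names(metamodels))) {
    if (!setequal(names(targets), names(metamodels)))
      stop("meta-model and target names do not match")
    targets <- targets[names(metamodels)]
  }
  dev <- vapply(seq_along(metamodels), function(k) {
    d <- predictMetaModel(metamodels[[k]], x1, x2) - targets[[k]]
    if (relative) {
      if (targets[[k]] == 0) stop("relative deviations need nonzero targets")
      d <- d / targets[[k]]
    }
    d
  }, 0)
  mean(dev^2)
}

#' Two-stage steepest-descent Lennard-Jones optimization
#'
#' Minimizes the meta-model objective by steepest descent with a variable
#' step length: the step grows on accepted moves and is halved on rejected
#' ones (backtracking).  Stage one runs for at most 4000 iterations from
#' the starting point; the lowest point found seeds a second, refining
#' stage of at most 100 iterations whose initial step is one tenth of the
#' final stage-one step.  The best point ever visited is returned, decoded
#' to physical units when a grid is supplied.
#'
#' @param metamodels list of \code{"metaModel"} objects.
#' @param targets numeric vector of experimental targets.
#' @param start coded starting point c(x1, x2).
#' @param grid optional \code{\link{buildDesignGrid}} for decoding.
#' @param relative passed to \code{\link{ljObjective}}.
#' @param step0 initial step length (coded units).
#' @param maxIter1,maxIter2 iteration caps of the two stages.
#' @param tol convergence threshold on the step length.
#' @return list with \code{x} (coded optimum), \code{sigma}/\code{epsilon}
#'   (when a grid is given), \code{objective}, \code{trace} (data.frame of
#'   accepted points) and \code{converged}.
#' @export
#' @examples
#' mm <- fitMetaModels(data.frame(x1 = rep(-1:1, 3), x2 = rep(-1:1, each = 3)),
#'   matrix((rep(-1:1, 3) - 0.3)^2 + (rep(-1:1, each = 3) + 0.2)^2))
#' optimizeLJ(mm, 0, start = c(0, 0))$x   # about (0.3, -0.2)
optimizeLJ <- function(metamodels, targets, start = c(0, 0), grid = NULL,
                       relative = FALSE, step0 = 0.1,
                       maxIter1 = 4000, maxIter2 = 100, tol = 1e-10) {
  f <- function(x) ljObjective(metamodels, targets, x[1], x[2],
                               relative = relative)
  grad <- function(x, h = 1e-7) {
    c((f(x + c(h, 0)) - f(x - c(h, 0))) / (2 * h),
      (f(x + c(0, h)) - f(x - c(0, h))) / (2 * h))
  }
  descend <- function(x, step, maxIter) {
    fx <- f(x)
    best <- list(x = x, f = fx)
    trace <- data.frame(iter = 0L, x1 = x[1], x2 = x[2], f = fx, step = step)
    for (it in seq_len(maxIter)) {
      g <- grad(x)
      gn <- sqrt(sum(g^2))
      if (gn < tol || step < tol) break
      cand <- x - step * g / gn
      fc <- f(cand)
      if (fc < fx) {
        x <- cand; fx <- fc
        step <- step * 1.2
        trace <- rbind(trace, data.frame(iter = it, x1 = x[1], x2 = x[2],
                                         f = fx, step = step))
        if (fx < best$f) best <- list(x = x, f = fx)
      } else {
        step <- step / 2
      }
      if (!is.finite(fx))
        stop("objective diverged; trace attached", call. = FALSE)
    }
    list(best = best, trace = trace, step = step)
  }
  s1 <- descend(start, step0, maxIter1)
  s2 <- descend(s1$best$x, max(s1$step / 10, tol), maxIter2)
  best <- if (s2$best$f < s1$best$f) s2$best else s1$best
  out <- list(x = best$x, objective = best$f,
              trace = rbind(cbind(stage = 1L, s1$trace),
                            cbind(stage = 2L, s2$trace)),
              converged = TRUE)
  if (!is.null(grid)) {
    dec <- decodeValues(grid, best$x[1], best$x[2])
    out$sigma <- dec$sigma
    out$epsilon <- dec$epsilon
  }
  out
}
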