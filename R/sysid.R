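#' Discrete transfer function in powers of z^-1
#'
#' `G(z) = (b0 + b1 z^-1 + ... + b4 z^-4) / (1 + a1 z^-1 + ... + a4 z^-4)`.
#' Both coefficient vectors have length 5 and the leading denominator
#' coefficient must be 1.
#'
#' @param num Numerator coefficients `b0..b4` (ascending powers of z^-1).
#' @param den Denominator coefficients `1, a1..a4`.
#' @param dt Sample time in seconds, or `NULL` when unspecified (frequency
#'   axes are then in rad/sample and time axes in samples).
#' @return An object of class `discrete_tf`.
#' @export
discrete_tf <- function(num, den, dt = NULL) {
  stopifnot(length(num) == 5, length(den) == 5,
            all(is.finite(num)), all(is.finite(den)))
  if (abs(den[1] - 1) > 1e-12) stop("den[1] must be 1 (monic in z^-1 form)")
  structure(list(num = as.numeric(num), den = as.numeric(den), dt = dt),
            class = "discrete_tf")
}

#' @export
print.discrete_tf <- function(x, ...) {
  term <- function(coefs) {
    paste(sprintf("%.5g z^-%d", coefs, seq_along(coefs) - 1), collapse = " + ")
  }
  cat("<discrete_tf>\n  num:", term(x$num), "\n  den:", term(x$den), "\n")
  if (!is.null(x$dt)) cat("  dt:", x$dt, "s\n")
  invisible(x)
}

#' Simulate a discrete transfer function
#'
#' Direct-form difference equation
#' `y[k] = sum(b_i u[k-i]) - sum(a_j y[k-j])` with zero initial conditions.
#'
#' @param tf A [discrete_tf()].
#' @param u Input sequence.
#' @return Output sequence of the same length.
#' @export
simulate_tf <- function(tf, u) {
  stopifnot(inherits(tf, "discrete_tf"))
  as.numeric(signal::filter(tf$num, tf$den, u))
}

#' Fit an ARX model by least squares
#'
#' Solves `y[k] = sum_{i=0}^{nb-1} b_i u[k-i] - sum_{j=1}^{na} a_j y[k-j]` in
#' the least-squares sense via the SVD (minimum-norm solution when the
#' regressor is rank deficient but the data are still exactly representable,
#' e.g. the identity system). A rank-deficient regressor that cannot
#' reproduce the output (e.g. a constant input) raises an error suggesting a
#' richer excitation.
#'
#' @param u Input sequence.
#' @param y Output sequence, same length as `u`, length >= `10*(na+nb)`.
#' @param na Autoregressive order (denominator), default 4.
#' @param nb Number of input coefficients including the direct term,
#'   default 5.
#' @param dt Optional sample time recorded on the result.
#' @return A [discrete_tf()] (for the default orders). For other orders, a
#'   list with `num`, `den`, `dt`.
#' @export
fit_arx <- function(u, y, na = 4, nb = 5, dt = NULL) {
  stopifnot(length(u) == length(y))
  n <- length(u)
  if (n < 10 * (na + nb)) {
    stop(sprintf("need at least %d samples for na=%d, nb=%d",
                 10 * (na + nb), na, nb))
  }
  k0 <- max(na, nb - 1) + 1
  rows <- k0:n
  reg <- matrix(0, length(rows), na + nb)
  for (i in 0:(nb - 1)) reg[, i + 1] <- u[rows - i]
  for (j in 1:na) reg[, nb + j] <- -y[rows - j]
  rhs <- y[rows]

  sv <- svd(reg)
  tol <- max(dim(reg)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  theta <- sv$v %*% (dinv * (t(sv$u) %*% rhs))
  if (rank < na + nb) {
    resid <- sqrt(sum((reg %*% theta - rhs)^2))
    if (resid > 1e-8 * max(1, sqrt(sum(rhs^2)))) {
      stop("ARX regressor is rank deficient and cannot explain the output; ",
           "use a persistently exciting input")
    }
  }
  num <- as.numeric(theta[1:nb])
  den <- c(1, as.numeric(theta[nb + 1:na]))
  if (na == 4 && nb == 5) discrete_tf(num, den, dt = dt)
  else list(num = num, den = den, dt = dt)
}

#' Write / read a discrete transfer function as JSON
#'
#' Format: `{"num": [...], "den": [...], "dt": null}`.
#'
#' @param tf A [discrete_tf()].
#' @param path File path.
#' @return `write_tf_json` returns `path` invisibly; `read_tf_json` returns a
#'   [discrete_tf()].
#' @export
write_tf_json <- function(tf, path) {
  jsonlite::write_json(list(num = tf$num, den = tf$den, dt = tf$dt),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_tf_json
#' @export
read_tf_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  discrete_tf(obj$num, obj$den, dt = obj$dt)
}

#' The workbench's reference transfer functions
#'
#' Fourth-order discrete closed-loop transfer functions identified for the
#' PID- and fuzzy-controlled flow loops, shipped as JSON fixtures
#' (`gpid.json`, `gfuzzy.json`) in the package's `extdata`.
#'
#' @param which `"pid"` or `"fuzzy"`.
#' @return A [discrete_tf()].
#' @export
reference_tf <- function(which = c("pid", "fuzzy")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "pid") "gpid.json" else "gfuzzy.json",
                   package = "ventbench", mustWork = TRUE)
  read_tf_json(f)
}
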