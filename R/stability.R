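#' Jury stability test for a discrete-time characteristic polynomial
#'
#' Classical Jury criterion for all roots of
#' `P(z) = c0 z^n + c1 z^(n-1) + ... + cn` lying strictly inside the unit
#' circle. The conditions are reported in the classical grouping: `P(1) > 0`,
#' `(-1)^n P(-1) > 0`, `|cn| < c0`, and the row constraints of the Jury array
#' (each derived row must have leading magnitude strictly larger than
#' constant-term magnitude). The polynomial is normalized so that the leading
#' coefficient is positive.
#'
#' @param den Characteristic polynomial coefficients in descending powers of
#'   `z` (equivalently, a [discrete_tf()] denominator in ascending powers of
#'   `z^-1`), or a `discrete_tf` whose denominator is used. `den[1]` must be
#'   non-zero.
#' @return An object of class `jury_report`: a list with `conditions` (named
#'   logical vector), `table` (list of Jury array rows, constant term first),
#'   and `stable`.
#' @examples
#' jury_test(c(1, -0.6273, 0.442, -0.3457, 0.1437))$stable
#' jury_test(c(1, -2))$stable # pole at 2
#' @export
jury_test <- function(den) {
  if (inherits(den, "discrete_tf")) den <- den$den
  stopifnot(is.numeric(den), length(den) >= 1, all(is.finite(den)))
  if (den[1] == 0) stop("leading coefficient must be non-zero")
  n <- length(den) - 1
  if (n == 0) {
    return(structure(list(conditions = c("degree >= 1" = TRUE),
                          table = list(), stable = TRUE),
                     class = "jury_report"))
  }
  if (den[1] < 0) den <- -den
  a <- rev(den) # ascending: a[1] = constant term, a[n+1] = leading

  conds <- c("P(1) > 0" = sum(den) > 0,
             "(-1)^n P(-1) > 0" =
               (-1)^n * sum(den * (-1)^(n:0)) > 0,
             "|a_n| < a_0" = abs(a[1]) < a[n + 1])

  rows <- list(a)
  cur <- a
  ok_rows <- TRUE
  # reduce the array down to a 3-element row; each derived row must dominate
  # at its first entry (|b_0| > |b_{m-1}|); degree <= 2 needs no array
  while (length(cur) > 3) {
    m <- length(cur)
    b <- cur[1] * cur[1:(m - 1)] - cur[m] * cur[m:2]
    rows[[length(rows) + 1]] <- b
    if (!(abs(b[1]) > abs(b[m - 1]))) ok_rows <- FALSE
    cur <- b
  }
  if (n >= 3) conds <- c(conds, "Jury array rows" = ok_rows)

  structure(list(conditions = conds, table = rows,
                 stable = all(conds)),
            class = "jury_report")
}

#' @export
print.jury_report <- function(x, ...) {
  cat("<jury_report>", if (x$stable) "STABLE" else "UNSTABLE", "\n")
  for (nm in names(x$conditions)) {
    cat(sprintf("  %-22s %s\n", nm, if (x$conditions[[nm]]) "pass" else "FAIL"))
  }
  invisible(x)
}

#' Poles of a discrete transfer function
#'
#' Roots of the denominator viewed as a degree-4 polynomial in `z`.
#'
#' @param tf A [discrete_tf()] (or a numeric denominator in descending powers
#'   of `z`).
#' @return Complex vector of roots.
#' @export
tf_poles <- function(tf) {
  den <- if (inherits(tf, "discrete_tf")) tf$den else tf
  # polyroot wants ascending powers of z
  polyroot(rev(den))
}

#' Frequency response on the unit circle
#'
#' Evaluates `G(e^(i*omega))` exactly from the coefficients.
#'
#' @param tf A [discrete_tf()].
#' @param omegas Frequencies, rad/sample.
#' @return Complex vector, one value per frequency.
#' @export
freq_response <- function(tf, omegas) {
  stopifnot(inherits(tf, "discrete_tf"))
  k <- seq_along(tf$num) - 1
  e <- exp(-1i * outer(omegas, k))
  as.complex((e %*% tf$num) / (e %*% tf$den))
}

# Bisection refinement of a scalar root of f on [lo, hi] (f(lo), f(hi) of
# opposite signs), to tolerance tol on the argument.
bisect_root <- function(f, lo, hi, tol = 1e-10) {
  flo <- f(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (hi - lo < tol) return(mid)
    fm <- f(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# Hybrid log+linear frequency grid on (1e-4, pi].
margin_grid <- function(n_log = 2e4, n_lin = 8e4) {
  g <- c(exp(seq(log(1e-4), log(pi), length.out = n_log)),
         seq(1e-4, pi, length.out = n_lin))
  sort(unique(pmin(g, pi)))
}

#' Gain and phase margins of a discrete loop transfer function
#'
#' The transfer function is treated as the loop transfer function of a unity
#' negative-feedback system. Phase crossovers are the frequencies in
#' `(0, pi]` where `G(e^(i*omega))` crosses the negative real axis (phase an
#' odd multiple of 180 degrees), located by a dense hybrid grid with
#' bisection refinement of `Im(G) = 0`; the endpoints `z = 1` and `z = -1`,
#' where the response is exactly real, are included as crossover candidates
#' when the response is negative there. The gain margin is the minimum of
#' `-20*log10(|G|)` over all phase crossovers (worst case); the phase margin
#' is the minimum of `180 + phase(G)` over all unity-gain crossovers. A
#' margin is `+Inf` when the corresponding crossover does not exist.
#'
#' @param tf A [discrete_tf()].
#' @return An object of class `margin_report`: `gain_margin_db`,
#'   `phase_margin_deg`, `gain_crossover_w` (rad/sample, where `|G| = 1`),
#'   `phase_crossover_w` (rad/sample, where the phase crosses -180 deg).
#' @examples
#' margins(reference_tf("pid"))$gain_margin_db # about 15.58 dB
#' @export
margins <- function(tf) {
  stopifnot(inherits(tf, "discrete_tf"))
  w <- margin_grid()
  G <- freq_response(tf, w)

  # --- phase crossovers: Im(G) = 0 with Re(G) < 0 ---
  pc_w <- numeric(0)
  im <- Im(G)
  s <- which(im[-1] * im[-length(im)] < 0)
  for (i in s) {
    wc <- bisect_root(function(x) Im(freq_response(tf, x)), w[i], w[i + 1])
    if (Re(freq_response(tf, wc)) < 0) pc_w <- c(pc_w, wc)
  }
  g1 <- sum(tf$num) / sum(tf$den)                          # G at z = 1
  gpi <- sum(tf$num * (-1)^(0:4)) / sum(tf$den * (-1)^(0:4)) # G at z = -1
  if (gpi < 0) pc_w <- c(pc_w, pi)
  if (g1 < 0) pc_w <- c(1e-12, pc_w)
  pc_w <- sort(unique(pc_w))

  gain_margin_db <- if (length(pc_w) == 0) Inf else {
    min(-20 * log10(Mod(freq_response(tf, pc_w))))
  }

  # --- gain crossovers: |G| = 1 ---
  gc_w <- numeric(0)
  m <- Mod(G) - 1
  s <- which(m[-1] * m[-length(m)] < 0)
  for (i in s) {
    gc_w <- c(gc_w, bisect_root(function(x) Mod(freq_response(tf, x)) - 1,
                                w[i], w[i + 1]))
  }
  if (abs(m[1]) < 1e-12) gc_w <- c(w[1], gc_w)
  phase_margin_deg <- if (length(gc_w) == 0) Inf else {
    ph <- Arg(freq_response(tf, gc_w)) * 180 / pi
    min(180 + ph)
  }

  structure(list(gain_margin_db = gain_margin_db,
                 phase_margin_deg = phase_margin_deg,
                 gain_crossover_w = gc_w,
                 phase_crossover_w = pc_w),
            class = "margin_report")
}

#' @export
print.margin_report <- function(x, ...) {
  fmt <- function(v, unit) if (is.infinite(v)) "infinite" else sprintf("%.2f %s", v, unit)
  cat("<margin_report>\n")
  cat("  gain margin: ", fmt(x$gain_margin_db, "dB"), "\n")
  cat("  phase margin:", fmt(x$phase_margin_deg, "deg"), "\n")
  invisible(x)
}

#' Nyquist curve of a discrete transfer function
#'
#' `G(e^(i*omega))` sampled over the full unit circle `omega` in `(-pi, pi]`
#' (conjugate-symmetric closure of the positive-frequency half).
#'
#' @param tf A [discrete_tf()].
#' @param n Number of positive-frequency samples.
#' @return Data frame with columns `omega`, `re`, `im`.
#' @export
nyquist_curve <- function(tf, n = 20000) {
  w_pos <- seq(1e-9, pi, length.out = n)
  g <- freq_response(tf, w_pos)
  data.frame(omega = c(-rev(w_pos), w_pos),
             re = c(rev(Re(g)), Re(g)),
             im = c(-rev(Im(g)), Im(g)))
}

#' Winding number of the Nyquist curve about (-1, 0)
#'
#' Sums the wrapped angle increments of `G(e^(i*omega)) + 1` as `omega`
#' traverses the full unit circle, refining the grid adaptively wherever an
#' increment exceeds 0.5 rad (which happens only near the critical point).
#' Errors when a pole lies on the unit circle, where the curve is unbounded
#' and the winding number indeterminate. A curve passing exactly through the
#' critical point also raises an error.
#'
#' @param tf A [discrete_tf()].
#' @param n Initial grid size over the full circle.
#' @return Integer winding number (positive = counter-clockwise).
#' @export
nyquist_encirclements <- function(tf, n = 65536) {
  p <- tf_poles(tf)
  if (any(abs(Mod(p) - 1) < 1e-9)) {
    stop("pole on the unit circle: winding number indeterminate")
  }
  w <- seq(-pi, pi, length.out = n)
  total <- 0
  ang <- Arg(freq_response(tf, w) + 1)
  wrap <- function(x) (x + pi) %% (2 * pi) - pi
  refine <- function(w1, w2, a1, a2, depth) {
    d <- wrap(a2 - a1)
    if (abs(d) < 0.5 || depth > 40) return(d)
    wm <- (w1 + w2) / 2
    gm <- freq_response(tf, wm) + 1
    if (Mod(gm) < 1e-12) stop("Nyquist curve passes through the critical point")
    am <- Arg(gm)
    refine(w1, wm, a1, am, depth + 1) + refine(wm, w2, am, a2, depth + 1)
  }
  for (i in seq_len(n - 1)) {
    total <- total + refine(w[i], w[i + 1], ang[i], ang[i + 1], 0)
  }
  as.integer(round(total / (2 * pi)))
}

#' Minimum distance of the Nyquist curve from the critical point
#'
#' Minimizes `|G(e^(i*omega)) - (-1)|` over a dense grid on `[0, pi]` with
#' local golden-section refinement around the best grid point (the curve is
#' conjugate symmetric, so the positive-frequency half suffices).
#'
#' @param tf A [discrete_tf()].
#' @param n Grid size.
#' @return Distance in the complex plane.
#' @examples
#' min_distance_to_critical(reference_tf("fuzzy")) >
#'   min_distance_to_critical(reference_tf("pid"))
#' @export
min_distance_to_critical <- function(tf, n = 20000) {
  w <- seq(0, pi, length.out = n)
  d <- Mod(freq_response(tf, w) + 1)
  i <- which.min(d)
  lo <- w[max(1, i - 1)]
  hi <- w[min(n, i + 1)]
  opt <- stats::optimize(function(x) Mod(freq_response(tf, x) + 1),
                         interval = c(lo, hi), tol = 1e-10)
  min(opt$objective, d[i])
}
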