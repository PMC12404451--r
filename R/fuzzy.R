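#' Triangular membership function
#'
#' @param a,b,c Left foot, apex and right foot abscissae; `a <= b <= c`,
#'   `a < c`.
#' @return An object of class `tri_mf`.
#' @export
tri_mf <- function(a, b, c) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c), a <= b, b <= c, a < c)
  structure(list(a = a, b = b, c = c), class = "tri_mf")
}

#' Evaluate a triangular membership function
#'
#' @param mf A [tri_mf()] object.
#' @param x Numeric vector of abscissae.
#' @return Membership degrees in `[0, 1]`, same length as `x`.
#' @export
mf_eval <- function(mf, x) {
  up <- if (mf$b > mf$a) (x - mf$a) / (mf$b - mf$a) else as.numeric(x >= mf$b)
  dn <- if (mf$c > mf$b) (mf$c - x) / (mf$c - mf$b) else as.numeric(x <= mf$b)
  pmax(0, pmin(1, up, dn))
}

#' Linguistic variable with five triangular terms
#'
#' Builds a five-term variable over `[lo, hi]` with apexes evenly spaced and
#' 50% overlap between neighbouring terms (each triangle's feet sit on the
#' adjacent apexes), so every point of the universe has positive total
#' membership.
#'
#' @param name Variable name.
#' @param lo,hi Universe bounds, `lo < hi`.
#' @param labels Character vector of 5 term labels, ordered low to high.
#' @return An object of class `fuzzy_variable`.
#' @export
fuzzy_variable <- function(name, lo, hi,
                           labels = c("LargeNegative", "SmallNegative", "Zero",
                                      "SmallPositive", "LargePositive")) {
  stopifnot(is.finite(lo), is.finite(hi), lo < hi, length(labels) == 5)
  apex <- seq(lo, hi, length.out = 5)
  h <- (hi - lo) / 4
  terms <- lapply(apex, function(b) tri_mf(b - h, b, b + h))
  names(terms) <- labels
  structure(list(name = name, universe = c(lo, hi), terms = terms),
            class = "fuzzy_variable")
}

#' Fuzzify a crisp input
#'
#' Values outside the universe are clamped to its bounds before evaluating the
#' five term memberships.
#'
#' @param x Crisp input value.
#' @param var A [fuzzy_variable()].
#' @return Named numeric vector of 5 membership degrees in `[0, 1]`.
#' @export
fuzzify <- function(x, var) {
  if (!inherits(var, "fuzzy_variable")) stop("var must be a fuzzy_variable")
  if (!is.finite(x)) stop("fuzzify input must be finite")
  x <- min(var$universe[2], max(var$universe[1], x))
  vapply(var$terms, mf_eval, numeric(1), x = x)
}

#' Default 5x5 fuzzy rule matrix
#'
#' Antisymmetric PD-type rule base mapping (error term, error-rate term) to a
#' valve-increment term. With error index `s` and rate index `r` centred at 0
#' (`-2..2`), the output index is `clip(s + trunc(r/2), -2, 2)`, except that
#' zero error always maps to `NoChange` regardless of the rate. The result is
#' antisymmetric (negating both inputs negates the output) and monotone
#' non-decreasing in the error for every fixed rate.
#'
#' @param output_labels Ordered labels of the output variable's 5 terms.
#' @return A 5x5 character matrix; rows = error terms (most negative first),
#'   columns = error-rate terms (most negative first).
#' @export
default_rule_base <- function(output_labels = c("CloseFast", "CloseSlow",
                                                "NoChange", "OpenSlow",
                                                "OpenFast")) {
  stopifnot(length(output_labels) == 5)
  m <- matrix("", 5, 5)
  for (i in 1:5) {
    for (j in 1:5) {
      o <- if (i == 3) 0 else {
        s <- i - 3
        r <- trunc((j - 3) / 2)
        min(2, max(-2, s + r))
      }
      m[i, j] <- output_labels[o + 3]
    }
  }
  m
}

#' Mamdani fuzzy controller configuration
#'
#' Fixes the inference operators of the controller: minimum for rule
#' activation (AND), clipping of output terms at their activation level,
#' maximum aggregation, and centroid defuzzification over a uniform
#' discretization of the output universe.
#'
#' @param error_var Fuzzy variable for the flow error (L/min).
#' @param derror_var Fuzzy variable for the error rate (L/min/s).
#' @param output_var Fuzzy variable for the valve-command increment.
#' @param rules 5x5 character matrix of output term labels (rows = error
#'   terms, columns = rate terms).
#' @param grid_points Number of discretization points of the output grid
#'   (>= 501; the default 1201 places every default apex exactly on a grid
#'   point).
#' @param step_time Reference control interval, s: the defuzzified increment
#'   is the command change applied per `step_time` of simulated time, so a
#'   loop running at `dt` applies `increment * dt / step_time` per step.
#' @return An object of class `flc_config`.
#' @export
flc_config <- function(error_var = fuzzy_variable("flow_error", -20, 20),
                       derror_var = fuzzy_variable(
                         "error_rate", -200, 200,
                         labels = c("RapidDecreasing", "Decreasing", "Constant",
                                    "Increasing", "RapidIncreasing")),
                       output_var = fuzzy_variable(
                         "command_increment", -0.1, 0.1,
                         labels = c("CloseFast", "CloseSlow", "NoChange",
                                    "OpenSlow", "OpenFast")),
                       rules = default_rule_base(names(output_var$terms)),
                       grid_points = 1201,
                       step_time = 0.005) {
  stopifnot(inherits(error_var, "fuzzy_variable"),
            inherits(derror_var, "fuzzy_variable"),
            inherits(output_var, "fuzzy_variable"),
            is.matrix(rules), all(dim(rules) == c(5, 5)),
            grid_points >= 501, step_time > 0)
  if (!all(rules %in% names(output_var$terms))) {
    stop("every rule consequent must be a term of the output variable")
  }
  # discretize over the full term supports (not just the universe) so the
  # outermost actions keep symmetric membership shapes; their centroid then
  # sits at the apex for every activation level, preserving monotonicity
  x <- seq(min(vapply(output_var$terms, function(m) m$a, numeric(1))),
           max(vapply(output_var$terms, function(m) m$c, numeric(1))),
           length.out = grid_points)
  mf_mat <- t(vapply(output_var$terms, mf_eval, numeric(length(x)), x = x))
  # integer consequent index per rule cell, for fast inference
  rule_idx <- matrix(match(rules, names(output_var$terms)), 5, 5)
  structure(list(error_var = error_var, derror_var = derror_var,
                 output_var = output_var, rules = rules,
                 and_op = "min", agg_op = "max", defuzz = "centroid",
                 grid = x, mf_mat = mf_mat, rule_idx = rule_idx,
                 step_time = step_time),
            class = "flc_config")
}

#' Mamdani inference
#'
#' Each rule's activation is `min(mu_e[i], mu_de[j])`; each output term is
#' clipped at the maximum activation over the rules firing it; the aggregate
#' is the pointwise maximum of the clipped terms over the output grid.
#'
#' @param mu_e,mu_de Length-5 membership vectors for error and error rate.
#' @param config An [flc_config()].
#' @return A list with `x` (output grid) and `mu` (aggregated membership).
#' @export
flc_infer <- function(mu_e, mu_de, config) {
  stopifnot(length(mu_e) == 5, length(mu_de) == 5)
  act <- outer(mu_e, mu_de, pmin)
  levels <- vapply(1:5, function(t) {
    sel <- config$rule_idx == t
    if (any(sel)) max(act[sel]) else 0
  }, numeric(1))
  mu <- rep(0, length(config$grid))
  for (t in which(levels > 0)) {
    mu <- pmax(mu, pmin(levels[t], config$mf_mat[t, ]))
  }
  list(x = config$grid, mu = mu)
}

#' Centroid defuzzification
#'
#' Centre of gravity of the aggregated membership function by the trapezoid
#' rule; returns 0 (no change) when the total area is zero.
#'
#' @param aggregate A list with `x` and `mu`, as returned by [flc_infer()].
#' @return Crisp output value within the output universe.
#' @export
defuzzify <- function(aggregate) {
  area <- pracma::trapz(aggregate$x, aggregate$mu)
  if (area <= 0) return(0)
  pracma::trapz(aggregate$x, aggregate$x * aggregate$mu) / area
}

#' One step of the fuzzy controller
#'
#' Incremental (velocity-form) actuation: the defuzzified valve increment,
#' scaled by `dt / step_time`, is added to the previous command and the result
#' clipped to `[0, 1]`.
#'
#' @param error Flow error, L/min.
#' @param derror Error rate, L/min/s.
#' @param config An [flc_config()].
#' @param prev_command Previous valve command in `[0, 1]`.
#' @param dt Sample time, s.
#' @return New valve command in `[0, 1]`.
#' @export
flc_step <- function(error, derror, config, prev_command, dt = config$step_time) {
  if (!is.finite(error) || !is.finite(derror)) {
    stop("fuzzy controller inputs must be finite")
  }
  stopifnot(prev_command >= 0, prev_command <= 1)
  mu_e <- fuzzify(error, config$error_var)
  mu_de <- fuzzify(derror, config$derror_var)
  du <- defuzzify(flc_infer(mu_e, mu_de, config))
  min(1, max(0, prev_command + du * dt / config$step_time))
}

#' Fuzzy controller for the closed-loop simulator
#'
#' Wraps [flc_step()] behind the [control_step()] interface; the error rate is
#' the backward difference of successive loop errors (zero on the first step).
#'
#' @param config An [flc_config()].
#' @param initial_command Starting valve command.
#' @return A controller object.
#' @export
flc_controller <- function(config = flc_config(), initial_command = 0) {
  structure(list(config = config, command = initial_command,
                 prev_error = NULL),
            class = c("flc_controller", "controller"))
}

#' @export
control_step.flc_controller <- function(controller, error, dt) {
  de <- if (is.null(controller$prev_error)) 0
        else (error - controller$prev_error) / dt
  cmd <- flc_step(error, de, controller$config, controller$command, dt)
  controller$command <- cmd
  controller$prev_error <- error
  list(command = cmd, controller = controller)
}

#' Write / read a fuzzy controller configuration as JSON
#'
#' Serializes the three variables (universe plus the 5 triangles each), the
#' 5x5 rule matrix as term labels, the fixed operator choices and the
#' reference control interval.
#'
#' @param config An [flc_config()].
#' @param path File path.
#' @return `write_flc_config` returns `path` invisibly; `read_flc_config`
#'   returns an [flc_config()].
#' @export
write_flc_config <- function(config, path) {
  ser_var <- function(v) {
    list(name = v$name, universe = v$universe,
         terms = lapply(v$terms, function(m) c(m$a, m$b, m$c)))
  }
  obj <- list(error_var = ser_var(config$error_var),
              derror_var = ser_var(config$derror_var),
              output_var = ser_var(config$output_var),
              rules = config$rules,
              and_op = config$and_op, agg_op = config$agg_op,
              defuzz = config$defuzz,
              grid_points = length(config$grid),
              step_time = config$step_time)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_flc_config
#' @export
read_flc_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  des_var <- function(o) {
    terms <- lapply(o$terms, function(x) tri_mf(x[1], x[2], x[3]))
    structure(list(name = o$name, universe = as.numeric(o$universe),
                   terms = terms),
              class = "fuzzy_variable")
  }
  rules <- obj$rules
  if (!is.matrix(rules)) rules <- matrix(unlist(rules), 5, 5, byrow = TRUE)
  flc_config(error_var = des_var(obj$error_var),
             derror_var = des_var(obj$derror_var),
             output_var = des_var(obj$output_var),
             rules = rules,
             grid_points = obj$grid_points,
             step_time = obj$step_time)
}
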