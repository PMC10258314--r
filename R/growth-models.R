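# Smallest volume (cc) at which model right-hand sides are evaluated.
# Volumes below this are clipped before log/power evaluation.
.VOLUME_FLOOR <- 1e-3

#' Tumor growth model registry
#'
#' Seven ordinary-differential-equation growth laws for cumulative tumor
#' volume \eqn{V} (cc) over time \eqn{t} (days). The exponential law
#' \eqn{dV/dt = \alpha V} has the single rate constant \eqn{\alpha}
#' (units 1/day); its fit between a pretreatment and a baseline scan is the
#' pretreatment tumor growth rate. The six alternative laws follow the forms
#' tabulated by Murphy, Jaafari and Dobrovolny (2016, BMC Cancer 16:163):
#' \describe{
#'   \item{exponential}{\eqn{dV/dt = a V}}
#'   \item{mendelsohn}{\eqn{dV/dt = a V^b}}
#'   \item{logistic}{\eqn{dV/dt = a V (1 - V/b)}}
#'   \item{linear}{\eqn{dV/dt = a V / (V + b)}}
#'   \item{surface}{\eqn{dV/dt = a V / (V + b)^{1/3}}}
#'   \item{gompertz}{\eqn{dV/dt = a V \log(b/V)}}
#'   \item{bertalanffy}{\eqn{dV/dt = a V^{2/3} - b V}}
#' }
#' All non-exponential laws have two parameters; \code{b} is a carrying
#' capacity (cc) for logistic and gompertz, a volume scale (cc) for linear
#' and surface, an exponent for mendelsohn, and a loss rate (1/day) for
#' bertalanffy.
#'
#' @param name model name; one of the strings listed above.
#' @return For \code{growth_models()}, the character vector of model names.
#'   For \code{growth_model_spec()}, a list of class \code{growth_model_spec}
#'   with elements \code{name}, \code{param_names}, \code{bounds(vmax)}
#'   (a function returning the per-parameter lower/upper matrix given the
#'   maximum observed volume), \code{init(obs)} (default starting values),
#'   \code{rhs(v, pars)} and, where one exists, \code{closed_form(t, v0, t0,
#'   pars)}.
#' @examples
#' growth_models()
#' growth_model_spec("gompertz")$param_names
#' @export
growth_models <- function() {
  c("exponential", "mendelsohn", "logistic", "linear", "surface",
    "gompertz", "bertalanffy")
}

#' @rdname growth_models
#' @export
growth_model_spec <- function(name) {
  name <- match.arg(name, growth_models())
  spec <- .model_registry[[name]]
  structure(c(list(name = name), spec), class = "growth_model_spec")
}

#' @export
print.growth_model_spec <- function(x, ...) {
  cat("Growth model:", x$name, "\n")
  cat("  dV/dt =", x$formula_text, "\n")
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  invisible(x)
}

# crude empirical growth rate over the observation span, used to seed the
# optimizer
.two_point_rate <- function(obs) {
  n <- nrow(obs)
  r <- log(obs$v[n] / obs$v[1]) / (obs$t[n] - obs$t[1])
  if (!is.finite(r) || r == 0) 0.01 else r
}

# capacity-style parameters get a data-dependent lower bound (> max observed
# volume) so that fitted curves stay monotone over the observation window
.model_registry <- list(
  exponential = list(
    formula_text = "a * V",
    param_names = "a",
    bounds = function(vmax) cbind(lower = -1, upper = 1),
    init = function(obs) c(a = .two_point_rate(obs)),
    rhs = function(v, pars) pars[["a"]] * v,
    closed_form = function(t, v0, t0, pars) v0 * exp(pars[["a"]] * (t - t0))
  ),
  mendelsohn = list(
    formula_text = "a * V^b",
    param_names = c("a", "b"),
    bounds = function(vmax) cbind(lower = c(-1, 0), upper = c(1, 3)),
    init = function(obs) c(a = .two_point_rate(obs), b = 1),
    rhs = function(v, pars) pars[["a"]] * v^pars[["b"]],
    closed_form = function(t, v0, t0, pars) {
      a <- pars[["a"]]; b <- pars[["b"]]
      if (abs(1 - b) < 1e-8) return(v0 * exp(a * (t - t0)))
      base <- v0^(1 - b) + a * (1 - b) * (t - t0)
      ifelse(base > 0, base^(1 / (1 - b)), NaN)
    }
  ),
  logistic = list(
    formula_text = "a * V * (1 - V/b)",
    param_names = c("a", "b"),
    bounds = function(vmax) cbind(lower = c(-1, vmax * (1 + 1e-9)),
                                  upper = c(1, 1e6)),
    init = function(obs) c(a = .two_point_rate(obs), b = 10 * max(obs$v)),
    rhs = function(v, pars) pars[["a"]] * v * (1 - v / pars[["b"]]),
    closed_form = function(t, v0, t0, pars) {
      a <- pars[["a"]]; b <- pars[["b"]]
      b / (1 + (b / v0 - 1) * exp(-a * (t - t0)))
    }
  ),
  linear = list(
    formula_text = "a * V / (V + b)",
    param_names = c("a", "b"),
    bounds = function(vmax) cbind(lower = c(-1e3, 1e-6),
                                  upper = c(1e3, 1e6)),
    init = function(obs) c(a = 2 * .two_point_rate(obs) * max(obs$v),
                           b = max(obs$v)),
    rhs = function(v, pars) pars[["a"]] * v / (v + pars[["b"]])
  ),
  surface = list(
    formula_text = "a * V / (V + b)^(1/3)",
    param_names = c("a", "b"),
    bounds = function(vmax) cbind(lower = c(-1e3, 1e-6),
                                  upper = c(1e3, 1e6)),
    init = function(obs) c(a = 2 * .two_point_rate(obs) * max(obs$v)^(1 / 3),
                           b = max(obs$v)),
    rhs = function(v, pars) pars[["a"]] * v / (v + pars[["b"]])^(1 / 3)
  ),
  gompertz = list(
    formula_text = "a * V * log(b/V)",
    param_names = c("a", "b"),
    bounds = function(vmax) cbind(lower = c(-1, vmax * (1 + 1e-9)),
                                  upper = c(1, 1e6)),
    init = function(obs) c(a = .two_point_rate(obs) / log(10),
                           b = 10 * max(obs$v)),
    rhs = function(v, pars) pars[["a"]] * v * log(pars[["b"]] / v),
    closed_form = function(t, v0, t0, pars) {
      a <- pars[["a"]]; b <- pars[["b"]]
      b * (v0 / b)^exp(-a * (t - t0))
    }
  ),
  bertalanffy = list(
    formula_text = "a * V^(2/3) - b * V",
    param_names = c("a", "b"),
    bounds = function(vmax) cbind(lower = c(-10, -1), upper = c(10, 1)),
    init = function(obs) c(a = 3 * .two_point_rate(obs) *
                             max(obs$v)^(1 / 3), b = 0.01),
    rhs = function(v, pars) pars[["a"]] * v^(2 / 3) - pars[["b"]] * v,
    closed_form = function(t, v0, t0, pars) {
      a <- pars[["a"]]; b <- pars[["b"]]
      if (abs(b) < 1e-12) {
        # dV/dt = a V^(2/3): V^(1/3) grows linearly
        w <- v0^(1 / 3) + a * (t - t0) / 3
        return(ifelse(w > 0, w^3, NaN))
      }
      w <- a / b + (v0^(1 / 3) - a / b) * exp(-b * (t - t0) / 3)
      ifelse(w > 0, w^3, NaN)
    }
  )
)

#' Solve a growth ODE forward in time
#'
#' Numerically integrates \eqn{dV/dt = f(V)} for a named growth model from
#' an initial volume over a time grid, using the \code{lsoda} solver of
#' \pkg{deSolve}. Volumes are clipped at a floor of \code{1e-3} cc inside
#' the right-hand side so that logarithms and fractional powers stay finite.
#'
#' @param model model name (see [growth_models()]) or a
#'   \code{growth_model_spec}.
#' @param params named numeric vector of model parameters.
#' @param v0 initial volume (cc) at \code{t_grid[1]}; must be positive.
#' @param t_grid increasing numeric vector of times (days).
#' @return numeric vector of volumes (cc), one per grid point, with
#'   \code{V(t_grid[1]) == v0}.
#' @examples
#' solve_growth_ode("exponential", c(a = 0.01), v0 = 1, t_grid = c(0, 100))
#' @export
solve_growth_ode <- function(model, params, v0, t_grid) {
  spec <- if (inherits(model, "growth_model_spec")) model
          else growth_model_spec(model)
  if (!is.numeric(v0) || length(v0) != 1L || !is.finite(v0) || v0 <= 0)
    stop("'v0' must be a single positive volume (cc)")
  if (length(t_grid) < 1L || is.unsorted(t_grid, strictly = TRUE))
    stop("'t_grid' must be strictly increasing")
  params <- .check_params(spec, params)
  if (v0 < .VOLUME_FLOOR) {
    warning("initial volume ", v0, " cc clipped to the evaluation floor ",
            .VOLUME_FLOOR, " cc")
    v0 <- .VOLUME_FLOOR
  }
  if (length(t_grid) == 1L) return(v0)
  rhs <- spec$rhs
  deriv <- function(t, y, p) {
    list(rhs(max(y[[1]], .VOLUME_FLOOR), p))
  }
  sol <- try(deSolve::ode(y = c(V = v0), times = t_grid, func = deriv,
                          parms = params, method = "lsoda",
                          rtol = 1e-10, atol = 1e-12), silent = TRUE)
  if (inherits(sol, "try-error") || any(!is.finite(sol[, "V"])))
    stop(sprintf("ODE integration failed for model '%s' (params: %s)",
                 spec$name, paste(sprintf("%s=%g", names(params), params),
                                  collapse = ", ")))
  unname(sol[, "V"])
}

.check_params <- function(spec, params) {
  pn <- spec$param_names
  if (is.null(names(params))) {
    if (length(params) != length(pn))
      stop(sprintf("model '%s' takes %d parameter(s): %s", spec$name,
                   length(pn), paste(pn, collapse = ", ")))
    names(params) <- pn
  }
  if (!all(pn %in% names(params)))
    stop(sprintf("model '%s' requires parameters: %s", spec$name,
                 paste(pn, collapse = ", ")))
  params[pn]
}

# trajectory anchored at the first observation; closed form when available
.predict_trajectory <- function(spec, params, v0, t0, times) {
  if (!is.null(spec$closed_form)) {
    v <- spec$closed_form(times, v0, t0, params)
    if (all(is.finite(v)) && all(v > 0)) return(v)
    # fall through to the numeric solver on a degenerate closed form
  }
  ord <- order(times)
  grid <- c(t0, times[ord])
  keep <- !duplicated(grid)
  sol <- solve_growth_ode(spec, params, v0, grid[keep])
  full <- sol[match(times[ord], grid[keep])]
  out <- numeric(length(times))
  out[ord] <- full
  out
}

#' Exponential growth rate from two volume measurements
#'
#' Closed-form fit of the exponential growth law \eqn{dV/dt = \alpha V}
#' between a pretreatment volume and a baseline volume separated by
#' \code{dt} days:
#' \deqn{\alpha = \log(V_{base} / V_{pre}) / \Delta t.}
#' This is the pretreatment tumor growth rate. A negative \eqn{\alpha}
#' (shrinking disease before treatment) is admissible.
#'
#' @param v_pre pretreatment cumulative volume (cc), > 0. For de novo
#'   metastatic patients this is the imputed minimal volume (0.1 cc by
#'   convention).
#' @param v_base baseline cumulative volume (cc), > 0.
#' @param dt elapsed days from the pretreatment scan to baseline, > 0.
#' @return an object of class \code{growth_fit}; its \code{alpha} component
#'   (equal to \code{coef(fit)[["a"]]}) has units 1/day.
#' @examples
#' fit <- fit_exponential_two_point(0.1, 28.4, 90)
#' coef(fit)  # about 0.0628 per day
#' @seealso [fit_growth_model()] for the general nonlinear least-squares fit.
#' @export
fit_exponential_two_point <- function(v_pre, v_base, dt) {
  for (nm in c("v_pre", "v_base", "dt")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stop(sprintf("'%s' must be a single positive number (got %s)",
                   nm, paste(val, collapse = ",")))
  }
  alpha <- log(v_base / v_pre) / dt
  obs <- data.frame(t = c(-dt, 0), v = c(v_pre, v_base))
  .new_growth_fit(model = "exponential", params = c(a = alpha), obs = obs,
                  rss = 0, converged = TRUE, underdetermined = FALSE,
                  method = "closed form")
}

.new_growth_fit <- function(model, params, obs, rss, converged,
                            underdetermined, method) {
  structure(list(model = model, params = params, alpha = unname(params[1]),
                 rss = rss, converged = converged,
                 underdetermined = underdetermined,
                 n_obs = nrow(obs), obs = obs, method = method),
            class = "growth_fit")
}

#' Fit a growth model to a sparse volume series
#'
#' Nonlinear least squares of the model trajectory against observed
#' cumulative volumes. The trajectory is anchored at the first observation
#' (\eqn{V(t_1) = v_1}) and the model parameters are chosen to minimize the
#' residual sum of squares over the remaining observations, by bounded
#' quasi-Newton optimization (multi-start L-BFGS-B). For the exponential
#' model with exactly two observations the closed form of
#' [fit_exponential_two_point()] is returned directly.
#'
#' Two-parameter models fitted to two observations are underdetermined (a
#' one-parameter family of curves interpolates both points); the fit still
#' proceeds but is flagged \code{underdetermined = TRUE}. Only the
#' exponential rate constant is identifiable from two points.
#'
#' @param model model name or \code{growth_model_spec}.
#' @param obs data frame with columns \code{t} (days, strictly increasing)
#'   and \code{v} (cc, positive); at least two rows.
#' @param init optional named numeric vector of starting parameter values.
#' @param log_scale if \code{TRUE}, least squares is computed on
#'   log-volumes instead of raw volumes (cc). Default \code{FALSE}.
#' @return an object of class \code{growth_fit} with components
#'   \code{model}, \code{params} (rate constant first), \code{rss},
#'   \code{converged}, \code{underdetermined} and \code{n_obs}.
#' @examples
#' obs <- data.frame(t = c(-90, 0), v = c(0.1, 28.4))
#' fit_growth_model("exponential", obs)
#' @export
fit_growth_model <- function(model, obs, init = NULL, log_scale = FALSE) {
  spec <- if (inherits(model, "growth_model_spec")) model
          else growth_model_spec(model)
  obs <- .check_observations(obs)
  if (nrow(obs) < 2L)
    stop("at least two volume observations are required to fit a growth model")

  if (spec$name == "exponential" && nrow(obs) == 2L && !log_scale) {
    fit <- fit_exponential_two_point(obs$v[1], obs$v[2], obs$t[2] - obs$t[1])
    fit$obs <- obs
    return(fit)
  }

  pn <- spec$param_names
  bounds <- spec$bounds(max(obs$v))
  start <- spec$init(obs)
  if (!is.null(init)) {
    init <- .check_params(spec, init)
    start[names(init)] <- init
  }
  start <- pmin(pmax(start, bounds[, "lower"]), bounds[, "upper"])

  v0 <- obs$v[1]; t0 <- obs$t[1]
  # log-scale targets use a tiny positivity guard only; clipping at the
  # volume floor would flatten the objective for shrinking tumors
  target <- if (log_scale) log(pmax(obs$v, 1e-300)) else obs$v
  resid_fn <- function(p) {
    names(p) <- pn
    pred <- try(suppressWarnings(
      .predict_trajectory(spec, p, v0, t0, obs$t)), silent = TRUE)
    if (inherits(pred, "try-error") || any(!is.finite(pred)) ||
        any(pred <= 0))
      return(rep(1e6, nrow(obs)))
    if (log_scale) pred <- log(pmax(pred, 1e-300))
    pred - target
  }

  # Levenberg-Marquardt with a multi-start over per-parameter scale
  # factors; the RSS valleys of the two-parameter laws are narrow and
  # nearly flat, which quasi-Newton line searches handle poorly
  facs <- if (length(pn) == 1L) list(1, 0.2, 5)
          else unlist(lapply(c(1, 0.2, 5), function(f1)
            lapply(c(1, 0.2, 5), function(f2) c(f1, f2))),
            recursive = FALSE)
  starts <- lapply(facs, function(f) {
    s <- start * f
    pmin(pmax(s, bounds[, "lower"]), bounds[, "upper"])
  })
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                     ptol = 1e-15)
  best <- NULL
  for (s in starts) {
    res <- try(suppressWarnings(
      minpack.lm::nls.lm(par = s, lower = bounds[, "lower"],
                         upper = bounds[, "upper"], fn = resid_fn,
                         control = ctrl)), silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) {
    params <- start; names(params) <- pn
    return(.new_growth_fit(spec$name, params, obs, rss = NA_real_,
                           converged = FALSE, underdetermined =
                             nrow(obs) <= length(pn),
                           method = "Levenberg-Marquardt"))
  }
  params <- best$par
  names(params) <- pn
  # info 1-3: ftol/ptol convergence; 4: gradient orthogonal to machine
  # precision (flat-valley optimum). 5 is the iteration cap.
  converged <- best$info %in% 1:4 && is.finite(best$deviance) &&
    best$deviance < 1e6
  .new_growth_fit(spec$name, params, obs, rss = best$deviance,
                  converged = converged,
                  underdetermined = nrow(obs) <= length(pn),
                  method = if (log_scale) "Levenberg-Marquardt (log scale)"
                           else "Levenberg-Marquardt")
}

.check_observations <- function(obs) {
  if (!is.data.frame(obs) || !all(c("t", "v") %in% names(obs)))
    stop("'obs' must be a data frame with columns 't' (days) and 'v' (cc)")
  if (nrow(obs) < 1L) stop("'obs' must be nonempty")
  if (any(!is.finite(obs$t)) || any(!is.finite(obs$v)))
    stop("'obs' contains non-finite values")
  if (any(obs$v <= 0)) stop("volumes in 'obs' must be positive (cc)")
  if (is.unsorted(obs$t, strictly = TRUE))
    stop("observation times in 'obs' must be strictly increasing")
  obs[c("t", "v")]
}

#' @export
print.growth_fit <- function(x, digits = 6, ...) {
  cat("Growth model fit:", x$model, "\n")
  cat("  parameters: ",
      paste(sprintf("%s = %.*g", names(x$params), digits, x$params),
            collapse = ", "), "\n", sep = "")
  if (x$model == "exponential")
    cat(sprintf("  growth rate alpha = %.*g /day (doubling time %.3g days)\n",
                digits, x$alpha,
                if (x$alpha > 0) log(2) / x$alpha else Inf))
  cat(sprintf("  n_obs = %d, RSS = %.4g, converged = %s%s\n", x$n_obs,
              x$rss, x$converged,
              if (isTRUE(x$underdetermined)) ", UNDERDETERMINED" else ""))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$params

#' @export
summary.growth_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object, residuals = res,
                 sigma = if (length(res) > length(object$params))
                   sqrt(sum(res^2) / (length(res) - length(object$params)))
                 else NA_real_),
            class = "summary.growth_fit")
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  print(x$fit)
  cat("  residuals (cc):\n")
  print(stats::quantile(x$residuals))
  invisible(x)
}

#' Predicted volumes from a fitted growth model
#'
#' @param object a \code{growth_fit}.
#' @param times numeric vector of days (same origin as the fitted data);
#'   defaults to the observation times.
#' @param ... unused.
#' @return numeric vector of predicted volumes (cc).
#' @export
predict.growth_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$obs$t
  spec <- growth_model_spec(object$model)
  .predict_trajectory(spec, object$params, object$obs$v[1], object$obs$t[1],
                      times)
}

#' @export
residuals.growth_fit <- function(object, ...) {
  object$obs$v - predict(object)
}

#' @export
plot.growth_fit <- function(x, n_grid = 200, ...) {
  tr <- range(x$obs$t)
  tg <- seq(tr[1], tr[2], length.out = n_grid)
  vg <- predict(x, tg)
  graphics::plot(x$obs$t, x$obs$v, xlab = "days from baseline",
                 ylab = "cumulative volume (cc)",
                 main = sprintf("%s growth fit", x$model), ...)
  graphics::lines(tg, vg, col = "firebrick")
  invisible(x)
}

#' Flatten growth fits to a table
#'
#' @param fits a list of \code{growth_fit} objects, optionally named by
#'   patient id.
#' @return a data frame with one row per fit: \code{patient_id},
#'   \code{model}, one column per parameter, \code{alpha}, \code{rss},
#'   \code{converged}, \code{underdetermined}.
#' @export
growth_fit_table <- function(fits) {
  stopifnot(is.list(fits), length(fits) > 0)
  ids <- names(fits)
  if (is.null(ids)) ids <- as.character(seq_along(fits))
  all_params <- unique(unlist(lapply(fits, function(f) names(f$params))))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    p <- stats::setNames(rep(NA_real_, length(all_params)), all_params)
    p[names(f$params)] <- f$params
    cbind(data.frame(patient_id = ids[i], model = f$model,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(p)),
          data.frame(alpha = f$alpha, rss = f$rss, converged = f$converged,
                     underdetermined = f$underdetermined,
                     n_obs = f$n_obs))
  })
  do.call(rbind, rows)
}
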