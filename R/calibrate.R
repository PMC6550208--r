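#' Fit a power-law volume model to one sensor
#'
#' Fits `V = a * dR^b` by ordinary least squares on log-log coordinates (a
#' convex, initialization-free surrogate for nonlinear least squares). R^2 is
#' reported both on the original volume scale (from the back-transformed
#' predictions) and on the log scale of the fit; the standard error of
#' estimate (SEE) is the residual SD of volume on the original scale.
#'
#' @param delta_r Per-breath resistance excursions, ohm (all > 0).
#' @param volume Per-breath exhaled (or inhaled) volumes, L (all > 0).
#' @return An object of class `power_model` with elements `a`, `b`, `r2`
#'   (original scale), `r2_log`, `see`, `n`.
#' @examples
#' dr <- seq(0.2, 2, length.out = 10)
#' fit_power(dr, 2 * dr^1.5)
#' @export
fit_power <- function(delta_r, volume) {
  delta_r <- as.numeric(delta_r); volume <- as.numeric(volume)
  if (length(delta_r) != length(volume)) stop("length mismatch")
  if (length(delta_r) < 5) stop("need at least 5 breaths to fit a power model")
  if (any(delta_r <= 0) || any(volume <= 0))
    stop("power fit requires positive resistance excursions and volumes")
  if (stats::sd(delta_r) == 0)
    stop("degenerate input: resistance excursions are constant")
  fit <- stats::lm(log(volume) ~ log(delta_r))
  b <- unname(stats::coef(fit)[2])
  a <- unname(exp(stats::coef(fit)[1]))
  pred <- a * delta_r^b
  res <- volume - pred
  ss_tot <- sum((volume - mean(volume))^2)
  lv <- log(volume)
  r2_log <- 1 - sum(stats::residuals(fit)^2) / sum((lv - mean(lv))^2)
  n <- length(volume)
  out <- list(a = a, b = b,
              r2 = 1 - sum(res^2) / ss_tot,
              r2_log = r2_log,
              see = sqrt(sum(res^2) / max(n - 2, 1)),
              n = n)
  class(out) <- "power_model"
  out
}

#' @export
print.power_model <- function(x, ...) {
  cat(sprintf("<power_model> V = %.4g * dR^%.4g  (n = %d, R2 = %.3f, SEE = %.3f L)\n",
              x$a, x$b, x$n, x$r2, x$see))
  invisible(x)
}

#' Linearize a resistance excursion through a power model
#'
#' Returns the power-model-predicted volume contribution `a * dR^b` (or
#' `dR^b` when `transform = "exponent"`); 0 maps to 0.
#'
#' @param delta_r Resistance excursion(s), ohm (>= 0).
#' @param model A `power_model`.
#' @param transform `"volume"` for `a * dR^b` (default, so downstream
#'   regression weights are near-unity mixing fractions) or `"exponent"` for
#'   the bare `dR^b`.
#' @return Numeric vector in L (or ohm^b).
#' @export
linearize <- function(delta_r, model, transform = c("volume", "exponent")) {
  transform <- match.arg(transform)
  stopifnot(inherits(model, "power_model"))
  if (any(delta_r < 0)) stop("delta_r must be >= 0")
  s <- if (transform == "volume") model$a else 1
  s * delta_r^model$b
}

#' Two-compartment calibration of breath volume from strain sensors
#'
#' Fits the per-subject calibration used to compute respiration volume from
#' skin strain: breathing has two dominant degrees of freedom — ribcage and
#' abdomen displacement — whose linear combination tracks lung volume change
#' (the Kono-Mead model). Each sensor's per-breath resistance excursion is
#' first linearized through its own power-law fit ([fit_power()]); ordinary
#' least squares then finds the best-fit plane between the transformed
#' excursions and the measured exhaled volume.
#'
#' @param formula Model formula, `volume ~ rib_dR` or
#'   `volume ~ rib_dR + abd_dR`, naming columns of `data`. The first
#'   right-hand term is treated as the ribcage sensor. A one-term formula
#'   fits the single-compartment special case.
#' @param data Data frame of per-breath values, e.g. a `breath_table` with
#'   `dr_rib_ohm` / `dr_abd_ohm` columns and `exhaled_l`.
#' @param transform Passed to [linearize()].
#' @param intercept Include an intercept in the regression plane (default
#'   TRUE).
#' @param direction Label recorded in the model: `"exhale"` or `"inhale"`
#'   (separate models are fitted per direction).
#' @return An object of class `kono_mead`: power models per sensor, the
#'   regression coefficients (`beta0`, `beta_rib`, `beta_abd`), adjusted R^2,
#'   SEE (L), the underlying `lm` fit, and the training data. Supports
#'   `print()`, `summary()`, `coef()`, `predict()`, `fitted()`,
#'   `residuals()`, and `plot()`.
#' @examples
#' cfg <- generator_config(seed = 11)
#' rec <- generate_recording(cfg)
#' prep <- preprocess_recording(rec$recording)
#' br <- add_delta_r(segment_breaths(prep$flow), prep$rib, prep$abd)
#' fit <- kono_mead(exhaled_l ~ dr_rib_ohm + dr_abd_ohm, br)
#' summary(fit)
#' @export
kono_mead <- function(formula, data, transform = c("volume", "exponent"),
                      intercept = TRUE, direction = "exhale") {
  transform <- match.arg(transform)
  tm <- stats::terms(formula, data = data)
  vars <- all.vars(formula)
  resp <- vars[1]
  preds <- attr(tm, "term.labels")
  if (!length(preds) || length(preds) > 2)
    stop("formula must have one or two sensor terms")
  volume <- data[[resp]]
  dr_rib <- data[[preds[1]]]
  dr_abd <- if (length(preds) == 2) data[[preds[2]]] else NULL
  rib_power <- fit_power(dr_rib, volume)
  abd_power <- if (!is.null(dr_abd)) fit_power(dr_abd, volume) else NULL
  fit_mlr(lin_rib = linearize(dr_rib, rib_power, transform),
          lin_abd = if (is.null(dr_abd)) NULL
                    else linearize(dr_abd, abd_power, transform),
          volume = volume,
          rib_power = rib_power, abd_power = abd_power,
          transform = transform, intercept = intercept,
          direction = direction,
          var_names = c(resp, preds))
}

#' Best-fit plane between linearized sensor excursions and volume
#'
#' The regression stage of [kono_mead()], exposed for use with
#' pre-linearized values: ordinary least squares of volume on one or two
#' linearized sensor channels, with adjusted R^2 and standard error of
#' estimate. Errors on a rank-deficient (collinear) design.
#'
#' @param lin_rib,lin_abd Linearized per-breath values, L (`lin_abd` may be
#'   NULL for the single-compartment case).
#' @param volume Measured per-breath volumes, L.
#' @param rib_power,abd_power The `power_model`s used for linearization
#'   (stored for prediction).
#' @param transform,intercept,direction As in [kono_mead()].
#' @param var_names Internal: response/predictor names for `predict()`.
#' @return A `kono_mead` object.
#' @export
fit_mlr <- function(lin_rib, lin_abd, volume, rib_power = NULL,
                    abd_power = NULL, transform = "volume",
                    intercept = TRUE, direction = "exhale",
                    var_names = c("volume", "dr_rib_ohm", "dr_abd_ohm")) {
  n <- length(volume)
  if (n < 6) stop("need at least 6 breaths to fit the regression plane")
  two <- !is.null(lin_abd)
  if (two && all(lin_abd == 0)) two <- FALSE  # single-compartment special case
  df <- data.frame(volume = volume, lin_rib = lin_rib)
  if (two) df$lin_abd <- lin_abd
  rhs <- if (two) "lin_rib + lin_abd" else "lin_rib"
  fml <- stats::as.formula(paste("volume ~", rhs,
                                 if (!intercept) "- 1" else ""))
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design: collinear predictor(s) ",
         paste(bad, collapse = ", "))
  }
  cf <- stats::coef(fit)
  p <- length(cf)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- if (intercept) sum((volume - mean(volume))^2) else sum(volume^2)
  r2 <- 1 - ss_res / ss_tot
  df_int <- if (intercept) 1L else 0L
  adj_r2 <- 1 - (1 - r2) * (n - df_int) / (n - p)
  out <- list(beta0 = if (intercept) unname(cf["(Intercept)"]) else 0,
              beta_rib = unname(cf["lin_rib"]),
              beta_abd = if (two) unname(cf["lin_abd"]) else 0,
              adj_r2 = adj_r2,
              r2 = r2,
              see = sqrt(sum(stats::residuals(fit)^2) / max(n - p, 1)),
              n = n,
              rib_power = rib_power, abd_power = abd_power,
              transform = transform, intercept = intercept,
              direction = direction, var_names = var_names,
              lm_fit = fit, data = df)
  class(out) <- "kono_mead"
  out
}

#' @export
print.kono_mead <- function(x, ...) {
  cat(sprintf("<kono_mead> %s-volume calibration, n = %d breaths\n",
              x$direction, x$n))
  cat(sprintf("  V = %.4g + %.4g * lin(rib) + %.4g * lin(abd)\n",
              x$beta0, x$beta_rib, x$beta_abd))
  cat(sprintf("  adjusted R2 = %.3f, SEE = %.3f L\n", x$adj_r2, x$see))
  invisible(x)
}

#' @export
summary.kono_mead <- function(object, ...) {
  structure(list(model = object), class = "summary.kono_mead")
}

#' @export
print.summary.kono_mead <- function(x, ...) {
  m <- x$model
  print(m)
  if (!is.null(m$rib_power)) {
    cat("  ribcage  "); print(m$rib_power)
  }
  if (!is.null(m$abd_power)) {
    cat("  abdomen  "); print(m$abd_power)
  }
  cat("  regression detail:\n")
  print(stats::coef(summary(m$lm_fit)))
  invisible(x)
}

#' @export
coef.kono_mead <- function(object, ...) {
  c(beta0 = object$beta0, beta_rib = object$beta_rib,
    beta_abd = object$beta_abd)
}

#' @export
fitted.kono_mead <- function(object, ...) stats::fitted(object$lm_fit)

#' @export
residuals.kono_mead <- function(object, ...) stats::residuals(object$lm_fit)

#' Predict breath volume from resistance excursions
#'
#' `beta0 + beta_rib * lin(dR_rib) + beta_abd * lin(dR_abd)`, floored at 0 L.
#'
#' @param object A `kono_mead` model.
#' @param newdata Data frame containing the predictor columns the model was
#'   fitted with (e.g. `dr_rib_ohm`, `dr_abd_ohm`), or with the generic names
#'   `dr_rib` / `dr_abd`.
#' @param ... Unused.
#' @return Numeric vector of predicted volumes, L.
#' @export
predict.kono_mead <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(pmax(stats::fitted(object$lm_fit), 0))
  pick <- function(nm, alt) {
    if (nm %in% names(newdata)) newdata[[nm]]
    else if (alt %in% names(newdata)) newdata[[alt]]
    else stop("newdata lacks column ", nm)
  }
  dr_rib <- pick(object$var_names[2], "dr_rib")
  pred <- object$beta0 +
    object$beta_rib * linearize(dr_rib, object$rib_power, object$transform)
  if (!is.null(object$abd_power)) {
    dr_abd <- pick(object$var_names[3], "dr_abd")
    pred <- pred +
      object$beta_abd * linearize(dr_abd, object$abd_power, object$transform)
  }
  pmax(pred, 0)
}

#' @export
plot.kono_mead <- function(x, ...) {
  meas <- x$data$volume
  pred <- pmax(stats::fitted(x$lm_fit), 0)
  graphics::plot(meas, pred, xlab = "measured volume (L)",
                 ylab = "calculated volume (L)",
                 main = sprintf("%s calibration (adj R2 = %.3f)",
                                x$direction, x$adj_r2), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Serialize a calibration model to JSON
#'
#' @param model A `kono_mead` model.
#' @param path File path; the JSON mirrors the model structure
#'   (`rib_power`, `abd_power`, `mlr`, `direction`, `transform`).
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "kono_mead"))
  pw <- function(p) if (is.null(p)) NULL else
    list(a = p$a, b = p$b, r2 = p$r2, r2_log = p$r2_log, see = p$see, n = p$n)
  obj <- list(rib_power = pw(model$rib_power),
              abd_power = pw(model$abd_power),
              mlr = list(beta0 = model$beta0, beta_rib = model$beta_rib,
                         beta_abd = model$beta_abd, adj_r2 = model$adj_r2,
                         see = model$see, n = model$n),
              transform = model$transform,
              direction = model$direction,
              var_names = model$var_names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a calibration model from JSON
#'
#' Restores a `kono_mead` object written by [write_calibration()] (without
#' the underlying `lm` fit or training data; prediction works as usual).
#'
#' @param path File path.
#' @return A `kono_mead` object.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pw <- function(p) if (is.null(p)) NULL else structure(p, class = "power_model")
  out <- list(beta0 = obj$mlr$beta0, beta_rib = obj$mlr$beta_rib,
              beta_abd = obj$mlr$beta_abd, adj_r2 = obj$mlr$adj_r2,
              see = obj$mlr$see, n = obj$mlr$n,
              rib_power = pw(obj$rib_power), abd_power = pw(obj$abd_power),
              transform = obj$transform, direction = obj$direction,
              var_names = obj$var_names, lm_fit = NULL, data = NULL)
  class(out) <- "kono_mead"
  out
}
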