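#' Logistic tumour control probability parameters
#'
#' The dose-response for tumour control is the two-parameter logistic
#' `TCP(D) = exp(p + qD) / (1 + exp(p + qD))`, parameterised clinically by
#' `D50` (dose giving 50% control) and `gamma50` (normalised slope at the
#' 50% point). For this logistic the slope at `D50` is `q/4` and
#' `gamma50 = D50 * q / 4`, which fixes `q = 4 * gamma50 / D50` and
#' `p = -q * D50 = -4 * gamma50`, so that `TCP(D50) = 0.5` exactly.
#'
#' The shipped defaults, D50 = 67.5 Gy and gamma50 = 2.0, are a
#' conventional prostate adenocarcinoma dose-response set drawn from pooled
#' clinical dose-control summaries; they are configuration, not constants,
#' and should be overridden when institution-specific fits are available.
#'
#' @param d50 Dose in Gy giving 50% tumour control (> 0).
#' @param gamma50 Normalised dose-response slope at `D50` (> 0).
#' @return An object of class `tcp_params` with fields `d50`, `gamma50`,
#'   `p` (dimensionless) and `q` (1/Gy).
#' @examples
#' pars <- tcp_params(67.5, 2)
#' tcp_uniform(78, pars)
#' @export
tcp_params <- function(d50 = 67.5, gamma50 = 2.0) {
  stopifnot_scalar_number(d50, "d50")
  stopifnot_scalar_number(gamma50, "gamma50")
  if (d50 <= 0 || gamma50 <= 0) {
    abort_validation("`d50` and `gamma50` must be positive.")
  }
  structure(
    list(d50 = d50, gamma50 = gamma50, p = -4 * gamma50, q = 4 * gamma50 / d50),
    class = "tcp_params"
  )
}

#' @export
print.tcp_params <- function(x, ...) {
  cat(sprintf("<tcp_params> D50 = %g Gy, gamma50 = %g (p = %g, q = %g /Gy)\n",
              x$d50, x$gamma50, x$p, x$q))
  invisible(x)
}

#' Tumour control probability
#'
#' `tcp_uniform()` evaluates the logistic dose-response at a uniform dose.
#' `tcp()` applies it to a heterogeneous dose distribution through the
#' tumorlet product: each differential-DVH bin `(v_i, D_i)` is treated as
#' an independently controlled sub-volume with `TCP(v_i, D_i) =
#' TCP(D_i)^{v_i}`, and the whole-volume TCP is the product over bins.
#' Since the fractions sum to one, a uniform distribution recovers
#' `tcp_uniform()` exactly, and refining a bin into sub-bins at the same
#' dose leaves the product unchanged. Accumulation is done in log space
#' (`plogis(log.p = TRUE)`) so very low per-bin control probabilities do
#' not underflow.
#'
#' @param dose Uniform dose in Gy (vectorised).
#' @param x A DVH object; a cumulative DVH is converted to differential
#'   form first.
#' @param params A [tcp_params()] object.
#' @return Probability in (0, 1) (exactly 0 only if some irradiated bin has
#'   zero control probability, which the logistic never produces at finite
#'   dose).
#' @examples
#' d <- differential_dvh(c(70, 80), c(0.5, 0.5))
#' tcp(d)
#' sqrt(tcp_uniform(70) * tcp_uniform(80))  # identical by construction
#' @export
tcp_uniform <- function(dose, params = tcp_params()) {
  stopifnot(inherits(params, "tcp_params"))
  if (any(dose < 0)) abort_validation("Dose must be non-negative.")
  stats::plogis(params$p + params$q * dose)
}

#' @rdname tcp_uniform
#' @export
tcp <- function(x, params = tcp_params()) {
  stopifnot(inherits(x, "dvh"), inherits(params, "tcp_params"))
  d <- as_differential(x)
  keep <- d$volume > 0
  log_tcp <- stats::plogis(params$p + params$q * d$dose[keep], log.p = TRUE)
  if (any(is.infinite(log_tcp))) {
    warning("A bin with nonzero volume has zero control probability; TCP = 0.")
    return(0)
  }
  exp(sum(d$volume[keep] * log_tcp))
}

#' Lyman-Kutcher-Burman NTCP parameters
#'
#' The Lyman model expresses the complication probability after uniform
#' irradiation of a partial volume `v` as `NTCP = Phi(t)` with
#' `t = (D - TD50(v)) / (m * TD50(v))` and the tolerance-dose volume
#' dependence `TD50(v) = TD50(1) * v^(-n)`. `TD50(1)` is the uniform
#' whole-organ dose giving 50% complications, `m` sets the probit slope
#' and `n` the strength of the volume effect. The defaults are the
#' conventional late rectal toxicity set: TD50(1) = 80 Gy, m = 0.15,
#' n = 0.12.
#'
#' @param td50_1 Whole-volume tolerance dose TD50(1) in Gy (> 0).
#' @param m Probit slope parameter (> 0).
#' @param n Volume-effect exponent (> 0).
#' @return An object of class `lkb_params`.
#' @export
lkb_params <- function(td50_1 = 80, m = 0.15, n = 0.12) {
  for (nm in c("td50_1", "m", "n")) stopifnot_scalar_number(get(nm), nm)
  if (td50_1 <= 0 || m <= 0 || n <= 0) {
    abort_validation("All LKB parameters must be positive.")
  }
  structure(list(td50_1 = td50_1, m = m, n = n), class = "lkb_params")
}

#' @export
print.lkb_params <- function(x, ...) {
  cat(sprintf("<lkb_params> TD50(1) = %g Gy, m = %g, n = %g\n", x$td50_1, x$m, x$n))
  invisible(x)
}

#' Kutcher-Burman effective volume
#'
#' Reduces a heterogeneous differential DVH to an equivalent fraction of
#' the organ uniformly irradiated at a reference dose:
#' `veff = sum_i v_i * (D_i / D_ref)^(1/n)`, with `D_ref` defaulting to the
#' maximum dose bin carrying volume. Zero-dose bins contribute nothing, so
#' `veff` lies in (0, 1] whenever some volume is irradiated, and it is
#' invariant under a common scaling of all doses.
#'
#' @param x A DVH object (converted to differential form if cumulative).
#' @param n Volume-effect exponent (> 0).
#' @param d_ref Reference dose in Gy; `NULL` (default) uses the maximum
#'   dose with nonzero volume.
#' @return A list with `veff` and `d_ref`.
#' @examples
#' d <- differential_dvh(c(35, 70), c(0.5, 0.5))
#' effective_volume(d, n = 0.12)  # veff = 0.5 + 0.5 * 0.5^(1/0.12)
#' @export
effective_volume <- function(x, n, d_ref = NULL) {
  stopifnot(inherits(x, "dvh"))
  stopifnot_scalar_number(n, "n")
  if (n <= 0) abort_validation("`n` must be positive.")
  d <- as_differential(x)
  keep <- d$volume > 0 & d$dose > 0
  if (!any(keep)) {
    return(list(veff = NA_real_, d_ref = NA_real_, degenerate = TRUE))
  }
  if (is.null(d_ref)) d_ref <- max(d$dose[keep])
  stopifnot_scalar_number(d_ref, "d_ref")
  veff <- sum(d$volume[keep] * (d$dose[keep] / d_ref)^(1 / n))
  list(veff = veff, d_ref = d_ref, degenerate = FALSE)
}

#' Lyman-Kutcher-Burman NTCP from a DVH
#'
#' `ntcp()` reduces the DVH to its Kutcher-Burman effective volume at the
#' maximum dose, evaluates the volume-corrected tolerance dose
#' `TD50(veff) = TD50(1) * veff^(-n)`, forms the probit argument
#' `t = (D_ref - TD50(veff)) / (m * TD50(veff))` and returns
#' `NTCP = Phi(t)` together with all intermediates for auditability.
#' A DVH with no irradiated volume yields NTCP 0 with `degenerate = TRUE`.
#'
#' `lyman_ntcp_uniform()` is the closed-form special case of uniform dose
#' `dose` to a fraction `v` of the organ, kept as a separate code path: for
#' a two-bin DVH (dose to `v`, zero elsewhere) the reduction gives
#' `veff = v` exactly, so both routes must agree to machine precision.
#'
#' @param x A DVH object.
#' @param params An [lkb_params()] object.
#' @return `ntcp()`: an object of class `lkb_ntcp` with fields `ntcp`,
#'   `veff`, `d_ref`, `td50_v`, `t`, `degenerate` and the parameters;
#'   use [generics::tidy()] to get it as a one-row tibble.
#' @examples
#' whole <- differential_dvh(80, 1)
#' ntcp(whole)$ntcp  # 0.5: whole organ at TD50(1)
#' @export
ntcp <- function(x, params = lkb_params()) {
  stopifnot(inherits(x, "dvh"), inherits(params, "lkb_params"))
  red <- effective_volume(x, params$n)
  if (isTRUE(red$degenerate)) {
    out <- list(ntcp = 0, veff = NA_real_, d_ref = NA_real_, td50_v = NA_real_,
                t = -Inf, degenerate = TRUE, params = params,
                structure = attr(x, "structure"))
    return(structure(out, class = "lkb_ntcp"))
  }
  td50_v <- params$td50_1 * red$veff^(-params$n)
  t <- (red$d_ref - td50_v) / (params$m * td50_v)
  out <- list(ntcp = normal_cdf(t), veff = red$veff, d_ref = red$d_ref,
              td50_v = td50_v, t = t, degenerate = FALSE, params = params,
              structure = attr(x, "structure"))
  structure(out, class = "lkb_ntcp")
}

#' @rdname ntcp
#' @param dose Uniform dose in Gy.
#' @param v Irradiated volume fraction in (0, 1].
#' @export
lyman_ntcp_uniform <- function(dose, v = 1, params = lkb_params()) {
  stopifnot(inherits(params, "lkb_params"))
  if (any(v <= 0 | v > 1)) abort_validation("`v` must be in (0, 1].")
  td50_v <- params$td50_1 * v^(-params$n)
  normal_cdf((dose - td50_v) / (params$m * td50_v))
}

#' @export
print.lkb_ntcp <- function(x, ...) {
  if (x$degenerate) {
    cat("<lkb_ntcp> degenerate (no irradiated volume): NTCP = 0\n")
    return(invisible(x))
  }
  cat(sprintf("<lkb_ntcp> NTCP = %.4f  (veff = %.4f, D_ref = %.2f Gy, TD50(v) = %.2f Gy, t = %.3f)\n",
              x$ntcp, x$veff, x$d_ref, x$td50_v, x$t))
  invisible(x)
}

#' @method tidy lkb_ntcp
#' @export
tidy.lkb_ntcp <- function(x, ...) {
  tibble::tibble(structure = x$structure, ntcp = x$ntcp, veff = x$veff,
                 d_ref = x$d_ref, td50_v = x$td50_v, t = x$t,
                 degenerate = x$degenerate)
}

#' @method glance lkb_ntcp
#' @export
glance.lkb_ntcp <- function(x, ...) {
  tibble::tibble(ntcp = x$ntcp, td50_1 = x$params$td50_1, m = x$params$m,
                 n = x$params$n)
}

#' Standard normal cumulative distribution function
#'
#' The probit link of the Lyman model, `Phi(t)`, the integral of the
#' standard Gaussian density up to `t`. Delegates to [stats::pnorm()],
#' whose absolute error is far below 1e-12; arguments beyond |t| = 8
#' saturate to probabilities within 1e-15 of 0 or 1.
#'
#' @param t Probit argument (finite, vectorised).
#' @return Probability in [0, 1].
#' @export
normal_cdf <- function(t) {
  if (any(!is.finite(t))) abort_validation("`t` must be finite.")
  stats::pnorm(t)
}

#' Read a model-parameter file
#'
#' JSON or YAML of the form
#' `{tcp: {d50, gamma50}, ntcp: {td50_1, m, n}}`; missing entries fall
#' back to the package defaults.
#'
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @return A list with elements `tcp` ([tcp_params()]) and `ntcp`
#'   ([lkb_params()]).
#' @export
read_model_params <- function(path = NULL) {
  if (is.null(path)) {
    return(list(tcp = tcp_params(), ntcp = lkb_params()))
  }
  if (!file.exists(path)) abort_validation("Parameter file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  tcp_cfg <- raw$tcp %||% list()
  ntcp_cfg <- raw$ntcp %||% list()
  list(
    tcp = tcp_params(d50 = tcp_cfg$d50 %||% 67.5,
                     gamma50 = tcp_cfg$gamma50 %||% 2.0),
    ntcp = lkb_params(td50_1 = ntcp_cfg$td50_1 %||% 80,
                      m = ntcp_cfg$m %||% 0.15,
                      n = ntcp_cfg$n %||% 0.12)
  )
}
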