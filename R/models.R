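# Continuous dose-response model suite on the log2-expression scale.
# Eight models: linear, poly2, power, hill, and the nested exponential
# family exp2-exp5. Every model evaluates to its background parameter `a`
# at concentration 0. `npar` counts free model parameters (the residual
# variance adds one more in the AIC).

MODEL_IDS <- c("linear", "poly2", "power", "hill", "exp2", "exp3", "exp4", "exp5")

MODEL_NPAR <- c(linear = 2L, poly2 = 3L, power = 3L, hill = 4L,
                exp2 = 2L, exp3 = 3L, exp4 = 3L, exp5 = 4L)

EXPONENT_BOX <- c(0.5, 18)   # power p, hill n
EXP_SHAPE_BOX <- c(1, 18)    # exponential-family shape d

check_params <- function(model_id, p) {
  bad <- function(msg) abort(sprintf("%s: %s", model_id, msg))
  in_box <- function(x, box) is.finite(x) && x >= box[1] && x <= box[2]
  switch(model_id,
    linear = if (!all(is.finite(c(p$a, p$b)))) bad("non-finite parameters"),
    poly2 = if (!all(is.finite(c(p$a, p$b, p$d)))) bad("non-finite parameters"),
    power = {
      if (!in_box(p$p, EXPONENT_BOX)) bad("power exponent outside [0.5, 18]")
    },
    hill = {
      if (!in_box(p$n, EXPONENT_BOX)) bad("Hill coefficient outside [0.5, 18]")
      if (!is.finite(p$k) || p$k <= 0) bad("Hill half-max k must be > 0")
    },
    exp2 = {
      if (!is.finite(p$b) || p$b < 0) bad("rate b must be >= 0")
      if (!p$s %in% c(-1, 1)) bad("sign s must be +/-1")
    },
    exp3 = {
      if (!is.finite(p$b) || p$b < 0) bad("rate b must be >= 0")
      if (!in_box(p$d, EXP_SHAPE_BOX)) bad("shape d outside [1, 18]")
      if (!p$s %in% c(-1, 1)) bad("sign s must be +/-1")
    },
    exp4 = {
      if (!is.finite(p$b) || p$b < 0) bad("rate b must be >= 0")
      if (!is.finite(p$cc) || p$cc <= 0) bad("asymptote ratio cc must be > 0")
    },
    exp5 = {
      if (!is.finite(p$b) || p$b < 0) bad("rate b must be >= 0")
      if (!is.finite(p$cc) || p$cc <= 0) bad("asymptote ratio cc must be > 0")
      if (!in_box(p$d, EXP_SHAPE_BOX)) bad("shape d outside [1, 18]")
    },
    bad("unknown model id")
  )
  invisible(TRUE)
}

#' Evaluate a dose-response model
#'
#' Closed-form evaluation of one of the eight continuous models at
#' concentrations `conc` (µM). Forms (background `a`, concentration `c`):
#' * `linear`: `a + b c`
#' * `poly2`:  `a + b c + d c^2`
#' * `power`:  `a + b c^p`, `p` in `[0.5, 18]`
#' * `hill`:   `a + v c^n / (k^n + c^n)`, `n` in `[0.5, 18]`, `k > 0`
#' * `exp2`:   `a exp(s b c)`, sign `s = ±1`
#' * `exp3`:   `a exp(s (b c)^d)`, `d` in `[1, 18]`
#' * `exp4`:   `a (cc - (cc - 1) exp(-b c))`
#' * `exp5`:   `a (cc - (cc - 1) exp(-(b c)^d))`
#'
#' @param model_id One of `"linear"`, `"poly2"`, `"power"`, `"hill"`,
#'   `"exp2"`, `"exp3"`, `"exp4"`, `"exp5"`.
#' @param params Named list of parameters (see above).
#' @param conc Concentrations (µM, >= 0).
#' @return Expected log2 expression at each concentration.
#' @examples
#' evaluate_model("hill", list(a = 0, v = 2, n = 1, k = 10), 10) # 1
#' @export
evaluate_model <- function(model_id, params, conc) {
  model_id <- match.arg(model_id, MODEL_IDS)
  if (any(conc < 0)) abort("concentrations must be >= 0")
  p <- params
  check_params(model_id, p)
  switch(model_id,
    linear = p$a + p$b * conc,
    poly2 = p$a + p$b * conc + p$d * conc^2,
    power = p$a + p$b * ifelse(conc == 0, 0, conc^p$p),
    hill = p$a + ifelse(conc == 0, 0,
                        p$v * conc^p$n / (p$k^p$n + conc^p$n)),
    exp2 = p$a * exp(p$s * p$b * conc),
    exp3 = p$a * exp(p$s * ifelse(conc == 0, 0, (p$b * conc)^p$d)),
    exp4 = p$a * (p$cc - (p$cc - 1) * exp(-p$b * conc)),
    exp5 = p$a * (p$cc - (p$cc - 1) *
                    exp(-ifelse(conc == 0, 0, (p$b * conc)^p$d)))
  )
}

# Deterministic Latin-hypercube-style start grid on the unit cube:
# m rows, d columns; column j visits each of the m strata once, in an order
# fixed by a small prime stride.
det_lhs <- function(m, d) {
  strides <- c(1L, 3L, 7L, 5L, 11L)
  sapply(seq_len(d), function(j) {
    ord <- ((seq_len(m) - 1L) * strides[(j - 1L) %% length(strides) + 1L]) %% m
    (ord + 0.5) / m
  })
}
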