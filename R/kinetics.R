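# Kinetic laws for macroscopic reactions. Each law is one of a small set of
# proportional forms (parsimony: one or two rate constants per reaction),
# matching the kinetics used for the packaged day/night model:
#
#   zero                   alpha = 0                       (futile cycle)
#   light-proportional     alpha = k * I                   (photosynthesis)
#   mass-action-1          alpha = k * X1
#   reversible-mass-action alpha = k * X1 - k' * X2
#   product-2              alpha = k * X1 * X2 - k' * X3
#   product-3              alpha = k * X1 * X2 * X3

LAW_FORMS <- data.frame(
  form = c("zero", "light-proportional", "mass-action-1",
           "reversible-mass-action", "product-2", "product-3"),
  n_effectors = c(0L, 0L, 1L, 2L, 3L, 3L),
  n_params = c(0L, 1L, 1L, 2L, 2L, 1L),
  stringsAsFactors = FALSE
)

#' Define the kinetic law of one macroscopic reaction
#'
#' @param reaction macroscopic reaction id the law drives.
#' @param form one of `"zero"`, `"light-proportional"`, `"mass-action-1"`,
#'   `"reversible-mass-action"`, `"product-2"`, `"product-3"`.
#' @param effectors species ids entering the rate expression, in order
#'   (forward effectors first, then the reverse-term species). The
#'   light-proportional form takes irradiance, not a species.
#' @param params nonnegative rate constants, in order (forward first).
#' @param units optional character vector of unit strings, same length as
#'   `params`.
#' @return object of class `drum_law`.
#' @export
kinetic_law <- function(reaction, form, effectors = character(),
                        params = numeric(), units = NULL) {
  row <- LAW_FORMS[LAW_FORMS$form == form, ]
  if (nrow(row) == 0L) stop("unknown kinetic form '", form, "'", call. = FALSE)
  if (length(effectors) != row$n_effectors) {
    stop("form '", form, "' takes ", row$n_effectors, " effector(s), got ",
         length(effectors), call. = FALSE)
  }
  if (length(params) != row$n_params) {
    stop("form '", form, "' takes ", row$n_params, " parameter(s), got ",
         length(params), call. = FALSE)
  }
  if (any(params < 0)) stop("rate constants must be nonnegative", call. = FALSE)
  structure(list(reaction = reaction, form = form, effectors = effectors,
                 params = unname(params), units = units),
            class = "drum_law")
}

law_ids <- function(laws) vapply(laws, `[[`, "", "reaction")

#' Evaluate all macroscopic reaction rates
#'
#' Rates of reversible forms may be negative (net rate); the biomass factor
#' is *not* applied here (the ODE right-hand side multiplies by B).
#'
#' @param state named nonnegative concentration vector (mM); must cover all
#'   effectors.
#' @param I irradiance (uE m-2 s-1).
#' @param laws list of [kinetic_law()].
#' @return named rate vector alpha (one entry per law; units mM/h per mM of
#'   functional biomass).
#' @export
rate_vector <- function(state, I, laws) {
  if (any(state < -1e-9)) {
    stop("negative concentration in rate evaluation: ",
         paste(names(state)[state < -1e-9], collapse = ", "), call. = FALSE)
  }
  state <- pmax(state, 0)
  alpha <- vapply(laws, function(l) {
    e <- l$effectors
    p <- l$params
    switch(l$form,
      "zero" = 0,
      "light-proportional" = p[1L] * I,
      "mass-action-1" = p[1L] * state[[e[1L]]],
      "reversible-mass-action" = p[1L] * state[[e[1L]]] - p[2L] * state[[e[2L]]],
      "product-2" = p[1L] * state[[e[1L]]] * state[[e[2L]]] - p[2L] * state[[e[3L]]],
      "product-3" = p[1L] * state[[e[1L]]] * state[[e[2L]]] * state[[e[3L]]]
    )
  }, numeric(1L))
  names(alpha) <- law_ids(laws)
  alpha
}

#' Number of free kinetic parameters (degrees of freedom)
#'
#' Total rate constants across the laws; `zero`-form laws contribute none.
#'
#' @param laws list of [kinetic_law()].
#' @return integer.
#' @export
count_free_parameters <- function(laws) {
  sum(vapply(laws, function(l) length(l$params), integer(1L)))
}

#' Flatten law parameters into a named vector
#'
#' One-parameter laws contribute `k_<reaction>`; two-parameter laws
#' contribute `k_<reaction>` and `kp_<reaction>` (forward then reverse).
#'
#' @param laws list of [kinetic_law()].
#' @return named numeric vector, in law order.
#' @export
param_vector <- function(laws) {
  out <- numeric(0)
  for (l in laws) {
    if (length(l$params) == 0L) next
    nm <- paste0(c("k_", "kp_")[seq_along(l$params)], l$reaction)
    v <- l$params
    names(v) <- nm
    out <- c(out, v)
  }
  out
}

#' Write a parameter vector back into a law set
#'
#' @param laws list of [kinetic_law()].
#' @param params numeric vector in [param_vector()] order (names optional).
#' @return the law list with updated rate constants.
#' @export
set_params <- function(laws, params) {
  if (length(params) != count_free_parameters(laws)) {
    stop("expected ", count_free_parameters(laws), " parameters, got ",
         length(params), call. = FALSE)
  }
  i <- 0L
  for (j in seq_along(laws)) {
    n <- length(laws[[j]]$params)
    if (n == 0L) next
    laws[[j]]$params <- unname(params[i + seq_len(n)])
    i <- i + n
  }
  laws
}
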