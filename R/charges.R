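#' Statistical charge weights from vertical ionization potentials
#'
#' When a hot ion breaks apart, the single positive charge is shared
#' statistically among the fragments: each fragment's weight is the
#' Boltzmann factor of its vertical IP at the average fragment
#' temperature,
#' `C_i = exp(-IP_i / (kB * T_av)) / sum_j exp(-IP_j / (kB * T_av))`.
#' Computed shift-stably (the minimum IP is subtracted before
#' exponentiation, which leaves the weights unchanged).  At `T_av -> 0`
#' all weight collapses onto the minimum-IP fragment, ties split equally;
#' nonpositive temperatures are treated as that limit with a warning.
#' The functional form is pluggable via the `weight_fn` argument of
#' [assign_and_select()].
#'
#' @param ips Numeric vector of vertical IPs, eV (>= 1 fragment).
#' @param t_av Average fragment temperature, K.
#' @return Numeric weights summing to 1.
#' @export
#' @examples
#' statistical_weights(c(8, 9), 5000)
statistical_weights <- function(ips, t_av) {
  if (!length(ips)) stop("empty IP list", call. = FALSE)
  if (t_av <= 0) {
    warning("nonpositive average temperature; using the zero-T limit")
    winners <- abs(ips - min(ips)) < 1e-12
    return(ifelse(winners, 1 / sum(winners), 0))
  }
  z <- exp(-(ips - min(ips)) / (.KB * t_av))
  z / sum(z)
}

#' Assign statistical charges and select the cascade survivor
#'
#' Multiplies each fragment's weight by the charge carried into the event
#' (`parent_weight`), selects the highest-charge fragment for further
#' cascade propagation (ties broken by lower fragment index, for
#' determinism), and returns the non-selected fragments as stored
#' records.  If the selected fragment is a single atom or the cascade
#' depth cap is reached, it terminates the cascade and is returned among
#' the stored records with `next_record = NULL`.
#'
#' @param fragments List of [fragment_record()]s from one fragmentation
#'   event (IPs and temperatures filled in).
#' @param parent_weight Charge entering the event, in (0, 1].
#' @param t_av Average fragment temperature; defaults to the unweighted
#'   mean of the records' temperatures.
#' @param depth_cap Maximum cascade depth (default 6).
#' @param weight_fn Weight rule `function(ips, t_av)`; defaults to
#'   [statistical_weights()].
#' @return List with `records` (stored [fragment_record()]s) and `next_record`
#'   (the cascade continuation, or `NULL`).
#' @export
assign_and_select <- function(fragments, parent_weight,
                              t_av = NULL, depth_cap = 6L,
                              weight_fn = statistical_weights) {
  stopifnot(parent_weight > 0, parent_weight <= 1 + 1e-12)
  ips <- vapply(fragments, function(f) f$vertical_ip, numeric(1))
  if (is.null(t_av))
    t_av <- mean(vapply(fragments, function(f) f$temperature, numeric(1)))
  w <- weight_fn(ips, t_av)
  for (i in seq_along(fragments))
    fragments[[i]]$statistical_charge <- parent_weight * w[i]
  sel <- which.max(w)  # which.max takes the first maximum: lower index wins
  terminal <- n_atoms(fragments[[sel]]$mol) == 1L ||
    fragments[[sel]]$cascade_depth >= depth_cap ||
    length(fragments) == 1L
  if (terminal) {
    list(records = fragments, next_record = NULL)
  } else {
    list(records = fragments[-sel], next_record = fragments[[sel]])
  }
}
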