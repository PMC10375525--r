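#' Timescale of donor-to-acceptor energy transfer from lifetime shortening
#'
#' A donor whose excited state decays with lifetime `tau_D` in isolation and
#' `tau_DA` in the presence of acceptors has gained one extra depopulation
#' channel; its timescale follows from the rate balance
#' `1/tau_DA = 1/tau_D + 1/tau_T`, i.e.
#' `tau_T = 1 / (1/tau_DA - 1/tau_D)`. When `tau_DA >= tau_D` no transfer is
#' resolvable and `Inf` is returned (flagged), never a negative timescale.
#'
#' @param tau_DA Donor lifetime with acceptor present, ns (> 0).
#' @param tau_D Donor reference lifetime without acceptor, ns (> 0).
#' @return Transfer timescale in ns; `Inf` with attribute
#'   `no_transfer = TRUE` when the donor is not quenched.
#' @export
#' @examples
#' transfer_timescale(3.126, 3.933) # ~15 ns for the coupled-disk system
transfer_timescale <- function(tau_DA, tau_D) {
  if (!is.finite(tau_DA) || tau_DA <= 0 || !is.finite(tau_D) || tau_D <= 0)
    stop("lifetimes must be positive and finite", call. = FALSE)
  if (tau_DA >= tau_D)
    return(structure(Inf, no_transfer = TRUE))
  1 / (1 / tau_DA - 1 / tau_D)
}

#' Rate of energy transfer
#'
#' The transfer rate is the inverse of the transfer timescale; an infinite
#' timescale (no resolvable transfer) maps to rate 0.
#'
#' @param tau_T Transfer timescale in ns (> 0, or `Inf` for no transfer).
#' @return Rate in 1/ns.
#' @export
transfer_rate <- function(tau_T) {
  if (is.na(tau_T) || tau_T < 0)
    stop("`tau_T` must be positive (or Inf for no transfer)", call. = FALSE)
  if (is.infinite(tau_T)) return(0)
  if (tau_T == 0) stop("`tau_T` must be positive", call. = FALSE)
  1 / tau_T
}

#' FRET efficiency from donor lifetime shortening
#'
#' `E = 1 - tau_DA / tau_D`: the fraction of donor excitations handed to the
#' acceptor. An unquenched donor (`tau_DA >= tau_D`) gives a non-positive
#' raw value, reported as 0 with attribute `no_transfer = TRUE`.
#'
#' @param tau_DA Donor lifetime with acceptor present, ns (> 0).
#' @param tau_D Donor reference lifetime, ns (> 0).
#' @return Efficiency as a fraction in `[0, 1)`.
#' @export
#' @examples
#' fret_efficiency(3.126, 3.933) # ~0.21
fret_efficiency <- function(tau_DA, tau_D) {
  if (!is.finite(tau_DA) || tau_DA <= 0 || !is.finite(tau_D) || tau_D <= 0)
    stop("lifetimes must be positive and finite", call. = FALSE)
  e <- 1 - tau_DA / tau_D
  if (e <= 0) return(structure(0, no_transfer = TRUE))
  e
}

#' Full lifetime-based FRET estimate for one donor/acceptor comparison
#'
#' Bundles the transfer timescale, rate and efficiency derived from a pair
#' of donor lifetimes, with provenance labels recording which samples (and
#' which component-averaging scheme) supplied them.
#'
#' @param tau_DA,tau_D Lifetimes in ns.
#' @param tau_DA_source,tau_D_source Labels recording where each lifetime
#'   came from (sample name, averaging scheme, ...).
#' @return A `fret_estimate` list with fields `tau_D`, `tau_DA`, `tau_T`,
#'   `k_T`, `E`, `no_transfer` and the provenance labels.
#' @export
#' @examples
#' fret_estimate(3.126, 3.933,
#'               tau_DA_source = "coupled donor-acceptor disks",
#'               tau_D_source = "donor-only disks")
fret_estimate <- function(tau_DA, tau_D, tau_DA_source = "donor+acceptor",
                          tau_D_source = "donor only") {
  tau_T <- transfer_timescale(tau_DA, tau_D)
  structure(list(tau_D = tau_D, tau_DA = tau_DA,
                 tau_T = as.numeric(tau_T),
                 k_T = transfer_rate(tau_T),
                 E = as.numeric(fret_efficiency(tau_DA, tau_D)),
                 no_transfer = is.infinite(tau_T),
                 tau_DA_source = tau_DA_source,
                 tau_D_source = tau_D_source),
            class = "fret_estimate")
}

#' @export
print.fret_estimate <- function(x, ...) {
  cat("Lifetime-based FRET estimate\n")
  cat(sprintf("  tau_D  = %.4g ns  (%s)\n", x$tau_D, x$tau_D_source))
  cat(sprintf("  tau_DA = %.4g ns  (%s)\n", x$tau_DA, x$tau_DA_source))
  if (x$no_transfer) {
    cat("  no resolvable transfer (tau_DA >= tau_D)\n")
  } else {
    cat(sprintf("  tau_T  = %s ns   (%.4g ns unrounded)\n",
                report_format(x$tau_T, "timescale"), x$tau_T))
    cat(sprintf("  k_T    = %s 1/ns (%.4g unrounded)\n",
                report_format(x$k_T, "rate"), x$k_T))
    cat(sprintf("  E      = %s%%    (%.4g unrounded)\n",
                report_format(x$E, "efficiency"), x$E))
  }
  invisible(x)
}

#' Apportion a total transfer rate across geometric pathways
#'
#' Splits the disk-to-disk transfer rate over individual donor-acceptor
#' pairs in proportion to their distance-only weights: `k_i = p_i * k_T`.
#'
#' @param k_T Total transfer rate in 1/ns (>= 0).
#' @param table A [pathway_table()] whose weights sum to 1.
#' @return The table with an extra `rate_per_ns` column.
#' @export
apportion_pathways <- function(k_T, table) {
  if (!is.finite(k_T) || k_T < 0)
    stop("`k_T` must be a non-negative rate", call. = FALSE)
  if (!inherits(table, "pathway_table") && !is.data.frame(table))
    stop("`table` must be a pathway_table", call. = FALSE)
  if (is.null(table$weight) || abs(sum(table$weight) - 1) > 1e-9)
    stop("pathway table is not normalized (weights must sum to 1)",
         call. = FALSE)
  table$rate_per_ns <- table$weight * k_T
  table
}

#' Foerster rate for a single donor-acceptor pair
#'
#' The textbook distance scaling `k(R) = (1/tau_D) * (R0 / R)^6`, where `R0`
#' is the Foerster radius (distance of 50% transfer efficiency).
#'
#' @param R Donor-acceptor distance in nm (> 0).
#' @param R0 Foerster radius in nm (> 0).
#' @param tau_D Donor lifetime in ns (> 0).
#' @return Pairwise transfer rate in 1/ns.
#' @export
forster_pair_rate <- function(R, R0, tau_D) {
  if (any(!is.finite(c(R, R0, tau_D))) || any(c(R, R0, tau_D) <= 0))
    stop("all arguments must be positive and finite", call. = FALSE)
  (1 / tau_D) * (R0 / R)^6
}

#' Round a FRET quantity to reporting precision
#'
#' Centralised rounding rules used in printed reports: rates to three
#' decimals (0.0657 -> "0.066"), timescales to the nearest ns
#' (15.22 -> "15"), efficiencies to whole percent (0.205 -> "21").
#'
#' @param x Value: rate in 1/ns, timescale in ns, or efficiency as a
#'   fraction.
#' @param quantity One of `"rate"`, `"timescale"`, `"efficiency"`.
#' @return Character scalar.
#' @export
report_format <- function(x, quantity = c("rate", "timescale",
                                         "efficiency")) {
  quantity <- match.arg(quantity)
  # report-style rounding: halves away from zero, not to even
  half_up <- function(x, digits) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
  }
  switch(quantity,
         rate = sprintf("%.3f", half_up(x, 3)),
         timescale = sprintf("%.0f", half_up(x, 0)),
         efficiency = sprintf("%.0f", half_up(100 * x, 0)))
}
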