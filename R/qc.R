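#' Quality-control filter for recorded cells
#'
#' Applies the exclusion rules exactly as stated for the recordings:
#' cells with a resting potential above -57 mV, an AP amplitude below
#' 75 mV, or a bridge balance above 22 MOhm are excluded (strict
#' inequalities), as are cells manually flagged as putative interneurons.
#' All violated rules are enumerated.
#'
#' @param v_m resting membrane potential, mV.
#' @param ap_amplitude AP amplitude, mV.
#' @param bridge_balance bridge balance, MOhm.
#' @param putative_interneuron manual flag.
#' @param config an [ephys_config()] carrying the bounds.
#' @return List with `included` (logical) and `reasons` (character vector,
#'   empty iff included).
#' @export
qc_filter <- function(v_m, ap_amplitude, bridge_balance,
                      putative_interneuron = FALSE,
                      config = ephys_config()) {
  reasons <- character(0)
  if (is.finite(v_m) && v_m > config$qc_vm_max)
    reasons <- c(reasons, "depolarized_Vm")
  if (is.finite(ap_amplitude) && ap_amplitude < config$qc_amp_min)
    reasons <- c(reasons, "low_AP_amplitude")
  if (is.finite(bridge_balance) && bridge_balance > config$qc_bridge_max)
    reasons <- c(reasons, "high_bridge_balance")
  if (isTRUE(putative_interneuron))
    reasons <- c(reasons, "putative_interneuron_flagged_manually")
  list(included = length(reasons) == 0L, reasons = reasons)
}

#' Percentage of a count, rounded as printed in reports
#'
#' Worked-example arithmetic for classification fractions: `100 * k / n`
#' rounded to the requested number of digits.
#'
#' @param k count of positives.
#' @param n total count.
#' @param digits decimal digits to round to.
#' @return Numeric percentage.
#' @export
fraction_percent <- function(k, n, digits = 0) {
  stopifnot(n > 0, k >= 0, k <= n)
  round(100 * k / n, digits)
}
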