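#' Delta-delta-Ct genotyping arithmetic
#'
#' Relative quantification of a transgene against a normalization gene,
#' referenced to a known homozygous sample:
#' \deqn{\Delta\Delta C_T = (C_T^{target} - C_T^{norm}) -
#'       (C_T^{target,ref} - C_T^{norm,ref})}
#' with relative quantity \eqn{2^{-\Delta\Delta C_T}}. The genotype call is
#' the nearest of relative quantity 0 (negative), 0.5 (hemizygous) and
#' 1 (homozygous); an undetermined target with a detected normalizer is
#' called negative directly.
#'
#' @param ct_target,ct_norm sample Ct values (target gene, normalizer);
#'   `ct_target = NA` encodes "undetermined".
#' @param ct_target_ref,ct_norm_ref reference (known homozygous) Ct values.
#' @return List with `ddct`, `relative_quantity`, `call` (one of
#'   `"negative"`, `"hemizygous"`, `"homozygous"`).
#' @export
ddct_genotype <- function(ct_target, ct_norm, ct_target_ref, ct_norm_ref) {
  if (!is.finite(ct_norm))
    stop_ecs("malformed_input", "normalizer Ct must be detected")
  if (!is.finite(ct_target_ref) || !is.finite(ct_norm_ref))
    stop_ecs("malformed_input", "reference Ct values must be finite")
  if (!is.finite(ct_target))
    return(list(ddct = NA_real_, relative_quantity = 0, call = "negative"))
  ddct <- (ct_target - ct_norm) - (ct_target_ref - ct_norm_ref)
  rq <- 2^(-ddct)
  calls <- c(negative = 0, hemizygous = 0.5, homozygous = 1)
  call <- names(calls)[which.min(abs(calls - rq))]
  list(ddct = ddct, relative_quantity = rq, call = call)
}
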