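#' Reference values from the motivating bonnethead shark study
#'
#' Small plain-text tables bundled with the package: the median AIC scores of
#' the seven simple demographic models compared on the bonnethead shark
#' two-bay dataset (Tampa Bay vs Biscayne Bay), and the best-fit demographic
#' parameters in physical units. They serve as worked-example inputs for
#' [rank_models()] and [to_physical()].
#'
#' @param which `"medians"` (model, description, median_AIC) or `"bestfit"`
#'   (quantity, value).
#' @return data.frame.
#' @export
bonnethead_reference <- function(which = c("medians", "bestfit")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("bonnethead_",
                          if (which == "medians") "model_medians" else "bestfit",
                          ".tsv"),
                   package = "jointsfs", mustWork = TRUE)
  read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Best-fit model of the bonnethead study in genetic units
#'
#' Converts the bundled physical-unit best-fit row back to the genetic units
#' used by the engine (theta, nu, T, M), via the same conversion definitions
#' as [to_physical()]. Useful as a worked example and as the generator preset.
#'
#' @param G generation time in years used for the time conversion.
#' @return list with `fit` (model name, `par`, `theta_hat`, suitable for
#'   [to_physical()]) and `scale` (a [physical_scale()]).
#' @export
bonnethead_bestfit_genetic <- function(G = 4) {
  b <- bonnethead_reference("bestfit")
  v <- setNames(b$value, b$quantity)
  Ne <- v[["Ne_anc"]]
  mu <- v[["mu_per_base_per_generation"]]
  L <- v[["sfs_total_sites"]]
  par <- c(nuA = v[["Ne_after_ancestral_growth"]] / Ne,
           TA = (v[["ancestral_growth_onset_years"]] - v[["split_years_G4"]]) /
             (2 * Ne * G),
           nu1 = v[["Ne_current_tampa"]] / Ne,
           nu2 = v[["Ne_current_biscayne"]] / Ne,
           T = v[["split_years_G4"]] / (2 * Ne * G),
           M12 = 2 * Ne * v[["m_tampa_to_biscayne"]])
  list(fit = list(model = "gadma_best", par = par,
                  theta_hat = 4 * Ne * mu * L),
       scale = physical_scale(mu = mu, G = G, L = L))
}
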