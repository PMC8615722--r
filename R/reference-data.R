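#' Published free-energy components for the Hfq-OxyS worked example
#'
#' Per-trajectory MM/GBSA enthalpies and interaction-entropy terms (kcal/mol)
#' reported for the Hfq protein bound to the two A-rich OxyS linker fragments
#' (Ads, Aus) and their N48A mutants, three independent trajectories each.
#' These printed values serve as inputs to the aggregation layer
#' ([binding_free_energy()], [average_and_ddg()], [result_table()]): the
#' package's worked example reproduces the published dG column, per-system
#' averages and mutant-wild ddG from them. The `dg` column is the published
#' one; note two rows differ by 0.1 kcal/mol from `dh + minus_tds` because
#' the source rounded each column independently.
#'
#' @return data.frame with columns `system`, `trajectory`, `dh`, `se_dh`,
#'   `minus_tds`, `dg`, plus attributes `averages` (published per-system
#'   average dG) and `ddg` (published mutant-wild differences).
#' @export
hfq_oxys_reference <- function() {
  df <- data.frame(
    system = rep(c("Ads", "Ads_N48A", "Aus", "Aus_N48A"), each = 3),
    trajectory = rep(1:3, 4),
    dh = c(-62.4, -60.3, -62.4, -65.4, -66.5, -64.1,
           -61.3, -64.2, -67.5, -68.7, -67.7, -65.8),
    se_dh = c(0.4, 0.5, 0.5, 0.4, 0.4, 0.3, 0.4, 0.4, 0.4, 0.4, 0.3, 0.4),
    minus_tds = c(33.8, 35.1, 33.3, 36.5, 38.2, 31.5,
                  30.7, 32.7, 40.4, 37.8, 33.3, 37.1),
    dg = c(-28.6, -25.2, -29.2, -28.9, -28.3, -32.6,
           -30.6, -31.5, -27.2, -30.9, -34.4, -28.7))
  attr(df, "averages") <- c(Ads = -27.7, Ads_N48A = -29.9,
                            Aus = -29.7, Aus_N48A = -31.3)
  attr(df, "ddg") <- c(Ads_N48A = -2.2, Aus_N48A = -1.6)
  df
}
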