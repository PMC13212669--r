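# Published backward-selection trace of the RFI pig blood RNA-seq dataset
# (E-MTAB-4179): 13 candidate covariates in removal order with the relevance
# value recorded at each removal.
rfi_backward_trace <- function() {
  selection_path(
    covariates = c("RINb", "Eosi", "Order", "Conca", "Diet", "RFI", "Lymp",
                   "Baso", "RINa", "Block", "Neut", "Concb", "Mono"),
    r = c(0.26, 0.49, 0.62, 0.65, 0.53, 2.07, 2.87, 3.46, 6.3, 7.71, 7.85,
          9.42, 11.45),
    primary = "Line")
}
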