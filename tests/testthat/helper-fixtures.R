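# Shared fixtures, built once per test run.

tiso <- build_tisochrysis_model()

# packaged model with CO2 tracked as a dynamic species (closed-system runs)
tiso_open_co2 <- function() {
  suppressWarnings(assemble_reduced_model(
    tiso$model$macro_reactions,
    accumulating = tiso$model$accumulating,
    biomass = "B",
    drop = tiso$model$dropped,
    clamp = setdiff(tiso$model$clamped, "CO2"),
    substrates = "NO3"))
}

mr8_only_network <- function() {
  line <- grep("^MR8", readLines(system.file("extdata",
                                             "tisochrysis_reactions.txt",
                                             package = "drumr")), value = TRUE)
  parse_reaction_table(line)
}
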