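# Small hand-built models used across tests. All are carbon-free unless
# stated; the toy generator supplies the carbon-balanced ones.

# A 1-D segment region: SRC fixed at 1 feeds A; A2B (the free coordinate,
# range [0, 1]) converts A to B which exits through BIOMASS; SINK_A takes
# the rest. Flux space is the segment {A2B = BIOMASS in [0,1]}.
segment_model <- function() {
  metabolic_model(
    reactions = c("SRC", "A2B", "SINK_A", "BIOMASS"),
    metabolites = c("A", "B"),
    S = matrix(c(1, 0, -1, 1, -1, 0, 0, -1), 2, 4,
               dimnames = list(c("A", "B"),
                               c("SRC", "A2B", "SINK_A", "BIOMASS"))),
    lower = c(1, 0, 0, 0), upper = c(1, 1000, 1000, 1000),
    biomass = "BIOMASS")
}

# A 2-simplex region: U fixed at 1 feeds A; X and Y drain it (the free
# coordinates, x + y <= 1 with x, y >= 0), SL takes the slack. BIOMASS taps
# a negligible fraction so the model has a growth flux.
simplex_model <- function() {
  metabolic_model(
    reactions = c("U", "X", "Y", "SL", "BIOMASS"),
    metabolites = c("A", "B"),
    S = matrix(c(1, 0, -1, 0.001, -1, 0.001, -1, 0, 0, -1), 2, 5,
               dimnames = list(c("A", "B"),
                               c("U", "X", "Y", "SL", "BIOMASS"))),
    lower = c(1, 0, 0, 0, 0), upper = c(1, 1000, 1000, 1000, 1000),
    biomass = "BIOMASS")
}

# Linear chain: uptake <= 10 glucose-like substrate, unit biomass yield.
chain_model <- function(uptake = 10, yield_ = 1) {
  make_toy_model(toy_spec(n_pathways = 1, yields = yield_,
                          uptake_limit = uptake, secretion = FALSE))$model
}

# Model with GPR rules: PWY1 needs (g1 or g2), PWY2 needs (g3 and g4).
gpr_toy_model <- function() {
  toy <- make_toy_model(toy_spec(n_pathways = 2, yields = c(1, 1),
                                 uptake_limit = 10, secretion = FALSE))
  m <- toy$model
  m$gpr <- c(PWY1 = "(g1 or g2)", PWY2 = "(g3 and g4)")
  m$genes <- c("g1", "g2", "g3", "g4")
  m
}
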