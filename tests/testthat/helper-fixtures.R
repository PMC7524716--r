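# small shared fixtures; everything generated in code at test time

fix_forcing <- function(years = 1, seed = 42, ...) {
  gen_forcing(years = years, seed = seed, ...)
}

fix_state <- function() mend_state()

# a state with every pool occupied, for flux fixtures
fix_rich_state <- function() {
  mend_state(p_ox = 2, p_hyd = 3, mom = 5, qom = 0.5, dom = 0.2,
             b_active = 0.3, b_dormant = 0.1,
             enz_ox = 0.02, enz_hyd = 0.03, enz_mom = 0.01)
}
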