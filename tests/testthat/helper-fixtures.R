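# Shared fixtures: the measured steady-state tables of the enrichment
# culture and the default reactor configuration.

ref_rates <- chemostat_rates()
ref_yields <- chemostat_yields()
ref_cfg <- chemostat_config()

# trapezoid rule, used as an independent quadrature oracle
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
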