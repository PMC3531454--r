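# Regenerates the bundled default parameter map (inst/extdata/param_map_default.json).
# Run from the repository root:  Rscript tools/make_default_map.R
library(caspike)
map <- fit_parameter_maps(cell_params(), n_samples = 1e4, seed = 20121227L)
print(map)
param_map_write(map, "inst/extdata/param_map_default.json")
cat("written inst/extdata/param_map_default.json\n")
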