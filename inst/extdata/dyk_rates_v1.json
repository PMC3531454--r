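{
  "version": 1,
  "model": "De Young-Keizer IP3 receptor subunit scheme (8 states per subunit)",
  "units": {"association": "uM^-1 s^-1", "dissociation_constant": "uM"},
  "sites": {
    "ip3": "site 1, association a1 (inhibitory site empty) or a3 (occupied)",
    "ca_inhibitory": "association a2 (IP3 bound) or a4 (IP3 unbound)",
    "ca_activating": "site 5, association a5, independent of other sites"
  },
  "association": {"a1": 400, "a2": 0.2, "a3": 400, "a4": 0.2, "a5": 20},
  "dissociation_constant": {"d1": 0.13, "d2": 1.049, "d3": 0.9434,
                            "d4": 0.1445, "d5": 0.08234},
  "subunits_per_channel": 4,
  "open_subunit_threshold": 3,
  "active_subunit_state": {"ip3_bound": 1, "ca_activating_bound": 1,
                           "ca_inhibitory_bound": 0},
  "note": "Dissociation rates are b_i = a_i * d_i; the scheme satisfies detailed balance d1*d2 = d3*d4."
}
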